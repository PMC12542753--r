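#' Classifier configuration for half-maximum temporal grouping
#'
#' A gene's temporal class is decided by the first timepoint at which its
#' percent-of-maximum expression reaches the half-maximum threshold, and by
#' whether it later falls back below that threshold:
#' reached by `early_deadline` minutes -> early; by `middle_deadline` ->
#' middle (or middle-down if any strictly later timepoint drops below the
#' threshold); later -> late.
#'
#' @param half_max_threshold percent-of-max threshold (default 50; reaching
#'   it is inclusive, `>=`).
#' @param early_deadline minutes; latest half-max time for "early"
#'   (default 20).
#' @param middle_deadline minutes; latest half-max time for "middle"/"middle
#'   -down" (default 60).
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(half_max_threshold = 50, early_deadline = 20,
                              middle_deadline = 60) {
  stopifnot(half_max_threshold > 0, half_max_threshold < 100,
            early_deadline < middle_deadline)
  structure(list(half_max_threshold = half_max_threshold,
                 early_deadline = early_deadline,
                 middle_deadline = middle_deadline),
            class = "classifier_config")
}

#' Temporal class of one expression profile
#'
#' Applies the half-maximum rule to a percent-of-maximum profile. Unexpressed
#' profiles (all-`NA` percent vector or `expressed = FALSE`) return
#' `"unclassified"` rather than an error. A gene classified early that later
#' drops below the threshold keeps the early label (the "-down" variant only
#' exists for the middle group) but is flagged with `early_drop = TRUE` as an
#' advisory.
#'
#' @param pct_of_max numeric vector of percent-of-max values.
#' @param timepoints matching vector of minutes post-infection.
#' @param config a [classifier_config()].
#' @param expressed logical; when `FALSE` the profile is unclassified.
#' @return list with `label` (one of `"early"`, `"middle"`, `"middle_down"`,
#'   `"late"`, `"unclassified"`), `t_half` (minutes, `NA` if unclassified)
#'   and `early_drop`.
#' @examples
#' tp <- c(5, 20, 60, 120, 180, 300)
#' classify_profile(c(5, 20, 100, 40, 30, 20), tp)$label  # "middle_down"
#' @export
classify_profile <- function(pct_of_max, timepoints,
                             config = classifier_config(),
                             expressed = TRUE) {
  stopifnot(length(pct_of_max) == length(timepoints))
  if (!isTRUE(expressed) || all(is.na(pct_of_max)))
    return(list(label = "unclassified", t_half = NA_real_,
                early_drop = FALSE))
  thr <- config$half_max_threshold
  reached <- which(pct_of_max >= thr)
  if (!length(reached))   # cannot happen for a true pct-of-max profile
    return(list(label = "unclassified", t_half = NA_real_,
                early_drop = FALSE))
  i_half <- reached[1]
  t_half <- timepoints[i_half]
  later <- seq_along(timepoints) > i_half
  drops <- any(pct_of_max[later] < thr)
  if (t_half <= config$early_deadline) {
    label <- "early"
  } else if (t_half <= config$middle_deadline) {
    label <- if (drops) "middle_down" else "middle"
  } else {
    label <- "late"
  }
  list(label = label, t_half = t_half,
       early_drop = label == "early" && drops)
}

#' Classify every feature of a profile set
#'
#' @param profiles a [temporal_profiles()] object.
#' @param config a [classifier_config()].
#' @return data.frame with one row per feature (`feature_id`, `label`,
#'   `t_half`, `early_drop`) and a `"summary"` attribute giving per-label
#'   counts and percentages over all features (including unclassified);
#'   retrieve it with [class_summary()].
#' @export
classify_all <- function(profiles, config = classifier_config()) {
  ids <- profiles$feature_id
  if (anyDuplicated(ids))
    stop("duplicate feature_id in profiles: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  res <- lapply(seq_along(ids), function(i)
    classify_profile(profiles$pct_of_max[i, ], profiles$timepoints, config,
                     expressed = profiles$expressed[i]))
  out <- data.frame(feature_id = ids,
                    label = vapply(res, `[[`, character(1), "label"),
                    t_half = vapply(res, `[[`, numeric(1), "t_half"),
                    early_drop = vapply(res, `[[`, logical(1), "early_drop"),
                    stringsAsFactors = FALSE)
  lv <- c("early", "middle", "middle_down", "late", "unclassified")
  counts <- table(factor(out$label, levels = lv))
  summary <- data.frame(label = lv, count = as.integer(counts),
                        pct = round(100 * as.integer(counts) / nrow(out), 1))
  attr(out, "summary") <- summary
  out
}

#' Per-class summary of a classification
#'
#' @param classes result of [classify_all()].
#' @return data.frame with `label`, `count` and `pct` (percent of all
#'   features, one decimal).
#' @export
class_summary <- function(classes) attr(classes, "summary")

#' Export a classification as TSV
#'
#' @param classes result of [classify_all()].
#' @param profiles the matching [temporal_profiles()] (adds the percent-of-max
#'   vector per feature); optional.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_class_table <- function(classes, path, profiles = NULL) {
  df <- classes
  if (!is.null(profiles)) {
    stopifnot(identical(profiles$feature_id, classes$feature_id))
    for (i in seq_along(profiles$timepoints))
      df[[sprintf("pct_t%g", profiles$timepoints[i])]] <-
        round(profiles$pct_of_max[, i], 3)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
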