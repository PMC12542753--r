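#' Assemble features into transcriptional units (operons)
#'
#' Greedy chaining in transcription order, per strand. A feature joins the
#' unit of its predecessor iff
#' (i) the intergenic gap is at most `gap_max` nt (overlaps allowed);
#' (ii) both have the same temporal class (middle and middle-down count as
#' different classes); and
#' (iii) coverage is continuous over the unit's transcribed span: at the
#' span's peak timepoint at least `continuity_frac` of bases have
#' replicate-averaged depth >= `continuity_min_cov`.
#' Independent of (i)-(iii), a detected promoter between the two features
#' forces a split: a sense TSS in the intergenic gap starts a new unit, and
#' an internal-sense TSS inside the downstream feature starts a new unit at
#' that TSS, with the feature kept in the downstream unit and flagged as
#' 5'-truncated (its mRNA from that promoter lacks the 5' part of the ORF).
#'
#' Each unit is then matched to its leading TSS: the internal TSS that
#' initiated it, or the nearest sense TSS within `upstream_max` nt upstream
#' of the first member's 5' end. Units with no assignable TSS are flagged
#' `orphan`. Only classified features (label not `"unclassified"`) are
#' assembled; each appears in exactly one unit.
#'
#' @param ann a [genome_annotation()].
#' @param classes result of [classify_all()] (or a data.frame with
#'   `feature_id` and `label` covering every feature).
#' @param exp a [coverage_experiment()] (for the continuity criterion).
#' @param tss oriented TSS data.frame from [detect_tss_both()] /
#'   [orient_tss()].
#' @param gap_max maximal intergenic gap within a unit (default 30 nt).
#' @param continuity_frac minimal covered fraction of the transcribed span
#'   (default 0.9).
#' @param continuity_min_cov depth that counts as covered (default 5).
#' @param upstream_max maximal TSS-to-start distance for the leading TSS
#'   (default 250 nt).
#' @return an object of class `operon_set`: a list of units, each a list
#'   with `operon_id`, `members` (feature ids in transcription order),
#'   `strand`, `leading_tss` (position or `NA`), `internal_promoter`,
#'   `first_member_truncated`, `class_label`, `monocistronic`, `orphan`.
#' @export
assemble_operons <- function(ann, classes, exp, tss, gap_max = 30,
                             continuity_frac = 0.9, continuity_min_cov = 5,
                             upstream_max = 250) {
  f <- ann$features
  lab <- classes$label[match(f$feature_id, classes$feature_id)]
  if (anyNA(lab))
    stop("class map missing feature(s): ",
         paste(f$feature_id[is.na(lab)], collapse = ", "))
  keep <- lab != "unclassified"
  f <- f[keep, , drop = FALSE]
  lab <- lab[keep]
  if (!nrow(f)) return(structure(list(), class = "operon_set"))

  repavg <- list("+" = replicate_mean_tracks(exp, "+"),
                 "-" = replicate_mean_tracks(exp, "-"))
  cum <- lapply(repavg, function(m) apply(m, 2, function(v) c(0, cumsum(v))))
  cum_cov <- lapply(repavg, function(m)
    apply(m, 2, function(v) c(0, cumsum(v >= continuity_min_cov))))

  continuity_ok <- function(s, lo, hi) {
    span <- hi - lo + 1
    ti <- which.max(cum[[s]][hi + 1L, ] - cum[[s]][lo, ])
    frac <- (cum_cov[[s]][hi + 1L, ti] - cum_cov[[s]][lo, ti]) / span
    frac >= continuity_frac
  }
  sense_tss <- tss[!is.na(tss$orientation) & tss$orientation == "sense", ,
                   drop = FALSE]
  internal_tss <- tss[!is.na(tss$orientation) &
                        tss$orientation == "internal_sense", , drop = FALSE]
  # 5'-most internal promoter inside a feature, if any
  internal_in <- function(feat) {
    hit <- internal_tss[internal_tss$strand == feat$strand &
                          internal_tss$position >= feat$start &
                          internal_tss$position <= feat$end, , drop = FALSE]
    if (!nrow(hit)) return(NA_integer_)
    if (feat$strand == "+") min(hit$position) else max(hit$position)
  }
  sense_in_gap <- function(s, lo, hi) {
    if (hi < lo) return(FALSE)
    any(sense_tss$strand == s & sense_tss$position >= lo &
          sense_tss$position <= hi)
  }

  units <- list()
  for (s in c("+", "-")) {
    idx <- which(f$strand == s)
    if (!length(idx)) next
    idx <- idx[order(f$start[idx])]
    if (s == "-") idx <- rev(idx)   # transcription order
    cur <- NULL
    flush <- function() if (!is.null(cur)) units[[length(units) + 1L]] <<- cur
    for (i in idx) {
      feat <- f[i, , drop = FALSE]
      ip <- internal_in(feat)
      if (is.null(cur)) {
        cur <- new_unit(feat, lab[i], ip)
        next
      }
      a <- cur$last
      gap <- if (s == "+") feat$start - a$end - 1L else a$start - feat$end - 1L
      gap_lo <- if (s == "+") a$end + 1L else feat$end + 1L
      gap_hi <- if (s == "+") feat$start - 1L else a$start - 1L
      force_split <- !is.na(ip) || sense_in_gap(s, gap_lo, gap_hi)
      span_lo <- if (s == "+") cur$tx_start else feat$start
      span_hi <- if (s == "+") feat$end else cur$tx_start
      ok <- !force_split && gap <= gap_max && cur$class_label == lab[i] &&
        continuity_ok(s, span_lo, span_hi)
      if (ok) {
        cur$members <- c(cur$members, feat$feature_id)
        cur$last <- feat
      } else {
        flush()
        cur <- new_unit(feat, lab[i], ip)
      }
    }
    flush()
  }
  # genome order, ids, leading TSS
  first_pos <- vapply(units, function(u) u$first_start, numeric(1))
  units <- units[order(first_pos)]
  for (k in seq_along(units)) {
    u <- units[[k]]
    u$operon_id <- sprintf("op%02d", k)
    if (is.na(u$leading_tss)) {
      cand <- sense_tss[sense_tss$strand == u$strand, , drop = FALSE]
      d <- if (u$strand == "+") u$tx_start - cand$position else
        cand$position - u$tx_start
      hit <- which(d >= 1 & d <= upstream_max)
      if (length(hit)) u$leading_tss <- cand$position[hit[which.min(d[hit])]]
    }
    u$orphan <- is.na(u$leading_tss)
    u$monocistronic <- length(u$members) == 1L
    u$last <- NULL
    units[[k]] <- u
  }
  structure(units, class = "operon_set")
}

new_unit <- function(feat, label, internal_pos) {
  has_ip <- !is.na(internal_pos)
  tx_start <- if (has_ip) internal_pos else
    if (feat$strand == "+") feat$start else feat$end
  list(operon_id = NA_character_,
       members = feat$feature_id,
       strand = as.character(feat$strand),
       leading_tss = if (has_ip) internal_pos else NA_integer_,
       internal_promoter = has_ip,
       first_member_truncated = has_ip,
       class_label = label,
       monocistronic = NA,
       orphan = NA,
       tx_start = tx_start,
       first_start = feat$start,
       last = feat)
}

#' @export
print.operon_set <- function(x, ...) {
  s <- summarize_operons(x)
  cat(sprintf(paste0("<operon_set> %d unit(s), %d monocistronic (%.1f%%), ",
                     "%.2f genes/unit\n"),
              s$n_units, s$n_monocistronic, s$pct_monocistronic,
              s$mean_genes_per_operon))
  invisible(x)
}

#' Operon set as a data.frame
#'
#' @param x an `operon_set`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with members collapsed by `";"`.
#' @export
as.data.frame.operon_set <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  if (!length(x)) return(data.frame())
  data.frame(
    operon_id = vapply(x, `[[`, character(1), "operon_id"),
    members = vapply(x, function(u) paste(u$members, collapse = ";"),
                     character(1)),
    n_genes = vapply(x, function(u) length(u$members), integer(1)),
    strand = vapply(x, `[[`, character(1), "strand"),
    tss_position = vapply(x, function(u) as.integer(u$leading_tss),
                          integer(1)),
    class_label = vapply(x, `[[`, character(1), "class_label"),
    monocistronic = vapply(x, `[[`, logical(1), "monocistronic"),
    internal_promoter = vapply(x, `[[`, logical(1), "internal_promoter"),
    first_member_truncated = vapply(x, `[[`, logical(1),
                                    "first_member_truncated"),
    orphan = vapply(x, `[[`, logical(1), "orphan"),
    stringsAsFactors = FALSE)
}

#' Summarize an operon set
#'
#' @param operons an `operon_set` (or list of units).
#' @return list with `n_units`, `n_monocistronic`, `pct_monocistronic`
#'   (percent, one decimal), `n_genes` and `mean_genes_per_operon`.
#' @examples
#' # 28 units with 12 monocistronic over 80 genes give 42.9% and 2.86
#' @export
summarize_operons <- function(operons) {
  stopifnot(length(operons) >= 1)
  sizes <- vapply(operons, function(u) length(u$members), integer(1))
  n_mono <- sum(sizes == 1L)
  list(n_units = length(operons),
       n_monocistronic = n_mono,
       pct_monocistronic = round(100 * n_mono / length(operons), 1),
       n_genes = sum(sizes),
       mean_genes_per_operon = sum(sizes) / length(operons))
}

#' Write an operon table as TSV
#'
#' @param operons an `operon_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_operon_table <- function(operons, path) {
  utils::write.table(as.data.frame(operons), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Operon membership as a partition
#'
#' @param operons an `operon_set`.
#' @return list of character vectors of member feature ids, one per unit, in
#'   genome order -- convenient for comparing partitions.
#' @export
operon_partition <- function(operons) {
  lapply(unclass(operons), `[[`, "members")
}
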