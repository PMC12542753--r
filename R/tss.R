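#' Detect transcription start sites from stranded coverage steps
#'
#' A TSS appears in coverage data as a sudden, replicated jump in depth. For
#' every candidate position `p` the detector compares mean depth in a window
#' of `window` nt just downstream (transcribed side, including `p`) against
#' the window just upstream, at the timepoint where local downstream coverage
#' (replicate-averaged) is maximal -- so late transcripts are not diluted by
#' early zero-coverage samples. A position qualifies when, in at least
#' `replicate_quorum` replicates at that timepoint, downstream/upstream ratio
#' >= `min_step_ratio` and downstream mean >= `min_coverage`. Contiguous runs
#' of qualifying positions are resolved to the position maximizing the
#' pseudocount step ratio `(down + 1)/(up + 1)` (replicate-averaged), with
#' ties broken to the leftmost base on the forward strand and the rightmost
#' on the reverse strand; on a clean step this is the first transcribed base.
#'
#' @param exp a [coverage_experiment()].
#' @param strand `"+"` or `"-"`.
#' @param window window width in nt (default 20).
#' @param min_step_ratio minimum downstream/upstream mean ratio (default 5).
#' @param min_coverage minimum downstream mean depth (default 10).
#' @param replicate_quorum replicates that must pass at the same base
#'   (default: all).
#' @return data.frame with one row per TSS: `position` (1-based first
#'   transcribed base), `strand`, `step_ratio` (replicate-averaged
#'   downstream/upstream ratio, `Inf` for a zero upstream), `peak_timepoint`
#'   (minutes), `downstream_mean`, plus `orientation`/`target_feature`
#'   columns filled by [orient_tss()].
#' @export
detect_tss <- function(exp, strand = c("+", "-"), window = 20,
                       min_step_ratio = 5, min_coverage = 10,
                       replicate_quorum = NULL) {
  strand <- match.arg(strand)
  w <- as.integer(window)
  L <- exp$genome_length
  if (w >= L) stop("window must be smaller than the genome")
  nt <- length(exp$timepoints)
  nr <- exp$n_replicates
  if (is.null(replicate_quorum)) replicate_quorum <- nr
  # orient so transcription runs left->right; reverse-strand results are
  # mirrored back afterwards
  orient <- function(v) if (strand == "-") rev(v) else v
  pos <- (w + 1L):(L - w + 1L)
  np <- length(pos)

  downs <- vector("list", nt)
  ups <- vector("list", nt)
  best <- rep(-Inf, np)
  tstar <- rep(1L, np)
  for (ti in seq_len(nt)) {
    avg <- numeric(L)
    for (r in seq_len(nr)) avg <- avg + orient(exp$tracks[, ti, r, strand])
    avg <- avg / nr
    cs <- c(0, cumsum(avg))
    down <- (cs[pos + w] - cs[pos]) / w
    up <- (cs[pos] - cs[pos - w]) / w
    downs[[ti]] <- down
    ups[[ti]] <- up
    sel <- down > best
    tstar[sel] <- ti
    best[sel] <- down[sel]
  }
  npass <- integer(np)
  for (r in seq_len(nr)) {
    dsel <- numeric(np)
    usel <- numeric(np)
    for (ti in seq_len(nt)) {
      idx <- tstar == ti
      if (!any(idx)) next
      cs <- c(0, cumsum(orient(exp$tracks[, ti, r, strand])))
      p <- pos[idx]
      dsel[idx] <- (cs[p + w] - cs[p]) / w
      usel[idx] <- (cs[p] - cs[p - w]) / w
    }
    ratio <- ifelse(usel > 0, dsel / usel, ifelse(dsel > 0, Inf, 0))
    npass <- npass + (ratio >= min_step_ratio & dsel >= min_coverage)
  }
  qual <- which(npass >= replicate_quorum)
  empty <- data.frame(position = integer(), strand = character(),
                      step_ratio = numeric(), peak_timepoint = numeric(),
                      downstream_mean = numeric(),
                      orientation = character(),
                      target_feature = character(),
                      stringsAsFactors = FALSE)
  if (!length(qual)) return(empty)
  davg <- uavg <- numeric(np)
  for (ti in seq_len(nt)) {
    idx <- tstar == ti
    davg[idx] <- downs[[ti]][idx]
    uavg[idx] <- ups[[ti]][idx]
  }
  ratio_pc <- (davg + 1) / (uavg + 1)
  grp <- cumsum(c(1L, diff(qual) != 1L))
  picks <- vapply(split(qual, grp),
                  function(jj) jj[which.max(ratio_pc[jj])], integer(1))
  p_or <- pos[picks]
  res <- data.frame(
    position = if (strand == "-") L - p_or + 1L else p_or,
    strand = strand,
    step_ratio = ifelse(uavg[picks] > 0, davg[picks] / uavg[picks], Inf),
    peak_timepoint = exp$timepoints[tstar[picks]],
    downstream_mean = davg[picks],
    orientation = NA_character_,
    target_feature = NA_character_,
    stringsAsFactors = FALSE)
  res <- res[order(res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect TSSs on both strands
#'
#' Convenience wrapper running [detect_tss()] on each strand and
#' [orient_tss()] against an annotation.
#'
#' @inheritParams detect_tss
#' @param ann a [genome_annotation()] for orientation (optional).
#' @param ... passed to [detect_tss()] and, as relevant, [orient_tss()].
#' @param upstream_max,antisense_downstream see [orient_tss()].
#' @return combined TSS data.frame sorted by position.
#' @export
detect_tss_both <- function(exp, ann = NULL, window = 20, min_step_ratio = 5,
                            min_coverage = 10, replicate_quorum = NULL,
                            upstream_max = 250, antisense_downstream = 100) {
  res <- rbind(
    detect_tss(exp, "+", window, min_step_ratio, min_coverage,
               replicate_quorum),
    detect_tss(exp, "-", window, min_step_ratio, min_coverage,
               replicate_quorum))
  res <- res[order(res$position), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(ann))
    res <- orient_tss(res, ann, upstream_max = upstream_max,
                      antisense_downstream = antisense_downstream)
  res
}

#' Orient TSSs against an annotation
#'
#' Assigns each detected TSS one of four orientation classes:
#' `internal_sense` -- inside a same-strand feature (an internal promoter,
#' whose transcript covers only the downstream part of the gene);
#' `sense` -- within `upstream_max` nt upstream of a same-strand feature
#' start and not inside any same-strand feature; `antisense` -- inside, or
#' within `antisense_downstream` nt past the 3' end of, an opposite-strand
#' feature; `orphan` otherwise. When several apply, precedence is
#' internal_sense > sense > antisense.
#'
#' @param tss TSS data.frame from [detect_tss()] (columns `position`,
#'   `strand`).
#' @param ann a [genome_annotation()].
#' @param upstream_max maximal upstream distance for a sense call
#'   (default 250 nt).
#' @param antisense_downstream how far past an opposite-strand feature's 3'
#'   end a TSS still counts antisense (default 100 nt).
#' @return `tss` with `orientation` and `target_feature` filled in.
#' @export
orient_tss <- function(tss, ann, upstream_max = 250,
                       antisense_downstream = 100) {
  f <- ann$features
  n <- nrow(tss)
  orientation <- rep("orphan", n)
  target <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- tss$position[i]
    s <- tss$strand[i]
    same <- f[f$strand == s, , drop = FALSE]
    opp <- f[f$strand != s, , drop = FALSE]
    inside_same <- which(same$start <= p & p <= same$end)
    if (length(inside_same)) {
      orientation[i] <- "internal_sense"
      target[i] <- same$feature_id[inside_same[1]]
      next
    }
    # distance from TSS to the 5' end of a same-strand feature, measured
    # against transcription direction
    d5 <- if (s == "+") same$start - p else p - same$end
    cand <- which(d5 >= 1 & d5 <= upstream_max)
    if (length(cand)) {
      j <- cand[which.min(d5[cand])]
      orientation[i] <- "sense"
      target[i] <- same$feature_id[j]
      next
    }
    # antisense: inside, or within antisense_downstream past the 3' end of,
    # an opposite-strand feature
    hit <- which(ifelse(opp$strand == "+",
                        p >= opp$start & p <= opp$end + antisense_downstream,
                        p >= opp$start - antisense_downstream & p <= opp$end))
    if (length(hit)) {
      mid <- (opp$start[hit] + opp$end[hit]) / 2
      j <- hit[which.min(abs(mid - p))]
      orientation[i] <- "antisense"
      target[i] <- opp$feature_id[j]
    }
  }
  tss$orientation <- orientation
  tss$target_feature <- target
  tss
}

#' Call antisense-dominated genes
#'
#' For each annotated feature and each timepoint, replicate-summed coverage
#' over the feature interval on the antisense strand is compared with the
#' sense strand; a gene is called antisense-dominated when antisense exceeds
#' sense strictly at `min_timepoints` or more timepoints.
#'
#' @param exp a [coverage_experiment()].
#' @param ann a [genome_annotation()].
#' @param min_timepoints minimum number of antisense-dominant timepoints for
#'   a call (default 3).
#' @return data.frame with `feature_id`, `n_antisense_dominant` and `called`.
#' @export
call_antisense_genes <- function(exp, ann, min_timepoints = 3) {
  f <- ann$features
  nt <- length(exp$timepoints)
  n_dom <- integer(nrow(f))
  cs <- list()
  for (s in c("+", "-")) {
    cs[[s]] <- lapply(seq_len(nt), function(ti) {
      tot <- numeric(exp$genome_length)
      for (r in seq_len(exp$n_replicates))
        tot <- tot + exp$tracks[, ti, r, s]
      c(0, cumsum(tot))
    })
  }
  for (i in seq_len(nrow(f))) {
    s <- f$strand[i]
    a <- setdiff(c("+", "-"), s)
    dom <- 0L
    for (ti in seq_len(nt)) {
      sense <- cs[[s]][[ti]][f$end[i] + 1L] - cs[[s]][[ti]][f$start[i]]
      anti <- cs[[a]][[ti]][f$end[i] + 1L] - cs[[a]][[ti]][f$start[i]]
      if (anti > sense) dom <- dom + 1L
    }
    n_dom[i] <- dom
  }
  data.frame(feature_id = f$feature_id, n_antisense_dominant = n_dom,
             called = n_dom >= min_timepoints, stringsAsFactors = FALSE)
}

#' Temporal profile at a TSS
#'
#' Replicate-averaged coverage in the window of `window` nt downstream of the
#' TSS (transcribed side), per timepoint, scaled to percent of its maximum.
#'
#' @param exp a [coverage_experiment()].
#' @param position TSS position (1-based first transcribed base), or a
#'   one-row TSS data.frame.
#' @param strand TSS strand (ignored when `position` is a data.frame row).
#' @param window window width in nt (default 20); truncated with a warning at
#'   the genome end.
#' @return list with `timepoints`, `coverage` (mean window depth) and
#'   `pct_of_max`.
#' @export
tss_profile <- function(exp, position, strand = "+", window = 20) {
  if (is.data.frame(position)) {
    strand <- position$strand[1]
    position <- position$position[1]
  }
  L <- exp$genome_length
  if (strand == "+") {
    lo <- position; hi <- position + window - 1L
  } else {
    lo <- position - window + 1L; hi <- position
  }
  if (lo < 1L || hi > L) {
    warning("TSS window truncated at genome boundary")
    lo <- max(1L, lo); hi <- min(L, hi)
  }
  cov <- vapply(seq_along(exp$timepoints), function(ti) {
    mean(vapply(seq_len(exp$n_replicates), function(r)
      mean(exp$tracks[lo:hi, ti, r, strand]), numeric(1)))
  }, numeric(1))
  mx <- max(cov)
  pct <- if (mx > 0) 100 * cov / mx else rep(0, length(cov))
  list(timepoints = exp$timepoints, coverage = cov, pct_of_max = pct)
}

#' Aggregate TSS profiles over a group
#'
#' Mean and standard deviation of percent-of-max TSS profiles per timepoint,
#' e.g. over all antisense TSSs, as used to show that antisense transcription
#' follows a late profile.
#'
#' @param exp a [coverage_experiment()].
#' @param tss TSS data.frame (rows define the group).
#' @param window window width passed to [tss_profile()].
#' @return list with `timepoints`, `mean`, `sd` and `n`.
#' @export
tss_profile_group <- function(exp, tss, window = 20) {
  stopifnot(nrow(tss) >= 1)
  mat <- t(vapply(seq_len(nrow(tss)), function(i)
    tss_profile(exp, tss$position[i], tss$strand[i], window)$pct_of_max,
    numeric(length(exp$timepoints))))
  sds <- apply(mat, 2, stats::sd)
  if (nrow(tss) == 1L) sds <- rep(0, ncol(mat))
  list(timepoints = exp$timepoints, mean = colMeans(mat), sd = sds,
       n = nrow(tss))
}

#' Write TSSs as BED6
#'
#' Name column carries the orientation, score the rounded step ratio (capped
#' at 1000), strand the TSS strand.
#'
#' @param tss TSS data.frame.
#' @param path output BED path.
#' @param genome_id chromosome name for column 1.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(tss, path, genome_id = "genome") {
  score <- pmin(round(ifelse(is.finite(tss$step_ratio),
                             tss$step_ratio, 1000)), 1000)
  bed <- data.frame(chrom = genome_id,
                    start = tss$position - 1L,
                    end = tss$position,
                    name = ifelse(is.na(tss$orientation), "tss",
                                  tss$orientation),
                    score = score,
                    strand = tss$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
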