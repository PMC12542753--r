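#' Construct a stranded coverage experiment
#'
#' Holds per-base read depth for every (timepoint, replicate, strand)
#' combination of an infection time course, together with per-sample library
#' sizes (total mapped reads, host plus virus).
#'
#' @param tracks numeric array of dimension
#'   `genome_length x n_timepoints x n_replicates x 2`, with the fourth
#'   dimension named `c("+", "-")`. All values must be >= 0.
#' @param timepoints strictly increasing vector of minutes post-infection.
#' @param library_size matrix `n_timepoints x n_replicates` of total mapped
#'   reads per sample (> 0).
#' @param genome_id genome name (used when writing bedGraph tracks).
#' @return an object of class `coverage_experiment`.
#' @export
coverage_experiment <- function(tracks, timepoints, library_size,
                                genome_id = "genome") {
  stopifnot(is.array(tracks), length(dim(tracks)) == 4L)
  nt <- length(timepoints)
  if (any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing")
  if (dim(tracks)[2] != nt) stop("tracks/timepoints mismatch")
  if (dim(tracks)[4] != 2L) stop("tracks must carry both strands")
  if (is.null(dimnames(tracks)[[4]])) dimnames(tracks)[[4]] <- c("+", "-")
  if (!identical(dimnames(tracks)[[4]], c("+", "-")))
    stop("strand dimension must be named c('+', '-')")
  if (min(tracks) < 0) stop("coverage values must be >= 0")
  library_size <- as.matrix(library_size)
  if (!identical(dim(library_size), c(nt, dim(tracks)[3])))
    stop("library_size must be a timepoints x replicates matrix")
  if (any(library_size <= 0)) stop("library sizes must be > 0")
  structure(list(genome_id = genome_id,
                 genome_length = dim(tracks)[1],
                 timepoints = as.numeric(timepoints),
                 n_replicates = dim(tracks)[3],
                 tracks = tracks,
                 library_size = library_size),
            class = "coverage_experiment")
}

#' @export
print.coverage_experiment <- function(x, ...) {
  cat(sprintf(paste0("<coverage_experiment> %s: %d nt, %d timepoint(s) ",
                     "(%s min), %d replicate(s), 2 strands\n"),
              x$genome_id, x$genome_length, length(x$timepoints),
              paste(x$timepoints, collapse = ", "), x$n_replicates))
  invisible(x)
}

track_of <- function(exp, timepoint, replicate, strand) {
  ti <- match(timepoint, exp$timepoints)
  if (is.na(ti)) stop("unknown timepoint: ", timepoint)
  if (replicate < 1 || replicate > exp$n_replicates)
    stop("unknown replicate: ", replicate)
  exp$tracks[, ti, replicate, strand]
}

# replicate-averaged coverage matrix (genome_length x n_timepoints)
replicate_mean_tracks <- function(exp, strand) {
  m <- exp$tracks[, , , strand, drop = FALSE]
  dim(m) <- dim(exp$tracks)[1:3]
  rowMeans(m, dims = 2)
}

#' Read a set of bedGraph tracks into a coverage experiment
#'
#' The manifest (TSV) must carry columns `path`, `timepoint_min`, `replicate`,
#' `strand` and `library_size`, one row per bedGraph file; every
#' (timepoint, replicate, strand) combination must be present exactly once.
#' Positions not covered by any bedGraph interval are filled with 0;
#' overlapping intervals within one file are an error.
#'
#' @param manifest path to the manifest TSV, or an equivalent data.frame.
#' @param dir directory against which relative `path` entries are resolved
#'   (defaults to the manifest's directory).
#' @param genome_length genome length in nt; when `NULL`, the largest end
#'   coordinate seen across all tracks.
#' @param genome_id genome name.
#' @return a [coverage_experiment()].
#' @export
read_bedgraph_set <- function(manifest, dir = NULL, genome_length = NULL,
                              genome_id = "genome") {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  needed <- c("path", "timepoint_min", "replicate", "strand", "library_size")
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols))
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(dir)) dir <- "."
  tps <- sort(unique(manifest$timepoint_min))
  reps <- sort(unique(manifest$replicate))
  grid <- expand.grid(timepoint_min = tps, replicate = reps,
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  key <- function(d) paste(d$timepoint_min, d$replicate, d$strand)
  gaps <- setdiff(key(grid), key(manifest))
  if (length(gaps))
    stop("manifest is missing (timepoint, replicate, strand) combination(s): ",
         paste(gaps, collapse = "; "))
  if (anyDuplicated(key(manifest)))
    stop("manifest lists duplicate (timepoint, replicate, strand) entries")

  paths <- ifelse(file.exists(manifest$path), manifest$path,
                  file.path(dir, manifest$path))
  grs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("bedGraph not found: ", p)
    rtracklayer::import(p, format = "bedGraph")
  })
  if (is.null(genome_length)) {
    ends <- vapply(grs, function(g)
      if (length(g)) max(GenomicRanges::end(g)) else 0L, numeric(1))
    genome_length <- max(ends, 1)
  }
  nt <- length(tps); nr <- length(reps)
  tracks <- array(0, dim = c(genome_length, nt, nr, 2),
                  dimnames = list(NULL, NULL, NULL, c("+", "-")))
  for (i in seq_len(nrow(manifest))) {
    g <- grs[[i]]
    v <- numeric(genome_length)
    if (length(g)) {
      s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
      if (any(e > genome_length))
        stop("bedGraph interval beyond genome end in ", paths[i])
      ir <- IRanges::IRanges(s, e)
      if (sum(IRanges::width(IRanges::reduce(ir))) < sum(IRanges::width(ir)))
        stop("overlapping bedGraph intervals in ", paths[i])
      for (j in seq_along(g)) v[s[j]:e[j]] <- g$score[j]
    }
    ti <- match(manifest$timepoint_min[i], tps)
    ri <- match(manifest$replicate[i], reps)
    tracks[, ti, ri, manifest$strand[i]] <- v
  }
  lib <- matrix(0, nt, nr)
  for (i in seq_len(nrow(manifest))) {
    ti <- match(manifest$timepoint_min[i], tps)
    ri <- match(manifest$replicate[i], reps)
    lib[ti, ri] <- manifest$library_size[i]
  }
  coverage_experiment(tracks, tps, lib, genome_id = genome_id)
}

#' Write a coverage experiment as bedGraph files plus manifest
#'
#' One bedGraph per (timepoint, replicate, strand), run-length encoded, plus
#' a `manifest.tsv` that [read_bedgraph_set()] accepts.
#'
#' @param exp a `coverage_experiment`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_bedgraph_set <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ti in seq_along(exp$timepoints)) for (r in seq_len(exp$n_replicates))
    for (s in c("+", "-")) {
      tag <- if (s == "+") "fwd" else "rev"
      fn <- sprintf("cov_t%g_r%d_%s.bedGraph", exp$timepoints[ti], r, tag)
      v <- exp$tracks[, ti, r, s]
      rl <- rle(v)
      e <- cumsum(rl$lengths)
      st <- e - rl$lengths + 1L
      keep <- rl$values != 0
      gr <- GenomicRanges::GRanges(rep(exp$genome_id, sum(keep)),
                                   IRanges::IRanges(st[keep], e[keep]),
                                   score = rl$values[keep])
      rtracklayer::export.bedGraph(gr, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        path = fn, timepoint_min = exp$timepoints[ti], replicate = r,
        strand = s, library_size = exp$library_size[ti, r])
    }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mp)
}

#' RPKM of one feature in one sample
#'
#' Per-base depth over the feature interval on the feature's own strand is
#' summed and divided by `read_length_proxy` to approximate a read count;
#' the count is then normalized by feature length and library size:
#' `RPKM = count * 1e9 / (length_nt * library_size)`. Percent-of-maximum
#' profiles are invariant to `read_length_proxy`, which cancels.
#'
#' @param exp a `coverage_experiment`.
#' @param feature one feature (row of an annotation's feature table).
#' @param timepoint timepoint in minutes (must match the experiment grid).
#' @param replicate replicate index.
#' @param read_length_proxy nominal read length in nt used to convert summed
#'   depth to a read-count equivalent (default 75).
#' @return RPKM value (reads per kb per million mapped reads).
#' @export
gene_rpkm <- function(exp, feature, timepoint, replicate,
                      read_length_proxy = 75) {
  len <- feature$end - feature$start + 1
  if (len < 1) stop("zero-length feature")
  if (feature$start < 1 || feature$end > exp$genome_length)
    stop("feature outside genome")
  v <- track_of(exp, timepoint, replicate, as.character(feature$strand))
  count_equiv <- sum(v[feature$start:feature$end]) / read_length_proxy
  ti <- match(timepoint, exp$timepoints)
  count_equiv * 1e9 / (len * exp$library_size[ti, replicate])
}

#' Temporal expression profile of one feature
#'
#' Replicate-averaged RPKM per timepoint, and the percent-of-maximum profile
#' `100 * rpkm / max(rpkm)`. A feature whose maximum replicate-averaged RPKM
#' falls below `expression_floor` is flagged unexpressed and gets an
#' all-`NA` percent profile.
#'
#' @inheritParams gene_rpkm
#' @param expression_floor minimum max-RPKM for a feature to count as
#'   expressed (default 1).
#' @return list with `feature_id`, `timepoints`, `rpkm`, `pct_of_max`,
#'   `expressed`.
#' @export
temporal_profile <- function(exp, feature, expression_floor = 1,
                             read_length_proxy = 75) {
  rpkm <- vapply(exp$timepoints, function(tp) {
    mean(vapply(seq_len(exp$n_replicates), function(r)
      gene_rpkm(exp, feature, tp, r, read_length_proxy), numeric(1)))
  }, numeric(1))
  expressed <- max(rpkm) >= expression_floor
  pct <- if (expressed) 100 * rpkm / max(rpkm) else rep(NA_real_, length(rpkm))
  list(feature_id = as.character(feature$feature_id),
       timepoints = exp$timepoints, rpkm = rpkm, pct_of_max = pct,
       expressed = expressed)
}

#' Temporal profiles for every feature of an annotation
#'
#' @inheritParams temporal_profile
#' @param ann a [genome_annotation()].
#' @return an object of class `temporal_profiles`: list with `feature_id`,
#'   `timepoints`, matrices `rpkm` and `pct_of_max` (features x timepoints)
#'   and logical vector `expressed`.
#' @export
temporal_profiles <- function(exp, ann, expression_floor = 1,
                              read_length_proxy = 75) {
  f <- ann$features
  n <- nrow(f); nt <- length(exp$timepoints)
  rpkm <- matrix(0, n, nt, dimnames = list(f$feature_id, exp$timepoints))
  # vectorized over features: per (t, r, strand) cumulative sums
  for (s in c("+", "-")) {
    idx <- which(f$strand == s)
    if (!length(idx)) next
    for (ti in seq_len(nt)) {
      acc <- numeric(length(idx))
      for (r in seq_len(exp$n_replicates)) {
        cs <- c(0, cumsum(exp$tracks[, ti, r, s]))
        counts <- (cs[f$end[idx] + 1L] - cs[f$start[idx]]) / read_length_proxy
        acc <- acc + counts * 1e9 /
          ((f$end[idx] - f$start[idx] + 1) * exp$library_size[ti, r])
      }
      rpkm[idx, ti] <- acc / exp$n_replicates
    }
  }
  mx <- apply(rpkm, 1, max)
  expressed <- mx >= expression_floor
  pct <- 100 * rpkm / ifelse(mx > 0, mx, NA_real_)
  pct[!expressed, ] <- NA_real_
  structure(list(feature_id = f$feature_id, timepoints = exp$timepoints,
                 rpkm = rpkm, pct_of_max = pct, expressed = expressed),
            class = "temporal_profiles")
}

#' @export
print.temporal_profiles <- function(x, ...) {
  cat(sprintf("<temporal_profiles> %d feature(s) x %d timepoint(s); %d expressed\n",
              length(x$feature_id), length(x$timepoints), sum(x$expressed)))
  invisible(x)
}

#' Export temporal profiles as TSV
#'
#' One row per feature: RPKM and percent-of-max per timepoint plus the
#' expressed flag.
#'
#' @param profiles a `temporal_profiles` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  tp <- profiles$timepoints
  df <- data.frame(feature_id = profiles$feature_id,
                   expressed = profiles$expressed)
  for (i in seq_along(tp)) df[[sprintf("rpkm_t%g", tp[i])]] <-
    profiles$rpkm[, i]
  for (i in seq_along(tp)) df[[sprintf("pct_t%g", tp[i])]] <-
    round(profiles$pct_of_max[, i], 3)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
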