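# small in-code builders shared across tests

default_tp <- c(5, 20, 60, 120, 180, 300)

# coverage_experiment from per-strand coverage matrices (L x n_timepoints),
# identical across replicates unless per-replicate arrays are given
toy_experiment <- function(fwd, rev = NULL, timepoints = default_tp,
                           n_replicates = 1, library_size = 1e6,
                           genome_id = "toy") {
  fwd <- as.matrix(fwd)
  if (is.null(rev)) rev <- matrix(0, nrow(fwd), ncol(fwd))
  rev <- as.matrix(rev)
  L <- nrow(fwd); nt <- ncol(fwd)
  stopifnot(nt == length(timepoints))
  tracks <- array(0, dim = c(L, nt, n_replicates, 2),
                  dimnames = list(NULL, NULL, NULL, c("+", "-")))
  for (r in seq_len(n_replicates)) {
    tracks[, , r, "+"] <- fwd
    tracks[, , r, "-"] <- rev
  }
  lib <- matrix(library_size, nt, n_replicates)
  coverage_experiment(tracks, timepoints, lib, genome_id = genome_id)
}

# constant-over-time coverage from a single per-base vector
toy_experiment_const <- function(fwd_vec, rev_vec = NULL, ...) {
  nt <- length(default_tp)
  toy_experiment(matrix(fwd_vec, length(fwd_vec), nt),
                 if (!is.null(rev_vec))
                   matrix(rev_vec, length(rev_vec), nt),
                 ...)
}

toy_feature <- function(start, end, strand = "+", id = "gpX",
                        kind = "ORF", group = "x") {
  data.frame(feature_id = id, start = start, end = end, strand = strand,
             kind = kind, functional_group = group,
             stringsAsFactors = FALSE)
}

toy_annotation <- function(..., genome_length = 2000, genome_id = "toy") {
  genome_annotation(do.call(rbind, list(...)), genome_id, genome_length)
}

# temporal_profiles-shaped object from a percent matrix (for classify_all)
toy_profiles <- function(pct, timepoints = default_tp,
                         ids = sprintf("gp%02d", seq_len(nrow(pct)))) {
  rpkm <- pct  # scale is irrelevant to classification
  structure(list(feature_id = ids, timepoints = timepoints, rpkm = rpkm,
                 pct_of_max = pct,
                 expressed = apply(pct, 1, function(x) !all(is.na(x)))),
            class = "temporal_profiles")
}
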