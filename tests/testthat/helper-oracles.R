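# Independent re-implementations used as oracles. Deliberately written as
# plain, slow loops that restate the rules from scratch, so they share no
# code path with the package.

# half-maximum temporal rule, brute force
oracle_classify <- function(pct, tp, thr = 50, early = 20, middle = 60) {
  if (all(is.na(pct))) return("unclassified")
  i_half <- NA
  for (i in seq_along(tp)) {
    if (!is.na(pct[i]) && pct[i] >= thr) { i_half <- i; break }
  }
  if (is.na(i_half)) return("unclassified")
  t_half <- tp[i_half]
  drops <- FALSE
  if (i_half < length(tp)) {
    for (j in (i_half + 1):length(tp)) if (pct[j] < thr) drops <- TRUE
  }
  if (t_half <= early) return("early")
  if (t_half <= middle) return(if (drops) "middle_down" else "middle")
  "late"
}

# all contiguous partitions of 1..n as lists of index vectors
oracle_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0L, cuts, n)
    out[[length(out) + 1L]] <-
      lapply(seq_len(length(bounds) - 1L),
             function(k) (bounds[k] + 1L):bounds[k + 1L])
  }
  out
}

# validity of one contiguous partition of a single forward-strand gene run
# under the chaining rules: gap <= gap_max, equal class, no promoter forcing
# a split, continuous coverage over the transcribed span; boundaries must
# fail the join they would otherwise make.
oracle_partition_valid <- function(part, feats, labels, cov, tss,
                                   gap_max = 30, frac = 0.9, min_cov = 5) {
  tx_start_of <- function(first_i) {
    f <- feats[first_i, ]
    ip <- tss$position[tss$orientation == "internal_sense" &
                         tss$position >= f$start & tss$position <= f$end]
    if (length(ip)) min(ip) else f$start
  }
  continuity <- function(lo, hi) {
    span <- lo:hi
    means <- colMeans(cov[span, , drop = FALSE])
    ti <- which.max(means)
    mean(cov[span, ti] >= min_cov) >= frac
  }
  join_ok <- function(txs, ai, bi) {
    a <- feats[ai, ]; b <- feats[bi, ]
    gap <- b$start - a$end - 1
    if (gap > gap_max) return(FALSE)
    if (labels[ai] != labels[bi]) return(FALSE)
    if (gap >= 1 &&
        any(tss$orientation == "sense" & tss$position > a$end &
              tss$position < b$start)) return(FALSE)
    if (any(tss$orientation == "internal_sense" &
              tss$position >= b$start & tss$position <= b$end))
      return(FALSE)
    continuity(txs, b$end)
  }
  for (k in seq_along(part)) {
    unit <- part[[k]]
    txs <- tx_start_of(unit[1])
    if (length(unit) > 1) {
      for (j in 2:length(unit)) {
        if (!join_ok(txs, unit[j - 1], unit[j])) return(FALSE)
      }
    }
    if (k < length(part)) {
      nxt <- part[[k + 1]][1]
      if (join_ok(txs, unit[length(unit)], nxt)) return(FALSE)
    }
  }
  TRUE
}

# random single-strand operon-assembly instance for the enumeration oracle
random_assembly_instance <- function(n_genes) {
  lens <- sample(60:140, n_genes, replace = TRUE)
  gaps <- sample(c(-4L, 0L, 5L, 15L, 40L, 120L), n_genes - 1,
                 replace = TRUE, prob = c(2, 2, 2, 2, 1, 1))
  starts <- integer(n_genes); ends <- integer(n_genes)
  starts[1] <- 150L
  ends[1] <- starts[1] + lens[1] - 1L
  if (n_genes > 1) for (j in 2:n_genes) {
    starts[j] <- ends[j - 1] + gaps[j - 1] + 1L
    ends[j] <- starts[j] + lens[j] - 1L
  }
  L <- ends[n_genes] + 200L
  feats <- data.frame(feature_id = sprintf("g%02d", 1:n_genes),
                      start = starts, end = ends, strand = "+",
                      kind = "ORF", functional_group = "x")
  labels <- sample(c("middle", "late"), n_genes, replace = TRUE)
  # coverage: two timepoints, transcripts over random contiguous blocks
  cov <- matrix(0, L, 2)
  blocks <- sort(unique(c(1, sample(seq_len(n_genes), 2, replace = TRUE))))
  for (b in blocks) {
    lo <- max(1L, starts[b] - 10L)
    hi <- ends[sample(b:n_genes, 1)]
    cov[lo:hi, 1] <- cov[lo:hi, 1] + 40
    cov[lo:hi, 2] <- cov[lo:hi, 2] + 10
  }
  # occasional coverage hole inside a gap
  if (n_genes > 1 && stats::runif(1) < 0.5) {
    j <- sample(n_genes - 1, 1)
    if (starts[j + 1] - ends[j] > 10)
      cov[(ends[j] + 2):(starts[j + 1] - 2), ] <- 0
  }
  tss <- data.frame(position = integer(), strand = character(),
                    orientation = character(), stringsAsFactors = FALSE)
  if (stats::runif(1) < 0.5 && n_genes > 1) {   # sense TSS in one gap
    j <- sample(n_genes - 1, 1)
    if (starts[j + 1] - ends[j] > 2) {
      p <- ends[j] + sample(starts[j + 1] - ends[j] - 1, 1)
      tss <- rbind(tss, data.frame(position = p, strand = "+",
                                   orientation = "sense"))
    }
  }
  if (stats::runif(1) < 0.4) {                  # internal promoter
    j <- sample(n_genes, 1)
    p <- starts[j] + sample(lens[j] - 2, 1)
    tss <- rbind(tss, data.frame(position = p, strand = "+",
                                 orientation = "internal_sense"))
  }
  list(feats = feats, labels = labels, cov = cov, tss = tss, L = L)
}
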