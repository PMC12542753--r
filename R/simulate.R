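#' Simulation specification
#'
#' Parameters of the synthetic infection time-course generator. Defaults
#' mirror the magnitudes of a 6-timepoint haloarchaeal virus infection
#' experiment: a ~36 kb viral genome with ~80 genes in ~28 transcriptional
#' units, sampled at 5-300 min post-infection in 3 replicates, with a
#' 7/25/14/54% early/middle/middle-down/late class mix, one internal
#' promoter, 23 antisense TSSs, and a ~4,000-gene host with planted DEGs.
#'
#' @param seed integer seed; every output is reproducible from it.
#' @param genome_length viral genome length in nt (default 36000).
#' @param n_features number of viral features to plant (default 80; one of
#'   them is emitted as a tRNA, the rest as ORFs).
#' @param timepoints minutes post-infection (default
#'   `c(5, 20, 60, 120, 180, 300)`).
#' @param n_replicates biological replicates (default 3).
#' @param class_mix named proportions over early/middle/middle_down/late
#'   (default `c(0.07, 0.25, 0.14, 0.54)`).
#' @param n_internal_promoters internal-promoter pairs to plant (default 1).
#' @param n_antisense_tss antisense TSSs to attempt to place (default 23).
#' @param noise viral coverage noise: `"none"` or `"poisson"` (per-base).
#' @param mean_depth mean peak coverage depth per transcript (default 50).
#' @param read_length_proxy nominal read length used when deriving library
#'   sizes and RPKMs (default 75).
#' @param host_n_genes host genome size (default 4053).
#' @param host_n_categories number of functional-category letters
#'   (default 20, including `"N"` sized 37 and `"S"` for unknowns).
#' @param host_noise host count noise: `"nb"` (negative binomial,
#'   `host_dispersion`), `"poisson"` or `"none"`.
#' @param host_dispersion NB dispersion of host counts (default 0.05).
#' @param host_deg_fold planted DEG fold change (default 6).
#' @param host_up,host_down planted up-/downregulated gene counts per
#'   timepoint. The defaults plant no DEGs at 5 min, few at 20 min, and --
#'   at the fourth timepoint -- exactly 118 downregulated genes of which 5
#'   sit in the 37-gene category `"N"`.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            genome_length = 36000,
                            n_features = 80,
                            timepoints = c(5, 20, 60, 120, 180, 300),
                            n_replicates = 3,
                            class_mix = c(early = 0.07, middle = 0.25,
                                          middle_down = 0.14, late = 0.54),
                            n_internal_promoters = 1,
                            n_antisense_tss = 23,
                            noise = c("none", "poisson"),
                            mean_depth = 50,
                            read_length_proxy = 75,
                            host_n_genes = 4053,
                            host_n_categories = 20,
                            host_noise = c("nb", "poisson", "none"),
                            host_dispersion = 0.05,
                            host_deg_fold = 6,
                            host_up = c(0, 5, 30, 60, 100, 90),
                            host_down = c(0, 0, 5, 118, 160, 140)) {
  noise <- match.arg(noise)
  host_noise <- match.arg(host_noise)
  stopifnot(abs(sum(class_mix) - 1) < 1e-9, n_replicates >= 1,
            length(host_up) == length(timepoints),
            length(host_down) == length(timepoints))
  structure(as.list(environment()), class = "simulation_spec")
}

archetype_profiles <- function(timepoints) {
  # piecewise-linear percent-of-max archetypes; by construction each obeys
  # the half-maximum rule for its class on the default grid
  shapes <- list(
    early       = list(t = c(0, 5, 60, 300),       pct = c(60, 100, 70, 50)),
    middle      = list(t = c(0, 20, 60, 300),      pct = c(2, 20, 100, 70)),
    middle_down = list(t = c(0, 20, 60, 120, 300), pct = c(2, 25, 100, 40, 15)),
    late        = list(t = c(0, 60, 120, 180, 300), pct = c(1, 15, 45, 100, 90)))
  out <- t(vapply(shapes, function(sh)
    stats::approx(sh$t, sh$pct, xout = timepoints, rule = 2)$y,
    numeric(length(timepoints))))
  rownames(out) <- names(shapes)
  out
}

#' Simulate a complete infection time-course experiment
#'
#' Generates a viral genome annotation, planted transcriptional units with
#' archetype temporal profiles, stranded per-base coverage over timepoints
#' and replicates (optionally Poisson-noised), sense/internal/antisense
#' TSSs realized as coverage steps, host count matrices with planted DEGs,
#' a gene-to-category map, and the full ground truth needed to score every
#' downstream stage.
#'
#' Layout: transcriptional-unit sizes are drawn to average about three genes
#' per unit; within units consecutive genes overlap by 4 nt or are separated
#' by 0-20 nt, between units by 50-500 nt. Each unit gets one archetype
#' class profile (all members share it) and a sense TSS 20-100 nt upstream
#' of its first gene; internal-promoter pairs are two adjacent forward
#' -strand units of different classes separated by <= 20 nt, the downstream
#' one initiated by a TSS inside its first gene. Antisense TSSs are placed
#' within or just past target units (mostly structural and DNA-metabolism
#' units), transcribe the opposite strand with a late archetype profile,
#' and are only accepted where they cannot mask or contaminate other
#' planted signal.
#'
#' @param spec a [simulation_spec()].
#' @return list of class `simulated_experiment` with elements `annotation`
#'   ([genome_annotation()]), `experiment` ([coverage_experiment()]), `host`
#'   (per-timepoint infected/control count matrices and library sizes),
#'   `category_map`, `truth` (list: `classes`, `operons`, `tss`,
#'   `antisense_called`, `host_deg`) and `spec`.
#' @export
simulate_experiment <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  L <- spec$genome_length
  tp <- spec$timepoints
  nt <- length(tp)
  nr <- spec$n_replicates
  arch <- archetype_profiles(tp)

  ## ---- unit layout ----
  sizes <- integer(0)
  while (sum(sizes) < spec$n_features) {
    sizes <- c(sizes, sample(1:6, 1,
                             prob = c(0.40, 0.15, 0.12, 0.12, 0.11, 0.10)))
  }
  sizes[length(sizes)] <- sizes[length(sizes)] -
    (sum(sizes) - spec$n_features)
  if (sizes[length(sizes)] == 0L) sizes <- sizes[-length(sizes)]
  n_units <- length(sizes)
  classes <- sample(names(spec$class_mix), n_units, replace = TRUE,
                    prob = spec$class_mix)
  strands <- sample(c("+", "-"), n_units, replace = TRUE,
                    prob = c(0.65, 0.35))
  internal <- rep(FALSE, n_units)
  if (spec$n_internal_promoters > 0 && n_units >= 3) {
    cand <- seq(3, n_units, by = 2)   # spaced, never unit 1/2
    picks <- cand[seq_len(min(spec$n_internal_promoters, length(cand)))]
    for (u in picks) {
      internal[u] <- TRUE
      strands[u] <- "+"; strands[u - 1] <- "+"
      if (classes[u] == classes[u - 1])
        classes[u] <- sample(setdiff(names(spec$class_mix), classes[u - 1]),
                             1)
    }
  }

  cursor <- 300L
  units <- vector("list", n_units)
  feat_rows <- list()
  for (u in seq_len(n_units)) {
    pre_gap <- if (internal[u]) sample(0:20, 1) else
      round(stats::runif(1, 50, 500))
    lens <- sample(150:380, sizes[u], replace = TRUE)
    intra <- if (sizes[u] > 1)
      ifelse(stats::runif(sizes[u] - 1) < 0.3, -4L, sample(0:20, sizes[u] - 1,
                                                           replace = TRUE))
    else integer(0)
    starts <- integer(sizes[u]); ends <- integer(sizes[u])
    starts[1] <- cursor + pre_gap
    ends[1] <- starts[1] + lens[1] - 1L
    if (sizes[u] > 1) for (j in 2:sizes[u]) {
      starts[j] <- ends[j - 1] + intra[j - 1] + 1L
      ends[j] <- starts[j] + lens[j] - 1L
    }
    if (ends[sizes[u]] > L - 450L)
      stop("infeasible packing: features exceed the genome; ",
           "increase genome_length")
    units[[u]] <- list(starts = starts, ends = ends, strand = strands[u],
                       class = classes[u], internal = internal[u])
    cursor <- ends[sizes[u]]
    feat_rows[[u]] <- data.frame(start = starts, end = ends,
                                 strand = strands[u], unit = u)
  }
  feats <- do.call(rbind, feat_rows)
  feats <- feats[order(feats$start), , drop = FALSE]
  feats$feature_id <- sprintf("gp%02d", seq_len(nrow(feats)))
  # one tRNA among the monocistronic units, the rest ORFs
  feats$kind <- "ORF"
  mono_units <- which(sizes == 1L & !internal)
  if (length(mono_units)) {
    tr_unit <- mono_units[sample.int(length(mono_units), 1)]
    feats$kind[feats$unit == tr_unit] <- "tRNA"
  }
  group_of <- c(early = "DNA replication", middle = "DNA metabolism",
                middle_down = "DNA metabolism", late = "structural")
  feats$functional_group <- ifelse(feats$kind == "tRNA", "tRNA",
                                   group_of[classes[feats$unit]])

  ## ---- TSS placement ----
  unit_span <- t(vapply(units, function(u)
    c(min(u$starts), max(u$ends)), numeric(2)))
  tss_rows <- list()
  for (u in seq_len(n_units)) {
    un <- units[[u]]
    if (un$internal) {
      # promoter inside the first (transcription order) gene
      first <- which.min(un$starts)   # forward strand by construction
      len1 <- un$ends[first] - un$starts[first] + 1L
      pos <- un$starts[first] + max(25L, round(0.4 * len1))
      units[[u]]$tss <- pos
      units[[u]]$tx_start <- pos
      tss_rows[[length(tss_rows) + 1L]] <- data.frame(
        position = pos, strand = "+", orientation = "internal_sense",
        unit = u)
      next
    }
    if (un$strand == "+") {
      gap <- unit_span[u, 1] -
        (if (u > 1) max(unit_span[u - 1, 2],
                        units[[u - 1]]$tss %||% 0) else 0L)
      off <- resample(20:max(20, min(100, gap - 25)))
      pos <- unit_span[u, 1] - off
    } else {
      nxt <- if (u < n_units) unit_span[u + 1, 1] else L
      gap <- nxt - unit_span[u, 2]
      off <- resample(20:max(20, min(100, gap - 25)))
      pos <- unit_span[u, 2] + off
    }
    units[[u]]$tss <- pos
    units[[u]]$tx_start <- if (un$strand == "+") pos else pos
    tss_rows[[length(tss_rows) + 1L]] <- data.frame(
      position = pos, strand = un$strand, orientation = "sense", unit = u)
  }

  ## ---- sense transcript intervals and amplitudes ----
  amp <- stats::runif(n_units, 0.8, 1.6) * spec$mean_depth
  tx <- lapply(seq_len(n_units), function(u) {
    un <- units[[u]]
    if (un$strand == "+") c(units[[u]]$tss, max(un$ends))
    else c(min(un$starts), units[[u]]$tss)
  })

  ## ---- antisense placement ----
  # intervals that must stay clear per strand: transcripts plus the TSS
  # upstream windows (margin), and sense-orientation zones upstream of 5'
  # ends (TSS positions only)
  w_margin <- 30L
  occupied <- list("+" = list(), "-" = list())
  for (u in seq_len(n_units)) {
    s <- units[[u]]$strand
    iv <- c(tx[[u]][1] - w_margin, tx[[u]][2] + w_margin)
    occupied[[s]][[length(occupied[[s]]) + 1L]] <- iv
  }
  sense_zone <- list("+" = list(), "-" = list())
  for (u in seq_len(n_units)) {
    s <- units[[u]]$strand
    z <- if (s == "+") c(unit_span[u, 1] - 250L, unit_span[u, 1])
    else c(unit_span[u, 2], unit_span[u, 2] + 250L)
    sense_zone[[s]][[length(sense_zone[[s]]) + 1L]] <- z
  }
  overlaps_any <- function(iv, lst) {
    for (z in lst) if (iv[1] <= z[2] && z[1] <= iv[2]) return(TRUE)
    FALSE
  }
  grp_w <- c(structural = 0.5, `DNA metabolism` = 0.35,
             `DNA replication` = 0.15)
  unit_group <- ifelse(classes == "early", "DNA replication",
                       ifelse(classes == "late", "structural",
                              "DNA metabolism"))
  target_w <- grp_w[unit_group]
  as_rows <- list()
  as_tx <- list()
  for (k in seq_len(spec$n_antisense_tss)) {
    placed <- FALSE
    for (try in 1:300) {
      u <- sample.int(n_units, 1, prob = target_w)
      s_t <- units[[u]]$strand
      s_a <- setdiff(c("+", "-"), s_t)
      pos <- if (s_t == "+")
        round(stats::runif(1, unit_span[u, 1] + 30, unit_span[u, 2] + 50))
      else
        round(stats::runif(1, unit_span[u, 1] - 50, unit_span[u, 2] - 30))
      len <- round(stats::runif(1, 300, 800))
      iv <- if (s_a == "-") c(pos - len + 1L, pos) else c(pos, pos + len - 1L)
      iv <- c(max(50L, iv[1]), min(L - 50L, iv[2]))
      up_iv <- if (s_a == "+") c(iv[1] - w_margin, iv[2] + 5L)
      else c(iv[1] - 5L, iv[2] + w_margin)
      if (overlaps_any(up_iv, occupied[[s_a]])) next
      if (overlaps_any(c(pos, pos), sense_zone[[s_a]])) next
      occupied[[s_a]][[length(occupied[[s_a]]) + 1L]] <- up_iv
      as_rows[[length(as_rows) + 1L]] <- data.frame(
        position = pos, strand = s_a, orientation = "antisense", unit = u)
      as_tx[[length(as_tx) + 1L]] <- list(iv = iv, strand = s_a,
                                          amp = stats::runif(1, 0.5, 1.5) *
                                            spec$mean_depth)
      placed <- TRUE
      break
    }
    if (!placed) next
  }

  ## ---- coverage tracks ----
  lam <- list("+" = matrix(0, L, nt), "-" = matrix(0, L, nt))
  for (u in seq_len(n_units)) {
    s <- units[[u]]$strand
    span <- tx[[u]][1]:tx[[u]][2]
    prof <- amp[u] * arch[units[[u]]$class, ] / 100
    lam[[s]][span, ] <- lam[[s]][span, ] + rep(prof, each = length(span))
  }
  for (a in as_tx) {
    span <- a$iv[1]:a$iv[2]
    prof <- a$amp * arch["late", ] / 100
    lam[[a$strand]][span, ] <- lam[[a$strand]][span, ] +
      rep(prof, each = length(span))
  }
  tracks <- array(0, dim = c(L, nt, nr, 2),
                  dimnames = list(NULL, NULL, NULL, c("+", "-")))
  for (s in c("+", "-")) for (ti in seq_len(nt)) for (r in seq_len(nr)) {
    tracks[, ti, r, s] <- if (spec$noise == "poisson")
      stats::rpois(L, lam[[s]][, ti]) else lam[[s]][, ti]
  }
  library_size <- matrix(round(stats::runif(nt * nr, 9.2e6, 10.8e6)),
                         nt, nr)
  ann <- genome_annotation(
    feats[c("feature_id", "start", "end", "strand", "kind",
            "functional_group")],
    genome_id = "synthvir1", genome_length = L)
  experiment <- coverage_experiment(tracks, tp, library_size,
                                    genome_id = "synthvir1")

  ## ---- ground truth ----
  truth_classes <- stats::setNames(classes[feats$unit], feats$feature_id)
  members_of <- split(feats$feature_id, feats$unit)
  op_order <- order(vapply(seq_len(n_units), function(u)
    if (strands[u] == "+") unit_span[u, 1] else unit_span[u, 1],
    numeric(1)))
  truth_operons <- lapply(op_order, function(u) {
    mem <- feats$feature_id[feats$unit == u]
    mem <- mem[order(feats$start[feats$unit == u])]
    if (strands[u] == "-") mem <- rev(mem)
    list(members = mem, strand = strands[u], tss = units[[u]]$tss,
         class = classes[u], internal_promoter = internal[u])
  })
  tss_truth <- do.call(rbind, c(tss_rows, as_rows))
  tss_truth <- tss_truth[order(tss_truth$position), , drop = FALSE]
  rownames(tss_truth) <- NULL
  # antisense dominance evaluated on the noise-free expected signal
  n_dom <- integer(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    s <- feats$strand[i]; a <- setdiff(c("+", "-"), s)
    span <- feats$start[i]:feats$end[i]
    sense <- colSums(lam[[s]][span, , drop = FALSE])
    anti <- colSums(lam[[a]][span, , drop = FALSE])
    n_dom[i] <- sum(anti > sense)
  }
  antisense_called <- feats$feature_id[n_dom >= 3]

  host <- simulate_host(spec)

  structure(list(annotation = ann, experiment = experiment,
                 host = host$data, category_map = host$category_map,
                 truth = list(classes = truth_classes,
                              operons = truth_operons,
                              tss = tss_truth,
                              antisense_called = antisense_called,
                              host_deg = host$truth),
                 spec = spec),
            class = "simulated_experiment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() that never falls into the scalar-x trap
resample <- function(x, size = 1) x[sample.int(length(x), size)]

simulate_host <- function(spec) {
  n <- spec$host_n_genes
  genes <- sprintf("hg%04d", seq_len(n))
  letters20 <- c("J", "K", "L", "D", "V", "T", "M", "N", "U", "O",
                 "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S")
  cats <- letters20[seq_len(min(spec$host_n_categories, 20))]
  size_N <- min(37L, n %/% 4)
  size_S <- min(round(0.427 * n), n - size_N - (length(cats) - 2L))
  rest <- n - size_N - size_S
  other <- setdiff(cats, c("N", "S"))
  other_sizes <- as.vector(stats::rmultinom(1, rest - length(other),
                                            stats::runif(length(other),
                                                         0.5, 1.5))) + 1L
  assign <- c(rep("N", size_N), rep("S", size_S),
              rep(other, other_sizes))
  category_map <- stats::setNames(sample(assign), genes)

  nt <- length(spec$timepoints)
  base_mu <- stats::rlnorm(n, log(80), 1)
  in_N <- names(category_map)[category_map == "N"]
  not_N <- setdiff(genes, in_N)
  # disjoint pools so a gene is never up and down at the same timepoint
  pool_size <- min(600L, max(1L, length(not_N) %/% 2 - 1L))
  pool_up <- sample(not_N, pool_size)
  pool_down_nonN <- sample(setdiff(not_N, pool_up), pool_size)
  core_up <- pool_up[seq_len(min(25L, pool_size))]
  core_down <- pool_down_nonN[seq_len(min(30L, pool_size))]
  down_N <- sample(in_N, min(5L, length(in_N)))
  up_sets <- vector("list", nt)
  down_sets <- vector("list", nt)
  for (ti in seq_len(nt)) {
    n_up <- spec$host_up[ti]
    n_dn <- spec$host_down[ti]
    up <- character(0)
    if (n_up > 0) {
      up <- if (spec$timepoints[ti] >= 60) core_up[seq_len(min(25, n_up))]
      else character(0)
      extra <- setdiff(pool_up, up)
      up <- c(up, extra[seq_len(n_up - length(up))])
    }
    dn <- character(0)
    if (n_dn > 0) {
      dn <- if (spec$timepoints[ti] >= 120)
        core_down[seq_len(min(30, n_dn))] else character(0)
      if (n_dn >= 100) dn <- c(dn, down_N)   # category-N plant, late tps
      extra <- setdiff(pool_down_nonN, dn)
      dn <- c(dn, extra[seq_len(n_dn - length(dn))])
    }
    up_sets[[ti]] <- up
    down_sets[[ti]] <- dn
  }
  draw <- function(mu) {
    switch(spec$host_noise,
           nb = stats::rnbinom(length(mu), mu = mu,
                               size = 1 / spec$host_dispersion),
           poisson = stats::rpois(length(mu), mu),
           none = round(mu))
  }
  data <- vector("list", nt)
  for (ti in seq_len(nt)) {
    fold <- rep(1, n)
    fold[match(up_sets[[ti]], genes)] <- spec$host_deg_fold
    fold[match(down_sets[[ti]], genes)] <- 1 / spec$host_deg_fold
    depth_i <- if (spec$host_noise == "none") rep(1, 3)
    else stats::runif(3, 0.9, 1.1)
    depth_c <- if (spec$host_noise == "none") rep(1, 3)
    else stats::runif(3, 0.9, 1.1)
    infected <- vapply(1:3, function(r) draw(base_mu * fold * depth_i[r]),
                       numeric(n))
    control <- vapply(1:3, function(r) draw(base_mu * depth_c[r]),
                      numeric(n))
    dimnames(infected) <- dimnames(control) <-
      list(genes, sprintf("rep%d", 1:3))
    data[[ti]] <- list(timepoint = spec$timepoints[ti],
                       infected = infected, control = control)
  }
  names(data) <- sprintf("t%g", spec$timepoints)
  truth <- lapply(seq_len(nt), function(ti)
    list(up = up_sets[[ti]], down = down_sets[[ti]]))
  names(truth) <- names(data)
  list(data = data, category_map = category_map, truth = truth)
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf(paste0("<simulated_experiment> seed %d: %d features, ",
                     "%d planted unit(s), %d planted TSS(s), %d antisense",
                     "-dominated gene(s)\n"),
              x$spec$seed, nrow(x$annotation$features),
              length(x$truth$operons), nrow(x$truth$tss),
              length(x$truth$antisense_called)))
  invisible(x)
}

#' Write a simulated experiment to disk as a fixture directory
#'
#' Produces `annotation.gff3`, one bedGraph per (timepoint, replicate,
#' strand) plus `manifest.tsv`, host count TSVs, `category_map.tsv` and
#' `ground_truth.json` -- everything readable back by the package's own
#' readers.
#'
#' @param sim a `simulated_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(sim$annotation, file.path(dir, "annotation.gff3"))
  write_bedgraph_set(sim$experiment, dir)
  for (nm in names(sim$host)) {
    h <- sim$host[[nm]]
    utils::write.table(h$infected, file.path(dir,
                                             sprintf("host_infected_%s.tsv",
                                                     nm)),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(h$control, file.path(dir,
                                            sprintf("host_control_%s.tsv",
                                                    nm)),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  utils::write.table(
    data.frame(gene = names(sim$category_map),
               category = unname(sim$category_map)),
    file.path(dir, "category_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  truth <- sim$truth
  truth$classes <- as.list(truth$classes)   # keep names as JSON keys
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(dir)
}

#' Read a fixture directory back into memory
#'
#' @param dir directory written by [write_fixture()].
#' @return list with `annotation`, `experiment`, `host`, `category_map` and
#'   `truth` (parsed JSON).
#' @export
read_fixture <- function(dir) {
  ann <- read_annotation(file.path(dir, "annotation.gff3"))
  exp <- read_bedgraph_set(file.path(dir, "manifest.tsv"),
                           genome_length = ann$genome_length,
                           genome_id = ann$genome_id)
  cm <- utils::read.delim(file.path(dir, "category_map.tsv"),
                          stringsAsFactors = FALSE)
  category_map <- stats::setNames(cm$category, cm$gene)
  host_files <- list.files(dir, "^host_infected_", full.names = FALSE)
  tags <- sub("^host_infected_(.*)\\.tsv$", "\\1", host_files)
  host <- lapply(tags, function(tag) {
    inf <- as.matrix(utils::read.delim(
      file.path(dir, sprintf("host_infected_%s.tsv", tag)), row.names = 1))
    ctl <- as.matrix(utils::read.delim(
      file.path(dir, sprintf("host_control_%s.tsv", tag)), row.names = 1))
    list(timepoint = as.numeric(sub("^t", "", tag)), infected = inf,
         control = ctl)
  })
  names(host) <- tags
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  list(annotation = ann, experiment = exp, host = host,
       category_map = category_map, truth = truth)
}
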