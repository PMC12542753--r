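#' Call differentially expressed host genes (exact count-ratio stand-in)
#'
#' A deliberately simple, fully documented DE caller: per gene, counts are
#' library-size-normalized, the log2 fold change is computed from normalized
#' means with a pseudocount of 0.5, and the p-value comes from the exact
#' conditional binomial test on replicate-summed raw counts (the classic
#' two-sample Poisson rate-ratio test, conditioning the infected sum on the
#' total with success probability equal to the infected share of the summed
#' library sizes). The test is exact under Poisson count noise and
#' anticonservative under strong overdispersion; see the package vignette.
#' External DEG tables can be substituted anywhere downstream.
#'
#' @param infected,control count matrices (genes x replicates) on a shared
#'   gene universe (rownames are gene ids).
#' @param lib_infected,lib_control library sizes per replicate (default:
#'   column sums).
#' @param alpha significance cutoff on the (by default unadjusted) p-value
#'   (default 0.05, mirroring a raw p < 0.05 DEG selection).
#' @param lfc_floor optional absolute log2FC floor; genes below it are `ns`
#'   (default 0 = off).
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg.
#' @return data.frame with `gene`, `log2_fold_change`, `p_value` and
#'   `direction` (`"up"`, `"down"` or `"ns"`).
#' @export
call_degs <- function(infected, control, lib_infected = NULL,
                      lib_control = NULL, alpha = 0.05, lfc_floor = 0,
                      p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  infected <- as.matrix(infected)
  control <- as.matrix(control)
  if (!identical(rownames(infected), rownames(control)) ||
      nrow(infected) != nrow(control))
    stop("infected and control matrices must share the same gene universe")
  if (is.null(lib_infected) || is.null(lib_control)) {
    # median-of-ratios effective sizes: robust to the composition shift a
    # strong planted/true DE signal induces in plain total counts
    sf <- estimate_size_factors(cbind(infected, control))
    if (is.null(lib_infected))
      lib_infected <- sf[seq_len(ncol(infected))] * 1e6
    if (is.null(lib_control))
      lib_control <- sf[ncol(infected) + seq_len(ncol(control))] * 1e6
  }
  scale_to <- mean(c(lib_infected, lib_control))
  m_inf <- rowMeans(sweep(infected, 2, scale_to / lib_infected, `*`))
  m_ctl <- rowMeans(sweep(control, 2, scale_to / lib_control, `*`))
  lfc <- log2((m_inf + 0.5) / (m_ctl + 0.5))
  x_inf <- rowSums(infected)
  x_ctl <- rowSums(control)
  t_inf <- sum(lib_infected)
  t_ctl <- sum(lib_control)
  p0 <- t_inf / (t_inf + t_ctl)
  n <- x_inf + x_ctl
  pv <- vapply(seq_along(n), function(i) {
    if (n[i] == 0) return(1)
    stats::binom.test(x_inf[i], n[i], p = p0)$p.value
  }, numeric(1))
  if (p_adjust == "BH") pv <- stats::p.adjust(pv, "BH")
  sig <- pv < alpha & abs(lfc) >= lfc_floor & abs(lfc) > 0
  direction <- ifelse(!sig, "ns", ifelse(lfc > 0, "up", "down"))
  data.frame(gene = rownames(infected), log2_fold_change = lfc,
             p_value = pv, direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Median-of-ratios size factors
#'
#' DESeq-style effective library sizes: per sample, the median ratio of its
#' counts to the per-gene geometric mean across samples, over genes with no
#' zero count. Falls back to relative total counts when no gene is
#' everywhere nonzero.
#'
#' @param mat count matrix (genes x samples).
#' @return numeric vector of size factors, one per sample.
#' @export
estimate_size_factors <- function(mat) {
  mat <- as.matrix(mat)
  lg <- log(mat)
  lg[!is.finite(lg)] <- NA
  ref <- rowMeans(lg)
  keep <- is.finite(ref)
  if (!any(keep)) return(colSums(mat) / mean(colSums(mat)))
  apply(lg[keep, , drop = FALSE], 2, function(col)
    exp(stats::median(col - ref[keep], na.rm = TRUE)))
}

#' Functional-category fold over-/underrepresentation
#'
#' For each category the observed share of DEGs is compared with the share
#' expected under a random distribution of all DEGs over categories:
#' `pct_expected = 100 * category_size / genome_size`,
#' `pct_observed = 100 * deg_in_category / deg_total`,
#' `fold = pct_observed / pct_expected`. For display, underrepresentation is
#' reported on a signed scale: `signed_representation = fold` when
#' `fold >= 1`, else `-1/fold` -- so values never fall in (-1, 1), 1 means
#' "as expected", and e.g. -2 means half the expected share. Genes missing
#' from the category map are assigned to category `"S"` (unknown function)
#' and remain part of the genome universe.
#'
#' @param deg_genes character vector of DEG ids (one direction, one
#'   timepoint).
#' @param category_map named character vector mapping every genome gene to a
#'   category letter (names = gene ids), or a data.frame with columns `gene`
#'   and `category`.
#' @param genome_size genome universe size (default: number of mapped genes).
#' @param hypergeometric also report a one-sided hypergeometric
#'   overrepresentation p-value per category (default `FALSE`).
#' @return data.frame with one row per category present in the genome:
#'   `category`, `category_size`, `genome_size`, `deg_count_in_category`,
#'   `deg_total`, `pct_expected`, `pct_observed`, `fold`,
#'   `signed_representation` (and `p_hyper` if requested). Empty, with a
#'   warning, when `deg_genes` is empty -- timepoints with too few DEGs are
#'   better omitted than over-interpreted.
#' @examples
#' map <- setNames(rep(c("N", "X"), c(37, 4016)), sprintf("g%04d", 1:4053))
#' degs <- c(names(map)[1:5], names(map)[38:150])  # 5 of 118 in category N
#' enr <- enrich_categories(degs, map)
#' round(enr[enr$category == "N",
#'           c("pct_expected", "pct_observed", "fold")], 2)
#' @export
enrich_categories <- function(deg_genes, category_map, genome_size = NULL,
                              hypergeometric = FALSE) {
  if (is.data.frame(category_map))
    category_map <- stats::setNames(as.character(category_map$category),
                                    category_map$gene)
  deg_genes <- unique(as.character(deg_genes))
  deg_total <- length(deg_genes)
  if (deg_total == 0L) {
    warning("no differentially expressed genes; returning empty enrichment")
    return(data.frame(category = character(), category_size = integer(),
                      genome_size = integer(),
                      deg_count_in_category = integer(),
                      deg_total = integer(), pct_expected = numeric(),
                      pct_observed = numeric(), fold = numeric(),
                      signed_representation = numeric()))
  }
  deg_cat <- category_map[deg_genes]
  deg_cat[is.na(deg_cat)] <- "S"
  if (is.null(genome_size)) genome_size <- length(category_map)
  cat_sizes <- table(category_map)
  n_unmapped <- genome_size - length(category_map)
  if (n_unmapped > 0) {
    # genome genes absent from the map count as category S (unknown)
    cat_sizes <- table(c(category_map,
                         rep("S", n_unmapped)))
  }
  cats <- sort(names(cat_sizes))
  out <- data.frame(category = cats,
                    category_size = as.integer(cat_sizes[cats]),
                    genome_size = as.integer(genome_size),
                    deg_count_in_category = as.integer(
                      table(factor(deg_cat, levels = cats))),
                    deg_total = deg_total, stringsAsFactors = FALSE)
  out$pct_expected <- 100 * out$category_size / out$genome_size
  out$pct_observed <- 100 * out$deg_count_in_category / out$deg_total
  out$fold <- out$pct_observed / out$pct_expected
  out$signed_representation <- ifelse(out$fold >= 1, out$fold,
                                      -1 / out$fold)
  if (hypergeometric)
    out$p_hyper <- stats::phyper(out$deg_count_in_category - 1,
                                 out$category_size,
                                 out$genome_size - out$category_size,
                                 out$deg_total, lower.tail = FALSE)
  out
}

#' Core and timepoint-exclusive DEG sets
#'
#' Set algebra over per-timepoint DEG sets of one direction: the core set of
#' genes differential at every timepoint in the window, and per-timepoint
#' exclusive sets (genes differential only at that timepoint).
#'
#' @param sets named list of character vectors (one per timepoint, in
#'   temporal order); at least one, typically >= 2.
#' @return list with `core` (intersection over all sets) and `exclusive`
#'   (named list of per-timepoint exclusive genes).
#' @export
core_deg_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  core <- Reduce(intersect, sets)
  exclusive <- lapply(seq_along(sets), function(i) {
    others <- unlist(sets[-i], use.names = FALSE)
    setdiff(sets[[i]], others)
  })
  names(exclusive) <- names(sets)
  list(core = core, exclusive = exclusive)
}

#' DEG gene sets by direction from a DEG table
#'
#' @param deg_table result of [call_degs()].
#' @param direction `"up"` or `"down"`.
#' @return character vector of gene ids.
#' @export
deg_set <- function(deg_table, direction = c("up", "down")) {
  direction <- match.arg(direction)
  deg_table$gene[deg_table$direction == direction]
}
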