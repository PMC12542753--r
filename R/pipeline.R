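#' Default pipeline configuration
#'
#' One nested list carrying every stage's parameters. Unknown keys are
#' rejected when merging user settings, so typos cannot silently fall back
#' to defaults.
#'
#' @param ... named overrides; nested lists merge section-wise, e.g.
#'   `pipeline_config(classifier = list(early_deadline = 30))`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    simulation = NULL,          # a simulation_spec to simulate inputs, or
    input = list(annotation = NULL, manifest = NULL,    # paths to read
                 genome_length = NULL),
    profiles = list(expression_floor = 1, read_length_proxy = 75),
    classifier = list(half_max_threshold = 50, early_deadline = 20,
                      middle_deadline = 60),
    tss = list(window = 20, min_step_ratio = 5, min_coverage = 10,
               replicate_quorum = NULL, upstream_max = 250,
               antisense_downstream = 100, antisense_min_timepoints = 3),
    operon = list(gap_max = 30, continuity_frac = 0.9,
                  continuity_min_cov = 5),
    de = list(alpha = 0.05, lfc_floor = 0, p_adjust = "none"),
    enrichment = list(hypergeometric = FALSE),
    run_host = TRUE,
    output_dir = NULL,
    verbose = FALSE)
  user <- list(...)
  cfg <- merge_config(defaults, user, path = "config")
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !inherits(user[[k]], "simulation_spec") &&
        !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste(path, k, sep = "$"))
    else defaults[k] <- user[k]
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds the same nested sections as [pipeline_config()];
#' unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation))
    y$simulation <- do.call(simulation_spec, y$simulation)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Orchestrates annotation -> coverage -> temporal profiles -> half-maximum
#' classification -> TSS detection and orientation -> antisense calling ->
#' operon assembly, either on simulated inputs (when `config$simulation` is
#' a [simulation_spec()]) or on files named in `config$input`. When output
#' files are requested every stage's table is written under
#' `config$output_dir` together with a provenance record (full
#' configuration, seed, package version).
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with `annotation`, `experiment`,
#'   `profiles`, `classes`, `tss`, `antisense`, `operons`,
#'   `operon_summary`, `truth` (when simulated), and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (isTRUE(config$verbose))
    message(sprintf(...))
  truth <- NULL
  sim <- NULL
  if (!is.null(config$simulation)) {
    stopifnot(inherits(config$simulation, "simulation_spec"))
    say("stage simulate: seed %d", config$simulation$seed)
    sim <- simulate_experiment(config$simulation)
    ann <- sim$annotation
    exp <- sim$experiment
    truth <- sim$truth
  } else {
    if (is.null(config$input$annotation) || is.null(config$input$manifest))
      stop("config must name input$annotation and input$manifest ",
           "(or set simulation)")
    say("stage read: %s", config$input$annotation)
    ann <- read_annotation(config$input$annotation)
    exp <- read_bedgraph_set(config$input$manifest,
                             genome_length = config$input$genome_length %||%
                               ann$genome_length,
                             genome_id = ann$genome_id)
  }
  say("stage profiles: %d features", nrow(ann$features))
  profiles <- temporal_profiles(exp, ann,
                                expression_floor =
                                  config$profiles$expression_floor,
                                read_length_proxy =
                                  config$profiles$read_length_proxy)
  ccfg <- classifier_config(config$classifier$half_max_threshold,
                            config$classifier$early_deadline,
                            config$classifier$middle_deadline)
  classes <- classify_all(profiles, ccfg)
  say("stage tss")
  tss <- detect_tss_both(exp, ann,
                         window = config$tss$window,
                         min_step_ratio = config$tss$min_step_ratio,
                         min_coverage = config$tss$min_coverage,
                         replicate_quorum = config$tss$replicate_quorum,
                         upstream_max = config$tss$upstream_max,
                         antisense_downstream =
                           config$tss$antisense_downstream)
  antisense <- call_antisense_genes(exp, ann,
                                    config$tss$antisense_min_timepoints)
  say("stage operons")
  operons <- assemble_operons(ann, classes, exp, tss,
                              gap_max = config$operon$gap_max,
                              continuity_frac = config$operon$continuity_frac,
                              continuity_min_cov =
                                config$operon$continuity_min_cov,
                              upstream_max = config$tss$upstream_max)
  host <- NULL
  if (!is.null(sim) && isTRUE(config$run_host)) {
    say("stage host DE + enrichment")
    host <- run_host_stage(sim$host, sim$category_map, config)
  }
  res <- structure(list(
    annotation = ann, experiment = exp, profiles = profiles,
    classes = classes, tss = tss, antisense = antisense,
    operons = operons,
    operon_summary = if (length(operons)) summarize_operons(operons) else
      NULL,
    host = host, truth = truth,
    provenance = list(config = config,
                      seed = if (!is.null(sim)) sim$spec$seed else NA,
                      package_version =
                        as.character(utils::packageVersion("virotime")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_outputs(res, config)
  res
}

run_host_stage <- function(host_data, category_map, config) {
  degs <- lapply(host_data, function(h)
    call_degs(h$infected, h$control, alpha = config$de$alpha,
              lfc_floor = config$de$lfc_floor,
              p_adjust = config$de$p_adjust))
  enr <- lapply(degs, function(d) {
    out <- list()
    for (dir in c("up", "down")) {
      genes <- deg_set(d, dir)
      out[[dir]] <- if (length(genes))
        enrich_categories(genes, category_map,
                          hypergeometric = config$enrichment$hypergeometric)
      else NULL   # omitted: too few DEGs to interpret
    }
    out
  })
  up_sets <- lapply(degs, deg_set, "up")
  down_sets <- lapply(degs, deg_set, "down")
  list(degs = degs, enrichment = enr,
       core = list(up = core_deg_sets(up_sets),
                   down = core_deg_sets(down_sets)))
}

write_pipeline_outputs <- function(res, config) {
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(res$annotation, file.path(dir, "features.tsv"))
  write_profile_table(res$profiles, file.path(dir, "profiles.tsv"))
  write_class_table(res$classes, file.path(dir, "classes.tsv"),
                    res$profiles)
  write_tss_bed(res$tss, file.path(dir, "tss.bed"),
                res$annotation$genome_id)
  utils::write.table(res$antisense, file.path(dir, "antisense.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(res$operons))
    write_operon_table(res$operons, file.path(dir, "operons.tsv"))
  if (!is.null(res$host)) {
    for (nm in names(res$host$degs)) {
      utils::write.table(res$host$degs[[nm]],
                         file.path(dir, sprintf("degs_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (dir2 in c("up", "down")) {
        e <- res$host$enrichment[[nm]][[dir2]]
        if (!is.null(e))
          utils::write.table(e, file.path(dir,
                                          sprintf("enrichment_%s_%s.tsv",
                                                  nm, dir2)),
                             sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  prov <- res$provenance
  prov$config$simulation <- unclass(prov$config$simulation)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  writeLines(pipeline_report(res), file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable summary of a pipeline run
#'
#' Per-class counts, operon summary, antisense-dominated genes and (when
#' host data was analyzed) enrichment highlights; percentages to one
#' decimal.
#'
#' @param res a `pipeline_result`.
#' @return character vector of report lines.
#' @export
pipeline_report <- function(res) {
  lines <- c(sprintf("== virotime pipeline report (%s) ==",
                     res$annotation$genome_id))
  s <- class_summary(res$classes)
  lines <- c(lines, "temporal classes:",
             sprintf("  %-12s %3d (%.1f%%)", s$label, s$count, s$pct))
  if (!is.null(res$operon_summary)) {
    o <- res$operon_summary
    lines <- c(lines, sprintf(
      "operons: %d unit(s), %d monocistronic (%.1f%%), %.2f genes/unit",
      o$n_units, o$n_monocistronic, o$pct_monocistronic,
      o$mean_genes_per_operon))
  }
  called <- res$antisense$feature_id[res$antisense$called]
  lines <- c(lines, sprintf("TSSs detected: %d (%s)", nrow(res$tss),
                            paste(names(table(res$tss$orientation)),
                                  table(res$tss$orientation),
                                  sep = ":", collapse = " ")),
             sprintf("antisense-dominated genes: %d%s", length(called),
                     if (length(called))
                       paste0(" (", paste(called, collapse = ", "), ")")
                     else ""))
  if (!is.null(res$host)) {
    for (nm in names(res$host$degs)) {
      d <- res$host$degs[[nm]]
      n_up <- sum(d$direction == "up"); n_dn <- sum(d$direction == "down")
      note <- if (is.null(res$host$enrichment[[nm]]$up) &&
                  is.null(res$host$enrichment[[nm]]$down))
        " [enrichment omitted: too few DEGs]" else ""
      lines <- c(lines, sprintf("host %s: %d up / %d down%s", nm, n_up,
                                n_dn, note))
    }
  }
  lines
}

#' Score a pipeline run against planted ground truth
#'
#' @param res a `pipeline_result` from a simulated run (or any list with
#'   `classes`, `tss`, `operons`, `antisense`).
#' @param truth the generator's ground-truth list.
#' @param genome_length genome length in nt (for the false-TSS rate).
#' @return list with `class_recovery` (fraction of features with the planted
#'   label), `tss_recall` (fraction of planted TSSs found at the exact
#'   position and strand), `false_tss` (count), `false_tss_per_10kb`,
#'   `operon_exact` (planted partition recovered exactly) and
#'   `antisense_exact` (called set equals the planted set).
#' @export
evaluate_recovery <- function(res, truth,
                              genome_length = res$annotation$genome_length) {
  pred <- stats::setNames(res$classes$label, res$classes$feature_id)
  ids <- names(truth$classes)
  class_recovery <- mean(pred[ids] == unlist(truth$classes[ids]))
  tkey <- paste(truth$tss$position, truth$tss$strand)
  dkey <- paste(res$tss$position, res$tss$strand)
  tss_recall <- mean(tkey %in% dkey)
  false_tss <- sum(!dkey %in% tkey)
  part <- operon_partition(res$operons)
  tpart <- lapply(truth$operons, `[[`, "members")
  key <- function(p) sort(vapply(p, paste, character(1), collapse = ";"))
  operon_exact <- identical(key(part), key(tpart))
  called <- sort(res$antisense$feature_id[res$antisense$called])
  antisense_exact <- identical(called,
                               sort(as.character(unlist(
                                 truth$antisense_called))))
  list(class_recovery = class_recovery,
       tss_recall = tss_recall,
       false_tss = false_tss,
       false_tss_per_10kb = false_tss / (genome_length / 1e4),
       operon_exact = operon_exact,
       antisense_exact = antisense_exact)
}
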