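#' Construct a genome annotation
#'
#' The basic feature container used throughout the package: a set of ORF/tRNA
#' features on a single (viral) genome. Coordinates are 1-based inclusive on
#' both ends, the convention of GFF3 and of Bioconductor ranges; features are
#' kept sorted by start position.
#'
#' @param features data.frame with columns `feature_id`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`), `kind` (`"ORF"` or `"tRNA"`) and
#'   `functional_group` (free-text label, e.g. `"DNA metabolism"`).
#' @param genome_id single string naming the genome.
#' @param genome_length genome length in nucleotides.
#' @param topology `"linear"` (default) or `"circular"`. All gap and coverage
#'   arithmetic in this package is linear; the flag is carried so circularly
#'   permuted genomes can be marked as such.
#' @return An object of class `genome_annotation`: a list with elements
#'   `genome_id`, `genome_length`, `features` (sorted data.frame) and
#'   `topology`.
#' @examples
#' feats <- data.frame(feature_id = c("gp01", "gp02"),
#'                     start = c(101, 501), end = c(400, 900),
#'                     strand = c("+", "-"), kind = "ORF",
#'                     functional_group = c("DNA metabolism", "structural"))
#' ann <- genome_annotation(feats, "toy", 2000)
#' ann
#' @export
genome_annotation <- function(features, genome_id, genome_length,
                              topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            is.numeric(genome_length), length(genome_length) == 1L,
            genome_length >= 1)
  needed <- c("feature_id", "start", "end", "strand", "kind",
              "functional_group")
  if (!is.data.frame(features))
    stop("`features` must be a data.frame")
  if (nrow(features) == 0L && !all(needed %in% names(features)))
    features <- empty_features()
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols))
    stop("features table lacks column(s): ", paste(missing_cols, collapse = ", "))
  features <- features[needed]
  features$feature_id <- as.character(features$feature_id)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.character(features$strand)
  features$kind <- as.character(features$kind)
  features$functional_group <- as.character(features$functional_group)
  ann <- structure(list(genome_id = genome_id,
                        genome_length = as.integer(genome_length),
                        features = features,
                        topology = topology),
                   class = "genome_annotation")
  validate_annotation(ann)
}

empty_features <- function() {
  data.frame(feature_id = character(), start = integer(), end = integer(),
             strand = character(), kind = character(),
             functional_group = character(), stringsAsFactors = FALSE)
}

#' Validate a genome annotation
#'
#' Checks the container invariants: coordinates within `[1, genome_length]`,
#' `end >= start`, ORFs at least 3 nt long, unique feature ids, strands in
#' `{+,-}` and kinds in `{ORF, tRNA}`. Features are re-sorted by start.
#'
#' @param ann a `genome_annotation`.
#' @return `ann`, invisibly sorted, or an error describing the violation.
#' @export
validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  f <- ann$features
  if (nrow(f) == 0L) return(invisible(ann))
  if (anyDuplicated(f$feature_id))
    stop("duplicate feature_id: ",
         paste(unique(f$feature_id[duplicated(f$feature_id)]), collapse = ", "))
  if (!all(f$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(f$kind %in% c("ORF", "tRNA")))
    stop("kind must be 'ORF' or 'tRNA'")
  if (any(f$end < f$start))
    stop("feature(s) with end < start: ",
         paste(f$feature_id[f$end < f$start], collapse = ", "))
  len <- f$end - f$start + 1L
  if (any(f$kind == "ORF" & len < 3L))
    stop("ORF shorter than 3 nt: ",
         paste(f$feature_id[f$kind == "ORF" & len < 3L], collapse = ", "))
  bad <- f$start < 1L | f$end > ann$genome_length
  if (any(bad))
    stop("feature(s) outside [1, genome_length]: ",
         paste(f$feature_id[bad], collapse = ", "))
  ord <- order(f$start, f$end)
  ann$features <- f[ord, , drop = FALSE]
  rownames(ann$features) <- NULL
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d nt (%s), %d feature(s)\n",
              x$genome_id, x$genome_length, x$topology, nrow(x$features)))
  if (nrow(x$features)) {
    cat(sprintf("  strands: +%d / -%d; kinds: %s\n",
                sum(x$features$strand == "+"), sum(x$features$strand == "-"),
                paste(names(table(x$features$kind)),
                      table(x$features$kind), sep = ":", collapse = " ")))
  }
  invisible(x)
}

#' Read a genome annotation from GFF3
#'
#' CDS features become kind `"ORF"` and tRNA features kind `"tRNA"`; other
#' types are ignored. The functional-group label is read from a configurable
#' attribute key. Genome length is taken from the `##sequence-region` pragma
#' when present, otherwise from `genome_length`.
#'
#' @param path GFF3 file (1-based inclusive coordinates, per the standard).
#' @param functional_group_attr attribute key holding the functional group
#'   (default `"function"`).
#' @param genome_length override/fallback genome length in nt.
#' @param topology genome topology flag, `"linear"` or `"circular"`.
#' @return a [genome_annotation()].
#' @export
read_annotation <- function(path, functional_group_attr = "function",
                            genome_length = NULL,
                            topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  seqreg <- read_sequence_region(path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("failed to parse GFF3 '", path,
                                          "': ", conditionMessage(e)))
  keep <- as.character(gr$type) %in% c("CDS", "tRNA")
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% colnames(mc)) as.character(mc$ID) else
    sprintf("feature_%d", seq_along(gr))
  fg <- if (functional_group_attr %in% colnames(mc))
    as.character(mc[[functional_group_attr]]) else rep(NA_character_, length(gr))
  feats <- data.frame(
    feature_id = ids,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = ifelse(as.character(mc$type) == "CDS", "ORF", "tRNA"),
    functional_group = fg,
    stringsAsFactors = FALSE)
  gid <- if (!is.null(seqreg)) seqreg$genome_id else
    as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(gr)))[1]
  glen <- if (!is.null(genome_length)) genome_length else if (!is.null(seqreg))
    seqreg$length else if (nrow(feats)) max(feats$end) else 1L
  if (is.na(gid) || !length(gid)) gid <- "genome"
  genome_annotation(feats, genome_id = gid, genome_length = glen,
                    topology = topology)
}

read_sequence_region <- function(path) {
  # lightweight pragma scan; rtracklayer drops ##sequence-region on import
  head_lines <- readLines(path, n = 50L)
  sr <- grep("^##sequence-region", head_lines, value = TRUE)
  if (!length(sr)) return(NULL)
  parts <- strsplit(trimws(sr[1]), "[ \t]+")[[1]]
  if (length(parts) < 4L) return(NULL)
  list(genome_id = parts[2], length = as.integer(parts[4]))
}

#' Write a genome annotation to GFF3
#'
#' Inverse of [read_annotation()]: the round trip preserves ids, coordinates,
#' strands, kinds and functional groups. A `##sequence-region` pragma records
#' the genome length.
#'
#' @param ann a `genome_annotation`.
#' @param path output file path.
#' @param functional_group_attr attribute key used for the functional group.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, functional_group_attr = "function") {
  ann <- validate_annotation(ann)
  f <- ann$features
  gr <- GenomicRanges::GRanges(
    seqnames = ann$genome_id,
    ranges = IRanges::IRanges(f$start, f$end),
    strand = f$strand)
  mc <- S4Vectors::mcols(gr)
  mc$ID <- f$feature_id
  mc$type <- ifelse(f$kind == "ORF", "CDS", "tRNA")
  mc[[functional_group_attr]] <- f$functional_group
  S4Vectors::mcols(gr) <- mc
  suppressWarnings(rtracklayer::export.gff3(gr, path))
  lines <- readLines(path)
  pragma <- sprintf("##sequence-region %s 1 %d", ann$genome_id,
                    ann$genome_length)
  lines <- append(lines, pragma, after = 1L)
  writeLines(lines, path)
  invisible(path)
}

#' Export the feature table as TSV
#'
#' Columns: feature_id, start, end (both 1-based inclusive), strand, kind,
#' functional_group.
#'
#' @param ann a `genome_annotation`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ann, path) {
  utils::write.table(ann$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Intergenic gap between two same-strand features
#'
#' Signed distance between a feature and the next one in genome order:
#' `gap = b$start - a$end - 1`. Zero means the stop of `a` abuts the start of
#' `b`; negative values denote overlap (e.g. -4 for an ATGA-type stop/start
#' overlap).
#'
#' @param a,b single features (one-row data.frames or lists with `start`,
#'   `end`, `strand`); `a` must precede `b` in genome order and both must be
#'   on the same strand.
#' @return signed integer gap in nucleotides.
#' @export
intergenic_gap <- function(a, b) {
  if (!identical(as.character(a$strand), as.character(b$strand)))
    stop("intergenic_gap is undefined for features on different strands")
  if (b$start < a$start)
    stop("`a` must precede `b` in genome order")
  as.integer(b$start) - as.integer(a$end) - 1L
}

feature_by_id <- function(ann, id) {
  i <- match(id, ann$features$feature_id)
  if (is.na(i)) stop("unknown feature_id: ", id)
  ann$features[i, , drop = FALSE]
}

# 5' end of a feature in transcription order
feature_5p <- function(feat) if (feat$strand == "+") feat$start else feat$end
feature_3p <- function(feat) if (feat$strand == "+") feat$end else feat$start
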