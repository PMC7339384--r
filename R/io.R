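# Readers and writers for the standard interchange formats: FASTA
# references, collapsed read TSVs, SAM alignments, BED annotations and
# YAML configurations.

#' Write sequences to FASTA
#' @param seqs Named character vector (RNA or DNA alphabet).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::RNAStringSet(gsub("T", "U", toupper(seqs)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector in the RNA alphabet.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readRNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a collapsed small-RNA read table
#'
#' TSV with columns `seq` and `count` (one row per distinct read).
#'
#' @param path Input path.
#' @return Tibble with `seq`, `count`.
#' @export
read_collapsed_reads <- function(path) {
  readr::read_tsv(path, col_types = "ci")
}

#' Write a collapsed small-RNA read table
#' @param reads Tibble with `seq` and `count` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_reads <- function(reads, path) {
  readr::write_tsv(reads[, c("seq", "count")], path)
  invisible(path)
}

#' Read alignments from a SAM/BAM file
#'
#' Maps primary and secondary alignments into the package's alignment
#' tibble (0-based half-open coordinates). Copy counts are taken from a
#' trailing `_xN` suffix on the read name (collapsed-read convention)
#' or default to 1.
#'
#' @param path SAM or BAM path.
#' @return Tibble with `seq`, `count`, `trna_id`, `start`, `end`,
#'   `strand`.
#' @export
read_alignments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read SAM/BAM input", call. = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "strand", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  count <- ifelse(grepl("_x[0-9]+$", b$qname),
                  as.integer(sub("^.*_x", "", b$qname)), 1L)
  tibble::tibble(
    seq = gsub("T", "U", as.character(b$seq)),
    count = count,
    trna_id = as.character(b$rname),
    start = b$pos - 1L,
    end = b$pos - 1L + b$qwidth,
    strand = as.character(b$strand)
  )
}

#' Write a feature table as BED
#'
#' 0-based half-open intervals; the `name` column carries the feature
#' id or label, `score` an optional score column.
#'
#' @param features Tibble with `ref_id` (or `trna_id`), `start`, `end`
#'   and optionally `name`/`score`/`strand` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  chrom <- features[["ref_id"]] %||% features[["trna_id"]]
  bed <- data.frame(
    chrom = chrom, start = features$start, end = features$end,
    name = features[["name"]] %||% features[["locus_id"]] %||%
      features[["trf_id"]] %||% ".",
    score = features[["score"]] %||% 0,
    strand = features[["strand"]] %||% features[["strands"]] %||% "."
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a simulation or pipeline configuration to YAML
#' @param config A [sim_config()] or [pipeline_config()] list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$trf_cleavage_profile)) {
    x$trf_cleavage_profile <- as.list(as.data.frame(x$trf_cleavage_profile))
  }
  if (!is.null(x$condition_effects)) {
    # as.list preserves the names that yaml drops from atomic vectors
    x$condition_effects <- as.list(x$condition_effects)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a configuration written by [write_config_yaml()]
#' @param path YAML path.
#' @param type `"sim"` or `"pipeline"`.
#' @return The restored configuration object.
#' @export
read_config_yaml <- function(path, type = c("sim", "pipeline")) {
  type <- match.arg(type)
  x <- yaml::read_yaml(path)
  if (type == "sim") {
    if (!is.null(x$trf_cleavage_profile)) {
      x$trf_cleavage_profile <- as.data.frame(x$trf_cleavage_profile)
    }
    if (!is.null(x$condition_effects)) {
      x$condition_effects <- unlist(x$condition_effects)
      if (is.null(x$condition_effects)) x$condition_effects <- numeric(0)
    }
    do.call(sim_config, x)
  } else {
    do.call(pipeline_config, x)
  }
}
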