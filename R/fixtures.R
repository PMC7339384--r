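# Packaged reference tables from a two-library (control C1D vs
# ABA-treated A1D) small-RNA experiment in tomato leaves: the
# stress-related phasiRNA/target table and the per-class expression
# totals. These ship as plain TSV under extdata and back the exact
# aggregate checks.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "trfphas")
  if (!nzchar(p)) stop("packaged fixture '", file, "' not found",
                       call. = FALSE)
  p
}

#' Stress-related phasiRNA / target-gene reference table
#'
#' The curated table of 15 differentially expressed phasiRNAs predicted
#' to target stress-related genes (transcription factors and the
#' NBS-LRR / STK / RLK resistance families), with their RPM in the
#' control (`C1D`) and ABA-treated (`A1D`) libraries, the number of
#' predicted target genes per family, and the detected-transcript
#' counts by response (`sum = up + down + no_change`; rows with `NA`
#' counts had no detected transcript). `shared` letters mark target
#' genes shared between phasiRNAs (lower case) and the reference sets
#' they belong to (upper case).
#'
#' @return Tibble with columns `phasirna_id`, `c1d_rpm`, `a1d_rpm`,
#'   `family`, `target_genes`, `sum`, `up`, `down`, `no_change`,
#'   `shared`.
#' @export
phasirna_target_table <- function() {
  tb <- readr::read_tsv(fixture_path("phasirna_stress_targets.tsv"),
                        col_types = "cddciiiiic")
  if (dplyr::n_distinct(tb$phasirna_id) != 15L) {
    stop("corrupt fixture: expected 15 distinct phasiRNA ids",
         call. = FALSE)
  }
  if (any(stats::na.omit(tb$c1d_rpm) < 0) ||
      any(stats::na.omit(tb$a1d_rpm) < 0)) {
    stop("corrupt fixture: negative RPM", call. = FALSE)
  }
  tb
}

#' Per-class small-RNA expression totals
#'
#' Jointly normalized RPM totals of the miRNA, tRF and phasiRNA classes
#' in the control (`C1D`) and ABA-treated (`A1D`) libraries.
#'
#' @return Tibble with columns `library`, `class`, `rpm`.
#' @export
srna_class_totals <- function() {
  readr::read_tsv(fixture_path("srna_class_totals.tsv"), col_types = "ccd")
}

#' Headline tRF expression pairs
#'
#' The RPM pairs behind the headline tRF numbers of the reference
#' experiment: the dominant 20-nt Ala 5' fragment
#' (`ENSRNA049443699:1-20`) and the totals of the down- and up-regulated
#' tRFs passing the 10-RPM reporting filter.
#'
#' @return Tibble with columns `label`, `c1d_rpm`, `a1d_rpm`.
#' @export
trf_expression_summary <- function() {
  readr::read_tsv(fixture_path("trf_expression_summary.tsv"),
                  col_types = "cdd")
}
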