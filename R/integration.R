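# Integration of differential phasiRNAs with target predictions and
# transcript expression status: the stress-target report, per-direction
# abundance sums, and the three-class RPM share summary.

#' Classify a transcript's expression status across conditions
#'
#' `undetected` when both FPKM values fall below the detection floor;
#' otherwise `elevated` / `decreased` when the absolute log2 ratio
#' reaches `fold_threshold` (default 0.585, i.e. a 1.5-fold change),
#' else `unaltered`. A transcript detected in only one condition has an
#' infinite ratio and classifies by sign.
#'
#' @param fpkm_c,fpkm_a FPKM in control and treatment (vectorized).
#' @param fold_threshold Minimum `|log2(fpkm_a / fpkm_c)|`.
#' @param floor Detection floor in FPKM.
#' @return Character vector of statuses.
#' @export
classify_transcript_status <- function(fpkm_c, fpkm_a,
                                       fold_threshold = 0.585,
                                       floor = 0.1) {
  if (any(fpkm_c < 0) || any(fpkm_a < 0)) {
    stop("FPKM values must be non-negative", call. = FALSE)
  }
  lfc <- log2(fpkm_a / fpkm_c)
  dplyr::case_when(
    fpkm_c < floor & fpkm_a < floor ~ "undetected",
    lfc >= fold_threshold ~ "elevated",
    lfc <= -fold_threshold ~ "decreased",
    .default = "unaltered"
  )
}

#' Build the phasiRNA-target report
#'
#' One row per (responsive phasiRNA, target gene family with at least
#' one passing site): the number of distinct target genes, and the
#' detected-transcript counts broken down by status (`sum` counts
#' detected transcripts only; `undetected` is reported separately, not
#' folded into "no change"). Transcripts shared between phasiRNAs are
#' annotated in the `shared_with` column.
#'
#' @param phasi_records Differential-expression tibble for phasiRNAs
#'   (columns `item_id`, `rpm_C1D`, `rpm_A1D`, `tier`).
#' @param target_sites [predict_targets()] output (only `passes` sites
#'   are used).
#' @param statuses Tibble with `transcript_id`, `family`, `status` and
#'   optionally `gene_id` (defaults to the transcript id with its last
#'   version suffix removed).
#' @return Tibble: `phasirna_id`, `rpm_C1D`, `rpm_A1D`, `tier`,
#'   `family`, `target_genes`, `sum`, `up`, `down`, `no_change`,
#'   `undetected`, `shared_with`.
#' @export
build_report <- function(phasi_records, target_sites, statuses) {
  sites <- target_sites[target_sites$passes, ]
  missing <- setdiff(unique(sites$srna_id), phasi_records$item_id)
  if (length(missing)) {
    stop("target sites reference phasiRNA(s) without expression records: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"gene_id" %in% names(statuses)) {
    statuses$gene_id <- sub("\\.[0-9]+$", "", statuses$transcript_id)
  }
  responsive <- phasi_records[phasi_records$tier %in% c("up", "down"), ]
  joined <- sites |>
    dplyr::filter(.data$srna_id %in% responsive$item_id) |>
    dplyr::distinct(.data$srna_id, .data$transcript_id) |>
    dplyr::inner_join(statuses, by = "transcript_id")
  if (nrow(joined) == 0) {
    return(tibble::tibble(phasirna_id = character(), rpm_C1D = numeric(),
                          rpm_A1D = numeric(), tier = character(),
                          family = character(), target_genes = integer(),
                          sum = integer(), up = integer(), down = integer(),
                          no_change = integer(), undetected = integer(),
                          shared_with = character()))
  }
  shared <- joined |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::ungroup()
  report <- joined |>
    dplyr::group_by(phasirna_id = .data$srna_id, .data$family) |>
    dplyr::summarise(
      target_genes = dplyr::n_distinct(.data$gene_id),
      sum = sum(.data$status != "undetected"),
      up = sum(.data$status == "elevated"),
      down = sum(.data$status == "decreased"),
      no_change = sum(.data$status == "unaltered"),
      undetected = sum(.data$status == "undetected"),
      shared_with = {
        tx <- intersect(.data$transcript_id, shared$transcript_id)
        others <- unique(shared$srna_id[shared$transcript_id %in% tx])
        paste(setdiff(others, dplyr::cur_group()$phasirna_id),
              collapse = ",")
      },
      .groups = "drop"
    ) |>
    dplyr::left_join(
      responsive[, c("item_id", "rpm_C1D", "rpm_A1D", "tier")],
      by = c(phasirna_id = "item_id")
    ) |>
    dplyr::relocate("rpm_C1D", "rpm_A1D", "tier", .after = "phasirna_id")
  dplyr::arrange(report, .data$phasirna_id, .data$family)
}

#' Per-direction phasiRNA abundance sums
#'
#' Sums the RPM pair of the distinct phasiRNAs (each counted once even
#' when it appears in several family rows) that match the direction and
#' target at least one family in the filter.
#'
#' @param report A tibble with columns `phasirna_id`, `family` and an
#'   RPM pair (`rpm_C1D`/`rpm_A1D` or `c1d_rpm`/`a1d_rpm`); direction
#'   is taken from a `tier` column when present, otherwise from the
#'   sign of the RPM change.
#' @param direction `"up"` or `"down"`.
#' @param families Families to include (default: the R-gene families).
#' @return Tibble with one row: `direction`, `n_phasirnas`, `c1d`,
#'   `a1d`, `delta` (= `a1d - c1d`).
#' @export
aggregate_direction_sums <- function(report, direction = c("down", "up"),
                                     families = c("NBS-LRR", "STK", "RLK")) {
  direction <- match.arg(direction)
  cols <- report_rpm_cols(report)
  dir <- if ("tier" %in% names(report)) {
    report$tier
  } else {
    ifelse(report[[cols[2]]] < report[[cols[1]]], "down", "up")
  }
  sel <- report[dir == direction & report$family %in% families, ]
  sel <- sel[!duplicated(sel$phasirna_id), ]
  if (nrow(sel) == 0) {
    warning("no phasiRNA matches direction '", direction,
            "' and the family filter", call. = FALSE)
    return(tibble::tibble(direction = direction, n_phasirnas = 0L,
                          c1d = 0, a1d = 0, delta = 0))
  }
  c1d <- sum(sel[[cols[1]]])
  a1d <- sum(sel[[cols[2]]])
  tibble::tibble(direction = direction, n_phasirnas = nrow(sel),
                 c1d = c1d, a1d = a1d, delta = a1d - c1d)
}

report_rpm_cols <- function(report) {
  if (all(c("rpm_C1D", "rpm_A1D") %in% names(report))) {
    c("rpm_C1D", "rpm_A1D")
  } else if (all(c("c1d_rpm", "a1d_rpm") %in% names(report))) {
    c("c1d_rpm", "a1d_rpm")
  } else {
    stop("report lacks an RPM column pair", call. = FALSE)
  }
}

#' Count phasiRNAs by targeted family group
#'
#' @param report Tibble with `phasirna_id` and `family` columns.
#' @param r_families Resistance-gene families.
#' @param tf_families Transcription-factor families.
#' @return Tibble with `n_phasirnas`, `n_targeting_r_genes`,
#'   `n_targeting_tfs`.
#' @export
count_target_families <- function(report,
                                  r_families = c("NBS-LRR", "STK", "RLK"),
                                  tf_families = c("AP2/ERF", "ERF", "MYB",
                                                  "NAC", "ARF", "GRAS",
                                                  "bHLH", "WRKY")) {
  tibble::tibble(
    n_phasirnas = dplyr::n_distinct(report$phasirna_id),
    n_targeting_r_genes = dplyr::n_distinct(
      report$phasirna_id[report$family %in% r_families]),
    n_targeting_tfs = dplyr::n_distinct(
      report$phasirna_id[report$family %in% tf_families])
  )
}

#' Per-class RPM totals and percentage shares
#'
#' For each library, the miRNA / tRF / phasiRNA RPM totals and each
#' class's percentage share of their combined sum. Shares sum to 100
#' within rounding.
#'
#' @param totals Tibble with columns `library`, `class`, `rpm`.
#' @param digits Rounding for the share column (default 2, matching the
#'   two-decimal percent convention).
#' @return `totals` with an added `share_pct` column.
#' @export
class_share_summary <- function(totals, digits = 2) {
  totals |>
    dplyr::group_by(.data$library) |>
    dplyr::mutate(share_pct = round(.data$rpm / sum(.data$rpm) * 100,
                                    digits)) |>
    dplyr::ungroup()
}

#' RPM declines from a paired expression summary
#'
#' Adds `delta = a1d_rpm - c1d_rpm` and `decline = c1d_rpm - a1d_rpm`
#' columns to a table of paired RPM values.
#'
#' @param table Tibble with `c1d_rpm` and `a1d_rpm` columns.
#' @return The table with `delta` and `decline` columns.
#' @export
rpm_change <- function(table) {
  table$delta <- table$a1d_rpm - table$c1d_rpm
  table$decline <- table$c1d_rpm - table$a1d_rpm
  table
}
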