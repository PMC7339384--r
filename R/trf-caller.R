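# tRF calling: exact (mismatch-free) alignment of 18-30-nt reads to
# tRNAs, read-end peak calling, 75%-overlap structural classification
# and the three-bases-outside quantification rule.

#' Align reads to tRNAs with no mismatches
#'
#' Reports every exact-substring occurrence of every read on every tRNA
#' (multi-mapping across isodecoders is preserved); reverse-complement
#' hits are not considered, matching the sense-only biology of tRF
#' production. Reads outside 18-30 nt are dropped before alignment.
#'
#' @param reads Tibble with columns `seq` and `count` (copy number of
#'   the collapsed read).
#' @param trnas List of [trna_gene()] objects, or a named character
#'   vector of tRNA sequences.
#' @return Tibble of alignments (`seq`, `count`, `trna_id`, `start`,
#'   `end`; 0-based half-open), with attributes `unmapped` (number of
#'   distinct reads with no hit) and `length_filtered`.
#' @export
align_exact <- function(reads, trnas) {
  seqs <- trna_sequences(trnas)
  keep <- nchar(reads$seq) >= 18 & nchar(reads$seq) <= 30
  n_len <- sum(!keep)
  reads <- reads[keep, ]
  hits <- vector("list", nrow(reads))
  unmapped <- 0L
  for (i in seq_len(nrow(reads))) {
    rs <- reads$seq[i]
    found <- lapply(names(seqs), function(tid) {
      m <- gregexpr(rs, seqs[[tid]], fixed = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      tibble::tibble(seq = rs, count = reads$count[i], trna_id = tid,
                     start = as.integer(m) - 1L,
                     end = as.integer(m) - 1L + nchar(rs))
    })
    found <- dplyr::bind_rows(found)
    if (nrow(found) == 0) unmapped <- unmapped + 1L else {
      hits[[i]] <- found
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble::tibble(seq = character(), count = integer(),
                          trna_id = character(), start = integer(),
                          end = integer())
  }
  if (unmapped > 0) message(unmapped, " read(s) had no exact tRNA hit")
  attr(out, "unmapped") <- unmapped
  attr(out, "length_filtered") <- n_len
  out
}

trna_sequences <- function(trnas) {
  if (is.character(trnas)) {
    stopifnot(!is.null(names(trnas)))
    return(as.list(trnas))
  }
  stats::setNames(lapply(trnas, `[[`, "sequence"),
                  vapply(trnas, `[[`, character(1), "id"))
}

#' Per-position read-end profile of a tRNA
#'
#' Copy-count-weighted 5'-end and 3'-end frequency vectors, the
#' substrate for peak calling. The column sums equal the total aligned
#' copy count on each tRNA.
#'
#' @param alignments Alignment tibble from [align_exact()].
#' @return Tibble with `trna_id`, `pos`, `n5` (reads starting at `pos`)
#'   and `n3` (reads whose last base is at `pos - 1`, i.e. end
#'   coordinate `pos`).
#' @export
end_profile <- function(alignments) {
  e5 <- alignments |>
    dplyr::group_by(.data$trna_id, pos = .data$start) |>
    dplyr::summarise(n5 = sum(.data$count), .groups = "drop")
  e3 <- alignments |>
    dplyr::group_by(.data$trna_id, pos = .data$end) |>
    dplyr::summarise(n3 = sum(.data$count), .groups = "drop")
  dplyr::full_join(e5, e3, by = c("trna_id", "pos")) |>
    dplyr::mutate(n5 = dplyr::coalesce(.data$n5, 0L),
                  n3 = dplyr::coalesce(.data$n3, 0L)) |>
    dplyr::arrange(.data$trna_id, .data$pos)
}

#' Call tRF peaks from read-end density
#'
#' A read-end peak caller in the spirit of small-RNA fragment-boundary
#' detection tools: iteratively (1) find the 5'-end position with the
#' highest unassigned copy support (at least `min_support`), (2) gather
#' the reads whose 5' ends lie within `end_tolerance` of it, (3) take
#' the copy-weighted modal 3' end of that cluster (ties broken toward
#' the longer fragment, which preserves the dominant-boundary behaviour
#' under symmetric noise), (4) emit the (modal 5', modal 3') pair as a
#' candidate, (5) mask the supporting reads and repeat. Candidates from
#' different clusters may overlap.
#'
#' Peaks are intended to be called on the pooled libraries and then
#' quantified per library, so that both conditions share one tRF
#' catalogue.
#'
#' @param alignments Alignment tibble (pooled across libraries).
#' @param min_support Minimum copy support of a 5'-end peak (default 2).
#' @param end_tolerance 5'-end clustering tolerance in nt (default 2).
#' @return Tibble of candidates (`trna_id`, `start`, `end`, `support`)
#'   sorted by support, descending.
#' @export
call_trf_peaks <- function(alignments, min_support = 2, end_tolerance = 2) {
  if (nrow(alignments) == 0) {
    return(tibble::tibble(trna_id = character(), start = integer(),
                          end = integer(), support = integer()))
  }
  out <- alignments |>
    dplyr::group_by(.data$trna_id) |>
    dplyr::group_map(function(df, key) {
      active <- rep(TRUE, nrow(df))
      cands <- list()
      repeat {
        if (!any(active)) break
        p5 <- tapply(df$count[active], df$start[active], sum)
        if (max(p5) < min_support) break
        best <- as.integer(names(p5)[which.max(p5)])
        cluster <- active & abs(df$start - best) <= end_tolerance
        e3 <- tapply(df$count[cluster], df$end[cluster], sum)
        ends <- as.integer(names(e3))
        modal3 <- max(ends[e3 == max(e3)])
        cands[[length(cands) + 1L]] <- tibble::tibble(
          trna_id = key$trna_id, start = best, end = modal3,
          support = sum(df$count[cluster])
        )
        active <- active & !cluster
      }
      dplyr::bind_rows(cands)
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    return(tibble::tibble(trna_id = character(), start = integer(),
                          end = integer(), support = integer()))
  }
  dplyr::arrange(out, dplyr::desc(.data$support))
}

#' Classify a tRF by structural region overlap
#'
#' A tRF receives the label of every source region that contains at
#' least `threshold` (default 75 percent) of the fragment's own length.
#' Fragments sitting in an overlap zone between two adjacent regions can
#' satisfy the rule for both and then carry both labels; fragments
#' satisfying it for none are labelled `"others"`.
#'
#' @param start,end tRF interval, 0-based half-open, within the tRNA.
#' @param partition A [partition_regions()] result for the source tRNA.
#' @param threshold Minimum overlap proportion of the tRF length.
#' @return Character vector of labels: one or two of `"5e-tRF"`,
#'   `"D-tRF"`, `"A-tRF"`, `"V-tRF"`, `"3e-tRF"`, or `"others"`.
#' @export
classify_trf <- function(start, end, partition, threshold = 0.75) {
  if (end <= start) stop("empty tRF interval", call. = FALSE)
  len <- end - start
  ov <- pmax(0L, pmin(end, partition$end) - pmax(start, partition$start))
  hit <- which(ov / len >= threshold)
  if (length(hit) == 0) return("others")
  if (length(hit) > 2) {
    stop("more than two regions reach the overlap threshold; ",
         "partition flanks are wider than a region", call. = FALSE)
  }
  paste0(partition$region[hit], "-tRF")
}

#' Quantify a tRF by the three-bases-outside rule
#'
#' A read is attributed to a tRF when at most `slack` (default 3) of its
#' bases fall outside the tRF interval, where bases outside =
#' `max(0, trf_start - read_start) + max(0, read_end - trf_end)`. The
#' tRF's expression is the sum of the copy counts of its attributed
#' reads. A read within `slack` of several overlapping tRFs counts
#' toward each of them.
#'
#' @param start,end tRF interval (0-based half-open).
#' @param alignments Alignment tibble on the same tRNA (columns `start`,
#'   `end`, `count`).
#' @param slack Maximum bases outside the tRF.
#' @return Total copy count attributed to the tRF.
#' @export
quantify_trf <- function(start, end, alignments, slack = 3) {
  outside <- pmax(0, start - alignments$start) +
    pmax(0, alignments$end - end)
  sum(alignments$count[outside <= slack])
}

#' Build a per-library tRF table from pooled peaks
#'
#' Calls peaks on the pooled alignments, classifies each candidate
#' against its tRNA's region partition and quantifies it in every
#' library with the three-bases-outside rule. tRF ids are
#' `tRNA:start-end` with a 1-based inclusive interval.
#'
#' @param alignments_by_library Named list of alignment tibbles, one per
#'   library (e.g. `C1D`, `A1D`).
#' @param trnas List of [trna_gene()] objects.
#' @param min_support,end_tolerance Passed to [call_trf_peaks()].
#' @param slack Passed to [quantify_trf()].
#' @param threshold Passed to [classify_trf()].
#' @return Tibble with `trf_id`, `trna_id`, `start`, `end`, `type`
#'   (labels joined by `+`), and one `count_<library>` column per
#'   library.
#' @export
trf_table <- function(alignments_by_library, trnas, min_support = 2,
                      end_tolerance = 2, slack = 3, threshold = 0.75) {
  pooled <- dplyr::bind_rows(alignments_by_library)
  peaks <- call_trf_peaks(pooled, min_support = min_support,
                          end_tolerance = end_tolerance)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(trf_id = character(), trna_id = character(),
                          start = integer(), end = integer(),
                          type = character()))
  }
  parts <- lapply(trnas, partition_regions)
  names(parts) <- vapply(trnas, `[[`, character(1), "id")
  peaks$type <- vapply(seq_len(nrow(peaks)), function(i) {
    paste(classify_trf(peaks$start[i], peaks$end[i],
                       parts[[peaks$trna_id[i]]], threshold = threshold),
          collapse = "+")
  }, character(1))
  for (lib in names(alignments_by_library)) {
    aln <- alignments_by_library[[lib]]
    peaks[[paste0("count_", lib)]] <- vapply(seq_len(nrow(peaks)),
      function(i) {
        sub <- aln[aln$trna_id == peaks$trna_id[i], ]
        as.numeric(quantify_trf(peaks$start[i], peaks$end[i], sub,
                                slack = slack))
      }, numeric(1))
  }
  tibble::tibble(
    trf_id = sprintf("%s:%d-%d", peaks$trna_id, peaks$start + 1L, peaks$end),
    peaks[, setdiff(names(peaks), "support")]
  )
}

#' Remove tRFs below the noise floor in both libraries
#'
#' Keeps a tRF when its RPM reaches `threshold` (default 2) in at least
#' one library; only features below the floor in every library are
#' removed.
#'
#' @param table Tibble containing the RPM columns.
#' @param rpm_cols Names of the per-library RPM columns.
#' @param threshold Minimum RPM.
#' @return The filtered tibble.
#' @export
filter_low_trfs <- function(table, rpm_cols = c("rpm_C1D", "rpm_A1D"),
                            threshold = 2) {
  keep <- Reduce(`|`, lapply(rpm_cols, function(cl) table[[cl]] >= threshold))
  table[keep, ]
}
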