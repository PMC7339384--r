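# phasiRNA target prediction: miRanda-style complementarity scoring of
# sRNA-transcript duplexes, nearest-neighbour duplex free energy, and
# the score/energy gates.

#' Default duplex alignment weights
#'
#' miRanda-style weights: Watson-Crick pair +5, G:U wobble +1, mismatch
#' -3, gap open -9, gap extend -4, and a 4x multiplier on the
#' substitution score over sRNA positions 2-8 (the seed). Gap penalties
#' are not seed-scaled.
#'
#' @return Named list of weights.
#' @export
duplex_weights <- function() {
  list(match = 5, wobble = 1, mismatch = -3, gap_open = -9, gap_extend = -4,
       seed = c(2L, 8L), seed_scale = 4)
}

encode_rna <- function(x) {
  v <- match(strsplit(x, "")[[1]], c("A", "C", "G", "U")) - 1L
  if (anyNA(v)) stop("sequence contains non-ACGU characters", call. = FALSE)
  v
}

#' Score an sRNA against a target window
#'
#' Local alignment of the sRNA (5'-3') against the window in
#' antiparallel orientation under the configured weights; the
#' highest-scoring alignment is returned with per-column pair states.
#' Ties are broken deterministically (leftmost target site, then the
#' shorter alignment). A window with no positive-scoring alignment
#' returns score 0 and no site.
#'
#' @param srna sRNA sequence, 18-25 nt.
#' @param window Target window sequence (RNA alphabet, 5'-3').
#' @param weights See [duplex_weights()].
#' @return A list of class `duplex_alignment`: `score`, `srna`,
#'   `window`, `srna_start`/`srna_end` (0-based half-open on the sRNA),
#'   `site_start`/`site_end` (0-based half-open on the window),
#'   `states` (string over `M` = Watson-Crick, `W` = wobble, `X` =
#'   mismatch, `T` = target gap, `S` = sRNA gap), and the per-column
#'   `srna_pos` (1-based) / `target_pos` (0-based) vectors.
#' @export
complementarity_score <- function(srna, window, weights = duplex_weights()) {
  if (nchar(srna) < 18 || nchar(srna) > 25) {
    stop("sRNA must be 18-25 nt", call. = FALSE)
  }
  res <- duplex_align_cpp(encode_rna(srna), encode_rna(window),
                          weights$match, weights$wobble, weights$mismatch,
                          weights$gap_open, weights$gap_extend,
                          weights$seed[1], weights$seed[2],
                          weights$seed_scale)
  res$srna <- srna
  res$window <- window
  class(res) <- "duplex_alignment"
  res
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("<duplex_alignment> score %.1f, site [%s,%s), states %s\n",
              x$score, x$site_start, x$site_end, x$states))
  invisible(x)
}

#' Nearest-neighbour RNA/RNA stack free-energy table
#'
#' Named vector of stack free energies (kcal/mol at 37C), keyed as
#' `"XY/ZW"`: top strand 5'-XY-3' over bottom strand 5'-ZW-3', with X:W
#' and Y:Z the two base pairs. Watson-Crick stacks carry the standard
#' Turner nearest-neighbour values; stacks involving G:U wobbles carry
#' representative values (-1.5 against a G:C neighbour, -0.8 against an
#' A:U neighbour, -0.4 for tandem wobbles). The duplex initiation
#' penalty is attached as attribute `"init"` (+4.09 kcal/mol).
#'
#' @return Named numeric vector with attribute `init`.
#' @export
rna_stack_table <- function() {
  wc <- c("AA/UU" = -0.93, "AU/AU" = -1.10, "UA/UA" = -1.33,
          "CU/AG" = -2.08, "CA/UG" = -2.11, "GU/AC" = -2.24,
          "GA/UC" = -2.35, "CG/CG" = -2.36, "GG/CC" = -3.26,
          "GC/GC" = -3.42)
  tab <- wc
  for (k in names(wc)) {
    sym <- paste0(substr(k, 4, 5), "/", substr(k, 1, 2))
    tab[sym] <- wc[[k]]
  }
  pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  is_wob <- function(p) p %in% c("GU", "UG")
  for (p1 in pairs) {
    for (p2 in pairs) {
      top <- paste0(substr(p1, 1, 1), substr(p2, 1, 1))
      bottom <- paste0(substr(p2, 2, 2), substr(p1, 2, 2))
      key <- paste0(top, "/", bottom)
      if (!key %in% names(tab)) {
        nw <- is_wob(p1) + is_wob(p2)
        tab[key] <- if (nw == 2) -0.4 else if (
          (is_wob(p1) && p2 %in% c("GC", "CG")) ||
          (is_wob(p2) && p1 %in% c("GC", "CG"))) -1.5 else -0.8
      }
    }
  }
  attr(tab, "init") <- 4.09
  tab
}

#' Duplex free energy of an alignment
#'
#' Sums nearest-neighbour stack energies over consecutive paired
#' columns (Watson-Crick or wobble) of the alignment and adds the
#' duplex initiation penalty. Mismatches and gaps interrupt stacking
#' and contribute nothing. An alignment without at least two
#' consecutive paired columns has no stack and returns 0.
#'
#' @param alignment A `duplex_alignment` from [complementarity_score()].
#' @param table Stack table from [rna_stack_table()].
#' @return Free energy in kcal/mol (0 when no stack exists).
#' @export
duplex_free_energy <- function(alignment, table = rna_stack_table()) {
  st <- strsplit(alignment$states, "")[[1]]
  if (length(st) < 2) return(0)
  s <- strsplit(alignment$srna, "")[[1]]
  w <- strsplit(alignment$window, "")[[1]]
  paired <- st %in% c("M", "W")
  stacks <- which(paired[-length(paired)] & paired[-1])
  if (length(stacks) == 0) return(0)
  e <- 0
  for (k in stacks) {
    a1 <- s[alignment$srna_pos[k]]
    a2 <- s[alignment$srna_pos[k + 1]]
    b1 <- w[alignment$target_pos[k] + 1L]
    b2 <- w[alignment$target_pos[k + 1] + 1L]
    e <- e + table[[paste0(a1, a2, "/", b2, b1)]]
  }
  e + attr(table, "init")
}

#' Predict sRNA target sites across a transcriptome
#'
#' Scans every window of every transcript (window length = sRNA length
#' + 4 to leave room for gaps, step 1), keeps the best local alignment
#' per window, merges overlapping hits of the same sRNA/transcript pair
#' (greedy by score), computes each surviving site's duplex free
#' energy, and flags sites passing both gates (`score >=
#' score_threshold` and `energy <= energy_threshold`). Sites failing a
#' gate are still reported with `passes = FALSE`, so the same scan
#' supports recalibrated gates. Many-to-many sRNA/transcript relations
#' are preserved.
#'
#' @param srnas Named character vector of sRNA sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @param score_threshold Score gate (default 500, the published gate;
#'   note that under the default weights a perfect 21-nt duplex scores
#'   210, so this default passes nothing and practical analyses
#'   calibrate the gates).
#' @param energy_threshold Free-energy gate in kcal/mol (default -50).
#' @param weights See [duplex_weights()].
#' @param min_score Minimum alignment score for a site to be reported
#'   at all.
#' @param table Stack table for the energy model.
#' @return Tibble: `srna_id`, `transcript_id`, `start`, `end` (0-based
#'   half-open on the transcript), `score`, `energy`, `passes`, sorted
#'   by (sRNA, transcript, start).
#' @export
predict_targets <- function(srnas, transcripts, score_threshold = 500,
                            energy_threshold = -50,
                            weights = duplex_weights(), min_score = 50,
                            table = rna_stack_table()) {
  if (length(transcripts) == 0) {
    warning("empty transcriptome; no target sites predicted", call. = FALSE)
    return(tibble::tibble(srna_id = character(), transcript_id = character(),
                          start = integer(), end = integer(),
                          score = numeric(), energy = numeric(),
                          passes = logical()))
  }
  rows <- list()
  for (sid in names(srnas)) {
    m <- nchar(srnas[[sid]])
    wlen <- m + 4L
    senc <- srnas[[sid]]
    for (tid in names(transcripts)) {
      tx <- transcripts[[tid]]
      n <- nchar(tx)
      if (n < m) next
      starts <- 0:max(0L, n - wlen)
      hits <- list()
      for (ws in starts) {
        win <- substr(tx, ws + 1L, min(ws + wlen, n))
        al <- complementarity_score(senc, win, weights = weights)
        if (al$score <= 0) next
        hits[[length(hits) + 1L]] <- list(
          score = al$score, start = ws + al$site_start,
          end = ws + al$site_end, alignment = al
        )
      }
      if (!length(hits)) next
      sc <- vapply(hits, `[[`, numeric(1), "score")
      keep <- integer(0)
      for (h in order(-sc)) {
        ov <- any(vapply(keep, function(k) {
          hits[[h]]$start < hits[[k]]$end && hits[[h]]$end > hits[[k]]$start
        }, logical(1)))
        if (!ov) keep <- c(keep, h)
      }
      for (h in keep) {
        if (hits[[h]]$score < min_score) next
        en <- duplex_free_energy(hits[[h]]$alignment, table = table)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          srna_id = sid, transcript_id = tid,
          start = hits[[h]]$start, end = hits[[h]]$end,
          score = hits[[h]]$score, energy = en,
          passes = hits[[h]]$score >= score_threshold &
            en <= energy_threshold
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(srna_id = character(), transcript_id = character(),
                          start = integer(), end = integer(),
                          score = numeric(), energy = numeric(),
                          passes = logical()))
  }
  dplyr::arrange(out, .data$srna_id, .data$transcript_id, .data$start)
}
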