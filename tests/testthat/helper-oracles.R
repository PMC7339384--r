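# Independent oracles used across the suite: brute-force interval
# arithmetic for tRF classification, exhaustive and independent-DP
# duplex alignment scoring, and direct stack-table summation for duplex
# free energies. These deliberately re-derive each quantity by a
# different route than the implementation under test.

# Brute-force tRF classification: count positions of the fragment
# inside each region one by one.
oracle_classify_trf <- function(start, end, partition, threshold = 0.75) {
  pos <- start:(end - 1)
  labels <- character(0)
  for (k in seq_len(nrow(partition))) {
    inside <- sum(pos >= partition$start[k] & pos < partition$end[k])
    if (inside / length(pos) >= threshold) {
      labels <- c(labels, paste0(partition$region[k], "-tRF"))
    }
  }
  if (length(labels) == 0) "others" else labels
}

pair_kind <- function(a, b) {
  wc <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE)
  key <- paste0(a, b)
  if (isTRUE(wc[key])) return("M")
  if (key %in% c("GU", "UG")) return("W")
  "X"
}

sub_score <- function(a, b, i, wts) {
  base <- switch(pair_kind(a, b), M = wts$match, W = wts$wobble,
                 X = wts$mismatch)
  if (i >= wts$seed[1] && i <= wts$seed[2]) base * wts$seed_scale else base
}

# Exhaustive enumeration of local alignments (paths of substitution and
# gap columns; opposite gap types never adjacent, alignments start and
# end with a substitution) with a cap on total gap columns. Only
# practical for very short sequences.
oracle_enum_align <- function(srna, window, wts = duplex_weights(),
                              max_gap = 3) {
  s <- strsplit(srna, "")[[1]]
  tr <- rev(strsplit(window, "")[[1]])
  m <- length(s)
  n <- length(tr)
  best <- 0
  rec <- function(i, j, sc, last, gaps) {
    if (last == "M" && sc > best) best <<- sc
    if (i < m && j < n) {
      rec(i + 1, j + 1, sc + sub_score(s[i + 1], tr[j + 1], i + 1, wts),
          "M", gaps)
    }
    if (gaps < max_gap) {
      if (i < m && last != "S") {
        rec(i + 1, j, sc + if (last == "T") wts$gap_extend else wts$gap_open,
            "T", gaps + 1)
      }
      if (j < n && last != "T") {
        rec(i, j + 1, sc + if (last == "S") wts$gap_extend else wts$gap_open,
            "S", gaps + 1)
      }
    }
  }
  for (i0 in seq_len(m)) {
    for (j0 in seq_len(n)) {
      rec(i0, j0, sub_score(s[i0], tr[j0], i0, wts), "M", 0)
    }
  }
  best
}

# Independent affine local-alignment DP (score only), written as a
# plain three-matrix recurrence over the same scoring definition.
oracle_dp_align <- function(srna, window, wts = duplex_weights()) {
  s <- strsplit(srna, "")[[1]]
  tr <- rev(strsplit(window, "")[[1]])
  m <- length(s)
  n <- length(tr)
  M <- Gx <- Gy <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sub <- sub_score(s[i], tr[j], i, wts)
      M[i + 1, j + 1] <- max(0, M[i, j], Gx[i, j], Gy[i, j]) + sub
      Gx[i + 1, j + 1] <- max(M[i, j + 1] + wts$gap_open,
                              Gx[i, j + 1] + wts$gap_extend)
      Gy[i + 1, j + 1] <- max(M[i + 1, j] + wts$gap_open,
                              Gy[i + 1, j] + wts$gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Direct stack-table summation for a gapless duplex whose pairing is
# known by construction: column i pairs srna base i with window base
# (len - i + 1).
oracle_duplex_energy <- function(srna, window, table = rna_stack_table()) {
  s <- strsplit(srna, "")[[1]]
  w <- rev(strsplit(window, "")[[1]])
  paired <- vapply(seq_along(s), function(i) {
    pair_kind(s[i], w[i]) %in% c("M", "W")
  }, logical(1))
  e <- 0
  n_stacks <- 0
  for (i in seq_len(length(s) - 1)) {
    if (paired[i] && paired[i + 1]) {
      key <- paste0(s[i], s[i + 1], "/", w[i + 1], w[i])
      e <- e + table[[key]]
      n_stacks <- n_stacks + 1
    }
  }
  if (n_stacks == 0) 0 else e + attr(table, "init")
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# A deterministic bank of simulated tRNA genes shared across tests.
test_genes <- local({
  genes <- NULL
  function(n = 20, seed = 42) {
    if (is.null(genes) || length(genes) < n) {
      genes <<- simulate_trna_set(sim_config(seed = seed, n_trnas = n))
    }
    genes[seq_len(n)]
  }
})
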