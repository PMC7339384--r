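# Joint RPM normalization of tRF, phasiRNA and miRNA reads, the
# Audic-Claverie exact test for two-library digital expression, and the
# response-tier classification.

#' Reads-per-million under the joint denominator
#'
#' `RPM = count / N * 1e6`, where `N` is the combined tRF + phasiRNA +
#' miRNA read total of the library. With this shared denominator the RPM
#' values of the three classes within one library sum to one million.
#'
#' @param count Raw counts (vectorized).
#' @param total Library total `N` (> 0).
#' @return RPM values.
#' @export
normalize_rpm <- function(count, total) {
  if (any(total <= 0)) {
    stop("normalization total must be positive", call. = FALSE)
  }
  count / total * 1e6
}

#' Audic-Claverie conditional probability mass
#'
#' `p(y | x) = (N2/N1)^y * (x+y)! / (x! y! (1 + N2/N1)^(x+y+1))`, the
#' probability of observing `y` counts in a library of size `N2` for a
#' feature observed `x` times in a library of size `N1`, under a shared
#' Poisson rate. Computed in log space.
#'
#' @param x,y Non-negative counts (vectorized, recycled).
#' @param n1,n2 Library totals.
#' @return `p(y | x)`.
#' @export
audic_pmf <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0", call. = FALSE)
  logr <- log(n2) - log(n1)
  exp(y * logr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(exp(logr)))
}

# log pmf vector over k = 0..kmax for fixed x, computed by the stable
# recurrence log p(k+1) = log p(k) + log r + log((x+k+1)/(k+1)).
audic_log_pmf_vector <- function(x, logr, kmax) {
  k <- seq_len(kmax)
  lp0 <- -(x + 1) * log1p(exp(logr))
  cumsum(c(lp0, logr + log((x + k) / k) - log1p(exp(logr))))
}

# Cumulative log-sum-exp (running log of partial sums), numerically
# stable under a running maximum.
cum_logsumexp <- function(lp) {
  out <- numeric(length(lp))
  s <- -Inf
  for (i in seq_along(lp)) {
    m <- max(s, lp[i])
    s <- m + log(exp(s - m) + exp(lp[i] - m))
    out[i] <- s
  }
  out
}

#' Audic-Claverie two-library test
#'
#' Exact test of differential digital expression between two libraries.
#' The two-sided p-value is the doubled smaller tail,
#' `p = min(1, 2 * min(P(K <= y | x), P(K >= y | x)))`, with both tails
#' including the observed `y`; one-sided alternatives return the
#' corresponding single tail. All tail sums are accumulated in log
#' space; the upper tail is summed directly (never via `1 - lower`) so
#' that extreme divergences keep full relative accuracy.
#'
#' @param x Count in library 1 (vectorized).
#' @param y Count in library 2 (vectorized, recycled against `x`).
#' @param n1,n2 Library totals (scalars, > 0).
#' @param alternative `"two.sided"` (default), `"less"` (tests depletion
#'   in library 2) or `"greater"`.
#' @return p-values in `(0, 1]`.
#' @export
audic_pvalue <- function(x, y, n1, n2,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0", call. = FALSE)
  if (n1 <= 0 || n2 <= 0) stop("library totals must be > 0", call. = FALSE)
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  logr <- log(n2) - log(n1)
  q <- exp(logr) / (1 + exp(logr))  # asymptotic term ratio bound factor
  out <- numeric(n)
  for (g in split(seq_len(n), x)) {
    xi <- x[g[1]]
    ymax <- max(y[g])
    # extend past ymax until the truncated geometric remainder is
    # negligible relative to the smallest upper tail we must report
    # (which is at least the point mass at ymax)
    floor_lp <- audic_lp_at(xi, logr, ymax) + log(1e-16)
    kmax <- ymax
    mode_k <- ceiling((xi + 1) * exp(logr))
    repeat {
      kmax <- max(kmax + 50L, ceiling(kmax * 1.5), mode_k)
      ratio <- q * (xi + kmax + 1) / (kmax + 1)
      lp_last <- audic_lp_at(xi, logr, kmax)
      if (ratio < 1 && lp_last + log(ratio / (1 - ratio)) < floor_lp) break
      if (kmax > 5e6) break
    }
    lp <- audic_log_pmf_vector(xi, logr, kmax)
    lower <- cum_logsumexp(lp)
    upper <- rev(cum_logsumexp(rev(lp)))
    lo <- exp(lower[y[g] + 1L])
    up <- exp(upper[y[g] + 1L])
    out[g] <- switch(alternative,
      two.sided = pmin(1, 2 * pmin(lo, up)),
      less = pmin(1, lo),
      greater = pmin(1, up)
    )
  }
  out
}

# log p(k|x) at a single k without building the whole vector.
audic_lp_at <- function(x, logr, k) {
  k * logr + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p(exp(logr))
}

#' Classify a feature's response tier
#'
#' Tiers follow the two-threshold scheme: features with
#' `|log2FC| < lfc_response` are `"unchanged"`; features passing both
#' `|log2FC| >= lfc_response` and `p < alpha` are `"up"` or `"down"` by
#' sign; features passing the fold-change bar but not the p-value are
#' `"non_responsive"`. The `significant` flag additionally requires
#' `|log2FC| >= lfc_significant`. Infinite fold changes (one library at
#' zero) classify by sign with significance from the p-value alone;
#' both-zero features (`NaN` fold change) are `"unchanged"`.
#'
#' @param log2fc Log2 fold changes (treatment / control).
#' @param pvalue p-values.
#' @param lfc_response Response fold-change threshold (default 0.25).
#' @param lfc_significant Significance fold-change threshold (default 1).
#' @param alpha p-value threshold (default 0.05).
#' @return Tibble with columns `tier` (one of `up`, `down`, `unchanged`,
#'   `non_responsive`) and `significant`.
#' @export
classify_tier <- function(log2fc, pvalue, lfc_response = 0.25,
                          lfc_significant = 1, alpha = 0.05) {
  afc <- abs(log2fc)
  afc[is.nan(afc)] <- 0
  tier <- dplyr::case_when(
    afc < lfc_response ~ "unchanged",
    pvalue < alpha & log2fc > 0 ~ "up",
    pvalue < alpha & log2fc < 0 ~ "down",
    .default = "non_responsive"
  )
  tibble::tibble(
    tier = tier,
    significant = tier %in% c("up", "down") & afc >= lfc_significant
  )
}

#' Two-library differential expression table
#'
#' Joint RPM normalization (tRF + phasiRNA counts plus the miRNA total
#' of each library form the denominator), log2 fold change A1D/C1D,
#' Audic-Claverie p-value on the raw counts, Benjamini-Hochberg q-value
#' (reported for transparency; the tier classification uses the raw
#' p-value, matching the single-library-per-condition design), and the
#' response tier.
#'
#' @param counts Tibble with `item_id`, `class` and raw count columns
#'   `C1D`, `A1D`.
#' @param mirna_totals Named vector (`C1D`, `A1D`) of miRNA read totals.
#' @param pseudocount Optional pseudocount added to both RPM values
#'   before the fold change (default 0: infinite fold changes are kept
#'   and classified by sign).
#' @param ... Passed to [classify_tier()].
#' @return Tibble with `item_id`, `class`, counts, `rpm_C1D`,
#'   `rpm_A1D`, `log2fc`, `pvalue`, `qvalue`, `tier`, `significant`.
#' @export
diffexp_table <- function(counts, mirna_totals, pseudocount = 0, ...) {
  n1 <- sum(counts$C1D) + mirna_totals[["C1D"]]
  n2 <- sum(counts$A1D) + mirna_totals[["A1D"]]
  rpm_c <- normalize_rpm(counts$C1D, n1)
  rpm_a <- normalize_rpm(counts$A1D, n2)
  log2fc <- log2((rpm_a + pseudocount) / (rpm_c + pseudocount))
  pvalue <- audic_pvalue(counts$C1D, counts$A1D, n1, n2)
  tiers <- classify_tier(log2fc, pvalue, ...)
  tibble::tibble(
    item_id = counts$item_id, class = counts$class,
    C1D = counts$C1D, A1D = counts$A1D,
    rpm_C1D = rpm_c, rpm_A1D = rpm_a,
    log2fc = log2fc, pvalue = pvalue,
    qvalue = stats::p.adjust(pvalue, method = "BH"),
    tier = tiers$tier, significant = tiers$significant
  )
}

#' Filter features for detailed reporting
#'
#' Keeps features whose RPM reaches `min_rpm` (default 10) in at least
#' one library.
#'
#' @param records Tibble with the RPM columns.
#' @param min_rpm Reporting threshold.
#' @param rpm_cols Names of the per-library RPM columns.
#' @return The filtered tibble.
#' @export
reporting_filter <- function(records, min_rpm = 10,
                             rpm_cols = c("rpm_C1D", "rpm_A1D")) {
  keep <- Reduce(`|`, lapply(rpm_cols, function(cl) {
    records[[cl]] >= min_rpm
  }))
  records[keep, ]
}
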