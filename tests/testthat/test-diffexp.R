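# Joint RPM normalization, the Audic-Claverie test and tier
# classification.

test_that("RPM normalization follows the joint-denominator formula", {
  expect_identical(normalize_rpm(100, 2e6), 50)
  expect_identical(normalize_rpm(0, 123), 0)
  expect_error(normalize_rpm(5, 0), "positive")
  # the three classes sum to one million under the shared denominator
  counts <- tibble::tibble(item_id = letters[1:4],
                           class = c("tRF", "tRF", "phasiRNA", "phasiRNA"),
                           C1D = c(100L, 50L, 30L, 20L),
                           A1D = c(80L, 60L, 25L, 35L))
  mirna <- c(C1D = 800L, A1D = 800L)
  de <- diffexp_table(counts, mirna)
  expect_equal(sum(de$rpm_C1D) + normalize_rpm(800, 1000), 1e6)
  expect_equal(sum(de$rpm_A1D) + normalize_rpm(800, 1000), 1e6)
})

test_that("audic_pmf reproduces the closed-form point mass", {
  expect_equal(audic_pmf(5, 5, 1e6, 1e6), 252 / 2048)
  expect_equal(audic_pmf(0, 0, 1e6, 1e6), 0.5)
  expect_error(audic_pmf(-1, 0, 1, 1), ">= 0")
})

test_that("audic_pvalue matches the negative-binomial tail oracle", {
  set.seed(4)
  x <- sample(0:200, 60, replace = TRUE)
  y <- sample(0:200, 60, replace = TRUE)
  for (r in c(0.5, 1, 2)) {
    n1 <- 1.5e6
    n2 <- n1 * r
    pp <- n1 / (n1 + n2)
    lo <- pnbinom(y, size = x + 1, prob = pp)
    up <- pnbinom(y - 1, size = x + 1, prob = pp, lower.tail = FALSE)
    orc <- pmin(1, 2 * pmin(lo, up))
    expect_equal(audic_pvalue(x, y, n1, n2), orc, tolerance = 1e-12)
  }
})

test_that("audic_pvalue has the symmetric-null and divergence properties", {
  expect_identical(audic_pvalue(0, 0, 1e6, 1e6), 1)
  expect_lt(audic_pvalue(0, 50, 1e6, 1e6), 1e-10)
  # the conditional probability mass is exactly symmetric for equal
  # totals; the doubled-tail p-value is directional (it conditions on
  # x), so only ratio-boundedness holds between the two orientations
  expect_equal(audic_pmf(7, 19, 1e6, 1e6), audic_pmf(19, 7, 1e6, 1e6))
  r <- audic_pvalue(7, 19, 1e6, 1e6) / audic_pvalue(19, 7, 1e6, 1e6)
  expect_lt(abs(log2(r)), 1.01)
  # p in (0, 1] and non-increasing in |x - y| for equal libraries
  for (tot in c(10L, 40L)) {
    p <- vapply(0:tot, function(x) {
      audic_pvalue(x, tot - x, 1e6, 1e6)
    }, numeric(1))
    expect_true(all(p > 0 & p <= 1))
    lower_half <- p[seq_len(tot %/% 2 + 1)]
    expect_true(all(diff(lower_half) >= -1e-12))
  }
})

test_that("tiers partition records and respect both thresholds", {
  # published RPM pair 1368.32 -> 291.07: down and significant
  lfc <- log2(291.07 / 1368.32)
  t1 <- classify_tier(lfc, 1e-6)
  expect_identical(t1$tier, "down")
  expect_true(t1$significant)
  expect_equal(lfc, -2.233, tolerance = 1e-3)
  # |lfc| below 0.25 is unchanged regardless of p
  expect_identical(classify_tier(0.24, 1e-9)$tier, "unchanged")
  # boundary: |lfc| = 0.25 with p just under alpha responds, not signif.
  t2 <- classify_tier(-0.25, 0.049)
  expect_identical(t2$tier, "down")
  expect_false(t2$significant)
  # fold-change pass with p fail is non-responsive, never unchanged
  expect_identical(classify_tier(2, 0.5)$tier, "non_responsive")
  # zero-count edges: one-sided zero classifies by sign, both-zero stays
  expect_identical(classify_tier(Inf, 0.01)$tier, "up")
  expect_identical(classify_tier(-Inf, 0.01)$tier, "down")
  expect_identical(classify_tier(NaN, 1)$tier, "unchanged")
  # every record lands in exactly one tier
  set.seed(8)
  tiers <- classify_tier(rnorm(200), runif(200))$tier
  expect_true(all(tiers %in% c("up", "down", "unchanged", "non_responsive")))
})

test_that("the 10-RPM reporting filter keeps at-least-one-library passes", {
  tb <- tibble::tibble(rpm_C1D = c(9.9, 9.9, 300), rpm_A1D = c(9.9, 10, 1))
  expect_identical(nrow(reporting_filter(tb)), 2L)
})

test_that("planted fold effects are recovered in direction", {
  set.seed(77)
  n <- 120
  items <- tibble::tibble(item_id = sprintf("it%03d", 1:n), class = "tRF",
                          base_mean = round(runif(n, 100, 600)))
  eff <- setNames(rep(c(4, 0.25), each = 20), items$item_id[1:40])
  cfg <- sim_config(seed = 33, condition_effects = eff, dispersion = 0.05)
  libs <- simulate_two_libraries(items, cfg)
  de <- diffexp_table(libs$counts, libs$mirna_totals)
  up_ok <- mean(de$tier[1:20] == "up")
  down_ok <- mean(de$tier[21:40] == "down")
  expect_gte(mean(c(up_ok, down_ok)), 0.95)
  # BH q-values are reported alongside raw p-values
  expect_true(all(de$qvalue >= de$pvalue - 1e-15))
})
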