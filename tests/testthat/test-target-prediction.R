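# Duplex scoring, nearest-neighbour free energy and target-site
# prediction.

test_that("a perfect 21-nt duplex scores the closed-form 210", {
  set.seed(5)
  s <- random_rna(21)
  al <- complementarity_score(s, rc_rna(s))
  # 7 seed positions at 4 x 5 plus 14 at 5
  expect_identical(al$score, 4 * 7 * 5 + 14 * 5)
  expect_identical(al$site_start, 0L)
  expect_identical(al$site_end, 21L)
  expect_identical(al$states, strrep("M", 21))
})

test_that("a non-complementary window yields no positive alignment", {
  al <- complementarity_score(strrep("A", 21), strrep("A", 25))
  expect_identical(al$score, 0)
  expect_identical(al$states, "")
})

test_that("one mismatch outside the seed costs exactly match - mismatch", {
  set.seed(6)
  repeat {  # sRNA whose position-15 pair cannot become a wobble
    s <- random_rna(21)
    if (!substr(s, 15, 15) %in% c("G", "U")) break
  }
  w <- rc_rna(s)
  # the base pairing sRNA position 15 sits at window position 21-15+1=7
  mism <- c(A = "C", C = "A", G = "A", U = "C")
  b <- substr(s, 15, 15)
  substr(w, 7, 7) <- mism[[b]]
  al <- complementarity_score(s, w)
  expect_identical(al$score, 210 - 8)
})

test_that("alignment score is invariant under site translation", {
  set.seed(7)
  s <- random_rna(21)
  core <- rc_rna(s)
  w1 <- paste0("ACGUA", core, "GGCAU")
  al <- complementarity_score(s, w1)
  expect_identical(al$score, 210)
  expect_identical(al$site_start, 5L)
  expect_identical(al$site_end, 26L)
})

test_that("alignment equals exhaustive enumeration on small instances", {
  set.seed(11)
  wts <- duplex_weights()
  for (i in 1:40) {
    s <- random_rna(sample(5:7, 1))
    w <- random_rna(sample(6:9, 1))
    got <- trfphas:::duplex_align_cpp(
      trfphas:::encode_rna(s), trfphas:::encode_rna(w),
      wts$match, wts$wobble, wts$mismatch, wts$gap_open, wts$gap_extend,
      wts$seed[1], wts$seed[2], wts$seed_scale)
    expect_identical(got$score, oracle_enum_align(s, w, wts))
  }
})

test_that("alignment equals an independent DP at production size", {
  set.seed(12)
  for (i in 1:40) {
    s <- random_rna(21)
    w <- random_rna(25)
    expect_identical(complementarity_score(s, w)$score,
                     oracle_dp_align(s, w))
  }
  # near-complementary windows too (the regime that matters)
  for (i in 1:20) {
    s <- random_rna(21)
    w <- rc_rna(s)
    k <- sample(3:19, 2)
    for (p in k) substr(w, p, p) <- sample(c("A", "C", "G", "U"), 1)
    expect_identical(complementarity_score(s, w)$score,
                     oracle_dp_align(s, w))
  }
})

test_that("stack energies sum per the packaged table", {
  tab <- rna_stack_table()
  # k identical GC/GC stacks: init + k * stack value
  al <- structure(list(srna = strrep("G", 10), window = strrep("C", 10),
                       states = strrep("M", 10), srna_pos = 1:10,
                       target_pos = 9:0),
                  class = "duplex_alignment")
  expect_equal(duplex_free_energy(al), 4.09 + 9 * tab[["GG/CC"]])
  # no stack (single pair or empty) gives zero
  one <- structure(list(srna = "G", window = "C", states = "M",
                        srna_pos = 1L, target_pos = 0L),
                   class = "duplex_alignment")
  expect_identical(duplex_free_energy(one), 0)
  empty <- structure(list(srna = "", window = "", states = "",
                          srna_pos = integer(), target_pos = integer()),
                     class = "duplex_alignment")
  expect_identical(duplex_free_energy(empty), 0)
  # appending matched stacks strictly lowers the energy
  set.seed(13)
  s <- random_rna(25)
  e <- vapply(18:25, function(k) {
    al <- complementarity_score(substr(s, 1, k), rc_rna(substr(s, 1, k)))
    duplex_free_energy(al)
  }, numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("energies match direct table summation on random duplexes", {
  set.seed(14)
  for (i in 1:200) {
    s <- random_rna(21)
    w <- rc_rna(s)
    for (p in sample(3:19, sample(0:2, 1))) {
      substr(w, p, p) <- sample(c("A", "C", "G", "U"), 1)
    }
    al <- complementarity_score(s, w)
    # compare only when the best alignment is the gapless identity
    # pairing the oracle assumes
    if (al$srna_start == 0 && al$site_start == 0 && al$site_end == 21 &&
        !grepl("[ST]", al$states)) {
      expect_equal(duplex_free_energy(al), oracle_duplex_energy(s, w))
    }
  }
})

test_that("planted sites are recovered under calibrated gates", {
  set.seed(15)
  srnas <- c(ph1 = random_rna(21), ph2 = random_rna(21))
  tx <- simulate_target_transcripts(srnas, seed = 3, n_per_srna = 2)
  sites <- predict_targets(srnas,
                           setNames(tx$sequence, tx$transcript_id),
                           score_threshold = 180, energy_threshold = -25)
  passing <- sites[sites$passes, ]
  for (i in seq_len(nrow(tx))) {
    hit <- passing[passing$srna_id == tx$srna_id[i] &
                     passing$transcript_id == tx$transcript_id[i], ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$start, tx$site_start[i])
    expect_identical(hit$end, tx$site_start[i] + 21L)
  }
  # two sRNAs sharing a transcript give two records
  shared <- paste0(substr(tx$sequence[1], 1, 81),
                   rc_rna(srnas[["ph2"]]),
                   substr(tx$sequence[1], 103, 141))
  s2 <- predict_targets(srnas, c(tx1 = shared), score_threshold = 180,
                        energy_threshold = -25)
  expect_setequal(unique(s2$srna_id[s2$passes]), c("ph1", "ph2"))
  # empty transcriptome warns and returns nothing
  expect_warning(none <- predict_targets(srnas, character(0)), "empty")
  expect_identical(nrow(none), 0L)
})

test_that("the published gates pass nothing under the default weights", {
  set.seed(16)
  s <- random_rna(21)
  sites <- predict_targets(c(a = s), c(t1 = rc_rna(s)))
  expect_true(all(!sites$passes))
  expect_identical(max(sites$score), 210)
})
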