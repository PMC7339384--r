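# Synthetic-data generator: configuration validation, determinism,
# conservation of read depth, planted-truth linkage and the binomial
# behaviour of the cleavage and phasing simulators.

test_that("sim_config validates its fields and names the offender", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_trnas = 0), "n_trnas")
  expect_error(sim_config(noise_fraction = 1.2), "noise_fraction")
  expect_error(sim_config(phase_len = 10), "phase_len")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(condition_effects = c(a = -2)), "condition_effects")
  bad_profile <- data.frame(start = 0, end = 20, prob = 0.5)
  expect_error(sim_config(trf_cleavage_profile = bad_profile),
               "trf_cleavage_profile")
})

test_that("simulated tRNAs have valid, ordered cloverleaf landmarks", {
  g <- simulate_trna_set(sim_config(seed = 7, n_trnas = 1))[[1]]
  expect_s3_class(g, "trna_gene")
  len <- nchar(g$sequence)
  expect_gte(len, 72)
  expect_lte(len, 90)
  expect_true(all(diff(g$landmarks$start) > 0))
  genes <- simulate_trna_set(sim_config(seed = 1, n_trnas = 100))
  for (g in genes) {
    expect_true(g$loops$d_loop[2] <= g$loops$ac_loop[1])
    expect_true(g$loops$ac_loop[2] <= g$loops$t_loop[1])
  }
  # every tRNA-Ala carries the canonical 5'-G / D-loop-U 20-mer signal
  alas <- Filter(function(g) g$isotype == "Ala", genes)
  expect_gt(length(alas), 0)
  for (g in alas) {
    expect_identical(substr(g$sequence, 1, 1), "G")
    expect_identical(substr(g$sequence, 20, 20), "U")
    expect_identical(g$loops$d_loop[2], 22L)
  }
})

test_that("identical configs give byte-identical simulations", {
  cfg <- sim_config(seed = 11, n_trnas = 5, depth_per_library = 2000)
  t1 <- simulate_trna_set(cfg)
  t2 <- simulate_trna_set(cfg)
  expect_identical(t1, t2)
  expect_identical(simulate_trf_reads(t1, cfg), simulate_trf_reads(t2, cfg))
  ref <- list(id = "r", sequence = paste(rep("A", 800), collapse = ""))
  expect_identical(simulate_phas_reads(ref, cfg),
                   simulate_phas_reads(ref, cfg))
})

test_that("tRF reads are exact substrings and conserve library depth", {
  cfg <- sim_config(seed = 3, n_trnas = 6, depth_per_library = 5000)
  trnas <- simulate_trna_set(cfg)
  sim <- simulate_trf_reads(trnas, cfg)
  expect_identical(sum(sim$reads$count), cfg$depth_per_library)
  seqs <- setNames(vapply(trnas, `[[`, character(1), "sequence"),
                   vapply(trnas, `[[`, character(1), "id"))
  for (i in seq_len(nrow(sim$reads))) {
    r <- sim$reads[i, ]
    expect_identical(r$seq, substr(seqs[[r$trna_id]], r$start + 1, r$end))
    expect_gte(nchar(r$seq), 18)
    expect_lte(nchar(r$seq), 30)
  }
})

test_that("degenerate cleavage profiles behave as specified", {
  prof <- data.frame(start = 0, end = 20, prob = 1)
  cfg <- sim_config(seed = 5, n_trnas = 3, trf_cleavage_profile = prof,
                    noise_fraction = 0, depth_per_library = 1000)
  trnas <- simulate_trna_set(cfg)
  sim <- simulate_trf_reads(trnas, cfg)
  expect_true(all(sim$reads$start == 0 & sim$reads$end == 20))
  # all-noise: no planted truth
  cfg1 <- sim_config(seed = 5, n_trnas = 3, noise_fraction = 1,
                     depth_per_library = 1000)
  expect_identical(nrow(simulate_trf_reads(trnas, cfg1)$truth), 0L)
  # profile exceeding the tRNA length errors
  long <- data.frame(start = 60, end = 88, prob = 1)
  cfgl <- sim_config(seed = 5, n_trnas = 3, trf_cleavage_profile = long)
  expect_error(simulate_trf_reads(trnas, cfgl), "exceed")
})

test_that("cleavage-length fractions follow the profile binomially", {
  prof <- data.frame(start = c(0, 0), end = c(20, 22), prob = c(0.9, 0.1))
  cfg <- sim_config(seed = 3, n_trnas = 1, trf_cleavage_profile = prof,
                    noise_fraction = 0, depth_per_library = 1000)
  sim <- simulate_trf_reads(simulate_trna_set(cfg), cfg)
  frac20 <- sum(sim$reads$count[sim$reads$end - sim$reads$start == 20]) /
    sum(sim$reads$count)
  expect_lt(abs(frac20 - 0.9), 3 * sqrt(0.9 * 0.1 / 1000))
})

test_that("noise-free planted truth links one-to-one with read records", {
  cfg <- sim_config(seed = 9, n_trnas = 4, noise_fraction = 0,
                    depth_per_library = 20000)
  trnas <- simulate_trna_set(cfg)
  sim <- simulate_trf_reads(trnas, cfg)
  truth_keys <- with(sim$truth, paste(trna_id, start, end))
  read_keys <- with(sim$reads, paste(trna_id, start, end))
  expect_setequal(truth_keys, read_keys)
  expect_false(any(duplicated(truth_keys)))
})

test_that("phased reads land on the planted register", {
  cfg <- sim_config(seed = 2, n_phase_cycles = 10, noise_fraction = 0,
                    depth_per_library = 1000)
  ref <- list(id = "r", sequence = paste(rep("A", 400), collapse = ""))
  sim <- simulate_phas_reads(ref, cfg)
  r <- sim$truth$register
  pos <- ifelse(sim$reads$strand == "-", sim$reads$start + 2L,
                sim$reads$start)
  expect_true(all(pos %% 21 == r))
  expect_true(all(sim$reads$length == 21))
  # zero cycles: empty planted set and empty truth
  cfg0 <- sim_config(seed = 2, n_phase_cycles = 0, noise_fraction = 0)
  sim0 <- simulate_phas_reads(ref, cfg0)
  expect_identical(nrow(sim0$reads), 0L)
  expect_identical(nrow(sim0$truth), 0L)
  # too-short reference errors
  tiny <- list(id = "t", sequence = paste(rep("A", 100), collapse = ""))
  expect_error(simulate_phas_reads(tiny, cfg), "shorter")
})

test_that("phased-copy fraction tracks 1 - noise_fraction binomially", {
  cfg <- sim_config(seed = 5, n_phase_cycles = 10, noise_fraction = 0.5,
                    depth_per_library = 2000)
  ref <- list(id = "r", sequence = paste(rep("A", 800), collapse = ""))
  sim <- simulate_phas_reads(ref, cfg)
  r <- sim$truth$register
  pos <- ifelse(sim$reads$strand == "-", sim$reads$start + 2L,
                sim$reads$start)
  phased <- pos %% 21 == r & sim$reads$length == 21
  frac <- sum(sim$reads$count[phased]) / sum(sim$reads$count)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000) + 0.01)
})

test_that("two-library counts scale by the condition effect", {
  items <- tibble::tibble(item_id = sprintf("it%02d", 1:50),
                          class = "tRF", base_mean = 20000)
  cfg <- sim_config(seed = 8, dispersion = 0.01,
                    condition_effects = c(it01 = 0.25))
  libs <- simulate_two_libraries(items, cfg)
  lfc <- log2(libs$counts$A1D[1] / libs$counts$C1D[1])
  expect_lt(abs(lfc - (-2)), 0.3)
  # effect keys outside the item set error
  cfgx <- sim_config(seed = 8, condition_effects = c(nosuch = 2))
  expect_error(simulate_two_libraries(items, cfgx), "nosuch")
  # empty truth: empty tables, no error
  empty <- items[0, ]
  out <- simulate_two_libraries(empty, cfg)
  expect_identical(nrow(out$counts), 0L)
  expect_length(out$mirna_totals, 2)
})
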