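# Register scanning, the phased score, locus calling with exclusions,
# phasiRNA extraction and origin classification.

mk_reads <- function(start, strand = "+", length = 21L, count = 1L,
                     ref = "chr1") {
  tibble::tibble(ref_id = ref, start = as.integer(start), strand = strand,
                 length = as.integer(length), count = as.integer(count))
}

test_that("scan_registers computes ratio, occupancy and abundance", {
  # ten in-register reads, nothing else: ratio 1, n_p = distinct starts
  r <- scan_registers(mk_reads(c(0, 21, 42, 63, 0), count = 2L), 0, 189)
  expect_identical(r$register, 0L)
  expect_identical(r$ratio, 1)
  expect_identical(r$n_p, 4L)
  expect_identical(r$a_p, 10)
  # half phased, half off-register: ratio 0.5
  reads <- dplyr::bind_rows(mk_reads(c(0, 21, 42, 63, 84), count = 1L),
                            mk_reads(c(5, 26, 47, 68, 89), count = 1L))
  r2 <- scan_registers(reads, 0, 189)
  expect_identical(r2$ratio, 0.5)
  # empty window scores zero
  expect_identical(scan_registers(mk_reads(integer(0)), 0, 189)$score, 0)
})

test_that("the phased score follows its documented formula and is monotone", {
  expect_identical(phase_score(0, 1, 100), 0)
  expect_equal(phase_score(10, 1, exp(1) - 1), 10)
  # constructed window: components known by hand
  reads <- dplyr::bind_rows(mk_reads(c(0, 21, 42, 63), count = 5L),
                            mk_reads(10, count = 4L))
  r <- scan_registers(reads, 0, 189)
  expect_equal(r$score, 4 * (20 / 24) * log1p(20))
  # monotone in each component over a grid
  grid <- expand.grid(n = 1:5, ratio = c(.2, .5, .9), a = c(5, 50, 500))
  s <- phase_score(grid$n, grid$ratio, grid$a)
  for (v in c("n", "ratio", "a")) {
    for (g in split(seq_len(nrow(grid)), grid[setdiff(names(grid), v)])) {
      ord <- order(grid[[v]][g])
      expect_true(all(diff(s[g][ord]) > 0))
    }
  }
})

test_that("antisense reads phase through the 2-nt overhang convention", {
  # sense ladder at register 3 plus one antisense read at start r-2
  reads <- dplyr::bind_rows(mk_reads(c(3, 24, 45, 66)),
                            mk_reads(1, strand = "-"))
  r <- scan_registers(reads, 0, 189)
  expect_identical(r$register, 3L)
  expect_identical(r$n_p, 5L)
  expect_identical(r$ratio, 1)
})

test_that("planted loci are called at the right register; exclusions drop", {
  cfg <- sim_config(seed = 17, n_phase_cycles = 8, noise_fraction = 0,
                    depth_per_library = 500)
  ref <- list(id = "chr1", sequence = paste(rep("A", 1000), collapse = ""))
  sim <- simulate_phas_reads(ref, cfg)
  loci <- call_phas_loci(sim$reads, c(chr1 = 1000))
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$register, sim$truth$register %% 21L)
  expect_lte(loci$start, sim$truth$start)
  expect_gte(loci$end, sim$truth$end - 21L)
  # the same locus inside an rRNA annotation is excluded with a log entry
  excl <- tibble::tibble(ref_id = "chr1", start = 0L, end = 1000L,
                         type = "rRNA")
  expect_message(
    none <- call_phas_loci(sim$reads, c(chr1 = 1000), exclusions = excl),
    "excluded"
  )
  expect_identical(nrow(none), 0L)
  expect_identical(attr(none, "excluded"), 1L)
  # annotations on unknown references are an input error
  bad <- tibble::tibble(ref_id = "chrX", start = 0L, end = 10L, type = "t")
  expect_error(call_phas_loci(sim$reads, c(chr1 = 1000), exclusions = bad),
               "unknown")
})

test_that("references shorter than four cycles are skipped with a note", {
  expect_message(
    out <- call_phas_loci(mk_reads(0, ref = "s"), c(s = 80L)),
    "skipped"
  )
  expect_identical(nrow(out), 0L)
})

test_that("phasiRNA extraction honours the exact-length and position rule", {
  locus <- tibble::tibble(locus_id = "chr1_1", ref_id = "chr1", start = 0L,
                          end = 84L, register = 0L, score = 10,
                          strands = "+")
  libs <- list(
    C1D = dplyr::bind_rows(mk_reads(c(0, 21, 42), count = 7L),
                           mk_reads(21, length = 22L, count = 9L)),
    A1D = mk_reads(0, count = 3L)[0, ]
  )
  ph <- extract_phasirnas(locus, libs)
  expect_identical(nrow(ph), 3L)
  expect_identical(ph$phasirna_id,
                   c("chr1_1_1(+)", "chr1_1_22(+)", "chr1_1_43(+)"))
  expect_identical(ph$count_C1D, c(7, 7, 7))  # the 22-mer never counts
  expect_identical(ph$count_A1D, c(0, 0, 0))
  # within-locus counts never exceed the 21-nt copies over the locus
  expect_lte(sum(ph$count_C1D),
             sum(libs$C1D$count[libs$C1D$length == 21]))
})

test_that("locus origin takes the larger-overlap gene, else noncoding", {
  loci <- tibble::tibble(locus_id = c("c_1", "c_2"), ref_id = "c",
                         start = c(100L, 900L), end = c(300L, 950L),
                         register = 0L, score = 5, strands = "+")
  genes <- tibble::tibble(ref_id = "c", start = c(0L, 250L),
                          end = c(260L, 600L),
                          class = c("NBS-LRR", "RLK"))
  out <- classify_phas_origin(loci, genes)
  expect_identical(out$origin, c("NBS-LRR", "noncoding"))
})

test_that("sensitivity is perfect at moderate noise and 8 cycles", {
  hits <- vapply(1:15, function(s) {
    cfg <- sim_config(seed = s, n_phase_cycles = 8, noise_fraction = 0.3,
                      depth_per_library = 800)
    ref <- list(id = "r", sequence = paste(rep("A", 1500), collapse = ""))
    sim <- simulate_phas_reads(ref, cfg)
    loci <- suppressMessages(call_phas_loci(sim$reads, c(r = 1500)))
    any(loci$register == sim$truth$register %% 21L &
          loci$start < sim$truth$end & loci$end > sim$truth$start)
  }, logical(1))
  expect_true(all(hits))
})
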