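# Exact alignment, read-end peak calling, 75%-overlap classification
# and the three-bases-outside quantification.

test_that("align_exact reports every exact occurrence and only those", {
  trnas <- test_genes(4)
  seqs <- setNames(vapply(trnas, `[[`, character(1), "sequence"),
                   vapply(trnas, `[[`, character(1), "id"))
  reads <- tibble::tibble(seq = substr(seqs[[1]], 1, 20), count = 7L)
  aln <- align_exact(reads, trnas)
  expect_identical(aln$start[aln$trna_id == trnas[[1]]$id][1], 0L)
  expect_identical(aln$end[aln$trna_id == trnas[[1]]$id][1], 20L)
  # a read present in two identical isodecoders maps to both
  twin <- trnas[1:2]
  twin[[2]]$sequence <- twin[[1]]$sequence
  twin[[2]]$id <- "twin"
  aln2 <- align_exact(reads, twin)
  expect_identical(nrow(aln2), 2L)
  expect_setequal(aln2$trna_id, c(twin[[1]]$id, "twin"))
  # an absent read counts as unmapped
  absent <- tibble::tibble(seq = strrep("ACGUA", 5), count = 1L)
  expect_message(aln3 <- align_exact(absent, trnas), "no exact")
  expect_identical(nrow(aln3), 0L)
  expect_identical(attr(aln3, "unmapped"), 1L)
})

test_that("end profiles conserve the aligned copy count", {
  aln <- tibble::tibble(seq = "x", count = c(10L, 5L, 3L),
                        trna_id = "t1", start = c(0L, 0L, 30L),
                        end = c(20L, 22L, 51L))
  prof <- end_profile(aln)
  expect_identical(sum(prof$n5), sum(aln$count))
  expect_identical(sum(prof$n3), sum(aln$count))
  expect_identical(prof$n5[prof$pos == 0], 15L)
})

test_that("peak calling finds modal ends, splits disjoint clusters", {
  mk <- function(start, end, count) {
    tibble::tibble(seq = "x", count = count, trna_id = "t1",
                   start = start, end = end)
  }
  # single pure fragment: one candidate
  one <- call_trf_peaks(mk(0L, 20L, 1000L))
  expect_identical(nrow(one), 1L)
  expect_identical(c(one$start, one$end), c(0L, 20L))
  # 900 vs 100 copies sharing a 5' end: one candidate at the modal 3' end
  two <- call_trf_peaks(dplyr::bind_rows(mk(0L, 20L, 900L),
                                         mk(0L, 22L, 100L)))
  expect_identical(nrow(two), 1L)
  expect_identical(c(two$start, two$end, two$support), c(0L, 20L, 1000L))
  # modal-3' tie breaks toward the longer fragment
  tie <- call_trf_peaks(dplyr::bind_rows(mk(0L, 20L, 500L),
                                         mk(0L, 22L, 500L)))
  expect_identical(tie$end, 22L)
  # disjoint clusters come out as separate candidates, support-sorted
  twoc <- call_trf_peaks(dplyr::bind_rows(mk(0L, 20L, 400L),
                                          mk(30L, 51L, 500L)))
  expect_identical(nrow(twoc), 2L)
  expect_identical(twoc$start, c(30L, 0L))
  # empty profile: empty result
  expect_identical(nrow(call_trf_peaks(mk(0L, 20L, 1L)[0, ])), 0L)
})

test_that("classification matches the 75% rule incl. the exact boundary", {
  g <- Filter(function(g) g$isotype == "Ala", test_genes(4))[[1]]
  p <- partition_regions(g)   # 5e = [0, 20)
  expect_identical(classify_trf(0L, 20L, p), "5e-tRF")
  # 15 of 20 bases inside 5e only: proportion exactly 0.75
  expect_identical(classify_trf(5L, 25L, p), "5e-tRF")
  # 14 of 20: below the bar everywhere relevant -> not 5e
  expect_false("5e-tRF" %in% classify_trf(6L, 26L, p))
  # a fragment in the D/A intersection carries both labels
  d_end <- p$end[p$region == "D"]
  both <- classify_trf(d_end - 4L, d_end, p)
  expect_setequal(both, c("D-tRF", "A-tRF"))
  expect_error(classify_trf(5L, 5L, p), "empty")
})

test_that("classification agrees with the brute-force interval oracle", {
  genes <- test_genes(20)
  set.seed(99)
  for (i in 1:500) {
    g <- genes[[sample(length(genes), 1)]]
    p <- partition_regions(g)
    len <- nchar(g$sequence)
    a <- sample(0:(len - 18), 1)
    b <- a + sample(18:min(30, len - a), 1)
    expect_identical(sort(classify_trf(a, b, p)),
                     sort(oracle_classify_trf(a, b, p)))
  }
})

test_that("quantification applies the three-bases-outside rule exactly", {
  aln <- tibble::tibble(start = c(0L, 2L, 0L, 0L),
                        end = c(20L, 25L, 23L, 24L),
                        count = c(10L, 100L, 1L, 1000L))
  # bases outside [0,20): 0, 5, 3, 4 -> counted, not, boundary-counted, not
  expect_identical(quantify_trf(0L, 20L, aln), 11L)
})

test_that("the 2-RPM noise filter removes only both-below features", {
  tb <- tibble::tibble(trf_id = c("a", "b", "c"),
                       rpm_C1D = c(1.9, 1.9, 0),
                       rpm_A1D = c(1.9, 2.0, 100))
  expect_identical(filter_low_trfs(tb)$trf_id, c("b", "c"))
})

test_that("planted tRFs are recovered with exact boundaries and labels", {
  prof <- data.frame(start = c(0L, 40L), end = c(20L, 62L),
                     prob = c(0.7, 0.3))
  cfg <- sim_config(seed = 13, n_trnas = 8, trf_cleavage_profile = prof,
                    noise_fraction = 0.2, depth_per_library = 20000)
  trnas <- simulate_trna_set(cfg)
  sim <- simulate_trf_reads(trnas, cfg)
  aln <- tibble::tibble(seq = sim$reads$seq, count = sim$reads$count,
                        trna_id = sim$reads$trna_id,
                        start = sim$reads$start, end = sim$reads$end)
  peaks <- call_trf_peaks(aln, min_support = 50)
  called <- paste(peaks$trna_id, peaks$start, peaks$end)
  parts <- lapply(trnas, partition_regions)
  names(parts) <- vapply(trnas, `[[`, character(1), "id")
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    support <- sum(aln$count[aln$trna_id == tr$trna_id &
                               aln$start == tr$start & aln$end == tr$end])
    if (support < 50) next
    expect_true(paste(tr$trna_id, tr$start, tr$end) %in% called)
    labs <- classify_trf(tr$start, tr$end, parts[[tr$trna_id]])
    expect_identical(sort(labs),
                     sort(oracle_classify_trf(tr$start, tr$end,
                                              parts[[tr$trna_id]])))
  }
})

test_that("label cardinality and 'others' exclusivity hold on tRF tables", {
  cfg <- sim_config(seed = 21, n_trnas = 6, depth_per_library = 8000)
  trnas <- simulate_trna_set(cfg)
  sim <- simulate_trf_reads(trnas, cfg)
  aln <- tibble::tibble(seq = sim$reads$seq, count = sim$reads$count,
                        trna_id = sim$reads$trna_id,
                        start = sim$reads$start, end = sim$reads$end)
  tb <- trf_table(list(C1D = aln, A1D = aln), trnas)
  labels <- strsplit(tb$type, "\\+")
  for (l in labels) {
    expect_gte(length(l), 1)
    expect_lte(length(l), 2)
    if ("others" %in% l) expect_length(l, 1)
  }
  expect_true(all(grepl("^.*:\\d+-\\d+$", tb$trf_id)))
})
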