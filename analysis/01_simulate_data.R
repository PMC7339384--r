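#!/usr/bin/env Rscript
# Stage 1: simulate the study design — a tRNA reference set, a
# cleavage-biased small-RNA read population with planted tRFs, a phased
# 21-nt ladder on a synthetic precursor, and two condition libraries
# (control C1D, ABA-treated A1D) in which selected items carry
# multiplicative treatment effects. Outputs land under results/synthetic/.

suppressMessages(library(trfphas))
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1L, n_trnas = 12, depth_per_library = 30000,
                  n_phase_cycles = 8, noise_fraction = 0.15)
write_config_yaml(cfg, file.path(out, "sim_config.yaml"))

trnas <- simulate_trna_set(cfg)
write_trna_tsv(trnas, file.path(out, "trnas.tsv"))
write_fasta(setNames(vapply(trnas, `[[`, character(1), "sequence"),
                     vapply(trnas, `[[`, character(1), "id")),
            file.path(out, "trnas.fasta"))

trf_sim <- simulate_trf_reads(trnas, cfg)
readr::write_tsv(trf_sim$reads, file.path(out, "trf_reads.tsv"))
readr::write_tsv(trf_sim$truth, file.path(out, "trf_truth.tsv"))

set.seed(cfg$seed)
precursor <- paste(sample(c("A", "C", "G", "U"), 1200, replace = TRUE),
                   collapse = "")
write_fasta(c(chr1 = precursor), file.path(out, "precursor.fasta"))
phas_sim <- simulate_phas_reads(list(id = "chr1", sequence = precursor), cfg)
readr::write_tsv(phas_sim$reads, file.path(out, "phas_reads.tsv"))
readr::write_tsv(phas_sim$truth, file.path(out, "phas_truth.tsv"))

# two-condition libraries: ABA broadly suppresses tRFs and the planted
# phasiRNA ladder (the strongest effects sit on the dominant items)
trf_items <- tibble::tibble(
  item_id = trf_sim$truth$item_id, class = "tRF",
  base_mean = vapply(seq_len(nrow(trf_sim$truth)), function(i) {
    with(trf_sim$reads, sum(count[trna_id == trf_sim$truth$trna_id[i] &
                                    start == trf_sim$truth$start[i] &
                                    end == trf_sim$truth$end[i]]))
  }, numeric(1))
)
eff <- setNames(rep(0.6, nrow(trf_items)), trf_items$item_id)
eff[trf_sim$truth$dominant] <- 0.8
cfg_lib <- sim_config(seed = 2L, condition_effects = eff, dispersion = 0.05)
libs <- simulate_two_libraries(trf_items, cfg_lib)
readr::write_tsv(libs$counts, file.path(out, "trf_library_counts.tsv"))
readr::write_tsv(tibble::tibble(library = names(libs$mirna_totals),
                                reads = as.integer(libs$mirna_totals)),
                 file.path(out, "mirna_totals.tsv"))

cat("simulated", length(trnas), "tRNAs,",
    sum(trf_sim$reads$count), "tRF read copies,",
    sum(phas_sim$reads$count), "phasing read copies;",
    "planted register", phas_sim$truth$register, "\n")
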