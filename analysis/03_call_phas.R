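#!/usr/bin/env Rscript
# Stage 3: scan the phased read ladder for 21-nt PHAS loci (phased
# ratio/number/abundance score over sliding 9-cycle windows), exclude
# any locus overlapping tRNA/rRNA-style annotations, and extract the
# individual phasiRNAs with per-library counts.

suppressMessages(library(trfphas))
syn <- "results/synthetic"
out <- "results"

precursor <- read_fasta(file.path(syn, "precursor.fasta"))
reads <- readr::read_tsv(file.path(syn, "phas_reads.tsv"),
                         col_types = "ciiciic")

# two libraries around the pooled ladder: ABA suppresses the locus
items <- tibble::tibble(
  item_id = paste0(reads$ref_id, ":", reads$start, reads$strand,
                   "/", reads$length),
  class = "phasiRNA", base_mean = reads$count)
eff <- setNames(ifelse(reads$source == "planted", 0.55, 1), items$item_id)
libs <- simulate_two_libraries(
  items, sim_config(seed = 3L, condition_effects = eff, dispersion = 0.05))
reads_by_lib <- list(
  C1D = dplyr::mutate(reads, count = libs$counts$C1D),
  A1D = dplyr::mutate(reads, count = libs$counts$A1D))
pooled <- dplyr::mutate(reads, count = libs$counts$C1D + libs$counts$A1D)

loci <- call_phas_loci(pooled, c(chr1 = nchar(precursor[["chr1"]])),
                       sequences = precursor)
phasirnas <- dplyr::bind_rows(lapply(seq_len(nrow(loci)), function(i) {
  extract_phasirnas(loci[i, ], reads_by_lib, sequences = precursor)
}))

readr::write_tsv(loci, file.path(out, "phas_loci.tsv"))
write_bed(loci, file.path(out, "phas_loci.bed"))
readr::write_tsv(phasirnas, file.path(out, "phasirnas.tsv"))
if (nrow(loci)) {
  write_fasta(setNames(loci$precursor, loci$locus_id),
              file.path(out, "phas_precursors.fasta"))
}

truth <- readr::read_tsv(file.path(syn, "phas_truth.tsv"),
                         col_types = "ciiii")
cat("called", nrow(loci), "locus/loci (planted register",
    truth$register, "-> called",
    paste(loci$register, collapse = ","), ");",
    nrow(phasirnas), "phasiRNAs extracted\n")
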