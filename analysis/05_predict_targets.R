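#!/usr/bin/env Rscript
# Stage 5: miRanda-style target prediction for the responsive
# phasiRNAs on synthetic transcripts carrying planted complementary
# sites, followed by the integration report joining phasiRNA tiers,
# passing sites and transcript expression status.

suppressMessages(library(trfphas))
out <- "results"

phas <- readr::read_tsv(file.path(out, "phasirnas.tsv"),
                        col_types = readr::cols())
de <- readr::read_tsv(file.path(out, "diffexp.tsv"),
                      col_types = readr::cols())

srnas <- setNames(phas$seq, phas$phasirna_id)
srnas <- srnas[!duplicated(names(srnas))]
tx <- simulate_target_transcripts(srnas, seed = 11,
                                  families = c("NBS-LRR", "STK", "RLK",
                                               "AP2/ERF", "WRKY"))
sites <- predict_targets(srnas, setNames(tx$sequence, tx$transcript_id),
                         score_threshold = 180, energy_threshold = -25)
readr::write_tsv(sites, file.path(out, "target_sites.tsv"))

# transcript status: targets of suppressed phasiRNAs are released
# (elevated), mirroring the negative-correlation expectation
set.seed(12)
tiers <- de$tier[match(tx$srna_id, de$item_id)]
fpkm_c <- runif(nrow(tx), 2, 12)
fold <- ifelse(tiers == "down", runif(nrow(tx), 1.6, 3),
               runif(nrow(tx), 0.7, 1.4))
statuses <- tibble::tibble(
  transcript_id = tx$transcript_id, family = tx$family,
  fpkm_C1D = fpkm_c, fpkm_A1D = fpkm_c * fold,
  status = classify_transcript_status(fpkm_c, fpkm_c * fold))
readr::write_tsv(statuses, file.path(out, "transcript_status.tsv"))

report <- build_report(de[de$class == "phasiRNA", ], sites,
                       statuses[, c("transcript_id", "family", "status")])
readr::write_tsv(report, file.path(out, "phasi_target_report.tsv"))

down <- aggregate_direction_sums(report, "down")
up <- aggregate_direction_sums(report, "up")
cat(nrow(sites), "sites scanned,", sum(sites$passes), "passing;",
    "report rows:", nrow(report), "\n")
cat(sprintf("down-regulated phasiRNAs targeting R genes: %d, RPM %.1f -> %.1f\n",
            down$n_phasirnas, down$c1d, down$a1d))
cat(sprintf("up-regulated:   %d, RPM %.1f -> %.1f\n",
            up$n_phasirnas, up$c1d, up$a1d))
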