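#!/usr/bin/env Rscript
# Stage 6: reproduce the published aggregate statistics from the
# packaged reference tables of the tomato ABA experiment — the
# per-direction abundance sums of stress-related phasiRNAs, the
# family-group counts, the three-class RPM shares, and the headline
# tRF declines.

suppressMessages(library(trfphas))
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tb <- phasirna_target_table()
r_fam <- c("NBS-LRR", "STK", "RLK")
sums <- dplyr::bind_rows(aggregate_direction_sums(tb, "down", r_fam),
                         aggregate_direction_sums(tb, "up", r_fam))
readr::write_tsv(sums, file.path(out, "reference_direction_sums.tsv"))

counts <- count_target_families(tb)
shares <- class_share_summary(srna_class_totals())
declines <- rpm_change(trf_expression_summary())
readr::write_tsv(shares, file.path(out, "reference_class_shares.tsv"))
readr::write_tsv(declines, file.path(out, "reference_trf_declines.tsv"))

cat("stress-related phasiRNAs:", counts$n_phasirnas,
    "| targeting R genes:", counts$n_targeting_r_genes,
    "| targeting TFs:", counts$n_targeting_tfs, "\n")
cat(sprintf("down (R-gene targets): %.2f -> %.2f RPM (delta %.2f)\n",
            sums$c1d[1], sums$a1d[1], sums$delta[1]))
cat(sprintf("up   (R-gene targets): %.2f -> %.2f RPM (delta %.2f)\n",
            sums$c1d[2], sums$a1d[2], sums$delta[2]))
cat(sprintf("tRF share C1D: %.2f%% | phasiRNA share A1D: %.2f%%\n",
            shares$share_pct[shares$library == "C1D" &
                               shares$class == "tRF"],
            shares$share_pct[shares$library == "A1D" &
                               shares$class == "phasiRNA"]))
cat(sprintf("dominant Ala tRF decline: %.2f RPM; down-regulated tRF total decline: %.2f RPM\n",
            declines$decline[declines$label == "ENSRNA049443699:1-20"],
            declines$decline[declines$label == "down_regulated_total"]))
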