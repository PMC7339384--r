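#!/usr/bin/env Rscript
# Stage 4: joint normalization of tRF + phasiRNA + miRNA reads to RPM,
# Audic-Claverie p-values on the raw counts, response tiers, the 2-RPM
# noise filter for tRFs and the 10-RPM reporting filter.

suppressMessages(library(trfphas))
out <- "results"

trfs <- readr::read_tsv(file.path(out, "trf_table.tsv"),
                        col_types = readr::cols())
phas <- readr::read_tsv(file.path(out, "phasirnas.tsv"),
                        col_types = readr::cols())
mirna_tab <- readr::read_tsv("results/synthetic/mirna_totals.tsv",
                             col_types = "ci")
mirna <- setNames(mirna_tab$reads, mirna_tab$library)

counts <- dplyr::bind_rows(
  tibble::tibble(item_id = trfs$trf_id, class = "tRF",
                 C1D = trfs$count_C1D, A1D = trfs$count_A1D),
  tibble::tibble(item_id = phas$phasirna_id, class = "phasiRNA",
                 C1D = phas$count_C1D, A1D = phas$count_A1D))

de <- diffexp_table(counts, mirna)
de_trf <- filter_low_trfs(de[de$class == "tRF", ])
de_all <- dplyr::bind_rows(de_trf, de[de$class == "phasiRNA", ])
readr::write_tsv(de_all, file.path(out, "diffexp.tsv"))
readr::write_tsv(reporting_filter(de_all),
                 file.path(out, "diffexp_reported.tsv"))

# class-level RPM totals and shares, the three-class view of the data
totals <- dplyr::bind_rows(
  de |>
    dplyr::group_by(class) |>
    dplyr::summarise(C1D = sum(rpm_C1D), A1D = sum(rpm_A1D)),
  tibble::tibble(class = "miRNA",
                 C1D = normalize_rpm(mirna[["C1D"]],
                                     sum(counts$C1D) + mirna[["C1D"]]),
                 A1D = normalize_rpm(mirna[["A1D"]],
                                     sum(counts$A1D) + mirna[["A1D"]]))) |>
  tidyr::pivot_longer(c("C1D", "A1D"), names_to = "library",
                      values_to = "rpm")
shares <- class_share_summary(totals)
readr::write_tsv(shares, file.path(out, "class_shares.tsv"))

n_resp <- sum(de_all$tier %in% c("up", "down"))
cat(nrow(de_all), "features after the noise filter;", n_resp,
    "responsive (", sum(de_all$tier == "up"), "up /",
    sum(de_all$tier == "down"), "down ),",
    sum(de_all$significant), "significant at |log2FC| >= 1\n")
print(as.data.frame(shares))
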