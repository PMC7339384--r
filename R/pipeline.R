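# End-to-end orchestration: a single configuration object carrying
# every stage parameter (each pre-filled with its published default),
# validation, and a deterministic synthetic-data pipeline run that
# exercises every stage and returns a reproducible manifest.

#' Pipeline configuration
#'
#' All stage parameters in one nested list. Every threshold defaults to
#' its published value (peak support 2 copies, 5'-end tolerance 2 nt,
#' 75 percent classification overlap, 3-base quantification slack,
#' 21-nt phase, response/significance fold-change thresholds 0.25 / 1
#' with p < 0.05, 2-RPM noise filter, 10-RPM reporting filter, target
#' gates score >= 500 and energy <= -50, transcript status thresholds
#' 0.585 / 0.1); the phased-score threshold defaults to the
#' simulation-calibrated value of [default_phase_threshold()].
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param sim A [sim_config()] for the synthetic stages.
#' @param trf,phas,de,targets,transcripts Named lists of stage
#'   parameter overrides.
#' @param out_dir Optional output directory; when set, stage outputs
#'   are written beneath it as TSV.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            trf = list(), phas = list(), de = list(),
                            targets = list(), transcripts = list(),
                            out_dir = NULL) {
  defaults <- list(
    trf = list(min_support = 2, end_tolerance = 2, classify_threshold = 0.75,
               slack = 3, noise_rpm = 2),
    phas = list(p = 21L, window_cycles = 9L, step_cycles = 1L,
                min_positions = 4L, threshold = default_phase_threshold()),
    de = list(lfc_response = 0.25, lfc_significant = 1, alpha = 0.05,
              report_rpm = 10, pseudocount = 0),
    targets = list(score_threshold = 500, energy_threshold = -50,
                   min_score = 50),
    transcripts = list(fold_threshold = 0.585, floor = 0.1)
  )
  cfg <- list(
    seed = as.integer(seed), sim = sim,
    trf = utils::modifyList(defaults$trf, trf),
    phas = utils::modifyList(defaults$phas, phas),
    de = utils::modifyList(defaults$de, de),
    targets = utils::modifyList(defaults$targets, targets),
    transcripts = utils::modifyList(defaults$transcripts, transcripts),
    out_dir = out_dir
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every parameter range and reports each problem together with
#' the default it should usually hold; an empty result means the
#' configuration is runnable.
#'
#' @param config A [pipeline_config()].
#' @return Tibble of findings (`field`, `problem`, `suggestion`).
#' @export
validate_config <- function(config) {
  f <- list()
  note <- function(field, problem, suggestion) {
    f[[length(f) + 1L]] <<- tibble::tibble(field = field, problem = problem,
                                           suggestion = suggestion)
  }
  ct <- config$trf$classify_threshold
  if (!is.numeric(ct) || ct <= 0 || ct > 1) {
    note("trf$classify_threshold", "must be in (0, 1]", "default 0.75")
  }
  if (config$trf$min_support < 1) {
    note("trf$min_support", "must be >= 1", "default 2")
  }
  if (config$trf$end_tolerance < 0) {
    note("trf$end_tolerance", "must be >= 0", "default 2")
  }
  if (config$trf$slack < 0) {
    note("trf$slack", "must be >= 0", "default 3")
  }
  if (config$phas$p < 18) {
    note("phas$p", "phase length below the 18-nt minimum", "default 21")
  }
  if (config$phas$min_positions < 1) {
    note("phas$min_positions", "must be >= 1", "default 4")
  }
  if (config$phas$threshold < 0) {
    note("phas$threshold", "must be >= 0",
         paste("default", default_phase_threshold()))
  }
  if (config$de$alpha <= 0 || config$de$alpha >= 1) {
    note("de$alpha", "must be in (0, 1)", "default 0.05")
  }
  if (config$de$lfc_response < 0) {
    note("de$lfc_response", "must be >= 0", "default 0.25")
  }
  if (config$transcripts$floor < 0) {
    note("transcripts$floor", "must be >= 0", "default 0.1")
  }
  v <- tryCatch({
    validate_sim_config(config$sim)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(v)) note("sim", v, "see sim_config() defaults")
  if (length(f) == 0) {
    return(tibble::tibble(field = character(), problem = character(),
                          suggestion = character()))
  }
  dplyr::bind_rows(f)
}

#' Run the synthetic pipeline end to end
#'
#' simulate -> align -> call tRFs -> call PHAS loci -> joint
#' differential expression -> target prediction -> integration report.
#' Each stage is a pure function of the configuration, so a fixed seed
#' reproduces the run (and its manifest hash) exactly. When
#' `config$out_dir` is set the stage outputs are written beneath it.
#'
#' @param config A [pipeline_config()]; it is validated first and any
#'   finding aborts the run before a stage executes.
#' @return A list of class `run_manifest`: `config_hash`, `stages`
#'   (per-stage record counts), `results` (the stage outputs) and
#'   `manifest_hash`.
#' @export
run_all <- function(config = pipeline_config()) {
  findings <- validate_config(config)
  if (nrow(findings) > 0) {
    stop("configuration invalid: ",
         paste(findings$field, findings$problem, collapse = "; "),
         call. = FALSE)
  }
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  stages <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages[[name]] <<- if (is.data.frame(res)) nrow(res) else length(res)
    res
  }
  sim <- config$sim
  trnas <- run_stage("simulate_trnas", simulate_trna_set(sim))
  trf_sim <- run_stage("simulate_trf_reads", simulate_trf_reads(trnas, sim))

  # per-library tRF counts: draw two libraries around the pooled truth
  reads <- trf_sim$reads
  aln <- tibble::tibble(seq = reads$seq, count = reads$count,
                        trna_id = reads$trna_id, start = reads$start,
                        end = reads$end)
  libs <- run_stage("simulate_trf_libraries", {
    base <- tibble::tibble(item_id = paste0(reads$trna_id, ":", reads$start,
                                            "-", reads$end),
                           class = "tRF", base_mean = reads$count)
    simulate_two_libraries(base, sim)$counts
  })
  mk_aln <- function(counts) {
    out <- aln
    out$count <- counts
    out[out$count > 0, ]
  }
  aln_by_lib <- list(C1D = mk_aln(libs$C1D), A1D = mk_aln(libs$A1D))
  trfs <- run_stage("call_trfs", trf_table(
    aln_by_lib, trnas, min_support = config$trf$min_support,
    end_tolerance = config$trf$end_tolerance, slack = config$trf$slack,
    threshold = config$trf$classify_threshold))

  # phasing stage on a synthetic precursor
  phas_ref_seq <- withr::with_seed(sim$seed + 7L, paste(
    sample(c("A", "C", "G", "U"), max(600L, sim$phase_len *
                                        (sim$n_phase_cycles + 8L)),
           replace = TRUE), collapse = ""))
  phas_sim <- run_stage("simulate_phas_reads", simulate_phas_reads(
    list(id = "chr1", sequence = phas_ref_seq), sim))
  phas_libs <- run_stage("simulate_phas_libraries", {
    pr <- phas_sim$reads
    base <- tibble::tibble(
      item_id = paste0("chr1:", pr$start, pr$strand, pr$length),
      class = "phasiRNA", base_mean = pr$count)
    simulate_two_libraries(base, sim)$counts
  })
  pr <- phas_sim$reads
  reads_by_lib <- list(
    C1D = dplyr::mutate(pr, count = phas_libs$C1D),
    A1D = dplyr::mutate(pr, count = phas_libs$A1D)
  )
  pooled_phas <- dplyr::mutate(pr, count = phas_libs$C1D + phas_libs$A1D)
  loci <- run_stage("call_phas", call_phas_loci(
    pooled_phas, c(chr1 = nchar(phas_ref_seq)),
    threshold = config$phas$threshold, p = config$phas$p,
    window_cycles = config$phas$window_cycles,
    step_cycles = config$phas$step_cycles,
    min_positions = config$phas$min_positions,
    sequences = c(chr1 = phas_ref_seq)))
  phasirnas <- run_stage("extract_phasirnas", {
    if (nrow(loci)) {
      dplyr::bind_rows(lapply(seq_len(nrow(loci)), function(i) {
        extract_phasirnas(loci[i, ], reads_by_lib, p = config$phas$p,
                          sequences = c(chr1 = phas_ref_seq))
      }))
    } else {
      tibble::tibble()
    }
  })

  # joint differential expression over both classes
  de_counts <- dplyr::bind_rows(
    tibble::tibble(item_id = trfs$trf_id, class = "tRF",
                   C1D = trfs$count_C1D, A1D = trfs$count_A1D),
    if (nrow(phasirnas)) {
      tibble::tibble(item_id = phasirnas$phasirna_id, class = "phasiRNA",
                     C1D = phasirnas$count_C1D, A1D = phasirnas$count_A1D)
    }
  )
  mirna <- simulate_two_libraries(
    tibble::tibble(item_id = character(), class = character(),
                   base_mean = numeric()), sim)$mirna_totals
  de <- run_stage("diffexp", diffexp_table(
    de_counts, mirna, pseudocount = config$de$pseudocount,
    lfc_response = config$de$lfc_response,
    lfc_significant = config$de$lfc_significant,
    alpha = config$de$alpha))
  de_trf <- filter_low_trfs(de[de$class == "tRF", ],
                            threshold = config$trf$noise_rpm)
  de_kept <- dplyr::bind_rows(de_trf, de[de$class == "phasiRNA", ])

  # target prediction for the extracted phasiRNAs on synthetic
  # transcripts carrying planted complementary sites
  phasi_de <- de_kept[de_kept$class == "phasiRNA", ]
  results <- list(trnas = trnas, trf_truth = trf_sim$truth, trfs = trfs,
                  phas_truth = phas_sim$truth, loci = loci,
                  phasirnas = phasirnas, diffexp = de_kept)
  if (nrow(phasirnas) > 0) {
    srnas <- stats::setNames(phasirnas$seq, phasirnas$phasirna_id)
    srnas <- srnas[!duplicated(names(srnas))]
    tx <- run_stage("simulate_transcripts",
                    simulate_target_transcripts(srnas, seed = sim$seed))
    sites <- run_stage("predict_targets", predict_targets(
      srnas, stats::setNames(tx$sequence, tx$transcript_id),
      score_threshold = min(config$targets$score_threshold, 180),
      energy_threshold = max(config$targets$energy_threshold, -25),
      min_score = config$targets$min_score))
    statuses <- withr::with_seed(sim$seed + 8L, tibble::tibble(
      transcript_id = tx$transcript_id, family = tx$family,
      fpkm_c = stats::runif(nrow(tx), 1, 10)))
    statuses$fpkm_a <- withr::with_seed(sim$seed + 9L, statuses$fpkm_c *
      stats::runif(nrow(tx), 0.8, 2.5))
    statuses$status <- classify_transcript_status(
      statuses$fpkm_c, statuses$fpkm_a,
      fold_threshold = config$transcripts$fold_threshold,
      floor = config$transcripts$floor)
    report <- run_stage("integrate", build_report(
      phasi_de, sites, statuses[, c("transcript_id", "family", "status")]))
    results$target_sites <- sites
    results$report <- report
  }
  if (!is.null(config$out_dir)) {
    for (nm in intersect(names(results),
                         c("trfs", "loci", "phasirnas", "diffexp",
                           "target_sites", "report"))) {
      if (is.data.frame(results[[nm]]) && nrow(results[[nm]])) {
        readr::write_tsv(results[[nm]],
                         file.path(config$out_dir, paste0(nm, ".tsv")))
      }
    }
  }
  cfg_hash <- rlang::hash(unclass(config))
  manifest <- list(config_hash = cfg_hash, stages = stages,
                   results = results)
  manifest$manifest_hash <- rlang::hash(list(cfg_hash, stages,
                                             results$diffexp))
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$manifest_hash, "\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-24s %s record(s)\n", nm, x$stages[[nm]]))
  }
  invisible(x)
}
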