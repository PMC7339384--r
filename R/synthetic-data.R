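# Synthetic-data generator: tRNA references, cleavage-biased tRF read
# sets, phased 21-nt read ladders, and two-condition count libraries,
# each with a planted ground truth so every downstream stage can be
# tested against known answers.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults
#' emulate the two-library tomato leaf design the package targets: a
#' control library (`C1D`) and an ABA-treated library (`A1D`), each a
#' single mixed-sample library, with a dominant 20-nt 5' tRF population
#' cleaved at a 5'-terminal guanine and a D-loop uracil, 21-nt phased
#' read ladders on resistance-gene-like precursors, unphased background
#' noise, and a miRNA read block that dominates the joint normalization
#' denominator (about 83 percent of the library).
#'
#' @param seed Integer seed; identical configs (including seed) give
#'   byte-identical outputs.
#' @param n_trnas Number of tRNA genes to simulate.
#' @param trf_cleavage_profile Data frame with columns `start`, `end`
#'   (0-based half-open intervals on the tRNA) and `prob`; probabilities
#'   must sum to 1. The default puts 80 percent of cleavage on the
#'   canonical 20-nt 5' fragment and the rest on 19/22-nt variants
#'   sharing the same 5' end.
#' @param phase_len Phase length in nt (>= 18; 21 for the phasiRNAs
#'   modelled here, 24 supported).
#' @param n_phase_cycles Number of phased positions planted per locus.
#' @param noise_fraction Fraction of read copies drawn from the uniform
#'   background, in `[0, 1]`.
#' @param depth_per_library Total read copies per simulated library.
#' @param condition_effects Named numeric vector of multiplicative
#'   treatment/control fold changes, keyed by truth item id. Must be
#'   non-negative.
#' @param dispersion Negative-binomial overdispersion of library counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param antisense_fraction Fraction of phased cycles populated on the
#'   antisense strand (2-nt offset convention).
#' @param mirna_depth Per-library miRNA read total; miRNAs are never
#'   simulated read-by-read because the pipeline only consumes their
#'   total through the normalization denominator.
#' @param ala_weight Abundance multiplier for tRNA-Ala genes, producing
#'   the Ala-dominated tRF population seen in leaf libraries.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_trnas = 20L,
                       trf_cleavage_profile = default_cleavage_profile(),
                       phase_len = 21L,
                       n_phase_cycles = 10L,
                       noise_fraction = 0.1,
                       depth_per_library = 50000L,
                       condition_effects = numeric(0),
                       dispersion = 0.05,
                       antisense_fraction = 0.3,
                       mirna_depth = 830000L,
                       ala_weight = 10) {
  cfg <- list(seed = as.integer(seed), n_trnas = as.integer(n_trnas),
              trf_cleavage_profile = trf_cleavage_profile,
              phase_len = as.integer(phase_len),
              n_phase_cycles = as.integer(n_phase_cycles),
              noise_fraction = noise_fraction,
              depth_per_library = as.integer(depth_per_library),
              condition_effects = condition_effects,
              dispersion = dispersion,
              antisense_fraction = antisense_fraction,
              mirna_depth = as.integer(mirna_depth),
              ala_weight = ala_weight)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_cleavage_profile <- function() {
  data.frame(start = c(0L, 0L, 0L), end = c(20L, 22L, 19L),
             prob = c(0.8, 0.1, 0.1))
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  }
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  if (cfg$n_trnas < 1L) bad("n_trnas", "must be >= 1")
  pr <- cfg$trf_cleavage_profile
  if (!all(c("start", "end", "prob") %in% names(pr))) {
    bad("trf_cleavage_profile", "needs columns start, end, prob")
  }
  if (nrow(pr) == 0) bad("trf_cleavage_profile", "must be non-empty")
  if (abs(sum(pr$prob) - 1) > 1e-9) {
    bad("trf_cleavage_profile", "probabilities must sum to 1")
  }
  if (any(pr$start < 0) || any(pr$end <= pr$start)) {
    bad("trf_cleavage_profile", "intervals must be non-empty and >= 0")
  }
  if (any(pr$end - pr$start < 18) || any(pr$end - pr$start > 30)) {
    bad("trf_cleavage_profile", "fragment lengths must lie in 18-30 nt")
  }
  if (cfg$phase_len < 18L) bad("phase_len", "must be >= 18")
  if (cfg$noise_fraction < 0 || cfg$noise_fraction > 1) {
    bad("noise_fraction", "must lie in [0, 1]")
  }
  if (cfg$depth_per_library < 1L) bad("depth_per_library", "must be >= 1")
  if (length(cfg$condition_effects) &&
      (is.null(names(cfg$condition_effects)) ||
       any(!nzchar(names(cfg$condition_effects))))) {
    bad("condition_effects", "must be a named vector")
  }
  if (any(cfg$condition_effects < 0)) {
    bad("condition_effects", "effects must be non-negative")
  }
  if (cfg$dispersion < 0) bad("dispersion", "must be non-negative")
  if (cfg$antisense_fraction < 0 || cfg$antisense_fraction > 1) {
    bad("antisense_fraction", "must lie in [0, 1]")
  }
  invisible(cfg)
}

isotype_anticodons <- c(
  Ala = "AGC", Gly = "GCC", Val = "CAC", Ser = "GCU", Asp = "GUC",
  Glu = "UUC", Cys = "GCA", Pro = "UGG", Thr = "UGU", Trp = "CCA",
  His = "GUG", Leu = "CAA"
)

#' Simulate a set of tRNA genes with valid cloverleaf landmarks
#'
#' Sequences are random within fixed landmark geometry (7-bp acceptor
#' stem plus 2-nt linker, 4-bp D-stems around a 7-11-nt D-loop, 17-nt
#' anticodon arm, 6-23-nt variable loop, 17-nt T-arm, 7-nt 3' acceptor
#' side), giving lengths of 72-90 nt. Isotypes cycle through the common
#' amino acids starting with Ala; every tRNA-Ala starts with a guanine,
#' carries a uracil as the 20th base (inside the D-loop) and has a
#' D-loop ending at position 22, so its canonical 5' fragment is the
#' 20-nt G...U read observed to dominate leaf libraries.
#'
#' @param config A [sim_config()].
#' @return List of [trna_gene()] objects.
#' @export
simulate_trna_set <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    isos <- rep_len(names(isotype_anticodons), config$n_trnas)
    lapply(seq_len(config$n_trnas), function(i) {
      iso <- isos[i]
      dl <- if (iso == "Ala") 9L else sample(7:11, 1L)
      v <- sample(6:min(23L, 31L - dl), 1L)
      len <- 59L + dl + v
      s <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
      ac_loop_start <- 23L + dl
      s[(ac_loop_start + 3L):(ac_loop_start + 5L)] <-
        strsplit(isotype_anticodons[[iso]], "")[[1]]
      if (iso == "Ala") {
        s[1L] <- "G"
        s[20L] <- "U"
      }
      lm <- tibble::tibble(
        name = c("acc5", "d_arm", "ac_arm", "v_loop", "t_arm", "acc3"),
        start = as.integer(c(0L, 9L, 17L + dl, 35L + dl, 35L + dl + v,
                             52L + dl + v)),
        end = as.integer(c(9L, 17L + dl, 35L + dl, 35L + dl + v,
                           52L + dl + v, len))
      )
      trna_gene(sprintf("trna%03d-%s", i, iso), iso,
                isotype_anticodons[[iso]], paste(s, collapse = ""), lm,
                list(d_loop = c(13L, 13L + dl),
                     ac_loop = c(ac_loop_start, ac_loop_start + 7L),
                     t_loop = c(40L + dl + v, 47L + dl + v)))
    })
  })
}

#' Simulate cleavage-biased tRF reads with planted truth
#'
#' Read copies are drawn from a multinomial over planted cleavage
#' products (per-tRNA abundance weights times the cleavage-profile
#' probabilities, scaled by `1 - noise_fraction`) and a uniform
#' background of random 18-30-nt substrings (`noise_fraction`). Every
#' read is an exact substring of its source tRNA. The truth table
#' records each planted fragment with its interval and expected
#' structural type; the highest-probability fragment of each tRNA is
#' flagged `dominant`.
#'
#' @param trnas List of [trna_gene()] objects.
#' @param config A [sim_config()].
#' @return List with elements `reads` (tibble: `trna_id`, `start`,
#'   `end`, `seq`, `count`, `source`) and `truth` (tibble: `item_id`,
#'   `trna_id`, `start`, `end`, `expected_type`, `dominant`). Copy
#'   counts sum to `depth_per_library` exactly.
#' @export
simulate_trf_reads <- function(trnas, config) {
  validate_sim_config(config)
  profile <- config$trf_cleavage_profile
  lens <- vapply(trnas, function(g) nchar(g$sequence), integer(1))
  ids <- vapply(trnas, `[[`, character(1), "id")
  isos <- vapply(trnas, `[[`, character(1), "isotype")
  if (any(max(profile$end) > lens)) {
    stop("cleavage profile offsets exceed tRNA length for: ",
         paste(ids[max(profile$end) > lens], collapse = ", "), call. = FALSE)
  }
  withr::with_seed(config$seed + 1L, {
    w <- stats::rlnorm(length(trnas), 0, 1) *
      ifelse(isos == "Ala", config$ala_weight, 1)
    w <- w / sum(w)
    planted <- tibble::tibble(
      trna = rep(ids, each = nrow(profile)),
      start = rep(profile$start, length(trnas)),
      end = rep(profile$end, length(trnas)),
      prob = rep(w, each = nrow(profile)) * rep(profile$prob, length(trnas)) *
        (1 - config$noise_fraction),
      source = "planted",
      dominant = rep(profile$prob == max(profile$prob), length(trnas))
    )
    if (config$noise_fraction > 0) {
      # enough distinct noise categories that the background stays
      # diffuse (a few copies each) rather than forming spurious stacks
      k <- max(256L, as.integer(ceiling(
        config$depth_per_library * config$noise_fraction / 8)))
      nl <- sample(18:30, k, replace = TRUE)
      ntr <- sample(seq_along(trnas), k, replace = TRUE)
      nst <- vapply(seq_len(k), function(j) {
        sample.int(lens[ntr[j]] - nl[j] + 1L, 1L) - 1L
      }, integer(1))
      noise <- tibble::tibble(
        trna = ids[ntr], start = nst, end = nst + nl,
        prob = config$noise_fraction / k, source = "noise", dominant = FALSE
      )
      cats <- dplyr::bind_rows(planted, noise)
    } else {
      cats <- planted
    }
    cats <- cats[cats$prob > 0, ]
    counts <- as.vector(stats::rmultinom(1L, config$depth_per_library,
                                         cats$prob))
  })
  cats$count <- counts
  seqs <- stats::setNames(vapply(trnas, `[[`, character(1), "sequence"), ids)
  reads <- cats[cats$count > 0, ] |>
    dplyr::group_by(.data$trna, .data$start, .data$end) |>
    dplyr::summarise(count = sum(.data$count),
                     source = if (any(.data$source == "planted")) "planted"
                              else "noise",
                     .groups = "drop") |>
    dplyr::transmute(trna_id = .data$trna, start = .data$start,
                     end = .data$end,
                     seq = unname(substr(seqs[.data$trna], .data$start + 1L,
                                         .data$end)),
                     count = .data$count, source = .data$source)
  truth <- cats[cats$source == "planted", ]
  if (nrow(truth)) {
    parts <- lapply(trnas, partition_regions)
    names(parts) <- ids
    truth$expected_type <- vapply(seq_len(nrow(truth)), function(i) {
      paste(classify_trf(truth$start[i], truth$end[i],
                         parts[[truth$trna[i]]]), collapse = "+")
    }, character(1))
  } else {
    truth$expected_type <- character(0)
  }
  truth <- tibble::tibble(
    item_id = sprintf("%s:%d-%d", truth$trna, truth$start + 1L, truth$end),
    trna_id = truth$trna, start = truth$start, end = truth$end,
    expected_type = truth$expected_type, dominant = truth$dominant
  )
  list(reads = reads, truth = truth)
}

#' Simulate a phased 21-nt read ladder with background noise
#'
#' Plants sense-strand reads of length `phase_len` starting at
#' `register + k * phase_len` for `k = 0 .. n_phase_cycles - 1`; a
#' configurable fraction of cycles is populated on the antisense strand
#' instead, shifted 2 nt to the left (the Dicer 2-nt overhang
#' convention, so that antisense starts + 2 fall in the sense register).
#' Noise reads are uniform over positions with lengths 18-24 nt.
#'
#' @param reference List with `id` and `sequence`, or a single named
#'   character string.
#' @param config A [sim_config()].
#' @param register Phase register in `[0, phase_len)`; `NULL` draws one
#'   at random.
#' @return List with `reads` (tibble: `ref_id`, `start`, `end`,
#'   `strand`, `length`, `count`, `source`) and `truth` (tibble:
#'   `ref_id`, `register`, `start`, `end`, `n_cycles`).
#' @export
simulate_phas_reads <- function(reference, config, register = NULL) {
  validate_sim_config(config)
  if (is.character(reference)) {
    reference <- list(id = names(reference) %||% "ref1",
                      sequence = unname(reference))
  }
  len <- nchar(reference$sequence)
  p <- config$phase_len
  n_cyc <- config$n_phase_cycles
  if (n_cyc > 0 && len < p * n_cyc) {
    stop("reference '", reference$id, "' (", len, " nt) is shorter than ",
         "phase_len * n_phase_cycles = ", p * n_cyc, call. = FALSE)
  }
  withr::with_seed(config$seed + 2L, {
    if (n_cyc > 0) {
      if (is.null(register)) {
        register <- sample.int(min(p, len - p * n_cyc + 1L), 1L) - 1L
      }
      pos <- register + p * (seq_len(n_cyc) - 1L)
      minus <- stats::runif(n_cyc) < config$antisense_fraction & pos >= 2L
      planted <- tibble::tibble(
        start = ifelse(minus, pos - 2L, pos),
        strand = ifelse(minus, "-", "+"),
        length = p,
        prob = (1 - config$noise_fraction) *
          as.vector(stats::rlnorm(n_cyc, 0, 0.5)),
        source = "planted"
      )
      planted$prob <- planted$prob / sum(planted$prob) *
        (1 - config$noise_fraction)
    } else {
      register <- NA_integer_
      planted <- tibble::tibble(start = integer(), strand = character(),
                                length = integer(), prob = numeric(),
                                source = character())
    }
    if (config$noise_fraction > 0) {
      k <- max(128L, as.integer(ceiling(
        config$depth_per_library * config$noise_fraction / 4)))
      nl <- sample(18:24, k, replace = TRUE)
      nst <- vapply(nl, function(l) sample.int(len - l + 1L, 1L) - 1L,
                    integer(1))
      noise <- tibble::tibble(
        start = nst, strand = sample(c("+", "-"), k, replace = TRUE),
        length = nl, prob = config$noise_fraction / k, source = "noise"
      )
      cats <- dplyr::bind_rows(planted, noise)
    } else {
      cats <- planted
    }
    if (nrow(cats) == 0) {
      return(list(
        reads = tibble::tibble(ref_id = character(), start = integer(),
                               end = integer(), strand = character(),
                               length = integer(), count = integer(),
                               source = character()),
        truth = tibble::tibble(ref_id = character(), register = integer(),
                               start = integer(), end = integer(),
                               n_cycles = integer())
      ))
    }
    counts <- as.vector(stats::rmultinom(1L, config$depth_per_library,
                                         cats$prob))
  })
  cats$count <- counts
  reads <- cats[cats$count > 0, ] |>
    dplyr::group_by(.data$start, .data$strand, .data$length) |>
    dplyr::summarise(count = sum(.data$count),
                     source = if (any(.data$source == "planted")) "planted"
                              else "noise",
                     .groups = "drop") |>
    dplyr::transmute(ref_id = reference$id, start = .data$start,
                     end = .data$start + .data$length,
                     strand = .data$strand, length = .data$length,
                     count = .data$count, source = .data$source)
  truth <- if (n_cyc > 0) {
    tibble::tibble(ref_id = reference$id, register = as.integer(register),
                   start = as.integer(register),
                   end = as.integer(register + p * n_cyc),
                   n_cycles = n_cyc)
  } else {
    tibble::tibble(ref_id = character(), register = integer(),
                   start = integer(), end = integer(), n_cycles = integer())
  }
  list(reads = reads, truth = truth)
}

#' Simulate raw counts for a control and a treatment library
#'
#' Library 1 (`C1D`) counts are drawn around each item's base mean;
#' library 2 (`A1D`) around the base mean times the item's condition
#' effect (default 1). Counts are negative-binomial with the configured
#' overdispersion, Poisson at dispersion 0. miRNA reads are emitted only
#' as a per-library total, since the pipeline consumes them solely
#' through the joint normalization denominator.
#'
#' @param items Tibble with columns `item_id`, `class` and `base_mean`
#'   (expected C1D count).
#' @param config A [sim_config()]; `condition_effects` keys must be a
#'   subset of `items$item_id`.
#' @return List with `counts` (tibble: `item_id`, `class`, `C1D`,
#'   `A1D`) and `mirna_totals` (named vector `C1D`, `A1D`).
#' @export
simulate_two_libraries <- function(items, config) {
  validate_sim_config(config)
  eff <- config$condition_effects
  if (length(eff) && nrow(items) && !all(names(eff) %in% items$item_id)) {
    stop("condition_effects keys not in items: ",
         paste(setdiff(names(eff), items$item_id), collapse = ", "),
         call. = FALSE)
  }
  draw <- function(mu) {
    if (config$dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
  }
  withr::with_seed(config$seed + 3L, {
    if (nrow(items)) {
      fold <- rep(1, nrow(items))
      fold[match(names(eff), items$item_id)] <- eff
      counts <- tibble::tibble(
        item_id = items$item_id, class = items$class,
        C1D = draw(items$base_mean),
        A1D = draw(items$base_mean * fold)
      )
    } else {
      counts <- tibble::tibble(item_id = character(), class = character(),
                               C1D = integer(), A1D = integer())
    }
    mirna <- c(C1D = draw(config$mirna_depth), A1D = draw(config$mirna_depth))
  })
  list(counts = counts, mirna_totals = mirna)
}

#' Simulate target transcripts carrying planted phasiRNA sites
#'
#' Each small RNA gets `n_per_srna` transcripts consisting of a random
#' background with one embedded perfectly complementary site, labelled
#' with a gene-family name. Used to exercise target prediction and the
#' integration report on known truth.
#'
#' @param srnas Named character vector of 21-nt small RNA sequences.
#' @param seed Integer seed.
#' @param families Family labels to cycle through.
#' @param n_per_srna Transcripts per small RNA.
#' @param flank Background length on each side of the planted site.
#' @return Tibble with `transcript_id`, `srna_id`, `family`, `sequence`
#'   and `site_start` (0-based start of the planted site).
#' @export
simulate_target_transcripts <- function(srnas, seed = 1L,
                                        families = c("NBS-LRR", "STK", "RLK"),
                                        n_per_srna = 2L, flank = 60L) {
  withr::with_seed(seed + 4L, {
    rows <- list()
    k <- 0L
    for (sid in names(srnas)) {
      for (j in seq_len(n_per_srna)) {
        k <- k + 1L
        left <- paste(sample(c("A", "C", "G", "U"), flank, replace = TRUE),
                      collapse = "")
        right <- paste(sample(c("A", "C", "G", "U"), flank, replace = TRUE),
                       collapse = "")
        rows[[k]] <- tibble::tibble(
          transcript_id = sprintf("Synt%02dg%05d.1.1", k, k * 10L),
          srna_id = sid,
          family = families[(k - 1L) %% length(families) + 1L],
          sequence = paste0(left, rc_rna(srnas[[sid]]), right),
          site_start = flank
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Reverse-complement an RNA sequence
#' @param x RNA string (`ACGU`).
#' @return The reverse complement.
#' @export
rc_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
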