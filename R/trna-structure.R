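# tRNA cloverleaf representation and the five tRF source regions.
#
# Coordinates are 0-based half-open everywhere inside the package; all
# human-facing output (ids, TSV/BED writers) is converted at the boundary
# (1-based inclusive ids, 0-based half-open BED).

#' Construct a tRNA gene with cloverleaf landmarks
#'
#' A `trna_gene` holds a mature tRNA sequence together with the six
#' cloverleaf landmark intervals (5' acceptor-stem side, D-arm,
#' anticodon arm, variable loop, T-arm, 3' acceptor-stem side) and the
#' three loop sub-intervals needed to derive tRF source regions.
#' Landmarks partition `[0, nchar(sequence))`: any linker nucleotides are
#' folded into the downstream arm, so the six intervals are contiguous,
#' ordered and non-overlapping.
#'
#' @param id Gene identifier.
#' @param isotype Amino-acid isotype code (e.g. `"Ala"`). `"His"` is a
#'   valid input isotype even though 5' tRFs from it may be absent in
#'   real libraries.
#' @param anticodon Anticodon 3-mer (RNA alphabet).
#' @param sequence RNA sequence (`A`/`C`/`G`/`U`), 72-90 nt.
#' @param landmarks Tibble with columns `name`, `start`, `end`
#'   (0-based half-open) and rows named `acc5`, `d_arm`, `ac_arm`,
#'   `v_loop`, `t_arm`, `acc3` in 5'-to-3' order.
#' @param loops Named list of `c(start, end)` pairs for `d_loop`,
#'   `ac_loop` and `t_loop`.
#' @return An object of class `trna_gene`.
#' @export
trna_gene <- function(id, isotype, anticodon, sequence, landmarks, loops) {
  stopifnot(is.character(id), length(id) == 1L)
  len <- nchar(sequence)
  if (len < 72 || len > 90) {
    stop("tRNA '", id, "' has length ", len, "; expected 72-90 nt",
         call. = FALSE)
  }
  if (grepl("[^ACGU]", sequence)) {
    stop("tRNA '", id, "' contains non-ACGU characters", call. = FALSE)
  }
  required <- c("acc5", "d_arm", "ac_arm", "v_loop", "t_arm", "acc3")
  if (!identical(landmarks$name, required)) {
    stop("landmarks must be exactly ", paste(required, collapse = ", "),
         " in 5'->3' order", call. = FALSE)
  }
  if (landmarks$start[1] != 0L || landmarks$end[6] != len) {
    stop("landmarks must cover [0, ", len, ")", call. = FALSE)
  }
  if (any(landmarks$start[-1] != landmarks$end[-6])) {
    stop("landmarks must be contiguous (linkers fold into the downstream arm)",
         call. = FALSE)
  }
  if (any(landmarks$end <= landmarks$start)) {
    stop("landmark intervals must be non-empty", call. = FALSE)
  }
  for (lp in c("d_loop", "ac_loop", "t_loop")) {
    iv <- loops[[lp]]
    if (is.null(iv) || length(iv) != 2L || iv[1] >= iv[2]) {
      stop("loop interval '", lp, "' missing or empty", call. = FALSE)
    }
  }
  arm_of <- function(lp, arm) {
    a <- landmarks[landmarks$name == arm, ]
    iv <- loops[[lp]]
    iv[1] >= a$start && iv[2] <= a$end
  }
  if (!arm_of("d_loop", "d_arm") || !arm_of("ac_loop", "ac_arm") ||
      !arm_of("t_loop", "t_arm")) {
    stop("loop intervals must lie within their arms", call. = FALSE)
  }
  structure(
    list(id = id, isotype = isotype, anticodon = anticodon,
         sequence = sequence, landmarks = landmarks,
         loops = lapply(loops[c("d_loop", "ac_loop", "t_loop")], as.integer)),
    class = "trna_gene"
  )
}

#' @export
print.trna_gene <- function(x, ...) {
  cat(sprintf("<trna_gene> %s tRNA-%s (%s), %d nt\n",
              x$id, x$isotype, x$anticodon, nchar(x$sequence)))
  lm <- x$landmarks
  cat(paste0("  ", lm$name, " [", lm$start, ",", lm$end, ")",
             collapse = "\n"), "\n")
  invisible(x)
}

landmark_value <- function(gene, name, field) {
  lm <- gene$landmarks
  lm[[field]][lm$name == name]
}

#' Derive the five tRF source regions of a tRNA
#'
#' Partitions a tRNA into the five structural source regions used for
#' tRF classification: `5e` (5' end), `D` (D-arm), `A` (anticodon arm),
#' `V` (variable loop) and `3e` (3' end). The 5e region runs from the
#' tRNA start to the third-from-last base of the D-loop, so that a tRNA
#' whose D-loop ends at position 22 yields the canonical 20-nt 5e
#' region. Adjacent regions deliberately overlap by a few nucleotides
#' (the "long intersection" zones), which is what allows a fragment
#' falling into an intersection to carry two type labels.
#'
#' Region bounds (0-based half-open, `flank` defaults to 2):
#' * `5e` = `[0, d_loop_end - 2)`
#' * `D`  = `[d_loop_start - flank, ac_arm_start + flank)`
#' * `A`  = `[ac_arm_start - flank, ac_arm_end + flank)`
#' * `V`  = `[v_loop_start - flank, t_loop_start + 2 + flank)`
#' * `3e` = `[t_loop_start + 2, len)`
#'
#' The V region extends to two bases past the 3e anchor so that the five
#' regions always cover the whole tRNA; every position belongs to one
#' or two regions, never three.
#'
#' @param gene A [trna_gene()].
#' @param flank Width of the overlap flanks around region junctions.
#' @return A tibble of class `region_partition` with columns `region`,
#'   `start`, `end` and attributes `trna_id` and `trna_length`.
#' @export
partition_regions <- function(gene, flank = 2L) {
  stopifnot(inherits(gene, "trna_gene"))
  len <- nchar(gene$sequence)
  d_loop <- gene$loops$d_loop
  t_loop <- gene$loops$t_loop
  ac_start <- landmark_value(gene, "ac_arm", "start")
  ac_end <- landmark_value(gene, "ac_arm", "end")
  v_start <- landmark_value(gene, "v_loop", "start")
  anchor3 <- t_loop[1] + 2L
  regions <- tibble::tibble(
    region = c("5e", "D", "A", "V", "3e"),
    start = as.integer(c(0L, max(0L, d_loop[1] - flank), ac_start - flank,
                         v_start - flank, anchor3)),
    end = as.integer(c(d_loop[2] - 2L, ac_start + flank, ac_end + flank,
                       anchor3 + flank, len))
  )
  if (any(diff(regions$start) < 0) || any(regions$end <= regions$start)) {
    stop("landmarks of '", gene$id, "' are out of order; cannot partition",
         call. = FALSE)
  }
  if (any(regions$start[-1] > regions$end[-5])) {
    stop("regions of '", gene$id, "' do not cover the tRNA", call. = FALSE)
  }
  structure(regions, class = c("region_partition", class(regions)),
            trna_id = gene$id, trna_length = len)
}

#' Parse tRNA references into `trna_gene` objects
#'
#' Reads one of three dialects:
#' * `"ss"`: tRNAscan-SE secondary-structure output. Only the header
#'   line, the `Type:` line, the `Seq:` line and the `Str:` line of each
#'   block are consumed; scores are ignored. Landmarks are inferred from
#'   the paired (`>`/`<`) and loop (`.`) runs of the structure string,
#'   assuming the standard four-arm cloverleaf.
#' * `"tsv"`: the simplified tabular dialect written by
#'   [write_trna_tsv()] (explicit landmark and loop coordinates).
#'
#' Records whose landmarks cannot be inferred are reported with their
#' line numbers and skipped, never silently dropped.
#'
#' @param path Path to the input file (or a character vector of lines
#'   via `text`).
#' @param dialect `"ss"` or `"tsv"`.
#' @param text Optional character vector of input lines, used instead of
#'   `path`.
#' @return A list of [trna_gene()] objects. Failed records are attached
#'   as attribute `"failures"` (tibble with `line` and `message`).
#' @export
parse_trnascan <- function(path = NULL, dialect = c("ss", "tsv"),
                           text = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(text)) {
    text <- readLines(path, warn = FALSE)
  }
  if (length(text) == 0 || all(!nzchar(trimws(text)))) {
    warning("empty tRNA reference; returning no genes", call. = FALSE)
    return(structure(list(), failures = tibble::tibble(
      line = integer(), message = character())))
  }
  if (dialect == "tsv") parse_trna_tsv(text) else parse_trna_ss(text)
}

parse_trna_ss <- function(lines) {
  headers <- grep("Length:", lines)
  genes <- list()
  failures <- list()
  for (h in headers) {
    res <- tryCatch(parse_ss_block(lines, h), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble::tibble(line = h, message = conditionMessage(res))
    } else {
      genes[[length(genes) + 1L]] <- res
    }
  }
  failures <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(line = integer(), message = character())
  if (nrow(failures)) {
    message(nrow(failures), " tRNA record(s) failed landmark inference; ",
            "see attr(, 'failures')")
  }
  structure(genes, failures = failures)
}

parse_ss_block <- function(lines, h) {
  id <- sub("\\s.*$", "", trimws(lines[h]))
  block <- lines[h:min(h + 6L, length(lines))]
  type_line <- grep("^Type:", trimws(block), value = TRUE)
  seq_line <- grep("^Seq:", trimws(block), value = TRUE)
  str_line <- grep("^Str:", trimws(block), value = TRUE)
  if (!length(seq_line) || !length(str_line)) {
    stop("block lacks Seq:/Str: lines")
  }
  isotype <- "Und"
  anticodon <- "NNN"
  if (length(type_line)) {
    isotype <- sub("^Type:\\s*(\\S+).*$", "\\1", type_line[1])
    ac <- regmatches(type_line[1],
                     regexpr("Anticodon:\\s*\\S+", type_line[1]))
    if (length(ac)) anticodon <- sub("Anticodon:\\s*", "", ac)
  }
  seq <- gsub("T", "U", toupper(sub("^Seq:\\s*", "", trimws(seq_line[1]))))
  str <- sub("^Str:\\s*", "", trimws(str_line[1]))
  if (nchar(seq) != nchar(str)) stop("Seq/Str length mismatch")
  lm <- landmarks_from_structure(str)
  trna_gene(id, isotype, gsub("T", "U", toupper(anticodon)), seq,
            lm$landmarks, lm$loops)
}

# Infer cloverleaf landmarks from a dot-bracket-like structure string
# (">" 5' side of a stem, "<" 3' side, "." unpaired), assuming the
# standard acceptor / D-arm / anticodon-arm / T-arm architecture.
landmarks_from_structure <- function(str) {
  chars <- strsplit(chartr("()", "><", str), "")[[1]]
  n <- length(chars)
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble::tibble(char = r$values, start = starts - 1L, end = ends)
  open <- which(runs$char == ">")
  close <- which(runs$char == "<")
  # the T-stem and acceptor-stem "<" characters usually merge into one
  # run, so three close runs suffice
  if (length(open) < 4 || length(close) < 3) {
    stop("structure string lacks the four cloverleaf stems")
  }
  # Arms: the D, anticodon and T stem-loops are the 2nd..4th ">" runs
  # (run 1 opens the acceptor stem); their loops are the "." runs between
  # an open run and the next close run. A close run can merge with the
  # following stem's close characters (the T-stem and acceptor-stem "<"
  # runs are contiguous in tRNAscan-SE output), so only the stem-width
  # prefix of the close run belongs to the arm.
  arm <- function(k) {
    o <- open[k]
    width <- runs$end[o] - runs$start[o]
    cl <- close[close > o][1]
    if (is.na(cl)) stop("unbalanced stem in structure string")
    dots <- which(runs$char == "." & seq_along(runs$char) > o &
                    seq_along(runs$char) < cl)
    if (!length(dots)) stop("stem without a loop in structure string")
    close_len <- runs$end[cl] - runs$start[cl]
    list(start = runs$start[o],
         end = runs$start[cl] + min(width, close_len),
         loop = c(runs$start[dots[1]], runs$end[dots[length(dots)]]))
  }
  d <- arm(2)
  ac <- arm(3)
  t <- arm(length(open))
  acc3_start <- t$end
  lm <- tibble::tibble(
    name = c("acc5", "d_arm", "ac_arm", "v_loop", "t_arm", "acc3"),
    start = as.integer(c(0L, d$start, d$end, ac$end, t$start, acc3_start)),
    end = as.integer(c(d$start, d$end, ac$end, t$start, acc3_start, n))
  )
  if (lm$start[4] >= lm$end[4]) {
    stop("no variable loop between anticodon arm and T-arm")
  }
  list(landmarks = lm,
       loops = list(d_loop = d$loop, ac_loop = ac$loop, t_loop = t$loop))
}

trna_tsv_columns <- c(
  "id", "isotype", "anticodon", "seq",
  "d_arm_start", "ac_arm_start", "v_loop_start", "t_arm_start", "acc3_start",
  "d_loop_start", "d_loop_end", "ac_loop_start", "ac_loop_end",
  "t_loop_start", "t_loop_end"
)

parse_trna_tsv <- function(lines) {
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(trna_tsv_columns, names(df))
  if (length(missing)) {
    stop("simplified tRNA TSV lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  genes <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    len <- nchar(row$seq)
    lm <- tibble::tibble(
      name = c("acc5", "d_arm", "ac_arm", "v_loop", "t_arm", "acc3"),
      start = as.integer(c(0L, row$d_arm_start, row$ac_arm_start,
                           row$v_loop_start, row$t_arm_start,
                           row$acc3_start)),
      end = as.integer(c(row$d_arm_start, row$ac_arm_start, row$v_loop_start,
                         row$t_arm_start, row$acc3_start, len))
    )
    genes[[i]] <- trna_gene(
      row$id, row$isotype, row$anticodon, row$seq, lm,
      list(d_loop = c(row$d_loop_start, row$d_loop_end),
           ac_loop = c(row$ac_loop_start, row$ac_loop_end),
           t_loop = c(row$t_loop_start, row$t_loop_end))
    )
  }
  structure(genes,
            failures = tibble::tibble(line = integer(), message = character()))
}

#' Write tRNA genes to the simplified TSV dialect
#'
#' Columns are the gene id, isotype, anticodon, sequence, the five
#' internal landmark boundaries and the three loop intervals (all
#' 0-based). [parse_trnascan()] with `dialect = "tsv"` round-trips this
#' format losslessly.
#'
#' @param genes List of [trna_gene()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trna_tsv <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    tibble::tibble(
      id = g$id, isotype = g$isotype, anticodon = g$anticodon,
      seq = g$sequence,
      d_arm_start = landmark_value(g, "d_arm", "start"),
      ac_arm_start = landmark_value(g, "ac_arm", "start"),
      v_loop_start = landmark_value(g, "v_loop", "start"),
      t_arm_start = landmark_value(g, "t_arm", "start"),
      acc3_start = landmark_value(g, "acc3", "start"),
      d_loop_start = g$loops$d_loop[1], d_loop_end = g$loops$d_loop[2],
      ac_loop_start = g$loops$ac_loop[1], ac_loop_end = g$loops$ac_loop[2],
      t_loop_start = g$loops$t_loop[1], t_loop_end = g$loops$t_loop[2]
    )
  })
  readr::write_tsv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' Write tRF source regions as BED
#'
#' tRNA-local coordinates, 0-based half-open, one line per region with
#' the region label in the name column.
#'
#' @param partitions A `region_partition` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(partitions, path) {
  if (inherits(partitions, "region_partition")) partitions <- list(partitions)
  rows <- lapply(partitions, function(p) {
    tibble::tibble(chrom = attr(p, "trna_id"), start = p$start, end = p$end,
                   name = p$region)
  })
  readr::write_tsv(dplyr::bind_rows(rows), path, col_names = FALSE)
  invisible(path)
}
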