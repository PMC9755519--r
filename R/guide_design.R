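# Single-guide RNA scaffold construction. The CRISPR repeat and the tracrRNA
# anti-repeat form an antiparallel duplex; the scaffold is built by trimming
# that helix from the loop-proximal end and fusing the two strands with a
# GAAA tetraloop, then prepending a spacer: sgRNA = spacer + trimmed repeat +
# GAAA + trimmed anti-repeat + tracr tail. The duplex itself is identified by
# a complementarity alignment (Smith-Waterman over the repeat vs the reversed
# tracr, with Watson-Crick and optionally G:U wobble pairs as matches), not
# by thermodynamic folding; an externally computed pairing can be supplied
# instead via duplex_model().

.pairs_ok <- function(a, b, allow_wobble) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
        (a == "C" & b == "G") | (a == "G" & b == "C")
  if (!allow_wobble) return(wc)
  wc | (a == "G" & b == "T") | (a == "T" & b == "G")
}

#' Construct a duplex model from an explicit pairing
#'
#' Hook for supplying a repeat:anti-repeat pairing computed elsewhere (e.g.
#' from a thermodynamic fold): validates that all pairs are Watson-Crick or
#' G:U and strictly monotone (antiparallel, no pseudoknots).
#'
#' @param repeat_seq,tracr_seq Repeat and tracrRNA sequences (RNA accepted;
#'   stored on the DNA alphabet).
#' @param pairs Tibble/data.frame with columns `repeat_index`, `tracr_index`
#'   (1-based); `repeat_index` must increase while `tracr_index` decreases.
#' @param min_duplex Minimum duplex length to accept.
#' @return A `duplex_model`.
#' @export
duplex_model <- function(repeat_seq, tracr_seq, pairs, min_duplex = 6L) {
  repeat_seq <- normalize_nt(repeat_seq)
  tracr_seq <- normalize_nt(tracr_seq)
  pairs <- as_tibble(pairs)
  stopifnot(all(c("repeat_index", "tracr_index") %in% names(pairs)))
  pairs <- arrange(pairs, .data$repeat_index)
  if (nrow(pairs) < min_duplex) abort("no repeat:anti-repeat duplex found")
  if (any(diff(pairs$repeat_index) <= 0) || any(diff(pairs$tracr_index) >= 0)) {
    abort("pairing must be strictly monotone and antiparallel")
  }
  rb <- substring(repeat_seq, pairs$repeat_index, pairs$repeat_index)
  tb <- substring(tracr_seq, pairs$tracr_index, pairs$tracr_index)
  if (!all(.pairs_ok(rb, tb, allow_wobble = TRUE))) {
    abort("pairing contains non-Watson-Crick, non-wobble pairs")
  }
  structure(
    list(repeat_seq = repeat_seq, tracr_seq = tracr_seq,
         pairing = pairs, duplex_len = nrow(pairs),
         min_duplex = as.integer(min_duplex), score = NA_real_),
    class = "duplex_model"
  )
}

#' Find the repeat:anti-repeat duplex
#'
#' Local (Smith-Waterman) alignment of the repeat against the reversed
#' tracrRNA in which complementary pairs (and G:U wobble when enabled) score
#' +1, mismatches -2, and each gapped base -3. Ties are resolved toward the
#' pairing closest to the repeat's 3' end. Only complementary aligned columns
#' enter the pairing list.
#'
#' @param repeat_seq,tracr_seq Repeat and tracrRNA sequences.
#' @param min_duplex Minimum acceptable number of base pairs (default 6).
#' @param allow_wobble Allow G:U pairs (default `TRUE`).
#' @return A `duplex_model` with elements `pairing` (tibble `repeat_index`,
#'   `tracr_index`), `duplex_len`, and the alignment `score`.
#' @export
find_duplex <- function(repeat_seq, tracr_seq, min_duplex = 6L,
                        allow_wobble = TRUE) {
  repeat_seq <- normalize_nt(repeat_seq)
  tracr_seq <- normalize_nt(tracr_seq)
  if (nchar(repeat_seq) == 0 || nchar(tracr_seq) == 0) {
    abort("repeat and tracr must be non-empty")
  }
  r <- strsplit(repeat_seq, "")[[1]]
  t_rev <- rev(strsplit(tracr_seq, "")[[1]])  # reversed: monotone co-indexing
  n <- length(r); m <- length(t_rev)
  MATCH <- 1; MISMATCH <- -2; GAP <- -3

  H <- matrix(0, n + 1, m + 1)
  # traceback: 0 stop, 1 diag, 2 up (gap in tracr), 3 left (gap in repeat)
  TB <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    ok_row <- .pairs_ok(r[i], t_rev, allow_wobble)
    for (j in seq_len(m)) {
      diag <- H[i, j] + if (ok_row[j]) MATCH else MISMATCH
      up <- H[i, j + 1] + GAP
      left <- H[i + 1, j] + GAP
      best <- max(0, diag, up, left)
      H[i + 1, j + 1] <- best
      TB[i + 1, j + 1] <- if (best == 0) 0L
        else if (best == diag) 1L else if (best == up) 2L else 3L
    }
  }
  score <- max(H)
  if (score < min_duplex * MATCH) abort("no repeat:anti-repeat duplex found")
  # tie-break: among maximal cells prefer largest repeat index (3'-most)
  cells <- which(H == score, arr.ind = TRUE)
  cells <- cells[order(-cells[, 1], -cells[, 2]), , drop = FALSE]
  i <- cells[1, 1]; j <- cells[1, 2]
  ri <- integer(); tj <- integer()
  while (TB[i, j] != 0L) {
    if (TB[i, j] == 1L) {
      if (.pairs_ok(r[i - 1], t_rev[j - 1], allow_wobble)) {
        ri <- c(i - 1L, ri)
        tj <- c(m - (j - 1L) + 1L, tj)  # back to original tracr coordinates
      }
      i <- i - 1L; j <- j - 1L
    } else if (TB[i, j] == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  if (length(ri) < min_duplex) abort("no repeat:anti-repeat duplex found")
  structure(
    list(repeat_seq = repeat_seq, tracr_seq = tracr_seq,
         pairing = tibble(repeat_index = as.integer(unname(ri)),
                          tracr_index = as.integer(unname(tj))),
         duplex_len = length(ri), min_duplex = as.integer(min_duplex),
         score = score),
    class = "duplex_model"
  )
}

#' @export
print.duplex_model <- function(x, ...) {
  cat("<duplex_model>", x$duplex_len, "bp, score", x$score, "\n",
      " repeat", min(x$pairing$repeat_index), "-", max(x$pairing$repeat_index),
      " : tracr", min(x$pairing$tracr_index), "-", max(x$pairing$tracr_index),
      "(antiparallel)\n")
  invisible(x)
}

to_rna <- function(x) gsub("T", "U", x, fixed = TRUE)

#' Build the sgRNA design series
#'
#' Emits the cartesian product of helix trim levels, spacer lengths, and
#' tracrRNA termination points. Trimming removes base pairs from the
#' tetraloop-proximal end of the duplex symmetrically on both strands; the
#' spacer is truncated from its 5' (PAM-distal) end. Combinations whose trim
#' would leave fewer than `min_duplex` pairs, or whose spacer length exceeds
#' the supplied spacer, are skipped with a warning.
#'
#' @param duplex A `duplex_model`.
#' @param spacer Source spacer sequence (longest version).
#' @param trim_levels Integer vector of pairs to remove (default 0).
#' @param spacer_lens Spacer lengths to emit (default: full length).
#' @param tail_ends tracrRNA termination points (1-based last retained tracr
#'   base; default: full tracr).
#' @param tetraloop Loop sequence fused between the strands (default "GAAA").
#' @return Tibble with one design per row: `design_id`, `trim_level`,
#'   `spacer_len`, `tail_end`, the five segments, `full_sequence` (DNA
#'   alphabet) and `full_sequence_rna`.
#' @export
build_designs <- function(duplex, spacer, trim_levels = 0L,
                          spacer_lens = NULL, tail_ends = NULL,
                          tetraloop = "GAAA") {
  stopifnot(inherits(duplex, "duplex_model"))
  spacer <- normalize_nt(spacer)
  if (is.null(spacer_lens)) spacer_lens <- nchar(spacer)
  if (is.null(tail_ends)) tail_ends <- nchar(duplex$tracr_seq)
  p <- duplex$pairing
  i_max <- max(p$repeat_index)             # repeat 3'-most paired base
  j_min <- min(p$tracr_index)              # pairs with i_max (antiparallel)
  j_max <- max(p$tracr_index)

  combos <- tidyr::expand_grid(trim_level = as.integer(trim_levels),
                               spacer_len = as.integer(spacer_lens),
                               tail_end = as.integer(tail_ends))
  rows <- purrr::pmap_dfr(combos, function(trim_level, spacer_len, tail_end) {
    if (duplex$duplex_len - trim_level < duplex$min_duplex) {
      warn(paste0("trim ", trim_level, " leaves fewer than ",
                  duplex$min_duplex, " base pairs; skipped"))
      return(NULL)
    }
    if (spacer_len > nchar(spacer)) {
      warn(paste0("spacer length ", spacer_len,
                  " exceeds supplied spacer; skipped"))
      return(NULL)
    }
    if (tail_end < j_max + trim_level) {
      warn(paste0("tail end ", tail_end, " truncates the anti-repeat; skipped"))
      return(NULL)
    }
    # trimming removes the trim_level pairs nearest the loop: highest repeat
    # indices, lowest tracr indices
    kept <- p[order(p$repeat_index), ][seq_len(duplex$duplex_len - trim_level), ]
    r_end <- max(kept$repeat_index)
    t_start <- min(kept$tracr_index)
    sp <- substr(spacer, nchar(spacer) - spacer_len + 1L, nchar(spacer))
    trimmed_repeat <- substr(duplex$repeat_seq, 1L, r_end)
    trimmed_antirepeat <- substr(duplex$tracr_seq, t_start, j_max)
    tracr_tail <- substr(duplex$tracr_seq, j_max + 1L, tail_end)
    full <- paste0(sp, trimmed_repeat, tetraloop, trimmed_antirepeat, tracr_tail)
    tibble(
      design_id = sprintf("trim%d_sp%d_tail%d", trim_level, spacer_len, tail_end),
      trim_level = trim_level, spacer_len = spacer_len, tail_end = tail_end,
      n_pairs = nrow(kept),
      spacer = sp, trimmed_repeat = trimmed_repeat, tetraloop = tetraloop,
      trimmed_antirepeat = trimmed_antirepeat, tracr_tail = tracr_tail,
      full_sequence = full, full_sequence_rna = to_rna(full)
    )
  })
  rows
}

#' Write sgRNA designs as RNA FASTA
#'
#' @param designs Tibble from [build_designs()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_designs_fasta <- function(designs, path) {
  write_fasta(tibble(id = designs$design_id,
                     sequence = designs$full_sequence_rna), path)
}
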