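# Amplicon-sequencing edit quantification: per-position base-conversion
# fractions (the base-editor heatmap readout) and the window-overlapping
# indel fraction (the nuclease readout). Reads are globally aligned to the
# amplicon reference with affine gap penalties; low-identity alignments
# (off-target amplicons, primer dimers) are rejected rather than counted.

#' Describe an amplicon reference
#'
#' @param sequence Amplicon reference sequence.
#' @param window Editing window, 1-based inclusive `(start, end)` in amplicon
#'   coordinates.
#' @param protospacer_start 1-based start of the protospacer in the amplicon.
#' @param protospacer_length Protospacer length in nt.
#' @param pam_side Which side of the protospacer carries the PAM
#'   (`"three_prime"` default).
#' @return An `amplicon_ref` object.
#' @export
amplicon_ref <- function(sequence, window, protospacer_start,
                         protospacer_length,
                         pam_side = c("three_prime", "five_prime")) {
  pam_side <- match.arg(pam_side)
  sequence <- normalize_nt(sequence)
  L <- nchar(sequence)
  window <- as.integer(window)
  if (length(window) != 2 || window[1] < 1 || window[2] > L ||
      window[1] > window[2]) {
    abort("window must be (start, end) within the amplicon")
  }
  if (protospacer_start < 1 ||
      protospacer_start + protospacer_length - 1 > L) {
    abort("protospacer must lie within the amplicon")
  }
  structure(
    list(sequence = sequence, window = window,
         protospacer_start = as.integer(protospacer_start),
         protospacer_length = as.integer(protospacer_length),
         pam_side = pam_side),
    class = "amplicon_ref"
  )
}

DEFAULT_ALIGN_SCORES <- c(match = 2, mismatch = -3, gap_open = -8,
                          gap_extend = -1)

#' Align reads globally to an amplicon reference
#'
#' Affine-gap global alignment (a gap of length L costs
#' `gap_open + L * gap_extend`); ties resolve deterministically preferring
#' mismatch over gap, then deletion over insertion. Alignments with identity
#' (matching columns / alignment length) below `min_identity` are rejected.
#' Identical read sequences are aligned once and the result reused.
#'
#' @param reads FASTQ record tibble (or character vector of sequences).
#' @param ref An `amplicon_ref` or reference string.
#' @param scores Named vector `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @param min_identity Rejection threshold, default 0.6.
#' @return Tibble `id`, `sequence`, `cigar`, `score`, `identity`, `accepted`.
#' @export
align_reads <- function(reads, ref, scores = DEFAULT_ALIGN_SCORES,
                        min_identity = 0.6) {
  refseq <- if (inherits(ref, "amplicon_ref")) ref$sequence else normalize_nt(ref)
  if (is.character(reads)) {
    reads <- tibble(id = paste0("r", seq_along(reads)),
                    sequence = normalize_nt(reads))
  }
  uniq <- unique(reads$sequence)
  res <- lapply(uniq, function(s) {
    align_affine_cpp(s, refseq, scores[["match"]], scores[["mismatch"]],
                     scores[["gap_open"]], scores[["gap_extend"]])
  })
  lut <- match(reads$sequence, uniq)
  score <- vapply(res, `[[`, 0, "score")[lut]
  cigar <- vapply(res, `[[`, "", "cigar")[lut]
  identity <- (vapply(res, `[[`, 0L, "n_match") /
               pmax(vapply(res, `[[`, 0L, "align_len"), 1L))[lut]
  tibble(id = reads$id, sequence = reads$sequence, cigar = cigar,
         score = score, identity = identity,
         accepted = identity >= min_identity)
}

cigar_ops <- function(cigar) {
  parts <- regmatches(cigar, gregexpr("\\d+[MDI]", cigar))[[1]]
  tibble(
    len = as.integer(sub("[MDI]$", "", parts)),
    op = sub("^\\d+", "", parts)
  )
}

#' Quantify per-position edits and indels
#'
#' Aligns all reads, then tallies, per reference position, the aligned read
#' bases (A/C/G/T and deletion) and the fraction of reads whose base differs
#' from the reference. The indel fraction is the fraction of accepted reads
#' with at least one insertion or deletion overlapping the editing window
#' (`whole_amplicon = TRUE` counts indels anywhere).
#'
#' @inheritParams align_reads
#' @param ref An `amplicon_ref`.
#' @param whole_amplicon Count indels over the whole amplicon instead of the
#'   window.
#' @return An `edit_matrix` object: `per_position` tibble (`position`,
#'   `ref_base`, base counts, `deletions`, `coverage`, `edited`,
#'   `edit_fraction`), `indel_fraction`, `n_reads_aligned`, `n_reads_total`,
#'   `rejections`, and the `ref`.
#' @export
quantify_edits <- function(reads, ref, scores = DEFAULT_ALIGN_SCORES,
                           min_identity = 0.6, whole_amplicon = FALSE) {
  stopifnot(inherits(ref, "amplicon_ref"))
  aln <- align_reads(reads, ref, scores, min_identity)
  n_total <- nrow(aln)
  acc <- aln[aln$accepted, , drop = FALSE]
  if (nrow(acc) == 0) {
    abort(paste0("zero accepted alignments (", n_total, " reads rejected at ",
                 "identity < ", min_identity, ")"))
  }
  L <- nchar(ref$sequence)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, nrow = 5, ncol = L,
                   dimnames = list(c(bases, "del"), NULL))
  win <- if (whole_amplicon) c(1L, L) else ref$window
  n_indel <- 0

  grp <- acc %>% count(.data$sequence, .data$cigar, name = "w")
  for (k in seq_len(nrow(grp))) {
    ops <- cigar_ops(grp$cigar[k])
    w <- grp$w[k]
    rchars <- strsplit(grp$sequence[k], "")[[1]]
    rpos <- 1L; gpos <- 1L
    has_indel <- FALSE
    for (o in seq_len(nrow(ops))) {
      len <- ops$len[o]
      switch(ops$op[o],
        M = {
          cols <- gpos:(gpos + len - 1L)
          b <- match(rchars[rpos:(rpos + len - 1L)], bases)
          ok <- !is.na(b)  # non-ACGT read bases are not tallied
          if (any(ok)) {
            ix <- cbind(b[ok], cols[ok])
            # accumulate with duplicates impossible (distinct columns)
            counts[ix] <- counts[ix] + w
          }
          rpos <- rpos + len; gpos <- gpos + len
        },
        D = {
          cols <- gpos:(gpos + len - 1L)
          counts["del", cols] <- counts["del", cols] + w
          if (any(cols >= win[1] & cols <= win[2])) has_indel <- TRUE
          gpos <- gpos + len
        },
        I = {
          # insertion between ref positions gpos-1 and gpos
          if (gpos - 1L >= win[1] - 1L && gpos - 1L <= win[2]) has_indel <- TRUE
          rpos <- rpos + len
        }
      )
    }
    if (has_indel) n_indel <- n_indel + w
  }

  refchars <- strsplit(ref$sequence, "")[[1]]
  coverage <- colSums(counts[bases, , drop = FALSE])
  ref_idx <- cbind(match(refchars, bases), seq_len(L))
  matches <- counts[ref_idx]
  edited <- coverage - matches
  per_position <- tibble(
    position = seq_len(L), ref_base = refchars,
    A = counts["A", ], C = counts["C", ], G = counts["G", ],
    T = counts["T", ], deletions = counts["del", ],
    coverage = coverage, edited = edited,
    edit_fraction = ifelse(coverage > 0, edited / coverage, NA_real_)
  )
  structure(
    list(per_position = per_position,
         indel_fraction = n_indel / nrow(acc),
         n_reads_aligned = nrow(acc), n_reads_total = n_total,
         rejections = n_total - nrow(acc),
         window = win, ref = ref),
    class = "edit_matrix"
  )
}

#' Per-conversion heatmap table
#'
#' One row per occurrence of the conversion's source base in the protospacer
#' (positions numbered within the protospacer, 5' to 3'), on the percent
#' scale of the standard base-editing heatmaps.
#'
#' @param matrix An `edit_matrix`.
#' @param conversion Length-2 character vector `(from_base, to_base)`, e.g.
#'   `c("A", "G")` for an adenine base editor.
#' @return Tibble `protospacer_position`, `amplicon_position`, `from_base`,
#'   `to_base`, `percent`.
#' @export
conversion_table <- function(matrix, conversion = c("A", "G")) {
  stopifnot(inherits(matrix, "edit_matrix"))
  from <- toupper(conversion[1]); to <- toupper(conversion[2])
  ref <- matrix$ref
  span <- seq(ref$protospacer_start,
              ref$protospacer_start + ref$protospacer_length - 1L)
  pp <- matrix$per_position[span, ]
  hit <- which(pp$ref_base == from)
  if (length(hit) == 0) {
    return(tibble(protospacer_position = integer(),
                  amplicon_position = integer(),
                  from_base = character(), to_base = character(),
                  percent = numeric()))
  }
  tibble(
    protospacer_position = hit,
    amplicon_position = span[hit],
    from_base = from, to_base = to,
    percent = 100 * pp[[to]][hit] / pmax(pp$coverage[hit], 1)
  )
}

#' @export
print.edit_matrix <- function(x, ...) {
  cat("<edit_matrix>", x$n_reads_aligned, "/", x$n_reads_total,
      "reads aligned;", x$rejections, "rejected\n",
      sprintf("  indel fraction (window %d-%d): %.4f\n",
              x$window[1], x$window[2], x$indel_fraction))
  invisible(x)
}

#' @rdname quantify_edits
#' @param x,object An `edit_matrix`.
#' @param ... Unused.
#' @export
tidy.edit_matrix <- function(x, ...) {
  x$per_position %>%
    tidyr::pivot_longer(cols = c("A", "C", "G", "T", "deletions"),
                        names_to = "to_base", values_to = "count") %>%
    mutate(fraction = ifelse(.data$coverage > 0,
                             .data$count / .data$coverage, NA_real_))
}

#' @rdname quantify_edits
#' @export
glance.edit_matrix <- function(x, ...) {
  tibble(
    n_reads_total = x$n_reads_total,
    n_reads_aligned = x$n_reads_aligned,
    rejections = x$rejections,
    indel_fraction = x$indel_fraction,
    max_edit_fraction = max(x$per_position$edit_fraction, na.rm = TRUE)
  )
}

#' @rdname quantify_edits
#' @export
autoplot.edit_matrix <- function(object, ...) {
  ggplot2::ggplot(object$per_position,
                  ggplot2::aes(x = .data$position,
                               y = 100 * .data$edit_fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::annotate("rect", xmin = object$window[1] - 0.5,
                      xmax = object$window[2] + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "blue") +
    ggplot2::labs(x = "amplicon position", y = "% reads edited") +
    ggplot2::theme_minimal()
}
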