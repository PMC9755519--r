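# PAM discovery from adapter-ligated cleavage products of a randomized (8N)
# PAM library. Reads have the layout adapter + protospacer-remnant + PAM +
# backbone anchor (or its reverse complement). The fixed backbone anchor is
# located exactly, the adjacent bases are taken as the putative PAM, and the
# distance between the ligated adapter and the PAM-proximal edge is the cut
# distance. Observations are filtered to the modal cut site +/- 2 before the
# position frequency matrix, information content, and IUPAC consensus are
# derived.

#' Describe the cleavage-assay read layout
#'
#' @param adapter Ligated adapter sequence as read (nucleotide).
#' @param anchor Fixed backbone sequence adjacent to the PAM, 14-24 nt.
#' @param pam_length Number of randomized PAM bases (default 8).
#' @param pam_side Whether the PAM lies `"before_anchor"` (between cut site
#'   and anchor, the usual 3'-PAM geometry as sequenced) or `"after_anchor"`.
#' @return An `assay_layout` object.
#' @export
assay_layout <- function(adapter, anchor,
                         pam_length = 8L,
                         pam_side = c("before_anchor", "after_anchor")) {
  pam_side <- match.arg(pam_side)
  adapter <- normalize_nt(adapter)
  anchor <- normalize_nt(anchor)
  if (nchar(anchor) < 14 || nchar(anchor) > 24) {
    abort("anchor must be 14-24 nt of known backbone sequence")
  }
  if (pam_length < 1) abort("pam_length must be >= 1")
  if (grepl("[^ACGT]", adapter) || grepl("[^ACGT]", anchor)) {
    abort("adapter and anchor must be concrete ACGT sequences")
  }
  structure(
    list(adapter = adapter, anchor = anchor,
         pam_length = as.integer(pam_length), pam_side = pam_side),
    class = "assay_layout"
  )
}

#' @export
print.assay_layout <- function(x, ...) {
  cat("<assay_layout> adapter:", x$adapter, "\n  anchor:", x$anchor,
      paste0("(", nchar(x$anchor), " nt)"),
      "\n  pam_length:", x$pam_length, " pam_side:", x$pam_side, "\n")
  invisible(x)
}

#' Locate the backbone anchor in each read
#'
#' Searches each read for an exact anchor match, first in the forward
#' orientation and then in the reverse complement. The leftmost match in the
#' searched orientation wins. Positions are 0-based within the searched
#' orientation.
#'
#' @param records FASTQ record tibble.
#' @param layout An [assay_layout()].
#' @return Tibble `id`, `position` (0-based start, `NA` if absent from both
#'   orientations), `orientation` (`"forward"`/`"reverse"`/`NA`).
#' @export
locate_anchor <- function(records, layout) {
  stopifnot(inherits(layout, "assay_layout"))
  fwd <- regexpr(layout$anchor, records$sequence, fixed = TRUE)
  pos <- ifelse(fwd > 0, fwd - 1L, NA_integer_)
  ori <- ifelse(fwd > 0, "forward", NA_character_)
  miss <- which(fwd < 0)
  if (length(miss)) {
    rc <- reverse_complement(records$sequence[miss])
    rev <- regexpr(layout$anchor, rc, fixed = TRUE)
    hit <- rev > 0
    pos[miss[hit]] <- rev[hit] - 1L
    ori[miss[hit]] <- "reverse"
  }
  tibble(id = records$id, position = as.integer(pos), orientation = ori)
}

#' Extract PAM observations from anchored reads
#'
#' For each read with an anchor hit, orients the read so the layout reads
#' adapter ... remnant ... PAM ... anchor, takes the `pam_length` bases on the
#' protospacer side of the anchor as the putative PAM, and the number of bases
#' between the end of the ligated adapter and the PAM-proximal edge as the cut
#' distance. Reads whose adapter cannot be found upstream of the PAM in the
#' same orientation, or that are too short to contain the full PAM window, are
#' tallied in the `discards` attribute rather than silently dropped.
#'
#' @param records FASTQ record tibble.
#' @param layout An [assay_layout()].
#' @return Tibble `read_id`, `pam`, `cut_distance`, `orientation`, with
#'   attribute `discards`: a tibble of (`reason`, `n`) accounting for every
#'   non-emitted read.
#' @export
extract_observations <- function(records, layout) {
  hits <- locate_anchor(records, layout)
  n_no_anchor <- sum(is.na(hits$position))
  keep <- !is.na(hits$position)
  seqs <- records$sequence[keep]
  ids <- records$id[keep]
  pos <- hits$position[keep]
  ori <- hits$orientation[keep]

  is_rev <- ori == "reverse"
  seqs[is_rev] <- reverse_complement(seqs[is_rev])

  if (layout$pam_side == "after_anchor") {
    # flip so the PAM is upstream of the anchor, reducing to the canonical case
    anchor_rc_pos <- nchar(seqs) - (pos + nchar(layout$anchor))
    seqs <- reverse_complement(seqs)
    pos <- anchor_rc_pos
    adapter <- reverse_complement(layout$adapter)
  } else {
    adapter <- layout$adapter
  }

  pam_start <- pos - layout$pam_length + 1L  # 1-based start of PAM window
  too_short <- pam_start < 1L
  pam <- ifelse(too_short, NA_character_,
                substr(seqs, pam_start, pos))
  apos <- regexpr(adapter, seqs, fixed = TRUE)
  adapter_end <- ifelse(apos > 0, apos + nchar(adapter) - 1L, NA_integer_)
  cut_distance <- pam_start - adapter_end - 1L
  bad_adapter <- !too_short & (apos < 0 | cut_distance < 0)

  ok <- !too_short & !bad_adapter
  obs <- tibble(
    read_id = ids[ok],
    pam = pam[ok],
    cut_distance = as.integer(cut_distance[ok]),
    orientation = ori[ok]
  )
  discards <- tibble(
    reason = c("no_anchor", "read_too_short", "adapter_not_found"),
    n = c(n_no_anchor, sum(too_short), sum(bad_adapter))
  )
  attr(obs, "discards") <- discards
  obs
}

#' Build a PAM profile from observations
#'
#' Determines the modal cut distance (ties broken toward the smaller,
#' PAM-proximal distance), retains only observations within +/-2 of the mode,
#' and computes a pseudocounted position frequency matrix, per-position
#' information content, and the IUPAC consensus.
#'
#' @param observations Tibble from [extract_observations()] (columns `pam`,
#'   `cut_distance`; others optional).
#' @param pseudocount Added to every PFM cell before row normalization
#'   (default 0.5).
#' @param include_threshold Consensus inclusion threshold passed to
#'   [call_consensus()] (default 0.2).
#' @return A `pam_profile` object with elements `n_raw`, `n_retained`,
#'   `modal_cut`, `cut_histogram` (tibble over all observations),
#'   `retained_cuts`, `pfm` (positions x ACGT), `information_bits`,
#'   `consensus`.
#' @export
build_profile <- function(observations, pseudocount = 0.5,
                          include_threshold = 0.2) {
  if (is.null(observations) || nrow(observations) == 0) {
    abort("no PAM observations")
  }
  cuts <- observations$cut_distance
  hist <- dplyr::count(tibble(cut_distance = cuts), .data$cut_distance,
                       name = "n")
  modal_cut <- hist$cut_distance[order(-hist$n, hist$cut_distance)][1]
  keep <- abs(cuts - modal_cut) <= 2
  retained <- observations[keep, , drop = FALSE]

  pams <- retained$pam
  pam_length <- nchar(pams[1])
  mat <- matrix(unlist(strsplit(pams, "")), nrow = length(pams),
                ncol = pam_length, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(pam_length), function(i) {
    tabulate(factor(mat[, i], levels = bases), nbins = 4)
  }, numeric(4))
  counts <- t(counts) + pseudocount       # positions x bases
  pfm <- counts / rowSums(counts)
  dimnames(pfm) <- list(NULL, bases)
  info <- 2 + rowSums(ifelse(pfm > 0, pfm * log2(pfm), 0))

  structure(
    list(
      n_raw = nrow(observations),
      n_retained = nrow(retained),
      modal_cut = as.integer(modal_cut),
      cut_histogram = hist,
      retained_cuts = sort(unique(retained$cut_distance)),
      pfm = pfm,
      information_bits = info,
      consensus = call_consensus(pfm, include_threshold)
    ),
    class = "pam_profile"
  )
}

#' Reduce a position frequency matrix to an IUPAC consensus
#'
#' Per position, the IUPAC code covering the set of bases whose frequency is
#' at least `include_threshold`; a position where all four bases qualify, or
#' none does, is reported as `N`. The default threshold (0.2) sits just below
#' the uniform expectation of 0.25 by a sampling margin, so at uninformative
#' positions all four bases qualify and the position collapses to `N`, while
#' a base genuinely absent from a degenerate position (members have frequency
#' at least 1/3) stays far below it.
#'
#' @param pfm Row-normalized positions x ACGT matrix.
#' @param include_threshold In (0, 1]; default 0.2.
#' @return IUPAC consensus string.
#' @export
call_consensus <- function(pfm, include_threshold = 0.2) {
  if (include_threshold <= 0 || include_threshold > 1) {
    abort("include_threshold must be in (0, 1]")
  }
  if (any(abs(rowSums(pfm) - 1) > 1e-6)) abort("pfm rows must sum to 1")
  codes <- apply(pfm, 1, function(row) {
    qual <- colnames(pfm)[row >= include_threshold]
    if (length(qual) == 0 || length(qual) == 4) "N" else iupac_code(qual)
  })
  paste(codes, collapse = "")
}

#' Information-scaled logo matrix
#'
#' Heights `f[i,b] * information_bits[i]`, the standard sequence-logo scaling;
#' column sums over bases equal the per-position information content.
#'
#' @param profile A `pam_profile`.
#' @return Tibble `position`, `base`, `freq`, `height`.
#' @export
logo_matrix <- function(profile) {
  stopifnot(inherits(profile, "pam_profile"))
  pfm <- profile$pfm
  tibble(
    position = rep(seq_len(nrow(pfm)), times = ncol(pfm)),
    base = rep(colnames(pfm), each = nrow(pfm)),
    freq = as.vector(pfm),
    height = as.vector(pfm * profile$information_bits)
  ) %>% arrange(.data$position, .data$base)
}

#' Infer overhang geometry from target-strand cut and NTS distances
#'
#' The profile's retained cut distances are interpreted as non-target-strand
#' (NTS) cleavage positions from the PAM; the target-strand cut position
#' (typically from Sanger run-off sequencing) is supplied externally. Positive
#' offsets (NTS distal to TS) give 5' overhangs, negative give 3' overhangs,
#' all-zero is blunt. Overhang lengths are reported as magnitudes; the type
#' carries the sign.
#'
#' @param ts_cut Target-strand cut position from the PAM.
#' @param profile A `pam_profile` (its retained cut distances are the NTS
#'   positions), or an integer vector of NTS positions.
#' @return An `overhang_call` list: `ts_cut`, `nts_positions`, `offsets`,
#'   `overhang_type`, `overhang_lengths`.
#' @export
infer_overhang <- function(ts_cut, profile) {
  nts <- if (inherits(profile, "pam_profile")) profile$retained_cuts
         else sort(unique(as.integer(profile)))
  offsets <- nts - ts_cut
  type <- if (all(offsets == 0)) "blunt"
          else if (all(offsets >= 0) && any(offsets > 0)) "five_prime"
          else if (all(offsets <= 0) && any(offsets < 0)) "three_prime"
          else abort("inconsistent cut geometry: mixed-sign overhangs")
  structure(
    list(ts_cut = as.integer(ts_cut), nts_positions = nts,
         offsets = offsets, overhang_type = type,
         overhang_lengths = abs(offsets)),
    class = "overhang_call"
  )
}

#' @export
print.overhang_call <- function(x, ...) {
  cat("<overhang_call>", x$overhang_type,
      "(TS cut", x$ts_cut, "| NTS", paste(x$nts_positions, collapse = ","),
      "| lengths", paste(x$overhang_lengths, collapse = ","), ")\n")
  invisible(x)
}

#' @export
print.pam_profile <- function(x, ...) {
  cat("<pam_profile>\n",
      " consensus:", x$consensus, "\n",
      " modal cut:", x$modal_cut,
      " retained:", x$n_retained, "/", x$n_raw, "reads\n",
      " information (bits):",
      paste(sprintf("%.2f", x$information_bits), collapse = " "), "\n")
  invisible(x)
}

#' @rdname build_profile
#' @param x A `pam_profile`.
#' @param ... Unused.
#' @export
tidy.pam_profile <- function(x, ...) {
  logo_matrix(x) %>%
    mutate(information_bits = x$information_bits[.data$position])
}

#' @rdname build_profile
#' @export
glance.pam_profile <- function(x, ...) {
  tibble(
    n_raw = x$n_raw, n_retained = x$n_retained,
    retained_fraction = x$n_retained / x$n_raw,
    modal_cut = x$modal_cut,
    consensus = x$consensus,
    total_information_bits = sum(x$information_bits)
  )
}

#' @rdname build_profile
#' @param object A `pam_profile`.
#' @export
autoplot.pam_profile <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$position),
                                    y = .data$height, fill = .data$base)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "PAM position", y = "information (bits)",
                  title = paste("PAM consensus:", object$consensus)) +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' Plot the cut-site distance histogram
#'
#' @param profile A `pam_profile`.
#' @return A ggplot of cut-distance counts; the retained window (modal cut
#'   +/-2) is shaded.
#' @export
plot_cut_histogram <- function(profile) {
  stopifnot(inherits(profile, "pam_profile"))
  dat <- profile$cut_histogram %>%
    mutate(retained = abs(.data$cut_distance - profile$modal_cut) <= 2)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cut_distance, y = .data$n,
                                    fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey25", `FALSE` = "grey75")) +
    ggplot2::labs(x = "cut position from PAM (nt)", y = "reads") +
    ggplot2::theme_minimal()
}
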