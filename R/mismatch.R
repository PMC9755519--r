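# Guide mismatch-tolerance mapping from plasmid-interference sequencing. The
# assay transforms E. coli carrying the nuclease + guide with a library of
# target plasmids: one perfect match plus single-mismatch variants tiling the
# spacer. Variants the nuclease still cleaves kill their host and are depleted
# among survivors; variants at positions requiring base pairing escape
# cleavage and are relatively enriched in the output library. Enrichment is a
# pseudocounted log2 relative-frequency ratio, and per-position calls compare
# the mean enrichment against the perfect-match spacer's own enrichment.

#' Define a single-mismatch variant library
#'
#' @param spacer_ref Reference protospacer (written 5'->3', PAM at the 3'
#'   end; position 1 counts from the PAM, i.e. the last base).
#' @param variants Tibble with columns `variant_id`, `position` (1-based from
#'   the PAM; 0 for the perfect-match entry), `ref_base`, `alt_base`,
#'   `protospacer`. Each variant must differ from `spacer_ref` at exactly the
#'   stated position (the perfect match at none).
#' @return A `variant_library` object.
#' @export
variant_library <- function(spacer_ref, variants) {
  spacer_ref <- normalize_nt(spacer_ref)
  need <- c("variant_id", "position", "ref_base", "alt_base", "protospacer")
  if (!all(need %in% names(variants))) {
    abort(paste("variant table needs columns:", paste(need, collapse = ", ")))
  }
  variants <- as_tibble(variants) %>%
    mutate(protospacer = normalize_nt(.data$protospacer))
  if (anyDuplicated(variants$protospacer)) {
    abort("two library entries share an identical protospacer")
  }
  L <- nchar(spacer_ref)
  ref_chars <- strsplit(spacer_ref, "")[[1]]
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (nchar(v$protospacer) != L) abort("variant length differs from spacer_ref")
    diffs <- which(strsplit(v$protospacer, "")[[1]] != ref_chars)
    if (v$position == 0) {
      if (length(diffs) != 0) abort("perfect-match entry differs from spacer_ref")
    } else {
      # position p from the PAM = string index L - p + 1
      if (length(diffs) != 1 || diffs != L - v$position + 1) {
        abort(paste0("variant ", v$variant_id,
                     " does not carry a single mismatch at position ",
                     v$position, " from the PAM"))
      }
    }
  }
  structure(list(spacer_ref = spacer_ref, variants = variants,
                 spacer_len = L),
            class = "variant_library")
}

#' Construct the canonical single-mismatch library
#'
#' Builds a perfect-match entry plus one transversion/transition variant per
#' position (default: the complement base at each position), the 24+1 layout
#' used for 24-nt spacers.
#'
#' @param spacer_ref Reference protospacer.
#' @param alt Function mapping a reference base to its alternate base, default
#'   the Watson-Crick complement.
#' @return A `variant_library`.
#' @export
single_mismatch_library <- function(spacer_ref,
                                    alt = function(b) chartr("ACGT", "TGCA", b)) {
  spacer_ref <- normalize_nt(spacer_ref)
  L <- nchar(spacer_ref)
  chars <- strsplit(spacer_ref, "")[[1]]
  rows <- purrr::map_dfr(seq_len(L), function(p) {
    idx <- L - p + 1
    ab <- alt(chars[idx])
    proto <- chars
    proto[idx] <- ab
    tibble(variant_id = sprintf("mm%02d", p), position = p,
           ref_base = chars[idx], alt_base = ab,
           protospacer = paste(proto, collapse = ""))
  })
  rows <- bind_rows(
    tibble(variant_id = "perfect", position = 0L,
           ref_base = NA_character_, alt_base = NA_character_,
           protospacer = spacer_ref),
    rows
  )
  variant_library(spacer_ref, rows)
}

#' Assign reads to library variants by exact protospacer match
#'
#' The protospacer is located between the supplied flanks; a read counts for
#' the unique variant whose protospacer it matches exactly. Reads without
#' both flanks, or whose protospacer matches no variant, are tallied as
#' unassigned (attribute `unassigned`), never force-assigned.
#'
#' @param reads FASTQ record tibble.
#' @param library A `variant_library`.
#' @param flank5,flank3 Constant sequences immediately flanking the
#'   protospacer in the amplicon.
#' @return Tibble `variant_id`, `count` covering every library entry.
#' @export
count_variants <- function(reads, library, flank5, flank3) {
  stopifnot(inherits(library, "variant_library"))
  flank5 <- normalize_nt(flank5)
  flank3 <- normalize_nt(flank3)
  L <- library$spacer_len
  pat <- paste0(flank5, "([ACGTN]{", L, "})", flank3)
  m <- regexpr(pat, reads$sequence, perl = TRUE)
  proto <- rep(NA_character_, nrow(reads))
  hit <- m > 0
  if (any(hit)) {
    st <- attr(m, "capture.start")[hit, 1]
    proto[hit] <- substr(reads$sequence[hit], st, st + L - 1L)
  }
  lut <- setNames(library$variants$variant_id, library$variants$protospacer)
  assigned <- lut[proto]
  counts <- tibble(variant_id = library$variants$variant_id) %>%
    left_join(
      tibble(variant_id = assigned[!is.na(assigned)]) %>%
        count(.data$variant_id, name = "count"),
      by = "variant_id"
    ) %>%
    mutate(count = dplyr::coalesce(.data$count, 0L))
  attr(counts, "unassigned") <- sum(is.na(assigned))
  counts
}

.as_count_vec <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("variant_id", "count") %in% names(x))) {
      abort(paste(what, "must have variant_id and count columns"))
    }
    setNames(as.numeric(x$count), x$variant_id)
  } else if (!is.null(names(x))) {
    setNames(as.numeric(x), names(x))
  } else {
    abort(paste(what, "must be a named vector or a (variant_id, count) table"))
  }
}

#' Log2 relative-frequency enrichment of survivors vs the input library
#'
#' For each variant `v` of `V` variants, with pseudocount `pc`:
#' `e(v) = log2(((out_v + pc)/(Out + pc*V)) / ((in_v + pc)/(In + pc*V)))`
#' where `Out` and `In` are the library totals. Relative frequencies make the
#' statistic invariant to sequencing depth. Positive values mean the variant
#' escaped cleavage (mismatch not tolerated at that position).
#'
#' @param counts_out,counts_in Survivor and input counts: named vectors or
#'   (`variant_id`, `count`) tibbles over the same variant ids.
#' @param pseudocount Default 1.
#' @return Tibble `variant_id`, `log2_enrichment`.
#' @export
enrichment <- function(counts_out, counts_in, pseudocount = 1) {
  out <- .as_count_vec(counts_out, "counts_out")
  inn <- .as_count_vec(counts_in, "counts_in")
  if (length(out) == 0 || length(inn) == 0) abort("empty counts")
  ids <- union(names(inn), names(out))
  out <- ifelse(is.na(out[ids]), 0, out[ids])
  inn <- ifelse(is.na(inn[ids]), 0, inn[ids])
  if (sum(out) <= 0 || sum(inn) <= 0) abort("count totals must be positive")
  V <- length(ids)
  f_out <- (out + pseudocount) / (sum(out) + pseudocount * V)
  f_in <- (inn + pseudocount) / (sum(inn) + pseudocount * V)
  tibble(variant_id = ids, log2_enrichment = unname(log2(f_out / f_in)))
}

#' Per-position tolerance calls
#'
#' Averages enrichment over the alternate-base variants at each spacer
#' position and compares against the perfect-match spacer's enrichment, which
#' anchors the fully-cut baseline: a position is `tolerated` when its score is
#' within `margin` log2 units of the perfect match, `intolerant` when at least
#' `2 * margin` above it, and `indeterminate` between.
#'
#' @param e Enrichment tibble from [enrichment()].
#' @param library A `variant_library`.
#' @param perfect_id Variant id of the perfect-match entry (default
#'   `"perfect"`).
#' @param margin Log2 margin, default 1.
#' @return A `tolerance_map` object with elements `enrichment`, `positions`
#'   (tibble `position`, `score`, `call`), `perfect_enrichment`, `margin`.
#' @export
position_calls <- function(e, library, perfect_id = "perfect", margin = 1.0) {
  stopifnot(inherits(library, "variant_library"))
  if (!perfect_id %in% e$variant_id) abort("perfect-match variant not found")
  e_perfect <- e$log2_enrichment[e$variant_id == perfect_id]
  mm <- library$variants %>% filter(.data$position > 0)
  missing_pos <- setdiff(seq_len(library$spacer_len), mm$position)
  if (length(missing_pos)) {
    warn(paste("no variants at position(s):",
               paste(missing_pos, collapse = ", ")))
  }
  pos <- mm %>%
    left_join(e, by = "variant_id") %>%
    group_by(.data$position) %>%
    summarise(score = mean(.data$log2_enrichment), .groups = "drop") %>%
    mutate(call = dplyr::case_when(
      .data$score <= e_perfect + margin ~ "tolerated",
      .data$score >= e_perfect + 2 * margin ~ "intolerant",
      TRUE ~ "indeterminate"
    ))
  structure(
    list(enrichment = e, positions = pos,
         perfect_enrichment = e_perfect, margin = margin,
         library = library),
    class = "tolerance_map"
  )
}

#' Full mismatch-tolerance pipeline from counts
#'
#' Convenience wrapper: [enrichment()] then [position_calls()].
#'
#' @inheritParams enrichment
#' @inheritParams position_calls
#' @return A `tolerance_map`.
#' @export
tolerance_map <- function(counts_out, counts_in, library,
                          perfect_id = "perfect", pseudocount = 1,
                          margin = 1.0) {
  e <- enrichment(counts_out, counts_in, pseudocount)
  position_calls(e, library, perfect_id, margin)
}

#' Position x alternate-base enrichment heatmap table
#'
#' Complete grid over spacer positions and the four bases; cells for
#' unassayed (position, base) pairs are `NA`, not zero.
#'
#' @param map A `tolerance_map`.
#' @param library A `variant_library` (defaults to the one stored in `map`).
#' @return Tibble `position`, `alt_base`, `log2_enrichment`.
#' @export
heatmap_table <- function(map, library = map$library) {
  stopifnot(inherits(map, "tolerance_map"))
  grid <- tidyr::expand_grid(position = seq_len(library$spacer_len),
                             alt_base = c("A", "C", "G", "T"))
  filled <- library$variants %>%
    filter(.data$position > 0) %>%
    left_join(map$enrichment, by = "variant_id") %>%
    select("position", "alt_base", "log2_enrichment")
  left_join(grid, filled, by = c("position", "alt_base"))
}

#' @export
print.tolerance_map <- function(x, ...) {
  intol <- x$positions$position[x$positions$call == "intolerant"]
  tol <- x$positions$position[x$positions$call == "tolerated"]
  cat("<tolerance_map>", nrow(x$positions), "positions;",
      "perfect-match enrichment", sprintf("%.2f", x$perfect_enrichment), "\n",
      " intolerant:", paste(intol, collapse = ","), "\n",
      " tolerated: ", paste(tol, collapse = ","), "\n")
  invisible(x)
}

#' @rdname position_calls
#' @param x,object A `tolerance_map`.
#' @param ... Unused.
#' @export
tidy.tolerance_map <- function(x, ...) x$positions

#' @rdname position_calls
#' @export
glance.tolerance_map <- function(x, ...) {
  tibble(
    n_positions = nrow(x$positions),
    n_intolerant = sum(x$positions$call == "intolerant"),
    n_tolerated = sum(x$positions$call == "tolerated"),
    n_indeterminate = sum(x$positions$call == "indeterminate"),
    perfect_enrichment = x$perfect_enrichment,
    margin = x$margin
  )
}

#' @rdname position_calls
#' @export
autoplot.tolerance_map <- function(object, ...) {
  dat <- heatmap_table(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$alt_base,
                                    fill = .data$log2_enrichment)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient2(low = "#5e3c99", mid = "grey95",
                                  high = "#e6c200", na.value = "white",
                                  name = "log2 enrichment") +
    ggplot2::labs(x = "spacer position from PAM", y = "mismatch base") +
    ggplot2::theme_minimal()
}
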