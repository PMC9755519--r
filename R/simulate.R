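# Synthetic-data generators with known ground truth for every assay module.
# Each generator is bit-reproducible under a fixed seed and attaches a
# machine-readable truth manifest (attribute "truth") that the test suite
# consumes directly. Defaults mirror the characterized assay regimes: PAM
# classes like NGG/NRC/NAR, cut distances 5-7 nt from the PAM, a 24-nt spacer
# whose PAM-proximal seed (positions 1-13, except 9) is mismatch-intolerant,
# and base-editing windows read out per position.

DEFAULT_PROTOSPACER <- "GACGTTACCGGTTGCATTCGATTCCTGTAG"  # fixed 30-mer

.sample_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

# substitution-only sequencing error on a character vector of reads
.apply_error <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  lens <- nchar(reads)
  chars <- unlist(strsplit(reads, ""))
  hit <- which(runif(length(chars)) < error_rate)
  if (length(hit)) {
    # substitute with one of the three other bases
    repl <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
    chars[hit] <- repl
  }
  vapply(split(chars, rep(seq_along(reads), lens)), paste, "", collapse = "")
}

#' Ground truth for a PAM-library cleavage simulation
#'
#' @param pam_iupac Ground-truth PAM as IUPAC (e.g. `"NGG"`); padded with `N`
#'   to `pam_length` on the right.
#' @param cut_dist Named probability vector over cut distances, default
#'   `c("5" = 0.55, "6" = 0.30, "7" = 0.15)`.
#' @param cleave_prob_match,cleave_prob_nonmatch Cleavage probability for
#'   molecules whose PAM matches / does not match the truth.
#' @param error_rate Per-base substitution error in emitted reads.
#' @param orientation_mix Fraction of reads emitted reverse-complemented.
#' @param pam_length Library randomization width (default 8).
#' @return A `pam_truth` list.
#' @export
pam_truth <- function(pam_iupac = "NGG",
                      cut_dist = c("5" = 0.55, "6" = 0.30, "7" = 0.15),
                      cleave_prob_match = 0.9,
                      cleave_prob_nonmatch = 0.0,
                      error_rate = 0.01,
                      orientation_mix = 0.0,
                      pam_length = 8L) {
  if (abs(sum(cut_dist) - 1) > 1e-9) abort("cut_dist probabilities must sum to 1")
  probs <- c(cleave_prob_match, cleave_prob_nonmatch, error_rate, orientation_mix)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (nchar(pam_iupac) > pam_length) abort("pam_iupac longer than pam_length")
  padded <- paste0(pam_iupac,
                   strrep("N", pam_length - nchar(pam_iupac)))
  structure(list(pam_iupac = pam_iupac, pam_padded = padded,
                 cut_dist = cut_dist,
                 cleave_prob_match = cleave_prob_match,
                 cleave_prob_nonmatch = cleave_prob_nonmatch,
                 error_rate = error_rate, orientation_mix = orientation_mix,
                 pam_length = as.integer(pam_length)),
            class = "pam_truth")
}

#' Simulate cleavage-product reads from a randomized PAM library
#'
#' Each library molecule draws a uniform random PAM; molecules are cleaved
#' with probability `cleave_prob_match` when the PAM matches the truth and
#' `cleave_prob_nonmatch` otherwise (enrichment-style assay: only cleaved
#' molecules are adapter-ligated and sequenced, so uncleaved molecules emit
#' no read). Molecules are generated until `n` cleavage-product reads have
#' been emitted; the number of molecules consumed is recorded in the truth
#' manifest. Cleaved molecules draw a cut distance and emit
#' `adapter + protospacer-remnant + PAM + anchor`, optionally
#' reverse-complemented, with substitution-only base-call errors and constant
#' Q37 qualities.
#'
#' @param truth A [pam_truth()].
#' @param layout An [assay_layout()].
#' @param n Number of cleavage-product reads to emit.
#' @param seed Random seed (bit-reproducible output).
#' @param protospacer Protospacer whose PAM-proximal tail forms the remnant.
#' @return FASTQ record tibble with attribute `truth` (manifest list).
#' @export
simulate_pam_reads <- function(truth, layout, n, seed,
                               protospacer = DEFAULT_PROTOSPACER) {
  stopifnot(inherits(truth, "pam_truth"), inherits(layout, "assay_layout"))
  if (n <= 0) abort("n must be positive")
  if (truth$pam_length != layout$pam_length) {
    abort("truth and layout disagree on pam_length")
  }
  if (truth$cleave_prob_match <= 0 && truth$cleave_prob_nonmatch <= 0) {
    abort("no molecule can be cleaved; nothing to sequence")
  }
  dmax <- max(as.integer(names(truth$cut_dist)))
  if (dmax > nchar(protospacer)) abort("protospacer shorter than max cut distance")
  # expected fraction of uniform PAMs matching the truth, for batch sizing
  match_frac <- prod(vapply(strsplit(truth$pam_padded, "")[[1]],
                            function(ch) length(IUPAC_SETS[[ch]]) / 4,
                            numeric(1)))
  est_rate <- match_frac * truth$cleave_prob_match +
    (1 - match_frac) * truth$cleave_prob_nonmatch
  withr::with_seed(seed, {
    pams <- character(0)
    n_molecules <- 0L
    batch <- max(1000L, ceiling(1.3 * n / max(est_rate, 1e-6)))
    while (length(pams) < n) {
      cols <- lapply(seq_len(truth$pam_length), function(i) .sample_bases(batch))
      cand <- do.call(paste0, cols)
      hit <- iupac_match(truth$pam_padded, cand)
      p <- ifelse(hit, truth$cleave_prob_match, truth$cleave_prob_nonmatch)
      cleaved <- runif(batch) < p
      pams <- c(pams, cand[cleaved])
      n_molecules <- n_molecules + batch
    }
    pams <- pams[seq_len(n)]
    k <- n
    d <- as.integer(sample(names(truth$cut_dist), k, replace = TRUE,
                           prob = truth$cut_dist))
    Lp <- nchar(protospacer)
    remnant <- substr(rep(protospacer, k), Lp - d + 1L, Lp)
    reads <- paste0(layout$adapter, remnant, pams, layout$anchor)
    reads <- .apply_error(reads, truth$error_rate)
    flip <- runif(k) < truth$orientation_mix
    reads[flip] <- reverse_complement(reads[flip])
    out <- tibble(
      id = sprintf("sim%06d", seq_len(k)),
      sequence = reads,
      quality = lapply(nchar(reads), function(L) rep(37L, L))
    )
    attr(out, "truth") <- list(
      pam_iupac = truth$pam_iupac, pam_padded = truth$pam_padded,
      cut_dist = as.list(truth$cut_dist),
      error_rate = truth$error_rate,
      orientation_mix = truth$orientation_mix,
      n_molecules = n_molecules, n_reads = k, seed = seed,
      protospacer = protospacer
    )
    out
  })
}

#' Ground truth for a mismatch-tolerance simulation
#'
#' @param tolerated Positions (1-based from the PAM) where a mismatch is
#'   tolerated (still cleaved). The preset `pattern = "seed13_except9"` gives
#'   the canonical seed profile: intolerant at 1-13 except position 9,
#'   tolerated 14 onwards.
#' @param spacer_len Spacer length (default 24).
#' @param cleave_tolerated,cleave_intolerant Cleavage probabilities for
#'   tolerated-mismatch (and perfect-match) vs intolerant-mismatch plasmids.
#' @param depth_per_variant Input-library depth per variant.
#' @param pattern Optional preset overriding `tolerated`.
#' @return A `tolerance_truth` list.
#' @export
tolerance_truth <- function(tolerated = NULL, spacer_len = 24L,
                            cleave_tolerated = 0.99,
                            cleave_intolerant = 0.05,
                            depth_per_variant = 10000L,
                            pattern = NULL) {
  if (!is.null(pattern)) {
    if (pattern != "seed13_except9") abort("unknown tolerance pattern")
    tolerated <- c(9L, seq(14L, spacer_len))
  }
  if (is.null(tolerated)) abort("supply tolerated positions or a pattern")
  tolerated <- as.integer(tolerated)
  if (any(tolerated < 1 | tolerated > spacer_len)) {
    abort("tolerated positions outside the spacer")
  }
  structure(list(tolerated = tolerated, spacer_len = as.integer(spacer_len),
                 cleave_tolerated = cleave_tolerated,
                 cleave_intolerant = cleave_intolerant,
                 depth_per_variant = as.integer(depth_per_variant)),
            class = "tolerance_truth")
}

#' Simulate mismatch-library interference counts
#'
#' Input counts are a uniform multinomial draw at the stated depth; each
#' input molecule survives (escapes cleavage) as a Bernoulli with probability
#' `1 - cleave_p(variant)`, where perfect-match and tolerated-position
#' variants are cleaved at `cleave_tolerated` and intolerant-position
#' variants at `cleave_intolerant`.
#'
#' @param truth A [tolerance_truth()].
#' @param library A `variant_library` consistent with the truth spacer length.
#' @param seed Random seed.
#' @return List `counts_in`, `counts_out` (tibbles `variant_id`, `count`)
#'   with attribute `truth`.
#' @export
simulate_mismatch_counts <- function(truth, library, seed) {
  stopifnot(inherits(truth, "tolerance_truth"),
            inherits(library, "variant_library"))
  if (library$spacer_len != truth$spacer_len) {
    abort("library and truth disagree on spacer length")
  }
  v <- library$variants
  V <- nrow(v)
  withr::with_seed(seed, {
    total <- truth$depth_per_variant * V
    counts_in <- as.integer(rmultinom(1, total, rep(1 / V, V)))
    cleave_p <- ifelse(v$position == 0 | v$position %in% truth$tolerated,
                       truth$cleave_tolerated, truth$cleave_intolerant)
    counts_out <- rbinom(V, counts_in, 1 - cleave_p)
    out <- list(
      counts_in = tibble(variant_id = v$variant_id, count = counts_in),
      counts_out = tibble(variant_id = v$variant_id, count = counts_out)
    )
    attr(out, "truth") <- list(
      tolerated = truth$tolerated,
      intolerant = setdiff(seq_len(truth$spacer_len), truth$tolerated),
      cleave_tolerated = truth$cleave_tolerated,
      cleave_intolerant = truth$cleave_intolerant,
      depth_per_variant = truth$depth_per_variant, seed = seed
    )
    out
  })
}

#' Ground truth for an amplicon-editing simulation
#'
#' @param edit_spec Tibble `position`, `from_base`, `to_base`, `fraction`:
#'   each substitution is applied independently per read with its fraction.
#' @param indel_spec Optional list `position`, `length`, `type`
#'   (`"del"`/`"ins"`), `fraction`.
#' @param error_rate Per-base substitution error.
#' @return An `edit_truth` list.
#' @export
edit_truth <- function(edit_spec = NULL, indel_spec = NULL, error_rate = 0) {
  if (is.null(edit_spec)) {
    edit_spec <- tibble(position = integer(), from_base = character(),
                        to_base = character(), fraction = numeric())
  }
  edit_spec <- as_tibble(edit_spec)
  if (nrow(edit_spec) && any(edit_spec$fraction < 0 | edit_spec$fraction > 1)) {
    abort("edit fractions must lie in [0, 1]")
  }
  if (!is.null(indel_spec)) {
    stopifnot(all(c("position", "length", "type", "fraction") %in%
                    names(indel_spec)))
    if (!indel_spec$type %in% c("del", "ins")) abort("indel type: del or ins")
  }
  structure(list(edit_spec = edit_spec, indel_spec = indel_spec,
                 error_rate = error_rate),
            class = "edit_truth")
}

#' Simulate amplicon reads with planted edits
#'
#' Each read copies the reference, applies each substitution independently
#' with its fraction, applies the indel with its fraction, then per-base
#' substitution errors; qualities are constant Q37. A substitution planted
#' inside a deleted window is skipped (with a warning at generation).
#'
#' @param ref An [amplicon_ref()].
#' @param truth An [edit_truth()].
#' @param n Number of reads.
#' @param seed Random seed.
#' @return FASTQ record tibble with attribute `truth`.
#' @export
simulate_amplicon_reads <- function(ref, truth, n, seed) {
  stopifnot(inherits(ref, "amplicon_ref"), inherits(truth, "edit_truth"))
  if (n <= 0) abort("n must be positive")
  L <- nchar(ref$sequence)
  es <- truth$edit_spec
  if (nrow(es) && any(es$position < 1 | es$position > L)) {
    abort("edit positions outside the amplicon")
  }
  refchars <- strsplit(ref$sequence, "")[[1]]
  if (nrow(es)) {
    bad <- refchars[es$position] != toupper(es$from_base)
    if (any(bad)) abort("edit_spec from_base disagrees with the reference")
  }
  ind <- truth$indel_spec
  if (!is.null(ind) && ind$type == "del" && nrow(es)) {
    del_span <- seq(ind$position, ind$position + ind$length - 1L)
    if (any(es$position %in% del_span)) {
      warn("substitution planted inside the deleted window; skipped in deleted reads")
    }
  }
  withr::with_seed(seed, {
    mat <- matrix(rep(refchars, n), nrow = n, byrow = TRUE)
    if (nrow(es)) {
      for (k in seq_len(nrow(es))) {
        take <- runif(n) < es$fraction[k]
        mat[take, es$position[k]] <- toupper(es$to_base[k])
      }
    }
    reads <- apply(mat, 1, paste, collapse = "")
    if (!is.null(ind)) {
      take <- runif(n) < ind$fraction
      if (ind$type == "del") {
        reads[take] <- paste0(substr(reads[take], 1, ind$position - 1L),
                              substr(reads[take], ind$position + ind$length, L))
      } else {
        insert <- paste(.sample_bases(ind$length), collapse = "")
        reads[take] <- paste0(substr(reads[take], 1, ind$position - 1L),
                              insert,
                              substr(reads[take], ind$position, L))
      }
      indel_carrier <- take
    } else {
      indel_carrier <- rep(FALSE, n)
    }
    reads <- .apply_error(reads, truth$error_rate)
    out <- tibble(
      id = sprintf("amp%06d", seq_len(n)),
      sequence = reads,
      quality = lapply(nchar(reads), function(l) rep(37L, l))
    )
    attr(out, "truth") <- list(
      edit_spec = es, indel_spec = ind,
      n_indel_reads = sum(indel_carrier),
      error_rate = truth$error_rate, n = n, seed = seed
    )
    out
  })
}

#' Simulate a protein sequence with planted motifs and skewed composition
#'
#' Residues are drawn i.i.d. from `base_composition` multiplied by the
#' `boosts` and renormalized; planted literal motif instances overwrite
#' their windows. Overlapping planted motifs are an error.
#'
#' @param length Sequence length in residues.
#' @param base_composition Named residue distribution
#'   (default [reference_composition()]).
#' @param boosts Named multipliers, e.g. `c(R = 2.5, K = 2.5, M = 0.3)`.
#' @param planted_motifs Tibble/data.frame `instance`, `position` of literal
#'   motif occurrences to plant (1-based start).
#' @param seed Random seed.
#' @return Protein sequence string with attribute `truth`.
#' @export
simulate_protein <- function(length, base_composition = reference_composition(),
                             boosts = NULL, planted_motifs = NULL, seed = 1) {
  probs <- base_composition[AA_CANONICAL]
  if (anyNA(probs)) abort("base_composition must cover all 20 residues")
  if (!is.null(boosts)) {
    probs[names(boosts)] <- probs[names(boosts)] * boosts
  }
  probs <- probs / sum(probs)
  if (!is.null(planted_motifs)) {
    planted_motifs <- as_tibble(planted_motifs)
    ends <- planted_motifs$position + nchar(planted_motifs$instance) - 1L
    if (any(ends > length) || any(planted_motifs$position < 1)) {
      abort("planted motif does not fit in the sequence")
    }
    ord <- order(planted_motifs$position)
    if (nrow(planted_motifs) > 1 &&
        any(planted_motifs$position[ord][-1] <= ends[ord][-nrow(planted_motifs)])) {
      abort("planted motifs overlap")
    }
  }
  withr::with_seed(seed, {
    chars <- sample(AA_CANONICAL, length, replace = TRUE, prob = probs)
    if (!is.null(planted_motifs)) {
      for (k in seq_len(nrow(planted_motifs))) {
        inst <- strsplit(toupper(planted_motifs$instance[k]), "")[[1]]
        at <- planted_motifs$position[k]
        chars[at:(at + length(inst) - 1L)] <- inst
      }
    }
    out <- paste(chars, collapse = "")
    attr(out, "truth") <- list(
      length = length, boosts = as.list(boosts),
      planted_motifs = planted_motifs, seed = seed
    )
    out
  })
}
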