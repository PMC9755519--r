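# Fixture builders and independent oracles used across the suite. The
# oracles deliberately re-derive results by brute force (enumeration, direct
# tallies, closed forms) and never call the implementation paths they check.

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

random_protein <- function(len) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aas, len, replace = TRUE), collapse = "")
}

default_layout <- function() {
  assay_layout(adapter = "ACGCTCTTCCGATCT", anchor = "GTCGCCAGTTGACCTA")
}

# tibble of constant-quality records
records_tbl <- function(seqs, q = 37L, ids = paste0("r", seq_along(seqs))) {
  tibble::tibble(id = ids, sequence = seqs,
                 quality = lapply(nchar(seqs), function(L) rep(q, L)))
}

# --- motif oracle -----------------------------------------------------------
# Brute-force scanner over a hand-written element list. Elements:
#   list("fixed", "R"); list("any"); list("gap", lo, hi); list("alt", c("C","H"))
# At every start, gap length combinations are tried in lexicographic order
# and the first (shortest-lex) success is reported.
brute_motif_scan <- function(seq, elements) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  gaps <- which(vapply(elements, function(e) e[[1]] == "gap", TRUE))
  gap_ranges <- lapply(elements[gaps], function(e) seq(e[[2]], e[[3]]))
  combos <- if (length(gaps)) {
    as.matrix(rev(expand.grid(rev(gap_ranges))))  # lexicographic order
  } else matrix(integer(), nrow = 1, ncol = 0)

  starts <- integer(); ends <- integer()
  for (s in seq_len(L)) {
    for (ci in seq_len(nrow(combos))) {
      pos <- s
      ok <- TRUE
      gi <- 0
      for (e in elements) {
        kind <- e[[1]]
        if (kind == "gap") {
          gi <- gi + 1
          pos <- pos + combos[ci, gi]
        } else {
          if (pos > L) { ok <- FALSE; break }
          ch <- chars[pos]
          ok <- switch(kind,
                       fixed = ch == e[[2]],
                       any = TRUE,
                       alt = ch %in% e[[2]])
          if (!ok) break
          pos <- pos + 1
        }
      }
      if (ok && pos - 1 <= L) {
        starts <- c(starts, as.integer(s)); ends <- c(ends, as.integer(pos - 1))
        break  # shortest-lex match at this start
      }
    }
  }
  tibble::tibble(start = starts, end = ends)
}

# element lists for the screen's patterns
MOTIF_ELEMENTS <- list(
  "RRXRR" = list(list("fixed", "R"), list("fixed", "R"), list("any"),
                 list("fixed", "R"), list("fixed", "R")),
  "CX(2-4)C" = list(list("fixed", "C"), list("gap", 2, 4), list("fixed", "C")),
  "CX(2-4)H" = list(list("fixed", "C"), list("gap", 2, 4), list("fixed", "H")),
  "HX(2-4)C" = list(list("fixed", "H"), list("gap", 2, 4), list("fixed", "C")),
  "CX(2,4)CX(27,31)CX(2,4)[C/H]" = list(
    list("fixed", "C"), list("gap", 2, 4), list("fixed", "C"),
    list("gap", 27, 31), list("fixed", "C"), list("gap", 2, 4),
    list("alt", c("C", "H")))
)

# --- duplex oracle ----------------------------------------------------------
# Best ungapped local complementarity alignment: enumerate every start pair
# of (repeat, reversed tracr) and every extension length; +1 for a
# complementary (or wobble) pair, -2 otherwise; best prefix score wins.
brute_duplex_score <- function(repeat_seq, tracr_seq, allow_wobble = TRUE) {
  comp_ok <- function(a, b) {
    wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
          (a == "C" & b == "G") | (a == "G" & b == "C")
    if (allow_wobble) wc | (a == "G" & b == "T") | (a == "T" & b == "G") else wc
  }
  r <- strsplit(repeat_seq, "")[[1]]
  t_rev <- rev(strsplit(tracr_seq, "")[[1]])
  best <- 0
  for (i0 in seq_along(r)) {
    for (j0 in seq_along(t_rev)) {
      run <- 0
      k <- 0
      while (i0 + k <= length(r) && j0 + k <= length(t_rev)) {
        run <- run + if (comp_ok(r[i0 + k], t_rev[j0 + k])) 1 else -2
        if (run > best) best <- run
        k <- k + 1
      }
    }
  }
  best
}

# Exhaustive enumeration over every monotone base pairing (gaps allowed):
# any local alignment is a strictly increasing matching of repeat positions to
# reversed-tracr positions; its score is the sum of column scores (+1
# complementary / -2 otherwise) minus 3 per base skipped between consecutive
# matched columns. Naive recursion over all chains; tiny inputs only.
brute_gapped_duplex_score <- function(repeat_seq, tracr_seq,
                                      allow_wobble = TRUE) {
  comp_ok <- function(a, b) {
    wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
          (a == "C" & b == "G") | (a == "G" & b == "C")
    if (allow_wobble) wc | (a == "G" & b == "T") | (a == "T" & b == "G") else wc
  }
  r <- strsplit(repeat_seq, "")[[1]]
  tv <- rev(strsplit(tracr_seq, "")[[1]])
  n <- length(r); m <- length(tv)
  s <- function(i, j) if (comp_ok(r[i], tv[j])) 1 else -2
  chain <- function(i, j) {
    best_ext <- 0
    if (i < n && j < m) for (i2 in (i + 1):n) for (j2 in (j + 1):m) {
      v <- -3 * ((i2 - i - 1) + (j2 - j - 1)) + chain(i2, j2)
      if (v > best_ext) best_ext <- v
    }
    s(i, j) + best_ext
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    v <- chain(i, j)
    if (v > best) best <- v
  }
  best
}

# --- alignment oracles ------------------------------------------------------
# Independent score-only affine-gap global DP (Gotoh), written separately
# from the compiled implementation.
oracle_affine_score <- function(read, ref, match = 2, mismatch = -3,
                                go = -8, ge = -1) {
  a <- strsplit(read, "")[[1]]; b <- strsplit(ref, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); D <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m)) D[1, j + 1] <- go + ge * j
  for (i in seq_len(n)) I[i + 1, 1] <- go + ge * i
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], D[i, j], I[i, j]) + s
      D[i + 1, j + 1] <- max(D[i + 1, j] + ge, M[i + 1, j] + go + ge,
                             I[i + 1, j] + go + ge)
      I[i + 1, j + 1] <- max(I[i, j + 1] + ge, M[i, j + 1] + go + ge,
                             D[i, j + 1] + go + ge)
    }
  }
  max(M[n + 1, m + 1], D[n + 1, m + 1], I[n + 1, m + 1])
}

# Exhaustive enumeration of every global alignment path (tiny inputs only):
# recursion over M/D/I moves, affine cost applied by tracking the last op.
oracle_exhaustive_score <- function(read, ref, match = 2, mismatch = -3,
                                    go = -8, ge = -1) {
  a <- strsplit(read, "")[[1]]; b <- strsplit(ref, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (j <= length(b)) {
      cost <- ge + if (last == "D") 0 else go
      best <- max(best, cost + rec(i, j + 1, "D"))
    }
    if (i <= length(a)) {
      cost <- ge + if (last == "I") 0 else go
      best <- max(best, cost + rec(i + 1, j, "I"))
    }
    best
  }
  rec(1, 1, "start")
}

# Independent Henderson-Hasselbalch net charge (EMBOSS pKa), for the pI checks
oracle_net_charge <- function(seq, pH) {
  ch <- strsplit(seq, "")[[1]]
  pka_pos <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
  pka_neg <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  counts_pos <- c(Nterm = 1, K = sum(ch == "K"), R = sum(ch == "R"),
                  H = sum(ch == "H"))
  counts_neg <- c(Cterm = 1, D = sum(ch == "D"), E = sum(ch == "E"),
                  C = sum(ch == "C"), Y = sum(ch == "Y"))
  sum(counts_pos / (1 + 10^(pH - pka_pos))) -
    sum(counts_neg / (1 + 10^(pka_neg - pH)))
}
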