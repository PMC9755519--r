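# adapter(15) + remnant + PAM(8) + anchor(16) fixtures built by hand
LAYOUT <- default_layout()

fixture_read <- function(remnant = "ACGTA", pam = "TGGATCAA",
                         layout = LAYOUT) {
  paste0(layout$adapter, remnant, pam, layout$anchor)
}

test_that("assay_layout validates the anchor length bounds", {
  expect_error(assay_layout("ACGT", strrep("A", 13)), "14-24")
  expect_error(assay_layout("ACGT", strrep("A", 25)), "14-24")
  expect_s3_class(assay_layout("ACGT", strrep("AC", 8)), "assay_layout")
})

test_that("locate_anchor finds exact hits in either orientation", {
  read <- fixture_read()  # adapter 15 + remnant 5 + PAM 8 -> anchor at 28
  hits <- locate_anchor(records_tbl(read), LAYOUT)
  expect_equal(hits$position, 28L)
  expect_equal(hits$orientation, "forward")

  rc <- locate_anchor(records_tbl(reverse_complement(read)), LAYOUT)
  expect_equal(rc$orientation, "reverse")
  expect_equal(rc$position, 28L)  # position within the re-oriented read

  # false-positive rate for a 16-mer anchor over random 100-mers is ~0
  set.seed(7)
  rand <- locate_anchor(records_tbl(random_dna(10000, 100)), LAYOUT)
  expect_equal(sum(!is.na(rand$position)), 0)
})

test_that("extract_observations reads off the PAM and cut distance", {
  obs <- extract_observations(
    records_tbl(fixture_read(remnant = "ACGTA", pam = "TGGATCAA")), LAYOUT)
  expect_equal(obs$pam, "TGGATCAA")
  expect_equal(obs$cut_distance, 5L)

  flush <- extract_observations(
    records_tbl(fixture_read(remnant = "", pam = "TGGATCAA")), LAYOUT)
  expect_equal(flush$cut_distance, 0L)

  # a read whose adapter is absent lands in the discard tally
  no_adapter <- paste0("TTTTTTTTTTTTTTT", "ACGTA", "TGGATCAA", LAYOUT$anchor)
  dropped <- extract_observations(records_tbl(no_adapter), LAYOUT)
  expect_equal(nrow(dropped), 0)
  d <- attr(dropped, "discards")
  expect_equal(d$n[d$reason == "adapter_not_found"], 1L)
})

test_that("simulated remnant lengths reproduce the cut-distance law", {
  probs <- c("5" = 0.55, "6" = 0.30, "7" = 0.15)
  set.seed(11)
  d <- sample(names(probs), 10000, replace = TRUE, prob = probs)
  reads <- fixture_read(remnant = substring(strrep("ACGTACG", 2), 1,
                                            as.integer(d)))
  obs <- extract_observations(records_tbl(reads), LAYOUT)
  got <- table(obs$cut_distance) / nrow(obs)
  for (k in names(probs)) {
    p <- probs[[k]]
    sigma <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(got[[k]] - p), 3 * sigma + 1e-9)
  }
})

test_that("build_profile filters to modal cut +/-2 and recovers consensus", {
  # degenerate: identical PAMs
  obs <- tibble::tibble(pam = rep("AGGTTTTT", 50), cut_distance = rep(5L, 50))
  prof <- build_profile(obs)
  expect_equal(prof$modal_cut, 5L)
  expect_gt(prof$pfm[1, "A"], 0.95)
  expect_equal(substr(prof$consensus, 1, 3), "AGG")

  # 20% re-ligation artifacts at distance 15 are excluded
  arte <- tibble::tibble(pam = rep("AGGTTTTT", 1000),
                         cut_distance = c(rep(5L, 800), rep(15L, 200)))
  prof2 <- build_profile(arte)
  expect_equal(prof2$n_retained / prof2$n_raw, 0.8)
  expect_true(all(abs(prof2$retained_cuts - prof2$modal_cut) <= 2))

  expect_error(build_profile(tibble::tibble()), "no PAM observations")
})

test_that("modal-cut ties break toward the smaller distance", {
  obs <- tibble::tibble(pam = rep("AGGTTTTT", 20),
                        cut_distance = rep(c(4L, 6L), each = 10))
  expect_equal(build_profile(obs)$modal_cut, 4L)
})

test_that("call_consensus maps qualifying base sets to IUPAC codes", {
  pfm <- rbind(c(0.05, 0.05, 0.85, 0.05),
               c(0.45, 0.02, 0.51, 0.02),
               c(0.25, 0.25, 0.25, 0.25))
  colnames(pfm) <- c("A", "C", "G", "T")
  expect_equal(call_consensus(pfm), "GRN")
  expect_error(call_consensus(pfm, 0), "include_threshold")
  expect_error(call_consensus(pfm, 1.5), "include_threshold")
  bad <- pfm; bad[1, 1] <- 0.5
  expect_error(call_consensus(bad), "sum to 1")
})

test_that("logo heights are information-scaled frequencies", {
  # pure-G column without pseudocount carries the full 2 bits
  obs <- tibble::tibble(pam = rep("GGGGGGGG", 100), cut_distance = rep(5L, 100))
  prof <- build_profile(obs, pseudocount = 0)
  lm_tab <- logo_matrix(prof)
  g1 <- lm_tab[lm_tab$position == 1 & lm_tab$base == "G", ]
  expect_equal(g1$height, 2)

  # uniform column: zero information, zero heights
  upfm <- matrix(0.25, nrow = 1, ncol = 4,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  uprof <- structure(list(pfm = upfm, information_bits = 0),
                     class = "pam_profile")
  expect_true(all(abs(logo_matrix(uprof)$height) < 1e-12))

  # column sums equal the information content
  sums <- tapply(lm_tab$height, lm_tab$position, sum)
  expect_equal(as.numeric(sums), prof$information_bits, tolerance = 1e-9)
})

test_that("infer_overhang classifies cut geometry", {
  five <- infer_overhang(3, c(5L, 6L, 7L))
  expect_equal(five$overhang_type, "five_prime")
  expect_equal(five$overhang_lengths, c(2L, 3L, 4L))

  expect_equal(infer_overhang(3, 3L)$overhang_type, "blunt")

  three <- infer_overhang(5, 4L)
  expect_equal(three$overhang_type, "three_prime")
  expect_equal(three$overhang_lengths, 1L)  # magnitude; sign in the type

  expect_error(infer_overhang(5, c(4L, 6L)), "inconsistent cut geometry")
})

test_that("consensus recovery holds over random degenerate truths", {
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V")
  layout <- LAYOUT
  set.seed(99)
  for (rep_i in 1:20) {
    k <- sample(1:4, 1)
    truth_chars <- rep("N", 8)
    truth_chars[seq_len(k)] <- sample(codes, k, replace = TRUE)
    truth_str <- sub("N+$", "", paste(truth_chars, collapse = ""))
    if (truth_str == "") truth_str <- sample(codes, 1)
    tr <- pam_truth(truth_str, cleave_prob_match = 1,
                    cleave_prob_nonmatch = 0, error_rate = 0)
    reads <- simulate_pam_reads(tr, layout, 5000, seed = 1000 + rep_i)
    prof <- build_profile(extract_observations(reads, layout))
    expect_equal(prof$consensus, tr$pam_padded,
                 label = paste("truth", tr$pam_padded))
  }
})

test_that("the profile is invariant to reverse-complementing every read", {
  tr <- pam_truth("NGG", error_rate = 0)
  reads <- simulate_pam_reads(tr, LAYOUT, 3000, seed = 5)
  fwd <- build_profile(extract_observations(reads, LAYOUT))
  flipped <- reads
  flipped$sequence <- reverse_complement(reads$sequence)
  rev <- build_profile(extract_observations(flipped, LAYOUT))
  expect_equal(rev$pfm, fwd$pfm)
  expect_equal(rev$modal_cut, fwd$modal_cut)
  expect_equal(rev$consensus, fwd$consensus)
})

test_that("information content never rises with base-call error", {
  info_tot <- vapply(c(0, 0.01, 0.05), function(e) {
    tr <- pam_truth("NGG", error_rate = e)
    reads <- simulate_pam_reads(tr, LAYOUT, 4000, seed = 21)
    prof <- build_profile(extract_observations(reads, LAYOUT))
    sum(prof$information_bits)
  }, numeric(1))
  expect_true(all(diff(info_tot) <= 0))
})
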