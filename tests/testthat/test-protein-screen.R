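test_that("aa_composition excludes ambiguity codes from both sides", {
  expect_equal(aa_composition("RRRR")[["R"]], 1)
  comp <- aa_composition("RKRKX")
  expect_equal(comp[["R"]], 0.5)
  expect_equal(comp[["K"]], 0.5)
  expect_error(aa_composition("XXX"), "no canonical residues")

  # long draw from a known distribution lands within binomial error
  set.seed(31)
  probs <- reference_composition()
  aas <- sample(names(probs), 10000, replace = TRUE, prob = probs)
  comp <- aa_composition(paste(aas, collapse = ""))
  for (r in names(probs)) {
    sigma <- sqrt(probs[[r]] * (1 - probs[[r]]) / 10000)
    expect_lt(abs(comp[[r]] - probs[[r]]), 3 * sigma + 1e-9)
  }
})

test_that("composition_deviation standardizes residuals off the OLS trend", {
  ref <- reference_composition()
  same <- composition_deviation(ref, ref)
  expect_true(all(abs(same$residual) < 1e-8))
  expect_length(attr(same, "flags"), 0)

  # double R and K, renormalize; closed-form OLS oracle on the 20 points
  obs <- ref
  obs[c("R", "K")] <- obs[c("R", "K")] * 2
  obs <- obs / sum(obs)
  dev <- composition_deviation(obs, ref)
  beta <- cov(obs, ref) / var(ref)
  alpha <- mean(obs) - beta * mean(ref)
  res <- obs - (alpha + beta * ref)
  z_oracle <- res / sqrt(sum(res^2) / 18)
  expect_equal(dev$residual, unname(z_oracle[dev$residue]), tolerance = 1e-9)
  top2 <- dev$residue[order(-dev$residual)][1:2]
  expect_setequal(top2, c("R", "K"))

  expect_error(composition_deviation(obs, setNames(rep(0.05, 20), names(ref))),
               "degenerate")
})

test_that("a planted R/K-inflated, M-deflated composition raises both flags", {
  # residual vector (+d, +d, -d) on R/K/M against an otherwise perfect fit:
  # residual sd is d*sqrt(3/18), so the planted residues sit near +-2.4 sigma
  ref <- reference_composition()
  d <- 0.02
  obs <- ref
  obs[c("R", "K")] <- obs[c("R", "K")] + d
  obs["M"] <- obs["M"] - d
  obs <- obs / sum(obs)
  flags <- attr(composition_deviation(obs, ref), "flags")
  expect_true("arg_lys_enriched" %in% flags)
  expect_true("met_depleted" %in% flags)
})

test_that("composition_deviation depends on composition, not length", {
  a <- composition_deviation(aa_composition(strrep("ARNDCQEGHILKMFPSTWYV", 2)))
  b <- composition_deviation(aa_composition(strrep("ARNDCQEGHILKMFPSTWYV", 40)))
  expect_equal(a$residual, b$residual, tolerance = 1e-12)
})

test_that("find_motifs matches the grammar with shortest-match gaps", {
  expect_equal(find_motifs("ARRQRRV", "RRXRR"),
               tibble::tibble(start = 2L, end = 6L))
  expect_equal(find_motifs("CAAC", "CX(2-4)C"),
               tibble::tibble(start = 1L, end = 4L))
  expect_equal(nrow(find_motifs("CAC", "CX(2-4)C")), 0)  # gap below 2

  # overlapping matches are all reported
  expect_equal(find_motifs("RRRRRR", "RRXRR")$start, c(1L, 2L))

  # Zn-finger planted at position 100
  set.seed(12)
  motif <- "CAACAWLDERTGHKLMNPQRSTVWYAACDEFGHCAGH"  # C.2.C.27.C.3.H
  seq <- simulate_protein(200, planted_motifs = tibble::tibble(
    instance = motif, position = 100L), seed = 9)
  hits <- find_motifs(seq, "CX(2,4)CX(27,31)CX(2,4)[C/H]")
  expect_true(100L %in% hits$start)

  expect_error(find_motifs("ACDE", "CX(4,2)C"), "out of order")
  expect_error(find_motifs("ACDE", "C[AB"), "unclosed")
})

test_that("find_motifs agrees with the brute-force scanner", {
  set.seed(55)
  for (pat in names(MOTIF_ELEMENTS)) {
    for (i in 1:200) {
      # enrich C/H/R so the patterns actually fire
      aas <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C", "C", "H", "R", "R")
      s <- paste(sample(aas, 90, replace = TRUE), collapse = "")
      got <- find_motifs(s, pat)
      want <- brute_motif_scan(s, MOTIF_ELEMENTS[[pat]])
      expect_equal(got$start, want$start, label = paste(pat, "starts", i))
      expect_equal(got$end, want$end, label = paste(pat, "ends", i))
    }
  }
})

test_that("net charge is strictly decreasing and pI is its unique root", {
  set.seed(66)
  for (i in 1:50) {
    s <- random_protein(sample(30:200, 1))
    ph <- seq(0, 14, by = 0.5)
    q <- net_charge(s, ph)
    expect_true(all(diff(q) < 0))
    pI <- isoelectric_point(s)
    expect_lt(abs(net_charge(s, pI)), 0.01)
    expect_lt(abs(oracle_net_charge(s, pI)), 0.01)  # independent HH form
  }
})

test_that("extreme compositions drive the pI to the expected ends", {
  expect_gt(isoelectric_point(strrep("R", 20)), 12)
  expect_lt(isoelectric_point(strrep("D", 20)), 4)
  # closed-form cross-check for poly-D: root of the independent formula
  oracle_root <- uniroot(function(p) oracle_net_charge(strrep("D", 20), p),
                         c(0, 14), tol = 1e-9)$root
  expect_equal(isoelectric_point(strrep("D", 20)), oracle_root,
               tolerance = 1e-3)
})

test_that("appending arginines never lowers the pI", {
  set.seed(13)
  for (i in 1:50) {
    s <- random_protein(sample(20:100, 1))
    expect_gte(isoelectric_point(paste0(s, "RRRR")) + 1e-6,
               isoelectric_point(s))
  }
})

test_that("smart_screen applies the size, composition, and motif verdict", {
  smartish <- simulate_protein(
    500, boosts = c(R = 2.5, K = 2.5, M = 0.3),
    planted_motifs = tibble::tibble(instance = c("RRQRR", "CAAC", "CDDC"),
                                    position = c(50L, 200L, 300L)),
    seed = 101)
  rep1 <- smart_screen(smartish)
  expect_true(rep1$smart_like)
  expect_true("size_compact" %in% rep1$flags)
  expect_gte(rep1$motif_counts[["RRXRR"]], 1)

  # SpCas9-sized sequences fail on size alone
  big <- simulate_protein(1376, boosts = c(R = 2.5, K = 2.5),
                          planted_motifs = tibble::tibble(
                            instance = "RRQRR", position = 10L), seed = 102)
  rep2 <- smart_screen(big)
  expect_false("size_compact" %in% rep2$flags)
  expect_false(rep2$smart_like)

  # unremarkable composition without motifs is not SMART-like
  plain <- simulate_protein(500, seed = 103)
  expect_false(smart_screen(plain)$smart_like)
})

test_that("screen_proteins ranks SMART-like sequences first", {
  smartish <- simulate_protein(500, boosts = c(R = 2.5, K = 2.5),
                               planted_motifs = tibble::tibble(
                                 instance = "RRQRR", position = 50L),
                               seed = 104)
  plain <- simulate_protein(500, seed = 105)
  ranked <- screen_proteins(tibble::tibble(id = c("plain", "cand"),
                                           sequence = c(plain, smartish)))
  expect_equal(ranked$id[1], "cand")
  expect_true(ranked$smart_like[1])
})
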