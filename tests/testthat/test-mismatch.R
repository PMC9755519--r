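SPACER <- "GTAATGCCTTAACGGATTCGCAGT"  # 24 nt, PAM at the 3' end
LIB <- single_mismatch_library(SPACER)

test_that("single_mismatch_library builds the 24+1 layout", {
  expect_equal(nrow(LIB$variants), 25)
  expect_setequal(LIB$variants$position, 0:24)
  # position p from the PAM is string index L - p + 1
  v1 <- LIB$variants[LIB$variants$position == 1, ]
  expect_equal(substr(v1$protospacer, 24, 24), v1$alt_base)
  expect_equal(substr(SPACER, 24, 24), v1$ref_base)
})

test_that("variant_library rejects malformed libraries", {
  v <- LIB$variants
  v$protospacer[2] <- v$protospacer[3]
  expect_error(variant_library(SPACER, v), "identical protospacer")

  v <- LIB$variants
  v$position[2] <- 5L  # wrong claimed position
  expect_error(variant_library(SPACER, v), "single mismatch")
})

test_that("count_variants assigns reads only on exact protospacer match", {
  flank5 <- "GGATCC"; flank3 <- "GAATTC"
  mk_reads <- function(protos) records_tbl(paste0("TT", flank5, protos, flank3, "AA"))

  counts <- count_variants(mk_reads(rep(SPACER, 100)), LIB, flank5, flank3)
  expect_equal(counts$count[counts$variant_id == "perfect"], 100L)
  expect_equal(sum(counts$count), 100L)

  two_mm <- paste0("CC", substr(SPACER, 3, 24))  # 2 mismatches: no variant
  res <- count_variants(mk_reads(two_mm), LIB, flank5, flank3)
  expect_equal(sum(res$count), 0L)
  expect_equal(attr(res, "unassigned"), 1L)

  # seeded multinomial mixture: counts equal a direct tally of the draw
  set.seed(20)
  picks <- sample(LIB$variants$variant_id, 20000, replace = TRUE)
  protos <- LIB$variants$protospacer[match(picks, LIB$variants$variant_id)]
  got <- count_variants(mk_reads(protos), LIB, flank5, flank3)
  want <- table(factor(picks, levels = got$variant_id))
  expect_equal(got$count, as.integer(want))
})

test_that("enrichment is a pseudocounted log2 relative-frequency ratio", {
  ids <- paste0("v", 1:5)
  inn <- setNames(c(100, 200, 300, 400, 500), ids)
  e0 <- enrichment(inn, inn)  # identical libraries
  expect_true(all(abs(e0$log2_enrichment) < 1e-12))
  # equal proportions at different depths: exactly zero without pseudocount
  e0p <- enrichment(inn * 3, inn, pseudocount = 0)
  expect_true(all(abs(e0p$log2_enrichment) < 1e-12))

  out <- inn; out["v1"] <- 0
  e <- enrichment(out, inn)
  expect_lt(e$log2_enrichment[e$variant_id == "v1"], 0)  # depleted

  # closed-form: expected survivor frequencies under cleavage 0.99 vs 0.05
  depth <- 10000
  surv <- c(rep(depth * (1 - 0.99), 12), rep(depth * (1 - 0.05), 13))
  names(surv) <- paste0("x", 1:25)
  inn2 <- setNames(rep(depth, 25), names(surv))
  e2 <- enrichment(surv, inn2)
  tol_e <- e2$log2_enrichment[1:12]
  intol_e <- e2$log2_enrichment[13:25]
  expect_gt(min(intol_e) - max(tol_e), 3)

  expect_error(enrichment(numeric(0), inn), "empty|named")
})

test_that("enrichment is scale-invariant and antisymmetric", {
  set.seed(4)
  ids <- LIB$variants$variant_id
  inn <- setNames(rpois(25, 800) + 1, ids)
  out <- setNames(rpois(25, 400) + 1, ids)
  # exact scale invariance in the pseudocount-free form; with the default
  # pseudocount the invariance is asymptotic in depth
  base0 <- enrichment(out, inn, pseudocount = 0)
  scaled0 <- enrichment(out * 7, inn, pseudocount = 0)
  expect_equal(scaled0$log2_enrichment, base0$log2_enrichment,
               tolerance = 1e-12)
  base <- enrichment(out, inn)
  scaled <- enrichment(out * 7, inn)
  expect_equal(scaled$log2_enrichment, base$log2_enrichment, tolerance = 0.02)

  swapped <- enrichment(inn, out)
  expect_equal(swapped$log2_enrichment, -base$log2_enrichment,
               tolerance = 1e-9)
})

test_that("position_calls anchors on the perfect-match enrichment", {
  ids <- LIB$variants$variant_id
  flat <- tibble::tibble(variant_id = ids, log2_enrichment = 1.7)
  tm <- position_calls(flat, LIB)
  expect_true(all(tm$positions$call == "tolerated"))

  sim <- simulate_mismatch_counts(
    tolerance_truth(pattern = "seed13_except9", depth_per_variant = 10000),
    LIB, seed = 42)
  tm2 <- tolerance_map(sim$counts_out, sim$counts_in, LIB)
  truth <- attr(sim, "truth")
  called_intol <- tm2$positions$position[tm2$positions$call == "intolerant"]
  expect_setequal(called_intol, truth$intolerant)
  expect_setequal(tm2$positions$position[tm2$positions$call == "tolerated"],
                  truth$tolerated)

  inf_margin <- position_calls(tm2$enrichment, LIB, margin = Inf)
  expect_true(all(inf_margin$positions$call == "tolerated"))
})

test_that("heatmap_table leaves unassayed cells empty, not zero", {
  sim <- simulate_mismatch_counts(
    tolerance_truth(pattern = "seed13_except9", depth_per_variant = 1000),
    LIB, seed = 8)
  tm <- tolerance_map(sim$counts_out, sim$counts_in, LIB)
  ht <- heatmap_table(tm)
  expect_equal(nrow(ht), 24 * 4)
  expect_equal(sum(!is.na(ht$log2_enrichment)), 24)  # one alt base per position
  # the filled cell at each position is the library's alt base
  filled <- ht[!is.na(ht$log2_enrichment), ]
  lut <- LIB$variants[LIB$variants$position > 0, ]
  expect_equal(filled$alt_base[order(filled$position)],
               lut$alt_base[order(lut$position)])
})

test_that("position calls recover 50 random tolerance truths exactly", {
  set.seed(77)
  for (i in 1:50) {
    tol <- which(runif(24) < 0.5)
    if (length(tol) == 24) tol <- tol[-1]  # keep at least one intolerant
    tr <- tolerance_truth(tolerated = tol, depth_per_variant = 5000)
    sim <- simulate_mismatch_counts(tr, LIB, seed = 3000 + i)
    tm <- tolerance_map(sim$counts_out, sim$counts_in, LIB)
    calls <- tm$positions
    expect_setequal(calls$position[calls$call == "tolerated"], tol)
    expect_setequal(calls$position[calls$call == "intolerant"],
                    setdiff(1:24, tol))
  }
})
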