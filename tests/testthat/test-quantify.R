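test_that("fractions and fold enrichment follow the definition arithmetic", {
  vt <- fractions_and_fold(c(A = 25, B = 975), c(A = 80, B = 20))
  expect_equal(vt$frac_pre[vt$genotype == "A"], 0.025)
  expect_equal(vt$frac_post[vt$genotype == "A"], 0.80)
  expect_equal(vt$fold_enrichment[vt$genotype == "A"], 32.0)
  same <- fractions_and_fold(c(A = 10, B = 30), c(A = 10, B = 30))
  expect_equal(same$fold_enrichment, c(1, 1))
})

test_that("fractions are invariant to count rescaling and zeros are flagged", {
  a <- fractions_and_fold(c(A = 3, B = 7), c(A = 6, B = 4))
  b <- fractions_and_fold(c(A = 300, B = 700), c(A = 60, B = 40))
  expect_equal(a$frac_pre, b$frac_pre)
  expect_equal(a$fold_enrichment, b$fold_enrichment)
  z <- fractions_and_fold(c(A = 0, B = 10), c(A = 5, B = 5))
  expect_true(z$flagged[z$genotype == "A"])
  expect_true(is.na(z$fold_enrichment[z$genotype == "A"]))
  expect_error(fractions_and_fold(c(A = 0, B = 0), c(A = 1, B = 1)), "zero total")
  expect_error(fractions_and_fold(c(A = 1), c(B = 1)), "same genotype")
})

test_that("replicate summaries average per-replicate fold, not pooled counts", {
  t1 <- fractions_and_fold(c(A = 10, B = 390), c(A = 8, B = 2))
  t2 <- fractions_and_fold(c(A = 10, B = 390), c(A = 6, B = 4))
  s <- summarize_replicates(list(t1, t2))
  expect_equal(s$fold_mean[s$genotype == "A"],
               mean(c(t1$fold_enrichment[1], t2$fold_enrichment[1])))
  expect_equal(s$fold_sd[s$genotype == "A"],
               sd(c(t1$fold_enrichment[1], t2$fold_enrichment[1])))
})

test_that("a perfect-doubling dilution series gives slope -1/log10(2)", {
  conc <- 10^seq(-5, 2)
  cq <- 20 - log2(conc)  # one cycle per doubling
  curve <- fit_standard_curve(conc, cq)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(curve$r_squared, 1)
  expect_equal(curve$efficiency, 1, tolerance = 1e-9)
})

test_that("noisy dilution series recovers the slope within +/- 0.1", {
  set.seed(12)
  conc <- 10^seq(-5, 2)
  cq <- 20 - log2(conc) + rnorm(8, 0, 0.1)
  curve <- fit_standard_curve(conc, cq)
  # se(slope) = 0.1 / sqrt(sum((log10 c - mean)^2)) ~= 0.015, so 0.1 is > 6 se
  expect_lt(abs(curve$slope + 3.3219), 0.1)
  expect_error(fit_standard_curve(c(1, 1, 1), c(20, 20, 20)), "distinct")
})

test_that("concentration inversion round-trips and respects doubling", {
  conc <- 10^seq(-4, 2)
  cq <- 19.3 - log2(conc)
  curve <- fit_standard_curve(conc, cq)
  expect_equal(qpcr_concentration(cq, curve), conc, tolerance = 1e-9)
  expect_equal(qpcr_concentration(curve$intercept, curve), 1)
  expect_equal(qpcr_concentration(10, curve) / qpcr_concentration(11, curve),
               2, tolerance = 1e-9)
  bad <- curve; bad$slope <- 1
  expect_error(qpcr_concentration(10, bad), "slope")
})

test_that("the read length filter keeps the closed 1100-1400 window", {
  mkread <- function(n) paste(rep("A", n), collapse = "")
  recs <- data.frame(id = as.character(1:10),
                     sequence = vapply(c(1000, 1099, 1100, 1200, 1398, 1400,
                                         1401, 500, 1250, 1300), mkread, ""))
  kept <- filter_reads(recs)
  expect_equal(nrow(kept), 6L)
  expect_false(any(nchar(kept$sequence) < 1100 | nchar(kept$sequence) > 1400))
  expect_equal(nrow(filter_reads(recs[0, , drop = FALSE])), 0L)
  expect_error(filter_reads(list(1, 2)), "sequence")
})

test_that("single-variant pools count entirely to that variant", {
  r <- generate_reads(c(Var7 = 1), 200, error_rate = 0, junk_frac = 0, seed = 2)
  cv <- count_variants(filter_reads(r))
  expect_equal(names(cv$counts), "Var7")
  expect_equal(unname(cv$counts), 200)
  expect_equal(unname(cv$qc["ok"]), 200L)
})

test_that("variant counting is orientation invariant", {
  r <- generate_reads(c(Var1 = 0.5, Var3 = 0.5), 300, error_rate = 0,
                      junk_frac = 0, seed = 9)
  cv_fwd <- count_variants(r)
  rc <- r
  rc$sequence <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(r$sequence)))
  cv_rc <- count_variants(rc)
  expect_equal(cv_fwd$counts[sort(names(cv_fwd$counts))],
               cv_rc$counts[sort(names(cv_rc$counts))])
})

test_that("ambiguous and missing anchors are discarded into QC", {
  ex <- mts_extractor()
  ref <- mts_reference()
  good <- ref$sequence
  # duplicate the left flank elsewhere in the read
  dup <- paste0(ex$left_flank, substr(good, 1, nchar(good)))
  noflank <- paste(rep("ACGT", 300), collapse = "")
  nwin <- good
  substr(nwin, ref$window_start, ref$window_start) <- "N"
  recs <- data.frame(id = c("g", "d", "m", "n"),
                     sequence = c(good, dup, noflank, nwin))
  cv <- count_variants(recs)
  expect_equal(unname(cv$qc["ok"]), 1L)
  expect_equal(unname(cv$qc["ambiguous_flank"]), 1L)
  expect_equal(unname(cv$qc["missing_flank"]), 1L)
  expect_equal(unname(cv$qc["ambiguous_base"]), 1L)
  expect_equal(sum(cv$counts), 1)
})

test_that("post-sort counts conserve successfully extracted reads", {
  r <- generate_reads(c(Var1 = 0.3, Var7 = 0.7), 500, error_rate = 0.003,
                      junk_frac = 0.1, seed = 14)
  kept <- filter_reads(r)
  cv <- count_variants(kept)
  expect_equal(sum(cv$counts), unname(cv$qc["ok"]))
  expect_equal(sum(cv$qc), nrow(kept))
})

test_that("estimated fractions converge to the loaded pool fractions", {
  fr <- c(Var1 = 0.6, Var7 = 0.4)
  r <- generate_reads(fr, 4000, error_rate = 0.002, junk_frac = 0, seed = 77)
  cv <- count_variants(filter_reads(r))
  est <- cv$counts / sum(cv$counts)
  ci <- qbinom(c(0.005, 0.995), sum(cv$counts), 0.6) / sum(cv$counts)
  expect_gte(est[["Var1"]], ci[1])
  expect_lte(est[["Var1"]], ci[2])
})

test_that("a sorted pool loaded with two variants reports exactly those two", {
  pre <- setNames(rep(1 / 9, 9), paste0("Var", 1:9))
  post <- c(Var1 = 0.55, Var7 = 0.45)
  r_pre <- generate_reads(pre, 900, error_rate = 0, junk_frac = 0, seed = 41)
  r_post <- generate_reads(post, 900, error_rate = 0, junk_frac = 0, seed = 42)
  c_pre <- count_variants(filter_reads(r_pre))$counts
  c_post <- count_variants(filter_reads(r_post))$counts
  expect_setequal(names(c_post), c("Var1", "Var7"))
  all9 <- setNames(rep(0, 9), paste0("Var", 1:9))
  cp <- all9; cp[names(c_pre)] <- c_pre
  cq <- all9; cq[names(c_post)] <- c_post
  vt <- fractions_and_fold(cp, cq)
  enriched <- vt$genotype[vt$frac_post > 0]
  expect_setequal(enriched, c("Var1", "Var7"))
})
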