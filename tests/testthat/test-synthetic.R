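test_that("cohort generator is deterministic given the seed, down to bytes", {
  cfg <- cohort_config(n_sites = 40, somatic_per_line = 5, seed = 77)
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  b1 <- generate_cohort(cfg, path = p1)
  b2 <- generate_cohort(cfg, path = p2)
  expect_identical(b1$variants, b2$variants)
  expect_identical(b1$truth, b2$truth)
  expect_identical(readLines(p1), readLines(p2))
  # and a different seed changes the draw
  b3 <- generate_cohort(cohort_config(n_sites = 40, somatic_per_line = 5,
                                      seed = 78))
  expect_false(identical(b1$variants, b3$variants))
})

test_that("with noise off, planted somatic SNVs are recovered exactly", {
  b <- generate_cohort(cohort_config(n_sites = 80, somatic_per_line = 25,
                                     depth_mean = 100, seed = 4))
  for (l in b$config$lines) {
    som <- call_somatic(b$variants, "parental", l)
    planted <- b$truth[b$truth$sample == l, ]
    expect_equal(nrow(som), 25L)
    expect_setequal(paste(som$chrom, som$pos), paste(planted$chrom, planted$pos))
  }
})

test_that("with all failure modes off the filter keeps every planted site", {
  b <- generate_cohort(cohort_config(n_sites = 0, somatic_per_line = 15,
                                     seed = 12))
  for (l in b$config$lines) {
    res <- apply_stringent_filter(b$variants, l)
    expect_true(all(res$verdicts$kept))
  }
})

test_that("configured clause-failure fractions eliminate sites accordingly", {
  cfg <- cohort_config(n_sites = 400, somatic_per_line = 0,
                       quality_fail_fracs = c(qual = 0.5, qd = 0, mq = 0,
                                              fs = 0, hs = 0, gq = 0),
                       seed = 6)
  b <- generate_cohort(cfg)
  v <- site_quality_filter(b$variants, "line1")
  frac_failed <- mean(!v$kept)
  expect_lt(abs(frac_failed - 0.5), 3 * sqrt(0.25 / 400))
  expect_true(all(unlist(v$reasons) == "QUAL_LT_400"))
})

test_that("planted spectrum and category mix are recovered at n = 1000", {
  probs12 <- setNames(c(0.3, rep(0.7 / 11, 11)),
                      c("C>T", setdiff(names(cohort_config()$spectrum_probs),
                                       "C>T")))
  cat_probs <- setNames(rep(0, 13), names(cohort_config()$category_probs))
  cat_probs[c("non_synonymous_coding", "synonymous_coding", "intron")] <-
    c(0.4, 0.2, 0.4)
  cfg <- cohort_config(n_sites = 0, somatic_per_line = 250,
                       spectrum_probs = probs12[names(cohort_config()$spectrum_probs)],
                       category_probs = cat_probs, seed = 19)
  b <- generate_cohort(cfg) # 4 x 250 = 1000 planted SNVs
  n <- nrow(b$truth)
  expect_equal(n, 1000L)
  sp <- mutation_spectrum(b$truth)
  obs_ct <- sp$counts12$n[sp$counts12$change == "C>T"] / n
  expect_lt(abs(obs_ct - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  tl <- tally_categories(b$truth)
  for (k in c("non_synonymous_coding", "synonymous_coding", "intron")) {
    p <- cat_probs[[k]]
    expect_lt(abs(tl$n[tl$category == k] / n - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("ambiguous planted calls pass the filter and appear on the list", {
  b <- generate_cohort(cohort_config(n_sites = 0, somatic_per_line = 40,
                                     ambiguous_frac = 0.3, seed = 23))
  expect_gt(nrow(b$ambiguous), 0)
  for (l in b$config$lines) {
    som <- call_somatic(b$variants, "parental", l)
    # ambiguous calls escape the automated filters...
    amb_l <- b$ambiguous[b$ambiguous$sample == l, ]
    expect_true(all(paste(amb_l$chrom, amb_l$pos) %in%
                      paste(som$chrom, som$pos)))
    # ...and are only removed by the manual exclusion list
    kept <- apply_exclusion_list(som, amb_l)$kept
    expect_equal(nrow(kept), nrow(som) - nrow(amb_l))
  }
})

test_that("structural region generator plants SNVs strictly inside regions", {
  spec <- tibble::tibble(chrom = c("chrA", "chrA", "chrB"),
                         length_kb = c(23314, 3586, 234),
                         event = c("CNLOH", "deletion", "deletion"),
                         n_snvs = c(2, 37, 1))
  reg <- generate_structural_regions(spec, seed = 3)
  expect_equal(nrow(reg$regions), 3L)
  expect_equal(reg$regions$length_kb, spec$length_kb)
  expect_equal(nrow(reg$planted), 40L)
  # all planted positions overlap their region by construction
  tagged <- match_regions(reg$planted, reg$regions)
  expect_identical(tagged$region_label, reg$planted$label)
  # non-overlap within a chromosome
  ca <- reg$regions[reg$regions$chrom == "chrA", ]
  ca <- ca[order(ca$start), ]
  expect_true(all(ca$end[-nrow(ca)] <= ca$start[-1]))
  expect_error(
    generate_structural_regions(
      tibble::tibble(chrom = "c", length_kb = 3e5, event = "other", n_snvs = 0),
      chrom_length_bp = 2.5e8, seed = 1),
    "exceed"
  )
  # zero regions give an empty interval set
  empty <- generate_structural_regions(spec[0, ], seed = 1)
  expect_equal(nrow(empty$regions), 0L)
})

test_that("Q-FISH generator hits the target ratio exactly when noise is off", {
  tfi <- generate_qfish(2.393, n_spreads = 14, dispersion = 0, seed = 5,
                        sample = "S", control = "C")
  qt <- qfish_table(tfi, tibble::tibble(sample = "S", control = "C"))
  expect_equal(qt$ratio, 2.393)
  expect_equal(qt$length_kbp, 16.54)
  one <- generate_qfish(1, n_spreads = 5, dispersion = 0, seed = 5,
                        sample = "S", control = "C")
  expect_equal(qfish_table(one, tibble::tibble(sample = "S",
                                               control = "C"))$length_kbp,
               6.91)
  expect_error(generate_qfish(-1, 5), "positive")
})

test_that("the fixed study scenario reproduces its stage counts end to end", {
  b <- scenario_paper(seed = 2)
  expect_equal(nrow(b$truth), 212L)
  res <- somatic_pipeline(b$variants, b$parental, b$lines, b$regions,
                          b$ambiguous)
  expect_equal(res$accounting$called, 212L)
  expect_setequal(unname(res$accounting$removed_by_region), c(2L, 37L, 1L))
  expect_equal(res$accounting$removed_manual, 5L)
  expect_equal(res$accounting$final, 167L)
  expect_equal(res$per_line$n_snvs, c(43L, 48L, 35L, 41L))
  # deterministic: the same seed reproduces the identical accounting
  b2 <- scenario_paper(seed = 2)
  res2 <- somatic_pipeline(b2$variants, b2$parental, b2$lines, b2$regions,
                           b2$ambiguous)
  expect_identical(glance(res$accounting), glance(res2$accounting))
  expect_identical(b$variants, b2$variants)
})
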