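test_that("category precedence resolves multi-label annotations", {
  expect_equal(resolve_category(c("downstream", "non_synonymous_coding")),
               "non_synonymous_coding")
  expect_equal(resolve_category("downstream"), "downstream")
  expect_equal(resolve_category(c("utr_3", "intron")), "utr_3")
  expect_error(resolve_category(character(0)), "no effect labels")
  expect_error(resolve_category("made_up"), "unknown")
  # exhaustive pairwise check against the precedence table itself
  for (i in seq_along(SNV_CATEGORIES)) {
    for (j in seq_along(SNV_CATEGORIES)) {
      expect_equal(
        resolve_category(c(SNV_CATEGORIES[i], SNV_CATEGORIES[j])),
        SNV_CATEGORIES[min(i, j)]
      )
    }
  }
  expect_equal(
    resolve_categories(c("downstream;non_synonymous_coding", "intron")),
    c("non_synonymous_coding", "intron")
  )
})

test_that("category tally reports explicit zeros and conserves the total", {
  snvs <- tibble::tibble(category = c(rep("non_synonymous_coding", 3),
                                      "synonymous_coding"))
  tl <- tally_categories(snvs)
  expect_equal(nrow(tl), 13L)
  expect_equal(sum(tl$n), 4L)
  expect_equal(tl$n[tl$category == "non_synonymous_coding"], 3L)
  expect_equal(tl$n[tl$category == "intergenic"], 0L)
  expect_equal(sum(tally_categories(snvs[0, ])$n), 0L)
  expect_error(tally_categories(tibble::tibble(category = "bogus")), "unknown")
  # permutation invariance
  expect_equal(tally_categories(snvs[sample(4), , drop = FALSE]), tl)
})

test_that("spectrum counts collapse correctly and flag non-SNVs", {
  one <- mutation_spectrum(tibble::tibble(ref = "C", alt = "T"))
  expect_equal(one$counts6$n[one$counts6$change == "C>T"], 1L)
  expect_equal(one$counts12$n[one$counts12$change == "C>T"], 1L)
  expect_identical(one$titv, Inf) # no transversion observed
  two <- mutation_spectrum(tibble::tibble(ref = c("C", "G"), alt = c("T", "A")))
  expect_equal(two$counts6$n[two$counts6$change == "C>T"], 2L)
  expect_equal(sum(two$counts12$n), sum(two$counts6$n))
  expect_error(mutation_spectrum(tibble::tibble(ref = "CT", alt = "T")),
               "single-base")
  expect_error(mutation_spectrum(tibble::tibble(ref = "A", alt = "A")),
               "single-base")
})

test_that("counts6 is the complement collapse of counts12 on random input", {
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  snvs <- tibble::tibble(ref = sample(bases, 500, replace = TRUE))
  snvs$alt <- vapply(snvs$ref, function(r) sample(setdiff(bases, r), 1),
                     character(1))
  sp <- mutation_spectrum(snvs)
  expect_equal(sum(sp$counts12$n), 500L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (ch in sp$counts6$change) {
    r <- substr(ch, 1, 1); a <- substr(ch, 3, 3)
    rc <- paste0(comp[[r]], ">", comp[[a]])
    expect_equal(sp$counts6$n[sp$counts6$change == ch],
                 sum(sp$counts12$n[sp$counts12$change %in% c(ch, rc)]))
  }
})

test_that("uniform 12-class draw gives Ti/Tv near the analytic 1/2", {
  set.seed(33)
  bases <- c("A", "C", "G", "T")
  classes12 <- unlist(lapply(bases, function(r)
    paste0(r, ">", setdiff(bases, r))))
  draws <- sample(classes12, 600, replace = TRUE)
  snvs <- tibble::tibble(ref = substr(draws, 1, 1), alt = substr(draws, 3, 3))
  sp <- mutation_spectrum(snvs)
  # transitions are 4 of 12 classes: expected Ti fraction 1/3
  p <- 1 / 3
  se <- sqrt(p * (1 - p) / 600)
  expect_lt(abs(sp$transitions / 600 - p), 3 * se)
})

test_that("per-PD mutation rate pools counts over passages", {
  expect_equal(
    mutation_rate_per_pd(tibble::tibble(line = "L1", snvs = 10, passages = 10),
                         pd_per_passage = 2)$rate,
    0.5
  )
  cohort <- tibble::tibble(line = c("262", "263", "264", "024"),
                           snvs = c(43, 48, 35, 41),
                           passages = c(17, 27, 25, 25))
  r <- mutation_rate_per_pd(cohort, pd_per_passage = 3.7)
  expect_equal(r$total_snvs, 167)
  expect_equal(r$rate, 167 / (94 * 3.7))
  expect_error(mutation_rate_per_pd(cohort[0, ]), "no lines")
  expect_error(mutation_rate_per_pd(dplyr::mutate(cohort, passages = 0)),
               "positive")
})
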