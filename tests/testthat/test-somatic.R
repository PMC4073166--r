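test_that("somatic calling requires a de novo allele over hom-ref parent", {
  v <- dplyr::bind_rows(
    clean_site("chr1", 100),                                   # de novo het
    clean_site("chr1", 200, par_gt = "0/1", par_ad = c(45L, 45L)), # inherited
    clean_site("chr1", 300, der_gt = "0/0", der_ad = c(90L, 0L))   # no variant
  )
  som <- call_somatic(v, "P", "D")
  expect_equal(som$pos, 100L)
  expect_equal(som$sample, "D")
  expect_error(call_somatic(v, "P", "nope"), "absent")
})

test_that("somatic sites must pass the stringent filter in both samples", {
  v <- dplyr::bind_rows(
    clean_site("chr1", 100),
    clean_site("chr1", 200, qual = 399),          # site clause fails
    clean_site("chr1", 300, der_ad = c(45L, 7L)), # derived AD fails
    clean_site("chr1", 400, par_ad = c(60L, 30L)) # parental hom rule fails
  )
  expect_equal(call_somatic(v, "P", "D")$pos, 100L)
  # switchable: without the parental-pass requirement site 400 comes back
  expect_setequal(call_somatic(v, "P", "D", require_parental_pass = FALSE)$pos,
                  c(100L, 400L))
})

test_that("somatic output is sorted in karyotype order", {
  v <- dplyr::bind_rows(
    clean_site("chr10", 5), clean_site("chr2", 9000), clean_site("chr2", 10),
    clean_site("chrX", 1)
  )
  som <- call_somatic(v, "P", "D")
  expect_equal(som$chrom, c("chr2", "chr2", "chr10", "chrX"))
  expect_equal(som$pos, c(10L, 9000L, 5L, 1L))
})

test_that("structural exclusion partitions the input and groups by region", {
  set.seed(5)
  snvs <- tibble::tibble(chrom = "chr1", pos = sample.int(10000, 100),
                         sample = "D")
  regions <- tibble::tibble(chrom = "chr1", start = c(0, 5000),
                            end = c(1000, 5500),
                            event = c("CNLOH", "deletion"),
                            label = c("cnloh", "del"))
  res <- exclude_structural(snvs, regions)
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(snvs))
  expect_equal(sum(res$removed_by_region), nrow(res$removed))
  # brute-force oracle per pair
  inside <- vapply(snvs$pos, function(p) {
    any(p > regions$start & p <= regions$end)
  }, logical(1))
  expect_setequal(res$removed$pos, snvs$pos[inside])
  expect_setequal(res$kept$pos, snvs$pos[!inside])
  # empty region list is the identity
  id <- exclude_structural(snvs, NULL)
  expect_equal(id$kept, snvs)
  expect_equal(nrow(id$removed), 0L)
})

test_that("exclusion list removes exact matches once, warns on misses/dups", {
  snvs <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L),
                         sample = c("A", "A", "B"))
  keep <- apply_exclusion_list(snvs, tibble::tibble(chrom = "chr1", pos = 10L,
                                                    sample = "A"))
  expect_equal(keep$kept$pos, c(20L, 30L))
  expect_equal(keep$n_removed, 1L)
  # wrong sample does not match
  expect_warning(
    miss <- apply_exclusion_list(snvs, tibble::tibble(chrom = "chr1",
                                                      pos = 30L, sample = "A")),
    "no SNV"
  )
  expect_equal(nrow(miss$kept), 3L)
  expect_warning(
    dup <- apply_exclusion_list(
      snvs, tibble::tibble(chrom = "chr1", pos = c(10L, 10L),
                           sample = c("A", "A"))),
    "duplicated"
  )
  expect_equal(dup$n_removed, 1L)
  # empty list is the identity
  expect_equal(apply_exclusion_list(snvs, NULL)$kept, snvs)
})

test_that("accounting enforces its conservation invariant", {
  acc <- somatic_accounting(212, c(CNLOH = 2, del1 = 37, del2 = 1), 5)
  expect_equal(acc$final, 167L)
  expect_equal(glance(acc)$final, 167L)
  td <- tidy(acc)
  expect_equal(sum(td$count[td$stage != "final"]), td$count[td$stage == "final"])
  expect_equal(somatic_accounting(0, integer(0), 0)$final, 0L)
  expect_error(somatic_accounting(10, c(r = 11), 0), "negative")
  expect_error(somatic_accounting(-1), "non-negative")
})

test_that("pipeline stages conserve records and commute with chrom partitioning", {
  b <- generate_cohort(cohort_config(n_sites = 60, somatic_per_line = 10,
                                     seed = 9))
  regions <- tibble::tibble(chrom = "chr1", start = 0, end = 5e7,
                            event = "deletion", label = "del")
  res <- somatic_pipeline(b$variants, "parental", b$config$lines, regions,
                          excluded = NULL)
  acc <- res$accounting
  expect_equal(acc$called - sum(acc$removed_by_region) - acc$removed_manual,
               acc$final)
  expect_equal(nrow(res$snvs), acc$final)
  # per-chromosome partition gives the same totals
  per_chrom <- purrr::map_int(paste0("chr", 1:4), function(cc) {
    vv <- dplyr::filter(b$variants, chrom == cc)
    somatic_pipeline(vv, "parental", b$config$lines, regions,
                     excluded = NULL)$accounting$final
  })
  expect_equal(sum(per_chrom), acc$final)
})
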