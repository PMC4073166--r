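# Builders and independent oracles shared across test files.

# One site x sample row in the long call-table schema.
call_row <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                     qual = 1000, qd = 20, mq = 60, fs = 1, hs = 1,
                     sample = "s1", gt = "0/1", ad = c(40L, 40L), gq = 90L) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    qual = qual, qd = qd, mq = mq, fs = fs, haplotype_score = hs,
    sample = sample, gt = gt, ad = list(as.integer(ad)), gq = as.integer(gq)
  )
}

# A clean two-sample site (parental hom-ref, derived het) at high depth.
clean_site <- function(chrom, pos, parental = "P", derived = "D",
                       der_gt = "0/1", der_ad = c(45L, 45L),
                       par_gt = "0/0", par_ad = c(90L, 0L), ...) {
  dplyr::bind_rows(
    call_row(chrom, pos, sample = parental, gt = par_gt, ad = par_ad, ...),
    call_row(chrom, pos, sample = derived, gt = der_gt, ad = der_ad, ...)
  )
}

# Independent transcription of the printed stringent-filter boolean,
# written as a plain per-record loop (kept iff TRUE). Strict missingness:
# any NA among the required fields eliminates the record.
oracle_keep <- function(qual, qd, mq, fs, hs, gq, gt, ad) {
  if (anyNA(c(qual, qd, mq, fs, hs, gq)) || is.na(gt) || anyNA(ad)) {
    return(FALSE)
  }
  if (qual < 400 || qd < 2.0 || mq < 40.0 || fs > 60.0 || hs > 13.0 ||
      gq <= 60) {
    return(FALSE)
  }
  g <- as.integer(strsplit(gt, "/", fixed = TRUE)[[1]])
  if (g[1] != g[2]) {
    a <- ad[g[1] + 1]; b <- ad[g[2] + 1]
    a >= 8 && b >= 8 && max(a, b) / min(a, b) <= 2
  } else {
    a <- ad[g[1] + 1]
    b <- max(ad[-(g[1] + 1)])
    hi <- max(a, b); lo <- min(a, b)
    (lo > 0 && hi / lo >= 32) || (lo == 1 && hi >= 16) || (lo == 0 && hi >= 8)
  }
}

# Random single-sample records concentrated near every clause boundary.
random_records <- function(n, seed) {
  set.seed(seed)
  gts <- c("0/0", "0/1", "1/1", "0/2", "1/2", "2/2")
  purrr::map_dfr(seq_len(n), function(i) {
    gt <- sample(gts, 1)
    n_allele <- if (grepl("2", gt)) 3L else 2L
    call_row(
      chrom = "chr1", pos = i,
      alt = if (n_allele == 3) "G,T" else "G",
      qual = sample(c(runif(1, 380, 420), 1000), 1),
      qd = sample(c(runif(1, 1.5, 2.5), 25), 1),
      mq = sample(c(runif(1, 38, 42), 60), 1),
      fs = sample(c(runif(1, 55, 65), 1), 1),
      hs = sample(c(runif(1, 12, 14), 1), 1),
      gq = sample(c(58:62, 90), 1),
      gt = gt,
      ad = sample(0:40, n_allele, replace = TRUE)
    )
  })
}
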