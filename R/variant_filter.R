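#' Stringent site-quality filter verdicts
#'
#' Applies the hard site filter used for post-calling SNV selection. A
#' call is eliminated when any clause holds:
#' `QUAL < 400 | QD < 2.0 | MQ < 40.0 | FS > 60.0 | HaplotypeScore > 13.0 |
#' GQ <= 60`, with GQ evaluated on the focal sample's call. Boundary
#' values pass exactly as the operators read: QUAL of 400 passes, GQ of
#' 60 is eliminated.
#'
#' Missing annotations are a first-class state: under the default strict
#' policy a record missing any required field is eliminated with reason
#' `MISSING_FIELD`; with `missing = "permissive"` a missing field simply
#' cannot fail its clause.
#'
#' @param variants Long call tibble from [read_vcf()].
#' @param sample Focal sample name (supplies the GQ clause).
#' @param missing `"strict"` (default) or `"permissive"`.
#' @return Tibble with one row per site: `chrom`, `pos`, `sample`,
#'   `kept`, and `reasons` (list column of failure codes drawn from
#'   QUAL_LT_400, QD_LT_2, MQ_LT_40, FS_GT_60, HS_GT_13, GQ_LE_60,
#'   MISSING_FIELD). `kept` is true iff `reasons` is empty.
#' @export
site_quality_filter <- function(variants, sample, missing = c("strict", "permissive")) {
  missing <- match.arg(missing)
  focal <- filter(variants, .data$sample == !!sample)
  if (!nrow(focal) && nrow(variants)) {
    abort(paste0("sample not present in call table: ", sample))
  }
  clause <- function(x, fails, code) {
    out <- ifelse(is.na(x), NA, fails)
    list(fail = out, code = code)
  }
  cl <- list(
    clause(focal$qual, focal$qual < 400, "QUAL_LT_400"),
    clause(focal$qd, focal$qd < 2.0, "QD_LT_2"),
    clause(focal$mq, focal$mq < 40.0, "MQ_LT_40"),
    clause(focal$fs, focal$fs > 60.0, "FS_GT_60"),
    clause(focal$haplotype_score, focal$haplotype_score > 13.0, "HS_GT_13"),
    clause(focal$gq, focal$gq <= 60, "GQ_LE_60")
  )
  reasons <- lapply(seq_len(nrow(focal)), function(i) {
    r <- unlist(lapply(cl, function(c1) {
      if (isTRUE(c1$fail[i])) c1$code else NULL
    }))
    any_missing <- any(vapply(cl, function(c1) is.na(c1$fail[i]), logical(1)))
    if (any_missing && missing == "strict") r <- c(r, "MISSING_FIELD")
    if (is.null(r)) character(0) else r
  })
  tibble(
    chrom = focal$chrom, pos = focal$pos, sample = sample,
    kept = lengths(reasons) == 0L, reasons = reasons
  )
}

# Depths addressed by a genotype: for het, the two counts the genotype's
# allele indices point at; for hom, the genotype allele's count paired with
# the largest count among all OTHER alleles (the most conservative
# contaminant), per the `hom_pair` policy.
ad_pair <- function(idx, ad, hom_pair = "max_other") {
  if (any(idx + 1L > length(ad)) || anyNA(ad)) return(NULL)
  if (length(unique(idx)) == 2L) {
    ad[unique(idx) + 1L]
  } else {
    a <- ad[idx[1] + 1L]
    others <- ad[-(idx[1] + 1L)]
    b <- if (!length(others)) 0L else if (hom_pair == "max_other") max(others) else sum(others)
    c(a, b)
  }
}

#' Allelic-depth rule for heterozygous calls
#'
#' A het call (genotype 0/1, 0/2 or 1/2) is selected only when both
#' depths addressed by the genotype are at least 8 reads and they differ
#' by at most twofold (ratio `<= 2`, boundary inclusive). Only the two
#' genotype alleles are inspected; other alleles' depths are ignored.
#'
#' @param gt Character vector of genotype strings (e.g. `"0/1"`).
#' @param ad List column of integer allelic depths (reference first).
#' @return Logical vector; `NA` where depths are missing.
#' @export
het_ad_filter <- function(gt, ad) {
  idx <- parse_gt(gt)
  purrr::map2_lgl(idx, ad, function(i, d) {
    if (is.null(i)) return(NA)
    if (length(unique(i)) != 2L) {
      abort("het_ad_filter called on a non-heterozygous genotype")
    }
    p <- ad_pair(i, d)
    if (is.null(p)) return(NA)
    min(p) >= 8 && max(p) <= 2 * min(p)
  })
}

#' Allelic-depth rule for homozygous calls
#'
#' A hom call (genotype 0/0, 1/1 or 2/2 -- 0/0 at a variant site is
#' evaluated exactly like 1/1) is selected only when the ordered depth
#' pair (a >= b) built from the genotype allele's depth and the largest
#' other-allele depth satisfies one of: b > 0 and a/b >= 32 ("no less
#' than 32-fold", boundary inclusive); b == 1 and a >= 16; or b == 0 and
#' a >= 8. The two degenerate-denominator carve-outs are what force the
#' fold-ratio (rather than arithmetic-difference) reading of the rule.
#'
#' @inheritParams het_ad_filter
#' @param hom_pair How to pick the contaminant depth: `"max_other"`
#'   (default, most conservative) or `"sum_other"`.
#' @return Logical vector; `NA` where depths are missing.
#' @export
hom_ad_filter <- function(gt, ad, hom_pair = c("max_other", "sum_other")) {
  hom_pair <- match.arg(hom_pair)
  idx <- parse_gt(gt)
  purrr::map2_lgl(idx, ad, function(i, d) {
    if (is.null(i)) return(NA)
    if (length(unique(i)) != 1L) {
      abort("hom_ad_filter called on a non-homozygous genotype")
    }
    p <- ad_pair(i, d, hom_pair)
    if (is.null(p)) return(NA)
    a <- max(p); b <- min(p)
    (b > 0 && a >= 32 * b) || (b == 1 && a >= 16) || (b == 0 && a >= 8)
  })
}

#' Apply the full stringent filter for one sample
#'
#' Combines [site_quality_filter()] with the genotype-class-appropriate
#' allelic-depth rule ([het_ad_filter()] for het calls, [hom_ad_filter()]
#' for hom calls) on the focal sample. A site is kept iff every site
#' clause passes and the AD rule passes. The operation is idempotent.
#'
#' @inheritParams site_quality_filter
#' @param hom_pair Passed to [hom_ad_filter()].
#' @return A list with `kept` (all rows of `variants`, every sample, at
#'   sites that pass for `sample`) and `verdicts` (one row per site:
#'   `chrom`, `pos`, `sample`, `kept`, `reasons` list column; AD failures
#'   appear as AD_HET_FAIL / AD_HOM_FAIL).
#' @export
apply_stringent_filter <- function(variants, sample,
                                   missing = c("strict", "permissive"),
                                   hom_pair = "max_other") {
  missing <- match.arg(missing)
  verdicts <- site_quality_filter(variants, sample, missing)
  focal <- filter(variants, .data$sample == !!sample)
  het <- is_het_gt(focal$gt)
  hom <- is_hom_gt(focal$gt)
  ad_ok <- rep(NA, nrow(focal))
  if (any(het)) ad_ok[het] <- het_ad_filter(focal$gt[het], focal$ad[het])
  if (any(hom)) ad_ok[hom] <- hom_ad_filter(focal$gt[hom], focal$ad[hom], hom_pair)
  ad_code <- ifelse(het, "AD_HET_FAIL", "AD_HOM_FAIL")
  verdicts$reasons <- lapply(seq_len(nrow(verdicts)), function(i) {
    r <- verdicts$reasons[[i]]
    if (is.na(ad_ok[i])) {
      if (missing == "strict" && !"MISSING_FIELD" %in% r) r <- c(r, "MISSING_FIELD")
    } else if (!ad_ok[i]) {
      r <- c(r, ad_code[i])
    }
    r
  })
  verdicts$kept <- lengths(verdicts$reasons) == 0L
  pass <- verdicts[verdicts$kept, c("chrom", "pos")]
  kept <- semi_join(variants, pass, by = c("chrom", "pos"))
  list(kept = kept, verdicts = verdicts)
}
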