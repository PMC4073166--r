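#' Read a multi-sample VCF into a long per-sample call table
#'
#' Parses a VCF 4.x file (via vcfR) into a tidy tibble with one row per
#' site x sample. Site-level annotations used by the stringent filter
#' (QUAL, QD, MQ, FS, HaplotypeScore) are pulled into their own columns;
#' an annotation absent from a record is recorded as `NA`, never silently
#' defaulted, because the filter must decide on missingness explicitly.
#'
#' @param path Path to a VCF file with FORMAT fields GT, AD and GQ.
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   (comma-joined alternate alleles), `qual`, `qd`, `mq`, `fs`,
#'   `haplotype_score`, `sample`, `gt` (genotype string or `NA`), `ad`
#'   (list column of integer per-allele depths, reference first) and `gq`.
#' @examples
#' \dontrun{
#' variants <- read_vcf("cohort.vcf")
#' }
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  for (req in c("GT", "AD")) {
    if (!req %in% fmt_keys) {
      abort(paste0("FORMAT field ", req, " absent from ", path,
                   "; GT and AD are required"))
    }
  }
  info_num <- function(key) {
    v <- vcfR::extract.info(vcf, element = key, as.numeric = TRUE)
    if (is.null(v)) rep(NA_real_, nrow(fix)) else as.numeric(v)
  }
  sites <- tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    qd = info_num("QD"),
    mq = info_num("MQ"),
    fs = info_num("FS"),
    haplotype_score = info_num("HaplotypeScore")
  )
  if (any(is.na(sites$pos)) || any(sites$pos < 1)) {
    abort(paste0("malformed VCF line: non-positive or unparseable POS at data line ",
                 which(is.na(sites$pos) | sites$pos < 1)[1]))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  gq <- if ("GQ" %in% fmt_keys) {
    vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
  } else {
    NULL
  }
  samples <- colnames(vcf@gt)[-1]
  calls <- purrr::map_dfr(samples, function(s) {
    mutate(
      sites,
      sample = s,
      gt = as.character(gt[, s]),
      ad = unname(lapply(strsplit(ifelse(is.na(ad[, s]), "", ad[, s]), ","),
                         function(x) suppressWarnings(as.integer(x)))),
      gq = if (is.null(gq)) NA_integer_ else as.integer(gq[, s])
    )
  })
  as_tibble(calls)
}

#' Write a call table back out as plain-text VCF 4.2
#'
#' Inverse of [read_vcf()] for tables this package emits: field values
#' round-trip exactly. INFO carries QD, MQ, FS and HaplotypeScore (keys
#' with `NA` are omitted, preserving missingness); FORMAT is `GT:AD:GQ`.
#'
#' @param variants Long call tibble as produced by [read_vcf()] or
#'   [generate_cohort()].
#' @param path Output file path (uncompressed VCF).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "sample", "gt", "ad") %in%
                  names(variants)))
  samples <- unique(variants$sample)
  sites <- distinct(variants, .data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$qual, .data$qd, .data$mq, .data$fs,
                    .data$haplotype_score)
  sites <- sort_karyotype(sites)
  fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.4f", x))
  info <- vapply(seq_len(nrow(sites)), function(i) {
    kv <- c(QD = sites$qd[i], MQ = sites$mq[i], FS = sites$fs[i],
            HaplotypeScore = sites$haplotype_score[i])
    kv <- kv[!is.na(kv)]
    if (!length(kv)) return(".")
    paste(paste0(names(kv), "=", fmt_num(kv)), collapse = ";")
  }, character(1))
  key <- paste(variants$chrom, variants$pos)
  skey <- paste(sites$chrom, sites$pos)
  body <- vapply(seq_len(nrow(sites)), function(i) {
    rows <- variants[key == skey[i], ]
    cells <- vapply(samples, function(s) {
      r <- rows[rows$sample == s, ]
      if (!nrow(r)) return("./.:.:.")
      paste(
        ifelse(is.na(r$gt[1]), "./.", r$gt[1]),
        if (length(r$ad[[1]]) && !anyNA(r$ad[[1]])) paste(r$ad[[1]], collapse = ",") else ".",
        ifelse(is.na(r$gq[1]), ".", r$gq[1]),
        sep = ":"
      )
    }, character(1))
    paste(sites$chrom[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
          ifelse(is.na(sites$qual[i]), ".", fmt_num(sites$qual[i])),
          ".", info[i], "GT:AD:GQ", paste(cells, collapse = "\t"),
          sep = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=HaplotypeScore,Number=1,Type=Float,Description=\"Haplotype consistency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read structural-alteration intervals from a BED-like file
#'
#' Three required columns (chrom, start, end; 0-based half-open, the BED
#' dialect) plus an optional fourth column naming the event type
#' (`CNLOH`, `deletion`, anything else is kept as `other`) and an optional
#' fifth free-text label. Missing labels default to `chrom:start-end`.
#'
#' @param path Path to a whitespace- or tab-delimited interval file
#'   without header.
#' @return Tibble with columns `chrom`, `start`, `end`, `event`, `label`
#'   and derived `length_kb`.
#' @export
read_intervals <- function(path) {
  raw <- readr::read_table(path, col_names = FALSE, col_types = readr::cols(),
                           progress = FALSE)
  if (ncol(raw) < 3) abort("interval file needs at least 3 columns (chrom start end)")
  out <- tibble(
    chrom = as.character(raw[[1]]),
    start = as.numeric(raw[[2]]),
    end = as.numeric(raw[[3]]),
    event = if (ncol(raw) >= 4) as.character(raw[[4]]) else "other",
    label = if (ncol(raw) >= 5) as.character(raw[[5]]) else NA_character_
  )
  as_intervals(out)
}

# Validate/normalise an interval table built in code or read from disk.
as_intervals <- function(x) {
  x <- as_tibble(x)
  if (!"event" %in% names(x)) x$event <- "other"
  x$event <- ifelse(x$event %in% c("CNLOH", "deletion"), x$event, "other")
  if (!"label" %in% names(x)) x$label <- NA_character_
  x$label <- ifelse(is.na(x$label),
                    paste0(x$chrom, ":", x$start, "-", x$end), x$label)
  bad <- which(!(x$start < x$end))
  if (length(bad)) {
    abort(paste0("empty or inverted interval (start >= end) at row ", bad[1]))
  }
  x$length_kb <- (x$end - x$start) / 1000
  x[, c("chrom", "start", "end", "event", "label", "length_kb")]
}

#' Does a variant position fall inside an interval?
#'
#' The one explicit bridge between the two coordinate systems the package
#' uses: VCF positions are 1-based, intervals are 0-based half-open
#' (BED dialect). A position `pos` overlaps `[start, end)` iff
#' `start < pos <= end` on the same chromosome. Vectorised over all
#' arguments.
#'
#' @param chrom,pos Variant chromosome and 1-based position.
#' @param interval_chrom,interval_start,interval_end Interval chromosome
#'   and 0-based half-open bounds.
#' @return Logical vector.
#' @examples
#' overlaps("chr1", 1, "chr1", 0, 1)   # first base of [0,1): TRUE
#' overlaps("chr1", 10, "chr1", 10, 20) # FALSE; base 10 precedes [10,20)
#' @export
overlaps <- function(chrom, pos, interval_chrom, interval_start, interval_end) {
  chrom == interval_chrom & interval_start < pos & pos <= interval_end
}

#' Match variants to the structural regions containing them
#'
#' @param snvs Data frame with `chrom` and `pos` columns.
#' @param regions Interval tibble as from [read_intervals()].
#' @return `snvs` with a `region_label` column: the label of the first
#'   (in `regions` order) containing interval, or `NA` if none.
#' @export
match_regions <- function(snvs, regions) {
  regions <- as_intervals(regions)
  lab <- rep(NA_character_, nrow(snvs))
  for (i in rev(seq_len(nrow(regions)))) {
    hit <- overlaps(snvs$chrom, snvs$pos, regions$chrom[i],
                    regions$start[i], regions$end[i])
    lab[hit] <- regions$label[i]
  }
  mutate(as_tibble(snvs), region_label = lab)
}
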