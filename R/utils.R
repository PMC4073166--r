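# Karyotype-style chromosome ordering: chr1..chr22, chrX, chrY, chrM(T),
# then anything else alphabetically. Tolerates names without the "chr" prefix.
chrom_levels <- function(chroms) {
  chroms <- unique(as.character(chroms))
  core <- c(as.character(1:22), "X", "Y", "M", "MT")
  key <- sub("^chr", "", chroms)
  rank <- match(key, core)
  ord <- order(is.na(rank), rank, chroms)
  chroms[ord]
}

#' Sort a variant or interval table in karyotype order
#'
#' Orders rows by chromosome (1-22, X, Y, M, then others alphabetically)
#' and position. Used by every operation that promises deterministic output
#' order.
#'
#' @param x A data frame with `chrom` and `pos` (or `start`) columns.
#' @return `x` reordered; column set unchanged.
#' @export
sort_karyotype <- function(x) {
  stopifnot(is.data.frame(x), "chrom" %in% names(x))
  poscol <- if ("pos" %in% names(x)) "pos" else "start"
  lv <- chrom_levels(x$chrom)
  x[order(match(x$chrom, lv), x[[poscol]]), , drop = FALSE]
}

# Parse "0/1" / "0|1" genotype strings into integer allele-index pairs.
# Missing ("./.", ".", NA) -> NULL entries.
parse_gt <- function(gt) {
  lapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NULL)
    idx <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
    if (anyNA(idx)) return(NULL)
    idx
  })
}

is_het_gt <- function(gt) {
  vapply(parse_gt(gt), function(i) !is.null(i) && length(unique(i)) == 2L,
         logical(1))
}

is_hom_gt <- function(gt) {
  vapply(parse_gt(gt), function(i) !is.null(i) && length(unique(i)) == 1L,
         logical(1))
}
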