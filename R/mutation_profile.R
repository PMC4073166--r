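#' Annotation categories in precedence order
#'
#' The single category an SNV receives is the highest-precedence label
#' among its effect annotations: coding effects first, then splice, UTR,
#' intron, up/downstream, non-coding exon, intergenic. The order is fixed
#' and exported so analyses can state it.
#'
#' @format Character vector of the 13 category labels, highest precedence
#'   first.
#' @export
SNV_CATEGORIES <- c(
  "stop_gained", "stop_lost", "start_lost",
  "non_synonymous_coding", "synonymous_coding",
  "splice_site", "utr_5", "utr_3", "intron",
  "upstream", "downstream", "non_coding_exon", "intergenic"
)

#' Resolve a set of effect labels to one category
#'
#' SnpEff-style annotation gives an SNV several effect labels (a variant
#' downstream of one gene may be coding in another); reporting requires
#' exactly one. The first label in the fixed precedence order
#' [SNV_CATEGORIES] wins.
#'
#' @param labels Character vector of effect labels for ONE variant.
#' @return A single category string.
#' @examples
#' resolve_category(c("downstream", "non_synonymous_coding"))
#' @export
resolve_category <- function(labels) {
  if (!length(labels)) abort("no effect labels supplied")
  bad <- setdiff(labels, SNV_CATEGORIES)
  if (length(bad)) abort(paste0("unknown effect label: ", bad[1]))
  SNV_CATEGORIES[min(match(labels, SNV_CATEGORIES))]
}

#' Vectorised category resolution over joined label strings
#'
#' @param effects Character vector; each element the `sep`-joined effect
#'   labels of one variant (the annotation-table convention).
#' @param sep Label separator (default `";"`).
#' @return Character vector of categories, one per input element.
#' @export
resolve_categories <- function(effects, sep = ";") {
  vapply(strsplit(effects, sep, fixed = TRUE), resolve_category, character(1))
}

#' Tally annotation categories
#'
#' @param snvs Data frame with a `category` column.
#' @return Tibble with all 13 categories in precedence order and their
#'   counts; categories absent from the input are reported as explicit
#'   zeros. Counts always sum to `nrow(snvs)`.
#' @export
tally_categories <- function(snvs) {
  snvs <- as_tibble(snvs)
  bad <- setdiff(unique(snvs$category), SNV_CATEGORIES)
  if (length(bad)) abort(paste0("unknown category label: ", bad[1]))
  tibble(
    category = factor(SNV_CATEGORIES, levels = SNV_CATEGORIES),
    n = unname(vapply(SNV_CATEGORIES, function(k) sum(snvs$category == k),
                      integer(1)))
  )
}

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
CHANGES12 <- {
  g <- expand.grid(ref = BASES, alt = BASES, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, ]
  sort(paste0(g$ref, ">", g$alt))
}
CHANGES6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

# Collapse an ordered change onto its pyrimidine-reference representative.
collapse_change <- function(change) {
  ref <- substr(change, 1, 1)
  alt <- substr(change, 3, 3)
  pyr <- ref %in% c("C", "T")
  ifelse(pyr, change,
         paste0(COMPLEMENT[ref], ">", COMPLEMENT[alt]))
}

#' Single-nucleotide change spectrum
#'
#' Classifies substitutions into the 12 ordered ref>alt classes and the 6
#' pyrimidine-collapsed classes (each purine-reference change pooled with
#' its reverse complement), and computes the transition/transversion
#' ratio. Both conventions are reported because published spectra use
#' either.
#'
#' @param snvs Data frame with single-base `ref` and `alt` columns
#'   (A/C/G/T, ref != alt).
#' @return A `mutation_spectrum` object with elements `counts12`,
#'   `counts6` (tibbles of change/count), `n`, and `titv` (Inf when no
#'   transversion is observed).
#' @export
mutation_spectrum <- function(snvs) {
  snvs <- as_tibble(snvs)
  ok <- snvs$ref %in% BASES & snvs$alt %in% BASES & snvs$ref != snvs$alt
  if (!all(ok)) {
    abort(paste0("not a single-base substitution at row ", which(!ok)[1]))
  }
  chg <- paste0(snvs$ref, ">", snvs$alt)
  n12 <- vapply(CHANGES12, function(k) sum(chg == k), integer(1))
  counts12 <- tibble(change = CHANGES12, n = unname(n12))
  coll <- collapse_change(chg)
  n6 <- vapply(CHANGES6, function(k) sum(coll == k), integer(1))
  counts6 <- tibble(change = CHANGES6, n = unname(n6))
  ti <- sum(chg %in% TRANSITIONS)
  tv <- length(chg) - ti
  structure(
    list(counts12 = counts12, counts6 = counts6, n = length(chg),
         transitions = ti, transversions = tv,
         titv = if (tv == 0) Inf else ti / tv),
    class = "mutation_spectrum"
  )
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("Mutation spectrum:", x$n, "substitutions; Ti/Tv =",
      format(x$titv, digits = 3), "\n")
  print(tidyr::pivot_wider(x$counts6, names_from = "change", values_from = "n"))
  invisible(x)
}

#' @rdname mutation_spectrum
#' @param x A `mutation_spectrum` object.
#' @param classes `"6"` (pyrimidine-collapsed, default) or `"12"`.
#' @param ... Unused.
#' @export
tidy.mutation_spectrum <- function(x, classes = c("6", "12"), ...) {
  classes <- match.arg(classes)
  if (classes == "6") x$counts6 else x$counts12
}

#' @rdname mutation_spectrum
#' @export
glance.mutation_spectrum <- function(x, ...) {
  tibble(n = x$n, transitions = x$transitions,
         transversions = x$transversions, titv = x$titv)
}

#' @export
autoplot.mutation_spectrum <- function(object, classes = c("6", "12"), ...) {
  d <- tidy(object, classes = match.arg(classes))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$change, y = .data$n,
                                  fill = .data$change)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "base change", y = "SNVs",
                  title = "Single-nucleotide change spectrum") +
    ggplot2::theme_minimal()
}

#' Somatic mutation rate per population doubling
#'
#' Pools SNV counts and passage numbers across derived lines:
#' `rate = sum(snvs) / (sum(passages) * pd_per_passage)`. The number of
#' population doublings per passage is rarely measured directly; the
#' default of 3.7 doublings/passage is an assumption consistent with
#' routine human iPS-cell split ratios, and should be replaced by a
#' measured value when one exists.
#'
#' @param per_line Data frame with columns `line`, `snvs`, `passages`.
#' @param pd_per_passage Population doublings per passage (> 0).
#' @return One-row tibble: `total_snvs`, `total_passages`,
#'   `pd_per_passage`, `total_pd`, `rate` (SNVs per population doubling).
#' @examples
#' cohort <- tibble::tibble(
#'   line = c("262", "263", "264", "024"),
#'   snvs = c(43, 48, 35, 41),
#'   passages = c(17, 27, 25, 25)
#' )
#' mutation_rate_per_pd(cohort, pd_per_passage = 3.7)
#' @export
mutation_rate_per_pd <- function(per_line, pd_per_passage = 3.7) {
  per_line <- as_tibble(per_line)
  if (!nrow(per_line)) abort("no lines supplied")
  if (pd_per_passage <= 0) abort("pd_per_passage must be positive")
  if (any(per_line$passages <= 0)) abort("passages must be positive")
  total_snvs <- sum(per_line$snvs)
  total_passages <- sum(per_line$passages)
  total_pd <- total_passages * pd_per_passage
  tibble(total_snvs = total_snvs, total_passages = total_passages,
         pd_per_passage = pd_per_passage, total_pd = total_pd,
         rate = total_snvs / total_pd)
}
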