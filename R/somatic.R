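#' Call derived-line-specific (somatic) SNVs against the parental sample
#'
#' A site is somatic for a derived line when (i) both the parental and
#' derived calls pass the stringent filter at the site, (ii) the parental
#' genotype is homozygous reference (0/0), and (iii) the derived genotype
#' carries at least one allele absent from the parental genotype, i.e. a
#' de novo allele acquired during reprogramming or culture. Genotype
#' changes without a new allele (loss of heterozygosity) are deliberately
#' not counted here; they are handled through the structural-region
#' exclusion channel.
#'
#' @param variants Long call tibble from [read_vcf()] or
#'   [generate_cohort()].
#' @param parental Parental sample name.
#' @param derived Derived line sample name.
#' @param require_parental_pass Require the parental call to pass the
#'   stringent filter too (default TRUE).
#' @inheritParams apply_stringent_filter
#' @return The derived sample's rows at somatic sites, sorted by
#'   (chromosome in karyotype order, position).
#' @export
call_somatic <- function(variants, parental, derived,
                         require_parental_pass = TRUE,
                         missing = "strict") {
  for (s in c(parental, derived)) {
    if (!s %in% variants$sample) abort(paste0("sample absent from call table: ", s))
  }
  pass_d <- apply_stringent_filter(variants, derived, missing)$verdicts
  pass <- pass_d[pass_d$kept, c("chrom", "pos")]
  if (require_parental_pass) {
    pass_p <- apply_stringent_filter(variants, parental, missing)$verdicts
    pass <- semi_join(pass, pass_p[pass_p$kept, c("chrom", "pos")],
                      by = c("chrom", "pos"))
  }
  par <- filter(variants, .data$sample == parental) %>%
    semi_join(pass, by = c("chrom", "pos"))
  der <- filter(variants, .data$sample == derived) %>%
    semi_join(pass, by = c("chrom", "pos"))
  par <- par[match(paste(der$chrom, der$pos), paste(par$chrom, par$pos)), ]
  par_idx <- parse_gt(par$gt)
  der_idx <- parse_gt(der$gt)
  somatic <- purrr::map2_lgl(par_idx, der_idx, function(p, d) {
    !is.null(p) && !is.null(d) && all(p == 0L) && any(!d %in% p)
  })
  sort_karyotype(der[somatic, , drop = FALSE])
}

#' Exclude SNVs inside large structural-alteration regions
#'
#' SNV-like calls falling inside copy-neutral LOH or deletion intervals
#' reflect large-scale structural events rather than single-nucleotide
#' substitutions, and are removed from the somatic count, grouped by the
#' region that captured them. `kept` and `removed` always partition the
#' input.
#'
#' @param snvs Somatic SNV tibble (needs `chrom`, `pos`).
#' @param regions Interval tibble as from [read_intervals()], or any data
#'   frame with `chrom`, `start`, `end` (0-based half-open).
#' @return List with `kept` (no overlap), `removed` (with a
#'   `region_label` column), and `removed_by_region` (named integer
#'   counts, one entry per region label even when zero).
#' @export
exclude_structural <- function(snvs, regions) {
  snvs <- as_tibble(snvs)
  if (!nrow(snvs) || is.null(regions) || !nrow(as_tibble(regions))) {
    return(list(kept = snvs,
                removed = mutate(snvs[0, ], region_label = character(0)),
                removed_by_region = setNames(integer(0), character(0))))
  }
  regions <- as_intervals(regions)
  tagged <- match_regions(snvs, regions)
  removed <- filter(tagged, !is.na(.data$region_label))
  kept <- select(filter(tagged, is.na(.data$region_label)), -"region_label")
  by_region <- setNames(
    vapply(regions$label, function(l) sum(removed$region_label == l), integer(1)),
    regions$label
  )
  list(kept = kept, removed = removed, removed_by_region = by_region)
}

#' Remove manually flagged ambiguous calls
#'
#' Applies an explicit exclusion list of (chrom, pos, sample) entries --
#' the auditable, reproducible form of a manual curation step for calls
#' that pass the automated filters but are judged ambiguous. Only exact
#' matches are removed; list entries matching nothing raise a warning,
#' not an error, and duplicated entries count once.
#'
#' @param snvs Somatic SNV tibble (needs `chrom`, `pos`, `sample`).
#' @param excluded Data frame with columns `chrom`, `pos`, `sample`.
#' @return List with `kept`, `removed`, and `n_removed`.
#' @export
apply_exclusion_list <- function(snvs, excluded) {
  snvs <- as_tibble(snvs)
  if (is.null(excluded) || !nrow(as_tibble(excluded))) {
    return(list(kept = snvs, removed = snvs[0, ], n_removed = 0L))
  }
  excluded <- as_tibble(excluded)[, c("chrom", "pos", "sample")]
  ndup <- nrow(excluded) - nrow(distinct(excluded))
  if (ndup > 0) {
    warn(paste0(ndup, " duplicated exclusion-list entr",
                if (ndup == 1) "y" else "ies", " ignored"))
    excluded <- distinct(excluded)
  }
  unmatched <- anti_join(excluded, snvs, by = c("chrom", "pos", "sample"))
  if (nrow(unmatched)) {
    warn(paste0(nrow(unmatched), " exclusion-list entr",
                if (nrow(unmatched) == 1) "y matches" else "ies match",
                " no SNV"))
  }
  removed <- semi_join(snvs, excluded, by = c("chrom", "pos", "sample"))
  kept <- anti_join(snvs, excluded, by = c("chrom", "pos", "sample"))
  list(kept = kept, removed = removed, n_removed = nrow(removed))
}

#' Somatic SNV accounting across the exclusion stages
#'
#' Tracks candidate calls through region exclusion and manual exclusion
#' down to the final count, enforcing
#' `final = called - sum(removed_by_region) - removed_manual`.
#'
#' @param called Number of candidate somatic SNVs.
#' @param removed_by_region Named integer vector of per-region removals
#'   (may be empty).
#' @param removed_manual Number removed via the exclusion list.
#' @return A `somatic_accounting` object (see [tidy()] / [glance()]).
#' @examples
#' somatic_accounting(212, c(CNLOH = 2, del1 = 37, del2 = 1), 5)
#' @export
somatic_accounting <- function(called, removed_by_region = integer(0),
                               removed_manual = 0L) {
  called <- as.integer(called)
  removed_by_region <- setNames(as.integer(removed_by_region),
                                names(removed_by_region))
  removed_manual <- as.integer(removed_manual)
  if (called < 0 || removed_manual < 0 || any(removed_by_region < 0)) {
    abort("accounting counts must be non-negative")
  }
  final <- called - sum(removed_by_region) - removed_manual
  if (final < 0) abort("accounting is inconsistent: final count would be negative")
  structure(
    list(called = called, removed_by_region = removed_by_region,
         removed_manual = removed_manual, final = final),
    class = "somatic_accounting"
  )
}

#' @export
print.somatic_accounting <- function(x, ...) {
  cat("Somatic SNV accounting\n")
  cat("  candidate calls:     ", x$called, "\n")
  for (l in names(x$removed_by_region)) {
    cat("  removed in region ", l, ": ", x$removed_by_region[[l]], "\n", sep = "")
  }
  cat("  removed manually:    ", x$removed_manual, "\n")
  cat("  final somatic SNVs:  ", x$final, "\n")
  invisible(x)
}

#' @rdname somatic_accounting
#' @param x A `somatic_accounting` object.
#' @param ... Unused.
#' @export
tidy.somatic_accounting <- function(x, ...) {
  tibble(
    stage = c("called",
              if (length(x$removed_by_region))
                paste0("removed_region_", names(x$removed_by_region)),
              "removed_manual", "final"),
    count = c(x$called, -unname(x$removed_by_region), -x$removed_manual, x$final)
  )
}

#' @rdname somatic_accounting
#' @export
glance.somatic_accounting <- function(x, ...) {
  tibble(called = x$called,
         removed_region = sum(x$removed_by_region),
         removed_manual = x$removed_manual,
         final = x$final)
}

#' @export
autoplot.somatic_accounting <- function(object, ...) {
  d <- tidy(object)
  d$stage <- factor(d$stage, levels = d$stage)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = abs(.data$count),
                                  fill = .data$count < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "SNVs",
                  title = "Somatic SNV accounting") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Run the full somatic-selection pipeline for a cohort
#'
#' Convenience wrapper: per-line somatic calling against the parental
#' sample, structural-region exclusion, manual exclusion list, and the
#' final accounting.
#'
#' @inheritParams call_somatic
#' @param derived Character vector of derived line names.
#' @param regions Interval tibble (or NULL).
#' @param excluded Exclusion-list tibble (or NULL).
#' @return List with `snvs` (final per-line somatic SNVs), `per_line`
#'   (tibble of final counts per line), and `accounting`.
#' @export
somatic_pipeline <- function(variants, parental, derived, regions = NULL,
                             excluded = NULL, missing = "strict") {
  calls <- purrr::map_dfr(derived, function(d)
    call_somatic(variants, parental, d, missing = missing))
  st <- exclude_structural(calls, regions)
  man <- apply_exclusion_list(st$kept, excluded)
  acc <- somatic_accounting(nrow(calls), st$removed_by_region, man$n_removed)
  per_line <- count(man$kept, .data$sample, name = "n_snvs")
  per_line <- left_join(tibble(sample = derived), per_line, by = "sample")
  per_line$n_snvs <- ifelse(is.na(per_line$n_snvs), 0L, per_line$n_snvs)
  list(snvs = sort_karyotype(man$kept), per_line = per_line, accounting = acc)
}
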