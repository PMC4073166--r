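#' Configuration for the synthetic exome cohort generator
#'
#' Captures the structure the somatic pipeline assumes: one parental
#' fibroblast line plus several derived iPS lines sequenced as a
#' multi-sample exome call set. Defaults emulate the study conditions:
#' 4 derived lines, mean mapped depth near 90 reads, and clean quality
#' annotations unless failure fractions are requested.
#'
#' @param n_sites Background (inherited) variant sites shared by all
#'   samples.
#' @param lines Derived line names (default 4 lines).
#' @param parental Parental sample name.
#' @param somatic_per_line Planted de novo SNVs per derived line
#'   (recycled to `length(lines)`).
#' @param depth_mean Mean sequencing depth (reads); per-site depths are
#'   Poisson.
#' @param het_af Parental alternate-allele frequency for background
#'   sites (Hardy-Weinberg genotype draw).
#' @param spectrum_probs Named probabilities over the 12 ordered base
#'   changes for planted SNVs (default uniform).
#' @param category_probs Named probabilities over [SNV_CATEGORIES] for
#'   planted SNVs (default: an exome-like mix dominated by
#'   non-synonymous coding, intron and flanking categories).
#' @param quality_fail_fracs Named fractions (`qual`, `qd`, `mq`, `fs`,
#'   `hs`, `gq`) of sites/calls drawn to fail each filter clause.
#' @param ad_noise Allelic-depth contamination fraction for homozygous
#'   calls (0 = noise off).
#' @param ambiguous_frac Fraction of planted somatic SNVs flagged
#'   ambiguous: they still pass every automated filter (depths skewed
#'   towards, but inside, the twofold boundary) and are emitted on the
#'   manual exclusion list.
#' @param seed Integer seed; every generator is a pure function of its
#'   configuration including the seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_sites = 300,
                          lines = paste0("line", 1:4),
                          parental = "parental",
                          somatic_per_line = 25,
                          depth_mean = 90,
                          het_af = 0.3,
                          spectrum_probs = NULL,
                          category_probs = NULL,
                          quality_fail_fracs = c(qual = 0, qd = 0, mq = 0,
                                                 fs = 0, hs = 0, gq = 0),
                          ad_noise = 0,
                          ambiguous_frac = 0,
                          seed = 1L) {
  if (is.null(spectrum_probs)) {
    spectrum_probs <- setNames(rep(1 / 12, 12), CHANGES12)
  }
  if (is.null(category_probs)) {
    category_probs <- c(
      stop_gained = 0.01, stop_lost = 0.002, start_lost = 0.002,
      non_synonymous_coding = 0.25, synonymous_coding = 0.12,
      splice_site = 0.01, utr_5 = 0.04, utr_3 = 0.08, intron = 0.20,
      upstream = 0.07, downstream = 0.07, non_coding_exon = 0.046,
      intergenic = 0.10
    )
  }
  check_probs <- function(p, names_needed, what) {
    if (!setequal(names(p), names_needed) || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      abort(paste0(what, " must be a named probability vector over ",
                   length(names_needed), " classes summing to 1"))
    }
  }
  check_probs(spectrum_probs, CHANGES12, "spectrum_probs")
  check_probs(category_probs, SNV_CATEGORIES, "category_probs")
  stopifnot(depth_mean > 0, het_af >= 0, het_af <= 1,
            ambiguous_frac >= 0, ambiguous_frac <= 1,
            ad_noise >= 0, ad_noise < 0.5)
  somatic_per_line <- rep_len(as.integer(somatic_per_line), length(lines))
  structure(
    list(n_sites = as.integer(n_sites), lines = lines, parental = parental,
         somatic_per_line = somatic_per_line, depth_mean = depth_mean,
         het_af = het_af, spectrum_probs = spectrum_probs,
         category_probs = category_probs,
         quality_fail_fracs = quality_fail_fracs, ad_noise = ad_noise,
         ambiguous_frac = ambiguous_frac, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Draw one site annotation set; each clause fails independently with the
# configured fraction, with passing and failing values drawn from
# disjoint plausible ranges.
draw_site_quality <- function(n, fracs) {
  pf <- function(frac, pass_lo, pass_hi, fail_lo, fail_hi) {
    fail <- runif(n) < frac
    ifelse(fail, runif(n, fail_lo, fail_hi), runif(n, pass_lo, pass_hi))
  }
  tibble(
    qual = pf(fracs[["qual"]], 500, 3000, 50, 399),
    qd = pf(fracs[["qd"]], 10, 30, 0.1, 1.9),
    mq = pf(fracs[["mq"]], 50, 60, 20, 39),
    fs = pf(fracs[["fs"]], 0, 10, 61, 200),
    haplotype_score = pf(fracs[["hs"]], 0, 5, 14, 50)
  )
}

# Allelic depths for one call given genotype class and total depth.
draw_ad <- function(gt, dp, ad_noise, ambiguous = FALSE) {
  if (gt == "0/1") {
    if (ambiguous) {
      # skewed but filter-passing: ratio in (1.6, 2], both depths >= 8
      r <- runif(1, 1.6, 2.0)
      b <- max(8L, round(dp / (1 + r)))
      a <- min(dp - b, as.integer(floor(b * r)))
      c(as.integer(a), as.integer(b))[c(2, 1)] # ref-major
    } else {
      # binomial draw conditioned on the het detection rule (both depths
      # >= 8, within twofold): planted calls are detected variants
      a <- rbinom(1, dp, 0.5)
      lo <- max(8L, as.integer(ceiling(dp / 3)))
      hi <- min(dp - 8L, as.integer(floor(2 * dp / 3)))
      a <- min(max(a, lo), hi)
      c(dp - a, a)
    }
  } else if (gt == "1/1") {
    k <- rbinom(1, dp, ad_noise)
    c(k, dp - k)
  } else { # 0/0
    k <- rbinom(1, dp, ad_noise)
    c(dp - k, k)
  }
}

# Workhorse shared by generate_cohort() and scenario_paper(): expand a
# site plan (one row per site) into the long per-sample call table.
# Plan columns: chrom, pos, ref, alt, parental_gt, somatic_line (NA for
# inherited background sites), ambiguous.
build_call_table <- function(plan, parental, lines, depth_mean,
                             quality_fail_fracs, ad_noise) {
  n <- nrow(plan)
  sq <- draw_site_quality(n, quality_fail_fracs)
  samples <- c(parental, lines)
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    gts <- setNames(rep(plan$parental_gt[i], length(samples)), samples)
    if (!is.na(plan$somatic_line[i])) gts[plan$somatic_line[i]] <- "0/1"
    purrr::map_dfr(samples, function(s) {
      dp <- max(24L, rpois(1, depth_mean))
      gq_fail <- runif(1) < quality_fail_fracs[["gq"]]
      tibble(
        chrom = plan$chrom[i], pos = plan$pos[i],
        ref = plan$ref[i], alt = plan$alt[i],
        qual = sq$qual[i], qd = sq$qd[i], mq = sq$mq[i],
        fs = sq$fs[i], haplotype_score = sq$haplotype_score[i],
        sample = s, gt = unname(gts[s]),
        ad = list(draw_ad(gts[s], dp, ad_noise,
                          plan$ambiguous[i] && s == plan$somatic_line[i])),
        gq = if (gq_fail) sample(0:60, 1) else sample(70L:99L, 1)
      )
    })
  })
  sort_karyotype(rows)
}

#' Generate a synthetic multi-sample exome call set with planted truth
#'
#' Emits a long call table (the [read_vcf()] schema) for a parental line
#' plus derived lines. Background sites carry parental genotypes drawn
#' from Hardy-Weinberg proportions and are inherited identically by all
#' derived lines; each derived line additionally receives planted de
#' novo heterozygous SNVs on its own synthetic chromosome. Allelic
#' depths are binomial around Poisson site depths, with het draws
#' truncated to the detection rule (planted calls model variants that
#' were detected); quality annotations fail each filter clause at the
#' configured fractions. The truth table
#' records every planted SNV with its base-change class, annotation
#' category and ambiguity flag, which is sufficient to score every
#' downstream stage.
#'
#' @param config A [cohort_config()].
#' @param path Optional path; when given the cohort is also written as
#'   plain-text VCF 4.2 via [write_vcf()].
#' @return List with `variants` (long call tibble), `truth` (tibble:
#'   `chrom`, `pos`, `sample`, `ref`, `alt`, `change`, `category`,
#'   `ambiguous`), `ambiguous` (exclusion-list tibble for the flagged
#'   subset) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), path = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_along(config$lines))
  af <- config$het_af
  gt_probs <- c((1 - af)^2, 2 * af * (1 - af), af^2)

  bg_n <- config$n_sites
  bg <- tibble(
    chrom = sample(chroms, bg_n, replace = TRUE),
    pos = sample.int(2e8, bg_n),
    ref = sample(BASES, bg_n, replace = TRUE),
    parental_gt = sample(c("0/0", "0/1", "1/1"), bg_n, replace = TRUE,
                         prob = gt_probs),
    somatic_line = NA_character_,
    ambiguous = FALSE
  )
  bg$alt <- vapply(bg$ref, function(r) sample(setdiff(BASES, r), 1), character(1))

  som <- purrr::map_dfr(seq_along(config$lines), function(i) {
    k <- config$somatic_per_line[i]
    if (!k) return(tibble())
    change <- sample(names(config$spectrum_probs), k, replace = TRUE,
                     prob = config$spectrum_probs)
    tibble(
      chrom = chroms[i],
      pos = sample.int(2e8, k),
      ref = substr(change, 1, 1),
      alt = substr(change, 3, 3),
      parental_gt = "0/0",
      somatic_line = config$lines[i],
      ambiguous = runif(k) < config$ambiguous_frac,
      category = sample(names(config$category_probs), k, replace = TRUE,
                        prob = config$category_probs)
    )
  })

  if (!nrow(som)) {
    som <- tibble(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), parental_gt = character(0),
                  somatic_line = character(0), ambiguous = logical(0),
                  category = character(0))
  }
  plan <- bind_rows(bg[, c("chrom", "pos", "ref", "alt", "parental_gt",
                           "somatic_line", "ambiguous")],
                    som[, c("chrom", "pos", "ref", "alt", "parental_gt",
                            "somatic_line", "ambiguous")])
  plan <- distinct(plan, .data$chrom, .data$pos, .keep_all = TRUE)
  som <- semi_join(som, plan, by = c("chrom", "pos"))

  variants <- build_call_table(plan, config$parental, config$lines,
                               config$depth_mean, config$quality_fail_fracs,
                               config$ad_noise)
  truth <- som %>%
    mutate(sample = .data$somatic_line,
           change = paste0(.data$ref, ">", .data$alt)) %>%
    select("chrom", "pos", "sample", "ref", "alt", "change", "category",
           "ambiguous") %>%
    sort_karyotype()
  ambiguous <- truth[truth$ambiguous, c("chrom", "pos", "sample")]
  if (!is.null(path)) write_vcf(variants, path)
  list(variants = variants, truth = truth, ambiguous = ambiguous,
       config = config)
}

#' Generate non-overlapping structural-alteration intervals
#'
#' Places the requested intervals end-to-start with random gaps along
#' each synthetic chromosome and plants the stated number of SNV
#' positions strictly inside each interval, so that every planted
#' position satisfies [overlaps()] by construction.
#'
#' @param spec Data frame with columns `chrom`, `length_kb`, `event`,
#'   `n_snvs` (one row per region).
#' @param chrom_length_bp Length of each synthetic chromosome.
#' @param seed Integer seed.
#' @return List with `regions` (interval tibble with labels `region1`,
#'   `region2`, ...) and `planted` (tibble `chrom`, `pos`, `label`).
#' @export
generate_structural_regions <- function(spec, chrom_length_bp = 2.5e8,
                                        seed = 1L) {
  spec <- as_tibble(spec)
  set.seed(as.integer(seed))
  if (!nrow(spec)) {
    return(list(
      regions = as_intervals(tibble(chrom = character(0), start = numeric(0),
                                    end = 1, event = character(0),
                                    label = character(0))[0, ]),
      planted = tibble(chrom = character(0), pos = integer(0),
                       label = character(0))
    ))
  }
  regions <- purrr::map_dfr(split(spec, factor(spec$chrom, levels = unique(spec$chrom))),
                            function(sp) {
    total <- sum(sp$length_kb) * 1000
    if (total >= chrom_length_bp) {
      abort("intervals exceed chromosome length")
    }
    gaps <- runif(nrow(sp), 0, (chrom_length_bp - total) / (nrow(sp) + 1))
    start <- cumsum(gaps) + cumsum(c(0, head(sp$length_kb * 1000, -1)))
    tibble(chrom = sp$chrom, start = floor(start),
           end = floor(start) + sp$length_kb * 1000,
           event = sp$event, n_snvs = sp$n_snvs)
  })
  regions$label <- paste0("region", seq_len(nrow(regions)))
  planted <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    k <- regions$n_snvs[i]
    if (!k) return(tibble())
    tibble(
      chrom = regions$chrom[i],
      # 1-based positions in (start, end] are strictly inside [start, end)
      pos = sample((regions$start[i] + 1):regions$end[i], k),
      label = regions$label[i]
    )
  })
  list(regions = as_intervals(regions[, c("chrom", "start", "end", "event",
                                          "label")]),
       planted = planted)
}

#' Generate synthetic Q-FISH intensity tables at a target TFI ratio
#'
#' Per-telomere intensities are lognormal: the control's log-median sits
#' at `log(control_tfi)` and the sample's at `log(control_tfi *
#' sample_ratio)`, so per-spread medians target the requested ratio;
#' `dispersion` is the lognormal sigma (0 gives the exact ratio).
#'
#' @param sample_ratio Target sample/control TFI ratio (> 0).
#' @param n_spreads Number of sample metaphase spreads.
#' @param signals_per_spread Telomere signals scored per spread (up to
#'   184 for 46 chromosomes with both arms; default 92).
#' @param dispersion Lognormal sigma of intensities (default 0.4).
#' @param seed Integer seed.
#' @param control_tfi Control line median TFI level (arbitrary units).
#' @param n_control_spreads Control spreads (default 5).
#' @param sample,control Sample names used in the output table.
#' @return Tibble `sample`, `spread_id`, `intensity` covering both the
#'   sample and its control spreads.
#' @export
generate_qfish <- function(sample_ratio, n_spreads,
                           signals_per_spread = 92, dispersion = 0.4,
                           seed = 1L, control_tfi = 8671,
                           n_control_spreads = 5,
                           sample = "sample", control = "control") {
  if (sample_ratio <= 0) abort("sample_ratio must be positive")
  set.seed(as.integer(seed))
  one <- function(name, n, level) {
    purrr::map_dfr(seq_len(n), function(i) {
      tibble(sample = name, spread_id = paste0(name, "_s", i),
             intensity = rlnorm(signals_per_spread, log(level), dispersion))
    })
  }
  bind_rows(one(sample, n_spreads, control_tfi * sample_ratio),
            one(control, n_control_spreads, control_tfi))
}

#' Fixed-seed fixture bundle reproducing the published study's accounting
#'
#' Emits a complete synthetic input bundle shaped like the study this
#' package re-analyses: a parental fibroblast line (AT1OS) and four
#' derived iPS lines carrying 84/49/36/43 planted candidate somatic SNVs
#' (212 in total), of which 2 fall inside a 23,314-kb copy-neutral LOH
#' region and 37 inside a 3,586-kb deletion (both in ATiPS-262), 1
#' inside a 234-kb deletion (ATiPS-024), and 5 (2/1/1/1 across lines)
#' are flagged on the ambiguous-call exclusion list. Running
#' [somatic_pipeline()] on the bundle therefore ends at 167 somatic
#' SNVs, split 43/48/35/41 across the four lines. The per-line candidate
#' and ambiguous splits are a reconstruction consistent with those
#' published stage counts; they are not printed in the source study.
#' Q-FISH intensity tables targeting the published TFI ratios for each
#' sample/control batch pairing are included.
#'
#' @param seed Integer seed (the bundle is a pure function of it).
#' @return List with `variants`, `truth`, `regions`, `ambiguous`,
#'   `parental`, `lines`, and `qfish` (list of `tfi`, `pairing`).
#' @export
scenario_paper <- function(seed = 1L) {
  seed <- as.integer(seed)
  lines <- c("ATiPS-262", "ATiPS-263", "ATiPS-264", "ATiPS-024")
  parental <- "AT1OS"
  reg <- generate_structural_regions(
    tibble(chrom = c("chr7", "chr12", "chr16"),
           length_kb = c(23314, 3586, 234),
           event = c("CNLOH", "deletion", "deletion"),
           n_snvs = c(2, 37, 1)),
    seed = seed
  )
  set.seed(seed + 1L)
  in_region <- function(lab) reg$planted[reg$planted$label == lab, c("chrom", "pos")]
  outside <- function(chrom, k) {
    r <- reg$regions[reg$regions$chrom == chrom, ]
    pos <- integer(0)
    while (length(pos) < k) {
      cand <- sample.int(2.4e8, 4 * k)
      if (nrow(r)) cand <- cand[!(r$start[1] < cand & cand <= r$end[1])]
      pos <- unique(c(pos, cand))
    }
    tibble(chrom = chrom, pos = pos[seq_len(k)])
  }
  som_pos <- bind_rows(
    mutate(bind_rows(in_region("region1"), in_region("region2"),
                     outside("chr7", 25), outside("chr12", 20)),
           sample = "ATiPS-262"),
    mutate(outside("chr2", 49), sample = "ATiPS-263"),
    mutate(outside("chr3", 36), sample = "ATiPS-264"),
    mutate(bind_rows(in_region("region3"), outside("chr16", 42)),
           sample = "ATiPS-024")
  )
  change <- sample(CHANGES12, nrow(som_pos), replace = TRUE)
  cfg <- cohort_config() # reuse the default exome-like category mix
  category <- sample(names(cfg$category_probs), nrow(som_pos), replace = TRUE,
                     prob = cfg$category_probs)
  plan <- tibble(
    chrom = som_pos$chrom, pos = som_pos$pos,
    ref = substr(change, 1, 1), alt = substr(change, 3, 3),
    parental_gt = "0/0", somatic_line = som_pos$sample,
    category = category, ambiguous = FALSE
  )
  # background inherited sites on an unrelated chromosome
  nbg <- 100
  bg <- tibble(
    chrom = "chr1", pos = sample.int(2.4e8, nbg),
    ref = sample(BASES, nbg, replace = TRUE),
    parental_gt = sample(c("0/0", "0/1", "1/1"), nbg, replace = TRUE,
                         prob = c(0.49, 0.42, 0.09)),
    somatic_line = NA_character_, category = NA_character_, ambiguous = FALSE
  )
  bg$alt <- vapply(bg$ref, function(r) sample(setdiff(BASES, r), 1), character(1))
  plan <- bind_rows(plan, bg)

  # ambiguous picks: outside-region sites only, 2/1/1/1 across lines
  tagged <- match_regions(plan[!is.na(plan$somatic_line), ], reg$regions)
  free <- tagged[is.na(tagged$region_label), ]
  amb_n <- c("ATiPS-262" = 2, "ATiPS-263" = 1, "ATiPS-264" = 1, "ATiPS-024" = 1)
  amb <- purrr::map_dfr(names(amb_n), function(l) {
    cand <- free[free$somatic_line == l, c("chrom", "pos")]
    cand <- cand[sample.int(nrow(cand), amb_n[[l]]), ]
    mutate(cand, sample = l)
  })
  plan$ambiguous <- paste(plan$chrom, plan$pos) %in% paste(amb$chrom, amb$pos)

  variants <- build_call_table(
    plan, parental, lines, depth_mean = 90,
    quality_fail_fracs = c(qual = 0, qd = 0, mq = 0, fs = 0, hs = 0, gq = 0),
    ad_noise = 0
  )
  truth <- plan %>%
    filter(!is.na(.data$somatic_line)) %>%
    mutate(sample = .data$somatic_line,
           change = paste0(.data$ref, ">", .data$alt)) %>%
    select("chrom", "pos", "sample", "ref", "alt", "change", "category",
           "ambiguous") %>%
    sort_karyotype()

  qf <- bind_rows(
    generate_qfish(0.598, 4, seed = seed + 10L, control_tfi = 8671,
                   n_control_spreads = 5, sample = "AT1OS", control = "TIG-1a"),
    generate_qfish(1.902, 8, seed = seed + 11L, control_tfi = 8671,
                   n_control_spreads = 0, sample = "ATiPS-262", control = "TIG-1a"),
    generate_qfish(2.263, 12, seed = seed + 12L, control_tfi = 7751,
                   n_control_spreads = 7, sample = "ATiPS-264", control = "TIG-1b"),
    generate_qfish(2.393, 14, seed = seed + 13L, control_tfi = 7378,
                   n_control_spreads = 10, sample = "ATiPS-024", control = "TIG-1c")
  )
  pairing <- tibble(
    sample = c("AT1OS", "ATiPS-262", "ATiPS-264", "ATiPS-024"),
    control = c("TIG-1a", "TIG-1a", "TIG-1b", "TIG-1c")
  )
  list(variants = variants, truth = truth, regions = reg$regions,
       ambiguous = amb, parental = parental, lines = lines,
       qfish = list(tfi = qf, pairing = pairing))
}
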