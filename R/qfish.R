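#' Median telomere fluorescence intensity of one metaphase spread
#'
#' The per-spread summary is the median over all telomere signals scored
#' (p- and q-arm telomeres of every chromosome in the spread), which is
#' robust to the occasional saturated or near-background signal.
#'
#' @param intensities Numeric vector of telomere fluorescence intensities
#'   (arbitrary units, all >= 0) for one spread.
#' @return The median intensity (mean of the central pair for even n).
#' @examples
#' median_tfi(c(1, 2, 3, 100)) # 2.5 -- insensitive to the outlier
#' @export
median_tfi <- function(intensities) {
  if (!length(intensities)) abort("spread has no telomere signals")
  if (any(is.na(intensities)) || any(intensities < 0)) {
    abort("intensities must be non-negative and non-missing")
  }
  median(intensities)
}

#' Per-sample telomere fluorescence summary over spreads
#'
#' Summarises a sample's metaphase spreads as the arithmetic mean of the
#' per-spread median TFIs (the quantity tabulated as "mean of median
#' TFI"), together with the number of spreads examined.
#'
#' @param tfi Data frame with columns `spread_id` and `intensity`; one
#'   row per telomere signal (a `sample` column, if present, must contain
#'   a single value).
#' @return One-row tibble: `n_spreads`, `mean_median_tfi`.
#' @export
sample_tfi <- function(tfi) {
  tfi <- as_tibble(tfi)
  if (!nrow(tfi)) abort("no spreads supplied")
  if ("sample" %in% names(tfi) && length(unique(tfi$sample)) > 1) {
    abort("sample_tfi summarises one sample; got several (use qfish_table)")
  }
  med <- tfi %>%
    group_by(.data$spread_id) %>%
    summarise(med = median_tfi(.data$intensity), .groups = "drop")
  tibble(n_spreads = nrow(med), mean_median_tfi = mean(med$med))
}

#' Telomere length from a sample/control TFI pair
#'
#' Telomere length is estimated by scaling a calibrated control line's
#' known length by the sample-to-control TFI ratio. The control is a
#' fibroblast standard whose telomere length (6.91 kbp at 34 population
#' doublings) anchors the fluorescence scale. Following the convention
#' of the published measurement table, the ratio is rounded to 3 decimals
#' before scaling, so tabulated ratio and length are mutually consistent;
#' the unrounded ratio is also returned.
#'
#' @param sample_tfi Sample mean-of-median TFI.
#' @param control_tfi Paired control mean-of-median TFI (> 0). Each
#'   sample must be paired with the control batch measured alongside it;
#'   the pairing is part of the input, never inferred.
#' @param control_length_kbp Control telomere length in kbp (default 6.91).
#' @return One-row tibble: `sample_tfi`, `control_tfi`, `ratio`
#'   (unrounded), `ratio_display` (3 decimals), `length_kbp`
#'   (= `ratio_display * control_length_kbp`, unrounded), and
#'   `length_display` (2 decimals).
#' @examples
#' telomere_length(5187, 8671) # ratio 0.598, length 4.13 kbp
#' @export
telomere_length <- function(sample_tfi, control_tfi, control_length_kbp = 6.91) {
  if (any(control_tfi <= 0)) abort("control TFI must be positive")
  ratio <- sample_tfi / control_tfi
  ratio_display <- round(ratio, 3)
  length_kbp <- ratio_display * control_length_kbp
  tibble(
    sample_tfi = sample_tfi, control_tfi = control_tfi,
    control_length_kbp = control_length_kbp,
    ratio = ratio, ratio_display = ratio_display,
    length_kbp = length_kbp, length_display = round(length_kbp, 2)
  )
}

#' Telomere-length table for a Q-FISH experiment
#'
#' End-to-end per-sample summary from raw per-telomere intensities:
#' spreads are summarised by [sample_tfi()], each sample's TFI is divided
#' by its paired control batch's TFI, and lengths are scaled from the
#' control length, mirroring the columns of a standard Q-FISH report
#' table.
#'
#' @param tfi Data frame with columns `sample`, `spread_id`, `intensity`.
#' @param pairing Data frame with columns `sample`, `control` mapping
#'   each non-control sample to its control sample name in `tfi`.
#' @param control_length_kbp Control telomere length in kbp.
#' @return A `qfish_table` tibble: `sample`, `n_spreads`,
#'   `mean_median_tfi`, `ratio` (3 decimals), `length_kbp` (2 decimals).
#' @export
qfish_table <- function(tfi, pairing, control_length_kbp = 6.91) {
  tfi <- as_tibble(tfi)
  pairing <- as_tibble(pairing)
  per_sample <- tfi %>%
    group_by(.data$sample) %>%
    dplyr::group_modify(~ sample_tfi(.x)) %>%
    ungroup()
  missing <- setdiff(c(pairing$sample, pairing$control), per_sample$sample)
  if (length(missing)) {
    abort(paste0("pairing references sample absent from intensity table: ",
                 missing[1]))
  }
  rows <- purrr::pmap_dfr(pairing, function(sample, control, ...) {
    s <- per_sample[per_sample$sample == sample, ]
    c0 <- per_sample[per_sample$sample == control, ]
    tl <- telomere_length(s$mean_median_tfi, c0$mean_median_tfi,
                          control_length_kbp)
    tibble(sample = sample, control = control, n_spreads = s$n_spreads,
           mean_median_tfi = s$mean_median_tfi,
           ratio = tl$ratio_display, length_kbp = tl$length_display)
  })
  class(rows) <- c("qfish_table", class(rows))
  rows
}

#' @export
autoplot.qfish_table <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$sample, .data$length_kbp),
                                  y = .data$length_kbp)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "telomere length (kbp)",
                  title = "Q-FISH telomere length estimates") +
    ggplot2::theme_minimal()
}
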