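#' Reprogramming efficiency
#'
#' Fraction of plated somatic cells that yielded an iPS colony, as a
#' percentage.
#'
#' @param colonies Number of iPS colonies obtained.
#' @param cells_plated Number of transduced cells plated (> 0).
#' @return One-row tibble: `colonies`, `cells_plated`,
#'   `efficiency_percent`.
#' @examples
#' reprogramming_efficiency(10, 2e5) # 0.005 %
#' @export
reprogramming_efficiency <- function(colonies, cells_plated) {
  if (cells_plated <= 0) abort("cells_plated must be positive")
  if (colonies < 0) abort("colonies must be non-negative")
  if (colonies > cells_plated) abort("more colonies than cells plated")
  tibble(colonies = colonies, cells_plated = cells_plated,
         efficiency_percent = 100 * colonies / cells_plated)
}

#' Fold ratio between two reprogramming efficiencies
#'
#' @param a,b Results of [reprogramming_efficiency()] (or one-row data
#'   frames with an `efficiency_percent` column).
#' @return `a`'s efficiency divided by `b`'s, as a plain number.
#' @examples
#' at <- reprogramming_efficiency(10, 2e5)
#' ctrl <- reprogramming_efficiency(1000, 2e5)
#' efficiency_ratio(at, ctrl) # 0.01, i.e. 1/100
#' @export
efficiency_ratio <- function(a, b) {
  ea <- a$efficiency_percent
  eb <- b$efficiency_percent
  if (eb == 0) abort("reference efficiency is zero")
  ea / eb
}

#' Post-irradiation survival fraction
#'
#' Viable-cell counts after irradiation are normalised to the matched
#' non-irradiated control, whose mean defines 100%. Each irradiated
#' replicate becomes `100 * count / mean(control)`; the mean and standard
#' deviation over replicates are reported. The statistic is invariant to
#' the counting unit.
#'
#' @param irradiated Numeric vector of viable-cell counts after
#'   irradiation (one per replicate).
#' @param control Numeric vector of matched non-irradiated counts.
#' @return One-row tibble: `n`, `percent_mean`, `percent_sd`.
#' @export
survival_fraction <- function(irradiated, control) {
  if (!length(irradiated) || !length(control)) abort("empty replicate set")
  if (mean(control) <= 0) abort("control mean must be positive")
  pct <- 100 * irradiated / mean(control)
  tibble(n = length(pct), percent_mean = mean(pct),
         percent_sd = if (length(pct) > 1) sd(pct) else 0)
}

#' Survival curve over irradiation doses
#'
#' Applies [survival_fraction()] per dose against the 0-Gy rows; by
#' construction the 0-Gy point is 100% on average.
#'
#' @param counts Data frame with columns `dose_gy` and `count` (one row
#'   per replicate).
#' @return Tibble with one row per dose: `dose_gy`, `n`, `percent_mean`,
#'   `percent_sd`.
#' @export
survival_table <- function(counts) {
  counts <- as_tibble(counts)
  ctrl <- counts$count[counts$dose_gy == 0]
  if (!length(ctrl)) abort("no 0-Gy control rows")
  counts %>%
    group_by(.data$dose_gy) %>%
    dplyr::group_modify(~ survival_fraction(.x$count, ctrl)) %>%
    ungroup() %>%
    arrange(.data$dose_gy)
}
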