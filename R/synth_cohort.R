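#' Canonical hemodynamic metric names
#'
#' Column names of the per-model metric row, in reporting order:
#' dome TAWSS summaries (dyne/cm^2), dome OSI summaries, and the
#' low-shear-area percentages.
#'
#' @return Character vector of metric names.
#' @export
shear_metric_names <- function() {
  c("Mean_TAWSS", "Max_TAWSS", "Min_TAWSS",
    "Mean_OSI", "Max_OSI", "Min_OSI",
    "LSA", "MTLSA_50", "MTLSA_70", "MTLSA_90")
}

# Valid range per metric, used to clip noisy synthetic draws.
metric_ranges <- function() {
  rbind(Mean_TAWSS = c(0, Inf), Max_TAWSS = c(0, Inf),
        Min_TAWSS = c(0, Inf),
        Mean_OSI = c(0, 0.5), Max_OSI = c(0, 0.5), Min_OSI = c(0, 0.5),
        LSA = c(0, 100), MTLSA_50 = c(0, 100), MTLSA_70 = c(0, 100),
        MTLSA_90 = c(0, 100))
}

#' Baseline metric template for synthetic cohorts
#'
#' Typical dome shear summaries of a stable cerebral aneurysm, used as
#' the center of synthetic cohort draws.
#'
#' @return Named numeric vector over [shear_metric_names()].
#' @export
cohort_baseline <- function() {
  c(Mean_TAWSS = 55.60, Max_TAWSS = 140.08, Min_TAWSS = 11.14,
    Mean_OSI = 0.03, Max_OSI = 0.27, Min_OSI = 0.002,
    LSA = 46.72, MTLSA_50 = 37.60, MTLSA_70 = 55.74, MTLSA_90 = 69.81)
}

# Default per-metric between/within-pair noise SDs, on each metric's
# own scale (dyne/cm^2, OSI units, percentage points).
cohort_noise_defaults <- function() {
  c(Mean_TAWSS = 20, Max_TAWSS = 60, Min_TAWSS = 5,
    Mean_OSI = 0.02, Max_OSI = 0.1, Min_OSI = 0.002,
    LSA = 25, MTLSA_50 = 25, MTLSA_70 = 25, MTLSA_90 = 25)
}

#' Generate a matched-pair growing/stable cohort
#'
#' Each pair has one stable and one growing member. The stable member
#' is the baseline template plus independent Gaussian noise; the
#' growing member equals its stable partner plus independent noise on
#' every metric, plus the additive `effect` on the single metric named
#' by `effect_metric`. All metrics are clipped to their valid ranges
#' (TAWSS >= 0, OSI in [0, 0.5], area fractions in [0, 100]).
#'
#' @param n_pairs number of matched pairs (>= 1).
#' @param baseline named numeric template over [shear_metric_names()].
#' @param effect additive shift applied to the growing member on
#'   `effect_metric`, in that metric's units.
#' @param effect_metric name of the shifted metric.
#' @param noise_sd per-metric noise SD: a single number recycled over
#'   all metrics, or a named vector; `NULL` uses built-in defaults.
#' @param location location label shared within each pair.
#' @param seed integer seed; draws are reproducible given the seed.
#' @return A `paired_cohort` data.frame with columns `pair_id`,
#'   `group` ("stable"/"growing"), `location`, then one column per
#'   metric.
#' @examples
#' coh <- make_cohort(11, effect = 17.56, effect_metric = "MTLSA_70",
#'                    noise_sd = 25, seed = 7)
#' head(coh)
#' @export
make_cohort <- function(n_pairs, baseline = cohort_baseline(),
                        effect = 0, effect_metric = "MTLSA_70",
                        noise_sd = NULL, location = "ICA", seed = 1L) {
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L) {
    stop("`n_pairs` must be at least 1", call. = FALSE)
  }
  metrics <- shear_metric_names()
  if (!all(metrics %in% names(baseline))) {
    stop("`baseline` must name all metrics: ",
         paste(metrics, collapse = ", "), call. = FALSE)
  }
  if (!effect_metric %in% metrics) {
    stop("unknown metric `", effect_metric, "`; valid metrics are: ",
         paste(metrics, collapse = ", "), call. = FALSE)
  }
  if (is.null(noise_sd)) noise_sd <- cohort_noise_defaults()
  if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep(noise_sd, length(metrics)), metrics)
  }
  if (!all(metrics %in% names(noise_sd))) {
    stop("`noise_sd` must be a single number or name all metrics",
         call. = FALSE)
  }
  if (any(noise_sd[metrics] < 0)) stop("`noise_sd` must be >= 0",
                                       call. = FALSE)

  set.seed(as.integer(seed))
  ranges <- metric_ranges()
  stable <- matrix(NA_real_, n_pairs, length(metrics),
                   dimnames = list(NULL, metrics))
  growing <- stable
  for (m in metrics) {
    s <- baseline[[m]] + stats::rnorm(n_pairs, 0, noise_sd[[m]])
    g <- s + stats::rnorm(n_pairs, 0, noise_sd[[m]]) +
      if (m == effect_metric) effect else 0
    stable[, m] <- pmin(pmax(s, ranges[m, 1L]), ranges[m, 2L])
    growing[, m] <- pmin(pmax(g, ranges[m, 1L]), ranges[m, 2L])
  }
  out <- data.frame(
    pair_id = rep(seq_len(n_pairs), each = 2L),
    group = rep(c("stable", "growing"), times = n_pairs),
    location = rep(location, length.out = n_pairs)[
      rep(seq_len(n_pairs), each = 2L)],
    stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, 2L * n_pairs, length(metrics),
                 dimnames = list(NULL, metrics))
  vals[seq(1L, 2L * n_pairs, by = 2L), ] <- stable
  vals[seq(2L, 2L * n_pairs, by = 2L), ] <- growing
  out <- cbind(out, as.data.frame(vals))
  class(out) <- c("paired_cohort", "data.frame")
  out
}
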