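#' Aneurysm size measurement
#'
#' Three orthogonal diameters of an aneurysm at one scan, with an
#' ellipsoid volume estimate pi/6 d1 d2 d3.
#'
#' @param diameters numeric vector of 3 orthogonal diameters in mm.
#' @param date scan date (anything orderable, e.g. `Date`); optional.
#' @return An object of class `aneurysm_measurement` with `diameters`,
#'   `date` and `volume` (mm^3).
#' @export
aneurysm_measurement <- function(diameters, date = NULL) {
  if (length(diameters) != 3L || any(is.na(diameters))) {
    stop("three orthogonal diameters are required (missing dimension)",
         call. = FALSE)
  }
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop("diameters must be positive (mm)", call. = FALSE)
  }
  structure(list(diameters = as.numeric(diameters), date = date,
                 volume = pi / 6 * prod(diameters)),
            class = "aneurysm_measurement")
}

#' Classify aneurysm growth between two scans
#'
#' An aneurysm is classified as growing when at least two of its three
#' orthogonal diameters increased by 1 mm or more between baseline and
#' follow-up; otherwise it is stable.
#'
#' @param baseline,followup [aneurysm_measurement()] objects (or bare
#'   length-3 diameter vectors in mm).
#' @param min_increase_mm growth threshold per dimension (default 1).
#' @param min_dimensions number of dimensions that must grow
#'   (default 2).
#' @return `"growing"` or `"stable"`.
#' @examples
#' classify_growth(c(5, 5, 5), c(6.2, 6.1, 5.0))  # growing
#' classify_growth(c(5, 5, 5), c(5.9, 5.9, 5.9))  # stable
#' @export
classify_growth <- function(baseline, followup, min_increase_mm = 1,
                            min_dimensions = 2L) {
  as_meas <- function(x) {
    if (inherits(x, "aneurysm_measurement")) x else aneurysm_measurement(x)
  }
  baseline <- as_meas(baseline)
  followup <- as_meas(followup)
  if (!is.null(baseline$date) && !is.null(followup$date) &&
      !(followup$date > baseline$date)) {
    stop("follow-up scan must be later than baseline", call. = FALSE)
  }
  delta <- followup$diameters - baseline$diameters
  if (sum(delta >= min_increase_mm) >= min_dimensions) "growing" else "stable"
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Tests whether paired differences `x - y` are symmetric about zero
#' using the Wilcoxon signed-rank statistic W (sum of ranks of
#' positive differences, mid-ranks for tied magnitudes). For
#' `n <= exact_max` effective pairs the two-sided p-value is computed
#' from the full permutation distribution over all 2^n sign
#' assignments (enumerated by dynamic programming over doubled ranks);
#' beyond that a normal approximation with tie and continuity
#' corrections is used. Zero differences are dropped before ranking
#' (`zero_method = "wilcox"`) or included in the ranking and then
#' removed from W (`"pratt"`).
#'
#' @param x,y equal-length paired numeric vectors (growing and stable
#'   members of each pair).
#' @param zero_method treatment of zero differences.
#' @param exact_max largest effective n for exact enumeration.
#' @return A list of class `paired_test_result`: `statistic` (W),
#'   `p_value` (two-sided), `n_effective`, `method`, `degenerate`
#'   (TRUE when all differences are zero, in which case p = 1).
#' @examples
#' wilcoxon_paired_exact(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p_value
#' # 2/32 = 0.0625: all five differences positive
#' @export
wilcoxon_paired_exact <- function(x, y,
                                  zero_method = c("wilcox", "pratt"),
                                  exact_max = 20L) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y) || length(x) < 1L) {
    stop("`x` and `y` must be equal-length paired vectors (n >= 1)",
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("paired values must be finite", call. = FALSE)
  }
  d <- x - y
  if (all(d == 0)) {
    return(structure(list(statistic = 0, p_value = 1, n_effective = 0L,
                          method = "degenerate", degenerate = TRUE),
                     class = "paired_test_result"))
  }
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    r <- r_all[keep]
    d <- d[keep]
  }
  n <- length(d)
  W <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))   # doubled mid-ranks are integers
  M2 <- sum(r2)
  if (n <= exact_max) {
    # counts[s + 1] = number of sign assignments with doubled-rank sum s
    counts <- numeric(M2 + 1L)
    counts[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(M2 + 1L - rr)])
      counts <- counts + shifted
    }
    w2 <- round(2 * W)
    dev <- abs(seq(0L, M2) - M2 / 2)
    p <- sum(counts[dev >= abs(w2 - M2 / 2) - 1e-9]) / 2^n
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  structure(list(statistic = W, p_value = p, n_effective = n,
                 method = method, degenerate = FALSE),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    "Paired Wilcoxon signed-rank: W = %g, n = %d, p = %.4g (%s)\n",
    x$statistic, x$n_effective, x$p_value, x$method))
  invisible(x)
}

# Extract per-pair (stable, growing) value matrices for one metric.
cohort_pairs <- function(cohort, metric) {
  if (!metric %in% names(cohort)) {
    stop(sprintf("metric `%s` missing from cohort table", metric),
         call. = FALSE)
  }
  ids <- unique(cohort$pair_id)
  g <- s <- numeric(length(ids))
  for (i in seq_along(ids)) {
    rows <- cohort[cohort$pair_id == ids[i], ]
    gi <- rows[rows$group == "growing", metric]
    si <- rows[rows$group == "stable", metric]
    if (length(gi) != 1L || length(si) != 1L) {
      stop(sprintf(
        "pair %s must have exactly one growing and one stable member",
        ids[i]), call. = FALSE)
    }
    if (is.na(gi) || is.na(si)) {
      stop(sprintf("metric `%s` missing for pair %s", metric, ids[i]),
           call. = FALSE)
    }
    g[i] <- gi
    s[i] <- si
  }
  list(growing = g, stable = s)
}

#' Shapiro-Wilk normality gate on paired differences
#'
#' Runs a Shapiro-Wilk test on the growing-minus-stable differences of
#' every metric. If any metric rejects normality at `alpha` (or is
#' degenerate, i.e. all differences equal), a nonparametric paired
#' test is recommended for the cohort.
#'
#' @param cohort a `paired_cohort` table (see [make_cohort()]).
#' @param alpha rejection level (default 0.05).
#' @param metrics metric columns to gate; defaults to all canonical
#'   metrics present.
#' @return A list with `table` (per metric: W, p, normal, degenerate)
#'   and `recommendation` ("nonparametric" or "parametric").
#' @export
shapiro_wilk_gate <- function(cohort, alpha = 0.05,
                              metrics = intersect(shear_metric_names(),
                                                  names(cohort))) {
  ids <- unique(cohort$pair_id)
  if (length(ids) < 3L) {
    stop("normality gate needs at least 3 pairs", call. = FALSE)
  }
  rows <- lapply(metrics, function(m) {
    pr <- cohort_pairs(cohort, m)
    d <- pr$growing - pr$stable
    if (diff(range(d)) == 0) {
      data.frame(metric = m, W = NA_real_, p_value = NA_real_,
                 normal = FALSE, degenerate = TRUE)
    } else {
      sw <- stats::shapiro.test(d)
      data.frame(metric = m, W = unname(sw$statistic),
                 p_value = sw$p.value, normal = sw$p.value > alpha,
                 degenerate = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  rec <- if (any(!tab$normal)) "nonparametric" else "parametric"
  list(table = tab, recommendation = rec)
}

#' Cohort comparison report
#'
#' Per-metric group means and SDs with the exact paired Wilcoxon
#' signed-rank p-value comparing growing against stable members, in
#' canonical metric order. Metrics with p at or below `alpha` are
#' flagged.
#'
#' @param cohort a `paired_cohort` table.
#' @param alpha significance flag level (default 0.1).
#' @param zero_method passed to [wilcoxon_paired_exact()].
#' @return A `cohort_report` data.frame: one row per metric with
#'   `stable_mean`, `stable_sd`, `growing_mean`, `growing_sd`,
#'   `n_pairs`, `statistic`, `p_value`, `significant`.
#' @export
cohort_report <- function(cohort, alpha = 0.1, zero_method = "wilcox") {
  metrics <- intersect(shear_metric_names(), names(cohort))
  if (length(metrics) == 0L) {
    stop("cohort table contains no recognized metric columns",
         call. = FALSE)
  }
  rows <- lapply(metrics, function(m) {
    pr <- cohort_pairs(cohort, m)
    ts <- wilcoxon_paired_exact(pr$growing, pr$stable,
                                zero_method = zero_method)
    data.frame(metric = m,
               stable_mean = mean(pr$stable),
               stable_sd = stats::sd(pr$stable),
               growing_mean = mean(pr$growing),
               growing_sd = stats::sd(pr$growing),
               n_pairs = length(pr$growing),
               statistic = ts$statistic,
               p_value = ts$p_value,
               significant = ts$p_value <= alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("cohort_report", "data.frame")
  out
}
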