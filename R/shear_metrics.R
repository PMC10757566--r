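#' Per-point TAWSS and OSI from a WSS vector time series
#'
#' Time-averaged wall shear stress TAWSS = (1/T) integral |WSS(t)| dt
#' and oscillatory shear index
#' OSI = 1/2 (1 - |integral WSS dt| / integral |WSS| dt), with time
#' integrals taken by the trapezoid rule on the stored (possibly
#' non-uniform) grid over one cardiac cycle. OSI is defined as 0 at
#' points where the shear magnitude integrates to 0.
#'
#' @param field a [tri_surface_field()].
#' @return A list with numeric vectors `tawss` (dyne/cm^2, >= 0) and
#'   `osi` (in [0, 0.5]), one entry per surface point.
#' @export
pointwise_tawss_osi <- function(field) {
  stopifnot(inherits(field, "tri_surface_field"))
  t <- field$times
  T_ <- t[length(t)]
  w <- trapz_weights(t)
  mag <- sqrt(field$wss[, 1L, ]^2 + field$wss[, 2L, ]^2 +
                field$wss[, 3L, ]^2)          # n_points x n_times
  S <- as.vector(mag %*% w)                    # integral |WSS| dt
  vx <- as.vector(field$wss[, 1L, ] %*% w)
  vy <- as.vector(field$wss[, 2L, ] %*% w)
  vz <- as.vector(field$wss[, 3L, ] %*% w)
  vmag <- sqrt(vx^2 + vy^2 + vz^2)
  osi <- rep(0, length(S))
  nz <- S > 0
  osi[nz] <- 0.5 * (1 - vmag[nz] / S[nz])
  # guard against rounding just outside [0, 0.5]
  osi <- pmin(pmax(osi, 0), 0.5)
  list(tawss = S / T_, osi = osi)
}

#' Area-weighted region summary of TAWSS and OSI
#'
#' Summarizes per-point TAWSS and OSI over the dome and parent
#' regions. Regional means are area-weighted over region triangles
#' (per-triangle value = mean of its vertex values, per-triangle
#' region = majority vote of vertex labels, ties to parent); minima
#' and maxima are taken over region points. Excluded points (label 0)
#' contribute to no region. Dome low-shear areas are filled in via
#' [low_shear_areas()].
#'
#' @param field a [tri_surface_field()].
#' @param tawss,osi per-point vectors from [pointwise_tawss_osi()];
#'   computed from `field` when omitted.
#' @param lsa_sd_mult SD multiplier in the LSA threshold (default 1).
#' @return An object of class `region_shear_summary`: lists `dome` and
#'   `parent` (each with `tawss_mean/min/max`, `osi_mean/min/max`,
#'   `area`), `lsa` and named vector `mtlsa` (percent).
#' @export
region_summary <- function(field, tawss = NULL, osi = NULL,
                           lsa_sd_mult = 1) {
  stopifnot(inherits(field, "tri_surface_field"))
  if (is.null(tawss) || is.null(osi)) {
    pw <- pointwise_tawss_osi(field)
    tawss <- pw$tawss
    osi <- pw$osi
  }
  t_area <- triangle_areas(field$points, field$triangles)
  t_reg <- triangle_regions(field$triangles, field$region)
  t_tawss <- triangle_values(field$triangles, tawss)
  t_osi <- triangle_values(field$triangles, osi)

  one_region <- function(lab) {
    tri <- t_reg == lab
    pts <- field$region == lab
    if (!any(tri) || !any(pts)) {
      stop(sprintf("region %d is empty", lab), call. = FALSE)
    }
    a <- t_area[tri]
    list(tawss_mean = sum(a * t_tawss[tri]) / sum(a),
         tawss_min = min(tawss[pts]), tawss_max = max(tawss[pts]),
         osi_mean = sum(a * t_osi[tri]) / sum(a),
         osi_min = min(osi[pts]), osi_max = max(osi[pts]),
         area = sum(a))
  }
  dome <- one_region(1L)
  parent <- one_region(2L)
  a_par <- t_area[t_reg == 2L]
  v_par <- t_tawss[t_reg == 2L]
  parent$tawss_sd <- sqrt(sum(a_par * (v_par - parent$tawss_mean)^2) /
                            sum(a_par))
  ls <- low_shear_areas(field, tawss,
                        parent_summary = parent, lsa_sd_mult = lsa_sd_mult)
  structure(list(dome = dome, parent = parent, lsa = ls$lsa,
                 mtlsa = ls$mtlsa),
            class = "region_shear_summary")
}

#' Dome low-shear area metrics
#'
#' LSA is the percentage of dome area whose TAWSS falls at least
#' `lsa_sd_mult` (spatial, area-weighted) standard deviations below
#' the parent-artery mean TAWSS; a non-positive threshold gives
#' LSA = 0. MTLSA_X is the percentage of dome area with TAWSS below
#' X% of the parent mean. Both use per-triangle TAWSS (vertex means)
#' with strict `<` at the threshold.
#'
#' @param field a [tri_surface_field()].
#' @param tawss per-point TAWSS vector.
#' @param parent_summary list with `tawss_mean` (> 0) and `tawss_sd`
#'   of the parent region, e.g. the `parent` element of a
#'   [region_summary()].
#' @param thresholds MTLSA thresholds as percents of the parent mean.
#' @param lsa_sd_mult SD multiplier in the LSA threshold.
#' @return List with `lsa` (percent) and named vector `mtlsa`.
#' @export
low_shear_areas <- function(field, tawss, parent_summary,
                            thresholds = c(50, 70, 90), lsa_sd_mult = 1) {
  stopifnot(inherits(field, "tri_surface_field"))
  pm <- parent_summary$tawss_mean
  psd <- parent_summary$tawss_sd
  if (!is.finite(pm) || pm <= 0) {
    stop("parent mean TAWSS must be positive", call. = FALSE)
  }
  t_area <- triangle_areas(field$points, field$triangles)
  t_reg <- triangle_regions(field$triangles, field$region)
  t_val <- triangle_values(field$triangles, tawss)
  dome <- t_reg == 1L
  a <- t_area[dome]
  v <- t_val[dome]
  total <- sum(a)
  if (total <= 0) stop("dome region has zero area", call. = FALSE)
  mtlsa <- vapply(thresholds,
                  function(x) 100 * sum(a[v < x / 100 * pm]) / total,
                  numeric(1))
  names(mtlsa) <- as.character(thresholds)
  thr <- pm - lsa_sd_mult * psd
  lsa <- if (!is.finite(thr) || thr <= 0) 0 else 100 * sum(a[v < thr]) / total
  list(lsa = lsa, mtlsa = mtlsa)
}

#' One-row metric table of a region summary
#'
#' Flattens a [region_summary()] into the canonical per-model metric
#' row used in cohort tables (dome summaries and low-shear areas; see
#' [shear_metric_names()]).
#'
#' @param summary a `region_shear_summary`.
#' @return A one-row data.frame with the canonical metric columns plus
#'   `Parent_Mean_TAWSS` and `Parent_SD_TAWSS`.
#' @export
metrics_row <- function(summary) {
  stopifnot(inherits(summary, "region_shear_summary"))
  data.frame(Mean_TAWSS = summary$dome$tawss_mean,
             Max_TAWSS = summary$dome$tawss_max,
             Min_TAWSS = summary$dome$tawss_min,
             Mean_OSI = summary$dome$osi_mean,
             Max_OSI = summary$dome$osi_max,
             Min_OSI = summary$dome$osi_min,
             LSA = summary$lsa,
             MTLSA_50 = summary$mtlsa[["50"]],
             MTLSA_70 = summary$mtlsa[["70"]],
             MTLSA_90 = summary$mtlsa[["90"]],
             Parent_Mean_TAWSS = summary$parent$tawss_mean,
             Parent_SD_TAWSS = summary$parent$tawss_sd)
}

#' @export
print.region_shear_summary <- function(x, ...) {
  cat(sprintf(
    "Region shear summary\n  dome:   mean TAWSS %.4g (min %.4g, max %.4g) dyne/cm^2, mean OSI %.3g, area %.4g cm^2\n",
    x$dome$tawss_mean, x$dome$tawss_min, x$dome$tawss_max,
    x$dome$osi_mean, x$dome$area))
  cat(sprintf(
    "  parent: mean TAWSS %.4g (SD %.3g), area %.4g cm^2\n",
    x$parent$tawss_mean, x$parent$tawss_sd, x$parent$area))
  cat(sprintf("  LSA %.2f%%; MTLSA %s\n", x$lsa,
              paste(sprintf("%s%%: %.2f", names(x$mtlsa), x$mtlsa),
                    collapse = ", ")))
  invisible(x)
}
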