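#' Labeled triangulated surface with a wall-shear-stress time series
#'
#' The postprocessing substrate: a triangle mesh in cm with a per-point
#' region label (0 = excluded, 1 = aneurysm dome, 2 = parent vessel)
#' and a per-point wall-shear-stress vector (dyne/cm^2) sampled at each
#' time in `times`, spanning one cardiac cycle [0, T].
#'
#' @param points numeric matrix (n x 3) of point coordinates in cm.
#' @param triangles integer matrix (m x 3) of 1-based point indices.
#' @param region integer vector of length n with values in {0, 1, 2}.
#' @param times strictly increasing sample times in s, starting at 0.
#' @param wss numeric array (n x 3 x length(times)) of WSS vectors.
#' @return An object of class `tri_surface_field`.
#' @export
tri_surface_field <- function(points, triangles, region, times, wss) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  region <- as.integer(region)
  n <- nrow(points)
  if (ncol(points) != 3L) stop("`points` must be n x 3", call. = FALSE)
  if (ncol(triangles) != 3L) stop("`triangles` must be m x 3", call. = FALSE)
  if (any(triangles < 1L) || any(triangles > n)) {
    stop("triangle indices out of range", call. = FALSE)
  }
  if (length(region) != n || any(!region %in% 0:2)) {
    stop("`region` must be one label in {0, 1, 2} per point", call. = FALSE)
  }
  if (!any(region == 1L) || !any(region == 2L)) {
    stop("surface must contain at least one dome and one parent point",
         call. = FALSE)
  }
  if (length(times) < 2L || times[1L] != 0 || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing and start at 0", call. = FALSE)
  }
  dw <- dim(wss)
  if (is.null(dw) || length(dw) != 3L || dw[1L] != n || dw[2L] != 3L ||
      dw[3L] != length(times)) {
    stop("`wss` must be an array of dim (n_points, 3, n_times)",
         call. = FALSE)
  }
  bad <- which(!is.finite(wss), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite WSS value at point %d, time index %d",
                 bad[1L, 1L], bad[1L, 3L]), call. = FALSE)
  }
  structure(list(points = points, triangles = triangles, region = region,
                 times = as.numeric(times), wss = wss),
            class = "tri_surface_field")
}

#' @export
print.tri_surface_field <- function(x, ...) {
  cat(sprintf(
    "Triangulated WSS surface: %d points, %d triangles, %d time samples over %.3g s\n",
    nrow(x$points), nrow(x$triangles), length(x$times),
    x$times[length(x$times)]))
  cat(sprintf("  regions: %d dome, %d parent, %d excluded points\n",
              sum(x$region == 1L), sum(x$region == 2L), sum(x$region == 0L)))
  invisible(x)
}

# Per-triangle areas by the cross-product formula (cm^2).
triangle_areas <- function(points, triangles) {
  p0 <- points[triangles[, 1L], , drop = FALSE]
  e1 <- points[triangles[, 2L], , drop = FALSE] - p0
  e2 <- points[triangles[, 3L], , drop = FALSE] - p0
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Per-triangle region label: majority vote of vertex labels, any full
# tie (all three labels distinct) goes to the parent vessel.
triangle_regions <- function(triangles, region) {
  r1 <- region[triangles[, 1L]]
  r2 <- region[triangles[, 2L]]
  r3 <- region[triangles[, 3L]]
  out <- integer(nrow(triangles))
  for (lab in 0:2) {
    cnt <- (r1 == lab) + (r2 == lab) + (r3 == lab)
    out[cnt >= 2L] <- lab
  }
  tie <- (r1 != r2) & (r2 != r3) & (r1 != r3)
  out[tie] <- 2L
  out
}

# Per-triangle scalar value: mean of the three vertex values.
triangle_values <- function(triangles, values) {
  (values[triangles[, 1L]] + values[triangles[, 2L]] +
     values[triangles[, 3L]]) / 3
}
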