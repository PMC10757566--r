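#' Specification of a synthetic aneurysm model
#'
#' Parameters of the synthetic tube-plus-dome surface generator. The
#' generated model stands in for an image-derived vessel with a
#' side-wall aneurysm: a straight parent tube of radius `tube_radius`
#' carrying a smoothly heterogeneous wall-shear field, and a
#' hemispherical dome of radius `dome_radius` carrying a two-level
#' field in which an exact area fraction `dome_low_fraction` of the
#' dome sits at `dome_low_level` times the realized parent mean TAWSS
#' and the rest sits exactly at the parent mean.
#'
#' @param tube_radius parent tube radius in cm.
#' @param tube_length parent tube length in cm.
#' @param dome_radius aneurysm dome (hemisphere) radius in cm.
#' @param mesh_edge_size target triangle edge length in cm; must not
#'   exceed `dome_radius`.
#' @param parent_tawss_mean nominal parent-artery mean TAWSS in
#'   dyne/cm^2; defaults to the Poiseuille wall shear of a 4 cm^3/s
#'   mean flow in the tube.
#' @param parent_tawss_cv spatial coefficient of variation of the
#'   parent TAWSS field; must satisfy `parent_tawss_cv * sqrt(2) < 1`
#'   so the field stays positive.
#' @param dome_low_fraction exact dome area fraction assigned the low
#'   shear level, in [0, 1].
#' @param dome_low_level low shear level as a fraction of the realized
#'   parent mean, in [0, 1).
#' @param osi_target oscillatory shear index of every dome point, in
#'   [0, 0.5]; must be 0 or at least 1 / (2 (n_time_samples - 1)).
#' @param n_time_samples samples over the cardiac cycle (>= 7).
#' @param period cardiac period in s.
#' @param seed integer seed for the (small) random component of the
#'   parent field phase.
#' @return An object of class `patient_spec`.
#' @export
patient_spec <- function(tube_radius = 0.2,
                         tube_length = 2.0,
                         dome_radius = 0.35,
                         mesh_edge_size = 0.06,
                         parent_tawss_mean = NULL,
                         parent_tawss_cv = 0.2,
                         dome_low_fraction = 0.3,
                         dome_low_level = 0.1,
                         osi_target = 0.25,
                         n_time_samples = 21L,
                         period = 1.0,
                         seed = 1L) {
  if (is.null(parent_tawss_mean)) {
    parent_tawss_mean <- poiseuille_wss(fluid_properties(), 4.0, tube_radius)
  }
  spec <- list(tube_radius = tube_radius, tube_length = tube_length,
               dome_radius = dome_radius, mesh_edge_size = mesh_edge_size,
               parent_tawss_mean = parent_tawss_mean,
               parent_tawss_cv = parent_tawss_cv,
               dome_low_fraction = dome_low_fraction,
               dome_low_level = dome_low_level,
               osi_target = osi_target,
               n_time_samples = as.integer(n_time_samples),
               period = period, seed = as.integer(seed))
  pos <- c("tube_radius", "tube_length", "dome_radius", "mesh_edge_size",
           "parent_tawss_mean", "period")
  for (f in pos) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number", f),
           call. = FALSE)
    }
  }
  if (spec$mesh_edge_size > spec$dome_radius) {
    stop("`mesh_edge_size` larger than `dome_radius`: degenerate mesh refused",
         call. = FALSE)
  }
  if (spec$parent_tawss_cv < 0 || spec$parent_tawss_cv * sqrt(2) >= 1) {
    stop("`parent_tawss_cv` must lie in [0, 1/sqrt(2)) for a positive field",
         call. = FALSE)
  }
  if (spec$dome_low_fraction < 0 || spec$dome_low_fraction > 1) {
    stop("`dome_low_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (spec$dome_low_level < 0 || spec$dome_low_level >= 1) {
    stop("`dome_low_level` must lie in [0, 1)", call. = FALSE)
  }
  if (spec$osi_target < 0 || spec$osi_target > 0.5) {
    stop("`osi_target` must lie in [0, 0.5]", call. = FALSE)
  }
  if (spec$n_time_samples < 7L) {
    stop("`n_time_samples` must be at least 7", call. = FALSE)
  }
  n_int <- spec$n_time_samples - 1L
  if (spec$osi_target > 0 && spec$osi_target < 1 / (2 * n_int)) {
    stop(sprintf(
      "`osi_target` %g below the smallest nonzero value representable on %d intervals (%g); use 0 or increase n_time_samples",
      spec$osi_target, n_int, 1 / (2 * n_int)), call. = FALSE)
  }
  structure(spec, class = "patient_spec")
}

# Open cylinder mesh along z: rings of n_c points at n_z + 1 stations.
cylinder_mesh <- function(radius, length, edge) {
  n_c <- max(8L, ceiling(2 * pi * radius / edge))
  n_z <- max(3L, ceiling(length / edge))
  th <- 2 * pi * (seq_len(n_c) - 1L) / n_c
  z <- seq(0, length, length.out = n_z + 1L)
  pts <- cbind(rep(radius * cos(th), n_z + 1L),
               rep(radius * sin(th), n_z + 1L),
               rep(z, each = n_c))
  tris <- matrix(0L, nrow = 2L * n_c * n_z, ncol = 3L)
  row <- 0L
  for (i in seq_len(n_z)) {
    base0 <- (i - 1L) * n_c
    base1 <- i * n_c
    for (j in seq_len(n_c)) {
      jn <- if (j == n_c) 1L else j + 1L
      tris[row + 1L, ] <- c(base0 + j, base0 + jn, base1 + j)
      tris[row + 2L, ] <- c(base0 + jn, base1 + jn, base1 + j)
      row <- row + 2L
    }
  }
  list(points = pts, triangles = tris)
}

# Hemisphere mesh of radius b, pole along +x, centered at `center`.
# Triangles are emitted pole-outward so cumulative-area walks select a
# cap-like patch.
hemisphere_mesh <- function(radius, center, edge) {
  n_phi <- max(3L, ceiling((pi / 2) * radius / edge))
  n_psi <- max(8L, ceiling(2 * pi * radius / edge))
  phi <- (pi / 2) * seq_len(n_phi) / n_phi
  psi <- 2 * pi * (seq_len(n_psi) - 1L) / n_psi
  pts <- matrix(center + c(radius, 0, 0), nrow = 1L, ncol = 3L,
                byrow = TRUE)  # pole at center + radius * x-hat
  for (i in seq_len(n_phi)) {
    ring <- cbind(radius * cos(phi[i]),
                  radius * sin(phi[i]) * cos(psi),
                  radius * sin(phi[i]) * sin(psi))
    pts <- rbind(pts, sweep(ring, 2L, center, "+"))
  }
  tris <- matrix(0L, nrow = n_psi * (2L * n_phi - 1L), ncol = 3L)
  row <- 0L
  for (j in seq_len(n_psi)) {  # pole fan
    jn <- if (j == n_psi) 1L else j + 1L
    tris[row + 1L, ] <- c(1L, 1L + j, 1L + jn)
    row <- row + 1L
  }
  for (i in seq_len(n_phi - 1L)) {  # quad strips
    base0 <- 1L + (i - 1L) * n_psi
    base1 <- 1L + i * n_psi
    for (j in seq_len(n_psi)) {
      jn <- if (j == n_psi) 1L else j + 1L
      tris[row + 1L, ] <- c(base0 + j, base1 + j, base0 + jn)
      tris[row + 2L, ] <- c(base0 + jn, base1 + j, base1 + jn)
      row <- row + 2L
    }
  }
  list(points = pts, triangles = tris)
}

# Direction-angle schedule over n+1 uniform samples realizing a target
# OSI exactly under trapezoidal integration of a constant-magnitude
# rotating vector. The schedule is 0 ... 0, +theta, -theta, pi ... pi;
# the integer flip position and the transition angle are solved in
# closed form from the target vector-integral magnitude m = (1-2a) n.
osi_angle_schedule <- function(n_intervals, osi_target) {
  n <- n_intervals
  if (osi_target == 0) return(rep(0, n + 1L))
  m <- (1 - 2 * osi_target) * n
  cand <- seq(3L - n, n - 3L, by = 2L)  # parity fixed by k integrality
  cand <- cand[abs(cand - m) <= 2]
  if (length(cand) == 0L) {
    stop("no feasible angle schedule; osi_target too close to 0 for this grid",
         call. = FALSE)
  }
  b <- cand[which.min(abs(cand - m))]
  k <- (b + n - 3L) / 2
  theta <- acos((m - b) / 2)
  c(rep(0, k + 1L), theta, -theta, rep(pi, n - k - 2L))
}

#' Generate a synthetic aneurysm surface with known ground truth
#'
#' Builds the labeled tube-plus-dome surface described by a
#' [patient_spec()], attaches a WSS vector time series with exactly
#' known per-point TAWSS and OSI, and returns the analytically exact
#' region summaries the metrics pipeline should recover.
#'
#' The dome's low-shear patch is made exact by splitting the one
#' triangle that straddles the requested cumulative area at the exact
#' area parameter, then duplicating the seam vertices so that every
#' dome triangle is purely low-level or purely normal-level. Dome
#' points oscillate between a direction and its reversal on a schedule
#' solved in closed form so the trapezoidal OSI equals `osi_target`
#' exactly; parent points have a constant direction (OSI 0).
#'
#' @param spec a [patient_spec()].
#' @return A list of class `synthetic_patient` with elements `field`
#'   (a [tri_surface_field()]), `truth` (ground-truth record: realized
#'   parent/dome area-weighted mean TAWSS, parent spatial SD, areas,
#'   LSA and MTLSA_50/70/90 percentages, dome OSI) and `spec`.
#' @examples
#' pat <- make_patient(patient_spec(mesh_edge_size = 0.12,
#'                                  n_time_samples = 9))
#' pat$truth$mtlsa[["70"]]
#' @export
make_patient <- function(spec) {
  stopifnot(inherits(spec, "patient_spec"))
  tube <- cylinder_mesh(spec$tube_radius, spec$tube_length,
                        spec$mesh_edge_size)
  dome <- hemisphere_mesh(spec$dome_radius,
                          c(spec$tube_radius, 0, spec$tube_length / 2),
                          spec$mesh_edge_size)

  n_tube <- nrow(tube$points)
  points <- rbind(tube$points, dome$points)
  dome_tris <- dome$triangles + n_tube
  tri_low <- matrix(integer(0), ncol = 3L)
  tri_norm <- dome_tris

  f <- spec$dome_low_fraction
  if (f > 0 && f < 1) {
    areas <- triangle_areas(points, dome_tris)
    target <- f * sum(areas)
    cum <- cumsum(areas)
    j <- which(cum > target)[1L]
    if (is.na(j)) j <- nrow(dome_tris)
    prev <- if (j > 1L) cum[j - 1L] else 0
    lambda <- (target - prev) / areas[j]
    if (lambda < 1e-12 || lambda > 1 - 1e-12) {
      sel <- seq_len(if (lambda < 1e-12) j - 1L else j)
      tri_low <- dome_tris[sel, , drop = FALSE]
      tri_norm <- dome_tris[setdiff(seq_len(nrow(dome_tris)), sel), ,
                            drop = FALSE]
    } else {
      i0 <- dome_tris[j, 1L]; i1 <- dome_tris[j, 2L]; i2 <- dome_tris[j, 3L]
      mpt <- points[i1, ] + lambda * (points[i2, ] - points[i1, ])
      points <- rbind(points, mpt)
      im <- nrow(points)
      tri_low <- rbind(dome_tris[seq_len(j - 1L), , drop = FALSE],
                       c(i0, i1, im))
      rest <- if (j < nrow(dome_tris)) {
        dome_tris[(j + 1L):nrow(dome_tris), , drop = FALSE]
      } else {
        matrix(integer(0), ncol = 3L)
      }
      tri_norm <- rbind(c(i0, im, i2), rest)
    }
    # Duplicate seam vertices so low and normal triangles share none.
    shared <- intersect(unique(as.vector(tri_low)),
                        unique(as.vector(tri_norm)))
    if (length(shared) > 0L) {
      dup_idx <- nrow(points) + seq_along(shared)
      points <- rbind(points, points[shared, , drop = FALSE])
      remap <- seq_len(nrow(points))
      remap[shared] <- dup_idx
      tri_norm <- matrix(remap[tri_norm], ncol = 3L)
    }
  } else if (f >= 1) {
    tri_low <- dome_tris
    tri_norm <- matrix(integer(0), ncol = 3L)
  }

  triangles <- rbind(tube$triangles, tri_low, tri_norm)
  n_pts <- nrow(points)
  region <- c(rep(2L, n_tube), rep(1L, n_pts - n_tube))

  # Parent TAWSS: smooth axial modulation with seeded phase; spatial
  # CV set by the sqrt(2) amplitude of a sinusoid.
  set.seed(spec$seed)
  phase <- stats::runif(1, 0, 2 * pi)
  tau <- numeric(n_pts)
  zt <- points[seq_len(n_tube), 3L]
  tau[seq_len(n_tube)] <- spec$parent_tawss_mean *
    (1 + sqrt(2) * spec$parent_tawss_cv *
       sin(2 * pi * zt / spec$tube_length + phase))

  t_area <- triangle_areas(points, triangles)
  t_reg <- triangle_regions(triangles, region)
  par_tris <- which(t_reg == 2L)
  t_val_par <- triangle_values(triangles, tau)[par_tris]
  a_par <- t_area[par_tris]
  parent_mean <- sum(a_par * t_val_par) / sum(a_par)
  parent_sd <- sqrt(sum(a_par * (t_val_par - parent_mean)^2) / sum(a_par))

  low_level <- spec$dome_low_level * parent_mean
  low_pts <- unique(as.vector(tri_low))
  dome_pts <- which(region == 1L)
  tau[dome_pts] <- parent_mean
  tau[low_pts] <- low_level

  # Exact ground-truth bookkeeping on the realized triangles.
  t_val <- triangle_values(triangles, tau)
  dome_tris_all <- which(t_reg == 1L)
  a_dome <- t_area[dome_tris_all]
  v_dome <- t_val[dome_tris_all]
  dome_area <- sum(a_dome)
  dome_mean <- sum(a_dome * v_dome) / dome_area
  mtlsa <- vapply(c(50, 70, 90), function(x) {
    100 * sum(a_dome[v_dome < x / 100 * parent_mean]) / dome_area
  }, numeric(1))
  names(mtlsa) <- c("50", "70", "90")
  lsa_thr <- parent_mean - parent_sd
  lsa <- if (lsa_thr <= 0) 0 else 100 * sum(a_dome[v_dome < lsa_thr]) / dome_area

  # Time series: constant magnitude per point; dome direction follows
  # the exact-OSI angle schedule in the (z, x) plane.
  times <- seq(0, spec$period, length.out = spec$n_time_samples)
  ang <- osi_angle_schedule(spec$n_time_samples - 1L, spec$osi_target)
  wss <- array(0, dim = c(n_pts, 3L, spec$n_time_samples))
  for (s in seq_along(times)) {
    wss[, 3L, s] <- tau          # parent and dome share z as primary axis
    wss[dome_pts, 3L, s] <- tau[dome_pts] * cos(ang[s])
    wss[dome_pts, 1L, s] <- tau[dome_pts] * sin(ang[s])
  }

  field <- tri_surface_field(points, triangles, region, times, wss)
  truth <- list(parent_mean_tawss = parent_mean,
                parent_sd_tawss = parent_sd,
                dome_mean_tawss = dome_mean,
                dome_area = dome_area,
                parent_area = sum(a_par),
                low_fraction = f,
                low_level = low_level,
                mtlsa = mtlsa,
                lsa = lsa,
                dome_osi = spec$osi_target)
  structure(list(field = field, truth = truth, spec = spec),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat("Synthetic aneurysm model\n")
  print(x$field)
  cat(sprintf("  truth: parent mean TAWSS %.4g, dome mean %.4g dyne/cm^2, MTLSA_70 %.2f%%, OSI %.3g\n",
              x$truth$parent_mean_tawss, x$truth$dome_mean_tawss,
              x$truth$mtlsa[["70"]], x$truth$dome_osi))
  invisible(x)
}
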