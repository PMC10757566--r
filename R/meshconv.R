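#' Mesh-convergence trace
#'
#' Bookkeeping for a WSS mesh-refinement study: the sequence of
#' (maximum edge size, spatially averaged dome TAWSS) pairs produced
#' by successive refinements. Two residual conventions are derived:
#' `residual_final`, (TAWSS - final TAWSS)/final TAWSS, used for
#' reporting against the finest mesh, and `residual_prev`,
#' (TAWSS - previous TAWSS)/previous TAWSS, used by the convergence
#' rule. Normalized mesh size is edge size / final edge size.
#'
#' @param edge_size_mm maximum edge sizes in mm, strictly decreasing.
#' @param dome_mean_tawss spatially averaged dome TAWSS in dyne/cm^2.
#' @return A `convergence_trace` data.frame with columns
#'   `edge_size_mm`, `dome_mean_tawss`, `normalized_size`,
#'   `residual_final`, `residual_prev`.
#' @export
convergence_trace <- function(edge_size_mm, dome_mean_tawss) {
  n <- length(edge_size_mm)
  if (n < 1L || length(dome_mean_tawss) != n) {
    stop("need equal-length edge size and TAWSS vectors (>= 1 record)",
         call. = FALSE)
  }
  if (any(!is.finite(edge_size_mm)) || any(edge_size_mm <= 0) ||
      any(!is.finite(dome_mean_tawss))) {
    stop("edge sizes must be positive and TAWSS finite", call. = FALSE)
  }
  if (n > 1L && any(diff(edge_size_mm) >= 0)) {
    stop("edge sizes must be strictly decreasing across refinements",
         call. = FALSE)
  }
  final <- dome_mean_tawss[n]
  out <- data.frame(
    edge_size_mm = edge_size_mm,
    dome_mean_tawss = dome_mean_tawss,
    normalized_size = edge_size_mm / edge_size_mm[n],
    residual_final = (dome_mean_tawss - final) / final,
    residual_prev = c(NA, diff(dome_mean_tawss) /
                        dome_mean_tawss[-n]))
  class(out) <- c("convergence_trace", "data.frame")
  out
}

#' Mesh-convergence decision
#'
#' A refinement sequence is converged at the first record whose dome
#' mean TAWSS is within `tol` (relative) of the previous refinement's
#' value.
#'
#' @param trace a [convergence_trace()].
#' @param tol relative tolerance (default 0.05).
#' @return List with `converged` (logical) and `index` (1-based index
#'   of the first converged record, NA if none).
#' @examples
#' tr <- convergence_trace(c(0.30, 0.27, 0.243),
#'                         c(10.0, 8.5, 8.6))
#' check_converged(tr)  # converged at index 3
#' @export
check_converged <- function(trace, tol = 0.05) {
  stopifnot(inherits(trace, "convergence_trace"))
  if (nrow(trace) < 2L) return(list(converged = FALSE, index = NA_integer_))
  rel <- abs(trace$residual_prev[-1L])
  hit <- which(rel <= tol)
  if (length(hit) == 0L) return(list(converged = FALSE, index = NA_integer_))
  list(converged = TRUE, index = hit[1L] + 1L)
}

#' Next mesh edge size in a refinement sequence
#'
#' @param current current maximum edge size in mm (> 0).
#' @param factor multiplicative decrement per refinement, in (0, 1);
#'   default 0.9 (about a 10% reduction per step).
#' @return The refined edge size, `current * factor`.
#' @export
next_edge_size <- function(current, factor = 0.9) {
  if (!is.numeric(current) || any(current <= 0)) {
    stop("`current` edge size must be positive (mm)", call. = FALSE)
  }
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 ||
      factor >= 1) {
    stop("`factor` must lie strictly between 0 and 1", call. = FALSE)
  }
  current * factor
}
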