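# Parameter-plane classification sweeps and region-boundary extraction.
#
# Outcome regions in e.g. the (dV_d, dV_f) window-shift plane: "No EADs",
# banded "EADs", and "Repolarization Failure". The "green" boundary is the
# No-EADs/EADs transition, the "black" boundary the EADs/failure transition.

.sweep_axes <- c("dV_d", "dV_f", "Ko", "alpha", "beta", "gCa")

.set_axis <- function(params, axis, value) {
  if (!axis %in% .sweep_axes)
    stop("axis must be one of: ", paste(.sweep_axes, collapse = ", "))
  if (axis == "Ko") apply_Ko(params, value)
  else {
    params[[axis]] <- as.numeric(value)
    validate_params(params)
    params
  }
}

#' Define a 2-D sweep grid
#'
#' @param axis1,axis2 parameter identifiers: one of \code{dV_d},
#'   \code{dV_f}, \code{Ko}, \code{alpha}, \code{beta}, \code{gCa}.
#' @param range1,range2 \code{c(lo, hi)} per axis (lo < hi).
#' @param n1,n2 grid counts (>= 1).
#' @return a \code{grid_spec} list.
#' @export
grid_spec <- function(axis1, axis2, range1, range2, n1 = 60, n2 = 60) {
  stopifnot(axis1 %in% .sweep_axes, axis2 %in% .sweep_axes,
            length(range1) == 2, length(range2) == 2,
            range1[1] < range1[2] || n1 == 1,
            range2[1] < range2[2] || n2 == 1, n1 >= 1, n2 >= 1)
  structure(list(axis1 = axis1, axis2 = axis2, range1 = range1,
                 range2 = range2, n1 = as.integer(n1), n2 = as.integer(n2)),
            class = "grid_spec")
}

# classification of one parameter point under the standard pulse protocol
.classify_point <- function(params, t_end = 10000, ...) {
  tr <- try(integrate_model(params, t_end = t_end), silent = TRUE)
  if (inherits(tr, "try-error"))
    return(list(classification = "INTEGRATION_FAILURE", ead_count = NA_integer_))
  f <- classify_response(tr, ...)
  list(classification = f$classification, ead_count = f$ead_count)
}

#' Classify model outcomes over a 2-D parameter grid
#'
#' Integrates the stimulated model for \code{t_end} ms from rest at every
#' grid cell and records the outcome classification and EAD count. Cells
#' are independent; per-cell integration failures are recorded as
#' \code{INTEGRATION_FAILURE}, not fatal.
#'
#' @param spec a \code{grid_spec}.
#' @param base an \code{ead_params} base parameter set.
#' @param t_end horizon, ms.
#' @param ... passed to \code{classify_response}.
#' @return data.frame with columns \code{axis1}, \code{axis2} (named after
#'   the axes), \code{class}, \code{ead_count}; attribute \code{spec} and
#'   \code{base}.
#' @export
run_grid <- function(spec, base = ead_params(), t_end = 10000, ...) {
  stopifnot(inherits(spec, "grid_spec"))
  v1 <- if (spec$n1 == 1) mean(spec$range1)
        else seq(spec$range1[1], spec$range1[2], length.out = spec$n1)
  v2 <- if (spec$n2 == 1) mean(spec$range2)
        else seq(spec$range2[1], spec$range2[2], length.out = spec$n2)
  cells <- expand.grid(a1 = v1, a2 = v2, KEEP.OUT.ATTRS = FALSE)
  res <- vapply(seq_len(nrow(cells)), function(i) {
    p <- .set_axis(.set_axis(base, spec$axis1, cells$a1[i]),
                   spec$axis2, cells$a2[i])
    cl <- .classify_point(p, t_end = t_end, ...)
    c(cl$classification, cl$ead_count)
  }, character(2))
  out <- data.frame(cells$a1, cells$a2, res[1, ],
                    as.integer(res[2, ]), stringsAsFactors = FALSE)
  names(out) <- c(spec$axis1, spec$axis2, "class", "ead_count")
  attr(out, "spec") <- spec
  attr(out, "base") <- base
  out
}

#' Locate a region boundary by bisection along one parameter
#'
#' @param base an \code{ead_params} object; all parameters but
#'   \code{move_axis} are held at their values in \code{base}.
#' @param move_axis parameter to bisect along.
#' @param bracket \code{c(lo, hi)} whose classifications must differ in the
#'   stated way.
#' @param transition \code{"green"} (No-EADs vs EADs-or-failure) or
#'   \code{"black"} (failure vs not).
#' @param tol bisection resolution in axis units (default 0.01).
#' @param t_end horizon, ms.
#' @param ... passed to \code{classify_response}.
#' @return midpoint of the final bracket (axis units).
#' @export
find_boundary <- function(base, move_axis, bracket, transition = "green",
                          tol = 0.01, t_end = 10000, ...) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  transition <- match.arg(transition, c("green", "black"))
  ind <- function(v) {
    cl <- .classify_point(.set_axis(base, move_axis, v), t_end = t_end,
                          ...)$classification
    if (cl == "INTEGRATION_FAILURE") stop("integration failed at ", v)
    if (transition == "green") cl != "NO_EADS" else cl == "REPOL_FAILURE"
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- ind(lo); fhi <- ind(hi)
  if (flo == fhi)
    stop("bracket endpoints have the same classification for the '",
         transition, "' transition")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ind(mid) == flo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Trace a boundary curve in the window-shift plane
#'
#' For each value of \code{dV_f} in \code{f_values}, bisects along
#' \code{dV_d} within \code{d_bracket} for the requested transition.
#'
#' @param base base parameter set.
#' @param f_values dV_f sample values, mV.
#' @param d_bracket dV_d bisection bracket, mV.
#' @param transition \code{"green"} or \code{"black"}.
#' @param tol bisection resolution, mV.
#' @return a \code{boundary_curve} data.frame with columns \code{dV_d},
#'   \code{dV_f}; attribute \code{transition}.
#' @export
boundary_curve <- function(base = ead_params(), f_values = seq(-1, 7, by = 1),
                           d_bracket = c(-6, 0.5), transition = "green",
                           tol = 0.01) {
  dd <- vapply(f_values, function(fv) {
    b <- .set_axis(base, "dV_f", fv)
    find_boundary(b, "dV_d", d_bracket, transition, tol)
  }, numeric(1))
  out <- data.frame(dV_d = dd, dV_f = f_values)
  attr(out, "transition") <- transition
  class(out) <- c("boundary_curve", "data.frame")
  out
}

#' Fitted slope magnitude of a boundary curve
#'
#' Least-squares line through the boundary points in the (dV_d, dV_f)
#' plane; returns |d(dV_f)/d(dV_d)|. With exactly two points, the segment
#' slope.
#'
#' @param curve a \code{boundary_curve} or data.frame with \code{dV_d},
#'   \code{dV_f} columns.
#' @return dimensionless slope magnitude.
#' @export
boundary_slope <- function(curve) {
  x <- curve$dV_d; y <- curve$dV_f
  if (length(x) < 2) stop("need at least two boundary points")
  if (diff(range(x)) < 1e-12) stop("degenerate boundary: constant dV_d")
  if (length(x) == 2) return(abs(diff(y) / diff(x)))
  abs(unname(coef(lm(y ~ x))[2]))
}
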