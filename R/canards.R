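# Maximal canards of the full system and the signed distance delta.
#
# The attracting slow manifold is computed by integrating a family of
# orbits seeded on the upper attracting sheet of the critical manifold away
# from the fold, and recording where they first cross the fold-adjacent
# section Sigma: the plane V = V(FN) through the folded node. Near the
# folded node the manifold twists, partitioning it into rotational sectors:
# an orbit in sector n executes n small voltage loops (EADs) before leaving
# the fold region. The maximal canards gamma_0, gamma_1, ... are the sector
# boundaries, located here by bisecting the rotation count over the seed
# parameter; gamma_n separates orbits with n loops from orbits with n+1
# loops (or from capture by the depolarized equilibrium E2). A repelling
# family (backward integration from the saddle sheet with a first-order
# slow-manifold seed correction) is provided for visual/diagnostic use: in
# this model the backward fast instability of the d gate makes it
# quantitatively reliable only for short flights.

.V_SCALE <- 100  # mV; voltage normalization for phase-space distances

# first Sigma crossing of an orbit of the autonomous full system
# flag: 0 forward, -1 time-reversed; sec_dir: required crossing direction
.sigma_cross <- function(pv, y0, Vsec, sec_dir, flag, t_max) {
  r <- cpp_integrate(pv, y0, 0, t_max, t_max, 1e-10, 1e-12, -1, flag,
                     Vsec, sec_dir, 1L, 1L)
  if (length(r$ev_t) < 1) return(NULL)
  list(t = r$ev_t[1], state = r$ev_y[1, ])
}

# Sigma anchor: the folded node when one exists; otherwise the
# most-singular point of the fold curve (minimum |dV/dtau| of the
# desingularized flow), through which the canard structure exits as
# parameters leave the folded-node region.
.sigma_anchor <- function(params) {
  fn <- try(folded_node(params), silent = TRUE)
  if (!inherits(fn, "try-error")) return(fn)
  pv <- .pvec(params)
  xs <- seq(0.005, 0.995, length.out = 200)
  Vf <- vapply(xs, .fold_V_at_x, numeric(1), params = params)
  keep <- is.finite(Vf)
  xs <- xs[keep]; Vf <- Vf[keep]
  if (!length(xs)) stop("no fold curve: cannot anchor Sigma")
  r <- vapply(seq_along(xs), function(i)
    abs(cpp_desing_rhs(Vf[i], xs[i], pv)[1]), numeric(1))
  i <- which.min(r)
  list(V = Vf[i], x = xs[i], f = cpp_h(Vf[i], xs[i], pv),
       lambda_s = NA_real_, lambda_w = NA_real_, mu = NA_real_,
       kind = "fold anchor (no folded node)", J = NULL)
}

# seed on the critical manifold at voltage V for IK gate x
.sheet_seed <- function(pv, V, x) {
  g <- cpp_gating(V, pv)
  c(V, g[1, "d_inf"], cpp_h(V, x, pv), x)
}

# seed with the first-order slow-manifold correction of the d gate:
# on the slow manifold dd/dt = d_inf'(V) * Vdot_reduced, so
# d = d_inf - tau_d * d_inf'(V) * Vdot.
.sheet_seed_corrected <- function(pv, V, x) {
  g <- cpp_gating(V, pv)
  hV <- cpp_hV(V, x, pv)
  if (abs(hV) < 1e-12) return(.sheet_seed(pv, V, x))
  dr <- cpp_desing_rhs(V, x, pv)
  vdot <- dr[1] / hV                      # reduced-flow dV/dt
  dd <- 1e-4
  dinf_p <- (cpp_gating(V + dd, pv)[1, "d_inf"] -
             cpp_gating(V - dd, pv)[1, "d_inf"]) / (2 * dd)
  d0 <- g[1, "d_inf"] - g[1, "tau_d"] * dinf_p * vdot
  c(V, d0, cpp_h(V, x, pv), x)
}

#' Compute attracting and repelling slow-manifold traces on Sigma
#'
#' Families of full-system orbits are launched from seed arcs on the upper
#' attracting sheet (at \code{V(FN) + dV_att}) and on the saddle sheet (at
#' \code{V(FN) + dV_rep}, integrated backward in time from seeds with a
#' first-order slow-manifold correction), and recorded where they first
#' cross the section Sigma: the plane \code{V = V(FN)} anchored at the
#' folded node.
#'
#' The attracting trace is quantitatively reliable (forward integration
#' onto an attracting object). The repelling trace is approximate: the
#' backward-time instability of the fast d-gate direction limits its
#' accuracy, which is why canard detection (\code{maximal_canards}) uses
#' rotation-count bisection on the attracting family instead of trace
#' intersection.
#'
#' @param params an \code{ead_params} object.
#' @param x_range seed range of the IK gate x.
#' @param n seeds per family.
#' @param dV_att,dV_rep seed-arc voltage offsets from the folded node, mV.
#' @param t_max integration horizon per orbit, ms.
#' @param node optionally, a precomputed folded node.
#' @return object of class \code{slow_manifolds}: list with \code{node},
#'   \code{sigma_V}, per-family data.frames (\code{attracting},
#'   \code{repelling}) of columns \code{seed_x}, \code{f}, \code{x},
#'   \code{d} (Sigma crossing coordinates), and \code{n_lost} (seeds whose
#'   orbits fail to cross, truncated backward blow-ups included).
#' @export
compute_slow_manifolds <- function(params, x_range = c(0.005, 0.6), n = 121,
                                   dV_att = 20, dV_rep = -4, t_max = 5000,
                                   node = NULL) {
  validate_params(params)
  pv <- .pvec(params)
  fn <- if (is.null(node)) .sigma_anchor(params) else node
  Vsec <- fn$V
  xs <- seq(x_range[1], x_range[2], length.out = n)
  trace_of <- function(dV, flag, sec_dir) {
    rows <- lapply(xs, function(x0) {
      y0 <- if (flag < 0) .sheet_seed_corrected(pv, Vsec + dV, x0)
            else .sheet_seed(pv, Vsec + dV, x0)
      if (y0[3] < 0 || y0[3] > 1) return(NULL)
      cr <- .sigma_cross(pv, y0, Vsec, sec_dir, flag, t_max)
      if (is.null(cr)) return(NULL)
      data.frame(seed_x = x0, f = cr$state[3], x = cr$state[4],
                 d = cr$state[2])
    })
    do.call(rbind, rows)
  }
  att <- trace_of(dV_att, 0L, -1L)
  rep_ <- trace_of(dV_rep, -1L, +1L)
  structure(list(node = fn, sigma_V = Vsec, attracting = att,
                 repelling = rep_,
                 n_lost = 2L * n - NROW(att) - NROW(rep_),
                 params = params, dV_att = dV_att, dV_rep = dV_rep,
                 t_max = t_max),
            class = "slow_manifolds")
}

# arclength coordinate of the projection of p = c(f, x) onto polyline P
.polyline_coord <- function(p, P) {
  n <- nrow(P)
  seglen <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-n, , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  best <- Inf; coord <- 0
  for (i in seq_len(n - 1)) {
    a <- P[i, ]; b <- P[i + 1, ]
    ab <- b - a
    L2 <- sum(ab^2)
    tt <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / L2))
    pr <- a + tt * ab
    d2 <- sum((p - pr)^2)
    if (d2 < best) { best <- d2; coord <- cum[i] + tt * sqrt(L2) }
  }
  coord
}

# attracting-family Sigma crossing for a single seed
.att_cross <- function(sm, x0) {
  pv <- .pvec(sm$params)
  y0 <- .sheet_seed(pv, sm$sigma_V + sm$dV_att, x0)
  cr <- .sigma_cross(pv, y0, sm$sigma_V, -1L, 0L, sm$t_max)
  if (is.null(cr)) return(NULL)
  c(f = cr$state[3], x = cr$state[4])
}

# rotation count of the attracting-family orbit with seed x0: number of
# small V-loops near the fold before the orbit leaves the fold band
# downward (repolarization) -- Inf when it is captured by the depolarized
# equilibrium E2 instead.
.rotation_count <- function(sm, x0, band = 25, t_max = 12000) {
  pv <- .pvec(sm$params)
  y0 <- .sheet_seed(pv, sm$sigma_V + sm$dV_att, x0)
  r <- cpp_integrate(pv, y0, 0, t_max, 0.25, 1e-10, 1e-12, -1, 0L,
                     0, 0L, 0L, 0L)
  V <- r$y[, 1]
  i0 <- which(V < sm$sigma_V)[1]
  if (is.na(i0)) return(Inf)              # never descends to Sigma
  seg <- V[i0:length(V)]
  out <- which(seg < sm$sigma_V - band)[1]
  captured <- is.na(out)
  if (!captured) seg <- seg[seq_len(out)]
  if (length(seg) < 3) return(0L)
  s <- sign(diff(seg)); s[s == 0] <- 1
  nmax <- sum(diff(s) < 0)
  if (captured) Inf else nmax
}

#' Maximal canards on the section Sigma
#'
#' Scans the attracting seed arc, computes each orbit's rotation count near
#' the fold, and bisects every count transition to tolerance \code{tol} in
#' the seed parameter. The refined boundary orbit between counts n and n+1
#' (or between n and capture by E2) is the maximal canard gamma_n; its
#' Sigma crossing, rotation count and arclength position along the
#' attracting trace are returned.
#'
#' @param params an \code{ead_params} object.
#' @param n_max highest index requested (returns up to n_max + 1 canards).
#' @param manifolds optionally, precomputed \code{slow_manifolds}.
#' @param tol bisection tolerance in the seed parameter.
#' @param ... passed to \code{compute_slow_manifolds}.
#' @return object of class \code{maximal_canards}: list with \code{node},
#'   \code{sigma_V}, \code{canards} (data.frame: \code{index},
#'   \code{seed_x}, \code{f}, \code{x}, \code{rotations} -- the count on
#'   the low side of the boundary, \code{coord} -- arclength position along
#'   the attracting trace), and the \code{manifolds} used. Fewer canards
#'   than requested may exist; the returned set is what was found.
#' @export
maximal_canards <- function(params, n_max = 3, manifolds = NULL,
                            tol = 1e-8, ...) {
  sm <- if (is.null(manifolds)) compute_slow_manifolds(params, ...)
        else manifolds
  if (NROW(sm$attracting) < 2)
    stop("attracting slow-manifold trace too short")
  s <- sm$attracting$seed_x
  cnt <- vapply(s, function(x0) as.numeric(.rotation_count(sm, x0)),
                numeric(1))
  # orientation of the EAD side along the Sigma trace: the arclength
  # direction in which rotation counts grow
  P <- as.matrix(sm$attracting[, c("f", "x")])
  vc <- c(0, cumsum(sqrt(rowSums((P[-1, , drop = FALSE] -
                                  P[-nrow(P), , drop = FALSE])^2))))
  cmin <- min(cnt)
  if (all(cnt == cmin)) stop("no rotational structure on the seed arc")
  ead_dir <- sign(mean(vc[cnt > cmin]) - mean(vc[cnt == cmin]))
  # rotation counts are monotone (non-increasing or non-decreasing) along
  # the seed arc: deeper into the funnel means more loops. gamma_n is the
  # boundary where the count first drops to <= n.
  increasing <- which.max(cnt) > which.min(cnt)
  if (increasing) { s <- rev(s); cnt <- rev(cnt) }  # now non-increasing
  found <- lapply(0:n_max, function(nn) {
    above <- which(cnt > nn)
    below <- which(cnt <= nn)
    if (!length(above) || !length(below)) return(NULL)
    i_lo <- max(above)          # last seed with count > nn
    blw <- below[below > i_lo]
    if (!length(blw)) return(NULL)
    i_hi <- min(blw)
    lo <- s[i_lo]; hi <- s[i_hi]
    while (abs(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      cm <- as.numeric(.rotation_count(sm, mid))
      if (cm > nn) lo <- mid else hi <- mid
    }
    sx <- (lo + hi) / 2
    cs <- .att_cross(sm, sx)
    if (is.null(cs)) return(NULL)
    data.frame(index = nn, seed_x = sx, f = cs[["f"]], x = cs[["x"]],
               rotations = nn,
               coord = .polyline_coord(cs,
                 as.matrix(sm$attracting[, c("f", "x")])))
  })
  found <- do.call(rbind, found)
  if (is.null(found) || !nrow(found)) stop("no maximal canards found")
  rownames(found) <- NULL
  structure(list(node = sm$node, sigma_V = sm$sigma_V,
                 canards = found[, c("index", "seed_x", "f", "x",
                                     "rotations", "coord")],
                 ead_dir = ead_dir, manifolds = sm),
            class = "maximal_canards")
}

#' @export
print.maximal_canards <- function(x, ...) {
  cat(sprintf("maximal canards on Sigma (V = %.3f mV):\n", x$sigma_V))
  print(x$canards, row.names = FALSE)
  invisible(x)
}

# first downward Sigma crossing of a pulsed trajectory, after the upstroke
.gamma_cross <- function(params, sigma_V, t_end = 10000) {
  pv <- .pvec(params)
  eqs <- find_equilibria(params)
  y0 <- eqs[[1]]$state
  r <- cpp_integrate(pv, y0, 0, t_end, t_end, 1e-10, 1e-12, -1, 1L,
                     sigma_V, -1L, 10L, 0L)
  if (length(r$ev_t) < 1) return(NULL)
  ok <- which(r$ev_t > params$stim_onset + 50)
  if (!length(ok)) return(NULL)
  c(f = r$ev_y[ok[1], 3], x = r$ev_y[ok[1], 4])
}

#' Rotational-sector assignment of a pulsed orbit
#'
#' Locates the Sigma crossing of the stimulated trajectory and places it
#' among the maximal canards along the attracting trace: the predicted EAD
#' count is the number of canards lying between the crossing and the
#' no-EAD side of the primary canard gamma_0.
#'
#' @param traj an \code{ead_trajectory} from the standard pulse protocol.
#' @param canards a \code{maximal_canards} object for the same parameters.
#' @return list with \code{flag} (\code{"sector"}, \code{"left-of-gamma0"},
#'   \code{"E2-basin"}, or \code{"no-plateau"}) and \code{predicted}
#'   (predicted EAD count; NA when not applicable).
#' @export
sector_of <- function(traj, canards) {
  stopifnot(inherits(canards, "maximal_canards"),
            inherits(traj, "ead_trajectory"))
  cls <- classify_response(traj)
  if (cls$classification == "REPOL_FAILURE")
    return(list(flag = "E2-basin", predicted = NA_integer_))
  g <- .gamma_cross(traj$params, canards$sigma_V, max(traj$times))
  if (is.null(g)) return(list(flag = "no-plateau", predicted = NA_integer_))
  P <- as.matrix(canards$manifolds$attracting[, c("f", "x")])
  gc <- .polyline_coord(g, P)
  cc <- canards$canards$coord
  # number of canards between the crossing and the no-EAD side
  n_pred <- sum(canards$ead_dir * (gc - cc) > 0)
  if (n_pred == 0)
    return(list(flag = "left-of-gamma0", predicted = 0L))
  list(flag = "sector", predicted = as.integer(n_pred))
}

#' Signed distance between the pulsed orbit and the primary maximal canard
#'
#' On the section Sigma, the Euclidean distance in the slow variables
#' (f, x) between the pulsed orbit's crossing and gamma_0's crossing,
#' signed positive when the orbit lies on the no-EAD side of gamma_0. Its
#' zero coincides with the boundary between plain action potentials and
#' action potentials with EADs.
#'
#' @param params base parameter set (the shift is applied on top of it).
#' @param shift_axis \code{"dV_d"} or \code{"dV_f"}.
#' @param magnitude shift magnitude, mV (>= 0): applied as a left shift of
#'   d_inf or right shift of f_inf (the window-broadening direction).
#' @param canards optionally, precomputed \code{maximal_canards} for the
#'   shifted parameters.
#' @return list with \code{delta} (signed, in normalized phase-space units
#'   on Sigma), \code{shift_axis}, \code{magnitude}.
#' @export
canard_delta <- function(params = ead_params(), shift_axis = "dV_d",
                         magnitude = 0, canards = NULL) {
  shift_axis <- match.arg(shift_axis, c("dV_d", "dV_f"))
  sgn <- if (shift_axis == "dV_d") -1 else 1
  p <- .set_axis(params, shift_axis, params[[shift_axis]] + sgn * magnitude)
  mc <- if (is.null(canards)) maximal_canards(p, n_max = 1) else canards
  g <- .gamma_cross(p, mc$sigma_V, 6000)
  if (is.null(g)) stop("pulsed orbit does not reach Sigma")
  P <- as.matrix(mc$manifolds$attracting[, c("f", "x")])
  gc <- .polyline_coord(g, P)
  row0 <- mc$canards[mc$canards$index == 0, , drop = FALSE]
  if (!nrow(row0)) stop("gamma_0 not found at these parameters")
  g0 <- as.numeric(row0[1, c("f", "x")])
  dist <- sqrt(sum((g - g0)^2))
  delta <- dist * ifelse(mc$ead_dir * (gc - row0$coord[1]) > 0, -1, 1)
  list(delta = delta, shift_axis = shift_axis, magnitude = magnitude)
}
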