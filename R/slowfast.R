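# Fast-slow decomposition of the model.
#
# Fast subsystem: (V, d) with (f, x) frozen; its equilibrium surface (with
# d = d_inf(V)) is the critical manifold. Because the current balance is
# affine in f, the manifold is the graph f = h(V, x), computed in closed
# form. The slow (reduced) flow on the manifold, desingularized by the time
# rescaling d tau = h_V dt, has ordinary equilibria on the fold curve
# (h_V = 0): the folded singularities. A folded node (real eigenvalues of
# the same sign, ratio mu = lambda_w/lambda_s in (0,1)) admits a singular
# strong canard that bounds the funnel of orbits crossing the fold.

# residual of the critical-manifold equation at (V, f, x): total current
# with d at quasi-steady state
.manifold_F <- function(V, f, x, params) {
  pv <- .pvec(params)
  g <- cpp_gating(V, pv)
  vapply(seq_along(V), function(i) {
    sum(cpp_currents(c(V[i], g[i, "d_inf"], f, x), pv))
  }, numeric(1))
}

#' Critical-manifold voltage roots
#'
#' Solves the fast-subsystem equilibrium condition for V at frozen slow
#' variables (f, x): total current zero with d = d_inf(V). Returns 1-3
#' sorted roots in [-100, 60] mV.
#'
#' @param f,x slow variables (gate fractions).
#' @param params an \code{ead_params} object.
#' @param Vrange scan range, mV.
#' @param n scan resolution.
#' @return sorted numeric vector of voltage roots.
#' @export
manifold_solve <- function(f, x, params = ead_params(),
                           Vrange = c(-100, 60), n = 1601) {
  stopifnot(f >= 0, f <= 1, x >= 0, x <= 1)
  Vs <- seq(Vrange[1], Vrange[2], length.out = n)
  Fv <- .manifold_F(Vs, f, x, params)
  idx <- which(Fv[-1] * Fv[-n] < 0)
  roots <- vapply(idx, function(i) {
    uniroot(function(v) .manifold_F(v, f, x, params), c(Vs[i], Vs[i + 1]),
            tol = 1e-13)$root
  }, numeric(1))
  sort(unique(c(roots, Vs[Fv == 0])))
}

# fast-subsystem right-hand side at a general (V, d) with (f, x) frozen
.fast_rhs <- function(V, d, f, x, params) {
  pv <- .pvec(params)
  g <- cpp_gating(V, pv)
  cur <- sum(cpp_currents(c(V, d, f, x), pv))
  c(-cur / params$Cm, (g[1, "d_inf"] - d) / g[1, "tau_d"])
}

#' Fast-subsystem Jacobian at a critical-manifold point
#'
#' 2x2 Jacobian of the (V, d) fast subsystem, by central differences. Its
#' eigenvalues classify the sheet: both real parts negative = attracting,
#' opposite-sign reals = saddle.
#'
#' @param V,f,x coordinates of the point (d is taken at d_inf(V)).
#' @param params an \code{ead_params} object.
#' @return list with \code{J} (2x2 matrix), \code{eigenvalues},
#'   \code{sheet} (\code{"attracting"}, \code{"saddle"} or
#'   \code{"repelling"}).
#' @export
fast_jacobian <- function(V, f, x, params = ead_params()) {
  d0 <- cpp_gating(V, .pvec(params))[1, "d_inf"]
  hV <- 1e-5 * max(1, abs(V)); hd <- 1e-7
  J <- matrix(0, 2, 2)
  J[, 1] <- (.fast_rhs(V + hV, d0, f, x, params) -
             .fast_rhs(V - hV, d0, f, x, params)) / (2 * hV)
  J[, 2] <- (.fast_rhs(V, d0 + hd, f, x, params) -
             .fast_rhs(V, d0 - hd, f, x, params)) / (2 * hd)
  ev <- eigen(J, only.values = TRUE)$values
  sheet <- if (all(Re(ev) < 0)) "attracting"
           else if (all(Im(ev) == 0) && prod(Re(ev)) < 0) "saddle"
           else "repelling"
  list(J = J, eigenvalues = ev, sheet = sheet)
}

# upper-fold voltage at given x: zero of h_V between the attracting plateau
# branch and the saddle branch. Scans V in `Vscan` for the sign change of
# h_V with largest V.
.fold_V_at_x <- function(x, params, Vscan = c(-60, 10), n = 701) {
  pv <- .pvec(params)
  Vs <- seq(Vscan[1], Vscan[2], length.out = n)
  hv <- vapply(Vs, function(v) cpp_hV(v, x, pv), numeric(1))
  idx <- which(hv[-1] * hv[-n] < 0)
  if (!length(idx)) return(NA_real_)
  i <- idx[length(idx)]
  uniroot(function(v) cpp_hV(v, x, pv), c(Vs[i], Vs[i + 1]), tol = 1e-12)$root
}

#' Upper fold curve L of the critical manifold
#'
#' Locus where the fast-subsystem Jacobian is singular along the manifold,
#' i.e. where the graph derivative h_V vanishes; the boundary between the
#' upper attracting sheet and the saddle sheet. Continued over a grid in x.
#'
#' @param params an \code{ead_params} object.
#' @param x_range range of the IK activation gate.
#' @param n number of fold points.
#' @return data.frame with columns \code{V}, \code{f}, \code{x},
#'   \code{det_fast} (determinant certificate). Rows with no fold in range
#'   are dropped; zero rows is legal for extreme parameters.
#' @export
fold_curve <- function(params = ead_params(), x_range = c(0.005, 0.995),
                       n = 200) {
  pv <- .pvec(params)
  xs <- seq(x_range[1], x_range[2], length.out = n)
  Vf <- vapply(xs, .fold_V_at_x, numeric(1), params = params)
  keep <- is.finite(Vf)
  xs <- xs[keep]; Vf <- Vf[keep]
  fs <- vapply(seq_along(xs), function(i) cpp_h(Vf[i], xs[i], pv), numeric(1))
  dets <- vapply(seq_along(xs), function(i) {
    fj <- fast_jacobian(Vf[i], fs[i], xs[i], params)
    det(fj$J)
  }, numeric(1))
  data.frame(V = Vf, f = fs, x = xs, det_fast = dets)
}

#' Desingularized reduced flow
#'
#' Right-hand side of the slow flow on the critical manifold in graph
#' coordinates (V, x), time-rescaled by h_V to remove the fold singularity:
#' dV/dtau = g_f - h_x g_x, dx/dtau = h_V g_x, where f = h(V, x) and g_f,
#' g_x are the slow gate equations. Orbits coincide with reduced-flow
#' orbits up to time orientation (reversed where h_V < 0).
#'
#' @param V,x graph coordinates.
#' @param params an \code{ead_params} object.
#' @return named numeric \code{c(dV, dx)} (per desingularized time).
#' @export
desingularized_flow <- function(V, x, params = ead_params()) {
  pv <- .pvec(params)
  g <- cpp_gating(V, pv)
  if (!is.finite(V) || abs(V - params$VCa) < 1e-9 || g[1, "d_inf"] <= 0)
    stop("graph f = h(V, x) undefined at this voltage")
  out <- cpp_desing_rhs(V, x, pv)
  names(out) <- c("V", "x")
  out
}

#' Folded singularities on the fold curve
#'
#' Roots of the desingularized flow on L: points where h_V = 0 and
#' g_f - h_x g_x = 0. Eigenvalues of the desingularized Jacobian give the
#' strong/weak rates lambda_s, lambda_w, their ratio mu and the kind
#' (folded node / folded saddle / folded focus).
#'
#' @param params an \code{ead_params} object.
#' @param x_range,n fold-curve sampling (see \code{fold_curve}).
#' @return list of folded singularities, each with \code{V}, \code{x},
#'   \code{f}, \code{lambda_s}, \code{lambda_w}, \code{mu}, \code{kind},
#'   \code{J} (2x2 desingularized Jacobian); empty list if none.
#' @export
folded_singularities <- function(params = ead_params(),
                                 x_range = c(0.005, 0.995), n = 400) {
  pv <- .pvec(params)
  xs <- seq(x_range[1], x_range[2], length.out = n)
  Vf <- vapply(xs, .fold_V_at_x, numeric(1), params = params)
  keep <- is.finite(Vf)
  xs <- xs[keep]; Vf <- Vf[keep]
  if (length(xs) < 2) return(list())
  # dV/dtau along the fold; folded singularities are its zeros
  r <- vapply(seq_along(xs), function(i)
    cpp_desing_rhs(Vf[i], xs[i], pv)[1], numeric(1))
  idx <- which(r[-1] * r[-length(r)] < 0)
  out <- lapply(idx, function(i) {
    xr <- uniroot(function(x) {
      v <- .fold_V_at_x(x, params)
      cpp_desing_rhs(v, x, pv)[1]
    }, c(xs[i], xs[i + 1]), tol = 1e-12)$root
    vr <- .fold_V_at_x(xr, params)
    # Jacobian of the desingularized flow, central differences scaled to
    # the (100 mV, 1) normalization
    hv <- 1e-5
    J <- matrix(0, 2, 2)
    J[, 1] <- (cpp_desing_rhs(vr + hv * 100, xr, pv) -
               cpp_desing_rhs(vr - hv * 100, xr, pv)) / (2 * hv * 100)
    J[, 2] <- (cpp_desing_rhs(vr, xr + hv, pv) -
               cpp_desing_rhs(vr, xr - hv, pv)) / (2 * hv)
    ev <- eigen(J, only.values = TRUE)$values
    if (any(Im(ev) != 0)) {
      kind <- "folded focus"; ls <- lw <- mu <- NA_real_
    } else {
      ev <- Re(ev)
      if (prod(ev) < 0) {
        kind <- "folded saddle"
        ls <- ev[which.max(abs(ev))]; lw <- ev[which.min(abs(ev))]
        mu <- lw / ls
      } else {
        kind <- "folded node"
        ls <- ev[which.max(abs(ev))]; lw <- ev[which.min(abs(ev))]
        mu <- lw / ls
      }
    }
    list(V = vr, x = xr, f = cpp_h(vr, xr, pv), lambda_s = ls,
         lambda_w = lw, mu = mu, kind = kind, J = J)
  })
  out
}

#' The folded node of a parameter set
#'
#' Convenience accessor: the unique folded node from
#' \code{folded_singularities}, or an error if none exists.
#' @param params an \code{ead_params} object.
#' @return a folded-singularity list (see \code{folded_singularities}).
#' @export
folded_node <- function(params = ead_params()) {
  fs <- Filter(function(s) s$kind == "folded node",
               folded_singularities(params))
  if (!length(fs)) stop("no folded node for this parameter set")
  fs[[1]]
}

#' Singular strong canard of the desingularized flow
#'
#' The desingularized-flow trajectory through the folded node tangent to
#' its strong eigendirection, obtained by integrating from offsets of
#' +/- eps along the strong eigenvector (V normalized by 100 mV). Together
#' with the fold curve it bounds the singular funnel on the upper
#' attracting sheet.
#'
#' @param params an \code{ead_params} object.
#' @param eps offset in normalized coordinates (default 1e-6).
#' @param t_max desingularized-time horizon per branch.
#' @return list with \code{node} (the folded node), \code{path}
#'   (data.frame V, x, f ordered along the canard), and \code{eigvec}
#'   (strong eigenvector in normalized coordinates).
#' @export
singular_strong_canard <- function(params = ead_params(), eps = 1e-6,
                                   t_max = 20000) {
  fn <- folded_node(params)
  pv <- .pvec(params)
  # normalized Jacobian: coordinates (V/100, x)
  Jn <- fn$J
  Jn[1, ] <- Jn[1, ] / 100   # row: dV/dtau -> d(V/100)/dtau ... see below
  # In normalized u = V/100: du/dtau = (1/100) dV/dtau; J_n = S J S^-1 with
  # S = diag(1/100, 1)
  S <- diag(c(1 / 100, 1))
  Jn <- S %*% fn$J %*% solve(S)
  ev <- eigen(Jn)
  if (any(Im(ev$values) != 0)) stop("folded singularity is not a node")
  i_s <- which.max(abs(Re(ev$values)))
  vs <- Re(ev$vectors[, i_s])
  vs <- vs / sqrt(sum(vs^2))
  seeds <- rbind(c(fn$V, fn$x) + eps * c(100 * vs[1], vs[2]),
                 c(fn$V, fn$x) - eps * c(100 * vs[1], vs[2]))
  # the node attracts in desingularized time (both eigenvalues of one
  # sign); trace the canard by integrating away from it, i.e. against the
  # stable direction of the node
  dir <- if (Re(ev$values[i_s]) < 0) -1L else 1L
  # escape from the node is exponential at rate |lambda_s|; integrate in
  # chunks until the path leaves a neighbourhood of the fold
  paths <- lapply(1:2, function(k) {
    y <- seeds[k, ]
    acc <- list()
    for (chunk in 1:60) {
      r <- cpp_integrate_desing(pv, y, t_max, 0, 1e-10, 1e-12, dir)
      m <- r$y
      if (nrow(m) == 0) break
      acc[[chunk]] <- data.frame(V = m[, 1], x = m[, 2])
      ynew <- m[nrow(m), ]
      moved <- max(abs(ynew - y))
      y <- ynew
      if (abs(y[1] - fn$V) > 40 || y[2] < 0.002 || y[2] > 0.998 ||
          r$status != 0 || moved < 1e-9) break
    }
    pp <- do.call(rbind, acc)
    # clip to the physical neighbourhood of the fold
    if (!is.null(pp)) {
      ok <- pp$x >= 0 & pp$x <= 1 & abs(pp$V - fn$V) <= 45
      bad <- which(!ok)
      if (length(bad)) pp <- pp[seq_len(min(bad) - 1), , drop = FALSE]
    }
    pp
  })
  path <- rbind(paths[[1]][rev(seq_len(nrow(paths[[1]]))), ],
                data.frame(V = fn$V, x = fn$x), paths[[2]])
  path$f <- vapply(seq_len(nrow(path)), function(i)
    cpp_h(path$V[i], path$x[i], pv), numeric(1))
  rownames(path) <- NULL
  list(node = fn, path = path, eigvec = vs)
}
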