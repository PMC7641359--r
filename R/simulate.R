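# Stimulated simulations, equilibria, and action-potential feature
# extraction (EAD counting and outcome classification).

#' Integrate the model under the stimulus protocol
#'
#' Adaptive Dormand-Prince 5(4) integration of the model from the rest state
#' (or a supplied initial state), with dense output on a uniform grid.
#'
#' @param params an \code{ead_params} object.
#' @param t_end simulation horizon, ms (default 10000, the grid protocol).
#' @param init \code{"rest"} (start at the stable low-voltage equilibrium
#'   E1) or a numeric \code{c(V, d, f, x)}.
#' @param out_dt output grid spacing, ms (<= 1 to resolve EADs).
#' @param rtol,atol solver tolerances.
#' @return an object of class \code{ead_trajectory}: list with \code{times},
#'   \code{states} (matrix with columns V, d, f, x), and \code{params}.
#' @export
integrate_model <- function(params, t_end = 10000, init = "rest",
                            out_dt = 0.5, rtol = 1e-8, atol = 1e-10) {
  validate_params(params)
  if (t_end <= 0) stop("t_end must be positive")
  if (identical(init, "rest")) {
    eqs <- find_equilibria(params)
    y0 <- eqs[[1]]$state
  } else {
    y0 <- .as_state(init)
  }
  r <- cpp_integrate(.pvec(params), y0, 0, t_end, out_dt, rtol, atol, -1,
                     1L, 0, 0L, 0L, 0L)
  if (r$status == 1)
    stop("integration failed (step-size collapse) at t = ", r$fail_time)
  st <- r$y
  colnames(st) <- c("V", "d", "f", "x")
  structure(list(times = r$t, states = st, params = params),
            class = "ead_trajectory")
}

#' @export
print.ead_trajectory <- function(x, ...) {
  cat(sprintf("ead_trajectory: %d samples over %.0f ms, V in [%.1f, %.1f] mV\n",
              length(x$times), max(x$times), min(x$states[, "V"]),
              max(x$states[, "V"])))
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' Columns \code{t_ms, V_mV, d, f, x}, preceded by a provenance header of
#' commented parameter lines.
#' @param traj an \code{ead_trajectory}.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  hdr <- sprintf("# %s = %g", .param_names,
                 vapply(.param_names, function(n) traj$params[[n]], 0))
  df <- data.frame(t_ms = traj$times, V_mV = traj$states[, "V"],
                   d = traj$states[, "d"], f = traj$states[, "f"],
                   x = traj$states[, "x"])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param path file path.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), " = "))
  pl <- as.list(as.numeric(kv[, 2]))
  names(pl) <- kv[, 1]
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  st <- as.matrix(df[, c("V_mV", "d", "f", "x")])
  colnames(st) <- c("V", "d", "f", "x")
  structure(list(times = df$t_ms, states = st,
                 params = do.call(ead_params, pl)),
            class = "ead_trajectory")
}

# ---- equilibria ---------------------------------------------------------

#' Locate and classify full-system equilibria
#'
#' Solves the one-dimensional steady-state current balance (all gates at
#' their steady-state curves) by a sign-change scan over V in
#' \code{Vrange} followed by bracketed root refinement, then classifies each
#' root by the eigenvalues of the 4x4 Jacobian. The rest state E1 is the
#' lowest-voltage root; EAD-capable parameter sets additionally have an
#' elevated-voltage spiral E2 and a saddle E3.
#'
#' @param params an \code{ead_params} object.
#' @param Vrange scan range, mV.
#' @param n scan resolution.
#' @return list of equilibria, each a list with \code{state} (named vector),
#'   \code{eigenvalues} (complex, 1/ms), \code{label} (E1/E2/E3),
#'   \code{stability}.
#' @export
find_equilibria <- function(params, Vrange = c(-100, 60), n = 3201) {
  validate_params(params)
  pv <- .pvec(params)
  Vs <- seq(Vrange[1], Vrange[2], length.out = n)
  S <- cpp_ss_current(Vs, pv)
  idx <- which(S[-1] * S[-n] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(function(v) cpp_ss_current(v, pv), c(Vs[i], Vs[i + 1]),
                   tol = 1e-12)$root
  }, numeric(1))
  # exact tangencies at scan points
  roots <- sort(unique(c(roots, Vs[S == 0])))
  if (!length(roots)) stop("no equilibrium found in scan range")
  eqs <- lapply(roots, function(v) {
    g <- cpp_gating(v, pv)
    st <- c(V = unname(v), d = unname(g[1, "d_inf"]),
            f = unname(g[1, "f_inf"]), x = unname(g[1, "x_inf"]))
    J <- .full_jacobian(st, pv)
    ev <- eigen(J, only.values = TRUE)$values
    list(state = st, eigenvalues = ev, stability = .stability_label(ev))
  })
  # label by voltage ordering and character
  eqs <- eqs[order(vapply(eqs, function(e) e$state[["V"]], 0))]
  labs <- if (length(eqs) == 1) "E1" else {
    l <- rep("E2", length(eqs))
    l[1] <- "E1"
    saddle <- vapply(eqs, function(e)
      all(Im(e$eigenvalues) == 0) && any(Re(e$eigenvalues) > 0) &&
        any(Re(e$eigenvalues) < 0), TRUE)
    saddle[1] <- FALSE
    if (any(saddle)) l[which(saddle)] <- "E3"
    l
  }
  for (i in seq_along(eqs)) eqs[[i]]$label <- labs[i]
  eqs
}

# central-difference Jacobian of the autonomous right-hand side
.full_jacobian <- function(state, pvec, h = 1e-6) {
  J <- matrix(0, 4, 4)
  sc <- pmax(abs(state), 1)
  for (j in 1:4) {
    e <- numeric(4); e[j] <- h * sc[j]
    J[, j] <- (cpp_rhs(0, state + e, pvec, FALSE) -
               cpp_rhs(0, state - e, pvec, FALSE)) / (2 * e[j])
  }
  J
}

.stability_label <- function(ev) {
  complexpair <- any(abs(Im(ev)) > 1e-12)
  if (all(Re(ev) < 0)) {
    if (complexpair) "stable spiral" else "stable node"
  } else if (any(Re(ev) > 0) && any(Re(ev) < 0) && !complexpair) {
    "saddle"
  } else if (complexpair) "unstable spiral" else "unstable node"
}

#' Linearized oscillation period at an equilibrium
#'
#' For an equilibrium with a complex-conjugate eigenvalue pair
#' lambda +/- omega*i, returns 2*pi/omega (ms) for the pair with the largest
#' |omega|. Near the depolarized equilibrium E2 this predicts the inter-EAD
#' interval.
#'
#' @param eq one element of the list returned by \code{find_equilibria}.
#' @return period, ms.
#' @export
eigen_period <- function(eq) {
  om <- abs(Im(eq$eigenvalues))
  if (max(om) < 1e-12) stop("no oscillatory (complex) eigenvalue pair")
  2 * pi / max(om)
}

# ---- AP feature extraction ----------------------------------------------

#' Classify a stimulated trajectory
#'
#' Counts EADs and classifies the response. An EAD is a local maximum of V
#' on the dense output that (i) occurs after the stimulus-evoked upstroke
#' peak, (ii) occurs while V > \code{v_gate}, and (iii) has prominence of at
#' least \code{prominence} mV above the higher of its flanking local minima.
#' The response is \code{REPOL_FAILURE} if V never falls below \code{v_gate}
#' after the upstroke; otherwise \code{EADS} or \code{NO_EADS} by count.
#' EAD durations are the intervals between the local minima flanking each
#' counted peak, the last one closed by the downward \code{v_gate} crossing.
#'
#' @param traj an \code{ead_trajectory} from \code{integrate_model} with the
#'   standard pulse.
#' @param v_gate plateau gate voltage, mV (default -45).
#' @param prominence minimum EAD peak prominence, mV (default 1).
#' @param upstroke_window time after stimulus onset treated as part of the
#'   stimulus-evoked upstroke complex, ms (default 250). The pulse produces
#'   a spike-notch-dome complex ending well before 150 ms; canard-induced
#'   EADs in this model appear hundreds of ms later, so maxima inside the
#'   window are not counted as EADs.
#' @return an object of class \code{ead_features}: list with
#'   \code{classification} (one of \code{"NO_EADS"}, \code{"EADS"},
#'   \code{"REPOL_FAILURE"}), \code{ead_count}, \code{ead_peak_times},
#'   \code{ead_durations}, \code{apd} (ms above \code{v_gate}; \code{Inf}
#'   for repolarization failure), \code{v_peak}.
#' @export
classify_response <- function(traj, v_gate = -45, prominence = 1,
                              upstroke_window = 250) {
  stopifnot(inherits(traj, "ead_trajectory"))
  t <- traj$times
  V <- traj$states[, "V"]
  on_t <- traj$params$stim_onset
  after <- which(t >= on_t)
  empty <- structure(list(classification = "NO_EADS", ead_count = 0L,
                          ead_peak_times = numeric(0),
                          ead_durations = numeric(0), apd = 0,
                          v_peak = max(V)), class = "ead_features")
  if (!length(after) || max(V[after]) < v_gate) return(empty)  # no upstroke
  i_up <- after[which.max(V[after])]
  v_peak <- V[i_up]

  # local extrema on the dense grid, after the upstroke peak
  seg <- i_up:length(V)
  Vs <- V[seg]
  dV <- diff(Vs)
  # strict sign-change maxima/minima (plateaus broken by first sample)
  s <- sign(dV)
  s[s == 0] <- 1
  chg <- diff(s)
  imax <- which(chg < 0) + 1L
  imin <- which(chg > 0) + 1L

  below <- which(Vs < v_gate)
  repol <- length(below) > 0
  i_cross <- if (repol) below[1] else length(Vs)

  counted <- integer(0)
  durations <- numeric(0)
  for (im in imax) {
    if (Vs[im] <= v_gate) next
    if (im >= i_cross) next
    if (t[seg[im]] <= on_t + upstroke_window) next  # upstroke complex
    lmin <- imin[imin < im]
    rmin <- imin[imin > im & imin < i_cross]
    lbase <- if (length(lmin)) Vs[max(lmin)] else Vs[1]
    rbase <- if (length(rmin)) Vs[min(rmin)] else min(Vs[im:i_cross])
    if (Vs[im] - max(lbase, rbase) >= prominence) {
      counted <- c(counted, im)
      # duration: interval between flanking local minima; the final EAD has
      # no right minimum before the downstroke, so it is closed where V
      # falls back through the level of its left trough
      l_t <- if (length(lmin)) t[seg[max(lmin)]] else t[seg[1]]
      r_t <- if (length(rmin)) {
        t[seg[min(rmin)]]
      } else {
        dn <- which(Vs < lbase & seq_along(Vs) > im)
        if (length(dn)) t[seg[dn[1]]] else t[seg[i_cross]]
      }
      durations <- c(durations, r_t - l_t)
    }
  }
  n_ead <- length(counted)
  cls <- if (!repol) "REPOL_FAILURE" else if (n_ead > 0) "EADS" else "NO_EADS"
  apd <- if (!repol) Inf else sum(Vs[1:i_cross] > v_gate) * mean(diff(t))
  structure(list(classification = cls, ead_count = as.integer(n_ead),
                 ead_peak_times = t[seg[counted]],
                 ead_durations = durations, apd = apd, v_peak = v_peak),
            class = "ead_features")
}

#' @export
print.ead_features <- function(x, ...) {
  cat(sprintf("AP outcome: %s (EADs: %d)\n", x$classification, x$ead_count))
  if (x$ead_count > 0)
    cat("  peak times (ms):", paste(round(x$ead_peak_times, 1),
                                    collapse = ", "), "\n")
  invisible(x)
}
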