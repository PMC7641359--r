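p208 <- preset_params("fig3_2.08")
pv208 <- canardEAD:::.pvec(p208)

test_that("manifold_solve: residuals, equilibria on the manifold, f = 0 branch loss", {
  # random slow states under a fixed seed
  set.seed(42)
  for (i in 1:10) {
    f <- runif(1, 0.05, 0.95); x <- runif(1, 0.05, 0.95)
    roots <- manifold_solve(f, x, p208)
    expect_gte(length(roots), 1)
    expect_lte(length(roots), 3)
    for (v in roots) {
      d <- gating_curves(v, p208)$d_inf
      expect_lt(abs(sum(ionic_currents(c(v, d, f, x), p208))), 1e-9)
    }
  }
  # full-system equilibria persist as fast-subsystem equilibria
  for (e in find_equilibria(p208)) {
    roots <- manifold_solve(e$state[["f"]], e$state[["x"]], p208)
    expect_true(any(abs(roots - e$state[["V"]]) < 1e-6))
  }
  # with f = 0 the ICa-L term vanishes and only low-voltage roots remain
  r0 <- manifold_solve(0, 0.2, p208)
  expect_true(all(r0 < -40))
})

test_that("sheet classification: attracting plateau, saddle between folds, no Hopf", {
  fc <- fold_curve(p208)
  expect_gt(nrow(fc), 50)
  x0 <- 0.2
  vf <- fc$V[which.min(abs(fc$x - x0))]
  f_pl <- canardEAD:::cpp_h(vf + 10, x0, pv208)
  f_sd <- canardEAD:::cpp_h(vf - 8, x0, pv208)
  expect_equal(fast_jacobian(vf + 10, f_pl, x0, p208)$sheet, "attracting")
  expect_equal(fast_jacobian(vf - 8, f_sd, x0, p208)$sheet, "saddle")
  # no purely-imaginary pair anywhere on a scan of both sheets
  for (dv in c(-10, -5, 5, 10, 20)) {
    for (x in c(0.05, 0.2, 0.5)) {
      vfx <- fc$V[which.min(abs(fc$x - x))]
      fx <- canardEAD:::cpp_h(vfx + dv, x, pv208)
      if (fx < 0 || fx > 1) next
      ev <- fast_jacobian(vfx + dv, fx, x, p208)$eigenvalues
      if (any(Im(ev) != 0)) expect_true(all(abs(Re(ev)) > 1e-6))
    }
  }
})

test_that("fold curve: defining residuals and displacement under a d-shift", {
  fc <- fold_curve(p208, n = 60)
  expect_true(all(abs(fc$det_fast) < 1e-6))
  for (i in seq(1, nrow(fc), by = 10)) {
    d <- gating_curves(fc$V[i], p208)$d_inf
    expect_lt(abs(sum(ionic_currents(c(fc$V[i], d, fc$f[i], fc$x[i]),
                                     p208))), 1e-8)
    expect_lt(abs(canardEAD:::cpp_hV(fc$V[i], fc$x[i], pv208)), 1e-8)
  }
  # at default parameters the upper fold sits at elevated voltages
  fc0 <- fold_curve(ead_params(), n = 40)
  expect_true(all(fc0$V > -30 & fc0$V < 0))
  # shifting d_inf displaces the fold
  fc_sh <- fold_curve(ead_params(dV_d = -3.6), n = 40)
  expect_gt(max(abs(fc_sh$V - fc0$V)), 0.5)
})

test_that("closed-form graph: F(V, h(V,x), x) = 0 and fold condition dx/dtau = 0", {
  set.seed(7)
  for (i in 1:12) {
    V <- runif(1, -40, 0); x <- runif(1, 0.05, 0.9)
    h <- canardEAD:::cpp_h(V, x, pv208)
    d <- gating_curves(V, p208)$d_inf
    expect_lt(abs(sum(ionic_currents(c(V, d, h, x), p208))), 1e-11)
  }
  fc <- fold_curve(p208, n = 20)
  i <- 10
  dr <- desingularized_flow(fc$V[i], fc$x[i], p208)
  expect_lt(abs(dr[["x"]]), 1e-8)   # h_V = 0 on the fold
})

test_that("desingularized orbits retrace reduced-flow orbits as point sets", {
  # on the attracting sheet away from the fold the reduced flow is the
  # desingularized flow up to the h_V time rescaling; integrating the
  # reduced flow directly (dV/dt = (gf - hx gx)/hV) must give the same path
  fn <- folded_node(p208)
  y0 <- c(fn$V + 12, fn$x - 0.05)
  des <- canardEAD:::cpp_integrate_desing(pv208, y0, 30000, 0, 1e-10,
                                          1e-12, 1L)
  path_d <- des$y
  # crude fixed-step reduced-flow integration (independent oracle)
  y <- y0; path_r <- y0
  for (i in 1:4000) {
    dr <- canardEAD:::cpp_desing_rhs(y[1], y[2], pv208)
    hv <- canardEAD:::cpp_hV(y[1], y[2], pv208)
    y <- y + 0.5 * c(dr[1] / hv, dr[2] / hv)
    path_r <- rbind(path_r, y)
    if (y[1] < fn$V + 2) break
  }
  # compare V at matched x values
  keep <- path_d[, 1] > fn$V + 2.5
  vd <- approx(path_d[keep, 2], path_d[keep, 1], xout = path_r[, 2],
               ties = "ordered")$y
  err <- abs(vd - path_r[, 1]) / 100
  expect_lt(max(err, na.rm = TRUE), 1e-3)
})

test_that("folded node at the EAD preset: kind, mu in (0,1), funnel geometry", {
  fs <- folded_singularities(p208)
  kinds <- vapply(fs, `[[`, "", "kind")
  expect_true("folded node" %in% kinds)
  fn <- fs[[which(kinds == "folded node")[1]]]
  expect_true(is.finite(fn$mu))
  expect_gt(fn$mu, 0)
  expect_lt(fn$mu, 1)
  expect_equal(sign(fn$lambda_s), sign(fn$lambda_w))
  # the node lies on the fold curve
  expect_lt(abs(canardEAD:::cpp_hV(fn$V, fn$x, pv208)), 1e-7)
})

test_that("mu shrinks faster under d-left-shifts than f-right-shifts", {
  mu_d <- vapply(c(0.5, 1, 1.5), function(s)
    folded_node(ead_params(dV_d = -2.08 - s, dV_f = 2.08))$mu, numeric(1))
  mu_f <- vapply(c(0.5, 1, 1.5), function(s)
    folded_node(ead_params(dV_d = -2.08, dV_f = 2.08 + s))$mu, numeric(1))
  mu_0 <- folded_node(p208)$mu
  expect_true(all(diff(c(mu_0, mu_d)) < 0))
  expect_true(all(mu_d < mu_f))
})

test_that("singular strong canard: through the node, tangent to the strong eigenvector", {
  sc <- singular_strong_canard(p208)
  fn <- sc$node
  d2 <- sqrt(((sc$path$V - fn$V) / 100)^2 + (sc$path$x - fn$x)^2)
  expect_lt(min(d2), 1e-5)
  # tangency: direction of the path at small distance from the node
  near <- which(d2 > 1e-5 & d2 < 1e-3)
  expect_gt(length(near), 0)
  vdir <- cbind((sc$path$V[near] - fn$V) / 100, sc$path$x[near] - fn$x)
  vdir <- vdir / sqrt(rowSums(vdir^2))
  ang <- acos(pmin(1, abs(vdir %*% sc$eigvec)))
  expect_lt(max(ang), 1e-3)
  # the canard spans both sides of the fold
  expect_gt(max(sc$path$V), fn$V + 5)
  expect_lt(min(sc$path$V), fn$V - 5)
})

test_that("funnel: orbits inside reach the node, orbits beyond it cross L away from it", {
  sc <- singular_strong_canard(p208)
  fn <- sc$node
  # section line on the attracting sheet ~8 mV above the fold
  up <- sc$path[sc$path$V > fn$V + 7.5 & sc$path$V < fn$V + 8.5, ]
  expect_gt(nrow(up), 0)
  V0 <- up$V[1]
  probe <- function(x0) {
    # forward desingularized flow: funnel orbits terminate at the node
    # (stable in the rescaled time); others cross L transversally
    y <- c(V0, x0)
    for (ch in 1:30) {
      r <- canardEAD:::cpp_integrate_desing(pv208, y, 50000, 0, 1e-10,
                                            1e-12, 1L)
      m <- r$y
      if (nrow(m) == 0) break
      if (any(m[, 1] < fn$V - 1)) {
        ic <- which(m[, 1] < fn$V)[1]
        return(list(crossed = TRUE, x_at_L = m[ic, 2]))
      }
      ynew <- m[nrow(m), ]
      if (max(abs(ynew - y)) < 1e-8) return(list(crossed = FALSE, end = ynew))
      y <- ynew
    }
    list(crossed = FALSE, end = y)
  }
  # the singular strong canard itself funnels into the node
  r_canard <- probe(up$x[1])
  expect_false(r_canard$crossed)
  expect_lt(abs(r_canard$end[2] - fn$x), 1e-4)
  # an orbit within the funnel sector funnels too
  r_in <- probe(fn$x + 0.05)
  expect_false(r_in$crossed)
  # an orbit well beyond the funnel crosses L away from the node (jump)
  r_out <- probe(0.5)
  expect_true(r_out$crossed)
  expect_gt(abs(r_out$x_at_L - fn$x), 0.1)
})
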