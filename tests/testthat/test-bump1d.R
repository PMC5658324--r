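test_that("psi_1d closed form agrees with adaptive quadrature", {
  wk <- bump_kernel()
  # even symmetry about the midpoint
  expect_equal(psi_1d(0, -1, 1, wk),
               2 * stats::integrate(function(y) evaluate_w(wk, y), 0, 1,
                                    rel.tol = 1e-12)$value,
               tolerance = 1e-12)
  # oracle equivalence on random evaluation points and widths
  set.seed(11)
  for (i in 1:100) {
    D <- stats::runif(1, 0.5, 30)
    x <- stats::runif(1, -25, 25)
    quad <- stats::integrate(function(y) evaluate_w(wk, abs(x - y)),
                             -D / 2, D / 2, rel.tol = 1e-13)$value
    expect_equal(psi_1d(x, -D / 2, D / 2, wk), quad, tolerance = 1e-10)
  }
  expect_error(psi_1d(0, 1, 1, wk), "x1 < x2")
})

test_that("the stationary bump drive P is symmetric and anchored", {
  wk <- bump_kernel()
  D <- 7.3
  # vanishes far away
  expect_lt(abs(P_field(100, D, wk)), 1e-14)
  # even about the bump centre
  xs <- c(0.7, 2.1, 5)
  expect_equal(P_field(xs, D, wk), P_field(-xs, D, wk), tolerance = 1e-14)
  # edge value equals the quadrature of the drive at the edge
  expect_equal(P_field(-D / 2, D, wk), psi_1d(-D / 2, -D / 2, D / 2, wk),
               tolerance = 1e-10)
  expect_error(P_field(0, 2, tophat_test()), "difference-of-Gaussians")
})

test_that("bump width solving finds the known branch structure", {
  wk <- bump_kernel()
  L <- 10 * pi
  # no crossing when kappa exceeds the drive maximum
  expect_length(solve_bump_widths(wk, 2.0, L, "none"), 0L)
  br <- solve_bump_widths(wk, 0.7, L, "none")
  expect_length(br, 2L)
  expect_false(br[[1]]$stable)  # narrow unstable
  expect_true(br[[2]]$stable)   # wide stable
  expect_true(all(vapply(br, function(b) abs(b$residual), numeric(1)) < 1e-10))
  brd <- solve_bump_widths(wk, 0.75, L, "dirichlet", u_BC = 0)
  expect_length(brd, 4L)
  expect_true(all(vapply(brd, function(b) abs(b$residual), numeric(1)) < 1e-10))
  expect_true(all(vapply(brd, function(b) b$Delta < 2 * L, logical(1))))
})

test_that("bump profiles hit the boundary value and the threshold", {
  wk <- bump_kernel()
  L <- 10 * pi
  b <- solve_bump_widths(wk, 0.75, L, "dirichlet", u_BC = 0)[[2]]
  expect_equal(bump_profile(b, wk, -L), 0, tolerance = 1e-14)
  expect_equal(bump_profile(b, wk, c(b$x1, b$x2)), c(0.75, 0.75),
               tolerance = 1e-8)
  xg <- seq(-L, L, length.out = 2001)
  q <- bump_profile(b, wk, xg)
  expect_equal(xg[which.max(q)], 0, tolerance = 0.05)  # interior max at 0
  expect_error(bump_profile(b, wk, 1.5 * L), "outside")
})

test_that("bump spectrum separates neutral and width modes", {
  wk <- bump_kernel()
  L <- 10 * pi
  br <- solve_bump_widths(wk, 0.7, L, "none")
  for (b in br) {
    # translation invariance: exact zero eigenvalue
    expect_equal(Re(b$lambda_neutral), 0, tolerance = 1e-14)
    # width mode closed form
    w0 <- evaluate_w(wk, 0); wD <- evaluate_w(wk, b$Delta)
    expect_equal(Re(b$lambda_width), -1 + (w0 + wD) / abs(w0 - wD),
                 tolerance = 1e-12)
  }
  # stable wide bump has inhibitory feedback at the far edge
  expect_lt(evaluate_w(wk, br[[2]]$Delta), 0)
  # Dirichlet branches carry a structural zero mode (continuous family of
  # laterally displaced steady bumps) plus a genuine width mode
  brd <- solve_bump_widths(wk, 0.75, L, "dirichlet", u_BC = 0)
  for (b in brd) expect_lt(abs(Re(b$lambda_neutral)), 1e-10)
  expect_equal(sum(vapply(brd, `[[`, logical(1), "stable")), 2L)
})

test_that("interface evolution holds steady states and tracks growth rates", {
  wk <- bump_kernel()
  L <- 10 * pi
  br <- solve_bump_widths(wk, 0.7, L, "none")
  b <- br[[2]]
  z0 <- function(x) evaluate_w(wk, abs(x - b$x1)) - evaluate_w(wk, abs(x - b$x2))
  tr <- evolve_interface_1d(b$x1, b$x2, z0, wk, 0.7, 0, L, "none",
                            T_final = 10, dt = 0.01)
  expect_lt(max(abs(tr$x1 - b$x1), abs(tr$x2 - b$x2)), 1e-6)
  # unstable branch: width deviation grows at the predicted exponential rate
  bu <- br[[1]]
  lam <- Re(bu$lambda_width)
  z0u <- function(x) evaluate_w(wk, abs(x - bu$x1)) - evaluate_w(wk, abs(x - bu$x2))
  tru <- evolve_interface_1d(bu$x1 - 1e-3, bu$x2 + 1e-3, z0u, wk, 0.7, 0, L,
                             "none", T_final = 0.35, dt = 0.002)
  dev <- (tru$x2 - tru$x1) - bu$Delta
  expect_true(all(diff(abs(dev)) > 0))  # monotone initial growth
  i1 <- which.min(abs(tru$t - 0.05)); i2 <- which.min(abs(tru$t - 0.3))
  rate <- (log(abs(dev[i2])) - log(abs(dev[i1]))) / (tru$t[i2] - tru$t[i1])
  expect_lt(abs(rate - lam) / lam, 0.1)
})

test_that("interface evolution reports degeneracies and extinctions", {
  wk <- bump_kernel()
  L <- 10 * pi
  # z0 sign contract
  expect_error(evolve_interface_1d(-1, 1, function(x) x, wk, 0.7, 0, L,
                                   "none", T_final = 1),
               "z0")
  # a tiny bump far below threshold collapses: extinction reported
  z0 <- function(x) evaluate_w(wk, abs(x + 0.05)) - evaluate_w(wk, abs(x - 0.05))
  tr <- evolve_interface_1d(-0.05, 0.05, z0, wk, 0.9, 0, L, "none",
                            T_final = 5, dt = 0.005)
  expect_true(attr(tr, "extinct"))
})

test_that("1D field simulation is anchored, quiescent-stable and stationary", {
  wk <- bump_kernel()
  L <- 10 * pi
  grid <- seq(-L, L, length.out = 513)
  # quiescent fixed point: subthreshold boundary value, zero gradient
  sq <- simulate_field_1d(list(z0 = numeric(513)), wk, kappa = 0.5,
                          u_BC = 0.1, grid = grid, bc_mode = "dirichlet",
                          T_final = 3)
  expect_equal(max(abs(sq$u - 0.1)), 0, tolerance = 1e-14)
  # boundary clamp to machine precision at every recorded step
  b <- solve_bump_widths(wk, 0.75, L, "dirichlet", u_BC = 0)[[2]]
  grid <- seq(-L, L, length.out = 1025)
  q <- bump_profile(b, wk, grid)
  sim <- simulate_field_1d(q, wk, 0.75, 0, grid, "dirichlet", T_final = 10)
  expect_equal(max(abs(sim$u[, 1])), 0, tolerance = 1e-13)
  expect_lt(max(abs(sim$u[nrow(sim$u), ] - q)), 1e-6)
  # no-BC stationary bump
  bn <- solve_bump_widths(wk, 0.7, L, "none")[[2]]
  qn <- bump_profile(bn, wk, grid)
  simn <- simulate_field_1d(qn, wk, 0.7, 0, grid, "none", T_final = 10)
  expect_lt(max(abs(simn$u[nrow(simn$u), ] - qn)), 1e-6)
  expect_error(simulate_field_1d(q, wk, 0.75, 0, grid, dt = -1), "dt")
  expect_error(simulate_field_1d(1, wk, 0.75, 0, numeric(0)), "grid")
})

test_that("the two 1D quadrature schemes agree to grid accuracy", {
  wk <- bump_kernel()
  L <- 10 * pi
  grid <- seq(-L, L, length.out = 513)
  h <- grid[2] - grid[1]
  b <- solve_bump_widths(wk, 0.7, L, "none")[[2]]
  u0 <- bump_profile(b, wk, grid) + 0.05 * cos(pi * grid / L)
  si <- simulate_field_1d(u0, wk, 0.7, 0, grid, "none", T_final = 2,
                          scheme = "interface")
  sm <- simulate_field_1d(u0, wk, 0.7, 0, grid, "none", T_final = 2,
                          scheme = "matrix")
  expect_lt(max(abs(si$u[nrow(si$u), ] - sm$u[nrow(sm$u), ])), h)
})

test_that("interface trajectory matches full-field level sets", {
  wk <- bump_kernel()
  L <- 10 * pi
  kap <- 0.75
  b <- solve_bump_widths(wk, kap, L, "dirichlet", u_BC = 0)[[2]]
  grid <- seq(-L, L, length.out = 513)
  h <- grid[2] - grid[1]
  # identical off-equilibrium initial data: edges displaced by 0.4
  x1 <- b$x1 - 0.4; x2 <- b$x2 + 0.4
  z0 <- function(x) evaluate_w(wk, abs(x - x1)) - evaluate_w(wk, abs(x - x2))
  tr <- evolve_interface_1d(x1, x2, z0, wk, kap, 0, L, "dirichlet",
                            T_final = 5, dt = 0.01)
  sim <- simulate_field_1d(list(z0 = z0(grid)), wk, kap, 0, grid, "dirichlet",
                           T_final = 5, dt = 0.01)
  eT <- level_crossings_1d(sim$u[nrow(sim$u), ], grid, kap)
  n <- nrow(tr)
  expect_lt(max(abs(c(tr$x1[n], tr$x2[n]) - eT[1:2])), 2 * h)
})

test_that("spectrum signs agree with perturbed 1D field simulations", {
  wk <- bump_kernel()
  L <- 10 * pi
  kap <- 0.75
  grid <- seq(-L, L, length.out = 1025)
  brd <- solve_bump_widths(wk, kap, L, "dirichlet", u_BC = 0)
  for (b in brd) {
    lam <- Re(b$lambda_width)
    if (abs(lam) < 0.05) next  # too slow to resolve over a short horizon
    # seed displaced symmetrically along the width mode
    d0 <- 0.05
    x1 <- b$x1 - d0; x2 <- b$x2 + d0
    z0 <- function(x) evaluate_w(wk, abs(x - x1)) - evaluate_w(wk, abs(x - x2))
    sim <- simulate_field_1d(list(z0 = z0(grid)), wk, kap, 0, grid,
                             "dirichlet", T_final = 5, dt = 0.01)
    devs <- vapply(seq_along(sim$t), function(i) {
      cr <- level_crossings_1d(sim$u[i, ], grid, kap)
      if (length(cr) < 2) NA_real_ else abs(diff(range(cr)) - b$Delta)
    }, numeric(1))
    grew <- devs[length(devs)] > 2 * devs[1]
    shrank <- devs[length(devs)] < 0.6 * devs[1]
    if (lam > 0) expect_true(grew) else expect_true(shrank)
  }
})
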