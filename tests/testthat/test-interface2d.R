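test_that("contour construction and geometry behave", {
  expect_error(nf_contour(cbind(1:5, 1:5)), "16 vertices")
  ct <- circle_contour(2, 64)
  expect_equal(nrow(unclass(ct)), 64L)
  expect_gt(polygon_area(ct), 0)  # CCW enforced
  # closing vertex dropped
  v <- unclass(ct)
  ct2 <- nf_contour(rbind(v, v[1, ]))
  expect_equal(nrow(unclass(ct2)), 64L)
  # reversed input re-oriented to CCW
  ct3 <- nf_contour(v[nrow(v):1, ])
  expect_gt(polygon_area(ct3), 0)
})

test_that("normals are outward unit vectors", {
  ct <- circle_contour(3, 128)
  nrm <- contour_normals(ct)
  expect_equal(sqrt(rowSums(nrm^2)), rep(1, 128), tolerance = 1e-12)
  # at (R, 0) the outward normal is (1, 0)
  expect_equal(nrm[1, ], c(1, 0), tolerance = 1e-12)
  # all normals point radially outward for a circle
  v <- unclass(ct)
  expect_equal(nrm, v / 3, tolerance = 1e-12)
  # reversing the stored orientation flips the normals
  rev_ct <- structure(v[nrow(v):1, ], class = "nf_contour")
  expect_equal(contour_normals(rev_ct)[nrow(v), ], c(-1, 0),
               tolerance = 1e-12)
  expect_error(contour_normals(structure(v[c(1, 1, 2:20), ],
                                         class = "nf_contour")), "duplicate")
})

test_that("winding indicator distinguishes inside, outside and the contour", {
  ct <- circle_contour(2, 128, center = c(0.5, -0.3))
  expect_equal(winding_C(c(0.5, -0.3), ct), 1)
  expect_equal(winding_C(c(4.5, -0.3), ct), 0)
  expect_equal(winding_C(unclass(ct)[7, ], ct), 0.5)
  # two disjoint contours: winding adds
  cts <- list(circle_contour(1, 64, center = c(-3, 0)),
              circle_contour(1, 64, center = c(3, 0)))
  expect_equal(winding_C(c(-3, 0), cts), 1)
  expect_equal(winding_C(c(0, 0), cts), 0)
})

test_that("line-integral psi equals area quadrature on standard shapes", {
  wk <- spot_kernel()
  # each shape at the working resolution (512) and, for the area oracle,
  # a fine polygon of the same analytic curve (8192 = 16 x 512, phases
  # aligned so 512-gon vertices are also fine-polygon vertices)
  mk <- list(
    circle = function(n) circle_contour(3, n),
    ellipse = function(n) ellipse_contour(4, 2, n),
    star = function(n) {
      th <- 2 * pi * (seq_len(n) - 1L) / n
      r <- 3 * (1 + 0.2 * cos(5 * th))
      nf_contour(cbind(r * cos(th), r * sin(th)))
    })
  set.seed(42)
  for (nm in names(mk)) {
    ct <- mk[[nm]](512L)
    ref <- mk[[nm]](8192L)
    v <- unclass(ct)
    # random interior, exterior, and on-contour evaluation points
    cen <- colMeans(v)
    pin <- cen + 0.3 * (v[sample(512, 7), ] - rep(cen, each = 7))
    pout <- 2.2 * v[sample(512, 7), ]
    pon <- v[sample(512, 6), ]
    for (P in list(pin, pout, pon)) {
      d <- psi_line(P, ct, wk) - psi_area(P, ref, wk)
      expect_lt(max(abs(d)), 1e-5)
    }
  }
})

test_that("psi decays far from a small contour and sums over components", {
  wk <- spot_kernel()
  ct <- circle_contour(0.5, 64)
  expect_lt(abs(psi_line(c(40, 0), ct, wk)), 1e-14)
  # two disjoint spots: drive superposes
  c1 <- circle_contour(1, 128, center = c(-4, 0))
  c2 <- circle_contour(1, 128, center = c(4, 0))
  x <- rbind(c(-4, 0), c(0, 0))
  both <- psi_line(x, list(c1, c2), wk)
  expect_equal(both, psi_line(x, c1, wk) + psi_line(x, c2, wk),
               tolerance = 1e-12)
})

test_that("grad psi line integral is consistent and linear", {
  wk <- spot_kernel()
  ct <- circle_contour(3, 512)
  expect_lt(max(abs(grad_psi_line(c(0, 0), ct, wk))), 1e-10)  # symmetry
  for (x0 in list(c(1.3, 0.7), c(4.2, -1))) {
    e <- 1e-5
    fd <- c(psi_area(c(x0[1] + e, x0[2]), ct, wk) -
              psi_area(c(x0[1] - e, x0[2]), ct, wk),
            psi_area(c(x0[1], x0[2] + e), ct, wk) -
              psi_area(c(x0[1], x0[2] - e), ct, wk)) / (2 * e)
    expect_lt(max(abs(grad_psi_line(x0, ct, wk) - fd)), 1e-5)
  }
  # linear in kernel amplitude
  wk2 <- dog_kernel(2 * 3.55, 2 * 3, 2.4, 3.2, 10)
  expect_equal(grad_psi_line(c(1, 1), ct, wk2),
               2 * grad_psi_line(c(1, 1), ct, wk), tolerance = 1e-12)
})

test_that("line quadrature converges at second order or better", {
  wk <- spot_kernel()
  ref <- psi_area(c(1, 0.5), circle_contour(3, 4096L), wk)
  err <- vapply(c(32L, 128L), function(nv) {
    ct <- circle_contour(3, nv)
    abs(psi_line(c(1, 0.5), ct, wk) - ref)
  }, numeric(1))
  # two doublings: at least 4x per doubling
  expect_gt(err[1] / err[2], 14)
})

test_that("gradient memory convolution has the right limits", {
  wk <- spot_kernel()
  ct <- circle_contour(3, 64)
  z0 <- function(X) cbind(X[, 1]^2, -X[, 2])
  X <- rbind(c(1, 0.5), c(4, 1))
  hist <- contour_history(ct, z0)
  # t = 0: exactly the initial gradient
  expect_equal(z_from_history(X, hist, wk, 0), z0(X))
  # frozen contour: geometric-series limit is grad psi
  histS <- stationary_history(ct, function(X) 0 * X, T_final = 30)
  expect_lt(max(abs(z_from_history(X, histS, wk, 30) -
                      grad_psi_line(X, ct, wk))), 1e-8)
  expect_error(z_from_history(X, hist, wk, 5), "beyond")
})

test_that("memory gradient matches the grid-based gradient simulation", {
  wk <- spot_kernel()
  kap <- 0.05
  g <- grid2d(2.5 * pi, 96)
  seed <- make_perturbed_spot(2, 0, 0, kappa = kap, width = 0.3,
                              n_vertices = 96L)
  sim <- simulate_gradient_2d(seed$z0, wk, kap, u_BC = 0, grid = g,
                              T_final = 2, dt = 0.01, record_every = 200)
  run <- evolve_contour(seed$contour, seed$z0, wk, kap, T_final = 2,
                        dt = 0.01, quad_dt = 0.05)
  # compare z at the evolved vertices with the gridded field (bilinear)
  V <- unclass(run$contour)
  zi <- z_from_history(V, run$history, wk, 2, quad_dt = 0.05)
  zg1 <- neurofield:::bilinear(sim$z1[[length(sim$z1)]], g$x, V[, 1], V[, 2])
  zg2 <- neurofield:::bilinear(sim$z2[[length(sim$z2)]], g$x, V[, 1], V[, 2])
  expect_lt(max(abs(zi - cbind(zg1, zg2))), 5 * g$h^2)
})

test_that("normal velocities vanish on constructed stationary spots", {
  wk <- spot_kernel()
  kap <- 0.05
  # free plane
  wide <- solve_spot_radius(wk, kap, "plane")[[2]]
  ct <- circle_contour(wide$R, 2048)
  hist <- contour_history(ct, function(X) grad_psi_line(X, ct, wk))
  cn <- normal_velocity_free(ct, hist, wk, kap, t = 0)
  expect_lt(max(abs(cn)), 1e-6)
  # clamped disc
  D <- 5 * pi
  spd <- solve_spot_radius(wk, kap, disc_domain(D), u_BC = 0)
  Rd <- vapply(spd, `[[`, numeric(1), "R")
  bd <- spd[[which.max(Rd)]]
  ctd <- circle_contour(bd$R, 2048)
  dom <- domain_spec("disc", D = D, bc_mode = "dirichlet", u_BC = 0)
  histd <- contour_history(ctd, function(X) grad_psi_line(X, ctd, wk))
  cnd <- normal_velocity_dirichlet(ctd, histd, wk, kap, dom, t = 0)
  expect_lt(max(abs(cnd)), 1e-6)
})

test_that("velocity rules have the right sign and limits", {
  wk <- spot_kernel()
  kap <- 0.05
  # a small spot whose drive exceeds threshold, gradient pointing inward:
  # uniform inflation, all speeds positive
  seed <- make_perturbed_spot(2, 0, 0, kappa = kap, width = 0.3)
  hist <- contour_history(seed$contour, seed$z0)
  cn <- normal_velocity_free(seed$contour, hist, wk, kap, t = 0)
  expect_true(all(cn > 0))
  # Dirichlet rule reduces to the free rule on a huge domain
  dom <- domain_spec("rectangle", L = 60, bc_mode = "dirichlet", u_BC = 0)
  cnd <- normal_velocity_dirichlet(seed$contour, hist, wk, kap, dom, t = 0)
  expect_lt(max(abs(cnd - cn)), 1e-6)
  # degenerate gradient reported with the vertex
  hist0 <- contour_history(seed$contour, function(X) 0 * X)
  expect_error(normal_velocity_free(seed$contour, hist0, wk, kap, t = 0),
               "degeneracy")
})

test_that("contour stepping moves, resamples, and detects topology changes", {
  ct <- circle_contour(2, 128)
  # zero velocity: identity
  c0 <- step_contour(ct, numeric(128), 0.01)
  expect_lt(hausdorff_distance(c0, ct), 1e-12)
  # constant speed: exact circle inflation
  c1 <- step_contour(ct, rep(0.5, 128), 0.01)
  expect_equal(sqrt(rowSums(unclass(c1)^2)), rep(2.005, nrow(unclass(c1))),
               tolerance = 1e-8)
  # resampling preserves the enclosed area to O(h_max^2)
  v <- unclass(circle_contour(2, 64))
  rs <- neurofield:::resample_closed(v, 48L)
  h_max <- max(sqrt(rowSums((rs[c(2:48, 1), ] - rs)^2)))
  expect_lt(abs(polygon_area(rs) - polygon_area(v)), h_max^2)
  # a figure-eight pinch is flagged as a topology change
  th <- 2 * pi * (0:63) / 64
  pinch <- nf_contour(cbind(cos(th), 0.05 * sin(th) + 0.2 * sin(2 * th)),
                      orient = FALSE)
  expect_true(neurofield:::self_intersects(pinch))
  # drive one half of a circle through the other
  punch <- ifelse(cos(th) > 0.2, -3, 0)
  expect_error(step_contour(nf_contour(cbind(cos(th), sin(th))),
                            punch, 0.5),
               class = "topology_change")
})

test_that("boundary projection honours shape and tie-breaks", {
  dom_d <- domain_spec("disc", D = 5, bc_mode = "dirichlet")
  Z <- neurofield:::boundary_map(rbind(c(1, 0), c(0, -2), c(1, 1)), dom_d)
  expect_equal(Z, rbind(c(5, 0), c(0, -5), c(5 / sqrt(2), 5 / sqrt(2))),
               tolerance = 1e-12)
  dom_r <- domain_spec("rectangle", L = 4, bc_mode = "dirichlet")
  Z2 <- neurofield:::boundary_map(rbind(c(-3.5, 0), c(0, 3.8), c(0, 0)), dom_r)
  expect_equal(Z2[1, ], c(-4, 0))
  expect_equal(Z2[2, ], c(0, 4))
  expect_equal(Z2[3, ], c(-4, 0))  # dead centre: tie goes to the left edge
})

test_that("contours round-trip through CSV", {
  ct <- circle_contour(2, 32)
  path <- tempfile(fileext = ".csv")
  write_contours_csv(list(ct, circle_contour(1, 24, center = c(5, 0))), path)
  back <- read_contours_csv(path)
  expect_length(back, 2L)
  expect_lt(hausdorff_distance(back[[1]], ct), 1e-12)
  unlink(path)
})
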