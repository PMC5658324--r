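#' Uniform square grid
#'
#' Discretisation of the square \eqn{[-L, L]^2} with `n` points per axis
#' (boundary nodes included), spacing `h = 2L/(n-1)`. Fields are stored as
#' `n x n` matrices `u[i, j] = u(x_i, y_j)`.
#'
#' @param L Half-width.
#' @param n Points per axis, at least 16.
#' @export
grid2d <- function(L, n) {
  stopifnot(L > 0, n >= 16)
  n <- as.integer(n)
  structure(list(L = L, n = n, h = 2 * L / (n - 1),
                 x = seq(-L, L, length.out = n)),
            class = "grid2d")
}

# spectral convolution plan: FFT of the (wrapped, padded) kernel samples,
# padding sized to the kernel support so circular wrap-around is below
# the kernel's own truncation error
conv_plan <- function(kernel, grid, type = c("w", "wx", "wy")) {
  type <- match.arg(type)
  n <- grid$n; h <- grid$h
  supp <- kernel_support_radius(kernel)
  if (!is.finite(supp))
    stop("conv_plan: kernel without compact/decaying support cannot be convolved spectrally")
  margin <- min(n, ceiling(supp / h) + 2L)
  P <- stats::nextn(n + margin, c(2L, 3L))
  off <- (((seq_len(P) - 1L) + P %/% 2) %% P - P %/% 2) * h
  OX <- matrix(off, P, P)
  OY <- t(OX)
  r <- sqrt(OX^2 + OY^2)
  W <- switch(type,
    w = evaluate_w(kernel, r),
    wx = ifelse(r > 0, OX / r, 0) * radial_derivative(kernel, r),
    wy = ifelse(r > 0, OY / r, 0) * radial_derivative(kernel, r))
  list(P = P, n = n, h = h, Wf = stats::fft(W))
}

conv_apply <- function(plan, H) {
  P <- plan$P; n <- plan$n
  Hp <- matrix(0, P, P)
  Hp[1:n, 1:n] <- H
  full <- Re(stats::fft(stats::fft(Hp) * plan$Wf, inverse = TRUE)) / P^2
  full[1:n, 1:n] * plan$h^2
}

heaviside_mid <- function(u, kappa) (u > kappa) + 0.5 * (u == kappa)

#' Simulate the classical 2D Amari field
#'
#' Evolves \eqn{u_t = -u + w * H[u - \kappa]} on the square grid by
#' exponential Euler (the linear decay integrated exactly), with the
#' convolution computed spectrally under zero padding sized to the kernel
#' support -- the domain is treated as compactly supported with no
#' boundary condition imposed. The Heaviside uses `H(0) = 1/2`.
#'
#' @param u0 Initial field: `n x n` matrix or `function(X)` of positions.
#' @param kernel `radial_kernel` with decaying support.
#' @param kappa Firing threshold.
#' @param grid A `grid2d`.
#' @param T_final,dt Horizon and step.
#' @param record_every Snapshot cadence in steps.
#' @return List `t` (times), `u` (list of matrices), `grid`.
#' @export
simulate_amari_2d <- function(u0, kernel, kappa, grid, T_final, dt = 0.01,
                              record_every = 50L) {
  if (dt <= 0) stop("simulate_amari_2d: dt must be positive")
  u <- field_on_grid(u0, grid)
  plan <- conv_plan(kernel, grid, "w")
  nstep <- ceiling(T_final / dt)
  ed <- exp(-dt)
  times <- 0; snaps <- list(u)
  for (k in seq_len(nstep)) {
    drive <- conv_apply(plan, heaviside_mid(u, kappa))
    u <- u * ed + (1 - ed) * drive
    if (k %% record_every == 0L || k == nstep) {
      times <- c(times, k * dt); snaps <- c(snaps, list(u))
    }
  }
  list(t = times, u = snaps, grid = grid)
}

#' Simulate the gradient reformulation with a Dirichlet clamp
#'
#' Evolves the gradient field \eqn{z = \nabla u} by
#' \eqn{z_t = -z + (\nabla w) * H[u - \kappa]} (exponential Euler, two
#' spectral convolutions with the partial-derivative kernels), rebuilding
#' `u` after every step by [reconstruct_u()] from the clamped boundary so
#' the Heaviside always sees the reconstructed activity. On a disc domain
#' the firing indicator is forced to zero outside the disc.
#'
#' @param z0 Initial gradient: list `list(z1, z2)` of `n x n` matrices, or
#'   `function(X)` returning an `m x 2` matrix. Must be discretely
#'   curl-free at `t = 0` (tolerance `curl_tol` on the max interior
#'   central-difference curl).
#' @param kernel,kappa Model parameters.
#' @param u_BC Clamped boundary activity.
#' @param grid A `grid2d`.
#' @param domain Optional `domain_spec`; default rectangle spanning the
#'   grid. A `"disc"` shape restricts firing to the inscribed disc.
#' @param path_policy Path family for the line-integral reconstruction.
#' @param T_final,dt,record_every As in [simulate_amari_2d()].
#' @param curl_tol Curl acceptance tolerance for `z0`.
#' @return List `t`, `u` (list), `z1`, `z2` (lists), `grid`, `domain`,
#'   plus `boundary_residual` (max `|u - u_BC|` over the non-anchored
#'   boundary at each snapshot, a diagnostic of how well the line-integral
#'   reconstruction enforces the clamp away from the path anchors).
#' @export
simulate_gradient_2d <- function(z0, kernel, kappa, u_BC, grid, domain = NULL,
                                 path_policy = "axis_from_left",
                                 T_final = 5, dt = 0.01, record_every = 50L,
                                 curl_tol = NULL) {
  if (dt <= 0) stop("simulate_gradient_2d: dt must be positive")
  if (is.null(domain))
    domain <- domain_spec("rectangle", L = grid$L, bc_mode = "dirichlet",
                          u_BC = u_BC)
  if (is.function(z0)) {
    X <- as.matrix(expand.grid(x = grid$x, y = grid$x))
    Z <- z0(X)
    z1 <- matrix(Z[, 1], grid$n, grid$n)
    z2 <- matrix(Z[, 2], grid$n, grid$n)
  } else { z1 <- z0[[1]]; z2 <- z0[[2]] }
  crl <- discrete_curl(z1, z2, grid$h)
  # default gate: discrete curl of a genuine sampled gradient is O(h^2 u'''),
  # far below |z|/h, which is the scale a non-gradient field would show
  if (is.null(curl_tol))
    curl_tol <- 0.05 * max(abs(c(z1, z2)), 1e-300) / grid$h
  if (max(abs(crl)) > curl_tol)
    stop("simulate_gradient_2d: initial z is not curl-free (max |curl| = ",
         signif(max(abs(crl)), 3), ")")
  mask <- domain_mask(grid, domain)
  plan_x <- conv_plan(kernel, grid, "wx")
  plan_y <- conv_plan(kernel, grid, "wy")
  nstep <- ceiling(T_final / dt)
  ed <- exp(-dt)
  u <- reconstruct_u(list(z1, z2), u_BC, grid, domain, path_policy)
  times <- 0
  su <- list(u); s1 <- list(z1); s2 <- list(z2)
  bres <- boundary_residual(u, u_BC, grid, domain)
  for (k in seq_len(nstep)) {
    H <- heaviside_mid(u, kappa) * mask
    z1 <- z1 * ed + (1 - ed) * conv_apply(plan_x, H)
    z2 <- z2 * ed + (1 - ed) * conv_apply(plan_y, H)
    u <- reconstruct_u(list(z1, z2), u_BC, grid, domain, path_policy)
    if (k %% record_every == 0L || k == nstep) {
      times <- c(times, k * dt)
      su <- c(su, list(u)); s1 <- c(s1, list(z1)); s2 <- c(s2, list(z2))
      bres <- c(bres, boundary_residual(u, u_BC, grid, domain))
    }
  }
  list(t = times, u = su, z1 = s1, z2 = s2, grid = grid, domain = domain,
       boundary_residual = bres)
}

field_on_grid <- function(u0, grid) {
  if (is.function(u0)) {
    X <- as.matrix(expand.grid(x = grid$x, y = grid$x))
    matrix(u0(X), grid$n, grid$n)
  } else {
    stopifnot(all(dim(u0) == c(grid$n, grid$n)))
    u0
  }
}

domain_mask <- function(grid, domain) {
  if (!is.null(domain) && domain$shape == "disc") {
    R2 <- outer(grid$x^2, grid$x^2, `+`)
    (R2 <= domain$D^2) * 1
  } else matrix(1, grid$n, grid$n)
}

discrete_curl <- function(z1, z2, h) {
  n <- nrow(z1)
  i <- 2:(n - 1)
  (z2[i + 1, i] - z2[i - 1, i]) / (2 * h) -
    (z1[i, i + 1] - z1[i, i - 1]) / (2 * h)
}

boundary_residual <- function(u, u_BC, grid, domain) {
  if (domain$shape == "disc") {
    edge <- abs(sqrt(outer(grid$x^2, grid$x^2, `+`)) - domain$D) < grid$h
    if (!any(edge)) return(NA_real_)
    max(abs(u[edge] - u_BC))
  } else {
    n <- grid$n
    max(abs(c(u[n, ], u[, 1], u[, n]) - u_BC))  # left edge is the anchor
  }
}

#' Rebuild activity from its gradient by line integration
#'
#' \eqn{u(x) = u_{BC} + \int_\Gamma z\cdot dy} along a path from a
#' boundary anchor to `x`. Two path families are provided:
#' `"axis_from_left"` integrates row-wise (cumulative trapezoid in `x`
#' from the left boundary -- for a disc, from the left intersection of
#' each row with the circle), consistent with the 1D anchoring;
#' `"radial"` (disc only) integrates inward along the ray from the
#' boundary point \eqn{D\hat x} with bilinearly interpolated `z`. For a
#' curl-free gradient the two agree up to quadrature error.
#'
#' @param z List `list(z1, z2)` of `n x n` matrices.
#' @param u_BC Boundary value at the path anchors.
#' @param grid A `grid2d`.
#' @param domain Optional `domain_spec` (default: rectangle).
#' @param path_policy `"axis_from_left"` or `"radial"`.
#' @return `n x n` matrix; on a disc, points outside carry `u_BC`.
#' @export
reconstruct_u <- function(z, u_BC, grid, domain = NULL,
                          path_policy = c("axis_from_left", "radial")) {
  path_policy <- match.arg(path_policy)
  z1 <- z[[1]]; z2 <- z[[2]]
  n <- grid$n; h <- grid$h; xs <- grid$x
  disc <- !is.null(domain) && domain$shape == "disc"
  if (path_policy == "axis_from_left") {
    if (!disc) {
      u <- apply(z1, 2L, cumtrapz, h = h)
      return(u + u_BC)
    }
    D <- domain$D
    u <- matrix(u_BC, n, n)
    for (j in seq_len(n)) {
      y <- xs[j]
      if (abs(y) >= D) next
      xb <- -sqrt(D^2 - y^2)
      ins <- which(xs > xb & xs < -xb)
      if (!length(ins)) next
      i0 <- ins[1]
      lead <- z1[i0, j] * (xs[i0] - xb)  # first partial cell, O(h) anchor
      u[ins, j] <- u_BC + lead + cumtrapz(z1[ins, j], h)
    }
    u
  } else {
    if (!disc) stop("reconstruct_u: radial paths are defined on a disc")
    D <- domain$D
    u <- matrix(u_BC, n, n)
    for (j in seq_len(n)) for (i in seq_len(n)) {
      r <- sqrt(xs[i]^2 + xs[j]^2)
      if (r >= D) next
      nseg <- max(2L, ceiling((D - r) / h) + 1L)
      tt <- seq(D, r, length.out = nseg)
      ux <- if (r > 1e-12) xs[i] / r else 1
      uy <- if (r > 1e-12) xs[j] / r else 0
      px <- ux * tt; py <- uy * tt
      zr <- bilinear(z1, xs, px, py) * ux + bilinear(z2, xs, px, py) * uy
      u[i, j] <- u_BC + sum((zr[-1] + zr[-nseg]) / 2 * diff(tt))
    }
    u
  }
}

cumtrapz <- function(v, h) {
  n <- length(v)
  c(0, cumsum((v[-n] + v[-1]) / 2 * h))
}

bilinear <- function(M, xs, px, py) {
  n <- length(xs); h <- xs[2] - xs[1]
  fx <- pmin(pmax((px - xs[1]) / h, 0), n - 1 - 1e-12)
  fy <- pmin(pmax((py - xs[1]) / h, 0), n - 1 - 1e-12)
  i <- floor(fx); j <- floor(fy)
  tx <- fx - i; ty <- fy - j
  i <- i + 1L; j <- j + 1L
  M[cbind(i, j)] * (1 - tx) * (1 - ty) + M[cbind(i + 1L, j)] * tx * (1 - ty) +
    M[cbind(i, j + 1L)] * (1 - tx) * ty + M[cbind(i + 1L, j + 1L)] * tx * ty
}

#' Extract threshold-level contours from a gridded field
#'
#' Marching-squares (with linear interpolation) level sets of `u` at
#' `kappa`, oriented counter-clockwise around the suprathreshold region.
#' Contours touching the domain edge are returned flagged `open = TRUE`
#' and should be excluded from interface comparisons.
#'
#' @param u `n x n` field matrix.
#' @param grid A `grid2d`.
#' @param kappa Level.
#' @param min_vertices Discard fragments with fewer vertices.
#' @return List of `nf_contour`s, each with attributes `open` and
#'   `hole` (`TRUE` when the enclosed region is subthreshold).
#' @export
extract_contours <- function(u, grid, kappa, min_vertices = 16L) {
  cl <- grDevices::contourLines(grid$x, grid$x, u, levels = kappa)
  out <- list()
  for (cc in cl) {
    v <- cbind(cc$x, cc$y)
    closed <- sqrt(sum((v[1, ] - v[nrow(v), ])^2)) < 1e-9
    if (closed) v <- v[-nrow(v), , drop = FALSE]
    if (nrow(v) < min_vertices) next
    ct <- nf_contour(v, orient = TRUE)
    # classify interior: probe just inside the polygon along the inward normal
    g <- contour_geometry(ct)
    probe <- g$vertices[1, ] - g$normals[1, ] * grid$h / 2
    uin <- bilinear(u, grid$x, probe[1], probe[2])
    attr(ct, "open") <- !closed
    attr(ct, "hole") <- uin < kappa
    out[[length(out) + 1L]] <- ct
  }
  out
}
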