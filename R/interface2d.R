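#' Closed contours bounding the active region
#'
#' An `nf_contour` is an oriented closed polyline: an `n x 2` matrix of
#' vertices, the last implicitly connected to the first, oriented
#' counter-clockwise around the suprathreshold region \eqn{\Omega_+}.
#'
#' @param vertices Two-column matrix of vertex coordinates (a repeated
#'   closing vertex is dropped).
#' @param orient If `TRUE` (default) the vertex order is flipped when the
#'   signed area is negative, enforcing counter-clockwise orientation.
#' @return An `nf_contour`.
#' @export
nf_contour <- function(vertices, orient = TRUE) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2L, is.numeric(v))
  if (nrow(v) > 1L && sqrt(sum((v[1, ] - v[nrow(v), ])^2)) < 1e-12)
    v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 16L)
    stop("nf_contour: need at least 16 vertices")
  if (orient && polygon_area(v) < 0) v <- v[nrow(v):1, , drop = FALSE]
  structure(v, class = "nf_contour")
}

#' @export
print.nf_contour <- function(x, ...) {
  cat(sprintf("<nf_contour> %d vertices, area %.4g, length %.4g\n",
              nrow(x), polygon_area(x), polygon_length(x)))
  invisible(x)
}

#' Circular and elliptic contour constructors
#'
#' @param R Radius (or semi-axis `a`, `b` for the ellipse).
#' @param n Vertex count.
#' @param center Centre point.
#' @param a,b Semi-axes.
#' @export
circle_contour <- function(R, n = 256L, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  nf_contour(cbind(center[1] + R * cos(th), center[2] + R * sin(th)))
}

#' @rdname circle_contour
#' @export
ellipse_contour <- function(a, b, n = 256L, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  nf_contour(cbind(center[1] + a * cos(th), center[2] + b * sin(th)))
}

# per-vertex geometry of the smooth closed curve through the vertices,
# from periodic cubic splines in the vertex index: unit tangents, outward
# unit normals (CCW => (t2, -t1)), arc-length weights ds = |gamma'| dt,
# and signed curvature (positive where the contour is convex). Spline
# derivatives make the periodic-trapezoid contour quadratures fourth-order
# accurate with respect to the underlying smooth contour.
contour_geometry <- function(contour) {
  v <- unclass(contour)
  n <- nrow(v)
  ip <- c(2:n, 1L)
  if (any(rowSums((v[ip, ] - v)^2) == 0))
    stop("contour_geometry: duplicate adjacent vertices")
  tt <- 0:n
  fx <- stats::splinefun(tt, c(v[, 1], v[1, 1]), method = "periodic")
  fy <- stats::splinefun(tt, c(v[, 2], v[1, 2]), method = "periodic")
  t0 <- tt[-(n + 1L)]
  xp <- fx(t0, deriv = 1L); yp <- fy(t0, deriv = 1L)
  xpp <- fx(t0, deriv = 2L); ypp <- fy(t0, deriv = 2L)
  ds <- sqrt(xp^2 + yp^2)          # |gamma'| dt with dt = 1
  that <- cbind(xp, yp) / ds
  nrm <- cbind(that[, 2], -that[, 1])
  curv <- (xp * ypp - yp * xpp) / ds^3
  list(vertices = v, normals = nrm, tangents = that, ds = ds,
       curvature = curv, n = n)
}

#' Outward unit normals of a contour
#'
#' Normals point from the active region \eqn{\Omega_+} into the quiescent
#' exterior, obtained by rotating the central-difference tangents by -90
#' degrees (counter-clockwise orientation assumed).
#'
#' @param contour An `nf_contour`.
#' @return `n x 2` matrix of unit normals.
#' @export
contour_normals <- function(contour) contour_geometry(contour)$normals

#' Winding indicator of a point relative to the active region
#'
#' Returns 1 for points inside \eqn{\Omega_+}, 0 outside, and 1/2 for
#' points within `tol` of the contour itself (the on-contour evaluation
#' convention of the line-integral representation). For a list of
#' disconnected contours the winding numbers add.
#'
#' @param x A point (length-2 vector) or an `m x 2` matrix of points.
#' @param contour An `nf_contour` or list of them.
#' @param tol On-contour distance tolerance; defaults to half the median
#'   vertex spacing (the contour's own resolution).
#' @return Vector with values in `{0, 1/2, 1, ...}`.
#' @export
winding_C <- function(x, contour, tol = NULL) {
  if (is.list(contour) && !inherits(contour, "nf_contour"))
    return(Reduce(`+`, lapply(contour, winding_C, x = x, tol = tol)))
  X <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
  v <- unclass(contour)
  g <- contour_geometry(contour)
  if (is.null(tol)) tol <- 0.5 * stats::median(g$ds)
  d <- dist_to_polyline(X, v)
  wind <- point_in_polygon(X, v)
  out <- as.numeric(wind)
  out[d <= tol] <- 0.5
  out
}

# even-odd/winding test, vectorised over points (ray casting)
point_in_polygon <- function(X, v) {
  n <- nrow(v)
  ip <- c(2:n, 1L)
  x1 <- v[, 1]; y1 <- v[, 2]; x2 <- v[ip, 1]; y2 <- v[ip, 2]
  vapply(seq_len(nrow(X)), function(i) {
    px <- X[i, 1]; py <- X[i, 2]
    cross <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    sum(cross) %% 2L == 1L
  }, logical(1))
}

# minimum distance from each point in X to the closed polyline v
dist_to_polyline <- function(X, v) {
  n <- nrow(v)
  ip <- c(2:n, 1L)
  A <- v; B <- v[ip, , drop = FALSE]
  AB <- B - A
  len2 <- pmax(rowSums(AB^2), 1e-300)
  vapply(seq_len(nrow(X)), function(i) {
    P <- X[i, ]
    t <- pmin(1, pmax(0, ((P[1] - A[, 1]) * AB[, 1] +
                          (P[2] - A[, 2]) * AB[, 2]) / len2))
    dx <- A[, 1] + t * AB[, 1] - P[1]
    dy <- A[, 2] + t * AB[, 2] - P[2]
    sqrt(min(dx * dx + dy * dy))
  }, numeric(1))
}

#' Synaptic drive via the contour line integral
#'
#' Evaluates the drive of the active region as a pure contour integral,
#' \deqn{\psi(x) = \oint f(|\gamma(s) - x|)\,
#'   \frac{\gamma(s) - x}{|\gamma(s) - x|}\cdot n(s)\,ds, \qquad
#'   f(r) = \frac{1}{r}\int_0^r \sigma\,w(\sigma)\,d\sigma,}
#' by the periodic trapezoid over the vertices. This is the divergence
#' theorem applied to \eqn{F(u) = f(|u|)\hat u}, whose radial profile
#' satisfies \eqn{(rf)' = rw}. It is algebraically equivalent to the usual
#' ring-potential form \eqn{\oint \varphi\,\hat r\cdot n\,ds +
#' \mathcal{K}C} (with \eqn{\varphi(r) = f(r) - \mathcal{K}/2\pi r}),
#' but because \eqn{f} is bounded and vanishes at the evaluation point the
#' integrand has no pole, no self-term limit is needed, the winding
#' constant \eqn{C} is carried implicitly -- on-contour points return the
#' principal value matching \eqn{C = 1/2} -- and the trapezoid error stays
#' uniformly second order in vertex spacing for interior, exterior and
#' on-contour points alike.
#'
#' Requires an integrable kernel; use [psi_area()] for the top-hat.
#'
#' @param x Evaluation point (length-2) or `m x 2` matrix.
#' @param contour An `nf_contour`, or a list of disjoint ones (their
#'   contributions add).
#' @param kernel An integrable `radial_kernel`.
#' @param C Ignored (kept for call compatibility); the winding
#'   contribution is implicit in this formulation.
#' @return Numeric vector of \eqn{\psi} values.
#' @export
psi_line <- function(x, contour, kernel, C = NULL) {
  if (!is_integrable(kernel))
    stop("psi_line: kernel is not integrable on the plane; use psi_area")
  X <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
  if (is.list(contour) && !inherits(contour, "nf_contour"))
    return(Reduce(`+`, lapply(contour, function(cc) psi_line(X, cc, kernel))))
  g <- contour_geometry(contour)
  dx1 <- t(outer(g$vertices[, 1], X[, 1], `-`))
  dx2 <- t(outer(g$vertices[, 2], X[, 2], `-`))
  r2 <- dx1^2 + dx2^2
  self <- r2 < (1e-9 * max(1, max(abs(g$vertices))))^2
  r2[self] <- 1  # placeholder; the integrand limit at the vertex is 0
  integrand <- radial_first_moment(kernel, sqrt(r2)) *
    (dx1 * rep(g$normals[, 1], each = nrow(X)) +
     dx2 * rep(g$normals[, 2], each = nrow(X))) / r2
  integrand[self] <- 0
  drop(integrand %*% g$ds)
}

#' Synaptic drive by direct area quadrature
#'
#' Evaluates \eqn{\psi(x) = \int_{\Omega_+} w(|x-y|)\,dy} exactly as an
#' area integral, decomposing the polygon into signed triangles fanned
#' from `x`: each directed edge contributes
#' \eqn{\int_0^1 F(|y(t)-x|)\,\frac{(y(t)-x)\times(B-A)}{|y(t)-x|^2}\,dt}
#' with \eqn{F(s) = \int_0^s \sigma w(\sigma)\,d\sigma} in closed form,
#' integrated adaptively. Valid for any simple polygon, any kernel family
#' and any evaluation point (on-contour included, where it returns the
#' principal value matching the `C = 1/2` convention of [psi_line()]).
#' It is the production path for piece-wise constant kernels and the
#' independent oracle for the line-integral representation.
#'
#' @inheritParams psi_line
#' @param kernel Any `radial_kernel`.
#' @param rel_tol Relative tolerance of the per-edge quadrature.
#' @export
psi_area <- function(x, contour, kernel, rel_tol = 1e-9) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
  if (is.list(contour) && !inherits(contour, "nf_contour"))
    return(Reduce(`+`, lapply(contour, psi_area, x = X, kernel = kernel,
                              rel_tol = rel_tol)))
  v <- unclass(contour)
  n <- nrow(v)
  if (n < 3L || abs(polygon_area(v)) < 1e-300)
    stop("psi_area: degenerate polygon")
  ip <- c(2:n, 1L)
  vapply(seq_len(nrow(X)), function(i) {
    P <- X[i, ]
    total <- 0
    for (e in seq_len(n)) {
      A <- v[e, ]; B <- v[ip[e], ]
      cr <- (A[1] - P[1]) * (B[2] - P[2]) - (A[2] - P[2]) * (B[1] - P[1])
      if (abs(cr) < 1e-14 * (1 + sum(abs(A - P)) * sum(abs(B - A)))) next
      f <- function(t) {
        yx <- cbind(A[1] + t * (B[1] - A[1]) - P[1],
                    A[2] + t * (B[2] - A[2]) - P[2])
        r2 <- yx[, 1]^2 + yx[, 2]^2
        crs <- yx[, 1] * (B[2] - A[2]) - yx[, 2] * (B[1] - A[1])
        radial_first_moment(kernel, sqrt(r2)) * crs / r2
      }
      total <- total + stats::integrate(f, 0, 1, rel.tol = rel_tol,
                                        subdivisions = 200L)$value
    }
    total
  }, numeric(1))
}

#' Gradient of the synaptic drive as a line integral
#'
#' \deqn{\nabla\psi(x) = -\oint n(s)\, w(|x - \gamma(s)|)\,ds,}
#' non-singular for bounded kernels; periodic trapezoid over vertices.
#'
#' @inheritParams psi_line
#' @return For a single point, a length-2 vector; for an `m x 2` matrix of
#'   points, an `m x 2` matrix.
#' @export
grad_psi_line <- function(x, contour, kernel) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
  if (is.list(contour) && !inherits(contour, "nf_contour")) {
    out <- Reduce(`+`, lapply(contour, grad_psi_line, x = X, kernel = kernel))
    return(if (is.matrix(x)) out else drop(out))
  }
  g <- contour_geometry(contour)
  out <- grad_psi_core(X, g, kernel)
  if (is.matrix(x)) out else drop(out)
}

grad_psi_core <- function(X, g, kernel) {
  dx1 <- outer(X[, 1], g$vertices[, 1], `-`)
  dx2 <- outer(X[, 2], g$vertices[, 2], `-`)
  wv <- evaluate_w(kernel, sqrt(dx1^2 + dx2^2))
  wds <- wv * rep(g$ds, each = nrow(X))
  cbind(-wds %*% g$normals[, 1], -wds %*% g$normals[, 2])
}

#' Contour history for the memory convolution
#'
#' The gradient field of the reformulated dynamics is a memory integral
#' over past interface shapes. A `contour_history` stores time-stamped
#' snapshots (strictly increasing times starting at 0) together with the
#' initial gradient evaluator `z0`.
#'
#' @param contour Initial `nf_contour` (snapshot at `t = 0`).
#' @param z0 Initial gradient: `function(X)` mapping an `m x 2` matrix of
#'   points to an `m x 2` matrix of gradient vectors.
#' @export
contour_history <- function(contour, z0) {
  stopifnot(inherits(contour, "nf_contour"), is.function(z0))
  h <- new.env(parent = emptyenv())
  h$times <- 0
  h$contours <- list(contour)
  h$geoms <- list(contour_geometry(contour))
  h$z0 <- z0
  class(h) <- "contour_history"
  h
}

history_append <- function(hist, contour, t) {
  if (t <= hist$times[length(hist$times)])
    stop("contour_history: timestamps must be strictly increasing")
  k <- length(hist$times) + 1L
  hist$times[k] <- t
  hist$contours[[k]] <- contour
  hist$geoms[[k]] <- contour_geometry(contour)
  invisible(hist)
}

#' Gradient field from the contour history
#'
#' Variation of parameters gives
#' \deqn{z(x,t) = e^{-t} z_0(x) + \int_0^t e^{-(t-s)}\,
#'   \nabla\psi(x; \partial\Omega_+(s))\,ds,}
#' with \eqn{\nabla\psi} the line integral of [grad_psi_line()] over the
#' stored contour at each past time. The time integral treats
#' \eqn{\nabla\psi} as piece-wise linear between stored snapshots
#' (optionally subsampled to spacing `quad_dt`) and integrates the
#' exponential weight exactly on each interval (product integration), so
#' a stationary history reproduces the geometric-series limit
#' \eqn{z \to \nabla\psi} to machine precision; the tail below `1e-12`
#' is dropped.
#'
#' @param x Point or `m x 2` matrix.
#' @param hist A `contour_history` covering `[0, t]`.
#' @param kernel Integrable kernel.
#' @param t Evaluation time.
#' @param quad_dt Optional coarser spacing for the memory quadrature.
#' @return `m x 2` matrix (or length-2 vector for a single point).
#' @export
z_from_history <- function(x, hist, kernel, t, quad_dt = NULL) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
  times <- hist$times
  if (t > times[length(times)] + 1e-12)
    stop("z_from_history: t beyond stored history")
  sel <- which(times <= t + 1e-12)
  if (!is.null(quad_dt) && length(sel) > 2L) {
    stride <- max(1L, round(quad_dt / max(diff(times[sel]))))
    keep <- unique(c(seq(1L, length(sel), by = stride), length(sel)))
    sel <- sel[keep]
  }
  ts <- times[sel]
  decay <- exp(-(t - ts))
  live <- decay >= 1e-12
  sel <- sel[live]; ts <- ts[live]; decay <- decay[live]
  acc <- exp(-t) * hist$z0(X)
  if (length(sel) >= 2L) {
    # product integration: G piece-wise linear, e^{-(t-s)} exact per interval
    m <- length(ts)
    a <- ts[-m]; b <- ts[-1L]; hseg <- b - a
    I0 <- exp(b - t) - exp(a - t)
    I1 <- hseg * exp(b - t) - I0
    wts <- numeric(m)
    wts[-m] <- wts[-m] + (I0 - I1 / hseg)
    wts[-1L] <- wts[-1L] + I1 / hseg
    for (j in seq_len(m)) {
      G <- grad_psi_core(X, hist$geoms[[sel[j]]], kernel)
      acc <- acc + wts[j] * G
    }
  }
  if (is.matrix(x)) acc else drop(acc)
}

#' Normal velocity of the interface
#'
#' Free-plane rule: \eqn{c_n = (-\kappa + \psi(x)) / |z(x,t)|} at each
#' vertex, with \eqn{\psi} from [psi_line()] at the on-contour convention
#' `C = 1/2` and \eqn{z} from [z_from_history()]. Positive speed moves the
#' interface along its outward normal, growing the active region.
#'
#' Dirichlet rule on a bounded domain:
#' \eqn{c_n = [u_{BC} - \kappa + \psi(x) - \psi(\zeta(x))]/|z(x,t)|},
#' where \eqn{\zeta} maps each contour vertex to the domain boundary --
#' radial projection on a disc; nearest boundary point on a rectangle
#' (ties broken toward the left edge, consistent with the 1D anchoring).
#'
#' @param contour Current `nf_contour`.
#' @param hist `contour_history` (used for `z`).
#' @param kernel Integrable kernel.
#' @param kappa Firing threshold.
#' @param t Current time.
#' @param domain A `domain_spec` with a bounded shape (Dirichlet rule).
#' @param quad_dt Memory-quadrature spacing passed to [z_from_history()].
#' @param z Optional precomputed `n x 2` gradient at the vertices.
#' @return Numeric vector of per-vertex normal speeds.
#' @export
normal_velocity_free <- function(contour, hist, kernel, kappa, t,
                                 quad_dt = NULL, z = NULL) {
  V <- unclass(contour)
  if (is.null(z)) z <- z_from_history(V, hist, kernel, t, quad_dt = quad_dt)
  zn <- sqrt(rowSums(z^2))
  if (any(zn < 1e-10))
    stop("normal_velocity_free: |z| ~ 0 at vertex ", which.min(zn),
         " (interface degeneracy)")
  psi <- psi_line(V, contour, kernel, C = 0.5)
  (psi - kappa) / zn
}

#' @rdname normal_velocity_free
#' @export
normal_velocity_dirichlet <- function(contour, hist, kernel, kappa, domain, t,
                                      quad_dt = NULL, z = NULL) {
  stopifnot(inherits(domain, "domain_spec"))
  if (domain$shape == "plane")
    stop("normal_velocity_dirichlet: bounded domain required")
  V <- unclass(contour)
  if (is.null(z)) z <- z_from_history(V, hist, kernel, t, quad_dt = quad_dt)
  zn <- sqrt(rowSums(z^2))
  if (any(zn < 1e-10))
    stop("normal_velocity_dirichlet: |z| ~ 0 at vertex ", which.min(zn),
         " (interface degeneracy)")
  zeta <- boundary_map(V, domain)
  psi_c <- psi_line(V, contour, kernel, C = 0.5)
  psi_b <- psi_line(zeta, contour, kernel)
  (domain$u_BC - kappa + psi_c - psi_b) / zn
}

#' Domain specification
#'
#' @param shape `"plane"`, `"rectangle"` (square `[-L, L]^2`) or
#'   `"disc"` (radius `D`).
#' @param L Half-width of the rectangle.
#' @param D Disc radius.
#' @param bc_mode `"none"` or `"dirichlet"` (requires a bounded shape).
#' @param u_BC Clamped boundary activity.
#' @export
domain_spec <- function(shape = c("plane", "rectangle", "disc"), L = NULL,
                        D = NULL, bc_mode = c("none", "dirichlet"), u_BC = 0) {
  shape <- match.arg(shape)
  bc_mode <- match.arg(bc_mode)
  if (bc_mode == "dirichlet" && shape == "plane")
    stop("domain_spec: Dirichlet condition requires a bounded domain")
  if (shape == "rectangle") stopifnot(is.numeric(L), L > 0)
  if (shape == "disc") stopifnot(is.numeric(D), D > 0)
  structure(list(shape = shape, L = L, D = D, bc_mode = bc_mode, u_BC = u_BC),
            class = "domain_spec")
}

# zeta: project contour vertices to the domain boundary
boundary_map <- function(V, domain) {
  if (domain$shape == "disc") {
    r <- sqrt(rowSums(V^2))
    if (any(r < 1e-12))
      stop("boundary_map: vertex at the disc centre has no radial projection")
    V * (domain$D / r)
  } else if (domain$shape == "rectangle") {
    L <- domain$L
    gaps <- cbind(V[, 1] + L, L - V[, 1], V[, 2] + L, L - V[, 2])
    side <- max.col(-gaps, ties.method = "first")  # ties -> left edge first
    Z <- V
    Z[side == 1L, 1] <- -L
    Z[side == 2L, 1] <- L
    Z[side == 3L, 2] <- -L
    Z[side == 4L, 2] <- L
    Z
  } else stop("boundary_map: unbounded domain has no boundary")
}

#' Advance a contour by one step of normal motion
#'
#' Moves each vertex by `velocity * dt` along its outward normal, then
#' resamples to uniform arc length whenever the vertex spacing leaves
#' `[h_min, h_max]`. Self-intersection after the step is treated as a
#' topology-change event and raised as an error carrying the offending
#' contour (contour surgery is out of scope; labyrinthine growth past a
#' merge is delegated to the field simulator).
#'
#' @param contour Current `nf_contour`.
#' @param velocities Per-vertex normal speeds.
#' @param dt Time step.
#' @param h_min,h_max Admissible vertex-spacing band; defaults keep the
#'   initial spacing within a factor of two.
#' @return The advanced `nf_contour`.
#' @export
step_contour <- function(contour, velocities, dt, h_min = NULL, h_max = NULL) {
  g <- contour_geometry(contour)
  v_new <- g$vertices + (velocities * dt) * g$normals
  if (is.null(h_min) || is.null(h_max)) {
    s0 <- mean(g$ds)
    if (is.null(h_min)) h_min <- s0 / 2
    if (is.null(h_max)) h_max <- s0 * 2
  }
  sp <- sqrt(rowSums((v_new[c(2:nrow(v_new), 1L), ] - v_new)^2))
  if (any(sp < h_min | sp > h_max)) {
    s_tgt <- sqrt(h_min * h_max)
    len <- polygon_length(v_new)
    v_new <- resample_closed(v_new, n_out = max(16L, round(len / s_tgt)))
  }
  out <- nf_contour(v_new, orient = FALSE)
  if (self_intersects(out))
    stop(structure(class = c("topology_change", "error", "condition"),
                   list(message = "step_contour: contour self-intersection (topology change)",
                        call = sys.call(), contour = out)))
  out
}

# uniform arc-length resampling of a closed polyline
resample_closed <- function(v, n_out) {
  vc <- rbind(v, v[1, ])
  seg <- sqrt(rowSums(diff(vc)^2))
  s <- c(0, cumsum(seg))
  stot <- s[length(s)]
  starget <- stot * (seq_len(n_out) - 1L) / n_out
  cbind(stats::approx(s, vc[, 1], xout = starget)$y,
        stats::approx(s, vc[, 2], xout = starget)$y)
}

# O(n^2) segment pair test, adjacent pairs excluded
self_intersects <- function(contour) {
  v <- unclass(contour)
  n <- nrow(v)
  ip <- c(2:n, 1L)
  A <- v; B <- v[ip, , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]
    if (!length(js)) next
    if (any(segments_cross(A[i, ], B[i, ], A[js, , drop = FALSE],
                           B[js, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  d <- p2 - p1
  o1 <- (q1[, 1] - p1[1]) * d[2] - (q1[, 2] - p1[2]) * d[1]
  o2 <- (q2[, 1] - p1[1]) * d[2] - (q2[, 2] - p1[2]) * d[1]
  e1 <- q2[, 1] - q1[, 1]; e2 <- q2[, 2] - q1[, 2]
  o3 <- (p1[1] - q1[, 1]) * e2 - (p1[2] - q1[, 2]) * e1
  o4 <- (p2[1] - q1[, 1]) * e2 - (p2[2] - q1[, 2]) * e1
  (o1 * o2 < 0) & (o3 * o4 < 0)
}

#' Evolve the interface dynamics
#'
#' Drives the contour-only evolution: at each step the per-vertex normal
#' velocity (free-plane or Dirichlet rule) is evaluated from the line
#' integrals and the memory convolution, the vertices advance by explicit
#' Euler, and the snapshot is appended to the history.
#'
#' @param contour Initial `nf_contour`.
#' @param z0 Initial gradient evaluator, `function(X) -> m x 2 matrix`.
#' @param kernel Integrable `radial_kernel`.
#' @param kappa Firing threshold.
#' @param T_final,dt Horizon and step (`dt <= 0.01` recommended).
#' @param domain Optional `domain_spec`; a bounded shape with
#'   `bc_mode = "dirichlet"` selects the Dirichlet velocity rule.
#' @param quad_dt Memory-quadrature spacing (default `5 * dt`), traded
#'   against the cost of re-evaluating line integrals over every stored
#'   snapshot.
#' @param record_every Keep a diagnostics row every this many steps.
#' @return List with `contour` (final), `history` (`contour_history`), and
#'   `diagnostics` (data frame: `t`, `area`, `length`, `max_speed`).
#' @export
evolve_contour <- function(contour, z0, kernel, kappa, T_final, dt = 0.01,
                           domain = NULL, quad_dt = 5 * dt,
                           record_every = 5L) {
  stopifnot(dt > 0, dt <= 0.011)
  dirichlet <- !is.null(domain) && domain$bc_mode == "dirichlet"
  hist <- contour_history(contour, z0)
  nstep <- ceiling(T_final / dt)
  diag_rows <- list()
  cur <- contour
  s0 <- mean(contour_geometry(contour)$ds)  # spacing band fixed at t = 0
  for (k in seq_len(nstep)) {
    t <- (k - 1L) * dt
    cn <- if (dirichlet)
      normal_velocity_dirichlet(cur, hist, kernel, kappa, domain, t,
                                quad_dt = quad_dt)
    else normal_velocity_free(cur, hist, kernel, kappa, t, quad_dt = quad_dt)
    if (k %% record_every == 1L || k == nstep)
      diag_rows[[length(diag_rows) + 1L]] <-
        data.frame(t = t, area = polygon_area(unclass(cur)),
                   length = polygon_length(unclass(cur)),
                   max_speed = max(abs(cn)))
    cur <- step_contour(cur, cn, dt, h_min = s0 / 2, h_max = 2 * s0)
    history_append(hist, cur, k * dt)
  }
  list(contour = cur, history = hist,
       diagnostics = do.call(rbind, diag_rows))
}

#' Hausdorff distance between two closed contours
#'
#' Symmetric Hausdorff distance, measuring each vertex set against the
#' other polyline's segments (not just its vertices).
#'
#' @param a,b `nf_contour`s or plain vertex matrices.
#' @export
hausdorff_distance <- function(a, b) {
  A <- unclass(a); B <- unclass(b)
  max(max(dist_to_polyline(A, B)), max(dist_to_polyline(B, A)))
}

#' Signed area and length of a closed polygon
#'
#' Shoelace signed area (positive for counter-clockwise orientation) and
#' perimeter length.
#'
#' @param v Vertex matrix or `nf_contour`.
#' @export
polygon_area <- function(v) {
  v <- unclass(v)
  n <- nrow(v)
  ip <- c(2:n, 1L)
  sum(v[, 1] * v[ip, 2] - v[ip, 1] * v[, 2]) / 2
}

#' @rdname polygon_area
#' @export
polygon_length <- function(v) {
  v <- unclass(v)
  n <- nrow(v)
  sum(sqrt(rowSums((v[c(2:n, 1L), ] - v)^2)))
}

#' Read and write contours as CSV
#'
#' Plain-text exchange format: columns `contour_id`, `vertex_index`,
#' `x`, `y`.
#'
#' @param contours An `nf_contour` or list of them.
#' @param path File path.
#' @export
write_contours_csv <- function(contours, path) {
  if (inherits(contours, "nf_contour")) contours <- list(contours)
  rows <- lapply(seq_along(contours), function(i) {
    v <- unclass(contours[[i]])
    data.frame(contour_id = i, vertex_index = seq_len(nrow(v)),
               x = v[, 1], y = v[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$contour_id), function(d)
    nf_contour(cbind(d$x, d$y), orient = FALSE))
}
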