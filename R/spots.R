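#' Overlap area of two discs
#'
#' Area of the intersection of a disc of radius `R` centred at the origin
#' with a disc of radius `sigma` whose centre lies at distance `r`. The
#' three regimes are handled piece-wise: disjoint (`r >= R + sigma`),
#' containment (`r <= |R - sigma|`), and the lens
#' \eqn{A(R,\phi_0) + A(\sigma,\phi_1)} with
#' \eqn{A(\rho,\phi) = \rho^2(\phi - \sin\phi)/2} and
#' \deqn{\phi_0 = 2\cos^{-1}\!\frac{R^2-\sigma^2+r^2}{2Rr},\quad
#'       \phi_1 = 2\cos^{-1}\!\frac{\sigma^2-R^2+r^2}{2\sigma r}.}
#' Continuous across the regime boundaries and symmetric in `(R, sigma)`.
#'
#' @param r Centre separation(s), non-negative (vectorised).
#' @param R,sigma Disc radii, positive.
#' @return Overlap area(s).
#' @examples
#' A_plus(1, 1, 1)   # classic lens: 2*pi/3 - sqrt(3)/2
#' @export
A_plus <- function(r, R, sigma) {
  if (any(r < 0) || R < 0 || sigma < 0) stop("A_plus: negative argument")
  out <- numeric(length(r))
  full <- r <= abs(R - sigma)
  out[full] <- pi * min(R, sigma)^2
  lens <- !full & r < R + sigma
  if (any(lens)) {
    rl <- r[lens]
    phi0 <- 2 * acos(pmin(1, pmax(-1, (R^2 - sigma^2 + rl^2) / (2 * R * rl))))
    phi1 <- 2 * acos(pmin(1, pmax(-1, (sigma^2 - R^2 + rl^2) / (2 * sigma * rl))))
    out[lens] <- R^2 * (phi0 - sin(phi0)) / 2 + sigma^2 * (phi1 - sin(phi1)) / 2
  }
  out
}

#' Synaptic drive of a centred disc-shaped active region
#'
#' \eqn{\psi(r) = \int_{|y|<R} w(|x - y|)\,dy} at distance `r` from the
#' centre of an active disc of radius `R`.
#'
#' For piece-wise constant kernels this reduces to disc-overlap areas:
#' top-hat \eqn{\psi = (w_+ - w_-)A_+(r;R,\sigma) + w_-\pi R^2}; piece-wise
#' Mexican hat \eqn{\psi = (w_+ - w_-)A_+(r;R,\sigma_1) +
#' w_- A_+(r;R,\sigma_2)}.
#'
#' For a difference of Gaussians the angular reduction
#' \deqn{\psi(r) = \frac{a_1}{\sqrt{c\pi b_1}}\rho(r;b_1)
#'   - \frac{a_2}{\sqrt{c\pi b_2}}\rho(r;b_2) + \mathcal{K}C,\quad
#'   \rho(r;\alpha) = \frac{\alpha}{2}\int_0^{2\pi}
#'   \frac{e^{-\mathcal{Q}^2/\alpha}}{\mathcal{Q}^2}R(r\cos\theta - R)
#'   \,d\theta}
#' is used with \eqn{\mathcal{Q}^2 = R^2 + r^2 - 2Rr\cos\theta} and the
#' winding constant \eqn{C \in \{1, 1/2, 0\}} for `r` inside / on / outside
#' the active disc. (The sign of the \eqn{\rho} integrand is fixed so that
#' the reduction agrees with the defining area integral; commonly printed
#' versions of this formula carry the opposite, inconsistent sign.) The
#' integrand is quadratured on midpoint nodes, which skip the removable
#' \eqn{\theta = 0} singularity for on-contour evaluation; in the thin band
#' \eqn{0 < |r - R| < 0.1\max(R,1)}, where the \eqn{1/\mathcal{Q}^2} peak
#' is too sharp for fixed nodes, the defining area integral is evaluated
#' by nested adaptive quadrature instead.
#'
#' @param r Evaluation radius (scalar or vector), non-negative.
#' @param R Active-disc radius, positive.
#' @param kernel A `radial_kernel`.
#' @param n_theta Fixed-node count for the angular quadrature.
#' @export
psi_radial <- function(r, R, kernel, n_theta = 4096L) {
  stopifnot(R > 0, all(r >= 0))
  if (length(r) > 1L)
    return(vapply(r, psi_radial, numeric(1), R = R, kernel = kernel,
                  n_theta = n_theta))
  if (inherits(kernel, "tophat_kernel"))
    return((kernel$w_plus - kernel$w_minus) * A_plus(r, R, kernel$sigma) +
             kernel$w_minus * pi * R^2)
  if (inherits(kernel, "pwc_mexican_hat_kernel"))
    return((kernel$w_plus - kernel$w_minus) * A_plus(r, R, kernel$sigma1) +
             kernel$w_minus * A_plus(r, R, kernel$sigma2))
  k <- kernel
  if (r != R && abs(r - R) < 0.1 * max(R, 1))
    return(psi_disc_direct(r, R, kernel))
  th <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  Q2 <- R^2 + r^2 - 2 * R * r * cos(th)
  C <- if (r < R) 1 else if (r > R) 0 else 0.5
  rho <- function(alpha)
    (alpha / 2) * mean(exp(-Q2 / alpha) / Q2 * R * (r * cos(th) - R)) * 2 * pi
  k$a1 / sqrt(k$c * pi * k$b1) * rho(k$b1) -
    k$a2 / sqrt(k$c * pi * k$b2) * rho(k$b2) + total_mass(kernel) * C
}

# direct polar quadrature of the defining area integral; smooth in r,
# used near the contour where the angular reduction is ill-conditioned
psi_disc_direct <- function(r, R, kernel) {
  outer_f <- function(s) vapply(s, function(si) {
    g <- function(th) evaluate_w(kernel, sqrt(si^2 + r^2 - 2 * si * r * cos(th)))
    2 * si * stats::integrate(g, 0, pi, rel.tol = 1e-11)$value
  }, numeric(1))
  stats::integrate(outer_f, 0, R, rel.tol = 1e-11)$value
}

#' Steady spot branches on the plane or a clamped disc
#'
#' Solves the radius condition for circularly symmetric stationary spots:
#' \eqn{\kappa = \psi(R)} on the plane, and
#' \eqn{\kappa = u_{BC} + \psi(R) - \psi(D)} on a disc of radius `D` with
#' Dirichlet boundary activity `u_BC` (\eqn{\psi} evaluated with the
#' on-contour convention \eqn{C = 1/2} at `r = R`). All roots in
#' \eqn{(\epsilon, D - \epsilon)} -- or up to `R_max` on the plane -- are
#' located by a sign-change scan plus bisection; each branch carries its
#' azimuthal spectrum from [spot_spectrum()].
#'
#' @param kernel A `radial_kernel`.
#' @param kappa Firing threshold.
#' @param domain `"plane"`, or `disc_domain(D)` (equivalently a number, the
#'   disc radius).
#' @param u_BC Boundary activity (disc only).
#' @param R_max Upper end of the scan on the plane.
#' @param m_max Azimuthal modes 0..m_max for the spectrum.
#' @param n_scan Scan resolution.
#' @return List of `spot_branch` objects with fields `R`, `kappa`,
#'   `domain`, `D`, `u_BC`, `lambda` (named vector, modes 0..m_max),
#'   `q_prime`, `stable`, `residual`. On the plane the translation mode
#'   `m = 1` is exempt from the stability call.
#' @examples
#' wk <- dog_kernel(3.55, 3, 2.4, 3.2, 10)
#' sp <- solve_spot_radius(wk, kappa = 0.05, domain = "plane")
#' sapply(sp, `[[`, "R")   # narrow and wide spot
#' @export
solve_spot_radius <- function(kernel, kappa, domain = "plane", u_BC = 0,
                              R_max = 12, m_max = 8L, n_scan = 400L) {
  is_plane <- identical(domain, "plane")
  D <- if (is_plane) Inf else as.numeric(if (is.list(domain)) domain$D else domain)
  if (!is_plane && !(D > 0)) stop("solve_spot_radius: disc radius must be positive")
  hi <- if (is_plane) R_max else D - 1e-3
  Rs <- seq(1e-3, hi, length.out = n_scan)
  resid <- function(R) {
    v <- kappa - psi_radial(R, R, kernel)
    if (!is_plane) v <- v - u_BC + psi_radial(D, R, kernel)
    v
  }
  fv <- vapply(Rs, resid, numeric(1))
  idx <- which(diff(sign(fv)) != 0)
  roots <- vapply(idx, function(j)
    stats::uniroot(resid, c(Rs[j], Rs[j + 1]), tol = 1e-12)$root, numeric(1))
  lapply(sort(roots), function(R) {
    br <- structure(list(R = R, kappa = kappa,
                         domain = if (is_plane) "plane" else "disc",
                         D = D, u_BC = u_BC, residual = resid(R)),
                    class = "spot_branch")
    br$q_prime <- q_prime_at_R(br, kernel)
    lam <- spot_spectrum(br, kernel, m_max = m_max)
    br$lambda <- lam
    check <- if (is_plane) lam[-2L] else lam  # m = 1 neutral on the plane
    br$stable <- all(check < -1e-10)
    br
  })
}

#' @export
print.spot_branch <- function(x, ...) {
  cat(sprintf("<spot_branch> R=%.6g kappa=%.4g domain=%s stable=%s\n",
              x$R, x$kappa, x$domain, x$stable))
  cat("  lambda:", paste(sprintf("m%d=%.3g", seq_along(x$lambda) - 1L,
                                 x$lambda), collapse = " "), "\n")
  invisible(x)
}

#' Helper describing a clamped disc domain
#' @param D Disc radius.
#' @export
disc_domain <- function(D) list(shape = "disc", D = D)

#' Radial derivative of the spot profile at its edge
#'
#' \eqn{q'(R) = d\psi/dr|_{r=R}}, the slope of the steady activity at the
#' spot boundary, which normalises the azimuthal eigenproblem. For the
#' top-hat kernel the closed form
#' \eqn{q'(R) = \sigma(w_- - w_+)\sqrt{4R^2 - \sigma^2}/R} applies
#' (requires \eqn{\sigma < 2R}). For smooth kernels a 4-point central
#' stencil excluding the centre node,
#' \eqn{[f(R-2e) - 8f(R-e) + 8f(R+e) - f(R+2e)]/12e} with
#' \eqn{e = 10^{-3}R}, differentiates \eqn{\psi(r)} -- which is continuous
#' across `r = R` (the winding-constant jump is cancelled by the angular
#' part) -- using the near-contour adaptive path of [psi_radial()].
#'
#' @param branch A `spot_branch` (or any list with `R`).
#' @param kernel The kernel.
#' @export
q_prime_at_R <- function(branch, kernel) {
  R <- branch$R
  if (inherits(kernel, "tophat_kernel")) {
    s <- kernel$sigma
    if (s >= 2 * R)
      stop("q_prime_at_R: top-hat closed form requires sigma < 2R")
    return(s * (kernel$w_minus - kernel$w_plus) * sqrt(4 * R^2 - s^2) / R)
  }
  if (inherits(kernel, "pwc_mexican_hat_kernel")) {
    f <- function(r) psi_radial(r, R, kernel)
    e <- 1e-6 * R
    return((f(R - 2 * e) - 8 * f(R - e) + 8 * f(R + e) - f(R + 2 * e)) / (12 * e))
  }
  e <- 1e-3 * R
  f <- function(r) psi_radial(r, R, kernel)
  (f(R - 2 * e) - 8 * f(R - e) + 8 * f(R + e) - f(R + 2 * e)) / (12 * e)
}

#' Azimuthal kernel integral
#'
#' \deqn{I_m(r) = \int_0^{2\pi} \cos(m\theta)\,
#'   w\!\left(\sqrt{r^2 + R^2 - 2rR\cos\theta}\right) d\theta,}
#' the coupling of an azimuthal `cos(m theta)` perturbation of a spot of
#' radius `R` felt at radius `r_eval`. Smooth kernels use a midpoint
#' trapezoid (spectrally accurate); piece-wise constant kernels are
#' integrated exactly by splitting \eqn{[0,\pi]} at the angles where the
#' chord length crosses a jump radius. For the top-hat with
#' `r_eval = R` this reproduces the closed form
#' \eqn{2\frac{w_+-w_-}{m}\sin(m\theta^*)},
#' \eqn{\theta^* = 2\arcsin(\sigma/2R)} (for \eqn{m = 0} the exact value
#' \eqn{2(w_+-w_-)\theta^* + 2\pi w_-}; the often-quoted \eqn{m\to 0} limit
#' of the closed form drops the \eqn{2\pi w_-} background term).
#'
#' @param m Mode number, non-negative integer.
#' @param R Spot radius.
#' @param r_eval Evaluation radius.
#' @param kernel A `radial_kernel`.
#' @param n_theta Node count for smooth kernels.
#' @export
angular_weight_integral <- function(m, R, r_eval, kernel, n_theta = 1024L) {
  stopifnot(m >= 0, m == round(m), R > 0, r_eval >= 0)
  if (inherits(kernel, "dog_kernel")) {
    th <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
    d <- sqrt(r_eval^2 + R^2 - 2 * r_eval * R * cos(th))
    return(mean(cos(m * th) * evaluate_w(kernel, d)) * 2 * pi)
  }
  # piece-wise constant: chord length d(theta) is increasing on [0, pi];
  # solve d(theta) = s for each jump radius s and integrate cos(m theta)
  # exactly on each constant piece (doubled by symmetry).
  jumps <- if (inherits(kernel, "tophat_kernel")) kernel$sigma
           else c(kernel$sigma1, kernel$sigma2)
  dmin <- abs(r_eval - R); dmax <- r_eval + R
  theta_of <- function(s) {
    if (s <= dmin) 0
    else if (s >= dmax) pi
    else acos(pmin(1, pmax(-1, (r_eval^2 + R^2 - s^2) / (2 * r_eval * R))))
  }
  brk <- c(0, vapply(jumps, theta_of, numeric(1)), pi)
  lvls <- evaluate_w(kernel, c((dmin + jumps[1]) / 2,
                               if (length(jumps) == 2L)
                                 (jumps[1] + jumps[2]) / 2 else NULL))
  lvls <- c(lvls, evaluate_w(kernel, jumps[length(jumps)] + 1))
  intcos <- function(a, b)
    if (m == 0) b - a else (sin(m * b) - sin(m * a)) / m
  2 * sum(vapply(seq_along(lvls), function(i)
    lvls[i] * intcos(brk[i], brk[i + 1]), numeric(1)))
}

#' Azimuthal (Evans-function) spectrum of a spot
#'
#' The Evans function of mode `m` is affine in \eqn{\lambda}, so each
#' eigenvalue is explicit:
#' \deqn{\lambda_m = -1 + \frac{R}{|q'(R)|}\left[I_m(R) - I_m(D)\right],}
#' with the boundary term \eqn{I_m(D)} present only on a clamped disc.
#' On the plane \eqn{\lambda_1 = 0} identically (translation symmetry);
#' computing it numerically is a strong consistency check between the
#' differentiated profile and the `m = 1` coupling integral.
#'
#' @param branch A solved `spot_branch`.
#' @param kernel The kernel.
#' @param m_max Largest mode.
#' @return Named numeric vector `lambda`, modes `0..m_max`.
#' @export
spot_spectrum <- function(branch, kernel, m_max = 8L) {
  qp <- if (is.null(branch$q_prime)) q_prime_at_R(branch, kernel) else branch$q_prime
  if (abs(qp) < 1e-12)
    stop("spot_spectrum: q'(R) = 0, degenerate spectrum")
  R <- branch$R
  on_disc <- identical(branch$domain, "disc") && is.finite(branch$D)
  lam <- vapply(0:m_max, function(m) {
    v <- angular_weight_integral(m, R, R, kernel)
    if (on_disc) v <- v - angular_weight_integral(m, R, branch$D, kernel)
    -1 + R / abs(qp) * v
  }, numeric(1))
  names(lam) <- paste0("m", 0:m_max)
  lam
}

#' Branch scan over the firing threshold
#'
#' Convenience scan producing the machine-readable twin of a
#' radius-vs-threshold bifurcation diagram: one row per `(kappa, branch)`
#' with the spot radius, eigenvalues and stability flag.
#'
#' @param kernel A `radial_kernel`.
#' @param kappas Thresholds to scan.
#' @inheritParams solve_spot_radius
#' @return Data frame with columns `kappa`, `R`, `lambda_0` ..
#'   `lambda_<m_max>`, `stable`.
#' @export
spot_branch_scan <- function(kernel, kappas, domain = "plane", u_BC = 0,
                             m_max = 8L, R_max = 12) {
  rows <- lapply(kappas, function(k) {
    brs <- solve_spot_radius(kernel, k, domain = domain, u_BC = u_BC,
                             m_max = m_max, R_max = R_max)
    if (!length(brs)) return(NULL)
    do.call(rbind, lapply(brs, function(b) {
      lam <- as.list(b$lambda)
      names(lam) <- paste0("lambda_", 0:m_max)
      cbind(data.frame(kappa = k, R = b$R), as.data.frame(lam),
            data.frame(stable = b$stable))
    }))
  })
  do.call(rbind, rows)
}
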