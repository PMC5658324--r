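# kernels used across the suite: the 1D bump study and the 2D spot/labyrinth
# study parameter sets, plus piece-wise constant test kernels
bump_kernel <- function() dog_kernel(a1 = 14, a2 = 13, b1 = 24, b2 = 150, c = 5)
spot_kernel <- function() dog_kernel(a1 = 3.55, a2 = 3, b1 = 2.4, b2 = 3.2, c = 10)
tophat_test <- function() tophat_kernel(w_plus = 1, w_minus = -0.5, sigma = 2)
pwcmh_test <- function() pwc_mexican_hat_kernel(w_plus = 1, w_minus = -0.4,
                                                sigma1 = 1.5, sigma2 = 3)

# numerical quadrature of the ring potential definition, independent of the
# closed form: phi(r) = (1/r) int_inf^r x w(x) dx
phi_quadrature <- function(kernel, r) {
  vapply(r, function(ri)
    -stats::integrate(function(x) x * evaluate_w(kernel, x), ri, Inf,
                      rel.tol = 1e-12)$value / ri, numeric(1))
}

# amplitude of the cos(m*theta) rim mode of the largest closed contour
contour_mode_amplitude <- function(u, grid, kappa, m) {
  ct <- extract_contours(u, grid, kappa)
  if (!length(ct)) return(NA_real_)
  v <- unclass(ct[[which.max(vapply(ct, function(cc)
    abs(polygon_area(unclass(cc))), numeric(1)))]])
  th <- atan2(v[, 2], v[, 1])
  r <- sqrt(rowSums(v^2))
  if (m == 0) mean(r)
  else sqrt((2 * mean(r * cos(m * th)))^2 + (2 * mean(r * sin(m * th)))^2)
}

# stationary-history helper: identical snapshots at spacing dt up to T
stationary_history <- function(contour, z0, T_final, dt = 0.1) {
  hist <- contour_history(contour, z0)
  for (k in seq_len(ceiling(T_final / dt)))
    neurofield:::history_append(hist, contour, k * dt)
  hist
}
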