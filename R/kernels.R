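#' Radially symmetric connectivity kernels
#'
#' Constructors for the synaptic connectivity kernels \eqn{w(r)} used
#' throughout the package. Three families are supported:
#'
#' * `dog_kernel()` -- a difference of Gaussians ("Mexican hat"),
#'   \deqn{w(r) = \frac{1}{\sqrt{c\pi}}\left[\frac{a_1}{\sqrt{b_1}}
#'     e^{-r^2/b_1} - \frac{a_2}{\sqrt{b_2}} e^{-r^2/b_2}\right],}
#'   the standard smooth choice with short-range excitation and longer-range
#'   inhibition.
#' * `tophat_kernel()` -- piece-wise constant: \eqn{w_+ > 0} for
#'   \eqn{r \le \sigma}, \eqn{w_- < 0} beyond. Not integrable on the plane,
#'   so quantities that require decay (total mass, ring potential) are
#'   unavailable for it.
#' * `pwc_mexican_hat_kernel()` -- piece-wise constant Mexican hat:
#'   \eqn{w_+} on \eqn{r \le \sigma_1}, \eqn{w_-} on
#'   \eqn{\sigma_1 < r \le \sigma_2}, zero beyond (closed intervals, so the
#'   excitatory plateau includes its rim).
#'
#' All parameters are validated at construction; invalid signs are rejected
#' early rather than surfacing as NaNs deep inside a simulation.
#'
#' @param a1,a2 Gaussian amplitudes (`a1` excitatory, `a2` inhibitory).
#' @param b1,b2 Squared Gaussian length scales, both positive.
#' @param c Positive normalisation constant.
#' @param w_plus Plateau value of the excitatory core, positive.
#' @param w_minus Value of the inhibitory surround, negative.
#' @param sigma Radius of the excitatory core, positive.
#' @param sigma1,sigma2 Core and surround radii, `0 < sigma1 < sigma2`.
#'
#' @return An object of class `radial_kernel` (with a family subclass).
#' @examples
#' wk <- dog_kernel(a1 = 3.55, a2 = 3, b1 = 2.4, b2 = 3.2, c = 10)
#' evaluate_w(wk, c(0, 1, 2))
#' total_mass(wk)
#' @export
dog_kernel <- function(a1, a2, b1, b2, c) {
  stopifnot(is.numeric(a1), is.numeric(a2), length(a1) == 1L, length(a2) == 1L)
  if (!(b1 > 0 && b2 > 0 && c > 0))
    stop("dog_kernel: b1, b2 and c must be positive")
  structure(list(family = "dog", a1 = a1, a2 = a2, b1 = b1, b2 = b2, c = c),
            class = c("dog_kernel", "radial_kernel"))
}

#' @rdname dog_kernel
#' @export
tophat_kernel <- function(w_plus, w_minus, sigma) {
  if (!(w_plus > 0)) stop("tophat_kernel: w_plus must be positive")
  if (!(w_minus < 0)) stop("tophat_kernel: w_minus must be negative")
  if (!(sigma > 0)) stop("tophat_kernel: sigma must be positive")
  structure(list(family = "tophat", w_plus = w_plus, w_minus = w_minus,
                 sigma = sigma),
            class = c("tophat_kernel", "radial_kernel"))
}

#' @rdname dog_kernel
#' @export
pwc_mexican_hat_kernel <- function(w_plus, w_minus, sigma1, sigma2) {
  if (!(w_plus > 0)) stop("pwc_mexican_hat_kernel: w_plus must be positive")
  if (!(w_minus < 0)) stop("pwc_mexican_hat_kernel: w_minus must be negative")
  if (!(sigma1 > 0 && sigma2 > sigma1))
    stop("pwc_mexican_hat_kernel: need 0 < sigma1 < sigma2")
  structure(list(family = "pwc_mexican_hat", w_plus = w_plus,
                 w_minus = w_minus, sigma1 = sigma1, sigma2 = sigma2),
            class = c("pwc_mexican_hat_kernel", "radial_kernel"))
}

#' @export
print.radial_kernel <- function(x, ...) {
  ps <- x[setdiff(names(x), "family")]
  cat("<radial_kernel: ", x$family, "> ",
      paste(names(ps), unlist(ps), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate a connectivity kernel
#'
#' `evaluate_w()` returns \eqn{w(r)}; `radial_derivative()` returns
#' \eqn{dw/dr}, used to assemble \eqn{w_x(|x-y|)} in one dimension and
#' \eqn{\nabla_x w} in two. For piece-wise constant kernels the derivative is
#' zero away from the jump radii and is refused exactly at a jump, where it
#' only exists as a distribution.
#'
#' @param kernel A `radial_kernel`.
#' @param r Non-negative radius (vectorised).
#' @return Numeric vector the length of `r`.
#' @export
evaluate_w <- function(kernel, r) {
  stopifnot(inherits(kernel, "radial_kernel"), is.numeric(r))
  if (any(r < 0)) stop("evaluate_w: r must be non-negative")
  UseMethod("evaluate_w")
}

#' @export
evaluate_w.dog_kernel <- function(kernel, r) {
  k <- kernel
  (k$a1 / sqrt(k$b1) * exp(-r^2 / k$b1) -
   k$a2 / sqrt(k$b2) * exp(-r^2 / k$b2)) / sqrt(k$c * pi)
}

#' @export
evaluate_w.tophat_kernel <- function(kernel, r) {
  ifelse(r <= kernel$sigma, kernel$w_plus, kernel$w_minus)
}

#' @export
evaluate_w.pwc_mexican_hat_kernel <- function(kernel, r) {
  out <- numeric(length(r))
  out[r <= kernel$sigma1] <- kernel$w_plus
  out[r > kernel$sigma1 & r <= kernel$sigma2] <- kernel$w_minus
  out
}

#' @rdname evaluate_w
#' @export
radial_derivative <- function(kernel, r) {
  stopifnot(inherits(kernel, "radial_kernel"), is.numeric(r))
  UseMethod("radial_derivative")
}

#' @export
radial_derivative.dog_kernel <- function(kernel, r) {
  k <- kernel
  (-2 * r) * (k$a1 / (k$b1 * sqrt(k$b1)) * exp(-r^2 / k$b1) -
              k$a2 / (k$b2 * sqrt(k$b2)) * exp(-r^2 / k$b2)) / sqrt(k$c * pi)
}

#' @export
radial_derivative.tophat_kernel <- function(kernel, r) {
  if (any(r == kernel$sigma))
    stop("radial_derivative: derivative does not exist at the jump radius")
  numeric(length(r))
}

#' @export
radial_derivative.pwc_mexican_hat_kernel <- function(kernel, r) {
  if (any(r == kernel$sigma1 | r == kernel$sigma2))
    stop("radial_derivative: derivative does not exist at a jump radius")
  numeric(length(r))
}

#' Ring potential and total mass of an integrable kernel
#'
#' The ring potential
#' \deqn{\varphi(r) = \frac{1}{r}\int_\infty^r x\,w(x)\,dx}
#' converts area integrals of \eqn{w} over the active region into contour
#' line integrals, and \eqn{\mathcal{K} = \int_{R^2} w} is the total mass
#' entering through the winding constant \eqn{C}. Both require \eqn{w} to be
#' integrable on the plane; the top-hat kernel is refused. For the difference
#' of Gaussians closed forms are used:
#' \eqn{\varphi(r) = [a_2\sqrt{b_2}e^{-r^2/b_2} - a_1\sqrt{b_1}e^{-r^2/b_1}]
#'  /(2r\sqrt{c\pi})} and
#' \eqn{\mathcal{K} = \sqrt{\pi/c}\,[a_1\sqrt{b_1} - a_2\sqrt{b_2}]}.
#'
#' \eqn{\varphi} has a \eqn{1/r} pole when \eqn{\mathcal{K}\neq 0}
#' (\eqn{r\varphi(r) \to -\mathcal{K}/2\pi} as \eqn{r \to 0^+}); it is only
#' exposed for `r > 0`, the contour quadratures never needing the origin.
#'
#' @inheritParams evaluate_w
#' @param r Positive radius (vectorised).
#' @return `ring_potential()`: \eqn{\varphi(r)}; `total_mass()`: a scalar.
#' @export
ring_potential <- function(kernel, r) {
  stopifnot(inherits(kernel, "radial_kernel"))
  UseMethod("ring_potential")
}

#' @export
ring_potential.dog_kernel <- function(kernel, r) {
  if (any(r <= 0)) stop("ring_potential: r must be positive")
  k <- kernel
  (k$a2 * sqrt(k$b2) * exp(-r^2 / k$b2) -
   k$a1 * sqrt(k$b1) * exp(-r^2 / k$b1)) / (2 * r * sqrt(k$c * pi))
}

#' @export
ring_potential.tophat_kernel <- function(kernel, r) {
  stop("ring_potential: top-hat kernel does not decay; phi is undefined")
}

#' @export
ring_potential.pwc_mexican_hat_kernel <- function(kernel, r) {
  if (any(r <= 0)) stop("ring_potential: r must be positive")
  k <- kernel
  # 1/r * int_inf^r x w(x) dx, integrated piece by piece inward
  inner <- function(ri) {
    if (ri >= k$sigma2) return(0)
    acc <- k$w_minus * (max(ri, k$sigma1)^2 - k$sigma2^2) / 2
    if (ri < k$sigma1) acc <- acc + k$w_plus * (ri^2 - k$sigma1^2) / 2
    acc / ri
  }
  vapply(r, inner, numeric(1))
}

#' @rdname ring_potential
#' @export
total_mass <- function(kernel) {
  stopifnot(inherits(kernel, "radial_kernel"))
  UseMethod("total_mass")
}

#' @export
total_mass.dog_kernel <- function(kernel) {
  k <- kernel
  sqrt(pi / k$c) * (k$a1 * sqrt(k$b1) - k$a2 * sqrt(k$b2))
}

#' @export
total_mass.tophat_kernel <- function(kernel) {
  stop("total_mass: divergent for the top-hat kernel")
}

#' @export
total_mass.pwc_mexican_hat_kernel <- function(kernel) {
  k <- kernel
  pi * (k$w_plus * k$sigma1^2 + k$w_minus * (k$sigma2^2 - k$sigma1^2))
}

# int_0^s x w(x) dx, the radial first moment; closed form per family.
# Feeds the triangle-fan decomposition used by psi_area().
radial_first_moment <- function(kernel, s) {
  UseMethod("radial_first_moment")
}

#' @export
radial_first_moment.dog_kernel <- function(kernel, s) {
  k <- kernel
  (k$a1 * sqrt(k$b1) * (1 - exp(-s^2 / k$b1)) -
   k$a2 * sqrt(k$b2) * (1 - exp(-s^2 / k$b2))) / (2 * sqrt(k$c * pi))
}

#' @export
radial_first_moment.tophat_kernel <- function(kernel, s) {
  k <- kernel
  ifelse(s <= k$sigma, k$w_plus * s^2 / 2,
         k$w_plus * k$sigma^2 / 2 + k$w_minus * (s^2 - k$sigma^2) / 2)
}

#' @export
radial_first_moment.pwc_mexican_hat_kernel <- function(kernel, s) {
  k <- kernel
  s1 <- pmin(s, k$sigma1)
  s2 <- pmax(pmin(s, k$sigma2), k$sigma1)
  k$w_plus * s1^2 / 2 + k$w_minus * (s2^2 - k$sigma1^2) / 2
}

is_integrable <- function(kernel) !inherits(kernel, "tophat_kernel")

# effective support radius used to size convolution padding and quadrature
kernel_support_radius <- function(kernel) {
  switch(kernel$family,
         dog = 4 * sqrt(max(kernel$b1, kernel$b2)),
         tophat = Inf,
         pwc_mexican_hat = kernel$sigma2)
}

#' Read and write kernel configuration blocks
#'
#' Kernels serialise to a small YAML block (`family` plus the family's
#' parameters) so that every command-line run is reproducible from its config
#' file alone.
#'
#' @param kernel A `radial_kernel`.
#' @param path File path.
#' @return `read_kernel_config()` returns a `radial_kernel`;
#'   `write_kernel_config()` returns `path` invisibly.
#' @export
write_kernel_config <- function(kernel, path) {
  stopifnot(inherits(kernel, "radial_kernel"))
  yaml::write_yaml(unclass(kernel), path)
  invisible(path)
}

#' @rdname write_kernel_config
#' @export
read_kernel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  kernel_from_list(cfg)
}

kernel_from_list <- function(cfg) {
  if (is.null(cfg$family)) stop("kernel config: missing 'family'")
  switch(cfg$family,
    dog = dog_kernel(cfg$a1, cfg$a2, cfg$b1, cfg$b2, cfg$c),
    tophat = tophat_kernel(cfg$w_plus, cfg$w_minus, cfg$sigma),
    pwc_mexican_hat = pwc_mexican_hat_kernel(cfg$w_plus, cfg$w_minus,
                                             cfg$sigma1, cfg$sigma2),
    stop("kernel config: unknown family ", cfg$family))
}
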