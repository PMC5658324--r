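---
title: "Interface dynamics for clamped neural fields: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface dynamics for clamped neural fields: models, numerics, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofield)
```

## The model

The package works in the "Heaviside world" of Amari-type neural fields: the
synaptic activity $u(\mathbf{x},t)$ on a one- or two-dimensional domain
$\Omega$ obeys

$$u_t = -u + \int_\Omega w(|\mathbf{x}-\mathbf{y}|)\,
  H[u(\mathbf{y},t)-\kappa]\,d\mathbf{y},$$

with a radial connectivity kernel $w$, firing threshold $\kappa$, and a
Heaviside firing rate. Because the firing rate is binary, a localized
solution is fully described by its *interface*: the level set
$\partial\Omega_+ = \{u = \kappa\}$ separating firing from quiescent
tissue. Differentiating the level-set condition yields the exact reduced
law $c_n = u_t/|\nabla u|$ for the outward normal velocity of the
interface, in which $u_t = -\kappa + \psi$ on the interface, with
$\psi(\mathbf{x}) = \int_{\Omega_+} w(|\mathbf{x}-\mathbf{y}|)\,d\mathbf{y}$
the drive of the active region.

A Dirichlet boundary condition $u|_{\partial\Omega} = u_\mathrm{BC}$ cannot
be imposed on the integro-differential equation directly (its Cauchy
problem needs no boundary data). The package follows the gradient
reformulation: evolve $z = \nabla u$,

$$z_t = -z + \nabla\psi, \qquad
  u(\mathbf{x}) = u_\mathrm{BC} + \int_{\Gamma(\mathbf{x})} z\cdot
  d\mathbf{y},$$

so the clamp enters through the path anchor of the line-integral
reconstruction. The interface law acquires a boundary correction,
$c_n = [\,u_\mathrm{BC} - \kappa + \psi(\mathbf{x}) -
\psi(\zeta(\mathbf{x}))\,]/|z|$, with $\zeta$ a map from interface points
to $\partial\Omega$.

Everything the contour engine needs is expressible as line integrals over
$\partial\Omega_+$:

* the drive $\psi$ via a kernel potential (below),
* its gradient $\nabla\psi = -\oint n(s)\,w(|\mathbf{x}-\gamma(s)|)\,ds$,
* and $z$ itself via variation of parameters as a memory integral
  $z(\mathbf{x},t) = e^{-t}z_0(\mathbf{x}) +
  \int_0^t e^{-(t-s)}\nabla\psi(\mathbf{x},s)\,ds$
  over stored past contours.

## Kernels and their derived quantities

Three families are provided. The difference of Gaussians
$w(r) = [a_1/\sqrt{b_1}\,e^{-r^2/b_1} - a_2/\sqrt{b_2}\,e^{-r^2/b_2}]
/\sqrt{c\pi}$ is the smooth Mexican hat used in the worked studies; its
total mass is $\mathcal{K} = \sqrt{\pi/c}(a_1\sqrt{b_1}-a_2\sqrt{b_2})$
and its ring potential
$\varphi(r) = [a_2\sqrt{b_2}e^{-r^2/b_2}-a_1\sqrt{b_1}e^{-r^2/b_1}]/
(2r\sqrt{c\pi})$ is closed-form. The parameter $c$ is a pure
normalization; it is kept exactly as supplied and never rescaled. The
top-hat and piece-wise constant Mexican hat make the geometry
quasi-analytic (disc-overlap areas); the top-hat does not decay, so its
plane integrals ($\mathcal{K}$, $\varphi$) are refused rather than
regularized, and its drives are computed from overlap areas instead.

Piece-wise constant kernels are evaluated with closed excitatory
intervals ($r \le \sigma$ fires at $w_+$), and their radial derivative is
refused exactly at a jump radius, where it exists only as a distribution.

## Numerical design of the contour quadratures

**Drive.** The textbook reduction writes
$\psi = \oint\varphi(r)\,\hat r\cdot n\,ds + \mathcal{K}C$ with
$C \in \{1, \tfrac12, 0\}$ for interior/on-contour/exterior evaluation.
`psi_line()` instead uses the algebraically identical *regular-part* form
built on $f(r) = \frac1r\int_0^r \sigma w(\sigma)\,d\sigma$ (so
$\varphi = f - \mathcal{K}/2\pi r$): the integrand
$f(r)\,\hat r\cdot n$ is bounded, vanishes at the evaluation point, and
carries the winding constant implicitly — on-contour points return the
principal value corresponding to $C = \tfrac12$. This removes the pole,
the self-term limit, and — importantly — the dominant quadrature error:
with the ring-potential form the periodic trapezoid commits an $O(h^2)$
error on the winding part that shows up as a systematic interior bias
(measured at $1.5\times10^{-5}$ for 512 vertices on a star-shaped
contour), while the regular-part form is uniformly accurate.

**Geometry.** Tangents, normals, arc-length weights and signed curvature
at the vertices come from periodic cubic splines in the vertex index.
Spline derivatives make the vertex sums fourth-order accurate with respect
to the smooth contour through the vertices (half-chord differences are
only second-order where $|\gamma'|$ varies, which is visibly insufficient
on rippled contours). With this geometry, `psi_line()` on a
2048-vertex circle matches the stationary-spot threshold to $10^{-13}$,
and agrees with the independent area quadrature `psi_area()` to
$10^{-7}$ at 512 vertices on circles, ellipses and stars.

**Oracle.** `psi_area()` evaluates $\int_{\Omega_+} w$ directly by fanning
the polygon into signed triangles from the evaluation point; each directed
edge contributes $\int_0^1 F(|y(t)-x|)\,
\frac{(y(t)-x)\times(B-A)}{|y(t)-x|^2}dt$ with
$F(s)=\int_0^s \sigma w\,d\sigma$ closed-form, integrated adaptively. It
is valid for any simple polygon and any kernel family, serves as the
production path for piece-wise constant kernels, and is deliberately kept
free of the line-integral identity so the two routes are independent.

**Memory integral.** `z_from_history()` treats $\nabla\psi(s)$ as
piece-wise linear between stored snapshots and integrates the exponential
weight exactly on each interval (product integration). A frozen history
then reproduces the geometric-series limit $z \to \nabla\psi$ to machine
precision, which a plain trapezoid cannot (its $O(\Delta t^2)$ weight
error floors near $10^{-5}$). The quadrature may subsample the stored
history (`quad_dt`, default five evolution steps): the induced
$O(\mathrm{quad\_dt}^2)$ error is far below the grid tolerance of the
field comparisons while cutting the dominant cost of long contour runs.

**Stepping.** Vertices advance by explicit Euler along their outward
normals with $dt \le 0.01$; the vertex spacing is kept within a factor of
two of its initial value by uniform arc-length resampling, with the vertex
count adapted to the growing perimeter. Self-intersection after a step is
a topology-change event and halts the contour engine (contour surgery for
merging labyrinth branches is out of scope; long labyrinth runs belong to
the field simulator). The boundary map $\zeta$ is the radial projection on
a disc, and the nearest boundary point on a rectangle with ties broken
toward the left edge, consistent with the 1D anchoring at $x = -L$.

## Steady states and spectra

**1D bumps.** A symmetric bump of width $\Delta$ on $[-L, L]$ satisfies
$\kappa = \int_0^\Delta w$ (free) or
$\kappa = u_\mathrm{BC} + \mathcal{P}(-\Delta/2) - \mathcal{P}(-L)$
(clamped), with $\mathcal{P}$ the error-function drive of the active
interval. Roots are found by a 2000-point sign-change scan plus bisection
to $10^{-12}$, duplicates merged at $10^{-8}$. Linear stability reduces to
a $2\times2$ matrix coupling the two edges; the eigenvalue pair follows
from its trace and determinant.

One eigenvalue is *always* neutral. Free bumps owe it to translation
invariance. Under the clamp the algebra still gives
$\det[\mathcal{A}-I] \equiv 0$, and the reason is structural: the drive at
either edge depends only on the width, so the two stationarity conditions
collapse to one scalar equation and the steady bumps form a one-parameter
family of laterally displaced (generally asymmetric) states. The package
therefore reports the neutral eigenvalue separately and classifies
stability by the sign of the non-neutral (width) mode; direct simulation
confirms the neutral family — a laterally shifted clamped bump stays
shifted while its width relaxes.

**Spots.** A circularly symmetric spot of radius $R$ satisfies
$\kappa = \psi(R)$ on the plane and
$\kappa = u_\mathrm{BC} + \psi(R) - \psi(D)$ on a clamped disc of radius
$D$. For the difference of Gaussians, $\psi$ uses the angular reduction of
the area integral; its $1/\mathcal{Q}^2$ integrand is a removable artifact
on the contour (handled by midpoint nodes) but becomes unresolvable by
fixed nodes in a thin band $0 < |r-R| \lesssim 0.1R$, where the code falls
back to nested adaptive quadrature of the defining area integral. That
fallback is what makes the numerical slope $q'(R)$ — obtained from a
4-point central stencil with step $10^{-3}R$ that excludes the centre
node — an honest, non-circular input to the azimuthal spectrum

$$\lambda_m = -1 + \frac{R}{|q'(R)|}\Big[I_m(R) - I_m(D)\Big], \qquad
I_m(r) = \oint \cos(m\theta)\,w\big(|\mathbf{r}-\mathbf{r}'|\big)
\big|_{r'=R}\,d\theta,$$

(the $I_m(D)$ term only on a disc): on the plane $\lambda_1 = 0$ is a
theorem (translation symmetry), and the package recovers it to
$5\times10^{-10}$ from two numerically independent quantities. The m = 0
top-hat coupling integral keeps the $2\pi w_-$ background term so that the
closed form agrees with direct quadrature for every mode; the background
cancels in disc-spectrum differences anyway. Stability on a disc includes
$m = 1$ (the clamp breaks translation symmetry); only plane branches
exempt it. For branches far from the disc boundary the computed
$\lambda_1$ sits at numerical zero, so their `stable` flag is reported at
the tolerance $10^{-10}$ and should be read together with the eigenvalues
themselves.

## Field simulators (the ground truth)

The 2D reference solvers use exponential Euler in time (the linear decay
integrated exactly) and FFT convolutions zero-padded past the kernel's
effective support (four Gaussian standard widths, or $\sigma_2$), so
wrap-around lies below the kernel's own truncation. The Heaviside is
evaluated pointwise with the midpoint convention $H(0) = \tfrac12$. In the
gradient formulation the two components of $\nabla w * H$ are convolved
separately and $u$ is rebuilt each step by cumulative trapezoid from the
clamped boundary — row-wise from the left edge (for a disc, from the left
intersection of each row with the circle), the 1D-consistent path family;
a radial path family is available for cross-checking path independence.
The reconstruction pins $u = u_\mathrm{BC}$ exactly at the path anchors
only; the residual $\max|u - u_\mathrm{BC}|$ over the rest of the boundary
is reported as a diagnostic rather than silently forced (it stays at the
$10^{-5}$ level in the clamped runs of the test suite while activity is
away from the walls).

The 1D solver exploits the Heaviside structure more aggressively: the
active set is a union of intervals whose endpoints are located by local
cubic interpolation of the threshold crossings, the drive is then
closed-form in those endpoints, and the cumulative reconstruction carries
an Euler–Maclaurin endpoint correction. A generic pointwise quadrature
(`scheme = "matrix"`) is retained for arbitrary initial data, but it is
only $O(h)$ accurate at the interface — about $10^{-2}$ drift for a
constructed steady bump at $n = 1025$ — whereas the interface-aware scheme
holds the same state to $10^{-8}$, which is what makes the $10^{-6}$
stationarity checks meaningful.

## What the synthetic seeds emulate

`make_perturbed_spot()` builds the standard initial condition of the
azimuthal-instability experiments: a rim $r(\theta) = R(1 + \epsilon\cos
m\theta)$ returned both as an exact polar contour and as a smoothed
indicator field $u_0 = \kappa + A\tanh[(r(\theta)-|\mathbf{x}|)/\ell]$
whose $\kappa$-level set is exactly that rim and whose gradient is
closed-form. With the default $A = \kappa$ the far field decays to zero,
matching a homogeneous clamp. Defaults $\ell = 0.3$ space units (a few
grid cells at the working resolutions) and $\epsilon \ll 1$ keep the seed
within the linear regime of the spot spectra. These seeds emulate the
*geometry* of localized cortical activity, not its physiology: there is no
noise, no heterogeneity, no adaptation, and the smooth profile is an
idealization of whatever transient created the spot. Passing tests
therefore validate the interface reduction against the full model under
identical idealized conditions — they do not certify behaviour on real
recordings.

## Problem sizes and test protocol

The cross-validation suite runs on deliberately scaled-down versions of
the big simulations: free-plane labyrinth onset at $\kappa = 0.03$ on
$[-4\pi, 4\pi]^2$ with a $128^2$ grid and a clamped run at $\kappa = 0.05$
on $[-2.5\pi, 2.5\pi]^2$, both to $T = 3$, where the interface engine and
the field solvers agree to a fraction of $2h$ in Hausdorff distance. The
full-size labyrinth ($L = 12\pi$) is qualitatively reproducible with the
same functions but its final shape is sensitive to the seed and is not a
quantitative target. Azimuthal-mode growth is probed at $\kappa = 0.11$,
where both plane branches carry eigenvalues of order $0.2$–$1$: slow modes
(the $|\lambda| \sim 0.03$ values at $\kappa = 0.05$) are unobservable in
a Heaviside field simulation at feasible resolution because the interface
only moves when the firing pattern changes on grid nodes — sub-grid mode
amplitudes pin. Perturbation amplitudes ($\epsilon = 0.1$–$0.15$) are
chosen to clear that pinning scale while staying linear. Stationarity of
unstable branches is checked over horizons scaled to the inverse growth
rate, since a $10^{-13}$ root residual amplified by $e^{\lambda T}$
swamps any fixed point long before $T = 10$ when $\lambda \approx 10$.

## Known limitations

* Contour-only evolution stops at topology changes; labyrinth growth past
  a merge is delegated to the field simulator.
* The Dirichlet clamp is enforced exactly only at the path anchors of the
  line-integral reconstruction; elsewhere on the boundary it is monitored,
  not imposed.
* Smooth (sigmoidal) firing rates, adaptation currents, feature-space and
  curved-cortex models, and space- or time-dependent boundary data are out
  of scope.
* The top-hat kernel has no plane-integrable potential; interface drives
  for it go through `psi_area()`, which is slower than the line integral.
* Disc-domain simulations embed the disc in a square grid with a firing
  mask; boundary effects are resolved only to grid accuracy.
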