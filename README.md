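# neurofield

Interface dynamics for Amari-type neural fields on bounded domains with
Dirichlet boundary conditions.

Continuum neural field models describe coarse-grained cortical activity
u(x, t) through a nonlocal integro-differential equation,

    u_t = -u + ∫_Ω w(|x - y|) H[u(y, t) - κ] dy,

with a radially symmetric synaptic kernel w (short-range excitation,
longer-range inhibition), a Heaviside firing rate H and a firing threshold
κ. Because the firing rate is binary, the entire dynamics is carried by the
interface ∂Ω₊ between firing (u > κ) and quiescent tissue: the interface
moves with normal velocity

    c_n = (-κ + ψ(x, t)) / |z(x, t)|,     ψ(x, t) = ∫_{Ω₊} w(|x - y|) dy,

where z = ∇u. Clamping the activity on the domain boundary to a prescribed
value u_BC (a Dirichlet condition, expressed through the gradient field z
and a line-integral reconstruction u(x) = u_BC + ∫_Γ z · dy) adds a boundary
correction to the velocity rule:

    c_n = (u_BC - κ + ψ(x, t) - ψ(ζ(x), t)) / |z(x, t)|,

with ζ mapping contour points to the domain boundary. The package
implements this reduced-but-exact description — contour evolution driven
purely by line integrals of a kernel potential, with the gradient obtained
from a memory convolution over past interface shapes — together with the
machinery around it:

* **kernels** — difference-of-Gaussians ("Mexican hat"), top-hat and
  piece-wise constant Mexican hat connectivities, their ring potentials and
  total mass (`dog_kernel()`, `ring_potential()`, `total_mass()`);
* **1D bumps** — steady bump branches on an interval with or without a
  Dirichlet clamp, their interface (Evans-function) spectra, edge-based
  interface evolution and a full 1D field solver
  (`solve_bump_widths()`, `bump_spectrum()`, `evolve_interface_1d()`,
  `simulate_field_1d()`);
* **2D interface engine** — contour geometry, line-integral drive
  `psi_line()` and its area-quadrature oracle `psi_area()`, normal-velocity
  rules for the free plane and clamped domains, contour stepping with
  resampling and topology-change detection (`evolve_contour()`);
* **spots** — circularly symmetric solutions on the plane and on a clamped
  disc, disc-overlap geometry for piece-wise constant kernels, and azimuthal
  (Evans-function) stability `λ_m` of cos(mθ) perturbations
  (`solve_spot_radius()`, `A_plus()`, `spot_spectrum()`);
* **full-field reference simulators** — spectral (FFT) solvers for the
  classical model and its gradient reformulation, used throughout the test
  suite as ground truth for the interface engine (`simulate_amari_2d()`,
  `simulate_gradient_2d()`, `extract_contours()`).

## Worked example

Bump branches on `[-10π, 10π]` with the kernel
`w(x) = [a₁/√b₁ e^{-x²/b₁} - a₂/√b₂ e^{-x²/b₂}]/√(cπ)`,
a₁ = 14, a₂ = 13, b₁ = 24, b₂ = 150, c = 5:

```r
library(neurofield)
wk <- dog_kernel(a1 = 14, a2 = 13, b1 = 24, b2 = 150, c = 5)

br <- solve_bump_widths(wk, kappa = 0.7, L = 10 * pi,
                        bc_mode = "dirichlet", u_BC = 0)
for (b in br) print(b)
#> <bump_branch> Delta=1.63006 kappa=0.7 bc=dirichlet stable=FALSE lambda=(10.8+0i,  0.0+0i)
#> <bump_branch> Delta=12.1402 kappa=0.7 bc=dirichlet stable=TRUE lambda=(-4.441e-16+0i, -3.509e-01+0i)
#> <bump_branch> Delta=38.7504 kappa=0.7 bc=dirichlet stable=FALSE lambda=(2.209e-01+0i, 8.882e-16+0i)
#> <bump_branch> Delta=59.5685 kappa=0.7 bc=dirichlet stable=TRUE lambda=(-2.220e-16+0i, -8.433e-01+0i)
```

Four bumps coexist under the Dirichlet clamp (the free interval supports
only two); the boundary induces wide stable states whose active region
fills a large part of the domain. Each branch carries the eigenvalue pair
of the 2×2 interface matrix: one eigenvalue is always the neutral zero mode
of the laterally-displaced family of steady bumps, the other decides
stability.

Spots on the free plane with the 2D kernel (a₁ = 3.55, a₂ = 3, b₁ = 2.4,
b₂ = 3.2, c = 10) at κ = 0.05:

```r
wk2 <- dog_kernel(3.55, 3, 2.4, 3.2, 10)
sp <- solve_spot_radius(wk2, kappa = 0.05, domain = "plane")
print(sp[[2]])
#> <spot_branch> R=6.80842 kappa=0.05 domain=plane stable=FALSE
#>   lambda: m0=-0.0109 m1=4.85e-10 m2=0.0294 m3=0.0682 m4=0.104 m5=0.123 m6=0.116 m7=0.0761 m8=0.00444
```

The wide spot's translation mode λ₁ vanishes (rotational/translational
symmetry), while modes m = 2..8 are unstable — the azimuthal instability
that seeds labyrinthine patterns. Evolving a perturbed spot with
`evolve_contour()` and comparing against `simulate_amari_2d()` reproduces
this growth with the two routes agreeing to a fraction of a grid cell (see
`tests/testthat/test-acceptance.R`).

A thin command-line front end is provided at `inst/cli/neurofield`
(subcommands `branch1d`, `simulate1d`, `simulate2d`, `interface2d`,
`spots`, each taking `--config`/`--out`); it writes CSV tables, contour
files and a resolved-config echo so every run is reproducible from its
config alone.

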