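#' Perturbed-spot initial condition
#'
#' Standard seed for azimuthal-instability and pattern-growth experiments:
#' a spot of radius `R` whose rim is modulated as
#' \eqn{r(\theta) = R(1 + \epsilon\cos m\theta)}, returned both as an
#' exact polar contour and as a smoothed-indicator activity field
#' \deqn{u_0(x) = \kappa + A\,\tanh\!\big[(r(\theta) - |x|)/\ell\big],}
#' whose \eqn{\kappa}-level set is exactly the perturbed rim and whose
#' gradient is available in closed form (the `z0` evaluator for the
#' gradient formulation and the interface memory term). With the default
#' `amplitude = kappa` the field decays to \eqn{u_0 \to 0} far from the
#' spot, matching a homogeneous Dirichlet clamp.
#'
#' @param R Unperturbed radius.
#' @param m Azimuthal mode (non-negative integer).
#' @param eps Relative rim perturbation, `abs(eps) < 1`.
#' @param kappa Firing threshold the seed is built around.
#' @param amplitude Half-range `A` of the tanh profile.
#' @param width Interface smoothing length \eqn{\ell}.
#' @param n_vertices Contour resolution.
#' @return List with `contour` (`nf_contour`), `u0` (`function(X)`),
#'   `z0` (`function(X) -> m x 2`), `area` (exact enclosed area
#'   \eqn{\pi R^2(1 + \epsilon^2/2)}), and the parameters.
#' @export
make_perturbed_spot <- function(R, m = 0L, eps = 0, kappa = 0.05,
                                amplitude = kappa, width = 0.3,
                                n_vertices = 256L) {
  stopifnot(R > 0, m >= 0, m == round(m), width > 0)
  if (abs(eps) >= 1) stop("make_perturbed_spot: need |eps| < 1")
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  rad <- R * (1 + eps * cos(m * th))
  contour <- nf_contour(cbind(rad * cos(th), rad * sin(th)))
  u0 <- function(X) {
    X <- if (is.matrix(X)) X else matrix(X, ncol = 2L)
    r <- sqrt(rowSums(X^2))
    theta <- atan2(X[, 2], X[, 1])
    d <- R * (1 + eps * cos(m * theta)) - r
    kappa + amplitude * tanh(d / width)
  }
  z0 <- function(X) {
    X <- if (is.matrix(X)) X else matrix(X, ncol = 2L)
    r <- sqrt(rowSums(X^2))
    theta <- atan2(X[, 2], X[, 1])
    d <- R * (1 + eps * cos(m * theta)) - r
    pref <- amplitude / width / cosh(d / width)^2
    safe <- r > 1e-9
    rx <- ifelse(safe, X[, 1] / r, 0)
    ry <- ifelse(safe, X[, 2] / r, 0)
    thx <- ifelse(safe, -X[, 2] / r^2, 0)
    thy <- ifelse(safe, X[, 1] / r^2, 0)
    gdx <- -R * eps * m * sin(m * theta) * thx - rx
    gdy <- -R * eps * m * sin(m * theta) * thy - ry
    cbind(pref * gdx, pref * gdy)
  }
  list(contour = contour, u0 = u0, z0 = z0,
       area = pi * R^2 * (1 + eps^2 / 2),
       R = R, m = m, eps = eps, kappa = kappa,
       amplitude = amplitude, width = width)
}

#' Run a configured experiment
#'
#' Dispatches a named experiment to the owning module and writes its
#' outputs (CSV tables, contour CSVs, a per-step diagnostics log and a
#' summary) under `out_dir`, together with an echo of the fully resolved
#' configuration so the run is reproducible from that file alone.
#'
#' Experiments and their blocks:
#' \describe{
#'   \item{`branch1d`}{`kappa_min/max/step`, `L`, `bc_mode`, `u_BC` ->
#'     `branches.csv` (one row per branch: kappa, Delta, eigenvalues,
#'     stability).}
#'   \item{`spots`}{`kappa_min/max/step`, `domain` (`"plane"` or disc
#'     radius `D`), `u_BC`, `m_max` -> `branches.csv` with radius and
#'     `lambda_0..lambda_m_max` columns.}
#'   \item{`simulate1d`}{1D field run seeded with a Gaussian bump
#'     (`bump: amplitude, width, center`) -> `field.csv` (final `u`, `z`)
#'     and `edges.csv` (threshold crossings per snapshot).}
#'   \item{`simulate2d`}{full-field 2D run (classical or gradient mode)
#'     -> final-state `u.csv` and `contours.csv`.}
#'   \item{`interface2d`}{contour-only evolution -> `contours.csv`
#'     (initial and final) and `diagnostics.csv` (area, length,
#'     max speed per step).}
#' }
#'
#' @param config A list, or path to a YAML file, with top-level fields
#'   `experiment`, `kernel`, experiment-specific blocks, and optional
#'   `seed`.
#' @param out_dir Output directory (created if missing).
#' @param verbose Print per-step progress.
#' @return The summary list, invisibly; side effect: files in `out_dir`.
#' @export
run_experiment <- function(config, out_dir, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$experiment))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  kernel <- kernel_from_list(config$kernel)
  summary <- switch(config$experiment,
    branch1d = run_branch1d(config, kernel, out_dir),
    spots = run_spots(config, kernel, out_dir),
    simulate1d = run_simulate1d(config, kernel, out_dir),
    simulate2d = run_simulate2d(config, kernel, out_dir, verbose),
    interface2d = run_interface2d(config, kernel, out_dir, verbose),
    stop("run_experiment: unknown experiment '", config$experiment, "'"))
  yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  invisible(summary)
}

run_branch1d <- function(cfg, kernel, out_dir) {
  kaps <- seq(cfg$kappa_min, cfg$kappa_max, by = cfg$kappa_step)
  bc <- if (is.null(cfg$bc_mode)) "none" else cfg$bc_mode
  uBC <- if (is.null(cfg$u_BC)) 0 else cfg$u_BC
  rows <- do.call(rbind, lapply(kaps, function(k) {
    brs <- solve_bump_widths(kernel, k, cfg$L, bc_mode = bc, u_BC = uBC)
    if (!length(brs)) return(NULL)
    do.call(rbind, lapply(brs, function(b)
      data.frame(kappa = k, Delta = b$Delta,
                 re_lambda_1 = Re(b$lambda[1]), re_lambda_2 = Re(b$lambda[2]),
                 lambda_width = Re(b$lambda_width), stable = b$stable)))
  }))
  utils::write.csv(rows, file.path(out_dir, "branches.csv"), row.names = FALSE)
  list(experiment = "branch1d", n_rows = nrow(rows),
       max_coexisting = max(table(rows$kappa)))
}

run_spots <- function(cfg, kernel, out_dir) {
  kaps <- seq(cfg$kappa_min, cfg$kappa_max, by = cfg$kappa_step)
  dom <- if (identical(cfg$domain, "plane")) "plane" else disc_domain(cfg$domain$D)
  m_max <- if (is.null(cfg$m_max)) 8L else cfg$m_max
  uBC <- if (is.null(cfg$u_BC)) 0 else cfg$u_BC
  tab <- spot_branch_scan(kernel, kaps, domain = dom, u_BC = uBC, m_max = m_max)
  utils::write.csv(tab, file.path(out_dir, "branches.csv"), row.names = FALSE)
  list(experiment = "spots", n_rows = if (is.null(tab)) 0L else nrow(tab),
       n_stable = if (is.null(tab)) 0L else sum(tab$stable))
}

run_simulate1d <- function(cfg, kernel, out_dir) {
  grid <- seq(-cfg$L, cfg$L, length.out = cfg$n)
  # initial bump: Gaussian profile of the configured amplitude and width
  b <- cfg$bump
  u0 <- b$amplitude * exp(-((grid - (b$center %||% 0)) / b$width)^2)
  sim <- simulate_field_1d(u0, kernel, cfg$kappa, u_BC = cfg$u_BC %||% 0,
                           grid = grid, bc_mode = cfg$bc_mode %||% "dirichlet",
                           T_final = cfg$T %||% 10, dt = cfg$dt %||% 0.01)
  last <- nrow(sim$u)
  utils::write.csv(data.frame(x = grid, u = sim$u[last, ],
                              z = if (is.null(sim$z)) NA else sim$z[last, ]),
                   file.path(out_dir, "field.csv"), row.names = FALSE)
  edges <- do.call(rbind, lapply(seq_along(sim$t), function(i) {
    xc <- level_crossings_1d(sim$u[i, ], grid, cfg$kappa)
    if (!length(xc)) return(NULL)
    data.frame(t = sim$t[i], crossing = xc)
  }))
  utils::write.csv(edges, file.path(out_dir, "edges.csv"), row.names = FALSE)
  list(experiment = "simulate1d", n_snapshots = length(sim$t))
}

run_simulate2d <- function(cfg, kernel, out_dir, verbose) {
  grid <- grid2d(cfg$L, cfg$n)
  seed <- make_perturbed_spot(cfg$spot$R, cfg$spot$m %||% 0L,
                              cfg$spot$eps %||% 0, kappa = cfg$kappa)
  T_final <- cfg$T %||% 5
  if (identical(cfg$mode, "gradient")) {
    sim <- simulate_gradient_2d(seed$z0, kernel, cfg$kappa,
                                u_BC = cfg$u_BC %||% 0, grid = grid,
                                T_final = T_final, dt = cfg$dt %||% 0.01)
  } else {
    sim <- simulate_amari_2d(seed$u0, kernel, cfg$kappa, grid,
                             T_final = T_final, dt = cfg$dt %||% 0.01)
  }
  u_last <- sim$u[[length(sim$u)]]
  utils::write.csv(as.data.frame(u_last), file.path(out_dir, "u.csv"),
                   row.names = FALSE)
  cts <- extract_contours(u_last, grid, cfg$kappa)
  if (length(cts)) write_contours_csv(cts, file.path(out_dir, "contours.csv"))
  area <- sum(u_last > cfg$kappa) * grid$h^2
  if (verbose) message("simulate2d: final active area ", signif(area, 4))
  list(experiment = "simulate2d", T = T_final, active_area = area,
       n_contours = length(cts))
}

run_interface2d <- function(cfg, kernel, out_dir, verbose) {
  seed <- make_perturbed_spot(cfg$spot$R, cfg$spot$m %||% 0L,
                              cfg$spot$eps %||% 0, kappa = cfg$kappa,
                              n_vertices = cfg$n_vertices %||% 128L)
  domain <- if (!is.null(cfg$domain)) {
    if (identical(cfg$domain$shape, "disc"))
      domain_spec("disc", D = cfg$domain$D, bc_mode = "dirichlet",
                  u_BC = cfg$u_BC %||% 0)
    else domain_spec("rectangle", L = cfg$domain$L, bc_mode = "dirichlet",
                     u_BC = cfg$u_BC %||% 0)
  } else NULL
  run <- evolve_contour(seed$contour, seed$z0, kernel, cfg$kappa,
                        T_final = cfg$T %||% 3, dt = cfg$dt %||% 0.01,
                        domain = domain)
  write_contours_csv(list(seed$contour, run$contour),
                     file.path(out_dir, "contours.csv"))
  utils::write.csv(run$diagnostics, file.path(out_dir, "diagnostics.csv"),
                   row.names = FALSE)
  if (verbose) message("interface2d: final area ",
                       signif(polygon_area(run$contour), 4))
  list(experiment = "interface2d",
       final_area = polygon_area(run$contour),
       final_max_speed = run$diagnostics$max_speed[nrow(run$diagnostics)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
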