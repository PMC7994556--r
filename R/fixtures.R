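#' Analytic plane-Poiseuille fixture case
#'
#' A straight channel (`S = 0`) carries a closed-form solution: with the line
#' flux `q` chosen so the wall shear rate equals `gamma0`, the velocity is
#' `u(y) = (6 q / w^3) y (w - y)` and the wall shear is exactly `gamma0`.
#' The attached closed form is the oracle for solver verification.
#'
#' @param Y0 channel width (um).
#' @param gamma0 wall shear rate (1/s).
#' @param fluid a [fluid_model()].
#' @return An object of class `fixture_case` with the geometry, fluid,
#'   operating point and a `closed_form` list (`u(y)`, `wall_shear`, `q`).
#' @export
make_poiseuille_case <- function(Y0 = 100, gamma0 = 1000, fluid = blood_newtonian()) {
  if (Y0 <= 0 || gamma0 <= 0) stop("'Y0' and 'gamma0' must be positive")
  geom <- stenosis_geometry(S = 0, alpha = 85, Y0 = Y0, X0 = 2 * Y0,
                            run_in = Y0, run_out = Y0)
  w <- Y0 * 1e-6
  q <- gamma0 * w^2 / 6
  closed_form <- list(
    q = q,
    u = function(y) 6 * q / w^3 * y * (w - y),
    wall_shear = gamma0
  )
  structure(list(label = sprintf("poiseuille Y0=%g gamma0=%g", Y0, gamma0),
                 geom = geom, fluid = fluid, gamma0 = gamma0,
                 closed_form = closed_form),
            class = "fixture_case")
}

#' Reproducible randomized geometry suite
#'
#' Draws valid stenosis geometries over the study envelope
#' (`S` in `[0, 0.95]`, `alpha` in `[30, 85]` degrees, both placements) for
#' property testing of the geometry invariants.
#'
#' @param n number of draws.
#' @param seed RNG seed; identical seeds give identical suites.
#' @return List of [stenosis_geometry()] objects.
#' @export
random_geometry_suite <- function(n, seed = 1) {
  if (n <= 0) stop("'n' must be positive")
  had_seed <- exists(".Random.seed", envir = globalenv())
  if (had_seed) saved <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (had_seed) assign(".Random.seed", saved, envir = globalenv()))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    S <- stats::runif(1, 0, 0.95)
    alpha <- stats::runif(1, 30, 85)
    placement <- sample(c("eccentric", "concentric"), 1)
    out[[k]] <- stenosis_geometry(S = S, alpha = alpha, placement = placement)
  }
  out
}

#' Grid-convergence (mesh-sensitivity) study
#'
#' Solves a case on a sequence of systematically refined grids (refinement
#' ratio 2), extracts a scalar observable, and reports the observed order of
#' accuracy `p = log((f1 - f2)/(f2 - f3)) / log 2` together with the
#' Richardson-extrapolated value and grid-convergence indices (GCI, with
#' safety factor 1.25). For a fixture with a closed form the observable is
#' the mean bottom-wall shear rate; for a stenosis case it is the peak shear
#' rate along the platelet trajectory.
#'
#' @param case a [make_poiseuille_case()] fixture, or `NULL` to use the
#'   default stenosis case (S = 0.8, alpha = 85 deg, eccentric, Newtonian
#'   blood at `gamma0` = 1000 1/s).
#' @param levels number of grid levels (>= 3).
#' @param base_grid `c(nx, ny)` of the coarsest level.
#' @param gamma0 bulk shear rate for the default case.
#' @return An object of class `convergence_report`.
#' @export
mesh_sensitivity <- function(case = NULL, levels = 3, base_grid = c(128, 32),
                             gamma0 = 1000) {
  if (levels < 3) stop("'levels' must be at least 3")
  default_case <- is.null(case)
  if (default_case) {
    geom <- stenosis_geometry(S = 0.8, alpha = 85)
    fluid <- blood_newtonian()
  } else {
    stopifnot(inherits(case, "fixture_case"))
    geom <- case$geom; fluid <- case$fluid; gamma0 <- case$gamma0
  }
  nxs <- base_grid[1] * 2^(0:(levels - 1))
  nys <- base_grid[2] * 2^(0:(levels - 1))
  f <- numeric(levels)
  for (k in seq_len(levels)) {
    if (default_case) {
      gr <- generate_grid(geom, nxs[k], nys[k])
      fl <- solve_flow(geom, fluid, gamma0, gr)
      map <- shear_rate_field(fl)
      pr <- platelet_trajectory_profile(fl, map)
      f[k] <- pr$gamma_max
    } else {
      gr <- generate_grid(geom, nxs[k], nys[k], cluster = 0, eta_cluster = 0)
      fl <- solve_flow(geom, fluid, gamma0, gr)
      # peak velocity: the wall shear of this discretization is nodally exact
      # for the parabolic oracle (no signal for an order estimate), while the
      # centerline velocity carries a clean second-order truncation error
      f[k] <- max(abs(fl$u))
    }
  }
  d <- diff(f)                       # f2-f1, f3-f2, ...
  n_last <- length(d)
  monotone <- all(d > 0) || all(d < 0)
  shrinking <- all(abs(d[-1]) < abs(d[-n_last]))
  p_obs <- if (monotone && n_last >= 2) {
    log(abs(d[n_last - 1] / d[n_last])) / log(2)
  } else NA_real_
  f_exact <- if (is.finite(p_obs) && p_obs > 0) {
    f[levels] + d[n_last] / (2^p_obs - 1) * 1  # Richardson, next-step limit
  } else NA_real_
  gci <- if (is.finite(p_obs) && p_obs > 0) {
    1.25 * abs(d[n_last] / f[levels]) / (2^p_obs - 1)
  } else NA_real_
  structure(list(
    nx = nxs, ny = nys, observable = f,
    refinement_ratio = 2,
    monotone = monotone, shrinking_differences = shrinking,
    asymptotic = monotone && shrinking && is.finite(p_obs),
    observed_order = p_obs,
    richardson = f_exact, gci = gci,
    case = if (default_case) "default stenosis (S=0.8, alpha=85, eccentric)"
           else case$label
  ), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report> ", x$case, "\n", sep = "")
  for (k in seq_along(x$nx))
    cat(sprintf("  %4d x %-4d  f = %.6g\n", x$nx[k], x$ny[k], x$observable[k]))
  if (is.finite(x$observed_order)) {
    cat(sprintf("  observed order %.2f, Richardson %.6g, GCI %.3g\n",
                x$observed_order, x$richardson, x$gci))
  } else {
    cat("  non-asymptotic sequence (order not estimated)\n")
  }
  invisible(x)
}

#' Verification report
#'
#' Runs the built-in verification battery: the Poiseuille oracle (velocity,
#' wall shear, mass conservation), the randomized geometry suite, and a
#' grid-convergence study on the Poiseuille fixture. Returns a list that can
#' be serialized to JSON, and optionally writes plain-text and JSON reports.
#'
#' @param outdir optional output directory for `verification.txt` /
#'   `verification.json`.
#' @param n_random size of the randomized geometry suite.
#' @param seed seed for the randomized suite.
#' @return Invisibly, the named list of check results.
#' @export
verification_report <- function(outdir = NULL, n_random = 200, seed = 7) {
  case <- make_poiseuille_case()
  gr <- generate_grid(case$geom, nx = 32, ny = 64, cluster = 0, eta_cluster = 0)
  fl <- solve_flow(case$geom, case$fluid, case$gamma0, gr)
  u_exact <- case$closed_form$u(gr$Y)
  vel_err <- max(abs(fl$u - u_exact)) / max(u_exact)
  map <- shear_rate_field(fl)
  ws_err <- max(abs(map$tau_bottom$gamma_wall[2:gr$nx] - case$gamma0)) / case$gamma0
  geoms <- random_geometry_suite(n_random, seed)
  throat_ok <- all(vapply(geoms, function(g) {
    xs <- seq(-g$footprint / 2 - 5, g$footprint / 2 + 5, length.out = 2001)
    abs(min(g$y_top(xs) - g$y_bottom(xs)) - g$throat) < 1e-9 * g$Y0
  }, logical(1)))
  conv <- mesh_sensitivity(case, levels = 3, base_grid = c(16, 16))
  out <- list(
    poiseuille_velocity_rel_err = vel_err,
    poiseuille_wall_shear_rel_err = ws_err,
    mass_imbalance = fl$mass_imbalance,
    random_suite_n = length(geoms),
    random_suite_throat_identity = throat_ok,
    convergence_observed_order = conv$observed_order,
    convergence_monotone = conv$monotone
  )
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(out, file.path(outdir, "verification.json"),
                         auto_unbox = TRUE, digits = NA)
    txt <- c("verification report",
             sprintf("  %-34s %s", names(out), vapply(out, format, character(1))))
    writeLines(txt, file.path(outdir, "verification.txt"))
  }
  invisible(out)
}
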