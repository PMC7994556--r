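#' Constitutive viscosity models for blood and reference fluids
#'
#' A `fluid_model` bundles a density with a viscosity law. Supported laws:
#'
#' * `newtonian` — constant dynamic viscosity `mu`.
#' * `gpl` — Generalized Power-Law: `mu = K(gamma) * gamma^(n(gamma) - 1)`
#'   with shear-dependent consistency `K` and index `n`,
#'   `K = mu_inf + d_mu * exp(-(1 + gamma/a) * exp(-b/gamma))` and
#'   `n = n_inf - d_n  * exp(-(1 + gamma/c) * exp(-d/gamma))`.
#'   The default parameter set (`mu_inf = 0.00345` Pa s, `n_inf = 1`,
#'   `d_mu = 0.25`, `d_n = 0.45`, `a = 50`, `b = 3`, `c = 50`, `d = 4`)
#'   reproduces whole-blood shear thinning below ~1000 1/s and relaxes to the
#'   Newtonian blood viscosity 0.00345 Pa s in the high-shear plateau.
#' * `carreau`, `casson`, `power_law` — standard literature blood fits used
#'   only for the multi-model viscosity benchmark; their constants are common
#'   textbook values, not fitted here (see [viscosity_benchmark()]).
#'
#' @param name label used in reports.
#' @param rho density (kg m^-3), must be positive.
#' @param law one of `"newtonian"`, `"gpl"`, `"carreau"`, `"casson"`,
#'   `"power_law"`.
#' @param mu constant dynamic viscosity (Pa s), Newtonian law only.
#' @param params named list of law parameters (see Details).
#' @return An object of class `fluid_model`.
#' @seealso [apparent_viscosity()], [viscosity_benchmark()]
#' @export
#' @examples
#' blood <- blood_gpl()
#' apparent_viscosity(blood, c(1, 10, 100, 1000))
fluid_model <- function(name, rho, law = "newtonian", mu = NULL, params = list()) {
  law <- match.arg(law, c("newtonian", "gpl", "carreau", "casson", "power_law"))
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("'rho' must be a single positive density (kg m^-3)")
  if (law == "newtonian") {
    if (is.null(mu) || mu <= 0) stop("newtonian law requires a positive 'mu' (Pa s)")
  }
  defaults <- switch(law,
    newtonian = list(),
    gpl = list(mu_inf = 0.00345, n_inf = 1.0, d_mu = 0.25, d_n = 0.45,
               a = 50, b = 3, c = 50, d = 4),
    # Cho & Kensey-style Carreau blood fit
    carreau = list(mu_inf = 0.00345, mu0 = 0.056, lambda = 3.313, n = 0.3568),
    # Casson with plasma-protein yield stress; mu_c is the high-shear viscosity
    casson = list(tau_y = 0.005, mu_c = 0.0035),
    # simple shear-thinning power law; no high-shear plateau by construction
    power_law = list(k = 0.035, m = 0.6)
  )
  params <- utils::modifyList(defaults, params)
  structure(list(name = name, rho = rho, law = law, mu = mu, params = params),
            class = "fluid_model")
}

#' @export
print.fluid_model <- function(x, ...) {
  cat("<fluid_model> ", x$name, "\n", sep = "")
  cat("  density : ", x$rho, " kg m^-3\n", sep = "")
  if (x$law == "newtonian") {
    cat("  law     : newtonian, mu = ", x$mu, " Pa s\n", sep = "")
  } else {
    cat("  law     : ", x$law, "\n", sep = "")
    cat("  params  : ", paste(names(x$params), unlist(x$params),
                              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Reference working fluids
#'
#' Convenience constructors for the three working fluids of the stenosis
#' microfluidic studies: water (Newtonian), blood treated as Newtonian, and
#' blood under the shear-thinning Generalized Power-Law model. Densities and
#' viscosities are the standard bench values (water 998 kg m^-3,
#' 0.001003 Pa s; blood 1060 kg m^-3, 0.00345 Pa s).
#'
#' @return A `fluid_model`.
#' @export
water <- function() fluid_model("water", rho = 998, law = "newtonian", mu = 0.001003)

#' @rdname water
#' @export
blood_newtonian <- function() fluid_model("blood (Newtonian)", rho = 1060,
                                          law = "newtonian", mu = 0.00345)

#' @rdname water
#' @export
blood_gpl <- function() fluid_model("blood (GPL)", rho = 1060, law = "gpl")

# GPL consistency index and power-law index as functions of shear rate
gpl_K <- function(gamma, p) p$mu_inf + p$d_mu * exp(-(1 + gamma / p$a) * exp(-p$b / gamma))
gpl_n <- function(gamma, p) p$n_inf - p$d_n * exp(-(1 + gamma / p$c) * exp(-p$d / gamma))

#' Apparent dynamic viscosity at a given shear rate
#'
#' Evaluates the fluid's constitutive law. Shear rates are floored at
#' `gamma_floor` before evaluation so that power-law-type laws (whose
#' `gamma^(n-1)` factor diverges as `gamma -> 0`) stay finite in quiescent
#' regions; the floor only matters in near-stagnant corners.
#'
#' @param fluid a [fluid_model()].
#' @param gamma shear rate(s), 1/s, non-negative.
#' @param gamma_floor lower clamp applied to `gamma` (1/s).
#' @return Apparent viscosity (Pa s), same length as `gamma`.
#' @export
apparent_viscosity <- function(fluid, gamma, gamma_floor = 1e-3) {
  stopifnot(inherits(fluid, "fluid_model"))
  if (any(!is.finite(gamma)) || any(gamma < 0))
    stop("'gamma' must be finite and non-negative")
  g <- pmax(gamma, gamma_floor)
  p <- fluid$params
  mu <- switch(fluid$law,
    newtonian = rep_len(fluid$mu, length(g)),
    gpl = gpl_K(g, p) * g^(gpl_n(g, p) - 1),
    carreau = p$mu_inf + (p$mu0 - p$mu_inf) * (1 + (p$lambda * g)^2)^((p$n - 1) / 2),
    casson = (sqrt(p$tau_y / g) + sqrt(p$mu_c))^2,
    power_law = p$k * g^(p$m - 1),
    stop("unknown viscosity law: ", fluid$law)
  )
  mu
}

#' Default model roster for the viscosity benchmark
#'
#' One Newtonian and four non-Newtonian blood models. The Carreau, Casson and
#' Power-Law parameter sets are common literature values supplied for
#' comparison curves only; the GPL set is the authoritative one used by the
#' flow solver.
#'
#' @return List of `fluid_model` objects.
#' @export
benchmark_fluids <- function() {
  list(
    blood_newtonian(),
    blood_gpl(),
    fluid_model("blood (Carreau)", rho = 1060, law = "carreau"),
    fluid_model("blood (Casson)", rho = 1060, law = "casson"),
    fluid_model("blood (Power-Law)", rho = 1060, law = "power_law")
  )
}

#' Tabulate viscosity curves for a set of constitutive models
#'
#' Evaluates each model over a grid of bulk shear rates, producing the curve
#' table behind a multi-model viscosity benchmark plot (viscosity vs shear
#' rate, one column per model).
#'
#' @param models list of [fluid_model()] objects; must be non-empty.
#' @param gamma shear-rate grid (1/s), positive and sorted increasing.
#' @return A data.frame with column `gamma_s_inv` followed by one viscosity
#'   column (Pa s) per model, named by the model labels.
#' @export
viscosity_benchmark <- function(models = benchmark_fluids(),
                                gamma = seq(50, 1050, by = 10)) {
  if (length(models) == 0L) stop("'models' must contain at least one fluid_model")
  if (any(gamma <= 0) || is.unsorted(gamma, strictly = TRUE))
    stop("'gamma' must be positive and strictly increasing")
  out <- data.frame(gamma_s_inv = gamma)
  for (m in models) {
    stopifnot(inherits(m, "fluid_model"))
    out[[m$name]] <- apparent_viscosity(m, gamma)
  }
  out
}
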