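#' Rectangular-duct cross-section descriptors
#'
#' Computes the cross-sectional area, hydraulic diameter and shape factor of
#' the rectangular microchannel. The shape factor
#' `lambda = 24 / [(1 - 0.351 Y0/Z0)(1 + Y0/Z0)]^2` is the rectangular-duct
#' correction that links flow rate to the wall shear rate of the wide face;
#' for `Y0/Z0 -> 0` it reduces to the plane-Poiseuille value 24.
#'
#' Mixed units are deliberate and follow microfluidics bench convention:
#' `A` is returned in um^2, `Dh` in meters (see [flow_rate()]).
#'
#' @param Y0 channel width (um), positive.
#' @param Z0 channel height (um), positive.
#' @return List with `A` (um^2), `Dh` (m), `lam` (dimensionless).
#' @export
#' @examples
#' cross_section(100, 130)  # A = 13000, Dh = 1.1304e-4, lam = 14.39
cross_section <- function(Y0, Z0) {
  if (!is.numeric(Y0) || !is.numeric(Z0) || Y0 <= 0 || Z0 <= 0)
    stop("'Y0' and 'Z0' must be positive (um)")
  A <- Y0 * Z0
  Dh <- 2 * A / (Y0 + Z0) * 1e-6 # um -> m
  lam <- 24 / ((1 - 0.351 * Y0 / Z0) * (1 + Y0 / Z0))^2
  list(A = A, Dh = Dh, lam = lam)
}

#' Flow rate that imposes a bulk wall shear rate
#'
#' `Q = 0.12 * A * Dh * gamma0 / lambda`, the syringe-pump flow rate that
#' produces a wall shear rate `gamma0` on the wide face of the unobstructed
#' rectangular channel. The formula uses the bench unit convention
#' (`A` in um^2, `Dh` in m, `Q` in uL/min); `flow_rate_si()` gives the same
#' quantity in m^3/s.
#'
#' @param gamma0 bulk wall shear rate (1/s), non-negative.
#' @param Y0,Z0 channel width and height (um).
#' @return Flow rate in uL/min (`flow_rate`) or m^3/s (`flow_rate_si`).
#' @export
#' @examples
#' flow_rate(150)   # 1.84 uL/min for the default 100 x 130 um channel
#' flow_rate(3000)  # 36.77 uL/min
flow_rate <- function(gamma0, Y0 = 100, Z0 = 130) {
  if (any(gamma0 < 0)) stop("'gamma0' must be non-negative")
  cs <- cross_section(Y0, Z0)
  0.12 * cs$A * cs$Dh * gamma0 / cs$lam
}

#' @rdname flow_rate
#' @export
flow_rate_si <- function(gamma0, Y0 = 100, Z0 = 130) {
  flow_rate(gamma0, Y0, Z0) * 1e-9 / 60 # uL/min -> m^3/s
}

#' Reynolds number of the operating point
#'
#' `Re = rho * Q * Dh / (mu * A)` in SI units, with `Q` from [flow_rate()].
#' For a Generalized Power-Law fluid the high-shear plateau viscosity
#' `mu_inf` is used, which is the relevant scale at the shear rates of
#' interest. Values well below 2300 confirm the laminar assumption.
#'
#' @param gamma0 bulk wall shear rate (1/s).
#' @param fluid a [fluid_model()].
#' @param Y0,Z0 channel width and height (um).
#' @return Reynolds number (dimensionless).
#' @export
reynolds <- function(gamma0, fluid = blood_newtonian(), Y0 = 100, Z0 = 130) {
  stopifnot(inherits(fluid, "fluid_model"))
  mu <- if (fluid$law == "newtonian") fluid$mu else fluid$params$mu_inf
  if (is.null(mu)) mu <- apparent_viscosity(fluid, 1e5) # plateau fallback
  cs <- cross_section(Y0, Z0)
  A_si <- cs$A * 1e-12
  fluid$rho * flow_rate_si(gamma0, Y0, Z0) * cs$Dh / (mu * A_si)
}

#' Womersley number
#'
#' `Wo = (D/2) * sqrt(rho * omega / mu)` with `omega = 2 * pi * f`. Used to
#' justify the steady-flow assumption: `Wo << 1` means pulsatility is damped
#' by viscosity at the micro scale. At a 120 bpm heart rate (f = 2 Hz) and
#' D = 130 um, blood gives Wo = 0.128.
#'
#' @param f oscillation frequency (Hz), non-negative.
#' @param D vessel/channel diameter (m), positive.
#' @param fluid a [fluid_model()]; Newtonian viscosity (or GPL plateau) used.
#' @return Womersley number (dimensionless).
#' @export
womersley <- function(f, D = 130e-6, fluid = blood_newtonian()) {
  stopifnot(inherits(fluid, "fluid_model"))
  if (f < 0) stop("'f' must be non-negative")
  if (D <= 0) stop("'D' must be positive (m)")
  mu <- if (fluid$law == "newtonian") fluid$mu else fluid$params$mu_inf
  omega <- 2 * pi * f
  (D / 2) * sqrt(fluid$rho * omega / mu)
}

#' Assemble the operating point of one run
#'
#' Collects the closed-form descriptors of a run into one record: bulk shear
#' rate, flow rate (bench units and SI), cross-section descriptors, Reynolds
#' number and (if a frequency is given) the Womersley number.
#'
#' @param gamma0 bulk wall shear rate (1/s).
#' @param fluid a [fluid_model()].
#' @param Y0,Z0 channel width and height (um).
#' @param f optional oscillation frequency (Hz) for the Womersley number.
#' @param D diameter used in the Womersley number (m).
#' @return An object of class `operating_point`.
#' @export
operating_point <- function(gamma0, fluid = blood_newtonian(),
                            Y0 = 100, Z0 = 130, f = NULL, D = 130e-6) {
  if (gamma0 < 0) stop("'gamma0' must be non-negative")
  cs <- cross_section(Y0, Z0)
  op <- list(
    gamma0 = gamma0,
    Q_uL_min = flow_rate(gamma0, Y0, Z0),
    Q_si = flow_rate_si(gamma0, Y0, Z0),
    A = cs$A, Dh = cs$Dh, lam = cs$lam,
    Re = reynolds(gamma0, fluid, Y0, Z0),
    Wo = if (!is.null(f)) womersley(f, D, fluid) else NA_real_,
    f = if (!is.null(f)) f else NA_real_, D = D,
    omega = if (!is.null(f)) 2 * pi * f else NA_real_,
    fluid = fluid$name
  )
  structure(op, class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat("<operating_point>\n")
  cat(sprintf("  gamma0 = %g 1/s   Q = %.4g uL/min (%.4g m^3/s)\n",
              x$gamma0, x$Q_uL_min, x$Q_si))
  cat(sprintf("  A = %g um^2   Dh = %.5g m   lambda = %.4f\n", x$A, x$Dh, x$lam))
  cat(sprintf("  Re = %.4g", x$Re))
  if (is.finite(x$Wo)) cat(sprintf("   Wo = %.4g (f = %g Hz)", x$Wo, x$f))
  cat("\n  fluid: ", x$fluid, "\n", sep = "")
  invisible(x)
}
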