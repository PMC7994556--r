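#' Solver controls for the steady flow solve
#'
#' The solver uses a pure streamfunction (fourth-order) discretization of
#' the steady incompressible momentum balance with all viscous terms
#' implicit, solved by direct sparse factorization inside a Picard
#' (successive substitution) loop that updates the convective velocities
#' and, for shear-thinning fluids, the apparent viscosity field. Because
#' every outer iteration is a direct solve, no pressure--velocity relaxation
#' is needed; `relax_u` under-relaxes the field update (1 = full step,
#' adequate at the creeping-flow Reynolds numbers of these channels) and
#' `relax_mu` under-relaxes the viscosity update of non-Newtonian runs
#' (applied in log space, since the apparent viscosity spans decades).
#'
#' @param tol scaled nonlinear residual tolerance (max streamfunction update
#'   over the through-flow, dimensionless).
#' @param max_iter outer-iteration cap; exceeding it is an error that carries
#'   the residual history.
#' @param relax_u field update under-relaxation in `(0, 1]`.
#' @param relax_mu viscosity update under-relaxation in `(0, 1]`.
#' @param convection_scheme only `"central"` is implemented: at `Re < 1` the
#'   cell Peclet numbers are far below the central-difference stability bound
#'   and upwinding would only add numerical diffusion.
#' @param gamma_floor shear-rate floor (1/s) used when evaluating the
#'   constitutive law inside the solver.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(tol = 1e-7, max_iter = 100, relax_u = 1,
                          relax_mu = 0.5, convection_scheme = "central",
                          gamma_floor = 1e-3) {
  if (tol <= 0) stop("'tol' must be positive")
  if (relax_u <= 0 || relax_u > 1 || relax_mu <= 0 || relax_mu > 1)
    stop("relaxation factors must lie in (0, 1]")
  convection_scheme <- match.arg(convection_scheme, "central")
  structure(list(tol = tol, max_iter = max_iter, relax_u = relax_u,
                 relax_mu = relax_mu, convection_scheme = convection_scheme,
                 gamma_floor = gamma_floor), class = "solver_config")
}

# scalar shear-rate field gamma = sqrt(2 D:D) from nodal velocity fields
shear_invariant <- function(ux, uy, vx, vy) {
  sqrt(2 * (ux^2 + vy^2) + (uy + vx)^2)
}

#' Solve the steady laminar flow through a stenosis microchannel
#'
#' Integrates the steady incompressible variable-viscosity momentum balance
#' in the x-y plane of the channel. The two-dimensional line flux is chosen
#' so that the wall shear rate of the unobstructed channel equals the
#' requested bulk shear rate (`q = gamma0 * Y0^2 / 6`), preserving the
#' meaning of `gamma0` as the operating-point dial; the three-dimensional
#' bench flow rate from [flow_rate()] is carried alongside in the returned
#' operating point for traceability.
#'
#' Boundary conditions: a fully developed velocity profile at the inlet
#' carrying the line flux, no-slip walls, and zero axial gradient at the
#' outlet (the steady-state equivalent of a pressure-inlet / flow-rate-outlet
#' arrangement, and better posed numerically). The streamfunction formulation
#' conserves mass exactly: the flux between the two walls is a fixed boundary
#' value, so the station-to-station mass imbalance is at round-off level by
#' construction.
#'
#' @param geom a [stenosis_geometry()]; stenosis levels at or above 0.97 are
#'   refused (the throat cannot be resolved reliably at desk-scale grids).
#' @param fluid a [fluid_model()].
#' @param gamma0 bulk wall shear rate (1/s), positive.
#' @param grid a [generate_grid()] result.
#' @param cfg a [solver_config()].
#' @return An object of class `flow_field` with nodal fields `u`, `v` (m/s),
#'   `P` (Pa, gauge, recovered from the momentum balance), `psi`, `omega`,
#'   `mu_field`, the grid and inputs, convergence diagnostics
#'   (`residual_history`, `converged`, `mass_imbalance`) and reference scales.
#' @export
solve_flow <- function(geom, fluid, gamma0, grid, cfg = solver_config()) {
  stopifnot(inherits(geom, "stenosis_geometry"), inherits(fluid, "fluid_model"),
            inherits(grid, "stenosis_grid"))
  if (!is.numeric(gamma0) || gamma0 <= 0) stop("'gamma0' must be positive (1/s)")
  if (geom$S >= 0.97)
    stop("S >= 0.97 is refused: throat of ", signif(geom$throat, 3),
         " um is too narrow to resolve reliably; reduce S or treat as occluded")
  if (!identical(grid$geom$S, geom$S) || !identical(grid$geom$placement, geom$placement))
    stop("'grid' was generated for a different geometry")
  if (any(grid_cell_areas(grid) <= 0)) stop("grid has non-positive cell areas")

  ni <- grid$nx + 1; nj <- grid$ny + 1; N <- ni * nj
  ops <- grid_operators(grid)
  Dx <- ops$Dx; Dy <- ops$Dy; Lap <- ops$Lap
  rho <- fluid$rho
  w_in <- grid$h[1]                       # inlet gap (m)
  q <- gamma0 * (geom$Y0 * 1e-6)^2 / 6    # 2D line flux (m^2/s)

  ii <- matrix(rep(1:ni, nj), ni, nj)
  jj <- matrix(rep(1:nj, each = ni), ni, nj)

  # physical wall-normalized coordinate of the inlet nodes (the transverse
  # node placement is clustered, so this differs from the computational eta)
  eta_in_phys <- (grid$Y[1, ] - grid$Y[1, 1]) / (grid$Y[1, nj] - grid$Y[1, 1])
  psi_in <- q * (3 * eta_in_phys^2 - 2 * eta_in_phys^3)  # developed cubic profile

  # --- row assignment ------------------------------------------------------
  # Pure streamfunction formulation: the vorticity is eliminated and the
  # steady vorticity balance becomes a fourth-order equation in psi,
  #   rho (u . grad)(-lap psi) = (d_xx - d_yy)[mu (psi_yy - psi_xx)]
  #                              - 4 d_xy(mu psi_xy),
  # with the convective velocities and the viscosity lagged (Picard). All
  # viscous terms are implicit, which keeps the loop stable at the three-
  # decade viscosity contrasts a shear-thinning fluid develops between the
  # wall layers and the plug along the channel axis; formulations that lag
  # part of the elliptic operator oscillate there. Each boundary supplies
  # the two conditions a fourth-order operator needs: the two node columns
  # nearest the inlet pin the developed profile, the wall rows pin the wall
  # streamline value (j = 1) and no-slip (j = 2, third-order one-sided
  # d(psi)/d(eta) = 0), and the outlet rows impose zero axial gradient of
  # psi (i = ni) and of the vorticity (row at i = ni-1).
  sel <- function(idx) Matrix::sparseMatrix(i = idx, j = idx, x = rep(1, length(idx)),
                                            dims = c(N, N))
  stencil_rows <- function(rows, cols, coefs) {
    Matrix::sparseMatrix(i = rep(rows, length(coefs)),
                         j = unlist(cols, use.names = FALSE),
                         x = rep(coefs, each = length(rows)), dims = c(N, N))
  }

  rows_in <- which(ii <= 2L)
  rows_out1 <- which(ii == ni & jj > 1L & jj < nj)
  rows_out2 <- which(ii == ni - 1L & jj > 1L & jj < nj)
  rows_wall <- which((jj == 1L | jj == nj) & ii > 2L)
  rows_ns_b <- which(jj == 2L & ii > 2L & ii < ni - 1L)
  rows_ns_t <- which(jj == nj - 1L & ii > 2L & ii < ni - 1L)
  rows_int <- setdiff(seq_len(N), c(rows_in, rows_out1, rows_out2, rows_wall,
                                    rows_ns_b, rows_ns_t))

  R_in <- sel(rows_in)
  b <- numeric(N)
  b[rows_in] <- psi_in[jj[rows_in]]
  b[rows_wall] <- ifelse(jj[rows_wall] == 1L, 0, q)

  R_out1 <- stencil_rows(rows_out1, list(rows_out1, rows_out1 - 1L, rows_out1 - 2L),
                         c(3, -4, 1))
  # zero axial vorticity gradient: lap(psi) equal on the last two columns
  S_map <- Matrix::sparseMatrix(i = rows_out2, j = rows_out2 + 1L,
                                x = rep(1, length(rows_out2)), dims = c(N, N))
  R_out2 <- (S_map - sel(rows_out2)) %*% Lap
  R_wall <- sel(rows_wall)
  # no-slip: third-order one-sided d(psi)/d(eta) = 0, written in the row of
  # the first interior node; the stencil spans the wall and three layers
  R_ns <- stencil_rows(rows_ns_b, list(rows_ns_b - ni, rows_ns_b, rows_ns_b + ni,
                                       rows_ns_b + 2L * ni), c(-11, 18, -9, 2)) +
    stencil_rows(rows_ns_t, list(rows_ns_t + ni, rows_ns_t, rows_ns_t - ni,
                                 rows_ns_t - 2L * ni), c(-11, 18, -9, 2))
  A_const <- R_in + R_out1 + R_out2 + R_wall + R_ns
  sel_int <- sel(rows_int)

  # --- Picard loop --------------------------------------------------------
  u <- matrix(0, ni, nj); v <- matrix(0, ni, nj)
  mu0 <- apparent_viscosity(fluid, max(gamma0, cfg$gamma_floor), cfg$gamma_floor)
  mu <- matrix(mu0, ni, nj)
  psi <- NULL
  hist <- data.frame(iter = integer(), res_psi = numeric(), mu_change = numeric())
  converged <- FALSE
  newtonian <- fluid$law == "newtonian"
  Dxy <- Dx %*% Dy
  Visc <- NULL
  for (iter in seq_len(cfg$max_iter)) {
    if (is.null(Visc) || (!newtonian && iter > 1L)) {
      dgmu <- Matrix::Diagonal(x = as.vector(mu))
      Visc <- (ops$Dxx - ops$Dyy) %*% dgmu %*% (ops$Dyy - ops$Dxx) -
        4 * (Dxy %*% dgmu %*% Dxy)
    }
    Conv <- Matrix::Diagonal(x = rho * as.vector(u)) %*% Dx +
            Matrix::Diagonal(x = rho * as.vector(v)) %*% Dy
    A <- A_const + sel_int %*% (-(Conv %*% Lap) - Visc)
    x <- solve_equilibrated(A, b, rep(q, N))
    psi_new <- matrix(x, ni, nj)

    if (!is.null(psi)) {
      psi_new <- cfg$relax_u * psi_new + (1 - cfg$relax_u) * psi
      res_psi <- max(abs(psi_new - psi)) / q
    } else res_psi <- Inf
    psi <- psi_new

    u <- op_apply(Dy, psi)
    v <- -op_apply(Dx, psi)
    # no-slip walls are boundary conditions, not reconstructions
    u[, 1] <- 0; u[, nj] <- 0
    v[, 1] <- 0; v[, nj] <- 0

    mu_change <- 0
    if (!newtonian) {
      ux <- op_apply(Dx, u); uy <- op_apply(Dy, u)
      vx <- op_apply(Dx, v); vy <- op_apply(Dy, v)
      gam <- shear_invariant(ux, uy, vx, vy)
      mu_target <- matrix(apparent_viscosity(fluid, pmax(as.vector(gam), 0),
                                             cfg$gamma_floor), ni, nj)
      # relax in log space: the apparent viscosity spans orders of magnitude
      # between the wall layers and the plug core, and linear relaxation
      # overshoots on that scale
      mu_new <- exp(cfg$relax_mu * log(mu_target) + (1 - cfg$relax_mu) * log(mu))
      mu_change <- max(abs(log(mu_new / mu)))
      mu <- mu_new
    }
    hist <- rbind(hist, data.frame(iter = iter, res_psi = res_psi,
                                   mu_change = mu_change))
    if (is.finite(res_psi) && res_psi < cfg$tol && mu_change < 1e-3) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(errorCondition(
      sprintf("flow solve did not converge in %d iterations (last residual %.3g)",
              cfg$max_iter, utils::tail(hist$res_psi, 1)),
      class = c("stenoflow_no_convergence", "error"),
      residual_history = hist))
  }

  mass_imb <- max(abs((psi[, nj] - psi[, 1]) - q)) / q
  U_ref <- max(abs(u))
  omega <- -op_apply(Lap, psi)
  P <- recover_pressure(ops, u, v, mu, rho, anchor = N)

  structure(list(
    psi = psi, omega = omega, u = u, v = v, P = P, mu_field = mu,
    grid = grid, geom = geom, fluid = fluid,
    gamma0 = gamma0, q2d = q,
    op = operating_point(gamma0, fluid, geom$Y0, geom$Z0),
    iterations = nrow(hist), residual_history = hist,
    converged = converged, mass_imbalance = mass_imb, U_ref = U_ref
  ), class = "flow_field")
}

# Direct sparse solve with column scaling (given) and infinity-norm row
# equilibration; the streamfunction/vorticity blocks differ by ~12 orders of
# magnitude in SI units, which overwhelms an unscaled LU.
solve_equilibrated <- function(A, b, col_scale) {
  A <- A %*% Matrix::Diagonal(x = col_scale)
  row_norm <- sqrt(Matrix::rowSums(A^2))
  if (any(row_norm == 0)) stop("singular system: empty row in flow matrix")
  Dr <- Matrix::Diagonal(x = 1 / row_norm)
  xh <- as.vector(Matrix::solve(Dr %*% A, as.vector(Dr %*% b)))
  col_scale * xh
}

# Gauge pressure recovered from the momentum balance by area-weighted sparse
# least squares: minimize the integral of |grad P - g|^2 (weights = nodal
# Jacobians, so the strongly clustered throat cells do not dominate the
# normal equations) with P anchored at one node.
recover_pressure <- function(ops, u, v, mu, rho, anchor) {
  Dx <- ops$Dx; Dy <- ops$Dy
  ux <- op_apply(Dx, u); uy <- op_apply(Dy, u)
  vx <- op_apply(Dx, v); vy <- op_apply(Dy, v)
  gx <- op_apply(Dx, 2 * mu * ux) + op_apply(Dy, mu * (uy + vx)) -
    rho * (u * ux + v * uy)
  gy <- op_apply(Dx, mu * (uy + vx)) + op_apply(Dy, 2 * mu * vy) -
    rho * (u * vx + v * vy)
  W <- Matrix::Diagonal(x = as.vector(ops$J))
  AtA <- Matrix::t(Dx) %*% W %*% Dx + Matrix::t(Dy) %*% W %*% Dy
  scale <- mean(Matrix::diag(AtA))
  AtA[anchor, anchor] <- AtA[anchor, anchor] + scale
  rhs <- as.vector(Matrix::t(Dx) %*% (as.vector(ops$J) * as.vector(gx)) +
                   Matrix::t(Dy) %*% (as.vector(ops$J) * as.vector(gy)))
  P <- as.vector(Matrix::solve(AtA, rhs))
  P <- P - P[anchor]
  dim(P) <- dim(u)
  P
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field> ", x$fluid$name, " @ gamma0 = ", x$gamma0, " 1/s\n", sep = "")
  cat(sprintf("  grid %d x %d, %d outer iterations, converged: %s\n",
              x$grid$nx, x$grid$ny, x$iterations, x$converged))
  cat(sprintf("  U_max = %.4g m/s, mass imbalance = %.2g\n",
              x$U_ref, x$mass_imbalance))
  invisible(x)
}
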