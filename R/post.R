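#' Shear-rate map of a converged flow field
#'
#' Computes the scalar shear rate `gamma = sqrt(2 D:D)` (second invariant of
#' the rate-of-strain tensor `D = (grad u + grad u^T)/2`), the apparent
#' viscosity field, and the wall-shear-stress distributions along both walls
#' (`tau = mu_wall * gamma_wall`, from one-sided second-order normal
#' differences at the boundary). For simple shear `u(y)` the invariant
#' reduces to `|du/dy|`; it vanishes for uniform translation and rigid-body
#' rotation.
#'
#' @param flow a converged [solve_flow()] result.
#' @return An object of class `shear_map`: `gamma` (nodal matrix, 1/s),
#'   `mu_field` (Pa s), `tau_bottom`, `tau_top` (data.frames with `x_um`,
#'   `s_um`, `gamma_wall`, `tau_Pa`, `tau_dyn_cm2`), `gamma_max_field` and
#'   `tau_max` peak records.
#' @export
shear_rate_field <- function(flow) {
  if (!isTRUE(flow$converged)) stop("flow field is not converged")
  grid <- flow$grid
  ops <- grid_operators(grid)
  ux <- op_apply(ops$Dx, flow$u); uy <- op_apply(ops$Dy, flow$u)
  vx <- op_apply(ops$Dx, flow$v); vy <- op_apply(ops$Dy, flow$v)
  gamma <- shear_invariant(ux, uy, vx, vy)
  nj <- ncol(gamma)
  # at a no-slip wall the shear rate equals |omega| exactly (the velocity
  # gradient reduces to the normal derivative of the tangential component);
  # the solved vorticity carries the wall closure directly and avoids the
  # first-order bias of differentiating the reconstructed velocity twice
  if (!is.null(flow$omega)) {
    gamma[, 1] <- abs(flow$omega[, 1])
    gamma[, nj] <- abs(flow$omega[, nj])
  }
  mu_field <- if (!is.null(flow$mu_field)) flow$mu_field else
    matrix(apparent_viscosity(flow$fluid, pmax(as.vector(gamma), 0)),
           nrow(gamma), ncol(gamma))
  wall_tab <- function(j) {
    x <- grid$X[, j] * 1e6
    y <- grid$Y[, j] * 1e6
    s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
    tau <- mu_field[, j] * gamma[, j]
    data.frame(x_um = x, s_um = s, gamma_wall = gamma[, j],
               tau_Pa = tau, tau_dyn_cm2 = 10 * tau)
  }
  tb <- wall_tab(1); tt <- wall_tab(nj)
  idx <- which.max(gamma)
  i <- (idx - 1) %% nrow(gamma) + 1; j <- (idx - 1) %/% nrow(gamma) + 1
  gmax <- list(value = gamma[idx], x_um = grid$X[i, j] * 1e6,
               y_um = grid$Y[i, j] * 1e6)
  pk_b <- peak_parabolic(tb$x_um, tb$tau_Pa)
  pk_t <- peak_parabolic(tt$x_um, tt$tau_Pa)
  tau_max <- if (pk_b$value >= pk_t$value) c(pk_b, wall = "bottom")
             else c(pk_t, wall = "top")
  structure(list(gamma = gamma, mu_field = mu_field,
                 tau_bottom = tb, tau_top = tt,
                 gamma_max_field = gmax,
                 tau_max = tau_max, grid = grid, flow = flow),
            class = "shear_map")
}

#' @export
print.shear_map <- function(x, ...) {
  cat("<shear_map>\n")
  cat(sprintf("  field gamma_max = %.4g 1/s at (%.1f, %.1f) um\n",
              x$gamma_max_field$value, x$gamma_max_field$x_um, x$gamma_max_field$y_um))
  cat(sprintf("  tau_max = %.4g Pa (%.4g dyn/cm2) on %s wall at x = %.1f um\n",
              x$tau_max$value, 10 * x$tau_max$value, x$tau_max$wall, x$tau_max$x))
  invisible(x)
}

#' Wall-shear-stress profile along one wall
#'
#' @param flow a converged [solve_flow()] result.
#' @param map optionally a precomputed [shear_rate_field()] of `flow`.
#' @param wall `"bottom"` or `"top"`.
#' @return data.frame with `x_um`, `s_um` (arc length), `gamma_wall` (1/s),
#'   `tau_Pa`, `tau_dyn_cm2`, with attributes `tau_max` and `x_max_um` (peak
#'   value and its parabolically refined location).
#' @export
wall_shear_stress <- function(flow, map = NULL, wall = c("bottom", "top")) {
  wall <- match.arg(wall)
  if (is.null(map)) map <- shear_rate_field(flow)
  tab <- if (wall == "bottom") map$tau_bottom else map$tau_top
  pk <- peak_parabolic(tab$x_um, tab$tau_Pa)
  attr(tab, "tau_max") <- pk$value
  attr(tab, "x_max_um") <- pk$x
  tab
}

# Parabolic sub-sample refinement of the maximum of y(x); tie-break toward
# the smallest |x|.
peak_parabolic <- function(x, y) {
  m <- max(y)
  cand <- which(y >= m * (1 - 1e-12))
  i <- cand[which.min(abs(x[cand]))]
  if (i <= 1 || i >= length(y)) return(list(value = y[i], x = x[i]))
  x3 <- x[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
  # quadratic through three (possibly unevenly spaced) samples
  d21 <- x3[2] - x3[1]; d32 <- x3[3] - x3[2]; d31 <- x3[3] - x3[1]
  denom <- d21 * d32 * d31
  A <- (d21 * (y3[3] - y3[2]) - d32 * (y3[2] - y3[1])) / denom
  B <- ((y3[2] - y3[1]) / d21) - A * (x3[1] + x3[2])
  if (A >= 0) return(list(value = y3[2], x = x3[2]))
  xv <- -B / (2 * A)
  if (xv < x3[1] || xv > x3[3]) return(list(value = y3[2], x = x3[2]))
  C <- y3[2] - A * x3[2]^2 - B * x3[2]
  list(value = A * xv^2 + B * xv + C, x = xv)
}

# ---- point location and interpolation on the curvilinear mesh -------------

# Walk search for the cell containing point p = c(x, y); returns c(i, j) of
# the cell's lower-left node or NULL when p leaves the domain.
locate_cell <- function(X, Y, p, start) {
  nx <- nrow(X) - 1L; ny <- ncol(X) - 1L
  i <- min(max(start[1], 1L), nx); j <- min(max(start[2], 1L), ny)
  for (it in 1:(2L * (nx + ny))) {
    x1 <- X[i, j];     y1 <- Y[i, j]
    x2 <- X[i + 1, j]; y2 <- Y[i + 1, j]
    x3 <- X[i + 1, j + 1]; y3 <- Y[i + 1, j + 1]
    x4 <- X[i, j + 1]; y4 <- Y[i, j + 1]
    # signed areas against the four CCW edges
    sS <- (x2 - x1) * (p[2] - y1) - (y2 - y1) * (p[1] - x1)
    sE <- (x3 - x2) * (p[2] - y2) - (y3 - y2) * (p[1] - x2)
    sN <- (x4 - x3) * (p[2] - y3) - (y4 - y3) * (p[1] - x3)
    sW <- (x1 - x4) * (p[2] - y4) - (y1 - y4) * (p[1] - x4)
    if (sS >= 0 && sE >= 0 && sN >= 0 && sW >= 0) return(c(i, j))
    worst <- which.min(c(sS, sE, sN, sW))
    if (worst == 1L) j <- j - 1L
    else if (worst == 2L) i <- i + 1L
    else if (worst == 3L) j <- j + 1L
    else i <- i - 1L
    if (i < 1L || i > nx || j < 1L || j > ny) return(NULL)
  }
  NULL
}

# Inverse bilinear local coordinates (a, b) in [0,1]^2 of p within cell (i,j)
cell_local_coords <- function(X, Y, i, j, p) {
  x1 <- X[i, j];     y1 <- Y[i, j]
  x2 <- X[i + 1, j]; y2 <- Y[i + 1, j]
  x3 <- X[i + 1, j + 1]; y3 <- Y[i + 1, j + 1]
  x4 <- X[i, j + 1]; y4 <- Y[i, j + 1]
  a <- 0.5; b <- 0.5
  for (it in 1:12) {
    Nx <- (1 - a) * (1 - b) * x1 + a * (1 - b) * x2 + a * b * x3 + (1 - a) * b * x4
    Ny <- (1 - a) * (1 - b) * y1 + a * (1 - b) * y2 + a * b * y3 + (1 - a) * b * y4
    rx <- Nx - p[1]; ry <- Ny - p[2]
    if (abs(rx) + abs(ry) < 1e-18) break
    dxa <- -(1 - b) * x1 + (1 - b) * x2 + b * x3 - b * x4
    dya <- -(1 - b) * y1 + (1 - b) * y2 + b * y3 - b * y4
    dxb <- -(1 - a) * x1 - a * x2 + a * x3 + (1 - a) * x4
    dyb <- -(1 - a) * y1 - a * y2 + a * y3 + (1 - a) * y4
    det <- dxa * dyb - dxb * dya
    if (abs(det) < 1e-30) break
    a <- a - (dyb * rx - dxb * ry) / det
    b <- b - (-dya * rx + dxa * ry) / det
  }
  c(max(min(a, 1), 0), max(min(b, 1), 0))
}

# Bilinear interpolation of one or more nodal fields at p; fields is a list
# of (nx+1) x (ny+1) matrices. Returns NULL if p is outside the mesh.
interp_fields <- function(grid, fields, p, start) {
  X <- grid$X; Y <- grid$Y
  cell <- locate_cell(X, Y, p, start)
  if (is.null(cell)) return(NULL)
  i <- cell[1]; j <- cell[2]
  ab <- cell_local_coords(X, Y, i, j, p)
  a <- ab[1]; b <- ab[2]
  w <- c((1 - a) * (1 - b), a * (1 - b), a * b, (1 - a) * b)
  vals <- vapply(fields, function(f)
    w[1] * f[i, j] + w[2] * f[i + 1, j] + w[3] * f[i + 1, j + 1] + w[4] * f[i, j + 1],
    numeric(1))
  list(vals = vals, cell = cell)
}

#' Trace a streamline of the steady flow
#'
#' Integrates the steady velocity field with classical fourth-order
#' Runge-Kutta from a seed point until the trajectory leaves the domain
#' through the outlet. The velocity is interpolated bilinearly on the
#' curvilinear mesh; the step length adapts to the local cell size (one
#' quarter of the smaller local cell dimension), which on the apex-clustered
#' grids of this package resolves the contraction without wasting steps in
#' the long entrance run.
#'
#' @param flow a converged [solve_flow()] result.
#' @param seed numeric `c(x, y)` in meters, strictly inside the fluid domain.
#' @param max_steps safety cap on the number of RK4 steps.
#' @return data.frame with the polyline (`x_um`, `y_um`) and the local speed
#'   (`speed`, m/s).
#' @export
trace_streamline <- function(flow, seed, max_steps = 200000L) {
  if (!isTRUE(flow$converged)) stop("flow field is not converged")
  grid <- flow$grid
  X <- grid$X; Y <- grid$Y
  u <- flow$u; v <- flow$v
  U_ref <- flow$U_ref
  nx <- grid$nx; ny <- grid$ny
  # local cell extent per cell (precomputed)
  dxc <- abs(X[2:(nx + 1), 1:ny] - X[1:nx, 1:ny])
  dyc <- abs(Y[1:nx, 2:(ny + 1)] - Y[1:nx, 1:ny])
  csize <- pmin(pmax(dxc, 1e-12), pmax(dyc, 1e-12))
  start <- guess_start_cell(grid, seed)
  probe <- interp_fields(grid, list(u, v), seed, start)
  if (is.null(probe)) stop("seed point lies outside the fluid domain")
  if (sqrt(sum(probe$vals^2)) < 1e-12 * U_ref)
    stop("seed point is effectively stagnant; streamline undefined")
  p <- seed
  cell <- probe$cell
  xs <- numeric(0); ys <- numeric(0); sp <- numeric(0)
  vel <- function(p, cell) {
    r <- interp_fields(grid, list(u, v), p, cell)
    if (is.null(r)) return(NULL)
    r
  }
  for (k in seq_len(max_steps)) {
    r1 <- vel(p, cell)
    if (is.null(r1)) break
    cell <- r1$cell
    xs[length(xs) + 1L] <- p[1]; ys[length(ys) + 1L] <- p[2]
    speed <- sqrt(sum(r1$vals^2))
    sp[length(sp) + 1L] <- speed
    if (speed < 1e-12 * U_ref) break
    hstep <- csize[cell[1], min(cell[2], ny)] / 4
    dt <- hstep / speed
    k1 <- r1$vals
    r2 <- vel(p + 0.5 * dt * k1, cell); if (is.null(r2)) break
    r3 <- vel(p + 0.5 * dt * r2$vals, cell); if (is.null(r3)) break
    r4 <- vel(p + dt * r3$vals, cell); if (is.null(r4)) break
    p <- p + dt / 6 * (k1 + 2 * r2$vals + 2 * r3$vals + r4$vals)
  }
  data.frame(x_um = xs * 1e6, y_um = ys * 1e6, speed = sp)
}

# Initial cell guess from the node nearest in x along the bottom row
guess_start_cell <- function(grid, p) {
  i <- findInterval(p[1], grid$X[, 1], all.inside = TRUE)
  j <- findInterval(p[2], grid$Y[i, ], all.inside = TRUE)
  c(i, j)
}

#' Platelet-trajectory shear profile
#'
#' Finds the streamline whose minimum distance to the stenosis apex surface
#' equals the platelet clearance (default 1 um, half a platelet diameter) by
#' bisection on the inlet seed ordinate, then samples the shear rate along it
#' and differentiates to obtain the shear-rate gradient history. The
#' acceleration zone is `x < 0` (upstream of the apex), the deceleration zone
#' `x > 0`.
#'
#' @param flow a converged [solve_flow()] result.
#' @param map optionally a precomputed [shear_rate_field()].
#' @param clearance target minimum wall clearance (um).
#' @param tol_um bisection tolerance on the achieved clearance (um).
#' @param window half-width (um) of the reporting window around the apex;
#'   defaults to the geometry's analysis half-length `X0/2`.
#' @return An object of class `shear_profile`: the polyline, `gamma_s` (1/s)
#'   and `gamma_prime` (1/um/s) sampled along it, peak records `gamma_max`
#'   and `gamma_prime_max` with locations, and the achieved clearance.
#' @export
platelet_trajectory_profile <- function(flow, map = NULL, clearance = 1,
                                        tol_um = 0.05, window = NULL) {
  if (!isTRUE(flow$converged)) stop("flow field is not converged")
  if (clearance <= 0) stop("'clearance' must be positive (um)")
  if (is.null(map)) map <- shear_rate_field(flow)
  geom <- flow$geom
  grid <- flow$grid
  if (is.null(window)) window <- geom$X0 / 2
  if (geom$throat / 2 <= clearance)
    stop("throat too narrow for the requested clearance: cannot bracket")

  # wall sample for clearance measurement, dense around the hump
  foot <- max(geom$footprint / 2, 5)
  xw <- seq(-foot - 10, foot + 10, length.out = 4001)
  wall <- cbind(xw, geom$y_bottom(xw))

  x_seed <- grid$X[2, 1] + 1e-9           # second station: strictly inside
  yb0 <- geom$y_bottom(x_seed * 1e6); yt0 <- geom$y_top(x_seed * 1e6)
  min_clear <- function(tr) {
    selp <- abs(tr$x_um) <= foot + 10
    if (!any(selp)) return(Inf)
    px <- tr$x_um[selp]; py <- tr$y_um[selp]
    dmin <- Inf
    for (kk in seq_along(px)) {
      d2 <- (wall[, 1] - px[kk])^2 + (wall[, 2] - py[kk])^2
      dmin <- min(dmin, min(d2))
    }
    sqrt(dmin)
  }
  trace_at <- function(y_um) {
    trace_streamline(flow, c(x_seed, y_um * 1e-6))
  }
  # bracket: near-wall seed passes close, mid-channel seed passes far. The
  # streamfunction gives an excellent initial guess: the streamline through
  # the point one clearance above the apex carries a known psi level, and the
  # monotone inlet profile maps that level back to a seed ordinate.
  lo <- yb0 + 1e-3 * (yt0 - yb0); hi <- yb0 + 0.6 * (yt0 - yb0)
  guess <- tryCatch({
    p_ap <- c(0, (geom$y_bottom(0) + clearance)) * 1e-6
    r <- interp_fields(grid, list(flow$psi), p_ap,
                       guess_start_cell(grid, p_ap))
    psi_col <- flow$psi[2, ]; y_col <- grid$Y[2, ] * 1e6
    stats::approx(psi_col, y_col, xout = r$vals[1], ties = "ordered")$y
  }, error = function(e) NA_real_)
  if (is.finite(guess)) {
    lo2 <- max(lo, guess - 0.5); hi2 <- min(hi, guess + 0.5)
    if (min_clear(trace_at(lo2)) < clearance && min_clear(trace_at(hi2)) > clearance) {
      lo <- lo2; hi <- hi2
    }
  }
  if (!(min_clear(trace_at(lo)) < clearance && min_clear(trace_at(hi)) > clearance))
    stop("failed to bracket the requested clearance between wall and mid-channel seeds")
  tr <- NULL; achieved <- NA_real_
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    tr <- trace_at(mid)
    cm <- min_clear(tr)
    if (is.finite(cm) && abs(cm - clearance) <= tol_um) { achieved <- cm; break }
    if (cm < clearance) lo <- mid else hi <- mid
    achieved <- cm
    if (it == 60) break
  }

  # sample gamma along the polyline inside the reporting window
  selp <- abs(tr$x_um) <= window
  px <- tr$x_um[selp]; py <- tr$y_um[selp]
  keep <- c(TRUE, diff(px) > 1e-9)        # strictly increasing x for d/dx
  px <- px[keep]; py <- py[keep]
  gam <- numeric(length(px))
  cell <- guess_start_cell(grid, c(px[1] * 1e-6, py[1] * 1e-6))
  for (kk in seq_along(px)) {
    r <- interp_fields(grid, list(map$gamma), c(px[kk], py[kk]) * 1e-6, cell)
    if (is.null(r)) { gam[kk] <- NA; next }
    gam[kk] <- r$vals[1]; cell <- r$cell
  }
  ok <- is.finite(gam)
  px <- px[ok]; py <- py[ok]; gam <- gam[ok]
  n <- length(px)
  gp <- numeric(n)
  gp[2:(n - 1)] <- (gam[3:n] - gam[1:(n - 2)]) / (px[3:n] - px[1:(n - 2)])
  gp[1] <- gp[2]; gp[n] <- gp[n - 1]

  pk_g <- peak_parabolic(px, gam)
  pk_gp <- peak_parabolic(px, abs(gp))
  structure(list(
    seed = c(x_seed, NA), clearance_um = achieved,
    x_um = px, y_um = py, gamma_s = gam, gamma_prime = gp,
    gamma_max = pk_g$value, gamma_max_x_um = pk_g$x,
    gamma_prime_max = pk_gp$value, gamma_prime_max_x_um = pk_gp$x,
    accel = data.frame(x_um = px[px < 0], gamma = gam[px < 0],
                       gamma_prime = gp[px < 0]),
    decel = data.frame(x_um = px[px > 0], gamma = gam[px > 0],
                       gamma_prime = gp[px > 0])
  ), class = "shear_profile")
}

#' @export
print.shear_profile <- function(x, ...) {
  cat("<shear_profile> platelet trajectory\n")
  cat(sprintf("  clearance = %.3f um, %d samples\n", x$clearance_um, length(x$x_um)))
  cat(sprintf("  gamma_max = %.4g 1/s at x = %.2f um\n", x$gamma_max, x$gamma_max_x_um))
  cat(sprintf("  gamma_prime_max = %.4g 1/um/s at x = %.2f um\n",
              x$gamma_prime_max, x$gamma_prime_max_x_um))
  invisible(x)
}

#' Flat peak record of one run
#'
#' Collects the headline observables of a solved case into one row for sweep
#' tables: peak shear rate and shear-rate gradient along the platelet
#' trajectory, and peak wall shear stress.
#'
#' @param profile a [platelet_trajectory_profile()] result.
#' @param map a [shear_rate_field()] result.
#' @return One-row data.frame with `gamma_max_s_inv`, `gamma_max_x_um`,
#'   `gamma_prime_max_um_inv_s_inv`, `tau_max_Pa`, `tau_max_dyn_cm2`,
#'   `tau_max_x_um`.
#' @export
peak_summary <- function(profile, map) {
  stopifnot(inherits(profile, "shear_profile"), inherits(map, "shear_map"))
  data.frame(
    gamma_max_s_inv = profile$gamma_max,
    gamma_max_x_um = profile$gamma_max_x_um,
    gamma_prime_max_um_inv_s_inv = profile$gamma_prime_max,
    tau_max_Pa = map$tau_max$value,
    tau_max_dyn_cm2 = 10 * map$tau_max$value,
    tau_max_x_um = map$tau_max$x
  )
}
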