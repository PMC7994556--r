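#' Parametric stenosis microchannel geometry
#'
#' Builds the hump-shaped micro-contraction as a pair of wall-profile
#' functions. The hump is a trapezoid-with-rounded-crest: linear ramps at the
#' contraction angle `alpha` on both sides, joined by a circular arc of radius
#' `fillet_radius` whose apex sits at `x = 0`. The rounding removes the corner
#' singularity that a sharp crest would imprint on the wall-shear-stress
#' field. `alpha` is measured between the ramp face and the unobstructed wall
#' (ramp slope `tan(alpha)`).
#'
#' Placements:
#' * `eccentric` — the full hump (height `S * Y0`) rises from the bottom wall,
#'   as when a device indents one side of a vessel;
#' * `concentric` — two mirrored humps of height `S * Y0 / 2`, one per wall,
#'   as in axisymmetric plaque narrowing.
#'
#' In both cases the throat width is `Y0 * (1 - S)`. The coordinate origin is
#' the hump apex (`x = 0`), with `y = 0` on the unobstructed bottom wall. The
#' analysis window is `x` in `[-X0/2, X0/2]`; straight entrance and exit runs
#' (`run_in`, `run_out`, default `3 * Y0`) extend beyond it so inflow is fully
#' developed before the contraction.
#'
#' @param S stenosis level, fraction of width occluded, in `[0, 1)`.
#' @param alpha contraction angle in degrees, in `(0, 90]`. Angles at (or
#'   numerically indistinguishable from) 90 degrees are rejected when `S > 0`
#'   because a vertical ramp face cannot be represented as a single-valued
#'   wall profile.
#' @param placement `"eccentric"` or `"concentric"`.
#' @param X0 axial analysis length (um).
#' @param Y0 channel width (um).
#' @param Z0 channel height (um); metadata for the operating-point formulas
#'   only, the solved plane is x-y.
#' @param fillet_radius crest rounding radius (um); internally capped at half
#'   the hump height so shallow humps stay well defined. The default (6 um)
#'   is the smallest rounding for which the wall-shear-stress peak of the
#'   steepest study geometry (85 degrees) sits on the crest middle rather
#'   than on the ramp shoulder: a much smaller radius concentrates shear at
#'   the shoulder tangency, which is exactly the corner pathology the
#'   rounding exists to remove.
#' @param run_in,run_out entrance/exit straight lengths (um) beyond the
#'   analysis window.
#' @return An object of class `stenosis_geometry` with wall-profile
#'   evaluators `y_bottom(x)`, `y_top(x)` and their slopes (um in, um out).
#' @export
#' @examples
#' g <- stenosis_geometry(S = 0.8, alpha = 85)
#' g$y_top(0) - g$y_bottom(0)  # throat width 20 um
stenosis_geometry <- function(S, alpha, placement = c("eccentric", "concentric"),
                              X0 = 200, Y0 = 100, Z0 = 130,
                              fillet_radius = 6, run_in = 3 * Y0, run_out = 3 * Y0) {
  placement <- match.arg(placement)
  if (!is.numeric(S) || length(S) != 1L || S < 0 || S >= 1)
    stop("'S' must be a stenosis fraction in [0, 1)")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 90)
    stop("'alpha' must be a contraction angle in (0, 90] degrees")
  if (X0 <= 0 || Y0 <= 0 || Z0 <= 0 || fillet_radius <= 0 ||
      run_in < 0 || run_out < 0)
    stop("channel dimensions must be positive")

  H_total <- S * Y0                       # total occlusion height
  H <- if (placement == "eccentric") H_total else H_total / 2
  a_rad <- alpha * pi / 180
  rf <- if (H > 0) min(fillet_radius, H / 2) else fillet_radius

  if (S > 0 && alpha > 89.99)
    stop("'alpha' = 90 degrees gives a vertical ramp face that cannot be a ",
         "single-valued wall profile; use alpha <= 89.99")

  # hump(x): 0 outside footprint, linear ramps at slope tan(alpha), circular
  # arc crest of radius rf centered on x = 0 with apex height H
  hump_fun <- make_hump(H, a_rad, rf)
  L_half <- hump_fun$L_half

  total_len <- X0 + run_in + run_out
  if (2 * L_half > total_len)
    stop(sprintf(paste0("hump axial footprint %.1f um exceeds the channel length ",
                        "%.1f um: the alpha = %g deg / S = %g combination is infeasible"),
                 2 * L_half, total_len, alpha, S))

  if (placement == "eccentric") {
    y_bottom <- hump_fun$f
    dy_bottom <- hump_fun$df
    ddy_bottom <- hump_fun$ddf
    y_top <- function(x) rep_len(Y0, length(x))
    dy_top <- function(x) rep_len(0, length(x))
    ddy_top <- function(x) rep_len(0, length(x))
  } else {
    y_bottom <- hump_fun$f
    dy_bottom <- hump_fun$df
    ddy_bottom <- hump_fun$ddf
    y_top <- function(x) Y0 - hump_fun$f(x)
    dy_top <- function(x) -hump_fun$df(x)
    ddy_top <- function(x) -hump_fun$ddf(x)
  }

  structure(list(
    S = S, alpha = alpha, placement = placement,
    X0 = X0, Y0 = Y0, Z0 = Z0,
    fillet_radius = rf, run_in = run_in, run_out = run_out,
    H = H, H_total = H_total, footprint = 2 * L_half,
    throat = Y0 * (1 - S),
    x_min = -(X0 / 2 + run_in), x_max = X0 / 2 + run_out,
    y_bottom = y_bottom, y_top = y_top,
    dy_bottom = dy_bottom, dy_top = dy_top,
    ddy_bottom = ddy_bottom, ddy_top = ddy_top
  ), class = "stenosis_geometry")
}

# Hump profile generator: height H, ramp angle a_rad, fillet radius rf.
# Per side (apex at x = 0): circular crest arc (radius rf, apex height H),
# straight ramp at slope tan(alpha), and a base fillet arc (radius rf)
# tangent to both the ramp and the flat wall. The profile is C1 everywhere;
# slope-discontinuous wall corners would imprint spurious shear-stress
# spikes on the discrete solution (the exact Stokes shear actually vanishes
# at such a concave corner, so nothing physical is lost by rounding it).
# Returns evaluator f, slope df and the half-footprint L_half (all um).
make_hump <- function(H, a_rad, rf) {
  if (H <= 0) {
    return(list(f = function(x) rep_len(0, length(x)),
                df = function(x) rep_len(0, length(x)),
                ddf = function(x) rep_len(0, length(x)),
                L_half = 0))
  }
  ta <- tan(a_rad)
  sa <- sin(a_rad)
  ca <- cos(a_rad)
  # shrink the fillet for shallow humps so a straight ramp segment remains
  rf <- min(rf, H / (2 * (1 - ca)))
  yc <- H - rf                            # crest arc center height
  xt <- rf * sa                           # crest tangency |x|
  Lc <- xt + (H - rf * (1 - ca)) / ta     # virtual ramp/ground corner |x|
  tb <- rf * (1 - ca) / sa                # base tangent length rf*tan(alpha/2)
  L_half <- Lc + tb                       # base fillet ground tangency |x|
  xb <- L_half                            # base arc center at (|x| = xb, y = rf)
  x_ramp_lo <- xb - rf * sa               # base-fillet/ramp tangency |x|
  f <- function(x) {
    ax <- abs(x)
    y <- numeric(length(x))
    base <- ax < L_half & ax >= x_ramp_lo
    y[base] <- rf - sqrt(pmax(rf^2 - (ax[base] - xb)^2, 0))
    ramp <- ax < x_ramp_lo & ax >= xt
    y[ramp] <- (Lc - ax[ramp]) * ta
    crest <- ax < xt
    y[crest] <- yc + sqrt(pmax(rf^2 - x[crest]^2, 0))
    y
  }
  df <- function(x) {
    ax <- abs(x)
    d <- numeric(length(x))
    base <- ax < L_half & ax >= x_ramp_lo
    dxb <- ax[base] - xb
    d[base] <- sign(x[base]) * dxb / sqrt(pmax(rf^2 - dxb^2, 1e-30))
    ramp <- ax < x_ramp_lo & ax >= xt
    d[ramp] <- -sign(x[ramp]) * ta
    crest <- ax < xt
    d[crest] <- -x[crest] / sqrt(pmax(rf^2 - x[crest]^2, 1e-30))
    d
  }
  ddf <- function(x) {
    ax <- abs(x)
    d <- numeric(length(x))
    base <- ax < L_half & ax >= x_ramp_lo
    s <- sqrt(pmax(rf^2 - (ax[base] - xb)^2, 1e-30))
    d[base] <- rf^2 / s^3
    crest <- ax < xt
    sc <- sqrt(pmax(rf^2 - x[crest]^2, 1e-30))
    d[crest] <- -rf^2 / sc^3
    d
  }
  list(f = f, df = df, ddf = ddf, L_half = L_half)
}

#' @export
print.stenosis_geometry <- function(x, ...) {
  cat("<stenosis_geometry> ", x$placement, "\n", sep = "")
  cat(sprintf("  S = %g  alpha = %g deg  throat = %g um\n", x$S, x$alpha, x$throat))
  cat(sprintf("  X0 x Y0 x Z0 = %g x %g x %g um  (runs %g / %g um)\n",
              x$X0, x$Y0, x$Z0, x$run_in, x$run_out))
  cat(sprintf("  hump footprint = %.2f um, fillet = %g um\n", x$footprint,
              x$fillet_radius))
  invisible(x)
}

#' Sample both wall profiles
#'
#' @param geom a [stenosis_geometry()].
#' @param x axial positions (um); default spans the analysis window.
#' @return data.frame with `x_um`, `y_bottom_um`, `y_top_um`.
#' @export
wall_profiles <- function(geom, x = seq(-geom$X0 / 2, geom$X0 / 2, length.out = 401)) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  data.frame(x_um = x, y_bottom_um = geom$y_bottom(x), y_top_um = geom$y_top(x))
}

#' Boundary-fitted structured grid for the stenosis channel
#'
#' Meshes the region between the wall profiles in three steps. First, axial
#' stations are distributed along the wall arc length (not along x), so steep
#' ramp faces receive proportionally finer axial spacing, with a smooth sinh
#' clustering toward the hump apex controlled by `cluster`. Second, a
#' transfinite map fills the gap: `ny` cells always span the local distance
#' between `y_bottom(x)` and `y_top(x)`, including the throat. Third, the
#' interior nodes are relaxed by Winslow elliptic smoothing with
#' Thomas-Middlecoff control functions (which preserve the boundary
#' clustering), bending the grid lines toward orthogonality at the walls;
#' without this step the nearly vertical ramp faces of high-angle
#' contractions leave the transverse grid direction almost tangent to the
#' wall, which ruins the accuracy of wall-shear extraction there.
#'
#' @param geom a [stenosis_geometry()].
#' @param nx,ny cell counts in the axial and transverse directions (>= 8).
#' @param cluster sinh stretching strength; 0 gives uniform axial spacing.
#' @param smooth number of elliptic smoothing sweeps (0 disables; the default
#'   is adequate for the geometries of interest).
#' @return An object of class `stenosis_grid` holding node coordinate
#'   matrices `X`, `Y` (m). Node `(i, j)` has `i = 1..nx+1`, `j = 1..ny+1`;
#'   `j = 1` lies on the bottom wall, `j = ny+1` on the top wall.
#' @export
generate_grid <- function(geom, nx, ny, cluster = 5, smooth = 250,
                          eta_cluster = 1.5) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  if (nx < 8 || ny < 8) stop("'nx' and 'ny' must be at least 8")

  Lin <- -geom$x_min   # um, positive
  Lout <- geom$x_max
  t <- seq(-1, 1, length.out = nx + 1)
  # Axial stations are distributed along the WALL ARC LENGTH, not along x:
  # on steep ramps (alpha near 90 deg the wall graph slope is ~11) equal arc
  # increments translate into proportionally finer x-spacing, so the hump is
  # resolved uniformly however steep it is. On top of the arc-length
  # equidistribution, a smooth sinh stretching clusters stations toward the
  # apex. The mapping x(t) is tabulated and splined; all axial metric terms
  # are evaluated discretely by the solver's own stencils.
  xs <- seq(-Lin, Lout, length.out = 32769)
  slope <- pmax(abs(geom$dy_bottom(xs)), abs(geom$dy_top(xs)))
  wgt <- sqrt(1 + slope^2)
  s_fine <- c(0, cumsum((wgt[-1] + wgt[-length(wgt)]) / 2 * diff(xs)))
  s_apex <- stats::approx(xs, s_fine, xout = 0)$y
  S_in <- s_apex; S_out <- s_fine[length(s_fine)] - s_apex
  if (cluster > 0) {
    beta <- cluster
    # s(t) = a * sinh(beta * (t - t0)) about the apex; endpoints pin a, t0
    f0 <- function(t0) sinh(beta * (1 - t0)) / sinh(beta * (1 + t0)) - S_out / S_in
    t0 <- stats::uniroot(f0, c(-0.999, 0.999), tol = 1e-14)$root
    a <- S_out / sinh(beta * (1 - t0))
    s_nodes <- s_apex + a * sinh(beta * (t - t0))
  } else {
    s_nodes <- (t + 1) / 2 * (S_in + S_out)
  }
  x_of_s <- stats::splinefun(s_fine, xs, method = "hyman")
  x_um <- x_of_s(pmin(pmax(s_nodes, 0), s_fine[length(s_fine)]))
  x_um[1] <- -Lin; x_um[nx + 1] <- Lout
  if (any(diff(x_um) <= 0)) stop("axial station distribution is not monotone")

  eta <- seq(0, 1, length.out = ny + 1)
  # two-sided tanh clustering of the transverse node placement toward both
  # walls: resolves the wall shear layers and keeps the wall-adjacent cells
  # compact where the axial stations are very fine
  eta_p <- if (eta_cluster > 0) {
    0.5 * (1 + tanh(eta_cluster * (2 * eta - 1)) / tanh(eta_cluster))
  } else eta
  eta_p[1] <- 0; eta_p[ny + 1] <- 1
  yb_um <- geom$y_bottom(x_um)
  yt_um <- geom$y_top(x_um)
  h_um <- yt_um - yb_um
  if (any(h_um <= 0)) stop("wall profiles cross: non-positive gap")

  # transfinite initialization, then elliptic relaxation of interior nodes
  X <- matrix(x_um, nx + 1, ny + 1)
  Y <- outer(yb_um, rep(1, ny + 1)) + outer(h_um, eta_p)  # (nx+1) x (ny+1), um
  if (smooth > 0 && geom$S > 0) {
    sm <- winslow_smooth(X, Y, sweeps = smooth)
    X <- sm$X; Y <- sm$Y
  }

  um <- 1e-6
  grid <- structure(list(
    nx = nx, ny = ny, t = t, eta = eta,
    deta = eta[2] - eta[1], dt = t[2] - t[1],
    X = X * um, Y = Y * um,
    x_um = x_um, y_um = Y,
    yb = yb_um * um, yt = yt_um * um, h = h_um * um,
    geom = geom,
    ops = new.env(parent = emptyenv())
  ), class = "stenosis_grid")

  areas <- grid_cell_areas(grid)
  if (any(areas <= 0)) {
    k <- which(areas <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("degenerate grid cell at (i = %d, j = %d): non-positive area",
                 k[1], k[2]))
  }
  grid
}

# Winslow elliptic smoothing with Thomas-Middlecoff control functions.
# Interior nodes relax toward a harmonic map while source terms derived from
# the boundary node spacing preserve the clustering; boundaries stay fixed.
# The sweep loop checkpoints the mesh and stops (reverting to the last good
# state) if the discrete one-sided Jacobian at any boundary node approaches
# zero: a partially smoothed valid mesh beats a fully smoothed tangled one.
winslow_smooth <- function(X, Y, sweeps, relax = 0.5, check_every = 25) {
  ni <- nrow(X); nj <- ncol(X)
  ic <- 2:(ni - 1); jc <- 2:(nj - 1)
  nodal_jac <- function(X, Y) {
    D1t <- d1_matrix(ni, 1); D1e <- d1_matrix(nj, 1)
    Xx <- as.matrix(D1t %*% X); Xe <- as.matrix(X %*% Matrix::t(D1e))
    Yx <- as.matrix(D1t %*% Y); Ye <- as.matrix(Y %*% Matrix::t(D1e))
    Xx * Ye - Xe * Yx
  }
  J0 <- min(nodal_jac(X, Y))
  floor_J <- 0.2 * J0
  X_ok <- X; Y_ok <- Y
  # control functions from the boundary distributions
  phi_of <- function(x, y) { # along a boundary line, -(r_s . r_ss)/|r_s|^2
    n <- length(x)
    xs <- (x[c(2:n, n)] - x[c(1, 1:(n - 1))]) / 2
    ys <- (y[c(2:n, n)] - y[c(1, 1:(n - 1))]) / 2
    xss <- x[c(2:n, n)] - 2 * x + x[c(1, 1:(n - 1))]
    yss <- y[c(2:n, n)] - 2 * y + y[c(1, 1:(n - 1))]
    p <- -(xs * xss + ys * yss) / pmax(xs^2 + ys^2, 1e-30)
    p[c(1, n)] <- 0
    pmax(pmin(p, 0.5), -0.5)
  }
  Pb <- phi_of(X[, 1], Y[, 1]); Pt <- phi_of(X[, nj], Y[, nj])
  Qi <- phi_of(X[1, ], Y[1, ]); Qo <- phi_of(X[ni, ], Y[ni, ])
  eta_w <- matrix(rep((jc - 1) / (nj - 1), each = length(ic)), length(ic))
  xi_w <- matrix(rep((ic - 1) / (ni - 1), length(jc)), length(ic))
  P <- (1 - eta_w) * matrix(Pb[ic], length(ic), length(jc)) +
    eta_w * matrix(Pt[ic], length(ic), length(jc))
  Q <- (1 - xi_w) * matrix(Qi[jc], length(ic), length(jc), byrow = TRUE) +
    xi_w * matrix(Qo[jc], length(ic), length(jc), byrow = TRUE)
  for (sweep in seq_len(sweeps)) {
    xE <- X[ic + 1, jc]; xW <- X[ic - 1, jc]; xN <- X[ic, jc + 1]; xS <- X[ic, jc - 1]
    yE <- Y[ic + 1, jc]; yW <- Y[ic - 1, jc]; yN <- Y[ic, jc + 1]; yS <- Y[ic, jc - 1]
    x_xi <- (xE - xW) / 2; y_xi <- (yE - yW) / 2
    x_et <- (xN - xS) / 2; y_et <- (yN - yS) / 2
    al <- x_et^2 + y_et^2
    be <- x_xi * x_et + y_xi * y_et
    ga <- x_xi^2 + y_xi^2
    xcr <- X[ic + 1, jc + 1] - X[ic + 1, jc - 1] - X[ic - 1, jc + 1] + X[ic - 1, jc - 1]
    ycr <- Y[ic + 1, jc + 1] - Y[ic + 1, jc - 1] - Y[ic - 1, jc + 1] + Y[ic - 1, jc - 1]
    den <- 2 * (al + ga)
    xn <- (al * (xE + xW) + ga * (xN + xS) - 0.5 * be * xcr +
           al * P * x_xi + ga * Q * x_et) / den
    yn <- (al * (yE + yW) + ga * (yN + yS) - 0.5 * be * ycr +
           al * P * y_xi + ga * Q * y_et) / den
    X[ic, jc] <- (1 - relax) * X[ic, jc] + relax * xn
    Y[ic, jc] <- (1 - relax) * Y[ic, jc] + relax * yn
    if (sweep %% check_every == 0) {
      if (min(nodal_jac(X, Y)) < floor_J) {
        return(list(X = X_ok, Y = Y_ok))
      }
      X_ok <- X; Y_ok <- Y
    }
  }
  list(X = X, Y = Y)
}

#' Cell areas of a structured grid (shoelace on each quad)
#'
#' @param grid a [generate_grid()] result.
#' @return `nx` by `ny` matrix of signed cell areas (m^2); all positive on a
#'   valid grid.
#' @export
grid_cell_areas <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  X <- grid$X
  Y <- grid$Y
  i <- 1:nx; j <- 1:ny
  x1 <- X[i, j]; y1 <- Y[i, j]
  x2 <- X[i + 1, j]; y2 <- Y[i + 1, j]
  x3 <- X[i + 1, j + 1]; y3 <- Y[i + 1, j + 1]
  x4 <- X[i, j + 1]; y4 <- Y[i, j + 1]
  0.5 * ((x1 * y2 - x2 * y1) + (x2 * y3 - x3 * y2) +
         (x3 * y4 - x4 * y3) + (x4 * y1 - x1 * y4))
}

#' @export
print.stenosis_grid <- function(x, ...) {
  cat(sprintf("<stenosis_grid> %d x %d cells (%d nodes)\n",
              x$nx, x$ny, (x$nx + 1) * (x$ny + 1)))
  cat(sprintf("  x span %.0f..%.0f um, min dx = %.3g um, min gap = %.3g um\n",
              min(x$x_um), max(x$x_um), min(diff(x$x_um)), min(x$h) * 1e6))
  invisible(x)
}

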