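# Sparse finite-difference operators on the curvilinear structured grid.
#
# The grid is a logical (xi, eta) rectangle with uniform computational
# spacing and node coordinates X, Y. Physical derivatives follow from the
# inverse mapping:
#   f_x = a f_xi + b f_eta     a =  Y_eta / J,  b = -Y_xi / J
#   f_y = c f_xi + d f_eta     c = -X_eta / J,  d =  X_xi / J
#   J = X_xi Y_eta - X_eta Y_xi
# Second derivatives expand by the product rule,
#   f_xx = a^2 f_xixi + 2ab f_xieta + b^2 f_etaeta + (Dx a) f_xi + (Dx b) f_eta
# and analogously for f_yy with (c, d) and Dy.
#
# ALL metric factors are evaluated DISCRETELY with the same 1D stencils that
# act on the solution ("freestream preservation"): Dx and Dy applied to the
# coordinate fields return exactly (1, 0) and (0, 1), so the mapping itself
# injects no spurious sources even where the walls are steep and strongly
# curved. Compact central second-derivative stencils are used inside (the
# composition of first derivatives would leave weakly damped odd-even modes),
# with second-order one-sided closures on the boundaries.

# 1D first-derivative matrix on n uniform points with spacing d
d1_matrix <- function(n, d) {
  i <- c(2:(n - 1), 2:(n - 1), 1, 1, 1, n, n, n)
  j <- c(1:(n - 2), 3:n, 1, 2, 3, n, n - 1, n - 2)
  v <- c(rep(-0.5, n - 2), rep(0.5, n - 2), -1.5, 2, -0.5, 1.5, -2, 0.5) / d
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n))
}

# 1D second-derivative matrix on n uniform points with spacing d
d2_matrix <- function(n, d) {
  i <- c(rep(2:(n - 1), 3), rep(1, 4), rep(n, 4))
  j <- c(1:(n - 2), 2:(n - 1), 3:n, 1:4, n:(n - 3))
  v <- c(rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2),
         2, -5, 4, -1, 2, -5, 4, -1) / d^2
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n))
}

# Build (and cache on the grid) the physical-space operators
grid_operators <- function(grid) {
  ops <- grid$ops
  if (!is.null(ops$Dx)) return(ops)
  nx <- grid$nx; ny <- grid$ny
  ni <- nx + 1; nj <- ny + 1
  It <- Matrix::Diagonal(ni)
  Ie <- Matrix::Diagonal(nj)
  # node ordering k = i + (j-1)*ni (column-major over (i, j) matrices)
  Dt <- Matrix::kronecker(Ie, d1_matrix(ni, grid$dt))
  De <- Matrix::kronecker(d1_matrix(nj, grid$deta), It)
  Dtt <- Matrix::kronecker(Ie, d2_matrix(ni, grid$dt))
  Dee <- Matrix::kronecker(d2_matrix(nj, grid$deta), It)
  Dte <- Dt %*% De

  Xv <- as.vector(grid$X); Yv <- as.vector(grid$Y)
  X_xi <- matrix(as.vector(Dt %*% Xv), ni, nj)
  X_et <- matrix(as.vector(De %*% Xv), ni, nj)
  Y_xi <- matrix(as.vector(Dt %*% Yv), ni, nj)
  Y_et <- matrix(as.vector(De %*% Yv), ni, nj)
  J <- X_xi * Y_et - X_et * Y_xi
  if (any(J <= 0)) {
    k <- which(J <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("degenerate mapping at node (i = %d, j = %d): non-positive Jacobian",
                 k[1], k[2]))
  }
  a <- Y_et / J; b <- -Y_xi / J
  cc <- -X_et / J; d <- X_xi / J
  dg <- function(m) Matrix::Diagonal(x = as.vector(m))

  Dx <- dg(a) %*% Dt + dg(b) %*% De
  Dy <- dg(cc) %*% Dt + dg(d) %*% De
  Dxx <- dg(a^2) %*% Dtt + dg(2 * a * b) %*% Dte + dg(b^2) %*% Dee +
    dg(as.vector(Dx %*% as.vector(a))) %*% Dt +
    dg(as.vector(Dx %*% as.vector(b))) %*% De
  Dyy <- dg(cc^2) %*% Dtt + dg(2 * cc * d) %*% Dte + dg(d^2) %*% Dee +
    dg(as.vector(Dy %*% as.vector(cc))) %*% Dt +
    dg(as.vector(Dy %*% as.vector(d))) %*% De

  ops$Dt <- Dt; ops$De <- De
  ops$Dx <- Dx; ops$Dy <- Dy
  ops$Dxx <- Dxx; ops$Dyy <- Dyy
  ops$Lap <- Dxx + Dyy
  ops$J <- J
  ops
}

# Apply a sparse operator to a field stored as an (nx+1) x (ny+1) matrix
op_apply <- function(op, f) {
  dim_f <- dim(f)
  out <- as.vector(op %*% as.vector(f))
  dim(out) <- dim_f
  out
}
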