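# Linear elastic mechanical equilibrium driven by the tumor-cell gradient.
#
# The momentum balance div(sigma) = lambda_f * grad(N_t) is discretized with
# second-order central differences on the voxel grid: variable-coefficient
# second derivatives use the conservative three-point stencil with
# face-averaged coefficients, mixed derivatives use nested central first
# differences. The central first-difference operators are kept exactly
# skew-symmetric (their end rows couple only to the interior, equivalent to
# extending fields by zero), which makes the assembled operator exactly
# symmetric; with the zero-normal-displacement degrees of freedom
# eliminated, the negated system is positive definite and is factorized
# once per domain with a cached supernodal Cholesky, so each equilibrium
# solve is a pair of triangular solves.

# binary dilation of a logical array by k voxels per axis (separable)
dilate_mask <- function(mask, k = 1L) {
  out <- mask
  n <- dim(mask)
  for (axis in 1:3) {
    acc <- out
    for (s in seq_len(k)) {
      lo <- out; hi <- out
      if (axis == 1L && n[1] > s) {
        lo[(1 + s):n[1], , ] <- lo[(1 + s):n[1], , ] | out[1:(n[1] - s), , ]
        hi[1:(n[1] - s), , ] <- hi[1:(n[1] - s), , ] | out[(1 + s):n[1], , ]
      } else if (axis == 2L && n[2] > s) {
        lo[, (1 + s):n[2], ] <- lo[, (1 + s):n[2], ] | out[, 1:(n[2] - s), ]
        hi[, 1:(n[2] - s), ] <- hi[, 1:(n[2] - s), ] | out[, (1 + s):n[2], ]
      } else if (axis == 3L && n[3] > s) {
        lo[, , (1 + s):n[3]] <- lo[, , (1 + s):n[3]] | out[, , 1:(n[3] - s)]
        hi[, , 1:(n[3] - s)] <- hi[, , 1:(n[3] - s)] | out[, , (1 + s):n[3]]
      }
      acc <- acc | lo | hi
    }
    out <- acc
  }
  out
}

# 1-D central first-derivative operator, exactly skew-symmetric (end rows
# use the half stencil, i.e. fields are extended by zero)
d1_matrix <- function(n, h) {
  if (n == 1L) return(Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(1, 1)))
  i <- c(1:(n - 1), 2:n)
  j <- c(2:n, 1:(n - 1))
  x <- c(rep(1 / (2 * h), n - 1), rep(-1 / (2 * h), n - 1))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

# 3-D first-derivative operator along `axis` (x fastest, column-major)
grad_op <- function(shape, spacing, axis) {
  mats <- lapply(1:3, function(a) {
    if (a == axis) d1_matrix(shape[a], spacing[a]) else Matrix::Diagonal(shape[a])
  })
  Matrix::kronecker(mats[[3]], Matrix::kronecker(mats[[2]], mats[[1]]))
}

# variable-coefficient second derivative d/dxa ( c d/dxa u ) with
# face-averaged coefficients (zero-flux natural boundary)
div_c_grad_op <- function(cmap, shape, spacing, axis) {
  n <- prod(shape)
  I <- array(seq_len(n), dim = shape)
  idx_lo <- switch(axis,
                   I[-shape[1], , , drop = FALSE],
                   I[, -shape[2], , drop = FALSE],
                   I[, , -shape[3], drop = FALSE])
  stride <- c(1, shape[1], shape[1] * shape[2])[axis]
  i <- as.vector(idx_lo)
  j <- i + stride
  if (length(i) == 0L)
    return(Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(n, n)))
  cf <- (cmap[i] + cmap[j]) / 2 / spacing[axis]^2
  Matrix::sparseMatrix(i = c(i, i, j, j), j = c(i, j, j, i),
                       x = c(-cf, cf, -cf, cf), dims = c(n, n))
}

# assemble (and cache) the elasticity operator for a domain
elasticity_operator <- function(domain) {
  cache <- domain$cache
  if (!is.null(cache$elasticity)) return(cache$elasticity)

  g <- domain$grid
  n <- prod(g$shape)
  if (n < 8) stop("elasticity solver error: domain grid is too small")
  G <- as.vector(domain$shear_modulus)
  nu <- domain$poisson_ratio
  a <- 2 * G * (1 - nu) / (1 - 2 * nu)   # normal self-coefficient
  b <- 2 * G * nu / (1 - 2 * nu)         # normal cross-coefficient

  D <- lapply(1:3, function(ax) grad_op(g$shape, g$spacing, ax))
  L <- function(cvec, ax) div_c_grad_op(cvec, g$shape, g$spacing, ax)
  Dg <- function(ax, cvec, ax2) D[[ax]] %*% Matrix::Diagonal(x = cvec) %*% D[[ax2]]

  blocks <- vector("list", 9)
  dim(blocks) <- c(3, 3)
  for (p in 1:3) for (q in 1:3) {
    if (p == q) {
      others <- setdiff(1:3, p)
      blocks[[p, q]] <- L(a, p) + L(G, others[1]) + L(G, others[2])
    } else {
      blocks[[p, q]] <- Dg(p, b, q) + Dg(q, G, p)
    }
  }
  A <- rbind(cbind(blocks[[1, 1]], blocks[[1, 2]], blocks[[1, 3]]),
             cbind(blocks[[2, 1]], blocks[[2, 2]], blocks[[2, 3]]),
             cbind(blocks[[3, 1]], blocks[[3, 2]], blocks[[3, 3]]))

  # Constraints, eliminated from the system (keeping it symmetric):
  # zero normal displacement on each pair of boundary faces, and full
  # clamping outside the brain mask dilated by two voxels per axis -- the
  # tissue there carries no load (forces vanish with N_t) and the rim of
  # the dilated mask acts as the rigid skull.
  I3 <- array(seq_len(n), dim = g$shape)
  bc_axis <- list(as.vector(I3[c(1, g$shape[1]), , ]),
                  as.vector(I3[, c(1, g$shape[2]), ]),
                  as.vector(I3[, , c(1, g$shape[3])]))
  bc <- logical(3 * n)
  for (p in 1:3) bc[(p - 1) * n + bc_axis[[p]]] <- TRUE
  mech_mask <- dilate_mask(domain$brain_mask, 2L)
  bc[!rep(as.vector(mech_mask), 3)] <- TRUE
  free <- which(!bc)
  if (!length(free))
    stop("elasticity solver error: empty mechanical domain")

  # -A restricted to the free dofs is the (positive definite) discrete
  # elastic-energy operator
  K <- Matrix::forceSymmetric(-A[free, free, drop = FALSE])
  fac <- tryCatch(Matrix::Cholesky(K, LDL = FALSE, super = TRUE),
                  error = function(e)
                    stop("elasticity solver error: singular discrete system (",
                         conditionMessage(e), ")"))

  op <- list(A = A, chol = fac, D = D, a = a, b = b, G = G, bc = bc,
             free = free, n = n)
  cache$elasticity <- op
  op
}

#' Solve mechanical equilibrium for a tumor-cell field
#'
#' Solves the linear elastic balance in which the tumor-cell gradient exerts
#' a body force with coupling constant `lambda_f` on the tissue, under zero
#' normal displacement (free tangential slip) at the domain boundary, and
#' returns displacements, strains, the Hooke's-law stress tensor with
#' tissue-dependent shear modulus, and the von Mises effective stress.
#'
#' @param N_t tumor-fraction `scalar_field` on the domain grid.
#' @param domain a [build_tissue_domain()] domain.
#' @param lambda_f force coupling constant, Pa (>= 0).
#' @return An object of class `stress_state`: `displacement` (n x 3 matrix,
#'   mm), `strain` and `stress` (lists of the six independent tensor
#'   component arrays; stress in Pa), `von_mises` (a `"stress"`
#'   `scalar_field`, Pa).
#' @export
solve_equilibrium <- function(N_t, domain, lambda_f) {
  if (lambda_f < 0) stop("lambda_f must be >= 0")
  g <- domain$grid
  if (!grids_identical(N_t$grid, g)) stop("N_t grid does not match the domain")
  op <- elasticity_operator(domain)
  n <- op$n
  nt <- as.vector(N_t$values)

  rhs <- c(as.vector(op$D[[1]] %*% nt), as.vector(op$D[[2]] %*% nt),
           as.vector(op$D[[3]] %*% nt)) * lambda_f

  if (lambda_f == 0 || max(abs(rhs)) == 0) {
    u <- matrix(0, n, 3)
  } else {
    sol_free <- tryCatch(
      as.vector(Matrix::solve(op$chol, -rhs[op$free], system = "A")),
      error = function(e)
        stop("elasticity solver error: ", conditionMessage(e)))
    sol <- numeric(3 * n)
    sol[op$free] <- sol_free
    u <- matrix(sol, n, 3)
  }

  dxu <- function(p, q) as.vector(op$D[[q]] %*% u[, p])
  eps <- list(xx = dxu(1, 1), yy = dxu(2, 2), zz = dxu(3, 3),
              xy = 0.5 * (dxu(1, 2) + dxu(2, 1)),
              xz = 0.5 * (dxu(1, 3) + dxu(3, 1)),
              yz = 0.5 * (dxu(2, 3) + dxu(3, 2)))
  sig <- list(xx = op$a * eps$xx + op$b * (eps$yy + eps$zz),
              yy = op$a * eps$yy + op$b * (eps$xx + eps$zz),
              zz = op$a * eps$zz + op$b * (eps$xx + eps$yy),
              xy = 2 * op$G * eps$xy,
              xz = 2 * op$G * eps$xz,
              yz = 2 * op$G * eps$yz)

  shp <- g$shape
  to_arr <- function(v) array(v, dim = shp)
  strain <- lapply(eps, to_arr)
  stress <- lapply(sig, to_arr)
  vm <- von_mises(stress)

  structure(list(displacement = u, strain = strain, stress = stress,
                 von_mises = scalar_field(vm, g, "stress", check = FALSE)),
            class = "stress_state")
}

#' Von Mises effective stress of a symmetric stress tensor field
#'
#' `sqrt( ((sxx-syy)^2 + (syy-szz)^2 + (szz-sxx)^2)/2 +
#'        3 (sxy^2 + sxz^2 + syz^2) )`, elementwise.
#'
#' @param stress list with components `xx, yy, zz, xy, xz, yz` (arrays or
#'   vectors of equal shape).
#' @return Array of von Mises stresses (same units as the input, >= 0).
#' @export
von_mises <- function(stress) {
  with(stress, sqrt(0.5 * ((xx - yy)^2 + (yy - zz)^2 + (zz - xx)^2) +
                      3 * (xy^2 + xz^2 + yz^2)))
}

#' Stress-modulated diffusion field
#'
#' Mechanical stress exponentially suppresses random motility:
#' `D(x) = D_0 * exp(-gamma * sigma_vm(x))` with the von Mises stress
#' expressed in kPa (the stress sensitivity `gamma` is per kPa).
#'
#' @param D_0 stress-free diffusion coefficient, mm^2/day.
#' @param sigma_vm von Mises stress `scalar_field` in Pa.
#' @param gamma_stress stress sensitivity, 1/kPa.
#' @return A `scalar_field` of diffusion coefficients (mm^2/day).
#' @export
stress_modulated_diffusion <- function(D_0, sigma_vm, gamma_stress) {
  if (D_0 < 0 || gamma_stress < 0)
    stop("D_0 and gamma_stress must be >= 0")
  vals <- D_0 * exp(-gamma_stress * sigma_vm$values / 1000)
  scalar_field(vals, sigma_vm$grid, "generic", check = FALSE)
}
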