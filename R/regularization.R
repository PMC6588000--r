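# Derivative operators and norms for TGV2 / TV regularization.
#
# The gradient uses finite forward differences with replicate (Neumann)
# boundary; the symmetrized derivative E uses the backward-difference
# companion D with D^T = -grad, which makes every operator/adjoint pair
# exact in the discrete inner products (required by the primal-dual
# convergence condition).  Symmetric tensor fields store 6 components
# (xx, yy, zz, xy, xz, yz); the off-diagonals carry weight 2 in all inner
# products and norms, compensating the symmetrization.
#
# "2D regularization" (for the 2D-vs-3D comparisons) zeroes every
# z-derivative while keeping shapes unchanged, so a single code path serves
# both modes.

SYM_WEIGHTS <- c(1, 1, 1, 2, 2, 2)

field_weights <- function(field) {
  nc <- dim(field)[length(dim(field)) - 1L]
  if (nc == 6L) SYM_WEIGHTS else rep(1, nc)
}

#' Gradient of a multi-channel volume (forward differences)
#'
#' @param u complex array `(nx, ny, nz, nu)` (a trailing unknown axis of 1
#'   is added to plain volumes).
#' @param reg_dim 3 for full 3D derivatives, 2 to zero the z-derivative
#'   (2D-regularization mode).
#' @return vector field `(nx, ny, nz, 3, nu)`.
#' @export
grad3 <- function(u, reg_dim = 3) {
  if (length(dim(u)) == 3L) dim(u) <- c(dim(u), 1L)
  d <- dim(u)
  out <- cpp_grad3(ensure_complex(u), d[1], d[2], d[3], d[4], reg_dim < 3)
  dim(out) <- c(d[1:3], 3L, d[4])
  out
}

#' Adjoint of [grad3()] (negative divergence)
#'
#' @param v vector field `(nx, ny, nz, 3, nu)`.
#' @inheritParams grad3
#' @return complex array `(nx, ny, nz, nu)`.
#' @export
grad3_adjoint <- function(v, reg_dim = 3) {
  d <- dim(v)
  stopifnot(length(d) == 5L, d[4] == 3L)
  out <- cpp_grad3_adj(ensure_complex(v), d[1], d[2], d[3], d[5],
                       reg_dim < 3)
  dim(out) <- d[c(1:3, 5)]
  out
}

#' Symmetrized derivative E of a vector field
#'
#' \eqn{Ev = (\nabla v + \nabla v^T)/2} discretized with backward
#' differences (the adjoint-consistent companion of the forward-difference
#' gradient).
#'
#' @param v vector field `(nx, ny, nz, 3, nu)`.
#' @inheritParams grad3
#' @return symmetric tensor field `(nx, ny, nz, 6, nu)`, components
#'   xx, yy, zz, xy, xz, yz.
#' @export
symgrad <- function(v, reg_dim = 3) {
  d <- dim(v)
  stopifnot(length(d) == 5L, d[4] == 3L)
  out <- cpp_symgrad(ensure_complex(v), d[1], d[2], d[3], d[5], reg_dim < 3)
  dim(out) <- c(d[1:3], 6L, d[5])
  out
}

#' Adjoint of [symgrad()] in the weighted tensor inner product
#'
#' The adjoint is taken with respect to the tensor inner product that
#' weights off-diagonal components by 2; with that convention the factor
#' 1/2 of the symmetrization cancels and the adjoint is the clean
#' (negative) tensor divergence.
#'
#' @param xi symmetric tensor field `(nx, ny, nz, 6, nu)`.
#' @inheritParams grad3
#' @return vector field `(nx, ny, nz, 3, nu)`.
#' @export
symgrad_adjoint <- function(xi, reg_dim = 3) {
  d <- dim(xi)
  stopifnot(length(d) == 5L, d[4] == 6L)
  out <- cpp_symgrad_adj(ensure_complex(xi), d[1], d[2], d[3], d[5],
                         reg_dim < 3)
  dim(out) <- c(d[1:3], 3L, d[5])
  out
}

# pointwise pooled squared magnitude of a field: sums |.|^2 with component
# weights over the component axis and, for joint coupling, the unknown axis
pooled_sq <- function(field, weights, joint) {
  d <- dim(field)
  vox <- prod(d[1:3])
  out <- cpp_pooled_sq(ensure_complex(field), vox, d[4], d[5], weights,
                       joint)
  if (joint) as.vector(out) else out
}

#' Joint (Frobenius-coupled) field norm
#'
#' \eqn{\|v\|_{1,2,2} = \sum_{voxels} \sqrt{\sum_i \sum_{comp} w\,|v|^2}}:
#' the pointwise 2-norm pools the derivative components and all unknowns
#' inside the square root (Frobenius coupling across parameter maps), and
#' the result is summed over voxels.  Tensor fields use off-diagonal weight
#' 2.
#'
#' @param field array `(nx, ny, nz, ncomp, nu)`.
#' @param weights per-component weights; defaults to 1 for vector fields
#'   and `(1,1,1,2,2,2)` for 6-component tensor fields.
#' @return scalar.
#' @export
norm_122 <- function(field, weights = field_weights(field)) {
  sum(sqrt(pooled_sq(field, weights, joint = TRUE)))
}

#' Separate field norm
#'
#' \eqn{\|v\|_{1,2}}: as [norm_122()] but the square root is taken per
#' unknown and the results summed, i.e. no coupling across parameter maps.
#'
#' @inheritParams norm_122
#' @return scalar.
#' @export
norm_12 <- function(field, weights = field_weights(field)) {
  sum(sqrt(pooled_sq(field, weights, joint = FALSE)))
}

#' Pointwise projection onto the dual norm ball
#'
#' Projects a dual field onto `{ ||z||_inf <= radius }` where the pointwise
#' norm pools components (and unknowns, for joint coupling):
#' `z <- z / max(1, ||z||_2 / radius)` voxelwise.
#'
#' @param z dual field `(nx, ny, nz, ncomp, nu)`.
#' @param radius ball radius (> 0).
#' @param coupling `"joint"` pools unknowns inside the pointwise norm,
#'   `"separate"` projects each unknown's field independently.
#' @param weights per-component weights (see [norm_122()]).
#' @return projected field, same shape.
#' @export
project_dual_ball <- function(z, radius, coupling = c("joint", "separate"),
                              weights = field_weights(z)) {
  coupling <- match.arg(coupling)
  stopifnot(radius > 0)
  d <- dim(z)
  out <- cpp_project_ball(ensure_complex(z), prod(d[1:3]), d[4], d[5],
                          weights, radius, coupling == "joint")
  dim(out) <- d
  out
}

#' TGV2 objective value at a given (u, v)
#'
#' Evaluates \eqn{\alpha_1 \|\nabla u - v\| + \alpha_0 \|E v\|} with the
#' joint or separate norm.  The TGV2 functional itself is the minimum of
#' this expression over v (zero exactly when u is affine and v its
#' gradient).
#'
#' @param u unknowns `(nx, ny, nz, nu)` (or a plain volume).
#' @param v auxiliary vector field `(nx, ny, nz, 3, nu)`.
#' @param alpha1,alpha0 first/second-order weights (ratio 1/2 by default in
#'   the reconstruction).
#' @param coupling `"joint"` or `"separate"`.
#' @inheritParams grad3
#' @return scalar.
#' @export
tgv2_value <- function(u, v, alpha1 = 1, alpha0 = 2,
                       coupling = c("joint", "separate"), reg_dim = 3) {
  coupling <- match.arg(coupling)
  nrm <- if (coupling == "joint") norm_122 else norm_12
  g <- grad3(u, reg_dim)
  alpha1 * nrm(g - v) + alpha0 * nrm(symgrad(v, reg_dim))
}

#' Total variation of multi-channel volumes
#'
#' @inheritParams tgv2_value
#' @return scalar \eqn{\|\nabla u\|} with the selected coupling.
#' @export
tv_value <- function(u, coupling = c("joint", "separate"), reg_dim = 3) {
  coupling <- match.arg(coupling)
  nrm <- if (coupling == "joint") norm_122 else norm_12
  nrm(grad3(u, reg_dim))
}
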