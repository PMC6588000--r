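# Internal conventions
# --------------------
# volumes:          complex arrays dim c(nx, ny, nz)
# coil maps:        complex arrays dim c(nx, ny, nz, nc)
# k-space data:     complex arrays dim c(ns, nspokes, nz, nc, np)
# solver unknowns:  complex arrays dim c(nx, ny, nz, nu)   (nu = 2: M0, T1)
# vector fields:    complex arrays dim c(nx, ny, nz, 3, nu) (x, y, z deriv)
# tensor fields:    complex arrays dim c(nx, ny, nz, 6, nu)
#                   components xx, yy, zz, xy, xz, yz; off-diagonals carry
#                   weight 2 in all inner products and norms (symmetrization)
#
# All inner products over complex fields are the real part of the Hermitian
# inner product.

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce to complex storage preserving dim, copying only when needed
ensure_complex <- function(x) {
  if (is.complex(x)) return(x)
  y <- as.complex(x)
  dim(y) <- dim(x)
  y
}

stopifnot_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(Re(x))) || (is.complex(x) && !all(is.finite(Im(x)))))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

# real part of the Hermitian inner product <a, b> = sum(Conj(a) * b)
cdot <- function(a, b) sum(Re(a) * Re(b)) + sum(Im(a) * Im(b))

cnorm2 <- function(a) sum(Re(a)^2) + sum(Im(a)^2)

cnorm <- function(a) sqrt(cnorm2(a))

# complex white Gaussian array with unit variance per complex sample
crandn <- function(dims) {
  n <- prod(dims)
  array(complex(real = stats::rnorm(n, sd = sqrt(0.5)),
                imaginary = stats::rnorm(n, sd = sqrt(0.5))), dim = dims)
}

# run expr with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# ---- shift / finite-difference primitives --------------------------------
# All operate along one of the first three dimensions of an array with an
# arbitrary number of trailing dimensions.

shift_slices <- function(a, d, ord) {
  idx <- lapply(dim(a), seq_len)
  idx[[d]] <- ord
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

zero_plane <- function(a, d, i) {
  idx <- lapply(dim(a), seq_len)
  idx[[d]] <- i
  do.call(`[<-`, c(list(a), idx, list(value = 0)))
}

# forward difference with replicate (Neumann) boundary: last plane is 0
fdiff <- function(a, d) {
  n <- dim(a)[d]
  if (n == 1L) return(array(0i, dim = dim(a)))
  shift_slices(a, d, c(2:n, n)) - a
}

# backward difference with replicated left boundary: annihilates constants
#   (D v)(j) = v(j) - v(j-1) for j > 1, 0 at j = 1
bdiff <- function(a, d) {
  n <- dim(a)[d]
  if (n == 1L) return(array(0i, dim = dim(a)))
  a - shift_slices(a, d, c(1, 1:(n - 1)))
}

# exact transpose of fdiff: (grad^T v)(j) = v(j-1) 1[j>1] - v(j) 1[j<n]
fdiff_adjoint <- function(v, d) {
  n <- dim(v)[d]
  if (n == 1L) return(array(0i, dim = dim(v)))
  zero_plane(shift_slices(v, d, c(1, 1:(n - 1))), d, 1) - zero_plane(v, d, n)
}

# exact transpose of bdiff: (D^T w)(j) = w(j) 1[j>1] - w(j+1) 1[j<n]
bdiff_adjoint <- function(w, d) {
  n <- dim(w)[d]
  if (n == 1L) return(array(0i, dim = dim(w)))
  zero_plane(w, d, 1) - zero_plane(shift_slices(w, d, c(2:n, n)), d, n)
}

# ---- small formatting helpers -------------------------------------------

fmt_si <- function(x, digits = 3) formatC(x, digits = digits, format = "g")
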