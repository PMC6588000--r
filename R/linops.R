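# Generic algebra over solver variables: a "variable" is either a complex
# array or a named list of complex arrays (one level deep).  Optional
# per-block component weights (e.g. the factor-2 symmetrization weights of
# tensor fields) enter all inner products through la_dot's `w` argument.

la_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- mapply(f, x, y, SIMPLIFY = FALSE)
    out
  } else f(x, y)
}

la_map1 <- function(f, x) if (is.list(x)) lapply(x, f) else f(x)

# a*x + b*y over matching structures
la_lin <- function(a, x, b, y) {
  f <- function(xi, yi) {
    r <- a * xi + b * yi
    if (!is.null(dim(xi))) dim(r) <- dim(xi)
    r
  }
  la_map2(f, x, y)
}

la_scale <- function(a, x) la_map1(function(xi) a * xi, x)

la_zero_like <- function(x)
  la_map1(function(xi) array(0i, dim = dim(xi) %||% length(xi)), x)

la_rand_like <- function(x)
  la_map1(function(xi) {
    d <- dim(xi) %||% length(xi)
    crandn(d)
  }, x)

# weighted real inner product; w is NULL, or a list (per block) of NULL /
# a weight vector applied along the component dimension (second-to-last)
la_dot <- function(x, y, w = NULL) {
  if (!is.list(x)) return(cdot_weighted(x, y, w))
  tot <- 0
  for (nm in names(x))
    tot <- tot + cdot_weighted(x[[nm]], y[[nm]], if (is.null(w)) NULL else w[[nm]])
  tot
}

cdot_weighted <- function(a, b, w = NULL) {
  if (is.null(w)) return(cdot(a, b))
  d <- dim(a)
  comp_dim <- length(d) - 1L   # component axis of field arrays
  stopifnot(length(w) == d[comp_dim])
  per <- prod(d[seq_len(comp_dim - 1L)])
  ww <- rep(rep(w, each = per), times = d[length(d)])
  sum(ww * (Re(a) * Re(b) + Im(a) * Im(b)))
}

la_norm <- function(x, w = NULL) sqrt(max(la_dot(x, x, w), 0))

#' Largest singular value of a linear operator by power iteration
#'
#' Estimates the operator (spectral) norm of a linear map given as a
#' forward/adjoint pair, by power iteration on the normal operator.  Used to
#' initialize the primal-dual step sizes, which must satisfy
#' \eqn{\sigma\tau\|K\|^2 < 1}.
#'
#' @param forward,adjoint functions implementing the map and its adjoint.
#' @param template an input-shaped object (complex array or named list of
#'   arrays) used to draw the random start vector.
#' @param n_iters number of power iterations.
#' @param seed integer seed making the estimate deterministic.
#' @param warm_start optional start vector from a previous estimate.
#' @return list with `norm` (the estimate) and `vector` (the final iterate,
#'   reusable as a warm start).  `adjoint` must be the adjoint with respect
#'   to the same (possibly weighted) inner products used elsewhere; the
#'   estimate is then the operator norm in that geometry.
#' @export
estimate_operator_norm <- function(forward, adjoint, template, n_iters = 20,
                                   seed = 1, warm_start = NULL) {
  x <- warm_start %||% with_seed(seed, la_rand_like(template))
  nrm <- la_norm(x)
  if (nrm == 0) return(list(norm = 0, vector = x))
  x <- la_scale(1 / nrm, x)
  est <- 0
  for (i in seq_len(n_iters)) {
    z <- adjoint(forward(x))     # normal operator K^H K applied to unit x
    nz <- la_norm(z)
    if (nz == 0) return(list(norm = 0, vector = x))
    est <- sqrt(nz)              # ||K^H K x|| -> sigma_max^2
    x <- la_scale(1 / nz, z)
  }
  list(norm = est, vector = x)
}
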