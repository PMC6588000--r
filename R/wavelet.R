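# Orthonormal Daubechies-4 wavelet transform, periodized, applied per slice
# (2D) even in 3D reconstructions: the few-slice geometry of stack-of-stars
# acquisitions leaves too little support along z for a useful decomposition
# there.  The transform matrix per size is cached; orthonormality makes the
# adjoint equal the inverse, which the round-trip and Parseval tests pin
# down.

.db4_cache <- new.env(parent = emptyenv())

db4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  list(h = h, g = g)
}

# one-level periodized analysis matrix (n x n), rows 1..n/2 approximation,
# rows n/2+1..n detail
db4_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.db4_cache[[key]])) return(.db4_cache[[key]])
  stopifnot(n %% 2 == 0, n >= 4)
  f <- db4_filters()
  Tm <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    cols <- ((2 * (k - 1) + 0:3) %% n) + 1
    for (m in 1:4) {
      Tm[k, cols[m]] <- Tm[k, cols[m]] + f$h[m]
      Tm[n / 2 + k, cols[m]] <- Tm[n / 2 + k, cols[m]] + f$g[m]
    }
  }
  .db4_cache[[key]] <- Tm
  Tm
}

#' Maximal useful Daubechies-4 decomposition depth for a slice size
#'
#' `floor(log2(n / (filter_length - 1)))`, additionally limited by the
#' number of times n is divisible by 2 (periodized transform).
#'
#' @param nx,ny slice dimensions.
#' @return integer level count (>= 1 required by the transform).
#' @export
wavelet_max_level <- function(nx, ny = nx) {
  n <- min(nx, ny)
  lv <- floor(log2(n / 3))
  div2 <- function(n) { k <- 0; while (n %% 2 == 0) { n <- n / 2; k <- k + 1 }; k }
  max(min(lv, div2(nx), div2(ny)), 0)
}

dwt2_slice <- function(x, levels) {
  n1 <- nrow(x); n2 <- ncol(x)
  for (l in seq_len(levels)) {
    m1 <- n1 / 2^(l - 1); m2 <- n2 / 2^(l - 1)
    T1 <- db4_matrix(m1); T2 <- db4_matrix(m2)
    x[1:m1, 1:m2] <- T1 %*% x[1:m1, 1:m2] %*% t(T2)
  }
  x
}

idwt2_slice <- function(x, levels) {
  n1 <- nrow(x); n2 <- ncol(x)
  for (l in rev(seq_len(levels))) {
    m1 <- n1 / 2^(l - 1); m2 <- n2 / 2^(l - 1)
    T1 <- db4_matrix(m1); T2 <- db4_matrix(m2)
    x[1:m1, 1:m2] <- t(T1) %*% x[1:m1, 1:m2] %*% T2
  }
  x
}

#' Per-slice 2D Daubechies-4 wavelet transform
#'
#' Orthonormal multi-level periodized transform of each (x, y) slice of a
#' volume or multi-channel volume; coefficients use the standard in-place
#' quadrant layout (approximation in the top-left block).
#'
#' @param u complex array `(nx, ny, nz)` or `(nx, ny, nz, nu)`.
#' @param levels decomposition depth; defaults to the maximal useful level
#'   for the slice size.
#' @return coefficient array of the same shape, with attribute `"levels"`.
#' @export
wavelet_forward <- function(u, levels = NULL) {
  d <- dim(u)
  levels <- levels %||% wavelet_max_level(d[1], d[2])
  if (levels < 1)
    stop("slice too small for one Daubechies-4 decomposition level")
  stopifnot(d[1] %% 2^levels == 0, d[2] %% 2^levels == 0)
  out <- u
  nsl <- prod(d[-(1:2)])
  dim(out) <- c(d[1], d[2], nsl)
  for (s in seq_len(nsl)) out[, , s] <- dwt2_slice(out[, , s], levels)
  dim(out) <- d
  attr(out, "levels") <- levels
  out
}

#' Adjoint (= inverse) of [wavelet_forward()]
#'
#' @param coeffs coefficient array from [wavelet_forward()] (or compatible).
#' @param levels decomposition depth; defaults to the `"levels"` attribute.
#' @return reconstructed array of the same shape.
#' @export
wavelet_adjoint <- function(coeffs, levels = NULL) {
  d <- dim(coeffs)
  levels <- levels %||% attr(coeffs, "levels") %||%
    wavelet_max_level(d[1], d[2])
  out <- coeffs
  nsl <- prod(d[-(1:2)])
  dim(out) <- c(d[1], d[2], nsl)
  for (s in seq_len(nsl)) out[, , s] <- idwt2_slice(out[, , s], levels)
  dim(out) <- d
  attr(out, "levels") <- NULL
  out
}
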