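# Golden-angle radial stack-of-stars trajectories and the gridding NUFFT.
#
# k-space coordinates are cycles/FOV normalized to [-0.5, 0.5); the image
# grid is 0-based with the phase reference (DC) at voxel floor(n/2).  Radial
# samples are uniformly spaced along each spoke from -0.5 to just below
# +0.5, so a spoke with an even number of samples passes exactly through
# k = 0.  The kz direction is Cartesian (stack of stars).

GOLDEN_ANGLE_DEG <- 111.25

#' Golden-angle spoke angles
#'
#' Angle of the k-th acquired spoke under the golden-angle increment of
#' 111.25 degrees: `((start_index + k) * 111.25) mod 360`, `k = 0, 1, ...`
#' in acquisition order.  Continuation of the angle sequence across
#' parameter encodings is achieved by advancing `start_index`.
#'
#' @param n_spokes number of spokes.
#' @param start_index 0-based index of the first spoke in the continued
#'   golden-angle sequence.
#' @return spoke angles in degrees, in acquisition order.
#' @export
golden_angle_spokes <- function(n_spokes, start_index = 0) {
  stopifnot(n_spokes >= 1)
  ((start_index + seq_len(n_spokes) - 1) * GOLDEN_ANGLE_DEG) %% 360
}

#' Radial stack-of-stars trajectory
#'
#' Builds the in-plane radial sampling pattern for `n_encodings` parameter
#' encodings with `spokes_per_encoding` spokes each.  With
#' `continue_across = TRUE` (the default) the golden-angle sequence is
#' continued over all encodings, i.e. encoding p starts at spoke index
#' `spokes_per_encoding * (p-1)`; otherwise every encoding repeats the same
#' spoke set.
#'
#' @param spokes_per_encoding spokes per parameter encoding.
#' @param n_samples read-out samples per spoke; radii are
#'   `(0:(n_samples-1))/n_samples - 0.5` cycles/FOV.
#' @param n_encodings number of parameter encodings.
#' @param continue_across continue the golden-angle sequence across
#'   encodings.
#' @param start_index 0-based global start index of the first spoke.
#' @return an object of class `sos_trajectory` with fields `angles`
#'   (radians, `spokes x encodings`), `kx`, `ky` (arrays
#'   `n_samples x spokes x encodings`), `n_samples`, `n_spokes`,
#'   `n_encodings`.
#' @export
make_trajectory <- function(spokes_per_encoding, n_samples, n_encodings = 1,
                            continue_across = TRUE, start_index = 0) {
  stopifnot(spokes_per_encoding >= 1, n_samples >= 1, n_encodings >= 1)
  ang <- matrix(0, spokes_per_encoding, n_encodings)
  for (p in seq_len(n_encodings)) {
    s0 <- if (continue_across)
      start_index + spokes_per_encoding * (p - 1) else start_index
    ang[, p] <- golden_angle_spokes(spokes_per_encoding, s0) * pi / 180
  }
  rad <- (seq_len(n_samples) - 1) / n_samples - 0.5
  kx <- array(0, c(n_samples, spokes_per_encoding, n_encodings))
  ky <- array(0, c(n_samples, spokes_per_encoding, n_encodings))
  for (p in seq_len(n_encodings)) {
    kx[, , p] <- outer(rad, cos(ang[, p]))
    ky[, , p] <- outer(rad, sin(ang[, p]))
  }
  structure(list(angles = ang, kx = kx, ky = ky,
                 n_samples = as.integer(n_samples),
                 n_spokes = as.integer(spokes_per_encoding),
                 n_encodings = as.integer(n_encodings),
                 continue_across = continue_across,
                 start_index = start_index),
            class = "sos_trajectory")
}

#' @export
print.sos_trajectory <- function(x, ...) {
  cat(sprintf(paste0("golden-angle stack-of-stars trajectory: %d spokes x ",
                     "%d samples, %d encoding(s)%s\n"),
              x$n_spokes, x$n_samples, x$n_encodings,
              if (x$continue_across && x$n_encodings > 1)
                ", angles continued across encodings" else ""))
  invisible(x)
}

# ---- Kaiser-Bessel gridding plan ----------------------------------------

KB_WIDTH <- 8L      # kernel taps per dimension (even)
KB_OS <- 2          # grid oversampling factor

kb_beta <- function(J = KB_WIDTH, os = KB_OS)
  pi * sqrt((J / os)^2 * (os - 0.5)^2 - 0.8)

kb_kernel <- function(t, J = KB_WIDTH, beta = kb_beta(J)) {
  x <- 1 - (2 * t / J)^2
  w <- ifelse(x > 0, besselI(beta * sqrt(pmax(x, 0)), 0) / besselI(beta, 0), 0)
  w[abs(t) > J / 2] <- 0
  w
}

# 1D deapodization: reciprocal of the continuous Fourier transform of the
# gridding kernel, evaluated at image offsets t = i - floor(n/2)
kb_apod1d <- function(n, osn, J = KB_WIDTH, beta = kb_beta(J)) {
  tt <- (0:(n - 1)) - n %/% 2
  arg <- beta^2 - (pi * J * tt / osn)^2
  f <- ifelse(arg > 0,
              sinh(sqrt(pmax(arg, 0))) / sqrt(pmax(arg, 1e-300)),
              sin(sqrt(pmax(-arg, 0))) / pmax(sqrt(pmax(-arg, 0)), 1e-300))
  1 / (J * f / besselI(beta, 0))
}

#' Precompute a gridding NUFFT plan for a trajectory
#'
#' Computes per-encoding interpolation indices and separable Kaiser-Bessel
#' weights on a 2x oversampled grid, plus the deapodization image.  Plans
#' are reused across coils, slices and solver iterations.
#'
#' @param traj an [make_trajectory()] object.
#' @param nx,ny image grid size.
#' @return an object of class `nufft_plan`.
#' @export
nufft_plan <- function(traj, nx, ny = nx) {
  stopifnot(inherits(traj, "sos_trajectory"))
  J <- KB_WIDTH
  beta <- kb_beta(J)
  osn <- as.integer(KB_OS * max(nx, ny))
  enc <- vector("list", traj$n_encodings)
  for (p in seq_len(traj$n_encodings)) {
    px <- as.vector(traj$kx[, , p]) * osn
    py <- as.vector(traj$ky[, , p]) * osn
    ix0 <- floor(px) - J %/% 2 + 1
    iy0 <- floor(py) - J %/% 2 + 1
    Ns <- length(px)
    wx <- matrix(0, J, Ns); wy <- matrix(0, J, Ns)
    gxw <- matrix(0L, J, Ns); gyo <- matrix(0L, J, Ns)
    for (j in seq_len(J)) {
      wx[j, ] <- kb_kernel(px - (ix0 + j - 1), J, beta)
      wy[j, ] <- kb_kernel(py - (iy0 + j - 1), J, beta)
      gxw[j, ] <- as.integer(((ix0 + j - 1) %% osn + osn) %% osn)
      gyo[j, ] <- as.integer((((iy0 + j - 1) %% osn + osn) %% osn) * osn)
    }
    enc[[p]] <- list(gxw = gxw, gyo = gyo, wx = wx, wy = wy)
  }
  ap <- outer(kb_apod1d(nx, osn, J, beta), kb_apod1d(ny, osn, J, beta))
  structure(list(enc = enc, apod = as.numeric(ap), osn = osn,
                 nx = as.integer(nx), ny = as.integer(ny),
                 n_samples = traj$n_samples, n_spokes = traj$n_spokes,
                 n_encodings = traj$n_encodings),
            class = "nufft_plan")
}

unit_coils <- function(nx, ny, nz) array(1 + 0i, c(nx, ny, nz, 1))

#' Stack-of-stars NUFFT (forward)
#'
#' Non-uniform Fourier transform of a volume along the radial trajectory of
#' one parameter encoding: unitary FFT along z followed by a 2D type-2
#' NUFFT per slice,
#' \eqn{d(k) = \sum_x u(x)\, e^{-2\pi i k \cdot (x - c)}} with the phase
#' reference c at the grid centre.
#'
#' @param volume complex array `(nx, ny, nz)`.
#' @param traj trajectory; `encoding` selects the spoke set.
#' @param encoding 1-based encoding index.
#' @param plan optional precomputed [nufft_plan()].
#' @return complex array `(n_samples, n_spokes, nz)`.
#' @export
nufft_forward <- function(volume, traj, encoding = 1, plan = NULL) {
  d <- dim(volume)
  if (length(d) == 2L) { dim(volume) <- c(d, 1L); d <- dim(volume) }
  stopifnot(length(d) == 3L)
  if (is.null(plan)) plan <- nufft_plan(traj, d[1], d[2])
  stopifnot(plan$nx == d[1], plan$ny == d[2])
  pe <- plan$enc[[encoding]]
  out <- cpp_sos_forward(ensure_complex(volume), unit_coils(d[1], d[2], d[3]),
                         plan$apod, pe$gxw, pe$gyo, pe$wx, pe$wy,
                         d[1], d[2], d[3], 1L, plan$osn)
  array(out, c(plan$n_samples, plan$n_spokes, d[3]))
}

#' Stack-of-stars NUFFT (adjoint)
#'
#' Exact conjugate transpose of [nufft_forward()] for the same trajectory
#' and grid.
#'
#' @param samples complex array `(n_samples, n_spokes, nz)`.
#' @param traj trajectory; `encoding` selects the spoke set.
#' @param nx,ny,nz image grid size.
#' @param encoding 1-based encoding index.
#' @param plan optional precomputed [nufft_plan()].
#' @return complex volume `(nx, ny, nz)`.
#' @export
nufft_adjoint <- function(samples, traj, nx, ny = nx, nz = dim(samples)[3],
                          encoding = 1, plan = NULL) {
  if (length(dim(samples)) == 2L) dim(samples) <- c(dim(samples), 1L)
  if (is.null(plan)) plan <- nufft_plan(traj, nx, ny)
  pe <- plan$enc[[encoding]]
  ns <- plan$n_samples * plan$n_spokes
  stopifnot(length(samples) == ns * nz)
  out <- cpp_sos_adjoint(matrix(ensure_complex(samples), ns, nz),
                         unit_coils(nx, ny, nz), plan$apod,
                         pe$gxw, pe$gyo, pe$wx, pe$wy,
                         as.integer(nx), as.integer(ny), as.integer(nz),
                         1L, plan$osn)
  array(out, c(nx, ny, nz))
}
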