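# Synthetic-data generation: digital brain-like phantom, Biot-Savart coil
# sensitivities, smooth B1 field, golden-angle k-space synthesis with
# complex Gaussian noise.  All generators are pure functions of their
# arguments and the seed.

#' Specification of the digital T1/M0 phantom
#'
#' A parametric brain-like phantom built from nested ellipsoids: a gray
#' matter head ellipsoid, a white matter core, CSF-filled ventricles, and
#' an ellipsoidal tumor with linearly varying T1 inside white matter.  T1
#' and M0 values default to literature-plausible 3T brain values.
#' Background (outside the head) is zero, which also serves as the
#' evaluation mask.
#'
#' @param shape grid dimensions `c(nx, ny, nz)`.
#' @param t1_ms named T1 values (ms) for `wm`, `gm`, `csf`.
#' @param m0 named M0 values for `wm`, `gm`, `csf`.
#' @param tumor list with `center` and `semiaxes` (relative coordinates in
#'   [-1, 1]), `t1_range_ms` (linear gradient endpoints along x) and `m0`;
#'   `NULL` omits the tumor.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 8),
                         t1_ms = c(wm = 900, gm = 1400, csf = 4200),
                         m0 = c(wm = 0.77, gm = 0.86, csf = 1),
                         tumor = list(center = c(-0.35, -0.25, 0),
                                      semiaxes = c(0.16, 0.14, 0.45),
                                      t1_range_ms = c(1200, 1800),
                                      m0 = 0.9)) {
  stopifnot(length(shape) == 3L, all(shape >= 2), all(t1_ms > 0))
  structure(list(shape = as.integer(shape), t1_ms = t1_ms, m0 = m0,
                 tumor = tumor), class = "phantom_spec")
}

rel_grid <- function(shape) {
  g <- lapply(shape, function(n) ((seq_len(n) - 0.5) / n) * 2 - 1)
  list(x = array(rep(g[[1]], times = shape[2] * shape[3]), shape),
       y = array(rep(rep(g[[2]], each = shape[1]), times = shape[3]), shape),
       z = array(rep(g[[3]], each = shape[1] * shape[2]), shape))
}

in_ellipsoid <- function(gr, center, semi) {
  ((gr$x - center[1]) / semi[1])^2 + ((gr$y - center[2]) / semi[2])^2 +
    ((gr$z - center[3]) / semi[3])^2 <= 1
}

#' Generate the digital phantom
#'
#' Deterministic ground-truth maps from a [phantom_spec()]: label volume
#' (0 background, 1 WM, 2 GM, 3 CSF, 4 tumor), T1 in ms, and M0.  Tumor
#' T1 varies linearly between its endpoints along the x extent of the
#' tumor ellipsoid.
#'
#' @param spec a [phantom_spec()].
#' @return list with complex volumes `M0`, `T1` (list usable as parameter
#'   maps) and integer volume `labels`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  sh <- spec$shape
  gr <- rel_grid(sh)
  labels <- array(0L, sh)
  labels[in_ellipsoid(gr, c(0, 0, 0), c(0.88, 0.92, 0.95))] <- 2L  # GM head
  labels[in_ellipsoid(gr, c(0, 0, 0), c(0.62, 0.72, 0.78))] <- 1L  # WM core
  vent <- in_ellipsoid(gr, c(-0.16, 0.12, 0), c(0.10, 0.3, 0.42)) |
    in_ellipsoid(gr, c(0.16, 0.12, 0), c(0.10, 0.3, 0.42))
  labels[vent & labels == 1L] <- 3L                                # CSF
  T1 <- array(0, sh); M0 <- array(0, sh)
  T1[labels == 1L] <- spec$t1_ms[["wm"]]
  T1[labels == 2L] <- spec$t1_ms[["gm"]]
  T1[labels == 3L] <- spec$t1_ms[["csf"]]
  M0[labels == 1L] <- spec$m0[["wm"]]
  M0[labels == 2L] <- spec$m0[["gm"]]
  M0[labels == 3L] <- spec$m0[["csf"]]
  if (!is.null(spec$tumor)) {
    tu <- spec$tumor
    sel <- in_ellipsoid(gr, tu$center, tu$semiaxes) & labels == 1L
    if (any(sel)) {
      x0 <- tu$center[1] - tu$semiaxes[1]
      tfrac <- (gr$x[sel] - x0) / (2 * tu$semiaxes[1])
      tfrac <- pmin(pmax(tfrac, 0), 1)
      # linear contrast between the endpoints, exact at the extremes
      tfrac <- (tfrac - min(tfrac)) / max(max(tfrac) - min(tfrac), 1e-12)
      T1[sel] <- tu$t1_range_ms[1] + tfrac * diff(tu$t1_range_ms)
      M0[sel] <- tu$m0
      labels[sel] <- 4L
    }
  }
  list(M0 = M0 + 0i, T1 = T1 + 0i, labels = labels)
}

#' Biot-Savart coil sensitivity maps
#'
#' Complex sensitivities of circular receive loops placed on a ring around
#' the FOV, computed by discretized Biot-Savart line integration; the
#' transverse field components form the complex sensitivity
#' (Bx - i By), and the set is normalized so the maximal root-sum-of-
#' squares over the volume is 1.
#'
#' @param n_coils number of loops (equally spaced on the ring).
#' @param shape grid dimensions `c(nx, ny, nz)`.
#' @param ring_radius ring radius in FOV-half units (> sqrt(2) keeps loops
#'   outside the grid).
#' @param loop_radius loop radius in FOV-half units.
#' @param n_segments segments of the line discretization.
#' @return complex array `(nx, ny, nz, n_coils)`.
#' @export
biot_savart_coils <- function(n_coils = 7, shape = c(64, 64, 8),
                              ring_radius = 1.6, loop_radius = 0.7,
                              n_segments = 32) {
  stopifnot(n_coils >= 1)
  if (ring_radius <= sqrt(2))
    stop("ring_radius must exceed sqrt(2): loops must stay outside the FOV")
  gr <- rel_grid(shape)
  vx <- as.vector(gr$x); vy <- as.vector(gr$y); vz <- as.vector(gr$z)
  sens <- array(0i, c(shape, n_coils))
  tt <- (seq_len(n_segments) - 0.5) / n_segments * 2 * pi
  dtt <- 2 * pi / n_segments
  for (ci in seq_len(n_coils)) {
    phi <- 2 * pi * (ci - 1) / n_coils
    ctr <- ring_radius * c(cos(phi), sin(phi), 0)
    e1 <- c(-sin(phi), cos(phi), 0)   # in-plane tangent
    e2 <- c(0, 0, 1)                  # axial
    Bx <- numeric(length(vx)); By <- numeric(length(vx))
    for (s in seq_along(tt)) {
      p <- ctr + loop_radius * (cos(tt[s]) * e1 + sin(tt[s]) * e2)
      dl <- loop_radius * (-sin(tt[s]) * e1 + cos(tt[s]) * e2) * dtt
      rx <- vx - p[1]; ry <- vy - p[2]; rz <- vz - p[3]
      r3 <- (rx^2 + ry^2 + rz^2)^1.5
      # dl x r / |r|^3
      Bx <- Bx + (dl[2] * rz - dl[3] * ry) / r3
      By <- By + (dl[3] * rx - dl[1] * rz) / r3
    }
    sens[, , , ci] <- array(complex(real = Bx, imaginary = -By), shape)
  }
  rss <- sqrt(rowSums(matrix(abs(sens)^2, prod(shape), n_coils)))
  sens / max(rss)
}

#' Smooth synthetic B1 correction field
#'
#' A low-order polynomial multiplicative flip-angle factor with mean 1,
#' bounded in `[1 - strength, 1 + strength]`, standing in for a measured
#' transmit-field map in simulations.
#'
#' @param shape grid dimensions.
#' @param strength relative deviation in [0, 0.5].
#' @return numeric array `(nx, ny, nz)`.
#' @export
make_b1_field <- function(shape = c(64, 64, 8), strength = 0.2) {
  stopifnot(strength >= 0, strength <= 0.5)
  gr <- rel_grid(shape)
  p <- gr$x^2 + gr$y^2 + 0.5 * gr$x * gr$y
  p <- p - mean(p)
  if (max(abs(p)) > 0) p <- p / max(abs(p))
  1 + strength * p
}

#' Synthesize multi-coil radial k-space data
#'
#' Applies the nonlinear forward operator to ground-truth maps and adds
#' complex white Gaussian noise scaled to a target k-space SNR:
#' `20*log10(||signal|| / ||noise||) = snr_db` in expectation.
#'
#' @param maps list with `M0` and `T1` volumes.
#' @param model signal model matching the trajectory's encoding count.
#' @param coils coil sensitivities.
#' @param traj trajectory.
#' @param snr_db target SNR in dB; `Inf` for noiseless data.
#' @param seed integer; fixes the noise realization exactly.
#' @param plan optional precomputed [nufft_plan()].
#' @return complex k-space array `(ns, nspokes, nz, nc, np)` with
#'   attributes `snr_db` and `seed`.
#' @export
synthesize_kspace <- function(maps, model, coils, traj, snr_db = Inf,
                              seed = 1, plan = NULL) {
  sig <- apply_forward_A(maps, model, coils, traj, plan)
  if (is.finite(snr_db)) {
    sig_nrm <- cnorm(sig)
    n <- length(sig)
    target_noise <- sig_nrm * 10^(-snr_db / 20)
    sd_per <- target_noise / sqrt(n)   # per complex sample, in expectation
    noise <- with_seed(seed, crandn(dim(sig))) * sd_per
    sig <- sig + noise
  }
  attr(sig, "snr_db") <- snr_db
  attr(sig, "seed") <- seed
  sig
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper reproducing the simulation protocol end to end:
#' digital phantom, Biot-Savart coils, optional B1 field, continued
#' golden-angle trajectory, VFA (or IRLL) contrast synthesis and noise.
#' Defaults follow the study geometry scaled to the requested grid: 2x
#' readout oversampling (samples per spoke = 2 nx), 34 spokes per
#' encoding, 10 flip angles 1-19 degrees, TR 5.38 ms, 7 coils.
#'
#' @param shape grid dimensions `c(nx, ny, nz)`.
#' @param spokes spokes per parameter encoding (Fibonacci numbers give
#'   uniform coverage).
#' @param flip_angles_deg VFA flip-angle set.
#' @param tr_ms repetition time.
#' @param n_coils number of simulated receive coils.
#' @param snr_db k-space SNR target (`Inf` = noiseless).
#' @param seed RNG seed for the noise realization.
#' @param spec phantom specification (defaults to [phantom_spec()] at
#'   `shape`).
#' @param b1_strength strength of the synthetic B1 field; 0 disables B1
#'   correction in both simulation and model.
#' @param model optional signal model overriding the VFA default (e.g. an
#'   [irll_model()]); its encoding count determines the trajectory.
#' @return list of class `t1_dataset` with fields `data`, `truth`
#'   (`M0`, `T1`, `labels`), `coils`, `traj`, `model`, `b1`, and the
#'   generation parameters.
#' @export
simulate_dataset <- function(shape = c(64, 64, 8), spokes = 34,
                             flip_angles_deg = seq(1, 19, by = 2),
                             tr_ms = 5.38, n_coils = 7, snr_db = 32,
                             seed = 1, spec = NULL, b1_strength = 0,
                             model = NULL) {
  spec <- spec %||% phantom_spec(shape)
  ph <- make_phantom(spec)
  coils <- biot_savart_coils(n_coils, shape)
  b1 <- if (b1_strength > 0) make_b1_field(shape, b1_strength) else NULL
  if (is.null(model))
    model <- vfa_model(flip_angles_deg, tr_ms, b1 = b1)
  traj <- make_trajectory(spokes, n_samples = 2 * shape[1],
                          n_encodings = model$n_enc, continue_across = TRUE)
  data <- synthesize_kspace(ph, model, coils, traj, snr_db = snr_db,
                            seed = seed)
  structure(list(data = data, truth = ph, coils = coils, traj = traj,
                 model = model, b1 = b1, snr_db = snr_db, seed = seed,
                 shape = as.integer(shape)),
            class = "t1_dataset")
}

#' @export
print.t1_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("synthetic %s dataset: grid %s, %d coils, %d x %d ",
                     "samples x spokes, %d encodings, SNR %s dB (seed %d)\n"),
              toupper(x$model$type), paste(x$shape, collapse = "x"),
              d[4], d[1], d[2], d[5],
              if (is.finite(x$snr_db)) format(x$snr_db) else "Inf", x$seed))
  invisible(x)
}
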