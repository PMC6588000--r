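# The nonlinear forward operator A and its Gauss-Newton linearization.
#
#   A : (M0, T1) -> { F_p [ b_c . S_p(M0, T1) ] }_{p,c}
#
# where S_p is the signal model for encoding p, b_c the coil sensitivities
# and F_p the stack-of-stars NUFFT of encoding p.  The Jacobian DA at a
# linearization point is applied through precomputed per-encoding partial
# derivative images; internal unknowns carry per-unknown scale factors
# (M0 = s1*u1, T1 = s2*u2) so DA and its adjoint include the scales.

check_geometry <- function(coils, traj, plan) {
  dc <- dim(coils)
  stopifnot(length(dc) == 4L)
  stopifnot(plan$nx == dc[1], plan$ny == dc[2])
  stopifnot(plan$n_encodings == traj$n_encodings)
  invisible(dc)
}

data_dims <- function(traj, coils)
  c(traj$n_samples, traj$n_spokes, dim(coils)[3], dim(coils)[4],
    traj$n_encodings)

#' Nonlinear forward operator A
#'
#' Maps parameter maps to multi-coil, multi-encoding k-space: for each
#' encoding p and coil c the signal-model image is multiplied by the coil
#' sensitivity and Fourier-encoded along the encoding's radial spokes.
#'
#' @param maps list with complex volumes `M0` and `T1` (T1 in ms).
#' @param model a [vfa_model()] or [irll_model()].
#' @param coils complex coil sensitivities `(nx, ny, nz, nc)`.
#' @param traj trajectory from [make_trajectory()] with
#'   `n_encodings == model$n_enc`.
#' @param plan optional [nufft_plan()]; computed on the fly if missing.
#' @return complex k-space array `(n_samples, n_spokes, nz, nc, n_enc)`.
#' @export
apply_forward_A <- function(maps, model, coils, traj, plan = NULL) {
  if (is.null(plan)) plan <- nufft_plan(traj, dim(coils)[1], dim(coils)[2])
  dc <- check_geometry(coils, traj, plan)
  stopifnot(model$n_enc == traj$n_encodings)
  nz <- dc[3]; nc <- dc[4]
  coils <- ensure_complex(coils)
  out <- array(0i, data_dims(traj, coils))
  for (p in seq_len(model$n_enc)) {
    sp <- ensure_complex(model$signal(p, maps$M0, maps$T1))
    pe <- plan$enc[[p]]
    d <- cpp_sos_forward(sp, coils, plan$apod,
                         pe$gxw, pe$gyo, pe$wx, pe$wy,
                         dc[1], dc[2], nz, nc, plan$osn)
    out[, , , , p] <- d
  }
  out
}

# Precompute per-encoding signal and partial-derivative images at the
# linearization point (physical units).
precompute_linearization <- function(maps_k, model) {
  n <- model$n_enc
  S <- vector("list", n); dM0 <- vector("list", n); dT1 <- vector("list", n)
  for (p in seq_len(n)) {
    S[[p]] <- model$signal(p, maps_k$M0, maps_k$T1)
    dv <- model$derivs(p, maps_k$M0, maps_k$T1)
    dM0[[p]] <- dv$dM0
    dT1[[p]] <- dv$dT1
  }
  list(S = S, dM0 = dM0, dT1 = dT1, dim = dim(maps_k$M0))
}

#' Apply the Jacobian DA of the forward operator
#'
#' Directional derivative of A at the linearization point, applied to an
#' internal-unit update `du` (complex array `(nx, ny, nz, 2)`):
#' \eqn{DA\,du = \sum_i F_p [ b_c\, (\partial S_p/\partial u_i)\, du_i ]}.
#'
#' @param du internal update, dims `(nx, ny, nz, 2)`.
#' @param lin precomputed linearization (internal; from the IRGN loop).
#' @param scales numeric length-2 vector of unknown scales (M0, T1).
#' @param coils,traj,plan as in [apply_forward_A()].
#' @return k-space array shaped like the data.
#' @export
apply_jacobian_DA <- function(du, lin, scales, coils, traj, plan = NULL) {
  if (is.null(plan)) plan <- nufft_plan(traj, dim(coils)[1], dim(coils)[2])
  dc <- check_geometry(coils, traj, plan)
  stopifnot(length(dim(du)) == 4L, all(dim(du)[1:3] == dc[1:3]),
            all(dim(du)[1:3] == lin$dim))
  nz <- dc[3]; nc <- dc[4]
  coils <- ensure_complex(coils)
  du1 <- du[, , , 1, drop = FALSE]; dim(du1) <- dc[1:3]
  du2 <- du[, , , 2, drop = FALSE]; dim(du2) <- dc[1:3]
  out <- array(0i, data_dims(traj, coils))
  for (p in seq_len(traj$n_encodings)) {
    img <- lin$dM0[[p]] * (scales[1] * du1) + lin$dT1[[p]] * (scales[2] * du2)
    pe <- plan$enc[[p]]
    out[, , , , p] <- cpp_sos_forward(ensure_complex(img), coils,
                                      plan$apod, pe$gxw, pe$gyo, pe$wx,
                                      pe$wy, dc[1], dc[2], nz, nc, plan$osn)
  }
  out
}

#' Adjoint of the Jacobian DA
#'
#' Conjugate transpose of [apply_jacobian_DA()]: back-projects a k-space
#' residual into an internal-unit gradient image `(nx, ny, nz, 2)`.
#'
#' @param residual k-space array shaped like the data.
#' @inheritParams apply_jacobian_DA
#' @return complex array `(nx, ny, nz, 2)`.
#' @export
apply_DA_adjoint <- function(residual, lin, scales, coils, traj,
                             plan = NULL) {
  if (is.null(plan)) plan <- nufft_plan(traj, dim(coils)[1], dim(coils)[2])
  dc <- check_geometry(coils, traj, plan)
  stopifnot(all(dim(residual) == data_dims(traj, coils)),
            all(dc[1:3] == lin$dim))
  nz <- dc[3]; nc <- dc[4]
  coils <- ensure_complex(coils)
  ns <- traj$n_samples * traj$n_spokes
  g1 <- array(0i, dc[1:3]); g2 <- array(0i, dc[1:3])
  for (p in seq_len(traj$n_encodings)) {
    rp <- residual[, , , , p]
    dim(rp) <- c(ns, nz * nc)
    pe <- plan$enc[[p]]
    vol <- cpp_sos_adjoint(rp, coils, plan$apod,
                           pe$gxw, pe$gyo, pe$wx, pe$wy,
                           dc[1], dc[2], nz, nc, plan$osn)
    dim(vol) <- dc[1:3]
    g1 <- g1 + Conj(lin$dM0[[p]]) * vol
    g2 <- g2 + Conj(lin$dT1[[p]]) * vol
  }
  out <- array(0i, c(dc[1:3], 2L))
  out[, , , 1] <- scales[1] * g1
  out[, , , 2] <- scales[2] * g2
  out
}
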