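# Analytic MR signal models and their partial derivatives.
#
# Both models are linear in M0 and smooth in T1; the T1 partials are exact
# chain-rule derivatives through the relaxation exponentials, which the
# Gauss-Newton linearization relies on.  T1 may be complex (the solver treats
# both unknowns as complex images); its real part is clamped to a physical
# range before it enters any exponential so that transient Gauss-Newton
# iterates cannot overflow.

T1_CLAMP_MIN <- 1
T1_CLAMP_MAX <- 1e6

clamp_t1 <- function(T1) {
  if (is.complex(T1)) {
    complex(real = pmin(pmax(Re(T1), T1_CLAMP_MIN), T1_CLAMP_MAX),
            imaginary = Im(T1))
  } else {
    pmin(pmax(T1, T1_CLAMP_MIN), T1_CLAMP_MAX)
  }
}

check_finite_args <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    x <- args[[i]]
    if (!all(is.finite(Re(x))) || (is.complex(x) && !all(is.finite(Im(x)))))
      stop(sprintf("non-finite value in argument '%s'", nm[i]), call. = FALSE)
  }
  invisible(NULL)
}

#' Spoiled gradient-echo (FLASH) steady-state signal
#'
#' Evaluates the variable-flip-angle signal
#' \deqn{S = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha}, \quad
#'       E_1 = e^{-T_R/T_1},}
#' the steady-state magnetization of an RF- and gradient-spoiled
#' gradient-echo sequence.  The signal is exactly linear in \code{M0}.
#'
#' @param M0 proton density (arbitrary units, possibly complex); any shape.
#' @param T1 longitudinal relaxation time in ms (possibly complex; the real
#'   part is clamped to \code{[1, 1e6]} ms before exponentiation).
#' @param alpha_deg flip angle in degrees (scalar or array matching `M0`,
#'   e.g. after multiplication with a B1 correction factor).
#' @param tr_ms repetition time in ms.
#' @return the complex signal, same shape as the broadcast arguments.
#' @seealso [vfa_derivatives()], [ernst_angle()], [vfa_model()]
#' @export
vfa_signal <- function(M0, T1, alpha_deg, tr_ms) {
  check_finite_args(M0 = M0, T1 = T1, alpha_deg = alpha_deg, tr_ms = tr_ms)
  stopifnot(tr_ms > 0)
  T1c <- clamp_t1(T1)
  a <- cos(alpha_deg * pi / 180)
  s <- sin(alpha_deg * pi / 180)
  E1 <- exp(-tr_ms / T1c)
  M0 * s * (1 - E1) / (1 - E1 * a)
}

#' Partial derivatives of the VFA signal
#'
#' Analytic partials of [vfa_signal()] with respect to M0 and T1.  The M0
#' partial is the unit-M0 signal (linearity); the T1 partial follows from
#' \eqn{dE_1/dT_1 = (T_R/T_1^2) E_1}.
#'
#' @inheritParams vfa_signal
#' @return list with components `dM0` and `dT1`.
#' @export
vfa_derivatives <- function(M0, T1, alpha_deg, tr_ms) {
  check_finite_args(M0 = M0, T1 = T1, alpha_deg = alpha_deg, tr_ms = tr_ms)
  stopifnot(tr_ms > 0)
  T1c <- clamp_t1(T1)
  a <- cos(alpha_deg * pi / 180)
  s <- sin(alpha_deg * pi / 180)
  E1 <- exp(-tr_ms / T1c)
  dE1 <- (tr_ms / T1c^2) * E1
  dM0 <- s * (1 - E1) / (1 - E1 * a)
  dT1 <- M0 * s * dE1 * (a - 1) / (1 - a * E1)^2
  list(dM0 = dM0 + 0 * M0, dT1 = dT1)
}

#' Ernst angle
#'
#' Flip angle maximizing the spoiled gradient-echo signal for given T1 and
#' TR: \eqn{\alpha_E = \arccos(e^{-T_R/T_1})}.
#'
#' @inheritParams vfa_signal
#' @return angle in degrees.
#' @export
ernst_angle <- function(T1, tr_ms) acos(exp(-tr_ms / T1)) * 180 / pi

#' Inversion-recovery Look-Locker timing parameters
#'
#' Describes an IRLL acquisition: an adiabatic inversion followed by a train
#' of `n_readouts` small-angle readout pulses spaced `tau_ms` apart, with
#' delay `td_ms` between inversion and first pulse and recovery time `tr_ms`
#' after the train.  When `tr_ms` is omitted it is derived from the total
#' shot time as `shot_time_ms - td_ms - n_readouts * tau_ms`.
#'
#' Consecutive readouts (spokes) are binned into frames of
#' `spokes_per_frame`; trailing readouts that do not fill a complete frame
#' are dropped so that every frame has the same temporal footprint.
#'
#' @param flip_angle_deg readout pulse angle in degrees.
#' @param tau_ms pulse spacing in ms.
#' @param td_ms inversion-to-first-pulse delay in ms.
#' @param n_readouts total number of readouts per inversion.
#' @param tr_ms recovery time at the end of the pulse train in ms.
#' @param shot_time_ms total shot time per slice in ms (used to derive
#'   `tr_ms` when that is not given).
#' @param spokes_per_frame number of consecutive spokes binned per frame.
#' @return an object of class `irll_params`.
#' @export
irll_params <- function(flip_angle_deg, tau_ms, td_ms, n_readouts,
                        tr_ms = NULL, shot_time_ms = NULL,
                        spokes_per_frame = 13L) {
  if (is.null(tr_ms)) {
    if (is.null(shot_time_ms))
      stop("either tr_ms or shot_time_ms must be given")
    tr_ms <- shot_time_ms - td_ms - n_readouts * tau_ms
  }
  stopifnot(flip_angle_deg > 0, flip_angle_deg < 90,
            tau_ms >= 0, td_ms >= 0, tr_ms >= 0, n_readouts >= 1,
            spokes_per_frame >= 1)
  structure(list(flip_angle_deg = flip_angle_deg, tau_ms = tau_ms,
                 td_ms = td_ms, tr_ms = tr_ms,
                 n_readouts = as.integer(n_readouts),
                 spokes_per_frame = as.integer(spokes_per_frame)),
            class = "irll_params")
}

# internal: everything the IRLL closed form and its T1 partial need, at a
# clamped complex T1 and effective flip angle (degrees, possibly per voxel)
irll_terms <- function(T1, params, alpha_deg) {
  T1c <- clamp_t1(T1)
  a <- cos(alpha_deg * pi / 180)
  s <- sin(alpha_deg * pi / 180)
  N <- params$n_readouts
  Etau <- exp(-params$tau_ms / T1c)
  Er <- exp(-params$tr_ms / T1c)
  Ed <- exp(-params$td_ms / T1c)
  dEtau <- (params$tau_ms / T1c^2) * Etau
  dEr <- (params$tr_ms / T1c^2) * Er
  dEd <- (params$td_ms / T1c^2) * Ed
  cc <- a * Etau
  dcc <- a * dEtau
  F <- (1 - Etau) / (1 - cc)
  dF <- dEtau * (a - 1) / (1 - cc)^2
  cN <- cc^(N - 1)
  dcN <- if (N > 1) (N - 1) * cc^(N - 2) * dcc else 0 * cc
  # cyclic steady state across inversion cycles: the longitudinal
  # magnetization before the first readout pulse
  num <- 1 - 2 * Ed + Ed * Er - a * Er * Ed * F * (1 - cN)
  dnum <- -2 * dEd + dEd * Er + Ed * dEr -
    a * (dEr * Ed * F * (1 - cN) + Er * dEd * F * (1 - cN) +
           Er * Ed * dF * (1 - cN) - Er * Ed * F * dcN)
  den <- 1 + a * Er * Ed * cN
  dden <- a * (dEr * Ed * cN + Er * dEd * cN + Er * Ed * dcN)
  Q <- num / den
  dQ <- (dnum * den - num * dden) / den^2
  list(a = a, s = s, cc = cc, dcc = dcc, F = F, dF = dF, Q = Q, dQ = dQ)
}

#' Inversion-recovery Look-Locker signal of the n-th readout
#'
#' Closed-form transient signal of the n-th gradient-echo readout after a
#' perfect inversion, in the cyclic steady state over repeated inversion
#' shots:
#' \deqn{S_n = \sin\alpha\, M_0 \left[F + (\cos\alpha\, E_\tau)^{n-1}(Q - F)\right]}
#' with \eqn{F = (1-E_\tau)/(1-\cos\alpha E_\tau)} the driven steady state of
#' the pulse train, \eqn{Q} the longitudinal magnetization before the first
#' pulse in the cyclic steady state, and
#' \eqn{E_\tau = e^{-\tau/T_1}}, \eqn{E_r = e^{-t_r/T_1}},
#' \eqn{E_d = e^{-t_d/T_1}}.
#'
#' @inheritParams vfa_signal
#' @param n readout index, 1-based, `1 <= n <= n_readouts` (scalar).
#' @param params an [irll_params()] object.
#' @param alpha_deg optional effective flip angle in degrees overriding
#'   `params$flip_angle_deg` (e.g. after B1 correction); scalar or array.
#' @return complex signal, same shape as the broadcast arguments.
#' @export
irll_signal <- function(M0, T1, n, params,
                        alpha_deg = params$flip_angle_deg) {
  check_finite_args(M0 = M0, T1 = T1, n = n)
  if (any(n < 1) || any(n > params$n_readouts))
    stop("readout index n out of range 1..n_readouts")
  tm <- irll_terms(T1, params, alpha_deg)
  cn <- tm$cc^(n - 1)
  tm$s * M0 * (tm$F + cn * (tm$Q - tm$F))
}

#' Partial derivatives of the IRLL signal
#'
#' Analytic chain-rule partials of [irll_signal()] through the relaxation
#' factors \eqn{E_\tau, E_r, E_d} (each with
#' \eqn{dE_t/dT_1 = (t/T_1^2)E_t}).
#'
#' @inheritParams irll_signal
#' @return list with components `dM0` and `dT1`.
#' @export
irll_derivatives <- function(M0, T1, n, params,
                             alpha_deg = params$flip_angle_deg) {
  check_finite_args(M0 = M0, T1 = T1, n = n)
  if (any(n < 1) || any(n > params$n_readouts))
    stop("readout index n out of range 1..n_readouts")
  tm <- irll_terms(T1, params, alpha_deg)
  cn <- tm$cc^(n - 1)
  dcn <- if (n > 1) (n - 1) * tm$cc^(n - 2) * tm$dcc else 0 * tm$cc
  dM0 <- tm$s * (tm$F + cn * (tm$Q - tm$F))
  dT1 <- tm$s * M0 *
    (tm$dF + dcn * (tm$Q - tm$F) + cn * (tm$dQ - tm$dF))
  list(dM0 = dM0 + 0 * M0, dT1 = dT1)
}

#' IRLL frame signal (spoke binning)
#'
#' Signal of one binned k-space frame: the arithmetic mean of
#' [irll_signal()] over the `spokes_per_frame` consecutive readout indices
#' that the frame combines.  The derivative frames are the means of the
#' per-readout derivatives.
#'
#' @inheritParams irll_signal
#' @param frame_index 1-based frame index; frame p combines readouts
#'   `(p-1)*spokes_per_frame + 1 .. p*spokes_per_frame`.
#' @param derivatives if `TRUE` return the mean derivative images instead.
#' @return complex frame signal (or list `dM0`, `dT1`).
#' @export
irll_frame_signal <- function(M0, T1, frame_index, params,
                              alpha_deg = params$flip_angle_deg,
                              derivatives = FALSE) {
  spf <- params$spokes_per_frame
  nfr <- params$n_readouts %/% spf
  if (frame_index < 1 || frame_index > nfr)
    stop(sprintf("frame_index must be in 1..%d (complete frames only)", nfr))
  ns <- (frame_index - 1L) * spf + seq_len(spf)
  if (!derivatives) {
    acc <- 0
    for (n in ns) acc <- acc + irll_signal(M0, T1, n, params, alpha_deg)
    return(acc / spf)
  }
  aM0 <- 0; aT1 <- 0
  for (n in ns) {
    d <- irll_derivatives(M0, T1, n, params, alpha_deg)
    aM0 <- aM0 + d$dM0; aT1 <- aT1 + d$dT1
  }
  list(dM0 = aM0 / spf, dT1 = aT1 / spf)
}

#' Variable-flip-angle signal model
#'
#' Bundles a VFA acquisition (flip-angle table, TR, optional per-voxel B1
#' correction) into the model interface used by the forward operator: one
#' parameter encoding per flip angle.
#'
#' @param flip_angles_deg vector of nominal flip angles in degrees
#'   (strictly positive, < 90).
#' @param tr_ms repetition time in ms.
#' @param b1 optional multiplicative flip-angle correction factor: a scalar
#'   or a volume matching the image grid (dimensionless, > 0).
#' @return an object of class `signal_model`.
#' @export
vfa_model <- function(flip_angles_deg, tr_ms, b1 = NULL) {
  stopifnot(all(flip_angles_deg > 0), all(flip_angles_deg < 90), tr_ms > 0)
  if (!is.null(b1)) stopifnot(all(b1 > 0))
  force(flip_angles_deg); force(tr_ms); force(b1)
  m <- list(
    type = "vfa",
    n_enc = length(flip_angles_deg),
    flip_angles_deg = flip_angles_deg,
    tr_ms = tr_ms,
    b1 = b1,
    signal = function(p, M0, T1) {
      a <- flip_angles_deg[p] * (if (is.null(b1)) 1 else b1)
      vfa_signal(M0, T1, a, tr_ms)
    },
    derivs = function(p, M0, T1) {
      a <- flip_angles_deg[p] * (if (is.null(b1)) 1 else b1)
      vfa_derivatives(M0, T1, a, tr_ms)
    },
    # |S_p(M0 = 1, T1)| averaged over encodings, for unknown scaling
    unit_signal = function(T1) {
      acc <- 0
      for (p in seq_along(flip_angles_deg))
        acc <- acc + abs(vfa_signal(1, T1, flip_angles_deg[p], tr_ms))
      acc / length(flip_angles_deg)
    })
  class(m) <- "signal_model"
  m
}

#' Inversion-recovery Look-Locker signal model
#'
#' Bundles an IRLL acquisition into the model interface used by the forward
#' operator: one parameter encoding per binned frame of
#' `spokes_per_frame` consecutive spokes (trailing incomplete frames are
#' dropped).
#'
#' @param params an [irll_params()] object.
#' @param b1 optional multiplicative flip-angle correction (scalar or
#'   volume).
#' @return an object of class `signal_model`.
#' @export
irll_model <- function(params, b1 = NULL) {
  stopifnot(inherits(params, "irll_params"))
  if (!is.null(b1)) stopifnot(all(b1 > 0))
  force(params); force(b1)
  n_frames <- params$n_readouts %/% params$spokes_per_frame
  if (n_frames < 1) stop("spokes_per_frame exceeds n_readouts")
  alpha_eff <- function() params$flip_angle_deg * (if (is.null(b1)) 1 else b1)
  m <- list(
    type = "irll",
    n_enc = n_frames,
    params = params,
    b1 = b1,
    signal = function(p, M0, T1)
      irll_frame_signal(M0, T1, p, params, alpha_eff()),
    derivs = function(p, M0, T1)
      irll_frame_signal(M0, T1, p, params, alpha_eff(), derivatives = TRUE),
    unit_signal = function(T1) {
      acc <- 0
      for (p in seq_len(n_frames))
        acc <- acc + abs(irll_frame_signal(1, T1, p, params,
                                           params$flip_angle_deg))
      acc / n_frames
    })
  class(m) <- "signal_model"
  m
}

#' @export
print.signal_model <- function(x, ...) {
  if (x$type == "vfa") {
    cat(sprintf("VFA signal model: %d flip angles (%s deg), TR = %g ms%s\n",
                x$n_enc, paste(range(x$flip_angles_deg), collapse = "-"),
                x$tr_ms, if (is.null(x$b1)) "" else ", B1-corrected"))
  } else {
    p <- x$params
    cat(sprintf(paste0("IRLL signal model: alpha = %g deg, tau = %g ms, ",
                       "td = %g ms, tr = %g ms, N = %d readouts, ",
                       "%d spokes/frame -> %d frames%s\n"),
                p$flip_angle_deg, p$tau_ms, p$td_ms, p$tr_ms, p$n_readouts,
                p$spokes_per_frame, x$n_enc,
                if (is.null(x$b1)) "" else ", B1-corrected"))
  }
  invisible(x)
}
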