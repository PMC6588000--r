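# Inner convex solver for the Gauss-Newton subproblems
#
#   min_{u,v} 1/2 ||DA u - d_k||^2 + lambda ( a1 ||grad u - v|| + a0 ||E v|| )
#             + 1/(2 gamma) ||u - u_k||^2
#
# (TGV2; for TV / L1-wavelet the v-block is absent and the regularizer is
# lambda ||H u||).  The saddle-point form min_x max_y <Kx, y> + G(x) - F*(y)
# uses K = [DA, 0; K1] with K1 = [grad, -id; 0, E], F* the sum of the
# quadratic data part in r and the dual-ball indicator in z, and
# G = 1/(2 gamma) ||u - u_k||^2.  It is solved by a primal-dual algorithm
# with Malitsky-Pock line search on the primal step size tau (coupled to
# the dual step by sigma = beta * tau): tau starts at the global bound
# delta / (sqrt(beta) ||K||), may grow by sqrt(1 + theta) per iteration,
# and every accepted step satisfies the directional step-size condition
#   sqrt(beta) * tau * ||K^T (y+ - y)|| <= delta * ||y+ - y||,
# i.e. sigma * tau * ||K||^2 < 1 along the realized dual increment, which
# is what guarantees convergence; the backtracking factor is mu.

#' Construct a saddle-point subproblem
#'
#' Packages a (linearized) data operator, shifted data, regularizer choice
#' and proximal data into the problem object consumed by [pd_solve()].
#' [assemble_subproblem()] builds this from the MRI operators; tests and
#' toy problems can supply any linear `A_op`/`At_op` pair (e.g. the
#' identity, for denoising).
#'
#' @param A_op,At_op linear data operator and its adjoint; `A_op` maps an
#'   unknown array `(nx, ny, nz, nu)` to the data space, `At_op` back.
#' @param dk shifted data (constant of the linearization).
#' @param lambda regularization weight; the dual-ball radii are
#'   `alpha1*lambda` and `alpha0*lambda` (TGV) or `lambda` (TV/wavelet).
#' @param gamma Gauss-Newton step-size penalty: the primal functional
#'   contains `1/(2*gamma) ||u - u_anchor||^2`.
#' @param u_anchor linearization point in internal units.
#' @param reg `"tgv"`, `"tv"` or `"wavelet"`.
#' @param coupling `"joint"` (Frobenius across unknowns) or `"separate"`.
#' @param reg_dim 3 for 3D regularization, 2 to zero z-derivatives.
#' @param alpha1,alpha0 TGV weights (defaults 1 and 2).
#' @param norm_K operator norm of the full K; estimated by power iteration
#'   when `NULL`.
#' @param norm_warm optional warm-start vector for the norm estimate.
#' @param norm_iters power iterations for the norm estimate (fewer suffice
#'   with a warm start).
#' @param wav_levels wavelet decomposition depth (wavelet regularizer).
#' @return object of class `saddle_problem`.
#' @export
saddle_problem <- function(A_op, At_op, dk, lambda, gamma, u_anchor,
                           reg = c("tgv", "tv", "wavelet"),
                           coupling = c("joint", "separate"), reg_dim = 3,
                           alpha1 = 1, alpha0 = 2, norm_K = NULL,
                           norm_warm = NULL, norm_iters = 12,
                           wav_levels = NULL) {
  reg <- match.arg(reg)
  coupling <- match.arg(coupling)
  stopifnot(lambda > 0, gamma > 0, length(dim(u_anchor)) == 4L)
  du <- dim(u_anchor)
  if (reg == "wavelet" && is.null(wav_levels))
    wav_levels <- wavelet_max_level(du[1], du[2])

  prob <- list(reg = reg, coupling = coupling, reg_dim = reg_dim,
               lambda = lambda, gamma = gamma, alpha1 = alpha1,
               alpha0 = alpha0, u_anchor = u_anchor, dk = dk,
               A_op = A_op, At_op = At_op, dims = du,
               wav_levels = wav_levels)
  prob$dual_weights <-
    if (reg == "tgv") list(r = NULL, z1 = NULL, z2 = SYM_WEIGHTS)
    else list(r = NULL, z = NULL)
  class(prob) <- "saddle_problem"

  if (is.null(norm_K)) {
    est <- estimate_operator_norm(
      forward = function(x) K_apply(prob, x),
      adjoint = function(y) Kt_apply(prob, y),
      template = x_template(prob), n_iters = norm_iters, seed = 7,
      warm_start = norm_warm)
    prob$norm_K <- est$norm
    prob$norm_vec <- est$vector
  } else {
    prob$norm_K <- norm_K
    prob$norm_vec <- norm_warm
  }
  prob
}

x_template <- function(prob) {
  du <- prob$dims
  if (prob$reg == "tgv")
    list(u = array(0i, du), v = array(0i, c(du[1:3], 3L, du[4])))
  else list(u = array(0i, du))
}

y_template <- function(prob) {
  du <- prob$dims
  if (prob$reg == "tgv")
    list(r = prob$dk * 0i, z1 = array(0i, c(du[1:3], 3L, du[4])),
         z2 = array(0i, c(du[1:3], 6L, du[4])))
  else if (prob$reg == "tv")
    list(r = prob$dk * 0i, z = array(0i, c(du[1:3], 3L, du[4])))
  else list(r = prob$dk * 0i, z = array(0i, c(du[1:3], 1L, du[4])))
}

# H u for the TV / wavelet regularizers, shaped with a component axis so a
# single dual-projection code path serves all regularizers
H_apply <- function(prob, u) {
  if (prob$reg == "tv") return(grad3(u, prob$reg_dim))
  w <- wavelet_forward(u, prob$wav_levels)
  attr(w, "levels") <- NULL
  du <- prob$dims
  dim(w) <- c(du[1:3], 1L, du[4])
  w
}

Ht_apply <- function(prob, z) {
  if (prob$reg == "tv") return(grad3_adjoint(z, prob$reg_dim))
  du <- prob$dims
  dim(z) <- du
  wavelet_adjoint(z, prob$wav_levels)
}

K_apply <- function(prob, x) {
  if (prob$reg == "tgv") {
    list(r = prob$A_op(x$u),
         z1 = grad3(x$u, prob$reg_dim) - x$v,
         z2 = symgrad(x$v, prob$reg_dim))
  } else {
    list(r = prob$A_op(x$u), z = H_apply(prob, x$u))
  }
}

Kt_apply <- function(prob, y) {
  if (prob$reg == "tgv") {
    list(u = prob$At_op(y$r) + grad3_adjoint(y$z1, prob$reg_dim),
         v = symgrad_adjoint(y$z2, prob$reg_dim) - y$z1)
  } else {
    list(u = prob$At_op(y$r) + Ht_apply(prob, y$z))
  }
}

# prox of sigma F*: quadratic shift for r (done in the fused kernel in the
# main loop), dual-ball projection for the z blocks
prox_z <- function(prob, y) {
  if (prob$reg == "tgv") {
    y$z1 <- project_dual_ball(y$z1, prob$alpha1 * prob$lambda, prob$coupling)
    y$z2 <- project_dual_ball(y$z2, prob$alpha0 * prob$lambda, prob$coupling,
                              weights = SYM_WEIGHTS)
  } else {
    y$z <- project_dual_ball(y$z, prob$lambda, prob$coupling,
                             weights = rep(1, dim(y$z)[4]))
  }
  y
}

prox_G <- function(prob, x, tau) {
  f <- tau / prob$gamma
  x$u <- (x$u + f * prob$u_anchor) / (1 + f)
  x
}

field_norm <- function(prob, f, weights = NULL) {
  w <- weights %||% field_weights(f)
  if (prob$coupling == "joint") norm_122(f, w) else norm_12(f, w)
}

#' Primal objective of the Gauss-Newton subproblem
#'
#' @param x primal iterate (list `u`, and `v` for TGV).
#' @param prob a [saddle_problem()].
#' @param Kx optional cached `K x` to avoid re-applying the operator.
#' @return scalar energy.
#' @export
primal_energy <- function(x, prob, Kx = NULL) {
  if (is.null(Kx)) Kx <- K_apply(prob, x)
  fid <- 0.5 * cpp_cdiff_norm2(Kx$r, prob$dk)
  reg <- if (prob$reg == "tgv") {
    prob$lambda * (prob$alpha1 * field_norm(prob, Kx$z1) +
                     prob$alpha0 * field_norm(prob, Kx$z2, SYM_WEIGHTS))
  } else {
    prob$lambda * field_norm(prob, Kx$z, rep(1, dim(Kx$z)[4]))
  }
  anchor <- cnorm2(x$u - prob$u_anchor) / (2 * prob$gamma)
  fid + reg + anchor
}

# pointwise max of the pooled dual norm, used by the feasibility projection
max_point_norm <- function(z, weights, joint) {
  sqrt(max(pooled_sq(z, weights, joint = joint)))
}

#' Primal-dual gap
#'
#' Duality-gap estimate `E(x) - D(y~)` where the dual candidate is first
#' projected onto the feasible set (for TGV the v-block optimality
#' `z1 = E^T z2` is enforced by rescaling `z2` and substituting
#' `z1 = E^T z2`), so weak duality makes the reported gap nonnegative.
#'
#' @param x,y primal and dual iterates.
#' @inheritParams primal_energy
#' @return scalar, nonnegative up to round-off.
#' @export
pd_gap <- function(x, y, prob, Kx = NULL) {
  joint <- prob$coupling == "joint"
  if (prob$reg == "tgv") {
    sg <- symgrad_adjoint(y$z2, prob$reg_dim)
    m1 <- max_point_norm(sg, rep(1, 3), joint)
    m2 <- max_point_norm(y$z2, SYM_WEIGHTS, joint)
    t <- min(1,
             if (m1 > 0) prob$alpha1 * prob$lambda / m1 else 1,
             if (m2 > 0) prob$alpha0 * prob$lambda / m2 else 1)
    yf <- list(r = y$r, z1 = t * sg, z2 = t * y$z2)
  } else {
    m <- max_point_norm(y$z, rep(1, dim(y$z)[4]), joint)
    t <- min(1, if (m > 0) prob$lambda / m else 1)
    yf <- list(r = y$r, z = t * y$z)
  }
  w <- Kt_apply(prob, yf)$u
  dual <- cdot(w, prob$u_anchor) - prob$gamma / 2 * cnorm2(w) -
    cdot(prob$dk, yf$r) - 0.5 * cnorm2(yf$r)
  primal_energy(x, prob, Kx) - dual
}

dual_diff_norm2 <- function(prob, ya, yb) {
  s <- cpp_cdiff_norm2(ya$r, yb$r)
  if (prob$reg == "tgv") {
    d1 <- ya$z1 - yb$z1
    d2 <- ya$z2 - yb$z2
    s <- s + cdot(d1, d1) + cdot_weighted(d2, d2, SYM_WEIGHTS)
  } else {
    d <- ya$z - yb$z
    s <- s + cdot(d, d)
  }
  s
}

#' Primal-dual solver with line search
#'
#' Solves a [saddle_problem()] by primal-dual iterations: a proximal primal
#' step on (u, v), extrapolation, and a proximal dual step on (r, z), with
#' a line search that adapts the primal step size tau under the coupling
#' `sigma = beta * tau`.  Accepted steps always satisfy
#' `sigma * tau * ||K||^2 < 1`.  The primal energy is tracked every
#' iteration and the primal-dual gap every `gap_every` iterations; the
#' solver stops early when the relative energy change over
#' `energy_window` iterations falls below `tol_energy`, or the relative
#' gap below `tol_gap`.
#'
#' @param prob a [saddle_problem()].
#' @param x0,y0 optional initial primal/dual iterates (zeros by default;
#'   in the reconstruction the primal is warm-started).
#' @param max_iters maximum number of iterations.
#' @param beta initial ratio between dual and primal step sizes.
#' @param mu reduction factor of tau when the line-search test fails.
#' @param delta line-search acceptance constant in (0, 1).
#' @param tol_energy,tol_gap early-stopping tolerances (relative).
#' @param energy_window iterations over which the energy change is
#'   measured.
#' @param gap_every compute the gap every this many iterations.
#' @param max_backtracks backtracks per iteration before declaring
#'   stagnation.
#' @param verbose print per-iteration diagnostics.
#' @return list with `x`, `y`, `energy` (history), `gap` (history, NA where
#'   not computed), `iters`, `converged`, `stagnated`, `tau`,
#'   `ls_condition_max`.
#' @export
pd_solve <- function(prob, x0 = NULL, y0 = NULL, max_iters = 100,
                     beta = 400, mu = 0.5, delta = 0.99,
                     tol_energy = 1e-6, tol_gap = 1e-5,
                     energy_window = 10, gap_every = 10,
                     max_backtracks = 20, verbose = FALSE) {
  stopifnot(max_iters >= 1)
  x <- x0 %||% x_template(prob)
  y <- y0 %||% y_template(prob)
  if (prob$norm_K <= 0) stop("operator norm estimate is zero")
  tau <- delta / (sqrt(beta) * prob$norm_K * 1.01)
  theta <- 1
  sqb <- sqrt(beta)
  ls_ratio_max <- 0

  Kx_cur <- K_apply(prob, x)
  Kt_cur <- Kt_apply(prob, y)
  energy <- numeric(max_iters)
  gaps <- rep(NA_real_, max_iters)
  stag_events <- 0L
  converged <- FALSE
  n_done <- 0L

  for (n in seq_len(max_iters)) {
    xn <- x
    xn$u <- x$u - tau * Kt_cur$u
    if (prob$reg == "tgv") xn$v <- x$v - tau * Kt_cur$v
    xn <- prox_G(prob, xn, tau)
    Kx_new <- K_apply(prob, xn)

    tau_try <- tau * sqrt(1 + theta)
    bt <- 0L
    repeat {
      theta_try <- tau_try / tau
      sigma <- beta * tau_try
      upd <- cpp_dual_r_update(y$r, Kx_new$r, Kx_cur$r, prob$dk,
                               sigma, theta_try)
      yn <- y
      yn$r <- array(upd$r, dim = dim(prob$dk))
      if (prob$reg == "tgv") {
        yn$z1 <- array(cpp_dual_z_update(y$z1, Kx_new$z1, Kx_cur$z1,
                                         sigma, theta_try), dim(y$z1))
        yn$z2 <- array(cpp_dual_z_update(y$z2, Kx_new$z2, Kx_cur$z2,
                                         sigma, theta_try), dim(y$z2))
      } else {
        yn$z <- array(cpp_dual_z_update(y$z, Kx_new$z, Kx_cur$z,
                                        sigma, theta_try), dim(y$z))
      }
      yn <- prox_z(prob, yn)
      Kt_new <- Kt_apply(prob, yn)
      dKt <- la_lin(1, Kt_new, -1, Kt_cur)
      lhs <- sqb * tau_try * sqrt(la_dot(dKt, dKt))
      rhs <- delta * sqrt(dual_diff_norm2(prob, yn, y))
      if (lhs <= rhs || rhs == 0 || bt >= max_backtracks) break
      tau_try <- tau_try * mu
      bt <- bt + 1L
    }
    if (bt >= max_backtracks) stag_events <- stag_events + 1L
    if (rhs > 0) ls_ratio_max <- max(ls_ratio_max, lhs / rhs)

    theta <- tau_try / tau
    tau <- tau_try
    x <- xn; y <- yn; Kx_cur <- Kx_new; Kt_cur <- Kt_new
    energy[n] <- primal_energy(x, prob, Kx_cur)
    n_done <- n

    do_gap <- (n %% gap_every == 0L) || n == max_iters
    if (do_gap) gaps[n] <- pd_gap(x, y, prob, Kx_cur)
    if (verbose)
      message(sprintf("  pd %4d  E = %.8g  gap = %s  tau = %.3g  bt = %d",
                      n, energy[n],
                      if (do_gap) fmt_si(gaps[n]) else "-", tau, bt))

    if (n >= energy_window) {
      de <- abs(energy[n - energy_window + 1L] - energy[n])
      if (de < tol_energy * (1 + abs(energy[n]))) { converged <- TRUE; break }
    }
    if (do_gap && is.finite(gaps[n]) &&
        gaps[n] < tol_gap * (1 + abs(energy[n]))) { converged <- TRUE; break }
    if (stag_events >= 5L) break
  }

  list(x = x, y = y, energy = energy[seq_len(n_done)],
       gap = gaps[seq_len(n_done)], iters = n_done, converged = converged,
       stagnated = stag_events >= 5L, tau = tau,
       ls_condition_max = ls_ratio_max)
}

#' Assemble the Gauss-Newton subproblem for the MRI operators
#'
#' Builds the [saddle_problem()] of one IRGN step: computes the shifted
#' data `d_k = d - A(u_k) + DA u_k`, wraps the precomputed Jacobian into
#' the data operator pair, and sets the dual-ball radii from
#' `lambda` and the TGV weights.
#'
#' @param u_k linearization point in internal units `(nx, ny, nz, 2)`.
#' @param data measured (normalized) k-space.
#' @param lin precomputed linearization from the model at `u_k`.
#' @param scales per-unknown scale factors (M0, T1).
#' @param coils,traj,plan encoding operators.
#' @param reg,coupling,reg_dim regularizer choice.
#' @param lambda,gamma,alpha1,alpha0 regularization parameters.
#' @param norm_K,norm_warm operator-norm estimate / warm start.
#' @param norm_iters power iterations for the norm estimate.
#' @param Auk optional precomputed forward evaluation A(u_k).
#' @return a [saddle_problem()].
#' @export
assemble_subproblem <- function(u_k, data, lin, scales, coils, traj, plan,
                                reg = "tgv", coupling = "joint", reg_dim = 3,
                                lambda, gamma, alpha1 = 1, alpha0 = 2,
                                norm_K = NULL, norm_warm = NULL,
                                norm_iters = 12, Auk = NULL) {
  dc <- dim(coils)
  A_op <- function(du) apply_jacobian_DA(du, lin, scales, coils, traj, plan)
  At_op <- function(res) apply_DA_adjoint(res, lin, scales, coils, traj, plan)
  if (is.null(Auk)) {
    # A(u_k) from the precomputed signal images
    coilsc <- ensure_complex(coils)
    Auk <- array(0i, data_dims(traj, coils))
    for (p in seq_len(traj$n_encodings)) {
      pe <- plan$enc[[p]]
      Auk[, , , , p] <- cpp_sos_forward(ensure_complex(lin$S[[p]]),
                                        coilsc, plan$apod,
                                        pe$gxw, pe$gyo, pe$wx, pe$wy,
                                        dc[1], dc[2], dc[3], dc[4], plan$osn)
    }
  }
  dk <- data - Auk + A_op(u_k)
  saddle_problem(A_op, At_op, dk, lambda, gamma, u_anchor = u_k,
                 reg = reg, coupling = coupling, reg_dim = reg_dim,
                 alpha1 = alpha1, alpha0 = alpha0, norm_K = norm_K,
                 norm_warm = norm_warm, norm_iters = norm_iters)
}
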