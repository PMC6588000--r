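# Independent oracles used across the test suite.  Each deliberately
# recomputes its quantity by a different route than the package code
# (dense matrices, explicit recursions, smoothed quasi-Newton optimization).

rand_carr <- function(dims, seed = NULL) {
  gen <- function() array(complex(real = rnorm(prod(dims)),
                                  imaginary = rnorm(prod(dims))), dims)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

re_dot <- function(a, b) sum(Re(Conj(a) * b))

# dense centred 2D non-uniform DFT + unitary centred z-DFT: the brute-force
# reference for the stack-of-stars encoding
dense_sos_forward <- function(vol, traj, encoding = 1) {
  d <- dim(vol)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  cx <- nx %/% 2; cy <- ny %/% 2; cz <- nz %/% 2
  kx <- as.vector(traj$kx[, , encoding])
  ky <- as.vector(traj$ky[, , encoding])
  xs <- rep(0:(nx - 1), ny) - cx
  ys <- rep(0:(ny - 1), each = nx) - cy
  E <- exp(-2i * pi * (outer(kx, xs) + outer(ky, ys)))   # Ns x (nx*ny)
  kzs <- (0:(nz - 1)) - cz
  zf <- exp(-2i * pi * outer(kzs, (0:(nz - 1)) - cz) / nz) / sqrt(nz)
  out <- array(0i, c(length(kx), nz))
  # z-transform first, then per-kz dense NDFT
  vz <- matrix(vol, nx * ny, nz) %*% t(zf)
  for (k in seq_len(nz)) out[, k] <- E %*% vz[, k]
  array(out, c(traj$n_samples, traj$n_spokes, nz))
}

# discrete Bloch recursion for the IRLL train: perfect inversion, relax td,
# N pulses with N-1 inter-pulse relaxations tau, recovery tr, iterated to
# the cyclic steady state.  Magnetization in units of M0.
bloch_irll <- function(T1, params, alpha_deg = params$flip_angle_deg,
                       tol = 1e-15, max_cycles = 10000) {
  a <- cos(alpha_deg * pi / 180); s <- sin(alpha_deg * pi / 180)
  Et <- exp(-params$tau_ms / T1)
  Er <- exp(-params$tr_ms / T1)
  Ed <- exp(-params$td_ms / T1)
  N <- params$n_readouts
  relax <- function(m, E) 1 + (m - 1) * E
  Mz <- 1
  S <- numeric(N)
  for (cyc in seq_len(max_cycles)) {
    Mz_start <- Mz
    Mz <- relax(-Mz, Ed)                 # inversion, then recover td
    for (n in seq_len(N)) {
      S[n] <- Mz * s
      Mz <- Mz * a
      if (n < N) Mz <- relax(Mz, Et)     # N-1 inter-pulse gaps
    }
    Mz <- relax(Mz, Er)
    if (abs(Mz - Mz_start) < tol) break
  }
  S
}

# central finite difference of f at x
fd_central <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)

# smoothed-objective quasi-Newton solution of a TV/TGV denoising subproblem
#   min 1/2||u - dk||^2 + lambda*R + 1/(2 gamma)||u - anchor||^2
# over complex u (and v for TGV) with joint (Frobenius) coupling, via
# L-BFGS-B on the real/imag split; norms are smoothed as sqrt(. + eps) for
# differentiability and the TRUE (unsmoothed) objective is returned at the
# smoothed minimizer.  Algorithmically independent of the primal-dual path.
oracle_denoise <- function(dk_img, anchor, lambda, gamma,
                           reg = c("tgv", "tv"),
                           alpha1 = 1, alpha0 = 2,
                           eps_schedule = c(1e-6, 1e-10, 1e-14),
                           maxit = 6000) {
  reg <- match.arg(reg)
  eps <- eps_schedule[1]
  du <- dim(anchor)
  vox <- prod(du[1:3]); nu <- du[4]
  dv <- c(du[1:3], 3L, nu)
  nun <- vox * nu
  nvv <- prod(dv)
  w2 <- c(1, 1, 1, 2, 2, 2)

  # joint pooled norm: n(vox) = sqrt(sum_{c,i} w_c |f|^2 + eps)
  pool <- function(f, w) {
    as.vector(radialT1:::pooled_sq(f, w, joint = TRUE))
  }
  sval <- function(f, w) sum(sqrt(pool(f, w) + eps))
  # d/df of sval: w_c * f / n, broadcast over components and unknowns
  sgrad_weighted <- function(f, w) {
    n <- sqrt(pool(f, w) + eps)
    d <- dim(f)
    g <- f * rep(1 / n, times = d[4] * d[5])
    g * rep(rep(w, each = vox), times = d[5])
  }
  # same but WITHOUT the component weights (for use with the weighted
  # adjoint symgrad_adjoint, which supplies them)
  sgrad_raw <- function(f, w) {
    n <- sqrt(pool(f, w) + eps)
    d <- dim(f)
    f * rep(1 / n, times = d[4] * d[5])
  }

  unpack <- function(p) {
    u <- array(complex(real = p[1:nun], imaginary = p[nun + 1:nun]), du)
    v <- if (reg == "tgv")
      array(complex(real = p[2 * nun + 1:nvv],
                    imaginary = p[2 * nun + nvv + 1:nvv]), dv)
    list(u = u, v = v)
  }
  objective <- function(u, v, smoothed) {
    fid <- 0.5 * sum(Mod(u - dk_img)^2)
    anc <- sum(Mod(u - anchor)^2) / (2 * gamma)
    if (reg == "tv") {
      f1 <- grad3(u)
      r <- if (smoothed) sval(f1, rep(1, 3)) else norm_122(f1, rep(1, 3))
      return(fid + anc + lambda * r)
    }
    f1 <- grad3(u) - v
    f2 <- symgrad(v)
    r <- if (smoothed) alpha1 * sval(f1, rep(1, 3)) + alpha0 * sval(f2, w2)
         else alpha1 * norm_122(f1, rep(1, 3)) + alpha0 * norm_122(f2, w2)
    fid + anc + lambda * r
  }
  fn <- function(p) { x <- unpack(p); objective(x$u, x$v, smoothed = TRUE) }
  gr <- function(p) {
    x <- unpack(p)
    gu <- (x$u - dk_img) + (x$u - anchor) / gamma
    if (reg == "tv") {
      g1 <- sgrad_weighted(grad3(x$u), rep(1, 3))
      dim(g1) <- dv
      gu <- gu + lambda * grad3_adjoint(g1)
      return(c(Re(gu), Im(gu)))
    }
    f1 <- grad3(x$u) - x$v
    f2 <- symgrad(x$v)
    g1 <- sgrad_weighted(f1, rep(1, 3)); dim(g1) <- dv
    g2r <- sgrad_raw(f2, w2); dim(g2r) <- dim(f2)
    gu <- gu + lambda * alpha1 * grad3_adjoint(g1)
    gv <- lambda * (-alpha1 * g1 + alpha0 * symgrad_adjoint(g2r))
    c(Re(gu), Im(gu), Re(gv), Im(gv))
  }
  # smoothing continuation: solve with decreasing eps, warm-starting each
  # stage from the previous minimizer (L-BFGS on the tightly smoothed
  # problem alone converges very slowly)
  p <- c(Re(dk_img), Im(dk_img),
         if (reg == "tgv") rep(0, 2 * nvv))
  for (e in eps_schedule) {
    eps <- e
    res <- optim(p, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = 10))
    p <- res$par
  }
  x <- unpack(p)
  objective(x$u, x$v, smoothed = FALSE)
}
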