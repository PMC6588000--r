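make_denoise_problem <- function(seed, reg = "tgv", n = 8, lambda = 0.25,
                                 gamma = 20, coupling = "joint") {
  dk <- rand_carr(c(n, n, 1, 2), seed = seed)
  anchor <- 0.3 * rand_carr(c(n, n, 1, 2), seed = seed + 1000)
  prob <- saddle_problem(identity, identity, dk, lambda = lambda,
                         gamma = gamma, u_anchor = anchor, reg = reg,
                         coupling = coupling, norm_iters = 60)
  list(prob = prob, dk = dk, anchor = anchor)
}

test_that("zero data, zero anchor: the solver converges to zero", {
  dk <- array(0i, c(6, 6, 1, 2))
  prob <- saddle_problem(identity, identity, dk, lambda = 0.2, gamma = 10,
                         u_anchor = dk, reg = "tgv", norm_iters = 40)
  sol <- pd_solve(prob, max_iters = 300)
  expect_lt(sqrt(sum(Mod(sol$x$u)^2)), 1e-8)
})

test_that("strongly convex quadratic toy matches the closed form", {
  # K = identity on u, negligible regularizer: the minimizer of
  # 1/2||u - dk||^2 + 1/(2 gamma)||u - anchor||^2 is
  # (gamma dk + anchor) / (gamma + 1)
  dk <- rand_carr(c(6, 6, 1, 2), seed = 31)
  anchor <- rand_carr(c(6, 6, 1, 2), seed = 32)
  gamma <- 3
  prob <- saddle_problem(identity, identity, dk, lambda = 1e-12,
                         gamma = gamma, u_anchor = anchor, reg = "tv",
                         norm_iters = 50)
  sol <- pd_solve(prob, max_iters = 2000, tol_energy = 1e-14,
                  tol_gap = 1e-12)
  ustar <- (gamma * dk + anchor) / (gamma + 1)
  expect_lt(max(abs(sol$x$u - ustar)), 1e-6)
  # at the optimum of this toy the projected-dual gap is essentially zero
  gfin <- tail(sol$gap[!is.na(sol$gap)], 1)
  expect_lt(gfin, 1e-6 * (1 + abs(tail(sol$energy, 1))))
})

test_that("PD objective reaches the convex-solver optimum (TV and TGV)", {
  for (cfg in list(list(seed = 1, reg = "tv"), list(seed = 2, reg = "tgv"),
                   list(seed = 3, reg = "tv"))) {
    mp <- make_denoise_problem(cfg$seed, cfg$reg)
    sol <- pd_solve(mp$prob, max_iters = 8000, tol_energy = 1e-13,
                    tol_gap = 1e-9, gap_every = 100)
    e_pd <- primal_energy(sol$x, mp$prob)
    e_or <- oracle_denoise(mp$dk, mp$anchor, lambda = 0.25, gamma = 20,
                           reg = cfg$reg)
    expect_lt(abs(e_pd - e_or) / abs(e_or), 1e-4)
  }
})

test_that("energy and gap diagnostics behave as monitors", {
  mp <- make_denoise_problem(5, "tgv")
  sol <- pd_solve(mp$prob, max_iters = 4000, gap_every = 100,
                  tol_energy = 0, tol_gap = 0)
  # primal energy near-monotone over the final 20 iterations (the line
  # search makes early iterations non-monotone; near the optimum the
  # fluctuations fall below the tolerance)
  e <- tail(sol$energy, 20)
  expect_true(all(diff(e) <= 1e-8 * (1 + abs(e[-length(e)]))))
  # the (feasibility-projected) gap shrinks towards the optimum and stays
  # a small fraction of the primal energy
  g <- sol$gap[!is.na(sol$gap)]
  efin <- tail(sol$energy, 1)
  expect_lt(tail(g, 1), 5e-3 * (1 + abs(efin)))
  expect_lt(tail(g, 1), 0.2 * g[1])
  # weak duality: gap nonnegative at random feasible duals
  y <- radialT1:::y_template(mp$prob)
  y$r <- 0.5 * rand_carr(dim(y$r), seed = 41)
  y$z1 <- rand_carr(dim(y$z1), seed = 42)
  y$z2 <- rand_carr(dim(y$z2), seed = 43)
  y <- radialT1:::prox_z(mp$prob, y)
  x <- radialT1:::x_template(mp$prob)
  x$u <- rand_carr(dim(x$u), seed = 44)
  expect_gte(pd_gap(x, y, mp$prob), 0)
  # doubling lambda doubles the regularization part of the energy
  p1 <- mp$prob; p2 <- mp$prob; p2$lambda <- 2 * p1$lambda
  e1 <- primal_energy(x, p1); e2 <- primal_energy(x, p2)
  fid_anchor <- 0.5 * sum(Mod(x$u - p1$dk)^2) +
    sum(Mod(x$u - p1$u_anchor)^2) / (2 * p1$gamma)
  expect_equal(e2 - fid_anchor, 2 * (e1 - fid_anchor), tolerance = 1e-10)
})

test_that("accepted steps satisfy the line-search step-size condition", {
  # directional form of sigma * tau * ||K||^2 < 1: at every accepted step
  # sqrt(beta) tau ||K^T dy|| <= delta ||dy||; the reported maximum ratio
  # stays below 1
  mp <- make_denoise_problem(7, "tgv")
  sol <- pd_solve(mp$prob, max_iters = 150)
  expect_lt(sol$ls_condition_max, 1)
  mp2 <- make_denoise_problem(8, "tv")
  sol2 <- pd_solve(mp2$prob, max_iters = 150)
  expect_lt(sol2$ls_condition_max, 1)
})

test_that("subproblem assembly: fixed point and dense-operator oracle", {
  set.seed(51)
  tr <- make_trajectory(3, 8, n_encodings = 2)
  model <- vfa_model(c(5, 15), 5.38)
  coils <- biot_savart_coils(2, c(4, 4, 1))
  plan <- nufft_plan(tr, 4, 4)
  maps <- list(M0 = array(0.8 + 0i, c(4, 4, 1)),
               T1 = array(1000 + 0i, c(4, 4, 1)))
  lin <- radialT1:::precompute_linearization(maps, model)
  scales <- c(1, 1000)
  u_k <- array(0i, c(4, 4, 1, 2))
  u_k[, , , 1] <- maps$M0; u_k[, , , 2] <- maps$T1 / scales[2]
  data <- apply_forward_A(maps, model, coils, tr, plan)
  prob <- assemble_subproblem(u_k, data, lin, scales, coils, tr, plan,
                              lambda = 0.01, gamma = 10, norm_iters = 40)
  # at u_k with A(u_k) = d the shifted data equal DA u_k
  DAuk <- apply_jacobian_DA(u_k, lin, scales, coils, tr, plan)
  expect_lt(max(abs(prob$dk - DAuk)), 1e-9 * max(abs(DAuk)))
  # the assembled K matches an explicitly constructed dense block matrix
  # (data block only; the regularization blocks are tested elsewhere)
  nuu <- length(u_k)
  Adense <- matrix(0i, length(data), nuu)
  for (j in seq_len(nuu)) {
    e <- array(0i, dim(u_k)); e[j] <- 1
    Adense[, j] <- as.vector(prob$A_op(e))
  }
  du <- rand_carr(dim(u_k), seed = 52)
  expect_lt(max(abs(Adense %*% as.vector(du) -
                      as.vector(prob$A_op(du)))), 1e-8)
  # data generated at the linearization point: the minimizer barely moves
  sol <- pd_solve(prob, x0 = list(u = u_k, v = array(0i, c(4, 4, 1, 3, 2))),
                  max_iters = 200)
  expect_lt(sqrt(sum(Mod(sol$x$u - u_k)^2)) / sqrt(sum(Mod(u_k)^2)), 0.05)
})

test_that("lambda -> infinity forces an affine minimizer (grad u = v, Ev = 0)", {
  dk <- rand_carr(c(8, 8, 1, 1), seed = 61)
  anchor <- array(0i, c(8, 8, 1, 1))
  prob <- saddle_problem(identity, identity, dk, lambda = 1e4, gamma = 1e4,
                         u_anchor = anchor, reg = "tgv", norm_iters = 50)
  sol <- pd_solve(prob, max_iters = 4000, tol_energy = 1e-13, tol_gap = 1e-11)
  g <- grad3(sol$x$u)
  scale_u <- sqrt(sum(Mod(sol$x$u)^2))
  expect_lt(norm_122(g - sol$x$v), 1e-3 * scale_u)
  expect_lt(norm_122(symgrad(sol$x$v)), 1e-3 * scale_u)
})
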