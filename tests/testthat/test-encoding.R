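test_that("golden-angle spoke sequence", {
  a <- golden_angle_spokes(17, 0)
  expect_equal(a[1], 0)
  expect_equal(a[2], 111.25)
  expect_equal(a[17], (16 * 111.25) %% 360)   # modular-arithmetic oracle
  # continuation: encoding p starts at index spokes * (p-1)
  tr <- make_trajectory(34, 16, n_encodings = 10, continue_across = TRUE)
  expect_equal(tr$angles[1, 4], ((34 * 3 * 111.25) %% 360) * pi / 180,
               tolerance = 1e-12)
  # golden angles never repeat within any Fibonacci spoke count <= 89
  for (nsp in c(5, 8, 13, 21, 34, 55, 89)) {
    ang <- golden_angle_spokes(nsp, 0)
    expect_equal(length(unique(round(ang, 9))), nsp)
  }
})

test_that("trajectory sampling convention", {
  tr <- make_trajectory(1, 4)
  r <- sqrt(tr$kx[, 1, 1]^2 + tr$ky[, 1, 1]^2) * sign(tr$kx[, 1, 1] + 1e-30)
  expect_equal(tr$kx[, 1, 1], c(-0.5, -0.25, 0, 0.25), tolerance = 1e-12)
  expect_equal(tr$ky[, 1, 1], rep(0, 4), tolerance = 1e-12)
  # every spoke of a 21-spoke set has exactly one sample at k = 0
  tr2 <- make_trajectory(21, 32)
  for (s in 1:21) {
    at0 <- sum(abs(tr2$kx[, s, 1]) < 1e-12 & abs(tr2$ky[, s, 1]) < 1e-12)
    expect_equal(at0, 1)
  }
  expect_true(all(abs(tr2$kx) < 0.5 + 1e-12 & abs(tr2$ky) < 0.5 + 1e-12))
})

test_that("NUFFT forward: zero, impulse, dense-DFT oracle", {
  tr <- make_trajectory(5, 32, n_encodings = 2)
  z <- nufft_forward(array(0i, c(16, 16, 4)), tr)
  expect_equal(max(abs(z)), 0)
  # centred unit impulse -> constant modulus
  imp <- array(0i, c(16, 16, 1)); imp[9, 9, 1] <- 1  # floor(n/2) 0-based = 8
  di <- nufft_forward(imp, tr)
  expect_lt(max(abs(abs(di) - 1)), 1e-6)
  # dense oracle on random volume, both encodings
  vol <- rand_carr(c(16, 16, 4), seed = 3)
  for (p in 1:2) {
    d1 <- nufft_forward(vol, tr, encoding = p)
    d0 <- dense_sos_forward(vol, tr, encoding = p)
    expect_lt(max(abs(d1 - d0)) / max(abs(d0)), 1e-6)
  }
})

test_that("NUFFT adjoint is the exact conjugate transpose", {
  tr <- make_trajectory(5, 32)
  plan <- nufft_plan(tr, 16, 16)
  x <- rand_carr(c(16, 16, 4), seed = 4)
  y <- rand_carr(c(32, 5, 4), seed = 5)
  lhs <- re_dot(y, nufft_forward(x, tr, plan = plan))
  rhs <- re_dot(nufft_adjoint(y, tr, 16, 16, 4, plan = plan), x)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  expect_error(nufft_forward(rand_carr(c(8, 8, 2)), tr, plan = plan))
})

test_that("forward model A: zeros, composition, dense oracle", {
  tr <- make_trajectory(3, 8, n_encodings = 2)
  model <- vfa_model(c(5, 15), 5.38)
  coils1 <- array(1 + 0i, c(4, 4, 1, 1))
  maps <- list(M0 = rand_carr(c(4, 4, 1), seed = 8),
               T1 = array(runif(16, 400, 2000) + 0i, c(4, 4, 1)))
  # M0 = 0 gives zero data
  z <- apply_forward_A(list(M0 = maps$M0 * 0, T1 = maps$T1), model, coils1, tr)
  expect_equal(max(abs(z)), 0)
  # single coil b = 1: A equals the NUFFT of the signal image
  A1 <- apply_forward_A(maps, model, coils1, tr)
  for (p in 1:2) {
    s <- vfa_signal(maps$M0, maps$T1, c(5, 15)[p], 5.38)
    expect_equal(as.vector(A1[, , , 1, p]),
                 as.vector(nufft_forward(s, tr, encoding = p)),
                 tolerance = 1e-12)
  }
  # 2-coil toy vs brute-force dense DFT
  coils2 <- biot_savart_coils(2, c(4, 4, 1))
  A2 <- apply_forward_A(maps, model, coils2, tr)
  for (p in 1:2) for (cc in 1:2) {
    s <- vfa_signal(maps$M0, maps$T1, c(5, 15)[p], 5.38)
    bi <- array(coils2[, , , cc], c(4, 4, 1))
    ref <- dense_sos_forward(s * bi, tr, encoding = p)
    expect_lt(max(abs(as.vector(A2[, , , cc, p]) - as.vector(ref))) /
                max(abs(ref)), 1e-5)
  }
})

test_that("Jacobian DA: zero input, Taylor remainder, adjointness", {
  set.seed(21)
  tr <- make_trajectory(5, 16, n_encodings = 3)
  model <- vfa_model(c(3, 9, 17), 5.38)
  coils <- biot_savart_coils(2, c(8, 8, 2))
  plan <- nufft_plan(tr, 8, 8)
  maps <- list(M0 = array(1 + 0i, c(8, 8, 2)),
               T1 = array(900 + 0i, c(8, 8, 2)))
  lin <- radialT1:::precompute_linearization(maps, model)
  scales <- c(0.05, 1100)
  du <- rand_carr(c(8, 8, 2, 2), seed = 9)
  expect_equal(max(abs(apply_jacobian_DA(du * 0, lin, scales, coils, tr, plan))), 0)
  # adjointness
  y <- rand_carr(c(16, 5, 2, 2, 3), seed = 10)
  Ax <- apply_jacobian_DA(du, lin, scales, coils, tr, plan)
  Aty <- apply_DA_adjoint(y, lin, scales, coils, tr, plan)
  lhs <- re_dot(y, Ax); rhs <- re_dot(Aty, du)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  # Taylor remainder ||A(u + h du) - A(u) - h DA du|| = O(h^2)
  A_at <- function(mM0, mT1)
    apply_forward_A(list(M0 = mM0, T1 = mT1), model, coils, tr, plan)
  A0 <- A_at(maps$M0, maps$T1)
  rem <- sapply(c(1e-2, 5e-3, 2.5e-3), function(h) {
    Ah <- A_at(maps$M0 + h * scales[1] * du[, , , 1],
               maps$T1 + h * scales[2] * du[, , , 2])
    sqrt(sum(Mod(Ah - A0 - h * Ax)^2))
  })
  # halving h divides the remainder by about 4
  expect_lt(rem[2] / rem[1], 0.3)
  expect_lt(rem[3] / rem[2], 0.3)
})

test_that("operator norm estimation by power iteration", {
  # identity on a grid
  est <- estimate_operator_norm(identity, identity,
                                array(0i, c(6, 6, 2)), n_iters = 10, seed = 2)
  expect_equal(est$norm, 1, tolerance = 1e-6)
  # diagonal scaling with maximum 3
  dsc <- array(runif(72, 0.2, 2.9), c(6, 6, 2)); dsc[3, 4, 1] <- 3
  fop <- function(x) dsc * x
  est2 <- estimate_operator_norm(fop, fop, array(0i, c(6, 6, 2)),
                                 n_iters = 300, seed = 2)
  expect_equal(est2$norm, 3, tolerance = 1e-4)
  # random 20 x 20 matrix vs dense SVD
  M <- withr::with_seed(6, matrix(rnorm(400), 20))
  fop3 <- function(x) array(M %*% as.vector(x), c(20, 1, 1))
  aop3 <- function(y) array(t(M) %*% as.vector(y), c(20, 1, 1))
  est3 <- estimate_operator_norm(fop3, aop3, array(0i, c(20, 1, 1)),
                                 n_iters = 400, seed = 3)
  expect_equal(est3$norm, max(svd(M)$d), tolerance = 1e-4)
  # zero operator
  z <- estimate_operator_norm(function(x) 0 * x, function(x) 0 * x,
                              array(0i, c(4, 4, 1)), n_iters = 5, seed = 1)
  expect_equal(z$norm, 0)
})
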