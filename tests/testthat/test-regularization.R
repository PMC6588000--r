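wdot <- function(a, b, w) {
  d <- dim(a); m <- Re(Conj(a) * b)
  dim(m) <- c(prod(d[1:3]), d[4], d[5])
  s <- 0
  for (i in seq_len(d[5])) s <- s + sum(m[, , i] %*% w)
  s
}

test_that("gradient: constants, ramps, adjointness", {
  u <- array(3.7 + 0i, c(6, 6, 4, 2))
  expect_equal(max(abs(grad3(u))), 0)
  # linear ramp along x with slope s: x-derivative s in the interior
  s <- 0.6
  ramp <- array(rep(s * (1:6), 6 * 4), c(6, 6, 4, 1))
  g <- grad3(ramp)
  expect_equal(max(abs(g[1:5, , , 1, 1] - s)), 0, tolerance = 1e-12)
  expect_equal(max(abs(g[6, , , 1, 1])), 0)           # Neumann boundary
  expect_equal(max(abs(g[, , , 2:3, 1])), 0)
  # adjointness on random fields
  uu <- rand_carr(c(8, 8, 4, 2), seed = 1)
  vv <- rand_carr(c(8, 8, 4, 3, 2), seed = 2)
  lhs <- re_dot(vv, grad3(uu)); rhs <- re_dot(grad3_adjoint(vv), uu)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-8)
  # matches the plain R shift-based implementation
  ref <- array(0i, dim(grad3(uu)))
  for (k in 1:3) ref[, , , k, ] <- radialT1:::fdiff(uu, k)
  expect_equal(grad3(uu), ref)
})

test_that("symmetrized derivative: constants, linear fields, adjointness", {
  v <- array(1 - 2i, c(6, 6, 4, 3, 1))
  expect_equal(max(abs(symgrad(v))), 0)
  # v = (a*x, 0, 0): xx component is a in the interior, everything else 0
  a <- 1.3
  vf <- array(0i, c(6, 6, 4, 3, 1))
  vf[, , , 1, 1] <- rep(a * (1:6), 6 * 4)
  E <- symgrad(vf)
  expect_equal(max(abs(E[2:5, , , 1, 1] - a)), 0, tolerance = 1e-12)
  expect_equal(max(abs(E[, , , 2:6, 1])), 0, tolerance = 1e-12)
  # weighted adjointness
  vv <- rand_carr(c(8, 8, 4, 3, 2), seed = 3)
  xi <- rand_carr(c(8, 8, 4, 6, 2), seed = 4)
  w <- c(1, 1, 1, 2, 2, 2)
  lhs <- wdot(xi, symgrad(vv), w)
  rhs <- re_dot(symgrad_adjoint(xi), vv)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-8)
})

test_that("2D-regularization mode zeroes z-derivatives consistently", {
  uu <- rand_carr(c(8, 8, 4, 2), seed = 5)
  g2 <- grad3(uu, reg_dim = 2)
  expect_equal(max(abs(g2[, , , 3, ])), 0)
  vv <- rand_carr(c(8, 8, 4, 3, 2), seed = 6)
  xi <- rand_carr(c(8, 8, 4, 6, 2), seed = 7)
  w <- c(1, 1, 1, 2, 2, 2)
  lhs <- wdot(xi, symgrad(vv, reg_dim = 2), w)
  rhs <- re_dot(symgrad_adjoint(xi, reg_dim = 2), vv)
  expect_lt(abs(lhs - rhs) / max(abs(lhs), 1), 1e-8)
  lhs2 <- re_dot(vv, g2); rhs2 <- re_dot(grad3_adjoint(vv, reg_dim = 2), uu)
  expect_lt(abs(lhs2 - rhs2) / abs(lhs2), 1e-8)
})

test_that("joint and separate norms follow their printed definitions", {
  # single nonzero entry 3 + 4i -> modulus 5
  f <- array(0i, c(4, 4, 1, 3, 2)); f[2, 3, 1, 1, 1] <- 3 + 4i
  expect_equal(norm_122(f), 5)
  expect_equal(norm_12(f), 5)
  # two unknowns with identical single-voxel vectors of length L
  f2 <- array(0i, c(4, 4, 1, 3, 2))
  f2[1, 1, 1, , 1] <- c(1, 2, 2); f2[1, 1, 1, , 2] <- c(1, 2, 2)  # L = 3
  expect_equal(norm_122(f2), sqrt(2) * 3)
  expect_equal(norm_12(f2), 2 * 3)
  # unit off-diagonal tensor entry carries weight 2
  xi <- array(0i, c(4, 4, 1, 6, 1)); xi[1, 1, 1, 4, 1] <- 1
  expect_equal(norm_122(xi), sqrt(2))
  # joint <= separate on random fields (Cauchy-Schwarz pooling)
  for (s in 1:5) {
    fr <- rand_carr(c(5, 5, 3, 3, 2), seed = 100 + s)
    expect_lte(norm_122(fr), norm_12(fr) + 1e-12)
  }
})

test_that("dual-ball projection: identity inside, scaling outside", {
  z <- array(0i, c(4, 4, 2, 3, 2))
  z[1, 1, 1, , 1] <- c(0.1, 0.1, 0)
  expect_equal(project_dual_ball(z, 1), z)
  # single voxel vector of norm 2r -> scaled by 1/2
  r <- 0.7
  z2 <- array(0i, c(4, 4, 1, 3, 1)); z2[2, 2, 1, , 1] <- c(2 * r, 0, 0)
  pz <- project_dual_ball(z2, r)
  expect_equal(Re(pz[2, 2, 1, 1, 1]), r, tolerance = 1e-12)
  # joint vs separate differ when one unknown is large, one small;
  # brute-force per-point projection as oracle
  z3 <- rand_carr(c(3, 3, 2, 3, 2), seed = 11)
  z3[, , , , 1] <- 5 * z3[, , , , 1]
  for (cpl in c("joint", "separate")) {
    pz3 <- project_dual_ball(z3, 1.2, cpl)
    for (i in 1:3) for (j in 1:3) for (k in 1:2) {
      if (cpl == "joint") {
        n <- sqrt(sum(abs(z3[i, j, k, , ])^2))
        f <- 1 / max(1, n / 1.2)
        expect_equal(pz3[i, j, k, , ], z3[i, j, k, , ] * f,
                     tolerance = 1e-12)
      } else {
        for (uidx in 1:2) {
          n <- sqrt(sum(abs(z3[i, j, k, , uidx])^2))
          f <- 1 / max(1, n / 1.2)
          expect_equal(pz3[i, j, k, , uidx], z3[i, j, k, , uidx] * f,
                       tolerance = 1e-12)
        }
      }
    }
  }
  expect_false(isTRUE(all.equal(project_dual_ball(z3, 1.2, "joint"),
                                project_dual_ball(z3, 1.2, "separate"))))
})

test_that("TGV2 value: affine images, TV reduction", {
  # u affine, v = grad u: the objective vanishes in the interior and only
  # the outermost boundary plane contributes (the Neumann gradient zeroes
  # the last forward difference), so the value is a vanishing fraction of
  # alpha1 * TV(u) as the grid grows
  n <- 24
  d <- c(n, n, 1, 1)
  xs <- rep(1:n, n); ys <- rep(1:n, each = n)
  u <- array((2 + 0.5 * xs + 0.25 * ys) + 0i, d)
  v <- grad3(u)
  expect_lt(tgv2_value(u, v) / tv_value(u), 0.2)
  # interior of E(grad u) is exactly zero
  E <- symgrad(v)
  expect_equal(max(abs(E[2:(n - 1), 2:(n - 1), 1, , 1])), 0,
               tolerance = 1e-12)
  # v = 0 reduces to alpha1 * TV(u)
  uu <- rand_carr(c(6, 6, 4, 2), seed = 12)
  v0 <- array(0i, c(6, 6, 4, 3, 2))
  expect_equal(tgv2_value(uu, v0, alpha1 = 1.3), 1.3 * tv_value(uu),
               tolerance = 1e-12)
  # TV vanishes exactly on constants
  expect_equal(tv_value(array(5 + 1i, c(4, 4, 2, 1))), 0)
})

test_that("wavelet transform: round trip, Parseval, adjointness, levels", {
  u <- rand_carr(c(16, 16, 2, 2), seed = 13)
  w <- wavelet_forward(u)
  expect_equal(attr(w, "levels"), 2)   # floor(log2(16/3)) = 2
  expect_lt(max(abs(wavelet_adjoint(w) - u)), 1e-10)
  expect_lt(abs(sqrt(sum(abs(w)^2)) - sqrt(sum(abs(u)^2))), 1e-10)
  # adjointness (orthonormal: adjoint = inverse)
  y <- rand_carr(c(16, 16, 2, 2), seed = 14)
  lhs <- re_dot(y, wavelet_forward(u, 2))
  rhs <- re_dot(wavelet_adjoint(y, 2), u)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-8)
  expect_equal(wavelet_max_level(64), 4)   # matches floor(log2(64/3))
  expect_error(wavelet_forward(rand_carr(c(2, 2, 1, 1))), "too small")
})

test_that("TGV2 inner minimum over v matches the convex-solver oracle", {
  # tiny denoising problem solved two ways: pd_solve on the saddle form vs
  # smoothed quasi-Newton on the primal
  set.seed(15)
  dk <- rand_carr(c(4, 4, 1, 2), seed = 15)
  anchor <- array(0i, c(4, 4, 1, 2))
  prob <- saddle_problem(identity, identity, dk, lambda = 0.3, gamma = 50,
                         u_anchor = anchor, reg = "tgv", norm_iters = 60)
  sol <- pd_solve(prob, max_iters = 3000, tol_energy = 1e-12, tol_gap = 1e-9)
  e_pd <- primal_energy(sol$x, prob)
  e_or <- oracle_denoise(dk, anchor, lambda = 0.3, gamma = 50, reg = "tgv")
  expect_lt(abs(e_pd - e_or) / abs(e_or), 1e-4)
})
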