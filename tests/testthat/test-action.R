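test_that("geometric action is zero along the deterministic flow", {
  p <- fx_params()
  H <- fx_ham()
  tr <- cc_integrate(fx_p2() + c(0.05, 0, 0), p, 400, dt_out = 0.02)
  A <- geometric_action(tr[, c("x", "y", "z")], H)
  # relaxation paths cost nothing; the residual is chord-discretization error
  expect_lt(A, 1e-4)
  He <- ham_extrinsic(p)
  expect_lt(geometric_action(tr[, c("x", "y", "z")], He), 1e-4)
  # zero-length path
  still <- matrix(rep(c(1, 1, 1), 5), ncol = 3, byrow = TRUE)
  expect_equal(geometric_action(still, H), 0)
})

test_that("the per-segment cost is 1-homogeneous: reparametrization invariance", {
  # the geometric action never sees the time parametrization; discretely this
  # is exact 1-homogeneity of the segment cost in the chord
  H <- fx_ham()
  set.seed(11)
  x <- runif(3, 0.2, 4)
  v <- runif(3, -1, 1) * 0.3
  a1 <- geometric_action(rbind(x, x + v), H)
  m <- x + v / 2
  s1 <- geometric_action(rbind(m - v / 2, m + v / 2), H)
  for (c in c(0.1, 0.5, 2)) {
    sc <- geometric_action(rbind(m - c * v / 2, m + c * v / 2), H)
    expect_lt(abs(sc / s1 - c) / c, 1e-8)
  }
  expect_gt(a1, 0)
})

test_that("1-D birth-death action matches the closed form within 1 percent", {
  cb <- 1; kd <- 1
  H <- ham_spec("intrinsic", "bd1", c(cb, kd))
  X <- 2 * cb / kd
  exact <- bd1_quasipotential(X, cb, kd)
  path <- matrix(seq(cb / kd, X, length.out = 101))
  expect_lt(abs(geometric_action(path, H) - exact) / exact, 0.01)
  mp <- minimize_action(H, cb / kd, X, n_nodes = 101)
  expect_lt(abs(attr(mp, "action") - exact) / exact, 0.01)
  # node-doubling convergence at the quadrature's O(h^2) rate
  a100 <- geometric_action(matrix(seq(cb / kd, X, length.out = 101)), H)
  a200 <- geometric_action(matrix(seq(cb / kd, X, length.out = 201)), H)
  expect_lt(abs(a200 - exact), abs(a100 - exact) + 1e-12)
})

test_that("gradient of the action agrees with finite differences", {
  H <- fx_ham()
  set.seed(21)
  path <- rbind(fx_p1(),
                matrix(runif(9, 0.5, 3), ncol = 3),
                c(3, 1, 0.5))
  g <- yeastscape:::cpp_action_grad(H$kcode, H$mcode, H$par, path)
  a0 <- geometric_action(path, H)
  h <- 1e-6
  for (i in 2:4) for (k in 1:3) {
    pp <- path; pp[i, k] <- pp[i, k] + h
    pm <- path; pm[i, k] <- pm[i, k] - h
    fd <- (geometric_action(pp, H) - geometric_action(pm, H)) / (2 * h)
    expect_equal(g[i, k], fd, tolerance = 1e-3)
  }
})

test_that("minimization follows steepest ascent in a gradient system: S = 2U", {
  # single-well anisotropic quadratic U = (x^2 + 2 y^2)/2 under additive noise
  Hq <- ham_spec("extrinsic", "quadwell", c(1, 2, 0, 0))
  for (tgt in list(c(1.5, 1), c(-1, 0.5), c(0.8, -1.2))) {
    mp <- minimize_action(Hq, c(0, 0), tgt, n_nodes = 50, max_iter = 6000,
                          tol = 1e-11)
    U <- (tgt[1]^2 + 2 * tgt[2]^2) / 2
    expect_lt(abs(attr(mp, "action") / U - 2), 0.05)
    expect_true(attr(mp, "converged"))
  }
  # degenerate transition: identical endpoints
  mp0 <- minimize_action(Hq, c(1, 1), c(1, 1))
  expect_equal(attr(mp0, "action"), 0)
})

test_that("minimize_action reports convergence state and tidies cleanly", {
  Hq <- ham_spec("extrinsic", "quadwell", c(1, 8, 0, 0))
  mpu <- minimize_action(Hq, c(0, 0), c(2, 2), n_nodes = 40, max_iter = 2L)
  expect_false(attr(mpu, "converged"))
  H <- ham_spec("intrinsic", "bd1", c(1, 1))
  mp <- minimize_action(H, 1, 2, n_nodes = 31, max_iter = 500L)
  gl <- glance(mp)
  expect_named(gl, c("action", "n_nodes", "converged", "iterations"))
  td <- tidy(mp)
  expect_equal(nrow(td), 31)
  expect_equal(td$arclength[1], 0)
  expect_true(all(diff(td$arclength) >= 0))
})

test_that("the G1 well depth is a positive barrier at baseline", {
  d <- fx("well_depth", g1_well_depth(fx_params(), n_nodes = 40,
                                      max_iter = 3000, tol = 1e-9))
  expect_gt(d, 0)
  expect_lt(d, 1)
})
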