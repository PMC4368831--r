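test_that("a gradient-system grid recovers twice the potential pointwise", {
  Hq <- ham_spec("extrinsic", "quadwell", c(1, 2, 0, 0))
  g <- quasipotential_grid(Hq, c(0, 0),
                           axes = list(x = seq(-1.5, 1.5, length.out = 13),
                                       y = seq(-1.5, 1.5, length.out = 13)),
                           n_path_nodes = 30L, max_iter = 800L, tol = 1e-9)
  df <- tidy(g)
  U <- (df$x^2 + 2 * df$y^2) / 2
  off <- U > 0.05
  expect_lt(max(abs(df$S[off] / U[off] - 2)), 0.05)
  expect_equal(df$S[df$x == 0 & df$y == 0], 0)
  expect_true(all(df$S >= 0))
})

test_that("hj_residual vanishes for exact landscapes and refines for bd1", {
  # constant grid: H(x, 0) = 0 everywhere
  Hbd <- ham_spec("intrinsic", "bd1", c(1, 1))
  gflat <- yeastscape:::new_landscape_grid(array(1, 41), list(seq(0.5, 2.5, length.out = 41)),
                                           matrix(1, 1, 1), Hbd)
  expect_lt(hj_residual(gflat)$max_residual, 1e-12)
  # analytic 1-D quasi-potential: residual decreases toward 0 with spacing
  res <- vapply(c(21, 41, 81, 161), function(n) {
    ax <- seq(0.5, 2.5, length.out = n)
    g <- yeastscape:::new_landscape_grid(array(bd1_quasipotential(ax), n),
                                         list(ax), matrix(1, 1, 1), Hbd)
    hj_residual(g)$mean_residual
  }, 0)
  expect_true(all(diff(res) < 0))
  expect_lt(res[4], res[1] / 10)
})

test_that("force field reduces to the drift where the landscape is flat", {
  Hbd <- ham_spec("intrinsic", "bd1", c(1, 1))
  ax <- seq(0.5, 2.5, length.out = 81)
  g <- yeastscape:::new_landscape_grid(array(bd1_quasipotential(ax), 81),
                                       list(ax), matrix(1, 1, 1), Hbd)
  ff <- force_field(g)
  # at the fixed point x* = 1 the gradient vanishes and F = b = 0
  i1 <- which.min(abs(ff$x - 1))
  expect_lt(abs(ff$Fx[i1] - ff$bx[i1]), 2e-3)
  # with the exact gradient p = ln(kx/c), F = dH/dp = c e^p - kx e^-p = kx - c
  expect_lt(max(abs(ff$Fx - (ff$x - 1))), 0.05)
  # extrinsic kind: F = b + grad S exactly
  He <- ham_spec("extrinsic", "quadwell", c(1, 1, 0, 0))
  gq <- quasipotential_grid(He, c(0, 0),
                            axes = list(x = seq(-1, 1, length.out = 11),
                                        y = seq(-1, 1, length.out = 11)),
                            n_path_nodes = 24L, max_iter = 500L, tol = 1e-9)
  fq <- force_field(gq)
  expect_lt(max(abs(fq$Fx - (fq$bx + fq$gx))), 1e-10)
})

test_that("gluing is identity for one attractor and 2U for the double well", {
  Hq <- ham_spec("extrinsic", "quadwell", c(1, 2, 0, 0))
  g <- quasipotential_grid(Hq, c(0, 0),
                           axes = list(x = seq(-1, 1, length.out = 9),
                                       y = seq(-1, 1, length.out = 9)),
                           n_path_nodes = 20L, max_iter = 400L, tol = 1e-8)
  expect_identical(glue_global(list(g)), g)
  # symmetric 1-D double well dx/dt = x - x^3: U = x^4/4 - x^2/2 (+1/4)
  Hd <- ham_spec("extrinsic", "doublewell1")
  ax <- seq(-1.6, 1.6, length.out = 33)
  gl <- quasipotential_grid(Hd, -1, axes = list(ax), n_path_nodes = 40L,
                            max_iter = 3000L, tol = 1e-10)
  gr <- quasipotential_grid(Hd, 1, axes = list(ax), n_path_nodes = 40L,
                            max_iter = 3000L, tol = 1e-10)
  gg <- glue_global(list(gl, gr))
  U <- ax^4 / 4 - ax^2 / 2 + 0.25
  expect_lt(max(abs(gg$values - 2 * U)), 0.05)
  expect_equal(min(gg$values), 0)
})

test_that("slices and projections extract planes and pointwise minima", {
  vals <- array(0, c(4, 3, 5))
  for (j in 1:3) for (k in 1:5) vals[, j, k] <- j + k  # constant along x
  g <- yeastscape:::new_landscape_grid(vals, list(x = 1:4, y = 1:3, z = 1:5),
                                       matrix(c(1, 1, 1), 1), fx_ham())
  mp <- min_project(g, "x")
  sl <- landscape_slice(g, "x", 2)
  expect_equal(as.vector(mp$values), as.vector(sl$values))
  sl2 <- landscape_slice(g, "z", 3.2)
  expect_equal(dim(sl2$values), c(4L, 3L, 1L))
  expect_equal(sl2$axes$z, 3)
  expect_error(landscape_slice(g, "z", 9), "outside")
  expect_error(landscape_slice(g, "w", 1), "unknown axis")
  # min_project is missing-aware
  vals2 <- vals; vals2[1, , ] <- NA
  g2 <- yeastscape:::new_landscape_grid(vals2, g$axes, g$attractor, g$spec)
  expect_false(anyNA(min_project(g2, "x")$values))
})

test_that("local minima detection finds planted pits and ignores noise", {
  set.seed(8)
  m <- matrix(5, 21, 21) + matrix(rnorm(441, sd = 0.01), 21)
  m[10, 10] <- 4.0   # deep planted pit
  m[3, 3] <- 4.97    # within-noise dip
  g <- yeastscape:::new_landscape_grid(array(m, c(21, 21, 1)),
                                       list(x = seq(0, 2, length.out = 21),
                                            y = seq(0, 2, length.out = 21),
                                            z = 0),
                                       matrix(c(0, 0, 0), 1), fx_ham())
  pits <- slice_local_minima(g)
  expect_true(g$axes$x[10] %in% pits$x[pits$depth > 0.5])  # the planted pit
  expect_false(g$axes$x[3] %in% pits$x)                    # the in-noise dip
  # explicit depth overrides the automatic threshold
  expect_gt(nrow(slice_local_minima(g, depth = 1e-4)), nrow(pits))
})

test_that("landscape text round-trip preserves values and axes", {
  Hq <- ham_spec("extrinsic", "quadwell", c(1, 2, 0, 0))
  g <- quasipotential_grid(Hq, c(0, 0),
                           axes = list(x = seq(-1, 1, length.out = 7),
                                       y = seq(-1, 1, length.out = 7)),
                           n_path_nodes = 16L, max_iter = 200L, tol = 1e-7)
  pfx <- tempfile()
  write_landscape(g, pfx)
  g2 <- read_landscape(pfx, spec = Hq)
  expect_equal(g2$values, g$values, tolerance = 1e-12)
  expect_equal(g2$axes$x, g$axes$x)
})

test_that("grid interpolation is exact on multilinear data", {
  vals <- array(0, c(5, 5, 5))
  ax <- list(x = 0:4, y = 0:4, z = 0:4)
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    vals[i, j, k] <- 2 * (i - 1) + 3 * (j - 1) - (k - 1)
  g <- yeastscape:::new_landscape_grid(vals, ax, matrix(0, 1, 3), fx_ham())
  pts <- matrix(c(0.5, 1.25, 3.75,  2, 2, 2), ncol = 3, byrow = TRUE)
  expect_equal(landscape_along(g, pts),
               2 * pts[, 1] + 3 * pts[, 2] - pts[, 3], tolerance = 1e-12)
  expect_true(is.na(landscape_along(g, matrix(c(-1, 0, 0), 1))))
})
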