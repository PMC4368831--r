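test_that("drift matches the term-by-term evaluation of the model equations", {
  p <- fx_params()
  # origin: every Hill and product term vanishes, only the basal input is left
  d0 <- cc_drift(c(0, 0, 0), p)
  expect_equal(as.numeric(d0[, c("dx", "dy", "dz")]), c(p$a0, 0, 0))
  # hand-evaluated x-component at (0.5, 0, 0.3):
  # 0.25/0.5 - 0.2*0.5 - 0 + 0.001 = 0.401
  d1 <- cc_drift(c(0.5, 0, 0.3), p)
  expect_equal(d1$dx, 0.401, tolerance = 1e-12)
  # with a0 = 0, any root of the decoupled z-subsystem quadratic
  # k3 z^2 - ks z + k3 j3^2 = 0 gives a zero drift at (0, 0, z)
  p0 <- cc_params(a0 = 1e-12)  # a0 must stay positive; use the analytic limit
  zroot <- (1 + sqrt(1 - 4 * 0.2^2 * 0.5^2)) / (2 * 0.2)
  expect_equal(0.2 * zroot^2 - zroot + 0.2 * 0.25, 0, tolerance = 1e-12)
  dz <- cc_drift(c(0, 0, zroot), p0)
  expect_lt(max(abs(as.numeric(dz[, c("dx", "dy", "dz")]))), 1e-9)
  expect_error(cc_drift(c(-0.1, 0, 0), p), "nonnegative")
})

test_that("analytic Jacobian agrees with finite differences and known entries", {
  p <- fx_params()
  J0 <- cc_jacobian(c(0, 0, 0), p)
  expect_equal(J0[1, 1], -p$k1)  # Hill derivative vanishes at 0
  p1 <- fx_p1()
  J1 <- cc_jacobian(p1, p)
  expect_equal(J1[1, 1], -p$k1 - p1[2] + 2 * p$j1^2 * p1[1] / (p$j1^2 + p1[1]^2)^2)
  set.seed(42)
  for (i in 1:10) {
    s <- runif(3, 0.05, 5)
    J <- cc_jacobian(s, p)
    h <- 1e-6
    for (k in 1:3) {
      e <- c(0, 0, 0); e[k] <- h
      fd <- (drift_num(s + e, p) - drift_num(s - e, p)) / (2 * h)
      expect_equal(J[, k], fd, tolerance = 1e-5)
    }
  }
})

test_that("fixed points include the stable G1 state and the excited-G1 saddle", {
  fp <- fx_fixed_points()
  expect_true(all(fp$drift_norm < 1e-9))
  # stability classes consistent with eigenvalue signs
  expect_true(all((fp$stability == "stable") == (fp$re1 < 0)))
  p1 <- fp[fp$label == "P1", ]
  expect_equal(nrow(p1), 1L)
  expect_gt(p1$z, 4)
  expect_lt(p1$x, 0.05)
  expect_lt(p1$y, 0.01)
  # the ki*z*x coupling shifts z below the decoupled subsystem root 4.9495;
  # the location must solve the full system to solver tolerance
  expect_lt(p1$z, 4.9495)
  p2 <- fp[fp$label == "P2", ]
  expect_equal(nrow(p2), 1L)
  expect_identical(p2$stability, "saddle")
  expect_gt(p2$re1, 0)   # exactly one unstable direction
  expect_lt(p2$re2, 0)
})

test_that("the origin is an exact fixed point in the a0 -> 0 limit", {
  # drift at the origin is (a0, 0, 0); with vanishing basal input the origin
  # is fixed
  p <- cc_params(a0 = 1e-14)
  expect_equal(drift_num(c(0, 0, 0), p), c(1e-14, 0, 0))
})

test_that("rich nutrient conditions remove the stable G1 fixed point", {
  fp <- cc_fixed_points(cc_params("rich_nutrient"))
  expect_false(any(fp$stability == "stable"))
})

test_that("bisection brackets and locates the nutrient bifurcation", {
  p <- fx_params()
  a0c <- fx("a0_crit", locate_bifurcation_a0(p, c(0.001, 0.01), tol = 1e-6))
  expect_gt(as.numeric(a0c), 0.002)
  expect_lt(as.numeric(a0c), 0.003)
  # nested-bracket property: halving the tolerance keeps the estimate inside
  # the previous bracket
  a0f <- locate_bifurcation_a0(p, attr(a0c, "bracket") + c(-2e-6, 2e-6),
                               tol = 5e-7)
  br <- attr(a0c, "bracket")
  expect_gte(as.numeric(a0f), br[1] - 2e-6)
  expect_lte(as.numeric(a0f), br[2] + 2e-6)
  # both ends excitable: no sign change to bisect
  expect_error(locate_bifurcation_a0(p, c(1e-4, 1e-3)), "bracketing")
})

test_that("bifurcation is consistent with fixed-point existence on either side", {
  p <- fx_params()
  a0c <- as.numeric(fx("a0_crit", locate_bifurcation_a0(p, c(0.001, 0.01), tol = 1e-6)))
  expect_true(yeastscape:::has_stable_g1(cc_params(a0 = a0c * 0.95)))
  expect_false(yeastscape:::has_stable_g1(cc_params(a0 = a0c * 1.05)))
})

test_that("limit cycle detection distinguishes oscillation from convergence", {
  cyc <- fx("rich_cycle", detect_limit_cycle(cc_params("rich_nutrient")))
  expect_false(is.null(cyc))
  expect_gt(cyc$period, 10)
  expect_lt(cyc$period_sd / cyc$period, 0.01)  # successive returns agree
  expect_null(detect_limit_cycle(fx_params(), t_transient = 1500, t_observe = 800))
  # period stable under tighter integrator accuracy
  tr <- cc_integrate(c(1, 0.1, 0.1), cc_params("rich_nutrient"), 3000,
                     dt_out = 0.25, rtol = 1e-10, atol = 1e-12)
  obs <- tr[tr$time > 2000, ]
  sec <- mean(range(obs$x))
  up <- which(diff(obs$x > sec) == 1L)
  per2 <- mean(diff(obs$time[up]))
  expect_lt(abs(per2 - cyc$period) / cyc$period, 0.01)
})

test_that("the excursion visits P3 then P4 then returns to G1 in order", {
  p <- fx_params()
  tr <- fx("excursion", cc_integrate(fx_p2() + c(0.02, 0, 0), p, 1500,
                                     dt_out = 0.25))
  t_xmax <- tr$time[which.max(tr$x)]
  t_ymax <- tr$time[which.max(tr$y)]
  late <- tr[tr$time > t_ymax, ]
  t_zrise <- late$time[which(late$z > 2)[1]]
  expect_lt(t_xmax, t_ymax)
  expect_lt(t_ymax, t_zrise)
  # passes near the vertices
  vt <- cc_vertices(p)
  expect_lt(min(sqrt((tr$x - vt$x[1])^2 + tr$y^2 + tr$z^2)), 0.15)
  expect_lt(min(sqrt(tr$x^2 + (tr$y - vt$y[2])^2 + tr$z^2)), 0.15)
  # ends at the stable G1 state
  fin <- as.numeric(tr[nrow(tr), c("x", "y", "z")])
  expect_lt(sqrt(sum((fin - fx_p1())^2)), 1e-3)
})

test_that("trajectories from the nonnegative octant stay nonnegative", {
  p <- fx_params()
  set.seed(7)
  for (i in 1:5) {
    tr <- cc_integrate(runif(3, 0, 4), p, 300, dt_out = 0.5)
    expect_true(all(tr$x >= 0 & tr$y >= 0 & tr$z >= 0))
  }
  # integration from P1 stays at P1
  trp <- cc_integrate(fx_p1(), p, 200, dt_out = 1)
  expect_lt(max(abs(as.matrix(trp[, c("x", "y", "z")]) -
                    matrix(fx_p1(), nrow(trp), 3, byrow = TRUE))), 1e-6)
})

test_that("sensitivity scan covers 11 parameters in both directions", {
  p <- fx_params()
  # a cheap analytic stand-in for the well-depth functional keeps this a
  # structural test; the quasi-potential functional is exercised elsewhere
  depth_stub <- function(par) par$a0 * 1000 + par$ka1
  sc <- sensitivity_scan(p, fraction = 0.20, well_depth_fn = depth_stub,
                         t_transient = 1200, t_observe = 600)
  expect_equal(nrow(sc), 22L)
  expect_setequal(unique(sc$parameter), yeastscape:::cc_param_names())
  # identity perturbation reproduces the baseline exactly
  sc0 <- sensitivity_scan(p, fraction = 0, well_depth_fn = depth_stub,
                          t_transient = 600, t_observe = 400)
  expect_true(all(abs(sc0$delta_S) < 1e-12))
  # a0 + 20% = 0.0012 stays below the bifurcation at ~0.0025: still excitable
  expect_identical(sc$regime[sc$parameter == "a0" & sc$direction == "increase"],
                   "excitable")
  expect_identical(sc$regime[sc$parameter == "ka1" & sc$direction == "decrease"],
                   "excitable")
})

test_that("parameter presets and config files round-trip", {
  expect_error(cc_params(a0 = -1), "strictly positive")
  expect_error(cc_params(bogus = 1), "unknown parameter")
  cfg <- tempfile(fileext = ".cfg")
  writeLines(c("# test configuration", "scenario = s_checkpoint", "a0 = 0.002"), cfg)
  p <- read_params_config(cfg)
  expect_equal(p$ka1, 1e-4)
  expect_equal(p$a0, 0.002)
  expect_equal(tidy(p)$value[tidy(p)$parameter == "ki"], 5)
})
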