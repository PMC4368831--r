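test_that("the event stream is reproducible and respects absorbing states", {
  net <- cc_network(fx_params(), V = 50)
  a <- ssa_simulate(net, c(10, 5, 100), t_end = 20, seed = 42)
  b <- ssa_simulate(net, c(10, 5, 100), t_end = 20, seed = 42)
  expect_identical(a$X, b$X)
  expect_identical(a$time, b$time)
  c2 <- ssa_simulate(net, c(10, 5, 100), t_end = 20, seed = 43)
  expect_false(identical(a$X, c2$X))
  # consecutive states differ by exactly one molecule of one species
  # (the final row repeats the state at the recording horizon)
  dm <- abs(diff(as.matrix(a[-nrow(a), c("X", "Y", "Z")])))
  expect_true(all(rowSums(dm) == 1))
  # a dead birth-death network absorbs immediately
  dead <- bd1_network(c = 0, k = 1, V = 10)
  tr <- ssa_simulate(dead, 0, t_end = 5, seed = 1)
  expect_true(attr(tr, "absorbed"))
  expect_equal(attr(tr, "n_events"), 0)
})

test_that("a pure birth process produces Poisson event counts", {
  # birth-only: rate c*V = 1, horizon 10 => Poisson(10) events
  net <- bd1_network(c = 0.1, k = 0, V = 10)
  counts <- vapply(1:200, function(s)
    attr(ssa_simulate(net, 0, t_end = 10, seed = s), "n_events"), 0)
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 200))
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.35)  # Fano factor ~ 1
})

test_that("trajectories track the deterministic flow with 1/sqrt(V) deviations", {
  p <- fx_params()
  # a smooth fast stretch of the excursion: timing jitter at the excitation
  # threshold would otherwise dominate the deviation metric
  s0 <- c(1, 0.02, 0.2)
  t_end <- 8
  tr_ode <- cc_integrate(s0, p, t_end, dt_out = 0.25)
  dev_at <- function(V, seeds) {
    net <- cc_network(p, V = V)
    devs <- vapply(seeds, function(sd) {
      s <- ssa_simulate(net, round(s0 * V), t_end, seed = sd, record_every = 25L,
                        max_events = 3e6)
      xi <- approx(s$time, s$X / V, xout = tr_ode$time, rule = 2, ties = "ordered")$y
      max(abs(xi - tr_ode$x))
    }, 0)
    mean(devs)
  }
  d500 <- dev_at(500, 1:20)
  d2000 <- dev_at(2000, 1:20)
  ratio <- d500 / d2000
  expect_gt(ratio, sqrt(4) * 0.6)    # ~2 expected from V^(-1/2) scaling
  expect_lt(ratio, sqrt(4) * 1.7)
})

test_that("1-D birth-death occupancy matches the Poisson stationary law", {
  # stationary distribution is Poisson(V c / k): mode and -ln P profile
  net <- bd1_network(c = 1, k = 1, V = 60)
  set.seed(9)
  h <- yeastscape:::cpp_ssa_hist_bd1(1, 1, 60, 60, 2e4, 100, 200)
  expect_equal(h$total_weight, 2e4 - 100, tolerance = 1e-6)
  counts <- h$counts
  mode_x <- which.max(counts) - 1L
  expect_lt(abs(mode_x - 60), 6)
  # -ln P agrees with V * S(x) + const within sampling error
  xs <- 40:85
  lp <- -log(counts[xs + 1] / sum(counts))
  SV <- 60 * bd1_quasipotential(xs / 60, 1, 1)
  resid <- lp - SV
  expect_lt(sd(resid), 0.25)
  expect_lt(max(abs(resid - mean(resid))), 0.8)
})

test_that("histogram residence time is conserved and conditioning excludes G1", {
  h <- fx_fv_hist()
  expect_equal(h$total_weight, 6e5, tolerance = 1e-3)
  L <- finite_volume_landscape(h)
  expect_equal(min(L$values, na.rm = TRUE), 0)
  # no occupancy inside the excluded G1 ball
  df <- tidy(L)
  p1 <- fx_p1()
  inside <- sqrt((df$x - p1[1])^2 + (df$y - p1[2])^2 + (df$z - p1[3])^2) < 0.9
  expect_true(all(is.na(df$S[inside])))
  expect_error(finite_volume_landscape(list(counts = array(0, c(2, 2, 2)),
                                            bin_edges = list(0:2, 0:2, 0:2))),
               "empty")
})

test_that("mean exit times match the exact chain solution and CLT scaling", {
  net <- bd1_network(c = 1, k = 1, V = 30)
  basin0 <- list(start = 1, exit_at = 1)   # exit predicate true at start
  m0 <- mean_exit_time(net, basin0, n_reps = 10, seed = 1)
  expect_equal(m0$mean, 0)
  basin <- list(start = 1, exit_at = 1.5)
  m1 <- mean_exit_time(net, basin, n_reps = 120, seed = 2, t_cap = 1e5)
  exact <- bd1_exact_mfpt(net, 1, 1.5)
  expect_gt(exact, m1$ci[1] * 0.85)
  expect_lt(exact, m1$ci[2] * 1.15)
  # doubling replicates shrinks the CI roughly by sqrt(2)
  m2 <- mean_exit_time(net, basin, n_reps = 480, seed = 3, t_cap = 1e5)
  w1 <- diff(m1$ci); w2 <- diff(m2$ci)
  expect_lt(w2 / w1, 0.85)
})
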