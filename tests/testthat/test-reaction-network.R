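test_that("the network translates the equations into exactly 12 channels", {
  net <- cc_network(fx_params(), V = 100)
  ch <- net$channels
  expect_equal(nrow(ch), 12L)
  # per equation: two birth (+1) and two death (-1) channels in its own
  # coordinate
  for (sp in c("X", "Y", "Z")) {
    nu <- ch[ch$species == sp, paste0("nu_", tolower(c("X", "Y", "Z")))]
    own <- nu[[paste0("nu_", tolower(sp))]]
    expect_equal(sort(own), c(-1L, -1L, 1L, 1L))
    expect_true(all(rowSums(abs(nu)) == 1L))
  }
  # x-equation state-change vectors exactly as printed: nu1 = nu4 = +e_x,
  # nu2 = nu3 = -e_x
  expect_equal(ch$nu_x[1:4], c(1L, -1L, -1L, 1L))
  expect_error(cc_network(fx_params(), V = -1), "positive")
})

test_that("x-equation propensities match the printed formulas", {
  p <- fx_params()
  net <- cc_network(p, V = 100)
  a <- propensities(net, c(50, 20, 10))
  # a1 = V X^2 / ((j1 V)^2 + X^2) = 100*2500/(2500 + 2500) = 50
  expect_equal(a$propensity[1], 50)
  expect_equal(a$propensity[2], p$k1 * 50)      # a2 = k1 X
  expect_equal(a$propensity[3], 50 * 20 / 100)  # a3 = X Y / V
  expect_equal(a$propensity[4], p$a0 * 100)     # a4 = a0 V
  # at baseline V = 1000 the constant-birth channel fires at rate 1.0
  a1000 <- propensities(cc_network(p, V = 1000), c(0, 0, 0))
  expect_equal(a1000$propensity[4], 1.0)
  # death propensities vanish at zero count of their species
  expect_true(all(a1000$propensity[c(2, 3, 6, 7, 10, 11)] == 0))
  expect_true(all(a1000$propensity >= 0))
})

test_that("mean-field drift equals the deterministic drift identically in V", {
  p <- fx_params()
  d <- drift_num(c(0.5, 0, 0.3), p)
  net <- cc_network(p, V = 100)
  expect_equal(mean_field_drift(net, c(0.5, 0, 0.3)), d, tolerance = 1e-13)
  expect_equal(mean_field_drift(net, c(0.5, 0, 0.3))[1], 0.401, tolerance = 1e-13)
  # only the constant-birth channel contributes at the origin
  expect_equal(mean_field_drift(net, c(0, 0, 0)), c(p$a0, 0, 0))
  set.seed(3)
  for (V in c(50, 500, 5000)) {
    netV <- cc_network(p, V = V)
    for (i in 1:7) {
      s <- runif(3, 0, 5)
      expect_equal(mean_field_drift(netV, s), drift_num(s, p), tolerance = 1e-12)
    }
  }
})

test_that("the jump Hamiltonian has the large-deviation structure", {
  H <- fx_ham()
  set.seed(5)
  for (i in 1:8) {
    x <- runif(3, 0.05, 5)
    expect_equal(ham(H, x, c(0, 0, 0)), 0)          # H(x, 0) = 0
    expect_equal(ham_dp(H, x, c(0, 0, 0)), drift_num(x, fx_params()),
                 tolerance = 1e-12)                  # dH/dp at 0 = drift
    # convexity in p along random directions
    p1 <- runif(3, -2, 2); p2 <- runif(3, -2, 2)
    mid <- ham(H, x, (p1 + p2) / 2)
    expect_lte(mid, (ham(H, x, p1) + ham(H, x, p2)) / 2 + 1e-12)
  }
})

test_that("1-D birth-death Hamiltonian has the closed-form zero momentum", {
  # H = c(e^p - 1) + kx(e^-p - 1): nontrivial root at p = log(kx/c)
  Hbd <- ham_spec("intrinsic", "bd1", c(2, 0.5))
  for (x in c(1, 4, 10)) {
    proot <- log(0.5 * x / 2)
    expect_equal(ham(Hbd, x, proot), 0, tolerance = 1e-12)
  }
})

test_that("extrinsic Hamiltonian is p.b + |p|^2/2", {
  He <- ham_extrinsic(fx_params())
  x <- c(0.5, 0, 0.3)
  b <- drift_num(x, fx_params())
  p <- c(0.2, -0.1, 0.4)
  expect_equal(ham(He, x, p), sum(p * b) + sum(p^2) / 2, tolerance = 1e-12)
  expect_equal(ham_dp(He, x, p), b + p, tolerance = 1e-12)
})

test_that("network serializes to a readable text description", {
  net <- cc_network(fx_params(), V = 50)
  f <- tempfile(fileext = ".txt")
  write_network(net, f)
  txt <- readLines(f)
  expect_length(grep("^channel", txt), 12L)
  expect_true(any(grepl("eq-1c term 4", txt)))
})
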