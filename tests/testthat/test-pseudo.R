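test_that("the canal path runs from the saddle through both vertices to G1", {
  cp <- fx_canal()
  expect_true(all(diff(cp$arclength) > 0))
  vt <- cc_vertices(fx_params(), path = cp)
  expect_gt(vt$x[vt$label == "P3"], 4)
  expect_gt(vt$y[vt$label == "P4"], 4)
  # speed has pronounced slow zones near the vertices
  near_p3 <- which.min(sqrt((cp$x - vt$x[1])^2 + cp$y^2 + cp$z^2))
  expect_lt(cp$speed[near_p3], 0.1)
})

test_that("the tangential pseudo potential falls with slope |b|", {
  ps <- fx("pseudo", build_pseudo(fx_params(), path_resolution = 24L,
                                  transverse_extent = 0.5, n_transverse = 3L,
                                  n_path_nodes = 20L, max_iter = 300L))
  pp <- ps$path
  expect_equal(pp$tangential[1], 0)
  expect_true(all(diff(pp$tangential) < 0))      # strictly decreasing
  # |dT/ds| equals the local driving-force strength
  slope <- -diff(pp$tangential) / diff(pp$arclength)
  mid_speed <- (pp$speed[-1] + pp$speed[-nrow(pp)]) / 2
  expect_equal(slope, mid_speed, tolerance = 1e-9)
  # steep where the drive is strong, almost flat near the slow vertices
  expect_gt(max(slope), 10 * min(slope))
  # transverse minimum lies on the reference path: S_transverse > 0 off-path
  expect_true(all(ps$sections$S_transverse >= 0))
  expect_true(all(ps$sections$combined <= ps$path$tangential[ps$sections$station] +
                    max(ps$sections$S_transverse) + 1e-9))
})

test_that("pseudo slice shows a barrier between the S and early-M canals", {
  ps <- fx("pseudo", build_pseudo(fx_params(), path_resolution = 24L,
                                  transverse_extent = 0.5, n_transverse = 3L,
                                  n_path_nodes = 20L, max_iter = 300L))
  # at matched transverse offset, the wall between the two canal arms rises
  # above the canal floor everywhere
  by_station <- dplyr::summarise(dplyr::group_by(ps$sections, .data$station),
                                 wall = max(.data$S_transverse), .groups = "drop")
  expect_true(all(by_station$wall > 0))
})

test_that("canal confinement narrows near the vertices under intrinsic noise", {
  p <- fx_params()
  cp <- fx_canal()
  vt <- cc_vertices(p, path = cp)
  # stations: a strong-drive mid-canal point and the two slow vertices
  d3 <- sqrt((cp$x - vt$x[1])^2 + cp$y^2 + cp$z^2)
  d4 <- sqrt(cp$x^2 + (cp$y - vt$y[2])^2 + cp$z^2)
  st <- c(which.max(cp$speed[5:60]) + 4,          # fast stretch of the S leg
          which.min(d3), which.min(d4))
  wi <- fx("width_intrinsic",
           canal_width_profile(fx_ham(), cp, attractor = fx_p1(),
                               stations = st, skeleton = fx_skeleton()))
  # narrower near P3 and P4 than at the fast mid-canal point
  expect_lt(wi$width[2], 0.7 * wi$width[1])
  expect_lt(wi$width[3], 0.7 * wi$width[1])
  expect_false(any(wi$capped))
})

test_that("the intrinsic noise intensity collapses at the slow vertices", {
  # the mechanism tying intrinsic confinement to the driving rates: the
  # transverse jump-noise intensity follows the propensities, which nearly
  # vanish where the cycle stalls, while extrinsic noise is constant by
  # construction
  p <- fx_params()
  cp <- fx_canal()
  m <- as.matrix(cp[, c("x", "y", "z")])
  st <- unique(round(seq(8, 112, length.out = 8)))
  D_int <- vapply(st, function(i) {
    n1 <- yeastscape:::canal_normal(m, i)
    r <- yeastscape:::cpp_rates(1L, yeastscape:::cc_par_vec(p), m[i, ])
    sum((r$birth + r$death) * n1^2)
  }, 0)
  expect_gt(max(D_int) / min(D_int), 50)
  slowest <- order(cp$speed[st])[1:2]
  expect_true(all(D_int[slowest] < median(D_int)))
})
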