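# Shared fixtures, computed lazily and cached for the whole test run.
.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx_cache, inherits = FALSE))
    assign(name, force(expr), envir = .fx_cache)
  get(name, envir = .fx_cache, inherits = FALSE)
}

fx_params <- function() fx("params", cc_params())

fx_fixed_points <- function() fx("fp", cc_fixed_points(fx_params()))

fx_p1 <- function() {
  fp <- fx_fixed_points()
  as.numeric(fp[fp$label == "P1", c("x", "y", "z")])
}

fx_p2 <- function() {
  fp <- fx_fixed_points()
  as.numeric(fp[fp$label == "P2", c("x", "y", "z")])
}

fx_skeleton <- function() fx("skeleton", cc_skeleton(fx_params()))

fx_canal <- function() fx("canal", canal_path(fx_params(), n = 120L))

fx_ham <- function() fx("ham", ham_intrinsic(fx_params()))

# baseline intrinsic quasi-potential, 21^3 over [0, 5]^3 (shared by the
# refinement, Lyapunov and pit-absence checks)
fx_grid21 <- function() fx("grid21",
  quasipotential_grid(fx_ham(), fx_p1(), bounds = c(0, 5), n = 21L,
                      skeleton = fx_skeleton(), n_sweeps = 2L))

# baseline z = 0 and x = 0 planar slices of the intrinsic landscape
fx_slice_z0 <- function() fx("slice_z0", {
  axes <- list(x = seq(0, 6, length.out = 31), y = seq(0, 6, length.out = 31), z = 0)
  quasipotential_grid(fx_ham(), fx_p1(), axes = axes,
                      skeleton = fx_skeleton(), n_sweeps = 2L)
})

fx_slice_x0 <- function() fx("slice_x0", {
  axes <- list(x = 0, y = seq(0, 6, length.out = 31), z = seq(0, 6, length.out = 31))
  quasipotential_grid(fx_ham(), fx_p1(), axes = axes,
                      skeleton = fx_skeleton(), n_sweeps = 2L)
})

# conditioned finite-volume histogram at V = 100 (reinjection at the
# excited-G1 point, G1 ball excluded)
fx_fv_hist <- function() fx("fv_hist", {
  skel <- fx_skeleton()
  net <- cc_network(fx_params(), V = 100)
  stationary_histogram(net, t_total = 6e5, bins = 60L, seed = 11L,
                       n_chunks = 4L,
                       restart_rule = list(center = fx_p1(), radius = 1.0,
                                           restart = skel[14, ]))
})

drift_num <- function(s, p) {
  as.numeric(cc_drift(s, p)[, c("dx", "dy", "dz")])
}

expect_close <- function(actual, expected, tol, label = NULL) {
  expect_lt(abs(actual - expected), tol, label = label)
}
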