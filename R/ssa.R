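#' Exact stochastic simulation of a reaction network
#'
#' Gillespie's direct method: exponential waiting times at the total
#' propensity, channel selection proportional to propensity.  The event
#' stream is bitwise reproducible given the seed.
#'
#' @param network a \code{\link{cc_network}} or \code{\link{bd1_network}}.
#' @param counts0 initial molecule counts (length 3 for the cell-cycle
#'   network, length 1 for birth-death).
#' @param t_end simulated time horizon.
#' @param seed RNG seed.
#' @param max_events hard event cap.
#' @param record_every record every k-th event (1 = full event stream).
#' @return a tibble of recorded states (\code{time, X[, Y, Z]}) with
#'   attributes \code{absorbed} (TRUE when the total propensity hit zero)
#'   and \code{n_events}.
#' @export
ssa_simulate <- function(network, counts0, t_end, seed = 1L,
                         max_events = 5e6, record_every = 1L) {
  stopifnot(t_end > 0)
  set.seed(seed)
  if (inherits(network, "cc_network")) {
    stopifnot(length(counts0) == 3L)
    res <- cpp_ssa_cc(cc_par_vec(network$params), network$V,
                      as.integer(round(counts0)), t_end,
                      as.integer(max_events), as.integer(record_every))
    out <- tibble::tibble(time = res$time, X = res$X, Y = res$Y, Z = res$Z)
  } else if (inherits(network, "bd1_network")) {
    stopifnot(length(counts0) == 1L)
    res <- cpp_ssa_bd1(network$c, network$k, network$V,
                       as.integer(round(counts0)), t_end,
                       as.integer(max_events), as.integer(record_every))
    out <- tibble::tibble(time = res$time, X = res$X)
  } else stop("unsupported network class")
  structure(out, absorbed = res$absorbed, n_events = res$n_events, seed = seed)
}

#' Simulate the extrinsic-noise model
#'
#' Euler-Maruyama integration of \eqn{dx = b(x)\,dt + a\,dW} (additive white
#' noise of amplitude \code{amp}, reflected at the coordinate planes).
#'
#' @param params a \code{\link{cc_params}} object.
#' @param state0 initial concentration state (length 3).
#' @param t_end time horizon.
#' @param amp noise amplitude (concentration / sqrt(time)).
#' @param dt integration step.
#' @param seed RNG seed.
#' @param record_every record every k-th step.
#' @return a tibble \code{time, x, y, z}.
#' @export
em_simulate <- function(params, state0, t_end, amp = 0.05, dt = 0.005,
                        seed = 1L, record_every = 10L) {
  stopifnot(t_end > 0, dt > 0, amp >= 0)
  set.seed(seed)
  res <- cpp_em_cc(cc_par_vec(params), amp, as.numeric(state0), t_end, dt,
                   as.integer(record_every))
  tibble::tibble(time = res$time, x = res$X, y = res$Y, z = res$Z)
}

#' Stationary occupancy histogram from SSA
#'
#' Residence-time-weighted histogram over concentration space after a
#' burn-in.  For the excitable baseline the global stationary distribution
#' concentrates in the G1 basin; to resolve statistics along the cycle path
#' a reinjection rule can be supplied: whenever the walker enters a ball
#' around the G1 state it is restarted from the excited-G1 point, and
#' residence inside an exclusion ball around G1 is not scored.  The result
#' is then a conditioned (cycling) distribution, not the global stationary
#' law.
#'
#' @param network a \code{\link{cc_network}}.
#' @param counts0 initial counts (default: restart point if reinjecting,
#'   else G1 counts).
#' @param t_total total simulated time.
#' @param burn_in discarded initial time.
#' @param bins number of bins per axis over \code{range_conc}.
#' @param range_conc concentration range per axis (default \code{c(0, 6)}).
#' @param seed RNG seed.
#' @param restart_rule \code{NULL} for the plain stationary histogram, or a
#'   list with \code{center} (concentration point), \code{radius},
#'   \code{restart} (concentration point to reinject at) and optional
#'   \code{exclude_radius} (defaults to \code{radius}).
#' @param n_chunks number of independent replicate streams (each of length
#'   \code{t_total / n_chunks}, with its own derived seed).  With more than
#'   one chunk the per-chunk counts are kept, which lets
#'   \code{\link{finite_volume_landscape}} attach per-bin standard errors.
#' @param max_events hard event cap.
#' @return an \code{occupancy_hist}: list with 3-D \code{counts} (residence
#'   time per bin, summed over chunks), \code{chunk_counts}, \code{bin_edges},
#'   \code{total_weight}, provenance.
#' @export
stationary_histogram <- function(network, counts0 = NULL, t_total = 2e4,
                                 burn_in = 0, bins = 60L,
                                 range_conc = c(0, 6), seed = 1L,
                                 restart_rule = NULL, n_chunks = 1L,
                                 max_events = 5e8) {
  stopifnot(inherits(network, "cc_network"), t_total > burn_in)
  V <- network$V
  reinject <- !is.null(restart_rule)
  if (reinject) {
    center <- as.numeric(restart_rule$center)
    radius <- restart_rule$radius
    excl <- restart_rule$exclude_radius %||% radius
    restart <- as.integer(round(restart_rule$restart * V))
  } else {
    center <- c(0, 0, 0); radius <- 0; excl <- -1; restart <- c(0L, 0L, 0L)
  }
  if (is.null(counts0)) {
    counts0 <- if (reinject) restart else
      as.integer(round(c(0.006, 0, 4.32) * V))
  }
  t_chunk <- t_total / n_chunks
  burn_chunk <- burn_in / n_chunks
  chunk_counts <- vector("list", n_chunks)
  wtot <- 0; nev <- 0; tfin <- 0
  for (ci in seq_len(n_chunks)) {
    set.seed((seed * 1000003L + ci - 1L) %% .Machine$integer.max)
    res <- cpp_ssa_hist_cc(cc_par_vec(network$params), V,
                           as.integer(round(counts0)), t_chunk, burn_chunk,
                           range_conc[1], range_conc[2], as.integer(bins),
                           reinject, restart, center, radius, excl, max_events)
    chunk_counts[[ci]] <- res$counts
    wtot <- wtot + res$total_weight
    nev <- nev + res$n_events
    tfin <- tfin + res$t_final
  }
  if (wtot <= 0) stop("empty histogram after burn-in")
  counts <- Reduce(`+`, chunk_counts)
  edges <- seq(range_conc[1], range_conc[2], length.out = bins + 1L)
  structure(list(counts = counts,
                 chunk_counts = if (n_chunks > 1L) chunk_counts else NULL,
                 bin_edges = list(x = edges, y = edges, z = edges),
                 total_weight = wtot,
                 t_final = tfin, n_events = nev,
                 params = network$params, V = V, seed = seed,
                 restart_rule = restart_rule),
            class = "occupancy_hist")
}

#' @export
print.occupancy_hist <- function(x, ...) {
  cat("<occupancy_hist>", paste(dim(x$counts), collapse = " x "),
      sprintf("bins, weight %.4g over %.4g time units, V = %g\n",
              x$total_weight, x$t_final, x$V))
  invisible(x)
}

#' Finite-volume energy landscape from an occupancy histogram
#'
#' Defines the landscape as \eqn{-\ln \hat P} with \eqn{\hat P} the
#' normalized residence frequencies.  Empty bins are marked missing rather
#' than carried as infinities, so minima searches are unaffected.  At small
#' system size this landscape develops pits near the slow-passage points
#' that the infinite-volume quasi-potential does not have.
#'
#' @param hist an \code{\link{stationary_histogram}} result, or a plain list
#'   with \code{counts} and \code{bin_edges}.
#' @return a \code{landscape_grid} of \eqn{-\ln \hat P} values at bin
#'   centres (normalized to zero at the minimum).
#' @export
finite_volume_landscape <- function(hist) {
  counts <- hist$counts
  if (sum(counts) <= 0) stop("histogram is empty")
  P <- counts / sum(counts)
  vals <- -log(P)
  vals[!is.finite(vals)] <- NA_real_
  shift <- min(vals, na.rm = TRUE)
  vals <- vals - shift
  se <- NULL
  if (!is.null(hist$chunk_counts)) {
    K <- length(hist$chunk_counts)
    lp <- lapply(hist$chunk_counts, function(cc) {
      v <- -log(cc / sum(cc))
      v[!is.finite(v)] <- NA_real_
      v
    })
    ok <- Reduce(`+`, lapply(lp, function(v) !is.na(v))) == K
    lmat <- vapply(lp, as.vector, numeric(length(vals)))
    se <- array(apply(lmat, 1L, sd) / sqrt(K), dim = dim(vals))
    se[!ok] <- NA_real_
  }
  axes <- lapply(hist$bin_edges, function(e) (head(e, -1L) + tail(e, -1L)) / 2)
  spec <- if (!is.null(hist$params)) ham_intrinsic(hist$params) else NULL
  g <- new_landscape_grid(vals, axes, matrix(NA_real_, 1L, length(axes)), spec,
                          meta = list(source = "ssa", V = hist$V, seed = hist$seed,
                                      conditioned = !is.null(hist$restart_rule)))
  g$se <- se
  g
}

#' Mean exit time from a basin by direct simulation
#'
#' First-passage times of the jump process out of a basin, repeated over
#' independent replicates with per-replicate seeds derived from the master
#' seed; replicates exceeding the time cap are censored and reported.
#'
#' @param network \code{\link{cc_network}} or \code{\link{bd1_network}}.
#' @param basin for the cell-cycle network a list with \code{start}
#'   (concentration point), \code{center} and \code{radius} (exit when the
#'   concentration leaves the ball); for birth-death a list with
#'   \code{start} and \code{exit_at} (exit when \eqn{X/V \ge} this
#'   concentration).
#' @param n_reps number of replicates.
#' @param seed master seed.
#' @param t_cap per-replicate time cap (censoring).
#' @param conf bootstrap confidence level.
#' @return a list with \code{times} (per-rep, NA = censored), \code{mean},
#'   \code{ci} (bootstrap CI of the mean), \code{n_censored}.
#' @export
mean_exit_time <- function(network, basin, n_reps = 100L, seed = 1L,
                           t_cap = 1e6, conf = 0.95) {
  times <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed((seed * 1000003L + r) %% .Machine$integer.max)
    times[r] <- if (inherits(network, "cc_network")) {
      cpp_ssa_exit_cc(cc_par_vec(network$params), network$V,
                      as.integer(round(basin$start * network$V)),
                      as.numeric(basin$center), basin$radius, t_cap)
    } else {
      cpp_ssa_exit_bd1(network$c, network$k, network$V,
                       as.integer(round(basin$start * network$V)),
                       as.integer(round(basin$exit_at * network$V)), t_cap)
    }
  }
  ok <- times[!is.na(times)]
  if (!length(ok)) stop("all replicates censored at t_cap")
  set.seed(seed)
  boots <- replicate(500L, mean(sample(ok, replace = TRUE)))
  alpha <- (1 - conf) / 2
  list(times = times, mean = mean(ok),
       ci = unname(quantile(boots, c(alpha, 1 - alpha))),
       n_censored = sum(is.na(times)))
}

#' Exact mean first-passage time of the 1-D birth-death chain
#'
#' Closed-form tridiagonal solution for the expected time from \code{start}
#' to the absorbing threshold, with a reflecting boundary at zero: the
#' independent oracle for the simulated exit times.
#'
#' @param network a \code{\link{bd1_network}}.
#' @param start start concentration.
#' @param exit_at exit threshold concentration.
#' @return scalar expected first-passage time.
#' @export
bd1_exact_mfpt <- function(network, start, exit_at) {
  cpp_mfpt_bd1(network$c, network$k, network$V,
               as.integer(round(start * network$V)),
               as.integer(round(exit_at * network$V)))
}
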