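#' Deterministic drift of the cell-cycle model
#'
#' Evaluates the right-hand side \eqn{b(x)} of the three-variable model at one
#' or more states.  Each module carries a second-order Hill positive feedback,
#' first-order degradation, a bilinear repression from the downstream module,
#' and a trigger/basal production term:
#' \deqn{\dot x = x^2/(j_1^2+x^2) - k_1 x - x y + a_0}
#' \deqn{\dot y = y^2/(j_2^2+y^2) - k_2 y - y z + k_{a1} x}
#' \deqn{\dot z = k_s z^2/(j_3^2+z^2) - k_3 z - k_i z x + k_{a2} y}
#'
#' @param states a data frame with columns \code{x, y, z} (one row per state)
#'   or a numeric length-3 vector.
#' @param params a \code{\link{cc_params}} object.
#' @return a tibble with columns \code{x, y, z, dx, dy, dz}; for a single
#'   vector input the same shape with one row.
#' @examples
#' cc_drift(c(0.5, 0, 0.3), cc_params())
#' @export
cc_drift <- function(states, params) {
  states <- as_state_matrix(states)
  if (any(states < 0)) stop("state components must be nonnegative")
  par <- cc_par_vec(params)
  d <- t(apply(states, 1L, function(s) cpp_drift(1L, par, s)))
  tibble::tibble(x = states[, 1], y = states[, 2], z = states[, 3],
                 dx = d[, 1], dy = d[, 2], dz = d[, 3])
}

as_state_matrix <- function(states) {
  if (is.data.frame(states)) {
    stopifnot(all(c("x", "y", "z") %in% names(states)))
    m <- as.matrix(states[, c("x", "y", "z")])
  } else if (is.numeric(states) && is.null(dim(states))) {
    stopifnot(length(states) == 3L)
    m <- matrix(states, nrow = 1L)
  } else {
    m <- as.matrix(states)
    stopifnot(ncol(m) == 3L)
  }
  storage.mode(m) <- "double"
  unname(m)
}

# drift as plain vector, no validation (internal hot path)
drift_vec <- function(s, par) cpp_drift(1L, par, s)

#' Analytic Jacobian of the drift
#'
#' @param state numeric length-3 state \code{(x, y, z)}.
#' @param params a \code{\link{cc_params}} object.
#' @return a 3x3 matrix of partial derivatives (rows: equations, columns:
#'   derivatives with respect to x, y, z).
#' @export
cc_jacobian <- function(state, params) {
  state <- as.numeric(as_state_matrix(state))
  if (any(state < 0)) stop("state components must be nonnegative")
  cpp_jac(1L, cc_par_vec(params), state)
}

#' Integrate the deterministic model
#'
#' Solves the ODE flow with a stiff-capable adaptive integrator
#' (\code{deSolve::lsoda}); the canal has pronounced fast-slow structure near
#' the subsystem vertices, so tight tolerances are the default.  States are
#' floored at zero (each negative term carries a factor of its own variable,
#' so the flow cannot cross the coordinate planes except by roundoff; any
#' clipping is recorded in the \code{clipped} attribute).
#'
#' @param state0 initial state: numeric length-3 or one-row data frame.
#' @param params a \code{\link{cc_params}} object.
#' @param t_end final time (time units).
#' @param dt_out output sampling interval.
#' @param rtol,atol relative/absolute integrator tolerances.
#' @return a tibble with columns \code{time, x, y, z} (class
#'   \code{cc_trajectory}).
#' @export
cc_integrate <- function(state0, params, t_end, dt_out = t_end / 2000,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_end > 0)
  s0 <- as.numeric(as_state_matrix(state0))
  par <- cc_par_vec(params)
  rhs <- function(t, s, p) list(cpp_drift(1L, par, pmax(s, 0)))
  out <- deSolve::ode(y = c(x = s0[1], y = s0[2], z = s0[3]),
                      times = seq(0, t_end, by = dt_out),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (any(!is.finite(out)))
    stop("integration failure: non-finite state (diagnostic: t = ",
         out[which(!is.finite(out[, 2]))[1], 1], ")")
  df <- tibble::as_tibble(as.data.frame(out))
  names(df)[1] <- "time"
  clipped <- sum(df$x < 0 | df$y < 0 | df$z < 0)
  df$x <- pmax(df$x, 0); df$y <- pmax(df$y, 0); df$z <- pmax(df$z, 0)
  structure(df, class = c("cc_trajectory", class(df)), clipped = clipped)
}

# Newton polish of a root of the drift; returns NULL on failure
newton_root <- function(s0, par, tol = 1e-12, maxit = 200L) {
  s <- pmax(s0, 0)
  for (i in seq_len(maxit)) {
    b <- drift_vec(s, par)
    if (max(abs(b)) < tol) break
    J <- cpp_jac(1L, par, s)
    d <- tryCatch(solve(J, b), error = function(e) NULL)
    if (is.null(d) || any(!is.finite(d))) return(NULL)
    s <- s - d
    if (any(!is.finite(s)) || any(abs(s) > 1e6)) return(NULL)
  }
  if (max(abs(drift_vec(pmax(s, 0), par))) < 1e-9 && all(s > -1e-8)) pmax(s, 0) else NULL
}

#' Locate and classify the fixed points of the model
#'
#' Multi-start Newton iteration from a low-discrepancy (Latin hypercube)
#' design over the search box, with analytic Jacobians, deduplication at
#' \code{1e-6} in max-norm, and stability classification from the Jacobian
#' eigenvalues.  The stable G1 state (large z, small x and y) is labelled
#' \code{P1}; the saddle with one unstable direction closest to it (the
#' excited-G1 start of the cycle) is labelled \code{P2}.
#'
#' @param params a \code{\link{cc_params}} object.
#' @param search_box numeric length-2: common lower/upper bound per axis.
#' @param n_starts number of Latin hypercube starts.
#' @param seed RNG seed for the design (recorded in the result).
#' @param extra_starts optional matrix of additional start points (rows).
#' @return a tibble with one row per fixed point: location \code{x, y, z},
#'   eigenvalue real parts \code{re1 >= re2 >= re3}, largest imaginary part
#'   magnitude \code{im_max}, \code{stability} (stable/saddle/unstable),
#'   \code{label} and \code{drift_norm}.
#' @export
cc_fixed_points <- function(params, search_box = c(0, 6), n_starts = 200L,
                            seed = 1L, extra_starts = NULL) {
  stopifnot(search_box[1] >= 0, search_box[2] > search_box[1])
  par <- cc_par_vec(params)
  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, 3L) * diff(search_box) + search_box[1]
  if (!is.null(extra_starts)) starts <- rbind(starts, as_state_matrix(extra_starts))
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    r <- newton_root(starts[i, ], par)
    if (is.null(r)) next
    if (any(r < -1e-8) || any(r > search_box[2] + 1)) next
    if (!any(vapply(roots, function(q) max(abs(q - r)) < 1e-6, logical(1L))))
      roots[[length(roots) + 1L]] <- r
  }
  if (!length(roots)) {
    return(tibble::tibble(x = double(), y = double(), z = double(),
                          re1 = double(), re2 = double(), re3 = double(),
                          im_max = double(), stability = character(),
                          label = character(), drift_norm = double()))
  }
  rows <- lapply(roots, function(r) {
    ev <- eigen(cpp_jac(1L, par, r), only.values = TRUE)$values
    re <- sort(Re(ev), decreasing = TRUE)
    stab <- if (all(re < 0)) "stable" else if (any(re < 0)) "saddle" else "unstable"
    tibble::tibble(x = r[1], y = r[2], z = r[3],
                   re1 = re[1], re2 = re[2], re3 = re[3],
                   im_max = max(abs(Im(ev))), stability = stab,
                   drift_norm = sqrt(sum(drift_vec(r, par)^2)))
  })
  fp <- dplyr::bind_rows(rows)
  fp$label <- "other"
  is_g1 <- fp$stability == "stable" & fp$z > 1 & fp$x < 0.5 & fp$y < 0.5
  if (any(is_g1)) {
    i1 <- which(is_g1)[which.max(fp$z[is_g1])]
    fp$label[i1] <- "P1"
    one_up <- fp$stability == "saddle" & fp$re1 > 0 & fp$re2 < 0
    if (any(one_up)) {
      dd <- sqrt((fp$x - fp$x[i1])^2 + (fp$y - fp$y[i1])^2 + (fp$z - fp$z[i1])^2)
      dd[!one_up] <- Inf
      fp$label[which.min(dd)] <- "P2"
    }
  }
  dplyr::arrange(fp, dplyr::desc(.data$stability == "stable"), .data$x)
}

#' Passage-point vertices P3 and P4
#'
#' P3 (the S-phase vertex, \eqn{(x_{max}, 0, 0)}) and P4 (the early-M
#' vertex, \eqn{(0, y_{max}, 0)}) are near-fixed points, not fixed points of
#' the full system: the trigger couplings keep the excursion moving through
#' them.  \eqn{x_{max}} and \eqn{y_{max}} are the peak values of x and y
#' along the deterministic cell-cycle excursion from the excited-G1 saddle
#' (they depend on the trigger rates: a weaker trigger lets the excursion
#' climb closer to the single-variable subsystem roots before the next
#' module fires).  The single-variable subsystem roots are returned alongside
#' for reference as \code{subsystem_root}.
#'
#' @param params a \code{\link{cc_params}} object.
#' @param path optional precomputed \code{\link{canal_path}} to reuse.
#' @return a tibble with rows P3 and P4 and columns \code{label, x, y, z,
#'   subsystem_root}.
#' @export
cc_vertices <- function(params, path = NULL) {
  if (is.null(path)) path <- canal_path(params, n = 400L)
  x_max <- max(path$x)
  y_max <- max(path$y)
  x_root <- uniroot(function(x) x^2 / (params$j1^2 + x^2) - params$k1 * x + params$a0,
                    c(1 / params$k1 / 2, 2 / params$k1), tol = 1e-12)$root
  y_root <- uniroot(function(y) y^2 / (params$j2^2 + y^2) - params$k2 * y,
                    c(1 / params$k2 / 2, 2 / params$k2), tol = 1e-12)$root
  tibble::tibble(label = c("P3", "P4"),
                 x = c(x_max, 0), y = c(0, y_max), z = c(0, 0),
                 subsystem_root = c(x_root, y_root))
}

# targeted search for a stable G1-like fixed point (z > 1, x and y < 0.5)
has_stable_g1 <- function(params, n_starts = 40L, seed = 1L) {
  par <- cc_par_vec(params)
  set.seed(seed)
  lh <- lhs::randomLHS(n_starts, 3L)
  starts <- cbind(lh[, 1] * 0.5, lh[, 2] * 0.5, 1 + lh[, 3] * 5)
  starts <- rbind(c(0.01, 1e-4, 4.3), c(0.05, 1e-3, 4.0), c(0.02, 1e-4, 3.0), starts)
  for (i in seq_len(nrow(starts))) {
    r <- newton_root(starts[i, ], par)
    if (is.null(r)) next
    if (r[3] > 1 && r[1] < 0.5 && r[2] < 0.5) {
      ev <- eigen(cpp_jac(1L, par, r), only.values = TRUE)$values
      if (all(Re(ev) < 0)) return(TRUE)
    }
  }
  FALSE
}

#' Locate the excitable-to-limit-cycle bifurcation in the nutrient parameter
#'
#' Bisection on the predicate "a stable G1-like fixed point exists"
#' (stable, \eqn{z > 1}, \eqn{x, y < 0.5}) over a bracketing range of
#' \code{a0}.  The stable G1 state annihilates with the excitation-threshold
#' saddle at the critical nutrient level, beyond which the model is a limit
#' cycle oscillator.
#'
#' @param params template \code{\link{cc_params}} (its \code{a0} is ignored).
#' @param a0_range numeric length-2 bracket, e.g. \code{c(0.001, 0.01)}.
#' @param tol absolute tolerance on the returned critical value.
#' @return the critical \code{a0} (scalar), with the final bracket as
#'   attribute \code{"bracket"}.
#' @export
locate_bifurcation_a0 <- function(params, a0_range = c(0.001, 0.01),
                                  tol = 1e-6) {
  f <- function(a0) has_stable_g1(cc_params_with(params, a0 = a0))
  lo <- a0_range[1]; hi <- a0_range[2]
  if (f(lo) == f(hi))
    stop("bracketing error: G1-stability predicate identical at both ends of a0_range")
  if (!f(lo)) { tmp <- lo; lo <- hi; hi <- tmp }  # lo = stable side
  while (abs(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    if (f(mid)) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, bracket = sort(c(lo, hi)))
}

# params with overrides, preserving class
cc_params_with <- function(params, ...) {
  dots <- list(...)
  params[names(dots)] <- dots
  validate_cc_params(params)
  params
}

#' Detect a limit cycle by Poincare return analysis
#'
#' Integrates past a transient, then detects upward crossings of a mid-range
#' section in x.  A cycle is reported when at least three successive crossings
#' agree in the transverse coordinates within tolerance; convergence to a
#' point reports no cycle.
#'
#' @param params a \code{\link{cc_params}} object.
#' @param state0 start state (defaults to an interior point).
#' @param t_transient transient time discarded before detection.
#' @param t_observe observation window (should span several periods).
#' @param tol return-point agreement tolerance (concentration units).
#' @return \code{NULL} if the trajectory converges to a point; otherwise a
#'   list with \code{period} (mean return time), \code{period_sd}, and
#'   \code{cycle}, a tibble sampling one period.
#' @export
detect_limit_cycle <- function(params, state0 = c(1, 0.1, 0.1),
                               t_transient = 2000, t_observe = 1000,
                               tol = 1e-3) {
  tr <- cc_integrate(state0, params, t_transient + t_observe,
                     dt_out = min(0.25, t_observe / 4000))
  obs <- tr[tr$time > t_transient, ]
  rng <- range(obs$x)
  if (diff(rng) < 10 * tol) return(NULL)           # settled to a point
  sec <- mean(rng)
  up <- which(diff(obs$x > sec) == 1L)
  if (length(up) < 4L) return(NULL)                # ambiguous recurrence
  # refine crossing times linearly
  tcross <- obs$time[up] + (sec - obs$x[up]) /
    (obs$x[up + 1L] - obs$x[up]) * (obs$time[up + 1L] - obs$time[up])
  periods <- diff(tcross)
  ret <- cbind(obs$y[up], obs$z[up])
  spread <- max(apply(ret[-1, , drop = FALSE], 2L, function(v) diff(range(v))))
  if (spread > max(tol, 0.05 * max(abs(ret)))) return(NULL)
  period <- mean(periods)
  i0 <- up[length(up) - 1L]
  cyc <- obs[obs$time >= obs$time[i0] & obs$time <= obs$time[i0] + period, ]
  list(period = period, period_sd = sd(periods), cycle = cyc)
}

#' Classify the dynamical regime
#'
#' \code{"excitable"} when a stable G1-like fixed point exists,
#' \code{"limit_cycle"} when there is none but a limit cycle is detected,
#' \code{"other"} otherwise.
#'
#' @param params a \code{\link{cc_params}} object.
#' @param ... passed to \code{\link{detect_limit_cycle}}.
#' @return a character scalar.
#' @export
classify_regime <- function(params, ...) {
  if (has_stable_g1(params)) return("excitable")
  if (!is.null(detect_limit_cycle(params, ...))) return("limit_cycle")
  "other"
}

#' Parameter sensitivity scan
#'
#' Perturbs each of the eleven parameters by \code{+/-fraction} and records
#' the qualitative trajectory class and, when a well-depth functional is
#' supplied, the change \eqn{\delta S} in the depth of the G1 basin.
#' Individual run failures are recorded as missing entries and the scan
#' continues.
#'
#' @param params baseline \code{\link{cc_params}}.
#' @param fraction perturbation fraction (default 0.20).
#' @param well_depth_fn optional function \code{params -> scalar} returning
#'   the G1 well depth (see \code{\link{g1_well_depth}}); \code{NULL} skips
#'   the depth column.
#' @param ... passed to \code{\link{classify_regime}}.
#' @return a tibble with 22 rows (11 parameters x 2 directions):
#'   \code{parameter, direction, value, regime, delta_S}.
#' @export
sensitivity_scan <- function(params, fraction = 0.20, well_depth_fn = NULL, ...) {
  base_depth <- if (is.null(well_depth_fn)) NA_real_ else
    tryCatch(well_depth_fn(params), error = function(e) NA_real_)
  grid <- tidyr::expand_grid(parameter = cc_param_names(),
                             direction = c("increase", "decrease"))
  res <- purrr::pmap_dfr(grid, function(parameter, direction) {
    mult <- if (direction == "increase") 1 + fraction else 1 - fraction
    val <- params[[parameter]] * mult
    row <- tibble::tibble(parameter = parameter, direction = direction,
                          value = val, regime = NA_character_,
                          delta_S = NA_real_)
    pert <- do.call(cc_params_with, c(list(params), setNames(list(val), parameter)))
    row$regime <- tryCatch(classify_regime(pert, ...), error = function(e) NA_character_)
    if (!is.null(well_depth_fn)) {
      d <- tryCatch(well_depth_fn(pert), error = function(e) NA_real_)
      row$delta_S <- d - base_depth
    }
    row
  })
  res
}
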