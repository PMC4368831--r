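#' Deterministic canal path from the excited-G1 saddle
#'
#' Integrates the flow from just past the saddle P2 along its unstable
#' direction and resamples the resulting cell-cycle excursion (P2 -> P3 ->
#' P4 -> G1) to equal arc length.  This is the reference path of the canal.
#'
#' @param params a \code{\link{cc_params}} object.
#' @param n number of arc-length samples.
#' @param delta initial displacement along the unstable eigenvector.
#' @param t_end integration horizon.
#' @param stop_radius stop once within this distance of the stable G1 state
#'   (the canal ends at the G1 well).
#' @return a tibble \code{x, y, z, arclength, speed} (speed = \eqn{\|b\|}).
#' @export
canal_path <- function(params, n = 200L, delta = 0.02, t_end = 3000,
                       stop_radius = 0.05) {
  fp <- cc_fixed_points(params)
  p2 <- fp[fp$label == "P2", ]
  if (nrow(p2) != 1L) stop("no excited-G1 saddle (P2) found for these parameters")
  par <- cc_par_vec(params)
  J <- cpp_jac(1L, par, as.numeric(p2[, c("x", "y", "z")]))
  ev <- eigen(J)
  iu <- which.max(Re(ev$values))
  u <- Re(ev$vectors[, iu])
  if (u[1] < 0) u <- -u                       # excite toward growing x
  s0 <- pmax(as.numeric(p2[, c("x", "y", "z")]) + delta * u, 0)
  tr <- cc_integrate(s0, params, t_end, dt_out = 0.2)
  p1 <- fp[fp$label == "P1", ]
  if (nrow(p1) == 1L) {
    dd <- sqrt((tr$x - p1$x)^2 + (tr$y - p1$y)^2 + (tr$z - p1$z)^2)
    stop_i <- which(dd < stop_radius)[1]
    if (!is.na(stop_i)) tr <- tr[seq_len(stop_i), ]
  }
  m <- as.matrix(tr[, c("x", "y", "z")])
  seg <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  L <- cs[length(cs)]
  starget <- seq(0, L, length.out = n)
  res <- vapply(1:3, function(k) approx(cs, m[, k], xout = starget, ties = "ordered")$y,
                numeric(n))
  speed <- vapply(seq_len(n), function(i)
    sqrt(sum(drift_vec(pmax(res[i, ], 0), par)^2)), 0)
  tibble::tibble(x = res[, 1], y = res[, 2], z = res[, 3],
                 arclength = starget, speed = speed)
}

#' Reference skeleton for cell-cycle landscape computations
#'
#' The concatenation of a straight segment from the stable G1 state P1 to the
#' excited-G1 saddle P2 with the deterministic excursion path (P2 -> P3 ->
#' P4 -> G1), used to seed initial paths in
#' \code{\link{quasipotential_grid}}.
#'
#' @param params a \code{\link{cc_params}} object.
#' @param n number of canal samples.
#' @return a matrix of points (rows), starting at P1.
#' @export
cc_skeleton <- function(params, n = 150L) {
  fp <- cc_fixed_points(params)
  p1 <- as.numeric(fp[fp$label == "P1", c("x", "y", "z")])
  cp <- canal_path(params, n = n)
  m <- as.matrix(cp[, c("x", "y", "z")])
  tt <- seq(0, 1, length.out = 12L)[-12L]
  head_seg <- outer(1 - tt, p1) + outer(tt, m[1, ])
  unname(rbind(head_seg, m))
}

#' Transverse fluctuation spread of simulated trajectories along the canal
#'
#' Assigns simulated states (concentration scale) to their nearest reference
#' path point and, per requested station, returns the standard deviation of
#' the transverse in-plane displacement over states assigned to a window of
#' neighbouring stations.  This is the directly measured fluctuation
#' strength along the cycle: under intrinsic noise it collapses near the
#' slow vertices (the reaction rates, and with them the noise, nearly
#' vanish there), whereas under extrinsic noise it tracks only the
#' transverse contraction rate and varies far less.
#'
#' @param traj a trajectory tibble with \code{x, y, z} (concentration
#'   scale, e.g. from \code{\link{ssa_simulate}} divided by V, or
#'   \code{\link{em_simulate}}).
#' @param path a \code{\link{canal_path}} tibble.
#' @param stations path row indices at which to report the spread.
#' @param window half-width, in path rows, of the assignment window.
#' @param max_dist discard states further than this from the path.
#' @return a tibble \code{station, arclength, n, spread}.
#' @export
canal_transverse_spread <- function(traj, path, stations, window = 3L,
                                    max_dist = 0.8) {
  m <- as.matrix(path[, c("x", "y", "z")])
  pts <- as.matrix(traj[, c("x", "y", "z")])
  # nearest path row per state
  d2 <- outer(rowSums(pts^2), rep(1, nrow(m))) +
    outer(rep(1, nrow(pts)), rowSums(m^2)) - 2 * pts %*% t(m)
  nearest <- max.col(-d2)
  dist_near <- sqrt(pmax(d2[cbind(seq_len(nrow(pts)), nearest)], 0))
  purrr::map_dfr(stations, function(i) {
    sel <- which(abs(nearest - i) <= window & dist_near <= max_dist)
    if (length(sel) < 10L)
      return(tibble::tibble(station = i, arclength = path$arclength[i],
                            n = length(sel), spread = NA_real_))
    n1 <- canal_normal(m, i)
    off <- (pts[sel, , drop = FALSE] -
              matrix(m[i, ], length(sel), 3L, byrow = TRUE)) %*% n1
    tibble::tibble(station = i, arclength = path$arclength[i],
                   n = length(sel), spread = sd(off))
  })
}

# in-plane transverse unit normal at path row i (the plane drops the axis
# the canal currently hugs)
canal_normal <- function(m, i) {
  if (i < nrow(m)) tang <- m[i + 1L, ] - m[i, ] else tang <- m[i, ] - m[i - 1L, ]
  tang <- tang / max(sqrt(sum(tang^2)), 1e-12)
  drop_ax <- which.min(m[i, ])
  keep <- setdiff(1:3, drop_ax)
  n1 <- c(0, 0, 0)
  n1[keep] <- c(-tang[keep[2]], tang[keep[1]])
  nn <- sqrt(sum(n1^2))
  if (nn < 1e-8) { n1 <- c(0, 0, 0); n1[keep[1]] <- 1; n1 } else n1 / nn
}

#' Local pseudo energy landscape along the canal
#'
#' The global quasi-potential is flat along the cell-cycle canal, so it
#' cannot display the direction of motion.  The pseudo landscape removes the
#' globally stable G1 well from view and encodes the non-gradient drive
#' tangentially: the tangential potential is
#' \deqn{T(s) = -\int_0^s \|b(\phi(u))\|\, du}
#' along the deterministic canal path \eqn{\phi} from P2 (strictly
#' decreasing, with slope \eqn{-\|b\|}: steep where the driving force is
#' strong, almost flat near the slow vertices P3 and P4), while the
#' transverse profile at each section is the local quasi-potential computed
#' in the plane normal to the path, with the path point as origin — so the
#' restriction of the landscape across the canal is unchanged.  The combined
#' value at a point near the path is \eqn{T(s^*) + S_\perp}, with \eqn{s^*}
#' the arc length of the nearest path point.
#'
#' @param params a \code{\link{cc_params}} object.
#' @param spec a \code{\link{ham_spec}} (defaults to the intrinsic
#'   Hamiltonian at \code{params}).
#' @param path_resolution number of arc-length stations along the path.
#' @param transverse_extent half-width of the transverse sections
#'   (concentration units).
#' @param n_transverse transverse offsets per side and section.
#' @param n_path_nodes,max_iter,tol minimizer settings for the transverse
#'   local quasi-potential solves.
#' @return a \code{pseudo_landscape}: list with \code{path} (the reference
#'   path with \code{tangential} = T(s)), \code{sections} (long tibble:
#'   \code{station, arclength, offset, S_transverse, combined}), and the
#'   inputs.
#' @export
build_pseudo <- function(params, spec = NULL, path_resolution = 40L,
                         transverse_extent = 0.6, n_transverse = 4L,
                         n_path_nodes = 24L, max_iter = 400L, tol = 1e-7) {
  if (is.null(spec)) spec <- ham_intrinsic(params)
  pp <- canal_path(params, n = path_resolution)
  ds <- diff(pp$arclength)
  speed_mid <- (pp$speed[-1] + pp$speed[-nrow(pp)]) / 2
  pp$tangential <- c(0, -cumsum(speed_mid * ds))
  m <- as.matrix(pp[, c("x", "y", "z")])
  par <- cc_par_vec(params)
  sections <- purrr::map_dfr(seq_len(nrow(pp)), function(i) {
    b <- drift_vec(pmax(m[i, ], 0), par)
    tang <- b / max(sqrt(sum(b^2)), 1e-12)
    # transverse frame: project out the tangent from two fixed probes
    probe <- diag(3)[, order(abs(tang))[1:2]]
    n1 <- probe[, 1] - sum(probe[, 1] * tang) * tang
    n1 <- n1 / sqrt(sum(n1^2))
    n2c <- c(tang[2] * n1[3] - tang[3] * n1[2],
             tang[3] * n1[1] - tang[1] * n1[3],
             tang[1] * n1[2] - tang[2] * n1[1])
    offs <- seq(transverse_extent / n_transverse, transverse_extent,
                length.out = n_transverse)
    grid <- tidyr::expand_grid(dir = list(n1, -n1, n2c, -n2c), off = offs)
    st <- purrr::pmap_dfr(grid, function(dir, off) {
      target <- m[i, ] + off * dir
      if (any(target < 0)) return(NULL)    # outside the concentration domain
      pth <- minimize_action(spec, m[i, ], target, n_nodes = n_path_nodes,
                             max_iter = max_iter, tol = tol)
      tibble::tibble(offset = off, S_transverse = attr(pth, "action"))
    })
    if (!nrow(st)) return(NULL)
    st <- dplyr::summarise(dplyr::group_by(st, .data$offset),
                           S_transverse = mean(.data$S_transverse), .groups = "drop")
    dplyr::mutate(st, station = i, arclength = pp$arclength[i],
                  combined = pp$tangential[i] + .data$S_transverse)
  })
  structure(list(path = pp, sections = sections, params = params,
                 spec = spec, transverse_extent = transverse_extent),
            class = "pseudo_landscape")
}

#' @export
print.pseudo_landscape <- function(x, ...) {
  cat("<pseudo_landscape>", nrow(x$path), "stations, tangential drop",
      sprintf("%.4g\n", -min(x$path$tangential)))
  invisible(x)
}

#' Transverse canal width at fixed energy offset
#'
#' For each arc-length station, the transverse distance at which the global
#' quasi-potential (relative to the origin attractor) rises by
#' \code{energy_offset} above its value on the canal floor, averaged over
#' both sides of the canal.  This is the restriction width that confines
#' stochastic trajectories: under intrinsic noise — whose local intensity
#' follows the reaction rates and nearly vanishes where the cycle stalls —
#' the canal narrows sharply near the vertices P3 and P4 relative to the
#' fast mid-canal stretches.  A sensible \code{energy_offset} is the noise
#' scale, e.g. \eqn{1/V} for the jump process at system size V.
#'
#' @param spec a \code{\link{ham_spec}}.
#' @param path a reference path tibble from \code{\link{canal_path}} (or any
#'   tibble with \code{x, y, z, arclength}).
#' @param attractor origin of the quasi-potential (the stable G1 state for
#'   the cell-cycle model); computed from the model parameters when omitted.
#' @param energy_offset energy rise defining the wall (quasi-potential
#'   units; default 0.01, the finite-volume scale at V = 100).
#' @param stations indices (rows of \code{path}) at which to measure;
#'   default: 8 stations spread over the path interior.
#' @param transverse_extent maximal transverse distance scanned; if the
#'   offset is never reached the width is reported as the extent and
#'   flagged.
#' @param skeleton optional seeding polyline for the landscape solves
#'   (defaults to the path itself, prefixed by the attractor).
#' @param n_path_nodes,max_iter,tol minimizer settings per landscape solve.
#' @return a tibble \code{station, arclength, x, y, z, S_floor, width,
#'   capped}.
#' @export
canal_width_profile <- function(spec, path, attractor = NULL,
                                energy_offset = 0.01,
                                stations = NULL, transverse_extent = 1.2,
                                skeleton = NULL,
                                n_path_nodes = 24L, max_iter = 800L,
                                tol = 1e-9) {
  m <- as.matrix(path[, c("x", "y", "z")])
  if (is.null(attractor)) {
    stopifnot(identical(spec$model, "cellcycle"))
    fp <- cc_fixed_points(spec$params)
    attractor <- as.numeric(fp[fp$label == "P1", c("x", "y", "z")])
  }
  attractor <- as.numeric(attractor)
  if (is.null(skeleton)) skeleton <- rbind(attractor, m)
  if (is.null(stations))
    stations <- unique(round(seq(2, nrow(m) - 1L, length.out = 8L)))
  S_of <- function(pts) quasipotential_at(spec, attractor, pts,
                                          skeleton = skeleton,
                                          n_path_nodes = n_path_nodes,
                                          max_iter = max_iter, tol = tol)
  purrr::map_dfr(stations, function(i) {
    b <- spec_drift(spec, m[i, ])
    tang <- b / max(sqrt(sum(b^2)), 1e-12)
    # transverse direction within the plane the canal currently hugs: drop
    # the axis with the smallest coordinate (the boundary face) and take the
    # in-plane perpendicular of the tangent
    drop_ax <- which.min(m[i, ])
    keep <- setdiff(1:3, drop_ax)
    n1 <- c(0, 0, 0)
    n1[keep] <- c(-tang[keep[2]], tang[keep[1]])
    nn <- sqrt(sum(n1^2))
    if (nn < 1e-8) {                       # tangent ~ parallel to dropped axis
      n1 <- c(0, 0, 0); n1[keep[1]] <- 1
    } else n1 <- n1 / nn
    S_floor <- S_of(matrix(m[i, ], 1L))
    # landscape rise when displaced transversally; leaving the domain counts
    # as a wall
    rise_at <- function(off, dir) {
      target <- m[i, ] + off * dir
      if (any(target < 0)) return(Inf)
      S_of(matrix(target, 1L)) - S_floor
    }
    wall <- function(dir) {
      if (rise_at(transverse_extent, dir) < energy_offset)
        return(c(transverse_extent, TRUE))
      lo <- 0; hi <- transverse_extent
      for (it in 1:9) {
        mid <- (lo + hi) / 2
        if (rise_at(mid, dir) < energy_offset) lo <- mid else hi <- mid
      }
      c((lo + hi) / 2, FALSE)
    }
    w1 <- wall(n1); w2 <- wall(-n1)
    tibble::tibble(station = i, arclength = path$arclength[i],
                   x = m[i, 1], y = m[i, 2], z = m[i, 3],
                   S_floor = S_floor,
                   width = (w1[1] + w2[1]) / 2,
                   capped = as.logical(w1[2] || w2[2]))
  })
}
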