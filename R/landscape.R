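#' Local quasi-potential on a regular grid
#'
#' Computes \eqn{S(x; x_0)} at every node of a regular grid by geometric
#' action minimization from the origin attractor, accelerated by
#' continuation: nodes are processed outward from the attractor and each
#' target's initial path is seeded from a converged grid neighbour.  The
#' attractor may be a point (stable fixed point) or a matrix of stored limit
#' cycle samples, in which case each path starts from the nearest cycle
#' point and the cycle is the zero level set.
#'
#' @param spec a \code{\link{ham_spec}}.
#' @param attractor numeric vector (one point) or matrix whose rows sample a
#'   limit cycle.
#' @param axes list of axis node vectors, one per model dimension (an axis of
#'   length 1 pins that coordinate, giving planar slices).  Alternatively use
#'   \code{bounds}/\code{n}.
#' @param bounds numeric length-2 common bounds used when \code{axes} is
#'   missing (default \code{c(0, 6)}).
#' @param n nodes per axis (scalar or per-axis vector) when \code{axes} is
#'   missing; default 21 in tests and 61 for production-quality figures.
#' @param n_path_nodes path discretization per target (default 16 for grid
#'   fills; single transitions deserve more, see
#'   \code{\link{minimize_action}}).
#' @param max_iter_first,max_iter relaxation iteration caps for the first
#'   (cold-started) node and for continuation nodes.
#' @param tol relative action-change tolerance per node.
#' @param skeleton optional reference polyline (matrix of points starting at
#'   the attractor), used as an alternative initial path per node: the path
#'   follows the skeleton to its nearest point and then runs straight to the
#'   target; the cheaper of the skeleton and neighbour-continuation inits is
#'   relaxed.  Supplying the deterministic cycle path (see
#'   \code{\link{cc_skeleton}}) lets the minimizer discover the excursion
#'   route along the canal instead of tunnelling through high-action
#'   territory.
#' @param n_sweeps number of post-fill improvement sweeps in which every node
#'   retries warm starts morphed from its neighbours' converged paths and
#'   keeps the best result (removes route inconsistencies between
#'   neighbouring nodes).
#' @return a \code{landscape_grid}: list with \code{values} (array of S,
#'   \code{NA} where the solve failed), \code{converged} (logical array),
#'   \code{axes}, \code{attractor}, \code{spec}.
#' @export
quasipotential_grid <- function(spec, attractor, axes = NULL,
                                bounds = c(0, 6), n = 21L,
                                n_path_nodes = 16L,
                                max_iter_first = 4000L, max_iter = 120L,
                                tol = 1e-6, skeleton = NULL, n_sweeps = 2L) {
  stopifnot(inherits(spec, "ham_spec"))
  d <- spec$dim
  if (is.null(axes)) {
    if (length(n) == 1L) n <- rep(n, d)
    axes <- lapply(seq_len(d), function(k) seq(bounds[1], bounds[2], length.out = n[k]))
  }
  stopifnot(length(axes) == d)
  A <- if (is.matrix(attractor)) attractor else matrix(as.numeric(attractor), nrow = 1L)
  stopifnot(ncol(A) == d)
  if (is.null(skeleton)) skeleton <- matrix(numeric(0), 0L, d)
  skeleton <- matrix(as.numeric(skeleton), ncol = d)
  res <- cpp_fill_grid(spec$kcode, spec$mcode, spec$par, axes, A, skeleton,
                       as.integer(n_path_nodes), as.integer(max_iter_first),
                       as.integer(max_iter), tol, spec_lb(spec),
                       as.integer(n_sweeps))
  vals <- res$S
  vals[vals < 0] <- 0
  new_landscape_grid(vals, axes, A, spec,
                     converged = array(res$converged == 1L, dim = dim(res$S)))
}

#' Quasi-potential at arbitrary points
#'
#' Direct geometric-action minimization from the attractor to each point
#' (no grid): the accurate way to evaluate S and its local derivatives at a
#' handful of locations, e.g. along the canal.
#'
#' @param spec a \code{\link{ham_spec}}.
#' @param attractor origin point (or matrix of cycle samples; the nearest is
#'   used per target).
#' @param points matrix/data frame of target points (rows).
#' @param skeleton optional reference polyline as in
#'   \code{\link{quasipotential_grid}}.
#' @param n_path_nodes,max_iter,tol minimizer settings.
#' @return numeric vector of S values.
#' @export
quasipotential_at <- function(spec, attractor, points, skeleton = NULL,
                              n_path_nodes = 24L, max_iter = 2000L,
                              tol = 1e-9) {
  pts <- path_matrix(points, spec)
  A <- if (is.matrix(attractor)) attractor else matrix(as.numeric(attractor), nrow = 1L)
  vapply(seq_len(nrow(pts)), function(i) {
    tgt <- pts[i, ]
    ia <- which.min(colSums((t(A) - tgt)^2))
    start <- A[ia, ]
    init <- NULL
    best <- Inf
    if (!is.null(skeleton)) {
      m <- which.min(colSums((t(skeleton) - tgt)^2))
      init <- rbind(skeleton[seq_len(m), , drop = FALSE], tgt)
      # resample the polyline to the requested node count
      seg <- sqrt(rowSums((init[-1, , drop = FALSE] - init[-nrow(init), , drop = FALSE])^2))
      cs <- c(0, cumsum(seg))
      starget <- seq(0, cs[length(cs)], length.out = n_path_nodes)
      init <- vapply(seq_len(ncol(init)), function(k)
        approx(cs, init[, k], xout = starget, ties = "ordered")$y, numeric(n_path_nodes))
      init <- pmax(init, spec_lb(spec))
      p_s <- minimize_action(spec, start, tgt, max_iter = max_iter, tol = tol,
                             init_path = init)
      best <- attr(p_s, "action")
    }
    p_d <- minimize_action(spec, start, tgt, n_nodes = n_path_nodes,
                           max_iter = max_iter, tol = tol)
    min(best, attr(p_d, "action"))
  }, 0)
}

new_landscape_grid <- function(values, axes, attractor, spec, converged = NULL,
                               meta = list()) {
  names(axes) <- c("x", "y", "z")[seq_along(axes)]
  structure(list(values = values, axes = axes, attractor = attractor,
                 spec = spec, converged = converged, meta = meta),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat("<landscape_grid>", paste(dim(x$values), collapse = " x "),
      "nodes;", sum(is.na(x$values)), "missing\n")
  cat("  axes:", paste(sprintf("%s [%g, %g]", names(x$axes),
                               vapply(x$axes, min, 0), vapply(x$axes, max, 0)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.landscape_grid <- function(x, ...) {
  g <- do.call(expand.grid, c(x$axes, KEEP.OUT.ATTRS = FALSE))
  tibble::as_tibble(cbind(g, S = as.vector(x$values)))
}

#' @export
glance.landscape_grid <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$values),
                 n_missing = sum(is.na(x$values)),
                 S_min = min(x$values, na.rm = TRUE),
                 S_max = max(x$values, na.rm = TRUE),
                 kind = x$spec$kind, model = x$spec$model)
}

# central finite-difference gradient of S, one-sided at boundaries/missing
grid_gradient <- function(grid) {
  v <- grid$values
  d <- length(grid$axes)
  dims <- dim(v)
  out <- vector("list", d)
  idx_shift <- function(k, by) {
    idx <- lapply(dims, seq_len)
    idx[[k]] <- pmin(pmax(idx[[k]] + by, 1L), dims[k])
    idx
  }
  for (k in seq_len(d)) {
    h <- diff(grid$axes[[k]])[1]
    up <- do.call(`[`, c(list(v), idx_shift(k, 1L)))
    dn <- do.call(`[`, c(list(v), idx_shift(k, -1L)))
    # spacing actually spanned (1 cell at the two boundary planes, else 2)
    span <- array(2 * h, dims)
    ifirst <- idx_shift(k, 0L); ifirst[[k]] <- ifelse(ifirst[[k]] %in% c(1L, dims[k]), 1L, 2L)
    bmask <- slice.index(v, k) %in% c(1L, dims[k])
    span[bmask] <- h
    g <- (up - dn) / span
    dim(g) <- dims
    out[[k]] <- g
  }
  out
}

#' Hamilton-Jacobi residual of a landscape grid
#'
#' The quasi-potential satisfies \eqn{H(x, \nabla S(x)) = 0}; this diagnostic
#' evaluates \eqn{|H(x, \nabla S)|} with central finite-difference gradients
#' over interior defined nodes.  The residual decreases under grid refinement
#' for an accurate landscape.
#'
#' @param grid a \code{\link{quasipotential_grid}} result.
#' @param spec a \code{\link{ham_spec}} (defaults to the grid's own).
#' @return a one-row tibble: \code{mean_residual, max_residual, n_nodes}.
#' @export
hj_residual <- function(grid, spec = grid$spec) {
  d <- length(grid$axes)
  gr <- grid_gradient(grid)
  dims <- dim(grid$values)
  interior <- array(TRUE, dims)
  for (k in seq_len(d)) {
    if (dims[k] >= 3L)
      interior <- interior & !(slice.index(grid$values, k) %in% c(1L, dims[k]))
  }
  ok <- interior & !is.na(grid$values)
  for (k in seq_len(d)) ok <- ok & !is.na(gr[[k]])
  idx <- which(ok, arr.ind = TRUE)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 1L)
  res <- vapply(seq_len(nrow(idx)), function(i) {
    pt <- vapply(seq_len(d), function(k) grid$axes[[k]][idx[i, k]], 0)
    p <- vapply(seq_len(d), function(k) gr[[k]][matrix(idx[i, ], 1L)], 0)
    abs(cpp_ham(spec$kcode, spec$mcode, spec$par, pt, p))
  }, 0)
  tibble::tibble(mean_residual = mean(res), max_residual = max(res),
                 n_nodes = length(res))
}

#' Non-gradient force field on a landscape grid
#'
#' The most probable cycling path under the jump dynamics follows
#' \eqn{\dot x = \nabla_p H(x, \nabla S) = F(x)}.  Where the landscape
#' gradient vanishes the force reduces exactly to the deterministic drift
#' \eqn{b(x)}; for the extrinsic Hamiltonian \eqn{F = b + \nabla S}.
#'
#' @param grid a \code{\link{quasipotential_grid}} result.
#' @param spec a \code{\link{ham_spec}} (defaults to the grid's own).
#' @return a tibble with node coordinates, \code{S}, finite-difference
#'   gradient columns \code{g*}, force components \code{F*}, drift
#'   components \code{b*}, and norms \code{gnorm, Fnorm, bnorm}.
#' @export
force_field <- function(grid, spec = grid$spec) {
  d <- length(grid$axes)
  gr <- grid_gradient(grid)
  df <- tidy.landscape_grid(grid)
  gm <- sapply(gr, as.vector)
  keep <- !is.na(df$S) & rowSums(is.na(gm)) == 0
  df <- df[keep, , drop = FALSE]
  gm <- gm[keep, , drop = FALSE]
  pts <- as.matrix(df[, seq_len(d), drop = FALSE])
  gm <- matrix(gm, ncol = d)
  FF <- matrix(vapply(seq_len(nrow(df)), function(i)
    cpp_ham_dp(spec$kcode, spec$mcode, spec$par, pts[i, ], gm[i, ]),
    numeric(d)), ncol = d, byrow = TRUE)
  bb <- matrix(vapply(seq_len(nrow(df)), function(i)
    cpp_drift(spec$mcode, spec$par, pts[i, ]), numeric(d)),
    ncol = d, byrow = TRUE)
  suff <- c("x", "y", "z")[seq_len(d)]
  for (k in seq_len(d)) {
    df[[paste0("g", suff[k])]] <- gm[, k]
    df[[paste0("F", suff[k])]] <- FF[, k]
    df[[paste0("b", suff[k])]] <- bb[, k]
  }
  df$gnorm <- sqrt(rowSums(gm^2))
  df$Fnorm <- sqrt(rowSums(FF^2))
  df$bnorm <- sqrt(rowSums(bb^2))
  df
}

#' Glue local quasi-potentials into a global landscape
#'
#' With a single attractor the local quasi-potential already is the global
#' landscape (identity passthrough).  With two attractors the standard
#' Freidlin-Wentzell sticking construction is used: each local grid is
#' shifted by a constant offset determined from the pairwise transition
#' costs \eqn{V_{ij} = S_i(A_j)} (interpolated from the grids), and the
#' global landscape is the pointwise minimum of the shifted grids,
#' renormalized to zero at its minimum.
#'
#' @param local_grids a list of \code{\link{quasipotential_grid}} results on
#'   identical axes, one per attractor.
#' @return a \code{landscape_grid}.
#' @export
glue_global <- function(local_grids) {
  if (inherits(local_grids, "landscape_grid")) local_grids <- list(local_grids)
  n <- length(local_grids)
  if (n == 1L) return(local_grids[[1L]])
  if (n > 2L) stop("gluing is implemented for at most two attractors")
  g1 <- local_grids[[1L]]; g2 <- local_grids[[2L]]
  if (!isTRUE(all.equal(g1$axes, g2$axes))) stop("grids must share axes")
  a1 <- as.numeric(g1$attractor[1, ]); a2 <- as.numeric(g2$attractor[1, ])
  V12 <- interp_grid(g1, matrix(a2, 1L))   # cost attractor1 -> attractor2
  V21 <- interp_grid(g2, matrix(a1, 1L))
  if (!is.finite(V12) || !is.finite(V21))
    stop("disconnected attractor graph: transition cost not defined on the grid")
  W <- c(V21, V12)                         # Freidlin-Wentzell W-values
  cshift <- W - min(W)
  vals <- pmin(g1$values + cshift[1], g2$values + cshift[2], na.rm = TRUE)
  vals <- vals - min(vals, na.rm = TRUE)
  new_landscape_grid(vals, g1$axes, rbind(g1$attractor, g2$attractor),
                     g1$spec, meta = list(glued = TRUE, offsets = cshift))
}

# multilinear interpolation of grid values at points (rows); NA outside
interp_grid <- function(grid, pts) {
  d <- length(grid$axes)
  pts <- matrix(pts, ncol = d)
  v <- grid$values
  dims <- dim(v)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    lo <- integer(d); frac <- numeric(d)
    bad <- FALSE
    for (k in seq_len(d)) {
      ax <- grid$axes[[k]]
      if (pts[i, k] < ax[1] - 1e-9 || pts[i, k] > ax[length(ax)] + 1e-9) { bad <- TRUE; break }
      if (length(ax) == 1L) { lo[k] <- 1L; frac[k] <- 0; next }
      j <- findInterval(pts[i, k], ax, rightmost.closed = TRUE)
      j <- min(max(j, 1L), length(ax) - 1L)
      lo[k] <- j
      frac[k] <- (pts[i, k] - ax[j]) / (ax[j + 1L] - ax[j])
    }
    if (bad) { out[i] <- NA_real_; next }
    acc <- 0; wtot <- 0
    for (corner in seq_len(2^d) - 1L) {
      idx <- integer(d); w <- 1
      for (k in seq_len(d)) {
        bit <- bitwAnd(corner, bitwShiftL(1L, k - 1L)) > 0L
        if (length(grid$axes[[k]]) == 1L) bit <- FALSE
        idx[k] <- lo[k] + as.integer(bit)
        w <- w * if (bit) frac[k] else 1 - frac[k]
      }
      val <- v[matrix(idx, 1L)]
      if (!is.na(val) && w > 0) { acc <- acc + w * val; wtot <- wtot + w }
    }
    out[i] <- if (wtot > 1e-9) acc / wtot else NA_real_
  }
  out
}

#' Extract a planar slice of a landscape
#'
#' Nearest-plane extraction along one axis.
#'
#' @param grid a \code{landscape_grid} (3-D).
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}.
#' @param value coordinate of the slicing plane (snapped to the nearest grid
#'   plane).
#' @return a 2-D \code{landscape_grid} over the remaining axes, with the
#'   fixed axis kept at length 1.
#' @export
landscape_slice <- function(grid, axis, value) {
  k <- match(axis, names(grid$axes))
  if (is.na(k)) stop("unknown axis '", axis, "'")
  ax <- grid$axes[[k]]
  half <- if (length(ax) > 1L) diff(ax)[1] / 2 else 0
  if (value < min(ax) - half - 1e-9 || value > max(ax) + half + 1e-9)
    stop("slice value ", value, " outside grid bounds for axis ", axis)
  j <- which.min(abs(ax - value))
  idx <- lapply(dim(grid$values), seq_len)
  idx[[k]] <- j
  vals <- do.call(`[`, c(list(grid$values), idx, list(drop = FALSE)))
  axes <- grid$axes
  axes[[k]] <- ax[j]
  out <- new_landscape_grid(vals, axes, grid$attractor, grid$spec,
                            meta = c(grid$meta, list(slice_axis = axis, slice_value = ax[j])))
  if (!is.null(grid$se))
    out$se <- do.call(`[`, c(list(grid$se), idx, list(drop = FALSE)))
  out
}

#' Minimum-projection of a landscape along one axis
#'
#' Pointwise minimum of S over the chosen axis for each combination of the
#' remaining coordinates (missing-aware), the convention used to project the
#' 3-D landscape onto a plane.
#'
#' @inheritParams landscape_slice
#' @return a 2-D \code{landscape_grid} with the projected axis of length 1
#'   (coordinate set to NA-meaningless midpoint).
#' @export
min_project <- function(grid, axis) {
  k <- match(axis, names(grid$axes))
  if (is.na(k)) stop("unknown axis '", axis, "'")
  keep <- setdiff(seq_along(grid$axes), k)
  vals <- apply(grid$values, keep, function(v)
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  newdims <- dim(grid$values); newdims[k] <- 1L
  dim(vals) <- newdims   # inserting a length-1 axis keeps the linear layout
  axes <- grid$axes
  axes[[k]] <- mean(range(grid$axes[[k]]))
  new_landscape_grid(vals, axes, grid$attractor, grid$spec,
                     meta = c(grid$meta, list(projected_axis = axis)))
}

# 2-D matrix view of a planar landscape_grid + the two free axes
slice_matrix <- function(slice) {
  free <- which(lengths(slice$axes) > 1L)
  if (length(free) != 2L) stop("not a planar landscape")
  m <- apply(slice$values, free, identity)
  list(m = m, ax1 = slice$axes[[free[1]]], ax2 = slice$axes[[free[2]]],
       names = names(slice$axes)[free])
}

#' Local minima of a planar landscape
#'
#' A node is a local minimum ("pit") when it lies below all of its defined
#' 8-neighbours by more than \code{depth}; boundary nodes are compared
#' against their existing neighbours.  The depth threshold is two grid-noise
#' standard errors: for sampled (\eqn{-\ln \hat P}) landscapes built from
#' replicate chunks the per-bin standard errors are used directly (margin
#' greater than \eqn{2\sqrt{se_c^2 + se_n^2}} against every neighbour);
#' otherwise a single robust noise scale is estimated as the median absolute
#' deviation of the residual against a 3x3 median filter.
#'
#' @param slice a planar \code{landscape_grid} (from
#'   \code{\link{landscape_slice}}, \code{\link{min_project}} or
#'   \code{\link{finite_volume_landscape}} of a slice).
#' @param depth minimum depth below every neighbour; \code{NULL} for the
#'   automatic estimate.
#' @return a tibble with the free-axis coordinates, \code{S} and
#'   \code{depth} (margin below the shallowest neighbour) per pit.
#' @export
slice_local_minima <- function(slice, depth = NULL) {
  sm <- slice_matrix(slice)
  m <- sm$m
  nr <- nrow(m); nc <- ncol(m)
  se <- NULL
  if (!is.null(slice$se)) {
    free <- which(lengths(slice$axes) > 1L)
    se <- apply(slice$se, free, identity)
  }
  if (is.null(depth) && is.null(se)) {
    med <- m
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      nb <- m[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
      med[i, j] <- median(nb, na.rm = TRUE)
    }
    noise <- mad(as.vector(m - med), na.rm = TRUE)
    depth <- 2 * max(noise, 1e-9)
  }
  se_cap <- if (!is.null(se)) max(se, na.rm = TRUE) else 0
  hits <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(m[i, j])) next
    ii <- max(1, i - 1):min(nr, i + 1)
    jj <- max(1, j - 1):min(nc, j + 1)
    nb <- m[ii, jj]
    if (sum(!is.na(nb)) < 4L) next
    if (!is.null(se) && is.null(depth)) {
      if (is.na(se[i, j])) next                 # centre must be well sampled
      ok <- TRUE
      for (a in seq_along(ii)) for (b in seq_along(jj)) {
        if (ii[a] == i && jj[b] == j) next
        v <- m[ii[a], jj[b]]
        if (is.na(v)) next                      # unvisited neighbour: above by construction
        sn <- se[ii[a], jj[b]]
        if (is.na(sn)) sn <- se_cap
        if (v - m[i, j] <= 2 * sqrt(se[i, j]^2 + sn^2)) { ok <- FALSE; break }
      }
      if (!ok) next
      margin <- min(sort(nb[!is.na(nb)])[-1]) - m[i, j]
    } else {
      others <- sort(nb[!is.na(nb)])[-1]        # drop one copy of the centre value
      margin <- min(others) - m[i, j]
      if (!(margin > depth)) next
    }
    hits[[length(hits) + 1L]] <- tibble::tibble(a1 = sm$ax1[i], a2 = sm$ax2[j],
                                                S = m[i, j], depth = margin)
  }
  out <- if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(a1 = double(), a2 = double(), S = double(), depth = double())
  names(out)[1:2] <- sm$names
  attr(out, "depth_threshold") <- depth
  out
}

#' Confirm a candidate landscape pit by its local escape barrier
#'
#' The local quasi-potential relative to the global attractor is *flat*
#' (at the height of the entry barrier) along every free-relaxation path,
#' so strict grid-based depth detection cannot separate a genuine pit from
#' the flat canal floor, and grid route noise can fake shallow minima.
#' What makes a pit a pit is that leaving it costs action: this check
#' computes the geometric action *from the candidate point* to a ring of
#' surrounding targets (within the slice plane when one coordinate is
#' pinned) and confirms the pit only when every escape direction costs more
#' than \code{margin}.  A flat-canal point fails immediately — relaxation
#' carries it through the downstream ring at zero cost — while a trapping
#' state (e.g. the checkpoint attractor) is confirmed.
#'
#' @param spec a \code{\link{ham_spec}}.
#' @param center candidate pit location (length = model dimension).
#' @param fixed_axis optional axis index/name held fixed (ring drawn in the
#'   remaining plane); \code{NULL} draws the ring in the first two axes.
#' @param radius ring radius (concentration units).
#' @param n_ring number of ring points.
#' @param margin minimal escape cost for a confirmed pit (absorbs
#'   direct-solve noise, default 0.002).
#' @param ... passed to \code{\link{quasipotential_at}} (path nodes,
#'   iterations, tolerance).
#' @return logical: is the candidate a confirmed trapping pit?
#' @export
confirm_local_min <- function(spec, center, fixed_axis = NULL,
                              radius = 0.25, n_ring = 8L, margin = 0.002,
                              ...) {
  d <- spec$dim
  center <- as.numeric(center)
  stopifnot(length(center) == d)
  if (is.character(fixed_axis)) fixed_axis <- match(fixed_axis, c("x", "y", "z"))
  free <- setdiff(seq_len(d), fixed_axis)[1:2]
  th <- seq(0, 2 * pi, length.out = n_ring + 1L)[-(n_ring + 1L)]
  ring <- matrix(rep(center, each = n_ring), nrow = n_ring)
  ring[, free[1]] <- ring[, free[1]] + radius * cos(th)
  ring[, free[2]] <- ring[, free[2]] + radius * sin(th)
  ring <- pmax(ring, spec_lb(spec))
  Sv <- quasipotential_at(spec, center, ring, ...)
  min(Sv) > margin
}

#' Evaluate a landscape along a trajectory
#'
#' Multilinear interpolation of S along integrated trajectory points, the
#' tool used to check the Lyapunov property (S non-increasing along
#' deterministic trajectories).
#'
#' @param grid a \code{landscape_grid}.
#' @param traj a trajectory tibble (\code{time, x, y, z}) or matrix of
#'   points.
#' @return numeric vector of interpolated S values (NA outside the grid or
#'   at missing cells).
#' @export
landscape_along <- function(grid, traj) {
  d <- length(grid$axes)
  m <- if (is.data.frame(traj)) as.matrix(traj[, names(grid$axes)]) else
    matrix(traj, ncol = d)
  interp_grid(grid, m)
}

#' Write / read a landscape grid as portable text
#'
#' The values go to a delimited long-format table (\code{<prefix>.tsv}), the
#' metadata (axes, attractor, Hamiltonian kind and parameters) to a JSON
#' sidecar (\code{<prefix>.json}).
#'
#' @param grid a \code{landscape_grid}.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_landscape <- function(grid, prefix) {
  df <- tidy.landscape_grid(grid)
  readr::write_tsv(df, paste0(prefix, ".tsv"))
  meta <- list(axes = grid$axes, attractor = grid$attractor,
               kind = grid$spec$kind, model = grid$spec$model,
               par = grid$spec$par, meta = grid$meta)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_landscape
#' @param spec optional \code{\link{ham_spec}} to attach on read (the sidecar
#'   stores kind/model/parameters for audit; cell-cycle grids rebuild their
#'   spec automatically).
#' @export
read_landscape <- function(prefix, spec = NULL) {
  df <- readr::read_tsv(paste0(prefix, ".tsv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  axes <- lapply(meta$axes, as.numeric)
  dims <- lengths(axes)
  vals <- array(df$S, dim = unname(dims))
  if (is.null(spec) && identical(meta$model, "cellcycle")) {
    p <- as.numeric(meta$par)
    names(p) <- cc_param_names()
    spec <- ham_spec(meta$kind, "cellcycle", do.call(cc_params, as.list(p)))
  }
  new_landscape_grid(vals, axes, matrix(unlist(meta$attractor),
                                        ncol = length(axes)),
                     spec, meta = meta$meta)
}
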