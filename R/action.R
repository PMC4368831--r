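#' Geometric (Maupertuis) action of a path
#'
#' Evaluates the time-free Freidlin-Wentzell action of a discretized curve.
#' Per chord the local cost is the support function of the zero-sublevel set
#' of the Hamiltonian,
#' \deqn{\ell(x, v) = \sup\{\, p \cdot v : H(x, p) \le 0 \,\}
#'                  = \inf_{\tau > 0} \tau\, L(x, v/\tau),}
#' evaluated at the segment midpoint; the path action is the sum over
#' segments.  The cost is 1-homogeneous in the chord, hence independent of
#' how the curve is parametrized in time; relaxation segments aligned with
#' the deterministic flow cost exactly zero.  For the separable jump-process
#' Hamiltonian the inner momentum maximization is closed-form per coordinate
#' and the scalar Maupertuis condition \eqn{H(x, p^*(v/\tau)) = 0} is solved
#' for \eqn{\tau}; for the extrinsic Hamiltonian the whole cost is the
#' closed form \eqn{|b||v| - b \cdot v}.
#'
#' @param path the curve: a matrix or data frame whose rows are nodes (at
#'   least 3), columns matching the model dimension (for the cell-cycle model
#'   a data frame with \code{x, y, z} also works).
#' @param spec a \code{\link{ham_spec}}.
#' @return the scalar action (nonnegative, dimensionless quasi-potential
#'   units).
#' @examples
#' H <- ham_spec("intrinsic", "bd1", c(1, 1))
#' path <- matrix(seq(1, 2, length.out = 101))
#' geometric_action(path, H)        # close to 2*log(2) - 1
#' @export
geometric_action <- function(path, spec) {
  m <- path_matrix(path, spec)
  if (nrow(m) < 2L) stop("path needs at least 2 nodes")
  res <- cpp_action(spec$kcode, spec$mcode, spec$par, m)
  if (!is.finite(res$action)) {
    bad <- which(!is.finite(res$tau))[1]
    stop("momentum solve divergence at path node ", bad)
  }
  res$action
}

path_matrix <- function(path, spec) {
  if (is.data.frame(path)) {
    cols <- intersect(c("x", "y", "z"), names(path))[seq_len(spec$dim)]
    m <- as.matrix(path[, cols])
  } else m <- as.matrix(path)
  if (ncol(m) != spec$dim)
    stop("path has ", ncol(m), " columns but the model dimension is ", spec$dim)
  storage.mode(m) <- "double"
  unname(m)
}

#' Minimize the geometric action between two points
#'
#' Curve-space minimization in the spirit of the geometric minimum action
#' method: the discretized path is relaxed by projected adaptive gradient
#' descent on the geometric action (analytic gradients via the envelope
#' theorem), interleaved with arc-length reparametrization so nodes stay
#' equally spaced; endpoints are pinned.  The action is non-increasing
#' across accepted iterations; convergence is declared when the relative
#' action change stays below \code{tol}.
#'
#' @param spec a \code{\link{ham_spec}}.
#' @param x_start start point (typically an attractor).
#' @param x_end end point.
#' @param n_nodes number of path nodes (default 100).
#' @param max_iter outer iteration cap; if reached without convergence the
#'   best path is returned flagged unconverged.
#' @param tol relative action-change tolerance.
#' @param init_path optional initial path (matrix of nodes); default is the
#'   straight line.
#' @return a \code{curve_path}: tibble of node coordinates with attributes
#'   \code{action}, \code{converged}, \code{iterations}, \code{spec}.
#' @export
minimize_action <- function(spec, x_start, x_end, n_nodes = 100L,
                            max_iter = 3000L, tol = 1e-8, init_path = NULL) {
  stopifnot(inherits(spec, "ham_spec"))
  x_start <- as.numeric(x_start); x_end <- as.numeric(x_end)
  stopifnot(length(x_start) == spec$dim, length(x_end) == spec$dim)
  if (is.null(init_path)) {
    tt <- seq(0, 1, length.out = n_nodes)
    init_path <- outer(1 - tt, x_start) + outer(tt, x_end)
  } else {
    init_path <- path_matrix(init_path, spec)
    n_nodes <- nrow(init_path)
  }
  if (sum((x_start - x_end)^2) < 1e-24) {
    out <- matrix(rep(x_start, each = n_nodes), nrow = n_nodes)
    return(new_curve_path(out, 0, TRUE, 0L, spec))
  }
  res <- cpp_minimize(spec$kcode, spec$mcode, spec$par, init_path,
                      as.integer(max_iter), tol, spec_lb(spec))
  new_curve_path(res$path, res$action, res$converged, res$iterations, spec)
}

new_curve_path <- function(m, action, converged, iterations, spec) {
  colnames(m) <- c("x", "y", "z")[seq_len(ncol(m))]
  df <- tibble::as_tibble(as.data.frame(m))
  structure(df, class = c("curve_path", class(df)),
            action = action, converged = converged,
            iterations = iterations, spec = spec)
}

#' @export
print.curve_path <- function(x, ...) {
  cat(sprintf("<curve_path> %d nodes, action = %.6g (%s)\n", nrow(x),
              attr(x, "action"),
              if (isTRUE(attr(x, "converged"))) "converged" else "NOT converged"))
  NextMethod()
}

#' @export
tidy.curve_path <- function(x, ...) {
  m <- as.matrix(as.data.frame(x))
  seg <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  dplyr::mutate(tibble::as_tibble(as.data.frame(m)),
                node = dplyr::row_number(),
                arclength = c(0, cumsum(seg)))
}

#' @export
glance.curve_path <- function(x, ...) {
  tibble::tibble(action = attr(x, "action"),
                 n_nodes = nrow(x),
                 converged = isTRUE(attr(x, "converged")),
                 iterations = attr(x, "iterations"))
}

#' Depth of the G1 basin
#'
#' The quasi-potential barrier protecting the G1 state: the minimized action
#' from the stable G1 fixed point P1 to the excited-G1 saddle P2 (the lowest
#' crossing of the basin boundary runs through the saddle).
#'
#' @param params a \code{\link{cc_params}} object.
#' @param kind noise kind, \code{"intrinsic"} or \code{"extrinsic"}.
#' @param n_nodes,max_iter,tol passed to \code{\link{minimize_action}}.
#' @return scalar well depth \eqn{\Delta S}; \code{NA} if P1 or P2 is not
#'   found.
#' @export
g1_well_depth <- function(params, kind = "intrinsic", n_nodes = 60L,
                          max_iter = 4000L, tol = 1e-9) {
  fp <- cc_fixed_points(params)
  p1 <- fp[fp$label == "P1", ]
  p2 <- fp[fp$label == "P2", ]
  if (nrow(p1) != 1L || nrow(p2) != 1L) return(NA_real_)
  spec <- ham_spec(kind, "cellcycle", params)
  pth <- minimize_action(spec, as.numeric(p1[, c("x", "y", "z")]),
                         as.numeric(p2[, c("x", "y", "z")]),
                         n_nodes = n_nodes, max_iter = max_iter, tol = tol)
  attr(pth, "action")
}
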