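#' Large-deviation Hamiltonian specifications
#'
#' A \code{ham_spec} bundles a noise model with a dynamical model so that the
#' action machinery can evaluate \eqn{H(x, p)} and its derivatives.
#'
#' Two noise kinds are supported.  For intrinsic (reaction-network) noise the
#' Hamiltonian of the Gillespie jump process is
#' \deqn{H(x, p) = \sum_j a_j(x) (e^{p \cdot \nu_j} - 1)}
#' with \eqn{a_j} the concentration-scale propensities.  For extrinsic
#' additive white noise, \eqn{\dot x = b(x) + \epsilon \dot w}, the
#' Hamiltonian is \eqn{H(x, p) = p \cdot b(x) + |p|^2 / 2}.  Both satisfy
#' \eqn{H(x, 0) = 0} and are convex in \eqn{p}.
#'
#' @param kind \code{"intrinsic"} (jump process) or \code{"extrinsic"}
#'   (additive white noise).
#' @param model model name: \code{"cellcycle"}, \code{"bd1"},
#'   \code{"quadwell"} (2-D quadratic single well, extrinsic only) or
#'   \code{"doublewell1"} (1-D symmetric double well, extrinsic only).
#' @param params model parameters: a \code{\link{cc_params}} for
#'   \code{"cellcycle"}; \code{c(c, k)} for \code{"bd1"}; \code{c(a1, a2, m1,
#'   m2)} for \code{"quadwell"} (potential \eqn{U = (a_1 (x-m_1)^2 + a_2
#'   (y-m_2)^2)/2}); ignored for \code{"doublewell1"}.
#' @return a \code{ham_spec} object.
#' @examples
#' H <- ham_spec("intrinsic", "cellcycle", cc_params())
#' ham(H, c(1, 1, 1), c(0, 0, 0))  # 0: H(x, 0) = 0
#' @export
ham_spec <- function(kind = c("intrinsic", "extrinsic"),
                     model = c("cellcycle", "bd1", "quadwell", "doublewell1"),
                     params = NULL) {
  kind <- match.arg(kind)
  model <- match.arg(model)
  mcode <- match(model, c("cellcycle", "bd1", "quadwell", "doublewell1"))
  kcode <- match(kind, c("intrinsic", "extrinsic"))
  if (kcode == 1L && !cpp_model_has_jump(mcode))
    stop("model '", model, "' has no jump-process representation; use kind = \"extrinsic\"")
  par <- switch(model,
    cellcycle = { stopifnot(inherits(params, "cc_params") || is.list(params))
                  cc_par_vec(params) },
    bd1       = { stopifnot(is.numeric(params), length(params) == 2L)
                  as.numeric(params) },
    quadwell  = { if (is.null(params)) params <- c(1, 2, 0, 0)
                  stopifnot(length(params) == 4L); as.numeric(params) },
    doublewell1 = numeric(0))
  structure(list(kind = kind, model = model, kcode = kcode, mcode = mcode,
                 par = par, dim = c(3L, 1L, 2L, 1L)[mcode],
                 params = params),
            class = "ham_spec")
}

#' Intrinsic-noise Hamiltonian of the cell-cycle network
#'
#' @param x a \code{\link{cc_params}} object or a \code{\link{cc_network}}.
#' @return a \code{ham_spec} of kind \code{"intrinsic"}.
#' @export
ham_intrinsic <- function(x) {
  if (inherits(x, "cc_network")) x <- x$params
  ham_spec("intrinsic", "cellcycle", x)
}

#' Extrinsic-noise Hamiltonian of the cell-cycle drift
#'
#' @param params a \code{\link{cc_params}} object.
#' @return a \code{ham_spec} of kind \code{"extrinsic"}.
#' @export
ham_extrinsic <- function(params) ham_spec("extrinsic", "cellcycle", params)

#' @export
print.ham_spec <- function(x, ...) {
  cat("<ham_spec>", x$kind, "noise,", x$model, "model, dim", x$dim, "\n")
  invisible(x)
}

#' Evaluate a Hamiltonian
#'
#' @param spec a \code{\link{ham_spec}}.
#' @param x state (length = model dimension).
#' @param p momentum (same length).  Momenta beyond \code{+/-35} per
#'   component are clipped to keep the exponentials finite.
#' @return scalar \eqn{H(x, p)}.
#' @export
ham <- function(spec, x, p) {
  stopifnot(inherits(spec, "ham_spec"),
            length(x) == spec$dim, length(p) == spec$dim)
  cpp_ham(spec$kcode, spec$mcode, spec$par, as.numeric(x), as.numeric(p))
}

#' Momentum gradient of a Hamiltonian
#'
#' \eqn{\partial H / \partial p}; at \eqn{p = 0} this equals the
#' deterministic drift \eqn{b(x)} for both noise kinds.
#'
#' @inheritParams ham
#' @return numeric vector of length = model dimension.
#' @export
ham_dp <- function(spec, x, p) {
  stopifnot(inherits(spec, "ham_spec"),
            length(x) == spec$dim, length(p) == spec$dim)
  cpp_ham_dp(spec$kcode, spec$mcode, spec$par, as.numeric(x), as.numeric(p))
}

# drift of the model underlying a ham_spec
spec_drift <- function(spec, x) cpp_drift(spec$mcode, spec$par, as.numeric(x))

# lower bound for path coordinates: concentrations live in the nonnegative
# orthant; the toy gradient systems are unconstrained
spec_lb <- function(spec) if (spec$model %in% c("quadwell", "doublewell1")) -Inf else 0
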