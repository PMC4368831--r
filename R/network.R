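#' Build the 12-channel volume-scaled reaction network
#'
#' Translates each additive term of the deterministic equations into a
#' chemical reaction channel at system size \code{V}.  Denoting molecule
#' counts \eqn{X = (X, Y, Z)}, the x-equation contributes four channels with
#' state-change vectors \eqn{\nu_1 = \nu_4 = [1,0,0]},
#' \eqn{\nu_2 = \nu_3 = [-1,0,0]} and propensities
#' \deqn{a_1 = V X^2 / ((j_1 V)^2 + X^2),\  a_2 = k_1 X,\  a_3 = X Y / V,\  a_4 = a_0 V.}
#' The y- and z-equations are translated by exact analogy (Hill births,
#' linear-degradation and bilinear-inhibition deaths, trigger births), giving
#' 12 channels in total.  With this \eqn{O(V)} scaling the concentration
#' process \eqn{X(t)/V} converges to the deterministic flow as
#' \eqn{V \to \infty}; for this network the mean-field identity
#' \eqn{\sum_j \nu_j a_j(Vx)/V = b(x)} is exact at every finite \code{V}.
#'
#' @param params a \code{\link{cc_params}} object.
#' @param V system size (volume); must be positive.
#' @return a \code{cc_network} object: a list with \code{channels} (a tibble
#'   with one row per channel: \code{channel, species, nu_x, nu_y, nu_z,
#'   rule, source_term}), \code{params} and \code{V}.
#' @examples
#' net <- cc_network(cc_params(), V = 100)
#' nrow(net$channels)  # 12
#' @export
cc_network <- function(params, V) {
  if (!is.numeric(V) || length(V) != 1L || V <= 0) stop("V must be positive")
  ch <- tibble::tibble(
    channel = 1:12,
    species = rep(c("X", "Y", "Z"), each = 4L),
    sign    = rep(c(1L, -1L, -1L, 1L), times = 3L),
    rule    = c("hill_x", "deg_x", "inhib_xy", "basal_a0",
                "hill_y", "deg_y", "inhib_yz", "trigger_ka1",
                "hill_z", "deg_z", "inhib_zx", "trigger_ka2"),
    source_term = c("eq-1a term 1", "eq-1a term 2", "eq-1a term 3", "eq-1a term 4",
                    "eq-1b term 1", "eq-1b term 2", "eq-1b term 3", "eq-1b term 4",
                    "eq-1c term 1", "eq-1c term 2", "eq-1c term 3", "eq-1c term 4"))
  sp <- match(ch$species, c("X", "Y", "Z"))
  ch$nu_x <- ifelse(sp == 1L, ch$sign, 0L)
  ch$nu_y <- ifelse(sp == 2L, ch$sign, 0L)
  ch$nu_z <- ifelse(sp == 3L, ch$sign, 0L)
  ch$sign <- NULL
  structure(list(channels = ch, params = params, V = V), class = "cc_network")
}

#' @export
print.cc_network <- function(x, ...) {
  cat("<cc_network> 12 channels, V =", x$V, "\n")
  print(x$channels)
  invisible(x)
}

#' Channel propensities at a count state
#'
#' Propensities are defined on real-valued concentration arguments, so the
#' same rules serve integer-count SSA states and the continuum Hamiltonian.
#'
#' @param network a \code{\link{cc_network}}.
#' @param counts numeric length-3 molecule counts \code{(X, Y, Z)} or a data
#'   frame with columns \code{X, Y, Z}.
#' @return a tibble: the channel table with a \code{propensity} column
#'   (1/time), one copy per input row.
#' @export
propensities <- function(network, counts) {
  stopifnot(inherits(network, "cc_network"))
  if (is.data.frame(counts)) m <- as.matrix(counts[, c("X", "Y", "Z")])
  else m <- matrix(as.numeric(counts), nrow = 1L)
  if (any(m < 0)) stop("counts must be nonnegative")
  par <- cc_par_vec(network$params)
  V <- network$V
  purrr::map_dfr(seq_len(nrow(m)), function(i) {
    X <- m[i, 1]; Y <- m[i, 2]; Z <- m[i, 3]
    x <- X / V; y <- Y / V; z <- Z / V
    a <- c(V * x^2 / (par[1]^2 + x^2), par[4] * X, X * Y / V, par[11] * V,
           V * y^2 / (par[2]^2 + y^2), par[5] * Y, Y * Z / V, par[9] * X,
           V * par[8] * z^2 / (par[3]^2 + z^2), par[6] * Z, par[7] * X * Z / V,
           par[10] * Y)
    dplyr::mutate(network$channels, X = X, Y = Y, Z = Z, propensity = a)
  })
}

#' Mean-field drift of the reaction network
#'
#' Computes \eqn{\sum_j \nu_j a_j(V x) / V} at a concentration state.  For
#' this network the propensity scaling makes the identity with the
#' deterministic drift exact (not merely asymptotic in \code{V}).
#'
#' @param network a \code{\link{cc_network}}.
#' @param state concentration state: numeric length-3 or data frame with
#'   \code{x, y, z}.
#' @return numeric length-3 drift vector (conc/time).
#' @export
mean_field_drift <- function(network, state) {
  s <- as.numeric(as_state_matrix(state))
  a <- propensities(network, s * network$V)
  nu <- as.matrix(a[, c("nu_x", "nu_y", "nu_z")])
  as.numeric(crossprod(nu, a$propensity)) / network$V
}

#' Serialize a network to a structured text description
#'
#' One line per channel: state-change vector, rule name and source term, for
#' audit alongside SSA output.
#'
#' @param network a \code{\link{cc_network}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_network <- function(network, path) {
  ch <- network$channels
  hdr <- c(sprintf("# cc_network V=%g", network$V),
           sprintf("# params: %s", format(network$params)))
  body <- sprintf("channel %2d  nu=[%2d,%2d,%2d]  rule=%-12s  %s",
                  ch$channel, ch$nu_x, ch$nu_y, ch$nu_z, ch$rule, ch$source_term)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' One-dimensional birth-death test network
#'
#' Constant birth at rate \code{c*V} and linear death \code{k*X}: the standard
#' analytically solvable jump process.  Its quasi-potential relative to the
#' fixed point \eqn{x^* = c/k} has the closed form
#' \deqn{S(x) = x \ln(k x / c) - x + c/k,}
#' used throughout as an independent oracle.
#'
#' @param c birth rate (conc/time).
#' @param k death rate constant (1/time).
#' @param V system size.
#' @return a \code{bd1_network} object.
#' @export
bd1_network <- function(c = 1, k = 1, V = 100) {
  stopifnot(c >= 0, k >= 0, V > 0)   # zero rates allowed: absorbing test systems
  structure(list(c = c, k = k, V = V), class = "bd1_network")
}

#' Analytic quasi-potential of the 1-D birth-death system
#'
#' @param x concentration value(s).
#' @param c,k birth/death rates.
#' @return \eqn{S(x) = x ln(kx/c) - x + c/k} (with \code{S(0) = c/k} by
#'   continuity).
#' @export
bd1_quasipotential <- function(x, c = 1, k = 1) {
  ifelse(x <= 0, c / k, x * log(k * x / c) - x + c / k)
}
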