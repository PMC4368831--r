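#' Cell-cycle model parameters
#'
#' Construct the rate/threshold constants of the three-node budding yeast
#' cell-cycle model.  The eleven parameters are the Hill half-saturation
#' constants \code{j1, j2, j3} (concentration units), degradation rates
#' \code{k1, k2, k3} (1/time), the inhibition strength \code{ki} of the late-M
#' regulator z on the G1/S regulator x (1/(conc time)), the synthesis scale
#' \code{ks} of z (conc/time at saturation), the trigger coupling rates
#' \code{ka1} (x activates y) and \code{ka2} (y activates z) (1/time), and the
#' basal nutrient-dependent production \code{a0} of x (conc/time).
#'
#' Scenario presets encode the signal-response experiments: the baseline
#' excitable regime (\code{a0 = 0.001}, \code{ka1 = ka2 = 0.001}), the
#' rich-nutrient limit-cycle regime (\code{a0 = 0.01}), and the DNA-replication
#' (S) and mitotic (M) checkpoints, modelled by reducing the corresponding
#' trigger rate to \code{1e-4}.
#'
#' @param scenario preset name: one of \code{"baseline"},
#'   \code{"rich_nutrient"}, \code{"s_checkpoint"}, \code{"m_checkpoint"}.
#' @param ... named parameter overrides applied on top of the preset,
#'   e.g. \code{cc_params(a0 = 0.005)}.
#' @return an object of class \code{cc_params}: a named list of the eleven
#'   strictly positive rate constants, with the scenario recorded as an
#'   attribute.
#' @examples
#' p <- cc_params()
#' p$a0
#' cc_params("rich_nutrient")$a0
#' @export
cc_params <- function(scenario = c("baseline", "rich_nutrient",
                                   "s_checkpoint", "m_checkpoint"), ...) {
  scenario <- match.arg(scenario)
  p <- list(j1 = 0.5, j2 = 0.5, j3 = 0.5,
            k1 = 0.2, k2 = 0.2, k3 = 0.2,
            ki = 5.0, ks = 1.0,
            ka1 = 0.001, ka2 = 0.001, a0 = 0.001)
  p <- switch(scenario,
    baseline      = p,
    rich_nutrient = { p$a0 <- 0.01; p },
    s_checkpoint  = { p$ka1 <- 1e-4; p },
    m_checkpoint  = { p$ka2 <- 1e-4; p })
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_cc_params(p)
  structure(p, class = "cc_params", scenario = scenario)
}

validate_cc_params <- function(p) {
  vals <- unlist(p[cc_param_names()])
  if (length(vals) != 11L || anyNA(vals) || any(!is.finite(vals)))
    stop("parameters must be eleven finite numbers")
  if (any(vals <= 0))
    stop("all model parameters must be strictly positive")
  invisible(p)
}

cc_param_names <- function() {
  c("j1", "j2", "j3", "k1", "k2", "k3", "ki", "ks", "ka1", "ka2", "a0")
}

# flat numeric vector in the order the compiled code expects
cc_par_vec <- function(p) {
  unlist(p[cc_param_names()], use.names = FALSE)
}

#' @export
print.cc_params <- function(x, ...) {
  cat("<cc_params> scenario:", attr(x, "scenario") %||% "custom", "\n")
  print(unlist(x[cc_param_names()]))
  invisible(x)
}

#' @export
format.cc_params <- function(x, ...) {
  paste0("cc_params(", paste(sprintf("%s=%g", cc_param_names(),
                                     unlist(x[cc_param_names()])), collapse = ", "), ")")
}

#' Read model parameters from a key = value configuration file
#'
#' Plain-text configuration: one \code{key = value} pair per line, \code{#}
#' comments allowed.  A \code{scenario} key selects a preset; all other keys
#' override individual parameters.
#'
#' @param path path to the configuration file.
#' @return a \code{cc_params} object.
#' @examples
#' cfg <- system.file("extdata", "rich_nutrient.cfg", package = "yeastscape")
#' read_params_config(cfg)
#' @export
read_params_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed configuration line")
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  scen <- if ("scenario" %in% keys) vals[keys == "scenario"][1L] else "baseline"
  ov <- as.list(as.numeric(vals[keys != "scenario"]))
  names(ov) <- keys[keys != "scenario"]
  do.call(cc_params, c(list(scenario = scen), ov))
}

#' @export
tidy.cc_params <- function(x, ...) {
  tibble::tibble(parameter = cc_param_names(),
                 value = unlist(x[cc_param_names()], use.names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
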