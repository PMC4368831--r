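#' Named signal-response scenarios
#'
#' Bundles a parameter preset with its expected dynamical regime and the
#' topological landscape features the scenario is known for: rich nutrients
#' (\code{a0} raised to 0.01) melt the G1 well into a limit-cycle ring;
#' activating the DNA-replication checkpoint (\code{ka1} lowered to 1e-4)
#' digs a pit into the flat canal near P3; the M-phase checkpoint
#' (\code{ka2} = 1e-4) does the same near P4.
#'
#' @param name one of \code{"baseline"}, \code{"rich_nutrient"},
#'   \code{"s_checkpoint"}, \code{"m_checkpoint"}.
#' @param ... parameter overrides forwarded to \code{\link{cc_params}}.
#' @return a \code{cc_scenario} object.
#' @export
cc_scenario <- function(name = c("baseline", "rich_nutrient",
                                 "s_checkpoint", "m_checkpoint"), ...) {
  name <- match.arg(name)
  params <- cc_params(name, ...)
  expected <- switch(name,
    baseline = list(regime = "excitable",
                    features = c("stable G1 global minimum", "flat canal")),
    rich_nutrient = list(regime = "limit_cycle",
                         features = c("no stable fixed point", "closed ring valley")),
    s_checkpoint = list(regime = "excitable",
                        features = c("local minimum near P3 on the z = 0 slice")),
    m_checkpoint = list(regime = "excitable",
                        features = c("local minimum near P4 on the x = 0 slice")))
  structure(list(name = name, params = params,
                 expected_regime = expected$regime,
                 expected_features = expected$features),
            class = "cc_scenario")
}

#' @export
print.cc_scenario <- function(x, ...) {
  cat("<cc_scenario>", x$name, "- expected regime:", x$expected_regime, "\n")
  invisible(x)
}

#' Confirm a candidate landscape pit of the cell-cycle model
#'
#' A pit that can arrest the cycle is a trapping state: a nearby stable
#' fixed point with a positive escape barrier in every direction.  The
#' candidate is relaxed along the deterministic flow and Newton-polished;
#' if no stable fixed point lies within \code{max_dist} of the candidate
#' the pit is rejected outright (flat-canal points relax away downstream).
#' Otherwise the escape barrier from the attractor is measured with
#' \code{\link{confirm_local_min}}.
#'
#' @param params a \code{\link{cc_params}} object.
#' @param center candidate location (length 3).
#' @param fixed_axis slice axis held fixed for the escape ring
#'   (\code{"z"} for the S-phase corner, \code{"x"} for the M-phase corner).
#' @param max_dist maximal distance between candidate and its attractor.
#' @param ... passed to \code{\link{confirm_local_min}}.
#' @return logical.
#' @export
confirm_pit <- function(params, center, fixed_axis = "z", max_dist = 0.35,
                        ...) {
  center <- as.numeric(center)
  tr <- cc_integrate(center, params, 400, dt_out = 4)
  endp <- as.numeric(tr[nrow(tr), c("x", "y", "z")])
  par <- cc_par_vec(params)
  r <- newton_root(endp, par)
  if (is.null(r)) return(FALSE)
  if (sqrt(sum((r - center)^2)) > max_dist) return(FALSE)
  ev <- eigen(cpp_jac(1L, par, r), only.values = TRUE)$values
  if (!all(Re(ev) < 0)) return(FALSE)
  confirm_local_min(ham_intrinsic(params), r, fixed_axis = fixed_axis, ...)
}

#' Run a scenario analysis plan
#'
#' Executes the requested computations for a scenario and checks its
#' expected features.  Sub-analysis failures are recorded in the report and
#' the remaining steps continue.
#'
#' @param scenario a \code{\link{cc_scenario}} (or preset name).
#' @param plan character vector of analyses: any of \code{"fixed_points"},
#'   \code{"regime"}, \code{"landscape"} (the checkpoint-relevant planar
#'   slice of the quasi-potential).
#' @param slice_n nodes per axis for the planar landscape.
#' @param pit_radius proximity (concentration units) within which a pit must
#'   lie to count as near its vertex.
#' @param n_path_nodes,max_iter,tol landscape minimizer settings.
#' @return a \code{scenario_report}: list with \code{scenario},
#'   \code{regime}, \code{fixed_points}, \code{slices} (named list of planar
#'   \code{landscape_grid}s), \code{features} (tibble: feature, pass),
#'   \code{errors}.
#' @export
run_scenario <- function(scenario, plan = c("fixed_points", "regime"),
                         slice_n = 61L, pit_radius = 0.5,
                         n_path_nodes = 16L, max_iter = 150L, tol = 1e-7) {
  if (is.character(scenario)) scenario <- cc_scenario(scenario)
  stopifnot(inherits(scenario, "cc_scenario"))
  params <- scenario$params
  errors <- character(0)
  fp <- NULL; regime <- NA_character_; slices <- list()
  if ("fixed_points" %in% plan || "regime" %in% plan || "landscape" %in% plan) {
    fp <- tryCatch(cc_fixed_points(params),
                   error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  }
  if ("regime" %in% plan) {
    regime <- tryCatch(classify_regime(params),
                       error = function(e) { errors <<- c(errors, conditionMessage(e)); NA_character_ })
  }
  if ("landscape" %in% plan) {
    slices <- tryCatch(scenario_slices(scenario, fp, slice_n = slice_n,
                                       n_path_nodes = n_path_nodes,
                                       max_iter = max_iter, tol = tol),
                       error = function(e) { errors <<- c(errors, conditionMessage(e)); list() })
  }
  features <- scenario_features(scenario, fp, regime, slices, pit_radius)
  structure(list(scenario = scenario, regime = regime, fixed_points = fp,
                 slices = slices, features = features, errors = errors),
            class = "scenario_report")
}

# planar quasi-potential slice relevant for the scenario, computed in-plane
# with full-3D paths from P1
scenario_slices <- function(scenario, fp, slice_n, n_path_nodes, max_iter, tol) {
  params <- scenario$params
  spec <- ham_intrinsic(params)
  p1 <- fp[fp$label == "P1", ]
  if (is.null(fp) || nrow(p1) != 1L) stop("landscape plan needs the stable G1 state")
  attract <- as.numeric(p1[, c("x", "y", "z")])
  which_plane <- if (scenario$name == "m_checkpoint") "x" else "z"
  axes <- list(x = seq(0, 6, length.out = slice_n),
               y = seq(0, 6, length.out = slice_n),
               z = seq(0, 6, length.out = slice_n))
  axes[[which_plane]] <- 0
  skel <- tryCatch(cc_skeleton(params), error = function(e) NULL)
  g <- quasipotential_grid(spec, attract, axes = axes,
                           n_path_nodes = n_path_nodes,
                           max_iter = max_iter, tol = tol, skeleton = skel)
  setNames(list(g), paste0(which_plane, "0"))
}

scenario_features <- function(scenario, fp, regime, slices, pit_radius) {
  rows <- list()
  add <- function(feature, pass)
    rows[[length(rows) + 1L]] <<- tibble::tibble(feature = feature, pass = pass)
  if (!is.na(regime))
    add(paste0("regime = ", scenario$expected_regime),
        identical(regime, scenario$expected_regime))
  if (!is.null(fp)) {
    has_g1 <- any(fp$label == "P1")
    if (scenario$name == "rich_nutrient") add("no stable fixed point",
                                              !any(fp$stability == "stable"))
    else add("stable G1 state present", has_g1)
  }
  if (length(slices)) {
    vtx <- cc_vertices(scenario$params)
    target <- if (scenario$name == "m_checkpoint") "P4" else "P3"
    vt <- vtx[vtx$label == target, ]
    sl <- slices[[1L]]
    pits <- slice_local_minima(sl)
    free <- names(pits)[1:2]
    near <- if (nrow(pits)) sqrt((pits[[free[1]]] - vt[[free[1]]])^2 +
                                 (pits[[free[2]]] - vt[[free[2]]])^2) else numeric(0)
    cand <- which(near <= pit_radius)
    # candidates: grid minima near the vertex, plus the vertex itself (the
    # landscape floor is flat, so a trapping cul-de-sac need not produce a
    # strict grid minimum).  A pit is confirmed as a trapping state: a
    # nearby stable fixed point with a positive escape barrier.
    fixed <- if (scenario$name == "m_checkpoint") "x" else "z"
    centres <- list(as.numeric(vt[, c("x", "y", "z")]))
    for (i in cand) {
      centre <- c(x = 0, y = 0, z = 0)
      centre[free] <- c(pits[[free[1]]][i], pits[[free[2]]][i])
      centres[[length(centres) + 1L]] <- centre
    }
    hit <- FALSE
    for (centre in centres) {
      ok <- tryCatch(confirm_pit(scenario$params, centre, fixed_axis = fixed,
                                 n_path_nodes = 24L, max_iter = 1000L,
                                 tol = 1e-9),
                     error = function(e) FALSE)
      if (ok) { hit <- TRUE; break }
    }
    if (scenario$name %in% c("s_checkpoint", "m_checkpoint"))
      add(paste("pit near", target), hit)
    else add(paste("no pit near", target), !hit)
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(feature = character(), pass = logical())
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report>", x$scenario$name, "- regime:", x$regime, "\n")
  if (!is.null(x$fixed_points))
    cat("  fixed points:", nrow(x$fixed_points),
        sprintf("(%d stable)\n", sum(x$fixed_points$stability == "stable")))
  if (nrow(x$features)) {
    for (i in seq_len(nrow(x$features)))
      cat(sprintf("  [%s] %s\n", if (x$features$pass[i]) "ok" else "FAIL",
                  x$features$feature[i]))
  }
  if (length(x$errors)) cat("  errors:", paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}

#' Compare two scenario reports
#'
#' Per-feature difference summary: regime change, stable fixed points
#' gained or lost, and pits (slice local minima) added or removed on
#' matching slices.
#'
#' @param report_a,report_b \code{\link{run_scenario}} results.
#' @param match_radius two pits are the same feature when within this
#'   distance.
#' @return a tibble \code{aspect, change}; empty when the reports agree.
#' @export
compare_scenarios <- function(report_a, report_b, match_radius = 0.3) {
  stopifnot(inherits(report_a, "scenario_report"),
            inherits(report_b, "scenario_report"))
  out <- list()
  add <- function(aspect, change)
    out[[length(out) + 1L]] <<- tibble::tibble(aspect = aspect, change = change)
  if (!identical(report_a$regime, report_b$regime))
    add("regime", paste(report_a$regime, "->", report_b$regime))
  na <- if (!is.null(report_a$fixed_points)) sum(report_a$fixed_points$stability == "stable") else NA
  nb <- if (!is.null(report_b$fixed_points)) sum(report_b$fixed_points$stability == "stable") else NA
  if (!identical(na, nb))
    add("stable fixed points", paste(na, "->", nb))
  common <- intersect(names(report_a$slices), names(report_b$slices))
  for (nm in common) {
    sa <- report_a$slices[[nm]]; sb <- report_b$slices[[nm]]
    if (!isTRUE(all.equal(sa$axes, sb$axes))) stop("incompatible grid specs for slice ", nm)
    pa <- slice_local_minima(sa); pb <- slice_local_minima(sb)
    unmatched <- function(p, q) {
      if (!nrow(p)) return(p)
      if (!nrow(q)) return(p)
      keep <- vapply(seq_len(nrow(p)), function(i) {
        dd <- sqrt((q[[1]] - p[[1]][i])^2 + (q[[2]] - p[[2]][i])^2)
        all(dd > match_radius)
      }, logical(1))
      p[keep, ]
    }
    gained <- unmatched(pb, pa); lost <- unmatched(pa, pb)
    if (nrow(gained)) add(paste0("slice ", nm),
                          paste0("local minimum added at (",
                                 paste(sprintf("%.2f", unlist(gained[1, 1:2])), collapse = ", "), ")"))
    if (nrow(lost)) add(paste0("slice ", nm),
                        paste0("local minimum removed at (",
                               paste(sprintf("%.2f", unlist(lost[1, 1:2])), collapse = ", "), ")"))
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(aspect = character(), change = character())
}

#' Serialize a scenario report to structured text
#'
#' Writes the regime, fixed-point table and feature checks as a plain-text
#' report; landscape slices are written next to it (via
#' \code{\link{write_landscape}}) and referenced by path, not inlined.
#'
#' @param report a \code{scenario_report}.
#' @param path output file path (slices use the same stem).
#' @return the path, invisibly.
#' @export
write_scenario_report <- function(report, path) {
  stem <- sub("\\.[^.]*$", "", path)
  lines <- c(paste("scenario:", report$scenario$name),
             paste("regime:", report$regime))
  if (!is.null(report$fixed_points)) {
    fp <- report$fixed_points
    lines <- c(lines, "fixed_points:",
               sprintf("  %-6s (%.6f, %.6f, %.6f) %s", fp$label, fp$x, fp$y,
                       fp$z, fp$stability))
  }
  if (nrow(report$features))
    lines <- c(lines, "features:",
               sprintf("  [%s] %s", ifelse(report$features$pass, "ok", "FAIL"),
                       report$features$feature))
  for (nm in names(report$slices)) {
    pfx <- paste0(stem, "_slice_", nm)
    write_landscape(report$slices[[nm]], pfx)
    lines <- c(lines, paste0("slice ", nm, ": ", pfx, ".tsv"))
  }
  writeLines(lines, path)
  invisible(path)
}
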