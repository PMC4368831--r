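#' Write a trajectory as a delimited text table
#'
#' Columns \code{t, x, y, z}, tab separated.
#'
#' @param traj a trajectory tibble from \code{\link{cc_integrate}} or a
#'   concentration-scaled SSA trajectory.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- tibble::as_tibble(traj)
  if ("time" %in% names(df)) names(df)[names(df) == "time"] <- "t"
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write fixed points as structured text records
#'
#' One record per fixed point: location, eigenvalue real parts, stability
#' class and label.
#'
#' @param fp tibble from \code{\link{cc_fixed_points}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_fixed_points <- function(fp, path) {
  lines <- unlist(lapply(seq_len(nrow(fp)), function(i) c(
    sprintf("[fixed_point %d]", i),
    sprintf("label = %s", fp$label[i]),
    sprintf("location = %.10g %.10g %.10g", fp$x[i], fp$y[i], fp$z[i]),
    sprintf("re_eigenvalues = %.6g %.6g %.6g", fp$re1[i], fp$re2[i], fp$re3[i]),
    sprintf("stability = %s", fp$stability[i]),
    sprintf("drift_norm = %.3g", fp$drift_norm[i]),
    "")))
  writeLines(lines, path)
  invisible(path)
}
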