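#' Export run artifacts to a directory
#'
#' Writes `release.csv` (`time_days,cumulative_fraction`, 9 significant
#' digits; re-reading reproduces the curve bit-exactly), `config.yaml`
#' (the fully resolved configuration, for provenance), `run.log` (per-step
#' released fraction, mass-balance residual, solver iterations),
#' `summary.json`, and, when field snapshots were kept, one legacy-VTK file
#' per step with the nodal concentration fields.
#'
#' @param run A `release_run` from [run_simulation()].
#' @param dir Output directory (created if missing; must be writable).
#' @return `dir`, invisibly.
#' @export
export_results <- function(run, dir) {
  stopifnot(inherits(run, "release_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2L) != 0L) stop("output directory is not writable: ", dir)

  write_release_csv(run$curve, file.path(dir, "release.csv"))
  yaml::write_yaml(run$config, file.path(dir, "config.yaml"))

  con <- file(file.path(dir, "run.log"), "wb")
  writeLines(sprintf("# %s model, %d DOFs, initial mass %.9g (conc*um^3)",
                     run$model, run$n_dof, run$initial_mass), con)
  writeLines("step\ttime_days\tD_fiber\treleased_fraction\tmass_residual\titerations", con)
  if (!is.null(run$log)) {
    writeLines(sprintf("%d\t%g\t%.9g\t%.9g\t%.3e\t%d",
                       run$log$step, run$log$time_days, run$log$D_fiber,
                       run$log$released_fraction, run$log$mass_residual,
                       run$log$iterations), con)
  }
  close(con)

  jsonlite::write_json(
    list(model = run$model, n_dof = run$n_dof,
         initial_mass = run$initial_mass,
         terminal_release_fraction =
           utils::tail(run$curve$cumulative_fraction, 1),
         max_mass_residual = if (is.null(run$log)) 0
                             else max(run$log$mass_residual)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)

  if (run$model == "detailed" && !is.null(run$built$points)) {
    lay <- run$layout
    pts <- run$built$points
    axis_dof <- lay$chain_offset + 1L
    chains <- data.frame(
      point_id = seq_len(nrow(pts)), R = pts$radius, Lbar = pts$Lbar,
      surface_node = run$built$mapping,
      final_axis_concentration = run$final_state[axis_dof])
    utils::write.csv(chains, file.path(dir, "chains.csv"), row.names = FALSE)
  }

  if (!is.null(run$fields)) {
    imm_mask <- integer(run$mesh$n_nodes)
    imm_mask[run$built$immersed] <- 1L
    for (i in seq_along(run$fields)) {
      write_vtk_structured(
        file.path(dir, sprintf("fields_step%03d.vtk", i)), run$mesh,
        scalars = run$fields[[i]],
        int_scalars = list(immersed = imm_mask))
    }
  }
  invisible(dir)
}

#' Write a release curve as CSV
#' @param curve Data frame `time_days`, `cumulative_fraction`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(curve, path) {
  con <- file(path, "wb")
  writeLines("time_days,cumulative_fraction", con)
  writeLines(sprintf("%.9g,%.9g", curve$time_days,
                     curve$cumulative_fraction), con)
  close(con)
  invisible(path)
}

#' Read a release curve written by [write_release_csv()]
#' @param path CSV path.
#' @return Data frame `time_days`, `cumulative_fraction`.
#' @export
read_release_csv <- function(path) {
  utils::read.csv(path, colClasses = c("numeric", "numeric"))
}

#' Write nodal scalar fields as a legacy-VTK structured-points file
#'
#' ASCII `STRUCTURED_POINTS` dataset with one `POINT_DATA` scalar array per
#' field, readable by ParaView/VisIt.
#'
#' @param path Output `.vtk` path.
#' @param mesh A [hex_mesh()].
#' @param scalars Named list of numeric per-node vectors.
#' @param int_scalars Named list of integer per-node vectors (masks).
#' @return `path`, invisibly.
#' @export
write_vtk_structured <- function(path, mesh, scalars = list(),
                                 int_scalars = list()) {
  stopifnot(inherits(mesh, "hex_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "fibrelease nodal fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", mesh$nn[1], mesh$nn[2], mesh$nn[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.9g %.9g %.9g", mesh$h[1], mesh$h[2], mesh$h[3]),
               sprintf("POINT_DATA %d", mesh$n_nodes)), con)
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default",
                 sprintf("%.9g", scalars[[nm]])), con)
  }
  for (nm in names(int_scalars)) {
    writeLines(c(sprintf("SCALARS %s int 1", nm),
                 "LOOKUP_TABLE default",
                 sprintf("%d", int_scalars[[nm]])), con)
  }
  invisible(path)
}
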