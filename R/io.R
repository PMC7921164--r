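#' Write a trajectory solution to a run directory
#'
#' One trajectory table (CSV, long format: `kind, name, time, value`, one
#' row per quantity and segment node), one per-segment objective table, and
#' a JSON manifest recording seeds, the regularization pair, discretization,
#' acceptance and the file paths — so every run is self-describing.
#'
#' @param solution an `adapt_solution`.
#' @param dir output directory (created if needed).
#' @param name file stem (default "solution").
#' @param config optional `run_config` archived into the manifest.
#' @return the manifest path, invisibly.
#' @export
write_solution <- function(solution, dir, name = "solution", config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traj_path <- file.path(dir, paste0(name, "_trajectories.csv"))
  obj_path <- file.path(dir, paste0(name, "_objective.csv"))
  readr::write_csv(tidy(solution), traj_path)
  readr::write_csv(solution$objective, obj_path)
  manifest <- list(
    name = name,
    lambda_g1 = solution$lambda[1], lambda_g2 = solution$lambda[2],
    n_t = solution$n_t, t_end = solution$t_end,
    seed = solution$seed, sample_index = solution$sample_index,
    accepted = solution$accepted,
    n_flagged = sum(solution$objective$flagged),
    measured = as.list(solution$measured),
    files = list(trajectories = basename(traj_path),
                 objective = basename(obj_path)))
  if (!is.null(config)) manifest$config <- unclass(config)[
    !vapply(unclass(config), is.null, TRUE)]
  man_path <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man_path)
}

#' Read back a trajectory table
#'
#' @param path CSV written by [write_solution()] or [write_ensemble()].
#' @return tibble `kind, name, time, value`.
#' @export
read_trajectory_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(kind = readr::col_character(),
                                          name = readr::col_character(),
                                          time = readr::col_double(),
                                          value = readr::col_double()))
}

#' Write a solution ensemble to a run directory
#'
#' A manifest (JSON) plus the runs table (CSV), per-solution trajectory
#' tables, robust summary tables for the requested quantities and, when a
#' reference group is supplied, a variance-reduction matrix
#' (quantity x time).
#'
#' @param ensemble a `solution_ensemble`.
#' @param dir output directory.
#' @param quantities quantity names to summarize (default: all parameters
#'   and states of the first solution).
#' @param reference optional `solution_ensemble` used as the
#'   variance-reduction reference (e.g. the unregularized group G0).
#' @param config optional `run_config` archived into the manifest.
#' @return the manifest path, invisibly.
#' @export
write_ensemble <- function(ensemble, dir, quantities = NULL, reference = NULL,
                           config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(ensemble$runs, file.path(dir, "runs.csv"))
  sol_files <- character(0)
  for (r in seq_along(ensemble$solutions)) {
    sol <- ensemble$solutions[[r]]
    if (is.null(sol)) next
    f <- sprintf("run%04d_trajectories.csv", ensemble$runs$run[r])
    readr::write_csv(tidy(sol), file.path(dir, f))
    sol_files <- c(sol_files, f)
  }
  first <- ensemble$solutions[[which(!vapply(ensemble$solutions, is.null, TRUE))[1]]]
  if (is.null(quantities)) {
    quantities <- c(rownames(first$parameters), rownames(first$states))
  }
  summ <- dplyr::bind_rows(lapply(quantities, function(q) {
    dplyr::mutate(ensemble_summary(ensemble, q), quantity = q, .before = 1)
  }))
  readr::write_csv(summ, file.path(dir, "summary.csv"))
  vr_file <- NULL
  if (!is.null(reference)) {
    vr <- dplyr::bind_rows(lapply(quantities, function(q) {
      dplyr::mutate(variance_reduction(ensemble, reference, q),
                    quantity = q, .before = 1)
    }))
    vr_file <- "variance_reduction.csv"
    readr::write_csv(vr, file.path(dir, vr_file))
  }
  manifest <- list(seed = ensemble$seed, n_runs = nrow(ensemble$runs),
                   n_accepted = sum(ensemble$runs$accepted),
                   lambda_range = ensemble$lambda_range,
                   p_zero = ensemble$p_zero,
                   files = list(runs = "runs.csv", summary = "summary.csv",
                                variance_reduction = vr_file,
                                solutions = as.list(sol_files)))
  if (!is.null(config)) manifest$config <- unclass(config)[
    !vapply(unclass(config), is.null, TRUE)]
  man_path <- file.path(dir, "ensemble_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man_path)
}

#' Write a scenario's synthetic data bundle to a directory
#'
#' Model spec (JSON), metabolic and transcript datasets (CSV), coupling map
#' (CSV), dense truth tables (CSV) and a scenario manifest (JSON): a
#' complete, download-free input for the whole pipeline.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory.
#' @param seed integer seed for the observation noise.
#' @param n_t,refine truth resolution, see [generate_truth()].
#' @return the manifest path, invisibly.
#' @export
write_scenario <- function(scenario, dir, seed, n_t = 50L, refine = 10L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- scenario_data(scenario, seed, n_t = n_t, refine = refine)
  write_model_json(scenario$model, file.path(dir, "model.json"))
  write_longitudinal_csv(bundle$metabolic, file.path(dir, "metabolic.csv"))
  files <- list(model = "model.json", metabolic = "metabolic.csv")
  if (!is.null(bundle$transcript)) {
    write_longitudinal_csv(bundle$transcript, file.path(dir, "transcript.csv"))
    write_coupling_csv(bundle$coupling, file.path(dir, "coupling.csv"))
    files$transcript <- "transcript.csv"
    files$coupling <- "coupling.csv"
  }
  truth <- bundle$truth
  kinds <- c(parameters = "parameter", states = "state",
             fluxes = "flux", outputs = "output")
  truth_tbl <- dplyr::bind_rows(lapply(names(kinds), function(slot) {
    tibble::as_tibble(t(truth[[slot]])) |>
      dplyr::mutate(time = truth$times, kind = kinds[[slot]]) |>
      tidyr::pivot_longer(-c("time", "kind"), names_to = "name",
                          values_to = "value")
  }))
  readr::write_csv(truth_tbl[c("kind", "name", "time", "value")],
                   file.path(dir, "truth.csv"))
  files$truth <- "truth.csv"
  manifest <- list(scenario = scenario$name, seed = seed,
                   schedule = scenario$schedule, cv = scenario$cv,
                   replicates = scenario$replicates, t_end = scenario$t_end,
                   files = files)
  man_path <- file.path(dir, "scenario_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man_path)
}
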