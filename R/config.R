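#' Run configuration
#'
#' Assembles and validates the full configuration of a reproducible run:
#' file paths, discretization, multistart settings, spline ensemble size,
#' regularization sampling, solver tolerances, seeds and output location.
#' Defaults follow the method's printed settings (200 time segments,
#' 2e5 scatter samples with 10% preselection, termination tolerances 1e-10,
#' at most 1e3 iterations and 1e5 evaluations, integration tolerances 1e-6).
#' The effective configuration is archived into every run manifest so runs
#' are self-describing.
#'
#' @param ... fields overriding the defaults (see Details in the vignette);
#'   unknown fields are rejected.
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    model_file = NULL, data_file = NULL, coupling_file = NULL,
    n_t = 200L, t_end = 21,
    n_scatter = 2e5, keep_fraction = 0.1,
    n_samples = 100L, q = 1,
    lambda = NULL,              # fixed (lambda_g1, lambda_g2) pair, or NULL
    lambda_range = c(1e-12, 1), # log-uniform scan range
    p_zero = 0.25, n_runs = 100L,
    rel_tol = 1e-10, x_tol = 1e-10, iter_max = 1000L, eval_max = 100000L,
    atol = 1e-6, rtol = 1e-6,
    seed = 1L, out_dir = "adapt-run", workers = 1L)
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown config field(s): ", toString(unknown))
  cfg <- modifyList(defaults, over, keep.null = TRUE)
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(cfg$n_t) && cfg$n_t >= 1, "n_t must be >= 1")
  chk(is.numeric(cfg$t_end) && cfg$t_end > 0, "t_end must be > 0")
  chk(is.numeric(cfg$n_scatter) && cfg$n_scatter >= 1, "n_scatter must be >= 1")
  chk(is.numeric(cfg$keep_fraction) && cfg$keep_fraction > 0 &&
        cfg$keep_fraction <= 1, "keep_fraction must be in (0, 1]")
  chk(is.numeric(cfg$n_samples) && cfg$n_samples >= 1, "n_samples must be >= 1")
  chk(is.numeric(cfg$q) && cfg$q >= 0 && cfg$q <= 1, "q must be in [0, 1]")
  chk(is.null(cfg$lambda) ||
        (is.numeric(cfg$lambda) && length(cfg$lambda) == 2 && all(cfg$lambda >= 0)),
      "lambda must be NULL or two nonnegative numbers")
  chk(is.numeric(cfg$lambda_range) && length(cfg$lambda_range) == 2 &&
        all(cfg$lambda_range > 0) && cfg$lambda_range[1] <= cfg$lambda_range[2],
      "lambda_range must be an increasing positive pair")
  chk(is.numeric(cfg$p_zero) && cfg$p_zero >= 0 && cfg$p_zero <= 1,
      "p_zero must be in [0, 1]")
  chk(is.numeric(cfg$n_runs) && cfg$n_runs >= 1, "n_runs must be >= 1")
  for (f in c("rel_tol", "x_tol", "atol", "rtol")) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] > 0, paste(f, "must be > 0"))
  }
  chk(is.numeric(cfg$iter_max) && cfg$iter_max >= 1, "iter_max must be >= 1")
  chk(is.numeric(cfg$eval_max) && cfg$eval_max >= 1, "eval_max must be >= 1")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be one integer")
  chk(is.numeric(cfg$workers) && cfg$workers >= 1, "workers must be >= 1")
  for (f in c("model_file", "data_file", "coupling_file")) {
    if (!is.null(cfg[[f]])) {
      chk(file.exists(cfg[[f]]), paste0(f, " does not exist: ", cfg[[f]]))
    }
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (JSON)
#'
#' Parse then serialize then parse is the identity; command-line flags are
#' applied on top of file values before validation.
#'
#' @param path JSON file path.
#' @param overrides named list applied over the file's values.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$lambda)) cfg$lambda <- as.numeric(cfg$lambda)
  if (!is.null(cfg$lambda_range)) cfg$lambda_range <- as.numeric(cfg$lambda_range)
  cfg <- modifyList(cfg, overrides, keep.null = TRUE)
  run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, TRUE)]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# nlminb control sub-list of a config
.cfg_control <- function(cfg) {
  list(iter.max = as.integer(cfg$iter_max), eval.max = as.integer(cfg$eval_max),
       rel.tol = cfg$rel_tol, x.tol = cfg$x_tol)
}
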