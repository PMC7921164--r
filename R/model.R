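#' Declare a mass-action flux
#'
#' A mass-action flux has rate `coef * p * x_a * x_b * ...` where `p` is a
#' model parameter (optional for fluxes with a fixed, literature-derived rate
#' constant) and the substrates are model states, repeated for higher orders.
#' Zeroth-order (constant source) fluxes have no substrates.
#'
#' @param name flux identifier.
#' @param parameter name of the rate parameter, or `NULL` for a fixed-rate flux.
#' @param substrates character vector of substrate state names (may be empty).
#' @param coef fixed multiplicative constant (default 1).
#' @return a flux specification list.
#' @export
flux_mass_action <- function(name, parameter = NULL, substrates = character(), coef = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  list(name = name, kind = "mass_action", parameter = parameter,
       substrates = as.character(substrates), coef = as.numeric(coef))
}

#' Declare a flux by an arbitrary closed-form expression
#'
#' Escape hatch for rate laws beyond mass action. The expression may reference
#' states, parameters, external inputs and `t`.
#'
#' @param name flux identifier.
#' @param expression rate law as a string, e.g. `"vmax * s / (km + s)"`.
#' @return a flux specification list.
#' @export
flux_expression <- function(name, expression) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(expression), length(expression) == 1L)
  list(name = name, kind = "expression", expression = expression)
}

#' Construct a metabolic state-space model
#'
#' Represents the system `dx/dt = N f(x, p, u)`, `y = g(x, f, p, u)`: states
#' `x`, stoichiometric matrix `N`, flux rate laws `f`, kinetic parameters `p`
#' with bounds, optional external inputs `u`, and an output map `g` to the
#' experimentally observable quantities.
#'
#' @param states character vector of state names.
#' @param parameters data frame with columns `name`, `lower`, `upper` and
#'   optionally `guess` (baseline initial guess). Lower bounds must be >= 0:
#'   rate constants are nonnegative.
#' @param stoichiometry numeric matrix, `length(states)` rows by one column per
#'   flux (integer entries).
#' @param fluxes list of flux specifications, see [flux_mass_action()] and
#'   [flux_expression()].
#' @param outputs named character vector mapping output names to expressions
#'   over states, fluxes and parameters.
#' @param x0 optional named baseline state vector; if omitted the baseline is
#'   obtained from [steady_state()].
#' @param inputs named list of external inputs: constants or functions of time.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(states, parameters, stoichiometry, fluxes, outputs,
                            x0 = NULL, inputs = list()) {
  states <- as.character(states)
  parameters <- tibble::as_tibble(parameters)
  stopifnot(all(c("name", "lower", "upper") %in% names(parameters)))
  if (!"guess" %in% names(parameters)) {
    parameters$guess <- sqrt(pmax(parameters$lower, 1e-6) * pmin(parameters$upper, 1e6))
  }
  if (any(parameters$lower < 0)) {
    stop("all parameter lower bounds must be >= 0 (rate constants are nonnegative)")
  }
  if (any(parameters$lower > parameters$upper)) stop("parameter lower bound exceeds upper bound")
  stoichiometry <- as.matrix(stoichiometry)
  if (nrow(stoichiometry) != length(states)) {
    stop("stoichiometry must have one row per state (", length(states), " states, ",
         nrow(stoichiometry), " rows)")
  }
  if (ncol(stoichiometry) != length(fluxes)) {
    stop("stoichiometry must have one column per flux")
  }
  flux_names <- vapply(fluxes, `[[`, "", "name")
  if (anyDuplicated(flux_names)) stop("duplicate flux names")
  if (anyDuplicated(states)) stop("duplicate state names")
  if (anyDuplicated(parameters$name)) stop("duplicate parameter names")
  dimnames(stoichiometry) <- list(states, flux_names)

  if (is.list(outputs) && !is.null(names(outputs))) {
    outputs <- unlist(outputs)
  }
  stopifnot(is.character(outputs), !is.null(names(outputs)))

  model <- structure(
    list(states = states, parameters = parameters,
         stoichiometry = stoichiometry, fluxes = fluxes, outputs = outputs,
         x0 = x0, inputs = inputs),
    class = "metabolic_model")
  .validate_model_symbols(model)
  # cache parsed expressions: parsing at evaluation time dominates the cost
  # of the inner estimation loop otherwise
  model$flux_expr <- lapply(fluxes, function(f) {
    if (f$kind == "expression") parse(text = f$expression)[[1]] else NULL
  })
  model$output_expr <- lapply(model$outputs, function(e) parse(text = e)[[1]])
  model
}

# every symbol in a flux or output expression must be declared
.validate_model_symbols <- function(model) {
  known_flux <- c(model$states, model$parameters$name, names(model$inputs), "t")
  for (fl in model$fluxes) {
    if (fl$kind == "mass_action") {
      bad <- setdiff(fl$substrates, model$states)
      if (length(bad)) stop("flux '", fl$name, "': unknown substrate(s) ", toString(bad))
      if (!is.null(fl$parameter) && !fl$parameter %in% model$parameters$name) {
        stop("flux '", fl$name, "': unknown parameter '", fl$parameter, "'")
      }
    } else {
      vars <- all.vars(parse(text = fl$expression))
      bad <- setdiff(vars, known_flux)
      if (length(bad)) stop("flux '", fl$name, "': undeclared symbol(s) ", toString(bad))
    }
  }
  known_out <- c(known_flux, colnames(model$stoichiometry))
  for (i in seq_along(model$outputs)) {
    vars <- all.vars(parse(text = model$outputs[[i]]))
    bad <- setdiff(vars, known_out)
    if (length(bad)) {
      stop("output '", names(model$outputs)[i], "': undeclared symbol(s) ", toString(bad))
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$states), " states, ",
      length(x$fluxes), " fluxes, ", nrow(x$parameters), " parameters, ",
      length(x$outputs), " outputs\n", sep = "")
  cat("  states:  ", toString(x$states), "\n", sep = "")
  cat("  outputs: ", toString(names(x$outputs)), "\n", sep = "")
  invisible(x)
}

.n_states <- function(model) length(model$states)
.n_fluxes <- function(model) length(model$fluxes)
.flux_names <- function(model) colnames(model$stoichiometry)

.is_mass_action <- function(model) {
  all(vapply(model$fluxes, function(f) f$kind == "mass_action", TRUE))
}

# per-flux multiplicative coefficient: fixed coef times parameter value
.flux_coefs <- function(model, p) {
  vapply(model$fluxes, function(f) {
    if (f$kind != "mass_action") stop("not a mass-action flux")
    if (is.null(f$parameter)) f$coef else f$coef * p[[f$parameter]]
  }, 0)
}

# states x fluxes matrix of mass-action orders
.expo_matrix <- function(model) {
  E <- matrix(0L, .n_states(model), .n_fluxes(model),
              dimnames = list(model$states, .flux_names(model)))
  for (j in seq_along(model$fluxes)) {
    f <- model$fluxes[[j]]
    for (s in f$substrates) E[s, j] <- E[s, j] + 1L
  }
  E
}

.check_parameters <- function(model, p) {
  pn <- model$parameters$name
  if (is.null(names(p))) {
    if (length(p) != length(pn)) stop("parameter vector has wrong length")
    names(p) <- pn
  }
  if (!all(pn %in% names(p))) {
    stop("missing parameter(s): ", toString(setdiff(pn, names(p))))
  }
  p[pn]
}

# resolve external inputs at (vector of) times
.input_values <- function(model, times) {
  lapply(model$inputs, function(u) if (is.function(u)) u(times) else u)
}

#' Evaluate model fluxes along a state trajectory
#'
#' @param model a [metabolic_model()].
#' @param states numeric matrix (times in rows, states in columns) or a single
#'   state vector.
#' @param p named parameter vector.
#' @param times time points matching the rows of `states`.
#' @return numeric matrix, one column per flux.
#' @export
eval_fluxes <- function(model, states, p, times = 0) {
  if (is.null(dim(states))) states <- matrix(states, 1, dimnames = list(NULL, model$states))
  p <- .check_parameters(model, p)
  nt <- nrow(states)
  out <- matrix(NA_real_, nt, .n_fluxes(model),
                dimnames = list(NULL, .flux_names(model)))
  env <- .trajectory_env(model, states, p, times)
  for (j in seq_along(model$fluxes)) {
    f <- model$fluxes[[j]]
    if (f$kind == "mass_action") {
      v <- rep(f$coef, nt)
      if (!is.null(f$parameter)) v <- v * p[[f$parameter]]
      for (s in f$substrates) v <- v * states[, s]
      out[, j] <- v
    } else {
      expr <- model$flux_expr[[j]] %||% parse(text = f$expression)[[1]]
      out[, j] <- rep_len(eval(expr, env), nt)
    }
  }
  out
}

.trajectory_env <- function(model, states, p, times, fluxes = NULL) {
  env <- new.env(parent = baseenv())
  for (s in model$states) assign(s, states[, s], envir = env)
  for (nm in names(p)) assign(nm, p[[nm]], envir = env)
  uv <- .input_values(model, times)
  for (nm in names(uv)) assign(nm, uv[[nm]], envir = env)
  assign("t", times, envir = env)
  if (!is.null(fluxes)) for (nm in colnames(fluxes)) assign(nm, fluxes[, nm], envir = env)
  env
}

#' Evaluate the model output map along a trajectory
#'
#' @inheritParams eval_fluxes
#' @param fluxes flux matrix as returned by [eval_fluxes()]; computed when
#'   omitted.
#' @return numeric matrix, one column per output.
#' @export
eval_outputs <- function(model, states, p, times = 0, fluxes = NULL) {
  if (is.null(dim(states))) states <- matrix(states, 1, dimnames = list(NULL, model$states))
  p <- .check_parameters(model, p)
  if (is.null(fluxes)) fluxes <- eval_fluxes(model, states, p, times)
  env <- .trajectory_env(model, states, p, times, fluxes)
  nt <- nrow(states)
  out <- matrix(NA_real_, nt, length(model$outputs),
                dimnames = list(NULL, names(model$outputs)))
  exprs <- model$output_expr %||% lapply(model$outputs,
                                          function(e) parse(text = e)[[1]])
  for (i in seq_along(model$outputs)) {
    out[, i] <- rep_len(eval(exprs[[i]], env), nt)
  }
  out
}

#' Simulate a metabolic model
#'
#' Integrates `dx/dt = N f(x, p, u)` and evaluates fluxes and outputs
#' pointwise on the returned states. Models affine in the states (every
#' mass-action flux of total order <= 1) are propagated exactly by a matrix
#' exponential — unconditionally stable, so stiff parameter regions cost
#' nothing; other pure mass-action models use a compiled Dormand-Prince
#' 5(4) adaptive method with absolute and relative tolerances 1e-6 by
#' default, and models with expression fluxes fall back to an R integrator
#' with the same Butcher tableau. `method = "rk45"` forces the adaptive
#' integrator.
#'
#' @param model a [metabolic_model()].
#' @param x0 initial state vector (named or in state order).
#' @param p parameter vector (named or in declared order); must lie within the
#'   declared bounds.
#' @param eval_times strictly increasing time points; the first element is the
#'   initial time.
#' @param atol,rtol integration tolerances.
#' @param check_bounds validate `p` against the declared bounds (default TRUE).
#' @param method `"auto"` (exact propagation where available) or `"rk45"`.
#' @return a `simulation_result`: list with `time`, `states`, `fluxes`,
#'   `outputs` matrices and a `diagnostics` list (negative-state excursions
#'   below -1e-8 are flagged, not clipped).
#' @export
simulate_model <- function(model, x0, p, eval_times, atol = 1e-6, rtol = 1e-6,
                           check_bounds = TRUE, method = c("auto", "rk45")) {
  method <- match.arg(method)
  p <- .check_parameters(model, p)
  if (check_bounds) {
    lo <- model$parameters$lower; up <- model$parameters$upper
    if (any(p < lo - 1e-12) || any(p > up + 1e-12)) {
      bad <- model$parameters$name[p < lo - 1e-12 | p > up + 1e-12]
      stop("parameter(s) outside declared bounds: ", toString(bad))
    }
  }
  if (is.null(names(x0))) names(x0) <- model$states
  x0 <- x0[model$states]
  if (length(x0) != .n_states(model) || anyNA(x0)) stop("x0 must cover every state")
  eval_times <- as.numeric(eval_times)
  if (length(eval_times) < 1L || is.unsorted(eval_times, strictly = TRUE)) {
    stop("eval_times must be strictly increasing")
  }

  if (method == "auto" && .is_affine(model)) {
    # linear(-affine) system: exact matrix-exponential propagation
    states <- .simulate_affine(model, x0, p, eval_times)
  } else if (.is_mass_action(model)) {
    res <- .rk45_mass_action(as.numeric(x0), eval_times,
                             t(model$stoichiometry), .flux_coefs(model, p),
                             .expo_matrix(model), atol, rtol)
    states <- res$states
    if (!res$ok || anyNA(states) || any(!is.finite(states))) {
      sf <- if (!is.na(res$state_fail %||% NA)) model$states[res$state_fail] else "unknown"
      stop(sprintf("integration failed near t = %.6g (state '%s')",
                   res$t_fail %||% NA_real_, sf))
    }
  } else {
    rhs <- .make_rhs_r(model, p)
    states <- .ode_rk45_r(rhs, as.numeric(x0), eval_times, atol, rtol)
  }
  colnames(states) <- model$states
  fluxes <- eval_fluxes(model, states, p, eval_times)
  outputs <- eval_outputs(model, states, p, eval_times, fluxes)
  diagnostics <- list()
  mins <- apply(states, 2, min)
  if (any(mins < -1e-8)) {
    diagnostics$negative_states <- mins[mins < -1e-8]
  }
  structure(list(time = eval_times, states = states, fluxes = fluxes,
                 outputs = outputs, diagnostics = diagnostics),
            class = "simulation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar RHS closure for expression models
.make_rhs_r <- function(model, p) {
  N <- model$stoichiometry
  force(p)
  function(t, x) {
    names(x) <- model$states
    fl <- eval_fluxes(model, matrix(x, 1, dimnames = list(NULL, model$states)), p, t)
    as.numeric(N %*% fl[1, ])
  }
}

#' Simulate one ADAPT time segment
#'
#' Integrates the model over `[t_start, t_start + dt]` holding the parameters
#' fixed, starting from the final state of the previous segment. Returns the
#' segment-end state together with the outputs and fluxes evaluated there.
#'
#' @inheritParams simulate_model
#' @param x_prev state vector at `t_start` (final state of segment `n - 1`).
#' @param p_n parameter vector held constant over the segment.
#' @param t_start segment start time.
#' @param dt segment length (> 0).
#' @return list with `x_end`, `outputs` (named vector), `fluxes` (named
#'   vector).
#' @export
simulate_segment <- function(model, x_prev, p_n, t_start, dt,
                             atol = 1e-6, rtol = 1e-6, check_bounds = FALSE) {
  stopifnot(dt > 0)
  sim <- simulate_model(model, x_prev, p_n, c(t_start, t_start + dt),
                        atol = atol, rtol = rtol, check_bounds = check_bounds)
  list(x_end = sim$states[2, ], outputs = sim$outputs[2, ], fluxes = sim$fluxes[2, ])
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", length(x$time), " time points, ",
      ncol(x$states), " states, ", ncol(x$fluxes), " fluxes, ",
      ncol(x$outputs), " outputs\n", sep = "")
  invisible(x)
}

#' @rdname simulate_model
#' @param x a `simulation_result`.
#' @param ... unused.
#' @method tidy simulation_result
#' @export
tidy.simulation_result <- function(x, ...) {
  bind <- function(mat, what) {
    tibble::as_tibble(mat) |>
      dplyr::mutate(time = x$time, kind = what) |>
      tidyr::pivot_longer(-c("time", "kind"), names_to = "name", values_to = "value")
  }
  dplyr::bind_rows(bind(x$states, "state"), bind(x$fluxes, "flux"),
                   bind(x$outputs, "output")) |>
    dplyr::select("kind", "name", "time", "value")
}

#' Steady state of a metabolic model
#'
#' For models affine in the states (every mass-action flux of total order
#' <= 1) the steady state solves the linear system `N f(x) = 0` directly;
#' otherwise the model is integrated until the state derivatives are
#' negligible.
#'
#' @inheritParams simulate_model
#' @param x_guess starting state for the relaxation path (defaults to 1s).
#' @param t_relax horizon for the relaxation path.
#' @param tol derivative norm declaring convergence.
#' @return named state vector, or `NULL` when no admissible (finite,
#'   nonnegative) steady state is found.
#' @export
steady_state <- function(model, p, x_guess = NULL, t_relax = 500, tol = 1e-8) {
  p <- .check_parameters(model, p)
  if (.is_mass_action(model)) {
    E <- .expo_matrix(model)
    if (all(colSums(E) <= 1L)) {
      # dx/dt = A x + b with A, b assembled from first-order / constant fluxes
      N <- model$stoichiometry
      coefs <- .flux_coefs(model, p)
      ns <- .n_states(model)
      A <- matrix(0, ns, ns); b <- numeric(ns)
      for (j in seq_len(ncol(E))) {
        sub <- which(E[, j] == 1L)
        if (length(sub) == 1L) A[, sub] <- A[, sub] + N[, j] * coefs[j]
        else b <- b + N[, j] * coefs[j]
      }
      x <- tryCatch(solve(A, -b), error = function(e) NULL)
      if (is.null(x) || any(!is.finite(x)) || any(x < -1e-9)) return(NULL)
      return(setNames(pmax(x, 0), model$states))
    }
  }
  x <- x_guess %||% setNames(rep(1, .n_states(model)), model$states)
  sim <- tryCatch(
    simulate_model(model, x, p, c(0, t_relax * c(0.5, 1)), check_bounds = FALSE),
    error = function(e) NULL)
  if (is.null(sim)) return(NULL)
  xe <- sim$states[3, ]
  dx <- .make_rhs_r(model, p)(t_relax, xe)
  if (sqrt(mean(dx^2)) > tol * max(1, max(abs(xe)))) return(NULL)
  setNames(pmax(xe, 0), model$states)
}
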