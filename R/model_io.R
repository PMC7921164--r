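#' Read / write a model specification file
#'
#' Models are stored as structured JSON with blocks `states`, `parameters`
#' (name, bounds, baseline guess), `stoichiometry` (dense integer matrix,
#' states in rows), `fluxes` and `outputs`. The round trip
#' `write_model_json()` then `read_model_json()` is lossless.
#'
#' @param path file path.
#' @return [read_model_json()] returns a [metabolic_model()];
#'   [write_model_json()] returns `path` invisibly.
#' @export
read_model_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  states <- vapply(spec$states, identity, "")
  parameters <- dplyr::bind_rows(lapply(spec$parameters, tibble::as_tibble))
  stoich <- do.call(rbind, lapply(spec$stoichiometry,
                                  function(r) vapply(r, as.numeric, 0)))
  fluxes <- lapply(spec$fluxes, function(f) {
    if (!is.null(f$expression)) {
      flux_expression(f$name, f$expression)
    } else {
      flux_mass_action(f$name, parameter = f$parameter,
                       substrates = unlist(f$substrates) %||% character(),
                       coef = f$coef %||% 1)
    }
  })
  outputs <- setNames(vapply(spec$outputs, `[[`, "", "expression"),
                      vapply(spec$outputs, `[[`, "", "name"))
  x0 <- if (!is.null(spec$x0)) unlist(spec$x0) else NULL
  inputs <- if (!is.null(spec$inputs)) lapply(spec$inputs, as.numeric) else list()
  metabolic_model(states, parameters, stoich, fluxes, outputs,
                  x0 = x0, inputs = inputs)
}

#' @rdname read_model_json
#' @param model a [metabolic_model()].
#' @export
write_model_json <- function(model, path) {
  if (any(vapply(model$inputs, is.function, TRUE))) {
    stop("function-valued external inputs cannot be serialized to JSON")
  }
  fluxes <- lapply(model$fluxes, function(f) {
    if (f$kind == "expression") {
      list(name = f$name, expression = f$expression)
    } else {
      out <- list(name = f$name, substrates = as.list(f$substrates), coef = f$coef)
      if (!is.null(f$parameter)) out$parameter <- f$parameter
      out
    }
  })
  spec <- list(
    states = as.list(model$states),
    parameters = lapply(seq_len(nrow(model$parameters)), function(i) {
      as.list(model$parameters[i, c("name", "lower", "upper", "guess")])
    }),
    stoichiometry = lapply(seq_len(nrow(model$stoichiometry)),
                           function(i) as.list(model$stoichiometry[i, ])),
    fluxes = fluxes,
    outputs = lapply(seq_along(model$outputs), function(i) {
      list(name = names(model$outputs)[i], expression = unname(model$outputs[[i]]))
    }))
  if (!is.null(model$x0)) spec$x0 <- as.list(model$x0)
  if (length(model$inputs)) spec$inputs <- model$inputs
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
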