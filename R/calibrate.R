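#' Calibrate baseline parameters for the untreated phenotype
#'
#' Multistart least squares with scatter preselection: (1) sample `n_scatter`
#' parameter vectors log-uniformly over a widely dispersed range (default
#' 1e-6 to 1e6, intersected with the declared bounds); (2) rank them by the
#' weighted SSE against the t = 0 data; (3) keep the best `keep_fraction`;
#' (4) polish each survivor with a bounded local optimizer (termination
#' tolerances 1e-10, at most 1e3 iterations / 1e5 evaluations). The baseline
#' state is the steady state implied by each candidate parameter set unless
#' the model declares a fixed `x0`.
#'
#' @param model a [metabolic_model()].
#' @param data a [longitudinal_dataset()]; only its earliest-time rows (the
#'   untreated phenotype) are used.
#' @param n_scatter number of scatter samples.
#' @param keep_fraction fraction of best scatter draws promoted to local
#'   optimization.
#' @param seed integer seed for the scatter draw.
#' @param scatter_range two-element range for the log-uniform scatter draw.
#' @param log_scale optimize in log10 parameter space (recommended: the
#'   scatter range spans 12 decades).
#' @param control optimizer control overrides, see [stats::nlminb()].
#' @return a `baseline_fit`: tibble with one row per local run, columns
#'   `start_rank`, `sse`, `converged`, one column per parameter, and a
#'   list-column `p` with the named parameter vector; sorted by `sse`
#'   (stable, then by scatter rank). Attributes carry the model, measured
#'   outputs and seed.
#' @export
calibrate_baseline <- function(model, data, n_scatter = 2e5, keep_fraction = 0.1,
                               seed = 1L, scatter_range = c(1e-6, 1e6),
                               log_scale = TRUE, control = list()) {
  data <- longitudinal_dataset(data)
  t0 <- min(data$time)
  d0 <- data[data$time == t0, , drop = FALSE]
  measured <- intersect(names(model$outputs), d0$observable)
  if (length(measured) == 0L) stop("no t = 0 observable matches a model output")
  if (length(measured) < nrow(model$parameters)) {
    warning("fewer t = 0 observables (", length(measured), ") than parameters (",
            nrow(model$parameters), "): the baseline may be under-determined")
  }
  d0 <- d0[match(measured, d0$observable), , drop = FALSE]

  pn <- model$parameters$name
  np <- length(pn)
  lo <- pmax(model$parameters$lower, scatter_range[1])
  up <- pmin(model$parameters$upper, scatter_range[2])

  big <- 1e100 # failure sentinel: finite (the local optimizer cannot digest
  # Inf) yet far above any attainable misfit, even with floored zero SDs
  sse_of <- function(p) {
    names(p) <- pn
    x0 <- if (!is.null(model$x0)) model$x0 else steady_state(model, p)
    if (is.null(x0)) return(big)
    y <- tryCatch(eval_outputs(model, x0, p, times = t0)[1, measured],
                  error = function(e) NULL)
    if (is.null(y) || any(!is.finite(y))) return(big)
    chi_d2(y, d0$mean, d0$sd)
  }

  draws <- .with_seed(seed, {
    matrix(10^runif(n_scatter * np,
                    rep(log10(lo), each = n_scatter),
                    rep(log10(up), each = n_scatter)),
           n_scatter, np)
  })
  sse0 <- apply(draws, 1, sse_of)
  n_keep <- max(1L, floor(n_scatter * keep_fraction))
  keep <- order(sse0)[seq_len(n_keep)] # stable: ties keep draw order

  ctrl <- modifyList(list(iter.max = 1000L, eval.max = 100000L,
                          rel.tol = 1e-10, x.tol = 1e-10), control)
  runs <- lapply(seq_along(keep), function(k) {
    start <- draws[keep[k], ]
    if (log_scale) {
      llo <- log10(pmax(lo, 1e-9)); lup <- log10(up)
      fit <- nlminb(log10(pmax(start, 1e-9)),
                    function(lp) sse_of(10^lp),
                    lower = llo, upper = lup, control = ctrl)
      par <- 10^fit$par
    } else {
      fit <- nlminb(start, sse_of, lower = lo, upper = up, control = ctrl)
      par <- fit$par
    }
    list(par = setNames(par, pn), sse = fit$objective,
         converged = fit$convergence == 0L, rank = k)
  })
  ok <- vapply(runs, function(r) is.finite(r$sse) && r$sse < big, TRUE)
  if (!any(ok)) {
    msgs <- unique(vapply(runs, function(r) as.character(r$sse), ""))
    stop("all local starts failed to converge (objectives: ", toString(msgs), ")")
  }
  runs <- runs[ok]
  out <- tibble::tibble(
    start_rank = vapply(runs, `[[`, 0L, "rank"),
    sse = vapply(runs, `[[`, 0, "sse"),
    converged = vapply(runs, `[[`, TRUE, "converged"),
    p = lapply(runs, `[[`, "par"))
  pm <- do.call(rbind, out$p)
  out <- dplyr::bind_cols(out, tibble::as_tibble(pm))
  out <- out[order(out$sse, out$start_rank), , drop = FALSE]
  structure(out, class = c("baseline_fit", class(out)),
            model = model, measured = measured, seed = seed, t0 = t0)
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat("<baseline_fit> ", nrow(x), " local runs; best SSE = ",
      format(x$sse[1], digits = 6), "\n", sep = "")
  NextMethod()
}

#' Refit the baseline to one Monte Carlo data realization
#'
#' Local polish of a baseline parameter set against the t = 0 anchors of a
#' sampled data realization (each spline sample of the Monte Carlo ensemble
#' carries its own perturbed untreated phenotype). Started from an existing
#' baseline estimate, this is a single bounded local fit.
#'
#' @param model a [metabolic_model()].
#' @param data the [longitudinal_dataset()] (supplies t = 0 SDs for the
#'   weights).
#' @param realization a [sample_realization()] tibble (or the `anchors`
#'   entry of a spline ensemble sample).
#' @param start named parameter vector to start from.
#' @param control optimizer control overrides.
#' @return named parameter vector.
#' @export
refine_baseline <- function(model, data, realization, start, control = list()) {
  data <- longitudinal_dataset(data)
  t0 <- min(data$time)
  d0 <- data[data$time == t0 & data$kind == "metabolic", , drop = FALSE]
  r0 <- realization[realization$time == t0 & realization$kind == "metabolic", ,
                    drop = FALSE]
  measured <- intersect(names(model$outputs), r0$observable)
  if (!length(measured)) stop("realization has no t = 0 model output")
  vals <- r0$value[match(measured, r0$observable)]
  sds <- d0$sd[match(measured, d0$observable)]
  pn <- model$parameters$name
  start <- .check_parameters(model, start)
  lo <- pmax(model$parameters$lower, 1e-9)
  up <- model$parameters$upper
  big <- 1e100
  obj <- function(lp) {
    p <- setNames(10^lp, pn)
    x0 <- if (!is.null(model$x0)) model$x0 else steady_state(model, p)
    if (is.null(x0)) return(big)
    y <- tryCatch(eval_outputs(model, x0, p, times = t0)[1, measured],
                  error = function(e) NULL)
    if (is.null(y) || any(!is.finite(y))) return(big)
    chi_d2(y, vals, sds)
  }
  # warm-started polish: a few hundred iterations suffice
  ctrl <- modifyList(list(iter.max = 200L, eval.max = 5000L,
                          rel.tol = 1e-10, x.tol = 1e-10), control)
  fit <- nlminb(log10(pmin(pmax(start, lo), up)), obj,
                lower = log10(lo), upper = log10(up), control = ctrl)
  setNames(10^fit$par, pn)
}
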