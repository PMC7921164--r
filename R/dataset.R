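#' Longitudinal mean +/- SD dataset
#'
#' Validates and tags a long-format table of longitudinal summary data: one
#' row per observable and time point with the replicate mean, standard
#' deviation and (optionally) replicate count. Two kinds of observables are
#' distinguished: `metabolic` (concentrations, fluxes) and `transcript`
#' (relative gene-expression levels).
#'
#' @param df data frame with columns `observable`, `kind`, `time`, `mean`,
#'   `sd` and optionally `n`.
#' @return a validated tibble of class `longitudinal_dataset`.
#' @export
longitudinal_dataset <- function(df) {
  df <- tibble::as_tibble(df)
  req <- c("observable", "kind", "time", "mean", "sd")
  if (!all(req %in% names(df))) {
    stop("dataset must have columns ", toString(req))
  }
  if (!"n" %in% names(df)) df$n <- NA_integer_
  if (any(df$sd < 0, na.rm = TRUE)) stop("standard deviations must be >= 0")
  if (!all(df$kind %in% c("metabolic", "transcript"))) {
    stop("kind must be 'metabolic' or 'transcript'")
  }
  ord <- order(df$observable, df$time)
  df <- df[ord, , drop = FALSE]
  dup <- df |>
    dplyr::count(.data$observable, .data$time) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate time points for observable(s): ",
         toString(unique(dup$observable)))
  }
  class(df) <- c("longitudinal_dataset", class(df))
  df
}

#' Read / write longitudinal data as delimited text
#'
#' Long-format CSV with columns `observable, kind, time, mean, sd, n`. The
#' reader validates monotone times per observable; writing then re-reading
#' reproduces the dataset.
#'
#' @param path file path.
#' @return a `longitudinal_dataset` tibble.
#' @export
read_longitudinal_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          observable = readr::col_character(),
                          kind = readr::col_character(),
                          time = readr::col_double(),
                          mean = readr::col_double(),
                          sd = readr::col_double(),
                          n = readr::col_integer()))
  longitudinal_dataset(df)
}

#' @rdname read_longitudinal_csv
#' @param data a `longitudinal_dataset`.
#' @export
write_longitudinal_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

# times common to every observable of the given kind
.dataset_times <- function(data, kind = NULL) {
  if (!is.null(kind)) data <- data[data$kind %in% kind, , drop = FALSE]
  sort(unique(data$time))
}

# run expr with a fixed RNG seed, restoring the caller's RNG state after
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Draw one Monte Carlo realization of a longitudinal dataset
#'
#' Each value is drawn independently from a Gaussian with the reported mean
#' and standard deviation; physically nonnegative observables are truncated
#' at zero (configurable). With all SDs zero the realization equals the
#' means exactly.
#'
#' @param data a [longitudinal_dataset()].
#' @param seed integer RNG seed; the global RNG state is restored afterwards.
#' @param truncate_at_zero truncate sampled anchors at 0 (default TRUE).
#' @param scale `"sd"` draws at the replicate standard deviation (the spread
#'   of individual animals); `"sem"` draws at the standard error of the mean
#'   `sd / sqrt(n)` (falling back to `sd` where `n` is missing), which
#'   quantifies uncertainty of the mean dynamics.
#' @return a tibble `observable, kind, time, value` in dataset order.
#' @export
sample_realization <- function(data, seed, truncate_at_zero = TRUE,
                               scale = c("sd", "sem")) {
  scale <- match.arg(scale)
  data <- longitudinal_dataset(data)
  s <- data$sd
  if (scale == "sem") {
    s <- ifelse(is.na(data$n) | data$n < 1, s, s / sqrt(data$n))
  }
  vals <- .with_seed(seed, rnorm(nrow(data), data$mean, s))
  if (truncate_at_zero) vals <- pmax(vals, 0)
  tibble::tibble(observable = data$observable, kind = data$kind,
                 time = data$time, value = vals)
}

#' Monte Carlo ensemble of smoothing splines
#'
#' Implements the spline-based continuous description of longitudinal data:
#' `n_samples` Gaussian realizations of the dataset are drawn and a cubic
#' smoothing spline (see [fit_smoothing_spline()]) is fitted to each
#' realization of each observable, yielding a collection of interpolants that
#' propagates measurement uncertainty into everything downstream.
#'
#' @inheritParams sample_realization
#' @param n_samples number of Monte Carlo realizations (>= 1).
#' @param q smoothing level in `[0, 1]`; the default 1 interpolates each
#'   realization exactly.
#' @param anchor_scale anchor sampling scale, see [sample_realization()];
#'   the default `"sem"` propagates uncertainty of the mean dynamics, which
#'   keeps the downstream 95%-interval acceptance filter meaningful.
#' @return a `spline_ensemble`: list with `splines` (list of length
#'   `n_samples`, each a named list of splines per observable), `anchors`
#'   (the sampled values), `times`, `seed`, `q` and the source dataset.
#' @export
build_spline_ensemble <- function(data, n_samples, seed, q = 1,
                                  truncate_at_zero = TRUE,
                                  anchor_scale = c("sem", "sd")) {
  anchor_scale <- match.arg(anchor_scale)
  stopifnot(n_samples >= 1)
  data <- longitudinal_dataset(data)
  # observables with a single time point (t = 0 anchors for latent
  # quantities) inform the baseline only; no spline is fitted for them
  counts <- table(data$observable)
  obs <- names(counts)[counts >= 2L]
  obs <- unique(data$observable)[unique(data$observable) %in% obs]
  splines <- vector("list", n_samples)
  anchors <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    real <- sample_realization(data, derive_seed(seed, s),
                               truncate_at_zero = truncate_at_zero,
                               scale = anchor_scale)
    anchors[[s]] <- real
    splines[[s]] <- setNames(lapply(obs, function(o) {
      idx <- real$observable == o
      di <- data[data$observable == o, , drop = FALSE]
      tryCatch(
        fit_smoothing_spline(real$time[idx], real$value[idx], sds = di$sd, q = q),
        error = function(e) stop("spline fit failed for sample ", s,
                                 ", observable '", o, "': ", conditionMessage(e),
                                 call. = FALSE))
    }), obs)
  }
  structure(list(splines = splines, anchors = anchors,
                 times = .dataset_times(data), seed = seed, q = q,
                 observables = obs, data = data),
            class = "spline_ensemble")
}

#' @export
print.spline_ensemble <- function(x, ...) {
  cat("<spline_ensemble> ", length(x$splines), " samples x ",
      length(x$observables), " observables on [",
      min(x$times), ", ", max(x$times), "]\n", sep = "")
  invisible(x)
}

# samples x times evaluation matrix for one observable
.ensemble_eval <- function(ensemble, observable, eval_times, deriv = 0) {
  if (!observable %in% ensemble$observables) {
    stop("unknown observable '", observable, "'")
  }
  t(vapply(ensemble$splines, function(ss) {
    predict(ss[[observable]], eval_times, deriv = deriv)
  }, numeric(length(eval_times))))
}

#' Central quantile band of a spline ensemble
#'
#' Pointwise empirical envelope enclosing the central `fraction` of the
#' interpolant density, as drawn around data interpolants in ensemble plots.
#'
#' @param ensemble a [build_spline_ensemble()] result.
#' @param observable observable name.
#' @param fraction central probability mass, in (0, 1).
#' @param eval_times evaluation time points.
#' @return tibble `time, lower, upper`.
#' @export
central_band <- function(ensemble, observable, fraction, eval_times) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  vals <- .ensemble_eval(ensemble, observable, eval_times)
  alpha <- (1 - fraction) / 2
  tibble::tibble(
    time = eval_times,
    lower = apply(vals, 2, quantile, probs = alpha, names = FALSE),
    upper = apply(vals, 2, quantile, probs = 1 - alpha, names = FALSE))
}
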