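#' Acceptance filter for a trajectory solution
#'
#' A solution is acceptable when every measured metabolic output lies within
#' the 95% confidence interval of the data — `mean +/- 1.96 sd`, interval
#' closed — at every measurement time. The solution's node grid must contain
#' the data times.
#'
#' @param solution an `adapt_solution`.
#' @param data the [longitudinal_dataset()] the solution was fitted to.
#' @return logical scalar.
#' @export
accept <- function(solution, data) {
  data <- longitudinal_dataset(data)
  met <- data[data$kind == "metabolic" &
                data$observable %in% solution$measured, , drop = FALSE]
  if (!nrow(met)) stop("no measured metabolic output to check")
  tol <- 1e-8 * max(1, max(abs(solution$times)))
  for (i in seq_len(nrow(met))) {
    j <- which(abs(solution$times - met$time[i]) <= tol)
    if (!length(j)) {
      stop("solution grid does not contain data time ", met$time[i],
           " (output coverage missing)")
    }
    y <- solution$outputs[met$observable[i], j[1]]
    half <- 1.96 * met$sd[i]
    if (y < met$mean[i] - half - 1e-12 || y > met$mean[i] + half + 1e-12) {
      return(FALSE)
    }
  }
  TRUE
}

#' Monte Carlo scan over regularization constants
#'
#' Runs the trajectory estimator for `n_runs` random combinations of the two
#' regularization constants, pairing each run with a Monte Carlo spline
#' sample and a baseline parameter set (cycled), and applies the acceptance
#' filter. Each constant is drawn log-uniformly over `lambda_range`
#' (defaults bracket the effective thresholds reported for the method,
#' 1e-6 and 1e-8), and is exactly zero with probability `p_zero` so that the
#' scan contains an unregularized reference group G0. Every run's seed
#' derives deterministically from `seed` and the run index, so results are
#' identical whatever the execution order or worker count.
#'
#' @param model a [metabolic_model()].
#' @param baselines list of named baseline parameter vectors, or a
#'   `baseline_fit` (its `p` column is used).
#' @param ensemble a [build_spline_ensemble()] covering metabolic observables
#'   and coupled genes.
#' @param data the [longitudinal_dataset()].
#' @param coupling a [gene_coupling_map()].
#' @param n_runs number of trajectory runs (>= 1).
#' @param seed master seed.
#' @param lambda_range log-uniform sampling range for each constant.
#' @param p_zero probability that a run is unregularized, i.e. draws the
#'   pair (0, 0) and joins the reference group G0.
#' @param lambda_fixed optional 2-column matrix / data frame of fixed lambda
#'   pairs (overrides sampling; recycled over runs).
#' @param workers accepted for API compatibility; execution is sequential and
#'   worker count never changes results.
#' @param ... further arguments passed to [run_adapt()] (`n_t`, `t_end`,
#'   `control`, ...).
#' @return a `solution_ensemble`: list with `solutions` (list of
#'   `adapt_solution`) and `runs` (tibble: run, lambda pair, sample and
#'   baseline indices, acceptance, summed objective components).
#' @export
scan_lambdas <- function(model, baselines, ensemble, data, coupling,
                         n_runs, seed, lambda_range = c(1e-12, 1),
                         p_zero = 0.25, lambda_fixed = NULL, workers = 1L,
                         ...) {
  stopifnot(n_runs >= 1L)
  if (inherits(baselines, "baseline_fit")) baselines <- baselines$p
  if (!is.list(baselines)) baselines <- list(baselines)
  n_s <- length(ensemble$splines)
  n_b <- length(baselines)

  run_one <- function(r) {
    seed_r <- derive_seed(seed, r)
    lam <- if (!is.null(lambda_fixed)) {
      as.numeric(lambda_fixed[(r - 1L) %% nrow(lambda_fixed) + 1L, ])
    } else {
      .with_seed(seed_r, {
        if (runif(1) < p_zero) c(0, 0)
        else 10^runif(2, log10(lambda_range[1]), log10(lambda_range[2]))
      })
    }
    si <- (r - 1L) %% n_s + 1L
    bi <- (r - 1L) %% n_b + 1L
    sol <- tryCatch(
      run_adapt(model, baselines[[bi]], ensemble$splines[[si]], data,
                coupling = coupling, lambda = lam, sample_index = si,
                seed = seed_r, ...),
      error = function(e) e)
    list(sol = sol, lam = lam, si = si, bi = bi)
  }
  results <- lapply(seq_len(n_runs), run_one)

  solutions <- vector("list", n_runs)
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    res <- results[[r]]
    failed <- inherits(res$sol, "condition")
    if (!failed) {
      # acceptance is undefined when the segment grid misses a data time;
      # record NA rather than aborting the scan
      acc <- tryCatch(accept(res$sol, data), error = function(e) NA)
      res$sol$accepted <- acc & !any(res$sol$objective$flagged)
      solutions[[r]] <- res$sol
    }
    rows[[r]] <- tibble::tibble(
      run = r, lambda_g1 = res$lam[1], lambda_g2 = res$lam[2],
      sample = res$si, baseline = res$bi,
      failed = failed,
      accepted = if (failed) FALSE else isTRUE(res$sol$accepted),
      chi_d2_sum = if (failed) NA_real_ else sum(res$sol$objective$chi_d2),
      chi_g1_sum = if (failed) NA_real_ else sum(res$sol$objective$chi_g1),
      chi_g2_sum = if (failed) NA_real_ else sum(res$sol$objective$chi_g2))
  }
  structure(list(solutions = solutions, runs = dplyr::bind_rows(rows),
                 seed = seed, lambda_range = lambda_range, p_zero = p_zero),
            class = "solution_ensemble")
}

#' @export
print.solution_ensemble <- function(x, ...) {
  cat("<solution_ensemble> ", nrow(x$runs), " runs, ",
      sum(x$runs$accepted), " accepted, ",
      sum(x$runs$lambda_g1 == 0 & x$runs$lambda_g2 == 0), " unregularized (G0)\n",
      sep = "")
  invisible(x)
}

#' @rdname scan_lambdas
#' @param x a `solution_ensemble`.
#' @method glance solution_ensemble
#' @export
glance.solution_ensemble <- function(x, ...) {
  dplyr::summarise(x$runs,
                   n_runs = dplyr::n(), n_accepted = sum(.data$accepted),
                   n_g0 = sum(.data$lambda_g1 == 0 & .data$lambda_g2 == 0),
                   chi_d2_median = median(.data$chi_d2_sum, na.rm = TRUE))
}

#' @rdname scan_lambdas
#' @method tidy solution_ensemble
#' @export
tidy.solution_ensemble <- function(x, ...) x$runs

# subset helper preserving class and run bookkeeping
.subset_ensemble <- function(ensemble, idx) {
  structure(list(solutions = ensemble$solutions[idx],
                 runs = ensemble$runs[idx, , drop = FALSE],
                 seed = ensemble$seed, lambda_range = ensemble$lambda_range,
                 p_zero = ensemble$p_zero),
            class = "solution_ensemble")
}

#' Solution groups by temporal gene correlation
#'
#' `group_g(ensemble, i)` returns the fraction-`i` group `G_i`: the
#' `floor(i * N)` accepted solutions (at least 1) with the lowest correlation
#' penalty summed over the whole treatment period (hence the highest
#' temporal correlation between parameter trajectories and gene expression).
#' Ties are broken by run index, so membership is deterministic.
#' `group_g0(ensemble)` returns the unregularized group (both constants
#' exactly zero).
#'
#' @param ensemble a `solution_ensemble`.
#' @param fraction group fraction `i`, in (0, 1].
#' @param over_accepted take fractions over accepted solutions (default) or
#'   over all non-failed runs.
#' @return a `solution_ensemble` containing the group.
#' @export
group_g <- function(ensemble, fraction, over_accepted = TRUE) {
  stopifnot(fraction > 0, fraction <= 1)
  runs <- ensemble$runs
  pool <- which(if (over_accepted) runs$accepted else !runs$failed)
  if (!length(pool)) stop("no accepted solutions to group")
  k <- max(1L, floor(fraction * length(pool)))
  ord <- pool[order(runs$chi_g1_sum[pool], runs$run[pool])]
  .subset_ensemble(ensemble, sort(ord[seq_len(k)]))
}

#' @rdname group_g
#' @export
group_by_correlation <- group_g

#' @rdname group_g
#' @export
group_g0 <- function(ensemble) {
  idx <- which(ensemble$runs$lambda_g1 == 0 & ensemble$runs$lambda_g2 == 0 &
                 !ensemble$runs$failed)
  .subset_ensemble(ensemble, idx)
}

# per-solution trajectory of one named quantity over the node grid
.solution_quantity <- function(solution, quantity) {
  for (slot in c("states", "parameters", "fluxes", "outputs")) {
    m <- solution[[slot]]
    if (quantity %in% rownames(m)) return(m[quantity, ])
  }
  stop("unknown quantity '", quantity, "'")
}

# matrix solutions x nodes for a quantity (optionally restricted to times)
.ensemble_quantity <- function(ensemble, quantity, eval_times = NULL) {
  sols <- ensemble$solutions[!vapply(ensemble$solutions, is.null, TRUE)]
  if (!length(sols)) stop("ensemble contains no solutions")
  times <- sols[[1]]$times
  M <- t(vapply(sols, .solution_quantity, numeric(length(times)), quantity))
  if (!is.null(eval_times)) {
    j <- vapply(eval_times, function(t) {
      k <- which.min(abs(times - t))
      if (abs(times[k] - t) > 1e-8 * max(1, abs(t))) {
        stop("time ", t, " is not on the solution grid")
      }
      k
    }, 0L)
    M <- M[, j, drop = FALSE]
    times <- times[j]
  }
  list(values = M, times = times)
}

#' Variance reduction of a solution group against a reference
#'
#' Per time point, `VR(t) = 1 - Var_group(q(t)) / Var_reference(q(t))` for a
#' named state, parameter, flux or output: how much an analysis group (for
#' example the highest-gene-correlation group) shrinks the estimation spread
#' relative to a reference group (for example the unregularized solutions).
#' The reference variance is floored at a small epsilon; VR is reported
#' unclipped (negative values mean the group is wider than the reference).
#'
#' @param group,reference `solution_ensemble` objects on a common node grid.
#' @param quantity name of a state, parameter, flux or output.
#' @param eval_times optional subset of node times.
#' @return tibble `time, var_group, var_reference, vr`.
#' @export
variance_reduction <- function(group, reference, quantity, eval_times = NULL) {
  g <- .ensemble_quantity(group, quantity, eval_times)
  r <- .ensemble_quantity(reference, quantity, eval_times)
  vg <- apply(g$values, 2, var)
  vr_ <- apply(r$values, 2, var)
  scale <- pmax(apply(r$values, 2, function(v) mean(v^2)), 1)
  vfloor <- pmax(vr_, 1e-12 * scale)
  tibble::tibble(time = g$times, var_group = vg, var_reference = vr_,
                 vr = 1 - vg / vfloor)
}

#' Robust pointwise summary of an ensemble quantity
#'
#' Median, median absolute deviation (unscaled) and the central-95% band per
#' node time across the solutions of an ensemble — the summaries drawn as
#' areas and bars in ensemble trajectory figures.
#'
#' @inheritParams variance_reduction
#' @param ensemble a `solution_ensemble`.
#' @return tibble `time, median, mad, q2.5, q97.5, variance`.
#' @export
ensemble_summary <- function(ensemble, quantity, eval_times = NULL) {
  q <- .ensemble_quantity(ensemble, quantity, eval_times)
  M <- q$values
  tibble::tibble(
    time = q$times,
    median = apply(M, 2, median),
    mad = apply(M, 2, function(v) median(abs(v - median(v)))),
    q2.5 = apply(M, 2, quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(M, 2, quantile, probs = 0.975, names = FALSE),
    variance = apply(M, 2, var))
}
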