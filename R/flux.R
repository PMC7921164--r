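#' Decompose the net rate of a metabolite pool into flux routes
#'
#' Classifies every model flux by its net stoichiometric action on a pool of
#' states (for example the total hepatic triglyceride pool): fluxes whose
#' coefficients summed over the pool states are positive are additive routes
#' (they feed the pool, collectively `F_a`), negative ones are subtractive
#' (`F_s`), and fluxes with zero net effect — internal transfers between
#' pool members — are excluded. Each route carries the absolute net
#' coefficient as its weight.
#'
#' @param model a [metabolic_model()].
#' @param pool_states character vector of state names forming the pool.
#' @return a `pool_decomposition` tibble: `flux, net_coef, side, weight`.
#' @export
decompose_pool <- function(model, pool_states) {
  stopifnot(length(pool_states) >= 1L)
  bad <- setdiff(pool_states, model$states)
  if (length(bad)) stop("unknown state(s): ", toString(bad))
  net <- colSums(model$stoichiometry[pool_states, , drop = FALSE])
  out <- tibble::tibble(
    flux = colnames(model$stoichiometry),
    net_coef = unname(net),
    side = dplyr::case_when(net > 0 ~ "additive",
                            net < 0 ~ "subtractive",
                            TRUE ~ "excluded"),
    weight = abs(unname(net)))
  out <- out[out$side != "excluded", , drop = FALSE]
  structure(out, class = c("pool_decomposition", class(out)),
            pool_states = pool_states)
}

#' Additive and subtractive flux sums along a solution
#'
#' `F_a(t)` and `F_s(t)` are the weighted sums of the additive and
#' subtractive routes at each segment node; their difference is the pool's
#' net accumulation rate (`F_a - F_s = d(pool)/dt` exactly, up to the
#' differentiation of the discrete trajectory).
#'
#' @param solution an `adapt_solution`, `synthetic_truth` or
#'   `simulation_result` with flux trajectories.
#' @param decomposition a [decompose_pool()] result.
#' @return tibble `time, F_a, F_s, imbalance`.
#' @export
flux_sums <- function(solution, decomposition) {
  fx <- .flux_matrix(solution) # fluxes in rows, nodes in columns
  times <- .solution_times(solution)
  add <- decomposition[decomposition$side == "additive", , drop = FALSE]
  sub <- decomposition[decomposition$side == "subtractive", , drop = FALSE]
  wsum <- function(d) {
    if (!nrow(d)) return(rep(0, length(times)))
    colSums(fx[d$flux, , drop = FALSE] * d$weight)
  }
  tibble::tibble(time = times, F_a = wsum(add), F_s = wsum(sub),
                 imbalance = wsum(add) - wsum(sub))
}

.flux_matrix <- function(solution) {
  if (inherits(solution, c("adapt_solution", "synthetic_truth"))) {
    return(solution$fluxes)
  }
  if (inherits(solution, "simulation_result")) return(t(solution$fluxes))
  stop("need an adapt_solution, synthetic_truth or simulation_result")
}

.solution_times <- function(solution) {
  if (inherits(solution, "simulation_result")) solution$time else solution$times
}

#' Additive route components along a solution
#'
#' The weighted per-route contributions making up `F_a(t)`, optionally
#' merged into named routes (for example grouping several reactions into
#' "de novo lipogenesis").
#'
#' @inheritParams flux_sums
#' @param routes optional named list mapping route names to flux names;
#'   default one route per additive flux.
#' @return matrix, nodes in rows, routes in columns.
#' @export
route_components <- function(solution, decomposition, routes = NULL) {
  fx <- .flux_matrix(solution)
  add <- decomposition[decomposition$side == "additive", , drop = FALSE]
  comp <- t(fx[add$flux, , drop = FALSE] * add$weight)
  colnames(comp) <- add$flux
  if (!is.null(routes)) {
    bad <- setdiff(unlist(routes), add$flux)
    if (length(bad)) stop("route(s) reference non-additive flux(es): ", toString(bad))
    comp <- vapply(routes, function(fl) {
      rowSums(comp[, fl, drop = FALSE])
    }, numeric(nrow(comp)))
  }
  comp
}

#' Fractional contribution of each route to the additive flux sum
#'
#' `fraction_k(t) = component_k(t) / F_a(t)`, so rows sum to 1 wherever
#' `F_a(t) > 0`. Times where the denominator is not positive are flagged:
#' the fractions there are reported missing, not zero, to avoid fabricating
#' contributions.
#'
#' @param components matrix of route components (nodes in rows, routes in
#'   columns), e.g. from [route_components()].
#' @return matrix of fractions with the same shape; rows with nonpositive
#'   total are all `NA` and listed in the `flagged_rows` attribute.
#' @export
fractional_contribution <- function(components) {
  stopifnot(is.matrix(components))
  total <- rowSums(components)
  frac <- components / total
  bad <- which(!(total > 0))
  if (length(bad)) frac[bad, ] <- NA_real_
  attr(frac, "flagged_rows") <- bad
  frac
}

#' Time of maximal fractional contribution per route
#'
#' The node time at which each route's fractional contribution peaks;
#' ties are broken to the earliest node. Peak times are resolved on the
#' segment grid (no sub-grid interpolation).
#'
#' @param fractions matrix from [fractional_contribution()] (nodes in rows).
#' @param times node times matching the rows.
#' @return tibble `route, time_to_peak, peak_fraction`.
#' @export
time_to_peak <- function(fractions, times) {
  stopifnot(nrow(fractions) == length(times))
  routes <- colnames(fractions) %||% paste0("route", seq_len(ncol(fractions)))
  rows <- lapply(seq_len(ncol(fractions)), function(k) {
    f <- fractions[, k]
    if (all(is.na(f))) stop("route '", routes[k], "': all fractions undefined")
    j <- which.max(f) # first maximum = earliest tie
    tibble::tibble(route = routes[k], time_to_peak = times[j],
                   peak_fraction = f[j])
  })
  dplyr::bind_rows(rows)
}
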