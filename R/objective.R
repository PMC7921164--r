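#' Weighted data misfit for one time segment
#'
#' The data term of the trajectory objective: the weighted sum of squared
#' errors between the model outputs at the segment end and the data
#' interpolants evaluated there, `sum_i ((Y_i - d_i) / sigma_i)^2` over the
#' measured outputs.
#'
#' @param y model output vector at the segment node.
#' @param d interpolant values at the node, same order.
#' @param sigma standard deviations of the data at the node (floored
#'   internally to avoid division by zero).
#' @return a nonnegative scalar.
#' @export
chi_d2 <- function(y, d, sigma) {
  if (length(y) != length(d) || length(y) != length(sigma)) {
    stop("y, d and sigma must have equal length")
  }
  s <- pmax(sigma, 1e-6 * abs(d) + 1e-12)
  sum(((y - d) / s)^2)
}

#' Pearson correlation with a degenerate-variance fallback
#'
#' Plain Pearson correlation, except that when either sequence has (near)
#' zero variance the correlation is defined as 0 - no evidence for or
#' against co-movement - giving the neutral penalty `(1 - 0)^2` in the
#' correlation objective.
#'
#' @param a,b numeric sequences of equal length >= 2.
#' @return a scalar in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("sequences must have equal length")
  if (length(a) < 2L) stop("need at least 2 points for a correlation")
  sa <- sd(a); sb <- sd(b)
  eps_a <- 1e-12 * max(1, max(abs(a)))
  eps_b <- 1e-12 * max(1, max(abs(b)))
  if (!is.finite(sa) || !is.finite(sb) || sa < eps_a || sb < eps_b) return(0)
  r <- cor(a, b)
  min(1, max(-1, r))
}

#' Temporal-correlation objective over a trajectory prefix
#'
#' For each gene-coupled parameter `i`, compares the parameter trajectory up
#' to the current segment with the coupled gene-expression interpolants
#' evaluated at the same segment nodes:
#' `chi_g1^2 = sum_i V_i`, `V_i = (1/N_ci) sum_j (1 - rho_ij)^2` where
#' `rho_ij` is the Pearson correlation of the prefixes. Uncoupled parameters
#' contribute 0. For prefixes shorter than 3 nodes the correlation is
#' ill-defined and the term contributes 0.
#'
#' @param p_prefix matrix of parameter values, parameters in rows, one column
#'   per segment node from 0 to the current segment.
#' @param gene_values matrix of gene interpolant values at the same nodes,
#'   genes in rows (rownames = gene names).
#' @param coupling a [gene_coupling_map()].
#' @return a nonnegative scalar.
#' @export
correlation_objective <- function(p_prefix, gene_values, coupling) {
  stopifnot(is.matrix(p_prefix), is.matrix(gene_values))
  if (ncol(p_prefix) != ncol(gene_values)) {
    stop("parameter and gene prefixes must cover the same nodes")
  }
  if (ncol(p_prefix) < 3L) return(0) # correlation needs >= 3 nodes to bite
  by_par <- .couples_by_parameter(coupling)
  bad <- setdiff(names(by_par), rownames(p_prefix))
  if (length(bad)) stop("coupling references unknown parameter(s): ", toString(bad))
  total <- 0
  for (par in names(by_par)) {
    genes <- by_par[[par]]
    miss <- setdiff(genes, rownames(gene_values))
    if (length(miss)) stop("coupling references unknown gene(s): ", toString(miss))
    rho <- vapply(genes, function(g) pearson(p_prefix[par, ], gene_values[g, ]), 0)
    total <- total + mean((1 - rho)^2)
  }
  total
}

#' Normalized parameter derivative over a segment
#'
#' `P_i = (p_i(n dt) - p_i((n-1) dt)) / (dt * p_i(0))`: the segment-wise
#' rate of change of a parameter relative to its baseline value, so that all
#' parameters are penalized on a comparable scale. The baseline is floored
#' to avoid division by zero.
#'
#' @param p_n,p_prev parameter value at the current and previous node.
#' @param p_0 baseline (t = 0) parameter value.
#' @param dt segment length.
#' @return a scalar.
#' @export
normalized_param_derivative <- function(p_n, p_prev, p_0, dt) {
  (p_n - p_prev) / (dt * .floor_eps(p_0, scale = 1))
}

#' Normalized gene-expression derivative
#'
#' `G_ij = s'(t) / d(0)`: the time derivative of a gene's interpolant
#' normalized by its baseline expression. To keep the fluctuation penalty
#' finite where expression is flat, `|G_ij|` is floored at 1e-6 (an exactly
#' zero derivative is floored to +1e-6; the sign is immaterial downstream
#' since `G` enters squared).
#'
#' @param gene_spline a [fit_smoothing_spline()] object for the gene.
#' @param baseline_value the gene's expression at t = 0 (floored internally).
#' @param t_eval evaluation time within the spline domain.
#' @return a scalar with `|G| >= 1e-6`.
#' @export
normalized_gene_derivative <- function(gene_spline, baseline_value, t_eval) {
  g <- predict(gene_spline, t_eval, deriv = 1) / .floor_eps(baseline_value, scale = 1)
  .floor_gene_derivative(g)
}

.floor_gene_derivative <- function(g) {
  if (abs(g) >= 1e-6) g else if (g < 0) -1e-6 else 1e-6
}

#' Fluctuation penalty for one segment
#'
#' `chi_g2^2 = sum_i W_i` with
#' `W_i = (1/N_ci) sum_j (P_i / G_ij)^2` for gene-coupled parameters: a
#' parameter change is cheap where its genes' expression is itself changing
#' (large `|G|`) and expensive where expression is flat. Uncoupled
#' parameters are penalized by `P_i^2` by default; `eq12_literal = TRUE`
#' uses the unsquared `P_i`, which is sign-dependent and can drive the term
#' negative (kept available for comparability).
#'
#' @param P named vector of normalized parameter derivatives
#'   ([normalized_param_derivative()]), one per parameter.
#' @param G named list: for each coupled parameter, the vector of floored
#'   normalized gene derivatives ([normalized_gene_derivative()]) of its
#'   genes.
#' @param eq12_literal use the unsquared uncoupled branch.
#' @return a scalar (nonnegative unless `eq12_literal`).
#' @export
fluctuation_objective <- function(P, G = list(), eq12_literal = FALSE) {
  total <- 0
  for (par in names(P)) {
    g <- G[[par]]
    if (!is.null(g) && length(g)) {
      total <- total + mean((P[[par]] / g)^2)
    } else {
      total <- total + if (eq12_literal) P[[par]] else P[[par]]^2
    }
  }
  total
}

#' Assemble the full trajectory objective
#'
#' `total = chi_d^2 + lambda_g1 * chi_g1^2 + lambda_g2 * chi_g2^2`, with the
#' components stored separately so that the decomposition identity can be
#' checked on every recorded segment.
#'
#' @param chi_d2,chi_g1,chi_g2 component values.
#' @param lambda_g1,lambda_g2 nonnegative regularization constants.
#' @return a one-row tibble of class `objective_breakdown`.
#' @export
total_objective <- function(chi_d2, chi_g1, chi_g2, lambda_g1, lambda_g2) {
  if (lambda_g1 < 0 || lambda_g2 < 0) stop("regularization constants must be >= 0")
  out <- tibble::tibble(chi_d2 = chi_d2, chi_g1 = chi_g1, chi_g2 = chi_g2,
                        lambda_g1 = lambda_g1, lambda_g2 = lambda_g2,
                        total = chi_d2 + lambda_g1 * chi_g1 + lambda_g2 * chi_g2)
  class(out) <- c("objective_breakdown", class(out))
  out
}
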