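# Precompute everything a trajectory run needs that does not depend on the
# parameters being optimized: interpolant values and data SDs at the segment
# nodes, gene interpolant values and floored normalized derivatives, parsed
# coupling structure.
.adapt_context <- function(model, splines, data, coupling, lambda, n_t, t_end,
                           eq12_literal = FALSE, n_colloc = 1L) {
  data <- longitudinal_dataset(data)
  nodes <- seq(0, t_end, length.out = n_t + 1L)
  dt <- t_end / n_t

  met <- data[data$kind == "metabolic", , drop = FALSE]
  measured <- intersect(names(model$outputs), unique(met$observable))
  # observables measured at a single time point (typically t = 0 only) have
  # no spline: baseline information only, excluded from the trajectory term
  n_times <- vapply(measured, function(o) sum(met$observable == o), 0L)
  measured <- measured[n_times >= 2L]
  if (!length(measured)) stop("no measured metabolic output has a spline")
  if (!all(measured %in% names(splines))) {
    stop("spline sample lacks observable(s): ",
         toString(setdiff(measured, names(splines))))
  }

  colloc <- lapply(seq_len(n_t), function(n) {
    nodes[n] + dt * seq_len(n_colloc) / n_colloc
  })
  all_ct <- unlist(colloc) # segment-major order: rows of segment n are
  colloc_idx <- split(seq_along(all_ct), rep(seq_len(n_t), each = n_colloc))
  d_m <- vapply(measured, function(o) predict(splines[[o]], all_ct),
                numeric(length(all_ct)))
  sig <- vapply(measured, function(o) {
    di <- met[met$observable == o, , drop = FALSE]
    stats::approx(di$time, di$sd, xout = all_ct, rule = 2)$y
  }, numeric(length(all_ct)))
  if (length(all_ct) == 1L) {
    d_m <- matrix(d_m, 1, dimnames = list(NULL, measured))
    sig <- matrix(sig, 1, dimnames = list(NULL, measured))
  }

  genes <- character(0)
  gene_nodes <- NULL
  G <- NULL
  by_par <- list()
  if (!is.null(coupling) && nrow(coupling)) {
    coupling <- validate_coupling(coupling, model = model,
                                  genes = names(splines))
    by_par <- .couples_by_parameter(coupling)
    genes <- unique(coupling$gene)
    gene_nodes <- t(vapply(genes, function(g) predict(splines[[g]], nodes),
                           numeric(length(nodes))))
    rownames(gene_nodes) <- genes
    G <- t(vapply(genes, function(g) {
      base <- predict(splines[[g]], nodes[1])
      raw <- predict(splines[[g]], nodes, deriv = 1) / .floor_eps(base, scale = 1)
      vapply(raw, .floor_gene_derivative, 0)
    }, numeric(length(nodes))))
    rownames(G) <- genes
  }

  # fast objective path for affine mass-action models: precompiled affine
  # basis, flux index tables and a reusable evaluation environment
  basis <- if (.is_affine(model)) .affine_basis(model) else NULL
  flux_tab <- NULL
  if (!is.null(basis)) {
    E <- .expo_matrix(model)
    flux_tab <- list(
      fixed = vapply(model$fluxes, `[[`, 0, "coef"),
      pidx = vapply(model$fluxes, function(f) {
        if (is.null(f$parameter)) 0L else match(f$parameter, model$parameters$name)
      }, 0L),
      sidx = vapply(seq_along(model$fluxes), function(j) {
        k <- which(E[, j] == 1L)
        if (length(k)) k + 1L else 1L # index into c(1, x)
      }, 0L))
  }
  sig_floor <- pmax(sig, 1e-6 * abs(d_m) + 1e-12)

  list(model = model, data = data, nodes = nodes, dt = dt, n_t = n_t,
       measured = measured, colloc = colloc, colloc_idx = colloc_idx,
       all_ct = all_ct, d_m = d_m, sig = sig, sig_floor = sig_floor,
       genes = genes, gene_nodes = gene_nodes, G = G, by_par = by_par,
       lambda = lambda, eq12_literal = eq12_literal,
       basis = basis, flux_tab = flux_tab,
       measured_idx = match(measured, names(model$outputs)))
}


#' Re-estimate the parameters of one time segment
#'
#' Minimizes the combined objective (data misfit at the segment's collocation
#' node(s), plus the correlation and fluctuation regularization terms when
#' their constants are positive) over the model parameters, holding the
#' segment's initial state at the previous segment's final state. The
#' optimizer starts from the previous segment's parameter estimate.
#'
#' Solver failures do not abort: the best iterate is returned with the
#' segment flagged, and the ensemble acceptance filter decides later.
#'
#' @param ctx internal run context (see [run_adapt()] for the user surface).
#' @param n segment index (1-based).
#' @param x_prev state at the segment start.
#' @param p_prev parameter estimate of segment `n - 1`.
#' @param p_prefix matrix of parameter estimates at nodes `0..n-1`
#'   (parameters in rows).
#' @param p0 baseline parameter vector (normalizes the fluctuation penalty).
#' @param control optimizer control list.
#' @return list `p_hat`, `x_end`, `outputs`, `fluxes`, `objective`
#'   (one-row breakdown tibble), `flagged`.
#' @keywords internal
.estimate_segment <- function(ctx, n, x_prev, p_prev, p_prefix, p0,
                              control = list()) {
  model <- ctx$model
  lam <- ctx$lambda
  dt <- ctx$dt
  t_start <- ctx$nodes[n]
  idx <- ctx$colloc_idx[[n]]
  d_n <- ctx$d_m[idx, , drop = FALSE]
  s_n <- ctx$sig[idx, , drop = FALSE]
  ct <- ctx$colloc[[n]]
  pn <- model$parameters$name
  lo <- model$parameters$lower
  up <- model$parameters$upper
  use_g1 <- lam[1] > 0 && length(ctx$by_par) > 0
  use_g2 <- lam[2] > 0
  p0f <- .floor_eps(p0, scale = 1)
  Gn <- if (!is.null(ctx$G)) ctx$G[, n + 1L] else NULL
  gene_prefix <- if (use_g1) ctx$gene_nodes[, seq_len(n + 1L), drop = FALSE] else NULL
  big <- 1e100 # failure sentinel, far above any attainable objective
  s_fl <- ctx$sig_floor[idx, , drop = FALSE]

  segment_outputs <- function(p) {
    sim <- tryCatch(
      simulate_model(model, x_prev, p, c(t_start, ct), check_bounds = FALSE),
      error = function(e) NULL)
    if (is.null(sim)) return(NULL)
    sim
  }
  # measured outputs at the collocation nodes, bypassing simulate_model's
  # per-call bookkeeping (used ~10^2 times per segment by the optimizer)
  fast <- !is.null(ctx$basis)
  ev <- if (fast) new.env(parent = baseenv())
  measured_outputs <- if (!fast) {
    function(p) {
      sim <- segment_outputs(p)
      if (is.null(sim)) return(NULL)
      sim$outputs[-1L, ctx$measured, drop = FALSE]
    }
  } else {
    ft <- ctx$flux_tab
    oexpr <- model$output_expr[ctx$measured_idx]
    n_col <- length(ct)
    function(p) {
      x <- x_prev
      out <- matrix(NA_real_, n_col, length(oexpr))
      tprev <- t_start
      for (i in seq_len(n_col)) {
        x <- tryCatch(.affine_step(ctx$basis, p, x, ct[i] - tprev),
                      error = function(e) NULL)
        tprev <- ct[i]
        if (is.null(x) || any(!is.finite(x))) return(NULL)
        fl <- ft$fixed * c(1, p)[ft$pidx + 1L] * c(1, x)[ft$sidx]
        for (k in seq_along(x)) assign(model$states[k], x[k], envir = ev)
        for (k in seq_along(p)) assign(pn[k], p[k], envir = ev)
        for (k in seq_along(fl)) assign(.flux_names(model)[k], fl[k], envir = ev)
        assign("t", ct[i], envir = ev)
        out[i, ] <- vapply(oexpr, eval, 0, envir = ev)
      }
      out
    }
  }
  # incremental prefix-correlation bookkeeping: within a segment only the
  # candidate value p(n) changes, so the prefix sums are precomputed and the
  # Pearson correlation of each couple costs O(1) per objective evaluation
  g1_pre <- NULL
  if (use_g1 && n + 1L >= 3L) {
    m_nodes <- n + 1L
    g1_pre <- lapply(names(ctx$by_par), function(par) {
      pp <- p_prefix[par, ]
      lapply(ctx$by_par[[par]], function(g) {
        gv <- gene_prefix[g, ]
        gmean <- mean(gv)
        gvar <- mean(gv^2) - gmean^2
        list(par = par, s1 = sum(pp), s2 = sum(pp^2),
             spg = sum(pp * gv[seq_along(pp)]),
             g_last = gv[m_nodes], gmean = gmean,
             gsd = sqrt(max(gvar, 0)), maxg = max(abs(gv)),
             maxp_pre = max(abs(pp)), n_genes = length(ctx$by_par[[par]]),
             m = m_nodes)
      })
    })
    g1_pre <- unlist(g1_pre, recursive = FALSE)
  }
  fast_g1 <- function(p) {
    if (is.null(g1_pre)) return(0)
    total <- 0
    for (cpl in g1_pre) {
      pv <- p[[cpl$par]]
      m <- cpl$m
      mp <- (cpl$s1 + pv) / m
      vp <- (cpl$s2 + pv^2) / m - mp^2
      sp <- sqrt(max(vp, 0))
      eps_p <- 1e-12 * max(1, cpl$maxp_pre, abs(pv))
      eps_g <- 1e-12 * max(1, cpl$maxg)
      rho <- if (sp < eps_p || cpl$gsd < eps_g) 0 else {
        cv <- (cpl$spg + pv * cpl$g_last) / m - mp * cpl$gmean
        min(1, max(-1, cv / (sp * cpl$gsd)))
      }
      total <- total + (1 - rho)^2 / cpl$n_genes
    }
    total
  }
  objective <- function(p) {
    names(p) <- pn
    y <- measured_outputs(p)
    if (is.null(y) || any(!is.finite(y))) return(big)
    cd <- sum(((y - d_n) / s_fl)^2)
    total <- cd
    if (use_g1) {
      total <- total + lam[1] * fast_g1(p)
    }
    if (use_g2) {
      P <- (p - p_prev) / (dt * p0f)
      w <- 0
      for (par in pn) {
        gpar <- ctx$by_par[[par]]
        if (!is.null(gpar) && length(gpar)) {
          w <- w + mean((P[[par]] / Gn[gpar])^2)
        } else {
          w <- w + if (ctx$eq12_literal) P[[par]] else P[[par]]^2
        }
      }
      total <- total + lam[2] * w
    }
    if (!is.finite(total)) big else total
  }

  ctrl <- modifyList(list(iter.max = 1000L, eval.max = 100000L,
                          rel.tol = 1e-10, x.tol = 1e-10), control)
  fit <- nlminb(pmin(pmax(p_prev, lo), up), objective, lower = lo, upper = up,
                control = ctrl)
  p_hat <- setNames(fit$par, pn)
  flagged <- !(fit$convergence %in% c(0L, 1L)) || fit$objective >= big

  sim <- segment_outputs(p_hat)
  if (is.null(sim)) {
    # unrecoverable segment: carry the previous parameters and state forward
    p_hat <- p_prev
    sim <- segment_outputs(p_hat)
    flagged <- TRUE
    if (is.null(sim)) stop("segment ", n, ": integration failed even at the previous estimate")
  }
  nlast <- nrow(sim$states)
  y_end <- sim$outputs[nlast, ]
  cd <- {
    y <- sim$outputs[-1L, ctx$measured, drop = FALSE]
    sum(((y - d_n) / pmax(s_n, 1e-6 * abs(d_n) + 1e-12))^2)
  }
  # record all components at the optimum, whatever entered the optimization
  cg1 <- if (length(ctx$by_par)) {
    .correlation_component(cbind(p_prefix, p_hat),
                           ctx$gene_nodes[, seq_len(n + 1L), drop = FALSE],
                           ctx$by_par)
  } else 0
  P <- (p_hat - p_prev) / (dt * p0f)
  cg2 <- {
    w <- 0
    for (par in pn) {
      gpar <- ctx$by_par[[par]]
      if (!is.null(gpar) && length(gpar)) w <- w + mean((P[[par]] / Gn[gpar])^2)
      else w <- w + if (ctx$eq12_literal) P[[par]] else P[[par]]^2
    }
    w
  }
  list(p_hat = p_hat, x_end = sim$states[nlast, ],
       outputs = y_end, fluxes = sim$fluxes[nlast, ],
       objective = total_objective(cd, cg1, cg2, lam[1], lam[2]),
       flagged = flagged)
}

# correlation component from precomputed structures (no name validation)
.correlation_component <- function(p_prefix, gene_values, by_par) {
  if (ncol(p_prefix) < 3L) return(0)
  total <- 0
  for (par in names(by_par)) {
    genes <- by_par[[par]]
    rho <- vapply(genes, function(g) pearson(p_prefix[par, ], gene_values[g, ]), 0)
    total <- total + mean((1 - rho)^2)
  }
  total
}

#' Estimate a full parameter-trajectory solution
#'
#' The trajectory estimator: the treatment period `[0, t_end]` is divided
#' into `n_t` segments; for each segment the model is simulated from the
#' previous segment's final state and the parameters are re-estimated against
#' the data interpolants, warm-starting from the previous estimate. With
#' positive regularization constants the two gene-expression terms shape the
#' trajectory; with `lambda = c(0, 0)` the estimator reduces exactly to the
#' data-only formulation.
#'
#' @param model a [metabolic_model()].
#' @param baseline_p named baseline parameter vector (from
#'   [calibrate_baseline()]).
#' @param splines one Monte Carlo spline sample: named list of
#'   [fit_smoothing_spline()] objects covering the measured metabolic
#'   observables and any coupled genes.
#' @param data the [longitudinal_dataset()] (metabolic and transcript rows):
#'   supplies measurement SDs for weighting and the acceptance filter.
#' @param coupling optional [gene_coupling_map()].
#' @param lambda numeric pair `c(lambda_g1, lambda_g2)`.
#' @param n_t number of time segments (the printed default of the method is
#'   200).
#' @param t_end treatment horizon (days).
#' @param x0 baseline state; default the steady state at `baseline_p`.
#' @param eq12_literal see [fluctuation_objective()].
#' @param n_colloc collocation points per segment for the data term (default
#'   1: the segment end node).
#' @param control optimizer control overrides.
#' @param sample_index,seed bookkeeping recorded in the solution.
#' @return an `adapt_solution`: parameter/state/output/flux trajectories on
#'   the `n_t + 1` node grid, per-segment objective breakdowns, flags.
#' @export
run_adapt <- function(model, baseline_p, splines, data, coupling = NULL,
                      lambda = c(0, 0), n_t = 200L, t_end = 21,
                      x0 = NULL, eq12_literal = FALSE, n_colloc = 1L,
                      control = list(), sample_index = NA_integer_,
                      seed = NA_integer_) {
  stopifnot(n_t >= 1L, t_end > 0, length(lambda) == 2L, all(lambda >= 0))
  baseline_p <- .check_parameters(model, baseline_p)
  ctx <- .adapt_context(model, splines, data, coupling, lambda, n_t, t_end,
                        eq12_literal = eq12_literal, n_colloc = n_colloc)
  if (is.null(x0)) {
    x0 <- if (!is.null(model$x0)) model$x0 else steady_state(model, baseline_p)
    if (is.null(x0)) stop("no admissible baseline steady state at baseline_p")
  }
  x0 <- x0[model$states]

  np <- nrow(model$parameters)
  P <- matrix(NA_real_, np, n_t + 1L,
              dimnames = list(model$parameters$name, NULL))
  X <- matrix(NA_real_, .n_states(model), n_t + 1L,
              dimnames = list(model$states, NULL))
  Y <- matrix(NA_real_, length(model$outputs), n_t + 1L,
              dimnames = list(names(model$outputs), NULL))
  Fx <- matrix(NA_real_, .n_fluxes(model), n_t + 1L,
               dimnames = list(.flux_names(model), NULL))
  P[, 1] <- baseline_p
  X[, 1] <- x0
  Fx[, 1] <- eval_fluxes(model, x0, baseline_p, times = 0)[1, ]
  Y[, 1] <- eval_outputs(model, x0, baseline_p, times = 0,
                         fluxes = matrix(Fx[, 1], 1, dimnames = list(NULL, rownames(Fx))))[1, ]

  objectives <- vector("list", n_t)
  flagged <- logical(n_t)
  for (n in seq_len(n_t)) {
    est <- .estimate_segment(ctx, n, X[, n], P[, n],
                             P[, seq_len(n), drop = FALSE], baseline_p,
                             control = control)
    P[, n + 1L] <- est$p_hat
    X[, n + 1L] <- est$x_end
    Y[, n + 1L] <- est$outputs
    Fx[, n + 1L] <- est$fluxes
    objectives[[n]] <- est$objective
    flagged[n] <- est$flagged
  }
  obj <- dplyr::bind_rows(objectives)
  obj$segment <- seq_len(n_t)
  obj$flagged <- flagged
  structure(list(parameters = P, states = X, outputs = Y, fluxes = Fx,
                 times = ctx$nodes, objective = obj, lambda = lambda,
                 measured = ctx$measured, sample_index = sample_index,
                 seed = seed, accepted = NA, n_t = n_t, t_end = t_end),
            class = "adapt_solution")
}

#' Data-only trajectory estimation (unregularized code path)
#'
#' Independent implementation of the unregularized estimator (data misfit
#' only); `run_adapt()` with `lambda = c(0, 0)` must agree with it exactly.
#'
#' @inheritParams run_adapt
#' @return an `adapt_solution`.
#' @export
run_adapt_unregularized <- function(model, baseline_p, splines, data,
                                    n_t = 200L, t_end = 21, x0 = NULL,
                                    n_colloc = 1L, control = list(),
                                    sample_index = NA_integer_,
                                    seed = NA_integer_) {
  run_adapt(model, baseline_p, splines, data, coupling = NULL,
            lambda = c(0, 0), n_t = n_t, t_end = t_end, x0 = x0,
            n_colloc = n_colloc, control = control,
            sample_index = sample_index, seed = seed)
}

#' @export
print.adapt_solution <- function(x, ...) {
  cat("<adapt_solution> ", x$n_t, " segments on [0, ", x$t_end, "]; lambda = (",
      format(x$lambda[1], digits = 3), ", ", format(x$lambda[2], digits = 3),
      "); ", sum(x$objective$flagged), " flagged segment(s)\n", sep = "")
  invisible(x)
}

#' Tidy a trajectory solution into long format
#'
#' @param x an `adapt_solution`.
#' @param ... unused.
#' @return tibble `kind, name, time, value` over the segment-node grid.
#' @method tidy adapt_solution
#' @export
tidy.adapt_solution <- function(x, ...) {
  long <- function(mat, what) {
    tibble::as_tibble(t(mat)) |>
      dplyr::mutate(time = x$times, kind = what) |>
      tidyr::pivot_longer(-c("time", "kind"), names_to = "name",
                          values_to = "value")
  }
  dplyr::bind_rows(long(x$parameters, "parameter"), long(x$states, "state"),
                   long(x$outputs, "output"), long(x$fluxes, "flux")) |>
    dplyr::select("kind", "name", "time", "value")
}

#' One-row summary of a trajectory solution
#'
#' @param x an `adapt_solution`.
#' @param ... unused.
#' @return tibble with summed objective components, lambda pair, acceptance
#'   and flag counts.
#' @method glance adapt_solution
#' @export
glance.adapt_solution <- function(x, ...) {
  tibble::tibble(
    n_t = x$n_t, t_end = x$t_end,
    lambda_g1 = x$lambda[1], lambda_g2 = x$lambda[2],
    chi_d2_sum = sum(x$objective$chi_d2),
    chi_g1_sum = sum(x$objective$chi_g1),
    chi_g2_sum = sum(x$objective$chi_g2),
    n_flagged = sum(x$objective$flagged),
    accepted = x$accepted)
}
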