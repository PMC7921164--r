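test_that("data misfit term matches a brute-force loop oracle", {
  expect_equal(chi_d2(c(1, 2), c(1, 2), c(1, 1)), 0)
  expect_equal(chi_d2(c(2, 3), c(1, 1), c(1, 2)), 2)
  expect_error(chi_d2(1:3, 1:2, 1:3), "equal length")
  set.seed(1)
  for (rep in 1:100) {
    y <- rnorm(15); d <- rnorm(15); s <- runif(15, 0.5, 2)
    oracle <- 0
    for (i in 1:15) oracle <- oracle + ((y[i] - d[i]) / s[i])^2
    expect_equal(chi_d2(y, d, s), oracle, tolerance = 1e-12)
  }
})

test_that("pearson correlation: exact cases and the textbook formula", {
  a <- c(1, 2, 3)
  expect_equal(pearson(a, a), 1)
  expect_equal(pearson(a, -a + 7), -1)
  # direct covariance-formula oracle
  b <- c(1, 2, 4)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson(a, b), oracle, tolerance = 1e-12)
  # degenerate variance falls back to 0 (neutral penalty)
  expect_equal(pearson(c(2, 2, 2), b), 0)
  expect_error(pearson(1, 2), "at least 2")
  set.seed(2)
  for (rep in 1:100) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(pearson(x, y), cor(x, y), tolerance = 1e-12)
    expect_true(abs(pearson(x, y)) <= 1)
  }
})

test_that("correlation objective matches a nested-loop oracle", {
  set.seed(3)
  n_nodes <- 6
  p_prefix <- matrix(rnorm(3 * n_nodes, 10), 3, n_nodes,
                     dimnames = list(c("p1", "p2", "p3"), NULL))
  genes <- matrix(rnorm(4 * n_nodes), 4, n_nodes,
                  dimnames = list(c("gA", "gB", "gC", "gD"), NULL))
  # p1 gets two genes, p2 one, p3 uncoupled
  cpl <- gene_coupling_map(tibble::tibble(
    parameter = c("p1", "p1", "p2"), gene = c("gA", "gB", "gC")))
  got <- correlation_objective(p_prefix, genes, cpl)
  oracle <- 0
  for (par in c("p1", "p2")) {
    gs <- cpl$gene[cpl$parameter == par]
    acc <- 0
    for (g in gs) acc <- acc + (1 - cor(p_prefix[par, ], genes[g, ]))^2
    oracle <- oracle + acc / length(gs)
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  # perfectly correlated couples: zero penalty
  genes2 <- genes
  genes2["gA", ] <- 2 * p_prefix["p1", ] + 1
  genes2["gB", ] <- 0.5 * p_prefix["p1", ] - 3
  genes2["gC", ] <- p_prefix["p2", ]
  expect_equal(correlation_objective(p_prefix, genes2, cpl), 0, tolerance = 1e-12)
  # perfectly anticorrelated single couple: (1 - (-1))^2 = 4
  cpl1 <- gene_coupling_map(tibble::tibble(parameter = "p1", gene = "gA"))
  genes3 <- genes
  genes3["gA", ] <- -p_prefix["p1", ]
  expect_equal(correlation_objective(p_prefix, genes3, cpl1), 4, tolerance = 1e-12)
  # short prefix contributes nothing
  expect_equal(correlation_objective(p_prefix[, 1:2], genes[, 1:2], cpl), 0)
  # unknown identifiers rejected
  bad <- gene_coupling_map(tibble::tibble(parameter = "ghost", gene = "gA"))
  expect_error(correlation_objective(p_prefix, genes, bad), "unknown parameter")
})

test_that("normalized derivatives follow their definitions", {
  expect_equal(normalized_param_derivative(2, 2, 2, 0.5), 0)
  expect_equal(normalized_param_derivative(3, 2, 2, 0.5), 1)
  set.seed(4)
  for (rep in 1:50) {
    pn <- runif(1, 0.1, 10); pp <- runif(1, 0.1, 10)
    p0 <- runif(1, 0.1, 10); dt <- runif(1, 0.05, 2)
    expect_equal(normalized_param_derivative(pn, pp, p0, dt),
                 (pn - pp) / (dt * p0), tolerance = 1e-12)
  }
  # gene derivative: linear growth profile d(t) = d0 (1 + t) has G = 1
  s <- fit_smoothing_spline(c(0, 1, 2, 4, 7), 3 * (1 + c(0, 1, 2, 4, 7)), q = 1)
  expect_equal(normalized_gene_derivative(s, 3, 2.5), 1, tolerance = 1e-9)
  # constant profile: derivative 0 floored to +1e-6
  sc <- fit_smoothing_spline(c(0, 1, 2, 4, 7), rep(5, 5), q = 1)
  expect_identical(normalized_gene_derivative(sc, 5, 3), 1e-6)
  # spline derivative vs central finite differences
  set.seed(5)
  sr <- fit_smoothing_spline(c(0, 1, 2, 4, 7), rnorm(5, 10), q = 1)
  h <- 1e-6
  fd <- (predict(sr, 3 + h) - predict(sr, 3 - h)) / (2 * h) / 10
  expect_equal(normalized_gene_derivative(sr, 10, 3), fd, tolerance = 1e-4)
})

test_that("fluctuation penalty matches a nested-loop oracle", {
  P <- c(p1 = 0, p2 = 0, p3 = 0)
  expect_equal(fluctuation_objective(P, list(p1 = c(1, 2))), 0)
  expect_equal(fluctuation_objective(c(p1 = 2), list(p1 = 1)), 4)
  set.seed(6)
  for (rep in 1:100) {
    P <- setNames(rnorm(4), paste0("p", 1:4))
    G <- list(p1 = runif(3, 0.01, 2), p3 = runif(1, 0.01, 2)) # p2, p4 uncoupled
    got <- fluctuation_objective(P, G)
    oracle <- mean((P["p1"] / G$p1)^2) + P[["p2"]]^2 +
      (P[["p3"]] / G$p3)^2 + P[["p4"]]^2
    expect_equal(got, unname(oracle), tolerance = 1e-12)
    # literal (unsquared) uncoupled branch
    got_lit <- fluctuation_objective(P, G, eq12_literal = TRUE)
    oracle_lit <- mean((P["p1"] / G$p1)^2) + P[["p2"]] +
      (P[["p3"]] / G$p3)^2 + P[["p4"]]
    expect_equal(got_lit, unname(oracle_lit), tolerance = 1e-12)
  }
  # penalty is non-increasing in |G| and quadratic in P
  base <- fluctuation_objective(c(p = 1), list(p = 0.5))
  expect_lt(fluctuation_objective(c(p = 1), list(p = 1)), base)
  expect_equal(fluctuation_objective(c(p = 3), list(p = 0.5)), 9 * base)
})

test_that("total objective decomposes exactly", {
  b <- total_objective(2, 4, 1, 0.5, 2)
  expect_equal(b$total, 6)
  expect_equal(total_objective(3.3, 100, 5, 0, 0)$total, 3.3)
  expect_error(total_objective(1, 1, 1, -0.1, 0), ">= 0")
  set.seed(7)
  for (rep in 1:100) {
    v <- runif(5)
    b <- total_objective(v[1], v[2], v[3], v[4], v[5])
    expect_equal(b$total, v[1] + v[4] * v[2] + v[5] * v[3], tolerance = 1e-12)
  }
})

test_that("coupling map I/O and validation", {
  cpl <- gene_coupling_map(tibble::tibble(parameter = c("k_upt", "k_dnl"),
                                          gene = c("g1", "g2")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_coupling_csv(cpl, path)
  expect_equal(tibble::as_tibble(read_coupling_csv(path)),
               tibble::as_tibble(cpl))
  expect_error(gene_coupling_map(tibble::tibble(
    parameter = c("a", "a"), gene = c("g", "g"))), "duplicate")
  expect_error(validate_coupling(cpl, model = toy_lipid_model(),
                                 genes = "g1"), "unknown gene")
})

test_that("baseline calibration recovers a noise-free truth", {
  suite <- benchmark_suite(cv = 0)
  A <- suite$A
  bundle <- scenario_data(A, seed = 1, n_t = 10, refine = 5)
  fit <- calibrate_baseline(A$model, bundle$data, n_scatter = 300,
                            keep_fraction = 0.05, seed = 2)
  expect_lt(fit$sse[1], 1e-6)
  expect_equal(unname(fit$p[[1]]), unname(A$p_base), tolerance = 0.01)
  # count arithmetic: keep fraction determines the number of local runs
  fit2 <- calibrate_baseline(A$model, bundle$data, n_scatter = 100,
                             keep_fraction = 0.1, seed = 2,
                             control = list(iter.max = 5, eval.max = 50))
  expect_lte(nrow(fit2), 10)
  # seeded determinism of the ranked candidate list
  fit3 <- calibrate_baseline(A$model, bundle$data, n_scatter = 300,
                             keep_fraction = 0.05, seed = 2)
  expect_identical(fit$p, fit3$p)
  expect_identical(fit$sse, fit3$sse)
})

test_that("segment estimation sits still at a stationary point", {
  suite <- benchmark_suite(cv = 0)
  A <- suite$A
  bundle <- scenario_data(A, seed = 1, n_t = 10, refine = 5)
  ens <- build_spline_ensemble(bundle$data, 1, seed = 3)
  sol <- run_adapt(A$model, A$p_base, ens$splines[[1]], bundle$data,
                   n_t = 5, t_end = 21)
  # data generated at constant truth, initialized at truth: stays at truth
  expect_equal(sol$parameters, matrix(A$p_base, 7, 6,
                                      dimnames = dimnames(sol$parameters)),
               tolerance = 1e-6)
})

test_that("one-state decay trajectory recovers the closed-form rate", {
  # data: x(t) = e^{-2t} sampled on the segment grid, so the interpolant is
  # exact at every segment end node; the estimator should find p ~ 2
  m <- decay_model()
  times <- seq(0, 2, 0.25)
  d <- longitudinal_dataset(tibble::tibble(
    observable = "y", kind = "metabolic", time = times,
    mean = exp(-2 * times), sd = 0, n = 1L))
  ens <- build_spline_ensemble(d, 1, seed = 1)
  sol <- run_adapt(m, c(k = 2), ens$splines[[1]], d, n_t = 8, t_end = 2,
                   x0 = c(x = 1))
  expect_equal(unname(sol$parameters["k", ]), rep(2, 9), tolerance = 1e-3)
})

test_that("the two code paths coincide bitwise at lambda = (0, 0)", {
  suite <- benchmark_suite()
  B <- suite$B
  bundle <- scenario_data(B, seed = 5, n_t = 10, refine = 5)
  base <- calibrate_baseline(B$model, bundle$data, n_scatter = 200,
                             keep_fraction = 0.05, seed = 2)
  ens <- build_spline_ensemble(bundle$data, 1, seed = 3)
  reg <- run_adapt(B$model, base$p[[1]], ens$splines[[1]], bundle$data,
                   coupling = bundle$coupling, lambda = c(0, 0),
                   n_t = 10, t_end = 21)
  unreg <- run_adapt_unregularized(B$model, base$p[[1]], ens$splines[[1]],
                                   bundle$data, n_t = 10, t_end = 21)
  expect_identical(reg$parameters, unreg$parameters)
  expect_identical(reg$states, unreg$states)
  expect_identical(reg$outputs, unreg$outputs)
})

test_that("objective breakdowns are recorded consistently on every segment", {
  suite <- benchmark_suite()
  B <- suite$B
  bundle <- scenario_data(B, seed = 5, n_t = 10, refine = 5)
  ens <- build_spline_ensemble(bundle$data, 1, seed = 3)
  sol <- run_adapt(B$model, B$p_base, ens$splines[[1]], bundle$data,
                   coupling = bundle$coupling, lambda = c(1e-4, 1e-10),
                   n_t = 8, t_end = 21)
  obj <- sol$objective
  expect_equal(obj$total,
               obj$chi_d2 + obj$lambda_g1 * obj$chi_g1 + obj$lambda_g2 * obj$chi_g2,
               tolerance = 1e-12)
  expect_true(all(obj$chi_d2 >= 0))
  expect_true(all(obj$chi_g1 >= 0))
  # trajectory bookkeeping: column 0 is the baseline, bounds respected
  expect_identical(unname(sol$parameters[, 1]), unname(B$p_base))
  expect_true(all(sol$parameters >= B$model$parameters$lower))
  expect_true(all(sol$parameters <= B$model$parameters$upper))
  expect_equal(length(sol$times), 9)
})
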