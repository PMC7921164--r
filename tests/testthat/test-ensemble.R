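# a fabricated solution on a given node grid, for filter/summary tests
fake_solution <- function(times, outputs, states = NULL, params = NULL,
                          measured = rownames(outputs), lambda = c(0, 0),
                          chi_g1 = runif(length(times) - 1)) {
  n_t <- length(times) - 1L
  structure(list(
    parameters = params %||% matrix(1, 2, n_t + 1,
                                    dimnames = list(c("p1", "p2"), NULL)),
    states = states %||% matrix(1, 2, n_t + 1,
                                dimnames = list(c("s1", "s2"), NULL)),
    outputs = outputs,
    fluxes = matrix(1, 1, n_t + 1, dimnames = list("f1", NULL)),
    times = times, lambda = lambda, measured = measured,
    objective = tibble::tibble(segment = seq_len(n_t),
                               chi_d2 = 0.1, chi_g1 = chi_g1, chi_g2 = 0,
                               lambda_g1 = lambda[1], lambda_g2 = lambda[2],
                               total = 0.1, flagged = FALSE),
    accepted = NA, n_t = n_t, t_end = max(times), sample_index = 1L,
    seed = 1L), class = "adapt_solution")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("acceptance filter applies the closed 95% interval pointwise", {
  d <- make_dataset(obs = "y1", times = c(0, 1, 2), means = c(10, 12, 14),
                    sds = c(1, 1, 1))
  times <- seq(0, 2, 0.5)
  mk <- function(vals_at_data) {
    out <- matrix(0, 1, length(times), dimnames = list("y1", NULL))
    out[1, c(1, 3, 5)] <- vals_at_data
    fake_solution(times, out)
  }
  expect_true(accept(mk(c(10, 12, 14)), d))                 # exact means
  expect_false(accept(mk(c(10, 12 + 2.5, 14)), d))          # 2.5 sd out
  expect_true(accept(mk(c(10 + 1.96, 12, 14)), d))          # boundary: closed
  expect_true(accept(mk(c(10 - 1.96, 12, 14)), d))
  # grid not containing a data time -> coverage error
  d2 <- make_dataset(obs = "y1", times = c(0, 0.75), means = c(10, 12),
                     sds = c(1, 1))
  expect_error(accept(mk(c(10, 12, 14)), d2), "does not contain data time")
})

test_that("solution groups are nested, stable and correctly sized", {
  times <- 0:3
  sols <- lapply(1:10, function(i) {
    out <- matrix(10, 1, 4, dimnames = list("y1", NULL))
    fake_solution(times, out, chi_g1 = rep(i %% 5, 3)) # ties by construction
  })
  ens <- structure(list(
    solutions = sols,
    runs = tibble::tibble(
      run = 1:10, lambda_g1 = c(0, 0, rep(1e-4, 8)),
      lambda_g2 = c(0, 0, rep(1e-9, 8)), sample = 1, baseline = 1,
      failed = FALSE, accepted = TRUE,
      chi_d2_sum = 1,
      chi_g1_sum = vapply(sols, function(s) sum(s$objective$chi_g1), 0),
      chi_g2_sum = 0),
    seed = 1, lambda_range = c(1e-12, 1), p_zero = 0.25),
    class = "solution_ensemble")
  g_all <- group_g(ens, 1)
  expect_equal(nrow(g_all$runs), 10)
  # N = 10, fraction 0.05 -> max(1, floor(0.5)) = 1 member
  g05 <- group_g(ens, 0.05)
  expect_equal(nrow(g05$runs), 1)
  # fraction 0.4 -> 4 members, verified against a full sort oracle
  g4 <- group_g(ens, 0.4)
  ord <- order(ens$runs$chi_g1_sum, ens$runs$run)[1:4]
  expect_setequal(g4$runs$run, ens$runs$run[sort(ord)])
  # ties broken by run index: runs 5 and 10 share chi_g1_sum = 0
  expect_true(5 %in% g4$runs$run && 10 %in% g4$runs$run)
  # nesting G_0.05 within G_0.4 within G_1
  expect_true(all(g05$runs$run %in% g4$runs$run))
  expect_true(all(g4$runs$run %in% g_all$runs$run))
  # G0 contains exactly the lambda = (0, 0) runs
  expect_equal(group_g0(ens)$runs$run, 1:2)
})

test_that("variance reduction matches a direct two-pass variance oracle", {
  times <- 0:4
  mk <- function(scale, seed) {
    set.seed(seed)
    st <- matrix(rnorm(10, sd = scale), 2, 5,
                 dimnames = list(c("s1", "s2"), NULL))
    out <- matrix(0, 1, 5, dimnames = list("y1", NULL))
    fake_solution(times, out, states = st)
  }
  wrap <- function(sols) structure(
    list(solutions = sols,
         runs = tibble::tibble(run = seq_along(sols), lambda_g1 = 0,
                               lambda_g2 = 0, sample = 1, baseline = 1,
                               failed = FALSE, accepted = TRUE,
                               chi_d2_sum = 1, chi_g1_sum = 1, chi_g2_sum = 0),
         seed = 1, lambda_range = c(1e-12, 1), p_zero = 0),
    class = "solution_ensemble")
  grp <- wrap(lapply(1:10, function(i) mk(0.5, i)))
  ref <- wrap(lapply(1:10, function(i) mk(2, 100 + i)))
  vr <- variance_reduction(grp, ref, "s1")
  gvals <- t(vapply(grp$solutions, function(s) s$states["s1", ], numeric(5)))
  rvals <- t(vapply(ref$solutions, function(s) s$states["s1", ], numeric(5)))
  expect_equal(vr$vr, 1 - apply(gvals, 2, var) / apply(rvals, 2, var),
               tolerance = 1e-12)
  expect_true(all(vr$vr <= 1))
  # a group against itself reduces nothing
  vr0 <- variance_reduction(grp, grp, "s1")
  expect_equal(vr0$vr, rep(0, 5), tolerance = 1e-12)
  # identical group members against a varying reference: full reduction
  same <- wrap(lapply(1:5, function(i) mk(0.5, 7)))
  vr1 <- variance_reduction(same, ref, "s1")
  expect_equal(vr1$vr, rep(1, 5), tolerance = 1e-12)
  expect_error(variance_reduction(grp, ref, "nope"), "unknown quantity")
})

test_that("ensemble summaries are robust pointwise statistics", {
  times <- 0:1
  vals <- c(1, 2, 3, 4, 100)
  sols <- lapply(vals, function(v) {
    st <- matrix(v, 2, 2, dimnames = list(c("s1", "s2"), NULL))
    out <- matrix(0, 1, 2, dimnames = list("y1", NULL))
    fake_solution(times, out, states = st)
  })
  ens <- structure(list(
    solutions = sols,
    runs = tibble::tibble(run = 1:5, lambda_g1 = 0, lambda_g2 = 0, sample = 1,
                          baseline = 1, failed = FALSE, accepted = TRUE,
                          chi_d2_sum = 1, chi_g1_sum = 1, chi_g2_sum = 0),
    seed = 1, lambda_range = c(1e-12, 1), p_zero = 0),
    class = "solution_ensemble")
  s <- ensemble_summary(ens, "s1")
  expect_equal(s$median, c(3, 3))
  expect_equal(s$mad, c(1, 1)) # unscaled median absolute deviation
  expect_equal(s$q2.5, rep(quantile(vals, 0.025, names = FALSE), 2))
  expect_equal(s$q97.5, rep(quantile(vals, 0.975, names = FALSE), 2))
  # single solution: median is the value, MAD is 0
  one <- structure(list(solutions = sols[3], runs = ens$runs[3, ],
                        seed = 1, lambda_range = c(1e-12, 1), p_zero = 0),
                   class = "solution_ensemble")
  s1 <- ensemble_summary(one, "s1")
  expect_equal(s1$median, c(3, 3))
  expect_equal(s1$mad, c(0, 0))
})

test_that("lambda scans are reproducible and label G0 correctly", {
  suite <- benchmark_suite()
  B <- suite$B
  bundle <- scenario_data(B, seed = 5, n_t = 7, refine = 5)
  ens <- build_spline_ensemble(bundle$data, 2, seed = 3)
  run_scan <- function(workers) {
    scan_lambdas(B$model, list(B$p_base), ens, bundle$data, bundle$coupling,
                 n_runs = 4, seed = 11, n_t = 7, t_end = 21,
                 workers = workers)
  }
  s1 <- run_scan(1)
  s2 <- run_scan(4) # worker count must never change results
  expect_identical(s1$runs, s2$runs)
  expect_identical(lapply(s1$solutions, `[[`, "parameters"),
                   lapply(s2$solutions, `[[`, "parameters"))
  # forcing lambda = (0, 0) labels every run G0
  s0 <- scan_lambdas(B$model, list(B$p_base), ens, bundle$data, bundle$coupling,
                     n_runs = 3, seed = 11, n_t = 7, t_end = 21,
                     lambda_fixed = matrix(0, 1, 2))
  expect_equal(nrow(group_g0(s0)$runs), 3)
  expect_true(all(s0$runs$lambda_g1 == 0))
})
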