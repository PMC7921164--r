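test_that("exponential decay matches the closed form", {
  m <- decay_model()
  sim <- simulate_model(m, c(x = 1), c(k = 1), c(0, 1))
  expect_equal(unname(sim$states[2, "x"]), exp(-1), tolerance = 1e-6)
  # fluxes and outputs evaluated pointwise on the states
  expect_equal(sim$fluxes[, "f_out"], unname(sim$states[, "x"]))
  expect_equal(sim$outputs[, "y"], unname(sim$states[, "x"]))
  # forced through the adaptive integrator as well
  sim2 <- simulate_model(m, c(x = 1), c(k = 1), c(0, 1), method = "rk45")
  expect_equal(unname(sim2$states[2, "x"]), exp(-1), tolerance = 1e-6)
})

test_that("closed exchange conserves total mass at every eval time", {
  m <- exchange_model()
  sim <- simulate_model(m, c(a = 3, b = 1), c(k1 = 1, k2 = 2), seq(0, 5, 0.25))
  expect_equal(rowSums(sim$states), rep(4, nrow(sim$states)), tolerance = 1e-6)
  sim2 <- simulate_model(m, c(a = 3, b = 1), c(k1 = 1, k2 = 2),
                         seq(0, 5, 0.25), method = "rk45")
  expect_equal(rowSums(sim2$states), rep(4, nrow(sim2$states)), tolerance = 1e-5)
})

test_that("toy model simulation matches a fine-step RK4 oracle", {
  m <- toy_lipid_model()
  p <- toy_p_base(m)
  set.seed(11)
  p <- p * exp(runif(length(p), -0.3, 0.3)) # random admissible perturbation
  x0 <- steady_state(m, toy_p_base(m))
  t_eval <- c(0, 0.5, 1, 2)
  sim <- simulate_model(m, x0, p, t_eval, check_bounds = FALSE)
  oracle <- rk4_oracle(m, x0, p, t_eval, h = 1e-4)
  expect_equal(sim$states, oracle, tolerance = 1e-5, ignore_attr = TRUE)
  # the nonlinear (bimolecular) compiled path against the same oracle
  mb <- bimolecular_model()
  simb <- simulate_model(mb, c(s = 2, p = 0.1), c(k1 = 0.5, k2 = 0.2), t_eval)
  oracleb <- rk4_oracle(mb, c(s = 2, p = 0.1), c(k1 = 0.5, k2 = 0.2), t_eval)
  expect_equal(simb$states, oracleb, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("segment simulation chains like the full flow", {
  m <- decay_model()
  # semigroup: two segments at the same p equal one 2*dt simulation
  s1 <- simulate_segment(m, c(x = 2), c(k = 0.7), 0, 0.8)
  s2 <- simulate_segment(m, s1$x_end, c(k = 0.7), 0.8, 0.8)
  full <- simulate_model(m, c(x = 2), c(k = 0.7), c(0, 1.6))
  expect_equal(unname(s2$x_end), unname(full$states[2, ]), tolerance = 1e-6)
  # half-life construction
  sh <- simulate_segment(m, c(x = 2), c(k = log(2)), 0, 1)
  expect_equal(unname(sh$x_end), 1, tolerance = 1e-6)
})

test_that("piecewise-constant segment chaining matches a concatenated oracle", {
  m <- toy_lipid_model()
  p0 <- toy_p_base(m)
  x0 <- steady_state(m, p0)
  set.seed(21)
  dt <- 0.3
  x <- x0
  states <- list()
  p_list <- lapply(1:10, function(i) p0 * exp(runif(length(p0), -0.2, 0.2)))
  for (n in 1:10) {
    seg <- simulate_segment(m, x, p_list[[n]], (n - 1) * dt, dt)
    x <- seg$x_end
    states[[n]] <- x
  }
  # oracle: fine-step RK4 through the same piecewise system, one segment at
  # a time (independent integrator, not the package's)
  xo <- x0
  for (n in 1:10) {
    xo <- rk4_oracle(m, xo, p_list[[n]], c((n - 1) * dt, n * dt), h = 1e-4)[2, ]
  }
  expect_equal(unname(states[[10]]), unname(xo), tolerance = 1e-5)
})

test_that("flow consistency: split simulation equals direct simulation", {
  m <- bimolecular_model()
  x0 <- c(s = 2, p = 0.1)
  p <- c(k1 = 0.5, k2 = 0.2)
  direct <- simulate_model(m, x0, p, c(0, 2))
  mid <- simulate_model(m, x0, p, c(0, 1))
  chained <- simulate_model(m, mid$states[2, ], p, c(1, 2))
  expect_equal(chained$states[2, ], direct$states[2, ], tolerance = 1e-5)
})

test_that("simulation is deterministic (bit-identical repeats)", {
  m <- toy_lipid_model()
  p <- toy_p_base(m)
  x0 <- steady_state(m, p)
  s1 <- simulate_model(m, x0, p, seq(0, 21, 1))
  s2 <- simulate_model(m, x0, p, seq(0, 21, 1))
  expect_identical(s1$states, s2$states)
  s3 <- simulate_model(m, x0, p, seq(0, 21, 1), method = "rk45")
  s4 <- simulate_model(m, x0, p, seq(0, 21, 1), method = "rk45")
  expect_identical(s3$states, s4$states)
})

test_that("model validation rejects malformed specifications", {
  pars <- tibble::tibble(name = "k", lower = 0, upper = 10, guess = 1)
  # stoichiometry row mismatch
  expect_error(
    metabolic_model(c("x", "z"), pars, matrix(-1, 1, 1),
                    list(flux_mass_action("f", "k", "x")), c(y = "x")),
    "one row per state")
  # undeclared symbol in an output
  expect_error(
    metabolic_model("x", pars, matrix(-1, 1, 1),
                    list(flux_mass_action("f", "k", "x")), c(y = "x + ghost")),
    "undeclared symbol")
  # negative lower bound
  expect_error(
    metabolic_model("x", tibble::tibble(name = "k", lower = -1, upper = 1),
                    matrix(-1, 1, 1), list(flux_mass_action("f", "k", "x")),
                    c(y = "x")),
    "nonnegative")
  # unknown substrate
  expect_error(
    metabolic_model("x", pars, matrix(-1, 1, 1),
                    list(flux_mass_action("f", "k", "ghost")), c(y = "x")),
    "unknown substrate")
  # parameters outside bounds refused at simulation time
  m <- decay_model()
  expect_error(simulate_model(m, c(x = 1), c(k = 1e9), c(0, 1)),
               "outside declared bounds")
})

test_that("integration failure names the first failing time and state", {
  # dx/dt = +k x^2 blows up in finite time (t* = 1/(k x0) = 0.1)
  m <- metabolic_model(
    "x", tibble::tibble(name = "k", lower = 0, upper = 1e3, guess = 1),
    matrix(1, 1, 1), list(flux_mass_action("f", "k", c("x", "x"))),
    c(y = "x"))
  expect_error(simulate_model(m, c(x = 10), c(k = 1), c(0, 1)),
               "integration failed near t = ")
})

test_that("expression fluxes evaluate through the R integrator", {
  # Michaelis-Menten consumption, against the mass-action-free RK4 oracle
  m <- metabolic_model(
    "s", tibble::tibble(name = c("vmax", "km"), lower = 0, upper = 100,
                        guess = c(1, 0.5)),
    matrix(-1, 1, 1), list(flux_expression("uptake", "vmax * s / (km + s)")),
    c(y = "s"))
  sim <- simulate_model(m, c(s = 2), c(vmax = 1, km = 0.5), c(0, 1, 2))
  oracle <- rk4_oracle(m, c(s = 2), c(vmax = 1, km = 0.5), c(0, 1, 2), h = 1e-4)
  expect_equal(sim$states, oracle, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("model JSON spec round-trips losslessly", {
  m <- toy_lipid_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$states, m$states)
  expect_equal(m2$parameters, m$parameters)
  expect_equal(m2$stoichiometry, m$stoichiometry)
  expect_equal(m2$fluxes, m$fluxes)
  expect_equal(m2$outputs, m$outputs)
  # write -> read -> write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model_json(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("steady state solves the balance equations", {
  m <- toy_lipid_model()
  p <- toy_p_base(m)
  x <- steady_state(m, p)
  fl <- eval_fluxes(m, x, p)
  dx <- m$stoichiometry %*% fl[1, ]
  expect_lt(max(abs(dx)), 1e-9)
  # hand-derived values for the baseline parameter set
  expect_equal(unname(x["ffa_plasma"]), 25)
  expect_equal(unname(x["ffa_hep"]), 10)
  expect_equal(unname(x["tg_cyt"]), 60 / 1.7, tolerance = 1e-12)
})
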