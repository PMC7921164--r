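# Small models and independent oracles shared across the suite.

# one-state exponential decay: dx/dt = -k x
decay_model <- function() {
  metabolic_model(
    states = "x",
    parameters = tibble::tibble(name = "k", lower = 0, upper = 100, guess = 1),
    stoichiometry = matrix(-1, 1, 1),
    fluxes = list(flux_mass_action("f_out", "k", "x")),
    outputs = c(y = "x"))
}

# closed two-state exchange: conservation forced by zero column sums
exchange_model <- function() {
  metabolic_model(
    states = c("a", "b"),
    parameters = tibble::tibble(name = c("k1", "k2"), lower = 0, upper = 100,
                                guess = c(1, 2)),
    stoichiometry = cbind(c(-1, 1), c(1, -1)),
    fluxes = list(flux_mass_action("fab", "k1", "a"),
                  flux_mass_action("fba", "k2", "b")),
    outputs = c(total = "a + b"))
}

# nonlinear (bimolecular) model: exercises the compiled RK45 path
bimolecular_model <- function() {
  metabolic_model(
    states = c("s", "p"),
    parameters = tibble::tibble(name = c("k1", "k2"), lower = 0, upper = 100,
                                guess = c(0.5, 0.2)),
    stoichiometry = cbind(c(-2, 1), c(1, -1)),
    fluxes = list(flux_mass_action("dimerize", "k1", c("s", "s")),
                  flux_mass_action("revert", "k2", "p")),
    outputs = c(s_obs = "s", p_obs = "p"))
}

toy_p_base <- function(model = toy_lipid_model()) {
  setNames(model$parameters$guess, model$parameters$name)
}

# independent fixed-step classical RK4 integrator (brute-force oracle)
rk4_oracle <- function(model, x0, p, t_eval, h = 1e-4) {
  p <- setNames(as.numeric(p[model$parameters$name]), model$parameters$name)
  N <- model$stoichiometry
  rhs <- function(x) {
    names(x) <- model$states
    fl <- eval_fluxes(model, matrix(x, 1, dimnames = list(NULL, model$states)), p, 0)
    as.numeric(N %*% fl[1, ])
  }
  out <- matrix(NA_real_, length(t_eval), length(x0))
  out[1, ] <- x0
  x <- as.numeric(x0)
  t <- t_eval[1]
  for (i in seq_along(t_eval)[-1]) {
    span <- t_eval[i] - t
    nstep <- ceiling(span / h)
    hh <- span / nstep
    for (s in seq_len(nstep)) {
      k1 <- rhs(x)
      k2 <- rhs(x + hh / 2 * k1)
      k3 <- rhs(x + hh / 2 * k2)
      k4 <- rhs(x + hh * k3)
      x <- x + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    t <- t_eval[i]
    out[i, ] <- x
  }
  colnames(out) <- model$states
  out
}

# smoothing-spline objective evaluated numerically (oracle for fit quality)
spline_objective_oracle <- function(sfun, times, values, sds, q,
                                    grid_n = 4001) {
  w <- 1 / pmax(sds, 1e-6 * abs(values) + 1e-12)^2
  fit <- sum(w * (values - sfun(times))^2)
  pad <- (max(times) - min(times)) * 1e-3
  grid <- seq(min(times) + pad, max(times) - pad, length.out = grid_n)
  h <- grid[2] - grid[1]
  d2 <- (sfun(grid + h / 2) - 2 * sfun(grid) + sfun(grid - h / 2)) / (h / 2)^2
  rough <- sum(d2^2) * h
  q * fit + (1 - q) * rough
}
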