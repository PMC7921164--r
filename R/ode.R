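# Pure-R Dormand-Prince 5(4) adaptive integrator: fallback path for models
# with expression-based rate laws. Same tableau and controller as the
# compiled mass-action path.
.ode_rk45_r <- function(rhs, x0, t_eval, atol = 1e-6, rtol = 1e-6) {
  ns <- length(x0)
  nt <- length(t_eval)
  out <- matrix(NA_real_, nt, ns)
  out[1, ] <- x0
  if (nt == 1L) return(out)

  A <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656))
  Cc <- c(1 / 5, 3 / 10, 4 / 5, 8 / 9, 1)
  B5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  B4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200, 187 / 2100, 1 / 40)

  t <- t_eval[1]
  x <- x0
  span <- t_eval[nt] - t
  h <- span * 0.01
  hmin <- max(span, 1) * 1e-14
  hmax <- span * 0.1
  k1 <- rhs(t, x)
  next_out <- 2L
  n_steps <- 0L

  while (next_out <= nt) {
    while (next_out <= nt && t_eval[next_out] - t <= 1e-12 * max(1, abs(t))) {
      out[next_out, ] <- x
      next_out <- next_out + 1L
    }
    if (next_out > nt) break
    if (t + h > t_eval[next_out]) h <- t_eval[next_out] - t

    K <- matrix(0, 7, ns)
    K[1, ] <- k1
    for (s in 2:6) {
      xs <- x + h * drop(A[[s - 1]] %*% K[seq_len(s - 1), , drop = FALSE])
      K[s, ] <- rhs(t + Cc[s - 1] * h, xs)
    }
    x5 <- x + h * drop(B5[1:6] %*% K[1:6, , drop = FALSE])
    K[7, ] <- rhs(t + h, x5)
    x4 <- x + h * drop(B4 %*% K)
    sc <- atol + rtol * pmax(abs(x), abs(x5))
    err <- sqrt(mean(((x5 - x4) / sc)^2))

    if (!all(is.finite(x5))) {
      h <- h / 4
      if (h < hmin) {
        stop(sprintf("integration failed near t = %.6g (state '%s')",
                     t, which(!is.finite(x5))[1]))
      }
      next
    }
    if (err <= 1) {
      t_new <- t + h
      if (abs(t_eval[next_out] - t_new) <= 1e-9 * max(1, abs(t_new))) {
        out[next_out, ] <- x5
        next_out <- next_out + 1L
      }
      t <- t_new
      x <- x5
      k1 <- K[7, ]
      n_steps <- n_steps + 1L
      if (n_steps > 2e6) stop(sprintf("integration failed near t = %.6g (step limit)", t))
      h <- h * min(5, 0.9 * max(err, 1e-10)^-0.2)
      h <- min(h, hmax)
    } else {
      h <- h * max(0.2, 0.9 * err^-0.2)
      if (h < hmin) {
        stop(sprintf("integration failed near t = %.6g (step underflow)", t))
      }
    }
  }
  out
}
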