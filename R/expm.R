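# Exact propagation for models affine in the states (every mass-action flux
# of total order <= 1): dx/dt = A x + b is solved by the matrix exponential
# of the augmented system [[A, b], [0, 0]], scaling-and-squaring with a
# Pade approximant. Unconditionally stable, so optimizer excursions into
# stiff parameter regions cost nothing.

# Pade(6,6) scaling-and-squaring matrix exponential (dense, small matrices)
.expm <- function(M) {
  n <- nrow(M)
  nrm <- max(rowSums(abs(M)))
  s <- 0L
  if (nrm > 0.5) {
    s <- max(0L, ceiling(log2(nrm / 0.5)))
    M <- M / 2^s
  }
  c_ <- c(1, 1 / 2, 5 / 44, 1 / 66, 1 / 792, 1 / 15840, 1 / 665280)
  I <- diag(n)
  M2 <- M %*% M
  M4 <- M2 %*% M2
  M6 <- M4 %*% M2
  U <- M %*% (c_[2] * I + c_[4] * M2 + c_[6] * M4)
  V <- c_[1] * I + c_[3] * M2 + c_[5] * M4 + c_[7] * M6
  E <- solve(V - U, V + U)
  for (k in seq_len(s)) E <- E %*% E
  E
}

# A (ns x ns) and b for an affine mass-action model at parameters p
.affine_system <- function(model, p) {
  E <- .expo_matrix(model)
  if (!all(colSums(E) <= 1L)) return(NULL)
  N <- model$stoichiometry
  coefs <- .flux_coefs(model, p)
  ns <- .n_states(model)
  A <- matrix(0, ns, ns)
  b <- numeric(ns)
  for (j in seq_len(ncol(E))) {
    sub <- which(E[, j] == 1L)
    if (length(sub) == 1L) A[, sub] <- A[, sub] + N[, j] * coefs[j]
    else b <- b + N[, j] * coefs[j]
  }
  list(A = A, b = b)
}

.is_affine <- function(model) {
  .is_mass_action(model) && all(colSums(.expo_matrix(model)) <= 1L)
}

# propagate an affine system over the eval grid; exact to machine precision
.simulate_affine <- function(model, x0, p, eval_times) {
  sys <- .affine_system(model, p)
  ns <- length(x0)
  M <- rbind(cbind(sys$A, sys$b), 0)
  nt <- length(eval_times)
  out <- matrix(NA_real_, nt, ns)
  out[1, ] <- x0
  if (nt == 1L) return(out)
  dts <- diff(eval_times)
  x <- c(as.numeric(x0), 1)
  E_prev <- NULL
  dt_prev <- NA_real_
  for (i in seq_len(nt - 1L)) {
    if (!identical(dts[i], dt_prev)) { # uniform grids reuse one exponential
      E_prev <- .expm(M * dts[i])
      dt_prev <- dts[i]
    }
    x <- E_prev %*% x
    out[i + 1L, ] <- x[seq_len(ns)]
  }
  if (any(!is.finite(out))) {
    stop(sprintf("integration failed near t = %.6g (state '%s')",
                 eval_times[which(rowSums(!is.finite(out)) > 0)[1]],
                 model$states[which(colSums(!is.finite(out)) > 0)[1]]))
  }
  out
}


# affine basis: A(p) = A0 + sum_k p_k A_k (same for b); assembled once per
# run so each objective evaluation only scales and sums small matrices
.affine_basis <- function(model) {
  E <- .expo_matrix(model)
  if (!all(colSums(E) <= 1L)) return(NULL)
  N <- model$stoichiometry
  ns <- .n_states(model)
  pn <- model$parameters$name
  A0 <- matrix(0, ns, ns); b0 <- numeric(ns)
  Ak <- setNames(lapply(pn, function(z) matrix(0, ns, ns)), pn)
  bk <- setNames(lapply(pn, function(z) numeric(ns)), pn)
  for (j in seq_along(model$fluxes)) {
    f <- model$fluxes[[j]]
    sub <- which(E[, j] == 1L)
    if (is.null(f$parameter)) {
      if (length(sub) == 1L) A0[, sub] <- A0[, sub] + N[, j] * f$coef
      else b0 <- b0 + N[, j] * f$coef
    } else {
      if (length(sub) == 1L) {
        Ak[[f$parameter]][, sub] <- Ak[[f$parameter]][, sub] + N[, j] * f$coef
      } else {
        bk[[f$parameter]] <- bk[[f$parameter]] + N[, j] * f$coef
      }
    }
  }
  list(A0 = A0, b0 = b0, Ak = Ak, bk = bk, pn = pn)
}

# propagate x over one interval dt with the basis-assembled affine system
.affine_step <- function(basis, p, x, dt) {
  A <- basis$A0; b <- basis$b0
  for (k in seq_along(basis$pn)) {
    pk <- p[[k]]
    if (pk != 0) {
      A <- A + pk * basis$Ak[[k]]
      b <- b + pk * basis$bk[[k]]
    }
  }
  M <- rbind(cbind(A, b), 0)
  E <- .expm(M * dt)
  drop(E[seq_along(x), , drop = FALSE] %*% c(x, 1))
}
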