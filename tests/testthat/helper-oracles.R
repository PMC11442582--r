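# Independent numerical oracles used to cross-check the package's analytic
# and adaptive-solver code paths.

# Central finite-difference Jacobian of rhs().
fd_jacobian <- function(state, params, h = 1e-6) {
  J <- matrix(0, 6L, 6L)
  for (j in 1:6) {
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (rhs(up, params) - rhs(dn, params)) / (2 * h)
  }
  dimnames(J) <- list(senliver::STATE_VARS, senliver::STATE_VARS)
  J
}

# Fixed-step classical 4th-order Runge-Kutta integrator, written directly
# against rhs(); independent of deSolve.
rk4_integrate <- function(params, y0, t_end, h) {
  n <- ceiling(t_end / h)
  y <- as.numeric(y0)
  out <- matrix(NA_real_, n + 1L, 6L)
  out[1L, ] <- y
  f <- function(y) unname(rhs(y, params))
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1L, ] <- y
  }
  list(times = seq(0, by = h, length.out = n + 1L), states = out)
}

# Short-horizon solver configuration for tests that only need the transient.
quick_cfg <- function(t_end = 60, n_save = 241L, ...) {
  solver_config(t_end = t_end, n_save = n_save, ...)
}

# The reference-parameter critical threshold is expensive; compute it once
# per test run.
ref_threshold <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- critical_senescence(model_params())
    val
  }
})

# A cached medium-dose trajectory shared by several tests.
medium_traj <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_injury(model_params(),
                                              initial_condition(1.4),
                                              solver_config())
    val
  }
})
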