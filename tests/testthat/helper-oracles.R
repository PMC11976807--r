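# Independent numerical oracles for the closed-form kinetic model.

# Numerical ODE solution of dC/dt = k_in * 1(t <= t_in) - k_e * C, C(0) = 0,
# integrated segment-wise so the input discontinuity at t_in is an exact
# breakpoint, not a stiffness event.
ode_concentration <- function(params, t, rtol = 1e-10, atol = 1e-12) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  deriv <- function(time, state, p) {
    input <- if (time <= p$t_in) p$k_in else 0
    list(input - p$k_e * state)
  }
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    c0 <- 0
    if (tt <= params$t_in) {
      out <- deSolve::lsoda(c(C = 0), c(0, tt), deriv, params,
                            rtol = rtol, atol = atol)
      return(out[nrow(out), "C"])
    }
    out1 <- deSolve::lsoda(c(C = 0), c(0, params$t_in), deriv, params,
                           rtol = rtol, atol = atol)
    c_tin <- unname(out1[nrow(out1), "C"])
    out2 <- deSolve::lsoda(c(C = c_tin), c(params$t_in, tt), deriv, params,
                           rtol = rtol, atol = atol)
    out2[nrow(out2), "C"]
  }, numeric(1))
}

# adaptive-quadrature interval average of the closed-form curve
quad_interval_average <- function(params, start, end, tol = 1e-10) {
  stats::integrate(function(t) pk_concentration(params, t), start, end,
                   rel.tol = tol, abs.tol = 0)$value / (end - start)
}

# dense-grid trapezoid AUC of the closed-form curve
trapezoid_auc <- function(params, t_last, dt = 0.01) {
  tt <- seq(0, t_last, by = dt)
  cc <- pk_concentration(params, tt)
  sum((cc[-1] + cc[-length(cc)]) / 2) * dt
}

# random but physiologically plausible parameter draws
random_pk_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pk_params(k_in = exp(stats::runif(1, log(0.003), log(0.1))),
              t_in = stats::runif(1, 60, 150),
              k_e = log(2) / stats::runif(1, 12, 50))
  })
}

# small noise-free experiment used by several estimation tests
noise_free_experiment <- function(seed = 7, n_animals = 8) {
  cfg <- generator_config(n_animals = n_animals,
                          residual_log_sd = 0,
                          re_sd = c(log_k_in = 0, log_k_e = 0),
                          failure_prob = 0)
  generate_experiment(cfg, seed = seed)
}
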