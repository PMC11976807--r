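test_that("starting values land near the truth on a noise-free curve", {
  p <- pk_params(0.05, 110, log(2) / 30)
  sch <- default_sampling_schedule()
  obs <- data.frame(t_start_min = sch$start_min, t_end_min = sch$end_min,
                    c_tissue_ug_ml = pk_interval_average(p, sch$start_min,
                                                         sch$end_min))
  sv <- starting_values(obs)
  expect_lt(abs(sv$k_in / p$k_in - 1), 0.25)
  expect_lt(abs(sv$t_in / p$t_in - 1), 0.25)
  expect_lt(abs(sv$k_e / p$k_e - 1), 0.25)
})

test_that("starting values fall back to the default elimination rate without post-peak data", {
  obs <- data.frame(t_start_min = c(0, 30, 60, 90),
                    t_end_min = c(30, 60, 90, 120),
                    c_tissue_ug_ml = c(0.1, 0.2, 0.3, 0.4)) # monotone rise
  sv <- starting_values(obs)
  expect_equal(sv$k_e, log(2) / 30)
  expect_error(starting_values(data.frame(t_start_min = 0:3, t_end_min = 1:4,
                                          c_tissue_ug_ml = rep(0, 4))),
               "positive observations")
})

test_that("noise-free data recover the generating parameters almost exactly", {
  ex <- noise_free_experiment(seed = 7)
  obs <- apply_recovery(ex$observations, estimate_recovery(ex$calibration))
  tru <- default_truth()
  for (tt in c("peritoneum_1", "rectum_profound", "liver_1")) {
    f <- fit_tissue(obs, tt)
    expect_true(f$converged)
    expect_lt(abs(f$params$k_in / tru[[tt]]$k_in - 1), 1e-3)
    expect_lt(abs(f$params$t_in / tru[[tt]]$t_in - 1), 1e-3)
    expect_lt(abs(f$params$k_e / tru[[tt]]$k_e - 1), 1e-3)
    # identical animals: between-animal variability collapses to the floor
    expect_lt(f$re_sd[["log_k_in"]], 0.01)
    expect_lt(f$re_sd[["log_k_e"]], 0.01)
    # per-catheter derived parameters match the truth's derived values
    pc <- per_catheter_parameters(f)
    dtruth <- pk_derived(tru[[tt]], t_last = 480)
    expect_equal(median(pc$auc_0_last), dtruth$auc_0_last, tolerance = 1e-3)
    expect_equal(median(pc$c_max), dtruth$c_max, tolerance = 1e-3)
    expect_equal(median(pc$t_half), dtruth$t_half, tolerance = 1e-3)
  }
})

test_that("the fit is invariant to the row order of the observation table", {
  cfg <- generator_config(n_animals = 5, failure_prob = 0)
  ex <- generate_experiment(cfg, seed = 3)
  obs <- apply_recovery(ex$observations, estimate_recovery(ex$calibration))
  f1 <- fit_tissue(obs, "liver_1")
  set.seed(99)
  obs_shuffled <- obs[sample(nrow(obs)), , drop = FALSE]
  f2 <- fit_tissue(obs_shuffled, "liver_1")
  expect_equal(f1$fixef, f2$fixef, tolerance = 1e-10)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-10)
})

test_that("the optimised likelihood is no worse than at the starting values", {
  cfg <- generator_config(n_animals = 6, failure_prob = 0)
  ex <- generate_experiment(cfg, seed = 5)
  obs <- apply_recovery(ex$observations, estimate_recovery(ex$calibration))
  for (tt in c("liver_2", "stomach_profound")) {
    f <- fit_tissue(obs, tt)
    expect_gte(f$logLik, -f$optim$start_objective - 1e-8)
  }
})

test_that("the Laplace marginal likelihood agrees with a quadrature oracle", {
  cfg <- generator_config(n_animals = 4, failure_prob = 0)
  ex <- generate_experiment(cfg, seed = 11)
  obs <- apply_recovery(ex$observations, estimate_recovery(ex$calibration))
  d <- obs[obs$tissue == "peritoneum_2", ]
  split_data <- lapply(split(d, d$animal_id),
                       function(x) list(y = log(x$c_tissue_ug_ml),
                                        start = x$t_start_min,
                                        end = x$t_end_min))
  tru <- default_truth()$peritoneum_2

  # independent oracle: the model is linear in the k_in deviation, so that
  # integral is an exact Gaussian convolution; the k_e deviation is then
  # integrated by adaptive quadrature
  quad_nll <- function(theta) {
    s1 <- exp(theta[4]); s2 <- exp(theta[5]); sig <- exp(theta[6])
    nll <- 0
    for (dd in split_data) {
      n <- length(dd$y)
      log_marg_b2 <- function(b2) {
        lu <- hipecpk:::log_unit_prediction(theta[2], theta[3] + b2,
                                            dd$start, dd$end, "interval")
        z <- dd$y - theta[1] - lu
        zb <- mean(z)
        -(n / 2) * log(2 * pi * sig^2) - sum((z - zb)^2) / (2 * sig^2) +
          0.5 * log(2 * pi * sig^2 / n) +
          stats::dnorm(zb, 0, sqrt(s1^2 + sig^2 / n), log = TRUE) +
          stats::dnorm(b2, 0, s2, log = TRUE)
      }
      M <- stats::optimize(function(b) -log_marg_b2(b), c(-2, 2))$objective * -1
      li <- stats::integrate(function(b) exp(vapply(b, log_marg_b2, 0) - M),
                             -2, 2, rel.tol = 1e-10)$value
      nll <- nll - (M + log(li))
    }
    nll
  }

  # with a near-degenerate k_e random effect the model is linear in the
  # remaining k_in effect, so the Laplace approximation is exact
  theta_lin <- c(log(tru$k_in), log(tru$t_in), log(tru$k_e),
                 log(0.4), log(1e-3), log(0.2))
  expect_equal(hipecpk:::laplace_nll(theta_lin, split_data, "interval"),
               quad_nll(theta_lin), tolerance = 1e-6)

  # with both random effects active the Laplace approximation is close but
  # not exact; agreement to ~2% of the log-likelihood
  theta <- c(log(tru$k_in), log(tru$t_in), log(tru$k_e),
             log(0.4), log(0.15), log(0.2))
  expect_equal(hipecpk:::laplace_nll(theta, split_data, "interval"),
               quad_nll(theta), tolerance = 0.02)
})

test_that("fixed effects agree with an independent nonlinear mixed-effects fit", {
  skip_if_not_installed("nlme")
  cfg <- generator_config(n_animals = 8, failure_prob = 0,
                          residual_log_sd = 0.15)
  ex <- generate_experiment(cfg, seed = 21)
  obs <- apply_recovery(ex$observations, estimate_recovery(ex$calibration))
  d <- obs[obs$tissue == "peritoneum_3", ]
  d$logc <- log(d$c_tissue_ug_ml)
  f <- fit_tissue(obs, "peritoneum_3")

  # nlme() evaluates the model expression in its own environment, so the
  # mean function must be reachable from the global search path
  assign("pk_log_mean_fn", function(lkin, ltin, lke, t_start_min, t_end_min) {
    lkin + hipecpk:::log_unit_prediction(ltin, lke, t_start_min, t_end_min,
                                         "interval")
  }, envir = globalenv())
  withr::defer(rm("pk_log_mean_fn", envir = globalenv()))
  nf <- nlme::nlme(logc ~ pk_log_mean_fn(lkin, ltin, lke, t_start_min, t_end_min),
                   fixed = lkin + ltin + lke ~ 1,
                   random = nlme::pdDiag(lkin + lke ~ 1),
                   groups = ~animal_id,
                   data = d,
                   start = unname(f$optim$start[1:3]),
                   control = nlme::nlmeControl(maxIter = 200, pnlsTol = 1e-3))
  expect_equal(unname(f$fixef), unname(nlme::fixef(nf)), tolerance = 0.05)
})

test_that("insufficient data raise explicit errors", {
  ex <- noise_free_experiment(seed = 1, n_animals = 1)
  obs <- apply_recovery(ex$observations, estimate_recovery(ex$calibration))
  expect_error(fit_tissue(obs, "liver_1"), ">=2 animals")
  expect_error(fit_tissue(obs, "no_such_tissue"), "no usable observations")
})

test_that("estimation error of log k_e shrinks with more animals", {
  errs <- sapply(c(4, 16), function(n_animals) {
    mean(sapply(1:3, function(r) {
      cfg <- generator_config(n_animals = n_animals, failure_prob = 0)
      ex <- generate_experiment(cfg, seed = 100 + r)
      obs <- apply_recovery(ex$observations, estimate_recovery(ex$calibration))
      f <- fit_tissue(obs, "liver_1")
      abs(f$fixef[["log_k_e"]] - log(default_truth()$liver_1$k_e))
    }))
  })
  expect_lt(errs[2], errs[1])
})
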