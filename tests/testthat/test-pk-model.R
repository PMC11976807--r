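test_that("concentration curve starts at zero and plateaus at k_in/k_e", {
  p <- pk_params(k_in = 0.1, t_in = 1e6, k_e = 0.02)
  expect_equal(pk_concentration(p, 0), 0)
  expect_equal(pk_concentration(p, 5000), 5.0, tolerance = 1e-12)
  expect_error(pk_concentration(p, -1), "non-negative")
  expect_error(pk_params(-1, 10, 0.1), "k_in")
  expect_error(pk_params(1, 0, 0.1), "t_in")
  expect_error(pk_params(1, 10, 0), "k_e")
})

test_that("closed form matches a numerical ODE oracle", {
  skip_if_not_installed("deSolve")
  # the worked example: k_in = 0.03, k_e = ln2/30, t_in = 110 at t = 240
  p <- pk_params(0.03, 110, log(2) / 30)
  expect_equal(pk_concentration(p, 240), ode_concentration(p, 240),
               tolerance = 1e-9)
  for (p in random_pk_params(30, seed = 3)) {
    tt <- c(15, p$t_in / 2, p$t_in, p$t_in + 1, 240, 480)
    expect_equal(pk_concentration(p, tt), ode_concentration(p, tt),
                 tolerance = 1e-7)
  }
})

test_that("curve is continuous, rises to a unique peak at t_in, then decays", {
  for (p in random_pk_params(20, seed = 5)) {
    eps <- 1e-9
    expect_equal(pk_concentration(p, p$t_in - eps),
                 pk_concentration(p, p$t_in + eps), tolerance = 1e-6)
    tt <- seq(1, 480, by = 1)
    cc <- pk_concentration(p, tt)
    rising <- tt < p$t_in
    falling <- tt > p$t_in
    expect_true(all(diff(cc[rising]) > 0))
    expect_true(all(diff(cc[falling]) < 0))
    expect_equal(pk_derived(p)$t_max, p$t_in)
  }
})

test_that("interval averages match adaptive quadrature, including straddling intervals", {
  # example straddling the input cutoff
  p <- pk_params(0.05, 100, 0.03)
  expect_equal(pk_interval_average(p, 90, 120),
               quad_interval_average(p, 90, 120), tolerance = 1e-9)
  for (p in random_pk_params(20, seed = 9)) {
    ivs <- rbind(c(0, 30), c(p$t_in - 10, p$t_in + 10), c(240, 300), c(420, 480))
    for (i in seq_len(nrow(ivs))) {
      expect_equal(pk_interval_average(p, ivs[i, 1], ivs[i, 2]),
                   quad_interval_average(p, ivs[i, 1], ivs[i, 2]),
                   tolerance = 1e-8)
    }
  }
  # plateau regime: the average of a constant is that constant
  pp <- pk_params(0.1, 1e7, 0.05)
  expect_equal(pk_interval_average(pp, 4e5, 5e5), 0.1 / 0.05, tolerance = 1e-9)
  # vanishing interval at the origin
  expect_lt(pk_interval_average(pk_params(0.05, 100, 0.02), 0, 1e-6), 1e-6)
  expect_error(pk_interval_average(p, 50, 50), "start < end")
})

test_that("analytic AUC matches dense trapezoidal integration", {
  p <- pk_params(0.05, 110, 0.03)
  expect_equal(pk_auc(p, 480), trapezoid_auc(p, 480), tolerance = 1e-6)
  for (p in random_pk_params(8, seed = 13)) {
    expect_equal(pk_auc(p, 480), trapezoid_auc(p, 480), tolerance = 1e-6)
  }
})

test_that("derived parameters follow their definitions", {
  p <- pk_params(0.05, 110, log(2) / 30)
  d <- pk_derived(p, t_last = 480)
  expect_equal(d$t_half, 30)
  expect_equal(d$t_max, 110)
  expect_equal(d$c_max, pk_concentration(p, 110))
  p0 <- pk_params(0, 110, 0.02)
  d0 <- pk_derived(p0)
  expect_equal(d0$c_max, 0)
  expect_equal(d0$auc_0_last, 0)
  expect_warning(dlate <- pk_derived(pk_params(0.05, 200, 0.02), t_last = 150),
                 "clamped")
  expect_equal(dlate$t_max, 150)
})

test_that("scaling the input rate scales concentrations and AUC but not times", {
  for (p in random_pk_params(10, seed = 17)) {
    k <- 3.7
    ps <- pk_params(k * p$k_in, p$t_in, p$k_e)
    tt <- c(30, 120, 300)
    expect_equal(pk_concentration(ps, tt), k * pk_concentration(p, tt))
    d <- pk_derived(p); ds <- pk_derived(ps)
    expect_equal(ds$auc_0_last, k * d$auc_0_last)
    expect_equal(ds$c_max, k * d$c_max)
    expect_equal(ds$t_max, d$t_max)
    expect_equal(ds$t_half, d$t_half)
  }
})

test_that("observable summaries invert exactly through the closed form", {
  for (p in random_pk_params(10, seed = 21)) {
    d <- pk_derived(p)
    q <- pk_params_from_observables(d$c_max, d$t_max, d$t_half)
    expect_equal(q$k_in, p$k_in, tolerance = 1e-10)
    expect_equal(q$t_in, p$t_in)
    expect_equal(q$k_e, p$k_e, tolerance = 1e-12)
  }
})

test_that("central-compartment mapping reproduces depletion windows", {
  # contiguous case: content 110 units at rate 1 -> single window, t_in 110
  m <- map_central_parameterization(
    c0_central = 55, transfer_rate = 1,
    doses = data.frame(time_min = c(30, 60), amount = c(27.5, 27.5)),
    k_e = 0.02)
  expect_equal(m$params$t_in, 110)
  expect_equal(nrow(m$windows), 1)
  expect_equal(m$windows$end_min, 110)

  # no drug at all
  m0 <- map_central_parameterization(0, 1, data.frame(time_min = numeric(),
                                                      amount = numeric()),
                                     k_e = 0.02)
  expect_equal(m0$params$k_in, 0)

  # staggered boluses with a depletion gap between dose 1 and dose 2
  mg <- map_central_parameterization(
    c0_central = 10, transfer_rate = 1,
    doses = data.frame(time_min = 30, amount = 20), k_e = 0.02)
  expect_equal(nrow(mg$windows), 2)
  expect_equal(mg$windows$start_min, c(0, 30))
  expect_equal(mg$windows$end_min, c(10, 50))
  expect_equal(mg$params$t_in, 30)

  # oracle: fine-step discrete-event simulation of the central content
  sim_windows <- function(c0, rate, doses, dt = 0.001, t_end = 200) {
    tt <- seq(0, t_end, by = dt)
    content <- c0
    active <- logical(length(tt))
    for (i in seq_along(tt)) {
      hit <- which(abs(doses$time_min - tt[i]) < dt / 2)
      if (length(hit)) content <- content + sum(doses$amount[hit])
      active[i] <- content > 0
      content <- max(content - rate * dt, 0)
    }
    sum(active) * dt
  }
  expect_equal(mg$params$t_in,
               sim_windows(10, 1, data.frame(time_min = 30, amount = 20)),
               tolerance = 1e-2)

  expect_error(map_central_parameterization(5, 0, data.frame(time_min = 0,
                                                             amount = 1),
                                            k_e = 0.02),
               "infinite")
})
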