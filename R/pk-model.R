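#' Structural kinetic parameters of the tissue model
#'
#' The tissue concentration follows a two-compartment structure observed
#' only in the peripheral (tissue) compartment: the perfusate supplies drug
#' at a constant (zero-order) rate for a finite input duration, and the
#' tissue eliminates drug by a first-order process. Because only the tissue
#' is observed, the central compartment's initial content, transfer rate
#' and dose amounts are not separately identifiable and collapse into
#' three parameters:
#'
#' * `k_in` — zero-order rise rate of the tissue concentration
#'   (µg·mL⁻¹·min⁻¹);
#' * `t_in` — duration of the input window (min);
#' * `k_e` — first-order elimination rate constant (min⁻¹).
#'
#' See [map_central_parameterization()] for the mapping from the
#' central-compartment view.
#'
#' @param k_in Zero-order input rate, >= 0.
#' @param t_in Input duration in minutes, > 0.
#' @param k_e Elimination rate constant in 1/min, > 0.
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(k_in, t_in, k_e) {
  if (!is.numeric(k_in) || k_in < 0) stop("`k_in` must be >= 0", call. = FALSE)
  if (!is.numeric(t_in) || t_in <= 0) stop("`t_in` must be > 0", call. = FALSE)
  if (!is.numeric(k_e) || k_e <= 0) stop("`k_e` must be > 0", call. = FALSE)
  structure(list(k_in = k_in, t_in = t_in, k_e = k_e), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("pk_params: k_in = %.4g ug/mL/min, t_in = %.4g min, k_e = %.4g /min (t_half = %.3g min)\n",
              x$k_in, x$t_in, x$k_e, log(2) / x$k_e))
  invisible(x)
}

#' Tissue concentration at time t
#'
#' Closed-form solution of `dC/dt = k_in * 1(t <= t_in) - k_e * C` with
#' `C(0) = 0`:
#' \deqn{C(t) = (k_{in}/k_e)(1 - e^{-k_e t}), \quad t \le t_{in}}
#' \deqn{C(t) = C(t_{in}) e^{-k_e (t - t_{in})}, \quad t > t_{in}}
#' The curve rises to a unique peak at `t = t_in` and decays exponentially
#' afterwards.
#'
#' @param params A [pk_params()].
#' @param t Time(s) in minutes, >= 0. Vectorised.
#' @return Concentration(s) in µg/mL.
#' @export
pk_concentration <- function(params, t) {
  stopifnot(inherits(params, "pk_params"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  a <- params$k_in / params$k_e
  cmax <- a * (1 - exp(-params$k_e * params$t_in))
  ifelse(t <= params$t_in,
         a * (1 - exp(-params$k_e * t)),
         cmax * exp(-params$k_e * (t - params$t_in)))
}

# cumulative integral of the concentration curve from 0 to t (vectorised)
pk_auc_cumulative <- function(params, t) {
  k_in <- params$k_in; t_in <- params$t_in; k_e <- params$k_e
  a <- k_in / k_e
  cmax <- a * (1 - exp(-k_e * t_in))
  rise <- function(u) a * u - (a / k_e) * (1 - exp(-k_e * u))
  ifelse(t <= t_in,
         rise(t),
         rise(t_in) + (cmax / k_e) * (1 - exp(-k_e * (t - t_in))))
}

#' Area under the concentration curve
#'
#' Analytic integral of [pk_concentration()] from `from` to `to`; with the
#' defaults this is the model-based AUC from time zero.
#'
#' @param params A [pk_params()].
#' @param to Upper limit (min).
#' @param from Lower limit (min), default 0.
#' @return AUC in µg·min/mL.
#' @export
pk_auc <- function(params, to, from = 0) {
  stopifnot(inherits(params, "pk_params"))
  if (from < 0 || to < from) stop("need 0 <= from <= to", call. = FALSE)
  pk_auc_cumulative(params, to) - pk_auc_cumulative(params, from)
}

#' Average concentration over a collection interval
#'
#' A microdialysis sample physically integrates the tissue concentration
#' over its collection window, so the model prediction for a sample is the
#' interval average, computed from the analytic antiderivative of the
#' piecewise curve (intervals straddling `t_in` are handled exactly).
#'
#' @param params A [pk_params()].
#' @param start,end Interval bounds in minutes, `0 <= start < end`.
#'   Vectorised in parallel.
#' @return Mean concentration over each interval (µg/mL).
#' @export
pk_interval_average <- function(params, start, end) {
  stopifnot(inherits(params, "pk_params"))
  if (any(start < 0) || any(start >= end)) {
    stop("need 0 <= start < end", call. = FALSE)
  }
  area <- pk_auc_cumulative(params, end) - pk_auc_cumulative(params, start)
  area / (end - start)
}

#' Derived pharmacokinetic parameters
#'
#' Model-based summary parameters of one fitted curve:
#' `t_max = t_in` (the unique peak), `c_max = C(t_in)`,
#' `t_half = ln(2)/k_e`, and `auc_0_last` as the analytic integral of the
#' curve from 0 to the last sampling time. If the observation window ends
#' before the peak (`t_last <= t_in`) the peak is not reached within the
#' window; `t_max` is clamped to `t_last` with a warning.
#'
#' @param params A [pk_params()].
#' @param t_last Last sampling time (min), default 480.
#' @return A list with elements `auc_0_last`, `c_max`, `t_max`, `t_half`.
#' @export
pk_derived <- function(params, t_last = 480) {
  stopifnot(inherits(params, "pk_params"))
  if (t_last <= params$t_in) {
    warning("t_last <= t_in: peak not reached within the sampling window; ",
            "t_max clamped to t_last", call. = FALSE)
    t_max <- t_last
  } else {
    t_max <- params$t_in
  }
  list(auc_0_last = pk_auc(params, to = t_last),
       c_max = pk_concentration(params, t_max),
       t_max = t_max,
       t_half = log(2) / params$k_e)
}

#' Kinetic parameters from observable summaries
#'
#' Inverts the closed form: given a target peak concentration, peak time
#' and half-life, returns the `(k_in, t_in, k_e)` that produce them.
#' Used to turn published medians into generator truth.
#'
#' @param c_max Peak concentration (µg/mL).
#' @param t_max Peak time (min).
#' @param t_half Half-life (min).
#' @return A [pk_params()].
#' @export
pk_params_from_observables <- function(c_max, t_max, t_half) {
  k_e <- log(2) / t_half
  k_in <- c_max * k_e / (1 - exp(-k_e * t_max))
  pk_params(k_in = k_in, t_in = t_max, k_e = k_e)
}

#' Map the central-compartment parameterization to (k_in, t_in, k_e)
#'
#' The mechanistic description of the experiment tracks the central
#' (perfusate) compartment: an initial drug content, bolus additions at
#' scheduled times, and depletion at a constant zero-order transfer rate
#' into the tissue. From tissue observations alone this is structurally
#' unidentifiable; what is identifiable is the input rate seen by the
#' tissue (`k_in = transfer_rate * volume_scale`) and the total duration
#' the central compartment is non-empty.
#'
#' The function runs an exact event-driven depletion of the central
#' content: between boluses the content falls linearly at `transfer_rate`;
#' when it hits zero the input switches off until the next bolus. It
#' returns both the active input windows and the contiguous-equivalent
#' parameters (`t_in` = total active input time). Under the default bolus
#' schedule the windows are contiguous and `t_in` is simply
#' `total content / transfer_rate`.
#'
#' @param c0_central Initial central content (same units as bolus amounts).
#' @param transfer_rate Zero-order depletion rate of the central content
#'   per minute, > 0 whenever any content is present.
#' @param doses Data frame or matrix with columns `time_min`, `amount`
#'   (may be empty).
#' @param k_e Elimination rate constant (1/min) carried through to the
#'   returned parameter set.
#' @param volume_scale Dimensionless factor converting the central
#'   depletion rate into the tissue concentration rise rate.
#' @return A list with `params` (a [pk_params()]) and `windows`, a data
#'   frame of active input intervals (`start_min`, `end_min`).
#' @export
map_central_parameterization <- function(c0_central, transfer_rate, doses,
                                         k_e, volume_scale = 1) {
  doses <- as.data.frame(doses)
  if (nrow(doses) == 0) doses <- data.frame(time_min = numeric(), amount = numeric())
  stopifnot(all(c("time_min", "amount") %in% names(doses)))
  if (c0_central < 0 || any(doses$amount < 0) || transfer_rate < 0 ||
      volume_scale < 0) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  total <- c0_central + sum(doses$amount)
  if (transfer_rate == 0) {
    if (total > 0) stop("zero transfer rate with positive content gives an infinite input duration",
                        call. = FALSE)
    return(list(params = pk_params(0, t_in = 1, k_e = k_e),
                windows = data.frame(start_min = numeric(), end_min = numeric())))
  }
  doses <- doses[order(doses$time_min), , drop = FALSE]
  # event-driven depletion: exact window endpoints, no discretisation
  content <- c0_central
  t_now <- 0
  open_at <- if (content > 0) 0 else NA_real_
  windows <- list()
  events <- rbind(doses[, c("time_min", "amount")],
                  data.frame(time_min = Inf, amount = 0))
  for (i in seq_len(nrow(events))) {
    t_ev <- events$time_min[i]
    if (content > 0) {
      t_empty <- t_now + content / transfer_rate
      if (t_empty <= t_ev) {
        windows[[length(windows) + 1]] <- c(open_at, t_empty)
        open_at <- NA_real_
        content <- 0
        t_now <- t_empty
      } else {
        content <- content - transfer_rate * (t_ev - t_now)
        t_now <- t_ev
      }
    }
    if (is.finite(t_ev)) {
      t_now <- max(t_now, t_ev)
      if (events$amount[i] > 0) {
        if (content == 0) open_at <- t_ev
        content <- content + events$amount[i]
      }
    }
  }
  win <- if (length(windows)) {
    as.data.frame(do.call(rbind, windows)) |> setNames(c("start_min", "end_min"))
  } else {
    data.frame(start_min = numeric(), end_min = numeric())
  }
  t_in <- sum(win$end_min - win$start_min)
  k_in <- transfer_rate * volume_scale
  if (t_in <= 0) {
    params <- pk_params(0, t_in = 1, k_e = k_e)
  } else {
    params <- pk_params(k_in, t_in = t_in, k_e = k_e)
  }
  list(params = params, windows = win)
}
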