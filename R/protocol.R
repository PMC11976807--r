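#' Body surface area of a pig from body weight
#'
#' Allometric power law for swine, `SA = 0.0970 * W^0.633`, with `W` the
#' body weight in kg and `SA` in m². Used to convert a dose intensity in
#' mg/m² into an absolute dose.
#'
#' @param weight_kg Body weight in kg; must be positive. Vectorised.
#' @return Body surface area in m².
#' @examples
#' body_surface_area(60) # 1.295 m^2
#' @export
body_surface_area <- function(weight_kg) {
  if (!is.numeric(weight_kg) || any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("`weight_kg` must be a positive finite number", call. = FALSE)
  }
  0.0970 * weight_kg^0.633
}

#' HIPEC protocol specification
#'
#' Bundles the dosing and sampling protocol of a HIPEC experiment: animal
#' weight, dose intensity, the fractionated bolus schedule, the perfusion
#' end time, the dialysate collection intervals and the assay LLOQ.
#'
#' The default protocol is the porcine experiment emulated throughout the
#' package: 100 mg/m² total dose split 50/25/25 % at 0/30/60 min, 90 min of
#' perfusion, 12 collection intervals (every 30 min from 0 to 240 min, then
#' every 60 min to 480 min) and an LLOQ of 0.030 µg/mL.
#'
#' @param body_weight_kg Animal body weight (kg), positive.
#' @param dose_per_m2 Dose intensity (mg/m²), non-negative.
#' @param dose_fractions Two-column matrix or data frame with columns
#'   `time_min` and `fraction`; fractions must sum to 1 within 1e-9.
#' @param perfusion_end_min Time (min) at which the perfusate is drained.
#' @param sampling_intervals Two-column matrix or data frame with columns
#'   `start_min`, `end_min`; intervals must be contiguous, non-overlapping
#'   and strictly increasing.
#' @param lloq_ug_per_ml Lower limit of quantification (µg/mL).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(body_weight_kg = 60,
                          dose_per_m2 = 100,
                          dose_fractions = default_dose_fractions(),
                          perfusion_end_min = 90,
                          sampling_intervals = default_sampling_schedule(),
                          lloq_ug_per_ml = 0.030) {
  dose_fractions <- as.data.frame(dose_fractions)
  sampling_intervals <- as.data.frame(sampling_intervals)
  stopifnot(all(c("time_min", "fraction") %in% names(dose_fractions)),
            all(c("start_min", "end_min") %in% names(sampling_intervals)))
  if (!is.numeric(body_weight_kg) || length(body_weight_kg) != 1 || body_weight_kg <= 0) {
    stop("`body_weight_kg` must be a single positive number", call. = FALSE)
  }
  if (dose_per_m2 < 0) stop("`dose_per_m2` must be non-negative", call. = FALSE)
  if (abs(sum(dose_fractions$fraction) - 1) > 1e-9) {
    stop("dose fractions must sum to 1", call. = FALSE)
  }
  s <- sampling_intervals
  if (any(s$end_min <= s$start_min)) {
    stop("sampling intervals must have end > start", call. = FALSE)
  }
  if (nrow(s) > 1 &&
      (any(diff(s$start_min) <= 0) ||
       any(abs(s$start_min[-1] - s$end_min[-nrow(s)]) > 1e-9))) {
    stop("sampling intervals must be contiguous and strictly increasing", call. = FALSE)
  }
  structure(
    list(body_weight_kg = body_weight_kg,
         dose_per_m2 = dose_per_m2,
         dose_fractions = dose_fractions,
         perfusion_end_min = perfusion_end_min,
         sampling_intervals = s,
         lloq_ug_per_ml = lloq_ug_per_ml),
    class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("HIPEC protocol:", x$dose_per_m2, "mg/m2,",
      nrow(x$dose_fractions), "boluses,",
      "perfusion to", x$perfusion_end_min, "min,",
      nrow(x$sampling_intervals), "sampling intervals, LLOQ",
      x$lloq_ug_per_ml, "ug/mL\n")
  invisible(x)
}

#' Default fractionated bolus schedule
#'
#' 50 % of the total dose at time 0, then 25 % at 30 min and 25 % at 60 min.
#'
#' @return Data frame with columns `time_min`, `fraction`.
#' @export
default_dose_fractions <- function() {
  data.frame(time_min = c(0, 30, 60), fraction = c(0.50, 0.25, 0.25))
}

#' Total administered dose
#'
#' Dose intensity (mg/m²) times the body surface area computed from the
#' animal's weight.
#'
#' @param spec A [protocol_spec()].
#' @return Total dose in mg.
#' @export
total_dose <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  spec$dose_per_m2 * body_surface_area(spec$body_weight_kg)
}

#' Bolus dose events
#'
#' Expands the fractionated schedule into absolute (time, dose) events.
#' Event doses always sum to [total_dose()].
#'
#' @param spec A [protocol_spec()].
#' @return Data frame with columns `time_min`, `dose_mg`.
#' @export
dose_events <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  d <- total_dose(spec)
  data.frame(time_min = spec$dose_fractions$time_min,
             dose_mg = spec$dose_fractions$fraction * d)
}

#' Default dialysate sampling schedule
#'
#' Eight 30-min collection intervals covering 0–240 min followed by four
#' 60-min intervals covering 240–480 min: 12 samples per catheter, with
#' time zero at the start of HIPEC.
#'
#' @return Data frame with columns `start_min`, `end_min` (12 rows).
#' @export
default_sampling_schedule <- function() {
  start <- c(seq(0, 210, by = 30), seq(240, 420, by = 60))
  end <- c(seq(30, 240, by = 30), seq(300, 480, by = 60))
  data.frame(start_min = start, end_min = end)
}
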