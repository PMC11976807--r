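#' Relative recovery from a retrodialysis calibration sample
#'
#' In retrodialysis-by-drug the perfusate contains a known drug
#' concentration and the fractional loss across the membrane estimates the
#' catheter's relative recovery:
#' `RR = 100 * (1 - C_dialysate / C_perfusate)` (percent).
#'
#' @param c_perfusate Drug concentration entering the catheter (µg/mL), > 0.
#' @param c_dialysate Drug concentration leaving the catheter (µg/mL), >= 0.
#' @return Relative recovery in percent. Values outside (0, 100] indicate a
#'   malfunctioning probe; see [estimate_recovery()] for the exclusion rule.
#' @export
relative_recovery <- function(c_perfusate, c_dialysate) {
  if (any(!is.finite(c_perfusate)) || any(c_perfusate <= 0)) {
    stop("`c_perfusate` must be positive", call. = FALSE)
  }
  if (any(c_dialysate < 0)) stop("`c_dialysate` must be non-negative", call. = FALSE)
  100 * (1 - c_dialysate / c_perfusate)
}

#' Absolute tissue concentration from a dialysate concentration
#'
#' Microdialysis samples only a fraction of the true extracellular
#' concentration; the calibrated relative recovery back-corrects it:
#' `C_tissue = 100 * C_dialysate / RR`.
#'
#' @param c_dialysate Dialysate concentration (µg/mL), >= 0. Vectorised.
#' @param rr_percent Relative recovery in percent, in (0, 100]. Vectorised.
#' @return Tissue concentration (µg/mL).
#' @export
tissue_concentration <- function(c_dialysate, rr_percent) {
  if (any(!is.finite(rr_percent)) || any(rr_percent <= 0)) {
    stop("`rr_percent` must be positive", call. = FALSE)
  }
  if (any(c_dialysate < 0)) stop("`c_dialysate` must be non-negative", call. = FALSE)
  100 * c_dialysate / rr_percent
}

#' Per-catheter relative recovery from calibration records
#'
#' Each catheter contributes one or more retrodialysis samples (typically
#' two, C1 and C2); the catheter's recovery is the mean of the per-sample
#' recoveries. Recoveries outside (0, 100] are physically impossible and
#' mark the catheter as malfunctioning (`valid = FALSE`); such catheters
#' are excluded downstream.
#'
#' @param calibration Data frame with columns `animal_id`, `catheter_id`,
#'   `tissue`, `c_perfusate_ug_ml`, `c_dialysate_ug_ml` (and optionally
#'   `sample_label`).
#' @return Data frame with one row per catheter: `animal_id`,
#'   `catheter_id`, `tissue`, `rr_percent`, `n_samples`, `valid`.
#' @export
estimate_recovery <- function(calibration) {
  req <- c("animal_id", "catheter_id", "tissue",
           "c_perfusate_ug_ml", "c_dialysate_ug_ml")
  if (!all(req %in% names(calibration))) {
    stop("calibration table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  rr <- relative_recovery(calibration$c_perfusate_ug_ml,
                          calibration$c_dialysate_ug_ml)
  key <- interaction(calibration$animal_id, calibration$catheter_id, drop = TRUE)
  agg <- lapply(split(seq_len(nrow(calibration)), key), function(idx) {
    m <- mean(rr[idx])
    data.frame(animal_id = calibration$animal_id[idx[1]],
               catheter_id = calibration$catheter_id[idx[1]],
               tissue = calibration$tissue[idx[1]],
               rr_percent = m,
               n_samples = length(idx),
               valid = is.finite(m) && m > 0 && m <= 100)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$animal_id, out$catheter_id), , drop = FALSE]
}

#' Pool recoveries per tissue compartment
#'
#' Arithmetic mean and sample SD (n-1 denominator) of the per-catheter
#' relative recoveries in each compartment, the layout of a published
#' recovery table. Invalid catheters are dropped first; compartments left
#' empty are omitted with a warning. A single-catheter compartment reports
#' `NA` for the SD.
#'
#' @param recovery Output of [estimate_recovery()].
#' @param by Column to group by (default `"tissue"`).
#' @return Data frame with columns `compartment`, `mean_rr`, `sd_rr`, `n`.
#' @export
pool_recovery <- function(recovery, by = "tissue") {
  stopifnot(by %in% names(recovery), "rr_percent" %in% names(recovery))
  if ("valid" %in% names(recovery)) {
    dropped <- unique(recovery[[by]][!recovery$valid])
    recovery <- recovery[recovery$valid, , drop = FALSE]
    gone <- setdiff(dropped, unique(recovery[[by]]))
    if (length(gone)) {
      warning("no valid calibration left for: ", paste(gone, collapse = ", "),
              call. = FALSE)
    }
  }
  groups <- split(recovery$rr_percent, recovery[[by]])
  out <- data.frame(
    compartment = names(groups),
    mean_rr = vapply(groups, mean, numeric(1)),
    sd_rr = vapply(groups, function(v) if (length(v) > 1) sd(v) else NA_real_,
                   numeric(1)),
    n = vapply(groups, length, integer(1)))
  rownames(out) <- NULL
  out
}

#' Convert a dialysate observation table to tissue concentrations
#'
#' Joins per-catheter recoveries onto the raw observation table, converts
#' dialysate to tissue concentrations with [tissue_concentration()], drops
#' catheters whose calibration was invalid, and applies the chosen
#' below-LLOQ policy.
#'
#' @param observations Data frame with columns `animal_id`, `tissue`,
#'   `catheter_id`, `t_start_min`, `t_end_min`, `c_dialysate_ug_ml`,
#'   `censored`.
#' @param recovery Output of [estimate_recovery()].
#' @param lloq_handling One of `"exclude"` (default: censored rows are
#'   removed), `"impute_half"` (censored dialysate values replaced by
#'   LLOQ/2 before correction) or `"keep"` (rows retained, flag untouched).
#' @param lloq LLOQ in µg/mL, needed for `"impute_half"`.
#' @return The observation table with an added `c_tissue_ug_ml` column and
#'   the `rr_percent` used for each row.
#' @export
apply_recovery <- function(observations, recovery,
                           lloq_handling = c("exclude", "impute_half", "keep"),
                           lloq = 0.030) {
  lloq_handling <- match.arg(lloq_handling)
  keep <- recovery[recovery$valid, c("animal_id", "catheter_id", "rr_percent")]
  obs <- merge(observations, keep, by = c("animal_id", "catheter_id"))
  if (nrow(obs) == 0) stop("no observations with a valid calibration", call. = FALSE)
  cens <- as.logical(obs$censored)
  if (lloq_handling == "exclude") {
    obs <- obs[!cens, , drop = FALSE]
  } else if (lloq_handling == "impute_half") {
    obs$c_dialysate_ug_ml[cens] <- lloq / 2
  }
  obs$c_tissue_ug_ml <- tissue_concentration(obs$c_dialysate_ug_ml, obs$rr_percent)
  obs[order(obs$animal_id, obs$tissue, obs$catheter_id, obs$t_start_min), ,
      drop = FALSE]
}
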