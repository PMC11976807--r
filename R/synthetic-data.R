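#' Reference pharmacokinetic medians for the porcine HIPEC experiment
#'
#' Published per-compartment medians (AUC from time zero to the last
#' sample in µg·min/mL, half-life and peak time in minutes, peak
#' concentration in µg/mL) from the porcine cisplatin HIPEC experiment the
#' generator emulates. These drive [default_truth()] and serve as printed
#' inputs for ratio arithmetic.
#'
#' @return Data frame with columns `compartment`, `organ`, `n`,
#'   `auc_0_last`, `t_half`, `c_max`, `t_max`.
#' @export
reference_pk_table <- function() {
  read.csv(system.file("extdata", "reference_pk_medians.csv",
                       package = "hipecpk"))
}

#' Reference relative recoveries per compartment
#'
#' Published mean (SD) retrodialysis recoveries for the nine catheter
#' compartments; drives the generator's recovery distributions.
#'
#' @return Data frame with columns `compartment`, `organ`, `mean_rr`,
#'   `sd_rr`.
#' @export
reference_recovery_table <- function() {
  read.csv(system.file("extdata", "reference_recovery.csv",
                       package = "hipecpk"))
}

#' Default catheter layout
#'
#' One catheter per compartment per animal: two liver catheters at the
#' same depth, superficial and profound catheters in rectum and stomach,
#' and three peritoneal catheters in different abdominal quadrants — nine
#' planned catheters per animal.
#'
#' @return Data frame with columns `compartment`, `organ`.
#' @export
default_catheter_layout <- function() {
  ref <- reference_pk_table()
  ref[, c("compartment", "organ")]
}

#' True population kinetic parameters per tissue
#'
#' Converts the published per-compartment medians (peak concentration,
#' peak time, half-life) into `(k_in, t_in, k_e)` through the closed-form
#' inverse [pk_params_from_observables()]. These are the generator's
#' population medians.
#'
#' @return Named list of [pk_params()], one per compartment.
#' @export
default_truth <- function() {
  ref <- reference_pk_table()
  out <- lapply(seq_len(nrow(ref)), function(i) {
    pk_params_from_observables(c_max = ref$c_max[i], t_max = ref$t_max[i],
                               t_half = ref$t_half[i])
  })
  names(out) <- ref$compartment
  out
}

#' Configuration of the synthetic-experiment generator
#'
#' The defaults reproduce the design of the porcine experiment: 8 animals,
#' the nine-compartment catheter layout, population kinetics consistent
#' with the published medians, per-compartment recovery distributions
#' matching the published means and SDs (truncated to (0, 100]),
#' between-animal log-scale SDs of 0.4 on `k_in` and 0.15 on `k_e`, a
#' residual log-SD of 0.2 (the assay's ~20% intermediary precision), a
#' per-catheter failure probability of 19/62, and censoring below an LLOQ
#' of 0.030 µg/mL.
#'
#' @param n_animals Number of animals.
#' @param layout Catheter layout (see [default_catheter_layout()]).
#' @param truth Named list of population [pk_params()] per compartment.
#' @param recovery Data frame with `compartment`, `mean_rr`, `sd_rr`.
#' @param re_sd Named numeric: between-animal SDs on `log_k_in`, `log_k_e`.
#' @param residual_log_sd Residual SD of log dialysate concentrations.
#' @param failure_prob Probability a planned catheter is lost (displaced
#'   or malfunctioning) and contributes no data.
#' @param lloq Lower limit of quantification (µg/mL).
#' @param perfusate_conc Retrodialysis perfusate concentration (µg/mL).
#' @param miscalibrated_rr_sd Log-scale SD of calibration-sample noise;
#'   0 (default) makes the calibration recover each catheter's true RR
#'   exactly, so corrupt-then-correct is an identity.
#' @param n_calibration_samples Calibration samples per catheter (C1, C2).
#' @param sampling Collection-interval schedule.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_animals = 8,
                             layout = default_catheter_layout(),
                             truth = default_truth(),
                             recovery = reference_recovery_table(),
                             re_sd = c(log_k_in = 0.4, log_k_e = 0.15),
                             residual_log_sd = 0.2,
                             failure_prob = 19 / 62,
                             lloq = 0.030,
                             perfusate_conc = 10,
                             miscalibrated_rr_sd = 0,
                             n_calibration_samples = 2,
                             sampling = default_sampling_schedule()) {
  if (n_animals < 1) stop("need at least one animal", call. = FALSE)
  stopifnot(failure_prob >= 0, failure_prob <= 1,
            residual_log_sd >= 0, all(re_sd >= 0), lloq >= 0,
            all(layout$compartment %in% names(truth)),
            all(layout$compartment %in% recovery$compartment))
  structure(list(n_animals = n_animals, layout = layout, truth = truth,
                 recovery = recovery, re_sd = re_sd,
                 residual_log_sd = residual_log_sd,
                 failure_prob = failure_prob, lloq = lloq,
                 perfusate_conc = perfusate_conc,
                 miscalibrated_rr_sd = miscalibrated_rr_sd,
                 n_calibration_samples = n_calibration_samples,
                 sampling = sampling),
            class = "generator_config")
}

# truncated-normal draw on (lo, hi] by rejection; deterministic under the
# current RNG state
rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 100) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x > lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Generate a complete in-silico HIPEC microdialysis experiment
#'
#' For each animal and compartment, draws individual kinetic parameters
#' log-normally around the population medians (`t_in` is common to the
#' compartment, matching the estimation model), draws a true relative
#' recovery per catheter, simulates interval-average tissue concentrations
#' from the closed-form model, attenuates them by RR/100 and multiplies
#' log-normal measurement noise to produce dialysate values, censors
#' values below the LLOQ, and removes failed catheters entirely.
#' Calibration records reproduce each surviving catheter's retrodialysis
#' samples. Fully deterministic given `(config, seed)`.
#'
#' @param config A [generator_config()].
#' @param seed Integer RNG seed.
#' @return A list with `observations` (dialysate table), `calibration`
#'   (retrodialysis table) and `truth` (per-catheter true parameters,
#'   recoveries and failure flags).
#' @export
generate_experiment <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  lay <- config$layout
  sch <- config$sampling
  rec <- config$recovery
  obs_list <- list(); cal_list <- list(); truth_list <- list()
  for (a in seq_len(config$n_animals)) {
    animal <- sprintf("pig_%02d", a)
    for (k in seq_len(nrow(lay))) {
      comp <- lay$compartment[k]
      pop <- config$truth[[comp]]
      b_kin <- rnorm(1, 0, config$re_sd[["log_k_in"]])
      b_ke <- rnorm(1, 0, config$re_sd[["log_k_e"]])
      p_i <- pk_params(pop$k_in * exp(b_kin), pop$t_in, pop$k_e * exp(b_ke))
      r <- rec[rec$compartment == comp, ]
      rr_true <- rtrunc_norm(1, r$mean_rr, r$sd_rr)
      failed <- rbinom(1, 1, config$failure_prob) == 1
      noise <- rnorm(nrow(sch), 0, config$residual_log_sd)
      cal_noise <- rnorm(config$n_calibration_samples, 0,
                         config$miscalibrated_rr_sd)
      cath <- paste0(animal, "_", comp)
      truth_list[[cath]] <- data.frame(
        animal_id = animal, tissue = comp, catheter_id = cath,
        k_in = p_i$k_in, t_in = p_i$t_in, k_e = p_i$k_e,
        rr_percent = rr_true, failed = failed)
      if (failed) next
      avg <- pk_interval_average(p_i, sch$start_min, sch$end_min)
      c_dial <- avg * rr_true / 100 * exp(noise)
      obs_list[[cath]] <- data.frame(
        animal_id = animal, tissue = comp, catheter_id = cath,
        t_start_min = sch$start_min, t_end_min = sch$end_min,
        c_dialysate_ug_ml = c_dial,
        censored = c_dial < config$lloq)
      cal_dial <- config$perfusate_conc * (1 - rr_true / 100) * exp(cal_noise)
      cal_list[[cath]] <- data.frame(
        animal_id = animal, tissue = comp, catheter_id = cath,
        sample_label = paste0("C", seq_len(config$n_calibration_samples)),
        c_perfusate_ug_ml = config$perfusate_conc,
        c_dialysate_ug_ml = cal_dial)
    }
  }
  bindrows <- function(x) {
    if (!length(x)) return(NULL)
    out <- do.call(rbind, x)
    rownames(out) <- NULL
    out
  }
  list(observations = bindrows(obs_list),
       calibration = bindrows(cal_list),
       truth = bindrows(truth_list),
       config = config,
       seed = seed)
}
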