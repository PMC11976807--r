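# Wald summary for one fixed-effect coefficient of an lmer fit
wald_from_lmer <- function(fit, term) {
  cf <- summary(fit)$coefficients
  est <- cf[term, "Estimate"]
  se <- cf[term, "Std. Error"]
  if (!is.finite(se) || se < 1e-6) {
    # a zero standard error arises when the random intercepts interpolate
    # the data (e.g. no animal observed in both tissues): the difference
    # itself is still estimable, its uncertainty is not
    if (abs(est) < 1e-12) {
      p <- 1
      ci <- c(est, est)
    } else {
      p <- NA_real_
      ci <- c(NA_real_, NA_real_)
    }
  } else {
    p <- 2 * pnorm(-abs(est / se))
    ci <- est + c(-1.96, 1.96) * se
  }
  list(est = est, se = se, ci = ci, p = p)
}

#' Between-tissue ratio of median pharmacokinetic parameters
#'
#' Compares one derived parameter between two tissue compartments on the
#' log scale, as a ratio of estimated medians: a linear mixed model on
#' `log(parameter)` with a tissue fixed effect and a random animal
#' intercept (each animal contributes catheters to both tissues). The
#' back-transformed coefficient is the median ratio `tissue_a / tissue_b`;
#' confidence interval and p-value are Wald on the log scale. No
#' multiplicity adjustment is applied; the raw p-values mirror how such
#' comparisons are conventionally reported, with significance read at 5%.
#'
#' @param per_catheter Data frame of per-catheter derived parameters (see
#'   [per_catheter_parameters()]), with columns `tissue`, `animal_id` and
#'   the parameter.
#' @param parameter Column to compare (e.g. `"auc_0_last"`, `"c_max"`).
#' @param tissue_a Numerator tissue.
#' @param tissue_b Denominator tissue.
#' @return Data frame with one row: `parameter`, `tissue_a`, `tissue_b`,
#'   `ratio`, `ci_low`, `ci_high`, `p`.
#' @export
compare_tissues <- function(per_catheter, parameter, tissue_a, tissue_b) {
  stopifnot(parameter %in% names(per_catheter))
  d <- per_catheter[per_catheter$tissue %in% c(tissue_a, tissue_b), , drop = FALSE]
  d <- d[is.finite(d[[parameter]]) & d[[parameter]] > 0, , drop = FALSE]
  n_animals <- vapply(c(tissue_a, tissue_b),
                      function(tt) length(unique(d$animal_id[d$tissue == tt])),
                      integer(1))
  if (any(n_animals < 2)) {
    stop("both tissues must be observed in at least 2 animals", call. = FALSE)
  }
  d$logv <- log(d[[parameter]])
  d$tissue <- factor(d$tissue, levels = c(tissue_b, tissue_a))
  d$animal_id <- factor(d$animal_id)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(logv ~ tissue + (1 | animal_id), data = d,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  w <- wald_from_lmer(fit, paste0("tissue", tissue_a))
  # when the animal intercepts interpolate the data (heavy dropout can
  # leave almost no animal with both tissues) the residual variance
  # collapses and the Wald uncertainty is meaningless
  if (stats::sigma(fit) < 0.01 * stats::sd(d$logv) && abs(w$est) > 1e-12) {
    w$ci <- c(NA_real_, NA_real_)
    w$p <- NA_real_
  }
  data.frame(parameter = parameter, tissue_a = tissue_a, tissue_b = tissue_b,
             ratio = exp(w$est), ci_low = exp(w$ci[1]), ci_high = exp(w$ci[2]),
             p = w$p)
}

#' Limits of agreement between duplicate catheters
#'
#' Quantifies how far apart two catheters in the same tissue of the same
#' animal can be expected to lie, for one derived parameter. A linear
#' mixed model `log(parameter) ~ 1 + (1 | animal)` separates between-animal
#' variation from the residual catheter-level SD `sigma`; the limits of
#' agreement are expressed as a median-ratio factor
#' `exp(1.96 * sqrt(2) * sigma)`, so that 95% of same-animal catheter
#' ratios fall within `[1/factor, factor]`. The factor's confidence
#' interval comes from a parametric bootstrap (simulate from the fitted
#' model, refit, take quantiles), deterministic for a fixed seed.
#'
#' @param per_catheter Data frame of per-catheter derived parameters, with
#'   columns `tissue`, `animal_id`, and the parameter; rows are subset to
#'   `tissue` (match on the `tissue` column or, if present, an `organ`
#'   column).
#' @param tissue Tissue (or organ) whose duplicate catheters to compare.
#' @param parameter Column to analyse.
#' @param nboot Parametric bootstrap replicates for the CI (default 1000;
#'   0 skips the CI).
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level.
#' @return Data frame with one row: `tissue`, `parameter`, `loa_factor`,
#'   `ci_low`, `ci_high`, `sigma_log`, `n_catheters`, `n_animals`.
#' @export
limits_of_agreement <- function(per_catheter, tissue, parameter,
                                nboot = 1000, seed = 1, conf = 0.95) {
  stopifnot(parameter %in% names(per_catheter))
  sel <- per_catheter$tissue == tissue
  if ("organ" %in% names(per_catheter)) sel <- sel | per_catheter$organ == tissue
  d <- per_catheter[sel, , drop = FALSE]
  d <- d[is.finite(d[[parameter]]) & d[[parameter]] > 0, , drop = FALSE]
  dup <- table(d$animal_id)
  if (sum(dup >= 2) < 2) {
    stop("limits of agreement need >=2 catheters in >=2 animals for '",
         tissue, "'", call. = FALSE)
  }
  d$logv <- log(d[[parameter]])
  d$animal_id <- factor(d$animal_id)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(logv ~ 1 + (1 | animal_id), data = d,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  sig <- stats::sigma(fit)
  factor_of <- function(s) exp(1.96 * sqrt(2) * s)
  ci <- c(NA_real_, NA_real_)
  if (nboot > 0) {
    set.seed(seed)
    sims <- stats::simulate(fit, nsim = nboot)
    bf <- vapply(seq_len(nboot), function(i) {
      dd <- d
      dd$logv <- sims[[i]]
      rf <- tryCatch(suppressMessages(suppressWarnings(
        lme4::lmer(logv ~ 1 + (1 | animal_id), data = dd,
                   control = lme4::lmerControl(check.conv.singular = "ignore")))),
        error = function(e) NULL)
      if (is.null(rf)) NA_real_ else factor_of(stats::sigma(rf))
    }, numeric(1))
    ci <- quantile(bf, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  }
  data.frame(tissue = tissue, parameter = parameter,
             loa_factor = factor_of(sig),
             ci_low = unname(ci[1]), ci_high = unname(ci[2]),
             sigma_log = sig,
             n_catheters = nrow(d),
             n_animals = length(unique(d$animal_id)))
}

#' Organ label of a tissue compartment
#'
#' Compartment labels follow the `organ_qualifier` convention
#' (`liver_1`, `rectum_profound`, ...); the organ is the label with its
#' final qualifier stripped.
#'
#' @param compartment Character vector of compartment labels.
#' @return Character vector of organ labels.
#' @export
compartment_organ <- function(compartment) {
  sub("_[^_]*$", "", compartment)
}
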