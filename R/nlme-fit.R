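#' Control options for the mixed-effects fit
#'
#' @param lloq_handling Below-LLOQ policy applied before fitting when the
#'   table still carries censored rows; see [apply_recovery()].
#' @param prediction `"interval"` (default) predicts each sample by the
#'   model's average concentration over its collection window;
#'   `"midpoint"` predicts the concentration at the interval midpoint.
#' @param sigma_min Lower bound for the residual SD on the log scale.
#'   Keeps the marginal likelihood bounded in the noise-free limit.
#' @param sd_min Lower bound for the random-effect SDs.
#' @param sd_max Upper bound for the random-effect and residual SDs.
#' @param t_in_bounds Allowed range (min) for the input duration.
#' @param start Optional named numeric overriding the starting values
#'   heuristic: `k_in`, `t_in`, `k_e` on the natural scale.
#' @param max_iter Maximum outer quasi-Newton iterations.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(lloq_handling = "exclude",
                        prediction = c("interval", "midpoint"),
                        sigma_min = 1e-3,
                        sd_min = 1e-4,
                        sd_max = 5,
                        t_in_bounds = c(5, 400),
                        start = NULL,
                        max_iter = 300) {
  structure(list(lloq_handling = lloq_handling,
                 prediction = match.arg(prediction),
                 sigma_min = sigma_min, sd_min = sd_min, sd_max = sd_max,
                 t_in_bounds = t_in_bounds, start = start,
                 max_iter = max_iter),
            class = "fit_control")
}

#' Starting values for the kinetic parameters
#'
#' Heuristic read off the observed curve, pooled over all catheters of a
#' tissue: `t_in` is the midpoint time of the largest observation; `k_e`
#' comes from a log-linear regression on the post-peak observations
#' (falling back to `ln(2)/30`, the middle of the plausible half-life
#' range, when fewer than two post-peak points exist); `k_in` then follows
#' from the closed form at the observed peak.
#'
#' @param obs Data frame with columns `t_start_min`, `t_end_min`,
#'   `c_tissue_ug_ml` (at least 4 rows with positive values).
#' @return A [pk_params()].
#' @export
starting_values <- function(obs) {
  ok <- is.finite(obs$c_tissue_ug_ml) & obs$c_tissue_ug_ml > 0
  obs <- obs[ok, , drop = FALSE]
  if (nrow(obs) < 4) stop("need at least 4 positive observations", call. = FALSE)
  tm <- (obs$t_start_min + obs$t_end_min) / 2
  cmax_obs <- max(obs$c_tissue_ug_ml)
  t_peak <- tm[which.max(obs$c_tissue_ug_ml)]
  post <- tm > t_peak
  if (sum(post) >= 2) {
    sl <- coef(lm(log(obs$c_tissue_ug_ml[post]) ~ tm[post]))[2]
    k_e <- max(-sl, 1e-4)
  } else {
    k_e <- log(2) / 30
  }
  t_in <- max(t_peak, 1)
  k_in <- cmax_obs * k_e / (1 - exp(-k_e * t_in))
  pk_params(k_in = max(k_in, 1e-8), t_in = t_in, k_e = k_e)
}

# Cumulative integral of the unit-k_in concentration curve (k_in = 1);
# branch-free so it vectorises over interval endpoints.
unit_cum <- function(t, tin, ke) {
  t1 <- pmin(t, tin)
  t2 <- pmax(t - tin, 0)
  a <- 1 / ke
  cmax <- a * (1 - exp(-ke * tin))
  a * t1 - (a / ke) * (1 - exp(-ke * t1)) + (cmax / ke) * (1 - exp(-ke * t2))
}

# The model concentration is linear in k_in, so every log prediction splits
# as log k_in + a unit shape depending only on (t_in, k_e). The estimation
# machinery exploits this: the k_in random effect enters additively.
log_unit_prediction <- function(ltin, lke, ts, te, prediction) {
  tin <- exp(ltin)
  ke <- exp(lke)
  if (prediction == "interval") {
    log((unit_cum(te, tin, ke) - unit_cum(ts, tin, ke)) / (te - ts))
  } else {
    tm <- (ts + te) / 2
    log((1 - exp(-ke * pmin(tm, tin))) / ke) - ke * pmax(tm - tin, 0)
  }
}

# log-scale model prediction for one parameter draw over a set of intervals
log_prediction <- function(lkin, ltin, lke, start, end, prediction) {
  lkin + log_unit_prediction(ltin, lke, start, end, prediction)
}

# One animal's contribution to the Laplace-approximate negative marginal
# log-likelihood, together with the joint modes of its random effects
# (b1 on log k_in, b2 on log k_e). b1 enters the residuals additively, so
# its conditional mode is available in closed form and the inner
# optimisation is one-dimensional in b2.
animal_laplace <- function(dd, lkin, ltin, lke, s1, s2, sigma, prediction) {
  y <- dd$y
  n <- length(y)
  prof <- function(b2) {
    lu <- log_unit_prediction(ltin, lke + b2, dd$start, dd$end, prediction)
    z <- y - lkin - lu
    b1 <- s1^2 * sum(z) / (n * s1^2 + sigma^2)
    r <- z - b1
    h <- n * log(sigma) + sum(r^2) / (2 * sigma^2) +
      log(s1) + log(s2) + b1^2 / (2 * s1^2) + b2^2 / (2 * s2^2)
    # far-tail intervals can underflow the unit shape; treat as infeasible
    if (!is.finite(h)) h <- 1e10
    list(h = h, b1 = b1, r = r, lu = lu)
  }
  o <- stats::optimize(function(b2) prof(b2)$h, interval = c(-8, 8), tol = 1e-9)
  b2 <- o$minimum
  p0 <- prof(b2)
  # joint 2x2 Hessian at the mode: the b1 block is exact; b2 derivatives of
  # the unit shape by central differences
  del <- 1e-4
  lup <- log_unit_prediction(ltin, lke + b2 + del, dd$start, dd$end, prediction)
  lum <- log_unit_prediction(ltin, lke + b2 - del, dd$start, dd$end, prediction)
  dlu <- (lup - lum) / (2 * del)
  d2lu <- (lup - 2 * p0$lu + lum) / del^2
  h11 <- n / sigma^2 + 1 / s1^2
  h12 <- sum(dlu) / sigma^2
  h22 <- (sum(dlu^2) - sum(p0$r * d2lu)) / sigma^2 + 1 / s2^2
  detH <- h11 * h22 - h12^2
  if (!is.finite(detH) || detH <= 0) detH <- .Machine$double.eps
  list(nll = p0$h + 0.5 * log(detH) + n * 0.5 * log(2 * pi),
       b = c(p0$b1, b2))
}

# central-difference Hessian with a step wide enough to dominate the
# numerical noise of the Laplace objective (inner modes are solved to
# ~1e-8; curvatures on the log scale are O(1)-O(100))
fd_hessian <- function(fn, x, h = 1e-3) {
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- fn(x)
  for (i in seq_len(n)) {
    ei <- rep(0, n); ei[i] <- h
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
    if (i < n) for (j in (i + 1):n) {
      ej <- rep(0, n); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

# Laplace-approximate negative marginal log-likelihood for one tissue.
# theta = (log k_in, log t_in, log k_e, log s_kin, log s_ke, log sigma);
# `split_data` is a list per animal with y, start, end.
laplace_nll <- function(theta, split_data, prediction) {
  lkin <- theta[1]; ltin <- theta[2]; lke <- theta[3]
  s1 <- exp(theta[4]); s2 <- exp(theta[5]); sigma <- exp(theta[6])
  total <- 0
  for (d in split_data) {
    total <- total + animal_laplace(d, lkin, ltin, lke, s1, s2, sigma,
                                    prediction)$nll
  }
  total
}

#' Fit the kinetic model to one tissue by nonlinear mixed effects
#'
#' Maximises the Laplace-approximate marginal likelihood of the
#' log-transformed tissue concentrations for one tissue compartment.
#' Fixed effects are the log kinetic parameters (`log k_in`, `log t_in`,
#' `log k_e`); animal-level random effects act on `log k_in` and `log k_e`
#' (independent normal deviations), while `t_in` is common to the tissue.
#' The residual error is additive on the log scale (proportional on the
#' natural scale). Exponentiated fixed effects are the population median
#' parameters; per-animal estimates are empirical-Bayes modes. The fit is
#' deterministic given data, control options and starting values.
#'
#' Censored (below-LLOQ) observations are excluded by default; see
#' [fit_control()].
#'
#' @param obs Observation table carrying `c_tissue_ug_ml` (see
#'   [apply_recovery()]); rows of other tissues are ignored.
#' @param tissue Tissue compartment label to fit.
#' @param control A [fit_control()].
#' @return An object of class `tissue_fit`: fixed effects and their
#'   asymptotic covariance, random-effect SDs, residual SD, per-animal
#'   empirical-Bayes estimates, log-likelihood and convergence
#'   diagnostics.
#' @export
fit_tissue <- function(obs, tissue, control = fit_control()) {
  stopifnot(inherits(control, "fit_control"))
  d <- obs[obs$tissue == tissue, , drop = FALSE]
  if ("censored" %in% names(d)) d <- d[!as.logical(d$censored), , drop = FALSE]
  d <- d[is.finite(d$c_tissue_ug_ml) & d$c_tissue_ug_ml > 0, , drop = FALSE]
  if (nrow(d) == 0) stop("no usable observations for tissue '", tissue, "'",
                         call. = FALSE)
  # keep animals with enough information, in a stable order
  counts <- table(d$animal_id)
  keep <- names(counts)[counts >= 4]
  dropped <- setdiff(names(counts), keep)
  if (length(dropped)) {
    message("dropping animals with <4 usable observations: ",
            paste(dropped, collapse = ", "))
  }
  d <- d[d$animal_id %in% keep, , drop = FALSE]
  if (length(keep) < 2) {
    stop("need >=2 animals with >=4 non-censored observations for tissue '",
         tissue, "'", call. = FALSE)
  }
  d <- d[order(d$animal_id, d$catheter_id, d$t_start_min), , drop = FALSE]
  split_data <- lapply(split(d, factor(d$animal_id, levels = sort(keep))),
                       function(x) list(y = log(x$c_tissue_ug_ml),
                                        start = x$t_start_min,
                                        end = x$t_end_min))

  sv <- if (is.null(control$start)) {
    starting_values(d)
  } else {
    pk_params(control$start[["k_in"]], control$start[["t_in"]],
              control$start[["k_e"]])
  }
  lb <- c(-20, log(control$t_in_bounds[1]), log(1e-5),
          log(control$sd_min), log(control$sd_min), log(control$sigma_min))
  ub <- c(10, log(control$t_in_bounds[2]), log(1),
          log(control$sd_max), log(control$sd_max), log(control$sd_max))

  # stage 1: pooled nonlinear least squares on the log scale for the fixed
  # effects, then per-animal least-squares deviations; the dispersion of
  # those deviations and the residual RMS seed the variance components.
  # This lands the joint Laplace optimisation inside the right basin and
  # makes the noise-free limit exact.
  ys <- unlist(lapply(split_data, `[[`, "y"), use.names = FALSE)
  ss <- unlist(lapply(split_data, `[[`, "start"), use.names = FALSE)
  es <- unlist(lapply(split_data, `[[`, "end"), use.names = FALSE)
  sse_pooled <- function(th) {
    mu <- th[1] + log_unit_prediction(th[2], th[3], ss, es, control$prediction)
    if (any(!is.finite(mu))) return(1e10)
    sum((ys - mu)^2)
  }
  th_f <- pmin(pmax(c(log(sv$k_in), log(sv$t_in), log(sv$k_e)), lb[1:3]), ub[1:3])
  th_f <- nlminb(th_f, sse_pooled, lower = lb[1:3], upper = ub[1:3])$par
  stage2 <- lapply(split_data, function(dd) {
    sse_i <- function(b2) {
      lu <- log_unit_prediction(th_f[2], th_f[3] + b2, dd$start, dd$end,
                                control$prediction)
      z <- dd$y - th_f[1] - lu
      sum((z - mean(z))^2)
    }
    b2 <- stats::optimize(sse_i, interval = c(-8, 8), tol = 1e-9)$minimum
    lu <- log_unit_prediction(th_f[2], th_f[3] + b2, dd$start, dd$end,
                              control$prediction)
    z <- dd$y - th_f[1] - lu
    list(b = c(mean(z), b2), sse = sum((z - mean(z))^2))
  })
  bmat <- vapply(stage2, `[[`, numeric(2), "b")
  resid2 <- vapply(stage2, `[[`, numeric(1), "sse")
  n_tot <- sum(vapply(split_data, function(dd) length(dd$y), numeric(1)))
  s0 <- pmax(pmin(apply(bmat, 1, sd), control$sd_max),
             2 * control$sd_min)
  sig0 <- max(min(sqrt(sum(resid2) / n_tot), control$sd_max),
              control$sigma_min)
  theta0 <- pmin(pmax(c(th_f, log(s0), log(sig0)), lb), ub)

  objfun <- function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    v <- tryCatch(laplace_nll(theta, split_data, control$prediction),
                  error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  start_objective <- objfun(theta0)
  opt <- nlminb(theta0, objfun, lower = lb, upper = ub,
                control = list(iter.max = control$max_iter,
                               eval.max = 10 * control$max_iter))
  # polish: restart from the optimum until no further improvement; "false
  # convergence" of the outer quasi-Newton step (the Laplace objective is
  # only piecewise-smooth through the inner modes) is accepted once a
  # restart cannot move the objective
  improved <- Inf
  for (r in 1:5) {
    opt2 <- nlminb(opt$par, objfun, lower = lb, upper = ub,
                   control = list(iter.max = control$max_iter,
                                  eval.max = 10 * control$max_iter))
    improved <- opt$objective - opt2$objective
    if (opt2$objective <= opt$objective) opt <- opt2
    if (improved < 1e-3) break
  }
  ok_code <- opt$convergence == 0 || improved < 1e-3
  theta <- opt$par

  # empirical-Bayes modes at the optimum
  s1 <- exp(theta[4]); s2 <- exp(theta[5]); sigma <- exp(theta[6])
  eb <- do.call(rbind, lapply(names(split_data), function(nm) {
    b <- animal_laplace(split_data[[nm]], theta[1], theta[2], theta[3],
                        s1, s2, sigma, control$prediction)$b
    data.frame(animal_id = nm, b_log_k_in = b[1], b_log_k_e = b[2])
  }))

  # asymptotic covariance: invert the Hessian over the parameters that are
  # free at the optimum (variance components pinned at a bound contribute
  # no curvature and are held fixed)
  vcov_fixef <- matrix(NA_real_, 3, 3)
  hess_ok <- FALSE
  free <- which(theta > lb + 1e-6 & theta < ub - 1e-6)
  objfree <- function(x) {
    th <- theta; th[free] <- x
    objfun(th)
  }
  H <- tryCatch(fd_hessian(objfree, theta[free]), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    V <- tryCatch(solve(H), error = function(e) tryCatch(pracma::pinv(H),
                                                         error = function(e2) NULL))
    if (!is.null(V)) {
      Vfull <- matrix(0, length(theta), length(theta))
      Vfull[free, free] <- (V + t(V)) / 2
      vcov_fixef <- Vfull[1:3, 1:3]
      hess_ok <- all(diag(vcov_fixef) >= 0)
    }
  }

  fixef <- setNames(theta[1:3], c("log_k_in", "log_t_in", "log_k_e"))
  structure(list(
    tissue = tissue,
    fixef = fixef,
    params = pk_params(exp(theta[1]), exp(theta[2]), exp(theta[3])),
    re_sd = c(log_k_in = s1, log_k_e = s2),
    sigma = sigma,
    eb = eb,
    vcov_fixef = vcov_fixef,
    logLik = -opt$objective,
    converged = ok_code && hess_ok,
    optim = list(convergence = opt$convergence, message = opt$message,
                 iterations = opt$iterations, hessian_ok = hess_ok,
                 start = theta0, start_objective = start_objective),
    n_obs = nrow(d),
    n_animals = length(split_data),
    control = control,
    data = d),
    class = "tissue_fit")
}

#' @export
print.tissue_fit <- function(x, ...) {
  cat("Nonlinear mixed-effects fit:", x$tissue, "\n")
  cat(sprintf("  population medians: k_in = %.4g, t_in = %.4g min, k_e = %.4g /min\n",
              x$params$k_in, x$params$t_in, x$params$k_e))
  cat(sprintf("  between-animal SD (log): k_in %.3g, k_e %.3g; residual SD (log) %.3g\n",
              x$re_sd[1], x$re_sd[2], x$sigma))
  cat(sprintf("  %d observations, %d animals, logLik %.2f, converged: %s\n",
              x$n_obs, x$n_animals, x$logLik, x$converged))
  invisible(x)
}

#' Per-catheter derived pharmacokinetic parameters
#'
#' Maps each catheter's empirical-Bayes kinetic parameters (the animal's
#' conditional modes applied to the tissue's fixed effects) through
#' [pk_derived()] at the last sampling time. Catheters absent from the fit
#' are skipped with a warning.
#'
#' @param fit A [fit_tissue()] result.
#' @param obs Observation table used to enumerate catheters (defaults to
#'   the data retained in the fit).
#' @param t_last Last sampling time (min).
#' @return Data frame: one row per catheter with the individual kinetic
#'   and derived parameters.
#' @export
per_catheter_parameters <- function(fit, obs = fit$data, t_last = 480) {
  stopifnot(inherits(fit, "tissue_fit"))
  d <- obs[obs$tissue == fit$tissue, , drop = FALSE]
  cats <- unique(d[, c("animal_id", "catheter_id")])
  known <- cats$animal_id %in% fit$eb$animal_id
  if (any(!known)) {
    warning("skipping catheters from animals absent from the fit: ",
            paste(cats$catheter_id[!known], collapse = ", "), call. = FALSE)
    cats <- cats[known, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(cats)), function(i) {
    b <- fit$eb[fit$eb$animal_id == cats$animal_id[i], ]
    p <- pk_params(exp(fit$fixef[1] + b$b_log_k_in),
                   exp(fit$fixef[2]),
                   exp(fit$fixef[3] + b$b_log_k_e))
    dv <- pk_derived(p, t_last = t_last)
    data.frame(tissue = fit$tissue,
               animal_id = cats$animal_id[i],
               catheter_id = cats$catheter_id[i],
               k_in = p$k_in, t_in = p$t_in, k_e = p$k_e,
               auc_0_last = dv$auc_0_last, c_max = dv$c_max,
               t_max = dv$t_max, t_half = dv$t_half)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Population pharmacokinetic summary table
#'
#' One row per fitted tissue with the population median derived parameters
#' (computed from the exponentiated fixed effects) and Wald 95% confidence
#' intervals obtained by the delta method on the log scale.
#'
#' @param fits A single [fit_tissue()] result or a list of them.
#' @param t_last Last sampling time (min) for the AUC.
#' @return Data frame with columns `tissue`, `n`, and point estimate plus
#'   `ci_low`/`ci_high` for `auc_0_last`, `t_half`, `c_max`, `t_max`.
#' @export
population_pk_table <- function(fits, t_last = 480) {
  if (inherits(fits, "tissue_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    qfun <- list(
      auc_0_last = function(th) log(pk_auc(pk_params(exp(th[1]), exp(th[2]), exp(th[3])), t_last)),
      t_half = function(th) log(log(2)) - th[3],
      c_max = function(th) log(pk_concentration(pk_params(exp(th[1]), exp(th[2]), exp(th[3])), exp(th[2]))),
      t_max = function(th) th[2])
    est <- list()
    for (nm in names(qfun)) {
      g <- qfun[[nm]]
      val <- g(f$fixef)
      se <- NA_real_
      if (all(is.finite(f$vcov_fixef))) {
        gr <- pracma::grad(g, as.numeric(f$fixef))
        v <- drop(t(gr) %*% f$vcov_fixef %*% gr)
        if (is.finite(v) && v >= 0) se <- sqrt(v)
      }
      est[[nm]] <- exp(val)
      est[[paste0(nm, "_ci_low")]] <- exp(val - 1.96 * se)
      est[[paste0(nm, "_ci_high")]] <- exp(val + 1.96 * se)
    }
    cbind(data.frame(tissue = f$tissue, n = f$n_animals), as.data.frame(est))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
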