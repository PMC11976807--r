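# lightweight djb2-style hash of a deparsed object, for output provenance
# headers; stays within exact double-precision integer arithmetic
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

output_header <- function(seed = NA, config = NULL) {
  sprintf("# hipecpk %s; seed=%s; config=%s",
          as.character(packageVersion("hipecpk")),
          ifelse(is.na(seed), "NA", seed),
          if (is.null(config)) "NA" else config_hash(config))
}

#' Write a result table as CSV with a provenance header
#'
#' The first line is a `#` comment recording the package version, the RNG
#' seed and a hash of the configuration that produced the table;
#' [read_table_csv()] skips it.
#'
#' @param df Data frame to write.
#' @param path Output file.
#' @param seed Seed recorded in the header.
#' @param config Configuration object hashed into the header.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, config), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_table_csv <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Read/write a protocol specification as YAML
#'
#' The YAML keys mirror the [protocol_spec()] fields; times are minutes
#' and doses mg/m².
#'
#' @param spec A [protocol_spec()].
#' @param path File path.
#' @return `read_protocol()` returns a [protocol_spec()];
#'   `write_protocol()` returns `path` invisibly.
#' @export
write_protocol <- function(spec, path) {
  stopifnot(inherits(spec, "protocol_spec"))
  x <- list(body_weight_kg = spec$body_weight_kg,
            dose_per_m2 = spec$dose_per_m2,
            dose_fractions = list(time_min = spec$dose_fractions$time_min,
                                  fraction = spec$dose_fractions$fraction),
            perfusion_end_min = spec$perfusion_end_min,
            sampling_intervals = list(start_min = spec$sampling_intervals$start_min,
                                      end_min = spec$sampling_intervals$end_min),
            lloq_ug_per_ml = spec$lloq_ug_per_ml)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- yaml::read_yaml(path)
  protocol_spec(body_weight_kg = x$body_weight_kg,
                dose_per_m2 = x$dose_per_m2,
                dose_fractions = data.frame(time_min = x$dose_fractions$time_min,
                                            fraction = x$dose_fractions$fraction),
                perfusion_end_min = x$perfusion_end_min,
                sampling_intervals = data.frame(start_min = x$sampling_intervals$start_min,
                                                end_min = x$sampling_intervals$end_min),
                lloq_ug_per_ml = x$lloq_ug_per_ml)
}

#' Write a generated experiment to disk
#'
#' Writes `observations.csv`, `calibration.csv` and `truth.json` under
#' `dir`, each stamped with the seed and configuration hash. Idempotent
#' for a fixed seed.
#'
#' @param experiment Output of [generate_experiment()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(experiment$observations, file.path(dir, "observations.csv"),
                  seed = experiment$seed, config = experiment$config)
  write_table_csv(experiment$calibration, file.path(dir, "calibration.csv"),
                  seed = experiment$seed, config = experiment$config)
  jsonlite::write_json(experiment$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Chains the analysis stages on an observation and calibration table:
#' recovery estimation and correction, per-tissue nonlinear mixed-effects
#' fits, per-catheter derived parameters, between-tissue ratio
#' comparisons, and per-organ limits of agreement. Optionally writes the
#' result tables (recovery, population PK, per-catheter PK, comparisons,
#' LOA) as headed CSVs under `out_dir`.
#'
#' @param observations Dialysate observation table.
#' @param calibration Retrodialysis calibration table.
#' @param control A [fit_control()].
#' @param comparisons Data frame of comparisons to run, with columns
#'   `parameter`, `tissue_a`, `tissue_b`; `NULL` (default) compares every
#'   pair of compartments for `auc_0_last` and `c_max`.
#' @param loa_parameters Parameters for the limits-of-agreement analysis.
#' @param loa_nboot Bootstrap replicates for LOA confidence intervals.
#' @param t_last Last sampling time (min).
#' @param out_dir Optional output directory.
#' @param seed Seed recorded in output headers and used for the LOA
#'   bootstrap.
#' @return A list with `recovery`, `recovery_by_compartment`, `fits`,
#'   `per_catheter`, `population`, `comparisons`, `loa`.
#' @export
run_pipeline <- function(observations, calibration,
                         control = fit_control(),
                         comparisons = NULL,
                         loa_parameters = c("auc_0_last", "c_max", "t_half"),
                         loa_nboot = 200,
                         t_last = 480,
                         out_dir = NULL,
                         seed = 1) {
  recov <- estimate_recovery(calibration)
  recov_tbl <- pool_recovery(recov)
  obs <- apply_recovery(observations, recov,
                        lloq_handling = control$lloq_handling)
  tissues <- sort(unique(obs$tissue))
  fits <- list()
  for (tt in tissues) {
    fits[[tt]] <- tryCatch(fit_tissue(obs, tt, control = control),
                           error = function(e) {
                             warning("fit failed for '", tt, "': ",
                                     conditionMessage(e), call. = FALSE)
                             NULL
                           })
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no tissue could be fitted", call. = FALSE)
  per_cath <- do.call(rbind, lapply(fits, per_catheter_parameters,
                                    t_last = t_last))
  rownames(per_cath) <- NULL
  per_cath$organ <- compartment_organ(per_cath$tissue)
  pop <- population_pk_table(fits, t_last = t_last)

  if (is.null(comparisons)) {
    prs <- t(utils::combn(names(fits), 2))
    comparisons <- do.call(rbind, lapply(c("auc_0_last", "c_max"), function(p) {
      data.frame(parameter = p, tissue_a = prs[, 2], tissue_b = prs[, 1])
    }))
  }
  cmp <- do.call(rbind, lapply(seq_len(nrow(comparisons)), function(i) {
    tryCatch(compare_tissues(per_cath, comparisons$parameter[i],
                             comparisons$tissue_a[i], comparisons$tissue_b[i]),
             error = function(e) NULL)
  }))

  organs <- unique(per_cath$organ)
  loa <- do.call(rbind, lapply(loa_parameters, function(p) {
    do.call(rbind, lapply(organs, function(o) {
      tryCatch(limits_of_agreement(per_cath, o, p, nboot = loa_nboot,
                                   seed = seed),
               error = function(e) NULL)
    }))
  }))

  out <- list(recovery = recov, recovery_by_compartment = recov_tbl,
              fits = fits, per_catheter = per_cath, population = pop,
              comparisons = cmp, loa = loa)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(recov_tbl, file.path(out_dir, "table2_recovery.csv"), seed)
    write_table_csv(pop, file.path(out_dir, "table3_pk.csv"), seed)
    write_table_csv(per_cath, file.path(out_dir, "per_catheter_pk.csv"), seed)
    if (!is.null(cmp)) write_table_csv(cmp, file.path(out_dir, "comparisons.csv"), seed)
    if (!is.null(loa)) write_table_csv(loa, file.path(out_dir, "loa.csv"), seed)
  }
  out
}

#' Time–concentration plot with fitted curves
#'
#' Observed tissue concentrations (interval midpoints, mean ± SE per
#' compartment) with the fitted population curves superimposed.
#'
#' @param obs Recovery-corrected observation table (see
#'   [apply_recovery()]).
#' @param fits List of [fit_tissue()] results.
#' @param t_max_plot Right edge of the time axis (min).
#' @return A ggplot object.
#' @export
plot_tissue_fits <- function(obs, fits, t_max_plot = 480) {
  tm <- (obs$t_start_min + obs$t_end_min) / 2
  agg <- stats::aggregate(list(c_mean = obs$c_tissue_ug_ml),
                          by = list(tissue = obs$tissue, t = tm), mean)
  agg_se <- stats::aggregate(list(se = obs$c_tissue_ug_ml),
                             by = list(tissue = obs$tissue, t = tm),
                             function(v) sd(v) / sqrt(length(v)))
  agg$se <- agg_se$se
  grid <- seq(0, t_max_plot, by = 2)
  curves <- do.call(rbind, lapply(fits, function(f) {
    data.frame(tissue = f$tissue, t = grid,
               c_fit = pk_concentration(f$params, grid))
  }))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$t, y = .data$c_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$c_mean - .data$se,
                                          ymax = .data$c_mean + .data$se),
                             size = 0.2) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$c_fit), colour = "red") +
    ggplot2::facet_wrap(~tissue, scales = "free_y") +
    ggplot2::labs(x = "time since start of HIPEC (min)",
                  y = expression(paste("tissue concentration (", mu, "g/mL)"))) +
    ggplot2::theme_minimal()
}

#' Limits-of-agreement chart
#'
#' Dot-and-interval display of the per-organ LOA factors per parameter.
#'
#' @param loa LOA table from [run_pipeline()] or rows of
#'   [limits_of_agreement()].
#' @return A ggplot object.
#' @export
plot_loa <- function(loa) {
  ggplot2::ggplot(loa, ggplot2::aes(x = .data$tissue, y = .data$loa_factor)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::labs(x = NULL, y = "limits-of-agreement factor") +
    ggplot2::theme_minimal()
}
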