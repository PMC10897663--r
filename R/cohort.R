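#' Filter specimens eligible for stent-graft deployment
#'
#' Keeps specimens whose proximal-landing-zone diameter (point 2) lies
#' inside the inclusive [eligibility_range()] of the device, i.e. those in
#' which the target oversizing window can be achieved.
#'
#' @param cohort List of [aorta_sample()] objects.
#' @param d_graft Stent-graft diameter in mm.
#' @param lo,hi Oversizing window as fractions.
#' @return The eligible subset of `cohort` (possibly empty, with a warning).
#' @export
filter_eligible <- function(cohort, d_graft = 26, lo = 0.10, hi = 0.20) {
  stopifnot(is.list(cohort))
  rng <- eligibility_range(d_graft, lo, hi)
  keep <- vapply(cohort, function(s) {
    s$d2 >= rng[["d_min"]] && s$d2 <= rng[["d_max"]]
  }, logical(1))
  out <- cohort[keep]
  if (length(out) == 0 && length(cohort) > 0)
    warning("no specimen is eligible for the device")
  out
}

modify_config <- function(config, ...) {
  upd <- list(...)
  for (nm in names(upd)) config[[nm]] <- upd[[nm]]
  config
}

# One full pipeline pass over a simulated acquisition: transit time from the
# flow pair, cycle-wise pressures, centerline length from three
# continuous-flow point sets evaluated at the realized MAP, then PWV.
analyze_acquisition <- function(sample, config, px_per_cm, n_points,
                                jitter_px, pointset_seed) {
  acq <- simulate_sample(sample, config)
  tt <- estimate_transit_time(acq$proximal, acq$distal,
                              min_cycles = min(25, config$n_cycles))
  ps <- pressure_summary(acq$zone3)
  delta <- if (config$arch_type == "III") config$arch_length_delta_cm else 0
  levels <- c(80, 100, 120)
  lens <- vapply(seq_along(levels), function(i) {
    pset <- generate_point_set(sample, levels[i], px_per_cm = px_per_cm,
                               jitter_px = jitter_px, n_points = n_points,
                               seed = substream_seed(pointset_seed, i),
                               arch_delta_cm = delta)
    arc_length(pset, calibrate_scale(pset))
  }, numeric(1))
  fit <- fit_length_pressure(levels, lens)
  L_cm <- length_at(fit, ps$MAP)
  pwv <- compute_pwv(L_cm / 100, tt$transit_time)
  data.frame(
    sample_id = sample$sample_id, arch_type = config$arch_type,
    stented = config$stent,
    configuration = paste0("Type", config$arch_type,
                           if (config$stent) "_stented" else "_native"),
    flow_lmin = mean(acq$proximal$values), DBP = ps$DBP, SBP = ps$SBP,
    PP = ps$PP, MAP = ps$MAP, transit_time_s = tt$transit_time,
    length_cm = L_cm, pwv_ms = pwv$pwv,
    true_wave_speed = acq$truth$true_wave_speed,
    true_transit_time = acq$truth$true_transit_time,
    true_length_cm = acq$truth$true_length_at_map_cm,
    stringsAsFactors = FALSE)
}

study_variables <- c(flow_lmin = "Flow (L/min)",
                     DBP = "Diastolic blood pressure (mmHg)",
                     SBP = "Systolic blood pressure (mmHg)",
                     PP = "Pulse pressure (mmHg)",
                     MAP = "Mean arterial pressure (mmHg)",
                     pwv_ms = "Pulse wave velocity (m/s)")

compare_configs <- function(records, cfg_a, cfg_b, analysis_label,
                            alpha = 0.05) {
  a <- records[records$configuration == cfg_a, ]
  b <- records[records$configuration == cfg_b, ]
  ids <- intersect(a$sample_id, b$sample_id) # complete pairs only
  if (length(ids) < 3) return(NULL)
  a <- a[match(ids, a$sample_id), ]
  b <- b[match(ids, b$sample_id), ]
  do.call(rbind, lapply(names(study_variables), function(v) {
    pc <- paired_compare(a[[v]], b[[v]], alpha = alpha)
    data.frame(analysis = analysis_label, variable = study_variables[[v]],
               config_a = cfg_a, config_b = cfg_b,
               mean_a = pc$mean_sd_a[["mean"]], sd_a = pc$mean_sd_a[["sd"]],
               mean_b = pc$mean_sd_b[["mean"]], sd_b = pc$mean_sd_b[["sd"]],
               n = pc$n, test_used = pc$test_used, p_value = pc$p_value,
               stringsAsFactors = FALSE)
  }))
}

pwv_percent_change <- function(records, cfg_a, cfg_b, label) {
  a <- records[records$configuration == cfg_a, ]
  b <- records[records$configuration == cfg_b, ]
  ids <- intersect(a$sample_id, b$sample_id)
  if (length(ids) < 2) return(NULL)
  a <- a[match(ids, a$sample_id), ]; b <- b[match(ids, b$sample_id), ]
  per_sample <- percent_change(a$pwv_ms, b$pwv_ms)
  data.frame(contrast = label, config_a = cfg_a, config_b = cfg_b,
             n = length(ids),
             mean_of_ratios_pct = mean(per_sample),
             sd_of_ratios_pct = stats::sd(per_sample),
             ratio_of_means_pct = percent_change(mean(a$pwv_ms),
                                                 mean(b$pwv_ms)),
             stringsAsFactors = FALSE)
}

#' Run the full in-silico bench study
#'
#' Simulates a cohort of aortic specimens, acquires each in the Type I and
#' Type III arch configurations (and, for specimens eligible for the
#' device, again with the stent-graft deployed in both configurations),
#' runs the estimation pipeline on every acquisition, and assembles
#' aggregates, paired comparisons and percent-change summaries. The bench
#' protocol's pairing is preserved: the same specimen parameters are reused
#' across its configurations, the afterload is tuned once at its Type I
#' baseline, and only the configuration deltas (arch factor, stent, small
#' cardiac-output re-mount jitter) differ between acquisitions.
#'
#' @param n Number of specimens.
#' @param population [cohort_population()] parameters.
#' @param loop_config Baseline [mockloop_config()].
#' @param graft_diameter_mm Stent-graft diameter.
#' @param oversizing_window Length-2 fractional window for eligibility.
#' @param co_range Per-specimen cardiac-output set-point range (L/min); the
#'   protocol sets the pump anywhere inside the physiologic 4.5-5.5 window.
#' @param co_remount_sd SD (L/min) of the small cardiac-output differences
#'   between re-mounted acquisitions of the same specimen.
#' @param px_per_cm,n_points,jitter_px Planar-image parameters passed to
#'   [generate_point_set()].
#' @param seed Master seed; all per-sample and per-acquisition streams are
#'   derived from it.
#' @return An object of class `cohort_summary`: list with `n_total`,
#'   `n_eligible`, `eligible_ids`, `records` (one row per analyzed
#'   acquisition), `aggregates`, `comparisons`, `percent_changes`,
#'   `failures`, `cohort`, `seed`.
#' @export
run_study <- function(n = 24, population = cohort_population(),
                      loop_config = mockloop_config(),
                      graft_diameter_mm = 26,
                      oversizing_window = c(0.10, 0.20),
                      co_range = c(4.5, 5.5), co_remount_sd = 0.1,
                      px_per_cm = 40, n_points = 16, jitter_px = 1,
                      seed = 1) {
  stopifnot(inherits(loop_config, "mockloop_config"))
  cohort <- generate_cohort(n, population, seed = substream_seed(seed, 1))
  eligible <- filter_eligible(cohort, graft_diameter_mm,
                              oversizing_window[1], oversizing_window[2])
  eligible_ids <- vapply(eligible, `[[`, character(1), "sample_id")

  records <- list(); failures <- list()
  for (i in seq_len(n)) {
    smp <- cohort[[i]]
    co_i <- with_seed(substream_seed(seed, 2, i),
                      stats::runif(1, co_range[1], co_range[2]))
    tuned <- tryCatch(
      tune_windkessel(modify_config(loop_config,
                                    cardiac_output_target = co_i)),
      error = function(e) e)
    if (inherits(tuned, "error")) {
      failures[[length(failures) + 1]] <- data.frame(
        sample_id = smp$sample_id, configuration = "tuning",
        message = conditionMessage(tuned), stringsAsFactors = FALSE)
      next
    }
    arch_factor <- exp(with_seed(substream_seed(seed, 6, i),
                                 stats::rnorm(1, 0,
                                              loop_config$arch_effect_sd)))
    combos <- list(list(arch = "I", stent = FALSE),
                   list(arch = "III", stent = FALSE))
    if (smp$sample_id %in% eligible_ids) {
      combos <- c(combos, list(list(arch = "I", stent = TRUE),
                               list(arch = "III", stent = TRUE)))
    }
    for (j in seq_along(combos)) {
      cb <- combos[[j]]
      co_acq <- co_i + with_seed(substream_seed(seed, 3, i, j),
                                 stats::rnorm(1, 0, co_remount_sd))
      cfg <- modify_config(loop_config, arch_type = cb$arch,
                           stent = cb$stent,
                           cardiac_output_target = co_acq,
                           arch_effect_factor = arch_factor,
                           R = tuned$R, C = tuned$C,
                           seed = substream_seed(seed, 4, i, j))
      row <- tryCatch(
        analyze_acquisition(smp, cfg, px_per_cm, n_points, jitter_px,
                            pointset_seed = substream_seed(seed, 5, i, j)),
        error = function(e) e)
      if (inherits(row, "error")) {
        failures[[length(failures) + 1]] <- data.frame(
          sample_id = smp$sample_id,
          configuration = paste0("Type", cb$arch,
                                 if (cb$stent) "_stented" else "_native"),
          message = conditionMessage(row), stringsAsFactors = FALSE)
      } else {
        records[[length(records) + 1]] <- row
      }
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame()
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(sample_id = character(), configuration = character(),
               message = character(), stringsAsFactors = FALSE)

  aggregates <- NULL
  if (nrow(records)) {
    aggregates <- do.call(rbind, lapply(
      split(records, records$configuration), function(g) {
        do.call(rbind, lapply(names(study_variables), function(v) {
          data.frame(configuration = g$configuration[1],
                     variable = study_variables[[v]],
                     mean = mean(g[[v]]), sd = stats::sd(g[[v]]),
                     n = nrow(g), stringsAsFactors = FALSE)
        }))
      }))
    rownames(aggregates) <- NULL
  }

  comparisons <- rbind(
    compare_configs(records, "TypeI_native", "TypeIII_native", "primary"),
    compare_configs(records, "TypeI_stented", "TypeIII_stented",
                    "subgroup_stented"),
    compare_configs(records, "TypeI_native", "TypeI_stented",
                    "subgroup_typeI_tevar"),
    compare_configs(records, "TypeIII_native", "TypeIII_stented",
                    "subgroup_typeIII_tevar"))
  percent_changes <- rbind(
    pwv_percent_change(records, "TypeI_native", "TypeIII_native",
                       "arch_native"),
    pwv_percent_change(records, "TypeI_stented", "TypeIII_stented",
                       "arch_stented"),
    pwv_percent_change(records, "TypeI_native", "TypeI_stented",
                       "tevar_typeI"),
    pwv_percent_change(records, "TypeIII_native", "TypeIII_stented",
                       "tevar_typeIII"))

  structure(
    list(n_total = n, n_eligible = length(eligible_ids),
         eligible_ids = eligible_ids, records = records,
         aggregates = aggregates, comparisons = comparisons,
         percent_changes = percent_changes, failures = failures,
         cohort = cohort, seed = seed),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<cohort_summary> %d specimens (%d stent-eligible), %d acquisitions, %d failures\n",
    x$n_total, x$n_eligible, nrow(x$records), nrow(x$failures)))
  if (!is.null(x$comparisons) && nrow(x$comparisons)) {
    pwv <- x$comparisons[x$comparisons$variable ==
                           "Pulse wave velocity (m/s)", ]
    for (r in seq_len(nrow(pwv)))
      cat(sprintf("  %s PWV: %.2f +/- %.2f vs %.2f +/- %.2f, p = %.3g\n",
                  pwv$analysis[r], pwv$mean_a[r], pwv$sd_a[r],
                  pwv$mean_b[r], pwv$sd_b[r], pwv$p_value[r]))
  }
  invisible(x)
}

table2_schema <- c("analysis", "variable", "type_i_mean", "type_i_sd",
                   "type_iii_mean", "type_iii_sd", "p_value", "n")

#' Write study reports
#'
#' Emits a baseline-characteristics CSV (diameters and measured centerline
#' lengths, full cohort and stented subgroup), a comparisons CSV laid out
#' like the study's hemodynamics table, a percent-change CSV, PDF boxplots
#' of PWV and pressures per configuration, and a full-precision JSON of all
#' numbers.
#'
#' @param summary A `cohort_summary` from [run_study()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of written file paths.
#' @export
report_study <- function(summary, out_dir) {
  stopifnot(inherits(summary, "cohort_summary"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory")

  samples_df <- function(samples) {
    do.call(rbind, lapply(samples, function(s)
      data.frame(sample_id = s$sample_id, d1 = s$d1, d2 = s$d2, d3 = s$d3,
                 d4 = s$d4, stringsAsFactors = FALSE)))
  }
  all_s <- samples_df(summary$cohort)
  sub_s <- all_s[all_s$sample_id %in% summary$eligible_ids, ]
  rec <- summary$records
  len_row <- function(cfg, label) {
    g_all <- rec[rec$configuration == cfg, "length_cm"]
    g_sub <- rec[rec$configuration == cfg &
                   rec$sample_id %in% summary$eligible_ids, "length_cm"]
    data.frame(variable = label,
               all_mean = if (length(g_all)) mean(g_all) else NA_real_,
               all_sd = if (length(g_all) > 1) stats::sd(g_all) else NA_real_,
               subgroup_mean = if (length(g_sub)) mean(g_sub) else NA_real_,
               subgroup_sd = if (length(g_sub) > 1) stats::sd(g_sub) else
                 NA_real_,
               stringsAsFactors = FALSE)
  }
  t1 <- rbind(
    do.call(rbind, lapply(1:4, function(k) {
      v <- all_s[[paste0("d", k)]]; vs <- sub_s[[paste0("d", k)]]
      data.frame(variable = sprintf("Diameter point %d (mm)", k),
                 all_mean = mean(v), all_sd = stats::sd(v),
                 subgroup_mean = if (length(vs)) mean(vs) else NA_real_,
                 subgroup_sd = if (length(vs) > 1) stats::sd(vs) else
                   NA_real_,
                 stringsAsFactors = FALSE)
    })),
    len_row("TypeI_native", "Centreline length, Type I arch (cm)"),
    len_row("TypeIII_native", "Centreline length, Type III arch (cm)"))
  table1_path <- file.path(out_dir, "table1_baseline.csv")
  utils::write.csv(t1, table1_path, row.names = FALSE)

  t2_from <- function(analysis_label, analysis_name) {
    cmp <- summary$comparisons
    if (!is.null(cmp))
      cmp <- cmp[cmp$analysis == analysis_label, , drop = FALSE]
    if (is.null(cmp) || nrow(cmp) == 0) {
      warning(sprintf("no data for the %s analysis: emitting NA columns",
                      analysis_name))
      return(data.frame(analysis = analysis_name,
                        variable = unname(study_variables),
                        type_i_mean = NA_real_, type_i_sd = NA_real_,
                        type_iii_mean = NA_real_, type_iii_sd = NA_real_,
                        p_value = NA_real_, n = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    data.frame(analysis = analysis_name, variable = cmp$variable,
               type_i_mean = cmp$mean_a, type_i_sd = cmp$sd_a,
               type_iii_mean = cmp$mean_b, type_iii_sd = cmp$sd_b,
               p_value = cmp$p_value, n = cmp$n, stringsAsFactors = FALSE)
  }
  t2 <- rbind(t2_from("primary", "primary"),
              t2_from("subgroup_stented", "subgroup_stented"))
  t2 <- t2[, table2_schema]
  table2_path <- file.path(out_dir, "table2_hemodynamics.csv")
  utils::write.csv(t2, table2_path, row.names = FALSE)

  pc_path <- file.path(out_dir, "percent_changes.csv")
  utils::write.csv(summary$percent_changes, pc_path, row.names = FALSE)

  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(n_total = summary$n_total, n_eligible = summary$n_eligible,
         table1 = t1, table2 = t2,
         percent_changes = summary$percent_changes,
         records = summary$records, seed = summary$seed),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")

  plot_path <- file.path(out_dir, "boxplots.pdf")
  grDevices::pdf(plot_path, width = 8, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  if (nrow(rec)) {
    graphics::boxplot(pwv_ms ~ configuration, data = rec,
                      ylab = "PWV (m/s)", xlab = "",
                      main = "Aortic PWV per configuration", las = 2)
    for (v in c("DBP", "SBP", "MAP")) {
      graphics::boxplot(stats::as.formula(paste(v, "~ configuration")),
                        data = rec, ylab = paste(v, "(mmHg)"), xlab = "",
                        main = paste(v, "per configuration"), las = 2)
    }
  }
  invisible(c(table1 = table1_path, table2 = table2_path,
              percent_changes = pc_path, json = json_path,
              boxplots = plot_path))
}
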