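#' Scenario configuration
#'
#' Bundles everything a scenario run needs: soluble kinetics, fibrillar
#' parameters, per-arm washout rates, therapy start, centiloid thresholds,
#' the output grid and a seed. All defaults are the package's reference
#' parameterisation with the shipped calibrated fibrillar surrogate.
#'
#' @param kinetic A [kinetic_params()].
#' @param fibrillar A [fibrillar_params()]; `NULL` is an error directing you
#'   to the calibrate step.
#' @param washout_it,washout_iv Post-discontinuation washout rates (1/month,
#'   or `Inf` for immediate); defaults are the shipped calibrated rates.
#' @param t_start Therapy start time (months).
#' @param positivity,negativity PET thresholds (CL); `negativity` must be
#'   below `positivity`.
#' @param t_end,dt Simulation horizon and grid step (months).
#' @param seed Integer seed recorded for provenance.
#'
#' @return An object of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(dt = 0.05)
#' @export
scenario_config <- function(kinetic = kinetic_params(),
                            fibrillar = default_fibrillar_params(),
                            washout_it = default_washout_rates()[["it"]],
                            washout_iv = default_washout_rates()[["iv"]],
                            t_start = 120, positivity = 35, negativity = 24,
                            t_end = 220, dt = 0.01, seed = 1L) {
  if (is.null(fibrillar))
    stop("no fibrillar parameters supplied; run the calibrate step ",
         "(calibrate_fibrillar()) or use default_fibrillar_params()",
         call. = FALSE)
  stopifnot(inherits(kinetic, "kinetic_params"),
            inherits(fibrillar, "fibrillar_params"))
  if (positivity <= 0 || negativity <= 0 || negativity >= positivity)
    stop("thresholds must be positive with negativity < positivity",
         call. = FALSE)
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  structure(list(kinetic = kinetic, fibrillar = fibrillar,
                 washout_it = washout_it, washout_iv = washout_iv,
                 t_start = t_start, positivity = positivity,
                 negativity = negativity, t_end = t_end, dt = dt,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

config_to_list <- function(config) {
  list(kinetic = unclass(config$kinetic),
       fibrillar = unclass(config$fibrillar),
       washout_it = config$washout_it, washout_iv = config$washout_iv,
       t_start = config$t_start,
       thresholds = list(positivity = config$positivity,
                         negativity = config$negativity),
       grid = list(t_end = config$t_end, dt = config$dt),
       seed = config$seed)
}

#' Read or write a scenario configuration as JSON
#'
#' The JSON schema mirrors [scenario_config()]: objects `kinetic`,
#' `fibrillar`, `thresholds` (`positivity`, `negativity`), `grid` (`t_end`,
#' `dt`) and scalars `washout_it`, `washout_iv`, `t_start`, `seed`. Missing
#' fields take the package defaults. `"fibrillar": "calibrate"` triggers a
#' fresh calibration (seeded from the config seed) instead of the shipped
#' parameters.
#'
#' @param path File path.
#' @param config A `scenario_config` (for writing).
#' @return `read_scenario_config()` returns a `scenario_config`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  kin <- do.call(kinetic_params, as.list(raw$kinetic))
  fib <- if (is.null(raw$fibrillar)) {
    default_fibrillar_params()
  } else if (identical(raw$fibrillar, "calibrate")) {
    cal <- calibrate_fibrillar(kin, seed = raw$seed %||% 1L)
    raw$washout_it <- raw$washout_it %||% cal$washout_it
    raw$washout_iv <- raw$washout_iv %||% cal$washout_iv
    cal$fparams
  } else {
    do.call(fibrillar_params, as.list(raw$fibrillar))
  }
  wo <- default_washout_rates()
  scenario_config(
    kinetic = kin, fibrillar = fib,
    washout_it = raw$washout_it %||% wo[["it"]],
    washout_iv = raw$washout_iv %||% wo[["iv"]],
    t_start = raw$t_start %||% 120,
    positivity = raw$thresholds$positivity %||% 35,
    negativity = raw$thresholds$negativity %||% 24,
    t_end = raw$grid$t_end %||% 220,
    dt = raw$grid$dt %||% 0.01,
    seed = raw$seed %||% 1L)
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable content hash of a configuration (md5 of its canonical JSON).
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config_to_list(config), tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}

arm_schedule <- function(config, arm, t_stop = NULL) {
  if (arm == "untreated") return(therapy_schedule("untreated"))
  therapy_schedule(arm, t_start = config$t_start, t_stop = t_stop,
                   washout_rate = if (arm == "intrathecal")
                     config$washout_it else config$washout_iv)
}

#' Export a trajectory as CSV
#'
#' Soluble trajectories are written with columns `time_month`, `conc_pg_ml`,
#' `event`; PET trajectories with `time_month`, `centiloid`. UTF-8, `.`
#' decimal separator.
#'
#' @param traj A `soluble_trajectory` or `pet_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path) {
  df <- if (inherits(traj, "soluble_trajectory"))
    data.frame(time_month = traj$time, conc_pg_ml = traj$conc,
               event = traj$event)
  else if (inherits(traj, "pet_trajectory"))
    data.frame(time_month = traj$time, centiloid = traj$centiloid)
  else stop("not a trajectory", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

simulate_arm <- function(config, arm, t_stop = NULL, t_end = config$t_end) {
  sched <- arm_schedule(config, arm, t_stop)
  sol <- simulate_soluble(sched, config$kinetic, t_end = t_end,
                          dt = config$dt)
  pet <- simulate_fibrillar(sol, config$fibrillar, sched)
  list(schedule = sched, soluble = sol, pet = pet)
}

report_skeleton <- function(config, kind) {
  list(kind = kind,
       provenance = list(config_hash = config_hash(config),
                         package_version =
                           as.character(utils::packageVersion("csfsink")),
                         seed = config$seed),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Two-arm cohort comparison
#'
#' Runs the full pipeline on a shared model clock: an untreated arm from
#' model time 0, plus intrathecal and IV arms whose therapy starts at
#' `t_start` from the shared untreated history. Reports per-arm PET
#' positivity and negativity crossing times, the CSF percent reduction 12
#' months after therapy start relative to the pre-treatment level (the
#' untreated trajectory's value at `t_start`; trough convention for IV), and
#' IV trough/peak summaries.
#'
#' @param config A [scenario_config()].
#' @param output_dir If non-`NULL`, trajectories (CSV) and the report (JSON)
#'   are written there.
#' @return A `scenario_report` list: `arms` (data frame), `comparison`,
#'   `baseline`, `provenance`, `timestamp`, and the simulated `trajectories`.
#' @examples
#' \donttest{
#' rep <- run_cohort_comparison(scenario_config(dt = 0.05))
#' rep$arms
#' }
#' @export
run_cohort_comparison <- function(config = scenario_config(),
                                  output_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  arms <- c("untreated", "intrathecal", "iv")
  sims <- lapply(arms, function(a) simulate_arm(config, a))
  names(sims) <- arms
  baseline <- soluble_closed_form(config$t_start, config$kinetic$a0,
                                  config$kinetic)
  t12 <- config$t_start + 12
  rows <- lapply(arms, function(a) {
    s <- sims[[a]]
    data.frame(
      arm = a,
      t_pet_positivity = detect_crossing(s$pet, config$positivity, "up"),
      t_pet_negativity = if (a == "untreated") NA_real_ else
        detect_crossing(s$pet, config$negativity, "down",
                        t_min = config$t_start),
      csf_reduction_12mo = if (t12 <= config$t_end)
        percent_reduction(s$soluble, baseline, t12, "pre_dose")
      else NA_real_,
      stringsAsFactors = FALSE)
  })
  arms_df <- do.call(rbind, rows)
  iv_sol <- sims$iv$soluble
  pre <- iv_sol$conc[iv_sol$event == "dose_pre"]
  post <- iv_sol$conc[iv_sol$event == "dose_post"]
  report <- report_skeleton(config, "cohort_comparison")
  report$baseline <- baseline
  report$arms <- arms_df
  report$comparison <- list(
    negativity_difference =
      arms_df$t_pet_negativity[arms_df$arm == "iv"] -
      arms_df$t_pet_negativity[arms_df$arm == "intrathecal"])
  report$iv_summary <- list(
    last_trough = if (length(pre)) pre[length(pre)] else NA_real_,
    last_peak = if (length(post)) post[length(post)] else NA_real_,
    analytic_trough = steady_state_soluble(config$kinetic, "iv_trough"),
    analytic_peak = steady_state_soluble(config$kinetic, "iv_peak"))
  report$trajectories <- sims
  class(report) <- "scenario_report"
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Discontinuation study with washout
#'
#' Each treated arm stops at its own PET-negativity time (the default stop
#' rule) and is simulated onwards with its washout rate. Reports, per arm,
#' the interval from discontinuation to re-crossing the positivity threshold
#' and the soluble half-recovery time (rebound to half the untreated steady
#' state), and the between-arm difference of the re-positivity intervals
#' (intrathecal minus IV). An arm that never reached negativity is reported
#' as `NA` throughout.
#'
#' @inheritParams run_cohort_comparison
#' @param delay_horizon Months past each arm's stop to search for
#'   re-positivity (the simulation horizon is extended as needed).
#' @return A `scenario_report` with per-arm discontinuation metrics.
#' @export
run_discontinuation <- function(config = scenario_config(),
                                output_dir = NULL, delay_horizon = 200) {
  stopifnot(inherits(config, "scenario_config"))
  base <- run_cohort_comparison(config)
  rows <- list(); sims <- list()
  for (a in c("intrathecal", "iv")) {
    t_neg <- base$arms$t_pet_negativity[base$arms$arm == a]
    if (is.na(t_neg)) {
      rows[[a]] <- data.frame(arm = a, t_stop = NA_real_,
                              t_repositivity = NA_real_,
                              repositivity_interval = NA_real_,
                              soluble_half_recovery = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    t_end2 <- max(config$t_end, t_neg + delay_horizon)
    s <- simulate_arm(config, a, t_stop = t_neg, t_end = t_end2)
    sims[[a]] <- s
    t_repos <- detect_crossing(s$pet, config$positivity, "up", t_min = t_neg)
    half <- 0.5 * config$kinetic$p_prod / config$kinetic$c_nat
    t_half <- detect_crossing(s$soluble, half, "up", t_min = t_neg)
    rows[[a]] <- data.frame(
      arm = a, t_stop = t_neg, t_repositivity = t_repos,
      repositivity_interval = t_repos - t_neg,
      soluble_half_recovery = t_half - t_neg,
      stringsAsFactors = FALSE)
  }
  arms_df <- do.call(rbind, rows)
  rownames(arms_df) <- NULL
  report <- report_skeleton(config, "discontinuation")
  report$arms <- arms_df
  report$comparison <- list(
    repositivity_delay_difference =
      arms_df$repositivity_interval[arms_df$arm == "intrathecal"] -
      arms_df$repositivity_interval[arms_df$arm == "iv"])
  report$trajectories <- sims
  class(report) <- "scenario_report"
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Scenario report:", x$kind, "\n")
  print(x$arms, row.names = FALSE)
  for (nm in names(x$comparison))
    cat(sprintf("  %s: %.4g\n", nm, x$comparison[[nm]]))
  cat("  config", substr(x$provenance$config_hash, 1, 8), "| seed",
      x$provenance$seed, "| csfsink", x$provenance$package_version, "\n")
  invisible(x)
}

#' Write a scenario report and its trajectories to disk
#'
#' Writes `report.json` (timestamp kept in a separate top-level field so the
#' remainder is byte-reproducible for a given config and seed) and one CSV
#' per simulated trajectory.
#'
#' @param report A `scenario_report`.
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  stopifnot(inherits(report, "scenario_report"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  body <- unclass(report)
  ts <- body$timestamp
  body$timestamp <- NULL
  body$trajectories <- NULL
  jsonlite::write_json(list(report = body, timestamp = ts),
                       file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  for (a in names(report$trajectories)) {
    export_trajectory(report$trajectories[[a]]$soluble,
                      file.path(output_dir, paste0("soluble_", a, ".csv")))
    export_trajectory(report$trajectories[[a]]$pet,
                      file.path(output_dir, paste0("pet_", a, ".csv")))
  }
  invisible(output_dir)
}

#' Sensitivity sweep over kinetic parameters
#'
#' Evaluates scenario metrics over the cross-product of the supplied
#' parameter values, holding everything else at the config. Metrics are
#' computed on the fast piecewise-analytic route ([milestone_times()] and
#' closed forms): time to PET negativity per arm, the 12-month CSF percent
#' reduction per arm, the analytic IV trough, and the soluble half-recovery
#' time after an immediate-washout discontinuation. Combinations yielding
#' invalid parameters are skipped with a message.
#'
#' @param config A [scenario_config()].
#' @param grid Named list of value vectors; names must be fields of
#'   [kinetic_params()] or `"washout_it"`/`"washout_iv"`.
#' @return A data frame with one row per combination: the swept values plus
#'   metric columns.
#' @examples
#' \donttest{
#' sensitivity_sweep(scenario_config(), list(c_it = c(0.45, 0.9)))
#' }
#' @export
sensitivity_sweep <- function(config = scenario_config(), grid) {
  stopifnot(inherits(config, "scenario_config"),
            is.list(grid), length(grid) > 0, !is.null(names(grid)))
  kin_fields <- names(unclass(kinetic_params()))
  ok <- names(grid) %in% c(kin_fields, "washout_it", "washout_iv")
  if (!all(ok))
    stop("unknown sweep parameters: ",
         paste(names(grid)[!ok], collapse = ", "), call. = FALSE)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    row <- as.list(combos[i, , drop = FALSE])
    kin_args <- unclass(config$kinetic)
    kin_args[intersect(names(row), kin_fields)] <-
      row[intersect(names(row), kin_fields)]
    kp <- tryCatch(do.call(kinetic_params, kin_args), error = function(e) {
      message("skipping invalid combination ", i, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(kp)) next
    w_it <- row$washout_it %||% config$washout_it
    w_iv <- row$washout_iv %||% config$washout_iv
    m <- milestone_times(kp, config$fibrillar, w_it, w_iv,
                         t_start = config$t_start,
                         pos_threshold = config$positivity,
                         neg_threshold = config$negativity)
    baseline <- soluble_closed_form(config$t_start, kp$a0, kp)
    red_it <- 1 - soluble_closed_form(12, baseline, kp, TRUE) / baseline
    a <- baseline
    n_dose <- floor(12 / kp$tau_dose + 1e-9)
    for (d in seq_len(n_dose)) {
      a <- apply_dose(a, kp$e_dose)
      s_next <- min(kp$tau_dose, 12 - (d - 1) * kp$tau_dose)
      a <- soluble_closed_form(s_next, a, kp)
    }
    red_iv <- 1 - a / baseline
    a_treated <- kp$p_prod / (kp$c_nat + kp$c_it)
    metrics <- data.frame(
      t_onset = m$t_onset, t_neg_it = m$t_neg_it, t_neg_iv = m$t_neg_iv,
      reduction_12mo_it = red_it, reduction_12mo_iv = red_iv,
      iv_trough = steady_state_soluble(kp, "iv_trough"),
      reaccumulation_half = reaccumulation_time(kp, a_treated, 0.5,
                                                "immediate"))
    out[[i]] <- cbind(combos[i, , drop = FALSE], metrics)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Plot the trajectories of a scenario report
#'
#' Two stacked panels: soluble CSF concentration (log scale) and PET burden
#' with the positivity/negativity thresholds, one line per arm.
#'
#' @param x A `scenario_report` containing trajectories.
#' @param thresholds Centiloid thresholds to draw.
#' @param ... Passed to `matplot`-style line drawing (unused).
#' @return `x`, invisibly.
#' @export
plot.scenario_report <- function(x, thresholds = c(35, 24), ...) {
  if (!length(x$trajectories)) stop("report holds no trajectories",
                                    call. = FALSE)
  arms <- names(x$trajectories)
  cols <- c(untreated = "grey40", intrathecal = "firebrick",
            iv = "steelblue")
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  sol <- lapply(x$trajectories, `[[`, "soluble")
  plot(NA, xlim = range(sol[[1]]$time),
       ylim = range(unlist(lapply(sol, `[[`, "conc"))), log = "y",
       xlab = "time (months)", ylab = "soluble A-beta (pg/mL)")
  for (a in arms) graphics::lines(sol[[a]]$time, pmax(sol[[a]]$conc, 1),
                                  col = cols[[a]])
  graphics::legend("bottomright", legend = arms, col = cols[arms], lty = 1,
                   bty = "n", cex = 0.8)
  pet <- lapply(x$trajectories, `[[`, "pet")
  plot(NA, xlim = range(pet[[1]]$time),
       ylim = c(0, max(unlist(lapply(pet, `[[`, "centiloid")), thresholds)),
       xlab = "time (months)", ylab = "amyloid burden (CL)")
  for (a in arms) graphics::lines(pet[[a]]$time, pet[[a]]$centiloid,
                                  col = cols[[a]])
  graphics::abline(h = thresholds, lty = 3)
  invisible(x)
}
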