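# Pipeline tests run on a coarser grid (dt = 0.05) than the default 0.01 to
# keep the suite fast; the acceptance tests exercise the default grid.

test_that("null therapy leaves both treated arms without a negativity crossing", {
  cfg <- scenario_config(kinetic = kinetic_params(c_it = 0, e_dose = 0),
                         t_end = 180, dt = 0.1)
  rep <- run_cohort_comparison(cfg)
  a <- rep$arms
  expect_true(is.na(a$t_pet_negativity[a$arm == "intrathecal"]))
  expect_true(is.na(a$t_pet_negativity[a$arm == "iv"]))
  # treated trajectories coincide with the untreated one
  expect_equal(rep$trajectories$intrathecal$pet$centiloid,
               rep$trajectories$untreated$pet$centiloid, tolerance = 1e-8)
})

test_that("reported crossing times are recomputable from the emitted trajectories", {
  out <- file.path(tempdir(), "csfsink-roundtrip")
  cfg <- scenario_config(dt = 0.05)
  rep <- run_cohort_comparison(cfg, output_dir = out)
  for (a in c("untreated", "intrathecal", "iv")) {
    csv <- utils::read.csv(file.path(out, paste0("pet_", a, ".csv")))
    redetect <- detect_crossing(csv, cfg$positivity, "up")
    expect_equal(redetect,
                 rep$arms$t_pet_positivity[rep$arms$arm == a],
                 tolerance = 1e-9)
    if (a != "untreated") {
      expect_equal(detect_crossing(csv, cfg$negativity, "down",
                                   t_min = cfg$t_start),
                   rep$arms$t_pet_negativity[rep$arms$arm == a],
                   tolerance = 1e-9)
    }
  }
  expect_true(file.exists(file.path(out, "report.json")))
  unlink(out, recursive = TRUE)
})

test_that("reports are deterministic apart from the timestamp field", {
  cfg <- scenario_config(t_end = 150, dt = 0.2)
  r1 <- run_cohort_comparison(cfg)
  r2 <- run_cohort_comparison(cfg)
  r1$timestamp <- r2$timestamp <- NULL
  expect_identical(r1, r2)
})

test_that("scenario config survives a JSON round trip", {
  cfg <- scenario_config(kinetic = kinetic_params(c_it = 0.7),
                         t_end = 200, dt = 0.02, seed = 9L)
  path <- tempfile(fileext = ".json")
  write_scenario_config(cfg, path)
  cfg2 <- read_scenario_config(path)
  expect_equal(cfg2, cfg)
  unlink(path)
  # partial config files fall back to defaults
  p2 <- tempfile(fileext = ".json")
  writeLines('{"grid": {"dt": 0.5}}', p2)
  cfg3 <- read_scenario_config(p2)
  expect_equal(cfg3$dt, 0.5)
  expect_equal(cfg3$kinetic, kinetic_params())
  expect_equal(cfg3$fibrillar, default_fibrillar_params())
  unlink(p2)
})

test_that("the shipped default config file reproduces the in-code defaults", {
  path <- system.file("extdata", "default_config.json", package = "csfsink")
  expect_true(nzchar(path))
  expect_equal(read_scenario_config(path), scenario_config())
})

test_that("missing fibrillar parameters raise an instructive error", {
  expect_error(scenario_config(fibrillar = NULL), "calibrate")
})

test_that("discontinuation reports per-arm re-positivity and half-recovery", {
  cfg <- scenario_config(dt = 0.05)
  rep <- run_discontinuation(cfg)
  a <- rep$arms
  it <- a[a$arm == "intrathecal", ]
  iv <- a[a$arm == "iv", ]
  # each arm stops at its own negativity time
  expect_lt(abs(it$t_stop - 132), 0.5)
  expect_lt(abs(iv$t_stop - 150), 0.5)
  expect_true(it$t_repositivity > it$t_stop)
  expect_true(iv$t_repositivity > iv$t_stop)
  # IV soluble rebound is unaffected by washout: closed-form inversion from
  # the trough-level stop state
  iv_sol <- rep$trajectories$iv$soluble
  a_stop_iv <- csfsink:::traj_interp(iv_sol$time, iv_sol$conc, iv$t_stop)
  expect_lt(abs(iv$soluble_half_recovery -
                  reaccumulation_time(cfg$kinetic, a_stop_iv, 0.5,
                                      "immediate")), 0.05)
  # the intrathecal arm's finite washout slows its rebound beyond the
  # immediate-washout bound
  expect_gt(it$soluble_half_recovery,
            reaccumulation_time(cfg$kinetic,
                                steady_state_soluble(cfg$kinetic,
                                                     "intrathecal"),
                                0.5, "immediate"))
  expect_lt(it$soluble_half_recovery, 30)
  expect_equal(rep$comparison$repositivity_delay_difference,
               it$repositivity_interval - iv$repositivity_interval)
})

test_that("null-therapy arms are reported as not applicable in discontinuation", {
  cfg <- scenario_config(kinetic = kinetic_params(c_it = 0, e_dose = 0),
                         t_end = 160, dt = 0.2)
  rep <- run_discontinuation(cfg)
  expect_true(all(is.na(rep$arms$t_stop)))
  expect_true(is.na(rep$comparison$repositivity_delay_difference))
})

test_that("sensitivity sweep reproduces limiting cases and monotonicity", {
  cfg <- scenario_config()
  sw <- sensitivity_sweep(cfg, list(c_it = c(0, 0.45, 0.9)))
  expect_equal(nrow(sw), 3L)
  # null intrathecal therapy equals the untreated arm: no negativity crossing
  expect_true(is.na(sw$t_neg_it[sw$c_it == 0]))
  expect_equal(sw$reduction_12mo_it[sw$c_it == 0],
               1 - soluble_closed_form(132, 100, cfg$kinetic) /
                 soluble_closed_form(120, 100, cfg$kinetic),
               tolerance = 1e-9)
  # time-to-negativity is non-increasing in the intrathecal clearance
  on <- sw[sw$c_it > 0, ]
  expect_true(all(diff(on$t_neg_it) <= 1e-9))
  # trough strictly decreasing in per-dose effect
  sw2 <- sensitivity_sweep(cfg, list(e_dose = c(0.3, 0.6, 0.9)))
  expect_true(all(diff(sw2$iv_trough) < 0))
  # invalid combinations are skipped with a message
  expect_message(sw3 <- sensitivity_sweep(cfg, list(c_nat = c(-1, 0.05))),
                 "skipping")
  expect_equal(nrow(sw3), 1L)
  expect_error(sensitivity_sweep(cfg, list(nope = 1)), "unknown")
})
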