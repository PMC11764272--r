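test_that("closed-form solution matches the integrated ODE oracle values", {
  p <- default_kp
  expect_identical(soluble_closed_form(0, 100, p, therapy_on = TRUE), 100)
  expect_equal(soluble_closed_form(12, 3600, p, therapy_on = TRUE),
               ORACLE$it_from_3600_at_12, tolerance = 1e-6)
  expect_equal(soluble_closed_form(120, 100, p, therapy_on = FALSE),
               ORACLE$untreated_at_120, tolerance = 1e-6)
  # therapy with zero added clearance equals the untreated form everywhere
  p0 <- kinetic_params(c_it = 0)
  tt <- seq(0, 60, by = 2.5)
  expect_equal(soluble_closed_form(tt, 250, p0, therapy_on = TRUE),
               soluble_closed_form(tt, 250, p0, therapy_on = FALSE))
  expect_error(soluble_closed_form(-1, 100, p), "t_rel")
  expect_error(soluble_closed_form(1, -5, p), "a_init")
})

test_that("dose map applies the exact fractional reduction", {
  expect_equal(apply_dose(100, 0.60), 40)
  expect_equal(apply_dose(123.45, 0), 123.45)
  expect_equal(apply_dose(0, 0.60), 0)
  expect_error(apply_dose(100, 1), "e_dose")
  expect_error(apply_dose(-1, 0.5), "a_pre")
})

test_that("steady states match analytic equilibria and the dose-map fixed point", {
  p <- default_kp
  expect_equal(steady_state_soluble(p, "untreated"), ORACLE$untreated_ss)
  expect_equal(steady_state_soluble(p, "intrathecal"), ORACLE$intrathecal_ss,
               tolerance = 1e-6)
  expect_equal(steady_state_soluble(p, "iv_trough"), ORACLE$iv_trough,
               tolerance = 1e-6)
  expect_equal(steady_state_soluble(p, "iv_peak"),
               (1 - p$e_dose) * ORACLE$iv_trough, tolerance = 1e-6)
  # the trough is a genuine fixed point of decay-then-dose
  tr <- steady_state_soluble(p, "iv_trough")
  one_cycle <- soluble_closed_form(p$tau_dose, apply_dose(tr, p$e_dose), p)
  expect_equal(one_cycle, tr, tolerance = 1e-12)
})

test_that("simulated trajectories reproduce closed-form endpoints and dose algebra", {
  p <- default_kp
  tr <- simulate_soluble(therapy_schedule("untreated"), p,
                         t_end = 120, dt = 0.05)
  expect_equal(tail(tr$conc, 1), ORACLE$untreated_at_120, tolerance = 1e-6)
  expect_true(all(diff(tr$time) > 0))

  iv <- simulate_soluble(therapy_schedule("iv", t_start = 120), p,
                         t_end = 132, dt = 0.02)
  pre <- iv$conc[iv$event == "dose_pre"]
  post <- iv$conc[iv$event == "dose_post"]
  expect_length(pre, 12L)  # doses at 120, 121, ..., 131
  expect_equal(post / pre, rep(1 - p$e_dose, 12L), tolerance = 1e-14)
  expect_equal(pre[2], ORACLE$iv_pre_dose2, tolerance = 1e-6)
  expect_true(all(iv$conc >= 0))
  # time non-decreasing; ties only at dose instants
  ties <- which(diff(iv$time) < 1e-12)
  expect_true(all(iv$event[ties] == "dose_pre"))

  # zero-effect IV equals untreated pointwise
  p0 <- kinetic_params(e_dose = 0)
  a <- simulate_soluble(therapy_schedule("iv", t_start = 10), p0,
                        t_end = 30, dt = 0.1)
  b <- simulate_soluble(therapy_schedule("untreated"), p0,
                        t_end = 30, dt = 0.1)
  expect_equal(
    vapply(seq(0, 30, 0.5), function(t) csfsink:::traj_interp(a$time, a$conc, t),
           numeric(1)),
    vapply(seq(0, 30, 0.5), function(t) csfsink:::traj_interp(b$time, b$conc, t),
           numeric(1)),
    tolerance = 1e-9)
})

test_that("therapy events outside the horizon are ignored with a warning", {
  expect_warning(
    tr <- simulate_soluble(therapy_schedule("intrathecal", t_start = 50),
                           default_kp, t_end = 40, dt = 0.5),
    "outside")
  un <- simulate_soluble(therapy_schedule("untreated"), default_kp,
                         t_end = 40, dt = 0.5)
  expect_equal(tr$conc, un$conc)
})

test_that("percent reduction uses the stated baseline and dose convention", {
  p <- default_kp
  tr <- simulate_soluble(therapy_schedule("intrathecal", t_start = 120), p,
                         t_end = 140, dt = 0.05)
  red <- percent_reduction(tr, ORACLE$untreated_at_120, 132)
  expect_equal(red, ORACLE$reduction_12mo, tolerance = 1e-5)
  # zero reduction against own value at start
  v0 <- csfsink:::traj_interp(tr$time, tr$conc, 120)
  expect_equal(percent_reduction(tr, v0, 120), 0, tolerance = 1e-12)
  expect_error(percent_reduction(tr, 0, 130), "baseline")
  # pre/post conventions differ exactly by the dose factor at a dose instant
  iv <- simulate_soluble(therapy_schedule("iv", t_start = 10), p,
                         t_end = 20, dt = 0.1)
  r_pre <- percent_reduction(iv, 1000, 15, "pre_dose")
  r_post <- percent_reduction(iv, 1000, 15, "instant")
  expect_equal(1 - r_post, (1 - p$e_dose) * (1 - r_pre), tolerance = 1e-12)
})

test_that("reaccumulation time inverts the rebound closed form", {
  p <- default_kp
  expect_equal(reaccumulation_time(p, 189.47, 0.5, "immediate"),
               ORACLE$half_recovery, tolerance = 1e-6)
  expect_equal(reaccumulation_time(p, 1800, 0.5, "immediate"), 0)
  expect_equal(reaccumulation_time(p, 2000, 0.5, "immediate"), 0)
  # the inverted time actually lands on the target (round trip)
  t_half <- reaccumulation_time(p, 189.47, 0.5, "immediate")
  expect_equal(soluble_closed_form(t_half, 189.47, p), 1800,
               tolerance = 1e-8)
  # slow washout delays the rebound
  t_wash <- reaccumulation_time(p, 189.47, 0.5, washout = 0.2)
  expect_gt(t_wash, t_half)
  # target asymptotically unreachable
  expect_error(reaccumulation_time(p, 100, 1.0), "target_fraction")
})

test_that("concentration and time-to-target are monotone in the intrathecal clearance", {
  cits <- c(0.1, 0.3, 0.9, 1.5)
  vals <- vapply(cits, function(ci)
    soluble_closed_form(6, 3600, kinetic_params(c_it = ci), TRUE), numeric(1))
  expect_true(all(diff(vals) < 0))
  # target below every treated equilibrium (max is 180/0.15 = 1200)
  t_to_target <- vapply(cits, function(ci) {
    p <- kinetic_params(c_it = ci)
    uniroot(function(t) soluble_closed_form(t, 3600, p, TRUE) - 1300,
            c(1e-6, 100))$root
  }, numeric(1))
  expect_true(all(diff(t_to_target) < 0))
})

test_that("IV pre-dose values converge geometrically to the analytic trough", {
  p <- default_kp
  tr <- simulate_soluble(therapy_schedule("iv", t_start = 0), p,
                         t_end = 40, dt = 0.1)
  pre <- tr$conc[tr$event == "dose_pre"][-1]  # from level above trough
  trough <- steady_state_soluble(p, "iv_trough")
  gaps <- abs(pre - trough)
  gaps <- gaps[gaps > 1e-7]  # below that, floating-point noise dominates
  expect_true(all(diff(gaps) < 0))
  ratios <- gaps[-1] / gaps[-length(gaps)]
  rho <- (1 - p$e_dose) * exp(-p$c_nat * p$tau_dose)
  expect_equal(ratios, rep(rho, length(ratios)), tolerance = 1e-6)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(kinetic_params(c_nat = 0), "c_nat")
  expect_error(kinetic_params(e_dose = 1), "e_dose")
  expect_error(kinetic_params(a0 = -1), "a0")
  expect_error(kinetic_params(tau_dose = 0), "tau_dose")
  expect_error(therapy_schedule("iv", t_start = 10, t_stop = 5), "t_stop")
  expect_error(therapy_schedule("iv", washout_rate = -1), "washout")
  # degenerate but valid: null therapies and zero production
  expect_s3_class(kinetic_params(c_it = 0, e_dose = 0), "kinetic_params")
  expect_s3_class(kinetic_params(p_prod = 0), "kinetic_params")
  expect_equal(soluble_closed_form(10, 100, kinetic_params(p_prod = 0)),
               100 * exp(-0.5), tolerance = 1e-12)
})
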