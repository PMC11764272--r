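test_that("zero variability reproduces the reference parameters exactly", {
  co <- generate_virtual_cohort(100, cv = 0, seed = 7)
  expect_equal(nrow(co), 100L)
  expect_true(all(co$p_prod == 180))
  expect_true(all(co$c_nat == 0.05))
  expect_true(all(co$c_it == 0.90))
  expect_true(all(co$e_dose == 0.60))
  expect_setequal(unique(co$arm), c("untreated", "intrathecal", "iv"))
})

test_that("cohort draws are reproducible and leave global RNG state alone", {
  a <- generate_virtual_cohort(50, cv = 0.2, seed = 7)
  set.seed(123)
  probe1 <- rnorm(1)
  set.seed(123)
  b <- generate_virtual_cohort(50, cv = 0.2, seed = 7)
  probe2 <- rnorm(1)
  expect_identical(a, b)
  expect_identical(probe1, probe2)  # cohort draw did not consume global RNG
  expect_error(generate_virtual_cohort(10, cv = 1.2), "cv")
})

test_that("lognormal draws centre on the reference values at the stated cv", {
  n <- 1000
  co <- generate_virtual_cohort(n, cv = 0.2, seed = 7)
  se <- 0.2 * 180 / sqrt(n)
  expect_lt(abs(mean(co$p_prod) - 180), 3 * se)
  expect_true(all(co$p_prod > 0 & co$c_nat > 0 & co$c_it > 0))
  expect_true(all(co$e_dose < 1))
  # truncation bounds respected
  sdlog <- sqrt(log(1 + 0.2^2))
  expect_gte(min(co$p_prod), qlnorm(0.01, log(180) - sdlog^2 / 2, sdlog))
  expect_lte(max(co$p_prod), qlnorm(0.99, log(180) - sdlog^2 / 2, sdlog))
})

test_that("noise-free observations equal the trajectory exactly", {
  tr <- simulate_soluble(therapy_schedule("intrathecal", t_start = 6),
                         default_kp, t_end = 24, dt = 0.05)
  pet <- simulate_fibrillar(tr, default_fibrillar_params())
  obs <- sample_observations(tr, pet, csf_times = c(0, 6, 12, 18),
                             pet_times = c(0, 12, 24),
                             csf_sigma_log = 0, pet_sigma_cl = 0, seed = 4)
  csf <- obs[obs$measure == "csf_pg_ml", ]
  expect_equal(csf$value,
               vapply(csf$time_month, function(t)
                 csfsink:::traj_interp(tr$time, tr$conc, t), numeric(1)))
  expect_identical(attr(obs, "n_clipped"), 0L)
  expect_identical(obs, sample_observations(tr, pet,
                                            csf_times = c(0, 6, 12, 18),
                                            pet_times = c(0, 12, 24),
                                            csf_sigma_log = 0,
                                            pet_sigma_cl = 0, seed = 4))
})

test_that("replicate CSF noise has the configured log-scale spread", {
  tr <- simulate_soluble(therapy_schedule("untreated"), default_kp,
                         t_end = 12, dt = 0.1)
  obs <- sample_observations(tr, csf_times = rep(6, 200),
                             csf_sigma_log = 0.1, seed = 21)
  lsd <- sd(log(obs$value))
  expect_lt(abs(lsd - 0.1), 0.02)
})

test_that("parameters are exactly identifiable from noiseless dense observations", {
  p <- default_kp
  tr <- simulate_soluble(therapy_schedule("intrathecal", t_start = 0), p,
                         t_end = 12, dt = 0.05)
  obs <- sample_observations(tr, csf_times = seq(0.25, 12, by = 0.25),
                             csf_sigma_log = 0, seed = 1)
  fit <- recover_params(obs)
  expect_equal(unname(fit$estimates["p_prod"]), 180, tolerance = 1e-6)
  expect_equal(unname(fit$estimates["k"]), 0.95, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-6)
  expect_error(recover_params(obs[1:2, ]), "3 distinct")
})

test_that("a null-dose IV arm fits the untreated model with zero residual", {
  p0 <- kinetic_params(e_dose = 0)
  tr <- simulate_soluble(therapy_schedule("iv", t_start = 0), p0,
                         t_end = 24, dt = 0.1)
  obs <- sample_observations(tr, csf_times = seq(1, 24, by = 1),
                             csf_sigma_log = 0, seed = 2)
  fit <- recover_params(obs)
  expect_lt(fit$residual_norm, 1e-5)
  expect_equal(unname(fit$estimates["k"]), p0$c_nat, tolerance = 1e-4)
})

test_that("clearance recovery stays accurate under assay noise and improves with sampling", {
  # therapy applied at the elevated pre-treatment level, observed monthly
  p <- kinetic_params(a0 = 3591.324)
  tr <- simulate_soluble(therapy_schedule("intrathecal", t_start = 0), p,
                         t_end = 24, dt = 0.05)
  rel_err_k <- function(n_obs, seed) {
    obs <- sample_observations(tr, csf_times = seq_len(n_obs) * 24 / n_obs,
                               csf_sigma_log = 0.1, seed = seed)
    fit <- tryCatch(recover_params(obs), error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(fit$estimates[["k"]] - 0.95) / 0.95
  }
  errs24 <- vapply(1:100, function(s) rel_err_k(24, s), numeric(1))
  expect_lt(median(errs24, na.rm = TRUE), 0.10)
  # error decreases with the number of observations
  med <- vapply(c(6, 12, 24), function(n)
    median(vapply(1:30, function(s) rel_err_k(n, s), numeric(1)),
           na.rm = TRUE), numeric(1))
  expect_true(med[3] < med[1])
})
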