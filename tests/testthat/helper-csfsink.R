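# Shared fixtures. Expected values marked "oracle" were computed by adaptive
# numerical integration of the governing ODEs (deSolve, rtol 1e-12),
# independent of the closed-form implementation under test.

default_kp <- kinetic_params()

ORACLE <- list(
  it_from_3600_at_12  = 189.5119,   # dA/dt = 180 - 0.95 A from 3600, t = 12
  untreated_at_120    = 3591.324,   # dA/dt = 180 - 0.05 A from 100, t = 120
  reduction_12mo      = 0.9472307,  # 1 - A(12)/3591.324 under therapy
  iv_trough           = 283.4088,   # fixed point of decay-then-dose map
  iv_pre_dose2        = 1542.043,   # dose at 120 from 3591.324, value at 121-
  half_recovery       = 12.78162,   # rebound from 189.47 to 1800, k = 0.05
  untreated_ss        = 3600,
  intrathecal_ss      = 189.4737)

# a randomized but valid therapy schedule + params, for property tests
random_case <- function() {
  arm <- sample(c("untreated", "intrathecal", "iv"), 1)
  t_end <- runif(1, 30, 60)
  t_start <- runif(1, 5, 15)
  has_stop <- arm != "untreated" && runif(1) < 0.5
  sched <- therapy_schedule(
    arm, t_start = t_start,
    t_stop = if (has_stop) t_start + runif(1, 5, 20) else NULL,
    washout_rate = if (has_stop && runif(1) < 0.5) runif(1, 0.2, 2)
    else "immediate")
  kp <- kinetic_params(a0 = runif(1, 50, 500),
                       p_prod = runif(1, 50, 400),
                       c_nat = runif(1, 0.02, 0.2),
                       c_it = runif(1, 0.2, 2),
                       e_dose = runif(1, 0.2, 0.9),
                       tau_dose = sample(c(0.5, 1, 2), 1))
  list(sched = sched, kp = kp, t_end = t_end)
}
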