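# Fibrillar amyloid burden on the centiloid scale, driven by the soluble pool:
#   dF/dt = k_agg * A(t) - (c_f + gamma_arm(t)) * F
# gamma_arm is active while the arm's soluble therapy is on and decays at the
# arm's washout rate after a stop.

# Therapy-induced fibrillar clearance for an arm. A null soluble therapy
# (c_it = 0 for intrathecal, e_dose = 0 for IV) delivers no antibody, so the
# fibrillar therapy effect is off as well.
effective_gamma <- function(fparams, arm, kparams) {
  switch(arm,
         untreated   = 0,
         intrathecal = if (kparams$c_it > 0) fparams$gamma_it else 0,
         iv          = if (kparams$e_dose > 0) fparams$gamma_iv else 0)
}

# Exact propagation of F over one segment where A(s) = b + a exp(-k s) and
# the total fibrillar clearance g is constant. Vectorized over s.
fib_segment <- function(f0, k_agg, g, b, a, k, s) {
  eg <- exp(-g * s)
  term_b <- if (g > 1e-14) k_agg * b / g * (1 - eg) else k_agg * b * s
  term_a <- if (abs(g - k) < 1e-10) k_agg * a * s * exp(-g * s)
  else k_agg * a * (exp(-k * s) - eg) / (g - k)
  f0 * eg + term_b + term_a
}

#' Simulate the fibrillar (PET centiloid) compartment
#'
#' Numerically integrates the fibrillar burden
#' `dF/dt = k_agg A(t) - (c_f + gamma(t)) F` from `f0`, where `A(t)` is taken
#' from a simulated soluble trajectory. The therapy-induced clearance
#' `gamma` is the arm's rate while therapy is on, decays exponentially at the
#' schedule's washout rate after a stop, and is zero for a null soluble
#' therapy (`c_it = 0` or `e_dose = 0`). Integration is adaptive
#' (`deSolve::lsoda`), restarted at every soluble discontinuity (dose) and
#' therapy boundary so each piece is smooth.
#'
#' @param soluble_traj A `soluble_trajectory` from [simulate_soluble()] or
#'   [ode_reference_solve()].
#' @param fparams A [fibrillar_params()] object.
#' @param schedule The arm's [therapy_schedule()]; defaults to the one stored
#'   on the trajectory.
#' @param tol Integrator relative/absolute tolerance.
#'
#' @return A `pet_trajectory`: data frame with columns `time` (months) and
#'   `centiloid` (CL), one row per unique trajectory time.
#' @examples
#' p <- kinetic_params()
#' tr <- simulate_soluble(therapy_schedule("untreated"), p, t_end = 60, dt = 0.1)
#' fp <- fibrillar_params(k_agg = 2e-4, c_f = 0.01)
#' head(simulate_fibrillar(tr, fp))
#' @export
simulate_fibrillar <- function(soluble_traj, fparams,
                               schedule = attr(soluble_traj, "schedule"),
                               tol = 1e-8) {
  stopifnot(inherits(soluble_traj, "soluble_trajectory"),
            inherits(fparams, "fibrillar_params"),
            inherits(schedule, "therapy_schedule"))
  kparams <- attr(soluble_traj, "params")
  tm <- soluble_traj$time
  cc <- soluble_traj$conc
  ev <- soluble_traj$event
  n <- length(tm)
  if (n < 2L) stop("soluble trajectory is empty or degenerate", call. = FALSE)
  gam <- effective_gamma(fparams, schedule$arm, kparams)
  t_start <- schedule$t_start
  t_stop <- schedule$t_stop
  w <- schedule$washout_rate

  # split into smooth chunks: at duplicated times (dose jumps) and at
  # start/stop boundaries (gamma jumps; boundary row shared by both chunks)
  starts <- 1L; ends <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (tm[i + 1L] - tm[i] < 1e-12) {
      ends <- c(ends, i); starts <- c(starts, i + 1L)
    } else if (ev[i] %in% c("start", "stop")) {
      ends <- c(ends, i); starts <- c(starts, i)
    }
  }
  ends <- c(ends, n)

  times_out <- tm[1L]
  f_out <- fparams$f0
  f <- fparams$f0
  for (j in seq_along(starts)) {
    idx <- starts[j]:ends[j]
    if (length(idx) < 2L) next
    tc <- tm[idx]; ac <- cc[idx]
    afun <- stats::approxfun(tc, ac, rule = 2)
    mid <- (tc[1L] + tc[length(tc)]) / 2
    gfun <-
      if (schedule$arm == "untreated" || gam == 0 || mid < t_start) {
        function(t) 0
      } else if (is.null(t_stop) || mid < t_stop) {
        function(t) gam
      } else if (is.infinite(w)) {
        function(t) 0
      } else {
        function(t) gam * exp(-w * (t - t_stop))
      }
    deriv <- function(t, y, p)
      list(fparams$k_agg * afun(t) - (fparams$c_f + gfun(t)) * y[1])
    out <- deSolve::lsoda(c(F = f), tc, deriv, NULL, rtol = tol, atol = tol)
    fv <- pmax(0, out[, "F"])
    f <- fv[length(fv)]
    times_out <- c(times_out, tc[-1L])
    f_out <- c(f_out, fv[-1L])
  }
  traj <- data.frame(time = times_out, centiloid = f_out)
  attr(traj, "schedule") <- schedule
  attr(traj, "fparams") <- fparams
  class(traj) <- c("pet_trajectory", "data.frame")
  traj
}

#' Quasi-steady fibrillar burden under constant soluble input
#'
#' Equilibrium of `dF/dt = k_agg a_const - (c_f + gamma) F`, i.e.
#' `k_agg a_const / (c_f + gamma)`.
#'
#' @param fparams A [fibrillar_params()].
#' @param a_const Constant soluble concentration (pg/mL).
#' @param gamma Additional therapy-induced clearance (1/month).
#' @return Equilibrium burden (CL).
#' @examples
#' quasi_steady_fibrillar(fibrillar_params(0.01, 0.05), 100)  # 20
#' @export
quasi_steady_fibrillar <- function(fparams, a_const, gamma = 0) {
  stopifnot(inherits(fparams, "fibrillar_params"), a_const >= 0, gamma >= 0)
  g <- fparams$c_f + gamma
  if (g <= 0) stop("total fibrillar clearance must be > 0", call. = FALSE)
  fparams$k_agg * a_const / g
}

#' First threshold crossing of a trajectory
#'
#' Finds the first time at or after `t_min` at which a simulated signal
#' crosses a threshold in the stated direction, linearly interpolating
#' between grid points. Vertical jumps (the dose discontinuities of a soluble
#' trajectory) that straddle the threshold cross at the jump instant.
#'
#' @param traj A `pet_trajectory`, `soluble_trajectory`, or data frame whose
#'   first column is time and second the signal.
#' @param threshold Threshold value (same units as the signal), `> 0`.
#' @param direction `"up"` (signal rises through the threshold) or `"down"`.
#' @param t_min Earliest admissible crossing time (months).
#' @return Crossing time in months, or `NA` if the signal never crosses.
#' @examples
#' detect_crossing(data.frame(t = 0:1, v = c(30, 20)), 24, "down")  # 0.6
#' @export
detect_crossing <- function(traj, threshold, direction = c("down", "up"),
                            t_min = 0) {
  direction <- match.arg(direction)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (inherits(traj, "pet_trajectory")) {
    tm <- traj$time; v <- traj$centiloid
  } else if (inherits(traj, "soluble_trajectory")) {
    tm <- traj$time; v <- traj$conc
  } else {
    tm <- traj[[1L]]; v <- traj[[2L]]
  }
  n <- length(tm)
  if (n == 0L) stop("empty trajectory", call. = FALSE)
  if (n == 1L) return(NA_real_)
  crosses <- if (direction == "down")
    v[-n] > threshold & v[-1L] <= threshold
  else
    v[-n] < threshold & v[-1L] >= threshold
  for (i in which(crosses)) {
    dtm <- tm[i + 1L] - tm[i]
    tc <- if (dtm < 1e-12) tm[i]
    else tm[i] + dtm * (threshold - v[i]) / (v[i + 1L] - v[i])
    if (tc >= t_min - 1e-9) return(max(tc, t_min))
  }
  NA_real_
}
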