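#' Closed-form soluble amyloid-beta concentration
#'
#' Evaluates the exact solution of the one-compartment balance
#' `dA/dt = P - k A` at elapsed time `t_rel` from the initial value `a_init`:
#' `A(t) = (a_init - P/k) exp(-k t) + P/k`, where the total clearance is
#' `k = c_nat + c_it` while intrathecal therapy is on and `k = c_nat`
#' otherwise. The same expression is the inter-dose segment of the IV regimen
#' (therapy off between instantaneous doses).
#'
#' @param t_rel Elapsed time (months), scalar or vector, all `>= 0`.
#' @param a_init Concentration at `t_rel = 0` (pg/mL).
#' @param params A [kinetic_params()] object.
#' @param therapy_on If `TRUE`, the intrathecal clearance `c_it` is added to
#'   the natural clearance.
#'
#' @return Concentration(s) in pg/mL, same length as `t_rel`.
#' @examples
#' p <- kinetic_params()
#' soluble_closed_form(12, 3600, p, therapy_on = TRUE)   # ~189.51
#' soluble_closed_form(120, 100, p, therapy_on = FALSE)  # ~3591.32
#' @export
soluble_closed_form <- function(t_rel, a_init, params = kinetic_params(),
                                therapy_on = FALSE) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(t_rel),
            is.numeric(a_init), length(a_init) == 1L)
  if (any(t_rel < 0)) stop("t_rel must be >= 0", call. = FALSE)
  if (a_init < 0) stop("a_init must be >= 0", call. = FALSE)
  k <- params$c_nat + if (isTRUE(therapy_on)) params$c_it else 0
  ass <- params$p_prod / k
  pmax(0, (a_init - ass) * exp(-k * t_rel) + ass)
}

#' Instantaneous IV dose effect
#'
#' Applies the per-dose fractional reduction: the concentration immediately
#' after a dose is `(1 - e_dose)` times the pre-dose concentration.
#'
#' @param a_pre Pre-dose concentration(s) (pg/mL), `>= 0`.
#' @param e_dose Fractional reduction per dose, in `[0, 1)`.
#' @return Post-dose concentration(s), in `[0, a_pre]`.
#' @examples
#' apply_dose(100, 0.60)  # 40
#' @export
apply_dose <- function(a_pre, e_dose) {
  stopifnot(is.numeric(a_pre), is.numeric(e_dose), length(e_dose) == 1L)
  if (any(a_pre < 0)) stop("a_pre must be >= 0", call. = FALSE)
  if (e_dose < 0 || e_dose >= 1)
    stop("e_dose must lie in [0, 1)", call. = FALSE)
  (1 - e_dose) * a_pre
}

#' Equilibria of the soluble compartment
#'
#' Long-run limits of the soluble concentration under each regimen. The
#' untreated and intrathecal cases are fixed points of the continuous
#' dynamics (`P/C` and `P/(C + CIT)`). Under periodic IV dosing the system
#' approaches a periodic orbit; `iv_trough` is the fixed point of the
#' one-interval decay-then-dose map,
#' `A_pre = P (1 - exp(-C tau)) / (C (1 - (1 - E) exp(-C tau)))`,
#' and `iv_peak = (1 - E) * iv_trough` is the post-dose limit.
#'
#' @param params A [kinetic_params()] object.
#' @param mode One of `"untreated"`, `"intrathecal"`, `"iv_trough"`,
#'   `"iv_peak"`.
#' @return Equilibrium concentration (pg/mL).
#' @examples
#' steady_state_soluble(kinetic_params(), "untreated")  # 3600
#' steady_state_soluble(kinetic_params(), "iv_trough")  # ~283.41
#' @export
steady_state_soluble <- function(params = kinetic_params(),
                                 mode = c("untreated", "intrathecal",
                                          "iv_trough", "iv_peak")) {
  stopifnot(inherits(params, "kinetic_params"))
  mode <- match.arg(mode)
  C <- params$c_nat
  decay <- exp(-C * params$tau_dose)
  trough <- params$p_prod * (1 - decay) /
    (C * (1 - (1 - params$e_dose) * decay))
  switch(mode,
         untreated   = params$p_prod / C,
         intrathecal = params$p_prod / (C + params$c_it),
         iv_trough   = trough,
         iv_peak     = (1 - params$e_dose) * trough)
}

# ---- segmented simulation engine ------------------------------------------

# Decompose a schedule into propagation segments over [0, t_end]. Each
# segment is (t0, t1, kind, boundary): kind governs the clearance in force,
# boundary the event recorded at t1.
build_segments <- function(schedule, params, t_end) {
  s <- schedule
  if (s$arm == "untreated")
    return(list(list(t0 = 0, t1 = t_end, kind = "natural", boundary = "")))
  if (s$t_start < 0 || s$t_start >= t_end) {
    warning("therapy start at ", s$t_start,
            " months lies outside [0, t_end]; arm simulated untreated",
            call. = FALSE)
    return(list(list(t0 = 0, t1 = t_end, kind = "natural", boundary = "")))
  }
  t_stop <- s$t_stop
  if (!is.null(t_stop) && t_stop >= t_end) {
    warning("therapy stop at ", t_stop,
            " months lies beyond the horizon and is ignored", call. = FALSE)
    t_stop <- NULL
  }
  segs <- list()
  if (s$arm == "intrathecal") {
    segs[[1]] <- list(t0 = 0, t1 = s$t_start, kind = "natural",
                      boundary = "start")
    on_end <- if (is.null(t_stop)) t_end else t_stop
    segs[[2]] <- list(t0 = s$t_start, t1 = on_end, kind = "on",
                      boundary = if (is.null(t_stop)) "" else "stop")
    if (!is.null(t_stop))
      segs[[3]] <- list(t0 = t_stop, t1 = t_end,
                        kind = if (is.infinite(s$washout_rate)) "natural"
                               else "washout",
                        boundary = "")
  } else {                                   # iv
    dose_end <- if (is.null(t_stop)) t_end else t_stop
    # a dose falling at the stop instant (to within 1e-3 month, under an
    # hour) is not administered: therapy is already discontinued then. The
    # window also absorbs the O(dt^2) interpolation error of a detected
    # crossing time used as a stop rule, which would otherwise flip the
    # knife-edge of a dose scheduled exactly at the stop.
    doses <- seq(s$t_start, dose_end - 1e-3, by = params$tau_dose)
    if (anyDuplicated(doses))
      stop("duplicate IV dose times in schedule", call. = FALSE)
    dose_at_zero <- doses[1] < 1e-12
    if (!dose_at_zero)
      segs[[1]] <- list(t0 = 0, t1 = doses[1], kind = "natural",
                        boundary = "dose")
    bounds <- c(doses, dose_end)
    for (i in seq_along(doses)) {
      t1 <- bounds[i + 1]
      last_dose <- i == length(doses)
      segs[[length(segs) + 1]] <- list(
        t0 = doses[i], t1 = t1, kind = "natural",
        boundary = if (!last_dose) "dose"
                   else if (!is.null(t_stop)) "stop" else "")
    }
    if (!is.null(t_stop))
      segs[[length(segs) + 1]] <- list(t0 = t_stop, t1 = t_end,
                                       kind = "natural", boundary = "")
    attr(segs, "dose_at_zero") <- dose_at_zero
  }
  out <- Filter(function(g) g$t1 > g$t0 + 1e-12, segs)
  attributes(out)$dose_at_zero <- isTRUE(attr(segs, "dose_at_zero"))
  out
}

# Propagate one segment analytically. `rel` are elapsed times from segment
# start; returns concentrations. Washout segments (time-varying clearance
# C + c_it exp(-w s)) have no elementary antiderivative and fall back to the
# adaptive integrator.
propagate_closed <- function(kind, a0, rel, params, schedule, tol = 1e-10) {
  switch(kind,
         natural = soluble_closed_form(rel, a0, params, therapy_on = FALSE),
         on      = soluble_closed_form(rel, a0, params, therapy_on = TRUE),
         washout = propagate_ode(kind, a0, rel, params, schedule, tol = tol))
}

propagate_ode <- function(kind, a0, rel, params, schedule, tol = 1e-8) {
  w <- schedule$washout_rate
  kfun <- switch(kind,
                 natural = function(s) params$c_nat,
                 on      = function(s) params$c_nat + params$c_it,
                 washout = function(s) params$c_nat + params$c_it * exp(-w * s))
  deriv <- function(s, y, parms) list(params$p_prod - kfun(s) * y[1])
  times <- c(0, rel)
  out <- deSolve::lsoda(c(A = a0), times, deriv, NULL,
                        rtol = tol, atol = tol)
  pmax(0, out[-1L, "A"])
}

simulate_soluble_engine <- function(schedule, params, t_end, dt, propagate) {
  stopifnot(inherits(schedule, "therapy_schedule"),
            inherits(params, "kinetic_params"))
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  segs <- build_segments(schedule, params, t_end)
  a <- params$a0
  if (isTRUE(attr(segs, "dose_at_zero"))) {
    post <- apply_dose(a, params$e_dose)
    times <- c(0, 0); conc <- c(a, post); event <- c("dose_pre", "dose_post")
    dose_times <- 0
    a <- post
  } else {
    times <- 0; conc <- params$a0; event <- ""
    dose_times <- numeric(0)
  }
  for (g in segs) {
    grid <- segment_grid(g$t0, g$t1, dt)
    vals <- propagate(g$kind, a, grid - g$t0, params, schedule)
    ev <- rep("", length(grid))
    a <- vals[length(vals)]
    if (g$boundary == "dose") {
      ev[length(ev)] <- "dose_pre"
      times <- c(times, grid); conc <- c(conc, vals); event <- c(event, ev)
      a <- apply_dose(a, params$e_dose)
      times <- c(times, g$t1); conc <- c(conc, a); event <- c(event, "dose_post")
      dose_times <- c(dose_times, g$t1)
    } else {
      ev[length(ev)] <- g$boundary
      times <- c(times, grid); conc <- c(conc, vals); event <- c(event, ev)
    }
  }
  traj <- data.frame(time = times, conc = conc, event = event,
                     stringsAsFactors = FALSE)
  attr(traj, "dose_times") <- dose_times
  attr(traj, "schedule") <- schedule
  attr(traj, "params") <- params
  class(traj) <- c("soluble_trajectory", "data.frame")
  traj
}

#' Simulate the soluble compartment under a therapy schedule
#'
#' Piecewise-exact simulation of the soluble CSF amyloid-beta concentration:
#' between events (therapy start, IV doses, therapy stop) the closed-form
#' exponential solution is evaluated on the output grid; IV doses are applied
#' as instantaneous fractional reductions, with both the pre-dose and
#' post-dose value recorded at each dose instant. After a stop with a finite
#' washout rate the intrathecal clearance decays as
#' `c_it exp(-washout_rate (t - t_stop))`; that segment has no elementary
#' solution and is integrated adaptively.
#'
#' @param schedule A [therapy_schedule()].
#' @param params A [kinetic_params()].
#' @param t_end Simulation horizon (months).
#' @param dt Output grid step (months).
#'
#' @return A `soluble_trajectory`: a data frame with columns `time` (months),
#'   `conc` (pg/mL) and `event` (one of `""`, `"start"`, `"stop"`,
#'   `"dose_pre"`, `"dose_post"`), with attributes `dose_times`, `schedule`
#'   and `params`.
#' @seealso [ode_reference_solve()] for the independent numerical route,
#'   [percent_reduction()], [detect_crossing()].
#' @examples
#' tr <- simulate_soluble(therapy_schedule("intrathecal", t_start = 12),
#'                        kinetic_params(), t_end = 36, dt = 0.1)
#' tail(tr, 3)
#' @export
simulate_soluble <- function(schedule, params = kinetic_params(),
                             t_end = 220, dt = 0.01) {
  simulate_soluble_engine(schedule, params, t_end, dt, propagate_closed)
}

#' Adaptive ODE reference solution of the soluble compartment
#'
#' Solves the same piecewise dynamics as [simulate_soluble()] by adaptive
#' numerical integration (`deSolve::lsoda`) within every segment, with doses
#' applied as instantaneous multiplications between segments. Serves as an
#' independent numerical oracle for the closed-form engine; the two agree to
#' within roughly the integrator tolerance.
#'
#' @inheritParams simulate_soluble
#' @param tol Relative (and absolute) integrator tolerance.
#' @return A `soluble_trajectory` (see [simulate_soluble()]).
#' @export
ode_reference_solve <- function(schedule, params = kinetic_params(),
                                t_end = 220, dt = 0.01, tol = 1e-8) {
  prop <- function(kind, a0, rel, params, schedule)
    propagate_ode(kind, a0, rel, params, schedule, tol = tol)
  simulate_soluble_engine(schedule, params, t_end, dt, prop)
}

#' Percent reduction of soluble concentration relative to a baseline
#'
#' Computes `1 - A(t_eval) / baseline`. At dose instants the trajectory holds
#' two values; the `pre_dose` convention (the default, a conservative trough
#' reading) uses the pre-dose value, `instant` the post-dose one.
#'
#' @param traj A `soluble_trajectory`.
#' @param baseline Reference concentration (pg/mL), `> 0`. Typically the
#'   pre-treatment level at therapy start.
#' @param t_eval Evaluation time on the trajectory clock (months).
#' @param convention `"pre_dose"` or `"instant"`.
#' @return Fractional reduction (may be negative if concentration rose).
#' @examples
#' p <- kinetic_params()
#' tr <- simulate_soluble(therapy_schedule("intrathecal", t_start = 120), p,
#'                        t_end = 140, dt = 0.05)
#' percent_reduction(tr, baseline = soluble_closed_form(120, 100, p), 132)
#' @export
percent_reduction <- function(traj, baseline, t_eval,
                              convention = c("pre_dose", "instant")) {
  stopifnot(inherits(traj, "soluble_trajectory"))
  if (!is.numeric(baseline) || baseline <= 0)
    stop("baseline must be > 0", call. = FALSE)
  convention <- match.arg(convention)
  1 - traj_interp(traj$time, traj$conc, t_eval, convention) / baseline
}

#' Time for soluble amyloid to reaccumulate after discontinuation
#'
#' Smallest `t >= 0` after therapy cessation at which the rebounding
#' concentration reaches `target_fraction` of the untreated steady state
#' `P/C`. With `"immediate"` washout the rebound is the untreated closed form
#' and the crossing time is inverted analytically; with a finite washout rate
#' the residual clearance `c_it exp(-washout t)` is integrated numerically and
#' the crossing found by root-finding (tolerance 1e-8 months).
#'
#' @param params A [kinetic_params()].
#' @param a_start Concentration at the moment of discontinuation (pg/mL).
#' @param target_fraction Fraction of the untreated steady state, in (0, 1).
#' @param washout `"immediate"` or a positive decay rate (1/month).
#' @param horizon Search horizon (months) for the numerical case.
#' @return Months to reach the target; `0` if already at or above it; `NA` if
#'   not reached within the horizon.
#' @examples
#' reaccumulation_time(kinetic_params(), 189.47, 0.5)  # ~12.78 months
#' @export
reaccumulation_time <- function(params = kinetic_params(), a_start,
                                target_fraction = 0.5, washout = "immediate",
                                horizon = 600) {
  stopifnot(inherits(params, "kinetic_params"), is.numeric(a_start))
  if (target_fraction <= 0 || target_fraction >= 1)
    stop("target_fraction must lie in (0, 1)", call. = FALSE)
  ass <- params$p_prod / params$c_nat
  target <- target_fraction * ass
  if (a_start >= target) return(0)
  if (identical(washout, "immediate") || is.infinite(washout))
    return(log((ass - a_start) / (ass - target)) / params$c_nat)
  stopifnot(is.numeric(washout), washout > 0)
  sched <- therapy_schedule("intrathecal", t_start = 0, t_stop = 1,
                            washout_rate = washout)
  a_of <- function(t) {
    if (t == 0) return(a_start)
    propagate_ode("washout", a_start, t, params, sched, tol = 1e-10)
  }
  f <- function(t) a_of(t) - target
  # bracket on a coarse grid, then polish
  grid <- seq(0, horizon, length.out = 241L)
  vals <- vapply(grid, f, numeric(1))
  idx <- which(vals >= 0)[1L]
  if (is.na(idx)) return(NA_real_)
  if (idx == 1L) return(0)
  stats::uniroot(f, c(grid[idx - 1L], grid[idx]), tol = 1e-8)$root
}
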