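#' Generate a virtual cohort of subjects
#'
#' Draws per-subject kinetic parameters around a reference set with
#' between-subject lognormal variability: `p_prod`, `c_nat`, `c_it` and
#' `e_dose` are drawn from lognormal distributions whose arithmetic mean
#' equals the reference value and whose coefficient of variation is `cv`
#' (`sdlog = sqrt(log(1 + cv^2))`, `meanlog = log(mean) - sdlog^2/2`). Draws
#' are truncated to the [1\%, 99\%] quantiles of their distribution to avoid
#' pathological subjects; `e_dose` is additionally capped below 1. Arms are
#' assigned in rotation (untreated, intrathecal, iv). `cv = 0` reproduces the
#' reference parameters exactly; the same seed reproduces the same cohort.
#'
#' @param n Number of subjects (`>= 1`).
#' @param cv Coefficient of variation of the between-subject distribution,
#'   in `[0, 1)`.
#' @param seed Integer seed.
#' @param params Reference [kinetic_params()].
#' @param arms Arms assigned in rotation.
#'
#' @return Data frame with columns `subject_id`, `arm` and one column per
#'   kinetic parameter; attribute `seed` records the seed.
#' @examples
#' head(generate_virtual_cohort(6, cv = 0.2, seed = 7))
#' @export
generate_virtual_cohort <- function(n, cv = 0.2, seed = 1L,
                                    params = kinetic_params(),
                                    arms = c("untreated", "intrathecal",
                                             "iv")) {
  stopifnot(n >= 1, inherits(params, "kinetic_params"))
  if (!is.numeric(cv) || cv < 0 || cv >= 1)
    stop("cv must lie in [0, 1)", call. = FALSE)
  draw <- function(mean_val) {
    if (cv == 0 || mean_val == 0) return(rep(mean_val, n))
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(mean_val) - sdlog^2 / 2
    x <- stats::rlnorm(n, meanlog, sdlog)
    lo <- stats::qlnorm(0.01, meanlog, sdlog)
    hi <- stats::qlnorm(0.99, meanlog, sdlog)
    pmin(pmax(x, lo), hi)
  }
  cohort <- with_local_seed(seed, {
    data.frame(subject_id = sprintf("S%04d", seq_len(n)),
               arm = rep_len(arms, n),
               a0 = rep(params$a0, n),
               p_prod = draw(params$p_prod),
               c_nat = draw(params$c_nat),
               c_it = draw(params$c_it),
               e_dose = pmin(draw(params$e_dose), 0.99),
               tau_dose = rep(params$tau_dose, n),
               stringsAsFactors = FALSE)
  })
  attr(cohort, "seed") <- seed
  attr(cohort, "cv") <- cv
  cohort
}

#' Sample noisy observations from simulated trajectories
#'
#' Emulates a lumbar-puncture and PET visit schedule: CSF concentrations get
#' multiplicative lognormal noise (`value = A(t) * exp(rnorm(0, csf_sigma_log))`,
#' keeping concentrations positive as assay error is proportional), PET
#' centiloids additive Gaussian noise clipped at 0 (the number of clipped
#' scans is recorded). Zero noise returns the trajectory values exactly.
#'
#' @param soluble_traj A `soluble_trajectory`, or `NULL`.
#' @param pet_traj A `pet_trajectory`, or `NULL`.
#' @param csf_times,pet_times Observation times (months) within the
#'   trajectory spans.
#' @param csf_sigma_log SD of the log-scale CSF noise.
#' @param pet_sigma_cl SD of the additive PET noise (CL).
#' @param seed Integer seed.
#'
#' @return Data frame with columns `time_month`, `measure`
#'   (`"csf_pg_ml"`/`"pet_cl"`), `value`; attributes `noise` and
#'   `n_clipped`.
#' @examples
#' tr <- simulate_soluble(therapy_schedule("untreated"), t_end = 24, dt = 0.1)
#' sample_observations(tr, csf_times = c(0, 6, 12), seed = 3)
#' @export
sample_observations <- function(soluble_traj = NULL, pet_traj = NULL,
                                csf_times = numeric(0),
                                pet_times = numeric(0),
                                csf_sigma_log = 0.1, pet_sigma_cl = 3,
                                seed = 1L) {
  stopifnot(csf_sigma_log >= 0, pet_sigma_cl >= 0)
  if (length(csf_times) && is.null(soluble_traj))
    stop("csf_times given without a soluble trajectory", call. = FALSE)
  if (length(pet_times) && is.null(pet_traj))
    stop("pet_times given without a PET trajectory", call. = FALSE)
  n_clipped <- 0L
  obs <- with_local_seed(seed, {
    rows <- list()
    if (length(csf_times)) {
      truth <- vapply(csf_times, function(t)
        traj_interp(soluble_traj$time, soluble_traj$conc, t, "pre_dose"),
        numeric(1))
      rows$csf <- data.frame(time_month = csf_times, measure = "csf_pg_ml",
                             value = truth *
                               exp(stats::rnorm(length(truth), 0,
                                                csf_sigma_log)))
    }
    if (length(pet_times)) {
      truth <- vapply(pet_times, function(t)
        traj_interp(pet_traj$time, pet_traj$centiloid, t), numeric(1))
      v <- truth + stats::rnorm(length(truth), 0, pet_sigma_cl)
      n_clipped <<- sum(v < 0)
      rows$pet <- data.frame(time_month = pet_times, measure = "pet_cl",
                             value = pmax(v, 0))
    }
    do.call(rbind, rows)
  })
  rownames(obs) <- NULL
  attr(obs, "noise") <- c(csf_sigma_log = csf_sigma_log,
                          pet_sigma_cl = pet_sigma_cl)
  attr(obs, "n_clipped") <- n_clipped
  attr(obs, "seed") <- seed
  obs
}

#' Recover kinetic parameters from CSF observations
#'
#' Bounded nonlinear least-squares fit (Levenberg-Marquardt,
#' `minpack.lm::nlsLM`) of the closed-form soluble solution
#' `A(t) = (a_init - P/k) exp(-k t) + P/k` to CSF observations, estimating
#' the initial level `a_init`, production `P` and the effective total
#' clearance `k` (for an on-therapy intrathecal subject `k = c_nat + c_it`).
#' Observation times are interpreted on the same clock as the fitted decay
#' (time since therapy start for a treated subject).
#'
#' @param obs Data frame from [sample_observations()] (rows with
#'   `measure == "csf_pg_ml"` are used), or any data frame with
#'   `time_month` and `value`.
#' @param init Named starting values `c(a_init=, p_prod=, k=)`; defaults are
#'   derived from the data.
#' @param lower,upper Named bounds on the three parameters.
#'
#' @return List with `estimates` (named vector `a_init`, `p_prod`, `k`),
#'   `residual_norm`, and the `fit` object.
#' @examples
#' p <- kinetic_params()
#' tr <- simulate_soluble(therapy_schedule("intrathecal", t_start = 0),
#'                        p, t_end = 12, dt = 0.05)
#' ob <- sample_observations(tr, csf_times = seq(0.5, 12, 0.5),
#'                           csf_sigma_log = 0, seed = 1)
#' recover_params(ob)$estimates  # p_prod ~180, k ~0.95
#' @export
recover_params <- function(obs, init = NULL,
                           lower = c(a_init = 0, p_prod = 0, k = 1e-4),
                           upper = c(a_init = Inf, p_prod = Inf, k = 20)) {
  df <- if ("measure" %in% names(obs))
    obs[obs$measure == "csf_pg_ml", ] else obs
  tt <- df$time_month; yy <- df$value
  if (length(unique(tt)) < 3L)
    stop("need at least 3 distinct CSF observation times", call. = FALSE)
  if (is.null(init)) {
    y_late <- mean(yy[tt >= stats::quantile(tt, 0.75)])
    init <- c(a_init = max(yy[which.min(tt)], 1e-3),
              p_prod = max(y_late, 1) * 0.5, k = 0.5)
  }
  dat <- data.frame(t = tt, y = yy)
  fit <- minpack.lm::nlsLM(
    y ~ (a_init - p_prod / k) * exp(-k * t) + p_prod / k,
    data = dat, start = as.list(init),
    lower = lower[c("a_init", "p_prod", "k")],
    upper = upper[c("a_init", "p_prod", "k")],
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  est <- stats::coef(fit)
  list(estimates = est,
       residual_norm = sqrt(sum(stats::residuals(fit)^2)),
       fit = fit)
}
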