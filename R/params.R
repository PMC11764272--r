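#' Soluble-compartment kinetic parameters
#'
#' Container for the parameters of the one-compartment soluble amyloid-beta
#' model: a constant production rate feeding a pool cleared by first-order
#' processes, with therapy acting either as an added continuous clearance
#' (intrathecal pseudodelivery) or as instantaneous per-dose fractional
#' reductions (intravenous mAb).
#'
#' Defaults are the reference parameterisation of early-to-moderate Alzheimer
#' pathology used throughout the package: baseline 100 pg/mL, production
#' 180 pg/mL/month, natural clearance 0.05/month, intrathecal therapy-induced
#' clearance 0.90/month, 60\% per-dose reduction at monthly IV intervals.
#'
#' @param a0 Initial soluble concentration at model time 0 (pg/mL).
#' @param p_prod Constant production rate (pg/mL/month).
#' @param c_nat Natural first-order clearance rate (1/month). Must be > 0.
#' @param c_it Therapy-induced intrathecal clearance rate (1/month).
#' @param e_dose Fractional reduction in soluble concentration per IV dose,
#'   in `[0, 1)`.
#' @param tau_dose IV dosing interval (months).
#'
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' kinetic_params()
#' kinetic_params(c_it = 0.5)
#' @export
kinetic_params <- function(a0 = 100, p_prod = 180, c_nat = 0.05,
                           c_it = 0.90, e_dose = 0.60, tau_dose = 1) {
  stopifnot(is.numeric(a0), is.numeric(p_prod), is.numeric(c_nat),
            is.numeric(c_it), is.numeric(e_dose), is.numeric(tau_dose))
  if (a0 < 0) stop("a0 must be >= 0", call. = FALSE)
  if (p_prod < 0) stop("p_prod must be >= 0", call. = FALSE)
  if (c_nat <= 0) stop("c_nat must be > 0", call. = FALSE)
  if (c_it < 0) stop("c_it must be >= 0", call. = FALSE)
  if (e_dose < 0 || e_dose >= 1)
    stop("e_dose must lie in [0, 1)", call. = FALSE)
  if (tau_dose <= 0) stop("tau_dose must be > 0", call. = FALSE)
  structure(list(a0 = a0, p_prod = p_prod, c_nat = c_nat, c_it = c_it,
                 e_dose = e_dose, tau_dose = tau_dose),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Soluble amyloid-beta kinetic parameters\n")
  cat(sprintf("  a0       %8.3f pg/mL        (baseline concentration)\n", x$a0))
  cat(sprintf("  p_prod   %8.3f pg/mL/month  (production rate)\n", x$p_prod))
  cat(sprintf("  c_nat    %8.4f /month       (natural clearance)\n", x$c_nat))
  cat(sprintf("  c_it     %8.4f /month       (intrathecal clearance)\n", x$c_it))
  cat(sprintf("  e_dose   %8.3f              (per-dose fractional reduction)\n",
              x$e_dose))
  cat(sprintf("  tau_dose %8.3f months       (IV dosing interval)\n", x$tau_dose))
  invisible(x)
}

#' Therapy schedule for one study arm
#'
#' Describes which delivery route an arm receives, when therapy starts and
#' (optionally) stops, and how the residual therapy effect decays after
#' discontinuation. For the intrathecal arm the added clearance decays as
#' `c_it * exp(-washout_rate * (t - t_stop))` after the stop; `"immediate"`
#' removes the effect instantaneously. For the IV arm dosing simply ceases at
#' `t_stop`; the washout rate is carried because the fibrillar therapy effect
#' of that arm washes out at the same rate.
#'
#' @param arm One of `"untreated"`, `"intrathecal"`, `"iv"`.
#' @param t_start Therapy start time (months). Ignored for the untreated arm.
#' @param t_stop Therapy stop time (months), or `NULL` for never.
#' @param washout_rate Post-stop exponential decay rate of the therapy effect
#'   (1/month), or `"immediate"`.
#'
#' @return An object of class `therapy_schedule`.
#' @examples
#' therapy_schedule("intrathecal", t_start = 120)
#' therapy_schedule("iv", t_start = 120, t_stop = 150, washout_rate = 1.5)
#' @export
therapy_schedule <- function(arm = c("untreated", "intrathecal", "iv"),
                             t_start = 120, t_stop = NULL,
                             washout_rate = "immediate") {
  arm <- match.arg(arm)
  if (identical(washout_rate, "immediate")) washout_rate <- Inf
  stopifnot(is.numeric(washout_rate), length(washout_rate) == 1L)
  if (washout_rate <= 0)
    stop("washout_rate must be > 0 or \"immediate\"", call. = FALSE)
  if (!is.null(t_stop)) {
    stopifnot(is.numeric(t_stop), length(t_stop) == 1L)
    if (t_stop <= t_start)
      stop("t_stop must be greater than t_start", call. = FALSE)
  }
  structure(list(arm = arm, t_start = t_start, t_stop = t_stop,
                 washout_rate = washout_rate),
            class = "therapy_schedule")
}

#' @export
print.therapy_schedule <- function(x, ...) {
  cat("Therapy schedule:", x$arm, "\n")
  if (x$arm != "untreated") {
    cat("  start", x$t_start, "months;",
        if (is.null(x$t_stop)) "no stop" else paste("stop", x$t_stop, "months"),
        "\n")
    if (!is.null(x$t_stop))
      cat("  washout:", if (is.infinite(x$washout_rate)) "immediate"
          else paste0(x$washout_rate, "/month"), "\n")
  }
  invisible(x)
}

#' Fibrillar (PET centiloid) compartment parameters
#'
#' Parameters of the fibrillar amyloid burden `F(t)`, expressed directly in
#' centiloids (CL): `dF/dt = k_agg * A(t) - (c_f + gamma_arm(t)) * F`, where
#' `A(t)` is the soluble concentration, `k_agg` converts soluble exposure into
#' burden accrual (the centiloid scaling is absorbed into it), `c_f` is
#' natural fibrillar clearance, and `gamma_it`/`gamma_iv` are route-specific
#' therapy-induced fibrillar clearance rates active while therapy is on (and
#' decaying at the arm's washout rate after a stop).
#'
#' @param k_agg Aggregation coefficient (CL per (pg/mL) month).
#' @param c_f Natural fibrillar clearance (1/month).
#' @param gamma_it Therapy-induced fibrillar clearance, intrathecal arm
#'   (1/month).
#' @param gamma_iv Therapy-induced fibrillar clearance, IV arm (1/month).
#' @param f0 Initial burden at model time 0 (CL).
#'
#' @return An object of class `fibrillar_params`.
#' @seealso [default_fibrillar_params()] for the shipped calibrated values.
#' @examples
#' fibrillar_params(k_agg = 2e-4, c_f = 0.01, gamma_it = 0.03, gamma_iv = 0.005)
#' @export
fibrillar_params <- function(k_agg, c_f, gamma_it = 0, gamma_iv = 0, f0 = 0) {
  vals <- c(k_agg = k_agg, c_f = c_f, gamma_it = gamma_it,
            gamma_iv = gamma_iv, f0 = f0)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all fibrillar parameters must be finite and >= 0", call. = FALSE)
  structure(as.list(vals), class = "fibrillar_params")
}

#' @export
print.fibrillar_params <- function(x, ...) {
  cat("Fibrillar (PET) compartment parameters\n")
  cat(sprintf("  k_agg    %.6g CL/(pg/mL)/month\n", x$k_agg))
  cat(sprintf("  c_f      %.6g /month\n", x$c_f))
  cat(sprintf("  gamma_it %.6g /month\n", x$gamma_it))
  cat(sprintf("  gamma_iv %.6g /month\n", x$gamma_iv))
  cat(sprintf("  f0       %.6g CL\n", x$f0))
  invisible(x)
}

#' Milestone crossing times used for calibration
#'
#' The centiloid-threshold crossing times the fibrillar surrogate is
#' calibrated to: symptomatic onset when the untreated burden rises above the
#' positivity threshold, per-arm negativity times when treated burdens fall
#' below the negativity threshold, and the between-arm difference in
#' post-discontinuation re-positivity intervals.
#'
#' @param t_onset Untreated up-crossing of the positivity threshold (months).
#' @param t_neg_it Intrathecal down-crossing of the negativity threshold
#'   (months).
#' @param t_neg_iv IV down-crossing of the negativity threshold (months).
#' @param repositivity_delay Intrathecal minus IV interval from each arm's
#'   discontinuation to re-crossing the positivity threshold (months).
#'
#' @return An object of class `milestones`.
#' @examples
#' milestones()
#' @export
milestones <- function(t_onset = 120, t_neg_it = 132, t_neg_iv = 150,
                       repositivity_delay = 6) {
  stopifnot(t_onset > 0, t_neg_it > 0, t_neg_iv > 0)
  if (t_neg_it >= t_neg_iv)
    stop("t_neg_it must be earlier than t_neg_iv", call. = FALSE)
  structure(list(t_onset = t_onset, t_neg_it = t_neg_it, t_neg_iv = t_neg_iv,
                 repositivity_delay = repositivity_delay),
            class = "milestones")
}
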