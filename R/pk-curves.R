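#' Concentration after a single oral dose
#'
#' Closed-form one-compartment disposition with first-order absorption and
#' elimination: with ke = CL/V,
#' \deqn{C(t) = \frac{D k_a}{V (k_a - k_e)} (e^{-k_e t} - e^{-k_a t}),}
#' evaluated in units such that mg doses and L volumes yield ng/ml.  When
#' ka and ke coincide (|ka - ke| < 1e-10) the analytic limit
#' \eqn{(D k_a t / V) e^{-k_a t}} is used.
#'
#' @param params One-row tibble or list with `cl_over_f` (L/h), `v_over_f`
#'   (L), `ka` (1/h); see [pk_params()].
#' @param amount Dose, mg (oral).
#' @param t Time since the dose, h; vectorised.
#' @return Concentrations, ng/ml.
#' @export
#' @examples
#' p <- pk_params(pediatric_sirolimus_model(), weight = 70)
#' conc_single_dose(p, amount = 1, t = c(0, 6, 24))
conc_single_dose <- function(params, amount, t) {
  check_number(amount, "amount", non_negative = TRUE)
  check_number(t, "t", non_negative = TRUE)
  conc_superpose(params$cl_over_f, params$v_over_f, params$ka,
                 dose_time = 0, dose_amount = amount, times = t)
}

#' Concentration profile under a dosing history
#'
#' Linear superposition of single-dose curves over an arbitrary oral dosing
#' history.  Times before the first dose return 0.
#'
#' @param params Individual parameters as for [conc_single_dose()].
#' @param doses Data frame with columns `time` (h since first dose, sorted
#'   ascending) and `amount` (mg).
#' @param times Times at which to evaluate the concentration, h.
#' @return A tibble with columns `time` and `conc` (ng/ml).
#' @export
#' @examples
#' p <- pk_params(pediatric_sirolimus_model(), weight = 20)
#' doses <- data.frame(time = seq(0, 96, by = 24), amount = 1)
#' conc_profile(p, doses, times = c(24, 96, 120))
conc_profile <- function(params, doses, times) {
  stopifnot(is.data.frame(doses), all(c("time", "amount") %in% names(doses)))
  check_number(doses$time, "doses$time", non_negative = TRUE)
  check_number(doses$amount, "doses$amount", non_negative = TRUE)
  check_number(times, "times", non_negative = TRUE)
  if (is.unsorted(doses$time)) {
    stop_sirodose("Dose times must be sorted ascending.",
                  "sirodose_invalid_input")
  }
  conc <- conc_superpose(params$cl_over_f, params$v_over_f, params$ka,
                         doses$time, doses$amount, times)
  tibble::tibble(time = times, conc = conc)
}

# Core superposition kernel (internal).  Units: amounts mg -> microgram once
# here, volumes L, so concentrations are microgram/L == ng/ml.
conc_superpose <- function(cl, v, ka, dose_time, dose_amount, times) {
  ke <- cl / v
  tau <- outer(times, dose_time, "-")      # h since each dose
  active <- tau >= 0
  tau[!active] <- 0
  amt_ug <- matrix(dose_amount * 1000, nrow = length(times),
                   ncol = length(dose_time), byrow = TRUE)
  if (abs(ka - ke) < 1e-10) {
    contrib <- amt_ug * ka * tau / v * exp(-ka * tau)
  } else {
    k <- ka / (v * (ka - ke))
    contrib <- amt_ug * k * (exp(-ke * tau) - exp(-ka * tau))
  }
  contrib[!active] <- 0
  rowSums(contrib)
}

# Superposition with analytic sensitivities to (CL, V) at fixed ka.  Returns
# conc plus dconc/deta_cl and dconc/deta_v (eta acts multiplicatively on
# CL resp. V, so d/deta = CL * d/dCL etc.).  Used by the FOCE inner problem;
# falls back to finite differences in the ka == ke corner.
conc_superpose_grad <- function(cl, v, ka, dose_time, dose_amount, times) {
  ke <- cl / v
  if (abs(ka - ke) < 1e-8) {
    f0 <- conc_superpose(cl, v, ka, dose_time, dose_amount, times)
    h <- 1e-6
    fcl <- conc_superpose(cl * exp(h), v, ka, dose_time, dose_amount, times)
    fv <- conc_superpose(cl, v * exp(h), ka, dose_time, dose_amount, times)
    return(list(conc = f0, d_eta_cl = (fcl - f0) / h, d_eta_v = (fv - f0) / h))
  }
  tau <- outer(times, dose_time, "-")
  active <- tau >= 0
  tau[!active] <- 0
  amt_ug <- matrix(dose_amount * 1000, nrow = length(times),
                   ncol = length(dose_time), byrow = TRUE)
  e1 <- exp(-ke * tau)
  e2 <- exp(-ka * tau)
  k <- ka / (v * (ka - ke))
  contrib <- amt_ug * k * (e1 - e2)
  dcontrib_dke <- amt_ug * (ka * (e1 - e2) / (v * (ka - ke)^2) -
                              k * tau * e1)
  contrib[!active] <- 0
  dcontrib_dke[!active] <- 0
  conc <- rowSums(contrib)
  dke <- rowSums(dcontrib_dke)
  # ke = CL/V: d/dCL = dke * 1/V ; d/dV = -conc/V + dke * (-CL/V^2)
  d_eta_cl <- dke * (cl / v)                       # CL * dconc/dCL
  d_eta_v <- -conc - dke * (cl / v)                # V * dconc/dV
  list(conc = conc, d_eta_cl = d_eta_cl, d_eta_v = d_eta_v)
}

#' Steady-state trough concentration
#'
#' Pre-dose concentration under repeated dosing every `tau` hours, from the
#' geometric accumulation of the single-dose curve:
#' \deqn{C_{min,ss} = \frac{D k_a}{V (k_a - k_e)} \left[
#'   \frac{e^{-k_e \tau}}{1 - e^{-k_e \tau}} -
#'   \frac{e^{-k_a \tau}}{1 - e^{-k_a \tau}} \right].}
#' This equals the limit of [conc_profile()] troughs as the number of doses
#' grows.
#'
#' @param params Individual parameters as for [conc_single_dose()];
#'   `cl_over_f` and `v_over_f` may be vectors (e.g. one virtual patient per
#'   element).
#' @param amount Dose per administration, mg.
#' @param tau Dosing interval, h (> 0).
#' @return Steady-state trough concentration(s), ng/ml.
#' @export
#' @examples
#' p <- pk_params(pediatric_sirolimus_model(), weight = 5)
#' ss_trough(p, amount = 0.5, tau = 24)
ss_trough <- function(params, amount, tau) {
  check_number(amount, "amount", non_negative = TRUE)
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau <= 0) {
    stop_sirodose("`tau` must be a single positive dosing interval in hours.",
                  "sirodose_invalid_input")
  }
  cl <- params$cl_over_f
  v <- params$v_over_f
  ka <- params$ka
  ke <- cl / v
  amt_ug <- amount * 1000
  acc <- function(k) exp(-k * tau) / (1 - exp(-k * tau))
  out <- ifelse(
    abs(ka - ke) < 1e-10,
    # limit ka -> ke of the accumulation bracket
    amt_ug * ka / v * tau * exp(-ka * tau) / (1 - exp(-ka * tau))^2,
    amt_ug * ka / (v * (ka - ke)) * (acc(ke) - acc(ka))
  )
  as.numeric(out)
}
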