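#' Define a population pharmacokinetic model
#'
#' Constructs the hierarchical model used throughout the package: a
#' one-compartment model with first-order absorption whose apparent oral
#' clearance (CL/F) and apparent volume (V/F) scale allometrically with body
#' weight, log-normal inter-individual variability on both parameters, and a
#' combined proportional-plus-additive residual error on observed
#' concentrations,
#' \deqn{OBS = IPRED (1 + \epsilon_1) + \epsilon_2.}
#'
#' Typical values are anchored at a standard weight of 70 kg with fixed
#' allometric exponents (0.75 for CL/F, 1 for V/F), so
#' \deqn{CL/F = \theta_{CL} (W/70)^{0.75} e^{\eta_{CL}}, \quad
#'       V/F = \theta_{V} (W/70)^{1} e^{\eta_{V}}.}
#' The absorption rate constant Ka is a structural constant, not estimated.
#'
#' `omega2_*` and `sigma2_*` are *variances* (of the log-normal random
#' effects eta and of the residual components), not standard deviations.
#'
#' @param theta_cl Typical CL/F at 70 kg (L/h).
#' @param theta_v Typical V/F at 70 kg (L).
#' @param ka First-order absorption rate constant (1/h), held fixed.
#' @param omega2_cl,omega2_v Variances of the log-normal inter-individual
#'   random effects on CL/F and V/F (dimensionless).
#' @param sigma2_prop Variance of the proportional residual component.
#' @param sigma2_add Variance of the additive residual component ((ng/ml)^2).
#' @param allo_exp_cl,allo_exp_v Allometric exponents for CL/F and V/F.
#' @param w_std Standard weight anchoring the typical values (kg).
#' @param covariates Optional tibble of covariate effects as produced by
#'   [covariate_spec()], with an estimated coefficient in column `theta`.
#' @return An object of class `pop_model`.
#' @seealso [pediatric_sirolimus_model()] for the reference parameter set,
#'   [pk_params()] to build individual parameters from it.
#' @export
#' @examples
#' m <- pop_model(theta_cl = 6.48, theta_v = 124, omega2_cl = 0.066,
#'                omega2_v = 0.003, sigma2_prop = 0.312, sigma2_add = 1.249)
#' m
pop_model <- function(theta_cl, theta_v, ka = 0.485,
                      omega2_cl = 0, omega2_v = 0,
                      sigma2_prop = 0, sigma2_add = 0,
                      allo_exp_cl = 0.75, allo_exp_v = 1,
                      w_std = 70, covariates = NULL) {
  check_number(theta_cl, "theta_cl", positive = TRUE)
  check_number(theta_v, "theta_v", positive = TRUE)
  check_number(ka, "ka", positive = TRUE)
  check_number(omega2_cl, "omega2_cl", non_negative = TRUE)
  check_number(omega2_v, "omega2_v", non_negative = TRUE)
  check_number(sigma2_prop, "sigma2_prop", non_negative = TRUE)
  check_number(sigma2_add, "sigma2_add", non_negative = TRUE)
  check_number(w_std, "w_std", positive = TRUE)
  if (!is.null(covariates)) {
    covariates <- validate_covariates(covariates)
  }
  structure(
    list(theta_cl = theta_cl, theta_v = theta_v, ka = ka,
         omega2_cl = omega2_cl, omega2_v = omega2_v,
         sigma2_prop = sigma2_prop, sigma2_add = sigma2_add,
         allo_exp_cl = allo_exp_cl, allo_exp_v = allo_exp_v,
         w_std = w_std, covariates = covariates),
    class = "pop_model"
  )
}

#' Reference pediatric sirolimus model
#'
#' The final published population model for sirolimus in children with
#' tuberous sclerosis complex: CL/F = 6.48 x (W/70)^0.75 L/h,
#' V/F = 124 x (W/70) L, Ka fixed at 0.485/h, with inter-individual
#' variances 0.066 (CL/F) and 0.003 (V/F) and combined residual variances
#' 0.312 (proportional) and 1.249 ng^2/ml^2 (additive).  Used as the
#' generating model for synthetic cohorts and as the simulation model for
#' initial-dose recommendation.
#'
#' @return A `pop_model`.
#' @export
#' @examples
#' pk_params(pediatric_sirolimus_model(), weight = 20)
pediatric_sirolimus_model <- function() {
  pop_model(theta_cl = 6.48, theta_v = 124, ka = 0.485,
            omega2_cl = 0.066, omega2_v = 0.003,
            sigma2_prop = 0.312, sigma2_add = 1.249)
}

#' @export
print.pop_model <- function(x, ...) {
  cat("<pop_model> one-compartment oral, allometric weight scaling\n")
  cat(sprintf("  CL/F = %.4g x (W/%g)^%g L/h   (omega2 = %.4g)\n",
              x$theta_cl, x$w_std, x$allo_exp_cl, x$omega2_cl))
  cat(sprintf("  V/F  = %.4g x (W/%g)^%g L     (omega2 = %.4g)\n",
              x$theta_v, x$w_std, x$allo_exp_v, x$omega2_v))
  cat(sprintf("  Ka   = %.4g 1/h (fixed)\n", x$ka))
  cat(sprintf("  residual: sigma2_prop = %.4g, sigma2_add = %.4g\n",
              x$sigma2_prop, x$sigma2_add))
  if (!is.null(x$covariates) && nrow(x$covariates) > 0) {
    cat("  covariates:\n")
    for (i in seq_len(nrow(x$covariates))) {
      cv <- x$covariates[i, ]
      cat(sprintf("    %s on %s (%s), theta = %.4g\n",
                  cv$name, toupper(cv$param), cv$form, cv$theta))
    }
  }
  invisible(x)
}

#' Individual pharmacokinetic parameters
#'
#' Builds subject-level CL/F, V/F and Ka from the population model, body
#' weight, covariate values and random effects:
#' CL/F = theta_cl x (W/w_std)^0.75 x covariate factors x exp(eta_cl), and
#' analogously for V/F with exponent 1.  Ka is copied unchanged.
#'
#' @param model A [pop_model()].
#' @param weight Body weight(s), kg; strictly positive.
#' @param eta_cl,eta_v Random effects on log CL/F and log V/F (default 0,
#'   i.e. the typical individual).
#' @param covariates Optional one-row data frame (or named list) of covariate
#'   values for the model's covariate effects.
#' @return A tibble with one row per weight: `weight`, `cl_over_f` (L/h),
#'   `v_over_f` (L), `ka` (1/h).
#' @export
#' @examples
#' pk_params(pediatric_sirolimus_model(), weight = c(5, 70))
pk_params <- function(model, weight, eta_cl = 0, eta_v = 0,
                      covariates = NULL) {
  stopifnot(inherits(model, "pop_model"))
  check_number(weight, "weight", positive = TRUE)
  check_number(eta_cl, "eta_cl")
  check_number(eta_v, "eta_v")
  fac <- covariate_factors(model, covariates)
  cl <- model$theta_cl * (weight / model$w_std)^model$allo_exp_cl *
    fac$cl * exp(eta_cl)
  v <- model$theta_v * (weight / model$w_std)^model$allo_exp_v *
    fac$v * exp(eta_v)
  tibble::tibble(weight = weight, cl_over_f = cl, v_over_f = v, ka = model$ka)
}

#' Typical per-kilogram clearance across body weights
#'
#' Evaluates CL/F(W)/W at eta = 0, the weight-normalised clearance implied by
#' allometric scaling with exponent 0.75: because clearance grows more slowly
#' than weight, per-kg clearance falls from about 0.18 L/h/kg at 5 kg to
#' about 0.10 L/h/kg at 60 kg under the reference model, which is why the
#' per-kg starting dose must shrink as children grow.
#'
#' @param model A [pop_model()].
#' @param weights Body weights, kg.
#' @return A tibble with columns `weight`, `cl_over_f`, `cl_per_kg`.
#' @export
#' @examples
#' clearance_per_kg(pediatric_sirolimus_model(), c(5, 20, 60))
clearance_per_kg <- function(model, weights = c(5, 10, 20, 30, 40, 50, 60)) {
  p <- pk_params(model, weights)
  tibble::tibble(weight = weights, cl_over_f = p$cl_over_f,
                 cl_per_kg = p$cl_over_f / weights)
}
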