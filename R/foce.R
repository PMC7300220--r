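#' Residual variance of an observed concentration
#'
#' Combined proportional + additive error model: an observation is
#' `IPRED * (1 + eps1) + eps2` with independent zero-mean `eps1`, `eps2`, so
#' its variance given the individual prediction is
#' `ipred^2 * sigma2_prop + sigma2_add`.
#'
#' @param ipred Individual predicted concentration(s), ng/ml (>= 0).
#' @param model A [pop_model()].
#' @return Variance(s), (ng/ml)^2.
#' @export
#' @examples
#' residual_variance(10, pediatric_sirolimus_model())
residual_variance <- function(ipred, model) {
  stopifnot(inherits(model, "pop_model"))
  check_number(ipred, "ipred", non_negative = TRUE)
  if (model$sigma2_prop < 0 || model$sigma2_add < 0) {
    stop_sirodose("Residual variance parameters must be non-negative.",
                  "sirodose_invalid_model")
  }
  ipred^2 * model$sigma2_prop + model$sigma2_add
}

# Individual predictions and their eta-sensitivities for one subject.
subject_pred <- function(model, subj, eta_cl = 0, eta_v = 0, grad = FALSE) {
  fac <- covariate_factors(model, subj$covs)
  cl <- model$theta_cl * (subj$wt / model$w_std)^model$allo_exp_cl *
    fac$cl * exp(eta_cl)
  v <- model$theta_v * (subj$wt / model$w_std)^model$allo_exp_v *
    fac$v * exp(eta_v)
  if (grad) {
    conc_superpose_grad(cl, v, model$ka, subj$dose_time, subj$dose_amount,
                        subj$obs_time)
  } else {
    list(conc = conc_superpose(cl, v, model$ka, subj$dose_time,
                               subj$dose_amount, subj$obs_time))
  }
}

# -2 log joint density of (y, eta) for one subject, up to no constants:
# sum_j [log(2 pi v_j) + r_j^2 / v_j] + sum_active [eta^2/omega2 +
# log(2 pi omega2)], with the residual variance evaluated at the
# eta-dependent prediction (the FOCE "interaction").
subject_joint_m2l <- function(model, subj, eta, active, omega2) {
  p <- subject_pred(model, subj, eta[1], eta[2])
  v <- p$conc^2 * model$sigma2_prop + model$sigma2_add
  if (any(v <= 0)) return(1e100)
  r <- subj$obs_dv - p$conc
  val <- sum(log(2 * pi * v) + r^2 / v)
  if (any(active)) {
    val <- val + sum(eta[active]^2 / omega2[active]) +
      sum(log(2 * pi * omega2[active]))
  }
  val
}

subject_joint_grad <- function(model, subj, eta, active, omega2) {
  p <- subject_pred(model, subj, eta[1], eta[2], grad = TRUE)
  v <- p$conc^2 * model$sigma2_prop + model$sigma2_add
  r <- subj$obs_dv - p$conc
  g <- numeric(2)
  for (k in 1:2) {
    df <- if (k == 1) p$d_eta_cl else p$d_eta_v
    dv <- 2 * p$conc * df * model$sigma2_prop
    g[k] <- sum(dv / v - 2 * r * df / v - r^2 * dv / v^2)
  }
  g[active] <- g[active] + 2 * eta[active] / omega2[active]
  g[!active] <- 0
  g
}

# FOCE-I contribution of one subject: locate the conditional mode of
# (eta_cl, eta_v), then apply the Laplace/first-order-conditional correction
# with the curvature of the joint objective evaluated at the mode.
foce_subject <- function(model, subj, inner_tol = 1e-8) {
  omega2 <- c(model$omega2_cl, model$omega2_v)
  active <- omega2 > 0
  eta <- c(0, 0)
  converged <- TRUE
  if (any(active)) {
    fn <- function(ea) {
      eta_full <- c(0, 0)
      eta_full[active] <- ea
      subject_joint_m2l(model, subj, eta_full, active, omega2)
    }
    gr <- function(ea) {
      eta_full <- c(0, 0)
      eta_full[active] <- ea
      subject_joint_grad(model, subj, eta_full, active, omega2)[active]
    }
    opt <- tryCatch(
      nlminb(rep(0, sum(active)), fn, gradient = gr,
             control = list(abs.tol = 0, rel.tol = 1e-12,
                            x.tol = 1e-10, iter.max = 200)),
      error = function(e) NULL)
    if (is.null(opt)) {
      converged <- FALSE
    } else {
      eta[active] <- opt$par
      gnorm <- sqrt(sum(gr(opt$par)^2))
      if (!is.finite(opt$objective)) converged <- FALSE
      if (gnorm > max(inner_tol, 1e-4 * abs(opt$objective))) {
        # retry from a BFGS polish before flagging
        opt2 <- tryCatch(
          optim(opt$par, fn, gr, method = "BFGS",
                control = list(reltol = 1e-14, maxit = 200)),
          error = function(e) NULL)
        if (!is.null(opt2) && opt2$value <= opt$objective + 1e-9) {
          eta[active] <- opt2$par
        }
      }
    }
  }
  h_val <- subject_joint_m2l(model, subj, eta, active, omega2)
  if (!is.finite(h_val)) {
    return(list(ofv = NA_real_, eta_cl = eta[1], eta_v = eta[2],
                converged = FALSE))
  }
  if (!any(active)) {
    return(list(ofv = h_val, eta_cl = 0, eta_v = 0, converged = TRUE))
  }
  p <- subject_pred(model, subj, eta[1], eta[2], grad = TRUE)
  v <- p$conc^2 * model$sigma2_prop + model$sigma2_add
  # Laplace curvature: exact Hessian of h/2 at the mode (finite differences
  # of the analytic gradient); fall back to the Gauss-Newton form
  # G' W G + Omega^-1 if the exact Hessian is not positive definite
  d_act <- sum(active)
  idx <- which(active)
  step <- 1e-5
  Hfull <- matrix(0, d_act, d_act)
  for (k in seq_len(d_act)) {
    e <- c(0, 0)
    e[idx[k]] <- step
    gp <- subject_joint_grad(model, subj, eta + e, active, omega2)[idx]
    gm <- subject_joint_grad(model, subj, eta - e, active, omega2)[idx]
    Hfull[, k] <- (gp - gm) / (2 * step)
  }
  H <- (Hfull + t(Hfull)) / 4   # symmetrise, then Hessian of h/2
  if (!all(is.finite(H)) || any(eigen(H, symmetric = TRUE,
                                      only.values = TRUE)$values <= 0)) {
    G <- cbind(p$d_eta_cl, p$d_eta_v)[, active, drop = FALSE]
    H <- crossprod(G / sqrt(v)) + diag(1 / omega2[active], nrow = d_act)
  }
  ld <- determinant(H, logarithm = TRUE)

  ofv <- h_val - d_act * log(2 * pi) + as.numeric(ld$modulus)
  list(ofv = ofv, eta_cl = eta[1], eta_v = eta[2], converged = converged,
       pred = p$conc, var = v)
}

#' FOCE-I objective function value
#'
#' Computes the first-order-conditional-estimation-with-interaction
#' approximation to -2 log marginal likelihood for a hierarchical
#' one-compartment model.  For each subject the mode of the joint density of
#' the random effects given the observations is located (quasi-Newton,
#' analytic gradient, started at eta = 0), and the marginal likelihood is
#' approximated by a Laplace-type expansion about that mode with the
#' residual variance evaluated at the eta-dependent individual prediction.
#' The OFV includes its `n log(2 pi)` constants, so in the limit of
#' vanishing inter-individual variance it equals the exact fixed-effects
#' -2 log-likelihood.
#'
#' @param data Dataset tibble (see [read_pk_dataset()]).
#' @param model A [pop_model()].
#' @return A list: `ofv` (scalar), `eta` (tibble of per-subject conditional
#'   modes with a convergence flag).
#' @export
#' @examples
#' d <- simulate_observations(generate_cohort(n = 3, seed = 1),
#'                            pediatric_sirolimus_model(), seed = 2)
#' ofv_foce(d, pediatric_sirolimus_model())$ofv
ofv_foce <- function(data, model) {
  stopifnot(inherits(model, "pop_model"))
  cov_names <- covariate_columns(model)
  subjects <- split_subjects(data, cov_names)
  res <- lapply(subjects, function(s) foce_subject(model, s))
  ofv_i <- vapply(res, function(r) r$ofv, numeric(1))
  if (all(is.na(ofv_i))) {
    stop_sirodose("FOCE inner problem failed for every subject.",
                  "sirodose_estimation_error")
  }
  eta <- tibble::tibble(
    id = vapply(subjects, function(s) s$id, data$id[1]),
    eta_cl = vapply(res, function(r) r$eta_cl, numeric(1)),
    eta_v = vapply(res, function(r) r$eta_v, numeric(1)),
    converged = vapply(res, function(r) r$converged, logical(1))
  )
  list(ofv = sum(ofv_i), ofv_by_subject = ofv_i, eta = eta)
}

covariate_columns <- function(model) {
  if (is.null(model$covariates)) character() else
    unique(model$covariates$name)
}
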