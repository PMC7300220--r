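#' Fit the population model by FOCE-I
#'
#' Maximum-likelihood estimation of the hierarchical model: minimises the
#' FOCE-I objective [ofv_foce()] over the typical values (theta_cl,
#' theta_v), the inter-individual variances (omega2_cl, omega2_v), the
#' residual variances (sigma2_prop, sigma2_add) and any covariate
#' coefficients, with the allometric exponents and Ka held fixed.  Typical
#' values and variances are optimised on the log scale (positivity by
#' construction; near-zero variance estimates land on a soft lower boundary
#' and are reported as boundary hits rather than failures).  The outer
#' optimisation is multi-started from deterministically jittered initials to
#' guard against local minima.
#'
#' @param data Dataset tibble (see [read_pk_dataset()]).
#' @param start A [pop_model()] giving starting values (and the fixed Ka,
#'   exponents and covariate structure).
#' @param fix Character vector of parameters to hold at their starting
#'   values; any of `"theta_cl","theta_v","omega2_cl","omega2_v",
#'   "sigma2_prop","sigma2_add"`.
#' @param settings List overriding defaults: `multi_start` (number of
#'   starts, default 3), `se` (compute standard errors, default TRUE),
#'   `rel_tol` (outer relative function tolerance, default 1e-9),
#'   `iter_max` (default 500).
#' @return A `pk_fit` object: fitted `model`, `ofv`, `estimates` tibble
#'   (estimate, SE% from the inverse curvature of the OFV surface), the
#'   per-subject random-effect modes `eta`, and convergence information.
#'   Methods: [tidy()], [glance()], `print()`.
#' @export
fit_pk <- function(data, start, fix = character(), settings = list()) {
  stopifnot(inherits(start, "pop_model"))
  data <- validate_pk_dataset(data)
  st <- modifyList(list(multi_start = 3, se = TRUE, rel_tol = 1e-9,
                        iter_max = 500), settings)
  base_names <- c("theta_cl", "theta_v", "omega2_cl", "omega2_v",
                  "sigma2_prop", "sigma2_add")
  bad_fix <- setdiff(fix, base_names)
  if (length(bad_fix)) {
    stop_sirodose(sprintf("Unknown parameter(s) in `fix`: %s.",
                          paste(bad_fix, collapse = ", ")),
                  "sirodose_invalid_input")
  }
  free <- setdiff(base_names, fix)
  covs <- start$covariates
  n_cov <- if (is.null(covs)) 0L else nrow(covs)

  # transformed parameter vector: log for positives, raw for power/linear
  # covariate coefficients
  pack <- function(model) {
    p <- if (length(free)) {
      log(unlist(model[free], use.names = FALSE))
    } else numeric(0)
    if (n_cov > 0) {
      ct <- model$covariates$theta
      gen <- model$covariates$form == "genotype"
      p <- c(p, ifelse(gen, log(ct), ct))
    }
    p
  }
  unpack <- function(p, model) {
    vals <- exp(p[seq_along(free)])
    for (i in seq_along(free)) model[[free[i]]] <- vals[i]
    if (n_cov > 0) {
      ct <- p[length(free) + seq_len(n_cov)]
      gen <- model$covariates$form == "genotype"
      model$covariates$theta <- ifelse(gen, exp(ct), ct)
    }
    model
  }
  var_idx <- which(free %in% c("omega2_cl", "omega2_v",
                               "sigma2_prop", "sigma2_add"))
  lower <- rep(-Inf, length(free) + n_cov)
  lower[var_idx] <- log(1e-8)   # soft variance floor; boundary hits reported

  n_eval <- 0L
  obj <- function(p) {
    n_eval <<- n_eval + 1L
    m <- unpack(p, start)
    val <- tryCatch(ofv_foce(data, m)$ofv, error = function(e) NA_real_)
    if (!is.finite(val)) 1e100 else val
  }

  p0 <- pack(start)
  if (length(p0) == 0) {
    # everything fixed: no outer problem, just evaluate at the given model
    final <- ofv_foce(data, start)
    estimates <- tibble::tibble(parameter = character(),
                                estimate = numeric(), se_pct = numeric(),
                                boundary = logical())
    fixed_rows <- tibble::tibble(
      parameter = c(fix, "ka"),
      estimate = c(unlist(start[fix], use.names = FALSE), start$ka),
      se_pct = NA_real_, boundary = FALSE)
    return(structure(
      list(model = start, ofv = final$ofv, estimates = estimates,
           fixed = fixed_rows, eta = final$eta, converged = TRUE,
           n_subjects = length(unique(data$id)),
           n_obs = sum(is_obs_row(data)), n_eval = 1L,
           settings = st, data = data),
      class = "pk_fit"))
  }
  jit <- c(0.4, -0.4)
  starts <- list(p0)
  if (st$multi_start >= 2) starts <- c(starts, list(p0 + jit[1]))
  if (st$multi_start >= 3) starts <- c(starts, list(p0 + jit[2]))
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      nlminb(pmax(s, lower), obj, lower = lower,
             control = list(rel.tol = st$rel_tol, iter.max = st$iter_max,
                            eval.max = 4L * st$iter_max)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$objective) &&
        (is.null(best) || opt$objective < best$objective)) best <- opt
  }
  if (is.null(best)) {
    stop_sirodose("All outer optimisation starts failed.",
                  "sirodose_estimation_error")
  }
  converged <- best$convergence == 0
  if (!converged) {
    # nlminb's "false convergence" is frequently a benign artefact of the
    # noisy inner optimisation; accept the optimum if a restart from it
    # cannot improve the objective materially
    recheck <- tryCatch(
      nlminb(best$par, obj, lower = lower,
             control = list(rel.tol = st$rel_tol, iter.max = 50)),
      error = function(e) NULL)
    if (!is.null(recheck) && is.finite(recheck$objective)) {
      improvement <- best$objective - recheck$objective
      if (recheck$objective < best$objective) best <- recheck
      if (improvement < 0.01 || recheck$convergence == 0) converged <- TRUE
    }
  }
  if (!converged) {
    warn(sprintf("Outer optimisation did not report convergence (%s); partial estimates returned.",
                 best$message %||% "unknown"))
  }
  fitted_model <- unpack(best$par, start)
  final <- ofv_foce(data, fitted_model)

  par_names <- free
  if (n_cov > 0) par_names <- c(par_names, paste0("beta_", covs$name))
  boundary <- rep(FALSE, length(best$par))
  boundary[var_idx] <- best$par[var_idx] < log(1e-8) + 1e-6

  se_pct <- rep(NA_real_, length(best$par))
  if (isTRUE(st$se)) {
    H <- tryCatch(fd_hessian(obj, best$par), error = function(e) NULL)
    if (!is.null(H)) {
      cv <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cv)) {
        s2 <- diag(cv)
        s2[s2 < 0] <- NA_real_
        se_t <- sqrt(s2)
        # log-scale parameters: SE% = 100 * SE(log); raw-scale: 100*SE/|est|
        raw <- rep(FALSE, length(best$par))
        if (n_cov > 0) {
          raw[length(free) + seq_len(n_cov)] <- covs$form != "genotype"
        }
        est_nat <- ifelse(raw, best$par, exp(best$par))
        se_pct <- ifelse(raw, 100 * se_t / abs(est_nat), 100 * se_t)
      }
    }
  }
  estimates <- tibble::tibble(
    parameter = par_names,
    estimate = {
      vals <- exp(best$par[seq_along(free)])
      if (n_cov > 0) vals <- c(vals, fitted_model$covariates$theta)
      vals
    },
    se_pct = se_pct,
    boundary = boundary
  )
  fixed_rows <- tibble::tibble(
    parameter = c(fix, "ka"),
    estimate = c(unlist(start[fix], use.names = FALSE), start$ka),
    se_pct = NA_real_, boundary = FALSE)
  structure(
    list(model = fitted_model, ofv = final$ofv, estimates = estimates,
         fixed = fixed_rows, eta = final$eta, converged = converged,
         n_subjects = length(unique(data$id)),
         n_obs = sum(is_obs_row(data)), n_eval = n_eval,
         settings = st, data = data),
    class = "pk_fit")
}

# central finite-difference Hessian of f at p
fd_hessian <- function(f, p, h = 1e-3) {
  n <- length(p)
  H <- matrix(NA_real_, n, n)
  hh <- pmax(abs(p), 1) * h
  f0 <- f(p)
  for (i in seq_len(n)) {
    for (j in i:n) {
      ei <- ej <- numeric(n); ei[i] <- hh[i]; ej[j] <- hh[j]
      if (i == j) {
        H[i, i] <- (f(p + ei) - 2 * f0 + f(p - ei)) / hh[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(p + ei + ej) - f(p + ei - ej) - f(p - ei + ej) +
             f(p - ei - ej)) / (4 * hh[i] * hh[j])
      }
    }
  }
  H
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit> FOCE-I, %d subjects, %d observations\n",
              x$n_subjects, x$n_obs))
  cat(sprintf("  OFV = %.3f  (%s)\n", x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  print(as.data.frame(x$estimates), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_pk
#' @param x A `pk_fit`.
#' @param ... Unused.
#' @export
tidy.pk_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$estimates, fixed = FALSE),
    dplyr::mutate(x$fixed, fixed = TRUE))
}

#' @rdname fit_pk
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(ofv = x$ofv, n_subjects = x$n_subjects, n_obs = x$n_obs,
                 converged = x$converged, n_eval = x$n_eval)
}
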