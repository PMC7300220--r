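#' Nonparametric bootstrap of the population model
#'
#' Resamples *subjects* with replacement (the exchangeable unit in
#' hierarchical TDM data), refits the model on each replicate, and
#' summarises every estimated parameter by its bootstrap median, 2.5th and
#' 97.5th percentiles, and relative bias
#' `100 * (bootstrap median - original estimate) / original estimate`.
#' Replicates whose fit fails are excluded and counted; more than 50%
#' failures triggers a warning.
#'
#' @param data Dataset tibble.
#' @param start Starting [pop_model()] (also defines fixed quantities).
#' @param n_reps Number of bootstrap replicates (the reference analysis used
#'   1,000).
#' @param seed Integer seed; replicate resampling is reproducible.
#' @param fix,settings Passed to [fit_pk()]; by default replicates use a
#'   single start and skip standard errors.
#' @return A `pk_boot` object; `tidy()` returns the summary table
#'   (`parameter, estimate, boot_median, ci_lo, ci_hi, bias_pct`), and
#'   `$replicates` holds the per-replicate estimates.
#' @export
bootstrap_pk <- function(data, start, n_reps = 1000, seed,
                         fix = character(),
                         settings = list(multi_start = 1, se = FALSE)) {
  data <- validate_pk_dataset(data)
  ids <- unique(data$id)
  if (length(ids) < 2) {
    stop_sirodose("Bootstrap needs at least 2 subjects.",
                  "sirodose_invalid_input")
  }
  original <- fit_pk(data, start, fix = fix, settings = settings)
  est0 <- original$estimates
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      take <- sample(ids, length(ids), replace = TRUE)
      boot_data <- dplyr::bind_rows(lapply(seq_along(take), function(k) {
        rows <- data[data$id == take[k], , drop = FALSE]
        rows$id <- k   # relabel so repeated subjects stay distinct
        rows
      }))
      fit <- tryCatch(
        fit_pk(boot_data, start, fix = fix, settings = settings),
        error = function(e) NULL)
      if (is.null(fit) || !all(is.finite(fit$estimates$estimate))) {
        return(NULL)
      }
      tibble::tibble(rep = r, parameter = fit$estimates$parameter,
                     estimate = fit$estimates$estimate)
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  if (mean(ok) < 0.5) {
    warn(sprintf("More than half of the bootstrap replicates failed (%d of %d).",
                 sum(!ok), n_reps))
  }
  replicates <- dplyr::bind_rows(reps[ok])
  summary <- replicates |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      boot_median = median(.data$estimate),
      ci_lo = quantile(.data$estimate, 0.025, names = FALSE),
      ci_hi = quantile(.data$estimate, 0.975, names = FALSE),
      .groups = "drop") |>
    dplyr::left_join(est0[, c("parameter", "estimate")], by = "parameter") |>
    dplyr::mutate(bias_pct = bootstrap_bias(.data$boot_median,
                                            .data$estimate)) |>
    dplyr::select("parameter", "estimate", "boot_median", "ci_lo", "ci_hi",
                  "bias_pct")
  structure(
    list(summary = summary, replicates = replicates,
         n_reps = n_reps, n_converged = sum(ok), seed = seed,
         original = original),
    class = "pk_boot")
}

#' Bootstrap relative bias
#'
#' `100 * (boot_median - estimate) / estimate`, the percentage by which the
#' bootstrap median deviates from the original estimate.
#'
#' @param boot_median Bootstrap median(s).
#' @param estimate Original estimate(s).
#' @return Bias in percent.
#' @export
#' @examples
#' bootstrap_bias(6.65, 6.48)  # 2.62 %
bootstrap_bias <- function(boot_median, estimate) {
  100 * (boot_median - estimate) / estimate
}

#' @export
print.pk_boot <- function(x, ...) {
  cat(sprintf("<pk_boot> %d/%d replicates converged (seed %s)\n",
              x$n_converged, x$n_reps, format(x$seed)))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @rdname bootstrap_pk
#' @param x A `pk_boot`.
#' @param ... Unused.
#' @export
tidy.pk_boot <- function(x, ...) x$summary

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the model at the observed
#' design (same subjects, doses and sampling times), prediction-corrects
#' observed and simulated concentrations by
#' `conc * median(PRED in bin) / PRED` (PRED = population prediction at
#' eta = 0), and compares observed percentiles with the simulated percentile
#' band within quantile-based time bins.
#'
#' @param data Dataset tibble with observations.
#' @param model Fitted [pop_model()] (or a `pk_fit`'s `$model`).
#' @param n_sim Number of simulation replicates (>= 100; default 1000).
#' @param seed Integer seed.
#' @param bins Number of quantile-based time bins (default 4, suited to
#'   sparse data); empty bins are dropped with a warning.
#' @return A `pk_vpc` object with `$bins` (per-bin observed 2.5/50/97.5th
#'   prediction-corrected percentiles and simulated bands), and
#'   `$fraction_inside` — the fraction of prediction-corrected observations
#'   inside the simulated 2.5th-97.5th band of their bin.  `autoplot()`
#'   draws the standard VPC panel.
#' @export
vpc_pk <- function(data, model, n_sim = 1000, seed, bins = 4) {
  stopifnot(inherits(model, "pop_model"))
  data <- validate_pk_dataset(data)
  if (n_sim < 100) {
    stop_sirodose("`n_sim` must be at least 100.", "sirodose_invalid_input")
  }
  cov_names <- covariate_columns(model)
  subjects <- split_subjects(data, cov_names)
  obs <- dplyr::bind_rows(lapply(subjects, function(s) {
    tibble::tibble(id = s$id, time = s$obs_time, dv = s$obs_dv,
                   pred = subject_pred(model, s)$conc)
  }))
  # quantile-based time bins
  edges <- unique(quantile(obs$time, probs = seq(0, 1, length.out = bins + 1),
                           names = FALSE))
  if (length(edges) < 2) edges <- range(obs$time) + c(-0.5, 0.5)
  obs$bin <- cut(obs$time, breaks = edges, include.lowest = TRUE)
  empty <- setdiff(levels(obs$bin), unique(as.character(obs$bin)))
  if (length(empty)) warn("Empty VPC bin(s) dropped.")
  obs <- obs |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(pred_bin_median = median(.data$pred)) |>
    dplyr::ungroup() |>
    dplyr::mutate(pc_dv = .data$dv * .data$pred_bin_median / .data$pred)

  sim_pc <- with_seed(seed, {
    lapply(seq_len(n_sim), function(r) {
      dv_sim <- unlist(lapply(subjects, function(s) {
        eta_cl <- rnorm(1, 0, sqrt(model$omega2_cl))
        eta_v <- rnorm(1, 0, sqrt(model$omega2_v))
        ipred <- subject_pred(model, s, eta_cl, eta_v)$conc
        pmax(ipred * (1 + rnorm(length(ipred), 0, sqrt(model$sigma2_prop))) +
               rnorm(length(ipred), 0, sqrt(model$sigma2_add)), 0)
      }))
      dv_sim * obs$pred_bin_median / obs$pred
    })
  })
  sim_mat <- do.call(cbind, sim_pc)   # n_obs x n_sim

  probs <- c(0.025, 0.5, 0.975)
  bin_ids <- unique(as.character(obs$bin))
  bin_rows <- lapply(bin_ids, function(b) {
    in_bin <- as.character(obs$bin) == b
    oq <- quantile(obs$pc_dv[in_bin], probs, names = FALSE)
    sq <- quantile(as.numeric(sim_mat[in_bin, , drop = FALSE]), probs,
                   names = FALSE)
    tibble::tibble(bin = b, time_mid = median(obs$time[in_bin]),
                   n_obs = sum(in_bin),
                   obs_p2.5 = oq[1], obs_p50 = oq[2], obs_p97.5 = oq[3],
                   sim_p2.5 = sq[1], sim_p50 = sq[2], sim_p97.5 = sq[3])
  })
  bins_tbl <- dplyr::arrange(dplyr::bind_rows(bin_rows), .data$time_mid)
  lo <- bins_tbl$sim_p2.5[match(as.character(obs$bin), bins_tbl$bin)]
  hi <- bins_tbl$sim_p97.5[match(as.character(obs$bin), bins_tbl$bin)]
  fraction_inside <- mean(obs$pc_dv >= lo & obs$pc_dv <= hi)
  structure(
    list(bins = bins_tbl, observations = obs,
         fraction_inside = fraction_inside, n_sim = n_sim, seed = seed),
    class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf(
    "<pk_vpc> %d simulations; %.1f%% of prediction-corrected observations inside the simulated 95%% band\n",
    x$n_sim, 100 * x$fraction_inside))
  print(as.data.frame(x$bins), row.names = FALSE)
  invisible(x)
}

#' @rdname vpc_pk
#' @param x A `pk_vpc`.
#' @param ... Unused.
#' @export
tidy.pk_vpc <- function(x, ...) x$bins

#' Residual diagnostics for a fitted model
#'
#' Per-observation goodness-of-fit quantities: population prediction `pred`
#' (eta = 0), individual prediction `ipred` (at the FOCE conditional modes),
#' `iwres = (dv - ipred) / sqrt(residual_variance(ipred))`, and `wres`
#' computed under the first-order population linearisation — the residual
#' vector of each subject decorrelated by the Cholesky factor of
#' `G Omega G' + diag(residual variance at pred)` with `G` the sensitivity
#' of the prediction to the random effects at eta = 0.
#'
#' @param data Dataset tibble (defaults to the data stored in `fit`).
#' @param fit A `pk_fit` from [fit_pk()].
#' @return A tibble: `id, time, dv, pred, ipred, iwres, wres`.
#' @export
residual_diagnostics <- function(data = NULL, fit) {
  stopifnot(inherits(fit, "pk_fit"))
  model <- fit$model
  data <- validate_pk_dataset(data %||% fit$data)
  eta <- fit$eta
  subjects <- split_subjects(data, covariate_columns(model))
  out <- lapply(subjects, function(s) {
    e <- eta[match(s$id, eta$id), ]
    if (nrow(e) == 0 || is.na(e$eta_cl[1])) e <- list(eta_cl = 0, eta_v = 0)
    ip <- subject_pred(model, s, e$eta_cl[1], e$eta_v[1])$conc
    pp <- subject_pred(model, s, 0, 0, grad = TRUE)
    v_i <- residual_variance(ip, model)
    v_p <- residual_variance(pp$conc, model)
    if (any(v_i <= 0) || any(v_p <= 0)) {
      stop_sirodose(sprintf(
        "Zero residual variance for subject %s; check sigma2 parameters.",
        format(s$id)), "sirodose_invalid_model")
    }
    G <- cbind(pp$d_eta_cl, pp$d_eta_v)
    C <- G %*% diag(c(model$omega2_cl, model$omega2_v)) %*% t(G) + diag(v_p,
      nrow = length(v_p))
    L <- t(chol(C))
    wres <- as.numeric(forwardsolve(L, s$obs_dv - pp$conc))
    tibble::tibble(id = s$id, time = s$obs_time, dv = s$obs_dv,
                   pred = pp$conc, ipred = ip,
                   iwres = (s$obs_dv - ip) / sqrt(v_i), wres = wres)
  })
  dplyr::bind_rows(out)
}
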