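#' Generate a synthetic therapeutic-drug-monitoring cohort
#'
#' Builds the design half of a TDM dataset — subjects, weights, oral dosing
#' histories and planned sampling times, without concentrations (fill those
#' with [simulate_observations()]).  The defaults emulate the kind of cohort
#' that motivates this package: 15 children, weights log-uniform on
#' 10-50 kg, once-daily weight-based sirolimus dosing continued well past
#' ten elimination half-lives before the first sample, and trough-only
#' sparse sampling (three pre-dose occasions).  A `"rich"` design instead
#' samples 1, 2, 4, 8, 12 and 24 h after the last dose, which is needed
#' when the absorption/distribution side of the model must be identifiable
#' from the data alone.
#'
#' @param n Number of subjects.
#' @param weight_range Weight bounds, kg; weights are log-uniform on this
#'   range.
#' @param dose_per_kg Daily dose, mg/kg/day.
#' @param regimen `"qd"` (every 24 h) or `"bid"` (every 12 h, daily dose
#'   split evenly).
#' @param design `"trough"` (default; `n_occasions` pre-dose samples) or
#'   `"rich"` (post-dose profile after the final dose).
#' @param n_occasions Number of trough sampling occasions.
#' @param n_days Days of dosing before the profile/last troughs.
#' @param seed Integer seed; required, the cohort is a pure function of the
#'   arguments and the seed.
#' @return A dataset tibble (`id, time, amt, dv, mdv, evid, wt`): dose rows
#'   (`EVID = 1`) and planned sample rows (`EVID = 0, MDV = 1`, `DV`
#'   missing).
#' @export
#' @examples
#' generate_cohort(n = 3, seed = 1)
generate_cohort <- function(n = 15, weight_range = c(10, 50),
                            dose_per_kg = 0.05,
                            regimen = c("qd", "bid"),
                            design = c("trough", "rich"),
                            n_occasions = 3, n_days = 14, seed) {
  regimen <- match.arg(regimen)
  design <- match.arg(design)
  if (!is.numeric(n) || n < 1) {
    stop_sirodose("`n` must be at least 1.", "sirodose_invalid_input")
  }
  if (length(weight_range) != 2 || any(weight_range <= 0) ||
      weight_range[1] > weight_range[2]) {
    stop_sirodose("`weight_range` must be positive and ascending.",
                  "sirodose_invalid_input")
  }
  check_number(dose_per_kg, "dose_per_kg", non_negative = TRUE)
  tau <- if (regimen == "qd") 24 else 12
  adm_per_day <- 24 / tau
  n_doses <- n_days * adm_per_day
  with_seed(seed, {
    weights <- exp(runif(n, log(weight_range[1]), log(weight_range[2])))
    rows <- lapply(seq_len(n), function(i) {
      wt <- weights[i]
      amt <- wt * dose_per_kg / adm_per_day
      dose_times <- tau * (seq_len(n_doses) - 1)
      if (design == "trough") {
        k <- min(n_occasions, n_doses - 1)
        sample_times <- dose_times[n_doses - rev(seq_len(k)) + 1]
      } else {
        sample_times <- dose_times[n_doses] + c(1, 2, 4, 8, 12, 24)
      }
      dplyr::bind_rows(
        tibble::tibble(id = i, time = dose_times, amt = amt, dv = NA_real_,
                       mdv = 1, evid = 1, wt = wt),
        tibble::tibble(id = i, time = sample_times, amt = 0, dv = NA_real_,
                       mdv = 1, evid = 0, wt = wt)
      )
    })
    dplyr::arrange(dplyr::bind_rows(rows), .data$id, .data$time, -.data$evid)
  })
}

#' Simulate observed concentrations for a cohort
#'
#' Draws one random-effect pair per subject (log-normal inter-individual
#' variability, variances `omega2_*`) shared across that subject's samples,
#' evaluates the individual concentration at each planned sample time, and
#' applies one independent combined residual draw per observation:
#' `OBS = IPRED * (1 + eps1) + eps2`, truncated at zero.  This is the exact
#' generative counterpart of the FOCE-I estimator, so fitting large
#' simulated datasets recovers the generating parameters.
#'
#' @param cohort Dataset tibble with dose rows and planned sample rows
#'   (`EVID = 0`); see [generate_cohort()].
#' @param model Generating [pop_model()].
#' @param seed Integer seed.
#' @return The dataset with `dv` filled in and `mdv = 0` on observation
#'   rows.
#' @export
#' @examples
#' simulate_observations(generate_cohort(n = 2, seed = 1),
#'                       pediatric_sirolimus_model(), seed = 2)
simulate_observations <- function(cohort, model, seed) {
  stopifnot(inherits(model, "pop_model"))
  cohort <- validate_pk_dataset(cohort, require_obs = FALSE)
  cov_names <- covariate_columns(model)
  with_seed(seed, {
    out <- cohort
    for (i in unique(cohort$id)) {
      rows <- which(cohort$id == i)
      sub <- cohort[rows, , drop = FALSE]
      doses <- sub[is_dose_row(sub), ]
      samp <- which(sub$evid == 0)
      if (!length(samp)) next
      eta_cl <- rnorm(1, 0, sqrt(model$omega2_cl))
      eta_v <- rnorm(1, 0, sqrt(model$omega2_v))
      covs <- if (length(cov_names)) {
        as.list(sub[1, cov_names, drop = FALSE])
      } else NULL
      subj <- list(wt = sub$wt[1], dose_time = doses$time,
                   dose_amount = doses$amt, obs_time = sub$time[samp],
                   covs = covs)
      if (length(doses$time) && any(sub$time[samp] < min(doses$time))) {
        warn("Sampling time before the first dose; concentration is 0 there.")
      }
      ipred <- subject_pred(model, subj, eta_cl, eta_v)$conc
      eps1 <- rnorm(length(ipred), 0, sqrt(model$sigma2_prop))
      eps2 <- rnorm(length(ipred), 0, sqrt(model$sigma2_add))
      dv <- pmax(ipred * (1 + eps1) + eps2, 0)
      out$dv[rows[samp]] <- dv
      out$mdv[rows[samp]] <- 0
    }
    out
  })
}

#' Sample genotype count tables under Hardy-Weinberg proportions
#'
#' Multinomial sampling of `n` subjects per variant at genotype
#' probabilities (p^2, 2p(1-p), (1-p)^2).
#'
#' @param allele_freqs Named numeric vector of reference-allele frequencies,
#'   each strictly inside (0, 1); names become variant ids.
#' @param n Subjects genotyped per variant.
#' @param seed Integer seed.
#' @return A tibble with columns `variant, n_aa, n_ab, n_bb`.
#' @export
#' @examples
#' generate_genotypes(c(rs1 = 0.3, rs2 = 0.5), n = 15, seed = 1)
generate_genotypes <- function(allele_freqs, n, seed) {
  if (!is.numeric(allele_freqs) || !length(allele_freqs) ||
      any(allele_freqs <= 0 | allele_freqs >= 1)) {
    stop_sirodose("Allele frequencies must lie strictly inside (0, 1).",
                  "sirodose_invalid_input")
  }
  if (!is.numeric(n) || n < 1) {
    stop_sirodose("`n` must be at least 1.", "sirodose_invalid_input")
  }
  ids <- names(allele_freqs) %||% paste0("variant", seq_along(allele_freqs))
  with_seed(seed, {
    counts <- vapply(allele_freqs, function(p) {
      as.numeric(rmultinom(1, n, c(p^2, 2 * p * (1 - p), (1 - p)^2)))
    }, numeric(3))
    tibble::tibble(variant = ids, n_aa = as.numeric(counts[1, ]),
                   n_ab = as.numeric(counts[2, ]),
                   n_bb = as.numeric(counts[3, ]))
  })
}
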