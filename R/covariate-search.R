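#' Stepwise covariate selection by likelihood-ratio thresholds
#'
#' Forward inclusion / backward elimination on the FOCE-I objective.
#' Forward: candidates are tested one at a time against the current model
#' and, repeatedly, the candidate giving the largest drop in OFV greater
#' than `ofv_in` (3.84, chi-squared 1 df at P = 0.05) is added.  Backward:
#' from the full model each retained covariate is removed in turn and kept
#' only if removal raises the OFV by more than `ofv_out` (6.64, chi-squared
#' 1 df at P = 0.01).  Ties in the forward drop are broken by candidate
#' order.
#'
#' @param data Dataset tibble; must contain every candidate covariate column.
#' @param base_model Starting [pop_model()] (typically without covariates).
#' @param candidates Tibble of candidate effects, rows from
#'   [covariate_spec()].
#' @param ofv_in,ofv_out Inclusion / retention thresholds on the OFV change.
#' @param fix Parameters held fixed in every fit, as in [fit_pk()].
#' @param settings Estimation settings passed to [fit_pk()]; defaults to a
#'   single start without standard errors for speed.
#' @return A list: `fit` (final `pk_fit`), `model` (final `pop_model`),
#'   `log` — a tibble with one row per tested step (`phase`, `candidate`,
#'   `param`, `delta_ofv`, `action`).
#' @export
covariate_search <- function(data, base_model, candidates,
                             ofv_in = 3.84, ofv_out = 6.64,
                             fix = character(),
                             settings = list(multi_start = 1, se = FALSE)) {
  if (!is.null(candidates) && nrow(candidates) > 0) {
    candidates <- validate_covariates(candidates)
    missing_cols <- setdiff(unique(candidates$name), names(data))
    if (length(missing_cols)) {
      stop_sirodose(sprintf("Candidate covariate column(s) absent: %s.",
                            paste(missing_cols, collapse = ", ")),
                    "sirodose_invalid_input")
    }
  }
  log_rows <- list()
  add_log <- function(phase, cand, dofv, action) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      phase = phase, candidate = cand$name, param = cand$param,
      delta_ofv = dofv, action = action)
  }
  with_covs <- function(model, covs) {
    model$covariates <- if (nrow(covs) == 0) NULL else covs
    model
  }
  refit <- function(covs, start_model) {
    tryCatch(fit_pk(data, with_covs(start_model, covs), fix = fix,
                    settings = settings),
             error = function(e) NULL)
  }

  empty <- if (is.null(base_model$covariates)) {
    candidates[0, ]
  } else validate_covariates(base_model$covariates)
  current_covs <- empty
  current_fit <- fit_pk(data, base_model, fix = fix, settings = settings)
  if (is.null(candidates) || nrow(candidates) == 0) {
    return(list(fit = current_fit, model = current_fit$model,
                log = tibble::tibble(phase = character(),
                                     candidate = character(),
                                     param = character(),
                                     delta_ofv = numeric(),
                                     action = character())))
  }

  remaining <- seq_len(nrow(candidates))
  # forward
  repeat {
    if (!length(remaining)) break
    drops <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (k in seq_along(remaining)) {
      cand <- candidates[remaining[k], ]
      f <- refit(dplyr::bind_rows(current_covs, cand), current_fit$model)
      if (is.null(f)) {
        add_log("forward", cand, NA_real_, "fit-failed")
        next
      }
      fits[[k]] <- f
      drops[k] <- current_fit$ofv - f$ofv
    }
    ok <- which(!is.na(drops) & drops > ofv_in)
    if (!length(ok)) {
      for (k in seq_along(remaining)) {
        if (!is.na(drops[k])) {
          add_log("forward", candidates[remaining[k], ], drops[k],
                  "not-included")
        }
      }
      break
    }
    pick <- ok[which.max(drops[ok])]   # largest drop; which.max keeps order
    cand <- candidates[remaining[pick], ]
    add_log("forward", cand, drops[pick], "included")
    current_covs <- dplyr::bind_rows(current_covs, cand)
    current_fit <- fits[[pick]]
    remaining <- remaining[-pick]
  }
  # backward: single pass over retained covariates
  if (nrow(current_covs) > 0) {
    keep <- rep(TRUE, nrow(current_covs))
    for (k in seq_len(nrow(current_covs))) {
      reduced <- current_covs[setdiff(which(keep), k), , drop = FALSE]
      f <- refit(reduced, current_fit$model)
      if (is.null(f)) {
        add_log("backward", current_covs[k, ], NA_real_, "fit-failed-kept")
        next
      }
      rise <- f$ofv - current_fit$ofv
      if (rise > ofv_out) {
        add_log("backward", current_covs[k, ], rise, "kept")
      } else {
        add_log("backward", current_covs[k, ], rise, "removed")
        keep[k] <- FALSE
        current_fit <- f
      }
    }
    current_covs <- current_covs[keep, , drop = FALSE]
  }
  list(fit = current_fit, model = current_fit$model,
       log = dplyr::bind_rows(log_rows))
}
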