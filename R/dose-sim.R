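#' Simulate steady-state troughs for virtual patients
#'
#' Monte-Carlo simulation of one weight / dose / regimen cell: draws `n`
#' independent random-effect pairs from the model's zero-mean normal
#' distributions (variances `omega2_cl`, `omega2_v`), builds each virtual
#' patient's parameters, and evaluates the analytic steady-state trough for
#' the per-administration amount (daily dose, split evenly for twice-daily
#' dosing).  With `include_residual = TRUE` each trough additionally gets
#' one combined residual draw (`c * (1 + eps1) + eps2`, truncated at 0),
#' emulating an observed rather than model-predicted trough.
#'
#' @param model A [pop_model()] with variance components.
#' @param weight Body weight, kg.
#' @param daily_dose Daily dose, mg/kg/day.
#' @param regimen `"qd"` (tau = 24 h) or `"bid"` (tau = 12 h).
#' @param n Number of virtual patients.
#' @param seed Integer seed.
#' @param include_residual Add residual error to each trough?
#' @return Numeric vector of `n` steady-state troughs, ng/ml.
#' @export
#' @examples
#' quantile(simulate_troughs(pediatric_sirolimus_model(), 10, 0.10,
#'                           n = 500, seed = 1))
simulate_troughs <- function(model, weight, daily_dose,
                             regimen = c("qd", "bid"), n = 1000, seed,
                             include_residual = FALSE) {
  stopifnot(inherits(model, "pop_model"))
  regimen <- match.arg(regimen)
  check_number(weight, "weight", positive = TRUE)
  check_number(daily_dose, "daily_dose", non_negative = TRUE)
  if (!is.numeric(n) || length(n) != 1 || n <= 0) {
    stop_sirodose("`n` must be a positive number of virtual patients.",
                  "sirodose_invalid_input")
  }
  tau <- if (regimen == "qd") 24 else 12
  amount <- weight * daily_dose / (24 / tau)
  with_seed(seed, {
    eta_cl <- rnorm(n, 0, sqrt(model$omega2_cl))
    eta_v <- rnorm(n, 0, sqrt(model$omega2_v))
    params <- pk_params(model, weight, eta_cl, eta_v)
    tr <- ss_trough(params, amount, tau)
    if (include_residual) {
      eps1 <- rnorm(n, 0, sqrt(model$sigma2_prop))
      eps2 <- rnorm(n, 0, sqrt(model$sigma2_add))
      tr <- pmax(tr * (1 + eps1) + eps2, 0)
    }
    tr
  })
}

#' Probability of target attainment
#'
#' Fraction of troughs inside the therapeutic window, bounds inclusive.
#' The sirolimus maintenance target used throughout is 5-15 ng/ml.
#'
#' @param troughs Numeric vector of trough concentrations, ng/ml.
#' @param window Length-2 target window, ng/ml.
#' @return A probability in `[0, 1]`.
#' @export
#' @examples
#' pta(c(4, 5, 10, 15, 16))
pta <- function(troughs, window = c(5, 15)) {
  if (!is.numeric(troughs) || !length(troughs)) {
    stop_sirodose("`troughs` must be a non-empty numeric vector.",
                  "sirodose_invalid_input")
  }
  mean(troughs >= window[1] & troughs <= window[2])
}

#' Probability of target attainment over a weight x dose x regimen grid
#'
#' Runs [simulate_troughs()] for every grid cell and summarises each cell by
#' its PTA and trough percentiles.  Defaults follow the simulation study the
#' package reproduces: 1,000 virtual patients per cell, weights
#' 5-60 kg, daily doses 0.01-0.10 mg/kg/day, once- and twice-daily
#' regimens, target window 5-15 ng/ml.  Each cell gets its own
#' deterministic sub-seed, so the grid is reproducible and insensitive to
#' cell order.
#'
#' @param model A [pop_model()].
#' @param weights Body weights, kg.
#' @param doses Daily doses, mg/kg/day.
#' @param regimens Subset of `c("qd", "bid")`.
#' @param n Virtual patients per cell.
#' @param seed Integer seed.
#' @param window Target window, ng/ml.
#' @param include_residual Passed to [simulate_troughs()].
#' @return A tibble: `weight, regimen, daily_dose, pta, trough_p2.5,
#'   trough_p50, trough_p97.5`.
#' @details Candidate doses within one weight/regimen cell share the same
#'   virtual population (common random numbers): steady-state troughs are
#'   linear in the dose, so the `n` patients are simulated once per
#'   weight/regimen and every dose is evaluated on them.  This is the
#'   standard variance-reduction design for dose comparisons — differences
#'   in PTA between doses then reflect the dose, not independent
#'   Monte-Carlo noise.
#' @export
pta_grid <- function(model, weights = c(5, 10, 20, 30, 40, 50, 60),
                     doses = seq(0.01, 0.10, by = 0.01),
                     regimens = c("qd", "bid"), n = 1000, seed,
                     window = c(5, 15), include_residual = FALSE) {
  grid <- tidyr::expand_grid(regimen = regimens, weight = weights,
                             daily_dose = doses)
  cells <- purrr::pmap(grid, function(regimen, weight, daily_dose) {
    cell_seed <- cell_subseed(seed, regimen, weight)
    tr <- simulate_troughs(model, weight, daily_dose, regimen, n, cell_seed,
                           include_residual)
    q <- quantile(tr, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(weight = weight, regimen = regimen,
                   daily_dose = daily_dose, pta = pta(tr, window),
                   trough_p2.5 = q[1], trough_p50 = q[2],
                   trough_p97.5 = q[3])
  })
  out <- dplyr::bind_rows(cells)
  class(out) <- c("pta_grid", class(out))
  out
}

# deterministic 31-bit sub-seed per weight/regimen cell; doses within a
# cell share it (common random numbers)
cell_subseed <- function(seed, regimen, weight) {
  key <- paste(regimen, format(weight), sep = "|")
  h <- sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1))
  (as.integer(seed) * 1009L + as.integer(h %% 1e6)) %% .Machine$integer.max
}

#' Recommend a starting dose for a weight bracket
#'
#' For each candidate daily dose, simulates steady-state troughs at both
#' bracket endpoint weights and computes the PTA at each; the recommended
#' dose maximises the *minimum* PTA across the two endpoints (so the dose
#' must work at both edges of the bracket), with ties broken toward the
#' lower dose.  The full endpoint-by-candidate PTA table is returned for
#' audit, so stricter selection rules (e.g. an explicit upper-exposure
#' safety bound from the trough percentiles) can be applied downstream.
#'
#' @param model A [pop_model()].
#' @param bracket Length-2 weight bracket, kg; both endpoints are simulated.
#' @param regimen `"qd"` or `"bid"`.
#' @param candidates Candidate daily doses, mg/kg/day.
#' @param n Virtual patients per weight/dose cell.
#' @param seed Integer seed.
#' @param window Target window, ng/ml.
#' @return A `dose_rec` object; `tidy()` gives the audit table, `print()`
#'   the recommendation.  Fields: `recommended` (mg/kg/day), `bracket`,
#'   `regimen`, `audit` (tibble with per-candidate endpoint PTAs and
#'   `min_pta`).
#' @export
#' @examples
#' recommend_dose(pediatric_sirolimus_model(), c(5, 10), "qd",
#'                n = 200, seed = 1)
recommend_dose <- function(model, bracket, regimen = c("qd", "bid"),
                           candidates = seq(0.01, 0.10, by = 0.01),
                           n = 1000, seed, window = c(5, 15)) {
  regimen <- match.arg(regimen)
  if (length(bracket) != 2 || any(bracket <= 0)) {
    stop_sirodose("`bracket` must be two positive weights.",
                  "sirodose_invalid_input")
  }
  grid <- pta_grid(model, weights = bracket, doses = candidates,
                   regimens = regimen, n = n, seed = seed, window = window)
  audit <- grid |>
    dplyr::group_by(.data$daily_dose) |>
    dplyr::summarise(
      pta_lo = .data$pta[.data$weight == bracket[1]],
      pta_hi = .data$pta[.data$weight == bracket[2]],
      min_pta = min(.data$pta), .groups = "drop") |>
    dplyr::arrange(.data$daily_dose)
  if (all(audit$min_pta <= 0)) {
    stop_sirodose("No candidate dose attains the target at both bracket endpoints.",
                  "sirodose_no_recommendation")
  }
  best <- which(audit$min_pta == max(audit$min_pta))[1]  # ties -> lower dose
  structure(
    list(recommended = audit$daily_dose[best], bracket = bracket,
         regimen = regimen, window = window, n = n, seed = seed,
         audit = audit, grid = grid),
    class = "dose_rec")
}

#' @export
print.dose_rec <- function(x, ...) {
  cat(sprintf(
    "<dose_rec> %s, %g-%g kg: %.2f mg/kg/day (min endpoint PTA %.3f, target %g-%g ng/ml)\n",
    toupper(x$regimen), x$bracket[1], x$bracket[2], x$recommended,
    max(x$audit$min_pta), x$window[1], x$window[2]))
  invisible(x)
}

#' @rdname recommend_dose
#' @param x A `dose_rec`.
#' @param ... Unused.
#' @export
tidy.dose_rec <- function(x, ...) {
  dplyr::mutate(x$audit,
                regimen = x$regimen,
                bracket_lo = x$bracket[1], bracket_hi = x$bracket[2],
                recommended = .data$daily_dose == x$recommended)
}

#' Starting-dose table across weight brackets
#'
#' Applies [recommend_dose()] to a set of weight brackets for each regimen
#' and assembles the recommendations into one table.  The default brackets
#' are the clinically used ones: 5-10, 10-20, 20-30, 30-50, 50-60 kg once
#' daily and 5-20, 20-40, 40-60 kg twice daily.
#'
#' @param model A [pop_model()].
#' @param brackets_qd,brackets_bid Lists of length-2 weight brackets.
#' @param candidates,n,seed,window As in [recommend_dose()].
#' @return A tibble: `regimen, weight_lo, weight_hi, dose_mg_kg_day,
#'   min_pta`.
#' @export
dose_recommendation_table <- function(
    model,
    brackets_qd = list(c(5, 10), c(10, 20), c(20, 30), c(30, 50), c(50, 60)),
    brackets_bid = list(c(5, 20), c(20, 40), c(40, 60)),
    candidates = seq(0.01, 0.10, by = 0.01), n = 1000, seed,
    window = c(5, 15)) {
  one <- function(bracket, regimen) {
    r <- recommend_dose(model, bracket, regimen, candidates, n, seed, window)
    tibble::tibble(regimen = regimen, weight_lo = bracket[1],
                   weight_hi = bracket[2], dose_mg_kg_day = r$recommended,
                   min_pta = max(r$audit$min_pta))
  }
  dplyr::bind_rows(
    purrr::map(brackets_qd, one, regimen = "qd"),
    purrr::map(brackets_bid, one, regimen = "bid"))
}
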