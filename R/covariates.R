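#' Describe a candidate covariate effect
#'
#' A covariate enters the model as a multiplicative factor on the typical
#' CL/F or V/F, in one of three forms:
#' \describe{
#'   \item{`"genotype"`}{`theta^x` with `x` a 0/1 genotype indicator — the
#'     reference genotype keeps the typical value, carriers are scaled by
#'     the estimated factor `theta`.}
#'   \item{`"power"`}{`(cov / ref)^theta` for a continuous covariate centred
#'     at its population median `ref`.}
#'   \item{`"linear"`}{`1 + theta * cov` for a categorical/linear covariate.}
#' }
#'
#' @param param Which typical parameter the covariate acts on: `"cl"` or
#'   `"v"`.
#' @param name Covariate column name in the dataset.
#' @param form One of `"genotype"`, `"power"`, `"linear"`.
#' @param theta Multiplicative coefficient; 1 is the null value for
#'   `"genotype"`, 0 for `"power"` and `"linear"`.
#' @param ref Reference value (population median) for the `"power"` form.
#' @return A one-row tibble; rows can be stacked into a candidate set for
#'   [covariate_search()].
#' @export
#' @examples
#' covariate_spec("cl", "cyp3a5", "genotype")
covariate_spec <- function(param = c("cl", "v"), name,
                           form = c("genotype", "power", "linear"),
                           theta = NULL, ref = NA_real_) {
  param <- match.arg(param)
  form <- match.arg(form)
  if (is.null(theta)) theta <- if (form == "genotype") 1 else 0
  if (form == "power" && (is.na(ref) || ref <= 0)) {
    stop_sirodose("The power form needs a positive reference (median) value.",
                  "sirodose_invalid_input")
  }
  tibble::tibble(param = param, name = name, form = form,
                 theta = as.numeric(theta), ref = as.numeric(ref))
}

validate_covariates <- function(covariates) {
  covariates <- tibble::as_tibble(covariates)
  needed <- c("param", "name", "form", "theta", "ref")
  if (!all(needed %in% names(covariates))) {
    stop_sirodose("Covariate table needs columns param, name, form, theta, ref.",
                  "sirodose_invalid_input")
  }
  bad <- !covariates$form %in% c("genotype", "power", "linear")
  if (any(bad)) {
    stop_sirodose("Covariate form must be genotype, power or linear.",
                  "sirodose_invalid_input")
  }
  if (any(covariates$form == "power" &
          (is.na(covariates$ref) | covariates$ref <= 0))) {
    stop_sirodose("Power covariates need a positive reference value.",
                  "sirodose_invalid_input")
  }
  covariates
}

# Multiplicative covariate factors on CL/F and V/F for one subject.
# `values` is a named list / one-row data frame of covariate values.
covariate_factors <- function(model, values) {
  out <- list(cl = 1, v = 1)
  covs <- model$covariates
  if (is.null(covs) || nrow(covs) == 0) return(out)
  if (is.null(values)) {
    stop_sirodose("Model has covariate effects but no covariate values given.",
                  "sirodose_invalid_input")
  }
  for (i in seq_len(nrow(covs))) {
    cv <- covs[i, ]
    if (is.null(values[[cv$name]])) {
      stop_sirodose(sprintf("Missing covariate value `%s`.", cv$name),
                    "sirodose_invalid_input")
    }
    x <- as.numeric(values[[cv$name]])
    fac <- switch(cv$form,
      genotype = cv$theta^x,
      power    = (x / cv$ref)^cv$theta,
      linear   = 1 + cv$theta * x
    )
    if (!is.finite(fac) || fac <= 0) fac <- 1e-10  # guard degenerate factors
    out[[cv$param]] <- out[[cv$param]] * fac
  }
  out
}
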