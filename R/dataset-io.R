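#' Read a NONMEM-style pharmacokinetic dataset
#'
#' Reads the comma-separated therapeutic-drug-monitoring layout with header
#' `ID,TIME,AMT,DV,MDV,EVID,WT[,covariates...]`: rows with `EVID = 1` and
#' `AMT > 0` are oral doses (mg), rows with `EVID = 0` and `MDV = 0` are
#' concentration observations (`DV`, ng/ml), `TIME` is hours since the first
#' dose, and a literal `"."` marks a missing `DV`.
#'
#' @param path File path.
#' @return A tibble with lower-case columns `id, time, amt, dv, mdv, evid,
#'   wt` plus any extra covariate columns.
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) {
    stop_sirodose(sprintf("Dataset file not found: %s", path),
                  "sirodose_invalid_input")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c(".", "NA"))
  names(raw) <- tolower(names(raw))
  needed <- c("id", "time", "amt", "dv", "mdv", "evid", "wt")
  if (!all(needed %in% names(raw))) {
    stop_sirodose(sprintf(
      "Dataset must have columns %s (any case).",
      paste(toupper(needed), collapse = ",")), "sirodose_invalid_input")
  }
  for (col in c("time", "amt", "dv", "mdv", "evid", "wt")) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  validate_pk_dataset(tibble::as_tibble(raw), require_obs = FALSE)
}

#' Write a dataset in the same NONMEM-style dialect
#'
#' @param data Dataset tibble as returned by [read_pk_dataset()] or
#'   [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  data <- validate_pk_dataset(data, require_obs = FALSE)
  out <- as.data.frame(data)
  core <- c("id", "time", "amt", "dv", "mdv", "evid", "wt")
  out <- out[, c(core, setdiff(names(out), core)), drop = FALSE]
  names(out) <- toupper(names(out))
  out$DV <- ifelse(is.na(out$DV), ".", format(out$DV, digits = 15,
                                              scientific = FALSE,
                                              trim = TRUE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Structural checks shared by the reader and the estimation layer.
# `require_obs = FALSE` admits design-only cohorts whose samples have not
# been simulated/observed yet (EVID = 0, MDV = 1, DV missing).
validate_pk_dataset <- function(data, require_obs = TRUE) {
  data <- tibble::as_tibble(data)
  needed <- c("id", "time", "amt", "dv", "mdv", "evid", "wt")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop_sirodose(sprintf("Dataset is missing columns: %s.",
                          paste(missing_cols, collapse = ", ")),
                  "sirodose_invalid_input")
  }
  if (nrow(data) == 0) {
    stop_sirodose("Dataset is empty.", "sirodose_invalid_input")
  }
  if (any(data$wt <= 0 | is.na(data$wt))) {
    stop_sirodose("Every row needs a positive body weight `wt`.",
                  "sirodose_invalid_input")
  }
  obs <- is_obs_row(data)
  dose <- is_dose_row(data)
  ids <- unique(data$id)
  if (require_obs) {
    no_obs <- setdiff(ids, unique(data$id[obs]))
    if (length(no_obs)) {
      stop_sirodose(sprintf("Subject(s) without observations: %s.",
                            paste(no_obs, collapse = ", ")),
                    "sirodose_invalid_input")
    }
  }
  no_dose <- setdiff(ids, unique(data$id[dose]))
  if (length(no_dose)) {
    stop_sirodose(sprintf("Subject(s) without dose records: %s.",
                          paste(no_dose, collapse = ", ")),
                  "sirodose_invalid_input")
  }
  data
}

is_obs_row <- function(data) data$evid == 0 & data$mdv == 0 & !is.na(data$dv)
is_dose_row <- function(data) data$evid == 1 & data$amt > 0

# Split a dataset into the per-subject pieces the estimator consumes.
split_subjects <- function(data, covariate_names = character()) {
  data <- validate_pk_dataset(data)
  ids <- unique(data$id)
  lapply(ids, function(i) {
    rows <- data[data$id == i, , drop = FALSE]
    doses <- rows[is_dose_row(rows), c("time", "amt")]
    obs <- rows[is_obs_row(rows), c("time", "dv")]
    covs <- if (length(covariate_names)) {
      as.list(rows[1, covariate_names, drop = FALSE])
    } else NULL
    list(id = i, wt = rows$wt[1],
         dose_time = doses$time, dose_amount = doses$amt,
         obs_time = obs$time, obs_dv = obs$dv, covs = covs)
  })
}
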