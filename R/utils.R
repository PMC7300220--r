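#' @importFrom rlang .data abort warn
#' @importFrom stats median optim nlminb pchisq qnorm quantile rnorm runif
#'   rbinom rmultinom sd setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

#' @export
generics::tidy

#' @export
generics::glance

# stop with a classed condition so callers can test on the class
stop_sirodose <- function(msg, class = "sirodose_error") {
  rlang::abort(msg, class = c(class, "sirodose_error"))
}

check_number <- function(x, name, positive = FALSE, non_negative = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_sirodose(sprintf("`%s` must be numeric and non-missing.", name),
                  "sirodose_invalid_input")
  }
  if (finite && any(!is.finite(x))) {
    stop_sirodose(sprintf("`%s` must be finite.", name),
                  "sirodose_invalid_input")
  }
  if (positive && any(x <= 0)) {
    stop_sirodose(sprintf("`%s` must be strictly positive.", name),
                  "sirodose_invalid_input")
  }
  if (non_negative && any(x < 0)) {
    stop_sirodose(sprintf("`%s` must be non-negative.", name),
                  "sirodose_invalid_input")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_sirodose("A single integer `seed` is required.",
                  "sirodose_invalid_input")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
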