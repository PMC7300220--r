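#' Hardy-Weinberg equilibrium test for one biallelic variant
#'
#' Pearson chi-squared goodness-of-fit test of observed genotype counts
#' against Hardy-Weinberg proportions.  The allele frequency is estimated
#' from the counts, `p = (2 n_aa + n_ab) / 2n`, expected counts are
#' `n p^2, 2 n p (1-p), n (1-p)^2`, and the statistic is
#' `sum((obs - exp)^2 / exp)` with 1 degree of freedom and *no* continuity
#' correction.  A monomorphic variant (p = 0 or 1) is flagged and reported
#' as a perfect fit (chi-squared 0, P = 1).
#'
#' @param n_aa,n_ab,n_bb Genotype counts (homozygous reference,
#'   heterozygous, homozygous alternate); non-negative, vectorised.
#' @return A tibble with one row per variant: `n_aa, n_ab, n_bb, p_allele,
#'   chisq, df, p_value, monomorphic`.
#' @export
#' @examples
#' hwe_test(1, 5, 9)
hwe_test <- function(n_aa, n_ab, n_bb) {
  check_number(n_aa, "n_aa", non_negative = TRUE)
  check_number(n_ab, "n_ab", non_negative = TRUE)
  check_number(n_bb, "n_bb", non_negative = TRUE)
  n <- n_aa + n_ab + n_bb
  if (any(n < 1)) {
    stop_sirodose("Each variant needs at least one genotyped subject.",
                  "sirodose_invalid_input")
  }
  p <- (2 * n_aa + n_ab) / (2 * n)
  mono <- p == 0 | p == 1
  e_aa <- n * p^2
  e_ab <- 2 * n * p * (1 - p)
  e_bb <- n * (1 - p)^2
  chisq <- ifelse(mono, 0,
                  (n_aa - e_aa)^2 / e_aa + (n_ab - e_ab)^2 / e_ab +
                    (n_bb - e_bb)^2 / e_bb)
  p_value <- ifelse(mono, 1, pchisq(chisq, df = 1, lower.tail = FALSE))
  tibble::tibble(n_aa = n_aa, n_ab = n_ab, n_bb = n_bb, p_allele = p,
                 chisq = chisq, df = 1L, p_value = p_value,
                 monomorphic = mono)
}

#' Hardy-Weinberg tests for a table of variants
#'
#' Applies [hwe_test()] row-wise and flags departures from equilibrium at
#' the chosen significance level.
#'
#' @param counts Data frame with columns `variant, n_aa, n_ab, n_bb`.
#' @param alpha Significance level for the departure flag.
#' @return A tibble with one row per variant: the [hwe_test()] columns plus
#'   `variant` and `significant`.
#' @export
#' @examples
#' hwe_table(data.frame(variant = c("rs1045642", "rs2231142"),
#'                      n_aa = c(1, 8), n_ab = c(5, 6), n_bb = c(9, 1)))
hwe_table <- function(counts, alpha = 0.05) {
  counts <- tibble::as_tibble(counts)
  needed <- c("variant", "n_aa", "n_ab", "n_bb")
  if (!all(needed %in% names(counts)) || nrow(counts) < 1) {
    stop_sirodose("`counts` needs >= 1 row and columns variant, n_aa, n_ab, n_bb.",
                  "sirodose_invalid_input")
  }
  res <- hwe_test(counts$n_aa, counts$n_ab, counts$n_bb)
  dplyr::mutate(dplyr::bind_cols(counts["variant"], res),
                significant = .data$p_value < alpha)
}

#' Read a genotype count table
#'
#' Long comma-separated layout `variant,genotype,count` with genotype codes
#' `AA`/`AB`/`BB` (reference homozygote, heterozygote, alternate
#' homozygote); returns the wide per-variant count table used by
#' [hwe_table()].
#'
#' @param path File path.
#' @return A tibble `variant, n_aa, n_ab, n_bb`.
#' @export
read_genotype_counts <- function(path) {
  if (!file.exists(path)) {
    stop_sirodose(sprintf("Genotype file not found: %s", path),
                  "sirodose_invalid_input")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("variant", "genotype", "count") %in% names(raw))) {
    stop_sirodose("Genotype file needs columns variant,genotype,count.",
                  "sirodose_invalid_input")
  }
  raw$genotype <- toupper(raw$genotype)
  if (!all(raw$genotype %in% c("AA", "AB", "BB"))) {
    stop_sirodose("Genotype codes must be AA, AB or BB.",
                  "sirodose_invalid_input")
  }
  raw |>
    tibble::as_tibble() |>
    tidyr::pivot_wider(names_from = "genotype", values_from = "count",
                       values_fill = 0) |>
    dplyr::rename_with(tolower) |>
    dplyr::rename(n_aa = "aa", n_ab = "ab", n_bb = "bb")
}
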