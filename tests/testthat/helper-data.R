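# Shared fixtures, built in code.

ref_model <- function(...) {
  m <- pediatric_sirolimus_model()
  args <- list(...)
  for (nm in names(args)) m[[nm]] <- args[[nm]]
  m
}

# tiny hand-built dataset: `n` subjects, daily 1 mg dosing for 5 days,
# observations at chosen offsets after the last dose
tiny_dataset <- function(model, n = 2, obs_offsets = c(2, 12, 24),
                         wt = 20, seed = 42) {
  cohort <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    dplyr::bind_rows(
      tibble::tibble(id = i, time = seq(0, 96, by = 24), amt = 1,
                     dv = NA_real_, mdv = 1, evid = 1, wt = wt),
      tibble::tibble(id = i, time = 96 + obs_offsets, amt = 0,
                     dv = NA_real_, mdv = 1, evid = 0, wt = wt))
  }))
  simulate_observations(cohort, model, seed = seed)
}

# genotype counts in the layout of a published pediatric pharmacogenetic
# panel (biallelic rows only)
panel_counts <- function() {
  tibble::tibble(
    variant = c("rs1045642", "rs1751034", "rs757110", "rs2231142",
                "rs1042597", "rs1902023"),
    n_aa = c(1, 1, 3, 8, 3, 7),
    n_ab = c(5, 2, 8, 6, 4, 6),
    n_bb = c(9, 12, 4, 1, 8, 2))
}
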