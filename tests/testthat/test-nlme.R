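test_that("residual variance combines proportional and additive components", {
  m <- ref_model()
  expect_equal(residual_variance(0, m), 1.249)
  expect_equal(residual_variance(10, m), 100 * 0.312 + 1.249)
  m2 <- ref_model(sigma2_prop = 0, sigma2_add = 4)
  expect_equal(residual_variance(10, m2), 4)
  expect_error(residual_variance(-1, m), class = "sirodose_invalid_input")
})

test_that("FOCE OFV equals the exact -2LL when inter-individual variance vanishes", {
  m0 <- ref_model(omega2_cl = 0, omega2_v = 0)
  d <- tiny_dataset(m0, n = 3, seed = 7)
  expect_equal(ofv_foce(d, m0)$ofv, ofv_fixed_effects(d, m0))

  m_eps <- ref_model(omega2_cl = 1e-8, omega2_v = 1e-8)
  expect_lt(abs(ofv_foce(d, m_eps)$ofv - ofv_fixed_effects(d, m_eps)), 0.1)
})

test_that("FOCE OFV agrees with Gauss-Hermite quadrature on small instances", {
  # small and moderate variance regimes, 2-3 subjects, 3 observations each
  for (om in list(c(0.01, 0.005), c(0.066, 0.02))) {
    m <- ref_model(omega2_cl = om[1], omega2_v = om[2])
    d <- tiny_dataset(m, n = 2, obs_offsets = c(2, 12, 24), seed = 11)
    expect_lt(abs(ofv_foce(d, m)$ofv - ofv_quadrature(d, m)), 0.5)
  }
  m <- ref_model(omega2_cl = 0.066, omega2_v = 0.003)
  d3 <- tiny_dataset(m, n = 3, obs_offsets = c(4, 12, 24), seed = 5)
  expect_lt(abs(ofv_foce(d3, m)$ofv - ofv_quadrature(d3, m)), 0.5)
})

test_that("OFV is additive over subjects and invariant to their order", {
  m <- ref_model()
  d <- tiny_dataset(m, n = 2, seed = 3)
  one <- d[d$id == 1, ]
  dup <- dplyr::bind_rows(one, dplyr::mutate(one, id = 99))
  expect_equal(ofv_foce(dup, m)$ofv, 2 * ofv_foce(one, m)$ofv)

  # permuting subjects / relabeling ids changes nothing
  perm <- dplyr::arrange(d, dplyr::desc(id), time)
  expect_equal(ofv_foce(perm, m)$ofv, ofv_foce(d, m)$ofv)
  relab <- dplyr::mutate(d, id = ifelse(id == 1, 207, 4))
  expect_equal(ofv_foce(relab, m)$ofv, ofv_foce(d, m)$ofv)
})

test_that("typical values are recovered within 1% in the near-noiseless limit", {
  gen <- ref_model(omega2_cl = 0, omega2_v = 0,
                   sigma2_prop = 1e-6, sigma2_add = 0)
  cohort <- generate_cohort(n = 8, design = "rich", dose_per_kg = 0.05,
                            seed = 21)
  d <- simulate_observations(cohort, gen, seed = 22)
  start <- ref_model(theta_cl = 4, theta_v = 80,
                     omega2_cl = 0, omega2_v = 0,
                     sigma2_prop = 1e-6, sigma2_add = 0)
  f <- fit_pk(d, start,
              fix = c("omega2_cl", "omega2_v", "sigma2_prop", "sigma2_add"),
              settings = list(multi_start = 1, se = FALSE))
  est <- setNames(f$estimates$estimate, f$estimates$parameter)
  expect_lt(abs(est["theta_cl"] / 6.48 - 1), 0.01)
  expect_lt(abs(est["theta_v"] / 124 - 1), 0.01)
})

test_that("the fit reports SEs, the OFV at the optimum, and eta modes per subject", {
  m <- ref_model()
  d <- tiny_dataset(m, n = 5, obs_offsets = c(2, 12, 24), seed = 31)
  f <- fit_pk(d, m, fix = c("omega2_v", "sigma2_add"),
              settings = list(multi_start = 1, se = TRUE))
  expect_s3_class(f, "pk_fit")
  expect_equal(nrow(f$eta), 5)
  expect_true(all(c("theta_cl", "theta_v") %in% f$estimates$parameter))
  expect_true(all(is.finite(f$ofv)))
  td <- tidy(f)
  expect_true(all(c("estimate", "se_pct", "fixed") %in% names(td)))
  expect_true(any(is.finite(td$se_pct)))
  g <- glance(f)
  expect_equal(g$n_subjects, 5L)
  expect_equal(g$n_obs, 15L)
})

test_that("replicated fits recover the generating model", {
  # replicated generate/fit cycles under the reference parameter set;
  # 4 replicates of 16 subjects with rich sampling keep the runtime modest
  m <- ref_model()
  est <- lapply(1:4, function(r) {
    cohort <- generate_cohort(n = 16, design = "rich", dose_per_kg = 0.05,
                              seed = 300 + r)
    d <- simulate_observations(cohort, m, seed = 400 + r)
    f <- fit_pk(d, m, settings = list(multi_start = 1, se = FALSE))
    setNames(f$estimates$estimate, f$estimates$parameter)
  })
  med <- apply(do.call(rbind, est), 2, median)
  expect_lt(abs(med["theta_cl"] / 6.48 - 1), 0.10)
  expect_lt(abs(med["theta_v"] / 124 - 1), 0.10)
  # identifiable variance components land within a factor of two; the
  # near-boundary omega2_v and the additive sigma2 are weakly identified
  # at these sample sizes and are only required to stay finite
  expect_gt(med["omega2_cl"] / 0.066, 0.5)
  expect_lt(med["omega2_cl"] / 0.066, 2)
  expect_gt(med["sigma2_prop"] / 0.312, 0.5)
  expect_lt(med["sigma2_prop"] / 0.312, 2)
  expect_true(all(is.finite(unlist(est))))
})

test_that("datasets survive a write/read round trip", {
  m <- ref_model()
  d <- tiny_dataset(m, n = 3, seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(d, path)
  back <- read_pk_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(d), tolerance = 1e-12)
  header <- toupper(strsplit(readLines(path, n = 1), ",")[[1]])
  expect_equal(header[1:7], c("ID", "TIME", "AMT", "DV", "MDV", "EVID", "WT"))
})

test_that("malformed datasets are rejected with informative errors", {
  m <- ref_model()
  d <- tiny_dataset(m, n = 2, seed = 1)
  expect_error(validate_pk_dataset <- fit_pk(d[d$evid == 1, ], m),
               class = "sirodose_invalid_input")
  bad_wt <- dplyr::mutate(d, wt = 0)
  expect_error(fit_pk(bad_wt, m), class = "sirodose_invalid_input")
  expect_error(fit_pk(d, m, fix = "nope"), class = "sirodose_invalid_input")
})
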