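test_that("bootstrap bias reproduces the published worked examples", {
  expect_equal(round(bootstrap_bias(6.65, 6.48), 2), 2.62)
  expect_equal(round(bootstrap_bias(133, 124), 2), 7.26)
  expect_equal(bootstrap_bias(5, 5), 0)
})

test_that("degenerate resampling leaves percentiles at the original estimate", {
  m <- ref_model()
  d <- tiny_dataset(m, n = 1, obs_offsets = c(2, 12, 24), seed = 15)
  two <- dplyr::bind_rows(d, dplyr::mutate(d, id = 2))  # identical subjects
  boot <- bootstrap_pk(two, m, n_reps = 6, seed = 1,
                       fix = c("omega2_cl", "omega2_v", "sigma2_prop",
                               "sigma2_add"))
  s <- boot$summary
  expect_equal(s$boot_median, s$estimate, tolerance = 1e-5)
  expect_equal(s$ci_lo, s$ci_hi, tolerance = 1e-5)
  expect_equal(s$bias_pct, rep(0, nrow(s)), tolerance = 1e-3)
})

test_that("bootstrap summaries are ordered and seed-reproducible", {
  m <- ref_model()
  d <- tiny_dataset(m, n = 6, obs_offsets = c(2, 12, 24), seed = 16)
  fix <- c("omega2_v", "sigma2_prop", "sigma2_add")
  b1 <- bootstrap_pk(d, m, n_reps = 8, seed = 5, fix = fix)
  b2 <- bootstrap_pk(d, m, n_reps = 8, seed = 5, fix = fix)
  expect_identical(b1$summary, b2$summary)
  expect_true(all(b1$summary$ci_lo <= b1$summary$boot_median))
  expect_true(all(b1$summary$boot_median <= b1$summary$ci_hi))
  expect_lte(b1$n_converged, 8)
  expect_error(bootstrap_pk(d[d$id == 1, ], m, n_reps = 2, seed = 1),
               class = "sirodose_invalid_input")
})

test_that("VPC coverage on self-simulated data is close to nominal", {
  m <- ref_model()
  cohort <- generate_cohort(n = 50, design = "rich", seed = 17)
  d <- simulate_observations(cohort, m, seed = 18)
  v <- vpc_pk(d, m, n_sim = 300, seed = 19, bins = 4)
  expect_gt(v$fraction_inside, 0.92)
  expect_lt(v$fraction_inside, 0.98)
  expect_true(all(v$bins$sim_p2.5 <= v$bins$sim_p50))
  expect_true(all(v$bins$sim_p50 <= v$bins$sim_p97.5))
})

test_that("inflating the residual variance widens the simulated band", {
  m <- ref_model()
  cohort <- generate_cohort(n = 20, seed = 20)
  d <- simulate_observations(cohort, m, seed = 21)
  wide <- ref_model(sigma2_prop = 2 * m$sigma2_prop,
                    sigma2_add = 2 * m$sigma2_add)
  for (s in 1:5) {
    f_fit <- vpc_pk(d, m, n_sim = 120, seed = 30 + s, bins = 3)
    f_wide <- vpc_pk(d, wide, n_sim = 120, seed = 30 + s, bins = 3)
    expect_gte(f_wide$fraction_inside, f_fit$fraction_inside)
  }
})

test_that("a zero-variance model collapses the simulated band onto the predictions", {
  m0 <- ref_model(omega2_cl = 0, omega2_v = 0, sigma2_prop = 0,
                  sigma2_add = 0)
  cohort <- generate_cohort(n = 5, seed = 22)
  d <- simulate_observations(cohort, m0, seed = 23)
  v <- vpc_pk(d, m0, n_sim = 100, seed = 24, bins = 2)
  expect_equal(v$bins$obs_p50, v$bins$sim_p50, tolerance = 1e-10)
  expect_equal(v$bins$sim_p2.5, v$bins$sim_p97.5, tolerance = 1e-10)
})

test_that("IWRES follows its definition and is calibrated on true-model data", {
  m <- ref_model()
  expect_equal((12 - 10) / sqrt(residual_variance(10, m)), 0.3511,
               tolerance = 1e-4)

  cohort <- generate_cohort(n = 100, design = "rich", dose_per_kg = 0.05,
                            seed = 25)
  d <- simulate_observations(cohort, m, seed = 26)
  f <- fit_pk(d, m, fix = c("theta_cl", "theta_v", "omega2_cl", "omega2_v",
                            "sigma2_prop", "sigma2_add"))
  diag <- residual_diagnostics(fit = f)
  expect_equal(nrow(diag), 600)
  expect_true(all(is.finite(diag$iwres)))
  expect_true(all(is.finite(diag$wres)))
  expect_lt(abs(mean(diag$iwres)), 3 / sqrt(600) + 0.05)
  expect_lt(abs(sd(diag$iwres) - 1), 0.2)
})

test_that("diagnostics are invariant to subject order", {
  m <- ref_model()
  d <- tiny_dataset(m, n = 4, seed = 27)
  f <- fit_pk(d, m, fix = c("theta_cl", "theta_v", "omega2_cl", "omega2_v",
                            "sigma2_prop", "sigma2_add"))
  d_perm <- dplyr::arrange(d, dplyr::desc(id), time)
  a <- residual_diagnostics(d, f)
  b <- dplyr::arrange(residual_diagnostics(d_perm, f), id, time)
  expect_equal(as.data.frame(a), as.data.frame(dplyr::arrange(b, id, time)))
})

test_that("zero residual variance in diagnostics raises a named error", {
  m <- ref_model()
  d <- tiny_dataset(m, n = 2, seed = 28)
  f <- fit_pk(d, m, fix = c("theta_cl", "theta_v", "omega2_cl", "omega2_v",
                            "sigma2_prop", "sigma2_add"))
  f$model$sigma2_prop <- 0
  f$model$sigma2_add <- 0
  expect_error(residual_diagnostics(fit = f), class = "sirodose_invalid_model")
})
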