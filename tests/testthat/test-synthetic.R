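test_that("cohorts are reproducible pure functions of spec and seed", {
  a <- generate_cohort(n = 15, seed = 1)
  b <- generate_cohort(n = 15, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(n = 15, seed = 2)))

  expect_equal(length(unique(a$id)), 15)
  expect_true(all(a$wt >= 10 & a$wt <= 50))
  # trough design: three pre-dose samples per subject
  expect_equal(sum(a$evid == 0), 45)
})

test_that("dosing histories span at least ten half-lives before sampling", {
  m <- ref_model()
  cohort <- generate_cohort(n = 10, seed = 3)
  for (i in unique(cohort$id)) {
    sub <- cohort[cohort$id == i, ]
    p <- pk_params(m, sub$wt[1])
    thalf <- log(2) / (p$cl_over_f / p$v_over_f)
    first_sample <- min(sub$time[sub$evid == 0])
    expect_gt(first_sample, 10 * thalf)
  }
})

test_that("weights follow the log-uniform target distribution", {
  w <- generate_cohort(n = 1000, seed = 2)
  w <- unique(w[, c("id", "wt")])$wt
  expect_lt(abs(median(w) / sqrt(10 * 50) - 1), 0.10)
})

test_that("noise-free simulation returns the typical-model predictions", {
  m0 <- ref_model(omega2_cl = 0, omega2_v = 0, sigma2_prop = 0,
                  sigma2_add = 0)
  cohort <- generate_cohort(n = 3, design = "rich", seed = 5)
  d <- simulate_observations(cohort, m0, seed = 6)
  obs <- d[d$evid == 0, ]
  for (i in unique(obs$id)) {
    sub <- d[d$id == i, ]
    doses <- sub[sub$evid == 1, ]
    o <- sub[sub$evid == 0, ]
    pred <- conc_profile(pk_params(m0, o$wt[1]),
                         data.frame(time = doses$time, amount = doses$amt),
                         o$time)$conc
    expect_equal(o$dv, pred)
  }
})

test_that("additive-only noise is truncated at zero but unbiased near zero", {
  m <- ref_model(omega2_cl = 0, omega2_v = 0, sigma2_prop = 0,
                 sigma2_add = 1.249)
  cohort <- generate_cohort(n = 40, seed = 7)
  d <- simulate_observations(cohort, m, seed = 8)
  obs <- d$dv[d$evid == 0]
  expect_true(all(obs >= 0))
  expect_gt(sd(obs), 0.5)
})

test_that("simulated datasets round-trip through the NONMEM-style dialect", {
  d <- simulate_observations(generate_cohort(n = 4, seed = 9), ref_model(),
                             seed = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(d, path)
  expect_equal(as.data.frame(read_pk_dataset(path)), as.data.frame(d),
               tolerance = 1e-12)
})

test_that("simulation reuses one eta pair per subject across observations", {
  # with pure CL variability and no residual noise, each subject's
  # observations must be internally consistent with a single eta
  m <- ref_model(omega2_cl = 0.3, omega2_v = 0, sigma2_prop = 0,
                 sigma2_add = 0)
  cohort <- generate_cohort(n = 6, seed = 11)
  d <- simulate_observations(cohort, m, seed = 12)
  m$sigma2_add <- 1e-6   # vanishing measurement noise for the refit
  f <- fit_pk(d, m, fix = c("omega2_cl", "omega2_v", "sigma2_prop",
                            "sigma2_add"),
              settings = list(multi_start = 1, se = FALSE))
  diag <- residual_diagnostics(fit = f)
  expect_lt(max(abs(diag$dv - diag$ipred)), 0.02)
})

test_that("genotype sampling matches Hardy-Weinberg proportions", {
  g <- generate_genotypes(c(a = 0.5), n = 10000, seed = 13)
  expect_equal(g$n_ab / 10000, 0.5, tolerance = 0.02)
  expect_equal(g$n_aa + g$n_ab + g$n_bb, 10000)
  expect_identical(g, generate_genotypes(c(a = 0.5), n = 10000, seed = 13))
  expect_error(generate_genotypes(c(a = 1), n = 10, seed = 1),
               class = "sirodose_invalid_input")
  expect_error(generate_genotypes(c(a = 0), n = 10, seed = 1),
               class = "sirodose_invalid_input")
})

test_that("HWE rejection rate on equilibrium data is near the nominal 5%", {
  rejections <- vapply(1:50, function(s) {
    g <- generate_genotypes(c(v = 0.3), n = 500, seed = 100 + s)
    hwe_test(g$n_aa, g$n_ab, g$n_bb)$p_value < 0.05
  }, logical(1))
  # Binomial(50, 0.05): P(X <= 7) > 0.996
  expect_lte(sum(rejections), 7)
})
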