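test_that("typical parameters follow the allometric model", {
  m <- ref_model()
  p <- pk_params(m, 70)
  expect_equal(p$cl_over_f, 6.48)
  expect_equal(p$v_over_f, 124)
  expect_equal(p$ka, 0.485)

  # per-kg clearance at the extremes of the paediatric weight range
  ck <- clearance_per_kg(m, c(5, 60, 70))
  expect_equal(round(ck$cl_per_kg[1], 2), 0.18)
  expect_equal(round(ck$cl_per_kg[2], 2), 0.10)
  expect_equal(ck$cl_per_kg[3], 6.48 / 70)

  # a log-normal random effect of log 2 doubles clearance
  expect_equal(pk_params(m, 70, eta_cl = log(2))$cl_over_f, 2 * 6.48)
  expect_error(pk_params(m, -1), class = "sirodose_invalid_input")
  expect_error(pk_params(m, 0), class = "sirodose_invalid_input")
})

test_that("per-kg clearance decreases monotonically over 5-60 kg", {
  ck <- clearance_per_kg(ref_model(), seq(5, 60, by = 1))
  expect_true(all(diff(ck$cl_per_kg) < 0))
})

test_that("single-dose curve matches numerical integration of the ODEs", {
  skip_if_not_installed("deSolve")
  grid <- expand.grid(cl = c(0.9, 2.5, 6.48), v = c(9, 35, 124),
                      amount = c(0.5, 2))
  times <- c(0.5, 2, 6, 12, 24, 48)
  for (k in seq_len(nrow(grid))) {
    p <- list(cl_over_f = grid$cl[k], v_over_f = grid$v[k], ka = 0.485)
    closed <- conc_single_dose(p, grid$amount[k], times)
    ode <- ode_conc(grid$cl[k], grid$v[k], 0.485, grid$amount[k], times)
    expect_equal(closed, ode, tolerance = 1e-6)
  }
})

test_that("single-dose boundary cases and the reference value hold", {
  p <- pk_params(ref_model(), 70)
  expect_equal(conc_single_dose(p, 0, 12), 0)
  expect_equal(conc_single_dose(p, 1, 0), 0)
  expect_equal(conc_single_dose(p, 1, 24), 2.5786, tolerance = 1e-4)
  expect_error(conc_single_dose(p, 1, -1), class = "sirodose_invalid_input")
})

test_that("superposition is linear in dose and degenerates to a single dose", {
  p <- pk_params(ref_model(), 20)
  doses <- data.frame(time = seq(0, 72, by = 24), amount = 0.8)
  times <- c(10, 30, 70, 95)
  base <- conc_profile(p, doses, times)$conc
  doubled <- conc_profile(p, transform(doses, amount = 2 * amount), times)$conc
  expect_equal(doubled, 2 * base)
  expect_true(all(base >= 0))

  one <- data.frame(time = 0, amount = 1.5)
  expect_equal(conc_profile(p, one, times)$conc,
               conc_single_dose(p, 1.5, times))

  # requested time before any dose is 0, not an error
  late <- data.frame(time = 48, amount = 1)
  expect_equal(conc_profile(p, late, 12)$conc, 0)
  expect_error(conc_profile(p, doses[c(2, 1), ], times),
               class = "sirodose_invalid_input")
})

test_that("steady-state trough equals the many-dose superposition limit", {
  m <- ref_model()
  cases <- list(list(wt = 5, amount = 0.5, ref = 6.9),
                list(wt = 10, amount = 1.0, ref = 10.2))
  for (cs in cases) {
    p <- pk_params(m, cs$wt)
    tr <- ss_trough(p, cs$amount, 24)
    doses <- data.frame(time = 24 * (0:149), amount = cs$amount)
    superposed <- conc_profile(p, doses, 150 * 24)$conc
    expect_equal(tr, superposed, tolerance = 1e-9)
    expect_equal(tr, cs$ref, tolerance = 0.01)
  }
  expect_equal(ss_trough(pk_params(m, 20), 0, 24), 0)
  expect_error(ss_trough(pk_params(m, 20), 1, 0),
               class = "sirodose_invalid_input")
})

test_that("trough after twenty half-lives of dosing matches the analytic value", {
  p <- pk_params(ref_model(), 30)
  ke <- p$cl_over_f / p$v_over_f
  n_doses <- ceiling(20 * log(2) / ke / 24) + 1
  doses <- data.frame(time = 24 * (seq_len(n_doses) - 1), amount = 0.2)
  trough <- conc_profile(p, doses, 24 * n_doses)$conc
  expect_lt(abs(trough - ss_trough(p, 0.2, 24)), 1e-6)
})

test_that("the coincident absorption/elimination branch is continuous", {
  ka <- 0.485
  v <- 50
  p_at <- list(cl_over_f = ka * v, v_over_f = v, ka = ka)
  p_near <- list(cl_over_f = ka * v * (1 + 1e-9), v_over_f = v, ka = ka)
  t <- c(1, 6, 24)
  expect_equal(conc_single_dose(p_at, 1, t), conc_single_dose(p_near, 1, t),
               tolerance = 1e-6)
  expect_equal(ss_trough(p_at, 1, 24), ss_trough(p_near, 1, 24),
               tolerance = 1e-6)
})
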