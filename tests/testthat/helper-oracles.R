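# Independent oracles used across the suite.  These deliberately avoid the
# package's closed-form/Laplace code paths: the concentration oracle
# integrates the absorption/elimination ODE system, and the likelihood
# oracle integrates the random effects by Gauss-Hermite quadrature.

# numerical integration of dA_gut/dt = -ka A_gut, dA_c/dt = ka A_gut - ke A_c
ode_conc <- function(cl, v, ka, amount_mg, times) {
  ke <- cl / v
  rhs <- function(t, y, p) {
    list(c(-ka * y[1], ka * y[1] - ke * y[2]))
  }
  out <- deSolve::lsoda(c(gut = amount_mg * 1000, central = 0), c(0, times),
                        rhs, parms = NULL, rtol = 1e-10, atol = 1e-10)
  out[-1, "central"] / v
}

# Gauss-Hermite nodes/weights by Golub-Welsch (weight exp(-x^2))
gauss_hermite <- function(n) {
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- J[cbind(k + 1, k)] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# -2 log marginal likelihood by 2-d Gauss-Hermite quadrature over the
# lognormal random effects of a subject list (as built by make_subject)
ofv_quadrature <- function(data, model, n_nodes = 40) {
  gh <- gauss_hermite(n_nodes)
  subjects <- split(seq_len(nrow(data)), data$id)
  total <- 0
  for (rows in subjects) {
    sub <- data[rows, , drop = FALSE]
    doses <- sub[sub$evid == 1 & sub$amt > 0, ]
    obs <- sub[sub$evid == 0 & sub$mdv == 0, ]
    lik_eta <- function(e1, e2) {
      cl <- model$theta_cl * (sub$wt[1] / model$w_std)^model$allo_exp_cl *
        exp(e1)
      v <- model$theta_v * (sub$wt[1] / model$w_std)^model$allo_exp_v *
        exp(e2)
      ke <- cl / v
      conc <- vapply(obs$time, function(t) {
        idx <- which(doses$time <= t)
        tau <- t - doses$time[idx]
        amt <- doses$amt[idx] * 1000
        sum(amt * model$ka / (v * (model$ka - ke)) *
              (exp(-ke * tau) - exp(-model$ka * tau)))
      }, numeric(1))
      vr <- conc^2 * model$sigma2_prop + model$sigma2_add
      prod(stats::dnorm(obs$dv, conc, sqrt(vr)))
    }
    s1 <- sqrt(2 * model$omega2_cl)
    s2 <- sqrt(2 * model$omega2_v)
    lik <- 0
    for (i in seq_len(n_nodes)) {
      for (j in seq_len(n_nodes)) {
        lik <- lik + gh$weights[i] * gh$weights[j] *
          lik_eta(s1 * gh$nodes[i], s2 * gh$nodes[j])
      }
    }
    total <- total - 2 * log(lik / pi)
  }
  total
}

# exact -2 log-likelihood when both inter-individual variances are zero
ofv_fixed_effects <- function(data, model) {
  obs <- data[data$evid == 0 & data$mdv == 0, ]
  total <- 0
  for (i in unique(data$id)) {
    sub <- data[data$id == i, ]
    doses <- sub[sub$evid == 1 & sub$amt > 0, ]
    o <- sub[sub$evid == 0 & sub$mdv == 0, ]
    p <- pk_params(model, sub$wt[1])
    conc <- conc_profile(p, data.frame(time = doses$time, amount = doses$amt),
                         o$time)$conc
    vr <- conc^2 * model$sigma2_prop + model$sigma2_add
    total <- total + sum(log(2 * pi * vr) + (o$dv - conc)^2 / vr)
  }
  total
}
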