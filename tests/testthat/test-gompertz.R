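test_that("survival function matches its contract and the quadrature oracle", {
  expect_equal(gompertz_survival(65, 0.02, 0.1), 1)
  expect_equal(gompertz_survival(75, 0.02, 0), exp(-0.2))
  expect_error(gompertz_survival(60, 0.02, 0.1), "age origin")
  expect_error(gompertz_survival(70, -0.1, 0.1), "a0")

  grid <- list(c(0.01, 0.12, 0), c(0.03, 0.05, log(0.7)),
               c(0.02, 1e-10, 0.2), c(0.05, 0.2, -0.5))
  for (p in grid) {
    for (x in c(66, 75, 90)) {
      expect_equal(gompertz_survival(x, p[1], p[2], p[3]),
                   oracle_survival(x, p[1], p[2], p[3]), tolerance = 1e-8)
    }
  }
})

test_that("death-age sampler reproduces the Gompertz distribution", {
  set.seed(101)
  # exponential limit at b0 = 0
  d0 <- simulate_death_age(4000, a0 = 0.05, b0 = 0, origin = 65) - 65
  ks <- suppressWarnings(stats::ks.test(d0, "pexp", rate = 0.05))
  expect_gt(ks$p.value, 0.01)

  # mean against numeric integration of the survival function
  n <- 1e5
  d <- simulate_death_age(n, a0 = 0.02, b0 = 0.09, origin = 65)
  mean_oracle <- 65 + stats::integrate(function(t) {
    vapply(t + 65, oracle_survival, numeric(1), a0 = 0.02, b0 = 0.09)
  }, 0, 80, rel.tol = 1e-10)$value
  mc_se <- stats::sd(d) / sqrt(n)
  expect_lt(abs(mean(d) - mean_oracle), 3 * mc_se)

  # survival curve at selected ages, within 3 Monte-Carlo SEs
  for (age in c(70, 80, 90)) {
    p_hat <- mean(d > age)
    p_true <- oracle_survival(age, 0.02, 0.09)
    expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  }

  # a protective hazard shift stochastically raises death ages
  adv <- simulate_death_age(n, a0 = 0.02, b0 = 0.09, bz = log(0.64), origin = 65)
  expect_gt(mean(adv), mean(d))
  expect_error(simulate_death_age(10, a0 = 0, b0 = 0.1), "a0")
})

test_that("truncated log-likelihood equals the quadrature-normalized brute force", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    a0 <- stats::runif(1, 0.005, 0.05)
    b0 <- stats::runif(1, 0.01, 0.2)
    beta <- stats::rnorm(1, 0, 0.4)
    by <- sample(1900:1935, n, replace = TRUE)
    obs <- tibble::tibble(
      x = stats::runif(n, 66, 80),
      L = pmax(65, 1988 - by - 0.5),
      U = 2005 - by + 0.5,
      weight = stats::runif(n, 0.5, 2),
      fb = stats::rbinom(n, 1, 0.5)
    )
    obs <- obs[obs$x >= obs$L & obs$x <= obs$U, ]
    if (nrow(obs) == 0) next
    got <- truncated_loglik(list(a0 = a0, b0 = b0, beta = beta), obs)
    want <- oracle_trunc_loglik(a0, b0, beta, obs)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("likelihood is linear in the weights and total without truncation", {
  obs <- tibble::tibble(x = c(70.5, 75.5, 82.5), L = 65, U = Inf,
                        weight = 1, fb = c(0, 1, 0))
  p <- list(a0 = 0.02, b0 = 0.1, beta = log(0.8))
  ll1 <- truncated_loglik(p, obs)
  # no-truncation limit: unconditional log density
  dens <- vapply(seq_len(3), function(i) {
    bz <- p$beta * obs$fb[i]
    log(oracle_density(obs$x[i], p$a0, p$b0, bz))
  }, numeric(1))
  expect_equal(ll1, sum(dens), tolerance = 1e-8)

  obs2 <- obs; obs2$weight <- 2
  expect_equal(truncated_loglik(p, obs2), 2 * ll1)

  # degenerate window is an error naming the record
  obs3 <- tibble::tibble(x = 70, L = 70, U = 70, weight = 1)
  expect_error(truncated_loglik(list(a0 = 0.02, b0 = 0.1), obs3),
               "no probability mass")
})

test_that("fit recovers generating parameters without truncation", {
  set.seed(42)
  n <- 1e5
  z <- rep(c(0, 1), each = n / 2)
  age <- simulate_death_age(n, 0.02, 0.09, bz = log(0.8) * z, origin = 65)
  obs <- tibble::tibble(x = age, L = 65, U = Inf, weight = 1, foreign_born = z)
  fit <- fit_gompertz(obs, origin = 65)
  se <- sqrt(diag(fit$vcov))
  truth <- c(log(0.02), 0.09, log(0.8))
  expect_true(all(abs(fit$theta - truth) < 3 * se))
  expect_lt(fit$gradient_norm, 1e-2)
})

test_that("null covariate effect is recovered and its CI covers 1", {
  tr <- simulate_two_group_design(8000, a0 = 0.012, b0 = 0.12, beta_fb = 0,
                                  seed = 5)
  fit <- fit_gompertz(death_observations(tr, truncation_window()))
  hr <- fit$hazard_ratios
  expect_lt(abs(hr$beta), 3 * hr$se)
  expect_true(hr$hr_lower <= 1 && hr$hr_upper >= 1)
})

test_that("weight scaling leaves point estimates unchanged", {
  tr <- simulate_two_group_design(3000, a0 = 0.012, b0 = 0.12,
                                  beta_fb = log(0.7), seed = 9)
  w <- truncation_window()
  obs1 <- death_observations(tr, w)
  obs2 <- obs1; obs2$weight <- 3 * obs2$weight
  f1 <- fit_gompertz(obs1)
  f2 <- fit_gompertz(obs2)
  expect_equal(f2$loglik, 3 * f1$loglik, tolerance = 1e-6)
  expect_equal(f2$theta, f1$theta, tolerance = 1e-5)
})

test_that("e65 functional: closed form, oracle, monotonicity, reparameterization", {
  expect_equal(gompertz_e65(0.02, 0), 65 + 1 / 0.02)
  expect_equal(gompertz_e65(0.02, 0, bz = log(2)), 65 + 1 / 0.04)
  expect_error(gompertz_e65(0.02, -0.05), "diverges")

  # dense trapezoid summation oracle
  tt <- seq(0, 60, by = 0.001)
  S <- vapply(65 + tt, function(x) exp(-0.012 / 0.14 * (exp(0.14 * (x - 65)) - 1)),
              numeric(1))
  trap <- 65 + sum((S[-1] + S[-length(S)]) / 2) * 0.001
  expect_equal(gompertz_e65(0.012, 0.14), trap, tolerance = 1e-6)

  # strictly decreasing in a0
  a_grid <- c(0.005, 0.01, 0.02, 0.05)
  e <- vapply(a_grid, gompertz_e65, numeric(1), b0 = 0.1)
  expect_true(all(diff(e) < 0))

  # age-origin reparameterization: conditioning an origin-0 hazard
  # a0' e^{b0 x} on survival to 65 gives the same e65 as the origin-65
  # parameterization with a0 = a0' e^{65 b0}
  a0 <- 0.012; b0 <- 0.11
  a0_0 <- a0 * exp(-65 * b0)
  e65_via_birth <- 65 + stats::integrate(function(x) {
    exp(-(a0_0 / b0) * (exp(b0 * x) - exp(b0 * 65)))
  }, 65, 200, rel.tol = 1e-10)$value
  expect_equal(gompertz_e65(a0, b0, origin = 65), e65_via_birth,
               tolerance = 1e-6)
})

test_that("e65 is invariant to fitting with a shifted age origin", {
  tr <- simulate_two_group_design(4000, a0 = 0.0115, b0 = 0.118,
                                  beta_fb = log(0.64), seed = 13)
  w <- truncation_window()
  f65 <- fit_gompertz(death_observations(tr, w, origin = 65))
  f0 <- fit_gompertz(death_observations(tr, w, origin = 0),
                     init = list(a0 = 0.0115 * exp(-65 * 0.118), b0 = 0.118,
                                 beta = log(0.64)))
  e65_a <- gompertz_e65(f65$a0, f65$b0, origin = 65)
  e65_b <- gompertz_e65(f0$a0 * exp(65 * f0$b0), f0$b0, origin = 65)
  expect_equal(e65_a, e65_b, tolerance = 1e-6)
})

test_that("calibration solver hits both e65 targets", {
  cal <- calibrate_gompertz_e65(82.26, 85.39, 0.64)
  expect_equal(cal$e65_native, 82.26, tolerance = 1e-7)
  expect_equal(cal$e65_foreign, 85.39, tolerance = 1e-7)
  expect_equal(gompertz_e65(cal$a0, cal$b0), 82.26, tolerance = 1e-6)
  expect_equal(gompertz_e65(cal$a0, cal$b0, bz = cal$beta_fb), 85.39,
               tolerance = 1e-6)
})

test_that("nativity effect: exact null, and HR < 1 iff delta-e65 > 0", {
  fit0 <- structure(list(
    a0 = 0.015, b0 = 0.1, beta = c(foreign_born = 0),
    theta = c(log_a0 = log(0.015), b0 = 0.1, foreign_born = 0),
    vcov = diag(1e-6, 3), vcov_ok = TRUE, conf_level = 0.95,
    hazard_ratios = tibble::tibble(term = "foreign_born", beta = 0, se = 1e-3,
                                   hr = 1, hr_lower = 0.99, hr_upper = 1.01),
    n = 10L, origin = 65, convergence = 0L, gradient_norm = 0
  ), class = "gompertz_fit")
  eff0 <- nativity_effect(fit0, n_boot = 50, seed = 2)
  expect_identical(eff0$hr, 1)
  expect_identical(eff0$delta_e65, 0)
  expect_error(nativity_effect(fit0, term = "nope"), "nope")

  for (hr in c(0.6, 0.8, 1.0, 1.2)) {
    for (b0 in c(0.05, 0.12, 0.2)) {
      d <- gompertz_e65(0.015, b0, bz = log(hr)) - gompertz_e65(0.015, b0)
      expect_equal(sign(d), -sign(log(hr)))
    }
  }
})

test_that("fixed-effects linear check recovers a uniform death-age shift", {
  set.seed(21)
  n <- 6000
  by <- sample(1910:1930, n, replace = TRUE)
  fb <- stats::rbinom(n, 1, 0.5)
  da <- round(72 + 0.1 * (by - 1920) + 2 * fb + stats::rnorm(n, 0, 4))
  rec <- tibble::tibble(birth_year = by, death_age = da,
                        foreign_born = fb == 1, weight = 1)
  out <- fe_linear_check(rec)
  expect_equal(out$estimate, 2, tolerance = 3 * out$se)

  # degenerate single cohort equals plain OLS
  one <- rec[rec$birth_year == 1920, ]
  out1 <- fe_linear_check(one)
  ols <- stats::lm(death_age ~ I(as.numeric(foreign_born)), data = one)
  expect_equal(out1$estimate, unname(coef(ols)[2]), tolerance = 1e-10)

  # collinear covariates are named
  rec$dup <- as.numeric(rec$foreign_born)
  expect_error(fe_linear_check(rec, c("foreign_born", "dup")), "dup")
})

test_that("descriptive statistics: means, modal tie-break, weights", {
  rec <- tibble::tibble(
    group = "g", sex = "male", foreign_born = FALSE,
    birth_year = 1920, death_age = rep(70, 5), weight = 1
  )
  d <- descriptive_stats(rec)
  expect_equal(d$mean_death_age, 70)
  expect_equal(d$modal_death_age, 70)

  bim <- tibble::tibble(
    group = "g", sex = "male", foreign_born = FALSE, birth_year = 1920,
    death_age = c(rep(66, 10), rep(80, 10)), weight = 1
  )
  expect_equal(descriptive_stats(bim)$modal_death_age, 66)

  wrec <- tibble::tibble(
    group = "g", sex = "male", foreign_born = FALSE, birth_year = 1920,
    death_age = c(70, 80), weight = c(3, 1)
  )
  expect_equal(descriptive_stats(wrec)$mean_death_age, 72.5)
})
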