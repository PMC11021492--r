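test_that("relaxation series are bit-identical for identical seeds", {
  a <- simulate_twist_relaxation(relaxation_params(seed = 42))
  b <- simulate_twist_relaxation(relaxation_params(seed = 42))
  expect_identical(a$theta_deg, b$theta_deg)
  c <- simulate_twist_relaxation(relaxation_params(seed = 43))
  expect_false(identical(a$theta_deg, c$theta_deg))
})

test_that("noise-free relaxation follows the closed form", {
  p <- relaxation_params(sigma = 0, n_runs = 1, dt = 0.5)
  ts <- simulate_twist_relaxation(p)
  at20 <- ts$theta_deg[ts$time == 20]
  expect_equal(at20, 98 * (1 - exp(-4)), tolerance = 1e-10)
  # exponential fit recovers tau to well within 1 percent
  fit <- fit_relaxation(ts)
  expect_equal(fit$tau, 5, tolerance = 0.01)
  expect_equal(fit$theta_eq, 98, tolerance = 0.01)
})

test_that("final-window mean sits on the plateau within the OU error bound", {
  p <- relaxation_params(seed = 11)
  ts <- simulate_twist_relaxation(p)
  tail_win <- ts[ts$time > 0.8 * p$t_total, ]
  # correlated (OU) samples: effective sample size shrinks by 2*tau_noise/dt
  n_eff <- nrow(tail_win) / (2 * p$tau_noise / p$dt)
  bound <- 2 * p$sigma / sqrt(n_eff)
  expect_lt(abs(mean(tail_win$theta_deg) - p$theta_eq), bound)
})

test_that("replicate summary has honest dimensions and flags", {
  ts <- simulate_twist_relaxation(relaxation_params(seed = 3, t_total = 20))
  smry <- attr(ts, "summary")
  expect_equal(nrow(smry), 100)
  expect_true(all(smry$n_runs == 4))
  expect_true(all(is.finite(smry$sd_theta)))
  one <- simulate_twist_relaxation(relaxation_params(n_runs = 1, t_total = 10))
  expect_true(all(is.na(attr(one, "summary")$sd_theta)))
})

test_that("tidy and glance expose the relaxation fit broom-style", {
  fit <- fit_relaxation(simulate_twist_relaxation(relaxation_params(seed = 2)))
  td <- generics::tidy(fit)
  expect_identical(td$term, c("theta_eq", "tau"))
  expect_true(all(td$std.error > 0))
  gl <- generics::glance(fit)
  expect_identical(names(gl), c("sigma", "df.residual", "nobs", "deviance"))
  expect_equal(gl$nobs, 2000)
})

test_that("parameter validation rejects impossible settings", {
  expect_error(relaxation_params(tau = 0), class = "ribbonhelix_domain_error")
  expect_error(relaxation_params(dt = 0), class = "ribbonhelix_domain_error")
  expect_error(relaxation_params(t_total = 0.1, dt = 0.2),
               class = "ribbonhelix_domain_error")
  expect_error(relaxation_params(n_runs = 0), class = "ribbonhelix_domain_error")
})
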