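test_that("free energy vanishes at N = 1 for any parameters", {
  withr::with_seed(11, {
    for (k in 1:20) {
      p <- model_params(kappa = runif(1, 0, 50), phi = runif(1, 0.001, 0.3),
                        beta_eps = runif(1, 1, 100))
      expect_identical(free_energy_per_monomer(1, p), 0)
    }
  })
})

test_that("free energy matches hand evaluation and is strictly convex", {
  p <- model_params(kappa = 1, phi = 0.0314)
  expect_equal(free_energy_per_monomer(2, p), -0.4998768, tolerance = 1e-6)
  # finite-difference second derivative positive everywhere
  n <- 1:59
  e <- free_energy_per_monomer(1:60, p)
  d2 <- diff(e, differences = 2)
  expect_true(all(d2 > 0))
  # quadratic penalty dominates at large N
  expect_gt(free_energy_per_monomer(1e4, p), 1e3)
  expect_gt(free_energy_per_monomer(1e4, p), free_energy_per_monomer(100, p))
  expect_error(free_energy_per_monomer(0, p), class = "ribbonhelix_domain_error")
})

test_that("width distribution is unit-max, unimodal, and kappa-ordered", {
  for (k in c(0.01, 0.1, 1, 10, 100)) {
    wd <- width_distribution(model_params(kappa = k))
    expect_identical(max(wd$p_scaled), 1)
    # p > 0 analytically; double-precision underflow can reach exactly 0
    # for extreme kappa, so positivity is asserted where representable
    expect_true(all(wd$p_scaled >= 0 & wd$p_scaled <= 1))
    if (k <= 10) expect_true(all(wd$p_scaled > 0))
    # unimodal: the sign of successive differences changes at most once
    s <- sign(diff(wd$p_scaled))
    s <- s[s != 0]
    expect_lte(sum(diff(s) != 0), 1)
  }
  modes <- vapply(c(0.01, 0.1, 1, 10, 100), function(k) {
    attr(width_distribution(model_params(kappa = k)), "mode_n")
  }, integer(1))
  expect_true(all(diff(modes) >= 0))
})

test_that("kappa = 0 gives a strictly decreasing distribution with mode 1", {
  wd <- width_distribution(model_params(kappa = 0))
  expect_true(all(diff(wd$p_scaled) < 0))
  expect_identical(attr(wd, "mode_n"), 1L)
  expect_error(model_params(n_max = 1), class = "ribbonhelix_domain_error")
})

test_that("continuous mode obeys the closed form and its scaling law", {
  mw <- mode_width(model_params(kappa = 1, phi = 0.0314))
  expect_equal(mw$n_star_continuous, 23.0, tolerance = 2e-3)
  expect_equal(mw$mode_d, mw$mode_n * 0.46)
  # integer mode brackets the continuous optimum
  expect_lte(abs(mw$mode_n - mw$n_star_continuous), 1)
  # cube-root scaling: 8x kappa doubles the optimum
  n1 <- mode_width(model_params(kappa = 2, phi = 0.05))$n_star_continuous
  n8 <- mode_width(model_params(kappa = 16, phi = 0.05))$n_star_continuous
  expect_equal(n8, 2 * n1, tolerance = 1e-12)
  # kappa = 0: no interfacial drive, single-column ribbons
  m0 <- mode_width(model_params(kappa = 0))
  expect_identical(m0$mode_n, 1L)
  expect_true(is.na(m0$n_star_continuous))
})

test_that("integer mode tracks the continuous optimum across a grid", {
  withr::with_seed(5, {
    for (k in 1:25) {
      p <- model_params(kappa = runif(1, 0.05, 30),
                        phi = runif(1, 0.01, 0.2), n_max = 200L)
      mw <- mode_width(p)
      if (mw$n_star_continuous > 1 && mw$n_star_continuous < p$n_max) {
        expect_lte(abs(mw$mode_n - mw$n_star_continuous), 1)
        # and it agrees with the argmax of the tabulated distribution
        expect_identical(mw$mode_n, attr(width_distribution(p), "mode_n"))
      }
    }
  })
})

test_that("pH mapping is monotone with the expected limits", {
  map <- ph_map()
  # half protonation at the apparent pKa
  expect_equal(kappa_from_ph(map$pka_app, map),
               (map$gamma_ha + map$gamma_a) / 2 * map$l * map$delta / map$epsilon)
  # saturation limits
  expect_equal(kappa_from_ph(-50, map),
               map$gamma_ha * map$l * map$delta / map$epsilon)
  expect_equal(kappa_from_ph(50, map),
               map$gamma_a * map$l * map$delta / map$epsilon)
  # acidic conditions raise kappa
  expect_gt(kappa_from_ph(4, map), kappa_from_ph(7, map))
  # monotone non-increasing on a fine grid
  grid <- kappa_from_ph(seq(0, 14, by = 0.1), map)
  expect_true(all(diff(grid) <= 0))
  expect_error(ph_map(gamma_ha = 0.1, gamma_a = 0.2),
               class = "ribbonhelix_domain_error")
})

test_that("width_curves stacks tidy curves for plotting", {
  cv <- width_curves(c(0.1, 1), n_max = 30)
  expect_s3_class(cv, "tbl_df")
  expect_setequal(unique(cv$kappa), c(0.1, 1))
  expect_equal(nrow(cv), 60)
  p <- plot_width_curves(c(0.1, 1), n_max = 30)
  expect_s3_class(p, "ggplot")
})
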