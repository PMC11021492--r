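# an ideal, finely sampled map: no instrument effects, 0.25 nm pixels
ideal_map <- function(W = 10.7, H = 5.2, P = 86.4, hand = "right") {
  render_heightmap(W, 2.46, pitch_nm = P, handedness = hand,
                   length_nm = 2.6 * P, pixel_size = 0.25,
                   tip_sigma_nm = 0, noise_sd = 0, seed = 17,
                   apparent_height_nm = H)
}

preset_map <- function(W = 10.7, H = 5.2, P = 86.4, hand = "right", seed = 42) {
  render_heightmap(W, 2.46, pitch_nm = P, handedness = hand,
                   length_nm = 2.6 * P, seed = seed, apparent_height_nm = H)
}

test_that("noise-free estimates recover the truth to within one percent", {
  hm <- ideal_map()
  p <- estimate_pitch(hm)
  expect_equal(p$pitch_nm, 86.4, tolerance = 0.01)
  expect_gte(p$n_periods, 2)
  expect_equal(estimate_width(hm), 10.7, tolerance = 0.01)
  expect_equal(estimate_height(hm), 5.2, tolerance = 0.01)
})

test_that("estimates at standard pixel size land within one pixel", {
  hm <- preset_map(seed = 5)
  expect_equal(estimate_width(hm), 10.7, tolerance = 1 / 10.7)
  expect_equal(estimate_height(hm), 5.2, tolerance = 1 / 5.2)
  expect_equal(estimate_pitch(hm)$pitch_nm, 86.4, tolerance = 1 / 86.4)
})

test_that("flat and empty maps raise the documented errors", {
  stripe <- render_heightmap(10.7, 2.46, pitch_nm = NULL, length_nm = 80,
                             tip_sigma_nm = 0.5, noise_sd = 0, seed = 1)
  expect_error(estimate_pitch(stripe),
               class = "ribbonhelix_no_periodicity_error")
  expect_equal(estimate_height(stripe), 2.46, tolerance = 0.02)
  expect_equal(estimate_width(stripe), 10.7, tolerance = 1 / 10.7)
  empty <- heightmap(matrix(abs(rnorm(400, 0, 1e-3)), 20), pixel_size = 1)
  expect_error(estimate_width(empty), class = "ribbonhelix_detection_error")
})

test_that("too short a map raises an insufficient-periods error", {
  short <- render_heightmap(10.7, 2.46, pitch_nm = 86.4, length_nm = 110,
                            tip_sigma_nm = 0.5, noise_sd = 0, seed = 2,
                            apparent_height_nm = 5.2)
  expect_error(estimate_pitch(short),
               class = "ribbonhelix_insufficient_periods_error")
})

test_that("mirroring flips the handedness label and keeps the confidence", {
  for (seed in c(3, 4)) {
    hm <- preset_map(seed = seed)
    a <- classify_handedness(hm)
    b <- classify_handedness(mirror_heightmap(hm))
    expect_identical(sort(c(a$handedness, b$handedness)), c("left", "right"))
    expect_equal(a$confidence, b$confidence, tolerance = 1e-8)
  }
})

test_that("noise-free handedness classification is perfect over a grid", {
  labels <- character(0); truths <- character(0)
  for (hand in c("right", "left")) {
    for (P in c(70, 86.4, 100, 120, 140)) {
      for (W in c(9, 12)) {
        hm <- render_heightmap(W, 2.46, pitch_nm = P, handedness = hand,
                               length_nm = 2.6 * P, tip_sigma_nm = 0.5,
                               noise_sd = 0, seed = 30,
                               apparent_height_nm = 5.2)
        labels <- c(labels, classify_handedness(hm)$handedness)
        truths <- c(truths, hand)
      }
    }
  }
  expect_identical(labels, truths)
})

test_that("a featureless stripe is labelled indeterminate", {
  stripe <- render_heightmap(10.7, 2.46, pitch_nm = NULL, length_nm = 80,
                             tip_sigma_nm = 0.5, noise_sd = 0, seed = 1)
  expect_identical(classify_handedness(stripe)$handedness, "indeterminate")
})

test_that("estimates are invariant to in-plane rotation within 2 percent", {
  base <- lapply(c(42, 43), function(s) preset_map(seed = s))
  m0 <- dplyr::bind_rows(lapply(base, measure_helix))
  for (ang in c(30, 60, 90)) {
    mr <- dplyr::bind_rows(lapply(base, function(h) {
      measure_helix(rotate_heightmap(h, ang))
    }))
    expect_equal(mean(mr$pitch_nm), mean(m0$pitch_nm), tolerance = 0.02)
    expect_equal(mean(mr$width_nm), mean(m0$width_nm), tolerance = 0.02)
    expect_equal(mean(mr$height_nm), mean(m0$height_nm), tolerance = 0.02)
    expect_identical(mr$handedness, m0$handedness)
  }
})

test_that("population summaries report sds, counts and formatted strings", {
  one <- measure_helix(preset_map(seed = 6))
  s1 <- summarize_population(one)
  expect_true(is.na(s1$sd[s1$quantity == "pitch_nm"]))
  expect_match(s1$formatted[1], "sd not applicable")
  two <- dplyr::bind_rows(one, one)
  s2 <- summarize_population(two)
  expect_equal(s2$sd, rep(0, 3))
  expect_equal(s2$n, rep(2L, 3))
  expect_match(s2$formatted[1], "± 0.0 nm \\(n = 2\\)")
  expect_error(summarize_population(one[0, ]),
               class = "ribbonhelix_domain_error")
})

test_that("an end-to-end preset summary has the expected shape", {
  pop <- generate_population(population_preset("ph7", n_helices = 8, seed = 12))
  meas <- measure_population(pop$maps)
  expect_equal(nrow(meas), 8)
  smry <- summarize_population(meas)
  expect_match(smry$formatted[smry$quantity == "pitch_nm"],
               "^[0-9]+\\.[0-9] ± [0-9.]+ nm \\(n = 8\\)$")
  expect_true(attr(smry, "fraction_right") >= 0 &&
                attr(smry, "fraction_right") <= 1)
  expect_gte(attr(smry, "n_periods_total"), 8)
})
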