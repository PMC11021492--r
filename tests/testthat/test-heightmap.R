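test_that("renders are bit-identical for identical seeds", {
  a <- render_heightmap(10.7, 2.46, pitch_nm = 86.4, length_nm = 120, seed = 9)
  b <- render_heightmap(10.7, 2.46, pitch_nm = 86.4, length_nm = 120, seed = 9)
  expect_identical(a$grid, b$grid)
  c <- render_heightmap(10.7, 2.46, pitch_nm = 86.4, length_nm = 120, seed = 10)
  expect_false(identical(a$grid, c$grid))
})

test_that("an untwisted ribbon renders as a flat stripe at its thickness", {
  hm <- render_heightmap(10.7, 2.46, pitch_nm = NULL, length_nm = 60,
                         tip_sigma_nm = 0, noise_sd = 0, seed = 1)
  fp <- hm$grid[hm$grid > 0]
  expect_true(all(abs(fp - 2.46) < 1e-9))
  # footprint is a stripe roughly one width across
  rows <- rowSums(hm$grid > 0)
  expect_lte(max(rows > 0) , nrow(hm$grid))
  expect_equal(max(colSums(hm$grid > 0)), 10, tolerance = 1)
})

test_that("raw rigid envelope spans thickness to the cross-section diagonal", {
  hm <- render_heightmap(10.7, 2.46, pitch_nm = 90, length_nm = 200,
                         tip_sigma_nm = 0, noise_sd = 0, seed = 2)
  prof <- apply(hm$grid, 2, max)
  expect_gte(min(prof), 2.46 - 1e-6)
  expect_lte(max(prof), sqrt(10.7^2 + 2.46^2) + 1e-6)
})

test_that("height-profile autocorrelation peaks at half the pitch", {
  hm <- render_heightmap(10.7, 2.46, pitch_nm = 90, length_nm = 270,
                         tip_sigma_nm = 0, noise_sd = 0, seed = 5,
                         apparent_height_nm = 5.2)
  prof <- apply(hm$grid, 2, max)
  d <- prof - mean(prof)
  ac <- stats::acf(d, lag.max = 120, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  peaks <- which(diff(sign(diff(ac))) < 0) + 1L
  peaks <- peaks[peaks > 3]
  best <- peaks[which.max(ac[peaks])] - 1L
  expect_equal(best, 45, tolerance = 2)
})

test_that("the apparent-height mapping pins the crest level exactly", {
  hm <- render_heightmap(10.7, 2.46, pitch_nm = 90, length_nm = 200,
                         tip_sigma_nm = 0, noise_sd = 0, seed = 3,
                         apparent_height_nm = 5.2)
  expect_equal(max(hm$grid), 5.2, tolerance = 1e-9)
  # every half-turn reaches the cap
  prof <- apply(hm$grid, 2, max)
  expect_gt(mean(prof > 5.2 - 1e-6), 0.2)
})

test_that("mirroring flips rows exactly and rotation round-trips", {
  hm <- render_heightmap(9, 2.46, pitch_nm = 80, length_nm = 100, seed = 4)
  mm <- mirror_heightmap(hm)
  expect_identical(mm$grid, hm$grid[rev(seq_len(nrow(hm$grid))), ])
  expect_identical(mirror_heightmap(mm)$grid, hm$grid)
  r90 <- rotate_heightmap(hm, 90)
  expect_equal(dim(r90$grid), rev(dim(hm$grid)) + c(0, 0), tolerance = 1)
  expect_equal(r90$axis_angle, 90)
})

test_that("renderer rejects non-positive geometry", {
  expect_error(render_heightmap(0, 2.46), class = "ribbonhelix_domain_error")
  expect_error(render_heightmap(10, 2.46, pitch_nm = -5),
               class = "ribbonhelix_domain_error")
  expect_error(render_heightmap(10, 2.46, noise_sd = -0.1),
               class = "ribbonhelix_domain_error")
})

test_that("population draws are reproducible with truthful tables", {
  spec <- population_preset("ph7", n_helices = 6, seed = 21)
  pop <- generate_population(spec)
  expect_equal(nrow(pop$truth), 6)
  expect_false(any(is.na(pop$truth)))
  expect_length(pop$maps, 6)
  pop2 <- generate_population(spec)
  expect_identical(pop$truth, pop2$truth)
  expect_identical(pop$maps[[3]]$grid, pop2$maps[[3]]$grid)
})

test_that("population draws honour the spec's statistics", {
  spec <- population_spec(n_helices = 400, pitch_mean = 86.4, pitch_sd = 6.7,
                          handedness_fraction_right = 0.5, seed = 8)
  pop <- generate_population(spec, render = FALSE)
  se <- 6.7 / sqrt(400)
  expect_lt(abs(mean(pop$truth$pitch_nm) - 86.4), 3 * se)
  expect_gt(min(pop$truth$pitch_nm), 0)
  n_right <- sum(pop$truth$handedness == "right")
  expect_lt(abs(n_right - 200), 3 * sqrt(400 * 0.25))
})
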