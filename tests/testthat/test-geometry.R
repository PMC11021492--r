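test_that("built ribbons carry the advertised lattice and labels", {
  rb <- build_ribbon(5, 7)
  lat <- ribbon_lattice()
  expect_equal(nrow(rb), 5 * 7 * 2 * lat$residues_per_chain)
  expect_equal(length(unique(rb$monomer_id)), 5 * 7 * 2)
  key <- paste(rb$leaflet, rb$column, rb$segment, rb$residue)
  expect_false(any(duplicated(key)))
  # untwisted: upper-leaflet backbone points coplanar, termini on the surface
  up <- rb[rb$leaflet == "upper" & rb$residue < lat$residues_per_chain, ]
  expect_true(all(up$z == lat$backbone_gap / 2))
  pol <- rb[rb$residue == lat$residues_per_chain, ]
  expect_true(all(abs(pol$z) == lat$bilayer_thickness / 2))
  # x period: adjacent residues along a chain one residue_spacing apart
  ch <- rb[rb$leaflet == "upper" & rb$column == 1 & rb$segment == 1, ]
  expect_equal(diff(sort(ch$x)), rep(lat$residue_spacing, 4))
})

test_that("builder refuses degenerate requests", {
  expect_error(build_ribbon(5, 7, pitch_nm = 0), class = "ribbonhelix_domain_error")
  expect_error(build_ribbon(5, 7, noise_sd = -1), class = "ribbonhelix_domain_error")
  expect_error(build_ribbon(1, 7), class = "ribbonhelix_domain_error")
  # more than a half-turn over the built length would alias the dihedral
  expect_error(build_ribbon(5, 40, pitch_nm = 30), "half turn")
})

test_that("twist dihedral recovers the built twist exactly at zero noise", {
  lat <- ribbon_lattice()
  for (case in list(c(87, 17), c(120, 12), c(300, 25))) {
    rb <- build_ribbon(11, case[2], pitch_nm = case[1])
    expected <- 360 * (case[2] - 1) * lat$residues_per_chain *
      lat$residue_spacing / case[1]
    tw <- twist_dihedral(rb)
    expect_lt(abs(tw$theta_deg - expected), 0.5)
    expect_equal(tw$pitch_nm, case[1], tolerance = 1e-6)
    expect_identical(tw$handedness, "right")
  }
})

test_that("twist dihedral degrades gracefully under positional noise", {
  rb <- build_ribbon(11, 17, pitch_nm = 87, noise_sd = 0.05, seed = 4)
  expect_lt(abs(twist_dihedral(rb)$theta_deg - 96.0), 3)
})

test_that("flat ribbons read as flat and mirror flips the sign exactly", {
  flat <- build_ribbon(8, 10)
  tw <- twist_dihedral(flat)
  expect_identical(tw$handedness, "flat")
  expect_lt(abs(tw$theta_deg), 1e-8)
  expect_true(is.na(tw$pitch_nm))

  rb <- build_ribbon(8, 10, pitch_nm = 150, noise_sd = 0.02, seed = 9)
  th <- twist_dihedral(rb)$theta_deg
  expect_equal(twist_dihedral(mirror_ribbon(rb))$theta_deg, -th)
  left <- build_ribbon(8, 10, pitch_nm = 150, handedness = "left")
  expect_identical(twist_dihedral(left)$handedness, "left")
})

test_that("twist dihedral is invariant under rigid motions", {
  rb <- build_ribbon(9, 14, pitch_nm = 160, noise_sd = 0.01, seed = 2)
  th <- twist_dihedral(rb)$theta_deg
  for (s in 1:5) {
    expect_lt(abs(twist_dihedral(rigid_motion(rb, seed = s))$theta_deg - th),
              1e-6)
  }
})

test_that("edge-vector angle matches the closed form on an analytic plane", {
  for (theta in c(15, 45, 98, 160, -98)) {
    pl <- twisted_plane(theta_total = theta)
    expect_lt(abs(twist_dihedral(pl)$theta_deg - theta), 0.1)
  }
})

test_that("insufficient or degenerate geometry raises typed errors", {
  rb <- build_ribbon(5, 7)
  expect_error(twist_dihedral(rb[rb$segment == 1, ]),
               class = "ribbonhelix_insufficient_data_error")
  degenerate <- rb
  degenerate$x <- 0; degenerate$y <- 0; degenerate$z <- 0
  expect_error(twist_dihedral(degenerate),
               class = "ribbonhelix_degenerate_error")
})

test_that("pitch extrapolation follows pitch = 360 L / theta", {
  expect_equal(pitch_from_twist(98, 23.7), 87.06122, tolerance = 1e-6)
  expect_equal(pitch_from_twist(360, 55), 55)
  expect_equal(pitch_from_twist(-98, 23.7), pitch_from_twist(98, 23.7))
  expect_error(pitch_from_twist(0.2, 50),
               class = "ribbonhelix_flat_ribbon_error")
})

test_that("twist profiles summarise replicate runs", {
  frame <- build_ribbon(6, 8)
  prof <- twist_profile(rep(list(frame), 6), n_runs = 2)
  smry <- attr(prof, "summary")
  expect_equal(nrow(smry), 3)
  expect_true(all(abs(smry$mean_theta) < 1e-8))
  expect_true(all(smry$sd_theta == 0))
  # single run: sd flagged as NA
  one <- twist_profile(list(frame, frame), n_runs = 1)
  expect_true(all(is.na(attr(one, "summary")$sd_theta)))
  expect_true(attr(one, "single_run"))
  expect_error(twist_profile(rep(list(frame), 5), n_runs = 2),
               class = "ribbonhelix_shape_error")
})

test_that("frames built from a relaxation series reproduce its plateau", {
  lat <- ribbon_lattice()
  L <- 5 * lat$residues_per_chain * lat$residue_spacing
  thetas <- 98 * (1 - exp(-(1:8) / 2))
  frames <- lapply(rep(thetas, 2), function(th) {
    build_ribbon(6, 6, pitch_nm = 360 * L / th)
  })
  prof <- twist_profile(frames, n_runs = 2, times = 1:8)
  smry <- attr(prof, "summary")
  expect_equal(smry$mean_theta, thetas, tolerance = 0.01)
  expect_true(all(smry$sd_theta < 1e-8))
})
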