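test_that("in-field entrance dose matches the fitted lines", {
  # MV: 6.63 + 0.926*FS + 0.5*FS*TF; cobalt: 12.9 + 1.85*FS
  expect_equal(as.numeric(entrance_infield("megavoltage", 30, tray = TRUE)),
               6.63 + 0.926 * 30 + 0.5 * 30)
  expect_equal(report_round(entrance_infield("megavoltage", 30, tray = TRUE)),
               49)
  expect_equal(as.numeric(entrance_infield("cobalt", 15, tray = TRUE)),
               12.9 + 1.85 * 15)
  expect_equal(report_round(entrance_infield("cobalt", 15, tray = TRUE)), 41)
  # the intercept is the small-field limit
  expect_equal(as.numeric(entrance_infield("megavoltage", 1e-9)), 6.63,
               tolerance = 1e-6)
  expect_error(entrance_infield("megavoltage", 0),
               class = "skindose_invalid_geometry")
  expect_warning(entrance_infield("megavoltage", 45), "outside the fitted")
})

test_that("beam class aliases map nominal energies to the two classes", {
  expect_equal(beam_class("6MV"), "megavoltage")
  expect_equal(beam_class("18 mv"), "megavoltage")
  expect_equal(beam_class("Co-60"), "cobalt")
  expect_error(beam_class("protons"), class = "skindose_invalid_input")
})

test_that("near-field dose matches the fitted lines and clamps at zero", {
  expect_equal(as.numeric(nearfield_2cm("megavoltage", 30, tray = TRUE)),
               -0.686 + 0.557 * 30 + 0.27 * 30)
  expect_equal(report_round(nearfield_2cm("megavoltage", 30, tray = TRUE)),
               24)
  expect_equal(as.numeric(nearfield_2cm("cobalt", 15)), -1.17 + 0.894 * 15)
  expect_equal(report_round(nearfield_2cm("cobalt", 15)), 12)
  # negative prediction for a 1 cm field clamps to zero and is flagged
  small <- nearfield_2cm("megavoltage", 1)
  expect_equal(as.numeric(small), 0)
  expect_true(attr(small, "clamped"))
})

test_that("under-block entrance dose equals the 2-cm-outside dose", {
  for (beam in c("megavoltage", "cobalt")) {
    for (fs in c(5, 15, 30)) {
      expect_equal(
        as.numeric(under_block_entrance(beam, fs, tray = TRUE)),
        as.numeric(nearfield_2cm(beam, fs, tray = TRUE))
      )
    }
  }
  # independent check against the literature cross-check value (~20%)
  expect_equal(as.numeric(under_block_entrance("megavoltage", 25,
                                               tray = TRUE)),
               -0.686 + 0.557 * 25 + 0.27 * 25)
  expect_equal(report_round(under_block_entrance("megavoltage", 25,
                                                 tray = TRUE)), 20)
})

test_that("entrance rules are strictly increasing in field size", {
  fs <- seq(1, 40, by = 0.5)
  for (beam in c("megavoltage", "cobalt")) {
    for (tray in c(FALSE, TRUE)) {
      infield <- as.numeric(entrance_infield(beam, fs, tray = tray))
      expect_true(all(diff(infield) > 0))
      near <- as.numeric(nearfield_2cm(beam, fs, tray = tray))
      # strictly increasing once off the zero clamp
      pos <- near > 0
      expect_true(all(diff(near[pos]) > 0))
    }
  }
})

test_that("tray raises MV doses for every field size but never cobalt", {
  fs <- seq(0.5, 40, by = 0.5)
  expect_true(all(entrance_infield("megavoltage", fs, tray = TRUE) >
                    entrance_infield("megavoltage", fs, tray = FALSE)))
  expect_true(all(nearfield_2cm("megavoltage", fs, tray = TRUE) >=
                    nearfield_2cm("megavoltage", fs, tray = FALSE)))
  expect_equal(as.numeric(entrance_infield("cobalt", fs, tray = TRUE)),
               as.numeric(entrance_infield("cobalt", fs, tray = FALSE)))
  expect_equal(as.numeric(nearfield_2cm("cobalt", fs, tray = TRUE)),
               as.numeric(nearfield_2cm("cobalt", fs, tray = FALSE)))
})

test_that("surface-to-depth ratio follows both formulas with the 12 cm clamp", {
  # MV: (FS+10)(x/150) + FS/100 + 1; cobalt: FS*x/85 + (FS-3)/10 + 1
  expect_equal(surface_to_depth_ratio("megavoltage", 40, 12), 5.4)
  expect_equal(surface_to_depth_ratio("megavoltage", 40, 30), 5.4) # clamped
  expect_equal(surface_to_depth_ratio("megavoltage", 5, 12), 2.25)
  expect_equal(surface_to_depth_ratio("cobalt", 15, 10),
               15 * 10 / 85 + (15 - 3) / 10 + 1)
  expect_equal(surface_to_depth_ratio("cobalt", 5, 12),
               5 * 12 / 85 + 0.2 + 1)
})

test_that("surface-to-depth ratio is >= 1, monotone, and constant past 12 cm", {
  set.seed(7)
  for (i in 1:100) {
    beam <- sample(c("megavoltage", "cobalt"), 1)
    fs <- runif(1, 0.5, 40)
    d <- sort(runif(8, 0, 25))
    r <- surface_to_depth_ratio(beam, fs, d)
    expect_true(all(r >= 1))
    expect_true(all(diff(r) >= -1e-12))
    expect_equal(surface_to_depth_ratio(beam, fs, 12),
                 surface_to_depth_ratio(beam, fs, 40))
  }
  # non-decreasing in field size too
  fs <- seq(1, 40, by = 1)
  expect_true(all(diff(surface_to_depth_ratio("megavoltage", fs, 8)) > 0))
  expect_true(all(diff(surface_to_depth_ratio("cobalt", fs, 8)) > 0))
})

test_that("far-field surface dose scales the dose at depth by the ratio", {
  expect_equal(as.numeric(farfield_surface("cobalt", 15, 10, 2.0)),
               surface_to_depth_ratio("cobalt", 15, 10) * 2.0)
  expect_equal(report_round(farfield_surface("cobalt", 15, 10, 2.0)), 7.9)
  expect_equal(as.numeric(farfield_surface("megavoltage", 30, 15, 1.0)),
               4.5)
  expect_equal(as.numeric(farfield_surface("megavoltage", 12, 20, 0)), 0)
  expect_error(farfield_surface("cobalt", 15, 2, 1.0),
               class = "skindose_wrong_rule")
})

test_that("exit surface dose is PDD scaled by the backscatter deficit", {
  expect_equal(exit_surface(100), 85)
  expect_equal(exit_surface(0), 0)
  expect_equal(exit_surface(46), 39.1)
  expect_error(exit_surface(120), class = "skindose_invalid_input")
  # property: never exceeds the PDD itself
  p <- seq(0, 100, by = 2.5)
  expect_true(all(exit_surface(p) <= p))
})

test_that("exit dose under a block combines transmission and deficit", {
  expect_equal(exit_under_block(), 6.8)
  expect_equal(exit_under_block(model_coefficients(block_transmission = 0.10)),
               8.5)
})

test_that("tangential dose is a flat 65% for both beam classes", {
  expect_equal(tangential_dose(), 65)
  expect_equal(tangential_dose(model_coefficients(tangential_fraction = 60)),
               60)
})

test_that("diverged-edge exit dose is half the in-field exit dose", {
  expect_equal(exit_edge_divergence(100), 42.5)
  expect_equal(exit_edge_divergence(0), 0)
  p <- seq(0, 100, by = 10)
  expect_equal(exit_edge_divergence(p), 0.5 * exit_surface(p))
})

test_that("cobalt tray-separation power law matches direct evaluation", {
  expect_equal(cobalt_tray_separation_dose(1, 1), 0.25)
  expect_equal(cobalt_tray_separation_dose(16, 1),
               0.25 * 16^(-0.44) * 1^(0.72))
  expect_equal(cobalt_tray_separation_dose(16, 1), 0.0738, tolerance = 1e-3)
  # monotone decreasing in separation, increasing in field radius
  h <- seq(1, 40, by = 1)
  expect_true(all(diff(cobalt_tray_separation_dose(h, 5)) < 0))
  r <- seq(1, 20, by = 1)
  expect_true(all(diff(cobalt_tray_separation_dose(10, r)) > 0))
  expect_lt(cobalt_tray_separation_dose(1e6, 5), 1e-2)
  expect_error(cobalt_tray_separation_dose(0, 1),
               class = "skindose_invalid_input")
})

test_that("edge interpolation joins the in-field and 2-cm anchors linearly", {
  a0 <- edge_interpolate("megavoltage", 30, tray = TRUE, distance = 0)
  a2 <- edge_interpolate("megavoltage", 30, tray = TRUE, distance = 2)
  expect_equal(as.numeric(a0),
               as.numeric(entrance_infield("megavoltage", 30, tray = TRUE)))
  expect_equal(as.numeric(a2),
               as.numeric(nearfield_2cm("megavoltage", 30, tray = TRUE)))
  mid <- edge_interpolate("megavoltage", 30, tray = TRUE, distance = 1)
  expect_equal(as.numeric(mid), (49.41 + 24.124) / 2)
  expect_error(edge_interpolate("megavoltage", 30, distance = 3),
               class = "skindose_wrong_rule")
})

test_that("all percent outputs stay within [0, 100]", {
  set.seed(11)
  for (i in 1:200) {
    beam <- sample(c("megavoltage", "cobalt"), 1)
    fs <- runif(1, 0.5, 40)
    tray <- sample(c(TRUE, FALSE), 1)
    vals <- c(
      entrance_infield(beam, fs, tray = tray),
      nearfield_2cm(beam, fs, tray = tray),
      edge_interpolate(beam, fs, tray = tray, distance = runif(1, 0, 2)),
      farfield_surface(beam, fs, runif(1, 2.1, 30), runif(1, 0, 5)),
      exit_surface(runif(1, 0, 100)),
      exit_under_block(),
      tangential_dose()
    )
    expect_true(all(vals >= 0 & vals <= 100))
  }
})

test_that("doses above 100% of Dmax are capped with a warning", {
  expect_warning(
    capped <- farfield_surface("megavoltage", 40, 12, dose_at_depth = 30),
    "capped"
  )
  expect_equal(as.numeric(capped), 100)
  expect_true(any(attr(capped, "clamped")))
})

test_that("coefficient overrides propagate and invalid ones are rejected", {
  co <- model_coefficients(mv_infield_intercept = 10, mv_infield_slope = 1)
  expect_equal(as.numeric(entrance_infield("megavoltage", 10, coeffs = co)),
               20)
  expect_error(model_coefficients(nonsense = 1),
               class = "skindose_config_error")
  expect_error(model_coefficients(block_transmission = 1.5),
               class = "skindose_config_error")
  expect_error(model_coefficients(exit_backscatter_deficit = 0),
               class = "skindose_config_error")
})
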