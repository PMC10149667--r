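test_that("canonical phantom encodes its nominal angles exactly", {
  lm <- canonical_phantom()
  expect_equal(femoral_torsion(lm, "NBC"), 21.5, tolerance = 1e-12)
  expect_equal(femoral_torsion(lm, "NC"), 21.5, tolerance = 1e-12)

  # explicit dot-product oracle for the 135 degree neck inclination
  p <- lm[lm$landmark %in% c("FHC", "FNBC"), ]
  neck <- unlist(p[p$landmark == "FHC", c("x_mm", "y_mm", "z_mm")]) -
    unlist(p[p$landmark == "FNBC", c("x_mm", "y_mm", "z_mm")])
  distal <- c(0, 0, -1)
  ang <- acos(sum(neck * distal) / sqrt(sum(neck^2))) * 180 / pi
  expect_equal(ang, 135, tolerance = 1e-9)
  expect_equal(femoral_inclination(lm, "NBC"), 135, tolerance = 1e-9)

  # zero-torsion phantom: neck has no cranial deviation, FHC stays in the
  # plane spanned by the long axis and the retrocondylar axis
  lm0 <- canonical_phantom(nominal_antetorsion_deg = 0)
  expect_equal(femoral_torsion(lm0, "NBC"), 0, tolerance = 1e-12)
  fhc <- unlist(lm0[lm0$landmark == "FHC", c("x_mm", "y_mm", "z_mm")])
  expect_equal(unname(fhc[2]), 0, tolerance = 1e-12)  # no cranial part
})

test_that("degenerate phantom specs are rejected", {
  expect_error(phantom_spec(neck_length = 0), "invalid phantom spec")
  expect_error(phantom_spec(hinge_level_fraction = 1), "hinge_level_fraction")
  expect_error(phantom_spec(nominal_inclination_deg = 90), "inclination")
})

test_that("hinge rotation adds exactly to torsion and composes as inverse", {
  lm <- canonical_phantom()
  expect_equal(femoral_torsion(apply_hinge(lm, -90), "NBC"), -68.5,
               tolerance = 1e-9)
  expect_equal(apply_hinge(lm, 0), lm)
  back <- apply_hinge(apply_hinge(lm, 40), -40)
  expect_equal(back$x_mm, lm$x_mm, tolerance = 1e-9)
  expect_equal(back$y_mm, lm$y_mm, tolerance = 1e-9)
  expect_equal(back$z_mm, lm$z_mm, tolerance = 1e-9)
})

test_that("rigid poses change coordinates but not angles", {
  lm <- canonical_phantom(hinge_angle_deg = 15)
  expect_equal(apply_pose(lm), lm)  # identity pose

  posed <- apply_pose(lm, random_rotation(11), c(100, -50, 30))
  expect_lt(max(abs(six_angles(posed) - six_angles(lm))), 1e-6)

  shifted <- apply_pose(lm, diag(3), c(100, -50, 30))
  expect_equal(six_angles(shifted), six_angles(lm), tolerance = 1e-12)

  expect_error(apply_pose(lm, matrix(1, 3, 3)), "invalid transform")
  refl <- diag(c(-1, 1, 1))
  expect_error(apply_pose(lm, refl), "invalid transform")  # det = -1
})

test_that("head surface sampling respects radius, cap and seed", {
  spec <- phantom_spec()
  pts <- sample_head_surface(spec, 200, noise_sigma_mm = 0, seed = 1)
  lm <- canonical_phantom()
  fhc <- unlist(lm[lm$landmark == "FHC", c("x_mm", "y_mm", "z_mm")])
  d <- sqrt((pts$x - fhc[1])^2 + (pts$y - fhc[2])^2 + (pts$z - fhc[3])^2)
  expect_equal(d, rep(spec$head_radius, 200), tolerance = 1e-9)

  expect_equal(sample_head_surface(spec, 50, seed = 4),
               sample_head_surface(spec, 50, seed = 4))
  expect_error(sample_head_surface(spec, 3), "at least 4")
})

test_that("observer perturbation is seed-reproducible with chi-mean noise", {
  lm <- canonical_phantom()
  expect_equal(perturb_observer(lm, 0, seed = 1), lm)
  expect_equal(perturb_observer(lm, 0.5, seed = 9),
               perturb_observer(lm, 0.5, seed = 9))

  # Monte-Carlo mean displacement vs chi(3) closed form: sigma * 2 sqrt(2/pi)
  sigma <- 0.5
  disp <- vapply(1:1000, function(i) {
    p <- perturb_observer(lm, sigma, seed = i)
    mean(sqrt((p$x_mm - lm$x_mm)^2 + (p$y_mm - lm$y_mm)^2 +
                (p$z_mm - lm$z_mm)^2))
  }, numeric(1))
  expect_equal(mean(disp), sigma * 2 * sqrt(2 / pi), tolerance = 0.02)
})

test_that("goniometer model rounds half away from zero and recovers bias", {
  g0 <- goniometer_model()
  expect_equal(simulate_goniometer(21.4, g0), 21)
  expect_equal(simulate_goniometer(-68.5, g0), -69)
  expect_equal(simulate_goniometer(68.5, g0), 69)

  g <- goniometer_model(alignment_bias_deg = -2.1, reading_sigma_deg = 0.5)
  readings <- simulate_goniometer(rep(37.2, 10000), g, seed = 2)
  expect_equal(mean(readings), 37.2 - 2.1, tolerance = 0.05)
})

test_that("cohort simulation has the observer/session structure and is deterministic", {
  spec <- cohort_spec(n_dogs = 5, seed = 42)
  co <- simulate_cohort(spec)
  expect_equal(nrow(co), 5 * 2 * 3)
  expect_equal(sort(unique(paste(co$observer, co$session))),
               c("O1 1", "O1 2", "O2 1"))
  expect_equal(simulate_cohort(spec), co)

  # zero noise on every route: duplicate sessions identical, CVs exactly 0
  quiet <- simulate_cohort(cohort_spec(n_dogs = 3, observer_sigma_mm = 0,
                                       seed = 1))
  left <- quiet[quiet$side == "left" & quiet$observer == "O1", ]
  cv <- cv_repeated(left, specimen_id, fta_nbc)
  expect_equal(cv$cv_percent, 0)
  expect_equal(cv$rating, "excellent")
})
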