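test_that("sphere fit recovers exact spheres", {
  # 100 exact points on a known sphere
  set.seed(1)
  dirs <- matrix(rnorm(300), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- tibble::tibble(x = 1 + 5 * dirs[, 1], y = 2 + 5 * dirs[, 2],
                        z = 3 + 5 * dirs[, 3])
  fit <- fit_sphere(pts)
  expect_equal(fit$center, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(fit$radius, 5, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9)

  # 4 non-degenerate points: the unique circumsphere
  tet <- tibble::tibble(x = c(1, -1, 0, 0), y = c(0, 0, 1, -1),
                        z = c(0.5, 0.5, -0.5, -0.5))
  fit4 <- fit_sphere(tet)
  expect_lt(fit4$rms_residual, 1e-9)
  expect_equal(fit4$center, c(0, 0, 0), tolerance = 1e-9)

  expect_error(fit_sphere(tet[1:3, ]), "at least 4")
  flat <- tibble::tibble(x = rnorm(10), y = rnorm(10), z = 0)
  expect_error(fit_sphere(flat), "degenerate")
})

test_that("noisy-cap sphere fit matches the nonlinear oracle and the truth", {
  spec <- phantom_spec()
  pts <- sample_head_surface(spec, 500, cap_halfangle_deg = 60,
                             noise_sigma_mm = 0.2, seed = 33)
  fit <- fit_sphere(pts)
  lm <- canonical_phantom()
  fhc <- unlist(lm[lm$landmark == "FHC", c("x_mm", "y_mm", "z_mm")])
  expect_lt(sqrt(sum((fit$center - fhc)^2)), 0.1)

  oracle <- sphere_oracle(pts)
  expect_lt(sqrt(sum((fit$center - oracle$center)^2)), 1e-6)
  expect_equal(fit$radius, oracle$radius, tolerance = 1e-6)
})

test_that("sphere fit is rigid-equivariant and consistent in n", {
  pts <- sample_head_surface(phantom_spec(), 200, noise_sigma_mm = 0.3,
                             seed = 5)
  fit <- fit_sphere(pts)
  R <- random_rotation(8); t <- c(12, -7, 40)
  P2 <- as.matrix(pts) %*% t(R) + matrix(t, nrow(pts), 3, byrow = TRUE)
  fit2 <- fit_sphere(tibble::tibble(x = P2[, 1], y = P2[, 2], z = P2[, 3]))
  expect_equal(fit2$center, as.numeric(R %*% fit$center + t),
               tolerance = 1e-9)
  expect_equal(fit2$radius, fit$radius, tolerance = 1e-9)

  lm <- canonical_phantom()
  fhc <- unlist(lm[lm$landmark == "FHC", c("x_mm", "y_mm", "z_mm")])
  med_err <- vapply(c(50, 500, 5000), function(n) {
    errs <- vapply(1:50, function(s) {
      f <- fit_sphere(sample_head_surface(phantom_spec(), n,
                                          noise_sigma_mm = 0.2,
                                          seed = 1000 + s))
      sqrt(sum((f$center - fhc)^2))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("longitudinal axis variants agree on a straight shaft and detect a bend", {
  lm <- canonical_phantom()
  for (v in c("pd", "dd", "td")) {
    ax <- longitudinal_axis(lm, v)
    expect_equal(ax$direction, c(0, 0, 1), tolerance = 1e-12)
  }

  # orientation independent of point labels: swap PS1/PS2
  sw <- lm
  sw$landmark[sw$landmark %in% c("PS1", "PS2")] <-
    rev(sw$landmark[sw$landmark %in% c("PS1", "PS2")])
  expect_equal(longitudinal_axis(sw, "pd")$direction,
               longitudinal_axis(lm, "pd")$direction, tolerance = 1e-12)

  # a 10 degree diaphyseal bend separates pd and dd by exactly 10 degrees
  bent <- canonical_phantom(shaft_bend_deg = 10)
  pd <- longitudinal_axis(bent, "pd")$direction
  dd <- longitudinal_axis(bent, "dd")$direction
  expect_equal(acos(sum(pd * dd)) * 180 / pi, 10, tolerance = 1e-9)

  no_ps <- lm[lm$landmark != "PS1", ]
  expect_error(longitudinal_axis(no_ps, "pd"), "PS1")
})

test_that("bone frame is orthonormal, canonical-aligned and pose-equivariant", {
  lm <- canonical_phantom()
  fr <- build_bone_frame(lm)
  B <- rbind(fr$L, fr$M, fr$C)
  expect_lt(max(abs(B %*% t(B) - diag(3))), 1e-12)
  expect_equal(fr$L, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$M, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$C, c(0, 1, 0), tolerance = 1e-12)

  R <- random_rotation(21); t <- c(-30, 8, 95)
  fr2 <- build_bone_frame(apply_pose(lm, R, t))
  expect_equal(fr2$L, as.numeric(R %*% fr$L), tolerance = 1e-9)
  expect_equal(fr2$M, as.numeric(R %*% fr$M), tolerance = 1e-9)
  expect_equal(fr2$C, as.numeric(R %*% fr$C), tolerance = 1e-9)
  expect_equal(fr2$origin, as.numeric(R %*% fr$origin + t),
               tolerance = 1e-9)

  # cranial axis points cranially on both sides (canonical +y)
  frR <- build_bone_frame(canonical_phantom(side = "right"))
  expect_equal(frR$C, c(0, 1, 0), tolerance = 1e-12)

  # frames for noisy landmarks stay orthonormal
  for (s in 1:20) {
    frn <- build_bone_frame(perturb_observer(lm, 0.5, seed = s))
    Bn <- rbind(frn$L, frn$M, frn$C)
    expect_lt(max(abs(Bn %*% t(Bn) - diag(3))), 1e-12)
  }
})
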