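# Synthetic femur generator: construction invariants, angle recovery by
# construction, sphere fitting, anatomical frame.

test_that("generated femurs satisfy construction invariants across parameter sets", {
  params <- list(
    femur_params(target_edge_length = 8),
    femur_params(target_edge_length = 8, neck_shaft_angle_deg = 135,
                 anteversion_deg = 0),
    femur_params(target_edge_length = 8, neck_shaft_angle_deg = 120,
                 anteversion_deg = 30, femur_length = 380)
  )
  for (p in params) {
    m <- generate_femur(p)
    expect_true(validate_model(m))
    expect_gt(min(tet_volumes(m$nodes, m$tets)), 0)
    expect_equal(measure_nsa(m), p$neck_shaft_angle_deg, tolerance = 0.5 / 120)
    expect_equal(measure_ava(m), p$anteversion_deg, tolerance = 0.5,
                 ignore_attr = TRUE)
    # boundary surface is a closed 2-manifold
    expect_equal(euler_characteristic(m$boundary_faces), 2)
  }
})

test_that("generation is deterministic given the seed", {
  a <- generate_femur(femur_params(target_edge_length = 9, rng_seed = 7L))
  b <- generate_femur(femur_params(target_edge_length = 9, rng_seed = 7L))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$element_gv, b$element_gv)
  c_ <- generate_femur(femur_params(target_edge_length = 9, rng_seed = 8L))
  expect_false(identical(a$element_gv, c_$element_gv))
})

test_that("halving the target edge length grows the element count about 8-fold", {
  m1 <- generate_femur(femur_params(target_edge_length = 6))
  m2 <- generate_femur(femur_params(target_edge_length = 3))
  ratio <- nrow(m2$tets) / nrow(m1$tets)
  expect_gt(ratio, 8 * 0.7)
  expect_lt(ratio, 8 * 1.3)
})

test_that("infeasible parameters are rejected at construction", {
  expect_error(femur_params(neck_length = 20, head_radius = 22), "infeasible")
  expect_error(femur_params(neck_shaft_angle_deg = 80), "90")
  expect_error(femur_params(anteversion_deg = 75), "-30")
  expect_error(femur_params(femur_length = -5), "positive")
})

test_that("sphere fit recovers exact, noisy, and hemispherical samples", {
  set.seed(42)
  ctr <- c(10, -4, 3); R <- 24
  dirs <- matrix(rnorm(600), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(dirs * R, 2, ctr, `+`)
  fit <- fit_head_sphere(pts)
  expect_equal(fit$radius, R, tolerance = 1e-9)
  expect_equal(fit$center, ctr, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9)

  # isotropic noise sigma = 0.1 mm: centre recovered within 0.05 mm
  noisy <- pts + matrix(rnorm(600, sd = 0.1), ncol = 3)
  fitn <- fit_head_sphere(noisy)
  expect_lt(sqrt(sum((fitn$center - ctr)^2)), 0.05)

  # hemisphere coverage only
  hemi <- pts[dirs[, 3] > 0, ]
  fith <- fit_head_sphere(hemi)
  expect_lt(sqrt(sum((fith$center - ctr)^2)), 0.5)

  # coplanar points are a singular fit
  flat <- cbind(matrix(rnorm(60), ncol = 2), 0)
  expect_error(fit_head_sphere(flat), "singular|coplanar")
})

test_that("head patch of a generated femur lies on the nominal sphere", {
  m <- coarse_femur()
  fit <- fit_head_sphere(m)
  expect_equal(fit$radius, m$params$head_radius, tolerance = 1e-6)
  expect_lt(sqrt(sum((fit$center - m$landmarks$head_center)^2)), 1e-6)
})

test_that("anatomical frame is orthonormal, right-handed and equivariant", {
  lms <- list(head_center = c(0, 0, 400), knee_center = c(0, 0, 0),
              lateral_epicondyle = c(40, 0, 0))
  fr <- build_frame(lms)
  expect_equal(fr$si, c(0, 0, 1))
  expect_equal(fr$ml, c(1, 0, 0))
  expect_equal(fr$ap, c(0, -1, 0))   # ap = ml x si (right-handed)

  set.seed(1)
  for (rep in 1:5) {
    lr <- list(head_center = rnorm(3, sd = 100),
               knee_center = rnorm(3, sd = 100),
               lateral_epicondyle = rnorm(3, sd = 100))
    fr <- tryCatch(build_frame(lr), error = function(e) NULL)
    if (is.null(fr)) next
    M <- rbind(fr$si, fr$ml, fr$ap)
    expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-12)
    # rigid rotation of the landmarks rotates the axes by exactly that rotation
    Rm <- rotation_about_axis(rnorm(3), runif(1, 0, pi))
    lrot <- lapply(lr, function(p) as.numeric(Rm %*% p))
    fr2 <- build_frame(lrot)
    expect_equal(fr2$si, as.numeric(Rm %*% fr$si), tolerance = 1e-12)
    expect_equal(fr2$ml, as.numeric(Rm %*% fr$ml), tolerance = 1e-12)
    expect_equal(fr2$ap, as.numeric(Rm %*% fr$ap), tolerance = 1e-12)
  }
  expect_error(build_frame(list(head_center = c(0, 0, 1), knee_center = c(0, 0, 0),
                                lateral_epicondyle = c(0, 0, 2))),
               "degenerate|collinear")
})

test_that("frame of a generated femur aligns with the head-knee line", {
  m <- coarse_femur()
  mech <- m$landmarks$head_center - m$landmarks$knee_center
  ang <- acos(sum(m$frame$si * mech / sqrt(sum(mech^2)))) * 180 / pi
  expect_lt(ang, 0.5)
})
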