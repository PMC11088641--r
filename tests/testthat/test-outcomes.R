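# Outcome measures: head deflection, guarded peak stress, strain paths, and
# the comparison statistics.

test_that("R^2 and nRMSE match hand computations and their edge cases", {
  ref <- c(0, 1, 2, 3)
  expect_equal(r_squared(ref, ref), 1)
  # SS_res = 4, SS_tot = 5
  expect_equal(r_squared(c(1, 2, 3, 4), ref), 1 - 4 / 5)
  expect_equal(r_squared(rep(mean(ref), 4), ref), 0)
  expect_warning(rc <- r_squared(ref, rep(2, 4)), "constant")
  expect_true(is.nan(rc))

  expect_equal(nrmse(ref, ref), 0)
  expect_equal(nrmse(ref + 1, ref), 1 / 3)
  expect_warning(nc <- nrmse(ref, rep(1, 4)), "dynamic range")
  expect_true(is.nan(nc))
  # scale invariance
  s <- c(2, 5, 1, 7); r <- c(1, 4, 2, 6)
  expect_equal(nrmse(3 * s, 3 * r), nrmse(s, r))
})

test_that("head deflection is a relative measure resolved in the local frame", {
  m <- coarse_femur()
  N <- nrow(m$nodes)
  # rigid translation: zero FHD
  U <- matrix(rep(c(3, -2, 5), N), ncol = 1)
  fhd <- femoral_head_deflection(m, U)
  expect_lt(max(abs(c(fhd$fhd_si, fhd$fhd_ml, fhd$fhd_ap))), 1e-9)

  # pure SI field: u_si grows linearly from knee (0) to head (-0.5 mm)
  t_head <- sum((m$landmarks$head_center - m$landmarks$knee_center) * m$frame$si)
  coord <- as.numeric(sweep(m$nodes, 2, m$landmarks$knee_center) %*% m$frame$si)
  U2 <- as.numeric(t(outer(-0.5 * coord / t_head, m$frame$si)))
  fhd2 <- femoral_head_deflection(m, matrix(U2, ncol = 1))
  expect_equal(fhd2$fhd_si, -0.5, tolerance = 1e-6)
  expect_equal(fhd2$fhd_resultant, 0.5, tolerance = 1e-6)
  expect_equal(fhd2$fhd_resultant^2,
               fhd2$fhd_si^2 + fhd2$fhd_ml^2 + fhd2$fhd_ap^2, tolerance = 1e-9)
})

test_that("peak stress guard excludes only artefact zones", {
  bf <- beam_fixture(24, 4, 4)
  res <- solve_static(bf$system, clamp_constraints(bf$fixed),
                      tip_load_vector(bf))
  flds <- recover_fields(bf$system, res$U)
  mesh <- bf$mesh
  mesh$attachment_patches <- list(tip = list(refpoint = c(100, 5, 5),
                                             nodes = bf$tip))
  cons <- clamp_constraints(bf$fixed)
  cons$method <- "clamp"
  p0 <- peak_von_mises(mesh, flds, cons, exclusion_radius = 0)
  p5 <- peak_von_mises(mesh, flds, cons, exclusion_radius = 5)
  expect_lte(p5, p0)
  # interior maximum: guarded peak equals the max over elements away from ends
  ctr <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
            mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  interior <- ctr[, 1] > 6 & ctr[, 1] < 94
  expect_equal(p5, max(flds$von_mises[interior, 1]), tolerance = 0.2)
  # uniform field: the guard does not change a constant maximum
  Uu <- as.numeric(t(cbind(mesh$nodes[, 1] * 1e-3, 0, 0)))
  fu <- recover_fields(bf$system, Uu)
  expect_equal(peak_von_mises(mesh, fu, cons, 5),
               peak_von_mises(mesh, fu, cons, 0), tolerance = 1e-9)
})

test_that("cortical strain paths recover beam bending strain", {
  bf <- beam_fixture(60, 6, 6)
  res <- solve_static(bf$system, clamp_constraints(bf$fixed),
                      tip_load_vector(bf))
  flds <- recover_fields(bf$system, res$U)
  mesh <- bf$mesh
  surf <- mesh$surface_nodes
  top <- surf[mesh$nodes[surf, 3] > 10 - 1e-9 &
                abs(mesh$nodes[surf, 2] - 5) < 1]
  top <- top[order(mesh$nodes[top, 1])]
  mesh$strain_paths <- list(tension = top)
  sp <- cortical_strain_paths(mesh, flds)
  # at x = 50: M = 100 * 50 N mm, c = 5 mm, I = 833.33 -> 3000 ue with E = 1e4
  xs <- mesh$nodes[top, 1]
  i50 <- which.min(abs(xs - 50))
  expect_equal(sp$tension$abs_ue[i50, 1], 3000, tolerance = 0.10)
  # tension side is positive in the signed variant
  expect_gt(sp$tension$signed_ue[i50, 1], 0)
  # zero load -> zero strain everywhere on the path
  sp0 <- cortical_strain_paths(mesh, recover_fields(bf$system, 0 * res$U))
  expect_equal(max(abs(sp0$tension$abs_ue)), 0)
})

test_that("comparison report covers every geometry and non-benchmark method", {
  fake_series <- function(shift) {
    structure(list(method = "x",
                   fhd = data.frame(instance = 1:7, fhd_si = 1:7 + shift,
                                    fhd_ml = (1:7) / 2 + shift,
                                    fhd_ap = (1:7) / 3,
                                    fhd_resultant = 1:7),
                   pvms = (1:7) * 2 + shift,
                   strain_paths = list()), class = "outcome_series")
  }
  outcomes <- list(
    geomA = list(inertia_relief = fake_series(0), m1 = fake_series(1),
                 m2 = fake_series(0)),
    geomB = list(inertia_relief = fake_series(0), m1 = fake_series(2),
                 m2 = fake_series(0.5))
  )
  rep <- compare_report(outcomes)
  expect_equal(nrow(rep), 2 * 2 * 5)   # geometries x methods x metrics
  # a method identical to the benchmark scores R^2 = 1, nRMSE = 0
  sub <- rep[rep$geometry == "geomA" & rep$method == "m2", ]
  expect_true(all(sub$r_squared == 1))
  expect_true(all(sub$nrmse == 0))
  # the benchmark itself is not compared
  expect_false("inertia_relief" %in% rep$method)
  expect_error(compare_report(list(g = list(m1 = fake_series(1)))),
               "inertia_relief")
})
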