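# Constraint-set builders: DoF counts, load-inclusion rules, constraint
# satisfaction, spring behaviour, slider kinematics.

test_that("constrained DoF counts match the method definitions", {
  m <- default_femur()
  expect_equal(constrained_dof_count(build_inertia_relief(m)), 0)
  expect_equal(constrained_dof_count(build_isostatic(m)), 6)
  expect_equal(constrained_dof_count(build_mid_shaft(m)), 6)
  # knee 3 + slider 2 + greater trochanter 3 (via couplings)
  expect_equal(constrained_dof_count(build_biomechanical(m)), 8)
  fk <- build_fixed_knee(m)
  expect_equal(constrained_dof_count(fk) %% 3, 0)
  expect_gt(constrained_dof_count(fk), 6)
  sp <- build_springs(m)
  expect_equal(constrained_dof_count(sp), 0)
  expect_length(sp$springs, 3)
})

test_that("fixed-knee load rules omit tibiofemoral and patellofemoral contact", {
  m <- default_femur(); case <- default_case()
  fk <- build_fixed_knee(m)
  expect_false(fk$load_rules$tf)
  expect_false(fk$load_rules$pf)
  f_fk <- build_load_vectors(m, case, fk)
  f_ir <- build_load_vectors(m, case, build_inertia_relief(m))
  # the omitted tibiofemoral + patellofemoral resultants explain the difference
  for (k in c(2, 5)) {
    dnet <- net_force_moment(m$nodes, f_ir[, k] - f_fk[, k])$force
    cc <- case$contact[[k]]
    omitted <- as.numeric(transform_from_frame(cc$tibiofemoral_jcf, m$frame)) +
      as.numeric(transform_from_frame(cc$patellofemoral_jcf, m$frame))
    expect_equal(dnet, omitted, tolerance = 1e-9)
  }
})

test_that("every builder yields a solvable system under stance loads", {
  m <- default_femur(); mats <- default_materials(); case <- default_case()
  sys <- default_system()
  for (meth in METHOD_NAMES) {
    run <- run_method(m, mats, meth, case, system = sys)
    expect_true(all(run$result$residual < 1e-8), info = meth)
    expect_true(all(is.finite(run$result$U)), info = meth)
  }
})

test_that("isostatic constraints are satisfied and its SI variant is nearly singular", {
  m <- default_femur(); mats <- default_materials(); sys <- default_system()
  case <- default_case()
  cs <- build_isostatic(m)
  run <- run_method(m, mats, cs, case, system = sys)
  head_node <- cs$dirichlet[[4]]$node
  uh <- run$result$U[3 * (head_node - 1) + 1:3, ]
  # ML and AP components of the pinned head node vanish
  expect_lt(max(abs(m$frame$ml %*% uh)), 1e-10)
  expect_lt(max(abs(m$frame$ap %*% uh)), 1e-10)

  # pure couple about the mechanical axis: the SI-epicondyle variant barely
  # restrains axial rotation, the AP default does
  axis <- unit_vec(m$landmarks$head_center - m$landmarks$knee_center)
  gt <- m$landmarks$greater_trochanter_lateral
  arm <- gt - m$landmarks$knee_center
  tang <- unit_vec(cross3(axis, arm - sum(arm * axis) * axis))
  f <- numeric(sys$ndof)
  n_gt <- which.min(rowSums(sweep(m$nodes, 2, gt)^2))
  med_pt <- 2 * m$landmarks$knee_center + c(0, 0, sum(arm * axis)) - gt
  n_md <- which.min(rowSums(sweep(m$nodes, 2, m$landmarks$mid_diaphysis)^2))
  f[3 * (n_gt - 1) + 1:3] <- 100 * tang
  # opposite tangential force lower down for a couple-dominated load
  f[3 * (n_md - 1) + 1:3] <- -100 * tang
  u_ap <- solve_static(sys, build_isostatic(m, "ap"), f)$U
  u_si <- solve_static(sys, build_isostatic(m, "si"), f)$U
  expect_gt(max(abs(u_si)) / max(abs(u_ap)), 10)
})

test_that("mid-shaft constraints pin ML/AP but leave SI free at the diaphysis", {
  m <- default_femur(); mats <- default_materials(); sys <- default_system()
  cs <- build_mid_shaft(m)
  run <- run_method(m, mats, cs, default_case(), system = sys)
  mid_node <- cs$dirichlet[[5]]$node
  um <- run$result$U[3 * (mid_node - 1) + 1:3, ]
  expect_lt(max(abs(m$frame$ml %*% um)), 1e-10)
  expect_lt(max(abs(m$frame$ap %*% um)), 1e-10)
  expect_gt(max(abs(m$frame$si %*% um)), 1e-4)
})

test_that("biomechanical slider keeps p1 motion parallel to the p1-p3 axis", {
  m <- default_femur(); mats <- default_materials(); sys <- default_system()
  axis <- unit_vec(m$landmarks$head_center - m$landmarks$knee_center)
  for (variant in c("full", "axial")) {
    cs <- build_biomechanical(m, hip_transmission = variant)
    run <- run_method(m, mats, cs, default_case(), system = sys)
    p1 <- run$result$refpoint_u$p1
    for (k in seq_len(ncol(p1))) {
      cr <- cross3(p1[, k], axis)
      expect_lt(sqrt(sum(cr^2)), 1e-10)
    }
  }
})

test_that("axial hip routing reacts exactly the transverse hip components at the slider", {
  m <- default_femur(); mats <- default_materials(); sys <- default_system()
  case <- default_case()
  cs <- build_biomechanical(m, hip_transmission = "axial")
  run <- run_method(m, mats, cs, case, system = sys)
  lab <- run$result$reaction_labels
  t_rows <- grep("^slider:p1:t", lab)
  ax_row <- grep("^slider:p1:axial_link", lab)
  axis <- unit_vec(m$landmarks$head_center - m$landmarks$knee_center)
  for (k in c(1, 4, 7)) {
    Fh <- as.numeric(transform_from_frame(case$contact[[k]]$hip_jcf, m$frame))
    trans_mag <- sqrt(sum(Fh^2) - sum(Fh * axis)^2)
    react_mag <- sqrt(sum(run$result$lambda[t_rows, k]^2))
    expect_equal(react_mag, trans_mag, tolerance = 1e-8)
    # the axial component is transmitted, not reacted transversely
    expect_equal(abs(run$result$lambda[ax_row, k]), abs(sum(Fh * axis)),
                 tolerance = 1e-8)
  }
})

test_that("springs carry a small share of the applied load and stiffen toward a fixed knee", {
  m <- default_femur(); mats <- default_materials(); sys <- default_system()
  case <- default_case()
  cs <- build_springs(m)
  run <- run_method(m, mats, cs, case, system = sys)
  spring_nodes <- unique(unlist(lapply(cs$springs, `[[`, "nodes")))
  dof <- as.integer(t(outer(3L * (spring_nodes - 1L), 1:3, `+`)))
  for (k in seq_along(case$instances)) {
    # net grounded-spring reaction vs the summed magnitude of applied loads
    fx <- matrix(cs$springs[[1]]$k * run$result$U[dof, k], ncol = 3,
                 byrow = TRUE)
    reaction <- sqrt(sum(colSums(fx)^2))
    applied <- sum(vapply(case$forces[[k]], function(v) sqrt(sum(v^2)),
                          numeric(1))) +
      sum(vapply(case$contact[[k]], function(v) sqrt(sum(v^2)), numeric(1)))
    expect_lt(reaction / applied, 0.02)
  }
  expect_error(build_springs(m, k_per_node = 0), "positive")

  # stiff springs approach a fixed knee-band
  hard <- build_springs(m, k_per_node = 1e7)
  runh <- run_method(m, mats, hard, case, system = sys)
  knee_nodes <- hard$springs$knee$nodes
  dofk <- as.integer(t(outer(3L * (knee_nodes - 1L), 1:3, `+`)))
  expect_lt(max(abs(runh$result$U[dofk, ])), 1e-3)
})
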