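# Tetrahedral FE engine: element stiffness, assembly, couplings, static and
# inertia-relief solves, field recovery. Oracles are closed forms (beam
# theory, uniform stress states) and brute-force dense assembly.

test_that("element stiffness is symmetric PSD with exactly six rigid modes", {
  tc <- rbind(c(0, 0, 0), c(2, 0.1, 0), c(0.3, 1.7, 0.2), c(0.1, 0.4, 1.9))
  K <- element_stiffness(tc, E = 12000, nu = 0.3)
  expect_equal(K, t(K))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)
  expect_true(all(ev > -1e-8 * max(ev)))
  # rigid translation and small rigid rotation produce zero force
  u_t <- rep(c(1, 1, 1), 4)
  expect_lt(max(abs(K %*% u_t)), 1e-8 * max(abs(K)))
  omega <- c(0.2, -0.1, 0.3)
  u_r <- as.numeric(apply(tc, 1, function(x)
    c(omega[2] * x[3] - omega[3] * x[2],
      omega[3] * x[1] - omega[1] * x[3],
      omega[1] * x[2] - omega[2] * x[1])))
  expect_lt(max(abs(K %*% u_r)), 1e-7 * max(abs(K)))
  expect_error(element_stiffness(tc[c(1, 3, 2, 4), ], 1000, 0.3), "inverted")
  expect_error(element_stiffness(tc, 1000, 0.5), "Poisson")
})

test_that("patch test: an imposed linear field is recovered as exact constant strain", {
  bm <- generate_box_mesh(3, 2, 2, 3, 2, 2)
  sys <- assemble(bm, uniform_materials(bm, E = 5000, nu = 0.25))
  A <- rbind(c(2e-4, 1e-4, 0), c(5e-5, -1e-4, 2e-4), c(0, 3e-5, 1.5e-4))
  U <- as.numeric(t(bm$nodes %*% t(A)))
  f <- recover_fields(sys, U)
  exx <- A[1, 1]; eyy <- A[2, 2]; ezz <- A[3, 3]
  gxy <- A[1, 2] + A[2, 1]; gyz <- A[2, 3] + A[3, 2]; gxz <- A[1, 3] + A[3, 1]
  expected <- c(exx, eyy, ezz, gxy, gyz, gxz)
  for (j in 1:6) {
    expect_equal(unname(f$strain[, j, 1]),
                 rep(expected[j], nrow(bm$tets)), tolerance = 1e-10)
  }
})

test_that("sparse assembly matches brute-force dense assembly on a two-tet mesh", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  tets <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  v <- tet_volumes(nodes, tets)
  expect_true(all(v > 0))
  mesh <- list(nodes = nodes, tets = tets, element_gv = c(1500, 1800))
  mats <- bin_materials(mesh, 2)
  sys <- assemble(mesh, mats)
  pr <- element_properties(mats)
  Kd <- matrix(0, 15, 15)
  for (e in 1:2) {
    Ke <- element_stiffness(nodes[tets[e, ], ], pr$E[e], pr$nu[e])
    dof <- as.integer(t(outer(3 * (tets[e, ] - 1), 1:3, `+`)))
    Kd[dof, dof] <- Kd[dof, dof] + Ke
  }
  expect_equal(as.matrix(sys$K), Kd, tolerance = 1e-12, ignore_attr = TRUE)
  # lumped mass conserves total mass: sum(rho V) in tonnes
  expect_equal(sum(sys$mass) / 3, sum(pr$rho * 1e-9 * v), tolerance = 1e-12)
})

test_that("free stiffness of a small mesh has exactly six near-zero eigenvalues", {
  bm <- generate_box_mesh(2, 2, 2, 2, 2, 2)
  sys <- assemble(bm, uniform_materials(bm, E = 1000, nu = 0.3))
  ev <- eigen(as.matrix(sys$K), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6)
})

test_that("cantilever tip deflection approaches the beam closed form", {
  bf <- beam_fixture(80, 8, 8)
  res <- solve_static(bf$system, clamp_constraints(bf$fixed),
                      tip_load_vector(bf))
  tip <- mean(res$U[3 * (bf$tip - 1) + 3, 1])
  expect_lt(res$residual[1], 1e-8)
  # Euler-Bernoulli PL^3 / 3EI = 4.0 mm, within 7% at this refinement
  expect_equal(tip, -4.0, tolerance = 0.07)
})

test_that("static solutions are linear and superposable", {
  bf <- beam_fixture(24, 4, 4)
  cons <- clamp_constraints(bf$fixed)
  f1 <- tip_load_vector(bf, 100)
  f2 <- numeric(bf$system$ndof)
  mid <- which(abs(bf$mesh$nodes[, 1] - 50) < 3 & bf$mesh$nodes[, 3] > 9.9)
  f2[3 * (mid - 1) + 2] <- 40
  u1 <- solve_static(bf$system, cons, f1)$U
  u2 <- solve_static(bf$system, cons, f2)$U
  u12 <- solve_static(bf$system, cons, f1 + f2)$U
  expect_equal(u12, u1 + u2, tolerance = 1e-9)
  expect_equal(max(abs(solve_static(bf$system, cons, 0 * f1)$U)), 0)
  # doubling E halves displacements
  sys2 <- assemble(bf$mesh, uniform_materials(bf$mesh, E = 2e4, nu = 0))
  expect_equal(solve_static(sys2, cons, f1)$U, u1 / 2, tolerance = 1e-9)
})

test_that("unconstrained static systems are refused", {
  bf <- beam_fixture(8, 2, 2)
  cons <- clamp_constraints(integer(0))
  expect_error(solve_static(bf$system, cons, tip_load_vector(bf)),
               "singular|rigid")
})

test_that("distributing couplings conserve force and moment", {
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(3:40, 1)
    patch <- matrix(rnorm(3 * n, sd = 10), ncol = 3)
    rp <- rnorm(3, sd = 5)
    cp <- build_coupling(rp, patch, "distributing")
    F <- rnorm(3, sd = 100)
    Fl <- cp$distribute(F)
    expect_equal(colSums(Fl), F, tolerance = 1e-9)
    r <- sweep(patch, 2, rp)
    M <- colSums(cbind(r[, 2] * Fl[, 3] - r[, 3] * Fl[, 2],
                       r[, 3] * Fl[, 1] - r[, 1] * Fl[, 3],
                       r[, 1] * Fl[, 2] - r[, 2] * Fl[, 1]))
    expect_lt(max(abs(M)), 1e-8 * sqrt(sum(F^2)) * 10)
  }
  # single-node patch: direct transfer
  cp1 <- build_coupling(c(0, 0, 0), rbind(c(1, 2, 3)), "distributing")
  expect_equal(cp1$distribute(c(5, -1, 2)), rbind(c(5, -1, 2)),
               ignore_attr = TRUE)
  expect_error(build_coupling(c(0, 0, 0), matrix(0, 0, 3)), "empty")
})

test_that("rigid couplings reproduce small-rotation kinematics", {
  patch <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  rp <- c(0, 0, 0)
  cp <- build_coupling(rp, patch, "rigid")
  theta <- 1e-3
  q <- c(0, 0, 0, 0, 0, theta)        # rotation about z (SI-like)
  u <- matrix(cp$T %*% q, ncol = 3, byrow = TRUE)
  # u = theta x r for each patch node
  for (a in 1:3) {
    expect_equal(u[a, ], c(-theta * patch[a, 2], theta * patch[a, 1], 0),
                 tolerance = 1e-12)
  }
})

test_that("inertia relief balances arbitrary loads to machine precision", {
  m <- default_femur()
  sys <- default_system()
  # a single 100 N point force on the free femur
  f <- numeric(sys$ndof)
  f[3 * (m$attachment_patches$vasti$nodes[1] - 1) + 1] <- 100
  res <- solve_inertia_relief(sys, f)
  expect_lt(res$balance_residual[1], 1e-8)
  nf <- net_force_moment(m$nodes, res$balanced_loads[, 1], colMeans(m$nodes))
  expect_lt(sqrt(sum(nf$force^2)), 1e-8 * 100)
  expect_lt(sqrt(sum(nf$moment^2)), 1e-6 * 100)  # mm lever arms
  expect_lt(res$residual[1], 1e-8)

  # stance loads: balanced load equilibrium for every instance
  case <- default_case()
  fl <- build_load_vectors(m, case, build_inertia_relief(m))
  resl <- solve_inertia_relief(sys, fl)
  expect_true(all(resl$balance_residual < 1e-8))
})

test_that("inertia relief of a self-equilibrated load matches a gauge-fixed static solve", {
  bm <- generate_box_mesh(40, 10, 10, 16, 4, 4)
  sys <- assemble(bm, uniform_materials(bm, E = 8000, nu = 0.3, rho = 1.5))
  left <- which(bm$nodes[, 1] < 1e-9)
  right <- which(abs(bm$nodes[, 1] - 40) < 1e-9)
  f <- numeric(sys$ndof)
  f[3 * (left - 1) + 1] <- -100 / length(left)
  f[3 * (right - 1) + 1] <- 100 / length(right)
  ir <- solve_inertia_relief(sys, f)
  expect_lt(max(abs(ir$accelerations)), 1e-10)
  # statically determinate gauge: 3-2-1 pins, which carry zero reaction here
  n1 <- which(bm$nodes[, 1] == 0 & bm$nodes[, 2] == 0 & bm$nodes[, 3] == 0)
  n2 <- which(bm$nodes[, 1] == 40 & bm$nodes[, 2] == 0 & bm$nodes[, 3] == 0)
  n3 <- which(bm$nodes[, 1] == 0 & bm$nodes[, 2] == 10 & bm$nodes[, 3] == 0)
  cons <- list(dirichlet = list(
    list(node = n1, dir = c(1, 0, 0), value = 0),
    list(node = n1, dir = c(0, 1, 0), value = 0),
    list(node = n1, dir = c(0, 0, 1), value = 0),
    list(node = n2, dir = c(0, 1, 0), value = 0),
    list(node = n2, dir = c(0, 0, 1), value = 0),
    list(node = n3, dir = c(0, 0, 1), value = 0)),
    sliders = list(), rigid_couplings = list(), springs = list())
  st <- solve_static(sys, cons, f)
  fir <- recover_fields(sys, ir$U)
  fst <- recover_fields(sys, st$U)
  scale <- max(abs(fst$stress))
  expect_lt(max(abs(fir$stress - fst$stress)) / scale, 1e-8)
})

test_that("a mass-proportional load produces pure rigid acceleration and no stress", {
  bm <- generate_box_mesh(20, 10, 10, 8, 4, 4)
  sys <- assemble(bm, uniform_materials(bm, E = 8000, nu = 0.3, rho = 2))
  g <- 5000 # mm/s^2
  f <- sys$mass * rep(c(g, 0, 0), sys$n_nodes)
  res <- solve_inertia_relief(sys, f)
  expect_equal(res$accelerations[1, 1], g, tolerance = 1e-9)
  expect_lt(max(abs(res$accelerations[2:6, 1])), 1e-6 * g)
  flds <- recover_fields(sys, res$U)
  expect_lt(max(abs(flds$stress)), 1e-8 * 8000)
})

test_that("inertia-relief stresses are invariant to rigid pre-translation", {
  bm <- generate_box_mesh(20, 8, 8, 6, 3, 3)
  f <- numeric(3 * nrow(bm$nodes))
  f[seq(1, 90, by = 3)] <- 10
  sys1 <- assemble(bm, uniform_materials(bm, E = 5000, nu = 0.3))
  bm2 <- bm; bm2$nodes <- sweep(bm$nodes, 2, c(100, -50, 30), `+`)
  sys2 <- assemble(bm2, uniform_materials(bm2, E = 5000, nu = 0.3))
  s1 <- recover_fields(sys1, solve_inertia_relief(sys1, f)$U)$stress
  s2 <- recover_fields(sys2, solve_inertia_relief(sys2, f)$U)$stress
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("field recovery reproduces canonical stress states", {
  bm <- generate_box_mesh(2, 2, 2, 1, 1, 1)
  E <- 1e4
  sys0 <- assemble(bm, uniform_materials(bm, E = E, nu = 0))
  # uniaxial: u_x = (10/E) x -> sigma_xx = 10, von Mises 10
  U <- as.numeric(t(cbind(bm$nodes[, 1] * 10 / E, 0, 0)))
  f <- recover_fields(sys0, U)
  expect_equal(unname(f$von_mises[, 1]), rep(10, nrow(bm$tets)),
               tolerance = 1e-9)
  # principal strains ordered, largest is the axial one
  expect_lt(max(abs(f$principal_strains[1, , 1] - c(10 / E, 0, 0))), 1e-9)

  sys3 <- assemble(bm, uniform_materials(bm, E = E, nu = 0.3))
  # hydrostatic: u = c x -> deviator-free stress, von Mises 0
  cshr <- 1e-3
  Uh <- as.numeric(t(bm$nodes * cshr))
  fh <- recover_fields(sys3, Uh)
  expect_lt(max(fh$von_mises[, 1]), 1e-9 * E)
  # pure shear tau = 5 MPa: u_x = gamma y with mu gamma = 5 -> vm = 5 sqrt(3)
  mu <- E / (2 * 1.3)
  gam <- 5 / mu
  Us <- as.numeric(t(cbind(bm$nodes[, 2] * gam, 0, 0)))
  fs <- recover_fields(sys3, Us)
  expect_equal(unname(fs$von_mises[, 1]), rep(5 * sqrt(3), nrow(bm$tets)),
               tolerance = 1e-9)
})
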