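# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; nothing is read from disk except the shipped load-case
# fixture under inst/extdata.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

default_femur <- function() memo("femur", generate_femur())

default_materials <- function() memo("materials",
                                     bin_materials(default_femur(), 10))

default_system <- function() memo("system",
                                  assemble(default_femur(), default_materials()))

default_case <- function() memo("case",
                                generate_stance_loads(default_femur(),
                                                      gait_fixture_params()))

# coarse femur for cheap structural tests
coarse_femur <- function() memo("coarse",
                                generate_femur(femur_params(target_edge_length = 8)))

# the full 5-geometry x 6-method benchmark, shared by the acceptance tests
full_benchmark <- function() memo("benchmark", run_benchmark(run_config()))

# cantilever beam oracle: 100 x 10 x 10 mm, E = 1e4 MPa, nu = 0, tip load
# 100 N; Euler-Bernoulli tip deflection PL^3/(3EI) = 4.0 mm with I = 833.33
beam_fixture <- function(nx = 60, ny = 6, nz = 6, E = 1e4, nu = 0) {
  key <- sprintf("beam_%d_%d_%d_%g_%g", nx, ny, nz, E, nu)
  memo(key, {
    bm <- generate_box_mesh(100, 10, 10, nx, ny, nz)
    mats <- uniform_materials(bm, E = E, nu = nu)
    sys <- assemble(bm, mats)
    fixed <- which(bm$nodes[, 1] < 1e-9)
    tip <- which(abs(bm$nodes[, 1] - 100) < 1e-9)
    list(mesh = bm, mats = mats, system = sys, fixed = fixed, tip = tip)
  })
}

clamp_constraints <- function(nodes) {
  dl <- list()
  for (n in nodes) for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    dl[[length(dl) + 1L]] <- list(node = n, dir = d, value = 0, label = "clamp")
  }
  list(dirichlet = dl, sliders = list(), rigid_couplings = list(),
       springs = list(), use_inertia_relief = FALSE)
}

tip_load_vector <- function(bf, P = 100) {
  f <- numeric(bf$system$ndof)
  f[3 * (bf$tip - 1) + 3] <- -P / length(bf$tip)
  f
}

# net force and moment (about `origin`) of a 3N load vector
net_force_moment <- function(nodes, f, origin = c(0, 0, 0)) {
  fx <- matrix(f, ncol = 3, byrow = TRUE)
  r <- sweep(nodes, 2, origin)
  list(force = colSums(fx),
       moment = colSums(cbind(r[, 2] * fx[, 3] - r[, 3] * fx[, 2],
                              r[, 3] * fx[, 1] - r[, 1] * fx[, 3],
                              r[, 1] * fx[, 2] - r[, 2] * fx[, 1])))
}

# surface Euler characteristic of a tetrahedral mesh boundary
euler_characteristic <- function(bf) {
  V <- length(unique(as.integer(bf)))
  ed <- rbind(bf[, 1:2], bf[, 2:3], bf[, c(1, 3)])
  lo <- pmin(ed[, 1], ed[, 2]); hi <- pmax(ed[, 1], ed[, 2])
  E <- length(unique(paste(lo, hi)))
  V - E + nrow(bf)
}
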