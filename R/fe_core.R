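# Linear-elastic 4-node tetrahedral finite-element engine.
#
# Units: mm-N-MPa-tonne. Apparent density in g/cm^3 is converted to tonne/mm^3
# (factor 1e-9) so that stresses emerge in MPa and forces in N. Displacement
# DoF are ordered (ux1, uy1, uz1, ux2, ...). All constraint types (directional
# Dirichlet rows, distributing-coupling slider rows, rigid couplings to 6-DoF
# reference points, inertia-relief mass orthogonality) are enforced through one
# Lagrange-multiplier saddle-point system; grounded springs augment the
# stiffness diagonal.

DENSITY_TO_TONNE_MM3 <- 1e-9

# Shape-function gradients and volumes for all tets, vectorised.
# Returns list(vol, g) with g a list of 3 M x 4 matrices (d/dx, d/dy, d/dz).
tet_gradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  p2 <- nodes[tets[, 2], , drop = FALSE]
  p3 <- nodes[tets[, 3], , drop = FALSE]
  p4 <- nodes[tets[, 4], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1; c_ <- p4 - p1
  detJ <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  if (any(detJ <= 0)) stop("inverted tetrahedra encountered in gradient computation")
  # rows of inv(J): cross products of edge pairs / detJ; gradient of N2..N4
  inv_row <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                  u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                  u[, 1] * v[, 2] - u[, 2] * v[, 1])
  g2 <- inv_row(b, c_) / detJ
  g3 <- inv_row(c_, a) / detJ
  g4 <- inv_row(a, b) / detJ
  g1 <- -(g2 + g3 + g4)
  list(vol = detJ / 6,
       g = list(cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1]),
                cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2]),
                cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3])))
}

#' Element stiffness matrix of a linear tetrahedron
#'
#' Standard constant-strain (C3D4) isotropic formulation,
#' `K_ab = V (lambda g_a g_b' + mu g_b g_a' + mu (g_a . g_b) I)` with the
#' shape-function gradients `g`.
#'
#' @param tet_coords 4 x 3 node coordinates (mm), positive orientation
#' @param E Young's modulus (MPa)
#' @param nu Poisson's ratio (0 <= nu < 0.5)
#' @return 12 x 12 symmetric positive semidefinite matrix (N/mm)
#' @export
element_stiffness <- function(tet_coords, E, nu) {
  if (nu < 0 || nu >= 0.5) stop("Poisson ratio must lie in [0, 0.5)")
  gr <- tet_gradients(tet_coords, matrix(1:4, 1))
  V <- gr$vol
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  G <- rbind(c(gr$g[[1]][1, ]), c(gr$g[[2]][1, ]), c(gr$g[[3]][1, ])) # 3 x 4
  K <- matrix(0, 12, 12)
  for (a in 1:4) for (b in 1:4) {
    ga <- G[, a]; gb <- G[, b]
    K[3 * a - 2:0, 3 * b - 2:0] <-
      V * (lam * outer(ga, gb) + mu * outer(gb, ga) + mu * sum(ga * gb) * diag(3))
  }
  (K + t(K)) / 2
}

#' Assemble the global system for a tetrahedral model
#'
#' Scatter-adds element stiffness blocks into a sparse symmetric operator and
#' lumps element mass (rho V / 4 to each node). Shape-function gradients are
#' cached on the returned object for strain recovery.
#'
#' @param model a `femur_model` or any list with `nodes` and `tets`
#' @param materials a `material_table` from [bin_materials()]
#' @return object of class `fe_system`: `K` (sparse, N/mm), `mass` (diagonal
#'   vector, tonne, length 3N), `ndof`, plus cached geometry
#' @export
assemble <- function(model, materials) {
  nodes <- model$nodes; tets <- model$tets
  M <- nrow(tets); N <- nrow(nodes)
  pr <- element_properties(materials)
  gr <- tet_gradients(nodes, tets)
  V <- gr$vol; G <- gr$g
  lam <- pr$E * pr$nu / ((1 + pr$nu) * (1 - 2 * pr$nu))
  mu <- pr$E / (2 * (1 + pr$nu))
  nE <- 144L * M
  ii <- integer(nE); jj <- integer(nE); xx <- numeric(nE)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    gab <- G[[1]][, a] * G[[1]][, b] + G[[2]][, a] * G[[2]][, b] +
      G[[3]][, a] * G[[3]][, b]
    ra <- 3L * (tets[, a] - 1L); rb <- 3L * (tets[, b] - 1L)
    for (i in 1:3) for (j in 1:3) {
      val <- V * (lam * G[[i]][, a] * G[[j]][, b] +
                    mu * G[[j]][, a] * G[[i]][, b] +
                    if (i == j) mu * gab else 0)
      idx <- pos + seq_len(M)
      ii[idx] <- ra + i; jj[idx] <- rb + j; xx[idx] <- val
      pos <- pos + M
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3L * N, 3L * N))
  m_node <- numeric(N)
  me <- pr$rho * DENSITY_TO_TONNE_MM3 * V / 4
  for (a in 1:4) {
    acc <- tapply(me, tets[, a], sum)
    m_node[as.integer(names(acc))] <- m_node[as.integer(names(acc))] + acc
  }
  structure(list(K = K, mass = rep(m_node, each = 3L), ndof = 3L * N,
                 n_nodes = N, nodes = nodes, tets = tets,
                 vol = V, grads = G, E = pr$E, nu = pr$nu),
            class = "fe_system")
}

#' @export
print.fe_system <- function(x, ...) {
  cat(sprintf("fe_system: %d nodes, %d DoF, total mass %.4f kg\n",
              x$n_nodes, x$ndof, sum(x$mass) / 3 * 1e3))
  invisible(x)
}

# Rigid-body modes (3 translations + 3 rotations about the mass centroid),
# 3N x 6 dense matrix.
rigid_modes <- function(system) {
  N <- system$n_nodes
  mn <- system$mass[seq(1, 3 * N, by = 3)]
  ctr <- colSums(system$nodes * mn) / sum(mn)
  r <- sweep(system$nodes, 2, ctr)
  Rm <- matrix(0, 3 * N, 6)
  ix <- seq(1, 3 * N, by = 3)
  Rm[ix, 1] <- 1; Rm[ix + 1, 2] <- 1; Rm[ix + 2, 3] <- 1
  # rotation about x: u = (0, -rz, ry) etc.
  Rm[ix + 1, 4] <- -r[, 3]; Rm[ix + 2, 4] <- r[, 2]
  Rm[ix, 5] <- r[, 3];      Rm[ix + 2, 5] <- -r[, 1]
  Rm[ix, 6] <- -r[, 2];     Rm[ix + 1, 6] <- r[, 1]
  Rm
}

#' Moment-consistent distributing coupling weights
#'
#' Spreads a force applied at a reference point over a patch of nodes: each
#' node receives an equal share plus a linear correction (`omega x r_i`) chosen
#' so the nodal loads are statically equivalent to the reference-point force
#' (same resultant, zero net moment about the reference point).
#'
#' @param refpoint 3-vector, reference point position (mm)
#' @param patch_coords n x 3 patch node positions
#' @param mode "distributing" (returns a force-distribution function) or
#'   "rigid" (returns the kinematic map from 6 reference DoF to patch DoF)
#' @return for distributing: list with `distribute(F)` returning an n x 3 load
#'   table; for rigid: list with `T` (3n x 6 kinematic matrix) and coordinates
#' @export
build_coupling <- function(refpoint, patch_coords, mode = c("distributing", "rigid")) {
  mode <- match.arg(mode)
  if (is.null(nrow(patch_coords)) || nrow(patch_coords) == 0) {
    stop("empty patch in coupling")
  }
  n <- nrow(patch_coords)
  r <- sweep(patch_coords, 2, refpoint)
  if (mode == "rigid") {
    Tm <- matrix(0, 3 * n, 6)
    ix <- seq(1, 3 * n, by = 3)
    Tm[ix, 1] <- 1; Tm[ix + 1, 2] <- 1; Tm[ix + 2, 3] <- 1
    Tm[ix + 1, 4] <- -r[, 3]; Tm[ix + 2, 4] <- r[, 2]
    Tm[ix, 5] <- r[, 3];      Tm[ix + 2, 5] <- -r[, 1]
    Tm[ix, 6] <- -r[, 2];     Tm[ix + 1, 6] <- r[, 1]
    return(list(mode = "rigid", T = Tm, r = r))
  }
  rbar <- colMeans(r)
  rc <- sweep(r, 2, rbar)                 # positions about the patch centroid
  Jc <- diag(sum(rowSums(rc^2)), 3) - crossprod(rc)
  # pseudo-inverse: collinear or tiny patches cannot react moments about the
  # degenerate axis, so that component of the correction is dropped
  sv <- svd(Jc)
  keep <- sv$d > max(sv$d) * 1e-9
  Jc_pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  distribute <- function(F) {
    if (n == 1) return(matrix(F, 1, 3))
    # equal shares carry moment rbar x F about the refpoint; cancel it with a
    # zero-resultant correction field omega x (r_i - rbar)
    omega <- as.numeric(Jc_pinv %*% -cross3(rbar, F))
    base <- matrix(F / n, n, 3, byrow = TRUE)
    corr <- cbind(omega[2] * rc[, 3] - omega[3] * rc[, 2],
                  omega[3] * rc[, 1] - omega[1] * rc[, 3],
                  omega[1] * rc[, 2] - omega[2] * rc[, 1])
    base + corr
  }
  list(mode = "distributing", distribute = distribute, r = r, n = n)
}

# --- constraint compilation -------------------------------------------------

# Compile a constraint_set (see boundary_conditions.R) into sparse constraint
# rows C u = g over the extended DoF vector: 3N node DoF, 6 per rigid-coupled
# reference point, and 3 per slider reference point (e.g. the acetabular
# surrogate p1, which is guided along its axis and linked to the patch-average
# axial displacement), plus the spring-augmented stiffness.
compile_constraints <- function(system, constraints) {
  N <- system$n_nodes
  n_rp <- length(constraints$rigid_couplings)
  n_sl <- length(constraints$sliders)
  ndof <- 3L * N + 6L * n_rp + 3L * n_sl
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0); rhs <- numeric(0)
  nrow_c <- 0L
  add_row <- function(cols, vals, g) {
    nrow_c <<- nrow_c + 1L
    trip_i <<- c(trip_i, rep(nrow_c, length(cols)))
    trip_j <<- c(trip_j, cols); trip_x <<- c(trip_x, vals)
    rhs <<- c(rhs, g)
  }
  labels <- character(0)

  for (d in constraints$dirichlet) {
    dir <- unit_vec(d$dir)
    add_row(3L * (d$node - 1L) + 1:3, dir, d$value)
    labels <- c(labels, sprintf("dirichlet:%s", d$label %||% d$node))
  }
  sl_dof0 <- 3L * N + 6L * n_rp
  slider_dof <- list()
  for (k_sl in seq_along(constraints$sliders)) {
    s <- constraints$sliders[[k_sl]]
    p0 <- sl_dof0 + 3L * (k_sl - 1L)
    slider_dof[[s$label %||% as.character(k_sl)]] <- p0
    pn <- s$nodes; n <- length(pn)
    ax <- unit_vec(s$axis)
    basis <- transverse_basis(ax)
    # the slider point may translate only along its axis ...
    for (k in 1:2) {
      add_row(p0 + 1:3, basis[, k], 0)
      labels <- c(labels, sprintf("slider:%s:t%d", s$label %||% "", k))
    }
    # ... and is linked to the patch-average axial displacement, so the dual
    # force transmits the axial thrust to the patch while the patch stays
    # transversely free (frictionless acetabulum surrogate)
    cols <- c(p0 + 1:3, as.integer(t(outer(3L * (pn - 1L), 1:3, `+`))))
    vals <- c(ax, rep(-ax / n, times = n))
    add_row(cols, vals, 0)
    labels <- c(labels, sprintf("slider:%s:axial_link", s$label %||% ""))
  }
  rp_dof0 <- 3L * N
  for (k in seq_along(constraints$rigid_couplings)) {
    rc <- constraints$rigid_couplings[[k]]
    cp <- build_coupling(rc$refpoint, system$nodes[rc$nodes, , drop = FALSE], "rigid")
    q0 <- rp_dof0 + 6L * (k - 1L)
    for (a in seq_along(rc$nodes)) {
      for (i in 1:3) {
        cols <- c(3L * (rc$nodes[a] - 1L) + i, q0 + which(cp$T[3 * (a - 1) + i, ] != 0))
        vals <- c(1, -cp$T[3 * (a - 1) + i, cp$T[3 * (a - 1) + i, ] != 0])
        add_row(cols, vals, 0)
        labels <- c(labels, sprintf("rigid:%s:n%d:d%d", rc$label %||% k, a, i))
      }
    }
    for (fd in rc$fixed_dof) {  # list of (kind = "trans"/"rot", dir)
      off <- if (fd$kind == "trans") 0L else 3L
      add_row(q0 + off + 1:3, unit_vec(fd$dir), 0)
      labels <- c(labels, sprintf("refpoint:%s:%s", rc$label %||% k, fd$kind))
    }
  }
  C <- if (nrow_c > 0) {
    Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                         dims = c(nrow_c, ndof))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(0L, ndof))
  }
  list(C = C, rhs = rhs, ndof = ndof, labels = labels, n_rp = n_rp,
       slider_dof = slider_dof)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two unit vectors spanning the orthogonal complement of axis
transverse_basis <- function(axis) {
  a <- unit_vec(axis)
  seed <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- unit_vec(seed - sum(seed * a) * a)
  cbind(t1, cross3(a, t1))
}

apply_springs <- function(system, constraints) {
  K <- system$K
  if (length(constraints$springs)) {
    idx <- integer(0); val <- numeric(0)
    for (sp in constraints$springs) {
      if (sp$k <= 0) stop("spring stiffness must be positive")
      dd <- as.integer(t(outer(3L * (sp$nodes - 1L), 1:3, `+`)))
      idx <- c(idx, dd); val <- c(val, rep(sp$k, length(dd)))
    }
    K <- K + Matrix::sparseMatrix(i = idx, j = idx, x = val,
                                  dims = dim(system$K))
  }
  K
}

#' Solve the constrained static problem
#'
#' Forms the saddle-point system `[K C'; C 0] [u; lambda] = [f; g]` where `C`
#' collects all constraint rows of the method (Dirichlet, slider, rigid
#' coupling, reference-point fixities) and springs have been added to `K`.
#' Factorised once and solved for all load instances.
#'
#' @param system an `fe_system` from [assemble()]
#' @param constraints a `constraint_set` (see [build_constraints()])
#' @param loads numeric matrix (3N x n_instances) or vector of nodal loads (N)
#' @return object of class `fe_result`: `U` (3N x T displacements, mm),
#'   `lambda` (constraint forces, N), `reactions` (per labelled constraint
#'   row), `residual` (relative equilibrium residual per instance), plus
#'   reference-point DoF `q` when rigid couplings are present
#' @export
solve_static <- function(system, constraints, loads) {
  if (isTRUE(constraints$use_inertia_relief)) {
    return(solve_inertia_relief(system, loads))
  }
  slider_loads <- attr(loads, "slider_loads")
  loads <- as.matrix(loads)
  cc <- compile_constraints(system, constraints)
  K <- apply_springs(system, constraints)
  ndof <- cc$ndof; nc <- nrow(cc$C)
  if (ndof > system$ndof) {
    K <- Matrix::bdiag(K, Matrix::Matrix(0, ndof - system$ndof,
                                         ndof - system$ndof, sparse = TRUE))
  }
  if (nc == 0 && !length(constraints$springs)) {
    stop("singular system: no constraints, no springs and no inertia relief; ",
         "rigid-body modes are unconstrained")
  }
  A <- rbind(cbind(K, Matrix::t(cc$C)),
             cbind(cc$C, Matrix::Matrix(0, nc, nc, sparse = TRUE)))
  f <- rbind(loads, matrix(0, ndof - system$ndof, ncol(loads)))
  # loads applied at slider reference points (e.g. hip contact at p1)
  for (lbl in names(slider_loads %||% list())) {
    p0 <- cc$slider_dof[[lbl]]
    if (is.null(p0)) stop("no slider named '", lbl, "' in the constraint set")
    f[p0 + 1:3, ] <- f[p0 + 1:3, ] + slider_loads[[lbl]]
  }
  B <- rbind(f, matrix(cc$rhs, nc, ncol(loads)))
  sol <- tryCatch(Matrix::solve(A, B),
                  error = function(e) stop("singular constrained system: ",
                                           conditionMessage(e)))
  sol <- as.matrix(sol)
  U <- sol[seq_len(system$ndof), , drop = FALSE]
  q <- if (ndof > system$ndof) {
    sol[(system$ndof + 1):ndof, , drop = FALSE]
  } else NULL
  refpoint_u <- list()
  for (k in seq_along(constraints$rigid_couplings)) {
    lbl <- constraints$rigid_couplings[[k]]$label %||% as.character(k)
    refpoint_u[[lbl]] <- sol[system$ndof + 6L * (k - 1L) + 1:6, , drop = FALSE]
  }
  for (lbl in names(cc$slider_dof)) {
    refpoint_u[[lbl]] <- sol[cc$slider_dof[[lbl]] + 1:3, , drop = FALSE]
  }
  lam <- if (nc > 0) sol[(ndof + 1):(ndof + nc), , drop = FALSE] else
    matrix(0, 0, ncol(loads))
  # equilibrium residual on the node DoF
  Ku <- as.matrix(K[seq_len(system$ndof), seq_len(ndof)] %*%
                    sol[seq_len(ndof), , drop = FALSE])
  CtL <- if (nc > 0) as.matrix(Matrix::t(cc$C)[seq_len(system$ndof), ] %*% lam)
  else 0
  resid <- sqrt(colSums((Ku + CtL - loads)^2)) /
    pmax(sqrt(colSums(loads^2)), 1e-12)
  structure(list(U = U, q = q, refpoint_u = refpoint_u, lambda = lam,
                 reaction_labels = cc$labels,
                 residual = resid, constraints = constraints),
            class = "fe_result")
}

#' Solve a free body by inertia relief
#'
#' Computes rigid-body accelerations `a = (R'MR)^-1 R'f`, subtracts the
#' inertial load `M R a` to obtain a self-equilibrated balanced load, and
#' solves the augmented system `[K, MR; (MR)', 0]` which fixes the rigid-body
#' gauge by mass orthogonality `R'Mu = 0`. No displacement constraints are
#' applied.
#'
#' @param system an `fe_system`
#' @param loads 3N x T load matrix (N)
#' @return `fe_result` with additional fields `accelerations` (6 x T),
#'   `balanced_loads`, and `balance_residual` (net force+moment of the
#'   balanced load relative to the applied-load norm)
#' @export
solve_inertia_relief <- function(system, loads) {
  loads <- as.matrix(loads)
  if (all(system$mass == 0)) stop("inertia relief requires a mass matrix")
  R <- rigid_modes(system)
  MR <- R * system$mass                  # diagonal mass times modes
  RtMR <- crossprod(R, MR)
  a <- solve(RtMR, crossprod(R, loads))
  fb <- loads - MR %*% a
  # net force and moment of the balanced load (should vanish)
  bal <- crossprod(R, fb)
  bal_res <- sqrt(colSums(bal^2)) / pmax(sqrt(colSums(loads^2)), 1e-12)
  nc <- 6L
  MRs <- Matrix::Matrix(MR, sparse = TRUE)
  A <- rbind(cbind(system$K, MRs),
             cbind(Matrix::t(MRs), Matrix::Matrix(0, nc, nc, sparse = TRUE)))
  B <- rbind(fb, matrix(0, nc, ncol(loads)))
  sol <- as.matrix(Matrix::solve(A, B))
  U <- sol[seq_len(system$ndof), , drop = FALSE]
  lam <- sol[system$ndof + 1:6, , drop = FALSE]
  Ku <- as.matrix(system$K %*% U)
  resid <- sqrt(colSums((Ku + MR %*% lam - fb)^2)) /
    pmax(sqrt(colSums(loads^2)), 1e-12)
  structure(list(U = U, q = NULL, lambda = lam,
                 reaction_labels = paste0("ir:mode", 1:6),
                 residual = resid, accelerations = as.matrix(a),
                 balanced_loads = fb, balance_residual = bal_res,
                 constraints = list(use_inertia_relief = TRUE)),
            class = "fe_result")
}

#' Recover element strain, stress and derived fields from displacements
#'
#' Constant-per-element fields for linear tetrahedra: engineering strain from
#' the cached shape-function gradients, Hooke's law stress, von Mises
#' equivalent stress, and ordered principal strains (closed-form symmetric
#' 3x3 eigenvalues). "Absolute principal strain" is `max |principal strain|`;
#' a signed companion (the extreme principal strain of largest magnitude,
#' tension positive) supports tension/compression pattern checks.
#'
#' @param system an `fe_system`
#' @param U displacement matrix (3N x T) or vector
#' @return list per instance fields, each M x T: `von_mises` (MPa),
#'   `abs_principal_strain`, `signed_principal_strain` (dimensionless),
#'   `principal_strains` (M x 3 x T array), `stress`, `strain`
#'   (M x 6 x T arrays, order xx, yy, zz, xy, yz, xz)
#' @export
recover_fields <- function(system, U) {
  U <- as.matrix(U)
  Tn <- ncol(U)
  M <- nrow(system$tets)
  G <- system$grads; tets <- system$tets
  lam <- system$E * system$nu / ((1 + system$nu) * (1 - 2 * system$nu))
  mu <- system$E / (2 * (1 + system$nu))
  strain <- array(0, c(M, 6, Tn))
  stress <- array(0, c(M, 6, Tn))
  vm <- matrix(0, M, Tn)
  pstr <- array(0, c(M, 3, Tn))
  for (t in seq_len(Tn)) {
    u <- U[, t]
    ux <- matrix(u[3 * (tets - 1) + 1], M, 4)
    uy <- matrix(u[3 * (tets - 1) + 2], M, 4)
    uz <- matrix(u[3 * (tets - 1) + 3], M, 4)
    exx <- rowSums(G[[1]] * ux); eyy <- rowSums(G[[2]] * uy)
    ezz <- rowSums(G[[3]] * uz)
    gxy <- rowSums(G[[2]] * ux) + rowSums(G[[1]] * uy)
    gyz <- rowSums(G[[3]] * uy) + rowSums(G[[2]] * uz)
    gxz <- rowSums(G[[3]] * ux) + rowSums(G[[1]] * uz)
    tr <- exx + eyy + ezz
    sxx <- lam * tr + 2 * mu * exx
    syy <- lam * tr + 2 * mu * eyy
    szz <- lam * tr + 2 * mu * ezz
    sxy <- mu * gxy; syz <- mu * gyz; sxz <- mu * gxz
    strain[, , t] <- cbind(exx, eyy, ezz, gxy, gyz, gxz)
    stress[, , t] <- cbind(sxx, syy, szz, sxy, syz, sxz)
    vm[, t] <- sqrt(pmax(0, 0.5 * ((sxx - syy)^2 + (syy - szz)^2 +
                                     (szz - sxx)^2) +
                           3 * (sxy^2 + syz^2 + sxz^2)))
    pstr[, , t] <- sym3_eigenvalues(exx, eyy, ezz, gxy / 2, gyz / 2, gxz / 2)
  }
  list(strain = strain, stress = stress, von_mises = vm,
       principal_strains = pstr,
       abs_principal_strain = apply(abs(pstr), c(1, 3), max),
       signed_principal_strain = {
         sel <- apply(abs(pstr), c(1, 3), which.max)
         out <- matrix(0, M, Tn)
         for (t in seq_len(Tn)) out[, t] <- pstr[cbind(seq_len(M), sel[, t], t)]
         out
       })
}

# Closed-form ordered eigenvalues (desc) of symmetric 3x3 tensors, vectorised.
sym3_eigenvalues <- function(a11, a22, a33, a12, a23, a13) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * (a12^2 + a23^2 + a13^2)
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / 2 / pmax(p^3, .Machine$double.xmin), 0)
  r <- pmax(-1, pmin(1, r))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  cbind(e1, e2, e3)
}
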