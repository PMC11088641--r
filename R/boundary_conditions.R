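# Declarative construction of the six constraining boundary-condition methods
# for the isolated femur:
#   inertia_relief - no displacement constraints; residual loads balanced by
#                    rigid-body inertial loads (the benchmark)
#   fixed_knee     - distal condylar region fully fixed; tibiofemoral and
#                    patellofemoral contact forces omitted
#   springs        - weak grounded springs on neck, epicondylar and knee-centre
#                    node bands; no Dirichlet constraints
#   isostatic      - exactly 6 constrained DoF (knee centre 3, head node ML+AP,
#                    lateral epicondyle 1)
#   mid_shaft      - exactly 6 constrained DoF (knee centre 3, epicondyle AP,
#                    mid-diaphysis ML+AP)
#   biomechanical  - head reference point on an axial slider along the
#                    mechanical axis, knee centre fixed, greater trochanter
#                    rigid-coupled with ML/AP translation and SI rotation fixed
# All directions are expressed in the local anatomical frame.

#' Boundary-condition method names
#' @export
METHOD_NAMES <- c("inertia_relief", "fixed_knee", "springs", "isostatic",
                  "mid_shaft", "biomechanical")

new_constraint_set <- function(method, dirichlet = list(), springs = list(),
                               sliders = list(), rigid_couplings = list(),
                               use_inertia_relief = FALSE,
                               load_rules = list(hip = TRUE, tf = TRUE,
                                                 pf = TRUE, muscles = TRUE),
                               snap_distances = numeric(0)) {
  structure(list(method = method, dirichlet = dirichlet, springs = springs,
                 sliders = sliders, rigid_couplings = rigid_couplings,
                 use_inertia_relief = use_inertia_relief,
                 load_rules = load_rules, snap_distances = snap_distances),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("constraint_set '%s': %d Dirichlet rows, %d slider rows, %d rigid couplings, %d spring groups%s\n",
              x$method, length(x$dirichlet), 2L * length(x$sliders),
              length(x$rigid_couplings), length(x$springs),
              if (x$use_inertia_relief) ", inertia relief" else ""))
  cat("  loads included:",
      paste(names(Filter(isTRUE, x$load_rules)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of explicitly constrained DoF of a method
#'
#' Counts Dirichlet rows, slider rows (2 per slider) and fixed reference-point
#' DoF; rigid-coupling slave relations are kinematic links, not fixities.
#'
#' @param cs a `constraint_set`
#' @return integer
#' @export
constrained_dof_count <- function(cs) {
  length(cs$dirichlet) + 2L * length(cs$sliders) +
    sum(vapply(cs$rigid_couplings, function(rc) length(rc$fixed_dof), integer(1)))
}

# nearest mesh node to a point; returns index and snap distance
nearest_node <- function(model, point, surface_only = FALSE) {
  idx <- if (surface_only) model$surface_nodes else seq_len(nrow(model$nodes))
  d2 <- rowSums(sweep(model$nodes[idx, , drop = FALSE], 2, point)^2)
  k <- which.min(d2)
  list(node = idx[k], dist = sqrt(d2[k]))
}

#' Inertia-relief "constraint" set
#'
#' No displacement or rotation constraints; all muscle and joint contact
#' forces (including tibiofemoral and patellofemoral) are applied and the
#' residual is balanced by rigid-body inertial loads.
#'
#' @param model a `femur_model`
#' @return `constraint_set`
#' @export
build_inertia_relief <- function(model) {
  new_constraint_set("inertia_relief", use_inertia_relief = TRUE)
}

#' Fixed-knee constraint set
#'
#' Fixes every surface node of the distal condylar region (distal 5% of femur
#' length) in all three translations, which removes all six rigid DoF; hip
#' contact and muscle forces are applied while tibiofemoral and patellofemoral
#' contact forces are omitted.
#'
#' @param model a `femur_model`
#' @return `constraint_set`
#' @export
build_fixed_knee <- function(model) {
  patch <- get_condylar_patch(model)
  dir3 <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  dl <- list()
  for (n in patch) for (d in dir3) {
    dl[[length(dl) + 1L]] <- list(node = n, dir = d, value = 0,
                                  label = "condyle")
  }
  new_constraint_set("fixed_knee", dirichlet = dl,
                     load_rules = list(hip = TRUE, tf = FALSE, pf = FALSE,
                                       muscles = TRUE))
}

get_condylar_patch <- function(model) {
  surf <- model$surface_nodes
  L <- sqrt(sum((model$landmarks$head_center - model$landmarks$knee_center)^2))
  si <- model$frame$si
  ax <- as.numeric(sweep(model$nodes[surf, , drop = FALSE], 2,
                         model$landmarks$knee_center) %*% si)
  surf[ax < 0.05 * L]
}

#' Springs constraint set
#'
#' Grounded weak springs (default 1 N/mm per node, each translation) on three
#' surface-node bands: around the femoral neck, around the epicondyles, and
#' around the knee joint centre. No Dirichlet constraints; all loads applied.
#' The default stiffness and band sizes keep the total spring reaction below
#' about 2% of the applied load on the synthetic femur.
#'
#' @param model a `femur_model`
#' @param k_per_node spring stiffness per node, N/mm (> 0)
#' @return `constraint_set`
#' @export
build_springs <- function(model, k_per_node = 1) {
  if (k_per_node <= 0) stop("spring stiffness must be positive")
  lm <- model$landmarks
  surf <- model$surface_nodes
  spos <- model$nodes[surf, , drop = FALSE]
  nearest_k <- function(point, k) {
    surf[order(rowSums(sweep(spos, 2, point)^2))[seq_len(min(k, length(surf)))]]
  }
  # about 50 nodes per band
  neck_mid <- lm$neck_base + 0.45 * (lm$head_center - lm$neck_base)
  neck_band <- nearest_k(neck_mid, 50)
  med_pt <- lm$knee_center - (lm$lateral_epicondyle - lm$knee_center)
  epi_band <- unique(c(nearest_k(lm$lateral_epicondyle, 25),
                       nearest_k(med_pt, 25)))
  knee_patch <- nearest_k(lm$knee_center, 50)
  groups <- list(neck = neck_band, epicondyles = epi_band, knee = knee_patch)
  for (g in names(groups)) {
    if (!length(groups[[g]])) stop("empty spring band: ", g)
  }
  new_constraint_set("springs",
                     springs = lapply(groups, function(n)
                       list(nodes = n, k = k_per_node)))
}

#' Isostatic constraint set
#'
#' Exactly six constrained translational DoF in local-frame directions: the
#' node at the knee centre (3), the head-surface node nearest the mechanical
#' axis intersection in ML and AP (so it can deflect only along the mechanical
#' axis), and the lateral-epicondyle node in one direction. The well-posed
#' anterior-posterior epicondyle constraint is the default; the
#' superior-inferior variant is selectable and leaves rotation about the
#' mechanical axis nearly unrestrained.
#'
#' @param model a `femur_model`
#' @param epicondyle_direction "ap" (default) or "si"
#' @return `constraint_set`
#' @export
build_isostatic <- function(model, epicondyle_direction = c("ap", "si")) {
  epicondyle_direction <- match.arg(epicondyle_direction)
  fr <- model$frame; lm <- model$landmarks
  knee <- nearest_node(model, lm$knee_center)
  mech <- unit_vec(lm$head_center - lm$knee_center)
  head_exit <- lm$head_center + model$params$head_radius * mech
  head_node <- nearest_node(model, head_exit, surface_only = TRUE)
  epi <- nearest_node(model, lm$lateral_epicondyle, surface_only = TRUE)
  epi_dir <- if (epicondyle_direction == "ap") fr$ap else fr$si
  dl <- list(
    list(node = knee$node, dir = fr$ml, value = 0, label = "knee_ml"),
    list(node = knee$node, dir = fr$ap, value = 0, label = "knee_ap"),
    list(node = knee$node, dir = fr$si, value = 0, label = "knee_si"),
    list(node = head_node$node, dir = fr$ml, value = 0, label = "head_ml"),
    list(node = head_node$node, dir = fr$ap, value = 0, label = "head_ap"),
    list(node = epi$node, dir = epi_dir, value = 0,
         label = paste0("epicondyle_", epicondyle_direction))
  )
  new_constraint_set("isostatic", dirichlet = dl,
                     snap_distances = c(knee = knee$dist, head = head_node$dist,
                                        epicondyle = epi$dist))
}

#' Mid-shaft constraint set
#'
#' Exactly six constrained translational DoF: knee centre (3), lateral
#' epicondyle in AP (1), and the mid-diaphysis node in ML and AP (2); the
#' mid-diaphysis SI translation remains free. All loads applied.
#'
#' @param model a `femur_model`
#' @return `constraint_set`
#' @export
build_mid_shaft <- function(model) {
  fr <- model$frame; lm <- model$landmarks
  knee <- nearest_node(model, lm$knee_center)
  epi <- nearest_node(model, lm$lateral_epicondyle, surface_only = TRUE)
  mid <- nearest_node(model, lm$mid_diaphysis, surface_only = TRUE)
  dl <- list(
    list(node = knee$node, dir = fr$ml, value = 0, label = "knee_ml"),
    list(node = knee$node, dir = fr$ap, value = 0, label = "knee_ap"),
    list(node = knee$node, dir = fr$si, value = 0, label = "knee_si"),
    list(node = epi$node, dir = fr$ap, value = 0, label = "epicondyle_ap"),
    list(node = mid$node, dir = fr$ml, value = 0, label = "midshaft_ml"),
    list(node = mid$node, dir = fr$ap, value = 0, label = "midshaft_ap")
  )
  new_constraint_set("mid_shaft", dirichlet = dl,
                     snap_distances = c(knee = knee$dist, epicondyle = epi$dist,
                                        midshaft = mid$dist))
}

#' Biomechanical constraint set
#'
#' The acetabulum surrogate: an axial translational connector between the head
#' centre reference point `p1` and the knee centre `p3`. `p1` may translate
#' only along the undeformed `p1`-`p3` (mechanical) axis and is linked to the
#' articulating head surface through the axial component of a distributing
#' coupling, so the full hip contact force applied at `p1` transmits its axial
#' component to the bone while the transverse components are reacted by the
#' slider -- the femoral head itself remains free to translate and rotate.
#' The knee centre node is fixed in all three translations. The greater
#' trochanter reference point, rigidly coupled to its small surface patch, is
#' constrained in ML and AP translation and in rotation about the SI axis (the
#' passive thigh soft-tissue surrogate). All muscle and contact forces are
#' applied.
#'
#' @param model a `femur_model`
#' @param hip_transmission "full" (default) applies the full hip contact force
#'   vector to the bone through the head coupling, with `p1` riding the
#'   connector as a passive axially-guided acetabular tracking point; "axial"
#'   routes the force through `p1` so only its axial component reaches the
#'   bone and the transverse components become slider reactions
#' @return `constraint_set`
#' @export
build_biomechanical <- function(model, hip_transmission = c("full", "axial")) {
  hip_transmission <- match.arg(hip_transmission)
  fr <- model$frame; lm <- model$landmarks
  knee <- nearest_node(model, lm$knee_center)
  axis <- unit_vec(lm$head_center - lm$knee_center)
  head_patch <- model$attachment_patches$hip_contact$nodes
  gt_patch <- get_gt_patch(model)
  dl <- list(
    list(node = knee$node, dir = fr$ml, value = 0, label = "knee_ml"),
    list(node = knee$node, dir = fr$ap, value = 0, label = "knee_ap"),
    list(node = knee$node, dir = fr$si, value = 0, label = "knee_si")
  )
  sliders <- list(list(nodes = head_patch, axis = axis, label = "p1"))
  rigid <- list(list(refpoint = lm$greater_trochanter_lateral,
                     nodes = gt_patch,
                     fixed_dof = list(list(kind = "trans", dir = fr$ml),
                                      list(kind = "trans", dir = fr$ap),
                                      list(kind = "rot", dir = fr$si)),
                     label = "p2"))
  new_constraint_set("biomechanical", dirichlet = dl, sliders = sliders,
                     rigid_couplings = rigid,
                     load_rules = list(hip = TRUE, tf = TRUE, pf = TRUE,
                                       muscles = TRUE,
                                       hip_via = if (hip_transmission ==
                                                     "axial") "p1"),
                     snap_distances = c(knee = knee$dist))
}

get_gt_patch <- function(model) {
  surf <- model$surface_nodes
  gt <- model$landmarks$greater_trochanter_lateral
  p <- surf[rowSums(sweep(model$nodes[surf, , drop = FALSE], 2, gt)^2) < 10^2]
  if (length(p) < 3) {
    p <- surf[order(rowSums(sweep(model$nodes[surf, , drop = FALSE], 2, gt)^2))[1:6]]
  }
  p
}

#' Build the constraint set for a named method
#'
#' @param model a `femur_model`
#' @param method one of `METHOD_NAMES`
#' @param ... method-specific options (`k_per_node` for springs,
#'   `epicondyle_direction` for isostatic)
#' @return `constraint_set`
#' @export
build_constraints <- function(model, method, ...) {
  method <- match.arg(method, METHOD_NAMES)
  switch(method,
         inertia_relief = build_inertia_relief(model),
         fixed_knee = build_fixed_knee(model),
         springs = build_springs(model, ...),
         isostatic = build_isostatic(model, ...),
         mid_shaft = build_mid_shaft(model),
         biomechanical = build_biomechanical(model))
}

#' Assemble nodal load vectors from a load case under a method's load rules
#'
#' Muscle forces and joint contact forces (local-frame vectors from the load
#' case) are converted to the global basis and spread over their attachment
#' patches with moment-consistent distributing couplings. The method's load
#' rules decide which contact forces enter (the fixed-knee method omits
#' tibiofemoral and patellofemoral contact).
#'
#' @param model a `femur_model`
#' @param case a `load_case`
#' @param constraints a `constraint_set` (for its `load_rules`)
#' @return 3N x n_instances numeric load matrix (N)
#' @export
build_load_vectors <- function(model, case, constraints) {
  rules <- constraints$load_rules
  N <- nrow(model$nodes)
  Tn <- length(case$instances)
  f <- matrix(0, 3 * N, Tn)
  coup_cache <- new.env(parent = emptyenv())
  get_coupling <- function(patch_name) {
    if (!is.null(coup_cache[[patch_name]])) return(coup_cache[[patch_name]])
    p <- model$attachment_patches[[patch_name]]
    if (is.null(p)) stop("model lacks attachment patch: ", patch_name)
    cp <- build_coupling(p$refpoint, model$nodes[p$nodes, , drop = FALSE],
                         "distributing")
    coup_cache[[patch_name]] <- list(cp = cp, nodes = p$nodes)
    coup_cache[[patch_name]]
  }
  add_force <- function(k, patch_name, F_local) {
    F_g <- as.numeric(transform_from_frame(F_local, model$frame))
    gc_ <- get_coupling(patch_name)
    Fl <- gc_$cp$distribute(F_g)
    dof <- 3L * (gc_$nodes - 1L)
    f[dof + 1L, k] <<- f[dof + 1L, k] + Fl[, 1]
    f[dof + 2L, k] <<- f[dof + 2L, k] + Fl[, 2]
    f[dof + 3L, k] <<- f[dof + 3L, k] + Fl[, 3]
  }
  hip_via_slider <- !is.null(rules$hip_via)
  slider_F <- matrix(0, 3, Tn)
  for (k in seq_len(Tn)) {
    if (isTRUE(rules$muscles)) {
      for (nm in names(case$forces[[k]])) add_force(k, nm, case$forces[[k]][[nm]])
    }
    cc <- case$contact[[k]]
    if (isTRUE(rules$hip)) {
      if (hip_via_slider) {
        slider_F[, k] <- as.numeric(transform_from_frame(cc$hip_jcf,
                                                         model$frame))
      } else {
        add_force(k, "hip_contact", cc$hip_jcf)
      }
    }
    if (isTRUE(rules$tf)) add_force(k, "tf_contact", cc$tibiofemoral_jcf)
    if (isTRUE(rules$pf)) add_force(k, "pf_contact", cc$patellofemoral_jcf)
  }
  if (hip_via_slider && isTRUE(rules$hip)) {
    attr(f, "slider_loads") <- stats::setNames(list(slider_F), rules$hip_via)
  }
  f
}

#' Run one boundary-condition method on a femur under a load case
#'
#' Convenience wrapper: builds (or accepts) the constraint set, assembles the
#' loads under its load rules, solves all stance instances, and recovers the
#' element fields.
#'
#' @param model a `femur_model`
#' @param materials a `material_table`
#' @param method a method name or a ready `constraint_set`
#' @param case a `load_case`
#' @param system optional pre-assembled `fe_system` (reused across methods)
#' @param ... passed to [build_constraints()]
#' @return list with `result` (`fe_result`), `fields` (from
#'   [recover_fields()]), `constraints`, `system`
#' @export
run_method <- function(model, materials, method, case, system = NULL, ...) {
  cs <- if (inherits(method, "constraint_set")) method
  else build_constraints(model, method, ...)
  if (is.null(system)) system <- assemble(model, materials)
  loads <- build_load_vectors(model, case, cs)
  res <- solve_static(system, cs, loads)
  fields <- recover_fields(system, res$U)
  list(result = res, fields = fields, constraints = cs, system = system)
}
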