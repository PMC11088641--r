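# Parametric synthetic femur generator.
#
# The femur is built as a generalized cylinder: elliptical cross-section rings
# are stacked along a centreline running from the distal condylar block, up the
# shaft, around a filleted bend at the neck base, and along the neck into a
# spherical head. Consecutive sections are connected into triangular prisms
# (via a fixed disk triangulation template) and each prism is split into three
# tetrahedra with an index-ordering rule that guarantees a conforming mesh.
# The construction is fully deterministic given the seed; no external mesher
# is involved. A hollow-cortex/cancellous-core structure is encoded through
# the per-element greyscale field, not through the mesh topology.

smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

#' Parameters of the synthetic femur
#'
#' Defaults describe a normal adult-scale femur: 420 mm length, 22 mm head
#' radius, 127 deg neck-shaft angle, 15 deg anteversion. Greyscale levels span
#' the CT segmentation window 1250-4095 used for density mapping; cortical and
#' cancellous levels are the two plateaus of the pseudo-CT field. The default
#' target edge length (5 mm) yields a desk-scale mesh of roughly 20-30k
#' tetrahedra.
#'
#' @param femur_length superior-inferior distance knee centre to head centre, mm
#' @param head_radius femoral head radius, mm
#' @param neck_length neck-base to head-centre distance, mm
#' @param neck_shaft_angle_deg NSA, angle between neck axis and distal shaft
#'   axis (90-160 deg)
#' @param anteversion_deg AVA, axial-plane angle of the neck relative to the
#'   posterior condylar axis; positive = anteversion (-30 to 60 deg)
#' @param shaft_outer_radius mid-shaft outer radius, mm
#' @param cortical_thickness diaphyseal cortical shell thickness, mm
#' @param target_edge_length nominal tetrahedron edge length, mm
#' @param cortical_gv,cancellous_gv greyscale plateaus of the pseudo-CT field
#' @param rng_seed integer seed for the (small) greyscale jitter
#' @return object of class `femur_params`
#' @export
femur_params <- function(femur_length = 420,
                         head_radius = 22,
                         neck_length = 55,
                         neck_shaft_angle_deg = 127,
                         anteversion_deg = 15,
                         shaft_outer_radius = 16,
                         cortical_thickness = 6,
                         target_edge_length = 5,
                         cortical_gv = 2200,
                         cancellous_gv = 1400,
                         rng_seed = 20240511L) {
  p <- list(femur_length = femur_length, head_radius = head_radius,
            neck_length = neck_length,
            neck_shaft_angle_deg = neck_shaft_angle_deg,
            anteversion_deg = anteversion_deg,
            shaft_outer_radius = shaft_outer_radius,
            cortical_thickness = cortical_thickness,
            target_edge_length = target_edge_length,
            cortical_gv = cortical_gv, cancellous_gv = cancellous_gv,
            rng_seed = as.integer(rng_seed))
  lengths <- c(femur_length, head_radius, neck_length, shaft_outer_radius,
               cortical_thickness, target_edge_length)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("all femur dimensions must be finite and positive")
  }
  if (neck_shaft_angle_deg < 90 || neck_shaft_angle_deg > 160) {
    stop("neck_shaft_angle_deg must lie in [90, 160]")
  }
  if (anteversion_deg < -30 || anteversion_deg > 60) {
    stop("anteversion_deg must lie in [-30, 60]")
  }
  if (neck_length <= head_radius) {
    stop("infeasible construction: neck_length must exceed head_radius")
  }
  if (cortical_gv < 0 || cancellous_gv < 0) stop("greyscale levels must be >= 0")
  class(p) <- "femur_params"
  p
}

# Disk triangulation template: centre node + n_r rings of n_theta nodes.
# Returns local 1-based ids and per-vertex radial fractions.
disk_template <- function(n_theta, n_r) {
  id <- function(i, j) 1L + (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  tris <- matrix(0L, 0, 3)
  # centre fan
  for (j in seq_len(n_theta)) {
    tris <- rbind(tris, c(1L, id(1L, j), id(1L, j + 1L)))
  }
  if (n_r > 1) {
    for (i in seq_len(n_r - 1L)) {
      for (j in seq_len(n_theta)) {
        a <- id(i, j); a1 <- id(i, j + 1L)
        b <- id(i + 1L, j); b1 <- id(i + 1L, j + 1L)
        tris <- rbind(tris, c(a, b, b1), c(a, b1, a1))
      }
    }
  }
  frac <- c(0, rep(seq_len(n_r) / n_r, each = n_theta))
  list(tris = tris, frac = frac, n_local = 1L + n_r * n_theta)
}

# Orientation-preserving prism relabelings that bring slot p (1..6) to slot 1.
.prism_perms <- rbind(
  c(1, 2, 3, 4, 5, 6),
  c(2, 3, 1, 5, 6, 4),
  c(3, 1, 2, 6, 4, 5),
  c(4, 6, 5, 1, 3, 2),
  c(5, 4, 6, 2, 1, 3),
  c(6, 5, 4, 3, 2, 1)
)

# Split prisms (rows: bottom v1 v2 v3, top v4 v5 v6, bottom triangle oriented
# toward the top) into 3 tets each, with the minimum-global-index diagonal
# rule so that shared quad faces receive the same diagonal on both sides.
split_prisms <- function(P) {
  n <- nrow(P)
  amin <- max.col(-P, ties.method = "first")
  Q <- matrix(0L, n, 6)
  for (p in 1:6) {
    rows <- amin == p
    if (any(rows)) Q[rows, ] <- P[rows, .prism_perms[p, ], drop = FALSE]
  }
  use_a <- pmin(Q[, 2], Q[, 6]) < pmin(Q[, 3], Q[, 5])
  tets <- matrix(0L, 3L * n, 4)
  ia <- which(use_a); ib <- which(!use_a)
  if (length(ia)) {
    tets[3 * (ia - 1) + 1, ] <- cbind(Q[ia, 1], Q[ia, 2], Q[ia, 3], Q[ia, 6])
    tets[3 * (ia - 1) + 2, ] <- cbind(Q[ia, 1], Q[ia, 2], Q[ia, 6], Q[ia, 5])
    tets[3 * (ia - 1) + 3, ] <- cbind(Q[ia, 1], Q[ia, 5], Q[ia, 6], Q[ia, 4])
  }
  if (length(ib)) {
    tets[3 * (ib - 1) + 1, ] <- cbind(Q[ib, 1], Q[ib, 2], Q[ib, 3], Q[ib, 5])
    tets[3 * (ib - 1) + 2, ] <- cbind(Q[ib, 1], Q[ib, 5], Q[ib, 3], Q[ib, 6])
    tets[3 * (ib - 1) + 3, ] <- cbind(Q[ib, 1], Q[ib, 5], Q[ib, 6], Q[ib, 4])
  }
  tets
}

#' Generate a synthetic femur model
#'
#' Builds a watertight tetrahedral femur-like solid: spherical head on an
#' angled, anteverted neck; tapered shaft with a greater-trochanter bulge; and
#' a widened elliptical condylar block distally. Landmarks, surface patches
#' (head articulating surface, condylar region, greater trochanter, muscle
#' attachment areas) and the four diaphyseal strain-path node sequences are
#' populated by construction. Cortical and cancellous bone are encoded in the
#' per-element greyscale field from the element's depth below the outer
#' surface.
#'
#' The canonical pose places the knee centre at the origin, the shaft along
#' +z (superior), the lateral direction along +x (right femur) and the
#' anterior direction along -y, matching the anatomical frame convention of
#' [build_frame()].
#'
#' @param params a [femur_params()] object
#' @return object of class `femur_model`: list with `nodes` (N x 3 mm),
#'   `tets` (M x 4), `element_gv`, `landmarks` (named list of positions),
#'   `attachment_patches`, `strain_paths`, `surface_nodes`, `frame`, `params`
#' @export
generate_femur <- function(params = femur_params()) {
  stopifnot(inherits(params, "femur_params"))
  L <- params$femur_length
  R <- params$head_radius
  Ln <- params$neck_length
  nsa <- deg2rad(params$neck_shaft_angle_deg)
  ava <- deg2rad(params$anteversion_deg)
  r_sh <- params$shaft_outer_radius
  h <- params$target_edge_length

  # --- centreline geometry -------------------------------------------------
  zhat <- c(0, 0, 1)
  # neck transverse direction: medial (-x) rotated by AVA toward anterior (-y)
  t_hat <- c(-cos(ava), -sin(ava), 0)
  d_neck <- sin(nsa) * t_hat - cos(nsa) * zhat
  z_nb <- L + Ln * cos(nsa)            # so the head centre sits at height L
  if (z_nb <= 0.55 * L) stop("infeasible construction: neck base too low")
  nb <- c(0, 0, z_nb)
  hc <- nb + Ln * d_neck

  phi <- acos(max(-1, min(1, sum(d_neck * zhat))))   # bend angle at neck base
  R_f <- min(30, 0.45 * z_nb / max(tan(phi / 2), 1e-9),
             0.55 * Ln / max(tan(phi / 2), 1e-9))
  t_f <- R_f * tan(phi / 2)
  if (t_f >= Ln - R) stop("infeasible construction: neck too short for bend fillet")
  w_axis <- unit_vec(cross3(zhat, d_neck))           # bend rotation axis
  u_in <- unit_vec(d_neck - sum(d_neck * zhat) * zhat) # horizontal turn dir
  T1 <- nb - t_f * zhat
  arc_centre <- T1 + R_f * u_in

  L1 <- z_nb - t_f
  La <- R_f * phi
  L2 <- (Ln - t_f) + R          # straight neck + head, up to the apex
  s_T2 <- L1 + La
  s_hc <- s_T2 + (Ln - t_f)     # arclength of the head centre
  s_gt <- s_T2                  # greater-trochanter bulge centred at neck base

  centre_at <- function(s) {
    if (s <= L1) return(list(p = c(0, 0, s), d = zhat))
    if (s <= s_T2) {
      a <- (s - L1) / R_f
      Rm <- rotation_about_axis(w_axis, a)
      list(p = arc_centre + R_f * as.numeric(Rm %*% (-u_in)),
           d = as.numeric(Rm %*% zhat))
    } else {
      list(p = nb + t_f * d_neck + (s - s_T2) * d_neck, d = d_neck)
    }
  }

  # --- station sampling ----------------------------------------------------
  r_neck <- 0.62 * R
  s_head_on <- s_hc - sqrt(max(R^2 - r_neck^2, 0))  # sphere overtakes neck
  n1 <- max(2L, ceiling(L1 / h)); s1 <- seq(0, L1, length.out = n1 + 1L)
  na <- max(2L, ceiling(La / h))
  sa <- seq(L1, s_T2, length.out = na + 1L)[-1]
  Lneck <- s_head_on - s_T2
  nn <- max(2L, ceiling(Lneck / h))
  sn <- seq(s_T2, s_head_on, length.out = nn + 1L)[-1]
  # spherical head: stations by polar angle until the ring radius ~ 0.8 h
  phi_max <- acos(min(1, 0.8 * h / R))
  d0 <- sqrt(max(R^2 - r_neck^2, 0))
  phi_on <- asin(max(-1, min(1, -d0 / R)))
  nsph <- max(3L, ceiling(R * (phi_max - phi_on) / h))
  ssph <- s_hc + R * sin(seq(phi_on, phi_max, length.out = nsph + 1L)[-1])
  stations_s <- c(s1, sa, sn, ssph)

  # --- per-station profile -------------------------------------------------
  Lc <- 0.10 * L                 # condylar block span
  Lt <- 35                       # condyle-to-shaft transition
  a_c <- 2.2 * r_sh; b_c <- 1.7 * r_sh
  prof <- function(s) {
    # returns list(a, b, on_sphere, t_cort)
    tc <- params$cortical_thickness
    if (s >= s_head_on) {
      d <- s - s_hc
      r <- sqrt(max(R^2 - d^2, (0.5 * h)^2))
      return(list(a = r, b = r, sphere = TRUE, t_cort = 0.4 * tc))
    }
    w_cs <- smoothstep((s - Lc) / Lt)          # condyle -> shaft
    a <- a_c + (r_sh - a_c) * w_cs
    b <- b_c + (r_sh - b_c) * w_cs
    w_sn <- smoothstep((s - L1) / (s_T2 - L1)) # shaft -> neck across the bend
    a <- a + (r_neck - a) * w_sn
    b <- b + (r_neck - b) * w_sn
    # distal rounding for cap quality
    g0 <- 0.88 + 0.12 * smoothstep(s / (0.35 * Lc))
    tc_loc <- (0.45 + 0.55 * w_cs) * tc
    tc_loc <- tc_loc + (0.5 * tc - tc_loc) * w_sn
    list(a = a * g0, b = b * g0, sphere = FALSE, t_cort = tc_loc)
  }
  gt_amp <- function(s) 0.5 * exp(-((s - s_gt) / 20)^2) *
    (1 - smoothstep((s - s_gt) / 12))   # fade before the head
  # metaphyseal flare: the intertrochanteric region of a real femur is
  # roughly 1.5x the mid-shaft diameter, stiffening the proximal frame corner
  flare <- function(s) 0.5 * exp(-((s - (z_nb - 20)) / 35)^2) *
    (1 - smoothstep((s - s_gt - 5) / 15))

  n_theta <- max(12L, ceiling(2 * pi * r_sh / h))
  n_r <- max(2L, round(r_sh / h))
  tmpl <- disk_template(n_theta, n_r)
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  lat_dir <- -t_hat                       # greater trochanter: opposite the neck

  n_stat <- length(stations_s)
  n_per <- tmpl$n_local
  nodes <- matrix(0, n_stat * n_per + 2L, 3)  # + distal and proximal apices
  info <- vector("list", n_stat)
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0); d_prev <- zhat
  for (k in seq_len(n_stat)) {
    ca <- centre_at(stations_s[k])
    # parallel-transport the section frame
    cr <- cross3(d_prev, ca$d)
    sn_ <- sqrt(sum(cr^2)); cs_ <- sum(d_prev * ca$d)
    if (sn_ > 1e-14) {
      Rm <- rotation_about_axis(cr, atan2(sn_, cs_))
      e1 <- as.numeric(Rm %*% e1); e2 <- as.numeric(Rm %*% e2)
    }
    d_prev <- ca$d
    pr <- prof(stations_s[k])
    # section boundary with lateral greater-trochanter bulge and flare
    lp <- lat_dir - sum(lat_dir * ca$d) * ca$d
    lp <- if (sqrt(sum(lp^2)) > 1e-9) unit_vec(lp) else c(0, 0, 0)
    bnd <- outer(cos(theta), e1 * pr$a) + outer(sin(theta), e2 * pr$b)
    if (!pr$sphere) {
      edir <- bnd / sqrt(rowSums(bnd^2))
      mult <- 1 + flare(stations_s[k]) +
        gt_amp(stations_s[k]) * pmax(0, edir %*% lp)^2
      bnd <- bnd * as.numeric(mult)
    }
    off <- (k - 1L) * n_per
    nodes[off + 1L, ] <- ca$p
    for (i in seq_len(n_r)) {
      f <- i / n_r
      nodes[off + 1L + (i - 1L) * n_theta + seq_len(n_theta), ] <-
        sweep(f * bnd, 2, ca$p, `+`)
    }
    info[[k]] <- list(s = stations_s[k], centre = ca$p, d = ca$d,
                      a = pr$a, b = pr$b, sphere = pr$sphere,
                      t_cort = pr$t_cort)
  }
  apex_d <- n_stat * n_per + 1L
  apex_p <- n_stat * n_per + 2L
  cap_depth <- min(h, 8)
  nodes[apex_d, ] <- c(0, 0, -cap_depth)
  nodes[apex_p, ] <- hc + R * d_neck

  # --- elements ------------------------------------------------------------
  ntri <- nrow(tmpl$tris)
  layer <- rep(seq_len(n_stat - 1L), each = ntri)
  tri_id <- rep(seq_len(ntri), times = n_stat - 1L)
  botoff <- (layer - 1L) * n_per
  P <- cbind(botoff + tmpl$tris[tri_id, 1], botoff + tmpl$tris[tri_id, 2],
             botoff + tmpl$tris[tri_id, 3],
             botoff + n_per + tmpl$tris[tri_id, 1],
             botoff + n_per + tmpl$tris[tri_id, 2],
             botoff + n_per + tmpl$tris[tri_id, 3])
  tets <- split_prisms(P)
  tet_layer <- rep(layer, each = 3L)
  tet_tri <- rep(tri_id, each = 3L)

  # caps: distal (apex below first section), proximal (head apex)
  cap_d <- cbind(tmpl$tris[, 1], tmpl$tris[, 3], tmpl$tris[, 2], apex_d)
  topoff <- (n_stat - 1L) * n_per
  cap_p <- cbind(topoff + tmpl$tris[, 1], topoff + tmpl$tris[, 2],
                 topoff + tmpl$tris[, 3], apex_p)
  tets <- rbind(tets, cap_d, cap_p)
  tet_layer <- c(tet_layer, rep(1L, ntri), rep(n_stat - 1L, ntri))
  tet_tri <- c(tet_tri, seq_len(ntri), seq_len(ntri))

  storage.mode(tets) <- "integer"
  vols <- tet_volumes(nodes, tets)
  neg <- vols <= 0
  if (any(neg)) {
    tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
    vols[neg] <- -vols[neg]
  }
  if (any(vols <= 1e-12)) {
    stop("infeasible parameter combination: degenerate elements in generated mesh")
  }

  # --- greyscale field -----------------------------------------------------
  tri_frac <- rowMeans(matrix(tmpl$frac[tmpl$tris], ncol = 3))
  rmin_k <- vapply(info, function(z) min(z$a, z$b), numeric(1))
  tc_k <- vapply(info, function(z) z$t_cort, numeric(1))
  depth <- (1 - tri_frac[tet_tri]) * rmin_k[tet_layer]
  cortical <- depth < tc_k[tet_layer]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(params$rng_seed)
  jit <- stats::runif(nrow(tets), 0.98, 1.02)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  gv <- ifelse(cortical, params$cortical_gv, params$cancellous_gv) * jit
  gv <- pmax(gv, 0)

  # --- surface, landmarks, patches ----------------------------------------
  bfaces <- boundary_faces(tets)
  surf <- sort(unique(as.integer(bfaces)))
  spos <- nodes[surf, , drop = FALSE]

  nearest_surface <- function(target) surf[which.max(-rowSums(sweep(spos, 2, target)^2))]
  ball_patch <- function(anchor, radius) {
    ctr <- nodes[nearest_surface(anchor), ]
    surf[rowSums(sweep(spos, 2, ctr)^2) <= radius^2]
  }

  lat_proj <- as.numeric(spos %*% lat_dir)
  gt_zone <- which(abs(spos[, 3] - z_nb) < 28 & lat_proj > 0)
  gt_node <- surf[gt_zone[which.max(lat_proj[gt_zone])]]
  landmarks <- list(
    head_center = hc,
    knee_center = c(0, 0, 0),
    neck_base = nb,
    lateral_epicondyle = nodes[nearest_surface(c(a_c, 0, 0.5 * Lc)), ],
    greater_trochanter_lateral = nodes[gt_node, ],
    mid_diaphysis = nodes[nearest_surface(c(r_sh, 0, 0.5 * L)), ],
    # exact mirror pair on the analytic condylar ellipse, so the posterior
    # condylar axis is parallel to ML by construction (node snapping would
    # skew it by up to half an angular grid spacing)
    post_condyle_medial = local({
      pr <- prof(0.3 * Lc)
      c(-pr$a * cos(deg2rad(60)), pr$b * sin(deg2rad(60)), 0.3 * Lc)
    }),
    post_condyle_lateral = local({
      pr <- prof(0.3 * Lc)
      c(pr$a * cos(deg2rad(60)), pr$b * sin(deg2rad(60)), 0.3 * Lc)
    })
  )

  dist_hc <- sqrt(rowSums(sweep(spos, 2, hc)^2))
  ax_hc <- as.numeric(sweep(spos, 2, hc) %*% d_neck)
  head_patch <- surf[abs(dist_hc - R) < 0.1 * R & ax_hc > -0.45 * R]
  condylar_patch <- surf[spos[, 3] < 0.05 * L]
  gt_patch <- ball_patch(landmarks$greater_trochanter_lateral, 10)

  patches <- list(
    hip_contact = list(refpoint = hc, nodes = head_patch),
    tf_contact = list(refpoint = c(0, 0, 0),
                      nodes = surf[spos[, 3] < 0.025 * L]),
    pf_contact = list(refpoint = NULL, nodes = ball_patch(c(0, -b_c, 0.55 * Lc), 12)),
    glut_med = list(refpoint = NULL,
                    nodes = ball_patch(landmarks$greater_trochanter_lateral +
                                         c(0, 0, 6), 14)),
    glut_max = list(refpoint = NULL, nodes = ball_patch(c(4, r_sh, z_nb - 55), 14)),
    iliopsoas = list(refpoint = NULL, nodes = ball_patch(c(-r_sh, 0.5 * r_sh,
                                                           z_nb - 35), 11)),
    vasti = list(refpoint = NULL, nodes = ball_patch(c(0.3 * r_sh, -r_sh,
                                                       0.62 * z_nb), 18)),
    adductors = list(refpoint = NULL, nodes = ball_patch(c(-r_sh, 0, 0.5 * z_nb), 14)),
    gastroc_med = list(refpoint = NULL, nodes = ball_patch(c(-0.5 * a_c, b_c,
                                                             0.8 * Lc), 11)),
    gastroc_lat = list(refpoint = NULL, nodes = ball_patch(c(0.5 * a_c, b_c,
                                                             0.8 * Lc), 11)),
    ext_rotators = list(refpoint = NULL,
                        nodes = ball_patch(c(0.3 * r_sh, 1.6 * r_sh,
                                             z_nb - 18), 11)),
    tfl = list(refpoint = NULL,
               nodes = ball_patch(landmarks$greater_trochanter_lateral +
                                    c(3, -10, 14), 9))
  )
  for (nm in names(patches)) {
    if (!length(patches[[nm]]$nodes)) stop("empty attachment patch: ", nm)
    if (is.null(patches[[nm]]$refpoint)) {
      patches[[nm]]$refpoint <- colMeans(nodes[patches[[nm]]$nodes, , drop = FALSE])
    }
  }

  # strain paths: surface meridians on the diaphysis, 20-80% of femur length
  path_dirs <- list(medial = c(-1, 0, 0), lateral = c(1, 0, 0),
                    anterior = c(0, -1, 0), posterior = c(0, 1, 0))
  zt <- seq(0.2 * L, 0.8 * L, length.out = 25)
  strain_paths <- lapply(path_dirs, function(dd) {
    idx <- integer(0)
    for (z in zt) {
      cand <- which(abs(spos[, 3] - z) < 0.9 * h)
      if (!length(cand)) next
      idx <- c(idx, surf[cand[which.max(spos[cand, , drop = FALSE] %*% dd)]])
    }
    unique(idx)
  })

  model <- structure(list(
    nodes = nodes, tets = tets, element_gv = as.numeric(gv),
    landmarks = landmarks,
    attachment_patches = patches,
    strain_paths = strain_paths,
    surface_nodes = surf, boundary_faces = bfaces,
    params = params
  ), class = "femur_model")
  model$frame <- build_frame(landmarks)

  nsa_meas <- measure_nsa(model)
  ava_meas <- measure_ava(model)
  if (abs(nsa_meas - params$neck_shaft_angle_deg) > 0.5 ||
      abs(ava_meas - params$anteversion_deg) > 0.5) {
    stop(sprintf(paste0("generator self-check failed: measured NSA %.2f / AVA %.2f",
                        " vs requested %.1f / %.1f"),
                 nsa_meas, ava_meas, params$neck_shaft_angle_deg,
                 params$anteversion_deg))
  }
  model
}

#' @export
print.femur_model <- function(x, ...) {
  cat(sprintf("femur_model: %d nodes, %d C3D4 tets, GV range [%.0f, %.0f]\n",
              nrow(x$nodes), nrow(x$tets), min(x$element_gv), max(x$element_gv)))
  cat(sprintf("  NSA %.1f deg, AVA %.1f deg, length %.0f mm\n",
              measure_nsa(x), measure_ava(x),
              sqrt(sum((x$landmarks$head_center - x$landmarks$knee_center)^2))))
  invisible(x)
}
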