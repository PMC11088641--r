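# Femur deformation toolbox: incremental mesh warps to target anteversion and
# neck-shaft angles, with mesh-quality tracking.
#
# Both warps are ramped rigid rotations: every node rotates about a fixed axis
# by an angle that blends smoothly (cosine ramp) along an axial coordinate, so
# torsion is distributed over the bone instead of applied as a step. The total
# rotation magnitude is found by root-solving the measured angle on the
# landmark set (cheap, since only landmarks need rotating), then applied to
# the full mesh in increments with an element-inversion check after each one.

#' Deformity warp specification
#'
#' @param target_ava_deg target anteversion angle (deg), or NA
#' @param target_nsa_deg target neck-shaft angle (deg), or NA
#' @param n_increments number of warp increments (inversion checked after each)
#' @param blend_span axial span (mm) over which the rotation ramps from 0 to
#'   full; `NULL` selects the per-warp default (200 mm along the mechanical
#'   axis for anteversion, 40 mm along the neck axis for neck-shaft)
#' @return object of class `deformity_spec`
#' @export
deformity_spec <- function(target_ava_deg = NA, target_nsa_deg = NA,
                           n_increments = 20, blend_span = NULL) {
  if (n_increments < 1) stop("n_increments must be >= 1")
  if (!is.null(blend_span) && blend_span <= 0) stop("blend_span must be positive")
  structure(list(target_ava_deg = target_ava_deg,
                 target_nsa_deg = target_nsa_deg,
                 n_increments = as.integer(n_increments),
                 blend_span = blend_span),
            class = "deformity_spec")
}

# cosine ramp: 0 below lo, 1 above hi, C1 in between
cos_ramp <- function(x, lo, hi) {
  w <- (x - lo) / (hi - lo)
  w <- pmin(1, pmax(0, w))
  0.5 - 0.5 * cos(pi * w)
}

# Apply a ramped rotation about `axis` through `origin`: point at ramp weight
# w rotates by w * theta. `coord` is the ramp coordinate of each point.
ramped_rotation <- function(pts, coord, lo, hi, axis, theta, origin) {
  w <- cos_ramp(coord, lo, hi)
  out <- pts
  active <- which(w > 0)
  for (grp in split(active, round(w[active] * 1e12))) {
    R <- rotation_about_axis(axis, w[grp[1]] * theta)
    out[grp, ] <- sweep(sweep(pts[grp, , drop = FALSE], 2, origin) %*% t(R),
                        2, origin, `+`)
  }
  out
}

warp_landmarks <- function(landmarks, coord_fun, lo, hi, axis, theta, origin) {
  nm <- names(landmarks)
  pos <- do.call(rbind, landmarks)
  out <- ramped_rotation(pos, coord_fun(pos), lo, hi, axis, theta, origin)
  stats::setNames(lapply(seq_len(nrow(out)), function(i) out[i, ]), nm)
}

#' Mesh quality report
#'
#' Scaled Jacobian (element volume over the volume of the regular tetrahedron
#' with the same RMS edge length), aspect ratio (longest/shortest edge),
#' inversion count, and total-volume change against a reference model.
#'
#' @param model a `femur_model` or mesh list
#' @param reference optional reference model for the volume-change fraction
#' @return object of class `quality_report`
#' @export
mesh_quality <- function(model, reference = NULL) {
  nodes <- model$nodes; tets <- model$tets
  vol <- tet_volumes(nodes, tets)
  edges <- cbind(tets[, c(1, 2), drop = FALSE], tets[, c(1, 3), drop = FALSE],
                 tets[, c(1, 4), drop = FALSE], tets[, c(2, 3), drop = FALSE],
                 tets[, c(2, 4), drop = FALSE], tets[, c(3, 4), drop = FALSE])
  el2 <- matrix(0, nrow(tets), 6)
  for (e in 1:6) {
    d <- nodes[edges[, 2 * e - 1], , drop = FALSE] -
      nodes[edges[, 2 * e], , drop = FALSE]
    el2[, e] <- rowSums(d^2)
  }
  lrms <- sqrt(rowMeans(el2))
  vreg <- lrms^3 / (6 * sqrt(2))          # regular tet volume at that edge
  sj <- vol / vreg
  ar <- sqrt(apply(el2, 1, max) / apply(el2, 1, min))
  vcf <- if (!is.null(reference)) {
    vr <- sum(tet_volumes(reference$nodes, reference$tets))
    (sum(abs(vol)) - vr) / vr
  } else 0
  structure(list(min_scaled_jacobian = min(sj),
                 max_aspect_ratio = max(ar),
                 n_inverted_elements = sum(vol <= 0),
                 volume_change_fraction = vcf),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(paste0("mesh quality: min scaled Jacobian %.3f, max aspect %.2f, ",
                     "%d inverted, volume change %.3f%%\n"),
              x$min_scaled_jacobian, x$max_aspect_ratio,
              x$n_inverted_elements, 100 * x$volume_change_fraction))
  invisible(x)
}

# shared driver for both warps
apply_warp <- function(model, spec, axis, origin, coord_fun, lo, hi,
                       measure, target) {
  current <- measure(model$landmarks)
  if (abs(target - current) < 1e-12) {
    qr_ <- mesh_quality(model, model)
    return(list(model = model, quality = qr_, theta_deg = 0))
  }
  # root-solve the total rotation on the landmark set only
  f <- function(theta) {
    lms <- warp_landmarks(model$landmarks, coord_fun, lo, hi, axis,
                          deg2rad(theta), origin)
    measure(lms) - target
  }
  # measured angle responds nearly linearly (slope about +/-1) to theta;
  # estimate the slope, then bracket around the predicted rotation
  d0 <- target - current
  slope <- (f(1) - f(-1)) / 2
  if (abs(slope) < 1e-6) stop("warp rotation axis does not move the measured angle")
  guess <- d0 / slope
  half <- max(10, 0.5 * abs(guess))
  lob <- guess - half; hib <- guess + half
  for (k in 1:6) {
    if (f(lob) * f(hib) <= 0) break
    lob <- lob - half; hib <- hib + half
  }
  if (f(lob) * f(hib) > 0) stop("could not bracket warp rotation for target angle")
  theta <- stats::uniroot(f, c(lob, hib), tol = 1e-10)$root
  ref <- model
  out <- model
  dth <- deg2rad(theta) / spec$n_increments
  for (k in seq_len(spec$n_increments)) {
    out$nodes <- ramped_rotation(out$nodes, coord_fun(out$nodes), lo, hi,
                                 axis, dth, origin)
    vol <- tet_volumes(out$nodes, out$tets)
    if (any(vol <= 0)) {
      qr_ <- mesh_quality(out, ref)
      stop(sprintf("warp aborted at increment %d: %d inverted elements",
                   k, qr_$n_inverted_elements))
    }
  }
  out$landmarks <- warp_landmarks(model$landmarks, coord_fun, lo, hi, axis,
                                  deg2rad(theta), origin)
  # attachment reference points ride along with the warp
  for (nm in names(out$attachment_patches)) {
    rp <- matrix(out$attachment_patches[[nm]]$refpoint, 1, 3)
    out$attachment_patches[[nm]]$refpoint <-
      as.numeric(ramped_rotation(rp, coord_fun(rp), lo, hi, axis,
                                 deg2rad(theta), origin))
  }
  out$frame <- build_frame(out$landmarks)
  list(model = out, quality = mesh_quality(out, ref), theta_deg = theta)
}

#' Warp a femur to a target anteversion angle
#'
#' Rotates nodes about the mechanical (head-knee) axis by an angle ramping
#' from zero at the distal condyles to the full rotation proximal to the
#' lesser-trochanter level (cosine blend over `blend_span`). Landmarks,
#' attachment reference points and the frame co-rotate; greyscale values and
#' patch memberships are untouched. The mechanical axis passes through both
#' the head centre and knee centre, so the axis itself is invariant and warps
#' compose exactly (applying +delta then -delta restores node positions).
#'
#' @param model a `femur_model`
#' @param spec a [deformity_spec()] with `target_ava_deg` set
#' @return list with `model` (warped), `quality` (a `quality_report`), and
#'   `theta_deg` (total rotation applied about the mechanical axis)
#' @export
apply_anteversion <- function(model, spec = deformity_spec()) {
  target <- spec$target_ava_deg
  if (is.na(target)) stop("spec$target_ava_deg is required")
  cur <- measure_ava(model)
  if (abs(target - cur) > 90) stop("anteversion change exceeds 90 degrees")
  lm <- model$landmarks
  axis <- unit_vec(lm$head_center - lm$knee_center)
  origin <- lm$knee_center
  t_head <- sum((lm$head_center - lm$knee_center) * axis)
  hi <- 0.85 * t_head                       # lesser-trochanter level
  span <- spec$blend_span %||% 200
  lo <- max(0.12 * t_head, hi - span)       # keep the condyles fixed
  coord_fun <- function(p) as.numeric(sweep(p, 2, origin) %*% axis)
  measure <- function(lms) {
    m <- model; m$landmarks <- lms
    measure_ava(m)
  }
  apply_warp(model, spec, axis, origin, coord_fun, lo, hi, measure, target)
}

#' Warp a femur to a target neck-shaft angle
#'
#' Rotates the head and neck about the anterior-posterior axis through the
#' neck-base point, ramped along the neck axis (cosine blend over
#' `blend_span`) so the shaft and distal femur stay fixed.
#'
#' @param model a `femur_model`
#' @param spec a [deformity_spec()] with `target_nsa_deg` set
#' @return list with `model`, `quality`, `theta_deg` as [apply_anteversion()]
#' @export
apply_neck_shaft <- function(model, spec = deformity_spec()) {
  target <- spec$target_nsa_deg
  if (is.na(target)) stop("spec$target_nsa_deg is required")
  lm <- model$landmarks
  axis <- model$frame$ap
  origin <- lm$neck_base
  neck_dir <- unit_vec(lm$head_center - lm$neck_base)
  span <- spec$blend_span %||% 40
  coord_fun <- function(p) as.numeric(sweep(p, 2, origin) %*% neck_dir)
  measure <- function(lms) {
    m <- model; m$landmarks <- lms
    measure_nsa(m)
  }
  apply_warp(model, spec, axis, origin, coord_fun, 0, span, measure, target)
}
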