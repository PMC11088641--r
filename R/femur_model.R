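# Anatomical frame, head-sphere fitting, clinical angle measurement, and
# model validation.

#' Build the local anatomical frame from landmarks
#'
#' The superior-inferior axis runs from the knee centre to the femoral head
#' centre; the medial-lateral axis is the knee-centre-to-lateral-epicondyle
#' direction orthogonalised against the SI axis (Gram-Schmidt, since the
#' epicondyle direction is generally not perpendicular to the mechanical
#' axis); the anterior-posterior axis is their cross product `ap = ml x si`,
#' giving a right-handed orthonormal triad. For a right femur in the package's
#' canonical pose the AP axis points anteriorly.
#'
#' @param landmarks named list with at least `head_center`, `knee_center`,
#'   `lateral_epicondyle` positions (mm)
#' @return object of class `anatomical_frame`: list `si`, `ml`, `ap`
#'   (unit 3-vectors), `origin` (knee centre)
#' @export
build_frame <- function(landmarks) {
  hd <- landmarks$head_center; kn <- landmarks$knee_center
  ep <- landmarks$lateral_epicondyle
  if (is.null(hd) || is.null(kn) || is.null(ep)) {
    stop("landmarks must include head_center, knee_center, lateral_epicondyle")
  }
  siv <- hd - kn
  if (sqrt(sum(siv^2)) < 1e-9) stop("degenerate frame: head and knee coincide")
  si <- unit_vec(siv)
  mlv <- ep - kn
  mlv <- mlv - sum(mlv * si) * si
  if (sqrt(sum(mlv^2)) < 1e-9) {
    stop("degenerate frame: lateral epicondyle collinear with mechanical axis")
  }
  ml <- unit_vec(mlv)
  ap <- cross3(ml, si)
  structure(list(si = si, ml = ml, ap = ap, origin = kn),
            class = "anatomical_frame")
}

#' Least-squares sphere fit to the femoral head surface patch
#'
#' Algebraic least squares: `|x|^2 = 2 c . x + (r^2 - |c|^2)` is linear in the
#' centre `c` and offset, solved by QR. Exact for noise-free sphere samples;
#' for partial coverage (hemisphere) it remains well conditioned.
#'
#' @param model a `femur_model`, or a numeric matrix of points (n x 3)
#' @return list `center` (mm), `radius` (mm), `rms_residual` (mm)
#' @export
fit_head_sphere <- function(model) {
  pts <- if (is.matrix(model)) model else {
    idx <- model$landmarks$head_surface_patch
    if (is.null(idx)) idx <- model$attachment_patches$hip_contact$nodes
    model$nodes[idx, , drop = FALSE]
  }
  if (nrow(pts) < 4) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  if (qr(A)$rank < 4) stop("singular sphere fit: points are coplanar or degenerate")
  beta <- qr.solve(A, b)
  ctr <- beta[1:3]
  r2 <- beta[4] + sum(ctr^2)
  if (r2 <= 0) stop("singular sphere fit: non-positive squared radius")
  r <- sqrt(r2)
  res <- sqrt(rowSums(sweep(pts, 2, ctr)^2)) - r
  list(center = as.numeric(ctr), radius = r,
       rms_residual = sqrt(mean(res^2)))
}

#' Measure the neck-shaft angle (NSA) of a femur model
#'
#' Angle in degrees between the neck axis (neck base to head centre) and the
#' distal shaft axis (neck base to knee centre). A straight femur would score
#' 180 deg; typical adult values are 120-135 deg.
#'
#' @param model a `femur_model`
#' @return NSA in degrees
#' @export
measure_nsa <- function(model) {
  lm <- model$landmarks
  v_neck <- lm$head_center - lm$neck_base
  v_shaft <- lm$knee_center - lm$neck_base
  if (sqrt(sum(v_neck^2)) < 1e-9 || sqrt(sum(v_shaft^2)) < 1e-9) {
    stop("degenerate landmarks for NSA measurement")
  }
  rad2deg(acos(max(-1, min(1, sum(unit_vec(v_neck) * unit_vec(v_shaft))))))
}

#' Measure the anteversion angle (AVA) of a femur model
#'
#' Signed angle, in the plane transverse to the shaft axis, between the
#' projected neck axis and the projected posterior condylar axis (the standard
#' clinical convention). Anteversion (neck rotated anteriorly) is positive;
#' retroversion negative.
#'
#' @param model a `femur_model`
#' @return AVA in degrees
#' @export
measure_ava <- function(model) {
  lm <- model$landmarks
  s <- unit_vec(lm$neck_base - lm$knee_center)     # shaft axis, pointing proximal
  pc <- lm$post_condyle_lateral - lm$post_condyle_medial
  pc <- pc - sum(pc * s) * s                       # posterior condylar axis, transverse
  if (sqrt(sum(pc^2)) < 1e-9) stop("degenerate posterior condylar axis")
  pc <- unit_vec(pc)
  vn <- lm$head_center - lm$neck_base
  vn_t <- vn - sum(vn * s) * s
  if (sqrt(sum(vn_t^2)) < 1e-9) stop("neck axis parallel to shaft axis")
  # rotation from the medial direction (-pc) toward the neck projection,
  # positive about the proximal shaft axis = positive toward anterior
  rad2deg(signed_angle(-pc, unit_vec(vn_t), s))
}

#' Validate femur model invariants
#'
#' Checks strictly positive tetrahedron volumes, landmark positions inside the
#' mesh bounding box, patch indices on the surface, and a finite, non-negative
#' greyscale field. Called by tests and by the IO layer after reading.
#'
#' @param model a `femur_model`
#' @return invisibly TRUE; stops with a message on violation
#' @export
validate_model <- function(model) {
  v <- tet_volumes(model$nodes, model$tets)
  if (any(v <= 0)) stop(sum(v <= 0), " tetrahedra have non-positive volume")
  if (any(!is.finite(model$element_gv)) || any(model$element_gv < 0)) {
    stop("element greyscale values must be finite and >= 0")
  }
  lo <- apply(model$nodes, 2, min) - 1e-9
  hi <- apply(model$nodes, 2, max) + 1e-9
  for (nm in names(model$landmarks)) {
    p <- model$landmarks[[nm]]
    if (any(p < lo) || any(p > hi)) stop("landmark outside bounding box: ", nm)
  }
  surf <- model$surface_nodes
  for (nm in names(model$attachment_patches)) {
    if (!all(model$attachment_patches[[nm]]$nodes %in% surf)) {
      stop("patch contains non-surface nodes: ", nm)
    }
  }
  invisible(TRUE)
}
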