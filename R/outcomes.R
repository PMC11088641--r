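# Outcome measures: femoral head deflection (FHD), peak von Mises stress
# (PVMS) with an artefact-exclusion guard, cortical strain paths, and the
# R^2 / nRMSE comparison of each method against the inertia-relief benchmark.

# Locate the tetrahedron containing a point; returns element index and
# barycentric weights of its four nodes.
locate_point <- function(model, point, tol = 1e-8) {
  ctr <- (model$nodes[model$tets[, 1], ] + model$nodes[model$tets[, 2], ] +
            model$nodes[model$tets[, 3], ] + model$nodes[model$tets[, 4], ]) / 4
  ord <- order(rowSums(sweep(ctr, 2, point)^2))
  for (e in ord[seq_len(min(300, length(ord)))]) {
    X <- model$nodes[model$tets[e, ], ]
    A <- rbind(t(X), rep(1, 4))
    w <- tryCatch(solve(A, c(point, 1)), error = function(err) NULL)
    if (!is.null(w) && all(w > -tol)) {
      return(list(element = e, weights = w, nodes = model$tets[e, ]))
    }
  }
  stop("point (", paste(signif(point, 4), collapse = ", "),
       ") lies outside the mesh: interpolation impossible")
}

interp_displacement <- function(model, U, point) {
  loc <- locate_point(model, point)
  dof <- 3L * (loc$nodes - 1L)
  rbind(loc$weights %*% U[dof + 1L, , drop = FALSE],
        loc$weights %*% U[dof + 2L, , drop = FALSE],
        loc$weights %*% U[dof + 3L, , drop = FALSE])  # 3 x T
}

#' Femoral head deflection per stance instance
#'
#' Displacement of the hip joint centre relative to the knee joint centre
#' (both interpolated inside their containing tetrahedra), resolved onto the
#' local SI/ML/AP axes. Rigid whole-body translations cancel exactly.
#'
#' @param model a `femur_model`
#' @param result an `fe_result` (or 3N x T displacement matrix)
#' @return data.frame with columns `instance`, `fhd_si`, `fhd_ml`, `fhd_ap`,
#'   `fhd_resultant` (mm)
#' @export
femoral_head_deflection <- function(model, result) {
  U <- if (inherits(result, "fe_result")) result$U else as.matrix(result)
  uh <- interp_displacement(model, U, model$landmarks$head_center)
  uk <- interp_displacement(model, U, model$landmarks$knee_center)
  rel <- uh - uk                                    # 3 x T, global basis
  fr <- model$frame
  loc <- transform_to_frame(t(rel), fr)             # T x 3 (ml, ap, si)
  data.frame(instance = seq_len(nrow(loc)),
             fhd_si = loc[, 3], fhd_ml = loc[, 1], fhd_ap = loc[, 2],
             fhd_resultant = sqrt(rowSums(loc^2)))
}

# element centroids, cached computation
element_centroids <- function(model) {
  (model$nodes[model$tets[, 1], ] + model$nodes[model$tets[, 2], ] +
     model$nodes[model$tets[, 3], ] + model$nodes[model$tets[, 4], ]) / 4
}

# positions that may carry load-application or constraint artefacts
artefact_guard_points <- function(model, constraints = NULL) {
  pts <- do.call(rbind, lapply(model$attachment_patches, function(p)
    model$nodes[p$nodes, , drop = FALSE]))
  if (!is.null(constraints)) {
    dn <- unique(vapply(constraints$dirichlet, function(d) d$node, numeric(1)))
    if (length(dn)) pts <- rbind(pts, model$nodes[dn, , drop = FALSE])
    for (rc in constraints$rigid_couplings) {
      pts <- rbind(pts, model$nodes[rc$nodes, , drop = FALSE])
    }
  }
  pts
}

#' Peak von Mises stress per instance, outside artefact zones
#'
#' Maximum element von Mises stress over elements whose centroid lies farther
#' than `exclusion_radius` from every load-application patch node and every
#' Dirichlet-constrained node. The guard is applied identically to all
#' methods; comparisons between methods, not absolute extremes, are the
#' object.
#'
#' @param model a `femur_model`
#' @param fields output of [recover_fields()]
#' @param constraints the method's `constraint_set` (for constrained nodes)
#' @param exclusion_radius guard radius in mm (default 5)
#' @return numeric vector, PVMS (MPa) per instance
#' @export
peak_von_mises <- function(model, fields, constraints = NULL,
                           exclusion_radius = 5) {
  vm <- fields$von_mises
  keep <- rep(TRUE, nrow(vm))
  if (exclusion_radius > 0) {
    ctr <- element_centroids(model)
    guard <- artefact_guard_points(model, constraints)
    # block distance computation to bound memory
    mind2 <- rep(Inf, nrow(ctr))
    for (start in seq(1, nrow(guard), by = 500)) {
      g <- guard[start:min(start + 499, nrow(guard)), , drop = FALSE]
      d2 <- outer(rowSums(ctr^2), rep(1, nrow(g))) +
        outer(rep(1, nrow(ctr)), rowSums(g^2)) - 2 * ctr %*% t(g)
      mind2 <- pmin(mind2, apply(d2, 1, min))
    }
    keep <- mind2 > exclusion_radius^2
    if (!any(keep)) stop("exclusion radius removed every element")
  }
  apply(vm[keep, , drop = FALSE], 2, max)
}

#' Cortical strain along the four diaphyseal paths
#'
#' Samples the absolute principal strain (max |principal strain|) of the
#' surface element nearest each path node, in microstrain, for every instance;
#' a signed companion (extreme principal strain of largest magnitude, tension
#' positive) supports tension/compression pattern checks.
#'
#' @param model a `femur_model` with `strain_paths`
#' @param fields output of [recover_fields()]
#' @return named list per path (`medial`, `lateral`, `anterior`, `posterior`):
#'   list with `arc_mm` (positions along the path), `abs_ue` and `signed_ue`
#'   (n_points x T matrices, microstrain)
#' @export
cortical_strain_paths <- function(model, fields) {
  if (is.null(model$strain_paths)) stop("model has no strain paths")
  surf_elems <- which(rowSums(matrix(model$tets %in% model$surface_nodes,
                                     nrow(model$tets)) ) >= 3)
  ctr <- element_centroids(model)[surf_elems, , drop = FALSE]
  out <- list()
  for (nm in names(model$strain_paths)) {
    pn <- model$strain_paths[[nm]]
    pos <- model$nodes[pn, , drop = FALSE]
    arc <- c(0, cumsum(sqrt(rowSums(diff(pos)^2))))
    eidx <- vapply(seq_len(nrow(pos)), function(i) {
      surf_elems[which.min(rowSums(sweep(ctr, 2, pos[i, ])^2))]
    }, integer(1))
    out[[nm]] <- list(
      arc_mm = arc,
      elements = eidx,
      abs_ue = fields$abs_principal_strain[eidx, , drop = FALSE] * 1e6,
      signed_ue = fields$signed_principal_strain[eidx, , drop = FALSE] * 1e6)
  }
  out
}

#' Coefficient of determination against a reference series
#'
#' `1 - SS_res / SS_tot` with the reference treated as truth and `SS_tot`
#' taken about the reference mean (not a symmetric squared correlation).
#' Returns `NaN` (with a warning) for a constant reference.
#'
#' @param series numeric vector (method outcome)
#' @param reference numeric vector (benchmark outcome), same length
#' @return R^2 (dimensionless, <= 1)
#' @export
r_squared <- function(series, reference) {
  stopifnot(length(series) == length(reference))
  ss_tot <- sum((reference - mean(reference))^2)
  if (ss_tot == 0) {
    warning("constant reference series: R^2 undefined")
    return(NaN)
  }
  1 - sum((series - reference)^2) / ss_tot
}

#' Normalised root-mean-square error against a reference series
#'
#' RMSE of the difference divided by the reference's dynamic range
#' (max - min). Returns `NaN` (with a warning) for zero dynamic range.
#'
#' @inheritParams r_squared
#' @return nRMSE (dimensionless, >= 0)
#' @export
nrmse <- function(series, reference) {
  stopifnot(length(series) == length(reference))
  rng <- max(reference) - min(reference)
  if (rng == 0) {
    warning("zero dynamic range in reference series: nRMSE undefined")
    return(NaN)
  }
  sqrt(mean((series - reference)^2)) / rng
}

#' Collect the outcome series of one method run
#'
#' @param model a `femur_model`
#' @param run output of [run_method()]
#' @param exclusion_radius artefact guard radius for PVMS, mm
#' @return object of class `outcome_series`: list with `fhd` (data.frame),
#'   `pvms` (per instance, MPa), `strain_paths`, `method`
#' @export
outcome_series <- function(model, run, exclusion_radius = 5) {
  structure(list(
    method = run$constraints$method,
    fhd = femoral_head_deflection(model, run$result),
    pvms = peak_von_mises(model, run$fields, run$constraints,
                          exclusion_radius),
    strain_paths = cortical_strain_paths(model, run$fields)
  ), class = "outcome_series")
}

#' Compare method outcome series against the inertia-relief benchmark
#'
#' For every geometry and non-benchmark method: R^2 and nRMSE of the PVMS
#' series and each FHD component series versus the inertia-relief run of the
#' same geometry.
#'
#' @param outcomes nested list: `outcomes[[geometry]][[method]]` of
#'   `outcome_series`, each geometry containing an `inertia_relief` entry
#' @return data.frame with columns `geometry`, `method`, `metric`,
#'   `r_squared`, `nrmse`
#' @export
compare_report <- function(outcomes) {
  rows <- list()
  for (geom in names(outcomes)) {
    ref <- outcomes[[geom]]$inertia_relief
    if (is.null(ref)) stop("geometry ", geom, " lacks an inertia_relief run")
    for (meth in setdiff(names(outcomes[[geom]]), "inertia_relief")) {
      os <- outcomes[[geom]][[meth]]
      series <- list(pvms = list(os$pvms, ref$pvms),
                     fhd_si = list(os$fhd$fhd_si, ref$fhd$fhd_si),
                     fhd_ml = list(os$fhd$fhd_ml, ref$fhd$fhd_ml),
                     fhd_ap = list(os$fhd$fhd_ap, ref$fhd$fhd_ap),
                     fhd_resultant = list(os$fhd$fhd_resultant,
                                          ref$fhd$fhd_resultant))
      for (met in names(series)) {
        rows[[length(rows) + 1L]] <- data.frame(
          geometry = geom, method = meth, metric = met,
          r_squared = suppressWarnings(r_squared(series[[met]][[1]],
                                                 series[[met]][[2]])),
          nrmse = suppressWarnings(nrmse(series[[met]][[1]],
                                         series[[met]][[2]])))
      }
    }
  }
  do.call(rbind, rows)
}
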