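# Stance-phase loading fixture emulating the outputs of a neuromusculoskeletal
# pipeline: muscle forces and hip / tibiofemoral / patellofemoral joint contact
# forces at seven equally spaced stance instances, expressed in the local
# anatomical femur frame (components ordered ML, AP, SI).
#
# The paper-scale pipeline (EMG-informed modelling) is out of scope; the
# fixture pins physiologically scaled magnitudes: a bimodal hip contact force
# peaking at a configurable multiple of body weight, muscle forces directed
# from attachment-patch centroids toward fixed anatomical via-points, and
# joint contact forces closing the distal load path. Magnitudes are fixed by
# configuration, deterministic given the seed (a small multiplicative jitter
# emulates step-to-step variability).

GRAVITY_M_S2 <- 9.81

#' Gait load fixture parameters
#'
#' @param body_mass_kg participant body mass (default 93.4 kg)
#' @param hip_peak_bw hip joint contact force peak, in body weights (1-6)
#' @param pf_peak_bw patellofemoral contact peak, body weights
#' @param residual_bw magnitude (body weights) of the dynamic residual force
#'   left unbalanced after the tibiofemoral force closes the distal load path;
#'   it represents thigh-segment dynamics and is what inertia relief absorbs
#' @param muscle_gain scalar on all muscle forces (0 disables muscles)
#' @param jitter_sd relative s.d. of the per-instance magnitude jitter
#' @param rng_seed integer seed
#' @return object of class `gait_fixture_params`
#' @export
gait_fixture_params <- function(body_mass_kg = 93.4, hip_peak_bw = 2.4,
                                pf_peak_bw = 0.4, residual_bw = 0.05,
                                muscle_gain = 1, jitter_sd = 0.02,
                                rng_seed = 20240511L) {
  if (body_mass_kg <= 0) stop("body_mass_kg must be positive")
  if (hip_peak_bw < 1 || hip_peak_bw > 6) stop("hip_peak_bw must lie in [1, 6]")
  structure(list(body_mass_kg = body_mass_kg, hip_peak_bw = hip_peak_bw,
                 pf_peak_bw = pf_peak_bw, residual_bw = residual_bw,
                 muscle_gain = muscle_gain, jitter_sd = jitter_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "gait_fixture_params")
}

# muscle set: peak force (body weights), activation waveform over stance
# fraction tau in [0,1], and via-point offsets (mm) in the local frame
# (ml, ap, si) relative to an anchor landmark.
.muscle_table <- list(
  glut_med   = list(peak_bw = 1.5, anchor = "head",
                    via = c(20, 0, 105),
                    wave = function(tau) bimodal_wave(tau)),
  glut_max   = list(peak_bw = 0.6, anchor = "head",
                    via = c(-15, -45, 70),
                    wave = function(tau) exp(-((tau - 0.25) / 0.25)^2)),
  iliopsoas  = list(peak_bw = 0.5, anchor = "head",
                    via = c(-20, 30, 20),
                    wave = function(tau) exp(-((tau - 0.80) / 0.20)^2)),
  vasti      = list(peak_bw = 0.9, anchor = "knee",
                    via = c(0, 35, -20),
                    wave = function(tau) exp(-((tau - 0.20) / 0.22)^2)),
  adductors  = list(peak_bw = 0.5, anchor = "head",
                    via = c(-70, 10, -30),
                    wave = function(tau) exp(-((tau - 0.50) / 0.30)^2)),
  gastroc_med = list(peak_bw = 0.45, anchor = "knee",
                     via = c(-10, -30, -60),
                     wave = function(tau) exp(-((tau - 0.85) / 0.18)^2)),
  gastroc_lat = list(peak_bw = 0.35, anchor = "knee",
                     via = c(10, -30, -60),
                     wave = function(tau) exp(-((tau - 0.85) / 0.18)^2)),
  # short external rotators (piriformis/obturator group) and tensor fasciae
  # latae: modest forces, but the only lines of action with appreciable
  # moment arms about the shaft axis, closing axial moments as in vivo
  ext_rotators = list(peak_bw = 0.3, anchor = "head",
                      via = c(-45, -45, 5),
                      wave = function(tau) 0.5 + 0.5 * bimodal_wave(tau)),
  tfl = list(peak_bw = 0.25, anchor = "head",
             via = c(30, 35, 35),
             wave = function(tau) 0.5 + 0.5 * bimodal_wave(tau))
)

# double-peaked stance waveform (early- and late-stance maxima), normalised
# to a maximum of 1 over a dense grid
bimodal_wave <- function(tau) {
  raw <- exp(-((tau - 0.18) / 0.14)^2) + 0.85 * exp(-((tau - 0.78) / 0.14)^2)
  raw / 1.0
}

#' Generate the stance-phase load case for a femur model
#'
#' Produces forces at seven equally spaced stance instances: a bimodal hip
#' contact force whose maximum over the instances equals exactly
#' `hip_peak_bw * body weight`, tibiofemoral and patellofemoral contact
#' forces, and the muscle set above directed from each attachment patch
#' centroid toward its via-point. All vectors are expressed in the local
#' anatomical frame (ML, AP, SI components). The resulting load system is
#' deliberately not self-equilibrated: residual force and moment represent
#' segment dynamics and are what inertia relief absorbs.
#'
#' @param model a `femur_model` with the standard attachment patches
#' @param params a [gait_fixture_params()]
#' @return object of class `load_case`: list with `instances` (7 stance
#'   fractions), `forces` (list per instance: named attachment -> 3-vector N,
#'   local frame), `contact` (list per instance: `hip_jcf`, `tibiofemoral_jcf`,
#'   `patellofemoral_jcf`), `body_weight` (N)
#' @export
generate_stance_loads <- function(model, params = gait_fixture_params()) {
  needed <- c("glut_med", "glut_max", "iliopsoas", "vasti", "adductors",
              "gastroc_med", "gastroc_lat", "ext_rotators", "tfl",
              "hip_contact", "tf_contact", "pf_contact")
  missing <- setdiff(needed, names(model$attachment_patches))
  if (length(missing)) {
    stop("model lacks attachment patches: ", paste(missing, collapse = ", "))
  }
  bw <- params$body_mass_kg * GRAVITY_M_S2
  tau <- seq(0, 1, length.out = 7)
  fr <- model$frame
  to_local <- function(v_global) as.numeric(transform_to_frame(rbind(v_global), fr))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(params$rng_seed)
  jit <- function() stats::rnorm(7, 1, params$jitter_sd)

  # hip contact: compressive onto the head. A low-friction ball joint
  # transmits its resultant through the head centre towards the support line,
  # so the stance-phase hip force lies close to the mechanical axis (-SI in
  # the local frame): about 8 deg lateral in the frontal plane (13 deg off
  # the shaft axis, the instrumented-implant average), with a small
  # AP component swinging from braking to propulsion; scaled so the instance
  # maximum is exactly the configured peak
  hip_dirs <- t(vapply(tau, function(tt)
    unit_vec(c(sin(deg2rad(8)), -0.08 + 0.14 * tt, -cos(deg2rad(8)))),
    numeric(3)))
  hip_mag <- bimodal_wave(tau) * jit()
  hip_mag <- hip_mag / max(hip_mag) * params$hip_peak_bw * bw
  hip <- hip_dirs * hip_mag

  pf_mag <- exp(-((tau - 0.7) / 0.25)^2) * jit()
  pf_mag <- pf_mag / max(pf_mag) * params$pf_peak_bw * bw
  pf <- matrix(rep(unit_vec(c(0, -0.92, 0.40)), each = 7), 7, 3) * pf_mag

  anchors <- list(head = model$landmarks$head_center,
                  knee = model$landmarks$knee_center)
  frame_mat <- rbind(fr$ml, fr$ap, fr$si)   # local row basis
  mnames <- names(.muscle_table)
  mdir_g <- matrix(0, length(mnames), 3, dimnames = list(mnames, NULL))
  mpos_g <- matrix(0, length(mnames), 3, dimnames = list(mnames, NULL))
  mmag <- matrix(0, 7, length(mnames), dimnames = list(NULL, mnames))
  for (nm in mnames) {
    mu <- .muscle_table[[nm]]
    via_global <- anchors[[mu$anchor]] + as.numeric(t(frame_mat) %*% mu$via)
    ctr <- model$attachment_patches[[nm]]$refpoint
    mdir_g[nm, ] <- unit_vec(via_global - ctr)
    mpos_g[nm, ] <- ctr
    # baseline tone (5% of peak) keeps every muscle recruitable at all instances
    mmag[, nm] <- mu$peak_bw * bw * pmax(mu$wave(tau), 0.05) *
      params$muscle_gain * jit()
  }

  # The upstream pipeline this fixture emulates produces forces that satisfy
  # segment dynamics. Emulate that property: per instance, ridge-adjust the
  # nominal muscle magnitudes so the net moment about the knee centre closes
  # (muscle recruitment resolving the external moments), then let the
  # tibiofemoral contact close the force path, leaving only a small dynamic
  # residual (thigh-segment accelerations) unbalanced.
  knee <- model$landmarks$knee_center
  hip_pt <- model$landmarks$head_center
  pf_pt <- model$attachment_patches$pf_contact$refpoint
  hip_g <- transform_from_frame(hip, fr)
  pf_g <- transform_from_frame(pf, fr)
  marm <- t(vapply(mnames, function(nm)
    cross3(mpos_g[nm, ] - knee, mdir_g[nm, ]), numeric(3)))  # moment per unit force
  for (k in 1:7) {
    m_fixed <- cross3(hip_pt - knee, hip_g[k, ]) + cross3(pf_pt - knee, pf_g[k, ])
    A <- t(marm * mmag[k, ])           # 3 x n_muscles, moment at nominal magnitude
    rhs <- -(m_fixed + rowSums(A))
    if (params$muscle_gain > 0 && max(mmag[k, ]) > 0) {
      # clamped ridge passes: recruit within [0, 6] x nominal
      s <- rep(1, ncol(A))
      lam <- 5e-4 * max(colSums(A^2))
      for (it in 1:8) {
        res_m <- -(m_fixed + as.numeric(A %*% s))
        ds <- as.numeric(t(A) %*% solve(A %*% t(A) + lam * diag(3), res_m))
        s <- pmax(0, pmin(6, s + ds))
      }
      mmag[k, ] <- mmag[k, ] * s
    }
  }
  forces <- lapply(1:7, function(k) {
    fl <- list()
    for (nm in mnames) {
      fl[[nm]] <- to_local(mdir_g[nm, ]) * mmag[k, nm]
    }
    fl
  })

  resid_dir <- t(vapply(tau, function(tt)
    unit_vec(c(0.4 * sin(2 * pi * tt), 0.5 * cos(2 * pi * tt), 0.8)), numeric(3)))
  resid <- resid_dir * (params$residual_bw * bw * bimodal_wave(tau) * jit())
  tf <- matrix(0, 7, 3)
  for (k in 1:7) {
    tot <- hip[k, ] + pf[k, ] + Reduce(`+`, forces[[k]])
    tf[k, ] <- -tot + resid[k, ]
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  contact <- lapply(1:7, function(k) list(hip_jcf = hip[k, ],
                                          tibiofemoral_jcf = tf[k, ],
                                          patellofemoral_jcf = pf[k, ]))
  structure(list(instances = tau, forces = forces, contact = contact,
                 body_weight = bw, params = params),
            class = "load_case")
}

#' @export
print.load_case <- function(x, ...) {
  hipmax <- max(vapply(x$contact, function(cc) sqrt(sum(cc$hip_jcf^2)), numeric(1)))
  cat(sprintf("load_case: %d stance instances, body weight %.1f N, peak hip JCF %.0f N\n",
              length(x$instances), x$body_weight, hipmax))
  invisible(x)
}

#' Transform global vectors into the local anatomical frame
#'
#' Orthogonal change of basis: rows of `vectors` are resolved onto the frame's
#' (ML, AP, SI) axes. Norms are preserved to machine precision.
#'
#' @param vectors n x 3 matrix (or 3-vector) in the source/global basis
#' @param frame an `anatomical_frame`
#' @return n x 3 matrix of (ML, AP, SI) components
#' @export
transform_to_frame <- function(vectors, frame) {
  if (is.null(dim(vectors))) vectors <- rbind(vectors)
  Rm <- rbind(frame$ml, frame$ap, frame$si)
  if (max(abs(Rm %*% t(Rm) - diag(3))) > 1e-9) {
    stop("frame axes are not orthonormal")
  }
  out <- vectors %*% t(Rm)
  dimnames(out) <- NULL
  out
}

#' Transform local-frame vectors back to the global basis
#' @inheritParams transform_to_frame
#' @return n x 3 matrix in the global basis
#' @export
transform_from_frame <- function(vectors, frame) {
  if (is.null(dim(vectors))) vectors <- rbind(vectors)
  Rm <- rbind(frame$ml, frame$ap, frame$si)
  if (max(abs(Rm %*% t(Rm) - diag(3))) > 1e-9) {
    stop("frame axes are not orthonormal")
  }
  out <- vectors %*% Rm
  dimnames(out) <- NULL
  out
}

#' Write a load case to CSV (one row per instance and target)
#'
#' Schema: `instance` (1-7), `tau` (stance fraction), `target` (attachment or
#' contact name), `Fx`, `Fy`, `Fz` (N, local ML/AP/SI components), plus a
#' `body_weight` column repeated for round-tripping.
#'
#' @param case a `load_case`
#' @param path output path (.csv or .json)
#' @export
write_loadcase <- function(case, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(instances = case$instances,
                              body_weight = case$body_weight,
                              forces = case$forces, contact = case$contact),
                         path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  rows <- list()
  for (k in seq_along(case$instances)) {
    for (nm in names(case$forces[[k]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        instance = k, tau = case$instances[k], target = nm,
        Fx = case$forces[[k]][[nm]][1], Fy = case$forces[[k]][[nm]][2],
        Fz = case$forces[[k]][[nm]][3], body_weight = case$body_weight)
    }
    for (nm in names(case$contact[[k]])) {
      v <- case$contact[[k]][[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        instance = k, tau = case$instances[k], target = nm,
        Fx = v[1], Fy = v[2], Fz = v[3], body_weight = case$body_weight)
    }
  }
  df <- do.call(rbind, rows)
  for (cl in c("tau", "Fx", "Fy", "Fz", "body_weight")) {
    df[[cl]] <- sprintf("%.17g", df[[cl]])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a load case from CSV or JSON
#'
#' @param path file written by [write_loadcase()] (or following its schema)
#' @return a `load_case`
#' @export
read_loadcase <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = FALSE)
    forces <- lapply(x$forces, function(fl)
      lapply(fl, function(v) as.numeric(unlist(v))))
    contact <- lapply(x$contact, function(cl)
      lapply(cl, function(v) as.numeric(unlist(v))))
    return(structure(list(instances = as.numeric(unlist(x$instances)),
                          forces = forces, contact = contact,
                          body_weight = as.numeric(x$body_weight)),
                     class = "load_case"))
  }
  df <- utils::read.csv(path)
  need <- c("instance", "tau", "target", "Fx", "Fy", "Fz")
  if (!all(need %in% names(df))) {
    stop("load case schema error: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  insts <- sort(unique(df$instance))
  if (!identical(as.integer(insts), seq_along(insts))) {
    stop("load case schema error: missing instance rows for instance(s) ",
         paste(setdiff(seq_len(max(insts)), insts), collapse = ", "))
  }
  tau <- vapply(insts, function(k) df$tau[df$instance == k][1], numeric(1))
  contact_names <- c("hip_jcf", "tibiofemoral_jcf", "patellofemoral_jcf")
  forces <- list(); contact <- list()
  for (k in insts) {
    sub <- df[df$instance == k, ]
    fl <- list(); cl <- list()
    for (r in seq_len(nrow(sub))) {
      v <- c(sub$Fx[r], sub$Fy[r], sub$Fz[r])
      if (sub$target[r] %in% contact_names) cl[[sub$target[r]]] <- v
      else fl[[sub$target[r]]] <- v
    }
    if (!all(contact_names %in% names(cl))) {
      stop("load case schema error: instance ", k, " lacks contact rows")
    }
    forces[[k]] <- fl; contact[[k]] <- cl
  }
  structure(list(instances = tau, forces = forces, contact = contact,
                 body_weight = if ("body_weight" %in% names(df))
                   df$body_weight[1] else NA_real_),
            class = "load_case")
}
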