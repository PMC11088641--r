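# End-to-end benchmark orchestration: generate -> deform -> loads ->
# solve (methods x geometries x instances) -> outcomes -> comparison report.

#' Benchmark run configuration
#'
#' @param femur a [femur_params()] object
#' @param loads a [gait_fixture_params()] object
#' @param geometries character vector from `normal`, `AVA45`, `AVAm10`,
#'   `NSA115`, `NSA150`
#' @param methods character vector of method names (see `METHOD_NAMES`)
#' @param n_bins number of material bins
#' @param exclusion_radius artefact guard radius for peak stress, mm
#' @param out_dir output directory for CSV artefacts (NULL = no files)
#' @param write_fields also write per-run VTK field files (slower, larger)
#' @param seed integer; seeds both the femur greyscale jitter and the load
#'   fixture
#' @return object of class `run_config`
#' @export
run_config <- function(femur = femur_params(), loads = gait_fixture_params(),
                       geometries = c("normal", "AVA45", "AVAm10",
                                      "NSA115", "NSA150"),
                       methods = METHOD_NAMES, n_bins = 10,
                       exclusion_radius = 5,
                       out_dir = NULL, write_fields = FALSE, seed = NULL) {
  known <- c("normal", "AVA45", "AVAm10", "NSA115", "NSA150")
  if (!all(geometries %in% known)) {
    stop("unknown geometries: ", paste(setdiff(geometries, known), collapse = ", "))
  }
  if (!all(methods %in% METHOD_NAMES)) {
    stop("unknown methods: ", paste(setdiff(methods, METHOD_NAMES), collapse = ", "))
  }
  if (!is.null(seed)) {
    femur$rng_seed <- as.integer(seed)
    loads$rng_seed <- as.integer(seed)
  }
  structure(list(femur = femur, loads = loads, geometries = geometries,
                 methods = methods, n_bins = n_bins,
                 exclusion_radius = exclusion_radius, out_dir = out_dir,
                 write_fields = write_fields),
            class = "run_config")
}

# the benchmark's pathological geometry set, produced by the deformation toolbox
deform_geometry <- function(model, geometry) {
  switch(geometry,
         normal = list(model = model, quality = NULL),
         AVA45 = apply_anteversion(model, deformity_spec(target_ava_deg = 45)),
         AVAm10 = apply_anteversion(model, deformity_spec(target_ava_deg = -10)),
         NSA115 = apply_neck_shaft(model, deformity_spec(target_nsa_deg = 115)),
         NSA150 = apply_neck_shaft(model, deformity_spec(target_nsa_deg = 150)),
         stop("unknown geometry: ", geometry))
}

#' Run the full boundary-condition benchmark
#'
#' Generates the synthetic normal femur, derives the pathological geometries
#' with the deformation toolbox, generates one stance load case (identical
#' forces applied to every geometry, as in the source study design), solves
#' every geometry x method x instance combination, and compares every method
#' against inertia relief per geometry. Deterministic given the seed.
#'
#' @param config a [run_config()]
#' @return object of class `benchmark_result`: list with `outcomes`
#'   (`outcomes[[geometry]][[method]]`, each an `outcome_series`), `report`
#'   (comparison data.frame), `case`, `models`, `quality` (deformation
#'   quality reports)
#' @export
run_benchmark <- function(config = run_config()) {
  normal <- generate_femur(config$femur)
  case <- generate_stance_loads(normal, config$loads)
  outcomes <- list(); models <- list(); quality <- list()
  for (g in config$geometries) {
    dg <- deform_geometry(normal, g)
    mg <- dg$model
    models[[g]] <- mg
    quality[[g]] <- dg$quality
    mats <- bin_materials(mg, config$n_bins)
    sys <- assemble(mg, mats)
    outcomes[[g]] <- list()
    for (meth in config$methods) {
      run <- run_method(mg, mats, meth, case, system = sys)
      outcomes[[g]][[meth]] <- outcome_series(mg, run,
                                              config$exclusion_radius)
      if (isTRUE(config$write_fields) && !is.null(config$out_dir)) {
        dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
        U <- run$result$U
        write_vtk(mg, file.path(config$out_dir,
                                sprintf("%s_%s.vtk", g, meth)),
                  cell_data = list(von_mises = run$fields$von_mises[, 4]),
                  point_data = list(u = matrix(U[, 4], ncol = 3, byrow = TRUE)))
      }
    }
  }
  report <- if ("inertia_relief" %in% config$methods &&
                length(config$methods) > 1) {
    compare_report(outcomes)
  } else NULL
  res <- structure(list(outcomes = outcomes, report = report, case = case,
                        models = models, quality = quality, config = config),
                   class = "benchmark_result")
  if (!is.null(config$out_dir)) write_benchmark(res, config$out_dir)
  res
}

#' Write benchmark artefacts (outcome and comparison CSVs) to a directory
#' @param res a `benchmark_result`
#' @param out_dir output directory (created if needed)
#' @export
write_benchmark <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (g in names(res$outcomes)) {
    for (meth in names(res$outcomes[[g]])) {
      os <- res$outcomes[[g]][[meth]]
      rows[[length(rows) + 1L]] <- data.frame(
        geometry = g, method = meth, instance = os$fhd$instance,
        fhd_si = os$fhd$fhd_si, fhd_ml = os$fhd$fhd_ml,
        fhd_ap = os$fhd$fhd_ap, fhd_resultant = os$fhd$fhd_resultant,
        pvms = os$pvms)
    }
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(out_dir, "outcomes.csv"), row.names = FALSE)
  if (!is.null(res$report)) {
    utils::write.csv(res$report, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.benchmark_result <- function(x, ...) {
  ng <- length(x$outcomes); nm <- length(x$outcomes[[1]])
  cat(sprintf("benchmark_result: %d geometries x %d methods x %d instances\n",
              ng, nm, length(x$case$instances)))
  if (!is.null(x$report)) {
    cat("PVMS agreement with inertia relief (nRMSE):\n")
    sub <- x$report[x$report$metric == "pvms", ]
    print(utils::head(sub[order(sub$geometry, sub$nrmse), ], 12),
          row.names = FALSE)
  }
  invisible(x)
}

#' Material-bin sensitivity of peak von Mises stress
#'
#' Re-solves one geometry/method with different numbers of material bins and
#' reports the PVMS of each, mirroring a material-set sensitivity study.
#'
#' @param model a `femur_model`
#' @param case a `load_case`
#' @param method method name (default `biomechanical`)
#' @param bins integer vector of bin counts
#' @return data.frame with `n_bins` and `pvms` (max over instances, MPa)
#' @export
material_sensitivity <- function(model, case, method = "biomechanical",
                                 bins = c(1, 2, 5, 10, 20)) {
  out <- lapply(bins, function(b) {
    mats <- bin_materials(model, b)
    run <- run_method(model, mats, method, case)
    data.frame(n_bins = b, pvms = max(peak_von_mises(model, run$fields,
                                                     run$constraints)))
  })
  do.call(rbind, out)
}
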