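# Model file IO.
#
# Abaqus-INP subset (read + write): *NODE, *ELEMENT TYPE=C3D4, *ELSET
# (material bins, generated on write when a material table is supplied),
# *NSET for surface patches and strain paths. Landmark positions and patch
# reference points do not fit the node-set vocabulary, so they travel in
# `** FEMURBC ...` comment records which standard FE tools ignore and this
# reader recovers, making write-read a lossless round trip.
#
# Legacy ASCII VTK (write only): unstructured grid with greyscale and optional
# result fields as cell/point data, for visualization.

#' Write a femur model to an Abaqus-INP subset file
#'
#' @param model a `femur_model`
#' @param path output path
#' @param materials optional `material_table`; when given, per-bin *ELSET
#'   records and *SOLID SECTION/*MATERIAL cards are emitted
#' @return the path, invisibly
#' @export
write_model <- function(model, path, materials = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("*HEADING")
  w("femurbc synthetic femur model")
  for (nm in names(model$landmarks)) {
    p <- model$landmarks[[nm]]
    w("** FEMURBC LANDMARK %s %.17g %.17g %.17g", nm, p[1], p[2], p[3])
  }
  for (nm in names(model$attachment_patches)) {
    p <- model$attachment_patches[[nm]]$refpoint
    w("** FEMURBC REFPOINT %s %.17g %.17g %.17g", nm, p[1], p[2], p[3])
  }
  w("** FEMURBC GV %s", paste(sprintf("%.10g", model$element_gv), collapse = " "))
  w("*NODE")
  writeLines(sprintf("%d, %.17g, %.17g, %.17g", seq_len(nrow(model$nodes)),
                     model$nodes[, 1], model$nodes[, 2], model$nodes[, 3]), con)
  w("*ELEMENT, TYPE=C3D4, ELSET=ALL")
  writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nrow(model$tets)),
                     model$tets[, 1], model$tets[, 2], model$tets[, 3],
                     model$tets[, 4]), con)
  write_set <- function(keyword, name, ids) {
    w("*%s, %s=%s", keyword, if (keyword == "NSET") "NSET" else "ELSET", name)
    for (start in seq(1, length(ids), by = 12)) {
      writeLines(paste(ids[start:min(start + 11, length(ids))], collapse = ", "),
                 con)
    }
  }
  for (nm in names(model$attachment_patches)) {
    write_set("NSET", paste0("PATCH_", toupper(nm)),
              model$attachment_patches[[nm]]$nodes)
  }
  if (!is.null(model$strain_paths)) {
    for (nm in names(model$strain_paths)) {
      write_set("NSET", paste0("PATH_", toupper(nm)), model$strain_paths[[nm]])
    }
  }
  if (!is.null(materials)) {
    for (b in seq_len(nrow(materials$bins))) {
      write_set("ELSET", sprintf("MAT_BIN_%02d", b),
                which(materials$element_bin == b))
      w("*SOLID SECTION, ELSET=MAT_BIN_%02d, MATERIAL=BONE_%02d", b, b)
      w("*MATERIAL, NAME=BONE_%02d", b)
      w("*ELASTIC")
      w("%.10g, %.10g", materials$bins$modulus[b], materials$bins$poisson[b])
    }
  }
  invisible(path)
}

#' Read a femur model from an Abaqus-INP subset file
#'
#' Supports the subset written by [write_model()]: `*NODE`, `*ELEMENT` with
#' `TYPE=C3D4`, `*NSET`/`*ELSET`, and `** FEMURBC` records. Any other element
#' type is rejected with the offending line. Files from other tools lacking
#' the FEMURBC records yield a model without landmarks (geometry and sets
#' only).
#'
#' @param path INP file path
#' @param format file format; only `"inp"` is supported (VTK is a write-only
#'   visualization format here)
#' @return a `femur_model`
#' @export
read_model <- function(path, format = c("inp", "vtk")) {
  format <- match.arg(format)
  if (format == "vtk") {
    stop("VTK is a write-only visualization format; read models from INP")
  }
  lines <- readLines(path)
  landmarks <- list(); refpoints <- list(); gv <- NULL
  lm_pat <- "^\\*\\* FEMURBC (LANDMARK|REFPOINT) (\\S+) (.+)$"
  for (ln in grep(lm_pat, lines, value = TRUE)) {
    m <- regmatches(ln, regexec(lm_pat, ln))[[1]]
    vals <- as.numeric(strsplit(trimws(m[4]), "\\s+")[[1]])
    if (m[2] == "LANDMARK") landmarks[[m[3]]] <- vals
    else refpoints[[m[3]]] <- vals
  }
  gv_line <- grep("^\\*\\* FEMURBC GV ", lines)
  if (length(gv_line)) {
    gv <- as.numeric(strsplit(sub("^\\*\\* FEMURBC GV ", "", lines[gv_line[1]]),
                              "\\s+")[[1]])
  }
  is_kw <- startsWith(lines, "*") & !startsWith(lines, "**")
  kw_idx <- which(is_kw)
  nodes <- NULL; tets <- NULL; nsets <- list(); elsets <- list()
  for (ki in seq_along(kw_idx)) {
    i0 <- kw_idx[ki]
    i1 <- if (ki < length(kw_idx)) kw_idx[ki + 1] - 1L else length(lines)
    body <- lines[(i0 + 1):i1]
    body <- body[!startsWith(body, "*") & nzchar(trimws(body))]
    kw <- toupper(lines[i0])
    if (startsWith(kw, "*NODE")) {
      df <- utils::read.csv(text = body, header = FALSE,
                            col.names = c("id", "x", "y", "z"))
      nodes <- matrix(0, max(df$id), 3)
      nodes[df$id, ] <- as.matrix(df[, 2:4])
    } else if (startsWith(kw, "*ELEMENT")) {
      ty <- sub(".*TYPE=([^,]+).*", "\\1", kw)
      if (trimws(ty) != "C3D4") {
        stop(sprintf("unsupported element type '%s' at line %d (only C3D4)",
                     trimws(ty), i0))
      }
      df <- utils::read.csv(text = body, header = FALSE,
                            col.names = c("id", "n1", "n2", "n3", "n4"))
      tets <- as.matrix(df[order(df$id), 2:5])
      dimnames(tets) <- NULL
    } else if (startsWith(kw, "*NSET") || startsWith(kw, "*ELSET")) {
      name <- sub(".*(NSET|ELSET)=([^,]+).*", "\\2", kw)
      ids <- as.integer(unlist(strsplit(paste(body, collapse = ","), ",")))
      ids <- ids[!is.na(ids)]
      if (startsWith(kw, "*NSET")) nsets[[name]] <- ids else elsets[[name]] <- ids
    }
  }
  if (is.null(nodes) || is.null(tets)) {
    stop("INP parse error: missing *NODE or *ELEMENT block")
  }
  patches <- list()
  for (nm in names(nsets)) {
    if (startsWith(nm, "PATCH_")) {
      key <- tolower(sub("^PATCH_", "", nm))
      patches[[key]] <- list(refpoint = refpoints[[key]], nodes = nsets[[nm]])
    }
  }
  strain_paths <- list()
  for (nm in names(nsets)) {
    if (startsWith(nm, "PATH_")) {
      strain_paths[[tolower(sub("^PATH_", "", nm))]] <- nsets[[nm]]
    }
  }
  bf <- boundary_faces(tets)
  model <- structure(list(
    nodes = nodes, tets = tets,
    element_gv = if (!is.null(gv)) gv else rep(0, nrow(tets)),
    landmarks = landmarks,
    attachment_patches = patches,
    strain_paths = if (length(strain_paths)) strain_paths else NULL,
    surface_nodes = sort(unique(as.integer(bf))),
    boundary_faces = bf,
    params = NULL
  ), class = "femur_model")
  if (all(c("head_center", "knee_center", "lateral_epicondyle") %in%
          names(landmarks))) {
    model$frame <- build_frame(landmarks)
  }
  model
}

#' Write a legacy ASCII VTK unstructured grid for visualization
#'
#' Greyscale is written as cell data; optional per-element scalars (e.g. von
#' Mises stress) and a nodal displacement field can be added.
#'
#' @param model a `femur_model` or mesh list
#' @param path output .vtk path
#' @param cell_data named list of per-element numeric vectors
#' @param point_data named list of per-node fields (vector of length N, or
#'   N x 3 matrix for vector fields such as displacement)
#' @return the path, invisibly
#' @export
write_vtk <- function(model, path, cell_data = list(), point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  N <- nrow(model$nodes); M <- nrow(model$tets)
  writeLines(c("# vtk DataFile Version 3.0", "femurbc model", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", N)), con)
  writeLines(sprintf("%.10g %.10g %.10g", model$nodes[, 1], model$nodes[, 2],
                     model$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", M, 5 * M), con)
  writeLines(sprintf("4 %d %d %d %d", model$tets[, 1] - 1L, model$tets[, 2] - 1L,
                     model$tets[, 3] - 1L, model$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", M), con)
  writeLines(rep("10", M), con)
  if (!is.null(model$element_gv)) cell_data <- c(list(gv = model$element_gv),
                                                 cell_data)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", M), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(sprintf("%.10g", cell_data[[nm]]), con)
    }
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", N), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.10g", v), con)
      }
    }
  }
  invisible(path)
}
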