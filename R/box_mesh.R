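# Structured tetrahedral box meshes, used as analytic oracles (patch test,
# cantilever bending, uniform stress states) for the FE engine.

#' Generate a structured tetrahedral box mesh
#'
#' Regular grid of `nx x ny x nz` cells over `[0,lx] x [0,ly] x [0,lz]`, each
#' cell split into six tetrahedra around its main diagonal (Kuhn subdivision),
#' which is conforming across cells. Useful as a closed-form oracle geometry.
#'
#' @param lx,ly,lz box dimensions (mm)
#' @param nx,ny,nz cells per direction
#' @param gv constant greyscale assigned to every element (default 1700)
#' @return list with `nodes`, `tets`, `element_gv`, `surface_nodes`,
#'   `boundary_faces`, compatible with [assemble()]
#' @export
generate_box_mesh <- function(lx, ly, lz, nx, ny, nz, gv = 1700) {
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  zs <- seq(0, lz, length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L) +
    (i - i)  # keep integer
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  v000 <- nid(cells$i, cells$j, cells$k)
  v100 <- nid(cells$i + 1L, cells$j, cells$k)
  v010 <- nid(cells$i, cells$j + 1L, cells$k)
  v110 <- nid(cells$i + 1L, cells$j + 1L, cells$k)
  v001 <- nid(cells$i, cells$j, cells$k + 1L)
  v101 <- nid(cells$i + 1L, cells$j, cells$k + 1L)
  v011 <- nid(cells$i, cells$j + 1L, cells$k + 1L)
  v111 <- nid(cells$i + 1L, cells$j + 1L, cells$k + 1L)
  # six tets sharing the v000-v111 diagonal
  tets <- rbind(cbind(v000, v100, v110, v111),
                cbind(v000, v110, v010, v111),
                cbind(v000, v010, v011, v111),
                cbind(v000, v011, v001, v111),
                cbind(v000, v001, v101, v111),
                cbind(v000, v101, v100, v111))
  storage.mode(tets) <- "integer"
  vol <- tet_volumes(nodes, tets)
  flip <- vol < 0
  tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  bf <- boundary_faces(tets)
  list(nodes = nodes, tets = tets,
       element_gv = rep(gv, nrow(tets)),
       surface_nodes = sort(unique(as.integer(bf))),
       boundary_faces = bf)
}

#' Uniform-property material table for oracle meshes
#'
#' Bypasses the greyscale mapping: one bin with the given modulus, density and
#' Poisson ratio applied to every element.
#'
#' @param model mesh list with `tets`
#' @param E Young's modulus (MPa)
#' @param nu Poisson ratio
#' @param rho density (g/cm^3)
#' @return `material_table`
#' @export
uniform_materials <- function(model, E, nu = 0.3, rho = 1.8) {
  bins <- data.frame(gv_lo = NA, gv_hi = NA, gv_rep = NA,
                     density = rho, modulus = E, poisson = nu,
                     n_elements = nrow(model$tets))
  structure(list(bins = bins, element_bin = rep(1L, nrow(model$tets)),
                 n_bins_requested = 1L),
            class = "material_table")
}
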