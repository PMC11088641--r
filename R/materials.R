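# CT greyscale -> apparent density -> Young's modulus material mapping, with
# equal-width greyscale binning into a finite number of material sets.

#' Convert CT greyscale value to apparent density
#'
#' Linear calibration `rho_app = 0.001029 * GV + 0.114259` (g/cm^3). The
#' mapping is applied as printed over the whole greyscale range; values at the
#' top of the 12-bit range produce supra-physiological densities (about
#' 4.33 g/cm^3 at GV = 4095), which is reported via the `supra_physiological`
#' attribute rather than clamped.
#'
#' @param gv numeric vector of greyscale values (dimensionless, >= 0)
#' @return apparent density in g/cm^3, with logical attribute
#'   `supra_physiological` marking densities above 2.1 g/cm^3
#' @export
gv_to_density <- function(gv) {
  if (any(!is.finite(gv))) stop("greyscale values must be finite")
  if (any(gv < 0)) stop("greyscale values must be non-negative")
  rho <- 0.001029 * gv + 0.114259
  attr(rho, "supra_physiological") <- rho > 2.1
  rho
}

#' Convert apparent density to Young's modulus
#'
#' Power law `E = 6850 * rho_app^1.49` (MPa, density in g/cm^3).
#'
#' @param rho apparent density in g/cm^3 (>= 0)
#' @return Young's modulus in MPa
#' @export
density_to_modulus <- function(rho) {
  if (any(!is.finite(rho))) stop("density must be finite")
  if (any(rho < 0)) stop("density must be non-negative")
  6850 * rho^1.49
}

#' Bin element greyscale values into material sets
#'
#' Elements are partitioned into `n_bins` equal-width greyscale intervals
#' spanning the observed range. Each populated bin is represented by the mean
#' greyscale of its member elements, mapped through [gv_to_density()] and
#' [density_to_modulus()]; empty bins are dropped. Poisson's ratio is 0.3 for
#' every bin.
#'
#' @param model a `femur_model` (or any list with `element_gv`)
#' @param n_bins number of greyscale bins (default 10)
#' @return object of class `material_table`: list with `bins` (data.frame of
#'   `gv_lo`, `gv_hi`, `gv_rep`, `density`, `modulus`, `poisson`, `n_elements`)
#'   and `element_bin` (bin index per element, rows of `bins`)
#' @export
bin_materials <- function(model, n_bins = 10) {
  gv <- model$element_gv
  if (is.null(gv) || !length(gv)) stop("model has no element greyscale field")
  if (n_bins < 1) stop("n_bins must be >= 1")
  rng <- range(gv)
  if (diff(rng) == 0) {
    idx <- rep(1L, length(gv))
  } else {
    brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
    idx <- findInterval(gv, brk, rightmost.closed = TRUE, all.inside = TRUE)
  }
  populated <- sort(unique(idx))
  remap <- match(idx, populated)
  gv_rep <- vapply(seq_along(populated),
                   function(b) mean(gv[remap == b]), numeric(1))
  # a bin's representative density can only grow with its member greyscales,
  # so modulus is strictly increasing across bins
  rho <- as.numeric(gv_to_density(gv_rep))
  bins <- data.frame(
    gv_lo = vapply(seq_along(populated), function(b) min(gv[remap == b]), numeric(1)),
    gv_hi = vapply(seq_along(populated), function(b) max(gv[remap == b]), numeric(1)),
    gv_rep = gv_rep,
    density = rho,
    modulus = density_to_modulus(rho),
    poisson = 0.3,
    n_elements = as.integer(table(remap))
  )
  structure(list(bins = bins, element_bin = remap, n_bins_requested = n_bins),
            class = "material_table")
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("Material table: %d populated bins (%d requested)\n",
              nrow(x$bins), x$n_bins_requested))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Per-element Young's modulus and density from a material table
#' @param materials a `material_table`
#' @return list with numeric vectors `E` (MPa), `rho` (g/cm^3), `nu`
#' @export
element_properties <- function(materials) {
  b <- materials$element_bin
  list(E = materials$bins$modulus[b],
       rho = materials$bins$density[b],
       nu = materials$bins$poisson[b])
}

#' Export a material table as CSV
#' @param materials a `material_table`
#' @param path output CSV path
#' @export
write_material_table <- function(materials, path) {
  utils::write.csv(materials$bins, path, row.names = FALSE)
  invisible(path)
}
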