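#' Gel geometry for the axisymmetric indentation model
#'
#' The gel is modelled as a cylinder of the given height bonded to a rigid
#' base; the model radius is truncated well beyond the contact zone (the
#' physical dish is millimetres wide, but the indentation field decays within
#' tens of micrometres, so a 500 um domain radius is the default).
#'
#' @param height Gel height (um), > 0.
#' @param radius Model domain radius (um). Must be at least 10 x the contact
#'   radius estimate `sqrt(R * depth)` of the indenter it will be used with;
#'   validated at solve time.
#' @return A `gel_geometry` list.
#' @export
gel_geometry <- function(height, radius = 500) {
  stopifnot(is.numeric(height), length(height) == 1, height > 0,
            is.numeric(radius), length(radius) == 1, radius > 0)
  structure(list(height = height, radius = radius), class = "gel_geometry")
}

#' Linear elastic, isotropic gel material
#'
#' @param youngs_modulus Young's modulus E (Pa), > 0. Default 450 Pa,
#'   a typical Matrigel modulus.
#' @param poisson_ratio Poisson ratio in `[0, 0.5)`. Hydrogels are
#'   water-dominated and near-incompressible; exactly 0.5 makes the
#'   displacement formulation singular, so the default is 0.45.
#' @return An `elastic_material` list.
#' @export
elastic_material <- function(youngs_modulus = 450, poisson_ratio = 0.45) {
  stopifnot(is.numeric(youngs_modulus), youngs_modulus > 0,
            is.numeric(poisson_ratio), poisson_ratio >= 0, poisson_ratio < 0.5)
  structure(list(youngs_modulus = youngs_modulus, poisson_ratio = poisson_ratio),
            class = "elastic_material")
}

#' Rigid spherical indenter specification
#'
#' @param radius Sphere radius (um). Default 5 (10 um diameter, cell-sized).
#' @param max_depth Final indentation depth (um), `0 <= max_depth <= radius`.
#' @param n_steps Number of equal displacement increments (>= 1). The contact
#'   set grows with depth, so the force-deflection curve is traced
#'   incrementally even though the material is linear.
#' @return An `indenter_spec` list.
#' @export
indenter_spec <- function(radius = 5, max_depth = 5, n_steps = 10) {
  stopifnot(radius > 0, max_depth >= 0, max_depth <= radius, n_steps >= 1)
  structure(list(radius = radius, max_depth = max_depth,
                 n_steps = as.integer(n_steps)), class = "indenter_spec")
}

# graded 1D node positions on [0, total]: uniform `fine_size` spacing over
# [0, fine_len], then geometric growth (factor `growth`) capped at
# `coarse_size`, rescaled so the last node lands exactly on `total`.
grade_1d <- function(total, fine_len, fine_size, coarse_size, growth = 1.3) {
  stopifnot(total > 0, fine_size > 0, coarse_size >= fine_size)
  if (total <= fine_len + fine_size) {
    n <- max(2L, as.integer(ceiling(total / fine_size)))
    return(seq(0, total, length.out = n + 1))
  }
  n_fine <- max(1L, as.integer(round(fine_len / fine_size)))
  x <- seq(0, fine_len, length.out = n_fine + 1)
  steps <- numeric(0)
  s <- fine_size
  pos <- fine_len
  while (pos < total) {
    s <- min(s * growth, coarse_size)
    steps <- c(steps, s)
    pos <- pos + s
  }
  steps <- steps * (total - fine_len) / sum(steps)
  c(x, fine_len + cumsum(steps))
}

#' Build a graded axisymmetric quadrilateral mesh of the gel cross-section
#'
#' Structured tensor-product mesh over the (r, z) rectangle
#' `[0, radius] x [0, height]`, graded so the finest elements sit under the
#' indenter axis at the top surface where contact stresses concentrate.
#' Node 1 dof ordering used throughout: `u_r = 2i - 1`, `u_z = 2i`.
#'
#' @param geometry A [gel_geometry()].
#' @param refine_radius Extent (um) of the finely meshed zone in r (from the
#'   axis) and in z (down from the top surface). Should cover the contact
#'   zone, i.e. at least `2 * sqrt(R * max_depth)`.
#' @param coarse_size Target far-field element size (um).
#' @param fine_size Element size inside the refined zone (um).
#' @return An `axisym_mesh` list: `nodes` (n x 2 matrix, um), `elements`
#'   (ne x 4 connectivity, counter-clockwise), and `boundary` node-index sets
#'   `bottom`, `axis`, `side`, `top`.
#' @export
build_axisym_mesh <- function(geometry, refine_radius = 15,
                              coarse_size = 25, fine_size = 0.5) {
  stopifnot(inherits(geometry, "gel_geometry"),
            fine_size < coarse_size, refine_radius > 0)
  h <- geometry$height
  if (h < 2 * fine_size) {
    stop("degenerate geometry: height ", h, " um < 2 * fine_size (",
         2 * fine_size, " um)")
  }
  rb <- grade_1d(geometry$radius, refine_radius, fine_size, coarse_size)
  # grade z downward from the top surface where the indenter acts
  zb <- h - rev(grade_1d(h, min(refine_radius, h), fine_size, coarse_size))
  nr <- length(rb)
  nz <- length(zb)
  nodes <- cbind(r = rep(rb, times = nz), z = rep(zb, each = nr))
  idx <- function(i, j) (j - 1L) * nr + i
  i <- rep(seq_len(nr - 1L), times = nz - 1L)
  j <- rep(seq_len(nz - 1L), each = nr - 1L)
  elements <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  tol <- 1e-9
  boundary <- list(
    bottom = which(abs(nodes[, 2]) < tol),
    axis   = which(abs(nodes[, 1]) < tol),
    side   = which(abs(nodes[, 1] - geometry$radius) < tol),
    top    = which(abs(nodes[, 2] - h) < tol)
  )
  structure(list(nodes = nodes, elements = elements, boundary = boundary,
                 height = h, radius = geometry$radius),
            class = "axisym_mesh")
}

#' @export
print.axisym_mesh <- function(x, ...) {
  cat("Axisymmetric quad mesh: ", nrow(x$nodes), " nodes, ",
      nrow(x$elements), " elements, ", x$radius, " x ", x$height,
      " um (r x z)\n", sep = "")
  invisible(x)
}
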