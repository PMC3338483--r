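# Post-processing of indentation results: equivalent stress fields, interface
# stress, effective stiffness, height sweeps, and the closed-form oracles used
# to validate the finite-element solution.

#' Von Mises equivalent stress per element
#'
#' Computed from the principal stresses of the full 3D stress tensor. In the
#' axisymmetric frame the hoop stress is principal; the other two principal
#' stresses come from the in-plane (r, z) block.
#'
#' @param result An `indentation_result` (or any object with a `stresses`
#'   matrix carrying `s_rr`, `s_zz`, `s_tt`, `s_rz` columns in Pa).
#' @return Numeric vector, one von Mises stress (Pa) per element.
#' @export
von_mises_field <- function(result) {
  s <- if (is.matrix(result)) result else result$stresses
  stopifnot(all(c("s_rr", "s_zz", "s_tt", "s_rz") %in% colnames(s)))
  mid <- (s[, "s_rr"] + s[, "s_zz"]) / 2
  rad <- sqrt(((s[, "s_rr"] - s[, "s_zz"]) / 2)^2 + s[, "s_rz"]^2)
  p1 <- mid + rad
  p2 <- mid - rad
  p3 <- s[, "s_tt"]
  unname(sqrt(0.5 * ((p1 - p2)^2 + (p2 - p3)^2 + (p3 - p1)^2)))
}

#' Maximum von Mises stress at the gel-substrate interface
#'
#' @param result An `indentation_result`.
#' @param mesh The mesh the result was computed on (defaults to the mesh
#'   stored in the result).
#' @return Maximum von Mises stress (Pa) over elements adjacent to `z = 0`.
#' @export
interface_stress <- function(result, mesh = result$mesh) {
  vm <- von_mises_field(result)
  bottom <- mesh$boundary$bottom
  touches <- matrix(mesh$elements %in% bottom, nrow(mesh$elements))
  max(vm[rowSums(touches) > 0])
}

#' Effective stiffness from a force-deflection record
#'
#' Ordinary least-squares straight line through the whole (depth, force)
#' record, including the (0, 0) state, with a free intercept; the slope is the
#' effective stiffness a cell-sized probe would report.
#'
#' @param result An `indentation_result`, or a data.frame with `depth_um` and
#'   `force_N` columns.
#' @return Stiffness k (N/m).
#' @export
effective_stiffness <- function(result) {
  steps <- if (is.data.frame(result)) result else result$steps
  if (nrow(steps) < 2) stop("need at least 2 load steps to fit a stiffness")
  unname(coef(lm(force_N ~ depth_um, data = steps))[2]) / UM
}

#' Hertz contact force on an elastic half-space (validation oracle)
#'
#' Closed-form frictionless rigid-sphere contact on an infinite half-space:
#' `F = (4/3) * E / (1 - nu^2) * sqrt(R) * depth^(3/2)`. Valid for small
#' indentation depth; used to validate the finite-element solution in the
#' thick-gel limit.
#'
#' @param material An [elastic_material()].
#' @param radius Sphere radius (um).
#' @param depth Indentation depth (um), >= 0.
#' @return Force (N).
#' @export
hertz_half_space_force <- function(material, radius, depth) {
  stopifnot(depth >= 0)
  Estar <- material$youngs_modulus / (1 - material$poisson_ratio^2)
  (4 / 3) * Estar * sqrt(radius * UM) * (depth * UM)^1.5
}

#' Finite-thickness stiffening factor for a bonded incompressible layer
#'
#' Polynomial correction (Dimitriadis-type) to the Hertz force for a sphere
#' indenting a thin layer bonded to a rigid base:
#' `1 + 1.133*x + 1.283*x^2 + 0.769*x^3 + 0.0975*x^4` with
#' `x = sqrt(R * depth) / h`. Tends to 1 as the layer thickens. Used as a
#' rank-order oracle for the finite-element height sweep.
#'
#' @param radius Sphere radius (um).
#' @param depth Indentation depth (um).
#' @param height Layer thickness h (um), > 0.
#' @return Dimensionless multiplicative factor >= 1.
#' @export
bonded_layer_correction <- function(radius, depth, height) {
  stopifnot(all(height > 0))
  x <- sqrt(radius * depth) / height
  1 + 1.133 * x + 1.283 * x^2 + 0.769 * x^3 + 0.0975 * x^4
}

#' Sweep gel height and extract stiffness and stress measures
#'
#' Runs the full contact indentation at each gel height and tabulates the
#' effective stiffness, the global maximum von Mises stress and the maximum
#' von Mises stress at the gel-substrate interface.
#'
#' @param heights Gel heights (um); output rows are sorted by height.
#' @param material An [elastic_material()].
#' @param indenter An [indenter_spec()].
#' @param domain_radius Model domain radius (um).
#' @param refine_radius,coarse_size,fine_size Meshing parameters, see
#'   [build_axisym_mesh()].
#' @return A tibble (`stiffness_sweep`): `height_um`, `stiffness_N_per_m`,
#'   `max_vm_Pa`, `interface_vm_Pa`, `n_elements`, `n_contact`.
#' @export
height_sweep <- function(heights, material = elastic_material(),
                         indenter = indenter_spec(), domain_radius = 500,
                         refine_radius = 15, coarse_size = 25, fine_size = 0.5) {
  stopifnot(length(heights) >= 1, all(heights > 0))
  heights <- sort(unique(heights))
  rows <- lapply(heights, function(h) {
    res <- tryCatch({
      mesh <- build_axisym_mesh(gel_geometry(h, domain_radius),
                                refine_radius, coarse_size, fine_size)
      solve_contact_indentation(mesh, material, indenter)
    }, error = function(e) {
      stop("height sweep failed at h = ", h, " um: ", conditionMessage(e),
           call. = FALSE)
    })
    vm <- von_mises_field(res)
    tibble::tibble(
      height_um = h,
      stiffness_N_per_m = effective_stiffness(res),
      max_vm_Pa = max(vm),
      interface_vm_Pa = interface_stress(res),
      n_elements = nrow(res$mesh$elements),
      n_contact = length(res$contact_set)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stiffness_sweep", class(out))
  out
}

#' Write an indentation stress field as a legacy ASCII VTK unstructured grid
#'
#' The (r, z) cross-section mesh is written as VTK quads with the von Mises
#' field and stress components as cell data, for inspection in ParaView.
#'
#' @param result An `indentation_result`.
#' @param path Output file path (`.vtk`).
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(result, path) {
  mesh <- result$mesh
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$elements)
  vm <- von_mises_field(result)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric gel indentation cross-section (um, Pa)",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  writeLines(sprintf("%.6g %.6g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", ne, 5 * ne), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L,
                     mesh$elements[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("9", ne), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  for (fld in c("von_mises", colnames(result$stresses))) {
    vals <- if (fld == "von_mises") vm else result$stresses[, fld]
    writeLines(c(sprintf("SCALARS %s float 1", fld), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.6g", vals), con)
  }
  invisible(path)
}
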