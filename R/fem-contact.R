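# Displacement-controlled frictionless contact of a rigid sphere with the gel
# top surface. Contact is node-on-analytic-sphere with direct elimination:
# active surface nodes have u_z prescribed to close the normal gap exactly
# (frictionless => no tangential constraint), and the active set is iterated
# until no prescribed node carries tension and no free node penetrates.

# sphere surface height above the gel top plane, as prescribed u_z (metres is
# not needed here -- gaps are computed in um and converted by the caller).
# centre sits on the axis at z = h + R - depth.
.sphere_gap_um <- function(r_um, R_um, depth_um) {
  (R_um - depth_um) - sqrt(pmax(R_um^2 - r_um^2, 0))
}

#' Solve displacement-controlled spherical indentation with contact
#'
#' Lowers a frictionless rigid sphere onto the top surface in
#' `indenter$n_steps` equal depth increments. At each increment an active-set
#' loop prescribes the vertical displacement of contacting surface nodes to
#' the local sphere gap, releases nodes whose contact reaction turns tensile,
#' and adds free nodes that penetrate the sphere. The bottom boundary is fully
#' fixed (bonded rigid substrate) and the axis carries the symmetry condition
#' `u_r = 0`.
#'
#' @param mesh An [build_axisym_mesh()] mesh.
#' @param material An [elastic_material()].
#' @param indenter An [indenter_spec()]; `max_depth <= radius` (the solver
#'   models contact up to the sphere equator).
#' @param max_iter Active-set iterations allowed per load step.
#' @return An `indentation_result`: `steps` (data.frame `depth_um`, `force_N`,
#'   starting at (0, 0)), `displacements` (n x 2 matrix `u_r`, `u_z` in um at
#'   the final step), `stresses` (per-element centroid stress components in
#'   Pa: `s_rr`, `s_zz`, `s_tt`, `s_rz`), `contact_set` (node indices in
#'   contact at the final step), plus the mesh and inputs.
#' @export
solve_contact_indentation <- function(mesh, material, indenter, max_iter = 40) {
  stopifnot(inherits(mesh, "axisym_mesh"), inherits(material, "elastic_material"),
            inherits(indenter, "indenter_spec"))
  R_um <- indenter$radius
  if (mesh$radius < 10 * sqrt(R_um * max(indenter$max_depth, 1e-12))) {
    stop("domain radius too small for the expected contact zone")
  }
  n_node <- nrow(mesh$nodes)
  n_dof <- 2L * n_node
  K <- assemble_system(mesh, material)

  fixed <- sort(unique(c(2L * mesh$boundary$bottom - 1L, 2L * mesh$boundary$bottom,
                         2L * mesh$boundary$axis - 1L)))
  top <- mesh$boundary$top
  top_r <- mesh$nodes[top, 1]
  cand <- top[top_r < R_um - 1e-9]      # only nodes under the sphere can touch
  cand_r <- mesh$nodes[cand, 1]

  depths <- if (indenter$max_depth == 0) numeric(0) else
    seq_len(indenter$n_steps) / indenter$n_steps * indenter$max_depth
  steps <- data.frame(depth_um = 0, force_N = 0)
  u <- numeric(n_dof)
  active <- integer(0)                  # indices into `cand`
  contact_tol <- 1e-12

  for (depth in depths) {
    gap_um <- .sphere_gap_um(cand_r, R_um, depth)
    pen0 <- which(gap_um < 0)           # geometric overlap candidates
    active <- intersect(active, pen0)
    if (length(active) == 0) active <- pen0[which.min(gap_um[pen0])]
    converged <- FALSE
    trace <- character(0)
    for (it in seq_len(max_iter)) {
      con_dof <- 2L * cand[active]
      u <- .solve_constrained(K, fixed, con_dof, gap_um[active] * UM, n_dof)
      lambda <- as.vector(K[con_dof, , drop = FALSE] %*% u)  # reactions (N)
      release <- active[lambda > contact_tol]
      free_idx <- setdiff(pen0, active)
      pen <- free_idx[u[2L * cand[free_idx]] > gap_um[free_idx] * UM + 1e-13]
      trace <- c(trace, sprintf("it %d: active %d, release %d, add %d",
                                it, length(active), length(release), length(pen)))
      if (length(release) == 0 && length(pen) == 0) {
        converged <- TRUE
        break
      }
      active <- sort(union(setdiff(active, release), pen))
      if (length(active) == 0) active <- pen0[which.min(gap_um[pen0])]
    }
    if (!converged) {
      stop("contact active set did not converge at depth ", depth, " um:\n",
           paste(trace, collapse = "\n"))
    }
    con_dof <- 2L * cand[active]
    lambda <- as.vector(K[con_dof, , drop = FALSE] %*% u)
    steps <- rbind(steps, data.frame(depth_um = depth, force_N = -sum(lambda)))
  }

  stresses <- .centroid_stresses(mesh, material, u)
  structure(list(
    steps = steps,
    displacements = cbind(u_r = u[seq(1, n_dof, 2)] / UM,
                          u_z = u[seq(2, n_dof, 2)] / UM),
    stresses = stresses,
    contact_set = if (length(depths)) cand[active] else integer(0),
    mesh = mesh, material = material, indenter = indenter
  ), class = "indentation_result")
}

# solve K u = 0 subject to u[fixed] = 0 and u[con_dof] = g (metres).
.solve_constrained <- function(K, fixed, con_dof, g, n_dof) {
  con <- c(fixed, con_dof)
  vals <- c(numeric(length(fixed)), g)
  free <- setdiff(seq_len(n_dof), con)
  u <- numeric(n_dof)
  u[con] <- vals
  rhs <- -K[free, con_dof, drop = FALSE] %*% g
  Kff <- K[free, free, drop = FALSE]
  u[free] <- as.vector(Matrix::solve(Kff, rhs, sparse = TRUE))
  u
}

#' @export
print.indentation_result <- function(x, ...) {
  n <- nrow(x$steps)
  cat("Indentation result: ", n - 1, " load steps to depth ",
      x$steps$depth_um[n], " um; final force ",
      format(x$steps$force_N[n], digits = 4), " N; ",
      length(x$contact_set), " contact nodes\n", sep = "")
  invisible(x)
}
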