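# Axisymmetric small-strain linear elasticity on 4-node bilinear quads.
#
# Strain ordering (Voigt, engineering shear): (e_rr, e_zz, e_tt, g_rz) with
# e_tt = u_r / r. Element stiffness uses 2x2 Gauss quadrature on the
# deviatoric part and a single centroid point on the volumetric part
# (selective-reduced / B-bar), which keeps bilinear quads usable at Poisson
# ratios near 0.5. All assembly is in SI (m, Pa, N); mesh coordinates arrive
# in um and are converted here. The full 2*pi hoop factor is included so
# forces are total Newtons.

UM <- 1e-6  # metres per micrometre

# bilinear shape functions and parent-space derivatives at (xi, eta)
.quad_shape <- function(xi, eta) {
  list(
    N = c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
          (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4,
    dxi  = c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4,
    deta = c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
  )
}

# per-element geometry factors at one quadrature point, vectorised over
# elements: derivatives dN/dr, dN/dz (ne x 4), radius r (ne), jacobian det.
.gp_geometry <- function(Rm, Zm, sh) {
  J11 <- Rm %*% sh$dxi; J12 <- Zm %*% sh$dxi
  J21 <- Rm %*% sh$deta; J22 <- Zm %*% sh$deta
  detJ <- as.vector(J11 * J22 - J12 * J21)
  if (any(detJ <= 0)) stop("inverted element: non-positive Jacobian")
  dNr <- matrix(0, nrow(Rm), 4)
  dNz <- matrix(0, nrow(Rm), 4)
  for (a in 1:4) {
    dNr[, a] <- (as.vector(J22) * sh$dxi[a] - as.vector(J12) * sh$deta[a]) / detJ
    dNz[, a] <- (-as.vector(J21) * sh$dxi[a] + as.vector(J11) * sh$deta[a]) / detJ
  }
  list(dNr = dNr, dNz = dNz, r = as.vector(Rm %*% sh$N), detJ = detJ,
       N = matrix(sh$N, nrow(Rm), 4, byrow = TRUE))
}

#' Assemble the axisymmetric elastic stiffness operator
#'
#' Builds the symmetric sparse stiffness matrix (SI units: N/m per dof pair)
#' for the mesh and material. No boundary conditions are applied here; the
#' operator has rigid-body modes until the bottom and axis constraints are
#' imposed by the solver.
#'
#' @param mesh An [build_axisym_mesh()] mesh (coordinates in um).
#' @param material An [elastic_material()].
#' @return A symmetric `dgCMatrix` of dimension `2 * n_nodes`; dof `2i - 1`
#'   is `u_r` of node `i` (in metres), dof `2i` is `u_z`.
#' @export
assemble_system <- function(mesh, material) {
  stopifnot(inherits(mesh, "axisym_mesh"), inherits(material, "elastic_material"))
  E <- material$youngs_modulus
  nu <- material$poisson_ratio
  mu <- E / (2 * (1 + nu))
  Kb <- E / (3 * (1 - 2 * nu))           # bulk modulus
  # deviatoric moduli (Voigt): diag 4mu/3, off-diag -2mu/3, shear mu
  d11 <- 4 * mu / 3; d12 <- -2 * mu / 3; G <- mu

  conn <- mesh$elements
  ne <- nrow(conn)
  Rm <- matrix(mesh$nodes[conn, 1], ne, 4) * UM
  Zm <- matrix(mesh$nodes[conn, 2], ne, 4) * UM

  g <- 1 / sqrt(3)
  gps <- list(c(-g, -g), c(g, -g), c(g, g), c(-g, g))

  ii <- vector("list", 0); jj <- vector("list", 0); xx <- vector("list", 0)
  push <- function(i, j, x) {
    ii[[length(ii) + 1L]] <<- i
    jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- x
  }
  dof_r <- 2L * conn - 1L
  dof_z <- 2L * conn

  add_block <- function(geo, w, dev) {
    dNr <- geo$dNr; dNz <- geo$dNz
    No <- geo$N / geo$r   # N_a / r (ne x 4)
    if (dev) {
      for (a in 1:4) for (b in 1:4) {
        k11 <- dNr[, a] * (d11 * dNr[, b] + d12 * No[, b]) +
               No[, a] * (d12 * dNr[, b] + d11 * No[, b]) +
               dNz[, a] * G * dNz[, b]
        k12 <- dNr[, a] * d12 * dNz[, b] + No[, a] * d12 * dNz[, b] +
               dNz[, a] * G * dNr[, b]
        k21 <- dNz[, a] * (d12 * dNr[, b] + d12 * No[, b]) +
               dNr[, a] * G * dNz[, b]
        k22 <- dNz[, a] * d11 * dNz[, b] + dNr[, a] * G * dNr[, b]
        push(dof_r[, a], dof_r[, b], k11 * w)
        push(dof_r[, a], dof_z[, b], k12 * w)
        push(dof_z[, a], dof_r[, b], k21 * w)
        push(dof_z[, a], dof_z[, b], k22 * w)
      }
    } else {
      # volumetric rank-one term: b_vol = (dN/dr + N/r, dN/dz)
      for (a in 1:4) for (b in 1:4) {
        bra <- dNr[, a] + No[, a]; brb <- dNr[, b] + No[, b]
        push(dof_r[, a], dof_r[, b], Kb * bra * brb * w)
        push(dof_r[, a], dof_z[, b], Kb * bra * dNz[, b] * w)
        push(dof_z[, a], dof_r[, b], Kb * dNz[, a] * brb * w)
        push(dof_z[, a], dof_z[, b], Kb * dNz[, a] * dNz[, b] * w)
      }
    }
  }

  for (gp in gps) {
    sh <- .quad_shape(gp[1], gp[2])
    geo <- .gp_geometry(Rm, Zm, sh)
    add_block(geo, 2 * pi * geo$r * geo$detJ, dev = TRUE)
  }
  shc <- .quad_shape(0, 0)
  geoc <- .gp_geometry(Rm, Zm, shc)
  add_block(geoc, 2 * pi * geoc$r * geoc$detJ * 4, dev = FALSE)

  n_dof <- 2L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n_dof, n_dof))
  (K + Matrix::t(K)) / 2
}

# element centroid stresses (Pa) from a full displacement vector u (metres).
# Returns ne x 4 matrix with columns (s_rr, s_zz, s_tt, s_rz).
.centroid_stresses <- function(mesh, material, u) {
  E <- material$youngs_modulus
  nu <- material$poisson_ratio
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  conn <- mesh$elements
  ne <- nrow(conn)
  Rm <- matrix(mesh$nodes[conn, 1], ne, 4) * UM
  Zm <- matrix(mesh$nodes[conn, 2], ne, 4) * UM
  geo <- .gp_geometry(Rm, Zm, .quad_shape(0, 0))
  ur <- matrix(u[2L * conn - 1L], ne, 4)
  uz <- matrix(u[2L * conn], ne, 4)
  e_rr <- rowSums(geo$dNr * ur)
  e_zz <- rowSums(geo$dNz * uz)
  e_tt <- rowSums(geo$N * ur) / geo$r
  g_rz <- rowSums(geo$dNz * ur) + rowSums(geo$dNr * uz)
  tr <- e_rr + e_zz + e_tt
  cbind(s_rr = lam * tr + 2 * mu * e_rr,
        s_zz = lam * tr + 2 * mu * e_zz,
        s_tt = lam * tr + 2 * mu * e_tt,
        s_rz = mu * g_rz)
}
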