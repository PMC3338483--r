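stress_row <- function(s_rr = 0, s_zz = 0, s_tt = 0, s_rz = 0) {
  matrix(c(s_rr, s_zz, s_tt, s_rz), 1,
         dimnames = list(NULL, c("s_rr", "s_zz", "s_tt", "s_rz")))
}

test_that("von Mises stress handles uniaxial, hydrostatic and shear states", {
  expect_equal(von_mises_field(stress_row(s_zz = -100)), 100)
  expect_equal(von_mises_field(stress_row(50, 50, 50, 0)), 0)
  tau <- 7
  expect_equal(von_mises_field(stress_row(s_rz = tau)), sqrt(3) * tau)
})

test_that("interface stress equals a brute-force scan of bottom elements", {
  mesh <- build_axisym_mesh(gel_geometry(25, 500), fine_size = 1)
  res <- solve_contact_indentation(mesh, elastic_material(),
                                   indenter_spec(5, 2.5, 3))
  vm <- von_mises_field(res)
  bottom_nodes <- mesh$boundary$bottom
  brute <- max(vm[apply(mesh$elements, 1,
                        function(el) any(el %in% bottom_nodes))])
  expect_equal(interface_stress(res), brute)
})

test_that("zero-load result has zero interface stress", {
  mesh <- small_mesh()
  res <- solve_contact_indentation(mesh, elastic_material(),
                                   indenter_spec(5, 0, 1))
  expect_equal(interface_stress(res), 0)
})

test_that("effective stiffness is the straight-line slope of F vs depth", {
  UM <- 1e-6
  lin <- data.frame(depth_um = 0:5, force_N = 3 * (0:5) * UM)
  expect_equal(effective_stiffness(lin), 3)
  pts <- data.frame(depth_um = c(0, 1, 2), force_N = c(0, 1, 3) * UM)
  expect_equal(effective_stiffness(pts), 1.5)
  expect_error(effective_stiffness(lin[1, , drop = FALSE]), "2 load steps")
})

test_that("a Hertz-shaped curve yields a slope close to the end secant", {
  # free-intercept straight line through F = c * d^(3/2): analytically the
  # slope/secant ratio tends to 36/35 for dense sampling on [0, d_max]
  d <- seq(0, 5, length.out = 11)
  curve <- data.frame(depth_um = d, force_N = d^1.5 * 1e-9)
  k <- effective_stiffness(curve)
  secant <- utils::tail(curve$force_N, 1) / (5 * 1e-6)
  expect_gt(k / secant, 2 / 3)
  expect_lt(k / secant, 36 / 35 + 0.01)
})

test_that("Hertz oracle evaluates the closed form", {
  mat <- elastic_material(450, 0.45)
  expect_equal(hertz_half_space_force(mat, 5, 0), 0)
  expect_equal(hertz_half_space_force(mat, 5, 0.25), 2.1029e-10,
               tolerance = 1e-4)
  expect_equal(hertz_half_space_force(mat, 5, 1) * 8,
               hertz_half_space_force(mat, 5, 4), tolerance = 1e-12)
})

test_that("bonded-layer correction has the documented limits and monotonicity", {
  expect_equal(bonded_layer_correction(5, 5, 1e12), 1, tolerance = 1e-10)
  # chi = sqrt(5 * 5) / 50 = 0.1
  expect_equal(bonded_layer_correction(5, 5, 50), 1.1269, tolerance = 1e-4)
  h <- c(12.5, 25, 50, 100, 200)
  expect_true(all(diff(bonded_layer_correction(5, 5, h)) < 0))
})
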