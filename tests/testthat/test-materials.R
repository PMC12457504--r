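test_that("reference compliance entries follow the orthotropic layout", {
  m <- build_cell_wall_material(cell_wall_params("axial"))
  D <- m$D * 1000  # 1/MPa -> 1/GPa
  expect_equal(D[1, 1], 1 / 5.8)
  expect_equal(D[1, 2], -0.24 / 5.8)
  expect_equal(D[1, 3], -0.19 / 5.8)
  expect_equal(D[2, 3], -0.02 / 3.7)
  expect_equal(D[4, 4], 1 / 1.2)   # shear 23
  expect_equal(D[5, 5], 1 / 4.4)
  expect_equal(D[6, 6], 1 / 1.0)
  expect_equal(m$beta, c(0.16, 0.40, 0.01))
  r <- build_cell_wall_material(cell_wall_params("ray"))
  expect_equal(1 / (r$D[3, 3] * 1000), 13.0)
  expect_equal(r$beta, c(0.17, 0.43, 0.00))
})

test_that("isotropic parameters reproduce the closed-form isotropic stiffness", {
  E <- 10; nu <- 0.3; G <- E / (2 * (1 + nu))
  p <- cell_wall_params("axial", E = c(E, E, E), nu = c(nu, nu, nu),
                        G = c(G, G, G), beta = c(0.1, 0.1, 0.1))
  m <- build_cell_wall_material(p)
  expect_equal(m$C, iso_stiffness(E * 1000, nu), tolerance = 1e-10)
})

test_that("stiffness and compliance are mutual inverses for random valid parameters", {
  set.seed(5)
  for (i in 1:5) {
    p <- cell_wall_params("axial",
                          E = runif(3, 2, 20), nu = runif(3, 0.01, 0.3),
                          G = runif(3, 0.5, 6), beta = runif(3, 0, 0.5))
    m <- build_cell_wall_material(p)
    expect_lt(max(abs(m$C %*% m$D - diag(6))), 1e-10)
  }
})

test_that("non-positive-definite parameter sets are rejected with the eigenvalue", {
  p <- cell_wall_params("axial", nu = c(0.9, 0.9, 0.9))
  expect_error(build_cell_wall_material(p), "positive definite.*eigenvalue|eigenvalue")
})

test_that("moisture scaling is 1 at the reference and interpolates within the hull", {
  tab <- data.frame(param = "E1", m = c(0, 12, 24), multiplier = c(1.3, 1.0, 0.7))
  sc <- moisture_scaling(tab)
  m12 <- build_cell_wall_material(cell_wall_params("axial"), 12, sc)
  ref <- build_cell_wall_material(cell_wall_params("axial"))
  expect_equal(m12$C, ref$C)
  m18 <- build_cell_wall_material(cell_wall_params("axial"), 18, sc)
  expect_equal(1 / m18$D[1, 1] / 1000, 5.8 * 0.85)
  expect_error(build_cell_wall_material(cell_wall_params("axial"), 30, sc),
               "hull")
})

test_that("orientation angle follows the level-set gradient convention", {
  # phi increasing in y (phi_x = 0, phi_y = 1): alpha = 0
  d <- c(6, 6, 3)
  phi_y <- new_level_set(array(rep(rep(1:6, each = 6), 3), d) * 1.0, 1)
  o1 <- compute_orientation(phi_y, periodic = FALSE)
  expect_equal(o1$alpha[3, 3, 2], 0)
  # phi increasing in x (phi_x = 1, phi_y = 0): alpha = pi/2
  phi_x <- new_level_set(array(rep(1:6, 18) * 1.0, d), 1)
  o2 <- compute_orientation(phi_x, periodic = FALSE)
  expect_equal(o2$alpha[3, 3, 2], pi / 2)
  expect_true(all(o1$alpha > -pi / 2 & o1$alpha <= pi / 2))
})

test_that("cylindrical level set yields wall-tangent angles within 2 degrees", {
  n <- 40
  phi <- analytic_levelset("cylinder", list(center = c(20, 20), radius = 10),
                           c(n, n, 4), 1)
  o <- suppressWarnings(compute_orientation(phi, periodic = FALSE))
  xc <- (1:n) - 0.5
  wall <- which(phi$phi >= 0.5 & phi$phi < 2, arr.ind = TRUE)
  th <- atan2(xc[wall[, 2]] - 20, xc[wall[, 1]] - 20)
  # tangent direction = theta + pi/2, reduced to (-pi/2, pi/2]
  expected <- ((th + pi / 2 + pi / 2) %% pi) - pi / 2
  err <- angle_error_deg(o$alpha[wall], expected)
  expect_lt(max(err), 2)
})

test_that("ray elements use the y-z slice with the 3-axis along x", {
  # phi increasing in z only: for a ray cell, alpha = 0
  d <- c(4, 6, 6)
  phi_z <- new_level_set(array(rep(1:6, each = 24) * 1.0, d), 1)
  ct <- array("ray", d)
  o <- compute_orientation(phi_z, ct, periodic = FALSE)
  expect_equal(o$alpha[2, 3, 3], 0)
  expect_equal(o$cell_type[2, 3, 3], 2L)
})

test_that("degenerate gradients are filled from neighbors, never silently zeroed", {
  d <- c(5, 5, 3)
  arr <- array(rep(1:5, 15) * 1.0, d)   # gradient in x -> alpha = pi/2
  arr[3, 3, 2] <- arr[2, 3, 2]          # flat spot
  o <- suppressWarnings(compute_orientation(new_level_set(arr, 1),
                                            periodic = FALSE))
  expect_equal(o$alpha[3, 3, 2], pi / 2, tolerance = 1e-6)
})

test_that("Bond rotation has the expected structure and group properties", {
  m <- build_cell_wall_material(cell_wall_params("axial"))
  # alpha = 0: identity mapping
  r0 <- rotate_material(m$C, m$beta, 0, "axial")
  expect_equal(r0$C, m$C)
  expect_equal(r0$beta[1:3], m$beta)
  # alpha = pi/2 then -pi/2 composes to identity
  r1 <- rotate_material(m$C, m$beta, pi / 2, "axial")
  # rotate the rotated tensor back: equivalent to rotating local by 0
  C90 <- r1$C
  # 90 degrees about z: x<->y swap pattern on the stiffness
  expect_equal(C90[1, 1], m$C[2, 2])
  expect_equal(C90[2, 2], m$C[1, 1])
  expect_equal(C90[4, 4], m$C[5, 5])
  expect_equal(C90[5, 5], m$C[4, 4])
  # Kelvin-form eigenvalues are rotation invariant
  kelvin <- function(C) {
    # engineering Voigt -> Kelvin (tensorial) form: T C T with sqrt(2)
    # shear scaling; its eigenvalues are frame invariant
    T <- diag(c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2)))
    T %*% C %*% T
  }
  ev0 <- sort(eigen(kelvin(m$C), symmetric = TRUE, only.values = TRUE)$values)
  set.seed(8)
  for (a in runif(4, -pi / 2, pi / 2)) {
    for (ctype in c("axial", "ray")) {
      r <- rotate_material(m$C, m$beta, a, ctype)
      ev <- sort(eigen(kelvin(r$C), symmetric = TRUE, only.values = TRUE)$values)
      expect_equal(ev, ev0, tolerance = 1e-9)
      # rotated stiffness stays symmetric positive definite
      expect_lt(max(abs(r$C - t(r$C))), 1e-8 * max(abs(r$C)))
      expect_gt(min(eigen((r$C + t(r$C)) / 2, symmetric = TRUE,
                          only.values = TRUE)$values), 0)
      # trace of the expansion tensor is rotation invariant
      expect_equal(sum(r$beta[1:3]), sum(m$beta), tolerance = 1e-12)
    }
  }
})
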