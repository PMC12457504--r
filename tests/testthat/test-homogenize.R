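solve_model <- function(model, tol = 1e-9) {
  asm <- assemble_system(model)
  solve_cell_problems(asm, diagonal_preconditioner(asm), tol = tol)
}

test_that("homogeneous solid unit cell returns its own material exactly", {
  phi <- new_level_set(array(1, c(4, 4, 4)), 1)
  model <- suppressWarnings(build_xfem_model(phi))
  sol <- solve_model(model)
  eff <- homogenize(sol, model)
  mat <- build_cell_wall_material(cell_wall_params("axial"))
  expect_equal(eff$Cbar, mat$C, tolerance = 1e-8)
  expect_equal(eff$beta_bar, mat$beta, tolerance = 1e-8)
  expect_lt(max(abs(sol$N)), 1e-8)
  expect_lt(max(abs(sol$b)), 1e-8)
  # free expansion: uniform strain beta * dm, zero stress
  ff <- reconstruct_fields(sol, model, 1, "free", eff$beta_bar_full)
  expect_lt(max(abs(ff$sigma)), 1e-6 * max(abs(mat$C %*% c(mat$beta, 0, 0, 0))))
  expect_equal(colMeans(ff$eps), c(mat$beta, 0, 0, 0), tolerance = 1e-8)
  # constrained expansion: zero strain, uniform stress -C:beta dm
  fc <- reconstruct_fields(sol, model, 1, "constrained")
  expect_lt(max(abs(fc$eps)), 1e-10)
  expect_equal(fc$sigma[1, ], as.vector(-mat$C %*% c(mat$beta, 0, 0, 0)),
               tolerance = 1e-8)
})

test_that("two-phase laminate matches the closed-form series/parallel result", {
  Ca <- iso_stiffness(10000, 0.3)
  Cb <- iso_stiffness(2000, 0.2)
  ba <- c(0.1, 0.1, 0.1, 0, 0, 0)
  bb <- c(0.4, 0.4, 0.4, 0, 0, 0)
  model <- laminate_model(8, Ca, Cb, ba, bb)
  sol <- solve_model(model, tol = 1e-10)
  eff <- homogenize(sol, model)
  C_exact <- backus_laminate(list(Ca, Cb), c(0.5, 0.5))
  expect_lt(max(abs(eff$Cbar - C_exact)) / max(abs(C_exact)), 1e-6)
  # constrained expansion: sigma_xx continuous (traction continuity across
  # layers normal to x)
  fc <- reconstruct_fields(sol, model, 1, "constrained")
  expect_lt(diff(range(fc$sigma[, 1])), 1e-6 * max(abs(fc$sigma)))
  # free expansion: volume-average stress vanishes, <eps> = beta_bar dm
  ff <- reconstruct_fields(sol, model, 1, "free", eff$beta_bar_full)
  expect_lt(max(abs(colMeans(ff$sigma))), 1e-6 * max(abs(fc$sigma)))
  expect_equal(colMeans(ff$eps), eff$beta_bar_full, tolerance = 1e-6)
  # constrained: volume-average strain vanishes
  expect_lt(max(abs(colMeans(fc$eps))), 1e-9)
})

test_that("porous cell stiffness respects the Voigt dilution bound", {
  # centered cylindrical void along z
  n <- 10
  phi <- analytic_levelset("cylinder", list(center = c(n / 2, n / 2),
                                            radius = 2.6), c(n, n, 4), 1)
  model <- suppressWarnings(build_xfem_model(phi))
  mat <- build_cell_wall_material(cell_wall_params("axial"))
  # homogeneous (unrotated) solid so the Voigt average is f_solid * C
  for (g in names(model$groups)) {
    model$groups[[g]]$C[] <- as.vector(mat$C)
    model$groups[[g]]$beta[] <- c(mat$beta, 0, 0, 0)
  }
  sol <- solve_model(model)
  eff <- homogenize(sol, model)
  # solid volume fraction from the quadrature weights themselves
  wsum <- sum(vapply(model$groups, function(g) sum(g$wdet), numeric(1)))
  fsolid <- wsum / (model$mesh$n_elements * prod(model$mesh$spacing))
  ev <- eigen(fsolid * mat$C - eff$Cbar, symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), -1e-6 * max(abs(mat$C)))
  expect_lt(eff$off_orthotropy, 0.05)
})

test_that("effective stiffness converges under mesh refinement (cylinder fixture)", {
  c11 <- vapply(c(6, 9, 12), function(n) {
    phi <- analytic_levelset("cylinder",
                             list(center = c(n / 2, n / 2), radius = 0.26 * n),
                             c(n, n, 2), 6 / n)
    model <- suppressWarnings(build_xfem_model(phi))
    sol <- solve_model(model)
    homogenize(sol, model)$Cbar[1, 1]
  }, numeric(1))
  # Cauchy contraction of successive differences
  expect_lt(abs(c11[3] - c11[2]), abs(c11[2] - c11[1]))
})

test_that("orthotropic constants round-trip and report off-orthotropy", {
  mat <- build_cell_wall_material(cell_wall_params("axial"))
  out <- extract_orthotropic_constants(mat$C)
  k <- out$constants
  expect_equal(unname(k["E_R"]) / 1000, 5.8, tolerance = 1e-9)
  expect_equal(unname(k["E_T"]) / 1000, 3.7, tolerance = 1e-9)
  expect_equal(unname(k["E_L"]) / 1000, 18.3, tolerance = 1e-9)
  expect_equal(unname(k["nu_RT"]), 0.24, tolerance = 1e-9)
  expect_equal(unname(k["G_RT"]) / 1000, 1.0, tolerance = 1e-9)
  expect_equal(out$off_orthotropy, 0)
  # symmetry relations of the engineering constants
  expect_equal(unname(k["nu_RT"] / k["E_R"]), unname(k["nu_TR"] / k["E_T"]),
               tolerance = 1e-12)
  # rotated (non-orthotropic) stiffness: residual > 0, constants still returned
  rot <- rotate_material(mat$C, mat$beta, 0.4, "axial")
  out2 <- extract_orthotropic_constants(rot$C)
  expect_gt(out2$off_orthotropy, 0)
  expect_true(all(is.finite(out2$constants)))
})
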