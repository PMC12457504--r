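test_that("periodic node reduction and DOF map behave on a 2x2x2 grid", {
  mesh <- hex_mesh(c(2, 2, 2), 1)
  expect_equal(mesh$n_nodes, 8)   # 27 grid nodes reduce to 8 unique
  en <- ringhomog:::element_nodes(mesh)
  expect_equal(dim(en), c(8L, 8L))
  expect_true(all(sort(unique(as.vector(en))) == 1:8))
  dm <- build_periodic_dof_map(mesh, en, rep(1L, 8))
  expect_equal(dm$n_dof, 24)
})

test_that("assembled periodic stiffness is symmetric with a translational nullspace", {
  phi <- new_level_set(array(1, c(3, 3, 3)), 1)
  model <- suppressWarnings(build_xfem_model(phi))
  asm <- assemble_system(model)
  K <- as.matrix(asm$K)
  expect_lt(max(abs(K - t(K))), 1e-9 * max(abs(K)))
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 3)
  # homogeneous material: loads are self-equilibrated (and here zero)
  expect_lt(max(abs(asm$F)), 1e-9 * max(abs(K)))
  expect_lt(max(abs(asm$f)), 1e-9 * max(abs(K)))
})

test_that("two-element periodic patch equals a hand-assembled matrix", {
  phi <- new_level_set(array(1, c(2, 1, 1)), 1)
  model <- suppressWarnings(build_xfem_model(phi))
  asm <- assemble_system(model)
  C <- matrix(model$groups$solid$C[, 1], 6, 6)
  q <- moment_fit_weights(rep(1, 8))
  Ke <- integrate_element(C, c(0, 0, 0, 0, 0, 0), q, 1)$K
  # hand scatter: element 1 nodes (1,2,2,1,...) under x-periodic wrap of a
  # 2x1x1 grid with 2 unique nodes
  en <- ringhomog:::element_nodes(model$mesh)
  ndof <- asm$model$dofmap$n_dof
  K_hand <- matrix(0, ndof, ndof)
  for (e in 1:2) {
    dofs <- as.vector(rbind(3 * en[, e] - 2, 3 * en[, e] - 1, 3 * en[, e]))
    for (a in 1:24) for (b in 1:24) {
      K_hand[dofs[a], dofs[b]] <- K_hand[dofs[a], dofs[b]] + Ke[a, b]
    }
  }
  expect_equal(as.matrix(asm$K), K_hand, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("element pseudo-inverse blocks follow the spectral threshold rule", {
  # diagonal block: entries above the threshold invert, others vanish
  d <- c(2, 5, 1e-20, rep(1, 21))
  Kel <- matrix(as.vector(diag(d)), ncol = 1)
  Sel <- ringhomog:::cpp_pinv_blocks(Kel, 1e-13)
  Sinv <- matrix(Sel[, 1], 24, 24)
  expect_equal(diag(Sinv)[1:3], c(0.5, 0.2, 0))
  # a rigid-body mode of a real element maps to zero
  C <- iso_stiffness(1000, 0.3)
  Ke <- integrate_element(C, rep(0, 6), moment_fit_weights(rep(1, 8)), 1)$K
  Sp <- matrix(ringhomog:::cpp_pinv_blocks(matrix(as.vector(Ke), ncol = 1),
                                           1e-13)[, 1], 24, 24)
  u <- rep(c(1, 0, 0), 8)
  expect_lt(max(abs(Sp %*% u)), 1e-10 * max(abs(Sp)))
  # pseudo-inverse inverts K on its range: K S K = K
  expect_lt(max(abs(Ke %*% Sp %*% Ke - Ke)), 1e-8 * max(abs(Ke)))
})

test_that("PCG with the element preconditioner matches a dense direct solve", {
  # 4^3 mesh with a plane cut (solid, cut and void elements)
  n <- 4
  phi_arr <- array(0, c(n, n, n))
  xs <- (1:n) - 0.5
  for (i in 1:n) phi_arr[i, , ] <- 2.6 - xs[i]
  model <- suppressWarnings(build_xfem_model(new_level_set(phi_arr, 1),
                                             cut_regularization = 0))
  asm <- assemble_system(model)
  S <- build_preconditioner(asm, 1e-13)
  sol <- pcg_solve(asm$K, cbind(-asm$F, asm$f), S,
                   model$dofmap$comp_index, tol = 1e-12, max_iter = 500)
  expect_true(all(sol$converged))
  # dense pseudo-inverse oracle with the same zero-mean gauge
  X_ref <- MASS::ginv(as.matrix(asm$K)) %*% cbind(-asm$F, asm$f)
  X_ref <- ringhomog:::project_translations(X_ref, model$dofmap$comp_index)
  expect_lt(max(abs(sol$X - X_ref)) / max(abs(X_ref)), 1e-8)
})

test_that("the element preconditioner improves conditioning and bounds sliver blow-up", {
  # condition number of the preconditioned operator on a solid mesh
  phi <- new_level_set(array(1, c(3, 3, 3)), 1)
  model <- suppressWarnings(build_xfem_model(phi))
  asm <- assemble_system(model)
  S <- build_preconditioner(asm, 1e-13)
  K <- as.matrix(asm$K)
  SK <- as.matrix(S) %*% K
  ev <- sort(Re(eigen(SK, only.values = TRUE)$values))
  ev <- ev[ev > 1e-8 * max(ev)]
  evK <- sort(eigen((K + t(K)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values)
  evK <- evK[evK > 1e-8 * max(evK)]
  expect_lt(max(ev) / min(ev), max(evK) / min(evK))
  # on a catastrophic sliver slab, plain CG diverges while the
  # preconditioned residual stays bounded
  n <- 6
  phi_arr <- array(0, c(n, n, n))
  xs <- (1:n) - 0.5
  for (i in 1:n) phi_arr[i, , ] <- 3.05 - xs[i]
  m2 <- suppressWarnings(build_xfem_model(new_level_set(phi_arr, 1),
                                          cut_regularization = 0))
  asm2 <- assemble_system(m2)
  rhs <- cbind(-asm2$F, asm2$f)
  plain <- pcg_solve(asm2$K, rhs, NULL, m2$dofmap$comp_index,
                     tol = 1e-8, max_iter = 400)
  prec <- pcg_solve(asm2$K, rhs, build_preconditioner(asm2, 1e-13),
                    m2$dofmap$comp_index, tol = 1e-8, max_iter = 400)
  expect_false(all(plain$converged))
  expect_gt(max(plain$residuals), 1e3)
  expect_lt(max(prec$residuals), 1e-4 * max(plain$residuals))
})

test_that("cell-problem solutions are zero-mean, energy-consistent and gauge invariant", {
  ph <- generate_growth_ring_phantom(
    phantom_spec(domain_size_voxels = c(16L, 8L, 4L), noise_sd = 0,
                 inhomogeneity_amplitude = 0,
                 vessel_radii_um = c(8, 4), vessel_fractions = c(0.05, 0)))
  seg <- make_periodic(segmented_mesostructure(ph$truth$binary_phase,
                                               ph$volume$spacing,
                                               cell_type = ph$truth$cell_type))
  phi <- init_level_set(seg$binary_phase, seg$spacing)
  model <- suppressWarnings(build_xfem_model(phi, seg$cell_type,
                                             seg$added_layers))
  asm <- assemble_system(model)
  sol <- solve_cell_problems(asm, diagonal_preconditioner(asm), tol = 1e-9)
  expect_true(sol$converged)
  # zero volume average per displacement component
  for (idx in model$dofmap$comp_index) {
    for (j in 1:6) {
      expect_lt(abs(mean(sol$N[idx, j])),
                1e-8 * max(sqrt(mean(sol$N[, j]^2)), 1e-12))
    }
  }
  # energy consistency: N^T K N >= 0 for every column
  for (j in 1:6) {
    expect_gte(as.numeric(t(sol$N[, j]) %*% (asm$K %*% sol$N[, j])), -1e-8)
  }
  # gauge invariance: adding a constant per component leaves Cbar unchanged
  eff0 <- homogenize(sol, model)
  sol2 <- sol
  shift <- rep(0, nrow(sol$N)); shift[model$dofmap$comp_index[[1]]] <- 0.37
  sol2$N <- sol$N + outer(shift, rep(1, 6))
  sol2$b <- sol$b + shift
  eff1 <- homogenize(sol2, model)
  expect_equal(eff1$Cbar, eff0$Cbar, tolerance = 1e-9)
  expect_equal(eff1$beta_bar, eff0$beta_bar, tolerance = 1e-9)
})
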