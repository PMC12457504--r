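#' Build the XFEM model for a periodic segmented unit cell
#'
#' Maps voxels to eight-node hexahedral elements, interpolates the level
#' set to nodes, classifies elements (solid / void / cut), computes
#' moment-fitted quadrature weights for cut elements and the standard
#' 2x2x2 Gauss rule for solid elements, builds the per-element
#' global-frame material field from the orientation angles, and sets up
#' the periodic DOF map (nodes touching only void elements are
#' deactivated).
#'
#' @param phi a `level_set` on the periodized voxel grid.
#' @param cell_type per-voxel labels (`"axial"`/`"ray"`/`"void"`) or NULL.
#' @param added_layers logical array marking artificial periodicity tie
#'   layers (their orientation is pinned to 0), or NULL.
#' @param m moisture content, % (default 12).
#' @param scaling a [moisture_scaling()].
#' @param params_axial,params_ray [cell_wall_params()] for the two classes.
#' @param p_q moment-fitting quadrature order (default 2).
#' @param n_c sub-cells per cut element (default 1000).
#' @param cut_regularization relative fictitious stiffness `alpha` assigned
#'   to the void part of cut elements (effective weights
#'   `(1 - alpha) w_moment + alpha w_full`). Bounds the conditioning caused
#'   by sliver cuts; 0 disables. Default `1e-6`.
#' @return object of class `xfem_model`.
#' @export
build_xfem_model <- function(phi, cell_type = NULL, added_layers = NULL,
                             m = 12, scaling = moisture_scaling(),
                             params_axial = cell_wall_params("axial"),
                             params_ray = cell_wall_params("ray"),
                             p_q = 2, n_c = 1000,
                             cut_regularization = 1e-6) {
  mesh <- hex_mesh(dim(phi$phi), phi$spacing)
  phin <- nodal_phi(phi$phi)
  enodes <- element_nodes(mesh)
  phi_nodes <- matrix(phin[enodes], nrow = 8)
  classes <- classify_elements(phi_nodes)
  dofmap <- build_periodic_dof_map(mesh, enodes, classes)

  orientation <- compute_orientation(phi, cell_type,
                                     force_zero = added_layers)
  mat_ax <- build_cell_wall_material(params_axial, m, scaling)
  mat_ray <- build_cell_wall_material(params_ray, m, scaling)

  basis <- subcell_factor_matrix(p_q, n_c)
  gl2 <- gauss_legendre(2)
  pts8 <- tensor_points(gl2$x)
  w8 <- as.vector(kronecker(kronecker(gl2$w, gl2$w), gl2$w))

  groups <- list()
  detJ <- prod(mesh$spacing) / 8
  for (gname in c("solid", "cut")) {
    idx <- which(classes == ifelse(gname == "solid", 1L, 2L))
    if (!length(idx)) next
    if (gname == "solid") {
      B <- b_matrix_cube(mesh$spacing, pts8)
      wdet <- matrix(w8 * detJ, nrow = 8, ncol = length(idx))
    } else {
      B <- b_matrix_cube(mesh$spacing, basis$points)
      wdet <- moment_fit_weights_batch(phi_nodes[, idx, drop = FALSE],
                                       basis) * detJ
      if (cut_regularization > 0) {
        wfull <- matrix(basis$full_weights * detJ, nrow = nrow(wdet),
                        ncol = ncol(wdet))
        wdet <- (1 - cut_regularization) * wdet +
          cut_regularization * wfull
      }
    }
    mf <- build_material_field(orientation, mat_ax, mat_ray, idx)
    groups[[gname]] <- list(
      elements = idx, B = B, wdet = as.matrix(wdet),
      C = mf$C, beta = mf$beta,
      conn = element_dofs(dofmap, enodes[, idx, drop = FALSE]))
  }
  structure(list(mesh = mesh, classes = classes, dofmap = dofmap,
                 groups = groups, orientation = orientation,
                 materials = list(axial = mat_ax, ray = mat_ray),
                 phi_nodes = phi_nodes, basis = basis, m = m,
                 cut_regularization = cut_regularization),
            class = "xfem_model")
}

#' @export
print.xfem_model <- function(x, ...) {
  tab <- table(factor(x$classes, levels = c(1, 0, 2),
                      labels = c("solid", "void", "cut")))
  cat(sprintf("<xfem_model> %s elements (%s), %d active nodes, %d DOFs\n",
              paste(x$mesh$dims, collapse = "x"),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$dofmap$n_active, x$dofmap$n_dof))
  invisible(x)
}

#' Stiffness and load contributions of a single element
#'
#' `K^e = sum_i w_i B^T C B det J`, unit-macroscopic-strain load columns
#' `F^e = sum_i w_i B^T C det J` and hygric load
#' `f^e = sum_i w_i B^T C beta det J`, with the trilinear-hex B-matrices
#' of an axis-aligned element. Void elements (zero-weight rules) yield
#' all-zero contributions.
#'
#' @param C 6x6 stiffness (MPa), global frame.
#' @param beta length-6 engineering expansion vector (a length-3 vector is
#'   zero-padded).
#' @param quad a [moment_fit_weights()] rule.
#' @param spacing element edge lengths (um).
#' @return list `K` (24x24), `F` (24x6), `f` (24).
#' @export
integrate_element <- function(C, beta, quad, spacing = 1) {
  spacing <- rep(spacing, length.out = 3)
  if (any(spacing <= 0)) stop("malformed spacing: singular Jacobian")
  if (length(beta) == 3) beta <- c(beta, 0, 0, 0)
  B <- b_matrix_cube(spacing, quad$points)
  detJ <- prod(spacing) / 8
  out <- cpp_element_system(B, matrix(as.vector(C), ncol = 1),
                            matrix(beta, ncol = 1),
                            matrix(quad$weights * detJ, ncol = 1),
                            matrix(1:24, ncol = 1), 24L)
  list(K = matrix(out$Kel[, 1], 24, 24), F = out$F, f = as.vector(out$f))
}

triplet_indices <- function(conn) {
  list(i = conn[rep(1:24, times = 24), , drop = FALSE],
       j = conn[rep(1:24, each = 24), , drop = FALSE])
}

#' Assemble the global periodic system
#'
#' Scatter-adds all element stiffness blocks into a sparse symmetric K on
#' the reduced periodic DOF numbering, along with the six
#' unit-macroscopic-strain load columns F and the hygric load f.
#'
#' @param model an [build_xfem_model()] result.
#' @return list `K` (sparse), `F` (n_dof x 6), `f` (n_dof), `Kel` per
#'   group (kept for the preconditioner).
#' @export
assemble_system <- function(model) {
  ndof <- model$dofmap$n_dof
  Fg <- matrix(0, ndof, 6)
  fg <- numeric(ndof)
  ii <- list(); jj <- list(); xx <- list()
  Kel <- list()
  for (gname in names(model$groups)) {
    g <- model$groups[[gname]]
    out <- cpp_element_system(g$B, g$C, g$beta, g$wdet, g$conn, ndof)
    Fg <- Fg + out$F
    fg <- fg + as.vector(out$f)
    tr <- triplet_indices(g$conn)
    ii[[gname]] <- as.vector(tr$i)
    jj[[gname]] <- as.vector(tr$j)
    xx[[gname]] <- as.vector(out$Kel)
    Kel[[gname]] <- out$Kel
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = unlist(xx), dims = c(ndof, ndof))
  K <- (K + Matrix::t(K)) / 2
  list(K = K, F = Fg, f = fg, Kel = Kel, model = model)
}

#' Element-sum spectral pseudo-inverse preconditioner
#'
#' `S = sum_e P_e^T (K^e_+)^{-1} P_e`, where the pseudo-inverse of each
#' element stiffness is obtained from its spectral decomposition with
#' eigenvalues at or below `lambda_th = eps * max_i(lambda_i)` zeroed.
#'
#' @param asm an [assemble_system()] result.
#' @param eps relative eigenvalue threshold (default 1e-13).
#' @return sparse symmetric matrix applied as an operator.
#' @export
build_preconditioner <- function(asm, eps = 1e-13) {
  ndof <- nrow(asm$K)
  ii <- list(); jj <- list(); xx <- list()
  for (gname in names(asm$Kel)) {
    g <- asm$model$groups[[gname]]
    Sel <- cpp_pinv_blocks(asm$Kel[[gname]], eps)
    tr <- triplet_indices(g$conn)
    ii[[gname]] <- as.vector(tr$i)
    jj[[gname]] <- as.vector(tr$j)
    xx[[gname]] <- as.vector(Sel)
  }
  S <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = unlist(xx), dims = c(ndof, ndof))
  (S + Matrix::t(S)) / 2
}
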