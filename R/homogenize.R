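#' Effective stiffness and hygro-expansion by asymptotic homogenization
#'
#' Discrete volume averages over the unit cell (void volume included in
#' `|Q|`; Heaviside-weighted quadrature carries the dilution):
#' `Cbar = (1/|Q|) sum_e sum_i w_i detJ C : (grad N1 + I)` and
#' `beta_bar = Cbar^{-1} (1/|Q|) sum_e sum_i w_i detJ C : (beta - grad b1)`.
#'
#' @param solution a [solve_cell_problems()] result.
#' @param model the [build_xfem_model()] used for the solve.
#' @return object of class `effective_properties`: `Cbar` (6x6, MPa),
#'   `beta_bar` (length-3 diagonal, %/%), `beta_bar_full` (length-6),
#'   `constants` (orthotropic engineering constants incl. anisotropy
#'   ratios), `off_orthotropy` (relative residual of the coupling terms).
#' @export
homogenize <- function(solution, model) {
  U <- cbind(solution$N, solution$b)
  Csum <- matrix(0, 6, 6)
  rsum <- numeric(6)
  for (g in model$groups) {
    acc <- cpp_homogenize_accum(g$B, g$C, g$beta, g$wdet, g$conn, U)
    Csum <- Csum + acc$Cbar_sum
    rsum <- rsum + acc$rbeta_sum
  }
  vol <- model$mesh$n_elements * prod(model$mesh$spacing)
  Cbar <- Csum / vol
  sym_res <- max(abs(Cbar - t(Cbar))) / max(abs(Cbar))
  Cbar <- (Cbar + t(Cbar)) / 2
  ev <- eigen(Cbar, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("effective stiffness not positive definite; spectrum: ",
         paste(signif(ev, 4), collapse = ", "))
  beta_full <- as.vector(solve(Cbar, rsum / vol))
  constants <- extract_orthotropic_constants(Cbar)
  structure(list(Cbar = Cbar, beta_bar = beta_full[1:3],
                 beta_bar_full = beta_full,
                 constants = constants$constants,
                 off_orthotropy = constants$off_orthotropy,
                 symmetry_residual = sym_res),
            class = "effective_properties")
}

#' Orthotropic engineering constants from an effective stiffness
#'
#' Inverts the stiffness to the compliance and reads the nine orthotropic
#' constants (global x, y, z = R, T, L): Young's moduli from the diagonal,
#' Poisson's ratios from the off-diagonal block, shear moduli from the
#' shear diagonal. The residual norm of the compliance entries that exact
#' orthotropy would set to zero is reported rather than enforced.
#'
#' @param Cbar 6x6 symmetric positive-definite stiffness (MPa).
#' @return list `constants` (named: E_R, E_T, E_L in MPa, nu_RT, nu_RL,
#'   nu_TL, nu_TR, nu_LR, nu_LT, G_RT, G_LR, G_LT in MPa, ratio_ER_ET),
#'   `off_orthotropy` (relative residual).
#' @export
extract_orthotropic_constants <- function(Cbar) {
  D <- solve(Cbar)
  E_R <- 1 / D[1, 1]; E_T <- 1 / D[2, 2]; E_L <- 1 / D[3, 3]
  constants <- c(
    E_R = E_R, E_T = E_T, E_L = E_L,
    nu_RT = -D[1, 2] * E_R, nu_RL = -D[1, 3] * E_R,
    nu_TL = -D[2, 3] * E_T,
    nu_TR = -D[1, 2] * E_T, nu_LR = -D[1, 3] * E_L,
    nu_LT = -D[2, 3] * E_L,
    G_LT = 1 / D[4, 4], G_LR = 1 / D[5, 5], G_RT = 1 / D[6, 6],
    ratio_ER_ET = E_R / E_T)
  coupling <- c(D[1:3, 4:6], D[4, 5], D[4, 6], D[5, 6])
  off <- sqrt(sum(coupling^2)) / sqrt(sum(D^2))
  list(constants = constants, off_orthotropy = off)
}

#' @export
print.effective_properties <- function(x, ...) {
  k <- x$constants
  cat(sprintf(paste0(
    "<effective_properties>\n",
    "  E_R = %.1f MPa, E_T = %.1f MPa, E_L = %.1f MPa (E_R/E_T = %.2f)\n",
    "  G_RT = %.1f, G_LR = %.1f, G_LT = %.1f MPa\n",
    "  nu_RT = %.3f, nu_RL = %.3f, nu_TL = %.3f\n",
    "  beta_R = %.3f, beta_T = %.3f, beta_L = %.3f %%/%% ",
    "(beta_T/beta_R = %.2f)\n",
    "  off-orthotropy residual %.2e\n"),
    k["E_R"], k["E_T"], k["E_L"], k["ratio_ER_ET"],
    k["G_RT"], k["G_LR"], k["G_LT"],
    k["nu_RT"], k["nu_RL"], k["nu_TL"],
    x$beta_bar[1], x$beta_bar[2], x$beta_bar[3],
    x$beta_bar[2] / x$beta_bar[1], x$off_orthotropy))
  invisible(x)
}

#' Reconstruct local strain and stress fields under moisture loading
#'
#' Element-center strains from the influence-function gradients:
#' constrained expansion (zero average deformation)
#' `eps = grad b1 * dm`; free expansion (zero average stress)
#' `eps = (beta_bar + grad N1 : beta_bar + grad b1) * dm`. Stresses follow
#' from `sigma = C : (eps - beta * dm)`. Fields are attached to solid and
#' cut elements.
#'
#' @param solution a [solve_cell_problems()] result.
#' @param model the corresponding `xfem_model`.
#' @param delta_m moisture content change, %.
#' @param mode `"free"` or `"constrained"`.
#' @param beta_bar effective expansion (length-6 engineering or length-3),
#'   required for `"free"`.
#' @return object of class `local_fields`: `elements` (indices into the
#'   element grid), `eps`, `sigma` (ne x 6, engineering strain / MPa),
#'   `mode`, `delta_m`.
#' @export
reconstruct_fields <- function(solution, model, delta_m = 1,
                               mode = c("free", "constrained"),
                               beta_bar = NULL) {
  mode <- match.arg(mode)
  if (mode == "free") {
    if (is.null(beta_bar)) stop("free expansion requires beta_bar")
    if (length(beta_bar) == 3) beta_bar <- c(beta_bar, 0, 0, 0)
  }
  B0 <- b_matrix_cube(model$mesh$spacing, matrix(0, 1, 3))[, , 1]
  U <- cbind(solution$N, solution$b)
  elements <- integer(0)
  eps <- NULL; sig <- NULL
  for (g in model$groups) {
    ne <- length(g$elements)
    # element DOF values per influence-function column, then center strains
    Ue <- array(U[g$conn, ], dim = c(24, ne, 7))
    E <- array(0, c(ne, 6, 7))
    for (cidx in 1:7) {
      E[, , cidx] <- t(Ue[, , cidx]) %*% t(B0)
    }
    if (mode == "constrained") {
      e_loc <- E[, , 7] * delta_m
    } else {
      e_loc <- matrix(rep(beta_bar, each = ne), ne, 6)
      for (j in 1:6) e_loc <- e_loc + E[, , j] * beta_bar[j]
      e_loc <- (e_loc + E[, , 7]) * delta_m
    }
    d <- e_loc - t(g$beta) * delta_m
    s_loc <- matrix(0, ne, 6)
    Cm <- g$C
    for (i in 1:6) for (k in 1:6) {
      s_loc[, i] <- s_loc[, i] + Cm[i + 6 * (k - 1), ] * d[, k]
    }
    elements <- c(elements, g$elements)
    eps <- rbind(eps, e_loc)
    sig <- rbind(sig, s_loc)
  }
  structure(list(elements = elements, eps = eps, sigma = sig,
                 mode = mode, delta_m = delta_m),
            class = "local_fields")
}
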