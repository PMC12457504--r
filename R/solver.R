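# Periodic cell-problem solver: preconditioned conjugate gradients with
# per-component mean projection (rigid translations are the only nullspace
# on the reduced periodic DOF set; uniqueness is fixed by zero-mean
# fluctuation fields).

project_translations <- function(X, comp_index) {
  for (idx in comp_index) {
    m <- colMeans(X[idx, , drop = FALSE])
    X[idx, ] <- sweep(X[idx, , drop = FALSE], 2, m, "-")
  }
  X
}

#' Preconditioned conjugate gradients for multiple right-hand sides
#'
#' Solves `K X = B` column-wise (all columns advanced simultaneously so the
#' sparse matrix products are amortized), with left preconditioner `S` and
#' projection of iterates and preconditioned residuals onto the zero-mean
#' subspace of each displacement component.
#'
#' @param K sparse symmetric positive semi-definite matrix.
#' @param B right-hand sides (n x m).
#' @param S preconditioner (sparse matrix) or `NULL` for plain CG.
#' @param comp_index list of DOF index vectors per displacement component.
#' @param tol relative residual tolerance.
#' @param max_iter iteration cap.
#' @return list `X`, `iterations`, `residuals` (relative, per column),
#'   `converged` (logical per column).
#' @export
pcg_solve <- function(K, B, S = NULL, comp_index, tol = 1e-8,
                      max_iter = 1000) {
  B <- as.matrix(B)
  n <- nrow(B); m <- ncol(B)
  bnorm <- sqrt(colSums(B^2))
  live <- bnorm > 0
  X <- matrix(0, n, m)
  if (!any(live)) {
    return(list(X = X, iterations = 0L, residuals = rep(0, m),
                converged = rep(TRUE, m)))
  }
  R <- project_translations(B, comp_index)
  P <- NULL
  rho_old <- NULL
  res <- rep(0, m)
  it <- 0L
  for (it in seq_len(max_iter)) {
    Z <- if (is.null(S)) R else as.matrix(S %*% R)
    Z <- project_translations(Z, comp_index)
    rho <- colSums(R * Z)
    if (is.null(P)) {
      P <- Z
    } else {
      bet <- rho / rho_old
      bet[!is.finite(bet)] <- 0
      P <- Z + sweep(P, 2, bet, "*")
    }
    rho_old <- rho
    Q <- as.matrix(K %*% P)
    alpha <- rho / colSums(P * Q)
    alpha[!is.finite(alpha)] <- 0
    X <- X + sweep(P, 2, alpha, "*")
    R <- R - sweep(Q, 2, alpha, "*")
    res <- ifelse(live, sqrt(colSums(R^2)) / pmax(bnorm, 1e-300), 0)
    if (all(res <= tol)) break
  }
  X <- project_translations(X, comp_index)
  list(X = X, iterations = it, residuals = res,
       converged = res <= tol)
}

#' Diagonal (Jacobi) preconditioner
#'
#' Inverse-diagonal equilibration of the assembled stiffness. On
#' cut-dominated thin-walled meshes this is the robust default for the
#' cell-problem solves (see the methods vignette); the element-sum
#' spectral pseudo-inverse of [build_preconditioner()] remains available
#' and is effective for isolated thin cuts.
#'
#' @param asm an [assemble_system()] result.
#' @export
diagonal_preconditioner <- function(asm) {
  dg <- Matrix::diag(asm$K)
  floor_dg <- 1e-14 * max(dg)
  Matrix::Diagonal(x = 1 / pmax(dg, floor_dg))
}

#' Solve the periodic mechanical and hygric cell problems
#'
#' Six mechanical influence-function columns (one per independent
#' macroscopic strain component, Voigt order) solve `K N = -F`; the hygric
#' column solves `K b = f`. Each returned fluctuation field is periodic by
#' construction of the shared-DOF numbering and has zero mean per
#' displacement component.
#'
#' @param asm an [assemble_system()] result.
#' @param S preconditioner from [build_preconditioner()] (or `NULL`).
#' @param tol relative residual tolerance (default 1e-8).
#' @param max_iter iteration cap; default `ceiling(10 * sqrt(n_dof))`.
#' @return object of class `cell_solution`: `N` (n_dof x 6), `b` (n_dof),
#'   solver diagnostics.
#' @export
solve_cell_problems <- function(asm, S = NULL, tol = 1e-8,
                                max_iter = NULL) {
  ndof <- nrow(asm$K)
  max_iter <- max_iter %||% ceiling(10 * sqrt(ndof))
  ci <- asm$model$dofmap$comp_index
  rhs <- cbind(-asm$F, asm$f)
  sol <- pcg_solve(asm$K, rhs, S, ci, tol = tol, max_iter = max_iter)
  if (!all(sol$converged))
    warning(sprintf("cell problems not converged (max rel. residual %.3g)",
                    max(sol$residuals)))
  structure(list(N = sol$X[, 1:6, drop = FALSE], b = sol$X[, 7],
                 iterations = sol$iterations, residuals = sol$residuals,
                 converged = all(sol$converged)),
            class = "cell_solution")
}

#' @export
print.cell_solution <- function(x, ...) {
  cat(sprintf(
    "<cell_solution> %d DOFs, %d PCG iterations, max rel. residual %.3g%s\n",
    nrow(x$N), x$iterations, max(x$residuals),
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
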