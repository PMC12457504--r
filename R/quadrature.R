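#' Gauss-Legendre rule on [-1, 1]
#'
#' Golub-Welsch via the symmetric Jacobi matrix; exact for polynomials of
#' degree 2n - 1.
#'
#' @param n number of points.
#' @return list `x` (nodes), `w` (weights).
#' @export
gauss_legendre <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(x = 0, w = 2))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = 2 * (e$vectors[1, ord])^2)
}

# 1D Lagrange basis values: rows = evaluation points, cols = basis index
lagrange_basis_1d <- function(x, nodes) {
  n <- length(nodes)
  out <- matrix(1, length(x), n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (k == j) next
    out[, j] <- out[, j] * (x - nodes[k]) / (nodes[j] - nodes[k])
  }
  out
}

# tensor-product point set, x fastest
tensor_points <- function(x1d) {
  g <- expand.grid(r = x1d, s = x1d, t = x1d)
  as.matrix(g)
}

#' Precompute the moment-fitting sub-cell factor matrix
#'
#' For quadrature order `p_q` with Gauss-Legendre point locations and
#' `n_c` equal cubic sub-cells per cut element, entry `A[c, i]` is the
#' integral of the 3D tensor-product Lagrange basis `l_i` over sub-cell
#' `c`, evaluated with the sub-cell's 8 (2 x 2 x 2) Gauss points. The
#' matrix factorizes over axes, is computed once, and yields all
#' moment-fitted weights of a cut element as `t(A) %*% H` with `H` the
#' per-sub-cell Heaviside values.
#'
#' @param p_q quadrature order (>= 1).
#' @param n_c number of sub-cells (a perfect cube; default 1000).
#' @return list with `A` (n_c x n_i), `points` (n_i x 3 Gauss-Legendre
#'   locations), `full_weights` (standard rule), `centers` (n_c x 3
#'   sub-cell centers), `W_tri` (n_c x 8 trilinear weights at sub-cell
#'   centers).
#' @export
subcell_factor_matrix <- function(p_q = 2, n_c = 1000) {
  if (p_q < 1) stop("quadrature order p_q must be >= 1")
  na <- round(n_c^(1 / 3))
  if (na^3 != n_c) stop("n_c must be a perfect cube")
  gl <- gauss_legendre(p_q + 1)
  s <- 2 / na
  ax <- matrix(0, na, p_q + 1)
  g2 <- gauss_legendre(2)
  centers_1d <- -1 + (seq_len(na) - 0.5) * s
  for (c1 in seq_len(na)) {
    pts <- centers_1d[c1] + g2$x * s / 2
    L <- lagrange_basis_1d(pts, gl$x)
    ax[c1, ] <- as.vector((g2$w * s / 2) %*% L)
  }
  A <- kronecker(ax, kronecker(ax, ax))
  # linearization check: both sub-cells and basis are x-fastest, so
  # kron(Az, Ay, Ax) with identical axis factors
  A <- kronecker(kronecker(ax, ax), ax)
  pts3 <- tensor_points(gl$x)
  w3 <- as.vector(kronecker(kronecker(gl$w, gl$w), gl$w))
  ctr <- tensor_points(centers_1d)
  W_tri <- trilinear_weights(ctr)
  list(A = A, points = pts3, full_weights = w3, centers = ctr,
       W_tri = W_tri, p_q = p_q, n_c = n_c)
}

# trilinear hex shape functions at points (m x 3), standard corner order
hex_corner_signs <- function() {
  matrix(c(-1, -1, -1,
            1, -1, -1,
            1,  1, -1,
           -1,  1, -1,
           -1, -1,  1,
            1, -1,  1,
            1,  1,  1,
           -1,  1,  1), ncol = 3, byrow = TRUE)
}

trilinear_weights <- function(pts) {
  S <- hex_corner_signs()
  out <- matrix(0, nrow(pts), 8)
  for (a in 1:8) {
    out[, a] <- 0.125 * (1 + pts[, 1] * S[a, 1]) *
      (1 + pts[, 2] * S[a, 2]) * (1 + pts[, 3] * S[a, 3])
  }
  out
}

#' Moment-fitted quadrature for one element
#'
#' Returns the quadrature rule for an element with nodal level-set values
#' `phi_nodes`: the standard Gauss-Legendre rule if the element is fully
#' solid (all `phi >= 0`), a zero rule if fully void, and moment-fitted
#' weights from the sub-cell Heaviside field (level set evaluated by
#' trilinear interpolation at sub-cell centers, `H(0) = 1`) if cut.
#'
#' @param phi_nodes numeric length-8 nodal level-set values (standard
#'   corner order).
#' @param p_q quadrature order (default 2, 27 points).
#' @param n_c number of sub-cells (default 1000).
#' @param basis optionally a precomputed [subcell_factor_matrix()].
#' @return object of class `quadrature_rule`: `points` (n_i x 3),
#'   `weights` (isoparametric measure; sum in `[0, 8]`), `order`, `n_i`,
#'   `element_class`.
#' @export
moment_fit_weights <- function(phi_nodes, p_q = 2, n_c = 1000,
                               basis = NULL) {
  stopifnot(length(phi_nodes) == 8)
  basis <- basis %||% subcell_factor_matrix(p_q, n_c)
  cls <- if (all(phi_nodes >= 0)) "solid"
         else if (all(phi_nodes < 0)) "void" else "cut"
  w <- switch(cls,
    solid = basis$full_weights,
    void = rep(0, length(basis$full_weights)),
    cut = {
      phic <- as.vector(basis$W_tri %*% phi_nodes)
      H <- as.numeric(phic >= 0)
      as.vector(crossprod(basis$A, H))
    })
  structure(list(points = basis$points, weights = w, order = p_q,
                 n_i = length(w), element_class = cls),
            class = "quadrature_rule")
}

# batch version: phi_nodes 8 x ne matrix of cut elements -> n_i x ne weights
moment_fit_weights_batch <- function(phi_nodes, basis) {
  H <- (basis$W_tri %*% phi_nodes) >= 0
  storage.mode(H) <- "double"
  crossprod(basis$A, H)
}
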