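#' Structured periodic hexahedral mesh over a voxel grid
#'
#' One eight-node hexahedral element per voxel. Under periodic boundary
#' conditions, opposite-face nodes coincide, so the mesh carries exactly
#' `nx * ny * nz` unique nodes (node `(i, j, k)` sits at the lower corner
#' of voxel `(i, j, k)`, with wrap-around).
#'
#' @param dims element grid dimensions (nx, ny, nz).
#' @param spacing element edge lengths (um), scalar or length-3.
#' @export
hex_mesh <- function(dims, spacing = 1) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1))
  structure(list(dims = dims, spacing = rep(as.numeric(spacing),
                                            length.out = 3),
                 n_elements = prod(dims), n_nodes = prod(dims)),
            class = "hex_mesh")
}

# unique periodic node id (1-based) for node grid coords (0-based, wrapped)
node_id <- function(mesh, i, j, k) {
  d <- mesh$dims
  1L + (i %% d[1]) + d[1] * ((j %% d[2]) + d[2] * (k %% d[3]))
}

# 8 x ne matrix of periodic node ids for all elements, standard corner order
element_nodes <- function(mesh) {
  d <- mesh$dims
  ne <- prod(d)
  ei <- (seq_len(ne) - 1L) %% d[1]
  ej <- ((seq_len(ne) - 1L) %/% d[1]) %% d[2]
  ek <- (seq_len(ne) - 1L) %/% (d[1] * d[2])
  S <- (hex_corner_signs() + 1) / 2   # 0/1 offsets
  out <- matrix(0L, 8, ne)
  for (a in 1:8) {
    out[a, ] <- node_id(mesh, ei + S[a, 1], ej + S[a, 2], ek + S[a, 3])
  }
  out
}

#' Interpolate a voxel-centered level set to mesh nodes
#'
#' Each node sits at the corner shared by eight voxels; the trilinear
#' interpolant of the voxel-center field at that corner is the mean of the
#' eight surrounding voxel values (wrapping periodically).
#'
#' @param phi_arr 3D array of voxel-centered level-set values.
#' @return 3D array of nodal values on the unique periodic node grid.
#' @export
nodal_phi <- function(phi_arr) {
  d <- dim(phi_arr)
  wrapm <- function(n) c(n, seq_len(n - 1))  # index i-1 with wrap
  xm <- wrapm(d[1]); ym <- wrapm(d[2]); zm <- wrapm(d[3])
  acc <- phi_arr +
    phi_arr[xm, , , drop = FALSE] +
    phi_arr[, ym, , drop = FALSE] +
    phi_arr[, , zm, drop = FALSE] +
    phi_arr[xm, ym, , drop = FALSE] +
    phi_arr[xm, , zm, drop = FALSE] +
    phi_arr[, ym, zm, drop = FALSE] +
    phi_arr[xm, ym, zm, drop = FALSE]
  acc / 8
}

#' Classify elements against the level set
#'
#' An element with all eight nodal values `>= 0` is solid (`H(0) = 1`),
#' with all `< 0` void, otherwise cut.
#'
#' @param phi_nodes 8 x ne matrix of nodal level-set values.
#' @return integer vector: 1 = solid, 0 = void, 2 = cut.
#' @export
classify_elements <- function(phi_nodes) {
  pos <- colSums(phi_nodes >= 0)
  cls <- integer(ncol(phi_nodes))
  cls[pos == 8] <- 1L
  cls[pos > 0 & pos < 8] <- 2L
  cls
}

#' Periodic degree-of-freedom map
#'
#' Assigns three displacement DOFs to every active unique periodic node
#' (a node is active when it touches at least one non-void element);
#' opposite-face nodes share DOFs by construction of the unique node grid.
#'
#' @param mesh a [hex_mesh()].
#' @param enodes 8 x ne element-node incidence ([element_nodes()]).
#' @param classes element classification ([classify_elements()]).
#' @return list: `active` (logical per node), `n_active`, `n_dof`,
#'   `node_dof` (integer per node: first DOF index or NA), `comp_index`
#'   (list of DOF indices per displacement component).
#' @export
build_periodic_dof_map <- function(mesh, enodes, classes) {
  active <- logical(mesh$n_nodes)
  nonvoid <- classes != 0L
  active[unique(as.vector(enodes[, nonvoid]))] <- TRUE
  rank <- cumsum(active)
  node_dof <- ifelse(active, 3L * (rank - 1L) + 1L, NA_integer_)
  n_active <- sum(active)
  n_dof <- 3L * n_active
  comp_index <- lapply(1:3, function(c) seq.int(c, n_dof, by = 3L))
  list(active = active, n_active = n_active, n_dof = n_dof,
       node_dof = node_dof, comp_index = comp_index)
}

# 24 x ne DOF connectivity for the given elements (node-major, x/y/z per node)
element_dofs <- function(dofmap, enodes_subset) {
  base <- matrix(dofmap$node_dof[enodes_subset], nrow = 8)
  out <- matrix(0L, 24, ncol(base))
  for (a in 1:8) {
    out[3 * a - 2, ] <- base[a, ]
    out[3 * a - 1, ] <- base[a, ] + 1L
    out[3 * a, ] <- base[a, ] + 2L
  }
  out
}

# B-matrix (6 x 24, engineering shear, Voigt order 11,22,33,23,13,12) at
# isoparametric points for an axis-aligned hex with edge lengths spacing;
# returns a 6 x 24 x nq array
b_matrix_cube <- function(spacing, pts) {
  S <- hex_corner_signs()
  nq <- nrow(pts)
  B <- array(0, c(6, 24, nq))
  for (q in seq_len(nq)) {
    xi <- pts[q, 1]; eta <- pts[q, 2]; zeta <- pts[q, 3]
    dN <- matrix(0, 8, 3)
    for (a in 1:8) {
      dN[a, 1] <- 0.125 * S[a, 1] * (1 + eta * S[a, 2]) * (1 + zeta * S[a, 3])
      dN[a, 2] <- 0.125 * (1 + xi * S[a, 1]) * S[a, 2] * (1 + zeta * S[a, 3])
      dN[a, 3] <- 0.125 * (1 + xi * S[a, 1]) * (1 + eta * S[a, 2]) * S[a, 3]
    }
    dN <- sweep(dN, 2, 2 / spacing, "*")   # d/dx = d/dxi * 2/h
    for (a in 1:8) {
      cx <- 3 * a - 2; cy <- 3 * a - 1; cz <- 3 * a
      B[1, cx, q] <- dN[a, 1]
      B[2, cy, q] <- dN[a, 2]
      B[3, cz, q] <- dN[a, 3]
      B[4, cy, q] <- dN[a, 3]; B[4, cz, q] <- dN[a, 2]
      B[5, cx, q] <- dN[a, 3]; B[5, cz, q] <- dN[a, 1]
      B[6, cx, q] <- dN[a, 2]; B[6, cy, q] <- dN[a, 1]
    }
  }
  B
}
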