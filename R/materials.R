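#' Orthotropic hygro-elastic cell-wall parameters
#'
#' Nine elastic constants plus three hygro-expansion coefficients in the
#' local (1, 2, 3) frame of the cell wall: 1 = in-plane wall tangent,
#' 2 = wall normal, 3 = extrusion axis (longitudinal for axial cells,
#' radial for rays). Defaults are the reference values at 12% moisture
#' content for the two cell-wall classes.
#'
#' @param cell_type `"axial"` or `"ray"`.
#' @param E Young's moduli (E1, E2, E3), GPa.
#' @param nu Poisson's ratios (nu23, nu13, nu12).
#' @param G shear moduli (G23, G13, G12), GPa.
#' @param beta hygro-expansion coefficients (beta1, beta2, beta3),
#'   % strain per % moisture content.
#' @param reference_moisture reference moisture content, % (default 12).
#' @export
cell_wall_params <- function(cell_type = c("axial", "ray"),
                             E = NULL, nu = NULL, G = NULL, beta = NULL,
                             reference_moisture = 12) {
  cell_type <- match.arg(cell_type)
  def <- if (cell_type == "axial") {
    list(E = c(E1 = 5.8, E2 = 3.7, E3 = 18.3),
         nu = c(nu23 = 0.02, nu13 = 0.19, nu12 = 0.24),
         G = c(G23 = 1.2, G13 = 4.4, G12 = 1.0),
         beta = c(beta1 = 0.16, beta2 = 0.40, beta3 = 0.01))
  } else {
    list(E = c(E1 = 4.9, E2 = 3.5, E3 = 13.0),
         nu = c(nu23 = 0.01, nu13 = 0.30, nu12 = 0.21),
         G = c(G23 = 1.1, G13 = 5.6, G12 = 1.0),
         beta = c(beta1 = 0.17, beta2 = 0.43, beta3 = 0.00))
  }
  p <- list(cell_type = cell_type,
            E = E %||% def$E, nu = nu %||% def$nu, G = G %||% def$G,
            beta = beta %||% def$beta,
            reference_moisture = reference_moisture)
  if (any(p$E <= 0) || any(p$G <= 0)) stop("moduli must be positive")
  class(p) <- "cell_wall_params"
  p
}

#' Moisture-dependent scaling of cell-wall parameters
#'
#' Tabulated multipliers versus moisture content for any subset of the
#' twelve parameters; multipliers are renormalized to 1 at the reference
#' moisture content. With `table = NULL` all multipliers are identically 1.
#'
#' @param table data frame with columns `param` (e.g. `"E1"`, `"G12"`,
#'   `"beta2"`), `m` (% moisture), `multiplier` (> 0), or `NULL`.
#' @export
moisture_scaling <- function(table = NULL) {
  if (!is.null(table)) {
    stopifnot(all(c("param", "m", "multiplier") %in% names(table)))
    if (any(table$multiplier <= 0)) stop("multipliers must be positive")
  }
  structure(list(table = table), class = "moisture_scaling")
}

scaling_multipliers <- function(scaling, m, reference_moisture,
                                params = c("E1", "E2", "E3", "nu23", "nu13",
                                           "nu12", "G23", "G13", "G12",
                                           "beta1", "beta2", "beta3")) {
  mult <- setNames(rep(1, length(params)), params)
  tb <- scaling$table
  if (is.null(tb)) return(mult)
  for (pn in intersect(params, unique(tb$param))) {
    sub <- tb[tb$param == pn, ]
    rng <- range(sub$m)
    if (m < rng[1] || m > rng[2])
      stop(sprintf("moisture %.3g%% outside scaling table hull [%g, %g] for %s",
                   m, rng[1], rng[2], pn))
    at <- function(mm) stats::approx(sub$m, sub$multiplier, xout = mm)$y
    mult[pn] <- at(m) / at(reference_moisture)
  }
  mult
}

#' Build the local-frame stiffness and expansion of a cell wall
#'
#' Assembles the orthotropic compliance in engineering Voigt form (order
#' 11, 22, 33, 23, 13, 12; engineering shear), applying the moisture
#' scaling, and inverts it to a stiffness matrix in MPa. The off-diagonal
#' symmetry relations (nu12/E1 = nu21/E2, ...) are built in.
#'
#' @param p a [cell_wall_params()].
#' @param m moisture content, %.
#' @param scaling a [moisture_scaling()].
#' @return list with `C` (6x6 stiffness, MPa), `D` (compliance, 1/MPa),
#'   `beta` (length-3, %/%), `cell_type`, `m`.
#' @export
build_cell_wall_material <- function(p, m = p$reference_moisture,
                                     scaling = moisture_scaling()) {
  mult <- scaling_multipliers(scaling, m, p$reference_moisture)
  E <- p$E * mult[c("E1", "E2", "E3")] * 1000   # GPa -> MPa
  nu <- p$nu * mult[c("nu23", "nu13", "nu12")]
  G <- p$G * mult[c("G23", "G13", "G12")] * 1000
  beta <- p$beta * mult[c("beta1", "beta2", "beta3")]
  D <- matrix(0, 6, 6)
  D[1, 1] <- 1 / E[1]; D[2, 2] <- 1 / E[2]; D[3, 3] <- 1 / E[3]
  D[1, 2] <- D[2, 1] <- -nu[["nu12"]] / E[1]
  D[1, 3] <- D[3, 1] <- -nu[["nu13"]] / E[1]
  D[2, 3] <- D[3, 2] <- -nu[["nu23"]] / E[2]
  D[4, 4] <- 1 / G[["G23"]]
  D[5, 5] <- 1 / G[["G13"]]
  D[6, 6] <- 1 / G[["G12"]]
  C <- solve(D)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("stiffness not positive definite: eigenvalue %.4g MPa",
                 min(ev)))
  list(C = C, D = D, beta = unname(beta), cell_type = p$cell_type, m = m)
}

#' Orientation field from the level-set gradient
#'
#' For axial elements the in-plane material angle is
#' `alpha = arctan(-phi_x / phi_y)` evaluated by central differences of the
#' signed distance in the x-y slice through the element center (extrusion
#' axis along z); for ray elements the same construction is applied in the
#' y-z slice (extrusion axis along x). Angles are reduced to
#' `(-pi/2, pi/2]`. Where the in-slice gradient magnitude falls below
#' `eps_grad` (medial-axis voxels), the angle is marked invalid and filled
#' by the circular mean of valid neighbors, falling back to 0.
#'
#' @param phi a `level_set` (reinitialized signed distance).
#' @param cell_type character array of per-voxel labels (`"axial"`,
#'   `"ray"`, `"void"`); `NULL` treats everything as axial.
#' @param force_zero logical array marking elements whose angle is pinned
#'   to 0 (e.g. artificial periodicity tie layers); `NULL` for none.
#' @param eps_grad gradient-magnitude validity threshold (defaults to
#'   `1e-6 * spacing`).
#' @param periodic use periodic wrapping for the central differences.
#' @return object of class `orientation_field`: `alpha` (radians),
#'   `cell_type` (integer: 1 axial, 2 ray, 0 void), `valid`.
#' @export
compute_orientation <- function(phi, cell_type = NULL, force_zero = NULL,
                                eps_grad = NULL, periodic = TRUE) {
  d <- dim(phi$phi)
  h <- phi$spacing
  eps_grad <- eps_grad %||% (1e-6 * min(h))
  gx <- central_diff(phi$phi, 1, h[1], periodic)
  gy <- central_diff(phi$phi, 2, h[2], periodic)
  gz <- central_diff(phi$phi, 3, h[3], periodic)

  type <- array(1L, d)
  if (!is.null(cell_type)) {
    type[cell_type == "ray"] <- 2L
    type[cell_type == "void"] <- 0L
  }
  reduce_halfpi <- function(a) {
    a <- a %% pi
    ifelse(a > pi / 2, a - pi, a)
  }
  alpha <- array(NA_real_, d)
  gn_ax <- sqrt(gx^2 + gy^2)
  gn_ray <- sqrt(gy^2 + gz^2)
  ax <- type != 2L
  alpha[ax] <- reduce_halfpi(atan2(-gx[ax], gy[ax]))
  alpha[!ax] <- reduce_halfpi(atan2(-gy[!ax], gz[!ax]))
  valid <- ifelse(ax, gn_ax, gn_ray) > eps_grad
  dim(valid) <- d

  # fill invalid entries from valid neighbors (circular mean with period pi)
  n_invalid <- sum(!valid & type != 0L)
  if (n_invalid > 0) {
    cosv <- ifelse(valid, cos(2 * alpha), 0)
    sinv <- ifelse(valid, sin(2 * alpha), 0)
    cnt <- array(as.numeric(valid), d)
    dim(cosv) <- d; dim(sinv) <- d
    # iterative 26-neighbor fill
    for (pass in 1:4) {
      todo <- which(!valid & type != 0L)
      if (!length(todo)) break
      acc_c <- array(0, d); acc_s <- array(0, d); acc_n <- array(0, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        sh <- shift_arr(shift_arr(shift_arr(cosv, 1, dx), 2, dy), 3, dz)
        acc_c <- acc_c + sh
        sh <- shift_arr(shift_arr(shift_arr(sinv, 1, dx), 2, dy), 3, dz)
        acc_s <- acc_s + sh
        sh <- shift_arr(shift_arr(shift_arr(cnt, 1, dx), 2, dy), 3, dz)
        acc_n <- acc_n + sh
      }
      fill <- todo[acc_n[todo] > 0]
      if (!length(fill)) break
      alpha[fill] <- reduce_halfpi(atan2(acc_s[fill], acc_c[fill]) / 2)
      valid[fill] <- TRUE
      cosv[fill] <- cos(2 * alpha[fill])
      sinv[fill] <- sin(2 * alpha[fill])
      cnt[fill] <- 1
    }
    still <- !valid & type != 0L
    if (any(still)) {
      warning(sprintf("%d orientation entries degenerate; set to 0",
                      sum(still)))
      alpha[still] <- 0
      valid[still] <- TRUE
    }
  }
  if (!is.null(force_zero)) alpha[force_zero & type != 0L] <- 0
  alpha[type == 0L] <- NA_real_
  structure(list(alpha = alpha, cell_type = type, valid = valid),
            class = "orientation_field")
}

#' Rotate a local cell-wall material into the global frame
#'
#' Axial cells rotate about z (local 3-axis to global z); ray cells rotate
#' about x (local 3-axis to global x). Stiffness transforms via the 6x6
#' Bond matrix consistent with engineering-shear Voigt notation; the
#' expansion tensor is rotated as a second-order tensor and returned as an
#' engineering 6-vector (rotation generally introduces shear expansion).
#'
#' @param C_local 6x6 stiffness (MPa), local frame.
#' @param beta_local length-3 expansion coefficients, local frame.
#' @param alpha in-plane angle, radians.
#' @param cell_type `"axial"` or `"ray"`.
#' @return list `C` (6x6 global), `beta` (length-6, engineering shear).
#' @export
rotate_material <- function(C_local, beta_local, alpha,
                            cell_type = c("axial", "ray")) {
  cell_type <- match.arg(cell_type)
  out <- cpp_rotate_materials(C_local, beta_local, C_local, beta_local,
                              alpha, as.integer(ifelse(cell_type == "ray",
                                                       2L, 1L)))
  list(C = matrix(out$C[, 1], 6, 6), beta = as.vector(out$beta[, 1]))
}

#' Per-element global-frame material field
#'
#' Rotates the two local cell-wall materials into the global frame using
#' the per-element orientation angles and cell types.
#'
#' @param orientation an [compute_orientation()] result (per element).
#' @param mat_axial,mat_ray outputs of [build_cell_wall_material()].
#' @param elements integer vector of element indices to materialize
#'   (typically the non-void elements).
#' @return list `C` (36 x ne), `beta` (6 x ne), `alpha`, `type`.
#' @export
build_material_field <- function(orientation, mat_axial, mat_ray, elements) {
  type <- orientation$cell_type[elements]
  type[type == 0L] <- 1L  # cut elements labeled void: treated as axial
  alpha <- orientation$alpha[elements]
  alpha[is.na(alpha)] <- 0
  out <- cpp_rotate_materials(mat_axial$C, mat_axial$beta,
                              mat_ray$C, mat_ray$beta, alpha, type)
  list(C = out$C, beta = out$beta, alpha = alpha, type = type)
}
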