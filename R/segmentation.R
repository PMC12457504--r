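#' Signed-distance level set container
#'
#' `phi >= 0` marks the solid subdomain; the zero level is the phase
#' boundary, which lies on the faces between voxels of opposite phase.
#'
#' @param phi 3D numeric array (distance in the units of `spacing`).
#' @param spacing voxel spacing (um), scalar or length 3.
#' @export
new_level_set <- function(phi, spacing = 1) {
  stopifnot(is.array(phi), length(dim(phi)) == 3)
  structure(list(phi = phi, spacing = rep(as.numeric(spacing),
                                          length.out = 3),
                 convention = "phi>=0 solid"),
            class = "level_set")
}

#' @export
print.level_set <- function(x, ...) {
  cat(sprintf("<level_set> %s voxels, spacing %s um, %.1f%% solid (phi>=0)\n",
              paste(dim(x$phi), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              100 * mean(x$phi >= 0)))
  invisible(x)
}

#' Initialize a signed-distance level set from a binary phase field
#'
#' Computes, for every voxel center, the exact Euclidean distance to the
#' closest point on the solid/void interface (the set of faces between
#' voxels of opposite phase), signed positive in the solid phase. A voxel
#' adjacent to the interface therefore carries `+/- spacing/2`.
#'
#' @param binary logical 3D array, `TRUE` = solid.
#' @param spacing voxel spacing (um).
#' @return a `level_set`.
#' @export
init_level_set <- function(binary, spacing = 1) {
  stopifnot(is.array(binary), length(dim(binary)) == 3)
  if (all(binary) || !any(binary)) stop("no phase boundary exists")
  spacing <- rep(spacing, length.out = 3)
  phi <- cpp_signed_face_distance(as.logical(binary), dim(binary), spacing)
  new_level_set(array(phi, dim(binary)), spacing)
}

#' Parameters of the hybrid global/local segmentation energy
#'
#' The evolution combines a two-region global mean term (Chan-Vese) with a
#' Gaussian-window local mean term that compensates smooth intensity
#' inhomogeneity, plus a curvature length penalty.
#'
#' @param omega_global,omega_local weights of the global and local intensity
#'   terms.
#' @param mu curvature (length penalty) weight.
#' @param sigma_local Gaussian window standard deviation (voxels).
#' @param dt descent step (voxels).
#' @param epsilon width of the smoothed Dirac delta (voxels).
#' @param phi_cap working band half-width (voxels): the evolving level set
#'   is clamped to `[-phi_cap, phi_cap]`, which makes the converged state a
#'   genuine fixed point of the update map.
#' @param tol stationarity tolerance: max |delta phi| per sweep (voxels).
#' @param max_iter iteration cap.
#' @export
energy_params <- function(omega_global = 1, omega_local = 1, mu = 0.02,
                          sigma_local = 4, dt = 2, epsilon = 1.5,
                          phi_cap = 4, tol = 1e-3, max_iter = 500) {
  structure(list(omega_global = omega_global, omega_local = omega_local,
                 mu = mu, sigma_local = sigma_local, dt = dt,
                 epsilon = epsilon, phi_cap = phi_cap, tol = tol,
                 max_iter = max_iter),
            class = "energy_params")
}

shift_arr <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]] - by
  i[i < 1] <- 1
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

central_diff <- function(a, axis, h = 1, periodic = FALSE) {
  d <- dim(a)
  if (d[axis] == 1) return(array(0, d))
  idx <- lapply(d, seq_len)
  ip <- idx; im <- idx
  if (periodic) {
    ip[[axis]] <- c(2:d[axis], 1)
    im[[axis]] <- c(d[axis], 1:(d[axis] - 1))
  } else {
    ip[[axis]] <- pmin(idx[[axis]] + 1, d[axis])
    im[[axis]] <- pmax(idx[[axis]] - 1, 1)
  }
  fwd <- do.call(`[`, c(list(a), ip, list(drop = FALSE)))
  bwd <- do.call(`[`, c(list(a), im, list(drop = FALSE)))
  (fwd - bwd) / (2 * h)
}

mean_curvature <- function(phi) {
  gx <- central_diff(phi, 1)
  gy <- central_diff(phi, 2)
  gz <- central_diff(phi, 3)
  gn <- sqrt(gx^2 + gy^2 + gz^2) + 1e-10
  central_diff(gx / gn, 1) + central_diff(gy / gn, 2) +
    central_diff(gz / gn, 3)
}

#' Evolve the level set on a gray-scale volume
#'
#' Monotone clipped descent on the hybrid global + local intensity energy:
#' per sweep, a voxel is moved only when the descent force disagrees with
#' its current phase, so a converged configuration is an exact fixed point
#' and a rerun from it returns within one sweep. Iterates until the maximum
#' per-sweep change drops below `tol` or `max_iter` is reached; the output
#' is reinitialized to an exact signed distance.
#'
#' @param volume a [voxel_volume()] with intensities in `[0, 1]`.
#' @param phi0 initial `level_set` (e.g. from a midpoint threshold).
#' @param energy an [energy_params()].
#' @return `level_set` with attributes `converged`, `iterations`.
#' @export
evolve_level_set <- function(volume, phi0, energy = energy_params()) {
  I <- volume$data
  if (sd(I) == 0) stop("energy has no two-phase minimizer: uniform image")
  d <- dim(I)
  stopifnot(all(dim(phi0$phi) == d))
  hv <- min(phi0$spacing)
  phi <- clamp(phi0$phi / hv, -energy$phi_cap, energy$phi_cap)  # voxel units
  eps <- energy$epsilon
  converged <- FALSE
  it <- 0
  for (it in seq_len(energy$max_iter)) {
    H <- phi >= 0
    n1 <- sum(H); n2 <- length(H) - n1
    if (n1 == 0 || n2 == 0) stop("energy has no two-phase minimizer")
    c1 <- mean(I[H]); c2 <- mean(I[!H])
    Fg <- (I - c2)^2 - (I - c1)^2
    G <- energy$omega_global * Fg
    if (energy$omega_local > 0) {
      bH <- array(cpp_gaussian_blur3(as.numeric(H), d, energy$sigma_local), d)
      bHI <- array(cpp_gaussian_blur3(as.numeric(H) * I, d,
                                      energy$sigma_local), d)
      bI <- array(cpp_gaussian_blur3(I, d, energy$sigma_local), d)
      f1 <- ifelse(bH > 1e-6, bHI / pmax(bH, 1e-6), c1)
      f2 <- ifelse(1 - bH > 1e-6, (bI - bHI) / pmax(1 - bH, 1e-6), c2)
      Fl <- (I - f2)^2 - (I - f1)^2
      G <- G + energy$omega_local * Fl
    }
    G <- G / max(abs(G), 1e-12)
    if (energy$mu > 0) G <- G + energy$mu * mean_curvature(phi)
    delta <- eps / (pi * (eps^2 + phi^2))
    upd <- energy$dt * delta * G
    # monotone clipping: only move voxels whose force opposes their phase
    upd[(phi >= 0) == (G >= 0)] <- 0
    phin <- clamp(phi + upd, -energy$phi_cap, energy$phi_cap)
    dmax <- max(abs(phin - phi))
    phi <- phin
    if (dmax < energy$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("level-set evolution not stationary after %d sweeps",
                    energy$max_iter))
  out <- init_level_set(phi >= 0, phi0$spacing)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  out
}

#' Two-phase segmentation container
#'
#' @param binary_phase logical 3D array, `TRUE` = solid (cell wall).
#' @param spacing voxel spacing (um).
#' @param cell_type optional character array of labels (`"axial"`, `"ray"`,
#'   `"void"`); `"void"` on void voxels.
#' @param provenance data frame logging cleanup / construction actions.
#' @export
segmented_mesostructure <- function(binary_phase, spacing = 1,
                                    cell_type = NULL, provenance = NULL) {
  stopifnot(is.array(binary_phase), length(dim(binary_phase)) == 3)
  structure(list(binary_phase = binary_phase,
                 spacing = rep(as.numeric(spacing), length.out = 3),
                 cell_type = cell_type,
                 added_layers = NULL,
                 provenance = provenance %||%
                   data.frame(action = character(), phase = character(),
                              size = integer())),
            class = "segmented_mesostructure")
}

#' Remove spurious islands and enclosed bubbles from a segmentation
#'
#' Solid components (26-connected) strictly smaller than the threshold and
#' fully embedded in void are flipped to void; void bubbles (6-connected)
#' strictly smaller than the threshold and enclosed in solid are flipped to
#' solid. Components touching the domain boundary are never flipped. Every
#' flip is recorded in the provenance log.
#'
#' @param seg a [segmented_mesostructure()].
#' @param island_threshold_voxels components with fewer voxels are removed
#'   (strict `<`); default 27 (one 3x3x3 block).
#' @export
clean_segmentation <- function(seg, island_threshold_voxels = 27L) {
  d <- dim(seg$binary_phase)
  if (island_threshold_voxels >= prod(d))
    stop("island threshold exceeds domain size")
  b <- seg$binary_phase
  log <- seg$provenance

  flip_small <- function(mask, conn, phase_name) {
    lab <- array(cpp_label_components(as.logical(mask), d, conn), d)
    if (max(lab) == 0) return(NULL)
    sizes <- tabulate(lab)
    boundary_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                                lab[, , c(1, d[3])]))
    small <- which(sizes < island_threshold_voxels)
    small <- setdiff(small, boundary_labels)
    if (!length(small)) return(NULL)
    list(mask = lab %in% small, ids = small, sizes = sizes[small],
         phase = phase_name)
  }

  fs <- flip_small(b, 26L, "solid")
  if (!is.null(fs)) {
    b[fs$mask] <- FALSE
    log <- rbind(log, data.frame(action = "island_to_void", phase = "solid",
                                 size = fs$sizes))
  }
  fv <- flip_small(!b, 6L, "void")
  if (!is.null(fv)) {
    b[fv$mask] <- TRUE
    log <- rbind(log, data.frame(action = "bubble_to_solid", phase = "void",
                                 size = fv$sizes))
  }
  out <- seg
  out$binary_phase <- b
  if (!is.null(seg$cell_type)) {
    ct <- seg$cell_type
    ct[!b] <- "void"
    newly_solid <- b & (ct == "void")
    ct[newly_solid] <- "axial"
    out$cell_type <- ct
  }
  out$provenance <- log
  out
}

#' Construct a periodic unit cell from a segmented volume
#'
#' Mirrors the volume across the R-T plane (doubling the thickness, which
#' makes the field exactly mirror-periodic in z) and appends two-voxel solid
#' tie layers on both x-faces and both y-faces so that opposite faces are
#' solid-connected.
#'
#' @param seg a [segmented_mesostructure()].
#' @return a periodic [segmented_mesostructure()] with an `added_layers`
#'   logical array marking the artificial tie layers.
#' @export
make_periodic <- function(seg) {
  d <- dim(seg$binary_phase)
  mirror_z <- function(a) {
    out <- array(a[1], dim = c(dim(a)[1:2], 2 * dim(a)[3]))
    out[, , seq_len(dim(a)[3])] <- a
    out[, , dim(a)[3] + seq_len(dim(a)[3])] <- a[, , rev(seq_len(dim(a)[3]))]
    out
  }
  pad_xy <- function(a, fill) {
    dm <- dim(a)
    out <- array(fill, dim = c(dm[1] + 4, dm[2] + 4, dm[3]))
    out[2 + seq_len(dm[1]), 2 + seq_len(dm[2]), ] <- a
    out
  }
  b <- pad_xy(mirror_z(seg$binary_phase), TRUE)
  added <- array(TRUE, dim(b))
  added[2 + seq_len(d[1]), 2 + seq_len(d[2]), ] <- FALSE
  ct <- NULL
  if (!is.null(seg$cell_type)) {
    ct <- pad_xy(mirror_z(seg$cell_type), "axial")
  }
  out <- segmented_mesostructure(b, seg$spacing, cell_type = ct,
                                 provenance = rbind(
                                   seg$provenance,
                                   data.frame(action = "periodize",
                                              phase = "both",
                                              size = sum(added))))
  out$added_layers <- added
  out
}

#' Morphometric summary of a segmented unit cell
#'
#' Porosity, density `rho = (1 - phi) * rho_cw`, cell dimensions, ray solid
#' volume fraction `v_ray = V_ray / (V_ax + V_ray)`, earlywood width, and
#' the earlywood vessel volume fraction (void components running the full
#' thickness whose in-plane equivalent radius exceeds a threshold).
#'
#' @param seg a [segmented_mesostructure()].
#' @param rho_cw cell-wall density, kg/m^3 (dry-state reference 1440).
#' @param ew_boundary_um x-coordinate (um) separating earlywood from
#'   latewood; `NULL` if unknown (vessel fraction then spans the full width).
#' @param vessel_radius_um_min minimum equivalent radius (um) for a void
#'   channel to count as a vessel rather than a lumen.
#' @return object of class `morphometrics` (a named list).
#' @export
compute_morphometrics <- function(seg, rho_cw = 1440, ew_boundary_um = NULL,
                                  vessel_radius_um_min = 15) {
  d <- dim(seg$binary_phase)
  h <- seg$spacing
  porosity <- mean(!seg$binary_phase)
  v_ray <- NA_real_
  if (!is.null(seg$cell_type)) {
    n_ray <- sum(seg$cell_type == "ray")
    n_ax <- sum(seg$cell_type == "axial")
    if (n_ray + n_ax > 0) v_ray <- n_ray / (n_ray + n_ax)
  }
  # vessels: void channels along z spanning the full thickness
  lab <- array(cpp_label_components(!seg$binary_phase, d, 6L), d)
  v_vess <- 0
  if (max(lab) > 0) {
    xs <- (seq_len(d[1]) - 0.5) * h[1]
    for (id in seq_len(max(lab))) {
      m <- lab == id
      zext <- apply(m, 3, any)
      if (!all(zext)) next
      vol_vox <- sum(m)
      r_eq <- sqrt((vol_vox / d[3]) * h[1] * h[2] / pi)
      if (r_eq < vessel_radius_um_min) next
      cx <- mean(xs[apply(m, 1, any)])
      if (is.null(ew_boundary_um) || cx <= ew_boundary_um)
        v_vess <- v_vess + vol_vox
    }
  }
  structure(list(
    porosity = porosity,
    density_kg_m3 = (1 - porosity) * rho_cw,
    W_um = d[1] * h[1], H_um = d[2] * h[2], T_um = d[3] * h[3],
    aspect_ratio = (d[1] * h[1]) / (d[2] * h[2]),
    v_ray = v_ray,
    W_e_um = ew_boundary_um %||% NA_real_,
    v_vess_EW = v_vess / prod(d)
  ), class = "morphometrics")
}

#' @export
print.morphometrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<morphometrics> porosity %.3f | density %.0f kg/m^3 | W x H x T = ",
    "%.0f x %.0f x %.0f um | v_ray %s | v_vess,EW %.3f\n"),
    x$porosity, x$density_kg_m3, x$W_um, x$H_um, x$T_um,
    ifelse(is.na(x$v_ray), "undefined", sprintf("%.3f", x$v_ray)),
    x$v_vess_EW))
  invisible(x)
}

#' Midpoint threshold of a two-mode volume
#'
#' @param volume a [voxel_volume()].
#' @param threshold intensity threshold; default midpoint of the range.
#' @return logical array, `TRUE` = solid (above threshold).
#' @export
threshold_volume <- function(volume,
                             threshold = mean(range(volume$data))) {
  volume$data >= threshold
}

#' Dice overlap coefficient between two binary masks
#' @param a,b logical arrays of equal dimension.
#' @export
dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
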