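#' Specification of a synthetic growth-ring phantom
#'
#' Describes an oak-like meso-structure: a honeycomb of thin-walled axial
#' cells extruded along z, large earlywood and small latewood vessels
#' (cylinders along z), and a horizontal band of radially oriented ray cells
#' (prisms along x). The phantom is rendered to gray scale with two intensity
#' modes, additive Gaussian noise and a smooth multiplicative intensity
#' inhomogeneity, and carries exact ground truth for every downstream stage.
#'
#' @param domain_size_voxels integer triple (nx, ny, nz).
#' @param spacing_um isotropic voxel spacing in micrometers.
#' @param earlywood_width_fraction fraction of the width W occupied by
#'   earlywood (vessels of the first, larger radius).
#' @param vessel_radii_um radii (um) of earlywood and latewood vessels.
#' @param vessel_fractions target void volume fractions (of total volume)
#'   contributed by earlywood and latewood vessels.
#' @param cell_wall_thickness_um wall thickness (um); must map to >= 2 voxels.
#' @param axial_cell_pitch_um center-to-center spacing of the axial-cell
#'   honeycomb (um); also used for the ray-cell cross-section lattice.
#' @param ray_band integer vector `c(y0, y1)` of voxel rows occupied by the
#'   ray band, or `NULL` for no rays.
#' @param intensity_modes gray values (void, solid) in `[0, 1]`.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param inhomogeneity_amplitude amplitude of the smooth low-order
#'   polynomial multiplicative intensity inhomogeneity (0 disables).
#' @param jitter_fraction lattice jitter as a fraction of the pitch.
#' @param seed integer seed controlling all randomness.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(domain_size_voxels = c(60L, 28L, 8L),
                         spacing_um = 5.2,
                         earlywood_width_fraction = 0.5,
                         vessel_radii_um = c(26, 10.4),
                         vessel_fractions = c(0.14, 0.03),
                         cell_wall_thickness_um = 10.4,
                         axial_cell_pitch_um = 26,
                         ray_band = c(1L, 8L),
                         intensity_modes = c(void = 0.3, solid = 0.75),
                         noise_sd = 0.05,
                         inhomogeneity_amplitude = 0.5,
                         jitter_fraction = 0.1,
                         seed = 1L) {
  spec <- list(
    domain_size_voxels = as.integer(domain_size_voxels),
    spacing_um = spacing_um,
    earlywood_width_fraction = earlywood_width_fraction,
    vessel_radii_um = vessel_radii_um,
    vessel_fractions = vessel_fractions,
    cell_wall_thickness_um = cell_wall_thickness_um,
    axial_cell_pitch_um = axial_cell_pitch_um,
    ray_band = if (is.null(ray_band)) NULL else as.integer(ray_band),
    intensity_modes = intensity_modes,
    noise_sd = noise_sd,
    inhomogeneity_amplitude = inhomogeneity_amplitude,
    jitter_fraction = jitter_fraction,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  d <- spec$domain_size_voxels
  h <- spec$spacing_um
  stopifnot(length(d) == 3, all(d >= 4), h > 0)
  if (abs(diff(spec$intensity_modes)) < 1e-12)
    stop("intensity modes must be distinct")
  if (spec$earlywood_width_fraction <= 0 || spec$earlywood_width_fraction >= 1)
    stop("earlywood_width_fraction must be in (0,1)")
  half_ext <- min(d[1:2]) * h / 2
  if (any(spec$vessel_radii_um >= half_ext))
    stop("vessel radii must be smaller than the domain half-extent")
  if (spec$cell_wall_thickness_um < 2 * h)
    stop(sprintf(
      "infeasible geometry: wall thickness %.3g um is below 2 voxels (%.3g um)",
      spec$cell_wall_thickness_um, 2 * h))
  if (spec$noise_sd < 0 || spec$inhomogeneity_amplitude < 0)
    stop("noise_sd and inhomogeneity_amplitude must be nonnegative")
  invisible(spec)
}

#' Generate a growth-ring phantom volume with exact ground truth
#'
#' Renders the phantom described by a [phantom_spec()] to a gray-scale
#' [voxel_volume()] and returns the exact binary phase, per-voxel cell-type
#' labels (axial / ray / void), the true in-plane wall-tangent orientation on
#' straight wall segments, and the porosity. Repeatable for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([voxel_volume()]) and `truth`
#'   (class `ground_truth`: `binary_phase`, `cell_type`, `orientation_angle`,
#'   `porosity`).
#' @export
generate_growth_ring_phantom <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$domain_size_voxels
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  h <- spec$spacing_um
  t_w <- spec$cell_wall_thickness_um
  p <- spec$axial_cell_pitch_um
  set.seed(spec$seed)

  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  zc <- (seq_len(nz) - 0.5) * h
  Wx <- nx * h; Wy <- ny * h; Wz <- nz * h

  jit <- function(n) (runif(n) - 0.5) * 2 * spec$jitter_fraction * p
  lines_of <- function(extent) {
    pos <- seq(0, extent + p, by = p)
    pos + jit(length(pos))
  }
  vx <- lines_of(Wx)   # vertical walls: planes x = const
  vy <- lines_of(Wy)   # horizontal walls: planes y = const

  dist_to <- function(coord, lines) {
    apply(abs(outer(coord, lines, "-")), 1, min)
  }
  dxw <- dist_to(xc, vx)             # per-x distance to nearest vertical wall
  dyw <- dist_to(yc, vy)
  near_vx <- dxw < t_w / 2           # logical over x
  near_vy <- dyw < t_w / 2

  solid2d <- outer(near_vx, near_vy, "|")          # nx x ny axial wall mask
  # straight segments: outside the junction influence zone of crossing walls
  marg <- t_w / 2 + 2 * h
  on_vert <- outer(near_vx, dyw > marg, "&")
  on_horz <- outer(dxw > marg, near_vy, "&")

  # ray band: prisms along x; cross-section lattice in (y, z)
  ray_mask2d <- matrix(FALSE, ny, nz)
  has_ray <- !is.null(spec$ray_band)
  if (has_ray) {
    ry <- lines_of(Wy)
    rz <- lines_of(Wz)
    nry <- dist_to(yc, ry) < t_w / 2
    nrz <- dist_to(zc, rz) < t_w / 2
    ray_mask2d <- outer(nry, nrz, "|")
    band <- seq(spec$ray_band[1], spec$ray_band[2])
    band <- band[band >= 1 & band <= ny]
  }

  solid <- array(FALSE, d)
  vert <- array(FALSE, d)
  horz <- array(FALSE, d)
  for (k in seq_len(nz)) {
    solid[, , k] <- solid2d
    vert[, , k] <- on_vert
    horz[, , k] <- on_horz
  }
  is_ray <- array(FALSE, d)
  if (has_ray && length(band)) {
    for (k in seq_len(nz)) {
      sl <- solid[, , k]
      sl[, band] <- matrix(ray_mask2d[band, k],
                           nrow = nx, ncol = length(band), byrow = TRUE)
      solid[, , k] <- sl
      r <- is_ray[, , k]
      r[, band] <- sl[, band]
      is_ray[, , k] <- r
      v <- vert[, , k]; v[, band] <- FALSE; vert[, , k] <- v
      hh <- horz[, , k]; hh[, band] <- FALSE; horz[, , k] <- hh
    }
  }

  # vessels: cylinders along z carved as void; jittered grid placement
  W_e <- spec$earlywood_width_fraction * Wx
  near_vessel <- array(FALSE, d)
  carve <- function(solid, region_x, radius, target_frac, near_vessel) {
    if (target_frac <= 0) return(list(solid = solid, near = near_vessel))
    area_frac_needed <- target_frac * (Wx * Wy) / (pi * radius^2)
    n_target <- max(0L, round(area_frac_needed))
    if (n_target == 0L) return(list(solid = solid, near = near_vessel))
    gap <- 2.2 * radius
    gx <- seq(region_x[1] + radius, region_x[2] - radius, by = gap)
    gy <- seq(radius, Wy - radius, by = gap)
    if (!length(gx) || !length(gy))
      return(list(solid = solid, near = near_vessel))
    centers <- expand.grid(x = gx, y = gy)
    centers$x <- centers$x + jit(nrow(centers)) / 2
    centers$y <- centers$y + jit(nrow(centers)) / 2
    centers <- centers[sample.int(nrow(centers)), , drop = FALSE]
    centers <- centers[seq_len(min(n_target, nrow(centers))), , drop = FALSE]
    for (ci in seq_len(nrow(centers))) {
      r2 <- outer((xc - centers$x[ci])^2, (yc - centers$y[ci])^2, "+")
      lumen <- r2 < radius^2
      near <- r2 < (radius + t_w)^2
      for (k in seq_len(nz)) {
        sl <- solid[, , k]
        sl[lumen] <- FALSE
        solid[, , k] <- sl
        nv <- near_vessel[, , k]
        nv[near] <- TRUE
        near_vessel[, , k] <- nv
      }
    }
    list(solid = solid, near = near_vessel)
  }
  cv <- carve(solid, c(0, W_e), spec$vessel_radii_um[1],
              spec$vessel_fractions[1], near_vessel)
  cv <- carve(cv$solid, c(W_e, Wx), spec$vessel_radii_um[2],
              spec$vessel_fractions[2], cv$near)
  solid <- cv$solid
  near_vessel <- cv$near

  cell_type <- array("void", d)
  cell_type[solid] <- "axial"
  cell_type[solid & is_ray] <- "ray"

  # orientation truth: wall tangent on straight axial segments only
  alpha <- array(NA_real_, d)
  ok_v <- solid & vert & !near_vessel & !is_ray
  ok_h <- solid & horz & !near_vessel & !is_ray
  alpha[ok_v] <- pi / 2   # vertical wall (normal x): tangent along y
  alpha[ok_h] <- 0        # horizontal wall (normal y): tangent along x

  porosity <- sum(!solid) / length(solid)

  # gray-scale rendering
  modes <- spec$intensity_modes
  img <- array(modes[1], d)
  img[solid] <- modes[2]
  if (spec$inhomogeneity_amplitude > 0) {
    u <- 2 * (xc / Wx) - 1
    v <- 2 * (yc / Wy) - 1
    g2d <- 0.5 * (outer(u, v, function(a, b) a + a * b))
    for (k in seq_len(nz)) img[, , k] <- img[, , k] * (1 + spec$inhomogeneity_amplitude * g2d)
  }
  if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)

  truth <- structure(
    list(binary_phase = solid, cell_type = cell_type,
         orientation_angle = alpha, porosity = porosity),
    class = "ground_truth")
  list(volume = voxel_volume(img, spacing = rep(h, 3)), truth = truth)
}

#' Tune the phantom wall thickness to hit a target porosity
#'
#' Binary search over the wall thickness; the achievable porosity is
#' quantized by the voxel grid, so the result is accurate to the porosity
#' jump between adjacent realizable thicknesses (one "voxel quantum").
#'
#' @param spec a [phantom_spec()].
#' @param target target porosity in (0, 1).
#' @param n_steps number of bisection steps.
#' @return list with the adjusted `spec`, `achieved` porosity and the local
#'   porosity `quantum` (resolution).
#' @export
calibrate_phantom_porosity <- function(spec, target, n_steps = 24) {
  h <- spec$spacing_um
  por_of <- function(t_w) {
    s <- spec
    s$cell_wall_thickness_um <- t_w
    generate_growth_ring_phantom(s)$truth$porosity
  }
  lo <- 2 * h
  hi <- spec$axial_cell_pitch_um * 0.98
  # porosity decreases with thickness
  for (i in seq_len(n_steps)) {
    mid <- (lo + hi) / 2
    if (por_of(mid) > target) lo <- mid else hi <- mid
  }
  best_t <- (lo + hi) / 2
  achieved <- por_of(best_t)
  quantum <- abs(por_of(best_t + h / 2) - por_of(best_t - h / 2))
  spec$cell_wall_thickness_um <- best_t
  list(spec = spec, achieved = achieved, quantum = max(quantum, 1e-12))
}

#' Analytic signed-distance level sets for oracle geometries
#'
#' Exact signed distance to a plane, an infinite cylinder along z, or a
#' sphere, sampled at voxel centers. The sign convention is `phi >= 0` in
#' the solid phase; for `"cylinder"` and `"sphere"` the interior is void
#' (a lumen), for `"plate"` the side selected by `solid_side` is solid.
#'
#' @param shape one of `"plate"`, `"cylinder"`, `"sphere"`.
#' @param params list: plate: `axis` (1..3), `offset` (um), `solid_side`
#'   (+1/-1); cylinder: `center` (x, y in um), `radius`; sphere: `center`
#'   (x, y, z), `radius`.
#' @param dims integer triple of voxels.
#' @param spacing voxel spacing (scalar or length-3), um.
#' @return a `level_set` object.
#' @export
analytic_levelset <- function(shape = c("plate", "cylinder", "sphere"),
                              params, dims, spacing = 1) {
  shape <- match.arg(shape)
  spacing <- rep(spacing, length.out = 3)
  cc <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * spacing[a])
  phi <- switch(shape,
    plate = {
      ax <- params$axis %||% 1
      ss <- params$solid_side %||% 1
      v <- ss * (cc[[ax]] - params$offset)
      reps <- c(1, dims[1], dims[1] * dims[2])[ax]
      array(rep(v, each = reps), dim = dims)
    },
    cylinder = {
      if (params$radius <= 0) stop("degenerate cylinder: zero radius")
      r <- sqrt(outer((cc[[1]] - params$center[1])^2,
                      (cc[[2]] - params$center[2])^2, "+"))
      array(rep(r - params$radius, dims[3]), dim = dims)
    },
    sphere = {
      if (params$radius <= 0) stop("degenerate sphere: zero radius")
      r2 <- outer(outer((cc[[1]] - params$center[1])^2,
                        (cc[[2]] - params$center[2])^2, "+"),
                  (cc[[3]] - params$center[3])^2, "+")
      sqrt(r2) - params$radius
    })
  if (!any(phi >= 0) || !any(phi < 0))
    stop("shape does not fit in grid: single-phase level set")
  new_level_set(phi, spacing)
}
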