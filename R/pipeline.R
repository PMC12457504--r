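#' Pipeline configuration
#'
#' Collects every tunable of the image-to-property pipeline with the
#' standard defaults (moment-fitting order `p_q = 2` with `n_c = 10^3`
#' sub-cells, preconditioner threshold `eps = 1e-13`, reference moisture
#' 12%). Round-trips losslessly through YAML.
#'
#' @param input path to a volume (TIFF / raw+JSON), or `NULL` to generate
#'   a phantom from `phantom`.
#' @param phantom a [phantom_spec()] (used when `input` is `NULL`).
#' @param spacing_um voxel spacing override.
#' @param energy an [energy_params()] list; `max_iter = 0` skips the
#'   evolution and uses the midpoint threshold directly.
#' @param island_threshold_voxels cleanup threshold (strict `<`).
#' @param p_q,n_c moment-fitting parameters.
#' @param cut_regularization relative fictitious stiffness in the void
#'   part of cut elements (see [build_xfem_model()]).
#' @param preconditioner `"jacobi"` (robust default) or `"element"`
#'   (element-sum spectral pseudo-inverse).
#' @param precond_eps element-preconditioner eigenvalue threshold.
#' @param solver_tol,solver_max_iter PCG controls (`NULL` max_iter =
#'   `10 sqrt(n_dof)`).
#' @param m,delta_m moisture content and its variation, %.
#' @param rho_cw cell-wall density, kg/m^3.
#' @param output_dir artifact directory.
#' @param seed integer seed.
#' @export
pipeline_config <- function(input = NULL, phantom = phantom_spec(),
                            spacing_um = NULL,
                            energy = energy_params(),
                            island_threshold_voxels = 27L,
                            p_q = 2, n_c = 1000,
                            cut_regularization = 1e-6,
                            preconditioner = c("jacobi", "element"),
                            precond_eps = 1e-13,
                            solver_tol = 1e-8, solver_max_iter = NULL,
                            m = 12, delta_m = 1, rho_cw = 1440,
                            output_dir = tempfile("ringhomog_run_"),
                            seed = 1L) {
  structure(list(input = input, phantom = phantom, spacing_um = spacing_um,
                 energy = energy,
                 island_threshold_voxels = as.integer(island_threshold_voxels),
                 p_q = p_q, n_c = n_c,
                 cut_regularization = cut_regularization,
                 preconditioner = match.arg(preconditioner),
                 precond_eps = precond_eps,
                 solver_tol = solver_tol, solver_max_iter = solver_max_iter,
                 m = m, delta_m = delta_m, rho_cw = rho_cw,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$phantom <- if (!is.null(x$phantom)) unclass(x$phantom)
  x$energy <- unclass(x$energy)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  ph <- if (!is.null(x$phantom)) do.call(phantom_spec, x$phantom)
  en <- do.call(energy_params, x$energy)
  x$phantom <- NULL; x$energy <- NULL
  do.call(pipeline_config, c(x, list(phantom = ph, energy = en)))
}

#' Run the full image-to-property pipeline
#'
#' Stages: acquire (read or generate a phantom) -> segment (level set)
#' -> clean -> periodize -> orient/material -> assemble -> precondition ->
#' solve cell problems -> homogenize -> reconstruct local fields. Writes
#' morphometrics and effective-property JSON, VTK field files, and a run
#' manifest; all randomness is controlled by the config seed, so reruns
#' with the same config are deterministic.
#'
#' @param config a [pipeline_config()].
#' @param write_artifacts write JSON/VTK outputs to `config$output_dir`.
#' @return (invisibly) list with `morphometrics`, `effective`, `solution`,
#'   `model`, `fields_free`, `fields_constrained`, `seg`, `truth`.
#' @export
run_pipeline <- function(config, write_artifacts = TRUE) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  truth <- NULL
  vol <- stage("acquire", {
    if (!is.null(config$input)) {
      read_volume(config$input, spacing = config$spacing_um)
    } else {
      ph <- generate_growth_ring_phantom(config$phantom)
      truth <- ph$truth
      ph$volume
    }
  })

  seg <- stage("segment", {
    binary0 <- threshold_volume(vol)
    needs_evolution <- !is.null(config$input) ||
      (!is.null(config$phantom) &&
         (config$phantom$noise_sd > 0 ||
            config$phantom$inhomogeneity_amplitude > 0))
    if (config$energy$max_iter > 0 && needs_evolution) {
      phi0 <- init_level_set(binary0, vol$spacing)
      phi <- evolve_level_set(vol, phi0, config$energy)
      binary0 <- phi$phi >= 0
    }
    ct <- if (!is.null(truth)) {
      ct0 <- truth$cell_type
      ct0[!binary0 & ct0 != "void"] <- "void"
      ct0[binary0 & ct0 == "void"] <- "axial"
      ct0
    }
    segmented_mesostructure(binary0, vol$spacing, cell_type = ct)
  })
  seg <- stage("clean",
               clean_segmentation(seg, config$island_threshold_voxels))
  per <- stage("periodize", make_periodic(seg))
  morpho <- stage("morphometrics", {
    we <- if (!is.null(config$phantom))
      config$phantom$earlywood_width_fraction *
        dim(seg$binary_phase)[1] * seg$spacing[1]
    compute_morphometrics(per, rho_cw = config$rho_cw, ew_boundary_um = we)
  })

  phi <- stage("level set", {
    if (all(per$binary_phase)) {
      # fully solid cell: constant positive level set (no interface)
      new_level_set(array(min(per$spacing), dim(per$binary_phase)),
                    per$spacing)
    } else {
      init_level_set(per$binary_phase, per$spacing)
    }
  })
  model <- stage("orient/material",
                 build_xfem_model(phi, per$cell_type, per$added_layers,
                                  m = config$m, p_q = config$p_q,
                                  n_c = config$n_c,
                                  cut_regularization =
                                    config$cut_regularization))
  asm <- stage("assemble", assemble_system(model))
  S <- stage("precondition",
             if (identical(config$preconditioner, "element"))
               build_preconditioner(asm, config$precond_eps)
             else diagonal_preconditioner(asm))
  solution <- stage("solve",
                    solve_cell_problems(asm, S, tol = config$solver_tol,
                                        max_iter = config$solver_max_iter))
  eff <- stage("homogenize", homogenize(solution, model))
  ff <- stage("fields", reconstruct_fields(solution, model, config$delta_m,
                                           "free", eff$beta_bar_full))
  fc <- stage("fields", reconstruct_fields(solution, model, config$delta_m,
                                           "constrained"))

  if (write_artifacts) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    jsonlite::write_json(unclass(morpho), file.path(od, "morphometrics.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(Cbar_MPa = eff$Cbar, beta_bar = eff$beta_bar,
           constants_MPa = as.list(eff$constants),
           off_orthotropy = eff$off_orthotropy),
      file.path(od, "effective_properties.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    dims <- model$mesh$dims
    for (nm in c("free", "constrained")) {
      f <- if (nm == "free") ff else fc
      full <- matrix(0, prod(dims), 12)
      full[f$elements, ] <- cbind(f$eps, f$sigma)
      write_vtk_cell_data(file.path(od, sprintf("fields_%s.vtk", nm)),
                          dims, model$mesh$spacing,
                          list(eps = full[, 1:6], sigma = full[, 7:12]))
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("ringhomog")),
      seed = config$seed,
      config = "config.yaml",
      stages = c("acquire", "segment", "clean", "periodize", "orient",
                 "assemble", "solve", "homogenize", "fields"),
      solver = list(iterations = solution$iterations,
                    residuals = solution$residuals,
                    converged = solution$converged),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(od, "config.yaml"))
  }
  invisible(list(morphometrics = morpho, effective = eff,
                 solution = solution, model = model, fields_free = ff,
                 fields_constrained = fc, seg = per, truth = truth))
}
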