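#' Gray-scale voxel volume container
#'
#' @param data 3D numeric array of intensities.
#' @param spacing voxel spacing, um (scalar or length-3).
#' @export
voxel_volume <- function(data, spacing = 1) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  structure(list(data = data, spacing = rep(as.numeric(spacing),
                                            length.out = 3)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %s um, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read a voxel volume from disk
#'
#' Supports multi-page TIFF stacks and raw binary with a JSON sidecar
#' (`<path>.json` holding `dtype`, `shape`, `spacing_um`). Intensities are
#' normalized to `[0, 1]`.
#'
#' @param path file path (`.tif`/`.tiff` or `.raw`).
#' @param spacing override spacing (um); otherwise taken from metadata
#'   (raw sidecar) or defaulting to 1.
#' @export
read_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nz <- length(pages)
    d1 <- dim(pages[[1]])
    # TIFF pages are row-major (y, x); store as (x, y, z)
    arr <- array(0, c(d1[2], d1[1], nz))
    for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]])
    sp <- spacing %||% 1
    return(voxel_volume(arr, sp))
  }
  if (ext == "raw") {
    meta_path <- paste0(path, ".json")
    if (!file.exists(meta_path)) stop("missing JSON sidecar: ", meta_path)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    shp <- as.integer(meta$shape)
    dtype <- meta$dtype %||% "float64"
    size <- switch(dtype, float64 = 8, float32 = 4, uint16 = 2, uint8 = 1,
                   stop("unsupported dtype: ", dtype))
    expect_bytes <- prod(shp) * size
    got <- file.size(path)
    if (got != expect_bytes)
      stop(sprintf("raw byte count mismatch: expected %d, found %d",
                   expect_bytes, got))
    con <- file(path, "rb")
    on.exit(close(con))
    what <- if (dtype %in% c("float64", "float32")) "double" else "integer"
    v <- readBin(con, what = what, n = prod(shp), size = size,
                 signed = !(dtype %in% c("uint16", "uint8")))
    if (dtype == "uint8") v <- v / 255
    if (dtype == "uint16") v <- v / 65535
    sp <- spacing %||% meta$spacing_um %||% 1
    return(voxel_volume(array(v, shp), sp))
  }
  stop("unsupported volume format: .", ext)
}

#' Write a voxel volume to disk
#'
#' @param vol a [voxel_volume()].
#' @param path output path; `.tif` writes a multi-page TIFF (values clamped
#'   to `[0,1]`), `.raw` writes float64 binary plus a JSON sidecar.
#' @export
write_volume <- function(vol, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    d <- dim(vol$data)
    pages <- lapply(seq_len(d[3]), function(k) t(clamp(vol$data[, , k], 0, 1)))
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else if (ext == "raw") {
    con <- file(path, "wb")
    writeBin(as.vector(vol$data), con, size = 8)
    close(con)
    jsonlite::write_json(
      list(dtype = "float64", shape = dim(vol$data),
           spacing_um = vol$spacing),
      paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  } else stop("unsupported volume format: .", ext)
  invisible(path)
}

#' Write cell-centered fields as a legacy ASCII VTK structured-points file
#'
#' @param path output `.vtk` path.
#' @param dims element grid dimensions (cells).
#' @param spacing cell spacing (um).
#' @param cell_data named list of numeric vectors/matrices; a matrix with 3
#'   or 6 columns is written component-wise.
#' @export
write_vtk_cell_data <- function(path, dims, spacing, cell_data) {
  spacing <- rep(spacing, length.out = 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "ringhomog cell data", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1] + 1, dims[2] + 1, dims[3] + 1),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.9g %.9g %.9g", spacing[1], spacing[2], spacing[3]),
               sprintf("CELL_DATA %d", prod(dims))), con)
  for (nm in names(cell_data)) {
    v <- cell_data[[nm]]
    if (is.matrix(v)) {
      for (j in seq_len(ncol(v))) {
        writeLines(c(sprintf("SCALARS %s_%d double 1", nm, j),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(v[, j], digits = 9, trim = TRUE, scientific = TRUE), con)
      }
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(as.vector(v), digits = 9, trim = TRUE,
                        scientific = TRUE), con)
    }
  }
  invisible(path)
}
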