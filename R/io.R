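#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' Planes are stored as 32-bit float pages, divided by `scale` to keep values
#' near the unit range TIFF viewers expect. Geometry (pixel size, z
#' positions, wavelength, the intensity scale) goes to `<file>.json`, since
#' baseline TIFF tags cannot carry it portably.
#'
#' @param stack an [image_stack()].
#' @param file output path (`.tif`).
#' @param scale intensity divisor stored in the sidecar.
#' @return `file`, invisibly.
#' @export
write_stack_tiff <- function(stack, file, scale = 4) {
  pages <- lapply(seq_along(stack$z_positions), function(j)
    stack$intensity[, , j] / scale)
  tiff::writeTIFF(pages, file, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(pixel_size_um = stack$pixel_size,
               z_positions_um = stack$z_positions,
               wavelength_um = stack$wavelength,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read a multi-page TIFF stack written by [write_stack_tiff()]
#'
#' Plain multi-page TIFFs (no sidecar) are supported when the geometry is
#' passed explicitly.
#'
#' @param file `.tif` path.
#' @param pixel_size,z_positions,wavelength geometry overrides when no
#'   sidecar is present.
#' @return an [image_stack()].
#' @export
read_stack_tiff <- function(file, pixel_size = NULL, z_positions = NULL,
                            wavelength = NULL) {
  pages <- tiff::readTIFF(file, all = TRUE)
  side <- paste0(file, ".json")
  scale <- 1
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
    if (is.null(z_positions)) z_positions <- meta$z_positions_um
    if (is.null(wavelength)) wavelength <- meta$wavelength_um
    scale <- meta$intensity_scale
  }
  stopifnot(!is.null(pixel_size), !is.null(z_positions), !is.null(wavelength))
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (j in seq_along(pages)) arr[, , j] <- pages[[j]] * scale
  image_stack(arr, z_positions, pixel_size, wavelength)
}

#' Write a phase or density map as 32-bit float TIFF
#'
#' @param map a [phase_map()] or plain matrix.
#' @param file output path.
#' @param scale divisor stored in the sidecar.
#' @return `file`, invisibly.
#' @export
write_map_tiff <- function(map, file, scale = 2 * pi, offset = 0.5) {
  m <- if (inherits(map, "phase_map")) map$phase else map
  # offset keeps slightly negative (background-corrected) values inside the
  # [0, 1] range TIFF stores portably
  tiff::writeTIFF(m / scale + offset, file, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(scale = scale, offset = offset,
               pixel_size_um = if (inherits(map, "phase_map")) map$pixel_size else NA)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a phase map written by [write_map_tiff()]
#'
#' @param file `.tif` path (the `.json` sidecar must sit next to it).
#' @param background_corrected flag to set on the restored map.
#' @return a [phase_map()].
#' @export
read_map_tiff <- function(file, background_corrected = TRUE) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  off <- if (is.null(meta$offset)) 0 else meta$offset
  m <- (tiff::readTIFF(file) - off) * meta$scale
  phase_map(m, meta$pixel_size_um, background_corrected = background_corrected)
}

#' Write per-cell measurements as CSV
#'
#' @param measurements data.frame from [measure_frame()].
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_measurements_csv <- function(measurements, file) {
  utils::write.csv(measurements, file, row.names = FALSE)
  invisible(file)
}

#' Read per-cell measurements CSV
#'
#' @param file path.
#' @return data.frame.
#' @export
read_measurements_csv <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
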