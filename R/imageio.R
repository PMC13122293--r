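# NIfTI I/O for multi-echo series, masks and maps.
#
# Conventions: 0-based voxel indices map to world coordinates through the
# NIfTI affine; B0 is taken along the image +z axis (axial acquisition,
# slice-normal ~ B0) unless the sidecar overrides it. Phase volumes may be
# stored in radians (float) or with signed-integer vendor scaling (e.g.
# [-4096, 4096) for [-pi, pi)); the dialect is auto-detected from the value
# range and can be forced.

#' Write an echo series as magnitude/phase NIfTI pairs plus a JSON sidecar
#'
#' @param series an `echo_series`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, a list with the written `mag`, `phase` and `sidecar`
#'   paths.
#' @export
write_series <- function(series, dir, prefix = tolower(series$series_type)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mag_path <- file.path(dir, paste0(prefix, "_mag.nii.gz"))
  ph_path <- file.path(dir, paste0(prefix, "_phase.nii.gz"))
  sc_path <- file.path(dir, paste0(prefix, ".json"))
  img <- RNifti::asNifti(Mod(series$data))
  RNifti::pixdim(img) <- series$voxel_size
  RNifti::writeNifti(img, mag_path)
  img <- RNifti::asNifti(Arg(series$data))
  RNifti::pixdim(img) <- series$voxel_size
  RNifti::writeNifti(img, ph_path)
  jsonlite::write_json(
    list(EchoTime = series$schedule$time,
         EchoLabel = series$schedule$label,
         PolaritySign = series$schedule$polarity,
         SourceSeries = series$schedule$source,
         SourceIndex = series$schedule$source_index,
         MagneticFieldStrength = series$B0,
         B0Direction = series$b0_direction,
         VoxelSize = series$voxel_size,
         SeriesType = series$series_type),
    sc_path, digits = NA, auto_unbox = FALSE)
  invisible(list(mag = mag_path, phase = ph_path, sidecar = sc_path))
}

#' Read a multi-echo series from magnitude/phase NIfTI volumes
#'
#' @param mag_paths magnitude NIfTI path(s): one 4D file or one 3D file per
#'   echo.
#' @param phase_paths matching phase path(s).
#' @param sidecar JSON sidecar path listing at least `EchoTime` (ms); written
#'   by [write_series()] or BIDS-style.
#' @param phase_scale "auto", "radians", or a numeric divisor `s` such that
#'   stored values map to radians as `value * pi / s`.
#' @return an `echo_series`.
#' @export
read_series <- function(mag_paths, phase_paths, sidecar,
                        phase_scale = "auto") {
  if (length(mag_paths) != length(phase_paths))
    stop("magnitude and phase volume counts differ")
  mag <- read_volumes_4d(mag_paths)
  ph <- read_volumes_4d(phase_paths)
  if (!identical(dim(mag), dim(ph))) stop("magnitude/phase grid mismatch")
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(sc$EchoTime)) stop("sidecar is missing echo times")
  te <- as.numeric(sc$EchoTime)
  if (length(te) != dim(mag)[4])
    stop("echo count mismatch: ", dim(mag)[4], " volumes vs ",
         length(te), " echo times in sidecar")
  ph <- rescale_phase(ph, phase_scale)
  sched <- new_echo_schedule(
    te,
    sc$EchoLabel %||% rep("IP", length(te)),
    sc$PolaritySign %||% rep(1L, length(te)),
    sc$SourceSeries %||% rep(sc$SeriesType %||% "IP", length(te)),
    sc$SourceIndex %||% seq_along(te))
  vox <- as.numeric(sc$VoxelSize %||% attr(mag, "pixdim"))
  cdata <- array(complex(modulus = mag, argument = ph), dim = dim(mag))
  echo_series(cdata, sched,
              voxel_size = vox,
              B0 = sc$MagneticFieldStrength %||% 3,
              b0_direction = as.numeric(sc$B0Direction %||% c(0, 0, 1)),
              series_type = sc$SeriesType %||% "IP")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_volumes_4d <- function(paths) {
  vols <- lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    a <- as.array(img)
    attr(a, "pixdim") <- RNifti::pixdim(img)[1:3]
    a
  })
  pd <- attr(vols[[1]], "pixdim")
  if (length(vols) == 1L) {
    a <- vols[[1]]
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  } else {
    d <- dim(vols[[1]])
    if (length(d) != 3L) stop("per-echo volumes must be 3D")
    for (v in vols[-1]) if (!identical(dim(v), d)) stop("grid mismatch between echoes")
    a <- array(0, dim = c(d, length(vols)))
    for (i in seq_along(vols)) a[, , , i] <- vols[[i]]
  }
  attr(a, "pixdim") <- pd
  a
}

# Map stored phase values to radians. Integer vendor dialects use a symmetric
# signed range [-s, s) for [-pi, pi) with s a power of two (typically 4096).
rescale_phase <- function(ph, phase_scale) {
  if (identical(phase_scale, "radians")) return(ph)
  if (is.numeric(phase_scale)) return(ph * pi / phase_scale)
  m <- max(abs(ph))
  if (m <= pi * 1.001) return(ph)
  s <- 2^ceiling(log2(m))
  ph * pi / s
}

#' Write a scalar map as NIfTI with a unit tag
#'
#' The volume inherits the reference series' voxel size; the unit string is
#' recorded in the header `descrip` field.
#'
#' @param volume real 3D array on the series grid.
#' @param reference an `echo_series` (or any object with `$voxel_size`).
#' @param path output path (.nii or .nii.gz).
#' @param units unit string, e.g. "ppb" or "Hz".
#' @return `path`, invisibly.
#' @export
write_map <- function(volume, reference, path, units = "") {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- reference$voxel_size
  if (nzchar(units)) img$descrip <- units
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a map written by [write_map()]
#' @param path NIfTI path.
#' @return array with attributes `units` and `pixdim`.
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attr(a, "units") <- RNifti::niftiHeader(img)$descrip
  attr(a, "pixdim") <- RNifti::pixdim(img)[1:3]
  a
}

#' Write / read binary masks as uint8 NIfTI
#' @param mask logical volume.
#' @param reference object with `$voxel_size`.
#' @param path NIfTI path.
#' @return `path` (write) or a logical array (read).
#' @export
write_mask <- function(mask, reference, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- reference$voxel_size
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  as.array(RNifti::readNifti(path)) > 0
}
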