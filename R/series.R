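# Container for a multi-echo complex GRE series.

#' Multi-echo complex GRE series
#'
#' @param data complex 4D array, dimensions (x, y, z, echo).
#' @param schedule an `echo_schedule` whose length matches the echo dimension.
#' @param voxel_size voxel size in mm (length 3).
#' @param B0 field strength, Tesla.
#' @param b0_direction unit vector of the main field in image coordinates.
#' @param series_type "IP", "OOP" or "merged".
#' @return an `echo_series` object.
#' @export
echo_series <- function(data, schedule, voxel_size = c(0.4, 0.4, 1),
                        B0 = 3, b0_direction = c(0, 0, 1),
                        series_type = schedule$source[1]) {
  stopifnot(length(dim(data)) == 4L)
  if (dim(data)[4] != nrow(schedule))
    stop("echo count of data (", dim(data)[4], ") does not match schedule (",
         nrow(schedule), ")")
  if (anyNA(Mod(data))) stop("NaN/NA magnitude in echo series")
  nb <- sqrt(sum(b0_direction^2))
  if (abs(nb - 1) > 1e-6) b0_direction <- b0_direction / nb
  structure(list(data = data, schedule = schedule, voxel_size = voxel_size,
                 B0 = B0, b0_direction = b0_direction,
                 series_type = series_type),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<echo_series ", x$series_type, "> ", d[1], "x", d[2], "x", d[3],
      " voxels, ", d[4], " echoes, B0 = ", x$B0, " T\n", sep = "")
  invisible(x)
}

#' Number of echoes in a series
#' @param series an `echo_series`.
#' @export
n_echoes <- function(series) dim(series$data)[4]

#' Extract one echo volume
#' @param series an `echo_series`.
#' @param i echo index.
#' @return complex 3D array.
#' @export
echo_volume <- function(series, i) {
  slice4(series$data, i)
}

#' Magnitude and phase of a series
#' @param series an `echo_series`.
#' @return real 4D array.
#' @export
series_magnitude <- function(series) Mod(series$data)

#' @rdname series_magnitude
#' @export
series_phase <- function(series) Arg(series$data)

#' Merge the IP and OOP series onto the joint echo grid
#'
#' Schedules are merged with [merge_schedules()]; image volumes are gathered
#' in merged-time order using the per-echo provenance.
#'
#' @param a,b `echo_series` objects on the same grid.
#' @return an `echo_series` with `series_type = "merged"`.
#' @export
merge_echo_series <- function(a, b) {
  if (!identical(dim(a$data)[1:3], dim(b$data)[1:3]))
    stop("series grids differ")
  sched <- merge_schedules(a$schedule, b$schedule)
  d <- dim(a$data)[1:3]
  out <- array(0i, dim = c(d, nrow(sched)))
  for (n in seq_len(nrow(sched))) {
    src <- if (sched$source[n] == a$series_type) a else b
    out[, , , n] <- src$data[, , , sched$source_index[n]]
  }
  echo_series(out, sched, a$voxel_size, a$B0, a$b0_direction, "merged")
}

#' Replace the complex data of a series, keeping metadata
#' @param series an `echo_series`.
#' @param data replacement complex 4D array of identical shape.
#' @keywords internal
series_with_data <- function(series, data) {
  stopifnot(identical(dim(data), dim(series$data)))
  series$data <- data
  series
}
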