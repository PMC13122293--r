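# Echo-schedule construction for the dual IP/OOP spinal-cord QSM protocol.
#
# The acquisition uses two bipolar 3D GRE sequences at 3T: one whose echoes
# fall on (or near) the water-fat in-phase times, one on the out-of-phase
# times, interleaved on a common 1.23 ms grid once merged. The first IP echo
# is typically only partially in phase (PIP) because gradient limits forbid
# reaching the nominal 2.46 ms in-phase time.

# Nominal water-fat in-phase period at 3T, in ms. Governs PIP labelling.
NOMINAL_IP_PERIOD_MS <- 2.46

# Echo-time tolerance (ms) for duplicate detection and PIP labelling;
# sub-microsecond timing differences are below protocol precision.
ECHO_TIME_TOL_MS <- 0.01

#' Acquisition protocol for one multi-echo GRE series
#'
#' @param series_type "IP" (in-phase echo times) or "OOP" (out-of-phase).
#' @param TE1 first echo time, ms.
#' @param dTE echo spacing, ms (from the second echo onward).
#' @param n_echoes number of echoes.
#' @param TE2 second echo time, ms. Defaults to `TE1 + dTE`; give it
#'   explicitly when the first echo is displaced off the regular grid (the
#'   PIP case, e.g. TE1 = 2.64 with TE2 = 4.92).
#' @param TR repetition time, ms.
#' @param flip_angle excitation flip angle, degrees.
#' @param voxel_size acquisition voxel size, mm (length 3).
#' @param B0 main field strength, Tesla.
#' @param readout_bandwidth readout bandwidth, Hz/pixel.
#' @param readout_polarity "bipolar" or "monopolar".
#' @return an `acquisition_protocol` object.
#' @export
#' @examples
#' acquisition_protocol("OOP", TE1 = 3.69)
acquisition_protocol <- function(series_type = c("IP", "OOP"),
                                 TE1,
                                 dTE = 2.46,
                                 n_echoes = 12L,
                                 TE2 = NULL,
                                 TR = 33,
                                 flip_angle = 12,
                                 voxel_size = c(0.4, 0.4, 1),
                                 B0 = 3,
                                 readout_bandwidth = 1000,
                                 readout_polarity = c("bipolar", "monopolar")) {
  series_type <- match.arg(series_type)
  readout_polarity <- match.arg(readout_polarity)
  if (is.null(TE2)) TE2 <- TE1 + dTE
  p <- structure(
    list(series_type = series_type, TR = TR, TE1 = TE1, TE2 = TE2, dTE = dTE,
         n_echoes = as.integer(n_echoes), flip_angle = flip_angle,
         voxel_size = voxel_size, B0 = B0,
         readout_bandwidth = readout_bandwidth,
         readout_polarity = readout_polarity),
    class = "acquisition_protocol")
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  if (p$TE1 <= 0) stop("protocol violation: TE1 must be positive")
  if (p$dTE <= 0) stop("protocol violation: dTE must be positive")
  if (p$n_echoes < 1L) stop("protocol violation: n_echoes must be >= 1")
  last_te <- if (p$n_echoes == 1L) p$TE1 else p$TE2 + (p$n_echoes - 2L) * p$dTE
  if (last_te >= p$TR)
    stop("protocol violation: echo train (last TE ", last_te,
         " ms) does not fit within TR ", p$TR, " ms")
  invisible(p)
}

#' The dual-series 3T spinal-cord protocol defaults
#'
#' IP series: TE1 = 2.64 ms (partially in phase), TE2 = 4.92 ms, spacing
#' 2.46 ms, 12 echoes. OOP series: TE1 = 3.69 ms, spacing 2.46 ms, 12 echoes.
#' Both TR = 33 ms, bipolar readout, 0.4 x 0.4 x 1 mm voxels at 3T.
#'
#' @return named list with elements `ip` and `oop`.
#' @export
default_protocols <- function() {
  list(
    ip  = acquisition_protocol("IP", TE1 = 2.64, TE2 = 4.92, dTE = 2.46,
                               n_echoes = 12L),
    oop = acquisition_protocol("OOP", TE1 = 3.69, dTE = 2.46, n_echoes = 12L)
  )
}

new_echo_schedule <- function(time, label, polarity, source, source_index) {
  df <- data.frame(time = time, label = label, polarity = as.integer(polarity),
                   source = source, source_index = as.integer(source_index),
                   stringsAsFactors = FALSE)
  class(df) <- c("echo_schedule", "data.frame")
  df
}

#' Build the echo schedule of one series
#'
#' Echo times are `TE1, TE2, TE2 + dTE, ...`. The first echo of an IP series
#' is labelled `"PIP"` (partially in phase) when `TE1` misses the nominal
#' in-phase time by more than 0.01 ms. Polarity signs alternate (+1, -1, ...)
#' for bipolar readouts.
#'
#' @param protocol an [acquisition_protocol()].
#' @param nominal_ip_period nominal 3T in-phase period, ms.
#' @return an `echo_schedule` data frame with columns `time` (ms), `label`
#'   (IP/PIP/OOP), `polarity` (+1/-1), `source` (series type), `source_index`.
#' @export
#' @examples
#' build_schedule(default_protocols()$ip)$time[1:3]  # 2.64 4.92 7.38
build_schedule <- function(protocol, nominal_ip_period = NOMINAL_IP_PERIOD_MS) {
  validate_protocol(protocol)
  n <- protocol$n_echoes
  times <- if (n == 1L) protocol$TE1
           else c(protocol$TE1, protocol$TE2 + (seq_len(n - 1L) - 1L) * protocol$dTE)
  labels <- rep(protocol$series_type, n)
  if (protocol$series_type == "IP") {
    # distance of TE1 from the nearest multiple of the in-phase period
    mis <- abs(protocol$TE1 - nominal_ip_period *
                 round(protocol$TE1 / nominal_ip_period))
    if (mis > ECHO_TIME_TOL_MS) labels[1] <- "PIP"
  }
  pol <- if (protocol$readout_polarity == "bipolar")
    rep_len(c(1L, -1L), n) else rep(1L, n)
  new_echo_schedule(times, labels, pol, protocol$series_type, seq_len(n))
}

#' An empty echo schedule (merge identity)
#' @return an `echo_schedule` with zero rows.
#' @export
empty_schedule <- function() {
  new_echo_schedule(numeric(0), character(0), integer(0), character(0),
                    integer(0))
}

#' Merge two echo schedules into one time-sorted grid
#'
#' The merged schedule keeps, per echo, the source series and the index
#' within that series, so image data can be gathered in the same order.
#'
#' @param a,b `echo_schedule` objects.
#' @param tol duplicate-time tolerance, ms.
#' @return merged `echo_schedule`, strictly increasing in time.
#' @export
#' @examples
#' p <- default_protocols()
#' m <- merge_schedules(build_schedule(p$ip), build_schedule(p$oop))
#' nrow(m)       # 24
#' m$time[1:4]   # 2.64 3.69 4.92 6.15
merge_schedules <- function(a, b, tol = ECHO_TIME_TOL_MS) {
  stopifnot(inherits(a, "echo_schedule"), inherits(b, "echo_schedule"))
  all_t <- c(a$time, b$time)
  if (length(all_t) > 1L) {
    st <- sort(all_t)
    if (any(diff(st) < tol))
      stop("ambiguous merge: duplicate echo times within ", tol, " ms")
  }
  out <- rbind(as.data.frame(a), as.data.frame(b))
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("echo_schedule", "data.frame")
  out
}

#' Read acquisition protocols from a YAML or JSON config file
#'
#' The config holds one block per series with the [acquisition_protocol()]
#' fields, e.g. `ip: {series_type: IP, TE1: 2.64, TE2: 4.92, ...}`.
#'
#' @param path file path; format chosen by extension (.yaml/.yml or .json).
#' @return named list of `acquisition_protocol` objects.
#' @export
read_protocol_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  lapply(cfg, function(b) {
    b$voxel_size <- unlist(b$voxel_size)
    do.call(acquisition_protocol, b)
  })
}

#' Write a merged schedule as a JSON sidecar
#'
#' @param schedule an `echo_schedule`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(as.data.frame(schedule), path, digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' Read a schedule sidecar written by [write_schedule_json()]
#' @param path JSON file path.
#' @return an `echo_schedule`.
#' @export
read_schedule_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_echo_schedule(df$time, df$label, df$polarity, df$source, df$source_index)
}

#' @export
print.echo_schedule <- function(x, ...) {
  cat("<echo_schedule> ", nrow(x), " echoes",
      if (nrow(x)) paste0(", TE ", format(min(x$time)), "-",
                          format(max(x$time)), " ms"), "\n", sep = "")
  if (nrow(x)) print(as.data.frame(x), ...)
  invisible(x)
}
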