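# Numerical cervical-cord phantom and forward signal simulator.
#
# The phantom is a 2.5D cylinder stack: a spinal cord (GM H-shape + WM) inside
# a CSF ring, a fat-bearing vertebral body anterior to the canal, optional
# lesions painted into the cord WM, and an air-like low-signal background with
# a reserved noise-measurement box. Susceptibilities are relative values in
# ppb; the absolute offset is unobservable in QSM and is left at zero.

#' Multi-peak fat spectrum
#'
#' Chemical-shift peaks of the fat signal relative to water. The default
#' six-peak model has peaks at (-3.80, -3.40, -2.60, -1.94, -0.39, +0.60) ppm
#' with amplitudes (0.087, 0.693, 0.128, 0.004, 0.039, 0.048), renormalised to
#' sum to one. `model = "1peak"` gives a single peak whose period equals the
#' nominal 2.46 ms in-phase spacing, convenient for closed-form checks.
#'
#' @param B0 field strength, Tesla (converts ppm to Hz).
#' @param model "6peak" or "1peak".
#' @param ppm,alpha optional explicit peak positions (ppm) and amplitudes,
#'   overriding `model`.
#' @return a `fat_spectrum` object with fields `delta_f` (Hz), `alpha`, `K`.
#' @export
fat_spectrum <- function(B0 = 3, model = c("6peak", "1peak"),
                         ppm = NULL, alpha = NULL) {
  if (is.null(ppm)) {
    model <- match.arg(model)
    if (model == "6peak") {
      ppm <- c(-3.80, -3.40, -2.60, -1.94, -0.39, 0.60)
      alpha <- c(0.087, 0.693, 0.128, 0.004, 0.039, 0.048)
    } else {
      # period of the water-fat beat = 2.46 ms at 3T
      ppm <- -1 / (NOMINAL_IP_PERIOD_MS * 1e-3) / larmor_hz(3) * 1e6
      alpha <- 1
    }
  }
  stopifnot(length(ppm) == length(alpha), length(ppm) >= 1, all(alpha > 0))
  alpha <- alpha / sum(alpha)
  structure(list(delta_f = ppm * 1e-6 * larmor_hz(B0), alpha = alpha,
                 K = length(ppm), B0 = B0),
            class = "fat_spectrum")
}

#' Fat dephasing factor at given echo times
#' @param fat a [fat_spectrum()].
#' @param te_ms echo times in ms.
#' @return complex vector: sum_k alpha_k exp(-i 2 pi df_k TE).
#' @keywords internal
fat_phasor <- function(fat, te_ms) {
  te_s <- te_ms * 1e-3
  vapply(te_s, function(t) sum(fat$alpha * exp(-2i * pi * fat$delta_f * t)),
         complex(1))
}

#' Unit dipole kernel in k-space
#'
#' D(k) = 1/3 - (k . b0)^2 / |k|^2 on the DFT grid of `grid_shape`, with
#' physical frequencies (cycles/mm) from `voxel_size`; D(0) is set to 0
#' (susceptibility has no observable mean offset).
#'
#' @param grid_shape integer triplet.
#' @param voxel_size mm triplet, all positive.
#' @param b0_direction main-field direction (normalised internally).
#' @return a `dipole_kernel` object: `D` (array), plus the grid metadata
#'   needed to rebuild the multiplier on padded grids.
#' @export
dipole_kernel <- function(grid_shape, voxel_size = c(0.4, 0.4, 1),
                          b0_direction = c(0, 0, 1)) {
  if (any(voxel_size <= 0)) stop("voxel size must be positive")
  b0 <- b0_direction / sqrt(sum(b0_direction^2))
  structure(list(D = dipole_multiplier(grid_shape, voxel_size, b0),
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, b0_direction = b0),
            class = "dipole_kernel")
}

dipole_multiplier <- function(shape, voxel_size, b0) {
  kx <- fft_freq(shape[1]) / voxel_size[1]
  ky <- fft_freq(shape[2]) / voxel_size[2]
  kz <- fft_freq(shape[3]) / voxel_size[3]
  KX <- array(kx, dim = shape)
  KY <- array(rep(ky, each = shape[1]), dim = shape)
  KZ <- array(rep(kz, each = shape[1] * shape[2]), dim = shape)
  k2 <- KX^2 + KY^2 + KZ^2
  kb <- KX * b0[1] + KY * b0[2] + KZ * b0[3]
  D <- 1 / 3 - kb^2 / k2
  D[k2 == 0] <- 0
  D
}

#' Field shift induced by a susceptibility distribution
#'
#' Computes f = gamma_bar * B0 * IFFT(D . FFT(chi * 1e-9)) in Hz, on a grid
#' zero-padded by a factor `pad_factor` per axis and cropped back, which
#' suppresses the circular-convolution wraparound of the FFT dipole model.
#'
#' @param chi susceptibility volume in ppb.
#' @param kernel a [dipole_kernel()] matching the grid of `chi`.
#' @param B0 field strength, Tesla.
#' @param pad_factor padding factor per axis (>= 1.5 recommended).
#' @return field volume in Hz, same shape as `chi`.
#' @export
forward_field <- function(chi, kernel, B0 = 3, pad_factor = 2) {
  stopifnot(inherits(kernel, "dipole_kernel"))
  if (!identical(dim(chi), as.integer(kernel$grid_shape)) &&
      !all(dim(chi) == kernel$grid_shape))
    stop("chi shape does not match kernel grid")
  if (any(!is.finite(chi))) stop("chi must be finite")
  shape <- dim(chi)
  pshape <- as.integer(ceiling(shape * pad_factor))
  D <- dipole_multiplier(pshape, kernel$voxel_size, kernel$b0_direction)
  f <- kspace_filter(pad_to(chi, pshape), D)
  crop_to(f, shape) * 1e-9 * larmor_hz(B0)
}

#' Phantom specification
#'
#' @param grid_shape voxel grid, default 64 x 64 x 16 (desk scale; the full
#'   154 mm FOV matrix is configurable but not default).
#' @param voxel_size mm, default the acquisition's 0.4 x 0.4 x 1 mm.
#' @param tissue_chi named susceptibilities in ppb for `CSF`, `WM`, `GM`,
#'   `bone`. Cord defaults follow measured relative values (GM +3.1, WM -0.7);
#'   bone/marrow are generator defaults chosen to exercise fat-water
#'   separation, not measurements.
#' @param tissue_r2s named R2* values, 1/ms.
#' @param tissue_fat_fraction named fat fractions in `[0, 1]`.
#' @param tissue_m0 named proton-density magnitudes (arbitrary units).
#' @param cord_radius,csf_radius,vertebra_radius geometry radii, mm.
#' @param vertebra_center in-plane offset (mm) of the vertebral body.
#' @param lesion_specs list of lesions, each
#'   `list(center = c(x, y, z) mm, radius = r mm, pattern = "hyper" |
#'   "iso" | "hypo" | "rim")`; centers are relative to the cord axis
#'   (z relative to volume center).
#' @param noise_sd complex noise sd as a fraction of peak signal magnitude
#'   (default 0.02, i.e. SNR 50 at the first echo).
#' @param seed integer RNG seed for the simulator.
#' @param B0 Tesla.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 16L),
                         voxel_size = c(0.4, 0.4, 1),
                         tissue_chi = c(CSF = 0, WM = -0.7, GM = 3.1,
                                        bone = -2000),
                         tissue_r2s = c(CSF = 0.01, WM = 0.03, GM = 0.035,
                                        bone = 0.05),
                         tissue_fat_fraction = c(CSF = 0, WM = 0, GM = 0,
                                                 bone = 0.5),
                         tissue_m0 = c(CSF = 1, WM = 0.9, GM = 0.85,
                                       bone = 0.7),
                         cord_radius = 4, csf_radius = 6,
                         vertebra_radius = 3.5,
                         vertebra_center = c(0, 8.5),
                         lesion_specs = list(),
                         noise_sd = 0.02, seed = 1L, B0 = 3) {
  if (any(tissue_fat_fraction < 0 | tissue_fat_fraction > 1))
    stop("fat fractions must lie in [0, 1]")
  if (any(tissue_r2s < 0)) stop("R2* must be nonnegative")
  for (ls in lesion_specs)
    if (ls$radius <= 0) stop("lesion radii must be positive")
  structure(as.list(environment()), class = "phantom_spec")
}

# Lesion susceptibility patterns (ppb): uniform disks at the measured category
# means; "rim" adds a 1-voxel paramagnetic shell around a hypointense core.
LESION_CHI <- c(hyper = 1.5, iso = -0.4, hypo = -3.6)
RIM_SHELL_CHI <- 3.0

#' Build the phantom ground truth
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_truth` object: `chi` (ppb), `r2s` (1/ms),
#'   `fat_fraction`, `m0`, `field_hz` (forward dipole field of `chi`),
#'   `masks` (cord/GM/WM/CSF/bone/lesion/noise logical volumes and a `label`
#'   volume), `voxel_size`, `B0`, `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- as.integer(spec$grid_shape); vs <- spec$voxel_size
  # world coordinates (mm), origin at volume center
  cx <- (seq_len(gs[1]) - (gs[1] + 1) / 2) * vs[1]
  cy <- (seq_len(gs[2]) - (gs[2] + 1) / 2) * vs[2]
  cz <- (seq_len(gs[3]) - (gs[3] + 1) / 2) * vs[3]
  X <- array(cx, dim = gs)
  Y <- array(rep(cy, each = gs[1]), dim = gs)
  Z <- array(rep(cz, each = gs[1] * gs[2]), dim = gs)
  r2 <- X^2 + Y^2

  cord <- r2 <= spec$cord_radius^2
  csf <- !cord & r2 <= spec$csf_radius^2
  vb <- spec$vertebra_center
  bone <- (X - vb[1])^2 + (Y - vb[2])^2 <= spec$vertebra_radius^2

  # GM "H": two ventral and two dorsal horns (axis-aligned ellipses) joined
  # by a central commissure; dorsal horns are the slender posterior pair.
  in_ellipse <- function(x0, y0, a, b) ((X - x0) / a)^2 + ((Y - y0) / b)^2 <= 1
  gm <- in_ellipse( 1.2, -1.0, 1.0, 1.2) | in_ellipse(-1.2, -1.0, 1.0, 1.2) |
        in_ellipse( 0.8,  1.3, 0.55, 1.5) | in_ellipse(-0.8,  1.3, 0.55, 1.5) |
        in_ellipse( 0.0,  0.0, 1.3, 0.45)
  gm <- gm & cord
  wm <- cord & !gm

  label <- array("air", dim = gs)
  label[csf] <- "CSF"; label[bone] <- "bone"
  label[wm] <- "WM"; label[gm] <- "GM"

  fill <- function(tab, default = 0) {
    v <- array(default, dim = gs)
    for (t in names(tab)) v[label == t] <- tab[[t]]
    v
  }
  chi <- fill(spec$tissue_chi)
  r2s <- fill(spec$tissue_r2s)
  ff <- fill(spec$tissue_fat_fraction)
  m0 <- fill(spec$tissue_m0, default = 0.05)  # faint background signal
  # axial structure: vertebral body / intervertebral disc alternation gives
  # the magnitude genuine z-content (registration is otherwise degenerate)
  zl <- max(cz) - min(cz) + vs[3]
  zmod <- 1 + 0.3 * cos(2 * pi * Z / zl)
  m0[bone] <- (m0 * zmod)[bone]

  lesion <- array(FALSE, dim = gs)
  for (ls in spec$lesion_specs) {
    d2 <- (X - ls$center[1])^2 + (Y - ls$center[2])^2 + (Z - ls$center[3])^2
    core <- d2 <= ls$radius^2
    if (!all(cord[core])) stop("lesion at (",
      paste(ls$center, collapse = ", "), ") mm extends outside the cord")
    if (ls$pattern == "rim") {
      shell_r <- ls$radius + max(vs[1:2])  # 1 in-plane voxel shell
      shell <- !core & d2 <= shell_r^2
      if (!all(cord[shell])) stop("lesion rim extends outside the cord")
      chi[core] <- LESION_CHI[["hypo"]]
      chi[shell] <- RIM_SHELL_CHI
      lesion <- lesion | core | shell
    } else {
      chi[core] <- LESION_CHI[[ls$pattern]]
      lesion <- lesion | core
    }
  }

  noise_box <- X < -9 & Y < -9  # air corner, clear of canal and vertebra
  kernel <- dipole_kernel(gs, vs)
  field <- forward_field(chi, kernel, B0 = spec$B0)

  truth <- structure(
    list(chi = chi, r2s = r2s, fat_fraction = ff, m0 = m0, field_hz = field,
         masks = list(cord = cord, GM = gm, WM = wm, CSF = label == "CSF",
                      bone = label == "bone",
                      lesion = lesion, noise = noise_box, label = label),
         voxel_size = vs, B0 = spec$B0, kernel = kernel, spec = spec),
    class = "phantom_truth")
  stopifnot(!any(truth$masks$GM & truth$masks$WM),
            all((truth$masks$GM | truth$masks$WM) == truth$masks$cord))
  truth
}

#' @export
print.phantom_truth <- function(x, ...) {
  gs <- dim(x$chi)
  cat("<phantom_truth> ", gs[1], "x", gs[2], "x", gs[3], " voxels, ",
      sum(x$masks$cord), " cord voxels (", sum(x$masks$GM), " GM)\n", sep = "")
  invisible(x)
}

#' Simulate the multi-echo complex signal of a phantom
#'
#' Per voxel, s(TE) = exp(-R2* TE) (rhoW + rhoF sum_k alpha_k
#' exp(-i 2 pi df_k TE)) exp(-i 2 pi dB TE) with rhoW = (1 - ff) m0 and
#' rhoF = ff m0, where dB is the phantom's forward-model field. Independent
#' complex Gaussian noise with per-component sd `noise_sd * max |s|` is added
#' per echo; `bipolar_psi` adds a constant phase offset to the
#' reversed-polarity echoes of a bipolar readout.
#'
#' @param truth a [build_phantom()] result.
#' @param schedule an `echo_schedule`.
#' @param fat a [fat_spectrum()].
#' @param noise_sd noise level (fraction of peak magnitude); `NULL` uses the
#'   spec's value.
#' @param seed RNG seed; `NULL` uses the spec's value.
#' @param bipolar_psi phase offset (radians) applied to polarity -1 echoes.
#' @return an `echo_series`.
#' @export
simulate_signal <- function(truth, schedule, fat = fat_spectrum(truth$B0),
                            noise_sd = NULL, seed = NULL, bipolar_psi = 0) {
  stopifnot(inherits(truth, "phantom_truth"), nrow(schedule) >= 1)
  if (is.null(noise_sd)) noise_sd <- truth$spec$noise_sd
  if (is.null(seed)) seed <- truth$spec$seed
  gs <- dim(truth$chi)
  ne <- nrow(schedule)
  cf <- fat_phasor(fat, schedule$time)
  rho_w <- (1 - truth$fat_fraction) * truth$m0
  rho_f <- truth$fat_fraction * truth$m0
  out <- array(0i, dim = c(gs, ne))
  for (n in seq_len(ne)) {
    te <- schedule$time[n]; te_s <- te * 1e-3
    s <- exp(-truth$r2s * te) * (rho_w + rho_f * cf[n]) *
      exp(-2i * pi * truth$field_hz * te_s)
    if (bipolar_psi != 0 && schedule$polarity[n] < 0)
      s <- s * exp(1i * bipolar_psi)
    out[, , , n] <- s
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    sdv <- noise_sd * max(Mod(out))
    out <- out + array(complex(real = rnorm(length(out), sd = sdv),
                               imaginary = rnorm(length(out), sd = sdv)),
                       dim = dim(out))
  }
  st <- if (length(unique(schedule$source)) > 1L) "merged"
        else schedule$source[1]
  echo_series(out, schedule, truth$voxel_size, truth$B0, series_type = st)
}
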