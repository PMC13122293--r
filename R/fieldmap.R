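# Total-field estimation from the merged IP/OOP echo train.

#' Field map container
#' @param value field volume, Hz.
#' @param mask logical validity mask; the field is zeroed outside it.
#' @param kind "total" or "local".
#' @return a `field_map` object.
#' @export
field_map <- function(value, mask, kind = c("total", "local")) {
  kind <- match.arg(kind)
  value[!mask] <- 0
  if (any(!is.finite(value[mask]))) stop("non-finite field inside mask")
  structure(list(value = value, mask = mask, kind = kind),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  v <- x$value[x$mask]
  cat("<field_map ", x$kind, "> ", sum(x$mask), " voxels, range [",
      signif(min(v), 4), ", ", signif(max(v), 4), "] Hz\n", sep = "")
  invisible(x)
}

#' Rigid translation registration by phase correlation
#'
#' Estimates a 3D subvoxel shift between the first-echo magnitude images
#' (integer peak of the cross-correlation, refined by a weighted least-squares
#' fit to the cross-spectrum phase slope) and applies it by Fourier
#' interpolation to the real and imaginary parts of every echo separately.
#'
#' @param moving,fixed `echo_series` on the same grid.
#' @param peak_threshold minimum normalised correlation peak; below it a
#'   warning is raised and the identity transform is returned.
#' @return the shifted `moving` series, with the estimated shift (voxels) in
#'   attribute `"shift"`.
#' @export
register_translation <- function(moving, fixed, peak_threshold = 0.03) {
  stopifnot(identical(dim(moving$data)[1:3], dim(fixed$data)[1:3]))
  a <- Mod(echo_volume(fixed, 1))
  b <- Mod(echo_volume(moving, 1))
  Fa <- fft3(a); Fb <- fft3(b)
  cross <- Fa * Conj(Fb)
  # regularised whitening: spectral bins with (near-)zero energy carry no
  # shift information and must not be amplified to unit weight
  denom <- Mod(cross) + 1e-3 * max(Mod(cross))
  corr <- Re(ifft3(cross / denom))
  cmax <- max(corr)
  # peak quality relative to a perfectly matched pair (value 1)
  quality <- cmax / mean(Mod(cross) / denom)
  if (quality < peak_threshold) {
    warning("phase-correlation peak below threshold; returning identity")
    out <- moving
    attr(out, "shift") <- c(0, 0, 0)
    return(out)
  }
  # among (near-)tied maxima, prefer the smallest displacement: invariant
  # axes (e.g. a z-uniform phantom) then resolve to zero shift
  d <- dim(a)
  cand <- which(corr >= cmax - 1e-6 * abs(cmax))
  ci <- arrayInd(cand, d) - 1L
  cs <- ifelse(ci > matrix(d, nrow(ci), 3, byrow = TRUE) / 2,
               ci - matrix(d, nrow(ci), 3, byrow = TRUE), ci)
  peak <- cand[which.min(rowSums(cs^2))]
  idx <- as.vector(arrayInd(peak, d)) - 1L
  shift_int <- ifelse(idx > d / 2, idx - d, idx)  # wraparound convention
  # subvoxel refinement: cross-spectrum phase is 2 pi k . shift; fit the
  # residual slope on low frequencies after removing the integer part
  kx <- fft_freq(d[1]); ky <- fft_freq(d[2]); kz <- fft_freq(d[3])
  KX <- array(kx, dim = d)
  KY <- array(rep(ky, each = d[1]), dim = d)
  KZ <- array(rep(kz, each = d[1] * d[2]), dim = d)
  resid <- cross * exp(-2i * pi * (KX * shift_int[1] + KY * shift_int[2] +
                                     KZ * shift_int[3]))
  sel <- abs(KX) < 0.15 & abs(KY) < 0.15 & abs(KZ) < 0.15
  w <- Mod(resid)[sel]
  ang <- Arg(resid)[sel]
  keep <- abs(ang) < 2.5  # guard against wrapped outliers
  M <- cbind(2 * pi * KX[sel], 2 * pi * KY[sel], 2 * pi * KZ[sel])[keep, ,
                                                                  drop = FALSE]
  w <- w[keep]; ang <- ang[keep]
  G <- crossprod(M, M * w)
  rhs <- crossprod(M, ang * w)
  # an axis with no weighted frequency content (e.g. a z-invariant image)
  # carries no shift information; freeze it at the integer estimate
  ident <- diag(G) > 1e-9 * max(diag(G), 1e-300)
  fit <- numeric(3)
  if (any(ident))
    fit[ident] <- as.numeric(solve(G[ident, ident, drop = FALSE],
                                   rhs[ident, , drop = FALSE]))
  fit[!is.finite(fit)] <- 0
  shift <- as.numeric(shift_int + fit)
  out <- series_with_data(moving, apply_fourier_shift(moving$data, shift))
  attr(out, "shift") <- unname(shift)
  out
}

# Shift every echo by `shift` voxels via a Fourier phase ramp, applied to the
# real and imaginary channels separately (avoids phase interpolation).
apply_fourier_shift <- function(data, shift) {
  if (all(abs(shift) < 1e-12)) return(data)
  d <- dim(data)[1:3]
  kx <- fft_freq(d[1]); ky <- fft_freq(d[2]); kz <- fft_freq(d[3])
  KX <- array(kx, dim = d)
  KY <- array(rep(ky, each = d[1]), dim = d)
  KZ <- array(rep(kz, each = d[1] * d[2]), dim = d)
  ramp <- exp(2i * pi * (KX * shift[1] + KY * shift[2] + KZ * shift[3]))
  out <- data
  for (n in seq_len(dim(data)[4])) {
    v <- data[, , , n]
    re <- Re(ifft3(fft3(Re(v)) * ramp))
    im <- Re(ifft3(fft3(Im(v)) * ramp))
    out[, , , n] <- complex(real = re, imaginary = im)
  }
  out
}

#' Correct the alternating phase offset of a bipolar readout
#'
#' Bipolar acquisitions carry a constant phase offset on the reversed-gradient
#' echoes. For each voxel the offset is estimated as half the angle of
#' s_n s_(n+2) / s_(n+1)^2 averaged over interior echo triplets (the quadratic
#' phase term cancels for a linear-in-TE phase), smoothed over a 3x3x3
#' neighbourhood, and removed from the reversed-polarity echoes. Magnitudes
#' are untouched.
#'
#' @param series an `echo_series` with alternating `polarity` signs.
#' @return the corrected `echo_series`, with the estimated offset volume in
#'   attribute `"psi"`.
#' @export
correct_bipolar_offsets <- function(series) {
  ne <- n_echoes(series)
  if (ne < 3) stop("bipolar offset correction needs at least 3 echoes")
  pol <- series$schedule$polarity
  if (length(unique(pol)) < 2)
    stop("schedule has no alternating polarity signs")
  d <- dim(series$data)[1:3]
  acc <- array(0i, dim = d)
  for (n in seq_len(ne - 2L)) {
    x <- slice4(series$data, n) * slice4(series$data, n + 2L) /
      (slice4(series$data, n + 1L)^2)
    x[!is.finite(x)] <- 0i
    u <- x / (Mod(x) + 1e-30)
    # triplet angle is -2 psi when the middle echo carries the offset,
    # +2 psi when the outer echoes do; fold onto a common sign
    if (pol[n + 1L] < 0) u <- Conj(u)
    acc <- acc + u
  }
  acc <- box_smooth3(Re(acc)) + 1i * box_smooth3(Im(acc))
  psi <- Arg(acc) / 2
  corr <- exp(-1i * psi)
  out <- series$data
  for (n in seq_len(ne))
    if (pol[n] < 0) out[, , , n] <- slice4(out, n) * corr
  res <- series_with_data(series, out)
  attr(res, "psi") <- psi
  res
}

# 3x3x3 box smoothing with replicated borders.
box_smooth3 <- function(x) {
  d <- dim(x)
  sh <- function(v, ax, by) {
    i <- pmin(pmax(seq_len(d[ax]) + by, 1L), d[ax])
    switch(ax, v[i, , , drop = FALSE], v[, i, , drop = FALSE],
           v[, , i, drop = FALSE])
  }
  out <- array(0, dim = d); cnt <- 0
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    out <- out + sh(sh(sh(x, 1, dx), 2, dy), 3, dz)
    cnt <- cnt + 1
  }
  out / cnt
}

#' Laplacian phase unwrapping
#'
#' Wrap-insensitive unwrapping: the smooth phase estimate
#' invlap(cos(phi) lap(sin(phi)) - sin(phi) lap(cos(phi))) is computed with
#' FFT-based Laplacian and inverse Laplacian on a mirror-padded grid (DC term
#' zeroed), its additive constant is restored as the circular mean of
#' (wrapped - estimate) over the mask, and the result is snapped to
#' congruence with the input: the estimate only decides the integer 2 pi
#' counts, the fractional phase is kept exactly as measured. Wherever the
#' spectral estimate is within pi of the true phase the output equals the
#' true phase up to one global 2 pi multiple.
#'
#' @param phase wrapped phase volume, radians.
#' @param mask logical volume used for the offset restoration (default: all).
#' @param congruent snap to `phase + 2 pi k`; set `FALSE` for the raw
#'   harmonic-filtered spectral estimate.
#' @return unwrapped phase volume.
#' @export
laplacian_unwrap <- function(phase, mask = NULL, congruent = TRUE) {
  d <- dim(phase)
  s <- mirror_pad(sin(phase))
  c <- mirror_pad(cos(phase))
  L <- laplace_multiplier(dim(s))
  rhs <- c * kspace_filter(s, L) - s * kspace_filter(c, L)
  Linv <- 1 / L
  Linv[1, 1, 1] <- 0  # DC undetermined; fixed by the offset restoration below
  u <- crop_to(kspace_filter(rhs, Linv), d)
  m <- if (is.null(mask)) TRUE else mask
  off <- Arg(mean(exp(1i * (phase - u))[m]))
  u <- u + off
  if (congruent) phase + 2 * pi * round((u - phase) / (2 * pi)) else u
}

#' Total field by the optimum-weights phase combination (no fat model)
#'
#' Successive-echo phase differences are Laplacian-unwrapped and combined as
#' an inverse-variance weighted average of per-pair field rates:
#' dB = sum_n w_n dphi_n / (2 pi dTE_n) / sum_n w_n with
#' w_n = A_n^2 A_(n+1)^2 / (A_n^2 + A_(n+1)^2) from the echo magnitudes
#' (high-SNR phase-noise limit).
#'
#' @param series an `echo_series` (typically the merged 24-echo train) with
#'   bipolar offsets already corrected.
#' @param mask logical volume delimiting where the field is estimated.
#' @return a `field_map` with `kind = "total"`. Voxels with all-zero
#'   magnitude are zeroed and dropped from the mask.
#' @export
fit_field_optimum_weights <- function(series, mask) {
  ne <- n_echoes(series)
  if (ne < 2) stop("need at least 2 echoes")
  te_s <- series$schedule$time * 1e-3
  d <- dim(series$data)[1:3]
  num <- array(0, dim = d); den <- array(0, dim = d)
  for (n in seq_len(ne - 1L)) {
    s1 <- slice4(series$data, n); s2 <- slice4(series$data, n + 1L)
    dphi <- laplacian_unwrap(Arg(s2 * Conj(s1)), mask)
    a1 <- Mod(s1)^2; a2 <- Mod(s2)^2
    w <- a1 * a2 / (a1 + a2)
    w[!is.finite(w)] <- 0
    dte <- te_s[n + 1L] - te_s[n]
    # model phase is exp(-i 2 pi dB TE): positive field advances negatively
    num <- num + w * (-dphi / (2 * pi * dte))
    den <- den + w
  }
  ok <- mask & den > 0
  f <- array(0, dim = d)
  f[ok] <- num[ok] / den[ok]
  field_map(f, ok, "total")
}

#' R2* by auto-regression on linear operations (ARLO)
#'
#' Closed-form R2* from uniformly spaced echo magnitudes y_i:
#' with alpha_i = (delta/3)(y_i + 4 y_(i+1) + y_(i+2)) and
#' beta_i = y_i - y_(i+2) over consecutive triplets,
#' R2* = sum(alpha_i beta_i) / sum(alpha_i^2), clipped at zero. Use a single
#' series (uniform 2.46 ms grid), not the merged train.
#'
#' @param series an `echo_series` with uniform echo spacing.
#' @param mask optional logical volume; outside it R2* is 0.
#' @param skip_first drop the first echo before fitting (the IP series is
#'   only uniform from its second echo).
#' @return R2* volume, 1/ms.
#' @export
arlo_r2star <- function(series, mask = NULL, skip_first = FALSE) {
  te <- series$schedule$time
  mag <- Mod(series$data)
  if (skip_first) {
    te <- te[-1]
    mag <- mag[, , , -1, drop = FALSE]
  }
  ne <- length(te)
  if (ne < 3) stop("ARLO needs at least 3 echoes")
  dt <- diff(te)
  if (max(dt) - min(dt) > 1e-3)
    stop("ARLO requires uniform echo spacing (got ",
         paste(signif(range(dt), 4), collapse = "-"), " ms)")
  delta <- mean(dt)
  d <- dim(mag)[1:3]
  sab <- array(0, dim = d); saa <- array(0, dim = d)
  for (i in seq_len(ne - 2L)) {
    y0 <- slice4(mag, i); y1 <- slice4(mag, i + 1L); y2 <- slice4(mag, i + 2L)
    al <- (delta / 3) * (y0 + 4 * y1 + y2)
    be <- y0 - y2
    sab <- sab + al * be
    saa <- saa + al * al
  }
  r2s <- array(0, dim = d)
  ok <- saa > 0
  r2s[ok] <- pmax(0, sab[ok] / saa[ok])
  if (!is.null(mask)) r2s[!mask] <- 0
  r2s
}

#' Two-point Dixon water/fat initialisation
#'
#' Uses the first IP echo (PIP accepted) and the first OOP echo. Magnitudes
#' are compensated for R2* decay between the two echo times, then the
#' water/fat pair is recovered from the in-phase magnitude and the
#' phase-corrected signed out-of-phase amplitude: the water phase at the OOP
#' time is predicted by linear interpolation of the IP phase evolution, so
#' fat-dominant voxels (negative signed OOP amplitude) resolve to fat
#' fractions above one half. The common phase is taken from the IP echo.
#'
#' @param ip,oop registered, offset-corrected `echo_series`.
#' @param r2s R2* volume (1/ms) for decay compensation; 0 disables it.
#' @return a `water_fat_pair`: complex `rho_w`, `rho_f` and `fat_fraction`
#'   = |rho_f| / (|rho_w| + |rho_f|).
#' @export
dixon_init <- function(ip, oop, r2s = 0) {
  if (missing(ip) || missing(oop) || is.null(ip) || is.null(oop))
    stop("both IP and OOP series are required")
  te_ip1 <- ip$schedule$time[1]
  te_oop <- oop$schedule$time[1]
  s_ip1 <- echo_volume(ip, 1)
  s_oop <- echo_volume(oop, 1)
  a <- Mod(s_ip1) * exp(r2s * te_ip1)
  # predicted water phase at the OOP time from the first two IP echoes
  if (n_echoes(ip) >= 2) {
    te_ip2 <- ip$schedule$time[2]
    dphi <- Arg(echo_volume(ip, 2) * Conj(s_ip1))
    frac <- (te_oop - te_ip1) / (te_ip2 - te_ip1)
    phi_pred <- Arg(s_ip1) + dphi * frac
  } else {
    phi_pred <- Arg(s_ip1)
  }
  b_signed <- Re(s_oop * exp(-1i * phi_pred)) * exp(r2s * te_oop)
  w <- (a + b_signed) / 2
  f <- (a - b_signed) / 2
  # numerical guard: tiny negatives from noise
  w <- pmax(w, 0); f <- pmax(f, 0)
  tot <- w + f
  ff <- array(0, dim = dim(a))
  ok <- tot > 0
  ff[ok] <- f[ok] / tot[ok]
  phase <- exp(1i * Arg(s_ip1))
  structure(list(rho_w = w * phase, rho_f = f * phase, fat_fraction = ff),
            class = "water_fat_pair")
}

#' Per-echo SNR weights from the phase-image noise floor
#'
#' SNR_n = mean in-mask magnitude / (1.526 x raw median absolute deviation of
#' the magnitude in the noise region); weights are SNR_n^2, normalised to sum
#' to one.
#'
#' @param series an `echo_series`.
#' @param mask cord mask.
#' @param noise_region background region disjoint from `mask`.
#' @return numeric weight vector (one per echo, summing to 1).
#' @export
compute_echo_weights <- function(series, mask, noise_region) {
  if (any(mask & noise_region)) stop("noise region overlaps the mask")
  ne <- n_echoes(series)
  if (sum(noise_region) == 0) {
    warning("empty noise region; falling back to uniform weights")
    return(rep(1 / ne, ne))
  }
  snr <- vapply(seq_len(ne), function(n) {
    m <- Mod(slice4(series$data, n))
    sigma <- 1.526 * stats::mad(m[noise_region], constant = 1)
    if (sigma <= 0) return(Inf)
    mean(m[mask]) / sigma
  }, numeric(1))
  if (any(!is.finite(snr))) {
    warning("degenerate noise region (zero spread); uniform weights")
    return(rep(1 / ne, ne))
  }
  w <- snr^2
  w / sum(w)
}
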