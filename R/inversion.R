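# Morphology-enabled dipole inversion (MEDI): L1-regularised field-to-
# susceptibility inversion with an anatomical edge mask, solved by
# iteratively reweighted least squares with inner conjugate-gradient solves,
# followed by global-mean referencing.

#' Anatomical image as the l2 norm of all echo magnitudes
#'
#' @param ip an `echo_series` (IP, or already-merged train).
#' @param oop optional second series (OOP); when given, the norm runs over
#'   the magnitudes of both series' echoes.
#' @return real 3D volume.
#' @export
build_anatomical <- function(ip, oop = NULL) {
  ss <- apply(Mod(ip$data)^2, 1:3, sum)
  if (!is.null(oop)) ss <- ss + apply(Mod(oop$data)^2, 1:3, sum)
  sqrt(ss)
}

# Forward differences with Neumann (replicated) boundary, and their adjoint.
grad_fd <- function(x, axis) {
  d <- dim(x)
  i <- seq_len(d[axis])
  ip1 <- pmin(i + 1L, d[axis])
  switch(axis,
         x[ip1, , , drop = FALSE] - x,
         x[, ip1, , drop = FALSE] - x,
         x[, , ip1, drop = FALSE] - x)
}

grad_fd_adj <- function(g, axis) {
  # exact adjoint of grad_fd: (G^T g)_1 = -g_1, (G^T g)_j = g_(j-1) - g_j
  # for 1 < j < n, (G^T g)_n = g_(n-1). Computed as shift-down-with-zero
  # minus g, plus g_n restored on the last slice.
  d <- dim(g)
  n <- d[axis]
  sd0 <- array(0, dim = d)
  if (n >= 2L) {
    if (axis == 1) sd0[2:n, , ] <- g[1:(n - 1L), , ]
    else if (axis == 2) sd0[, 2:n, ] <- g[, 1:(n - 1L), ]
    else sd0[, , 2:n] <- g[, , 1:(n - 1L)]
  }
  out <- sd0 - g
  if (axis == 1) out[n, , ] <- out[n, , ] + g[n, , ]
  else if (axis == 2) out[, n, ] <- out[, n, ] + g[, n, ]
  else out[, , n] <- out[, , n] + g[, , n]
  out
}

#' Gradient-domain edge mask from an anatomical image
#'
#' Per gradient direction, voxels whose anatomical gradient magnitude lies
#' below the `keep_fraction` quantile (within the mask) are marked 1 and are
#' smoothness-regularised; strong anatomical edges are marked 0 and left
#' free, so susceptibility boundaries can follow anatomy.
#'
#' @param anatomical real volume (see [build_anatomical()]).
#' @param mask region over which the quantile is taken.
#' @param keep_fraction fraction of in-mask gradients to regularise,
#'   in (0, 1).
#' @return list of three binary volumes (x, y, z gradient directions).
#' @export
edge_mask <- function(anatomical, mask, keep_fraction = 0.7) {
  stopifnot(keep_fraction > 0, keep_fraction < 1)
  lapply(1:3, function(ax) {
    g <- abs(grad_fd(anatomical, ax))
    thr <- stats::quantile(g[mask], keep_fraction, names = FALSE)
    m <- array(1, dim = dim(anatomical))
    m[g > thr] <- 0
    m
  })
}

#' MEDI dipole inversion
#'
#' Solves chi = argmin lambda ||M_G grad chi||_1 + ||W (f_local - D*chi)||_2^2
#' by IRLS: the l1 term is smoothed as sqrt(t^2 + eps^2) and reweighted each
#' outer iteration; each subproblem is solved by conjugate gradient. The
#' field is normalised to its in-mask maximum before inversion and the result
#' converted to ppb.
#'
#' @param local a `field_map` with `kind = "local"` (Hz).
#' @param weights data-fidelity weight volume; default 1.
#' @param edge edge-mask list from [edge_mask()]; default all-ones.
#' @param kernel optional [dipole_kernel()] for geometry.
#' @param lambda regularisation parameter (> 0), on the normalised-field
#'   scale.
#' @param B0 Tesla (Hz-to-ppb conversion).
#' @param voxel_size,b0_direction geometry when `kernel` is `NULL`.
#' @param eps l1 smoothing parameter.
#' @param outer_max maximum IRLS iterations.
#' @param outer_tol relative-update stopping tolerance.
#' @param cg_max,cg_tol inner CG controls.
#' @param pad_factor dipole-convolution padding.
#' @return a `susceptibility_map`: `value` (ppb), `mask`, `reference`
#'   ("none" until [reference_map()]), `lambda_used`; attribute `objective`
#'   holds the per-outer-iteration objective values.
#' @export
medi_invert <- function(local, weights = NULL, edge = NULL, kernel = NULL,
                        lambda = 1e-3, B0 = 3,
                        voxel_size = c(0.4, 0.4, 1),
                        b0_direction = c(0, 0, 1),
                        eps = 1e-6, outer_max = 10L, outer_tol = 1e-2,
                        cg_max = 50L, cg_tol = 1e-3, pad_factor = 2) {
  stopifnot(inherits(local, "field_map"))
  if (local$kind != "local") stop("medi_invert expects a local field")
  if (lambda <= 0) stop("lambda must be positive")
  d <- dim(local$value)
  if (!is.null(kernel)) {
    voxel_size <- kernel$voxel_size
    b0_direction <- kernel$b0_direction
  }
  conv <- make_dipole_conv(d, voxel_size, b0_direction, pad_factor)
  W2 <- if (is.null(weights)) array(1, dim = d) else weights^2
  if (is.null(edge)) edge <- lapply(1:3, function(i) array(1, dim = d))

  fmax <- max(abs(local$value))
  if (fmax == 0) {
    out <- structure(list(value = array(0, dim = d), mask = local$mask,
                          reference = "none", lambda_used = lambda),
                     class = "susceptibility_map")
    attr(out, "objective") <- 0
    return(out)
  }
  f <- local$value / fmax

  smooth_abs <- function(t) sqrt(t * t + eps^2)
  objective <- function(u) {
    reg <- 0
    for (ax in 1:3) reg <- reg + sum(smooth_abs(edge[[ax]] * grad_fd(u, ax)))
    lambda * reg + sum(W2 * (f - conv(u))^2)
  }

  u <- array(0, dim = d)
  obj <- objective(u)
  for (outer in seq_len(outer_max)) {
    Rw <- lapply(1:3, function(ax)
      edge[[ax]] / smooth_abs(edge[[ax]] * grad_fd(u, ax)))
    Aop <- function(x) {
      y <- 2 * conv(W2 * conv(x))
      for (ax in 1:3)
        y <- y + lambda * grad_fd_adj(Rw[[ax]] * edge[[ax]] * grad_fd(x, ax),
                                      ax)
      y
    }
    b <- 2 * conv(W2 * f)
    # CG from warm start
    r <- b - Aop(u)
    p <- r
    rs <- sum(r * r)
    rs0 <- rs
    u_new <- u
    for (k in seq_len(cg_max)) {
      if (sqrt(rs / rs0) < cg_tol || rs == 0) break
      Ap <- Aop(p)
      alpha <- rs / sum(p * Ap)
      if (!is.finite(alpha)) break
      u_new <- u_new + alpha * p
      r <- r - alpha * Ap
      rs_new <- sum(r * r)
      p <- r + (rs_new / rs) * p
      rs <- rs_new
    }
    upd <- sqrt(sum((u_new - u)^2)) / max(sqrt(sum(u^2)), 1e-300)
    u <- u_new
    obj <- c(obj, objective(u))
    if (upd < outer_tol) break
  }

  chi_ppb <- u * fmax / (larmor_hz(B0) * 1e-9)
  out <- structure(list(value = chi_ppb, mask = local$mask,
                        reference = "none", lambda_used = lambda),
                   class = "susceptibility_map")
  attr(out, "objective") <- obj
  out
}

#' Reference a susceptibility map to its global mask mean
#'
#' Subtracts the mean susceptibility over the mask, fixing the inversion's
#' undetermined offset; the map mean over the mask is exactly 0 afterwards.
#'
#' @param chi a `susceptibility_map`.
#' @param mask logical volume; default the map's own mask.
#' @return the referenced `susceptibility_map`.
#' @export
reference_map <- function(chi, mask = chi$mask) {
  if (sum(mask) == 0) stop("mask is empty")
  chi$value <- chi$value - mean(chi$value[mask])
  chi$reference <- "global_mean"
  chi
}

#' @export
print.susceptibility_map <- function(x, ...) {
  v <- x$value[x$mask]
  cat("<susceptibility_map> ", sum(x$mask), " voxels, mean ",
      signif(mean(v), 3), " ppb, ref = ", x$reference, "\n", sep = "")
  invisible(x)
}
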