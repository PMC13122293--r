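# R2*-IDEAL: joint fat-water separation and field fitting on the merged
# 24-echo grid by variable projection. For fixed (dB, R2*) the complex water
# and fat amplitudes are linear and solved in closed form per voxel; the two
# nonlinear parameters are updated by a damped (Levenberg-Marquardt)
# Gauss-Newton step with R2* >= 0 enforced. All voxels in the mask are
# iterated simultaneously as flat vectors.

#' Fit the R2*-IDEAL fat-water model
#'
#' Minimises, per voxel, sum_n w_n | s(TE_n) - exp(-R2* TE_n)
#' (rhoW + rhoF sum_k alpha_k exp(-i 2 pi df_k TE_n)) exp(-i 2 pi dB TE_n) |^2.
#' The per-echo phase is first unwrapped with the Laplacian method (the
#' magnitude is kept as-is), matching the pipeline's sequential
#' unwrap-then-fit treatment.
#'
#' @param series merged `echo_series` (registered, offset-corrected).
#' @param fat a [fat_spectrum()].
#' @param weights per-echo weights (from [compute_echo_weights()]); `NULL`
#'   for uniform.
#' @param init list with optional entries `field0` (Hz volume or `field_map`;
#'   default the null field map), `r2s0` (1/ms volume; default ARLO-style
#'   0.02 everywhere). Water/fat amplitudes need no initial value: variable
#'   projection recomputes them in closed form at every step.
#' @param mask logical volume of voxels to fit.
#' @param unwrap pre-unwrap the echo phases (default TRUE).
#' @param tol relative cost-change convergence tolerance.
#' @param max_iter maximum outer iterations.
#' @return list with `field` (a `field_map`), `r2s` (1/ms volume), `wf` (a
#'   `water_fat_pair`), `converged` (logical volume), `iterations`,
#'   `cost_trace` (mean in-mask cost per iteration).
#' @export
ideal_fit <- function(series, fat = fat_spectrum(series$B0), weights = NULL,
                      init = list(), mask, unwrap = TRUE,
                      tol = 1e-8, max_iter = 50L) {
  d <- dim(series$data)[1:3]
  ne <- n_echoes(series)
  te_ms <- series$schedule$time
  te_s <- te_ms * 1e-3
  w <- if (is.null(weights)) rep(1 / ne, ne) else weights / sum(weights)
  cf <- fat_phasor(fat, te_ms)

  # drop zero-signal voxels: nothing to fit there
  mag_sum <- apply(Mod(series$data), 1:3, sum)
  fit_mask <- mask & mag_sum > 0

  data <- series$data
  if (unwrap) {
    for (n in seq_len(ne)) {
      v <- slice4(data, n)
      phi <- laplacian_unwrap(Arg(v), fit_mask)
      data[, , , n] <- complex(modulus = Mod(v), argument = phi)
    }
  }

  vix <- which(fit_mask)
  nv <- length(vix)
  if (nv == 0) stop("empty fit mask")
  S <- matrix(0i, nv, ne)
  for (n in seq_len(ne)) S[, n] <- slice4(data, n)[vix]

  f0 <- init$field0
  if (inherits(f0, "field_map")) f0 <- f0$value
  dB <- if (is.null(f0)) numeric(nv) else as.numeric(f0[vix])
  r0 <- init$r2s0
  r2s <- if (is.null(r0)) rep(0.02, nv) else pmax(0, as.numeric(r0[vix]))

  TEs <- matrix(te_s, nv, ne, byrow = TRUE)
  TEms <- matrix(te_ms, nv, ne, byrow = TRUE)
  W <- matrix(w, nv, ne, byrow = TRUE)
  CF <- matrix(cf, nv, ne, byrow = TRUE)
  cf_abs2 <- matrix(Mod(cf)^2, nv, ne, byrow = TRUE)

  # closed-form water/fat amplitudes and cost for given (dB, r2s)
  eval_state <- function(dB, r2s) {
    E <- exp(-r2s * TEms)                      # nv x ne, real
    P <- exp(-2i * pi * dB * TEs)              # nv x ne
    E2 <- E * E
    g11 <- rowSums(W * E2)
    g22 <- rowSums(W * E2 * cf_abs2)
    g12 <- rowSums(W * E2 * CF)                # conj(b1) b2, phase cancels
    B1 <- E * P
    r1 <- rowSums(W * Conj(B1) * S)
    r2 <- rowSums(W * Conj(B1 * CF) * S)
    det <- g11 * g22 - Mod(g12)^2
    bad <- det < 1e-14 * pmax(g11 * g22, 1e-300)
    rw <- (g22 * r1 - g12 * r2) / det
    rf <- (g11 * r2 - Conj(g12) * r1) / det
    rw[bad] <- (r1 / g11)[bad]
    rf[bad] <- 0i
    Mdl <- B1 * (rw + rf * CF)
    Rres <- S - Mdl
    cost <- rowSums(W * Mod(Rres)^2)
    list(rw = rw, rf = rf, M = Mdl, R = Rres, cost = cost)
  }

  st <- eval_state(dB, r2s)
  cost <- st$cost
  cost_floor <- 1e-22 * rowSums(W * Mod(S)^2)  # numerically perfect fit
  lam <- rep(1e-2, nv)
  active <- cost > cost_floor
  trace <- mean(cost)
  iter <- 0L
  while (any(active) && iter < max_iter) {
    iter <- iter + 1L
    Mabs2 <- Mod(st$M)^2
    MR <- Conj(st$M) * st$R
    h11 <- 2 * rowSums(W * (2 * pi * TEs)^2 * Mabs2)
    h22 <- 2 * rowSums(W * TEms^2 * Mabs2)
    g1 <- 2 * rowSums(W * 2 * pi * TEs * Im(MR))
    g2 <- 2 * rowSums(W * TEms * Re(MR))
    step1 <- -g1 / (h11 * (1 + lam) + 1e-300)
    step2 <- -g2 / (h22 * (1 + lam) + 1e-300)
    step1[!is.finite(step1)] <- 0
    step2[!is.finite(step2)] <- 0
    dB_try <- dB + ifelse(active, step1, 0)
    r2s_try <- pmax(0, r2s + ifelse(active, step2, 0))
    st_try <- eval_state(dB_try, r2s_try)
    accept <- active & st_try$cost <= cost
    if (any(accept)) {
      dB[accept] <- dB_try[accept]
      r2s[accept] <- r2s_try[accept]
      rel <- abs(cost[accept] - st_try$cost[accept]) /
        pmax(cost[accept], 1e-300)
      done <- accept
      done[accept] <- rel < tol
      active[done] <- FALSE
      active[accept & st_try$cost <= cost_floor] <- FALSE
      cost[accept] <- st_try$cost[accept]
      st$M[accept, ] <- st_try$M[accept, , drop = FALSE]
      st$R[accept, ] <- st_try$R[accept, , drop = FALSE]
      st$rw[accept] <- st_try$rw[accept]
      st$rf[accept] <- st_try$rf[accept]
      lam[accept] <- pmax(lam[accept] / 3, 1e-10)
    }
    rejected <- active & !accept
    lam[rejected] <- pmin(lam[rejected] * 5, 1e10)
    # voxels whose damping explodes have stalled at a (local) optimum
    active[lam >= 1e10] <- FALSE
    trace <- c(trace, mean(cost))
  }

  to_vol <- function(v, fill = 0) {
    out <- array(fill, dim = d); out[vix] <- v; out
  }
  fmap <- field_map(to_vol(dB), fit_mask, "total")
  ffv <- Mod(st$rf) / (Mod(st$rw) + Mod(st$rf) + 1e-300)
  wf <- structure(list(rho_w = to_vol(st$rw, 0i), rho_f = to_vol(st$rf, 0i),
                       fat_fraction = to_vol(ffv)),
                  class = "water_fat_pair")
  list(field = fmap, r2s = to_vol(r2s), wf = wf,
       converged = to_vol(!active, FALSE) & fit_mask,
       iterations = iter, cost_trace = trace)
}
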