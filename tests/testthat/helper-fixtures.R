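# Shared fixtures: all test inputs are generated in code.

# A tiny grid with spatially uniform tissue parameters (every voxel is cord
# tissue) and a prescribed uniform field: ideal for closed-form checks.
uniform_phantom <- function(field_hz = 5, r2s = 0, ff = 0,
                            grid = c(4L, 4L, 2L)) {
  sp <- phantom_spec(
    grid_shape = grid,
    tissue_chi = c(CSF = 0, WM = 0, GM = 0, bone = 0),
    tissue_r2s = c(CSF = r2s, WM = r2s, GM = r2s, bone = r2s),
    tissue_fat_fraction = c(CSF = ff, WM = ff, GM = ff, bone = ff),
    tissue_m0 = c(CSF = 1, WM = 1, GM = 1, bone = 1),
    cord_radius = 1e3, csf_radius = 1e3 + 1, vertebra_radius = 1e-2,
    vertebra_center = c(500, 500), noise_sd = 0)
  ph <- build_phantom(sp)
  ph$field_hz[] <- field_hz
  ph
}

# Default-geometry phantom at reduced size for unit tests (the cord still
# fits; the vertebral body is partly clipped, which is fine for field tests).
small_phantom <- function(..., grid = c(32L, 32L, 8L)) {
  build_phantom(phantom_spec(grid_shape = grid, ...))
}

# The acquisition's IP/OOP schedule pair.
protocol_schedules <- function() {
  p <- default_protocols()
  list(ip = build_schedule(p$ip), oop = build_schedule(p$oop))
}

# Single-peak fat model whose beat period equals the 2.46 ms in-phase
# spacing: IP/OOP echo times are exactly in/out of phase.
fat_1peak <- function() fat_spectrum(model = "1peak")

# numpy-style 1D phase unwrapping (path following along a vector).
unwrap_1d <- function(v) {
  if (length(v) < 2) return(v)
  v[1] + c(0, cumsum(Arg(exp(1i * diff(v)))))
}

# Path-following 3D unwrap oracle: z-spine at (1,1), then y-lines, then
# x-lines, each anchored on the previously unwrapped value.
path_unwrap <- function(w) {
  d <- dim(w)
  u <- w
  u[1, 1, ] <- unwrap_1d(w[1, 1, ])
  for (k in seq_len(d[3])) {
    u[1, , k] <- unwrap_1d(c(u[1, 1, k], w[1, -1, k]))
    for (j in seq_len(d[2]))
      u[, j, k] <- unwrap_1d(c(u[1, j, k], w[-1, j, k]))
  }
  u
}

# Brute-force two-parameter exponential fit y ~ A exp(-r t): profiles the
# amplitude in closed form and optimises the rate in 1D.
brute_force_expfit <- function(y, t, interval = c(0, 0.5)) {
  sse <- function(r) {
    e <- exp(-r * t)
    a <- sum(y * e) / sum(e * e)
    sum((y - a * e)^2)
  }
  stats::optimize(sse, interval, tol = 1e-10)$minimum
}

expect_all_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)), tol)
}
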