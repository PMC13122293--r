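# Field-estimation building blocks: registration, bipolar offsets,
# unwrapping, optimum weights, ARLO, Dixon, echo weights.

noiseless_pair <- function(grid = c(64L, 64L, 16L)) {
  ph <- build_phantom(phantom_spec(grid_shape = grid, noise_sd = 0))
  s <- protocol_schedules()
  list(ph = ph,
       ip = simulate_signal(ph, s$ip, noise_sd = 0),
       oop = simulate_signal(ph, s$oop, noise_sd = 0))
}

test_that("translation registration recovers a known subvoxel shift", {
  px <- noiseless_pair()
  shifted <- scqsm:::series_with_data(
    px$ip, scqsm:::apply_fourier_shift(px$ip$data, c(1.2, -0.8, 0)))
  reg <- register_translation(shifted, px$ip)
  expect_all_equal(attr(reg, "shift"), c(-1.2, 0.8, 0), 0.1)
  ident <- register_translation(px$ip, px$ip)
  expect_equal(attr(ident, "shift"), c(0, 0, 0))
})

test_that("registration is magnitude-driven: phase differences give zero
           shift", {
  px <- noiseless_pair(grid = c(32L, 32L, 8L))
  ph2 <- px$ip
  ph2$data <- ph2$data * exp(1i * 0.8)  # same magnitude, different phase
  reg <- register_translation(ph2, px$ip)
  expect_equal(attr(reg, "shift"), c(0, 0, 0))
})

test_that("bipolar offset correction removes an alternating phase term", {
  # fat-free phantom: the echo-triplet curvature is then exactly zero and
  # the estimator is unbiased everywhere
  ph <- build_phantom(phantom_spec(
    grid_shape = c(32L, 32L, 8L),
    tissue_fat_fraction = c(CSF = 0, WM = 0, GM = 0, bone = 0),
    noise_sd = 0))
  s <- protocol_schedules()
  clean <- simulate_signal(ph, s$oop, noise_sd = 0)
  off <- simulate_signal(ph, s$oop, noise_sd = 0, bipolar_psi = 0.3)
  fixed <- correct_bipolar_offsets(off)
  m <- ph$masks$cord
  resid <- Arg(fixed$data * Conj(clean$data))
  for (i in 1:4) expect_lt(max(abs(resid[, , , i][m])), 0.01)
  # magnitudes untouched (phase-only correction)
  expect_equal(Mod(fixed$data), Mod(off$data), tolerance = 1e-14)
  # null offset: output equals input to numerical precision
  same <- correct_bipolar_offsets(clean)
  expect_all_equal(Mod(same$data - clean$data), 0, 1e-9)
  one_echo <- simulate_signal(
    ph, build_schedule(acquisition_protocol("OOP", TE1 = 3.69,
                                            n_echoes = 2)), noise_sd = 0)
  expect_error(correct_bipolar_offsets(one_echo), "at least 3")
})

test_that("Laplacian unwrapping matches a path-following oracle", {
  d <- c(48L, 48L, 24L)
  co <- function(n) seq_len(n) - (n + 1) / 2
  X <- array(co(48), d)
  Y <- array(rep(co(48), each = 48), d)
  Z <- array(rep(co(24), each = 48 * 48), d)
  phi <- 6 * pi * exp(-(X^2 + Y^2 + (2 * Z)^2) / (2 * 10^2))
  w <- Arg(exp(1i * phi))
  u <- laplacian_unwrap(w)
  o <- path_unwrap(w)
  interior <- abs(X) < 16 & abs(Y) < 16 & abs(Z) < 8
  dev <- (u - o)[interior]
  expect_lt(max(abs(dev - 2 * pi * round(mean(dev) / (2 * pi)))), 0.05)
})

test_that("unwrapping is exact for constant and smooth inputs", {
  w <- array(1.2, dim = c(8, 8, 4))
  expect_all_equal(laplacian_unwrap(w), 1.2, 1e-9)
  # idempotence: already-unwrapped smooth phase comes back unchanged up to
  # a constant
  d <- c(32L, 32L, 8L)
  co <- function(n) seq_len(n) - (n + 1) / 2
  X <- array(co(32), d); Y <- array(rep(co(32), each = 32), d)
  phi <- 2 * exp(-(X^2 + Y^2) / 60)
  u1 <- laplacian_unwrap(phi)
  expect_lt(stats::sd(u1 - phi), 1e-9)
  # adding 2 pi to the input changes the output by a constant only
  u2 <- laplacian_unwrap(phi + 2 * pi)
  expect_lt(stats::sd(u2 - u1), 1e-9)
})

test_that("optimum weights recover a uniform field exactly without noise", {
  ph <- uniform_phantom(field_hz = 10, r2s = 0.03, grid = c(8L, 8L, 4L))
  s <- protocol_schedules()
  merged <- merge_echo_series(simulate_signal(ph, s$ip, noise_sd = 0),
                              simulate_signal(ph, s$oop, noise_sd = 0))
  mask <- array(TRUE, dim = c(8, 8, 4))
  fm <- fit_field_optimum_weights(merged, mask)
  expect_all_equal(fm$value, 10, 1e-6)
  ph0 <- uniform_phantom(field_hz = 0, grid = c(8L, 8L, 4L))
  m0 <- merge_echo_series(simulate_signal(ph0, s$ip, noise_sd = 0),
                          simulate_signal(ph0, s$oop, noise_sd = 0))
  expect_all_equal(fit_field_optimum_weights(m0, mask)$value, 0, 1e-9)
})

test_that("two equal-magnitude echoes reduce to the phase-difference rate", {
  sched <- build_schedule(acquisition_protocol("OOP", TE1 = 3, dTE = 2,
                                               n_echoes = 2))
  d <- c(4L, 4L, 2L)
  phi1 <- array(0.3, dim = d); phi2 <- array(-0.2, dim = d)
  data <- array(0i, dim = c(d, 2))
  data[, , , 1] <- exp(1i * phi1)
  data[, , , 2] <- exp(1i * phi2)
  ser <- echo_series(data, sched)
  fm <- fit_field_optimum_weights(ser, array(TRUE, d))
  expect_all_equal(fm$value, -(-0.2 - 0.3) / (2 * pi * 2e-3), 1e-9)
})

test_that("zero-magnitude voxels are dropped from the field mask", {
  sched <- build_schedule(acquisition_protocol("OOP", TE1 = 3, dTE = 2,
                                               n_echoes = 2))
  d <- c(4L, 4L, 1L)
  data <- array(1 + 0i, dim = c(d, 2))
  data[1, 1, 1, ] <- 0
  fm <- fit_field_optimum_weights(echo_series(data, sched), array(TRUE, d))
  expect_false(fm$mask[1, 1, 1])
  expect_equal(fm$value[1, 1, 1], 0)
  expect_true(all(is.finite(fm$value)))
})

test_that("ARLO matches the closed form and a brute-force fit", {
  sched <- build_schedule(acquisition_protocol("OOP", TE1 = 2.46,
                                               n_echoes = 12))
  te <- sched$time
  d <- c(3L, 3L, 1L)
  data <- array(0i, dim = c(d, 12))
  for (i in 1:12) data[, , , i] <- exp(-0.05 * te[i])
  ser <- echo_series(data, sched)
  r2s <- arlo_r2star(ser)
  expect_all_equal(r2s, 0.05, 1e-3)
  oracle <- brute_force_expfit(exp(-0.05 * te), te)
  expect_equal(oracle, 0.05, tolerance = 1e-6)
  # constant magnitude -> zero rate; doubling magnitudes changes nothing
  flat <- echo_series(array(2 + 0i, dim = c(d, 12)), sched)
  expect_all_equal(arlo_r2star(flat), 0, 1e-12)
  expect_identical(arlo_r2star(ser), arlo_r2star(
    echo_series(2 * data, sched)))
})

test_that("ARLO refuses non-uniform spacing but accepts skip_first", {
  s <- protocol_schedules()
  ph <- uniform_phantom(field_hz = 0, r2s = 0.04, grid = c(3L, 3L, 1L))
  ip <- simulate_signal(ph, s$ip, noise_sd = 0)
  expect_error(arlo_r2star(ip), "uniform")
  expect_all_equal(arlo_r2star(ip, skip_first = TRUE), 0.04, 1e-3)
})

test_that("two-point Dixon separates water and fat at exact IP/OOP times", {
  prot_ip <- acquisition_protocol("IP", TE1 = 2.46, n_echoes = 3)
  prot_oop <- acquisition_protocol("OOP", TE1 = 3.69, n_echoes = 3)
  fat <- fat_1peak()
  run <- function(ffv, r2sv = 0, comp = 0) {
    ph <- uniform_phantom(field_hz = 5, r2s = r2sv, ff = ffv)
    ip <- simulate_signal(ph, build_schedule(prot_ip), fat = fat,
                          noise_sd = 0)
    oop <- simulate_signal(ph, build_schedule(prot_oop), fat = fat,
                           noise_sd = 0)
    dixon_init(ip, oop, r2s = comp)$fat_fraction
  }
  expect_all_equal(run(0.4), 0.4, 1e-6)
  expect_all_equal(run(0), 0, 1e-6)
  expect_all_equal(run(1), 1, 1e-6)
  # R2* decay compensated through the ARLO map
  ph <- uniform_phantom(field_hz = 5, r2s = 0.05, ff = 0)
  oop <- simulate_signal(ph, build_schedule(prot_oop), fat = fat,
                         noise_sd = 0)
  expect_all_equal(run(0, r2sv = 0.05, comp = arlo_r2star(oop)), 0, 1e-4)
  expect_error(dixon_init(NULL, oop), "required")
})

test_that("echo weights follow the per-echo SNR and sum to one", {
  # deterministic decay + identical noise-floor pattern per echo: the SNR
  # profile, and hence the weights, must decrease strictly with TE
  sched <- build_schedule(acquisition_protocol("OOP", TE1 = 3.69,
                                               n_echoes = 8))
  d <- c(8L, 8L, 2L)
  mask <- array(FALSE, d); mask[5:8, 5:8, ] <- TRUE
  noise_box <- array(FALSE, d); noise_box[1:3, 1:3, ] <- TRUE
  data <- array(0i, dim = c(d, 8))
  floor_pattern <- array(0, d)
  floor_pattern[noise_box] <- rep(c(-0.01, 0.004, 0.011), length.out =
                                    sum(noise_box))
  for (n in 1:8) {
    v <- array(0, d)
    v[mask] <- exp(-0.05 * sched$time[n])
    v <- v + floor_pattern
    data[, , , n] <- v
  }
  ser <- echo_series(data, sched)
  w <- compute_echo_weights(ser, mask, noise_box)
  expect_equal(sum(w), 1)
  expect_true(all(diff(w) < 0))
  # identical echoes: uniform weights
  flat <- echo_series(array(1 + 0i, dim = c(8, 8, 2, 4)),
                      build_schedule(acquisition_protocol("OOP", TE1 = 3.69,
                                                          n_echoes = 4)))
  noise_box <- array(FALSE, c(8, 8, 2)); noise_box[1:2, 1:2, ] <- TRUE
  msk <- array(FALSE, c(8, 8, 2)); msk[5:8, 5:8, ] <- TRUE
  expect_warning(wu <- compute_echo_weights(flat, msk, noise_box),
                 "degenerate|uniform")
  expect_equal(wu, rep(0.25, 4))
  expect_warning(we <- compute_echo_weights(flat, msk, array(FALSE, c(8, 8, 2))),
                 "empty noise region")
  expect_equal(we, rep(0.25, 4))
  expect_error(compute_echo_weights(flat, msk, msk), "overlaps")
})
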