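mk_set <- function(data, t, role, layout = NULL, pulse = NULL) {
  structure(list(data = data, t = t, role = role, layout = layout,
                 pulse = pulse, meta = list()), class = "imtr_signalset")
}

rand_cube <- function(n, nt, seed) {
  set.seed(seed)
  array(rnorm(n * n * nt), dim = c(n, n, nt))
}

test_that("calibration subtracts the background channel-wise", {
  nt <- 64; t <- (0:(nt - 1)) * 1e-11
  tot <- mk_set(rand_cube(3, nt, 1), t, "total")
  bg <- mk_set(rand_cube(3, nt, 2), t, "background")

  # self-subtraction and identity
  e0 <- calibrate(tot, tot, detrend = FALSE)
  expect_true(all(e0$data == 0))
  zero <- mk_set(array(0, dim = c(3, 3, nt)), t, "background")
  expect_equal(calibrate(tot, zero, channels = "all", detrend = FALSE)$data[1, ],
               tot$data[1, 1, ])

  # elementwise oracle on every selected channel
  e3 <- calibrate(tot, bg, channels = "all", detrend = FALSE)
  for (k in seq_len(nrow(e3$channels)))
    expect_equal(e3$data[k, ],
                 tot$data[e3$channels$tx[k], e3$channels$rx[k], ] -
                   bg$data[e3$channels$tx[k], e3$channels$rx[k], ])

  # channel selections
  expect_identical(nrow(calibrate(tot, bg, "upper", detrend = FALSE)$data), 3L)
  expect_identical(nrow(calibrate(tot, bg, "all", detrend = FALSE)$data), 9L)
  expect_identical(nrow(calibrate(tot, bg, "row1", detrend = FALSE)$data), 3L)

  # misalignment errors
  bg_short <- mk_set(rand_cube(3, nt, 2)[, , 1:32], t[1:32], "background")
  expect_error(calibrate(tot, bg_short), "shape")
  bg_shift <- mk_set(bg$data, t + 1e-12, "background")
  expect_error(calibrate(tot, bg_shift), "time axes")
})

test_that("detrending removes sub-carrier drift but keeps band content", {
  nt <- 2048; dt <- 1e-12; t <- (0:(nt - 1)) * dt
  pulse <- pulse_spec()
  sig <- gaussian_modulated_pulse(pulse, t - 0.5e-9)
  drift <- 0.3 * (t / max(t))          # slow ramp
  cube <- array(0, dim = c(1, 1, nt)); cube[1, 1, ] <- sig + drift
  tot <- mk_set(cube, t, "total", pulse = pulse)
  zero <- mk_set(array(0, dim = c(1, 1, nt)), t, "background")
  e3 <- calibrate(tot, zero, channels = "all", detrend = TRUE)
  late <- t > 1.2e-9 & t < 1.8e-9   # after the pulse, only drift remains
  expect_lt(max(abs(e3$data[1, late])), 0.02)
  expect_gt(max(abs(e3$data[1, ])), 0.5 * max(abs(sig)))
})

test_that("early-content removal subtracts the (group) channel average", {
  nt <- 32; t <- (0:(nt - 1)) * 1e-11
  s <- sin(2 * pi * (1:nt) / 8)

  same <- toy_signals(rbind(s, s, s), stage = "E3")
  expect_true(all(early_content_removal(same)$data == 0))

  pm <- toy_signals(rbind(s, -s), stage = "E3")
  expect_equal(early_content_removal(pm, weight = 1)$data, rbind(s, -s))

  set.seed(3)
  x <- matrix(rnorm(5 * nt), 5)
  e3 <- toy_signals(x, stage = "E3")
  e4 <- early_content_removal(e3, weight = 2)
  expect_equal(e4$data, 2 * sweep(x, 2, colMeans(x)), tolerance = 1e-12)

  expect_warning(early_content_removal(toy_signals(s, stage = "E3")), "degenerate")
  expect_error(early_content_removal(e3, weight = -1), "weight")
})

test_that("separation grouping removes rotationally symmetric clutter exactly", {
  lay <- place_antennas(9, 60e-3)
  ch <- expand.grid(rx = 1:9, tx = 1:9)[, c("tx", "rx")]
  nt <- 64
  # clutter depends only on the angular separation of the channel
  dth <- abs((lay$thetas[ch$tx] - lay$thetas[ch$rx] + pi) %% (2 * pi) - pi)
  set.seed(9)
  base <- matrix(rnorm(9 * nt), 9)
  clut <- base[round(dth / (2 * pi / 9)) + 1, ]
  e3 <- processed_signals(clut, (0:(nt - 1)) * 1e-11, "E3", channels = ch,
                          layout = lay)
  e4 <- early_content_removal(e3, group_by = "separation")
  expect_lt(max(abs(e4$data)), 1e-12)
})

test_that("pair multiplication enumerates unordered pairs lexicographically", {
  nt <- 16
  x4 <- matrix(rnorm(4 * nt), 4)
  e4 <- toy_signals(x4, stage = "E4")
  pp <- pair_multiply(e4)
  expect_identical(nrow(pp$data), 6L)
  expect_equal(as.matrix(pp$pair_index),
               matrix(c(1, 1, 1, 2, 2, 3, 2, 3, 4, 3, 4, 4), 6, 2,
                      dimnames = list(NULL, c("i", "j"))))
  for (k in 1:6)
    expect_equal(pp$data[k, ], x4[pp$pair_index$i[k], ] * x4[pp$pair_index$j[k], ])

  expect_identical(nrow(pair_multiply(toy_signals(matrix(rnorm(2 * nt), 2),
                                                  stage = "E4"))$data), 1L)
  x9 <- toy_signals(matrix(rnorm(9 * nt), 9), stage = "E4")
  expect_identical(nrow(pair_multiply(x9)$data), 36L)
  expect_error(pair_multiply(toy_signals(rnorm(nt), stage = "E4")), "2 channels")

  # bilinearity: scaling the input by a scales the pairs by a^2
  e4b <- toy_signals(3 * x4, stage = "E4")
  expect_equal(pair_multiply(e4b)$data, 9 * pp$data)
})

test_that("shared-transmitter pairing yields 36 pairs per transmitting element", {
  lay <- place_antennas(9, 60e-3)
  ch <- expand.grid(rx = 1:9, tx = 1:9)[, c("tx", "rx")]
  e4 <- processed_signals(matrix(rnorm(81 * 8), 81), (0:7) * 1e-11, "E4",
                          channels = ch, layout = lay)
  pp <- pair_multiply(e4, pairing = "shared_tx")
  expect_identical(nrow(pp$data), 9L * 36L)
  txs <- ch$tx[pp$pair_index$i]
  expect_true(all(txs == ch$tx[pp$pair_index$j]))
})

test_that("pair averaging: smoothing kernel and cross-pair mean realizations", {
  nt <- 64
  const <- toy_signals(rbind(rep(2, nt), rep(-1, nt)), stage = "E4")
  pc <- pair_multiply(const)
  expect_equal(average_pairs(pc, kernel = 9)$data, pc$data)  # constants unchanged

  imp <- matrix(0, 2, nt); imp[, 32] <- 1
  pi2 <- pair_multiply(toy_signals(imp, stage = "E4"))
  sm <- average_pairs(pi2, kernel = 5)
  expect_equal(sm$data[1, 30:34], rep(1 / 5, 5))
  expect_equal(sum(sm$data[1, ]), 1)

  set.seed(5)
  pr <- pair_multiply(toy_signals(matrix(rnorm(4 * nt), 4), stage = "E4"))
  expect_equal(average_pairs(pr, kernel = 1)$data, pr$data)  # identity
  xm <- average_pairs(pr, method = "cross_pair_mean")
  expect_equal(colMeans(xm$data), rep(0, nt), tolerance = 1e-12)
  expect_equal(xm$data, sweep(pr$data, 2, colMeans(pr$data)))
})

test_that("the geometric gate brackets front- and back-wall echoes", {
  pulse <- pulse_spec()
  lay <- place_antennas(9, 60e-3)
  # vacuum 'breast': front wall at 50 mm, antennas at 60 mm
  phv <- build_phantom(50e-3, 2e-3, list(), vacuum_tissues(),
                       grid_spacing = 1e-3, min_cells_per_wavelength = 0)
  g <- estimate_gate(lay, phv, pulse)
  expect_equal(g$tE, pulse$t0 + 2 * 10e-3 / .c0_test, tolerance = 1e-12)
  expect_lt(g$tE, g$tL)

  # fat slows the in-breast legs by sqrt(eps_fat): ray-time oracle for tL
  phf <- build_phantom(50e-3, 2e-3, list(), grid_spacing = 1e-3,
                       min_cells_per_wavelength = 0)
  gf <- estimate_gate(lay, phf, pulse)
  pos <- lay$positions
  v_fat <- .c0_test / sqrt(5.1)
  worst <- 0
  for (i in 1:9) {
    f <- pos[i, ] * (50e-3 / 60e-3)
    for (j in 1:9) {
      tt <- (sqrt(sum((pos[i, ] - f)^2)) + sqrt(sum((f - pos[j, ])^2))) / .c0_test +
        4 * 50e-3 / v_fat
      worst <- max(worst, tt)
    }
  }
  expect_equal(gf$tL, pulse$t0 + worst, tolerance = 1e-12)

  # random layouts always give tE < tL
  for (n in c(3, 6, 9))
    with(estimate_gate(place_antennas(n, 60e-3), phf, pulse), expect_lt(tE, tL))
})

test_that("time gating keeps strictly inside samples and is idempotent", {
  e5 <- toy_signals(matrix(c(1, 2, 3, 4), 1), dt = 1e-9, stage = "E5")  # t = 1..4 ns
  g <- gate_window(1.5e-9, 3.5e-9)
  out <- time_gate(e5, g)
  expect_equal(as.vector(out$data), c(0, 2, 3, 0))

  full <- time_gate(e5, gate_window(0, 5e-9))
  expect_equal(full$data, e5$data)

  expect_warning(z <- time_gate(e5, gate_window(1e-9, 1e-9)), "empty")
  expect_true(all(z$data == 0))

  twice <- time_gate(time_gate(e5, g), g)
  expect_equal(twice$data, out$data)

  # gating never increases energy
  expect_lte(sum(out$data^2), sum(e5$data^2))
})

test_that("the Gaussian taper behaves analytically and commutes with gating", {
  nt <- 101; dt <- 1e-11
  set.seed(7)
  e6 <- toy_signals(matrix(rnorm(nt), 1), dt = dt, stage = "E6")
  tp <- e6$t[51]; tau <- 20 * dt
  w <- window_spec(tp, tau)
  out <- gaussian_window(e6, w)
  expect_equal(out$data[1, 51], e6$data[1, 51])                 # at the apex
  expect_equal(out$data[1, 71], e6$data[1, 71] * exp(-1))       # at tp + tau
  expect_lte(sum(out$data^2), sum(e6$data^2))

  wide <- gaussian_window(e6, window_spec(tp, 100 * nt * dt))
  expect_equal(wide$data, e6$data, tolerance = 1e-4)

  # elementwise masks commute: gate-then-window equals window applied to
  # the gated data computed by hand in either order
  e5 <- toy_signals(e6$data, dt = dt, stage = "E5")
  g <- gate_window(20 * dt, 80 * dt)
  taper <- exp(-((e6$t - tp) / tau)^2)
  mask <- as.numeric(e6$t > g$tE & e6$t < g$tL)
  expect_equal(as.vector(gaussian_window(time_gate(e5, g), w)$data),
               as.vector(e6$data) * mask * taper)
  expect_error(window_spec(0, -1), "tau")
})

test_that("stage order is enforced", {
  nt <- 16
  e3 <- toy_signals(matrix(rnorm(2 * nt), 2), stage = "E3")
  expect_error(pair_multiply(e3), "stage")
  expect_error(time_gate(e3, gate_window(0, 1e-9)), "stage")
  e4 <- toy_signals(matrix(rnorm(2 * nt), 2), stage = "E4")
  expect_error(early_content_removal(e4), "stage")
})

test_that("the full chain composes the stages and is null for no target", {
  pulse <- pulse_spec()
  lay <- place_antennas(3, 60e-3)
  ph <- build_phantom(50e-3, 2e-3, list(), grid_spacing = 1e-3,
                      min_cells_per_wavelength = 0)
  nt <- 2400; dt <- 1.2e-12; t <- (0:(nt - 1)) * dt
  set.seed(11)
  cube <- array(rnorm(9 * nt, sd = 1), dim = c(3, 3, nt))
  tot <- mk_set(cube, t, "total", layout = lay, pulse = pulse)
  bg <- mk_set(array(rnorm(9 * nt), dim = c(3, 3, nt)), t, "background",
               layout = lay, pulse = pulse)

  # total = background propagates a null result through every stage
  e7n <- imtr_chain(tot, tot, ph)
  expect_true(all(e7n$data == 0))

  # composition equals the manual stage-by-stage application
  params <- chain_params(weight = 1.5, channels = "upper", pairing = "all",
                         ecr_group = "none", e5_method = "smooth", kernel = 7)
  e7 <- imtr_chain(tot, bg, ph, params)
  m3 <- calibrate(tot, bg, channels = "upper")
  m4 <- early_content_removal(m3, weight = 1.5, group_by = "none")
  m5 <- average_pairs(pair_multiply(m4, "all"), kernel = 7)
  gate <- estimate_gate(lay, ph, pulse)
  gate <- gate_window(min(gate$tE, max(t)), min(gate$tL, max(t) + dt))
  m7 <- gaussian_window(time_gate(m5, gate))
  expect_equal(e7$data, m7$data, tolerance = 1e-12)

  # doubling the weight scales the (pair-product) output by 4
  e7w <- imtr_chain(tot, bg, ph, chain_params(weight = 2, channels = "upper",
                                              pairing = "all", ecr_group = "none",
                                              e5_method = "smooth", kernel = 7))
  e7u <- imtr_chain(tot, bg, ph, chain_params(weight = 1, channels = "upper",
                                              pairing = "all", ecr_group = "none",
                                              e5_method = "smooth", kernel = 7))
  expect_equal(e7w$data, 4 * e7u$data, tolerance = 1e-10)
})
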