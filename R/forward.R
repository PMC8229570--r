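#' FDTD solver configuration
#'
#' @param courant_factor dimensionless Courant number `c dt / dx`; must be
#'   below the 2-D stability bound `1/sqrt(2)` (default 0.5)
#' @param pml_cells thickness of the convolutional PML in cells; 0 gives a
#'   perfectly reflecting (PEC) box, useful for boundary tests
#' @param pml_target_reflection acceptance bound used by
#'   [pml_reflection_test()] (default 1e-2)
#' @param n_timesteps number of timesteps, or `NULL` to size the record
#'   automatically from the geometry (pulse start + round trip across the
#'   breast at the fat-tissue speed, with margin)
#' @param pml_m polynomial grading order of the PML conductivity
#' @param pml_r0 design reflection coefficient used to grade the PML
#' @param pml_alpha CFS alpha at the inner PML edge (S/m)
#' @return an object of class `imtr_solver_config`
#' @export
solver_config <- function(courant_factor = 0.5, pml_cells = 10,
                          pml_target_reflection = 1e-2, n_timesteps = NULL,
                          pml_m = 3, pml_r0 = 1e-6, pml_alpha = 0.05) {
  if (courant_factor <= 0 || courant_factor >= 1 / sqrt(2))
    stop("courant_factor must lie in (0, 1/sqrt(2)) for 2-D stability", call. = FALSE)
  if (pml_cells < 0) stop("pml_cells must be >= 0", call. = FALSE)
  structure(list(courant_factor = courant_factor, pml_cells = as.integer(pml_cells),
                 pml_target_reflection = pml_target_reflection,
                 n_timesteps = n_timesteps, pml_m = pml_m, pml_r0 = pml_r0,
                 pml_alpha = pml_alpha),
            class = "imtr_solver_config")
}

# record length (s) long enough for the pulse plus a round trip across the
# breast at the fat speed plus the air legs
.auto_duration <- function(phantom, layout, pulse) {
  v_fat <- .c0 / sqrt(phantom$tissues$fat$eps_r)
  air <- 4 * max(layout$gamma - phantom$breast_radius, 0)
  (pulse$t0 + 6 * pulse$omega) + air / .c0 + 4 * phantom$breast_radius / v_fat
}

.new_signalset <- function(data, t, role, layout, pulse, meta = list()) {
  structure(list(data = data, t = t, role = role, layout = layout,
                 pulse = pulse, meta = meta),
            class = "imtr_signalset")
}

#' @export
print.imtr_signalset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<imtr_signalset> role '%s': %d tx x %d rx x %d samples (dt = %.3f ps)\n",
              x$role, d[1], d[2], d[3], diff(x$t[1:2]) * 1e12))
  invisible(x)
}

#' Simulate a multistatic UWB acquisition with the 2-D FDTD solver
#'
#' Each antenna in turn injects the excitation pulse as a soft source at its
#' grid cell; the out-of-plane electric field is recorded at every antenna
#' cell each timestep. The result is the (tx, rx, time) trace cube of one
#' acquisition role (background or total).
#'
#' @param phantom an [build_phantom()] result
#' @param layout an [place_antennas()] result
#' @param pulse a [pulse_spec()]
#' @param cfg a [solver_config()]; `pml_cells >= 8` is required here
#' @param role role tag, `"total"` or `"background"`
#' @return an `imtr_signalset` with `data` of shape (n, n, n_t) and time axis
#'   `t`; deterministic for fixed inputs
#' @export
simulate_multistatic <- function(phantom, layout, pulse, cfg = solver_config(),
                                 role = "total") {
  stopifnot(inherits(phantom, "imtr_phantom"), inherits(layout, "imtr_layout"),
            inherits(pulse, "imtr_pulse"), inherits(cfg, "imtr_solver_config"))
  if (cfg$pml_cells < 8)
    stop("simulate_multistatic requires pml_cells >= 8", call. = FALSE)
  dx <- phantom$dx
  dt <- cfg$courant_factor * dx / .c0
  nt <- cfg$n_timesteps
  if (is.null(nt))
    nt <- as.integer(ceiling(1.15 * .auto_duration(phantom, layout, pulse) / dt))
  t_axis <- (seq_len(nt) - 1) * dt

  n <- layout$n
  ai <- integer(n); aj <- integer(n)
  bg_eps <- phantom$tissues$background$eps_r
  for (a in seq_len(n)) {
    ai[a] <- .cell_index(phantom$x, layout$positions[a, 1])
    aj[a] <- .cell_index(phantom$y, layout$positions[a, 2])
    if (phantom$eps[ai[a], aj[a]] != bg_eps)
      stop(sprintf("antenna %d cell is not in the background medium", a), call. = FALSE)
  }
  wf <- matrix(gaussian_modulated_pulse(pulse, t_axis), ncol = 1)

  data <- array(0, dim = c(n, n, nt))
  for (tx in seq_len(n)) {
    res <- .fdtd_run_cpp(phantom$eps, phantom$sigma, dx, dt, nt,
                         ai[tx] - 1L, aj[tx] - 1L, wf,
                         ai - 1L, aj - 1L,
                         cfg$pml_cells, cfg$pml_m, cfg$pml_r0, cfg$pml_alpha,
                         FALSE)
    data[tx, , ] <- t(res$traces)
  }
  snapped <- cbind(phantom$x[ai], phantom$y[aj])
  colnames(snapped) <- c("x", "y")
  .new_signalset(data, t_axis, role, layout, pulse,
                 meta = list(dx = dx, dt = dt, cfg = cfg,
                             positions_snapped = snapped,
                             phantom_hash = phantom_hash(phantom)))
}

#' Analytic Born point-scatterer forward model
#'
#' Independent oracle for beamformer validation: each scatterer contributes
#' `amp / sqrt(d_tx * d_rx) * S(t - (d_tx + d_rx)/v)` to the (tx, rx) trace,
#' with `S` the modulated Gaussian pulse. Arrival times are exact by
#' construction.
#'
#' @param layout an [place_antennas()] result
#' @param scatterers list of `list(center = c(x, y), amp = a)` entries (or an
#'   empty list for an all-zero set)
#' @param pulse a [pulse_spec()]
#' @param v homogeneous background propagation speed in m/s
#' @param dt sample interval in seconds (default: 32 samples per modulation
#'   period)
#' @param duration record length in seconds (default: latest arrival plus
#'   pulse tail)
#' @return an `imtr_signalset` with role `"total"`
#' @export
born_point_scatterer <- function(layout, scatterers, pulse, v = .c0,
                                 dt = 1 / (32 * pulse$f_r), duration = NULL) {
  stopifnot(inherits(layout, "imtr_layout"), inherits(pulse, "imtr_pulse"), v > 0)
  n <- layout$n
  pos <- layout$positions
  dists <- lapply(scatterers, function(s) {
    d <- sqrt((pos[, 1] - s$center[1])^2 + (pos[, 2] - s$center[2])^2)
    if (any(d < 1e-6))
      stop("scatterer coincides with an antenna (singular distance)", call. = FALSE)
    d
  })
  if (is.null(duration)) {
    dmax <- if (length(dists)) max(vapply(dists, max, numeric(1))) else layout$gamma
    duration <- pulse$t0 + 2 * dmax / v + 6 * pulse$omega
  }
  nt <- as.integer(ceiling(duration / dt))
  t_axis <- (seq_len(nt) - 1) * dt
  data <- array(0, dim = c(n, n, nt))
  for (s in seq_along(scatterers)) {
    d <- dists[[s]]
    amp <- scatterers[[s]]$amp
    for (tx in seq_len(n)) for (rx in seq_len(n)) {
      delay <- (d[tx] + d[rx]) / v
      data[tx, rx, ] <- data[tx, rx, ] +
        amp / sqrt(d[tx] * d[rx]) * gaussian_modulated_pulse(pulse, t_axis - delay)
    }
  }
  .new_signalset(data, t_axis, "total", layout, pulse,
                 meta = list(model = "born", v = v, dt = dt))
}

#' Measure the residual reflection of the PML boundary
#'
#' Runs a vacuum-domain experiment: a point source near one wall, a probe
#' between source and wall. A reference run in an enlarged domain (whose own
#' boundaries stay causally silent at the probe during the record) isolates
#' the boundary reflection; the returned value is the peak reflected-to-peak
#' incident amplitude ratio.
#'
#' @param cfg a [solver_config()]; its `pml_cells` is the tested thickness
#' @param dx grid spacing in meters (default 1 mm)
#' @param pulse a [pulse_spec()]
#' @return scalar reflection magnitude
#' @export
pml_reflection_test <- function(cfg = solver_config(), dx = 1e-3,
                                pulse = pulse_spec()) {
  np <- cfg$pml_cells
  n <- 100L + 2L * np
  dt <- cfg$courant_factor * dx / .c0
  # source 28 cells, probe 8 cells inside the PML inner edge
  edge <- n - np                       # inner PML edge (cell index)
  src <- c(edge - 28L, n %/% 2L)
  prb <- c(edge - 8L, n %/% 2L)
  # record: direct arrival + round trip probe-edge-probe + tail
  dist_direct <- (prb[1] - src[1]) * dx
  roundtrip <- dist_direct + 2 * (n - prb[1]) * dx
  nt <- as.integer(ceiling((pulse$t0 + roundtrip / .c0 + 8 * pulse$omega) / dt))
  run1 <- .vacuum_run(n, n, dx, dt, nt, src, prb, cfg, pulse)
  # reference: pad the right side far enough that its wall cannot echo back
  pad <- as.integer(ceiling(nt * dt * .c0 / dx)) + 10L
  run2 <- .vacuum_run(n + pad, n, dx, dt, nt, src, prb, cfg, pulse)
  reflected <- run1 - run2
  # compensate 2-D cylindrical spreading over the longer reflected path so a
  # perfect reflector scores ~1
  spread <- sqrt((dist_direct + 2 * (edge - prb[1]) * dx) / dist_direct)
  max(abs(reflected)) * spread / max(abs(run2))
}

.vacuum_run <- function(nx, ny, dx, dt, nt, src, prb, cfg, pulse) {
  eps <- matrix(1, nx, ny)
  sig <- matrix(0, nx, ny)
  wf <- matrix(gaussian_modulated_pulse(pulse, (seq_len(nt) - 1) * dt), ncol = 1)
  res <- .fdtd_run_cpp(eps, sig, dx, dt, nt,
                       src[1] - 1L, src[2] - 1L, wf, prb[1] - 1L, prb[2] - 1L,
                       cfg$pml_cells, cfg$pml_m, cfg$pml_r0, cfg$pml_alpha, FALSE)
  as.numeric(res$traces)
}

#' Envelope-peak arrival time of a trace
#'
#' Time of the maximum of the analytic-signal envelope, refined by parabolic
#' interpolation. Absolute peak times carry a small constant systematic from
#' the source response and the 2-D line-source wake, so propagation speed is
#' best measured differentially between two receiver distances (the constant
#' cancels).
#'
#' @param x numeric trace
#' @param t time axis in seconds
#' @return arrival time in seconds
#' @export
arrival_time <- function(x, t) {
  env <- Mod(analytic_signal(x))
  i <- which.max(env)
  if (i <= 1 || i >= length(env)) return(t[i])
  dt <- t[2] - t[1]
  den <- env[i - 1] - 2 * env[i] + env[i + 1]
  if (den == 0) return(t[i])
  t[i] + 0.5 * (env[i - 1] - env[i + 1]) / den * dt
}

#' Stable content hash of a phantom
#' @param phantom an `imtr_phantom`
#' @return md5 string
#' @export
phantom_hash <- function(phantom) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(list(phantom$eps, phantom$sigma, phantom$dx), NULL,
                     version = 2), f)
  unname(tools::md5sum(f))
}
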