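#' Analytic signal of one or more traces
#'
#' FFT-based Hilbert construction: positive frequencies doubled, negative
#' zeroed. `Mod()` of the result is the signal envelope.
#'
#' @param x numeric vector, or matrix with one trace per row
#' @return complex vector/matrix of the same shape
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  m <- rbind(x)
  nt <- ncol(m)
  X <- stats::mvfft(t(m))
  h <- numeric(nt)
  if (nt %% 2 == 0) {
    h[c(1, nt / 2 + 1)] <- 1
    h[2:(nt / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((nt + 1) / 2)] <- 2
  }
  a <- t(stats::mvfft(X * h, inverse = TRUE)) / nt
  if (vec) as.vector(a) else a
}

#' Image grid definition
#'
#' @param extent numeric length-4 `c(xmin, xmax, ymin, ymax)` in meters
#' @param pixel pixel size in meters (default 1 mm)
#' @return object of class `imtr_grid` with pixel-center axes `x`, `y`
#' @export
image_grid <- function(extent, pixel = 1e-3) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3],
            pixel > 0)
  x <- seq(extent[1] + pixel / 2, extent[2] - pixel / 2, by = pixel)
  y <- seq(extent[3] + pixel / 2, extent[4] - pixel / 2, by = pixel)
  structure(list(x = x, y = y, pixel = pixel, extent = extent,
                 nx = length(x), ny = length(y)),
            class = "imtr_grid")
}

#' Image grid covering a phantom's breast region
#'
#' @param phantom an `imtr_phantom`
#' @param pad margin beyond the breast bounding box in meters (default 10 mm)
#' @param pixel pixel size in meters
#' @return an [image_grid()]
#' @export
grid_for_phantom <- function(phantom, pad = 10e-3, pixel = 1e-3) {
  R <- phantom$breast_radius + pad
  image_grid(c(-R, R, -R, R), pixel)
}

.new_image <- function(intensity, grid) {
  intensity[!is.finite(intensity)] <- 0
  intensity[intensity < 0] <- 0
  mx <- max(intensity)
  if (mx > 0) intensity <- intensity / mx
  structure(list(intensity = intensity, x = grid$x, y = grid$y,
                 pixel = grid$pixel, extent = grid$extent),
            class = "imtr_image")
}

#' @export
print.imtr_image <- function(x, ...) {
  cat(sprintf("<imtr_image> %d x %d px at %.1f mm; extent [%.0f, %.0f] x [%.0f, %.0f] mm\n",
              length(x$x), length(x$y), x$pixel * 1e3,
              x$extent[1] * 1e3, x$extent[2] * 1e3, x$extent[3] * 1e3, x$extent[4] * 1e3))
  invisible(x)
}

#' Propagation-delay model for backprojection
#'
#' Homogeneous mode uses one effective speed everywhere. Two-speed mode
#' splits each straight ray into the in-breast chord (at an effective breast
#' speed, see [effective_permittivity()]) and the remainder at the
#' background speed. Layered mode (the pipeline default) traces the straight
#' ray through the three media explicitly: background, the skin shell
#' (chord through the outer circle minus chord through the inner circle),
#' and fat, each at its own tissue speed.
#'
#' @param mode `"layered"`, `"two_speed"` or `"homogeneous"`
#' @param phantom an `imtr_phantom`; required unless the speeds and radii are
#'   given explicitly
#' @param speed in-breast (or global, for homogeneous mode) speed in m/s
#' @param background_speed speed outside the breast
#' @param breast_radius breast radius in meters
#' @param skin_thickness skin shell thickness in meters (layered mode)
#' @param skin_speed,fat_speed tissue speeds in m/s (layered mode)
#' @return object of class `imtr_delay_model`
#' @export
delay_model <- function(mode = c("layered", "two_speed", "homogeneous"),
                        phantom = NULL, speed = NULL, background_speed = .c0,
                        breast_radius = NULL, skin_thickness = NULL,
                        skin_speed = NULL, fat_speed = NULL) {
  mode <- match.arg(mode)
  if (is.null(speed)) {
    if (!is.null(phantom)) speed <- .c0 / sqrt(effective_permittivity(phantom))
    else if (mode != "layered") stop("need a phantom or an explicit speed", call. = FALSE)
  }
  if (!is.null(speed) && speed <= 0) stop("speed must be > 0", call. = FALSE)
  if (mode != "homogeneous" && is.null(breast_radius)) {
    if (is.null(phantom)) stop(mode, " mode needs breast_radius", call. = FALSE)
    breast_radius <- phantom$breast_radius
  }
  if (mode == "layered") {
    if (is.null(skin_thickness))
      skin_thickness <- if (!is.null(phantom)) phantom$skin_thickness
                        else stop("layered mode needs skin_thickness", call. = FALSE)
    if (is.null(skin_speed))
      skin_speed <- if (!is.null(phantom)) .c0 / sqrt(phantom$tissues$skin$eps_r)
                    else stop("layered mode needs skin_speed", call. = FALSE)
    if (is.null(fat_speed))
      fat_speed <- if (!is.null(phantom)) .c0 / sqrt(phantom$tissues$fat$eps_r)
                   else stop("layered mode needs fat_speed", call. = FALSE)
  }
  structure(list(mode = mode, speed = speed, background_speed = background_speed,
                 breast_radius = breast_radius, skin_thickness = skin_thickness,
                 skin_speed = skin_speed, fat_speed = fat_speed),
            class = "imtr_delay_model")
}

#' Effective permittivity of the tumor-free breast for delay modeling
#'
#' Slowness-weighted along a diametral ray: a straight ray through the
#' breast spends a fraction `skin_thickness / breast_radius` of its in-breast
#' path in skin and the rest in fat, so the effective index is the
#' path-weighted mean of the tissue indices (and the effective permittivity
#' its square). This matches the travel times the backprojection delay model
#' must reproduce, unlike an area-weighted mean which over-counts the skin
#' shell.
#'
#' @param phantom an `imtr_phantom`
#' @return effective relative permittivity
#' @export
effective_permittivity <- function(phantom) {
  f <- phantom$skin_thickness / phantom$breast_radius
  ((1 - f) * sqrt(phantom$tissues$fat$eps_r) +
     f * sqrt(phantom$tissues$skin$eps_r))^2
}

#' Per-antenna one-way focal delays over an image grid
#'
#' @param layout an `imtr_layout`
#' @param grid an [image_grid()]
#' @param dm a [delay_model()]
#' @return matrix (n_antennas x n_pixels) of one-way delays in seconds;
#'   pixels in column-major order (x fastest)
#' @export
focal_delays <- function(layout, grid, dm) {
  stopifnot(inherits(dm, "imtr_delay_model"))
  px <- rep(grid$x, times = grid$ny)
  py <- rep(grid$y, each = grid$nx)
  n <- layout$n
  out <- matrix(0, n, length(px))
  for (a in seq_len(n)) {
    p <- layout$positions[a, ]
    d <- sqrt((px - p[1])^2 + (py - p[2])^2)
    if (dm$mode == "homogeneous") {
      out[a, ] <- d / dm$speed
    } else if (dm$mode == "two_speed") {
      L <- .chord_in_circle(p, px, py, dm$breast_radius)
      out[a, ] <- (d - L) / dm$background_speed + L / dm$speed
    } else {
      Lo <- .chord_in_circle(p, px, py, dm$breast_radius)
      Li <- .chord_in_circle(p, px, py, dm$breast_radius - dm$skin_thickness)
      out[a, ] <- (d - Lo) / dm$background_speed +
        (Lo - Li) / dm$skin_speed + Li / dm$fat_speed
    }
  }
  out
}

# length of the segment p -> (qx, qy) inside the circle of radius R at origin
.chord_in_circle <- function(p, qx, qy, R) {
  ux <- qx - p[1]; uy <- qy - p[2]
  d2 <- ux^2 + uy^2
  d <- sqrt(d2)
  # solve |p + t u|^2 = R^2 for t
  b <- (p[1] * ux + p[2] * uy) / pmax(d2, 1e-30)
  c0 <- (p[1]^2 + p[2]^2 - R^2) / pmax(d2, 1e-30)
  disc <- b^2 - c0
  t1 <- pmax(-b - sqrt(pmax(disc, 0)), 0)
  t2 <- pmin(-b + sqrt(pmax(disc, 0)), 1)
  L <- pmax(t2 - t1, 0) * d
  L[disc <= 0] <- 0
  L
}

# sample rows of a complex/real trace matrix at per-pixel delay times;
# delays outside the record contribute zero
.sample_traces <- function(traces, t, idx_times) {
  dt <- t[2] - t[1]
  idx <- round((idx_times - t[1]) / dt) + 1
  bad <- idx < 1 | idx > length(t)
  idx[bad] <- 1
  list(idx = idx, bad = bad)
}

.channel_delays <- function(signals, tau) {
  ch <- signals$channels
  if (is.null(ch)) stop("signals carry no channel index", call. = FALSE)
  tau[ch$tx, , drop = FALSE] + tau[ch$rx, , drop = FALSE]
}

#' Modified weighted delay-and-sum (MWDAS) image
#'
#' Coherent delay-and-sum over channels: the analytic channel traces are
#' sampled at the two-way focal delay `tau_tx(r) + tau_rx(r)`, weighted,
#' summed, and the squared magnitude (envelope power of the focused sum)
#' forms the pixel intensity. Default weights compensate the tx-rx path
#' length per channel.
#'
#' @param e3 `imtr_signals` at stage E3 or E4
#' @param layout an `imtr_layout`
#' @param grid an [image_grid()]
#' @param dm a [delay_model()]
#' @param weights per-channel weights; `NULL` = tx-rx path-length
#'   compensation, or a numeric vector, or `1` for plain DAS
#' @return an `imtr_image`, max-normalized
#' @export
mwdas_image <- function(e3, layout, grid, dm, weights = NULL) {
  .expect_stage(e3, c("E3", "E4"))
  ch <- e3$channels
  if (is.null(weights)) {
    pl <- sqrt(rowSums((layout$positions[ch$tx, , drop = FALSE] -
                          layout$positions[ch$rx, , drop = FALSE])^2))
    pl[pl == 0] <- min(pl[pl > 0], 1)
    weights <- pl / mean(pl)
  }
  if (length(weights) == 1) weights <- rep(weights, nrow(ch))
  tau <- focal_delays(layout, grid, dm)
  dly <- .channel_delays(e3, tau) + e3$pulse$t0
  a <- analytic_signal(e3$data)
  acc <- complex(real = numeric(ncol(tau)))
  for (k in seq_len(nrow(ch))) {
    s <- .sample_traces(a[k, ], e3$t, dly[k, ])
    v <- a[k, s$idx]
    v[s$bad] <- 0
    acc <- acc + weights[k] * v
  }
  .new_image(matrix(Mod(acc)^2, grid$nx, grid$ny), grid)
}

#' Delay-multiply-and-sum (FDMAS) image
#'
#' Sign-preserving square roots of the delayed real channel samples are
#' combined pairwise via the combinatorial identity
#' `sum_{i<j} s_i s_j = ((sum s)^2 - sum s^2)/2`, and the squared pair sum is
#' integrated over a short window of pulse length around the focal delay.
#'
#' @inheritParams mwdas_image
#' @param n_taps number of integration taps across one pulse width
#' @return an `imtr_image`, max-normalized
#' @export
fdmas_image <- function(e3, layout, grid, dm, n_taps = 9) {
  .expect_stage(e3, c("E3", "E4"))
  nch <- nrow(e3$data)
  if (nch < 2) {
    warning("fewer than 2 channels: no pairs, falling back to delay-and-sum")
    return(mwdas_image(e3, layout, grid, dm, weights = 1))
  }
  tau <- focal_delays(layout, grid, dm)
  dly <- .channel_delays(e3, tau) + e3$pulse$t0
  dt <- e3$t[2] - e3$t[1]
  span <- if (!is.null(e3$pulse)) 2 * e3$pulse$omega else 10 * dt
  offs <- round(seq(-span / 2, span / 2, length.out = n_taps) / dt)
  npx <- ncol(tau)
  I <- numeric(npx)
  nt <- ncol(e3$data)
  base_idx <- round((dly - e3$t[1]) / dt) + 1
  for (o in offs) {
    S1 <- numeric(npx); S2 <- numeric(npx)
    for (k in seq_len(nch)) {
      idx <- base_idx[k, ] + o
      bad <- idx < 1 | idx > nt
      idx[bad] <- 1
      v <- e3$data[k, idx]
      v[bad] <- 0
      sv <- sign(v) * sqrt(abs(v))
      S1 <- S1 + sv
      S2 <- S2 + sv * sv
    }
    y <- (S1 * S1 - S2) / 2
    I <- I + y * y
  }
  .new_image(matrix(I, grid$nx, grid$ny), grid)
}

#' Time-reversal (TR) image
#'
#' Numeric mode re-injects each transmitter row's time-reversed calibrated
#' traces at the receiving antenna cells of the background phantom and
#' accumulates field energy with the FDTD solver; the energies of all
#' transmitter rows are summed. With
#' `imaging_condition = "snapshot"` (default) a first back-propagation pass
#' locates the refocus instant (the step of maximum field energy inside the
#' imaging region) and a second pass accumulates `|E(r, t)|^2` under a
#' Gaussian time window of one pulse width around it, suppressing the
#' traversal energy that plain whole-record accumulation
#' (`imaging_condition = "energy"`) spreads along every propagation path.
#' Synthetic mode is the fast phase-conjugate backprojection equivalent
#' (unweighted delay-and-sum on the analytic traces).
#'
#' @inheritParams mwdas_image
#' @param phantom_background tumor-free `imtr_phantom` (numeric mode)
#' @param mode `"synthetic"` or `"numeric"`
#' @param cfg [solver_config()] for numeric mode
#' @param antenna_mask_radius pixels closer than this to any antenna are
#'   zeroed in numeric mode (source-cell energy dominates otherwise)
#' @param roi_radius numeric mode: pixels farther than this from the origin
#'   are zeroed (default: the inner skin wall, breast radius minus skin
#'   thickness). The skin shell is part of the known background model that
#'   the reversed fields propagate through, so energy converging onto it is
#'   explained by the model rather than by an unknown scatterer; outside the
#'   sample the accumulated energy is injection near-field
#' @param imaging_condition `"snapshot"` or `"energy"` (numeric mode)
#' @return an `imtr_image`, max-normalized
#' @export
tr_image <- function(e3, layout, grid, dm = NULL, phantom_background = NULL,
                     mode = c("synthetic", "numeric"), cfg = solver_config(),
                     antenna_mask_radius = 10e-3, roi_radius = NULL,
                     imaging_condition = c("snapshot", "energy")) {
  imaging_condition <- match.arg(imaging_condition)
  mode <- match.arg(mode)
  .expect_stage(e3, c("E3", "E4"))
  if (mode == "synthetic") {
    if (is.null(dm)) stop("synthetic mode needs a delay model", call. = FALSE)
    return(mwdas_image(e3, layout, grid, dm, weights = 1))
  }
  if (is.null(phantom_background))
    stop("numeric mode needs the background phantom", call. = FALSE)
  ph <- phantom_background
  bg_eps <- ph$tissues$background$eps_r
  ai <- integer(layout$n); aj <- integer(layout$n)
  for (a in seq_len(layout$n)) {
    ai[a] <- .cell_index(ph$x, layout$positions[a, 1])
    aj[a] <- .cell_index(ph$y, layout$positions[a, 2])
    if (ph$eps[ai[a], aj[a]] != bg_eps)
      stop(sprintf("antenna %d does not sit in the background medium of the phantom", a),
           call. = FALSE)
  }
  dt_sig <- e3$t[2] - e3$t[1]
  dt <- cfg$courant_factor * ph$dx / .c0
  if (abs(dt - dt_sig) / dt_sig > 1e-9)
    stop("numeric TR needs traces sampled at the solver timestep of this phantom", call. = FALSE)
  nt <- ncol(e3$data)
  ch <- e3$channels
  if (is.null(roi_radius)) roi_radius <- ph$breast_radius - ph$skin_thickness
  emask <- outer(ph$x, ph$y, function(px, py) px^2 + py^2 < roi_radius^2)
  energy <- matrix(0, nrow(ph$eps), ncol(ph$eps))
  for (tx in unique(ch$tx)) {
    rows <- which(ch$tx == tx)
    wf <- t(e3$data[rows, rev(seq_len(nt)), drop = FALSE])  # time-reversed
    run1 <- .fdtd_run_cpp(ph$eps, ph$sigma, ph$dx, dt, nt,
                          ai[ch$rx[rows]] - 1L, aj[ch$rx[rows]] - 1L, wf,
                          ai[1] - 1L, aj[1] - 1L,
                          cfg$pml_cells, cfg$pml_m, cfg$pml_r0, cfg$pml_alpha,
                          TRUE, NULL, emask)
    if (imaging_condition == "energy") {
      energy <- energy + run1$energy
    } else {
      nstar <- which.max(run1$step_energy)
      sig <- max(e3$pulse$omega / dt, 1)
      w <- exp(-0.5 * ((seq_len(nt) - nstar) / sig)^2)
      run2 <- .fdtd_run_cpp(ph$eps, ph$sigma, ph$dx, dt, nt,
                            ai[ch$rx[rows]] - 1L, aj[ch$rx[rows]] - 1L, wf,
                            ai[1] - 1L, aj[1] - 1L,
                            cfg$pml_cells, cfg$pml_m, cfg$pml_r0, cfg$pml_alpha,
                            TRUE, w, emask)
      energy <- energy + run2$energy
    }
  }
  # resample the cell-centered energy map onto the image grid (nearest cell)
  ix <- vapply(grid$x, function(v) .cell_index(ph$x, v), integer(1))
  iy <- vapply(grid$y, function(v) .cell_index(ph$y, v), integer(1))
  img <- energy[ix, iy, drop = FALSE]
  px <- rep(grid$x, times = grid$ny)
  py <- rep(grid$y, each = grid$nx)
  for (a in seq_len(layout$n)) {
    near <- (px - layout$positions[a, 1])^2 + (py - layout$positions[a, 2])^2 <
      antenna_mask_radius^2
    img[near] <- 0
  }
  img[px^2 + py^2 > roi_radius^2] <- 0
  .new_image(img, grid)
}

#' IMTR pair-delay backprojection image
#'
#' A pair trace is the product of two channels, so it encodes only the *sum*
#' of its channels' arrival times: the product of two pulses arriving at
#' `a_i` and `a_j` is supported near their midpoint (where its
#' double-frequency component carries the phase `2 pi f_r (a_i + a_j)`), and
#' single-pair backprojection at summed delays is therefore ambiguous along
#' iso-sum loci. Closed channel triangles resolve the ambiguity - from the
#' sums `S_ij, S_ik, S_jk` the individual delay follows as
#' `a_i = (S_ij + S_ik - S_jk)/2` - and the same closure holds for the
#' phases. The image is accordingly formed by phase-closure (bispectral)
#' backprojection: for every channel triple whose three pairs exist, the
#' complex analytic pair signals are sampled at the mean of their two
#' channels' focal arrival times and combined as `z_ij z_ik z*_jk` (all
#' three conjugation placements); the closure phase is stationary exactly at
#' focal points consistent with the individual channel delays, so triples
#' add coherently at the target and cancel elsewhere. The intensity is the
#' squared magnitude of the accumulated closure sum, followed by a clutter
#' floor (`floor_db`, default -20 dB) that implements the algorithm's final
#' artifact-removal step. When no complete triple exists (fewer than three
#' mutually paired channels) the method falls back to summed single-pair
#' midpoint envelope sampling.
#'
#' @param e7 `imtr_signals` at a pair stage (E5, E6 or E7)
#' @inheritParams mwdas_image
#' @param floor_db clutter floor in dB relative to the intensity maximum;
#'   pixels below it are zeroed (`-Inf` disables)
#' @return an `imtr_image`, max-normalized
#' @export
imtr_image <- function(e7, layout, grid, dm, floor_db = -20) {
  .expect_stage(e7, c("E5", "E6", "E7"))
  if (is.null(e7$pair_index)) stop("pair-stage signals required", call. = FALSE)
  tau <- focal_delays(layout, grid, dm)
  chd <- .channel_delays(e7, tau)   # per-channel two-way delays
  z <- analytic_signal(e7$data)
  zmax <- apply(Mod(z), 1, max)
  zmax[zmax == 0] <- 1
  z <- z / zmax
  t0 <- if (!is.null(e7$pulse)) e7$pulse$t0 else 0
  npx <- ncol(tau)
  nt <- ncol(z)
  dt <- e7$t[2] - e7$t[1]
  pidx <- e7$pair_index
  key <- paste(pmin(pidx$i, pidx$j), pmax(pidx$i, pidx$j))
  rowk <- stats::setNames(seq_len(nrow(pidx)), key)
  samp <- function(k, times) {
    idx <- round((times - e7$t[1]) / dt) + 1
    bad <- idx < 1 | idx > nt
    idx[bad] <- 1
    v <- z[k, idx]
    v[bad] <- 0 + 0i
    v
  }
  mid <- function(i, j) (chd[i, ] + chd[j, ]) / 2 + t0
  # channel triples whose three pairs are all present
  adj <- split(c(pidx$j, pidx$i), c(pidx$i, pidx$j))
  triples <- list()
  for (i in as.integer(names(adj))) {
    nb <- sort(adj[[as.character(i)]])
    nb <- nb[nb > i]
    if (length(nb) < 2) next
    cmb <- t(utils::combn(nb, 2))
    ok <- paste(cmb[, 1], cmb[, 2]) %in% key
    if (any(ok))
      triples[[length(triples) + 1]] <- cbind(i, cmb[ok, , drop = FALSE])
  }
  if (length(triples)) {
    acc <- complex(real = numeric(npx))
    tri <- do.call(rbind, triples)
    for (m in seq_len(nrow(tri))) {
      i <- tri[m, 1]; j <- tri[m, 2]; k <- tri[m, 3]
      a <- samp(rowk[[paste(i, j)]], mid(i, j))
      b <- samp(rowk[[paste(i, k)]], mid(i, k))
      cc <- samp(rowk[[paste(j, k)]], mid(j, k))
      acc <- acc + a * b * Conj(cc) + a * Conj(b) * cc + Conj(a) * b * cc
    }
    I <- Mod(acc)^2
  } else {
    I <- numeric(npx)
    for (k in seq_len(nrow(pidx)))
      I <- I + Mod(samp(k, mid(pidx$i[k], pidx$j[k])))
    I <- I^2
  }
  img <- .new_image(matrix(I, grid$nx, grid$ny), grid)
  if (is.finite(floor_db)) {
    floor_lin <- 10^(floor_db / 10)
    img$intensity[img$intensity < floor_lin] <- 0
  }
  img
}

#' Location of the image intensity maximum
#' @param image an `imtr_image`
#' @return numeric length-2 (x, y) in meters
#' @export
image_argmax <- function(image) {
  ij <- which(image$intensity == max(image$intensity), arr.ind = TRUE)[1, ]
  c(image$x[ij[1]], image$y[ij[2]])
}
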