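#' Processed-signal container
#'
#' Channel (or channel-pair) traces at one stage of the IMTR preprocessing
#' chain. Stages advance strictly in the order
#' E3 (calibrated) -> E4 (early content removed) -> pairs -> E5 (averaged)
#' -> E6 (time gated) -> E7 (Gaussian windowed).
#'
#' @param data numeric matrix, one row per channel (or pair), columns = time
#' @param t time axis in seconds
#' @param stage one of `"E3"`, `"E4"`, `"pairs"`, `"E5"`, `"E6"`, `"E7"`
#' @param channels data.frame with columns `tx`, `rx` describing each row of
#'   `data` (for stages up to E4) or each underlying channel (for pair stages)
#' @param pair_index data.frame with columns `i`, `j` (row indices into
#'   `channels`) for pair stages, else `NULL`
#' @param layout,pulse provenance objects (optional but needed downstream)
#' @param gate the [gate_window()] applied at E6 (carried forward), or `NULL`
#' @return an object of class `imtr_signals`
#' @export
processed_signals <- function(data, t, stage, channels = NULL,
                              pair_index = NULL, layout = NULL, pulse = NULL,
                              gate = NULL) {
  stage <- match.arg(stage, c("E3", "E4", "pairs", "E5", "E6", "E7"))
  data <- rbind(data)
  if (ncol(data) != length(t)) stop("data columns must match time axis", call. = FALSE)
  structure(list(data = data, t = t, stage = stage, channels = channels,
                 pair_index = pair_index, layout = layout, pulse = pulse,
                 gate = gate),
            class = "imtr_signals")
}

#' @export
print.imtr_signals <- function(x, ...) {
  cat(sprintf("<imtr_signals> stage %s: %d trace(s) x %d samples\n",
              x$stage, nrow(x$data), ncol(x$data)))
  invisible(x)
}

.expect_stage <- function(x, expected) {
  if (!inherits(x, "imtr_signals"))
    stop("expected an imtr_signals object", call. = FALSE)
  if (!x$stage %in% expected)
    stop(sprintf("stage '%s' input where %s expected (stages advance E3 -> E4 -> pairs -> E5 -> E6 -> E7)",
                 x$stage, paste(expected, collapse = "/")), call. = FALSE)
  invisible(x)
}

# channel selection from an (n, n, nt) cube
.select_channels <- function(n, channels) {
  if (is.data.frame(channels)) return(channels)
  switch(channels,
    upper = {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      data.frame(tx = idx[, 1], rx = idx[, 2])
    },
    all = expand.grid(rx = seq_len(n), tx = seq_len(n))[, c("tx", "rx")],
    row1 = data.frame(tx = 1L, rx = seq_len(n)),
    stop(sprintf("unknown channel selection '%s'", channels), call. = FALSE)
  )
}

#' Calibrate a total acquisition against a background acquisition
#'
#' E3 = E2 - E1 per (tx, rx) channel: the elementwise difference between the
#' total (with-target) and background signal sets, flattened to a channel
#' list. The background may be either a target-free phantom acquisition or an
#' empty-domain acquisition.
#'
#' The excitation pulse carries appreciable DC content (its envelope is much
#' shorter than one modulation period), and a soft source with DC deposits a
#' static residual that survives background subtraction around the target.
#' Since physical UWB receivers are AC coupled, `detrend = TRUE` (default)
#' removes the sub-carrier drift by subtracting a per-channel running mean
#' over one modulation period.
#'
#' @param total `imtr_signalset`, role total (E2)
#' @param background `imtr_signalset`, role background (E1)
#' @param channels `"upper"` (tx < rx, default), `"all"`, `"row1"` (fixed
#'   transmitter), or a data.frame with columns `tx`, `rx`
#' @param detrend remove per-channel running-mean drift (window = one
#'   modulation period `1/f_r`)
#' @return `imtr_signals` at stage E3
#' @export
calibrate <- function(total, background, channels = "upper", detrend = TRUE) {
  stopifnot(inherits(total, "imtr_signalset"), inherits(background, "imtr_signalset"))
  if (!identical(dim(total$data), dim(background$data)))
    stop("total and background shapes differ", call. = FALSE)
  if (length(total$t) != length(background$t) ||
      max(abs(total$t - background$t)) > 1e-15)
    stop("total and background time axes differ", call. = FALSE)
  n <- dim(total$data)[1]
  ch <- .select_channels(n, channels)
  diff <- total$data - background$data
  m <- t(vapply(seq_len(nrow(ch)),
                function(k) diff[ch$tx[k], ch$rx[k], ], numeric(length(total$t))))
  if (isTRUE(detrend) && !is.null(total$pulse)) {
    dt <- total$t[2] - total$t[1]
    k <- as.integer(round(1 / (total$pulse$f_r * dt)))
    if (k >= 3) {
      if (k %% 2 == 0) k <- k + 1L
      m <- m - t(apply(m, 1, .movavg, k = k))
    }
  }
  processed_signals(m, total$t, "E3", channels = ch,
                    layout = total$layout, pulse = total$pulse)
}

#' Weighting and early-content removal
#'
#' Each calibrated channel is multiplied by a weighting factor and the
#' average (at each time sample) of the weighted signals is subtracted:
#' `E4_ch(t) = w * E3_ch(t) - mean(w * E3(t))`. With `group_by = "none"` the
#' average runs over all channels, removing content common to the whole set.
#' With `group_by = "separation"` (chosen automatically when the layout is
#' known) channels are grouped by the angular tx-rx separation on the ring:
#' for a rotationally symmetric phantom, equal-separation channels see
#' identical early-time skin/interface echoes, so the group average removes
#' them exactly while an off-center target - which breaks the symmetry -
#' survives. This is the rotated-reference flavor of early-time artifact
#' removal.
#'
#' @param e3 `imtr_signals` at stage E3
#' @param weight positive scalar weighting factor (default 1)
#' @param group_by `"auto"` (separation grouping when layout metadata is
#'   available), `"separation"`, or `"none"`
#' @return `imtr_signals` at stage E4
#' @export
early_content_removal <- function(e3, weight = 1,
                                  group_by = c("auto", "separation", "none")) {
  .expect_stage(e3, "E3")
  group_by <- match.arg(group_by)
  if (!is.numeric(weight) || weight <= 0) stop("weight must be > 0", call. = FALSE)
  w <- weight * e3$data
  if (nrow(w) == 1)
    warning("single-channel input: early-content removal is degenerate (E4 == 0)")
  if (group_by == "auto")
    group_by <- if (!is.null(e3$layout) && !is.null(e3$channels)) "separation" else "none"
  if (group_by == "separation") {
    th <- e3$layout$thetas
    dth <- abs((th[e3$channels$tx] - th[e3$channels$rx] + pi) %% (2 * pi) - pi)
    grp <- as.character(signif(dth, 8))
    e4 <- w
    for (g in unique(grp)) {
      rows <- which(grp == g)
      e4[rows, ] <- w[rows, , drop = FALSE] -
        matrix(colMeans(w[rows, , drop = FALSE]), length(rows), ncol(w), byrow = TRUE)
    }
  } else {
    e4 <- sweep(w, 2, colMeans(w), "-")
  }
  processed_signals(e4, e3$t, "E4", channels = e3$channels,
                    layout = e3$layout, pulse = e3$pulse)
}

#' Pairwise multiplication of channel signals
#'
#' One output trace per unordered channel pair (i < j), the elementwise
#' product `y_(i,j)(t) = S_i(t) * S_j(t)`, enumerated in lexicographic order:
#' for four channels y1 = S1 S2, y2 = S1 S3, y3 = S1 S4, y4 = S2 S3,
#' y5 = S2 S4, y6 = S3 S4.
#'
#' With `pairing = "shared_tx"` and multistatic channels, only receiver
#' traces sharing a transmitter are paired (for a 9-element ring this yields
#' the printed 36-pair enumeration per transmitting element).
#'
#' @param e4 `imtr_signals` at stage E4 (>= 2 channels)
#' @param pairing `"all"` (every unordered channel pair, the default) or
#'   `"shared_tx"` (pairs restricted to channels with a common transmitter)
#' @return `imtr_signals` at the pair stage with `pair_index`
#' @export
pair_multiply <- function(e4, pairing = c("all", "shared_tx")) {
  .expect_stage(e4, "E4")
  pairing <- match.arg(pairing)
  nch <- nrow(e4$data)
  if (nch < 2) stop("pair multiplication needs at least 2 channels", call. = FALSE)
  pr <- if (pairing == "shared_tx") {
    if (is.null(e4$channels)) stop("shared_tx pairing needs channel metadata", call. = FALSE)
    grp <- lapply(unique(e4$channels$tx), function(txv) {
      rows <- which(e4$channels$tx == txv)
      if (length(rows) >= 2) t(utils::combn(rows, 2))
    })
    do.call(rbind, grp)
  } else t(utils::combn(nch, 2))
  if (is.null(pr) || nrow(pr) < 1)
    stop("no channel pairs under the requested pairing", call. = FALSE)
  y <- e4$data[pr[, 1], , drop = FALSE] * e4$data[pr[, 2], , drop = FALSE]
  processed_signals(y, e4$t, "pairs", channels = e4$channels,
                    pair_index = data.frame(i = pr[, 1], j = pr[, 2]),
                    layout = e4$layout, pulse = e4$pulse)
}

#' Second averaging of the pair traces (clutter suppression)
#'
#' Two realizations are provided. `"cross_pair_mean"` (the pipeline default)
#' subtracts the across-pair average at each time sample, removing product
#' content common to all pairs while leaving each pair's own delay structure
#' - including the double-frequency phase the phase-conjugate backprojection
#' relies on - untouched. `"smooth"` instead applies a centered
#' moving-average kernel per trace (the pair product of two aligned
#' band-pass pulses carries a near-DC coherent term plus a double-frequency
#' term; the moving average retains the former). Per-pair traces and
#' `pair_index` are preserved either way.
#'
#' @param pairs `imtr_signals` at the pair stage
#' @param kernel odd moving-average length in samples for
#'   `method = "smooth"`; default = the pulse width `omega` in samples
#'   (at least 1); 1 is the identity
#' @param method `"cross_pair_mean"` or `"smooth"`
#' @return `imtr_signals` at stage E5
#' @export
average_pairs <- function(pairs, kernel = NULL,
                          method = c("cross_pair_mean", "smooth")) {
  .expect_stage(pairs, "pairs")
  method <- match.arg(method)
  if (!is.null(kernel)) method <- "smooth"
  if (method == "cross_pair_mean") {
    out <- if (nrow(pairs$data) > 1)
      sweep(pairs$data, 2, colMeans(pairs$data), "-")
    else pairs$data
  } else {
    if (is.null(kernel)) {
      dt <- diff(pairs$t[1:2])
      kernel <- if (!is.null(pairs$pulse)) max(1L, round(pairs$pulse$omega / dt)) else 1L
    }
    kernel <- as.integer(kernel)
    if (kernel < 1) stop("kernel length must be >= 1", call. = FALSE)
    if (kernel %% 2 == 0) kernel <- kernel + 1L
    out <- if (kernel == 1L) pairs$data else t(apply(pairs$data, 1, .movavg, k = kernel))
  }
  processed_signals(out, pairs$t, "E5", channels = pairs$channels,
                    pair_index = pairs$pair_index,
                    layout = pairs$layout, pulse = pairs$pulse)
}

# centered moving average; windows truncated at the record edges are
# normalized by their actual length so constants stay constant
.movavg <- function(x, k) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h - 1L, 0L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Time-gate window
#'
#' @param tE early time (s), the first front-wall skin echo
#' @param tL late time (s), the last back-wall round-trip echo
#' @return object of class `imtr_gate`
#' @export
gate_window <- function(tE, tL) {
  if (!(tE >= 0 && tE <= tL)) stop("need 0 <= tE <= tL", call. = FALSE)
  structure(list(tE = tE, tL = tL), class = "imtr_gate")
}

#' Estimate the time gate from geometry or from the signals
#'
#' Geometric mode traces straight rays at per-segment speeds `c/sqrt(eps_r)`:
#' the early time is the smallest over (tx, rx) pairs of the time for the
#' wave to reach the breast front wall (nearest skin point to the
#' transmitter) and travel on to the receiver; the late time is the largest
#' round trip that additionally crosses the breast to the back wall and
#' returns at the fat speed. Signal mode instead takes the first and last
#' crossings of a fraction of the envelope peak across channels.
#'
#' @param layout an `imtr_layout`
#' @param phantom an `imtr_phantom`
#' @param pulse an `imtr_pulse`
#' @param mode `"geometric"` (default) or `"signal"`
#' @param signals `imtr_signals`, required for `mode = "signal"`
#' @param threshold envelope fraction for signal mode (default 0.1)
#' @return a [gate_window()]
#' @export
estimate_gate <- function(layout, phantom, pulse,
                          mode = c("geometric", "signal"),
                          signals = NULL, threshold = 0.1) {
  mode <- match.arg(mode)
  if (mode == "signal") {
    if (is.null(signals)) stop("signal mode needs `signals`", call. = FALSE)
    env <- abs(analytic_signal(signals$data))
    peak <- max(env)
    on_t <- signals$t[colSums(env >= threshold * peak) > 0]
    if (!length(on_t)) stop("no samples above threshold", call. = FALSE)
    return(gate_window(min(on_t), max(on_t)))
  }
  R <- phantom$breast_radius
  pos <- layout$positions
  n <- layout$n
  v_fat <- .c0 / sqrt(phantom$tissues$fat$eps_r)
  tE_best <- Inf; tL_best <- 0
  for (i in seq_len(n)) {
    # front-wall point nearest the transmitter
    f <- pos[i, ] * (R / sqrt(sum(pos[i, ]^2)))
    d_tf <- sqrt(sum((pos[i, ] - f)^2))
    for (j in seq_len(n)) {
      d_fr <- sqrt(sum((f - pos[j, ])^2))
      tE_best <- min(tE_best, (d_tf + d_fr) / .c0)
      tL_best <- max(tL_best, (d_tf + d_fr) / .c0 + 4 * R / v_fat)
    }
  }
  gate_window(pulse$t0 + tE_best, pulse$t0 + tL_best)
}

#' Apply a time gate
#'
#' Samples strictly inside `(tE, tL)` are preserved; everything else is
#' zeroed.
#'
#' @param e5 `imtr_signals` at stage E5
#' @param gate a [gate_window()]
#' @return `imtr_signals` at stage E6
#' @export
time_gate <- function(e5, gate) {
  .expect_stage(e5, c("E5", "E6"))
  stopifnot(inherits(gate, "imtr_gate"))
  keep <- e5$t > gate$tE & e5$t < gate$tL
  if (!any(keep)) warning("empty time gate: output is all zero")
  out <- e5$data
  out[, !keep] <- 0
  processed_signals(out, e5$t, "E6", channels = e5$channels,
                    pair_index = e5$pair_index, layout = e5$layout,
                    pulse = e5$pulse, gate = gate)
}

#' Gaussian tapering window
#'
#' @param tp apex time (s)
#' @param tau tapering factor (s), > 0
#' @return object of class `imtr_window`
#' @export
window_spec <- function(tp, tau) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  structure(list(tp = tp, tau = tau), class = "imtr_window")
}

#' Apply the Gaussian taper
#'
#' `E7(t) = E6(t) * exp(-((t - tp)/tau)^2)`. The default window apex is the
#' gate midpoint with `tau = (tL - tE)/4`, so content near the gate edges
#' (residual skin echo) is strongly attenuated while mid-gate tumor returns
#' pass.
#'
#' @param e6 `imtr_signals` at stage E6
#' @param w a [window_spec()]; default derived from the carried gate
#' @return `imtr_signals` at stage E7, the IMTR preprocessing output
#' @export
gaussian_window <- function(e6, w = NULL) {
  .expect_stage(e6, "E6")
  if (is.null(w)) {
    if (is.null(e6$gate)) stop("no gate carried; supply a window_spec", call. = FALSE)
    w <- window_spec((e6$gate$tE + e6$gate$tL) / 2, (e6$gate$tL - e6$gate$tE) / 4)
  }
  stopifnot(inherits(w, "imtr_window"))
  taper <- exp(-((e6$t - w$tp) / w$tau)^2)
  processed_signals(sweep(e6$data, 2, taper, "*"), e6$t, "E7",
                    channels = e6$channels, pair_index = e6$pair_index,
                    layout = e6$layout, pulse = e6$pulse, gate = e6$gate)
}

#' Chain parameters for the IMTR preprocessing pipeline
#'
#' @param weight weighting factor for [early_content_removal()]
#' @param channels channel selection for [calibrate()]; the full pipeline
#'   defaults to `"all"` so pairs can be grouped by transmitter
#' @param pairing pairing mode for [pair_multiply()]
#' @param ecr_group grouping mode for [early_content_removal()]
#' @param e5_method averaging realization for [average_pairs()]
#' @param kernel moving-average kernel for `e5_method = "smooth"`
#' @param gate_mode `"geometric"` or `"signal"`
#' @param gate optional fixed [gate_window()] overriding estimation
#' @param window optional fixed [window_spec()]
#' @param gate_threshold envelope fraction for signal-mode gating
#' @return list of class `imtr_chain_params`
#' @export
chain_params <- function(weight = 1, channels = "all", pairing = "shared_tx",
                         ecr_group = "auto", e5_method = "cross_pair_mean",
                         kernel = NULL, gate_mode = "geometric", gate = NULL,
                         window = NULL, gate_threshold = 0.1) {
  structure(list(weight = weight, channels = channels, pairing = pairing,
                 ecr_group = ecr_group, e5_method = e5_method,
                 kernel = kernel, gate_mode = gate_mode, gate = gate,
                 window = window, gate_threshold = gate_threshold),
            class = "imtr_chain_params")
}

#' Run the complete IMTR preprocessing chain
#'
#' Composition calibrate -> early-content removal -> pair multiplication ->
#' temporal averaging -> time gating -> Gaussian windowing, producing the E7
#' pair traces that feed [imtr_image()].
#'
#' @param total,background `imtr_signalset` objects (roles E2 and E1)
#' @param phantom the `imtr_phantom` (needed for geometric gate estimation)
#' @param params a [chain_params()]
#' @param trace if `TRUE`, attach all intermediate stages as attribute
#'   `"stages"`
#' @return `imtr_signals` at stage E7
#' @export
imtr_chain <- function(total, background, phantom, params = chain_params(),
                       trace = FALSE) {
  stopifnot(inherits(params, "imtr_chain_params"))
  e3 <- calibrate(total, background, channels = params$channels)
  e4 <- early_content_removal(e3, weight = params$weight,
                              group_by = params$ecr_group)
  pp <- pair_multiply(e4, pairing = params$pairing)
  e5 <- average_pairs(pp, kernel = params$kernel, method = params$e5_method)
  gate <- params$gate
  if (is.null(gate)) {
    gate <- if (params$gate_mode == "signal")
      estimate_gate(total$layout, phantom, total$pulse, mode = "signal",
                    signals = e5, threshold = params$gate_threshold)
    else
      estimate_gate(total$layout, phantom, total$pulse)
  }
  gate <- gate_window(min(gate$tE, max(total$t)),
                      min(gate$tL, max(total$t) + diff(total$t[1:2])))
  e6 <- time_gate(e5, gate)
  e7 <- gaussian_window(e6, params$window)
  if (trace)
    attr(e7, "stages") <- list(E3 = e3, E4 = e4, pairs = pp, E5 = e5, E6 = e6)
  e7
}
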