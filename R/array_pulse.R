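#' Place antenna elements on a ring by the polar slot rule
#'
#' Antennas occupy slots on a circle of radius `gamma = r_max - d`; slot A
#' (1-based) sits at angle `theta_A = (A - 1) * 2 * pi / angular_slots`, so the
#' default 9-slot ring gives a 40 degree spacing. For `n < angular_slots`
#' either the first `n` slots are used (`placement = "contiguous"`, the
#' default) or `n` slots uniformly spread over the full circle
#' (`placement = "uniform"`).
#'
#' @param n number of antennas (>= 1)
#' @param r_max maximum ring radius in meters
#' @param d radial displacement in meters; the ring radius is `r_max - d`
#' @param angular_slots number of angular slots on the full ring (default 9)
#' @param placement `"contiguous"` or `"uniform"` sub-ring selection
#' @param breast_radius optional breast radius in meters; when given, the
#'   5 mm antenna standoff is enforced
#' @param standoff minimum antenna-to-skin clearance in meters (default 5 mm)
#' @return an object of class `imtr_layout` with fields `n`, `r_max`, `d`,
#'   `gamma`, `thetas` (rad), `positions` (n x 2 matrix, meters)
#' @export
place_antennas <- function(n, r_max, d = 0, angular_slots = 9,
                           placement = c("contiguous", "uniform"),
                           breast_radius = NULL, standoff = 5e-3) {
  placement <- match.arg(placement)
  stopifnot(n >= 1, angular_slots >= 1, r_max > 0)
  gamma <- r_max - d
  if (gamma <= 0) stop("r_max - d must be positive", call. = FALSE)
  if (!is.null(breast_radius) && gamma < breast_radius + standoff)
    stop(sprintf("standoff violation: ring radius %.1f mm < breast %.1f mm + %.0f mm",
                 gamma * 1e3, breast_radius * 1e3, standoff * 1e3), call. = FALSE)
  slots <- if (placement == "contiguous" || n >= angular_slots) {
    seq_len(n)
  } else {
    # n uniformly spaced picks over the full circle (fractional slots allowed)
    1 + (seq_len(n) - 1) * angular_slots / n
  }
  thetas <- (slots - 1) * 2 * pi / angular_slots
  positions <- cbind(gamma * cos(thetas), gamma * sin(thetas))
  colnames(positions) <- c("x", "y")
  structure(list(n = as.integer(n), r_max = r_max, d = d, gamma = gamma,
                 angular_slots = as.integer(angular_slots),
                 placement = placement, thetas = thetas, positions = positions),
            class = "imtr_layout")
}

#' @export
print.imtr_layout <- function(x, ...) {
  cat(sprintf("<imtr_layout> %d antenna(s) on a %d-slot ring of radius %.1f mm (%s)\n",
              x$n, x$angular_slots, x$gamma * 1e3, x$placement))
  invisible(x)
}

#' Modulated Gaussian excitation pulse specification
#'
#' S(t) = exp(-(t - t0)^2 / (2 omega^2)) * cos(2 pi f_r t). Defaults follow
#' the reference system: modulation frequency 2.4 GHz and envelope width
#' 78.1 ps, which makes the pulse ultra-wideband (several GHz at -10 dB).
#' `t0` defaults to `5 * omega` so the pulse switches on near zero amplitude.
#'
#' @param f_r modulation frequency in Hz
#' @param omega Gaussian envelope width in seconds (> 0)
#' @param t0 envelope center in seconds
#' @return an object of class `imtr_pulse`
#' @export
pulse_spec <- function(f_r = 2.4e9, omega = 78.1e-12, t0 = 5 * omega) {
  if (!is.numeric(omega) || length(omega) != 1 || omega <= 0)
    stop("omega (pulse width) must be > 0", call. = FALSE)
  stopifnot(f_r > 0, t0 >= 0)
  structure(list(f_r = f_r, omega = omega, t0 = t0), class = "imtr_pulse")
}

#' @export
print.imtr_pulse <- function(x, ...) {
  cat(sprintf("<imtr_pulse> f_r = %.2f GHz, omega = %.1f ps, t0 = %.1f ps\n",
              x$f_r / 1e9, x$omega * 1e12, x$t0 * 1e12))
  invisible(x)
}

#' Sample the modulated Gaussian pulse on a time axis
#'
#' @param spec a [pulse_spec()]
#' @param t numeric vector of sample times in seconds (uniformly spaced)
#' @return numeric vector of samples, bounded in \[-1, 1\]
#' @export
gaussian_modulated_pulse <- function(spec, t) {
  stopifnot(inherits(spec, "imtr_pulse"), is.numeric(t))
  exp(-(t - spec$t0)^2 / (2 * spec$omega^2)) * cos(2 * pi * spec$f_r * t)
}
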