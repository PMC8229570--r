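#' Clutter-free reference image for similarity scoring
#'
#' A binary map that is 1 inside a disc at each tumor center and 0
#' elsewhere. The disc diameter defaults to 4 mm irrespective of the
#' simulated tumor size (the conventional reference definition for this
#' scoring protocol); optional Gaussian edge smoothing softens the rim.
#'
#' @param grid an [image_grid()]
#' @param tumors list of [tumor_spec()] objects (possibly empty)
#' @param diameter reference disc diameter in meters (default 4 mm)
#' @param smooth_sigma_px Gaussian edge smoothing in pixels (0 = off)
#' @return an `imtr_image`
#' @export
make_reference_image <- function(grid, tumors, diameter = 4e-3,
                                 smooth_sigma_px = 0) {
  px <- rep(grid$x, times = grid$ny)
  py <- rep(grid$y, each = grid$nx)
  img <- numeric(length(px))
  r2 <- (diameter / 2)^2
  for (tm in tumors)
    img[(px - tm$center[1])^2 + (py - tm$center[2])^2 <= r2] <- 1
  m <- matrix(img, grid$nx, grid$ny)
  if (smooth_sigma_px > 0)
    m <- .gauss_blur(m, smooth_sigma_px)
  out <- .new_image(m, grid)
  if (length(tumors) == 0) out$intensity[] <- 0
  out
}

.gauss_kernel_1d <- function(sigma, half = ceiling(3 * sigma)) {
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

.gauss_blur <- function(m, sigma) {
  k <- .gauss_kernel_1d(sigma)
  m <- apply(m, 2, function(col) .conv_same(col, k))
  t(apply(m, 1, function(row) .conv_same(row, k)))
}

.conv_same <- function(x, k) {
  h <- (length(k) - 1) / 2
  xp <- c(numeric(h), x, numeric(h))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(h + 1):(h + length(x))])
}

.as_intensity <- function(x) {
  m <- if (inherits(x, "imtr_image")) x$intensity else as.matrix(x)
  mx <- max(m)
  if (mx > 0) m / mx else m
}

# local means via 2-D Gaussian-weighted window, 'valid' region only
.local_stats <- function(a, b, kernel) {
  kh <- nrow(kernel)
  conv2v <- function(m) {
    nr <- nrow(m) - kh + 1; nc <- ncol(m) - kh + 1
    out <- matrix(0, nr, nc)
    for (di in seq_len(kh)) for (dj in seq_len(kh)) {
      w <- kernel[di, dj]
      if (w != 0)
        out <- out + w * m[di:(di + nr - 1), dj:(dj + nc - 1)]
    }
    out
  }
  list(mu1 = conv2v(a), mu2 = conv2v(b),
       e11 = conv2v(a * a), e22 = conv2v(b * b), e12 = conv2v(a * b))
}

#' Structural similarity index between a reconstruction and a reference
#'
#' Mean SSIM with a 7x7 Gaussian window (sigma = 1.5), stabilizers
#' K1 = 0.01, K2 = 0.03 on dynamic range L = 1. Both inputs are
#' max-normalized to \[0, 1\] before comparison, so the index is invariant
#' to a global positive scaling of either image.
#'
#' @param image,ref `imtr_image` objects or numeric matrices of equal shape
#' @param K1,K2 stabilizer constants
#' @param win_size odd window size (default 7)
#' @param win_sigma Gaussian window sigma in pixels (default 1.5)
#' @return scalar mean SSIM in \[-1, 1\]
#' @export
ssim <- function(image, ref, K1 = 0.01, K2 = 0.03, win_size = 7,
                 win_sigma = 1.5) {
  a <- .as_intensity(image)
  b <- .as_intensity(ref)
  if (!all(dim(a) == dim(b)))
    stop("image and reference shapes differ", call. = FALSE)
  half <- (win_size - 1) / 2
  k1d <- .gauss_kernel_1d(win_sigma, half)
  kernel <- outer(k1d, k1d)
  st <- .local_stats(a, b, kernel)
  C1 <- K1^2; C2 <- K2^2   # L = 1
  v1 <- st$e11 - st$mu1^2
  v2 <- st$e22 - st$mu2^2
  cov <- st$e12 - st$mu1 * st$mu2
  smap <- ((2 * st$mu1 * st$mu2 + C1) * (2 * cov + C2)) /
    ((st$mu1^2 + st$mu2^2 + C1) * (v1 + v2 + C2))
  mean(smap)
}

#' Mean squared error between normalized images
#'
#' @param image,ref `imtr_image` objects or numeric matrices of equal shape
#' @return scalar MSE (>= 0)
#' @export
mse <- function(image, ref) {
  a <- .as_intensity(image)
  b <- .as_intensity(ref)
  if (!all(dim(a) == dim(b)))
    stop("image and reference shapes differ", call. = FALSE)
  mean((a - b)^2)
}

#' Detect and match intensity peaks to true target locations
#'
#' Finds the `n_targets` strongest local maxima separated by at least
#' `min_separation`, then greedily matches detections to the true centers by
#' increasing distance. Unmatched truths are reported as misses (error `NA`),
#' never as an exception.
#'
#' @param image an `imtr_image`
#' @param truths list of length-2 centers (m) or an n x 2 matrix
#' @param n_targets number of peaks to extract (>= 1)
#' @param min_separation minimum peak separation in meters (default 5 mm)
#' @return list with `peaks` (matrix of detected (x, y)), `errors` (per-truth
#'   Euclidean error in meters, `NA` for misses), `n_missed`
#' @export
localize <- function(image, truths, n_targets = NULL, min_separation = 5e-3) {
  if (is.list(truths)) truths <- do.call(rbind, lapply(truths, function(p) {
    if (inherits(p, "imtr_tumor")) p$center else as.numeric(p)
  }))
  truths <- rbind(truths)
  if (is.null(n_targets)) n_targets <- nrow(truths)
  stopifnot(n_targets >= 1)
  m <- image$intensity
  nx <- nrow(m); ny <- ncol(m)
  # 8-neighbor local maxima, plateau-tolerant: a cell qualifies when no
  # neighbor exceeds it and it rises above the image floor; flat images
  # (constant everywhere) yield none
  pad <- matrix(-Inf, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- m
  ismax <- matrix(TRUE, nx, ny)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (m >= pad[(2 + di):(nx + 1 + di), (2 + dj):(ny + 1 + dj)])
  }
  ismax <- ismax & (m > min(m))
  cand <- which(ismax, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(list(peaks = matrix(numeric(0), 0, 2),
                errors = rep(NA_real_, nrow(truths)), n_missed = nrow(truths)))
  vals <- m[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  sel <- matrix(numeric(0), 0, 2)
  for (r in seq_len(nrow(cand))) {
    p <- .plateau_centroid(m, cand[r, 1], cand[r, 2], image$x, image$y)
    if (nrow(sel) == 0 ||
        min(sqrt(rowSums(sweep(sel, 2, p)^2))) >= min_separation)
      sel <- rbind(sel, p)
    if (nrow(sel) >= n_targets) break
  }
  errors <- rep(NA_real_, nrow(truths))
  if (nrow(sel) > 0) {
    D <- outer(seq_len(nrow(truths)), seq_len(nrow(sel)),
               Vectorize(function(i, j) sqrt(sum((truths[i, ] - sel[j, ])^2))))
    D <- rbind(D)
    dim(D) <- c(nrow(truths), nrow(sel))
    while (any(is.finite(D))) {
      ij <- which(D == min(D), arr.ind = TRUE)[1, ]
      errors[ij[1]] <- D[ij[1], ij[2]]
      D[ij[1], ] <- Inf
      D[, ij[2]] <- Inf
    }
  }
  list(peaks = unname(sel), errors = errors, n_missed = sum(is.na(errors)))
}

# centroid of the flat plateau (equal-valued connected region) containing
# cell (i0, j0); a binary reference disc thus localizes to its center
.plateau_centroid <- function(m, i0, j0, xax, yax) {
  v0 <- m[i0, j0]
  tol <- 1e-9 * max(abs(v0), 1e-300)
  nx <- nrow(m); ny <- ncol(m)
  seen <- matrix(FALSE, nx, ny)
  queue <- matrix(c(i0, j0), 1, 2)
  seen[i0, j0] <- TRUE
  cells <- queue
  while (nrow(queue)) {
    nxt <- NULL
    for (r in seq_len(nrow(queue))) {
      i <- queue[r, 1]; j <- queue[r, 2]
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nx || jj < 1 || jj > ny || seen[ii, jj]) next
        if (abs(m[ii, jj] - v0) <= tol) {
          seen[ii, jj] <- TRUE
          nxt <- rbind(nxt, c(ii, jj))
        }
      }
    }
    if (is.null(nxt)) break
    cells <- rbind(cells, nxt)
    queue <- nxt
  }
  c(mean(xax[cells[, 1]]), mean(yax[cells[, 2]]))
}

#' Empirical range / cross-range resolution from the point-spread function
#'
#' Images a single Born point scatterer with (unweighted) delay-and-sum and
#' measures the full width at half maximum of the PSF along the radial
#' (range) and tangential (cross-range) directions through the peak.
#'
#' @param layout an `imtr_layout`
#' @param pulse a [pulse_spec()]
#' @param dm a [delay_model()] (homogeneous, speed matching the Born model)
#' @param scatterer length-2 scatterer position in meters
#' @param grid an [image_grid()]; default covers the array interior
#' @param v Born propagation speed (m/s)
#' @return list `fwhm_range`, `fwhm_crossrange` (m) and the `image`
#' @export
empirical_resolution <- function(layout, pulse, dm = NULL,
                                 scatterer = c(20e-3, 0), grid = NULL,
                                 v = .c0) {
  if (is.null(dm)) dm <- delay_model("homogeneous", speed = v)
  if (is.null(grid)) {
    R <- layout$gamma * 0.8
    grid <- image_grid(c(-R, R, -R, R), 0.5e-3)
  }
  ss <- born_point_scatterer(layout, list(list(center = scatterer, amp = 1)), pulse, v)
  e3 <- signalset_channels(ss)
  img <- mwdas_image(e3, layout, grid, dm, weights = 1)
  pk <- image_argmax(img)
  u <- if (sqrt(sum(pk^2)) > grid$pixel) pk / sqrt(sum(pk^2)) else c(1, 0)
  ucross <- c(-u[2], u[1])
  list(fwhm_range = .profile_fwhm(img, pk, u),
       fwhm_crossrange = .profile_fwhm(img, pk, ucross),
       image = img)
}

# FWHM of the image profile through `center` along unit vector `u`
.profile_fwhm <- function(img, center, u, half_span = NULL) {
  if (is.null(half_span))
    half_span <- 0.45 * min(diff(img$extent[1:2]), diff(img$extent[3:4]))
  s <- seq(-half_span, half_span, by = img$pixel / 2)
  qx <- center[1] + s * u[1]
  qy <- center[2] + s * u[2]
  vals <- .bilinear(img, qx, qy)
  pk_i <- which.max(vals)
  half <- vals[pk_i] / 2
  right <- which(vals[pk_i:length(vals)] < half)
  left <- which(vals[pk_i:1] < half)
  if (!length(right) || !length(left)) return(NA_real_)
  # linear interpolation at the crossings
  ri <- pk_i + right[1] - 1
  fr <- (vals[ri - 1] - half) / (vals[ri - 1] - vals[ri])
  li <- pk_i - left[1] + 1
  fl <- (vals[li + 1] - half) / (vals[li + 1] - vals[li])
  ((right[1] - 2 + fr) + (left[1] - 2 + fl)) * img$pixel / 2
}

.bilinear <- function(img, qx, qy) {
  x <- img$x; y <- img$y
  fx <- (qx - x[1]) / img$pixel
  fy <- (qy - y[1]) / img$pixel
  i0 <- pmin(pmax(floor(fx), 0), length(x) - 2)
  j0 <- pmin(pmax(floor(fy), 0), length(y) - 2)
  tx <- pmin(pmax(fx - i0, 0), 1)
  ty <- pmin(pmax(fy - j0, 0), 1)
  m <- img$intensity
  idx <- function(i, j) m[cbind(i + 1, j + 1)]
  (1 - tx) * (1 - ty) * idx(i0, j0) + tx * (1 - ty) * idx(i0 + 1, j0) +
    (1 - tx) * ty * idx(i0, j0 + 1) + tx * ty * idx(i0 + 1, j0 + 1)
}

#' Flatten a signal set into calibrated-style channel signals
#'
#' Convenience for oracle data (e.g. the Born model) where no background
#' subtraction is needed: selects channels from the (tx, rx, time) cube and
#' tags them stage E3.
#'
#' @param ss an `imtr_signalset`
#' @param channels channel selection as in [calibrate()]
#' @return `imtr_signals` at stage E3
#' @export
signalset_channels <- function(ss, channels = "upper") {
  stopifnot(inherits(ss, "imtr_signalset"))
  n <- dim(ss$data)[1]
  ch <- .select_channels(n, channels)
  m <- t(vapply(seq_len(nrow(ch)),
                function(k) ss$data[ch$tx[k], ch$rx[k], ], numeric(length(ss$t))))
  processed_signals(m, ss$t, "E3", channels = ch, layout = ss$layout,
                    pulse = ss$pulse)
}

#' Bundle reconstruction scores into a report
#'
#' @param ssim scalar SSIM
#' @param mse scalar MSE
#' @param localization_errors numeric vector (m), `NA` = miss
#' @param detected_peaks n x 2 matrix of detected (x, y) in meters
#' @param fwhm_range,fwhm_crossrange optional lengths (m)
#' @return object of class `imtr_metrics`
#' @export
metrics_report <- function(ssim, mse, localization_errors = numeric(0),
                           detected_peaks = matrix(numeric(0), 0, 2),
                           fwhm_range = NA_real_, fwhm_crossrange = NA_real_) {
  stopifnot(ssim <= 1 + 1e-12, mse >= 0)
  structure(list(ssim = ssim, mse = mse,
                 localization_errors = localization_errors,
                 detected_peaks = detected_peaks,
                 fwhm_range = fwhm_range, fwhm_crossrange = fwhm_crossrange),
            class = "imtr_metrics")
}

#' Serialize a metrics report to JSON
#' @param report an `imtr_metrics`
#' @param path optional file path; when `NULL` the JSON string is returned
#' @return JSON string (invisibly when written to file)
#' @export
write_metrics <- function(report, path = NULL) {
  obj <- unclass(report)
  obj$detected_peaks <- if (nrow(report$detected_peaks))
    lapply(seq_len(nrow(report$detected_peaks)),
           function(i) as.numeric(report$detected_peaks[i, ]))
  else list()
  js <- jsonlite::toJSON(obj, digits = NA, null = "null", na = "null",
                         auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a metrics report back from JSON
#' @param path file path or JSON string
#' @return an `imtr_metrics`
#' @export
read_metrics <- function(path) {
  obj <- jsonlite::fromJSON(path)
  pk <- if (length(obj$detected_peaks)) {
    p <- obj$detected_peaks
    if (is.list(p)) do.call(rbind, lapply(p, as.numeric)) else rbind(as.matrix(p))
  } else matrix(numeric(0), 0, 2)
  metrics_report(obj$ssim, obj$mse,
                 localization_errors = as.numeric(obj$localization_errors),
                 detected_peaks = pk,
                 fwhm_range = obj$fwhm_range %||% NA_real_,
                 fwhm_crossrange = obj$fwhm_crossrange %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
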