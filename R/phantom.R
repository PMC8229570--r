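#' Tissue dielectric specification
#'
#' Frequency-independent relative permittivity and conductivity for one tissue
#' class. The phantom model is non-dispersive: properties are taken at band
#' center, and magnetic permeability is the vacuum value everywhere.
#'
#' @param name tissue label
#' @param eps_r relative permittivity (dimensionless, >= 1)
#' @param sigma conductivity in S/m (>= 0)
#' @return an object of class `imtr_tissue`
#' @export
tissue_spec <- function(name, eps_r, sigma) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(eps_r) || length(eps_r) != 1 || eps_r < 1)
    stop("eps_r must be a single number >= 1", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop("sigma must be a single number >= 0 (S/m)", call. = FALSE)
  structure(list(name = name, eps_r = eps_r, sigma = sigma),
            class = "imtr_tissue")
}

#' Default tissue table
#'
#' Literature-typical constant dielectric properties for the background (air),
#' breast fat, skin, and tumor. The malignant/fat permittivity ratio (about
#' 9.8) honors the reported 2-10x contrast between healthy and unhealthy
#' tissue.
#'
#' @return named list of [tissue_spec()] objects
#' @export
default_tissues <- function() {
  list(
    background = tissue_spec("background", 1, 0),
    fat        = tissue_spec("fat", 5.1, 0.14),
    skin       = tissue_spec("skin", 36, 4),
    tumor      = tissue_spec("tumor", 50, 7)
  )
}

#' Tumor specification
#'
#' @param center numeric length-2 center (x, y) in meters
#' @param radius tumor radius in meters (> 0)
#' @return an object of class `imtr_tumor`
#' @export
tumor_spec <- function(center, radius) {
  stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)))
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("tumor radius must be > 0", call. = FALSE)
  structure(list(center = as.numeric(center), radius = radius),
            class = "imtr_tumor")
}

#' Build a 2-D dielectric breast phantom
#'
#' Paints nested regions (background < fat disc < skin shell < tumors) onto
#' permittivity and conductivity maps on a uniform square grid. Coordinates
#' are in meters with the origin at the breast center; cell centers sit at
#' half-integer multiples of the grid spacing so no cell center lies exactly
#' at the origin.
#'
#' @param breast_radius outer breast radius in meters
#' @param skin_thickness skin shell thickness in meters (default 2 mm)
#' @param tumors list of [tumor_spec()] objects (may be empty)
#' @param tissues named list with entries `background`, `fat`, `skin`,
#'   `tumor` (see [default_tissues()])
#' @param grid_spacing cell size in meters
#' @param domain_half half-width of the square computational domain in meters;
#'   defaults to `breast_radius + 30 mm` which leaves room for a 5 mm antenna
#'   standoff ring plus PML
#' @param pulse a [pulse_spec()] used for the grid-resolution check
#' @param min_cells_per_wavelength required number of cells per shortest
#'   in-tissue wavelength at the pulse's -10 dB upper band edge (default 10)
#' @param contrast_band allowed range for tumor/fat permittivity ratio
#' @return an object of class `imtr_phantom` with fields `eps`, `sigma`
#'   (matrices indexed (x cell, y cell)), `x`, `y` (cell-center coordinates),
#'   `region` (integer label map: 0 background, 1 fat, 2 skin, 3.. tumors),
#'   `dx`, `breast_radius`, `skin_thickness`, `tumors`, `tissues`
#' @export
build_phantom <- function(breast_radius,
                          skin_thickness = 2e-3,
                          tumors = list(),
                          tissues = default_tissues(),
                          grid_spacing = 0.7e-3,
                          domain_half = breast_radius + 30e-3,
                          pulse = pulse_spec(),
                          min_cells_per_wavelength = 10,
                          contrast_band = c(2, 10)) {
  stopifnot(breast_radius > 0, skin_thickness > 0, grid_spacing > 0)
  if (inherits(tumors, "imtr_tumor")) tumors <- list(tumors)
  for (tm in tumors) {
    if (!inherits(tm, "imtr_tumor")) stop("tumors must be tumor_spec objects", call. = FALSE)
    if (sqrt(sum(tm$center^2)) + tm$radius > breast_radius)
      stop(sprintf("tumor at (%.1f, %.1f) mm with radius %.2f mm lies outside the breast",
                   tm$center[1] * 1e3, tm$center[2] * 1e3, tm$radius * 1e3), call. = FALSE)
  }
  ratio <- tissues$tumor$eps_r / tissues$fat$eps_r
  if (ratio < contrast_band[1] || ratio > contrast_band[2])
    stop(sprintf("tumor/fat permittivity contrast %.2f outside the allowed band [%g, %g]",
                 ratio, contrast_band[1], contrast_band[2]), call. = FALSE)

  # resolution check: >= min_cells cells per shortest in-tissue wavelength at
  # the upper band edge
  if (!is.null(min_cells_per_wavelength) && min_cells_per_wavelength > 0) {
    eps_max <- max(vapply(tissues, function(t) t$eps_r, numeric(1)))
    f_up <- pulse_band_edge(pulse)
    lambda_min <- .c0 / (f_up * sqrt(eps_max))
    cells <- lambda_min / grid_spacing
    if (cells < min_cells_per_wavelength)
      stop(sprintf(paste0("grid_spacing %.3g mm resolves the shortest in-tissue wavelength ",
                          "(%.2f mm at %.2f GHz in eps_r=%.1f) by only %.1f cells; ",
                          "%g required"),
                   grid_spacing * 1e3, lambda_min * 1e3, f_up / 1e9, eps_max, cells,
                   min_cells_per_wavelength), call. = FALSE)
  }
  if (domain_half < breast_radius + 5e-3 + 10 * grid_spacing - 1e-9)
    stop("domain too small: need breast + 5 mm standoff + >= 10 cells margin", call. = FALSE)

  n <- 2L * as.integer(ceiling(domain_half / grid_spacing))
  xs <- (seq_len(n) - n / 2 - 0.5) * grid_spacing
  ys <- xs
  X <- matrix(xs, n, n)
  Y <- matrix(ys, n, n, byrow = TRUE)
  R2 <- X^2 + Y^2

  region <- matrix(0L, n, n)
  region[R2 <= breast_radius^2] <- 1L                       # fat
  inner <- (breast_radius - skin_thickness)^2
  region[R2 <= breast_radius^2 & R2 > inner] <- 2L          # skin shell
  for (k in seq_along(tumors)) {
    tm <- tumors[[k]]
    region[(X - tm$center[1])^2 + (Y - tm$center[2])^2 <= tm$radius^2] <- 2L + k
  }

  eps <- matrix(tissues$background$eps_r, n, n)
  sig <- matrix(tissues$background$sigma, n, n)
  eps[region == 1L] <- tissues$fat$eps_r
  sig[region == 1L] <- tissues$fat$sigma
  eps[region == 2L] <- tissues$skin$eps_r
  sig[region == 2L] <- tissues$skin$sigma
  eps[region >= 3L] <- tissues$tumor$eps_r
  sig[region >= 3L] <- tissues$tumor$sigma

  structure(list(eps = eps, sigma = sig, region = region,
                 x = xs, y = ys, dx = grid_spacing,
                 breast_radius = breast_radius, skin_thickness = skin_thickness,
                 tumors = tumors, tissues = tissues, domain_half = domain_half),
            class = "imtr_phantom")
}

#' @export
print.imtr_phantom <- function(x, ...) {
  cat(sprintf("<imtr_phantom> %d x %d cells at %.2f mm; breast radius %.0f mm, %d tumor(s)\n",
              nrow(x$eps), ncol(x$eps), x$dx * 1e3, x$breast_radius * 1e3,
              length(x$tumors)))
  invisible(x)
}

#' Per-region cell counts of a phantom
#'
#' @param phantom an `imtr_phantom`
#' @return named integer vector (background, fat, skin, tumor_1, ...)
#' @export
region_cell_counts <- function(phantom) {
  labs <- sort(unique(as.vector(phantom$region)))
  counts <- vapply(labs, function(l) sum(phantom$region == l), integer(1))
  names(counts) <- vapply(labs, function(l) {
    if (l == 0) "background" else if (l == 1) "fat" else if (l == 2) "skin"
    else paste0("tumor_", l - 2)
  }, character(1))
  counts
}

# nearest-cell index for a physical coordinate
.cell_index <- function(phantom_axis, pos) {
  idx <- which.min(abs(phantom_axis - pos))
  as.integer(idx)
}
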