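#' Save / load a signal set
#'
#' Signal sets persist as RDS containers (self-describing R serialization);
#' round-trips are bit exact.
#'
#' @param ss an `imtr_signalset`
#' @param path file path (conventionally `.rds`)
#' @return `load_signalset` returns the `imtr_signalset`
#' @export
save_signalset <- function(ss, path) {
  stopifnot(inherits(ss, "imtr_signalset"))
  saveRDS(ss, path, version = 2)
  invisible(path)
}

#' @rdname save_signalset
#' @export
load_signalset <- function(path) {
  ss <- readRDS(path)
  stopifnot(inherits(ss, "imtr_signalset"))
  ss
}

#' Write an image as CSV (plain intensity matrix with coordinate headers)
#' @param image an `imtr_image`
#' @param path file path
#' @export
write_image_csv <- function(image, path) {
  m <- image$intensity
  df <- data.frame(x_mm = rep(image$x, times = length(image$y)) * 1e3,
                   y_mm = rep(image$y, each = length(image$x)) * 1e3,
                   intensity = as.vector(m))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Render an image to PNG with physical axes (requires the png package)
#' @param image an `imtr_image`
#' @param path file path
#' @export
write_image_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    warning("png package not available; skipping PNG output")
    return(invisible(NULL))
  }
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  graphics::image(image$x * 1e3, image$y * 1e3, image$intensity,
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "x (mm)", ylab = "y (mm)", asp = 1, useRaster = TRUE)
  invisible(path)
}

#' Run a complete imaging scenario
#'
#' Simulates background and total acquisitions with the FDTD solver, runs the
#' IMTR preprocessing chain, reconstructs the requested algorithms, scores
#' each against the clutter-free reference image, and writes all artifacts
#' plus a run manifest to `out_dir`.
#'
#' @param scenario an `imtr_scenario` from [scenario_catalogue()] /
#'   [load_scenario()], or a scenario name, or a YAML path
#' @param algorithms subset of `c("mwdas", "fdmas", "tr", "imtr")` or
#'   `"all"`
#' @param out_dir output directory (created if needed); `NULL` = no files
#' @param seed integer seed; the pipeline is deterministic, the seed covers
#'   optional stochastic additions such as receiver noise
#' @param noise_sd receiver noise standard deviation relative to the peak
#'   signal (0 = off, the default)
#' @param tr_mode `"numeric"` (default) or `"synthetic"` time reversal
#' @param signals optional precomputed list with elements `total` and
#'   `background` (`imtr_signalset`) to reuse instead of re-simulating
#' @return a run manifest list: scenario id, config hash, seed, images,
#'   metrics (data.frame), artifact paths
#' @export
run_scenario <- function(scenario, algorithms = "all", out_dir = NULL,
                         seed = 1, noise_sd = 0, tr_mode = "numeric",
                         signals = NULL) {
  if (is.character(scenario)) {
    scenario <- if (file.exists(scenario)) load_scenario(scenario)
                else scenario_catalogue(scenario)
  }
  stopifnot(inherits(scenario, "imtr_scenario"))
  algs <- c("mwdas", "fdmas", "tr", "imtr")
  if (identical(algorithms, "all")) algorithms <- algs
  bad <- setdiff(algorithms, algs)
  if (length(bad))
    stop(sprintf("unknown algorithm name(s) in `algorithms`: %s (valid: %s)",
                 paste(bad, collapse = ", "), paste(algs, collapse = ", ")),
         call. = FALSE)
  set.seed(seed)

  sc <- scenario
  if (is.null(signals)) {
    background_phantom <- if (identical(sc$background_mode, "empty")) {
      build_phantom(sc$phantom$breast_radius, sc$phantom$skin_thickness,
                    tumors = list(), tissues = .air_tissues(sc$phantom$tissues),
                    grid_spacing = sc$phantom$dx,
                    domain_half = sc$phantom$domain_half, pulse = sc$pulse,
                    min_cells_per_wavelength = 0, contrast_band = c(0, Inf))
    } else sc$phantom_background
    total <- simulate_multistatic(sc$phantom, sc$layout, sc$pulse, sc$cfg,
                                  role = "total")
    cfg_bg <- sc$cfg
    cfg_bg$n_timesteps <- length(total$t)   # identical record for both roles
    background <- simulate_multistatic(background_phantom, sc$layout, sc$pulse,
                                       cfg_bg, role = "background")
  } else {
    total <- signals$total
    background <- signals$background
  }
  if (noise_sd > 0) {
    amp <- max(abs(total$data))
    total$data <- total$data + stats::rnorm(length(total$data), 0, noise_sd * amp)
    background$data <- background$data +
      stats::rnorm(length(background$data), 0, noise_sd * amp)
  }

  grid <- grid_for_phantom(sc$phantom, pad = sc$image$pad, pixel = sc$image$pixel)
  dm <- delay_model("layered", phantom = sc$phantom)
  e3 <- calibrate(total, background, channels = sc$chain$channels)
  e7 <- imtr_chain(total, background, sc$phantom, sc$chain)

  cfg_tr <- sc$cfg
  cfg_tr$n_timesteps <- length(total$t)
  images <- list()
  for (alg in algorithms) {
    images[[alg]] <- switch(alg,
      mwdas = mwdas_image(e3, sc$layout, grid, dm),
      fdmas = fdmas_image(e3, sc$layout, grid, dm),
      tr = tr_image(e3, sc$layout, grid, dm,
                    phantom_background = sc$phantom_background,
                    mode = tr_mode, cfg = cfg_tr),
      imtr = imtr_image(e7, sc$layout, grid, dm))
    # the reconstruction domain is the sample under test: restrict every
    # algorithm's image to the breast disc and renormalize
    images[[alg]] <- mask_image_disc(images[[alg]], sc$phantom$breast_radius)
  }

  ref <- make_reference_image(grid, sc$phantom$tumors)
  truths <- lapply(sc$phantom$tumors, function(tm) tm$center)
  metrics <- do.call(rbind, lapply(names(images), function(alg) {
    img <- images[[alg]]
    loc <- if (length(truths)) localize(img, truths)
           else list(errors = numeric(0), n_missed = 0L)
    data.frame(scenario = sc$name, algorithm = alg,
               ssim = ssim(img, ref), mse = mse(img, ref),
               max_loc_error_mm = if (length(loc$errors) && !all(is.na(loc$errors)))
                 max(loc$errors, na.rm = TRUE) * 1e3 else NA_real_,
               n_missed = loc$n_missed)
  }))

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$total <- file.path(out_dir, "signals_total.rds")
    paths$background <- file.path(out_dir, "signals_background.rds")
    save_signalset(total, paths$total)
    save_signalset(background, paths$background)
    for (alg in names(images)) {
      paths[[paste0("image_", alg, "_csv")]] <-
        write_image_csv(images[[alg]], file.path(out_dir, paste0("image_", alg, ".csv")))
      p <- write_image_png(images[[alg]], file.path(out_dir, paste0("image_", alg, ".png")))
      if (!is.null(p)) paths[[paste0("image_", alg, "_png")]] <- p
    }
    paths$metrics <- file.path(out_dir, "metrics.csv")
    utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  }

  manifest <- list(scenario = sc$name, seed = seed,
                   config_hash = config_hash(sc$config),
                   package_version = as.character(utils::packageVersion("imtr")),
                   algorithms = algorithms,
                   artifacts = paths)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest$artifacts$manifest <- file.path(out_dir, "manifest.json")
  }
  manifest$images <- images
  manifest$metrics <- metrics
  manifest$signals <- list(total = total, background = background)
  manifest$e7 <- e7
  invisible(manifest)
}

.air_tissues <- function(tissues) {
  bg <- tissues$background
  list(background = bg,
       fat = tissue_spec("fat", bg$eps_r, bg$sigma),
       skin = tissue_spec("skin", bg$eps_r, bg$sigma),
       tumor = tissue_spec("tumor", bg$eps_r, bg$sigma))
}

#' Restrict an image to a centered disc and renormalize
#'
#' @param image an `imtr_image`
#' @param radius disc radius in meters
#' @return the masked, max-renormalized `imtr_image`
#' @export
mask_image_disc <- function(image, radius) {
  px <- rep(image$x, times = length(image$y))
  py <- rep(image$y, each = length(image$x))
  m <- image$intensity
  m[matrix(px^2 + py^2 > radius^2, nrow(m))] <- 0
  mx <- max(m)
  if (mx > 0) m <- m / mx
  image$intensity <- m
  image
}

#' Stable md5 hash of a configuration list
#' @param cfg a list
#' @return md5 string
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Generate a small pre-simulated fixture for a catalogue scenario
#'
#' Simulates the named scenario on a coarsened grid with a short record and
#' stores both acquisition roles, for fast downstream testing. Re-running
#' with the same configuration reproduces the stored traces bit-exactly.
#'
#' @param name a [scenario_names()] entry
#' @param out_dir output directory
#' @param grid_spacing_mm coarse grid spacing (default 2 mm)
#' @return invisible list of written paths (total, background)
#' @export
fixture_generator <- function(name, out_dir, grid_spacing_mm = 2) {
  sc <- scenario_catalogue(name, overrides = list(
    grid_spacing_mm = grid_spacing_mm, min_cells_per_wavelength = 0,
    solver = list(pml_cells = 8)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  total <- simulate_multistatic(sc$phantom, sc$layout, sc$pulse, sc$cfg, "total")
  background <- simulate_multistatic(sc$phantom_background, sc$layout, sc$pulse,
                                     sc$cfg, "background")
  paths <- list(total = file.path(out_dir, paste0(name, "_total.rds")),
                background = file.path(out_dir, paste0(name, "_background.rds")))
  save_signalset(total, paths$total)
  save_signalset(background, paths$background)
  invisible(paths)
}
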