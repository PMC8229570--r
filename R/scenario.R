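#' Names of the packaged scenario catalogue
#' @return character vector
#' @export
scenario_names <- function() {
  c("three_antennas", "six_antennas", "nine_antennas", "small_tumor",
    "two_tumors", "three_tumors", "large_breast")
}

#' Load a packaged scenario by name
#'
#' The catalogue mirrors the reference trials: 3-, 6- and 9-element rings
#' around a 50 mm-radius breast with a 2 mm-radius tumor, a smaller (1.5 mm
#' radius) tumor, two and three tumors, and a 16 cm-diameter breast on a
#' coarsened grid.
#'
#' @param name one of [scenario_names()]
#' @param overrides named list merged over the YAML configuration (nested
#'   lists merge recursively), e.g. `list(grid_spacing_mm = 2)`
#' @return an `imtr_scenario`: list with `phantom`, `phantom_background`,
#'   `layout`, `pulse`, `cfg`, `chain`, `image`, `config`, `name`
#' @export
scenario_catalogue <- function(name, overrides = list()) {
  if (!name %in% scenario_names())
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(scenario_names(), collapse = ", ")), call. = FALSE)
  path <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                      package = "imtr", mustWork = TRUE)
  load_scenario(path, overrides = overrides, name = name)
}

.merge_config <- function(base, over) {
  for (k in names(over)) {
    if (is.list(over[[k]]) && is.list(base[[k]]))
      base[[k]] <- .merge_config(base[[k]], over[[k]])
    else base[[k]] <- over[[k]]
  }
  base
}

#' Load a scenario from a YAML configuration file
#'
#' Configuration keys use mm / GHz / ps units for readability; they are
#' converted to SI here. See the packaged files under
#' `system.file("extdata", "scenarios", package = "imtr")` for the schema.
#'
#' @param path YAML file path
#' @param overrides named list merged over the file contents
#' @param name optional scenario id recorded in the result
#' @return an `imtr_scenario`
#' @export
load_scenario <- function(path, overrides = list(), name = NULL) {
  cfg <- yaml::read_yaml(path)
  cfg <- .merge_config(cfg, overrides)
  .validate_scenario_config(cfg)

  pulse <- pulse_spec(f_r = .ghz(cfg$pulse$f_r_ghz),
                      omega = .ps(cfg$pulse$omega_ps))
  tissues <- default_tissues()
  for (nm in names(cfg$tissues))
    tissues[[nm]] <- tissue_spec(nm, cfg$tissues[[nm]]$eps_r,
                                 cfg$tissues[[nm]]$sigma)
  tumors <- lapply(cfg$tumors, function(tm)
    tumor_spec(c(.mm(tm$x_mm), .mm(tm$y_mm)), .mm(tm$radius_mm)))
  mk_phantom <- function(tms) build_phantom(
    breast_radius = .mm(cfg$breast_radius_mm),
    skin_thickness = .mm(cfg$skin_thickness_mm),
    tumors = tms, tissues = tissues,
    grid_spacing = .mm(cfg$grid_spacing_mm),
    domain_half = .mm(cfg$array$r_max_mm - cfg$array$d_mm) + 15e-3,
    pulse = pulse,
    min_cells_per_wavelength = cfg$min_cells_per_wavelength %||% 10)
  phantom <- mk_phantom(tumors)
  layout <- place_antennas(cfg$array$n_antennas, .mm(cfg$array$r_max_mm),
                           .mm(cfg$array$d_mm),
                           angular_slots = cfg$array$angular_slots %||% 9,
                           placement = cfg$array$placement %||% "contiguous",
                           breast_radius = .mm(cfg$breast_radius_mm))
  sol <- cfg$solver %||% list()
  cfg_sol <- solver_config(
    courant_factor = sol$courant_factor %||% 0.5,
    pml_cells = sol$pml_cells %||% 10,
    n_timesteps = if (!is.null(sol$record_ns)) {
      dt <- (sol$courant_factor %||% 0.5) * .mm(cfg$grid_spacing_mm) / .c0
      as.integer(ceiling(sol$record_ns * 1e-9 / dt))
    })
  chain <- chain_params(
    weight = cfg$chain$weight %||% 1,
    channels = cfg$chain$channels %||% "upper",
    kernel = cfg$chain$smoothing_kernel,
    gate_mode = cfg$chain$gate$mode %||% "geometric",
    gate_threshold = cfg$chain$gate$threshold %||% 0.1)

  structure(list(
    name = name %||% (cfg$name %||% basename(path)),
    phantom = phantom,
    phantom_background = mk_phantom(list()),
    layout = layout, pulse = pulse, cfg = cfg_sol, chain = chain,
    image = list(pixel = .mm(cfg$image$pixel_mm %||% 1),
                 pad = .mm(cfg$image$pad_mm %||% 10)),
    background_mode = cfg$background %||% "tumor_free",
    config = cfg), class = "imtr_scenario")
}

.validate_scenario_config <- function(cfg) {
  req <- c("breast_radius_mm", "skin_thickness_mm", "tumors", "grid_spacing_mm",
           "array", "pulse")
  missing <- setdiff(req, names(cfg))
  if (length(missing))
    stop("scenario config missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (f in c("n_antennas", "r_max_mm", "d_mm"))
    if (is.null(cfg$array[[f]]))
      stop("scenario config missing field: array$", f, call. = FALSE)
  for (f in c("f_r_ghz", "omega_ps"))
    if (is.null(cfg$pulse[[f]]))
      stop("scenario config missing field: pulse$", f, call. = FALSE)
  for (i in seq_along(cfg$tumors))
    for (f in c("x_mm", "y_mm", "radius_mm"))
      if (is.null(cfg$tumors[[i]][[f]]))
        stop(sprintf("scenario config missing field: tumors[[%d]]$%s", i, f),
             call. = FALSE)
  invisible(cfg)
}

#' @export
print.imtr_scenario <- function(x, ...) {
  cat(sprintf("<imtr_scenario> '%s': %d antennas, breast radius %.0f mm, %d tumor(s)\n",
              x$name, x$layout$n, x$phantom$breast_radius * 1e3,
              length(x$phantom$tumors)))
  invisible(x)
}
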