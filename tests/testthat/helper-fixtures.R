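# Shared fixtures, all generated in code. Expensive objects (FDTD runs) are
# memoized for the session so several test files can share them.

.c0_test <- 299792458

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# vacuum-like tissue table (background contrast checks disabled via values)
vacuum_tissues <- function(eps = 1, sigma = 0) {
  list(background = tissue_spec("background", 1, 0),
       fat = tissue_spec("fat", eps, sigma),
       skin = tissue_spec("skin", eps, sigma),
       tumor = tissue_spec("tumor", max(2 * eps, 2), sigma))
}

# small vacuum phantom for free-space solver tests
vacuum_phantom <- function(dx = 1e-3, domain_half = 50e-3) {
  build_phantom(10e-3, 2e-3, list(), vacuum_tissues(),
                grid_spacing = dx, domain_half = domain_half,
                min_cells_per_wavelength = 0)
}

# Born oracle channel signals (stage E3/E4) without early-content removal:
# the oracle data are clutter-free, so the reconstruction operators are
# tested in isolation
born_pair_stage <- function(scatterers, layout = place_antennas(9, 60e-3),
                            pulse = pulse_spec(), channels = "all",
                            pairing = "shared_tx") {
  ss <- born_point_scatterer(layout,
                             lapply(scatterers, function(p) list(center = p, amp = 1)),
                             pulse)
  e3 <- signalset_channels(ss, channels = channels)
  e4 <- processed_signals(e3$data, e3$t, "E4", channels = e3$channels,
                          layout = layout, pulse = pulse)
  average_pairs(pair_multiply(e4, pairing = pairing))
}

# full end-to-end run of the packaged default scenario (shared by the
# end-to-end and ranking acceptance tests)
nine_antennas_run <- function() {
  memo("nine_antennas_run", run_scenario("nine_antennas", algorithms = "all", seed = 1))
}

two_tumors_imtr_run <- function() {
  memo("two_tumors_imtr_run", run_scenario("two_tumors", algorithms = "imtr", seed = 1))
}

# synthetic processed_signals builder for preprocessing unit tests; the time
# axis starts at dt (not 0) so a gate starting at 0 keeps every sample
toy_signals <- function(data, dt = 1e-11, stage = "E3", ...) {
  data <- rbind(data)
  processed_signals(data, seq_len(ncol(data)) * dt, stage, ...)
}
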