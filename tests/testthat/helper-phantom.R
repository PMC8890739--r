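# Shared fixtures. Heavy synthetic measurements are computed once per test
# session and memoized here so several test files can share them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

default_geometry <- function() memo("geom", build_geometry())

default_model <- function() {
  memo("model", aneurysm_flow_model(default_geometry()))
}

model_with <- function(name) {
  memo(paste0("model_", name),
       apply_scenario(default_model(), scenario_preset(name)))
}

# peak-systole time of the default waveform
peak_time <- function(model = default_model()) {
  model$waveform$peak_phase * model$waveform$cycle_duration
}

# small particle ensemble helper for kinematics tests
free_particles <- function(pos, diameter = 3, seed = 1L) {
  structure(list(pos = pos, diameter_px = diameter, seed = as.integer(seed)),
            class = "aneupiv_particles")
}

# synthetic Gaussian-particle tile rendered at arbitrary sub-pixel offsets
particle_tile <- function(n = 64, centers, diameter = 3, amp = 0.8,
                          background = 0.05) {
  img <- aneupiv:::cpp_render_spots(centers[, 1], centers[, 2],
                                    rep(amp, nrow(centers)),
                                    rep(diameter / 4, nrow(centers)),
                                    n, n, radius = 4)
  img + background
}

# random particle centers for correlation tiles
random_centers <- function(n_tile, n_part, seed) {
  withr::with_seed(seed, cbind(runif(n_part, -2, n_tile + 2),
                               runif(n_part, -2, n_tile + 2)))
}

# ground-truth phase-averaged cycle for a scenario on a coarse grid (fast,
# no imaging): used by metric-level tests
truth_pac <- function(scenario = "noFD", n_cycles = 8, n_phases = 32,
                      pitch = 0.5) {
  memo(sprintf("truth_%s_%d_%d_%g", scenario, n_cycles, n_phases, pitch), {
    model <- if (identical(scenario, "base")) default_model() else
      model_with(scenario)
    geom <- model$geometry
    x <- seq(-11, 11, by = pitch)
    y <- seq(-1, 21.2, by = pitch)
    phase_average(ground_truth_recordings(model, x, y, n_cycles, n_phases),
                  cycle_duration = model$waveform$cycle_duration)
  })
}

truth_roi <- function(pac) roi_mask_for(default_geometry(), pac$x, pac$y)

# full synthetic PIV measurements (heavy; shared by the acceptance tests)
measured <- function(scenario, n_phases = 32L, seed = 101L,
                     target_px = NULL) {
  memo(sprintf("meas_%s_%d_%d_%s", scenario, n_phases, seed,
               target_px %||% "default"), {
    cfg <- acceptance_config(scenario, n_phases, seed, target_px)
    measure_scenario(cfg)
  })
}

acceptance_config <- function(scenario, n_phases = 32L, seed = 101L,
                              target_px = NULL) {
  cfg <- default_run_config(seed = seed)
  cfg$scenario <- scenario
  cfg$acquisition$n_phases <- as.integer(n_phases)
  if (!is.null(target_px)) cfg$acquisition$target_disp_px <- target_px
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
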