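# small desk-scale renders shared across tests; built once per test run

small_params <- function(n_frames = 400, ...) {
  oscillation_params(n_frames = n_frames, width = 64, height = 128,
                     glottal_length = 96, ...)
}

# symmetric low-noise render + its analysis objects
symmetric_render <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- simulate_recording(small_params(noise_sd = 0.01, seed = 7L))
      res <- analyze_stiffness(rec$stack)
      cache <<- list(rec = rec, res = res, objects = attr(res, "objects"))
    }
    cache
  }
})

# fully rigid right fold
rigid_render <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- simulate_recording(small_params(
        lesion_side = "right", lesion_extent = c(0, 1),
        lesion_stiffness = 1, noise_sd = 0.01, seed = 8L
      ))
      res <- analyze_stiffness(rec$stack)
      cache <<- list(rec = rec, res = res, objects = attr(res, "objects"))
    }
    cache
  }
})

# a 625 ms recording (2000 frames @ 3200 fps) for cycle/phase/OQ tests
long_render <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- simulate_recording(oscillation_params(
        n_frames = 2000, width = 64, height = 128, glottal_length = 96,
        phase_offset = 30, open_quotient = 0.6, noise_sd = 0.01, seed = 9L
      ))
      part <- partition_glottis(rec$stack, detect_poles(rec$stack),
                                "adaptive")
      traj <- extract_edge_trajectories(rec$stack, part, m = 33)
      cyc <- segment_cycles(traj)
      cache <<- list(rec = rec, part = part, traj = traj, cyc = cyc,
                     pars = compute_kymo_parameters(traj, cyc))
    }
    cache
  }
})

# cohort with 3 informative + 20 pure-noise features, for selection tests
planted_cohort_spec <- function(seed) {
  informative <- default_cohort_effects()[
    default_cohort_effects()$parameter %in%
      c("SAI", "AmplAsymAvg", "AbsPhaseDiffAvg"), ]
  informative$loading <- 0 # independent informative features
  noise <- purrr::map_dfr(1:20, function(i)
    tibble::tibble(parameter = sprintf("noise%02d", i),
                   mean_norm = 0, mean_benign = 0, mean_malignant = 0,
                   sd_norm = 1, sd_benign = 1, sd_malignant = 1,
                   lower = -Inf, upper = Inf, loading = 0))
  cohort_spec(effects = dplyr::bind_rows(informative, noise), seed = seed)
}
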