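# analytic trajectories for oracle tests: half-rectified sinusoids sampled
# like the simulator's kinematics, fed straight into the parameter registry
analytic_traj <- function(tt = 1280, fps = 3200, f0 = 160, m = 9,
                          amp_l = 6, amp_r = 6, phase_deg = 0, oq = 0.5,
                          len = 96) {
  ts <- (seq_len(tt) - 1) / fps
  c0 <- cos(pi * oq)
  wave <- function(th) pmax((sin(th) - c0) / (1 - c0), 0)
  prof <- 0.5 + 0.5 * sin(pi * seq_len(m) / (m + 1))
  x_l <- outer(wave(2 * pi * f0 * ts), amp_l * prof)
  x_r <- outer(wave(2 * pi * f0 * ts - 2 * pi * phase_deg / 360),
               amp_r * prof)
  edge_trajectories(x_l, x_r, fps, glottal_length = len)
}

test_that("edge trajectories are symmetric and match ground truth on renders", {
  lr <- long_render()
  traj <- lr$traj
  # left/right agreement on a noiseless symmetric render
  sym <- list(rec = simulate_recording(small_params(noise_sd = 0)))
  part <- partition_glottis(sym$rec$stack, detect_poles(sym$rec$stack),
                            "adaptive")
  sym$objects <- list(partition = part)
  tr2 <- extract_edge_trajectories(sym$rec$stack, part, m = 9)
  expect_lt(max(abs(tr2$x_left - tr2$x_right)), 0.5)
  # measured vs analytic ground-truth edges: sub-pixel RMS error
  truth <- sym$rec$truth
  len <- length(part$rows)
  pos_rows <- 1L + round(seq_len(9) / 9 * (len - 1L))
  gt_left <- truth$midline - truth$edge_left[, pos_rows]
  gt_right <- truth$edge_right[, pos_rows] - truth$midline
  open <- gt_left + gt_right > 2 # where the gap is measurable
  rms <- sqrt(mean((tr2$x_left[open] - gt_left[open])^2))
  expect_lt(rms, 1)
  expect_equal(tr2$positions_pct, 100 * (1:9) / 9)
})

test_that("gap and area waveform identities hold", {
  tr <- analytic_traj()
  expect_true(all(tr$gap >= 0))
  expect_equal(tr$gap, pmax(tr$x_left + tr$x_right, 0))
  expect_equal(tr$ga, rowSums(tr$gap) * tr$glottal_length / tr$m)
  expect_error(extract_edge_trajectories(long_render()$rec$stack,
                                         long_render()$part, m = 10),
               "thirds")
})

test_that("closed glottis is rejected", {
  st <- frame_stack(array(0.8, dim = c(128, 64, 32)), 3200)
  part <- partition_glottis(st, rbind(c(10, 16), c(50, 16)), "straight")
  expect_error(extract_edge_trajectories(st, part, m = 9, threshold = 0.4),
               "closed glottis")
})

test_that("cycle segmentation finds ~f0*duration cycles and agrees with LTG F0", {
  lr <- long_render()
  cyc <- lr$cyc
  # 150 Hz * 625 ms = 93.75 full cycles
  expect_lt(abs(cyc$n_cycles - 93), 1.5)
  expect_lt(abs(cyc$f0 - 150) / 150, 0.02)
  sai <- analyze_stiffness(lr$rec$stack)
  expect_lt(abs(cyc$f0 - sai$f0) / sai$f0, 0.02)
  # constant waveform is rejected
  flat <- edge_trajectories(matrix(1, 200, 9), matrix(1, 200, 9), 3200, 96)
  flat$ga[] <- 1
  expect_error(segment_cycles(flat), "constant")
})

test_that("registry identities hold exactly on analytic trajectories", {
  tr <- analytic_traj(amp_l = 8, amp_r = 4) # amp_left = 2 * amp_right
  cyc <- segment_cycles(tr)
  pars <- compute_kymo_parameters(tr, cyc)
  # |2a - a| / 2a = 50 % at every position, hence exactly 50 in all aggregates
  expect_equal(pars$AmplAsymAvg, 50, tolerance = 1e-9)
  expect_equal(pars$AmplAsymWeighted, 50, tolerance = 1e-9)
  expect_equal(pars$`AmplAsymAvg_2/3`, 50, tolerance = 1e-9)
  # uniform weights: weighted equals unweighted (here weights are uniform
  # across positions only for the symmetric-profile phase diff of 0)
  expect_equal(pars$PhaseDiffAvg, 0, tolerance = 1e-6)
  expect_equal(pars$AbsPhaseDiffAvg, 0, tolerance = 1e-6)
  # thirds bookkeeping: position-count weighted mean of thirds = global
  thirds_mean <- mean(c(pars$`AmpAvg_1/3`, pars$`AmpAvg_2/3`,
                        pars$`AmpAvg_3/3`))
  expect_equal(thirds_mean, pars$AmpAvg, tolerance = 1e-12)
  oq_thirds <- mean(c(pars$`OQAvg_1/3`, pars$`OQAvg_2/3`, pars$`OQAvg_3/3`))
  expect_equal(oq_thirds, pars$OQAvg, tolerance = 1e-12)
})

test_that("weighted aggregates with uniform weights equal plain means", {
  # constant amplitude profile -> uniform weights
  tr <- analytic_traj(amp_l = 5, amp_r = 5, phase_deg = 25)
  tr$x_left <- tr$x_left[, 1] %o% rep(1, 9) * 1.0
  tr$x_right <- tr$x_right[, 1] %o% rep(1, 9)
  tr$gap <- pmax(tr$x_left + tr$x_right, 0)
  tr$ga <- rowSums(tr$gap) * tr$glottal_length / tr$m
  cyc <- segment_cycles(tr)
  pars <- compute_kymo_parameters(tr, cyc)
  expect_equal(pars$PhaseDiffWeighted, pars$PhaseDiffAvg, tolerance = 1e-9)
  expect_equal(pars$AbsPhaseDiffWeighted, pars$AbsPhaseDiffAvg,
               tolerance = 1e-9)
  expect_equal(pars$AmplAsymWeighted, pars$AmplAsymAvg, tolerance = 1e-9)
  expect_equal(pars$PhaseAsymWeighted, pars$PhaseAsymAvg, tolerance = 1e-9)
})

test_that("phase difference and open quotient are recovered from renders", {
  pars <- long_render()$pars
  expect_lt(abs(pars$PhaseDiffAvg - 30), 3)
  expect_lt(abs(pars$AbsPhaseDiffAvg - 30), 3)
  expect_gte(pars$AbsPhaseDiffAvg, abs(pars$PhaseDiffAvg) - 1e-9)
  expect_lt(abs(pars$OQAvg - 60), 3)
  # symmetric render: asymmetries and phase differences near zero
  sym <- symmetric_render()
  tr <- extract_edge_trajectories(sym$rec$stack, sym$objects$partition, m = 9)
  p0 <- compute_kymo_parameters(tr, segment_cycles(tr))
  expect_lt(abs(p0$AmplAsymAvg), 1)
  expect_lt(abs(p0$PhaseDiffAvg), 1)
  expect_lt(abs(p0$AbsPhaseDiffAvg), 1)
})

test_that("analytic phase lag is recovered through the cross-spectrum", {
  tr <- analytic_traj(phase_deg = 30, oq = 0.6, tt = 2000, f0 = 150)
  cyc <- segment_cycles(tr)
  pars <- compute_kymo_parameters(tr, cyc)
  expect_lt(abs(pars$PhaseDiffAvg - 30), 3)
  expect_lt(abs(pars$OQAvg - 60), 3)
  expect_lt(abs(pars$PhaseAsymAvg - 100 * 30 / 360), 3)
})

test_that("rigid positions are excluded from asymmetry with a reported count", {
  tr <- analytic_traj(tt = 640)
  tr$x_left[, 5] <- 0
  tr$x_right[, 5] <- 0
  tr$gap <- pmax(tr$x_left + tr$x_right, 0)
  tr$ga <- rowSums(tr$gap) * tr$glottal_length / tr$m
  pars <- compute_kymo_parameters(tr, segment_cycles(tr))
  expect_equal(attr(pars, "n_excluded"), 1L)
  expect_true(all(is.finite(unlist(pars))))
})

test_that("all 38 parameters are finite and in range across a render sweep", {
  set.seed(31)
  grid <- list(
    small_params(seed = 61L),
    small_params(phase_offset = 40, open_quotient = 0.5, seed = 62L),
    small_params(amp_left = 9, amp_right = 5, seed = 63L),
    small_params(lesion_side = "right", lesion_extent = c(0.2, 0.8),
                 lesion_stiffness = 0.7, seed = 64L)
  )
  for (p in grid) {
    rec <- simulate_recording(p)
    part <- partition_glottis(rec$stack, detect_poles(rec$stack), "adaptive")
    traj <- extract_edge_trajectories(rec$stack, part, m = 9)
    pars <- compute_kymo_parameters(traj, segment_cycles(traj))
    expect_named(pars, kymo_parameter_names())
    v <- unlist(pars)
    expect_true(all(is.finite(v)))
    pctish <- grepl("Asym|OQ|Nonclosing|Nonopening|RGGA|EffectiveArea|Rel2",
                    names(v)) & !grepl("PhaseDiff", names(v))
    expect_true(all(v[pctish] >= 0 & v[pctish] <= 100))
    phase <- grepl("^PhaseDiff", names(v))
    expect_true(all(v[phase] > -180 & v[phase] <= 180))
    expect_true(all(v[grepl("^AbsPhaseDiff", names(v))] >= 0))
  }
})
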