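# tiny synthetic stack with per-pixel sinusoids for closed-form spectra
tone_stack <- function(freqs, tt = 256, fps = 3200, h = 4, w = 4,
                       amp = 0.3, offset = 0.5) {
  frames <- array(offset, dim = c(tt, h, w))
  ts <- (seq_len(tt) - 1) / fps
  k <- 1
  for (j in seq_len(w)) for (i in seq_len(h)) {
    f <- freqs[(k - 1) %% length(freqs) + 1]
    if (!is.na(f)) frames[, i, j] <- offset + amp * sin(2 * pi * f * ts)
    k <- k + 1
  }
  frame_stack(frames, fps)
}

test_that("constant pixels give zero spectra after DC removal", {
  st <- frame_stack(array(0.42, dim = c(128, 4, 4)), 3200)
  sp <- extract_brightness_spectra(st)
  expect_true(all(abs(sp$amplitude) < 1e-10))
  expect_true(sp$dc_removed)
  expect_equal(sp$freq[2] - sp$freq[1], 3200 / 128)
})

test_that("a 150 Hz brightness sinusoid peaks at 150 Hz within resolution", {
  st <- tone_stack(150, tt = 2000)
  sp <- extract_brightness_spectra(st)
  pk <- sp$freq[apply(sp$amplitude, 2, which.max)]
  expect_true(all(abs(pk - 150) <= 3200 / 2000 + 1e-9))
})

test_that("the complex transform is linear pixel-wise", {
  s1 <- tone_stack(120, tt = 128)
  s2 <- tone_stack(240, tt = 128, amp = 0.1)
  both <- frame_stack(s1$frames + s2$frames - 0.5, 3200)
  f1 <- extract_brightness_spectra(s1, window = "rect")
  f2 <- extract_brightness_spectra(s2, window = "rect")
  fb <- extract_brightness_spectra(both, window = "rect")
  expect_equal(fb$transform, f1$transform + f2$transform, tolerance = 1e-10)
})

test_that("roi handling rejects bad masks and empty rois", {
  st <- tone_stack(150, tt = 128)
  expect_error(extract_brightness_spectra(st, matrix(TRUE, 2, 2)), "mask")
  expect_error(extract_brightness_spectra(st, matrix(FALSE, 4, 4)), "empty")
  expect_error(extract_brightness_spectra(
    frame_stack(array(0.5, c(32, 4, 4)), 3200)), "64 frames")
})

test_that("global F0 is recovered and absent oscillation is reported", {
  sym <- symmetric_render()
  expect_lt(abs(sym$res$f0 - 150), 3200 / 400 + 1e-9)
  st <- tone_stack(150, tt = 256)
  sp <- extract_brightness_spectra(st)
  # band excluding the true F0
  out <- identify_f0(sp, band = c(400, 900))
  expect_equal(out$status, "no oscillation detected")
  expect_true(is.na(out$f0))
  expect_error(identify_f0(sp, band = c(100, 5000)), "Nyquist")
})

test_that("per-pixel F0 map is bimodal on a two-tone stack", {
  st <- tone_stack(c(120, 240), tt = 1600)
  sp <- extract_brightness_spectra(st)
  out <- identify_f0(sp, band = c(70, 500))
  f0s <- sort(unique(as.vector(out$f0_pixel)))
  expect_length(f0s, 2L)
  expect_lt(abs(f0s[1] - 120), 2 + 1e-9)
  expect_lt(abs(f0s[2] - 240), 2 + 1e-9)
})

test_that("amplitude map is mirror-symmetric with maxima on the fold edges", {
  sym <- symmetric_render()
  o <- sym$objects
  amp <- o$ltg$amplitude
  mid <- sym$rec$truth$midline
  rows <- sym$rec$truth$rows
  # compare columns mirrored about the midline over the fold rows
  off <- 1:10
  lcol <- round(mid - 0.5) - off + 1
  rcol <- round(mid + 0.5) + off - 1
  a_l <- colMeans(amp[rows, lcol], na.rm = TRUE)
  a_r <- colMeans(amp[rows, rcol], na.rm = TRUE)
  expect_lt(max(abs(a_l - a_r)) / max(a_l), 0.12)
  # the map maxima sit inside the ground-truth swept band
  vib <- sym$rec$truth$vibrating_mask
  top <- order(amp, decreasing = TRUE, na.last = TRUE)[1:50]
  expect_gt(mean(vib[top]), 0.95)
})

test_that("LTG phase difference recovers the simulated phase lag", {
  rec <- simulate_recording(small_params(phase_offset = 30, seed = 21L))
  res <- analyze_stiffness(rec$stack)
  o <- attr(res, "objects")
  d <- ltg_phase_difference(o$ltg, o$partition, o$mask)
  expect_lt(abs(abs(d) - 30), 5)
})

test_that("vibration mask is empty over a rigid fold and symmetric otherwise", {
  rig <- rigid_render()
  o <- rig$objects
  right_frac <- sum(o$mask & o$partition$right) / sum(o$mask)
  expect_lt(right_frac, 0.05)
  expect_gt(sum(o$mask & o$partition$left), 100)
  sym <- symmetric_render()
  so <- sym$objects
  a_l <- sum(so$mask & so$partition$left)
  a_r <- sum(so$mask & so$partition$right)
  expect_lt(abs(a_l - a_r) / max(a_l, a_r), 0.02)
})

test_that("raising the mask threshold k never grows the mask", {
  sym <- symmetric_render()
  ltg <- sym$objects$ltg
  sizes <- vapply(c(1, 2, 4, 8, 16), function(k)
    sum(detect_vibration_mask(ltg, k)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("degenerate all-zero amplitude yields an empty mask", {
  st <- frame_stack(array(0.5, dim = c(128, 6, 6)), 3200)
  sp <- extract_brightness_spectra(st)
  ltg <- build_ltg_map(sp, 150)
  expect_false(any(detect_vibration_mask(ltg)))
})

test_that("partition modes agree on symmetric renders and tile the frame", {
  sym <- symmetric_render()
  st <- sym$rec$stack
  poles <- detect_poles(st)
  ps <- partition_glottis(st, poles, "straight")
  pa <- partition_glottis(st, poles, "adaptive")
  rms <- sqrt(mean((ps$boundary - pa$boundary)^2))
  expect_lt(rms, 1)
  expect_false(any(pa$left & pa$right))
  rows <- pa$rows
  expect_true(all((pa$left | pa$right)[rows, ]))
  expect_error(partition_glottis(st, rbind(c(5, 5), c(5, 5))), "distinct")
  expect_error(partition_glottis(st, rbind(c(0, 5), c(900, 5))), "inside")
})

test_that("adaptive boundary assigns a bulging lesion to its own side", {
  rec <- simulate_recording(small_params(
    amp_left = 10, amp_right = 10,
    lesion_side = "right", lesion_extent = c(0.3, 0.7),
    lesion_stiffness = 1, lesion_bulge = 6, noise_sd = 0.01, seed = 22L
  ))
  st <- rec$stack
  poles <- detect_poles(st)
  pa <- partition_glottis(st, poles, "adaptive")
  ps <- partition_glottis(st, poles, "straight")
  # over the lesion extent the adaptive boundary moves left of the straight one
  lesion_rows <- seq(round(0.35 * length(pa$rows)), round(0.65 * length(pa$rows)))
  expect_lt(mean(pa$boundary[lesion_rows]), mean(ps$boundary[lesion_rows]) - 1)
  # and the measured left-side RVA differs between the modes
  roi_a <- glottis_roi(pa)
  roi_s <- glottis_roi(ps)
  sp <- extract_brightness_spectra(st, roi_a | roi_s)
  f0 <- identify_f0(sp)
  mask <- detect_vibration_mask(build_ltg_map(sp, f0$f0))
  rva_a <- compute_sai(mask, pa, roi_a)$rva_left
  rva_s <- compute_sai(mask, ps, roi_s)$rva_left
  expect_gt(abs(rva_a - rva_s), 0.001)
  # a bulge-tissue pixel medial to the straight axis: adaptive assigns it to
  # the right (lesion) side, straight misassigns it to the left
  mid_row <- pa$rows[length(pa$rows) %/% 2]
  bulge_col <- 30 # between the adaptive contact line and the straight axis
  expect_true(pa$right[mid_row, bulge_col])
  expect_true(ps$left[mid_row, bulge_col])
})

test_that("no detectable gap falls back to the straight partition", {
  st <- frame_stack(array(0.8, dim = c(80, 32, 32)), 3200)
  expect_warning(
    p <- partition_glottis(st, rbind(c(4, 16), c(28, 16)), "adaptive"),
    "falling back"
  )
  expect_equal(p$status, "fallback_straight")
  expect_equal(p$mode, "straight")
})

test_that("SAI follows its closed form and the ratio-invariance property", {
  # direct arithmetic on synthetic masks
  part <- structure(
    list(boundary = rep(8.5, 16), rows = 1:16,
         left = cbind(matrix(TRUE, 16, 8), matrix(FALSE, 16, 8)),
         right = cbind(matrix(FALSE, 16, 8), matrix(TRUE, 16, 8)),
         poles = rbind(c(1, 8.5), c(16, 8.5)),
         mode = "straight", status = "ok"),
    class = "glottis_partition"
  )
  roi <- matrix(TRUE, 16, 16)
  mk <- function(nl, nr) {
    m <- matrix(FALSE, 16, 16)
    if (nl > 0) m[seq_len(nl)] <- TRUE
    if (nr > 0) m[8 * 16 + seq_len(nr)] <- TRUE
    m
  }
  r <- compute_sai(mk(90, 90), part, roi) # 90/128 each side
  expect_equal(r$sai, 0)
  # RVA_L = 0.8, RVA_R = 0.4 -> SAI = 0.5 (sides hold 128 px each)
  r2 <- compute_sai(mk(102, 51), part, roi)
  expect_equal(r2$rva_left, 102 / 128)
  expect_equal(r2$sai, 1 - (51 / 128) / (102 / 128))
  expect_equal(r2$sai, 0.5)
  # proportional scaling of one side's vibrating AND total areas: shrink the
  # right side region and its vibrating pixels by the same factor
  roi_scaled <- roi
  roi_scaled[, 13:16] <- FALSE # right side total 128 -> 64 px
  m3 <- mk(102, 0)
  m3[8 * 16 + seq_len(26)] <- TRUE # right vibrating 51 -> 25.5 ~ 26/64
  r3a <- compute_sai(mk(102, 51), part, roi)
  r3b <- compute_sai(m3, part, roi_scaled)
  expect_equal(r3b$sai, 1 - (26 / 64) / (102 / 128), tolerance = 1e-12)
  expect_lt(abs(r3a$sai - r3b$sai), 0.02) # 26/64 vs 25.5/64 rounding only
  # exact invariance at machine precision with an exactly divisible factor
  roi_half <- roi; roi_half[, 13:16] <- FALSE
  r4 <- compute_sai(mk(102, 24), part, roi_half) # 24/64 = 48/128 scaled by 1/2
  r5 <- compute_sai(mk(102, 48), part, roi)
  expect_identical(r4$sai, r5$sai)
  # no vibration at all
  r6 <- compute_sai(mk(0, 0), part, roi)
  expect_equal(r6$sai, 1)
  expect_equal(r6$status, "no vibration")
  expect_error(compute_sai(mk(1, 1), part, matrix(FALSE, 16, 16)), "empty side")
})

test_that("mask and SAI agree with an independent brute-force DFT on a toy stack", {
  set.seed(5)
  tt <- 128
  frames <- array(0.5, dim = c(tt, 8, 8))
  ts <- (seq_len(tt) - 1) / 3200
  vib <- matrix(FALSE, 8, 8)
  vib[3:6, 2:3] <- TRUE # "left" vibrating block
  vib[3:4, 6:7] <- TRUE # smaller "right" block
  for (i in 1:8) for (j in 1:8) {
    if (vib[i, j]) frames[, i, j] <- 0.5 + 0.3 * sin(2 * pi * 160 * ts)
    frames[, i, j] <- frames[, i, j] + rnorm(tt, sd = 0.01)
  }
  st <- frame_stack(frames, 3200)
  sp <- extract_brightness_spectra(st, window = "rect")
  f0 <- identify_f0(sp)
  ltg <- build_ltg_map(sp, f0$f0)
  mask <- detect_vibration_mask(ltg, k = 4)
  # independent oracle: naive per-pixel DFT loop, no mvfft, no package helpers
  n_keep <- tt %/% 2 + 1
  amp_o <- array(NA_real_, c(8, 8, n_keep))
  for (i in 1:8) for (j in 1:8) {
    b <- frames[, i, j]; b <- b - mean(b)
    for (k in seq_len(n_keep)) {
      w <- exp(-2i * pi * (k - 1) * (seq_len(tt) - 1) / tt)
      amp_o[i, j, k] <- Mod(sum(b * w))
    }
  }
  freqs <- (seq_len(n_keep) - 1) * 3200 / tt
  band <- freqs >= 70 & freqs <= 500
  peak_o <- apply(amp_o[, , band], c(1, 2), max)
  oob <- as.vector(amp_o[, , !band & freqs > 0])
  thr_o <- median(oob) + 4 * mad(oob)
  mask_o <- peak_o >= thr_o
  expect_identical(mask, mask_o)
  # SAI from both masks under a straight split at column 4.5
  part <- structure(
    list(boundary = rep(4.5, 8), rows = 1:8,
         left = cbind(matrix(TRUE, 8, 4), matrix(FALSE, 8, 4)),
         right = cbind(matrix(FALSE, 8, 4), matrix(TRUE, 8, 4)),
         poles = rbind(c(1, 4.5), c(8, 4.5)), mode = "straight",
         status = "ok"),
    class = "glottis_partition"
  )
  roi <- matrix(TRUE, 8, 8)
  sai_pkg <- compute_sai(mask, part, roi)$sai
  rva_l_o <- sum(mask_o[, 1:4]) / 32
  rva_r_o <- sum(mask_o[, 5:8]) / 32
  sai_o <- 1 - min(rva_l_o, rva_r_o) / max(rva_l_o, rva_r_o)
  expect_equal(sai_pkg, sai_o)
  expect_equal(sai_o, 1 - 4 / 8) # 8 left, 4 right vibrating pixels
})
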