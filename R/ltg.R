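#' Per-pixel brightness spectra of a frame stack
#'
#' Computes the discrete Fourier transform of every pixel's brightness
#' time-series inside `roi`, after removing the temporal mean (DC) and,
#' optionally, applying a Hann window to control spectral leakage on
#' non-integer-cycle segments. Only the positive-frequency half of the
#' spectrum is retained.
#'
#' @param stack a [frame_stack()].
#' @param roi logical `H x W` mask of pixels to analyse; `NULL` analyses the
#'   whole frame.
#' @param window `"hann"` (default) or `"rect"`.
#' @return An object of class `spectral_maps`: list with `amplitude`
#'   (`n_freq x n_pixels` magnitude matrix), `transform` (complex, same
#'   shape), `freq` (Hz), `pixel_index` (column-major indices into the
#'   `H x W` plane), `roi`, `frame_rate`, `window`, and `dc_removed = TRUE`.
#'   The frequency resolution is `frame_rate / n_frames`.
#' @export
extract_brightness_spectra <- function(stack, roi = NULL,
                                       window = c("hann", "rect")) {
  stopifnot(inherits(stack, "frame_stack"))
  window <- match.arg(window)
  tt <- stack$n_frames
  if (tt < 64L) abort("need at least 64 frames for spectral analysis.")
  if (is.null(roi)) {
    roi <- matrix(TRUE, stack$height, stack$width)
  } else {
    if (!is.logical(roi) || !all(dim(roi) == c(stack$height, stack$width)))
      abort("`roi` must be a logical H x W mask matching the stack.")
    if (!any(roi)) abort("`roi` is empty.")
  }
  m <- stack_pixel_matrix(stack, roi)
  m <- sweep(m, 2, colMeans(m))
  win <- if (window == "hann") 0.5 * (1 - cos(2 * pi * (seq_len(tt) - 1) / tt))
         else rep(1, tt)
  ft <- mvfft(m * win)
  n_keep <- tt %/% 2L + 1L
  ft <- ft[seq_len(n_keep), , drop = FALSE]
  structure(
    list(
      amplitude = Mod(ft),
      transform = ft,
      freq = (seq_len(n_keep) - 1) * stack$frame_rate / tt,
      pixel_index = which(as.vector(roi)),
      roi = roi,
      dim = c(stack$height, stack$width),
      frame_rate = stack$frame_rate,
      window = window,
      dc_removed = TRUE
    ),
    class = "spectral_maps"
  )
}

#' @export
print.spectral_maps <- function(x, ...) {
  cat(sprintf("<spectral_maps> %d pixels, %d frequency bins (res %.2f Hz, %s window)\n",
              ncol(x$amplitude), nrow(x$amplitude), x$freq[2] - x$freq[1],
              x$window))
  invisible(x)
}

#' Identify the fundamental frequency of the vibratory pattern
#'
#' Per pixel, F0 is the frequency of the in-band amplitude maximum; the global
#' F0 is the amplitude-weighted mode over the analysed region (the band bin
#' collecting the largest total peak amplitude). Harmonic bins at `k * F0`
#' within the spectrum are reported. Pixels whose in-band peak does not rise
#' above the robust out-of-band noise floor do not vote; if no pixel votes the
#' status is `"no oscillation detected"`.
#'
#' @param maps a `spectral_maps` object.
#' @param band physiological F0 search band in Hz, default 70-500.
#' @param noise_k multiple of the out-of-band MAD a peak must exceed to vote.
#' @return A list with `f0` (global, Hz; `NA` if none), `f0_pixel` (per-pixel
#'   F0 map, `H x W`, `NA` outside the region), `harmonics` (Hz),
#'   `status` (`"ok"` or `"no oscillation detected"`).
#' @export
identify_f0 <- function(maps, band = c(70, 500), noise_k = 4) {
  stopifnot(inherits(maps, "spectral_maps"))
  nyq <- maps$frame_rate / 2
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    abort("`band` must lie within (0, Nyquist).")
  in_band <- maps$freq >= band[1] & maps$freq <= band[2]
  if (!any(in_band)) abort("`band` contains no frequency bin.")
  amp_band <- maps$amplitude[in_band, , drop = FALSE]
  freq_band <- maps$freq[in_band]
  peak_idx <- max.col(t(amp_band), ties.method = "first")
  peak_amp <- amp_band[cbind(peak_idx, seq_len(ncol(amp_band)))]
  floor_ <- noise_floor(maps, band, noise_k)
  voting <- peak_amp >= floor_$threshold
  f0_map <- matrix(NA_real_, maps$dim[1], maps$dim[2])
  f0_map[maps$pixel_index] <- freq_band[peak_idx]
  if (!any(voting)) {
    return(list(f0 = NA_real_, f0_pixel = f0_map, harmonics = numeric(),
                status = "no oscillation detected"))
  }
  votes <- tapply(peak_amp[voting], peak_idx[voting], sum)
  best_bin <- as.integer(names(votes)[which.max(votes)])
  f0 <- freq_band[best_bin]
  harmonics <- f0 * seq_len(floor(nyq / f0))
  list(f0 = f0, f0_pixel = f0_map, harmonics = harmonics, status = "ok")
}

# robust noise floor from out-of-band amplitude: median + k * MAD
noise_floor <- function(maps, band, noise_k = 4) {
  out_band <- maps$freq < band[1] | maps$freq > band[2]
  out_band[1] <- FALSE # DC bin is zero by construction
  oob <- maps$amplitude[out_band, , drop = FALSE]
  med <- median(oob)
  s <- mad(oob, center = med)
  list(median = med, mad = s, threshold = med + noise_k * s)
}

#' Build a laryngotopographic map at a given fundamental frequency
#'
#' Samples every analysed pixel's amplitude and phase at the spectrum bin
#' nearest `f0`, producing the spatial maps of vibratory activity from which
#' non-vibrating regions and the Stiffness Asymmetry Index are derived.
#'
#' @param maps a `spectral_maps` object.
#' @param f0 fundamental frequency in Hz (e.g. from [identify_f0()]).
#' @param band band used for the noise floor stored with the map.
#' @return An object of class `ltg_map`: list with `amplitude` and `phase_deg`
#'   (`H x W`, `NA` outside the region), `f0`, `f0_bin`, `freq_resolution`,
#'   `noise` (robust floor statistics), and `roi`.
#' @export
build_ltg_map <- function(maps, f0, band = c(70, 500)) {
  stopifnot(inherits(maps, "spectral_maps"))
  if (is.na(f0) || f0 < band[1] || f0 > band[2])
    abort("`f0` must lie inside the analysed band.")
  bin <- which.min(abs(maps$freq - f0))
  amp <- matrix(NA_real_, maps$dim[1], maps$dim[2])
  ph <- matrix(NA_real_, maps$dim[1], maps$dim[2])
  amp[maps$pixel_index] <- maps$amplitude[bin, ]
  ph[maps$pixel_index] <- Arg(maps$transform[bin, ]) * 180 / pi
  structure(
    list(amplitude = amp, phase_deg = ph, f0 = f0, f0_bin = bin,
         freq_resolution = maps$freq[2] - maps$freq[1],
         noise = noise_floor(maps, band), roi = maps$roi),
    class = "ltg_map"
  )
}

#' Extract the vibration mask from a laryngotopographic map
#'
#' A pixel is classified as vibrating iff its amplitude at F0 reaches
#' `median + k * MAD` of the out-of-band amplitude distribution (a robust
#' noise floor). Raising `k` can only shrink the mask.
#'
#' @param ltg an `ltg_map`.
#' @param k threshold in MAD units above the out-of-band median, default 4.
#' @return Logical `H x W` mask (FALSE outside the analysed region).
#' @export
detect_vibration_mask <- function(ltg, k = 4) {
  stopifnot(inherits(ltg, "ltg_map"))
  thr <- ltg$noise$median + k * ltg$noise$mad
  mask <- !is.na(ltg$amplitude) & ltg$amplitude >= thr
  if (all(ltg$amplitude[!is.na(ltg$amplitude)] == 0)) {
    mask[] <- FALSE
  }
  mask
}

#' Partition the glottis into left and right sides
#'
#' Splits the analysis region at the glottal midline between the anterior and
#' posterior poles. In `straight` mode the boundary is the segment joining the
#' poles. In `adaptive` mode the boundary follows, row by row, the midline of
#' the dark glottal gap in the minimum-intensity projection of the stack
#' (rows where the gap never opens are interpolated from neighbouring rows),
#' so that a lesion bulging across the straight axis is still assigned to its
#' own side. If no gap is detectable the partition falls back to straight mode
#' with status `"fallback_straight"`.
#'
#' @param stack a [frame_stack()].
#' @param poles 2 x 2 matrix `rbind(c(row, col), c(row, col))` of the
#'   posterior and anterior glottal poles, e.g. from [detect_poles()].
#' @param mode `"straight"` or `"adaptive"`.
#' @param gap_quantile intensity threshold for "dark gap" in adaptive mode,
#'   expressed as the fraction between the projection's minimum and maximum.
#' @return An object of class `glottis_partition`: list with `boundary`
#'   (per-row boundary column over the pole row span), `rows`, `left`/`right`
#'   logical `H x W` masks tiling the frame over the row span, `poles`,
#'   `mode`, `status`.
#' @export
partition_glottis <- function(stack, poles, mode = c("straight", "adaptive"),
                              gap_quantile = 0.35) {
  stopifnot(inherits(stack, "frame_stack"))
  mode <- match.arg(mode)
  poles <- as.matrix(poles)
  if (!all(dim(poles) == c(2L, 2L))) abort("`poles` must be a 2 x 2 matrix.")
  if (all(poles[1, ] == poles[2, ])) abort("poles must be distinct.")
  if (any(poles[, 1] < 1) || any(poles[, 1] > stack$height) ||
      any(poles[, 2] < 1) || any(poles[, 2] > stack$width))
    abort("poles must lie inside the image.")
  rows <- seq.int(min(poles[, 1]), max(poles[, 1]))
  straight <- approx(x = poles[, 1], y = poles[, 2], xout = rows)$y
  status <- "ok"
  boundary <- straight
  if (mode == "adaptive") {
    proj <- apply(stack$frames, c(2, 3), min) # min-intensity projection
    thr <- min(proj) + gap_quantile * (max(proj) - min(proj))
    # boundary = contact line between the folds: per row, the midpoint of the
    # inner envelope of the sub-pixel gap edges over time (the most medial
    # excursion of each fold edge), which tracks a lesion bulging across the
    # straight axis
    # each fold's most medial edge excursion brackets the contact line; the
    # envelope of a mobile edge is truncated by the finite gap-detection
    # limit near closure, so the endpoints are weighted by the inverse of
    # each edge's excursion range (a rigid edge pins the contact exactly)
    mid <- vapply(rows, function(r) {
      if (!any(proj[r, ] < thr)) return(NA_real_)
      ed <- subpixel_gap_edges(stack$frames[, r, ], thr)
      ok <- !is.na(ed$left)
      if (!any(ok)) return(NA_real_)
      el <- ed$left[ok]; er <- ed$right[ok]
      w_l <- 1 / (diff(range(el)) + 0.5)
      w_r <- 1 / (diff(range(er)) + 0.5)
      (max(el) * w_l + min(er) * w_r) / (w_l + w_r)
    }, numeric(1))
    if (all(is.na(mid))) {
      mode <- "straight"
      status <- "fallback_straight"
      warn("no detectable glottal gap; falling back to straight partition.")
    } else {
      known <- which(!is.na(mid))
      mid <- approx(rows[known], mid[known], xout = rows, rule = 2)$y
      # clip to the poles so boundary endpoints coincide with them
      mid[1] <- straight[1]
      mid[length(mid)] <- straight[length(mid)]
      boundary <- mid
    }
  }
  left <- right <- matrix(FALSE, stack$height, stack$width)
  cols <- seq_len(stack$width)
  for (k in seq_along(rows)) {
    left[rows[k], cols < boundary[k]] <- TRUE
    right[rows[k], cols >= boundary[k]] <- TRUE
  }
  structure(
    list(boundary = boundary, rows = rows, left = left, right = right,
         poles = poles, mode = mode, status = status),
    class = "glottis_partition"
  )
}

# sub-pixel gap edges of one image row over time: `mat` is T x W intensity;
# returns per-frame left/right edge columns (NA when the gap is closed or
# narrower than the ~2 px needed to resolve both edges), using the linear
# brightness ramp of the anti-aliased edge for coverage refinement
subpixel_gap_edges <- function(mat, thr) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  tt <- nrow(mat)
  tissue <- apply(mat, 1, max)
  gap_i <- pmin(apply(mat, 1, min), thr - 1e-6)
  depth <- pmax(tissue - gap_i, 1e-6)
  cov <- (tissue - mat) / depth
  cov[cov < 0] <- 0
  cov[cov > 1] <- 1
  is_gap <- mat < thr & cov > 0.5
  e_l <- e_r <- rep(NA_real_, tt)
  wide <- rowSums(is_gap) >= 2L
  if (any(wide)) {
    dk <- is_gap[wide, , drop = FALSE]
    first <- max.col(dk, ties.method = "first")
    last <- max.col(dk, ties.method = "last")
    ri <- seq_len(sum(wide))
    cv <- cov[wide, , drop = FALSE]
    e_l[wide] <- first + 0.5 - cv[cbind(ri, first)]
    e_r[wide] <- last - 0.5 + cv[cbind(ri, last)]
  }
  list(left = e_l, right = e_r)
}

#' Locate the glottal poles automatically
#'
#' Finds the anterior and posterior ends of the dark glottal gap from the
#' minimum-intensity projection of the stack: the first and last image rows
#' containing gap-dark pixels, with the pole column at the gap midline of
#' those rows. Intended for synthetic and well-centred recordings; for
#' clinical recordings pole coordinates are typically supplied manually.
#'
#' @inheritParams partition_glottis
#' @return 2 x 2 matrix of `(row, col)` pole coordinates.
#' @export
detect_poles <- function(stack, gap_quantile = 0.35) {
  stopifnot(inherits(stack, "frame_stack"))
  proj <- apply(stack$frames, c(2, 3), min)
  thr <- min(proj) + gap_quantile * (max(proj) - min(proj))
  dark_rows <- which(apply(proj < thr, 1, any))
  if (length(dark_rows) < 2L) abort("no detectable glottal gap.")
  mid <- function(r) {
    dark <- which(proj[r, ] < thr)
    (min(dark) + max(dark)) / 2
  }
  r1 <- min(dark_rows); r2 <- max(dark_rows)
  matrix(c(r1, mid(r1), r2, mid(r2)), ncol = 2, byrow = TRUE,
         dimnames = list(c("posterior", "anterior"), c("row", "col")))
}

#' Fold-region mask around the glottal gap
#'
#' The total fold region used to normalise vibrating areas: all pixels within
#' `margin * glottal_length` columns of the partition boundary, over the pole
#' row span. Each side's total area is the part of this region on its side of
#' the boundary.
#'
#' @param partition a `glottis_partition`.
#' @param margin lateral half-width as a fraction of the glottal length,
#'   default 0.25.
#' @return Logical `H x W` mask.
#' @export
glottis_roi <- function(partition, margin = 0.25) {
  stopifnot(inherits(partition, "glottis_partition"))
  h <- nrow(partition$left); w <- ncol(partition$left)
  len <- length(partition$rows)
  half <- margin * len
  roi <- matrix(FALSE, h, w)
  cols <- seq_len(w)
  for (k in seq_along(partition$rows)) {
    b <- partition$boundary[k]
    roi[partition$rows[k], abs(cols - b) <= half] <- TRUE
  }
  roi
}

#' Stiffness Asymmetry Index from a vibration mask and partition
#'
#' For each side `s`, the relative vibrating area is
#' `RVA_s = vibrating pixels on side s / total fold-region pixels on side s`;
#' the Stiffness Asymmetry Index is
#' `SAI = 1 - min(RVA_L, RVA_R) / max(RVA_L, RVA_R)`.
#' SAI is 0 iff the two relative vibrating areas are equal, 1 when one fold
#' does not vibrate at all, and is exactly invariant under proportional
#' scaling of one side's vibrating and total areas (robustness to moderate
#' perspective distortion). If neither side vibrates, SAI is 1 with status
#' `"no vibration"`.
#'
#' @param mask logical vibration mask from [detect_vibration_mask()].
#' @param partition a `glottis_partition`.
#' @param roi total fold-region mask, default [glottis_roi()] of the
#'   partition.
#' @return A one-row tibble: `rva_left`, `rva_right`, `sai`, `mode`, `status`.
#' @export
compute_sai <- function(mask, partition, roi = glottis_roi(partition)) {
  stopifnot(inherits(partition, "glottis_partition"), is.logical(mask))
  left_tot <- sum(roi & partition$left)
  right_tot <- sum(roi & partition$right)
  if (left_tot == 0L || right_tot == 0L)
    abort("empty side region; check poles/ROI.")
  rva_l <- sum(mask & roi & partition$left) / left_tot
  rva_r <- sum(mask & roi & partition$right) / right_tot
  if (max(rva_l, rva_r) == 0) {
    return(tibble(rva_left = 0, rva_right = 0, sai = 1,
                  mode = partition$mode, status = "no vibration"))
  }
  tibble(
    rva_left = rva_l, rva_right = rva_r,
    sai = 1 - min(rva_l, rva_r) / max(rva_l, rva_r),
    mode = partition$mode, status = "ok"
  )
}

#' Phase difference between the two folds from an LTG map
#'
#' Circular mean of the F0 phase over vibrating pixels, per side; returns
#' the left-minus-right difference wrapped to (-180, 180]. Because brightness
#' at both fold edges is modulated by occlusion in the same way, the
#' brightness-phase difference equals the kinematic left/right phase lag.
#'
#' @param ltg an `ltg_map`.
#' @param partition a `glottis_partition`.
#' @param mask vibration mask, default from [detect_vibration_mask()].
#' @return Phase difference in degrees.
#' @export
ltg_phase_difference <- function(ltg, partition,
                                 mask = detect_vibration_mask(ltg)) {
  circ_mean <- function(deg) {
    if (!length(deg)) return(NA_real_)
    Arg(mean(exp(1i * deg * pi / 180))) * 180 / pi
  }
  ph_l <- circ_mean(ltg$phase_deg[mask & partition$left])
  ph_r <- circ_mean(ltg$phase_deg[mask & partition$right])
  d <- ph_l - ph_r
  ((d + 180) %% 360) - 180
}

#' One-shot stiffness asymmetry analysis of a frame stack
#'
#' Convenience pipeline: brightness spectra over the fold region, global F0,
#' LTG map, vibration mask, partition and SAI.
#'
#' @inheritParams partition_glottis
#' @param poles pole coordinates; `NULL` detects them with [detect_poles()].
#' @param band F0 search band (Hz).
#' @param k vibration threshold in MAD units.
#' @param mode partition mode.
#' @param margin fold-region margin (fraction of glottal length).
#' @param window spectral window.
#' @return A one-row tibble as [compute_sai()], plus columns `f0` and
#'   `n_vibrating`. The intermediate objects are attached as attribute
#'   `"objects"` (list: `spectra`, `ltg`, `partition`, `mask`, `roi`).
#' @export
analyze_stiffness <- function(stack, poles = NULL, band = c(70, 500), k = 4,
                              mode = c("adaptive", "straight"), margin = 0.25,
                              window = "hann") {
  mode <- match.arg(mode)
  if (is.null(poles)) poles <- detect_poles(stack)
  partition <- partition_glottis(stack, poles, mode)
  roi <- glottis_roi(partition, margin)
  spectra <- extract_brightness_spectra(stack, roi, window = window)
  f0 <- identify_f0(spectra, band)
  if (f0$status != "ok")
    abort("no oscillation detected in the configured band.")
  ltg <- build_ltg_map(spectra, f0$f0, band)
  mask <- detect_vibration_mask(ltg, k)
  res <- compute_sai(mask, partition, roi)
  res$f0 <- f0$f0
  res$n_vibrating <- sum(mask)
  attr(res, "objects") <- list(spectra = spectra, ltg = ltg,
                               partition = partition, mask = mask, roi = roi)
  res
}
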