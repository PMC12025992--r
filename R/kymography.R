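#' Edge trajectories container
#'
#' Lateral displacement of the left and right fold edges sampled at `M` axis
#' positions (posterior to anterior, as percent of fold length) over time,
#' measured from the partition boundary (positive = abducted). The per-position
#' gap width is `g_i(t) = max(0, x_L,i(t) + x_R,i(t))` and the glottal area
#' waveform is `GA(t) = sum_i g_i(t) * delta` with `delta = L / M`.
#'
#' @param x_left,x_right `T x M` matrices of edge displacements in pixels.
#' @param frame_rate frames per second.
#' @param glottal_length fold length `L` in pixels.
#' @param positions_pct axis positions in %FL; default `100 * (1:M) / M`.
#' @return An object of class `edge_trajectories`.
#' @export
edge_trajectories <- function(x_left, x_right, frame_rate, glottal_length,
                              positions_pct = NULL) {
  stopifnot(is.matrix(x_left), is.matrix(x_right),
            all(dim(x_left) == dim(x_right)))
  m <- ncol(x_left)
  if (is.null(positions_pct)) positions_pct <- 100 * seq_len(m) / m
  gap <- pmax(x_left + x_right, 0)
  delta <- glottal_length / m
  structure(
    list(
      x_left = x_left, x_right = x_right, gap = gap,
      ga = rowSums(gap) * delta,
      positions_pct = positions_pct, m = m,
      glottal_length = glottal_length, delta = delta,
      frame_rate = frame_rate
    ),
    class = "edge_trajectories"
  )
}

#' @export
print.edge_trajectories <- function(x, ...) {
  cat(sprintf("<edge_trajectories> %d frames x %d positions, L = %.0f px\n",
              nrow(x$x_left), x$m, x$glottal_length))
  invisible(x)
}

#' Extract fold-edge trajectories from a frame stack
#'
#' At `M` equidistant axis positions (`100 * i / M` %FL, posterior to
#' anterior), segments the dark glottal gap of every frame by an intensity
#' threshold (Otsu over the fold region by default) and localises the left and
#' right fold edges with sub-pixel precision from the linear brightness ramp
#' of the anti-aliased edge. Rows whose gap is fully closed give
#' `x_L = x_R = 0` at the boundary.
#'
#' @param stack a [frame_stack()].
#' @param partition a `glottis_partition`.
#' @param m number of axis positions; must be a multiple of 3 and >= 9
#'   (default 33).
#' @param threshold fixed gap/tissue intensity threshold; `NULL` computes an
#'   Otsu threshold over the fold region of a frame subsample.
#' @param search_margin lateral search half-width around the boundary, as a
#'   fraction of the glottal length (default 0.3).
#' @return An [edge_trajectories()] object (plus attribute `"threshold"`).
#' @export
extract_edge_trajectories <- function(stack, partition, m = 33,
                                      threshold = NULL, search_margin = 0.3) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(partition, "glottis_partition"))
  if (m < 9 || m %% 3 != 0)
    abort("`m` must be >= 9 and divisible into thirds.")
  len <- length(partition$rows)
  pos_idx <- 1L + round(seq_len(m) / m * (len - 1L))
  rows <- partition$rows[pos_idx]
  bnd <- partition$boundary[pos_idx]
  half <- max(3, round(search_margin * len))
  tt <- stack$n_frames
  if (is.null(threshold)) {
    sub <- stack$frames[unique(round(seq(1, tt, length.out = min(32, tt)))),
                        rows, , drop = FALSE]
    threshold <- EBImage::otsu(EBImage::Image(as.vector(sub)),
                               range = range(sub), levels = 256)
  }
  x_l <- x_r <- matrix(0, tt, m)
  cols_all <- seq_len(stack$width)
  for (i in seq_len(m)) {
    cols <- cols_all[abs(cols_all - bnd[i]) <= half]
    prof <- stack$frames[, rows[i], cols, drop = TRUE] # T x n_cols
    if (is.null(dim(prof))) prof <- matrix(prof, nrow = tt)
    tissue <- apply(prof, 1, max)
    gap_i <- pmin(apply(prof, 1, min), threshold - 1e-6)
    depth <- pmax(tissue - gap_i, 1e-6)
    cov <- (tissue - prof) / depth
    cov[cov < 0] <- 0
    cov[cov > 1] <- 1
    is_gap <- prof < threshold & cov > 0.5
    open <- rowSums(is_gap) > 0
    if (any(open)) {
      first <- max.col(is_gap[open, , drop = FALSE], ties.method = "first")
      last <- max.col(is_gap[open, , drop = FALSE], ties.method = "last")
      ri <- seq_len(sum(open))
      e_left <- cols[first] + 0.5 - cov[open, , drop = FALSE][cbind(ri, first)]
      e_right <- cols[last] - 0.5 + cov[open, , drop = FALSE][cbind(ri, last)]
      x_l[open, i] <- bnd[i] - e_left
      x_r[open, i] <- e_right - bnd[i]
    }
  }
  if (all(x_l == 0) && all(x_r == 0))
    abort("closed glottis: no gap detectable in any frame.")
  out <- edge_trajectories(x_l, x_r, stack$frame_rate,
                           glottal_length = len,
                           positions_pct = 100 * seq_len(m) / m)
  attr(out, "threshold") <- as.numeric(threshold)
  out
}

#' Segment the glottal area waveform into oscillation cycles
#'
#' Cycle boundaries are placed at the minima (closed-phase midpoints) of the
#' lightly smoothed glottal area waveform, separated by at least half the
#' estimated period. The period estimate comes from the spectral peak of the
#' waveform inside `band`.
#'
#' @param traj an [edge_trajectories()] object.
#' @param band F0 search band in Hz.
#' @return A list of class `cycle_segmentation`: `boundaries` (frame indices,
#'   strictly increasing), `n_cycles`, `period_frames` (mean period `T0`),
#'   `f0` (Hz).
#' @export
segment_cycles <- function(traj, band = c(70, 500)) {
  stopifnot(inherits(traj, "edge_trajectories"))
  ga <- traj$ga
  if (diff(range(ga)) < 1e-9) abort("glottal area waveform is constant.")
  tt <- length(ga)
  # spectral period estimate
  spec <- Mod(fft(ga - mean(ga)))[seq_len(tt %/% 2 + 1)]
  freq <- (seq_along(spec) - 1) * traj$frame_rate / tt
  in_band <- freq >= band[1] & freq <= band[2]
  if (!any(in_band)) abort("no frequency bin inside `band`.")
  f0_est <- freq[in_band][which.max(spec[in_band])]
  period <- traj$frame_rate / f0_est
  k <- max(3L, round(period / 8))
  k <- k + (k + 1L) %% 2L # odd window
  s <- as.numeric(stats::filter(ga, rep(1 / k, k), sides = 2))
  s[is.na(s)] <- ga[is.na(s)]
  level <- min(s) + 0.3 * diff(range(s))
  ups <- which(s[-1] >= level & s[-tt] < level) + 1L
  min_sep <- floor(0.5 * period)
  if (length(ups) > 1L) {
    keep <- c(TRUE, diff(ups) >= min_sep)
    while (!all(keep)) {
      ups <- ups[keep]
      keep <- c(TRUE, diff(ups) >= min_sep)
    }
  }
  if (length(ups) < 4L) abort("fewer than 3 complete cycles detected.")
  boundaries <- vapply(seq_len(length(ups) - 1L), function(j) {
    span <- ups[j]:ups[j + 1L]
    mins <- span[s[span] == min(s[span])]
    mins[ceiling(length(mins) / 2)] # middle of a closed-phase plateau
  }, integer(1))
  boundaries <- unique(boundaries)
  if (length(boundaries) < 4L) abort("fewer than 3 complete cycles detected.")
  t0 <- mean(diff(boundaries))
  structure(
    list(boundaries = boundaries, n_cycles = length(boundaries) - 1L,
         period_frames = t0, f0 = traj$frame_rate / t0),
    class = "cycle_segmentation"
  )
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation> %d cycles, T0 = %.2f frames (F0 = %.1f Hz)\n",
              x$n_cycles, x$period_frames, x$f0))
  invisible(x)
}

#' Names of the 38 kymographic vibratory parameters
#'
#' Ordered registry of the parameter names produced by
#' [compute_kymo_parameters()] (units: %FL for amplitudes and their argmax
#' indices, % for quotients and asymmetries, degrees for phase differences).
#'
#' @return Character vector of length 38.
#' @export
kymo_parameter_names <- function() {
  c("AmpMaxInd", "AmpRMaxInd", "AmpLMaxInd",
    "AmpCenter", "AmpRCenter", "AmpLCenter",
    "AmpAvg", "AmpAvg_1/3", "AmpAvg_2/3", "AmpAvg_3/3",
    "AmpLAvg", "AmpRAvg",
    "Nonclosing", "Nonopening",
    "EffectiveArea", "RGGA",
    "OQAvg", "OQAvg_1/3", "OQAvg_2/3", "OQAvg_3/3",
    "AmplAsymAvg", "AmplAsymAvg_1/3", "AmplAsymAvg_2/3", "AmplAsymAvg_3/3",
    "AmplAsymWeighted",
    "PhaseAsymAvg", "PhaseAsymAvg_1/3", "PhaseAsymAvg_2/3", "PhaseAsymAvg_3/3",
    "PhaseAsymWeighted",
    "Rel2CommonAmplAvg",
    "PhaseDiffAvg", "PhaseDiffAvg_1/3", "PhaseDiffAvg_2/3", "PhaseDiffAvg_3/3",
    "PhaseDiffWeighted",
    "AbsPhaseDiffAvg", "AbsPhaseDiffWeighted")
}

# phase of the cross-spectrum of two series at frequency f0 (degrees,
# (-180, 180]); positive = left leads right
cross_spectrum_phase <- function(x_l, x_r, f0, frame_rate) {
  tt <- length(x_l)
  w <- exp(-2i * pi * f0 * (seq_len(tt) - 1) / frame_rate)
  z <- sum((x_l - mean(x_l)) * w) * Conj(sum((x_r - mean(x_r)) * w))
  d <- Arg(z) * 180 / pi
  d <- ((d + 180) %% 360) - 180
  if (d == -180) d <- 180
  d
}

# open fraction of one cycle of gap samples: open runs are located by the
# closure threshold, then the opening/closing instants are refined by linear
# extrapolation of the gap slope to zero gap, removing the threshold bias
open_fraction <- function(g, theta_c) {
  n <- length(g)
  open <- g > theta_c
  if (!any(open)) return(0)
  if (all(open)) return(1)
  r <- rle(open)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dur <- 0
  for (k in which(r$values)) {
    j1 <- starts[k]; j2 <- ends[k]
    if (j2 - j1 < 1L) { dur <- dur + 1; next }
    slope_up <- g[j1 + 1L] - g[j1]
    t_open <- if (j1 > 1L && slope_up > 0) j1 - g[j1] / slope_up else j1 - 0.5
    slope_dn <- g[j2 - 1L] - g[j2]
    t_close <- if (j2 < n && slope_dn > 0) j2 + g[j2] / slope_dn else j2 + 0.5
    dur <- dur + min(t_close, n) - max(t_open, 1)
  }
  min(1, dur / n)
}

# circular lag (frames) maximizing the cross-correlation of x_l and x_r,
# restricted to +/- half a period
xcorr_lag <- function(x_l, x_r, max_lag) {
  tt <- length(x_l)
  cc <- Re(fft(fft(x_l - mean(x_l)) * Conj(fft(x_r - mean(x_r))),
               inverse = TRUE)) / tt
  lags <- c(0:max_lag, -(max_lag:1))
  idx <- c(seq_len(max_lag + 1L), tt - (max_lag:1) + 1L)
  lags[which.max(cc[idx])]
}

#' Compute the 38 kymographic vibratory parameters
#'
#' Per-position, per-cycle amplitudes (half peak-to-peak of the edge
#' displacement and of the gap width), open quotients and glottal-area
#' extrema are averaged over cycles and then aggregated into the named
#' parameter registry (see [kymo_parameter_names()]):
#' amplitudes in %FL (`100 * px / L`), argmax-position indices in %FL,
#' `Nonclosing`/`Nonopening` as the percentage of positions whose gap never
#' closes below / never opens above `theta_c`, glottal-area quantities
#' (`EffectiveArea`, `RGGA`), open quotients in %, amplitude asymmetry
#' `100 * |A_L - A_R| / max(A_L, A_R)` (mean, thirds, and weighted by
#' `A_L + A_R`), phase asymmetry `100 * |lag| / T0` from the circular
#' cross-correlation lag, `Rel2CommonAmplAvg`, and phase differences from the
#' cross-spectrum at F0 (mean, thirds, weighted, and absolute variants).
#' Thirds split the positions by index into posterior/middle/anterior.
#'
#' Positions where both folds are effectively rigid (amplitude below
#' `rigid_tol` pixels) are excluded from the asymmetry and phase families;
#' the count is reported in attribute `"n_excluded"`.
#'
#' @param traj an [edge_trajectories()] object.
#' @param cycles a `cycle_segmentation` from [segment_cycles()].
#' @param theta_c closure threshold in pixels (default 1).
#' @param rigid_tol amplitude (px) below which a fold is considered rigid at
#'   a position.
#' @return A one-row tibble with the 38 named parameters, attribute
#'   `"n_excluded"`.
#' @export
compute_kymo_parameters <- function(traj, cycles, theta_c = 1,
                                    rigid_tol = 0.25) {
  stopifnot(inherits(traj, "edge_trajectories"),
            inherits(cycles, "cycle_segmentation"))
  if (cycles$n_cycles < 3L) abort("need at least 3 complete cycles.")
  m <- traj$m
  b <- cycles$boundaries
  nc <- cycles$n_cycles
  amp <- function(v) (max(v) - min(v)) / 2
  a_l <- a_r <- a_g <- oq <- ming <- maxg <- matrix(0, nc, m)
  eff <- rgga <- numeric(nc)
  for (c_ in seq_len(nc)) {
    fr <- b[c_]:b[c_ + 1L]
    xl <- traj$x_left[fr, , drop = FALSE]
    xr <- traj$x_right[fr, , drop = FALSE]
    g <- traj$gap[fr, , drop = FALSE]
    a_l[c_, ] <- apply(xl, 2, amp)
    a_r[c_, ] <- apply(xr, 2, amp)
    a_g[c_, ] <- apply(g, 2, amp)
    oq[c_, ] <- apply(g, 2, open_fraction, theta_c = theta_c)
    ming[c_, ] <- apply(g, 2, min)
    maxg[c_, ] <- apply(g, 2, max)
    ga <- traj$ga[fr]
    eff[c_] <- if (max(ga) > 0) 100 * (max(ga) - min(ga)) / max(ga) else 0
    rgga[c_] <- if (max(ga) > 0) 100 * min(ga) / max(ga) else 0
  }
  # cycle-averaged, per position (pixels)
  al <- colMeans(a_l); ar <- colMeans(a_r); ag <- colMeans(a_g)
  oq_i <- 100 * colMeans(oq)
  l <- traj$glottal_length
  pct <- function(px) 100 * px / l
  pos <- traj$positions_pct
  third <- ceiling(3 * seq_len(m) / m)
  full_span <- b[1]:b[nc + 1L]
  max_lag <- floor(cycles$period_frames / 2)
  active <- pmax(al, ar) >= rigid_tol
  n_excluded <- sum(!active)
  pd <- pa <- rep(NA_real_, m)
  for (i in which(active)) {
    pd[i] <- cross_spectrum_phase(traj$x_left[full_span, i],
                                  traj$x_right[full_span, i],
                                  cycles$f0, traj$frame_rate)
    lag <- xcorr_lag(traj$x_left[full_span, i], traj$x_right[full_span, i],
                     max_lag)
    pa[i] <- 100 * abs(lag) / cycles$period_frames
  }
  asym <- ifelse(active & pmax(al, ar) > 0,
                 100 * abs(al - ar) / pmax(al, ar), NA_real_)
  wgt <- al + ar
  mean_in <- function(v, idx = rep(TRUE, m)) {
    v <- v[idx & !is.na(v)]
    if (!length(v)) return(NA_real_)
    mean(v)
  }
  wmean_in <- function(v, w) {
    ok <- !is.na(v)
    if (!any(ok) || sum(w[ok]) == 0) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }
  rel2common <- {
    ok <- ag > rigid_tol
    if (any(ok)) mean(c(100 * al[ok] / ag[ok], 100 * ar[ok] / ag[ok]))
    else NA_real_
  }
  vals <- c(
    AmpMaxInd = pos[which.max(ag)],
    AmpRMaxInd = pos[which.max(ar)],
    AmpLMaxInd = pos[which.max(al)],
    AmpCenter = pct(ag[which.min(abs(pos - 50))]),
    AmpRCenter = pct(ar[which.min(abs(pos - 50))]),
    AmpLCenter = pct(al[which.min(abs(pos - 50))]),
    AmpAvg = mean(pct(ag)),
    `AmpAvg_1/3` = mean(pct(ag[third == 1])),
    `AmpAvg_2/3` = mean(pct(ag[third == 2])),
    `AmpAvg_3/3` = mean(pct(ag[third == 3])),
    AmpLAvg = mean(pct(al)),
    AmpRAvg = mean(pct(ar)),
    Nonclosing = 100 * mean(colMeans(ming) > theta_c),
    Nonopening = 100 * mean(colMeans(maxg) < theta_c),
    EffectiveArea = mean(eff),
    RGGA = mean(rgga),
    OQAvg = mean(oq_i),
    `OQAvg_1/3` = mean(oq_i[third == 1]),
    `OQAvg_2/3` = mean(oq_i[third == 2]),
    `OQAvg_3/3` = mean(oq_i[third == 3]),
    AmplAsymAvg = mean_in(asym),
    `AmplAsymAvg_1/3` = mean_in(asym, third == 1),
    `AmplAsymAvg_2/3` = mean_in(asym, third == 2),
    `AmplAsymAvg_3/3` = mean_in(asym, third == 3),
    AmplAsymWeighted = wmean_in(asym, wgt),
    PhaseAsymAvg = mean_in(pa),
    `PhaseAsymAvg_1/3` = mean_in(pa, third == 1),
    `PhaseAsymAvg_2/3` = mean_in(pa, third == 2),
    `PhaseAsymAvg_3/3` = mean_in(pa, third == 3),
    PhaseAsymWeighted = wmean_in(pa, wgt),
    Rel2CommonAmplAvg = rel2common,
    PhaseDiffAvg = mean_in(pd),
    `PhaseDiffAvg_1/3` = mean_in(pd, third == 1),
    `PhaseDiffAvg_2/3` = mean_in(pd, third == 2),
    `PhaseDiffAvg_3/3` = mean_in(pd, third == 3),
    PhaseDiffWeighted = wmean_in(pd, wgt),
    AbsPhaseDiffAvg = mean_in(abs(pd)),
    AbsPhaseDiffWeighted = wmean_in(abs(pd), wgt)
  )
  out <- as_tibble(as.list(vals))
  attr(out, "n_excluded") <- n_excluded
  out
}
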