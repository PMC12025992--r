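#' Parameters of a synthetic glottal oscillation recording
#'
#' Defines the kinematic and photometric model used by [simulate_recording()]:
#' two opposed fold edges oscillating about a vertical midline with a
#' half-rectified sinusoidal waveform (which yields a genuine closed phase and
#' a controllable open quotient), an optional unilateral lesion that
#' attenuates the local vibration amplitude and may protrude medially, a dark
#' glottal gap on bright tissue, and additive Gaussian sensor noise.
#'
#' The lateral edge position of side `s` at axis position `u` (0 = posterior
#' pole, 1 = anterior pole) and time `t` is
#' `x_s(u, t) = bulge_s(u) + A_s(u) * w(2*pi*f0*t + phi_s) * (1 - stiffness * 1[u in lesion])`
#' with `w(theta) = max(0, (sin(theta) - cos(pi*q)) / (1 - cos(pi*q)))`, so the
#' fold is abducted for exactly the fraction `q = open_quotient` of each cycle.
#' Colliding folds are clamped so the gap width is never negative.
#'
#' @param f0 fundamental frequency in Hz; must be below `frame_rate / 2`.
#' @param n_frames,frame_rate recording length (frames) and rate (frames/s).
#'   The defaults (2000 frames at 3200 fps) give a 625 ms segment.
#' @param width,height frame size in pixels.
#' @param glottal_length glottal axis extent in pixels (along image rows).
#' @param amp_left,amp_right peak half-width oscillation amplitudes (pixels,
#'   non-negative) of the left/right fold; scaled along the axis by a smooth
#'   profile vanishing towards neither pole completely (see
#'   `amp_profile_floor`).
#' @param amp_profile_floor relative amplitude retained at the poles; the
#'   axial profile is `floor + (1 - floor) * sin(pi * u)`.
#' @param phase_offset right-fold phase lag behind the left fold, degrees.
#' @param open_quotient fraction of the cycle each fold is abducted, in (0, 1].
#' @param lesion_side `"none"`, `"left"` or `"right"`.
#' @param lesion_extent fractional axis interval `c(a, b)` within `[0, 1]`
#'   covered by the lesion.
#' @param lesion_stiffness amplitude attenuation inside the lesion, in
#'   `[0, 1]`; 1 renders the covered extent fully non-vibrating.
#' @param lesion_bulge static medial protrusion of the lesion, pixels.
#' @param noise_sd standard deviation of additive brightness noise
#'   (intensity units on the `[0, 1]` scale).
#' @param tissue,gap brightness of fold tissue and of the glottal gap.
#' @param seed integer seed making the render reproducible.
#' @return A validated list of class `oscillation_params`.
#' @export
oscillation_params <- function(f0 = 150,
                               n_frames = 2000,
                               frame_rate = 3200,
                               width = 64,
                               height = 256,
                               glottal_length = 192,
                               amp_left = 6,
                               amp_right = 6,
                               amp_profile_floor = 0.35,
                               phase_offset = 0,
                               open_quotient = 0.6,
                               lesion_side = c("none", "left", "right"),
                               lesion_extent = c(0.3, 0.7),
                               lesion_stiffness = 0,
                               lesion_bulge = 0,
                               noise_sd = 0.01,
                               tissue = 0.8,
                               gap = 0.1,
                               seed = 1L) {
  lesion_side <- match.arg(lesion_side)
  p <- list(
    f0 = f0, n_frames = as.integer(n_frames), frame_rate = frame_rate,
    width = as.integer(width), height = as.integer(height),
    glottal_length = as.integer(glottal_length),
    amp_left = amp_left, amp_right = amp_right,
    amp_profile_floor = amp_profile_floor,
    phase_offset = phase_offset, open_quotient = open_quotient,
    lesion_side = lesion_side, lesion_extent = as.numeric(lesion_extent),
    lesion_stiffness = lesion_stiffness, lesion_bulge = lesion_bulge,
    noise_sd = noise_sd, tissue = tissue, gap = gap, seed = as.integer(seed)
  )
  validate_oscillation_params(p)
  structure(p, class = "oscillation_params")
}

validate_oscillation_params <- function(p) {
  if (p$f0 >= p$frame_rate / 2)
    abort("`f0` must be below the Nyquist frequency frame_rate/2.")
  if (p$f0 <= 0) abort("`f0` must be positive.")
  if (p$n_frames < 2L || p$width < 4L || p$height < 4L || p$glottal_length < 4L)
    abort("non-positive or degenerate dimensions are not allowed.")
  if (p$glottal_length > p$height)
    abort("`glottal_length` cannot exceed `height`.")
  if (p$amp_left < 0 || p$amp_right < 0) abort("amplitudes must be >= 0.")
  if (p$open_quotient <= 0 || p$open_quotient > 1)
    abort("`open_quotient` must lie in (0, 1].")
  if (p$lesion_stiffness < 0 || p$lesion_stiffness > 1)
    abort("`lesion_stiffness` must lie in [0, 1].")
  if (length(p$lesion_extent) != 2L || p$lesion_extent[1] > p$lesion_extent[2] ||
      p$lesion_extent[1] < 0 || p$lesion_extent[2] > 1)
    abort("`lesion_extent` must be an interval [a, b] within [0, 1].")
  if (p$lesion_bulge < 0) abort("`lesion_bulge` must be >= 0.")
  if (p$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  invisible(p)
}

# analytic edge columns for every frame; returns list of T x L matrices
# (left/right edge column positions, continuous coordinates) plus axis info
analytic_edges <- function(p) {
  ll <- p$glottal_length
  u <- if (ll > 1) (seq_len(ll) - 1) / (ll - 1) else 0
  prof <- p$amp_profile_floor + (1 - p$amp_profile_floor) * sin(pi * u)
  a_l <- p$amp_left * prof
  a_r <- p$amp_right * prof
  in_lesion <- u >= p$lesion_extent[1] & u <= p$lesion_extent[2]
  att <- 1 - p$lesion_stiffness * in_lesion
  bulge_l <- bulge_r <- numeric(ll)
  if (p$lesion_side == "left") {
    a_l <- a_l * att
    bulge_l[in_lesion] <- p$lesion_bulge
  } else if (p$lesion_side == "right") {
    a_r <- a_r * att
    bulge_r[in_lesion] <- p$lesion_bulge
  }
  cx <- (p$width + 1) / 2
  tt <- (seq_len(p$n_frames) - 1) / p$frame_rate
  c0 <- cos(pi * p$open_quotient)
  wave <- function(theta) {
    if (p$open_quotient == 1) return(pmax(0, sin(theta)))
    pmax(0, (sin(theta) - c0) / (1 - c0))
  }
  th <- 2 * pi * p$f0 * tt
  w_l <- wave(th)
  w_r <- wave(th - 2 * pi * p$phase_offset / 360)
  e_l <- cx + matrix(bulge_l, p$n_frames, ll, byrow = TRUE) - outer(w_l, a_l)
  e_r <- cx - matrix(bulge_r, p$n_frames, ll, byrow = TRUE) + outer(w_r, a_r)
  # fold collision: clamp so the gap never goes negative
  collide <- e_l > e_r
  if (any(collide)) {
    mid <- (e_l + e_r) / 2
    e_l[collide] <- mid[collide]
    e_r[collide] <- mid[collide]
  }
  r0 <- (p$height - ll) %/% 2L + 1L
  list(
    e_left = e_l, e_right = e_r, midline = cx, u = u,
    rows = seq.int(r0, r0 + ll - 1L),
    amp_left = a_l, amp_right = a_r
  )
}

#' Render a synthetic high-speed recording of an oscillating glottis
#'
#' Renders bright fold tissue with a dark glottal gap between the two edge
#' curves defined by `params` (linear anti-aliasing at the edges), adds
#' Gaussian sensor noise, and returns the frame stack together with the exact
#' ground truth used for rendering. Rendering is deterministic given
#' `params$seed`.
#'
#' @param params an [oscillation_params()] object.
#' @return A list with elements
#'   * `stack`: a [frame_stack()];
#'   * `truth`: a `ground_truth` list carrying the analytic edge trajectories
#'     (`edge_left`, `edge_right`, `T x L` matrices of edge columns), the true
#'     vibrating-pixel mask, poles, midline, the fold row span, and the
#'     expected parameter values (`sai_expected`, `ampl_asym_expected_pct`,
#'     `phase_offset_deg`, `open_quotient`, `f0`).
#' @export
simulate_recording <- function(params) {
  stopifnot(inherits(params, "oscillation_params"))
  validate_oscillation_params(params)
  p <- params
  ed <- analytic_edges(p)
  tt <- p$n_frames
  ll <- p$glottal_length
  w <- p$width
  frames <- array(p$tissue, dim = c(tt, p$height, w))
  col_lo <- matrix(seq_len(w) - 0.5, ll, w, byrow = TRUE)
  col_hi <- col_lo + 1
  depth <- p$tissue - p$gap
  for (t in seq_len(tt)) {
    cov <- pmin(col_hi, ed$e_right[t, ]) - pmax(col_lo, ed$e_left[t, ])
    cov <- pmin(1, pmax(0, cov))
    frames[t, ed$rows, ] <- p$tissue - depth * cov
  }
  if (p$noise_sd > 0) {
    set.seed(p$seed)
    frames <- frames + rnorm(length(frames), sd = p$noise_sd)
    frames[frames < 0] <- 0
    frames[frames > 1] <- 1
  }
  truth <- ground_truth_from_edges(p, ed)
  list(stack = frame_stack(frames, p$frame_rate), truth = truth)
}

ground_truth_from_edges <- function(p, ed) {
  sweep_l <- apply(ed$e_left, 2, function(x) diff(range(x)))
  sweep_r <- apply(ed$e_right, 2, function(x) diff(range(x)))
  h <- p$height
  w <- p$width
  mask <- matrix(FALSE, h, w)
  min_l <- apply(ed$e_left, 2, min); max_l <- apply(ed$e_left, 2, max)
  min_r <- apply(ed$e_right, 2, min); max_r <- apply(ed$e_right, 2, max)
  eps <- 0.25 # sub-pixel sweeps do not modulate brightness measurably
  for (k in seq_along(ed$rows)) {
    r <- ed$rows[k]
    if (sweep_l[k] > eps)
      mask[r, seq_len(w) + 0.5 > min_l[k] & seq_len(w) - 0.5 < max_l[k]] <- TRUE
    if (sweep_r[k] > eps)
      mask[r, seq_len(w) + 0.5 > min_r[k] & seq_len(w) - 0.5 < max_r[k]] <- TRUE
  }
  v_l <- sum(sweep_l)
  v_r <- sum(sweep_r)
  sai_exp <- if (max(v_l, v_r) == 0) 1 else 1 - min(v_l, v_r) / max(v_l, v_r)
  amp_pair_max <- pmax(ed$amp_left, ed$amp_right)
  ok <- amp_pair_max > 0
  asym <- if (any(ok))
    100 * mean(abs(ed$amp_left[ok] - ed$amp_right[ok]) / amp_pair_max[ok])
  else NA_real_
  structure(
    list(
      edge_left = ed$e_left, edge_right = ed$e_right,
      midline = ed$midline, rows = ed$rows, u = ed$u,
      vibrating_mask = mask,
      poles = matrix(c(ed$rows[1], ed$midline,
                       ed$rows[length(ed$rows)], ed$midline),
                     ncol = 2, byrow = TRUE,
                     dimnames = list(c("posterior", "anterior"),
                                     c("row", "col"))),
      sai_expected = sai_exp,
      ampl_asym_expected_pct = asym,
      phase_offset_deg = p$phase_offset,
      open_quotient = p$open_quotient,
      f0 = p$f0,
      params = p
    ),
    class = "ground_truth"
  )
}

#' Specification of a synthetic three-group cohort
#'
#' Describes the group-conditional distributions from which
#' [simulate_cohort_params()] draws per-subject vibratory parameter vectors.
#' The default emulates a clinical cohort of 21 normophonic subjects, 39
#' benign and 42 malignant unilateral glottic lesions, with stiffness and
#' asymmetry parameters ordered malignant > benign > norm (SAI group centres
#' 0.06 / 0.30 / 0.60) and the remaining vibratory parameters carrying mild or
#' no group effect.
#'
#' @param group_sizes named integer vector `c(Norm = , Benign = , Malignant = )`.
#' @param effects a tibble with one row per parameter and columns `parameter`,
#'   `mean_norm`, `mean_benign`, `mean_malignant`, `sd_norm`, `sd_benign`,
#'   `sd_malignant`, `lower`, `upper`. Defaults to [default_cohort_effects()].
#' @param effect_scale scales every between-group difference relative to the
#'   normophonic mean; 0 collapses all groups onto the normophonic
#'   distribution (a null cohort), 1 is the calibrated default.
#' @param seed integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(Norm = 21L, Benign = 39L, Malignant = 42L),
                        effects = default_cohort_effects(),
                        effect_scale = 1,
                        seed = 1L) {
  if (length(group_sizes) != 3L || is.null(names(group_sizes)))
    abort("`group_sizes` must be a named length-3 vector (Norm/Benign/Malignant).")
  if (any(group_sizes < 2L)) abort("every group must have size >= 2.")
  needed <- c("parameter", "mean_norm", "mean_benign", "mean_malignant",
              "sd_norm", "sd_benign", "sd_malignant", "lower", "upper")
  if (!all(needed %in% names(effects)))
    abort(paste("`effects` must contain columns:", paste(needed, collapse = ", ")))
  if (effect_scale != 1) {
    effects <- dplyr::mutate(
      effects,
      mean_benign = .data$mean_norm + effect_scale * (.data$mean_benign - .data$mean_norm),
      mean_malignant = .data$mean_norm + effect_scale * (.data$mean_malignant - .data$mean_norm)
    )
  }
  structure(
    list(group_sizes = as.integer(group_sizes) |> setNames(names(group_sizes)),
         effects = as_tibble(effects), seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default group-conditional parameter distributions
#'
#' One row per vibratory parameter ([kymo_parameter_names()] plus `"SAI"`)
#' giving group means, group standard deviations, physical bounds, and the
#' loading on a shared latent "stiffness severity" factor. SAI centres are
#' 0.06 / 0.30 / 0.60 for Norm / Benign / Malignant, and the group spreads
#' of the six discriminative parameters (SAI, the amplitude-asymmetry
#' family, the absolute phase differences) are sized via the binormal
#' identity `AUC = Phi(dmu / sqrt(s1^2 + s0^2))` so that each reproduces the
#' published univariate operating characteristics (AUC about 0.9 for
#' organic-lesion detection and 0.75-0.8 for malignancy). Their high latent
#' loadings encode that they all measure the same underlying stiffness
#' asymmetry — without that correlation a multivariate classifier on
#' independent draws would separate the groups almost perfectly. Amplitude
#' and open-quotient parameters carry weak effects, the remaining parameters
#' essentially none.
#'
#' @return A tibble, suitable for the `effects` argument of [cohort_spec()].
#' @export
default_cohort_effects <- function() {
  spec1 <- function(parameter, m, sd, lower, upper, loading = 0)
    tibble(parameter = parameter, mean_norm = m[1], mean_benign = m[2],
           mean_malignant = m[3], sd_norm = sd[1], sd_benign = sd[2],
           sd_malignant = sd[3], lower = lower, upper = upper,
           loading = loading)
  dplyr::bind_rows(
    spec1("SAI", c(0.06, 0.30, 0.60), c(0.05, 0.22, 0.28), 0, 1, 0.85),
    spec1("AmplAsymAvg", c(10, 30, 48), c(7, 12, 22), 0, 100, 0.85),
    spec1("AmplAsymAvg_1/3", c(10, 20, 30), c(7, 12, 18), 0, 100, 0.5),
    spec1("AmplAsymAvg_2/3", c(9, 28, 45), c(7, 12, 22), 0, 100, 0.8),
    spec1("AmplAsymAvg_3/3", c(11, 22, 33), c(7, 12, 18), 0, 100, 0.5),
    spec1("AmplAsymWeighted", c(10, 32, 52), c(7, 12, 22), 0, 100, 0.85),
    spec1("AbsPhaseDiffAvg", c(12, 35, 55), c(8, 16, 26), 0, 180, 0.75),
    spec1("AbsPhaseDiffWeighted", c(12, 36, 57), c(8, 16, 26), 0, 180, 0.75),
    spec1("PhaseDiffAvg", c(0, 8, 14), c(12, 22, 30), -180, 180, 0.4),
    spec1("PhaseDiffAvg_1/3", c(0, 6, 10), c(14, 24, 32), -180, 180, 0.4),
    spec1("PhaseDiffAvg_2/3", c(0, 9, 16), c(13, 23, 31), -180, 180, 0.4),
    spec1("PhaseDiffAvg_3/3", c(0, 7, 12), c(14, 24, 32), -180, 180, 0.4),
    spec1("PhaseDiffWeighted", c(0, 9, 15), c(13, 23, 31), -180, 180, 0.4),
    spec1("PhaseAsymAvg", c(5, 11, 17), c(3, 6, 8), 0, 100, 0.4),
    spec1("PhaseAsymAvg_1/3", c(5, 9, 13), c(3, 6, 8), 0, 100, 0.4),
    spec1("PhaseAsymAvg_2/3", c(5, 11, 17), c(3, 6, 8), 0, 100, 0.4),
    spec1("PhaseAsymAvg_3/3", c(5, 10, 14), c(3, 6, 8), 0, 100, 0.4),
    spec1("PhaseAsymWeighted", c(5, 11, 17), c(3, 6, 8), 0, 100, 0.4),
    spec1("AmpMaxInd", c(50, 50, 48), c(12, 14, 16), 0, 100, 0),
    spec1("AmpRMaxInd", c(50, 50, 47), c(13, 15, 17), 0, 100, 0),
    spec1("AmpLMaxInd", c(50, 50, 47), c(13, 15, 17), 0, 100, 0),
    spec1("AmpCenter", c(7, 6.2, 5.0), c(1.8, 1.8, 1.8), 0, 40, -0.3),
    spec1("AmpRCenter", c(3.5, 3.0, 2.3), c(1.0, 1.0, 1.1), 0, 25, -0.3),
    spec1("AmpLCenter", c(3.5, 3.1, 2.4), c(1.0, 1.0, 1.1), 0, 25, -0.3),
    spec1("AmpAvg", c(6, 5.4, 4.4), c(1.5, 1.5, 1.6), 0, 40, -0.3),
    spec1("AmpAvg_1/3", c(4.5, 4.1, 3.4), c(1.3, 1.3, 1.4), 0, 40, -0.3),
    spec1("AmpAvg_2/3", c(6.5, 5.8, 4.7), c(1.6, 1.6, 1.7), 0, 40, -0.3),
    spec1("AmpAvg_3/3", c(4.8, 4.4, 3.6), c(1.4, 1.4, 1.5), 0, 40, -0.3),
    spec1("AmpLAvg", c(3.0, 2.8, 2.2), c(0.8, 0.8, 0.9), 0, 25, -0.3),
    spec1("AmpRAvg", c(3.0, 2.7, 2.1), c(0.8, 0.8, 0.9), 0, 25, -0.3),
    spec1("Nonclosing", c(12, 16, 24), c(8, 10, 13), 0, 100, 0.4),
    spec1("Nonopening", c(2, 6, 14), c(3, 6, 11), 0, 100, 0.4),
    spec1("EffectiveArea", c(92, 88, 80), c(6, 9, 12), 0, 100, -0.4),
    spec1("RGGA", c(8, 12, 20), c(6, 9, 12), 0, 100, 0.4),
    spec1("OQAvg", c(60, 62, 65), c(7, 8, 9), 0, 100, 0.2),
    spec1("OQAvg_1/3", c(56, 58, 61), c(8, 9, 10), 0, 100, 0.2),
    spec1("OQAvg_2/3", c(64, 66, 69), c(7, 8, 9), 0, 100, 0.2),
    spec1("OQAvg_3/3", c(58, 60, 63), c(8, 9, 10), 0, 100, 0.2),
    spec1("Rel2CommonAmplAvg", c(50, 49, 46), c(6, 7, 9), 0, 100, -0.2)
  )
}

#' Draw a tabular synthetic cohort of vibratory parameters
#'
#' Draws one parameter vector per subject from the group-conditional normal
#' distributions of `spec`, clipped to the stated physical bounds.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with columns `subject_id`, `label` (factor
#'   Norm/Benign/Malignant) and one column per parameter in
#'   `spec$effects$parameter`.
#' @export
simulate_cohort_params <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$group_sizes < 1L)) abort("empty group in `spec`.")
  set.seed(spec$seed)
  groups <- names(spec$group_sizes)
  eff <- spec$effects
  loading <- if ("loading" %in% names(eff)) eff$loading else rep(0, nrow(eff))
  rows <- purrr::map(seq_along(groups), function(g) {
    n <- spec$group_sizes[[g]]
    key <- c("norm", "benign", "malignant")[g]
    z <- rnorm(n) # shared latent severity factor
    vals <- purrr::map(seq_len(nrow(eff)), function(i) {
      m <- eff[[paste0("mean_", key)]][i]
      s <- eff[[paste0("sd_", key)]][i]
      rho <- loading[i]
      x <- m + s * (rho * z + sqrt(1 - rho^2) * rnorm(n))
      pmin(eff$upper[i], pmax(eff$lower[i], x))
    })
    names(vals) <- eff$parameter
    dplyr::bind_cols(tibble(label = groups[g]), as_tibble(vals))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(
    out,
    subject_id = sprintf("S%03d", dplyr::row_number()),
    label = factor(.data$label, levels = groups),
    .before = 1
  )
  out
}

#' Render a small set of cohort videos with ground truth
#'
#' Desk-scale end-to-end asset: renders `n_per_group` recordings per
#' diagnostic group with group-dependent lesion stiffness (none for
#' normophonic folds, moderate for benign, severe for malignant lesions),
#' amplitude asymmetry and phase lag, and returns the stacks together with
#' their ground truth and labels.
#'
#' @param spec a [cohort_spec()] (supplies group names and the seed).
#' @param n_per_group recordings per group.
#' @param base_params template [oscillation_params()]; per-video fields
#'   (lesion, asymmetry, seed) are filled in per group.
#' @param max_bytes memory guard on `n_videos * n_frames * height * width * 8`.
#' @return A list of lists with elements `stack`, `truth`, `label`.
#' @export
render_cohort_videos <- function(spec = cohort_spec(),
                                 n_per_group = 2,
                                 base_params = oscillation_params(
                                   n_frames = 400, width = 64, height = 128,
                                   glottal_length = 96
                                 ),
                                 max_bytes = 2e9) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_videos <- 3L * n_per_group
  need <- n_videos * base_params$n_frames * base_params$height *
    base_params$width * 8
  if (need > max_bytes)
    abort(sprintf("requested renders need ~%.1f GB > max_bytes.", need / 1e9))
  set.seed(spec$seed)
  groups <- names(spec$group_sizes)
  draws <- list(
    stiffness = list(c(0, 0), c(0.3, 0.55), c(0.7, 0.98)),
    amp_ratio = list(c(0.95, 1.05), c(0.75, 0.95), c(0.55, 0.8)),
    phase = list(c(0, 8), c(10, 30), c(25, 60)),
    bulge = list(c(0, 0), c(0, 1.5), c(0.5, 2.5))
  )
  out <- list()
  for (g in seq_along(groups)) {
    for (i in seq_len(n_per_group)) {
      rdraw <- function(nm) runif(1, draws[[nm]][[g]][1], draws[[nm]][[g]][2])
      p <- base_params
      p$lesion_side <- if (g == 1) "none" else "right"
      p$lesion_stiffness <- rdraw("stiffness")
      p$amp_right <- base_params$amp_right * rdraw("amp_ratio")
      p$phase_offset <- rdraw("phase")
      p$lesion_bulge <- rdraw("bulge")
      p$seed <- spec$seed + 1000L * g + i
      class(p) <- "oscillation_params"
      validate_oscillation_params(p)
      rec <- simulate_recording(p)
      out[[length(out) + 1L]] <-
        list(stack = rec$stack, truth = rec$truth, label = groups[g])
    }
  }
  out
}

#' Render a lesion-stiffness sweep
#'
#' Renders one recording per value of `stiffness`, holding everything else
#' fixed; used to check that the measured Stiffness Asymmetry Index grows
#' monotonically with the simulated lesion stiffness.
#'
#' @param stiffness numeric vector of lesion stiffness values in `[0, 1]`.
#' @param base_params template [oscillation_params()]; the lesion side is
#'   forced to `"right"` over the full fold extent.
#' @return A list of `list(stack, truth, stiffness)` entries.
#' @export
render_stiffness_sweep <- function(stiffness = seq(0, 1, by = 0.2),
                                   base_params = oscillation_params(
                                     n_frames = 400, width = 64, height = 128,
                                     glottal_length = 96, noise_sd = 0.01
                                   )) {
  purrr::map(seq_along(stiffness), function(i) {
    p <- base_params
    p$lesion_side <- "right"
    p$lesion_extent <- c(0.25, 0.75)
    p$lesion_stiffness <- stiffness[i]
    p$seed <- base_params$seed + i
    class(p) <- "oscillation_params"
    rec <- simulate_recording(p)
    list(stack = rec$stack, truth = rec$truth, stiffness = stiffness[i])
  })
}
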