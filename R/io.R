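#' Read a frame stack from a multi-page TIFF or a PNG directory
#'
#' Intensities are normalized to `[0, 1]`. The frame rate is taken from a
#' JSON sidecar (`<path>.json` or `metadata.json` in a PNG directory, key
#' `frame_rate`) unless supplied explicitly. PNG directories must contain a
#' gap-free numbered sequence (`frame_0001.png`, ...).
#'
#' @param path a `.tif`/`.tiff` file or a directory of PNG frames.
#' @param frame_rate frames per second; overrides any sidecar value.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, frame_rate = NULL) {
  sidecar <- NULL
  if (dir.exists(path)) {
    meta_file <- file.path(path, "metadata.json")
    if (file.exists(meta_file)) sidecar <- jsonlite::read_json(meta_file)
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) abort("no PNG frames found in directory.")
    nums <- as.integer(gsub("\\D", "", basename(files)))
    if (anyNA(nums)) abort("PNG frames must carry a numeric index.")
    expected <- seq(min(nums), max(nums))
    missing <- setdiff(expected, nums)
    if (length(missing))
      abort(sprintf("PNG sequence has gap(s); missing index: %s",
                    paste(missing, collapse = ", ")))
    imgs <- lapply(files[order(nums)], png::readPNG)
  } else {
    if (!file.exists(path)) abort(sprintf("no such file: %s", path))
    json_file <- paste0(path, ".json")
    if (file.exists(json_file)) sidecar <- jsonlite::read_json(json_file)
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
  }
  imgs <- lapply(imgs, function(im) {
    if (length(dim(im)) == 3L) im <- im[, , 1] # first channel of gray RGB
    im
  })
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("mixed frame sizes in stack.")
  if (is.null(frame_rate)) frame_rate <- sidecar$frame_rate
  if (is.null(frame_rate))
    abort("frame rate unknown: supply `frame_rate` or a JSON sidecar with a `frame_rate` field.")
  tt <- length(imgs)
  frames <- array(0, dim = c(tt, dims[1, 1], dims[2, 1]))
  for (t in seq_len(tt)) frames[t, , ] <- imgs[[t]]
  frame_stack(frames, as.numeric(frame_rate))
}

#' Write a frame stack to disk
#'
#' Writes a multi-page grayscale TIFF (8 or 16 bit) or a numbered PNG
#' directory, plus a JSON sidecar carrying the frame rate (and any extra
#' metadata supplied).
#'
#' @param stack a [frame_stack()].
#' @param path output `.tif` file or directory (created) for PNG frames.
#' @param format `"tiff"` or `"png"`.
#' @param bits 8 or 16.
#' @param metadata named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, format = c("tiff", "png"),
                              bits = 16, metadata = list()) {
  stopifnot(inherits(stack, "frame_stack"))
  format <- match.arg(format)
  if (!bits %in% c(8, 16)) abort("`bits` must be 8 or 16.")
  if (format == "png") bits <- 8 # PNG frames are written 8-bit
  side <- modifyList(list(frame_rate = stack$frame_rate,
                          n_frames = stack$n_frames,
                          height = stack$height, width = stack$width,
                          bits = bits),
                     metadata)
  frames <- lapply(seq_len(stack$n_frames), function(t) stack$frames[t, , ])
  if (format == "tiff") {
    tiff::writeTIFF(frames, path, bits.per.sample = bits)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (t in seq_along(frames))
      png::writePNG(frames[[t]],
                    file.path(path, sprintf("frame_%05d.png", t)))
    jsonlite::write_json(side, file.path(path, "metadata.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Configuration of a reproducible end-to-end run
#'
#' @param cohort_spec a [cohort_spec()] for the tabular cohort; `NULL` with
#'   `cohort_csv` reads a cohort from file instead.
#' @param cohort_csv path to a cohort CSV (columns `subject_id`, `label`,
#'   parameters); used when supplied, skipping simulation.
#' @param n_videos_per_group videos rendered per group (0 skips the imaging
#'   stages).
#' @param video_params template [oscillation_params()] for rendered videos.
#' @param band F0 search band (Hz).
#' @param partition_mode `"adaptive"` or `"straight"`.
#' @param vibration_k vibration-mask threshold in MAD units.
#' @param m_positions kymographic axis positions.
#' @param b bootstrap iterations for ROC analyses.
#' @param k_folds cross-validation folds.
#' @param roc_parameters parameters given bootstrap ROC analyses; default
#'   [mct_features()].
#' @param ml_arms feature arms evaluated: subset of `c("mct", "sffs")`.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory (created by [run_pipeline()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort_spec = laryngovib::cohort_spec(),
                       cohort_csv = NULL,
                       n_videos_per_group = 0,
                       video_params = oscillation_params(
                         n_frames = 400, width = 64, height = 128,
                         glottal_length = 96
                       ),
                       band = c(70, 500),
                       partition_mode = "adaptive",
                       vibration_k = 4,
                       m_positions = 33,
                       b = 1000,
                       k_folds = 5,
                       roc_parameters = mct_features(),
                       ml_arms = "mct",
                       seed = 1L,
                       out_dir = tempfile("laryngovib_run_")) {
  cfg <- list(cohort_spec = cohort_spec, cohort_csv = cohort_csv,
              n_videos_per_group = n_videos_per_group,
              video_params = video_params, band = band,
              partition_mode = partition_mode, vibration_k = vibration_k,
              m_positions = m_positions, b = b, k_folds = k_folds,
              roc_parameters = roc_parameters, ml_arms = ml_arms,
              seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages — synthetic video rendering with per-video
#' stiffness/kymography measurement, tabular cohort simulation (or CSV
#' input), univariate statistics with bootstrap ROC, and cross-validated SVM
#' classification — writing each stage's tables to `cfg$out_dir` along with a
#' provenance manifest (config hash, seeds, package version, per-stage
#' status). A stage failure is recorded in the manifest and the remaining
#' stages are skipped; earlier outputs are retained.
#'
#' @param cfg a [run_config()].
#' @return A list of class `run_report` with elements `cohort`,
#'   `video_measurements`, `stats`, `roc`, `ml`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("laryngovib")),
    stages = list()
  )
  report <- list(manifest = manifest)
  fail <- NULL
  run_stage <- function(name, fun) {
    if (!is.null(fail)) {
      manifest$stages[[name]] <<- "skipped"
      return(NULL)
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- paste("failed:", conditionMessage(res))
      fail <<- name
      NULL
    } else {
      manifest$stages[[name]] <<- "ok"
      res
    }
  }

  report$video_measurements <- run_stage("videos", function() {
    if (cfg$n_videos_per_group < 1) return(NULL)
    vids <- render_cohort_videos(cfg$cohort_spec, cfg$n_videos_per_group,
                                 cfg$video_params)
    rows <- purrr::map_dfr(seq_along(vids), function(i) {
      v <- vids[[i]]
      sai <- analyze_stiffness(v$stack, band = cfg$band,
                               k = cfg$vibration_k,
                               mode = cfg$partition_mode)
      objs <- attr(sai, "objects")
      traj <- extract_edge_trajectories(v$stack, objs$partition,
                                        m = cfg$m_positions)
      cyc <- segment_cycles(traj, cfg$band)
      pars <- compute_kymo_parameters(traj, cyc)
      dplyr::bind_cols(
        tibble(subject_id = sprintf("V%03d", i), label = v$label,
               SAI = sai$sai, sai_expected = v$truth$sai_expected,
               f0 = sai$f0),
        pars
      )
    })
    utils::write.csv(rows, file.path(cfg$out_dir, "video_measurements.csv"),
                     row.names = FALSE)
    rows
  })

  report$cohort <- run_stage("cohort", function() {
    co <- if (!is.null(cfg$cohort_csv)) {
      read_cohort_csv(cfg$cohort_csv)
    } else {
      simulate_cohort_params(cfg$cohort_spec)
    }
    utils::write.csv(co, file.path(cfg$out_dir, "cohort.csv"),
                     row.names = FALSE)
    co
  })

  report$stats <- run_stage("stats", function() {
    compare_groups(report$cohort)
  })

  report$roc <- run_stage("roc", function() {
    tasks <- c("lesion_vs_norm", "malignant_vs_benign")
    purrr::map(setNames(tasks, tasks), function(task) {
      y <- task_labels(report$cohort$label, task)
      keep <- !is.na(y)
      purrr::map(setNames(cfg$roc_parameters, cfg$roc_parameters),
                 function(p) {
        bootstrap_roc(report$cohort[[p]][keep], y[keep],
                      positive = levels(y)[2], b = cfg$b,
                      seed = cfg$seed)
      })
    })
  })

  report$ml <- run_stage("ml", function() {
    tasks <- c("3class", "lesion_vs_norm", "malignant_vs_benign")
    arms <- list()
    if ("mct" %in% cfg$ml_arms)
      arms$mct <- purrr::map(setNames(tasks, tasks), function(task)
        evaluate_cv(report$cohort, mct_features(), task, k = cfg$k_folds,
                    seed = cfg$seed))
    if ("sffs" %in% cfg$ml_arms) {
      feats <- setdiff(names(report$cohort), c("subject_id", "label"))
      arms$sffs <- purrr::map(setNames(tasks, tasks), function(task)
        evaluate_cv(report$cohort, feats, task, k = cfg$k_folds,
                    seed = cfg$seed, select = "sffs"))
    }
    arms
  })

  manifest$outputs <- list(
    cohort_hash = if (!is.null(report$cohort)) rlang::hash(report$cohort),
    stats_hash = if (!is.null(report$stats)) rlang::hash(report$stats)
  )
  manifest$failed_stage <- fail
  report$manifest <- manifest
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  if (!is.null(report$stats)) export_tables(report, cfg$out_dir)
  class(report) <- "run_report"
  report
}

#' Read a cohort CSV
#'
#' Expects columns `subject_id`, `label` and numeric parameter columns named
#' as in [kymo_parameter_names()] plus `SAI`.
#'
#' @param path CSV path.
#' @return A tibble with `label` as a Norm/Benign/Malignant factor.
#' @export
read_cohort_csv <- function(path) {
  co <- as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!all(c("subject_id", "label") %in% names(co)))
    abort("cohort CSV must contain `subject_id` and `label` columns.")
  lv <- intersect(c("Norm", "Benign", "Malignant"), unique(co$label))
  co$label <- factor(co$label, levels = lv)
  co
}

#' Format an estimate with its 95% confidence interval
#'
#' `"0.735 (0.612–0.882)"` style (en-dash between the bounds).
#'
#' @param est,lo,hi numeric vectors.
#' @param digits decimal places.
#' @return Character vector.
#' @export
format_ci <- function(est, lo, hi, digits = 3) {
  r <- function(x) {
    s <- sprintf("%.*f", digits, x)
    s <- sub("0+$", "", s)       # trim trailing zeros
    sub("\\.$", ".0", s)         # but keep one decimal place
  }
  sprintf("%s (%s–%s)", r(est), r(lo), r(hi))
}

#' Parse a "est (lo-hi)" cell back into numbers
#'
#' Inverse of [format_ci()].
#'
#' @param x character vector.
#' @return Tibble with columns `est`, `lo`, `hi`.
#' @export
parse_ci <- function(x) {
  m <- regmatches(x, regexec("^([-0-9.]+) \\(([-0-9.]+)–([-0-9.]+)\\)$", x))
  tibble(
    est = as.numeric(vapply(m, `[`, "", 2)),
    lo = as.numeric(vapply(m, `[`, "", 3)),
    hi = as.numeric(vapply(m, `[`, "", 4))
  )
}

#' Export publication-shaped tables from a run report
#'
#' Writes `group_comparisons.csv` (parameter, pair, p-value, U statistic)
#' and, per ROC task, `roc_<task>.csv` with columns `Parameter`,
#' `Youden's Index (95% CI)`, `Sensitivity (95% CI)`,
#' `Specificity (95% CI)` formatted as `"0.735 (0.612-0.882)"` (en-dash),
#' plus machine-readable numeric companions (`*_numeric.csv`) and the mean
#' ROC curves (`roc_curves_<task>.csv`).
#'
#' @param report a `run_report` (or a list with `stats`/`roc` elements).
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
export_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(report$stats)) {
    pw <- report$stats$pairwise
    if (nrow(pw)) {
      tab <- dplyr::transmute(
        pw, Parameter = .data$parameter, Groups = .data$pair,
        `p-Value` = signif(.data$p_adj, 2), Statistic = .data$u
      )
      p <- file.path(dir, "group_comparisons.csv")
      utils::write.csv(tab, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if (!is.null(report$roc)) {
    for (task in names(report$roc)) {
      g <- purrr::map_dfr(report$roc[[task]], glance, .id = "parameter")
      tab <- tibble(
        Parameter = g$parameter,
        `Youden's Index (95% CI)` = format_ci(g$youden, g$youden_lo,
                                              g$youden_hi),
        `Sensitivity (95% CI)` = format_ci(g$sensitivity, g$sensitivity_lo,
                                           g$sensitivity_hi),
        `Specificity (95% CI)` = format_ci(g$specificity, g$specificity_lo,
                                           g$specificity_hi)
      )
      p1 <- file.path(dir, paste0("roc_", task, ".csv"))
      utils::write.csv(tab, p1, row.names = FALSE)
      p2 <- file.path(dir, paste0("roc_", task, "_numeric.csv"))
      utils::write.csv(g, p2, row.names = FALSE)
      curves <- purrr::map_dfr(report$roc[[task]], tidy, .id = "parameter")
      p3 <- file.path(dir, paste0("roc_curves_", task, ".csv"))
      utils::write.csv(curves, p3, row.names = FALSE)
      paths <- c(paths, p1, p2, p3)
    }
  }
  invisible(paths)
}
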