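#' Normality-gated choice of the group-comparison route
#'
#' Applies the Shapiro-Wilk test per group; the parametric route (one-way
#' ANOVA) is taken only if every group is compatible with normality at level
#' `alpha`, otherwise the nonparametric route (Kruskal-Wallis). Groups with
#' fewer than 3 values (or constant values) force the nonparametric route
#' with a warning status.
#'
#' @param data a data frame.
#' @param value,label column names (strings) of the numeric values and group
#'   labels.
#' @param alpha significance level for the Shapiro-Wilk tests.
#' @return A one-row tibble: `route` (`"parametric"` or `"nonparametric"`),
#'   `min_p` (smallest per-group Shapiro-Wilk p), `status`.
#' @export
normality_gate <- function(data, value = "value", label = "label",
                           alpha = 0.05) {
  v <- data[[value]]
  g <- factor(data[[label]])
  ps <- vapply(split(v, g), function(x) {
    if (length(x) < 3L || diff(range(x)) < .Machine$double.eps^0.5)
      return(NA_real_)
    shapiro.test(x)$p.value
  }, numeric(1))
  if (anyNA(ps)) {
    warn("group with n < 3 or constant values; using nonparametric route.")
    return(tibble(route = "nonparametric", min_p = NA_real_,
                  status = "degenerate group"))
  }
  tibble(
    route = if (all(ps >= alpha)) "parametric" else "nonparametric",
    min_p = min(ps), status = "ok"
  )
}

#' Global three-group test (ANOVA or Kruskal-Wallis)
#'
#' @inheritParams normality_gate
#' @param route `"parametric"`, `"nonparametric"`, or `NULL` to decide with
#'   [normality_gate()].
#' @return A one-row tibble: `method`, `statistic`, `p_value`, `route`.
#' @export
global_group_test <- function(data, value = "value", label = "label",
                              route = NULL) {
  v <- data[[value]]
  g <- factor(data[[label]])
  if (is.null(route)) route <- normality_gate(data, value, label)$route
  if (diff(range(v)) < .Machine$double.eps^0.5) {
    return(tibble(method = "degenerate", statistic = NA_real_, p_value = 1,
                  route = route))
  }
  if (route == "parametric") {
    fit <- summary(aov(v ~ g))[[1]]
    tibble(method = "anova", statistic = fit$`F value`[1],
           p_value = fit$`Pr(>F)`[1], route = route)
  } else {
    kw <- kruskal.test(v, g)
    tibble(method = "kruskal-wallis", statistic = unname(kw$statistic),
           p_value = kw$p.value, route = route)
  }
}

#' Pairwise Mann-Whitney U tests with Bonferroni correction
#'
#' All three group pairs (Norm-Benign, Norm-Malignant, Benign-Malignant, in
#' the order of the factor levels); the U statistic is oriented to the
#' smaller group of each pair, and adjusted p-values are `min(1, 3 * p)`.
#'
#' @inheritParams normality_gate
#' @return A tibble with one row per pair: `pair`, `n1`, `n2`, `u`, `p_raw`,
#'   `p_adj`, `status`.
#' @export
pairwise_mwu_bonferroni <- function(data, value = "value", label = "label") {
  v <- data[[value]]
  g <- factor(data[[label]])
  lev <- levels(g)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    x <- v[g == pr[1]]
    y <- v[g == pr[2]]
    if (!length(x) || !length(y)) {
      return(tibble(pair = paste(pr, collapse = " vs "),
                    n1 = length(x), n2 = length(y),
                    u = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                    status = "skipped: empty group"))
    }
    # orient U to the smaller group
    if (length(y) < length(x)) { tmp <- x; x <- y; y <- tmp }
    wt <- suppressWarnings(wilcox.test(x, y, exact = length(x) + length(y) <= 30))
    tibble(pair = paste(pr, collapse = " vs "),
           n1 = length(x), n2 = length(y),
           u = unname(wt$statistic), p_raw = wt$p.value,
           p_adj = NA_real_, status = "ok")
  })
  out <- dplyr::bind_rows(rows)
  ok <- out$status == "ok"
  out$p_adj[ok] <- pmin(1, length(pairs) * out$p_raw[ok])
  out
}

#' Youden index from sensitivity and specificity
#'
#' `J = sensitivity + specificity - 1`, vectorized; inputs must lie in
#' `[0, 1]`.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @return Numeric vector of Youden indices.
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 | specificity > 1,
          na.rm = TRUE))
    abort("rates must lie in [0, 1].")
  sensitivity + specificity - 1
}

# empirical ROC of scores (higher = positive); returns fpr/tpr step points
# including (0,0) and (1,1), plus the trapezoid/Mann-Whitney AUC
empirical_roc <- function(scores, positive) {
  o <- order(scores, decreasing = TRUE)
  pos <- positive[o]
  n1 <- sum(positive)
  n0 <- length(positive) - n1
  # merge tied scores into single operating points
  s <- scores[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  # Mann-Whitney AUC with tie correction
  r <- rank(scores)
  auc <- (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

# stepwise-conservative interpolation of an ROC onto a fixed FPR grid:
# the maximal TPR attainable at or below each grid FPR
interp_roc <- function(roc, grid) {
  idx <- findInterval(grid, roc$fpr)
  cummax(roc$tpr)[pmax(idx, 1)]
}

#' Bootstrap ROC analysis with percentile confidence intervals
#'
#' Resamples the data with replacement (`b` iterations, original sample
#' size), computes each iteration's empirical ROC, interpolates the curves
#' onto a fixed FPR grid (maximal TPR at or below each grid point), and
#' averages. Bootstrap samples that lose one of the classes are redrawn so
#' `b` stays fixed. Scores are oriented so that larger values indicate the
#' positive class; if the full-data AUC is below 0.5 the orientation is
#' flipped and flagged.
#'
#' Reported summary: the mean AUC over iterations with 2.5/97.5 percentile
#' bounds; the Youden index of the mean curve (`J = max(TPR - FPR)` over the
#' grid) with the mean curve's sensitivity/specificity at that point; and
#' percentile confidence intervals of the per-iteration Youden optimum and
#' its sensitivity/specificity. The full-data cutoff comes from
#' [full_data_cutoff()].
#'
#' @param scores numeric scores.
#' @param labels class labels (logical, or factor/character with `positive`).
#' @param positive label of the positive class (default: `TRUE` for logical,
#'   last factor level otherwise).
#' @param b number of bootstrap iterations, default 1000.
#' @param seed integer seed.
#' @param grid_size number of FPR grid points (default 101).
#' @return An object of class `roc_boot`; see [glance.roc_boot()] and
#'   [tidy.roc_boot()].
#' @export
bootstrap_roc <- function(scores, labels, positive = NULL, b = 1000,
                          seed = 1L, grid_size = 101L) {
  stopifnot(b >= 1)
  pos <- as_positive(labels, positive)
  if (!any(pos) || all(pos)) abort("both classes must be present.")
  flipped <- FALSE
  full <- empirical_roc(scores, pos)
  if (full$auc < 0.5) {
    scores <- -scores
    flipped <- TRUE
    full <- empirical_roc(scores, pos)
  }
  n <- length(scores)
  grid <- seq(0, 1, length.out = grid_size)
  set.seed(seed)
  tpr_mat <- matrix(NA_real_, b, grid_size)
  auc_i <- j_i <- sens_i <- spec_i <- numeric(b)
  redraws <- 0L
  for (it in seq_len(b)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(pos[idx]) && !all(pos[idx])) break
      redraws <- redraws + 1L
    }
    roc <- empirical_roc(scores[idx], pos[idx])
    tp <- interp_roc(roc, grid)
    tpr_mat[it, ] <- tp
    auc_i[it] <- roc$auc
    jj <- tp - grid
    k <- which.max(jj)
    j_i[it] <- jj[k]
    sens_i[it] <- tp[k]
    spec_i[it] <- 1 - grid[k]
  }
  mean_tpr <- colMeans(tpr_mat)
  jgrid <- mean_tpr - grid
  kstar <- which.max(jgrid)
  ci <- function(x) unname(quantile(x, c(0.025, 0.975), type = 7))
  cutoff <- full_data_cutoff(scores, pos)
  structure(
    list(
      fpr_grid = grid, mean_tpr = mean_tpr,
      tpr_ci = apply(tpr_mat, 2, ci),
      auc = mean(auc_i), auc_ci = ci(auc_i), auc_full = full$auc,
      youden = jgrid[kstar],
      sensitivity = mean_tpr[kstar], specificity = 1 - grid[kstar],
      youden_iter_mean = mean(j_i), youden_ci = ci(j_i),
      sensitivity_iter_mean = mean(sens_i), sensitivity_ci = ci(sens_i),
      specificity_iter_mean = mean(spec_i), specificity_ci = ci(spec_i),
      cutoff = cutoff,
      b = b, seed = seed, n = n, n_pos = sum(pos),
      flipped = flipped, redraws = redraws
    ),
    class = "roc_boot"
  )
}

as_positive <- function(labels, positive = NULL) {
  if (is.logical(labels)) {
    if (is.null(positive)) return(labels)
    return(labels == positive)
  }
  f <- factor(labels)
  if (is.null(positive)) positive <- levels(f)[nlevels(f)]
  if (!positive %in% levels(f)) abort("`positive` is not a label level.")
  f == positive
}

#' @export
print.roc_boot <- function(x, ...) {
  cat(sprintf(
    "<roc_boot> AUC %.3f (95%% CI %.3f-%.3f), B = %d, n = %d (%d positive)%s\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], x$b, x$n, x$n_pos,
    if (x$flipped) " [orientation flipped]" else ""
  ))
  cat(sprintf("  Youden J %.3f (sens %.3f, spec %.3f)\n",
              x$youden, x$sensitivity, x$specificity))
  invisible(x)
}

#' @describeIn bootstrap_roc mean ROC curve as a tibble (`fpr`, `tpr`,
#'   `tpr_lo`, `tpr_hi`).
#' @param x an `roc_boot` object.
#' @param ... unused.
#' @method tidy roc_boot
#' @export
tidy.roc_boot <- function(x, ...) {
  tibble(fpr = x$fpr_grid, tpr = x$mean_tpr,
         tpr_lo = x$tpr_ci[1, ], tpr_hi = x$tpr_ci[2, ])
}

#' One-row summary of a bootstrap ROC analysis
#'
#' @param x an `roc_boot` object.
#' @param ... unused.
#' @return Tibble with the mean AUC and its CI, the Youden index of the mean
#'   curve with sensitivity/specificity and their percentile CIs, and the
#'   full-data cutoff.
#' @method glance roc_boot
#' @export
glance.roc_boot <- function(x, ...) {
  tibble(
    auc = x$auc, auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2],
    youden = x$youden,
    youden_lo = x$youden_ci[1], youden_hi = x$youden_ci[2],
    sensitivity = x$sensitivity,
    sensitivity_lo = x$sensitivity_ci[1], sensitivity_hi = x$sensitivity_ci[2],
    specificity = x$specificity,
    specificity_lo = x$specificity_ci[1], specificity_hi = x$specificity_ci[2],
    cutoff = x$cutoff$threshold[1], b = x$b, n = x$n, flipped = x$flipped
  )
}

#' Youden-optimal cutoff on the full (unresampled) data
#'
#' Scans the midpoints between consecutive distinct scores (plus outer
#' sentinels); classifying `score >= threshold` as positive, returns the
#' threshold maximizing `J = sens + spec - 1`, breaking ties toward higher
#' specificity.
#'
#' @inheritParams bootstrap_roc
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`, `j`,
#'   `status`.
#' @export
full_data_cutoff <- function(scores, labels, positive = NULL) {
  pos <- as_positive(labels, positive)
  if (!any(pos) || all(pos)) abort("both classes must be present.")
  su <- sort(unique(scores))
  if (length(su) == 1L) {
    return(tibble(threshold = NA_real_, sensitivity = NA_real_,
                  specificity = NA_real_, j = NA_real_,
                  status = "all scores equal"))
  }
  cand <- c(su[1] - 1, (su[-1] + su[-length(su)]) / 2, su[length(su)] + 1)
  n1 <- sum(pos); n0 <- sum(!pos)
  best <- NULL
  for (th in cand) {
    sens <- sum(pos & scores >= th) / n1
    spec <- sum(!pos & scores < th) / n0
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      best <- list(th = th, sens = sens, spec = spec, j = j)
    }
  }
  tibble(threshold = best$th, sensitivity = best$sens,
         specificity = best$spec, j = best$j, status = "ok")
}

#' Univariate statistics over all parameters of a cohort
#'
#' For each parameter column: normality gate, global group test, and (when
#' the global test is significant at `alpha`, or `gate = FALSE`) the
#' Bonferroni-corrected pairwise Mann-Whitney tests.
#'
#' @param cohort tibble with a `label` factor column and numeric parameter
#'   columns.
#' @param parameters parameter column names; default: all numeric columns.
#' @param alpha significance level gating the pairwise stage.
#' @param gate if `FALSE`, pairwise tests run regardless of the global test.
#' @return A list with `global` (one row per parameter) and `pairwise` (three
#'   rows per gated-in parameter).
#' @export
compare_groups <- function(cohort, parameters = NULL, alpha = 0.05,
                           gate = TRUE) {
  if (is.null(parameters))
    parameters <- setdiff(names(cohort)[vapply(cohort, is.numeric, TRUE)],
                          c("subject_id"))
  global <- purrr::map_dfr(parameters, function(p) {
    d <- tibble(value = cohort[[p]], label = cohort$label)
    gtest <- global_group_test(d)
    dplyr::bind_cols(tibble(parameter = p), gtest)
  })
  run_pw <- if (gate) global$parameter[global$p_value < alpha]
            else global$parameter
  pairwise <- purrr::map_dfr(run_pw, function(p) {
    d <- tibble(value = cohort[[p]], label = cohort$label)
    dplyr::bind_cols(tibble(parameter = p), pairwise_mwu_bonferroni(d))
  })
  list(global = global, pairwise = pairwise)
}
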