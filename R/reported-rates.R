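#' Published diagnostic operating points for the six discriminative parameters
#'
#' The published Youden indices with the sensitivity and specificity at the
#' bootstrap-ROC optimum (95% percentile CIs) for the six vibratory
#' parameters that separate the diagnostic groups, for both binary tasks
#' (organic-lesion detection and malignancy differentiation). Shipped as a
#' plain-text fixture; the `consistent` flag marks rows whose printed Youden
#' index satisfies `J = sensitivity + specificity - 1` to the printed
#' precision (one row does not).
#'
#' @return A tibble with columns `task`, `parameter`, `youden`, `sensitivity`,
#'   `specificity` (each with `_lo`/`_hi` bounds) and `consistent`.
#' @export
reported_cutpoint_rates <- function() {
  path <- system.file("extdata", "reported_cutpoint_rates.csv",
                      package = "laryngovib", mustWork = TRUE)
  out <- as_tibble(utils::read.csv(path, check.names = FALSE))
  out$consistent <- as.logical(out$consistent)
  out
}
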