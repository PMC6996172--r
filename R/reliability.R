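# Test-retest reliability of the DCP metrics: intraclass correlation
# coefficients (two-way random effects, absolute agreement) with
# F-based confidence intervals.

#' Intraclass correlation for repeated OCT-A measurements
#'
#' Computes the ICC between paired scans of one metric: intra-session
#' (`visit1_scan1` vs `visit1_scan2`) or inter-session (`visit1_scan1`
#' vs `visit2_scan1`). The model is the two-way random-effects,
#' absolute-agreement ICC - single measure ICC(2,1) by default, with the
#' average-measure ICC(2,k) available via `measure` - and the 95%
#' confidence interval uses the F-distribution form of McGraw & Wong.
#'
#' @param data Long data frame with columns `eye_id`, `session_label`,
#'   `metric_name`, `value` (one eye per subject).
#' @param metric_name Which metric to analyse.
#' @param pair `"intra"` (same visit) or `"inter"` (different visits).
#' @param measure `"single"` (default) or `"average"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `metric_name`, `pair`, `measure`, `n_eyes`,
#'   `icc`, `ci_low`, `ci_high`, `model_label`.
#' @export
#' @examples
#' rm_ <- simulate_repeated_measures(30, subject_sd = 1, error_sd = 0.4, seed = 2)
#' compute_icc(rm_, "fd", "intra")
compute_icc <- function(data, metric_name, pair = c("intra", "inter"),
                        measure = c("single", "average"),
                        conf_level = 0.95) {
  pair <- match.arg(pair)
  measure <- match.arg(measure)
  stopifnot(is.data.frame(data))
  sessions <- if (pair == "intra") {
    c("visit1_scan1", "visit1_scan2")
  } else {
    c("visit1_scan1", "visit2_scan1")
  }
  d <- dplyr::filter(
    as_tibble(data),
    .data$metric_name == !!metric_name, .data$session_label %in% sessions
  )
  wide <- tidyr::pivot_wider(
    d[, c("eye_id", "session_label", "value")],
    names_from = "session_label", values_from = "value"
  )
  wide <- wide[complete.cases(wide), , drop = FALSE]
  n <- nrow(wide)
  if (n < 5) {
    abort("insufficient data: need >= 5 eyes with complete pairs",
          class = "deepangio_insufficient_data")
  }
  Y <- as.matrix(wide[, sessions])
  k <- ncol(Y)
  grand <- mean(Y)
  if (sum((Y - grand)^2) < 1e-12) {
    abort("degenerate variance: all measurements identical",
          class = "deepangio_degenerate_variance")
  }
  MSR <- k * var(rowMeans(Y))
  MSC <- n * var(colMeans(Y))
  SSE <- sum((Y - grand)^2) - (n - 1) * MSR - (k - 1) * MSC
  MSE <- max(SSE, 0) / ((n - 1) * (k - 1))

  icc1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - conf_level
  if (MSE <= 1e-12 && MSC <= 1e-12) {
    lo1 <- hi1 <- icc1 <- 1
  } else {
    a <- (k * icc1) / (n * (1 - icc1))
    b <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    lo1 <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi1 <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  }
  if (measure == "single") {
    icc <- icc1; lo <- lo1; hi <- hi1
    label <- "ICC(2,1) two-way random, absolute agreement, single measure"
  } else {
    upk <- function(r) k * r / (1 + (k - 1) * r)
    icc <- upk(icc1); lo <- upk(lo1); hi <- upk(hi1)
    label <- sprintf(
      "ICC(2,%d) two-way random, absolute agreement, average measure", k
    )
  }
  tibble(
    metric_name = metric_name, pair = pair, measure = measure,
    n_eyes = n, icc = icc, ci_low = min(lo, icc), ci_high = max(hi, icc),
    model_label = label
  )
}
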