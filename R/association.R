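# Association workflow: per-SD standardization, univariate screen,
# multivariable GEE per outcome, and the DME-excluded sensitivity
# repeat.

#' Convert Snellen acuity to logMAR
#'
#' `logmar = log10(denominator / numerator)`; Snellen 20/20 maps to 0.0
#' and 20/200 to 1.0.
#'
#' @param numerator,denominator Positive Snellen fraction components
#'   (vectorized).
#' @return Numeric logMAR values.
#' @export
#' @examples
#' snellen_to_logmar(20, 200)  # 1
#' snellen_to_logmar(6, 12)    # log10(2)
snellen_to_logmar <- function(numerator, denominator) {
  if (any(numerator <= 0) || any(denominator <= 0)) {
    abort("Snellen components must be positive",
          class = "deepangio_invalid_acuity")
  }
  log10(denominator / numerator)
}

#' Standardize continuous covariates of a cohort
#'
#' Replaces each listed column by `(x - mean) / SD`, with mean and SD
#' computed on the analysis rows supplied (so per-SD effects refer to
#' the analyzed cohort). Categorical columns are untouched.
#'
#' @param cohort A cohort data frame.
#' @param continuous_vars Character vector of columns to standardize.
#' @return The cohort tibble with standardized columns.
#' @export
standardize_cohort <- function(cohort, continuous_vars) {
  stopifnot(is.data.frame(cohort))
  out <- as_tibble(cohort)
  for (v in continuous_vars) {
    if (!v %in% names(out)) abort(paste0("column `", v, "` not found"))
    x <- out[[v]]
    if (!is.numeric(x)) abort(paste0("column `", v, "` is not numeric"))
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      abort(paste0("degenerate covariate `", v, "`: zero SD"),
            class = "deepangio_degenerate_covariate")
    }
    out[[v]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  out
}

default_candidate_factors <- function() {
  c("dr_severity", "dme", "logmar", "axial_length_mm", "cst_um",
    "gcipl_um", "choroid_um", "age_y", "bmi", "sbp", "dbp",
    "hba1c_pct", "dm_duration_y", "total_chol", "ldl")
}

default_continuous_vars <- function() {
  setdiff(default_candidate_factors(), c("dr_severity", "dme"))
}

#' Univariate association screen
#'
#' Fits one GEE per candidate factor against the outcome and marks the
#' factors whose association is significant at `alpha` (two-sided,
#' robust Wald). DR severity enters as a block of three dummies and is
#' selected when any dummy is significant.
#'
#' @param cohort A cohort data frame with standardized continuous
#'   covariates.
#' @param outcome Outcome column name.
#' @param candidate_factors Character vector of candidate factors.
#' @param alpha Screening significance level (default 0.05).
#' @param id Cluster column.
#' @return A tibble of univariate results with columns of [fit_gee()]
#'   plus `candidate` (the factor/block name) and `selected`.
#' @export
univariate_screen <- function(cohort, outcome,
                              candidate_factors = default_candidate_factors(),
                              alpha = 0.05, id = "subject_id") {
  if (!length(candidate_factors)) {
    abort("empty candidate list", class = "deepangio_invalid_input")
  }
  if (!nrow(cohort)) abort("empty cohort", class = "deepangio_invalid_input")
  res <- purrr::map(candidate_factors, function(v) {
    dplyr::mutate(fit_gee(cohort, outcome, v, id = id), candidate = v)
  })
  res <- dplyr::bind_rows(res)
  sel <- dplyr::summarise(
    dplyr::group_by(res, .data$candidate),
    selected = any(.data$p < alpha), .groups = "drop"
  )
  dplyr::left_join(res, sel, by = "candidate")
}

#' Full association analysis of the three DCP metrics
#'
#' For each outcome (FAZ area, VD, FD): standardize the continuous
#' covariates on the analysis rows, screen every candidate factor
#' univariately, then fit the multivariable GEE on the selected
#' factors. The whole procedure is run on the full cohort and repeated
#' on the subset without DME (the sensitivity variant, since macular
#' edema can mimic non-perfusion); standardization is recomputed on
#' each variant's rows.
#'
#' @param cohort A cohort data frame ([generate_cohort()] schema).
#' @param alpha Univariate screening level.
#' @param candidate_factors Candidate factors (DME is dropped from the
#'   no-DME variant automatically).
#' @param id Cluster column.
#' @return A tibble of class `dcp_assoc`: columns `outcome` (FAZ, VD,
#'   FD), `predictor`, `candidate`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `p`, `model_stage` (univariate / multivariable), `cohort_variant`
#'   (all / no_dme).
#' @export
#' @examples
#' coh <- generate_cohort(150, seed = 5)
#' res <- run_full_analysis(coh)
#' dplyr::filter(res, model_stage == "multivariable", cohort_variant == "all")
run_full_analysis <- function(cohort, alpha = 0.05,
                              candidate_factors = default_candidate_factors(),
                              id = "subject_id") {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  outcomes <- c(FAZ = "faz_area_mm2", VD = "vd_pct", FD = "fd")
  variants <- list(all = cohort, no_dme = dplyr::filter(cohort, !.data$dme))
  cont <- intersect(default_continuous_vars(), candidate_factors)
  out <- purrr::imap(variants, function(dat, vname) {
    cand <- candidate_factors
    if (vname == "no_dme") cand <- setdiff(cand, "dme")
    datz <- standardize_cohort(dat, intersect(cont, names(dat)))
    purrr::imap(outcomes, function(col, lab) {
      scr <- univariate_screen(datz, col, cand, alpha = alpha, id = id)
      uni <- dplyr::mutate(scr, model_stage = "univariate")
      selected <- unique(scr$candidate[scr$selected])
      multi <- NULL
      if (length(selected)) {
        multi <- fit_gee(datz, col, selected, id = id)
        multi$candidate <- NA_character_
        multi$selected <- NA
        multi$model_stage <- "multivariable"
      }
      res <- dplyr::bind_rows(uni, multi)
      res$outcome <- lab
      res$cohort_variant <- vname
      res
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out <- dplyr::select(
    out, "outcome", "predictor", "candidate", "beta", "se",
    "ci_low", "ci_high", "p", "model_stage", "cohort_variant", "selected"
  )
  class(out) <- c("dcp_assoc", class(out))
  out
}

#' @export
autoplot.dcp_assoc <- function(object, stage = "multivariable",
                               variant = "all", ...) {
  df <- dplyr::filter(
    as_tibble(object),
    .data$model_stage == stage, .data$cohort_variant == variant
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$beta, y = .data$predictor,
    xmin = .data$ci_low, xmax = .data$ci_high
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(~outcome, scales = "free_x") +
    ggplot2::labs(
      x = "beta (per SD / vs reference)", y = NULL,
      title = sprintf("%s associations (%s cohort)", stage, variant)
    ) +
    ggplot2::theme_minimal()
}
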