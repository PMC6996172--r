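# Synthetic clinical cohorts: eye-level rows clustered by subject, with
# covariate marginals configurable to a target mean/SD and outcomes
# generated as linear functions of standardized predictors plus a
# subject-level random effect that induces inter-eye correlation.

cohort_covariate_defaults <- function() {
  tibble(
    name = c("age_y", "bmi", "sbp", "dbp", "hba1c_pct", "dm_duration_y",
             "total_chol", "ldl",
             "logmar", "axial_length_mm", "cst_um", "gcipl_um", "choroid_um"),
    mean = c(60.7, 26.2, 137.8, 78.1, 7.48, 12.9, 4.34, 2.31,
             0.14, 23.88, 258.2, 80.2, 208.58),
    sd = c(13.2, 4.19, 20.4, 10.5, 1.33, 9.07, 0.95, 0.77,
           0.15, 1.34, 47.4, 10.9, 78.13),
    level = c(rep("subject", 8), rep("eye", 5))
  )
}

effect_keys_allowed <- function() {
  c("dr_mild", "dr_moderate", "dr_severe", "dme",
    cohort_covariate_defaults()$name)
}

#' Specify linear effects for cohort simulation
#'
#' Defines, per outcome (FAZ area, VD, FD), the linear coefficient of
#' each predictor on the standardized scale (per-SD for continuous
#' predictors, dummy-vs-reference for DR severity and DME), together
#' with the residual SD of each outcome and the inter-eye (within
#' subject) correlation of the outcome residuals. Defaults are
#' diabetic-retinopathy effect magnitudes typical of multivariable
#' fellow-eye analyses of the deep capillary plexus, e.g. an FD
#' reduction of 0.891 for severe-vs-no DR.
#'
#' @param faz,vd,fd Named numeric vectors of coefficients; names must be
#'   among `dr_mild`, `dr_moderate`, `dr_severe`, `dme`, or a continuous
#'   covariate name (see [generate_cohort()]).
#' @param residual_sd Named numeric (faz, vd, fd), all positive.
#' @param inter_eye_correlation Correlation of fellow-eye outcome
#'   residuals, in \[0, 1).
#' @param intercepts Outcome values at reference levels / covariate means.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(
    faz = c(dr_mild = 0.221, dr_moderate = 0.103, dr_severe = 0.687,
            dme = 0.138, logmar = 0.102, axial_length_mm = -0.171,
            choroid_um = -0.122, bmi = -0.090, sbp = 0.077, age_y = 0.051),
    vd = c(dr_mild = -0.345, dr_moderate = -0.249, dr_severe = -0.842,
           dme = -0.160, axial_length_mm = 0.107, logmar = -0.133,
           choroid_um = 0.104, bmi = 0.073, sbp = -0.030, age_y = -0.078),
    fd = c(dr_mild = -0.307, dr_moderate = -0.357, dr_severe = -0.891,
           logmar = -0.074, gcipl_um = 0.113, bmi = 0.077, sbp = 0.062,
           age_y = -0.142),
    residual_sd = c(faz = 1, vd = 1, fd = 1),
    inter_eye_correlation = 0.4,
    intercepts = c(faz = 0.35, vd = 92, fd = 1.5)) {
  eff <- list(faz = faz, vd = vd, fd = fd)
  allowed <- effect_keys_allowed()
  for (o in names(eff)) {
    bad <- setdiff(names(eff[[o]]), allowed)
    if (length(bad)) {
      abort(paste0("unknown effect keys for ", o, ": ",
                   paste(bad, collapse = ", ")))
    }
  }
  if (any(residual_sd <= 0)) abort("`residual_sd` must be positive")
  if (abs(inter_eye_correlation) >= 1) {
    abort("`inter_eye_correlation` must have absolute value < 1")
  }
  structure(
    list(effects = eff, residual_sd = residual_sd,
         inter_eye_correlation = inter_eye_correlation,
         intercepts = intercepts),
    class = "effect_spec"
  )
}

#' Simulate an eye-level clinical cohort
#'
#' Generates `n_subjects` subjects, a fraction of whom contribute both
#' eyes; draws subject- and eye-level covariates from Gaussian marginals
#' with configurable target mean/SD; assigns DR severity (four ordinal
#' levels) and DME; and generates the three DCP outcome metrics as
#' linear functions of the standardized predictors (per the
#' [effect_spec()]) plus a subject-level random effect inducing the
#' requested inter-eye correlation, plus Gaussian noise. Deterministic
#' given `seed`.
#'
#' @param n_subjects Number of subjects (`>= 2`).
#' @param both_eyes_fraction Fraction of subjects contributing two eyes,
#'   in \[0, 1\].
#' @param effects An [effect_spec()].
#' @param dr_probs Probabilities of the four DR-severity levels
#'   (none, mild, moderate, severe).
#' @param dme_prob Probability an eye has DME.
#' @param covariate_spec Data frame `name`, `mean`, `sd`, `level`
#'   overriding the default covariate marginals.
#' @param seed Integer seed.
#' @return A `cohort` tibble with one row per eye: identifiers,
#'   `dr_severity`, `dme`, the covariates, and outcomes `faz_area_mm2`,
#'   `vd_pct`, `fd`.
#' @export
#' @examples
#' coh <- generate_cohort(50, seed = 1)
#' dplyr::count(coh, dr_severity)
generate_cohort <- function(n_subjects, both_eyes_fraction = 0.8,
                            effects = effect_spec(),
                            dr_probs = c(0.428, 0.254, 0.227, 0.091),
                            dme_prob = 0.144,
                            covariate_spec = cohort_covariate_defaults(),
                            seed = 1L) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2")
  if (both_eyes_fraction < 0 || both_eyes_fraction > 1) {
    abort("`both_eyes_fraction` must be in [0, 1]",
          class = "deepangio_invalid_parameter")
  }
  stopifnot(inherits(effects, "effect_spec"))
  cs <- as_tibble(covariate_spec)
  withr::with_seed(seed, {
    subj <- sprintf("subj%04d", seq_len(n_subjects))
    two <- runif(n_subjects) < both_eyes_fraction
    dat <- tibble(
      subject_id = rep(subj, ifelse(two, 2L, 1L)),
      eye = unlist(lapply(two, function(b) if (b) c("OD", "OS") else "OD"))
    )
    dat$eye_id <- paste0(dat$subject_id, "_", dat$eye)
    n_eyes <- nrow(dat)
    idx <- match(dat$subject_id, subj)

    for (k in seq_len(nrow(cs))) {
      if (cs$level[k] == "subject") {
        v <- rnorm(n_subjects, cs$mean[k], cs$sd[k])[idx]
      } else {
        v <- rnorm(n_eyes, cs$mean[k], cs$sd[k])
      }
      dat[[cs$name[k]]] <- v
    }
    lv <- c("none", "mild", "moderate", "severe")
    dat$dr_severity <- factor(
      sample(lv, n_eyes, replace = TRUE, prob = dr_probs), levels = lv
    )
    dat$dme <- runif(n_eyes) < dme_prob

    # standardized design relative to the configured targets
    z <- lapply(seq_len(nrow(cs)), function(k) {
      (dat[[cs$name[k]]] - cs$mean[k]) / cs$sd[k]
    })
    names(z) <- cs$name
    z$dr_mild <- as.numeric(dat$dr_severity == "mild")
    z$dr_moderate <- as.numeric(dat$dr_severity == "moderate")
    z$dr_severe <- as.numeric(dat$dr_severity == "severe")
    z$dme <- as.numeric(dat$dme)

    outcome_cols <- c(faz = "faz_area_mm2", vd = "vd_pct", fd = "fd")
    rho <- effects$inter_eye_correlation
    for (o in names(outcome_cols)) {
      beta <- effects$effects[[o]]
      lp <- effects$intercepts[[o]]
      for (nm in names(beta)) lp <- lp + beta[[nm]] * z[[nm]]
      sdo <- effects$residual_sd[[o]]
      b_subj <- rnorm(n_subjects, 0, sqrt(rho) * sdo)[idx]
      e <- rnorm(n_eyes, 0, sqrt(1 - rho) * sdo)
      dat[[outcome_cols[[o]]]] <- lp + b_subj + e
    }
    dat$eye <- NULL
    out <- dplyr::relocate(dat, "subject_id", "eye_id", "dr_severity", "dme")
    class(out) <- c("cohort", class(out))
    out
  })
}

#' Simulate paired repeated measurements of one metric
#'
#' Generates a long table of test-retest measurements for reliability
#' analysis: one randomly-selected eye per subject, with a shared
#' subject component (SD `subject_sd`) and independent measurement
#' error (SD `error_sd`) per scan. Session labels follow the
#' `visit1_scan1` / `visit1_scan2` / `visit2_scan1` convention.
#'
#' @param n_eyes Number of eyes (one per subject).
#' @param subject_sd,error_sd Between-eye and within-eye (scan) SDs.
#' @param metric_name Metric label (default `"fd"`).
#' @param mean Metric mean.
#' @param seed Integer seed.
#' @return A tibble `eye_id`, `session_label`, `metric_name`, `value`.
#' @export
simulate_repeated_measures <- function(n_eyes, subject_sd = 1, error_sd = 0.5,
                                       metric_name = "fd", mean = 1.5,
                                       seed = 1L) {
  withr::with_seed(seed, {
    truth <- rnorm(n_eyes, mean, subject_sd)
    sessions <- c("visit1_scan1", "visit1_scan2", "visit2_scan1")
    tidyr::expand_grid(
      eye_id = sprintf("eye%04d", seq_len(n_eyes)),
      session_label = sessions
    ) |>
      dplyr::mutate(
        metric_name = metric_name,
        value = rep(truth, each = length(sessions)) +
          rnorm(n_eyes * length(sessions), 0, error_sd)
      )
  })
}
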