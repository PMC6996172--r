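test_that("Snellen to logMAR conversion", {
  expect_equal(snellen_to_logmar(20, 20), 0)
  expect_equal(snellen_to_logmar(20, 200), 1)
  expect_equal(round(snellen_to_logmar(6, 12), 3), 0.301)
  expect_error(snellen_to_logmar(0, 20), class = "deepangio_invalid_acuity")
})

test_that("standardization centres, scales, and is scale-invariant", {
  coh <- generate_cohort(100, seed = 1)
  z <- standardize_cohort(coh, c("age_y", "bmi"))
  expect_equal(mean(z$age_y), 0, tolerance = 1e-9)
  expect_equal(sd(z$age_y), 1, tolerance = 1e-9)

  doubled <- coh
  doubled$age_y <- 2 * doubled$age_y
  z2 <- standardize_cohort(doubled, "age_y")
  expect_equal(z2$age_y, z$age_y, tolerance = 1e-12)

  const <- coh
  const$age_y <- 7
  expect_error(standardize_cohort(const, "age_y"),
               class = "deepangio_degenerate_covariate")
})

test_that("GEE degenerates to OLS with one eye per subject", {
  coh <- generate_cohort(200, both_eyes_fraction = 0, seed = 2)
  f <- fd ~ age_y + bmi + dr_severity
  g <- gee_lm(coh, f, id = "subject_id")
  expect_lt(max(abs(g$coefficients - coef(lm(f, coh)))), 1e-6)
  expect_equal(g$rho, 0)
})

test_that("independence-model robust SEs exceed naive SEs under clustering", {
  es <- effect_spec(inter_eye_correlation = 0.6)
  coh <- generate_cohort(300, both_eyes_fraction = 1, effects = es, seed = 3)
  g <- gee_lm(coh, fd ~ age_y + bmi, id = "subject_id", corstr = "independence")
  # age and bmi are subject-level: clustering inflates their true SE
  rob <- sqrt(diag(g$vcov_robust))
  nai <- sqrt(diag(g$vcov_naive))
  expect_true(all(rob[c("age_y", "bmi")] >= nai[c("age_y", "bmi")]))
})

test_that("robust GEE agrees with the lm + cluster-sandwich oracle", {
  skip_if_not_installed("sandwich")
  coh <- generate_cohort(250, both_eyes_fraction = 1, seed = 4)
  f <- vd_pct ~ age_y + logmar
  g <- gee_lm(coh, f, id = "subject_id", corstr = "independence")
  o <- lm(f, coh)
  expect_lt(max(abs(g$coefficients - coef(o))), 1e-8)
  vcl <- sandwich::vcovCL(o, cluster = coh$subject_id, type = "HC0",
                          cadjust = FALSE)
  expect_equal(sqrt(diag(g$vcov_robust)), sqrt(diag(vcl)), tolerance = 1e-6)
})

test_that("collinear designs raise an error naming the aliased term", {
  coh <- generate_cohort(50, seed = 5)
  coh$age_copy <- coh$age_y
  expect_error(gee_lm(coh, fd ~ age_y + age_copy, id = "subject_id"),
               class = "deepangio_collinear")
})

test_that("univariate screen selects strong factors and none on empty input", {
  coh <- generate_cohort(400, seed = 6)
  cz <- standardize_cohort(coh, deepangio:::default_continuous_vars())
  scr <- univariate_screen(cz, "fd", c("dr_severity", "age_y", "ldl"))
  sel <- unique(scr$candidate[scr$selected])
  expect_true("dr_severity" %in% sel)  # |beta| up to 0.891
  expect_true("age_y" %in% sel)        # injected -0.142 per SD at n=400
  expect_error(univariate_screen(cz, "fd", character(0)),
               class = "deepangio_invalid_input")
  expect_error(univariate_screen(cz[0, ], "fd", "age_y"),
               class = "deepangio_invalid_input")
})

test_that("full analysis emits both cohort variants with coherent filtering", {
  coh <- generate_cohort(250, seed = 7)
  res <- run_full_analysis(coh)
  expect_s3_class(res, "dcp_assoc")
  expect_setequal(unique(res$cohort_variant), c("all", "no_dme"))
  expect_setequal(unique(res$outcome), c("FAZ", "VD", "FD"))
  expect_true(all(res$ci_low <= res$beta & res$beta <= res$ci_high))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$se > 0))

  # recovered multivariable signs match the injected signs (defaults)
  multi <- dplyr::filter(res, model_stage == "multivariable",
                         cohort_variant == "all", outcome == "FD",
                         predictor %in% c("dr_severe", "age_y"))
  expect_true(all(sign(multi$beta) == -1))

  # a DME-free cohort yields identical variants
  nodme <- dplyr::mutate(coh, dme = FALSE)
  res2 <- run_full_analysis(nodme, candidate_factors =
    setdiff(deepangio:::default_candidate_factors(), "dme"))
  a <- dplyr::filter(res2, cohort_variant == "all")
  b <- dplyr::filter(res2, cohort_variant == "no_dme")
  expect_equal(a$beta, b$beta, tolerance = 1e-12)

  # the DME-excluded variant never has more rows of data
  n_all <- nrow(coh)
  n_nodme <- nrow(dplyr::filter(coh, !dme))
  expect_lte(n_nodme, n_all)
})

test_that("tidy and glance methods expose the fitted GEE", {
  coh <- generate_cohort(80, seed = 8)
  g <- gee_lm(coh, fd ~ age_y, id = "subject_id")
  td <- tidy(g)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value", "conf.low", "conf.high"))
  gl <- glance(g)
  expect_equal(gl$n, nrow(coh))
  expect_true(gl$converged)
})
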