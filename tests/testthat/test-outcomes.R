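# small analysed cohort shared across outcome tests
outcome_fixture <- function(n = 1500, seed = 91, outcome = list()) {
  cfg <- sim_config(n_per_stratum = n, seed = seed, outcome = outcome)
  ch <- apply_inclusion_filter(simulate_cohort(cfg))
  memb <- planted_membership(ch$catalog)
  part <- label_patterns(partition_result("optimal", memb, 0.5),
                         default_label_rules())
  sc <- setNames(rowSums(abs(ch$coupling)), ch$catalog$code)
  asn <- assign_all_waves(ch, part, sc)
  list(cohort = ch, assignments = asn)
}

test_that("counting-process rows split follow-up at wave boundaries", {
  fx <- outcome_fixture(n = 400)
  rows <- build_counting_process(fx$cohort, fx$assignments)
  pe <- fx$cohort$persons
  # survivor to 2019: two rows, no events
  surv <- pe$person_id[pe$time >= 8 & pe$death == 0][1]
  r <- rows[rows$person_id == surv, ]
  expect_equal(nrow(r), 2)
  expect_equal(r$event, c(0, 0))
  expect_equal(r$start, c(0, 5))
  expect_equal(r$stop, c(5, 8))
  # death between waves: event on the second interval
  dead <- pe$person_id[pe$death == 1 & pe$time > 5 & pe$time < 8][1]
  r2 <- rows[rows$person_id == dead, ]
  expect_equal(r2$event, c(0, 1))
  expect_equal(r2$stop[2], pe$time[pe$person_id == dead])
  # person-time is conserved over the emitted intervals: each person
  # contributes min(time, 5) on the first and (min(time,8) - 5) on the
  # second interval they appear in
  a <- fx$assignments
  pat1 <- a$pattern[a$wave == 2011][match(pe$person_id,
                                          a$person_id[a$wave == 2011])]
  pat2 <- a$pattern[a$wave == 2016][match(pe$person_id,
                                          a$person_id[a$wave == 2016])]
  exp_pt <- sum(pmin(pe$time, 5)[!is.na(pat1)]) +
    sum((pmin(pe$time, 8) - 5)[pe$time > 5 & !is.na(pat2)])
  expect_equal(sum(rows$stop - rows$start), exp_pt)
  expect_true(all(rows$start < rows$stop))
})

test_that("AIC equals -2 loglik + 2k on a hand-fit model", {
  set.seed(92)
  d <- data.frame(x = rnorm(200))
  d$y <- rbinom(200, 1, plogis(0.5 * d$x))
  fit <- glm(y ~ x, binomial(), data = d)
  expect_equal(AIC(fit), -2 * as.numeric(logLik(fit)) + 2 * 2)
})

test_that("null covariates give hazard ratios covering one", {
  fx <- outcome_fixture(n = 1200, seed = 93, outcome = list(
    pattern_loghr = c(cardiovascular = 0, neuropsychiatric = 0,
                      respiratory_digestive = 0, metabolic_pain = 0),
    count_loghr = 0, exposure_loghr = 0,
    education_loghr = c(no_primary = 0, lower_secondary = 0,
                        upper_secondary = 0, university = 0),
    urbanity_loghr = c(cities = 0, suburban = 0, rural = 0)))
  rows <- build_counting_process(fx$cohort, fx$assignments)
  rows <- rows[rows$age_group == "70-79", ]
  fit <- fit_cox(rows)
  pat <- grep("^pattern", fit$coefs$term)
  expect_true(all(fit$coefs$ci_low[pat] < 0 & fit$coefs$ci_high[pat] > 0))
})

test_that("time rescaling leaves hazard ratios unchanged", {
  fx <- outcome_fixture(n = 800, seed = 94)
  rows <- build_counting_process(fx$cohort, fx$assignments)
  rows <- rows[rows$age_group == "60-69", ]
  f1 <- fit_cox(rows)
  rows2 <- rows
  rows2$start <- rows2$start * 2
  rows2$stop <- rows2$stop * 2
  f2 <- fit_cox(rows2)
  expect_equal(f1$coefs$estimate, f2$coefs$estimate, tolerance = 1e-6)
  expect_error(fit_cox(rows[rows$event == 0, ]), "no events")
})

test_that("AIC comparison prefers the mechanism that drove the hazard", {
  # comparisons are within-stratum, as in the stratified analysis: a
  # pooled fit would let the disease count proxy age instead
  one_stratum <- function(rows) rows[rows$sex == "F" &
                                       rows$age_group == "70-79", ]
  # pattern-driven hazards
  fx <- outcome_fixture(n = 4000, seed = 95, outcome = list(
    pattern_loghr = c(cardiovascular = 0, neuropsychiatric = 0.8,
                      respiratory_digestive = 0.5, metabolic_pain = -0.4),
    count_loghr = 0))
  rows <- one_stratum(build_counting_process(fx$cohort, fx$assignments))
  cmp <- compare_models_aic(rows)
  expect_gt(cmp$delta, 0)
  # count-driven hazards reverse the preference
  fx2 <- outcome_fixture(n = 4000, seed = 96, outcome = list(
    pattern_loghr = c(cardiovascular = 0, neuropsychiatric = 0,
                      respiratory_digestive = 0, metabolic_pain = 0),
    count_loghr = 0.35))
  rows2 <- one_stratum(build_counting_process(fx2$cohort,
                                              fx2$assignments))
  cmp2 <- compare_models_aic(rows2)
  expect_lt(cmp2$delta, 0)
  # identical covariate sets give identical AICs
  r <- rows
  fit_a <- fit_cox(r, terms = c("n_diseases", "education"))
  fit_b <- fit_cox(r, terms = c("n_diseases", "education"))
  expect_equal(fit_a$aic - fit_b$aic, 0)
})

test_that("exposure GLMs return the three families with sane nulls", {
  fx <- outcome_fixture(n = 1500, seed = 97, outcome = list(
    exposure_loghr = 0, exposure_logirr = 0, exposure_loglos = 0,
    pattern_loghr = c(cardiovascular = 0, neuropsychiatric = 0,
                      respiratory_digestive = 0, metabolic_pain = 0),
    count_loghr = 0, hosp_count_coef = 0,
    mortality_model = "ph"))
  # fit within one stratum, as in the stratified analysis (the yearly
  # baseline hazard differs by age group, so pooling would confound)
  ch <- subset_cohort(fx$cohort, fx$cohort$persons$sex == "F" &
                        fx$cohort$persons$age_group == "70-79")
  flags <- setNames(ch$persons$exposed, ch$persons$person_id)
  glms <- fit_exposure_glms(ch, flags)
  expect_named(glms, c("mortality", "hospitalization", "length_of_stay"))
  expect_equal(glms$mortality$family, "logistic")
  expect_equal(glms$hospitalization$family, "negative-binomial")
  for (g in glms) {
    row <- g$coefs[g$coefs$term == "exposedTRUE", ]
    expect_true(row$ci_low < 0 && row$ci_high > 0)
  }
  # quasi-Poisson option
  glms2 <- fit_exposure_glms(ch, flags, count_model = "quasi-poisson")
  expect_equal(glms2$hospitalization$family, "quasi-poisson")
})

test_that("length-of-stay effect is invariant to unit rescaling", {
  # with stays far above one day, the +1 offset in log(days + 1) is
  # negligible and the fitted multiplier is unit-free
  fx <- outcome_fixture(n = 1500, seed = 98,
                        outcome = list(los_log_mu = log(80)))
  # restrict to persons hospitalized at least once so no zero stays
  ch <- subset_cohort(fx$cohort, fx$cohort$persons$hosp_count > 0)
  flags <- setNames(ch$persons$exposed, ch$persons$person_id)
  b1 <- fit_exposure_glms(ch, flags)$length_of_stay
  ch2 <- ch
  ch2$persons$los_days <- ch2$persons$los_days * 3
  b2 <- fit_exposure_glms(ch2, flags)$length_of_stay
  e1 <- b1$coefs$estimate[b1$coefs$term == "exposedTRUE"]
  e2 <- b2$coefs$estimate[b2$coefs$term == "exposedTRUE"]
  expect_equal(e1, e2, tolerance = 0.05)
})
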