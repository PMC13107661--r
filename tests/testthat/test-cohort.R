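test_that("simulation is reproducible and monotone across waves", {
  cfg <- sim_config(n_per_stratum = 200, seed = 81)
  ch1 <- simulate_cohort(cfg)
  ch2 <- simulate_cohort(cfg)
  expect_identical(ch1$waves, ch2$waves)
  expect_identical(ch1$persons, ch2$persons)
  expect_true(all(ch1$waves[["2011"]] <= ch1$waves[["2016"]]))
  expect_true(all(ch1$waves[["2016"]] <= ch1$waves[["2019"]]))
  expect_true(all(ch1$persons$time <= 8))
})

test_that("inclusion filter drops rare diseases then sub-multimorbid persons", {
  cfg <- sim_config(n_per_stratum = 1200, seed = 82)
  ch <- simulate_cohort(cfg)
  fl <- apply_inclusion_filter(ch)
  rep <- attr(fl, "filter_report")
  # the default 33-disease catalog retains 30 after the 1% line
  expect_equal(nrow(fl$catalog), 30)
  expect_setequal(rep$diseases_dropped, c("ms", "bre", "lup"))
  expect_true(all(rowSums(fl$waves[["2019"]]) >= 2))
  # threshold 0 keeps the catalog unchanged
  fl0 <- apply_inclusion_filter(ch, threshold = 0)
  expect_equal(nrow(fl0$catalog), 33)
  # impossible threshold: explicit empty-catalog error
  expect_error(apply_inclusion_filter(ch, threshold = 0.999),
               "empty catalog")
  # a person with exactly one remaining disease is excluded
  one <- rowSums(ch$waves[["2019"]][, fl$catalog$code]) == 1
  expect_true(all(!ch$persons$person_id[one] %in%
                    fl$persons$person_id))
})

test_that("median lifetime disease counts rise with age as configured", {
  cfg <- sim_config(n_per_stratum = 1200, seed = 83)
  fl <- apply_inclusion_filter(simulate_cohort(cfg))
  med <- aggregate(n_dis_lifetime ~ age_group, fl$persons, median)
  expect_true(all(abs(med$n_dis_lifetime - c(3, 4, 5, 6)) <= 1))
})

test_that("null outcome coefficients give exchangeable survival", {
  ch <- simulate_cohort(sim_config(
    n_per_stratum = 2000, seed = 84,
    outcome = list(pattern_loghr = c(cardiovascular = 0,
                                     neuropsychiatric = 0,
                                     respiratory_digestive = 0,
                                     metabolic_pain = 0),
                   count_loghr = 0, exposure_loghr = 0,
                   education_loghr = c(no_primary = 0,
                                       lower_secondary = 0,
                                       upper_secondary = 0,
                                       university = 0),
                   urbanity_loghr = c(cities = 0, suburban = 0,
                                      rural = 0))))
  pe <- subset(ch$persons, age_group == "60-69")
  fit <- survival::coxph(survival::Surv(time, death) ~ education,
                         data = pe)
  ci <- exp(confint(fit))
  expect_true(all(ci[, 1] < 1 & ci[, 2] > 1))
})

test_that("dispersion zero gives Poisson-like counts", {
  cfg <- sim_config(n_per_stratum = 2500, seed = 85,
                    outcome = list(dispersion = 0, exposure_logirr = 0,
                                   hosp_count_coef = 0,
                                   education_loghr = c(no_primary = 0,
                                                       lower_secondary = 0,
                                                       upper_secondary = 0,
                                                       university = 0),
                                   urbanity_loghr = c(cities = 0,
                                                      suburban = 0,
                                                      rural = 0)))
  ch <- simulate_cohort(cfg)
  h <- ch$persons$hosp_count
  expect_equal(stats::var(h) / mean(h), 1, tolerance = 0.1)
  # overdispersed default: variance well above the mean
  ch2 <- simulate_cohort(sim_config(n_per_stratum = 2500, seed = 85))
  h2 <- ch2$persons$hosp_count
  expect_gt(stats::var(h2) / mean(h2), 1.3)
  expect_error(sim_config(outcome = list(dispersion = -1)),
               "dispersion")
})

test_that("cohorts round-trip through delimited text", {
  cfg <- sim_config(n_per_stratum = 150, seed = 86)
  ch <- apply_inclusion_filter(simulate_cohort(cfg))
  d <- tempfile()
  write_cohort(ch, d)
  back <- read_cohort(d)
  expect_equal(back$persons$person_id, ch$persons$person_id)
  expect_equal(back$persons$time, ch$persons$time)
  for (w in names(ch$waves))
    expect_true(all(back$waves[[w]] == ch$waves[[w]]))
  # schema violations are rejected
  diag <- read.csv(file.path(d, "diagnoses.csv"))
  bad <- diag
  bad$disease_code[1] <- "nonsense"
  write.csv(bad, file.path(d, "diagnoses.csv"), row.names = FALSE)
  expect_error(read_cohort(d), "unknown disease codes")
  write.csv(diag[0, ], file.path(d, "diagnoses.csv"), row.names = FALSE)
  expect_error(read_cohort(d), "empty")
  # a diagnosis recorded after end of follow-up is rejected
  pe <- read.csv(file.path(d, "persons.csv"))
  early <- pe$person_id[which(pe$time < 5)[1]]
  bad2 <- rbind(diag, data.frame(person_id = early,
                                 disease_code = diag$disease_code[1],
                                 wave = 2019))
  write.csv(bad2, file.path(d, "diagnoses.csv"), row.names = FALSE)
  expect_error(read_cohort(d), "after end of follow-up")
  unlink(d, recursive = TRUE)
})

test_that("education and urbanity margins follow the census tables", {
  cfg <- sim_config(n_per_stratum = 4000, seed = 87)
  ch <- simulate_cohort(cfg, outcomes = FALSE)
  pe <- subset(ch$persons, sex == "F" & age_group == "80+")
  expect_equal(mean(pe$education == "no_primary"), 0.8239,
               tolerance = 0.05)
  pe2 <- subset(ch$persons, sex == "M" & age_group == "50-59")
  expect_equal(mean(pe2$urbanity == "suburban"), 0.4466,
               tolerance = 0.05)
})
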