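SEXES <- c("F", "M")
AGE_GROUPS <- c("50-59", "60-69", "70-79", "80+")
EDU_LEVELS <- c("no_primary", "lower_secondary", "upper_secondary",
                "university")
URB_LEVELS <- c("cities", "suburban", "rural")
WAVES <- c(2011L, 2016L, 2019L)
WAVE_TIMES <- c(`2011` = 0, `2016` = 5, `2019` = 8)

# Baseline census distributions of education and urbanity per sex x age
# group (percent), reflecting a northern-Italian older population: education
# improves in younger cohorts, suburban residence dominates everywhere.
EDU_TABLE <- matrix(c(
  15.19, 48.13, 24.73, 11.95,   # F 50-59
  48.21, 32.36, 12.43,  7.00,   # F 60-69
  72.72, 17.24,  7.16,  2.87,   # F 70-79
  82.39, 10.45,  5.04,  2.13,   # F 80+
  12.71, 47.68, 28.00, 11.61,   # M 50-59
  35.92, 36.02, 18.56,  9.50,   # M 60-69
  60.75, 23.15, 10.50,  5.60,   # M 70-79
  71.63, 16.10,  7.35,  4.92),  # M 80+
  nrow = 8, byrow = TRUE,
  dimnames = list(paste(rep(SEXES, each = 4), AGE_GROUPS), EDU_LEVELS))

URB_TABLE <- matrix(c(
  34.07, 44.59, 21.33,
  36.92, 43.28, 19.80,
  38.73, 41.48, 19.78,
  39.01, 39.14, 21.84,
  32.88, 44.66, 22.45,
  34.45, 43.75, 21.80,
  36.22, 42.43, 21.35,
  37.38, 40.31, 22.31),
  nrow = 8, byrow = TRUE,
  dimnames = list(paste(rep(SEXES, each = 4), AGE_GROUPS), URB_LEVELS))

#' Simulation configuration for synthetic closed cohorts
#'
#' Assembles the full parameter set of the synthetic-cohort generator:
#' disease catalog, planted Ising couplings, per-stratum prevalence shifts,
#' inter-wave incidence model, and outcome coefficients. Defaults emulate a
#' regional administrative cohort aged 50+ followed 2011-2019: prevalence
#' and disease accumulation increase with age group so that median lifetime
#' disease counts among multimorbid persons rise from about 3 (ages 50-59)
#' to about 6 (80+), education and urbanity follow the census margins in
#' `EDU_TABLE`/`URB_TABLE`, mortality is driven by pattern membership and
#' disease count, hospitalization counts are negative-binomial and length
#' of stay log-normal.
#'
#' @param n_per_stratum Persons simulated per sex x age-group stratum
#'   (before inclusion filtering).
#' @param catalog Disease catalog (see [generate_catalog()]).
#' @param coupling Named list of planted-coupling parameters passed to
#'   [planted_coupling()]: `within`, `bridge`, `background`,
#'   `within_density`, `negative_frac`.
#' @param age_logit_shift Additive log-odds shift of every disease's
#'   baseline prevalence per age group.
#' @param sex_logit_shift Same, per sex.
#' @param incidence List: `scale` (per-disease 5-year new-diagnosis
#'   probability as a fraction of its baseline prevalence), `neighbor_coef`
#'   (added log-odds per already-affected planted network neighbor).
#' @param outcome List of outcome coefficients: `base_hazard` (yearly
#'   baseline death hazard per age group), `pattern_loghr` (named,
#'   reference cardiovascular = 0), `count_loghr` (per lifetime disease
#'   beyond two), `education_loghr`, `urbanity_loghr`, `exposure_loghr`
#'   (planted-dyad exposure on the death hazard), `mortality_model`
#'   (`"ph"` or `"logistic"`; the latter plants `exposure_logor` directly
#'   on the 8-year death odds), `exposure_logor`, `migration_rate`
#'   (yearly out-migration censoring hazard), `hosp_log_mu`, `hosp_count_coef`,
#'   `exposure_logirr`, `dispersion` (negative-binomial; 0 = Poisson),
#'   `los_log_mu`, `los_sdlog`, `exposure_loglos`.
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_stratum = 5000,
                       catalog = default_catalog(),
                       coupling = list(),
                       age_logit_shift = c(`50-59` = 0.1, `60-69` = 0.55,
                                           `70-79` = 0.95, `80+` = 1.25),
                       sex_logit_shift = c(F = 0, M = 0),
                       incidence = list(),
                       outcome = list(),
                       seed = 1L) {
  if (is.null(seed)) stop("a seed is mandatory in sim_config()")
  coupling <- utils::modifyList(
    list(within = 0.8, bridge = 0.5, background = 0,
         within_density = 0.5, negative_frac = 0.1), coupling)
  incidence <- utils::modifyList(
    list(scale = 0.22, neighbor_coef = 0.3), incidence)
  outcome <- utils::modifyList(
    list(base_hazard = c(`50-59` = 0.006, `60-69` = 0.015,
                         `70-79` = 0.035, `80+` = 0.075),
         pattern_loghr = c(cardiovascular = 0, neuropsychiatric = 0.4,
                           respiratory_digestive = 0.15,
                           metabolic_pain = 0.1),
         count_loghr = 0.16,
         education_loghr = c(no_primary = 0, lower_secondary = -0.08,
                             upper_secondary = -0.12, university = -0.2),
         urbanity_loghr = c(cities = 0, suburban = -0.05, rural = 0.05),
         exposure_loghr = 0.3,
         mortality_model = "ph",
         exposure_logor = log(2.5),
         migration_rate = 0.012,
         hosp_log_mu = log(0.9),
         hosp_count_coef = 0.12,
         exposure_logirr = log(1.5),
         dispersion = 0.8,
         los_log_mu = log(6),
         los_sdlog = 0.9,
         exposure_loglos = log(1.6)),
    outcome)
  stopifnot(all(is.finite(unlist(incidence))),
            all(is.finite(unlist(outcome[!vapply(outcome, is.character,
                                                 logical(1))]))))
  if (outcome$dispersion < 0) stop("negative dispersion is not allowed")
  structure(list(n_per_stratum = n_per_stratum, catalog = catalog,
                 coupling = coupling, age_logit_shift = age_logit_shift,
                 sex_logit_shift = sex_logit_shift, incidence = incidence,
                 outcome = outcome, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  diseases:", nrow(x$catalog), " strata: 2 sexes x 4 age groups\n")
  cat("  n per stratum:", x$n_per_stratum, " seed:", x$seed, "\n")
  invisible(x)
}

#' Accumulate diagnoses across follow-up waves
#'
#' Propagates a baseline (wave 2011) binary disease matrix through later
#' waves with a discrete-time logistic incidence hazard per disease per
#' inter-wave interval. The log-odds of a new diagnosis of disease j is
#' `qlogis(base_j * years/5) + neighbor_coef * (number of already-present
#' planted network neighbors)`, so disease accumulation is coupled to the
#' dependence structure. Diagnoses are never removed (chronic, no
#' remission).
#'
#' @param baseline `n x p` binary matrix (wave 2011).
#' @param support Binary neighbor matrix (planted coupling support).
#' @param base_prob Per-disease 5-year baseline new-diagnosis probability.
#' @param neighbor_coef Added log-odds per affected neighbor.
#' @param wave_years Years of each inter-wave interval (default 5, 3).
#' @param seed Optional seed.
#' @return Named list of per-wave cumulative matrices (2011, 2016, 2019).
#' @export
accumulate_waves <- function(baseline, support, base_prob,
                             neighbor_coef = 0.35, wave_years = c(5, 3),
                             seed = NULL) {
  p <- ncol(baseline)
  stopifnot(length(base_prob) == p, all(dim(support) == c(p, p)))
  with_seed(seed, {
    waves <- vector("list", length(wave_years) + 1L)
    names(waves) <- as.character(WAVES[seq_along(waves)])
    waves[[1L]] <- baseline
    X <- baseline
    for (w in seq_along(wave_years)) {
      pr <- pmin(pmax(base_prob * wave_years[w] / 5, 0), 0.999)
      if (all(pr == 0)) {
        waves[[w + 1L]] <- X
        next
      }
      nb <- X %*% (support != 0)
      logit <- matrix(qlogis(pmax(pr, 1e-12)), nrow(X), p, byrow = TRUE) +
        neighbor_coef * nb
      prob <- plogis(logit)
      prob[, pr == 0] <- 0
      new <- (X == 0) & (matrix(runif(length(prob)), nrow(prob)) < prob)
      X <- X | new
      storage.mode(X) <- "double"
      waves[[w + 1L]] <- X
    }
    waves
  })
}

# Dominant planted pattern of each row of a binary disease matrix:
# the block holding most of the person's diseases; ties go to the block
# with the larger summed planted strength; residual ties to the smallest
# block index. Rows without diseases get NA.
planted_pattern <- function(X, membership, strength) {
  K <- max(membership)
  counts <- sapply(seq_len(K), function(k)
    rowSums(X[, membership == k, drop = FALSE]))
  scr <- sapply(seq_len(K), function(k)
    X[, membership == k, drop = FALSE] %*% strength[membership == k])
  counts <- matrix(counts, ncol = K)
  scr <- matrix(scr, ncol = K)
  out <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    if (all(counts[i, ] == 0)) { out[i] <- NA_integer_; next }
    best <- which(counts[i, ] == max(counts[i, ]))
    if (length(best) > 1) {
      s <- scr[i, best]
      best <- best[s == max(s)]
    }
    out[i] <- best[1L]
  }
  out
}

#' Simulate a synthetic closed cohort
#'
#' Generates one closed cohort per sex x age-group stratum: census
#' covariates from the configured multinomials, baseline diseases from the
#' planted Ising model (intercepts mean-field-calibrated to the stratum's
#' prevalence targets), monotone disease accumulation across waves 2011,
#' 2016 and 2019, and (by default) death/censoring times, hospitalization
#' counts and length of stay via [simulate_outcomes()].
#'
#' @param config A [sim_config()] object.
#' @param outcomes Whether to also simulate outcomes (default TRUE).
#' @return A `morb_cohort` object: `persons` data frame, per-wave binary
#'   matrices `waves`, the `catalog`, the planted `coupling` matrix and the
#'   generating `config`.
#' @export
simulate_cohort <- function(config = sim_config(), outcomes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cat <- config$catalog
  p <- nrow(cat)
  theta <- planted_coupling(
    cat, within = config$coupling$within, bridge = config$coupling$bridge,
    background = config$coupling$background,
    within_density = config$coupling$within_density,
    negative_frac = config$coupling$negative_frac,
    seed = child_seed(config$seed, "coupling"))
  support <- (theta != 0) * 1
  persons_list <- list()
  wave_list <- lapply(WAVES, function(w) list())
  idx0 <- 0L
  for (sx in SEXES) for (ag in AGE_GROUPS) {
    n <- config$n_per_stratum
    key <- paste(sx, ag)
    sd_s <- child_seed(config$seed, "stratum", match(key, paste(
      rep(SEXES, each = 4), AGE_GROUPS)))
    target <- plogis(qlogis(cat$base_prevalence) +
                       config$age_logit_shift[[ag]] +
                       config$sex_logit_shift[[sx]])
    h <- calibrate_intercepts(theta, target, refine = 0)
    base <- sample_ising(theta, h, n, seed = child_seed(sd_s, "ising"))
    waves <- accumulate_waves(
      base, support,
      base_prob = config$incidence$scale * target,
      neighbor_coef = config$incidence$neighbor_coef,
      seed = child_seed(sd_s, "waves"))
    pe <- with_seed(child_seed(sd_s, "covars"), {
      edu <- sample(EDU_LEVELS, n, TRUE, prob = EDU_TABLE[key, ])
      urb <- sample(URB_LEVELS, n, TRUE, prob = URB_TABLE[key, ])
      data.frame(
        person_id = sprintf("%s%s_%06d", sx, gsub("[-+]", "", ag),
                            idx0 + seq_len(n)),
        sex = sx, age_group = ag, education = edu, urbanity = urb,
        stringsAsFactors = FALSE)
    })
    persons_list[[key]] <- pe
    for (w in seq_along(WAVES)) {
      rownames(waves[[w]]) <- pe$person_id
      wave_list[[w]][[key]] <- waves[[w]]
    }
    idx0 <- idx0 + n
  }
  persons <- do.call(rbind, persons_list)
  rownames(persons) <- NULL
  waves <- lapply(wave_list, function(l) do.call(rbind, l))
  names(waves) <- as.character(WAVES)
  for (w in seq_along(waves)) colnames(waves[[w]]) <- cat$code
  persons$sex <- factor(persons$sex, SEXES)
  persons$age_group <- factor(persons$age_group, AGE_GROUPS)
  persons$education <- factor(persons$education, EDU_LEVELS)
  persons$urbanity <- factor(persons$urbanity, URB_LEVELS)
  cohort <- structure(list(persons = persons, waves = waves, catalog = cat,
                           coupling = theta, config = config),
                      class = "morb_cohort")
  if (outcomes)
    cohort <- simulate_outcomes(cohort,
                                seed = child_seed(config$seed, "outcomes"))
  cohort
}

#' Planted-dyad exposure flag used by the outcome simulator
#'
#' A person is exposed when both members of at least one planted bridge
#' dyad (a coupling edge incident to a bridge disease) are present in their
#' baseline (2011) diseases.
#'
#' @param cohort A `morb_cohort`.
#' @return Logical vector, one element per person.
#' @export
planted_exposure <- function(cohort) {
  theta <- cohort$coupling
  br <- which(cohort$catalog$block == "bridge")
  X <- cohort$waves[[1L]]
  if (length(br) == 0) return(rep(FALSE, nrow(X)))
  flag <- rep(FALSE, nrow(X))
  for (b in br) {
    nb <- which(theta[b, ] != 0)
    for (j in nb) flag <- flag | (X[, b] == 1 & X[, j] == 1)
  }
  flag
}

#' Simulate death, censoring, hospitalization and length of stay
#'
#' Adds outcomes to a simulated cohort. Survival follows a piecewise
#' proportional-hazards model: the yearly baseline hazard of the person's
#' age group is multiplied by `exp` of the planted pattern effect (pattern
#' of the current wave), the lifetime disease-count effect, education and
#' urbanity effects, and the planted-dyad exposure effect. Follow-up is
#' administratively censored 8 years after baseline (end of 2019), with
#' additional exponential out-migration censoring. Hospitalization counts
#' are negative-binomial (Poisson when `dispersion = 0`) and total length
#' of stay is log-normal for persons with at least one admission. Wave
#' matrices are truncated at death/censoring: diagnoses are only recorded
#' at waves the person was still under observation.
#'
#' @param cohort A `morb_cohort` from [simulate_cohort()].
#' @param outcome Optional list overriding the config's outcome
#'   coefficients (see [sim_config()]).
#' @param seed Optional seed.
#' @return The cohort with outcome columns added to `persons`:
#'   `time` (years of follow-up), `death` (0/1), `exposed`,
#'   `planted_pattern_2011/2016`, `n_dis_2011/2016/lifetime`,
#'   `hosp_count`, `los_days`.
#' @export
simulate_outcomes <- function(cohort, outcome = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "morb_cohort"))
  oc <- utils::modifyList(cohort$config$outcome, outcome %||% list())
  if (oc$dispersion < 0) stop("negative dispersion is not allowed")
  membership <- planted_membership(cohort$catalog)
  strength <- rowSums(abs(cohort$coupling))
  pat_names <- names(oc$pattern_loghr)
  pe <- cohort$persons
  n <- nrow(pe)
  with_seed(seed, {
    pat1 <- planted_pattern(cohort$waves[[1L]], membership, strength)
    pat2 <- planted_pattern(cohort$waves[[2L]], membership, strength)
    exposed <- planted_exposure(cohort)
    lp_fixed <- oc$education_loghr[as.character(pe$education)] +
      oc$urbanity_loghr[as.character(pe$urbanity)] +
      oc$exposure_loghr * exposed
    cnt1 <- rowSums(cohort$waves[[1L]])
    cnt2 <- rowSums(cohort$waves[[2L]])
    lp1 <- lp_fixed + oc$count_loghr * pmax(cnt1 - 2, 0) +
      ifelse(is.na(pat1), 0, oc$pattern_loghr[pat1])
    lp2 <- lp_fixed + oc$count_loghr * pmax(cnt2 - 2, 0) +
      ifelse(is.na(pat2), 0, oc$pattern_loghr[pat2])
    h0 <- oc$base_hazard[as.character(pe$age_group)]
    t1 <- rexp(n, pmax(h0 * exp(lp1), 1e-12))
    t2 <- 5 + rexp(n, pmax(h0 * exp(lp2), 1e-12))
    death_time <- ifelse(t1 < 5, t1, pmin(t2, Inf))
    mig <- if (oc$migration_rate > 0) rexp(n, oc$migration_rate) else
      rep(Inf, n)
    time <- pmin(death_time, mig, 8)
    death <- as.integer(death_time <= pmin(mig, 8))
    if (identical(oc$mortality_model, "logistic")) {
      # direct logistic mechanism on the 8-year death indicator, used when
      # a planted odds ratio must be recovered by the baseline GLMs
      lp_d <- qlogis(pmin(pmax(mean(death), 0.02), 0.6)) +
        oc$education_loghr[as.character(pe$education)] +
        oc$urbanity_loghr[as.character(pe$urbanity)] +
        oc$exposure_logor * exposed +
        oc$count_loghr * pmax(cnt1 - 2, 0)
      death <- rbinom(n, 1, plogis(lp_d))
      mig <- rep(Inf, n)
      time <- ifelse(death == 1, runif(n, 0.5, 8), 8)
    }
    # truncate diagnoses at end of observation
    waves <- cohort$waves
    for (w in 2:3) {
      gone <- time < WAVE_TIMES[w]
      if (any(gone)) waves[[w]][gone, ] <- waves[[w - 1L]][gone, ]
    }
    lifetime <- rowSums(waves[[3L]])
    mu_h <- exp(oc$hosp_log_mu +
                  oc$hosp_count_coef * pmax(cnt1 - 2, 0) +
                  oc$education_loghr[as.character(pe$education)] +
                  oc$urbanity_loghr[as.character(pe$urbanity)] +
                  oc$exposure_logirr * exposed)
    hosp <- if (oc$dispersion == 0) rpois(n, mu_h) else
      rnbinom(n, size = 1 / oc$dispersion, mu = mu_h)
    mu_l <- oc$los_log_mu + oc$exposure_loglos * exposed +
      0.5 * oc$education_loghr[as.character(pe$education)]
    los <- ifelse(hosp > 0,
                  round(rlnorm(n, mu_l + 0.35 * log(pmax(hosp, 1)),
                               oc$los_sdlog), 1), 0)
    pe$time <- round(time, 6)
    pe$death <- death
    pe$exposed <- exposed
    pe$planted_pattern_2011 <- pat_names[pat1]
    pe$planted_pattern_2016 <- pat_names[pat2]
    pe$n_dis_2011 <- cnt1
    pe$n_dis_2016 <- rowSums(waves[[2L]])
    pe$n_dis_lifetime <- lifetime
    pe$hosp_count <- hosp
    pe$los_days <- los
    cohort$persons <- pe
    cohort$waves <- waves
    cohort
  })
}

#' Apply the pooled-prevalence and multimorbidity inclusion filters
#'
#' Drops diseases whose pooled lifetime prevalence (union of diagnoses over
#' all waves, over the whole cohort by default) is below `threshold`, then
#' drops persons left with fewer than `min_diseases` lifetime diseases.
#'
#' @param cohort A `morb_cohort`.
#' @param threshold Prevalence threshold (default 0.01).
#' @param min_diseases Minimum lifetime diseases for inclusion (default 2).
#' @param scope `"pooled"` (whole cohort, default) or `"stratum"` (a
#'   disease is dropped only if below threshold in every stratum).
#' @return The filtered cohort, with a `filter_report` attribute listing
#'   dropped diseases and person counts.
#' @export
apply_inclusion_filter <- function(cohort, threshold = 0.01,
                                   min_diseases = 2,
                                   scope = c("pooled", "stratum")) {
  stopifnot(inherits(cohort, "morb_cohort"))
  scope <- match.arg(scope)
  lifetime <- cohort$waves[[length(cohort$waves)]]
  if (scope == "pooled") {
    prev <- colMeans(lifetime)
    keep <- prev >= threshold
  } else {
    strata <- interaction(cohort$persons$sex, cohort$persons$age_group)
    by_stratum <- rowsum(lifetime, strata) / as.vector(table(strata))
    keep <- apply(by_stratum, 2, max) >= threshold
  }
  if (!any(keep))
    stop("all diseases fall below the prevalence threshold; empty catalog")
  dropped_d <- colnames(lifetime)[!keep]
  waves <- lapply(cohort$waves, function(m) m[, keep, drop = FALSE])
  keep_p <- rowSums(waves[[length(waves)]]) >= min_diseases
  n_dropped_p <- sum(!keep_p)
  waves <- lapply(waves, function(m) m[keep_p, , drop = FALSE])
  persons <- cohort$persons[keep_p, , drop = FALSE]
  rownames(persons) <- NULL
  if (!is.null(persons$n_dis_lifetime)) {
    persons$n_dis_2011 <- rowSums(waves[[1L]])
    persons$n_dis_2016 <- rowSums(waves[[2L]])
    persons$n_dis_lifetime <- rowSums(waves[[3L]])
  }
  out <- cohort
  out$persons <- persons
  out$waves <- waves
  out$catalog <- cohort$catalog[keep, , drop = FALSE]
  out$coupling <- cohort$coupling[keep, keep, drop = FALSE]
  attr(out, "filter_report") <- list(
    diseases_dropped = dropped_d, n_diseases_dropped = length(dropped_d),
    n_persons_dropped = n_dropped_p, n_persons_retained = nrow(persons))
  out
}

#' @export
print.morb_cohort <- function(x, ...) {
  cat("Synthetic multimorbidity cohort\n")
  cat(" ", nrow(x$persons), "persons,", nrow(x$catalog), "diseases,",
      length(x$waves), "waves (", paste(names(x$waves), collapse = ", "),
      ")\n")
  if (!is.null(x$persons$death))
    cat("  deaths:", sum(x$persons$death), " median lifetime diseases:",
        stats::median(x$persons$n_dis_lifetime), "\n")
  invisible(x)
}

# Survivors under observation at a wave: follow-up extends at least to the
# wave date (everyone at baseline).
survivors_at_wave <- function(cohort, wave) {
  t0 <- WAVE_TIMES[as.character(wave)]
  if (t0 == 0 || is.null(cohort$persons$time))
    rep(TRUE, nrow(cohort$persons))
  else cohort$persons$time >= t0
}

#' Write a cohort to delimited text files
#'
#' Writes `persons.csv` (one row per person, covariates and outcomes),
#' `diagnoses.csv` (long format: person_id, disease_code, wave of first
#' record), `hospitalizations.csv` and `catalog.csv` into `dir`.
#'
#' @param cohort A `morb_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$persons, file.path(dir, "persons.csv"),
            row.names = FALSE)
  diag <- list()
  prev <- matrix(0, nrow(cohort$waves[[1]]), ncol(cohort$waves[[1]]))
  for (w in names(cohort$waves)) {
    new <- which(cohort$waves[[w]] == 1 & prev == 0, arr.ind = TRUE)
    if (nrow(new) > 0)
      diag[[w]] <- data.frame(
        person_id = rownames(cohort$waves[[w]])[new[, 1]],
        disease_code = colnames(cohort$waves[[w]])[new[, 2]],
        wave = as.integer(w), stringsAsFactors = FALSE)
    prev <- cohort$waves[[w]]
  }
  diag <- do.call(rbind, diag)
  diag <- diag[order(diag$person_id, diag$wave, diag$disease_code), ]
  write.csv(diag, file.path(dir, "diagnoses.csv"), row.names = FALSE)
  hosp <- cohort$persons[, intersect(c("person_id", "hosp_count",
                                       "los_days"), names(cohort$persons))]
  write.csv(hosp, file.path(dir, "hospitalizations.csv"),
            row.names = FALSE)
  write.csv(cohort$catalog, file.path(dir, "catalog.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from delimited text files
#'
#' Inverse of [write_cohort()]. Validates the schema: unknown disease
#' codes, diagnoses recorded at waves after the person's end of follow-up,
#' and empty diagnosis files are rejected with informative errors.
#'
#' @param dir Directory containing `persons.csv`, `diagnoses.csv`,
#'   `catalog.csv` (and optionally `hospitalizations.csv`).
#' @return A `morb_cohort`.
#' @export
read_cohort <- function(dir) {
  persons <- read.csv(file.path(dir, "persons.csv"),
                      stringsAsFactors = FALSE)
  catalog <- read.csv(file.path(dir, "catalog.csv"),
                      stringsAsFactors = FALSE)
  diag <- read.csv(file.path(dir, "diagnoses.csv"),
                   stringsAsFactors = FALSE)
  if (nrow(diag) == 0)
    stop("diagnoses.csv is empty: no multimorbid persons to analyse")
  bad <- setdiff(unique(diag$disease_code), catalog$code)
  if (length(bad) > 0)
    stop("unknown disease codes in diagnoses.csv: ",
         paste(bad, collapse = ", "))
  bad_p <- setdiff(unique(diag$person_id), persons$person_id)
  if (length(bad_p) > 0)
    stop("diagnoses.csv references unknown person ids (first rows: ",
         paste(utils::head(which(diag$person_id %in% bad_p), 5),
               collapse = ", "), ")")
  if (!is.null(persons$time)) {
    end_t <- persons$time[match(diag$person_id, persons$person_id)]
    late <- WAVE_TIMES[as.character(diag$wave)] > end_t
    if (any(late))
      stop("diagnoses recorded after end of follow-up at rows: ",
           paste(utils::head(which(late), 5), collapse = ", "))
  }
  persons$sex <- factor(persons$sex, SEXES)
  persons$age_group <- factor(persons$age_group, AGE_GROUPS)
  persons$education <- factor(persons$education, EDU_LEVELS)
  persons$urbanity <- factor(persons$urbanity, URB_LEVELS)
  waves <- list()
  cur <- matrix(0, nrow(persons), nrow(catalog),
                dimnames = list(persons$person_id, catalog$code))
  for (w in WAVES) {
    rows <- diag[diag$wave == w, ]
    if (nrow(rows) > 0)
      cur[cbind(match(rows$person_id, persons$person_id),
                match(rows$disease_code, catalog$code))] <- 1
    waves[[as.character(w)]] <- cur
  }
  structure(list(persons = persons, waves = waves, catalog = catalog,
                 coupling = NULL, config = NULL), class = "morb_cohort")
}
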