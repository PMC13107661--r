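#' Counting-process rows with time-dependent pattern and disease count
#'
#' Splits each person's follow-up at the wave boundaries (5 and 8 years
#' after the 2011 baseline) into `(start, stop]` intervals. Within an
#' interval the covariates take the values of the wave opening it: the
#' assigned multimorbidity pattern and the cumulative disease count at
#' 2011 for `(0, 5]`, at 2016 for `(5, 8]`. Death or censoring terminates
#' the last interval; the event indicator is set on it. Intervals whose
#' pattern is undefined (no diagnosed disease at the wave) are dropped.
#'
#' @param cohort A `morb_cohort` with outcomes.
#' @param assignments Assignment table from [assign_all_waves()].
#' @return Data frame: `person_id`, `start`, `stop`, `event`, `pattern`,
#'   `n_diseases`, `education`, `urbanity`, `sex`, `age_group`.
#' @export
build_counting_process <- function(cohort, assignments) {
  pe <- cohort$persons
  if (is.null(pe$time))
    stop("cohort has no outcomes; run simulate_outcomes() first")
  a1 <- assignments[assignments$wave == 2011, ]
  a2 <- assignments[assignments$wave == 2016, ]
  pat1 <- a1$pattern[match(pe$person_id, a1$person_id)]
  pat2 <- a2$pattern[match(pe$person_id, a2$person_id)]
  cnt1 <- rowSums(cohort$waves[["2011"]])
  cnt2 <- rowSums(cohort$waves[["2016"]])
  rows <- list()
  # interval (0, min(time, 5)]
  stop1 <- pmin(pe$time, 5)
  ev1 <- as.integer(pe$death == 1 & pe$time <= 5)
  rows[[1]] <- data.frame(
    person_id = pe$person_id, start = 0, stop = stop1, event = ev1,
    pattern = pat1, n_diseases = cnt1, education = pe$education,
    urbanity = pe$urbanity, sex = pe$sex, age_group = pe$age_group,
    stringsAsFactors = FALSE)
  # interval (5, min(time, 8)] for persons followed past 5 years
  sel <- pe$time > 5
  if (any(sel)) {
    rows[[2]] <- data.frame(
      person_id = pe$person_id[sel], start = 5,
      stop = pmin(pe$time[sel], 8),
      event = as.integer(pe$death[sel] == 1 & pe$time[sel] <= 8),
      pattern = pat2[sel], n_diseases = cnt2[sel],
      education = pe$education[sel], urbanity = pe$urbanity[sel],
      sex = pe$sex[sel], age_group = pe$age_group[sel],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[out$stop > out$start, , drop = FALSE]
  out <- out[!is.na(out$pattern), , drop = FALSE]
  out$pattern <- stats::relevel(factor(out$pattern),
                                ref = reference_pattern(out$pattern))
  out <- out[order(out$person_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# cardiovascular is the reference pattern when present
reference_pattern <- function(pattern) {
  lev <- levels(factor(pattern))
  if ("cardiovascular" %in% lev) "cardiovascular" else lev[1]
}

#' Construct a model fit result table
#'
#' @param family Model family label.
#' @param coefs Data frame `term`, `estimate`, `se`, `ci_low`, `ci_high`,
#'   `p` (estimates on the link scale; `exp_estimate` added for
#'   ratio-scale families).
#' @param aic AIC of the fit.
#' @param n Number of observations (rows) used.
#' @param stratum Optional stratum label.
#' @return A `fit_result` object.
#' @export
fit_result <- function(family, coefs, aic, n, stratum = NULL) {
  if (family %in% c("cox", "logistic", "negative-binomial",
                    "quasi-poisson"))
    coefs$exp_estimate <- exp(coefs$estimate)
  structure(list(family = family, coefs = coefs, aic = aic, n = n,
                 stratum = stratum), class = "fit_result")
}

#' @export
print.fit_result <- function(x, digits = 3, ...) {
  cat("Fit (", x$family, ")", sep = "")
  if (!is.null(x$stratum)) cat(" [", x$stratum, "]", sep = "")
  cat("  n =", x$n, " AIC =", round(x$aic, 1), "\n")
  print(format(x$coefs, digits = digits), row.names = FALSE)
  invisible(x)
}

coef_table <- function(est, se, p) {
  z <- qnorm(0.975)
  data.frame(term = names(est), estimate = as.numeric(est),
             se = as.numeric(se), ci_low = as.numeric(est - z * se),
             ci_high = as.numeric(est + z * se), p = as.numeric(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cox model on counting-process rows
#'
#' Partial-likelihood fit with the Efron tie approximation. Reference
#' levels: cardiovascular pattern, no/primary education, cities.
#'
#' @param rows Counting-process rows (see [build_counting_process()]).
#' @param terms Character vector of right-hand-side terms (default
#'   pattern + number of diseases + education + urbanity).
#' @param stratum Optional stratum label for the result.
#' @return A `fit_result` with family `"cox"` (hazard ratios in
#'   `coefs$exp_estimate`).
#' @export
fit_cox <- function(rows, terms = c("pattern", "n_diseases", "education",
                                    "urbanity"), stratum = NULL) {
  if (sum(rows$event) < 1) stop("no events in the counting-process rows")
  rows <- droplevels(rows)
  keep <- vapply(terms, function(tm) {
    v <- rows[[tm]]
    !(is.factor(v) && nlevels(v) < 2) && length(unique(v)) > 1
  }, logical(1))
  terms <- terms[keep]
  f <- as.formula(paste("survival::Surv(start, stop, event) ~",
                        paste(terms, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(f, data = rows, ties = "efron"),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w))) {
        warning("possible separation; consider a penalized fit",
                call. = FALSE)
        suppressWarnings(survival::coxph(f, data = rows, ties = "efron"))
      } else suppressWarnings(survival::coxph(f, data = rows,
                                              ties = "efron"))
    })
  sm <- summary(fit)$coefficients
  # aliased (NA) coefficients are absent from the summary; align on it
  fit_result("cox",
             coef_table(coef(fit)[rownames(sm)], sm[, "se(coef)"],
                        sm[, "Pr(>|z|)"]),
             aic = AIC(fit), n = nrow(rows), stratum = stratum)
}

#' Compare disease-count and pattern Cox models by AIC
#'
#' Fits, on identical counting-process rows, a Cox model using the total
#' number of chronic diseases and one using the multimorbidity pattern
#' (both controlling for education and urbanity), and returns their AICs.
#' A positive delta means the pattern model fits better.
#'
#' @param rows Counting-process rows.
#' @param stratum Optional stratum label.
#' @return List `aic_count`, `aic_pattern`, `delta`
#'   (`aic_count - aic_pattern`).
#' @export
compare_models_aic <- function(rows, stratum = NULL) {
  fit_n <- fit_cox(rows, terms = c("n_diseases", "education", "urbanity"),
                   stratum = stratum)
  fit_p <- fit_cox(rows, terms = c("pattern", "education", "urbanity"),
                   stratum = stratum)
  list(aic_count = fit_n$aic, aic_pattern = fit_p$aic,
       delta = fit_n$aic - fit_p$aic, stratum = stratum)
}

#' Baseline-exposure models for mortality, hospitalization and stay
#'
#' Fits the three generalized linear models quantifying the impact of
#' having at least one strong gatekeeper dyad at baseline: logistic
#' regression on death during follow-up (odds ratio), an overdispersed
#' count model on unplanned hospitalizations (negative-binomial by
#' default, quasi-Poisson optionally; incidence-rate ratio) and a linear
#' model on `log(length of stay + 1)` (multiplicative change `exp(beta)`;
#' the +1 accommodates persons never hospitalized). All models control for
#' education and urbanity.
#'
#' @param cohort A `morb_cohort` with outcomes.
#' @param exposure Logical exposure flags from [flag_exposure()] (aligned
#'   with `cohort$persons`).
#' @param count_model `"negative-binomial"` (default) or
#'   `"quasi-poisson"`.
#' @param stratum Optional stratum label.
#' @return Named list of three `fit_result`s: `mortality`,
#'   `hospitalization`, `length_of_stay`.
#' @export
fit_exposure_glms <- function(cohort, exposure,
                              count_model = c("negative-binomial",
                                              "quasi-poisson"),
                              stratum = NULL) {
  count_model <- match.arg(count_model)
  pe <- droplevels(cohort$persons)
  if (is.null(pe$death))
    stop("cohort has no outcomes; run simulate_outcomes() first")
  if (all(pe$hosp_count == 0))
    stop("all hospitalization counts are zero")
  d <- data.frame(death = pe$death, hosp = pe$hosp_count,
                  log_los = log(pe$los_days + 1),
                  exposed = as.logical(exposure[pe$person_id]),
                  education = pe$education, urbanity = pe$urbanity)
  ctrl <- c("education", "urbanity")
  ctrl <- ctrl[vapply(ctrl, function(v) nlevels(d[[v]]) > 1, logical(1))]
  rhs <- paste(c("exposed", ctrl), collapse = " + ")
  glm_tab <- function(fit) {
    sm <- summary(fit)$coefficients
    coef_table(coef(fit)[rownames(sm)], sm[, 2], sm[, 4])
  }
  f_mort <- glm(as.formula(paste("death ~", rhs)), binomial(), data = d)
  mort <- fit_result("logistic", glm_tab(f_mort), AIC(f_mort), nrow(d),
                     stratum)
  if (count_model == "negative-binomial") {
    f_h <- MASS::glm.nb(as.formula(paste("hosp ~", rhs)), data = d)
    hosp <- fit_result("negative-binomial", glm_tab(f_h), AIC(f_h),
                       nrow(d), stratum)
  } else {
    f_h <- glm(as.formula(paste("hosp ~", rhs)),
               stats::quasipoisson(), data = d)
    hosp <- fit_result("quasi-poisson", glm_tab(f_h), NA_real_, nrow(d),
                       stratum)
  }
  f_l <- lm(as.formula(paste("log_los ~", rhs)), data = d)
  los_tab <- glm_tab(f_l)
  los_tab$exp_estimate <- exp(los_tab$estimate)
  los <- fit_result("lognormal-linear", los_tab, AIC(f_l), nrow(d),
                    stratum)
  list(mortality = mort, hospitalization = hosp, length_of_stay = los)
}

#' Export a fit result as a CSV-ready table
#'
#' @param fit A `fit_result`.
#' @return Data frame with the ratio-scale estimate, CI bounds, p and AIC.
#' @export
fit_result_table <- function(fit) {
  co <- fit$coefs
  ratio <- if (!is.null(co$exp_estimate)) co$exp_estimate else
    exp(co$estimate)
  data.frame(term = co$term, estimate = co$estimate, ratio = ratio,
             ci_low = exp(co$ci_low), ci_high = exp(co$ci_high),
             p = co$p, aic = fit$aic, family = fit$family,
             n = fit$n, stringsAsFactors = FALSE)
}
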