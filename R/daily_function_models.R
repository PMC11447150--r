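# Per-domain multilevel regression of functioning scores on interval
# hypoglycaemia status: participant random intercept, Huber-weighted robust
# estimation, two-stage AR(1) autocorrelation adjustment, Bonferroni
# multiplicity control and percent-change-from-intercept presentation.

#' Size of the testing family for multiplicity control
#'
#' The family counts every fitted model: each of the morning-functioning
#' domains and evening-functioning domains, per diabetes-type cohort, per
#' model iteration explored during model development.
#'
#' @param n_morning_domains Number of morning-functioning domains (default 10).
#' @param n_evening_domains Number of evening-functioning domains (default 9).
#' @param n_cohorts Number of cohorts analysed separately (default 2).
#' @param n_model_iterations Number of model iterations (default 7).
#' @return Integer: `(n_morning + n_evening) * n_cohorts * n_iterations`.
#' @export
count_tests <- function(n_morning_domains = 10, n_evening_domains = 9,
                        n_cohorts = 2, n_model_iterations = 7) {
  stopifnot(n_morning_domains >= 0, n_evening_domains >= 0,
            n_morning_domains + n_evening_domains >= 1,
            n_cohorts >= 1, n_model_iterations >= 1)
  as.integer((n_morning_domains + n_evening_domains) * n_cohorts *
               n_model_iterations)
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha_family Family-wise error rate (default 0.05).
#' @param n_tests Number of tests in the family.
#' @return `alpha_family / n_tests`.
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, n_tests) {
  stopifnot(alpha_family > 0, alpha_family <= 1)
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha_family / n_tests
}

#' Build a multiplicity plan
#'
#' @inheritParams bonferroni_threshold
#' @return A list with `alpha_family`, `n_tests`, `alpha_per_test`.
#' @export
multiplicity_plan <- function(alpha_family = 0.05, n_tests = count_tests()) {
  list(alpha_family = alpha_family, n_tests = n_tests,
       alpha_per_test = bonferroni_threshold(alpha_family, n_tests))
}

#' Percent change in score relative to the model intercept
#'
#' Regression coefficients (score units) are presented as a percentage change
#' from the intercept; confidence bounds are transformed by the same
#' division, treating the intercept as fixed.
#'
#' @param coefficient Coefficient(s) in score units.
#' @param intercept Model intercept (score units), non-zero.
#' @return `100 * coefficient / intercept` (vectorised).
#' @export
percent_change <- function(coefficient, intercept) {
  if (any(intercept == 0)) stop("percent change undefined for a zero intercept")
  100 * coefficient / intercept
}

# Huber weight on scaled residuals; c = 1.345 gives 95% efficiency at the
# Gaussian model
.huber_weights <- function(resid, k = 1.345) {
  s <- stats::mad(resid, center = 0)
  if (s <= 0) return(rep(1, length(resid)))
  r <- abs(resid) / s
  ifelse(r <= k, 1, k / r)
}

# lag-1 autocorrelation of residuals within participant, observations ordered
# by interval start time
.lag1_rho <- function(resid, participant, order_time) {
  o <- order(participant, order_time)
  r <- resid[o]; p <- participant[o]
  same <- p[-length(p)] == p[-1L]
  x <- r[-length(r)][same]; y <- r[-1L][same]
  if (length(x) < 3L) return(0)
  rho <- suppressWarnings(stats::cor(x, y))
  if (!is.finite(rho)) 0 else max(min(rho, 0.99), -0.99)
}

#' Fit one domain's multilevel model
#'
#' Fits `outcome ~ exposure + covariates` with a participant random
#' intercept. Estimation is by maximum likelihood with, optionally, (i)
#' iteratively reweighted robust estimation using Huber weights (tuning
#' constant 1.345) on MAD-scaled residuals, and (ii) a two-stage AR(1)
#' working correlation on within-participant residuals ordered by interval
#' start: the AR parameter is estimated from the lag-1 residual correlation
#' of the weighted fit, then the model is refitted once with that correlation
#' held fixed. Rows with a missing outcome, exposure or covariate are dropped
#' pairwise. The reference level of the exposure is the no-hypoglycaemia
#' category. Numeric covariates are centred so the intercept stays
#' interpretable as the expected score of the reference category.
#'
#' @param data Data frame of interval-outcome rows.
#' @param outcome Name of the outcome column (0-10 domain score).
#' @param exposure Name of the exposure factor column.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param participant Name of the participant-id column.
#' @param order_col Name of the column ordering observations in time within
#'   participant (interval start); required when `ar1 = TRUE`.
#' @param reference Exposure level used as baseline (default `"A"`).
#' @param robust Use Huber-weighted iteratively reweighted estimation
#'   (default `TRUE`).
#' @param ar1 Apply the two-stage AR(1) adjustment (default `TRUE`).
#' @param huber_k Huber tuning constant (default 1.345).
#' @param max_iter Maximum reweighting iterations (default 10).
#' @param tol Convergence tolerance on the maximum absolute change in weights
#'   (default 1e-4).
#'
#' @return An object of class `domain_model`: a list with `coefficients`
#'   (a data frame: term, estimate, se, ci_lo, ci_hi, p, percent_change,
#'   percent_ci_lo, percent_ci_hi), `intercept`, `rho` (AR parameter used),
#'   `n_observations`, `n_participants`, `converged`, and the call
#'   metadata (`outcome`, `exposure`, `reference`, dropped levels).
#' @export
fit_domain_model <- function(data, outcome, exposure, covariates = character(),
                             participant = "participant_id",
                             order_col = "start", reference = "A",
                             robust = TRUE, ar1 = TRUE, huber_k = 1.345,
                             max_iter = 10, tol = 1e-4) {
  cols <- c(outcome, exposure, covariates, participant,
            if (ar1) order_col)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("model data is missing column(s): ", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  names(d)[match(c(outcome, exposure, participant), names(d))] <-
    c(".y", ".x", ".pid")
  d$.pid <- factor(d$.pid)
  if (nlevels(d$.pid) < 2L)
    stop("multilevel fit requires at least two participants")
  x <- factor(d$.x)
  if (!reference %in% levels(x))
    stop("reference exposure level '", reference, "' not observed")
  # unobserved levels are dropped by factor(); warn if the caller declared more
  d$.x <- stats::relevel(droplevels(x), ref = reference)
  if (nlevels(d$.x) < 2L)
    stop("exposure must have at least two observed levels")
  for (cv in covariates)
    if (is.numeric(d[[cv]])) d[[cv]] <- d[[cv]] - mean(d[[cv]])
  d$.ord <- if (ar1) as.numeric(d[[order_col]]) else seq_len(nrow(d))
  d <- d[order(d$.pid, d$.ord), , drop = FALSE]
  d$.seq <- stats::ave(seq_len(nrow(d)), d$.pid, FUN = seq_along)

  rhs <- paste(c(".x", covariates), collapse = " + ")
  fixed_fml <- stats::as.formula(paste(".y ~", rhs))
  lmer_fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .pid)"))

  converged <- TRUE
  d$.w <- rep(1, nrow(d))
  fit0 <- tryCatch(
    lme4::lmer(lmer_fml, data = d, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) e)
  if (inherits(fit0, "error"))
    stop("initial multilevel fit failed: ", conditionMessage(fit0))

  if (robust) {
    weights_settled <- FALSE
    for (it in seq_len(max_iter)) {
      res <- stats::residuals(fit0)
      w_new <- .huber_weights(res, k = huber_k)
      delta <- max(abs(w_new - d$.w))
      d$.w <- w_new
      fit_try <- tryCatch(
        lme4::lmer(lmer_fml, data = d, REML = FALSE, weights = d$.w,
                   control = lme4::lmerControl(check.conv.singular = "ignore")),
        error = function(e) e)
      if (inherits(fit_try, "error")) { converged <- FALSE; break }
      fit0 <- fit_try
      if (delta < tol) { weights_settled <- TRUE; break }
    }
    if (!weights_settled) converged <- FALSE
  }

  rho <- 0
  if (ar1) {
    rho <- .lag1_rho(stats::residuals(fit0), d$.pid, d$.ord)
  }

  if (ar1 && abs(rho) > 1e-8) {
    d$.invw <- 1 / pmax(d$.w, 1e-6)
    fit_final <- tryCatch(
      nlme::lme(fixed_fml, random = ~ 1 | .pid, data = d, method = "ML",
                correlation = nlme::corAR1(rho, form = ~ .seq | .pid,
                                           fixed = TRUE),
                weights = if (robust) nlme::varFixed(~ .invw) else NULL,
                control = nlme::lmeControl(opt = "optim", returnObject = TRUE)),
      error = function(e) e)
    if (inherits(fit_final, "error")) {
      converged <- FALSE
      est <- lme4::fixef(fit0)
      se <- sqrt(diag(as.matrix(stats::vcov(fit0))))
    } else {
      est <- nlme::fixef(fit_final)
      se <- sqrt(diag(as.matrix(stats::vcov(fit_final))))
    }
  } else {
    est <- lme4::fixef(fit0)
    se <- sqrt(diag(as.matrix(stats::vcov(fit0))))
  }

  terms <- names(est)
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  ci_lo <- est - 1.96 * se
  ci_hi <- est + 1.96 * se
  intercept <- unname(est[["(Intercept)"]])
  is_exp <- grepl("^\\.x", terms)
  coefs <- data.frame(
    term = sub("^\\.x", paste0(exposure, ""), terms),
    level = ifelse(is_exp, sub("^\\.x", "", terms), NA_character_),
    estimate = unname(est), se = unname(se),
    ci_lo = unname(ci_lo), ci_hi = unname(ci_hi), p = unname(p),
    stringsAsFactors = FALSE)
  pc <- percent_change(coefs$estimate, intercept)
  pl <- percent_change(coefs$ci_lo, intercept)
  ph <- percent_change(coefs$ci_hi, intercept)
  coefs$percent_change <- pc
  coefs$percent_ci_lo <- pmin(pl, ph)
  coefs$percent_ci_hi <- pmax(pl, ph)
  structure(list(
    coefficients = coefs, intercept = intercept, rho = rho,
    n_observations = nrow(d), n_participants = nlevels(d$.pid),
    converged = converged, outcome = outcome, exposure = exposure,
    reference = reference, robust = robust, ar1 = ar1,
    dropped_levels = setdiff(levels(x), levels(d$.x))),
    class = "domain_model")
}

#' @exportS3Method base::print
print.domain_model <- function(x, ...) {
  cat(sprintf("<domain_model> %s ~ %s (ref %s), %d obs / %d participants, rho=%.3f%s\n",
              x$outcome, x$exposure, x$reference, x$n_observations,
              x$n_participants, x$rho,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients[!is.na(x$coefficients$level),
                       c("level", "estimate", "se", "p", "percent_change")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit the full family of domain models
#'
#' One model per cohort, phase, domain and exposure family. The primary
#' family regresses scores on the A-D category; the two exploratory families
#' use the PRH subtypes (adjusted for SDH presence) and the SDH subtypes
#' (adjusted for PRH presence). Significance in the primary family uses the
#' Bonferroni per-test threshold; the exploratory families use the unadjusted
#' 0.05 level and are flagged `adjusted_for_multiplicity = FALSE` in the
#' output.
#'
#' @param model_data Data frame of classified interval-outcome rows with
#'   columns `cohort`, `phase`, `participant_id`, `start`, `category`,
#'   `prh_combined`, `prh_present`, `sdh_subtype`, `sdh_present` and one
#'   column per domain score.
#' @param catalogue Domain catalogue (default [domain_catalogue()]).
#' @param covariates Covariate column names (default `character()`).
#' @param exposures Which families to fit: subset of
#'   `c("category", "prh_subtypes", "sdh_subtypes")`.
#' @param plan Multiplicity plan from [multiplicity_plan()].
#' @param ... Passed to [fit_domain_model()] (e.g. `robust`, `ar1`).
#'
#' @return A list with `results` (tidy data frame: cohort, phase, domain,
#'   family, level, estimate, se, ci bounds, p, percent change columns,
#'   significant, adjusted_for_multiplicity, n_observations,
#'   n_participants, converged) and `plan`.
#' @export
run_model_family <- function(model_data, catalogue = domain_catalogue(),
                             covariates = character(),
                             exposures = c("category", "prh_subtypes",
                                           "sdh_subtypes"),
                             plan = multiplicity_plan(), ...) {
  if (!nrow(model_data)) stop("no model rows; check the upstream join")
  fam_spec <- list(
    category = list(exposure = "category", reference = "A",
                    extra = character(), primary = TRUE),
    prh_subtypes = list(exposure = "prh_combined", reference = "none",
                        extra = "sdh_present", primary = FALSE),
    sdh_subtypes = list(exposure = "sdh_subtype", reference = "none",
                        extra = "prh_present", primary = FALSE))
  res <- list()
  for (cohort in sort(unique(model_data$cohort))) {
    for (phase in c("night", "day")) {
      domains <- if (phase == "night") catalogue$morning_domains
                 else catalogue$evening_domains
      sub <- model_data[model_data$cohort == cohort &
                          model_data$phase == phase, , drop = FALSE]
      if (!nrow(sub)) next
      for (fam in exposures) {
        fs <- fam_spec[[fam]]
        for (dom in domains) {
          if (!dom %in% names(sub)) next
          fit <- tryCatch(
            fit_domain_model(sub, outcome = dom, exposure = fs$exposure,
                             covariates = c(fs$extra, covariates),
                             reference = fs$reference, ...),
            error = function(e) e)
          if (inherits(fit, "error")) next
          cf <- fit$coefficients
          cf <- cf[!is.na(cf$level), , drop = FALSE]
          if (!nrow(cf)) next
          alpha <- if (fs$primary) plan$alpha_per_test else plan$alpha_family
          res[[length(res) + 1L]] <- data.frame(
            cohort = cohort, phase = phase, domain = dom, family = fam,
            level = cf$level, estimate = cf$estimate, se = cf$se,
            ci_lo = cf$ci_lo, ci_hi = cf$ci_hi, p = cf$p,
            percent_change = cf$percent_change,
            percent_ci_lo = cf$percent_ci_lo,
            percent_ci_hi = cf$percent_ci_hi,
            intercept = fit$intercept,
            significant = cf$p < alpha,
            adjusted_for_multiplicity = fs$primary,
            n_observations = fit$n_observations,
            n_participants = fit$n_participants,
            converged = fit$converged,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- if (length(res)) do.call(rbind, res) else
    data.frame()
  rownames(results) <- NULL
  list(results = results, plan = plan)
}
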