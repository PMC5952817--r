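#' Published survival risk-model coefficients
#'
#' Named coefficient vectors of the five cross-validated Cox linear
#' predictors reported by the study: the baseline clinical model
#' (age, sex, LGE) and its four perfusion extensions (visual or
#' quantitative ischemic burden, each as a continuous fraction or
#' dichotomized at the consensus threshold). Sex is coded 1 = male, LGE
#' 1 = present, burdens are fractions of myocardium on a 0-1 scale.
#'
#' @return A named list of named numeric vectors.
#' @export
published_risk_models <- function() {
  list(
    baseline = c(age = 0.025, sex = 2.993, lge = 0.616),
    visual_continuous = c(age = 0.028, sex = 3.108, lge = 0.563,
                          visual_burden = 1.423),
    mpr_continuous = c(age = 0.02, sex = 2.722, lge = 0.678,
                       mpr_burden = 2.490),
    visual_dichotomized = c(age = 0.019, sex = 2.949, lge = 0.486,
                            visual_positive = 1.374),
    mpr_dichotomized = c(age = 0.016, sex = 2.486, lge = 0.497,
                         mpr_positive = 1.761)
  )
}

#' Evaluate a linear predictor
#'
#' @param coefficients Named numeric vector of log hazard ratios.
#' @param covariates Named numeric vector (or single-row data.frame) of
#'   covariate values; must cover every coefficient name.
#' @return The dot product (scalar).
#' @export
linear_predictor <- function(coefficients, covariates) {
  if (is.data.frame(covariates)) covariates <- unlist(covariates[1, ])
  missing_cov <- setdiff(names(coefficients), names(covariates))
  if (length(missing_cov))
    stop("missing covariate(s): ", paste(missing_cov, collapse = ", "))
  sum(coefficients * as.numeric(covariates[names(coefficients)]))
}

#' Cox model specification
#'
#' @param unpenalized Names of covariates entering without shrinkage
#'   (default the established prognostic set: age, sex, lge).
#' @param penalized Names of covariates subject to the L1 penalty.
#' @param penalty_weight `NULL` to select the penalty on an inner
#'   cross-validation loop, or a fixed nonnegative scalar.
#' @return An object of class `cox_model_spec`.
#' @export
cox_model_spec <- function(unpenalized = c("age", "sex", "lge"),
                           penalized = character(0),
                           penalty_weight = NULL) {
  if (length(intersect(unpenalized, penalized)))
    stop("covariate lists must be disjoint")
  if (!is.null(penalty_weight) &&
      (!is.numeric(penalty_weight) || penalty_weight < 0))
    stop("'penalty_weight' must be NULL or a nonnegative scalar")
  structure(list(unpenalized = unpenalized, penalized = penalized,
                 penalty_weight = penalty_weight),
            class = "cox_model_spec")
}

#' Model specification for one of the study's five risk models
#'
#' @param model One of `"baseline"`, `"visual"`, `"mpr"`,
#'   `"visual_dichot"`, `"mpr_dichot"`.
#' @param penalty_weight Passed to [cox_model_spec()].
#' @return A [cox_model_spec()] whose penalized set holds the matching
#'   perfusion covariate (none for the baseline model).
#' @export
perfusion_model_spec <- function(model = c("baseline", "visual", "mpr",
                                           "visual_dichot", "mpr_dichot"),
                                 penalty_weight = NULL) {
  model <- match.arg(model)
  pen <- switch(model,
                baseline = character(0),
                visual = "visual_burden",
                mpr = "mpr_burden",
                visual_dichot = "visual_positive",
                mpr_dichot = "mpr_positive")
  cox_model_spec(penalized = pen, penalty_weight = penalty_weight)
}

# stratified fold assignment: spreads events across folds so no training
# fold is event-free; reshuffles (with a message) in the degenerate case
make_folds <- function(event, k) {
  n <- length(event)
  fold <- integer(n)
  for (g in unique(event)) {
    idx <- which(event == g)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  tries <- 0L
  while (any(vapply(seq_len(k), function(f) sum(event[fold != f]),
                    numeric(1)) < 2) && tries < 20L) {
    message("refolding: a training fold had fewer than 2 events")
    idx <- which(event == 1L)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    tries <- tries + 1L
  }
  fold
}

#' Breslow baseline survival
#'
#' Baseline survival at a horizon from the Breslow estimator of the
#' cumulative baseline hazard,
#' `S0(h) = exp(-sum_{t_i <= h} d_i / sum_{j in R(t_i)} exp(lp_j))`.
#'
#' @param time,event Follow-up times and event indicators.
#' @param lp Linear predictor per subject (centred as fitted).
#' @param horizon Evaluation time.
#' @return `S0(horizon)`, a probability.
#' @export
breslow_baseline_survival <- function(time, event, lp, horizon) {
  dtimes <- sort(unique(time[event == 1L & time <= horizon]))
  if (!length(dtimes)) return(1.0)
  elp <- exp(lp)
  haz <- vapply(dtimes, function(td) {
    sum(event == 1L & time == td) / sum(elp[time >= td])
  }, numeric(1))
  exp(-sum(haz))
}

#' Fit an L1-penalized Cox risk classifier
#'
#' Maximizes the Cox partial likelihood with a Lasso penalty restricted to
#' the penalized covariates (`penalty.factor` machinery of glmnet); the
#' established covariates are never shrunk. The penalty weight is chosen
#' on an inner cross-validation loop by partial-likelihood deviance unless
#' fixed in the spec. Penalized covariates shrunk exactly to zero are not
#' retained in the final model specification. When the penalized set is
#' empty the model is an ordinary Cox fit (`survival::coxph`, Efron ties).
#'
#' @param data A `data.frame` with columns `time_days`, `event`, and every
#'   covariate named in `spec`; at least 2 events.
#' @param spec A [cox_model_spec()].
#' @param horizon Horizon (days) at which the Breslow baseline survival is
#'   stored (default 730).
#' @param inner_folds Folds of the inner penalty-selection loop.
#' @param lambda_rule Inner-loop selection rule: `"lambda.1se"` (default;
#'   the sparsest penalty within one standard error of the minimum
#'   cross-validated deviance) or `"lambda.min"`.
#' @return An object of class `fitted_risk_model`: `coefficients` (named,
#'   zeros kept), `retained` (penalized covariates surviving selection),
#'   `lambda`, `baseline_survival` (`S0(horizon)`), `horizon`, `spec`.
#' @export
fit_penalized_cox <- function(data, spec, horizon = 730, inner_folds = 5,
                              lambda_rule = c("lambda.1se", "lambda.min")) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(inherits(spec, "cox_model_spec"))
  covs <- c(spec$unpenalized, spec$penalized)
  miss <- setdiff(c("time_days", "event", covs), names(data))
  if (length(miss)) stop("data missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(data[covs])) stop("missing covariate values")
  if (sum(data$event) < 2) stop("need at least 2 events")

  x <- as.matrix(data[covs])
  storage.mode(x) <- "double"
  y <- survival::Surv(data$time_days, data$event)

  if (length(spec$penalized) == 0L) {
    fml <- stats::as.formula(paste("y ~", paste(covs, collapse = " + ")))
    fit <- survival::coxph(fml, data = cbind(data[covs], y = y))
    beta <- stats::coef(fit)
    lambda <- 0
  } else {
    pf <- c(rep(0, length(spec$unpenalized)), rep(1, length(spec$penalized)))
    if (is.null(spec$penalty_weight)) {
      foldid <- make_folds(data$event, inner_folds)
      cvfit <- glmnet::cv.glmnet(x, y, family = "cox", penalty.factor = pf,
                                 foldid = foldid, type.measure = "deviance",
                                 nlambda = 50)
      lambda <- cvfit[[lambda_rule]]
      beta <- as.numeric(stats::coef(cvfit, s = lambda_rule))
    } else {
      lambda <- spec$penalty_weight
      path <- sort(unique(c(lambda, lambda * 2^(8:1), 0.5)),
                   decreasing = TRUE)
      fit <- glmnet::glmnet(x, y, family = "cox", penalty.factor = pf,
                            lambda = path)
      beta <- as.numeric(stats::coef(fit, s = lambda))
    }
    names(beta) <- covs
  }
  names(beta) <- covs
  lp <- drop(x %*% beta)
  s0 <- breslow_baseline_survival(data$time_days, data$event, lp, horizon)
  structure(list(coefficients = beta,
                 retained = spec$penalized[
                   abs(beta[spec$penalized]) > 1e-12],
                 lambda = lambda, baseline_survival = s0,
                 horizon = horizon, spec = spec),
            class = "fitted_risk_model")
}

#' @export
print.fitted_risk_model <- function(x, ...) {
  cat("<fitted_risk_model>\n  coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  lambda = %.4g, S0(%g d) = %.4f\n",
              x$lambda, x$horizon, x$baseline_survival))
  invisible(x)
}

#' Predicted event probability at the model horizon
#'
#' @param model A [fit_penalized_cox()] result.
#' @param newdata Data frame with the model covariates.
#' @return `1 - S0(horizon)^exp(lp)` per row.
#' @export
predict_event_probability <- function(model, newdata) {
  covs <- names(model$coefficients)
  lp <- as.matrix(newdata[covs]) %*% model$coefficients
  1 - model$baseline_survival^exp(drop(lp))
}

#' Cross-validated out-of-fold survival probabilities
#'
#' Double-loop cross-validation: outer folds yield held-out 2-year event
#' probabilities (`1 - S0(h)^exp(lp)` with the Breslow baseline from the
#' training fold), inner folds select the penalty. Restarts redraw the
#' fold assignment and the final probability is the per-patient average
#' over restarts; all randomness derives from `seed`.
#'
#' @param data As in [fit_penalized_cox()].
#' @param spec A [cox_model_spec()].
#' @param k_folds Outer folds (default 10).
#' @param restarts Fold-assignment restarts (default 25; the study design
#'   uses 500).
#' @param horizon Days (default 730).
#' @param seed Master seed.
#' @param inner_folds Inner folds for penalty selection.
#' @return A list: `prob` (averaged out-of-fold probabilities),
#'   `per_restart` (patients x restarts matrix), `mc_se` (per-patient
#'   Monte-Carlo standard error of the average over restarts).
#' @export
cv_survival_probabilities <- function(data, spec, k_folds = 10,
                                      restarts = 25, horizon = 730,
                                      seed = 1L, inner_folds = 5) {
  if (k_folds < 2) stop("'k_folds' must be >= 2")
  n <- nrow(data)
  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, restarts)
  per <- matrix(NA_real_, n, restarts)
  for (r in seq_len(restarts)) {
    set.seed(restart_seeds[r])
    fold <- make_folds(data$event, k_folds)
    for (f in seq_len(k_folds)) {
      train <- data[fold != f, , drop = FALSE]
      test <- data[fold == f, , drop = FALSE]
      fit <- fit_penalized_cox(train, spec, horizon = horizon,
                               inner_folds = inner_folds)
      per[fold == f, r] <- predict_event_probability(fit, test)
    }
  }
  prob <- rowMeans(per)
  mc_se <- if (restarts > 1)
    apply(per, 1, stats::sd) / sqrt(restarts) else rep(NA_real_, n)
  list(prob = prob, per_restart = per, mc_se = mc_se)
}

# Kaplan-Meier estimate of the censoring survival G(t); returns an
# evaluator with a left-limit option for IPCW weights
censoring_survival <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  st <- c(0, fit$time)
  sv <- c(1, fit$surv)
  function(t, left = FALSE) {
    tt <- if (left) t - 1e-9 else t
    idx <- findInterval(tt, st)
    out <- sv[pmax(idx, 1L)]
    pmax(out, 1e-12)
  }
}

ipcw_case_control <- function(time, event, horizon) {
  G <- censoring_survival(time, event)
  is_case <- event == 1L & time <= horizon
  is_control <- time > horizon
  w <- numeric(length(time))
  w[is_case] <- 1 / G(time[is_case], left = TRUE)
  w[is_control] <- 1 / G(horizon)
  list(case = is_case, control = is_control, w = w)
}

#' Time-dependent ROC curve and AUC at a horizon
#'
#' Cumulative/dynamic AUC with inverse-probability-of-censoring weighting:
#' cases are subjects with an event on or before the horizon, controls are
#' subjects still at risk beyond it; subjects censored before the horizon
#' enter only through the censoring model. With no censoring before the
#' horizon the estimator reduces to the Mann-Whitney statistic over
#' case/control pairs.
#'
#' @param prob Risk scores (out-of-fold probabilities).
#' @param time,event Follow-up and event indicator.
#' @param horizon Days.
#' @return A list of class `cv_roc`: `auc`, `n_cases`, `n_controls`,
#'   `defined` flag, and `roc` (`data.frame` of threshold, fpr, tpr).
#' @export
cv_roc_auc <- function(prob, time, event, horizon = 730) {
  cc <- ipcw_case_control(time, event, horizon)
  nca <- sum(cc$case); nco <- sum(cc$control)
  if (nca == 0L || nco == 0L) {
    return(structure(list(auc = NA_real_, n_cases = nca, n_controls = nco,
                          defined = FALSE, roc = NULL), class = "cv_roc"))
  }
  pc <- prob[cc$case];    wc <- cc$w[cc$case]
  pn <- prob[cc$control]; wn <- cc$w[cc$control]
  cmp <- outer(pc, pn, ">") + 0.5 * outer(pc, pn, "==")
  auc <- drop(wc %*% cmp %*% wn) / (sum(wc) * sum(wn))
  thr <- c(Inf, sort(unique(prob), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(cth) sum(wc[pc > cth]) / sum(wc), numeric(1))
  fpr <- vapply(thr, function(cth) sum(wn[pn > cth]) / sum(wn), numeric(1))
  structure(list(auc = auc, n_cases = nca, n_controls = nco, defined = TRUE,
                 roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "cv_roc")
}

#' Risk categories from predicted probabilities
#'
#' Guideline categories: low (< 1%), intermediate (1% to 3%, both bounds
#' inclusive), high (> 3%). Applied here to 2-year probabilities; an
#' optional scale factor converts to annualized risk before
#' categorization.
#'
#' @param probability Predicted event probabilities.
#' @param cutpoints `c(low, high)` boundaries (default `c(0.01, 0.03)`).
#' @param annualize Scale factor applied to the probability before
#'   categorization (default 1; 0.5 approximates 2-year to per-year).
#' @return Ordered factor with levels `low < intermediate < high`.
#' @export
risk_categorize <- function(probability, cutpoints = c(0.01, 0.03),
                            annualize = 1) {
  p <- probability * annualize
  out <- ifelse(p < cutpoints[1], "low",
                ifelse(p <= cutpoints[2], "intermediate", "high"))
  factor(out, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' Categorical net reclassification improvement and IDI
#'
#' Compares risk categorization under a new model against a baseline
#' model. NRI = [P(up | event) - P(down | event)] +
#' [P(down | nonevent) - P(up | nonevent)]; IDI is the difference in mean
#' predicted probability (new - baseline) among events minus the same
#' among nonevents. Event status at the horizon is weighted by inverse
#' probability of censoring; subjects censored before the horizon drop
#' out through zero weight.
#'
#' @param base_prob,new_prob Predicted probabilities from the two models.
#' @param time,event Follow-up and event indicator.
#' @param horizon Days.
#' @param cutpoints Category boundaries as in [risk_categorize()].
#' @return A list of class `reclassification_metrics`: `nri`, `idi`,
#'   `defined`, component probabilities (`p_up_event`, `p_down_event`,
#'   `p_up_nonevent`, `p_down_nonevent`), and `table` (3x3x2 counts by
#'   event status).
#' @export
categorical_nri <- function(base_prob, new_prob, time, event,
                            horizon = 730, cutpoints = c(0.01, 0.03)) {
  stopifnot(length(base_prob) == length(new_prob))
  cc <- ipcw_case_control(time, event, horizon)
  if (sum(cc$case) == 0L || sum(cc$control) == 0L) {
    return(structure(list(nri = NA_real_, idi = NA_real_, defined = FALSE,
                          table = NULL), class = "reclassification_metrics"))
  }
  cb <- risk_categorize(base_prob, cutpoints)
  cn <- risk_categorize(new_prob, cutpoints)
  up <- as.integer(cn) > as.integer(cb)
  down <- as.integer(cn) < as.integer(cb)

  we <- cc$w * cc$case
  wn <- cc$w * cc$control
  p_up_e <- sum(we[up]) / sum(we)
  p_dn_e <- sum(we[down]) / sum(we)
  p_up_n <- sum(wn[up]) / sum(wn)
  p_dn_n <- sum(wn[down]) / sum(wn)
  nri <- (p_up_e - p_dn_e) + (p_dn_n - p_up_n)

  idi <- (sum(we * (new_prob - base_prob)) / sum(we)) -
    (sum(wn * (new_prob - base_prob)) / sum(wn))

  status <- ifelse(cc$case, "event", ifelse(cc$control, "nonevent", NA))
  keep <- !is.na(status)
  tab <- table(baseline = cb[keep], new = cn[keep], status = status[keep])
  structure(list(nri = nri, idi = idi, defined = TRUE,
                 p_up_event = p_up_e, p_down_event = p_dn_e,
                 p_up_nonevent = p_up_n, p_down_nonevent = p_dn_n,
                 table = tab),
            class = "reclassification_metrics")
}

#' Kaplan-Meier curves by risk stratum
#'
#' Product-limit survival per stratum (e.g. LGE x dichotomized perfusion),
#' via `survival::survfit`.
#'
#' @param time,event Follow-up and event indicator.
#' @param strata Factor (or vector coercible to one) with >= 1 patient per
#'   level.
#' @return A `data.frame` of step-function points: `stratum`, `time`,
#'   `surv`, `n_risk`, `n_event`; every curve starts at 1.0 and is
#'   non-increasing.
#' @export
kaplan_meier_strata <- function(time, event, strata) {
  strata <- factor(strata)
  if (any(table(strata) < 1L)) stop("every stratum needs >= 1 patient")
  d <- data.frame(time = time, event = event, stratum = strata)
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = d)
  lab <- if (is.null(fit$strata)) levels(strata)[1] else
    rep(sub("^stratum=", "", names(fit$strata)), fit$strata)
  out <- data.frame(stratum = lab, time = fit$time, surv = fit$surv,
                    n_risk = fit$n.risk, n_event = fit$n.event,
                    stringsAsFactors = FALSE)
  start <- do.call(rbind, lapply(unique(out$stratum), function(s)
    data.frame(stratum = s, time = 0, surv = 1, n_risk = sum(strata == s),
               n_event = 0, stringsAsFactors = FALSE)))
  res <- rbind(start, out)
  res[order(res$stratum, res$time), ]
}
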