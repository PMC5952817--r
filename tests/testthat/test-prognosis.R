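test_that("linear predictors reproduce the published risk calculators", {
  m <- published_risk_models()
  expect_equal(linear_predictor(m$baseline,
                                c(age = 0, sex = 0, lge = 0)), 0)
  expect_equal(linear_predictor(m$baseline,
                                c(age = 60, sex = 1, lge = 1)), 5.109)
  lp <- linear_predictor(m$mpr_continuous,
                         c(age = 63, sex = 1, lge = 1, mpr_burden = 0.234))
  expect_equal(lp, 0.02 * 63 + 2.722 + 0.678 + 2.490 * 0.234,
               tolerance = 1e-12)
  expect_equal(round(lp, 3), 5.243)
  expect_error(linear_predictor(m$baseline, c(age = 60, sex = 1)),
               "missing covariate")
})

sim_data <- function(n, coefs = c(age = 0.02, sex = 2.722, lge = 0.678,
                                  burden = 2.490), seed = 1,
                     h0 = 0.002) {
  cs <- cohort_spec(n_patients = n, coefficients = coefs,
                    baseline_hazard_rate = h0, rng_seed = seed)
  assemble_risk_data(generate_cohort(cs))
}

test_that("an infinite penalty shrinks only the penalized covariates", {
  d <- sim_data(1500, seed = 2)
  spec_big <- cox_model_spec(penalized = "mpr_burden", penalty_weight = 5)
  fit <- fit_penalized_cox(d, spec_big)
  expect_equal(unname(fit$coefficients["mpr_burden"]), 0)
  expect_length(fit$retained, 0)
  # unpenalized coefficients agree with a plain Cox fit without the covariate
  plain <- survival::coxph(survival::Surv(time_days, event) ~ age + sex + lge,
                           data = d)
  expect_equal(fit$coefficients[c("age", "sex", "lge")], coef(plain),
               tolerance = 0.05)
})

test_that("a vanishing penalty approaches the maximum-likelihood Cox fit", {
  d <- sim_data(2000, seed = 3)
  fit <- fit_penalized_cox(d, cox_model_spec(penalized = "mpr_burden",
                                             penalty_weight = 1e-5))
  full <- survival::coxph(
    survival::Surv(time_days, event) ~ age + sex + lge + mpr_burden, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(full)), tolerance = 0.02)
})

test_that("a pure-noise penalized covariate is selected out", {
  set.seed(44)
  dropped <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    d <- sim_data(2000, seed = 1000 + i)
    d$noise <- rnorm(nrow(d))
    fit <- fit_penalized_cox(d, cox_model_spec(penalized = "noise"))
    if (abs(fit$coefficients["noise"]) < 1e-12) dropped <- dropped + 1L
  }
  expect_gte(dropped / n_rep, 0.9)
})

test_that("Breslow baseline survival matches the survival-package oracle", {
  d <- sim_data(400, seed = 6, h0 = 0.05)
  fit <- survival::coxph(survival::Surv(time_days, event) ~ age + sex + lge,
                         data = d, ties = "breslow")
  lp <- as.matrix(d[c("age", "sex", "lge")]) %*% coef(fit)
  s0 <- breslow_baseline_survival(d$time_days, d$event, drop(lp), 730)
  bh <- survival::basehaz(fit, centered = FALSE)
  s0_oracle <- exp(-max(c(0, bh$hazard[bh$time <= 730])))
  expect_equal(s0, s0_oracle, tolerance = 1e-8)
})

test_that("out-of-fold probabilities are deterministic under a seed", {
  d <- sim_data(400, seed = 7, h0 = 0.05)
  spec <- perfusion_model_spec("baseline")
  a <- cv_survival_probabilities(d, spec, k_folds = 4, restarts = 1, seed = 9)
  b <- cv_survival_probabilities(d, spec, k_folds = 4, restarts = 1, seed = 9)
  expect_identical(a$prob, b$prob)
})

test_that("an uninformative model predicts the marginal event probability", {
  d <- sim_data(1200, seed = 8,
                coefs = c(age = 0, sex = 0, lge = 0, burden = 0), h0 = 0.08)
  cvp <- cv_survival_probabilities(d, perfusion_model_spec("baseline"),
                                   k_folds = 5, restarts = 2, seed = 10)
  km <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = d)
  p_km <- 1 - summary(km, times = 730)$surv
  expect_lt(abs(mean(cvp$prob) - p_km), 0.03)
})

test_that("a strong covariate orders the predicted risks", {
  set.seed(12)
  n <- 800
  x <- rnorm(n)
  lp <- log(5) * x
  t_ev <- rexp(n, 0.0008 * exp(lp))
  t_cn <- rexp(n, 0.001)
  d <- data.frame(age = rnorm(n, 58, 13), sex = rbinom(n, 1, 0.7),
                  lge = rbinom(n, 1, 0.35), x = x,
                  time_days = pmin(t_ev, t_cn, 2000),
                  event = as.integer(t_ev <= pmin(t_cn, 2000)))
  cvp <- cv_survival_probabilities(
    d, cox_model_spec(penalized = "x"), k_folds = 5, restarts = 1, seed = 3)
  expect_gt(cor(x, cvp$prob, method = "spearman"), 0.9)
})

test_that("time-dependent AUC matches pairwise counting without censoring", {
  set.seed(13)
  n <- 300
  time <- sample(100:1500, n, replace = TRUE)
  event <- rep(1L, n)   # no censoring at all
  prob <- runif(n)
  res <- cv_roc_auc(prob, time, event, horizon = 730)
  is_case <- time <= 730
  expect_equal(res$auc, oracle_pairwise_auc(prob, is_case), tolerance = 1e-9)
  # perfect scores separate cases from controls
  perfect <- cv_roc_auc(as.numeric(is_case), time, event, 730)
  expect_equal(perfect$auc, 1.0)
})

test_that("AUC is invariant under monotone transforms of the score", {
  set.seed(14)
  d <- sim_data(600, seed = 14, h0 = 0.05)
  p <- runif(600)
  a1 <- cv_roc_auc(p, d$time_days, d$event, 730)$auc
  a2 <- cv_roc_auc(qlogis(p * 0.98 + 0.01), d$time_days, d$event, 730)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("AUC flags degenerate horizons", {
  res <- cv_roc_auc(runif(50), rep(1000, 50), rep(0L, 50), 730)
  expect_false(res$defined)
  expect_true(is.na(res$auc))
})

test_that("risk categories follow the guideline boundaries", {
  expect_equal(as.character(risk_categorize(0.005)), "low")
  expect_equal(as.character(risk_categorize(0.02)), "intermediate")
  expect_equal(as.character(risk_categorize(0.031)), "high")
  # both boundaries belong to the intermediate band
  expect_equal(as.character(risk_categorize(c(0.01, 0.03))),
               c("intermediate", "intermediate"))
})

test_that("NRI and IDI vanish for identical classifiers and hit the extremes", {
  d <- sim_data(500, seed = 16, h0 = 0.05)
  p <- runif(500, 0, 0.2)
  same <- categorical_nri(p, p, d$time_days, d$event)
  expect_equal(same$nri, 0)
  expect_equal(same$idi, 0)
  # every event up one category, every nonevent down: NRI = 2
  n <- 200
  time <- c(rep(100, 50), rep(1500, 150))
  event <- c(rep(1L, 50), rep(0L, 150))
  base <- rep(0.02, n)                      # everyone intermediate
  new <- c(rep(0.5, 50), rep(0.001, 150))   # events high, nonevents low
  ext <- categorical_nri(base, new, time, event)
  expect_equal(ext$nri, 2)
})

test_that("NRI matches the counting oracle on a constructed 3x3x2 table", {
  # 10 events: 6 reclassified up, 1 down; 20 nonevents: 2 up, 5 down
  ev_base <- rep(0.02, 10)
  ev_new <- c(rep(0.05, 6), 0.005, rep(0.02, 3))
  ne_base <- rep(0.02, 20)
  ne_new <- c(rep(0.05, 2), rep(0.005, 5), rep(0.02, 13))
  time <- c(rep(200, 10), rep(1500, 20))
  event <- c(rep(1L, 10), rep(0L, 20))
  res <- categorical_nri(c(ev_base, ne_base), c(ev_new, ne_new), time, event)
  expect_equal(res$nri, (0.6 - 0.1) + (0.25 - 0.1), tolerance = 1e-12)
  cb <- risk_categorize(c(ev_base, ne_base))
  cn <- risk_categorize(c(ev_new, ne_new))
  expect_equal(res$nri, oracle_counting_nri(cb, cn, event == 1L),
               tolerance = 1e-12)
})

test_that("Kaplan-Meier strata match the risk-set counting oracle", {
  # no events: flat at 1
  flat <- kaplan_meier_strata(rep(500, 10), rep(0L, 10), rep("a", 10))
  expect_true(all(flat$surv == 1))
  # all events at day 100: drop to zero
  drop0 <- kaplan_meier_strata(rep(100, 10), rep(1L, 10), rep("a", 10))
  expect_equal(min(drop0$surv), 0)
  expect_equal(drop0$surv[drop0$time < 100], 1)
  # random small data set against explicit risk-set counting
  set.seed(18)
  time <- sample(1:400, 40, replace = TRUE)
  event <- rbinom(40, 1, 0.6)
  km <- kaplan_meier_strata(time, event, rep("a", 40))
  for (at in c(50, 150, 399)) {
    s_pkg <- min(km$surv[km$time <= at])
    expect_equal(s_pkg, oracle_km(time, event, at), tolerance = 1e-12)
  }
})

test_that("model ranking favours the burden model on informative cohorts", {
  recovered <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    d <- sim_data(2000, seed = 3000 + i)
    pb <- cv_survival_probabilities(d, perfusion_model_spec("baseline"),
                                    k_folds = 4, restarts = 1,
                                    seed = 100 + i)
    pm <- cv_survival_probabilities(d, perfusion_model_spec("mpr"),
                                    k_folds = 4, restarts = 1,
                                    seed = 100 + i)
    ab <- cv_roc_auc(pb$prob, d$time_days, d$event)$auc
    am <- cv_roc_auc(pm$prob, d$time_days, d$event)$auc
    if (am > ab) recovered <- recovered + 1L
  }
  expect_gte(recovered, 18L)
})
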