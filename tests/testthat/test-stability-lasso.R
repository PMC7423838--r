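test_that("stratified_split balances subtype x outcome strata", {
  # one stratum of 9: exact thirds
  sp <- stratified_split(paste0("P", 1:9), rep("NSCLC", 9), rep(0, 9),
                         seed = 1)
  expect_length(sp$train_ids, 6)
  expect_length(sp$validation_ids, 3)
  # strata all divisible by 3: overall split exactly 2/3
  ids <- paste0("P", 1:60)
  subtype <- rep(c("NSCLC", "SCLC"), each = 30)
  outcome <- rep(c(0, 1), 30)
  sp2 <- stratified_split(ids, subtype, outcome, seed = 2)
  expect_length(sp2$train_ids, 40)
  expect_setequal(c(sp2$train_ids, sp2$validation_ids), ids)
  # singleton stratum goes to training with a warning
  expect_warning(
    sp3 <- stratified_split(paste0("P", 1:10), c(rep("a", 9), "b"),
                            rep(0, 10), seed = 3),
    "size 1")
  expect_true("P10" %in% sp3$train_ids)
  # property: per-stratum event counts differ by <= 1 patient from the
  # 2/3 allocation over random cohorts
  set.seed(4)
  for (i in 1:100) {
    n <- sample(30:90, 1)
    ids <- paste0("P", seq_len(n))
    st <- sample(c("x", "y"), n, replace = TRUE)
    y <- rbinom(n, 1, 0.3)
    # random cohorts occasionally produce size-1 strata; the warning is the
    # documented behavior, not a failure
    s <- suppressWarnings(stratified_split(ids, st, y, seed = i))
    for (lab in unique(paste(st, y))) {
      in_str <- paste(st, y) == lab
      n_tr <- sum(ids[in_str] %in% s$train_ids)
      expect_lte(abs(n_tr - 2 / 3 * sum(in_str)), 1)
    }
  }
})

test_that("lasso logistic fit matches its shrinkage and MLE limits", {
  set.seed(31)
  n <- 200
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, plogis(0.4 + 0.9 * X[, 1] - 0.6 * X[, 2]))
  # full-shrinkage limit: slopes 0, intercept = logit(event rate)
  big <- fit_lasso_logistic(X, y, lambda_rule = "fixed", lambda = 5)
  expect_equal(unname(big$coefficients), c(0, 0, 0))
  expect_equal(big$intercept, qlogis(mean(y)), tolerance = 1e-6)
  expect_length(big$selected, 0)
  # lambda = 0 matches the Newton-Raphson MLE oracle
  mle <- newton_logistic(X, y)
  f0 <- fit_lasso_logistic(X, y, lambda_rule = "fixed", lambda = 0)
  expect_equal(unname(c(f0$intercept, f0$coefficients)), unname(mle),
               tolerance = 1e-4)
  # 2x2 closed form: slope = log odds ratio of the table
  x2 <- matrix(c(rep(1, 100), rep(0, 100)), dimnames = list(NULL, "g"))
  y2 <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  f2 <- fit_lasso_logistic(x2, y2, lambda_rule = "fixed", lambda = 0)
  expect_equal(unname(f2$coefficients), log((30 / 70) / (10 / 90)),
               tolerance = 1e-4)
  # degenerate outcome
  expect_error(fit_lasso_logistic(X, rep(1, n)), "single class")
})

test_that("evaluate_auc implements the Mann-Whitney pair statistic", {
  expect_equal(evaluate_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(evaluate_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(evaluate_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(evaluate_auc(1:4, rep(1, 4)), "both classes")
  set.seed(41)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    s <- round(runif(n), 2)  # rounding forces ties
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    a <- evaluate_auc(s, l)
    expect_equal(a, trapezoid_auc(s, l), tolerance = 1e-10)
    # monotone-transform invariance
    expect_equal(a, evaluate_auc(plogis(3 * s - 1), l), tolerance = 1e-12)
  }
})

test_that("bootstrap_ensemble aggregates replicates reproducibly", {
  set.seed(51)
  n <- 90
  X <- cbind(d = rnorm(n), e = rnorm(n), f = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * X[, 1]))
  tr <- 1:60
  ens <- bootstrap_ensemble(X[tr, ], y[tr], X[-tr, ], y[-tr], n_boot = 25,
                            seed = 7, lambda_rule = "fixed", lambda = 0.02)
  # singleton aggregate
  one <- bootstrap_ensemble(X[tr, ], y[tr], X[-tr, ], y[-tr], n_boot = 1,
                            seed = 7, lambda_rule = "fixed", lambda = 0.02)
  expect_equal(one$mean_auc, one$validation_aucs[1])
  # determinism and non-degeneracy
  ens2 <- bootstrap_ensemble(X[tr, ], y[tr], X[-tr, ], y[-tr], n_boot = 25,
                             seed = 7, lambda_rule = "fixed", lambda = 0.02)
  expect_identical(ens$selection_counts, ens2$selection_counts)
  expect_identical(ens$validation_aucs, ens2$validation_aucs)
  ens3 <- bootstrap_ensemble(X[tr, ], y[tr], X[-tr, ], y[-tr], n_boot = 25,
                             seed = 8, lambda_rule = "fixed", lambda = 0.02)
  expect_false(identical(ens$validation_aucs, ens3$validation_aucs))
  # pair-count identities
  expect_equal(unname(diag(ens$pair_counts)),
               unname(ens$selection_counts))
  expect_true(all(ens$pair_counts <=
                    pmin(outer(ens$selection_counts, rep(1, 3)),
                         outer(rep(1, 3), ens$selection_counts))))
  expect_true(all(ens$selection_counts <= ens$n_boot))
  expect_equal(ens$mean_auc, mean(ens$validation_aucs))
  expect_equal(ens$sd_auc, sd(ens$validation_aucs))
})

test_that("degenerate bootstrap resamples are redrawn, keeping n_boot", {
  set.seed(61)
  n <- 14
  X <- cbind(u = rnorm(n), v = rnorm(n))
  y <- c(rep(0, 12), 1, 1)  # rare events: single-class resamples likely
  # tiny event counts make glmnet grumble ("dangerous ground"); that is
  # exactly the regime this test exercises
  ens <- suppressWarnings(
    bootstrap_ensemble(X, y, X, y, n_boot = 30, seed = 2,
                       lambda_rule = "fixed", lambda = 0.05))
  expect_length(ens$validation_aucs, 30)
  expect_gte(ens$degenerate_redraws, 1)
})

test_that("final_model reports bootstrap uncertainty around the full fit", {
  set.seed(71)
  n <- 240
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.8 + 1.1 * X[, 1]))
  tr <- 1:160
  ens <- bootstrap_ensemble(X[tr, ], y[tr], X[-tr, ], y[-tr], n_boot = 60,
                            seed = 5, lambda_rule = "fixed", lambda = 0.01)
  fm <- final_model(X[tr, ], y[tr], ens, seed = 5,
                    lambda_rule = "fixed", lambda = 0.01)
  expect_true("Constant" %in% fm$variable)
  expect_true("a" %in% fm$variable)
  # odds ratio is exp(coefficient) to tight tolerance, CI brackets it
  expect_equal(fm$odds_ratio, exp(fm$coefficient), tolerance = 1e-12)
  sel <- fm$variable != "Constant"
  expect_true(all(fm$ci95_low[sel] <= fm$odds_ratio[sel] + 1e-8 |
                    fm$std[sel] > 0))
  expect_true(all(fm$ci95_low <= fm$ci95_high))
  expect_true(all(fm$std >= 0))
})
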