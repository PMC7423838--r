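#' Stratified train/validation split
#'
#' Splits patients into training and validation sets within each
#' subtype x outcome stratum so both partitions are balanced on cancer
#' subtype and event status. Per stratum the training allocation is the
#' integer nearest to `train_fraction * n` (floor/ceil), so train and
#' validation event prevalences differ by at most one patient per stratum.
#' Strata of size 1 go to training with a warning. Deterministic given the
#' seed.
#'
#' @param ids patient identifiers.
#' @param subtype cancer subtype labels.
#' @param outcome binary event indicator (grade >= 2).
#' @param train_fraction training fraction (default 2/3).
#' @param seed integer seed.
#' @return list with `train_ids`, `validation_ids`, `strata` (data.frame).
#' @export
stratified_split <- function(ids, subtype, outcome, train_fraction = 2 / 3,
                             seed = 1L) {
  stopifnot(length(ids) == length(subtype),
            length(ids) == length(outcome))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_param("train_fraction must lie in (0, 1)")
  strata <- paste(subtype, as.integer(outcome >= 1 | outcome == TRUE),
                  sep = ":")
  train <- character(0)
  with_seed(seed, {
    for (st in sort(unique(strata))) {
      members <- ids[strata == st]
      n <- length(members)
      if (n == 1) {
        warning("stratum of size 1 (", st, ") assigned to training",
                call. = FALSE)
        train <- c(train, members)
        next
      }
      n_train <- round(train_fraction * n)
      n_train <- max(1L, min(n - 1L, n_train))
      train <- c(train, sample(members, n_train))
    }
  })
  list(train_ids = sort(train),
       validation_ids = sort(setdiff(ids, train)),
       strata = data.frame(patient_id = ids, stratum = strata,
                           stringsAsFactors = FALSE))
}

#' LASSO-penalized logistic regression
#'
#' L1-penalized logistic fit via coordinate descent (glmnet backend).
#' Predictors are standardized internally to mean 0 / unit variance using
#' the supplied (training) data, the penalty applies on the standardized
#' scale, and coefficients are reported back on the original feature scale;
#' the intercept is unpenalized. The penalty weight is chosen by the
#' configured rule: 5-fold cross-validated binomial deviance minimum with
#' seeded fold assignment (default), or a fixed value.
#'
#' @param X numeric matrix or data.frame of predictors (training rows).
#' @param y binary outcome vector.
#' @param lambda_rule `"cv"` (default) or `"fixed"`.
#' @param lambda fixed penalty weight (required for `"fixed"`; a value of 0
#'   gives the unpenalized maximum-likelihood fit).
#' @param nfolds cross-validation folds (default 5).
#' @param seed seed for the fold assignment.
#' @param selection_tol |coefficient| above which a feature counts as
#'   selected (default 1e-8, on the original scale).
#' @return object of class `lasso_fit`: list with `coefficients` (named,
#'   original scale), `intercept`, `lambda`, `selected`, `center`, `scale`.
#' @export
fit_lasso_logistic <- function(X, y, lambda_rule = c("cv", "fixed"),
                               lambda = NULL, nfolds = 5, seed = 1L,
                               selection_tol = 1e-8) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop_param("outcome has a single class; logistic fit is degenerate")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- scl > 0
  if (!any(keep)) stop_param("all predictors are constant")
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, center[keep]), 2, scl[keep],
             "/")
  fit_at <- function(lam) {
    # glmnet needs >= 2 columns; a constant dummy always gets coefficient 0
    Zf <- if (ncol(Z) == 1) cbind(Z, .dummy = 0) else Z
    # glmnet wants a decreasing path; land exactly on the requested lambda
    lam_max <- max(abs(crossprod(Zf, y - mean(y)))) / length(y)
    path <- sort(unique(c(exp(seq(log(max(lam_max, lam + 1e-3, 1e-3)),
                                  log(max(lam, 1e-5)), length.out = 50)),
                          lam)), decreasing = TRUE)
    if (lam == 0) path <- c(path[path > 0], 0)
    g <- glmnet::glmnet(Zf, y, family = "binomial", alpha = 1,
                        lambda = path, standardize = FALSE,
                        thresh = 1e-12, maxit = 1e6)
    # lambda.interp's "collapsing to unique 'x' values" is benign here: the
    # requested lambda is always a member of the fitted path
    co <- suppressWarnings(
      as.numeric(stats::coef(g, s = lam, exact = FALSE)))
    if (ncol(Z) == 1) co <- co[1:2]
    co
  }
  if (lambda_rule == "cv") {
    if (ncol(Z) < 2) {
      # cv.glmnet needs >= 2 columns; fall back to a tiny fixed penalty
      lam <- 1e-4
    } else {
      lam <- with_seed(seed, {
        foldid <- sample(rep(seq_len(nfolds), length.out = length(y)))
        cv <- glmnet::cv.glmnet(Z, y, family = "binomial", alpha = 1,
                                foldid = foldid, standardize = FALSE,
                                type.measure = "deviance")
        cv$lambda.min
      })
    }
  } else {
    if (is.null(lambda) || lambda < 0)
      stop_param("fixed lambda_rule needs lambda >= 0")
    lam <- lambda
  }
  co <- fit_at(lam)
  beta_std <- co[-1]
  beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
  beta[keep] <- beta_std / scl[keep]
  intercept <- co[1] - sum(beta_std * center[keep] / scl[keep])
  selected <- names(beta)[abs(beta) > selection_tol]
  structure(list(coefficients = beta, intercept = intercept, lambda = lam,
                 selected = selected, center = center, scale = scl),
            class = "lasso_fit")
}

#' Linear predictor / risk score of a LASSO fit
#'
#' @param object a `lasso_fit`.
#' @param newdata matrix or data.frame with the fit's feature columns.
#' @param type `"link"` (linear predictor) or `"response"` (probability).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.lasso_fit <- function(object, newdata, type = c("link", "response"),
                              ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, names(object$coefficients), drop = FALSE])
  lp <- object$intercept + as.numeric(X %*% object$coefficients)
  if (type == "response") stats::plogis(lp) else lp
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Fraction of positive-negative pairs in which the positive scores higher,
#' ties counted one half. Invariant under monotone transforms of the score.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (1 = event).
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  pos <- labels == 1
  if (!any(pos) || all(pos))
    stop_param("AUC undefined: both classes must be present")
  r <- rank(scores)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap LASSO stability-selection ensemble
#'
#' Repeats `n_boot` times: resample the training patients with replacement
#' (same n), fit a LASSO logistic model on the resample, score the fixed
#' validation set, and record the validation AUC, the selected feature set,
#' and the coefficient vector. Resamples whose outcome is single-class are
#' redrawn (count logged in `degenerate_redraws`), keeping `n_boot` fixed.
#' Selection counts, pairwise co-selection counts and AUC summaries are
#' aggregated. Fully reproducible given the seed.
#'
#' @param X_train,y_train training predictors and binary outcome.
#' @param X_val,y_val validation predictors and outcome.
#' @param n_boot bootstrap replicates (the reference analysis uses 1000).
#' @param seed integer master seed.
#' @param lambda_rule,lambda,nfolds passed to [fit_lasso_logistic()].
#' @return object of class `bootstrap_ensemble`: list with `coef_matrix`
#'   (features x n_boot, original scale), `intercepts`, `lambdas`,
#'   `validation_aucs`, `mean_auc`, `sd_auc`, `selection_counts`,
#'   `pair_counts` (features x features symmetric; diagonal = selection
#'   counts), `n_boot`, `seed`, `degenerate_redraws`.
#' @export
bootstrap_ensemble <- function(X_train, y_train, X_val, y_val,
                               n_boot = 1000, seed = 1L,
                               lambda_rule = "cv", lambda = NULL,
                               nfolds = 5) {
  X_train <- as.matrix(X_train)
  X_val <- as.matrix(X_val[, colnames(X_train), drop = FALSE])
  n <- nrow(X_train)
  p <- ncol(X_train)
  feats <- colnames(X_train)
  coef_matrix <- matrix(0, p, n_boot, dimnames = list(feats, NULL))
  intercepts <- numeric(n_boot)
  lambdas <- numeric(n_boot)
  aucs <- numeric(n_boot)
  sel <- matrix(FALSE, p, n_boot, dimnames = list(feats, NULL))
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        # at least two observations of each class, the minimum the
        # coordinate-descent backend accepts
        if (min(tabulate(y_train[idx] + 1L, 2L)) >= 2L) break
        redraws <- redraws + 1L
      }
      fit <- fit_lasso_logistic(X_train[idx, , drop = FALSE], y_train[idx],
                                lambda_rule = lambda_rule, lambda = lambda,
                                nfolds = nfolds,
                                seed = sample.int(2^30, 1))
      coef_matrix[, b] <- fit$coefficients[feats]
      intercepts[b] <- fit$intercept
      lambdas[b] <- fit$lambda
      sel[, b] <- feats %in% fit$selected
      aucs[b] <- evaluate_auc(
        fit$intercept + as.numeric(X_val %*% fit$coefficients[feats]),
        y_val)
    }
  })
  pair_counts <- sel %*% t(sel)
  structure(list(coef_matrix = coef_matrix, intercepts = intercepts,
                 lambdas = lambdas, validation_aucs = aucs,
                 mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
                 selection_counts = rowSums(sel),
                 pair_counts = pair_counts, n_boot = n_boot, seed = seed,
                 degenerate_redraws = redraws),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_ensemble> %d replicates, %d features, AUC %.3f (SD %.3f)\n",
    x$n_boot, nrow(x$coef_matrix), x$mean_auc, x$sd_auc))
  invisible(x)
}

#' Final model on the full training data
#'
#' One LASSO logistic fit on the full (non-resampled) training data. For
#' each retained variable the table reports the coefficient, a bootstrap
#' standard error (SD of that coefficient across the ensemble, zeros
#' included), the odds ratio `exp(coefficient)` and a 95% percentile CI of
#' the bootstrap coefficient distribution mapped through `exp`. The
#' intercept appears as `"Constant"` with its bootstrap spread.
#'
#' @param X_train,y_train full training predictors and outcome.
#' @param ensemble a [bootstrap_ensemble()] fitted on the same features.
#' @param seed seed for the lambda cross-validation.
#' @param lambda_rule,lambda,nfolds passed to [fit_lasso_logistic()].
#' @return data.frame (variable, coefficient, std, odds_ratio, ci95_low,
#'   ci95_high); attribute `"fit"` carries the underlying `lasso_fit`.
#' @export
final_model <- function(X_train, y_train, ensemble, seed = 1L,
                        lambda_rule = "cv", lambda = NULL, nfolds = 5) {
  fit <- fit_lasso_logistic(X_train, y_train, lambda_rule = lambda_rule,
                            lambda = lambda, nfolds = nfolds, seed = seed)
  vars <- fit$selected
  if (length(vars) == 0)
    warning("LASSO retained no variables; intercept-only model",
            call. = FALSE)
  rows <- lapply(vars, function(v) {
    boot <- ensemble$coef_matrix[v, ]
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(variable = v, coefficient = fit$coefficients[[v]],
               std = stats::sd(boot),
               odds_ratio = exp(fit$coefficients[[v]]),
               ci95_low = exp(ci[1]), ci95_high = exp(ci[2]),
               stringsAsFactors = FALSE)
  })
  ci0 <- stats::quantile(ensemble$intercepts, c(0.025, 0.975),
                         names = FALSE, type = 7)
  rows <- c(rows, list(data.frame(
    variable = "Constant", coefficient = fit$intercept,
    std = stats::sd(ensemble$intercepts), odds_ratio = exp(fit$intercept),
    ci95_low = exp(ci0[1]), ci95_high = exp(ci0[2]),
    stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}
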