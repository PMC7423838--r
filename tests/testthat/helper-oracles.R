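# Independent oracles used by the unit and acceptance suites. These stay
# deliberately naive: brute force, closed forms, textbook algorithms.

# Unpenalized logistic MLE via Newton-Raphson (IRLS)
newton_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  X1 <- cbind(1, as.matrix(X))
  b <- rep(0, ncol(X1))
  for (i in seq_len(maxit)) {
    p <- stats::plogis(as.numeric(X1 %*% b))
    w <- p * (1 - p)
    step <- solve(crossprod(X1, X1 * w), crossprod(X1, y - p))
    b <- b + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  stats::setNames(b, c("(Intercept)", colnames(X)))
}

# AUC by trapezoidal integration of the empirical ROC curve
trapezoid_auc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1))
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Dose at volume fraction by scanning a fine uniform grid (bin width in Gy)
brute_force_dx <- function(curve, x, step = 0.01) {
  grid <- seq(0, max(curve$dose_bins), by = step)
  v <- stats::approx(curve$dose_bins, curve$volume_fractions, xout = grid,
                     rule = 2)$y
  target <- x / 100
  i0 <- max(which(v >= 1 - 1e-12))
  if (target >= v[i0] - 1e-12) return(grid[i0])
  hit <- which(v <= target + 1e-12)[1]
  # curve never falls to the target: max dose, same convention as the package
  if (is.na(hit)) grid[length(grid)] else grid[hit]
}

# Connected components of the graph "pairwise |r| > threshold"
connected_components <- function(corr, threshold) {
  n <- nrow(corr)
  adj <- abs(corr) > threshold
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  stats::setNames(match(comp, unique(comp)), rownames(corr))
}

# Random plausible cumulative DVH on an irregular grid (consumes global RNG)
random_dvh <- function(patient_id = "P1", structure = "test",
                       max_dose = stats::runif(1, 20, 80)) {
  n <- sample(20:60, 1)
  d <- sort(c(0, stats::runif(n - 2, 0, max_dose), max_dose))
  d <- unique(round(d, 4))
  v <- sort(stats::runif(length(d) - 1, 0, 1), decreasing = TRUE)
  v <- c(1, v * stats::runif(1, 0.3, 1))
  if (length(v) > 2 && stats::runif(1) < 0.5) v[length(v)] <- 0
  dvh_curve(patient_id, structure, d, v)
}

# Small synthetic cohort spec used across tests (cheap dose grid)
small_cohort_spec <- function(n = 80, seed = 421, bin_width = 0.5, ...) {
  cohort_spec(n_patients = n, seed = seed, bin_width = bin_width, ...)
}

# The parameter-recovery world: one conventional schedule, two dosimetric
# drivers with published-range discrimination (oracle AUC ~0.8), six null
# features, 30% prevalence.
recovery_spec <- function(n = 600, seed = 1234) {
  menu <- data.frame(label = "conv60", total_dose_gy = 60,
                     fraction_number = 30L, treatment_days = 40L,
                     sbrt = FALSE, prob = 1)
  om <- list(recovery = list(
    endpoint = "recovery",
    coefficients = c(esophagus_D40 = 0.4, lung_minus_gtv_D15 = 0.45),
    intercept = NULL, target_rate = 0.30,
    event_grade_probs = c(`2` = 1), nonevent_grade_probs = c(`0` = 1)))
  cohort_spec(n_patients = n, seed = seed, fractionation_menu = menu,
              outcome_models = om, bin_width = 0.5)
}
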