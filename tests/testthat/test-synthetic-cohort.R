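test_that("sample_dvh_curve produces valid curves with the stated limits", {
  fx <- list(total_dose_gy = 60)
  # steep limit with full coverage: step function at the prescription
  step_shape <- list(prescription_dose = 60, falloff_steepness = 1e4,
                     coverage_fraction = 1, midpoint_sdlog = 0,
                     steepness_sdlog = 0)
  cv <- with_seed(1, sample_dvh_curve("P1", "s", step_shape, fx,
                                      bin_width = 0.5))
  expect_equal(cv$volume_fractions[cv$dose_bins <= 59], rep(1, 119))
  expect_equal(cv$volume_fractions[cv$dose_bins >= 61],
               rep(0, sum(cv$dose_bins >= 61)))
  # V(0) = 1 exactly for arbitrary valid parameters
  set.seed(5)
  for (i in 1:20) {
    sh <- list(prescription_dose = runif(1, 20, 70),
               falloff_steepness = runif(1, 0.5, 6),
               coverage_fraction = runif(1),
               midpoint_sdlog = 0.2, steepness_sdlog = 0.2)
    cv <- sample_dvh_curve("P1", "s", sh,
                           list(total_dose_gy = sh$prescription_dose),
                           bin_width = 1)
    expect_identical(cv$volume_fractions[1], 1)
    expect_lte(max(cv$dose_bins), 1.2 * sh$prescription_dose + 1e-9)
  }
  # sigmoid family, coverage 0.5, no jitter: the dose at V = 0.5 equals the
  # analytic inversion of the normalized generating sigmoid (close to, but
  # because of the [0, Dmax] normalization not exactly, the raw midpoint)
  sh <- list(prescription_dose = 60, falloff_steepness = 4,
             coverage_fraction = 0.5, midpoint_sdlog = 0,
             steepness_sdlog = 0)
  cv <- sample_dvh_curve("P1", "s", sh, fx, bin_width = 0.05)
  m <- 30; s <- 60 / 4; dmax <- 72
  sig <- function(d) 1 / (1 + exp((d - m) / s))
  vfun <- function(d) (sig(d) - sig(dmax)) / (sig(0) - sig(dmax))
  analytic <- uniroot(function(d) vfun(d) - 0.5, c(0, dmax),
                      tol = 1e-10)$root
  expect_equal(dose_at_volume(cv, 50), analytic, tolerance = 0.06)
  expect_equal(analytic, m, tolerance = 0.05 * m)
  # parameter errors
  bad <- list(prescription_dose = -1, falloff_steepness = 2,
              coverage_fraction = 0.5)
  expect_error(sample_dvh_curve("P1", "s", bad, fx), "positive")
})

test_that("generated DVHs are monotone and bounded over random draws", {
  set.seed(77)
  for (i in 1:1000) {
    sh <- list(prescription_dose = runif(1, 15, 80),
               falloff_steepness = runif(1, 0.3, 8),
               coverage_fraction = runif(1),
               midpoint_sdlog = runif(1, 0, 0.4),
               steepness_sdlog = runif(1, 0, 0.4))
    cv <- sample_dvh_curve("P1", "s", sh,
                           list(total_dose_gy = sh$prescription_dose),
                           bin_width = 2)
    v <- cv$volume_fractions
    expect_true(all(v >= 0 & v <= 1) && all(diff(v) <= 1e-12))
  }
})

test_that("sample_clinical reproduces the configured marginals", {
  dists <- default_clinical_dists()
  menu <- default_fractionation_menu()
  draw <- function(n, d) {
    with_seed(2024, do.call(rbind, lapply(seq_len(n), function(i)
      sample_clinical(paste0("P", i), d, menu))))
  }
  big <- draw(10000, dists)
  # A2M median within 5% of the configured 191 mg/dL
  expect_lt(abs(stats::median(big$a2m_mg_dl) - 191) / 191, 0.05)
  # smoking-category frequencies converge to the configured probabilities
  freq <- prop.table(table(factor(big$smoking_status,
                                  c("never", "former", "current"))))
  expect_lt(max(abs(as.numeric(freq) - c(0.182, 0.694, 0.124))), 0.02)
  # smokers carry higher A2M under the default upward shift
  med <- tapply(big$a2m_mg_dl, big$smoking_status, median)
  expect_gt(med[["current"]], med[["never"]])
  expect_gt(med[["former"]], med[["never"]])
  # null case: zero shift makes the strata indistinguishable
  d0 <- dists
  d0$a2m$shift_former <- 0
  d0$a2m$shift_current <- 0
  nul <- draw(6000, d0)
  p <- wilcoxon_rank_sum(nul$a2m_mg_dl[nul$smoking_status == "never"],
                         nul$a2m_mg_dl[nul$smoking_status != "never"])$p
  expect_gt(p, 0.01)
  # schedule sanity from the menu
  expect_true(all(big$treatment_days >= big$fraction_number))
})

test_that("assign_outcomes follows the logistic ground truth", {
  set.seed(9)
  n <- 20000
  feats <- data.frame(z = rnorm(n))
  # all beta = 0, intercept = logit(0.2): event rate converges to 0.2
  m0 <- list(coefficients = c(z = 0), intercept = qlogis(0.2),
             event_grade_probs = c(`2` = 0.9, `3` = 0.1),
             nonevent_grade_probs = c(`0` = 0.8, `1` = 0.2))
  r0 <- with_seed(3, assign_outcomes(feats, m0))
  expect_lt(abs(mean(r0$grades >= 2) - 0.2), 0.015)
  expect_true(all(r0$grades %in% 0:3))
  # intercept -> -Inf: no events at all
  mneg <- m0; mneg$intercept <- -50
  expect_true(all(with_seed(3, assign_outcomes(feats, mneg))$grades < 2))
  # huge positive beta: events concentrate at the top of the feature
  mbig <- m0; mbig$coefficients <- c(z = 25); mbig$intercept <- 0
  rbig <- with_seed(3, assign_outcomes(feats, mbig))
  expect_gt(cor(rank(feats$z), rank(as.numeric(rbig$grades >= 2))), 0.85)
  # target_rate route solves the intercept
  mt <- m0; mt$intercept <- NULL; mt$target_rate <- 0.35
  rt <- with_seed(3, assign_outcomes(feats, mt))
  expect_equal(mean(rt$prob), 0.35, tolerance = 1e-8)
  # missing truth feature is a configuration error
  mmiss <- m0; mmiss$coefficients <- c(nope = 1)
  expect_error(assign_outcomes(feats, mmiss), "missing from feature table")
})

test_that("generate_cohort is deterministic and correctly sized", {
  sp <- cohort_spec(n_patients = 258, seed = 314, bin_width = 1)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$grades, b$grades)
  expect_identical(a$dvhs, b$dvhs)
  expect_identical(nrow(a$clinical), 258L)
  expect_identical(length(a$dvhs), 258L * 3L)
  expect_true(all(a$grades$esophagitis %in% 0:5))
  expect_true(all(a$grades$pneumonitis %in% 0:5))
  # different seeds give different draws
  c2 <- generate_cohort(cohort_spec(n_patients = 258, seed = 315,
                                    bin_width = 1))
  expect_false(identical(a$clinical$a2m_mg_dl, c2$clinical$a2m_mg_dl))
  # caller RNG state is untouched
  set.seed(1); before <- .Random.seed
  invisible(generate_cohort(small_cohort_spec(n = 12)))
  expect_identical(before, .Random.seed)
})

test_that("adjacent Dx metrics are collinear in a default cohort", {
  co <- generate_cohort(small_cohort_spec(n = 200, seed = 88))
  ft <- build_feature_table(co$dvhs, co$clinical, co$grades,
                            bin_width = 0.5)
  for (pair in list(c("esophagus_D25", "esophagus_D30"),
                    c("lung_minus_gtv_D25", "lung_minus_gtv_D30"),
                    c("heart_D45", "heart_D50"))) {
    expect_gt(cor(ft[[pair[1]]], ft[[pair[2]]]), 0.75)
  }
})

test_that("cohort_spec rejects invalid configurations", {
  expect_error(cohort_spec(n_patients = 5), "n_patients")
  bad_menu <- default_fractionation_menu()
  bad_menu$treatment_days[1] <- 10
  expect_error(cohort_spec(fractionation_menu = bad_menu),
               "treatment_days")
  bad_dists <- default_clinical_dists()
  bad_dists$smoking_probs <- c(never = 0.5, former = 0.6, current = 0.1)
  expect_error(cohort_spec(clinical_dists = bad_dists), "sum to 1")
  bad_shapes <- default_dvh_shapes()
  bad_shapes$heart$coverage_fraction <- 1.4
  expect_error(cohort_spec(dvh_shapes = bad_shapes), "coverage_fraction")
})

test_that("default endpoint prevalences land on their targets at n = 10,000", {
  # one large draw; coarse 2 Gy dose grid, which leaves the Bernoulli
  # outcome layer (what this invariant is about) untouched
  co <- generate_cohort(cohort_spec(n_patients = 10000, seed = 5,
                                    bin_width = 2))
  expect_lt(abs(mean(co$grades$esophagitis >= 2) - 0.236), 0.03)
  expect_lt(abs(mean(co$grades$pneumonitis >= 2) - 0.140), 0.03)
  # grade split among esophagitis events follows the configured proportions
  g <- co$grades$esophagitis[co$grades$esophagitis >= 2]
  expect_equal(mean(g == 2), 53 / 61, tolerance = 0.05)
})
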