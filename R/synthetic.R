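#' Default fractionation menu
#'
#' Discrete set of treatment schedules mixing conventional fractionation
#' (2 Gy/fraction, treatment days spanning weekends) and SBRT (few large
#' fractions). Medians of the menu reproduce typical conventional (54 Gy)
#' and SBRT (50 Gy) prescriptions.
#'
#' @return data.frame with columns `label`, `total_dose_gy`,
#'   `fraction_number`, `treatment_days`, `sbrt`, `prob`.
#' @export
default_fractionation_menu <- function() {
  data.frame(
    label = c("conv60", "conv54", "sbrt50"),
    total_dose_gy = c(60, 54, 50),
    fraction_number = c(30L, 27L, 5L),
    treatment_days = c(40L, 37L, 10L),
    sbrt = c(FALSE, FALSE, TRUE),
    prob = c(0.30, 0.35, 0.35),
    stringsAsFactors = FALSE)
}

#' Default clinical covariate distributions
#'
#' Marginals emulating a thoracic radiotherapy cohort: age ~ N(68, 10)
#' truncated to 25-93 y; 52.7% female; KPS on the 50-100 scale peaked at 90;
#' never/former/current smoking 18.2/69.4/12.4%; pack-years lognormal
#' (median 37) for ever-smokers; serum alpha-2-macroglobulin (A2M) lognormal
#' with overall median 191 mg/dL and multiplicative upward shifts for former
#' and current smokers (targeting group means near 185/207/217 mg/dL);
#' chemotherapy timing concurrent/sequential/none 23.2/28.7/48.1%; cancer
#' subtype mix dominated by NSCLC.
#'
#' @return named list of distribution parameters.
#' @export
default_clinical_dists <- function() {
  list(
    age = list(mean = 68, sd = 10, min = 25, max = 93),
    p_female = 0.527,
    kps = list(values = seq(50, 100, by = 10),
               probs = c(0.02, 0.03, 0.10, 0.25, 0.40, 0.20)),
    smoking_probs = c(never = 0.182, former = 0.694, current = 0.124),
    pack_years = list(meanlog = log(37), sdlog = 0.8, min = 1, max = 204),
    a2m = list(median = 191, sdlog = 0.34,
               shift_former = log(207.3 / 185.4),
               shift_current = log(217.3 / 185.4)),
    chemo_probs = c(concurrent = 0.232, sequential = 0.287, none = 0.481),
    subtype_probs = c(NSCLC = 0.783, SCLC = 0.066, thymoma = 0.031,
                      mesothelioma = 0.097, lung_metastases = 0.023))
}

#' Default per-structure DVH shape parameters
#'
#' Scaled logistic sigmoid family: the cumulative volume fraction follows a
#' normalized logistic falloff in dose with midpoint
#' `coverage_fraction * prescription` and steepness `falloff_steepness`
#' (dimensionless; the dose scale of the falloff is
#' `prescription / falloff_steepness`). Target-adjacent esophagus gets higher
#' coverage and steeper falloff than the largely spared lung and heart.
#'
#' @return named list per structure with `prescription_dose`,
#'   `falloff_steepness`, `coverage_fraction`, `midpoint_sdlog`,
#'   `steepness_sdlog` (patient-level lognormal jitter), and
#'   `sbrt_coverage_scale` (multiplier on the coverage fraction for SBRT
#'   plans — tightly conformal few-fraction plans spare organs at risk far
#'   more than conventional fields do).
#' @export
default_dvh_shapes <- function() {
  list(
    esophagus = list(prescription_dose = 60, falloff_steepness = 2.5,
                     coverage_fraction = 0.45, midpoint_sdlog = 0.15,
                     steepness_sdlog = 0.20, sbrt_coverage_scale = 0.35),
    lung_minus_gtv = list(prescription_dose = 60, falloff_steepness = 1.8,
                          coverage_fraction = 0.18, midpoint_sdlog = 0.20,
                          steepness_sdlog = 0.20,
                          sbrt_coverage_scale = 0.35),
    heart = list(prescription_dose = 60, falloff_steepness = 2.0,
                 coverage_fraction = 0.25, midpoint_sdlog = 0.20,
                 steepness_sdlog = 0.20, sbrt_coverage_scale = 0.35))
}

#' Default ground-truth outcome models
#'
#' Logistic models over named features generating binary grade >= 2 events,
#' with grade splits conditional on event status. Target prevalences are
#' 23.6% (esophagitis) and 14.0% (pneumonitis); event grades split
#' 53:8 (grade 2:3) for esophagitis and 26:9:1 (2:3:4) for pneumonitis.
#' The intercept is solved at generation time so that the mean event
#' probability over the realized cohort equals `target_rate`.
#'
#' @return named list of outcome-model specifications.
#' @export
default_outcome_models <- function() {
  list(
    esophagitis = list(
      endpoint = "esophagitis",
      coefficients = c(esophagus_D50 = 0.12, treatment_days = 0.05,
                       chemo = 0.8, a2m_mg_dl = -0.004, age = -0.03),
      intercept = NULL,
      target_rate = 0.236,
      event_grade_probs = c(`2` = 53, `3` = 8, `4` = 0) / 61,
      nonevent_grade_probs = c(`0` = 0.8, `1` = 0.2)),
    pneumonitis = list(
      endpoint = "pneumonitis",
      coefficients = c(lung_minus_gtv_D15 = 0.06, heart_max = 0.02,
                       treatment_days = 0.02, sex_female = 0.8),
      intercept = NULL,
      target_rate = 0.140,
      event_grade_probs = c(`2` = 26, `3` = 9, `4` = 1) / 36,
      nonevent_grade_probs = c(`0` = 0.85, `1` = 0.15)))
}

#' Specify a synthetic cohort
#'
#' Bundles and validates everything the generator needs: cohort size, seed,
#' structures with DVH shape parameters, clinical covariate distributions,
#' the fractionation menu, and ground-truth outcome models.
#'
#' @param n_patients cohort size (>= 10; default 258).
#' @param seed integer seed (default 20200806).
#' @param structures named list of alpha/beta ratios per structure
#'   (default esophagus 10, lung_minus_gtv 3, heart 3).
#' @param dvh_shapes per-structure shape parameters
#'   ([default_dvh_shapes()]).
#' @param clinical_dists clinical distributions
#'   ([default_clinical_dists()]).
#' @param fractionation_menu schedule menu
#'   ([default_fractionation_menu()]).
#' @param outcome_models ground-truth logistic models
#'   ([default_outcome_models()]).
#' @param bin_width DVH dose-grid width in Gy (default 0.1).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 258,
                        seed = 20200806,
                        structures = c(esophagus = 10, lung_minus_gtv = 3,
                                       heart = 3),
                        dvh_shapes = default_dvh_shapes(),
                        clinical_dists = default_clinical_dists(),
                        fractionation_menu = default_fractionation_menu(),
                        outcome_models = default_outcome_models(),
                        bin_width = 0.1) {
  if (!is.numeric(n_patients) || n_patients < 10)
    stop_param("n_patients must be >= 10")
  if (is.null(names(structures)) || any(structures <= 0))
    stop_param("structures must be a named vector of positive alpha/beta")
  missing_shapes <- setdiff(names(structures), names(dvh_shapes))
  if (length(missing_shapes))
    stop_param("missing dvh_shapes for: ",
               paste(missing_shapes, collapse = ", "))
  for (s in names(structures)) {
    sh <- dvh_shapes[[s]]
    if (sh$prescription_dose <= 0 || sh$falloff_steepness <= 0)
      stop_param("non-positive DVH shape parameter for structure ", s)
    if (sh$coverage_fraction < 0 || sh$coverage_fraction > 1)
      stop_param("coverage_fraction must lie in [0, 1] for structure ", s)
  }
  for (p in list(clinical_dists$smoking_probs, clinical_dists$chemo_probs,
                 clinical_dists$subtype_probs, clinical_dists$kps$probs,
                 fractionation_menu$prob)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop_param("categorical probabilities must be in [0,1] and sum to 1")
  }
  if (any(fractionation_menu$treatment_days <
          fractionation_menu$fraction_number))
    stop_param("treatment_days must be >= fraction_number in every menu entry")
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         structures = structures, dvh_shapes = dvh_shapes,
         clinical_dists = clinical_dists,
         fractionation_menu = fractionation_menu,
         outcome_models = outcome_models, bin_width = bin_width),
    class = "cohort_spec")
}

#' Sample one synthetic cumulative DVH
#'
#' Normalized logistic sigmoid in dose: with midpoint
#' `m = coverage_fraction * prescription` (lognormal patient jitter),
#' steepness scale `s = prescription / falloff_steepness`, and maximum dose
#' `1.2 * prescription`, the curve is
#' `V(D) = (sig(D) - sig(Dmax)) / (sig(0) - sig(Dmax))` with
#' `sig(D) = 1 / (1 + exp((D - m)/s))`, giving V(0) = 1 exactly, a smooth
#' monotone falloff, and V = 0 at the maximum dose. In the limit of infinite
#' steepness with coverage 1 this is a step function at the prescription.
#' Consumes the global RNG stream (seed it, e.g. via [generate_cohort()]).
#'
#' @param patient_id patient identifier.
#' @param structure structure name.
#' @param shape shape parameter list (see [default_dvh_shapes()]).
#' @param fractionation one row of the fractionation menu; its
#'   `total_dose_gy` is used as the prescription dose.
#' @param bin_width dose grid width in Gy.
#' @return a physical-dose [dvh_curve()].
#' @export
sample_dvh_curve <- function(patient_id, structure, shape, fractionation,
                             bin_width = 0.1) {
  if (shape$prescription_dose <= 0 || shape$falloff_steepness <= 0)
    stop_param("DVH shape parameters must be positive")
  rx <- fractionation$total_dose_gy %||% shape$prescription_dose
  cov_frac <- shape$coverage_fraction
  if (isTRUE(fractionation$sbrt))
    cov_frac <- cov_frac * (shape$sbrt_coverage_scale %||% 1)
  m <- cov_frac * rx *
    exp(stats::rnorm(1, 0, shape$midpoint_sdlog %||% 0))
  k <- shape$falloff_steepness *
    exp(stats::rnorm(1, 0, shape$steepness_sdlog %||% 0))
  s <- rx / k
  dmax <- 1.2 * rx
  grid <- seq(0, dmax, by = bin_width)
  if (grid[length(grid)] < dmax) grid <- c(grid, dmax)
  sig <- function(d) 1 / (1 + exp((d - m) / s))
  v <- (sig(grid) - sig(dmax)) / (sig(0) - sig(dmax))
  v <- pmin(1, pmax(0, v))
  v[1] <- 1
  v <- rev(cummax(rev(v)))
  dvh_curve(patient_id, structure, grid, v, dose_kind = "physical")
}

#' Sample one clinical record
#'
#' Draws every clinical covariate from the configured marginals. The A2M
#' level is lognormal conditional on smoking status: the never-smoker
#' location is anchored so the smoking-mixture median equals the configured
#' overall median, and former/current smokers get the configured additive
#' shifts on the log scale. Consumes the global RNG stream.
#'
#' @param patient_id patient identifier.
#' @param dists clinical distribution list ([default_clinical_dists()]).
#' @param fractionation_menu schedule menu to draw from.
#' @return one-row data.frame (a ClinicalRecord).
#' @export
sample_clinical <- function(patient_id, dists, fractionation_menu) {
  age <- round(min(dists$age$max,
                   max(dists$age$min,
                       stats::rnorm(1, dists$age$mean, dists$age$sd))))
  sex <- if (stats::runif(1) < dists$p_female) "female" else "male"
  kps <- sample(dists$kps$values, 1, prob = dists$kps$probs)
  smoking <- sample(names(dists$smoking_probs), 1,
                    prob = dists$smoking_probs)
  pack_years <- if (smoking == "never") 0 else
    round(min(dists$pack_years$max,
              max(dists$pack_years$min,
                  stats::rlnorm(1, dists$pack_years$meanlog,
                                dists$pack_years$sdlog))))
  shift <- switch(smoking,
                  never = 0,
                  former = dists$a2m$shift_former,
                  current = dists$a2m$shift_current)
  p <- dists$smoking_probs
  mean_shift <- p[["former"]] * dists$a2m$shift_former +
    p[["current"]] * dists$a2m$shift_current
  meanlog_never <- log(dists$a2m$median) - mean_shift
  a2m <- round(stats::rlnorm(1, meanlog_never + shift, dists$a2m$sdlog), 1)
  chemo_timing <- sample(names(dists$chemo_probs), 1,
                         prob = dists$chemo_probs)
  subtype <- sample(names(dists$subtype_probs), 1,
                    prob = dists$subtype_probs)
  fx <- fractionation_menu[sample(nrow(fractionation_menu), 1,
                                  prob = fractionation_menu$prob), ]
  data.frame(
    patient_id = as.character(patient_id), age = age, sex = sex, kps = kps,
    smoking_status = smoking, pack_years = pack_years, a2m_mg_dl = a2m,
    chemo_timing = chemo_timing, subtype = subtype,
    rt_modality = if (fx$sbrt) "SBRT" else "conventional",
    total_dose_gy = fx$total_dose_gy, fraction_number = fx$fraction_number,
    treatment_days = fx$treatment_days,
    stringsAsFactors = FALSE)
}

#' Assign ordinal toxicity grades from a logistic ground truth
#'
#' Draws the binary grade >= 2 event from Bernoulli(p) with
#' `logit(p) = intercept + sum(beta_i * feature_i)`, then assigns an ordinal
#' CTCAE grade: events get grades 2-4 and non-events grades 0-1 according to
#' the configured split proportions. If the model's `intercept` is NULL and
#' `target_rate` is set, the intercept is solved (uniroot) so that the mean
#' event probability over the supplied feature rows equals the target.
#' Consumes the global RNG stream.
#'
#' @param features data.frame containing every feature named in
#'   `model$coefficients`.
#' @param model outcome-model list (see [default_outcome_models()]).
#' @return list with `grades` (integer 0-5), `prob` (event probabilities),
#'   and `intercept` (the value actually used).
#' @export
assign_outcomes <- function(features, model) {
  beta <- model$coefficients
  missing_f <- setdiff(names(beta), names(features))
  if (length(missing_f))
    stop_param("outcome model features missing from feature table: ",
               paste(missing_f, collapse = ", "))
  lp0 <- as.numeric(as.matrix(features[names(beta)]) %*% beta)
  intercept <- model$intercept
  if (is.null(intercept)) {
    if (is.null(model$target_rate))
      stop_param("outcome model needs either intercept or target_rate")
    f <- function(b0) mean(stats::plogis(b0 + lp0)) - model$target_rate
    intercept <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
  }
  p <- stats::plogis(intercept + lp0)
  event <- stats::runif(length(p)) < p
  grades <- integer(length(p))
  ev_g <- as.integer(names(model$event_grade_probs))
  ne_g <- as.integer(names(model$nonevent_grade_probs))
  n_ev <- sum(event)
  if (n_ev > 0)
    grades[event] <- ev_g[sample.int(length(ev_g), n_ev, replace = TRUE,
                                     prob = model$event_grade_probs)]
  if (n_ev < length(p))
    grades[!event] <- ne_g[sample.int(length(ne_g), length(p) - n_ev,
                                      replace = TRUE,
                                      prob = model$nonevent_grade_probs)]
  list(grades = grades, prob = p, intercept = intercept)
}

# features needed by the truth models, computed lazily from DVHs + clinical
truth_feature_table <- function(dvhs, clinical, spec, feature_names) {
  out <- data.frame(patient_id = clinical$patient_id,
                    stringsAsFactors = FALSE)
  clin <- encode_clinical(clinical)
  for (f in feature_names) {
    if (f %in% names(clin)) {
      out[[f]] <- clin[[f]]
      next
    }
    parsed <- parse_dose_feature(f, names(spec$structures))
    if (is.null(parsed))
      stop_param("unknown truth feature: ", f)
    vals <- vapply(seq_len(nrow(clinical)), function(i) {
      curve <- dvhs[[paste(clinical$patient_id[i], parsed$structure,
                           sep = "\r")]]
      sm <- summarize_structure(
        curve, spec$structures[[parsed$structure]],
        clinical$fraction_number[i], clinical$treatment_days[i],
        x_grid = if (parsed$kind == "Dx") parsed$x else c(50),
        fractional = parsed$fractional, bin_width = spec$bin_width)
      switch(parsed$kind,
             Dx = if (parsed$fractional)
               unname(sm$fDx[paste0("fD", parsed$x)])
             else unname(sm$Dx[paste0("D", parsed$x)]),
             mean = if (parsed$fractional) unname(sm$fDx["fmean"])
             else sm$mean_dose,
             max = if (parsed$fractional) unname(sm$fDx["fmax"])
             else sm$max_dose)
    }, numeric(1))
    out[[f]] <- vals
  }
  out
}

# "esophagus_D50" / "esophagus_fD10" / "heart_max" / "lung_minus_gtv_mean"
parse_dose_feature <- function(name, structure_names) {
  for (s in structure_names) {
    pre <- paste0(s, "_")
    if (!startsWith(name, pre)) next
    rest <- substring(name, nchar(pre) + 1)
    if (grepl("^fD[0-9]+$", rest))
      return(list(structure = s, kind = "Dx",
                  x = as.numeric(sub("^fD", "", rest)), fractional = TRUE))
    if (grepl("^D[0-9]+$", rest))
      return(list(structure = s, kind = "Dx",
                  x = as.numeric(sub("^D", "", rest)), fractional = FALSE))
    if (rest %in% c("mean", "max"))
      return(list(structure = s, kind = rest, fractional = FALSE))
    if (rest %in% c("fmean", "fmax"))
      return(list(structure = s, kind = sub("^f", "", rest),
                  fractional = TRUE))
  }
  NULL
}

#' Numeric encodings of clinical covariates
#'
#' Adds the derived numeric columns the modeling stages use:
#' `sex_female` (0/1), `smoking_ordinal` (never 0 < former 1 < current 2),
#' `smoking_ever` (0/1), `chemo` (0/1, any chemotherapy),
#' `sbrt` (0/1), `dose_per_fraction` (Gy).
#'
#' @param clinical clinical data.frame.
#' @return the data.frame with encoding columns appended.
#' @export
encode_clinical <- function(clinical) {
  clinical$sex_female <- as.numeric(clinical$sex == "female")
  clinical$smoking_ordinal <- match(clinical$smoking_status,
                                    c("never", "former", "current")) - 1
  clinical$smoking_ever <- as.numeric(clinical$smoking_status != "never")
  clinical$chemo <- as.numeric(clinical$chemo_timing != "none")
  clinical$sbrt <- as.numeric(clinical$rt_modality == "SBRT")
  clinical$dose_per_fraction <-
    clinical$total_dose_gy / clinical$fraction_number
  clinical
}

#' Generate a synthetic cohort
#'
#' Draws clinical records, per-structure DVHs, and ordinal toxicity grades
#' from the ground-truth outcome models. Deterministic given the spec's
#' seed: identical spec + seed yields byte-identical cohorts. The caller's
#' RNG state is untouched.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: list with `clinical`
#'   (data.frame), `dvhs` (named list of [dvh_curve()], keyed
#'   `patient_id.structure`), `grades` (data.frame patient_id + one ordinal
#'   column per endpoint), `truth` (outcome models with solved intercepts and
#'   true event probabilities), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    ids <- sprintf("P%05d", seq_len(spec$n_patients))
    rows <- lapply(ids, sample_clinical, dists = spec$clinical_dists,
                   fractionation_menu = spec$fractionation_menu)
    clinical <- as.data.frame(
      lapply(stats::setNames(nm = names(rows[[1]])),
             function(cn) unlist(lapply(rows, `[[`, cn), use.names = FALSE)),
      stringsAsFactors = FALSE)
    sn <- names(spec$structures)
    dvhs <- vector("list", length(ids) * length(sn))
    keys <- character(length(dvhs))
    k <- 0L
    for (i in seq_along(ids)) {
      fx <- list(total_dose_gy = clinical$total_dose_gy[i],
                 sbrt = clinical$rt_modality[i] == "SBRT")
      for (s in sn) {
        k <- k + 1L
        dvhs[[k]] <- sample_dvh_curve(ids[i], s, spec$dvh_shapes[[s]], fx,
                                      bin_width = spec$bin_width)
        keys[k] <- paste(ids[i], s, sep = "\r")
      }
    }
    names(dvhs) <- keys
    grades <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
    truth <- list()
    for (m in spec$outcome_models) {
      feats <- truth_feature_table(dvhs, clinical, spec,
                                   names(m$coefficients))
      res <- assign_outcomes(feats, m)
      grades[[m$endpoint]] <- res$grades
      m$intercept <- res$intercept
      m$prob <- res$prob
      truth[[m$endpoint]] <- m
    }
    structure(list(clinical = clinical, dvhs = dvhs, grades = grades,
                   truth = truth, spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients, %d structures, endpoints: %s (seed %d)\n",
    nrow(x$clinical), length(x$spec$structures),
    paste(names(x$truth), collapse = ", "), x$spec$seed))
  invisible(x)
}
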