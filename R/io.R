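#' Write DVH curves to long-format CSV
#'
#' Columns: `patient_id, structure, dose_gy, volume_fraction`; comma
#' separated, UTF-8, `"."` decimal separator.
#'
#' @param dvhs list of [dvh_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(dvhs, path) {
  tabs <- lapply(dvhs, function(cv)
    data.frame(patient_id = cv$patient_id, structure = cv$structure,
               dose_gy = cv$dose_bins, volume_fraction = cv$volume_fractions,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read DVH curves from long-format CSV
#'
#' Each `patient_id x structure` block becomes one [dvh_curve()]; curves are
#' validated on construction (monotone dose bins starting at 0, volume
#' fractions in \[0, 1\] non-increasing from 1.0) and violations are
#' reported with the offending patient and structure.
#'
#' @param path CSV with columns `patient_id, structure, dose_gy,
#'   volume_fraction`.
#' @return named list of physical-dose [dvh_curve()], keyed
#'   `patient_id\rstructure`.
#' @export
read_dvh_csv <- function(path) {
  if (!file.exists(path)) stop_param("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "structure", "dose_gy", "volume_fraction")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_param("DVH CSV missing column(s): ",
               paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$dose_gy) || !is.numeric(df$volume_fraction))
    stop_param("dose_gy and volume_fraction must be numeric")
  bad <- which(is.na(df$dose_gy) | is.na(df$volume_fraction))
  if (length(bad))
    stop_param("malformed DVH rows (line ",
               paste(bad + 1, collapse = ", "), ")")
  key <- paste(df$patient_id, df$structure, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(key, unique(key))),
                function(idx)
                  dvh_curve(df$patient_id[idx[1]], df$structure[idx[1]],
                            df$dose_gy[idx], df$volume_fraction[idx]))
  names(out) <- unique(key)
  out
}

#' Write a clinical table (with grade columns) to CSV
#'
#' Grade columns are written as `grade_<endpoint>`.
#'
#' @param clinical clinical data.frame.
#' @param grades data.frame `patient_id` + one ordinal column per endpoint,
#'   or NULL.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clinical_csv <- function(clinical, grades = NULL, path) {
  df <- clinical
  if (!is.null(grades)) {
    m <- match(df$patient_id, grades$patient_id)
    for (ep in setdiff(names(grades), "patient_id"))
      df[[paste0("grade_", ep)]] <- grades[[ep]][m]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a clinical table
#'
#' Required columns: patient_id, age, sex, kps, smoking_status, pack_years,
#' a2m_mg_dl, chemo_timing, rt_modality, total_dose_gy, fraction_number,
#' treatment_days, subtype, plus one `grade_<endpoint>` column per requested
#' endpoint. Categorical levels are validated case-insensitively
#' (smoking: never/former/current; chemo timing: concurrent/sequential/none;
#' sex: male/female; modality: conventional/SBRT) and normalized to lower
#' case (SBRT kept upper). A schedule sanity warning is emitted when
#' `treatment_days < fraction_number`.
#'
#' @param path CSV file.
#' @param endpoints endpoint names whose grade columns must be present
#'   (default: every `grade_*` column found).
#' @return list with `clinical` (data.frame) and `grades` (data.frame).
#' @export
read_clinical_csv <- function(path, endpoints = NULL) {
  if (!file.exists(path)) stop_param("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "sex", "kps", "smoking_status",
            "pack_years", "a2m_mg_dl", "chemo_timing", "rt_modality",
            "total_dose_gy", "fraction_number", "treatment_days", "subtype")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_param("clinical CSV missing column(s): ",
               paste(missing_cols, collapse = ", "))
  if (is.null(endpoints))
    endpoints <- sub("^grade_", "", grep("^grade_", names(df), value = TRUE))
  for (ep in endpoints)
    if (!paste0("grade_", ep) %in% names(df))
      stop_param("clinical CSV missing grade column for endpoint: ", ep)
  norm_cat <- function(x, levels, column) {
    z <- match(tolower(trimws(x)), tolower(levels))
    if (anyNA(z))
      stop_param("unknown ", column, " level(s): ",
                 paste(unique(x[is.na(z)]), collapse = ", "))
    levels[z]
  }
  df$patient_id <- as.character(df$patient_id)
  df$sex <- norm_cat(df$sex, c("male", "female"), "sex")
  df$smoking_status <- norm_cat(df$smoking_status,
                                c("never", "former", "current"),
                                "smoking_status")
  df$chemo_timing <- norm_cat(df$chemo_timing,
                              c("concurrent", "sequential", "none"),
                              "chemo_timing")
  df$rt_modality <- norm_cat(df$rt_modality, c("conventional", "SBRT"),
                             "rt_modality")
  if (any(df$treatment_days < df$fraction_number))
    warning("treatment_days < fraction_number for patient(s): ",
            paste(df$patient_id[df$treatment_days < df$fraction_number],
                  collapse = ", "), call. = FALSE)
  grades <- df[, c("patient_id", paste0("grade_", endpoints)), drop = FALSE]
  names(grades) <- c("patient_id", endpoints)
  for (ep in endpoints) {
    g <- grades[[ep]]
    if (any(is.na(g)) || any(g < 0 | g > 5 | g != round(g)))
      stop_param("grades for ", ep, " must be integers 0-5")
  }
  clinical <- df[, setdiff(names(df), paste0("grade_", endpoints)),
                 drop = FALSE]
  list(clinical = clinical, grades = grades)
}

#' Default pipeline configuration
#'
#' @param endpoint endpoint to model.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param out_dir output directory.
#' @param ... overrides for any configuration field.
#' @return named list of class `run_config`.
#' @export
run_config <- function(endpoint = "esophagitis", seed = 1L,
                       out_dir = tempfile("ntcp_run_"), ...) {
  cfg <- list(
    endpoint = endpoint,
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(n_patients = 258),
    dvh_csv = NULL,
    clinical_csv = NULL,
    alpha_beta = c(esophagus = 10, lung_minus_gtv = 3, heart = 3),
    x_grid = seq(5, 100, by = 5),
    fractional_structures = "esophagus",
    fractional_basis = "physical",
    bin_width = 0.1,
    screening_alpha = 0.1,
    always_include = c("treatment_days", "sbrt", "chemo"),
    exclude = c("dose_per_fraction", "fraction_number"),
    correlation_threshold = 0.75,
    linkage = "average",
    train_fraction = 2 / 3,
    n_boot = 1000,
    lambda_rule = "cv",
    lambda = NULL,
    nfolds = 5,
    n_bins = 6)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_param("unknown configuration field(s): ",
               paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (is.null(cfg$endpoint) || !nzchar(cfg$endpoint))
    stop_param("configuration must name an endpoint")
  stopifnot(cfg$screening_alpha >= 0, cfg$screening_alpha <= 1,
            cfg$correlation_threshold >= 0, cfg$correlation_threshold <= 1,
            cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$n_boot >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from a JSON file
#'
#' @param path JSON file whose keys mirror [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_param("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$alpha_beta)) raw$alpha_beta <- unlist(raw$alpha_beta)
  if (!is.null(raw$simulate)) raw$simulate <- as.list(raw$simulate)
  do.call(run_config, raw)
}

#' Run the full modeling pipeline
#'
#' simulate (optional) -> features -> screen -> cluster -> fit ->
#' calibrate -> report. When `config$dvh_csv`/`config$clinical_csv` are
#' set, curves and covariates are read from disk; otherwise a synthetic
#' cohort of `config$simulate$n_patients` is generated with a seed derived
#' from the master seed. All artifacts are written under `config$out_dir`
#' and returned invisibly. The master seed fully determines every
#' stochastic stage.
#'
#' @param config a [run_config()].
#' @param write write artifacts to `config$out_dir` (default TRUE).
#' @return list with `features`, `univariate`, `clusters`, `split`,
#'   `ensemble`, `final`, `calibration`, `report`, `run_id`, and (when
#'   simulated) `cohort`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  run_id <- sprintf("%s-seed%d", config$endpoint, config$seed)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      stop_param("stage '", name, "' failed: ", conditionMessage(e)))
    message(sprintf("[%s] %s done in %.1fs", run_id, name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    val
  }
  cohort <- NULL
  if (!is.null(config$dvh_csv) || !is.null(config$clinical_csv)) {
    if (is.null(config$dvh_csv) || is.null(config$clinical_csv))
      stop_param("both dvh_csv and clinical_csv must be set to load data")
    dvhs <- stage("read_dvh", read_dvh_csv(config$dvh_csv))
    clin <- stage("read_clinical", read_clinical_csv(config$clinical_csv))
    clinical <- clin$clinical
    grades <- clin$grades
  } else {
    spec_args <- config$simulate
    spec_args$seed <- spec_args$seed %||% derive_seed(config$seed,
                                                      "simulate")
    spec_args$bin_width <- spec_args$bin_width %||% config$bin_width
    cohort <- stage("simulate", generate_cohort(
      do.call(cohort_spec, spec_args)))
    dvhs <- cohort$dvhs
    clinical <- cohort$clinical
    grades <- cohort$grades
  }
  if (!config$endpoint %in% names(grades))
    stop_param("endpoint '", config$endpoint, "' has no grade column")
  features <- stage("features", build_feature_table(
    dvhs, clinical, grades, alpha_beta = config$alpha_beta,
    x_grid = config$x_grid,
    fractional_structures = config$fractional_structures,
    fractional_basis = config$fractional_basis,
    bin_width = config$bin_width))
  univ <- stage("screen", screen_features(
    features, config$endpoint, alpha = config$screening_alpha,
    always_include = config$always_include))
  dose_cols <- dosimetric_columns(features)
  dose_pass <- intersect(attr(univ, "selected"), dose_cols)
  empty_clusters <- structure(
    data.frame(feature = character(0), cluster_id = integer(0),
               rs_with_endpoint = numeric(0), representative = logical(0),
               stringsAsFactors = FALSE),
    reduced = character(0))
  clusters <- stage("cluster", if (length(dose_pass) >= 1)
    decorrelate(features, dose_pass, univ,
                threshold = config$correlation_threshold,
                linkage = config$linkage, exclude = config$exclude)
    else empty_clusters)
  clin_pass <- setdiff(attr(univ, "selected"),
                       c(dose_cols, config$exclude))
  candidates <- unique(c(attr(clusters, "reduced"), clin_pass))
  if (length(candidates) == 0)
    stop_param("no candidate features survived screening")
  binary <- paste0(config$endpoint, "_grade2plus")
  split <- stage("split", stratified_split(
    features$patient_id, features$subtype, features[[binary]],
    train_fraction = config$train_fraction,
    seed = derive_seed(config$seed, "split")))
  tr <- features$patient_id %in% split$train_ids
  X <- as.matrix(features[candidates])
  y <- features[[binary]]
  ensemble <- stage("fit", bootstrap_ensemble(
    X[tr, , drop = FALSE], y[tr], X[!tr, , drop = FALSE], y[!tr],
    n_boot = config$n_boot, seed = derive_seed(config$seed, "boot"),
    lambda_rule = config$lambda_rule, lambda = config$lambda,
    nfolds = config$nfolds))
  final <- stage("final_model", final_model(
    X[tr, , drop = FALSE], y[tr], ensemble,
    seed = derive_seed(config$seed, "final"),
    lambda_rule = config$lambda_rule, lambda = config$lambda,
    nfolds = config$nfolds))
  fit <- attr(final, "fit")
  pred <- stats::plogis(fit$intercept +
                          as.numeric(X[!tr, , drop = FALSE] %*%
                                       fit$coefficients))
  calibration <- stage("calibrate", calibration_bins(
    pred, y[!tr], n_bins = config$n_bins,
    ids = features$patient_id[!tr]))
  report <- stage("report", build_report(
    run_id, config$endpoint, univ, clusters, ensemble, final, calibration,
    config = list(seed = config$seed, n_boot = config$n_boot,
                  lambda_rule = config$lambda_rule,
                  screening_alpha = config$screening_alpha,
                  correlation_threshold = config$correlation_threshold,
                  candidates = candidates)))
  out <- list(features = features, univariate = univ, clusters = clusters,
              split = split, ensemble = ensemble, final = final,
              calibration = calibration, report = report, run_id = run_id,
              cohort = cohort)
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    if (!is.null(cohort)) {
      write_dvh_csv(cohort$dvhs, p("dvh.csv"))
      write_clinical_csv(cohort$clinical, cohort$grades, p("clinical.csv"))
      truth <- lapply(cohort$truth, function(m)
        m[c("endpoint", "coefficients", "intercept", "target_rate")])
      jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                           digits = NA)
    }
    utils::write.csv(features, p("features.csv"), row.names = FALSE)
    utils::write.csv(univ, p("univariate.csv"), row.names = FALSE)
    utils::write.csv(clusters, p("clusters.csv"), row.names = FALSE)
    utils::write.csv(data.frame(
      feature = names(ensemble$selection_counts),
      count = as.integer(ensemble$selection_counts)),
      p("selection_frequency.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(ensemble$pair_counts),
                     p("pair_frequency.csv"), row.names = TRUE)
    utils::write.csv(final, p("final_model.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(calibration), p("calibration.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(run_id = run_id, seed = config$seed, n_boot = ensemble$n_boot,
           mean_auc = ensemble$mean_auc, sd_auc = ensemble$sd_auc,
           degenerate_redraws = ensemble$degenerate_redraws,
           candidates = candidates),
      p("ensemble.json"), auto_unbox = TRUE, digits = NA)
    writeLines(unclass(report), p("report.md"))
  }
  invisible(out)
}
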