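#' Assemble the patients x features modeling table
#'
#' Computes the full dosimetric feature set for every patient and structure
#' (EQD2 Dx grid, mean and max dose; fractional fDx/fmean/fmax for the
#' fractional structures), appends encoded clinical covariates, the ordinal
#' grade column per endpoint, and the derived binary grade >= 2 indicator.
#' Dosimetric columns are named `{structure}_D{x}`, `{structure}_mean`,
#' `{structure}_max`, and `{structure}_fD{x}` etc. for fractional sets.
#'
#' @param dvhs named list of physical-dose [dvh_curve()] keyed
#'   `patient_id\rstructure` (as produced by [generate_cohort()]), or a
#'   plain list of curves.
#' @param clinical clinical data.frame (one row per patient).
#' @param grades data.frame with `patient_id` and one ordinal grade column
#'   per endpoint, or NULL.
#' @param alpha_beta named vector of alpha/beta ratios per structure.
#' @param x_grid Dx percentages.
#' @param fractional_structures structures for which fDx is computed
#'   (default `"esophagus"`).
#' @param fractional_basis `"physical"` or `"EQD2"` (see
#'   [summarize_structure()]).
#' @param bin_width resampling grid width in Gy.
#' @return data.frame, one row per patient; attribute `"endpoints"` lists
#'   the grade columns; binary indicators are named `{endpoint}_grade2plus`.
#' @export
build_feature_table <- function(dvhs, clinical, grades = NULL,
                                alpha_beta = c(esophagus = 10,
                                               lung_minus_gtv = 3,
                                               heart = 3),
                                x_grid = seq(5, 100, by = 5),
                                fractional_structures = "esophagus",
                                fractional_basis = "physical",
                                bin_width = 0.1) {
  if (is.null(names(dvhs)))
    names(dvhs) <- vapply(dvhs, function(cv)
      paste(cv$patient_id, cv$structure, sep = "\r"), character(1))
  clin <- encode_clinical(clinical)
  structures <- unique(vapply(dvhs, `[[`, character(1), "structure"))
  missing_ab <- setdiff(structures, names(alpha_beta))
  if (length(missing_ab))
    stop_param("no alpha/beta ratio for structure(s): ",
               paste(missing_ab, collapse = ", "))
  out <- clin
  for (s in structures) {
    dose_cols <- NULL
    rows <- lapply(seq_len(nrow(clin)), function(i) {
      key <- paste(clin$patient_id[i], s, sep = "\r")
      curve <- dvhs[[key]]
      if (is.null(curve))
        stop_param("missing DVH for patient ", clin$patient_id[i],
                   ", structure ", s)
      sm <- summarize_structure(
        curve, alpha_beta[[s]], clin$fraction_number[i],
        clin$treatment_days[i], x_grid = x_grid,
        fractional = s %in% fractional_structures,
        fractional_basis = fractional_basis, bin_width = bin_width)
      c(sm$Dx, mean = sm$mean_dose, max = sm$max_dose, sm$fDx)
    })
    mat <- do.call(rbind, rows)
    colnames(mat) <- paste(s, colnames(mat), sep = "_")
    out <- cbind(out, as.data.frame(mat))
  }
  endpoints <- character(0)
  if (!is.null(grades)) {
    m <- match(out$patient_id, grades$patient_id)
    if (anyNA(m))
      stop_param("grades missing for some patients")
    endpoints <- setdiff(names(grades), "patient_id")
    for (ep in endpoints) {
      out[[ep]] <- grades[[ep]][m]
      out[[paste0(ep, "_grade2plus")]] <- as.numeric(out[[ep]] >= 2)
    }
  }
  if (anyNA(out))
    stop_param("feature table contains missing values")
  attr(out, "endpoints") <- endpoints
  out
}

#' Dosimetric column names of a feature table
#'
#' @param features feature table from [build_feature_table()].
#' @param structures structure names to match (default: infer from column
#'   prefixes ending in `_D{x}`, `_mean`, `_max`, `_fD{x}`).
#' @return character vector of dosimetric column names.
#' @export
dosimetric_columns <- function(features, structures = NULL) {
  cols <- names(features)
  pat <- "_(f?D[0-9]+|f?mean|f?max)$"
  hits <- grepl(pat, cols)
  if (!is.null(structures))
    hits <- hits & Reduce(`|`, lapply(paste0("^", structures, "_"),
                                      grepl, cols))
  cols[hits]
}
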