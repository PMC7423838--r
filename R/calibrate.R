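#' Six-bin observed vs predicted calibration table
#'
#' Sorts patients by predicted risk (stable: ties resolved by patient id),
#' cuts them into `n_bins` contiguous equal-size bins from lowest (bin 1) to
#' highest risk (bin `n_bins`) — when the cohort size is not divisible the
#' extra patients go to the highest-risk bins — and tabulates per bin the
#' observed incidence and the mean predicted probability. Patients and
#' events are conserved exactly.
#'
#' @param predicted predicted event probabilities.
#' @param observed binary observed outcomes.
#' @param n_bins number of risk bins (default 6).
#' @param ids patient identifiers for the tie-break (default index order).
#' @return data.frame (bin, n, events_observed, incidence_observed,
#'   incidence_predicted_mean) of class `calibration_table`.
#' @export
calibration_bins <- function(predicted, observed, n_bins = 6, ids = NULL) {
  n <- length(predicted)
  if (length(observed) != n)
    stop_param("predicted and observed must have equal length")
  if (n < n_bins)
    stop_param("need at least n_bins = ", n_bins, " patients")
  if (any(predicted < 0 | predicted > 1))
    stop_param("predicted values must be probabilities")
  if (is.null(ids)) ids <- seq_len(n)
  ord <- order(predicted, ids)
  base <- n %/% n_bins
  extra <- n %% n_bins
  # remainder goes to the top-risk bins (the last `extra` bins)
  sizes <- as.integer(rep(base, n_bins) +
                        c(rep(0, n_bins - extra), rep(1, extra)))
  bin <- rep(seq_len(n_bins), times = sizes)
  out <- data.frame(
    bin = seq_len(n_bins),
    n = sizes,
    events_observed = as.integer(tapply(as.numeric(observed)[ord], bin,
                                        sum)),
    incidence_observed = as.numeric(tapply(as.numeric(observed)[ord], bin,
                                           mean)),
    incidence_predicted_mean = as.numeric(tapply(predicted[ord], bin,
                                                 mean)))
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Assemble a run report
#'
#' Single human-readable markdown report combining the univariate screen,
#' the cluster assignment, the feature selection frequencies and pairwise
#' co-selection matrix of the bootstrap ensemble, the final model table, and
#' the calibration table, plus the configuration seeds for reproducibility.
#' All components must carry the same `run_id`.
#'
#' @param run_id character run identifier; every component must have a
#'   matching `run_id` attribute (components without one are stamped by the
#'   pipeline).
#' @param endpoint endpoint name.
#' @param univariate univariate screen results.
#' @param clusters cluster assignment ([select_representatives()] output).
#' @param ensemble a [bootstrap_ensemble()].
#' @param final final-model table ([final_model()]).
#' @param calibration a [calibration_bins()] table.
#' @param config named list echoed into the report (seeds etc.).
#' @return character vector of markdown lines (class `ntcp_report`).
#' @export
build_report <- function(run_id, endpoint, univariate, clusters, ensemble,
                         final, calibration, config = list()) {
  parts <- list(univariate = univariate, clusters = clusters,
                ensemble = ensemble, final = final,
                calibration = calibration)
  for (nm in names(parts)) {
    if (is.null(parts[[nm]]))
      stop_param("report component missing: ", nm)
    rid <- attr(parts[[nm]], "run_id")
    if (!is.null(rid) && !identical(rid, run_id))
      stop_param("run_id mismatch in component '", nm, "': ", rid,
                 " vs ", run_id)
  }
  if (ensemble$n_boot < 1) stop_param("empty ensemble")
  fmt_df <- function(df, digits = 4) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(z) signif(z, digits))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- if (nrow(df) == 0) "(none)" else
      apply(df, 1, function(r)
        paste0("| ", paste(trimws(r), collapse = " | "), " |"))
    c(header, sep, body)
  }
  sel <- sort(ensemble$selection_counts, decreasing = TRUE)
  freq_df <- data.frame(feature = names(sel), count = as.integer(sel),
                        frequency = as.numeric(sel) / ensemble$n_boot)
  pair <- ensemble$pair_counts / ensemble$n_boot
  pair_df <- data.frame(feature = rownames(pair),
                        round(pair, 3), check.names = FALSE)
  lines <- c(
    sprintf("# Toxicity model report — endpoint: %s (run %s)", endpoint,
            run_id),
    "",
    "## Univariate associations (Spearman vs ordinal grade)",
    "",
    fmt_df(utils::head(univariate, 30)),
    "",
    "## Collinearity clusters and representatives",
    "",
    fmt_df(clusters),
    "",
    sprintf("## Feature selection frequency (%d bootstrap models)",
            ensemble$n_boot),
    "",
    sprintf("Mean validation AUC %.3f (SD %.3f); %d degenerate resamples redrawn.",
            ensemble$mean_auc, ensemble$sd_auc,
            ensemble$degenerate_redraws),
    "",
    fmt_df(freq_df),
    "",
    "## Pairwise co-selection frequency",
    "",
    fmt_df(pair_df),
    "",
    "## Final model (full training data)",
    "",
    fmt_df(final),
    "",
    "## Calibration (validation data, six risk bins)",
    "",
    fmt_df(as.data.frame(calibration)),
    "",
    "## Configuration",
    "",
    vapply(names(config), function(k)
      sprintf("- %s: %s", k, paste(format(config[[k]]), collapse = ", ")),
      character(1)))
  structure(lines, class = c("ntcp_report", "character"))
}

#' @export
print.ntcp_report <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
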