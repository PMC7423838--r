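#' Construct a cumulative dose-volume histogram curve
#'
#' A cumulative DVH gives, for each dose level, the fraction of a structure's
#' volume receiving at least that dose. Curves are validated on construction:
#' dose bins strictly increasing and starting at 0 Gy, volume fractions in
#' \[0, 1\], non-increasing, and equal to 1 at zero dose.
#'
#' @param patient_id patient identifier (character scalar).
#' @param structure structure name, e.g. `"esophagus"`, `"lung_minus_gtv"`,
#'   `"heart"`.
#' @param dose_bins numeric vector of dose levels in Gy.
#' @param volume_fractions numeric vector of cumulative volume fractions.
#' @param dose_kind `"physical"` (planned dose) or `"EQD2"` (already
#'   converted to equivalent dose in 2 Gy fractions).
#' @return an object of class `dvh_curve`.
#' @export
dvh_curve <- function(patient_id, structure, dose_bins, volume_fractions,
                      dose_kind = c("physical", "EQD2")) {
  dose_kind <- match.arg(dose_kind)
  n <- length(dose_bins)
  if (n < 2 || length(volume_fractions) != n)
    stop_param("dose_bins and volume_fractions must have equal length >= 2")
  if (dose_bins[1] != 0)
    stop_param("dose_bins must start at 0 Gy (patient ", patient_id,
               ", structure ", structure, ")")
  if (any(diff(dose_bins) <= 0))
    stop_param("dose_bins must be strictly increasing (patient ", patient_id,
               ", structure ", structure, ")")
  if (any(volume_fractions < 0 | volume_fractions > 1))
    stop_param("volume_fractions must lie in [0, 1] (patient ", patient_id,
               ", structure ", structure, ")")
  if (any(diff(volume_fractions) > 1e-12))
    stop_param("volume_fractions must be non-increasing (patient ",
               patient_id, ", structure ", structure, ")")
  if (abs(volume_fractions[1] - 1) > 1e-12)
    stop_param("volume fraction at 0 Gy must be 1.0 (patient ", patient_id,
               ", structure ", structure, ")")
  structure(
    list(patient_id = as.character(patient_id),
         structure = as.character(structure),
         dose_bins = as.numeric(dose_bins),
         volume_fractions = pmin(1, pmax(0, as.numeric(volume_fractions))),
         dose_kind = dose_kind),
    class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> patient %s, %s (%s dose): %d bins, 0-%.1f Gy\n",
              x$patient_id, x$structure, x$dose_kind,
              length(x$dose_bins), max(x$dose_bins)))
  invisible(x)
}

#' Convert a physical-dose DVH to EQD2
#'
#' Applies the linear-quadratic equivalent dose in 2 Gy fractions to every
#' dose bin: `EQD2 = D * (d + ab) / (2 + ab)` with per-fraction dose
#' `d = D / fraction_number` and `ab` the tissue alpha/beta ratio in Gy.
#' Volume fractions are unchanged; the transform is monotone in D, so
#' cumulative-DVH monotonicity is preserved. Dose delivered at exactly
#' 2 Gy/fraction is a fixed point.
#'
#' @param curve a physical-dose [dvh_curve()].
#' @param alpha_beta alpha/beta ratio in Gy; conventional defaults are 10 for
#'   acutely responding tissue (esophagus) and 3 for late-responding tissue
#'   (lung minus GTV, heart).
#' @param fraction_number number of treatment fractions (>= 1).
#' @return an EQD2 [dvh_curve()].
#' @export
eqd2_transform <- function(curve, alpha_beta, fraction_number) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (curve$dose_kind != "physical")
    stop_param("curve is already EQD2-converted")
  if (!is.numeric(alpha_beta) || alpha_beta <= 0)
    stop_param("alpha_beta must be > 0 Gy")
  if (!is.numeric(fraction_number) || fraction_number < 1)
    stop_param("fraction_number must be >= 1")
  d <- curve$dose_bins / fraction_number
  eq <- curve$dose_bins * (d + alpha_beta) / (2 + alpha_beta)
  dvh_curve(curve$patient_id, curve$structure, eq, curve$volume_fractions,
            dose_kind = "EQD2")
}

#' Minimum dose to the hottest x% of a structure (Dx)
#'
#' Reads the dose at cumulative volume fraction `x/100` from the curve by
#' linear interpolation between bins. Plateaus below 1.0 resolve to the
#' lowest dose achieving the target fraction ("minimum dose to the volume");
#' if `x/100` meets or exceeds every tabulated fraction below 1.0, the
#' largest dose still covering the full volume (the minimum structure dose)
#' is returned, so D100 is the structure minimum dose.
#'
#' @param curve a [dvh_curve()].
#' @param x volume percentage in (0, 100].
#' @return dose in Gy.
#' @export
dose_at_volume <- function(curve, x) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.numeric(x) || any(x <= 0) || any(x > 100))
    stop_param("x must lie in (0, 100]")
  v <- x / 100
  d <- curve$dose_bins
  vf <- curve$volume_fractions
  # end of the leading V = 1 plateau: the minimum structure dose
  i0 <- max(which(vf >= 1 - 1e-12))
  vapply(v, function(vt) {
    if (vt >= vf[i0] - 1e-12) return(d[i0])
    # lowest-dose tie rule: first bin whose fraction has dropped to <= vt
    i <- which(vf <= vt + 1e-12)[1]
    if (is.na(i)) return(d[length(d)])  # curve never reaches vt: max dose
    if (abs(vf[i] - vt) <= 1e-12) return(d[i])
    # strict crossing between i-1 and i
    d[i - 1] + (vf[i - 1] - vt) / (vf[i - 1] - vf[i]) * (d[i] - d[i - 1])
  }, numeric(1))
}

#' Resample a DVH onto a uniform dose grid
#'
#' Linear interpolation onto bins of width `bin_width` spanning 0 to the
#' curve maximum. Removes grid-dialect differences between planning-system
#' exports before metric extraction.
#'
#' @param curve a [dvh_curve()].
#' @param bin_width grid spacing in Gy (default 0.1).
#' @return a [dvh_curve()] on the uniform grid.
#' @export
resample_dvh <- function(curve, bin_width = 0.1) {
  stopifnot(inherits(curve, "dvh_curve"), bin_width > 0)
  dmax <- max(curve$dose_bins)
  grid <- seq(0, dmax, by = bin_width)
  if (grid[length(grid)] < dmax) grid <- c(grid, dmax)
  vf <- stats::approx(curve$dose_bins, curve$volume_fractions, xout = grid,
                      method = "linear", rule = 2)$y
  vf <- rev(cummax(rev(vf)))  # guard monotonicity against FP jitter
  vf[1] <- 1
  dvh_curve(curve$patient_id, curve$structure, grid, vf, curve$dose_kind)
}

#' Mean dose from a cumulative DVH
#'
#' Trapezoidal integral of the cumulative curve over dose. For a piecewise
#' linear curve falling to zero this equals the differential-DVH
#' volume-weighted mean dose exactly (integration by parts); a terminal
#' volume fraction above zero contributes its mass at the last bin edge.
#'
#' @param curve a [dvh_curve()].
#' @return mean dose in Gy.
#' @export
mean_dose <- function(curve) {
  stopifnot(inherits(curve, "dvh_curve"))
  d <- curve$dose_bins
  v <- curve$volume_fractions
  n <- length(d)
  sum((v[-n] + v[-1]) / 2 * diff(d))
}

#' Maximum dose from a cumulative DVH
#'
#' The largest dose bin with positive volume fraction (the bin edge itself,
#' no half-bin offset).
#'
#' @param curve a [dvh_curve()].
#' @return max dose in Gy.
#' @export
max_dose <- function(curve) {
  stopifnot(inherits(curve, "dvh_curve"))
  d <- curve$dose_bins[curve$volume_fractions > 1e-12]
  if (length(d) == 0) 0 else max(d)
}

#' Fractional (per-treatment-day) dose metrics
#'
#' Divides every dose-valued metric by the number of treatment days between
#' the start and end of radiotherapy (weekends included), yielding Gy/day.
#' These "f"-prefixed variables capture daily dose intensity, relevant for
#' acutely developing toxicity.
#'
#' @param metrics named numeric vector of dose metrics in Gy (e.g. the `Dx`
#'   grid plus `mean`/`max`).
#' @param treatment_days elapsed treatment days (>= 1).
#' @return named numeric vector in Gy/day, names prefixed with `"f"`.
#' @export
fractional_metrics <- function(metrics, treatment_days) {
  if (!is.numeric(treatment_days) || treatment_days < 1)
    stop_param("treatment_days must be >= 1")
  out <- metrics / treatment_days
  names(out) <- paste0("f", names(metrics))
  out
}

#' Full dosimetric metric set for one patient x structure
#'
#' Converts the physical curve to EQD2, resamples both to a uniform grid, and
#' extracts the Dx grid (default x = 5%..100% in 5% steps), mean and max dose
#' on the EQD2 curve, plus fractional fDx/fmean/fmax when requested. The
#' fractional set divides the chosen basis curve's metrics by
#' `treatment_days`; the default basis is the physical curve (daily physical
#' dose intensity), switchable to EQD2.
#'
#' @param curve a physical-dose [dvh_curve()].
#' @param alpha_beta alpha/beta ratio in Gy for the EQD2 conversion.
#' @param fraction_number number of fractions delivered.
#' @param treatment_days elapsed treatment days (needed when
#'   `fractional = TRUE`).
#' @param x_grid Dx percentages (default `seq(5, 100, by = 5)`).
#' @param fractional compute the fDx set? Default: only for the esophagus.
#' @param fractional_basis `"physical"` (default) or `"EQD2"`.
#' @param bin_width resampling grid width in Gy.
#' @return list with `patient_id`, `structure`, `Dx` (named Gy vector),
#'   `mean_dose`, `max_dose`, `fDx` (named Gy/day vector or NULL),
#'   `treatment_days`.
#' @export
summarize_structure <- function(curve, alpha_beta, fraction_number,
                                treatment_days = NULL,
                                x_grid = seq(5, 100, by = 5),
                                fractional = identical(curve$structure,
                                                       "esophagus"),
                                fractional_basis = c("physical", "EQD2"),
                                bin_width = 0.1) {
  stopifnot(inherits(curve, "dvh_curve"))
  fractional_basis <- match.arg(fractional_basis)
  # resample the physical curve first: transforming a coarse curve and
  # interpolating afterwards would lose the transform's curvature
  phys <- resample_dvh(curve, bin_width)
  eq <- eqd2_transform(phys, alpha_beta, fraction_number)
  dx <- dose_at_volume(eq, x_grid)
  names(dx) <- paste0("D", x_grid)
  fdx <- NULL
  if (isTRUE(fractional)) {
    if (is.null(treatment_days))
      stop_param("treatment_days required for fractional metrics")
    base <- if (fractional_basis == "physical") phys else eq
    fx <- dose_at_volume(base, x_grid)
    names(fx) <- paste0("D", x_grid)
    fm <- c(fx, mean = mean_dose(base), max = max_dose(base))
    fdx <- fractional_metrics(fm, treatment_days)
  }
  list(patient_id = curve$patient_id,
       structure = curve$structure,
       Dx = dx,
       mean_dose = mean_dose(eq),
       max_dose = max_dose(eq),
       fDx = fdx,
       treatment_days = treatment_days)
}
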