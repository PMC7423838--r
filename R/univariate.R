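#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties), the convention
#' used to associate features with ordinal CTCAE grades 0-5 without
#' dichotomizing. The two-sided p-value uses the t-approximation with n - 2
#' degrees of freedom; a seeded permutation p-value is available for
#' validation.
#'
#' @param x numeric vector (binary covariates enter as 0/1).
#' @param grades ordinal outcome vector (or any numeric).
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm permutation count (default 10000).
#' @param seed seed for the permutation p-value.
#' @return list with `rs` and `p`.
#' @export
spearman <- function(x, grades, method = c("t", "permutation"),
                     n_perm = 10000, seed = 1L) {
  method <- match.arg(method)
  if (length(x) != length(grades))
    stop_param("x and grades must have equal length")
  n <- length(x)
  if (n < 3) stop_param("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(grades) == 0)
    stop_param("correlation undefined for constant input")
  rs_of <- function(xx) stats::cor(rank(xx), rank(grades))
  rs <- rs_of(x)
  if (method == "t") {
    if (abs(rs) >= 1 - 1e-15) {
      p <- 0
    } else {
      tval <- rs * sqrt((n - 2) / (1 - rs^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  } else {
    p <- with_seed(seed, {
      perm <- replicate(n_perm, rs_of(sample(x)))
      (1 + sum(abs(perm) >= abs(rs) - 1e-12)) / (n_perm + 1)
    })
  }
  list(rs = rs, p = p)
}

#' Wilcoxon rank-sum test
#'
#' Mid-rank rank-sum statistic for group `a`. The two-sided p-value is exact
#' (full enumeration of rank assignments, doubling the smaller tail, capped
#' at 1) when `length(a) + length(b) <= 12` and there are no ties; otherwise
#' a normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list with `statistic` (rank sum of `a`) and `p`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop_param("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  ties <- any(duplicated(pooled))
  if (n <= 12 && !ties) {
    # exact: enumerate all C(n, na) assignments of ranks to group a
    sums <- utils::combn(n, na, sum)
    lower <- mean(sums <= w)
    upper <- mean(sums >= w)
    p <- min(1, 2 * min(lower, upper))
  } else {
    mu <- na * (n + 1) / 2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_corr)
    if (sigma2 <= 0) return(list(statistic = w, p = 1))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    if (abs(w - mu) < 0.5) z <- 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = w, p = p)
}

#' Univariate screen of every feature against an endpoint
#'
#' For each candidate feature computes Spearman rs/p against the ordinal
#' grade vector and a Wilcoxon rank-sum p between the dichotomized groups
#' (grade < 2 vs >= 2). Features with Spearman p below `alpha` pass the
#' screen; the `always_include` set (conventionally treatment days, the SBRT
#' flag and chemotherapy) passes regardless. No multiple-testing correction
#' is applied at this stage.
#'
#' @param features feature table ([build_feature_table()]).
#' @param endpoint endpoint name; the ordinal column `endpoint` must exist.
#' @param candidates feature columns to screen (default: all dosimetric
#'   columns plus standard clinical encodings present).
#' @param alpha screening threshold on the Spearman p-value (default 0.1).
#' @param always_include features forced into the candidate set (default
#'   `c("treatment_days", "sbrt", "chemo")`).
#' @return data.frame (feature, rs, p, wilcoxon_p, n, passed, forced),
#'   sorted by decreasing |rs|; attribute `"selected"` holds the passing
#'   feature names.
#' @export
screen_features <- function(features, endpoint, candidates = NULL,
                            alpha = 0.1,
                            always_include = c("treatment_days", "sbrt",
                                               "chemo")) {
  if (nrow(features) == 0) stop_param("empty feature table")
  if (!endpoint %in% names(features))
    stop_param("endpoint column not found: ", endpoint)
  grades <- features[[endpoint]]
  if (is.null(candidates)) {
    clin_default <- c("age", "sex_female", "kps", "smoking_ordinal",
                      "smoking_ever", "pack_years", "a2m_mg_dl", "chemo",
                      "sbrt", "total_dose_gy", "dose_per_fraction",
                      "fraction_number", "treatment_days")
    candidates <- c(dosimetric_columns(features),
                    intersect(clin_default, names(features)))
  }
  candidates <- setdiff(unique(candidates),
                        c(endpoint, paste0(endpoint, "_grade2plus")))
  rows <- lapply(candidates, function(f) {
    x <- features[[f]]
    if (stats::sd(x) == 0)
      return(data.frame(feature = f, rs = NA_real_, p = NA_real_,
                        wilcoxon_p = NA_real_, n = length(x),
                        stringsAsFactors = FALSE))
    sp <- spearman(x, grades)
    grp <- grades >= 2
    wp <- if (any(grp) && any(!grp))
      wilcoxon_rank_sum(x[!grp], x[grp])$p else NA_real_
    data.frame(feature = f, rs = sp$rs, p = sp$p, wilcoxon_p = wp,
               n = length(x), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$forced <- res$feature %in% always_include
  res$passed <- (!is.na(res$p) & res$p < alpha) | res$forced
  res <- res[order(-abs(res$rs), res$feature, na.last = TRUE), ]
  rownames(res) <- NULL
  attr(res, "selected") <- res$feature[res$passed]
  res
}
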