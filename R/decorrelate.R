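#' Pearson correlation matrix of a feature set
#'
#' @param features numeric matrix or data.frame (patients x features);
#'   constant columns are an error (correlation undefined).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(features) {
  x <- as.matrix(features)
  if (ncol(x) < 2 || nrow(x) < 3)
    stop_param("need >= 2 features and >= 3 patients")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop_param("correlation undefined for constant column(s): ",
               paste(colnames(x)[sds == 0], collapse = ", "))
  r <- stats::cor(x)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Cluster collinear features by hierarchical clustering
#'
#' Agglomerative clustering (average linkage by default) on the distance
#' `1 - |r|`, cut at height `1 - threshold`, so any two features in a
#' cluster are linked through correlations above the threshold on average.
#' Absolute correlation is used because anticorrelated variables carry
#' redundant information for a linear model; set `absolute = FALSE` to
#' cluster on signed `r`.
#'
#' @param corr correlation matrix from [pearson_matrix()].
#' @param threshold correlation cutoff in (0, 1); default 0.75.
#' @param linkage `"average"` (default) or `"complete"`.
#' @param absolute cluster on |r| (default TRUE).
#' @return named integer vector of cluster ids (1-based).
#' @export
cluster_features <- function(corr, threshold = 0.75,
                             linkage = c("average", "complete"),
                             absolute = TRUE) {
  linkage <- match.arg(linkage)
  if (threshold < 0 || threshold > 1)
    stop_param("threshold must lie in [0, 1]")
  if (nrow(corr) == 1)
    return(stats::setNames(1L, rownames(corr)))
  if (threshold == 0)  # everything is "correlated enough": one cluster
    return(stats::setNames(rep(1L, nrow(corr)), rownames(corr)))
  r <- if (absolute) abs(corr) else corr
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = linkage)
  # strict "> threshold" semantics: a pair at exactly the cutoff stays apart
  stats::cutree(hc, h = 1 - threshold - 1e-10)
}

#' Pick one representative feature per cluster
#'
#' Within each cluster the feature with the largest absolute univariate
#' correlation (|rs|) with the endpoint is kept; ties break to the
#' alphabetically first feature name.
#'
#' @param clusters named cluster-id vector from [cluster_features()].
#' @param univariate univariate screen results ([screen_features()]) or any
#'   data.frame with `feature` and `rs` columns.
#' @return data.frame (feature, cluster_id, rs_with_endpoint,
#'   representative); attribute `"reduced"` holds the representative names
#'   in cluster order.
#' @export
select_representatives <- function(clusters, univariate) {
  feats <- names(clusters)
  m <- match(feats, univariate$feature)
  if (anyNA(m))
    stop_param("no univariate result for feature(s): ",
               paste(feats[is.na(m)], collapse = ", "))
  rs <- univariate$rs[m]
  out <- data.frame(feature = feats, cluster_id = as.integer(clusters),
                    rs_with_endpoint = rs, representative = FALSE,
                    stringsAsFactors = FALSE)
  for (cid in sort(unique(out$cluster_id))) {
    idx <- which(out$cluster_id == cid)
    ord <- idx[order(-abs(out$rs_with_endpoint[idx]), out$feature[idx])]
    out$representative[ord[1]] <- TRUE
  }
  out <- out[order(out$cluster_id, -out$representative, out$feature), ]
  rownames(out) <- NULL
  attr(out, "reduced") <- out$feature[out$representative]
  out
}

#' Reduce a collinear feature set to cluster representatives
#'
#' Convenience wrapper: correlation matrix, clustering, and representative
#' selection in one call, with an explicit exclusion list for variables
#' removed a priori (e.g. dose per fraction and fraction number, near-copies
#' of treatment days).
#'
#' @param features feature table.
#' @param columns dosimetric columns to decorrelate.
#' @param univariate univariate screen results covering `columns`.
#' @param threshold,linkage,absolute passed to [cluster_features()].
#' @param exclude columns dropped before clustering.
#' @return see [select_representatives()].
#' @export
decorrelate <- function(features, columns, univariate, threshold = 0.75,
                        linkage = "average", absolute = TRUE,
                        exclude = character(0)) {
  columns <- setdiff(columns, exclude)
  if (length(columns) == 0) stop_param("no columns left to decorrelate")
  if (length(columns) == 1) {
    out <- data.frame(feature = columns, cluster_id = 1L,
                      rs_with_endpoint =
                        univariate$rs[match(columns, univariate$feature)],
                      representative = TRUE, stringsAsFactors = FALSE)
    attr(out, "reduced") <- columns
    return(out)
  }
  corr <- pearson_matrix(features[columns])
  cl <- cluster_features(corr, threshold, linkage, absolute)
  select_representatives(cl, univariate)
}
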