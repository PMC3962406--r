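#' Standardize each observation column
#'
#' Centres and scales every observation column to mean 0, standard
#' deviation 1, so that no single observation dominates the between-column
#' distances used by [cluster_observations()]. The sample (n - 1) standard
#' deviation is the default convention; the population (n) divisor is
#' available for completeness. Imputation is expected to happen *before*
#' normalization, so the imputed no-change value enters the column moments
#' like any other value (normalizing first would shift what the imputed 0
#' means).
#'
#' @param matrix an [build_matrix()] result.
#' @param sd_type `"sample"` (n - 1 divisor, default) or `"population"`.
#' @return an `expression_matrix` with standardized columns (imputation
#'   mask carried through).
#' @export
normalize_within_observation <- function(matrix,
                                         sd_type = c("sample", "population")) {
  stopifnot(inherits(matrix, "expression_matrix"))
  sd_type <- match.arg(sd_type)
  values <- matrix$values
  n <- nrow(values)
  mu <- colMeans(values)
  sdev <- apply(values, 2, stats::sd)
  if (sd_type == "population") sdev <- sdev * sqrt((n - 1) / n)
  if (any(sdev == 0))
    .stopf("zero-spread observation column(s): %s",
           paste(colnames(values)[sdev == 0], collapse = ", "))
  out <- matrix
  out$values <- sweep(sweep(values, 2, mu, "-"), 2, sdev, "/")
  out
}

#' Hierarchical clustering of observations
#'
#' Agglomerative clustering of the observation columns with Euclidean
#' distance and complete linkage. The expression matrix must already be
#' imputation-complete (see [build_matrix()]); normalize columns first with
#' [normalize_within_observation()] if desired. The two-way cut at the top
#' split is reported alongside the merge history, since the leading
#' question for a factorial design is which single factor divides the
#' observations first.
#'
#' @param matrix an [build_matrix()] (optionally normalized) result.
#' @return object of class `observation_dendrogram`: `hclust` (the
#'   [stats::hclust()] fit), `merge`, `height`, `labels`, and `cut2`
#'   (named two-group labels from [stats::cutree()]).
#' @export
cluster_observations <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  values <- matrix$values
  .assert(ncol(values) >= 2, "need at least 2 observations to cluster")
  .assert(!anyNA(values), "matrix must be imputation-complete")
  fit <- stats::hclust(stats::dist(t(values), method = "euclidean"),
                       method = "complete")
  structure(
    list(hclust = fit, merge = fit$merge, height = fit$height,
         labels = fit$labels, cut2 = stats::cutree(fit, k = 2)),
    class = "observation_dendrogram"
  )
}

#' @export
print.observation_dendrogram <- function(x, ...) {
  g1 <- names(x$cut2)[x$cut2 == 1]
  g2 <- names(x$cut2)[x$cut2 == 2]
  cat(sprintf("observation_dendrogram: %d leaves\n  top split: {%s} | {%s}\n",
              length(x$labels), paste(g1, collapse = ", "),
              paste(g2, collapse = ", ")))
  invisible(x)
}

#' Does the two-way cut separate a given observation set?
#'
#' Convenience predicate: `TRUE` when the dendrogram's top split puts the
#' listed observations in one branch and all remaining observations in the
#' other.
#'
#' @param dendrogram an [cluster_observations()] result.
#' @param observations keys expected to form one branch.
#' @return logical flag.
#' @export
cut_separates <- function(dendrogram, observations) {
  stopifnot(inherits(dendrogram, "observation_dendrogram"))
  labels <- names(dendrogram$cut2)
  inside <- labels %in% observations
  length(unique(dendrogram$cut2[inside])) == 1 &&
    length(unique(dendrogram$cut2[!inside])) == 1 &&
    dendrogram$cut2[inside][1L] != dendrogram$cut2[!inside][1L]
}
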