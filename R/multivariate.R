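#' Build a protein x observation expression matrix
#'
#' Extracts the log2-ratio grid for the chosen observations. Proteins whose
#' ratios are missing in every chosen observation are dropped with a
#' warning. The remaining missing cells are handled by `impute`:
#' `"zero"` (default) assigns the no-change log2 ratio 0 and records the
#' cell in the `imputed` mask, `"drop"` removes any protein with a missing
#' cell. Optionally, cells whose ratio test is non-significant can first be
#' treated as missing (`nonsig_as_missing`), reproducing the reading of the
#' clustering protocol under which "no significant change" cells carry no
#' information.
#'
#' @param table a [quant_table()].
#' @param observations keys to include, default all.
#' @param impute `"zero"` or `"drop"`.
#' @param nonsig_as_missing if `TRUE`, cells with p >= `nonsig_alpha` are
#'   blanked before imputation. Default `FALSE`.
#' @param nonsig_alpha threshold used by `nonsig_as_missing`.
#' @return object of class `expression_matrix`: list with `values` (numeric
#'   matrix, no missing cells), `imputed` (logical mask of cells that were
#'   filled in), `protein_ids`, `observation_keys`.
#' @export
build_matrix <- function(table, observations = NULL,
                         impute = c("zero", "drop"),
                         nonsig_as_missing = FALSE, nonsig_alpha = 0.05) {
  impute <- match.arg(impute)
  observations <- observations %||% table$observations
  .check_obs(table, observations)
  values <- table$log2_ratio[, observations, drop = FALSE]
  if (nonsig_as_missing) {
    p <- table$p_value[, observations, drop = FALSE]
    values[!is.na(p) & p >= nonsig_alpha] <- NA_real_
  }
  miss <- is.na(values)
  all_missing <- rowSums(!miss) == 0
  if (any(all_missing)) {
    warning(sprintf("dropping %d protein(s) with no observed value: %s",
                    sum(all_missing),
                    paste(utils::head(rownames(values)[all_missing], 5),
                          collapse = ", ")))
    values <- values[!all_missing, , drop = FALSE]
    miss <- miss[!all_missing, , drop = FALSE]
  }
  if (impute == "drop") {
    keep <- rowSums(miss) == 0
    values <- values[keep, , drop = FALSE]
    miss <- miss[keep, , drop = FALSE]
  } else {
    values[miss] <- 0
  }
  structure(
    list(values = values, imputed = miss,
         protein_ids = rownames(values), observation_keys = observations),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d proteins x %d observations (%d imputed cells)\n",
              nrow(x$values), ncol(x$values), sum(x$imputed)))
  invisible(x)
}

#' Principal component analysis of an expression matrix
#'
#' Proteins are the samples and observations the variables, so each protein
#' gets a score vector and each observation a loading vector (the biplot
#' orientation in which condition contrasts appear as projected axes and
#' per-protein outlyingness can be measured). Columns are mean-centered by
#' default and not variance-scaled; component variances are the eigenvalues
#' of the (n-1)-divisor sample covariance of the centered columns.
#'
#' @param matrix an [build_matrix()] result (or plain numeric matrix).
#' @param center,scale. passed to the decomposition; defaults centre only.
#' @return object of class `pca_result`: `scores` (proteins x components),
#'   `loadings` (observations x components, orthonormal columns),
#'   `lambda` (per-component variances), `explained_fraction`, `center`,
#'   `scale`.
#' @seealso [hotelling_rank()]
#' @export
run_pca <- function(matrix, center = TRUE, scale. = FALSE) {
  values <- if (inherits(matrix, "expression_matrix")) matrix$values else as.matrix(matrix)
  .assert(nrow(values) >= 2 && ncol(values) >= 2,
          "PCA needs at least 2 proteins and 2 observations")
  .assert(!anyNA(values), "PCA input must not contain missing cells")
  if (sum(apply(values, 2, stats::var)) == 0)
    .stopf("PCA input has zero total variance")
  fit <- stats::prcomp(values, center = center, scale. = scale.)
  lambda <- fit$sdev^2
  structure(
    list(scores = fit$x, loadings = fit$rotation, lambda = lambda,
         explained_fraction = lambda / sum(lambda),
         center = if (isTRUE(center)) fit$center else rep(0, ncol(values)),
         scale = fit$scale),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result: explained variance fractions\n")
  print(round(x$explained_fraction, 4))
  invisible(x)
}

#' Hotelling T-squared ranking of proteins
#'
#' Measures each protein's multivariate distance from the centre of the
#' data in the leading principal-component subspace:
#' T2_i = sum_k score_ik^2 / lambda_k over the smallest number of
#' components whose cumulative explained variance reaches
#' `variance_target`. With all components retained this equals the squared
#' Mahalanobis distance to the column means under the sample covariance.
#' Proteins are ranked by T2 descending; the `selected` subset holds those
#' with T2 strictly greater than the third quartile of all T2 values
#' (linear-interpolation quantile, the R default type 7).
#'
#' @param pca a [run_pca()] result.
#' @param variance_target fraction of variance the retained components must
#'   explain, in (0, 1]; default 0.90.
#' @return object of class `hotelling_rank`: `t2` (named vector in input
#'   order), `ranking` (data.frame sorted by T2 descending), `selected`
#'   (protein ids above the third quartile), `n_components_used`, `q3`.
#' @export
hotelling_rank <- function(pca, variance_target = 0.90) {
  stopifnot(inherits(pca, "pca_result"))
  .assert(is.numeric(variance_target) && variance_target > 0 &&
            variance_target <= 1, "variance_target must be in (0, 1]")
  cum <- cumsum(pca$explained_fraction)
  m <- which(cum >= variance_target - 1e-12)[1L]
  use <- seq_len(m)
  zero <- pca$lambda[use] <= 0
  if (any(zero)) {
    warning(sprintf("skipping %d zero-variance component(s) in T2", sum(zero)))
    use <- use[!zero]
  }
  t2 <- rowSums(sweep(pca$scores[, use, drop = FALSE]^2, 2,
                      pca$lambda[use], "/"))
  names(t2) <- rownames(pca$scores) %||% as.character(seq_along(t2))
  ord <- order(t2, decreasing = TRUE)
  q3 <- stats::quantile(t2, 0.75, names = FALSE, type = 7)
  structure(
    list(t2 = t2,
         ranking = data.frame(protein_id = names(t2)[ord], t2 = t2[ord],
                              row.names = NULL, stringsAsFactors = FALSE),
         selected = names(t2)[t2 > q3],
         n_components_used = m, q3 = q3),
    class = "hotelling_rank"
  )
}

#' @export
print.hotelling_rank <- function(x, ...) {
  cat(sprintf("hotelling_rank: %d components, Q3 = %.3f, %d/%d proteins selected\n",
              x$n_components_used, x$q3, length(x$selected), length(x$t2)))
  print(utils::head(x$ranking, 6))
  invisible(x)
}
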