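.anova_long <- function(matrix, use_imputed = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  values <- matrix$values
  keep <- if (use_imputed) !is.na(values) else !matrix$imputed
  obs <- rep(matrix$observation_keys, each = nrow(values))
  long <- data.frame(value = as.vector(values),
                     obs = factor(obs, levels = matrix$observation_keys),
                     stringsAsFactors = FALSE)[as.vector(keep), ]
  n_per <- table(long$obs)
  if (any(n_per < 2))
    .stopf("observation group(s) with fewer than 2 values: %s",
           paste(names(n_per)[n_per < 2], collapse = ", "))
  long
}

#' One-way ANOVA across observation groups
#'
#' Tests the null hypothesis that the mean protein log2 expression change is
#' equal across the observation columns, treating each column as a group of
#' protein-level values (proteins act as replicates within a group, i.e.
#' protein-level pairing across observations is deliberately ignored).
#' Cells imputed by [build_matrix()] are excluded by default, so group
#' sizes may be unequal.
#'
#' @param matrix an [build_matrix()] result.
#' @param use_imputed include imputed cells as data. Default `FALSE`.
#' @return object of class `anova_result`: `f_statistic`, `p_value`,
#'   `df_between`, `df_within`, `group_means`, `group_n`, `ms_within`, and
#'   the underlying `fit` ([stats::aov()] object).
#' @seealso [tukey_kramer()]
#' @export
observation_anova <- function(matrix, use_imputed = FALSE) {
  long <- .anova_long(matrix, use_imputed)
  fit <- stats::aov(value ~ obs, data = long)
  tab <- summary(fit)[[1L]]
  structure(
    list(f_statistic = tab[["F value"]][1L],
         p_value = tab[["Pr(>F)"]][1L],
         df_between = tab[["Df"]][1L],
         df_within = tab[["Df"]][2L],
         group_means = tapply(long$value, long$obs, mean),
         group_n = as.vector(table(long$obs)),
         ms_within = tab[["Mean Sq"]][2L],
         fit = fit),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("anova_result: F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}

#' Tukey-Kramer multiple comparison of observation means
#'
#' Simultaneous confidence intervals for all pairwise differences of
#' observation-group means, based on the studentized range distribution and
#' allowing unequal group sizes (Tukey-Kramer). The interval half-width for
#' pair (i, j) is `q(1 - alpha, k, df) / sqrt(2) * sqrt(MSw * (1/n_i + 1/n_j))`;
#' a pair is significant at the family level when its interval excludes 0.
#' Studentized-range quantiles come from [stats::qtukey()], computed
#' numerically rather than from printed tables.
#'
#' @param matrix an [build_matrix()] result.
#' @param family_alpha family-wise error level, default 0.05.
#' @param use_imputed include imputed cells as data. Default `FALSE`.
#' @return object of class `tukey_kramer`: `comparisons` data.frame with
#'   columns `obs_a`, `obs_b`, `mean_difference`, `ci_low`, `ci_high`,
#'   `p_adj`, `significant`; plus `family_alpha`, `ms_within`, `df_within`.
#' @export
tukey_kramer <- function(matrix, family_alpha = 0.05, use_imputed = FALSE) {
  .assert(is.numeric(family_alpha) && family_alpha > 0 && family_alpha < 1,
          "family_alpha must be in (0, 1)")
  long <- .anova_long(matrix, use_imputed)
  fit <- stats::aov(value ~ obs, data = long)
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - family_alpha)$obs
  pair <- strsplit(rownames(hsd), "-", fixed = FALSE)
  # observation keys contain no "-", so the first hyphen splits the pair
  obs_a <- vapply(rownames(hsd), function(s) sub("-.*$", "", s), "")
  obs_b <- vapply(rownames(hsd), function(s) sub("^[^-]*-", "", s), "")
  comparisons <- data.frame(
    obs_a = unname(obs_a), obs_b = unname(obs_b),
    mean_difference = hsd[, "diff"],
    ci_low = hsd[, "lwr"], ci_high = hsd[, "upr"],
    p_adj = hsd[, "p adj"],
    significant = hsd[, "lwr"] > 0 | hsd[, "upr"] < 0,
    row.names = NULL, stringsAsFactors = FALSE)
  tab <- summary(fit)[[1L]]
  structure(
    list(comparisons = comparisons, family_alpha = family_alpha,
         ms_within = tab[["Mean Sq"]][2L], df_within = tab[["Df"]][2L]),
    class = "tukey_kramer"
  )
}

#' @export
print.tukey_kramer <- function(x, ...) {
  sig <- x$comparisons[x$comparisons$significant, c("obs_a", "obs_b")]
  cat(sprintf("tukey_kramer: %d pairs, %d significant at family alpha %.2f\n",
              nrow(x$comparisons), nrow(sig), x$family_alpha))
  if (nrow(sig))
    cat(paste0("  ", sig$obs_a, " vs ", sig$obs_b, collapse = "\n"), "\n")
  invisible(x)
}
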