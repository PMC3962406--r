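#' Deviation-from-equal-expression distance
#'
#' Perpendicular distance of the point (e_a, e_b) from the identity line
#' e_a = e_b: `D = |e_a - e_b| / sqrt(2)`, in log2 units. A protein whose
#' expression change is identical in the two observations sits on the line
#' (D = 0); the farther from the line, the more the second condition
#' modifies the first condition's effect. Any positive rescaling of D
#' yields identical K-means cluster memberships, so the sqrt(2)
#' normalization is a geometric convention, not a tuning choice.
#'
#' @param e_a,e_b finite log2 ratios (vectorized).
#' @return non-negative distances.
#' @export
equal_expression_distance <- function(e_a, e_b) {
  .assert(all(is.finite(e_a)) && all(is.finite(e_b)),
          "log2 ratios must be finite")
  abs(e_a - e_b) / sqrt(2)
}

#' Classify a point against the equal-expression line
#'
#' `"lower_right"` when e_a > e_b (the second condition pushes expression
#' below the first condition's change), `"upper_left"` when e_a < e_b,
#' `"on_line"` when equal.
#'
#' @param e_a,e_b finite log2 ratios (vectorized).
#' @return character vector of section labels.
#' @export
classify_section <- function(e_a, e_b) {
  .assert(all(is.finite(e_a)) && all(is.finite(e_b)),
          "log2 ratios must be finite")
  ifelse(e_a > e_b, "lower_right", ifelse(e_a < e_b, "upper_left", "on_line"))
}

#' Build deviation points for two observations
#'
#' Assembles the (e_a, e_b) pairs, their deviation distances and section
#' labels for proteins that are expression-changed (ratio p < `alpha`) in
#' at least one of the two observations and carry a ratio in both.
#'
#' @param table a [quant_table()].
#' @param obs_a first observation key (x-axis, e.g. the ethanol effect).
#' @param obs_b second observation key (y-axis, e.g. knockout + ethanol).
#' @param alpha changed-protein p threshold, default 0.05; `NA` keeps all
#'   proteins with both ratios present.
#' @return data.frame of class `deviation_points` with columns
#'   `protein_id`, `gene_symbol`, `e_a`, `p_a`, `e_b`, `p_b`, `distance`,
#'   `section` (plus `function` tag when the table carries one).
#' @export
deviation_points <- function(table, obs_a, obs_b, alpha = 0.05) {
  .check_obs(table, c(obs_a, obs_b))
  if (!is.na(alpha)) table <- changed_proteins(table, c(obs_a, obs_b), alpha)
  e_a <- table$log2_ratio[, obs_a]
  e_b <- table$log2_ratio[, obs_b]
  keep <- !is.na(e_a) & !is.na(e_b)
  ann <- table$annotation[keep, , drop = FALSE]
  e_a <- e_a[keep]; e_b <- e_b[keep]
  out <- data.frame(
    protein_id = as.character(ann$accession),
    gene_symbol = if ("gene_symbol" %in% names(ann))
      as.character(ann$gene_symbol) else NA_character_,
    e_a = unname(e_a), p_a = unname(table$p_value[keep, obs_a]),
    e_b = unname(e_b), p_b = unname(table$p_value[keep, obs_b]),
    distance = equal_expression_distance(e_a, e_b),
    section = classify_section(e_a, e_b),
    row.names = NULL, stringsAsFactors = FALSE)
  if ("function" %in% names(ann)) out$`function` <- as.character(ann$`function`)
  attr(out, "obs_a") <- obs_a
  attr(out, "obs_b") <- obs_b
  class(out) <- c("deviation_points", "data.frame")
  out
}

# best k-means fit on a 1-D vector from a given start, NULL on degenerate start
.kmeans_try <- function(x, centers) {
  if (anyDuplicated(centers)) return(NULL)
  tryCatch(stats::kmeans(x, centers = matrix(centers, ncol = 1)),
           error = function(e) NULL, warning = function(w) NULL)
}

#' K-means clustering on the deviation distance
#'
#' One-dimensional K-means on the deviation-from-equal-expression
#' distances. Clustering the scalar distance (not the 2-D point) groups
#' proteins into bands around the equal-expression line, so a point and its
#' reflection across the line always share a cluster. Clusters are
#' renumbered by ascending centroid: cluster 1 hugs the line (conditions
#' agree), cluster `k` is farthest from it (strongest interaction).
#'
#' Initialization is deterministic (centroids at the 1/6, 3/6, 5/6 ...
#' quantiles of the distances) with `restarts` additional seeded random
#' starts; the fit with the lowest within-cluster sum of squares wins, so
#' results are reproducible for a fixed seed.
#'
#' @param points a [deviation_points()] data.frame.
#' @param k number of clusters, default 3.
#' @param restarts random restarts on top of the deterministic start.
#' @param seed RNG seed for the restarts.
#' @return object of class `deviation_kmeans`: `points` (the input with a
#'   `cluster` column), `centroids` (ascending), `withinss`,
#'   `tot_withinss`, `k`.
#' @export
kmean_deviation <- function(points, k = 3, restarts = 10, seed = 1) {
  stopifnot(inherits(points, "deviation_points"))
  x <- points$distance
  n_distinct <- length(unique(x))
  if (k > n_distinct)
    .stopf("k = %d exceeds the %d distinct distance value(s)", k, n_distinct)
  starts <- list(stats::quantile(x, (2 * seq_len(k) - 1) / (2 * k),
                                 names = FALSE, type = 7))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  starts <- c(starts, replicate(restarts, sample(unique(x), k), simplify = FALSE))
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  fits <- Filter(Negate(is.null), lapply(starts, .kmeans_try, x = x))
  .assert(length(fits) > 0, "k-means failed from every start")
  best <- fits[[which.min(vapply(fits, function(f) f$tot.withinss, 0))]]
  ord <- order(best$centers[, 1])
  relabel <- match(seq_len(k), ord)
  points$cluster <- relabel[best$cluster]
  structure(
    list(points = points, centroids = unname(best$centers[ord, 1]),
         withinss = unname(best$withinss[ord]),
         tot_withinss = best$tot.withinss, k = k),
    class = "deviation_kmeans"
  )
}

#' @export
print.deviation_kmeans <- function(x, ...) {
  cat(sprintf("deviation_kmeans: k = %d, cluster sizes %s, centroids %s\n",
              x$k, paste(tabulate(x$points$cluster, x$k), collapse = "/"),
              paste(sprintf("%.3f", x$centroids), collapse = ", ")))
  invisible(x)
}

#' Section-by-cluster contingency counts
#'
#' Cross-tabulates the scatter section (lower-right / upper-left / on-line)
#' against the K-means cluster label, and emits the publication-style
#' report of the outer clusters (cluster >= 2), grouped by section and
#' sorted by `e_a` descending within section.
#'
#' @param points a data.frame with `section` and `cluster` columns — either
#'   the `points` element of a [kmean_deviation()] result or a table with
#'   externally assigned labels.
#' @return list with `crosstab` (section x cluster count matrix) and
#'   `report` (data.frame of cluster >= 2 points).
#' @export
section_cluster_crosstab <- function(points) {
  if (inherits(points, "deviation_kmeans")) points <- points$points
  .assert(all(c("section", "cluster") %in% names(points)),
          "points must carry 'section' and 'cluster' columns")
  crosstab <- as.matrix(table(section = points$section,
                              cluster = points$cluster))
  outer <- points[points$cluster >= 2, , drop = FALSE]
  if (nrow(outer) && "e_a" %in% names(outer)) {
    outer <- outer[order(outer$section, -rank(outer$e_a)), , drop = FALSE]
    rownames(outer) <- NULL
  }
  list(crosstab = crosstab, report = outer)
}
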