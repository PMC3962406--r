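#' Significance criteria for protein expression changes
#'
#' A changed protein must satisfy |log2 R| strictly greater than
#' `min_abs_log2` *and* ratio p strictly below `alpha`. The strict
#' inequalities mean boundary values (|log2 R| = 1, p = 0.05) are excluded.
#' `alpha = NA` disables the p criterion, which is the right mode for tables
#' that list only already-tested significant entries and therefore print no
#' p-values.
#'
#' @param min_abs_log2 threshold on |log2 ratio| (log2 units), default 1,
#'   i.e. a two-fold change.
#' @param alpha ratio-test p-value threshold in (0, 1), default 0.05, or
#'   `NA` to skip the p filter.
#' @return an object of class `significance_criteria`.
#' @export
significance_criteria <- function(min_abs_log2 = 1, alpha = 0.05) {
  .assert(is.numeric(min_abs_log2) && length(min_abs_log2) == 1 &&
            min_abs_log2 >= 0, "min_abs_log2 must be a single value >= 0")
  .assert(length(alpha) == 1 && (is.na(alpha) ||
            (is.numeric(alpha) && alpha > 0 && alpha < 1)),
          "alpha must be in (0, 1), or NA to disable the p filter")
  structure(list(min_abs_log2 = min_abs_log2, alpha = as.numeric(alpha)),
            class = "significance_criteria")
}

#' Significantly changed proteins in one observation
#'
#' Applies the fold-change / p-value criteria to a single observation.
#' Proteins with a missing ratio never pass. Returns the passing subset
#' together with up/down counts (by the sign of the log2 ratio).
#'
#' @param table a [quant_table()].
#' @param obs observation key present in the table.
#' @param criteria a [significance_criteria()].
#' @return object of class `significant_set`: list with elements `table`
#'   (the passing [quant_table()] subset), `obs`, `n`, `n_up`, `n_down`,
#'   `criteria`, and `parent_accessions` (all accessions of the parent
#'   table, used by [overlap_analysis()] validation).
#' @examples
#' tab <- read_quant_table(plexfactor_example("ethanol_gender"))
#' significant_proteins(tab, "116:114", significance_criteria(alpha = NA))
#' @export
significant_proteins <- function(table, obs,
                                 criteria = significance_criteria()) {
  .check_obs(table, obs)
  stopifnot(inherits(criteria, "significance_criteria"))
  lr <- table$log2_ratio[, obs]
  p <- table$p_value[, obs]
  pass <- !is.na(lr) & abs(lr) > criteria$min_abs_log2
  if (!is.na(criteria$alpha))
    pass <- pass & !is.na(p) & p < criteria$alpha
  subset <- table[which(pass)]
  structure(
    list(table = subset, obs = obs,
         n = n_proteins(subset),
         n_up = sum(subset$log2_ratio[, obs] > 0),
         n_down = sum(subset$log2_ratio[, obs] < 0),
         criteria = criteria,
         parent_accessions = as.character(table$annotation$accession)),
    class = "significant_set"
  )
}

#' @export
print.significant_set <- function(x, ...) {
  cat(sprintf("significant_set [%s]: %d proteins (%d up, %d down)\n",
              x$obs, x$n, x$n_up, x$n_down))
  invisible(x)
}

#' Proteins changed in at least one observation
#'
#' Selects proteins whose ratio p-value is strictly below `alpha` in one or
#' more of the listed observations. This is the input filter for PCA,
#' ANOVA and hierarchical clustering over the multi-observation matrix.
#'
#' @param table a [quant_table()].
#' @param observations keys to test over; defaults to all observations.
#' @param alpha p-value threshold, default 0.05.
#' @return the passing [quant_table()] subset (row order preserved).
#' @export
changed_proteins <- function(table, observations = NULL, alpha = 0.05) {
  observations <- observations %||% table$observations
  .assert(length(observations) > 0, "at least one observation is required")
  .check_obs(table, observations)
  p <- table$p_value[, observations, drop = FALSE]
  hit <- !is.na(p) & p < alpha
  table[which(rowSums(hit) > 0)]
}

#' Overlap of two significant-protein sets
#'
#' Partitions two significant sets (from the same parent table) into shared
#' and set-exclusive accessions, flags shared proteins whose log2 ratios
#' point in opposite directions in the two observations, and tallies
#' up/down counts per partition.
#'
#' @param set_a,set_b [significant_proteins()] results from the same parent
#'   table.
#' @return object of class `overlap_report`: list with accession vectors
#'   `shared`, `only_a`, `only_b`, `opposite_direction` (a subset of
#'   `shared`), the observation keys, and a `counts` data.frame of up/down
#'   tallies per partition.
#' @export
overlap_analysis <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "significant_set"),
            inherits(set_b, "significant_set"))
  acc_a <- as.character(set_a$table$annotation$accession)
  acc_b <- as.character(set_b$table$annotation$accession)
  stray <- c(setdiff(acc_a, set_a$parent_accessions),
             setdiff(acc_b, set_b$parent_accessions))
  if (length(stray))
    .stopf("accession(s) not in the parent table: %s",
           paste(stray, collapse = ", "))
  if (!setequal(set_a$parent_accessions, set_b$parent_accessions))
    .stopf("the two sets come from different parent tables")
  shared <- intersect(acc_a, acc_b)
  only_a <- setdiff(acc_a, shared)
  only_b <- setdiff(acc_b, shared)
  sign_a <- sign(set_a$table$log2_ratio[match(shared, acc_a), set_a$obs])
  sign_b <- sign(set_b$table$log2_ratio[match(shared, acc_b), set_b$obs])
  opposite <- shared[sign_a * sign_b < 0]
  count_updown <- function(set, acc) {
    lr <- set$table$log2_ratio[match(acc, as.character(set$table$annotation$accession)),
                               set$obs]
    c(up = sum(lr > 0), down = sum(lr < 0))
  }
  counts <- rbind(shared_a = count_updown(set_a, shared),
                  shared_b = count_updown(set_b, shared),
                  only_a = count_updown(set_a, only_a),
                  only_b = count_updown(set_b, only_b))
  structure(
    list(shared = shared, only_a = only_a, only_b = only_b,
         opposite_direction = opposite,
         obs_a = set_a$obs, obs_b = set_b$obs,
         counts = as.data.frame(counts)),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report [%s vs %s]: %d shared, %d only-a, %d only-b, %d opposite-direction\n",
              x$obs_a, x$obs_b, length(x$shared), length(x$only_a),
              length(x$only_b), length(x$opposite_direction)))
  invisible(x)
}
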