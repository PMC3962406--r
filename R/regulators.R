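#' Hypergeometric overlap p-value
#'
#' Upper-tail probability that at least `overlap` of a regulator's known
#' targets appear when `dataset_size` genes are drawn without replacement
#' from a background of `background_size` genes containing
#' `regulator_targets` targets: `P(X >= overlap)` for
#' X ~ Hypergeometric.
#'
#' @param overlap observed number of the regulator's targets in the
#'   dataset.
#' @param dataset_size number of genes in the analyzed dataset.
#' @param regulator_targets number of the regulator's targets in the
#'   background.
#' @param background_size total number of quantified genes.
#' @return the tail probability, in (0, 1].
#' @export
overlap_pvalue <- function(overlap, dataset_size, regulator_targets,
                           background_size) {
  .assert(overlap >= 0 && dataset_size >= 0 && regulator_targets >= 0 &&
            background_size >= 1, "counts must be non-negative")
  .assert(overlap <= min(dataset_size, regulator_targets),
          "overlap cannot exceed dataset size or the regulator's target count")
  .assert(regulator_targets <= background_size,
          "regulator target count cannot exceed the background size")
  .assert(dataset_size <= background_size,
          "dataset size cannot exceed the background size")
  stats::phyper(overlap - 1, regulator_targets,
                background_size - regulator_targets, dataset_size,
                lower.tail = FALSE)
}

.dataset_directions <- function(dataset, obs) {
  .check_obs(dataset, obs)
  .assert("gene_symbol" %in% names(dataset$annotation),
          "dataset proteins must carry gene symbols")
  lr <- dataset$log2_ratio[, obs]
  data.frame(gene = as.character(dataset$annotation$gene_symbol),
             direction = as.integer(sign(lr)),
             stringsAsFactors = FALSE)
}

#' Score upstream regulators on a filtered dataset
#'
#' For every regulator in the network, intersects its known targets with
#' the dataset's gene symbols and scores the agreement between each
#' target's observed direction (the sign of its log2 ratio in `obs`) and
#' the signed regulator-target edge. A target is *consistent* with
#' regulator activation when its direction equals the edge sign. The
#' activation z-score is `(n_consistent - n_inconsistent) / sqrt(N)` over
#' the N sign-scorable in-dataset targets; z >= +2 predicts the regulator
#' activated, z <= -2 inhibited. Enrichment of the regulator's targets in
#' the dataset is measured by the hypergeometric [overlap_pvalue()]
#' against a background of `background_size` quantified genes (every
#' in-dataset target counts toward the overlap, signed or not).
#'
#' This is the open, unweighted form of the commercial upstream-regulator
#' score: no literature-derived edge weights or bias corrections, so
#' published weighted z-scores are approximated, not reproduced.
#'
#' @param dataset a filtered [quant_table()] (e.g. the outer K-means
#'   clusters restricted to significantly changed proteins) whose
#'   annotation carries `gene_symbol`.
#' @param obs observation key giving the observed directions.
#' @param network a [read_network()] edge list.
#' @param background_size number of quantified genes the dataset was drawn
#'   from; must be at least the dataset size.
#' @return data.frame of class `regulator_scores`, one row per regulator:
#'   `regulator`, `n_targets_network`, `n_overlap`, `n_targets_scored`,
#'   `n_consistent`, `n_inconsistent`, `z`, `overlap_p`,
#'   `predicted_state`, and comma-separated `consistent_targets` /
#'   `inconsistent_targets`.
#' @export
score_regulators <- function(dataset, obs, network, background_size) {
  stopifnot(inherits(network, "regulator_network"))
  dirs <- .dataset_directions(dataset, obs)
  .assert(background_size >= nrow(dirs),
          "background_size must be at least the dataset size")
  res <- lapply(split(network, network$regulator), function(edges) {
    hit <- match(edges$target, dirs$gene)
    present <- !is.na(hit)
    n_overlap <- sum(present)
    direction <- dirs$direction[hit[present]]
    esign <- edges$sign[present]
    scorable <- !is.na(esign) & !is.na(direction) & direction != 0
    n_cons <- sum(scorable & direction == esign)
    n_incons <- sum(scorable & direction == -esign)
    n_scored <- n_cons + n_incons
    z <- if (n_scored > 0) (n_cons - n_incons) / sqrt(n_scored) else NA_real_
    data.frame(
      regulator = edges$regulator[1L],
      n_targets_network = nrow(edges),
      n_overlap = n_overlap,
      n_targets_scored = n_scored,
      n_consistent = n_cons,
      n_inconsistent = n_incons,
      z = z,
      overlap_p = overlap_pvalue(n_overlap, nrow(dirs),
                                 min(nrow(edges), background_size),
                                 background_size),
      predicted_state = if (is.na(z)) "undetermined" else if (z >= 2)
        "activated" else if (z <= -2) "inhibited" else "undetermined",
      consistent_targets = paste(edges$target[present][scorable &
                                   direction == esign], collapse = ","),
      inconsistent_targets = paste(edges$target[present][scorable &
                                     direction == -esign], collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-abs(ifelse(is.na(out$z), 0, out$z)), out$overlap_p), ]
  rownames(out) <- NULL
  class(out) <- c("regulator_scores", "data.frame")
  out
}

#' Per-target consistency report for one regulator
#'
#' Labels each in-dataset target of `regulator` by how its observed
#' direction relates to the signed edge: `consistent_with_activation`
#' (direction equals edge sign), `consistent_with_inhibition` (direction
#' opposes edge sign), `sign_unknown` (unsigned edge) or
#' `direction_unknown` (zero/missing observed ratio).
#'
#' @inheritParams score_regulators
#' @param regulator regulator name present in the network.
#' @return data.frame with columns `target`, `direction` (+1/-1/0/NA),
#'   `edge_sign`, `status`.
#' @export
consistency_report <- function(dataset, obs, network, regulator) {
  stopifnot(inherits(network, "regulator_network"))
  edges <- network[network$regulator == regulator, , drop = FALSE]
  .assert(nrow(edges) > 0, "regulator '%s' not in the network", regulator)
  dirs <- .dataset_directions(dataset, obs)
  hit <- match(edges$target, dirs$gene)
  present <- !is.na(hit)
  edges <- edges[present, , drop = FALSE]
  direction <- dirs$direction[hit[present]]
  status <- ifelse(is.na(edges$sign), "sign_unknown",
            ifelse(is.na(direction) | direction == 0, "direction_unknown",
            ifelse(direction == edges$sign, "consistent_with_activation",
                   "consistent_with_inhibition")))
  data.frame(target = edges$target, direction = direction,
             edge_sign = edges$sign, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}
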