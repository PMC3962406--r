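#' Default 8-plex channel-to-condition map
#'
#' The reporter-channel layout of a 2x2x2 (knockout x ethanol x gender)
#' factorial design: channel 114 is the reference condition (wild-type,
#' control diet, male) and the remaining seven channels carry every other
#' factor combination.
#'
#' @return data.frame with columns `channel`, `ko`, `ethanol`, `female`,
#'   `label`.
#' @export
default_channel_map <- function() {
  data.frame(
    channel = c("113", "114", "115", "116", "117", "118", "119", "121"),
    ko      = c(0, 0, 0, 0, 1, 1, 1, 1),
    ethanol = c(0, 0, 1, 1, 0, 0, 1, 1),
    female  = c(1, 0, 1, 0, 1, 0, 1, 0),
    label   = c("G", "ref", "E+G", "E", "KO+G", "KO", "KO+E+G", "KO+E"),
    stringsAsFactors = FALSE)
}

#' The seven reference-relative observation keys
#'
#' Every non-reference channel ratioed against the reference channel 114.
#'
#' @return character vector of seven `"num:114"` keys.
#' @export
factorial_observations <- function() {
  map <- default_channel_map()
  paste0(map$channel[map$channel != "114"], ":114")
}

#' Configuration for the factorial proteome simulator
#'
#' Defines a ground-truth model for an 8-channel factorial quant table.
#' Each protein's true log2 ratio versus the reference channel is
#' `beta_ko * KO + beta_e * E + beta_g * G + beta_ko_x_e * KO * E`, with
#' each coefficient applied only to its disjoint block of effect-carrying
#' proteins (a fraction `effect_fraction` of the proteins per effect;
#' remaining proteins are null). Observed replicate log2 ratios are truth
#' plus Normal(0, `noise_sd`) noise; the per-cell ratio p-value is a
#' two-sided one-sample t test of the replicates against 0, a transparent
#' stand-in for proprietary ratio statistics. Cells then go missing
#' independently with probability `missing_prob`.
#'
#' Defaults describe a liver study-like regime: a dominant knockout main
#' effect (|beta_ko| > |beta_e| > |beta_g|), a knockout-by-ethanol
#' interaction that reverses the ethanol induction, four replicates per
#' condition and moderate spectral noise.
#'
#' @param n_proteins number of simulated proteins.
#' @param n_replicates peptide-level replicates per protein per
#'   observation (>= 2).
#' @param beta_ko,beta_e,beta_g main-effect log2 shifts.
#' @param beta_ko_x_e knockout-by-ethanol interaction log2 shift.
#' @param effect_fraction fraction of proteins carrying each effect.
#' @param noise_sd replicate-level log2 noise standard deviation (> 0).
#' @param missing_prob per-cell missingness probability.
#' @param seed RNG seed.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 150, n_replicates = 4,
                             beta_ko = 2, beta_e = 1, beta_g = 0.5,
                             beta_ko_x_e = -1.5, effect_fraction = 0.1,
                             noise_sd = 0.5, missing_prob = 0.05,
                             seed = 1) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(n_proteins) && n_proteins >= 1, "n_proteins must be >= 1")
  chk(is.numeric(n_replicates) && n_replicates >= 2, "n_replicates must be >= 2")
  chk(is.numeric(effect_fraction) && effect_fraction >= 0 &&
        effect_fraction <= 1, "effect_fraction must be in [0, 1]")
  chk(4 * effect_fraction <= 1,
      "effect blocks are disjoint: 4 * effect_fraction must be <= 1")
  chk(is.numeric(noise_sd) && noise_sd > 0, "noise_sd must be > 0")
  chk(is.numeric(missing_prob) && missing_prob >= 0 && missing_prob < 1,
      "missing_prob must be in [0, 1)")
  chk(all(is.finite(c(beta_ko, beta_e, beta_g, beta_ko_x_e))),
      "effect sizes must be finite")
  if (length(problems))
    .stopf("invalid synthetic_config:\n  - %s",
           paste(problems, collapse = "\n  - "))
  structure(list(n_proteins = as.integer(n_proteins),
                 n_replicates = as.integer(n_replicates),
                 beta_ko = beta_ko, beta_e = beta_e, beta_g = beta_g,
                 beta_ko_x_e = beta_ko_x_e,
                 effect_fraction = effect_fraction, noise_sd = noise_sd,
                 missing_prob = missing_prob, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a factorial quant table with known ground truth
#'
#' Simulates the seven reference-relative observations of the 2x2x2 design
#' under the model of [synthetic_config()]. Identical configurations
#' (including the seed) produce identical tables.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_proteome` with `table` (a
#'   [quant_table()]), `truth` (data.frame of per-protein effect flags and
#'   the `effect` label), `truth_matrix` (true log2 ratios, proteins x
#'   observations) and `config`.
#' @export
generate_quant_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  obs <- factorial_observations()
  map <- default_channel_map()
  num <- sub(":114$", "", obs)
  design <- map[match(num, map$channel), c("ko", "ethanol", "female")]

  m <- round(config$effect_fraction * n)
  effect <- rep("null", n)
  if (m > 0) {
    effect[seq_len(m)] <- "ko"
    effect[m + seq_len(m)] <- "ethanol"
    effect[2 * m + seq_len(m)] <- "gender"
    effect[3 * m + seq_len(m)] <- "ko_x_ethanol"
  }
  beta <- cbind(ko = (effect == "ko") * config$beta_ko,
                ethanol = (effect == "ethanol") * config$beta_e,
                gender = (effect == "gender") * config$beta_g,
                interaction = (effect == "ko_x_ethanol") * config$beta_ko_x_e)
  x <- rbind(design$ko, design$ethanol, design$female,
             design$ko * design$ethanol)
  truth <- beta %*% x
  colnames(truth) <- obs

  k <- length(obs); r <- config$n_replicates
  noise <- array(stats::rnorm(n * k * r, 0, config$noise_sd), c(n, k, r))
  reps <- array(rep(truth, r), c(n, k, r)) + noise
  mean_lr <- apply(reps, c(1, 2), mean)
  sd_lr <- apply(reps, c(1, 2), stats::sd)
  tstat <- mean_lr / (sd_lr / sqrt(r))
  pval <- 2 * stats::pt(-abs(tstat), df = r - 1)

  if (config$missing_prob > 0) {
    drop <- matrix(stats::runif(n * k) < config$missing_prob, n, k)
    mean_lr[drop] <- NA_real_
    pval[drop] <- NA_real_
  }
  dimnames(mean_lr) <- dimnames(pval) <- list(NULL, obs)

  acc <- sprintf("SYN%04d", seq_len(n))
  annotation <- data.frame(accession = acc, gene_symbol = acc,
                           `function` = effect, check.names = FALSE,
                           stringsAsFactors = FALSE)
  structure(
    list(table = quant_table(annotation, mean_lr, pval),
         truth = data.frame(accession = acc, effect = effect,
                            stringsAsFactors = FALSE),
         truth_matrix = `rownames<-`(truth, acc),
         config = config),
    class = "synthetic_proteome"
  )
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat(sprintf("synthetic_proteome: %d proteins, %d replicates, effects: %s\n",
              x$config$n_proteins, x$config$n_replicates,
              paste(sprintf("%s=%d", c("ko", "ethanol", "gender", "ko_x_ethanol"),
                            tabulate(factor(x$truth$effect,
                                            c("ko", "ethanol", "gender",
                                              "ko_x_ethanol")), 4)),
                    collapse = ", ")))
  invisible(x)
}

#' Pipeline recovery report over repeated simulations
#'
#' Runs the full analysis chain on `n_sims` independently seeded
#' simulations from `config` and summarizes how well each stage recovers
#' the planted structure:
#' \describe{
#'   \item{`ko_separation_rate`}{fraction of runs in which the two-way
#'     hierarchical cut puts the four knockout observations in one branch.}
#'   \item{`tukey_any_significant_rate`}{fraction of runs with at least one
#'     significant Tukey-Kramer pair (under an all-null configuration this
#'     is the family-wise false-positive rate).}
#'   \item{`interaction_enrichment`}{pooled 2x2 counts of
#'     interaction-carrying proteins versus membership in the farthest
#'     K-means cluster, with the odds ratio (0.5 added to each cell when
#'     any is empty).}
#'   \item{`t2_spearman`}{mean Spearman correlation between each protein's
#'     true total effect magnitude and its Hotelling T2 (`NA` when truth
#'     is all-null).}
#' }
#'
#' @param config a [synthetic_config()]; simulation i runs with seed
#'   `config$seed + i - 1`.
#' @param n_sims number of simulation replicates, default 200.
#' @param family_alpha Tukey-Kramer family level.
#' @param k K-means cluster count.
#' @param alpha changed-protein threshold for the K-means input.
#' @return list of class `recovery_report`.
#' @export
recovery_suite <- function(config, n_sims = 200, family_alpha = 0.05,
                           k = 3, alpha = 0.05) {
  stopifnot(inherits(config, "synthetic_config"))
  map <- default_channel_map()
  ko_obs <- paste0(map$channel[map$ko == 1], ":114")
  sep <- logical(n_sims); any_sig <- logical(n_sims)
  rho <- rep(NA_real_, n_sims)
  enrich <- matrix(0, 2, 2,
                   dimnames = list(interaction = c("yes", "no"),
                                   farthest_cluster = c("in", "out")))
  for (i in seq_len(n_sims)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    sim <- generate_quant_table(cfg)
    em <- build_matrix(sim$table)
    sep[i] <- cut_separates(cluster_observations(em), ko_obs)
    any_sig[i] <- any(tukey_kramer(em, family_alpha)$comparisons$significant)

    pts <- deviation_points(sim$table, "116:114", "121:114", alpha)
    if (nrow(pts) >= k && length(unique(pts$distance)) >= k) {
      km <- kmean_deviation(pts, k = k, seed = cfg$seed)
      carriers <- sim$truth$accession[sim$truth$effect == "ko_x_ethanol"]
      is_carrier <- km$points$protein_id %in% carriers
      in_far <- km$points$cluster == k
      enrich <- enrich + rbind(c(sum(is_carrier & in_far),
                                 sum(is_carrier & !in_far)),
                               c(sum(!is_carrier & in_far),
                                 sum(!is_carrier & !in_far)))
    }

    truth_mag <- sqrt(rowSums(sim$truth_matrix[em$protein_ids, , drop = FALSE]^2))
    if (length(unique(truth_mag)) > 1) {
      t2 <- hotelling_rank(run_pca(em))$t2
      rho[i] <- stats::cor(truth_mag, t2, method = "spearman")
    }
  }
  or <- if (any(enrich == 0))
    prod(diag(enrich + 0.5)) / prod((enrich + 0.5)[cbind(1:2, 2:1)])
  else prod(diag(enrich)) / prod(enrich[cbind(1:2, 2:1)])
  structure(
    list(n_sims = n_sims,
         ko_separation_rate = mean(sep),
         tukey_any_significant_rate = mean(any_sig),
         interaction_enrichment = list(counts = enrich, odds_ratio = or),
         t2_spearman = if (all(is.na(rho))) NA_real_ else mean(rho, na.rm = TRUE),
         config = config),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0("recovery_report (%d simulations):\n",
                     "  KO two-way-cut separation rate: %.3f\n",
                     "  Tukey-Kramer any-significant rate: %.3f\n",
                     "  interaction enrichment odds ratio: %.3g\n",
                     "  T2 ~ true-effect Spearman: %s\n"),
              x$n_sims, x$ko_separation_rate, x$tukey_any_significant_rate,
              x$interaction_enrichment$odds_ratio,
              ifelse(is.na(x$t2_spearman), "NA",
                     sprintf("%.3f", x$t2_spearman))))
  invisible(x)
}
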