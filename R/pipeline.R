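.write_stage_tsv <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.pipeline_defaults <- function(config) {
  config$filter <- utils::modifyList(
    list(obs = NULL, min_abs_log2 = 1, alpha = 0.05), config$filter %||% list())
  config$changed <- utils::modifyList(
    list(observations = NULL, alpha = 0.05), config$changed %||% list())
  config$pca <- utils::modifyList(
    list(variance_target = 0.90, scale = FALSE, impute = "zero"),
    config$pca %||% list())
  config$anova <- utils::modifyList(
    list(family_alpha = 0.05), config$anova %||% list())
  config$kmeans <- utils::modifyList(
    list(obs_a = NULL, obs_b = NULL, k = 3, alpha = 0.05, seed = 1,
         restarts = 10), config$kmeans %||% list())
  config$regulators <- utils::modifyList(
    list(obs = NULL, background_size = NULL), config$regulators %||% list())
  config
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates the stages `filter` (significance filtering), `pca` (PCA +
#' Hotelling T2 on the changed-protein matrix), `anova` (one-way ANOVA +
#' Tukey-Kramer), `hclust` (normalized complete-linkage clustering of
#' observations), `kmeans` (deviation-distance K-means) and `regulators`
#' (activation scoring of the outer K-means clusters), writing one or more
#' plot-ready TSVs per stage plus a `manifest.json` recording package
#' version, seeds, thresholds, input checksum and per-stage output
#' checksums. Stage outputs are pure functions of (input, config), so
#' identical runs yield identical manifests.
#'
#' A stage that errors is recorded as `failed` and every later stage is
#' `skipped`; outputs already written are retained.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognized fields: `input` (quant table TSV, required), `network`
#'   (edge-list TSV, needed by the `regulators` stage), `outdir`
#'   (required), `stages` (subset of the six stage names, default all
#'   runnable given the config), and per-stage parameter lists `filter`
#'   (`obs`, `min_abs_log2`, `alpha`), `changed` (`observations`,
#'   `alpha`), `pca` (`variance_target`, `scale`, `impute`), `anova`
#'   (`family_alpha`), `kmeans` (`obs_a`, `obs_b`, `k`, `alpha`, `seed`,
#'   `restarts`), `regulators` (`obs`, `background_size`).
#' @return the manifest (a list), invisibly. Inspect `$stages` for
#'   per-stage status.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    .assert(file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  .assert(is.list(config), "config must be a list or a YAML file path")
  .assert(!is.null(config$input), "config$input is required")
  .assert(!is.null(config$outdir), "config$outdir is required")
  .assert(file.exists(config$input), "input file not found: %s", config$input)
  if (!is.null(config$network))
    .assert(file.exists(config$network), "network file not found: %s",
            config$network)
  config <- .pipeline_defaults(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  table <- read_quant_table(config$input)
  stages <- config$stages %||% c(
    if (!is.null(config$filter$obs)) "filter",
    "pca", "anova", "hclust",
    if (!is.null(config$kmeans$obs_a)) "kmeans",
    if (!is.null(config$network) && !is.null(config$regulators$obs))
      "regulators")
  .assert(all(stages %in% c("filter", "pca", "anova", "hclust", "kmeans",
                            "regulators")),
          "unknown stage name(s): %s",
          paste(setdiff(stages, c("filter", "pca", "anova", "hclust",
                                  "kmeans", "regulators")), collapse = ", "))
  input_md5 <- .md5(config$input)
  prov <- function(stage) sprintf("plexfactor %s | stage=%s | input_md5=%s",
                                  as.character(utils::packageVersion("plexfactor")),
                                  stage, input_md5)
  outfile <- function(name) file.path(config$outdir, name)
  manifest <- list(
    package = "plexfactor",
    version = as.character(utils::packageVersion("plexfactor")),
    input = config$input, input_md5 = input_md5,
    parameters = config[c("filter", "changed", "pca", "anova", "kmeans",
                          "regulators")],
    stages = list())
  state <- new.env(parent = emptyenv())
  state$failed <- FALSE
  state$km <- NULL

  run_stage <- function(name, fun) {
    if (state$failed) {
      manifest$stages[[name]] <<- list(status = "skipped", outputs = list())
      return(invisible())
    }
    res <- tryCatch(list(ok = TRUE, outputs = fun()),
                    error = function(e) list(ok = FALSE,
                                             message = conditionMessage(e)))
    if (res$ok) {
      outs <- lapply(res$outputs, function(p)
        list(path = p, md5 = .md5(p)))
      manifest$stages[[name]] <<- list(status = "complete", outputs = outs)
    } else {
      message(sprintf("stage '%s' failed: %s", name, res$message))
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = res$message, outputs = list())
      state$failed <- TRUE
    }
  }

  changed <- NULL
  get_changed <- function() {
    if (is.null(changed))
      changed <<- changed_proteins(table, config$changed$observations,
                                   config$changed$alpha)
    changed
  }

  for (stage in stages) {
    switch(stage,
      filter = run_stage("filter", function() {
        crit <- significance_criteria(config$filter$min_abs_log2,
                                      config$filter$alpha)
        sig <- significant_proteins(table, config$filter$obs, crit)
        path <- outfile("filter.tsv")
        df <- data.frame(accession = sig$table$annotation$accession,
                         log2_ratio = sig$table$log2_ratio[, sig$obs],
                         p_value = sig$table$p_value[, sig$obs],
                         direction = ifelse(sig$table$log2_ratio[, sig$obs] > 0,
                                            "up", "down"))
        .write_stage_tsv(df, path, prov("filter"))
        list(path)
      }),
      pca = run_stage("pca", function() {
        em <- build_matrix(get_changed(), impute = config$pca$impute)
        pca <- run_pca(em, scale. = isTRUE(config$pca$scale))
        hr <- hotelling_rank(pca, config$pca$variance_target)
        p1 <- .write_stage_tsv(
          data.frame(protein_id = rownames(pca$scores), pca$scores),
          outfile("pca_scores.tsv"), prov("pca"))
        p2 <- .write_stage_tsv(
          data.frame(observation = rownames(pca$loadings), pca$loadings),
          outfile("pca_loadings.tsv"), prov("pca"))
        p3 <- .write_stage_tsv(
          data.frame(component = seq_along(pca$lambda),
                     variance = pca$lambda,
                     explained_fraction = pca$explained_fraction),
          outfile("pca_variance.tsv"), prov("pca"))
        p4 <- .write_stage_tsv(
          transform(hr$ranking,
                    selected = hr$ranking$protein_id %in% hr$selected),
          outfile("hotelling_t2.tsv"), prov("pca"))
        list(p1, p2, p3, p4)
      }),
      anova = run_stage("anova", function() {
        em <- build_matrix(get_changed(), impute = config$pca$impute)
        an <- observation_anova(em)
        tk <- tukey_kramer(em, config$anova$family_alpha)
        p1 <- .write_stage_tsv(
          data.frame(f_statistic = an$f_statistic, p_value = an$p_value,
                     df_between = an$df_between, df_within = an$df_within),
          outfile("anova.tsv"), prov("anova"))
        p2 <- .write_stage_tsv(tk$comparisons, outfile("tukey.tsv"),
                               prov("anova"))
        list(p1, p2)
      }),
      hclust = run_stage("hclust", function() {
        em <- normalize_within_observation(
          build_matrix(get_changed(), impute = config$pca$impute))
        dend <- cluster_observations(em)
        p1 <- .write_stage_tsv(
          data.frame(merge1 = dend$merge[, 1], merge2 = dend$merge[, 2],
                     height = dend$height),
          outfile("hclust_merges.tsv"), prov("hclust"))
        p2 <- .write_stage_tsv(
          data.frame(observation = names(dend$cut2), group = dend$cut2),
          outfile("hclust_cut2.tsv"), prov("hclust"))
        list(p1, p2)
      }),
      kmeans = run_stage("kmeans", function() {
        pts <- deviation_points(table, config$kmeans$obs_a,
                                config$kmeans$obs_b, config$kmeans$alpha)
        km <- kmean_deviation(pts, k = config$kmeans$k,
                              restarts = config$kmeans$restarts,
                              seed = config$kmeans$seed)
        state$km <- km
        .write_stage_tsv(km$points, outfile("kmeans.tsv"), prov("kmeans"))
        list(outfile("kmeans.tsv"))
      }),
      regulators = run_stage("regulators", function() {
        network <- read_network(config$network)
        dataset <- if (!is.null(state$km)) {
          outer_ids <- state$km$points$protein_id[state$km$points$cluster >= 2]
          table[outer_ids]
        } else get_changed()
        bg <- config$regulators$background_size %||% n_proteins(table)
        scores <- score_regulators(dataset, config$regulators$obs, network, bg)
        .write_stage_tsv(scores[, setdiff(names(scores), character())],
                         outfile("regulators.tsv"), prov("regulators"))
        list(outfile("regulators.tsv"))
      }))
  }
  manifest_path <- outfile("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
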