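#' Protein quantification table
#'
#' A `quant_table` holds per-protein log2 expression ratios and ratio p-values
#' for a set of *observations*. An observation is a reporter-channel ratio
#' comparison written `"num:den"` (e.g. `"116:114"`, ethanol-fed versus
#' dextrose-fed wild-type male in the default 8-plex layout). This is the
#' central exchange object of the package: significance filtering, PCA,
#' ANOVA, clustering and regulator scoring all consume it.
#'
#' @param annotation data.frame of per-protein annotations. Must contain a
#'   non-empty, unique `accession` column; `gene_symbol` and `function`
#'   columns are used downstream when present, any further columns are
#'   carried along untouched.
#' @param log2_ratio numeric matrix, proteins x observations. Column names
#'   must be well-formed `"num:den"` keys; `NA` marks a missing ratio.
#' @param p_value numeric matrix of ratio-test p-values with the same shape
#'   as `log2_ratio`, or `NULL` for all-missing p-values.
#'
#' @return An object of class `quant_table` with elements `annotation`,
#'   `log2_ratio`, `p_value` and `observations`.
#' @seealso [read_quant_table()], [re_reference()], [significant_proteins()]
#' @export
quant_table <- function(annotation, log2_ratio, p_value = NULL) {
  .assert(is.data.frame(annotation), "annotation must be a data.frame")
  .assert("accession" %in% names(annotation),
          "annotation must contain an 'accession' column")
  acc <- as.character(annotation$accession)
  .assert(!anyNA(acc) && all(nzchar(acc)), "accessions must be non-empty")
  if (anyDuplicated(acc))
    .stopf("duplicate accession(s): %s",
           paste(unique(acc[duplicated(acc)]), collapse = ", "))
  log2_ratio <- as.matrix(log2_ratio)
  .assert(nrow(log2_ratio) == nrow(annotation),
          "log2_ratio must have one row per annotation row")
  keys <- colnames(log2_ratio)
  .assert(!is.null(keys) && all(.is_obs_key(keys)),
          "log2_ratio column names must be 'num:den' observation keys")
  .assert(!anyDuplicated(keys), "observation keys must be unique")
  if (is.null(p_value)) {
    p_value <- matrix(NA_real_, nrow(log2_ratio), ncol(log2_ratio),
                      dimnames = dimnames(log2_ratio))
  }
  p_value <- as.matrix(p_value)
  .assert(identical(dim(p_value), dim(log2_ratio)),
          "p_value must have the same shape as log2_ratio")
  colnames(p_value) <- keys
  bad_p <- p_value[!is.na(p_value)]
  .assert(all(bad_p >= 0 & bad_p <= 1), "p-values must lie in [0, 1]")
  .assert(all(is.finite(log2_ratio[!is.na(log2_ratio)])),
          "non-missing log2 ratios must be finite")
  rownames(log2_ratio) <- rownames(p_value) <- acc
  structure(
    list(annotation = annotation, log2_ratio = log2_ratio,
         p_value = p_value, observations = keys),
    class = "quant_table"
  )
}

#' Number of proteins in a quant table
#' @param table a [quant_table()].
#' @return integer count of protein records.
#' @export
n_proteins <- function(table) nrow(table$log2_ratio)

#' Observation keys of a quant table
#' @param table a [quant_table()].
#' @return character vector of `"num:den"` observation keys, in table order.
#' @export
observations <- function(table) table$observations

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d proteins x %d observations (%s)\n",
              n_proteins(x), length(x$observations),
              paste(x$observations, collapse = ", ")))
  invisible(x)
}

#' Subset a quant table by protein
#'
#' @param x a [quant_table()].
#' @param i protein index: integer/logical vector or accession characters.
#' @param ... unused.
#' @return a `quant_table` containing the selected proteins, observations
#'   unchanged.
#' @export
`[.quant_table` <- function(x, i, ...) {
  if (is.character(i)) {
    idx <- match(i, x$annotation$accession)
    if (anyNA(idx))
      .stopf("unknown accession(s): %s", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  quant_table(x$annotation[i, , drop = FALSE],
              x$log2_ratio[i, , drop = FALSE],
              x$p_value[i, , drop = FALSE])
}

.check_obs <- function(table, obs) {
  missing <- setdiff(obs, table$observations)
  if (length(missing))
    .stopf("unknown observation key(s): %s", paste(missing, collapse = ", "))
  invisible(obs)
}

#' Read a protein quantification table
#'
#' Parses a delimited text table with one row per protein. Columns whose
#' header is `"<num>:<den> log2R"` or `"<num>:<den> p"` become observation
#' data; every other column is kept as annotation. `"-"`, empty and `NA`
#' cells are read as missing values (the dash is the conventional missing
#' marker in printed ratio tables).
#'
#' @param path file to read.
#' @param sep field delimiter, default tab.
#' @return a [quant_table()]. Row order of the file is preserved.
#' @examples
#' tab <- read_quant_table(plexfactor_example("ethanol_gender"))
#' tab
#' @export
read_quant_table <- function(path, sep = "\t") {
  .assert(file.exists(path), "file not found: %s", path)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""), comment.char = "#",
                           stringsAsFactors = FALSE)
  hdr <- names(raw)
  looks_ratio <- grepl(":", hdr, fixed = TRUE)
  well_formed <- grepl("^[0-9]+:[0-9]+ (log2R|p)$", hdr)
  if (any(looks_ratio & !well_formed))
    .stopf("malformed observation column header: '%s' (expected '<num>:<den> log2R' or '<num>:<den> p')",
           hdr[looks_ratio & !well_formed][1L])
  ratio_cols <- hdr[well_formed]
  nd <- .split_obs_key(sub(" (log2R|p)$", "", ratio_cols))
  if (any(nd$num == nd$den))
    .stopf("self-ratio observation column: '%s'",
           ratio_cols[nd$num == nd$den][1L])
  .assert("accession" %in% hdr, "table must have an 'accession' column")
  annotation <- raw[, setdiff(hdr, ratio_cols), drop = FALSE]

  keys <- unique(sub(" (log2R|p)$", "", ratio_cols))
  parse_col <- function(col) {
    if (is.null(col)) return(rep(NA_real_, nrow(raw)))
    col[col == "-"] <- NA_character_
    as.numeric(col)
  }
  log2_ratio <- sapply(keys, function(k) parse_col(raw[[paste(k, "log2R")]]))
  p_value <- sapply(keys, function(k) parse_col(raw[[paste(k, "p")]]))
  if (nrow(raw) == 0L) {
    log2_ratio <- matrix(NA_real_, 0, length(keys), dimnames = list(NULL, keys))
    p_value <- log2_ratio
  } else if (nrow(raw) == 1L) {
    log2_ratio <- matrix(log2_ratio, 1, dimnames = list(NULL, keys))
    p_value <- matrix(p_value, 1, dimnames = list(NULL, keys))
  }
  quant_table(annotation, log2_ratio, p_value)
}

#' Write a protein quantification table
#'
#' Inverse of [read_quant_table()]: annotation columns first, then a
#' `"<key> log2R"` and `"<key> p"` column per observation. Missing cells are
#' written as `"-"`. Numeric values are written at full double precision so
#' a write/read round trip reproduces the table exactly.
#'
#' @param table a [quant_table()].
#' @param path output file.
#' @param sep field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path, sep = "\t") {
  out <- table$annotation
  out$accession <- as.character(out$accession)
  for (k in table$observations) {
    out[[paste(k, "log2R")]] <- .num_chr(table$log2_ratio[, k])
    out[[paste(k, "p")]] <- .num_chr(table$p_value[, k])
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a re-referenced observation
#'
#' Given two observations that share the same denominator channel, derives
#' the ratio between their numerator channels using
#' log2(a/b) = log2(a/d) - log2(b/d). The derived observation gets key
#' `"num_a:num_b"`; its p-values are missing, because a ratio-level table
#' carries no replicate information from which to re-test the derived ratio.
#' A protein missing either input ratio is missing in the derived column.
#' The degenerate call with `obs_a == obs_b` yields an all-zero self-ratio
#' column (a sanity identity; such keys are rejected in input files).
#'
#' @param table a [quant_table()].
#' @param obs_a,obs_b observation keys sharing one denominator channel.
#' @return the table with the derived observation appended (replaced, if the
#'   derived key already exists).
#' @export
re_reference <- function(table, obs_a, obs_b) {
  .check_obs(table, c(obs_a, obs_b))
  a <- .split_obs_key(obs_a); b <- .split_obs_key(obs_b)
  if (!identical(a$den, b$den))
    .stopf("observations %s and %s do not share a denominator channel",
           obs_a, obs_b)
  key <- paste(a$num, b$num, sep = ":")
  derived <- table$log2_ratio[, obs_a] - table$log2_ratio[, obs_b]
  log2_ratio <- table$log2_ratio
  p_value <- table$p_value
  log2_ratio <- log2_ratio[, setdiff(colnames(log2_ratio), key), drop = FALSE]
  p_value <- p_value[, setdiff(colnames(p_value), key), drop = FALSE]
  log2_ratio <- cbind(log2_ratio, matrix(derived, ncol = 1, dimnames = list(NULL, key)))
  p_value <- cbind(p_value, matrix(NA_real_, nrow(p_value), 1, dimnames = list(NULL, key)))
  quant_table(table$annotation, log2_ratio, p_value)
}

#' Read a signed regulator-target network
#'
#' Reads a three-column delimited file `regulator`, `target`, `sign` (header
#' required). `sign` is `+1` when the regulator up-regulates the target,
#' `-1` when it down-regulates it, and `0`/`NA` when the direction of
#' regulation is unknown; unknown-sign edges still count for overlap
#' enrichment but are excluded from activation-consistency scoring.
#'
#' @param path file to read.
#' @return data.frame of class `regulator_network` with columns `regulator`,
#'   `target`, `sign` (integer +1 / -1 / NA).
#' @examples
#' net <- read_network(plexfactor_example("regulators"))
#' head(net)
#' @export
read_network <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  .assert(all(c("regulator", "target", "sign") %in% names(raw)),
          "network file must have columns regulator, target, sign")
  sign_chr <- raw$sign
  sign <- rep(NA_integer_, length(sign_chr))
  sign[sign_chr %in% c("+1", "+", "1")] <- 1L
  sign[sign_chr %in% c("-1", "-")] <- -1L
  sign[sign_chr %in% c("0")] <- NA_integer_
  bad <- !is.na(sign_chr) & !sign_chr %in% c("+1", "+", "1", "-1", "-", "0")
  if (any(bad))
    .stopf("invalid edge sign '%s' (allowed: +1, -1, +, -, 0, NA)",
           sign_chr[bad][1L])
  key <- paste(raw$regulator, raw$target)
  if (anyDuplicated(key))
    .stopf("duplicate regulator-target edge(s): %s",
           paste(unique(key[duplicated(key)]), collapse = ", "))
  structure(
    data.frame(regulator = raw$regulator, target = raw$target, sign = sign,
               stringsAsFactors = FALSE),
    class = c("regulator_network", "data.frame")
  )
}

#' Paths to the packaged example data
#'
#' Three small curated tables from a chronic-ethanol mouse liver 8-plex
#' study of CYP2E1 function ship with the package:
#' \describe{
#'   \item{`"ethanol_gender"`}{90 proteins significantly changed by ethanol
#'     feeding in male (`116:114`) and/or female (`115:113`) wild-type mice.
#'     Only already-significant entries are present, so no p-value columns.}
#'   \item{`"ethanol_ko"`}{45 proteins from the K-means interaction analysis
#'     of the ethanol (`116:114`) and knockout-plus-ethanol (`121:114`)
#'     observations, with ratio p-values, the published cluster label (2 or
#'     3) and the scatter section each protein falls in.}
#'   \item{`"regulators"`}{a signed regulator-to-target edge list for eight
#'     upstream regulators (NRF2, PPARA, ...); edge signs are set only where
#'     the direction of regulation is established.}
#' }
#'
#' @param which one of `"ethanol_gender"`, `"ethanol_ko"`, `"regulators"`.
#' @return path to the packaged TSV file.
#' @export
plexfactor_example <- function(which = c("ethanol_gender", "ethanol_ko",
                                         "regulators")) {
  which <- match.arg(which)
  file <- switch(which,
                 ethanol_gender = "ethanol_gender_significant.tsv",
                 ethanol_ko = "ethanol_ko_interaction.tsv",
                 regulators = "regulator_targets.tsv")
  system.file("extdata", file, package = "plexfactor", mustWork = TRUE)
}
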