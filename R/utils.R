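`%||%` <- function(a, b) if (is.null(a)) b else a

.obs_key_re <- "^[0-9]+:[0-9]+$"

.is_obs_key <- function(x) grepl(.obs_key_re, x)

.split_obs_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  list(num = vapply(parts, `[`, "", 1L), den = vapply(parts, `[`, "", 2L))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) if (!isTRUE(cond)) .stopf(fmt, ...)

# full-precision numeric formatting so write -> read round trips are exact
.num_chr <- function(x, missing_marker = "-") {
  out <- vapply(x, function(v) {
    if (is.na(v)) missing_marker else sprintf("%.17g", v)
  }, "")
  out
}

.md5 <- function(path) unname(tools::md5sum(path))
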