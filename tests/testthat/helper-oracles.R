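# Independent brute-force oracles used to validate the analytical code paths.
# These deliberately avoid the package's own implementations.

# Exhaustive agglomerative complete linkage: returns merge heights in order.
complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    besth <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < besth) {
          besth <- h
          best <- c(j, i)
        }
      }
    }
    heights <- c(heights, besth)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Optimal 3-cluster within-cluster sum of squares over all contiguous
# partitions of the sorted values (1-D k-means optima are contiguous).
best_contiguous_wss3 <- function(x) {
  x <- sort(x)
  n <- length(x)
  wss <- function(v) sum((v - mean(v))^2)
  best <- Inf
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      s <- wss(x[1:i]) + wss(x[(i + 1):j]) + wss(x[(j + 1):n])
      if (s < best) best <- s
    }
  }
  best
}

# Hypergeometric upper tail by exhaustive enumeration of all draws.
hyper_tail_enum <- function(overlap, draws, targets, background) {
  sets <- utils::combn(background, draws)
  mean(apply(sets, 2, function(s) sum(s <= targets) >= overlap))
}

# Tukey-Kramer intervals straight from the studentized-range formula.
tukey_direct <- function(groups, alpha = 0.05) {
  k <- length(groups)
  n <- lengths(groups)
  means <- vapply(groups, mean, 0)
  df <- sum(n) - k
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / df
  q <- stats::qtukey(1 - alpha, k, df)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    d <- means[j] - means[i]
    hw <- q / sqrt(2) * sqrt(msw * (1 / n[i] + 1 / n[j]))
    c(i = i, j = j, diff = d, lwr = d - hw, upr = d + hw)
  })
  t(out)
}

# Small quant table from matrices, for compact test construction.
tiny_table <- function(log2, p = NULL, genes = NULL) {
  acc <- sprintf("P%03d", seq_len(nrow(log2)))
  ann <- data.frame(accession = acc,
                    gene_symbol = genes %||% acc,
                    stringsAsFactors = FALSE)
  quant_table(ann, log2, p)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Seven-gene dataset mirroring the published NRF2 target panel under the
# chronic-ethanol observation: six targets up, Fabp1 down.
nrf2_demo_table <- function() {
  genes <- c("Vcp", "Prdx1", "Gstp1", "Gstm1", "Fabp1", "Cbr1", "Bhmt")
  lr <- matrix(c(0.62, 0.85, 0.90, 2.92, -1.74, 1.02, 0.55), ncol = 1,
               dimnames = list(NULL, "116:114"))
  quant_table(data.frame(accession = genes, gene_symbol = genes,
                         stringsAsFactors = FALSE), lr)
}
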