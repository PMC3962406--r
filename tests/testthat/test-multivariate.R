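test_that("build_matrix imputes, drops and preserves as configured", {
  lr <- matrix(c(1, NA, 2, 0.5, 4, 3), ncol = 2,
               dimnames = list(NULL, c("116:114", "121:114")))
  tab <- tiny_table(lr)
  em <- build_matrix(tab)
  expect_equal(unname(em$values[2, ]), c(0, 4))
  expect_true(em$imputed[2, 1])
  expect_equal(sum(em$imputed), 1)
  # drop policy keeps only complete rows
  expect_equal(nrow(build_matrix(tab, impute = "drop")$values), 2)
  # fully observed input is returned unchanged
  full <- tiny_table(matrix(1:6 / 2, 3, 2,
                            dimnames = list(NULL, c("116:114", "121:114"))))
  expect_equal(build_matrix(full)$values, full$log2_ratio,
               ignore_attr = FALSE)
  # an all-missing protein row is dropped with a warning
  lr2 <- lr; lr2[2, ] <- NA
  expect_warning(em2 <- build_matrix(tiny_table(lr2)), "no observed value")
  expect_equal(nrow(em2$values), 2)
})

test_that("PCA matches a direct covariance eigendecomposition", {
  set.seed(31)
  x <- matrix(rnorm(80), 20, 4,
              dimnames = list(sprintf("P%03d", 1:20),
                              c("113:114", "116:114", "118:114", "121:114")))
  pca <- run_pca(x)
  eig <- eigen(cov(x), symmetric = TRUE)
  expect_equal(pca$lambda, eig$values, tolerance = 1e-10)
  expect_equal(pca$explained_fraction, eig$values / sum(eig$values),
               tolerance = 1e-10)
  # loadings are orthonormal
  expect_equal(crossprod(pca$loadings), diag(4), ignore_attr = TRUE,
               tolerance = 1e-10)
  # scores + loadings reconstruct the centered data
  centered <- sweep(x, 2, colMeans(x))
  expect_equal(pca$scores %*% t(pca$loadings), centered, tolerance = 1e-10,
               ignore_attr = TRUE)
  # explained fractions are non-increasing and sum to one
  expect_true(all(diff(pca$explained_fraction) <= 1e-12))
  expect_equal(sum(pca$explained_fraction), 1)
})

test_that("degenerate PCA inputs behave as specified", {
  x <- cbind("116:114" = c(1, 2, 3, 4), "121:114" = rep(5, 4))
  pca <- run_pca(x)
  expect_equal(pca$explained_fraction[1], 1)
  expect_error(run_pca(matrix(1, 3, 2,
                              dimnames = list(NULL, c("116:114", "121:114")))),
               "zero total variance")
})

test_that("full-component Hotelling T2 equals the Mahalanobis distance", {
  set.seed(47)
  x <- matrix(rnorm(60), 15, 4,
              dimnames = list(sprintf("P%03d", 1:15),
                              c("113:114", "116:114", "118:114", "121:114")))
  t2 <- hotelling_rank(run_pca(x), variance_target = 1)$t2
  s_inv <- solve(cov(x))
  centered <- sweep(x, 2, colMeans(x))
  maha <- rowSums((centered %*% s_inv) * centered)
  expect_equal(unname(t2), unname(maha), tolerance = 1e-10)
})

test_that("T2 is invariant under orthogonal rotation of the variables", {
  set.seed(13)
  x <- matrix(rnorm(100), 25, 4,
              dimnames = list(NULL, c("113:114", "116:114", "118:114",
                                      "121:114")))
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  xr <- x %*% q
  colnames(xr) <- colnames(x)
  t2a <- hotelling_rank(run_pca(x), 1)$t2
  t2b <- hotelling_rank(run_pca(xr), 1)$t2
  expect_equal(unname(t2a), unname(t2b), tolerance = 1e-8)
})

test_that("a protein at the column means scores T2 = 0", {
  base <- matrix(rnorm(40, sd = 1.5), 10, 4)
  x <- rbind(base, -base, 0)  # column means are exactly zero
  colnames(x) <- c("113:114", "116:114", "118:114", "121:114")
  rownames(x) <- sprintf("P%03d", seq_len(nrow(x)))
  t2 <- hotelling_rank(run_pca(x), 1)$t2
  expect_equal(unname(t2[nrow(x)]), 0, tolerance = 1e-20)
})

test_that("third-quartile selection keeps about a quarter of proteins", {
  set.seed(99)
  for (n in c(16, 27, 45)) {
    x <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(sprintf("P%03d", seq_len(n)),
                                c("113:114", "116:114", "118:114", "121:114")))
    hr <- hotelling_rank(run_pca(x), 0.90)
    expect_lte(abs(length(hr$selected) - n / 4), 1)
    # selection is strict: nothing at or below Q3
    expect_true(all(hr$t2[hr$selected] > hr$q3))
  }
})
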