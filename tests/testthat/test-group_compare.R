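em_from_matrix <- function(x) {
  tab <- tiny_table(x)
  build_matrix(tab)
}

test_that("identical observation columns give F = 0, p = 1", {
  col <- c(0.2, -0.4, 1.1, 0.7)
  x <- cbind("116:114" = col, "121:114" = col, "118:114" = col)
  an <- observation_anova(em_from_matrix(x))
  expect_equal(an$f_statistic, 0)
  expect_equal(an$p_value, 1)
  expect_equal(an$df_between, 2)
  expect_equal(an$df_within, 9)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(8)
  for (rep in 1:4) {
    a <- rnorm(6); b <- rnorm(9, mean = 0.5)
    x <- matrix(NA_real_, 9, 2, dimnames = list(NULL, c("116:114", "121:114")))
    x[1:6, 1] <- a; x[, 2] <- b
    tab <- tiny_table(x)
    em <- build_matrix(tab)  # the 3 absent cells are imputed, then excluded
    an <- observation_anova(em)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(an$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(an$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("groups with fewer than two values are refused by name", {
  x <- matrix(NA_real_, 4, 2, dimnames = list(NULL, c("116:114", "121:114")))
  x[, 1] <- 1:4; x[1, 2] <- 2
  expect_error(observation_anova(build_matrix(tiny_table(x))), "121:114")
})

test_that("Tukey-Kramer intervals match the direct studentized-range formula", {
  set.seed(21)
  groups <- list(rnorm(5), rnorm(7, 1), rnorm(4, -0.5))
  n <- max(lengths(groups))
  x <- matrix(NA_real_, n, 3,
              dimnames = list(NULL, c("116:114", "118:114", "121:114")))
  for (i in 1:3) x[seq_along(groups[[i]]), i] <- groups[[i]]
  tk <- tukey_kramer(build_matrix(tiny_table(x)), family_alpha = 0.05)
  oracle <- tukey_direct(groups, alpha = 0.05)
  keys <- colnames(x)
  for (r in seq_len(nrow(oracle))) {
    i <- oracle[r, "i"]; j <- oracle[r, "j"]
    row <- tk$comparisons[
      (tk$comparisons$obs_a == keys[j] & tk$comparisons$obs_b == keys[i]) |
      (tk$comparisons$obs_a == keys[i] & tk$comparisons$obs_b == keys[j]), ]
    expect_equal(nrow(row), 1)
    flip <- if (row$obs_a == keys[j]) 1 else -1
    expect_equal(flip * row$mean_difference, unname(oracle[r, "diff"]),
                 tolerance = 1e-10)
    lims <- sort(flip * c(row$ci_low, row$ci_high))
    expect_equal(lims, unname(oracle[r, c("lwr", "upr")]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # interval bracketing and significance flag agree
  expect_true(all(tk$comparisons$ci_low <= tk$comparisons$mean_difference &
                  tk$comparisons$mean_difference <= tk$comparisons$ci_high))
  expect_equal(tk$comparisons$significant,
               !(tk$comparisons$ci_low <= 0 & tk$comparisons$ci_high >= 0))
})

test_that("with equal group sizes the Kramer half-width reduces to Tukey HSD", {
  set.seed(4)
  x <- matrix(rnorm(24), 8, 3,
              dimnames = list(NULL, c("116:114", "118:114", "121:114")))
  tk <- tukey_kramer(build_matrix(tiny_table(x)))
  hw <- (tk$comparisons$ci_high - tk$comparisons$ci_low) / 2
  hsd <- qtukey(0.95, 3, 21) * sqrt(tk$ms_within / 8)
  expect_equal(hw, rep(hsd, 3), tolerance = 1e-10)
})

test_that("constant equal groups yield no significant pairs", {
  x <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3, 3,
              dimnames = list(NULL, c("116:114", "118:114", "121:114")))
  tk <- tukey_kramer(build_matrix(tiny_table(x)))
  expect_false(any(tk$comparisons$significant))
})

test_that("the F p-value agrees with a permutation null", {
  set.seed(301)
  x <- matrix(rnorm(120), 30, 4,
              dimnames = list(NULL, c("113:114", "116:114", "118:114",
                                      "121:114")))
  x[, 2] <- x[, 2] + 0.35
  em <- em_from_matrix(x)
  an <- observation_anova(em)
  vals <- as.vector(x)
  grp <- factor(rep(colnames(x), each = nrow(x)))
  fstat <- function(v) summary(aov(v ~ grp))[[1]][["F value"]][1]
  b <- 600
  perm <- replicate(b, fstat(sample(vals)))
  p_perm <- (sum(perm >= an$f_statistic) + 1) / (b + 1)
  tol <- 4 * sqrt(an$p_value * (1 - an$p_value) / b) + 2 / b
  expect_lt(abs(p_perm - an$p_value), tol)
})
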