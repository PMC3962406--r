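test_that("deviation distance and section classification follow the sign rule", {
  expect_equal(equal_expression_distance(0.7, 0.7), 0)
  expect_equal(equal_expression_distance(1.26, -4.29), abs(1.26 + 4.29) / sqrt(2))
  expect_equal(equal_expression_distance(2.92, -0.31), abs(2.92 + 0.31) / sqrt(2))
  expect_error(equal_expression_distance(Inf, 0), "finite")
  expect_error(equal_expression_distance(0, NA_real_), "finite")
  expect_equal(classify_section(1.26, -4.29), "lower_right")
  expect_equal(classify_section(-2.91, 1.61), "upper_left")
  expect_equal(classify_section(0.5, 0.5), "on_line")
  # a point and its reflection across the line share distance and swap section
  expect_equal(equal_expression_distance(2, -1), equal_expression_distance(-1, 2))
  expect_equal(classify_section(-1, 2), "upper_left")
})

make_points <- function(e_a, e_b, p_a = 0.01, p_b = 0.01) {
  lr <- cbind("116:114" = e_a, "121:114" = e_b)
  p <- cbind(rep(p_a, length(e_a)), rep(p_b, length(e_a)))
  deviation_points(tiny_table(lr, p), "116:114", "121:114")
}

test_that("deviation_points applies the changed filter and drops incomplete pairs", {
  lr <- cbind("116:114" = c(1, 2, NA, 3), "121:114" = c(0, -2, 1, 3))
  p <- cbind(c(0.01, 0.5, 0.01, 0.9), c(0.8, 0.01, 0.01, 0.9))
  pts <- deviation_points(tiny_table(lr, p), "116:114", "121:114")
  expect_equal(pts$protein_id, c("P001", "P002"))  # P003 lacks e_a, P004 fails p
  expect_equal(pts$distance, abs(lr[1:2, 1] - lr[1:2, 2]) / sqrt(2),
               ignore_attr = TRUE)
  pts_all <- deviation_points(tiny_table(lr, p), "116:114", "121:114",
                              alpha = NA)
  expect_equal(nrow(pts_all), 3)
})

test_that("perfectly separated distances yield the exact three-way partition", {
  pts <- make_points(e_a = c(0, 0, 0, 5, 5, 5, 10, 10, 10) * sqrt(2),
                     e_b = rep(0, 9))
  km <- kmean_deviation(pts, k = 3, seed = 1)
  expect_equal(km$points$cluster, rep(1:3, each = 3))
  expect_equal(km$centroids, c(0, 5, 10))
  expect_equal(km$tot_withinss, 0)
})

test_that("1-D K-means attains the exhaustive contiguous-partition optimum", {
  set.seed(55)
  for (n in c(6, 9, 12, 15)) {
    for (rep in 1:4) {
      pts <- make_points(e_a = rnorm(n, sd = 2), e_b = rnorm(n, sd = 2))
      km <- kmean_deviation(pts, k = 3, restarts = 10, seed = rep)
      expect_equal(km$tot_withinss, best_contiguous_wss3(pts$distance),
                   tolerance = 1e-8)
      # clusters are ordered by distance from the equal-expression line
      expect_true(max(pts$distance[km$points$cluster == 1]) <=
                    min(pts$distance[km$points$cluster == 3]))
    }
  }
})

test_that("cluster labels are scale-invariant and reflection-invariant", {
  set.seed(77)
  e_a <- rnorm(20, sd = 2); e_b <- rnorm(20, sd = 2)
  km <- kmean_deviation(make_points(e_a, e_b), k = 3, seed = 3)
  km_scaled <- kmean_deviation(make_points(3.7 * e_a, 3.7 * e_b), k = 3,
                               seed = 3)
  expect_equal(km$points$cluster, km_scaled$points$cluster)
  km_reflected <- kmean_deviation(make_points(e_b, e_a), k = 3, seed = 3)
  expect_equal(km$points$cluster, km_reflected$points$cluster)
})

test_that("k beyond the distinct distance count is refused", {
  pts <- make_points(c(1, 1, 2), c(0, 0, 1))  # distances: d, d, d
  expect_error(kmean_deviation(pts, k = 3), "distinct")
})

test_that("crosstab marginals and the outer-cluster report are conserved", {
  set.seed(5)
  pts <- make_points(rnorm(30), rnorm(30))
  pts$cluster <- sample(1:3, 30, replace = TRUE)
  xt <- section_cluster_crosstab(pts)
  expect_equal(sum(xt$crosstab), 30)
  expect_equal(unname(colSums(xt$crosstab)),
               unname(as.vector(table(pts$cluster))))
  expect_equal(unname(rowSums(xt$crosstab)),
               unname(as.vector(table(pts$section))))
  expect_equal(nrow(xt$report), sum(pts$cluster >= 2))
  # all points on the line collapse to a single on_line row
  on_line <- make_points(c(1, 2, 3), c(1, 2, 3))
  on_line$cluster <- 1
  expect_equal(rownames(section_cluster_crosstab(on_line)$crosstab), "on_line")
})
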