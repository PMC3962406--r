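test_that("activation z follows (consistent - inconsistent) / sqrt(N)", {
  net <- read_network(plexfactor_example("regulators"))
  scores <- score_regulators(nrf2_demo_table(), "116:114", net,
                             background_size = 863)
  nrf2 <- scores[scores$regulator == "NRF2", ]
  expect_equal(nrf2$n_overlap, 7)
  expect_equal(nrf2$n_consistent, 7)
  expect_equal(nrf2$n_inconsistent, 0)
  expect_equal(nrf2$z, 7 / sqrt(7), tolerance = 1e-12)
  expect_equal(nrf2$predicted_state, "activated")
  # a regulator with no in-dataset targets is reported, not dropped
  ctnnb1 <- scores[scores$regulator == "CTNNB1", ]
  expect_equal(ctnnb1$n_overlap, 0)
  expect_true(is.na(ctnnb1$z))
  expect_equal(ctnnb1$overlap_p, 1)
  expect_equal(ctnnb1$predicted_state, "undetermined")
})

test_that("balanced consistency gives z = 0 and flipping directions negates z", {
  genes <- c("T1", "T2", "T3", "T4")
  net_df <- data.frame(regulator = "R", target = genes, sign = c(1L, 1L, -1L, -1L),
                       stringsAsFactors = FALSE)
  class(net_df) <- c("regulator_network", "data.frame")
  lr <- matrix(c(1, -1, 1, -1), ncol = 1, dimnames = list(NULL, "116:114"))
  tab <- quant_table(data.frame(accession = genes, gene_symbol = genes), lr)
  s <- score_regulators(tab, "116:114", net_df, background_size = 10)
  expect_equal(s$z, 0)
  expect_equal(s$predicted_state, "undetermined")
  # flip every observed direction
  tab2 <- quant_table(data.frame(accession = genes, gene_symbol = genes), -lr)
  set.seed(10)
  for (rep in 1:5) {
    signs <- sample(c(-1L, 1L), 4, replace = TRUE)
    net_df$sign <- signs
    za <- score_regulators(tab, "116:114", net_df, 10)$z
    zb <- score_regulators(tab2, "116:114", net_df, 10)$z
    expect_equal(za, -zb)
    expect_lte(abs(za), sqrt(4))
  }
})

test_that("unsigned edges and zero directions are excluded from scoring", {
  genes <- c("T1", "T2", "T3")
  net_df <- data.frame(regulator = "R", target = genes,
                       sign = c(1L, NA_integer_, 1L), stringsAsFactors = FALSE)
  class(net_df) <- c("regulator_network", "data.frame")
  lr <- matrix(c(2, 3, 0), ncol = 1, dimnames = list(NULL, "116:114"))
  tab <- quant_table(data.frame(accession = genes, gene_symbol = genes), lr)
  s <- score_regulators(tab, "116:114", net_df, 100)
  expect_equal(s$n_overlap, 3)         # all three targets count for overlap
  expect_equal(s$n_targets_scored, 1)  # only T1 has sign and direction
  expect_equal(s$n_consistent + s$n_inconsistent, s$n_targets_scored)
  expect_equal(s$z, 1)
})

test_that("per-target consistency labels match the published direction logic", {
  net <- read_network(plexfactor_example("regulators"))
  rep <- consistency_report(nrf2_demo_table(), "116:114", net, "NRF2")
  fabp1 <- rep[rep$target == "Fabp1", ]
  expect_equal(fabp1$direction, -1L)
  expect_equal(fabp1$edge_sign, -1L)
  expect_equal(fabp1$status, "consistent_with_activation")
  expect_true(all(rep$status == "consistent_with_activation"))
  # single-target direction logic
  one <- data.frame(regulator = "R", target = "T1", sign = 1L)
  class(one) <- c("regulator_network", "data.frame")
  up <- quant_table(data.frame(accession = "T1", gene_symbol = "T1"),
                    matrix(1, dimnames = list(NULL, "116:114")))
  down <- quant_table(data.frame(accession = "T1", gene_symbol = "T1"),
                      matrix(-1, dimnames = list(NULL, "116:114")))
  expect_equal(consistency_report(up, "116:114", one, "R")$status,
               "consistent_with_activation")
  expect_equal(consistency_report(down, "116:114", one, "R")$status,
               "consistent_with_inhibition")
  # empty dataset gives an empty report
  empty <- quant_table(
    data.frame(accession = character(), gene_symbol = character()),
    matrix(numeric(0), 0, 1, dimnames = list(NULL, "116:114")))
  expect_equal(nrow(consistency_report(empty, "116:114", one, "R")), 0)
})

test_that("overlap p-value matches exhaustive enumeration and its bounds", {
  expect_equal(overlap_pvalue(0, 5, 4, 10), 1)
  expect_equal(overlap_pvalue(4, 4, 4, 4), 1)
  for (case in list(c(2, 5, 4, 10), c(3, 6, 5, 12), c(1, 3, 2, 8))) {
    expect_equal(overlap_pvalue(case[1], case[2], case[3], case[4]),
                 hyper_tail_enum(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12)
  }
  # monotone non-increasing in the observed overlap
  ps <- vapply(0:4, overlap_pvalue, 0, dataset_size = 5,
               regulator_targets = 4, background_size = 10)
  expect_true(all(diff(ps) <= 0))
  expect_error(overlap_pvalue(5, 4, 4, 10), "exceed")
  expect_error(overlap_pvalue(2, 5, 11, 10), "background")
})
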