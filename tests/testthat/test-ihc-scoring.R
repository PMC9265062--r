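test_that("labeling index sums the scheme's intensity levels", {
  p <- data.frame(pct_0 = c(90, 50, 0), pct_1 = c(10, 30, 0),
                  pct_2 = c(0, 15, 40), pct_3 = c(0, 5, 60))
  expect_equal(labeling_index(p, "S123"), c(10, 50, 100))
  expect_equal(labeling_index(p, "S23"), c(0, 20, 100))
})

test_that("invalid intensity profiles are rejected with the read named", {
  bad <- data.frame(sample_id = "PDX-001", marker = "TP53", lab_id = "L1",
                    reader_id = "R2",
                    pct_0 = 50, pct_1 = 30, pct_2 = 15, pct_3 = 10)
  expect_error(validate_profiles(bad), "PDX-001/TP53/L1/R2")
  expect_error(labeling_index(data.frame(pct_0 = 101, pct_1 = -1,
                                         pct_2 = 0, pct_3 = 0), "S123"),
               "invalid intensity profile")
})

test_that("S23 index never exceeds S123 index", {
  set.seed(42)
  for (i in 1:50) {
    raw <- stats::runif(4)
    p <- as.data.frame(as.list(100 * raw / sum(raw)))
    names(p) <- c("pct_0", "pct_1", "pct_2", "pct_3")
    expect_lte(labeling_index(p, "S23"), labeling_index(p, "S123"))
  }
})

test_that("marker calls apply closed 10% thresholds with direction", {
  expect_equal(call_marker(15, "TP53"), "abnormal")  # nuclear accumulation
  expect_equal(call_marker(0, "TP53"), "normal")     # no accumulation
  expect_equal(call_marker(c(0, 10, 10.1), "RB1"),
               c("abnormal", "abnormal", "normal"))
  expect_equal(call_marker(c(0, 10, 10.1), "PTEN"),
               c("abnormal", "abnormal", "normal"))
  expect_equal(call_marker(10, "TP53"), "abnormal")  # boundary closed
  expect_equal(call_marker(9.99, "TP53"), "normal")
})

test_that("marker calls are monotone in the labeling index", {
  grid <- sort(stats::runif(40, 0, 100))
  high <- call_marker(grid, "TP53")
  low <- call_marker(grid, "RB1")
  # high_aberrant: once abnormal, stays abnormal as index rises
  expect_true(all(diff(high == "abnormal") >= 0))
  # low_aberrant: once normal, stays normal as index rises
  expect_true(all(diff(low == "normal") >= 0))
})

test_that("rule overrides change scheme and threshold", {
  rules <- marker_rules(data.frame(marker = "TP53", threshold_pct = 20,
                                   scheme = "S123"))
  expect_equal(rules$threshold_pct[rules$marker == "TP53"], 20)
  expect_equal(call_marker(15, "TP53", rules = rules), "normal")
  expect_error(marker_rules(data.frame(marker = "TP53", scheme = "S12")),
               "scheme")
})

test_that("consensus is the strict majority with tie handling", {
  cc <- consensus_call(c(rep("abnormal", 5), rep("normal", 4)))
  expect_equal(cc$consensus, "abnormal")
  expect_equal(cc$agreement_fraction, 5 / 9)
  expect_equal(consensus_call(rep("abnormal", 9))$agreement_fraction, 1)
  tie <- consensus_call(c(rep("abnormal", 4), rep("normal", 4)))
  expect_equal(tie$consensus, "indeterminate")
  expect_equal(tie$agreement_fraction, 0.5)
  expect_equal(consensus_call(c(rep("abnormal", 4), rep("normal", 4)),
                              tie = "abnormal")$consensus, "abnormal")
  expect_error(consensus_call(character(0)), "at least one read")
})

test_that("consensus is permutation-invariant and decisive for odd reads", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(c(1, 3, 5, 7, 9), 1)
    calls <- sample(c("normal", "abnormal"), n, replace = TRUE)
    a <- consensus_call(calls)
    b <- consensus_call(sample(calls))
    expect_equal(a$consensus, b$consensus)
    expect_false(a$consensus == "indeterminate")
  }
})

test_that("Fleiss' kappa matches a frozen direct evaluation", {
  mat <- matrix(c("A", "A", "A",
                  "A", "A", "N",
                  "N", "N", "A",
                  "N", "N", "N"), 4, 3, byrow = TRUE)
  # direct evaluation: P_bar = 2/3, P_e = 1/2 -> kappa = 1/3
  expect_equal(fleiss_kappa(mat), 1 / 3, tolerance = 1e-12)
  expect_equal(fleiss_kappa(mat), fleiss_oracle(mat), tolerance = 1e-12)
})

test_that("Fleiss' kappa is 1 under unanimity with both categories", {
  mat <- matrix(rep(rep(c("abnormal", "normal"), each = 14), times = 9),
                28, 9)
  expect_equal(fleiss_kappa(mat), 1)
})

test_that("Fleiss' kappa rejects degenerate and undersized inputs", {
  expect_error(fleiss_kappa(matrix("abnormal", 5, 3)), "single category")
  expect_error(fleiss_kappa(matrix(c("A", "N"), 1, 2)), "2 complete subjects")
  # subjects with missing ratings are dropped, not propagated
  mat <- random_call_matrix(6, 4)
  mat2 <- rbind(mat, c("normal", NA, "normal", "normal"))
  expect_equal(fleiss_kappa(mat2), fleiss_kappa(mat))
})

test_that("Fleiss' kappa is invariant to relabeling and permutation", {
  set.seed(11)
  for (i in 1:20) {
    mat <- random_call_matrix(sample(3:6, 1), sample(3:5, 1))
    k <- fleiss_kappa(mat)
    swapped <- ifelse(mat == "normal", "abnormal", "normal")
    expect_equal(fleiss_kappa(swapped), k, tolerance = 1e-12)
    expect_equal(fleiss_kappa(mat[sample(nrow(mat)), sample(ncol(mat))]), k,
                 tolerance = 1e-12)
  }
})

test_that("agreement scores map to the standard verbal bins", {
  expect_equal(interpret_kappa(0.55), "moderate agreement")
  expect_equal(interpret_kappa(c(-0.1, 0.1, 0.3, 0.7, 0.95)),
               c("poor agreement", "slight agreement", "fair agreement",
                 "substantial agreement", "almost perfect agreement"))
})

test_that("the per-marker Fleiss report sweeps both schemes", {
  cfg <- fast_config(seed = 5, ihc_noise_sd = 0)
  sim <- simulate_cohort(cfg)
  rep <- ihc_fleiss_report(sim$ihc)
  expect_setequal(rep$scheme, c("S123", "S23"))
  expect_setequal(rep$marker, c("TP53", "RB1", "PTEN"))
  expect_equal(rep$n_raters, rep(9, 6))
  # noiseless reads are unanimous -> perfect agreement everywhere
  expect_true(all(rep$fleiss_kappa == 1))
})
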