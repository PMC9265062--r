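test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- fast_config(seed = 17)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$ihc, b$ihc)
  expect_identical(a$expression$expr, b$expression$expr)
  expect_identical(a$genomics$variants, b$genomics$variants)
  expect_identical(a$genomics$cnv, b$genomics$cnv)
  # a different seed changes the draw
  expect_false(identical(a$ihc, simulate_cohort(fast_config(seed = 18))$ihc))
})

test_that("degenerate prevalences give all-or-nothing truth", {
  none <- generate_truth(cohort_config(
    seed = 1, marker_loss_prevalence = c(TP53 = 0, RB1 = 0, PTEN = 0)))
  expect_false(any(none$TP53, none$RB1, none$PTEN, none$avpcm_true))
  all3 <- generate_truth(cohort_config(
    seed = 1, marker_loss_prevalence = c(TP53 = 1, RB1 = 1, PTEN = 1)))
  expect_true(all(all3$TP53 & all3$RB1 & all3$PTEN & all3$avpcm_true))
})

test_that("AVPC-m prevalence matches its expectation at large n", {
  # independent markers: expected P(>=2 of 3) from the marginals
  p <- c(TP53 = 0.607, RB1 = 0.50, PTEN = 0.536)
  expected <- p[[1]] * p[[2]] * (1 - p[[3]]) + p[[1]] * p[[3]] * (1 - p[[2]]) +
    p[[2]] * p[[3]] * (1 - p[[1]]) + p[[1]] * p[[2]] * p[[3]]
  truth <- generate_truth(cohort_config(n_samples = 1e4, seed = 4))
  se <- sqrt(expected * (1 - expected) / 1e4)
  expect_lt(abs(mean(truth$avpcm_true) - expected), 3 * se)

  # calibrated co-occurrence: low marginals lifted to a higher target
  target <- 0.15
  cfg <- cohort_config(n_samples = 1e4, seed = 5,
                       marker_loss_prevalence = c(TP53 = 0.2, RB1 = 0.2,
                                                  PTEN = 0.2),
                       avpcm_target_prevalence = target)
  truth2 <- generate_truth(cfg)
  se2 <- sqrt(target * (1 - target) / 1e4)
  expect_lt(abs(mean(truth2$avpcm_true) - target), 3 * se2)
  # marginals are preserved by the latent-lift construction
  expect_lt(abs(mean(truth2$TP53) - 0.2), 3 * sqrt(0.2 * 0.8 / 1e4))
})

test_that("an unachievable co-occurrence target is refused", {
  expect_error(generate_truth(cohort_config(
    seed = 1, avpcm_target_prevalence = 0.95)), "unachievable")
})

test_that("noiseless reads are identical across the 9 reviews", {
  cfg <- fast_config(seed = 6, ihc_noise_sd = 0)
  sim <- simulate_cohort(cfg)
  per_group <- split(sim$ihc[, c("pct_0", "pct_1", "pct_2", "pct_3")],
                     list(sim$ihc$sample_id, sim$ihc$marker), drop = TRUE)
  for (g in per_group) expect_equal(nrow(unique(g)), 1)
  # construction guarantees: true-loss TP53 clears the S23 threshold
  scored <- score_ihc_reads(sim$ihc)
  tp53 <- scored[scored$marker == "TP53", ]
  lost <- sim$truth$TP53[match(tp53$sample_id, sim$truth$sample_id)]
  expect_true(all(tp53$labeling_index[lost] >= 10))
  expect_true(all(tp53$call[lost] == "abnormal"))
})

test_that("profiles sum to 100 and reader agreement degrades with noise", {
  kappas <- vapply(c(0, 10, 35), function(noise) {
    mean(vapply(1:8, function(s) {
      cfg <- fast_config(seed = 300 + s, ihc_noise_sd = noise)
      sim <- simulate_cohort(cfg)
      validate_profiles(sim$ihc)
      rep <- ihc_fleiss_report(sim$ihc)
      mean(rep$fleiss_kappa, na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(kappas[1], 1)
  expect_true(all(diff(kappas) <= 0))
})

test_that("generated files round-trip through the module readers", {
  cfg <- fast_config(seed = 23)
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(cfg, out_dir = dir)
  ihc <- read_ihc_reads(file.path(dir, "ihc_reads.csv"))
  expect_equal(nrow(ihc), nrow(sim$ihc))
  expect_equal(ihc$pct_2, sim$ihc$pct_2, tolerance = 1e-9)
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(dim(expr), dim(sim$expression$expr))
  expect_equal(unname(expr), unname(sim$expression$expr), tolerance = 1e-9)
  v <- read_variant_table(file.path(dir, "variants.tsv"))
  expect_equal(nrow(v), nrow(sim$genomics$variants))
  expect_equal(v$cadd_score, sim$genomics$variants$cadd_score,
               tolerance = 1e-9)
  expect_equal(v$in_cosmic, sim$genomics$variants$in_cosmic)
  cnv <- read_cnv_table(file.path(dir, "cnv.tsv"))
  expect_equal(nrow(cnv), nrow(sim$genomics$cnv))
  sig <- read_signature_table(file.path(dir, "signature_TP53.tsv"))
  rebuilt <- subselect_signature(sig, "TP53")
  expect_setequal(rebuilt$up_genes, sim$expression$signatures$TP53$up_genes)
})

test_that("decoy variants are eliminated by the downstream filters", {
  cfg <- fast_config(seed = 31, assay_concordance = c(SNV = 1, CNV = 1),
                     decoys_per_sample_gene = 2)
  sim <- simulate_cohort(cfg)
  calls <- genomic_calls(variants = sim$genomics$variants,
                         cnv = sim$genomics$cnv,
                         samples = sim$genomics$evaluable,
                         genes = c("TP53", "RB1", "PTEN"))
  truth <- sim$truth[match(calls$sample_id, sim$truth$sample_id), ]
  for (m in c("TP53", "RB1", "PTEN")) {
    sub <- calls[calls$gene == m, ]
    expect_equal(sub$abnormal,
                 sim$truth[[m]][match(sub$sample_id, sim$truth$sample_id)])
  }
})

test_that("the evaluable sample count matches its expectation", {
  cfg <- cohort_config(n_samples = 28, seed = 2)
  counts <- vapply(1:30, function(s) {
    g <- generate_genomics(generate_truth(cohort_config(n_samples = 28,
                                                        seed = s)),
                           cohort_config(n_samples = 28, seed = s))
    length(g$evaluable)
  }, numeric(1))
  # expectation 20 of 28; binomial SE over 30 replicates
  se <- sqrt(20 / 28 * 8 / 28 * 28 / 30)
  expect_lt(abs(mean(counts) - 20), 3 * se)
})
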