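mk_variant <- function(af = 0.4, t = 50, n = 20, pop = FALSE, cosmic = FALSE,
                       consequence = "missense", cadd = NA_real_,
                       sample_id = "s1", gene = "TP53") {
  data.frame(sample_id = sample_id, gene = gene, consequence = consequence,
             allele_frequency = af, tumor_read_support = t,
             normal_read_support = n, in_population_db = pop,
             in_cosmic = cosmic, cadd_score = cadd,
             stringsAsFactors = FALSE)
}

test_that("variant filters apply support, frequency and germline rules", {
  v <- rbind(
    mk_variant(af = 0.05, t = 100, n = 50),            # low AF
    mk_variant(af = 0.4, t = 19),                      # low tumor support
    mk_variant(af = 0.4, t = 50, n = 9),               # low normal support
    mk_variant(af = 0.4, pop = TRUE),                  # germline, no rescue
    mk_variant(af = 0.4, t = 50, n = 20, pop = TRUE, cosmic = TRUE),  # rescued
    mk_variant(af = 0.4))                              # clean
  kept <- filter_variants(v)
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "dropped")$row, 1:4)
  # strict AF boundary: exactly 0.1 is dropped, just above retained
  expect_equal(nrow(filter_variants(mk_variant(af = 0.1))), 0)
  expect_equal(nrow(filter_variants(mk_variant(af = 0.1000001))), 1)
  # closed support boundaries: exactly 20/10 retained
  expect_equal(nrow(filter_variants(mk_variant(t = 20, n = 10))), 1)
})

test_that("variant filtering is idempotent", {
  set.seed(3)
  v <- do.call(rbind, lapply(1:40, function(i)
    mk_variant(af = runif(1), t = sample(0:60, 1), n = sample(0:30, 1),
               pop = runif(1) < 0.3, cosmic = runif(1) < 0.3)))
  once <- filter_variants(v)
  twice <- filter_variants(once)
  expect_equal(nrow(twice), nrow(once))
  expect_equal(twice$allele_frequency, once$allele_frequency)
})

test_that("CADD bins decide pathogenicity when a score exists", {
  expect_equal(classify_pathogenicity("missense", 25), "pathogenic")
  expect_equal(classify_pathogenicity("missense", 15), "vus")
  expect_equal(classify_pathogenicity("missense", 9.99), "benign")
  expect_equal(classify_pathogenicity("missense", 10), "vus")    # closed at 10
  expect_equal(classify_pathogenicity("missense", 19.99), "vus")
  expect_equal(classify_pathogenicity("missense", 20), "pathogenic")
})

test_that("without a score the consequence fallback decides", {
  expect_equal(classify_pathogenicity("nonsense", NA), "pathogenic")
  expect_equal(classify_pathogenicity(
    c("frameshift", "splice", "silent", "utr3", "utr5", "flank",
      "noncoding", "missense", "other"), NA_real_),
    c("pathogenic", "pathogenic", "benign", "benign", "benign", "benign",
      "benign", "vus", "vus"))
  expect_error(classify_pathogenicity("stop_gained", NA), "accepted")
})

test_that("a CADD score overrides the consequence entirely", {
  set.seed(13)
  cons <- sample(c("missense", "nonsense", "silent", "utr3", "frameshift",
                   "other"), 60, replace = TRUE)
  for (score in c(5, 15, 25)) {
    calls <- classify_pathogenicity(cons, rep(score, 60))
    expect_equal(unique(calls),
                 c("benign", "vus", "pathogenic")[findInterval(score, c(10, 20)) + 1])
  }
})

test_that("copy-number classes use closed 0.8 boundaries", {
  expect_equal(classify_cnv(c(-0.9, -0.8, -0.79, 0, 0.79, 0.8, 0.9)),
               c("deletion", "deletion", "neutral", "neutral", "neutral",
                 "amplification", "amplification"))
  expect_error(classify_cnv(Inf), "finite")
})

test_that("gene-level calls combine pathogenic variants and deletions", {
  cnv_neutral <- data.frame(sample_id = "s1", gene = "TP53", log2_ratio = 0)
  cnv_del <- data.frame(sample_id = "s1", gene = "PTEN", log2_ratio = -1.2)
  path_mis <- mk_variant(cadd = 25)
  calls <- genomic_calls(variants = path_mis, cnv = cnv_neutral)
  expect_true(calls$abnormal)
  expect_equal(calls$evidence, "pathogenic_snv")
  del_only <- genomic_calls(variants = NULL, cnv = cnv_del)
  expect_true(del_only$abnormal)
  expect_equal(del_only$evidence, "deletion")
  neutral <- genomic_calls(variants = NULL, cnv = cnv_neutral)
  expect_false(neutral$abnormal)
  # VUS and amplification contribute no evidence
  vus <- mk_variant(cadd = 15)
  amp <- data.frame(sample_id = "s1", gene = "TP53", log2_ratio = 1.4)
  expect_false(genomic_calls(variants = vus, cnv = amp)$abnormal)
  expect_true(genomic_calls(variants = vus, cnv = amp,
                            count_vus = TRUE)$abnormal)
})

test_that("adding pathogenic evidence never flips abnormal to normal", {
  cnv <- data.frame(sample_id = "s1", gene = "TP53", log2_ratio = -1)
  with_del <- genomic_calls(variants = NULL, cnv = cnv)
  with_both <- genomic_calls(variants = mk_variant(cadd = 30), cnv = cnv)
  expect_true(with_del$abnormal)
  expect_true(with_both$abnormal)
  expect_equal(with_both$evidence, "pathogenic_snv+deletion")
})

test_that("conflicting duplicate CNV rows are an error, identical ones are not", {
  dup_conflict <- data.frame(sample_id = "s1", gene = "TP53",
                             log2_ratio = c(-1, 0))
  expect_error(genomic_calls(cnv = dup_conflict), "conflicting")
  dup_same <- data.frame(sample_id = "s1", gene = "TP53",
                         log2_ratio = c(-1, -1))
  expect_true(genomic_calls(cnv = dup_same)$abnormal)
})

test_that("SEG segments reduce to gene log2 ratios by weighted mean or min", {
  # gene spans 100-300 (0-based half-open); two segments overlap it:
  # 1-based [1,200] (mean -1, overlap 100) and [201,400] (mean 0, overlap 100)
  seg <- data.frame(sample = "s1", chrom = "chr17",
                    start = c(1, 201), end = c(200, 400),
                    seg_mean = c(-1, 0))
  genes <- data.frame(chrom = "chr17", start = 100, end = 300, gene = "TP53")
  wm <- reduce_seg_to_genes(seg, genes)
  expect_equal(wm$log2_ratio, (-1 * 100 + 0 * 100) / 200)
  mn <- reduce_seg_to_genes(seg, genes, reduce = "min")
  expect_equal(mn$log2_ratio, -1)
  # unequal overlap weights
  seg2 <- data.frame(sample = "s1", chrom = "chr17",
                     start = c(1, 151), end = c(150, 400),
                     seg_mean = c(-2, 0))
  expect_equal(reduce_seg_to_genes(seg2, genes)$log2_ratio,
               (-2 * 50 + 0 * 150) / 200)
  # no overlap -> empty result
  far <- data.frame(chrom = "chr1", start = 0, end = 10, gene = "X")
  expect_equal(nrow(reduce_seg_to_genes(seg, far)), 0)
})
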