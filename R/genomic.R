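CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice", "silent",
                  "utr3", "utr5", "flank", "noncoding", "other")

#' Filter a somatic variant table
#'
#' Retains variants passing all of: tumor read support >= 20, matched-normal
#' read support >= 10, allele frequency > 0.1 (strict), and not reported in
#' a germline population database unless also flagged as potentially
#' pathogenic by a somatic catalog (the COSMIC rescue). Row order is
#' preserved; the reason each dropped row failed is attached as the
#' `"dropped"` attribute and logged when verbose.
#'
#' @param variants data frame with columns `sample_id`, `gene`,
#'   `consequence`, `allele_frequency`, `tumor_read_support`,
#'   `normal_read_support`, `in_population_db`, `in_cosmic`, and optionally
#'   `cadd_score`, `protein_position`.
#' @return the retained rows, order preserved.
#' @export
filter_variants <- function(variants) {
  assert_cols(variants,
              c("sample_id", "gene", "consequence", "allele_frequency",
                "tumor_read_support", "normal_read_support",
                "in_population_db", "in_cosmic"),
              "variant table")
  abort_if(any(variants$allele_frequency < 0 | variants$allele_frequency > 1),
           "allele_frequency must lie in [0, 1]")
  abort_if(any(variants$tumor_read_support < 0 |
                 variants$normal_read_support < 0 |
                 variants$tumor_read_support %% 1 != 0 |
                 variants$normal_read_support %% 1 != 0),
           "read supports must be non-negative integers")
  pop <- as.logical(variants$in_population_db)
  cos <- as.logical(variants$in_cosmic)
  reason <- rep(NA_character_, nrow(variants))
  reason[variants$tumor_read_support < 20]  <- "tumor_read_support < 20"
  reason[is.na(reason) & variants$normal_read_support < 10] <-
    "normal_read_support < 10"
  reason[is.na(reason) & variants$allele_frequency <= 0.1] <-
    "allele_frequency <= 0.1"
  reason[is.na(reason) & pop & !cos] <- "germline (population db, not in COSMIC)"
  keep <- is.na(reason)
  if (any(!keep)) {
    for (r in unique(reason[!keep]))
      vlog("filter_variants: dropped %d variant(s): %s",
           sum(reason == r, na.rm = TRUE), r)
  }
  out <- variants[keep, , drop = FALSE]
  attr(out, "dropped") <- data.frame(
    row = which(!keep), reason = reason[!keep], stringsAsFactors = FALSE)
  out
}

#' Rule-based variant pathogenicity classification
#'
#' When a CADD deleteriousness score is available it decides alone:
#' `< 10` benign, `>= 20` pathogenic, `[10, 20)` VUS (variant of unclear
#' significance). Without a score the consequence decides: UTR/flank/
#' silent/noncoding are benign; nonsense/frameshift/splice are pathogenic;
#' everything else (including missense) is VUS.
#'
#' @param consequence character vector over the accepted vocabulary
#'   (`missense`, `nonsense`, `frameshift`, `splice`, `silent`, `utr3`,
#'   `utr5`, `flank`, `noncoding`, `other`).
#' @param cadd_score numeric vector, `NA` when not computed.
#' @return character vector of `"benign"` / `"vus"` / `"pathogenic"`.
#' @examples
#' classify_pathogenicity("missense", 25)   # pathogenic (score decides)
#' classify_pathogenicity("nonsense", NA)   # pathogenic (consequence fallback)
#' classify_pathogenicity("missense", 15)   # vus
#' @export
classify_pathogenicity <- function(consequence, cadd_score = NA_real_) {
  bad <- setdiff(unique(consequence), CONSEQUENCES)
  abort_if(length(bad) > 0,
           sprintf("unknown consequence term(s): %s; accepted: %s",
                   paste(bad, collapse = ", "),
                   paste(CONSEQUENCES, collapse = ", ")))
  if (length(cadd_score) == 1 && length(consequence) > 1)
    cadd_score <- rep(cadd_score, length(consequence))
  benign_cons <- c("utr3", "utr5", "flank", "silent", "noncoding")
  path_cons <- c("nonsense", "frameshift", "splice")
  ifelse(!is.na(cadd_score),
         ifelse(cadd_score < 10, "benign",
                ifelse(cadd_score >= 20, "pathogenic", "vus")),
         ifelse(consequence %in% benign_cons, "benign",
                ifelse(consequence %in% path_cons, "pathogenic", "vus")))
}

#' Classify a copy-number log2 ratio
#'
#' `<= -0.8` is a deletion, `>= 0.8` an amplification, anything between is
#' neutral (closed boundaries).
#'
#' @param log2_ratio finite numeric vector of tumor/reference log2 ratios.
#' @return character vector of `"deletion"` / `"neutral"` /
#'   `"amplification"`.
#' @examples
#' classify_cnv(c(-0.9, 0, 0.8))  # deletion neutral amplification
#' @export
classify_cnv <- function(log2_ratio) {
  abort_if(any(!is.finite(log2_ratio)), "log2 ratios must be finite")
  ifelse(log2_ratio <= -0.8, "deletion",
         ifelse(log2_ratio >= 0.8, "amplification", "neutral"))
}

#' Per-gene, per-sample genomic abnormality calls
#'
#' A gene is genomically abnormal in a sample when, after filtering, it
#' carries at least one pathogenic variant or a copy-number deletion.
#' VUS and benign variants, neutral copy state and amplification of a tumor
#' suppressor contribute no evidence.
#'
#' @param variants raw variant table (filtered internally via
#'   [filter_variants()]); pass `NULL` when no variant data exist.
#' @param cnv gene-level copy-number table with columns `sample_id`,
#'   `gene`, `log2_ratio` (or `NULL`). Conflicting duplicate rows for one
#'   (sample, gene) are an error.
#' @param samples,genes the sample/gene universe for the output; defaults
#'   to those observed in the inputs.
#' @param count_vus if `TRUE`, VUS variants also count as evidence
#'   (sensitivity analysis).
#' @return data frame with one row per (sample, gene): `sample_id`, `gene`,
#'   `abnormal` (logical), `evidence` (`"pathogenic_snv"`, `"deletion"`,
#'   both joined by `"+"`, or `""`).
#' @export
genomic_calls <- function(variants = NULL, cnv = NULL,
                          samples = NULL, genes = NULL,
                          count_vus = FALSE) {
  abort_if(is.null(variants) && is.null(cnv),
           "at least one of 'variants' or 'cnv' is required")
  if (!is.null(variants) && nrow(variants) > 0) {
    variants <- filter_variants(variants)
    variants$pathogenicity <- classify_pathogenicity(
      variants$consequence,
      if ("cadd_score" %in% names(variants)) variants$cadd_score else NA_real_)
  }
  if (!is.null(cnv) && nrow(cnv) > 0) {
    assert_cols(cnv, c("sample_id", "gene", "log2_ratio"), "CNV table")
    key <- paste(cnv$sample_id, cnv$gene)
    if (anyDuplicated(key) > 0) {
      dup <- unique(key[duplicated(key)])
      agree <- vapply(dup, function(k) {
        length(unique(cnv$log2_ratio[key == k])) == 1
      }, logical(1))
      abort_if(any(!agree),
               sprintf("conflicting duplicate CNV rows for: %s",
                       paste(utils::head(dup[!agree], 3), collapse = "; ")))
      cnv <- cnv[!duplicated(key), , drop = FALSE]
    }
    cnv$cnv_class <- classify_cnv(cnv$log2_ratio)
  }
  samples <- samples %||% sort(unique(c(
    if (!is.null(variants)) variants$sample_id,
    if (!is.null(cnv)) cnv$sample_id)))
  genes <- genes %||% sort(unique(c(
    if (!is.null(variants)) variants$gene,
    if (!is.null(cnv)) cnv$gene)))
  grid <- expand.grid(sample_id = samples, gene = genes,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  path_classes <- if (count_vus) c("pathogenic", "vus") else "pathogenic"
  has_snv <- if (!is.null(variants) && nrow(variants) > 0) {
    hit <- variants[variants$pathogenicity %in% path_classes, , drop = FALSE]
    paste(grid$sample_id, grid$gene) %in% paste(hit$sample_id, hit$gene)
  } else rep(FALSE, nrow(grid))
  has_del <- if (!is.null(cnv) && nrow(cnv) > 0) {
    del <- cnv[cnv$cnv_class == "deletion", , drop = FALSE]
    paste(grid$sample_id, grid$gene) %in% paste(del$sample_id, del$gene)
  } else rep(FALSE, nrow(grid))
  grid$abnormal <- has_snv | has_del
  grid$evidence <- trimws(paste0(ifelse(has_snv, "pathogenic_snv", ""),
                                 ifelse(has_snv & has_del, "+", ""),
                                 ifelse(has_del, "deletion", "")))
  grid[order(grid$sample_id, grid$gene), , drop = FALSE]
}

#' Separate per-assay (SNV vs CNV) abnormality calls
#'
#' Convenience wrapper around [genomic_calls()] producing the two evidence
#' channels the agreement analysis tabulates separately.
#'
#' @inheritParams genomic_calls
#' @return list with data frames `snv` and `cnv`, each as in
#'   [genomic_calls()].
#' @export
genomic_calls_by_assay <- function(variants = NULL, cnv = NULL,
                                   samples = NULL, genes = NULL,
                                   count_vus = FALSE) {
  samples <- samples %||% sort(unique(c(
    if (!is.null(variants)) variants$sample_id,
    if (!is.null(cnv)) cnv$sample_id)))
  genes <- genes %||% sort(unique(c(
    if (!is.null(variants)) variants$gene,
    if (!is.null(cnv)) cnv$gene)))
  list(
    snv = if (!is.null(variants))
      genomic_calls(variants = variants, cnv = NULL, samples = samples,
                    genes = genes, count_vus = count_vus) else NULL,
    cnv = if (!is.null(cnv))
      genomic_calls(variants = NULL, cnv = cnv, samples = samples,
                    genes = genes) else NULL)
}

#' Reduce copy-number segments to gene-level log2 ratios
#'
#' Projects SEG-style segments (1-based inclusive coordinates) onto gene
#' intervals (BED-style, 0-based half-open) and summarizes the segments
#' overlapping each gene either by overlap-length-weighted mean (default,
#' the common convention) or by the minimum segment mean (most conservative
#' for deletion calling).
#'
#' @param seg data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `seg_mean` (an optional `num_mark` column is ignored).
#' @param genes data frame with columns `chrom`, `start`, `end`, `gene`
#'   (0-based half-open).
#' @param reduce `"weighted-mean"` or `"min"`.
#' @return gene-level table `sample_id`, `gene`, `log2_ratio`; genes with no
#'   overlapping segment in a sample are omitted.
#' @export
reduce_seg_to_genes <- function(seg, genes, reduce = c("weighted-mean", "min")) {
  reduce <- match.arg(reduce)
  assert_cols(seg, c("sample", "chrom", "start", "end", "seg_mean"),
              "SEG table")
  assert_cols(genes, c("chrom", "start", "end", "gene"), "gene interval table")
  seg_gr <- GenomicRanges::GRanges(
    seqnames = seg$chrom,
    ranges = IRanges::IRanges(start = seg$start, end = seg$end))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  # suppress the seqlevel warning: disjoint chromosome sets simply mean no
  # overlap
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gene_gr, seg_gr))
  if (length(hits) == 0)
    return(data.frame(sample_id = character(), gene = character(),
                      log2_ratio = numeric(), stringsAsFactors = FALSE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gene_gr)[qi], IRanges::ranges(seg_gr)[si]))
  d <- data.frame(sample_id = seg$sample[si], gene = genes$gene[qi],
                  seg_mean = seg$seg_mean[si], w = ov,
                  stringsAsFactors = FALSE)
  groups <- split(d, list(d$sample_id, d$gene), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    val <- if (reduce == "weighted-mean")
      stats::weighted.mean(g$seg_mean, g$w) else min(g$seg_mean)
    data.frame(sample_id = g$sample_id[1], gene = g$gene[1],
               log2_ratio = val, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$sample_id, out$gene), , drop = FALSE]
}

#' Read a MAF-like variant table (TSV)
#'
#' Header `sample_id gene consequence protein_position allele_frequency
#' t_depth n_depth in_population_db in_cosmic cadd_score`; booleans as 0/1,
#' missing CADD as an empty field. Depth columns are renamed to the
#' `*_read_support` names used internally.
#' @param path TSV file path.
#' @return data frame of variants.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_cols(tab, c("sample_id", "gene", "consequence", "allele_frequency",
                     "t_depth", "n_depth", "in_population_db", "in_cosmic"),
              basename(path))
  names(tab)[names(tab) == "t_depth"] <- "tumor_read_support"
  names(tab)[names(tab) == "n_depth"] <- "normal_read_support"
  tab$in_population_db <- as.logical(tab$in_population_db)
  tab$in_cosmic <- as.logical(tab$in_cosmic)
  if (!"cadd_score" %in% names(tab)) tab$cadd_score <- NA_real_
  tab$cadd_score <- suppressWarnings(as.numeric(tab$cadd_score))
  tab
}

#' Read a gene-level CNV table (TSV)
#'
#' Header `sample_id gene log2_ratio`.
#' @param path TSV file path.
#' @return data frame.
#' @export
read_cnv_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_cols(tab, c("sample_id", "gene", "log2_ratio"), basename(path))
  tab
}

#' Read a SEG file
#'
#' Header `sample chrom start end num_mark seg_mean`, 1-based inclusive.
#' @param path TSV file path.
#' @return data frame of segments.
#' @export
read_seg <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_cols(tab, c("sample", "chrom", "start", "end", "seg_mean"),
              basename(path))
  tab
}

#' Read a BED-style gene interval file
#'
#' Four tab-separated columns `chrom start end gene` without header,
#' 0-based half-open.
#' @param path file path.
#' @return data frame with named columns.
#' @export
read_gene_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  abort_if(ncol(tab) < 4, "gene interval file needs 4 columns: chrom start end gene")
  names(tab)[1:4] <- c("chrom", "start", "end", "gene")
  tab[, 1:4]
}
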