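DEFAULT_COMBOS <- c("IHC", "CNV", "SNV", "CNV+SNV", "CNV+SNV+IHC",
                    "SNV+IHC", "CNV+IHC")

#' Run the multi-assay AVPC-m pipeline end to end
#'
#' Orchestrates all stages over whichever assay inputs are present: IHC
#' read scoring and 9-read consensus with Fleiss' kappa, loss-of-function
#' transcriptional scoring and dichotomization, variant filtering /
#' pathogenicity and copy-number classification, cross-method agreement
#' (Cohen's kappa per marker and method combination against the
#' dichotomized score), union-combined per-marker calls and the composite
#' two-of-three AVPC-m determination.
#'
#' Inputs may be in-memory objects or file paths (dispatched on type):
#' IHC reads as in [read_ihc_reads()], expression as in
#' [read_expression_matrix()], signatures as [signature_set()]s or
#' signature-table paths (sub-selected at `weight_threshold`), variants as
#' in [read_variant_table()], copy number as a gene-level table or as a
#' SEG file plus gene intervals.
#'
#' @param ihc IHC read table (data frame or CSV path), or `NULL`.
#' @param expression expression matrix (matrix or TSV path), or `NULL`.
#' @param signatures named list (per marker) of [signature_set()] objects
#'   or signature-table TSV paths; required when `expression` is given.
#' @param variants variant table (data frame or TSV path), or `NULL`.
#' @param cnv gene-level CNV table (data frame or TSV path), or `NULL`.
#' @param seg,gene_intervals SEG table/path plus BED-style gene intervals
#'   (frame or path); used to derive gene-level CNV when `cnv` is absent.
#' @param rules per-marker IHC rules, see [marker_rules()].
#' @param tie consensus tie policy, see [consensus_call()].
#' @param weighted weighted LOF scoring, see [compute_lof_scores()].
#' @param weight_threshold sub-selection threshold for signature-table
#'   paths.
#' @param count_vus count VUS variants as genomic evidence (sensitivity
#'   analysis).
#' @param seg_reduce segment reduction rule, see [reduce_seg_to_genes()].
#' @param combos method combinations for the agreement report.
#' @param out_dir optional directory for the CSV report bundle and run
#'   manifest.
#' @return (invisibly) object of class `avpcm_run`: list with
#'   `ihc_read_calls`, `ihc_consensus`, `fleiss_report`, `lof_scores`,
#'   `snv_calls`, `cnv_calls`, `calls_by_marker`, `agreement`,
#'   `combined_calls`, `avpcm`, `summary`, `manifest`.
#' @export
run_pipeline <- function(ihc = NULL, expression = NULL, signatures = NULL,
                         variants = NULL, cnv = NULL, seg = NULL,
                         gene_intervals = NULL,
                         rules = marker_rules(),
                         tie = c("indeterminate", "abnormal", "normal"),
                         weighted = FALSE, weight_threshold = 0.9,
                         count_vus = FALSE,
                         seg_reduce = c("weighted-mean", "min"),
                         combos = DEFAULT_COMBOS,
                         out_dir = NULL) {
  tie <- match.arg(tie)
  seg_reduce <- match.arg(seg_reduce)
  abort_if(is.null(ihc) && is.null(expression) && is.null(variants) &&
             is.null(cnv) && is.null(seg),
           "at least one assay input is required")
  if (is.character(ihc)) ihc <- read_ihc_reads(ihc)
  if (is.character(expression)) expression <- read_expression_matrix(expression)
  if (is.character(variants)) variants <- read_variant_table(variants)
  if (is.character(cnv)) cnv <- read_cnv_table(cnv)
  if (is.character(seg)) seg <- read_seg(seg)
  if (is.character(gene_intervals)) gene_intervals <- read_gene_bed(gene_intervals)
  if (is.null(cnv) && !is.null(seg)) {
    abort_if(is.null(gene_intervals),
             "SEG input requires gene_intervals for reduction")
    cnv <- reduce_seg_to_genes(seg, gene_intervals, reduce = seg_reduce)
  }

  calls_by_marker <- stats::setNames(
    replicate(length(MARKERS), list(), simplify = FALSE), MARKERS)

  # --- IHC stage -----------------------------------------------------------
  ihc_read_calls <- NULL; ihc_consensus <- NULL; fleiss_report <- NULL
  if (!is.null(ihc)) {
    ihc_read_calls <- score_ihc_reads(ihc, rules = rules)
    ihc_consensus <- consensus_table(ihc_read_calls, tie = tie)
    fleiss_report <- ihc_fleiss_report(ihc, rules = rules, tie = tie)
    for (m in intersect(MARKERS, unique(ihc_consensus$marker))) {
      sub <- ihc_consensus[ihc_consensus$marker == m, , drop = FALSE]
      v <- ifelse(sub$consensus == "indeterminate", NA,
                  sub$consensus == "abnormal")
      calls_by_marker[[m]]$IHC <- stats::setNames(v, sub$sample_id)
    }
  } else {
    vlog("run_pipeline: no IHC input; IHC rows absent from agreement report")
  }

  # --- LOF stage -----------------------------------------------------------
  lof_scores <- NULL
  if (!is.null(expression)) {
    abort_if(is.null(signatures),
             "'signatures' are required to score an expression matrix")
    sigs <- lapply(names(signatures), function(m) {
      s <- signatures[[m]]
      if (is.character(s)) s <- subselect_signature(
        read_signature_table(s), m, weight_threshold = weight_threshold)
      s
    })
    names(sigs) <- names(signatures)
    lof_scores <- do.call(rbind, lapply(sigs, function(s)
      compute_lof_scores(expression, s, weighted = weighted)))
    rownames(lof_scores) <- NULL
  }

  # --- genomic stage -------------------------------------------------------
  snv_calls <- NULL; cnv_calls <- NULL
  if (!is.null(variants) || !is.null(cnv)) {
    evaluable <- sort(unique(c(
      if (!is.null(variants)) variants$sample_id,
      if (!is.null(cnv)) cnv$sample_id)))
    by_assay <- genomic_calls_by_assay(
      variants = variants, cnv = cnv, samples = evaluable,
      genes = MARKERS, count_vus = count_vus)
    snv_calls <- by_assay$snv; cnv_calls <- by_assay$cnv
    for (m in MARKERS) {
      if (!is.null(snv_calls)) {
        sub <- snv_calls[snv_calls$gene == m, , drop = FALSE]
        calls_by_marker[[m]]$SNV <- stats::setNames(sub$abnormal, sub$sample_id)
      }
      if (!is.null(cnv_calls)) {
        sub <- cnv_calls[cnv_calls$gene == m, , drop = FALSE]
        calls_by_marker[[m]]$CNV <- stats::setNames(sub$abnormal, sub$sample_id)
      }
    }
  }

  # --- agreement + composite stages ---------------------------------------
  agreement <- if (!is.null(lof_scores))
    agreement_report(calls_by_marker, lof_scores, combos = combos)
  else NULL

  methods_present <- unique(unlist(lapply(calls_by_marker, names)))
  combined_calls <- NULL; avpcm <- NULL; summary_tab <- NULL
  if (length(methods_present) > 0 &&
      all(vapply(calls_by_marker, function(x) length(x) > 0, logical(1)))) {
    all_samples <- sort(unique(unlist(
      lapply(calls_by_marker, function(x) unlist(lapply(x, names))))))
    combined_calls <- do.call(rbind, lapply(MARKERS, function(m) {
      v <- suppressWarnings(combine_calls(
        calls_by_marker[[m]], samples = all_samples))
      data.frame(sample_id = names(v), marker = m, abnormal = as.logical(v),
                 methods = paste(names(calls_by_marker[[m]]), collapse = "+"),
                 stringsAsFactors = FALSE)
    }))
    avpcm <- avpcm_call(combined_calls)
    long <- do.call(rbind, lapply(MARKERS, function(m) {
      do.call(rbind, lapply(names(calls_by_marker[[m]]), function(meth) {
        v <- calls_by_marker[[m]][[meth]]
        v <- v[!is.na(v)]
        data.frame(sample_id = names(v), marker = m, method = meth,
                   abnormal = as.logical(v), stringsAsFactors = FALSE)
      }))
    }))
    combined_long <- combined_calls
    combined_long$method <- "combined"
    summary_tab <- cohort_summary(rbind(
      long, combined_long[, c("sample_id", "marker", "method", "abnormal")]))
  }

  manifest <- list(
    package = "avpcm",
    version = as.character(utils::packageVersion("avpcm")),
    parameters = list(tie = tie, weighted = weighted,
                      weight_threshold = weight_threshold,
                      count_vus = count_vus, seg_reduce = seg_reduce,
                      combos = combos),
    inputs = list(
      ihc_reads = if (is.null(ihc)) 0L else nrow(ihc),
      expression_genes = if (is.null(expression)) 0L else nrow(expression),
      expression_samples = if (is.null(expression)) 0L else ncol(expression),
      variants = if (is.null(variants)) 0L else nrow(variants),
      cnv_rows = if (is.null(cnv)) 0L else nrow(cnv)))

  result <- structure(list(
    ihc_read_calls = ihc_read_calls, ihc_consensus = ihc_consensus,
    fleiss_report = fleiss_report, lof_scores = lof_scores,
    snv_calls = snv_calls, cnv_calls = cnv_calls,
    calls_by_marker = calls_by_marker, agreement = agreement,
    combined_calls = combined_calls, avpcm = avpcm,
    summary = summary_tab, manifest = manifest), class = "avpcm_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(obj, name) {
      if (!is.null(obj))
        utils::write.csv(obj, file.path(out_dir, name), row.names = FALSE,
                         quote = FALSE)
    }
    wr(ihc_read_calls, "ihc_read_calls.csv")
    wr(ihc_consensus, "ihc_consensus.csv")
    wr(fleiss_report, "fleiss_report.csv")
    wr(lof_scores, "lof_scores.csv")
    wr(snv_calls, "snv_calls.csv")
    wr(cnv_calls, "cnv_calls.csv")
    wr(agreement, "agreement_report.csv")
    wr(combined_calls, "combined_calls.csv")
    wr(avpcm, "avpcm_calls.csv")
    wr(summary_tab, "cohort_summary.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}

#' @export
print.avpcm_run <- function(x, ...) {
  cat("<avpcm_run>\n")
  if (!is.null(x$ihc_consensus))
    cat(sprintf("  IHC: %d consensus calls over %d samples\n",
                nrow(x$ihc_consensus),
                length(unique(x$ihc_consensus$sample_id))))
  if (!is.null(x$lof_scores))
    cat(sprintf("  LOF: %d scores (%d loss)\n", nrow(x$lof_scores),
                sum(x$lof_scores$loss)))
  if (!is.null(x$agreement))
    cat(sprintf("  agreement: %d (marker, combination) rows\n",
                nrow(x$agreement)))
  if (!is.null(x$avpcm))
    cat(sprintf("  AVPC-m positive: %d / %d samples\n",
                sum(x$avpcm$avpcm_positive), nrow(x$avpcm)))
  invisible(x)
}

#' Cross-method agreement table in the published layout
#'
#' Produces one row per (marker, method combination) with the 2x2 cells,
#' Cohen's kappa and its 95% confidence bounds rounded to 3 d.p. Accepts
#' either per-marker call vectors plus dichotomized scores (delegating to
#' [agreement_report()]), or a data frame of pre-tabulated 2x2 counts --
#' e.g. counts transcribed from a published table -- whose kappas are then
#' recomputed from the cells.
#'
#' @param x per-marker calls as in [agreement_report()], or a data frame
#'   with columns `n_nn`, `n_ny`, `n_yn`, `n_yy` (any identifier columns
#'   are carried through).
#' @param lof_loss dichotomized score table (needed in the calls form).
#' @param combos method combinations (calls form).
#' @param conf_level confidence level.
#' @return data frame in the layout of [agreement_report()].
#' @examples
#' table1_report(data.frame(marker = "TP53", combination = "IHC",
#'                          n_nn = 5, n_ny = 2, n_yn = 4, n_yy = 9))
#' @export
table1_report <- function(x, lof_loss = NULL, combos = DEFAULT_COMBOS,
                          conf_level = 0.95) {
  cells <- c("n_nn", "n_ny", "n_yn", "n_yy")
  if (is.data.frame(x) && all(cells %in% names(x))) {
    out <- x
    stats_list <- lapply(seq_len(nrow(x)), function(i) {
      kr <- tryCatch(cohens_kappa(as.numeric(x[i, cells]),
                                  conf_level = conf_level),
                     error = function(e) NULL)
      if (is.null(kr)) c(NA_real_, NA_real_, NA_real_)
      else c(kr$kappa, kr$ci_low, kr$ci_high)
    })
    m <- do.call(rbind, stats_list)
    out$n <- rowSums(x[, cells])
    out$kappa <- round(m[, 1], 3)
    out$ci_low <- round(m[, 2], 3)
    out$ci_high <- round(m[, 3], 3)
    return(out)
  }
  abort_if(is.null(lof_loss),
           "'lof_loss' is required when 'x' holds call vectors")
  agreement_report(x, lof_loss, combos = combos, conf_level = conf_level)
}
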