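#' Construct a loss-of-function signature set
#'
#' A signature set holds the up-regulated (induced on pathway loss) and
#' down-regulated gene lists for one tumor suppressor, with optional member
#' weights used by weighted scoring.
#'
#' @param marker tumor suppressor the signature tracks.
#' @param up_genes,dn_genes character vectors of gene identifiers; disjoint.
#' @param up_weights,dn_weights optional non-negative weights aligned with
#'   the gene vectors (default 1).
#' @param subselected logical; `TRUE` when the set came from
#'   weight-threshold sub-selection, `FALSE` for signatures used as
#'   published.
#' @param weight_threshold threshold recorded for provenance.
#' @return object of class `signature_set`.
#' @export
signature_set <- function(marker, up_genes, dn_genes,
                          up_weights = NULL, dn_weights = NULL,
                          subselected = FALSE, weight_threshold = NA_real_) {
  assert_marker(marker)
  up_genes <- as.character(up_genes); dn_genes <- as.character(dn_genes)
  abort_if(anyDuplicated(up_genes) > 0 || anyDuplicated(dn_genes) > 0,
           "duplicate gene_ids within a signature direction")
  both <- intersect(up_genes, dn_genes)
  abort_if(length(both) > 0,
           sprintf("gene(s) in both up and dn lists (ambiguous direction): %s",
                   paste(utils::head(both, 5), collapse = ", ")))
  abort_if(length(up_genes) + length(dn_genes) == 0,
           "signature has no genes")
  up_weights <- up_weights %||% rep(1, length(up_genes))
  dn_weights <- dn_weights %||% rep(1, length(dn_genes))
  abort_if(length(up_weights) != length(up_genes) ||
             length(dn_weights) != length(dn_genes),
           "weights must align with gene lists")
  abort_if(any(c(up_weights, dn_weights) < 0), "weights must be >= 0")
  structure(list(marker = marker,
                 up_genes = up_genes, dn_genes = dn_genes,
                 up_weights = up_weights, dn_weights = dn_weights,
                 subselected = subselected,
                 weight_threshold = weight_threshold),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %s: %d up / %d dn genes%s\n",
              x$marker, length(x$up_genes), length(x$dn_genes),
              if (isTRUE(x$subselected))
                sprintf(" (sub-selected at weight >= %g)", x$weight_threshold)
              else " (as published)"))
  invisible(x)
}

#' Sub-select a signature by weight threshold
#'
#' From a full signature table (one row per gene with `weight_up` and
#' `weight_dn` evidence weights), keeps genes whose up-weight meets the
#' threshold as the up list and genes whose down-weight meets it as the dn
#' list. A gene meeting both thresholds has no unambiguous direction and is
#' an error. With the 0.9 default this reproduces the "top most-weighted"
#' sub-selection used for TP53-style signatures.
#'
#' @param table data frame with columns `gene_id`, `weight_up`, `weight_dn`
#'   (an optional `p_value` column is carried but not used).
#' @param marker marker the signature is for.
#' @param weight_threshold inclusion threshold in `(0, max weight]`
#'   (default 0.9); membership uses `>=`.
#' @return a [signature_set()] with `subselected = TRUE`, member weights
#'   taken from the table.
#' @examples
#' tab <- data.frame(gene_id = c("A", "B", "C"),
#'                   weight_up = c(0.95, 0.5, 0),
#'                   weight_dn = c(0, 0.5, 0.92))
#' subselect_signature(tab, "TP53")
#' @export
subselect_signature <- function(table, marker, weight_threshold = 0.9) {
  assert_cols(table, c("gene_id", "weight_up", "weight_dn"), "signature table")
  abort_if(nrow(table) == 0, "signature table is empty")
  dup <- table$gene_id[duplicated(table$gene_id)]
  abort_if(length(dup) > 0,
           sprintf("duplicate gene_id(s) in signature table: %s",
                   paste(utils::head(unique(dup), 5), collapse = ", ")))
  maxw <- max(table$weight_up, table$weight_dn)
  abort_if(!is.finite(weight_threshold) || weight_threshold <= 0 ||
             weight_threshold > maxw,
           "weight_threshold must lie in (0, max weight]")
  up <- table$weight_up >= weight_threshold
  dn <- table$weight_dn >= weight_threshold
  both <- which(up & dn)
  abort_if(length(both) > 0,
           sprintf("gene(s) meet both up and dn thresholds (ambiguous direction): %s",
                   paste(utils::head(table$gene_id[both], 5), collapse = ", ")))
  abort_if(!any(up) && !any(dn),
           sprintf("no genes meet weight threshold %g; lower the threshold",
                   weight_threshold))
  signature_set(marker,
                up_genes = table$gene_id[up], dn_genes = table$gene_id[dn],
                up_weights = table$weight_up[up],
                dn_weights = table$weight_dn[dn],
                subselected = TRUE, weight_threshold = weight_threshold)
}

#' Compute loss-of-function transcriptional scores
#'
#' Scores each sample for loss of a tumor suppressor pathway from a
#' normalized (log-scale) expression matrix: each signature gene is
#' z-scored across the cohort, and the score is the mean z over up genes
#' minus the mean z over dn genes (optionally weighted by the signature
#' weights). Scores are therefore cohort-relative and centered near 0; a
#' positive score indicates transcriptional evidence of pathway loss.
#'
#' @param expr numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns.
#' @param sig a [signature_set()].
#' @param weighted if `TRUE`, use weighted means with the signature weights.
#' @return data frame with columns `sample_id`, `marker`, `score`, `loss`
#'   (the `score > 0` dichotomization).
#' @details Signature genes absent from the matrix are dropped with a
#'   warning; a zero-variance gene contributes z = 0 for every sample. At
#'   least two samples are required -- single-sample scoring is refused
#'   because a cohort-relative score has no meaning for one sample. An
#'   empty up or dn side (after dropping absent genes) contributes 0.
#' @export
compute_lof_scores <- function(expr, sig, weighted = FALSE) {
  abort_if(!inherits(sig, "signature_set"), "'sig' must be a signature_set")
  expr <- as.matrix(expr)
  abort_if(is.null(rownames(expr)) || is.null(colnames(expr)),
           "expression matrix needs gene rownames and sample colnames")
  abort_if(anyDuplicated(rownames(expr)) > 0, "duplicate gene ids in matrix")
  abort_if(anyNA(expr), "expression matrix contains missing values")
  abort_if(ncol(expr) < 2,
           "cohort-relative scoring requires at least 2 samples")
  present_up <- sig$up_genes %in% rownames(expr)
  present_dn <- sig$dn_genes %in% rownames(expr)
  n_absent <- sum(!present_up) + sum(!present_dn)
  if (n_absent > 0)
    warning(sprintf("%s signature: %d gene(s) absent from matrix, dropped",
                    sig$marker, n_absent), call. = FALSE)
  abort_if(!any(present_up) && !any(present_dn),
           sprintf("no %s signature genes present in the matrix", sig$marker))

  zrow <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  side_mean <- function(genes, weights, keep) {
    genes <- genes[keep]; weights <- weights[keep]
    if (length(genes) == 0) return(rep(0, ncol(expr)))
    z <- t(apply(expr[genes, , drop = FALSE], 1, zrow))
    if (any(apply(expr[genes, , drop = FALSE], 1, stats::sd) == 0))
      vlog("%s: zero-variance signature gene(s) contribute z = 0", sig$marker)
    w <- if (weighted) weights else rep(1, length(genes))
    if (sum(w) == 0) return(rep(0, ncol(expr)))
    as.numeric(crossprod(z, w) / sum(w))
  }
  score <- side_mean(sig$up_genes, sig$up_weights, present_up) -
    side_mean(sig$dn_genes, sig$dn_weights, present_dn)
  data.frame(sample_id = colnames(expr), marker = sig$marker,
             score = score, loss = dichotomize(score),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dichotomize a loss-of-function score
#'
#' Scores strictly greater than 0 are classified as "loss"; 0 and negative
#' scores are "not loss".
#'
#' @param score finite numeric score(s).
#' @return logical vector: `TRUE` for loss.
#' @examples
#' dichotomize(c(0.5, 0, -1.3))  # TRUE FALSE FALSE
#' @export
dichotomize <- function(score) {
  abort_if(any(!is.finite(score)), "scores must be finite")
  score > 0
}

#' Read a gene-signature table (TSV)
#'
#' Header `gene_id`, `weight_up`, `weight_dn` and optionally `p_value`.
#' @param path TSV file path.
#' @return data frame.
#' @export
read_signature_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_cols(tab, c("gene_id", "weight_up", "weight_dn"), basename(path))
  tab
}

#' Read an explicit signature gene list (TSV)
#'
#' Header `gene_id`, `direction` with direction in up/dn; used for
#' signatures employed as published, without sub-selection.
#' @param path TSV file path.
#' @param marker marker the list is for.
#' @return a [signature_set()] with `subselected = FALSE`.
#' @export
read_signature_list <- function(path, marker) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_cols(tab, c("gene_id", "direction"), basename(path))
  abort_if(!all(tab$direction %in% c("up", "dn")),
           "direction must be 'up' or 'dn'")
  signature_set(marker,
                up_genes = tab$gene_id[tab$direction == "up"],
                dn_genes = tab$gene_id[tab$direction == "dn"])
}

#' Read an expression matrix (TSV, genes x samples)
#'
#' First column `gene_id`, remaining columns one per sample.
#' @param path TSV file path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_cols(tab, "gene_id", basename(path))
  m <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  rownames(m) <- tab$gene_id
  storage.mode(m) <- "double"
  abort_if(anyNA(m), sprintf("%s contains missing values", basename(path)))
  abort_if(anyDuplicated(rownames(m)) > 0,
           sprintf("%s contains duplicate gene ids", basename(path)))
  m
}
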