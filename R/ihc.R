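#' Default per-marker IHC scoring rules
#'
#' Returns the scoring rule applied to each tumor suppressor: which staining
#' intensities count toward the labeling index (`scheme`), the percent
#' threshold, and the direction of aberrancy. The defaults encode the
#' validated AVPC-m convention: TP53 is aberrant when >=10% of tumor cell
#' nuclei stain at 2+/3+ (nuclear accumulation marks missense mutants),
#' while RB1 and PTEN are aberrant when staining is lost, i.e. when at most
#' 10% of cells retain signal (RB1 nuclear at 2+/3+, PTEN cytoplasmic at
#' 1+/2+/3+).
#'
#' @param overrides optional data frame with columns `marker` and any of
#'   `scheme`, `threshold_pct`, `direction` to override per marker.
#' @return data frame with one row per marker and columns `marker`,
#'   `compartment`, `scheme` (`"S123"` or `"S23"`), `threshold_pct`,
#'   `direction` (`"high_aberrant"` or `"low_aberrant"`).
#' @examples
#' marker_rules()
#' marker_rules(data.frame(marker = "TP53", threshold_pct = 20))
#' @export
marker_rules <- function(overrides = NULL) {
  rules <- data.frame(
    marker        = MARKERS,
    compartment   = c("nuclear", "nuclear", "cytoplasmic"),
    scheme        = c("S23", "S23", "S123"),
    threshold_pct = c(10, 10, 10),
    direction     = c("high_aberrant", "low_aberrant", "low_aberrant"),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    assert_cols(overrides, "marker", "rule overrides")
    assert_marker(overrides$marker)
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$marker[i], rules$marker)
      for (col in intersect(names(overrides), c("scheme", "threshold_pct", "direction")))
        rules[[col]][j] <- overrides[[col]][i]
    }
  }
  abort_if(!all(rules$scheme %in% c("S123", "S23")),
           "scheme must be 'S123' or 'S23'")
  abort_if(!all(rules$direction %in% c("high_aberrant", "low_aberrant")),
           "direction must be 'high_aberrant' or 'low_aberrant'")
  abort_if(any(rules$threshold_pct <= 0 | rules$threshold_pct >= 100),
           "threshold_pct must lie in (0, 100)")
  rules
}

#' Validate intensity profiles
#'
#' Each IHC read records the percentage of malignant cells at staining
#' intensities 0 (none), 1+ (weak), 2+ (moderate) and 3+ (strong). Every
#' percentage must lie in \[0, 100\] and the four must sum to 100.
#'
#' @param profiles data frame with columns `pct_0`, `pct_1`, `pct_2`, `pct_3`;
#'   additional identifier columns (`sample_id`, `marker`, `lab_id`,
#'   `reader_id`) are used to name offending rows in error messages.
#' @param tol tolerance on the sum-to-100 constraint.
#' @return `profiles`, invisibly, if valid; otherwise an error.
#' @export
validate_profiles <- function(profiles, tol = 1e-9) {
  assert_cols(profiles, c("pct_0", "pct_1", "pct_2", "pct_3"),
              "intensity profile table")
  pct <- as.matrix(profiles[, c("pct_0", "pct_1", "pct_2", "pct_3")])
  bad_range <- which(apply(pct < 0 | pct > 100 | !is.finite(pct), 1, any))
  bad_sum   <- which(abs(rowSums(pct) - 100) > tol)
  bad <- union(bad_range, bad_sum)
  if (length(bad) > 0) {
    lab <- if (all(c("sample_id", "marker") %in% names(profiles))) {
      paste0(profiles$sample_id[bad[1]], "/", profiles$marker[bad[1]],
             if ("lab_id" %in% names(profiles))
               paste0("/", profiles$lab_id[bad[1]]) else "",
             if ("reader_id" %in% names(profiles))
               paste0("/", profiles$reader_id[bad[1]]) else "")
    } else paste("row", bad[1])
    stop(sprintf(
      "%d invalid intensity profile(s); first offender: %s (percentages must lie in [0,100] and sum to 100)",
      length(bad), lab), call. = FALSE)
  }
  invisible(profiles)
}

#' Labeling index from an intensity profile
#'
#' The labeling index is the percentage of malignant cells counted as
#' positive under an intensity scheme: `"S123"` counts 1+, 2+ and 3+ cells;
#' `"S23"` counts only 2+ and 3+ (excluding weak staining).
#'
#' @param profiles data frame of intensity profiles (see
#'   [validate_profiles()]); validated before use.
#' @param scheme `"S123"` or `"S23"`.
#' @return numeric vector of labeling indices in \[0, 100\], one per row.
#' @examples
#' p <- data.frame(pct_0 = 50, pct_1 = 30, pct_2 = 15, pct_3 = 5)
#' labeling_index(p, "S23")   # 20
#' labeling_index(p, "S123")  # 50
#' @export
labeling_index <- function(profiles, scheme = c("S123", "S23")) {
  scheme <- match.arg(scheme)
  validate_profiles(profiles)
  if (scheme == "S123") {
    profiles$pct_1 + profiles$pct_2 + profiles$pct_3
  } else {
    profiles$pct_2 + profiles$pct_3
  }
}

#' Call a marker normal or abnormal from a labeling index
#'
#' Applies the closed-threshold rule: a `high_aberrant` marker (TP53) is
#' abnormal when the index is at or above the threshold; a `low_aberrant`
#' marker (RB1, PTEN) is abnormal when the index is at or below it. The
#' boundary value (exactly 10% under the defaults) counts as abnormal in
#' both directions.
#'
#' @param index numeric labeling index (or vector), each in \[0, 100\].
#' @param marker marker name used to look up the rule in `rules`; ignored
#'   when `direction`/`threshold_pct` are given directly.
#' @param rules rule table from [marker_rules()].
#' @param direction,threshold_pct explicit rule components, overriding the
#'   lookup.
#' @return character vector of `"normal"` / `"abnormal"`.
#' @examples
#' call_marker(15, "TP53")   # abnormal: nuclear accumulation
#' call_marker(0,  "TP53")   # normal
#' call_marker(10, "RB1")    # abnormal: <=10% retained
#' @export
call_marker <- function(index, marker = NULL, rules = marker_rules(),
                        direction = NULL, threshold_pct = NULL) {
  abort_if(any(!is.finite(index) | index < -1e-9 | index > 100 + 1e-9),
           "labeling index must lie in [0, 100]")
  if (is.null(direction) || is.null(threshold_pct)) {
    abort_if(is.null(marker), "either 'marker' or an explicit rule is required")
    assert_marker(unique(marker))
    j <- match(marker, rules$marker)
    direction <- direction %||% rules$direction[j]
    threshold_pct <- threshold_pct %||% rules$threshold_pct[j]
  }
  k <- max(length(index), length(direction))
  high <- rep_len(direction == "high_aberrant", k)
  thr <- rep_len(threshold_pct, k)
  idx <- rep_len(index, k)
  ifelse(ifelse(high, idx >= thr, idx <= thr), "abnormal", "normal")
}

#' Score a table of IHC reads
#'
#' Computes, for each read, the labeling index under the marker's scheme and
#' the resulting normal/abnormal call. Pass `scheme` to force a single
#' scheme for all markers (used when comparing S123 vs S23 agreement).
#'
#' @param reads data frame with columns `sample_id`, `marker`, `lab_id`,
#'   `reader_id`, `pct_0`..`pct_3`.
#' @param rules per-marker rules, see [marker_rules()].
#' @param scheme `"rule"` (default; each marker's own scheme) or `"S123"` /
#'   `"S23"`.
#' @return the input with `scheme`, `labeling_index` and `call` columns
#'   appended.
#' @export
score_ihc_reads <- function(reads, rules = marker_rules(),
                            scheme = c("rule", "S123", "S23")) {
  scheme <- match.arg(scheme)
  assert_cols(reads, c("sample_id", "marker", "lab_id", "reader_id",
                       "pct_0", "pct_1", "pct_2", "pct_3"), "IHC read table")
  assert_marker(unique(reads$marker))
  validate_profiles(reads)
  j <- match(reads$marker, rules$marker)
  sch <- if (scheme == "rule") rules$scheme[j] else rep(scheme, nrow(reads))
  idx <- ifelse(sch == "S123",
                reads$pct_1 + reads$pct_2 + reads$pct_3,
                reads$pct_2 + reads$pct_3)
  out <- reads
  out$scheme <- sch
  out$labeling_index <- idx
  out$call <- call_marker(idx, direction = rules$direction[j],
                          threshold_pct = rules$threshold_pct[j])
  out
}

#' Majority consensus over the reads of one sample-marker pair
#'
#' The consensus is the strict majority of normal/abnormal calls across the
#' up-to-9 reads (3 labs x 3 readers). A tie is only possible when reads are
#' missing (even count); by default it is reported as `"indeterminate"`
#' rather than silently resolved.
#'
#' @param calls character vector of `"normal"` / `"abnormal"`.
#' @param tie policy for an exact tie: `"indeterminate"` (default),
#'   `"abnormal"` or `"normal"`.
#' @return list with `n_reads`, `n_abnormal`, `consensus` and
#'   `agreement_fraction` (share of reads voting with the majority; 0.5 at a
#'   tie).
#' @examples
#' consensus_call(c(rep("abnormal", 5), rep("normal", 4)))
#' @export
consensus_call <- function(calls, tie = c("indeterminate", "abnormal", "normal")) {
  tie <- match.arg(tie)
  calls <- calls[!is.na(calls)]
  abort_if(length(calls) == 0, "consensus requires at least one read")
  abort_if(!all(calls %in% c("normal", "abnormal")),
           "calls must be 'normal' or 'abnormal'")
  n <- length(calls)
  n_ab <- sum(calls == "abnormal")
  consensus <- if (n_ab * 2 > n) "abnormal"
  else if (n_ab * 2 < n) "normal"
  else tie
  list(n_reads = n, n_abnormal = n_ab, consensus = consensus,
       agreement_fraction = max(n_ab, n - n_ab) / n)
}

#' Consensus table across a cohort
#'
#' Applies [consensus_call()] per (sample, marker) to a scored read table.
#'
#' @param scored output of [score_ihc_reads()].
#' @inheritParams consensus_call
#' @return data frame with one row per (sample, marker): `sample_id`,
#'   `marker`, `scheme`, `n_reads`, `n_abnormal`, `consensus`,
#'   `agreement_fraction`.
#' @export
consensus_table <- function(scored, tie = c("indeterminate", "abnormal", "normal")) {
  tie <- match.arg(tie)
  assert_cols(scored, c("sample_id", "marker", "call"), "scored read table")
  groups <- split(scored, list(scored$marker, scored$sample_id), drop = TRUE)
  rows <- lapply(groups, function(g) {
    cc <- consensus_call(g$call, tie = tie)
    data.frame(sample_id = g$sample_id[1], marker = g$marker[1],
               scheme = if ("scheme" %in% names(g)) g$scheme[1] else NA_character_,
               n_reads = cc$n_reads, n_abnormal = cc$n_abnormal,
               consensus = cc$consensus,
               agreement_fraction = cc$agreement_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$marker), , drop = FALSE]
}

#' Fleiss' kappa for multi-reader categorical agreement
#'
#' Chance-corrected agreement among m raters assigning categorical labels to
#' n subjects, here the 9 (lab, reader) pairs labeling each sample
#' normal/abnormal. Subjects with an incomplete rater set are dropped (the
#' classical estimator assumes a fixed number of ratings per subject).
#'
#' @param x matrix of category labels, subjects in rows and raters in
#'   columns (`NA` marks a missing read).
#' @return Fleiss' kappa as a single number.
#' @details With subject-wise agreement
#'   \eqn{P_i = (\sum_j n_{ij}^2 - m) / (m(m-1))} and category shares
#'   \eqn{p_j}, kappa is \eqn{(\bar P - \sum_j p_j^2)/(1 - \sum_j p_j^2)}.
#'   When every rater places every subject in one single category the
#'   expected agreement is 1 and the statistic is undefined; this raises an
#'   error rather than returning a value.
#' @export
fleiss_kappa <- function(x) {
  x <- as.matrix(x)
  complete <- rowSums(is.na(x)) == 0
  if (any(!complete)) {
    vlog("fleiss_kappa: dropping %d subject(s) with missing ratings",
         sum(!complete))
    x <- x[complete, , drop = FALSE]
  }
  abort_if(nrow(x) < 2, "Fleiss' kappa requires at least 2 complete subjects")
  abort_if(ncol(x) < 2, "Fleiss' kappa requires at least 2 raters")
  categories <- sort(unique(as.vector(x)))
  abort_if(length(categories) < 2,
           "degenerate input: all ratings fall in a single category, expected agreement is 1 and kappa is undefined")
  m <- ncol(x)
  counts <- vapply(categories,
                   function(k) rowSums(x == k), numeric(nrow(x)))
  counts <- matrix(counts, nrow = nrow(x))
  P_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  p_j <- colSums(counts) / (nrow(x) * m)
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  (P_bar - P_e) / (1 - P_e)
}

#' Verbal interpretation of an agreement score
#'
#' Standard bins: 0 poor; 0.01-0.20 slight; 0.21-0.40 fair; 0.41-0.60
#' moderate; 0.61-0.80 substantial; 0.81-1.00 almost perfect.
#'
#' @param kappa numeric agreement value(s).
#' @return character vector of interpretations.
#' @examples
#' interpret_kappa(0.55)  # "moderate agreement"
#' @export
interpret_kappa <- function(kappa) {
  vapply(kappa, function(k) {
    if (!is.finite(k)) return(NA_character_)
    if (k <= 0) "poor agreement"
    else if (k <= 0.20) "slight agreement"
    else if (k <= 0.40) "fair agreement"
    else if (k <= 0.60) "moderate agreement"
    else if (k <= 0.80) "substantial agreement"
    else "almost perfect agreement"
  }, character(1))
}

#' Inter-reader agreement report per marker and intensity scheme
#'
#' For each marker and each scheme (S123 and S23), forms the subjects x
#' raters call matrix with the 9 (lab, reader) pairs as raters, and reports
#' the consensus abnormal count and Fleiss' kappa.
#'
#' @param reads raw IHC read table (see [score_ihc_reads()]).
#' @param rules per-marker rules; only thresholds/directions are used (the
#'   scheme is swept).
#' @inheritParams consensus_call
#' @return data frame with columns `marker`, `scheme`, `n_samples`,
#'   `n_raters`, `n_consensus_abnormal`, `fleiss_kappa`, `interpretation`.
#' @export
ihc_fleiss_report <- function(reads, rules = marker_rules(),
                              tie = c("indeterminate", "abnormal", "normal")) {
  tie <- match.arg(tie)
  rows <- list()
  for (marker in intersect(MARKERS, unique(reads$marker))) {
    for (scheme in c("S123", "S23")) {
      scored <- score_ihc_reads(reads[reads$marker == marker, , drop = FALSE],
                                rules = rules, scheme = scheme)
      rater <- paste(scored$lab_id, scored$reader_id, sep = ":")
      mat <- tapply(scored$call, list(scored$sample_id, rater), `[`, 1)
      kap <- tryCatch(fleiss_kappa(mat), error = function(e) NA_real_)
      cons <- consensus_table(scored, tie = tie)
      rows[[paste(marker, scheme)]] <- data.frame(
        marker = marker, scheme = scheme,
        n_samples = length(unique(scored$sample_id)),
        n_raters = length(unique(rater)),
        n_consensus_abnormal = sum(cons$consensus == "abnormal"),
        fleiss_kappa = kap,
        interpretation = interpret_kappa(kap),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an IHC read table from CSV
#'
#' Expects the header `sample_id,marker,lab_id,reader_id,pct_0,pct_1,pct_2,
#' pct_3`; validates intensity profiles and annotates the stained
#' compartment (nuclear for TP53/RB1, cytoplasmic for PTEN).
#'
#' @param path CSV file path.
#' @return validated data frame of reads with a `compartment` column.
#' @export
read_ihc_reads <- function(path) {
  reads <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(reads, c("sample_id", "marker", "lab_id", "reader_id",
                       "pct_0", "pct_1", "pct_2", "pct_3"), basename(path))
  assert_marker(unique(reads$marker))
  validate_profiles(reads)
  rules <- marker_rules()
  reads$compartment <- rules$compartment[match(reads$marker, rules$marker)]
  reads
}
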