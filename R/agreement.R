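#' Cross-tabulate paired binary calls
#'
#' Builds the 2x2 contingency table between a method's abnormal/normal
#' calls and a reference call (typically the dichotomized loss-of-function
#' transcriptional score) over the samples covered by both. Samples missing
#' either call are dropped (and logged).
#'
#' @param method_calls named logical vector (`TRUE` = abnormal/yes), names
#'   are sample ids.
#' @param reference_calls named logical vector on the same id space.
#' @return object of class `contingency_2x2`: a list with counts `n_nn`,
#'   `n_ny`, `n_yn`, `n_yy` (method x reference, no/yes order) and `n`.
#' @examples
#' m <- c(a = TRUE, b = FALSE, c = TRUE)
#' r <- c(a = TRUE, b = FALSE, c = FALSE)
#' build_contingency(m, r)
#' @export
build_contingency <- function(method_calls, reference_calls) {
  abort_if(is.null(names(method_calls)) || is.null(names(reference_calls)),
           "call vectors must be named by sample id")
  shared <- intersect(names(method_calls)[!is.na(method_calls)],
                      names(reference_calls)[!is.na(reference_calls)])
  dropped <- length(union(names(method_calls), names(reference_calls))) -
    length(shared)
  if (dropped > 0)
    vlog("build_contingency: %d sample(s) missing a call, dropped", dropped)
  abort_if(length(shared) < 1, "no samples with both calls")
  m <- as.logical(method_calls[shared])
  r <- as.logical(reference_calls[shared])
  structure(list(n_nn = sum(!m & !r), n_ny = sum(!m & r),
                 n_yn = sum(m & !r), n_yy = sum(m & r),
                 n = length(shared)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$n_nn, x$n_ny, x$n_yn, x$n_yy), 2, 2, byrow = TRUE,
              dimnames = list(method = c("no", "yes"),
                              reference = c("no", "yes")))
  print(m)
  invisible(x)
}

#' Cohen's kappa with asymptotic 95% confidence interval
#'
#' Chance-corrected agreement between two binary call sets:
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with observed agreement
#' \eqn{p_o} and expected agreement \eqn{p_e} from the marginal products.
#' The standard error uses the Fleiss-Cohen-Everitt (1969) non-null
#' asymptotic variance, and the Wald interval
#' \eqn{\kappa \pm z_{1-\alpha/2}\,se} is truncated to \[-1, 1\].
#'
#' @param x a `contingency_2x2` from [build_contingency()], or a numeric
#'   vector of four counts `(n_nn, n_ny, n_yn, n_yy)`.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `kappa_result`: list with `kappa`, `se`,
#'   `ci_low`, `ci_high`, `p_o`, `p_e`, `n`, `conf_level`.
#' @details Requires `n >= 2` and `p_e < 1`; a table with all mass in one
#'   margin pair (e.g. every call "no" on both sides) has expected
#'   agreement 1 and kappa is undefined, which raises an error.
#' @examples
#' cohens_kappa(c(5, 2, 4, 9))   # kappa 0.381 (-0.021, 0.784)
#' cohens_kappa(c(10, 0, 0, 10)) # perfect agreement
#' @export
cohens_kappa <- function(x, conf_level = 0.95) {
  if (inherits(x, "contingency_2x2"))
    x <- c(x$n_nn, x$n_ny, x$n_yn, x$n_yy)
  abort_if(length(x) != 4 || any(x < 0) || any(x %% 1 != 0),
           "expected four non-negative integer counts (n_nn, n_ny, n_yn, n_yy)")
  n <- sum(x)
  abort_if(n < 2, "kappa requires at least 2 paired calls")
  p <- matrix(x / n, 2, 2, byrow = TRUE)  # rows: method, cols: reference
  p_o <- p[1, 1] + p[2, 2]
  pr <- rowSums(p); pc <- colSums(p)
  p_e <- sum(pr * pc)
  abort_if(p_e >= 1 - 1e-12,
           "degenerate table: expected agreement is 1 (all mass in one margin pair), kappa undefined")
  kappa <- (p_o - p_e) / (1 - p_e)
  # Fleiss-Cohen-Everitt non-null large-sample variance
  A <- sum(diag(p) * (1 - (pr + pc) * (1 - kappa))^2)
  B <- (1 - kappa)^2 * (p[1, 2] * (pc[1] + pr[2])^2 +
                          p[2, 1] * (pc[2] + pr[1])^2)
  C <- (kappa - p_e * (1 - kappa))^2
  se <- sqrt(max(0, A + B - C) / (n * (1 - p_e)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kappa, se = se,
                 ci_low = max(-1, kappa - z * se),
                 ci_high = min(1, kappa + z * se),
                 p_o = p_o, p_e = p_e, n = n, conf_level = conf_level),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%d%% CI %.3f, %.3f), n = %d\n",
              x$kappa, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n))
  cat(sprintf("  observed agreement %.3f, expected %.3f -- %s\n",
              x$p_o, x$p_e, interpret_kappa(x$kappa)))
  invisible(x)
}

#' Combine per-method calls by union
#'
#' The "and/or" combination: a sample is abnormal for a marker when any of
#' the listed methods calls it abnormal. A method missing a call for some
#' sample contributes "normal" there, with a warning, so denominators are
#' preserved.
#'
#' @param calls_by_method named list of named logical vectors
#'   (`TRUE` = abnormal), one per method, e.g. `list(IHC = ..., SNV = ...)`.
#' @param methods which methods to combine (default: all in the list).
#' @param samples sample universe (default: union of names).
#' @return named logical vector over `samples`.
#' @examples
#' combine_calls(list(IHC = c(s1 = TRUE), SNV = c(s1 = FALSE)))
#' @export
combine_calls <- function(calls_by_method, methods = names(calls_by_method),
                          samples = NULL) {
  abort_if(length(methods) == 0, "at least one method is required")
  missing_m <- setdiff(methods, names(calls_by_method))
  abort_if(length(missing_m) > 0,
           sprintf("no calls supplied for method(s): %s",
                   paste(missing_m, collapse = ", ")))
  samples <- samples %||%
    sort(unique(unlist(lapply(calls_by_method[methods], names))))
  out <- stats::setNames(rep(FALSE, length(samples)), samples)
  for (m in methods) {
    v <- calls_by_method[[m]]
    absent <- setdiff(samples, names(v)[!is.na(v)])
    if (length(absent) > 0)
      warning(sprintf("method %s missing calls for %d sample(s); treated as normal",
                      m, length(absent)), call. = FALSE)
    hit <- intersect(samples, names(v)[!is.na(v) & v])
    out[hit] <- TRUE
  }
  out
}

#' Composite AVPC-m call
#'
#' A sample bears the aggressive variant prostate cancer molecular profile
#' (AVPC-m positive) when at least two of the three tumor suppressors
#' TP53, RB1, PTEN are abnormal.
#'
#' @param marker_calls data frame with columns `sample_id`, `marker`,
#'   `abnormal` (logical), covering all three markers per sample.
#' @return data frame with one row per sample: `sample_id`, `TP53`, `RB1`,
#'   `PTEN` (logicals), `n_abnormal`, `avpcm_positive`.
#' @export
avpcm_call <- function(marker_calls) {
  assert_cols(marker_calls, c("sample_id", "marker", "abnormal"),
              "marker call table")
  assert_marker(unique(marker_calls$marker))
  wide <- stats::reshape(
    marker_calls[, c("sample_id", "marker", "abnormal")],
    idvar = "sample_id", timevar = "marker", direction = "wide")
  names(wide) <- sub("^abnormal\\.", "", names(wide))
  missing_m <- setdiff(MARKERS, names(wide))
  abort_if(length(missing_m) > 0,
           sprintf("calls missing for marker(s): %s",
                   paste(missing_m, collapse = ", ")))
  abort_if(anyNA(wide[, MARKERS]),
           "every sample needs a call for all three markers")
  wide <- wide[, c("sample_id", MARKERS)]
  wide$n_abnormal <- rowSums(wide[, MARKERS])
  wide$avpcm_positive <- wide$n_abnormal >= 2
  wide[order(wide$sample_id), , drop = FALSE]
}

#' Cohort-level summary of abnormality calls
#'
#' Counts and percentages of abnormal samples per (marker, method), plus
#' AVPC-m prevalence rows per method covering all three markers.
#' Percentages are true-rounded to 1 decimal place.
#'
#' @param calls data frame with columns `sample_id`, `marker`, `method`,
#'   `abnormal`.
#' @return data frame `method`, `marker` (or `"AVPC-m"`), `n_abnormal`,
#'   `n_total`, `pct_abnormal`.
#' @export
cohort_summary <- function(calls) {
  assert_cols(calls, c("sample_id", "marker", "method", "abnormal"),
              "call table")
  abort_if(nrow(calls) == 0, "empty cohort")
  rows <- list()
  for (method in unique(calls$method)) {
    sub <- calls[calls$method == method, , drop = FALSE]
    for (marker in intersect(MARKERS, unique(sub$marker))) {
      mm <- sub[sub$marker == marker, , drop = FALSE]
      rows[[paste(method, marker)]] <- data.frame(
        method = method, marker = marker,
        n_abnormal = sum(mm$abnormal), n_total = nrow(mm),
        pct_abnormal = round(100 * sum(mm$abnormal) / nrow(mm), 1),
        stringsAsFactors = FALSE)
    }
    if (all(MARKERS %in% sub$marker)) {
      av <- avpcm_call(sub[, c("sample_id", "marker", "abnormal")])
      rows[[paste(method, "AVPC-m")]] <- data.frame(
        method = method, marker = "AVPC-m",
        n_abnormal = sum(av$avpcm_positive), n_total = nrow(av),
        pct_abnormal = round(100 * mean(av$avpcm_positive), 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Agreement report across method combinations
#'
#' For each marker and each requested method combination, tabulates the
#' (union-combined) abnormality calls against the dichotomized
#' loss-of-function score and computes Cohen's kappa with its confidence
#' interval -- the layout of a published cross-method agreement table. Each
#' row's denominator is the set of samples holding calls for every member
#' method and a reference score, so combinations involving sequencing are
#' naturally restricted to the sequenced subset.
#'
#' @param calls_by_marker named list (per marker) of named lists (per
#'   method) of named logical call vectors; e.g.
#'   `calls_by_marker$TP53$IHC`.
#' @param lof_loss data frame with `sample_id`, `marker`, `loss` from
#'   [compute_lof_scores()].
#' @param combos character vector of combinations, members joined by `"+"`
#'   (e.g. `"IHC"`, `"CNV+SNV"`); only combinations whose members all have
#'   calls for a marker are reported for it.
#' @param conf_level confidence level for the kappa interval.
#' @return data frame with one row per (marker, combination): cells `n_nn`,
#'   `n_ny`, `n_yn`, `n_yy`, `n`, `kappa`, `ci_low`, `ci_high` (kappa and
#'   bounds rounded to 3 d.p.). Degenerate tables give `NA` kappa rather
#'   than an error.
#' @export
agreement_report <- function(calls_by_marker, lof_loss,
                             combos = c("IHC", "CNV", "SNV", "CNV+SNV",
                                        "CNV+SNV+IHC", "SNV+IHC", "CNV+IHC"),
                             conf_level = 0.95) {
  assert_cols(lof_loss, c("sample_id", "marker", "loss"), "LOF loss table")
  rows <- list()
  for (marker in intersect(MARKERS, names(calls_by_marker))) {
    methods_avail <- names(calls_by_marker[[marker]])
    ref <- lof_loss[lof_loss$marker == marker, , drop = FALSE]
    reference <- stats::setNames(as.logical(ref$loss), ref$sample_id)
    for (combo in combos) {
      members <- strsplit(combo, "+", fixed = TRUE)[[1]]
      if (!all(members %in% methods_avail)) next
      # restrict to samples every member method actually evaluated
      evaluated <- Reduce(intersect, lapply(members, function(m) {
        v <- calls_by_marker[[marker]][[m]]
        names(v)[!is.na(v)]
      }))
      combined <- combine_calls(calls_by_marker[[marker]], members,
                                samples = evaluated)
      tab <- tryCatch(build_contingency(combined, reference),
                      error = function(e) NULL)
      if (is.null(tab)) next
      kr <- tryCatch(cohens_kappa(tab, conf_level = conf_level),
                     error = function(e) NULL)
      rows[[paste(marker, combo)]] <- data.frame(
        marker = marker, combination = combo,
        n_nn = tab$n_nn, n_ny = tab$n_ny, n_yn = tab$n_yn, n_yy = tab$n_yy,
        n = tab$n,
        kappa = if (is.null(kr)) NA_real_ else round(kr$kappa, 3),
        ci_low = if (is.null(kr)) NA_real_ else round(kr$ci_low, 3),
        ci_high = if (is.null(kr)) NA_real_ else round(kr$ci_high, 3),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(marker = character(), combination = character(),
               n_nn = integer(), n_ny = integer(), n_yn = integer(),
               n_yy = integer(), n = integer(), kappa = numeric(),
               ci_low = numeric(), ci_high = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bundled example cross-method agreement tables
#'
#' The printed 2x2 cross-tabulations (method call vs dichotomized
#' loss-of-function score) from a 20-sample PDX concordance study of the
#' three AVPC-m tumor suppressors, as shipped with the package. Useful for
#' demonstrating [cohens_kappa()] on real published counts.
#'
#' @return data frame with columns `marker`, `combination`, `n_nn`, `n_ny`,
#'   `n_yn`, `n_yy` and the published `kappa`, `ci_low`, `ci_high`.
#' @examples
#' tab <- example_agreement_tables()
#' cohens_kappa(unlist(tab[1, c("n_nn", "n_ny", "n_yn", "n_yy")]))
#' @export
example_agreement_tables <- function() {
  path <- system.file("extdata", "pdx_agreement_tables.csv",
                      package = "avpcm", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
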