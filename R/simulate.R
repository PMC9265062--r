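#' Configuration for the synthetic PDX cohort generator
#'
#' Bundles the parameters of the simulated study: cohort size and the
#' 3-lab x 3-reader IHC design, per-marker true loss prevalences, reader
#' noise, expression signature effect size, and the concordance between
#' genomic evidence and true loss status. Defaults emulate the 28-sample
#' PDX study structure the analysis targets: prevalences near the observed
#' IHC consensus rates, 20/28 of samples evaluable by sequencing, and a
#' bimodal labeling-index distribution clustered near 0% and 100%.
#'
#' @param n_samples cohort size (default 28).
#' @param n_labs,n_readers IHC design (3 x 3 = 9 reads per sample-marker).
#' @param seed integer seed; every generator stage derives its own
#'   substream from it, so runs are bit-reproducible.
#' @param marker_loss_prevalence named probabilities of true loss per
#'   marker.
#' @param avpcm_target_prevalence optional target P(>= 2 of 3 losses); when
#'   set, co-occurrence is induced via a latent shared-aggressiveness
#'   Bernoulli lift calibrated to hit the target in expectation. `NULL`
#'   (default) leaves markers independent.
#' @param aggressive_fraction mixing weight of the latent aggressive
#'   stratum.
#' @param ihc_noise_sd per-read (and per-sample base) Gaussian perturbation
#'   of the labeling index, percent scale.
#' @param intensity_dirichlet_conc length-3 Dirichlet concentration
#'   splitting positive mass across 1+/2+/3+.
#' @param max_weak_share cap on the 1+ share of positive mass, so that
#'   pole-level reads keep S23 and S123 indices on the same side of the
#'   threshold.
#' @param expression_effect_size shift (log2 units; SD units under the
#'   default noise) applied to signature genes in true-loss samples.
#' @param expression_noise_sd residual expression noise.
#' @param n_background_genes non-signature genes in the matrix.
#' @param n_signature_genes up/dn signature genes per direction per marker.
#' @param assay_concordance named probabilities (`SNV`, `CNV`) that genomic
#'   evidence reflects true status; with probability 1 - concordance the
#'   evidence is drawn from an independent fair coin instead.
#' @param ngs_evaluable_fraction probability a sample yields DNA (default
#'   20/28).
#' @param decoys_per_sample_gene benign/filterable decoy variants added per
#'   evaluable (sample, gene), cycling through the filter failure modes.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_samples = 28, n_labs = 3, n_readers = 3,
                          seed = 1,
                          marker_loss_prevalence = c(TP53 = 0.607, RB1 = 0.50,
                                                     PTEN = 0.536),
                          avpcm_target_prevalence = NULL,
                          aggressive_fraction = 0.5,
                          ihc_noise_sd = 5,
                          intensity_dirichlet_conc = c(1, 2, 2),
                          max_weak_share = 0.3,
                          expression_effect_size = 2,
                          expression_noise_sd = 1,
                          n_background_genes = 1000,
                          n_signature_genes = 50,
                          assay_concordance = c(SNV = 0.9, CNV = 0.9),
                          ngs_evaluable_fraction = 20 / 28,
                          decoys_per_sample_gene = 1) {
  probs <- c(marker_loss_prevalence, avpcm_target_prevalence,
             aggressive_fraction, assay_concordance, ngs_evaluable_fraction)
  abort_if(any(probs < 0 | probs > 1), "probabilities must lie in [0, 1]")
  abort_if(ihc_noise_sd < 0 || expression_noise_sd < 0,
           "noise standard deviations must be >= 0")
  abort_if(!all(MARKERS %in% names(marker_loss_prevalence)),
           "marker_loss_prevalence needs entries for TP53, RB1 and PTEN")
  abort_if(!all(c("SNV", "CNV") %in% names(assay_concordance)),
           "assay_concordance needs entries for SNV and CNV")
  abort_if(length(intensity_dirichlet_conc) != 3 ||
             any(intensity_dirichlet_conc <= 0),
           "intensity_dirichlet_conc must be 3 positive values")
  structure(list(
    n_samples = as.integer(n_samples), n_labs = as.integer(n_labs),
    n_readers = as.integer(n_readers), seed = seed,
    marker_loss_prevalence = marker_loss_prevalence[MARKERS],
    avpcm_target_prevalence = avpcm_target_prevalence,
    aggressive_fraction = aggressive_fraction,
    ihc_noise_sd = ihc_noise_sd,
    intensity_dirichlet_conc = intensity_dirichlet_conc,
    max_weak_share = max_weak_share,
    expression_effect_size = expression_effect_size,
    expression_noise_sd = expression_noise_sd,
    n_background_genes = as.integer(n_background_genes),
    n_signature_genes = as.integer(n_signature_genes),
    assay_concordance = assay_concordance,
    ngs_evaluable_fraction = ngs_evaluable_fraction,
    decoys_per_sample_gene = as.integer(decoys_per_sample_gene)),
    class = "cohort_config")
}

# P(>=2 of 3 independent Bernoulli losses) given per-marker probabilities
prob_two_of_three <- function(p) {
  p[1] * p[2] * (1 - p[3]) + p[1] * p[3] * (1 - p[2]) +
    p[2] * p[3] * (1 - p[1]) + p[1] * p[2] * p[3]
}

# stratum probabilities implied by a shared-aggressiveness lift
stratum_probs <- function(prev, lift, a) {
  p1 <- pmin(pmax(prev + lift, 0), 1)
  p0 <- pmin(pmax((prev - a * p1) / (1 - a), 0), 1)
  list(p1 = p1, p0 = p0)
}

#' Draw true per-marker loss status for a cohort
#'
#' Marker losses are Bernoulli with the configured marginal prevalences.
#' When `avpcm_target_prevalence` is set, a latent "aggressive" indicator
#' shifts all three probabilities up (down in the complementary stratum, so
#' marginals are preserved) by a lift calibrated with [stats::uniroot()] so
#' that P(>= 2 of 3 losses) equals the target in expectation.
#'
#' @param config a [cohort_config()].
#' @return data frame with columns `sample_id`, `TP53`, `RB1`, `PTEN`
#'   (logical true loss) and `avpcm_true` (>= 2 of 3).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  prev <- config$marker_loss_prevalence
  a <- config$aggressive_fraction
  lift <- 0
  if (!is.null(config$avpcm_target_prevalence)) {
    target <- config$avpcm_target_prevalence
    f <- function(l) {
      s <- stratum_probs(prev, l, a)
      a * prob_two_of_three(s$p1) + (1 - a) * prob_two_of_three(s$p0) - target
    }
    # restrict to lifts where no stratum probability needs clamping, so the
    # configured marginals are preserved exactly
    l_max <- min(1 - prev, (1 - a) * prev / a)
    l_min <- max(-prev, (1 - a) * (prev - 1) / a)
    # the lift -> prevalence map need not be monotone (for high marginals it
    # peaks at independence), so scan a grid and refine the bracketing
    # interval closest to zero lift
    grid <- seq(l_min, l_max, length.out = 201)
    fv <- vapply(grid, f, numeric(1))
    sign_change <- which(fv[-1] * fv[-length(fv)] <= 0)
    abort_if(length(sign_change) == 0 && all(abs(fv) > 1e-9),
             sprintf("avpcm_target_prevalence %.3f unachievable for these marginals (achievable range %.3f..%.3f)",
                     target, target + min(fv), target + max(fv)))
    if (length(sign_change) > 0) {
      i <- sign_change[which.min(abs(grid[sign_change]))]
      lift <- if (fv[i] == 0) grid[i] else
        stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-9)$root
    }
  }
  s <- stratum_probs(prev, lift, a)
  with_stage_seed(config$seed, "truth", {
    n <- config$n_samples
    aggressive <- stats::rbinom(n, 1, a) == 1
    loss <- vapply(MARKERS, function(m) {
      p <- ifelse(aggressive, s$p1[[m]], s$p0[[m]])
      stats::rbinom(n, 1, p) == 1
    }, logical(n))
    loss <- matrix(loss, nrow = n,
                   dimnames = list(NULL, MARKERS))
    out <- data.frame(sample_id = sprintf("PDX-%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(loss))
    out$avpcm_true <- rowSums(loss) >= 2
    out
  })
}

# cap the weak-intensity (1+) share and redistribute onto 2+/3+
split_intensities <- function(conc, max_weak) {
  g <- stats::rgamma(3, shape = conc)
  if (sum(g) == 0) g <- rep(1, 3)
  w <- g / sum(g)
  if (w[1] > max_weak) {
    extra <- w[1] - max_weak
    w[1] <- max_weak
    rest <- w[2] + w[3]
    if (rest > 0) w[2:3] <- w[2:3] + extra * w[2:3] / rest
    else w[2:3] <- extra / 2
  }
  w
}

#' Generate the 9-read IHC table for a cohort
#'
#' Each (sample, marker) gets one read per (lab, reader) pair. The base
#' labeling index sits at a pole determined by truth and marker direction
#' (TP53 loss accumulates nuclear protein, so its loss pole is high; RB1
#' and PTEN loss poles are low), perturbed per sample and per read by
#' Gaussian noise and clipped to \[0, 100\]. The positive mass of each
#' sample-marker is split across 1+/2+/3+ by one Dirichlet draw shared by
#' its 9 reads, so a noiseless configuration yields 9 identical reads.
#'
#' @param truth output of [generate_truth()].
#' @param config a [cohort_config()].
#' @param pole_high,pole_low labeling-index poles (defaults 98 and 2).
#' @return data frame of reads: `sample_id`, `marker`, `lab_id`,
#'   `reader_id`, `pct_0`..`pct_3`.
#' @export
generate_ihc <- function(truth, config, pole_high = 98, pole_low = 2) {
  stopifnot(inherits(config, "cohort_config"))
  with_stage_seed(config$seed, "ihc", {
    sd <- config$ihc_noise_sd
    labs <- sprintf("L%d", seq_len(config$n_labs))
    readers <- sprintf("R%d", seq_len(config$n_readers))
    rows <- vector("list", nrow(truth) * length(MARKERS))
    k <- 0
    for (i in seq_len(nrow(truth))) {
      for (m in MARKERS) {
        lost <- truth[[m]][i]
        # TP53: loss -> high labeling; RB1/PTEN: loss -> low labeling
        pole <- if (m == "TP53") {
          if (lost) pole_high else pole_low
        } else {
          if (lost) pole_low else pole_high
        }
        base <- min(100, max(0, pole + stats::rnorm(1, 0, sd)))
        w <- split_intensities(config$intensity_dirichlet_conc,
                               config$max_weak_share)
        idx <- pmin(100, pmax(0, base + stats::rnorm(
          length(labs) * length(readers), 0, sd)))
        grid <- expand.grid(reader_id = readers, lab_id = labs,
                            stringsAsFactors = FALSE)
        k <- k + 1
        pct_1 <- idx * w[1]; pct_2 <- idx * w[2]
        pct_3 <- pmax(0, idx - pct_1 - pct_2)  # exact complement
        rows[[k]] <- data.frame(
          sample_id = truth$sample_id[i], marker = m,
          lab_id = grid$lab_id, reader_id = grid$reader_id,
          pct_0 = 100 - idx,
          pct_1 = pct_1, pct_2 = pct_2, pct_3 = pct_3,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows[seq_len(k)])
  })
}

#' Generate a signature-structured expression matrix
#'
#' Background genes carry baseline log-scale intensities (gene-specific
#' means, Gaussian noise). Each marker owns disjoint up/dn signature gene
#' sets; in true-loss samples, up genes are shifted up and dn genes down by
#' the configured effect size. Also emits, per marker, a full signature
#' table (members weighted >= 0.9 in their direction, background genes
#' below) and the corresponding sub-selected [signature_set()].
#'
#' @param truth output of [generate_truth()].
#' @param config a [cohort_config()].
#' @return list with `expr` (genes x samples matrix), `signatures` (named
#'   list of [signature_set()]), `signature_tables` (named list of data
#'   frames with `gene_id`, `weight_up`, `weight_dn`, `p_value`).
#' @export
generate_expression <- function(truth, config) {
  stopifnot(inherits(config, "cohort_config"))
  with_stage_seed(config$seed, "expression", {
    n <- nrow(truth)
    nsig <- config$n_signature_genes
    bg <- sprintf("BG%04d", seq_len(config$n_background_genes))
    sig_genes <- lapply(stats::setNames(MARKERS, MARKERS), function(m)
      list(up = sprintf("%s_UP%03d", m, seq_len(nsig)),
           dn = sprintf("%s_DN%03d", m, seq_len(nsig))))
    genes <- c(bg, unlist(lapply(sig_genes, unlist), use.names = FALSE))
    mu <- stats::rnorm(length(genes), 7, 1)
    expr <- matrix(mu, nrow = length(genes), ncol = n) +
      matrix(stats::rnorm(length(genes) * n, 0, config$expression_noise_sd),
             nrow = length(genes))
    rownames(expr) <- genes
    colnames(expr) <- truth$sample_id
    delta <- config$expression_effect_size
    for (m in MARKERS) {
      lost <- which(truth[[m]])
      if (length(lost) > 0) {
        expr[sig_genes[[m]]$up, lost] <- expr[sig_genes[[m]]$up, lost] + delta
        expr[sig_genes[[m]]$dn, lost] <- expr[sig_genes[[m]]$dn, lost] - delta
      }
    }
    tables <- lapply(stats::setNames(MARKERS, MARKERS), function(m) {
      up <- sig_genes[[m]]$up; dn <- sig_genes[[m]]$dn
      data.frame(
        gene_id = c(bg, up, dn),
        weight_up = c(stats::runif(length(bg), 0, 0.85),
                      stats::runif(length(up), 0.9, 1),
                      stats::runif(length(dn), 0, 0.3)),
        weight_dn = c(stats::runif(length(bg), 0, 0.85),
                      stats::runif(length(up), 0, 0.3),
                      stats::runif(length(dn), 0.9, 1)),
        p_value = stats::runif(length(bg) + length(up) + length(dn)),
        stringsAsFactors = FALSE)
    })
    signatures <- lapply(stats::setNames(MARKERS, MARKERS), function(m)
      subselect_signature(tables[[m]], m, weight_threshold = 0.9))
    list(expr = expr, signatures = signatures, signature_tables = tables)
  })
}

# one decoy variant exercising a specific filter/benign failure mode
decoy_variant <- function(sample_id, gene, mode) {
  base <- data.frame(sample_id = sample_id, gene = gene,
                     consequence = "missense",
                     protein_position = sample.int(400, 1),
                     allele_frequency = stats::runif(1, 0.2, 0.6),
                     tumor_read_support = sample(30:150, 1),
                     normal_read_support = sample(15:60, 1),
                     in_population_db = FALSE, in_cosmic = FALSE,
                     cadd_score = NA_real_, stringsAsFactors = FALSE)
  switch(as.character(mode),
         "1" = { base$consequence <- "silent" },                 # benign by consequence
         "2" = { base$allele_frequency <- stats::runif(1, 0.01, 0.1) },
         "3" = { base$tumor_read_support <- sample(1:19, 1) },
         "4" = { base$in_population_db <- TRUE },                # germline, no rescue
         "5" = { base$cadd_score <- stats::runif(1, 0, 9.9) },   # benign by score
         "6" = { })                                              # VUS: missense, no CADD
  base
}

#' Generate variant and copy-number tables for a cohort
#'
#' Samples are NGS-evaluable with the configured probability. For each
#' evaluable (sample, marker), an evidence channel is drawn from a
#' marker-specific mix (TP53 deletions/missense/nonsense roughly 4:6:4,
#' RB1 13:1:1, PTEN deletions only); with the channel assay's concordance
#' probability the effective status equals true loss, otherwise an
#' independent fair coin. Effective loss yields either a deletion-range
#' log2 ratio or a pathogenic variant (missense with CADD >= 20, or
#' nonsense without a score). All evaluable pairs get a CNV row (neutral
#' unless deleted), plus benign/filterable decoy variants cycling through
#' the filter clauses.
#'
#' @param truth output of [generate_truth()].
#' @param config a [cohort_config()].
#' @param evidence_mix named list of length-3 channel weights
#'   (deletion, missense, nonsense) per marker.
#' @return list with `variants` (data frame), `cnv` (data frame),
#'   `evaluable` (character vector of sample ids).
#' @export
generate_genomics <- function(truth, config,
                              evidence_mix = list(
                                TP53 = c(4, 6, 4),
                                RB1 = c(13, 1, 1),
                                PTEN = c(1, 0, 0))) {
  stopifnot(inherits(config, "cohort_config"))
  abort_if(!all(MARKERS %in% names(evidence_mix)),
           "evidence_mix needs entries for all three markers")
  with_stage_seed(config$seed, "genomics", {
    evaluable <- truth$sample_id[
      stats::rbinom(nrow(truth), 1, config$ngs_evaluable_fraction) == 1]
    variants <- list(); cnv <- list(); k <- 0; j <- 0
    for (sid in evaluable) {
      i <- match(sid, truth$sample_id)
      for (m in MARKERS) {
        mix <- evidence_mix[[m]]
        channel <- sample(c("deletion", "missense", "nonsense"), 1,
                          prob = mix / sum(mix))
        assay <- if (channel == "deletion") "CNV" else "SNV"
        conc <- config$assay_concordance[[assay]]
        effective <- if (stats::runif(1) < conc) truth[[m]][i]
        else stats::runif(1) < 0.5
        log2r <- if (effective && channel == "deletion")
          stats::runif(1, -2.5, -0.8) else stats::runif(1, -0.3, 0.3)
        j <- j + 1
        cnv[[j]] <- data.frame(sample_id = sid, gene = m,
                               log2_ratio = log2r, stringsAsFactors = FALSE)
        if (effective && channel != "deletion") {
          k <- k + 1
          variants[[k]] <- data.frame(
            sample_id = sid, gene = m, consequence = channel,
            protein_position = sample.int(400, 1),
            allele_frequency = stats::runif(1, 0.2, 0.8),
            tumor_read_support = sample(30:200, 1),
            normal_read_support = sample(15:60, 1),
            in_population_db = FALSE,
            in_cosmic = channel == "missense",
            cadd_score = if (channel == "missense")
              stats::runif(1, 20, 40) else NA_real_,
            stringsAsFactors = FALSE)
        }
        n_decoys <- config$decoys_per_sample_gene
        if (n_decoys > 0) {
          for (d in seq_len(n_decoys)) {
            k <- k + 1
            mode <- ((i + match(m, MARKERS) + d) %% 6) + 1
            variants[[k]] <- decoy_variant(sid, m, mode)
          }
        }
      }
    }
    list(variants = if (k > 0) do.call(rbind, variants) else
      decoy_variant(character(0), character(0), 6)[0, ],
      cnv = if (j > 0) do.call(rbind, cnv) else
        data.frame(sample_id = character(), gene = character(),
                   log2_ratio = numeric(), stringsAsFactors = FALSE),
      evaluable = evaluable)
  })
}

#' Simulate a full multi-assay cohort
#'
#' Runs all generator stages under seeds derived from the config seed and
#' optionally writes the standard input files consumed by the pipeline:
#' `ihc_reads.csv`, `expression.tsv`, `signature_<marker>.tsv`,
#' `variants.tsv`, `cnv.tsv` and `truth.csv` (the last is withheld from
#' pipeline inputs and used only for validation).
#'
#' @param config a [cohort_config()].
#' @param out_dir optional output directory (created if needed).
#' @return (invisibly) list with `truth`, `ihc`, `expression`
#'   (`expr`/`signatures`/`signature_tables`), `genomics`
#'   (`variants`/`cnv`/`evaluable`), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  truth <- generate_truth(config)
  ihc <- generate_ihc(truth, config)
  expression <- generate_expression(truth, config)
  genomics <- generate_genomics(truth, config)
  result <- list(truth = truth, ihc = ihc, expression = expression,
                 genomics = genomics, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ihc, file.path(out_dir, "ihc_reads.csv"),
                     row.names = FALSE, quote = FALSE)
    expr_df <- data.frame(gene_id = rownames(expression$expr),
                          expression$expr, check.names = FALSE,
                          stringsAsFactors = FALSE)
    utils::write.table(expr_df, file.path(out_dir, "expression.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (m in MARKERS)
      utils::write.table(expression$signature_tables[[m]],
                         file.path(out_dir, sprintf("signature_%s.tsv", m)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    v <- genomics$variants
    v_out <- data.frame(sample_id = v$sample_id, gene = v$gene,
                        consequence = v$consequence,
                        protein_position = v$protein_position,
                        allele_frequency = v$allele_frequency,
                        t_depth = v$tumor_read_support,
                        n_depth = v$normal_read_support,
                        in_population_db = as.integer(v$in_population_db),
                        in_cosmic = as.integer(v$in_cosmic),
                        cadd_score = ifelse(is.na(v$cadd_score), "",
                                            format(v$cadd_score, digits = 10)),
                        stringsAsFactors = FALSE)
    utils::write.table(v_out, file.path(out_dir, "variants.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(genomics$cnv, file.path(out_dir, "cnv.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
    vlog("simulate_cohort: wrote %d files to %s", 6 + length(MARKERS) - 1,
         out_dir)
  }
  invisible(result)
}
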