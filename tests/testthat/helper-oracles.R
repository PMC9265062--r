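# Independent brute-force oracles for the agreement statistics. These stay
# deliberately naive (explicit loops over subjects/categories) so they share
# no code path with the package implementations they check.

fleiss_oracle <- function(mat) {
  cats <- sort(unique(as.vector(mat)))
  n <- nrow(mat); m <- ncol(mat)
  P_i <- numeric(n)
  for (i in seq_len(n)) {
    agree_pairs <- 0
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (a != b && mat[i, a] == mat[i, b]) agree_pairs <- agree_pairs + 1
    }
    P_i[i] <- agree_pairs / (m * (m - 1))
  }
  P_e <- 0
  for (k in cats) {
    p_k <- sum(mat == k) / (n * m)
    P_e <- P_e + p_k^2
  }
  (mean(P_i) - P_e) / (1 - P_e)
}

# Cohen's kappa recomputed by expanding the 2x2 counts into paired call
# vectors and counting category-wise agreement from scratch.
cohen_oracle <- function(nn, ny, yn, yy) {
  a <- c(rep("n", nn), rep("n", ny), rep("y", yn), rep("y", yy))
  b <- c(rep("n", nn), rep("y", ny), rep("n", yn), rep("y", yy))
  p_o <- mean(a == b)
  p_e <- 0
  for (k in c("n", "y")) p_e <- p_e + mean(a == k) * mean(b == k)
  (p_o - p_e) / (1 - p_e)
}

# random non-degenerate call matrix (both categories present)
random_call_matrix <- function(n_subjects, n_raters) {
  repeat {
    mat <- matrix(sample(c("normal", "abnormal"), n_subjects * n_raters,
                         replace = TRUE),
                  nrow = n_subjects)
    if (length(unique(as.vector(mat))) == 2) return(mat)
  }
}

# random 2x2 table with n >= 2 and non-degenerate margins
random_table <- function(max_count = 30) {
  repeat {
    x <- sample(0:max_count, 4, replace = TRUE)
    if (sum(x) < 2) next
    p <- matrix(x / sum(x), 2, 2, byrow = TRUE)
    pe <- sum(rowSums(p) * colSums(p))
    if (pe < 1 - 1e-9) return(x)
  }
}

# small default config for fast end-to-end tests
fast_config <- function(seed = 1, ...) {
  cohort_config(seed = seed, n_background_genes = 100,
                n_signature_genes = 20, ...)
}
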