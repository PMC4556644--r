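# Independent oracles used to pin down the package's statistics.
# Each is a deliberately naive implementation kept separate from the code
# paths it checks.

# Average ranks computed by hand (no rank()): position in the sorted order,
# averaging over tied blocks.
oracle_avg_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    smaller <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- smaller + (ties + 1) / 2
  }
  r
}

# Spearman correlation as rank-then-Pearson with explicit sums.
oracle_spearman <- function(x, y) {
  rx <- oracle_avg_ranks(x)
  ry <- oracle_avg_ranks(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Two-sample log-rank chi-square via the textbook O-E / hypergeometric
# variance sums over distinct event times.
oracle_logrank_chisq <- function(time, event, group) {
  group <- as.character(group)
  g1 <- unique(group)[1]
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & group == g1)
    d_j <- sum(time == t & event == 1)
    d1_j <- sum(time == t & event == 1 & group == g1)
    o <- o + d1_j
    e <- e + d_j * n1_j / n_j
    if (n_j > 1) {
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  (o - e)^2 / v
}

# AUC by brute-force pair counting (ties count half).
oracle_auc <- function(votes, is_pos) {
  pos <- votes[is_pos]
  neg <- votes[!is_pos]
  total <- 0
  for (p in pos) for (g in neg) {
    total <- total + (p > g) + 0.5 * (p == g)
  }
  total / (length(pos) * length(neg))
}

# Wrap a bare correlation matrix as a correlation_stage object so the
# transition statistic can be exercised on constructed inputs.
make_corr_stage <- function(mat, stage = "development", n_samples = 20L) {
  genes <- rownames(mat)
  if (is.null(genes)) {
    genes <- sprintf("g%02d", seq_len(nrow(mat)))
    dimnames(mat) <- list(genes, genes)
  }
  structure(
    list(stage = stage, genes = genes, matrix = mat, n_samples = n_samples,
         adjustment = "none", flagged = character(0)),
    class = "correlation_stage"
  )
}

# Random symmetric unit-diagonal correlation-like matrix.
rand_corr_mat <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(p * (p + 2)), p + 2, p)
  m <- stats::cov2cor(crossprod(a))
  dimnames(m) <- list(sprintf("g%02d", 1:p), sprintf("g%02d", 1:p))
  m
}

# Stage-labelled expression set built directly from a matrix; development
# samples spread over the four developmental types.
make_expr_set <- function(values, n_dev, n_prog, n_cancer) {
  samples <- sprintf("s%03d", seq_len(n_dev + n_prog + n_cancer))
  colnames(values) <- samples
  types <- c(rep_len(c("WE", "EEC", "MEC", "Normal"), n_dev),
             rep("Adenoma", n_prog), rep("Adenocarcinoma", n_cancer))
  names(types) <- samples
  stage_expression_set(values, types)
}
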