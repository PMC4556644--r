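#' Per-stage adjusted correlation matrix
#'
#' Computes the pairwise Pearson correlation of all genes over the samples of
#' one macro-stage. With \code{adjustment = "small_sample_bias"} every
#' off-diagonal r is replaced by the Olkin-Pratt-style corrected value
#' \eqn{r (1 + (1 - r^2) / (2(n - 3)))}, clipped to [-1, 1] — the three
#' macro-stages typically have unequal sample counts, and the correction
#' removes the first-order small-sample bias of the sample correlation so
#' their matrices are comparable. Zero-variance genes get correlation 0 to
#' everything and are flagged.
#'
#' Row g of the resulting matrix is gene g's "intra-immune vector" for the
#' stage: its correlation with every other gene in the set.
#'
#' @param expr a [stage_expression_set()].
#' @param stage one of "development", "progression", "cancer".
#' @param adjustment "small_sample_bias" (default) or "none".
#' @return object of class \code{correlation_stage}: list with \code{stage},
#'   \code{genes}, \code{matrix}, \code{n_samples}, \code{adjustment},
#'   \code{flagged} (zero-variance gene identifiers).
#' @export
stage_correlation_matrix <- function(expr, stage,
                                     adjustment = c("small_sample_bias", "none")) {
  adjustment <- match.arg(adjustment)
  stopifnot(inherits(expr, "stage_expression_set"))
  if (!stage %in% MACRO_STAGES) stop("unknown macro-stage: ", stage)
  samples <- expr$samples[expr$macro_stage == stage]
  n <- length(samples)
  if (n < 4L) stop("stage '", stage, "' has ", n, " samples; need >= 4")
  x <- expr$values[, samples, drop = FALSE]
  sds <- apply(x, 1L, sd)
  flagged <- expr$genes[sds == 0]
  r <- suppressWarnings(cor(t(x)))
  r[is.na(r)] <- 0
  if (adjustment == "small_sample_bias") {
    r <- r * (1 + (1 - r^2) / (2 * (n - 3)))
    r[r > 1] <- 1
    r[r < -1] <- -1
  }
  diag(r) <- 1
  structure(
    list(stage = stage, genes = expr$genes, matrix = r, n_samples = n,
         adjustment = adjustment, flagged = flagged),
    class = "correlation_stage"
  )
}

#' @export
print.correlation_stage <- function(x, ...) {
  cat("correlation_stage [", x$stage, "]: ", length(x$genes), " genes, n = ",
      x$n_samples, ", adjustment = ", x$adjustment, "\n", sep = "")
  invisible(x)
}

#' Spearman transition of one gene between two stages
#'
#' The transition statistic ST of a gene between two macro-stages is the
#' Spearman rank correlation between its intra-immune vectors in the two
#' stages — its correlations with all other genes, self excluded (the self
#' entry is identically 1 in both stages and would inflate agreement). ST
#' near 1 means the rank order of the gene's associations is preserved; near
#' 0, randomly reshuffled; near -1, inverted. Ties get average ranks. If
#' either vector is constant the statistic is undefined and 0 is returned.
#'
#' @param corr_a,corr_b \code{correlation_stage} objects over the identical
#'   gene universe and ordering.
#' @param gene gene identifier.
#' @return the transition statistic, in [-1, 1].
#' @export
spearman_transition <- function(corr_a, corr_b, gene) {
  if (!identical(corr_a$genes, corr_b$genes)) {
    stop("the two stages must share the identical gene universe and ordering")
  }
  i <- match(gene, corr_a$genes)
  if (is.na(i)) stop("gene not found: ", gene)
  if (length(corr_a$genes) < 4L) stop("need at least 3 other genes")
  va <- corr_a$matrix[i, -i]
  vb <- corr_b$matrix[i, -i]
  if (sd(va) == 0 || sd(vb) == 0) return(0)
  cor(va, vb, method = "spearman")
}

#' Transition coordinates and obedient/diversion labels for all genes
#'
#' Projects every gene onto the transition coordinate system: x = ST between
#' development and progression, y = ST between progression and cancer. The
#' point (1, 1) is the theoretically stable point (TSP) — a gene sitting
#' there kept its correlation rank structure through the whole process. Genes
#' within \code{radius} Euclidean distance of the TSP (boundary inclusive)
#' are labelled "obedient", the rest "diversion".
#'
#' @param dev,prog,cancer \code{correlation_stage} objects over the identical
#'   gene universe.
#' @param radius distance threshold from the TSP (default 1).
#' @return data.frame with columns \code{gene_id}, \code{st_dp},
#'   \code{st_pc}, \code{tsp_distance}, \code{label}, \code{flagged}.
#' @export
transition_coordinates <- function(dev, prog, cancer, radius = 1) {
  stopifnot(radius > 0)
  if (!identical(dev$genes, prog$genes) || !identical(prog$genes, cancer$genes)) {
    stop("the three stages must share the identical gene universe and ordering")
  }
  genes <- dev$genes
  flagged_genes <- unique(c(dev$flagged, prog$flagged, cancer$flagged))
  st_dp <- vapply(genes, function(g) spearman_transition(dev, prog, g), 0)
  st_pc <- vapply(genes, function(g) spearman_transition(prog, cancer, g), 0)
  dist <- sqrt((1 - st_dp)^2 + (1 - st_pc)^2)
  data.frame(
    gene_id = genes,
    st_dp = unname(st_dp),
    st_pc = unname(st_pc),
    tsp_distance = unname(dist),
    label = ifelse(dist <= radius, "obedient", "diversion"),
    flagged = genes %in% flagged_genes,
    row.names = NULL
  )
}

#' Fit the Spearman correlation-transition model
#'
#' The package's core procedure. For each macro-stage the adjusted gene-gene
#' correlation matrix is computed over that stage's samples; each gene's
#' intra-immune vector is then compared between consecutive stages by
#' Spearman rank correlation, giving transition coordinates (ST_D-P, ST_P-C);
#' genes farther than \code{radius} from the theoretically stable point
#' (1, 1) are classified as diversion genes — the genes whose cooperative
#' behaviour with the rest of the set is disoriented during carcinogenesis.
#'
#' @param expr a [stage_expression_set()], typically restricted to the
#'   development-varying members of a gene set of interest.
#' @param radius Euclidean distance threshold from the TSP (default 1, i.e.
#'   the quarter-circle arc through (1, 0) and (0, 1)).
#' @param adjustment correlation adjustment passed to
#'   [stage_correlation_matrix()].
#' @return object of class \code{codis_transition}: list with \code{table}
#'   (the per-gene transition data.frame), \code{stages} (the three
#'   \code{correlation_stage} objects), \code{radius}, \code{adjustment}.
#' @seealso [transition_coordinates()], [spearman_transition()]
#' @examples
#' sim <- simulate_stage_expression(sim_config(n_genes = 60, seed = 7))
#' fit <- transition_model(sim$expr)
#' print(fit)
#' head(summary(fit)$table)
#' @export
transition_model <- function(expr, radius = 1,
                             adjustment = c("small_sample_bias", "none")) {
  adjustment <- match.arg(adjustment)
  stages <- lapply(setNames(MACRO_STAGES, MACRO_STAGES), function(st) {
    stage_correlation_matrix(expr, st, adjustment)
  })
  tab <- transition_coordinates(stages$development, stages$progression,
                                stages$cancer, radius)
  structure(
    list(table = tab, stages = stages, radius = radius,
         adjustment = adjustment),
    class = "codis_transition"
  )
}

#' @export
print.codis_transition <- function(x, ...) {
  n <- nrow(x$table)
  nd <- sum(x$table$label == "diversion")
  cat("Spearman correlation-transition model\n")
  cat("  genes:", n, " radius:", x$radius, " adjustment:", x$adjustment, "\n")
  cat(sprintf("  obedient: %d  diversion: %d\n", n - nd, nd))
  invisible(x)
}

#' @export
summary.codis_transition <- function(object, ...) {
  tab <- object$table
  out <- list(
    table = tab[order(-tab$tsp_distance), ],
    n_obedient = sum(tab$label == "obedient"),
    n_diversion = sum(tab$label == "diversion"),
    median_st_dp = median(tab$st_dp),
    median_st_pc = median(tab$st_pc),
    radius = object$radius
  )
  class(out) <- "summary.codis_transition"
  out
}

#' @export
print.summary.codis_transition <- function(x, ...) {
  cat("Transition-model summary\n")
  cat(sprintf("  obedient %d / diversion %d (radius %.3g)\n",
              x$n_obedient, x$n_diversion, x$radius))
  cat(sprintf("  median ST_D-P %.3f, median ST_P-C %.3f\n",
              x$median_st_dp, x$median_st_pc))
  cat("  genes farthest from the stable point:\n")
  print(utils::head(x$table[, c("gene_id", "st_dp", "st_pc", "tsp_distance", "label")]),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.codis_transition <- function(object, ...) {
  m <- as.matrix(object$table[, c("st_dp", "st_pc")])
  rownames(m) <- object$table$gene_id
  m
}

#' Plot transition coordinates
#'
#' Scatter of (ST_D-P, ST_P-C) with the theoretically stable point and the
#' classification arc at the fitted radius.
#'
#' @param x a \code{codis_transition} fit.
#' @param ... passed to [plot()].
#' @export
plot.codis_transition <- function(x, ...) {
  tab <- x$table
  cols <- ifelse(tab$label == "diversion", "firebrick", "steelblue")
  plot(tab$st_dp, tab$st_pc, col = cols, pch = 16, cex = 0.7,
       xlim = c(-1, 1.05), ylim = c(-1, 1.05),
       xlab = "ST development-progression", ylab = "ST progression-cancer", ...)
  theta <- seq(0, 2 * pi, length.out = 361)
  lines(1 + x$radius * cos(theta), 1 + x$radius * sin(theta), lty = 2)
  points(1, 1, pch = 3, cex = 1.5)
  text(1, 1, "TSP", pos = 3)
  legend("bottomleft", legend = c("obedient", "diversion"), pch = 16,
         col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Density summary of a stage's pairwise correlations
#'
#' Gaussian kernel density of the upper-triangle off-diagonal correlations,
#' evaluated on the fixed grid [-1, 1] in steps of 0.01. Modes are local
#' maxima whose density exceeds 1% of the peak. The development stage of a
#' strongly factor-structured gene set is typically multimodal, while a
#' decorrelated (cancer-like) stage is unimodal around zero.
#'
#' @param corr a \code{correlation_stage}.
#' @param bandwidth kernel bandwidth (default 0.05).
#' @return list with \code{grid} (data.frame correlation, density),
#'   \code{n_modes}, \code{density_at_zero}.
#' @export
correlation_density_summary <- function(corr, bandwidth = 0.05) {
  stopifnot(inherits(corr, "correlation_stage"), bandwidth > 0)
  vals <- corr$matrix[upper.tri(corr$matrix)]
  if (length(vals) < 1L) stop("need at least 2 genes")
  d <- density(vals, bw = bandwidth, from = -1, to = 1, n = 201L)
  y <- d$y
  is_mode <- vapply(seq_along(y), function(i) {
    left <- if (i > 1L) y[i - 1L] else -Inf
    right <- if (i < length(y)) y[i + 1L] else -Inf
    y[i] > left && y[i] >= right && y[i] > 0.01 * max(y)
  }, TRUE)
  list(
    grid = data.frame(correlation = d$x, density = y),
    n_modes = sum(is_mode),
    density_at_zero = y[which.min(abs(d$x))]
  )
}
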