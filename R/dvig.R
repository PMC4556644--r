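#' Restrict an expression set to a gene set
#'
#' Subsets the matrix to genes present in both the expression set and the gene
#' set, preserving the matrix's gene order. The number of set members absent
#' from the matrix is attached as attribute \code{n_absent}.
#'
#' @param expr a [stage_expression_set()].
#' @param genes a gene set as from [read_gene_set()], or a character vector.
#' @return a [stage_expression_set()] over the intersection.
#' @export
restrict_to_gene_set <- function(expr, genes) {
  members <- if (is.list(genes)) genes$members else genes
  keep <- expr$genes[expr$genes %in% members]
  if (length(keep) == 0L) stop("gene set and expression matrix are disjoint")
  out <- expr[keep, ]
  attr(out, "n_absent") <- length(setdiff(members, expr$genes))
  out
}

#' Screen for development-varying genes by one-way ANOVA
#'
#' Tests each gene for differential expression across the four developmental
#' sample types (WE, EEC, MEC, Normal) with an equal-variance one-way F test;
#' progression and cancer samples are ignored. P-values are adjusted by
#' Benjamini-Hochberg over all tested genes and genes with q below
#' \code{fdr_threshold} are selected — the screen that yields the
#' development-varying immune gene (DVIG) candidates. A gene with zero
#' variance within every group has no defined F statistic; it is assigned
#' p = 1 and flagged degenerate.
#'
#' @param expr a [stage_expression_set()] (typically already restricted to an
#'   immune gene set).
#' @param fdr_threshold selection threshold on the BH q-value (default 1e-4).
#' @return data.frame with columns \code{gene_id}, \code{F}, \code{p},
#'   \code{q}, \code{selected}, \code{degenerate}.
#' @export
development_anova_screen <- function(expr, fdr_threshold = 1e-4) {
  dev_samples <- expr$samples[expr$macro_stage == "development"]
  grp <- factor(expr$sample_type[dev_samples], levels = DEV_TYPES)
  grp <- droplevels(grp)
  counts <- table(grp)
  if (sum(counts >= 2L) < 2L) {
    stop("need at least 2 developmental sample types with >= 2 samples each")
  }
  x <- expr$values[, dev_samples, drop = FALSE]

  res <- vapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    if (all(tapply(v, grp, function(g) length(g) < 2L || var(g) == 0))) {
      return(c(F = NA_real_, p = 1))
    }
    ft <- oneway.test(v ~ grp, var.equal = TRUE)
    c(F = unname(ft$statistic), p = unname(ft$p.value))
  }, c(F = 0, p = 0))

  p <- res["p", ]
  q <- p.adjust(p, method = "BH")
  data.frame(
    gene_id = expr$genes,
    F = res["F", ],
    p = p,
    q = q,
    selected = q < fdr_threshold & !is.na(res["F", ]),
    degenerate = is.na(res["F", ]),
    row.names = NULL
  )
}
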