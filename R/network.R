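#' Test predicted miRNA-mRNA pairs for inverse expression correlation
#'
#' For every predicted (miRNA, gene) pair with at least one sequence-prediction
#' source, computes the correlation of the two profiles across the paired
#' samples and a one-sided p-value for negative association (the repression
#' hypothesis is directional). P-values are BH-adjusted over all tested pairs;
#' the source-support count is attached. Pairs referencing a miRNA or gene
#' absent from the matrices, or with a constant profile, are skipped and
#' counted.
#'
#' @param mirna_expr numeric matrix, miRNAs x samples.
#' @param mrna_expr numeric matrix, genes x samples; must cover the identical
#'   sample set (columns are aligned by name).
#' @param pairs prediction edges as from [read_prediction_edges()].
#' @param method correlation estimator, "pearson" (default) or "spearman".
#' @param alternative "less" (default, one-sided negative) or "two.sided".
#' @return data.frame with columns \code{mirna_id}, \code{gene_id},
#'   \code{correlation}, \code{p}, \code{q}, \code{support}; attribute
#'   \code{n_skipped} counts skipped pairs.
#' @export
inverse_correlation_test <- function(mirna_expr, mrna_expr, pairs,
                                     method = c("pearson", "spearman"),
                                     alternative = c("less", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  shared <- intersect(colnames(mirna_expr), colnames(mrna_expr))
  if (length(shared) == 0L) stop("no shared samples between the two matrices")
  if (length(shared) < 5L) stop("need at least 5 shared samples")
  mirna_expr <- mirna_expr[, shared, drop = FALSE]
  mrna_expr <- mrna_expr[, shared, drop = FALSE]

  sup <- edge_support(pairs)
  n_skipped <- 0L
  rows <- vector("list", nrow(sup))
  for (i in seq_len(nrow(sup))) {
    m <- sup$mirna_id[i]
    g <- sup$gene_id[i]
    if (!(m %in% rownames(mirna_expr)) || !(g %in% rownames(mrna_expr))) {
      n_skipped <- n_skipped + 1L
      next
    }
    vm <- mirna_expr[m, ]
    vg <- mrna_expr[g, ]
    if (sd(vm) == 0 || sd(vg) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    ct <- suppressWarnings(
      cor.test(vm, vg, method = method, alternative = alternative, exact = FALSE)
    )
    rows[[i]] <- data.frame(
      mirna_id = m, gene_id = g,
      correlation = unname(ct$estimate),
      p = ct$p.value,
      support = sup$support[i]
    )
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (n_skipped > 0L) {
    warning(n_skipped, " pair(s) skipped (absent identifier or constant profile)")
  }
  if (length(rows) == 0L) {
    out <- data.frame(
      mirna_id = character(), gene_id = character(), correlation = numeric(),
      p = numeric(), q = numeric(), support = integer()
    )
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[, c("mirna_id", "gene_id", "correlation", "p", "q", "support")]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Assemble the regulatory network from scored pairs
#'
#' A predicted pair is kept as a solid regulatory edge only when it is listed
#' by at least \code{min_support} prediction sources, its BH q-value is below
#' \code{fdr_threshold}, and its correlation is negative.
#'
#' @param scored scored pair table from [inverse_correlation_test()].
#' @param min_support minimum number of prediction sources (default 2).
#' @param fdr_threshold q-value threshold (default 0.01).
#' @return object of class \code{regulatory_network}: list with \code{edges}
#'   (the retained rows), \code{regulated_genes}, \code{min_support},
#'   \code{fdr_threshold}.
#' @export
build_network <- function(scored, min_support = 2L, fdr_threshold = 0.01) {
  keep <- scored$support >= min_support &
    scored$q < fdr_threshold &
    scored$correlation < 0
  edges <- scored[keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(
      edges = edges,
      regulated_genes = sort(unique(edges$gene_id)),
      min_support = as.integer(min_support),
      fdr_threshold = fdr_threshold
    ),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:", nrow(x$edges), "edges,",
      length(unique(x$edges$mirna_id)), "miRNAs,",
      length(x$regulated_genes), "regulated genes\n")
  cat(sprintf("  filters: support >= %d, q < %g, correlation < 0\n",
              x$min_support, x$fdr_threshold))
  invisible(x)
}

#' Export a regulatory network
#'
#' Writes directed miRNA -> gene edges in SIF, GraphML or TSV form. SIF uses
#' the interaction label "regulates"; GraphML (via igraph) and TSV carry
#' correlation, q-value and support as edge attributes.
#'
#' @param net a \code{regulatory_network}.
#' @param path output file path.
#' @param format one of "sif", "graphml", "tsv".
#' @return invisibly, \code{path}.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  edges <- net$edges
  if (format == "sif") {
    lines <- if (nrow(edges) == 0L) character(0) else {
      paste(edges$mirna_id, "regulates", edges$gene_id, sep = "\t")
    }
    writeLines(lines, path)
  } else if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("mirna_id", "gene_id", "correlation", "q", "support")],
      directed = TRUE
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
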