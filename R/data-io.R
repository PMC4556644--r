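# Sample-type vocabulary and the fixed macro-stage map.
SAMPLE_TYPES <- c("WE", "EEC", "MEC", "Normal", "Adenoma", "Adenocarcinoma")
DEV_TYPES <- c("WE", "EEC", "MEC", "Normal")
MACRO_STAGES <- c("development", "progression", "cancer")

#' Macro-stage of each sample type
#'
#' Whole embryos (WE), early and middle embryonic colons (EEC, MEC) and normal
#' mucosa together form the developmental stage; adenomas are precancerous
#' lesions (the progression stage); adenocarcinomas are the cancer stage.
#'
#' @param sample_type character vector of sample types.
#' @return character vector of macro-stages ("development", "progression",
#'   "cancer"), same length as the input.
#' @examples
#' macro_stage_of(c("WE", "Normal", "Adenoma", "Adenocarcinoma"))
#' @export
macro_stage_of <- function(sample_type) {
  map <- c(
    WE = "development", EEC = "development", MEC = "development",
    Normal = "development", Adenoma = "progression",
    Adenocarcinoma = "cancer"
  )
  bad <- setdiff(unique(sample_type), names(map))
  if (length(bad) > 0L) {
    stop("unknown sample_type token(s): ", paste(bad, collapse = ", "))
  }
  unname(map[sample_type])
}

#' Construct a stage-labelled expression set
#'
#' Bundles a log2 expression matrix (genes x samples) with the sample-type
#' annotation and the derived macro-stage labels. All downstream screens and
#' the transition model operate on this container.
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene identifiers and colnames sample identifiers.
#' @param sample_type named character vector mapping every sample to one of
#'   WE, EEC, MEC, Normal, Adenoma, Adenocarcinoma.
#' @return an object of class \code{stage_expression_set} with components
#'   \code{genes}, \code{samples}, \code{values}, \code{sample_type},
#'   \code{macro_stage}.
#' @export
stage_expression_set <- function(values, sample_type) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stop("values must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  if (anyNA(values)) stop("missing values in expression matrix are not supported")
  missing_ann <- setdiff(samples, names(sample_type))
  if (length(missing_ann) > 0L) {
    stop(
      "samples without annotation: ",
      paste(utils::head(missing_ann, 5L), collapse = ", ")
    )
  }
  st <- as.character(sample_type[samples])
  names(st) <- samples
  ms <- macro_stage_of(st)
  names(ms) <- samples
  structure(
    list(
      genes = genes, samples = samples, values = values,
      sample_type = st, macro_stage = ms
    ),
    class = "stage_expression_set"
  )
}

#' @export
print.stage_expression_set <- function(x, ...) {
  cat("stage_expression_set:", length(x$genes), "genes x",
      length(x$samples), "samples\n")
  tab <- table(factor(x$macro_stage, levels = MACRO_STAGES))
  cat("  samples per macro-stage:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.stage_expression_set` <- function(x, genes, samples) {
  v <- x$values
  if (!missing(genes)) v <- v[genes, , drop = FALSE]
  if (!missing(samples)) v <- v[, samples, drop = FALSE]
  stage_expression_set(v, x$sample_type)
}

#' Read an expression matrix plus sample annotations
#'
#' The expression file is a TSV whose first column is \code{gene_id} and whose
#' remaining columns are samples; the annotation file is a TSV with columns
#' \code{sample_id} and \code{sample_type}. Every sample in the matrix must be
#' annotated with a known sample type; missing values and duplicate
#' identifiers are rejected.
#'
#' @param path expression TSV path.
#' @param annotations_path annotation TSV path.
#' @return a [stage_expression_set()].
#' @export
read_expression <- function(path, annotations_path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L || names(tab)[1L] != "gene_id") {
    stop("expression file must have a first column named 'gene_id'")
  }
  genes <- tab[[1L]]
  num <- suppressWarnings(
    vapply(tab[-1L], function(col) as.numeric(col), numeric(nrow(tab)))
  )
  if (nrow(tab) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(tab)[-1L]))
  bad <- which(is.na(num) & !is.na(as.matrix(tab[-1L])), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "malformed numeric cell at gene '%s', sample '%s'",
      genes[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]
    ))
  }
  rownames(num) <- genes
  ann <- utils::read.delim(annotations_path, colClasses = "character")
  if (!all(c("sample_id", "sample_type") %in% names(ann))) {
    stop("annotation file needs columns sample_id, sample_type")
  }
  sample_type <- stats::setNames(ann$sample_type, ann$sample_id)
  stage_expression_set(num, sample_type)
}

#' Write an expression set (and its annotations) to TSV
#'
#' Inverse of [read_expression()]; numeric values are written with full
#' precision so a write/read round trip is lossless.
#'
#' @param expr a [stage_expression_set()].
#' @param path expression TSV path.
#' @param annotations_path annotation TSV path (optional).
#' @return invisibly, \code{path}.
#' @export
write_expression <- function(expr, path, annotations_path = NULL) {
  tab <- data.frame(
    gene_id = expr$genes,
    format(expr$values, digits = 17, trim = TRUE, scientific = FALSE),
    check.names = FALSE
  )
  names(tab) <- c("gene_id", expr$samples)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotations_path)) {
    ann <- data.frame(sample_id = expr$samples, sample_type = unname(expr$sample_type))
    utils::write.table(ann, annotations_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read survival endpoints
#'
#' TSV with columns \code{sample_id}, \code{os_time}, \code{os_event} and
#' optionally \code{dfs_time}, \code{dfs_event}. Times are in months and must
#' be non-negative; event flags are 0/1.
#'
#' @param path TSV path.
#' @return data.frame with one row per sample; DFS columns present only when
#'   found in the file. Attribute \code{has_dfs} records which endpoints exist.
#' @export
read_survival <- function(path) {
  tab <- utils::read.delim(path)
  need <- c("sample_id", "os_time", "os_event")
  if (!all(need %in% names(tab))) {
    stop("survival file needs columns ", paste(need, collapse = ", "))
  }
  has_dfs <- all(c("dfs_time", "dfs_event") %in% names(tab))
  check_endpoint <- function(time, event, label) {
    if (!is.numeric(time) || anyNA(time) || any(time < 0)) {
      stop("negative or non-numeric ", label, " time")
    }
    if (!all(event %in% c(0, 1))) stop("non-binary ", label, " event flag")
  }
  check_endpoint(tab$os_time, tab$os_event, "OS")
  if (has_dfs) check_endpoint(tab$dfs_time, tab$dfs_event, "DFS")
  cols <- c(need, if (has_dfs) c("dfs_time", "dfs_event"))
  out <- tab[, cols]
  out$sample_id <- as.character(out$sample_id)
  attr(out, "has_dfs") <- has_dfs
  out
}

#' Bundle expression with survival endpoints
#'
#' @param expression numeric matrix genes x samples (log2 scale).
#' @param endpoints endpoint table as returned by [read_survival()], one row
#'   per sample; must cover exactly the matrix's samples.
#' @return object of class \code{survival_dataset}.
#' @export
survival_dataset <- function(expression, endpoints) {
  if (is.null(colnames(expression))) stop("expression needs sample colnames")
  if (!setequal(colnames(expression), endpoints$sample_id)) {
    stop("expression samples and endpoint samples differ")
  }
  endpoints <- endpoints[match(colnames(expression), endpoints$sample_id), ]
  structure(
    list(
      samples = colnames(expression),
      expression = expression,
      endpoints = endpoints
    ),
    class = "survival_dataset"
  )
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("survival_dataset:", nrow(x$expression), "genes x",
      length(x$samples), "samples;",
      if (isTRUE(attr(x$endpoints, "has_dfs"))) "OS + DFS" else "OS only", "\n")
  invisible(x)
}

#' Read a gene set
#'
#' Plain text, one gene identifier per line; blank lines ignored.
#'
#' @param path file path.
#' @param name label for the set (defaults to the file name).
#' @return list with components \code{name} and \code{members}.
#' @export
read_gene_set <- function(path, name = basename(path)) {
  members <- unique(trimws(readLines(path)))
  members <- members[nzchar(members)]
  if (length(members) == 0L) stop("gene set is empty")
  list(name = name, members = members)
}

#' Read miRNA target-prediction edge files
#'
#' One TSV per prediction source (columns \code{mirna_id}, \code{gene_id}).
#' Duplicate pairs within a source are collapsed; the support of a pair is the
#' number of distinct sources listing it.
#'
#' @param paths character vector of file paths.
#' @param source_labels labels for the sources, same length as \code{paths}
#'   (e.g. the prediction algorithm names).
#' @return data.frame with columns \code{mirna_id}, \code{gene_id},
#'   \code{source}; attribute \code{sources} holds the label set.
#' @export
read_prediction_edges <- function(paths, source_labels) {
  if (length(paths) != length(source_labels)) {
    stop("paths and source_labels must have the same length")
  }
  pieces <- lapply(seq_along(paths), function(i) {
    tab <- utils::read.delim(paths[i], colClasses = "character")
    if (!all(c("mirna_id", "gene_id") %in% names(tab))) {
      stop("prediction file ", paths[i], " needs columns mirna_id, gene_id")
    }
    if (nrow(tab) == 0L) {
      return(data.frame(
        mirna_id = character(), gene_id = character(), source = character()
      ))
    }
    tab <- unique(tab[, c("mirna_id", "gene_id")])
    tab$source <- source_labels[i]
    tab
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "sources") <- source_labels
  out
}

#' Write prediction edges, one file per source
#' @param edges data.frame as from [read_prediction_edges()].
#' @param dir output directory.
#' @return invisibly, the written paths (named by source).
#' @export
write_prediction_edges <- function(edges, dir) {
  sources <- attr(edges, "sources")
  if (is.null(sources)) sources <- unique(edges$source)
  paths <- character(0)
  for (s in sources) {
    p <- file.path(dir, paste0("pred_", s, ".tsv"))
    utils::write.table(
      edges[edges$source == s, c("mirna_id", "gene_id")],
      p, sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths[s] <- p
  }
  invisible(paths)
}

#' Support count per predicted miRNA-gene pair
#' @param edges data.frame as from [read_prediction_edges()].
#' @return data.frame mirna_id, gene_id, support.
#' @export
edge_support <- function(edges) {
  if (nrow(edges) == 0L) {
    return(data.frame(
      mirna_id = character(), gene_id = character(), support = integer()
    ))
  }
  key <- paste(edges$mirna_id, edges$gene_id, sep = "\r")
  agg <- tapply(edges$source, key, function(s) length(unique(s)))
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(
    mirna_id = vapply(parts, `[[`, "", 1L),
    gene_id = vapply(parts, `[[`, "", 2L),
    support = as.integer(agg)
  )
  rownames(out) <- NULL
  out[order(out$mirna_id, out$gene_id), , drop = FALSE]
}
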