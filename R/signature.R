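#' Dichotomize overall survival into Good / Poor outcome classes
#'
#' Patients who died within \code{cutoff_years} of follow-up are "Poor";
#' patients observed beyond the cutoff (dead or alive) are "Good"; patients
#' censored at or before the cutoff carry no usable class and are "excluded".
#'
#' @param endpoints endpoint table (columns \code{sample_id}, \code{os_time}
#'   in months, \code{os_event}), as from [read_survival()].
#' @param cutoff_years class boundary in years (default 5).
#' @return data.frame \code{sample_id}, \code{class}; attribute
#'   \code{counts} tabulates the classes.
#' @export
dichotomize_survival <- function(endpoints, cutoff_years = 5) {
  stopifnot(cutoff_years > 0)
  cutoff <- cutoff_years * 12
  cls <- ifelse(
    endpoints$os_time > cutoff, "Good",
    ifelse(endpoints$os_event == 1, "Poor", "excluded")
  )
  out <- data.frame(sample_id = endpoints$sample_id, class = cls)
  if (all(cls == "excluded")) stop("all samples are excluded at this cutoff")
  attr(out, "counts") <- table(factor(cls, levels = c("Good", "Poor", "excluded")))
  out
}

#' Random-forest parameters
#'
#' @param n_trees trees per forest (default 1000).
#' @param mtry variables tried per split; NULL uses floor(sqrt(p)).
#' @param seed RNG seed making every fit reproducible.
#' @return list of class \code{rf_params}.
#' @export
rf_params <- function(n_trees = 1000L, mtry = NULL, seed = 1L) {
  structure(
    list(n_trees = as.integer(n_trees), mtry = mtry, seed = as.integer(seed)),
    class = "rf_params"
  )
}

# Align an expression matrix with usable (non-excluded) outcome labels.
# Returns list(x = samples x genes, y = factor Good/Poor).
rf_design <- function(expr, labels) {
  keep <- labels$sample_id[labels$class %in% c("Good", "Poor")]
  keep <- intersect(colnames(expr), keep)
  y <- factor(labels$class[match(keep, labels$sample_id)],
              levels = c("Good", "Poor"))
  if (nlevels(droplevels(y)) < 2L) stop("need both Good and Poor classes")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  list(x = t(expr[, keep, drop = FALSE]), y = y)
}

rf_fit <- function(x, y, params, balance = FALSE) {
  mtry <- if (is.null(params$mtry)) max(1L, floor(sqrt(ncol(x)))) else params$mtry
  if (balance) {
    # class-stratified bootstrap: leaving one sample out makes its class
    # underrepresented in training, which biases noise votes against the
    # held-out class; equal per-class sampling removes the artifact
    n_min <- min(table(y))
    randomForest::randomForest(x = x, y = y, ntree = params$n_trees,
                               mtry = min(mtry, ncol(x)),
                               strata = y, sampsize = rep(n_min, nlevels(y)))
  } else {
    randomForest::randomForest(x = x, y = y, ntree = params$n_trees,
                               mtry = min(mtry, ncol(x)))
  }
}

#' Rank genes by mean decrease Gini importance
#'
#' Fits one random forest of all candidate genes on the Good/Poor labels and
#' orders genes by their mean decrease Gini (MDG) importance, descending.
#' This initial ranking drives the backward elimination in [aucrf_select()].
#'
#' @param expr numeric matrix, candidate genes x samples.
#' @param labels outcome labels from [dichotomize_survival()].
#' @param params [rf_params()].
#' @return data.frame \code{gene_id}, \code{mdg}, ordered by decreasing MDG.
#' @export
rank_genes_mdg <- function(expr, labels, params = rf_params()) {
  d <- rf_design(expr, labels)
  set.seed(params$seed)
  fit <- rf_fit(d$x, d$y, params)
  im <- randomForest::importance(fit)
  imp <- setNames(im[, "MeanDecreaseGini"], rownames(im))
  ord <- order(-imp, names(imp))
  data.frame(gene_id = names(imp)[ord], mdg = unname(imp[ord]))
}

#' Leave-one-out cross-validated Poor-vote proportions
#'
#' For each non-excluded sample, a forest is trained on all other samples and
#' the held-out sample's "Poor voting" proportion — the fraction of trees
#' voting it into the Poor class — is recorded. The vote proportions form a
#' continuous predictor for ROC analysis. Training forests use a
#' class-stratified bootstrap (equal per-class sample size): leaving a sample
#' out underrepresents its class in training, and without stratification
#' noise votes are systematically biased against the held-out class, pulling
#' the null vote AUC below one half.
#'
#' @inheritParams rank_genes_mdg
#' @return named numeric vector of vote proportions in [0, 1].
#' @export
loocv_vote_proportions <- function(expr, labels, params = rf_params()) {
  d <- rf_design(expr, labels)
  n <- nrow(d$x)
  if (n < 3L) stop("need at least 3 usable samples for LOOCV")
  set.seed(params$seed)
  votes <- numeric(n)
  for (i in seq_len(n)) {
    fit <- rf_fit(d$x[-i, , drop = FALSE], d$y[-i], params, balance = TRUE)
    v <- stats::predict(fit, d$x[i, , drop = FALSE], type = "vote")
    votes[i] <- v[1L, "Poor"]
  }
  names(votes) <- rownames(d$x)
  votes
}

#' Sensitivity, specificity and AUC of vote proportions
#'
#' Predicts Poor when the vote proportion is at or above \code{threshold}.
#' The AUC is the Mann-Whitney rank statistic of the votes against the
#' labels (ties counted half).
#'
#' @param votes named numeric vector of Poor-vote proportions.
#' @param labels outcome labels from [dichotomize_survival()].
#' @param threshold vote cutoff in [0, 1].
#' @return list with \code{sensitivity}, \code{specificity}, \code{auc},
#'   \code{threshold}.
#' @export
classification_performance <- function(votes, labels, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  cls <- labels$class[match(names(votes), labels$sample_id)]
  poor <- cls == "Poor"
  good <- cls == "Good"
  if (!any(poor) || !any(good)) stop("both classes must be present")
  pred_poor <- votes >= threshold
  r <- rank(votes)
  n_p <- sum(poor)
  n_g <- sum(good)
  auc <- (sum(r[poor]) - n_p * (n_p + 1) / 2) / (n_p * n_g)
  list(
    sensitivity = sum(pred_poor & poor) / n_p,
    specificity = sum(!pred_poor & good) / n_g,
    auc = auc,
    threshold = threshold
  )
}

# Vote threshold maximizing Youden's J; lowest such threshold on ties.
youden_threshold <- function(votes, labels) {
  cands <- sort(unique(votes))
  j <- vapply(cands, function(th) {
    perf <- classification_performance(votes, labels, th)
    perf$sensitivity + perf$specificity - 1
  }, 0)
  cands[which.max(j)]
}

#' AUC-optimised random-forest backward elimination
#'
#' The AUC-RF selection procedure: genes are ranked once by mean decrease
#' Gini on the full candidate set; subsets are then formed by repeatedly
#' removing the \code{elimination_step} lowest-ranked genes, down to a single
#' gene. Every subset is scored by the AUC of its leave-one-out Poor-vote
#' proportions against the outcome labels, and the best subset is the
#' smallest one attaining the maximal AUC. The operating threshold on the
#' best subset's votes defaults to the value maximizing Youden's J, and the
#' resulting sensitivity and specificity are reported.
#'
#' @inheritParams rank_genes_mdg
#' @param elimination_step genes removed per elimination round (default 1).
#' @param threshold explicit vote cutoff; NULL (default) uses Youden's J.
#' @return object of class \code{codis_signature}: list with
#'   \code{ranked_genes} (MDG table), \code{auc_by_size} (named numeric),
#'   \code{best_subset}, \code{votes} (LOOCV votes of the best subset),
#'   \code{threshold}, \code{sensitivity}, \code{specificity}, \code{auc},
#'   \code{labels}, \code{rf_params}.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_genes = 30, survival_n = 40, seed = 3)
#' cohort <- simulate_survival_cohort(cfg)
#' labels <- dichotomize_survival(cohort$dataset$endpoints)
#' fit <- aucrf_select(cohort$dataset$expression, labels,
#'                     params = rf_params(n_trees = 100, seed = 3),
#'                     elimination_step = 5)
#' print(fit)
#' }
#' @export
aucrf_select <- function(expr, labels, params = rf_params(),
                         elimination_step = 1L, threshold = NULL) {
  p <- nrow(expr)
  if (p < 1L) stop("need at least 1 candidate gene")
  if (p > 1L && elimination_step >= p) {
    stop("elimination_step must be below the candidate count")
  }
  ranking <- rank_genes_mdg(expr, labels, params)
  sizes <- unique(c(seq(p, 1L, by = -elimination_step), 1L))
  aucs <- setNames(numeric(length(sizes)), sizes)
  votes_by_size <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    sub <- ranking$gene_id[seq_len(sizes[k])]
    v <- loocv_vote_proportions(expr[sub, , drop = FALSE], labels, params)
    votes_by_size[[k]] <- v
    aucs[k] <- classification_performance(v, labels, 0.5)$auc
  }
  best_auc <- max(aucs)
  best_k <- sizes[aucs == best_auc]
  best_size <- min(best_k)
  best_idx <- which(sizes == best_size)
  best_subset <- ranking$gene_id[seq_len(best_size)]
  votes <- votes_by_size[[best_idx]]
  if (is.null(threshold)) threshold <- youden_threshold(votes, labels)
  perf <- classification_performance(votes, labels, threshold)
  structure(
    list(
      ranked_genes = ranking,
      auc_by_size = aucs[order(as.integer(names(aucs)))],
      best_subset = best_subset,
      votes = votes,
      threshold = threshold,
      sensitivity = perf$sensitivity,
      specificity = perf$specificity,
      auc = perf$auc,
      labels = labels,
      rf_params = params
    ),
    class = "codis_signature"
  )
}

#' @export
print.codis_signature <- function(x, ...) {
  cat("AUC-RF gene signature\n")
  cat(sprintf("  candidates: %d  best subset: %d genes  AUC: %.3f\n",
              nrow(x$ranked_genes), length(x$best_subset), x$auc))
  cat(sprintf("  threshold %.3f: sensitivity %.3f, specificity %.3f\n",
              x$threshold, x$sensitivity, x$specificity))
  cat("  genes:", paste(x$best_subset, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.codis_signature <- function(object, ...) {
  out <- list(
    best_subset = object$best_subset,
    auc = object$auc,
    auc_by_size = object$auc_by_size,
    sensitivity = object$sensitivity,
    specificity = object$specificity,
    threshold = object$threshold,
    counts = attr(object$labels, "counts")
  )
  class(out) <- "summary.codis_signature"
  out
}

#' @export
print.summary.codis_signature <- function(x, ...) {
  cat("AUC-RF summary\n")
  cat(sprintf("  best AUC %.3f at %d genes (sens %.3f / spec %.3f at vote >= %.3f)\n",
              x$auc, length(x$best_subset), x$sensitivity, x$specificity,
              x$threshold))
  if (!is.null(x$counts)) {
    cat("  classes:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                            collapse = ", "), "\n")
  }
  cat("  AUC by subset size (head):\n")
  print(utils::head(round(x$auc_by_size, 3)))
  invisible(x)
}

#' Plot the AUC elimination profile
#'
#' AUC of the LOOCV vote proportions as a function of subset size, with the
#' selected size marked.
#'
#' @param x a \code{codis_signature}.
#' @param ... passed to [plot()].
#' @export
plot.codis_signature <- function(x, ...) {
  sizes <- as.integer(names(x$auc_by_size))
  plot(sizes, x$auc_by_size, type = "b", pch = 16, cex = 0.7,
       xlab = "subset size (top-ranked genes)", ylab = "LOOCV vote AUC", ...)
  abline(v = length(x$best_subset), lty = 2)
  invisible(x)
}
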