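# First-principal-component scores of samples over a gene submatrix.
# Centered per gene; optionally unit-scaled. Sign fixed so the sum of the
# gene loadings is positive, making the orientation deterministic across
# linear-algebra backends.
pc1_scores <- function(mat, scale = FALSE) {
  if (nrow(mat) < 1L || ncol(mat) < 2L) stop("need >= 1 gene and >= 2 samples")
  sds <- apply(mat, 1L, sd)
  if (all(sds == 0)) stop("zero total variance across the panel")
  if (scale && any(sds == 0)) {
    mat <- mat[sds > 0, , drop = FALSE]
  }
  pc <- prcomp(t(mat), center = TRUE, scale. = scale)
  scores <- pc$x[, 1L]
  if (sum(pc$rotation[, 1L]) < 0) scores <- -scores
  scores
}

#' Split samples into two equal groups by PC1 rank
#'
#' Principal component analysis of the panel submatrix (per-gene centered,
#' optionally unit-scaled); samples are ordered by their first-principal-
#' component score and cut at the median rank into two groups of equal size
#' (for odd n the extra sample joins the lower-PC1 group). The PC1 sign is
#' fixed so the sum of gene loadings is positive, so group identity — not
#' just the partition — is deterministic.
#'
#' @param expr numeric matrix, panel genes x samples (>= 2 genes, >= 4
#'   samples).
#' @param scale unit-scale genes before the decomposition (default FALSE:
#'   centering only, expression is already on log scale).
#' @return list with \code{groups} (named factor "low"/"high") and
#'   \code{pc1} (named numeric scores).
#' @export
pc1_group_split <- function(expr, scale = FALSE) {
  if (nrow(expr) < 2L) stop("need at least 2 panel genes")
  if (ncol(expr) < 4L) stop("need at least 4 samples")
  scores <- pc1_scores(expr, scale = scale)
  n <- length(scores)
  n_low <- ceiling(n / 2)
  ord <- order(scores)
  grp <- rep("high", n)
  grp[ord[seq_len(n_low)]] <- "low"
  groups <- factor(grp, levels = c("low", "high"))
  names(groups) <- names(scores)
  list(groups = groups, pc1 = scores)
}

#' Kaplan-Meier curves and the two-sample log-rank test
#'
#' @param endpoints data.frame with columns \code{time} and \code{event}
#'   (or \code{os_time}/\code{os_event}), one row per sample, aligned with
#'   \code{groups}.
#' @param groups factor with two levels assigning each sample to a group.
#' @return object of class \code{km_result}: list with \code{group_sizes},
#'   \code{chisq}, \code{p}, \code{curves} (per-group time / at-risk /
#'   events / survival-estimate table).
#' @export
km_logrank <- function(endpoints, groups) {
  if (!is.null(endpoints$time)) {
    time <- endpoints$time
    event <- endpoints$event
  } else {
    time <- endpoints$os_time
    event <- endpoints$os_event
  }
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2L) stop("need exactly 2 non-empty groups")
  stopifnot(length(time) == length(groups), all(time >= 0))
  surv <- survival::Surv(time, event)
  fit <- survival::survfit(surv ~ groups)
  strata_names <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(
    group = sub("^groups=", "", strata_names),
    time = fit$time,
    at_risk = fit$n.risk,
    events = fit$n.event,
    survival = fit$surv
  )
  if (sum(event) == 0) {
    chisq <- 0
    p <- 1
  } else {
    sd <- survival::survdiff(surv ~ groups)
    chisq <- unname(sd$chisq)
    p <- pchisq(chisq, df = 1L, lower.tail = FALSE)
  }
  structure(
    list(group_sizes = table(groups), chisq = chisq, p = p, curves = curves),
    class = "km_result"
  )
}

#' @export
print.km_result <- function(x, ...) {
  cat("Kaplan-Meier / log-rank:",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes), collapse = ", "),
      sprintf("; chisq = %.3f, p = %.4g\n", x$chisq, x$p))
  invisible(x)
}

#' Univariate screen plus one multivariate Cox model
#'
#' Each covariate is first fit in its own proportional-hazards model;
#' covariates reaching univariate p below \code{entry_p} enter a single
#' multivariate fit. Hazard ratios with 95% Wald intervals are reported for
#' both scopes. Covariates whose univariate fit fails to converge are flagged
#' and dropped with a warning; collinear covariates in the multivariate fit
#' are an error.
#'
#' @param endpoints data.frame with \code{time} and \code{event} columns.
#' @param covariates data.frame of covariates, same row order; no missing
#'   values.
#' @param entry_p univariate entry threshold (default 0.05).
#' @return list with data.frames \code{univariate} and \code{multivariate}
#'   (columns term, hr, ci_low, ci_high, p) and \code{entered} (covariate
#'   names included in the multivariate fit).
#' @export
cox_stepwise <- function(endpoints, covariates, entry_p = 0.05) {
  if (anyNA(covariates)) stop("covariates contain missing values")
  surv <- survival::Surv(endpoints$time, endpoints$event)
  tidy_fit <- function(fit) {
    s <- summary(fit)
    data.frame(
      term = rownames(s$coefficients),
      hr = unname(s$coefficients[, "exp(coef)"]),
      ci_low = unname(s$conf.int[, "lower .95"]),
      ci_high = unname(s$conf.int[, "upper .95"]),
      p = unname(s$coefficients[, "Pr(>|z|)"])
    )
  }
  uni <- list()
  entered <- character(0)
  failed <- character(0)
  for (nm in names(covariates)) {
    dat <- data.frame(covariates[nm])
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(surv ~ ., data = dat),
        warning = function(w) {
          if (grepl("converge|infinite|beta", conditionMessage(w))) {
            stop("no-convergence")
          }
          invokeRestart("muffleWarning")
        }
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || anyNA(stats::coef(fit))) {
      failed <- c(failed, nm)
      next
    }
    tf <- tidy_fit(fit)
    tf$covariate <- nm
    uni[[nm]] <- tf
    if (min(tf$p) < entry_p) entered <- c(entered, nm)
  }
  if (length(failed) > 0L) {
    warning("covariate(s) failed to converge and were dropped: ",
            paste(failed, collapse = ", "))
  }
  univariate <- do.call(rbind, uni)
  rownames(univariate) <- NULL
  multivariate <- NULL
  if (length(entered) > 0L) {
    mfit <- survival::coxph(surv ~ ., data = covariates[entered])
    if (anyNA(stats::coef(mfit))) stop("collinear covariates in multivariate model")
    multivariate <- tidy_fit(mfit)
  }
  list(univariate = univariate, multivariate = multivariate, entered = entered)
}

# Endpoint columns of a survival_dataset endpoint table, normalized
# to time/event; NULL if the endpoint is absent.
endpoint_columns <- function(endpoints, endpoint) {
  if (endpoint == "os") {
    data.frame(time = endpoints$os_time, event = endpoints$os_event)
  } else if (all(c("dfs_time", "dfs_event") %in% names(endpoints))) {
    data.frame(time = endpoints$dfs_time, event = endpoints$dfs_event)
  } else {
    NULL
  }
}

#' Evaluate a gene panel across survival datasets
#'
#' For every dataset and requested endpoint the panel submatrix is split by
#' PC1 rank ([pc1_group_split()]) and the two groups compared by log-rank
#' test ([km_logrank()]). Panel genes absent from a dataset are dropped with
#' a warning; a dataset retaining fewer than 2 panel genes is skipped and
#' recorded.
#'
#' @param panel character vector of gene identifiers.
#' @param datasets list of [survival_dataset()] objects (named, optionally).
#' @param endpoints endpoints to test, subset of c("os", "dfs").
#' @param scale passed to [pc1_group_split()].
#' @return data.frame with one row per dataset x endpoint: \code{dataset},
#'   \code{endpoint}, \code{n}, \code{n_genes}, \code{chisq}, \code{p};
#'   attribute \code{skipped} lists skipped dataset labels.
#' @export
evaluate_panel <- function(panel, datasets, endpoints = "os", scale = FALSE) {
  stopifnot(all(endpoints %in% c("os", "dfs")))
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  rows <- list()
  skipped <- character(0)
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    present <- intersect(panel, rownames(ds$expression))
    if (length(present) < length(panel)) {
      warning(length(panel) - length(present), " panel gene(s) absent from ",
              ds_name)
    }
    if (length(present) < 2L) {
      skipped <- c(skipped, ds_name)
      next
    }
    split <- pc1_group_split(ds$expression[present, , drop = FALSE], scale = scale)
    for (ep in endpoints) {
      cols <- endpoint_columns(ds$endpoints, ep)
      if (is.null(cols)) next
      km <- km_logrank(cols, split$groups)
      rows[[paste(ds_name, ep)]] <- data.frame(
        dataset = ds_name, endpoint = ep, n = length(split$groups),
        n_genes = length(present), chisq = km$chisq, p = km$p
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(dataset = character(), endpoint = character(),
                      n = integer(), n_genes = integer(),
                      chisq = numeric(), p = numeric())
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Random-panel null distribution of joint prognostic significance
#'
#' Draws \code{n_draws} random panels of \code{n_genes} genes from a pool and
#' counts how many panels are simultaneously significant (log-rank p below
#' \code{alpha}) on every dataset/endpoint tested — the permutation control
#' for a signature-selection pipeline: a pool enriched in genuinely
#' prognostic genes yields more jointly significant panels than an
#' uninformative pool.
#'
#' @param pool character vector of gene identifiers to draw from.
#' @param n_genes panel size per draw.
#' @param n_draws number of draws (the study design uses 2000).
#' @param datasets list of [survival_dataset()] objects.
#' @param endpoints endpoints to require, subset of c("os", "dfs").
#' @param alpha per-test significance level (default 0.05).
#' @param seed RNG seed.
#' @param scale passed to [pc1_group_split()].
#' @return object of class \code{panel_null_result}: list with
#'   \code{n_draws}, \code{n_significant_all}, \code{p_values} (draws x
#'   dataset/endpoint matrix), \code{alpha}, \code{seed}.
#' @export
random_panel_null <- function(pool, n_genes, n_draws, datasets,
                              endpoints = "os", alpha = 0.05, seed = 1L,
                              scale = FALSE) {
  if (length(pool) < n_genes) stop("pool smaller than the panel size")
  set.seed(seed)
  if (n_draws == 0L) {
    return(structure(
      list(n_draws = 0L, n_significant_all = 0L,
           p_values = matrix(numeric(0), 0, 0), alpha = alpha, seed = seed),
      class = "panel_null_result"
    ))
  }
  p_rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    panel <- sample(pool, n_genes)
    res <- evaluate_panel(panel, datasets, endpoints, scale = scale)
    p_rows[[i]] <- setNames(res$p, paste(res$dataset, res$endpoint, sep = "."))
  }
  p_mat <- do.call(rbind, p_rows)
  n_sig <- sum(apply(p_mat, 1L, function(p) all(p < alpha)))
  structure(
    list(n_draws = as.integer(n_draws), n_significant_all = as.integer(n_sig),
         p_values = p_mat, alpha = alpha, seed = as.integer(seed)),
    class = "panel_null_result"
  )
}

#' @export
print.panel_null_result <- function(x, ...) {
  cat(sprintf(
    "random-panel null: %d / %d draws jointly significant at alpha = %g\n",
    x$n_significant_all, x$n_draws, x$alpha))
  invisible(x)
}
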