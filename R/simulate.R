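#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults define the
#' benchmark conditions used throughout the test-suite and the acceptance
#' script: 200 genes over three macro-stages of 40 samples each, a 5-factor
#' latent correlation structure, 15% planted diversion genes, observation
#' noise with SD 0.5; 20 miRNAs with 3 targets each measured on 60 paired
#' samples at regulation strength -1 with 200 double-source and 100
#' single-source uncoupled decoy predictions; and a 200-patient survival
#' cohort whose hazard follows the first principal component of a planted
#' 12-gene signature with log hazard ratio ln 2 and a baseline hazard of 1/60
#' per month.
#'
#' @param n_genes number of simulated genes.
#' @param n_samples_per_stage named integer vector, samples per macro-stage.
#' @param n_latent_factors number of latent factors shared within a stage.
#' @param diversion_fraction fraction of genes whose factor loadings are
#'   re-drawn in progression and again in cancer (the planted diversion set).
#' @param noise_sd SD of the additive observation noise (log2 units).
#' @param n_mirnas number of regulating miRNAs.
#' @param n_null_mirnas additional miRNAs with no targets (decoy regulators).
#' @param targets_per_mirna planted targets per regulating miRNA.
#' @param regulation_strength multiplier linking a miRNA profile to the mean
#'   expression of its targets; must be <= 0 (repression).
#' @param n_mirna_samples number of paired samples carrying miRNA data.
#' @param n_decoys_double,n_decoys_single numbers of uncoupled decoy
#'   prediction edges listed by two sources resp. one source.
#' @param survival_n patients in the simulated survival cohort.
#' @param signature_genes identifiers of the planted prognostic genes; NULL
#'   uses the first \code{n_signature_genes} simulated genes.
#' @param n_signature_genes size of the default planted signature.
#' @param log_hazard_coef log hazard ratio per SD of signature PC1.
#' @param baseline_hazard baseline event rate, per month.
#' @param censor_rate expected fraction of censored patients under the null.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 200L,
                       n_samples_per_stage = c(development = 40L,
                                               progression = 40L,
                                               cancer = 40L),
                       n_latent_factors = 5L,
                       diversion_fraction = 0.15,
                       noise_sd = 0.5,
                       n_mirnas = 20L,
                       n_null_mirnas = 10L,
                       targets_per_mirna = 3L,
                       regulation_strength = -1,
                       n_mirna_samples = 60L,
                       n_decoys_double = 200L,
                       n_decoys_single = 100L,
                       survival_n = 200L,
                       signature_genes = NULL,
                       n_signature_genes = 12L,
                       log_hazard_coef = log(2),
                       baseline_hazard = 1 / 60,
                       censor_rate = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_per_stage = unlist(n_samples_per_stage),
    n_latent_factors = as.integer(n_latent_factors),
    diversion_fraction = diversion_fraction,
    noise_sd = noise_sd,
    n_mirnas = as.integer(n_mirnas),
    n_null_mirnas = as.integer(n_null_mirnas),
    targets_per_mirna = as.integer(targets_per_mirna),
    regulation_strength = regulation_strength,
    n_mirna_samples = as.integer(n_mirna_samples),
    n_decoys_double = as.integer(n_decoys_double),
    n_decoys_single = as.integer(n_decoys_single),
    survival_n = as.integer(survival_n),
    signature_genes = signature_genes,
    n_signature_genes = as.integer(n_signature_genes),
    log_hazard_coef = log_hazard_coef,
    baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_genes > 0L, all(cfg$n_samples_per_stage > 0L),
    cfg$n_latent_factors > 0L,
    cfg$diversion_fraction >= 0, cfg$diversion_fraction <= 1,
    cfg$noise_sd > 0, cfg$n_mirnas > 0L, cfg$targets_per_mirna > 0L,
    cfg$regulation_strength <= 0, cfg$survival_n > 0L,
    cfg$censor_rate >= 0, cfg$censor_rate < 1, cfg$baseline_hazard > 0
  )
  if (!setequal(names(cfg$n_samples_per_stage), MACRO_STAGES)) {
    stop("n_samples_per_stage must be named development/progression/cancer")
  }
  class(cfg) <- "sim_config"
  cfg
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))
mirna_ids <- function(n) sprintf("mir%03d", seq_len(n))

# One stage's expression block under the latent-factor model:
# X[g, s] = L[g, ] . F[, s] + noise.
factor_block <- function(loadings, n_samples, noise_sd) {
  k <- ncol(loadings)
  f <- matrix(rnorm(k * n_samples), k, n_samples)
  loadings %*% f + matrix(rnorm(nrow(loadings) * n_samples, sd = noise_sd),
                          nrow(loadings), n_samples)
}

#' Simulate stage-labelled expression with planted diversion genes
#'
#' Each gene carries a loading vector over a small number of latent factors;
#' factors are drawn independently per sample, so within a stage genes sharing
#' loadings are strongly correlated. "Obedient" genes reuse the same loadings
#' in all three macro-stages, preserving their correlation pattern; planted
#' "diversion" genes draw fresh, independent loadings in progression and again
#' in cancer, so their correlation rank order is re-randomised at each
#' transition. Development samples are spread evenly over the four
#' developmental sample types (WE, EEC, MEC, Normal).
#'
#' @param config a [sim_config()].
#' @return list with components \code{expr} (a [stage_expression_set()]) and
#'   \code{truth} (list with \code{diversion_genes}).
#' @export
simulate_stage_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- gene_ids(n)
  n_div <- round(config$diversion_fraction * n)
  if (config$diversion_fraction > 0 && n_div < 1L) {
    stop("diversion_fraction > 0 but rounds to zero genes; increase n_genes")
  }
  diversion <- sort(sample(genes, n_div))
  k <- config$n_latent_factors

  base_load <- matrix(rnorm(n * k), n, k, dimnames = list(genes, NULL))
  loadings <- list(development = base_load)
  for (stage in c("progression", "cancer")) {
    l <- base_load
    l[diversion, ] <- matrix(rnorm(n_div * k), n_div, k)
    loadings[[stage]] <- l
  }

  blocks <- list()
  types <- character(0)
  for (stage in MACRO_STAGES) {
    ns <- config$n_samples_per_stage[[stage]]
    blocks[[stage]] <- factor_block(loadings[[stage]], ns, config$noise_sd)
    types <- c(types, if (stage == "development") {
      rep_len(DEV_TYPES, ns)
    } else if (stage == "progression") {
      rep("Adenoma", ns)
    } else {
      rep("Adenocarcinoma", ns)
    })
  }
  values <- do.call(cbind, blocks)
  samples <- sprintf("s%04d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  names(types) <- samples
  list(
    expr = stage_expression_set(values, types),
    truth = list(diversion_genes = diversion)
  )
}

#' Simulate a paired miRNA layer with planted repression edges
#'
#' Each regulating miRNA represses a module of \code{targets_per_mirna}
#' co-expressed genes from \code{target_pool} (a random seed gene plus the
#' pool genes most correlated with it); modules are disjoint across miRNAs.
#' The miRNA profile on the paired samples is \code{regulation_strength}
#' times the mean expression of its module plus noise, so every planted
#' (miRNA, gene) pair is strongly negatively correlated. Null miRNAs are pure
#' noise. The returned prediction-edge table lists every planted edge under
#' two sources and adds decoy edges with double and single source support;
#' decoys pair a null miRNA with a random gene, so they carry prediction
#' support but no expression coupling. Paired samples are taken from the
#' cancer stage first, then progression, then development (mirroring paired
#' profiling of carcinoma biopsies).
#'
#' @param config a [sim_config()].
#' @param expr a [stage_expression_set()] from [simulate_stage_expression()].
#' @param target_pool genes eligible as planted targets (default: all genes).
#' @return list with \code{mirna} (matrix miRNAs x paired samples),
#'   \code{edges} (prediction-edge data.frame as from
#'   [read_prediction_edges()]) and \code{truth} (list with
#'   \code{planted_edges}).
#' @export
simulate_mirna_layer <- function(config, expr, target_pool = expr$genes) {
  stopifnot(inherits(config, "sim_config"), inherits(expr, "stage_expression_set"))
  if (config$targets_per_mirna > length(target_pool)) {
    stop("targets_per_mirna exceeds the number of eligible target genes")
  }
  set.seed(config$seed + 1L)
  stage_order <- unlist(lapply(c("cancer", "progression", "development"),
                               function(st) expr$samples[expr$macro_stage == st]))
  if (config$n_mirna_samples > length(stage_order)) {
    stop("n_mirna_samples exceeds the number of simulated samples")
  }
  paired <- stage_order[seq_len(config$n_mirna_samples)]

  if (config$n_mirnas * config$targets_per_mirna > length(target_pool)) {
    stop("not enough eligible target genes for disjoint miRNA target modules")
  }
  mirnas <- mirna_ids(config$n_mirnas + config$n_null_mirnas)
  reg <- mirnas[seq_len(config$n_mirnas)]
  null_mirnas <- setdiff(mirnas, reg)

  # Each miRNA represses a co-expressed module: a random seed gene plus the
  # pool genes most correlated with it on the paired samples. Modules are
  # disjoint so every planted edge carries the full repression signal.
  pool_cor <- cor(t(expr$values[target_pool, paired, drop = FALSE]))
  available <- target_pool
  planted <- NULL
  for (m in reg) {
    seed_gene <- sample(available, 1L)
    others <- setdiff(available, seed_gene)
    mates <- others[order(-pool_cor[seed_gene, others])]
    tg <- c(seed_gene, mates[seq_len(config$targets_per_mirna - 1L)])
    available <- setdiff(available, tg)
    planted <- rbind(planted, data.frame(mirna_id = m, gene_id = tg))
  }

  mat <- matrix(rnorm(length(mirnas) * length(paired), sd = config$noise_sd),
                length(mirnas), length(paired),
                dimnames = list(mirnas, paired))
  for (m in reg) {
    tg <- planted$gene_id[planted$mirna_id == m]
    sig <- colMeans(expr$values[tg, paired, drop = FALSE])
    mat[m, ] <- config$regulation_strength * sig +
      rnorm(length(paired), sd = config$noise_sd)
  }

  sources <- c("miranda", "targetscan", "pictar")
  planted_rows <- do.call(rbind, lapply(seq_len(nrow(planted)), function(i) {
    data.frame(mirna_id = planted$mirna_id[i], gene_id = planted$gene_id[i],
               source = sample(sources, 2L))
  }))
  # Decoy predictions pair a null miRNA (pure noise profile, hence no
  # expression coupling to any gene) with a random gene.
  draw_decoys <- function(n_decoys, n_sources, exclude_key = character(0)) {
    if (n_decoys == 0L) return(NULL)
    out <- unique(data.frame(
      mirna_id = sample(null_mirnas, 4L * n_decoys, replace = TRUE),
      gene_id = sample(expr$genes, 4L * n_decoys, replace = TRUE)
    ))
    out <- out[!(paste(out$mirna_id, out$gene_id) %in% exclude_key), , drop = FALSE]
    out <- out[seq_len(min(n_decoys, nrow(out))), , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
      data.frame(mirna_id = out$mirna_id[i], gene_id = out$gene_id[i],
                 source = sample(sources, n_sources))
    }))
  }
  doubles <- draw_decoys(config$n_decoys_double, 2L)
  singles <- draw_decoys(config$n_decoys_single, 1L,
                         exclude_key = paste(doubles$mirna_id, doubles$gene_id))
  edges <- rbind(planted_rows, doubles, singles)
  rownames(edges) <- NULL
  attr(edges, "sources") <- sources
  list(
    mirna = mat,
    edges = edges,
    truth = list(planted_edges = planted[order(planted$mirna_id, planted$gene_id), ])
  )
}

#' Simulate a survival cohort with a planted prognostic signature
#'
#' The planted signature genes share a latent-factor block (loadings over
#' \code{n_latent_factors} factors, as in the stage model); all other genes
#' are independent noise with matched marginal variance, so panels of
#' non-signature genes carry no survival information. The linear risk score
#' of each patient is \code{log_hazard_coef} times the unit-scaled first
#' principal component of the signature submatrix.
#' Event times are exponential with rate \code{baseline_hazard * exp(risk)};
#' censoring is an independent exponential time calibrated so that roughly
#' \code{censor_rate} of patients are censored under the null. DFS times are
#' the OS times scaled by Uniform(0.5, 1) with the same event flags.
#'
#' @param config a [sim_config()].
#' @return list with \code{dataset} (a [survival_dataset()]) and \code{truth}
#'   (list with \code{prognostic_genes}).
#' @export
simulate_survival_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_genes
  genes <- gene_ids(n)
  sig_genes <- config$signature_genes
  if (is.null(sig_genes)) sig_genes <- genes[seq_len(config$n_signature_genes)]
  if (length(sig_genes) == 0L && config$log_hazard_coef != 0) {
    stop("signature_genes empty but log_hazard_coef is non-zero")
  }
  if (!all(sig_genes %in% genes)) stop("signature_genes outside simulated genes")

  k <- config$n_latent_factors
  marginal_sd <- sqrt(k + config$noise_sd^2)
  values <- matrix(rnorm(n * config$survival_n, sd = marginal_sd),
                   n, config$survival_n, dimnames = list(genes, NULL))
  if (length(sig_genes) > 0L) {
    loadings <- matrix(rnorm(length(sig_genes) * k), length(sig_genes), k,
                       dimnames = list(sig_genes, NULL))
    values[sig_genes, ] <- factor_block(loadings, config$survival_n,
                                        config$noise_sd)
  }
  samples <- sprintf("p%04d", seq_len(config$survival_n))
  dimnames(values) <- list(genes, samples)

  if (config$log_hazard_coef != 0) {
    pc1 <- pc1_scores(values[sig_genes, , drop = FALSE])
    risk <- config$log_hazard_coef * (pc1 / sd(pc1))
  } else {
    risk <- rep(0, config$survival_n)
  }
  rate <- config$baseline_hazard * exp(risk)
  t_event <- rexp(config$survival_n, rate = rate)
  if (config$censor_rate > 0) {
    c_rate <- config$baseline_hazard * config$censor_rate / (1 - config$censor_rate)
    t_cens <- rexp(config$survival_n, rate = c_rate)
  } else {
    t_cens <- rep(Inf, config$survival_n)
  }
  os_time <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)
  dfs_time <- os_time * runif(config$survival_n, 0.5, 1)
  endpoints <- data.frame(
    sample_id = samples,
    os_time = os_time, os_event = os_event,
    dfs_time = dfs_time, dfs_event = os_event
  )
  attr(endpoints, "has_dfs") <- TRUE
  list(
    dataset = survival_dataset(values, endpoints),
    truth = list(prognostic_genes = sig_genes)
  )
}

#' Write a full simulated study to a directory
#'
#' Emits expression.tsv, annotations.tsv, mirna.tsv, one prediction-edge TSV
#' per source, survival.tsv, survival_expression.tsv and ground_truth.json.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the ground-truth list.
#' @export
write_simulation <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_stage_expression(config)
  write_expression(sim$expr, file.path(out_dir, "expression.tsv"),
                   file.path(out_dir, "annotations.tsv"))
  mir <- simulate_mirna_layer(config, sim$expr)
  mtab <- data.frame(gene_id = rownames(mir$mirna),
                     format(mir$mirna, digits = 17, trim = TRUE, scientific = FALSE),
                     check.names = FALSE)
  names(mtab) <- c("mirna_id", colnames(mir$mirna))
  utils::write.table(mtab, file.path(out_dir, "mirna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_prediction_edges(mir$edges, out_dir)
  surv <- simulate_survival_cohort(config)
  utils::write.table(surv$dataset$endpoints, file.path(out_dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stab <- data.frame(gene_id = rownames(surv$dataset$expression),
                     format(surv$dataset$expression, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE)
  names(stab) <- c("gene_id", surv$dataset$samples)
  utils::write.table(stab, file.path(out_dir, "survival_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    diversion_genes = sim$truth$diversion_genes,
    planted_edges = mir$truth$planted_edges,
    prognostic_genes = surv$truth$prognostic_genes
  )
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       dataframe = "columns", pretty = TRUE)
  invisible(truth)
}
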