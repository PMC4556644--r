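test_that("PC1 split halves the cohort deterministically", {
  set.seed(1)
  x <- matrix(rnorm(5 * 10), 5, 10,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%02d", 1:10)))
  sp <- pc1_group_split(x)
  expect_equal(as.vector(table(sp$groups)), c(5L, 5L))

  # odd n: extra sample in the low-PC1 group
  sp9 <- pc1_group_split(x[, 1:9])
  expect_equal(as.vector(table(sp9$groups)), c(5L, 4L))

  # one gene carrying all the variance: PC1 order equals that gene's order
  y <- rbind(signal = seq(1, 30, length.out = 12), flat1 = rnorm(12, sd = 1e-4),
             flat2 = rnorm(12, sd = 1e-4))
  colnames(y) <- sprintf("s%02d", 1:12)
  spy <- pc1_group_split(y)
  expect_equal(order(spy$pc1), order(y["signal", ]))

  # global sign flip leaves the partition unchanged (labels may swap with
  # the orientation, the grouping of samples may not)
  spn <- pc1_group_split(-x)
  ref <- sp$groups[colnames(x)] == sp$groups[colnames(x)][1]
  neg <- spn$groups[colnames(x)] == spn$groups[colnames(x)][1]
  expect_true(all(ref == neg))

  # sample-order invariance
  perm <- sample(10)
  spp <- pc1_group_split(x[, perm])
  expect_identical(spp$groups[colnames(x)], sp$groups[colnames(x)])

  expect_error(pc1_group_split(x[1, , drop = FALSE]), "2 panel genes")
  expect_error(pc1_group_split(matrix(1, 3, 5,
    dimnames = list(letters[1:3], letters[4:8]))), "zero total variance")
})

test_that("log-rank agrees with the hand-rolled oracle and is symmetric", {
  # 6-subject worked set: times 1..6, all events, alternating groups
  time <- 1:6
  event <- rep(1, 6)
  grp <- factor(rep(c("A", "B"), 3))
  km <- km_logrank(data.frame(time = time, event = event), grp)
  expect_equal(km$chisq, oracle_logrank_chisq(time, event, grp), tolerance = 1e-12)
  expect_equal(km$p, pchisq(km$chisq, 1, lower.tail = FALSE), tolerance = 1e-12)

  # label swap changes nothing
  grp2 <- factor(rep(c("B", "A"), 3))
  km2 <- km_logrank(data.frame(time = time, event = event), grp2)
  expect_equal(km2$chisq, km$chisq, tolerance = 1e-12)

  # identical endpoint data duplicated across groups -> chi-square 0
  dup <- data.frame(time = c(time, time), event = c(event, event))
  gdup <- factor(rep(c("A", "B"), each = 6))
  kmd <- km_logrank(dup, gdup)
  expect_equal(kmd$chisq, 0, tolerance = 1e-9)
  expect_equal(kmd$p, 1, tolerance = 1e-6)

  # no events at all -> defined degenerate result
  none <- data.frame(time = 1:6, event = rep(0, 6))
  km0 <- km_logrank(none, grp)
  expect_equal(km0$chisq, 0)
  expect_equal(km0$p, 1)

  # richer case with censoring against the oracle
  set.seed(2)
  t2 <- round(rexp(40, 1 / 20), 3)
  e2 <- rbinom(40, 1, 0.7)
  g2 <- factor(sample(c("A", "B"), 40, replace = TRUE))
  km3 <- km_logrank(data.frame(time = t2, event = e2), g2)
  expect_equal(km3$chisq, oracle_logrank_chisq(t2, e2, g2), tolerance = 1e-9)
})

test_that("KM estimate reduces to the empirical survival function without censoring", {
  time <- c(2, 5, 5, 9, 12, 14)
  event <- rep(1, 6)
  grp <- factor(rep(c("A", "B"), each = 3))
  km <- km_logrank(data.frame(time = time, event = event), grp)
  a <- km$curves[km$curves$group == "A", ]
  # group A has events at 2 and a double event at 5: S = 2/3 then 0
  expect_equal(a$survival, c(2 / 3, 0), tolerance = 1e-12)
  expect_equal(a$events, c(1, 2))
})

test_that("stepwise Cox screens covariates at the entry threshold", {
  set.seed(3)
  n <- 200
  risk <- rbinom(n, 1, 0.5)
  time <- rexp(n, rate = (1 / 40) * exp(log(2.5) * risk))
  cens <- rexp(n, 1 / 120)
  endpoints <- data.frame(time = pmin(time, cens),
                          event = as.integer(time <= cens))
  covs <- data.frame(risk = risk, noise = rnorm(n))
  res <- cox_stepwise(endpoints, covs, entry_p = 0.05)
  expect_true("risk" %in% res$entered)
  expect_false("noise" %in% res$entered)
  expect_false(any(res$multivariate$term == "noise"))
  uni_risk <- res$univariate[res$univariate$covariate == "risk", ]
  expect_true(uni_risk$ci_low <= uni_risk$hr && uni_risk$hr <= uni_risk$ci_high)
  expect_gt(uni_risk$hr, 1)

  covs_bad <- data.frame(a = risk, b = risk)
  expect_error(cox_stepwise(endpoints, covs_bad), "collinear")
  expect_error(cox_stepwise(endpoints, data.frame(a = c(NA, rep(1, n - 1)))),
               "missing")
})

test_that("evaluate_panel applies the split per dataset and endpoint", {
  cfg <- sim_config(n_genes = 40, survival_n = 60, seed = 13)
  co <- simulate_survival_cohort(cfg)
  panel <- co$truth$prognostic_genes
  two <- list(a = co$dataset, b = co$dataset)
  res <- evaluate_panel(panel, two, endpoints = c("os", "dfs"))
  expect_equal(nrow(res), 4L)
  expect_equal(res$p[res$dataset == "a"], res$p[res$dataset == "b"])
  expect_true(all(res$n_genes == length(panel)))

  # absent genes dropped with a warning; below 2 genes the dataset is skipped
  expect_warning(
    res2 <- evaluate_panel(c(panel[1:3], "absent1"), two["a"], "os"),
    "absent"
  )
  expect_equal(res2$n_genes, 3L)
  suppressWarnings(
    res3 <- evaluate_panel(c(panel[1], "absent1", "absent2"), two["a"], "os")
  )
  expect_equal(nrow(res3), 0L)
  expect_identical(attr(res3, "skipped"), "a")
})

test_that("random panel null is seeded, bounded and empty-safe", {
  cfg <- sim_config(n_genes = 60, survival_n = 60, seed = 17)
  co <- simulate_survival_cohort(cfg)
  ds <- list(a = co$dataset)
  pool <- rownames(co$dataset$expression)

  r0 <- random_panel_null(pool, 5, 0, ds, seed = 1)
  expect_equal(r0$n_significant_all, 0L)

  r1 <- random_panel_null(pool, 5, 25, ds, seed = 2)
  r2 <- random_panel_null(pool, 5, 25, ds, seed = 2)
  expect_identical(r1$p_values, r2$p_values)
  expect_true(r1$n_significant_all >= 0 && r1$n_significant_all <= 25)
  expect_error(random_panel_null(pool[1:3], 5, 10, ds), "pool smaller")
})

test_that("log-rank chi-square responds monotonically to the planted hazard", {
  coefs <- c(0, log(1.5), log(3))
  med_chi <- numeric(length(coefs))
  for (k in seq_along(coefs)) {
    chis <- numeric(15)
    for (s in 1:15) {
      co <- simulate_survival_cohort(
        sim_config(n_genes = 30, survival_n = 120,
                   log_hazard_coef = coefs[k], seed = 400 + s)
      )
      sp <- pc1_group_split(co$dataset$expression[co$truth$prognostic_genes, ])
      km <- km_logrank(data.frame(time = co$dataset$endpoints$os_time,
                                  event = co$dataset$endpoints$os_event),
                       sp$groups)
      chis[s] <- km$chisq
    }
    med_chi[k] <- median(chis)
  }
  expect_true(all(diff(med_chi) >= 0))
})
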