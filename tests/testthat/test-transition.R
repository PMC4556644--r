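test_that("stage correlations: exact linear relations and the bias adjustment", {
  # construct two genes with exactly r = 0.5 via Gram-Schmidt
  n <- 20
  set.seed(1)
  x <- scale(rnorm(n))[, 1]
  z <- rnorm(n)
  z <- scale(z - x * sum(x * z) / sum(x * x))[, 1]
  y <- 0.5 * x + sqrt(0.75) * z
  vals <- rbind(a = x, b = y, c = 2 * x + 1, d = -x)
  expr <- make_expr_set(vals, n, 0, 0)

  raw <- stage_correlation_matrix(expr, "development", "none")
  expect_equal(raw$matrix["a", "b"], 0.5, tolerance = 1e-12)
  expect_equal(raw$matrix["a", "c"], 1, tolerance = 1e-12)
  expect_equal(raw$matrix["a", "d"], -1, tolerance = 1e-12)

  adj <- stage_correlation_matrix(expr, "development", "small_sample_bias")
  # closed form: 0.5 * (1 + 0.75 / (2 * 17))
  expect_equal(adj$matrix["a", "b"], 0.5 * (1 + 0.75 / 34), tolerance = 1e-12)
  expect_equal(adj$matrix["a", "b"], 0.5110294, tolerance = 1e-7)
  # |r| = 1 is a fixed point of the adjustment
  expect_equal(adj$matrix["a", "c"], 1, tolerance = 1e-12)
  expect_equal(adj$matrix["a", "d"], -1, tolerance = 1e-12)
  expect_true(all(diag(adj$matrix) == 1))
  expect_identical(adj$matrix, t(adj$matrix))
})

test_that("stage correlation guards sample counts and zero-variance genes", {
  vals <- matrix(rnorm(4 * 3), 4, 3, dimnames = list(sprintf("g%d", 1:4), NULL))
  expr <- make_expr_set(vals, 3, 0, 0)
  expect_error(stage_correlation_matrix(expr, "development"), "need >= 4")

  vals <- matrix(rnorm(4 * 10), 4, 10, dimnames = list(sprintf("g%d", 1:4), NULL))
  vals[2, ] <- 7
  expr <- make_expr_set(vals, 10, 0, 0)
  cs <- stage_correlation_matrix(expr, "development")
  expect_identical(cs$flagged, "g2")
  expect_true(all(cs$matrix["g2", -2] == 0))
})

test_that("transition statistic: identity, reversal and a hand-ranked case", {
  m <- rand_corr_mat(5, seed = 2)
  a <- make_corr_stage(m)
  b <- make_corr_stage(m, "progression")
  for (g in rownames(m)) {
    expect_equal(spearman_transition(a, b, g), 1.0, tolerance = 1e-12)
  }

  # order-reversing transform of the off-diagonal vector -> -1
  rev_m <- m
  rev_m[1, -1] <- -m[1, -1]
  rev_m[-1, 1] <- -m[-1, 1]
  b_rev <- make_corr_stage(rev_m, "progression")
  expect_equal(spearman_transition(a, b_rev, rownames(m)[1]), -1.0,
               tolerance = 1e-12)

  # vectors with ranks (1,2,3,4) vs (1,3,2,4): rho = 0.8
  ma <- diag(5)
  ma[1, 2:5] <- ma[2:5, 1] <- c(-0.6, -0.2, 0.2, 0.6)
  mb <- diag(5)
  mb[1, 2:5] <- mb[2:5, 1] <- c(-0.6, 0.2, -0.2, 0.6)
  dimnames(ma) <- dimnames(mb) <- list(sprintf("g%02d", 1:5), sprintf("g%02d", 1:5))
  expect_equal(
    spearman_transition(make_corr_stage(ma), make_corr_stage(mb, "progression"), "g01"),
    0.8, tolerance = 1e-12
  )
  expect_error(spearman_transition(a, b, "nope"), "not found")
})

test_that("transition statistic is invariant under common gene-universe permutations", {
  set.seed(3)
  p <- 8
  ma <- rand_corr_mat(p)
  mb <- rand_corr_mat(p)
  ref <- spearman_transition(make_corr_stage(ma), make_corr_stage(mb, "cancer"), "g03")
  for (i in 1:100) {
    perm <- sample(p)
    pa <- ma[perm, perm]
    pb <- mb[perm, perm]
    got <- spearman_transition(make_corr_stage(pa), make_corr_stage(pb, "cancer"), "g03")
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("transition coordinates obey the distance formula and inclusive boundary", {
  cfg <- sim_config(n_genes = 30, seed = 6)
  sim <- simulate_stage_expression(cfg)
  fit <- transition_model(sim$expr)
  tab <- fit$table
  expect_equal(tab$tsp_distance,
               sqrt((1 - tab$st_dp)^2 + (1 - tab$st_pc)^2), tolerance = 1e-15)
  expect_true(all(tab$tsp_distance >= 0 & tab$tsp_distance <= 2 * sqrt(2)))

  # a gene exactly on the arc is obedient (boundary inclusive)
  mid <- tab$gene_id[which.min(abs(tab$tsp_distance - median(tab$tsp_distance)))]
  r_star <- tab$tsp_distance[tab$gene_id == mid]
  on_arc <- transition_coordinates(fit$stages$development, fit$stages$progression,
                                   fit$stages$cancer, radius = r_star)
  expect_identical(on_arc$label[on_arc$gene_id == mid], "obedient")

  # identical stages put every gene at the stable point
  same <- transition_coordinates(fit$stages$development, fit$stages$development,
                                 fit$stages$development, radius = 1)
  expect_true(all(same$tsp_distance < 1e-12))
  expect_true(all(same$label == "obedient"))
})

test_that("median transition degrades monotonically with the diversion fraction", {
  fracs <- c(0, 0.25, 0.5, 0.9)
  med_dp <- numeric(length(fracs))
  for (k in seq_along(fracs)) {
    pooled <- c()
    for (s in 1:2) {
      cfg <- sim_config(n_genes = 60, diversion_fraction = fracs[k],
                        n_samples_per_stage = c(development = 30,
                                                progression = 30, cancer = 30),
                        seed = s)
      sim <- simulate_stage_expression(cfg)
      fit <- transition_model(sim$expr)
      pooled <- c(pooled, fit$table$st_dp)
    }
    med_dp[k] <- median(pooled)
  }
  expect_true(all(diff(med_dp) <= 0))
})

test_that("correlation density summary finds the expected modes", {
  flat <- matrix(0.8, 6, 6)
  diag(flat) <- 1
  dimnames(flat) <- list(sprintf("g%d", 1:6), sprintf("g%d", 1:6))
  one <- correlation_density_summary(make_corr_stage(flat), bandwidth = 0.05)
  expect_equal(one$n_modes, 1L)
  expect_equal(one$grid$correlation[which.max(one$grid$density)], 0.8,
               tolerance = 0.02)

  set.seed(7)
  mix <- diag(8)
  mix[upper.tri(mix)] <- rep(c(-0.7, 0.7), length.out = sum(upper.tri(mix))) +
    runif(sum(upper.tri(mix)), -0.02, 0.02)
  mix[lower.tri(mix)] <- t(mix)[lower.tri(mix)]
  dimnames(mix) <- list(sprintf("g%d", 1:8), sprintf("g%d", 1:8))
  two <- correlation_density_summary(make_corr_stage(mix), bandwidth = 0.05)
  expect_equal(two$n_modes, 2L)

  set.seed(8)
  noise <- matrix(rnorm(30 * 300), 30, 300,
                  dimnames = list(sprintf("g%02d", 1:30), NULL))
  expr <- make_expr_set(noise, 300, 0, 0)
  cs <- stage_correlation_matrix(expr, "development", "none")
  pure <- correlation_density_summary(cs, bandwidth = 0.05)
  expect_equal(pure$n_modes, 1L)
  expect_lt(abs(pure$grid$correlation[which.max(pure$grid$density)]), 0.1)
})
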