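test_that("bivariate pair draws honour the requested correlations", {
  set.seed(1)
  # degenerate r = 1: the two rows coincide
  m <- simulate_gene_pair(1, 0.2, 50, 10)
  expect_lt(max(abs(m[1, 1:50] - m[2, 1:50])), 1e-12)
  expect_error(simulate_gene_pair(1.2, 0, 5, 5), "\\[-1, 1\\]")
  # empirical correlation within 3 Fisher-z standard errors
  for (r in c(0, 0.8)) {
    m <- simulate_gene_pair(r, 0, 10000, 2)
    z_obs <- atanh(cor(m[1, 1:10000], m[2, 1:10000]))
    se <- 1 / sqrt(10000 - 3)
    expect_lt(abs(z_obs - atanh(r)), 3 * se)
  }
})

test_that("truth tables follow the class composition and correlation bounds", {
  cfg <- sim_config(n_pairs = 1000L, n_case = 10L, n_control = 10L)
  truth <- simulate_truth(cfg, 9L)
  expect_identical(as.vector(table(truth$class)[c("NDG", "GCDG", "LCDG")]),
                   c(950L, 25L, 25L))
  ndg <- truth[truth$class == "NDG", ]
  expect_equal(ndg$r1, ndg$r2)
  expect_true(all(abs(truth$r1) <= 1 & abs(truth$r2) <= 1))
  g <- truth[truth$class == "GCDG", ]
  expect_equal(g$r2, g$r1 - g$delta)
  # the 0.8-shift block draws r1 from [-0.2, 1]
  g8 <- g[g$delta == 0.8, ]
  expect_true(all(g8$r1 >= -0.2 & g8$r1 <= 1))
  l <- truth[truth$class == "LCDG", ]
  expect_equal(l$r2, l$r1 + l$delta)
  # default composition scales to the canonical 95,000 / 2,500 / 2,500 split
  cfg_full <- sim_config()
  expect_identical(cfg_full$n_pairs, 100000L)
  expect_identical(cfg_full$per_block * 2L * length(cfg_full$deltas), 5000L)
})

test_that("simulated expression matches its truth correlations and layout", {
  cfg <- sim_config(n_pairs = 200L, n_case = 80L, n_control = 60L)
  truth <- simulate_truth(cfg, 21L)
  dat <- simulate_expression(truth, cfg, 22L)
  expect_identical(dim(dat$expr), c(400L, 140L))
  expect_identical(nrow(dat$bg), 200L)
  expect_identical(sum(dat$labels$group == "case"), 80L)
  # per-pair empirical correlations track r1 in cases / r2 in controls
  ca <- dat$labels$sample[dat$labels$group == "case"]
  co <- dat$labels$sample[dat$labels$group == "control"]
  err1 <- err2 <- numeric(50)
  for (i in 1:50) {
    a <- dat$expr[dat$bg$gene_a[i], ]
    b <- dat$expr[dat$bg$gene_b[i], ]
    err1[i] <- atanh(cor(a[ca], b[ca])) - atanh(min(truth$r1[i], 0.999))
    err2[i] <- atanh(cor(a[co], b[co])) - atanh(min(truth$r2[i], 0.999))
  }
  # average z-error should be near zero (individual pairs are noisy)
  expect_lt(abs(mean(err1)), 3 / sqrt(50 * (80 - 3)))
  expect_lt(abs(mean(err2)), 3 / sqrt(50 * (60 - 3)))
})

test_that("generated pathways respect the dysregulation design", {
  cfg <- sim_config(n_pairs = 2000L, n_case = 10L, n_control = 10L,
                    prop_ndg = 0.75, pathway_sizes = c(20L),
                    n_pathways_per_size = 200L, n_dys_per_size = 20L,
                    p_dysgp = 0.5)
  truth <- simulate_truth(cfg, 31L)
  pw <- generate_pathways(cfg, truth, 32L)
  expect_length(pw$pathways, 200L)
  expect_identical(sum(pw$truth$dysregulated), 20L)
  expect_identical(as.vector(table(pw$truth$true_direction[pw$truth$dysregulated])),
                   c(10L, 10L))
  cls <- truth$class
  names(cls) <- truth$pair
  for (k in seq_len(nrow(pw$truth))) {
    p <- pw$pathways[[pw$truth$pathway_id[k]]]
    expect_identical(nrow(p$pairs), 20L)
    ids <- as.integer(sub("^g0*(\\d+)\\.a$", "\\1", p$pairs$gene_a))
    if (pw$truth$dysregulated[k]) {
      # exactly round(p_dysgp * size) pairs from the matching pool
      expect_identical(sum(cls[as.character(ids)] != "NDG"), 10L)
      want <- if (pw$truth$true_direction[k] == "gain") "GCDG" else "LCDG"
      expect_true(all(cls[as.character(ids)] %in% c("NDG", want)))
      dys_deltas <- truth$delta[match(ids, truth$pair)]
      dys_deltas <- dys_deltas[dys_deltas > 0]
      if (pw$truth$strength[k] == "strong") {
        expect_true(all(dys_deltas >= 0.7))
      } else {
        expect_true(all(dys_deltas <= 0.5))
      }
    } else {
      expect_true(all(cls[as.character(ids)] == "NDG"))
    }
  }
  # full default design: 1,000 pathways, 100 dysregulated
  cfg_full <- sim_config(n_pairs = 20000L, n_case = 10L, n_control = 10L)
  truth_full <- simulate_truth(cfg_full, 33L)
  pw_full <- generate_pathways(cfg_full, truth_full, 34L)
  expect_length(pw_full$pathways, 1000L)
  expect_identical(sum(pw_full$truth$dysregulated), 100L)
})

test_that("roc_auc matches the concordance oracle and handles ties", {
  expect_equal(roc_auc(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
  set.seed(44)
  score <- sample(c(rnorm(16), rep(0.3, 4)))
  truth <- runif(20) < 0.4
  if (sum(truth) %in% c(0, 20)) truth[1:2] <- c(TRUE, FALSE)
  expect_equal(roc_auc(score, truth), auc_concordance_oracle(score, truth),
               tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(score), truth), roc_auc(score, truth))
  # randomized labels give chance-level AUC within 3 Hanley-McNeil SEs
  set.seed(45)
  aucs <- replicate(40, {
    sc <- rnorm(100)
    roc_auc(sc, sample(rep(c(TRUE, FALSE), 50)))
  })
  se <- sd(aucs) / sqrt(40)
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.01)
})

test_that("the ranking statistic orders by p-value then |DysPS| with shared ties", {
  p <- c(0.01, 0.5, 0.01, 0.5, 0.2)
  d <- c(0.9, 0.1, 0.3, 0.1, -0.5)
  r <- pathway_ranking_score(p, d)
  expect_identical(order(-r), order(p, -abs(d)))
  expect_identical(r[2], r[4])  # identical (p, |d|) share a rank group
  expect_false(r[1] == r[3])
})

test_that("a scaled simulation study recovers dysregulated pathways", {
  cfg <- sim_config(n_pairs = 1000L, n_case = 40L, n_control = 40L,
                    prop_ndg = 0.6, pathway_sizes = c(20L, 40L),
                    n_pathways_per_size = 20L, n_dys_per_size = 4L,
                    p_dysgp = 0.5)
  study <- suppressMessages(
    run_simulation_study(p_dysgp = 0.5, cfg = cfg, n_perm = 200L, seed = 3L))
  expect_identical(study$size, c("all", "20", "40"))
  expect_identical(study$n_pathways, c(40L, 20L, 20L))
  expect_true(all(study$auc >= 0 & study$auc <= 1))
  expect_gt(study$auc[study$size == "all"], 0.8)
  det <- attr(study, "details")[["0.5"]]
  expect_identical(nrow(det), 40L)
})
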