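ranked_fixture <- function(n = 50, seed = 2) {
  set.seed(seed)
  pairs <- all_pairs_of(sprintf("G%02d", 1:50))[seq_len(n), ]
  pairs$score <- rnorm(n)
  rank_pairs(pairs)
}

test_that("rank_pairs sorts descending with deterministic canonical tie-break", {
  sc <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("X", "Y", "C"),
                   score = c(1, 3, -2))
  r <- rank_pairs(sc)
  expect_identical(r$gene_b, c("Y", "X", "C"))
  # exact ties fall back to pair-name order
  sc$score <- c(1, 1, 1)
  r2 <- rank_pairs(sc)
  expect_identical(paste(r2$gene_a, r2$gene_b), c("A X", "A Y", "B C"))
  sc$score[2] <- NaN
  expect_error(rank_pairs(sc), "A\\|Y")
  # large random instance equals an independent sort
  big <- ranked_fixture(n = 1000, seed = 42)
  expect_false(is.unsorted(rev(big$score)))
})

test_that("enrichment_score hits the extreme values for single-pair pathways", {
  r <- ranked_fixture(n = 100)
  expect_equal(enrichment_score(r, positions = 1), 1.0)
  expect_equal(enrichment_score(r, positions = 100), -1.0)
})

test_that("reference and fast DysPS agree with a brute-force running sum", {
  r <- ranked_fixture(n = 50)
  set.seed(9)
  for (m in c(1, 5, 12)) {
    pos <- sort(sample(50, m))
    brute <- brute_running_sum_es(r$score, pos, p_exp = 1)
    expect_equal(enrichment_score(r, pos), brute, tolerance = 1e-12)
    expect_equal(unname(all_enrichment_scores(r, list(p = pos))[1]), brute,
                 tolerance = 1e-12)
  }
})

test_that("fast multi-pathway scorer equals the naive scorer on random instances", {
  set.seed(31)
  worst <- 0
  for (trial in 1:200) {
    n <- sample(20:120, 1)
    r <- ranked_fixture(n = n, seed = trial)
    p_exp <- sample(c(0, 1, 1, 2), 1)
    idx <- lapply(1:3, function(i) sort(sample(n, sample(1:(n - 1), 1))))
    names(idx) <- paste0("p", 1:3)
    fast <- all_enrichment_scores(r, idx, p_exp)
    naive <- vapply(idx, function(pos) enrichment_score(r, pos, p_exp),
                    numeric(1))
    worst <- max(worst, max(abs(fast - naive)))
  }
  expect_lt(worst, 1e-12)
})

test_that("with p_exp = 0 the score magnitude is the classic KS statistic", {
  set.seed(12)
  for (trial in 1:20) {
    n <- sample(30:80, 1)
    r <- ranked_fixture(n = n, seed = 100 + trial)
    pos <- sort(sample(n, sample(3:(n - 3), 1)))
    es <- enrichment_score(r, pos, p_exp = 0)
    ks <- suppressWarnings(
      ks.test(pos, setdiff(seq_len(n), pos))$statistic)
    expect_equal(abs(es), unname(ks), tolerance = 1e-12)
    expect_lte(abs(es), 1)
  }
})

test_that("|DysPS| never exceeds 1 for weight exponents 0 and 1", {
  set.seed(77)
  for (trial in 1:50) {
    n <- sample(10:60, 1)
    r <- ranked_fixture(n = n, seed = 300 + trial)
    pos <- sort(sample(n, sample(1:(n - 1), 1)))
    expect_lte(abs(enrichment_score(r, pos, 1)), 1)
    expect_lte(abs(enrichment_score(r, pos, 0)), 1)
  }
})

test_that("nominal p-values follow the signed-portion counting rule", {
  expect_equal(nominal_pvalue(0.9, c(0.1, 0.2, 0.3)), 0.25)
  # boundary: equal to the largest null value counts as >=
  expect_equal(nominal_pvalue(0.3, c(0.1, 0.2, 0.3)), 2 / 4)
  # negative observed uses the negative portion
  expect_equal(nominal_pvalue(-0.25, c(-0.1, -0.3, 0.2, 0.5)), 2 / 3)
  # degenerate portion: warn and return 1
  expect_warning(p <- nominal_pvalue(-0.5, c(0.1, 0.2)), "p = 1")
  expect_equal(p, 1)
  # monotone non-increasing in |observed| for a fixed null
  null <- rnorm(200)
  obs <- seq(0, 2, by = 0.1)
  ps <- vapply(obs, nominal_pvalue, numeric(1), null_values = null)
  expect_true(all(diff(ps) <= 0))
})

test_that("bh_fdr reproduces the step-up oracle and p.adjust edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.73), 0.73)
  set.seed(15)
  p <- runif(100)^2
  expect_equal(bh_fdr(p), bh_stepup_oracle(p), tolerance = 1e-12)
  o <- order(p)
  expect_true(all(diff(bh_fdr(p)[o]) >= -1e-12))
})

test_that("direction calls combine FDR significance and DysPS sign", {
  expect_identical(classify_direction(0.7, 0.01), "gain")
  expect_identical(classify_direction(-0.7, 0.01), "loss")
  expect_identical(classify_direction(0.7, 0.06), "not_significant")
  expect_identical(classify_direction(c(0.5, -0.5, 0.5), c(0.01, 0.04, 0.8)),
                   c("gain", "loss", "not_significant"))
})

test_that("the pipeline is deterministic and antisymmetric under label swap", {
  cfg <- sim_config(n_pairs = 400L, n_case = 12L, n_control = 12L,
                    prop_ndg = 0.8, pathway_sizes = c(10L, 20L),
                    n_pathways_per_size = 10L, n_dys_per_size = 4L,
                    p_dysgp = 0.5)
  dat <- generate_pair_background(cfg, 5L)
  pw <- generate_pathways(cfg, dat$truth, 6L)
  res1 <- suppressMessages(run_dyspia(dat$expr, dat$labels, pw$pathways,
                                      bg = dat$bg, n_perm = 50L, seed = 11L))
  res2 <- suppressMessages(run_dyspia(dat$expr, dat$labels, pw$pathways,
                                      bg = dat$bg, n_perm = 50L, seed = 11L))
  expect_identical(res1, res2)
  # label swap: every DysPS flips sign, |DysPS| and size are preserved
  lab_sw <- phenotype_labels(dat$labels$sample,
                             ifelse(dat$labels$group == "case",
                                    "control", "case"))
  res_sw <- suppressMessages(run_dyspia(dat$expr, lab_sw, pw$pathways,
                                        bg = dat$bg, n_perm = 50L, seed = 11L))
  m <- match(res1$pathway_id, res_sw$pathway_id)
  expect_equal(res_sw$dysps[m], -res1$dysps, tolerance = 1e-9)
})

test_that("tiny samples fall back to exhaustive permutation enumeration", {
  # 2+2 samples admit exactly choose(4, 2) = 6 label assignments
  perms <- suppressWarnings(
    dyspathway:::make_permutations(4L, 2L, n_perm = 1000L, seed = 1L))
  expect_identical(dim(perms), c(4L, 6L))
  expect_identical(anyDuplicated(asplit(perms, 2)), 0L)
  expect_true(all(colSums(perms) == 2L))
  # (with only 2 samples per group the CILP products are constant within
  # each group and the Welch score does not exist, so the smallest group
  # size the pipeline itself can enumerate exhaustively is 3+3)
  toy <- make_toy_data(n_genes = 10, n_case = 3, n_control = 3, seed = 33)
  bg <- all_pairs_of(rownames(toy$expr))
  pwl <- list(pathway_pair_set("pw1", "pw1", bg$gene_a[1:8], bg$gene_b[1:8]))
  suppressWarnings({
    bg_r <- suppressMessages(restrict_to_expression(bg, toy$expr, toy$labels))
    idx <- dyspathway:::pathway_pair_index(pwl, bg_r, min_size = 1L)
    null <- permutation_null(toy$expr, toy$labels, bg_r, idx,
                             n_perm = 1000L, seed = 2L)
  })
  expect_identical(nrow(null), as.integer(choose(6, 3)))
  # p-values live on the exhaustive grid k / (1 + #same-sign nulls)
  obs <- 0.5
  p <- nominal_pvalue(obs, null[, 1])
  pos <- sum(null[, 1] >= 0)
  expect_true(p %in% (seq_len(pos + 1) / (pos + 1)))
})

test_that("a planted strongly dysregulated pathway ranks first among nulls", {
  cfg <- sim_config(n_pairs = 2000L, n_case = 30L, n_control = 30L,
                    prop_ndg = 0.9)
  dat <- generate_pair_background(cfg, 71L)
  # 99 null pathways + 1 pathway made of strongly dysregulated pairs
  strong <- dat$truth$pair[dat$truth$class == "GCDG" &
                           dat$truth$delta >= 0.7]
  ndg <- dat$truth$pair[dat$truth$class == "NDG"]
  set.seed(72)
  pwl <- list()
  gp <- dyspathway:::sim_pair_genes(sample(strong, 15))
  pwl[["planted"]] <- pathway_pair_set("planted", "planted", gp$a, gp$b)
  for (i in 1:99) {
    gp <- dyspathway:::sim_pair_genes(sample(ndg, 15))
    pwl[[paste0("null", i)]] <- pathway_pair_set(paste0("null", i),
                                                 "null", gp$a, gp$b)
  }
  res <- suppressMessages(run_dyspia(dat$expr, dat$labels, pwl, bg = dat$bg,
                                     n_perm = 200L, seed = 73L))
  expect_identical(res$pathway_id[1], "planted")
  expect_gt(res$dysps[res$pathway_id == "planted"], 0)
})
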