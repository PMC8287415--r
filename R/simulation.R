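#' Configuration for the synthetic gene-pair benchmark
#'
#' The benchmark draws every gene pair from a bivariate normal distribution
#' with unit variances and a condition-specific correlation: non-dysregulated
#' pairs (NDG) share one correlation `r1 = r2 ~ U[-1, 1]`; gain-of-correlation
#' pairs (GCDG) have `r1 ~ U[delta - 1, 1]`, `r2 = r1 - delta`; loss pairs
#' (LCDG) mirror them (`r1 ~ U[-1, 1 - delta]`, `r2 = r1 + delta`), for
#' correlation shifts `delta` of 0.4-0.8 in equal blocks.  Cases carry the
#' `r1` correlation, controls `r2`.  Defaults reproduce the 100,000-pair
#' design: 95% NDG, 2.5% GCDG and 2.5% LCDG split over the five shifts,
#' 100 case and 100 control samples, and 1,000 pathways (200 per size in
#' 20/40/60/80/100, of which 20 per size are dysregulated).
#'
#' @param n_pairs Total background pairs.
#' @param n_case,n_control Samples per condition.
#' @param prop_ndg Fraction of non-dysregulated pairs.
#' @param deltas Correlation shifts for dysregulated pairs.
#' @param pathway_sizes Pathway sizes (pairs per pathway).
#' @param n_pathways_per_size Pathways generated per size.
#' @param n_dys_per_size Dysregulated pathways per size (half gain, half
#'   loss; within each direction half strong - drawing from the two largest
#'   shifts - and half weak - the two smallest).
#' @param p_dysgp Fraction of a dysregulated pathway's pairs drawn from its
#'   dysregulated pool (the rest are NDG pairs).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 100000L, n_case = 100L, n_control = 100L,
                       prop_ndg = 0.95, deltas = seq(0.4, 0.8, by = 0.1),
                       pathway_sizes = c(20L, 40L, 60L, 80L, 100L),
                       n_pathways_per_size = 200L, n_dys_per_size = 20L,
                       p_dysgp = 0.2) {
  n_dys_total <- n_pairs * (1 - prop_ndg)
  per_block <- n_dys_total / 2 / length(deltas)
  if (abs(per_block - round(per_block)) > 1e-9)
    stop("(1 - prop_ndg) * n_pairs must split evenly over 2 directions x ",
         length(deltas), " shifts")
  if (p_dysgp <= 0 || p_dysgp > 1) stop("p_dysgp must be in (0, 1]")
  if (n_case < 2L || n_control < 2L) stop("need >= 2 samples per condition")
  if (n_dys_per_size %% 4L != 0L)
    stop("n_dys_per_size must be divisible by 4 (gain/loss x strong/weak)")
  if (length(deltas) < 2L) stop("need at least 2 correlation shifts")
  structure(list(n_pairs = as.integer(n_pairs), n_case = as.integer(n_case),
                 n_control = as.integer(n_control), prop_ndg = prop_ndg,
                 deltas = deltas, per_block = as.integer(round(per_block)),
                 pathway_sizes = as.integer(pathway_sizes),
                 n_pathways_per_size = as.integer(n_pathways_per_size),
                 n_dys_per_size = as.integer(n_dys_per_size),
                 p_dysgp = p_dysgp),
            class = "sim_config")
}

## Deterministic synthetic gene names: pair i owns genes g<i>.a and g<i>.b
## (zero-padded, so canonical and background order coincide).
sim_pair_genes <- function(i) {
  list(a = sprintf("g%07d.a", i), b = sprintf("g%07d.b", i))
}

#' Draw expression for a single gene pair
#'
#' Samples the two genes from a bivariate normal with unit variances and
#' correlation `r1` in the case condition and `r2` in the control
#' condition, via the Cholesky construction `b = r a + sqrt(1 - r^2) e`.
#'
#' @param r1,r2 Correlations in case / control condition (|r| <= 1).
#' @param n1,n2 Sample counts for case / control.
#' @return A 2 x (n1 + n2) matrix (rows: the two genes; case columns
#'   first).
#' @export
simulate_gene_pair <- function(r1, r2, n1, n2) {
  if (abs(r1) > 1 || abs(r2) > 1) stop("correlations must be in [-1, 1]")
  draw <- function(r, n) {
    a <- rnorm(n)
    b <- r * a + sqrt(1 - r^2) * rnorm(n)
    rbind(a, b)
  }
  cbind(draw(r1, n1), draw(r2, n2))
}

#' Ground-truth pair classes and correlations
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return `data.frame` with one row per pair: `pair`, `class`
#'   (`NDG`/`GCDG`/`LCDG`), `delta` (0 for NDG), `r1`, `r2`.
#' @export
simulate_truth <- function(cfg, seed) {
  with_seed(seed, {
    n_ndg <- as.integer(round(cfg$n_pairs * cfg$prop_ndg))
    blocks <- list(data.frame(class = "NDG", delta = 0,
                              r1 = runif(n_ndg, -1, 1)))
    blocks[[1L]]$r2 <- blocks[[1L]]$r1
    if (cfg$per_block > 0L) {
      for (d in cfg$deltas) {
        r1 <- runif(cfg$per_block, d - 1, 1)
        blocks[[length(blocks) + 1L]] <-
          data.frame(class = "GCDG", delta = d, r1 = r1, r2 = r1 - d)
      }
      for (d in cfg$deltas) {
        r1 <- runif(cfg$per_block, -1, 1 - d)
        blocks[[length(blocks) + 1L]] <-
          data.frame(class = "LCDG", delta = d, r1 = r1, r2 = r1 + d)
      }
    }
    truth <- do.call(rbind, blocks)
    truth <- data.frame(pair = seq_len(nrow(truth)), truth,
                        stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    truth
  })
}

#' Expression matrix, labels and background for a simulated truth table
#'
#' Each pair uses its own private two genes (pairs are independent); cases
#' are drawn with correlation `r1`, controls with `r2`.
#'
#' @param truth From [simulate_truth()].
#' @param cfg The matching [sim_config()].
#' @param seed Integer seed.
#' @return List with `expr` (genes x samples matrix), `labels`
#'   ([phenotype_labels()]), `bg` (background pair `data.frame`, row i =
#'   truth pair i).
#' @export
simulate_expression <- function(truth, cfg, seed) {
  np <- nrow(truth)
  n1 <- cfg$n_case; n2 <- cfg$n_control
  gp <- sim_pair_genes(truth$pair)
  draw_cond <- function(r, n) {
    a <- matrix(rnorm(n * np), n, np)
    b <- a * rep(r, each = n) +
      matrix(rnorm(n * np), n, np) * rep(sqrt(pmax(0, 1 - r^2)), each = n)
    list(a = a, b = b)
  }
  with_seed(seed, {
    cs <- draw_cond(truth$r1, n1)
    ct <- draw_cond(truth$r2, n2)
    expr <- matrix(NA_real_, 2L * np, n1 + n2)
    odd <- seq(1L, 2L * np, by = 2L)
    expr[odd, seq_len(n1)] <- t(cs$a)
    expr[odd + 1L, seq_len(n1)] <- t(cs$b)
    expr[odd, n1 + seq_len(n2)] <- t(ct$a)
    expr[odd + 1L, n1 + seq_len(n2)] <- t(ct$b)
    rownames(expr) <- as.vector(rbind(gp$a, gp$b))
    colnames(expr) <- c(sprintf("case_%03d", seq_len(n1)),
                        sprintf("ctrl_%03d", seq_len(n2)))
    labels <- phenotype_labels(colnames(expr),
                               rep(c("case", "control"), c(n1, n2)))
    bg <- data.frame(gene_a = gp$a, gene_b = gp$b, stringsAsFactors = FALSE)
    list(expr = expr, labels = labels, bg = bg)
  })
}

#' Generate the full simulated background
#'
#' Convenience wrapper: truth table plus expression, labels and background.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer master seed (truth and expression use derived
#'   sub-seeds).
#' @return List with `expr`, `labels`, `bg`, `truth`.
#' @export
generate_pair_background <- function(cfg, seed) {
  truth <- simulate_truth(cfg, derive_seed(seed, 11L))
  out <- simulate_expression(truth, cfg, derive_seed(seed, 12L))
  out$truth <- truth
  out
}

#' Generate simulated pathways with known dysregulation status
#'
#' Per pathway size: `n_pathways_per_size` pathways of which
#' `n_dys_per_size` are dysregulated, split equally into gain/loss
#' direction and, within direction, strong (two largest shifts) / weak
#' (two smallest) pools.  A dysregulated pathway draws
#' `round(p_dysgp * size)` pairs without replacement from its pool and the
#' rest from the NDG pool; null pathways draw all pairs from NDG.  Pairs
#' may recur across pathways but never within one.
#'
#' @param cfg A [sim_config()].
#' @param truth From [simulate_truth()].
#' @param seed Integer seed.
#' @return List with `pathways` (named list of [pathway_pair_set()]) and
#'   `truth` (`data.frame`: `pathway_id`, `size`, `dysregulated`,
#'   `true_direction`, `strength`, `n_dys_pairs`).
#' @export
generate_pathways <- function(cfg, truth, seed) {
  ndg_pool <- truth$pair[truth$class == "NDG"]
  strong <- sort(cfg$deltas, decreasing = TRUE)[1:2]
  weak <- sort(cfg$deltas)[1:2]
  pools <- list(
    gain_strong = truth$pair[truth$class == "GCDG" & truth$delta %in% strong],
    gain_weak   = truth$pair[truth$class == "GCDG" & truth$delta %in% weak],
    loss_strong = truth$pair[truth$class == "LCDG" & truth$delta %in% strong],
    loss_weak   = truth$pair[truth$class == "LCDG" & truth$delta %in% weak])
  q <- cfg$n_dys_per_size / 4L
  design <- data.frame(direction = rep(c("gain", "loss"), each = 2L * q),
                       strength = rep(rep(c("strong", "weak"), each = q), 2L),
                       stringsAsFactors = FALSE)
  with_seed(seed, {
    pathways <- list()
    rows <- list()
    for (s in cfg$pathway_sizes) {
      n_dys_pairs <- as.integer(round(cfg$p_dysgp * s))
      if (n_dys_pairs < 1L) stop("p_dysgp * size rounds to zero pairs")
      for (i in seq_len(cfg$n_pathways_per_size)) {
        id <- sprintf("pw_s%03d_%03d", s, i)
        dys <- i <= cfg$n_dys_per_size
        if (dys) {
          dirn <- design$direction[i]; strn <- design$strength[i]
          pool <- pools[[paste(dirn, strn, sep = "_")]]
          if (n_dys_pairs > length(pool))
            stop("dysregulated pool exhausted for pathway size ", s)
          members <- c(sample(pool, n_dys_pairs),
                       sample(ndg_pool, s - n_dys_pairs))
        } else {
          dirn <- "none"; strn <- "none"
          members <- sample(ndg_pool, s)
        }
        gp <- sim_pair_genes(members)
        pathways[[id]] <- pathway_pair_set(id, id, gp$a, gp$b)
        rows[[id]] <- data.frame(pathway_id = id, size = s,
                                 dysregulated = dys, true_direction = dirn,
                                 strength = strn,
                                 n_dys_pairs = if (dys) n_dys_pairs else 0L,
                                 stringsAsFactors = FALSE)
      }
    }
    list(pathways = pathways,
         truth = do.call(rbind, c(rows, list(make.row.names = FALSE))))
  })
}

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' Midrank tie handling: `AUC = (sum of positive-class ranks - n1 (n1 +
#' 1) / 2) / (n1 n0)`, with ranks of `score` in ascending order (higher
#' score = predicted positive).  Constant scores give 0.5.
#'
#' @param score Numeric ranking statistic, higher = more likely positive.
#' @param truth Logical (or 0/1) class labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(score, truth) {
  truth <- as.logical(truth)
  stopifnot(length(score) == length(truth), !anyNA(truth))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present for an AUC")
  r <- rank(score, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Ranking statistic for pathway-detection ROC
#'
#' Pathways are ranked by nominal p-value ascending with ties broken by
#' `|DysPS|` descending (the pipeline's own decision variable); pathways
#' tied on both share a rank group.  Returned as a numeric score where
#' higher means "more dysregulated", suitable for [roc_auc()].
#'
#' @param pval,dysps Aligned numeric vectors.
#' @return Numeric ranking score.
#' @export
pathway_ranking_score <- function(pval, dysps) {
  stopifnot(length(pval) == length(dysps))
  o <- order(pval, -abs(dysps), method = "radix")
  ps <- pval[o]; ds <- abs(dysps)[o]
  new_grp <- c(TRUE, ps[-1] != ps[-length(ps)] | ds[-1] != ds[-length(ds)])
  gid <- cumsum(new_grp)
  out <- numeric(length(pval))
  out[o] <- -gid
  out
}

#' Run the simulated detection benchmark
#'
#' For each dysregulated-pair proportion: generate a background and
#' pathways per the configuration, run the full pipeline, and measure how
#' well the nominal p-value (ties by `|DysPS|`) separates the dysregulated
#' from the null pathways, pooled and per pathway size.
#'
#' @param p_dysgp Vector of dysregulated-pair proportions to evaluate.
#' @param cfg Base [sim_config()]; its `p_dysgp` is overridden per setting.
#' @param n_perm Permutations per run (default 1000).
#' @param seed Integer master seed; each setting uses derived sub-seeds.
#' @return `data.frame` with columns `p_dysgp`, `size` (`"all"` pools all
#'   sizes), `auc`, `n_pathways`.  Attribute `details`: per-setting merged
#'   result + truth tables.
#' @export
run_simulation_study <- function(p_dysgp = seq(0.2, 0.6, by = 0.1),
                                 cfg = sim_config(), n_perm = 1000L,
                                 seed = 1L) {
  out <- list(); details <- list()
  for (i in seq_along(p_dysgp)) {
    cfg_i <- cfg
    cfg_i$p_dysgp <- p_dysgp[i]
    sub_seed <- derive_seed(seed, 100L + i)
    dat <- generate_pair_background(cfg_i, sub_seed)
    pw <- generate_pathways(cfg_i, dat$truth, derive_seed(sub_seed, 13L))
    res <- run_dyspia(dat$expr, dat$labels, pw$pathways, bg = dat$bg,
                      n_perm = n_perm, seed = derive_seed(sub_seed, 14L))
    merged <- merge(res, pw$truth, by = "pathway_id")
    merged$risk <- pathway_ranking_score(merged$pval, merged$dysps)
    details[[as.character(p_dysgp[i])]] <- merged
    rows <- data.frame(p_dysgp = p_dysgp[i], size = "all",
                       auc = roc_auc(merged$risk, merged$dysregulated),
                       n_pathways = nrow(merged), stringsAsFactors = FALSE)
    for (s in sort(unique(merged$size))) {
      sel <- merged$size == s
      rows <- rbind(rows, data.frame(
        p_dysgp = p_dysgp[i], size = as.character(s),
        auc = roc_auc(merged$risk[sel], merged$dysregulated[sel]),
        n_pathways = sum(sel), stringsAsFactors = FALSE))
    }
    out[[i]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "details") <- details
  res
}
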