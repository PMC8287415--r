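#' Rank background pairs by DysGPS
#'
#' Stable descending sort of the scored background; exact score ties are
#' broken by canonical pair name ascending (`gene_a`, then `gene_b`, byte
#' order) so the ranking is reproducible across platforms.
#'
#' @param scores DysGPS table from [compute_dysgps()] (columns `gene_a`,
#'   `gene_b`, `score`).
#' @return The same `data.frame` reordered, with attribute `N` (list
#'   length).
#' @export
rank_pairs <- function(scores) {
  if (any(!is.finite(scores$score))) {
    i <- which(!is.finite(scores$score))[1L]
    stop("non-finite score for pair ", scores$gene_a[i], "|", scores$gene_b[i])
  }
  o <- order(-scores$score, scores$gene_a, scores$gene_b, method = "radix")
  out <- scores[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "N") <- nrow(out)
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score (DysPS) for one pathway
#'
#' Walks the full ranked list accumulating `S_hit - S_miss`: hits (pathway
#' pairs) add their `|DysGPS|^p_exp` weight normalized by the pathway total
#' `N_R`; misses subtract `1/N_miss`.  Returns the extremum of largest
#' magnitude (`S_max` on an exact magnitude tie).  With `p_exp = 0` this is
#' the classic two-sample Kolmogorov-Smirnov statistic on ranks.
#'
#' This is the reference O(N) implementation; [all_enrichment_scores()] is
#' the fast path used by the pipeline.
#'
#' @param ranked Ranked list from [rank_pairs()].
#' @param positions 1-based ranks of the pathway's pairs in `ranked`
#'   (strictly fewer than `N` of them).
#' @param p_exp Weight exponent (default 1).
#' @return The DysPS value (in `[-1, 1]` for `p_exp` 0 or 1).
#' @export
enrichment_score <- function(ranked, positions, p_exp = 1) {
  N <- nrow(ranked)
  positions <- sort(as.integer(positions))
  m <- length(positions)
  if (m < 1L || m >= N) stop("pathway must cover between 1 and N-1 positions")
  if (positions[1L] < 1L || positions[m] > N) stop("positions out of range")
  if (anyDuplicated(positions)) stop("duplicate positions")
  hit <- rep(0, N)
  hit[positions] <- 1
  w <- abs(ranked$score)^p_exp * hit
  n_r <- sum(w)
  if (n_r <= 0) stop("all pathway pair weights are zero (N_R = 0)")
  running <- cumsum(w) / n_r - cumsum(1 - hit) / (N - m)
  s_max <- max(running)
  s_min <- min(running)
  if (abs(s_max) > abs(s_min)) s_max
  else if (abs(s_max) < abs(s_min)) s_min
  else s_max
}

#' Fast DysPS for many pathways
#'
#' Compiled evaluation touching only each pathway's own hit positions (the
#' running-sum extrema can occur only at a hit or immediately before one),
#' so after the one global ranking each pathway costs O(m log m) instead of
#' O(N).  Agrees with [enrichment_score()] to floating-point rounding.
#'
#' @param ranked Ranked list from [rank_pairs()].
#' @param index Named list of 1-based position vectors, one per pathway.
#' @param p_exp Weight exponent (default 1).
#' @return Named numeric vector of DysPS values.
#' @export
all_enrichment_scores <- function(ranked, index, p_exp = 1) {
  N <- nrow(ranked)
  out <- dysps_cpp(ranked$score, seq_len(N), index, p_exp)
  names(out) <- names(index)
  out
}

## Map each pathway's pairs to row indices of a background; drop pathways
## whose usable-pair count falls outside [min_size, max_size].
pathway_pair_index <- function(pathways, bg, min_size = 5L, max_size = 5000L) {
  keys <- pair_key(bg)
  pw_keys <- lapply(pathways, function(p) pair_key(p$pairs))
  hits <- match(unlist(pw_keys, use.names = FALSE), keys)
  grp <- factor(rep(seq_along(pathways), lengths(pw_keys)),
                levels = seq_along(pathways))
  idx <- lapply(split(hits, grp), function(i) sort(i[!is.na(i)]))
  names(idx) <- vapply(pathways, `[[`, "", "pathway_id")
  sizes <- lengths(idx)
  keep <- sizes >= min_size & sizes <= max_size & sizes < nrow(bg)
  if (!any(keep))
    stop("no pathway has a usable pair count in [", min_size, ", ", max_size,
         "] against this background")
  if (any(!keep))
    message(sum(!keep), " pathway(s) outside the usable-size window [",
            min_size, ", ", max_size, "] were excluded")
  idx[keep]
}

## Sample-label shuffles preserving group sizes, one column per
## permutation (1 = case).  Falls back to exhaustive enumeration of all
## C(ns, n_case) assignments when that count does not exceed n_perm.
make_permutations <- function(ns, n_case, n_perm, seed) {
  stopifnot(n_perm >= 1)
  n_distinct <- choose(ns, n_case)
  if (n_distinct <= n_perm) {
    if (n_distinct < n_perm)
      warning("only ", n_distinct, " distinct label assignments exist; ",
              "using exhaustive enumeration instead of ", n_perm, " draws")
    sets <- combn(ns, n_case)
    out <- matrix(0L, ns, ncol(sets))
    for (j in seq_len(ncol(sets))) out[sets[, j], j] <- 1L
    return(out)
  }
  with_seed(seed, {
    out <- matrix(0L, ns, n_perm)
    for (j in seq_len(n_perm)) out[sample(ns, n_case), j] <- 1L
    out
  })
}

#' Permutation null distribution of DysPS
#'
#' Shuffles the case/control labels (preserving group sizes), recomputes
#' the group-wise standardization, every DysGPS, the ranking and every
#' pathway's DysPS per shuffle.  One shared shuffle serves all pathways.
#' When the number of distinct label assignments does not exceed `n_perm`,
#' all of them are enumerated instead of sampled.
#'
#' @param expr Expression matrix.
#' @param labels Phenotype labels.
#' @param bg Restricted background (see [restrict_to_expression()]).
#' @param pathway_index Named list of bg row-index vectors per pathway
#'   (from the internal index builder; see [run_dyspia()]).
#' @param n_perm Number of permutations (>= 1000 recommended).
#' @param seed Integer seed.
#' @param p_exp Weight exponent.
#' @return Matrix (`n_perm_used` x pathways) of null DysPS values;
#'   attribute `perm_case` stores the shuffles used.
#' @export
permutation_null <- function(expr, labels, bg, pathway_index, n_perm, seed,
                             p_exp = 1) {
  validate_expression(expr)
  labels <- validate_phenotype(labels, expr)
  genes <- unique(c(bg$gene_a, bg$gene_b))
  Xt <- t(expr[genes, , drop = FALSE])
  ia <- match(bg$gene_a, genes) - 1L
  ib <- match(bg$gene_b, genes) - 1L
  n_case <- sum(labels$group == "case")
  perms <- make_permutations(ncol(expr), n_case, n_perm, seed)
  null <- perm_null_cpp(Xt, ia, ib, perms, seq_len(nrow(bg)),
                        unname(pathway_index), p_exp)
  colnames(null) <- names(pathway_index)
  attr(null, "perm_case") <- perms
  null
}

#' Nominal permutation p-value from a signed null
#'
#' Uses the portion of the null distribution matching the sign of the
#' observed DysPS, with a pseudocount so p is never 0:
#' `p = (1 + #\{null same-sign and at least as extreme\}) / (1 + #\{null
#' same-sign\})`.
#'
#' @param observed Observed DysPS (length 1).
#' @param null_values Numeric vector of null DysPS values.
#' @return p-value in (0, 1].
#' @export
nominal_pvalue <- function(observed, null_values) {
  if (length(null_values) == 0L) stop("empty null distribution")
  if (observed >= 0) {
    portion <- null_values[null_values >= 0]
    b <- sum(portion >= observed)
  } else {
    portion <- null_values[null_values < 0]
    b <- sum(portion <= observed)
  }
  if (length(portion) == 0L)
    warning("no null values share the sign of the observed score; p = 1")
  (1 + b) / (1 + length(portion))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (monotone, clipped at 1), applied across
#' all tested pathways of one run as a single family.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  p.adjust(pvals, method = "BH")
}

#' Gain / loss of correlation call
#'
#' A pathway gains correlation when its FDR is below `alpha` and DysPS is
#' positive (its pairs are more co-expressed in cases), loses correlation
#' when the FDR is below `alpha` and DysPS is negative; otherwise it is not
#' significant.
#'
#' @param dysps,fdr Numeric vectors (recycled).
#' @param alpha FDR threshold (default 0.05).
#' @return Character vector in `{"gain", "loss", "not_significant"}`.
#' @export
classify_direction <- function(dysps, fdr, alpha = 0.05) {
  ifelse(fdr < alpha & dysps > 0, "gain",
         ifelse(fdr < alpha & dysps < 0, "loss", "not_significant"))
}

#' Run the full dysregulated-pathway identification pipeline
#'
#' Restricts the background to the expression data, computes every DysGPS,
#' ranks the background, scores each usable pathway with DysPS, builds a
#' shared label-permutation null, and reports nominal p-values, BH-FDR and
#' gain/loss calls.
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Phenotype labels ([phenotype_labels()]).
#' @param pathways Named list of [pathway_pair_set()] objects.
#' @param bg Optional background pair `data.frame`; when `NULL` a combined
#'   background is built from the pathways' own pairs (observed part) plus
#'   an equal number of random pairs drawn from the measured genes.
#' @param n_perm Number of label permutations (default 10000; >= 1000
#'   recommended, 10000 or more for stable FDRs over many pathways).
#' @param seed Integer master seed (permutations and any auto-background
#'   draw derive sub-seeds from it).
#' @param min_size,max_size Usable-pair count window for testing a pathway
#'   (defaults 5 and 5000).
#' @param p_exp DysPS weight exponent (default 1).
#' @param alpha FDR threshold for the direction call (default 0.05).
#' @return A `data.frame` with one row per tested pathway: `pathway_id`,
#'   `name`, `n_pairs_used`, `dysps`, `pval`, `fdr`, `direction`, ordered
#'   by `pval` then `|dysps|` descending.  Attributes: `n_background`,
#'   `n_perm_used`, `seed`.
#' @export
run_dyspia <- function(expr, labels, pathways, bg = NULL, n_perm = 10000L,
                       seed = 1L, min_size = 5L, max_size = 5000L,
                       p_exp = 1, alpha = 0.05) {
  validate_expression(expr)
  labels <- validate_phenotype(labels, expr)
  if (length(pathways) == 0L) stop("no pathways supplied")
  if (is.null(bg)) {
    observed <- build_observed_background(pathways)
    measured <- observed[observed$gene_a %in% rownames(expr) &
                         observed$gene_b %in% rownames(expr), , drop = FALSE]
    n_random <- nrow(measured)
    random <- sample_random_background(rownames(expr), n_random,
                                       derive_seed(seed, 1L))
    bg <- combine_backgrounds(observed, random,
                              universe_size = nrow(expr))
    message("auto-background: ", nrow(observed), " observed + ", n_random,
            " random pairs (", nrow(bg), " combined)")
  }
  bg <- restrict_to_expression(bg, expr, labels)
  gps <- compute_dysgps(expr, labels, bg)
  ranked <- rank_pairs(gps)
  idx <- pathway_pair_index(pathways, bg, min_size, max_size)
  ## positions in the ranked list, from bg-row indices
  rank_of <- integer(nrow(bg))
  rank_of[order(-gps$score, gps$gene_a, gps$gene_b, method = "radix")] <-
    seq_len(nrow(bg))
  positions <- lapply(idx, function(i) sort(rank_of[i]))
  dysps <- all_enrichment_scores(ranked, positions, p_exp)
  null <- permutation_null(expr, labels, bg, idx, n_perm,
                           derive_seed(seed, 2L), p_exp)
  pval <- vapply(seq_along(idx), function(k) {
    nominal_pvalue(dysps[k], null[, k])
  }, numeric(1))
  fdr <- bh_fdr(pval)
  nm <- vapply(pathways, `[[`, "", "name")
  names(nm) <- vapply(pathways, `[[`, "", "pathway_id")
  res <- data.frame(pathway_id = names(idx), name = unname(nm[names(idx)]),
                    n_pairs_used = unname(lengths(idx)),
                    dysps = unname(dysps), pval = pval, fdr = fdr,
                    direction = classify_direction(dysps, fdr, alpha),
                    stringsAsFactors = FALSE)
  o <- order(res$pval, -abs(res$dysps), res$pathway_id, method = "radix")
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_background") <- nrow(bg)
  attr(res, "n_perm_used") <- nrow(null)
  attr(res, "seed") <- seed
  res
}
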