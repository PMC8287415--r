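# Independent oracles and small fixture builders shared across tests.
# Every oracle here is a deliberately slow, direct transcription of the
# definition it checks, kept free of the package's own fast paths.

make_toy_data <- function(n_genes = 12, n_case = 8, n_control = 6, seed = 99) {
  set.seed(seed)
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  samples <- c(sprintf("ca%02d", seq_len(n_case)),
               sprintf("co%02d", seq_len(n_control)))
  expr <- matrix(rnorm(n_genes * (n_case + n_control), mean = 8, sd = 2),
                 n_genes, dimnames = list(genes, samples))
  labels <- phenotype_labels(samples,
                             rep(c("case", "control"), c(n_case, n_control)))
  list(expr = expr, labels = labels)
}

all_pairs_of <- function(genes) {
  cmb <- t(combn(genes, 2))
  canonical_pair(cmb[, 1], cmb[, 2])
}

# Full running-sum evaluated position by position (double loop in spirit;
# used to cross-check both the R reference and the compiled scorer).
brute_running_sum_es <- function(scores_desc, positions, p_exp = 1) {
  N <- length(scores_desc)
  m <- length(positions)
  w <- abs(scores_desc[positions])^p_exp
  n_r <- sum(w)
  s <- numeric(N)
  run <- 0
  for (i in seq_len(N)) {
    if (i %in% positions) {
      run <- run + abs(scores_desc[i])^p_exp / n_r
    } else {
      run <- run - 1 / (N - m)
    }
    s[i] <- run
  }
  smax <- max(s); smin <- min(s)
  if (abs(smax) > abs(smin)) smax else if (abs(smax) < abs(smin)) smin else smax
}

# Benjamini-Hochberg step-up written from the definition.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# AUC by explicit pairwise concordance counting.
auc_concordance_oracle <- function(score, truth) {
  pos <- score[as.logical(truth)]
  neg <- score[!as.logical(truth)]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Per-pair DysGPS via the scalar composition of the three scoring steps.
scalar_dysgps <- function(expr, labels, gene_a, gene_b) {
  z <- standardize_within_group(expr, labels)
  welch_t(cilp_products(z, gene_a, gene_b), labels)
}
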