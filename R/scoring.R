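#' Standardize expression within each phenotype group
#'
#' Every gene is mean-centered and scaled to unit standard deviation
#' separately in the case and control samples.  The unbiased (n-1) standard
#' deviation is used throughout, matching the variance estimator of the
#' downstream Welch test; a consequence is that the within-group mean of a
#' pair's products equals `(n-1)/n` times the within-group Pearson
#' correlation, exactly.
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Phenotype labels ([phenotype_labels()]).
#' @return Matrix of the same shape: per gene and group, mean 0 and sd 1.
#' @export
standardize_within_group <- function(expr, labels) {
  validate_expression(expr)
  labels <- validate_phenotype(labels, expr)
  grp <- labels$group[match(colnames(expr), labels$sample)]
  z <- expr
  for (g in c("case", "control")) {
    cols <- grp == g
    sub <- expr[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- sqrt(rowSums((sub - mu)^2) / (ncol(sub) - 1L))
    if (any(sdv == 0)) {
      bad <- rownames(expr)[which(sdv == 0)[1L]]
      stop("gene '", bad, "' has zero variance in the ", g, " group")
    }
    z[, cols] <- (sub - mu) / sdv
  }
  z
}

#' Per-sample CILP products for one gene pair
#'
#' The correlation-by-individual-level-product statistic: for each sample,
#' the product of the two genes' group-wise standardized expression values.
#' Its mean within a group tracks that group's Pearson correlation, so the
#' case/control difference in products carries differential co-expression
#' at single-sample resolution.
#'
#' @param z Standardized matrix from [standardize_within_group()].
#' @param gene_a,gene_b The two gene symbols.
#' @return Numeric vector of products, one per sample, in column order.
#' @export
cilp_products <- function(z, gene_a, gene_b) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(z)) stop("gene '", g, "' not present in matrix")
  }
  y <- z[gene_a, ] * z[gene_b, ]
  names(y) <- colnames(z)
  y
}

#' Welch two-sample t statistic
#'
#' `(mean_case - mean_control) / sqrt(s1^2/n1 + s2^2/n2)` with unbiased
#' group variances.  Positive values mean the quantity is higher in cases.
#' Used as a ranking score only; no degrees of freedom or parametric
#' p-value are computed.
#'
#' @param y Numeric vector, one value per sample (named or aligned with
#'   `labels$sample` order as in the expression matrix).
#' @param labels Phenotype labels; matched to `y` by name when `y` is
#'   named, else by position against `labels$sample`.
#' @return The t statistic (length-1 numeric).
#' @export
welch_t <- function(y, labels) {
  if (!is.null(names(y))) {
    grp <- labels$group[match(names(y), labels$sample)]
    if (anyNA(grp)) stop("sample names of `y` not covered by labels")
  } else {
    if (length(y) != nrow(labels)) stop("length(y) != number of labeled samples")
    grp <- labels$group
  }
  y1 <- y[grp == "case"]; y0 <- y[grp == "control"]
  if (length(y1) < 2L || length(y0) < 2L) stop("need >= 2 samples per group")
  v1 <- var(y1); v0 <- var(y0)
  if (v1 + v0 == 0) stop("zero variance in both groups: statistic undefined")
  (mean(y1) - mean(y0)) / sqrt(v1 / length(y1) + v0 / length(y0))
}

#' Dysregulated gene-pair scores (DysGPS) for a background
#'
#' For every background pair: standardize within groups, form per-sample
#' CILP products, and summarise with the Welch t statistic (case minus
#' control).  This is the vectorized (compiled) equivalent of
#' `welch_t(cilp_products(standardize_within_group(expr, labels), a, b),
#' labels)` applied pair by pair.
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Phenotype labels.
#' @param bg Background pair `data.frame`, already restricted via
#'   [restrict_to_expression()].
#' @return A `data.frame` with columns `gene_a`, `gene_b`, `score`, one row
#'   per background pair (background order preserved); attributes `n_case`
#'   and `n_control` record the group sizes used.
#' @export
compute_dysgps <- function(expr, labels, bg) {
  validate_expression(expr)
  labels <- validate_phenotype(labels, expr)
  genes <- unique(c(bg$gene_a, bg$gene_b))
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0L)
    stop("background genes absent from expression matrix: ",
         paste(head(absent, 5L), collapse = ", "),
         " (restrict the background first)")
  grp <- as.integer(labels$group[match(colnames(expr), labels$sample)] == "case")
  Xt <- t(expr[genes, , drop = FALSE])
  ia <- match(bg$gene_a, genes) - 1L
  ib <- match(bg$gene_b, genes) - 1L
  score <- dysgps_cpp(Xt, ia, ib, grp)
  if (any(!is.finite(score))) {
    i <- which(!is.finite(score))[1L]
    stop("undefined DysGPS for pair ", bg$gene_a[i], "|", bg$gene_b[i],
         " (zero within-group variance?)")
  }
  out <- data.frame(gene_a = bg$gene_a, gene_b = bg$gene_b, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "n_case") <- sum(grp == 1L)
  attr(out, "n_control") <- sum(grp == 0L)
  out
}
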