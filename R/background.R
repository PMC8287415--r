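#' Canonicalize gene pairs
#'
#' A canonical gene pair stores its two symbols in ascending lexicographic
#' byte order (`gene_a < gene_b`, case-sensitive, no locale folding), so
#' that an unordered pair has exactly one representation in backgrounds and
#' pathway sets.
#'
#' @param gene_a,gene_b Character vectors of gene symbols (recycled to a
#'   common length).
#' @return A `data.frame` with character columns `gene_a` and `gene_b`,
#'   `gene_a < gene_b` byte-wise in every row.
#' @examples
#' canonical_pair("TP53", "BRCA1")
#' @export
canonical_pair <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  n <- max(length(gene_a), length(gene_b))
  gene_a <- rep_len(gene_a, n)
  gene_b <- rep_len(gene_b, n)
  if (anyNA(gene_a) || anyNA(gene_b)) stop("gene symbols must not be NA")
  self <- gene_a == gene_b
  if (any(self)) {
    stop("self-pair not allowed: ", paste(unique(gene_a[self]), collapse = ", "))
  }
  swap <- str_gt_cpp(gene_a, gene_b)
  data.frame(gene_a = ifelse(swap, gene_b, gene_a),
             gene_b = ifelse(swap, gene_a, gene_b),
             stringsAsFactors = FALSE)
}

## Single string key per pair; `|` never occurs in HGNC symbols.
pair_key <- function(pairs) paste(pairs$gene_a, pairs$gene_b, sep = "|")

## Deterministic pair ordering: gene_a then gene_b, byte order.
order_pairs <- function(pairs) {
  order(pairs$gene_a, pairs$gene_b, method = "radix")
}

new_background <- function(pairs, provenance, universe_size = NA_integer_) {
  stopifnot(is.data.frame(pairs), nrow(pairs) == length(provenance))
  bg <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                   provenance = provenance, stringsAsFactors = FALSE)
  bg <- bg[order_pairs(bg), , drop = FALSE]
  rownames(bg) <- NULL
  if (anyDuplicated(pair_key(bg))) stop("duplicate pairs in background")
  attr(bg, "universe_size") <- as.integer(universe_size)
  class(bg) <- c("dys_background", "data.frame")
  bg
}

#' Pool the observed gene-pair background from pathway edge sets
#'
#' The observed part of a combined background is the union of all regulated
#' gene pairs appearing in the supplied pathways, deduplicated.
#'
#' @param pathways A list of pathway pair sets as returned by
#'   [read_pathway_pairs()] or [pathway_pair_set()].
#' @return A `data.frame` of unique canonical pairs (`gene_a`, `gene_b`),
#'   sorted by `gene_a` then `gene_b`.
#' @export
build_observed_background <- function(pathways) {
  if (length(pathways) == 0L) stop("`pathways` must be non-empty")
  ga <- unlist(lapply(pathways, function(p) p$pairs$gene_a), use.names = FALSE)
  gb <- unlist(lapply(pathways, function(p) p$pairs$gene_b), use.names = FALSE)
  pairs <- canonical_pair(ga, gb)
  pairs <- pairs[!duplicated(pair_key(pairs)), , drop = FALSE]
  pairs <- pairs[order_pairs(pairs), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Sample a random gene-pair background
#'
#' Draws `n_pairs` unordered gene pairs uniformly without replacement from
#' all `choose(length(universe), 2)` pairs of a gene universe.  Equivalent
#' to drawing ordered pairs and keeping the ascending half, but with no
#' wasted draws.
#'
#' @param universe Character vector of distinct gene symbols.
#' @param n_pairs Number of pairs to draw.
#' @param seed Integer seed; the draw is reproducible bit-for-bit.
#' @return A `data.frame` of `n_pairs` unique canonical pairs, sorted.
#' @export
sample_random_background <- function(universe, n_pairs, seed) {
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop("`universe` must not contain duplicates")
  g <- length(universe)
  if (g < 2L) stop("`universe` must contain at least 2 genes")
  total <- g * (g - 1) / 2
  if (n_pairs > total) {
    stop("cannot draw ", n_pairs, " pairs from a universe of ", g,
         " genes (only ", total, " pairs exist)")
  }
  universe <- universe[order(universe, method = "radix")]
  idx <- with_seed(seed, sample(total, n_pairs))
  ij <- decode_pair_index(idx, g)
  pairs <- data.frame(gene_a = universe[ij$i], gene_b = universe[ij$j],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order_pairs(pairs), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

## Map linear indices 1..choose(g,2) to (i < j) over a sorted universe.
## Pairs are enumerated (1,2),(1,3),...,(1,g),(2,3),...  The closed form
## uses a sqrt; an integer correction step absorbs any rounding.
decode_pair_index <- function(idx, g) {
  total <- g * (g - 1) / 2
  rev <- total - idx               # pairs strictly after idx
  k <- floor((sqrt(8 * rev + 1) - 1) / 2)
  k <- ifelse((k + 1) * (k + 2) / 2 <= rev, k + 1, k)
  k <- ifelse(k * (k + 1) / 2 > rev, k - 1, k)
  i <- g - 1 - k
  j <- idx - (total - (k + 1) * (k + 2) / 2) + i
  list(i = as.integer(i), j = as.integer(j))
}

#' Combine observed and random backgrounds
#'
#' Union of the two pair sets; pairs present in both are kept once and
#' flagged with provenance `"both"`.
#'
#' @param observed,random Canonical pair `data.frame`s (`gene_a`, `gene_b`).
#' @param universe_size Optional count of genes behind the random draw,
#'   recorded as metadata.
#' @return A background `data.frame` with columns `gene_a`, `gene_b`,
#'   `provenance` (`"observed"`, `"random"` or `"both"`), sorted, unique.
#' @export
combine_backgrounds <- function(observed, random, universe_size = NA_integer_) {
  ko <- pair_key(observed)
  kr <- pair_key(random)
  if (anyDuplicated(ko)) stop("duplicate pairs in `observed`")
  if (anyDuplicated(kr)) stop("duplicate pairs in `random`")
  both <- intersect(ko, kr)
  all_pairs <- rbind(observed[, c("gene_a", "gene_b")],
                     random[!(kr %in% both), c("gene_a", "gene_b")])
  ka <- pair_key(all_pairs)
  prov <- ifelse(ka %in% both, "both",
                 ifelse(ka %in% ko, "observed", "random"))
  new_background(all_pairs, prov, universe_size)
}

#' Restrict a background to what an expression matrix can score
#'
#' Keeps only pairs whose two genes are both measured and both have nonzero
#' variance within each phenotype group (a zero-variance gene cannot be
#' standardized).  Filtering here, before scoring, keeps the ranked-list
#' length fixed across label permutations.
#'
#' @param bg Background `data.frame` (`gene_a`, `gene_b`, optionally
#'   `provenance`).
#' @param expr Expression matrix (genes x samples) as from
#'   [read_expression()].
#' @param labels Phenotype labels as from [read_phenotype()]; required for
#'   the within-group variance check.
#' @return The filtered background, same columns, sorted; the counts of
#'   pairs removed for missing genes and for zero variance are reported via
#'   `message()`.
#' @export
restrict_to_expression <- function(bg, expr, labels) {
  validate_expression(expr)
  labels <- validate_phenotype(labels, expr)
  measured <- bg$gene_a %in% rownames(expr) & bg$gene_b %in% rownames(expr)
  n_missing <- sum(!measured)
  bg2 <- bg[measured, , drop = FALSE]
  genes <- unique(c(bg2$gene_a, bg2$gene_b))
  grp <- labels$group[match(colnames(expr), labels$sample)]
  ok_gene <- rep(TRUE, length(genes))
  for (g in unique(grp)) {
    sub <- expr[genes, grp == g, drop = FALSE]
    ss <- rowSums((sub - rowMeans(sub))^2)
    ok_gene <- ok_gene & (ss > 0)
  }
  names(ok_gene) <- genes
  ok <- ok_gene[bg2$gene_a] & ok_gene[bg2$gene_b]
  n_zerovar <- sum(!ok)
  bg2 <- bg2[ok, , drop = FALSE]
  message(sprintf(
    "background restricted: %d pairs dropped (unmeasured gene), %d dropped (zero within-group variance), %d retained",
    n_missing, n_zerovar, nrow(bg2)))
  if (nrow(bg2) == 0L) stop("no background pairs measurable in this expression matrix")
  if (is.null(bg2$provenance)) bg2$provenance <- "observed"
  new_background(bg2[, c("gene_a", "gene_b")], bg2$provenance,
                 attr(bg, "universe_size") %||% NA_integer_)
}
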