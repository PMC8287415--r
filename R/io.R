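#' Read a gene x sample expression matrix
#'
#' Expects a delimited text file with a header row of sample identifiers
#' and gene symbols in the first column.  Values are used as supplied
#' (log-scale or linear); no transformation is applied.
#'
#' Duplicate gene rows keep the first occurrence with a warning.  Missing
#' cells (`NA`, `NaN` or empty) are rejected by default; `impute =
#' "row-mean"` replaces them by the gene's mean over the remaining samples.
#' Any other non-numeric cell is a parse error naming the gene and sample.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param impute Missing-value policy: `"error"` (default) or `"row-mean"`.
#' @return Numeric matrix with gene symbols as `rownames` and sample ids as
#'   `colnames`.
#' @export
read_expression <- function(path, dialect = c("tsv", "csv"),
                            impute = c("error", "row-mean")) {
  dialect <- match.arg(dialect)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          na.strings = NULL)
  if (ncol(dt) < 3L) stop("expression matrix needs at least 2 sample columns")
  genes <- as.character(dt[[1L]])
  samples <- colnames(dt)[-1L]
  if (anyDuplicated(samples)) stop("duplicate sample ids in header")
  vals <- dt[, -1L, drop = FALSE]
  missing_tokens <- c("NA", "NaN", "")
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      raw <- trimws(as.character(col))
      num <- suppressWarnings(as.numeric(raw))
      bad <- is.na(num) & !(raw %in% missing_tokens)
      if (any(bad)) {
        i <- which(bad)[1L]
        stop(sprintf("malformed numeric cell '%s' at gene '%s', sample '%s'",
                     raw[i], genes[i], samples[j]))
      }
      vals[[j]] <- num
    }
  }
  mat <- as.matrix(vals)
  dimnames(mat) <- list(genes, samples)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("duplicate gene rows (keeping first occurrence): ",
            paste(head(dup, 5L), collapse = ", "),
            if (length(dup) > 5L) ", ..." else "")
    mat <- mat[!duplicated(genes), , drop = FALSE]
  }
  if (anyNA(mat)) {
    if (impute == "error") {
      i <- which(is.na(mat), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at gene '%s', sample '%s' (use impute = \"row-mean\" to impute)",
                   rownames(mat)[i[1L]], colnames(mat)[i[2L]]))
    }
    for (i in which(rowSums(is.na(mat)) > 0L)) {
      miss <- is.na(mat[i, ])
      if (all(miss)) stop("gene '", rownames(mat)[i], "' has no observed values")
      mat[i, miss] <- mean(mat[i, !miss])
    }
  }
  if (any(!is.finite(mat))) stop("non-finite expression values after ingest")
  validate_expression(mat)
  mat
}

validate_expression <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids")
  if (ncol(expr) < 2L) stop("need at least 2 samples")
  invisible(expr)
}

#' Construct two-group phenotype labels
#'
#' @param sample Character vector of sample identifiers.
#' @param group Character vector of group memberships, two distinct values.
#' @param case Which group value is the case group (the other becomes
#'   control).  May be omitted when the values are already `"case"` and
#'   `"control"`.
#' @return A `data.frame` with columns `sample` and `group` (values
#'   `"case"`/`"control"`), class `dys_phenotype`.  The DysGPS sign
#'   convention is case minus control, so the `case` assignment fixes the
#'   direction of every downstream score.
#' @export
phenotype_labels <- function(sample, group, case = NULL) {
  sample <- as.character(sample)
  group <- as.character(group)
  stopifnot(length(sample) == length(group))
  if (anyDuplicated(sample)) stop("duplicate sample ids in phenotype labels")
  lev <- sort(unique(group))
  if (length(lev) != 2L)
    stop("exactly two groups required, found: ", paste(lev, collapse = ", "))
  if (is.null(case)) {
    if (setequal(lev, c("case", "control"))) case <- "case"
    else stop("groups are ", paste(lev, collapse = "/"),
              "; specify which one is `case`")
  }
  if (!case %in% lev) stop("`case` value '", case, "' not among groups")
  out <- data.frame(sample = sample,
                    group = ifelse(group == case, "case", "control"),
                    stringsAsFactors = FALSE)
  n <- table(out$group)
  if (any(n < 2L)) stop("each group needs at least 2 samples")
  if (any(n < 3L))
    warning("group with fewer than 3 samples: variance estimates will be unstable")
  class(out) <- c("dys_phenotype", "data.frame")
  out
}

#' Read phenotype labels from a two-column TSV
#'
#' The file must have a header line `sample_id<TAB>group`.
#'
#' @inheritParams phenotype_labels
#' @param path Path to the file.
#' @return See [phenotype_labels()].
#' @export
read_phenotype <- function(path, case = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (ncol(dt) != 2L) stop("phenotype file must have exactly 2 columns")
  phenotype_labels(dt[[1L]], dt[[2L]], case = case)
}

validate_phenotype <- function(labels, expr) {
  if (!inherits(labels, "dys_phenotype"))
    labels <- phenotype_labels(labels$sample, labels$group)
  absent <- setdiff(labels$sample, colnames(expr))
  if (length(absent) > 0L)
    stop("labeled samples absent from expression matrix: ",
         paste(head(absent, 5L), collapse = ", "))
  unlabeled <- setdiff(colnames(expr), labels$sample)
  if (length(unlabeled) > 0L)
    stop("expression samples without phenotype label: ",
         paste(head(unlabeled, 5L), collapse = ", "))
  labels
}

#' Construct a pathway gene-pair set
#'
#' @param pathway_id Identifier string.
#' @param name Human-readable description.
#' @param gene_a,gene_b Gene symbols of the member pairs (any order;
#'   canonicalized on construction, duplicates collapsed).
#' @return A list with fields `pathway_id`, `name`, `pairs` (canonical pair
#'   `data.frame`), class `pathway_pair_set`.
#' @export
pathway_pair_set <- function(pathway_id, name, gene_a, gene_b) {
  pairs <- canonical_pair(gene_a, gene_b)
  pairs <- pairs[!duplicated(pair_key(pairs)), , drop = FALSE]
  pairs <- pairs[order_pairs(pairs), , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0L) stop("pathway '", pathway_id, "' has no pairs")
  structure(list(pathway_id = as.character(pathway_id),
                 name = as.character(name), pairs = pairs),
            class = "pathway_pair_set")
}

#' Read pathway gene-pair sets
#'
#' Two dialects are supported.  `pair_gmt` is a GMT-style line format where
#' each member token is a `|`-joined gene pair:
#' `pathway_id<TAB>description<TAB>GENEA|GENEB<TAB>...`.  `sif` is an edge
#' list `GENEA<TAB>relation<TAB>GENEB` with an optional fourth column
#' holding the pathway id; a 3-column SIF yields a single pathway named
#' after the file.
#'
#' Pairs are canonicalized; self-pairs are dropped with a warning;
#' duplicate pairs within a pathway are collapsed; pathways left with no
#' pairs are dropped with a warning.
#'
#' @param path Path to the file.
#' @param fmt `"pair_gmt"` (default) or `"sif"`.
#' @return Named list of [pathway_pair_set()] objects.
#' @export
read_pathway_pairs <- function(path, fmt = c("pair_gmt", "sif")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "pair_gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    out <- list()
    for (li in seq_along(lines)) {
      f <- strsplit(lines[li], "\t", fixed = TRUE)[[1L]]
      if (length(f) < 3L)
        stop("line ", li, ": expected pathway_id, description and >= 1 pair token")
      tokens <- f[-(1:2)]
      halves <- strsplit(tokens, "|", fixed = TRUE)
      bad <- vapply(halves, length, 1L) != 2L
      if (any(bad))
        stop("line ", li, ": pair token without a single '|': ",
             tokens[which(bad)[1L]])
      ga <- vapply(halves, `[`, "", 1L)
      gb <- vapply(halves, `[`, "", 2L)
      ps <- make_pathway_dropping_self(f[1L], f[2L], ga, gb)
      if (!is.null(ps)) out[[f[1L]]] <- ps
    }
    out
  } else {
    dt <- data.table::fread(path, sep = "\t", header = FALSE,
                            data.table = FALSE, colClasses = "character")
    if (!ncol(dt) %in% c(3L, 4L))
      stop("SIF file must have 3 or 4 tab-separated columns")
    pw <- if (ncol(dt) == 4L) dt[[4L]] else
      rep(sub("\\.[^.]*$", "", basename(path)), nrow(dt))
    out <- list()
    for (id in unique(pw)) {
      sel <- pw == id
      ps <- make_pathway_dropping_self(id, id, dt[[1L]][sel], dt[[3L]][sel])
      if (!is.null(ps)) out[[id]] <- ps
    }
    out
  }
}

make_pathway_dropping_self <- function(id, name, ga, gb) {
  self <- ga == gb
  if (any(self)) {
    warning("pathway '", id, "': dropped ", sum(self), " self-pair(s)")
    ga <- ga[!self]; gb <- gb[!self]
  }
  if (length(ga) == 0L) {
    warning("pathway '", id, "' has no usable pairs; dropped")
    return(NULL)
  }
  pathway_pair_set(id, name, ga, gb)
}

#' Write pathway gene-pair sets in pair_gmt format
#'
#' @param pathways Named list of [pathway_pair_set()] objects.
#' @param path Output path.
#' @export
write_pathway_pairs <- function(pathways, path) {
  lines <- vapply(pathways, function(p) {
    paste(c(p$pathway_id, p$name,
            paste(p$pairs$gene_a, p$pairs$gene_b, sep = "|")),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a gene-pair background TSV
#'
#' Format: header `gene_a<TAB>gene_b[<TAB>provenance]`; pairs must be
#' canonical and unique; provenance values are `observed`, `random` or
#' `both` (defaulting to `observed` when the column is absent).
#'
#' @param path Path to the file.
#' @return A background `data.frame` (see [combine_backgrounds()]).
#' @export
read_background <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (!all(c("gene_a", "gene_b") %in% colnames(dt)))
    stop("background file must have columns gene_a and gene_b")
  bad <- str_gt_cpp(dt$gene_a, dt$gene_b) | dt$gene_a == dt$gene_b
  if (any(bad)) stop("non-canonical or self pair at line ", which(bad)[1L] + 1L)
  prov <- dt$provenance %||% rep("observed", nrow(dt))
  if (!all(prov %in% c("observed", "random", "both")))
    stop("provenance must be one of observed/random/both")
  new_background(dt[, c("gene_a", "gene_b")], prov)
}

#' @rdname read_background
#' @param bg Background `data.frame`.
#' @export
write_background <- function(bg, path) {
  out <- data.frame(gene_a = bg$gene_a, gene_b = bg$gene_b,
                    provenance = bg$provenance %||% "observed")
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write / read an enrichment result table
#'
#' TSV with columns `pathway_id`, `name`, `n_pairs_used`, `DysPS`, `pval`,
#' `FDR`, `direction`, ordered by p-value ascending then `|DysPS|`
#' descending.  Reals are printed with 10 significant digits so the table
#' round-trips through [read_results()].
#'
#' @param results Result `data.frame` from [run_dyspia()].
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0L)
    stop("empty result table: nothing to write")
  o <- order(results$pval, -abs(results$dysps), results$pathway_id,
             method = "radix")
  r <- results[o, , drop = FALSE]
  out <- data.frame(pathway_id = r$pathway_id, name = r$name,
                    n_pairs_used = r$n_pairs_used,
                    DysPS = sprintf("%.10g", r$dysps),
                    pval = sprintf("%.10g", r$pval),
                    FDR = sprintf("%.10g", r$fdr),
                    direction = r$direction)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  data.frame(pathway_id = as.character(dt$pathway_id),
             name = as.character(dt$name),
             n_pairs_used = as.integer(dt$n_pairs_used),
             dysps = as.numeric(dt$DysPS), pval = as.numeric(dt$pval),
             fdr = as.numeric(dt$FDR), direction = as.character(dt$direction),
             stringsAsFactors = FALSE)
}
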