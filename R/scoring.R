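#' Rank-based per-cell signature scores
#'
#' A capped Mann-Whitney U statistic per cell and signature: genes are
#' ranked by descending expression within the cell (average ties), ranks
#' beyond `rank_cap` are set to `rank_cap + 1` (as are signature genes
#' absent from the matrix), and the score is
#' `max(0, 1 - U' / (n * rank_cap))` with
#' `U' = sum(ranks of signature genes) - n(n+1)/2`. Scores live in
#' `[0, 1]` and are invariant under any strictly monotone transform of a
#' cell's expression values.
#'
#' @param expr Cell x gene matrix of normalized expression (dense or
#'   sparse), or a single named per-gene vector for one cell.
#' @param signatures Named list of gene vectors (or one character
#'   vector).
#' @param rank_cap Ranks beyond this are truncated (default 1500).
#' @return Cell x signature matrix of scores (or a named vector for a
#'   single cell input).
#' @export
ucell_score <- function(expr, signatures, rank_cap = 1500) {
  single <- is.null(dim(expr))
  if (single) expr <- matrix(expr, 1, dimnames = list("cell", names(expr)))
  if (is.character(signatures)) signatures <- list(signature = signatures)
  if (any(lengths(signatures) == 0)) stop("empty signature", call. = FALSE)
  genes <- colnames(expr)
  if (is.null(genes)) stop("expr must have gene names", call. = FALSE)
  sig_idx <- lapply(signatures, function(s) match(s, genes)) # NA = missing gene
  expr <- as.matrix(expr)

  out <- matrix(NA_real_, nrow(expr), length(signatures),
                dimnames = list(rownames(expr), names(signatures)))
  for (c_i in seq_len(nrow(expr))) {
    r <- rank(-expr[c_i, ], ties.method = "average")
    r <- pmin(r, rank_cap + 1)
    for (s_i in seq_along(sig_idx)) {
      idx <- sig_idx[[s_i]]
      rs <- ifelse(is.na(idx), rank_cap + 1, r[idx])
      n <- length(idx)
      u <- sum(rs) - n * (n + 1) / 2
      out[c_i, s_i] <- max(0, 1 - u / (n * rank_cap))
    }
  }
  if (single) out[1, ] else out
}

#' Assign each cell to its dominant signature
#'
#' The label is the argmax signature provided the maximum score reaches
#' `min_score` and beats the runner-up by at least `margin`; exact ties
#' and sub-threshold cells are `"unassigned"`.
#'
#' @param scores Cell x signature score matrix.
#' @param min_score Minimum winning score.
#' @param margin Required gap to the second-best score.
#' @return Character vector of labels, one per cell.
#' @export
assign_state <- function(scores, min_score = 0.2, margin = 0.0) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 1) stop("need at least one signature", call. = FALSE)
  apply(scores, 1, function(s) {
    top <- max(s)
    second <- if (length(s) > 1) max(s[-which.max(s)]) else -Inf
    if (top < min_score || top - second < margin || sum(s == top) > 1)
      "unassigned" else colnames(scores)[which.max(s)]
  })
}

#' Single-sample gene-set enrichment score
#'
#' Weighted Kolmogorov-Smirnov-style running sum: with genes ordered by
#' decreasing expression, the enrichment score is
#' `ES = sum_i [P_in^w(i) - P_out(i)]` where `P_in^w` accumulates
#' `rank^alpha` weights over in-set genes (rank counted from the bottom,
#' so the top gene carries weight `N^alpha`) and `P_out` is the uniform
#' ECDF over out-of-set genes. When a matrix is scored, scores are
#' min-max normalized across samples per gene set.
#'
#' @param expr Sample x gene matrix, or one named per-gene vector.
#' @param gene_sets Named list of gene vectors (or one character vector).
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Min-max normalize across samples (matrix input only).
#' @return Sample x set matrix of scores (vector input: named vector of
#'   raw enrichment scores).
#' @export
ssgsea_score <- function(expr, gene_sets, alpha = 0.25, normalize = TRUE) {
  single <- is.null(dim(expr))
  if (single) expr <- matrix(expr, 1, dimnames = list("sample", names(expr)))
  if (is.character(gene_sets)) gene_sets <- list(set = gene_sets)
  expr <- as.matrix(expr)
  genes <- colnames(expr)
  N <- length(genes)

  es <- matrix(NA_real_, nrow(expr), length(gene_sets),
               dimnames = list(rownames(expr), names(gene_sets)))
  for (g_i in seq_along(gene_sets)) {
    in_set <- genes %in% gene_sets[[g_i]]
    if (!any(in_set)) stop("gene set has no overlap with measured genes", call. = FALSE)
    if (all(in_set)) {
      warning("gene set covers all measured genes; enrichment defined as 0",
              call. = FALSE)
      es[, g_i] <- 0
      next
    }
    for (s_i in seq_len(nrow(expr))) {
      ord <- order(-expr[s_i, ])
      inside <- in_set[ord]
      w <- (N - seq_len(N) + 1) ^ alpha
      p_in <- cumsum(ifelse(inside, w, 0)) / sum(w[inside])
      p_out <- cumsum(!inside) / sum(!inside)
      es[s_i, g_i] <- sum(p_in - p_out)
    }
  }
  if (single) return(es[1, ])
  if (normalize && nrow(es) > 1) {
    rng <- apply(es, 2, function(x) diff(range(x)))
    es <- sweep(es, 2, apply(es, 2, min))
    es <- sweep(es, 2, ifelse(rng > 0, rng, 1), "/")
  }
  es
}

#' Wilcoxon differential expression with fold-change and detection filters
#'
#' Per gene: a two-sided Wilcoxon rank-sum test of the in-group against
#' the out-group on normalized expression, Benjamini-Hochberg adjustment,
#' `log2fc = log2((mean_in + eps) / (mean_out + eps))`, and the
#' detection-rate difference `d = pct_in - pct_out`. A gene is a survivor
#' when `p_adj < p_adj_max` and `log2fc > log2fc_min` and `d > d_min`
#' simultaneously; stricter thresholds always select a subset.
#'
#' @param expr Cell x gene normalized matrix.
#' @param group Logical per-cell vector (`TRUE` = in-group) or a
#'   two-level factor whose first level is the in-group.
#' @param p_adj_max,log2fc_min,d_min The three filters.
#' @param eps Pseudocount guarding the fold change.
#' @return Data frame (one row per gene) with `log2fc`, `p`, `p_adj`,
#'   `pct_in`, `pct_out`, `d`, `significant`.
#' @export
de_genes <- function(expr, group, p_adj_max = 0.05, log2fc_min = 1.2,
                     d_min = 0.4, eps = 1e-9) {
  expr <- as.matrix(expr)
  if (!is.logical(group)) {
    f <- factor(group)
    if (nlevels(f) != 2) stop("group must have exactly two levels", call. = FALSE)
    group <- f == levels(f)[1]
  }
  if (sum(group) < 3 || sum(!group) < 3)
    stop("both groups need at least 3 cells", call. = FALSE)
  xin <- expr[group, , drop = FALSE]
  xout <- expr[!group, , drop = FALSE]
  p <- vapply(seq_len(ncol(expr)), function(j) {
    a <- xin[, j]; b <- xout[, j]
    if (var(c(a, b)) == 0) return(1)
    # exact null when small and tie-free (stats default), else normal approx
    suppressWarnings(wilcox.test(a, b)$p.value)
  }, numeric(1))
  res <- data.frame(
    gene = colnames(expr) %||% as.character(seq_len(ncol(expr))),
    log2fc = log2((colMeans(xin) + eps) / (colMeans(xout) + eps)),
    p = p,
    p_adj = p.adjust(p, "BH"),
    pct_in = colMeans(xin > 0),
    pct_out = colMeans(xout > 0),
    row.names = NULL)
  res$d <- res$pct_in - res$pct_out
  res$significant <- res$p_adj < p_adj_max & res$log2fc > log2fc_min & res$d > d_min
  res
}
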