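#' Cell-level quality-control filter
#'
#' Retains cells with more than `min_genes` detected genes, total UMI
#' counts between `umi_min` and `umi_max` (inclusive), mitochondrial
#' content strictly under `mito_max` and haemoglobin content strictly
#' under `hb_max`. Boundary semantics follow a literal reading of the
#' protocol ("over 500 detected genes, UMI counts between 500 and 10,000,
#' mitochondrial gene content under 20%, haemoglobin ... below 1%") and
#' every bound is configurable. The gene set is never modified and
#' retained cells keep their values untouched, so the filter is
#' idempotent.
#'
#' @param em An [expr_matrix()].
#' @param min_genes Detected-gene threshold (strict `>`).
#' @param umi_min,umi_max Inclusive total-UMI bounds.
#' @param mito_max Mitochondrial fraction bound (strict `<`).
#' @param hb_max Haemoglobin fraction bound (strict `<`).
#' @return The filtered `expr_matrix`. The attribute `"qc_summary"`
#'   tabulates, per criterion, how many cells failed it, plus the number
#'   retained and removed overall.
#' @export
qc_filter <- function(em, min_genes = 500, umi_min = 500, umi_max = 10000,
                      mito_max = 0.20, hb_max = 0.01) {
  stopifnot(inherits(em, "expr_matrix"))
  stopifnot(mito_max >= 0, mito_max <= 1, hb_max >= 0, hb_max <= 1)
  meta <- em$cell_meta
  pass_genes <- meta$n_genes_detected > min_genes
  pass_umi <- meta$total_umi >= umi_min & meta$total_umi <= umi_max
  pass_mito <- meta$mito_fraction < mito_max
  pass_hb <- meta$hb_fraction < hb_max
  keep <- pass_genes & pass_umi & pass_mito & pass_hb
  if (!any(keep)) warning("qc_filter removed all cells", call. = FALSE)
  out <- subset_cells(em, keep)
  attr(out, "qc_summary") <- data.frame(
    criterion = c("min_genes", "umi_range", "mito_max", "hb_max", "retained", "removed"),
    n = c(sum(!pass_genes), sum(!pass_umi), sum(!pass_mito), sum(!pass_hb),
          sum(keep), sum(!keep)))
  out
}

#' Log2 counts-per-10k normalization
#'
#' `x_cg = log2(1 + 1e4 * count_cg / total_umi_c)`. Zeros map to zero so
#' sparsity is preserved; within a cell the transform is strictly
#' monotone in the raw counts.
#'
#' @param em An [expr_matrix()].
#' @param scale_factor Pseudo-library size (default 1e4).
#' @return A sparse cell x gene `dgCMatrix` of normalized values.
#' @export
normalize_log_cpm <- function(em, scale_factor = 1e4) {
  stopifnot(inherits(em, "expr_matrix"))
  tot <- em$cell_meta$total_umi
  if (any(tot == 0))
    stop("cells with zero total counts present; run qc_filter first", call. = FALSE)
  x <- em$counts
  # column-compressed storage: the row of nonzero j is x@i[j] + 1
  x@x <- log2(1 + scale_factor * x@x / tot[x@i + 1L])
  x
}

#' Drop samples with too few cells
#'
#' Excludes samples contributing fewer than `min_cells` cells (strict
#' "fewer than", so a sample with exactly `min_cells` is retained).
#'
#' @param em An [expr_matrix()].
#' @param min_cells Minimum cells per retained sample.
#' @return The filtered `expr_matrix`; attribute `"samples_dropped"`
#'   lists the excluded sample ids.
#' @export
filter_samples_min_cells <- function(em, min_cells = 100) {
  stopifnot(inherits(em, "expr_matrix"))
  tab <- table(em$cell_meta$sample_id)
  drop <- names(tab)[tab < min_cells]
  if (length(drop) == length(tab))
    warning("all samples have fewer than ", min_cells, " cells", call. = FALSE)
  out <- subset_cells(em, !(em$cell_meta$sample_id %in% drop))
  attr(out, "samples_dropped") <- drop
  out
}
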