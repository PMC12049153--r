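#' Cell-by-gene expression matrix with per-cell metadata
#'
#' The central container of the package: a sparse cell x gene count matrix
#' together with per-cell metadata (sample of origin, optional compartment
#' label, QC covariates) and the ordered gene identifiers. QC covariates
#' (`total_umi`, `n_genes_detected`, `mito_fraction`, `hb_fraction`) are
#' recomputed from the counts at construction so they can never drift out
#' of sync with the matrix.
#'
#' @param counts A cell x gene matrix of non-negative integer counts
#'   (dense or any `Matrix` sparse class; stored as `dgCMatrix`).
#' @param cell_meta A data.frame with one row per cell; must contain a
#'   `cell_id` column (unique) and a `sample_id` column. A `compartment`
#'   column, if present, is carried along.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column of `counts`.
#' @param annot Optional [gene_annotation()] table used to flag
#'   mitochondrial and haemoglobin genes when computing QC fractions.
#'   Without it, genes named with an `MT-` prefix count as mitochondrial
#'   and `HBA`/`HBB` prefixes as haemoglobin.
#' @return An object of class `expr_matrix`: a list with elements
#'   `counts`, `cell_meta`, `gene_ids`.
#' @export
expr_matrix <- function(counts, cell_meta, gene_ids, annot = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  vals <- counts@x
  if (length(vals) && (any(vals < 0) || any(vals != round(vals))))
    stop("counts must be non-negative integers", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers", call. = FALSE)
  if (!is.data.frame(cell_meta) || is.null(cell_meta$cell_id))
    stop("cell_meta must be a data.frame with a cell_id column", call. = FALSE)
  if (anyDuplicated(cell_meta$cell_id)) stop("duplicate cell identifiers", call. = FALSE)
  if (nrow(cell_meta) != nrow(counts) || length(gene_ids) != ncol(counts))
    stop("dimension mismatch between counts, cell_meta and gene_ids", call. = FALSE)
  rownames(counts) <- cell_meta$cell_id
  colnames(counts) <- gene_ids

  mito <- mito_hb_flags(gene_ids, annot)
  tot <- Matrix::rowSums(counts)
  cell_meta$total_umi <- as.numeric(tot)
  cell_meta$n_genes_detected <- as.numeric(Matrix::rowSums(counts > 0))
  cell_meta$mito_fraction <- safe_frac(Matrix::rowSums(counts[, mito$mito, drop = FALSE]), tot)
  cell_meta$hb_fraction <- safe_frac(Matrix::rowSums(counts[, mito$hb, drop = FALSE]), tot)
  rownames(cell_meta) <- cell_meta$cell_id

  structure(list(counts = counts, cell_meta = cell_meta, gene_ids = gene_ids),
            class = "expr_matrix")
}

safe_frac <- function(num, den) ifelse(den > 0, as.numeric(num) / as.numeric(den), 0)

mito_hb_flags <- function(gene_ids, annot = NULL) {
  if (!is.null(annot) && all(c("is_mito", "is_hb") %in% names(annot))) {
    idx <- match(gene_ids, annot$gene)
    list(mito = which(annot$is_mito[idx] %in% TRUE),
         hb = which(annot$is_hb[idx] %in% TRUE))
  } else {
    list(mito = grep("^MT-", gene_ids),
         hb = grep("^HB[AB]", gene_ids))
  }
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d cells x %d genes, %d sample(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' Subset an expression matrix by cells
#' @param em An [expr_matrix()].
#' @param keep Logical or integer index over cells.
#' @return The subset `expr_matrix`; values of retained cells are untouched.
#' @export
subset_cells <- function(em, keep) {
  stopifnot(inherits(em, "expr_matrix"))
  out <- em
  out$counts <- em$counts[keep, , drop = FALSE]
  out$cell_meta <- em$cell_meta[keep, , drop = FALSE]
  out
}

#' Synthetic-genome / real-genome gene annotation table
#'
#' @param gene Character gene identifiers.
#' @param chrom Chromosome of each gene.
#' @param arm Chromosome arm label (`"p"`/`"q"`).
#' @param start,end Half-open 0-based genomic coordinates.
#' @param is_mito,is_hb Logical flags for the mitochondrial and
#'   haemoglobin gene sets used by QC.
#' @return A data.frame with a `genomic_order` column: the 0-based rank of
#'   each gene under the (chromosome, start) sort.
#' @export
gene_annotation <- function(gene, chrom, arm, start, end,
                            is_mito = FALSE, is_hb = FALSE) {
  df <- data.frame(gene = gene, chrom = chrom, arm = arm,
                   start = start, end = end,
                   is_mito = rep_len(is_mito, length(gene)),
                   is_hb = rep_len(is_hb, length(gene)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene)) stop("duplicate genes in annotation", call. = FALSE)
  ord <- order(chrom_rank(df$chrom), df$start)
  df$genomic_order <- integer(nrow(df))
  df$genomic_order[ord] <- seq_len(nrow(df)) - 1L
  df
}

# numeric-aware chromosome ordering ("1" < "2" < ... < "22" < "X" < "Y")
chrom_rank <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(ch))
  num[is.na(num)] <- 100 + as.numeric(factor(ch[is.na(num)]))
  num
}
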