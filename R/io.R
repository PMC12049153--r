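#' Read a sparse count matrix from Matrix Market plus TSV metadata
#'
#' Expects the on-disk layout written by [write_counts()]: a Matrix Market
#' file with cells as rows and genes as columns, a `cells.tsv` with one
#' metadata row per cell, and a BED-like `genes.tsv`
#' (gene, chrom, arm, start, end, index, is_mito, is_hb).
#'
#' @param mtx_path Path to the `.mtx` file.
#' @param cells_tsv Path to the per-cell metadata TSV.
#' @param genes_tsv Path to the gene table TSV.
#' @return A list with elements `em` ([expr_matrix()]) and `annot`
#'   (gene annotation data.frame).
#' @export
read_counts <- function(mtx_path, cells_tsv, genes_tsv) {
  for (p in c(mtx_path, cells_tsv, genes_tsv))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  m <- Matrix::readMM(mtx_path)
  cells <- read.delim(cells_tsv, stringsAsFactors = FALSE)
  genes <- read.delim(genes_tsv, stringsAsFactors = FALSE)
  if (nrow(m) != nrow(cells) || ncol(m) != nrow(genes))
    stop("dimension mismatch between matrix and metadata tables", call. = FALSE)
  if (length(m@x) && any(m@x != round(m@x)))
    stop("matrix contains non-integer entries", call. = FALSE)
  annot <- if (all(c("chrom", "start") %in% names(genes))) {
    gene_annotation(genes$gene, genes$chrom, genes$arm, genes$start, genes$end,
                    is_mito = genes$is_mito %||% FALSE,
                    is_hb = genes$is_hb %||% FALSE)
  } else NULL
  em <- expr_matrix(m, cells, genes$gene, annot = annot)
  list(em = em, annot = annot)
}

#' Write a count matrix as Matrix Market plus TSV metadata
#'
#' @param em An [expr_matrix()].
#' @param dir Output directory (created if needed).
#' @param annot Optional gene annotation; genes without one get a
#'   minimal table with identifiers only.
#' @return Invisibly, the paths written (`mtx`, `cells`, `genes`).
#' @export
write_counts <- function(em, dir, annot = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(mtx = file.path(dir, "counts.mtx"),
                cells = file.path(dir, "cells.tsv"),
                genes = file.path(dir, "genes.tsv"))
  Matrix::writeMM(em$counts, paths$mtx)
  write.table(em$cell_meta, paths$cells, sep = "\t", quote = FALSE, row.names = FALSE)
  genes <- if (is.null(annot)) data.frame(gene = em$gene_ids) else
    annot[match(em$gene_ids, annot$gene),
          c("gene", "chrom", "arm", "start", "end", "genomic_order", "is_mito", "is_hb")]
  names(genes)[names(genes) == "genomic_order"] <- "index"
  write.table(genes, paths$genes, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read gene sets from a GMT file
#' @param path Path to a tab-delimited GMT file (set name, description,
#'   then member genes, one set per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field per set (recycled).
#' @export
write_gmt <- function(sets, path, description = "scMPKit") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a ligand-receptor pair table
#'
#' Tab-separated with columns `pair_id`, `ligand_subunits`,
#' `receptor_subunits`; subunits comma-joined for multi-subunit complexes.
#'
#' @param path Path to the TSV.
#' @return An `lr_database` (see [lr_database()]).
#' @export
read_lr_db <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lr_database(df$pair_id,
              strsplit(df$ligand_subunits, ",", fixed = TRUE),
              strsplit(df$receptor_subunits, ",", fixed = TRUE))
}

#' Write a ligand-receptor pair table
#' @param db An [lr_database()].
#' @param path Output path.
#' @export
write_lr_db <- function(db, path) {
  df <- data.frame(pair_id = db$pair_id,
                   ligand_subunits = vapply(db$ligand, paste, "", collapse = ","),
                   receptor_subunits = vapply(db$receptor, paste, "", collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
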