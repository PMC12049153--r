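#' Smooth per-cell expression residuals along the genome
#'
#' A simplified expression-based copy-number estimator: per gene the
#' residual of each cell's normalized expression against the mean of a
#' reference cell population is clipped, then averaged over a uniform
#' moving window of genome-ordered genes that never crosses a chromosome
#' boundary (the window shrinks near chromosome ends), and finally each
#' cell's track is median-centred. Reference cells should be populations
#' presumed diploid (e.g. immune and stromal cells).
#'
#' @param expr_log Normalized (log-scale) cell x gene matrix, e.g. from
#'   [normalize_log_cpm()].
#' @param annot Gene annotation with `chrom` and `genomic_order`.
#' @param reference_ids Character ids (rownames of `expr_log`) of the
#'   reference cells; must be non-empty.
#' @param window Odd window width in genes (number of genes averaged).
#' @param clip Residuals are clipped to `[-clip, clip]` before smoothing.
#' @return A `cnv_profile`: list with `smoothed` (cells x genes in genome
#'   order), `genes`, `reference_ids`; scores/calls are added by
#'   [cnv_score()], [cnv_correlation()] and [classify_malignant()].
#' @export
smooth_cnv_profile <- function(expr_log, annot, reference_ids,
                               window = 101, clip = 3.0) {
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (length(reference_ids) == 0) stop("empty reference set", call. = FALSE)
  if (!all(reference_ids %in% rownames(expr_log)))
    stop("reference_ids missing from expr_log", call. = FALSE)
  ord <- order(annot$genomic_order)
  genes <- annot$gene[ord]
  if (!all(genes %in% colnames(expr_log)))
    stop("annotation genes missing from expr_log", call. = FALSE)
  x <- as.matrix(expr_log[, genes, drop = FALSE])
  chrom <- annot$chrom[ord]
  if (max(table(chrom)) < window)
    stop("no chromosome holds a full smoothing window; reduce `window`",
         call. = FALSE)

  ref_mean <- colMeans(x[reference_ids, , drop = FALSE])
  r <- sweep(x, 2, ref_mean)
  r[r > clip] <- clip
  r[r < -clip] <- -clip

  sm <- as.matrix(r %*% smoothing_operator(chrom, window))
  sm <- sm - apply(sm, 1, median)
  colnames(sm) <- genes
  structure(list(smoothed = sm, genes = genes, chrom = chrom,
                 reference_ids = reference_ids),
            class = "cnv_profile")
}

# sparse gene x gene averaging operator: column j averages the window of
# genes centred on j, truncated at its chromosome's ends
smoothing_operator <- function(chrom, window) {
  h <- (window - 1) / 2
  blocks <- split(seq_along(chrom), factor(chrom, levels = unique(chrom)))
  trip <- lapply(blocks, function(idx) {
    n <- length(idx)
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    j <- rep.int(seq_len(n), hi - lo + 1)
    i <- unlist(lapply(seq_len(n), function(k) lo[k]:hi[k]), use.names = FALSE)
    cbind(i = idx[i], j = idx[j], w = 1 / (hi - lo + 1)[j])
  })
  trip <- do.call(rbind, trip)
  Matrix::sparseMatrix(i = trip[, "i"], j = trip[, "j"], x = trip[, "w"],
                       dims = rep(length(chrom), 2))
}

#' Suppress sub-threshold noise in a smoothed CNV profile
#'
#' Sets smoothed values whose magnitude is below `sd_mult` reference
#' standard deviations (computed per gene over the reference cells) to
#' zero, so that per-cell scores reflect confident dosage deviations
#' rather than each cell's sampling-noise floor. Without this step the
#' score threshold of [classify_malignant()] tracks the reference noise
#' floor and systematically misses well-measured (deep) aberrant cells
#' whose noise floor is lower than the reference mean.
#'
#' @param profile A `cnv_profile` whose rows include the reference cells.
#' @param sd_mult Positive multiplier of the per-gene reference SD.
#' @return The profile with thresholded `smoothed` values.
#' @export
denoise_cnv_profile <- function(profile, sd_mult = 2.0) {
  stopifnot(inherits(profile, "cnv_profile"), sd_mult > 0)
  sm <- profile$smoothed
  if (!all(profile$reference_ids %in% rownames(sm)))
    stop("reference cells missing from the profile", call. = FALSE)
  gene_sd <- apply(sm[profile$reference_ids, , drop = FALSE], 2, sd)
  cut <- matrix(sd_mult * gene_sd, nrow(sm), ncol(sm), byrow = TRUE)
  sm[abs(sm) < cut] <- 0
  profile$smoothed <- sm
  profile$denoise_sd <- sd_mult
  profile
}

#' Per-cell CNV score
#'
#' Mean of squared smoothed log-dosage values; zero iff the track is flat.
#'
#' @param profile A `cnv_profile`.
#' @return Named numeric vector, one non-negative score per cell.
#' @export
cnv_score <- function(profile) {
  stopifnot(inherits(profile, "cnv_profile"))
  rowMeans(profile$smoothed ^ 2)
}

#' Per-cell CNV correlation with the top-score consensus track
#'
#' Pearson correlation of each cell's smoothed track with the mean track
#' of the top `top_fraction` of cells by CNV score. Cells with a constant
#' track get correlation 0 (flagged via attribute `"constant_cells"`).
#'
#' @param profile A `cnv_profile`.
#' @param top_fraction Fraction of highest-scoring cells defining the
#'   consensus aberrant track.
#' @return Named numeric vector in `[-1, 1]`.
#' @export
cnv_correlation <- function(profile, top_fraction = 0.05) {
  stopifnot(inherits(profile, "cnv_profile"))
  sm <- profile$smoothed
  if (nrow(sm) < 20) stop("need at least 20 cells", call. = FALSE)
  score <- cnv_score(profile)
  n_top <- max(1L, ceiling(top_fraction * nrow(sm)))
  top <- order(score, decreasing = TRUE)[seq_len(n_top)]
  consensus <- colMeans(sm[top, , drop = FALSE])
  sds <- apply(sm, 1, sd)
  const <- sds == 0 | sd(consensus) == 0
  cc <- rep(0, nrow(sm))
  if (any(!const)) cc[!const] <- as.numeric(cor(t(sm[!const, , drop = FALSE]), consensus))
  names(cc) <- rownames(sm)
  attr(cc, "constant_cells") <- rownames(sm)[const & sds == 0]
  cc
}

#' Call malignant cells from CNV score and correlation
#'
#' A cell is called malignant iff its CNV score exceeds the reference
#' mean by `score_k` reference standard deviations AND its CNV
#' correlation exceeds `corr_min`. If the reference scores have zero
#' variance the score gate falls back to the 95th percentile of the
#' reference scores. Thresholds are reported in the result so runs are
#' auditable.
#'
#' @param profile A `cnv_profile` (reference cells must be rows of it).
#' @param score_k Reference-SD multiplier for the score gate.
#' @param corr_min Minimum CNV correlation.
#' @param top_fraction Passed to [cnv_correlation()].
#' @return List with `malignant_call` (named logical), `cnv_score`,
#'   `cnv_correlation`, and `thresholds`.
#' @export
classify_malignant <- function(profile, score_k = 2.0, corr_min = 0.3,
                               top_fraction = 0.05) {
  stopifnot(inherits(profile, "cnv_profile"))
  score <- cnv_score(profile)
  corr <- cnv_correlation(profile, top_fraction = top_fraction)
  ref <- profile$reference_ids
  ref_scores <- score[ref]
  if (sd(ref_scores) > 0) {
    score_thr <- mean(ref_scores) + score_k * sd(ref_scores)
  } else {
    score_thr <- quantile(ref_scores, 0.95, names = FALSE)
  }
  call <- score > score_thr & corr > corr_min
  list(malignant_call = call, cnv_score = score, cnv_correlation = corr,
       thresholds = c(score = score_thr, corr = corr_min))
}
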