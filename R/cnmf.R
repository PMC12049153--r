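#' Configuration for per-sample consensus NMF
#'
#' @param k_range Integer ranks to scan (default 4:10).
#' @param n_restarts Random restarts pooled by [consensus_factorize()].
#' @param n_restarts_scan Restarts used per rank during the
#'   [select_k()] scan; stability estimation needs fewer restarts than
#'   the final consensus.
#' @param max_iter Maximum multiplicative-update iterations per restart.
#' @param tol Relative change in squared Frobenius error at which a
#'   restart stops early.
#' @param outlier_filter_quantile Pooled components whose mean distance
#'   to their `k - 1` nearest neighbours exceeds this quantile of all
#'   such distances are dropped before clustering.
#' @param hvg_n Number of highly variable genes the factorization is run
#'   on (selected by log-CPM variance); `Inf` keeps all genes.
#' @param seed Seed from which all restart seeds are derived.
#' @return A validated list of class `nmf_config`.
#' @export
nmf_config <- function(k_range = 4:10, n_restarts = 20, n_restarts_scan = 10,
                       max_iter = 500, tol = 1e-5,
                       outlier_filter_quantile = 0.9, hvg_n = 500, seed = 1L) {
  if (length(k_range) < 1 || any(k_range < 2))
    stop("k_range must contain ranks >= 2", call. = FALSE)
  if (n_restarts < 3) stop("n_restarts must be >= 3", call. = FALSE)
  stopifnot(tol > 0, max_iter >= 1,
            outlier_filter_quantile >= 0, outlier_filter_quantile <= 1)
  structure(list(k_range = sort(unique(as.integer(k_range))),
                 n_restarts = as.integer(n_restarts),
                 n_restarts_scan = as.integer(max(3, n_restarts_scan)),
                 max_iter = as.integer(max_iter), tol = tol,
                 outlier_filter_quantile = outlier_filter_quantile,
                 hvg_n = hvg_n, seed = as.integer(seed)),
            class = "nmf_config")
}

#' Prepare a normalized matrix for NMF
#'
#' Selects the `hvg_n` most variable genes of the log-normalized matrix,
#' z-scores each gene and sets negative values to zero, yielding the
#' non-negative variance-scaled input the factorization expects.
#' Zero-variance genes are dropped.
#'
#' @param expr_log Normalized cell x gene matrix (cells of one sample).
#' @param hvg_n Number of highly variable genes to keep.
#' @return Dense non-negative cell x gene matrix.
#' @export
nmf_preprocess <- function(expr_log, hvg_n = 500) {
  x <- as.matrix(expr_log)
  v <- apply(x, 2, var)
  keep <- v > 0
  if (is.finite(hvg_n) && sum(keep) > hvg_n)
    keep <- keep & rank(-v, ties.method = "first") <= hvg_n
  x <- x[, keep, drop = FALSE]
  x <- scale(x)
  x[x < 0] <- 0
  x[, , drop = FALSE]
}

#' Single NMF factorization by multiplicative updates
#'
#' Minimizes the squared Frobenius error of `X ~ W H` under
#' non-negativity; the error sequence is non-increasing and iteration
#' stops once its relative change drops below `tol`. `H` rows are
#' rescaled to unit L1 with the compensating scale moved into `W`.
#' All-zero rows or columns of `X` are dropped for the updates and
#' re-inserted as zeros.
#'
#' @param X Non-negative cell x gene matrix.
#' @param k Rank (>= 1).
#' @param seed Seed for the random uniform initialization.
#' @param max_iter,tol Stopping rule.
#' @return List with `W` (cell x k), `H` (k x gene, rows unit-L1),
#'   `err` (per-iteration squared error), `iterations`.
#' @export
nmf_factorize <- function(X, k, seed = 1L, max_iter = 500, tol = 1e-5) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative", call. = FALSE)
  rz <- rowSums(X) > 0
  cz <- colSums(X) > 0
  Xa <- X[rz, cz, drop = FALSE]
  if (any(!rz) || any(!cz))
    message(sprintf("nmf_factorize: dropped %d all-zero rows and %d all-zero columns",
                    sum(!rz), sum(!cz)))
  fit <- withr::with_seed(seed, {
    scale0 <- sqrt(mean(Xa) / k)
    W0 <- matrix(runif(nrow(Xa) * k, 0.1, 1), ncol = k) * scale0
    H0 <- matrix(runif(k * ncol(Xa), 0.1, 1), nrow = k) * scale0
    nmf_mu_cpp(Xa, W0, H0, as.integer(max_iter), tol)
  })
  W <- matrix(0, nrow(X), k, dimnames = list(rownames(X), NULL))
  H <- matrix(0, k, ncol(X), dimnames = list(NULL, colnames(X)))
  W[rz, ] <- fit$W
  H[, cz] <- fit$H
  s <- rowSums(H)
  s[s == 0] <- 1
  H <- H / s
  W <- sweep(W, 2, s, "*")
  list(W = W, H = H, err = fit$err, iterations = fit$iterations)
}

#' Consensus NMF at a fixed rank
#'
#' Runs `n_restarts` factorizations from distinct derived seeds, pools
#' the unit-L1 spectra rows, drops outlier components by
#' nearest-neighbour distance, clusters the survivors into `k` groups by
#' k-means on a Pearson-correlation embedding, takes the element-wise
#' median of each cluster as the consensus spectrum, and refits the cell
#' usages by non-negative least squares. Stability is the mean
#' silhouette width of the component clustering under `1 - Pearson`
#' distance; a rank where some cluster has fewer than 2 components is
#' flagged unstable with stability -1.
#'
#' @param X Non-negative cell x gene matrix (from [nmf_preprocess()]).
#' @param k Rank.
#' @param config An [nmf_config()].
#' @param n_restarts Override of `config$n_restarts`.
#' @return List of class `program_set`: `spectra` (k x gene, unit-L1
#'   rows), `usages` (cell x k), `stability`, `reconstruction_error`
#'   (relative, refit), `best_restart_error`, `k`.
#' @export
consensus_factorize <- function(X, k, config = nmf_config(),
                                n_restarts = config$n_restarts) {
  X <- as.matrix(X)
  seeds <- vapply(seq_len(n_restarts),
                  function(i) derive_seed(config$seed, paste0("restart", i, "k", k)),
                  integer(1))
  fits <- lapply(seeds, function(s)
    nmf_factorize(X, k, seed = s, max_iter = config$max_iter, tol = config$tol))
  pooled <- do.call(rbind, lapply(fits, `[[`, "H"))
  best_err <- min(vapply(fits, function(f) min(f$err), numeric(1)))

  ## outlier component filter: mean 1-Pearson distance to k-1 nearest peers
  d <- as.matrix(pearson_dist(pooled))
  diag(d) <- Inf
  nn <- max(1L, k - 1L)
  mean_nn <- apply(d, 1, function(row) mean(sort(row)[seq_len(nn)]))
  keep <- mean_nn <= quantile(mean_nn, config$outlier_filter_quantile)
  comp <- pooled[keep, , drop = FALSE]

  ## k-means in an embedding where squared Euclidean ~ 1 - Pearson
  emb <- t(scale(t(comp)))
  emb[is.na(emb)] <- 0
  emb <- emb / sqrt(ncol(emb) - 1)
  km <- withr::with_seed(derive_seed(config$seed, paste0("kmeans", k)),
                         kmeans(emb, centers = k, nstart = 10, iter.max = 50))
  cl <- km$cluster

  spectra <- do.call(rbind, lapply(seq_len(k), function(g) {
    apply(comp[cl == g, , drop = FALSE], 2, median)
  }))
  rs <- rowSums(spectra)
  rs[rs == 0] <- 1
  spectra <- spectra / rs
  colnames(spectra) <- colnames(X)
  rownames(spectra) <- sprintf("p%d", seq_len(k))

  usages <- t(nnls_cpp(t(spectra), t(X)))
  dimnames(usages) <- list(rownames(X), rownames(spectra))
  resid <- X - usages %*% spectra
  recon_err <- sum(resid ^ 2)

  stability <- if (min(table(factor(cl, levels = seq_len(k)))) < 2) {
    -1
  } else {
    sil <- cluster::silhouette(cl, stats::as.dist(
      {dd <- d[keep, keep, drop = FALSE]; dd[!is.finite(dd)] <- 0; dd}))
    mean(sil[, "sil_width"])
  }

  structure(list(spectra = spectra, usages = usages, k = k,
                 stability = stability,
                 reconstruction_error = recon_err,
                 best_restart_error = best_err,
                 n_components_pooled = nrow(pooled),
                 n_components_kept = nrow(comp)),
            class = "program_set")
}

#' Scan ranks and choose the optimal K
#'
#' For each rank in `config$k_range` a consensus factorization (with
#' `config$n_restarts_scan` restarts) yields a stability (mean consensus
#' silhouette) and a refit reconstruction error. The chosen rank is the
#' one maximizing stability (ties broken toward the larger rank): the
#' residual error of noisy count data declines almost linearly in k and
#' carries little rank information, while component stability peaks
#' sharply at the rank of the underlying program structure. When no rank
#' reaches `stability_floor` the decomposition is considered unstable at
#' every rank and the range minimum is returned as a flagged fallback.
#'
#' @param X Non-negative cell x gene matrix.
#' @param config An [nmf_config()].
#' @param stability_floor Minimum stability for a rank to be trusted.
#' @return List with `k` (chosen), `fallback` (logical), `diagnostics`
#'   (per-rank table) and `fits` (per-rank `program_set`s, keyed by rank).
#' @export
select_k <- function(X, config = nmf_config(), stability_floor = 0.5) {
  fits <- lapply(config$k_range, function(k)
    consensus_factorize(X, k, config, n_restarts = config$n_restarts_scan))
  names(fits) <- as.character(config$k_range)
  stab <- vapply(fits, `[[`, numeric(1), "stability")
  err <- vapply(fits, `[[`, numeric(1), "reconstruction_error")
  fallback <- max(stab) < stability_floor
  k <- if (fallback) min(config$k_range) else
    max(config$k_range[stab == max(stab)])
  diagnostics <- data.frame(k = config$k_range, stability = stab,
                            reconstruction_error = err, row.names = NULL)
  list(k = k, fallback = fallback, diagnostics = diagnostics, fits = fits)
}

#' Top-weight genes of a spectra row
#'
#' @param spectra_row Named numeric gene weights.
#' @param n Number of genes to return.
#' @return Character vector of the `n` largest-weight genes in
#'   descending weight order; ties broken by gene identifier.
#' @export
top_genes <- function(spectra_row, n = 50) {
  if (n > length(spectra_row)) stop("n exceeds gene count", call. = FALSE)
  ord <- order(-spectra_row, names(spectra_row))
  names(spectra_row)[ord][seq_len(n)]
}
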