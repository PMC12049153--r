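#' Signature-matrix NNLS bulk deconvolution
#'
#' For each bulk sample solves `min ||S x - b||^2` subject to `x >= 0`
#' over the signature genes (Lawson-Hanson active set) and reports the
#' normalized proportions `x / sum(x)`. A sample with an all-zero
#' solution gets uniform proportions and is flagged.
#'
#' @param bulk Sample x gene matrix.
#' @param signature_matrix Gene x state matrix of reference profiles
#'   (>= 2 states); genes must appear in `bulk`.
#' @param warn_rank Warn when the signature matrix is rank deficient.
#' @return List of class `deconvolution_result`: `proportions` (sample x
#'   state rows on the simplex), `residual_norm`, `signature_matrix`,
#'   `flagged` (ids of all-zero solutions).
#' @export
nnls_deconvolve <- function(bulk, signature_matrix, warn_rank = TRUE) {
  S <- as.matrix(signature_matrix)
  if (ncol(S) < 2) stop("need at least 2 states", call. = FALSE)
  genes <- rownames(S)
  if (is.null(genes) || !all(genes %in% colnames(bulk)))
    stop("signature genes missing from bulk matrix", call. = FALSE)
  B <- t(as.matrix(bulk)[, genes, drop = FALSE])
  if (warn_rank && qr(S)$rank < ncol(S))
    warning("signature matrix is rank deficient; proportions may be unstable",
            call. = FALSE)
  X <- nnls_cpp(S, B)
  tot <- colSums(X)
  flagged <- colnames(bulk)[FALSE]
  prop <- t(X)
  zero <- tot == 0
  prop[!zero, ] <- prop[!zero, , drop = FALSE] / tot[!zero]
  if (any(zero)) {
    prop[zero, ] <- 1 / ncol(S)
    flagged <- rownames(bulk)[zero]
  }
  dimnames(prop) <- list(rownames(bulk), colnames(S))
  resid <- sqrt(colSums((S %*% X - B) ^ 2))
  structure(list(proportions = prop,
                 residual_norm = setNames(resid, rownames(bulk)),
                 signature_matrix = S, flagged = flagged),
            class = "deconvolution_result")
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho is the Pearson correlation of average-tie ranks. For `n <= 9`
#' with untied data the two-sided p-value comes from full enumeration of
#' the `n!` rank permutations; otherwise from the t approximation
#' `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y Numeric vectors (pairs with missing values dropped).
#' @return List of class `correlation_result` with `R`, `p`, `n`,
#'   `method`; symmetric in its arguments.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input; Spearman rho undefined", call. = FALSE)
    return(structure(list(R = NA_real_, p = NA_real_, n = n,
                          method = "undefined"), class = "correlation_result"))
  }
  rx <- rank(x); ry <- rank(y)
  r <- cor(rx, ry)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (n <= 9 && !ties) {
    null_r <- spearman_null_exact(n)
    p <- mean(abs(null_r) >= abs(r) - 1e-12)
    method <- "exact enumeration"
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r ^ 2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
    method <- "t approximation"
  }
  structure(list(R = r, p = min(p, 1), n = n, method = method),
            class = "correlation_result")
}

# all n! Spearman rho values for untied samples of size n (n <= 9)
spearman_null_exact <- function(n) {
  perms <- permutations_all(n)
  base <- seq_len(n)
  d2 <- colSums((t(perms) - base) ^ 2)
  1 - 6 * d2 / (n * (n ^ 2 - 1))
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(i, matrix(rest[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' Kruskal-Wallis omnibus with gated Dunn post hoc tests
#'
#' Runs the tie-corrected Kruskal-Wallis test across groups; only when
#' the omnibus p-value is below `alpha` are all pairwise Dunn z tests
#' computed (tie-corrected pooled variance), with Benjamini-Hochberg
#' adjustment across pairs. Groups smaller than 2 are dropped with a
#' warning.
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 3 groups after dropping).
#' @param alpha Omnibus gate.
#' @return List with `H`, `df`, `p`, and `pairwise` (data frame of Dunn
#'   comparisons; empty when the gate fails).
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("dropping groups with < 2 values: ", paste(small, collapse = ", "),
            call. = FALSE)
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 3) stop("need at least 3 groups", call. = FALSE)
  kw <- kruskal.test(values, factor(groups))
  pairwise <- empty_dunn()
  if (kw$p.value < alpha) pairwise <- dunn_pairwise(values, groups)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pairwise)
}

empty_dunn <- function() {
  data.frame(group1 = character(0), group2 = character(0), z = numeric(0),
             p = numeric(0), p_adj = numeric(0))
}

dunn_pairwise <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab ^ 3 - tie_tab) / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  gs <- sort(names(mean_rank))
  combs <- utils::combn(gs, 2)
  z <- apply(combs, 2, function(gg) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[gg[1]] + 1 / n_g[gg[2]]))
    (mean_rank[gg[1]] - mean_rank[gg[2]]) / se
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = as.numeric(z),
             p = p, p_adj = p.adjust(p, "BH"), row.names = NULL)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival curves per group and the 1-df log-rank
#' chi-square via the standard observed-minus-expected tables. A group
#' without events is flagged but still tested.
#'
#' @param times Positive follow-up times.
#' @param events Logical (or 0/1) event indicators.
#' @param groups Two-level group labels.
#' @return List of class `survival_stratification`: `logrank_chi2`, `p`,
#'   `obs`, `exp`, `var` (for the first group), `km_curves` (data frame
#'   time/surv/group), `flagged_no_events`.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- factor(as.character(groups))
  if (nlevels(groups) != 2) stop("need exactly 2 groups", call. = FALSE)
  events <- as.logical(events)
  no_ev <- tapply(events, groups, sum) == 0
  if (all(no_ev)) stop("need at least one event", call. = FALSE)
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  km <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata_id <- rep(sub("^groups=", "", names(km$strata)), km$strata)
  curves <- data.frame(time = km$time, surv = km$surv, group = strata_id)
  v <- if (is.matrix(sd_fit$var)) sd_fit$var[1, 1] else sd_fit$var[1]
  structure(list(logrank_chi2 = unname(sd_fit$chisq),
                 p = pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE),
                 obs = sd_fit$obs, exp = sd_fit$exp, var = v,
                 km_curves = curves,
                 flagged_no_events = names(no_ev)[no_ev]),
            class = "survival_stratification")
}

#' Survival stratification at the maximally selected cutpoint
#'
#' Scans candidate cutpoints (midpoints between adjacent distinct scores
#' within the `[min_prop, 1 - min_prop]` score quantiles) and keeps the
#' one maximizing the absolute standardized log-rank statistic. The
#' median split is reported alongside. The p-value at the selected
#' cutpoint is NOT corrected for the maximal selection and is
#' anti-conservative; `p_flag` says so.
#'
#' @param score Numeric per-sample scores.
#' @param times,events Survival outcome.
#' @param min_prop Minimum fraction of samples on each side.
#' @return List with `cutpoint`, `z`, `groups` (high/low), `logrank`
#'   (the [km_logrank()] result at the cutpoint), `median_split`, and
#'   `p_flag`.
#' @export
optimal_cutpoint <- function(score, times, events, min_prop = 0.1) {
  n <- length(score)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  qs <- quantile(score, c(min_prop, 1 - min_prop), names = FALSE)
  u <- sort(unique(score))
  mid <- (u[-1] + u[-length(u)]) / 2
  cand <- mid[mid >= qs[1] & mid <= qs[2]]
  med_groups <- ifelse(score > median(score), "high", "low")
  median_split <- if (length(unique(med_groups)) == 2)
    km_logrank(times, events, med_groups) else NULL
  if (length(cand) < 2) {
    if (is.null(median_split))
      stop("no usable cutpoint: scores nearly constant", call. = FALSE)
    return(list(cutpoint = median(score), z = NA_real_, groups = med_groups,
                logrank = median_split, median_split = median_split,
                p_flag = "median fallback"))
  }
  zs <- vapply(cand, function(cp) {
    g <- ifelse(score > cp, "high", "low")
    sd_fit <- survival::survdiff(survival::Surv(times, as.logical(events)) ~ g)
    v <- if (is.matrix(sd_fit$var)) sd_fit$var[1, 1] else sd_fit$var[1]
    (sd_fit$obs[1] - sd_fit$exp[1]) / sqrt(v)
  }, numeric(1))
  best <- which.max(abs(zs))
  cp <- cand[best]
  groups <- ifelse(score > cp, "high", "low")
  list(cutpoint = cp, z = zs[best], groups = groups,
       logrank = km_logrank(times, events, groups),
       median_split = median_split,
       p_flag = "maximally selected; uncorrected p is anti-conservative")
}
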