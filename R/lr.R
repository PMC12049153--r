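#' Ligand-receptor pair database
#'
#' @param pair_id Unique pair identifiers.
#' @param ligand,receptor Lists of character subunit vectors (multi-
#'   subunit complexes are summarized by their limiting subunit).
#' @return List of class `lr_database`.
#' @export
lr_database <- function(pair_id, ligand, receptor) {
  if (anyDuplicated(pair_id)) stop("pair_ids must be unique", call. = FALSE)
  ligand <- lapply(ligand, as.character)
  receptor <- lapply(receptor, as.character)
  if (any(lengths(ligand) == 0) || any(lengths(receptor) == 0))
    stop("subunit lists must be non-empty", call. = FALSE)
  structure(list(pair_id = as.character(pair_id), ligand = ligand,
                 receptor = receptor), class = "lr_database")
}

#' Bundled toy ligand-receptor database
#'
#' Twenty synthetic pairs over the synthetic genome's reserved gene tail,
#' including two multi-subunit receptor complexes; intended for tests and
#' examples, not biology.
#'
#' @param n_genes Genome size the gene names refer to.
#' @return An [lr_database()].
#' @export
toy_lr_database <- function(n_genes = 2000) {
  g <- function(i) sprintf("g%04d", n_genes - i)
  ligand <- as.list(g(seq(3, 41, by = 2)))
  receptor <- as.list(g(seq(2, 40, by = 2)))
  # two complexes with a second (limiting) subunit
  receptor[[3]] <- c(receptor[[3]], g(43))
  receptor[[7]] <- c(receptor[[7]], g(45))
  lr_database(sprintf("pair%02d", 1:20), ligand, receptor)
}

#' Cluster-level ligand-receptor interaction statistic
#'
#' The ligand summary is the minimum over ligand subunits of the mean
#' normalized expression in the sender state (a complex is only as
#' available as its limiting subunit); the receptor summary is the
#' analogue in the receiver state. The statistic is the average of the
#' two summaries, set to 0 when either molecule is expressed in fewer
#' than `min_frac` of its state's cells. Genes absent from the matrix
#' count as unexpressed subunits.
#'
#' @param expr Cell x gene normalized matrix.
#' @param labels Per-cell state labels.
#' @param ligand,receptor Character subunit vectors.
#' @param sender,receiver State labels.
#' @param min_frac Minimum expressed fraction per molecule.
#' @param min_cells Minimum cells per participating state.
#' @return Non-negative scalar.
#' @export
interaction_mean <- function(expr, labels, ligand, receptor, sender, receiver,
                             min_frac = 0.1, min_cells = 10) {
  s_cells <- which(labels == sender)
  r_cells <- which(labels == receiver)
  if (length(s_cells) < min_cells || length(r_cells) < min_cells)
    stop("sender/receiver state below the cell floor", call. = FALSE)
  lig <- molecule_summary(expr, s_cells, ligand, min_frac)
  rec <- molecule_summary(expr, r_cells, receptor, min_frac)
  if (lig == 0 || rec == 0) 0 else (lig + rec) / 2
}

molecule_summary <- function(expr, cells, subunits, min_frac) {
  idx <- match(subunits, colnames(expr))
  if (anyNA(idx)) return(0) # absent subunit: complex cannot form
  sub <- expr[cells, idx, drop = FALSE]
  means <- Matrix::colMeans(sub)
  fracs <- Matrix::colMeans(sub > 0)
  if (any(fracs < min_frac)) return(0)
  min(means)
}

#' Label-permutation test for ligand-receptor interactions
#'
#' Computes the interaction statistic for every (pair, sender, receiver)
#' combination and a permutation p-value under random reshuffling of the
#' state labels; one shared shuffle per round is used across all pairs so
#' the null preserves the cross-pair correlation structure. The add-one
#' convention `p = (1 + #{perm >= obs}) / (n_perm + 1)` never returns an
#' exact zero.
#'
#' @param expr Cell x gene normalized matrix.
#' @param labels Per-cell state labels.
#' @param db An [lr_database()].
#' @param senders,receivers State labels to test (default: all states
#'   with at least `min_cells` cells; sender == receiver combinations are
#'   included).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; fixes the full permutation stream.
#' @param min_frac,min_cells Gates passed to the statistic.
#' @return Data frame with `pair_id`, `sender`, `receiver`, `mean_score`,
#'   `p`, `n_perm`.
#' @export
permutation_test <- function(expr, labels, db, senders = NULL, receivers = NULL,
                             n_perm = 1000, seed = 1L, min_frac = 0.1,
                             min_cells = 10) {
  stopifnot(inherits(db, "lr_database"))
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  labels <- as.character(labels)
  big <- names(which(table(labels) >= min_cells))
  senders <- senders %||% big
  receivers <- receivers %||% big
  stopifnot(all(c(senders, receivers) %in% big))

  # restrict to the genes the database touches; dense & small
  genes_used <- unique(unlist(c(db$ligand, db$receptor)))
  genes_used <- intersect(genes_used, colnames(expr))
  sub <- as.matrix(expr[, genes_used, drop = FALSE])

  combos <- expand.grid(pair = seq_along(db$pair_id), sender = senders,
                        receiver = receivers, stringsAsFactors = FALSE)
  stat_all <- function(lab) {
    ms <- state_summaries(sub, lab, c(senders, receivers))
    vapply(seq_len(nrow(combos)), function(i) {
      pr <- combos$pair[i]
      lig <- complex_from_summary(ms, combos$sender[i], db$ligand[[pr]],
                                  genes_used, min_frac)
      rec <- complex_from_summary(ms, combos$receiver[i], db$receptor[[pr]],
                                  genes_used, min_frac)
      if (lig == 0 || rec == 0) 0 else (lig + rec) / 2
    }, numeric(1))
  }

  obs <- stat_all(labels)
  exceed <- integer(nrow(combos))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- stat_all(sample(labels))
      exceed <- exceed + (perm >= obs)
    }
  })
  data.frame(pair_id = db$pair_id[combos$pair],
             sender = combos$sender, receiver = combos$receiver,
             mean_score = obs,
             p = (1 + exceed) / (n_perm + 1),
             n_perm = n_perm, stringsAsFactors = FALSE)
}

# per-state mean and expressed fraction of each database gene
state_summaries <- function(sub, lab, states) {
  states <- unique(states)
  out <- list()
  for (s in states) {
    cells <- lab == s
    m <- sub[cells, , drop = FALSE]
    out[[s]] <- list(mean = colMeans(m), frac = colMeans(m > 0))
  }
  out
}

complex_from_summary <- function(ms, state, subunits, genes_used, min_frac) {
  idx <- match(subunits, genes_used)
  if (anyNA(idx)) return(0)
  st <- ms[[state]]
  if (any(st$frac[idx] < min_frac)) return(0)
  min(st$mean[idx])
}

#' Select the top interacting pairs
#'
#' Keeps results with `p < p_max`, ranks by decreasing mean statistic
#' (ties broken by pair id, then sender, then receiver) and truncates to
#' the `n_top` strongest.
#'
#' @param results Output of [permutation_test()].
#' @param n_top Maximum rows returned.
#' @param p_max Strict p-value cutoff.
#' @return The ranked, truncated data frame.
#' @export
select_top_pairs <- function(results, n_top = 100, p_max = 0.01) {
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  keep <- results[results$p < p_max, , drop = FALSE]
  keep <- keep[order(-keep$mean_score, keep$pair_id, keep$sender, keep$receiver), ,
               drop = FALSE]
  head(keep, n_top)
}
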