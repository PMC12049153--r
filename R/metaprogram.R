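#' Construct a program object
#'
#' A program is one sample's consensus NMF component: its full gene
#' weight vector plus the derived top-gene set used for overlap and
#' signature rules.
#'
#' @param id Program identifier (conventionally `<sample>_p<index>`).
#' @param sample_id Sample of origin.
#' @param weights Named numeric gene weight vector (non-negative).
#' @param n_top Size of the stored top-gene set.
#' @return List of class `program`.
#' @export
program <- function(id, sample_id, weights, n_top = 50) {
  stopifnot(!is.null(names(weights)), all(weights >= 0))
  structure(list(id = id, sample_id = sample_id, weights = weights,
                 top_gene_set = top_genes(weights, min(n_top, length(weights)))),
            class = "program")
}

#' Extract programs from a consensus factorization
#'
#' @param ps A `program_set` from [consensus_factorize()].
#' @param sample_id Sample identifier used to prefix program ids.
#' @param n_top Top-gene set size.
#' @return List of [program()] objects.
#' @export
programs_from_set <- function(ps, sample_id, n_top = 50) {
  lapply(seq_len(ps$k), function(i)
    program(sprintf("%s_p%d", sample_id, i), sample_id, ps$spectra[i, ], n_top))
}

#' Keep programs that recur within their tumour
#'
#' A program is recurrent when a program from another collection of the
#' same sample (e.g. the consensus at a neighbouring rank, or another
#' restart batch) shares strictly more than `overlap_min` of its top
#' genes (overlap = shared genes / top-set size). Non-recurrent programs
#' are dropped; the programs of the first collection per sample are the
#' ones carried downstream.
#'
#' @param programs_per_sample Named list (by sample) of lists of program
#'   collections; each collection is a list of [program()]s. Samples with
#'   a single collection pass through with a warning.
#' @param overlap_min Overlap fraction that must be exceeded.
#' @return Flat list of retained programs; attribute `"recurrence"`
#'   tabulates retained/dropped per sample.
#' @export
filter_recurrent_programs <- function(programs_per_sample, overlap_min = 0.5) {
  retained <- list()
  report <- data.frame(sample_id = character(0), retained = integer(0),
                       dropped = integer(0))
  for (s in names(programs_per_sample)) {
    colls <- programs_per_sample[[s]]
    primary <- colls[[1]]
    if (length(colls) < 2) {
      warning("sample ", s, " has a single program collection; passing through",
              call. = FALSE)
      retained <- c(retained, primary)
      report <- rbind(report, data.frame(sample_id = s,
                                         retained = length(primary), dropped = 0L))
      next
    }
    others <- unlist(colls[-1], recursive = FALSE)
    keep <- vapply(primary, function(p) {
      best <- max(vapply(others, function(q)
        length(intersect(p$top_gene_set, q$top_gene_set)) / length(p$top_gene_set),
        numeric(1)))
      best > overlap_min
    }, logical(1))
    retained <- c(retained, primary[keep])
    report <- rbind(report, data.frame(sample_id = s, retained = sum(keep),
                                       dropped = sum(!keep)))
  }
  attr(retained, "recurrence") <- report
  retained
}

#' Cluster recurrent programs into meta-programs
#'
#' Programs are hierarchically clustered (average linkage) on
#' `1 - Pearson` distance between their unit-L1 weight vectors restricted
#' to the union of all top-gene sets; the tree is cut at correlation
#' `cut_corr`. A cluster becomes a meta-program only if it is shared
#' across at least `max(ceiling(share_min * n_samples), min_samples_abs)`
#' distinct samples. Members from the same sample are allowed. Output is
#' invariant to the input order of the programs.
#'
#' @param programs List of [program()]s from >= 2 samples.
#' @param share_min Fraction-of-cohort sharing requirement.
#' @param min_samples_abs Absolute minimum number of distinct samples.
#' @param cut_corr Correlation at which the dendrogram is cut.
#' @param n_signature Signature length.
#' @return List of `meta_program` objects (`mp_id` MP1..MPm, ordered by
#'   decreasing sample representation then member count), each with
#'   `member_programs`, `n_samples_represented`, `mean_weight_vector` and
#'   `signature`. Attribute `"dropped_clusters"` reports clusters that
#'   failed the sharing rule; attribute `"hclust"` carries the tree.
#' @export
cluster_programs <- function(programs, share_min = 0.2, min_samples_abs = 3,
                             cut_corr = 0.3, n_signature = 50) {
  if (length(programs) < 2) stop("need at least 2 programs", call. = FALSE)
  ord0 <- order(vapply(programs, `[[`, "", "id"))
  programs <- programs[ord0] # canonical order: output independent of input order
  ids <- vapply(programs, `[[`, "", "id")
  samples <- vapply(programs, `[[`, "", "sample_id")
  n_samples <- length(unique(samples))
  min_share <- max(ceiling(share_min * n_samples), min_samples_abs)

  union_genes <- sort(unique(unlist(lapply(programs, `[[`, "top_gene_set"))))
  wmat <- t(vapply(programs, function(p) {
    w <- p$weights[union_genes]
    w[is.na(w)] <- 0
    s <- sum(w)
    if (s > 0) w / s else w
  }, numeric(length(union_genes))))
  rownames(wmat) <- ids

  hc <- hclust(pearson_dist(wmat), method = "average")
  cl <- cutree(hc, h = 1 - cut_corr)

  groups <- split(seq_along(programs), cl)
  n_rep <- vapply(groups, function(g) length(unique(samples[g])), integer(1))
  keep <- n_rep >= min_share
  kept <- groups[keep]
  if (length(kept) == 0) {
    out <- list()
    attr(out, "dropped_clusters") <- data.frame(size = lengths(groups),
                                                n_samples = n_rep)
    attr(out, "hclust") <- hc
    return(out)
  }
  ord <- order(-n_rep[keep], -lengths(kept),
               vapply(kept, function(g) min(ids[g]), ""))
  kept <- kept[ord]

  mps <- lapply(seq_along(kept), function(i) {
    g <- kept[[i]]
    mw <- average_weights(programs[g])
    structure(list(mp_id = sprintf("MP%d", i),
                   member_programs = ids[g],
                   n_samples_represented = length(unique(samples[g])),
                   mean_weight_vector = mw,
                   signature = top_genes(mw, min(n_signature, length(mw)))),
              class = "meta_program")
  })
  attr(mps, "dropped_clusters") <- data.frame(size = lengths(groups[!keep]),
                                              n_samples = n_rep[!keep])
  attr(mps, "hclust") <- hc
  mps
}

# equal-weight average of unit-L1 normalized member weight vectors over
# the union of their genes
average_weights <- function(member_programs) {
  genes <- sort(unique(unlist(lapply(member_programs, function(p) names(p$weights)))))
  acc <- setNames(numeric(length(genes)), genes)
  for (p in member_programs) {
    w <- p$weights / max(sum(p$weights), .Machine$double.xmin)
    acc[names(w)] <- acc[names(w)] + w
  }
  acc / length(member_programs)
}

#' Meta-program signature
#'
#' Averages the member programs' unit-L1 weight vectors with equal weight
#' per program and returns the `n` largest-weight genes (ties broken by
#' gene identifier).
#'
#' @param mp A `meta_program` from [cluster_programs()], or a list of
#'   [program()]s.
#' @param n Signature length.
#' @return Ordered character vector of genes.
#' @export
mp_signature <- function(mp, n = 50) {
  mw <- if (inherits(mp, "meta_program")) mp$mean_weight_vector
        else average_weights(mp)
  top_genes(mw, min(n, length(mw)))
}
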