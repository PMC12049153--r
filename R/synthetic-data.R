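#' Configuration for the synthetic multi-sample single-cell generator
#'
#' Defines the planted ground truth of a simulated cohort: shared and
#' sample-private expression programs, chromosome-arm dosage shifts in
#' malignant cells, ligand-receptor interactions confined to specific
#' compartments, and a survival effect tied to a program's bulk activity.
#' Defaults describe a desk-scale cohort of 8 samples x 300 cells x 2000
#' genes with 3 shared programs plus 1 private program per sample, graded
#' program loadings with 5-fold peak elevation, and a planted -0.6 usage
#' correlation between the first two shared programs.
#'
#' @param n_samples Number of samples.
#' @param cells_per_sample Cells per sample; a single count or a
#'   `c(min, max)` range sampled uniformly per sample.
#' @param n_genes Genes in the synthetic genome (8 chromosomes in
#'   contiguous equal blocks, two equal arms each).
#' @param n_shared_programs Programs planted in every sample's epithelial
#'   cells.
#' @param n_private_programs_per_sample Additional programs unique to each
#'   sample.
#' @param program_gene_size Genes per program. Loadings are graded: the
#'   fold elevation tapers linearly from `loading_strength` for the
#'   program's first gene down to ~1 for its last, so each program has a
#'   well-defined strongest-50 subset.
#' @param loading_strength Peak fold elevation of program genes over the
#'   baseline spectrum; 1 means no signal.
#' @param dirichlet_alpha Concentration of the per-cell Dirichlet usage
#'   over the sample's programs (scalar or one value per program).
#' @param usage_correlation Square correlation matrix over the per-sample
#'   programs (shared first, then private) imposed through a Gaussian
#'   copula on the Dirichlet gamma marginals; entries in `[-1, 1]`.
#' @param compartment_fractions Named fractions of epithelial/stromal/
#'   immune cells per sample.
#' @param libsize_log_mean,libsize_log_sd Log-normal library-size model.
#' @param nb_dispersion Shared negative-binomial dispersion (counts are
#'   drawn with `size = 1/nb_dispersion`).
#' @param malignant_fraction Fraction of epithelial cells per sample that
#'   carry the configured arm dosages.
#' @param cnv_arms Data frame with columns `arm` (e.g. `"3q"`) and
#'   `dosage` (multiplier in `{0.5, 1, 1.5, 2}`).
#' @param lr_pairs_true Data frame of planted interactions with columns
#'   `ligand`, `receptor` (gene ids), `sender`, `receiver` (compartment
#'   labels), `strength` (fold elevation of the gene in that compartment);
#'   `NULL` plants none.
#' @param survival_effect Log-hazard coefficient applied to the
#'   z-scored bulk activity of the first shared program by
#'   [generate_survival()].
#' @param seed Integer seed; fully determines the generated dataset.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 8,
                       cells_per_sample = 300,
                       n_genes = 2000,
                       n_shared_programs = 3,
                       n_private_programs_per_sample = 1,
                       program_gene_size = 100,
                       loading_strength = 5,
                       dirichlet_alpha = 0.4,
                       usage_correlation = NULL,
                       compartment_fractions = c(epithelial = 0.55,
                                                 stromal = 0.25,
                                                 immune = 0.20),
                       libsize_log_mean = log(3000),
                       libsize_log_sd = 0.3,
                       nb_dispersion = 0.3,
                       malignant_fraction = 0.85,
                       cnv_arms = data.frame(arm = c("3q", "5p"),
                                             dosage = c(1.5, 1.5)),
                       lr_pairs_true = default_lr_truth(n_genes),
                       survival_effect = -1,
                       seed = 1L) {
  assert_scalar_num(n_samples, "n_samples", 1)
  assert_scalar_num(n_genes, "n_genes", 1)
  assert_scalar_num(n_shared_programs, "n_shared_programs", 1)
  assert_scalar_num(n_private_programs_per_sample, "n_private_programs_per_sample", 0)
  assert_scalar_num(program_gene_size, "program_gene_size", 1)
  assert_scalar_num(loading_strength, "loading_strength", .Machine$double.eps)
  assert_scalar_num(nb_dispersion, "nb_dispersion", .Machine$double.eps)
  assert_scalar_num(malignant_fraction, "malignant_fraction", 0, 1)
  if (any(dirichlet_alpha <= 0)) stop("dirichlet_alpha must be strictly positive", call. = FALSE)
  if (!is.null(cnv_arms) && any(cnv_arms$dosage <= 0))
    stop("dosage multipliers must be positive", call. = FALSE)
  if (length(cells_per_sample) == 1L) cells_per_sample <- rep(cells_per_sample, 2L)
  if (any(cells_per_sample < 1)) stop("cells_per_sample must be >= 1", call. = FALSE)

  k_per_sample <- n_shared_programs + n_private_programs_per_sample
  if (is.null(usage_correlation)) {
    usage_correlation <- diag(k_per_sample)
    if (n_shared_programs >= 2)
      usage_correlation[1, 2] <- usage_correlation[2, 1] <- -0.6
  }
  if (!isSymmetric(unname(usage_correlation)) ||
      nrow(usage_correlation) != k_per_sample ||
      any(abs(usage_correlation) > 1))
    stop("usage_correlation must be a symmetric [-1,1] matrix over the per-sample programs",
         call. = FALSE)
  if (min(eigen(usage_correlation, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("usage_correlation must be positive semi-definite", call. = FALSE)
  dirichlet_alpha <- rep_len(dirichlet_alpha, k_per_sample)

  n_programs_total <- n_shared_programs + n_samples * n_private_programs_per_sample
  n_marker <- 2L * marker_genes_per_compartment()
  # reserved: the 15 QC-flag genes plus the 100-gene tail withheld for
  # ligand-receptor planting
  if (program_gene_size * n_programs_total + n_marker + 115L > n_genes)
    stop("configuration error: disjoint program/marker gene sets exceed n_genes",
         call. = FALSE)

  structure(list(n_samples = as.integer(n_samples),
                 cells_per_sample = as.integer(cells_per_sample),
                 n_genes = as.integer(n_genes),
                 n_shared_programs = as.integer(n_shared_programs),
                 n_private_programs_per_sample = as.integer(n_private_programs_per_sample),
                 program_gene_size = as.integer(program_gene_size),
                 loading_strength = loading_strength,
                 dirichlet_alpha = dirichlet_alpha,
                 usage_correlation = usage_correlation,
                 compartment_fractions = compartment_fractions,
                 libsize_log_mean = libsize_log_mean,
                 libsize_log_sd = libsize_log_sd,
                 nb_dispersion = nb_dispersion,
                 malignant_fraction = malignant_fraction,
                 cnv_arms = cnv_arms,
                 lr_pairs_true = lr_pairs_true,
                 survival_effect = survival_effect,
                 seed = as.integer(seed)),
            class = "sim_config")
}

marker_genes_per_compartment <- function() 100L

# planted interactions use the tail of the gene index, which the program /
# marker sampler never touches
default_lr_truth <- function(n_genes) {
  g <- function(i) sprintf("g%04d", n_genes - i)
  data.frame(ligand = c(g(3), g(1)), receptor = c(g(2), g(0)),
             sender = c("epithelial", "stromal"),
             receiver = c("stromal", "immune"),
             strength = c(8, 8), stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-sample single-cell dataset
#'
#' Draws counts from a negative binomial whose mean is
#' `libsize_c * sum_k usage_ck * spectra_kg * dosage_cg`: every epithelial
#' cell is a Dirichlet mixture of its sample's program spectra (each a
#' common baseline with graded elevation on that program's genes), stromal
#' and immune cells express compartment baselines with their own marker
#' genes, malignant epithelial cells additionally carry the configured
#' chromosome-arm dosage multipliers, and planted ligand/receptor genes
#' are elevated in their sender/receiver compartments.
#'
#' @param config A [sim_config()].
#' @return A list with `em` ([expr_matrix()]), `annot` (gene annotation)
#'   and `truth` — the planted ground truth: `program_gene_lists` (genes
#'   in decreasing planted weight), `spectra`, `usage_matrix` (rows on the
#'   simplex), `malignant_labels`, `arm_dosage`, `libsize`, `compartment`
#'   and the config itself.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  G <- cfg$n_genes
  genes <- sprintf("g%04d", seq_len(G))
  annot <- synthetic_genome(genes)

  ## ---- spectra -------------------------------------------------------
  baseline <- rlnorm(G, meanlog = 0, sdlog = 0.5)
  # never plant programs on QC-flag genes or on the reserved tail used for
  # ligand-receptor planting
  reserved <- unique(c(which(annot$is_mito | annot$is_hb), (G - 99L):G))
  pool <- sample(setdiff(seq_len(G), reserved))

  S <- cfg$n_shared_programs
  P <- cfg$n_private_programs_per_sample
  m <- cfg$program_gene_size
  sample_ids <- sprintf("s%02d", seq_len(cfg$n_samples))
  prog_names <- c(if (S > 0) sprintf("shared%d", seq_len(S)),
                  unlist(lapply(sample_ids, function(s)
                    if (P > 0) sprintf("%s_private%d", s, seq_len(P)))))
  n_prog <- length(prog_names)
  take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }

  program_gene_idx <- lapply(seq_len(n_prog), function(i) take(m))
  names(program_gene_idx) <- prog_names
  marker_idx <- list(stromal = take(marker_genes_per_compartment()),
                     immune = take(marker_genes_per_compartment()))

  taper <- 1 + (cfg$loading_strength - 1) * rev(seq_len(m)) / m
  all_names <- c(prog_names, "stromal_base", "immune_base")
  spectra <- matrix(rep(baseline, each = length(all_names)),
                    nrow = length(all_names), dimnames = list(all_names, genes))
  for (i in seq_len(n_prog))
    spectra[i, program_gene_idx[[i]]] <- baseline[program_gene_idx[[i]]] * taper
  for (comp in c("stromal", "immune"))
    spectra[paste0(comp, "_base"), marker_idx[[comp]]] <-
      baseline[marker_idx[[comp]]] * cfg$loading_strength
  spectra <- spectra / rowSums(spectra)

  ## ---- cells ---------------------------------------------------------
  n_cells_s <- if (cfg$cells_per_sample[1] == cfg$cells_per_sample[2])
    rep(cfg$cells_per_sample[1], cfg$n_samples) else
    sample(cfg$cells_per_sample[1]:cfg$cells_per_sample[2], cfg$n_samples, replace = TRUE)
  comp_levels <- names(cfg$compartment_fractions)

  usage <- matrix(0, sum(n_cells_s), length(all_names),
                  dimnames = list(NULL, all_names))
  cell_sample <- character(sum(n_cells_s))
  compartment <- character(sum(n_cells_s))
  malignant <- logical(sum(n_cells_s))
  chol_R <- chol(cfg$usage_correlation + diag(1e-10, nrow(cfg$usage_correlation)))

  offset <- 0L
  for (s in seq_len(cfg$n_samples)) {
    n <- n_cells_s[s]
    idx <- offset + seq_len(n)
    cell_sample[idx] <- sample_ids[s]
    comp <- sample(comp_levels, n, replace = TRUE, prob = cfg$compartment_fractions)
    compartment[idx] <- comp

    epi <- which(comp == "epithelial")
    own_progs <- c(if (S > 0) seq_len(S),
                   if (P > 0) S + (s - 1L) * P + seq_len(P))
    if (length(epi)) {
      u <- copula_dirichlet(length(epi), cfg$dirichlet_alpha, chol_R)
      usage[idx[epi], own_progs] <- u
      n_mal <- round(cfg$malignant_fraction * length(epi))
      if (n_mal > 0) malignant[idx[epi][sample(length(epi), n_mal)]] <- TRUE
    }
    usage[idx[comp == "stromal"], "stromal_base"] <- 1
    usage[idx[comp == "immune"], "immune_base"] <- 1
    offset <- offset + n
  }

  ## ---- dosage, interactions, counts ---------------------------------
  n_cells <- sum(n_cells_s)
  gene_arm <- paste0(annot$chrom, annot$arm)
  arms <- if (is.null(cfg$cnv_arms)) character(0) else cfg$cnv_arms$arm
  arm_dosage <- matrix(1, n_cells, length(arms), dimnames = list(NULL, arms))
  for (j in seq_along(arms)) arm_dosage[malignant, j] <- cfg$cnv_arms$dosage[j]

  mu <- usage %*% spectra
  if (length(arms)) {
    for (j in seq_along(arms)) {
      on_arm <- gene_arm == arms[j]
      if (!any(on_arm)) stop("cnv_arms arm not in synthetic genome: ", arms[j], call. = FALSE)
      mu[malignant, on_arm] <- mu[malignant, on_arm] * cfg$cnv_arms$dosage[j]
    }
  }
  if (!is.null(cfg$lr_pairs_true)) {
    lr <- cfg$lr_pairs_true
    for (i in seq_len(nrow(lr))) {
      lg <- match(lr$ligand[i], genes); rg <- match(lr$receptor[i], genes)
      if (is.na(lg) || is.na(rg))
        stop("lr_pairs_true names a gene outside the synthetic genome", call. = FALSE)
      mu[compartment == lr$sender[i], lg] <- mu[compartment == lr$sender[i], lg] * lr$strength[i]
      mu[compartment == lr$receiver[i], rg] <- mu[compartment == lr$receiver[i], rg] * lr$strength[i]
    }
  }
  libsize <- rlnorm(n_cells, cfg$libsize_log_mean, cfg$libsize_log_sd)
  mu <- mu * libsize
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = n_cells)

  cell_meta <- data.frame(cell_id = sprintf("%s_c%04d", cell_sample,
                                            unlist(lapply(n_cells_s, seq_len))),
                          sample_id = cell_sample,
                          compartment = compartment,
                          stringsAsFactors = FALSE)
  em <- expr_matrix(counts, cell_meta, genes, annot = annot)
  rownames(usage) <- cell_meta$cell_id
  names(libsize) <- cell_meta$cell_id

  truth <- list(program_names = prog_names,
                program_gene_lists = lapply(program_gene_idx, function(i) genes[i]),
                marker_gene_lists = lapply(marker_idx, function(i) genes[i]),
                spectra = spectra,
                usage_matrix = usage,
                malignant_labels = stats::setNames(malignant, cell_meta$cell_id),
                arm_dosage = arm_dosage,
                libsize = libsize,
                compartment = stats::setNames(compartment, cell_meta$cell_id),
                config = cfg)
  list(em = em, annot = annot, truth = truth)
}

# 8 chromosomes in contiguous equal blocks, two equal arms each, so the
# default genome (2000 genes) has ~125-gene arms and holds a full
# 101-gene smoothing window, as a real genome would;
# 10 mito + 5 hb flag genes near the genome start (never program genes)
synthetic_genome <- function(genes) {
  G <- length(genes)
  chrom <- as.character(cut(seq_len(G), 8, labels = seq_len(8)))
  start <- unlist(lapply(split(seq_len(G), factor(chrom, levels = unique(chrom))),
                         function(i) (seq_along(i) - 1L) * 1000L), use.names = FALSE)
  arm <- unlist(lapply(split(seq_len(G), factor(chrom, levels = unique(chrom))),
                       function(i) ifelse(seq_along(i) <= length(i) / 2, "p", "q")),
                use.names = FALSE)
  is_mito <- seq_len(G) %in% 3:12
  is_hb <- seq_len(G) %in% 15:19
  gene_annotation(genes, chrom, arm, start, start + 500L,
                  is_mito = is_mito, is_hb = is_hb)
}

# Gaussian copula over gamma marginals -> correlated Dirichlet usage rows
copula_dirichlet <- function(n, alpha, chol_R) {
  k <- length(alpha)
  z <- matrix(rnorm(n * k), n, k) %*% chol_R
  u <- pnorm(z)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  g <- vapply(seq_len(k), function(j) qgamma(u[, j], shape = alpha[j]), numeric(n))
  g <- matrix(g, n, k)
  g <- pmax(g, 1e-300)
  g / rowSums(g)
}

#' Generate bulk expression mixtures from state profiles
#'
#' Each bulk sample is a convex combination of per-state mean expression
#' profiles with additive Gaussian noise truncated at zero:
#' `bulk_s = sum_state prop[s, state] * profile[state, ] + noise`.
#'
#' @param state_profiles State x gene matrix of non-negative mean
#'   expression profiles (rows named by state).
#' @param n_bulk Number of bulk samples.
#' @param noise_sd Gaussian noise standard deviation on the scale of the
#'   profiles.
#' @param seed Integer seed.
#' @param proportions Optional n_bulk x state matrix of mixing weights
#'   (rows summing to 1); drawn from a flat Dirichlet when omitted.
#' @return List with `bulk` (n_bulk x gene) and `proportions`.
#' @export
generate_bulk <- function(state_profiles, n_bulk, noise_sd = 0, seed = 1L,
                          proportions = NULL) {
  if (n_bulk < 1) stop("n_bulk must be >= 1", call. = FALSE)
  if (any(state_profiles < 0)) stop("state_profiles must be non-negative", call. = FALSE)
  withr::with_seed(seed, {
    k <- nrow(state_profiles)
    if (is.null(proportions)) {
      g <- matrix(rgamma(n_bulk * k, shape = 2), n_bulk, k)
      proportions <- g / rowSums(g)
    }
    stopifnot(ncol(proportions) == k, all(abs(rowSums(proportions) - 1) < 1e-8))
    colnames(proportions) <- rownames(state_profiles)
    bulk <- proportions %*% state_profiles
    if (noise_sd > 0)
      bulk <- pmax(bulk + matrix(rnorm(length(bulk), sd = noise_sd),
                                 nrow(bulk), ncol(bulk)), 0)
    rownames(bulk) <- rownames(proportions) <- sprintf("bulk%03d", seq_len(n_bulk))
    list(bulk = bulk, proportions = proportions)
  })
}

#' Generate survival outcomes from per-sample scores
#'
#' Times are exponential with rate
#' `baseline_hazard * exp(effect * zscore(score))`; censoring is
#' independent exponential calibrated so that roughly `censor_rate` of
#' subjects are censored. A 4-level ordinal stage correlated with the
#' score is attached for stage-comparison analyses.
#'
#' @param bulk_scores Numeric per-sample scores.
#' @param effect Log-hazard coefficient per score standard deviation;
#'   negative means high score is protective.
#' @param baseline_hazard Positive baseline hazard rate.
#' @param censor_rate Target fraction censored in `[0, 1)`.
#' @param seed Integer seed.
#' @return Data frame with `sample`, `time`, `event` (logical), `stage`.
#' @export
generate_survival <- function(bulk_scores, effect, baseline_hazard = 0.1,
                              censor_rate = 0.2, seed = 1L) {
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  stopifnot(censor_rate >= 0, censor_rate < 1)
  withr::with_seed(seed, {
    n <- length(bulk_scores)
    z <- if (sd(bulk_scores) > 0) as.numeric(scale(bulk_scores)) else rep(0, n)
    t_event <- rexp(n, rate = baseline_hazard * exp(effect * z))
    if (censor_rate > 0) {
      t_cens <- rexp(n, rate = baseline_hazard * censor_rate / (1 - censor_rate))
      time <- pmin(t_event, t_cens)
      event <- t_event <= t_cens
    } else {
      time <- t_event
      event <- rep(TRUE, n)
    }
    stage_latent <- effect_sign_safe(effect) * z + rnorm(n)
    stage <- findInterval(stage_latent, c(-0.8, 0, 0.8)) + 1L
    data.frame(sample = names(bulk_scores) %||% sprintf("bulk%03d", seq_len(n)),
               time = time, event = event, stage = stage,
               stringsAsFactors = FALSE)
  })
}

effect_sign_safe <- function(effect) if (effect == 0) 1 else sign(effect)
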