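#' Assemble a full pipeline configuration
#'
#' One nested configuration drives the whole analysis: simulate (or
#' ingest) -> QC -> CNV malignancy calling -> per-sample consensus NMF ->
#' meta-programs -> per-cell scoring -> ligand-receptor permutation
#' testing -> bulk/ecosystem statistics. Every stage draws its seed from
#' the global seed via [derive_seed()], so toggling one stage never
#' shifts another's random stream.
#'
#' @param sim A [sim_config()] for the simulate stage (its seed is
#'   overridden by the derived stage seed).
#' @param qc Named list of [qc_filter()] thresholds plus
#'   `min_cells_per_sample`.
#' @param cnv Named list: `window`, `clip`, `denoise_sd` (`NULL`
#'   disables [denoise_cnv_profile()]), `score_k`, `corr_min`,
#'   `top_fraction`, `reference_compartments`.
#' @param nmf An [nmf_config()]; plus `cells_use` choosing which cells
#'   are factorized per sample (`"malignant"` or `"epithelial"`).
#' @param mp Named list: `overlap_min`, `share_min`, `min_samples_abs`,
#'   `cut_corr`, `n_signature`.
#' @param score Named list: `rank_cap`, `min_score`, `margin`.
#' @param lr Named list: `db` (an [lr_database()]; default the bundled
#'   toy database), `n_perm`, `min_frac`, `min_cells`, `n_top`, `p_max`.
#' @param ecosystem Named list: `n_bulk`, `noise_sd`, `censor_rate`,
#'   `baseline_hazard`, `n_marker`.
#' @param stages Character vector of enabled stages, in any order;
#'   dependencies are checked at run time.
#' @param seed Global integer seed.
#' @param out_dir Optional output directory for artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            qc = list(),
                            cnv = list(),
                            nmf = nmf_config(),
                            mp = list(),
                            score = list(),
                            lr = list(),
                            ecosystem = list(),
                            stages = c("simulate", "qc", "cnv", "nmf",
                                       "metaprogram", "score", "lr", "ecosystem"),
                            seed = 1L,
                            out_dir = NULL) {
  defaults <- list(
    qc = list(min_genes = 500, umi_min = 500, umi_max = 10000,
              mito_max = 0.20, hb_max = 0.01, min_cells_per_sample = 100),
    cnv = list(window = 101, clip = 3.0, denoise_sd = 2.0,
               score_k = 2.0, corr_min = 0.3,
               top_fraction = 0.05,
               reference_compartments = c("stromal", "immune")),
    mp = list(overlap_min = 0.5, share_min = 0.2, min_samples_abs = 3,
              cut_corr = 0.3, n_signature = 50),
    score = list(rank_cap = 1500, min_score = 0.2, margin = 0.0),
    lr = list(db = NULL, n_perm = 1000, min_frac = 0.1, min_cells = 10,
              n_top = 100, p_max = 0.01),
    ecosystem = list(n_bulk = 50, noise_sd = 0.1, censor_rate = 0.2,
                     baseline_hazard = 0.1, n_marker = 50))
  merge1 <- function(user, def) utils::modifyList(def, user)
  cfg <- list(sim = sim,
              qc = merge1(qc, defaults$qc),
              cnv = merge1(cnv, defaults$cnv),
              nmf = nmf,
              nmf_cells_use = "malignant",
              mp = merge1(mp, defaults$mp),
              score = merge1(score, defaults$score),
              lr = merge1(lr, defaults$lr),
              ecosystem = merge1(ecosystem, defaults$ecosystem),
              stages = stages, seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order and returns all stage
#' results plus a manifest: the complete parameter set, the derived
#' per-stage seeds, and content hashes of every result object. Two runs
#' with identical configuration (and inputs) produce identical manifests
#' bit for bit.
#'
#' @param config A [pipeline_config()].
#' @param data Optional ingest input instead of the simulate stage: a
#'   list with `em` ([expr_matrix()]) and `annot`.
#' @return List of class `pipeline_run` with elements `results` (one
#'   entry per executed stage), `report` (compact summary tables) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  need <- function(stage, from) {
    if (is.null(res[[from]]))
      stop(sprintf("stage '%s' requires the '%s' stage; enable it or supply its artifact",
                   stage, from), call. = FALSE)
  }
  res <- list()

  ## simulate / ingest --------------------------------------------------
  if (!is.null(data)) {
    res$simulate <- list(em = data$em, annot = data$annot, truth = data$truth)
  } else if ("simulate" %in% stages) {
    sim <- config$sim
    sim$seed <- derive_seed(config$seed, "simulate")
    res$simulate <- generate_dataset(sim)
  } else {
    stop("no input data: enable the 'simulate' stage or pass `data`", call. = FALSE)
  }
  annot <- res$simulate$annot

  ## qc ------------------------------------------------------------------
  if ("qc" %in% stages) {
    need("qc", "simulate")
    p <- config$qc
    em_f <- qc_filter(res$simulate$em, p$min_genes, p$umi_min, p$umi_max,
                      p$mito_max, p$hb_max)
    qc_summary <- attr(em_f, "qc_summary")
    em_f <- filter_samples_min_cells(em_f, p$min_cells_per_sample)
    res$qc <- list(em = em_f, summary = qc_summary,
                   samples_dropped = attr(em_f, "samples_dropped"),
                   norm = normalize_log_cpm(em_f))
  }

  ## cnv -----------------------------------------------------------------
  if ("cnv" %in% stages) {
    need("cnv", "qc")
    comp <- res$qc$em$cell_meta$compartment
    if (is.null(comp)) stop("CNV stage needs compartment labels on the cells",
                            call. = FALSE)
    p <- config$cnv
    ref_ids <- res$qc$em$cell_meta$cell_id[comp %in% p$reference_compartments]
    prof <- smooth_cnv_profile(res$qc$norm, annot, ref_ids,
                               window = p$window, clip = p$clip)
    if (!is.null(p$denoise_sd)) prof <- denoise_cnv_profile(prof, p$denoise_sd)
    calls <- classify_malignant(prof, score_k = p$score_k,
                                corr_min = p$corr_min,
                                top_fraction = p$top_fraction)
    res$cnv <- c(list(profile = prof), calls)
  }

  ## per-sample consensus NMF -------------------------------------------
  if ("nmf" %in% stages) {
    need("nmf", "qc")
    em_f <- res$qc$em
    comp <- em_f$cell_meta$compartment
    if (is.null(comp)) stop("NMF stage needs compartment labels to pick epithelial cells",
                            call. = FALSE)
    epi <- comp == "epithelial"
    cells_basis <- "epithelial"
    use <- if (identical(config$nmf_cells_use, "malignant")) {
      need("nmf", "cnv")
      cells_basis <- "malignant"
      epi & res$cnv$malignant_call[em_f$cell_meta$cell_id]
    } else epi
    em_nmf <- suppressWarnings(
      filter_samples_min_cells(subset_cells(em_f, use),
                               config$qc$min_cells_per_sample))
    if (nrow(em_nmf$counts) == 0 && cells_basis == "malignant") {
      # the malignancy filter can leave no sample above the cell floor on
      # low-purity data; factorizing all epithelial cells is the standard
      # fallback and is reported in the result
      warning("no sample retains enough CNV-called malignant cells; ",
              "falling back to all epithelial cells for NMF", call. = FALSE)
      cells_basis <- "epithelial_fallback"
      em_nmf <- filter_samples_min_cells(subset_cells(em_f, epi),
                                         config$qc$min_cells_per_sample)
    }
    norm_nmf <- res$qc$norm[em_nmf$cell_meta$cell_id, , drop = FALSE]

    per_sample <- list()
    for (s in unique(em_nmf$cell_meta$sample_id)) {
      rows <- em_nmf$cell_meta$sample_id == s
      nc <- config$nmf
      nc$seed <- derive_seed(config$seed, paste0("nmf_", s))
      X <- nmf_preprocess(norm_nmf[rows, , drop = FALSE], hvg_n = nc$hvg_n)
      ks <- select_k(X, nc)
      final <- consensus_factorize(X, ks$k, nc)
      alt_k <- if (ks$k < max(nc$k_range)) ks$k + 1L else ks$k - 1L
      per_sample[[s]] <- list(k = ks$k, diagnostics = ks$diagnostics,
                              final = final,
                              alt = ks$fits[[as.character(alt_k)]],
                              sample_id = s)
    }
    res$nmf <- list(per_sample = per_sample, cells = em_nmf$cell_meta$cell_id,
                    cells_basis = cells_basis)
  }

  ## meta-programs -------------------------------------------------------
  if ("metaprogram" %in% stages) {
    need("metaprogram", "nmf")
    p <- config$mp
    colls <- lapply(res$nmf$per_sample, function(ps) {
      list(programs_from_set(ps$final, ps$sample_id, p$n_signature),
           programs_from_set(ps$alt, paste0(ps$sample_id, "alt"), p$n_signature))
    })
    # the alt collection validates recurrence but keeps the primary's sample id
    for (s in names(colls))
      for (pr in seq_along(colls[[s]][[2]]))
        colls[[s]][[2]][[pr]]$sample_id <- s
    recurrent <- filter_recurrent_programs(colls, overlap_min = p$overlap_min)
    mps <- cluster_programs(recurrent, share_min = p$share_min,
                            min_samples_abs = p$min_samples_abs,
                            cut_corr = p$cut_corr, n_signature = p$n_signature)
    res$metaprogram <- list(recurrent = recurrent, mps = mps,
                            recurrence = attr(recurrent, "recurrence"),
                            signatures = setNames(
                              lapply(mps, `[[`, "signature"),
                              vapply(mps, `[[`, "", "mp_id")))
  }

  ## per-cell scoring ----------------------------------------------------
  if ("score" %in% stages) {
    need("score", "metaprogram")
    if (length(res$metaprogram$signatures) == 0) {
      res$score <- list(scores = NULL, assignment = NULL)
    } else {
      p <- config$score
      sc <- ucell_score(res$qc$norm[res$nmf$cells, , drop = FALSE],
                        res$metaprogram$signatures, rank_cap = p$rank_cap)
      res$score <- list(scores = sc,
                        assignment = assign_state(sc, p$min_score, p$margin))
    }
  }

  ## ligand-receptor -----------------------------------------------------
  if ("lr" %in% stages) {
    need("lr", "qc")
    p <- config$lr
    db <- p$db %||% toy_lr_database(ncol(res$qc$em$counts))
    labels <- res$qc$em$cell_meta$compartment
    if (is.null(labels)) stop("LR stage needs compartment labels", call. = FALSE)
    lr_res <- permutation_test(res$qc$norm, labels, db,
                               n_perm = p$n_perm,
                               seed = derive_seed(config$seed, "lr"),
                               min_frac = p$min_frac, min_cells = p$min_cells)
    res$lr <- list(results = lr_res,
                   top = select_top_pairs(lr_res, p$n_top, p$p_max))
  }

  ## ecosystem -----------------------------------------------------------
  if ("ecosystem" %in% stages) {
    need("ecosystem", "score")
    res$ecosystem <- run_ecosystem_stage(config, res)
  }

  report <- build_report(res)
  manifest <- build_manifest(config, res)
  run <- structure(list(results = res, report = report, manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(run, config, annot)
  run
}

run_ecosystem_stage <- function(config, res) {
  p <- config$ecosystem
  em <- res$qc$em
  comp <- em$cell_meta$compartment
  cpm <- t(t_cpm(em))

  ## per-state mean CPM profiles and a marker-gene signature matrix
  states <- sort(unique(comp))
  profiles <- t(vapply(states, function(s)
    colMeans(cpm[comp == s, , drop = FALSE]), numeric(ncol(cpm))))
  rownames(profiles) <- states
  sig_genes <- unique(unlist(lapply(states, function(s) {
    fc <- profiles[s, ] / (colMeans(profiles[setdiff(states, s), , drop = FALSE]) + 1e-9)
    names(sort(fc, decreasing = TRUE))[seq_len(p$n_marker)]
  })))
  sig_matrix <- t(profiles[, sig_genes, drop = FALSE])

  bulk_sim <- generate_bulk(profiles, p$n_bulk, noise_sd = p$noise_sd,
                            seed = derive_seed(config$seed, "bulk"))
  deconv <- nnls_deconvolve(bulk_sim$bulk, sig_matrix, warn_rank = FALSE)

  ## correlations: per-cell MP score layer and bulk proportion layer
  score_cor <- NULL
  sc <- res$score$scores
  if (!is.null(sc) && ncol(sc) >= 2) {
    prs <- utils::combn(colnames(sc), 2)
    score_cor <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      r <- spearman_cor(sc[, prs[1, i]], sc[, prs[2, i]])
      data.frame(var1 = prs[1, i], var2 = prs[2, i], R = r$R, p = r$p, n = r$n,
                 layer = "cell_scores")
    }))
  }
  prop_cor <- {
    prs <- utils::combn(colnames(deconv$proportions), 2)
    do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      r <- spearman_cor(deconv$proportions[, prs[1, i]],
                        deconv$proportions[, prs[2, i]])
      data.frame(var1 = prs[1, i], var2 = prs[2, i], R = r$R, p = r$p, n = r$n,
                 layer = "bulk_proportions")
    }))
  }

  ## bulk MP activity, survival and stage comparisons
  surv <- NULL; cut_res <- NULL; stage_test <- NULL
  if (length(res$metaprogram$signatures) > 0) {
    bulk_log <- log2(1 + bulk_sim$bulk)
    mp_bulk <- ssgsea_score(bulk_log, res$metaprogram$signatures)
    score1 <- mp_bulk[, 1]
    surv <- generate_survival(score1, effect = config$sim$survival_effect,
                              baseline_hazard = p$baseline_hazard,
                              censor_rate = p$censor_rate,
                              seed = derive_seed(config$seed, "survival"))
    cut_res <- optimal_cutpoint(score1, surv$time, surv$event)
    stage_test <- kruskal_dunn(deconv$proportions[, 1], surv$stage)
  }
  list(profiles = profiles, bulk = bulk_sim, deconvolution = deconv,
       correlations = rbind(score_cor, prop_cor),
       survival = surv, cutpoint = cut_res, stage_test = stage_test)
}

# linear-scale counts-per-10k (genes x cells transposed helper)
t_cpm <- function(em) {
  x <- em$counts
  x@x <- 1e4 * x@x / em$cell_meta$total_umi[x@i + 1L]
  t(as.matrix(x))
}

build_report <- function(res) {
  rep <- list()
  if (!is.null(res$qc)) rep$qc_summary <- res$qc$summary
  if (!is.null(res$cnv))
    rep$cnv <- data.frame(n_malignant = sum(res$cnv$malignant_call),
                          n_cells = length(res$cnv$malignant_call))
  if (!is.null(res$nmf))
    rep$chosen_k <- data.frame(
      sample_id = names(res$nmf$per_sample),
      k = vapply(res$nmf$per_sample, `[[`, integer(1), "k"),
      stability = vapply(res$nmf$per_sample,
                         function(p) p$final$stability, numeric(1)),
      row.names = NULL)
  if (!is.null(res$metaprogram))
    rep$meta_programs <- data.frame(
      mp_id = vapply(res$metaprogram$mps, `[[`, "", "mp_id"),
      n_members = vapply(res$metaprogram$mps,
                         function(m) length(m$member_programs), integer(1)),
      n_samples = vapply(res$metaprogram$mps, `[[`, integer(1),
                         "n_samples_represented"), row.names = NULL)
  if (!is.null(res$lr)) rep$top_lr <- utils::head(res$lr$top, 10)
  if (!is.null(res$ecosystem)) {
    rep$correlations <- res$ecosystem$correlations
    if (!is.null(res$ecosystem$cutpoint))
      rep$survival <- data.frame(
        cutpoint = res$ecosystem$cutpoint$cutpoint,
        logrank_chi2 = res$ecosystem$cutpoint$logrank$logrank_chi2,
        p_uncorrected = res$ecosystem$cutpoint$logrank$p,
        n_high = sum(res$ecosystem$cutpoint$groups == "high"),
        n_low = sum(res$ecosystem$cutpoint$groups == "low"))
    if (!is.null(res$ecosystem$stage_test))
      rep$stage_test <- data.frame(H = res$ecosystem$stage_test$H,
                                   df = res$ecosystem$stage_test$df,
                                   p = res$ecosystem$stage_test$p)
  }
  rep
}

build_manifest <- function(config, res) {
  cfg_flat <- unclass(config)
  cfg_flat$out_dir <- NULL
  hashes <- lapply(res, rlang::hash)
  list(parameters = cfg_flat,
       seed = config$seed,
       stage_seeds = setNames(
         lapply(c("simulate", "lr", "bulk", "survival"),
                function(s) derive_seed(config$seed, s)),
         c("simulate", "lr", "bulk", "survival")),
       artifact_hashes = hashes,
       config_hash = rlang::hash(cfg_flat))
}

write_pipeline_artifacts <- function(run, config, annot) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  res <- run$results
  write_counts(res$simulate$em, out("counts"), annot = annot)
  tsv <- function(df, name) write.table(df, out(name), sep = "\t",
                                        quote = FALSE, row.names = FALSE)
  if (!is.null(res$qc)) tsv(res$qc$summary, "qc_summary.tsv")
  if (!is.null(res$cnv))
    tsv(data.frame(cell_id = names(res$cnv$malignant_call),
                   cnv_score = res$cnv$cnv_score,
                   cnv_correlation = res$cnv$cnv_correlation,
                   malignant = res$cnv$malignant_call), "cnv_calls.tsv")
  if (!is.null(res$nmf))
    for (s in names(res$nmf$per_sample)) {
      ps <- res$nmf$per_sample[[s]]$final
      spectra <- as.data.frame(ps$spectra)
      spectra <- cbind(program = sprintf("%s_p%d", s, seq_len(ps$k)), spectra)
      tsv(spectra, sprintf("spectra_%s.tsv", s))
      tsv(res$nmf$per_sample[[s]]$diagnostics, sprintf("k_diagnostics_%s.tsv", s))
    }
  if (!is.null(res$metaprogram) && length(res$metaprogram$mps)) {
    tsv(run$report$meta_programs, "meta_programs.tsv")
    write_gmt(res$metaprogram$signatures, out("mp_signatures.gmt"))
  }
  if (!is.null(res$score$scores))
    tsv(cbind(cell_id = rownames(res$score$scores),
              as.data.frame(res$score$scores),
              assignment = res$score$assignment), "mp_scores.tsv")
  if (!is.null(res$lr)) tsv(res$lr$results, "lr_results.tsv")
  if (!is.null(res$ecosystem)) {
    tsv(as.data.frame(res$ecosystem$deconvolution$proportions), "bulk_proportions.tsv")
    tsv(res$ecosystem$correlations, "correlations.tsv")
    if (!is.null(res$ecosystem$survival)) tsv(res$ecosystem$survival, "survival_table.tsv")
  }
  yaml::write_yaml(list(config_hash = run$manifest$config_hash,
                        artifact_hashes = run$manifest$artifact_hashes,
                        seed = run$manifest$seed), out("manifest.yaml"))
  invisible(config$out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run with stages:", paste(names(x$results), collapse = ", "), "\n")
  if (!is.null(x$report$meta_programs)) {
    cat("meta-programs:\n")
    print(x$report$meta_programs)
  }
  invisible(x)
}
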