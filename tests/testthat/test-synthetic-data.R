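small_cfg <- function(seed = 7L, ...) {
  sim_config(n_samples = 2, cells_per_sample = 120, n_genes = 800,
             n_shared_programs = 2, n_private_programs_per_sample = 1,
             program_gene_size = 40, seed = seed, ...)
}

test_that("generate_dataset is deterministic in the seed", {
  d1 <- generate_dataset(small_cfg())
  d2 <- generate_dataset(small_cfg())
  expect_identical(as.matrix(d1$em$counts), as.matrix(d2$em$counts))
  expect_identical(d1$truth$usage_matrix, d2$truth$usage_matrix)
  d3 <- generate_dataset(small_cfg(seed = 8L))
  expect_false(identical(as.matrix(d1$em$counts), as.matrix(d3$em$counts)))
})

test_that("dataset dimensions, names and compartments are as configured", {
  d <- generate_dataset(small_cfg())
  expect_equal(dim(d$em), c(240L, 800L))
  expect_identical(d$em$gene_ids, sprintf("g%04d", 1:800))
  expect_setequal(unique(d$em$cell_meta$sample_id), c("s01", "s02"))
  comp <- table(d$em$cell_meta$compartment)
  expect_setequal(names(comp), c("epithelial", "stromal", "immune"))
  # default mix 0.55/0.25/0.20; compartments are drawn per cell, so allow
  # 3 binomial SEs around the expectation
  expect_lt(abs(as.numeric(comp["epithelial"]) / 240 - 0.55),
            3 * sqrt(0.55 * 0.45 / 240))
})

test_that("total counts track the planted library sizes (NB mean oracle)", {
  # no dosage/LR perturbations: with unit-L1 spectra rows the expected
  # total count equals the planted library size exactly
  d <- generate_dataset(small_cfg(cnv_arms = NULL, lr_pairs_true = NULL))
  ratio <- d$em$cell_meta$total_umi / d$truth$libsize
  se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * se)
})

test_that("malignant labels hit the configured fraction per sample", {
  d <- generate_dataset(small_cfg(malignant_fraction = 0.5))
  cm <- d$em$cell_meta
  mal <- d$truth$malignant_labels[cm$cell_id]
  for (s in unique(cm$sample_id)) {
    epi <- cm$sample_id == s & cm$compartment == "epithelial"
    expect_equal(sum(mal[epi]), round(0.5 * sum(epi)))
    expect_false(any(mal[cm$sample_id == s & cm$compartment != "epithelial"]))
  }
})

test_that("planted arm dosage elevates malignant counts by the multiplier", {
  d <- generate_dataset(sim_config(n_samples = 2, cells_per_sample = 300,
                                   n_genes = 1000, malignant_fraction = 0.5,
                                   cnv_arms = data.frame(arm = "3q", dosage = 1.5),
                                   seed = 9L))
  mal <- d$truth$malignant_labels
  cm <- d$em$cell_meta
  epi <- cm$compartment == "epithelial"
  arm_genes <- d$annot$gene[paste0(d$annot$chrom, d$annot$arm) == "3q"]
  x <- as.matrix(d$em$counts[, arm_genes])
  lib <- d$truth$libsize
  # depth-normalized arm totals: malignant/non-malignant epithelial ratio ~ 1.5
  arm_rate <- rowSums(x) / lib
  r <- mean(arm_rate[epi & mal[cm$cell_id]]) / mean(arm_rate[epi & !mal[cm$cell_id]])
  expect_equal(r, 1.5, tolerance = 0.1)
  # non-arm genes unaffected
  other <- setdiff(d$em$gene_ids, arm_genes)
  oth_rate <- rowSums(as.matrix(d$em$counts[, other])) / lib
  r0 <- mean(oth_rate[epi & mal[cm$cell_id]]) / mean(oth_rate[epi & !mal[cm$cell_id]])
  expect_equal(r0, 1, tolerance = 0.05)
})

test_that("usage copula plants the requested correlation sign", {
  R <- diag(3); R[1, 2] <- R[2, 1] <- -0.6
  d <- generate_dataset(sim_config(n_samples = 1, cells_per_sample = 400,
                                   n_genes = 800, n_shared_programs = 3,
                                   n_private_programs_per_sample = 0,
                                   usage_correlation = R, seed = 3L))
  u <- d$truth$usage_matrix
  epi <- names(d$truth$compartment)[d$truth$compartment == "epithelial"]
  r <- cor(u[epi, "shared1"], u[epi, "shared2"], method = "spearman")
  expect_lt(r, -0.3)
})

test_that("program gene lists are disjoint, off the reserved tail, graded", {
  d <- generate_dataset(small_cfg())
  lists <- d$truth$program_gene_lists
  all_genes <- unlist(lists)
  expect_false(anyDuplicated(all_genes) > 0)
  tail_genes <- sprintf("g%04d", 701:800)
  expect_length(intersect(all_genes, tail_genes), 0)
  # graded taper: relative elevation over baseline is non-increasing in
  # list order (stromal_base carries pure baseline on program genes)
  elev <- d$truth$spectra["shared1", lists$shared1] /
    d$truth$spectra["stromal_base", lists$shared1]
  expect_true(all(diff(elev) <= 1e-12))
  expect_gt(elev[1] / elev[length(elev)], 2) # loading_strength = 5 default
})

test_that("synthetic genome has 8 chromosomes with p/q halves and QC flags", {
  d <- generate_dataset(small_cfg())
  a <- d$annot
  expect_setequal(unique(a$chrom), as.character(1:8))
  expect_equal(as.numeric(table(a$chrom)), rep(100, 8))
  one <- a[a$chrom == "1", ]
  expect_equal(sum(one$arm == "p"), 50)
  expect_identical(which(a$is_mito), 3:12)
  expect_identical(which(a$is_hb), 15:19)
  expect_identical(sort(a$genomic_order), 0:(nrow(a) - 1L))
})

test_that("sim_config validates its arguments", {
  expect_error(sim_config(dirichlet_alpha = c(1, -1)), "alpha")
  expect_error(sim_config(cnv_arms = data.frame(arm = "3q", dosage = -1)),
               "positive")
  expect_error(sim_config(malignant_fraction = 1.5), "malignant_fraction")
  expect_error(sim_config(n_genes = 300, n_shared_programs = 10,
                          program_gene_size = 100),
               "gene")
})

test_that("generate_bulk mixes profiles exactly when noiseless", {
  prof <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3,
                 dimnames = list(c("a", "b"), c("g1", "g2", "g3")))
  pr <- matrix(c(0.25, 0.75, 0.6, 0.4), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("a", "b")))
  b <- generate_bulk(prof, n_bulk = 2, noise_sd = 0, seed = 5L, proportions = pr)
  expect_equal(unname(b$bulk), unname(pr %*% prof), tolerance = 1e-12)
  expect_equal(rowSums(b$proportions), c(1, 1), ignore_attr = TRUE)
  b2 <- generate_bulk(prof, n_bulk = 4, noise_sd = 0.1, seed = 5L)
  expect_identical(b2$bulk, generate_bulk(prof, 4, 0.1, seed = 5L)$bulk)
  expect_true(all(b2$bulk >= 0)) # truncated noise never goes negative
})

test_that("generate_survival is deterministic with sane outputs", {
  sc <- setNames(runif(30), sprintf("b%02d", 1:30))
  s1 <- generate_survival(sc, effect = -1, seed = 2L)
  s2 <- generate_survival(sc, effect = -1, seed = 2L)
  expect_identical(s1, s2)
  expect_true(all(s1$time > 0))
  expect_true(is.logical(s1$event))
  expect_true(all(s1$stage %in% 1:4))
  expect_equal(nrow(s1), 30)
})
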