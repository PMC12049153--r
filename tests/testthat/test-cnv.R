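# small deterministic genome: 2 chromosomes x 20 genes, arms of 10
toy_annot <- function() {
  g <- sprintf("g%02d", 1:40)
  gene_annotation(g, chrom = rep(c("1", "2"), each = 20),
                  arm = rep(rep(c("p", "q"), each = 10), 2),
                  start = rep((0:19) * 100L, 2), end = rep((0:19) * 100L + 50L, 2))
}

mk_expr <- function(mat, annot) {
  rownames(mat) <- sprintf("c%02d", seq_len(nrow(mat)))
  colnames(mat) <- annot$gene
  mat
}

test_that("query identical to the reference mean smooths to all zeros", {
  annot <- toy_annot()
  x <- mk_expr(matrix(rep(seq(0, 3.9, by = 0.1), each = 5), 5, 40), annot)
  prof <- smooth_cnv_profile(x, annot, reference_ids = c("c01", "c02"),
                             window = 5)
  expect_equal(max(abs(prof$smoothed)), 0)
  expect_equal(unname(cnv_score(prof)), rep(0, 5))
})

test_that("window=1 reduces to the median-centred residual matrix", {
  annot <- toy_annot()
  set.seed(1)
  x <- mk_expr(matrix(rnorm(200, 2), 5, 40), annot)
  prof <- smooth_cnv_profile(x, annot, reference_ids = c("c04", "c05"),
                             window = 1, clip = 100)
  ord <- order(annot$genomic_order)
  r <- sweep(x[, annot$gene[ord]], 2,
             colMeans(x[c("c04", "c05"), annot$gene[ord]]))
  r <- r - apply(r, 1, median)
  expect_equal(unname(prof$smoothed), unname(r), tolerance = 1e-12)
})

test_that("noiseless 2x dosage on one arm yields a +1 plateau in its interior", {
  annot <- toy_annot()
  base <- seq(1, 4.9, by = 0.1)
  x <- mk_expr(rbind(base, base, base, base), annot)
  gained <- annot$gene[annot$chrom == "2" & annot$arm == "q"]
  x[4, gained] <- x[4, gained] + 1 # log2 of a 2x dosage
  prof <- smooth_cnv_profile(x, annot, reference_ids = c("c01", "c02", "c03"),
                             window = 7)
  sm4 <- prof$smoothed["c04", ]
  # windows never cross chromosome 1 -> exactly 0 there
  expect_equal(unname(sm4[prof$chrom == "1"]), rep(0, 20), tolerance = 1e-12)
  # arm interior (window fully inside the gained arm) -> exactly +1
  expect_equal(unname(sm4[34:37]), rep(1, 4), tolerance = 1e-12)
  # interior of the neutral arm of the same chromosome -> 0
  expect_equal(unname(sm4[24:27]), rep(0, 4), tolerance = 1e-12)
})

test_that("residual clipping bounds the influence of outliers", {
  annot <- toy_annot()
  x <- mk_expr(matrix(2, 4, 40), annot)
  x[3, 25] <- 100 # huge spike; residual must clip at +3
  prof <- smooth_cnv_profile(x, annot, reference_ids = c("c01", "c02"),
                             window = 1, clip = 3)
  expect_lte(max(prof$smoothed["c03", ]), 3)
})

test_that("smoothing is translation-equivariant after median-centering", {
  annot <- toy_annot()
  set.seed(2)
  x <- mk_expr(matrix(rnorm(160, 5, 0.1), 4, 40), annot) # small residuals, unclipped
  p1 <- smooth_cnv_profile(x, annot, c("c01", "c02"), window = 5, clip = 50)
  x2 <- x
  x2["c04", ] <- x2["c04", ] + 0.7
  p2 <- smooth_cnv_profile(x2, annot, c("c01", "c02"), window = 5, clip = 50)
  expect_equal(p1$smoothed["c04", ], p2$smoothed["c04", ], tolerance = 1e-10)
})

test_that("smooth_cnv_profile enforces its error contract", {
  annot <- toy_annot()
  x <- mk_expr(matrix(1, 4, 40), annot)
  expect_error(smooth_cnv_profile(x, annot, "c01", window = 4), "odd")
  expect_error(smooth_cnv_profile(x, annot, character(0)), "empty reference")
  expect_error(smooth_cnv_profile(x, annot, "c99", window = 5), "missing")
  expect_error(smooth_cnv_profile(x, annot, "c01", window = 21),
               "window") # no chromosome holds 21 genes
})

test_that("cnv_score is the mean of squares, order-invariant at window=1", {
  sm <- matrix(c(rep(1, 20), rep(0, 20)), 1, 40)
  prof <- structure(list(smoothed = sm), class = "cnv_profile")
  expect_equal(unname(cnv_score(prof)), 0.5)
  set.seed(3)
  sm2 <- matrix(rnorm(120), 3, 40, dimnames = list(c("a", "b", "c"), NULL))
  prof2 <- structure(list(smoothed = sm2), class = "cnv_profile")
  expect_equal(cnv_score(prof2), rowMeans(sm2 ^ 2), tolerance = 1e-12)
  perm <- sample(40)
  prof3 <- structure(list(smoothed = sm2[, perm]), class = "cnv_profile")
  expect_equal(cnv_score(prof3), cnv_score(prof2), tolerance = 1e-12)
})

test_that("cnv_correlation matches brute force, with trivial extremes", {
  set.seed(4)
  n <- 30
  sm <- matrix(rnorm(n * 40), n, 40, dimnames = list(sprintf("c%02d", 1:n), NULL))
  sm[1, ] <- sm[1, ] + 5 # dominant-score cell; top 5% of 30 = 2 cells
  sm[2, ] <- sm[2, ] + 4
  prof <- structure(list(smoothed = sm), class = "cnv_profile")
  cc <- cnv_correlation(prof, top_fraction = 0.05)
  score <- rowMeans(sm ^ 2)
  top <- order(score, decreasing = TRUE)[1:2]
  consensus <- colMeans(sm[top, ])
  brute <- apply(sm, 1, cor, consensus)
  expect_equal(as.numeric(cc), unname(brute), tolerance = 1e-12)
  expect_error(cnv_correlation(structure(list(smoothed = sm[1:10, ]),
                                         class = "cnv_profile")), "20 cells")
})

test_that("a cell with an exactly (anti)parallel track hits +/-1", {
  base <- sin(seq_len(50))
  sm <- rbind(matrix(rep(base, each = 18), 18) * seq(1.1, 2.8, by = 0.1),
              5 * base, -5 * base)
  rownames(sm) <- sprintf("c%02d", 1:20)
  prof <- structure(list(smoothed = sm), class = "cnv_profile")
  cc <- cnv_correlation(prof, top_fraction = 0.05) # top cell = row 19 (5*base)
  expect_equal(unname(cc["c19"]), 1, tolerance = 1e-12)
  expect_equal(unname(cc["c20"]), -1, tolerance = 1e-12)
})

test_that("constant tracks get correlation 0 and are flagged", {
  set.seed(5)
  sm <- matrix(rnorm(25 * 30), 25, 30, dimnames = list(sprintf("c%02d", 1:25), NULL))
  sm[3, ] <- 0
  prof <- structure(list(smoothed = sm), class = "cnv_profile")
  cc <- cnv_correlation(prof)
  expect_equal(unname(cc["c03"]), 0)
  expect_identical(attr(cc, "constant_cells"), "c03")
})

test_that("denoise_cnv_profile zeroes exactly the sub-threshold entries", {
  set.seed(6)
  sm <- matrix(rnorm(30 * 40), 30, 40, dimnames = list(sprintf("c%02d", 1:30), NULL))
  prof <- structure(list(smoothed = sm, reference_ids = sprintf("c%02d", 1:10)),
                    class = "cnv_profile")
  den <- denoise_cnv_profile(prof, sd_mult = 1.2)
  gsd <- apply(sm[1:10, ], 2, sd)
  manual <- sm
  manual[abs(manual) < matrix(1.2 * gsd, 30, 40, byrow = TRUE)] <- 0
  expect_equal(den$smoothed, manual, tolerance = 1e-15)
  expect_equal(den$denoise_sd, 1.2)
  expect_error(denoise_cnv_profile(prof, sd_mult = 0), "sd_mult")
  bad <- prof; bad$reference_ids <- "nope"
  expect_error(denoise_cnv_profile(bad), "reference cells missing")
})

test_that("classify_malignant applies both gates with reference thresholds", {
  set.seed(7)
  n_ref <- 40
  base <- rep(0, 60)
  mk <- function(amp) amp * c(rep(1, 30), rep(0, 30)) + rnorm(60, sd = 0.05)
  sm <- rbind(t(replicate(n_ref, rnorm(60, sd = 0.05))),  # flat reference
              t(replicate(15, mk(1.5))),                  # aberrant, correlated
              t(replicate(5, rnorm(60, sd = 0.8))))       # high score, uncorrelated
  rownames(sm) <- sprintf("c%02d", 1:60)
  prof <- structure(list(smoothed = sm, reference_ids = sprintf("c%02d", 1:n_ref)),
                    class = "cnv_profile")
  cls <- classify_malignant(prof, score_k = 2, corr_min = 0.3)
  expect_true(all(cls$malignant_call[41:55]))
  expect_false(any(cls$malignant_call[1:40]))
  expect_false(any(cls$malignant_call[56:60])) # score passes, correlation fails
  sc <- cls$cnv_score
  expect_equal(unname(cls$thresholds["score"]),
               mean(sc[1:n_ref]) + 2 * sd(sc[1:n_ref]), tolerance = 1e-12)
})

test_that("zero reference variance falls back to the 95th percentile gate", {
  sm <- rbind(matrix(0, 20, 30), matrix(1, 5, 30))
  rownames(sm) <- sprintf("c%02d", 1:25)
  prof <- structure(list(smoothed = sm, reference_ids = sprintf("c%02d", 1:20)),
                    class = "cnv_profile")
  cls <- classify_malignant(prof)
  expect_equal(unname(cls$thresholds["score"]), 0) # 95th pct of all-zero ref
  expect_false(any(cls$malignant_call[1:20]))
})

test_that("all-zero profiles produce no malignant calls", {
  sm <- matrix(0, 25, 30, dimnames = list(sprintf("c%02d", 1:25), NULL))
  prof <- structure(list(smoothed = sm, reference_ids = sprintf("c%02d", 1:10)),
                    class = "cnv_profile")
  cls <- classify_malignant(prof)
  expect_false(any(cls$malignant_call))
})

test_that("planted gained arm exceeds neutral arms in mean smoothed value", {
  ok <- logical(3)
  for (i in 1:3) {
    d <- generate_dataset(sim_config(n_samples = 1, cells_per_sample = 250,
                                     n_genes = 1000, malignant_fraction = 0.6,
                                     cnv_arms = data.frame(arm = "3q", dosage = 1.5),
                                     seed = 20L + i))
    norm <- normalize_log_cpm(d$em)
    comp <- d$truth$compartment
    ref <- names(comp)[comp != "epithelial"]
    prof <- smooth_cnv_profile(norm, d$annot, ref, window = 51)
    mal <- names(d$truth$malignant_labels)[d$truth$malignant_labels]
    mal <- intersect(mal, rownames(prof$smoothed))
    ga <- paste0(prof$chrom, d$annot$arm[order(d$annot$genomic_order)])
    gained <- mean(prof$smoothed[mal, ga == "3q"])
    neutral <- mean(prof$smoothed[mal, ga != "3q"])
    ok[i] <- gained > neutral
  }
  expect_true(all(ok))
})
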