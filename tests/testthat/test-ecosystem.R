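test_that("nnls_deconvolve recovers exact noiseless mixtures", {
  set.seed(41)
  S <- matrix(runif(60 * 3, 0, 5), 60, 3,
              dimnames = list(sprintf("g%02d", 1:60), c("A", "B", "C")))
  P <- rbind(c(0.2, 0.3, 0.5), c(0.7, 0.1, 0.2), c(0, 0.5, 0.5))
  bulk <- P %*% t(S)
  dimnames(bulk) <- list(sprintf("b%d", 1:3), rownames(S))
  dec <- nnls_deconvolve(bulk, S)
  expect_equal(unname(dec$proportions), unname(P), tolerance = 1e-10)
  expect_lt(max(dec$residual_norm), 1e-8)
  expect_length(dec$flagged, 0)
  expect_equal(unname(rowSums(dec$proportions)), rep(1, 3), tolerance = 1e-12)
})

test_that("nnls_deconvolve flags degenerate inputs", {
  S <- matrix(runif(20 * 2, 1, 2), 20, 2,
              dimnames = list(sprintf("g%02d", 1:20), c("A", "B")))
  bulk <- matrix(0, 1, 20, dimnames = list("b1", rownames(S)))
  dec <- nnls_deconvolve(bulk, S)
  expect_equal(unname(dec$proportions[1, ]), c(0.5, 0.5))
  expect_identical(dec$flagged, "b1")
  S2 <- S; S2[, 2] <- 2 * S2[, 1] # rank deficient
  expect_warning(nnls_deconvolve(bulk + 1, S2), "rank deficient")
  expect_error(nnls_deconvolve(bulk, S[, 1, drop = FALSE]), "2 states")
  expect_error(nnls_deconvolve(bulk[, 1:5], S), "missing from bulk")
})

test_that("spearman_cor matches cor.test exactly for untied n = 6", {
  x <- c(1.2, 4.7, 2.2, 9.1, 3.3, 5.5)
  y <- c(2.1, 3.3, 1.0, 8.8, 4.4, 4.0)
  got <- spearman_cor(x, y)
  ref <- cor.test(x, y, method = "spearman") # exact for small untied n
  expect_equal(got$R, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(got$n, 6)
  expect_identical(got$method, "exact enumeration")
  sym <- spearman_cor(y, x)
  expect_equal(sym$R, got$R)
  expect_equal(sym$p, got$p)
})

test_that("spearman_cor handles ties, large n, NAs and degenerate input", {
  set.seed(42)
  x <- rnorm(40); y <- x + rnorm(40)
  got <- spearman_cor(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$R, unname(ref$estimate), tolerance = 1e-12)
  expect_identical(got$method, "t approximation")
  # t approximation agrees with the closed form
  tt <- got$R * sqrt((40 - 2) / (1 - got$R ^ 2))
  expect_equal(got$p, 2 * pt(-abs(tt), 38), tolerance = 1e-12)
  # NA pairs dropped
  x[3] <- NA
  expect_equal(spearman_cor(x, y)$n, 39)
  expect_warning(out <- spearman_cor(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(out$R))
  expect_error(spearman_cor(1:4, 4:1), "at least 5")
})

test_that("kruskal_dunn matches the hand-computed 3x2 toy (H = 32/7)", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- c("a", "a", "b", "b", "c", "c")
  # ranks 1..6; mean ranks 1.5, 3.5, 5.5; H = 12/(6*7) * 2*(4 + 0 + 4)
  res <- kruskal_dunn(vals, grp, alpha = 1)
  expect_equal(res$H, 32 / 7, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, pchisq(32 / 7, 2, lower.tail = FALSE), tolerance = 1e-12)
  ref <- kruskal.test(vals, factor(grp))
  expect_equal(res$H, unname(ref$statistic), tolerance = 1e-12)
  # Dunn z for a vs c: (1.5 - 5.5) / sqrt((6*7/12) * (1/2 + 1/2))
  z_ac <- res$pairwise$z[res$pairwise$group1 == "a" & res$pairwise$group2 == "c"]
  expect_equal(z_ac, -4 / sqrt(3.5), tolerance = 1e-12)
  expect_equal(res$pairwise$p_adj, p.adjust(res$pairwise$p, "BH"))
})

test_that("the Dunn gate and degenerate-group handling work", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- c("a", "a", "b", "b", "c", "c")
  gated <- kruskal_dunn(vals, grp, alpha = 1e-6)
  expect_equal(nrow(gated$pairwise), 0)
  expect_warning(res <- kruskal_dunn(c(vals, 99), c(grp, "d"), alpha = 1),
                 "dropping groups")
  expect_equal(res$df, 2) # group d dropped
  expect_error(suppressWarnings(kruskal_dunn(1:4, c("a", "a", "b", "c"))),
               "3 groups")
})

# logrank_oracle comes from helper-oracles.R

test_that("km_logrank matches the hand-coded log-rank on a 6-subject toy", {
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  grp <- c("A", "B", "A", "B", "A", "B")
  res <- km_logrank(times, events, grp)
  chi2 <- logrank_oracle(times, events, grp == "A")
  expect_equal(res$logrank_chi2, chi2, tolerance = 1e-10)
  expect_equal(res$p, pchisq(chi2, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(sum(res$obs), sum(events))
  expect_equal(sum(res$obs), sum(res$exp), tolerance = 1e-10)
  # KM curves: first strata drop is 1 - 1/n at the first event time
  a_curve <- res$km_curves[res$km_curves$group == "A", ]
  expect_equal(a_curve$surv[a_curve$time == 1], 1 - 1 / 3, tolerance = 1e-12)
  expect_length(res$flagged_no_events, 0)
})

test_that("km_logrank error contract and no-event flagging", {
  times <- c(1, 2, 3, 4, 5, 6)
  expect_error(km_logrank(times, rep(TRUE, 6), c("A", "B", "C", "A", "B", "C")),
               "2 groups")
  expect_error(km_logrank(times, rep(FALSE, 6), rep(c("A", "B"), 3)),
               "at least one event")
  ev <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE) # all events in A
  res <- km_logrank(times, ev, rep(c("A", "B"), 3))
  expect_identical(res$flagged_no_events, "B")
})

test_that("optimal_cutpoint maximizes |z| over the candidate scan", {
  set.seed(43)
  n <- 40
  score <- runif(n)
  times <- rexp(n, rate = 0.2 + score) # higher score -> earlier events
  events <- runif(n) < 0.8
  res <- optimal_cutpoint(score, times, events, min_prop = 0.1)
  qs <- quantile(score, c(0.1, 0.9), names = FALSE)
  u <- sort(unique(score))
  cand <- ((u[-1] + u[-length(u)]) / 2)
  cand <- cand[cand >= qs[1] & cand <= qs[2]]
  zs <- vapply(cand, function(cp) {
    g1 <- score > cp
    sd_fit <- survival::survdiff(survival::Surv(times, events) ~ g1)
    (sd_fit$obs[1] - sd_fit$exp[1]) / sqrt(sd_fit$var[1, 1])
  }, numeric(1))
  expect_equal(res$cutpoint, cand[which.max(abs(zs))])
  expect_equal(abs(res$z), max(abs(zs)), tolerance = 1e-10)
  expect_setequal(unique(res$groups), c("high", "low"))
  expect_equal(res$logrank$logrank_chi2,
               logrank_oracle(times, events, score > res$cutpoint),
               tolerance = 1e-8)
  expect_match(res$p_flag, "anti-conservative")
  expect_s3_class(res$median_split, "survival_stratification")
})

test_that("optimal_cutpoint falls back to the median on near-constant scores", {
  score <- rep(c(0, 1), each = 10)
  set.seed(44)
  times <- rexp(20, 0.5)
  events <- rep(TRUE, 20)
  res <- optimal_cutpoint(score, times, events)
  expect_identical(res$p_flag, "median fallback")
  expect_true(is.na(res$z))
  expect_identical(unname(res$groups), ifelse(score > 0.5, "high", "low"))
  expect_error(optimal_cutpoint(rep(1, 20), times, events), "nearly constant")
  expect_error(optimal_cutpoint(1:5, times[1:5], events[1:5]), "at least 10")
})
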