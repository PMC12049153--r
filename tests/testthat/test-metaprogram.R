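genes120 <- sprintf("g%03d", 1:120)

# program whose weight mass sits on a 40-gene block, with a tiny
# deterministic per-program perturbation so members are not identical
mk_prog <- function(id, sample, block, eps) {
  w <- setNames(rep(0.01, 120), genes120)
  w[block] <- seq(2, 1, length.out = 40) + eps * seq_len(40) / 40
  program(id, sample, w, n_top = 40)
}

block_a <- genes120[1:40]
block_b <- genes120[41:80]
block_c <- genes120[81:120]

test_that("program stores weights and a top-gene set, validating input", {
  p <- mk_prog("s1_p1", "s1", block_a, 0.001)
  expect_s3_class(p, "program")
  expect_identical(p$top_gene_set[1], "g001")
  expect_setequal(p$top_gene_set, block_a)
  expect_error(program("x", "s", c(1, 2)), "names")
  expect_error(program("x", "s", c(a = 1, b = -2)), "weights")
})

test_that("programs_from_set prefixes ids with the sample", {
  sp <- matrix(c(0.7, 0.2, 0.1, 0.1, 0.3, 0.6), 2, 3, byrow = TRUE,
               dimnames = list(c("p1", "p2"), c("ga", "gb", "gc")))
  ps <- structure(list(spectra = sp, k = 2L), class = "program_set")
  pr <- programs_from_set(ps, "s7", n_top = 2)
  expect_identical(vapply(pr, `[[`, "", "id"), c("s7_p1", "s7_p2"))
  expect_identical(pr[[1]]$top_gene_set, c("ga", "gb"))
  expect_identical(pr[[2]]$top_gene_set, c("gc", "gb"))
})

test_that("recurrence requires strictly more than the overlap threshold", {
  # primary program with a 50-gene top set; counterpart shares exactly 25
  # (-> dropped at overlap_min = 0.5) or 26 (-> retained)
  gene_u <- sprintf("u%03d", 1:200)
  mk50 <- function(id, idx) {
    w <- setNames(rep(0.01, 200), gene_u)
    w[gene_u[idx]] <- seq(2, 1, length.out = length(idx))
    program(id, "sX", w, n_top = 50)
  }
  primary <- mk50("sX_p1", 1:50)
  at_half <- mk50("sX_q1", c(1:25, 101:125))
  above <- mk50("sX_q2", c(1:26, 101:124))
  out1 <- filter_recurrent_programs(list(sX = list(list(primary), list(at_half))),
                                    overlap_min = 0.5)
  expect_length(out1, 0)
  expect_equal(attr(out1, "recurrence")$dropped, 1L)
  out2 <- filter_recurrent_programs(list(sX = list(list(primary), list(above))),
                                    overlap_min = 0.5)
  expect_length(out2, 1)
  expect_identical(out2[[1]]$id, "sX_p1")
  # single collection passes through with a warning
  expect_warning(out3 <- filter_recurrent_programs(list(sX = list(list(primary)))),
                 "single program collection")
  expect_length(out3, 1)
})

test_that("cluster_programs recovers planted groups and applies the sharing rule", {
  progs <- c(
    lapply(1:4, function(i) mk_prog(sprintf("s%d_pa", i), sprintf("s%d", i),
                                    block_a, 0.001 * i)),
    lapply(1:3, function(i) mk_prog(sprintf("s%d_pb", i), sprintf("s%d", i),
                                    block_b, 0.002 * i)),
    list(mk_prog("s4_pc", "s4", block_c, 0.001))
  )
  mps <- cluster_programs(progs, share_min = 0.2, min_samples_abs = 3,
                          cut_corr = 0.3, n_signature = 40)
  expect_length(mps, 2)
  expect_identical(mps[[1]]$mp_id, "MP1")
  expect_equal(mps[[1]]$n_samples_represented, 4)
  expect_setequal(mps[[1]]$member_programs, sprintf("s%d_pa", 1:4))
  expect_equal(mps[[2]]$n_samples_represented, 3)
  expect_setequal(mps[[2]]$signature, block_b)
  expect_identical(mps[[2]]$signature[1], "g041") # descending mean weight
  dc <- attr(mps, "dropped_clusters")
  expect_equal(nrow(dc), 1) # the private block-c singleton
  expect_equal(dc$n_samples, 1L)
})

test_that("cluster_programs output is invariant to input order", {
  progs <- c(
    lapply(1:4, function(i) mk_prog(sprintf("s%d_pa", i), sprintf("s%d", i),
                                    block_a, 0.001 * i)),
    lapply(1:3, function(i) mk_prog(sprintf("s%d_pb", i), sprintf("s%d", i),
                                    block_b, 0.002 * i))
  )
  m1 <- cluster_programs(progs)
  m2 <- cluster_programs(rev(progs))
  attributes(m1) <- NULL
  attributes(m2) <- NULL
  expect_identical(m1, m2)
})

test_that("a cohort-wide fraction or absolute floor can drop every cluster", {
  # 13 one-program samples: a shared 3-sample cluster plus 10 mutually
  # distinct programs on rotating 40-gene blocks
  progs <- c(
    lapply(1:3, function(i) mk_prog(sprintf("s%02d_p", i), sprintf("s%02d", i),
                                    block_a, 0.001 * i)),
    lapply(4:13, function(i) {
      start <- ((i * 7) %% 80) + 1
      mk_prog(sprintf("s%02d_p", i), sprintf("s%02d", i),
              genes120[(start:(start + 39) - 1) %% 120 + 1], 0.01 * i)
    })
  )
  mps <- cluster_programs(progs, share_min = 0.2, min_samples_abs = 3)
  expect_gte(length(mps), 1)
  expect_true(any(vapply(mps, `[[`, 0, "n_samples_represented") >= 3))
  # raising the absolute floor above any cluster's reach empties the result
  none <- cluster_programs(progs, min_samples_abs = 8)
  expect_length(none, 0)
  expect_true(nrow(attr(none, "dropped_clusters")) >= 1)
  expect_error(cluster_programs(progs[1]), "at least 2")
})

test_that("average_weights is the equal-weight mean of unit-L1 vectors", {
  p1 <- structure(list(id = "a", sample_id = "s1",
                       weights = c(a = 1, b = 1)), class = "program")
  p2 <- structure(list(id = "b", sample_id = "s2",
                       weights = c(b = 2, c = 6)), class = "program")
  avg <- scMPKit:::average_weights(list(p1, p2))
  expect_equal(avg, c(a = 0.25, b = 0.375, c = 0.375), tolerance = 1e-12)
})

test_that("mp_signature works on meta_programs and raw program lists", {
  progs <- lapply(1:3, function(i) mk_prog(sprintf("s%d_pa", i), sprintf("s%d", i),
                                           block_a, 0.001 * i))
  sig <- mp_signature(progs, n = 10)
  expect_identical(sig, block_a[1:10])
  mps <- cluster_programs(c(progs, lapply(1:3, function(i)
    mk_prog(sprintf("s%d_pb", i), sprintf("s%d", i), block_b, 0.002 * i))))
  expect_identical(mp_signature(mps[[1]], 10), mp_signature(progs, 10))
})
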