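mk_design <- function(tissues) {
  samples <- paste0(tissues, ave(seq_along(tissues), tissues, FUN = seq_along))
  tissue_design(samples, tissues)
}

test_that("log-transform normalisation computes depth factors from raw counts", {
  counts <- matrix(c(10, 10, 20, 20), nrow = 2,
                   dimnames = list(NULL, c("s1", "s2")))
  # sample means 10 and 20, global mean 15 -> factors 1.5 and 0.75
  X <- log_transform_normalize(counts)
  expect_equal(X[, "s1"], log1p(c(10, 10)) * 1.5)
  expect_equal(X[, "s2"], log1p(c(20, 20)) * 0.75)
  # a sample at the global mean is unchanged
  c2 <- matrix(c(5, 25, 15, 15), nrow = 2,
               dimnames = list(NULL, c("a", "b")))
  expect_equal(log_transform_normalize(c2)[, "b"], log1p(c(15, 15)))
  # count 0 -> ln 1 = 0 before scaling
  expect_equal(unname(log_transform_normalize(
    matrix(c(0, 4, 3, 5), 2, dimnames = list(NULL, c("x", "y"))))[1, "x"]), 0)
  expect_error(log_transform_normalize(
    matrix(c(0, 0, 1, 2), 2, dimnames = list(NULL, c("z", "ok")))),
    "all-zero")
  # the alternative order differs but stays finite
  expect_true(all(is.finite(log_transform_normalize(c2, "scale-then-log"))))
})

test_that("pooled sd matches hand case and naive oracle", {
  X <- matrix(c(3, 1, 1, -1), nrow = 1,
              dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  d <- tissue_design(colnames(X), c("A", "A", "B", "B"))
  expect_equal(pooled_within_tissue_sd(X, d), sqrt(2))
  # identical samples within each tissue -> s = 0
  X0 <- matrix(c(5, 5, 2, 2), nrow = 1,
               dimnames = list(NULL, colnames(X)))
  expect_equal(pooled_within_tissue_sd(X0, d), 0)
  set.seed(3)
  tissues <- rep(c("A", "B", "C"), times = c(3, 2, 4))
  Xr <- matrix(rnorm(9 * 20), 20, 9,
               dimnames = list(NULL, paste0("s", 1:9)))
  dr <- tissue_design(colnames(Xr), tissues)
  expect_equal(pooled_within_tissue_sd(Xr, dr), naive_pooled_sd(Xr, tissues),
               tolerance = 1e-12)
  d1 <- tissue_design(colnames(X), c("A", "A", "B", "C"))
  expect_error(pooled_within_tissue_sd(X, d1), "fewer than 2")
})

test_that("t-statistics match the stated formula (hand case + oracle)", {
  X <- matrix(c(3, 1, 1, -1), nrow = 1,
              dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  d <- tissue_design(colnames(X), c("A", "A", "B", "B"))
  st <- tissue_t_statistics(X, d)
  # m=2, n_j=2, s=s0=sqrt2: t_A = (2-1)/(1 * 2*sqrt2)
  expect_equal(unname(st$t[1, "A"]), 1 / (2 * sqrt(2)))
  expect_equal(unname(st$t[1, "B"]), -unname(st$t[1, "A"]))  # 2-tissue symmetry
  # all-equal window scores 0 everywhere
  Xe <- rbind(X, c(2, 2, 2, 2))
  ste <- tissue_t_statistics(Xe, d)
  expect_equal(unname(ste$t[2, ]), c(0, 0))
  set.seed(4)
  tissues <- rep(c("A", "B", "C"), times = c(2, 3, 3))
  Xr <- matrix(rnorm(8 * 30), 30, 8, dimnames = list(NULL, paste0("s", 1:8)))
  dr <- tissue_design(colnames(Xr), tissues)
  expect_equal(unname(tissue_t_statistics(Xr, dr)$t),
               unname(naive_tstats(Xr, tissues)), tolerance = 1e-10)
  expect_error(tissue_t_statistics(matrix(1, 3, 4,
    dimnames = list(NULL, colnames(X))), d), "constant")
})

test_that("raising one tissue's counts in a window raises its t", {
  set.seed(5)
  counts <- matrix(rpois(200 * 8, 20), 200, 8,
                   dimnames = list(NULL, paste0("s", 1:8)))
  d <- tissue_design(colnames(counts), rep(c("A", "B"), each = 4))
  t0 <- tissue_t_statistics(log_transform_normalize(counts), d)$t[1, "A"]
  counts2 <- counts
  counts2[1, 1:4] <- counts2[1, 1:4] + 50
  t1 <- tissue_t_statistics(log_transform_normalize(counts2), d)$t[1, "A"]
  expect_gt(t1, t0)
})

test_that("CTS and ubiquitous rankings behave at the edges", {
  set.seed(6)
  windows <- data.frame(chrom = "w", start = 0:99 * 200, end = 1:100 * 200)
  counts <- matrix(rpois(100 * 4, 10), 100, 4,
                   dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  d <- tissue_design(colnames(counts), c("A", "A", "B", "B"))
  X <- log_transform_normalize(counts)
  st <- tissue_t_statistics(X, d, windows = windows)
  all_w <- call_cts_dhs(st, "A", top_n = 100)
  expect_equal(nrow(all_w), 100)
  top1 <- call_cts_dhs(st, "A", top_n = 1)
  expect_equal(which(windows$start == top1$start), which.max(st$t[, "A"]))
  expect_error(call_cts_dhs(st, "A", top_n = 101), "exceeds")
  expect_error(call_cts_dhs(st, "Z", 1), "unknown tissue")
  # constant matrix: ubiquitous ranking falls back to genomic order
  Xc <- matrix(1, 100, 4, dimnames = list(NULL, colnames(counts)))
  expect_equal(ubiquitous_ranking(Xc, d, 5), 1:5)
})

test_that("split-half ratio is 1 for duplicated samples and near n/W for noise", {
  set.seed(7)
  base <- matrix(rpois(500 * 2, 15), 500, 2)
  counts <- cbind(base, base)
  colnames(counts) <- c("a1", "b1", "a2", "b2")
  d <- tissue_design(colnames(counts), c("A", "B", "A", "B"))
  sh <- split_half_reproducibility(counts, d, grid = c(10, 50, 100), seed = 1)
  expect_true(all(sh$curves$ratio == 1))
  # independent halves: expected overlap ratio ~ n/W (hypergeometric)
  counts2 <- matrix(rpois(500 * 4, 15), 500, 4,
                    dimnames = list(NULL, colnames(counts)))
  d2 <- tissue_design(colnames(counts2), c("A", "A", "B", "B"))
  sh2 <- split_half_reproducibility(counts2, d2, grid = c(100, 250), seed = 2)
  r100 <- sh2$curves$ratio[sh2$curves$n == 100]
  expect_true(all(abs(r100 - 100 / 500) < 0.15))
  expect_error(split_half_reproducibility(
    counts2[, 1:3], tissue_design(colnames(counts2)[1:3], c("A", "A", "B")),
    grid = 10, seed = 1), "single sample")
})

test_that("sample distances are 1 - correlation with zero diagonal", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  D <- sample_distance_matrix(X)
  expect_equal(unname(diag(D)), c(0, 0, 0))
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 2)
  set.seed(8)
  Xr <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(sample_distance_matrix(Xr)["s1", "s2"]),
               1 - cor(Xr[, 1], Xr[, 2]))
  expect_error(sample_distance_matrix(Xr[, 1, drop = FALSE]), "2 samples")
})
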