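test_that("FDR table reproduces the hand-counted example", {
  # 100 targets in >=1 dataset, 60 in >=2, 30 in >=3;
  # decoy A detected in datasets 1 and 2, decoy B in dataset 1 only
  det <- matrix(FALSE, nrow = 102, ncol = 3,
                dimnames = list(NULL, paste0("ds", 1:3)))
  det[1:30, ] <- TRUE
  det[31:60, 1:2] <- TRUE
  det[61:100, 1] <- TRUE
  det[101, 1:2] <- TRUE
  det[102, 1] <- TRUE
  decoy <- c(rep(FALSE, 100), TRUE, TRUE)
  fdr <- cross_dataset_fdr(det, decoy)
  expect_equal(fdr$targets, c(100L, 60L, 30L))
  expect_equal(fdr$decoys, c(2L, 1L, 0L))
  expect_equal(fdr$fdr, c(0.02, 1 / 60, 0))
})

test_that("FDR handles no decoys, a single dataset, and empty k", {
  det <- matrix(c(TRUE, TRUE, FALSE, TRUE), ncol = 2)
  fdr <- cross_dataset_fdr(det, c(FALSE, FALSE))
  expect_equal(fdr$fdr, c(0, 0))

  det1 <- matrix(c(TRUE, TRUE, TRUE, FALSE), ncol = 1)
  fdr1 <- cross_dataset_fdr(det1, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(fdr1$fdr, 0.5)

  det2 <- matrix(c(TRUE, FALSE, FALSE, FALSE), ncol = 2)
  fdr2 <- cross_dataset_fdr(det2, c(TRUE, TRUE))
  expect_true(is.na(fdr2$fdr[1]))  # only decoys detected
})

test_that("target and decoy counts never increase with k", {
  study <- simulate_study(tiny_config())
  det <- detection_matrix(lapply(study$datasets, `[[`, "pg"))
  fdr <- cross_dataset_fdr(det$detected, det$is_decoy)
  expect_equal(nrow(fdr), 2L)
  expect_true(all(diff(fdr$targets) <= 0))
  expect_true(all(diff(fdr$decoys) <= 0))
})

test_that("bin correlation uses pairwise complete observations", {
  bins <- cbind(a = c(1, 2, 3, NA),
                b = c(2, 4, 6, 5),
                c = c(3, 2, 1, 1))
  rownames(bins) <- paste0("g", 1:4)
  corr <- pairwise_bin_correlation(bins)
  expect_equal(diag(corr), stats::setNames(rep(1, 3), c("a", "b", "c")))
  expect_equal(corr["a", "b"], 1)          # computed on first three genes
  expect_equal(corr["a", "c"], -1)         # perfectly anti-ordered
  expect_equal(corr, t(corr))
})

test_that("degenerate correlation pairs become NA", {
  bins <- cbind(a = c(1, 2, NA, NA), b = c(2, 3, NA, NA),
                d = c(2, 2, 2, 2), e = c(1, 2, 3, 4))
  expect_warning(corr <- pairwise_bin_correlation(bins), "constant")
  expect_true(is.na(corr["a", "b"]))   # fewer than 3 complete pairs
  expect_true(is.na(corr["d", "e"]))   # constant vector
})

test_that("clustering puts identical samples on adjacent leaves", {
  set.seed(41)
  base <- sample(1:5, 30, replace = TRUE)
  bins <- cbind(s_dup1 = base, s_dup2 = base,
                s_far = rev(base),
                s_mid = pmin(base + sample(0:1, 30, TRUE), 5))
  rownames(bins) <- sprintf("g%02d", 1:30)
  corr <- pairwise_bin_correlation(bins)
  cl <- cluster_order(corr)
  pos <- match(c("s_dup1", "s_dup2"), cl$order)
  expect_equal(abs(diff(pos)), 1L)
  expect_equal(cl$hclust$height[1], 0)   # identical pair merges first

  # invariance of the tree to input permutation (up to mirror): leaf
  # adjacency of the duplicate pair must persist
  perm <- sample(ncol(corr))
  cl2 <- cluster_order(corr[perm, perm])
  pos2 <- match(c("s_dup1", "s_dup2"), cl2$order)
  expect_equal(abs(diff(pos2)), 1L)
  expect_setequal(cl2$order, cl$order)
})

test_that("PCA filters sparse genes and orders variance fractions", {
  set.seed(42)
  bins <- matrix(sample(1:5, 60, replace = TRUE), nrow = 10,
                 dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  bins[1, 3:6] <- NA               # quantified in 2 of 6 samples: excluded
  res <- pca_on_bins(bins, min_fraction = 0.5)
  expect_equal(res$n_genes_used, 9L)
  expect_true(all(diff(res$variance_fraction) <= 1e-12))

  # eigen-decomposition oracle: variance fractions are the normalized
  # eigenvalues of the gene covariance of the complete submatrix
  x <- bins[-1, ]
  ev <- eigen(stats::cov(t(x)), symmetric = TRUE)$values
  expect_equal(res$variance_fraction[1:5], (ev / sum(ev))[1:5],
               tolerance = 1e-8)

  dup <- cbind(bins[-1, ], s7 = bins[-1, "s1"])
  res2 <- pca_on_bins(dup, min_fraction = 0.5)
  expect_equal(unname(res2$coordinates["s1", ]),
               unname(res2$coordinates["s7", ]), tolerance = 1e-8)
})

test_that("PCA errors when no gene passes the quantification filter", {
  bins <- matrix(NA_integer_, nrow = 3, ncol = 4,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  bins[, 1] <- 1L
  expect_error(pca_on_bins(bins, min_fraction = 0.5), "no gene")
})
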