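test_that("rank binning reproduces worked examples", {
  expect_equal(rank_bin_run(c(1, 2, 3, 4, 5), 5), 1:5)
  b <- rank_bin_run(10^(1:10), 5)                 # 10 distinct values
  expect_equal(as.vector(table(b)), rep(2L, 5))
  expect_equal(b, rep(1:5, each = 2))
  # tied lowest pair shares the bin of its average rank
  expect_equal(rank_bin_run(c(1, 1, 3, 4, 5), 5), c(1, 1, 3, 4, 5))
  # three-level re-binning, same algorithm
  expect_equal(rank_bin_run(c(7, 2, 9), 3), c(2, 1, 3))
  expect_equal(as.vector(table(rank_bin_run(1:6, 3))), rep(2L, 3))
  # missing entries stay missing here
  expect_equal(rank_bin_run(c(2, NA, 1), 2), c(2L, NA, 1L))
})

test_that("binning agrees with the sort-and-slice oracle on random vectors", {
  set.seed(11)
  for (i in 1:300) {
    m <- sample(1:100, 1)
    x <- sample(c(10^stats::runif(m, 0, 6), rep(NA, 5)))[seq_len(m)]
    if (all(is.na(x))) next
    det <- which(!is.na(x))                       # force ties by rounding
    v <- round(x[det], sample(0:3, 1))
    x[det] <- v[sample.int(length(v))]
    for (n_bins in c(3L, 5L)) {
      expect_identical(rank_bin_run(x, n_bins), oracle_bin(x, n_bins))
    }
  }
})

test_that("bins are monotone in ppb and invariant to increasing transforms", {
  set.seed(12)
  for (i in 1:50) {
    x <- 10^stats::rnorm(40, 3, 2)
    x[sample(40, 8)] <- NA
    b <- rank_bin_run(x, 5)
    ord <- order(x, na.last = NA)
    expect_true(all(diff(b[ord]) >= 0))
    expect_identical(rank_bin_run(log10(x), 5), b)
    expect_identical(rank_bin_run(x^3, 5), b)
    expect_identical(rank_bin_run(1e6 * x + 5, 5), b)
  }
})

test_that("batch rules: all-missing -> NA, partial -> bin 1, detected kept", {
  sm <- make_sample_map(paste0("s", 1:3), tissue = "cortex", organ = "brain")
  bins <- matrix(c(NA, NA, NA,
                   4, NA, 3,
                   2, 5, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  out <- apply_batch_missing_rules(bins, sm)
  expect_equal(unname(out["g1", ]), c(NA_integer_, NA, NA))
  expect_equal(unname(out["g2", ]), c(4, 1, 3))
  expect_equal(unname(out["g3", ]), c(2, 5, 1))
})

test_that("batch rules handle every detection pattern of a 3-sample batch", {
  sm <- make_sample_map(paste0("s", 1:3))
  for (mask in 0:7) {
    det <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
    row <- ifelse(det, 3L, NA_integer_)
    bins <- matrix(row, nrow = 1,
                   dimnames = list("g", paste0("s", 1:3)))
    out <- apply_batch_missing_rules(bins, sm)
    if (!any(det)) {
      expect_true(all(is.na(out)))
    } else {
      expect_equal(unname(out[1, ]), ifelse(det, 3L, 1L))
    }
  }
})

test_that("batch rules apply within batches, not across them", {
  sm <- make_sample_map(paste0("s", 1:4),
                        tissue = c("a", "a", "b", "b"))
  bins <- matrix(c(2L, NA, NA, NA), nrow = 1,
                 dimnames = list("g", paste0("s", 1:4)))
  out <- apply_batch_missing_rules(bins, sm)
  # detected in batch a -> partner filled with 1; batch b untouched -> NA
  expect_equal(unname(out[1, ]), c(2L, 1L, NA, NA))
  expect_error(
    apply_batch_missing_rules(
      matrix(1L, 1, 1, dimnames = list("g", "unknown")), sm),
    "no batch")
})

test_that("multi-run samples aggregate to the rounded median run bin", {
  sm <- make_sample_map(paste0("r", 1:4),
                        sample = c("s1", "s1", "s1", "s2"))
  run_bins <- matrix(c(1L, 2L, 4L, 5L,
                       NA, NA, NA, 3L,
                       2L, 3L, NA, 1L), nrow = 3, byrow = TRUE,
                     dimnames = list(paste0("g", 1:3), paste0("r", 1:4)))
  out <- aggregate_runs_to_samples(run_bins, sm)
  expect_equal(unname(out[, "s1"]), c(2L, NA, 3L))  # median(1,2,4)=2; NA; 2.5 up
  expect_equal(unname(out[, "s2"]), c(5L, 3L, 1L))
})

test_that("rebinning recomputes three levels from ppb or collapses five", {
  sm <- make_sample_map(paste0("s", 1:3), tissue = c("a", "b", "c"))
  ppb <- matrix(10^c(1, 5, 3,
                     2, 6, 1,
                     3, 4, 2,
                     4, 2, 5,
                     5, 1, 6,
                     6, 3, 4), nrow = 6, byrow = TRUE,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  b3 <- rebin(ppb, sm)
  expect_equal(attr(b3, "n_bins"), 3L)
  expect_equal(unname(b3[, "s1"]), rep(1:3, each = 2))
  b5 <- bin_abundance(ppb, sm, n_bins = 5L)
  collapsed <- rebin(method = "collapse", five_bins = b5)
  expect_equal(sort(unique(as.vector(collapsed))), 1:3)
  expect_equal(unname(collapsed[, 1]),
               c(1L, 1L, 2L, 2L, 3L, 3L)[unname(b5[, 1])])
})
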