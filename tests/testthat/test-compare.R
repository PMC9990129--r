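test_that("categorical levels map to the documented numeric codes", {
  atlas <- as_categorical_atlas(data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    organ = "heart",
    level = c("high", "not detected", "ascending", "descending",
              "not representative", "medium"),
    reliability = c("approved", "approved", "approved", "supported",
                    "enhanced", "uncertain"),
    stringsAsFactors = FALSE))
  m <- map_categorical_levels(atlas)
  expect_equal(unname(m["g1", "heart"]), 3)
  expect_true(is.na(m["g2", "heart"]))
  expect_equal(unname(m["g3", "heart"]), 1)
  expect_equal(unname(m["g4", "heart"]), 1)
  expect_equal(unname(m["g5", "heart"]), 1)
  expect_false("g6" %in% rownames(m))  # uncertain dropped
})

test_that("true edit distance follows the worked arithmetic and drops NAs", {
  expect_equal(true_edit_distance(c(2, 3, 1), c(2, 3, 1))$mean, 0)
  d <- true_edit_distance(c(1, 2, 3), c(3, 2, 1))
  expect_equal(d$distances, c(2, 0, 2))
  expect_equal(d$mean, 4 / 3)
  d2 <- true_edit_distance(c(1, NA, 3), c(1, 2, 3))
  expect_equal(d2$n, 2L)
  expect_equal(d2$mean, 0)
  expect_error(true_edit_distance(c(NA, 1), c(2, NA)), "no shared")
})

test_that("difference bookkeeping is exact and constants randomize to zero", {
  v <- rep(2, 10)
  rep0 <- randomized_edit_distance_difference(v, v, n_perm = 5, seed = 3)
  expect_equal(rep0$difference, 0)
  rep1 <- randomized_edit_distance_difference(c(1, 2, 3, 2, 1),
                                              c(3, 1, 2, 2, 3),
                                              n_perm = 50, seed = 9)
  expect_identical(rep1$difference,
                   rep1$randomized_distance_mean - rep1$true_distance_mean)
  rep2 <- randomized_edit_distance_difference(c(1, 2, 3, 2, 1),
                                              c(3, 1, 2, 2, 3),
                                              n_perm = 50, seed = 9)
  expect_identical(rep1$difference, rep2$difference)  # seeded determinism
})

test_that("permutation mean converges to the exhaustive enumeration value", {
  v1 <- c(1, 2, 3)
  v2 <- c(3, 2, 1)
  # independent oracle: average the mean absolute difference over all 3! = 6
  # rearrangements of v2
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  exact <- mean(vapply(perms, function(p) mean(abs(v1 - v2[p])), 0))
  expect_equal(exact, 8 / 9)
  rep <- randomized_edit_distance_difference(v1, v2, n_perm = 6000, seed = 1)
  expect_equal(rep$true_distance_mean, 4 / 3)
  expect_lt(abs(rep$randomized_distance_mean - exact), 0.02)
  expect_lt(abs(rep$difference - (-4 / 9)), 0.02)
})

test_that("unrelated uniform profiles give a difference near zero", {
  set.seed(31)
  v1 <- sample(1:3, 3000, replace = TRUE)
  v2 <- sample(1:3, 3000, replace = TRUE)
  rep <- randomized_edit_distance_difference(v1, v2, n_perm = 200, seed = 8)
  expect_lt(abs(rep$difference), 0.05)
})

test_that("NA pairs are removed before both true and randomized distances", {
  v1 <- c(1, NA, 3, 2)
  v2 <- c(1, 2, NA, 2)
  rep <- randomized_edit_distance_difference(v1, v2, n_perm = 10, seed = 2)
  expect_equal(rep$n_proteins, 2L)
  expect_equal(rep$true_distance_mean, 0)
})

test_that("overlap percentages partition the union", {
  same <- overlap_summary(list(o = c("a", "b")), list(o = c("a", "b")))
  expect_equal(c(same$pct_common, same$pct_pipeline_only,
                 same$pct_reference_only), c(100, 0, 0))
  disj <- overlap_summary(list(o = c("a", "b")), list(o = c("c", "d")))
  expect_equal(c(disj$pct_common, disj$pct_pipeline_only,
                 disj$pct_reference_only), c(0, 50, 50))
  mix <- overlap_summary(list(o = c("a", "b", "c")),
                         list(o = c("b", "c", "d")))
  expect_equal(mix$n_union, 4L)
  expect_equal(c(mix$pct_common, mix$pct_pipeline_only,
                 mix$pct_reference_only), c(50, 25, 25))
  expect_equal(mix$pct_common + mix$pct_pipeline_only +
                 mix$pct_reference_only, 100)
  expect_error(overlap_summary(list(o = character()),
                               list(o = character())), "empty union")
})

test_that("continuous atlas correlation is exact on self and scaled copies", {
  set.seed(32)
  genes <- sprintf("g%02d", 1:20)
  atlas <- matrix(10^stats::runif(40, 1, 6), ncol = 2,
                  dimnames = list(genes, c("brain", "liver")))
  sm <- make_sample_map(c("s1", "s2"), organ = c("brain", "liver"))
  ppb <- atlas
  colnames(ppb) <- c("s1", "s2")
  r <- continuous_atlas_correlation(ppb, sm, atlas)
  expect_equal(r$r, c(1, 1))
  r2 <- continuous_atlas_correlation(ppb, sm, atlas * 2)
  expect_equal(r2$r, c(1, 1))
})

test_that("organ medians feed the correlation on the log2 scale", {
  genes <- c("g1", "g2", "g3")
  ppb <- matrix(c(4, 16, 1,    # g1 organ samples (4,16) -> median 10
                  2, 2, 8,
                  32, 8, 64), nrow = 3, byrow = TRUE,
                dimnames = list(genes, c("s1", "s2", "s3")))
  sm <- make_sample_map(paste0("s", 1:3), organ = c("brain", "brain", "liver"))
  atlas <- matrix(c(5, 3, 20, 1, 4, 2), ncol = 2,
                  dimnames = list(genes, c("brain", "liver")))
  res <- continuous_atlas_correlation(ppb, sm, atlas)
  med <- c(stats::median(c(4, 16)), stats::median(c(2, 2)),
           stats::median(c(32, 8)))
  expect_equal(med[1], 10)
  expect_equal(log2(med[1]), 3.321928, tolerance = 1e-6)
  expect_equal(res$r[res$organ == "brain"],
               stats::cor(log2(med), log2(atlas[, "brain"])))
})

test_that("organs with too few shared genes are skipped with a warning", {
  ppb <- matrix(c(1, 2), nrow = 2,
                dimnames = list(c("g1", "g2"), "s1"))
  sm <- make_sample_map("s1", organ = "brain")
  atlas <- matrix(c(1, 2), nrow = 2,
                  dimnames = list(c("g1", "g2"), "brain"))
  expect_warning(res <- continuous_atlas_correlation(ppb, sm, atlas),
                 "skipped")
  expect_equal(nrow(res), 0L)
})
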