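test_that("truth generation is deterministic and honors class fractions", {
  cfg <- sim_config(n_genes = 100L, n_datasets = 1L, n_organs = 5L,
                    frac_organ_enriched = 0.10, frac_group_enriched = 0.20,
                    seed = 5L)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1$classes, t2$classes)
  expect_identical(t1$organ_effects, t2$organ_effects)
  tab <- table(t1$classes$class)
  expect_equal(unname(tab["organ-enriched"]), 10L)
  expect_equal(unname(tab["group-enriched"]), 20L)
  # organ-enriched genes have exactly one organ with fold > 1,
  # group-enriched 2..7, mixed none
  n_enr <- rowSums(t1$organ_effects > 1)
  expect_true(all(n_enr[t1$classes$class == "organ-enriched"] == 1))
  expect_true(all(n_enr[t1$classes$class == "group-enriched"] %in% 2:7))
  expect_true(all(n_enr[t1$classes$class == "mixed"] == 0))
})

test_that("group enrichment needs at least two organs", {
  expect_error(
    generate_truth(sim_config(n_genes = 50L, n_organs = 1L,
                              frac_group_enriched = 0.2)),
    "fewer than 2 organs")
})

test_that("simulated tables have the constructed dimensions and flags", {
  cfg <- tiny_config(contaminant_count = 0L)
  study <- simulate_study(cfg)
  ds <- study$datasets[[1]]
  expect_false(any(ds$pg$is_contaminant))
  n_split <- sum(study$truth$split)
  n_expected <- cfg$n_genes + n_split + nrow(study$truth$decoys) +
    nrow(study$truth$false_targets)
  expect_equal(length(ds$pg$group_id), n_expected)
  n_runs <- cfg$n_organs * cfg$tissues_per_organ * cfg$samples_per_tissue *
    cfg$runs_per_sample
  expect_equal(ncol(ds$pg$ibaq), n_runs)
  expect_equal(sort(colnames(ds$pg$ibaq)), sort(ds$sample_map$run_name))
  # same seed reproduces the dataset exactly
  ds2 <- simulate_dataset(study$truth, cfg, 1L)
  expect_identical(ds2$pg$ibaq, ds$pg$ibaq)
})

test_that("missingness decreases with true abundance", {
  cfg <- tiny_config()
  study <- simulate_study(cfg)
  ds <- study$datasets[[1]]
  keep <- !ds$pg$is_decoy & !ds$pg$is_contaminant &
    vapply(ds$pg$majority_protein_ids, length, 0L) >= 1
  gene_of <- vapply(ds$pg$majority_protein_ids,
                    function(a) sub("-.*$", "", sub("^ACC", "gene", a[1])),
                    "")
  rows <- which(keep & gene_of %in% study$truth$genes)
  abund <- study$truth$baseline[gene_of[rows]]
  missing <- rowMeans(is.na(ds$pg$ibaq[rows, , drop = FALSE]))
  dec <- cut(rank(abund), 10, labels = FALSE)
  by_dec <- tapply(missing, dec, mean)
  expect_gt(by_dec[[1]], by_dec[[10]])
  # and the trend is essentially monotone from bottom to top decile
  expect_gt(by_dec[[1]], by_dec[[5]])
  expect_gte(by_dec[[5]], by_dec[[10]])
})

test_that("a fold of 1 with no dropout leaves nothing to classify", {
  cfg <- sim_config(n_genes = 150L, n_datasets = 1L, n_organs = 4L,
                    tissues_per_organ = 1L, samples_per_tissue = 1L,
                    enrichment_fold = 1, dropout = FALSE,
                    noise_log10_sd = 0, dataset_log10_sd = 0,
                    run_depth_log10_sd = 0, low_psm_fraction = 0,
                    decoy_fraction = 0, contaminant_count = 0L, seed = 8L)
  study <- simulate_study(cfg)
  ds <- study$datasets[[1]]
  flt <- filter_protein_groups(ds$pg)$groups
  mapped <- map_groups_to_genes(fot_normalize(flt), study$gene_map)
  bins <- bin_abundance(mapped$ppb, ds$sample_map)
  prof <- organ_bin_profile(bins, ds$sample_map)
  res <- classify_specificity(prof)
  expect_equal(mean(res$category == "mixed"), 1)
})

test_that("noiseless reference atlases match the truth terciles", {
  cfg <- tiny_config()
  truth <- generate_truth(cfg)
  atl <- emit_reference_atlases(truth, noise_rate = 0)
  truth_abund <- truth$baseline * truth$organ_effects
  for (o in truth$organs[1:2]) {
    terc <- c("low", "medium", "high")[rank_bin_run(truth_abund[, o], 3)]
    got <- atl$categorical[atl$categorical$organ == o, ]
    expect_equal(got$level[match(truth$genes, got$gene_id)], terc)
  }
  expect_equal(atl$continuous, truth_abund)
})

test_that("decoy detections thin out across datasets", {
  cfg <- sim_config(n_genes = 500L, n_datasets = 4L, n_organs = 3L,
                    tissues_per_organ = 1L, samples_per_tissue = 2L,
                    decoy_fraction = 0.2, seed = 12L)
  study <- simulate_study(cfg)
  det <- detection_matrix(lapply(study$datasets, `[[`, "pg"))
  fdr <- cross_dataset_fdr(det$detected, det$is_decoy)
  expect_true(all(diff(fdr$decoys) <= 0))
  expect_lt(fdr$decoys[4], fdr$decoys[1])
  # decoy intensities sit inside the target intensity range (exchangeable
  # with low-abundance targets)
  pg <- study$datasets[[1]]$pg
  dec_med <- stats::median(pg$ibaq[pg$is_decoy, ], na.rm = TRUE)
  tgt <- pg$ibaq[!pg$is_decoy & !pg$is_contaminant, ]
  expect_gt(dec_med, min(tgt, na.rm = TRUE))
  expect_lt(dec_med, stats::median(tgt, na.rm = TRUE))
})
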