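#' Configuration for the synthetic multi-dataset study
#'
#' Collects all knobs of the generator that emulates a multi-dataset
#' label-free proteomics study: cohort design (datasets, organs, tissues,
#' samples, runs), the abundance model, organ-enrichment structure, batch
#' effects, abundance-dependent dropout, and the nuisance rows (decoys,
#' contaminants, planted false targets).
#'
#' The abundance model is log-normal: log10 iBAQ ~ N(\code{baseline_log10_mean},
#' \code{baseline_log10_sd}), spanning roughly five orders of magnitude at
#' the default sd of 1. Organ-enriched and group-enriched genes are modeled
#' as tissue-restricted proteins: their out-of-organ baseline is placed in
#' a narrow band just below the per-run detection limit
#' (\code{restricted_z}, in sd units of the baseline distribution), and the
#' multiplicative \code{enrichment_fold} lifts them above it in their
#' enriched organs — the expression regime in which bin-based specificity
#' classification is informative. Batch effects are per-dataset global
#' multiplicative factors plus per-run depth factors (log10 sds
#' \code{dataset_log10_sd}, \code{run_depth_log10_sd}). Detection is
#' Bernoulli with logistic probability in log10 intensity, centered at the
#' \code{dropout_midpoint_q} quantile of each run's target abundances
#' (so depth and batch factors do not shift detection rates) with slope
#' \code{dropout_steepness} per log10 unit.
#'
#' @param n_genes Number of target genes.
#' @param n_datasets Number of independently simulated datasets.
#' @param n_organs Number of organs in the study.
#' @param organs_per_dataset Organs covered by each dataset (default: all).
#' @param tissues_per_organ,samples_per_tissue,runs_per_sample Cohort
#'   design within each dataset.
#' @param frac_organ_enriched,frac_group_enriched Fractions of genes that
#'   are organ-enriched (one enriched organ) and group-enriched (2-7).
#' @param enrichment_fold Multiplicative abundance fold in enriched organs
#'   (>= 1).
#' @param baseline_log10_mean,baseline_log10_sd Log10-normal baseline
#'   abundance parameters (arbitrary iBAQ units).
#' @param restricted_z Two-element band (in baseline sd units) from which
#'   the out-of-organ baseline of enriched genes is drawn uniformly.
#' @param noise_log10_sd Per-measurement log10-normal noise sd.
#' @param dataset_log10_sd,run_depth_log10_sd Batch-effect log10 sds.
#' @param dropout Logical; disable to make every protein detected in every
#'   run (useful for noiseless sanity checks).
#' @param dropout_midpoint_q Abundance quantile at which detection
#'   probability is 0.5 (default 0.30).
#' @param dropout_steepness Logistic slope per log10 unit (default 25: the
#'   detection limit is sharp, with detection rising from 10\% to 90\% over
#'   about a fifth of an order of magnitude).
#' @param decoy_fraction Decoy rows as a fraction of \code{n_genes}; decoy
#'   abundances are drawn from the bottom half of the target distribution.
#' @param decoy_presence_prob Probability that a decoy (or planted false
#'   target) is matched at all in any given dataset; presence is drawn
#'   independently per dataset, which is what makes the cross-dataset FDR
#'   fall as detections are required in more datasets. Spurious decoy
#'   matches are search artifacts of a dataset, not reproducible signal,
#'   so presence is gated at the dataset level rather than accumulating
#'   over runs.
#' @param contaminant_count Number of contaminant rows (high abundance).
#' @param false_target_count Planted false-positive targets: rows that look
#'   like targets but whose detections follow the decoy model; used to
#'   validate FDR estimation against a realized error rate.
#' @param low_psm_fraction Fraction of target groups forced below 2 PSMs.
#' @param isoform_rate Controls the per-gene isoform count
#'   (1 + Binomial(2, rate)).
#' @param multi_group_fraction Fraction of multi-isoform genes whose
#'   isoforms are split across two protein groups (exercising gene-level
#'   median aggregation).
#' @param seed Integer seed; all generator randomness derives from it
#'   (Mersenne-Twister).
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000L, n_datasets = 3L, n_organs = 6L,
                       organs_per_dataset = n_organs,
                       tissues_per_organ = 2L, samples_per_tissue = 2L,
                       runs_per_sample = 1L,
                       frac_organ_enriched = 0.10,
                       frac_group_enriched = 0.10,
                       enrichment_fold = 8,
                       baseline_log10_mean = 6, baseline_log10_sd = 1,
                       restricted_z = c(-1.45, -1.25),
                       noise_log10_sd = 0.1,
                       dataset_log10_sd = 0.3, run_depth_log10_sd = 0.1,
                       dropout = TRUE, dropout_midpoint_q = 0.30,
                       dropout_steepness = 25,
                       decoy_fraction = 0.10, decoy_presence_prob = 0.4,
                       contaminant_count = 5L,
                       false_target_count = 0L,
                       low_psm_fraction = 0.05,
                       isoform_rate = 0.15, multi_group_fraction = 0.10,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_datasets = as.integer(n_datasets),
              n_organs = as.integer(n_organs),
              organs_per_dataset = as.integer(min(organs_per_dataset,
                                                  n_organs)),
              tissues_per_organ = as.integer(tissues_per_organ),
              samples_per_tissue = as.integer(samples_per_tissue),
              runs_per_sample = as.integer(runs_per_sample),
              frac_organ_enriched = frac_organ_enriched,
              frac_group_enriched = frac_group_enriched,
              enrichment_fold = enrichment_fold,
              baseline_log10_mean = baseline_log10_mean,
              baseline_log10_sd = baseline_log10_sd,
              restricted_z = restricted_z,
              noise_log10_sd = noise_log10_sd,
              dataset_log10_sd = dataset_log10_sd,
              run_depth_log10_sd = run_depth_log10_sd,
              dropout = isTRUE(dropout),
              dropout_midpoint_q = dropout_midpoint_q,
              dropout_steepness = dropout_steepness,
              decoy_fraction = decoy_fraction,
              decoy_presence_prob = decoy_presence_prob,
              contaminant_count = as.integer(contaminant_count),
              false_target_count = as.integer(false_target_count),
              low_psm_fraction = low_psm_fraction,
              isoform_rate = isoform_rate,
              multi_group_fraction = multi_group_fraction,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes > 0L, n_datasets > 0L, n_organs > 0L,
              organs_per_dataset > 0L, tissues_per_organ > 0L,
              samples_per_tissue > 0L, runs_per_sample > 0L,
              enrichment_fold >= 1,
              frac_organ_enriched >= 0, frac_group_enriched >= 0,
              frac_organ_enriched + frac_group_enriched <= 1,
              dropout_midpoint_q >= 0, dropout_midpoint_q <= 1,
              dropout_steepness >= 0,
              decoy_fraction >= 0,
              decoy_presence_prob >= 0, decoy_presence_prob <= 1,
              contaminant_count >= 0L,
              false_target_count >= 0L,
              low_psm_fraction >= 0, low_psm_fraction <= 1,
              multi_group_fraction >= 0, multi_group_fraction <= 1)
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the ground-truth model of a synthetic study
#'
#' Draws the gene roster, specificity classes with their enriched organ
#' sets, baseline abundances, organ effect folds, isoform counts, and the
#' shared decoy / contaminant / false-target rosters. Deterministic given
#' \code{config$seed}. Organ-enriched genes have exactly one organ with
#' fold > 1, group-enriched genes 2-7, mixed genes none.
#'
#' @param config A \code{sim_config}.
#' @return A \code{truth_model}: list with \code{genes}, \code{organs},
#'   \code{classes} (data.frame gene_id / class / enriched_organs /
#'   baseline), \code{baseline} (named vector), \code{organ_effects}
#'   (genes x organs fold matrix), \code{isoform_count}, \code{split}
#'   (logical: gene's isoforms split over two protein groups),
#'   \code{decoys}, \code{false_targets}, \code{contaminants}
#'   (data.frames with accession / baseline), and \code{config}.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  organs <- sprintf("organ%02d", seq_len(config$n_organs))
  genes <- sprintf("gene%05d", seq_len(n))
  n_oe <- round(config$frac_organ_enriched * n)
  n_ge <- round(config$frac_group_enriched * n)
  max_group <- min(7L, config$n_organs)
  if (n_ge > 0L && max_group < 2L) {
    stop("group-enriched genes requested but fewer than 2 organs available")
  }
  cls <- rep("mixed", n)
  idx <- sample.int(n)
  oe_idx <- idx[seq_len(n_oe)]
  ge_idx <- idx[n_oe + seq_len(n_ge)]
  cls[oe_idx] <- "organ-enriched"
  cls[ge_idx] <- "group-enriched"

  effects <- matrix(1, nrow = n, ncol = length(organs),
                    dimnames = list(genes, organs))
  enriched_str <- character(n)
  for (i in oe_idx) {
    o <- sample(organs, 1L)
    effects[i, o] <- config$enrichment_fold
    enriched_str[i] <- o
  }
  for (i in ge_idx) {
    size <- if (max_group == 2L) 2L else sample(2:max_group, 1L)
    os <- sample(organs, size)
    effects[i, os] <- config$enrichment_fold
    enriched_str[i] <- paste(sort(os), collapse = ";")
  }

  z <- stats::rnorm(n)
  restricted <- cls != "mixed"
  z[restricted] <- stats::runif(sum(restricted), config$restricted_z[1L],
                                config$restricted_z[2L])
  baseline <- stats::setNames(
    10^(config$baseline_log10_mean + config$baseline_log10_sd * z), genes)

  isoform_count <- stats::setNames(
    1L + stats::rbinom(n, 2L, config$isoform_rate), genes)
  split <- stats::setNames(rep(FALSE, n), genes)
  multi <- which(isoform_count >= 2L)
  if (length(multi)) {
    split[multi] <- stats::runif(length(multi)) < config$multi_group_fraction
  }

  low_half <- baseline[baseline <= stats::median(baseline)]
  draw_low <- function(k, prefix) {
    data.frame(accession = sprintf("%s%05d", prefix, seq_len(k)),
               baseline = if (k) unname(sample(low_half, k, replace = TRUE))
                          else numeric(0),
               stringsAsFactors = FALSE)
  }
  n_dec <- round(config$decoy_fraction * n)
  decoys <- draw_low(n_dec, "REV_DEC")
  false_targets <- draw_low(config$false_target_count, "FT")
  contaminants <- data.frame(
    accession = sprintf("CON_%03d", seq_len(config$contaminant_count)),
    baseline = 10^(config$baseline_log10_mean + 1 +
                     0.5 * stats::rnorm(config$contaminant_count)),
    stringsAsFactors = FALSE)

  structure(list(genes = genes, organs = organs,
                 classes = data.frame(gene_id = genes, class = cls,
                                      enriched_organs = enriched_str,
                                      baseline = unname(baseline),
                                      stringsAsFactors = FALSE),
                 baseline = baseline,
                 organ_effects = effects,
                 isoform_count = isoform_count,
                 split = split,
                 decoys = decoys,
                 false_targets = false_targets,
                 contaminants = contaminants,
                 config = config),
            class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  tab <- table(x$classes$class)
  cat("truth_model:", length(x$genes), "genes,", length(x$organs),
      "organs\n  ")
  cat(paste(names(tab), tab, sep = ": ", collapse = "  "), "\n")
  cat("  decoys:", nrow(x$decoys), " contaminants:", nrow(x$contaminants),
      " false targets:", nrow(x$false_targets), "\n")
  invisible(x)
}

# isoform accessions of one gene: ACCnnnnn or ACCnnnnn-1..-k
.gene_accessions <- function(gene, k) {
  base <- sub("^gene", "ACC", gene)
  if (k == 1L) base else paste0(base, "-", seq_len(k))
}

#' Accession-to-gene mapping table implied by a truth model
#'
#' Covers every isoform accession of every target gene and the planted
#' false targets (which carry their own gene identifiers). Decoy and
#' contaminant accessions are deliberately absent: they have no gene.
#'
#' @param truth A \code{truth_model}.
#' @return Data.frame with columns \code{accession}, \code{gene_id}.
#' @export
gene_map_from_truth <- function(truth) {
  acc <- lapply(truth$genes,
                function(g) .gene_accessions(g, truth$isoform_count[[g]]))
  df <- data.frame(accession = unlist(acc),
                   gene_id = rep(truth$genes, lengths(acc)),
                   stringsAsFactors = FALSE)
  if (nrow(truth$false_targets)) {
    df <- rbind(df, data.frame(
      accession = truth$false_targets$accession,
      gene_id = sub("^FT", "genefalse", truth$false_targets$accession),
      stringsAsFactors = FALSE))
  }
  df
}

#' Simulate one dataset of the synthetic study
#'
#' Emits a MaxQuant-style protein-group table and its SDRF-like sample map
#' for one dataset. Per-run intensity of a group is baseline x organ fold
#' x dataset batch factor x run depth factor x log-normal noise; detection
#' is Bernoulli with logistic probability in log10 intensity; decoy and
#' contaminant rows are appended after the gene-derived groups; genes with
#' more than one isoform emit groups whose majority IDs are isoform
#' accessions of that gene (split across two groups for a configured
#' fraction); PSM counts increase with mean detected intensity, with a
#' configured fraction of target groups forced below 2 PSMs.
#'
#' Each dataset derives its own RNG stream from \code{config$seed} and the
#' dataset index, so adding another dataset to a study leaves previously
#' simulated datasets unchanged.
#'
#' @param truth A \code{truth_model}.
#' @param config The \code{sim_config} used for the truth (cohort sizes and
#'   noise are read from here).
#' @param dataset_index Positive integer index of the dataset.
#' @param dataset_id Dataset identifier (default \code{"PXDSIM<index>"}).
#' @return List with \code{dataset_id}, \code{pg} (a
#'   \code{protein_groups}) and \code{sample_map}.
#' @export
simulate_dataset <- function(truth, config, dataset_index,
                             dataset_id = sprintf("PXDSIM%03d",
                                                  dataset_index)) {
  stopifnot(inherits(truth, "truth_model"), inherits(config, "sim_config"),
            dataset_index >= 1L)
  set.seed((config$seed + dataset_index * 100003L) %% 2147483647L)

  organs <- truth$organs
  if (config$organs_per_dataset < length(organs)) {
    organs <- sort(sample(organs, config$organs_per_dataset))
  }
  design <- expand.grid(run = seq_len(config$runs_per_sample),
                        smp = seq_len(config$samples_per_tissue),
                        tis = seq_len(config$tissues_per_organ),
                        organ = organs, stringsAsFactors = FALSE)
  tissue <- paste0(design$organ, "_t", design$tis)
  sample_id <- paste(dataset_id, tissue, paste0("s", design$smp), sep = "_")
  run_name <- paste0(sample_id, "_r", design$run)
  sm <- as_sample_map(data.frame(run_name = run_name, sample_id = sample_id,
                                 tissue = tissue, organ = design$organ,
                                 dataset_id = dataset_id,
                                 condition = "normal",
                                 stringsAsFactors = FALSE))
  n_runs <- nrow(sm)

  # group roster: gene-derived groups (split genes contribute two), then
  # planted false targets, then decoys, then contaminants
  grp_gene <- character(0); grp_acc <- list(); grp_kind <- character(0)
  grp_base <- numeric(0); grp_offset <- numeric(0)
  for (g in truth$genes) {
    k <- truth$isoform_count[[g]]
    acc <- .gene_accessions(g, k)
    if (truth$split[[g]] && k >= 2L) {
      off <- stats::rnorm(2L, 0, 0.15)
      grp_gene <- c(grp_gene, g, g)
      grp_acc <- c(grp_acc, list(acc[1L]), list(acc[-1L]))
      grp_kind <- c(grp_kind, "target", "target")
      grp_base <- c(grp_base, rep(truth$baseline[[g]], 2L))
      grp_offset <- c(grp_offset, off)
    } else {
      grp_gene <- c(grp_gene, g)
      grp_acc <- c(grp_acc, list(acc))
      grp_kind <- c(grp_kind, "target")
      grp_base <- c(grp_base, truth$baseline[[g]])
      grp_offset <- c(grp_offset, 0)
    }
  }
  add_roster <- function(df, kind) {
    if (!nrow(df)) return()
    grp_gene <<- c(grp_gene, rep(NA_character_, nrow(df)))
    grp_acc <<- c(grp_acc, as.list(df$accession))
    grp_kind <<- c(grp_kind, rep(kind, nrow(df)))
    grp_base <<- c(grp_base, df$baseline)
    grp_offset <<- c(grp_offset, rep(0, nrow(df)))
  }
  add_roster(truth$false_targets, "false_target")
  add_roster(truth$decoys, "decoy")
  add_roster(truth$contaminants, "contaminant")
  n_grp <- length(grp_base)

  # log10 intensity: baseline + organ fold (targets only) + group offset
  # + dataset shift + run depth + measurement noise
  organ_of_run <- sm$organ
  log10a <- matrix(log10(grp_base) + grp_offset, nrow = n_grp, ncol = n_runs)
  is_target_gene <- grp_kind == "target"
  log10a[is_target_gene, ] <- log10a[is_target_gene, ] +
    log10(truth$organ_effects[grp_gene[is_target_gene], organ_of_run,
                              drop = FALSE])
  ds_shift <- stats::rnorm(1L, 0, config$dataset_log10_sd)
  run_depth <- stats::rnorm(n_runs, 0, config$run_depth_log10_sd)
  log10a <- log10a + ds_shift +
    matrix(run_depth, n_grp, n_runs, byrow = TRUE) +
    matrix(stats::rnorm(n_grp * n_runs, 0, config$noise_log10_sd),
           n_grp, n_runs)

  if (config$dropout) {
    detected <- matrix(FALSE, n_grp, n_runs)
    for (j in seq_len(n_runs)) {
      mid <- stats::quantile(log10a[is_target_gene, j],
                             config$dropout_midpoint_q, names = FALSE)
      p <- stats::plogis(config$dropout_steepness * (log10a[, j] - mid))
      detected[, j] <- stats::runif(n_grp) < p
    }
  } else {
    detected <- matrix(TRUE, n_grp, n_runs)
  }
  # decoys and planted false targets are spurious search matches: whether
  # they appear at all in this dataset is an independent Bernoulli event
  spurious <- grp_kind %in% c("decoy", "false_target")
  if (any(spurious)) {
    absent <- stats::runif(sum(spurious)) >= config$decoy_presence_prob
    detected[which(spurious)[absent], ] <- FALSE
  }
  ibaq <- 10^log10a
  ibaq[!detected] <- NA_real_
  colnames(ibaq) <- sm$run_name

  # PSM counts: Poisson with rate increasing in mean detected intensity
  mean_log <- rowMeans(ifelse(detected, log10a, NA), na.rm = TRUE)
  any_det <- rowSums(detected) > 0L
  psm <- integer(n_grp)
  if (any(any_det)) {
    pct <- rep(0, n_grp)
    pct[any_det] <- rank(mean_log[any_det]) / sum(any_det)
    psm[any_det] <- stats::rpois(sum(any_det),
                                 2 + 40 * pct[any_det]^2) + 1L
  }
  low <- which(is_target_gene & any_det &
                 stats::runif(n_grp) < config$low_psm_fraction)
  psm[low] <- sample(0:1, length(low), replace = TRUE)

  pg <- new_protein_groups(
    group_id = sprintf("%s_grp%05d", dataset_id, seq_len(n_grp)),
    protein_ids = grp_acc,
    majority_protein_ids = grp_acc,
    psm_count = psm,
    is_decoy = grp_kind == "decoy",
    is_contaminant = grp_kind == "contaminant",
    ibaq = ibaq
  )
  list(dataset_id = dataset_id, pg = pg, sample_map = sm)
}

#' Simulate a complete multi-dataset study
#'
#' Convenience wrapper: generates the truth, simulates every dataset, and
#' derives the accession-to-gene map.
#'
#' @param config A \code{sim_config}.
#' @return List with \code{truth}, \code{gene_map} and \code{datasets}
#'   (each a list with \code{dataset_id}, \code{pg}, \code{sample_map}).
#' @export
simulate_study <- function(config) {
  truth <- generate_truth(config)
  datasets <- lapply(seq_len(config$n_datasets),
                     function(i) simulate_dataset(truth, config, i))
  names(datasets) <- vapply(datasets, `[[`, "", "dataset_id")
  list(truth = truth, gene_map = gene_map_from_truth(truth),
       datasets = datasets)
}

#' Emit reference atlases implied by a truth model
#'
#' Builds the two kinds of external reference an organ atlas is compared
#' against: a categorical atlas whose levels are the per-organ abundance
#' terciles of the true organ-level abundances (low/medium/high), and a
#' continuous atlas equal to the true organ abundances with log-normal
#' noise. With \code{noise_rate = 0} the categorical atlas is exactly the
#' tercile discretization of the truth; with probability \code{noise_rate}
#' a level is resampled uniformly from \{low, medium, high\}, so at
#' \code{noise_rate = 1} the atlas carries no signal.
#'
#' @param truth A \code{truth_model}.
#' @param noise_rate Probability in [0, 1] of resampling each categorical
#'   level; also used as the log10 sd of the continuous atlas noise.
#' @param seed Optional seed (global RNG state restored on exit).
#' @return List with \code{categorical} (a \code{categorical_atlas}) and
#'   \code{continuous} (genes x organs matrix of true organ abundances
#'   with noise).
#' @export
emit_reference_atlases <- function(truth, noise_rate = 0, seed = NULL) {
  stopifnot(noise_rate >= 0, noise_rate <= 1)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  truth_abund <- truth$baseline * truth$organ_effects
  levels3 <- c("low", "medium", "high")
  cat_rows <- lapply(truth$organs, function(o) {
    terc <- rank_bin_run(truth_abund[, o], n_bins = 3L)
    lev <- levels3[terc]
    flip <- stats::runif(length(lev)) < noise_rate
    lev[flip] <- sample(levels3, sum(flip), replace = TRUE)
    data.frame(gene_id = truth$genes, organ = o, level = lev,
               reliability = "approved", stringsAsFactors = FALSE)
  })
  categorical <- as_categorical_atlas(do.call(rbind, cat_rows))
  continuous <- truth_abund *
    10^matrix(stats::rnorm(length(truth_abund), 0, noise_rate),
              nrow = nrow(truth_abund))
  dimnames(continuous) <- dimnames(truth_abund)
  list(categorical = categorical, continuous = continuous)
}
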