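# hand-built protein_groups with sensible defaults; ibaq given as a matrix
# or a vector (single run "run1")
make_pg <- function(majority, ibaq, psm = NULL, decoy = NULL, contam = NULL,
                    protein_ids = NULL) {
  if (!is.list(majority)) majority <- as.list(majority)
  majority <- lapply(majority, function(x) strsplit(x, ";")[[1]])
  n <- length(majority)
  if (!is.matrix(ibaq)) {
    ibaq <- matrix(ibaq, ncol = 1, dimnames = list(NULL, "run1"))
  }
  new_protein_groups(
    group_id = sprintf("g%03d", seq_len(n)),
    protein_ids = if (is.null(protein_ids)) majority else protein_ids,
    majority_protein_ids = majority,
    psm_count = if (is.null(psm)) rep(5L, n) else as.integer(psm),
    is_decoy = if (is.null(decoy)) rep(FALSE, n) else decoy,
    is_contaminant = if (is.null(contam)) rep(FALSE, n) else contam,
    ibaq = ibaq
  )
}

# minimal sample map: one row per run
make_sample_map <- function(run, sample = run, tissue = "t1", organ = "o1",
                            dataset = "D1", condition = "normal") {
  as_sample_map(data.frame(run_name = run, sample_id = sample,
                           tissue = tissue, organ = organ,
                           dataset_id = dataset, condition = condition,
                           stringsAsFactors = FALSE))
}

# small synthetic study configuration used by most unit tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 200L, n_datasets = 2L, n_organs = 4L,
         tissues_per_organ = 1L, samples_per_tissue = 2L,
         contaminant_count = 2L, seed = 42L),
    list(...))
  do.call(sim_config, args)
}

# independent sort-and-slice binning oracle: explicit equal-frequency cut
# points k*m/n over sorted positions, average-rank midpoint located with
# findInterval
oracle_bin <- function(x, n_bins) {
  out <- rep(NA_integer_, length(x))
  det <- which(!is.na(x))
  m <- length(det)
  if (m == 0L) return(out)
  xs <- x[det]
  avg_rank <- vapply(xs, function(v) {
    less <- sum(xs < v)
    eq <- sum(xs == v)
    less + (eq + 1) / 2
  }, numeric(1))
  cuts <- (0:n_bins) * m / n_bins
  out[det] <- findInterval(avg_rank - 0.5, cuts, rightmost.closed = TRUE,
                           left.open = FALSE)
  # midpoints exactly on a cut belong to the lower slice
  on_cut <- (avg_rank - 0.5) %in% cuts[-1]
  out[det][on_cut] <- out[det][on_cut] - 1L
  pmax(out, 1L)
}
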