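#' Rank-bin one MS run's abundances
#'
#' Converts the detected (non-missing) ppb values of one run into
#' equal-frequency rank bins: values are ranked ascending, and the entry
#' with rank r among m detected values gets bin
#' \code{ceiling((r - 0.5) * n_bins / m)} — the bin whose equal-frequency
#' slice of \code{1..m} contains the rank's midpoint — so bin 1 holds the
#' lowest and bin \code{n_bins} the highest abundances, with occupancy as
#' equal as the division allows. Ties receive the average rank and share
#' the bin that rank falls in. Missing entries remain missing at this
#' stage (the batch-wise rules of [apply_batch_missing_rules()] decide
#' between NA and bin 1 later).
#'
#' Because bins depend on ranks only, any strictly increasing transform of
#' the abundances — in particular a multiplicative dataset batch effect —
#' leaves them unchanged; that robustness is the reason binning is used for
#' cross-dataset comparison at all.
#'
#' Equal-frequency bins are used rather than equal-width: iBAQ abundances
#' span several orders of magnitude, and equal-width bins on ppb would put
#' nearly every protein in bin 1.
#'
#' @param x Numeric vector of non-negative ppb values, \code{NA} allowed.
#' @param n_bins Number of bins (default 5).
#' @return Integer vector of bins in \code{1..n_bins}, \code{NA} where the
#'   input was missing.
#' @export
rank_bin_run <- function(x, n_bins = 5L) {
  stopifnot(n_bins >= 2L)
  out <- rep(NA_integer_, length(x))
  det <- !is.na(x)
  m <- sum(det)
  if (m == 0L) return(out)
  r <- rank(x[det], ties.method = "average")
  out[det] <- as.integer(ceiling((r - 0.5) * n_bins / m))
  out
}

#' Rank-bin every run of a ppb matrix
#'
#' @param ppb Genes x runs numeric matrix.
#' @param n_bins Number of bins.
#' @return Integer matrix of the same shape with per-run bins (runs with no
#'   detections are all-\code{NA}).
#' @export
bin_matrix <- function(ppb, n_bins = 5L) {
  out <- apply(ppb, 2L, rank_bin_run, n_bins = n_bins)
  dimnames(out) <- dimnames(ppb)
  out
}

# round half up, used for median-of-bins aggregation
.round_half_up <- function(x) floor(x + 0.5)

#' Aggregate run-level bins to sample-level bins
#'
#' When a sample was acquired as several runs or fractions, its bin is the
#' median of the non-missing run bins, rounded half up; a sample with no
#' detected run stays missing.
#'
#' @param run_bins Genes x runs integer matrix from [bin_matrix()].
#' @param sample_map A \code{sample_map} covering every run column.
#' @return Genes x samples integer matrix.
#' @export
aggregate_runs_to_samples <- function(run_bins, sample_map) {
  missing_runs <- setdiff(colnames(run_bins), sample_map$run_name)
  if (length(missing_runs)) {
    stop("run(s) absent from the sample map: ",
         paste(missing_runs, collapse = ", "))
  }
  sm <- sample_map[match(colnames(run_bins), sample_map$run_name), ]
  samples <- unique(sm$sample_id)
  out <- matrix(NA_integer_, nrow = nrow(run_bins), ncol = length(samples),
                dimnames = list(rownames(run_bins), samples))
  for (s in samples) {
    cols <- which(sm$sample_id == s)
    if (length(cols) == 1L) {
      out[, s] <- run_bins[, cols]
    } else {
      sub <- run_bins[, cols, drop = FALSE]
      med <- apply(sub, 1L, function(v) {
        v <- v[!is.na(v)]
        if (length(v)) .round_half_up(stats::median(v)) else NA_real_
      })
      out[, s] <- as.integer(med)
    }
  }
  out
}

#' Apply the batch-wise missing-value rules
#'
#' Within each batch (all samples of one tissue in one dataset), a protein
#' not detected in any sample is annotated \code{NA} (not detected in the
#' batch), while a protein detected in some but not all samples has its
#' missing cells assigned the lowest bin value 1; detected cells keep their
#' bins. This distinguishes "absent from the batch" from "below the
#' detection limit of one sample".
#'
#' @param sample_bins Genes x samples integer matrix.
#' @param sample_map A \code{sample_map} assigning every sample to a batch.
#' @param n_bins Number of bin levels recorded on the result (default: the
#'   largest bin present, NA for an all-missing matrix).
#' @return A \code{binned_matrix}: the genes x samples integer matrix with
#'   attributes \code{batch} (named character, sample -> batch) and
#'   \code{n_bins}.
#' @export
apply_batch_missing_rules <- function(sample_bins, sample_map,
                                      n_bins = NULL) {
  if (is.null(n_bins)) {
    n_bins <- if (all(is.na(sample_bins))) NA_integer_
              else max(sample_bins, na.rm = TRUE)
  }
  batch_of <- .batch_of_samples(colnames(sample_bins), sample_map)
  out <- sample_bins
  for (b in unique(batch_of)) {
    cols <- which(batch_of == b)
    sub <- out[, cols, drop = FALSE]
    n_det <- rowSums(!is.na(sub))
    fill <- n_det > 0L & n_det < length(cols)
    if (any(fill)) {
      sub[fill, ][is.na(sub[fill, , drop = FALSE])] <- 1L
      out[, cols] <- sub
    }
  }
  structure(out, batch = batch_of, n_bins = as.integer(n_bins),
            class = c("binned_matrix", class(out)))
}

.batch_of_samples <- function(samples, sample_map) {
  idx <- match(samples, sample_map$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) with no batch assignment in the sample map: ",
         paste(samples[is.na(idx)], collapse = ", "))
  }
  stats::setNames(sample_map$batch[idx], samples)
}

#' Full ppb-to-bins transformation
#'
#' Chains per-run rank binning ([rank_bin_run()]), run-to-sample
#' aggregation and the batch-wise missing value rules.
#'
#' @param ppb Genes x runs ppb matrix.
#' @param sample_map A \code{sample_map} covering the run columns.
#' @param n_bins Number of bins (5 for the main pipeline, 3 for categorical
#'   atlas comparison).
#' @return A \code{binned_matrix} (genes x samples) as returned by
#'   [apply_batch_missing_rules()].
#' @export
bin_abundance <- function(ppb, sample_map, n_bins = 5L) {
  run_bins <- bin_matrix(ppb, n_bins = n_bins)
  sample_bins <- aggregate_runs_to_samples(run_bins, sample_map)
  apply_batch_missing_rules(sample_bins, sample_map, n_bins = n_bins)
}

#' Re-bin abundances into three levels (low / medium / high)
#'
#' For comparison against categorical reference atlases the abundances are
#' re-binned into three categories. By default the three-level bins are
#' recomputed from ppb with the same rank-binning algorithm (keeping the
#' definition self-consistent); alternatively the existing 5-level bins can
#' be collapsed as \{1,2\}->1, \{3,4\}->2, \{5\}->3.
#'
#' @param ppb Genes x runs ppb matrix (for \code{method = "recompute"}).
#' @param sample_map A \code{sample_map}.
#' @param method \code{"recompute"} (default) or \code{"collapse"}.
#' @param five_bins A 5-level \code{binned_matrix}, required for
#'   \code{method = "collapse"}.
#' @return A 3-level \code{binned_matrix}.
#' @export
rebin <- function(ppb = NULL, sample_map = NULL,
                  method = c("recompute", "collapse"), five_bins = NULL) {
  method <- match.arg(method)
  if (method == "recompute") {
    stopifnot(!is.null(ppb), !is.null(sample_map))
    return(bin_abundance(ppb, sample_map, n_bins = 3L))
  }
  stopifnot(!is.null(five_bins))
  out <- five_bins
  out[] <- c(1L, 1L, 2L, 2L, 3L)[five_bins]
  attr(out, "n_bins") <- 3L
  out
}
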