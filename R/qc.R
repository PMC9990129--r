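#' Build a cross-dataset detection matrix from unfiltered tables
#'
#' Identifies protein groups across datasets by their sorted majority
#' protein IDs and records, for each, the datasets in which the group was
#' detected (present with at least one non-missing intensity). Consumes the
#' \emph{unfiltered} tables, since decoy hits must be retained for FDR
#' estimation.
#'
#' @param tables Named list of \code{protein_groups}, one per dataset
#'   (names are the dataset identifiers).
#' @return List with \code{detected}, a proteins x datasets logical matrix,
#'   and \code{is_decoy}, a logical vector per protein.
#' @export
detection_matrix <- function(tables) {
  stopifnot(length(tables) >= 1L)
  if (is.null(names(tables))) names(tables) <- paste0("ds", seq_along(tables))
  per_ds <- lapply(tables, function(pg) {
    key <- vapply(pg$majority_protein_ids,
                  function(a) paste(sort(a), collapse = ";"), "")
    det <- rowSums(!is.na(pg$ibaq)) > 0L
    data.frame(key = key[det], decoy = pg$is_decoy[det],
               stringsAsFactors = FALSE)
  })
  keys <- sort(unique(unlist(lapply(per_ds, `[[`, "key"))))
  detected <- matrix(FALSE, nrow = length(keys), ncol = length(tables),
                     dimnames = list(keys, names(tables)))
  decoy <- stats::setNames(rep(FALSE, length(keys)), keys)
  for (d in names(tables)) {
    detected[unique(per_ds[[d]]$key), d] <- TRUE
    decoy[per_ds[[d]]$key[per_ds[[d]]$decoy]] <- TRUE
  }
  list(detected = detected, is_decoy = unname(decoy))
}

#' Cross-dataset decoy-based FDR curve
#'
#' Estimates the protein false discovery rate as a function of the number
#' of datasets a protein was detected in: with T(k) target and D(k) decoy
#' proteins detected in at least k datasets, FDR(k) = D(k) / T(k). As k
#' grows, decoys — whose detections are independent noise — drop out much
#' faster than genuine targets, so requiring detection in several datasets
#' drives the FDR of the aggregated protein list down.
#'
#' @param detected Proteins x datasets logical matrix (see
#'   [detection_matrix()]), or a list of dataset-id sets per protein.
#' @param is_decoy Logical vector flagging decoy proteins.
#' @return A data.frame of class \code{fdr_table} with columns \code{k},
#'   \code{targets}, \code{decoys}, \code{fdr} (NA where T(k) = 0), one
#'   row per k = 1..n_datasets.
#' @export
cross_dataset_fdr <- function(detected, is_decoy) {
  if (is.list(detected) && !is.matrix(detected)) {
    ds <- sort(unique(unlist(detected)))
    m <- matrix(FALSE, nrow = length(detected), ncol = length(ds),
                dimnames = list(names(detected), ds))
    for (i in seq_along(detected)) m[i, as.character(detected[[i]])] <- TRUE
    detected <- m
  }
  stopifnot(nrow(detected) == length(is_decoy), ncol(detected) >= 1L)
  n_det <- rowSums(detected)
  ks <- seq_len(ncol(detected))
  targets <- vapply(ks, function(k) sum(n_det >= k & !is_decoy), 0L)
  decoys <- vapply(ks, function(k) sum(n_det >= k & is_decoy), 0L)
  fdr <- ifelse(targets > 0L, decoys / targets, NA_real_)
  out <- data.frame(k = ks, targets = targets, decoys = decoys, fdr = fdr)
  class(out) <- c("fdr_table", "data.frame")
  out
}

#' Pairwise sample correlation on binned abundances
#'
#' Pearson correlation for every sample pair, computed on pairwise
#' complete observations of the bin-transformed abundances. Pairs with
#' fewer than 3 complete observations, or with a constant bin vector on
#' either side, yield \code{NA} (the latter with a warning).
#'
#' @param binned Genes x samples bin matrix (\code{NA} allowed).
#' @return Symmetric samples x samples correlation matrix with unit
#'   diagonal.
#' @export
pairwise_bin_correlation <- function(binned) {
  ns <- ncol(binned)
  if (ns < 2L) stop("need at least 2 samples")
  out <- diag(1, ns)
  dimnames(out) <- list(colnames(binned), colnames(binned))
  constant_seen <- FALSE
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      x <- binned[, i]; y <- binned[, j]
      keep <- !is.na(x) & !is.na(y)
      if (sum(keep) < 3L) {
        out[i, j] <- out[j, i] <- NA_real_
        next
      }
      if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
        constant_seen <- TRUE
        out[i, j] <- out[j, i] <- NA_real_
        next
      }
      out[i, j] <- out[j, i] <- stats::cor(x[keep], y[keep])
    }
  }
  if (constant_seen) {
    warning("constant bin vector in at least one sample pair; ",
            "correlation set to NA")
  }
  out
}

#' Hierarchical clustering order of samples
#'
#' Agglomerative clustering of the rows of a sample correlation matrix on
#' Euclidean distances. Rows are sorted lexicographically by sample id
#' first so that the leaf order is deterministic under ties. The linkage
#' method defaults to complete linkage and is configurable.
#'
#' @param corr Square correlation matrix with sample dimnames; \code{NA}
#'   entries are imputed as 0 with a warning.
#' @param method Linkage method passed to [stats::hclust()].
#' @return List with \code{order} (sample ids in leaf order),
#'   \code{hclust} (the fitted tree) and \code{method}.
#' @export
cluster_order <- function(corr, method = "complete") {
  if (nrow(corr) < 2L) stop("need at least 2 samples to cluster")
  if (anyNA(corr)) {
    warning("NA correlations imputed as 0 for clustering")
    corr[is.na(corr)] <- 0
  }
  ord <- order(rownames(corr))
  corr <- corr[ord, ord, drop = FALSE]
  h <- stats::hclust(stats::dist(corr), method = method)
  list(order = rownames(corr)[h$order], hclust = h, method = method)
}

#' PCA of samples on binned abundances
#'
#' Retains the genes quantified (non-NA) in at least \code{min_fraction}
#' of the samples, imputes the remaining missing bins (0 by default —
#' undetected approximates lowest signal — or the gene mean), centers each
#' gene and computes sample coordinates by singular value decomposition.
#'
#' @param binned Genes x samples bin matrix.
#' @param min_fraction Minimum fraction of samples a gene must be
#'   quantified in (default 0.5).
#' @param impute \code{"zero"} (default) or \code{"mean"}.
#' @return List with \code{coordinates} (samples x components),
#'   \code{variance_fraction} (non-increasing), and \code{n_genes_used}.
#' @export
pca_on_bins <- function(binned, min_fraction = 0.5,
                        impute = c("zero", "mean")) {
  impute <- match.arg(impute)
  if (ncol(binned) < 3L) stop("need at least 3 samples for PCA")
  frac <- rowMeans(!is.na(binned))
  keep <- frac >= min_fraction
  if (!any(keep)) stop("no gene quantified in at least ",
                       round(100 * min_fraction), "% of samples")
  x <- binned[keep, , drop = FALSE]
  if (impute == "zero") {
    x[is.na(x)] <- 0
  } else {
    mu <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 1L]]
  }
  fit <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  list(coordinates = fit$x, variance_fraction = vf,
       n_genes_used = sum(keep))
}
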