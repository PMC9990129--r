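#' Convert a categorical atlas to a numeric bin matrix
#'
#' Rows with reliability \code{"uncertain"} are dropped first. The
#' remaining abundance levels are mapped to the three-level bin scale:
#' \code{"low"} -> 1, \code{"medium"} -> 2, \code{"high"} -> 3,
#' \code{"not detected"} -> \code{NA}, and \code{"ascending"},
#' \code{"descending"} and \code{"not representative"} -> 1.
#'
#' @param atlas A \code{categorical_atlas} (see [read_categorical_atlas()]).
#' @return Genes x organs numeric matrix with values in \{1, 2, 3, NA\}.
#' @export
map_categorical_levels <- function(atlas) {
  bad <- setdiff(unique(atlas$level), .atlas_levels)
  if (length(bad)) {
    stop("unknown abundance level '", bad[1L], "'; allowed levels: ",
         paste(.atlas_levels, collapse = ", "))
  }
  atlas <- atlas[atlas$reliability != "uncertain", , drop = FALSE]
  value <- c("not detected" = NA_real_, "low" = 1, "medium" = 2, "high" = 3,
             "ascending" = 1, "descending" = 1, "not representative" = 1)
  genes <- sort(unique(atlas$gene_id))
  organs <- sort(unique(atlas$organ))
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(organs),
                dimnames = list(genes, organs))
  out[cbind(match(atlas$gene_id, genes), match(atlas$organ, organs))] <-
    unname(value[atlas$level])
  out
}

# align two named (or equal-length) bin vectors on shared, pairwise non-NA
# entries
.complete_pairs <- function(v1, v2) {
  if (!is.null(names(v1)) && !is.null(names(v2))) {
    shared <- intersect(names(v1), names(v2))
    v1 <- v1[shared]; v2 <- v2[shared]
  } else if (length(v1) != length(v2)) {
    stop("unnamed bin vectors must have equal length")
  }
  keep <- !is.na(v1) & !is.na(v2)
  list(v1 = unname(v1[keep]), v2 = unname(v2[keep]))
}

#' True edit distance between two bin profiles
#'
#' The per-protein edit distance between two aligned bin vectors is the
#' absolute difference of their bins; pairs with \code{NA} on either side
#' are dropped.
#'
#' @param v1,v2 Bin vectors, aligned by name (shared genes) or position.
#' @return List with \code{distances}, their \code{mean}, and \code{n}
#'   (retained pairs).
#' @export
true_edit_distance <- function(v1, v2) {
  p <- .complete_pairs(v1, v2)
  if (length(p$v1) == 0L) stop("no shared genes with non-NA bins")
  d <- abs(p$v1 - p$v2)
  list(distances = d, mean = mean(d), n = length(d))
}

#' Randomized edit distance difference between two bin profiles
#'
#' Contrasts the observed agreement of two bin profiles with a permutation
#' null: the randomized edit distance is the mean absolute difference
#' between profile 1 and a random rearrangement of profile 2 across
#' proteins, averaged over \code{n_perm} replicates, and
#' \code{difference = randomized - true}. A difference near zero means the
#' profiles agree no better than random noise; a positive difference
#' indicates concordant signal. NA pairs are dropped before both the true
#' and randomized distances, so both use the same support.
#'
#' Randomization permutes the reference vector across proteins (sampling
#' without replacement), preserving its bin composition;
#' \code{method = "resample"} draws with replacement instead.
#'
#' @param v1,v2 Bin vectors, aligned by name or position.
#' @param n_perm Number of randomization replicates (default 10).
#' @param seed Optional integer seed; the global RNG state is restored on
#'   exit.
#' @param method \code{"permute"} (default) or \code{"resample"}.
#' @return An \code{edit_distance_report}: list with
#'   \code{true_distance_mean}, \code{randomized_distance_mean},
#'   \code{difference} (randomized - true, exactly), \code{n_proteins},
#'   \code{n_permutations}, \code{seed}, \code{method}.
#' @export
randomized_edit_distance_difference <- function(v1, v2, n_perm = 10L,
                                                seed = NULL,
                                                method = c("permute",
                                                           "resample")) {
  method <- match.arg(method)
  stopifnot(n_perm >= 1L)
  p <- .complete_pairs(v1, v2)
  n <- length(p$v1)
  if (n == 0L) stop("no shared genes with non-NA bins")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  true_mean <- mean(abs(p$v1 - p$v2))
  rand <- vapply(seq_len(n_perm), function(i) {
    v2r <- sample(p$v2, n, replace = (method == "resample"))
    mean(abs(p$v1 - v2r))
  }, numeric(1))
  rand_mean <- mean(rand)
  structure(list(true_distance_mean = true_mean,
                 randomized_distance_mean = rand_mean,
                 difference = rand_mean - true_mean,
                 n_proteins = n,
                 n_permutations = as.integer(n_perm),
                 seed = seed,
                 method = method),
            class = "edit_distance_report")
}

#' @export
print.edit_distance_report <- function(x, ...) {
  cat("edit distance over", x$n_proteins, "proteins:\n")
  cat(sprintf("  true mean       %.4f\n", x$true_distance_mean))
  cat(sprintf("  randomized mean %.4f  (%d %s replicates)\n",
              x$randomized_distance_mean, x$n_permutations, x$method))
  cat(sprintf("  difference      %.4f\n", x$difference))
  invisible(x)
}

#' Per-organ overlap of two gene-set collections
#'
#' For every organ present in both collections, partitions the union of
#' the two gene sets into genes found by both, by the pipeline only, and
#' by the reference only, as percentages of the union (summing to 100).
#'
#' @param genes_pipeline,genes_reference Named lists of gene identifier
#'   vectors, one element per organ.
#' @return Data.frame with columns \code{organ}, \code{n_union},
#'   \code{pct_common}, \code{pct_pipeline_only}, \code{pct_reference_only}.
#' @export
overlap_summary <- function(genes_pipeline, genes_reference) {
  organs <- intersect(names(genes_pipeline), names(genes_reference))
  if (length(organs) == 0L) stop("no shared organs")
  rows <- lapply(organs, function(o) {
    a <- unique(genes_pipeline[[o]])
    b <- unique(genes_reference[[o]])
    u <- union(a, b)
    if (length(u) == 0L) stop("empty union of gene sets for organ ", o)
    data.frame(organ = o, n_union = length(u),
               pct_common = 100 * length(intersect(a, b)) / length(u),
               pct_pipeline_only = 100 * length(setdiff(a, b)) / length(u),
               pct_reference_only = 100 * length(setdiff(b, a)) / length(u),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-organ correlation against a continuous reference atlas
#'
#' Aggregates the pipeline's ppb matrix to organ-level gene medians (over
#' the organ's samples, non-missing values), log2-transforms both sides
#' (dropping non-positive and missing values pairwise), and reports the
#' Pearson correlation over shared genes for each organ present in both.
#' Organs with fewer than \code{min_genes} usable shared genes are skipped
#' with a warning.
#'
#' @param ppb Genes x samples (or runs) ppb matrix.
#' @param sample_map A \code{sample_map} whose \code{sample_id} (or
#'   \code{run_name}) matches the columns of \code{ppb}.
#' @param atlas Genes x organs numeric reference matrix.
#' @param min_genes Minimum shared genes per organ (default 3).
#' @return Data.frame with columns \code{organ}, \code{n_genes}, \code{r}.
#' @export
continuous_atlas_correlation <- function(ppb, sample_map, atlas,
                                         min_genes = 3L) {
  idx <- match(colnames(ppb), sample_map$sample_id)
  if (anyNA(idx)) idx <- match(colnames(ppb), sample_map$run_name)
  if (anyNA(idx)) {
    stop("ppb columns not resolvable through the sample map")
  }
  organ_of <- sample_map$organ[idx]
  organs <- intersect(unique(organ_of), colnames(atlas))
  rows <- list()
  for (o in organs) {
    med <- apply(ppb[, organ_of == o, drop = FALSE], 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) stats::median(v) else NA_real_
    })
    shared <- intersect(names(med), rownames(atlas))
    a <- med[shared]
    b <- atlas[shared, o]
    keep <- !is.na(a) & !is.na(b) & a > 0 & b > 0
    if (sum(keep) < min_genes) {
      warning("organ '", o, "' skipped: fewer than ", min_genes,
              " usable shared genes")
      next
    }
    rows[[o]] <- data.frame(organ = o, n_genes = sum(keep),
                            r = stats::cor(log2(a[keep]), log2(b[keep])),
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(organ = character(), n_genes = integer(),
                      r = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
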