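#' Summarize sample-level bins per organ
#'
#' For each gene and organ, the organ-level bin is the median of the
#' non-missing sample bins over all samples of that organ (across tissues
#' and datasets), rounded half up; a gene missing in every sample of an
#' organ gets \code{NA}. Organs with no samples are dropped with a warning.
#'
#' @param binned A \code{binned_matrix} (genes x samples), batch rules
#'   applied.
#' @param sample_map A \code{sample_map} covering the sample columns.
#' @return Genes x organs integer matrix.
#' @export
organ_bin_profile <- function(binned, sample_map) {
  idx <- match(colnames(binned), sample_map$sample_id)
  if (anyNA(idx)) {
    stop("sample(s) absent from the sample map: ",
         paste(colnames(binned)[is.na(idx)], collapse = ", "))
  }
  organ_of <- sample_map$organ[idx]
  organs <- unique(sample_map$organ)
  absent <- setdiff(organs, organ_of)
  if (length(absent)) {
    warning("organ(s) with zero samples excluded: ",
            paste(absent, collapse = ", "))
    organs <- setdiff(organs, absent)
  }
  out <- matrix(NA_integer_, nrow = nrow(binned), ncol = length(organs),
                dimnames = list(rownames(binned), organs))
  for (o in organs) {
    sub <- binned[, organ_of == o, drop = FALSE]
    med <- apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) .round_half_up(stats::median(v)) else NA_real_
    })
    out[, o] <- as.integer(med)
  }
  out
}

#' Classify genes as organ-enriched, group-enriched or mixed
#'
#' Implements a bin-level variant of the tissue-specificity scheme used for
#' expression atlases. For each gene, the mean bin value across all organs
#' is computed (by default including the candidate organ, with \code{NA}
#' organs counted as 0, so that absence elsewhere strengthens specificity);
#' the enrichment threshold is twice that mean. Organs whose bin reaches
#' the threshold form the enriched set E:
#' \itemize{
#'   \item \code{|E| == 1}: organ-enriched — one unique organ with bin
#'     values twofold higher than the mean bin across all organs;
#'   \item \code{2 <= |E| <= group_max} (default 7): group-enriched;
#'   \item otherwise: mixed.
#' }
#' A gene with no detected organ at all is classified mixed and flagged
#' \code{"undetected"}. The categories partition all classified genes.
#'
#' Note a consequence of the twofold rule on a bounded bin scale: a gene
#' expressed at a similar level everywhere can never be enriched (for a
#' constant profile the threshold exceeds the maximum bin), so enrichment
#' requires genuinely low or absent signal in the non-enriched organs.
#'
#' @param profile Genes x organs matrix from [organ_bin_profile()] (or a
#'   single named profile vector).
#' @param group_max Largest enriched-set size still called group-enriched.
#' @param inclusive If \code{TRUE} (default) the threshold comparison is
#'   \code{>=}; set \code{FALSE} for strict \code{>}.
#' @param na_as_zero Count \code{NA} organs as 0 in the mean (default
#'   \code{TRUE}).
#' @param exclude_self If \code{TRUE}, each candidate organ is compared
#'   against twice the mean of the \emph{other} organs instead (the
#'   original transcriptome-atlas variant); the reported \code{mean_bin}
#'   and \code{threshold} then refer to the all-organ mean.
#' @return Data.frame of class \code{specificity_result} with columns
#'   \code{gene_id}, \code{category}, \code{enriched_organs}
#'   (semicolon-separated), \code{n_enriched}, \code{mean_bin},
#'   \code{threshold}, \code{flag}.
#' @export
classify_specificity <- function(profile, group_max = 7L, inclusive = TRUE,
                                 na_as_zero = TRUE, exclude_self = FALSE) {
  if (!is.matrix(profile)) profile <- matrix(profile, nrow = 1L,
                                             dimnames = list("gene",
                                                             names(profile)))
  if (ncol(profile) < 2L) stop("need bins for at least 2 organs")
  organs <- colnames(profile)
  n <- nrow(profile)
  category <- character(n)
  enriched <- character(n)
  n_enr <- integer(n)
  mean_bin <- numeric(n)
  threshold <- numeric(n)
  flag <- character(n)
  cmp <- if (inclusive) `>=` else `>`
  for (i in seq_len(n)) {
    v <- profile[i, ]
    if (all(is.na(v))) {
      category[i] <- "mixed"; flag[i] <- "undetected"
      next
    }
    v0 <- if (na_as_zero) ifelse(is.na(v), 0, v) else v
    mean_bin[i] <- mean(v0, na.rm = TRUE)
    threshold[i] <- 2 * mean_bin[i]
    if (exclude_self) {
      k <- sum(!is.na(v0))
      tot <- sum(v0, na.rm = TRUE)
      other_mean <- (tot - v0) / (k - 1)
      e <- which(!is.na(v) & !is.na(other_mean) & cmp(v, 2 * other_mean))
    } else {
      e <- which(!is.na(v) & cmp(v, threshold[i]))
    }
    n_enr[i] <- length(e)
    category[i] <- if (length(e) == 1L) "organ-enriched"
                   else if (length(e) >= 2L && length(e) <= group_max)
                     "group-enriched"
                   else "mixed"
    if (length(e) && category[i] != "mixed") {
      enriched[i] <- paste(organs[e], collapse = ";")
    } else {
      n_enr[i] <- if (category[i] == "mixed") 0L else n_enr[i]
      enriched[i] <- ""
    }
  }
  out <- data.frame(gene_id = rownames(profile), category = category,
                    enriched_organs = enriched, n_enriched = n_enr,
                    mean_bin = mean_bin, threshold = threshold, flag = flag,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("specificity_result", "data.frame")
  out
}

#' Gene lists of enriched genes per organ
#'
#' Collects, for each organ, the organ-enriched and group-enriched genes
#' whose enriched set contains that organ — the input lists typically fed
#' to downstream over-representation tools.
#'
#' @param spec A \code{specificity_result}.
#' @return Named list of character vectors, one per organ.
#' @export
enriched_gene_lists <- function(spec) {
  keep <- spec$category %in% c("organ-enriched", "group-enriched")
  sets <- strsplit(spec$enriched_organs[keep], ";", fixed = TRUE)
  genes <- rep(spec$gene_id[keep], lengths(sets))
  organ <- unlist(sets)
  if (!length(organ)) return(list())
  lapply(split(genes, organ), unique)
}
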