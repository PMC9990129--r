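#' Fraction-of-total (FOT) normalization to parts per billion
#'
#' Scales each protein's iBAQ intensity by the total signal of its MS run
#' and expresses the result in parts per billion:
#' \code{ppb_i = ibaq_i / sum_j(ibaq_j) * 1e9}, the sum running over the
#' non-missing intensities of that run. Missing values stay missing. After
#' normalization every run's non-missing ppb values sum to 1e9 (up to
#' floating-point round-off), and the result is invariant under any global
#' rescaling of the run, which is what makes ppb values comparable across
#' acquisition depths.
#'
#' Normalization is intended to run after [filter_protein_groups()], so
#' that contaminant and decoy signal does not distort the denominator.
#'
#' @param x A numeric vector (one run) or matrix (runs in columns) of iBAQ
#'   intensities with \code{NA} for non-detections, or a
#'   \code{protein_groups} object whose \code{ibaq} slot is replaced by ppb.
#' @return Same shape as the input, in ppb.
#' @export
fot_normalize <- function(x) UseMethod("fot_normalize")

#' @export
fot_normalize.default <- function(x) {
  if (is.matrix(x)) {
    bad <- colSums(!is.na(x)) == 0L
    if (any(bad)) {
      stop("run(s) with no detected intensities: ",
           paste(colnames(x)[bad], collapse = ", "))
    }
    if (any(x < 0, na.rm = TRUE)) stop("negative intensity")
    totals <- colSums(x, na.rm = TRUE)
    return(sweep(x, 2L, totals, "/") * 1e9)
  }
  if (all(is.na(x))) stop("run with no detected intensities")
  if (any(x < 0, na.rm = TRUE)) stop("negative intensity")
  x / sum(x, na.rm = TRUE) * 1e9
}

#' @export
fot_normalize.protein_groups <- function(x) {
  x$ibaq <- fot_normalize.default(x$ibaq)
  x
}

#' Collapse protein groups to canonical genes
#'
#' Maps each protein group to the set of distinct gene identifiers of its
#' majority protein IDs (isoform accessions of one gene collapse to that
#' gene, so isoform-only groups are kept). Groups whose majority IDs map to
#' more than one gene are excluded with reason \code{"multi-gene"}; groups
#' with any unmapped accession are excluded with reason \code{"unmapped"}.
#' When several groups map to the same gene, the gene's per-run value is
#' the median of their non-missing ppb values (missing if all are missing).
#' The resulting gene-level entity is the canonical protein.
#'
#' @param pg A filtered \code{protein_groups} object whose \code{ibaq} slot
#'   holds ppb values (see [fot_normalize()]).
#' @param gene_map Data.frame with columns \code{accession}, \code{gene_id}
#'   (see [read_gene_map()]).
#' @return A list with \code{ppb}, a genes x runs numeric matrix, and
#'   \code{excluded}, a data.frame (\code{group_id}, \code{majority_ids},
#'   \code{genes}, \code{reason}) of groups left out of the gene matrix.
#' @export
map_groups_to_genes <- function(pg, gene_map) {
  stopifnot(inherits(pg, "protein_groups"))
  lookup <- stats::setNames(gene_map$gene_id, gene_map$accession)
  n <- length(pg$group_id)
  gene_of <- character(n)
  reason <- rep(NA_character_, n)
  genes_str <- character(n)
  for (i in seq_len(n)) {
    acc <- pg$majority_protein_ids[[i]]
    g <- unname(lookup[acc])
    if (anyNA(g)) {
      reason[i] <- "unmapped"
      genes_str[i] <- paste(unique(g[!is.na(g)]), collapse = ";")
    } else {
      gu <- unique(g)
      genes_str[i] <- paste(gu, collapse = ";")
      if (length(gu) > 1L) reason[i] <- "multi-gene" else gene_of[i] <- gu
    }
  }
  keep <- is.na(reason)
  excluded <- data.frame(
    group_id = pg$group_id[!keep],
    majority_ids = vapply(pg$majority_protein_ids[!keep], paste, "",
                          collapse = ";"),
    genes = genes_str[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  genes <- sort(unique(gene_of[keep]))
  ppb <- matrix(NA_real_, nrow = length(genes), ncol = ncol(pg$ibaq),
                dimnames = list(genes, colnames(pg$ibaq)))
  idx <- split(which(keep), gene_of[keep])
  for (g in names(idx)) {
    rows <- idx[[g]]
    if (length(rows) == 1L) {
      ppb[g, ] <- pg$ibaq[rows, ]
    } else {
      ppb[g, ] <- apply(pg$ibaq[rows, , drop = FALSE], 2L,
                        function(v) {
                          v <- v[!is.na(v)]
                          if (length(v)) stats::median(v) else NA_real_
                        })
    }
  }
  list(ppb = ppb, excluded = excluded)
}
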