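#' Filter a protein-group table before quantification
#'
#' Removes potential contaminants, decoy (reversed-sequence) hits, and
#' protein groups with fewer than \code{min_psm} peptide-spectrum matches,
#' preserving the original row order. A row failing several criteria is
#' counted once in the report, with precedence decoy > contaminant >
#' low_psm, so that \code{nrow(input) == nrow(output) + sum(report$removed)}
#' always holds. Filtering is idempotent.
#'
#' @param pg A \code{protein_groups} object.
#' @param min_psm Minimum PSM count to keep a group (default 2, i.e. groups
#'   with fewer than 2 PSMs are dropped).
#' @return A list with elements \code{groups} (the filtered
#'   \code{protein_groups}) and \code{report}, a data.frame with columns
#'   \code{reason} (\code{"decoy"}, \code{"contaminant"}, \code{"low_psm"})
#'   and \code{removed}.
#' @export
filter_protein_groups <- function(pg, min_psm = 2L) {
  stopifnot(inherits(pg, "protein_groups"), min_psm >= 0)
  low <- pg$psm_count < min_psm
  reason <- rep(NA_character_, length(pg$group_id))
  reason[low] <- "low_psm"
  reason[pg$is_contaminant] <- "contaminant"
  reason[pg$is_decoy] <- "decoy"
  keep <- is.na(reason)
  report <- data.frame(
    reason = c("decoy", "contaminant", "low_psm"),
    removed = c(sum(reason == "decoy", na.rm = TRUE),
                sum(reason == "contaminant", na.rm = TRUE),
                sum(reason == "low_psm", na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  list(groups = pg[keep], report = report)
}
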