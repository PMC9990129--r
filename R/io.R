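#' Read a MaxQuant-style proteinGroups.txt table
#'
#' Parses the tab-separated protein-group output of a label-free MaxQuant
#' search into a \code{protein_groups} object. Only the columns needed for
#' downstream abundance post-processing are consumed: the majority protein
#' identifiers, the per-run iBAQ intensities, the group-level MS/MS (PSM)
#' count, and the decoy / contaminant flags.
#'
#' iBAQ cells that are empty or exactly \code{"0"} are treated as missing:
#' MaxQuant emits 0 for non-detection, and fraction-of-total normalization
#' and rank binning must exclude non-detections.
#'
#' @param path Path to a tab-separated file whose header contains
#'   \code{"Majority protein IDs"} and at least one column whose name starts
#'   with \code{"iBAQ "}.
#' @param psm_column Name of the column holding the group-level PSM count.
#'   MaxQuant writes the dataset-total count as \code{"MS/MS count"}; some
#'   versions expose razor+unique counts under a different header.
#' @return An object of class \code{protein_groups}: a list with elements
#'   \code{group_id}, \code{protein_ids} (list of character vectors),
#'   \code{majority_protein_ids} (list of character vectors),
#'   \code{psm_count}, \code{is_decoy}, \code{is_contaminant}, and
#'   \code{ibaq}, a numeric matrix (groups x runs, \code{NA} = not detected)
#'   whose column names are the run names with the \code{"iBAQ "} prefix
#'   stripped.
#' @seealso [filter_protein_groups()], [fot_normalize()],
#'   [map_groups_to_genes()]
#' @export
read_protein_groups <- function(path, psm_column = "MS/MS count") {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL, stringsAsFactors = FALSE)
  names(df) <- trimws(names(df))
  for (col in c("Majority protein IDs", psm_column)) {
    if (!col %in% names(df)) {
      stop("protein groups file '", path, "' lacks mandatory column '",
           col, "'", call. = FALSE)
    }
  }
  ibaq_cols <- grep("^iBAQ ", names(df), value = TRUE)
  if (length(ibaq_cols) == 0L) {
    stop("protein groups file '", path,
         "' lacks mandatory column 'iBAQ <run>'", call. = FALSE)
  }
  n <- nrow(df)
  majority <- strsplit(df[["Majority protein IDs"]], ";", fixed = TRUE)
  majority <- lapply(majority, trimws)
  protein_ids <- if ("Protein IDs" %in% names(df)) {
    lapply(strsplit(df[["Protein IDs"]], ";", fixed = TRUE), trimws)
  } else {
    majority
  }
  flag <- function(col) {
    if (col %in% names(df)) trimws(df[[col]]) == "+" else rep(FALSE, n)
  }
  psm_raw <- trimws(df[[psm_column]])
  psm <- suppressWarnings(as.integer(psm_raw))
  psm[psm_raw == ""] <- 0L
  if (anyNA(psm)) {
    stop("non-numeric PSM count at row ",
         which(is.na(psm))[1L], call. = FALSE)
  }
  ibaq <- matrix(NA_real_, nrow = n, ncol = length(ibaq_cols),
                 dimnames = list(NULL, sub("^iBAQ ", "", ibaq_cols)))
  for (j in seq_along(ibaq_cols)) {
    raw <- trimws(df[[ibaq_cols[j]]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & !(raw %in% c("", "NA", "NaN"))
    if (any(bad)) {
      stop("non-numeric intensity in column '", ibaq_cols[j], "' at row ",
           which(bad)[1L], call. = FALSE)
    }
    val[raw %in% c("", "NA", "NaN")] <- NA_real_
    val[!is.na(val) & val == 0] <- NA_real_
    ibaq[, j] <- val
  }
  new_protein_groups(
    group_id = sprintf("grp%05d", seq_len(n)),
    protein_ids = protein_ids,
    majority_protein_ids = majority,
    psm_count = psm,
    is_decoy = flag("Reverse"),
    is_contaminant = flag("Potential contaminant"),
    ibaq = ibaq
  )
}

#' Construct a protein_groups object
#'
#' Low-level constructor used by [read_protein_groups()] and the synthetic
#' data generator. Validates the container invariants: equal lengths, the
#' majority identifiers being a subset of the group's identifiers, and
#' non-negative PSM counts and intensities.
#'
#' @param group_id Character vector of opaque row keys.
#' @param protein_ids,majority_protein_ids Lists of accession vectors.
#' @param psm_count Integer vector of group-level PSM counts.
#' @param is_decoy,is_contaminant Logical flags.
#' @param ibaq Numeric matrix, groups x runs; \code{NA} means not detected.
#' @return A \code{protein_groups} object.
#' @export
new_protein_groups <- function(group_id, protein_ids, majority_protein_ids,
                               psm_count, is_decoy, is_contaminant, ibaq) {
  n <- length(group_id)
  stopifnot(length(protein_ids) == n, length(majority_protein_ids) == n,
            length(psm_count) == n, length(is_decoy) == n,
            length(is_contaminant) == n, nrow(ibaq) == n)
  if (any(psm_count < 0L)) stop("psm_count must be non-negative")
  if (any(!is.na(ibaq) & ibaq < 0)) stop("iBAQ intensities must be non-negative")
  ok <- mapply(function(m, p) all(m %in% p), majority_protein_ids, protein_ids)
  if (!all(ok)) {
    stop("majority protein IDs must be a subset of the group's protein IDs ",
         "(row ", which(!ok)[1L], ")")
  }
  structure(list(group_id = group_id,
                 protein_ids = protein_ids,
                 majority_protein_ids = majority_protein_ids,
                 psm_count = as.integer(psm_count),
                 is_decoy = is_decoy,
                 is_contaminant = is_contaminant,
                 ibaq = ibaq),
            class = "protein_groups")
}

#' @export
print.protein_groups <- function(x, ...) {
  cat("protein_groups:", length(x$group_id), "groups x",
      ncol(x$ibaq), "runs\n")
  cat("  decoys:", sum(x$is_decoy),
      " contaminants:", sum(x$is_contaminant),
      " median PSM:", stats::median(x$psm_count), "\n")
  invisible(x)
}

#' Subset a protein_groups object by row
#'
#' @param x A \code{protein_groups} object.
#' @param i Row index (logical or integer).
#' @param ... Ignored.
#' @return The subsetted \code{protein_groups} object.
#' @export
`[.protein_groups` <- function(x, i, ...) {
  new_protein_groups(x$group_id[i], x$protein_ids[i],
                     x$majority_protein_ids[i], x$psm_count[i],
                     x$is_decoy[i], x$is_contaminant[i],
                     x$ibaq[i, , drop = FALSE])
}

#' Write a protein_groups object as a MaxQuant-style TSV
#'
#' Inverse of [read_protein_groups()]: missing intensities are written as
#' \code{0} (the MaxQuant convention for non-detection), flags as \code{"+"}.
#'
#' @param pg A \code{protein_groups} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_protein_groups <- function(pg, path) {
  ibaq_chr <- apply(pg$ibaq, 2, function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "0"
    out
  })
  if (is.null(dim(ibaq_chr))) ibaq_chr <- matrix(ibaq_chr, nrow = 1L)
  df <- data.frame(
    `Protein IDs` = vapply(pg$protein_ids, paste, "", collapse = ";"),
    `Majority protein IDs` = vapply(pg$majority_protein_ids, paste, "",
                                    collapse = ";"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(pg$ibaq))) {
    df[[paste0("iBAQ ", colnames(pg$ibaq)[j])]] <- ibaq_chr[, j]
  }
  df[["MS/MS count"]] <- pg$psm_count
  df[["Reverse"]] <- ifelse(pg$is_decoy, "+", "")
  df[["Potential contaminant"]] <- ifelse(pg$is_contaminant, "+", "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# header synonyms for the SDRF-like sample map, matched case-insensitively
# after trimming; first hit wins
.sample_map_synonyms <- list(
  run_name   = c("run_name", "comment[data file]", "assay name", "run"),
  sample_id  = c("sample_id", "source name", "sample"),
  tissue     = c("tissue", "characteristics[organism part]"),
  organ      = c("organ", "characteristics[organ]"),
  dataset_id = c("dataset_id", "comment[dataset]", "dataset"),
  condition  = c("condition", "characteristics[disease]", "disease")
)

#' Read an SDRF-like sample map
#'
#' Maps MS runs to samples, tissues, organs, datasets and condition. A
#' "tissue" is a distinct functional or structural region within an "organ"
#' (e.g. left ventricle, aorta and tricuspid valve are tissues of the
#' heart); all samples of one tissue within one dataset form a batch, the
#' unit within which the missing-value rules of rank binning apply.
#'
#' @param path Tab-separated file with columns for run, sample, tissue,
#'   organ, dataset and condition. SDRF-style headers
#'   (\code{"comment[data file]"}, \code{"characteristics[organism part]"},
#'   ...) are recognized by default.
#' @param synonyms Named list of accepted header synonyms per field;
#'   override to adapt other dialects.
#' @return A \code{data.frame} of class \code{sample_map} with columns
#'   \code{run_name}, \code{sample_id}, \code{tissue}, \code{organ},
#'   \code{dataset_id}, \code{condition} and the derived \code{batch}
#'   (\code{dataset_id} x \code{tissue}).
#' @export
read_sample_map <- function(path, synonyms = .sample_map_synonyms) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  names(df) <- trimws(names(df))
  lower <- tolower(names(df))
  pick <- function(field) {
    hit <- match(tolower(synonyms[[field]]), lower)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) {
      stop("sample map '", path, "' has no column for '", field,
           "' (accepted: ", paste(synonyms[[field]], collapse = ", "), ")",
           call. = FALSE)
    }
    trimws(df[[hit[1L]]])
  }
  out <- data.frame(run_name = pick("run_name"),
                    sample_id = pick("sample_id"),
                    tissue = pick("tissue"),
                    organ = pick("organ"),
                    dataset_id = pick("dataset_id"),
                    condition = pick("condition"),
                    stringsAsFactors = FALSE)
  as_sample_map(out)
}

#' Validate and classify a sample map data.frame
#'
#' @param df A data.frame with columns \code{run_name}, \code{sample_id},
#'   \code{tissue}, \code{organ}, \code{dataset_id}, \code{condition}.
#' @return The validated \code{sample_map} with a derived \code{batch}
#'   column.
#' @export
as_sample_map <- function(df) {
  needed <- c("run_name", "sample_id", "tissue", "organ", "dataset_id",
              "condition")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("sample map lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$run_name)) {
    stop("duplicated run_name in sample map: ",
         df$run_name[duplicated(df$run_name)][1L])
  }
  sample_ds <- tapply(df$dataset_id, df$sample_id,
                      function(x) length(unique(x)))
  if (any(sample_ds > 1L)) {
    stop("sample assigned to more than one dataset: ",
         names(sample_ds)[sample_ds > 1L][1L])
  }
  df$batch <- paste(df$dataset_id, df$tissue, sep = "//")
  rownames(df) <- NULL
  class(df) <- c("sample_map", "data.frame")
  df
}

#' Write a sample map as an SDRF-like TSV
#'
#' @param sm A \code{sample_map}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_sample_map <- function(sm, path) {
  df <- data.frame(`source name` = sm$sample_id,
                   `characteristics[organism part]` = sm$tissue,
                   `characteristics[organ]` = sm$organ,
                   `characteristics[disease]` = sm$condition,
                   `comment[data file]` = sm$run_name,
                   `comment[dataset]` = sm$dataset_id,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein accession to gene identifier mapping table
#'
#' The table stands in for an annotation service: each accession (isoform
#' suffixes permitted, e.g. \code{"P12345-2"}) maps to exactly one stable
#' gene identifier. Lookups of unknown accessions yield \code{NA}, which is
#' distinguishable from a mapped accession.
#'
#' @param path Tab-separated file with columns \code{accession} and
#'   \code{gene_id}.
#' @return A data.frame with columns \code{accession}, \code{gene_id}.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("accession", "gene_id") %in% names(df))) {
    stop("gene map '", path, "' must have columns 'accession' and 'gene_id'")
  }
  if (anyDuplicated(df$accession)) {
    dup <- df$accession[duplicated(df$accession)][1L]
    stop("accession mapped more than once in gene map: ", dup)
  }
  df[c("accession", "gene_id")]
}

.atlas_levels <- c("not detected", "low", "medium", "high",
                   "ascending", "descending", "not representative")
.atlas_reliability <- c("enhanced", "supported", "approved", "uncertain")

#' Read a categorical reference atlas
#'
#' Parses an HPA-style table of categorical protein abundance levels per
#' gene and organ, with a reliability score per row.
#'
#' @param path Tab-separated file with columns \code{gene_id}, \code{organ},
#'   \code{level} and \code{reliability}.
#' @return A data.frame of class \code{categorical_atlas}.
#' @seealso [map_categorical_levels()] for the numeric conversion used in
#'   atlas comparison.
#' @export
read_categorical_atlas <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  needed <- c("gene_id", "organ", "level", "reliability")
  if (!all(needed %in% names(df))) {
    stop("categorical atlas '", path, "' must have columns: ",
         paste(needed, collapse = ", "))
  }
  as_categorical_atlas(df[needed])
}

#' Validate a categorical atlas data.frame
#'
#' @param df Data.frame with columns \code{gene_id}, \code{organ},
#'   \code{level}, \code{reliability}.
#' @return The validated \code{categorical_atlas}.
#' @export
as_categorical_atlas <- function(df) {
  bad <- setdiff(unique(df$level), .atlas_levels)
  if (length(bad)) {
    stop("unknown abundance level '", bad[1L], "'; allowed levels: ",
         paste(.atlas_levels, collapse = ", "))
  }
  bad <- setdiff(unique(df$reliability), .atlas_reliability)
  if (length(bad)) {
    stop("unknown reliability '", bad[1L], "'; allowed: ",
         paste(.atlas_reliability, collapse = ", "))
  }
  if (anyDuplicated(df[c("gene_id", "organ")])) {
    stop("duplicated (gene_id, organ) pair in categorical atlas")
  }
  rownames(df) <- NULL
  class(df) <- c("categorical_atlas", "data.frame")
  df
}

#' Write / read a genes-by-samples abundance or bin matrix
#'
#' Plain TSV with the gene identifier in the first column and one column
#' per sample; missing cells are written as \code{"NA"}. The round trip
#' \code{read_matrix(write_matrix(x))} reproduces \code{x} exactly,
#' including \code{NA} cells (values are serialized at full double
#' precision).
#'
#' @param x Numeric matrix with gene row names and sample column names.
#' @param path File path.
#' @return \code{write_matrix} returns \code{path} invisibly;
#'   \code{read_matrix} returns the numeric matrix.
#' @export
write_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  chr <- sprintf("%.17g", x)
  chr[is.na(x)] <- "NA"
  dim(chr) <- dim(x)
  df <- data.frame(gene_id = rownames(x), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("gene_id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}
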