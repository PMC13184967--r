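#' Construct a community matrix
#'
#' The central data object: a taxa-by-samples matrix of non-negative integer
#' counts together with per-sample metadata (treatment, replicate, numeric
#' timepoint). All downstream analyses (null models, ordination, indicator
#' species, networks) consume this object.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns, with
#'   dimnames. Values must be non-negative integers (see `strict`).
#' @param metadata data frame with columns `sample`, `treatment`,
#'   `replicate`, `timepoint`; one row per sample column of `counts`.
#' @param strict if `TRUE` (default) non-integer counts are an error; if
#'   `FALSE` they are rounded half-to-even (with a message), matching the
#'   integer-rounding convention used by count-based null models.
#' @return An object of class `community_matrix`: a list with elements
#'   `counts` (integer matrix) and `metadata` (data frame, one row per
#'   sample, in column order of `counts`).
#' @export
#' @examples
#' cm <- community_matrix(
#'   matrix(c(5L, 3L, 0L, 2L), 2, 2,
#'          dimnames = list(c("t1", "t2"), c("s1", "s2"))),
#'   data.frame(sample = c("s1", "s2"), treatment = "glucose",
#'              replicate = c("r1", "r2"), timepoint = 0)
#' )
#' cm
community_matrix <- function(counts, metadata, strict = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxa ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and non-missing")
  if (any(counts < 0)) stop("negative count found in the table")
  if (any(counts != floor(counts))) {
    if (strict) stop("non-integer counts found; use strict = FALSE to round half-to-even")
    message("rounding non-integer counts half-to-even")
    counts <- round(counts)
  }
  storage.mode(counts) <- "integer"

  metadata <- as.data.frame(metadata)
  need <- c("sample", "treatment", "replicate", "timepoint")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample))
    stop("duplicate sample ids in metadata")
  absent <- setdiff(colnames(counts), metadata$sample)
  if (length(absent))
    stop("metadata missing row(s) for sample(s): ", paste(absent, collapse = ", "))
  metadata <- metadata[match(colnames(counts), metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  metadata$timepoint <- as.numeric(metadata$timepoint)
  if (anyNA(metadata$timepoint)) stop("non-numeric timepoint in metadata")

  zero_samples <- colSums(counts) == 0
  if (any(zero_samples))
    stop("all-zero sample(s): ", paste(colnames(counts)[zero_samples], collapse = ", "))
  if (any(rowSums(counts) == 0))
    warning("all-zero taxa present (kept): ",
            sum(rowSums(counts) == 0), " taxa", call. = FALSE)

  structure(list(counts = counts, metadata = metadata), class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d taxa x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  treatments: %s\n",
              paste(unique(x$metadata$treatment), collapse = ", ")))
  cat(sprintf("  replicates: %d, timepoints: %d\n",
              length(unique(x$metadata$replicate)),
              length(unique(x$metadata$timepoint))))
  invisible(x)
}

#' @rdname community_matrix
#' @param cm a `community_matrix`.
#' @export
taxa_ids <- function(cm) rownames(cm$counts)

#' @rdname community_matrix
#' @export
sample_ids <- function(cm) colnames(cm$counts)

#' Read a community table and sample metadata from disk
#'
#' Reads a TSV count table (taxa rows x sample columns, first column the
#' taxon id) or a BIOM-format JSON table, plus a TSV metadata table with
#' columns `sample`, `treatment`, `replicate`, `timepoint`. Table orientation
#' (taxa-rows vs samples-rows) is auto-detected by matching ids against the
#' metadata; an ambiguous table is an error, never a guess.
#'
#' @param table_path path to the count table (`.tsv`/`.txt`, or `.json`/
#'   `.biom` for BIOM JSON, which requires the `biomformat` package).
#' @param metadata_path path to the metadata TSV.
#' @param strict passed to [community_matrix()].
#' @return A validated [community_matrix()].
#' @export
read_community <- function(table_path, metadata_path, strict = TRUE) {
  metadata <- read.delim(metadata_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (grepl("\\.(json|biom)$", table_path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM tables requires the 'biomformat' package")
    b <- biomformat::read_biom(table_path)
    counts <- as.matrix(biomformat::biom_data(b))
  } else {
    tab <- read.delim(table_path, check.names = FALSE,
                      stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    counts <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(counts)) stop("non-numeric values in the count table")
    rownames(counts) <- ids
  }
  samp <- as.character(metadata$sample)
  cols_are_samples <- all(colnames(counts) %in% samp)
  rows_are_samples <- all(rownames(counts) %in% samp)
  if (cols_are_samples && rows_are_samples)
    stop("table orientation ambiguous: both row and column ids match metadata samples")
  if (!cols_are_samples && rows_are_samples) counts <- t(counts)
  if (!cols_are_samples && !rows_are_samples)
    stop("metadata missing row(s) for sample(s): ",
         paste(setdiff(colnames(counts), samp), collapse = ", "))
  community_matrix(counts, metadata, strict = strict)
}

#' Write a community matrix as TSV files
#'
#' @param cm a [community_matrix()].
#' @param table_path,metadata_path output paths.
#' @return `table_path`, invisibly.
#' @export
write_community <- function(cm, table_path, metadata_path) {
  tab <- data.frame(taxon = taxa_ids(cm), cm$counts, check.names = FALSE)
  write.table(tab, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$metadata, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(table_path)
}

#' Total sum scaling (TSS) normalization
#'
#' Converts counts to relative abundances: each sample column is divided by
#' its total, so columns sum to one. This is the standard normalization ahead
#' of Bray-Curtis dissimilarity, ordination and the phylogenetic null models;
#' taxonomic (Raup-Crick) null models use the raw integer counts instead.
#'
#' @param cm a [community_matrix()], or a numeric matrix (taxa x samples).
#' @return A numeric matrix of proportions with the same dimnames; class
#'   `relative_abundance`.
#' @export
#' @examples
#' m <- matrix(c(2, 2, 4), 3, 1, dimnames = list(paste0("t", 1:3), "s1"))
#' tss_normalize(m)
tss_normalize <- function(cm) {
  m <- if (inherits(cm, "community_matrix")) cm$counts else as.matrix(cm)
  tot <- colSums(m)
  if (any(tot == 0)) stop("zero-sum sample(s): ",
                          paste(colnames(m)[tot == 0], collapse = ", "))
  out <- sweep(m, 2, tot, "/")
  class(out) <- c("relative_abundance", class(out))
  out
}

#' Internal-standard correction of qPCR 16S quantification
#'
#' Corrects a measured 16S copy concentration for DNA extraction efficiency
#' using a spiked internal standard (e.g. an EGFP plasmid): the measurement
#' is multiplied by the ratio of spiked to recovered standard copies. Volume
#' scaling, if any, is left to the caller.
#'
#' @param measured_16s_copies positive: measured 16S copies/ml.
#' @param spiked_egfp_copies positive: standard copies added per extraction.
#' @param recovered_egfp_copies positive: standard copies recovered.
#' @return Corrected 16S copies/ml.
#' @export
#' @examples
#' normalize_qpcr(1e6, 1e7, 5e6)  # recovery 50% -> 2e6
normalize_qpcr <- function(measured_16s_copies, spiked_egfp_copies,
                           recovered_egfp_copies) {
  vals <- c(measured_16s_copies, spiked_egfp_copies, recovered_egfp_copies)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all qPCR quantities must be positive")
  measured_16s_copies * (spiked_egfp_copies / recovered_egfp_copies)
}

#' Restrict a community matrix to a subset of taxa and/or samples
#'
#' @param cm a [community_matrix()].
#' @param taxa,samples character vectors of ids to keep (default all).
#' @param drop_empty_samples drop samples whose counts become all zero after
#'   taxon subsetting (default `TRUE`, with a message).
#' @return A [community_matrix()].
#' @export
subset_community <- function(cm, taxa = taxa_ids(cm), samples = sample_ids(cm),
                             drop_empty_samples = TRUE) {
  stopifnot(inherits(cm, "community_matrix"))
  bad <- setdiff(taxa, taxa_ids(cm))
  if (length(bad)) stop("unknown taxa: ", paste(bad, collapse = ", "))
  bad <- setdiff(samples, sample_ids(cm))
  if (length(bad)) stop("unknown samples: ", paste(bad, collapse = ", "))
  counts <- cm$counts[taxa, samples, drop = FALSE]
  empty <- colSums(counts) == 0
  if (any(empty)) {
    if (!drop_empty_samples)
      stop("subsetting produced all-zero sample(s): ",
           paste(colnames(counts)[empty], collapse = ", "))
    message("dropping ", sum(empty), " sample(s) left empty by the taxon subset")
    counts <- counts[, !empty, drop = FALSE]
  }
  md <- cm$metadata[match(colnames(counts), cm$metadata$sample), , drop = FALSE]
  suppressWarnings(community_matrix(counts, md))
}
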