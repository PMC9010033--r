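#' Construct an annotated OTU count table
#'
#' The central container of the package: a samples x OTUs matrix of
#' non-negative integer read counts together with per-sample annotations
#' (patient, body site, study day). Days are integers relative to the first
#' chemotherapy day (day 0); baseline samples collected before the start of
#' therapy may carry negative days.
#'
#' Samples whose counts sum to zero are dropped with a warning: they carry
#' no compositional information and would make relative abundances and
#' distances undefined. No minimum-depth filter beyond that is applied.
#'
#' @param counts numeric matrix (samples x OTUs) of non-negative finite
#'   integers. Row names, if present, must agree with `samples$sample_id`.
#' @param samples data.frame with columns `sample_id`, `patient_id`,
#'   `site` (one of `"oral"`, `"stool"`) and integer `day`, one row per
#'   row of `counts`.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (matrix with sample ids as row names and OTU ids as column names) and
#'   `samples` (the validated annotation data.frame).
#' @export
otu_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (!is.data.frame(samples)) stop("samples must be a data.frame")
  req <- c("sample_id", "patient_id", "site", "day")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0)
    stop("samples is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(samples) != nrow(counts))
    stop("samples has ", nrow(samples), " rows but counts has ", nrow(counts))
  samples$sample_id <- as.character(samples$sample_id)
  samples$patient_id <- as.character(samples$patient_id)
  samples$site <- as.character(samples$site)
  samples$day <- as.integer(samples$day)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  bad_site <- setdiff(unique(samples$site), c("oral", "stool"))
  if (length(bad_site) > 0)
    stop("site must be 'oral' or 'stool'; found: ", paste(bad_site, collapse = ", "))
  if (any(is.na(samples$patient_id) | samples$patient_id == ""))
    stop("every sample needs a patient_id")
  if (any(is.na(samples$day))) stop("every sample needs an integer day")
  if (!is.null(rownames(counts)) && !identical(rownames(counts), samples$sample_id))
    stop("rownames(counts) disagree with samples$sample_id")
  rownames(counts) <- samples$sample_id
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("OTU_%04d", seq_len(ncol(counts)))
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU ids")

  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " sample(s) with zero total counts: ",
            paste(samples$sample_id[zero], collapse = ", "))
    counts <- counts[!zero, , drop = FALSE]
    samples <- samples[!zero, , drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(counts = counts, samples = samples), class = "otu_table")
}

#' @exportS3Method base::print
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs\n")
  cat("  patients:", length(unique(x$samples$patient_id)),
      " sites:", paste(sprintf("%s=%d", names(table(x$samples$site)),
                               table(x$samples$site)), collapse = " "),
      " days:", paste(range(x$samples$day), collapse = ".."), "\n")
  invisible(x)
}

#' Number of samples / OTUs
#' @param x an `otu_table`
#' @return integer
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname n_samples
#' @export
n_otus <- function(x) ncol(x$counts)

#' Subset an OTU table by sample
#'
#' @param x an `otu_table`
#' @param keep logical or index vector over samples, or character sample ids
#' @return an `otu_table` restricted to the selected samples (OTU columns are
#'   kept as-is, including columns that become all-zero)
#' @export
subset_samples <- function(x, keep) {
  if (is.character(keep)) keep <- match(keep, x$samples$sample_id)
  counts <- x$counts[keep, , drop = FALSE]
  samples <- x$samples[keep, , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "otu_table")
}

#' Aggregate counts to a taxonomic rank and normalize to proportions
#'
#' Collapses OTU counts to the requested rank using a taxonomy map and
#' converts each sample to relative abundances. OTUs whose lineage is
#' unassigned at that rank are pooled into an explicit `"unclassified"`
#' bucket rather than silently dropped, so rows always sum to one.
#'
#' @param table an `otu_table`
#' @param taxonomy taxonomy data.frame from [read_taxonomy()] /
#'   [taxonomy_map()]: one row per OTU with rank columns
#' @param level taxonomic rank, one of the columns of `taxonomy`
#'   (default `"genus"`)
#' @return matrix (samples x taxa) of proportions; rows sum to 1
#' @export
relative_abundance <- function(table, taxonomy, level = "genus") {
  stopifnot(inherits(table, "otu_table"))
  if (!level %in% names(taxonomy))
    stop("taxonomy has no rank column '", level, "'")
  tot <- rowSums(table$counts)
  if (any(tot == 0))
    stop("zero-sum sample(s): ",
         paste(rownames(table$counts)[tot == 0], collapse = ", "))
  miss <- setdiff(colnames(table$counts), taxonomy$otu_id)
  if (length(miss) > 0)
    stop("OTU(s) absent from taxonomy: ", paste(miss, collapse = ", "))
  lin <- taxonomy[[level]][match(colnames(table$counts), taxonomy$otu_id)]
  lin[is.na(lin) | lin == ""] <- "unclassified"
  groups <- factor(lin, levels = unique(lin))
  # rowsum() aggregates columns after transpose: taxa x samples, then back
  agg <- t(rowsum(t(table$counts), group = groups))
  colnames(agg) <- levels(groups)
  agg / tot
}

#' Build a taxonomy map
#'
#' @param otu_id character vector of OTU ids
#' @param lineage character vector of semicolon-delimited lineages
#'   (domain;phylum;class;order;family;genus); short lineages are padded
#'   with `NA` at the missing ranks
#' @return data.frame with columns `otu_id`, `lineage` and one column per rank
#' @export
taxonomy_map <- function(otu_id, lineage) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  mat <- t(vapply(parts, function(p) {
    p <- trimws(p)
    length(p) <- length(ranks)
    p
  }, character(length(ranks))))
  colnames(mat) <- ranks
  out <- data.frame(otu_id = as.character(otu_id), lineage = as.character(lineage),
                    mat, stringsAsFactors = FALSE)
  if (anyDuplicated(out$otu_id)) stop("duplicate otu_id in taxonomy")
  rownames(out) <- NULL
  out
}
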