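#' Read an OTU count table with sample annotations
#'
#' Expects a tab-separated file with one row per sample; the first four
#' columns are `sample_id`, `patient_id`, `site`, `day`, and every further
#' column is an OTU with integer read counts.
#'
#' @param path path to `otu_table.tsv`
#' @return an [otu_table()]
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "site", "day")
  if (!identical(names(df)[1:4], req))
    stop("otu table header must start with ", paste(req, collapse = ", "),
         "; got: ", paste(utils::head(names(df), 4), collapse = ", "))
  if (ncol(df) < 5) stop("otu table has no OTU columns")
  counts <- as.matrix(df[, -(1:4), drop = FALSE])
  storage.mode(counts) <- "double"
  otu_table(counts, df[, 1:4])
}

#' Write an OTU table to TSV
#' @param table an `otu_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_otu_table <- function(table, path) {
  df <- cbind(table$samples, as.data.frame(table$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree (newick)
#'
#' @param path path to a newick file
#' @return an [ape::read.tree()] `phylo` object, validated to be rooted,
#'   with unique tip labels and non-negative branch lengths
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  invisible(tree)
}

#' Write a tree to newick
#' @param tree a `phylo` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a taxonomy map (otu_id TAB semicolon-delimited lineage)
#' @param path path to `taxonomy.tsv`
#' @return data.frame as returned by [taxonomy_map()]
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("otu_id", "lineage") %in% names(df)))
    stop("taxonomy header must contain otu_id and lineage")
  taxonomy_map(df$otu_id, df$lineage)
}

#' Write a taxonomy map
#' @param taxonomy a taxonomy data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy[, c("otu_id", "lineage")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an antibiotic exposure ledger
#'
#' One row per (patient, drug, calendar day). An antimicrobial therapy day is
#' a calendar day on which the drug was administered at all, regardless of
#' dose, route or frequency, so duplicate (patient, drug, day) rows are
#' collapsed to one with a warning.
#'
#' @param path path to `exposures.tsv` with columns `patient_id`, `drug`, `day`
#' @return data.frame of class `exposure_ledger` with character `patient_id`,
#'   `drug` and integer `day >= 0`
#' @export
read_exposures <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("patient_id", "drug", "day") %in% names(df)))
    stop("exposures header must contain patient_id, drug, day")
  exposure_ledger(df)
}

#' Construct/validate an exposure ledger
#' @param df data.frame with columns `patient_id`, `drug`, `day`
#' @return deduplicated, validated data.frame of class `exposure_ledger`
#' @export
exposure_ledger <- function(df) {
  df <- data.frame(patient_id = as.character(df$patient_id),
                   drug = as.character(df$drug),
                   day = as.integer(df$day), stringsAsFactors = FALSE)
  if (any(is.na(df$day)) || any(df$day < 0))
    stop("exposure days must be integers >= 0")
  dup <- duplicated(df[, c("patient_id", "drug", "day")])
  if (any(dup)) {
    warning("collapsing ", sum(dup), " duplicate (patient, drug, day) exposure row(s)")
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$patient_id, df$drug, df$day), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("exposure_ledger", "data.frame")
  df
}

#' Write an exposure ledger
#' @param ledger an `exposure_ledger`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_exposures <- function(ledger, path) {
  utils::write.table(as.data.frame(ledger), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-patient clinical outcomes
#'
#' Columns: `patient_id`, `recovery_day` (first day with neutrophils above
#' 500 cells/ul), `death_day` (blank/NA if alive through follow-up),
#' `infection_pre` and `infection_post90` (0/1: infection before neutrophil
#' recovery, and within the 90 days after).
#'
#' @param path path to `outcomes.tsv`
#' @return validated data.frame of class `outcome_table`
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("patient_id", "recovery_day", "death_day", "infection_pre", "infection_post90")
  if (!all(req %in% names(df)))
    stop("outcomes header must contain ", paste(req, collapse = ", "))
  outcome_table(df)
}

#' Construct/validate an outcome table
#' @param df data.frame with outcome columns (see [read_outcomes()])
#' @return validated data.frame of class `outcome_table`
#' @export
outcome_table <- function(df) {
  df <- data.frame(patient_id = as.character(df$patient_id),
                   recovery_day = as.integer(df$recovery_day),
                   death_day = as.integer(df$death_day),
                   infection_pre = as.logical(df$infection_pre),
                   infection_post90 = as.logical(df$infection_post90),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id in outcomes")
  if (any(is.na(df$recovery_day)) || any(df$recovery_day <= 0))
    stop("recovery_day must be a positive integer for every patient")
  rownames(df) <- NULL
  class(df) <- c("outcome_table", "data.frame")
  df
}

#' Write an outcome table
#' @param outcomes an `outcome_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_outcomes <- function(outcomes, path) {
  df <- as.data.frame(outcomes)
  df$infection_pre <- as.integer(df$infection_pre)
  df$infection_post90 <- as.integer(df$infection_post90)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Cross-validate the pieces of a cohort directory
#'
#' Checks that every OTU in the count table is a tip of the tree and a row of
#' the taxonomy, that exposure/outcome patients are annotated in the sample
#' table, and that every patient has an outcome row.
#'
#' @param table an `otu_table`
#' @param tree a `phylo`
#' @param taxonomy a taxonomy data.frame
#' @param exposures an `exposure_ledger`
#' @param outcomes an `outcome_table`
#' @return invisibly `TRUE`; stops with a specific message otherwise
#' @export
validate_cohort <- function(table, tree, taxonomy, exposures, outcomes) {
  miss_tip <- setdiff(colnames(table$counts), tree$tip.label)
  if (length(miss_tip) > 0)
    stop("OTU(s) in table absent from tree: ", paste(miss_tip, collapse = ", "))
  miss_tax <- setdiff(colnames(table$counts), taxonomy$otu_id)
  if (length(miss_tax) > 0)
    stop("OTU(s) in table absent from taxonomy: ", paste(miss_tax, collapse = ", "))
  pats <- unique(table$samples$patient_id)
  miss_out <- setdiff(pats, outcomes$patient_id)
  if (length(miss_out) > 0)
    stop("patient(s) without outcome row: ", paste(miss_out, collapse = ", "))
  stray <- setdiff(unique(exposures$patient_id), outcomes$patient_id)
  if (length(stray) > 0)
    stop("exposure patient(s) without outcome row: ", paste(stray, collapse = ", "))
  invisible(TRUE)
}
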