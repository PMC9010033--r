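#' Shannon diversity of a single sample
#'
#' H = -sum p_i log p_i over taxa with nonzero counts, natural log (the
#' vegan/phyloseq convention).
#'
#' @param counts numeric vector of non-negative counts
#' @return H >= 0
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("total count must be > 0")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Observed OTU richness of a single sample
#' @param counts numeric vector of non-negative counts
#' @return number of OTUs with count >= 1
#' @export
observed_otus <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("total count must be > 0")
  sum(counts >= 1)
}

#' Per-sample alpha diversity of an OTU table
#' @param table an `otu_table`
#' @return data.frame with sample annotations plus `observed_otus`, `shannon`
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  out <- table$samples
  out$observed_otus <- apply(table$counts, 1, observed_otus)
  out$shannon <- apply(table$counts, 1, shannon)
  out
}

dist_matrix <- function(m, sample_ids, metric) {
  dimnames(m) <- list(sample_ids, sample_ids)
  attr(m, "metric") <- metric
  class(m) <- c("dist_matrix", class(m))
  m
}

#' Validate a distance matrix object
#' @param d square numeric matrix
#' @param tol symmetry tolerance
#' @return invisibly `TRUE`
#' @export
check_dist_matrix <- function(d, tol = 1e-12) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("not a square matrix")
  if (max(abs(diag(d))) > tol) stop("nonzero diagonal")
  if (max(abs(d - t(d))) > tol) stop("asymmetric distance matrix")
  invisible(TRUE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = 1 - 2 sum_i min(x_i, y_i) / (sum x + sum y), computed on raw
#' counts (no rarefaction or transformation).
#'
#' @param table an `otu_table`
#' @return square `dist_matrix` in \[0, 1\]
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  x <- table$counts
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples")
  tot <- rowSums(x)
  if (any(tot == 0)) stop("zero-sum sample(s)")
  d <- matrix(0, n, n)
  # 2*min(x,y) = x + y - |x - y|
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    absdiff <- rowSums(abs(x[rest, , drop = FALSE] -
                             rep(x[i, ], each = length(rest))))
    d[rest, i] <- d[i, rest] <- absdiff / (tot[i] + tot[rest])
  }
  dist_matrix(d, table$samples$sample_id, "braycurtis")
}

# Per-sample proportion of reads descending through each branch of the tree.
# Returns list(P = samples x edges matrix, len = edge lengths).
branch_proportions <- function(table, tree) {
  counts <- table$counts
  present <- colSums(counts) > 0
  miss <- setdiff(colnames(counts)[present], tree$tip.label)
  if (length(miss) > 0)
    stop("OTU(s) with nonzero counts missing from tree: ",
         paste(miss, collapse = ", "))
  props <- counts / rowSums(counts)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  n <- nrow(counts)
  node_val <- matrix(0, n, ntip + nnode)
  tipidx <- match(colnames(counts), tree$tip.label)
  ok <- !is.na(tipidx)
  node_val[, tipidx[ok]] <- props[, ok, drop = FALSE]
  tr <- ape::reorder.phylo(tree, "postorder")
  P <- matrix(0, n, nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2]
    P[, e] <- node_val[, child]
    node_val[, tr$edge[e, 1]] <- node_val[, tr$edge[e, 1]] + node_val[, child]
  }
  list(P = P, len = tr$edge.length)
}

#' UniFrac distance matrix
#'
#' Phylogenetic beta diversity computed from first principles by a single
#' post-order accumulation of per-branch community proportions.
#' Unweighted: fraction of observed branch length unique to one community,
#' `sum(l * xor) / sum(l * or)` over branches with any descendant reads.
#' Weighted (normalized): `sum(l * |A - B|) / sum(l * (A + B))` with `A`, `B`
#' the proportions of each community descending from the branch; the
#' normalization bounds it in \[0, 1\].
#'
#' @param table an `otu_table`; every OTU with nonzero counts must be a tree tip
#' @param tree rooted `phylo` with branch lengths
#' @param weighted logical; `FALSE` = unweighted, `TRUE` = weighted-normalized
#' @return square `dist_matrix` in \[0, 1\]
#' @export
unifrac <- function(table, tree, weighted = FALSE) {
  stopifnot(inherits(table, "otu_table"))
  validate_tree(tree)
  n <- nrow(table$counts)
  if (n < 2) stop("need at least 2 samples")
  bp <- branch_proportions(table, tree)
  P <- bp$P
  len <- bp$len
  d <- matrix(0, n, n)
  if (weighted) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        a <- P[i, ]; b <- P[j, ]
        denom <- sum(len * (a + b))
        d[i, j] <- d[j, i] <- if (denom > 0) sum(len * abs(a - b)) / denom else 0
      }
    }
  } else {
    pres <- P > 0
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        a <- pres[i, ]; b <- pres[j, ]
        obs <- a | b
        denom <- sum(len[obs])
        d[i, j] <- d[j, i] <- if (denom > 0) sum(len[xor(a, b)]) / denom else 0
      }
    }
  }
  dist_matrix(d, table$samples$sample_id,
              if (weighted) "unifrac-w" else "unifrac-u")
}

#' Dispatch a beta-diversity metric by name
#' @param table an `otu_table`
#' @param metric `"braycurtis"`, `"unifrac-u"` or `"unifrac-w"`
#' @param tree rooted `phylo`; required for the UniFrac metrics
#' @return square `dist_matrix`
#' @export
beta_diversity <- function(table, metric = c("braycurtis", "unifrac-u", "unifrac-w"),
                           tree = NULL) {
  metric <- match.arg(metric)
  if (metric == "braycurtis") return(bray_curtis(table))
  if (is.null(tree)) stop("UniFrac needs a tree")
  unifrac(table, tree, weighted = metric == "unifrac-w")
}
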