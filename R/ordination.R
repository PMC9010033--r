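#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres the matrix of squared distances (Gower's transformation),
#' eigendecomposes it, and scales eigenvectors by the square root of their
#' eigenvalues. Axes with negative eigenvalues (non-Euclidean distances such
#' as Bray-Curtis can produce them) are dropped with a warning rather than
#' corrected.
#'
#' @param d square `dist_matrix` (or plain symmetric matrix)
#' @param n_axes number of axes to retain (truncated with a warning if it
#'   exceeds the number of positive eigenvalues)
#' @return object of class `pcoa_ordination`: list with `coordinates`
#'   (samples x axes, sample ids as row names), `eigenvalues` (positive ones,
#'   decreasing), `prop_variance` (eigenvalue / sum of positive eigenvalues),
#'   and `negative_eigenvalues` (count dropped)
#' @export
pcoa <- function(d, n_axes = 2) {
  check_dist_matrix(unclass(d), tol = 1e-8)
  n <- nrow(d)
  ids <- rownames(d)
  A <- -0.5 * unclass(d)^2
  rm_ <- rowMeans(A)
  B <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  pos <- eig$values > tol
  n_neg <- sum(eig$values < -tol)
  if (n_neg > 0)
    warning("dropping ", n_neg, " negative eigenvalue(s) (non-Euclidean distances)")
  lambda <- eig$values[pos]
  vec <- eig$vectors[, pos, drop = FALSE]
  if (n_axes > length(lambda)) {
    warning("n_axes = ", n_axes, " exceeds rank ", length(lambda), "; truncating")
    n_axes <- length(lambda)
  }
  coords <- sweep(vec, 2, sqrt(lambda), `*`)[, seq_len(n_axes), drop = FALSE]
  rownames(coords) <- ids
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  structure(list(coordinates = coords,
                 eigenvalues = lambda,
                 prop_variance = lambda / sum(lambda),
                 negative_eigenvalues = n_neg),
            class = "pcoa_ordination")
}

#' @exportS3Method base::print
print.pcoa_ordination <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,", ncol(x$coordinates), "axes;",
      "axis variance:", paste(sprintf("%.1f%%",
        100 * x$prop_variance[seq_len(min(3, length(x$prop_variance)))]),
        collapse = " "), "\n")
  invisible(x)
}

permanova_ss <- function(D2, idx_by_group, n) {
  ss_total <- sum(D2) / (2 * n)
  ss_within <- 0
  for (idx in idx_by_group)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  c(total = ss_total, within = ss_within)
}

permanova_F <- function(D2, groups_int, group_sizes, n, a) {
  idx <- split(seq_len(n), groups_int)
  ss <- permanova_ss(D2, idx, n)
  ss_between <- ss["total"] - ss["within"]
  unname((ss_between / (a - 1)) / (ss["within"] / (n - a)))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-way PERMANOVA on a distance matrix (Anderson's pseudo-F from squared
#' distances): `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within` summed within
#' groups with denominators `n_g`, `F = (SS_between/(a-1)) / (SS_within/(N-a))`.
#' The p-value permutes sample labels freely (no strata):
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`. With
#' `exhaustive = TRUE` all `n!` index permutations are enumerated (guarded to
#' n <= 8) and `p` is the exact proportion with `F >= F_obs`, identity
#' included.
#'
#' @param d square `dist_matrix`
#' @param labels per-sample group labels (>= 2 non-empty groups)
#' @param n_permutations number of random permutations (default 999)
#' @param seed integer seed for the permutations
#' @param exhaustive enumerate all permutations instead of sampling
#' @return list of class `permanova_result`: `pseudo_F`, `r_squared`,
#'   `p_value`, `n_permutations`
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = NULL,
                      exhaustive = FALSE) {
  check_dist_matrix(unclass(d), tol = 1e-8)
  n <- nrow(d)
  if (length(labels) != n) stop("labels length != number of samples")
  groups <- as.integer(factor(labels))
  a <- length(unique(groups))
  if (a < 2) stop("need at least 2 groups")
  if (any(tabulate(groups) == 0)) stop("empty group")
  D2 <- unclass(d)^2
  sizes <- tabulate(groups)
  f_obs <- permanova_F(D2, groups, sizes, n, a)
  idx <- split(seq_len(n), groups)
  ss <- permanova_ss(D2, idx, n)
  r2 <- unname((ss["total"] - ss["within"]) / ss["total"])

  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(n)
    f_perm <- vapply(seq_len(nrow(perms)), function(k)
      permanova_F(D2, groups[perms[k, ]], sizes, n, a), numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    f_perm <- vapply(seq_len(n_permutations), function(k)
      permanova_F(D2, groups[sample.int(n)], sizes, n, a), numeric(1))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(pseudo_F = f_obs, r_squared = r2, p_value = p,
                 n_permutations = n_perm),
            class = "permanova_result")
}

#' @exportS3Method base::print
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R^2 = %.4g, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$r_squared, x$p_value, x$n_permutations))
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L), drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' 95% confidence-ellipse membership on the first two ordination axes
#'
#' For each group g the ellipse is
#' \{z : (z - mu_g)' Sigma_g^{-1} (z - mu_g) <= chi^2_2(level)\}
#' with mu_g and Sigma_g the sample mean and covariance of the group's points
#' on the first two axes. A sample is "in both" iff it falls inside the
#' ellipses of both groups.
#'
#' @param ord a `pcoa_ordination` with >= 2 axes (or a samples x 2 matrix)
#' @param labels per-sample group labels (exactly 2 groups, >= 3 samples each)
#' @param level coverage level of the ellipse (default 0.95)
#' @return data.frame: `sample_id`, `label`, one logical `in_<group>` column
#'   per group, and `in_both`
#' @export
confidence_ellipse_overlap <- function(ord, labels, level = 0.95) {
  coords <- if (inherits(ord, "pcoa_ordination")) ord$coordinates else as.matrix(ord)
  if (ncol(coords) < 2) stop("need at least 2 ordination axes")
  coords <- coords[, 1:2, drop = FALSE]
  labels <- as.character(labels)
  if (length(labels) != nrow(coords)) stop("labels length != number of samples")
  gs <- sort(unique(labels))
  if (length(gs) != 2) stop("expected exactly 2 groups")
  cutoff <- stats::qchisq(level, df = 2)
  inside <- sapply(gs, function(g) {
    pts <- coords[labels == g, , drop = FALSE]
    if (nrow(pts) < 3) stop("group '", g, "' has fewer than 3 samples")
    S <- stats::cov(pts)
    if (abs(det(S)) < 1e-300) stop("singular covariance in group '", g, "'")
    stats::mahalanobis(coords, colMeans(pts), S) <= cutoff
  })
  colnames(inside) <- paste0("in_", gs)
  out <- data.frame(sample_id = rownames(coords) %||% seq_len(nrow(coords)),
                    label = labels, inside, in_both = inside[, 1] & inside[, 2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Agglomerative clustering of a distance matrix
#'
#' Average-linkage (UPGMA) hierarchical clustering, cut into `k` groups.
#' Deterministic for a given input order (ties resolved by `stats::hclust`'s
#' fixed merge order).
#'
#' @param d square `dist_matrix`
#' @param k number of clusters (1 <= k <= n)
#' @param method linkage passed to [stats::hclust()] (default `"average"`)
#' @return integer vector of cluster labels named by sample id
#' @export
hierarchical_clusters <- function(d, k, method = "average") {
  check_dist_matrix(unclass(d), tol = 1e-8)
  n <- nrow(d)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds number of samples")
  hc <- stats::hclust(stats::as.dist(unclass(d)), method = method)
  stats::cutree(hc, k = k)
}
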