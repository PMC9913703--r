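#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U is the number of (x, y) pairs with x > y (+ half the ties). The p-value
#' is computed by exact enumeration of the rank distribution when the pooled
#' size is at most `exact_cutoff` and there are no ties, otherwise by the
#' normal approximation with tie and continuity corrections (the standard
#' large-sample path).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param exact_cutoff Pooled-size threshold for the exact path. Default 20.
#' @return List with `statistic` (U for x vs y), `p_value`, `n` (per-group
#'   sizes), `method` (`"exact"` or `"normal-approx"`).
#' @export
mann_whitney <- function(x, y, exact_cutoff = 20) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs >= 2 values")
  if (any(!is.finite(c(x, y)))) stop("non-finite values")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= exact_cutoff) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       n = c(length(x), length(y)),
       method = if (exact) "exact" else "normal-approx")
}

#' Kruskal-Wallis rank test across k groups
#'
#' H statistic with tie correction; p-value from the chi-square distribution
#' with k - 1 degrees of freedom.
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @return List with `statistic` (H), `p_value`, `df`, `n` (per-group sizes).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs >= 2 values")
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic),
       p_value = kt$p.value,
       df = unname(kt$parameter),
       n = sizes)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midrank vectors; the p-value uses the
#' t approximation with n - 2 degrees of freedom (two-sided).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need >= 3 paired observations")
  if (any(!is.finite(c(x, y)))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman rho undefined")
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Agglomerative hierarchical clustering under correlation distance
#'
#' Distance is `1 - Pearson correlation` between items (samples or genes),
#' linkage is average (UPGMA) by default. Both the merge tree and the leaf
#' order are deterministic; items are taken in their matrix order and exact
#' distance ties resolve by that order.
#'
#' @param matrix Genes x samples expression or score matrix.
#' @param axis Cluster `"samples"` (columns, default) or `"genes"` (rows).
#' @param linkage Linkage passed to [stats::hclust()]. Default `"average"`.
#' @return List with `hclust` (the merge tree), `leaf_order` (item IDs), and
#'   `distance` (the `dist` object).
#' @export
hierarchical_cluster <- function(matrix, axis = c("samples", "genes"),
                                 linkage = "average") {
  axis <- match.arg(axis)
  validate_expression_matrix(matrix, allow_duplicates = TRUE)
  items <- if (axis == "samples") t(matrix) else matrix
  if (nrow(items) < 2) stop("need >= 2 items to cluster")
  sds <- apply(items, 1, stats::sd)
  if (any(sds == 0))
    stop("constant ", sub("s$", "", axis), " under correlation distance: ",
         paste(rownames(items)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(items)))
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, leaf_order = rownames(items)[hc$order], distance = d)
}

#' Principal component analysis of samples
#'
#' Genes (rows) are mean-centered; sample coordinates are the projections
#' onto the top-k right singular vectors of the centered matrix. No scaling:
#' expression is assumed to be on a common log2 scale already. Sign
#' convention: within each component the gene loading of largest magnitude is
#' made positive, so results are bit-stable across runs and platforms.
#'
#' @param matrix Genes x samples matrix.
#' @param k Number of components, at most the matrix rank.
#' @return List with `coordinates` (samples x k), `explained` (variance
#'   fractions, non-increasing, summing to <= 1), `loadings` (genes x k).
#' @export
pca_samples <- function(matrix, k = 2) {
  validate_expression_matrix(matrix, allow_duplicates = TRUE)
  centered <- matrix - rowMeans(matrix)
  sv <- svd(centered)
  tol <- max(dim(centered)) * max(sv$d) * .Machine$double.eps
  rank_ <- sum(sv$d > tol)
  if (k > rank_)
    stop("k = ", k, " exceeds the matrix rank (", rank_, ")")
  flip <- vapply(seq_len(k), function(j) {
    u <- sv$u[, j]
    sign(u[which.max(abs(u))])
  }, numeric(1))
  coords <- sweep(sv$v[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  loadings <- sweep(sv$u[, seq_len(k), drop = FALSE], 2, flip, `*`)
  dimnames(coords) <- list(colnames(matrix), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(rownames(matrix), paste0("PC", seq_len(k)))
  list(coordinates = coords,
       explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
       loadings = loadings)
}

#' Group-comparison tests on a score vector
#'
#' Convenience wrapper: splits `scores` by `groups` and runs [mann_whitney()]
#' for two groups or [kruskal_wallis()] for more.
#'
#' @param scores Named numeric vector (names = sample IDs).
#' @param groups Factor or character vector aligned with `scores`.
#' @return The test result list, plus `groups` (levels) and `test`.
#' @export
compare_groups <- function(scores, groups) {
  if (length(scores) != length(groups))
    stop("scores and groups must be aligned")
  split_ <- split(as.numeric(scores), as.character(groups))
  if (length(split_) < 2) stop("need >= 2 groups")
  res <- if (length(split_) == 2) {
    c(mann_whitney(split_[[1]], split_[[2]]), list(test = "mann-whitney"))
  } else {
    c(kruskal_wallis(split_), list(test = "kruskal-wallis"))
  }
  res$groups <- names(split_)
  res
}
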