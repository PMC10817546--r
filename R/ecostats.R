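#' Total-sum scaling normalization
#'
#' Divides each sample row by its total so rows sum to 1. Zero-sum samples
#' are dropped with a warning.
#'
#' @param counts Samples x taxa numeric matrix (or `amf_otutable`).
#' @return Relative-abundance matrix.
#' @export
tss_normalize <- function(counts) {
  if (inherits(counts, "amf_otutable")) counts <- counts$counts
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    warning("dropping ", sum(rs == 0), " zero-sum sample(s)")
    counts <- counts[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  sweep(counts, 1L, rs, "/")
}

#' Pearson correlation with the small-sample significance rule
#'
#' Product-moment r, reported rounded to two decimals; the significance
#' star follows the two-sided t-test on r with n - 2 degrees of freedom at
#' alpha = 0.05 (for n = 9 that is |r| > 0.6664).
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @param alpha Significance level.
#' @return List: `r` (full precision), `r_rounded`, `p`, `significant`.
#' @export
pearson_r <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, r_rounded = NA_real_, p = NA_real_,
                significant = NA))
  r <- stats::cor(x, y)
  n <- length(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, r_rounded = round(r, 2), p = p, significant = p < alpha)
}

#' Correlation matrix with significance flags
#'
#' @param tab Numeric data frame or matrix (columns = parameters).
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha Significance level for the stars.
#' @return List of class `amf_cormat`: `r` (rounded matrix), `significant`
#'   (logical matrix), `method`, `n`.
#' @export
correlation_matrix <- function(tab, method = c("pearson", "spearman"),
                               alpha = 0.05) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  n <- nrow(tab)
  r <- stats::cor(tab, method = method)
  tt <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  diag(p) <- 0
  structure(list(r = round(r, 2), significant = p < alpha & !diag(ncol(r)) == 1,
                 method = method, n = n),
            class = "amf_cormat")
}

#' Spearman distance matrix (1 - rho) between samples
#'
#' Ranks use midranks for ties. Pairs involving a constant profile have
#' undefined correlation and are flagged by `NA`.
#'
#' @param x Samples x features matrix.
#' @return Symmetric `dist`-convertible matrix of 1 - rho.
#' @export
spearman_distance_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 features")
  rho <- suppressWarnings(stats::cor(t(x), method = "spearman"))
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of between-group versus within-group
#' distances: `R = (mean_between - mean_within) / (M/2)` over the ranked
#' pairwise distances, with the permutation p-value computed with the +1
#' correction. Delegates the computation to `vegan::anosim`; seeded for
#' reproducibility.
#'
#' @param d Distance matrix (symmetric matrix or `dist`).
#' @param groups Group labels, >= 2 groups with >= 2 members each.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List of class `amf_anosim`: `R`, `p`, `n_perm`, `seed`.
#' @export
anosim_test <- function(d, groups, n_perm = 999L, seed = 1L) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 members")
  set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(d), groups, permutations = n_perm)
  structure(list(R = unname(fit$statistic), p = fit$signif,
                 n_perm = n_perm, seed = seed),
            class = "amf_anosim")
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centering plus eigendecomposition; coordinates are ordered by
#' eigenvalue and signed so the largest-magnitude entry of each axis is
#' positive.
#'
#' @param d Distance matrix.
#' @param k Number of dimensions.
#' @return List: `points` (n x k), `eig` (all eigenvalues).
#' @export
classical_mds <- function(d, k = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) {
    warning("k reduced to n - 1")
    k <- n - 1L
  }
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  pts <- fit$points
  for (j in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  }
  list(points = pts, eig = fit$eig)
}

#' Principal component analysis
#'
#' PCA on centered (optionally unit-scaled) data with the same sign
#' convention as [classical_mds()] applied to the loadings.
#'
#' @param x Samples x features matrix.
#' @param k Number of components.
#' @param scale. Scale columns to unit variance.
#' @return List: `scores`, `loadings`, `variance_fraction`.
#' @export
pca_scores <- function(x, k = 2L, scale. = FALSE) {
  x <- as.matrix(x)
  keep <- apply(x, 2L, stats::sd) > 0 | !scale.
  fit <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  k <- min(k, ncol(fit$x))
  scores <- fit$x[, seq_len(k), drop = FALSE]
  loadings <- fit$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = scores, loadings = loadings,
       variance_fraction = vf[seq_len(k)])
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Ward's minimum-variance agglomeration (Lance-Williams update as
#' implemented by `hclust(method = "ward.D2")`); the dendrogram can be
#' serialized as Newick with node heights via [ape::write.tree].
#'
#' @param d Distance matrix.
#' @return List: `hclust` (the fit), `newick` (string).
#' @export
ward_clustering <- function(d) {
  d <- stats::as.dist(as.matrix(d))
  if (attr(d, "Size") < 2L) stop("need at least 2 items")
  hc <- stats::hclust(d, method = "ward.D2")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy))
}

#' Per-taxon group difference tests
#'
#' One-way ANOVA F-test per taxon (Welch's variant or, for exactly two
#' groups, the two-sample t-test, when `welch = TRUE`). Raw p-values with
#' alpha-level flags are reported — no multiplicity correction by default,
#' with an optional Benjamini-Hochberg column.
#'
#' @param rel Samples x taxa relative-abundance matrix.
#' @param groups Group labels per sample.
#' @param welch Use the unequal-variance variant.
#' @param alpha Flagging level.
#' @param fdr Add a BH-adjusted column.
#' @return Data frame: taxon, p, significant (and `p_bh` when `fdr`).
#' @export
group_difference_tests <- function(rel, groups, welch = FALSE, alpha = 0.05,
                                   fdr = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  usable <- table(groups) >= 2L
  if (!all(usable)) {
    keep <- groups %in% names(usable)[usable]
    rel <- rel[keep, , drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  p <- vapply(seq_len(ncol(rel)), function(j) {
    y <- rel[, j]
    if (stats::var(y) == 0) return(1)
    ok <- tryCatch({
      if (welch) stats::oneway.test(y ~ groups, var.equal = FALSE)$p.value
      else stats::oneway.test(y ~ groups, var.equal = TRUE)$p.value
    }, error = function(e) NA_real_)
    ok
  }, numeric(1))
  out <- data.frame(taxon = colnames(rel) %||% as.character(seq_len(ncol(rel))),
                    p = p, significant = !is.na(p) & p < alpha,
                    stringsAsFactors = FALSE)
  if (fdr) out$p_bh <- stats::p.adjust(p, method = "BH")
  out
}
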