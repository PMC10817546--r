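#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Saitou-Nei agglomeration on a symmetric distance matrix. When several
#' pairs attain the minimal Q criterion the lexicographically smallest pair
#' of node labels is joined (internal nodes inherit the smallest leaf label
#' of their subtree), making the topology order-independent. Negative
#' branch lengths are clamped to zero with the deficit moved to the sister
#' edge, preserving the joined pair's distance.
#'
#' @param d Symmetric numeric matrix with zero diagonal, labelled rows and
#'   columns, at least 3 taxa, no NA/NaN.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (any(is.na(d)) || any(!is.finite(d))) stop("distance matrix contains NA/NaN")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)) || any(abs(diag(d)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal")
  dimnames(d) <- list(rownames(d), rownames(d))

  newick <- rownames(d)          # growing subtree strings per active node
  label <- rownames(d)           # tie-break label = smallest leaf in subtree
  fmt <- function(x) sprintf("%.10g", max(x, 0))

  while (nrow(d) > 3L) {
    N <- nrow(d)
    r <- rowSums(d)
    q <- (N - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographically smallest (label_i, label_j) with labels sorted per pair
    keys <- apply(cand, 1L, function(ij) {
      paste(sort(c(label[ij[1]], label[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]

    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- d[i, j]; li <- 0 }
    if (lj < 0) { li <- d[i, j]; lj <- 0 }
    if (label[j] < label[i]) {   # canonical child order: smaller label first
      tmp <- i; i <- j; j <- tmp
      tmp <- li; li <- lj; lj <- tmp
    }
    new_nwk <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(li), newick[j], fmt(lj))
    new_lab <- min(label[i], label[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    nm <- c(rownames(d)[keep], new_lab)
    dimnames(d2) <- list(nm, nm)
    d <- d2
    newick <- c(newick[keep], new_nwk)
    label <- c(label[keep], new_lab)
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- c(la, lb, lc)
  ord3 <- order(label)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 newick[ord3[1]], fmt(lens[ord3[1]]),
                 newick[ord3[2]], fmt(lens[ord3[2]]),
                 newick[ord3[3]], fmt(lens[ord3[3]]))
  ape::read.tree(text = nwk)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; the split is canonicalized
#' as the sorted side not containing the alphabetically first leaf.
#'
#' @param tree An `ape::phylo`.
#' @return Named list of character vectors (one per internal edge); names
#'   are stable keys usable across trees on the same leaf set.
#' @export
tree_splits <- function(tree) {
  n_tip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  splits <- list()
  internal_edges <- which(tree$edge[, 2] > n_tip)
  for (e in internal_edges) {
    node <- tree$edge[e, 2]
    tips <- tree$tip.label[descendant_tips(tree, node)]
    if (anchor %in% tips) tips <- setdiff(tree$tip.label, tips)
    if (length(tips) < 2L || length(tips) > n_tip - 2L) next
    key <- paste(sort(tips), collapse = "\r")
    splits[[key]] <- sort(tips)
  }
  splits
}

descendant_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  out <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    out <- c(out, ch[ch <= n_tip])
    stack <- c(stack, ch[ch > n_tip])
  }
  out
}

#' Bootstrap support for the bipartitions of an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' p-distance/NJ tree for each replicate and reports, for every internal
#' edge of the original tree, the percentage of replicates containing the
#' same bipartition. Deterministic under `seed`.
#'
#' @param alignment Character matrix (rows = sequences, columns = aligned
#'   positions) covering the tree's leaves.
#' @param tree The NJ tree whose edges are to be supported (defaults to the
#'   tree built from the full alignment).
#' @param n_reps Number of bootstrap replicates; 0 returns no supports.
#' @param seed Integer seed.
#' @return Named numeric vector of supports in \[0, 100\], keyed like
#'   [tree_splits()]; attribute `low_confidence` is `TRUE` when the
#'   alignment has fewer than 10 columns.
#' @export
bootstrap_support <- function(alignment, tree = NULL, n_reps = 100L, seed = 1L) {
  if (is.null(tree)) tree <- nj_tree(p_distance_matrix(alignment))
  splits <- tree_splits(tree)
  if (n_reps <= 0L)
    return(stats::setNames(numeric(0), character(0)))
  low_conf <- ncol(alignment) < 10L
  if (low_conf)
    warning("alignment shorter than 10 columns; supports are low-confidence")
  set.seed(seed)
  hits <- stats::setNames(numeric(length(splits)), names(splits))
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(alignment), replace = TRUE)
    db <- p_distance_matrix(alignment[, cols, drop = FALSE], impute = TRUE)
    tb <- nj_tree(db)
    sb <- names(tree_splits(tb))
    hits[names(hits) %in% sb] <- hits[names(hits) %in% sb] + 1
  }
  out <- 100 * hits / n_reps
  attr(out, "low_confidence") <- low_conf
  out
}

#' Pairwise p-distance matrix from an alignment
#'
#' Pairwise deletion: for each pair, columns where either sequence has a
#' gap are excluded. A pair with no comparable columns is an error, unless
#' `impute = TRUE` (used inside bootstrap replicates), where it receives
#' the matrix maximum.
#'
#' @param alignment Character matrix with row names.
#' @param impute Replace undefined pairs instead of failing.
#' @return Symmetric matrix of p-distances.
#' @export
p_distance_matrix <- function(alignment, impute = FALSE) {
  n <- nrow(alignment)
  d <- matrix(0, n, n, dimnames = list(rownames(alignment), rownames(alignment)))
  gaps <- alignment == "-"
  undef <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      valid <- !gaps[i, ] & !gaps[j, ]
      if (!any(valid)) {
        if (!impute) stop("no comparable columns for pair (", i, ",", j, ")")
        d[i, j] <- d[j, i] <- NA_real_
        undef <- TRUE
      } else {
        d[i, j] <- d[j, i] <- mean(alignment[i, valid] != alignment[j, valid])
      }
    }
  }
  if (undef) {
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- mx
  }
  d
}

#' Alignment-free pre-clustering by k-mer profile distance
#'
#' Builds an NJ tree on the cosine distance between k-mer count profiles
#' and cuts it by removing edges longer than `cut_height`; connected leaf
#' groups become candidate clusters. A cluster is marked alignable when
#' every member pair shares at least half of the smaller member's distinct
#' k-mers.
#'
#' @param seqs Named character vector (>= 1 sequence).
#' @param k K-mer size (default 6).
#' @param cut_height Edge length above which the tree is cut.
#' @return Data frame with `name`, `cluster` (integer) and `alignable`
#'   (logical, per cluster).
#' @export
precluster_alignment_free <- function(seqs, k = 6L, cut_height = 0.1) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  if (length(seqs) == 1L)
    return(data.frame(name = names(seqs), cluster = 1L, alignable = TRUE,
                      stringsAsFactors = FALSE))
  prof <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                               width = k)
  cosd <- function(x, y) {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) return(1)
    1 - sum(x * y) / (nx * ny)
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
    d[i, j] <- d[j, i] <- cosd(prof[i, ], prof[j, ])

  if (n == 2L) {
    cl <- if (d[1, 2] <= 2 * cut_height) c(1L, 1L) else c(1L, 2L)
  } else {
    tree <- nj_tree(d)
    cl <- cut_tree_components(tree, cut_height)[names(seqs)]
  }
  km <- kmer_sets(seqs, k)
  alignable <- vapply(split(seq_len(n), cl), function(idx) {
    if (length(idx) == 1L) return(TRUE)
    for (a in idx) for (b in idx) {
      if (a >= b) next
      sh <- length(intersect(km[[a]], km[[b]])) /
        max(1L, min(length(km[[a]]), length(km[[b]])))
      if (sh < 0.5) return(FALSE)
    }
    TRUE
  }, logical(1))
  data.frame(name = names(seqs), cluster = as.integer(cl),
             alignable = alignable[as.character(cl)],
             stringsAsFactors = FALSE)
}

# Connected components of a tree's leaves after removing long edges;
# components numbered by their smallest leaf label.
cut_tree_components <- function(tree, cut_height) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  parent <- seq_len(n_node)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (e in seq_len(nrow(tree$edge))) {
    if (tree$edge.length[e] <= cut_height) {
      a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
      if (a != b) parent[a] <- b
    }
  }
  comp <- vapply(seq_len(n_tip), find, integer(1))
  first_leaf <- vapply(unique(comp), function(cmp) {
    min(tree$tip.label[comp == cmp])
  }, character(1))
  ids <- stats::setNames(rank(first_leaf), unique(comp))
  stats::setNames(as.integer(ids[as.character(comp)]), tree$tip.label)
}
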