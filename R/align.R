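#' Global pairwise identity between two sequences
#'
#' End-to-end (Needleman-Wunsch-style) alignment with match +1, mismatch -1,
#' gap open -2, gap extend -1; identity is the fraction of alignment columns
#' (terminal gaps included) in which the two sequences carry the same base.
#' This is the strictest common reading of a "97% identity" radius and is the
#' definition used throughout OTU construction.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Identity in \[0, 1\].
#' @export
global_identity <- function(a, b) {
  check_dna(a, "a"); check_dna(b, "b")
  global_identity_many(a, b)[1]
}

# Vectorized form: identity of each query against one subject.
global_identity_many <- function(queries, subject) {
  check_dna(queries, "queries"); check_dna(subject, "subject")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(subject),
    type = "global",
    substitutionMatrix = identity_submat(),
    gapOpening = 2, gapExtension = 1
  )
  # matching columns over all alignment columns, terminal gaps included:
  # every column consumes a base from one or both sequences, so
  # columns = n_query + n_subject - (base-to-base columns)
  bb <- Biostrings::nmatch(pa) + Biostrings::nmismatch(pa)
  Biostrings::nmatch(pa) / (nchar(queries) + nchar(subject) - bb)
}

identity_submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat))
      mat <<- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                       baseOnly = FALSE, type = "DNA")
    mat
  }
})

# Aligned pair (two gapped strings of equal length) for a query/subject;
# used where per-column information is needed (p-distance, chimera profiles).
align_pair <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = identity_submat(),
    gapOpening = 2, gapExtension = 1
  )
  c(as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)))
}

#' Proportion of differing sites between two sequences (p-distance)
#'
#' For unaligned input the pair is first globally aligned; under pairwise
#' deletion every column containing a gap is excluded from the comparison.
#'
#' @param a,b Nucleotide strings, or two equal-length gapped strings when
#'   `aligned = TRUE`.
#' @param aligned Set `TRUE` when `a` and `b` are already aligned (may
#'   contain `-`).
#' @param pairwise_deletion Drop gapped columns (the default and only
#'   supported mode for unaligned input).
#' @return p-distance in \[0, 1\].
#' @export
p_distance <- function(a, b, aligned = FALSE, pairwise_deletion = TRUE) {
  if (!aligned) {
    al <- align_pair(a, b)
    a <- al[1]; b <- al[2]
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("aligned sequences must have equal length")
  keep <- if (pairwise_deletion) ca != "-" & cb != "-" else rep(TRUE, length(ca))
  if (!any(keep)) stop("no comparable columns after gap deletion")
  mean(ca[keep] != cb[keep])
}

#' Center-star multiple alignment of near-identical sequences
#'
#' Progressive alignment seeded on the longest sequence (ties broken
#' lexicographically): every other sequence is globally aligned to the
#' center, and the union of center gaps across the pairwise alignments
#' defines the master coordinate system. Adequate at the low intra-genus
#' divergences for which the genus bins are built; not a general-purpose
#' aligner.
#'
#' @param seqs Named character vector of sequences.
#' @return Character matrix (rows = sequences, columns = alignment columns)
#'   with row names preserved.
#' @export
center_star_align <- function(seqs) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  if (length(seqs) == 1L)
    return(matrix(strsplit(seqs, "")[[1]], nrow = 1, dimnames = list(names(seqs))))
  ord <- order(-nchar(seqs), seqs)
  center_i <- ord[1]
  center <- seqs[center_i]
  others <- seqs[-center_i]

  pairs <- lapply(others, function(s) align_pair(s, center))
  # Gap pattern of the center in each pairwise alignment, expressed as number
  # of gaps inserted after each center position (index 0 = before first base).
  ins_counts <- lapply(pairs, function(al) {
    cs <- strsplit(al[2], "", fixed = TRUE)[[1]]
    pos <- cumsum(cs != "-")
    tab <- table(factor(pos[cs == "-"], levels = 0:nchar(center)))
    as.integer(tab)
  })
  max_ins <- Reduce(pmax, ins_counts, accumulate = FALSE)
  ncol_out <- nchar(center) + sum(max_ins)

  project <- function(gapped_seq, gapped_center) {
    sc <- strsplit(gapped_center, "", fixed = TRUE)[[1]]
    ss <- strsplit(gapped_seq, "", fixed = TRUE)[[1]]
    out <- character(ncol_out)
    out[] <- "-"
    pos <- 0L   # center position already passed
    ins_here <- 0L
    for (j in seq_along(sc)) {
      if (sc[j] == "-") {
        ins_here <- ins_here + 1L
        col <- master_offset(pos, max_ins) + ins_here
      } else {
        pos <- pos + 1L
        ins_here <- 0L
        col <- master_base_col(pos, max_ins)
      }
      out[col] <- ss[j]
    }
    paste(out, collapse = "")
  }

  rows <- character(length(seqs))
  names(rows) <- names(seqs)
  # center itself
  center_row <- character(ncol_out); center_row[] <- "-"
  cb <- strsplit(center, "", fixed = TRUE)[[1]]
  for (pos in seq_along(cb)) center_row[master_base_col(pos, max_ins)] <- cb[pos]
  rows[names(seqs)[center_i]] <- paste(center_row, collapse = "")
  for (k in seq_along(others)) {
    al <- pairs[[k]]
    rows[names(others)[k]] <- project(al[1], al[2])
  }
  do.call(rbind, lapply(rows, function(r) strsplit(r, "", fixed = TRUE)[[1]]))
}

# Column index (1-based) in the master alignment of the pos-th center base.
master_base_col <- function(pos, max_ins) {
  pos + sum(max_ins[seq_len(pos)])
}
# Last column used by insertions after center position `pos` starts here.
master_offset <- function(pos, max_ins) {
  pos + sum(max_ins[seq_len(pos)])
}
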