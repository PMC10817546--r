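# Independent oracles, deliberately coded without the package's alignment
# or clustering machinery.

# Enumerate every global alignment of two short sequences, score with
# match +1 / mismatch -1 / gap open -2 / gap extend -1 (first gap character
# costs open + extend), and return the identities (match columns / all
# columns) of all maximum-score alignments. Exponential; only for n <= 6.
enum_align_identities <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  acc <- new.env(); acc$score <- numeric(); acc$id <- numeric()
  rec <- function(i, j, score, matches, cols, prev_gap) {
    if (i > length(av) && j > length(bv)) {
      acc$score <- c(acc$score, score)
      acc$id <- c(acc$id, matches / cols)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) 1 else -1
      rec(i + 1, j + 1, score + s, matches + (av[i] == bv[j]), cols + 1, "")
    }
    if (i <= length(av)) {
      pen <- if (prev_gap == "a") -1 else -3
      rec(i + 1, j, score + pen, matches, cols + 1, "a")
    }
    if (j <= length(bv)) {
      pen <- if (prev_gap == "b") -1 else -3
      rec(i, j + 1, score + pen, matches, cols + 1, "b")
    }
  }
  rec(1, 1, 0, 0, 0, "")
  unique(acc$id[acc$score > max(acc$score) - 1e-9])
}

# Hamming identity for equal-length sequences (the gapless special case).
hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  mean(av == bv)
}

# Brute-force re-implementation of the two-step OTU construction for
# equal-length dereplicated sequences, using Hamming identity and explicit
# crossover-model construction for the chimera test.
brute_two_step <- function(dereps, refs, radius = 0.97, chim_id = 0.99) {
  n <- nrow(dereps)
  mapped <- rep(NA_character_, n)
  cur_ab <- stats::setNames(numeric(length(refs)), names(refs))
  for (i in seq_len(n)) {
    ids <- vapply(refs, function(r) hamming_identity(dereps$sequence[i], r),
                  numeric(1))
    best <- max(ids)
    if (best >= radius) {
      cand <- names(refs)[abs(ids - best) < 1e-12]
      if (length(cand) > 1L) {
        cand <- cand[cur_ab[cand] == max(cur_ab[cand])]
        cand <- sort(cand)[1]
      }
      mapped[i] <- cand
      cur_ab[cand] <- cur_ab[cand] + dereps$total_abundance[i]
    }
  }
  unmapped <- which(is.na(mapped))
  ord <- unmapped[order(-dereps$total_abundance[unmapped],
                        dereps$sequence[unmapped])]
  cents <- character(); cent_ab <- numeric()
  member_of <- rep(NA_integer_, n)
  discarded <- integer(); disc_reason <- character()
  for (i in ord) {
    s <- dereps$sequence[i]
    if (length(cents)) {
      ids <- vapply(cents, function(cs) hamming_identity(s, cs), numeric(1),
                    USE.NAMES = FALSE)
      j <- which.max(ids)
      if (ids[j] >= radius) {
        member_of[i] <- j
        cent_ab[j] <- cent_ab[j] + dereps$total_abundance[i]
        next
      }
    }
    pool <- c(cents, unname(refs))  # references are eligible chimera parents
    if (length(pool) >= 2L && brute_is_chimera(s, pool, chim_id)) {
      discarded <- c(discarded, i); disc_reason <- c(disc_reason, "chimera")
      next
    }
    cents <- c(cents, s)
    cent_ab <- c(cent_ab, dereps$total_abundance[i])
    member_of[i] <- length(cents)
  }
  keep <- which(cent_ab > 1)
  for (i in seq_len(n)) {
    if (!is.na(member_of[i]) && !(member_of[i] %in% keep)) {
      discarded <- c(discarded, i)
      disc_reason <- c(disc_reason, "residual_singleton")
      member_of[i] <- NA_integer_
    }
  }
  list(mapped = mapped, centroids = cents[keep],
       member_of = ifelse(is.na(member_of), NA, match(member_of, keep)),
       discarded = sort(discarded))
}

brute_is_chimera <- function(s, cents, chim_id = 0.99) {
  L <- nchar(s)
  for (a in seq_along(cents)) for (b in seq_along(cents)) {
    if (a == b) next
    for (k in seq_len(L - 1L)) {
      model <- paste0(substr(cents[a], 1, k), substr(cents[b], k + 1, L))
      if (hamming_identity(s, model) >= chim_id) return(TRUE)
    }
  }
  FALSE
}

# Random sequence helpers for fixture construction.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
mutate_at <- function(seq, pos) {
  v <- strsplit(seq, "")[[1]]
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[sample.int(3, 1)]
  paste(v, collapse = "")
}

# Build an amf_dereps frame directly from sequences and abundances.
make_dereps <- function(seqs, abund, samples = "S1") {
  reads <- data.frame(
    sequence = rep(seqs, abund),
    sample_id = rep(samples, length.out = sum(abund)),
    stringsAsFactors = FALSE)
  dereplicate(reads)
}
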