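#' Merge a read pair into a consensus sequence
#'
#' Reverse-complements mate 2, scans all overlap lengths of at least
#' `min_overlap` (up to full containment) and selects the overlap minimizing
#' the mismatch fraction, with ties resolved in favor of the longest
#' overlap. Consensus bases take the higher-quality call; consensus quality
#' is the sum of the two qualities capped at 45 on agreement and their
#' absolute difference on disagreement. Pairs with no overlap passing
#' `max_mismatch_frac` are rejected with a reason.
#'
#' @param r1,r2 Mate sequences (5'->3' as sequenced).
#' @param q1,q2 Phred+33 quality strings matching the mates.
#' @param min_overlap Minimum overlap length to consider.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction in the
#'   chosen overlap.
#' @param id Read identifier carried into the result.
#' @return List of class `merged_read` with `id`, `sequence`, `qualities`
#'   (integer Phred), `expected_errors`; or class `merge_rejection` with
#'   `id` and `reason`.
#' @export
merge_pairs <- function(r1, r2, q1, q2, min_overlap = 16L,
                        max_mismatch_frac = 0.25, id = "read") {
  check_dna(r1, "r1"); check_dna(r2, "r2")
  if (nchar(r1) != nchar(q1) || nchar(r2) != nchar(q2))
    stop("sequence and quality lengths differ")
  if (nchar(r1) < min_overlap || nchar(r2) < min_overlap)
    return(structure(list(id = id, reason = "mate shorter than min_overlap"),
                     class = "merge_rejection"))
  f <- strsplit(r1, "", fixed = TRUE)[[1]]
  r <- strsplit(revcomp(r2), "", fixed = TRUE)[[1]]
  qf <- char_to_phred(q1)
  qr <- rev(char_to_phred(q2))
  nf <- length(f); nr <- length(r)

  # Overlap of length L: last L bases of the forward mate against the first
  # L bases of the reverse-complemented mate.
  best <- NULL
  for (L in seq.int(min_overlap, min(nf, nr))) {
    fi <- seq.int(nf - L + 1L, nf)
    ri <- seq_len(L)
    mm <- mean(f[fi] != r[ri])
    if (mm <= max_mismatch_frac &&
        (is.null(best) || mm < best$mm || (mm == best$mm && L > best$L)))
      best <- list(L = L, mm = mm)
  }
  if (is.null(best))
    return(structure(list(id = id, reason = "no acceptable overlap"),
                     class = "merge_rejection"))
  L <- best$L
  fi <- seq.int(nf - L + 1L, nf)
  ri <- seq_len(L)
  cons <- ifelse(qf[fi] >= qr[ri], f[fi], r[ri])
  agree <- f[fi] == r[ri]
  qcons <- ifelse(agree, pmin(qf[fi] + qr[ri], 45L), abs(qf[fi] - qr[ri]))
  seq_out <- c(f[seq_len(nf - L)], cons, r[seq.int(L + 1L, length.out = nr - L)])
  qual_out <- c(qf[seq_len(nf - L)], qcons, qr[seq.int(L + 1L, length.out = nr - L)])
  structure(list(id = id, sequence = paste(seq_out, collapse = ""),
                 qualities = as.integer(qual_out),
                 expected_errors = expected_errors(qual_out)),
            class = "merged_read")
}

#' Merge all pairs of a simulated (or imported) read set
#'
#' @param reads Data frame with columns read_id, sample_id, r1, q1, r2, q2.
#' @inheritParams merge_pairs
#' @return List with `merged` (data frame: read_id, sample_id, sequence,
#'   qualities as Phred+33 string, expected_errors) and `rejected`
#'   (read_id, reason).
#' @export
merge_read_table <- function(reads, min_overlap = 16L, max_mismatch_frac = 0.25) {
  out <- vector("list", nrow(reads))
  rej <- list()
  for (i in seq_len(nrow(reads))) {
    m <- merge_pairs(reads$r1[i], reads$r2[i], reads$q1[i], reads$q2[i],
                     min_overlap, max_mismatch_frac, id = reads$read_id[i])
    if (inherits(m, "merge_rejection")) {
      rej[[length(rej) + 1L]] <- data.frame(read_id = m$id, reason = m$reason,
                                            stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(read_id = m$id, sample_id = reads$sample_id[i],
                             sequence = m$sequence,
                             qualities = phred_to_char(m$qualities),
                             expected_errors = m$expected_errors,
                             stringsAsFactors = FALSE)
    }
  }
  list(merged = do.call(rbind, c(Filter(Negate(is.null), out),
                                 list(make.row.names = FALSE))) %||%
         empty_merged_frame(),
       rejected = do.call(rbind, c(rej, list(make.row.names = FALSE))) %||%
         data.frame(read_id = character(), reason = character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_merged_frame <- function() {
  data.frame(read_id = character(), sample_id = character(),
             sequence = character(), qualities = character(),
             expected_errors = numeric())
}

#' Remove merged reads shorter than a minimum length
#'
#' "Shorter than" is strict: a read of exactly `min_len` bases is kept.
#'
#' @param merged Data frame with a `sequence` column.
#' @param min_len Minimum retained length (default 120 bp).
#' @return The retained rows.
#' @export
length_filter <- function(merged, min_len = 120L) {
  merged[nchar(merged$sequence) >= min_len, , drop = FALSE]
}

#' Strip primer spans and tag the amplicon region
#'
#' Looks for a forward primer (at most one mismatch) at the 5' end and the
#' reverse complement of the matching reverse primer at the 3' end; matched
#' spans are removed (qualities kept in register) and the read is tagged
#' with the region whose primer pair matched. Reads matching no forward
#' primer are returned unchanged and tagged `"unknown"`.
#'
#' @param merged Data frame with `sequence` and `qualities` columns.
#' @param primer_set Primer list as returned by [amf_primers()].
#' @param max_mismatch Mismatches tolerated in a primer match.
#' @return The input with trimmed `sequence`/`qualities` and a `region_tag`
#'   column (`"ITS1"`, `"ITS2"` or `"unknown"`).
#' @export
strip_primers <- function(merged, primer_set = amf_primers(), max_mismatch = 1L) {
  tag <- rep("unknown", nrow(merged))
  seqs <- merged$sequence
  quals <- merged$qualities
  for (rg in names(primer_set)) {
    fwd <- primer_set[[rg]]$fwd
    rev_rc <- revcomp(primer_set[[rg]]$rev)
    hit <- tag == "unknown" &
      prefix_mismatches(seqs, fwd) <= max_mismatch
    if (!any(hit)) next
    tag[hit] <- rg
    seqs[hit] <- substr(seqs[hit], nchar(fwd) + 1L, nchar(seqs[hit]))
    quals[hit] <- substr(quals[hit], nchar(fwd) + 1L, nchar(quals[hit]))
    tail_hit <- hit & suffix_mismatches(seqs, rev_rc) <= max_mismatch
    if (any(tail_hit)) {
      keep <- nchar(seqs[tail_hit]) - nchar(rev_rc)
      seqs[tail_hit] <- substr(seqs[tail_hit], 1L, keep)
      quals[tail_hit] <- substr(quals[tail_hit], 1L, keep)
    }
  }
  merged$sequence <- seqs
  merged$qualities <- quals
  merged$region_tag <- tag
  merged
}

# Hamming mismatches of `probe` against the start/end of each sequence;
# sequences shorter than the probe count as no match (Inf).
prefix_mismatches <- function(seqs, probe) {
  n <- nchar(probe)
  out <- rep(Inf, length(seqs))
  ok <- nchar(seqs) >= n
  if (any(ok)) {
    pre <- substr(seqs[ok], 1L, n)
    out[ok] <- hamming_many(pre, probe)
  }
  out
}
suffix_mismatches <- function(seqs, probe) {
  n <- nchar(probe)
  out <- rep(Inf, length(seqs))
  ok <- nchar(seqs) >= n
  if (any(ok)) {
    suf <- substr(seqs[ok], nchar(seqs[ok]) - n + 1L, nchar(seqs[ok]))
    out[ok] <- hamming_many(suf, probe)
  }
  out
}
hamming_many <- function(xs, probe) {
  pb <- strsplit(probe, "", fixed = TRUE)[[1]]
  vapply(strsplit(xs, "", fixed = TRUE),
         function(b) sum(b != pb), numeric(1))
}

#' Discard reads whose expected error count exceeds a maximum
#'
#' The expected error of a read is `sum(10^(-Q/10))` over its quality
#' scores; the comparison is strictly greater-than, so a read at exactly
#' `max_ee` is kept.
#'
#' @param merged Data frame with `qualities` (Phred+33 string) or
#'   `expected_errors` column.
#' @param max_ee Expected-error ceiling (default 1.0).
#' @return The retained rows.
#' @export
maxee_filter <- function(merged, max_ee = 1.0) {
  ee <- if (!is.null(merged$expected_errors)) merged$expected_errors
        else vapply(merged$qualities, function(q) expected_errors(char_to_phred(q)),
                    numeric(1))
  merged[ee <= max_ee, , drop = FALSE]
}

#' Run the full preprocessing chain on simulated reads
#'
#' merge -> length filter (>= `min_len`) -> primer strip -> expected-error
#' filter, returning per-region read tables ready for dereplication.
#'
#' @param sim An `amf_simreads` object (or any list with a compatible
#'   `reads` data frame).
#' @param min_len,max_ee,min_overlap,max_mismatch_frac Filter settings.
#' @return List with `reads` (read_id, sample_id, sequence, qualities,
#'   expected_errors, region_tag), `rejected` (read_id, reason) and
#'   `log` (named counts per stage).
#' @export
preprocess_reads <- function(sim, min_len = 120L, max_ee = 1.0,
                             min_overlap = 16L, max_mismatch_frac = 0.25) {
  mg <- merge_read_table(sim$reads, min_overlap, max_mismatch_frac)
  n0 <- nrow(sim$reads)
  lf <- length_filter(mg$merged, min_len)
  st <- strip_primers(lf)
  ee <- maxee_filter(st, max_ee)
  list(reads = ee,
       rejected = mg$rejected,
       log = c(input = n0, merged = nrow(mg$merged), length_ok = nrow(lf),
               maxee_ok = nrow(ee)))
}
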