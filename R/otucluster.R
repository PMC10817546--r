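#' Dereplicate reads into unique sequences with abundances
#'
#' Groups exactly identical sequences, keeping per-sample counts. The
#' result is ordered by total abundance (descending) with ties broken by
#' lexicographic sequence order, the canonical input order for
#' abundance-greedy clustering.
#'
#' @param reads Data frame with `sequence` and `sample_id` columns.
#' @return Data frame of class `amf_dereps`: `sequence`, `total_abundance`,
#'   plus one `count.<sample>` column per sample.
#' @export
dereplicate <- function(reads) {
  if (nrow(reads) == 0L) {
    out <- data.frame(sequence = character(), total_abundance = integer())
    class(out) <- c("amf_dereps", class(out))
    return(out)
  }
  tab <- table(reads$sequence, reads$sample_id)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  total <- rowSums(counts)
  ord <- order(-total, rownames(counts))
  out <- data.frame(sequence = rownames(counts)[ord],
                    total_abundance = as.integer(total[ord]),
                    stringsAsFactors = FALSE)
  cm <- counts[ord, , drop = FALSE]
  colnames(cm) <- paste0("count.", colnames(cm))
  out <- cbind(out, as.data.frame(cm, row.names = NULL))
  rownames(out) <- NULL
  class(out) <- c("amf_dereps", class(out))
  out
}

derep_sample_cols <- function(dereps) {
  grep("^count\\.", names(dereps), value = TRUE)
}

#' Map dereplicated sequences onto reference centroids (closed-reference step)
#'
#' Every dereplicated sequence is assigned to the reference centroid with
#' the highest global identity, provided that identity reaches `threshold`;
#' ties go to the centroid with the larger current mapped abundance, then to
#' the lexicographically smallest accession. Singletons are eligible — this
#' is the asymmetric singleton policy that lets reliable one-off reads
#' survive via the reference database. A shared-k-mer prefilter skips
#' alignments that cannot reach the identity threshold.
#'
#' @param dereps An `amf_dereps` frame.
#' @param centroids Named character vector of reference centroid sequences
#'   (names = accessions).
#' @param threshold Identity radius (default 0.97).
#' @param prefilter_k,prefilter_min Prefilter k-mer size and minimum shared
#'   k-mer fraction; set `prefilter_min = 0` to disable.
#' @return List with `mapped` (data frame: sequence index `derep_row`,
#'   `accession`, `identity`) and `unmapped` (the unassigned derep rows).
#' @export
closed_ref_map <- function(dereps, centroids, threshold = 0.97,
                           prefilter_k = 8L, prefilter_min = 0.2) {
  if (nrow(dereps) == 0L || length(centroids) == 0L)
    return(list(mapped = data.frame(derep_row = integer(), accession = character(),
                                    identity = numeric()),
                unmapped = dereps))
  stopifnot(!is.null(names(centroids)))
  idm <- identity_to_refs(dereps$sequence, centroids, prefilter_k, prefilter_min)
  n <- nrow(dereps)
  mapped_rows <- integer(); mapped_acc <- character(); mapped_id <- numeric()
  # current mapped abundance per centroid, for the tie rule
  cur_ab <- stats::setNames(numeric(length(centroids)), names(centroids))
  for (i in seq_len(n)) {
    ids <- idm[i, ]
    best <- max(ids)
    if (is.finite(best) && best >= threshold) {
      cand <- names(centroids)[ids == best]
      if (length(cand) > 1L) {
        ab <- cur_ab[cand]
        cand <- cand[ab == max(ab)]
        cand <- sort(cand)[1]
      }
      mapped_rows <- c(mapped_rows, i)
      mapped_acc <- c(mapped_acc, cand)
      mapped_id <- c(mapped_id, best)
      cur_ab[cand] <- cur_ab[cand] + dereps$total_abundance[i]
    }
  }
  list(mapped = data.frame(derep_row = mapped_rows, accession = mapped_acc,
                           identity = mapped_id, stringsAsFactors = FALSE),
       unmapped = dereps[setdiff(seq_len(n), mapped_rows), , drop = FALSE])
}

# Identity matrix dereps x centroids, with a shared-k-mer prefilter: pairs
# sharing too few k-mers are reported as -Inf without alignment.
identity_to_refs <- function(seqs, centroids, k = 8L, min_shared = 0.2) {
  n <- length(seqs); m <- length(centroids)
  out <- matrix(-Inf, n, m)
  if (min_shared > 0 && all(nchar(c(seqs, centroids)) > k)) {
    qk <- kmer_sets(seqs, k)
    ck <- kmer_sets(centroids, k)
    cand <- matrix(FALSE, n, m)
    for (j in seq_len(m)) {
      cand[, j] <- vapply(qk, function(s)
        length(intersect(s, ck[[j]])) / max(1L, length(s)) >= min_shared,
        logical(1))
    }
  } else {
    cand <- matrix(TRUE, n, m)
  }
  for (j in seq_len(m)) {
    rows <- which(cand[, j])
    if (length(rows))
      out[rows, j] <- global_identity_many(seqs[rows], centroids[[j]])
  }
  out
}

kmer_sets <- function(seqs, k) {
  lapply(seqs, function(s) {
    if (nchar(s) < k) return(character())
    unique(substring(s, seq_len(nchar(s) - k + 1L), k:nchar(s)))
  })
}

#' Abundance-greedy de novo OTU clustering with chimera removal
#'
#' One greedy pass over dereplicated sequences sorted by (abundance
#' descending, sequence ascending): a sequence joins the highest-identity
#' existing de novo centroid at identity >= `radius` (ties to the earlier,
#' i.e. more abundant, centroid); otherwise it is tested as a two-parent
#' chimera of the current centroids and discarded if positive; otherwise it
#' founds a new centroid. After the pass, centroids whose total member
#' abundance is 1 (residual singletons) are removed together with their
#' assignments — the de novo side of the asymmetric singleton policy.
#'
#' @param dereps An `amf_dereps` frame (the unmapped sequences).
#' @param radius Identity radius (default 0.97).
#' @param chimera_identity Identity a crossover model must reach for a
#'   chimera verdict (default 0.99).
#' @param extra_centroids Additional centroid sequences (the reference
#'   centroids of the closed-reference step) eligible as chimera parents;
#'   chimeric amplicons of two reference-mapped parents are otherwise
#'   undetectable when few de novo centroids exist.
#' @return List with `centroids` (data frame: otu_id, centroid_sequence),
#'   `assignments` (derep_row, otu_id, identity), `discarded`
#'   (derep_row, reason).
#' @export
denovo_cluster <- function(dereps, radius = 0.97, chimera_identity = 0.99,
                           extra_centroids = character()) {
  n <- nrow(dereps)
  cent_seq <- character(); cent_rows <- integer()
  assign_row <- integer(); assign_otu <- integer(); assign_id <- numeric()
  discard_row <- integer(); discard_reason <- character()
  ord <- order(-dereps$total_abundance, dereps$sequence)
  member_ab <- numeric()

  for (i in ord) {
    s <- dereps$sequence[i]
    best_single <- NULL
    if (length(cent_seq)) {
      ids <- global_identity_many(cent_seq, s)
      j <- which.max(ids)  # earliest (most abundant centroid) wins ties
      if (ids[j] >= radius) {
        assign_row <- c(assign_row, i); assign_otu <- c(assign_otu, j)
        assign_id <- c(assign_id, ids[j])
        member_ab[j] <- member_ab[j] + dereps$total_abundance[i]
        next
      }
      best_single <- max(ids)  # < radius vs extras too (they are unmapped)
    }
    if (chimera_check(s, c(cent_seq, extra_centroids), radius = radius,
                      chimera_identity = chimera_identity,
                      best_single = best_single)) {
      discard_row <- c(discard_row, i)
      discard_reason <- c(discard_reason, "chimera")
      next
    }
    cent_seq <- c(cent_seq, s); cent_rows <- c(cent_rows, i)
    j <- length(cent_seq)
    member_ab[j] <- dereps$total_abundance[i]
    assign_row <- c(assign_row, i); assign_otu <- c(assign_otu, j)
    assign_id <- c(assign_id, 1.0)
  }

  # Residual-singleton removal: centroids whose final abundance is 1.
  keep <- which(member_ab > 1)
  relabel <- match(seq_along(cent_seq), keep)
  dropped <- assign_otu %in% which(member_ab <= 1)
  discard_row <- c(discard_row, assign_row[dropped])
  discard_reason <- c(discard_reason,
                      rep("residual_singleton", sum(dropped)))
  assign_row <- assign_row[!dropped]
  assign_id <- assign_id[!dropped]
  assign_otu <- relabel[assign_otu[!dropped]]

  otu_ids <- sprintf("DN%04d", seq_along(keep))
  list(centroids = data.frame(otu_id = otu_ids,
                              centroid_sequence = cent_seq[keep],
                              derep_row = cent_rows[keep],
                              stringsAsFactors = FALSE),
       assignments = data.frame(derep_row = assign_row,
                                otu_id = otu_ids[assign_otu],
                                identity = assign_id,
                                stringsAsFactors = FALSE),
       discarded = data.frame(derep_row = discard_row,
                              reason = discard_reason,
                              stringsAsFactors = FALSE))
}

#' Test whether a query is a two-parent single-crossover chimera
#'
#' The query is chimeric when some model taking a left prefix from one
#' centroid and the right suffix from another (crossover scanned at 1-bp
#' granularity over the query) matches the query at identity >=
#' `chimera_identity`, while the query's best single-parent identity is
#' below `radius`. Match profiles against each parent come from one global
#' alignment per parent projected onto query coordinates.
#'
#' @param query Sequence to test.
#' @param centroids Character vector of current centroid sequences (fewer
#'   than two centroids can never yield a chimera verdict).
#' @param radius De novo identity radius.
#' @param chimera_identity Crossover-model identity threshold.
#' @param best_single Optional precomputed best single-parent identity.
#' @return `TRUE` iff the query is called chimeric.
#' @export
chimera_check <- function(query, centroids, radius = 0.97,
                          chimera_identity = 0.99, best_single = NULL) {
  if (length(centroids) < 2L) return(FALSE)
  if (is.null(best_single))
    best_single <- max(vapply(centroids, function(cs) global_identity(query, cs),
                              numeric(1)))
  if (best_single >= radius) return(FALSE)
  L <- nchar(query)
  profiles <- lapply(centroids, function(cs) query_match_profile(query, cs))
  pre <- lapply(profiles, cumsum)                 # matches in query[1..k]
  tot <- vapply(profiles, sum, numeric(1))
  for (a in seq_along(centroids)) {
    for (b in seq_along(centroids)) {
      if (a == b) next
      # crossover after position k: matches = pre_a[k] + (tot_b - pre_b[k])
      sc <- pre[[a]] + tot[b] - pre[[b]]
      if (max(sc) / L >= chimera_identity) return(TRUE)
    }
  }
  FALSE
}

# Per-query-position match indicator against a parent, from one global
# alignment; positions aligned to a gap or mismatching count 0.
query_match_profile <- function(query, parent) {
  al <- align_pair(query, parent)
  qa <- strsplit(al[1], "", fixed = TRUE)[[1]]
  pa <- strsplit(al[2], "", fixed = TRUE)[[1]]
  is_q <- qa != "-"
  m <- (qa == pa)[is_q]
  as.numeric(m)
}

#' Build the OTU table from mapped and de novo assignments
#'
#' Counts are summed read abundances per (sample, OTU); reference-origin and
#' de novo OTUs coexist. Reference OTUs are labelled by their accession,
#' de novo OTUs by stable `DN` ids. All-zero OTU columns never occur.
#'
#' @param dereps The full `amf_dereps` frame used for both steps.
#' @param mapping Result of [closed_ref_map()].
#' @param denovo Result of [denovo_cluster()] on `mapping$unmapped`.
#' @param marker Marker label stored on the table (`"ITS1"`/`"ITS2"`).
#' @return Object of class `amf_otutable`: list with `counts` (samples x
#'   OTUs integer matrix), `otus` (otu_id, origin, centroid_sequence,
#'   centroid_accession), `marker`.
#' @export
build_otu_table <- function(dereps, mapping, denovo, marker = "ITS1") {
  sample_cols <- derep_sample_cols(dereps)
  samples <- sub("^count\\.", "", sample_cols)
  unmapped_rows <- as.integer(rownames(mapping$unmapped))
  if (nrow(mapping$unmapped) && is.null(rownames(mapping$unmapped)))
    stop("unmapped dereps must keep their original row indices")

  recs <- list()
  if (nrow(mapping$mapped)) {
    for (acc in unique(mapping$mapped$accession)) {
      rows <- mapping$mapped$derep_row[mapping$mapped$accession == acc]
      recs[[length(recs) + 1L]] <- list(otu_id = acc, origin = "reference",
                                        accession = acc, rows = rows,
                                        centroid = NA_character_)
    }
  }
  if (nrow(denovo$centroids)) {
    for (k in seq_len(nrow(denovo$centroids))) {
      oid <- denovo$centroids$otu_id[k]
      sub_rows <- denovo$assignments$derep_row[denovo$assignments$otu_id == oid]
      # assignment rows index into mapping$unmapped
      rows <- unmapped_rows[sub_rows]
      recs[[length(recs) + 1L]] <- list(otu_id = oid, origin = "denovo",
                                        accession = NA_character_, rows = rows,
                                        centroid = denovo$centroids$centroid_sequence[k])
    }
  }
  counts <- matrix(0L, nrow = length(samples), ncol = length(recs),
                   dimnames = list(samples,
                                   vapply(recs, function(r) r$otu_id, character(1))))
  for (k in seq_along(recs)) {
    sub <- dereps[recs[[k]]$rows, sample_cols, drop = FALSE]
    counts[, k] <- as.integer(colSums(sub))
  }
  nonzero <- colSums(counts) > 0L
  counts <- counts[, nonzero, drop = FALSE]
  recs <- recs[nonzero]
  otus <- data.frame(
    otu_id = vapply(recs, function(r) r$otu_id, character(1)),
    origin = vapply(recs, function(r) r$origin, character(1)),
    centroid_sequence = vapply(recs, function(r)
      if (is.na(r$centroid)) NA_character_ else r$centroid, character(1)),
    centroid_accession = vapply(recs, function(r) r$accession, character(1)),
    stringsAsFactors = FALSE)
  structure(list(counts = counts, otus = otus, marker = marker),
            class = "amf_otutable")
}

#' Two-step OTU construction for one marker
#'
#' Dereplicates the preprocessed reads of one region, maps them against the
#' reference centroids at the identity radius, clusters the remainder de
#' novo (with chimera and residual-singleton removal) and assembles the OTU
#' table. Centroid sequences of reference OTUs are filled in from the
#' reference set.
#'
#' @param reads Preprocessed read frame (must carry `region_tag`).
#' @param ref_centroids Named character vector of reference centroids for
#'   this marker.
#' @param marker `"ITS1"` or `"ITS2"`.
#' @param radius Identity radius.
#' @param chimera_identity Chimera model threshold.
#' @return List with `table` (an `amf_otutable`), `dereps`, `mapping`,
#'   `denovo`, and a per-sample read `conservation` frame
#'   (assigned + discarded = input).
#' @export
cluster_marker <- function(reads, ref_centroids, marker = "ITS1",
                           radius = 0.97, chimera_identity = 0.99) {
  sel <- reads[reads$region_tag == marker, , drop = FALSE]
  dereps <- dereplicate(sel)
  mapping <- closed_ref_map(dereps, ref_centroids, threshold = radius)
  denovo <- denovo_cluster(mapping$unmapped, radius = radius,
                           chimera_identity = chimera_identity,
                           extra_centroids = unname(ref_centroids))
  tab <- build_otu_table(dereps, mapping, denovo, marker = marker)
  # fill reference centroid sequences
  ref_rows <- tab$otus$origin == "reference"
  tab$otus$centroid_sequence[ref_rows] <-
    unname(ref_centroids[tab$otus$centroid_accession[ref_rows]])

  sample_cols <- derep_sample_cols(dereps)
  unmapped_rows <- as.integer(rownames(mapping$unmapped))
  disc_rows <- unmapped_rows[denovo$discarded$derep_row]
  per_sample_in <- colSums(dereps[, sample_cols, drop = FALSE])
  per_sample_disc <- if (length(disc_rows))
    colSums(dereps[disc_rows, sample_cols, drop = FALSE]) else 0 * per_sample_in
  conservation <- data.frame(
    sample_id = sub("^count\\.", "", sample_cols),
    reads_in = as.integer(per_sample_in),
    reads_assigned = as.integer(per_sample_in - per_sample_disc),
    reads_discarded = as.integer(per_sample_disc))
  list(table = tab, dereps = dereps, mapping = mapping, denovo = denovo,
       conservation = conservation)
}
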