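#' Annotate a sequence by its best reference hit
#'
#' Global identity against every reference region sequence of the marker;
#' the lineage (down to genus) of the best hit is inherited when the best
#' identity reaches `min_identity`, else the sequence is unclassified.
#' Equal-identity ties are flagged ambiguous and resolved to the
#' lexicographically smallest accession.
#'
#' @param seq Query sequence (a primer-stripped amplicon).
#' @param db An `amf_refdb`.
#' @param marker `"ITS1"` or `"ITS2"`.
#' @param min_identity Identity floor for phylum-level classification
#'   (default 0.80).
#' @return One-row data frame: accession, identity, phylum...genus,
#'   classified (logical), ambiguous (logical).
#' @export
annotate_best_hit <- function(seq, db, marker = "ITS1", min_identity = 0.80) {
  annotate_many(seq, db, marker, min_identity)
}

# Vectorized annotation: identity of every query against every reference
# region sequence (one vectorized alignment call per reference).
annotate_many <- function(seqs, db, marker = "ITS1", min_identity = 0.80) {
  refs <- ref_region_seqs(db, marker, with_anchors = TRUE)
  if (length(refs) == 0L) stop("reference database is empty")
  ids <- vapply(refs, function(r) global_identity_many(seqs, r),
                numeric(length(seqs)))
  if (length(seqs) == 1L) ids <- matrix(ids, nrow = 1, dimnames = list(NULL, names(refs)))
  rows <- lapply(seq_along(seqs), function(i) {
    best <- max(ids[i, ])
    cand <- sort(names(refs)[ids[i, ] >= best - 1e-12])
    amb <- length(cand) > 1L
    acc <- cand[1]
    row <- db$taxa[db$taxa$accession == acc, , drop = FALSE]
    classified <- best >= min_identity
    data.frame(accession = if (classified) acc else NA_character_,
               identity = best,
               phylum = if (classified) row$phylum else "unclassified",
               class = if (classified) row$class else NA_character_,
               order = if (classified) row$order else NA_character_,
               family = if (classified) row$family else NA_character_,
               genus = if (classified) row$genus else NA_character_,
               classified = classified, ambiguous = amb,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Trim rRNA coding flanks, leaving the spacer
#'
#' Locates the conserved left/right anchor motifs (at most `max_mismatch`
#' mismatches each) that the amplicon retains around the spacer and returns
#' the sequence between them. When an anchor cannot be found the input is
#' returned unchanged and flagged untrimmed (soft failure).
#'
#' @param seq Sequence to trim.
#' @param region `"ITS1"` or `"ITS2"` (selects the anchor pair).
#' @param anchors Anchor set as returned by [amf_anchors()].
#' @param max_mismatch Mismatches tolerated per anchor.
#' @return List with `sequence` and `trimmed` (logical).
#' @export
trim_rrna <- function(seq, region = c("ITS1", "ITS2"), anchors = amf_anchors(),
                      max_mismatch = 1L) {
  region <- match.arg(region)
  left <- anchors[[region]]$left
  right <- anchors[[region]]$right
  lpos <- find_motif(seq, left, max_mismatch)
  rpos <- find_motif(seq, right, max_mismatch,
                     from = if (is.na(lpos)) 1L else lpos + nchar(left))
  if (is.na(lpos) || is.na(rpos) || rpos <= lpos + nchar(left) - 1L)
    return(list(sequence = seq, trimmed = FALSE))
  list(sequence = substr(seq, lpos + nchar(left), rpos - 1L), trimmed = TRUE)
}

# First position (1-based) where `motif` matches with <= max_mismatch
# mismatches, or NA.
find_motif <- function(seq, motif, max_mismatch = 1L, from = 1L) {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(NA_integer_)
  mb <- strsplit(motif, "", fixed = TRUE)[[1]]
  sb <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in seq.int(from, n - m + 1L)) {
    if (sum(sb[p:(p + m - 1L)] != mb) <= max_mismatch) return(p)
  }
  NA_integer_
}

#' Species-diagnostic alignment positions within a genus
#'
#' A position is diagnostic for species S when every reference of S carries
#' one state there and every other congeneric reference carries a single,
#' different state (gaps disqualify).
#'
#' @param ref_alignment Character matrix of reference rows (aligned).
#' @param species Character vector of species labels, one per row.
#' @return Named list (per species) of data frames with `pos` and `state`.
#' @export
diagnostic_sites <- function(ref_alignment, species) {
  stopifnot(nrow(ref_alignment) == length(species))
  out <- list()
  for (sp in unique(species)) {
    inn <- ref_alignment[species == sp, , drop = FALSE]
    outg <- ref_alignment[species != sp, , drop = FALSE]
    if (nrow(outg) == 0L) { out[[sp]] <- data.frame(pos = integer(), state = character()); next }
    pos <- integer(); st <- character()
    for (j in seq_len(ncol(ref_alignment))) {
      a <- unique(inn[, j]); b <- unique(outg[, j])
      if (length(a) == 1L && length(b) == 1L && a != b && a != "-" && b != "-") {
        pos <- c(pos, j); st <- c(st, a)
      }
    }
    out[[sp]] <- data.frame(pos = pos, state = st, stringsAsFactors = FALSE)
  }
  out
}

#' Default thresholds for the clade decision rules
#'
#' @param s_min Minimum bootstrap support (percent) for a clade to count.
#' @param t_species Maximum p-distance to a reference for a species call.
#' @param t_genus p-distance beyond which an unplaced OTU is excluded as a
#'   higher-rank virtual taxon.
#' @return Named list of thresholds.
#' @export
taxon_thresholds <- function(s_min = 70, t_species = 0.03, t_genus = 0.15) {
  list(s_min = s_min, t_species = t_species, t_genus = t_genus)
}

#' Apply the clade decision rules to one genus bin
#'
#' Rules, in order: (1) an OTU inside a supported clade whose references
#' all belong to one species, within `t_species` of the nearest such
#' reference and not contradicting that species' diagnostic sites, is
#' called to that species; (2) maximal supported reference-free clades with
#' at least two OTUs become species-level virtual taxa (one shared label);
#' (3) an OTU in no supported clade and farther than `t_genus` from every
#' reference is excluded as a higher-rank VT; (4) remaining OTUs form
#' species-level VTs with other unplaced OTUs within `t_species`
#' (single-linkage), else are excluded. Clades are minority sides of
#' supported bipartitions. Deterministic and invariant to OTU input order.
#'
#' @param tree Unrooted `phylo` over OTUs and references (or `NULL` for
#'   bins too small for a tree; rule 1 then uses distances alone).
#' @param supports Named support vector from [bootstrap_support()].
#' @param dmat Symmetric p-distance matrix over all leaves.
#' @param otu_ids Leaf names that are OTUs.
#' @param ref_species Named character vector: leaf name -> species, for
#'   reference leaves.
#' @param genus Genus label used in VT labels.
#' @param thresholds A [taxon_thresholds()] list.
#' @param diag Optional [diagnostic_sites()] result.
#' @param otu_alignment Optional aligned rows for the OTUs (needed only for
#'   the diagnostic-site check).
#' @return Data frame of taxon calls: otu_id, verdict (`species`,
#'   `vt_species`, `excluded_vt_higher`), label, support,
#'   nearest_ref_p_distance.
#' @export
classify_clades <- function(tree, supports, dmat, otu_ids, ref_species,
                            genus = "Genus", thresholds = taxon_thresholds(),
                            diag = NULL, otu_alignment = NULL) {
  leaves <- rownames(dmat)
  otu_ids <- intersect(leaves, otu_ids)
  refs <- intersect(leaves, names(ref_species))
  nearest_ref <- function(o, sp = NULL) {
    rr <- if (is.null(sp)) refs else refs[ref_species[refs] == sp]
    if (!length(rr)) return(c(NA_real_, NA))
    dd <- dmat[o, rr]
    k <- which.min(dd)
    c(dd[k], rr[k])
  }

  clades <- list(); clade_support <- numeric()
  if (!is.null(tree)) {
    n_leaves <- length(leaves)
    splits <- tree_splits(tree)
    for (key in names(splits)) {
      sup <- if (key %in% names(supports)) supports[[key]] else NA_real_
      if (is.na(sup) || sup < thresholds$s_min) next
      side <- splits[[key]]
      other <- setdiff(leaves, side)
      for (s in list(side, other)) {
        if (length(s) >= 2L && length(s) <= n_leaves / 2) {
          clades[[length(clades) + 1L]] <- sort(s)
          clade_support <- c(clade_support, sup)
        }
      }
    }
  }

  verdict <- stats::setNames(rep(NA_character_, length(otu_ids)), otu_ids)
  label <- support_out <- stats::setNames(rep(NA_character_, length(otu_ids)), otu_ids)
  support_out <- stats::setNames(rep(NA_real_, length(otu_ids)), otu_ids)
  ndist <- stats::setNames(rep(NA_real_, length(otu_ids)), otu_ids)

  # Rule 1: species via smallest supported reference-containing clade.
  for (o in otu_ids) {
    nr <- nearest_ref(o)
    ndist[o] <- as.numeric(nr[1])
    cands <- which(vapply(clades, function(cl) o %in% cl && any(cl %in% refs),
                          logical(1)))
    use_tree <- length(clades) > 0L
    if (use_tree) {
      if (!length(cands)) next
      k <- cands[which.min(vapply(cands, function(i) length(clades[[i]]), numeric(1)))]
      cl <- clades[[k]]
      sps <- unique(ref_species[intersect(cl, refs)])
      if (length(sps) != 1L) next
      nr_sp <- nearest_ref(o, sps)
      if (as.numeric(nr_sp[1]) > thresholds$t_species) next
      if (diag_contradicts(o, sps, diag, otu_alignment)) next
      verdict[o] <- "species"; label[o] <- sps
      support_out[o] <- clade_support[k]
      ndist[o] <- as.numeric(nr_sp[1])
    } else {
      # no usable clades (tiny bin): distance-only species call
      if (!is.na(ndist[o]) && ndist[o] <= thresholds$t_species) {
        sp <- as.character(nearest_ref(o)[2])
        sps <- ref_species[[sp]]
        if (!diag_contradicts(o, sps, diag, otu_alignment)) {
          verdict[o] <- "species"; label[o] <- sps
        }
      }
    }
  }

  # Rule 2: each uncalled OTU joins its smallest supported reference-free
  # clade; OTUs sharing that clade form one species-level VT. Smallest (not
  # maximal) clades keep sibling ref-free species separate when each has
  # its own supported cluster.
  vt_groups <- list()
  if (length(clades)) {
    free <- which(vapply(clades, function(cl) !any(cl %in% refs), logical(1)))
    if (length(free)) {
      key <- stats::setNames(rep(NA_integer_, length(otu_ids)), otu_ids)
      for (o in otu_ids) {
        if (!is.na(verdict[o])) next
        cands <- free[vapply(free, function(i) o %in% clades[[i]], logical(1))]
        if (!length(cands)) next
        key[o] <- cands[which.min(vapply(cands, function(i)
          length(clades[[i]]), numeric(1)))]
      }
      # merge groups whose key clades are nested (an OTU whose smallest
      # reference-free clade strictly contains another group's clade belongs
      # with that group); disjoint sibling clades stay separate
      used <- unique(stats::na.omit(key))
      parent <- stats::setNames(used, used)
      findp <- function(x) { while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]; x }
      for (a in used) for (b in used) {
        if (a == b) next
        if (all(clades[[a]] %in% clades[[b]])) {
          ra <- findp(a); rb <- findp(b)
          if (ra != rb) parent[[as.character(ra)]] <- rb
        }
      }
      root_of <- vapply(used, findp, numeric(1))
      for (r in unique(root_of)) {
        ks <- used[root_of == r]
        members <- names(key)[!is.na(key) & key %in% ks]
        if (length(members) >= 2L) {
          vt_groups[[length(vt_groups) + 1L]] <-
            list(members = members, support = max(clade_support[ks]))
        }
      }
    }
  }

  # Rule 3: unplaced loners far from every reference are excluded.
  in_any_clade <- vapply(otu_ids, function(o)
    any(vapply(clades, function(cl) o %in% cl, logical(1))), logical(1))
  for (o in otu_ids) {
    if (!is.na(verdict[o])) next
    if (o %in% unlist(lapply(vt_groups, `[[`, "members"))) next
    far <- is.na(ndist[o]) || ndist[o] > thresholds$t_genus
    if (!in_any_clade[[o]] && far) verdict[o] <- "excluded_vt_higher"
  }

  # Rule 4: remaining unplaced OTUs pair up at t_species or are excluded.
  rest <- otu_ids[is.na(verdict[otu_ids]) &
                    !otu_ids %in% unlist(lapply(vt_groups, `[[`, "members"))]
  if (length(rest)) {
    comp <- single_linkage(dmat[rest, rest, drop = FALSE], thresholds$t_species)
    for (cmp in split(rest, comp)) {
      if (length(cmp) >= 2L) {
        vt_groups[[length(vt_groups) + 1L]] <- list(members = cmp, support = NA_real_)
      } else {
        verdict[cmp] <- "excluded_vt_higher"
      }
    }
  }

  # Stable VT labels: clades ordered by their lexicographically smallest
  # member (sequence order is inherited through leaf naming upstream).
  if (length(vt_groups)) {
    keys <- vapply(vt_groups, function(g) min(g$members), character(1))
    for (k in seq_along(vt_groups)) {
      g <- vt_groups[[order(keys)[k]]]
      lab <- sprintf("VT_%s_%d", genus, k)
      for (o in g$members) {
        verdict[o] <- "vt_species"; label[o] <- lab
        support_out[o] <- g$support
      }
    }
  }

  data.frame(otu_id = otu_ids, verdict = unname(verdict[otu_ids]),
             label = unname(label[otu_ids]),
             support = unname(support_out[otu_ids]),
             nearest_ref_p_distance = unname(ndist[otu_ids]),
             stringsAsFactors = FALSE)
}

diag_contradicts <- function(o, sp, diag, otu_alignment) {
  if (is.null(diag) || is.null(otu_alignment)) return(FALSE)
  if (!sp %in% names(diag) || !o %in% rownames(otu_alignment)) return(FALSE)
  dd <- diag[[sp]]
  if (!nrow(dd)) return(FALSE)
  states <- otu_alignment[o, dd$pos]
  # contradiction: the OTU misses the species state at more than half the
  # diagnostic positions (robust to a stray substitution)
  mean(states != dd$state) > 0.5
}

single_linkage <- function(d, h) {
  n <- nrow(d)
  if (n == 0L) return(integer(0))
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (d[i, j] <= h && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' Classify all OTUs of a marker against the reference taxonomy
#'
#' Annotates each OTU centroid, bins OTUs by best-hit genus, trims spacers,
#' aligns each bin (center-star), builds the NJ tree with bootstrap
#' supports and applies the clade decision rules. OTUs that fail
#' phylum-level annotation are reported unclassified.
#'
#' @param otutab An `amf_otutable`.
#' @param db An `amf_refdb`.
#' @param thresholds A [taxon_thresholds()].
#' @param n_boot Bootstrap replicates per genus tree.
#' @param seed Seed for bootstrap resampling.
#' @param amf_only Classify only OTUs annotated to Glomeromycota.
#' @return List with `calls` (taxon-call frame with genus and annotation
#'   columns), `bins` (per-genus leaf sets), `trees` (per-genus `phylo`).
#' @export
classify_otus <- function(otutab, db, thresholds = taxon_thresholds(),
                          n_boot = 100L, seed = 1L, amf_only = TRUE) {
  otus <- otutab$otus
  if (nrow(otus) == 0L)
    return(list(calls = data.frame(otu_id = character(), verdict = character(),
                                   label = character(), support = numeric(),
                                   nearest_ref_p_distance = numeric(),
                                   genus = character(), accession = character(),
                                   identity = numeric(), phylum = character()),
                bins = list(), trees = list()))
  ann <- annotate_many(otus$centroid_sequence, db, otutab$marker)
  ann$otu_id <- otus$otu_id

  keep <- ann$classified & (!amf_only | ann$phylum == "Glomeromycota")
  calls <- list(); trees <- list(); bins <- list()
  for (g in sort(unique(ann$genus[keep]))) {
    sel <- which(keep & ann$genus == g)
    member_seqs <- vapply(otus$centroid_sequence[sel], function(s)
      trim_rrna(s, otutab$marker)$sequence, character(1), USE.NAMES = FALSE)
    names(member_seqs) <- otus$otu_id[sel]
    ref_rows <- db$taxa$genus == g
    ref_seqs <- ref_region_seqs(db, otutab$marker)[db$taxa$accession[ref_rows]]
    names(ref_seqs) <- paste0("REF|", names(ref_seqs))
    ref_species <- stats::setNames(db$taxa$species[ref_rows],
                                   paste0("REF|", db$taxa$accession[ref_rows]))
    res <- classify_genus_bin(member_seqs, ref_seqs, ref_species, genus = g,
                              thresholds = thresholds, n_boot = n_boot,
                              seed = derive_seed(seed, match(g, sort(unique(ann$genus[keep])))))
    calls[[g]] <- cbind(res$calls, genus = g, stringsAsFactors = FALSE)
    trees[[g]] <- res$tree
    bins[[g]] <- names(member_seqs)
  }
  call_df <- do.call(rbind, c(calls, list(make.row.names = FALSE))) %||%
    data.frame(otu_id = character(), verdict = character(), label = character(),
               support = numeric(), nearest_ref_p_distance = numeric(),
               genus = character())
  excluded <- which(!keep)
  if (length(excluded)) {
    call_df <- rbind(call_df, data.frame(
      otu_id = ann$otu_id[excluded],
      verdict = ifelse(ann$classified[excluded], "nontarget", "unclassified"),
      label = NA_character_,
      support = NA_real_, nearest_ref_p_distance = NA_real_,
      genus = NA_character_, stringsAsFactors = FALSE))
  }
  list(calls = merge(call_df, ann[, c("otu_id", "accession", "identity", "phylum")],
                     by = "otu_id", sort = TRUE),
       bins = bins, trees = trees)
}

#' Align one genus bin and classify its members
#'
#' @param member_seqs Named OTU spacer sequences.
#' @param ref_seqs Named reference spacer sequences (may be empty).
#' @param ref_species Accession -> species map for the references.
#' @inheritParams classify_otus
#' @param genus Genus label.
#' @return List with `calls`, `tree`, `supports`, `alignment`, `dmat`.
#' @export
classify_genus_bin <- function(member_seqs, ref_seqs, ref_species,
                               genus = "Genus",
                               thresholds = taxon_thresholds(),
                               n_boot = 100L, seed = 1L) {
  seqs <- c(member_seqs, ref_seqs)
  if (anyDuplicated(names(seqs))) stop("duplicate leaf names in genus bin")
  aln <- center_star_align(seqs)
  dmat <- p_distance_matrix(aln)
  tree <- NULL; supports <- stats::setNames(numeric(0), character(0))
  if (length(seqs) >= 4L) {
    tree <- nj_tree(dmat)
    supports <- bootstrap_support(aln, tree, n_reps = n_boot, seed = seed)
  } else if (length(seqs) == 3L) {
    tree <- nj_tree(dmat)  # no internal edges, no supports
  }
  diag <- NULL
  ref_in <- intersect(rownames(aln), names(ref_species))
  if (length(ref_in) >= 2L && length(unique(ref_species[ref_in])) >= 2L)
    diag <- diagnostic_sites(aln[ref_in, , drop = FALSE], ref_species[ref_in])
  calls <- classify_clades(tree, supports, dmat, names(member_seqs),
                           ref_species, genus = genus, thresholds = thresholds,
                           diag = diag, otu_alignment = aln)
  list(calls = calls, tree = tree, supports = supports,
       alignment = aln, dmat = dmat)
}

#' Per-biotope species/VT/OTU summaries and shared/endemic sets
#'
#' @param calls Taxon-call frame (needs otu_id, verdict, label).
#' @param otutab The matching `amf_otutable`.
#' @param biotope_map Named vector sample_id -> biotope.
#' @return List with `per_biotope` (biotope, n_otus, n_species, n_vt),
#'   `venn` (named intersection counts over species+VT labels),
#'   `endemics` (biotope -> species labels found only there).
#' @export
species_summary <- function(calls, otutab, biotope_map) {
  counts <- otutab$counts
  biotopes <- unique(unname(biotope_map[rownames(counts)]))
  present <- lapply(biotopes, function(b) {
    rows <- rownames(counts)[biotope_map[rownames(counts)] == b]
    otus <- colnames(counts)[colSums(counts[rows, , drop = FALSE]) > 0]
    otus
  })
  names(present) <- biotopes

  lab_of <- stats::setNames(calls$label, calls$otu_id)
  verdict_of <- stats::setNames(calls$verdict, calls$otu_id)
  species_sets <- lapply(present, function(otus) {
    v <- verdict_of[otus]
    sort(unique(stats::na.omit(lab_of[otus][v %in% c("species", "vt_species")])))
  })
  known_sets <- lapply(present, function(otus) {
    v <- verdict_of[otus]
    sort(unique(stats::na.omit(lab_of[otus][v == "species"])))
  })
  per_biotope <- data.frame(
    biotope = biotopes,
    n_otus = vapply(present, length, integer(1)),
    n_species = vapply(known_sets, length, integer(1)),
    n_vt = vapply(species_sets, length, integer(1)) -
      vapply(known_sets, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  venn <- venn_counts(species_sets)
  all_labels <- sort(unique(unlist(species_sets)))
  endemics <- lapply(stats::setNames(biotopes, biotopes), function(b) {
    others <- unlist(species_sets[setdiff(biotopes, b)])
    setdiff(species_sets[[b]], others)
  })
  list(per_biotope = per_biotope, venn = venn, endemics = endemics,
       species_sets = species_sets)
}

# Exclusive intersection counts for up to a handful of sets; keys list the
# member sets in alphabetical order.
venn_counts <- function(sets) {
  sets <- sets[sort(names(sets))]
  nms <- names(sets)
  all_items <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) all_items %in% s, logical(length(all_items)))
  if (length(all_items) == 1L) membership <- matrix(membership, nrow = 1,
                                                    dimnames = list(NULL, nms))
  key <- apply(membership, 1L, function(m) paste(nms[m], collapse = "&"))
  as.list(table(key))
}
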