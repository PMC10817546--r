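test_that("dereplication groups exact sequences with the ordering contract", {
  reads <- data.frame(
    sequence = c(rep("AAAA", 5), "AAAT", "CCCC", "AAAT"),
    sample_id = c(rep("S1", 3), "S2", "S2", "S1", "S1", "S2"))
  d <- dereplicate(reads)
  expect_equal(d$sequence, c("AAAA", "AAAT", "CCCC"))
  expect_equal(d$total_abundance, c(5L, 2L, 1L))
  expect_equal(d$count.S1[1], 3L)
  expect_equal(d$count.S2[1], 2L)
  # equal abundance -> lexicographically smaller first
  d2 <- dereplicate(data.frame(sequence = c("TTTT", "GGGG"),
                               sample_id = "S1"))
  expect_equal(d2$sequence, c("GGGG", "TTTT"))
})

test_that("closed-reference mapping applies the 97% best-hit rule", {
  set.seed(8)
  ref <- rand_dna(100)
  refs <- c(R1 = ref, R2 = mutate_at(ref, 1:20))
  d <- make_dereps(c(ref, mutate_at(ref, 1:3), mutate_at(ref, 1:4)),
                   c(5L, 3L, 2L))
  m <- closed_ref_map(d, refs)
  ident <- m$mapped$identity[match(match(ref, d$sequence), m$mapped$derep_row)]
  expect_equal(ident, 1.0)
  # 3 substitutions / 100 -> 0.97, mapped; 4 -> 0.96, unmapped
  expect_equal(nrow(m$mapped), 2)
  expect_equal(nrow(m$unmapped), 1)
  expect_equal(sort(m$mapped$identity), c(0.97, 1.0))
  # singletons are eligible for mapping
  d1 <- make_dereps(mutate_at(ref, 1), 1L)
  m1 <- closed_ref_map(d1, refs)
  expect_equal(nrow(m1$mapped), 1)
  expect_equal(m1$mapped$identity, 0.99)
})

test_that("greedy de novo clustering follows abundance order and removes singletons", {
  set.seed(12)
  A <- rand_dna(100)
  B <- mutate_at(A, 7)        # 1 substitution: within the 97% radius
  C <- mutate_at(A, seq(5, 95, 10))  # 10 substitutions: outside
  d <- make_dereps(c(A, B, C), c(10L, 5L, 3L))
  res <- denovo_cluster(d)
  expect_setequal(res$centroids$centroid_sequence, c(A, C))
  bi <- match(B, d$sequence)
  otuA <- res$centroids$otu_id[res$centroids$centroid_sequence == A]
  expect_equal(res$assignments$otu_id[res$assignments$derep_row == bi], otuA)

  # n exact copies -> a single OTU
  one <- denovo_cluster(make_dereps(A, 7L))
  expect_equal(nrow(one$centroids), 1)

  # a lone unmapped singleton unlike everything is removed
  lone <- denovo_cluster(make_dereps(c(A, rand_dna(100)), c(5L, 1L)))
  expect_equal(nrow(lone$centroids), 1)
  expect_true("residual_singleton" %in% lone$discarded$reason)
})

test_that("chimera detection matches explicit crossover-model construction", {
  set.seed(23)
  X <- rand_dna(120)
  Y <- mutate_at(X, seq(3, 117, 10))   # 12 substitutions, ~10% divergent
  chim <- paste0(substr(X, 1, 60), substr(Y, 61, 120))
  expect_true(chimera_check(chim, c(X, Y)))
  expect_true(brute_is_chimera(chim, c(X, Y)))
  expect_false(chimera_check(X, c(X, Y)))
  out <- mutate_at(X, sample(1:120, 50))   # far from both and any crossover
  expect_equal(chimera_check(out, c(X, Y)), brute_is_chimera(out, c(X, Y)))
  expect_false(chimera_check(chim, X))     # fewer than two centroids
})

test_that("OTU table accumulates counts and drops empty columns", {
  set.seed(31)
  ref <- rand_dna(100)
  refs <- c(R1 = ref)
  reads <- data.frame(sequence = rep(ref, 10),
                      sample_id = c(rep("S1", 3), rep("S2", 7)))
  d <- dereplicate(reads)
  m <- closed_ref_map(d, refs)
  dn <- denovo_cluster(m$unmapped)
  tab <- build_otu_table(d, m, dn, marker = "ITS1")
  expect_equal(dim(tab$counts), c(2L, 1L))
  expect_equal(sum(tab$counts), 10L)
  expect_equal(unname(tab$counts["S1", 1]), 3L)
  expect_true(all(colSums(tab$counts) > 0))
})

test_that("two-step result matches the brute-force oracle on random instances", {
  set.seed(77)
  for (trial in 1:20) {
    L <- 60L
    t1 <- rand_dna(L); t2 <- mutate_at(t1, sample(1:L, 18))
    t3 <- mutate_at(t1, sample(1:L, 25))
    refs <- c(RA = t1, RB = t2)
    seqs <- character(); ab <- integer()
    for (k in seq_len(sample(8:12, 1))) {
      base <- sample(c(t1, t2, t3), 1)
      seqs <- c(seqs, mutate_at(base, sample(1:L, sample(0:3, 1))))
      ab <- c(ab, sample(1:8, 1))
    }
    # inject one explicit chimera of the two most common templates
    seqs <- c(seqs, paste0(substr(t1, 1, 30), substr(t3, 31, L)))
    ab <- c(ab, 1L)
    d <- make_dereps(seqs, ab)
    got_map <- closed_ref_map(d, refs)
    got_dn <- denovo_cluster(got_map$unmapped, extra_centroids = unname(refs))
    want <- brute_two_step(d, refs)

    mapped_got <- rep(NA_character_, nrow(d))
    mapped_got[got_map$mapped$derep_row] <- got_map$mapped$accession
    expect_identical(mapped_got, want$mapped)
    expect_setequal(got_dn$centroids$centroid_sequence, want$centroids)
    unmapped_rows <- as.integer(rownames(got_map$unmapped))
    got_disc <- sort(unmapped_rows[got_dn$discarded$derep_row])
    expect_identical(got_disc, want$discarded)
    # same member-centroid relation
    cent_of_got <- setNames(got_dn$centroids$centroid_sequence,
                            got_dn$centroids$otu_id)
    for (r in seq_len(nrow(got_dn$assignments))) {
      row <- unmapped_rows[got_dn$assignments$derep_row[r]]
      expect_identical(unname(cent_of_got[got_dn$assignments$otu_id[r]]),
                       want$centroids[want$member_of[row]])
    }
  }
})

test_that("simulated run conserves reads and respects the radius invariants", {
  cfg <- sim_config(seed = 19, n_genera = 3, species_per_genus = 3,
                    depth_per_sample = 120L, n_samples = 3L,
                    background_fraction = 0.2, n_background_species = 4L)
  db <- generate_reference_db(cfg)
  sim <- simulate_reads(cfg, db)
  prep <- preprocess_reads(sim)
  refs <- ref_region_seqs(db, "ITS1", with_anchors = TRUE)
  # hold out one genus from the references to force de novo OTUs
  held <- db$taxa$accession[db$taxa$genus == "Glomerogenus03"]
  refs <- refs[setdiff(names(refs), held)]
  cl <- cluster_marker(prep$reads, refs, marker = "ITS1")

  expect_true(all(cl$conservation$reads_in ==
                    cl$conservation$reads_assigned + cl$conservation$reads_discarded))

  # member-centroid identity >= 0.97 for every de novo assignment
  unmapped_rows <- as.integer(rownames(cl$mapping$unmapped))
  cent_of <- setNames(cl$denovo$centroids$centroid_sequence,
                      cl$denovo$centroids$otu_id)
  for (r in seq_len(nrow(cl$denovo$assignments))) {
    s <- cl$dereps$sequence[unmapped_rows[cl$denovo$assignments$derep_row[r]]]
    expect_gte(global_identity(s, cent_of[[cl$denovo$assignments$otu_id[r]]]), 0.97)
  }
  # mapped identities >= 0.97
  expect_true(all(cl$mapping$mapped$identity >= 0.97))
  # de novo centroids mutually < 0.97 and < 0.97 to every reference
  cents <- cl$denovo$centroids$centroid_sequence
  if (length(cents) >= 2) {
    for (i in seq_len(length(cents) - 1)) for (j in seq.int(i + 1, length(cents)))
      expect_lt(global_identity(cents[i], cents[j]), 0.97)
  }
  for (cs in cents) for (rf in refs)
    expect_lt(global_identity(cs, rf), 0.97)
})
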