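mini_db <- function(seed = 13) {
  generate_reference_db(sim_config(seed = seed, n_genera = 2,
                                   species_per_genus = 3,
                                   n_background_species = 2L))
}

test_that("best-hit annotation inherits lineage and handles ties and misses", {
  db <- mini_db()
  ref1 <- ref_region_seqs(db, "ITS1", with_anchors = TRUE)[1]
  hit <- annotate_best_hit(unname(ref1), db, "ITS1")
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$genus, db$taxa$genus[1])
  expect_true(hit$classified)

  # duplicate reference in another genus: ambiguous, smallest accession wins
  db2 <- db
  db2$taxa$sequence[4] <- db2$taxa$sequence[1]
  tie <- annotate_best_hit(unname(ref1), db2, "ITS1")
  expect_true(tie$ambiguous)
  expect_equal(tie$accession, min(db2$taxa$accession[c(1, 4)]))

  set.seed(2)
  miss <- annotate_best_hit(rand_dna(180), db, "ITS1")
  expect_false(miss$classified)
  expect_equal(miss$phylum, "unclassified")
})

test_that("spacer trimming locates anchors with up to one mismatch", {
  db <- mini_db()
  amp <- ref_region_seqs(db, "ITS1", with_anchors = TRUE)[1]
  spacer <- ref_region_seqs(db, "ITS1")[1]
  tr <- trim_rrna(unname(amp), "ITS1")
  expect_true(tr$trimmed)
  expect_identical(tr$sequence, unname(spacer))

  # one mismatch inside the left anchor still trims
  amp_mut <- unname(amp); substr(amp_mut, 3, 3) <- if (substr(amp_mut, 3, 3) == "A") "C" else "A"
  tr2 <- trim_rrna(amp_mut, "ITS1")
  expect_true(tr2$trimmed)

  set.seed(3)
  naked <- rand_dna(150)
  tr3 <- trim_rrna(naked, "ITS1")
  expect_false(tr3$trimmed)
  expect_identical(tr3$sequence, naked)
})

test_that("diagnostic sites are exactly the fixed between-species differences", {
  aln <- rbind(s1a = strsplit("AAAAT", "")[[1]],
               s1b = strsplit("AAAAT", "")[[1]],
               s2a = strsplit("AACAT", "")[[1]],
               s2b = strsplit("AACAT", "")[[1]])
  d <- diagnostic_sites(aln, c("sp1", "sp1", "sp2", "sp2"))
  expect_equal(d$sp1$pos, 3)
  expect_equal(d$sp1$state, "A")
  expect_equal(d$sp2$pos, 3)
  expect_equal(d$sp2$state, "C")

  # no fixed difference -> empty
  aln2 <- rbind(a = strsplit("AAAA", "")[[1]], b = strsplit("AAAA", "")[[1]])
  d2 <- diagnostic_sites(aln2, c("sp1", "sp2"))
  expect_equal(nrow(d2$sp1), 0)

  # three species with constructed fixed blocks
  aln3 <- rbind(x = strsplit("AATT", "")[[1]],
                y = strsplit("CATT", "")[[1]],
                z = strsplit("CGTT", "")[[1]])
  d3 <- diagnostic_sites(aln3, c("spx", "spy", "spz"))
  expect_equal(d3$spx$pos, 1)   # x is A, y and z are both C at 1
  expect_equal(d3$spz$pos, 2)   # z is G, x and y are both A at 2
  expect_equal(nrow(d3$spy), 0) # y shares each state with another species
})

test_that("clade rules call species, virtual taxa and exclusions", {
  set.seed(66)
  base <- rand_dna(200)
  other <- mutate_at(base, sample(1:200, 24))      # second species, ~12%
  vtbase <- mutate_at(base, sample(1:200, 44))     # reference-free lineage
  seqs <- c(O1 = mutate_at(base, 1),
            O2 = mutate_at(base, 199),
            V1 = mutate_at(vtbase, 2), V2 = mutate_at(vtbase, 3),
            V3 = mutate_at(vtbase, 5))
  refs <- c(`REF|X1` = base, `REF|X2` = other)
  ref_species <- c(`REF|X1` = "Species_one", `REF|X2` = "Species_two")
  res <- classify_genus_bin(seqs, refs, ref_species, genus = "Testgenus",
                            n_boot = 100, seed = 4)
  calls <- res$calls
  expect_setequal(calls$otu_id, names(seqs))
  expect_equal(calls$verdict[calls$otu_id %in% c("O1", "O2")],
               c("species", "species"))
  expect_equal(calls$label[calls$otu_id == "O1"], "Species_one")
  # the three reference-free sequences share one stable species-level VT
  vt <- calls[calls$otu_id %in% c("V1", "V2", "V3"), ]
  expect_true(all(vt$verdict == "vt_species"))
  expect_equal(length(unique(vt$label)), 1)
  expect_match(vt$label[1], "^VT_Testgenus_")

  # an OTU identical to the sole reference: species at distance 0
  solo <- classify_genus_bin(c(OO = base), c(`REF|X1` = base),
                             c(`REF|X1` = "Species_one"), genus = "G")
  expect_equal(solo$calls$verdict, "species")
  expect_equal(solo$calls$nearest_ref_p_distance, 0)

  # a lone OTU far from every reference is excluded as higher-rank VT
  set.seed(67)
  lone <- classify_genus_bin(c(LX = mutate_at(base, sample(1:200, 70))),
                             refs, ref_species, genus = "G")
  expect_equal(lone$calls$verdict, "excluded_vt_higher")
})

test_that("classification is invariant to the order of input OTUs", {
  set.seed(68)
  base <- rand_dna(180)
  other <- mutate_at(base, sample(1:180, 20))
  vtb <- mutate_at(base, sample(1:180, 40))
  seqs <- c(A1 = mutate_at(base, 4), A2 = mutate_at(base, 9),
            B1 = mutate_at(other, 2),
            W1 = mutate_at(vtb, 7), W2 = mutate_at(vtb, 11))
  refs <- c(`REF|R1` = base, `REF|R2` = other)
  rsp <- c(`REF|R1` = "sp_a", `REF|R2` = "sp_b")
  r1 <- classify_genus_bin(seqs, refs, rsp, genus = "G", n_boot = 60, seed = 2)
  r2 <- classify_genus_bin(seqs[c(4, 2, 5, 1, 3)], refs, rsp, genus = "G",
                           n_boot = 60, seed = 2)
  o <- order(r1$calls$otu_id)
  o2 <- order(r2$calls$otu_id)
  expect_equal(r1$calls[o, c("otu_id", "verdict", "label")],
               r2$calls[o2, c("otu_id", "verdict", "label")],
               ignore_attr = TRUE)
})

test_that("per-biotope summaries recover planted endemic structure", {
  counts <- matrix(c(5L, 0L, 0L,
                     4L, 6L, 0L,
                     0L, 0L, 7L,
                     2L, 2L, 2L), nrow = 3,
                   dimnames = list(c("S1", "S2", "S3"),
                                   c("otuA", "otuB", "otuC", "otuD")))
  tab <- structure(list(counts = counts,
                        otus = data.frame(otu_id = colnames(counts)),
                        marker = "ITS1"), class = "amf_otutable")
  calls <- data.frame(
    otu_id = colnames(counts),
    verdict = c("species", "species", "vt_species", "species"),
    label = c("sp_meadow", "sp_shared", "VT_G_1", "sp_everywhere"))
  bmap <- c(S1 = "meadow", S2 = "forest", S3 = "valley")
  ss <- species_summary(calls, tab, bmap)
  expect_equal(ss$endemics$meadow, "sp_meadow")
  expect_equal(ss$endemics$valley, "VT_G_1")
  expect_equal(ss$venn[["forest&meadow&valley"]], 1L)  # sp_everywhere
  pb <- ss$per_biotope
  expect_equal(pb$n_otus[pb$biotope == "meadow"], 3)
  expect_equal(pb$n_vt[pb$biotope == "valley"], 1)
})
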