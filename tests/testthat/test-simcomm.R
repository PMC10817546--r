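small_cfg <- function(...) {
  sim_config(seed = 101, n_genera = 2, species_per_genus = 3,
             ribotypes_per_species = 2, depth_per_sample = 60L,
             n_samples = 3L, background_fraction = 0.2,
             chimera_rate = 0.05, singleton_rate = 0.05,
             n_background_species = 4L, ...)
}

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(intra_species_divergence = 0.2,
                          inter_species_divergence = 0.1), "divergence")
  expect_error(sim_config(background_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(r_annual_target = 1), "r_annual_target")
  expect_error(sim_config(depth_per_sample = c(10, 10), n_samples = 3),
               "depth_per_sample")
})

test_that("reference database honors the configured taxonomy shape", {
  cfg <- small_cfg()
  db <- generate_reference_db(cfg)
  amf <- db$taxa[db$taxa$phylum == "Glomeromycota", ]
  expect_equal(nrow(amf), 6)
  expect_equal(unname(table(amf$genus)), rep(3L, 2), ignore_attr = TRUE)
  expect_false(anyDuplicated(amf$species) > 0)
  # region bounds ordered, disjoint, inside the construct
  expect_true(all(amf$its1_start < amf$its1_end))
  expect_true(all(amf$its1_end <= amf$its2_start))
  expect_true(all(amf$its2_end <= nchar(amf$sequence)))
  # spacer extraction matches the bounds
  sp <- ref_region_seqs(db, "ITS1")
  expect_equal(unname(nchar(sp)), rep(cfg$spacer_len, nrow(db$taxa)))
})

test_that("congeneric species diverge near the configured rate", {
  cfg <- sim_config(seed = 7, n_genera = 2, species_per_genus = 3,
                    inter_species_divergence = 0.10,
                    intra_species_divergence = 0.005, spacer_len = 400L)
  db <- generate_reference_db(cfg)
  sp <- ref_region_seqs(db, "ITS1", amf_only = TRUE)
  tx <- db$taxa[db$taxa$phylum == "Glomeromycota", ]
  ds <- c()
  for (g in unique(tx$genus)) {
    accs <- tx$accession[tx$genus == g]
    for (i in 1:2) for (j in (i + 1):3)
      ds <- c(ds, 1 - hamming_identity(sp[[accs[i]]], sp[[accs[j]]]))
  }
  expect_true(all(abs(ds - 0.10) < 0.045))
  expect_lt(abs(mean(ds) - 0.10), 0.025)
})

test_that("same seed and config give byte-identical outputs", {
  cfg <- small_cfg()
  db1 <- generate_reference_db(cfg); db2 <- generate_reference_db(cfg)
  expect_identical(db1$taxa, db2$taxa)
  s1 <- simulate_reads(cfg, db1); s2 <- simulate_reads(cfg, db2)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  set.seed(1); ab <- rlnorm(3, 5, 1)
  expect_identical(simulate_metadata(cfg, ab), simulate_metadata(cfg, ab))
})

test_that("zero intra-species divergence collapses ribotypes onto references", {
  cfg <- sim_config(seed = 5, n_genera = 2, species_per_genus = 2,
                    intra_species_divergence = 0, ribotypes_per_species = 3,
                    depth_per_sample = 40L, n_samples = 2L,
                    background_fraction = 0, chimera_rate = 0,
                    singleton_rate = 0, p_bad = 0, q_good = 93L)
  db <- generate_reference_db(cfg)
  sim <- simulate_reads(cfg, db)
  prep <- preprocess_reads(sim)
  # with error-free bases and zero divergence every read's spacer equals the
  # species reference spacer exactly
  acc_of <- setNames(db$taxa$accession, db$taxa$species)
  for (i in seq_len(nrow(prep$reads))) {
    rg <- prep$reads$region_tag[i]
    sp <- sim$truth$species[match(prep$reads$read_id[i], sim$truth$read_id)]
    spacer <- trim_rrna(prep$reads$sequence[i], rg)
    expect_true(spacer$trimmed)
    expect_identical(spacer$sequence,
                     unname(ref_region_seqs(db, rg)[acc_of[sp]]))
  }
})

test_that("truth table is complete and flags behave at the extremes", {
  cfg <- small_cfg()
  db <- generate_reference_db(cfg)
  sim <- simulate_reads(cfg, db)
  expect_setequal(sim$reads$read_id, sim$truth$read_id)
  expect_false(anyDuplicated(sim$truth$read_id) > 0)

  cfg0 <- sim_config(seed = 3, n_genera = 2, species_per_genus = 2,
                     chimera_rate = 0, depth_per_sample = 50L, n_samples = 2L)
  s0 <- simulate_reads(cfg0, generate_reference_db(cfg0))
  expect_equal(sum(s0$truth$is_chimera), 0)

  cfg1 <- sim_config(seed = 3, n_genera = 2, species_per_genus = 2,
                     depth_per_sample = 1L, n_samples = 1L,
                     singleton_rate = 1, chimera_rate = 0)
  s1 <- simulate_reads(cfg1, generate_reference_db(cfg1))
  expect_equal(nrow(s1$reads), 1)
  expect_true(all(s1$truth$is_singleton))

  cfgz <- sim_config(seed = 3, n_genera = 2, species_per_genus = 2,
                     depth_per_sample = 0L, n_samples = 2L)
  sz <- simulate_reads(cfgz, generate_reference_db(cfgz))
  expect_equal(nrow(sz$reads), 0)
})

test_that("background fraction is respected within binomial error", {
  cfg <- sim_config(seed = 9, n_genera = 2, species_per_genus = 2,
                    background_fraction = 0.5, depth_per_sample = 1000L,
                    n_samples = 1L)
  sim <- simulate_reads(cfg, generate_reference_db(cfg))
  n_bkg <- sum(sim$truth$is_background)
  expect_true(abs(n_bkg - 500) < 4 * sqrt(1000 * 0.25))
})

test_that("metadata plants the annual-plant correlation and altitude order", {
  cfg <- sim_config(seed = 21, n_samples = 51L, depth_per_sample = 1L,
                    r_annual_target = 0.8)
  set.seed(99)
  ab <- rlnorm(51, 5, 1)
  md <- simulate_metadata(cfg, ab)
  r <- cor(md$percent_annual_plants, ab)
  expect_gt(r, 0.6)
  expect_lt(r, 0.95)
  expect_true(max(md$altitude_m[md$biotope == "river_valley"]) <
                min(md$altitude_m[md$biotope == "forest"]))
  expect_true(max(md$altitude_m[md$biotope == "forest"]) <
                min(md$altitude_m[md$biotope == "subalpine_meadow"]))
  expect_error(simulate_metadata(sim_config(r_annual_target = 0.5), 1:5),
               "one value per sample")
})

test_that("planted correlation is recovered in expectation over seeds", {
  rs <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s, n_samples = 51L, r_annual_target = 0.8)
    set.seed(1000 + s)
    ab <- rlnorm(51, 5, 1)
    md <- simulate_metadata(cfg, ab)
    cor(md$percent_annual_plants, ab)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.8), 0.05)

  r0 <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = s, n_samples = 51L, r_annual_target = 0)
    set.seed(2000 + s)
    ab <- rlnorm(51, 5, 1)
    cor(simulate_metadata(cfg, ab)$percent_annual_plants, ab)
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.08)
})
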