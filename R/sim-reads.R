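#' Simulate paired amplicon reads with truth tables
#'
#' Draws a community per sample (lognormal species abundances with a
#' biotope-preference effect so that biotopes differ in composition), then
#' emits paired reads from the ITS1 and ITS2 amplicon pools. Each species
#' carries a cloud of ribotypes (divergent rDNA variants mimicking
#' heterokaryosis); a configurable fraction of reads are fresh one-off
#' ribotype variants (singletons), two-parent single-crossover chimeras
#' (breakpoint uniform in the middle 50% of the amplicon), or background
#' non-Glomeromycota templates. Bases are error-free except for substitution
#' errors injected at the rate implied by a two-state (good/bad) per-base
#' quality profile, so expected-error filtering is exercised meaningfully.
#'
#' @param config A [sim_config()]; must be the one used for `db`.
#' @param db Reference database from [generate_reference_db()].
#' @return Object of class `amf_simreads`: list with `reads` (data frame:
#'   read_id, sample_id, r1, q1, r2, q2), `truth` (read_id, sample_id,
#'   species, ribotype, region, is_chimera, is_background, is_singleton),
#'   `samples` (sample/biotope/depth frame) and `config`.
#' @export
simulate_reads <- function(config, db) {
  stopifnot(inherits(config, "sim_config"), inherits(db, "amf_refdb"))
  if (!identical(db$config$seed, config$seed))
    stop("db was generated under a different config")
  set.seed(derive_seed(config$seed, 22L))

  samples <- sim_samples(config)
  prm <- amf_primers()
  anc <- amf_anchors()
  tx <- db$taxa
  is_amf <- tx$phylum == "Glomeromycota"
  amf_species <- tx$species[is_amf]
  bkg_species <- tx$species[!is_amf]

  # Ribotype clouds: spacer variants per species and region.
  spacers <- list(
    ITS1 = ref_region_seqs(db, "ITS1"),
    ITS2 = ref_region_seqs(db, "ITS2")
  )
  acc_of <- stats::setNames(tx$accession, tx$species)
  ribo <- list()
  for (sp in tx$species) {
    for (rg in c("ITS1", "ITS2")) {
      base <- spacers[[rg]][[acc_of[[sp]]]]
      ribo[[paste(sp, rg, sep = "|")]] <- vapply(
        seq_len(config$ribotypes_per_species),
        function(i) mutate_seq(base, config$intra_species_divergence),
        character(1))
    }
  }
  rc_rev <- lapply(prm, function(p) revcomp(p$rev))
  build_amplicon <- function(spacer, rg) {
    paste0(prm[[rg]]$fwd, anc[[rg]]$left, spacer, anc[[rg]]$right, rc_rev[[rg]])
  }

  # Biotope-preference community model.
  n_amf <- length(amf_species)
  base_ab <- stats::rlnorm(n_amf, 0, 1)
  pref <- sample(config$biotope_labels, n_amf, replace = TRUE)
  names(base_ab) <- names(pref) <- amf_species

  reads <- list(); truth <- list()
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    depth <- samples$depth[si]
    if (depth == 0L) next
    w <- base_ab * ifelse(pref == samples$biotope[si], 8, 1) *
      stats::rlnorm(n_amf, 0, 0.5)
    p_amf <- w / sum(w)

    n_bkg <- stats::rbinom(1L, depth, config$background_fraction)
    src_bkg <- c(rep(TRUE, n_bkg), rep(FALSE, depth - n_bkg))
    sp_read <- character(depth)
    sp_read[src_bkg] <- sample(bkg_species, n_bkg, replace = TRUE)
    sp_read[!src_bkg] <- sample(amf_species, depth - n_bkg, replace = TRUE,
                                prob = p_amf)
    rg_read <- ifelse(stats::runif(depth) < config$its1_proportion, "ITS1", "ITS2")
    singleton <- stats::runif(depth) < config$singleton_rate
    chimera <- stats::runif(depth) < config$chimera_rate
    ribo_idx <- sample.int(config$ribotypes_per_species, depth, replace = TRUE)

    amplicons <- character(depth)
    for (i in seq_len(depth)) {
      rg <- rg_read[i]
      pool <- if (src_bkg[i]) bkg_species else amf_species
      if (chimera[i] && length(pool) < 2L) chimera[i] <- FALSE
      if (chimera[i]) {
        # two distinct parents from the sample's source pool, same region
        pp <- if (src_bkg[i]) NULL else p_amf
        par <- sample(pool, 2L, replace = FALSE, prob = pp)
        a1 <- build_amplicon(ribo[[paste(par[1], rg, sep = "|")]][
          sample.int(config$ribotypes_per_species, 1L)], rg)
        a2 <- build_amplicon(ribo[[paste(par[2], rg, sep = "|")]][
          sample.int(config$ribotypes_per_species, 1L)], rg)
        L <- min(nchar(a1), nchar(a2))
        bp <- sample(seq.int(floor(0.25 * L), floor(0.75 * L)), 1L)
        amplicons[i] <- paste0(substr(a1, 1L, bp), substr(a2, bp + 1L, nchar(a2)))
        sp_read[i] <- par[1]
        ribo_idx[i] <- NA_integer_
      } else if (singleton[i]) {
        base <- spacers[[rg]][[acc_of[[sp_read[i]]]]]
        amplicons[i] <- build_amplicon(
          mutate_seq(base, config$intra_species_divergence), rg)
        ribo_idx[i] <- NA_integer_
      } else {
        amplicons[i] <- build_amplicon(
          ribo[[paste(sp_read[i], rg, sep = "|")]][ribo_idx[i]], rg)
      }
    }
    m1 <- substr(amplicons, 1L, config$read_len)
    m2 <- substr(revcomp(amplicons), 1L, config$read_len)
    r1 <- q1 <- r2 <- q2 <- character(depth)
    for (i in seq_len(depth)) {
      e1 <- sequencer_pass(m1[i], config)
      e2 <- sequencer_pass(m2[i], config)
      r1[i] <- e1$seq; q1[i] <- e1$qual
      r2[i] <- e2$seq; q2[i] <- e2$qual
    }
    ids <- sprintf("%s_read%06d", sid, seq_len(depth))
    reads[[sid]] <- data.frame(read_id = ids, sample_id = sid,
                               r1 = r1, q1 = q1, r2 = r2, q2 = q2,
                               stringsAsFactors = FALSE)
    truth[[sid]] <- data.frame(read_id = ids, sample_id = sid,
                               species = sp_read, ribotype = ribo_idx,
                               region = rg_read, is_chimera = chimera,
                               is_background = src_bkg,
                               is_singleton = singleton & !chimera,
                               stringsAsFactors = FALSE)
  }
  out <- list(reads = if (length(reads))
                do.call(rbind, c(reads, list(make.row.names = FALSE))) else NULL,
              truth = if (length(truth))
                do.call(rbind, c(truth, list(make.row.names = FALSE))) else NULL,
              samples = samples, config = config)
  if (is.null(out$reads)) {  # all depths zero
    out$reads <- data.frame(read_id = character(), sample_id = character(),
                            r1 = character(), q1 = character(),
                            r2 = character(), q2 = character())
    out$truth <- data.frame(read_id = character(), sample_id = character(),
                            species = character(), ribotype = integer(),
                            region = character(), is_chimera = logical(),
                            is_background = logical(), is_singleton = logical())
  }
  class(out) <- "amf_simreads"
  out
}

# Apply the two-state quality model to one mate: draw per-base qualities and
# inject substitution errors at rate 10^(-Q/10).
sequencer_pass <- function(seq, config) {
  n <- nchar(seq)
  if (n == 0L) return(list(seq = seq, qual = ""))
  bad <- stats::runif(n) < config$p_bad
  q <- ifelse(bad, config$q_bad, config$q_good)
  err <- stats::runif(n) < 10^(-q / 10)
  if (any(err)) {
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    bases[err] <- vapply(bases[err], function(b) sample(setdiff(DNA_BASES4, b), 1L),
                         character(1))
    seq <- paste(bases, collapse = "")
  }
  list(seq = seq, qual = phred_to_char(as.integer(q)))
}

#' Write simulated reads as per-sample paired FASTQ plus a truth TSV
#'
#' @param sim An `amf_simreads` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_sim_fastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in unique(sim$reads$sample_id)) {
    sub <- sim$reads[sim$reads$sample_id == sid, , drop = FALSE]
    write_fastq(sub$read_id, sub$r1, sub$q1, file.path(dir, paste0(sid, "_R1.fastq")))
    write_fastq(sub$read_id, sub$r2, sub$q2, file.path(dir, paste0(sid, "_R2.fastq")))
  }
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
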