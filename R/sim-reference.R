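#' Generate the synthetic reference database
#'
#' Builds a set of reference taxa over the full 18S-ITS1-5.8S-ITS2-28S
#' construct: `n_genera` Glomeromycota genera with `species_per_genus`
#' species each, plus a panel of deeply divergent non-Glomeromycota
#' (background) taxa. Within a genus, each species' spacers are derived from
#' a shared genus ancestor by substituting sites at half the configured
#' inter-species divergence, so that pairwise congeneric p-distances land
#' near `inter_species_divergence` in expectation. Coding segments (18S
#' tail, 5.8S, 28S head) are fixed and conserved across all taxa.
#'
#' @param config A [sim_config()].
#' @return Object of class `amf_refdb`: list with `taxa` (data frame with
#'   accession, the six lineage ranks, 0-based half-open region bounds for
#'   ITS1/ITS2, and the full construct sequence) and `config`.
#' @export
generate_reference_db <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 11L))

  sl <- config$spacer_len
  its1_start <- nchar(SSU_TAIL)
  its1_end <- its1_start + sl
  its2_start <- its1_end + nchar(R58S)
  its2_end <- its2_start + sl

  rows <- list()
  acc <- 0L
  for (g in seq_len(config$n_genera)) {
    genus <- sprintf("Glomerogenus%02d", g)
    anc1 <- random_seq(sl)
    anc2 <- random_seq(sl)
    half <- config$inter_species_divergence / 2
    for (s in seq_len(config$species_per_genus)) {
      acc <- acc + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        accession = sprintf("SYNA%04d", acc),
        phylum = "Glomeromycota", class = "Glomeromycetes",
        order = sprintf("Glomeroorder%02d", (g - 1L) %/% 3L + 1L),
        family = sprintf("Glomerofam%02d", g),
        genus = genus,
        species = sprintf("%s_sp%02d", genus, s),
        its1_start = its1_start, its1_end = its1_end,
        its2_start = its2_start, its2_end = its2_end,
        sequence = paste0(SSU_TAIL, mutate_seq(anc1, half), R58S,
                          mutate_seq(anc2, half), LSU_HEAD),
        stringsAsFactors = FALSE)
    }
  }
  for (b in seq_len(config$n_background_species)) {
    acc <- acc + 1L
    genus <- sprintf("Fungigenus%02d", (b - 1L) %/% 2L + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      accession = sprintf("SYNB%04d", b),
      phylum = if (b %% 2L == 0L) "Ascomycota" else "Basidiomycota",
      class = sprintf("Fungiclass%02d", (b - 1L) %/% 2L + 1L),
      order = sprintf("Fungiorder%02d", (b - 1L) %/% 2L + 1L),
      family = sprintf("Fungifam%02d", (b - 1L) %/% 2L + 1L),
      genus = genus,
      species = sprintf("%s_sp%02d", genus, (b - 1L) %% 2L + 1L),
      its1_start = its1_start, its1_end = its1_end,
      its2_start = its2_start, its2_end = its2_end,
      sequence = paste0(SSU_TAIL, random_seq(sl), R58S, random_seq(sl), LSU_HEAD),
      stringsAsFactors = FALSE)
  }
  taxa <- do.call(rbind, rows)
  rownames(taxa) <- NULL
  db <- list(taxa = taxa, config = config)
  class(db) <- "amf_refdb"
  db
}

#' Extract a spacer (or amplicon interior) from reference taxa
#'
#' @param db An `amf_refdb`.
#' @param region `"ITS1"` or `"ITS2"`.
#' @param with_anchors If `TRUE`, include the conserved anchor flanks that a
#'   primer-stripped amplicon retains; this is the form used as
#'   closed-reference mapping centroids.
#' @param amf_only Keep only Glomeromycota taxa.
#' @return Named character vector (names = accessions).
#' @export
ref_region_seqs <- function(db, region = c("ITS1", "ITS2"),
                            with_anchors = FALSE, amf_only = FALSE) {
  region <- match.arg(region)
  tx <- db$taxa
  if (amf_only) tx <- tx[tx$phylum == "Glomeromycota", , drop = FALSE]
  s <- if (region == "ITS1") tx$its1_start else tx$its2_start
  e <- if (region == "ITS1") tx$its1_end else tx$its2_end
  pad <- if (with_anchors) ANCHOR_LEN else 0L
  out <- substr(tx$sequence, s + 1L - pad, e + pad)  # bounds are 0-based half-open
  names(out) <- tx$accession
  out
}

#' Write the reference database as FASTA plus a lineage TSV
#'
#' @param db An `amf_refdb`.
#' @param fasta_path,taxonomy_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_reference_db <- function(db, fasta_path, taxonomy_path) {
  seqs <- Biostrings::DNAStringSet(db$taxa$sequence)
  names(seqs) <- db$taxa$accession
  Biostrings::writeXStringSet(seqs, fasta_path)
  utils::write.table(
    db$taxa[, c("accession", "phylum", "class", "order", "family", "genus",
                "species", "its1_start", "its1_end", "its2_start", "its2_end")],
    taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, taxonomy_path))
}
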