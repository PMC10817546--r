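#' Run configuration for an end-to-end analysis
#'
#' @param sim A [sim_config()] describing the synthetic input (the only
#'   input source the package ships; real FASTQ can be fed to the stage
#'   functions directly).
#' @param markers Markers to process.
#' @param radius OTU identity radius.
#' @param chimera_identity Chimera model threshold.
#' @param min_len,max_ee Read filters.
#' @param thresholds Clade decision thresholds ([taxon_thresholds()]).
#' @param n_boot Bootstrap replicates per genus tree.
#' @param n_perm ANOSIM permutations.
#' @param hill_boot Bootstrap replicates for Hill CIs.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), markers = c("ITS1", "ITS2"),
                       radius = 0.97, chimera_identity = 0.99,
                       min_len = 120L, max_ee = 1.0,
                       thresholds = taxon_thresholds(), n_boot = 50L,
                       n_perm = 999L, hill_boot = 100L) {
  structure(list(sim = sim, markers = markers, radius = radius,
                 chimera_identity = chimera_identity, min_len = min_len,
                 max_ee = max_ee, thresholds = thresholds, n_boot = n_boot,
                 n_perm = n_perm, hill_boot = hill_boot),
            class = "run_config")
}

#' Run the full pipeline on a synthetic community
#'
#' Stages: simulate (reference DB, reads, metadata) -> preprocess (merge,
#' length filter, primer strip, expected-error filter) -> per-marker
#' two-step OTU construction -> taxon classification -> per-biotope Hill
#' diversity -> community statistics (ANOSIM on Spearman distances of the
#' TSS-normalized OTU table, metadata correlations). When `outdir` is
#' given, all artifacts (FASTA/FASTQ/TSV/Newick/JSON) plus a provenance
#' manifest with input hashes are written there.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory.
#' @return List with all stage outputs (`db`, `sim`, `metadata`, `prep`,
#'   `markers` (per-marker cluster+classify results), `hill`, `stats`,
#'   `study_table`).
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  db <- generate_reference_db(config$sim)
  sim <- simulate_reads(config$sim, db)
  amf_ab <- amf_truth_abundance(sim)
  metadata <- simulate_metadata(config$sim, amf_ab)
  prep <- preprocess_reads(sim, min_len = config$min_len, max_ee = config$max_ee)

  markers <- list()
  for (mk in config$markers) {
    refs <- ref_region_seqs(db, mk, with_anchors = TRUE)
    cl <- cluster_marker(prep$reads, refs, marker = mk,
                         radius = config$radius,
                         chimera_identity = config$chimera_identity)
    stopifnot(all(cl$conservation$reads_in ==
                    cl$conservation$reads_assigned + cl$conservation$reads_discarded))
    ann <- classify_otus(cl$table, db, thresholds = config$thresholds,
                         n_boot = config$n_boot,
                         seed = derive_seed(config$sim$seed, match(mk, config$markers)))
    biotope_map <- stats::setNames(sim$samples$biotope, sim$samples$sample_id)
    summ <- species_summary(ann$calls, cl$table, biotope_map)
    markers[[mk]] <- list(cluster = cl, classify = ann, summary = summ)
  }

  # Hill diversity per biotope on pooled AMF OTU counts (first marker).
  hill <- list()
  for (mk in names(markers)) {
    counts <- markers[[mk]]$cluster$table$counts
    amf_ids <- markers[[mk]]$classify$calls$otu_id[
      !is.na(markers[[mk]]$classify$calls$phylum) &
        markers[[mk]]$classify$calls$phylum == "Glomeromycota"]
    counts <- counts[, intersect(colnames(counts), amf_ids), drop = FALSE]
    per_biotope <- lapply(split(sim$samples$sample_id, sim$samples$biotope),
                          function(ids) {
                            v <- colSums(counts[ids, , drop = FALSE])
                            v[v > 0]
                          })
    hill[[mk]] <- lapply(per_biotope, function(v) {
      if (sum(v) < 2) return(NULL)
      hill_profile(v, n_boot = config$hill_boot, seed = config$sim$seed)
    })
  }

  # Community statistics on the first marker's normalized AMF table.
  mk1 <- names(markers)[1]
  counts1 <- markers[[mk1]]$cluster$table$counts
  stats_out <- list()
  if (ncol(counts1) >= 2 && all(rowSums(counts1) > 0)) {
    rel <- tss_normalize(counts1)
    d <- spearman_distance_matrix(rel)
    grp <- sim$samples$biotope[match(rownames(rel), sim$samples$sample_id)]
    if (length(unique(grp)) >= 2 && all(table(grp) >= 2)) {
      stats_out$anosim <- anosim_test(d, grp, n_perm = config$n_perm,
                                      seed = config$sim$seed)
    }
    stats_out$mds <- classical_mds(d, k = 2L)
    stats_out$ward <- ward_clustering(d)
  }
  stats_out$annual_vs_amf <- pearson_r(metadata$percent_annual_plants, amf_ab)

  study <- build_study_table(sim, prep,
                             markers[["ITS1"]]$cluster, markers[["ITS2"]]$cluster,
                             markers[["ITS1"]]$classify, markers[["ITS2"]]$classify)

  out <- list(db = db, sim = sim, metadata = metadata, prep = prep,
              markers = markers, hill = hill, stats = stats_out,
              study_table = study, config = config)
  if (!is.null(outdir)) write_run_outputs(out, outdir)
  out
}

# Per-sample AMF (non-background, non-chimera) truth read counts.
amf_truth_abundance <- function(sim) {
  t <- sim$truth
  amf <- t[!t$is_background & !t$is_chimera, , drop = FALSE]
  counts <- table(factor(amf$sample_id, levels = sim$samples$sample_id))
  as.numeric(counts)
}

write_run_outputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_reference_db(run$db, file.path(outdir, "reference.fasta"),
                     file.path(outdir, "reference_taxonomy.tsv"))
  write_sim_fastq(run$sim, file.path(outdir, "reads"))
  write_tsv(run$metadata, file.path(outdir, "metadata.tsv"))
  write_tsv(run$prep$reads, file.path(outdir, "preprocessed_reads.tsv"))
  write_tsv(run$prep$rejected, file.path(outdir, "merge_rejections.tsv"))
  for (mk in names(run$markers)) {
    m <- run$markers[[mk]]
    tab <- m$cluster$table
    otu_df <- cbind(otu_id = colnames(tab$counts),
                    as.data.frame(t(tab$counts)))
    write_tsv(otu_df, file.path(outdir, sprintf("otu_table_%s.tsv", mk)))
    cents <- stats::setNames(tab$otus$centroid_sequence,
                             paste0(tab$otus$otu_id, ";origin=", tab$otus$origin))
    cents <- cents[!is.na(cents)]
    if (length(cents)) write_fasta(cents, file.path(outdir, sprintf("centroids_%s.fasta", mk)))
    write_tsv(m$classify$calls, file.path(outdir, sprintf("taxon_calls_%s.tsv", mk)))
    write_tsv(m$summary$per_biotope, file.path(outdir, sprintf("biotope_summary_%s.tsv", mk)))
    for (g in names(m$classify$trees)) {
      tr <- m$classify$trees[[g]]
      if (!is.null(tr)) write_newick(tr, file.path(outdir, sprintf("tree_%s_%s.nwk", mk, g)))
    }
  }
  manifest <- list(
    config = unclass(run$config$sim),
    markers = run$config$markers,
    thresholds = run$config$thresholds,
    file_md5 = as.list(tools::md5sum(list.files(outdir, full.names = TRUE,
                                                recursive = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
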