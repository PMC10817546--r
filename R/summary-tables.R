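#' Packaged per-plot study tables
#'
#' The per-plot (stationary trial plot, STP) read/OTU accounting and site
#' table of the nine-plot North Caucasus survey, shipped as plain TSV
#' fixtures: altitudes per plot, per-plot total/merged/Glomeromycota read
#' and OTU counts for both markers, and the pooled per-biotope OTU counts.
#'
#' @param which One of `"stp_sites"`, `"stp_reads"`, `"biotope_otus"`.
#' @return Data frame.
#' @export
study_table <- function(which = c("stp_reads", "stp_sites", "biotope_otus")) {
  which <- match.arg(which)
  f <- switch(which,
              stp_sites = "table1_stp.tsv",
              stp_reads = "table2_stp.tsv",
              biotope_otus = "table2_biotope_otus.tsv")
  path <- system.file("extdata", f, package = "amfdiv")
  if (path == "") path <- file.path("inst", "extdata", f)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Headline summary statistics from a per-plot study table
#'
#' Derives the report-style numbers from a per-plot table shaped like
#' [study_table("stp_reads")]: per-marker mean AMF reads per plot (rounded
#' to integer), per-marker AMF read totals, the ITS1:ITS2 read ratio
#' (1 decimal), and per-marker biotope OTU ratios (river valley / forest
#' and subalpine meadow / forest, 1 decimal) from pooled per-biotope OTU
#' counts.
#'
#' @param stp_reads Per-plot frame with columns `amf_reads_its1`,
#'   `amf_reads_its2` (and optionally `total_reads`, `merged_reads`).
#' @param biotope_otus Frame with `biotope`, `otus_its1`, `otus_its2`.
#' @return List of named numbers: `mean_reads` (per marker), `total_reads`
#'   (per marker), `marker_read_ratio`, `otu_ratio` (matrix of ratios).
#' @export
summary_tables <- function(stp_reads = study_table("stp_reads"),
                           biotope_otus = study_table("biotope_otus")) {
  mean_reads <- c(ITS1 = round(mean(stp_reads$amf_reads_its1)),
                  ITS2 = round(mean(stp_reads$amf_reads_its2)))
  total_reads <- c(ITS1 = sum(stp_reads$amf_reads_its1),
                   ITS2 = sum(stp_reads$amf_reads_its2))
  marker_read_ratio <- round(total_reads[["ITS1"]] / total_reads[["ITS2"]], 1)
  bt <- biotope_otus
  rownames(bt) <- bt$biotope
  ratio_of <- function(a, b, col) {
    if (!all(c(a, b) %in% rownames(bt))) return(NA_real_)
    round(bt[a, col] / bt[b, col], 1)
  }
  otu_ratio <- rbind(
    ITS1 = c(river_over_forest = ratio_of("river_valley", "forest", "otus_its1"),
             meadow_over_forest = ratio_of("subalpine_meadow", "forest", "otus_its1")),
    ITS2 = c(river_over_forest = ratio_of("river_valley", "forest", "otus_its2"),
             meadow_over_forest = ratio_of("subalpine_meadow", "forest", "otus_its2")))
  list(mean_reads = mean_reads, total_reads = total_reads,
       marker_read_ratio = marker_read_ratio, otu_ratio = otu_ratio)
}

#' Build a per-plot study table from pipeline outputs
#'
#' Mirrors the packaged per-plot table's shape for a synthetic run:
#' per-sample raw and merged read counts plus per-marker Glomeromycota
#' read and OTU counts, and pooled per-biotope OTU counts.
#'
#' @param sim The `amf_simreads` input.
#' @param prep Output of [preprocess_reads()].
#' @param cl_its1,cl_its2 Outputs of [cluster_marker()] per marker.
#' @param ann_its1,ann_its2 Classification results from [classify_otus()]
#'   (used for Glomeromycota membership), or `NULL` to count all OTUs.
#' @return List with `stp_reads` and `biotope_otus` frames shaped like the
#'   packaged fixtures.
#' @export
build_study_table <- function(sim, prep, cl_its1, cl_its2,
                              ann_its1 = NULL, ann_its2 = NULL) {
  samples <- sim$samples
  raw <- table(factor(sim$reads$sample_id, levels = samples$sample_id))
  merged <- table(factor(prep$reads$sample_id, levels = samples$sample_id))

  marker_counts <- function(cl, ann) {
    counts <- cl$table$counts
    keep <- colnames(counts)
    if (!is.null(ann)) {
      amf <- ann$calls$otu_id[!is.na(ann$calls$phylum) &
                                ann$calls$phylum == "Glomeromycota"]
      keep <- intersect(keep, amf)
    }
    counts[samples$sample_id, keep, drop = FALSE]
  }
  c1 <- marker_counts(cl_its1, ann_its1)
  c2 <- marker_counts(cl_its2, ann_its2)
  stp_reads <- data.frame(
    stp = samples$sample_id, biotope = samples$biotope,
    total_reads = as.integer(raw), merged_reads = as.integer(merged),
    amf_reads_its1 = as.integer(rowSums(c1)),
    amf_otus_its1 = as.integer(rowSums(c1 > 0)),
    amf_reads_its2 = as.integer(rowSums(c2)),
    amf_otus_its2 = as.integer(rowSums(c2 > 0)),
    stringsAsFactors = FALSE)
  biotopes <- unique(samples$biotope)
  biotope_otus <- data.frame(
    biotope = biotopes,
    otus_its1 = vapply(biotopes, function(b) {
      rows <- samples$sample_id[samples$biotope == b]
      sum(colSums(c1[rows, , drop = FALSE]) > 0)
    }, numeric(1)),
    otus_its2 = vapply(biotopes, function(b) {
      rows <- samples$sample_id[samples$biotope == b]
      sum(colSums(c2[rows, , drop = FALSE]) > 0)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(stp_reads = stp_reads, biotope_otus = biotope_otus)
}
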