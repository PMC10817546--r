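#' Configuration for the synthetic AMF community generator
#'
#' Collects every knob of the simulator: the shape of the synthetic reference
#' database (genera, species, divergences), the ribotype-cloud model standing
#' in for heterokaryosis, the read model (depth, length, quality states), the
#' artifact rates (chimeras, singletons, non-AMF background) and the planted
#' metadata correlation structure. Validated on construction; the same
#' `sim_config()` plus seed always yields byte-identical simulator output.
#'
#' @param seed Integer seed driving every stochastic choice.
#' @param n_genera,species_per_genus Size of the synthetic Glomeromycota
#'   reference taxonomy.
#' @param inter_species_divergence Expected pairwise p-distance between
#'   congeneric species' spacers (substitutions per site).
#' @param intra_species_divergence Expected p-distance between a species'
#'   ribotypes and its reference spacer; must be strictly smaller than
#'   `inter_species_divergence`.
#' @param ribotypes_per_species Number of rDNA variants per species
#'   (heterokaryosis model).
#' @param background_fraction Proportion of reads drawn from non-Glomeromycota
#'   (background) lineages.
#' @param chimera_rate Proportion of reads replaced by two-parent
#'   single-crossover recombinants.
#' @param singleton_rate Proportion of reads that carry a fresh, never-reused
#'   ribotype variant (quasi-unique rDNA copies).
#' @param depth_per_sample Reads per sample; scalar or vector of length
#'   `n_samples`.
#' @param n_samples Number of samples (stationary trial plots).
#' @param biotope_labels Closed set of biotope names; samples are assigned in
#'   contiguous blocks.
#' @param its1_proportion Fraction of read pairs drawn from the ITS1 amplicon
#'   pool (the remainder are ITS2); the source study does not report this
#'   ratio, so it is a free parameter defaulting to an even split.
#' @param spacer_len Length of each simulated spacer (ITS1 and ITS2).
#' @param read_len Length of each mate in a simulated pair.
#' @param q_good,q_bad,p_bad Two-state per-base quality model: each base is
#'   "bad" with probability `p_bad` and gets Phred `q_bad`, else `q_good`;
#'   sequencing errors are injected at the rate the quality implies.
#' @param n_background_species Number of background (non-AMF) reference taxa.
#' @param r_annual_target Planted Pearson correlation between "percent of
#'   annual plants" and per-sample AMF read abundance; must lie in (-1, 1).
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genera = 10L,
                       species_per_genus = 3L,
                       inter_species_divergence = 0.10,
                       intra_species_divergence = 0.005,
                       ribotypes_per_species = 3L,
                       background_fraction = 0.5,
                       chimera_rate = 0.02,
                       singleton_rate = 0.05,
                       depth_per_sample = 2000L,
                       n_samples = 9L,
                       biotope_labels = c("subalpine_meadow", "forest", "river_valley"),
                       its1_proportion = 0.5,
                       spacer_len = 160L,
                       read_len = 150L,
                       q_good = 38L, q_bad = 12L, p_bad = 0.03,
                       n_background_species = 8L,
                       r_annual_target = 0.8) {
  cfg <- list(seed = as.integer(seed),
              n_genera = as.integer(n_genera),
              species_per_genus = as.integer(species_per_genus),
              inter_species_divergence = inter_species_divergence,
              intra_species_divergence = intra_species_divergence,
              ribotypes_per_species = as.integer(ribotypes_per_species),
              background_fraction = background_fraction,
              chimera_rate = chimera_rate,
              singleton_rate = singleton_rate,
              depth_per_sample = as.integer(depth_per_sample),
              n_samples = as.integer(n_samples),
              biotope_labels = biotope_labels,
              its1_proportion = its1_proportion,
              spacer_len = as.integer(spacer_len),
              read_len = as.integer(read_len),
              q_good = as.integer(q_good), q_bad = as.integer(q_bad),
              p_bad = p_bad,
              n_background_species = as.integer(n_background_species),
              r_annual_target = r_annual_target)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  props <- c("background_fraction", "chimera_rate", "singleton_rate",
             "its1_proportion", "p_bad")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("configuration error: ", p, " must lie in [0, 1]")
  }
  if (cfg$intra_species_divergence >= cfg$inter_species_divergence)
    stop("configuration error: intra-species divergence must be < inter-species divergence")
  if (cfg$intra_species_divergence < 0 || cfg$inter_species_divergence > 1)
    stop("configuration error: divergences must lie in [0, 1]")
  if (abs(cfg$r_annual_target) >= 1)
    stop("configuration error: |r_annual_target| must be < 1")
  if (cfg$n_samples < 1 || cfg$n_genera < 1 || cfg$species_per_genus < 1)
    stop("configuration error: counts must be positive")
  if (!length(cfg$depth_per_sample) %in% c(1L, cfg$n_samples))
    stop("configuration error: depth_per_sample must be scalar or one value per sample")
  if (any(cfg$depth_per_sample < 0))
    stop("configuration error: depths must be non-negative")
  invisible(cfg)
}

# Per-sample depth vector and sample/biotope frame for a config.
sim_samples <- function(cfg) {
  depth <- rep_len(cfg$depth_per_sample, cfg$n_samples)
  biotope <- cfg$biotope_labels[
    ceiling(seq_len(cfg$n_samples) / (cfg$n_samples / length(cfg$biotope_labels)))]
  data.frame(sample_id = sprintf("STP%02d", seq_len(cfg$n_samples)),
             biotope = biotope, depth = depth,
             stringsAsFactors = FALSE)
}
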