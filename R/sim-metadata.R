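#' Simulate per-plot metadata with a planted abundance correlation
#'
#' Produces one metadata record per sample: biotope, altitude (strictly
#' ordered river valley < forest < subalpine meadow, mimicking the field
#' layout), soil chemistry, and plant-community fields. "Percent of annual
#' plants" is planted to achieve a target Pearson correlation with the
#' supplied per-sample AMF abundance: the field is built as a linear
#' projection `r * z(abundance) + sqrt(1 - r^2) * noise` of the standardized
#' abundance, which keeps the expected Pearson coefficient at the target even
#' for skewed read-count distributions, then mapped onto the 0-100 scale.
#' At small n the realized correlation is noisy (documented power caveat);
#' the target is recovered in expectation.
#'
#' @param config A [sim_config()]; `r_annual_target` must lie in (-1, 1).
#' @param amf_abundance Numeric vector of per-sample AMF truth abundances,
#'   one per configured sample (e.g. AMF read counts from the truth table).
#' @return Data frame with one row per sample: stp_id, biotope, altitude_m,
#'   pH_KCl, Pi_mg_per_kg, N_total_pct, P_total_pct, percent_annual_plants,
#'   n_herb_species, fraction_lt_0_01mm, soil_type_code.
#' @export
simulate_metadata <- function(config, amf_abundance) {
  stopifnot(inherits(config, "sim_config"))
  if (abs(config$r_annual_target) >= 1)
    stop("configuration error: |r_annual_target| must be < 1")
  samples <- sim_samples(config)
  n <- nrow(samples)
  if (length(amf_abundance) != n)
    stop("amf_abundance must have one value per sample")
  set.seed(derive_seed(config$seed, 33L))

  r <- config$r_annual_target
  z <- as.numeric(scale(amf_abundance))
  if (any(!is.finite(z))) z <- rep(0, n)  # constant abundances carry no signal
  y <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
  percent_annual <- pmin(100, pmax(0, 50 + 16 * y))

  alt_range <- list(river_valley = c(700, 1400), forest = c(1450, 1950),
                    subalpine_meadow = c(2100, 2500))
  altitude <- vapply(seq_len(n), function(i) {
    rng <- alt_range[[samples$biotope[i]]]
    if (is.null(rng)) rng <- c(500, 2500)
    stats::runif(1, rng[1], rng[2])
  }, numeric(1))

  soil_code <- match(samples$biotope, unique(samples$biotope))
  data.frame(
    stp_id = samples$sample_id,
    biotope = samples$biotope,
    altitude_m = round(altitude),
    pH_KCl = round(stats::runif(n, 4.5, 7.5), 2),
    Pi_mg_per_kg = round(stats::runif(n, 5, 60), 1),
    N_total_pct = round(stats::runif(n, 0.2, 0.8), 2),
    P_total_pct = round(stats::runif(n, 0.05, 0.30), 3),
    percent_annual_plants = round(percent_annual, 1),
    n_herb_species = as.integer(round(stats::runif(n, 10, 60))),
    fraction_lt_0_01mm = round(stats::runif(n, 0.2, 0.7), 2),
    soil_type_code = soil_code,
    stringsAsFactors = FALSE)
}
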