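# Scenario configuration for the synthetic-community generator.

#' Configure a synthetic community scenario
#'
#' Defines the generative conditions for a synthetic gut-microbiome study:
#' a pool of family-level phylotypes with heavy-tailed (log-normal) mean
#' relative abundances, a pathway catalog whose enzyme (EC) repertoires are
#' distributed across genomes with a planted redundancy structure, repeated
#' weekly sampling of individuals, and diet treatments that suppress a
#' rarity-biased subset of families.
#'
#' Defaults are calibrated to a cockroach frass microbiome time course:
#' 144 family-level phylotypes across 21 phyla with roughly 70% of families
#' below 1% mean relative abundance, 370 metabolic pathways of which 32 are
#' obligately shared (their EC set split across two or more genomes) and 8%
#' of the remaining per-taxon pathways are carried by exactly one family,
#' 7 individuals per diet treatment sampled weekly for 8 weeks at a mean
#' depth of 20,000 reads, and unbalanced diets that suppress 30% of families
#' with a strong bias toward rare ones.
#'
#' @param n_taxa Number of family-level phylotypes.
#' @param n_phyla Number of phyla the families are spread across.
#' @param n_pathways Total number of pathways in the catalog.
#' @param ec_range Integer vector of length 2: minimum and maximum number of
#'   required ECs per pathway.
#' @param singleton_fraction Probability that a per-taxon pathway is carried
#'   by exactly one family.
#' @param redundancy_prob Success parameter of the truncated geometric
#'   distribution of carriers-per-pathway for non-singleton per-taxon
#'   pathways.
#' @param redundancy_support Integer vector of length 2: support of the
#'   truncated geometric carrier-count distribution.
#' @param n_obligate Number of obligately-shared pathways (EC set split
#'   across >= 2 genomes, no single genome complete).
#' @param variant_class_count Number of variant classes, each grouping >= 2
#'   pathways that yield the same metabolites through distinct enzymes.
#' @param treatments Character vector of treatment names; the first is the
#'   control (balanced) diet.
#' @param perturbed Character vector naming the treatments that suppress
#'   taxa; defaults to all but the first treatment.
#' @param n_individuals_per_treatment Individuals per treatment.
#' @param n_weeks Number of weekly samples per individual.
#' @param depth_mean Expected reads per sample (Poisson mean).
#' @param abundance_sigma Log-normal sigma of the rare-tail component of
#'   mean relative abundances.
#' @param common_fraction Fraction of taxa belonging to the dominant core of
#'   the community. Mean relative abundances follow a two-component
#'   log-normal mixture: a dominant core (log-mean `common_boost`, sigma
#'   `common_sigma`) over a rare tail (log-mean 0, sigma `abundance_sigma`).
#'   The defaults put about 70% of taxa below 1% mean relative abundance, the
#'   calibration anchor; a single log-normal cannot reach that fraction with
#'   144 taxa (its achievable minimum is roughly 80%).
#' @param common_boost Log-mean offset of the dominant core.
#' @param common_sigma Log-normal sigma of the dominant core.
#' @param individual_sigma Log-normal sigma of per-individual multiplicative
#'   noise around the community-level abundance profile.
#' @param dropout_fraction Fraction of taxa suppressed in each perturbed
#'   treatment.
#' @param dropout_bias Rarity-weighting exponent for choosing suppressed
#'   taxa: suppression weight is (abundance rank from most abundant)^bias,
#'   so larger values concentrate suppression on rare families; 0 is
#'   uniform.
#' @param dropout_start_week First week (inclusive) at which suppression
#'   applies in perturbed treatments.
#' @param leak Residual relative-abundance multiplier for suppressed taxa
#'   (0 = total dropout; small positive values model "below detection"
#'   rather than extinction).
#' @param singleton_rank_quantile Singleton-pathway carriers are drawn from
#'   families in this top fraction of mean abundance (default top quartile),
#'   so singleton pathways survive rarity-biased loss by default.
#' @param singleton_uniform If `TRUE`, singleton carriers are drawn
#'   uniformly from all taxa instead (stress-testing switch).
#' @param carrier_bias Exponent on mean relative abundance used to weight
#'   carrier assignment for non-singleton and obligately-shared pathways;
#'   1.0 concentrates pathway carriage in the persistent abundant families,
#'   0 assigns carriers uniformly.
#' @param copy_number_variation If `TRUE`, carried ECs get Poisson-dispersed
#'   copy numbers >= 1; by default every carried EC has copy number 1
#'   (presence, not dosage, drives the classification).
#' @param seed Integer top-level RNG seed; all stage streams are derived
#'   from it.
#' @return A validated `scenario_config` list.
#' @examples
#' cfg <- scenario_config(seed = 1)
#' cfg$n_taxa
#' @export
scenario_config <- function(n_taxa = 144,
                            n_phyla = 21,
                            n_pathways = 370,
                            ec_range = c(3L, 8L),
                            singleton_fraction = 0.08,
                            redundancy_prob = 0.25,
                            redundancy_support = c(2L, 30L),
                            n_obligate = 32,
                            variant_class_count = 10,
                            treatments = c("balanced", "cellulose", "protein"),
                            perturbed = NULL,
                            n_individuals_per_treatment = 7,
                            n_weeks = 8,
                            depth_mean = 20000,
                            abundance_sigma = 2.0,
                            common_fraction = 0.30,
                            common_boost = 4.5,
                            common_sigma = 0.5,
                            individual_sigma = 0.5,
                            dropout_fraction = 0.30,
                            dropout_bias = 2.0,
                            dropout_start_week = 1,
                            leak = 0,
                            singleton_rank_quantile = 0.25,
                            singleton_uniform = FALSE,
                            carrier_bias = 1.0,
                            copy_number_variation = FALSE,
                            seed = 1L) {
  cfg <- list(
    n_taxa = as.integer(n_taxa), n_phyla = as.integer(n_phyla),
    n_pathways = as.integer(n_pathways),
    ec_range = as.integer(ec_range),
    singleton_fraction = singleton_fraction,
    redundancy_prob = redundancy_prob,
    redundancy_support = as.integer(redundancy_support),
    n_obligate = as.integer(n_obligate),
    variant_class_count = as.integer(variant_class_count),
    treatments = treatments,
    perturbed = perturbed %||% treatments[-1],
    n_individuals_per_treatment = as.integer(n_individuals_per_treatment),
    n_weeks = as.integer(n_weeks),
    depth_mean = depth_mean,
    abundance_sigma = abundance_sigma,
    common_fraction = common_fraction,
    common_boost = common_boost,
    common_sigma = common_sigma,
    individual_sigma = individual_sigma,
    dropout_fraction = dropout_fraction,
    dropout_bias = dropout_bias,
    dropout_start_week = as.integer(dropout_start_week),
    leak = leak,
    singleton_rank_quantile = singleton_rank_quantile,
    singleton_uniform = isTRUE(singleton_uniform),
    carrier_bias = carrier_bias,
    copy_number_variation = isTRUE(copy_number_variation),
    seed = as.integer(seed)
  )
  validate_scenario(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(paste0("invalid scenario: ", msg))
  counts <- c("n_taxa", "n_phyla", "n_pathways", "n_individuals_per_treatment",
              "n_weeks")
  for (f in counts) chk(cfg[[f]] >= 1, sprintf("%s must be >= 1", f))
  props <- c("singleton_fraction", "dropout_fraction", "leak",
             "singleton_rank_quantile", "common_fraction")
  for (f in props) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, sprintf("%s must be in [0, 1]", f))
  }
  chk(cfg$n_obligate >= 0 && cfg$n_obligate <= cfg$n_pathways,
      "n_obligate must be between 0 and n_pathways (n_obligate + per-taxon pathways = n_pathways)")
  chk(length(cfg$ec_range) == 2 && cfg$ec_range[1] >= 1 &&
        cfg$ec_range[1] <= cfg$ec_range[2],
      "ec_range must be an increasing pair of positive integers")
  chk(length(cfg$redundancy_support) == 2 &&
        cfg$redundancy_support[1] >= 2 &&
        cfg$redundancy_support[1] <= cfg$redundancy_support[2],
      "redundancy_support must be an increasing pair with lower bound >= 2")
  chk(cfg$redundancy_support[2] <= cfg$n_taxa,
      "redundancy_support upper bound exceeds n_taxa")
  chk(cfg$redundancy_prob > 0 && cfg$redundancy_prob < 1,
      "redundancy_prob must be in (0, 1)")
  chk(cfg$n_phyla <= cfg$n_taxa, "n_phyla must not exceed n_taxa")
  chk(cfg$n_obligate == 0 || cfg$ec_range[2] >= 2,
      "obligately-shared pathways need ec_range upper bound >= 2 to split")
  chk(cfg$depth_mean > 0, "depth_mean must be positive")
  chk(cfg$abundance_sigma >= 0 && cfg$individual_sigma >= 0 &&
        cfg$common_sigma >= 0,
      "sigmas must be non-negative")
  chk(cfg$dropout_bias >= 0, "dropout_bias must be non-negative")
  chk(cfg$carrier_bias >= 0, "carrier_bias must be non-negative")
  chk(length(cfg$treatments) >= 1 && !anyDuplicated(cfg$treatments),
      "treatments must be distinct names")
  chk(all(cfg$perturbed %in% cfg$treatments),
      "perturbed treatments must be a subset of treatments")
  chk(cfg$variant_class_count * 2 <= cfg$n_pathways,
      "variant_class_count too large: each class needs >= 2 pathways")
  n_singleton_pool <- max(1L, ceiling(cfg$singleton_rank_quantile * cfg$n_taxa))
  chk(n_singleton_pool >= 1, "singleton carrier pool is empty")
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  %d taxa / %d phyla, %d pathways (%d obligately shared)\n",
              x$n_taxa, x$n_phyla, x$n_pathways, x$n_obligate))
  cat(sprintf("  treatments: %s (perturbed: %s)\n",
              paste(x$treatments, collapse = ", "),
              paste(x$perturbed, collapse = ", ")))
  cat(sprintf("  %d individuals/treatment x %d weeks, depth ~ Poisson(%g)\n",
              x$n_individuals_per_treatment, x$n_weeks, x$depth_mean))
  cat(sprintf("  dropout: %.0f%% of taxa, rarity bias %.1f, leak %.2g, seed %d\n",
              100 * x$dropout_fraction, x$dropout_bias, x$leak, x$seed))
  invisible(x)
}
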