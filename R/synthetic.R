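# Synthetic community generator: genome content, pathway catalog, planted
# truth, and taxon-by-sample count tables with diet-perturbation effects.

taxon_ids <- function(n) sprintf("F%03d", seq_len(n))
pathway_ids <- function(n) sprintf("PWY%04d", seq_len(n))

# Community-level mean relative abundances, drawn on their own stream so that
# genome-content and count generation see the same vector. Two-component
# log-normal mixture: a dominant core of families over a rare tail, which
# reproduces the flat-head/long-tail rank-abundance shape of family-level
# gut communities (a single log-normal cannot put only ~70% of 144 taxa
# below 1% relative abundance).
scenario_abundance <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "abundance"), {
    common <- runif(cfg$n_taxa) < cfg$common_fraction
    a <- exp(ifelse(common,
                    rnorm(cfg$n_taxa, cfg$common_boost, cfg$common_sigma),
                    rnorm(cfg$n_taxa, 0, cfg$abundance_sigma)))
    a / sum(a)
  })
}

# Truncated geometric on support kmin..kmax: pmf(k) proportional to
# p * (1-p)^(k - kmin).
rtrunc_geom <- function(n, p, support) {
  ks <- seq.int(support[1], support[2])
  pmf <- p * (1 - p)^(ks - support[1])
  sample(ks, n, replace = TRUE, prob = pmf / sum(pmf))
}

#' Generate genome content, pathway catalog, and planted truth
#'
#' Builds the genome-content side of a synthetic scenario: a taxon-by-EC
#' copy-number table, a pathway catalog mapping each pathway to its required
#' EC set (with optional variant class), and a `synthetic_truth` record of
#' what was planted (carriers per pathway, EC partitions of obligately-shared
#' pathways, suppressed taxa per perturbed treatment, variant classes).
#'
#' Each pathway owns a disjoint set of ECs. Per-taxon pathways assign the
#' full EC repertoire to each carrier genome; carrier counts follow the
#' configured singleton fraction and truncated-geometric redundancy
#' distribution, singleton carriers are drawn from the most abundant
#' families, and multi-carrier identities are weighted by mean abundance
#' (see [scenario_config()]). Obligately-shared pathways have their EC set
#' partitioned across two or more genomes so that no single genome is
#' complete.
#'
#' @param cfg A [scenario_config()].
#' @return A list with elements `content` (tibble, first column `taxon`, one
#'   numeric column per EC), `annotations` (tibble: taxon, phylum, nsti),
#'   `catalog` (tibble: pathway, ecs list-column, variant_class), and `truth`
#'   (a `synthetic_truth` list).
#' @examples
#' sim <- generate_genome_content(scenario_config(n_taxa = 20, n_pathways = 15,
#'                                                n_obligate = 3, seed = 1))
#' dim(sim$content)
#' @export
generate_genome_content <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  validate_scenario(cfg)
  abund <- scenario_abundance(cfg)
  taxa <- taxon_ids(cfg$n_taxa)

  with_seed(derive_seed(cfg$seed, "genome_content"), {
    n_pertaxon <- cfg$n_pathways - cfg$n_obligate
    pwys <- pathway_ids(cfg$n_pathways)
    is_obligate <- c(rep(FALSE, n_pertaxon), rep(TRUE, cfg$n_obligate))

    sizes <- sample(seq.int(cfg$ec_range[1], cfg$ec_range[2]),
                    cfg$n_pathways, replace = TRUE)
    sizes[is_obligate] <- pmax(sizes[is_obligate], 2L)  # splittable
    ec_sets <- lapply(seq_len(cfg$n_pathways), function(i) {
      sprintf("EC:%04d.%d", i, seq_len(sizes[i]))
    })
    names(ec_sets) <- pwys

    # carrier counts for per-taxon pathways
    n_singleton_pool <- max(1L, ceiling(cfg$singleton_rank_quantile * cfg$n_taxa))
    top_pool <- order(abund, decreasing = TRUE)[seq_len(n_singleton_pool)]
    carrier_w <- if (cfg$carrier_bias == 0) rep(1, cfg$n_taxa) else abund^cfg$carrier_bias

    carriers <- vector("list", cfg$n_pathways)
    names(carriers) <- pwys
    obligate_split <- list()
    if (n_pertaxon > 0) {
      singleton <- runif(n_pertaxon) < cfg$singleton_fraction
      for (i in seq_len(n_pertaxon)) {
        if (singleton[i]) {
          pool <- if (cfg$singleton_uniform) seq_len(cfg$n_taxa) else top_pool
          carriers[[i]] <- taxa[sample(pool, 1L)]
        } else {
          k <- rtrunc_geom(1L, cfg$redundancy_prob, cfg$redundancy_support)
          carriers[[i]] <- taxa[sample.int(cfg$n_taxa, k, prob = carrier_w)]
        }
      }
    }
    if (cfg$n_obligate > 0) {
      for (j in seq_len(cfg$n_obligate)) {
        i <- n_pertaxon + j
        n_ec <- sizes[i]
        n_blocks <- sample(2:min(3L, n_ec), 1L)
        blk_taxa <- taxa[sample.int(cfg$n_taxa, n_blocks, prob = carrier_w)]
        # partition ECs into n_blocks non-empty blocks
        grp <- c(seq_len(n_blocks),
                 if (n_ec > n_blocks) sample.int(n_blocks, n_ec - n_blocks,
                                                 replace = TRUE))
        grp <- sample(grp)  # shuffle which EC lands in which block
        split_ecs <- split(ec_sets[[i]], blk_taxa[grp])
        obligate_split[[pwys[i]]] <- split_ecs
        carriers[[i]] <- blk_taxa
      }
    }

    # content matrix
    all_ecs <- unlist(ec_sets, use.names = FALSE)
    m <- matrix(0, cfg$n_taxa, length(all_ecs),
                dimnames = list(taxa, all_ecs))
    for (i in seq_len(cfg$n_pathways)) {
      p <- pwys[i]
      if (is_obligate[i]) {
        for (tx in names(obligate_split[[p]])) {
          m[tx, obligate_split[[p]][[tx]]] <- 1
        }
      } else {
        m[carriers[[p]], ec_sets[[p]]] <- 1
      }
    }
    if (cfg$copy_number_variation) {
      idx <- which(m > 0)
      m[idx] <- 1 + rpois(length(idx), 0.5)
    }

    # variant classes: each groups >= 2 pathways
    variant_class <- rep(NA_character_, cfg$n_pathways)
    variant_classes <- list()
    if (cfg$variant_class_count > 0) {
      cls_sizes <- sample(2:3, cfg$variant_class_count, replace = TRUE)
      cls_sizes <- pmin(cls_sizes, cfg$n_pathways)
      while (sum(cls_sizes) > cfg$n_pathways) cls_sizes[which.max(cls_sizes)] <-
          cls_sizes[which.max(cls_sizes)] - 1L
      members <- sample.int(cfg$n_pathways, sum(cls_sizes))
      offset <- 0L
      for (v in seq_len(cfg$variant_class_count)) {
        ids <- members[offset + seq_len(cls_sizes[v])]
        offset <- offset + cls_sizes[v]
        lab <- sprintf("V%02d", v)
        variant_class[ids] <- lab
        variant_classes[[lab]] <- pwys[ids]
      }
    }

    # per-taxon annotations: phylum (all phyla represented) and NSTI
    phyla <- sprintf("p%02d", seq_len(cfg$n_phyla))
    phylum <- c(phyla, sample(phyla, cfg$n_taxa - cfg$n_phyla, replace = TRUE))
    phylum <- sample(phylum)
    nsti <- runif(cfg$n_taxa, 0, 1.5)

    # suppressed taxa per perturbed treatment, rarity-biased
    n_drop <- floor(cfg$dropout_fraction * cfg$n_taxa)
    rarity_rank <- rank(-abund, ties.method = "first")  # 1 = most abundant
    drop_w <- rarity_rank^cfg$dropout_bias
    suppressed <- lapply(cfg$perturbed, function(tr) {
      if (n_drop == 0) character(0) else
        taxa[sample.int(cfg$n_taxa, n_drop, prob = drop_w)]
    })
    names(suppressed) <- cfg$perturbed

    truth <- structure(list(
      carriers = carriers,
      obligate_split = obligate_split,
      suppressed_taxa = suppressed,
      variant_classes = variant_classes,
      obligate_pathways = pwys[is_obligate],
      per_taxon_pathways = pwys[!is_obligate],
      mean_abundance = setNames(abund, taxa)
    ), class = "synthetic_truth")

    list(
      content = matrix_to_table(m, "taxon"),
      annotations = tibble(taxon = taxa, phylum = phylum, nsti = nsti),
      catalog = tibble(pathway = pwys, ecs = unname(ec_sets),
                       variant_class = variant_class),
      truth = truth
    )
  })
}

#' Generate a taxon-by-sample count table with metadata
#'
#' Simulates the sampling design: each individual is assigned to one
#' treatment and sampled once per week; counts are multinomial draws at a
#' Poisson-distributed depth from individual-specific log-normal perturbations
#' of the community abundance profile. In perturbed treatments the
#' planted suppressed taxa have their relative abundance multiplied by the
#' configured leak factor (0 = total dropout) from `dropout_start_week`
#' onward.
#'
#' @param cfg A [scenario_config()].
#' @param truth The `synthetic_truth` from [generate_genome_content()] run on
#'   the same config (supplies the suppressed-taxa sets).
#' @return A list with `counts` (tibble, first column `taxon`, one integer
#'   column per sample) and `metadata` (tibble: sample_id, individual, week,
#'   treatment).
#' @export
generate_counts <- function(cfg, truth) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(truth, "synthetic_truth"))
  abund <- scenario_abundance(cfg)
  taxa <- taxon_ids(cfg$n_taxa)

  with_seed(derive_seed(cfg$seed, "counts"), {
    meta <- tidyr::expand_grid(
      treatment = cfg$treatments,
      ind = seq_len(cfg$n_individuals_per_treatment),
      week = seq_len(cfg$n_weeks)
    )
    meta$individual <- sprintf("%s_I%02d", meta$treatment, meta$ind)
    meta$sample_id <- sprintf("%s_w%d", meta$individual, meta$week)
    meta <- meta[, c("sample_id", "individual", "week", "treatment")]

    # individual-specific abundance profiles
    inds <- unique(meta$individual)
    p_ind <- lapply(inds, function(i) {
      p <- abund * exp(rnorm(cfg$n_taxa, 0, cfg$individual_sigma))
      p / sum(p)
    })
    names(p_ind) <- inds

    m <- matrix(0L, cfg$n_taxa, nrow(meta), dimnames = list(taxa, meta$sample_id))
    for (s in seq_len(nrow(meta))) {
      p <- p_ind[[meta$individual[s]]]
      tr <- meta$treatment[s]
      if (tr %in% names(truth$suppressed_taxa) &&
          meta$week[s] >= cfg$dropout_start_week) {
        p[taxa %in% truth$suppressed_taxa[[tr]]] <-
          p[taxa %in% truth$suppressed_taxa[[tr]]] * cfg$leak
        if (sum(p) == 0) abort("all taxa suppressed; cannot draw a sample")
        p <- p / sum(p)
      }
      depth <- rpois(1L, cfg$depth_mean)
      m[, s] <- rmultinom(1L, depth, p)[, 1]
    }
    list(counts = matrix_to_table(m, "taxon"), metadata = as_tibble(meta))
  })
}

#' Simulate a complete synthetic scenario
#'
#' Convenience wrapper running [generate_genome_content()] then
#' [generate_counts()] under one configuration.
#'
#' @param cfg A [scenario_config()].
#' @return A list: `counts`, `metadata`, `content`, `annotations`, `catalog`,
#'   `truth`, `cfg`.
#' @examples
#' sim <- simulate_community(scenario_config(n_taxa = 12, n_pathways = 10,
#'   n_obligate = 2, variant_class_count = 2, n_individuals_per_treatment = 2,
#'   n_weeks = 2, seed = 42))
#' names(sim)
#' @export
simulate_community <- function(cfg = scenario_config()) {
  gc <- generate_genome_content(cfg)
  ct <- generate_counts(cfg, gc$truth)
  c(ct, gc, list(cfg = cfg))
}
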