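# End-to-end pipeline: filtering -> alpha diversity -> beta statistics ->
# capacity -> prevalence / fates / buffering, with a run manifest.

#' Configure a pipeline run
#'
#' Either `scenario` (simulation mode) or the four file paths (file mode)
#' must be given, not both.
#'
#' @param counts_path,metadata_path,content_path,catalog_path Input files
#'   (file mode).
#' @param annotations_path Optional per-taxon annotation TSV (taxon, phylum,
#'   nsti).
#' @param scenario A [scenario_config()] (simulation mode).
#' @param filter A [filter_config()].
#' @param q Hill orders for the diversity summary.
#' @param weeks Named list of analysis windows (label -> weeks), as in
#'   [window_spec()].
#' @param baseline_label,end_label Window labels compared by the fate
#'   classification (within each treatment).
#' @param threshold Prevalence threshold for presence calls.
#' @param high_threshold Secondary threshold for the high-prevalence table.
#' @param n_perm,n_perm_disp Permutation counts for PERMANOVA and the
#'   dispersion test.
#' @param scheme Permutation restriction scheme for PERMANOVA.
#' @param n_starts NMDS random starts.
#' @param buffering_fractions,buffering_strategy,buffering_reps Knockout
#'   simulation settings.
#' @param seed Top-level seed.
#' @param outdir Optional output directory for the report tables.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts_path = NULL, metadata_path = NULL,
                            content_path = NULL, catalog_path = NULL,
                            annotations_path = NULL, scenario = NULL,
                            filter = filter_config(), q = c(0, 1, 2),
                            weeks = list(w1_2 = 1:2, w3_4 = 3:4, w7_8 = 7:8),
                            baseline_label = names(weeks)[1],
                            end_label = names(weeks)[length(weeks)],
                            threshold = 0.25, high_threshold = 0.75,
                            n_perm = 999, n_perm_disp = 9999,
                            scheme = "blocks", n_starts = 100,
                            buffering_fractions = c(0, 0.1, 0.2, 0.3),
                            buffering_strategy = "rarity_biased",
                            buffering_reps = 20, seed = 1L, outdir = NULL) {
  paths <- list(counts = counts_path, metadata = metadata_path,
                content = content_path, catalog = catalog_path)
  file_mode <- any(!vapply(paths, is.null, logical(1)))
  if (file_mode && !is.null(scenario)) {
    abort("simulation and file inputs are mutually exclusive")
  }
  if (!file_mode && is.null(scenario)) {
    abort("either a scenario or input file paths must be supplied")
  }
  if (file_mode) {
    if (any(vapply(paths, is.null, logical(1)))) {
      abort("file mode needs counts, metadata, content and catalog paths")
    }
    missing <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing) > 0) {
      abort(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")))
    }
  }
  structure(list(paths = paths, annotations_path = annotations_path,
                 scenario = scenario, filter = filter, q = q, weeks = weeks,
                 baseline_label = baseline_label, end_label = end_label,
                 threshold = threshold, high_threshold = high_threshold,
                 n_perm = n_perm, n_perm_disp = n_perm_disp, scheme = scheme,
                 n_starts = n_starts,
                 buffering_fractions = buffering_fractions,
                 buffering_strategy = buffering_strategy,
                 buffering_reps = buffering_reps,
                 seed = as.integer(seed), outdir = outdir,
                 mode = if (file_mode) "file" else "simulation"),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  inform(sprintf("[stage %s]", name))
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Chains the stages in the order quality filtering, relative abundance,
#' Hill-diversity summary, dissimilarity statistics (NMDS, PERMANOVA with
#' restricted permutations, dispersion test, pairwise comparisons with
#' BH-FDR), per-sample metabolic capacity, window prevalence calls, fate
#' classification between the baseline and end windows of each treatment,
#' redundancy distribution, and a knockout buffering curve. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg A [pipeline_config()].
#' @return A `capacity_report` list of tibbles and result objects; if
#'   `cfg$outdir` is set the tables are also written there as TSV along with
#'   a JSON run manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seed <- cfg$seed

  dat <- run_stage("load", {
    if (cfg$mode == "simulation") {
      sim <- simulate_community(cfg$scenario)
      sim["truth"] <- NULL
      sim
    } else {
      list(counts = read_count_table(cfg$paths$counts),
           metadata = read_metadata(cfg$paths$metadata),
           content = read_gene_content(cfg$paths$content),
           catalog = read_catalog(cfg$paths$catalog),
           annotations = if (!is.null(cfg$annotations_path)) {
             readr::read_tsv(cfg$annotations_path, comment = "#",
                             show_col_types = FALSE, progress = FALSE)
           })
    }
  })

  filt <- run_stage("filter", {
    counts <- filter_samples(dat$counts, cfg$filter)
    sample_report <- exclusions(counts)
    counts <- filter_phylotypes(counts, cfg$filter)
    taxon_report <- exclusions(counts)
    content <- filter_nsti(dat$content, dat$annotations, cfg$filter)
    metadata <- dat$metadata |> filter(.data$sample_id %in% names(counts)[-1])
    inform(sprintf("  retained %d taxa x %d samples", nrow(counts),
                   ncol(counts) - 1))
    list(counts = counts, content = content, metadata = metadata,
         exclusions = bind_rows(sample_report, taxon_report))
  })

  diversity <- run_stage("diversity", {
    diversity_summary(filt$counts, filt$metadata, q = cfg$q)
  })

  beta <- run_stage("beta", {
    groups <- filt$metadata$treatment[match(names(filt$counts)[-1],
                                            filt$metadata$sample_id)]
    blocks <- filt$metadata$individual[match(names(filt$counts)[-1],
                                             filt$metadata$sample_id)]
    res <- purrr::map(list(bray = bray_curtis, sorensen = sorensen),
                      function(fn) {
      d <- fn(filt$counts)
      list(
        nmds = nmds_ordination(d, n_starts = cfg$n_starts,
                               seed = derive_seed(seed, "nmds")),
        permanova = permanova(d, groups, blocks, n_perm = cfg$n_perm,
                              scheme = cfg$scheme,
                              seed = derive_seed(seed, "permanova")),
        dispersion = dispersion_test(d, groups, n_perm = cfg$n_perm_disp,
                                     seed = derive_seed(seed, "dispersion")),
        pairwise = pairwise_permanova(d, groups, blocks, n_perm = cfg$n_perm,
                                      scheme = cfg$scheme,
                                      seed = derive_seed(seed, "pairwise"))
      )
    })
    res
  })

  capacity <- run_stage("capacity", {
    capacity_by_sample(filt$content, filt$counts, dat$catalog)
  })

  windows <- run_stage("windows", window_spec(filt$metadata, cfg$weeks))

  prevalence <- run_stage("prevalence", {
    prevalence_calls(capacity$presence, windows, threshold = cfg$threshold,
                     pathways = sort(dat$catalog$pathway))
  })
  high_prevalence <- prevalence |>
    mutate(present = .data$prevalence >= cfg$high_threshold)

  fates <- run_stage("fates", {
    treatments <- unique(filt$metadata$treatment)
    out <- purrr::map(treatments, function(tr) {
      bw <- paste(tr, cfg$baseline_label, sep = ".")
      ew <- paste(tr, cfg$end_label, sep = ".")
      if (!all(c(bw, ew) %in% prevalence$window)) return(NULL)
      fate_classification(
        prevalence |> filter(.data$window == bw),
        prevalence |> filter(.data$window == ew),
        incidence = capacity$incidence, windows = windows,
        baseline_window = bw, end_window = ew, threshold = cfg$threshold)
    })
    setNames(out, treatments)
  })

  redundancy <- run_stage("redundancy", {
    profile <- community_capacity(filt$content, filt$counts, dat$catalog)
    list(profile = profile,
         distribution = redundancy_distribution(profile$incidence))
  })

  buffering <- run_stage("buffering", {
    buffering_curve(filt$content, filt$counts, dat$catalog,
                    fractions = cfg$buffering_fractions,
                    strategy = cfg$buffering_strategy,
                    n_reps = cfg$buffering_reps,
                    seed = derive_seed(seed, "buffering"))
  })

  manifest <- list(
    mode = cfg$mode, seed = seed,
    parameters = list(threshold = cfg$threshold,
                      high_threshold = cfg$high_threshold,
                      n_perm = cfg$n_perm, n_perm_disp = cfg$n_perm_disp,
                      scheme = cfg$scheme, q = cfg$q,
                      weeks = cfg$weeks,
                      buffering = list(fractions = cfg$buffering_fractions,
                                       strategy = cfg$buffering_strategy,
                                       n_reps = cfg$buffering_reps)),
    n_taxa = nrow(filt$counts), n_samples = ncol(filt$counts) - 1,
    n_pathways = nrow(dat$catalog),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  report <- structure(list(
    counts = filt$counts, metadata = filt$metadata,
    exclusions = filt$exclusions, diversity = diversity, beta = beta,
    presence = capacity$presence, incidence = capacity$incidence,
    prevalence = prevalence, high_prevalence = high_prevalence,
    fates = fates, redundancy = redundancy, buffering = buffering,
    manifest = manifest, catalog = dat$catalog
  ), class = "capacity_report")

  if (!is.null(cfg$outdir)) write_report(report, cfg$outdir)
  report
}

#' Write a pipeline report bundle to a directory
#'
#' @param report A `capacity_report` from [run_pipeline()].
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_tsv(x, file.path(outdir, f), progress = FALSE)
  w(report$diversity, "diversity.tsv")
  w(report$prevalence, "prevalence.tsv")
  w(report$high_prevalence, "high_prevalence.tsv")
  w(report$presence, "pathway_presence.tsv")
  w(report$incidence, "incidence.tsv")
  w(report$exclusions, "exclusions.tsv")
  w(as_tibble(report$buffering), "buffering.tsv")
  for (tr in names(report$fates)) {
    if (!is.null(report$fates[[tr]])) {
      w(report$fates[[tr]]$pathway, sprintf("fates_pathway_%s.tsv", tr))
      w(report$fates[[tr]]$family, sprintf("fates_family_%s.tsv", tr))
    }
  }
  stats <- purrr::map_dfr(names(report$beta), function(ix) {
    b <- report$beta[[ix]]
    tibble(index = ix,
           permanova_F = b$permanova$pseudo_F, permanova_p = b$permanova$p,
           dispersion_F = b$dispersion$F_disp, dispersion_p = b$dispersion$p,
           nmds_stress = b$nmds$stress)
  })
  w(stats, "beta_stats.tsv")
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.capacity_report <- function(x, ...) {
  cat("<capacity_report>\n")
  cat(sprintf("  %d taxa x %d samples, %d pathways\n",
              nrow(x$counts), ncol(x$counts) - 1, nrow(x$catalog)))
  cat(sprintf("  diversity rows: %d; prevalence rows: %d\n",
              nrow(x$diversity), nrow(x$prevalence)))
  invisible(x)
}
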