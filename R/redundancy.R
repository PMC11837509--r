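# Prevalence-based presence calls, pathway fate classification between
# treatment windows, redundancy distributions, and taxon-knockout buffering
# simulations.

#' Define treatment-by-week analysis windows
#'
#' A window pools the samples of one treatment over a set of weeks; pathway
#' prevalence is computed over the pooled samples. The default windows are
#' the two-week pairs used for age-matched comparisons: weeks 1-2 (baseline),
#' 3-4, and 7-8 of every treatment.
#'
#' @param metadata Sample metadata (sample_id, individual, week, treatment).
#' @param weeks Named list: window label -> integer vector of weeks.
#' @return Tibble: window, treatment, sample_id.
#' @export
window_spec <- function(metadata,
                        weeks = list(w1_2 = 1:2, w3_4 = 3:4, w7_8 = 7:8)) {
  purrr::map_dfr(names(weeks), function(w) {
    metadata |>
      filter(.data$week %in% weeks[[w]]) |>
      mutate(window = paste(.data$treatment, w, sep = ".")) |>
      select("window", "treatment", "sample_id")
  })
}

#' Prevalence-based pathway presence calls per window
#'
#' A pathway is deemed present in a window if it is detected in at least
#' `threshold` (default 25%) of that window's samples; the comparison is
#' inclusive (prevalence equal to the threshold counts as present). Window
#' denominators pool all samples of the window.
#'
#' @param presence Per-sample pathway presence tibble (sample_id, pathway,
#'   and optionally class), e.g. `capacity_by_sample()$presence`.
#' @param windows Window assignment tibble from [window_spec()]; every
#'   sample may belong to at most one window per window label.
#' @param threshold Minimum fraction of window samples for a present call.
#' @param pathways Pathway universe; defaults to the pathways appearing in
#'   `presence` (supply the full catalog to report never-detected pathways).
#' @return Tibble: window, pathway, n_samples, n_detected, prevalence,
#'   present.
#' @examples
#' pres <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
#'                        pathway = c("P1", "P1", "P2", "P1"))
#' win <- tibble::tibble(window = "w", treatment = "b",
#'                       sample_id = paste0("s", 1:4))
#' prevalence_calls(pres, win)
#' @export
prevalence_calls <- function(presence, windows, threshold = 0.25,
                             pathways = NULL) {
  pathways <- pathways %||% sort(unique(presence$pathway))
  if (nrow(windows) == 0) abort("no windows supplied")
  sizes <- windows |> group_by(.data$window) |>
    summarise(n_samples = dplyr::n_distinct(.data$sample_id), .groups = "drop")
  if (any(sizes$n_samples == 0)) {
    abort(sprintf("empty window(s): %s",
                  paste(sizes$window[sizes$n_samples == 0], collapse = ", ")))
  }
  det <- windows |>
    inner_join(presence, by = "sample_id",
               relationship = "many-to-many") |>
    filter(.data$pathway %in% pathways) |>
    group_by(.data$window, .data$pathway) |>
    summarise(n_detected = dplyr::n_distinct(.data$sample_id), .groups = "drop")
  grid <- tidyr::expand_grid(window = sizes$window, pathway = pathways)
  out <- grid |>
    left_join(sizes, by = "window") |>
    left_join(det, by = c("window", "pathway")) |>
    mutate(n_detected = tidyr::replace_na(.data$n_detected, 0L),
           prevalence = .data$n_detected / .data$n_samples,
           present = .data$prevalence >= threshold)
  out
}

#' Classify pathway fates between a baseline and an end window
#'
#' Compares prevalence-based presence between two windows and assigns each
#' pathway one of four fates: `retained` (present in both), `never` (absent
#' in both), `gained` (absent at baseline, present at the end), `lost`
#' (present at baseline, absent at the end). When per-sample taxon-by-pathway
#' incidence is supplied the same classification is additionally made at
#' family-by-pathway granularity (a family "carries" a pathway in a window if
#' it completes the pathway alone in at least `threshold` of the window's
#' samples); a pathway can then be `lost` for one family while the
#' pathway-level aggregate stays `retained` because another family still
#' completes it.
#'
#' @param baseline_calls,end_calls Single-window slices of a
#'   [prevalence_calls()] table (pathway universes must match).
#' @param incidence Optional per-sample incidence (sample_id, taxon,
#'   pathway), e.g. `capacity_by_sample()$incidence`.
#' @param windows Window assignment tibble (required with `incidence`).
#' @param baseline_window,end_window Window labels (required with
#'   `incidence`).
#' @param threshold Prevalence threshold for family-level presence.
#' @return A `fate_matrix` list: `pathway` (tibble pathway, baseline,
#'   end, fate) and `family` (tibble taxon, pathway, fate; empty without
#'   incidence).
#' @export
fate_classification <- function(baseline_calls, end_calls, incidence = NULL,
                                windows = NULL, baseline_window = NULL,
                                end_window = NULL, threshold = 0.25) {
  if (!setequal(baseline_calls$pathway, end_calls$pathway)) {
    abort("baseline and end windows cover different pathway universes")
  }
  fates <- function(base, end) {
    dplyr::case_when(base & end ~ "retained",
                     !base & !end ~ "never",
                     !base & end ~ "gained",
                     TRUE ~ "lost")
  }
  pw <- baseline_calls |>
    select("pathway", baseline = "present") |>
    inner_join(end_calls |> select("pathway", end = "present"),
               by = "pathway") |>
    mutate(fate = fates(.data$baseline, .data$end)) |>
    arrange(.data$pathway)

  fam <- tibble(taxon = character(0), pathway = character(0),
                fate = character(0))
  if (!is.null(incidence)) {
    if (is.null(windows) || is.null(baseline_window) || is.null(end_window)) {
      abort("family-level fates need windows, baseline_window and end_window")
    }
    fam_prev <- function(wlab) {
      win <- windows |> filter(.data$window == wlab)
      if (nrow(win) == 0) abort(sprintf("empty window(s): %s", wlab))
      n_w <- dplyr::n_distinct(win$sample_id)
      incidence |>
        inner_join(win, by = "sample_id") |>
        group_by(.data$taxon, .data$pathway) |>
        summarise(n_detected = dplyr::n_distinct(.data$sample_id),
                  .groups = "drop") |>
        mutate(present = .data$n_detected / n_w >= threshold)
    }
    b <- fam_prev(baseline_window) |> select("taxon", "pathway", base = "present")
    e <- fam_prev(end_window) |> select("taxon", "pathway", end = "present")
    fam <- dplyr::full_join(b, e, by = c("taxon", "pathway")) |>
      mutate(base = tidyr::replace_na(.data$base, FALSE),
             end = tidyr::replace_na(.data$end, FALSE),
             fate = fates(.data$base, .data$end)) |>
      select("taxon", "pathway", "fate") |>
      arrange(.data$taxon, .data$pathway)
  }
  structure(list(pathway = pw, family = fam,
                 baseline_window = baseline_window, end_window = end_window),
            class = "fate_matrix")
}

#' @export
print.fate_matrix <- function(x, ...) {
  cat("<fate_matrix>\n")
  print(dplyr::count(x$pathway, .data$fate))
  invisible(x)
}

#' Redundancy distribution of single-genome pathway completions
#'
#' From a taxon-by-pathway incidence (which families complete which pathways
#' alone), tabulates the number of completing families per pathway and the
#' singleton fraction: the share of per-taxon pathways carried by no more
#' than one family.
#'
#' @param incidence Tibble with columns `taxon` and `pathway` (one row per
#'   completing family-pathway pair), e.g. a `capacity_profile`'s
#'   `incidence`.
#' @return A list: `per_pathway` (tibble pathway, n_families), `histogram`
#'   (tibble n_families, n_pathways), `singleton_fraction`.
#' @export
redundancy_distribution <- function(incidence) {
  if (nrow(incidence) == 0) {
    return(list(per_pathway = tibble(pathway = character(0),
                                     n_families = integer(0)),
                histogram = tibble(n_families = integer(0),
                                   n_pathways = integer(0)),
                singleton_fraction = NA_real_))
  }
  per <- incidence |>
    distinct(.data$taxon, .data$pathway) |>
    dplyr::count(.data$pathway, name = "n_families") |>
    arrange(.data$pathway)
  hist <- per |> dplyr::count(.data$n_families, name = "n_pathways") |>
    arrange(.data$n_families)
  list(per_pathway = per, histogram = hist,
       singleton_fraction = mean(per$n_families <= 1))
}

#' Pathway retention after removing a set of taxa
#'
#' Recomputes the community capacity profile with the removed taxa's counts
#' zeroed and reports the fraction of the baseline total pathway set still
#' encoded, along with the lost pathways and their former single-genome
#' redundancy.
#'
#' @param content Genome-content table.
#' @param counts Count table (all samples are pooled into one community).
#' @param catalog Pathway catalog.
#' @param removed_taxa Character vector of taxa to knock out (must be a
#'   subset of the community's taxa).
#' @param baseline Optional precomputed baseline `capacity_profile` for these
#'   inputs (saves recomputation in sweeps).
#' @param ctx Precomputed internal capacity context; leave `NULL`.
#' @return A list: `retention` (fraction of baseline total retained), `lost`
#'   (tibble pathway, former_redundancy), `baseline_total`, `after_total`.
#' @examples
#' sim <- simulate_community(scenario_config(n_taxa = 12, n_pathways = 10,
#'   n_obligate = 2, variant_class_count = 2, n_individuals_per_treatment = 2,
#'   n_weeks = 1, seed = 5))
#' knockout_retention(sim$content, sim$counts, sim$catalog,
#'                    removed_taxa = character(0))$retention
#' @export
knockout_retention <- function(content, counts, catalog, removed_taxa,
                               baseline = NULL, ctx = NULL) {
  ctx <- ctx %||% capacity_context(content, counts, catalog)
  bad <- setdiff(removed_taxa, rownames(ctx$xm))
  if (length(bad) > 0) {
    abort(sprintf("removed taxa not in community: %s", paste(bad, collapse = ", ")))
  }
  base <- baseline %||% community_capacity(content, counts, catalog, ctx = ctx)
  x <- rowSums(ctx$xm)
  x[names(x) %in% removed_taxa] <- 0
  red <- former_redundancy(base)
  if (all(x == 0)) {
    warn("all taxa removed: retention is 0")
    return(list(retention = 0,
                lost = tibble(pathway = base$total,
                              former_redundancy = unname(red[base$total])),
                baseline_total = base$total, after_total = character(0)))
  }
  after <- capacity_core(x, ctx$cm, ctx$comp, ctx$idx, completeness = 1.0,
                         max_exact = 25)
  lost_p <- setdiff(base$total, after$total)
  list(
    retention = if (length(base$total) == 0) NA_real_ else
      length(intersect(base$total, after$total)) / length(base$total),
    lost = tibble(pathway = lost_p,
                  former_redundancy = unname(red[lost_p])),
    baseline_total = base$total, after_total = after$total
  )
}

# Number of families completing each baseline-total pathway alone (0 for
# obligately-shared pathways).
former_redundancy <- function(profile) {
  red <- setNames(rep(0L, length(profile$total)), profile$total)
  if (nrow(profile$incidence) > 0) {
    tab <- table(profile$incidence$pathway)
    red[names(tab)] <- as.integer(tab)
  }
  red
}

#' Buffering curve: retention under increasing taxon loss
#'
#' Monte-Carlo knockout simulation: for each removal fraction, `n_reps`
#' random taxon sets are removed under the chosen strategy and the pathway
#' retention of each replicate is recorded.
#'
#' Strategies weight the sampled taxa by pooled relative abundance rank:
#' `random` is uniform; `rarity_biased` prefers rare taxa (weight =
#' rarity rank^bias, the regime diet perturbations emulate);
#' `abundance_biased` prefers abundant taxa (the worst case for capacity).
#'
#' @param content,counts,catalog Community inputs as in
#'   [knockout_retention()].
#' @param fractions Removal fractions in [0, 1).
#' @param strategy One of "random", "rarity_biased", "abundance_biased".
#' @param bias Rank-weight exponent for the biased strategies.
#' @param n_reps Replicates per fraction (>= 1).
#' @param seed Integer seed; per-replicate seeds are derived
#'   deterministically.
#' @return A `buffering_curve` tibble: fraction, strategy, mean_retention,
#'   sd_retention, n_reps, with the per-replicate values in attribute
#'   `replicates`.
#' @export
buffering_curve <- function(content, counts, catalog,
                            fractions = c(0, 0.1, 0.2, 0.3, 0.5),
                            strategy = c("random", "rarity_biased",
                                         "abundance_biased"),
                            bias = 2.0, n_reps = 20, seed = 1L) {
  strategy <- match.arg(strategy)
  if (n_reps < 1) abort("n_reps must be >= 1")
  if (any(fractions < 0 | fractions >= 1)) abort("fractions must lie in [0, 1)")
  ctx <- capacity_context(content, counts, catalog)
  pooled <- rowSums(ctx$xm)
  taxa <- rownames(ctx$xm)
  rarity_rank <- rank(-pooled, ties.method = "first")  # 1 = most abundant
  w <- switch(strategy,
              random = rep(1, length(taxa)),
              rarity_biased = rarity_rank^bias,
              abundance_biased = (length(taxa) + 1 - rarity_rank)^bias)
  base <- community_capacity(content, counts, catalog, ctx = ctx)
  reps <- purrr::map_dfr(fractions, function(f) {
    n_rm <- floor(f * length(taxa))
    purrr::map_dfr(seq_len(n_reps), function(r) {
      rm_taxa <- if (n_rm == 0) character(0) else {
        with_seed(derive_seed(seed, sprintf("knockout-%s-%g-%d", strategy, f, r)),
                  taxa[sample.int(length(taxa), n_rm, prob = w)])
      }
      kr <- knockout_retention(content, counts, catalog, rm_taxa,
                               baseline = base, ctx = ctx)
      tibble(fraction = f, rep = r, retention = kr$retention)
    })
  })
  out <- reps |>
    group_by(.data$fraction) |>
    summarise(mean_retention = mean(.data$retention),
              sd_retention = if (dplyr::n() > 1) sd(.data$retention) else 0,
              n_reps = dplyr::n(), .groups = "drop") |>
    mutate(strategy = strategy, .after = "fraction")
  attr(out, "replicates") <- reps
  class(out) <- c("buffering_curve", class(out))
  out
}
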