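# Hill-number alpha diversity: richness (q = 0), Hill-Shannon (q = 1),
# Hill-Simpson (q = 2), and any real order q >= 0.

#' Hill diversity of a relative-abundance vector
#'
#' Computes D(q) = (sum p_i^q)^(1/(1-q)) in effective numbers of taxa. The
#' special cases are richness at q = 0, the exponential of Shannon entropy in
#' the q -> 1 limit (used whenever |q - 1| < 1e-9), and inverse Simpson
#' concentration at q = 2. Zeros are dropped and the vector renormalized
#' before evaluation.
#'
#' @param p Non-negative relative-abundance vector summing to 1 (within
#'   1e-9; counts can be passed through [relative_abundance()] first).
#' @param q Hill order(s), real and >= 0; vectorized.
#' @return Numeric vector of effective taxon numbers, one per `q`.
#' @examples
#' hill_diversity(c(0.5, 0.25, 0.25), q = c(0, 1, 2))
#' @export
hill_diversity <- function(p, q) {
  if (length(p) == 0 || all(p == 0)) abort("empty or all-zero abundance vector")
  if (any(p < 0)) abort("relative abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) {
    abort("abundances must sum to 1; use relative_abundance() on counts first")
  }
  if (any(q < 0)) abort("Hill order q must be >= 0")
  p <- p[p > 0]
  p <- p / sum(p)
  vapply(q, function(qi) {
    if (abs(qi - 1) < 1e-9) {
      exp(-sum(p * log(p)))
    } else {
      sum(p^qi)^(1 / (1 - qi))
    }
  }, numeric(1))
}

#' Per-sample Hill diversity for a count table
#'
#' @param counts Count table (first column `taxon`).
#' @param q Hill orders to evaluate.
#' @return Tidy tibble: sample_id, q, D.
#' @export
sample_diversity <- function(counts, q = c(0, 1, 2)) {
  assert_id_table(counts)
  m <- table_to_matrix(counts)
  purrr::map_dfr(colnames(m), function(s) {
    tibble(sample_id = s, q = q,
           D = hill_diversity(m[, s] / sum(m[, s]), q))
  })
}

#' Summarise Hill diversity by treatment and week
#'
#' Computes per-sample Hill diversity at each requested order and aggregates
#' to group means with standard deviations (plotted as two-standard-deviation
#' error bars by [autoplot.diversity_summary()]). Groups with a single sample
#' report `sd_D = 0` and are identifiable by `n = 1`.
#'
#' @param counts Count table (first column `taxon`).
#' @param metadata Tibble with columns sample_id, individual, week, treatment.
#' @param q Hill orders to evaluate (default 0, 1, 2).
#' @return A `diversity_summary` tibble: treatment, week, q, mean_D, sd_D, n.
#' @examples
#' sim <- simulate_community(scenario_config(n_taxa = 15, n_pathways = 10,
#'   n_obligate = 2, variant_class_count = 2, n_individuals_per_treatment = 2,
#'   n_weeks = 2, seed = 3))
#' diversity_summary(sim$counts, sim$metadata)
#' @export
diversity_summary <- function(counts, metadata, q = c(0, 1, 2)) {
  per_sample <- sample_diversity(counts, q)
  out <- per_sample |>
    inner_join(metadata, by = "sample_id") |>
    group_by(.data$treatment, .data$week, .data$q) |>
    summarise(mean_D = mean(.data$D),
              sd_D = if (dplyr::n() > 1) sd(.data$D) else 0,
              n = dplyr::n(), .groups = "drop")
  class(out) <- c("diversity_summary", class(out))
  out
}
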