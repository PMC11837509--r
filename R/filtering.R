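# Sample- and phylotype-level quality filters and relative abundances.

#' Configure quality-filter thresholds
#'
#' @param min_reads_per_sample Samples with fewer reads than this are
#'   excluded (strictly fewer; the default keeps samples at exactly 5,000).
#' @param max_amplicons Phylotype exclusion bound on per-sample counts.
#' @param max_occupied_samples Phylotype exclusion bound on occupancy. A
#'   phylotype is excluded iff it occurs in at most `max_occupied_samples`
#'   samples AND every one of its nonzero counts is at most `max_amplicons`.
#' @param nsti_max Taxa with a nearest-sequenced-taxon-index annotation above
#'   this are dropped from genome-content tables; applied only when NSTI
#'   annotations are supplied.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_reads_per_sample = 5000,
                          max_amplicons = 10,
                          max_occupied_samples = 10,
                          nsti_max = 2.0) {
  cfg <- list(min_reads_per_sample = min_reads_per_sample,
              max_amplicons = max_amplicons,
              max_occupied_samples = max_occupied_samples,
              nsti_max = nsti_max)
  if (any(unlist(cfg) < 0)) abort("filter thresholds must be >= 0")
  structure(cfg, class = "filter_config")
}

#' Exclude low-depth samples
#'
#' Removes samples whose total read count is strictly below
#' `cfg$min_reads_per_sample`. The exclusion report (sample id, reason, read
#' total) is attached as an attribute; retrieve it with [exclusions()].
#'
#' @param counts Count table: tibble with first column `taxon` and one
#'   numeric column per sample.
#' @param cfg A [filter_config()].
#' @return The retained count table (same shape, fewer columns), with an
#'   `exclusions` attribute.
#' @examples
#' x <- tibble::tibble(taxon = c("a", "b"), s1 = c(2000L, 2999L),
#'                     s2 = c(4000L, 1000L))
#' filtered <- filter_samples(x, filter_config())
#' exclusions(filtered)
#' @export
filter_samples <- function(counts, cfg = filter_config()) {
  assert_id_table(counts)
  m <- table_to_matrix(counts)
  depth <- colSums(m)
  drop <- depth < cfg$min_reads_per_sample
  out <- counts[, c(TRUE, !drop), drop = FALSE]
  if (all(drop) && length(drop) > 0) {
    warn("all samples excluded by the read-depth filter")
  }
  attr(out, "exclusions") <- tibble(
    id = colnames(m)[drop],
    reason = "reads below minimum",
    statistic = unname(depth[drop])
  )
  out
}

#' Exclude rare, low-occupancy phylotypes
#'
#' A phylotype is excluded iff it occurs (nonzero count) in at most
#' `cfg$max_occupied_samples` samples AND every nonzero count is at most
#' `cfg$max_amplicons`; a single high count or wide occupancy retains it.
#' Run after [filter_samples()] so occupancy is computed on retained samples
#' only.
#'
#' @inheritParams filter_samples
#' @return The retained count table with an `exclusions` attribute
#'   (statistic = number of occupied samples).
#' @export
filter_phylotypes <- function(counts, cfg = filter_config()) {
  assert_id_table(counts)
  m <- table_to_matrix(counts)
  if (ncol(m) == 0) return(counts)
  occupancy <- rowSums(m > 0)
  max_count <- apply(m, 1, max)
  drop <- occupancy <= cfg$max_occupied_samples & max_count <= cfg$max_amplicons
  out <- counts[!drop, , drop = FALSE]
  attr(out, "exclusions") <- tibble(
    id = counts$taxon[drop],
    reason = "low abundance and occupancy",
    statistic = unname(occupancy[drop])
  )
  out
}

#' Drop taxa with unreliable genome-content predictions
#'
#' Pass-through filter on supplied per-taxon NSTI annotations: taxa whose
#' nearest-sequenced-taxon index exceeds `cfg$nsti_max` are removed from the
#' genome-content table. If no `nsti` column is supplied the table is
#' returned unchanged with a message.
#'
#' @param content Genome-content table (first column `taxon`, EC columns).
#' @param annotations Optional tibble with columns `taxon` and `nsti`.
#' @param cfg A [filter_config()].
#' @return The retained content table with an `exclusions` attribute.
#' @export
filter_nsti <- function(content, annotations = NULL, cfg = filter_config()) {
  assert_id_table(content, what = "genome-content table")
  if (is.null(annotations) || !"nsti" %in% names(annotations)) {
    inform("no NSTI annotations supplied; NSTI filter skipped")
    return(content)
  }
  ann <- annotations[match(content$taxon, annotations$taxon), ]
  drop <- !is.na(ann$nsti) & ann$nsti > cfg$nsti_max
  out <- content[!drop, , drop = FALSE]
  attr(out, "exclusions") <- tibble(
    id = content$taxon[drop],
    reason = "NSTI above maximum",
    statistic = ann$nsti[drop]
  )
  out
}

#' Convert counts to per-sample relative abundances
#'
#' @inheritParams filter_samples
#' @return A tibble of the same shape whose sample columns each sum to 1.
#' @examples
#' x <- tibble::tibble(taxon = c("a", "b", "c"), s1 = c(2, 2, 4))
#' relative_abundance(x)
#' @export
relative_abundance <- function(counts) {
  assert_id_table(counts)
  m <- table_to_matrix(counts)
  depth <- colSums(m)
  if (any(depth == 0)) {
    abort(sprintf("zero-depth sample(s): %s",
                  paste(colnames(m)[depth == 0], collapse = ", ")))
  }
  matrix_to_table(sweep(m, 2, depth, "/"), "taxon")
}
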