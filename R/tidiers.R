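# broom-style tidiers for the test-result objects.

#' Tidy a PERMANOVA result
#'
#' @param x A `permanova_result`.
#' @param ... Unused.
#' @return One-row-per-term tibble: term, df, sum_of_squares, statistic,
#'   p.value.
#' @method tidy permanova_result
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble(term = c("among groups", "within groups", "total"),
         df = c(x$df_among, x$df_within, x$df_among + x$df_within),
         sum_of_squares = c(x$ss_among, x$ss_within, x$ss_total),
         statistic = c(x$pseudo_F, NA_real_, NA_real_),
         p.value = c(x$p, NA_real_, NA_real_))
}

#' @rdname tidy.permanova_result
#' @method glance permanova_result
#' @export
glance.permanova_result <- function(x, ...) {
  tibble(statistic = x$pseudo_F, df_among = x$df_among,
         df_within = x$df_within, p.value = x$p, n_perm = x$n_perm,
         scheme = x$scheme, exhaustive = x$exhaustive)
}

#' Tidy a dispersion-test result
#'
#' @param x A `dispersion_result`.
#' @param ... Unused.
#' @return Per-sample tibble of distances to the group centroid.
#' @method tidy dispersion_result
#' @export
tidy.dispersion_result <- function(x, ...) x$distances

#' @rdname tidy.dispersion_result
#' @method glance dispersion_result
#' @export
glance.dispersion_result <- function(x, ...) {
  tibble(statistic = x$F_disp, df_among = x$df_among,
         df_within = x$df_within, p.value = x$p, n_perm = x$n_perm,
         correction = x$correction)
}

#' Tidy a capacity profile
#'
#' @param x A `capacity_profile`.
#' @param ... Unused.
#' @return Tibble: pathway, class ("per_taxon" or "obligately_shared"),
#'   abundance.
#' @method tidy capacity_profile
#' @export
tidy.capacity_profile <- function(x, ...) {
  tibble(pathway = x$total,
         class = ifelse(x$total %in% x$per_taxon, "per_taxon",
                        "obligately_shared")) |>
    left_join(x$pathway_abundance, by = "pathway")
}

#' @rdname tidy.capacity_profile
#' @method glance capacity_profile
#' @export
glance.capacity_profile <- function(x, ...) {
  tibble(scope = x$scope, n_total = length(x$total),
         n_per_taxon = length(x$per_taxon),
         n_obligately_shared = length(x$obligately_shared),
         cover_mode = x$cover_mode)
}

#' Tidy a fate matrix
#'
#' @param x A `fate_matrix`.
#' @param ... Unused.
#' @return The pathway-level fate tibble; family-level cells are in
#'   `x$family`.
#' @method tidy fate_matrix
#' @export
tidy.fate_matrix <- function(x, ...) x$pathway

#' @rdname tidy.fate_matrix
#' @method glance fate_matrix
#' @export
glance.fate_matrix <- function(x, ...) {
  counts <- table(factor(x$pathway$fate,
                         levels = c("retained", "never", "gained", "lost")))
  tibble(retained = counts[["retained"]], never = counts[["never"]],
         gained = counts[["gained"]], lost = counts[["lost"]],
         baseline_window = x$baseline_window %||% NA_character_,
         end_window = x$end_window %||% NA_character_)
}
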