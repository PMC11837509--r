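# Shared fixtures: small scenario configurations and hand-built communities.

# A small but fully featured scenario for fast end-to-end tests; any
# scenario_config() argument can be overridden through `...`.
small_scenario <- function(seed = 1, ...) {
  defaults <- list(n_taxa = 24, n_phyla = 5, n_pathways = 30, n_obligate = 5,
                   variant_class_count = 3, n_individuals_per_treatment = 3,
                   n_weeks = 4, depth_mean = 5000,
                   redundancy_support = c(2L, 8L),
                   treatments = c("balanced", "perturbed"),
                   seed = seed)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

# Hand-built community: pathway P1 needs {e1, e2} and is split across taxa
# A (e1) and B (e2); P2 needs {e3} carried by both A and C; P3 needs
# {e4, e5} fully carried by C only.
toy_content <- function() {
  tibble::tibble(taxon = c("A", "B", "C"),
                 e1 = c(1, 0, 0), e2 = c(0, 1, 0),
                 e3 = c(1, 0, 1), e4 = c(0, 0, 1), e5 = c(0, 0, 1))
}

toy_catalog <- function() {
  tibble::tibble(pathway = c("P1", "P2", "P3"),
                 ecs = list(c("e1", "e2"), "e3", c("e4", "e5")),
                 variant_class = c("V1", "V1", NA))
}

toy_counts <- function(a = 10L, b = 10L, c = 10L, sample = "s1") {
  out <- tibble::tibble(taxon = c("A", "B", "C"))
  out[[sample]] <- c(a, b, c)
  out
}

# Random simplex point (relative-abundance vector).
random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}
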