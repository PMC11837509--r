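make_presence <- function(...) {
  # presence tibble from named lists sample -> pathways
  args <- list(...)
  purrr::map_dfr(names(args), function(s) {
    tibble::tibble(sample_id = s, pathway = args[[s]])
  })
}

test_that("prevalence calls use an inclusive 25 percent threshold", {
  win <- tibble::tibble(window = "b.w1", treatment = "b",
                        sample_id = paste0("s", 1:4))
  pres <- make_presence(s1 = "P1", s2 = c("P1", "P2"), s3 = "P1", s4 = "P1")
  out <- prevalence_calls(pres, win, threshold = 0.25,
                          pathways = c("P1", "P2", "P3"))
  expect_equal(nrow(out), 3)
  # exactly 1 of 4 samples -> prevalence 0.25 -> present (boundary)
  expect_equal(out$prevalence[out$pathway == "P2"], 0.25)
  expect_true(out$present[out$pathway == "P2"])
  # never detected -> absent
  expect_equal(out$prevalence[out$pathway == "P3"], 0)
  expect_false(out$present[out$pathway == "P3"])
  # detected everywhere -> present at any threshold <= 1
  expect_true(all(prevalence_calls(pres, win, threshold = 1,
                                   pathways = "P1")$present))
  # empty windows are an error naming the window
  expect_error(prevalence_calls(pres, win[0, ]), "no windows")
})

test_that("fate classification distinguishes the four states", {
  win <- tibble::tibble(window = rep(c("b.base", "b.end"), each = 2),
                        treatment = "b",
                        sample_id = c("s1", "s2", "s3", "s4"))
  pres <- make_presence(s1 = c("P1", "P3"), s2 = c("P1", "P3"),
                        s3 = c("P1", "P4"), s4 = c("P1", "P4"))
  calls <- prevalence_calls(pres, win, pathways = paste0("P", 1:4))
  fm <- fate_classification(calls[calls$window == "b.base", ],
                            calls[calls$window == "b.end", ])
  fate <- tibble::deframe(fm$pathway[, c("pathway", "fate")])
  expect_equal(fate[["P1"]], "retained")
  expect_equal(fate[["P2"]], "never")
  expect_equal(fate[["P3"]], "lost")
  expect_equal(fate[["P4"]], "gained")
  # identical windows -> only retained/never
  fm2 <- fate_classification(calls[calls$window == "b.base", ],
                             calls[calls$window == "b.base", ])
  expect_setequal(unique(fm2$pathway$fate), c("retained", "never"))
  # mismatched universes are rejected
  expect_error(fate_classification(calls[calls$window == "b.base", ],
                                   calls[calls$window == "b.end" &
                                           calls$pathway != "P1", ]),
               "universes")
})

test_that("family-level loss can coexist with pathway-level retention", {
  # Families X and Y both complete P1 alone at baseline; X vanishes from the
  # end window but Y persists: X's cell is "lost", the pathway is retained.
  win <- tibble::tibble(window = rep(c("t.base", "t.end"), each = 2),
                        treatment = "t",
                        sample_id = c("s1", "s2", "s3", "s4"))
  pres <- make_presence(s1 = "P1", s2 = "P1", s3 = "P1", s4 = "P1")
  inc <- dplyr::bind_rows(
    tibble::tibble(sample_id = c("s1", "s2"), taxon = "X", pathway = "P1"),
    tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"), taxon = "Y",
                   pathway = "P1"))
  calls <- prevalence_calls(pres, win, pathways = "P1")
  fm <- fate_classification(calls[calls$window == "t.base", ],
                            calls[calls$window == "t.end", ],
                            incidence = inc, windows = win,
                            baseline_window = "t.base", end_window = "t.end")
  expect_equal(fm$pathway$fate, "retained")
  fam <- tibble::deframe(fm$family[, c("taxon", "fate")])
  expect_equal(fam[["X"]], "lost")
  expect_equal(fam[["Y"]], "retained")
})

test_that("a family removed from the end window loses all its pathways", {
  win <- tibble::tibble(window = rep(c("t.base", "t.end"), each = 2),
                        treatment = "t",
                        sample_id = c("s1", "s2", "s3", "s4"))
  pres <- make_presence(s1 = c("P1", "P2"), s2 = c("P1", "P2"),
                        s3 = "P9", s4 = "P9")
  inc <- tibble::tibble(sample_id = rep(c("s1", "s2"), each = 2),
                        taxon = "X", pathway = rep(c("P1", "P2"), 2))
  calls <- prevalence_calls(pres, win, pathways = c("P1", "P2", "P9"))
  fm <- fate_classification(calls[calls$window == "t.base", ],
                            calls[calls$window == "t.end", ],
                            incidence = inc, windows = win,
                            baseline_window = "t.base", end_window = "t.end")
  x_cells <- fm$family[fm$family$taxon == "X", ]
  expect_equal(nrow(x_cells), 2)
  expect_true(all(x_cells$fate == "lost"))
})

test_that("prevalence and fates are pure functions", {
  sim <- simulate_community(small_scenario(seed = 31))
  caps <- capacity_by_sample(sim$content, sim$counts, sim$catalog)
  win <- window_spec(sim$metadata, list(base = 1:2, end = 3:4))
  a <- prevalence_calls(caps$presence, win, pathways = sim$catalog$pathway)
  b <- prevalence_calls(caps$presence, win, pathways = sim$catalog$pathway)
  expect_identical(a, b)
  fa <- fate_classification(a[a$window == "balanced.base", ],
                            a[a$window == "balanced.end", ])
  fb <- fate_classification(b[b$window == "balanced.base", ],
                            b[b$window == "balanced.end", ])
  expect_identical(fa$pathway, fb$pathway)
})

test_that("redundancy distribution counts completing families", {
  # every pathway completed by exactly two families -> singleton fraction 0
  inc <- tibble::tibble(taxon = rep(c("X", "Y"), 3),
                        pathway = rep(paste0("P", 1:3), each = 2))
  rd <- redundancy_distribution(inc)
  expect_equal(rd$singleton_fraction, 0)
  expect_equal(rd$histogram$n_families, 2L)
  expect_equal(rd$histogram$n_pathways, 3L)
  # empty incidence -> empty histogram, no error
  rd0 <- redundancy_distribution(inc[0, ])
  expect_equal(nrow(rd0$histogram), 0)
  expect_true(is.na(rd0$singleton_fraction))
})

test_that("planted singleton fraction is recovered exactly from the profile", {
  for (seed in c(2, 7)) {
    g <- generate_genome_content(scenario_config(seed = seed))
    all_present <- tibble::tibble(taxon = g$content$taxon,
                                  s1 = rep(10L, nrow(g$content)))
    prof <- community_capacity(g$content, all_present, g$catalog)
    rd <- redundancy_distribution(prof$incidence)
    planted <- mean(lengths(g$truth$carriers[g$truth$per_taxon_pathways]) == 1)
    expect_equal(rd$singleton_fraction, planted)
    expect_equal(nrow(rd$per_pathway), length(g$truth$per_taxon_pathways))
  }
})

test_that("knockout retention follows the planted redundancy", {
  content <- toy_content()
  catalog <- toy_catalog()
  counts <- toy_counts(10, 10, 10)
  # removing nothing retains everything
  expect_equal(knockout_retention(content, counts, catalog,
                                  character(0))$retention, 1)
  # removing the sole carrier of P3 (taxon C) loses P3 (and e3 survives via A)
  kr <- knockout_retention(content, counts, catalog, "C")
  expect_true("P3" %in% kr$lost$pathway)
  expect_equal(kr$lost$former_redundancy[kr$lost$pathway == "P3"], 1L)
  expect_true("P2" %in% kr$after_total)  # redundancy-2 pathway survives
  # unknown taxon is rejected
  expect_error(knockout_retention(content, counts, catalog, "Z"), "Z")
  # removing everything: retention 0 with warning
  expect_warning(
    kr0 <- knockout_retention(content, counts, catalog, c("A", "B", "C")),
    "all taxa")
  expect_equal(kr0$retention, 0)
})

test_that("knockout retention is monotone in the removed set", {
  withr::with_seed(41, {
    g <- generate_genome_content(small_scenario(seed = 37))
    counts <- tibble::tibble(taxon = g$content$taxon,
                             s1 = rpois(nrow(g$content), 20) + 1L)
    for (i in 1:10) {
      a <- sample(g$content$taxon, 5)
      b <- union(a, sample(setdiff(g$content$taxon, a), 5))
      ra <- knockout_retention(g$content, counts, g$catalog, a)$retention
      rb <- knockout_retention(g$content, counts, g$catalog, b)$retention
      expect_lte(rb, ra)
    }
  })
})

test_that("no single knockout loses a pathway with redundancy >= 2", {
  g <- generate_genome_content(small_scenario(seed = 43, n_taxa = 20,
                                              n_phyla = 4))
  counts <- tibble::tibble(taxon = g$content$taxon,
                           s1 = rep(50L, nrow(g$content)))
  base <- community_capacity(g$content, counts, g$catalog)
  red <- table(base$incidence$pathway)
  protected <- names(red)[red >= 2]
  for (tx in g$content$taxon) {  # exhaustive single-knockout sweep
    kr <- knockout_retention(g$content, counts, g$catalog, tx,
                             baseline = base)
    expect_length(intersect(kr$lost$pathway, protected), 0)
  }
})

test_that("buffering curves start at 1 and decline monotonically", {
  sim <- simulate_community(small_scenario(seed = 47))
  bc <- buffering_curve(sim$content, sim$counts, sim$catalog,
                        fractions = c(0, 0.2, 0.5, 0.8),
                        strategy = "random", n_reps = 8, seed = 3)
  expect_equal(bc$mean_retention[bc$fraction == 0], 1)
  expect_true(all(diff(bc$mean_retention) <= 0.02))  # within Monte-Carlo error
  # determinism
  bc2 <- buffering_curve(sim$content, sim$counts, sim$catalog,
                         fractions = c(0, 0.2, 0.5, 0.8),
                         strategy = "random", n_reps = 8, seed = 3)
  expect_identical(as.data.frame(bc), as.data.frame(bc2))
  expect_error(buffering_curve(sim$content, sim$counts, sim$catalog,
                               n_reps = 0), "n_reps")
  expect_error(buffering_curve(sim$content, sim$counts, sim$catalog,
                               fractions = 1), "fractions")
})

test_that("abundance-biased removal hurts capacity more than rarity-biased", {
  sim <- simulate_community(scenario_config(
    seed = 51, n_weeks = 2, n_individuals_per_treatment = 3))
  rar <- buffering_curve(sim$content, sim$counts, sim$catalog,
                         fractions = 0.3, strategy = "rarity_biased",
                         n_reps = 10, seed = 5)
  abn <- buffering_curve(sim$content, sim$counts, sim$catalog,
                         fractions = 0.3, strategy = "abundance_biased",
                         n_reps = 10, seed = 5)
  expect_lt(abn$mean_retention, rar$mean_retention)
})
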