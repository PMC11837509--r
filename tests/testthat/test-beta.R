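euclid_dist_table <- function(pts) {
  # tibble "count table" whose Bray-Curtis is irrelevant; used to build
  # labelled Euclidean distance matrices directly
  d <- as.matrix(stats::dist(pts))
  rownames(d) <- colnames(d) <- sprintf("s%d", seq_len(nrow(pts)))
  d
}

test_that("Bray-Curtis and Sorensen hit their closed-form anchors", {
  x <- tibble::tibble(taxon = c("a", "b", "c"),
                      s1 = c(1, 1, 0), s2 = c(0, 1, 1))
  expect_equal(as.numeric(bray_curtis(x)), 0.5)
  expect_equal(as.numeric(sorensen(x)), 0.5)

  same <- tibble::tibble(taxon = c("a", "b"), s1 = c(3, 7), s2 = c(30, 70))
  expect_equal(as.numeric(bray_curtis(same)), 0)  # depth-invariant
  expect_equal(as.numeric(sorensen(same)), 0)

  disj <- tibble::tibble(taxon = c("a", "b"), s1 = c(5, 0), s2 = c(0, 5))
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  expect_equal(as.numeric(sorensen(disj)), 1)

  zero <- tibble::tibble(taxon = "a", s1 = 1L, s2 = 0L)
  expect_error(bray_curtis(zero), "s2")
  expect_error(sorensen(zero), "s2")
})

test_that("NMDS embeds collinear points with near-zero stress", {
  pts <- cbind(seq(0, 10, length.out = 8), 0)
  fit <- nmds_ordination(euclid_dist_table(pts), k = 2, n_starts = 20, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_equal(dim(fit$points), c(8L, 3L))
})

test_that("NMDS separates planted clusters", {
  withr::with_seed(3, {
    pts <- rbind(matrix(rnorm(6, 0, 0.05), 3),
                 matrix(rnorm(6, 5, 0.05), 3))
  })
  fit <- nmds_ordination(euclid_dist_table(pts), k = 2, n_starts = 20, seed = 2)
  xy <- as.matrix(fit$points[, -1])
  dd <- as.matrix(stats::dist(xy))
  within <- c(dd[1:3, 1:3][lower.tri(diag(3))], dd[4:6, 4:6][lower.tri(diag(3))])
  between <- as.vector(dd[1:3, 4:6])
  expect_gt(min(between), max(within))
})

test_that("degenerate dissimilarities trigger a warning", {
  d <- matrix(0.5, 4, 4); diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  expect_warning(nmds_ordination(d, n_starts = 3, seed = 1), "degenerate")
})

test_that("planted two-group fixture gives the exact enumeration p-value", {
  # two tight groups far apart: observed labeling and its mirror uniquely
  # maximise pseudo-F among the 20 balanced relabelings -> p = 2/20
  withr::with_seed(11, {
    pts <- rbind(matrix(rnorm(6, 0, 0.1), 3), matrix(rnorm(6, 20, 0.1), 3))
  })
  d <- euclid_dist_table(pts)
  g <- rep(c("A", "B"), each = 3)
  fit <- permanova(d, g, scheme = "free", exhaustive = TRUE)
  expect_equal(fit$p, 2 / 20)
  expect_equal(fit$df_among, 1L)
  expect_equal(fit$df_within, 4L)
})

test_that("exhaustive PERMANOVA equals the brute-force oracle", {
  withr::with_seed(5, {
    fixtures <- list(
      list(n = 6, g = rep(c("A", "B"), each = 3), blocks = NULL),
      list(n = 7, g = c("A", "A", "A", "B", "B", "B", "B"), blocks = NULL),
      list(n = 8, g = rep(c("A", "B"), each = 4),
           blocks = rep(c("i1", "i2", "i3", "i4"), each = 2))
    )
    for (fx in fixtures) {
      pts <- matrix(rnorm(fx$n * 2), fx$n)
      d <- euclid_dist_table(pts)
      if (is.null(fx$blocks)) {
        fit <- permanova(d, fx$g, scheme = "free", exhaustive = TRUE)
        expect_equal(fit$p, oracle_permanova_free(d, fx$g))
      } else {
        fit <- permanova(d, fx$g, blocks = fx$blocks, scheme = "blocks",
                         exhaustive = TRUE)
        expect_equal(fit$p, oracle_permanova_blocks(d, fx$g, fx$blocks))
      }
      expect_equal(fit$pseudo_F, oracle_pseudo_f(d, fx$g), tolerance = 1e-12)
    }
  })
})

test_that("pseudo-F matches vegan::adonis2 and ignores sample order", {
  withr::with_seed(9, {
    x <- tibble::as_tibble(cbind(
      data.frame(taxon = sprintf("t%02d", 1:12)),
      matrix(rpois(12 * 10, 40), 12, dimnames = list(NULL, sprintf("s%d", 1:10)))))
  })
  d <- bray_curtis(x)
  g <- rep(c("A", "B"), each = 5)
  fit <- permanova(d, g, scheme = "free", n_perm = 99, seed = 1)
  ad <- vegan::adonis2(d ~ g, permutations = 19)
  expect_equal(fit$pseudo_F, ad$F[1], tolerance = 1e-10)
  # relabeling sample order leaves the statistic unchanged
  ord <- sample(10)
  m <- as.matrix(d)[ord, ord]
  fit2 <- permanova(m, g[ord], scheme = "free", n_perm = 99, seed = 1)
  expect_equal(fit2$pseudo_F, fit$pseudo_F, tolerance = 1e-12)
})

test_that("PERMANOVA p-values are uniform under a true null", {
  withr::with_seed(21, {
    ps <- vapply(1:500, function(i) {
      pts <- matrix(rnorm(12), 6)
      g <- sample(rep(c("A", "B"), each = 3))
      permanova(euclid_dist_table(pts), g, scheme = "free",
                exhaustive = TRUE)$p
    }, numeric(1))
  })
  # the exact null is discrete: 20 balanced relabelings whose F values tie in
  # mirror pairs, so p lives on the 10 atoms 0.1, 0.2, ..., 1.0 with equal
  # probability; test uniformity over those atoms
  expect_equal(sort(unique(ps)), seq(0.1, 1, by = 0.1))
  counts <- table(factor(round(ps * 10), levels = 1:10))
  gof <- stats::chisq.test(counts, p = rep(0.1, 10))
  expect_gt(gof$p.value, 0.01)
  # validity at the attainable levels
  expect_lt(abs(mean(ps <= 0.1) - 0.1), 0.05)
  expect_lt(abs(mean(ps <= 0.5) - 0.5), 0.07)
})

test_that("PERMANOVA validates its design", {
  d <- euclid_dist_table(matrix(rnorm(12), 6))
  expect_error(permanova(d, rep("A", 6), scheme = "free"), "one group")
  expect_error(permanova(d, c("A", rep("B", 5)), scheme = "free"),
               "at least 2 samples")
  # blocks spanning groups are rejected under block exchange
  expect_error(
    permanova(d, rep(c("A", "B"), 3), blocks = rep(c("i1", "i2"), each = 3),
              scheme = "blocks"),
    "spanning")
  expect_error(permanova(d, rep(c("A", "B"), each = 3), scheme = "blocks"),
               "blocks")
})

test_that("restricted schemes are more conservative for clustered designs", {
  # samples within an individual are near-duplicates; block exchange must not
  # treat them as independent evidence
  withr::with_seed(33, {
    base <- matrix(rnorm(8, sd = 3), 4)
    pts <- base[rep(1:4, each = 3), ] + matrix(rnorm(24, sd = 0.05), 12)
  })
  d <- euclid_dist_table(pts)
  g <- rep(c("A", "B"), each = 6)
  blocks <- rep(sprintf("i%d", 1:4), each = 3)
  fit_block <- permanova(d, g, blocks = blocks, scheme = "blocks",
                         exhaustive = TRUE)
  # only 6 distinct block relabelings: attainable floor is 2/6
  expect_gte(fit_block$p, 2 / 6 - 1e-12)
  # within-block scheme exists and returns a valid p
  fit_within <- permanova(d, rep(c("A", "B"), 6), blocks = blocks,
                          scheme = "within", n_perm = 199, seed = 2)
  expect_true(fit_within$p >= 1 / 200 && fit_within$p <= 1)
})

test_that("dispersion test calls equal spread equal and unequal unequal", {
  # mirror-image groups: identical internal geometry
  withr::with_seed(13, { shape <- matrix(rnorm(16), 8) })
  pts <- rbind(shape, shape + 50)
  d <- euclid_dist_table(pts)
  g <- rep(c("A", "B"), each = 8)
  fit <- dispersion_test(d, g, n_perm = 499, seed = 1)
  expect_lt(fit$F_disp, 1e-10)
  expect_gt(fit$p, 0.9)
  # one group three times as dispersed
  pts2 <- rbind(shape, 3 * shape + 50)
  fit2 <- dispersion_test(euclid_dist_table(pts2), g, n_perm = 999, seed = 1)
  expect_lt(fit2$p, 0.05)
  expect_gt(fit2$F_disp, fit$F_disp)
})

test_that("dispersion distances round-trip Euclidean geometry", {
  withr::with_seed(17, { pts <- matrix(rnorm(30), 10) })
  g <- rep(c("A", "B"), each = 5)
  direct <- numeric(10)
  for (grp in c("A", "B")) {
    idx <- which(g == grp)
    ctr <- colMeans(pts[idx, ])
    direct[idx] <- sqrt(rowSums(sweep(pts[idx, ], 2, ctr)^2))
  }
  # raw PCoA on a Euclidean matrix is an isometry: exact round-trip
  fit0 <- dispersion_test(euclid_dist_table(pts), g, n_perm = 99, seed = 1,
                          correction = "none")
  expect_equal(fit0$distances$dist_to_centroid, direct, tolerance = 1e-8)
  # the Cailliez constant is numerically ~0 here, so the corrected embedding
  # agrees to slightly looser precision
  fit1 <- dispersion_test(euclid_dist_table(pts), g, n_perm = 99, seed = 1)
  expect_equal(fit1$distances$dist_to_centroid, direct, tolerance = 1e-6)
})

test_that("size-1 groups are flagged and contribute zero distance", {
  pts <- matrix(rnorm(10), 5)
  g <- c("A", "A", "A", "A", "B")
  expect_warning(fit <- dispersion_test(euclid_dist_table(pts), g,
                                        n_perm = 49, seed = 1), "size 1")
  expect_equal(fit$distances$dist_to_centroid[5], 0)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # rank-monotone and capped at 1
  withr::with_seed(2, { p <- runif(20) })
  adj <- bh_fdr(p)
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("tidiers expose PERMANOVA and dispersion results", {
  d <- euclid_dist_table(rbind(matrix(rnorm(6), 3), matrix(rnorm(6, 4), 3)))
  g <- rep(c("A", "B"), each = 3)
  fit <- permanova(d, g, scheme = "free", n_perm = 99, seed = 1)
  td <- generics::tidy(fit)
  expect_equal(td$df, c(1L, 4L, 5L))
  expect_equal(sum(td$sum_of_squares[1:2]), td$sum_of_squares[3])
  gl <- generics::glance(fit)
  expect_equal(gl$statistic, fit$pseudo_F)
  disp <- dispersion_test(d, g, n_perm = 49, seed = 1)
  expect_equal(nrow(generics::tidy(disp)), 6)
  expect_equal(generics::glance(disp)$p.value, disp$p)
})
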