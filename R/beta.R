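# Community dissimilarity and permutation statistics: Bray-Curtis and
# Sorensen distances, NMDS ordination, distance-based PERMANOVA with
# restricted permutation schemes for repeated-measures designs, and a
# multivariate homogeneity-of-dispersion test.

#' Bray-Curtis dissimilarity between samples
#'
#' Computes d_ij = sum|x_i - x_j| / sum(x_i + x_j) on per-sample relative
#' abundances (columns are converted with [relative_abundance()] first, so
#' sequencing depth does not enter).
#'
#' @param counts Count or proportion table (first column `taxon`, one column
#'   per sample).
#' @return A `dist` object with sample labels; entries in [0, 1].
#' @examples
#' x <- tibble::tibble(taxon = c("a", "b", "c"), s1 = c(1, 1, 0), s2 = c(0, 1, 1))
#' bray_curtis(x)
#' @export
bray_curtis <- function(counts) {
  rel <- relative_abundance(counts)
  vegan::vegdist(t(table_to_matrix(rel)), method = "bray")
}

#' Sorensen (presence-absence) dissimilarity between samples
#'
#' With a = number of shared taxa and b, c = taxa unique to each sample,
#' d_ij = (b + c) / (2a + b + c).
#'
#' @inheritParams bray_curtis
#' @return A `dist` object with sample labels; entries in [0, 1].
#' @export
sorensen <- function(counts) {
  assert_id_table(counts)
  m <- table_to_matrix(counts)
  if (any(colSums(m) == 0)) {
    abort(sprintf("zero-sum sample(s): %s",
                  paste(colnames(m)[colSums(m) == 0], collapse = ", ")))
  }
  vegan::vegdist(t(m), method = "bray", binary = TRUE)
}

# Coerce dist or square matrix to a validated square matrix with labels.
as_distmatrix <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) abort("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-12) abort("distance matrix must be symmetric")
  if (any(diag(m) != 0)) abort("distance matrix must have a zero diagonal")
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- sprintf("s%d", seq_len(nrow(m)))
  }
  m
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Best-of-`n_starts` NMDS minimising Kruskal stress-1, deterministic under
#' `seed`. A thin wrapper around [vegan::metaMDS()] returning tidy
#' coordinates.
#'
#' @param d A `dist` or square symmetric matrix of dissimilarities.
#' @param k Number of ordination dimensions.
#' @param n_starts Number of random starts.
#' @param seed Integer seed.
#' @return An `nmds_result` list: `points` (tibble sample_id, NMDS1..NMDSk),
#'   `stress`, `converged`.
#' @export
nmds_ordination <- function(d, k = 2, n_starts = 100, seed = 1L) {
  m <- as_distmatrix(d)
  if (nrow(m) < k + 1) abort("need at least k + 1 samples for a k-dim NMDS")
  off <- m[lower.tri(m)]
  if (length(unique(round(off, 12))) == 1) {
    warn("degenerate dissimilarity matrix: all off-diagonal entries equal")
  }
  fit <- with_seed(derive_seed(seed, "nmds"), {
    suppressWarnings(suppressMessages(
      vegan::metaMDS(stats::as.dist(m), k = k, try = n_starts,
                     trymax = n_starts, trace = 0, autotransform = FALSE,
                     wascores = FALSE)
    ))
  })
  pts <- as_tibble(fit$points, .name_repair = "minimal")
  names(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = bind_cols(tibble(sample_id = rownames(m)), pts),
                 stress = fit$stress,
                 converged = isTRUE(fit$converged) || fit$stress < 1e-3),
            class = "nmds_result")
}

# Distance-based one-way pseudo-F from a squared-distance decomposition:
# SS_total = (1/N) sum_{i<j} d_ij^2; SS_within = sum_g (1/n_g) sum_{i<j in g};
# F = (SS_among / (g - 1)) / (SS_within / (N - g)).
permanova_stat <- function(m2, groups) {
  n <- length(groups)
  ss_total <- sum(m2[lower.tri(m2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- m2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  g <- length(unique(groups))
  list(F = (ss_among / (g - 1)) / (ss_within / (n - g)),
       ss_total = ss_total, ss_among = ss_among, ss_within = ss_within,
       df_among = g - 1L, df_within = n - g)
}

# All distinct permutations of a label multiset (columns of the result).
multiset_permutations <- function(labels) {
  rec <- function(lab) {
    if (length(lab) <= 1) return(list(lab))
    out <- list()
    for (u in unique(lab)) {
      rest <- lab[-match(u, lab)]
      out <- c(out, lapply(rec(rest), function(r) c(u, r)))
    }
    out
  }
  do.call(cbind, rec(labels))
}

#' Distance-based PERMANOVA with restricted permutations
#'
#' One-way permutational multivariate analysis of variance on a dissimilarity
#' matrix, with permutation schemes for repeated-measures designs:
#'
#' * `"blocks"` (default): individuals (blocks) are the exchangeable units;
#'   each block's samples move together when group labels are permuted
#'   across blocks. This is the scheme for a between-individual factor such
#'   as diet treatment, and it requires blocks to be nested in groups.
#' * `"within"`: labels are permuted independently within each block (for
#'   within-individual factors).
#' * `"free"`: unrestricted label permutation.
#'
#' With `exhaustive = TRUE` every allowed relabelling is enumerated and the
#' p-value is the exact proportion with a permuted pseudo-F at least the
#' observed (the identity relabelling included); otherwise `n_perm` random
#' permutations are drawn and the observed statistic is counted into the
#' null set (p = (m + 1) / (n_perm + 1)).
#'
#' @param d `dist` or square symmetric dissimilarity matrix.
#' @param groups Group label per sample (e.g. treatment).
#' @param blocks Block id per sample (e.g. individual); required for the
#'   restricted schemes.
#' @param n_perm Number of random permutations.
#' @param scheme Permutation restriction: "blocks", "within", or "free".
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive Enumerate all allowed relabellings (schemes "blocks" and
#'   "free" only) instead of sampling.
#' @return A `permanova_result`: pseudo_F, df_among, df_within, p, n_perm,
#'   scheme, sums of squares.
#' @examples
#' x <- tibble::tibble(taxon = c("a", "b"),
#'   s1 = c(9, 1), s2 = c(8, 2), s3 = c(1, 9), s4 = c(2, 8))
#' d <- bray_curtis(x)
#' permanova(d, groups = c("A", "A", "B", "B"), scheme = "free",
#'           exhaustive = TRUE)
#' @export
permanova <- function(d, groups, blocks = NULL, n_perm = 999,
                      scheme = c("blocks", "within", "free"), seed = 1L,
                      exhaustive = FALSE) {
  scheme <- match.arg(scheme)
  m <- as_distmatrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) abort("one group label per sample required")
  if (length(unique(groups)) < 2) {
    abort("all samples share one group label: no among-group contrast")
  }
  if (any(table(groups) < 2)) abort("every group needs at least 2 samples")
  if (scheme != "free") {
    if (is.null(blocks)) abort(sprintf("scheme '%s' requires blocks", scheme))
    blocks <- as.character(blocks)
    if (length(blocks) != nrow(m)) abort("one block id per sample required")
  }
  if (scheme == "blocks") {
    span <- tapply(groups, blocks, function(g) length(unique(g)))
    if (any(span > 1)) {
      abort(sprintf("block(s) spanning several groups under the block-exchange scheme: %s",
                    paste(names(span)[span > 1], collapse = ", ")))
    }
  }

  m2 <- m^2
  obs <- permanova_stat(m2, groups)

  perm_groups <- switch(scheme,
    free = function() sample(groups),
    blocks = {
      blk <- unique(blocks)
      blk_group <- vapply(blk, function(b) groups[match(b, blocks)], character(1))
      function() {
        permuted <- sample(blk_group)
        permuted[match(blocks, blk)]
      }
    },
    within = function() {
      out <- groups
      for (b in unique(blocks)) {
        idx <- which(blocks == b)
        out[idx] <- sample(groups[idx])
      }
      out
    }
  )

  if (exhaustive) {
    if (scheme == "within") {
      abort("exhaustive enumeration is available for schemes 'free' and 'blocks'")
    }
    if (scheme == "free") {
      perms <- multiset_permutations(groups)
      f_perm <- apply(perms, 2, function(g) permanova_stat(m2, g)$F)
    } else {
      blk <- unique(blocks)
      blk_group <- vapply(blk, function(b) groups[match(b, blocks)], character(1))
      perms <- multiset_permutations(blk_group)
      f_perm <- apply(perms, 2, function(bg) {
        permanova_stat(m2, bg[match(blocks, blk)])$F
      })
    }
    p <- mean(f_perm >= obs$F - 1e-12)
    n_used <- length(f_perm)
  } else {
    f_perm <- with_seed(derive_seed(seed, "permanova"), {
      vapply(seq_len(n_perm), function(i) permanova_stat(m2, perm_groups())$F,
             numeric(1))
    })
    p <- (sum(f_perm >= obs$F - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }

  structure(list(pseudo_F = obs$F, df_among = obs$df_among,
                 df_within = obs$df_within, p = p, n_perm = n_used,
                 scheme = scheme, exhaustive = exhaustive,
                 ss_among = obs$ss_among, ss_within = obs$ss_within,
                 ss_total = obs$ss_total),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("Distance-based PERMANOVA\n")
  cat(sprintf("  pseudo-F(%d, %d) = %.4f, p = %.4g (%s%s, %d permutations)\n",
              x$df_among, x$df_within, x$pseudo_F, x$p, x$scheme,
              if (x$exhaustive) ", exhaustive" else "", x$n_perm))
  invisible(x)
}

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the dissimilarity matrix by principal coordinates (Cailliez
#' additive correction for negative eigenvalues by default), computes each
#' sample's Euclidean distance to its group centroid, and tests equality of
#' mean dispersion across groups with a one-way ANOVA F whose null
#' distribution comes from permuting group labels. Size-1 groups contribute
#' a zero distance and are flagged with a warning.
#'
#' @param d `dist` or square symmetric dissimilarity matrix.
#' @param groups Group label per sample.
#' @param n_perm Number of permutations (default 9,999).
#' @param seed Integer seed.
#' @param correction Negative-eigenvalue handling: "cailliez" (additive
#'   constant) or "none" (drop negative-eigenvalue axes).
#' @return A `dispersion_result`: `distances` (tibble sample_id, group,
#'   dist_to_centroid), F_disp, df, p, n_perm.
#' @export
dispersion_test <- function(d, groups, n_perm = 9999, seed = 1L,
                            correction = c("cailliez", "none")) {
  correction <- match.arg(correction)
  m <- as_distmatrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) abort("one group label per sample required")
  if (length(unique(groups)) < 2) abort("need at least 2 groups")
  if (any(table(groups) == 1)) {
    warn("group(s) of size 1: their distance to centroid is 0 by definition")
  }
  n <- nrow(m)
  pts <- suppressWarnings(
    cmdscale(stats::as.dist(m), k = n - 1, add = (correction == "cailliez"))
  )
  if (is.list(pts)) pts <- pts$points
  dists <- numeric(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ctr <- colMeans(pts[idx, , drop = FALSE])
    dists[idx] <- sqrt(rowSums(sweep(pts[idx, , drop = FALSE], 2, ctr)^2))
  }

  anova_f <- function(y, lab) {
    gm <- mean(y)
    ssb <- sum(tapply(y, lab, function(v) length(v) * (mean(v) - gm)^2))
    ssw <- sum(tapply(y, lab, function(v) sum((v - mean(v))^2)))
    g <- length(unique(lab))
    (ssb / (g - 1)) / (ssw / (length(y) - g))
  }
  f_obs <- anova_f(dists, groups)
  f_perm <- with_seed(derive_seed(seed, "dispersion"), {
    vapply(seq_len(n_perm), function(i) anova_f(dists, sample(groups)),
           numeric(1))
  })
  p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
  g <- length(unique(groups))
  structure(list(
    distances = tibble(sample_id = rownames(m), group = groups,
                       dist_to_centroid = dists),
    F_disp = f_obs, df_among = g - 1L, df_within = n - g, p = p,
    n_perm = n_perm, correction = correction
  ), class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Multivariate dispersion homogeneity test\n")
  cat(sprintf("  F(%d, %d) = %.4f, p = %.4g (%d permutations, %s correction)\n",
              x$df_among, x$df_within, x$F_disp, x$p, x$n_perm, x$correction))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values (delegates to
#' [stats::p.adjust()] after validating the range).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, capped at 1.
#' @examples
#' bh_fdr(c(0.01, 0.04, 0.03))
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be in [0, 1] and non-missing")
  }
  p.adjust(p, method = "BH")
}

#' Pairwise PERMANOVA between groups with FDR adjustment
#'
#' Runs [permanova()] on every pair of group levels and adjusts the p-values
#' with [bh_fdr()].
#'
#' @inheritParams permanova
#' @return Tibble: group1, group2, pseudo_F, p, p_adj.
#' @export
pairwise_permanova <- function(d, groups, blocks = NULL, n_perm = 999,
                               scheme = c("blocks", "within", "free"),
                               seed = 1L) {
  scheme <- match.arg(scheme)
  m <- as_distmatrix(d)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  pairs <- combn(lev, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    keep <- groups %in% pairs[, j]
    fit <- permanova(m[keep, keep], groups[keep],
                     blocks = if (!is.null(blocks)) blocks[keep],
                     n_perm = n_perm, scheme = scheme,
                     seed = derive_seed(seed, paste(pairs[, j], collapse = "-")))
    tibble(group1 = pairs[1, j], group2 = pairs[2, j],
           pseudo_F = fit$pseudo_F, p = fit$p)
  })
  res$p_adj <- bh_fdr(res$p)
  res
}
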