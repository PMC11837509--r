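# Independent brute-force oracles. These recompute results from first
# principles with plain loops and exhaustive enumeration; they share no code
# with the package internals they check.

# All distinct labelings obtainable by permuting `labels` (columns).
oracle_label_perms <- function(labels) {
  perms <- unique(combinat_perms(seq_along(labels)))
  mats <- vapply(perms, function(p) labels[p], character(length(labels)))
  unique(t(mats))  # rows = distinct labelings
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Pseudo-F from a distance matrix and group labels, written out long-hand.
oracle_pseudo_f <- function(dmat, groups) {
  n <- length(groups)
  ss_tot <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    ss_tot <- ss_tot + dmat[i, j]^2
  }
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) for (b in seq.int(a + 1, length(idx))) {
        s <- s + dmat[idx[a], idx[b]]^2
      }
    }
    ss_w <- ss_w + s / length(idx)
  }
  g <- length(unique(groups))
  ((ss_tot - ss_w) / (g - 1)) / (ss_w / (n - g))
}

# Exact permutation p-value by enumerating every distinct relabeling
# (identity included), free scheme.
oracle_permanova_free <- function(dmat, groups) {
  f_obs <- oracle_pseudo_f(dmat, groups)
  labelings <- oracle_label_perms(groups)
  f_all <- apply(labelings, 1, function(g) oracle_pseudo_f(dmat, g))
  mean(f_all >= f_obs - 1e-12)
}

# Exact block-exchange p-value: permute the block -> group assignment.
oracle_permanova_blocks <- function(dmat, groups, blocks) {
  f_obs <- oracle_pseudo_f(dmat, groups)
  blk <- unique(blocks)
  blk_grp <- sapply(blk, function(b) groups[which(blocks == b)[1]])
  labelings <- oracle_label_perms(blk_grp)
  f_all <- apply(labelings, 1, function(bg) {
    oracle_pseudo_f(dmat, bg[match(blocks, blk)])
  })
  mean(f_all >= f_obs - 1e-12)
}

# Minimum set cover by exhaustive subset enumeration in order of increasing
# cardinality; combn enumerates lexicographically, so the first cover found
# at the minimum size is also the lexicographically smallest.
oracle_min_cover <- function(ec_sets, observed) {
  universe <- observed[observed %in% unlist(ec_sets)]
  if (length(universe) == 0) return(character(0))
  ids <- sort(names(ec_sets))
  for (k in seq_along(ids)) {
    combos <- utils::combn(ids, k, simplify = FALSE)
    for (cc in combos) {
      covered <- unique(unlist(ec_sets[cc]))
      if (all(universe %in% covered)) return(cc)
    }
  }
  stop("no cover found")  # impossible if every EC is in some set
}

# Random set-cover instance: n_pathways sets over an EC pool, plus an
# observed EC vector guaranteed coverable.
random_cover_instance <- function(n_pathways, n_ecs = 12, sizes = 1:4) {
  pool <- sprintf("e%02d", seq_len(n_ecs))
  ecs <- lapply(seq_len(n_pathways), function(i) {
    sample(pool, sample(sizes, 1))
  })
  names(ecs) <- sprintf("P%02d", seq_len(n_pathways))
  observed <- unique(unlist(ecs[sample(n_pathways, max(2, n_pathways %/% 2))]))
  list(catalog = tibble::tibble(pathway = names(ecs), ecs = unname(ecs),
                                variant_class = NA_character_),
       ec_sets = ecs, observed = observed)
}
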