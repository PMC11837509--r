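# Metabolic-capacity engine: community EC abundances, minimal pathway-set
# parsimony (MinPath-style set cover), and the partition of community
# capacity into per-taxon and obligately-shared pathway classes.

# Align a genome-content table to the catalog's EC universe and return a
# taxa x EC numeric matrix (catalog ECs absent from the table are zero).
content_matrix <- function(content, ec_universe = NULL) {
  assert_id_table(content, what = "genome-content table")
  m <- table_to_matrix(content)
  if (is.null(ec_universe)) return(m)
  out <- matrix(0, nrow(m), length(ec_universe),
                dimnames = list(rownames(m), ec_universe))
  shared <- intersect(colnames(m), ec_universe)
  out[, shared] <- m[, shared]
  out
}

# EC x pathway logical membership matrix plus required-set sizes.
catalog_index <- function(catalog) {
  stopifnot(is.data.frame(catalog), all(c("pathway", "ecs") %in% names(catalog)))
  if (anyDuplicated(catalog$pathway)) abort("duplicate pathway ids in catalog")
  if (any(lengths(catalog$ecs) == 0)) abort("every pathway needs a non-empty EC set")
  ord <- order(catalog$pathway)
  catalog <- catalog[ord, ]
  ecs <- sort(unique(unlist(catalog$ecs)))
  M <- matrix(FALSE, length(ecs), nrow(catalog),
              dimnames = list(ecs, catalog$pathway))
  for (j in seq_len(nrow(catalog))) M[catalog$ecs[[j]], j] <- TRUE
  list(M = M, sizes = colSums(M), pathways = catalog$pathway, ecs = ecs)
}

#' Community and per-taxon EC abundances
#'
#' Multiplies genome content (EC copy numbers per taxon) by the taxon count
#' table: community abundance of an EC in a sample is
#' sum over taxa of count(taxon, sample) x copy_number(taxon, EC).
#'
#' @param content Genome-content table (first column `taxon`, EC columns).
#' @param counts Count table (first column `taxon`, sample columns). Every
#'   taxon in `counts` must appear in `content`.
#' @param per_taxon If `TRUE`, also return the per-taxon contributions as a
#'   long tibble (can be large; meant for small communities or single
#'   samples).
#' @return A tibble with first column `sample_id` and one numeric column per
#'   EC; with `per_taxon = TRUE`, a list with elements `community` and
#'   `contributions` (tibble: sample_id, taxon, ec, abundance; zero rows
#'   omitted).
#' @examples
#' content <- tibble::tibble(taxon = "A", EC1 = 2)
#' counts <- tibble::tibble(taxon = "A", s1 = 5L)
#' ec_abundance(content, counts)
#' @export
ec_abundance <- function(content, counts, per_taxon = FALSE) {
  assert_id_table(counts)
  cm <- content_matrix(content)
  xm <- table_to_matrix(counts)
  missing <- setdiff(rownames(xm), rownames(cm))
  if (length(missing) > 0) {
    abort(sprintf("taxa in counts missing from genome content: %s",
                  paste(missing, collapse = ", ")))
  }
  cm <- cm[rownames(xm), , drop = FALSE]
  comm <- t(xm) %*% cm  # samples x ECs
  community <- bind_cols(tibble(sample_id = rownames(comm)),
                         as_tibble(comm, .name_repair = "minimal"))
  if (!per_taxon) return(community)
  contrib <- purrr::map_dfr(colnames(xm), function(s) {
    w <- cm * xm[, s]
    idx <- which(w > 0, arr.ind = TRUE)
    tibble(sample_id = s, taxon = rownames(cm)[idx[, 1]],
           ec = colnames(cm)[idx[, 2]], abundance = w[idx])
  })
  list(community = community, contributions = contrib)
}

# Greedy set cover over pathway coverage sets (integer EC indices), with
# incremental gain updates via an EC -> sets reverse index. Tie-break:
# candidates are in lexicographic pathway order and which.max takes the
# first maximum.
greedy_cover <- function(cov_sets, n_universe) {
  ec_sets <- vector("list", n_universe)
  for (j in seq_along(cov_sets)) {
    for (e in cov_sets[[j]]) ec_sets[[e]] <- c(ec_sets[[e]], j)
  }
  uncovered <- rep(TRUE, n_universe)
  n_left <- n_universe
  gain <- lengths(cov_sets)
  chosen <- integer(0)
  while (n_left > 0) {
    j <- which.max(gain)
    if (gain[j] <= 0) break  # should not happen: every EC is in some set
    chosen <- c(chosen, j)
    newly <- cov_sets[[j]][uncovered[cov_sets[[j]]]]
    uncovered[newly] <- FALSE
    n_left <- n_left - length(newly)
    for (e in newly) gain[ec_sets[[e]]] <- gain[ec_sets[[e]]] - 1L
    gain[chosen] <- -1L
  }
  sort(chosen)
}

# Exact minimum set cover by depth-first branch and bound over candidates in
# lexicographic order. Among minimum-cardinality covers the lexicographically
# smallest (by sorted candidate index vector) is returned.
exact_cover <- function(cov_sets, n_universe) {
  nc <- length(cov_sets)
  best <- list(size = Inf, sel = integer(0))
  max_gain <- max(vapply(cov_sets, length, integer(1)), 1L)
  better_lex <- function(a, b) {
    # TRUE if a < b lexicographically (both sorted integer vectors, equal length)
    d <- a - b
    nz <- which(d != 0)
    length(nz) > 0 && d[nz[1]] < 0
  }
  rec <- function(i, sel, uncovered, n_left) {
    if (n_left == 0) {
      sel <- sort(sel)
      if (length(sel) < best$size ||
          (length(sel) == best$size && better_lex(sel, best$sel))) {
        best <<- list(size = length(sel), sel = sel)
      }
      return(invisible(NULL))
    }
    lb <- length(sel) + ceiling(n_left / max_gain)
    if (lb > best$size) return(invisible(NULL))
    if (i > nc) return(invisible(NULL))
    gain_i <- sum(uncovered[cov_sets[[i]]])
    if (gain_i > 0) {
      unc2 <- uncovered
      unc2[cov_sets[[i]]] <- FALSE
      rec(i + 1L, c(sel, i), unc2, n_left - gain_i)
    }
    # exclude i only if the remaining sets can still cover what i covers
    rest_cover <- rep(FALSE, length(uncovered))
    if (i < nc) for (j in seq.int(i + 1L, nc)) rest_cover[cov_sets[[j]]] <- TRUE
    if (all(rest_cover[uncovered])) rec(i + 1L, sel, uncovered, n_left)
    invisible(NULL)
  }
  rec(1L, integer(0), rep(TRUE, n_universe), n_universe)
  best$sel
}

#' Minimal pathway set explaining the observed ECs
#'
#' MinPath-style parsimony: selects a minimum-cardinality set of pathways
#' such that every observed EC that maps to at least one catalog pathway is
#' a member of at least one selected pathway. An exact branch-and-bound
#' search runs when the number of candidate pathways (those sharing an EC
#' with the observation) is at most `max_exact`; otherwise greedy set cover
#' is used. Ties are broken lexicographically by pathway id, so the result
#' is deterministic.
#'
#' @param observed_ecs Character vector of ECs observed in the community.
#' @param catalog Pathway catalog: tibble with `pathway` and list-column
#'   `ecs` (and optionally `variant_class`).
#' @param max_exact Candidate-count bound below which exact search runs.
#' @return A list: `pathways` (selected ids, sorted), `mode` ("exact" or
#'   "greedy"), `unmapped_ecs` (observed ECs absent from the catalog).
#' @examples
#' catalog <- tibble::tibble(pathway = c("P1", "P2", "P3"),
#'   ecs = list(c("e1", "e2"), c("e2", "e3"), "e3"))
#' min_pathway_set(c("e1", "e2", "e3"), catalog)
#' @export
min_pathway_set <- function(observed_ecs, catalog, max_exact = 25) {
  idx <- catalog_index(catalog)
  observed_ecs <- unique(observed_ecs)
  min_cover_indexed(intersect(observed_ecs, idx$ecs), idx, max_exact,
                    unmapped = setdiff(observed_ecs, idx$ecs))
}

# Cover computation against a prebuilt catalog_index (hot path for
# per-sample profiles).
min_cover_indexed <- function(mappable, idx, max_exact, unmapped = character(0)) {
  if (length(mappable) == 0) {
    return(list(pathways = character(0), mode = "exact", unmapped_ecs = unmapped))
  }
  sub <- idx$M[mappable, , drop = FALSE]
  cand <- which(colSums(sub) > 0)  # already lexicographic via catalog_index
  cov_sets <- lapply(cand, function(j) which(sub[, j]))
  if (length(cand) <= max_exact) {
    sel <- exact_cover(cov_sets, length(mappable))
    mode <- "exact"
  } else {
    sel <- greedy_cover(cov_sets, length(mappable))
    mode <- "greedy"
  }
  list(pathways = idx$pathways[cand[sel]], mode = mode, unmapped_ecs = unmapped)
}

#' Partition community capacity into per-taxon and obligately-shared classes
#'
#' Given the total pathway set of a community and the subset completable by
#' a single genome, the obligately-shared class is the set difference: the
#' pathways whose required enzymes must be pooled across two or more
#' genomes. The three sets satisfy per_taxon plus obligately_shared = total
#' as a disjoint union.
#'
#' @param total Character vector: total pathway set.
#' @param per_taxon Character vector: pathways completable by at least one
#'   single genome present in the community (entries outside `total` are
#'   dropped, keeping the partition valid).
#' @return A list with `total`, `per_taxon`, `obligately_shared`.
#' @examples
#' partition_capacity(c("P1", "P2", "P3"), c("P1", "P3"))
#' @export
partition_capacity <- function(total, per_taxon) {
  total <- sort(unique(total))
  per_taxon <- sort(intersect(unique(per_taxon), total))
  list(total = total, per_taxon = per_taxon,
       obligately_shared = setdiff(total, per_taxon))
}

# Logical taxa x pathway matrix: does the taxon's genome alone carry every
# required EC of the pathway?
taxon_completion <- function(content, catalog) {
  idx <- catalog_index(catalog)
  cm <- content_matrix(content, idx$ecs) > 0
  (cm %*% idx$M) >= matrix(idx$sizes, nrow(cm), ncol(idx$M), byrow = TRUE)
}

# Prebuilt structures shared across capacity computations on the same
# content/catalog pair: catalog index, aligned content matrix, and the
# taxon x pathway single-genome completion matrix.
capacity_context <- function(content, counts, catalog) {
  assert_id_table(counts)
  idx <- catalog_index(catalog)
  cm <- content_matrix(content, idx$ecs)
  xm <- table_to_matrix(counts)
  missing <- setdiff(rownames(xm), rownames(cm))
  if (length(missing) > 0) {
    abort(sprintf("taxa in counts missing from genome content: %s",
                  paste(missing, collapse = ", ")))
  }
  cml <- cm > 0
  comp <- (cml %*% idx$M) >= matrix(idx$sizes, nrow(cml), ncol(idx$M),
                                    byrow = TRUE)
  list(idx = idx, cm = cm, comp = comp, xm = xm)
}

# Core single-community capacity computation on a named count vector.
capacity_core <- function(x, cm, comp, idx, completeness, max_exact) {
  present <- names(x)[x > 0]
  if (length(present) == 0) {
    warn("no taxa present in this scope; empty capacity profile")
    return(list(total = character(0), per_taxon = character(0),
                obligately_shared = character(0),
                incidence = tibble(taxon = character(0), pathway = character(0)),
                pathway_abundance = tibble(pathway = character(0),
                                           abundance = numeric(0)),
                cover_mode = "exact", unmapped_ecs = character(0)))
  }
  ec_ab <- drop(crossprod(cm[names(x), , drop = FALSE], x))  # EC abundances
  observed <- idx$ecs[ec_ab > 0]
  cover <- min_cover_indexed(observed, idx, max_exact)
  frac_complete <- drop(crossprod(idx$M, ec_ab > 0)) / idx$sizes
  complete <- idx$pathways[frac_complete >= completeness]
  total <- intersect(cover$pathways, complete)
  single <- idx$pathways[colSums(comp[present, , drop = FALSE]) > 0]
  part <- partition_capacity(total, single)
  inc_m <- comp[present, part$total, drop = FALSE]
  pairs <- which(inc_m, arr.ind = TRUE)
  incidence <- tibble(taxon = rownames(inc_m)[pairs[, 1]],
                      pathway = colnames(inc_m)[pairs[, 2]])
  abund <- vapply(part$total, function(p) {
    median(ec_ab[idx$M[, p]])
  }, numeric(1))
  list(total = part$total, per_taxon = part$per_taxon,
       obligately_shared = part$obligately_shared,
       incidence = arrange(incidence, .data$taxon, .data$pathway),
       pathway_abundance = tibble(pathway = part$total,
                                  abundance = unname(abund)),
       cover_mode = cover$mode, unmapped_ecs = cover$unmapped_ecs)
}

#' Metabolic capacity of a sample or pooled group
#'
#' Computes the community's total pathway set (pathways selected by
#' [min_pathway_set()] whose required ECs all have community abundance > 0),
#' the per-taxon subset (pathways for which at least one taxon present in
#' the scope carries the complete EC repertoire in its own genome), and the
#' obligately-shared complement, plus the taxon-by-pathway incidence of
#' single-genome completions and a per-pathway abundance (median of the
#' required ECs' community abundances).
#'
#' @param content Genome-content table.
#' @param counts Count table.
#' @param catalog Pathway catalog.
#' @param samples Sample ids to use (default: all columns of `counts`).
#' @param pool If `TRUE` (default) counts are summed across the selected
#'   samples into one community; otherwise exactly one sample must be named.
#' @param completeness Minimum fraction of a pathway's required ECs that
#'   must be present in the community (default 1 = all).
#' @param max_exact Passed to [min_pathway_set()].
#' @param ctx Precomputed internal context (used by knockout sweeps to avoid
#'   rebuilding the catalog index); leave `NULL`.
#' @return A `capacity_profile`: scope, total, per_taxon, obligately_shared,
#'   incidence (tibble taxon, pathway: single-genome completions among
#'   present taxa, restricted to the total set), pathway_abundance,
#'   cover_mode, unmapped_ecs.
#' @export
community_capacity <- function(content, counts, catalog,
                               samples = NULL, pool = TRUE,
                               completeness = 1.0, max_exact = 25,
                               ctx = NULL) {
  ctx <- ctx %||% capacity_context(content, counts, catalog)
  xm <- ctx$xm
  samples <- samples %||% colnames(xm)
  bad <- setdiff(samples, colnames(xm))
  if (length(bad) > 0) {
    abort(sprintf("unknown sample(s): %s", paste(bad, collapse = ", ")))
  }
  if (!pool && length(samples) != 1) {
    abort("pool = FALSE requires exactly one sample")
  }
  x <- rowSums(xm[, samples, drop = FALSE])
  core <- capacity_core(x, ctx$cm, ctx$comp, ctx$idx, completeness, max_exact)
  structure(c(list(scope = if (length(samples) == 1) samples else
                     sprintf("pooled(%d samples)", length(samples))),
              core),
            class = "capacity_profile")
}

#' @export
print.capacity_profile <- function(x, ...) {
  cat(sprintf("<capacity_profile: %s>\n", x$scope))
  cat(sprintf("  total %d | per-taxon %d | obligately shared %d (%s cover)\n",
              length(x$total), length(x$per_taxon),
              length(x$obligately_shared), x$cover_mode))
  invisible(x)
}

#' Per-sample pathway presence and incidence across a count table
#'
#' Vectorised capacity computation over every sample: for each sample,
#' which pathways are in the total set and which class they fall in, plus
#' the per-sample taxon-by-pathway incidence of single-genome completions.
#'
#' @inheritParams community_capacity
#' @return A list of two tibbles: `presence` (sample_id, pathway, class
#'   in "per_taxon"/"obligately_shared") and `incidence` (sample_id, taxon,
#'   pathway).
#' @export
capacity_by_sample <- function(content, counts, catalog,
                               completeness = 1.0, max_exact = 25) {
  ctx <- capacity_context(content, counts, catalog)
  xm <- ctx$xm
  res <- purrr::map(colnames(xm), function(s) {
    core <- capacity_core(xm[, s], ctx$cm, ctx$comp, ctx$idx, completeness,
                          max_exact)
    list(
      presence = tibble(
        sample_id = s, pathway = core$total,
        class = ifelse(core$total %in% core$per_taxon,
                       "per_taxon", "obligately_shared")),
      incidence = bind_cols(tibble(sample_id = rep(s, nrow(core$incidence))),
                            core$incidence)
    )
  })
  list(presence = purrr::map_dfr(res, "presence"),
       incidence = purrr::map_dfr(res, "incidence"))
}

#' Variant-class groupings of a pathway catalog
#'
#' Groups pathways by their declared variant class (pathways with distinct
#' enzyme repertoires yielding the same metabolites). A class is covered in
#' a profile if at least one member pathway is present.
#'
#' @param catalog Pathway catalog with a `variant_class` column (NA = not a
#'   member of any class).
#' @return Named list: variant class -> character vector of member pathways.
#' @export
variant_groups <- function(catalog) {
  if (!"variant_class" %in% names(catalog)) return(list())
  keep <- !is.na(catalog$variant_class)
  if (!any(keep)) return(list())
  split(catalog$pathway[keep], catalog$variant_class[keep])
}

#' Variant-class coverage of a pathway set
#'
#' @param pathways Character vector of present pathways (e.g. a profile's
#'   `total` set).
#' @param catalog Pathway catalog with `variant_class`.
#' @return Tibble: variant_class, n_members, n_present, covered.
#' @export
variant_coverage <- function(pathways, catalog) {
  groups <- variant_groups(catalog)
  if (length(groups) == 0) {
    return(tibble(variant_class = character(0), n_members = integer(0),
                  n_present = integer(0), covered = logical(0)))
  }
  tibble(
    variant_class = names(groups),
    n_members = unname(lengths(groups)),
    n_present = vapply(groups, function(g) sum(g %in% pathways), integer(1),
                       USE.NAMES = FALSE)
  ) |> mutate(covered = .data$n_present > 0)
}
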