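# Internal helpers shared across modules: argument checks, seed derivation,
# and accessors for tables that carry side reports as attributes.

#' Derive a module-specific RNG seed from a top-level seed
#'
#' Every randomised stage consumes its own stream, split deterministically
#' from a single top-level seed so that any stage can be re-run in isolation.
#' The derived seed is kept below 2^31 - 1.
#'
#' @param seed Integer top-level seed.
#' @param label Character label naming the consuming stage.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99991L
  as.integer((abs(seed) %% 1000003L) * 2011L + h * 31L) %% 2147483647L
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# A count/content table is a tibble whose first column is the identifier
# (`taxon`) and whose remaining columns are numeric.
assert_id_table <- function(x, id = "taxon", what = "count table") {
  if (!is.data.frame(x)) abort(sprintf("%s must be a data frame", what))
  if (ncol(x) < 1 || names(x)[1] != id) {
    abort(sprintf("%s must have '%s' as its first column", what, id))
  }
  if (anyDuplicated(x[[id]])) {
    dup <- unique(x[[id]][duplicated(x[[id]])])
    abort(sprintf("duplicated %s id(s): %s", id, paste(dup, collapse = ", ")))
  }
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (length(vals) > 0 && !is.numeric(vals)) {
    abort(sprintf("%s has non-numeric cells", what))
  }
  if (any(vals < 0, na.rm = TRUE)) abort(sprintf("%s has negative entries", what))
  invisible(x)
}

# Convert an id-first tibble to a numeric matrix with ids as rownames.
table_to_matrix <- function(x, id = "taxon") {
  m <- as.matrix(x[, setdiff(names(x), id), drop = FALSE])
  rownames(m) <- x[[id]]
  m
}

matrix_to_table <- function(m, id = "taxon") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- bind_cols(tibble(!!id := rownames(m)), out)
  out
}

#' Retrieve the exclusion report attached to a filtered table
#'
#' [filter_samples()] and [filter_phylotypes()] return the retained table with
#' an exclusion report (id, reason, statistic) attached as an attribute; this
#' accessor extracts it.
#'
#' @param x A table returned by a filtering function.
#' @return A tibble with columns `id`, `reason`, `statistic` (empty if nothing
#'   was excluded or the table was not produced by a filter).
#' @export
exclusions <- function(x) {
  attr(x, "exclusions") %||%
    tibble(id = character(), reason = character(), statistic = numeric())
}
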