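# Readers and writers for the interchange formats: TSV tables (taxa as rows,
# first column = identifier, '#' comment lines ignored), a BIOM-style JSON
# dialect for count tables (read-only), and JSON pathway catalogs.

read_id_tsv <- function(path, id) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (ncol(x) == 0) abort(sprintf("%s: empty table", path))
  names(x)[1] <- id
  x[[1]] <- as.character(x[[1]])
  for (j in seq.int(2, length.out = ncol(x) - 1)) {
    col <- x[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      if (anyNA(num)) {
        abort(sprintf("%s: non-numeric cell at row %d, column '%s'",
                      path, which(is.na(num))[1], names(x)[j]))
      }
      x[[j]] <- col <- num
    }
    if (all(col == round(col)) && max(abs(col)) < .Machine$integer.max) {
      x[[j]] <- as.integer(col)
    }
  }
  assert_id_table(x, id = id, what = path)
  x
}

#' Read a taxon-by-sample count table
#'
#' Accepts tab-separated text (taxa as rows, first column the taxon id,
#' `#`-prefixed comment lines ignored) or a BIOM-style JSON file with
#' `shape`, `rows`, `columns` and `data` keys (dense or sparse
#' `matrix_type`). The two encodings of the same table parse to identical
#' objects.
#'
#' @param path File path.
#' @param format "auto" (by file signature), "tsv", or "biom".
#' @return A tibble with first column `taxon` and one integer column per
#'   sample.
#' @export
read_count_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readChar(path, 1L)
    format <- if (identical(first, "{")) "biom" else "tsv"
  }
  if (format == "tsv") return(read_id_tsv(path, "taxon"))
  b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("shape", "rows", "columns", "data")
  if (!all(need %in% names(b))) {
    abort(sprintf("%s: BIOM-style JSON must carry keys %s", path,
                  paste(need, collapse = ", ")))
  }
  nr <- b$shape[[1]]; nc <- b$shape[[2]]
  taxa <- vapply(b$rows, function(r) as.character(r$id), character(1))
  samples <- vapply(b$columns, function(s) as.character(s$id), character(1))
  if (length(taxa) != nr || length(samples) != nc) {
    abort(sprintf("%s: shape [%d, %d] does not match %d rows / %d columns",
                  path, nr, nc, length(taxa), length(samples)))
  }
  m <- matrix(0L, nr, nc, dimnames = list(taxa, samples))
  if (identical(b$matrix_type %||% "dense", "sparse")) {
    for (trip in b$data) {
      m[trip[[1]] + 1L, trip[[2]] + 1L] <- as.integer(trip[[3]])
    }
  } else {
    for (i in seq_len(nr)) m[i, ] <- as.integer(unlist(b$data[[i]]))
  }
  out <- matrix_to_table(m, "taxon")
  assert_id_table(out, what = path)
  out
}

#' Write a count (or genome-content) table as TSV
#'
#' @param x Tibble with identifier first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  assert_id_table(x, id = names(x)[1], what = "table")
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a genome-content table (taxon by EC copy numbers)
#'
#' @param path TSV path (first column = taxon id).
#' @return Tibble with first column `taxon`.
#' @export
read_gene_content <- function(path) read_id_tsv(path, "taxon")

#' Read or write sample metadata
#'
#' Metadata is TSV with columns sample_id, individual, week, treatment.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_metadata <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("sample_id", "individual", "week", "treatment")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s: metadata missing column(s) %s", path,
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(x$sample_id)) {
    abort(sprintf("%s: duplicated sample_id", path))
  }
  x
}

#' @rdname read_metadata
#' @param metadata Metadata tibble.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Read or write a pathway catalog
#'
#' JSON catalogs are arrays of objects with keys `pathway_id`, `ec_list`,
#' and optional `variant_class`; TSV catalogs have columns `pathway`, `ecs`
#' (semicolon-separated) and `variant_class`.
#'
#' @param path File path (`.json` or `.tsv` by extension).
#' @return Tibble: pathway, ecs (list-column), variant_class.
#' @export
read_catalog <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    out <- tibble(
      pathway = vapply(raw, function(p) as.character(p$pathway_id), character(1)),
      ecs = lapply(raw, function(p) as.character(unlist(p$ec_list))),
      variant_class = vapply(raw, function(p) {
        vc <- p$variant_class
        if (is.null(vc)) NA_character_ else as.character(vc)
      }, character(1))
    )
  } else {
    x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
    out <- tibble(pathway = as.character(x$pathway),
                  ecs = strsplit(as.character(x$ecs), ";", fixed = TRUE),
                  variant_class = if ("variant_class" %in% names(x)) {
                    as.character(x$variant_class)
                  } else NA_character_)
  }
  if (anyDuplicated(out$pathway)) abort(sprintf("%s: duplicate pathway ids", path))
  if (any(lengths(out$ecs) == 0)) {
    abort(sprintf("%s: pathway with empty EC set", path))
  }
  out
}

#' @rdname read_catalog
#' @param catalog Catalog tibble.
#' @export
write_catalog <- function(catalog, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- purrr::pmap(catalog, function(pathway, ecs, variant_class = NA, ...) {
      out <- list(pathway_id = pathway, ec_list = as.list(ecs))
      if (!is.na(variant_class)) out$variant_class <- variant_class
      out
    })
    jsonlite::write_json(obj, path, auto_unbox = TRUE)
  } else {
    readr::write_tsv(
      tibble(pathway = catalog$pathway,
             ecs = vapply(catalog$ecs, paste, character(1), collapse = ";"),
             variant_class = catalog$variant_class),
      path, progress = FALSE)
  }
  invisible(path)
}

#' Write the planted truth of a synthetic scenario as JSON
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write all tables of a simulated scenario to a directory
#'
#' Emits counts.tsv, metadata.tsv, gene_content.tsv, annotations.tsv,
#' catalog.json and truth.json.
#'
#' @param sim Result of [simulate_community()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_community <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(outdir, "counts.tsv"))
  write_metadata(sim$metadata, file.path(outdir, "metadata.tsv"))
  write_count_table(sim$content, file.path(outdir, "gene_content.tsv"))
  readr::write_tsv(sim$annotations, file.path(outdir, "annotations.tsv"),
                   progress = FALSE)
  write_catalog(sim$catalog, file.path(outdir, "catalog.json"))
  write_truth(sim$truth, file.path(outdir, "truth.json"))
  invisible(outdir)
}
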