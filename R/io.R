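#' Read a gene-by-sample expression matrix from tab-separated text
#'
#' The expected layout is the one most expression tables ship in: a header
#' row whose first field names the gene-identifier column and whose remaining
#' fields are sample identifiers, followed by one row per gene holding the
#' gene id and one numeric expression value per sample. Values are assumed
#' continuous (log-scale or otherwise normalized upstream); no normalization
#' is applied here.
#'
#' @param path Path to a tab-separated text file.
#' @return A numeric matrix with genes in rows (rownames = gene ids) and
#'   samples in columns (colnames = sample ids).
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' write_expression_matrix(m, f)
#' all.equal(read_expression_matrix(f), m)
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) abort("expression file must have a header and at least one gene row.")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) < 2L) abort("expression file must have at least 2 sample columns.")
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("duplicated sample id(s): %s",
                  paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    abort(sprintf("duplicated gene id(s): %s",
                  paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  }
  n_fields <- lengths(body)
  bad <- which(n_fields != length(header))
  if (length(bad)) {
    abort(sprintf("row %d (gene '%s') has %d fields, expected %d.",
                  bad[1L] + 1L, gene_ids[bad[1L]], n_fields[bad[1L]], length(header)))
  }
  values <- matrix(NA_real_, length(gene_ids), length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      abort(sprintf("non-numeric value in row for gene '%s', sample '%s'.",
                    gene_ids[i], sample_ids[j]))
    }
    values[i, ] <- v
  }
  check_expression_matrix(values, arg = basename(path))
  values
}

#' Write an expression matrix as tab-separated text
#'
#' Full `%.17g`-style precision, '.' decimal separator, UTF-8: a written
#' matrix re-read with [read_expression_matrix()] reproduces the object
#' exactly.
#'
#' @param values Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param id_column Name for the gene-identifier column in the header.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(values, path, id_column = "gene_id") {
  check_expression_matrix(values)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(values)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], format_num(values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

format_num <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  trimws(out)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT is the MSigDB gene-set distribution format: one set per line, fields
#' tab-separated — set name, description (ignored), then one or more gene
#' identifiers. Duplicate gene ids within a line are dropped (first
#' occurrence kept) with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene ids, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields.", short[1L]))
  }
  set_names <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(set_names)) {
    abort(sprintf("duplicated gene-set name(s): %s",
                  paste(unique(set_names[duplicated(set_names)]), collapse = ", ")))
  }
  sets <- lapply(seq_along(fields), function(i) {
    genes <- fields[[i]][-(1:2)]
    if (anyDuplicated(genes)) {
      warn(sprintf("gene set '%s': duplicate gene ids de-duplicated.", set_names[i]))
      genes <- genes[!duplicated(genes)]
    }
    genes
  })
  names(sets) <- set_names
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors of gene ids.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Restrict a gene-set collection to the measured genes
#'
#' Each pathway is intersected with the rownames of the expression matrix
#' (exact, case-sensitive string match — identifier-namespace curation is out
#' of scope) and pathways whose intersection falls below `min_size` are
#' dropped. Below two genes a multivariate mixture degenerates, hence the
#' default.
#'
#' @param expr Numeric gene-by-sample matrix (see [read_expression_matrix()]).
#' @param sets Named list of gene-id vectors.
#' @param min_size Minimum matched pathway size to keep (>= 2).
#' @return The filtered collection, with a `coverage` attribute: a tibble
#'   with one row per input pathway (`pathway`, `size`, `matched`, `kept`).
#' @export
match_pathways <- function(expr, sets, min_size = 2L) {
  check_expression_matrix(expr)
  assert_scalar_number(min_size, "min_size", min = 2)
  genes <- rownames(expr)
  matched <- lapply(sets, function(g) g[g %in% genes])
  keep <- lengths(matched) >= min_size
  coverage <- tibble::tibble(
    pathway = names(sets),
    size = unname(lengths(sets)),
    matched = unname(lengths(matched)),
    kept = unname(keep)
  )
  if (!any(keep)) {
    abort(paste(
      "no pathway retains", min_size, "or more measured genes after matching;",
      "check that expression gene ids and gene-set ids use the same namespace."
    ))
  }
  out <- matched[keep]
  attr(out, "coverage") <- coverage
  out
}

#' Read / write a square score or distance matrix
#'
#' Square matrices are stored as tab-separated text with sample ids both in
#' the header and in the first column.
#'
#' @param path File path.
#' @return For the reader, a symmetric numeric matrix with sample-id dimnames.
#' @export
read_distance_matrix <- function(path) {
  m <- read_expression_matrix(path)
  if (!identical(rownames(m), colnames(m))) {
    abort("square matrix file must carry the same sample ids in header and first column.")
  }
  check_distance_matrix(m, arg = basename(path))
  m
}

#' @rdname read_distance_matrix
#' @param d Symmetric numeric matrix with sample-id dimnames.
#' @export
write_distance_matrix <- function(d, path) {
  check_distance_matrix(d)
  write_expression_matrix(unclass_keep_dim(d), path, id_column = "sample_id")
}

unclass_keep_dim <- function(m) {
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}

#' Read / write cluster labels
#'
#' Two-column tab-separated text: sample id, integer label, with a header.
#'
#' @param path File path.
#' @return For the reader, a named integer vector of labels.
#' @export
read_cluster_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  as_labels(df)
}

#' @rdname read_cluster_labels
#' @param labels Named integer vector of cluster labels.
#' @export
write_cluster_labels <- function(labels, path) {
  labels <- as_labels(labels)
  df <- data.frame(sample_id = names(labels), label = unname(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
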