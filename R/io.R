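#' Read an expression matrix from tab-delimited text
#'
#' Expects a header row of probe identifiers and a first column of sample
#' identifiers (samples in rows). Set `transpose = TRUE` for the common
#' probes-in-rows layout (first column probe IDs, header of sample IDs).
#' Duplicate sample or probe identifiers are an error.
#'
#' @param path File path.
#' @param transpose Is the file probes x samples?
#' @return Numeric samples x probes matrix with dimnames.
#' @export
read_expression <- function(path, transpose = FALSE) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate identifiers in first column of ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) abort(paste0("Non-numeric expression values in ", path))
  rownames(mat) <- ids
  if (anyDuplicated(colnames(mat))) {
    abort(paste0("Duplicate identifiers in header of ", path))
  }
  if (transpose) mat <- t(mat)
  mat
}

#' Read a phenotype file
#'
#' Two tab-delimited columns: sample identifier and continuous phenotype
#' value. A header row is detected automatically (non-numeric second
#' field).
#'
#' @param path File path.
#' @return Named numeric vector keyed by sample identifier.
#' @export
read_phenotype <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- length(first) >= 2 && is.na(suppressWarnings(
    as.numeric(first[2])))
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) abort(paste0("Phenotype file needs two columns: ", path))
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sample identifiers in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  y <- as.numeric(tab[[2]])
  if (anyNA(y)) abort(paste0("Non-numeric phenotype values in ", path))
  stats::setNames(y, ids)
}

#' Align a phenotype to the rows of an expression matrix
#'
#' Joins by sample identifier and reorders the phenotype to the expression
#' row order. Every phenotype sample must be present in the expression
#' matrix and vice versa; unmatched identifiers are an error naming them.
#'
#' @param X Expression matrix with sample row names.
#' @param y Named phenotype vector.
#' @return List with aligned `X` and `y`.
#' @export
align_samples <- function(X, y) {
  X <- as_expression_matrix(X)
  if (is.null(rownames(X)) || is.null(names(y))) {
    abort("Both X rows and y must carry sample identifiers to align.")
  }
  miss_x <- setdiff(names(y), rownames(X))
  miss_y <- setdiff(rownames(X), names(y))
  if (length(miss_x) > 0 || length(miss_y) > 0) {
    abort(paste0(
      "Sample identifiers do not match. ",
      if (length(miss_x) > 0)
        paste0("Absent from expression: ",
               paste(head(miss_x, 5), collapse = ", "), ". ") else "",
      if (length(miss_y) > 0)
        paste0("Absent from phenotype: ",
               paste(head(miss_y, 5), collapse = ", "), ".") else ""
    ))
  }
  list(X = X, y = y[rownames(X)])
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated — set name, description,
#' then member identifiers. Lines with fewer than three fields are an
#' error naming the line number.
#'
#' @param path File path.
#' @return A tibble with columns `set`, `description`, `members`
#'   (list-column of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- purrr::imap(lines, function(line, i) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("Malformed GMT line %d in %s: needs name, description and at least one member.",
                    i, path))
    }
    tibble::tibble(set = f[1], description = f[2],
                   members = list(unique(f[-(1:2)])))
  })
  out <- dplyr::bind_rows(parsed)
  if (anyDuplicated(out$set)) {
    abort(paste0("Duplicate gene-set names in ", path))
  }
  out
}

#' Write a results table as CSV
#'
#' Full floating precision, header row, never interleaved with logs.
#'
#' @param rows A tibble (e.g. from [screen_gene_sets()] or
#'   [run_grid()]). List-columns are flattened to comma-joined text.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  rows <- dplyr::mutate(rows, dplyr::across(
    dplyr::where(is.list), ~ purrr::map_chr(.x, paste, collapse = ",")))
  readr::write_csv(rows, path)
  invisible(path)
}
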