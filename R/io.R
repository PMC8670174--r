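# Expression matrix readers/writers and the key=value config reader.

#' Read an expression matrix
#'
#' Dense CSV/TSV (first column = cell ids, header = gene ids) or
#' MatrixMarket MTX with companion label files (one id per line) for
#' rows and columns.  Use `transpose = TRUE` when the file stores genes
#' in rows.
#'
#' @param path path to a `.csv`, `.tsv`/`.txt`, or `.mtx` file.
#' @param transpose is the file genes x cells rather than cells x genes?
#' @param row_ids,col_ids label files for MTX input (defaults:
#'   `<path>.rows` and `<path>.cols`).
#' @return a raw [expression_matrix()].
#' @export
read_expression <- function(path, transpose = FALSE,
                            row_ids = paste0(path, ".rows"),
                            col_ids = paste0(path, ".cols")) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    values <- as.matrix(Matrix::readMM(path))
    dimnames(values) <- list(readLines(row_ids, warn = FALSE),
                             readLines(col_ids, warn = FALSE))
  } else {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            row.names = 1L, check.names = FALSE)
    values <- as.matrix(df)
  }
  if (transpose) values <- t(values)
  message("read expression matrix: ", nrow(values), " cells x ",
          ncol(values), " genes from ", path)
  expression_matrix(values)
}

#' Write an expression matrix as CSV
#'
#' Cells x genes, cell ids in the first column (`cell_id` header).
#'
#' @param expr an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(cell_id = rownames(expr), as.data.frame(unclass(expr)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature matrix as CSV
#'
#' The block provenance (which functional gene set contributed which
#' column range) is recorded in `#`-prefixed header comments.
#'
#' @param features a matrix from [build_feature_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bi <- attr(features, "block_index")
  for (id in names(bi)) {
    writeLines(sprintf("# block %s: columns %d-%d", id,
                       min(bi[[id]]), max(bi[[id]])), con)
  }
  df <- data.frame(cell_id = rownames(features),
                   as.data.frame(unclass(features)), check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a key=value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored.  Values are returned as character strings.
#'
#' @param path config file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad)) stop("malformed config line(s): ",
                        paste(bad, collapse = "; "))
  stats::setNames(lapply(kv, function(m) trimws(m[[3L]])),
                  vapply(kv, function(m) trimws(m[[2L]]), ""))
}
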