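#' Read a signed weight matrix from CSV
#'
#' Accepts either a labeled matrix (header row plus a leading label column)
#' or a bare numeric grid, auto-detected; `#`-prefixed metadata lines are
#' ignored.  The matrix is validated with [signed_matrix()].
#'
#' @param path CSV file path.
#' @return a [signed_matrix()].
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) stop("no data in ", path)
  fields <- strsplit(lines, ",")
  nf <- lengths(fields)
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged CSV: line %d has %d fields, expected %d",
                 bad, nf[bad], nf[1]))
  }
  first <- suppressWarnings(as.numeric(fields[[1]]))
  has_header <- anyNA(first)
  txt <- textConnection(lines)
  on.exit(close(txt))
  if (has_header) {
    df <- utils::read.csv(txt, header = TRUE, row.names = 1,
                          check.names = FALSE)
    m <- as.matrix(df)
    labels <- rownames(df)
  } else {
    m <- as.matrix(utils::read.csv(txt, header = FALSE))
    labels <- NULL
    dimnames(m) <- NULL
  }
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  signed_matrix(m, labels = labels)
}

#' Write a signed weight matrix as CSV
#'
#' Writes node labels as header row and leading column, preceded by
#' optional `#` metadata lines; 12 significant digits so that a
#' write/read round trip is exact to 1e-12.
#'
#' @param w a [signed_matrix()].
#' @param path output path.
#' @param meta named character/numeric vector written as `# key: value`.
#' @export
write_matrix <- function(w, path, meta = NULL) {
  if (!inherits(w, "signed_matrix")) w <- signed_matrix(w)
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, meta)
  df <- as.data.frame(signif(unclass(w), 12))
  utils::write.csv(cbind(node = rownames(w), df), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

write_meta <- function(con, meta) {
  meta <- c(package = paste("signedclust", utils::packageVersion("signedclust")),
            meta)
  writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
}

#' Write a result table as CSV with a metadata header
#'
#' @param df data frame.
#' @param path output path.
#' @param meta named vector of `# key: value` metadata lines (seeds,
#'   parameters).
#' @export
write_result <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, meta)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an item-response table from CSV
#'
#' @param path CSV with a header row of item names.
#' @param scale_min,scale_max response-scale bounds.
#' @param reverse_keyed character vector of reverse-keyed item names.
#' @return an [item_table()]; out-of-range scores or unknown reverse-keyed
#'   names are errors with coordinates.
#' @export
read_items <- function(path, scale_min = 1, scale_max = 5,
                       reverse_keyed = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, comment.char = "#",
                        check.names = FALSE)
  item_table(df, scale_min, scale_max, reverse_keyed)
}
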