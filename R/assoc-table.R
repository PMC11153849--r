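#' Binary drug-microbe association table
#'
#' Container for a binary adjacency matrix `A` (rows = drugs, columns =
#' microbes) together with the two identifier lists. `A[i, j] = 1` records a
#' known association between drug `i` and microbe `j`; everything else is an
#' unlabelled candidate pair.
#'
#' @param A numeric or integer matrix containing only 0/1.
#' @param drug_ids,microbe_ids character vectors of unique identifiers; default
#'   to the dimnames of `A` or generated `d1..dN` / `m1..mN` labels.
#'
#' @return An object of class `"association_table"`: a list with elements
#'   `drug_ids`, `microbe_ids` and the binary matrix `A` (with dimnames set).
#' @export
#' @examples
#' A <- matrix(c(1, 0, 0, 1), 2, 2)
#' association_table(A)
association_table <- function(A, drug_ids = rownames(A),
                              microbe_ids = colnames(A)) {
  A <- as.matrix(A)
  if (!all(A %in% c(0, 1))) {
    stop("association matrix must contain only 0/1 entries", call. = FALSE)
  }
  storage.mode(A) <- "double"
  if (is.null(drug_ids))    drug_ids <- paste0("d", seq_len(nrow(A)))
  if (is.null(microbe_ids)) microbe_ids <- paste0("m", seq_len(ncol(A)))
  drug_ids <- as.character(drug_ids); microbe_ids <- as.character(microbe_ids)
  if (anyDuplicated(drug_ids) || anyDuplicated(microbe_ids)) {
    stop("identifiers must be unique within drugs and within microbes",
         call. = FALSE)
  }
  if (length(drug_ids) != nrow(A) || length(microbe_ids) != ncol(A)) {
    stop("identifier lists must match the matrix dimensions", call. = FALSE)
  }
  dimnames(A) <- list(drug_ids, microbe_ids)
  structure(list(drug_ids = drug_ids, microbe_ids = microbe_ids, A = A),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("Association table: %d drugs x %d microbes, %d known pairs (density %.4f)\n",
              nrow(x$A), ncol(x$A), sum(x$A), mean(x$A)))
  invisible(x)
}

#' @export
dim.association_table <- function(x) dim(x$A)

#' Read an association table from disk
#'
#' Two dialects are supported. `pair_list` is the canonical interchange
#' format (the shape in which public microbe-drug dumps such as MDAD or
#' aBiofilm circulate): one association per line, `drug<TAB>microbe` (comma
#' also accepted), `#`-prefixed comment lines ignored, duplicate pairs
#' collapsed. Identifier order is first appearance. `dense_matrix` is a
#' delimited 0/1 matrix with an identifier header row and first column.
#'
#' @param path path to an existing text file.
#' @param dialect `"pair_list"` or `"dense_matrix"`.
#' @return An [association_table()].
#' @export
read_association_table <- function(path,
                                   dialect = c("pair_list", "dense_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "pair_list") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
    if (length(keep) == 0L) stop("empty association file: ", path, call. = FALSE)
    pairs <- vector("list", length(keep))
    for (ii in seq_along(keep)) {
      ln <- lines[[keep[ii]]]
      fields <- strsplit(ln, sniff_sep(ln), fixed = TRUE)[[1]]
      fields <- trimws(fields)
      fields <- fields[nzchar(fields)]
      if (length(fields) < 2L) {
        stop(sprintf("malformed association row at line %d of %s: %s",
                     keep[ii], path, ln), call. = FALSE)
      }
      pairs[[ii]] <- fields[1:2]
    }
    pm <- do.call(rbind, pairs)
    drug_ids <- unique(pm[, 1]); microbe_ids <- unique(pm[, 2])
    A <- matrix(0, length(drug_ids), length(microbe_ids),
                dimnames = list(drug_ids, microbe_ids))
    A[cbind(match(pm[, 1], drug_ids), match(pm[, 2], microbe_ids))] <- 1
    association_table(A, drug_ids, microbe_ids)
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 0L) stop("empty association file: ", path, call. = FALSE)
    df <- utils::read.table(path, header = TRUE, sep = sniff_sep(first),
                            row.names = 1, check.names = FALSE,
                            stringsAsFactors = FALSE)
    A <- as.matrix(df)
    if (!is.numeric(A) || !all(A %in% c(0, 1))) {
      stop("dense association matrix must contain only 0/1 entries: ", path,
           call. = FALSE)
    }
    association_table(A, rownames(A), colnames(A))
  }
}

#' Write an association table to disk
#'
#' @param x an [association_table()].
#' @param path output path.
#' @param dialect `"pair_list"` (tab-separated pairs, row-major over `A`) or
#'   `"dense_matrix"`.
#' @param sep field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(x, path,
                                    dialect = c("pair_list", "dense_matrix"),
                                    sep = "\t") {
  stopifnot(inherits(x, "association_table"))
  dialect <- match.arg(dialect)
  if (dialect == "pair_list") {
    idx <- which(x$A == 1, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    writeLines(paste(x$drug_ids[idx[, 1]], x$microbe_ids[idx[, 2]], sep = sep),
               path)
  } else {
    utils::write.table(x$A, path, sep = sep, quote = FALSE,
                       row.names = TRUE, col.names = NA)
  }
  invisible(path)
}

#' Read / write a square similarity matrix
#'
#' Dense delimited text with an identifier header row and first column, the
#' same dialect as `dense_matrix` association files. Values are expected in
#' \[0, 1\].
#'
#' @param path file path.
#' @return `read_similarity_matrix()` returns a numeric matrix with dimnames.
#' @export
read_similarity_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(first),
                          row.names = 1, check.names = FALSE)
  S <- as.matrix(df)
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square", call. = FALSE)
  S
}

#' @rdname read_similarity_matrix
#' @param S square numeric matrix.
#' @param sep field separator.
#' @export
write_similarity_matrix <- function(S, path, sep = "\t") {
  utils::write.table(S, path, sep = sep, quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
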