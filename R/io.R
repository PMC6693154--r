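#' Read an expression matrix from disk
#'
#' Dense input is a TSV/CSV table whose header row holds feature ids and whose
#' first column holds cell ids (use `cells_axis = "cols"` for the transposed
#' orientation, in which case the header holds cell ids and the first column
#' feature ids). Sparse input is a MatrixMarket coordinate file with two
#' sidecar newline-delimited id files (rows and columns, 1-based indices per
#' the MTX standard); the matrix is densified on load.
#'
#' @param path path to the matrix file.
#' @param format `"dense"` or `"matrixmarket"`.
#' @param cells_axis whether cells are on `"rows"` (default) or `"cols"` of
#'   the stored matrix.
#' @param row_ids,col_ids for `matrixmarket`, paths to the sidecar id files
#'   for the rows and columns of the stored matrix.
#' @param condition_of condition labels (single name, per-cell vector, or a
#'   path to a two-column TSV of `cell_id<TAB>label`).
#' @param type_of optional type labels in the same forms; cells absent from a
#'   label file stay unlabeled.
#' @param sep field separator for dense input (guessed from the file
#'   extension when `NULL`: `.csv` uses comma, everything else tab).
#' @return An `expression_dataset` in the `counts` layer.
#' @export
load_expression <- function(path, format = c("dense", "matrixmarket"),
                            cells_axis = c("rows", "cols"),
                            row_ids = NULL, col_ids = NULL,
                            condition_of = "condition_1", type_of = NULL,
                            sep = NULL) {
  format <- match.arg(format)
  cells_axis <- match.arg(cells_axis)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense") {
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                             check.names = FALSE, comment.char = "")
    mat <- as.matrix(tab)
    if (!is.numeric(mat)) {
      bad <- which(!vapply(tab, is.numeric, logical(1)))[1]
      stop("parse error: non-numeric values in column '",
           colnames(tab)[bad], "' of ", path)
    }
  } else {
    if (is.null(row_ids) || is.null(col_ids))
      stop("matrixmarket input needs row_ids and col_ids sidecar files")
    for (f in c(row_ids, col_ids))
      if (!file.exists(f)) stop("file not found: ", f)
    sp <- Matrix::readMM(path)
    mat <- as.matrix(sp)
    rn <- readLines(row_ids)
    cn <- readLines(col_ids)
    if (length(rn) != nrow(mat))
      stop("shape error: ", length(rn), " row ids for ", nrow(mat), " rows")
    if (length(cn) != ncol(mat))
      stop("shape error: ", length(cn), " column ids for ", ncol(mat),
           " columns")
    dimnames(mat) <- list(rn, cn)
  }
  if (cells_axis == "cols") mat <- t(mat)
  condition_of <- resolve_labels(condition_of, rownames(mat),
                                 default = NULL, what = "condition")
  type_of <- resolve_labels(type_of, rownames(mat), default = UNLABELED,
                            what = "type")
  expression_dataset(mat, condition_of = condition_of, type_of = type_of,
                     layer = "counts")
}

# internal: turn a label spec (NULL / scalar / vector / TSV path) into a
# per-cell vector aligned with cell_ids
resolve_labels <- function(spec, cell_ids, default, what) {
  n <- length(cell_ids)
  if (is.null(spec)) {
    if (is.null(default)) stop("every cell needs a ", what, " label")
    return(rep(default, n))
  }
  if (length(spec) == 1L && is.character(spec) && file.exists(spec)) {
    tab <- utils::read.table(spec, header = FALSE, sep = "\t",
                             col.names = c("cell_id", "label"),
                             colClasses = "character")
    lab <- stats::setNames(tab$label, tab$cell_id)[cell_ids]
    if (is.null(default) && anyNA(lab))
      stop(what, " label file misses cell: ", cell_ids[is.na(lab)][1])
    lab[is.na(lab)] <- default
    return(unname(lab))
  }
  if (length(spec) == 1L) return(rep(spec, n))
  if (length(spec) != n)
    stop(what, " labels: expected ", n, " entries, got ", length(spec))
  as.character(spec)
}

#' Write a matrix as a TSV with cell ids in the first column
#'
#' @param mat matrix with rownames and colnames.
#' @param path output path.
#' @param id_name header for the id column.
#' @export
write_matrix_tsv <- function(mat, path, id_name = "cell_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  colnames(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
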