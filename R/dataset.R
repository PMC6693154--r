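#' Expression dataset container
#'
#' A light S3 container for a cells-by-features expression matrix together
#' with per-cell condition labels, optional per-cell type labels, and a
#' `layer` tag recording which stage of the preprocessing chain the values
#' represent (`counts`, `tp10k`, `log`, `scaled` or `pca`).
#'
#' Cells are rows, features are columns. Cell and feature identifiers must be
#' unique. Type labels may be missing for some or all cells; missing labels
#' are stored as the sentinel `"unlabeled"`, which is never a valid class.
#'
#' @param values numeric matrix, cells x features.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   rownames of `values`).
#' @param feature_ids character vector of unique feature identifiers
#'   (defaults to colnames of `values`).
#' @param condition_of character vector, one condition name per cell.
#' @param type_of optional character vector of per-cell type labels; `NA`
#'   entries are recoded to `"unlabeled"`.
#' @param layer processing-state tag, one of `"counts"`, `"tp10k"`, `"log"`,
#'   `"scaled"`, `"pca"`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, cell_ids = rownames(values),
                               feature_ids = colnames(values),
                               condition_of, type_of = NULL,
                               layer = "counts") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("feat_", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  layer <- match.arg(layer, c("counts", "tp10k", "log", "scaled", "pca"))
  if (nrow(values) != length(cell_ids))
    stop("row count (", nrow(values), ") != number of cell ids (",
         length(cell_ids), ")")
  if (ncol(values) != length(feature_ids))
    stop("column count (", ncol(values), ") != number of feature ids (",
         length(feature_ids), ")")
  if (anyDuplicated(cell_ids))
    stop("duplicated cell id: ", cell_ids[duplicated(cell_ids)][1])
  if (anyDuplicated(feature_ids))
    stop("duplicated feature id: ", feature_ids[duplicated(feature_ids)][1])
  condition_of <- as.character(condition_of)
  if (length(condition_of) == 1L)
    condition_of <- rep(condition_of, nrow(values))
  if (length(condition_of) != nrow(values))
    stop("condition_of must name a condition for every cell")
  if (anyNA(condition_of)) stop("every cell needs a condition label")
  if (is.null(type_of)) type_of <- rep(UNLABELED, nrow(values))
  type_of <- as.character(type_of)
  type_of[is.na(type_of)] <- UNLABELED
  if (length(type_of) != nrow(values))
    stop("type_of must have one entry per cell")
  if (layer == "counts" && any(values < 0))
    stop("counts layer must be non-negative")
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(
    list(values = values, cell_ids = cell_ids, feature_ids = feature_ids,
         condition_of = condition_of, type_of = type_of, layer = layer),
    class = "expression_dataset")
}

#' Sentinel used for cells without a type label
#' @export
UNLABELED <- "unlabeled"

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset: ", nrow(x$values), " cells x ", ncol(x$values),
      " features [layer: ", x$layer, "]\n", sep = "")
  tab <- table(x$condition_of)
  cat("conditions: ",
      paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "), "\n",
      sep = "")
  n_lab <- sum(x$type_of != UNLABELED)
  cat("typed cells: ", n_lab, "/", length(x$type_of), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Subset a dataset by cells and/or features
#'
#' @param ds an `expression_dataset`.
#' @param cells integer/logical/character index of cells to keep.
#' @param features integer/logical/character index of features to keep.
#' @return A new `expression_dataset`.
#' @export
subset_cells <- function(ds, cells = NULL, features = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  ci <- if (is.null(cells)) seq_along(ds$cell_ids) else cells
  if (is.character(ci)) ci <- match(ci, ds$cell_ids)
  fi <- if (is.null(features)) seq_along(ds$feature_ids) else features
  if (is.character(fi)) fi <- match(fi, ds$feature_ids)
  expression_dataset(ds$values[ci, fi, drop = FALSE],
                     cell_ids = ds$cell_ids[ci],
                     feature_ids = ds$feature_ids[fi],
                     condition_of = ds$condition_of[ci],
                     type_of = ds$type_of[ci],
                     layer = ds$layer)
}

#' Condition names present in a dataset
#' @param ds an `expression_dataset`.
#' @return Character vector of condition names in sorted order.
#' @export
conditions_of <- function(ds) sort(unique(ds$condition_of))

# internal: stop unless the dataset is in one of the given layers
check_layer <- function(ds, allowed) {
  if (!ds$layer %in% allowed)
    stop("expected layer in {", paste(allowed, collapse = ", "),
         "}, got '", ds$layer, "'")
  invisible(TRUE)
}
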