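#' Robust common marker genes per cell type
#'
#' Within each condition, every gene is tested per cell type (one-vs-rest
#' Wilcoxon rank-sum) and p values are Benjamini-Hochberg corrected; genes
#' with adjusted p below `alpha` and higher expression in the type form that
#' condition's marker set, expanded with genes correlated above
#' `corr_threshold` with any marker (correlation computed within the
#' condition). The robust common set for a type is the intersection of its
#' per-condition sets, so only markers reproducible across every condition
#' survive.
#'
#' @param ds an `expression_dataset` (normalised/scaled values).
#' @param labels per-cell type labels (complete within each condition;
#'   defaults to `ds$type_of`).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param corr_threshold correlation threshold for marker expansion
#'   (default 0.9).
#' @return Named list: cell type -> character vector of robust marker genes.
#' @export
robust_markers <- function(ds, labels = NULL, alpha = 0.05,
                           corr_threshold = 0.9) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(labels)) labels <- ds$type_of
  labels <- as.character(labels)
  conds <- conditions_of(ds)
  types <- sort(setdiff(unique(labels), UNLABELED))
  per_cond <- vector("list", length(conds))
  names(per_cond) <- conds
  for (cn in conds) {
    rows <- which(ds$condition_of == cn)
    X <- ds$values[rows, , drop = FALSE]
    lab <- labels[rows]
    sets <- list()
    for (ty in types) {
      in_ty <- lab == ty
      if (!any(in_ty) || all(in_ty)) {
        warning("cell type '", ty, "' cannot be tested in condition '", cn,
                "' (absent or sole type); skipped")
        next
      }
      p <- apply(X, 2, function(g) {
        if (stats::sd(g) == 0) return(1)
        stats::wilcox.test(g[in_ty], g[!in_ty], exact = FALSE)$p.value
      })
      up <- colMeans(X[in_ty, , drop = FALSE]) >
        colMeans(X[!in_ty, , drop = FALSE])
      padj <- stats::p.adjust(p, method = "BH")
      markers <- ds$feature_ids[padj < alpha & up]
      if (length(markers)) {
        cm <- suppressWarnings(
          stats::cor(X, X[, markers, drop = FALSE]))
        cm[is.na(cm)] <- 0
        expanded <- ds$feature_ids[apply(cm > corr_threshold, 1, any)]
        markers <- union(markers, expanded)
      }
      sets[[ty]] <- markers
    }
    per_cond[[cn]] <- sets
  }
  out <- lapply(types, function(ty) {
    have <- Filter(Negate(is.null), lapply(per_cond, `[[`, ty))
    if (!length(have)) character(0) else Reduce(intersect, have)
  })
  names(out) <- types
  out
}

#' Expression-matched control gene sets
#'
#' Genes are split into `n_bins` approximately equally sized bins by mean
#' expression across all cells; each control set is drawn (without
#' replacement within bins) to match the target set's size and per-bin
#' composition, giving a null ensemble matched for expression level.
#'
#' @param ds an `expression_dataset`.
#' @param target_set character vector of gene ids.
#' @param n_sets number of control sets (the conventional choice is 10,000).
#' @param n_bins number of expression bins (default 5).
#' @param seed RNG seed.
#' @return List of `n_sets` character vectors.
#' @export
matched_control_sets <- function(ds, target_set, n_sets = 10000L,
                                 n_bins = 5L, seed = 1L) {
  stopifnot(length(target_set) > 0)
  if (!all(target_set %in% ds$feature_ids))
    stop("target gene absent from dataset: ",
         setdiff(target_set, ds$feature_ids)[1])
  mean_expr <- colMeans(ds$values)
  bin_of <- gene_bins(mean_expr, n_bins)
  names(bin_of) <- ds$feature_ids
  need <- table(factor(bin_of[target_set], levels = seq_len(n_bins)))
  avail <- split(ds$feature_ids, bin_of)
  for (b in seq_len(n_bins)) {
    nb <- as.character(b)
    have <- if (nb %in% names(avail)) length(avail[[nb]]) else 0
    if (need[b] > have)
      stop("bin ", b, " has ", have, " genes but ", need[b], " are required")
  }
  withr::with_seed(seed, {
    lapply(seq_len(n_sets), function(i) {
      unlist(lapply(seq_len(n_bins), function(b) {
        nb <- as.character(b)
        if (need[b] == 0) return(character(0))
        sample(avail[[nb]], need[b])
      }), use.names = FALSE)
    })
  })
}

# internal: rank-based assignment of genes to approximately equal bins;
# tied mean expression shares a bin (all-equal input collapses to one bin)
gene_bins <- function(mean_expr, n_bins) {
  r <- rank(mean_expr, ties.method = "average")
  as.integer(ceiling(r * n_bins / length(mean_expr)))
}

#' Embedding deviation under in-silico gene-set zeroing
#'
#' Zeroes the expression of all genes in `gene_set` across all cells,
#' re-embeds, and reports the median and maximum per-cell Euclidean
#' displacement in alignment space. For encoders trained on PCA scores, the
#' stored projection is applied to the zeroed expression to derive the
#' perturbed scores.
#'
#' @param model a trained `alignment_model`.
#' @param ds gene-space `expression_dataset` matching the model's training
#'   expression layer (the dataset the PCA basis was computed on, when one
#'   is stored).
#' @param gene_set character vector of gene ids to zero.
#' @return List with `median_shift` and `max_shift`.
#' @export
perturb_embedding_shift <- function(model, ds, gene_set) {
  stopifnot(inherits(model, "alignment_model"))
  if (length(gene_set) &&
      !all(gene_set %in% ds$feature_ids))
    stop("gene absent from dataset: ",
         setdiff(gene_set, ds$feature_ids)[1])
  X <- ds$values
  Xz <- X
  Xz[, gene_set] <- 0
  if (!is.null(model$projection)) {
    X <- pca_project(X, model$projection)
    Xz <- pca_project(Xz, model$projection)
  }
  E0 <- embed_cells(model, X)
  E1 <- embed_cells(model, Xz)
  shift <- sqrt(rowSums((E1 - E0)^2))
  list(median_shift = stats::median(shift), max_shift = max(shift))
}

#' Permutation p value for an observed embedding deviation
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)`; the add-one keeps the p
#' value strictly positive, as is standard for permutation tests.
#'
#' @param observed_median observed median shift.
#' @param null_medians vector of median shifts from control gene sets.
#' @return p value in `(0, 1]`.
#' @export
perturbation_pvalue <- function(observed_median, null_medians) {
  stopifnot(length(null_medians) > 0)
  (1 + sum(null_medians >= observed_median)) / (1 + length(null_medians))
}

#' Full gene-set perturbation test
#'
#' Convenience wrapper: observed shift for `gene_set`, null shifts from
#' expression-matched control sets, permutation p value and fold enrichment
#' of the observed median over the null median.
#'
#' @inheritParams perturb_embedding_shift
#' @inheritParams matched_control_sets
#' @return List of class `gene_set_perturbation`: `gene_set`,
#'   `median_shift`, `max_shift`, `null_medians`, `p_value`, `fold_vs_null`.
#' @export
perturbation_test <- function(model, ds, gene_set, n_sets = 1000L,
                              n_bins = 5L, seed = 1L) {
  controls <- matched_control_sets(ds, gene_set, n_sets = n_sets,
                                   n_bins = n_bins, seed = seed)
  # baseline embedding is shared across the observed and all null shifts
  X <- ds$values
  X_in <- if (!is.null(model$projection)) pca_project(X, model$projection)
  else X
  E0 <- embed_cells(model, X_in)
  one_shift <- function(gs) {
    Xz <- X
    Xz[, gs] <- 0
    Xz_in <- if (!is.null(model$projection))
      pca_project(Xz, model$projection) else Xz
    E1 <- embed_cells(model, Xz_in)
    sqrt(rowSums((E1 - E0)^2))
  }
  if (length(gene_set) &&
      !all(gene_set %in% ds$feature_ids))
    stop("gene absent from dataset: ",
         setdiff(gene_set, ds$feature_ids)[1])
  obs_shift <- one_shift(gene_set)
  obs <- list(median_shift = stats::median(obs_shift),
              max_shift = max(obs_shift))
  null_medians <- vapply(controls, function(gs)
    stats::median(one_shift(gs)), numeric(1))
  structure(list(gene_set = gene_set,
                 median_shift = obs$median_shift,
                 max_shift = obs$max_shift,
                 null_medians = null_medians,
                 p_value = perturbation_pvalue(obs$median_shift,
                                               null_medians),
                 fold_vs_null = obs$median_shift /
                   stats::median(null_medians)),
            class = "gene_set_perturbation")
}
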