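#' Specification for the multi-condition synthetic generator
#'
#' Describes a multi-condition scRNA-seq-like study with discrete cell
#' types, planted marker genes, global and cell-type-specific condition
#' effects, library-size variation, negative-binomial counting noise and
#' logistic dropout. Defaults describe the package's standard desk-scale
#' instance: 3 cell types, 150 cells per type per condition, 2 conditions,
#' 500 genes, 10 markers per type, a global condition effect on 10% of
#' genes and a mild 20-gene effect restricted to one cell type.
#'
#' @param n_types number of cell types.
#' @param cells_per_type_per_condition scalar, or an `n_types` x
#'   `n_conditions` matrix of cell counts (to emulate ablation designs).
#' @param n_conditions number of conditions.
#' @param n_genes number of genes.
#' @param n_markers_per_type planted markers per type (disjoint across
#'   types).
#' @param marker_effect log-scale mean shift added to a type's markers.
#' @param condition_effect_global log-scale shift applied, for each
#'   condition after the first, to that condition's own random 10% of genes.
#' @param condition_effect_specific list of heterogeneous-response entries,
#'   each `list(type =, condition =, n_genes =, shift =)`: the shift is
#'   applied to a seeded random gene subset but only in cells of that type
#'   in that condition.
#' @param library_size_mean mean library size (total counts per cell).
#' @param library_size_dispersion log-normal sd of library sizes.
#' @param nb_dispersion negative-binomial dispersion phi
#'   (`var = mu + phi mu^2`).
#' @param dropout_midpoint,dropout_slope logistic dropout parameters: a
#'   count with expected value mu is zeroed with probability
#'   `plogis(-slope * (log(mu) - midpoint))`.
#' @param seed generator seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_types = 3L,
                           cells_per_type_per_condition = 150L,
                           n_conditions = 2L,
                           n_genes = 500L,
                           n_markers_per_type = 10L,
                           marker_effect = 2.0,
                           condition_effect_global = 0.75,
                           condition_effect_specific = list(
                             list(type = "type_2", condition = "condition_2",
                                  n_genes = 20L, shift = 0.5)),
                           library_size_mean = 2000,
                           library_size_dispersion = 0.3,
                           nb_dispersion = 0.5,
                           dropout_midpoint = 1.5,
                           dropout_slope = 1.0,
                           seed = 1L) {
  stopifnot(n_types >= 1, n_conditions >= 1, n_genes >= 1,
            n_markers_per_type >= 0, library_size_mean > 0,
            nb_dispersion > 0)
  if (n_types * n_markers_per_type > n_genes)
    stop("marker demand (", n_types * n_markers_per_type,
         ") exceeds n_genes (", n_genes, ")")
  cells <- cells_per_type_per_condition
  if (is.matrix(cells)) {
    stopifnot(nrow(cells) == n_types, ncol(cells) == n_conditions)
  } else {
    stopifnot(length(cells) == 1, cells >= 1)
    cells <- matrix(as.integer(cells), n_types, n_conditions)
  }
  structure(list(n_types = as.integer(n_types),
                 cells = cells,
                 n_conditions = as.integer(n_conditions),
                 n_genes = as.integer(n_genes),
                 n_markers_per_type = as.integer(n_markers_per_type),
                 marker_effect = marker_effect,
                 condition_effect_global = condition_effect_global,
                 condition_effect_specific = condition_effect_specific,
                 library_size_mean = library_size_mean,
                 library_size_dispersion = library_size_dispersion,
                 nb_dispersion = nb_dispersion,
                 dropout_midpoint = dropout_midpoint,
                 dropout_slope = dropout_slope,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a multi-condition scRNA-seq-like dataset
#'
#' Per gene g a baseline log-mean is drawn from Normal(1, 0.5). A cell of
#' type t gets `marker_effect` added on t's markers; condition c (c > 1)
#' adds `condition_effect_global` on its own fixed random 10% of genes, plus
#' any (type, condition)-specific shifts. The per-cell expected counts are
#' `library_size * softmax(log-means)`; observed counts are negative
#' binomial with dispersion `nb_dispersion` and are then zeroed with the
#' logistic dropout probability. Everything is driven by `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `dataset` (counts-layer `expression_dataset` with
#'   condition and type labels) and `truth` (list: `markers` per type,
#'   `global_effect_genes` per condition, `specific_effect_genes` per
#'   (type, condition) entry, and the per-cell `type_of`/`condition_of`).
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    G <- spec$n_genes
    genes <- sprintf("gene_%03d", seq_len(G))
    types <- paste0("type_", seq_len(spec$n_types))
    conds <- paste0("condition_", seq_len(spec$n_conditions))
    beta <- stats::rnorm(G, mean = 1, sd = 0.5)

    if (spec$n_markers_per_type > 0) {
      marker_pool <- sample(genes, spec$n_types * spec$n_markers_per_type)
      markers <- split(marker_pool,
                       rep(types, each = spec$n_markers_per_type))[types]
    } else {
      markers <- stats::setNames(rep(list(character(0)), length(types)),
                                 types)
    }

    n_global <- max(1L, round(0.1 * G))
    global_genes <- stats::setNames(vector("list", length(conds)), conds)
    for (ci in seq_along(conds))
      if (ci > 1 && spec$condition_effect_global != 0)
        global_genes[[ci]] <- sample(genes, n_global)

    spec_genes <- list()
    for (ent in spec$condition_effect_specific) {
      key <- paste(ent$type, ent$condition, sep = "|")
      spec_genes[[key]] <- list(type = ent$type, condition = ent$condition,
                                genes = sample(genes, ent$n_genes),
                                shift = ent$shift)
    }

    n_cells <- sum(spec$cells)
    type_of <- character(n_cells)
    cond_of <- character(n_cells)
    counts <- matrix(0L, n_cells, G, dimnames = list(NULL, genes))
    row <- 0L
    for (ci in seq_along(conds)) for (ti in seq_along(types)) {
      nc <- spec$cells[ti, ci]
      if (nc == 0) next
      lm <- beta
      gi <- match(markers[[types[ti]]], genes)
      lm[gi] <- lm[gi] + spec$marker_effect
      if (!is.null(global_genes[[ci]])) {
        gg <- match(global_genes[[ci]], genes)
        lm[gg] <- lm[gg] + spec$condition_effect_global
      }
      for (sg in spec_genes)
        if (sg$type == types[ti] && sg$condition == conds[ci]) {
          si <- match(sg$genes, genes)
          lm[si] <- lm[si] + sg$shift
        }
      w <- exp(lm - max(lm))
      p <- w / sum(w)
      lib <- stats::rlnorm(nc,
                           meanlog = log(spec$library_size_mean) -
                             spec$library_size_dispersion^2 / 2,
                           sdlog = spec$library_size_dispersion)
      mu <- outer(lib, p)                       # nc x G expected counts
      size <- 1 / spec$nb_dispersion
      cts <- matrix(stats::rnbinom(nc * G, size = size, mu = mu), nc, G)
      p_drop <- stats::plogis(-spec$dropout_slope *
                                (log(pmax(mu, 1e-12)) -
                                   spec$dropout_midpoint))
      drop <- matrix(stats::runif(nc * G) < p_drop, nc, G)
      cts[drop] <- 0L
      rows <- row + seq_len(nc)
      counts[rows, ] <- cts
      type_of[rows] <- types[ti]
      cond_of[rows] <- conds[ci]
      row <- row + nc
    }
    # guard against all-zero cells (possible at extreme dropout settings)
    zero <- rowSums(counts) == 0
    if (any(zero)) {
      j <- sample.int(G, sum(zero), replace = TRUE)
      counts[cbind(which(zero), j)] <- 1L
    }
    cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
    rownames(counts) <- cell_ids
    ds <- expression_dataset(counts, condition_of = cond_of,
                             type_of = type_of, layer = "counts")
    truth <- list(markers = markers,
                  global_effect_genes = global_genes,
                  specific_effect_genes = spec_genes,
                  type_of = stats::setNames(type_of, cell_ids),
                  condition_of = stats::setNames(cond_of, cell_ids))
    list(dataset = ds, truth = truth)
  })
}

#' Remove a fraction of one cell type from one condition
#'
#' Emulates cell-type ablation designs: a uniformly chosen
#' `round(fraction * count)` subset of the (type, condition) cells is
#' dropped; `fraction = 1` removes the type from that condition entirely.
#'
#' @param ds an `expression_dataset`.
#' @param condition,cell_type which cells are eligible for removal.
#' @param fraction fraction to remove, in `[0, 1]`.
#' @param seed selection seed.
#' @return The reduced `expression_dataset`.
#' @export
ablate_cells <- function(ds, condition, cell_type, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  hit <- which(ds$condition_of == condition & ds$type_of == cell_type)
  if (!length(hit))
    stop("no cells of type '", cell_type, "' in condition '", condition, "'")
  n_rm <- round(fraction * length(hit))
  if (n_rm == 0) return(ds)
  rm_idx <- withr::with_seed(seed, sample(hit, n_rm))
  subset_cells(ds, cells = setdiff(seq_along(ds$cell_ids), rm_idx))
}
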