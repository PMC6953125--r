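#' Remove genes expressed in too few cells
#'
#' A gene is "expressed" in a cell when its count is at least 1; genes
#' expressed in fewer than `min_cells` cells are dropped. The cell set is
#' never changed.
#'
#' @param matrix a [layered_cell_matrix()].
#' @param min_cells minimum number of expressing cells (default 15).
#' @return A [layered_cell_matrix()] with the retained genes.
#' @export
filter_low_expression <- function(matrix, min_cells = 15L) {
  stopifnot(inherits(matrix, "layered_cell_matrix"), min_cells >= 0)
  n_expr <- rowSums(matrix$counts >= 1)
  keep <- n_expr >= min_cells
  if (!any(keep)) {
    warning("filter_low_expression: no gene passes the ", min_cells,
            "-cell filter")
  }
  layered_cell_matrix(matrix$counts[keep, , drop = FALSE], matrix$layer_probs)
}

#' Normalize single-cell counts with median-of-ratios size factors
#'
#' Size factor of a cell = median, over reference genes, of the ratio of its
#' count to the gene's geometric mean count across cells. Reference genes are
#' those with nonzero counts in every cell (nonzero geometric mean), which
#' makes the estimator exactly scale-equivariant; when a sparse UMI matrix has
#' no such gene, the geometric means and per-cell medians are computed over
#' nonzero entries only. Factors are rescaled to geometric mean 1 and divided
#' out of the counts. Only cross-cell scaling matters downstream because the
#' trend screen is rank-based.
#'
#' @param matrix a [layered_cell_matrix()] (or plain genes x cells matrix).
#' @return A list with `normalized` (genes x cells matrix) and `size_factors`
#'   (per-cell, geometric mean 1).
#' @export
normalize_cells <- function(matrix) {
  counts <- if (inherits(matrix, "layered_cell_matrix")) matrix$counts else
    as.matrix(matrix)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    stop("normalize_cells: cell(s) with zero total counts: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  sf <- cell_size_factors(counts)
  sf <- sf / exp(mean(log(sf)))
  normalized <- sweep(counts, 2, sf, "/")
  list(normalized = normalized, size_factors = sf)
}

## median-of-ratios; strict (all-cell) reference genes when any exist,
## nonzero-entry variant otherwise
cell_size_factors <- function(counts) {
  dense <- rowSums(counts > 0) == ncol(counts)
  if (any(dense)) {
    gm <- exp(rowMeans(log(counts[dense, , drop = FALSE])))
    sf <- apply(counts[dense, , drop = FALSE] / gm, 2, stats::median)
  } else {
    logc <- log(counts)
    logc[!is.finite(logc)] <- NA
    gm <- exp(rowMeans(logc, na.rm = TRUE))  # geometric mean over expressing cells
    ratios <- counts / gm
    ratios[counts == 0] <- NA
    sf <- apply(ratios, 2, stats::median, na.rm = TRUE)
  }
  if (any(!is.finite(sf))) {
    stop("normalize_cells: size factor undefined for cell(s) ",
         paste(utils::head(colnames(counts)[!is.finite(sf)], 5),
               collapse = ", "))
  }
  sf
}

#' Assign each cell to its most probable lobule layer
#'
#' Returns, per cell, the layer with the highest membership probability; ties
#' are broken toward the lowest layer index so results are deterministic.
#'
#' @param layer_probs cells x layers probability matrix; rows must sum to 1
#'   within 1e-9.
#' @return Integer vector of layer indices, named by cell.
#' @export
assign_layers <- function(layer_probs) {
  layer_probs <- as.matrix(layer_probs)
  check_prob_rows(layer_probs)
  out <- max.col(layer_probs, ties.method = "first")
  names(out) <- rownames(layer_probs)
  out
}

#' Call pericentral and periportal genes by monotone trend across layers
#'
#' Runs the Jonckheere-Terpstra test on each gene's normalized expression
#' across the ordered layers, corrects p-values with Benjamini-Hochberg over
#' all tested genes, and labels genes with q at or below the threshold as
#' periportal (increasing trend, z > 0) or pericentral (decreasing, z < 0).
#'
#' @param normalized genes x cells matrix of normalized expression.
#' @param layers per-cell layer assignment from [assign_layers()].
#' @param fdr_threshold FDR cutoff for a zonation call (default 0.001).
#' @param mode passed to [jt_test()]; with hundreds of cells per layer the
#'   asymptotic branch is always taken under `"auto"`.
#' @return A data frame (one row per gene) with columns `gene_id`, `U`, `z`,
#'   `p`, `q`, `direction`.
#' @export
call_zonation <- function(normalized, layers, fdr_threshold = 0.001,
                          mode = "auto") {
  normalized <- as.matrix(normalized)
  stopifnot(ncol(normalized) == length(layers))
  occupied <- sort(unique(layers))
  if (length(occupied) < 2L) {
    stop("call_zonation: fewer than 2 occupied layers")
  }
  g <- factor(layers, levels = occupied)
  res <- t(vapply(seq_len(nrow(normalized)), function(i) {
    r <- jt_test(normalized[i, ], g, mode = mode)
    c(r$U, r$z, r$p)
  }, numeric(3)))
  q <- bh_fdr(res[, 3])
  direction <- ifelse(q <= fdr_threshold & res[, 2] > 0, "periportal",
               ifelse(q <= fdr_threshold & res[, 2] < 0, "pericentral",
                      "none"))
  data.frame(
    gene_id = rownames(normalized),
    U = res[, 1], z = res[, 2], p = res[, 3], q = q,
    direction = direction,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Update gene symbols through an alias table
#'
#' Replaces every set member by its current symbol when the alias table maps
#' it; members collapsing onto the same symbol are deduplicated.
#'
#' @param set a [gene_set()].
#' @param aliases named character vector (old symbol -> current symbol) or a
#'   two-column data frame (old, current).
#' @return The updated [gene_set()].
#' @export
map_aliases <- function(set, aliases) {
  stopifnot(inherits(set, "gene_set"))
  if (is.data.frame(aliases)) {
    aliases <- stats::setNames(as.character(aliases[[2]]),
                               as.character(aliases[[1]]))
  }
  if (anyDuplicated(names(aliases))) {
    stop("map_aliases: alias table maps a symbol to multiple outputs")
  }
  m <- set$members
  hit <- m %in% names(aliases)
  m[hit] <- unname(aliases[m[hit]])
  gene_set(set$name, m, direction = set$direction)
}

#' Build consensus zonation sets across studies
#'
#' A gene enters the consensus pericentral (periportal) set when at least
#' `min_studies` studies report it as pericentral (periportal). Genes that
#' qualify in both directions are excluded from both sets and returned
#' separately.
#'
#' @param per_study_sets list of studies, each a list with elements
#'   `pericentral` and `periportal` ([gene_set()]s, alias-mapped already).
#' @param min_studies minimum number of reporting studies (default 2).
#' @return A list with `pericentral` and `periportal` consensus
#'   [gene_set()]s and `conflicts` (genes qualifying in both directions).
#' @export
build_consensus <- function(per_study_sets, min_studies = 2L) {
  if (min_studies < 1L) stop("build_consensus: min_studies must be >= 1")
  if (length(per_study_sets) < min_studies) {
    stop("build_consensus: fewer studies than min_studies")
  }
  tally <- function(direction) {
    all_m <- unlist(lapply(per_study_sets, function(s) s[[direction]]$members))
    counts <- table(all_m)
    names(counts)[counts >= min_studies]
  }
  pc <- tally("pericentral")
  pp <- tally("periportal")
  conflicts <- intersect(pc, pp)
  if (length(conflicts)) {
    message("build_consensus: ", length(conflicts),
            " gene(s) qualify in both directions; excluded: ",
            paste(utils::head(conflicts, 10), collapse = ", "))
  }
  list(
    pericentral = gene_set("consensus_pericentral", sort(setdiff(pc, conflicts)),
                           direction = "pericentral"),
    periportal = gene_set("consensus_periportal", sort(setdiff(pp, conflicts)),
                          direction = "periportal"),
    conflicts = conflicts
  )
}
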