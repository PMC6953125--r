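#' Layered single-cell count matrix
#'
#' Couples a genes x cells count matrix with a cells x layers matrix of
#' layer-membership probabilities. Layer 1 is the most pericentral and the
#' last layer the most periportal.
#'
#' @param counts genes x cells matrix of non-negative integer counts, with
#'   row and column names.
#' @param layer_probs cells x layers numeric matrix; every row must sum to 1
#'   within 1e-9 and all entries lie in \[0, 1\].
#' @return An object of class `layered_cell_matrix`.
#' @export
layered_cell_matrix <- function(counts, layer_probs) {
  counts <- as.matrix(counts)
  layer_probs <- as.matrix(layer_probs)
  if (ncol(counts) != nrow(layer_probs)) {
    stop("layer_probs must have one row per cell (column of counts)")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  check_prob_rows(layer_probs)
  structure(
    list(counts = counts, layer_probs = layer_probs,
         gene_ids = rownames(counts), cell_ids = colnames(counts),
         n_layers = ncol(layer_probs)),
    class = "layered_cell_matrix"
  )
}

check_prob_rows <- function(p, tol = 1e-9) {
  if (any(p < 0) || any(p > 1)) {
    stop("layer probabilities must lie in [0, 1]")
  }
  bad <- which(abs(rowSums(p) - 1) > tol)
  if (length(bad)) {
    stop("probability rows not summing to 1: rows ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.layered_cell_matrix <- function(x, ...) {
  cat("layered_cell_matrix:", nrow(x$counts), "genes x",
      ncol(x$counts), "cells,", x$n_layers, "layers\n")
  invisible(x)
}

#' Bulk count experiment with treatment x month design
#'
#' @param counts genes x samples matrix of non-negative integer counts.
#' @param design data frame with columns `sample`, `treatment` (one of
#'   untreated, oil, ccl4), `month` (0, 2, 6 or 12) and `replicate`; `sample`
#'   must match the column names of `counts`.
#' @return An object of class `bulk_experiment`.
#' @export
bulk_experiment <- function(counts, design) {
  counts <- as.matrix(counts)
  stopifnot(is.data.frame(design),
            all(c("sample", "treatment", "month", "replicate") %in%
                  names(design)))
  if (!identical(colnames(counts), as.character(design$sample))) {
    stop("design$sample must match the count matrix columns, in order")
  }
  if (!all(design$treatment %in% c("untreated", "oil", "ccl4"))) {
    stop("unknown treatment level in design")
  }
  if (!all(design$month %in% c(0L, 2L, 6L, 12L))) {
    stop("unknown month in design")
  }
  structure(list(counts = counts, design = design), class = "bulk_experiment")
}

#' @export
print.bulk_experiment <- function(x, ...) {
  grp <- table(paste(x$design$treatment, x$design$month, sep = "_m"))
  cat("bulk_experiment:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", paste(names(grp), grp, sep = ":", collapse = ", "), ")\n")
  invisible(x)
}

#' Gene set
#'
#' A named set of gene identifiers with an optional zonation direction tag.
#'
#' @param name set name.
#' @param members character vector of gene ids; duplicates are removed.
#' @param direction one of `"pericentral"`, `"periportal"`, `"untagged"`.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members,
                     direction = c("untagged", "pericentral", "periportal")) {
  direction <- match.arg(direction)
  structure(list(name = name, members = unique(as.character(members)),
                 direction = direction),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "' (", x$direction, "): ",
      length(x$members), " genes\n", sep = "")
  invisible(x)
}
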