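#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   (name, description, members...).
#' @return Named list of [gene_set()]s.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("read_gmt: malformed line in ", path)
    desc <- f[2]
    dir <- if (desc %in% c("pericentral", "periportal")) desc else "untagged"
    gene_set(f[1], f[-(1:2)], direction = dir)
  })
  stats::setNames(sets, vapply(sets, function(s) s$name, character(1)))
}

#' Write gene sets to a GMT file
#'
#' The description column carries the direction tag.
#'
#' @param sets a [gene_set()] or list of them.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$direction, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a count matrix from TSV or MatrixMarket files
#'
#' `path` may be a TSV with gene ids in the first column and samples/cells in
#' the header, or a MatrixMarket `.mtx` file with sibling `<stem>_genes.tsv`
#' and `<stem>_cells.tsv` index files (one id per line).
#'
#' @param path input file.
#' @return A genes x columns integer matrix with dimnames.
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, "_genes.tsv"))
    colnames(m) <- readLines(paste0(stem, "_cells.tsv"))
    m
  } else {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
}

#' Write a count matrix as MatrixMarket plus index files, or TSV
#'
#' @param counts genes x columns matrix.
#' @param path output path; `.mtx` selects MatrixMarket (with `<stem>_genes.tsv`
#'   and `<stem>_cells.tsv` index files), anything else tab-separated text.
#' @export
write_counts <- function(counts, path) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(counts), paste0(stem, "_genes.tsv"))
    writeLines(colnames(counts), paste0(stem, "_cells.tsv"))
  } else {
    write_tsv(data.frame(gene_id = rownames(counts), counts,
                         check.names = FALSE), path)
  }
  invisible(path)
}

#' Read a cells x layers probability matrix from TSV
#'
#' First column = cell id, remaining columns = layers in order.
#' @param path input TSV.
#' @return Numeric matrix with cell rownames.
#' @export
read_layer_probs <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a bulk design table from TSV
#'
#' Columns: sample, treatment, month, replicate.
#' @param path input TSV.
#' @return Data frame.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "treatment", "month", "replicate")
  if (!all(need %in% names(df))) {
    stop("read_design: design table needs columns ",
         paste(need, collapse = ", "))
  }
  df$month <- as.integer(df$month)
  df
}

#' Read a footprint weight model from long-format TSV
#'
#' Columns: pathway, gene, weight (signed, nonzero).
#' @param path input TSV.
#' @return Named list of named weight vectors, as [footprint_scores()] expects.
#' @export
read_footprint_model <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pathway", "gene", "weight") %in% names(df)))
  df <- df[df$weight != 0, ]
  lapply(split(df, df$pathway), function(d) {
    stats::setNames(d$weight, d$gene)
  })
}

#' Read signed regulons from TSV
#'
#' Columns: tf, target, mode (+1 or -1).
#' @param path input TSV.
#' @return Named list of named mode vectors, as [regulon_activity()] expects.
#' @export
read_regulons <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "target", "mode") %in% names(df)))
  if (!all(df$mode %in% c(-1, 1))) stop("read_regulons: mode must be +1 or -1")
  lapply(split(df, df$tf), function(d) stats::setNames(d$mode, d$target))
}

#' Write a data frame as TSV
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature (gene, statistic) from TSV
#' @param path two-column TSV (gene_id, t or stat).
#' @return Ranked signature via [rank_signature()].
#' @export
read_signature <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_id", "t")
  rank_signature(df)
}
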