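#' Build a ranked signature from a contrast table
#'
#' Orders genes by the moderated t-statistic, descending (upregulated genes at
#' the top). Exact ties are broken lexicographically by gene id so the ranking
#' is deterministic.
#'
#' @param rows data frame with columns `gene_id` and `t` (finite, one row per
#'   gene).
#' @return A data frame of class `signature` with columns `gene_id`, `stat`,
#'   sorted descending by `stat`.
#' @export
rank_signature <- function(rows) {
  stopifnot(all(c("gene_id", "t") %in% names(rows)))
  if (anyDuplicated(rows$gene_id)) {
    stop("rank_signature: duplicate gene ids")
  }
  if (any(!is.finite(rows$t))) stop("rank_signature: non-finite statistics")
  ord <- order(-rows$t, rows$gene_id)
  out <- data.frame(gene_id = rows$gene_id[ord], stat = rows$t[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("signature", "data.frame")
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked signature; at each set member ("hit") the running sum
#' increases by |stat|^weight_exponent normalized over all hits, at each
#' non-member it decreases by 1/(n - k). The enrichment score is the running
#' sum value of maximal absolute deviation from zero.
#'
#' @param signature a [rank_signature()] result (or data frame with `gene_id`,
#'   `stat` sorted descending).
#' @param set a [gene_set()]; members absent from the signature are dropped
#'   (their count is recorded in the result).
#' @param weight_exponent exponent on |stat| for hit increments (default 1;
#'   0 gives the unweighted KS statistic).
#' @return A list with `es`, `running` (length-n profile), `peak` (index of
#'   the extremum), `hits` (logical length n), `n_dropped`.
#' @export
gsea_es <- function(signature, set, weight_exponent = 1) {
  stopifnot(inherits(set, "gene_set"))
  hits <- signature$gene_id %in% set$members
  n_dropped <- length(set$members) - sum(hits)
  if (!any(hits)) stop("gsea_es: no set member present in the signature")
  n <- nrow(signature)
  k <- sum(hits)
  w <- abs(signature$stat)^weight_exponent
  w[!hits] <- 0
  total_w <- sum(w)
  if (total_w == 0) w[hits] <- 1 / k else w <- w / total_w
  step <- w
  step[!hits] <- -1 / (n - k)
  running <- cumsum(step)
  peak <- which.max(abs(running))
  list(es = running[peak], running = running, peak = peak, hits = hits,
       n_dropped = n_dropped)
}

## Fast ES for a set given by hit positions in a ranked signature.
## pos must be sorted increasing; wabs = |stat|^exponent over the whole
## signature. Returns the signed ES only.
es_from_positions <- function(pos, wabs, n) {
  k <- length(pos)
  wh <- wabs[pos]
  tw <- sum(wh)
  cw <- if (tw == 0) seq_len(k) / k else cumsum(wh) / tw
  miss <- 1 / (n - k)
  ## running sum just after hit i and just before hit i
  after <- cw - (pos - seq_len(k)) * miss
  before <- c(0, cw[-k]) - (pos - 1 - (seq_len(k) - 1)) * miss
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Permutation GSEA test
#'
#' Tests the observed enrichment score against a null of random same-size gene
#' sets drawn from the signature. The p-value is one-tailed on the observed
#' sign: with b extreme draws among the m sign-matched null ES values,
#' p = (1 + b) / (1 + m), so it is calibrated (uniform under the null) and
#' floored at its attainable minimum. NES is the observed ES divided by the
#' mean |null ES| of matching sign.
#'
#' @param signature a ranked signature.
#' @param set a [gene_set()].
#' @param n_perm number of null sets (default 1e5; minimum 100).
#' @param seed integer seed for the null draws.
#' @param weight_exponent passed to [gsea_es()].
#' @return A data frame (one row) with columns `set`, `es`, `nes`, `p_perm`,
#'   `n_perm`, `size`, plus attribute `leading_edge`.
#' @export
gsea_test <- function(signature, set, n_perm = 1e5, seed = 1L,
                      weight_exponent = 1) {
  if (n_perm < 100) stop("gsea_test: n_perm must be at least 100")
  obs <- gsea_es(signature, set, weight_exponent)
  n <- nrow(signature)
  k <- sum(obs$hits)
  wabs <- abs(signature$stat)^weight_exponent
  set.seed(as.integer(seed))
  null_es <- vapply(seq_len(n_perm), function(i) {
    es_from_positions(sort.int(sample.int(n, k)), wabs, n)
  }, numeric(1))
  same_sign <- if (obs$es >= 0) null_es >= 0 else null_es <= 0
  b <- sum(same_sign & abs(null_es) >= abs(obs$es))
  p <- (1 + b) / (1 + max(1L, sum(same_sign)))
  denom <- mean(abs(null_es[same_sign]))
  nes <- if (is.finite(denom) && denom > 0) obs$es / denom else 0
  le <- leading_edge(signature, set, obs)
  out <- data.frame(set = set$name, es = obs$es, nes = nes, p_perm = p,
                    n_perm = n_perm, size = k,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "leading_edge") <- le
  out
}

#' Leading-edge genes of an enrichment result
#'
#' For a positive enrichment score, the set members ranked at or before the
#' running-sum peak; for a negative score, the members at or after it.
#'
#' @param signature the ranked signature used for `es_result`.
#' @param set the [gene_set()] used for `es_result`.
#' @param es_result result of [gsea_es()] on the same inputs.
#' @return Character vector of leading-edge gene ids (ranking order).
#' @export
leading_edge <- function(signature, set, es_result) {
  if (es_result$es == 0) return(character(0))
  idx <- which(es_result$hits)
  if (es_result$es > 0) {
    sel <- idx[idx <= es_result$peak]
  } else {
    sel <- idx[idx >= es_result$peak]
  }
  signature$gene_id[sel]
}

#' Over-representation analysis by Fisher's exact test
#'
#' One-sided (enrichment) Fisher exact test of the overlap between a query
#' gene list and a gene set against a fixed background universe; the p-value
#' is the hypergeometric upper tail. The odds ratio is computed from the 2x2
#' table, with a 0.5 continuity correction applied (and flagged) only when a
#' cell is zero.
#'
#' @param query a [gene_set()] (e.g. an overlap or DE gene list).
#' @param set a [gene_set()] to test against.
#' @param background_n background universe size (default 20000).
#' @return A data frame (one row): `set`, `k` (overlap), `n` (query size),
#'   `K` (set size), `N` (background), `odds_ratio`, `p`,
#'   `continuity_corrected`.
#' @export
ora_test <- function(query, set, background_n = 20000) {
  stopifnot(inherits(query, "gene_set"), inherits(set, "gene_set"))
  k <- length(intersect(query$members, set$members))
  n <- length(query$members)
  K <- length(set$members)
  N <- background_n
  if (N < length(union(query$members, set$members))) {
    stop("ora_test: background smaller than the union of query and set")
  }
  tab <- c(k, n - k, K - k, N - n - K + k)
  if (any(tab < 0)) stop("ora_test: inconsistent counts")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  cc <- any(tab == 0)
  t2 <- if (cc) tab + 0.5 else tab
  or <- (t2[1] * t2[4]) / (t2[2] * t2[3])
  data.frame(set = set$name, k = k, n = n, K = K, N = N,
             odds_ratio = or, p = p, continuity_corrected = cc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Footprint pathway activity scores
#'
#' Raw pathway score = sum over the model's footprint genes (present in the
#' signature) of weight times gene statistic. Significance is assessed by
#' permuting the gene-to-statistic assignment: the z-score standardizes the
#' raw score against that permutation null.
#'
#' @param signature a ranked signature (or data frame with `gene_id`, `stat`).
#' @param model named list: per pathway, a named numeric vector of signed gene
#'   weights (no zero weights stored).
#' @param n_perm permutations of the gene-statistic assignment (default 1e4).
#' @param seed integer seed.
#' @return A data frame with one row per pathway: `pathway`, `n_genes`,
#'   `score`, `z`.
#' @export
footprint_scores <- function(signature, model, n_perm = 1e4, seed = 1L) {
  stats_all <- stats::setNames(signature$stat, signature$gene_id)
  stats_all <- stats_all[order(names(stats_all))]  # order-independent null
  set.seed(as.integer(seed))
  out <- lapply(names(model), function(pw) {
    w <- model[[pw]]
    w <- w[names(w) %in% names(stats_all)]
    if (length(w) == 0) stop("footprint_scores: no overlap for pathway ", pw)
    raw <- sum(w * stats_all[names(w)])
    perm <- vapply(seq_len(n_perm), function(i) {
      sum(w * sample(stats_all, length(w)))
    }, numeric(1))
    sdn <- stats::sd(perm)
    z <- if (is.finite(sdn) && sdn > 0) (raw - mean(perm)) / sdn else 0
    data.frame(pathway = pw, n_genes = length(w), score = raw, z = z,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Regulon (transcription-factor) activity scores
#'
#' Rank-transforms the signature statistics to standard-normal quantiles and
#' scores each regulon as the mode-signed sum of its targets' quantiles,
#' scaled by the square root of the target count — a rank-based normalized
#' enrichment score for TF activity.
#'
#' @param signature a ranked signature.
#' @param regulons named list: per TF, a named numeric vector of target modes
#'   (+1 activating, -1 repressing).
#' @return A data frame with one row per TF: `tf`, `n_targets`, `nes`.
#' @export
regulon_activity <- function(signature, regulons) {
  n <- nrow(signature)
  ## larger statistic -> larger quantile
  r <- rank(signature$stat, ties.method = "average")
  q <- stats::qnorm(r / (n + 1))
  names(q) <- signature$gene_id
  out <- lapply(names(regulons), function(tf) {
    mode <- regulons[[tf]]
    mode <- mode[names(mode) %in% names(q)]
    if (length(mode) == 0) {
      stop("regulon_activity: no target of ", tf, " in the signature")
    }
    nes <- sum(mode * q[names(mode)]) / sqrt(length(mode))
    data.frame(tf = tf, n_targets = length(mode), nes = nes,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Periportalization report
#'
#' Runs the permutation GSEA of the consensus pericentral and periportal sets
#' against each month's ranked signature. P-values are not adjusted across
#' the two sets. A periportalized signature shows negative enrichment of the
#' pericentral set and positive enrichment of the periportal set.
#'
#' @param signatures_by_month named list of ranked signatures (e.g. from
#'   [rank_signature()] per contrast month).
#' @param pericentral,periportal consensus [gene_set()]s (non-empty).
#' @param n_perm,seed passed to [gsea_test()]; each (month, set) pair uses a
#'   distinct seed derived from `seed`.
#' @return A data frame with one row per (month, set direction): `month`,
#'   `direction`, `es`, `nes`, `p_perm`, `size`, `n_leading_edge`.
#' @export
periportalization_report <- function(signatures_by_month, pericentral,
                                     periportal, n_perm = 1e4, seed = 1L) {
  stopifnot(length(pericentral$members) > 0, length(periportal$members) > 0)
  sets <- list(pericentral = pericentral, periportal = periportal)
  rows <- list()
  i <- 0L
  for (m in names(signatures_by_month)) {
    for (d in names(sets)) {
      i <- i + 1L
      r <- gsea_test(signatures_by_month[[m]], sets[[d]], n_perm = n_perm,
                     seed = as.integer(seed) + i)
      rows[[i]] <- data.frame(
        month = m, direction = d, es = r$es, nes = r$nes,
        p_perm = r$p_perm, size = r$size,
        n_leading_edge = length(attr(r, "leading_edge")),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
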