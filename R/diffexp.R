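#' TMM-normalized log2 counts per million
#'
#' Computes trimmed-mean-of-M-values scale factors (30% trim on M-values, 5%
#' on A-values, inverse-asymptotic-variance precision weights; reference
#' sample = the one whose upper-quartile count fraction is closest to the
#' mean upper quartile), rescales them to geometric mean 1, and returns
#' log2(CPM + 0.5) on the effective library sizes. The pseudocount is applied
#' on the CPM scale, which makes the transform exactly invariant to scaling a
#' sample's counts.
#'
#' @param experiment a [bulk_experiment()] or a genes x samples count matrix.
#' @return A list with `logcpm` (genes x samples), `factors` (TMM scale
#'   factors, geometric mean 1) and `lib_sizes`.
#' @export
normalize_bulk <- function(experiment) {
  counts <- if (inherits(experiment, "bulk_experiment")) experiment$counts else
    as.matrix(experiment)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("normalize_bulk: sample(s) with zero total counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  f <- tmm_factors(counts, lib)
  f <- f / exp(mean(log(f)))
  eff <- lib * f
  cpm <- sweep(counts, 2, eff / 1e6, "/")
  list(logcpm = log2(cpm + 0.5), factors = f, lib_sizes = lib)
}

## TMM scale factors relative to an automatically chosen reference column.
tmm_factors <- function(counts, lib = colSums(counts),
                        trim_m = 0.3, trim_a = 0.05) {
  p <- sweep(counts, 2, lib, "/")           # count fractions
  uq <- apply(p, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f
}

tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  ## inverse asymptotic variance of M (delta method, binomial sampling)
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & is.finite(w)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (length(m) == 0) return(1)
  if (max(abs(m)) < 1e-6) return(1)        # identical composition
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(sel)) return(1)
  f <- sum(m[sel] / w[sel]) / sum(1 / w[sel])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Impute the missing month-6 oil group
#'
#' The design lacks oil controls at month 6; their log expression is imputed
#' as the elementwise arithmetic mean of the month-2 and month-12 oil group
#' means. The imputed group carries no samples and must contribute no
#' residual degrees of freedom downstream.
#'
#' @param logexpr_oil_m2,logexpr_oil_m12 per-gene mean log expression of the
#'   two observed oil groups, identically named/ordered.
#' @return Named numeric vector of imputed month-6 oil log expression, with
#'   attribute `imputed = TRUE`.
#' @export
impute_oil_month6 <- function(logexpr_oil_m2, logexpr_oil_m12) {
  if (length(logexpr_oil_m2) != length(logexpr_oil_m12) ||
      (!is.null(names(logexpr_oil_m2)) &&
       !identical(names(logexpr_oil_m2), names(logexpr_oil_m12)))) {
    stop("impute_oil_month6: gene lists do not match")
  }
  out <- (logexpr_oil_m2 + logexpr_oil_m12) / 2
  attr(out, "imputed") <- TRUE
  out
}

#' Per-gene group-mean fits and CCl4-vs-oil contrasts
#'
#' Fits, per gene, ordinary least squares on the (treatment, month) group
#' means of the log expression matrix and evaluates the contrast
#' ccl4(month) - oil(month) for each requested month. The month-6 oil mean is
#' imputed via [impute_oil_month6()], expressed as (oil_m2 + oil_m12)/2 in the
#' contrast so the standard error follows from the real groups; the imputed
#' group contributes zero residual degrees of freedom. The residual variance
#' is pooled across all real groups.
#'
#' @param logexpr genes x samples matrix (e.g. `normalize_bulk()$logcpm`).
#' @param design design data frame as in [bulk_experiment()].
#' @param months months for which to form the ccl4 - oil contrast
#'   (default `c(2, 6, 12)`).
#' @return A list with `logFC` (genes x months), `stderr_unit` (per-month
#'   contrast standard-error multiplier, in units of the residual sd),
#'   `s_sq` (per-gene pooled residual variance), `df` (residual degrees of
#'   freedom) and `mean_expr` (per-gene average log expression).
#' @export
fit_contrasts <- function(logexpr, design, months = c(2, 6, 12)) {
  logexpr <- as.matrix(logexpr)
  stopifnot(ncol(logexpr) == nrow(design))
  grp <- paste(design$treatment, design$month, sep = "_m")
  glev <- unique(grp)
  n_g <- table(factor(grp, levels = glev))
  if (any(n_g < 2)) stop("fit_contrasts: every fitted group needs >= 2 replicates")
  G <- nrow(logexpr)

  ## group means and pooled residual variance
  means <- vapply(glev, function(g)
    rowMeans(logexpr[, grp == g, drop = FALSE]), numeric(G))
  df <- ncol(logexpr) - length(glev)
  if (df <= 0) stop("fit_contrasts: residual degrees of freedom <= 0")
  resid <- logexpr - means[, match(grp, glev)]
  s_sq <- rowSums(resid^2) / df

  has_oil_m6 <- "oil_m6" %in% glev
  logFC <- matrix(NA_real_, G, length(months),
                  dimnames = list(rownames(logexpr), paste0("m", months)))
  stderr_unit <- numeric(length(months))
  names(stderr_unit) <- paste0("m", months)
  for (i in seq_along(months)) {
    m <- months[i]
    ccl4 <- paste0("ccl4_m", m)
    oil <- paste0("oil_m", m)
    if (!ccl4 %in% glev) stop("fit_contrasts: missing group ", ccl4)
    cvec <- stats::setNames(numeric(length(glev)), glev)
    cvec[ccl4] <- 1
    if (oil %in% glev) {
      cvec[oil] <- -1
    } else if (m == 6 && all(c("oil_m2", "oil_m12") %in% glev)) {
      oil_m6 <- impute_oil_month6(means[, "oil_m2"], means[, "oil_m12"])
      stopifnot(isTRUE(attr(oil_m6, "imputed")))
      cvec["oil_m2"] <- -0.5
      cvec["oil_m12"] <- -0.5
    } else {
      stop("fit_contrasts: missing group ", oil, " and no imputation rule")
    }
    logFC[, i] <- means %*% cvec
    stderr_unit[i] <- sqrt(sum(cvec^2 / as.numeric(n_g)))
  }
  list(logFC = logFC, stderr_unit = stderr_unit, s_sq = s_sq, df = df,
       mean_expr = rowMeans(logexpr))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method-of-moments fit of a scaled inverse-chi-squared prior to the per-gene
#' residual variances, on the log scale: the excess dispersion of log s^2 over
#' the sampling trigamma term determines the prior degrees of freedom d0 (via
#' the monotone inverse of the trigamma function), and the mean determines the
#' prior variance s0^2. Zero or negative excess dispersion yields d0 = Inf
#' (all gene variances shrunk fully to s0^2).
#'
#' @param s_sq per-gene residual variances (length >= 10, positive).
#' @param df residual degrees of freedom (scalar, shared by all genes).
#' @return A list with `d0` and `s0_sq`.
#' @export
estimate_eb_prior <- function(s_sq, df) {
  s_sq <- s_sq[is.finite(s_sq) & s_sq > 0]
  if (length(s_sq) < 10) {
    stop("estimate_eb_prior: need at least 10 positive finite variances")
  }
  stopifnot(df >= 1)
  z <- log(s_sq)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  evar <- sum((e - ebar)^2) / (n - 1) - trigamma(df / 2)
  if (evar <= 0) {
    ## no excess dispersion: point-mass prior at the average variance
    return(list(d0 = Inf, s0_sq = mean(s_sq)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

## monotone Newton iteration on trigamma(y) = x, y > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated t-statistics
#'
#' Shrinks each gene's residual variance toward the empirical-Bayes prior,
#' s_tilde^2 = (d0 s0^2 + df s^2) / (d0 + df), and tests logFC / (stderr_unit
#' * s_tilde) against a t distribution with d0 + df degrees of freedom
#' (standard normal when d0 is infinite). With d0 = 0 this is the ordinary
#' t-statistic.
#'
#' @param logFC per-gene contrast estimates.
#' @param s_sq per-gene residual variances.
#' @param df residual degrees of freedom (scalar).
#' @param prior a list with `d0`, `s0_sq` from [estimate_eb_prior()].
#' @param stderr_unit contrast standard-error multiplier (scalar; the
#'   per-month value from [fit_contrasts()]).
#' @return A data frame with columns `logFC`, `t`, `p`.
#' @export
moderated_t <- function(logFC, s_sq, df, prior, stderr_unit) {
  stopifnot(is.numeric(prior$d0), prior$d0 >= 0,
            is.numeric(prior$s0_sq), prior$s0_sq > 0 || prior$d0 == 0)
  d0 <- prior$d0
  if (is.infinite(d0)) {
    s_tilde_sq <- rep(prior$s0_sq, length(s_sq))
    t_stat <- logFC / (stderr_unit * sqrt(s_tilde_sq))
    p <- 2 * stats::pnorm(-abs(t_stat))
  } else {
    s_tilde_sq <- (d0 * prior$s0_sq + df * s_sq) / (d0 + df)
    t_stat <- logFC / (stderr_unit * sqrt(s_tilde_sq))
    p <- 2 * stats::pt(-abs(t_stat), df = d0 + df)
  }
  data.frame(logFC = as.numeric(logFC), t = t_stat, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; a thin validating wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("bh_fdr: p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed genes
#'
#' Applies the standard fibrosis-signature thresholds: a gene is up (down)
#' when logFC >= lfc_min (<= -lfc_min) and q <= fdr_max, boundaries inclusive.
#'
#' @param rows data frame with columns `gene_id`, `logFC`, `q`.
#' @param lfc_min absolute log2 fold-change threshold (default 1.5).
#' @param fdr_max FDR threshold (default 0.05).
#' @return A list with character vectors `up` and `down`.
#' @export
select_de <- function(rows, lfc_min = 1.5, fdr_max = 0.05) {
  stopifnot(all(c("gene_id", "logFC", "q") %in% names(rows)))
  list(
    up = rows$gene_id[rows$logFC >= lfc_min & rows$q <= fdr_max],
    down = rows$gene_id[rows$logFC <= -lfc_min & rows$q <= fdr_max]
  )
}

#' Overlap of relaxed DE genes with a zonation set, unioned over months
#'
#' Per month, intersects the genes passing relaxed DE thresholds
#' (|logFC| >= lfc_min, q <= fdr_max) with the zonation set; returns the union
#' of the monthly overlaps.
#'
#' @param rows_by_month named list of per-month contrast tables (columns
#'   `gene_id`, `logFC`, `q`), same gene universe in each.
#' @param zonation_set a [gene_set()].
#' @param lfc_min,fdr_max relaxed thresholds (defaults 0.8 and 0.2).
#' @return A [gene_set()] holding the union overlap.
#' @export
overlap_union <- function(rows_by_month, zonation_set, lfc_min = 0.8,
                          fdr_max = 0.2) {
  stopifnot(inherits(zonation_set, "gene_set"))
  universe <- lapply(rows_by_month, function(r) sort(r$gene_id))
  if (length(unique(universe)) != 1L) {
    stop("overlap_union: gene universe differs across months")
  }
  hits <- unlist(lapply(rows_by_month, function(r) {
    de <- r$gene_id[abs(r$logFC) >= lfc_min & r$q <= fdr_max]
    intersect(de, zonation_set$members)
  }))
  gene_set(paste0(zonation_set$name, "_overlap"), sort(unique(hits)),
           direction = zonation_set$direction)
}

#' Full differential-expression stage for the CCl4 time course
#'
#' Normalizes a bulk experiment, fits group means with the month-6 oil
#' imputation, estimates the empirical-Bayes prior, and returns per-month
#' contrast tables with moderated t, p and BH q values.
#'
#' @param experiment a [bulk_experiment()].
#' @param months contrast months (default `c(2, 6, 12)`).
#' @return Named list of per-month data frames with columns `gene_id`,
#'   `logFC`, `t`, `p`, `q`, `mean_expr`, plus attributes `prior` and `df`.
#' @export
run_diffexp <- function(experiment, months = c(2, 6, 12)) {
  stopifnot(inherits(experiment, "bulk_experiment"))
  norm <- normalize_bulk(experiment)
  fit <- fit_contrasts(norm$logcpm, experiment$design, months = months)
  prior <- estimate_eb_prior(fit$s_sq, fit$df)
  out <- lapply(seq_along(months), function(i) {
    mt <- moderated_t(fit$logFC[, i], fit$s_sq, fit$df, prior,
                      fit$stderr_unit[i])
    data.frame(
      gene_id = rownames(fit$logFC),
      logFC = mt$logFC, t = mt$t, p = mt$p, q = bh_fdr(mt$p),
      mean_expr = fit$mean_expr,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  names(out) <- paste0("m", months)
  attr(out, "prior") <- prior
  attr(out, "df") <- fit$df
  out
}
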