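two_group_design <- function(n = 3) {
  data.frame(
    sample = c(paste0("oil", 1:n), paste0("ccl4", 1:n)),
    treatment = rep(c("oil", "ccl4"), each = n),
    month = 2L, replicate = rep(1:n, 2)
  )
}

full_design <- function(R = 4) {
  grp <- data.frame(
    treatment = c("untreated", "oil", "oil", "ccl4", "ccl4", "ccl4"),
    month = c(0L, 2L, 12L, 2L, 6L, 12L)
  )
  d <- grp[rep(1:6, each = R), ]
  d$replicate <- rep(1:R, 6)
  d$sample <- sprintf("%s_m%d_r%d", d$treatment, d$month, d$replicate)
  d[, c("sample", "treatment", "month", "replicate")]
}

test_that("TMM factors are 1 for identical samples and scale-invariant", {
  counts <- matrix(rep(c(10L, 20L, 5L, 40L), 4), 4,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  nb <- normalize_bulk(counts)
  expect_equal(unname(nb$factors), rep(1, 4))

  # scaling one sample's counts: its count fractions are unchanged, so its
  # log2-CPM moves only through the precision re-weighting of its TMM factor,
  # which stays below 0.05 log2 units here (the CPM-scale pseudocount itself
  # is exactly scale-invariant)
  set.seed(2)
  counts <- matrix(rnbinom(2000, mu = 60, size = 3) + 1L, 200, 10,
                   dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:10)))
  base <- normalize_bulk(counts)
  scaled <- counts
  scaled[, 4] <- 4L * scaled[, 4]
  nb2 <- normalize_bulk(scaled)
  expect_lt(max(abs(nb2$logcpm[, 4] - base$logcpm[, 4])), 0.05)
  # with the factor effect divided out, invariance holds to the tiny
  # pseudocount perturbation
  resc <- nb2$logcpm[, 4] + log2(nb2$factors[4] / base$factors[4])
  expect_equal(unname(resc), unname(base$logcpm[, 4]), tolerance = 1e-4)
})

test_that("TMM factors match edgeR's reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(2)
  counts <- matrix(rnbinom(3000, mu = 40, size = 2), 300, 10,
                   dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:10)))
  counts[counts < 0] <- 0L
  ours <- normalize_bulk(counts)$factors
  theirs <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("zero-total samples are rejected", {
  counts <- cbind(a = c(1L, 2L), b = c(0L, 0L))
  rownames(counts) <- c("g1", "g2")
  expect_error(normalize_bulk(counts), "zero total")
})

test_that("month-6 oil imputation is the elementwise mean", {
  expect_equal(as.numeric(impute_oil_month6(2, 4)), 3)
  x <- rnorm(5)
  expect_equal(as.numeric(impute_oil_month6(x, x)), x)
  set.seed(1)
  a <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  b <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  out <- impute_oil_month6(a, b)
  expect_equal(as.numeric(out), unname((a + b) / 2))
  expect_true(attr(out, "imputed"))
  expect_error(impute_oil_month6(a, b[c(2:100, 1)]), "do not match")
})

test_that("contrast fits recover group-mean arithmetic", {
  d <- two_group_design(3)
  le <- rbind(g1 = c(1, 1, 1, 3, 3, 3), g2 = c(2, 4, 3, 0, 1, 2))
  colnames(le) <- d$sample
  fit <- fit_contrasts(le, d, months = 2)
  expect_equal(unname(fit$logFC["g1", 1]), 2)
  expect_equal(unname(fit$s_sq["g1"]), 0)
  # hand-pooled variance for g2: groups (2,4,3) and (0,1,2)
  expect_equal(unname(fit$logFC["g2", 1]), mean(c(0, 1, 2)) - mean(c(2, 4, 3)))
  expect_equal(unname(fit$s_sq["g2"]), (2 + 2) / 4)
  expect_equal(unname(fit$stderr_unit), sqrt(1 / 3 + 1 / 3))
  expect_equal(fit$df, 4)

  # location invariance
  fit2 <- fit_contrasts(le + 7, d, months = 2)
  expect_equal(fit2$logFC, fit$logFC)
})

test_that("the imputed oil month-6 group adds no residual df", {
  d <- full_design(R = 4)
  set.seed(3)
  le <- matrix(rnorm(20 * nrow(d)), 20, nrow(d),
               dimnames = list(sprintf("g%02d", 1:20), d$sample))
  fit <- fit_contrasts(le, d, months = c(2, 6, 12))
  expect_equal(fit$df, 24 - 6)  # 6 real groups; the imputed oil m6 adds none
  # month-6 contrast equals ccl4_m6 mean minus the imputed oil mean
  gm <- function(tr, mo) rowMeans(le[, d$treatment == tr & d$month == mo])
  expect_equal(fit$logFC[, "m6"],
               gm("ccl4", 6) - (gm("oil", 2) + gm("oil", 12)) / 2)
  expect_equal(unname(fit$stderr_unit["m6"]),
               sqrt(1 / 4 + 0.25 / 4 + 0.25 / 4))
  expect_error(fit_contrasts(le, d, months = 3), "missing group")
})

test_that("EB prior: equal variances give infinite d0, moments invert", {
  pr <- estimate_eb_prior(rep(2.5, 50), df = 4)
  expect_true(is.infinite(pr$d0))
  expect_equal(pr$s0_sq, 2.5)

  # 10-gene fixture against an independent uniroot solution of the
  # moment equations; heterogeneous true variances keep d0 finite
  set.seed(41)
  s2 <- exp(rnorm(10, 0, 1.5)) * rchisq(10, 4) / 4
  df <- 4
  pr <- estimate_eb_prior(s2, df)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  d0_oracle <- 2 * uniroot(function(y) trigamma(y) - evar,
                           c(1e-6, 1e8), tol = 1e-12)$root
  expect_equal(pr$d0, d0_oracle, tolerance = 1e-6)
  expect_equal(pr$s0_sq,
               exp(mean(e) + digamma(d0_oracle / 2) - log(d0_oracle / 2)),
               tolerance = 1e-6)
  expect_error(estimate_eb_prior(rep(1, 5), 4), "at least 10")
})

test_that("EB prior recovers the generating parameters", {
  set.seed(9)
  d0 <- 4; s0 <- 1; df <- 6
  sigma2 <- s0 * d0 / rchisq(5000, d0)          # scaled inverse-chi-squared
  s2 <- sigma2 * rchisq(5000, df) / df          # sampling noise
  pr <- estimate_eb_prior(s2, df)
  expect_gte(pr$d0, 2.5); expect_lte(pr$d0, 6)
  expect_gte(pr$s0_sq, 0.8); expect_lte(pr$s0_sq, 1.25)
})

test_that("moderated t collapses to the ordinary t in its limits", {
  set.seed(12)
  lfc <- rnorm(30); s2 <- rchisq(30, 5) / 5; df <- 5; su <- sqrt(2 / 3)
  ord_t <- lfc / (su * sqrt(s2))

  # d0 = 0: no shrinkage
  m0 <- moderated_t(lfc, s2, df, list(d0 = 0, s0_sq = 1), su)
  expect_equal(m0$t, ord_t)
  expect_equal(m0$p, 2 * pt(-abs(ord_t), df))

  # homogeneous variances equal to the prior target: shrinkage is a no-op
  mh <- moderated_t(lfc, rep(1.7, 30), df, list(d0 = 4, s0_sq = 1.7), su)
  expect_equal(mh$t, lfc / (su * sqrt(1.7)))

  # direct posterior-variance formula on a fixture
  pr <- list(d0 = 4, s0_sq = 1)
  mt <- moderated_t(lfc[1:10], s2[1:10], df, pr, su)
  stilde <- (4 * 1 + 5 * s2[1:10]) / 9
  expect_equal(mt$t, lfc[1:10] / (su * sqrt(stilde)), tolerance = 1e-12)
  expect_equal(mt$p, 2 * pt(-abs(mt$t), 9), tolerance = 1e-12)

  # infinite d0: fully shrunk, normal reference
  mi <- moderated_t(lfc, s2, df, list(d0 = Inf, s0_sq = 2), su)
  expect_equal(mi$t, lfc / (su * sqrt(2)))
  expect_equal(mi$p, 2 * pnorm(-abs(mi$t)))
})

test_that("moderated pipeline agrees with limma on a two-group dataset", {
  skip_if_not_installed("limma")
  set.seed(23)
  n <- 4
  # heterogeneous gene-wise variances so the prior d0 is finite and the
  # shrinkage path is exercised for real
  sds <- exp(rnorm(500, 0, 0.6))
  le <- matrix(rnorm(500 * 2 * n, mean = 6), 500, 2 * n,
               dimnames = list(sprintf("g%03d", 1:500), NULL)) * sds
  le[1:40, (n + 1):(2 * n)] <- le[1:40, (n + 1):(2 * n)] + 2
  d <- two_group_design(n)
  colnames(le) <- d$sample

  fit <- fit_contrasts(le, d, months = 2)
  pr <- estimate_eb_prior(fit$s_sq, fit$df)
  mt <- moderated_t(fit$logFC[, 1], fit$s_sq, fit$df, pr, fit$stderr_unit[1])

  design <- model.matrix(~ 0 + factor(d$treatment, c("oil", "ccl4")))
  colnames(design) <- c("oil", "ccl4")
  lf <- limma::lmFit(le, design)
  lf <- limma::contrasts.fit(lf, limma::makeContrasts(ccl4 - oil,
                                                      levels = design))
  eb <- limma::eBayes(lf)
  expect_equal(pr$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(pr$s0_sq, eb$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mt$t), unname(eb$t[, 1]), tolerance = 1e-6)
  expect_equal(unname(mt$p), unname(eb$p.value[, 1]), tolerance = 1e-6)
})

test_that("BH adjustment passes its closed-form cases and is order-invariant", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  p <- runif(50)
  o <- sample(50)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
  expect_true(all(bh_fdr(p) <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "in \\[0, 1\\]")
})

test_that("DE selection keeps inclusive boundaries", {
  rows <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    logFC = c(1.5, -1.5, 0, 2, -2),
    q = c(0.05, 0.05, 1, 0.06, 0.01)
  )
  de <- select_de(rows)
  expect_setequal(de$up, "a")          # boundary gene retained
  expect_setequal(de$down, c("b", "e"))

  # 20-row fixture against a manual filter pass
  set.seed(30)
  rows <- data.frame(gene_id = sprintf("g%02d", 1:20),
                     logFC = rnorm(20, sd = 2), q = runif(20))
  de <- select_de(rows, lfc_min = 1, fdr_max = 0.3)
  expect_setequal(de$up,
                  rows$gene_id[rows$logFC >= 1 & rows$q <= 0.3])
  expect_setequal(de$down,
                  rows$gene_id[rows$logFC <= -1 & rows$q <= 0.3])
})

test_that("overlap union intersects per month then unions", {
  mk <- function(lfc, q) data.frame(gene_id = paste0("g", 1:4),
                                    logFC = lfc, q = q)
  months <- list(
    m2 = mk(c(1, 0, 0, 2), c(0.1, 1, 1, 0.01)),
    m6 = mk(c(0, -1, 0, 0), c(1, 0.1, 1, 1)),
    m12 = mk(c(0, 0, 0, 0), c(1, 1, 1, 1))
  )
  zs <- gene_set("zone", c("g1", "g2", "g3"), direction = "pericentral")
  out <- overlap_union(months, zs, lfc_min = 0.8, fdr_max = 0.2)
  # g1 passes only at month 2, g2 only at month 6, g4 passes but not in set
  expect_setequal(out$members, c("g1", "g2"))
  expect_equal(out$direction, "pericentral")

  none <- overlap_union(list(m2 = mk(rep(0, 4), rep(1, 4))), zs)
  expect_length(none$members, 0)
})

test_that("run_diffexp recovers planted bulk effects end to end", {
  cfg <- sim_config(n_genes = 1200, n_cells = 20, frac_pericentral = 0.05,
                    frac_periportal = 0.05, nb_dispersion = 0.1, seed = 5,
                    bulk_effects = list(
                      pericentral = c("2" = -1.5, "6" = -2, "12" = -3),
                      periportal = c("2" = 2, "6" = 2, "12" = 2)
                    ))
  sim <- simulate_layered_cells(cfg)
  pc <- names(sim$truth$direction)[sim$truth$direction == "pericentral"]
  pp <- names(sim$truth$direction)[sim$truth$direction == "periportal"]
  bulk <- simulate_bulk_timecourse(cfg, pc, pp)
  de <- run_diffexp(bulk$experiment)

  planted <- bulk$truth$planted_logfc
  # with 6 replicates and dispersion 0.1 the delta-method SE of a log2
  # ratio of group means is about sqrt(2 * (phi + 1/mu) / 6) / ln 2; check
  # that planted effects are recovered without bias at that precision
  for (m in c("m2", "m12")) {
    rows <- de[[m]]
    idx <- rows$gene_id %in% c(pc, pp)
    err <- rows$logFC[idx] - planted[rows$gene_id[idx], sub("m", "", m)]
    se <- sqrt(2 * 0.1 / 6) / log(2)   # lower bound, mu large
    expect_gte(mean(abs(err) <= 3 * se), 0.9)
    # no systematic bias among well-measured genes (log2-CPM pseudocount
    # attenuates genes near the detection floor)
    strong <- idx & rows$mean_expr > 5
    err_s <- rows$logFC[strong] - planted[rows$gene_id[strong], sub("m", "", m)]
    expect_lt(abs(mean(err_s)), 0.1)
  }
  # empirical FDR at q <= 0.05 stays controlled
  rows <- de$m12
  sig <- rows$q <= 0.05
  truth_null <- !(rows$gene_id %in% c(pc, pp))
  expect_lte(sum(sig & truth_null) / max(1, sum(sig)), 0.10)
})

test_that("null bulk data yield few DE calls", {
  cfg <- sim_config(n_genes = 1000, n_cells = 20, frac_pericentral = 0,
                    frac_periportal = 0, seed = 8,
                    bulk_effects = list(pericentral = c("2" = 0, "6" = 0, "12" = 0),
                                        periportal = c("2" = 0, "6" = 0, "12" = 0)))
  sim <- simulate_layered_cells(cfg)
  bulk <- simulate_bulk_timecourse(cfg, character(0), character(0))
  de <- run_diffexp(bulk$experiment)
  fpp <- mean(de$m2$q <= 0.05)
  expect_lte(fpp, 0.10)
})
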