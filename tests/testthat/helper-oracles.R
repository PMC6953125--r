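# Independent brute-force oracles, deliberately written as literal
# (slow, loop-based) re-derivations so they share no code paths with the
# package implementations they check.

# JT statistic by explicit pairwise comparison over ordered group pairs.
oracle_jt_stat <- function(values, groups) {
  lev <- sort(unique(groups))
  U <- 0
  for (ai in seq_along(lev)) {
    for (bi in seq_along(lev)) {
      if (bi <= ai) next
      xa <- values[groups == lev[ai]]
      xb <- values[groups == lev[bi]]
      cmp <- outer(xa, xb, "<") + 0.5 * outer(xa, xb, "==")
      U <- U + sum(cmp)
    }
  }
  U
}

# Exact two-sided JT p by enumerating every permutation of values over the
# fixed label vector (tie-free inputs only; total n <= 8 stays fast).
oracle_jt_exact_p <- function(values, groups) {
  n <- length(values)
  perms <- all_permutations(seq_len(n))
  us <- apply(perms, 1, function(o) oracle_jt_stat(values[o], groups))
  u_obs <- oracle_jt_stat(values, groups)
  e <- mean(us)
  mean(abs(us - e) >= abs(u_obs - e) - 1e-9)
}

# Exact two-sided JT p by enumerating the distinct assignments of values to
# groups (equivalent to the label-permutation null, without the n! blowup).
oracle_jt_exact_p_enum <- function(values, groups) {
  sizes <- as.integer(table(factor(groups, levels = sort(unique(groups)))))
  assignments <- list()
  recurse <- function(remaining, grps) {
    if (length(grps) == 0) {
      assignments[[length(assignments) + 1]] <<- list()
      return(list(list()))
    }
    out <- list()
    picks <- combn(seq_along(remaining), grps[1], simplify = FALSE)
    for (p in picks) {
      rest <- recurse(remaining[-p], grps[-1])
      for (r in rest) out[[length(out) + 1]] <- c(list(remaining[p]), r)
    }
    out
  }
  asg <- recurse(values, sizes)
  us <- vapply(asg, function(a) {
    v <- unlist(a)
    g <- rep(seq_along(sizes), sizes)
    oracle_jt_stat(v, g)
  }, numeric(1))
  u_obs <- oracle_jt_stat(values, groups)
  e <- mean(us)
  mean(abs(us - e) >= abs(u_obs - e) - 1e-9)
}

all_permutations <- function(v) {
  if (length(v) == 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- all_permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# Asymptotic JT z and two-sided p written straight from the tie-corrected
# moment formulas.
oracle_jt_asymptotic <- function(values, groups) {
  n_i <- as.numeric(table(groups))
  n <- sum(n_i)
  t_j <- as.numeric(table(values))
  U <- oracle_jt_stat(values, groups)
  e_u <- (n^2 - sum(n_i^2)) / 4
  v_u <- (n * (n - 1) * (2 * n + 5) -
            sum(n_i * (n_i - 1) * (2 * n_i + 5)) -
            sum(t_j * (t_j - 1) * (2 * t_j + 5))) / 72 +
    sum(n_i * (n_i - 1) * (n_i - 2)) * sum(t_j * (t_j - 1) * (t_j - 2)) /
      (36 * n * (n - 1) * (n - 2)) +
    sum(n_i * (n_i - 1)) * sum(t_j * (t_j - 1)) / (8 * n * (n - 1))
  z <- (U - e_u) / sqrt(v_u)
  list(U = U, z = z, p = 2 * pnorm(-abs(z)))
}

# GSEA running sum stepped literally, one rank at a time.
oracle_gsea_running <- function(stats, is_hit, exponent = 1) {
  n <- length(stats)
  k <- sum(is_hit)
  hit_w <- abs(stats)^exponent
  total <- sum(hit_w[is_hit])
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      cur <- cur + if (total > 0) hit_w[i] / total else 1 / k
    } else {
      cur <- cur - 1 / (n - k)
    }
    running[i] <- cur
  }
  running
}

oracle_gsea_es <- function(stats, is_hit, exponent = 1) {
  running <- oracle_gsea_running(stats, is_hit, exponent)
  running[which.max(abs(running))]
}

# Hypergeometric enrichment tail by explicit summation of point masses.
oracle_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(dhyper(i, K, N - K, n))
}

# Per-cell median-of-ratios size factors, recomputed longhand. Reference
# genes = those expressed in every cell; fall back to nonzero entries when
# none exists.
oracle_size_factors <- function(counts) {
  G <- nrow(counts); C <- ncol(counts)
  dense <- which(apply(counts, 1, function(x) all(x > 0)))
  sf <- numeric(C)
  if (length(dense) > 0) {
    gm <- vapply(dense, function(g) exp(mean(log(counts[g, ]))), numeric(1))
    for (j in seq_len(C)) sf[j] <- median(counts[dense, j] / gm)
  } else {
    gm <- numeric(G)
    for (g in seq_len(G)) {
      pos <- counts[g, counts[g, ] > 0]
      gm[g] <- exp(mean(log(pos)))
    }
    for (j in seq_len(C)) {
      nz <- counts[, j] > 0
      sf[j] <- median(counts[nz, j] / gm[nz])
    }
  }
  sf / exp(mean(log(sf)))
}

# Small NB helpers for moment checks: variance = mu + phi mu^2.
nb_var <- function(mu, phi) mu + phi * mu^2

# Fourth central moment of NB(mu, phi) by direct pmf summation.
nb_mu4 <- function(mu, phi) {
  size <- 1 / phi
  upper <- max(50, ceiling(mu + 40 * sqrt(nb_var(mu, phi))))
  x <- 0:upper
  p <- dnbinom(x, mu = mu, size = size)
  sum(p * (x - mu)^4) / sum(p)
}
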