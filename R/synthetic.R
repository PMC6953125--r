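#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic single-cell and bulk
#' generators. Defaults reproduce the study conditions the pipeline was built
#' for: 1415 hepatocytes spread over 9 lobule layers, and a CCl4/oil
#' time course with six replicates per group in which pericentral genes are
#' progressively downregulated and periportal genes transiently upregulated.
#'
#' @param n_genes number of genes to simulate.
#' @param n_cells number of cells (default 1415).
#' @param n_layers number of lobule layers; layer 1 is the most pericentral,
#'   layer `n_layers` the most periportal (default 9).
#' @param frac_pericentral,frac_periportal fractions of genes planted with a
#'   decreasing / increasing monotone profile; must sum to at most 1.
#' @param profile_amplitude total log2 fold-range of a planted profile across
#'   the layers (layer 1 to layer `n_layers`).
#' @param nb_dispersion negative-binomial dispersion phi in
#'   variance = mu + phi * mu^2; 0 gives Poisson counts.
#' @param dirichlet_concentration extra Dirichlet weight put on a cell's true
#'   layer; larger values concentrate the layer-membership probabilities.
#' @param depth_meanlog,depth_sdlog log-normal parameters of the per-gene
#'   baseline mean UMI count per cell; the default (median 0.2, sdlog 1.2)
#'   emulates sparse whole-transcriptome droplet/plate UMI depth. Detection
#'   power of the trend screen depends strongly on this floor.
#' @param bulk_depth_meanlog,bulk_depth_sdlog log-normal parameters of the
#'   per-gene baseline mean count in the bulk time course.
#' @param libsize_sigma log-normal sd of per-cell / per-sample size factors.
#' @param n_replicates bulk replicates per (treatment, month) group (default 6).
#' @param bulk_effects named list with numeric vectors `pericentral` and
#'   `periportal`, each named by month ("2", "6", "12"): planted log2 fold
#'   changes of CCl4 versus oil at that month.
#' @param seed integer seed; all randomness flows from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L,
                       n_cells = 1415L,
                       n_layers = 9L,
                       frac_pericentral = 0.05,
                       frac_periportal = 0.05,
                       profile_amplitude = 2,
                       nb_dispersion = 0.1,
                       dirichlet_concentration = 10,
                       depth_meanlog = log(0.2),
                       depth_sdlog = 1.2,
                       bulk_depth_meanlog = log(150),
                       bulk_depth_sdlog = 1.5,
                       libsize_sigma = 0.3,
                       n_replicates = 6L,
                       bulk_effects = list(
                         pericentral = c("2" = -1.5, "6" = -2, "12" = -3),
                         periportal  = c("2" = 1.5, "6" = 1.5, "12" = 0)
                       ),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
    n_layers = as.integer(n_layers),
    frac_pericentral = frac_pericentral, frac_periportal = frac_periportal,
    profile_amplitude = profile_amplitude, nb_dispersion = nb_dispersion,
    dirichlet_concentration = dirichlet_concentration,
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    bulk_depth_meanlog = bulk_depth_meanlog,
    bulk_depth_sdlog = bulk_depth_sdlog,
    libsize_sigma = libsize_sigma,
    n_replicates = as.integer(n_replicates),
    bulk_effects = bulk_effects, seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L || cfg$n_cells < 1L) {
    stop("sim_config: n_genes and n_cells must be positive")
  }
  if (cfg$n_layers < 2L) stop("sim_config: n_layers must be at least 2")
  if (frac_pericentral < 0 || frac_periportal < 0 ||
      frac_pericentral + frac_periportal > 1) {
    stop("sim_config: zonated fractions must be in [0,1] and sum to at most 1")
  }
  if (profile_amplitude < 0) stop("sim_config: profile_amplitude must be >= 0")
  if (nb_dispersion < 0) stop("sim_config: nb_dispersion must be >= 0")
  if (dirichlet_concentration <= 0) {
    stop("sim_config: dirichlet_concentration must be > 0")
  }
  if (cfg$n_replicates < 2L) stop("sim_config: n_replicates must be >= 2")
  stopifnot(is.list(bulk_effects),
            all(c("pericentral", "periportal") %in% names(bulk_effects)))
  class(cfg) <- "sim_config"
  cfg
}

## NB draw with variance = mu + phi mu^2; phi = 0 degenerates to Poisson.
rnb <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

## Per-gene per-layer mean matrix implied by a config; geometric profiles with
## constant log2 step, centred so the mid-lobule mean equals the baseline.
layer_mean_matrix <- function(base, direction, n_layers, amplitude) {
  step <- amplitude / (n_layers - 1)
  centred <- seq_len(n_layers) - (n_layers + 1) / 2
  slope <- ifelse(direction == "periportal", step,
           ifelse(direction == "pericentral", -step, 0))
  base * 2^(outer(slope, centred))
}

#' Simulate a layered single-cell count matrix
#'
#' Draws UMI-like counts for `n_genes` genes in `n_cells` cells. Each cell has
#' a true lobule layer (uniform over layers); its layer-membership probability
#' row is a Dirichlet draw concentrated on the true layer. Planted pericentral
#' genes have strictly decreasing, periportal strictly increasing geometric
#' mean profiles from layer 1 to layer `n_layers`; all other genes are flat.
#' Counts are negative-binomial around the profile mean scaled by a log-normal
#' per-cell size factor.
#'
#' @param config a [sim_config()].
#' @return A list with `matrix` (a [layered_cell_matrix()]) and `truth`
#'   (per-gene `direction`, per-cell `true_layer`).
#' @export
simulate_layered_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes; C <- config$n_cells; L <- config$n_layers

  gene_ids <- sprintf("gene%04d", seq_len(G))
  cell_ids <- sprintf("cell%04d", seq_len(C))

  n_pc <- round(config$frac_pericentral * G)
  n_pp <- round(config$frac_periportal * G)
  direction <- rep("none", G)
  if (n_pc > 0) direction[seq_len(n_pc)] <- "pericentral"
  if (n_pp > 0) direction[n_pc + seq_len(n_pp)] <- "periportal"
  names(direction) <- gene_ids

  true_layer <- sample.int(L, C, replace = TRUE)
  names(true_layer) <- cell_ids

  ## Dirichlet rows via gamma draws, extra weight on the true layer
  alpha0 <- 0.3
  gam <- matrix(stats::rgamma(C * L, shape = alpha0), nrow = C)
  gam[cbind(seq_len(C), true_layer)] <-
    stats::rgamma(C, shape = alpha0 + config$dirichlet_concentration)
  layer_probs <- gam / rowSums(gam)
  dimnames(layer_probs) <- list(cell_ids, paste0("layer", seq_len(L)))

  ## baseline mean counts per cell: sparse UMI scale
  base <- stats::rlnorm(G, meanlog = config$depth_meanlog,
                        sdlog = config$depth_sdlog)
  mu_layer <- layer_mean_matrix(base, direction, L, config$profile_amplitude)

  sf <- stats::rlnorm(C, meanlog = 0, sdlog = config$libsize_sigma)
  mu <- mu_layer[, true_layer, drop = FALSE] *
    rep(sf, each = G)  # genes x cells
  counts <- matrix(rnb(G * C, as.vector(mu), config$nb_dispersion),
                   nrow = G, dimnames = list(gene_ids, cell_ids))

  truth <- list(direction = direction, true_layer = true_layer,
                layer_means = mu_layer)
  list(matrix = layered_cell_matrix(counts, layer_probs), truth = truth)
}

#' Simulate a bulk CCl4/oil time course
#'
#' Generates the six-group design the fibrosis analysis assumes: untreated at
#' month 0, oil at months 2 and 12, and CCl4 at months 2, 6 and 12, each with
#' `n_replicates` samples. Oil and untreated group means equal the per-gene
#' baseline; CCl4 group means at month m are the baseline shifted by the
#' planted log2 fold change from `config$bulk_effects` for genes in the
#' supplied pericentral / periportal lists. Counts are negative-binomial with
#' the configured dispersion, scaled by log-normal per-sample size factors.
#'
#' @param config a [sim_config()].
#' @param pericentral_genes,periportal_genes disjoint character vectors of gene
#'   ids receiving the planted effects.
#' @return A list with `experiment` (a [bulk_experiment()]) and `truth`
#'   (gene x month matrix of planted log2 fold changes).
#' @export
simulate_bulk_timecourse <- function(config, pericentral_genes,
                                     periportal_genes) {
  stopifnot(inherits(config, "sim_config"))
  if (length(intersect(pericentral_genes, periportal_genes)) > 0) {
    stop("pericentral and periportal gene lists must be disjoint")
  }
  set.seed(config$seed + 1L)
  G <- config$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(G))
  stopifnot(all(pericentral_genes %in% gene_ids),
            all(periportal_genes %in% gene_ids))

  groups <- data.frame(
    treatment = c("untreated", "oil", "oil", "ccl4", "ccl4", "ccl4"),
    month = c(0L, 2L, 12L, 2L, 6L, 12L),
    stringsAsFactors = FALSE
  )
  R <- config$n_replicates
  design <- data.frame(
    sample = character(0), treatment = character(0),
    month = integer(0), replicate = integer(0)
  )
  months_chr <- c("2", "6", "12")
  planted <- matrix(0, nrow = G, ncol = 3,
                    dimnames = list(gene_ids, months_chr))
  for (m in months_chr) {
    planted[pericentral_genes, m] <- config$bulk_effects$pericentral[[m]]
    planted[periportal_genes, m] <- config$bulk_effects$periportal[[m]]
  }

  base <- stats::rlnorm(G, meanlog = config$bulk_depth_meanlog,
                        sdlog = config$bulk_depth_sdlog)
  counts_cols <- list()
  for (gi in seq_len(nrow(groups))) {
    tr <- groups$treatment[gi]; mo <- groups$month[gi]
    lfc <- if (tr == "ccl4") planted[, as.character(mo)] else rep(0, G)
    mu_g <- base * 2^lfc
    for (r in seq_len(R)) {
      sf <- stats::rlnorm(1, 0, config$libsize_sigma)
      nm <- sprintf("%s_m%d_r%d", tr, mo, r)
      counts_cols[[nm]] <- rnb(G, mu_g * sf, config$nb_dispersion)
      design <- rbind(design, data.frame(
        sample = nm, treatment = tr, month = mo, replicate = r
      ))
    }
  }
  counts <- do.call(cbind, counts_cols)
  rownames(counts) <- gene_ids

  list(
    experiment = bulk_experiment(counts, design),
    truth = list(planted_logfc = planted,
                 pericentral = pericentral_genes,
                 periportal = periportal_genes)
  )
}

#' Simulate noisy per-study zonation gene sets
#'
#' Builds `n_studies` independent (pericentral, periportal) set pairs from the
#' truth labels: each true zonated gene enters the matching set with
#' probability `sensitivity`; each gene whose true direction is "none" enters
#' each set with probability `fpr`.
#'
#' @param truth the `truth` element of [simulate_layered_cells()] (needs
#'   `$direction`).
#' @param sensitivity,fpr detection probability for true members / false
#'   positive probability for non-zonated genes; both in \[0, 1\].
#' @param n_studies number of studies to emulate.
#' @param seed integer seed.
#' @return A list of length `n_studies`; each element has `pericentral` and
#'   `periportal` [gene_set()]s.
#' @export
simulate_study_sets <- function(truth, sensitivity, fpr, n_studies, seed) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fpr >= 0, fpr <= 1,
            n_studies >= 1)
  set.seed(as.integer(seed))
  dir <- truth$direction
  genes <- names(dir)
  lapply(seq_len(n_studies), function(s) {
    pick <- function(target) {
      true_m <- genes[dir == target]
      none_m <- genes[dir == "none"]
      members <- c(
        true_m[stats::runif(length(true_m)) < sensitivity],
        none_m[stats::runif(length(none_m)) < fpr]
      )
      gene_set(sprintf("study%d_%s", s, target), members, direction = target)
    }
    list(pericentral = pick("pericentral"), periportal = pick("periportal"))
  })
}
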