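# Independent oracles used across the suite.

# Brute-force root marginal likelihood of a BHC tree: sum over all
# tree-consistent partitions, each weighted by its Dirichlet-process prior
# mass alpha^|phi| prod_c Gamma(n_c) / d_root, times the product of
# per-cluster Dirichlet-multinomial marginal likelihoods. Enumerates
# partitions directly, independent of the package's recursion.
oracle_root_logml <- function(tree, values, beta, n_bins) {
  n <- tree$n_items
  leaves <- function(node) {
    if (node <= n) return(node)
    c(leaves(tree$children[node, 1]), leaves(tree$children[node, 2]))
  }
  parts_of <- function(node) {
    if (node <= n) return(list(list(node)))
    l <- parts_of(tree$children[node, 1])
    r <- parts_of(tree$children[node, 2])
    out <- list(list(leaves(node)))
    for (pl in l) for (pr in r) out[[length(out) + 1]] <- c(pl, pr)
    out
  }
  ml_cluster <- function(rows) {
    cts <- vapply(seq_len(ncol(values)), function(j)
      tabulate(values[rows, j] + 1L, nbins = n_bins), integer(n_bins))
    dirichlet_multinomial_logml(as.matrix(cts), beta)
  }
  lw <- vapply(parts_of(2L * n - 1L), function(phi)
    length(phi) * log(tree$alpha) +
      sum(vapply(phi, function(cl) lgamma(length(cl)) + ml_cluster(cl),
                 numeric(1))),
    numeric(1))
  mx <- max(lw)
  mx + log(sum(exp(lw - mx))) - tree$log_d[2L * n - 1L]
}

# Fisher-z approximation to P(|r_hat| >= threshold) for a sample Pearson
# correlation at true rho and sample size n.
fisher_z_tail <- function(rho, threshold, n) {
  se <- 1 / sqrt(n - 3)
  upper <- stats::pnorm((atanh(rho) - atanh(threshold)) / se)
  lower <- stats::pnorm((-atanh(threshold) - atanh(rho)) / se)
  upper + lower
}

# Linear-scan annotation oracle: all library entries within ppm_tol of each
# peak, no windowed query.
oracle_annotate <- function(peaks, library, mode, ppm_tol) {
  lib <- library[library$mode == mode, , drop = FALSE]
  lapply(peaks$mz, function(mz) {
    sort(lib$rank[1e6 * abs(mz - lib$theoretical_mz) / lib$theoretical_mz <= ppm_tol])
  })
}

# A positive-mode-only spec for fast chain simulations: the glyceride,
# phospholipid and sterol classes of the bundled library without water-loss
# fragment entries, the PE isobar, blanks or QCs. Many species per class
# keep compositional-closure distortion of planted correlations small.
slim_chain_spec <- function(n_pairs = 30, r = 0.7, noise_sigma = 0.25,
                            blank_level = 0.01, n_blanks = 2) {
  lib <- default_lipid_library()
  sub <- lib[order(lib$rank), ]
  sub <- sub[sub$mode == "positive" &
               sub$lipid_class %in% c("TG", "PC", "PC-O", "SM", "CE", "Chol") &
               !grepl("-H2O$", sub$name), ]
  sub <- lipid_library(sub[, c("name", "lipid_class", "total_carbons",
                               "double_bonds", "theoretical_mz", "mode")])
  prof <- list(
    maternal_plasma = list(positive = c(TG = 25, PC = 30, `PC-O` = 10,
                                        SM = 15, CE = 15, Chol = 5)),
    milk = list(positive = c(TG = 70, SM = 15, PC = 5, `PC-O` = 5,
                             CE = 3, Chol = 2)),
    infant_plasma = list(positive = c(TG = 30, PC = 30, `PC-O` = 10,
                                      SM = 15, CE = 10, Chol = 5)))
  chain <- if (is.null(r)) list() else
    list(list(cbm = "PC(34:1)", milk = "TG(49:4)", maternal = "CE(18:2)", r = r))
  cohort_spec(n_pairs = n_pairs, library = sub, class_profiles = prof,
              species_targets = list(), noise_sigma = noise_sigma,
              chain_spec = chain, cluster_spec = list(),
              blank_level = blank_level, dg_fragment_fraction = 0,
              n_blanks = n_blanks, n_qc = 0)
}

# tiny two-species positive-mode library for unit tests
toy_library <- function() {
  lipid_library(data.frame(
    name = c("PC(34:1)", "TG(52:2)", "SM(34:1)", "PS(36:1)"),
    class = c("PC", "TG", "SM", "PS"),
    carbons = c(34, 52, 34, 36),
    double_bonds = c(1, 2, 1, 1),
    mz = c(760.5851, 876.8015, 703.5749, 788.5447),
    mode = c("positive", "positive", "positive", "negative"),
    stringsAsFactors = FALSE))
}
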