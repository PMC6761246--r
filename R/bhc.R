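# Bayesian hierarchical clustering under a multinomial Dirichlet-process
# mixture (the "latent structure model"). Greedy agglomeration: each
# candidate merge k = (i, j) is scored by the posterior probability r_k that
# its members form a single cluster, with
#   d_k  = alpha * Gamma(n_k) + d_i * d_j              (log space)
#   pi_k = alpha * Gamma(n_k) / d_k
#   p(D_k | T_k) = pi_k p(D_k | H1) + (1 - pi_k) p(D_i | T_i) p(D_j | T_j)
#   r_k  = pi_k p(D_k | H1) / p(D_k | T_k)
# and the pair with the highest r_k merged at each step. All recursions run
# in log space via log-sum-exp.

.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

#' Quantile discretization of a matrix
#'
#' Each column is cut at its empirical quantiles into `n_bins` categories
#' (tertiles by default), values tied with an edge going to the lower bin.
#' A monotone transform of a column leaves its discretization unchanged.
#' Constant columns collapse into category 0 with a warning.
#'
#' @param matrix numeric matrix.
#' @param n_bins number of categories, >= 2 (default 3).
#' @return object of class `discretized_matrix`: list with integer `values`
#'   (categories in `0:(n_bins-1)`), `bin_edges` per column and `n_bins`.
#' @export
discretize <- function(matrix, n_bins = 3) {
  matrix <- as.matrix(matrix)
  if (n_bins < 2) stop("n_bins must be >= 2")
  probs <- seq_len(n_bins - 1) / n_bins
  edges <- vector("list", ncol(matrix))
  vals <- matrix(0L, nrow(matrix), ncol(matrix),
                 dimnames = dimnames(matrix))
  n_const <- 0L
  for (j in seq_len(ncol(matrix))) {
    x <- matrix[, j]
    e <- stats::quantile(x, probs, names = FALSE, type = 7)
    if (length(unique(x)) == 1) n_const <- n_const + 1L
    # ties at an edge go to the lower bin: count edges strictly below x;
    # unique() keeps the coding dense when quantile edges coincide
    vals[, j] <- findInterval(x, unique(e), left.open = TRUE)
    edges[[j]] <- e
  }
  if (n_const) warning(n_const, " constant column(s) discretized to category 0")
  structure(list(values = vals, bin_edges = edges, n_bins = as.integer(n_bins)),
            class = "discretized_matrix")
}

#' Dirichlet-multinomial log marginal likelihood of a cluster
#'
#' Columns are modelled as independent categorical distributions with a
#' symmetric Dirichlet(beta) prior over `m` categories. For per-column
#' category counts `c_v` over a cluster of `n` items the marginal
#' likelihood of one column is
#' `Gamma(m b) / Gamma(m b + n) * prod_v Gamma(b + c_v) / Gamma(b)`,
#' and columns multiply (sum in log space).
#'
#' @param counts m x C matrix of category counts (categories in rows,
#'   columns of the data in columns), or a vector for a single column.
#' @param prior symmetric Dirichlet pseudo-count beta > 0.
#' @return log marginal likelihood (scalar).
#' @export
dirichlet_multinomial_logml <- function(counts, prior = 1) {
  if (prior <= 0) stop("prior pseudo-count must be positive")
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- nrow(counts)
  n <- colSums(counts)
  sum(lgamma(m * prior) - lgamma(m * prior + n)) +
    sum(lgamma(prior + counts) - lgamma(prior))
}

# counts matrix (n_bins x C) for a set of item rows of an integer matrix
.category_counts <- function(values, rows, n_bins) {
  sub <- values[rows, , drop = FALSE]
  vapply(seq_len(ncol(sub)), function(j)
    tabulate(sub[, j] + 1L, nbins = n_bins), integer(n_bins))
}

#' Build a Bayesian hierarchical clustering tree
#'
#' Greedy agglomeration over items (rows) under the multinomial
#' Dirichlet-process mixture model. Deterministic: ties in the greedy merge
#' are broken towards the lexicographically smallest pair of cluster
#' indices (creation order).
#'
#' @param data a [discretize()]d matrix, or an integer matrix of categories
#'   in `0:(n_bins-1)` (items in rows).
#' @param alpha Dirichlet-process concentration (> 0), default 1.
#' @param beta symmetric Dirichlet pseudo-count per category (> 0),
#'   default 1.
#' @param n_bins number of categories when `data` is a plain matrix.
#' @return object of class `bhc_tree`: list with `merges` (two-column
#'   matrix of node indices, negative = leaf), per-node vectors `log_d`,
#'   `log_pi`, `log_ml_h1`, `log_ml_tree`, `r`, `n_k`, plus `items`,
#'   `alpha`, `beta`, `n_bins`. `log_ml_root` gives log p(D | T).
#' @export
bhc_build <- function(data, alpha = 1, beta = 1, n_bins = NULL) {
  if (inherits(data, "discretized_matrix")) {
    values <- data$values
    n_bins <- data$n_bins
  } else {
    values <- as.matrix(data)
    if (is.null(n_bins)) n_bins <- max(values) + 1L
  }
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  storage.mode(values) <- "integer"
  if (any(values < 0) || any(values >= n_bins))
    stop("categories must lie in 0:(n_bins-1)")
  n <- nrow(values)
  if (n < 2) stop("need at least 2 items")
  items <- rownames(values)
  if (is.null(items)) items <- paste0("item", seq_len(n))

  n_nodes <- 2L * n - 1L
  counts <- vector("list", n_nodes)      # n_bins x C count matrices
  log_d <- log_pi <- log_ml_h1 <- log_ml_tree <- r <- n_k <-
    rep(NA_real_, n_nodes)
  children <- matrix(NA_integer_, n_nodes, 2)
  log_alpha <- log(alpha)
  for (i in seq_len(n)) {
    counts[[i]] <- .category_counts(values, i, n_bins)
    n_k[i] <- 1
    log_d[i] <- log_alpha
    log_ml_h1[i] <- log_ml_tree[i] <- dirichlet_multinomial_logml(counts[[i]], beta)
    r[i] <- 1
  }

  # score a candidate merge of active nodes a, b; returns the node fields
  score_pair <- function(a, b) {
    nk <- n_k[a] + n_k[b]
    log_ag <- log_alpha + lgamma(nk)
    ld <- .logsumexp2(log_ag, log_d[a] + log_d[b])
    lpi <- log_ag - ld
    cts <- counts[[a]] + counts[[b]]
    lh1 <- dirichlet_multinomial_logml(cts, beta)
    ltree <- .logsumexp2(lpi + lh1,
                         log1p(-exp(lpi)) + log_ml_tree[a] + log_ml_tree[b])
    if (!is.finite(ltree))
      stop("non-finite marginal likelihood when merging nodes ", a, " and ", b)
    list(n_k = nk, log_d = ld, log_pi = lpi, log_ml_h1 = lh1,
         log_ml_tree = ltree, r = exp(lpi + lh1 - ltree), counts = cts)
  }

  active <- seq_len(n)
  # pair scores cached by node-id key; node ids are never reused
  cache <- new.env(parent = emptyenv())
  key <- function(a, b) paste0(min(a, b), ".", max(a, b))
  get_score <- function(a, b) {
    k <- key(a, b)
    s <- cache[[k]]
    if (is.null(s)) {
      s <- score_pair(min(a, b), max(a, b))
      cache[[k]] <- s
    }
    s
  }

  merges <- matrix(NA_integer_, n - 1L, 2)
  node <- n
  while (length(active) > 1) {
    best <- NULL; best_r <- -Inf; best_ab <- c(NA, NA)
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        a <- active[ii]; b <- active[jj]
        s <- get_score(a, b)
        # strict > : ties resolve to the earliest (lexicographic) pair,
        # since `active` stays in ascending node order
        if (s$r > best_r) {
          best_r <- s$r; best <- s; best_ab <- c(a, b)
        }
      }
    }
    node <- node + 1L
    a <- best_ab[1]; b <- best_ab[2]
    counts[[node]] <- best$counts
    n_k[node] <- best$n_k
    log_d[node] <- best$log_d
    log_pi[node] <- best$log_pi
    log_ml_h1[node] <- best$log_ml_h1
    log_ml_tree[node] <- best$log_ml_tree
    r[node] <- best$r
    children[node, ] <- c(a, b)
    merges[node - n, ] <- c(a, b)
    active <- c(setdiff(active, c(a, b)), node)
  }

  structure(list(merges = merges, children = children, items = items,
                 n_items = n, n_k = n_k, log_d = log_d, log_pi = log_pi,
                 log_ml_h1 = log_ml_h1, log_ml_tree = log_ml_tree, r = r,
                 log_ml_root = log_ml_tree[n_nodes],
                 alpha = alpha, beta = beta, n_bins = n_bins),
            class = "bhc_tree")
}

#' @export
print.bhc_tree <- function(x, ...) {
  cat(sprintf("bhc_tree: %d items, alpha = %g, beta = %g, log p(D|T) = %.4f\n",
              x$n_items, x$alpha, x$beta, x$log_ml_root))
  cat(sprintf("  clusters at r >= 0.5 cut: %d\n",
              length(unique(cut_tree(x)))))
  invisible(x)
}

#' Cut a BHC tree into clusters
#'
#' Depth-first from the root: a node with posterior merge probability
#' `r_k >= cut` becomes a cluster; below-threshold nodes are severed and
#' their children visited. Clusters are numbered in left-to-right dendrogram
#' order.
#'
#' @param tree a [bhc_build()] tree.
#' @param cut threshold on `r_k` (default 0.5).
#' @return integer vector of cluster ids named by item label.
#' @export
cut_tree <- function(tree, cut = 0.5) {
  stopifnot(inherits(tree, "bhc_tree"))
  n <- tree$n_items
  assignment <- integer(n)
  cluster_id <- 0L
  leaves_of <- function(node) {
    if (node <= n) return(node)
    c(leaves_of(tree$children[node, 1]), leaves_of(tree$children[node, 2]))
  }
  visit <- function(node) {
    if (node <= n || tree$r[node] >= cut) {
      cluster_id <<- cluster_id + 1L
      assignment[leaves_of(node)] <<- cluster_id
    } else {
      visit(tree$children[node, 1])
      visit(tree$children[node, 2])
    }
  }
  visit(2L * n - 1L)
  stats::setNames(assignment, tree$items)
}

#' Select the DP concentration by marginal likelihood
#'
#' Rebuilds the tree for every alpha in `grid` and returns the value with
#' the highest root log marginal likelihood, ties going to the smallest
#' alpha.
#'
#' @param data as for [bhc_build()].
#' @param grid numeric vector of candidate concentrations.
#' @param beta,n_bins passed to [bhc_build()].
#' @return list with `alpha`, `log_ml` per grid point, and the winning
#'   `tree`.
#' @export
optimize_concentration <- function(data, grid = 10^seq(-2, 2), beta = 1,
                                   n_bins = NULL) {
  if (!length(grid)) stop("grid must be non-empty")
  grid <- sort(grid)
  trees <- lapply(grid, function(a) bhc_build(data, alpha = a, beta = beta,
                                              n_bins = n_bins))
  lml <- vapply(trees, function(t) t$log_ml_root, numeric(1))
  best <- which.max(lml) # first maximum = smallest alpha on ties
  list(alpha = grid[best], log_ml = stats::setNames(lml, grid),
       tree = trees[[best]])
}

#' Export a BHC tree as Newick
#'
#' Internal nodes carry their posterior merge probability `r_k` as support
#' values; branch lengths are unit. Item labels are sanitised (characters
#' meaningful to Newick replaced by `_`).
#'
#' @param tree a [bhc_build()] tree.
#' @param path optional file to write to.
#' @return the Newick string, invisibly if written to file.
#' @export
bhc_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "bhc_tree"))
  n <- tree$n_items
  lab <- gsub("[][();,: ]", "_", tree$items)
  render <- function(node) {
    if (node <= n) return(paste0(lab[node], ":1"))
    paste0("(", render(tree$children[node, 1]), ",",
           render(tree$children[node, 2]), ")",
           formatC(tree$r[node], digits = 4, format = "f"), ":1")
  }
  nwk <- paste0("(", render(tree$children[2 * n - 1, 1]), ",",
                render(tree$children[2 * n - 1, 2]), ")",
                formatC(tree$r[2 * n - 1], digits = 4, format = "f"), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Bi-cluster a concatenated triad feature matrix
#'
#' Runs BHC twice on a features x individuals matrix (rows typically
#' concatenate the three compartments' variables over the shared pairs):
#' once with items = features and once with items = individuals. Both runs
#' see per-feature quantile categories — each variable is discretized across
#' individuals into `n_bins` levels, which removes the between-feature
#' abundance scale so that clustering reflects co-variation patterns.
#' Transposing the input swaps the two trees.
#'
#' @param feature_matrix numeric matrix, features in rows, individuals in
#'   columns.
#' @param alpha,beta,n_bins model hyperparameters (defaults 1, 1, 3).
#' @return list with `feature_tree`, `individual_tree`, and the two cluster
#'   assignments `feature_clusters`, `individual_clusters` at the r >= 0.5
#'   cut.
#' @export
bicluster <- function(feature_matrix, alpha = 1, beta = 1, n_bins = 3) {
  fm <- as.matrix(feature_matrix)
  if (nrow(fm) < 2 || ncol(fm) < 2)
    stop("need at least 2 features and 2 individuals")
  feat_disc <- t(discretize(t(fm), n_bins)$values)   # per-feature categories
  ind_disc <- discretize(fm, n_bins)$values          # per-individual categories
  feature_tree <- bhc_build(feat_disc, alpha, beta, n_bins)
  individual_tree <- bhc_build(t(ind_disc), alpha, beta, n_bins)
  list(feature_tree = feature_tree,
       individual_tree = individual_tree,
       feature_clusters = cut_tree(feature_tree),
       individual_clusters = cut_tree(individual_tree))
}

#' Assemble the concatenated triad feature matrix
#'
#' Stacks the three compartments' variables row-wise over the shared pair
#' identifiers; feature names are prefixed with their compartment.
#'
#' @param maternal,milk,infant matrices with pair-id rownames (samples x
#'   variables), e.g. from [compartment_matrix()].
#' @return features x pairs numeric matrix.
#' @export
triad_feature_matrix <- function(maternal, milk, infant) {
  mats <- list(maternal_plasma = as.matrix(maternal), milk = as.matrix(milk),
               infant_plasma = as.matrix(infant))
  pairs <- Reduce(intersect, lapply(mats, rownames))
  if (length(pairs) < 2) stop("fewer than 2 shared pair identifiers")
  do.call(rbind, lapply(names(mats), function(cp) {
    m <- t(mats[[cp]][pairs, , drop = FALSE])
    rownames(m) <- paste0(cp, ":", rownames(m))
    m
  }))
}

#' Write a cluster assignment table as TSV
#'
#' Columns `item cluster_id compartment`; the compartment is parsed from a
#' `compartment:variable` item prefix when present.
#' @param clusters named integer vector from [cut_tree()].
#' @param path file path.
#' @export
write_clusters <- function(clusters, path) {
  item <- names(clusters)
  compartment <- ifelse(grepl(":", item), sub(":.*$", "", item), NA_character_)
  utils::write.table(
    data.frame(item = item, cluster_id = as.integer(clusters),
               compartment = compartment, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
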