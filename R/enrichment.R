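# Marker enrichment within feature clusters: expected-by-chance counts,
# percentage enrichment, and an exact hypergeometric tail as companion
# statistic.

#' Expected marker count in a cluster under random placement
#'
#' If `marker_set_size` markers are placed uniformly among
#' `total_features` features, a cluster (or union of clusters) holding
#' `cluster_size` features is expected to contain
#' `marker_set_size * cluster_size / total_features` of them. For the five
#' growth biomarkers in a 46-feature cluster union out of 428 features this
#' is 0.54.
#'
#' @param marker_set_size,cluster_size,total_features non-negative counts
#'   with `total_features >= cluster_size`.
#' @return expected count (real).
#' @export
expected_count <- function(marker_set_size, cluster_size, total_features) {
  if (any(total_features <= 0)) stop("total_features must be positive")
  if (any(cluster_size < 0) || any(marker_set_size < 0))
    stop("counts must be non-negative")
  if (any(cluster_size > total_features))
    stop("cluster_size cannot exceed total_features")
  marker_set_size * cluster_size / total_features
}

#' Percentage enrichment of an observed marker count
#'
#' `100 * observed / expected`; 100% means exactly the chance expectation.
#' Values are retained at full precision; round to the nearest integer for
#' reporting.
#'
#' @param observed observed marker count in the cluster(s).
#' @param expected expected count, > 0 (e.g. from [expected_count()]).
#' @return enrichment in percent.
#' @export
enrichment_percent <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected count must be positive")
  if (any(observed < 0)) stop("observed count must be non-negative")
  100 * observed / expected
}

#' Upper-tail hypergeometric probability of a marker count
#'
#' `P(X >= observed)` where X is the number of markers landing in a cluster
#' of `cluster_size` features drawn without replacement from
#' `total_features` features of which `marker_set_size` are markers.
#'
#' @inheritParams expected_count
#' @param observed observed marker count.
#' @return upper-tail probability.
#' @export
hypergeometric_pvalue <- function(observed, marker_set_size, cluster_size,
                                  total_features) {
  if (total_features <= 0 || cluster_size < 0 || marker_set_size < 0 ||
      observed < 0 || cluster_size > total_features ||
      marker_set_size > total_features ||
      observed > min(marker_set_size, cluster_size))
    stop("inconsistent counts for the hypergeometric null")
  stats::phyper(observed - 1, marker_set_size,
                total_features - marker_set_size, cluster_size,
                lower.tail = FALSE)
}

#' Score marker enrichment over a cluster assignment
#'
#' Evaluates one or more marker sets against clusters of a feature
#' partition (e.g. from [cut_tree()]). Clusters can be grouped: passing
#' `clusters_eval = list(growth = c(11, 12))` evaluates the union of
#' clusters 11 and 12 as one selection, mirroring joint-cluster arithmetic.
#'
#' @param assignment named integer vector: feature -> cluster id.
#' @param marker_sets named list of character vectors of feature names.
#' @param clusters_eval named list of integer vectors of cluster ids to
#'   evaluate (default: each cluster separately).
#' @return data frame, one row per (marker set, cluster selection):
#'   observed, expected, enrichment percent and hypergeometric p.
#' @export
enrichment_report <- function(assignment, marker_sets, clusters_eval = NULL) {
  total <- length(assignment)
  if (is.null(clusters_eval)) {
    ids <- sort(unique(assignment))
    clusters_eval <- stats::setNames(as.list(ids), paste0("cluster_", ids))
  }
  rows <- list()
  for (ms in names(marker_sets)) {
    markers <- intersect(marker_sets[[ms]], names(assignment))
    for (sel in names(clusters_eval)) {
      in_sel <- assignment %in% clusters_eval[[sel]]
      size <- sum(in_sel)
      obs <- sum(names(assignment)[in_sel] %in% markers)
      exp_ <- expected_count(length(markers), size, total)
      rows[[length(rows) + 1]] <- data.frame(
        marker_set = ms, clusters = sel,
        cluster_size = size, total_features = total,
        marker_set_size = length(markers), observed = obs,
        expected = exp_,
        enrichment_pct = if (exp_ > 0) enrichment_percent(obs, exp_) else NA_real_,
        p_hyper = if (size > 0 && length(markers) > 0)
          hypergeometric_pvalue(obs, length(markers), size, total) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an enrichment report as TSV
#' @param report output of [enrichment_report()].
#' @param path file path.
#' @export
write_enrichment <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
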