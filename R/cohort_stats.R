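# Mother-vs-infant univariate comparison and PCA.

#' Square-root-corrected significance threshold
#'
#' The multiple-testing threshold used for the dependent DIMS variables:
#' `alpha / sqrt(n_variables)`. With 1248 variables and alpha = 0.05 this
#' gives 0.0014 (2 s.f.).
#'
#' @param alpha nominal level in (0, 1); default 0.05.
#' @param n_variables number of variables tested (>= 1).
#' @return the threshold p-value.
#' @export
fdr_threshold <- function(alpha = 0.05, n_variables) {
  if (length(n_variables) != 1 || !is.finite(n_variables) || n_variables < 1)
    stop("n_variables must be a single integer >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / sqrt(n_variables)
}

#' Univariate mother-vs-infant comparison
#'
#' Per shared variable: compartment means and SDs and a two-sided Student
#' t-test, paired by mother-infant pair identifier by default (Welch
#' two-sample with `paired = FALSE`). Significance is called by strict `<`
#' against [fdr_threshold()]. Zero-variance paired differences do not abort
#' the run: they yield `degenerate = TRUE` with p = 1 when all differences
#' are zero (no effect) and p = NA otherwise.
#'
#' @param mothers,infants [abundance_matrix()] objects or plain matrices
#'   (rows aligned by rowname, typically pair ids).
#' @param paired paired t-test (default) or Welch two-sample.
#' @param alpha nominal level for the threshold.
#' @param n_variables variable count used in the threshold; defaults to the
#'   number of shared variables tested here, but can be set to the full
#'   survey size when this is a subset.
#' @return data frame with one row per variable: means, SDs, `p_value`,
#'   `significant`, `degenerate`, plus the `threshold` as an attribute.
#' @export
compare_pairs <- function(mothers, infants, paired = TRUE, alpha = 0.05,
                          n_variables = NULL) {
  M <- if (inherits(mothers, "abundance_matrix"))
    compartment_matrix(mothers, "maternal_plasma") else as.matrix(mothers)
  I <- if (inherits(infants, "abundance_matrix"))
    compartment_matrix(infants, "infant_plasma") else as.matrix(infants)
  shared <- intersect(colnames(M), colnames(I))
  if (is.null(colnames(M)) && ncol(M) == ncol(I)) {
    shared <- colnames(M) <- colnames(I) <- paste0("V", seq_len(ncol(M)))
  }
  if (!length(shared)) stop("matrices share no variables")
  M <- M[, shared, drop = FALSE]; I <- I[, shared, drop = FALSE]
  if (paired) {
    common <- intersect(rownames(M), rownames(I))
    if (length(common) < 2) stop("need at least 2 aligned pairs")
    M <- M[common, , drop = FALSE]; I <- I[common, , drop = FALSE]
  } else if (nrow(M) < 2 || nrow(I) < 2) stop("need at least 2 samples per group")
  if (is.null(n_variables)) n_variables <- length(shared)
  thr <- fdr_threshold(alpha, n_variables)
  res <- do.call(rbind, lapply(shared, function(v) {
    x <- M[, v]; y <- I[, v]
    degenerate <- FALSE
    # a zero-variance difference (or a variance at floating-point noise
    # level, as from exactly shifted data) cannot support a t statistic
    if (paired) {
      d <- x - y
      tiny <- stats::sd(d) <= 1e-10 * (abs(mean(d)) + mean(abs(d)))
      if (stats::sd(d) == 0 || tiny) {
        degenerate <- TRUE
        p <- if (all(d == 0)) 1 else NA_real_
      } else p <- stats::t.test(x, y, paired = TRUE)$p.value
    } else {
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        degenerate <- TRUE
        p <- if (mean(x) == mean(y)) 1 else NA_real_
      } else p <- stats::t.test(x, y, paired = FALSE)$p.value
    }
    data.frame(variable = v,
               mean_mother = mean(x), sd_mother = stats::sd(x),
               mean_infant = mean(y), sd_infant = stats::sd(y),
               p_value = p,
               significant = !is.na(p) && p < thr,
               degenerate = degenerate,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  attr(res, "n_variables") <- n_variables
  res
}

#' Principal component scores of a lipid profile
#'
#' Mean-centred (and by default unit-variance-scaled) PCA via singular value
#' decomposition, with a deterministic sign convention: within each
#' component the largest-magnitude loading is made positive. Zero-variance
#' variables are dropped with a warning when scaling; rank deficiency
#' reduces the number of returned components with a warning.
#'
#' @param x an [abundance_matrix()] or numeric matrix (samples x variables).
#' @param n_components number of components requested (default 2).
#' @param scale. unit-variance scaling (default `TRUE`).
#' @return list with `scores`, `loadings`, `explained_variance` (fractions)
#'   and `sdev`.
#' @export
pca_scores <- function(x, n_components = 2, scale. = TRUE) {
  values <- if (inherits(x, "abundance_matrix")) x$values else as.matrix(x)
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("PCA needs at least 2 samples and 2 variables")
  if (scale.) {
    const <- apply(values, 2, stats::sd) == 0
    if (any(const)) {
      warning(sum(const), " zero-variance variable(s) dropped before scaling")
      values <- values[, !const, drop = FALSE]
    }
  }
  pc <- stats::prcomp(values, center = TRUE, scale. = scale.)
  k <- min(n_components, sum(pc$sdev > 1e-12))
  if (k < n_components)
    warning("rank-deficient input: returning ", k, " component(s)")
  k <- max(k, 1)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  list(scores = scores, loadings = loadings,
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       sdev = pc$sdev[seq_len(k)])
}

#' Write univariate comparison results as TSV
#' @param results output of [compare_pairs()].
#' @param path file path.
#' @export
write_comparison <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
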