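# Cross-compartment biomarker correlation chain:
# infant candidate biomarkers -> milk variables -> maternal variables.

#' Default candidate-biomarker set
#'
#' The five infant-plasma phospholipids previously associated with infant
#' growth: healthy growth PC(34:1) (i.e. PC(18:1/16:0)) and PC-O(34:1);
#' poor weight gain PC(38:4) (PC(20:4/18:0)), PC-O(36:4) and SM(34:2)
#' (SM(d18:1/16:0)).
#'
#' @return list with character vectors `healthy_growth` and `poor_growth`.
#' @export
cbm_default <- function() {
  list(healthy_growth = c("PC(34:1)", "PC-O(34:1)"),
       poor_growth = c("PC(38:4)", "PC-O(36:4)", "SM(34:2)"))
}

#' Pearson correlation table between two variable sets
#'
#' Sample Pearson correlations for every (X-variable, Y-variable) pair,
#' using pairwise-complete observations. Pairs with fewer than `min_pairs`
#' complete observations, or with zero variance, are reported as `NA`.
#'
#' @param X,Y numeric matrices with aligned rows (same pair identifiers, in
#'   the same order if unnamed).
#' @param min_pairs minimum complete observations per pair (default 10).
#' @return matrix of correlations, X variables in rows, Y variables in
#'   columns.
#' @export
pearson_table <- function(X, Y, min_pairs = 10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    if (!setequal(rownames(X), rownames(Y)))
      stop("X and Y are not aligned on the same pair identifiers")
    Y <- Y[rownames(X), , drop = FALSE]
  } else if (nrow(X) != nrow(Y)) {
    stop("X and Y must have the same number of rows")
  }
  if (nrow(X) < 3) stop("need at least 3 observations")
  r <- suppressWarnings(stats::cor(X, Y, use = "pairwise.complete.obs"))
  n_complete <- crossprod(!is.na(X) * 1, !is.na(Y) * 1)
  r[n_complete < min_pairs] <- NA_real_
  r
}

#' Build the three-compartment correlation chain
#'
#' Stage 1 correlates every infant-plasma candidate biomarker with every
#' milk variable; milk variables with at least one `|r| >= threshold` are
#' selected. Stage 2 correlates the selected milk variables with every
#' maternal-plasma variable. Rows of both stages are ordered by their
#' maximum absolute correlation.
#'
#' @param infant,milk,maternal [abundance_matrix()] objects or matrices with
#'   pair-id rownames (aligned rows).
#' @param cbms candidate-biomarker set as from [cbm_default()].
#' @param threshold selection threshold on `|r|`, inclusive (default 0.5).
#' @param min_pairs passed to [pearson_table()].
#' @return object of class `chain_result`: list with `stage1`,
#'   `selected_milk`, `stage2`, `threshold`.
#' @export
build_chain <- function(infant, milk, maternal, cbms = cbm_default(),
                        threshold = 0.5, min_pairs = 10) {
  I <- if (inherits(infant, "abundance_matrix"))
    compartment_matrix(infant, "infant_plasma") else as.matrix(infant)
  K <- if (inherits(milk, "abundance_matrix"))
    compartment_matrix(milk, "milk") else as.matrix(milk)
  M <- if (inherits(maternal, "abundance_matrix"))
    compartment_matrix(maternal, "maternal_plasma") else as.matrix(maternal)
  cbm_all <- unlist(cbms, use.names = FALSE)
  absent <- setdiff(cbm_all, colnames(I))
  if (length(absent))
    stop("candidate biomarkers absent from infant matrix: ",
         paste(absent, collapse = ", "))
  stage1 <- pearson_table(I[, cbm_all, drop = FALSE], K, min_pairs = min_pairs)
  max_abs <- suppressWarnings(apply(abs(stage1), 2, max, na.rm = TRUE))
  max_abs[!is.finite(max_abs)] <- -Inf
  selected <- colnames(stage1)[max_abs >= threshold]
  stage2 <- if (length(selected)) {
    s2 <- pearson_table(K[, selected, drop = FALSE], M, min_pairs = min_pairs)
    ord <- order(-suppressWarnings(apply(abs(s2), 1, max, na.rm = TRUE)))
    s2[ord, , drop = FALSE]
  } else matrix(numeric(0), 0, ncol(M), dimnames = list(NULL, colnames(M)))
  structure(list(stage1 = stage1,
                 selected_milk = selected[order(-max_abs[selected])],
                 stage2 = stage2,
                 threshold = threshold),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf(
    "chain_result: %d CBMs x %d milk variables; %d milk variable(s) with |r| >= %g; stage2 vs %d maternal variables\n",
    nrow(x$stage1), ncol(x$stage1), length(x$selected_milk), x$threshold,
    ncol(x$stage2)))
  invisible(x)
}

#' Write the two chain tables as TSV
#'
#' `<stem>_stage1.tsv` holds CBM rows by milk columns; `<stem>_stage2.tsv`
#' holds selected-milk rows by maternal columns.
#' @param x a `chain_result`.
#' @param stem output path stem.
#' @export
write_chain <- function(x, stem) {
  stopifnot(inherits(x, "chain_result"))
  for (part in c("stage1", "stage2")) {
    tab <- data.frame(variable = rownames(x[[part]]), x[[part]],
                      check.names = FALSE)
    utils::write.table(tab, paste0(stem, "_", part, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(stem)
}
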