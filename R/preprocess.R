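# DIMS preprocessing: annotated peak lists -> per-mode relative-abundance
# matrices. Fixed stage order: blank subtraction -> isobar aggregation ->
# presence filter -> total-signal normalization.

#' Subtract mean blank signal from every sample
#'
#' Per variable, the mean intensity over all blank samples is subtracted from
#' every study sample; negative results are clipped to zero.
#'
#' @param samples numeric matrix, samples x variables.
#' @param blanks numeric matrix with the same variables (columns), one row
#'   per blank sample, or `NULL`.
#' @return matrix of the same shape as `samples`.
#' @export
subtract_blank <- function(samples, blanks) {
  samples <- as.matrix(samples)
  if (is.null(blanks) || nrow(as.matrix(blanks)) == 0) {
    warning("no blank samples supplied; intensities passed through unchanged")
    return(samples)
  }
  blanks <- as.matrix(blanks)
  if (ncol(blanks) != ncol(samples) ||
      !identical(colnames(blanks), colnames(samples)))
    stop("blanks and samples must share the same variables")
  out <- sweep(samples, 2, colMeans(blanks), "-")
  out[out < 0] <- 0
  out
}

#' Presence filter
#'
#' Keeps a variable iff it is measured (nonzero) in strictly more than
#' `min_fraction` of the samples considered.
#'
#' @param matrix numeric matrix, samples x variables.
#' @param min_fraction minimum presence fraction, in `[0, 1)`; default 0.05.
#' @param consider optional logical vector of rows over which presence is
#'   assessed (e.g. study samples only); default all rows.
#' @return the matrix restricted to surviving variables.
#' @export
presence_filter <- function(matrix, min_fraction = 0.05, consider = NULL) {
  matrix <- as.matrix(matrix)
  if (min_fraction < 0 || min_fraction >= 1)
    stop("min_fraction must lie in [0, 1)")
  if (is.null(consider)) consider <- rep(TRUE, nrow(matrix))
  frac <- colMeans(matrix[consider, , drop = FALSE] > 0)
  matrix[, frac > min_fraction, drop = FALSE]
}

# Union-find over library ranks: peaks whose candidate sets overlap collapse
# into one composite variable.
.components <- function(match_sets) {
  ids <- sort(unique(unlist(match_sets)))
  parent <- stats::setNames(ids, as.character(ids))
  find <- function(i) {
    while (parent[[as.character(i)]] != i) i <- parent[[as.character(i)]]
    i
  }
  for (s in match_sets) {
    if (length(s) < 2) next
    r <- find(s[1])
    for (j in s[-1]) {
      rj <- find(j)
      if (rj != r) parent[[as.character(max(rj, r))]] <- min(rj, r)
      r <- min(r, rj)
    }
  }
  stats::setNames(vapply(ids, find, numeric(1)), as.character(ids))
}

#' Aggregate annotated peaks into composite variables
#'
#' Library species linked by any shared peak (isobars within the ppm window)
#' are merged into one composite variable. A variable's intensity in a sample
#' is the sum of the member peaks' intensities; its label is the
#' highest-ranked member species (library order), the remaining members being
#' recorded as alternates.
#'
#' @param annotated output of [annotate_peaks()], optionally with
#'   `sample_id`/`compartment` columns (single-sample lists are treated as
#'   one sample).
#' @return list with `values` (samples x variables intensity matrix),
#'   `sample_info` and `var_info`.
#' @export
aggregate_isobars <- function(annotated) {
  library <- attr(annotated, "library")
  mode <- attr(annotated, "mode")
  if (is.null(library)) stop("input must come from annotate_peaks()")
  if (!"sample_id" %in% names(annotated))
    annotated$sample_id <- rep("sample1", nrow(annotated))
  if (!"compartment" %in% names(annotated))
    annotated$compartment <- rep(NA_character_, nrow(annotated))
  kept <- annotated[!annotated$removed, , drop = FALSE]
  sample_ids <- unique(annotated$sample_id)
  comp <- vapply(sample_ids, function(s)
    as.character(annotated$compartment[annotated$sample_id == s][1]), character(1),
    USE.NAMES = FALSE)
  lib_by_rank <- library[order(library$rank), , drop = FALSE]
  if (nrow(kept) == 0) {
    return(list(values = matrix(0, length(sample_ids), 0,
                                dimnames = list(sample_ids, NULL)),
                sample_info = data.frame(sample_id = sample_ids,
                                         compartment = comp,
                                         stringsAsFactors = FALSE),
                var_info = data.frame(label = character(0),
                                      lipid_class = character(0),
                                      members = character(0),
                                      alternates = character(0),
                                      stringsAsFactors = FALSE)))
  }
  comp_of <- .components(kept$matches)       # species rank -> component root
  peak_var <- vapply(kept$matches, function(s)
    comp_of[[as.character(s[1])]], numeric(1))
  roots <- sort(unique(peak_var))
  var_info <- do.call(rbind, lapply(roots, function(r) {
    members <- sort(as.numeric(names(comp_of)[comp_of == r]))
    nm <- lib_by_rank$name[members]
    data.frame(label = nm[1],
               lipid_class = lib_by_rank$lipid_class[members[1]],
               members = paste(nm, collapse = ";"),
               alternates = paste(nm[-1], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  values <- matrix(0, length(sample_ids), length(roots),
                   dimnames = list(sample_ids, var_info$label))
  agg <- stats::aggregate(kept$intensity,
                          by = list(sample = kept$sample_id, var = peak_var),
                          FUN = sum)
  values[cbind(match(agg$sample, sample_ids), match(agg$var, roots))] <- agg$x
  list(values = values,
       sample_info = data.frame(sample_id = sample_ids, compartment = comp,
                                stringsAsFactors = FALSE),
       var_info = var_info)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize intensities to percent of per-sample total signal
#'
#' Each sample's intensities are divided by the sample total and scaled to
#' percent, the relative-abundance convention for semi-quantitative DIMS.
#' Positive- and negative-mode matrices are normalized separately.
#'
#' @param values samples x variables intensity matrix.
#' @param sample_info,var_info metadata data frames (see
#'   [abundance_matrix()]).
#' @param mode ionisation mode tag.
#' @return an [abundance_matrix()] whose rows each sum to 100.
#' @export
normalize_relative <- function(values, sample_info, var_info, mode) {
  values <- as.matrix(values)
  totals <- rowSums(values)
  bad <- which(totals <= 0)
  if (length(bad))
    stop("sample(s) with zero total signal: ",
         paste(sample_info$sample_id[bad], collapse = ", "))
  abundance_matrix(100 * values / totals, sample_info, var_info, mode,
                   normalized = TRUE)
}

#' Summarize variables to lipid-class level
#'
#' @param x a normalized [abundance_matrix()].
#' @param compartments restrict the cohort summary to these compartments
#'   (default: all study samples, excluding blanks and QCs).
#' @return list with `per_sample` (samples x classes matrix of summed
#'   relative abundance) and `summary` (cohort mean and SD per class per
#'   compartment).
#' @export
summarize_classes <- function(x, compartments = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  cls <- x$var_info$lipid_class
  if (anyNA(cls) || any(!cls %in% .VALID_CLASSES))
    stop("variables with unknown lipid class")
  classes <- sort(unique(cls))
  ind <- outer(cls, classes, "==") * 1
  per_sample <- x$values %*% ind
  colnames(per_sample) <- classes
  keep <- .study_rows(x)
  if (!is.null(compartments)) keep <- keep & x$sample_info$compartment %in% compartments
  comp <- x$sample_info$compartment[keep]
  ps <- per_sample[keep, , drop = FALSE]
  summary <- do.call(rbind, lapply(unique(comp), function(cp) {
    m <- ps[comp == cp, , drop = FALSE]
    data.frame(compartment = cp, lipid_class = classes,
               mean = colMeans(m), sd = apply(m, 2, stats::sd),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(per_sample = per_sample, summary = summary)
}

#' Run the full DIMS preprocessing pipeline
#'
#' For each ionisation mode present in `peaks`: annotate against the library
#' (ppm window), aggregate isobars into composite variables, subtract the
#' mean blank signal, apply the presence filter over study samples, and
#' normalize each sample to percent of total signal. Blank samples are
#' dropped after subtraction; QC samples are carried through but never enter
#' presence assessment or downstream statistics.
#'
#' @param peaks long-format peak table with columns
#'   `sample_id compartment mode mz intensity`.
#' @param library a [lipid_library()]; default [default_lipid_library()].
#' @param ppm_tol annotation mass tolerance in ppm (default 8).
#' @param min_fraction presence threshold (default 0.05, strictly exceeded).
#' @return named list of [abundance_matrix()] objects, one per mode, with a
#'   `log` attribute recording per-stage variable counts.
#' @export
preprocess_peaks <- function(peaks, library = default_lipid_library(),
                             ppm_tol = 8, min_fraction = 0.05) {
  peaks <- as.data.frame(peaks)
  need <- c("sample_id", "compartment", "mode", "mz", "intensity")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peak table missing columns: ", paste(miss, collapse = ", "))
  out <- list()
  log <- list()
  for (mode in intersect(c("positive", "negative"), unique(peaks$mode))) {
    pk <- peaks[peaks$mode == mode, , drop = FALSE]
    ann <- annotate_peaks(pk, library, mode = mode, ppm_tol = ppm_tol)
    agg <- aggregate_isobars(ann)
    is_blank <- agg$sample_info$compartment == "blank"
    values <- subtract_blank(agg$values[!is_blank, , drop = FALSE],
                             if (any(is_blank)) agg$values[is_blank, , drop = FALSE]
                             else NULL)
    sample_info <- agg$sample_info[!is_blank, , drop = FALSE]
    study <- !sample_info$compartment %in% c("blank", "qc")
    filtered <- presence_filter(values, min_fraction, consider = study)
    var_info <- agg$var_info[match(colnames(filtered), agg$var_info$label), ,
                             drop = FALSE]
    # drop samples that lost all signal to annotation/blank stages early,
    # so normalization can report them by name rather than divide by zero
    sample_info$pair_id <- .pair_from_sample(sample_info$sample_id)
    out[[mode]] <- normalize_relative(filtered, sample_info, var_info, mode)
    log[[mode]] <- list(n_peaks = nrow(pk), n_removed = sum(ann$removed),
                        n_variables_annotated = ncol(agg$values),
                        n_variables_filtered = ncol(filtered))
  }
  attr(out, "log") <- log
  out
}

# Sample-id convention of the bundled generator: one letter for the
# compartment (M/K/I), digits for the pair. Unknown ids get NA pair.
.pair_from_sample <- function(sample_id) {
  m <- regmatches(sample_id, regexec("^[MKI](\\d+)$", sample_id))
  vapply(m, function(x) if (length(x) == 2) sprintf("P%s", x[2]) else NA_character_,
         character(1))
}

#' Read a long-format peak-list TSV
#'
#' Columns: `sample_id compartment mode mz intensity`.
#' @param path file path.
#' @export
read_peaklists <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @param peaks long-format peak table.
#' @rdname read_peaklists
#' @export
write_peaklists <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
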