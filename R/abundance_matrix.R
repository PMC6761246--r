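#' Relative-abundance matrix container
#'
#' Light S3 container pairing a numeric samples-by-variables matrix with
#' sample metadata (compartment, pair identifier) and variable metadata
#' (lipid class, composite members, ionisation mode). Values are relative
#' abundance in percent of the per-mode total signal once
#' [normalize_relative()] has run; before that they are raw intensities.
#'
#' @param values numeric matrix, rows = samples, columns = variables.
#' @param sample_info data frame with `sample_id`, `compartment` and
#'   optionally `pair_id`, one row per matrix row.
#' @param var_info data frame with `label`, `lipid_class`, `members` and
#'   `alternates`, one row per matrix column.
#' @param mode ionisation mode of all variables.
#' @param normalized logical; `TRUE` once values are percentages.
#' @return object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, sample_info, var_info, mode,
                             normalized = FALSE) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values),
            nrow(values) == nrow(sample_info),
            ncol(values) == nrow(var_info))
  if (!"pair_id" %in% names(sample_info)) sample_info$pair_id <- NA_character_
  rownames(values) <- sample_info$sample_id
  colnames(values) <- var_info$label
  structure(list(values = values,
                 sample_info = as.data.frame(sample_info),
                 var_info = as.data.frame(var_info),
                 mode = mode, normalized = normalized),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix [%s%s]: %d samples x %d variables\n",
              x$mode, if (x$normalized) ", % of total" else ", raw intensity",
              nrow(x$values), ncol(x$values)))
  tb <- table(x$sample_info$compartment)
  cat("  samples:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' @export
as.matrix.abundance_matrix <- function(x, ...) x$values

#' Extract one compartment as a pair-indexed matrix
#'
#' Returns the value matrix restricted to a compartment, with rows named and
#' ordered by pair identifier so that matrices from different compartments
#' align row-by-row.
#'
#' @param x an [abundance_matrix()].
#' @param compartment one of the compartment labels in `x$sample_info`.
#' @return numeric matrix with `pair_id` rownames.
#' @export
compartment_matrix <- function(x, compartment) {
  stopifnot(inherits(x, "abundance_matrix"))
  keep <- x$sample_info$compartment == compartment
  if (!any(keep)) stop("no samples in compartment ", compartment)
  m <- x$values[keep, , drop = FALSE]
  pid <- x$sample_info$pair_id[keep]
  if (anyNA(pid)) stop("compartment ", compartment, " has samples without pair_id")
  rownames(m) <- pid
  m[order(pid), , drop = FALSE]
}

.study_rows <- function(x) !x$sample_info$compartment %in% c("blank", "qc")

#' Write / read an abundance matrix as TSV
#'
#' The wide table holds samples by variables; a `<path>.vars.tsv` sidecar
#' records each variable's class, composite members and mode.
#' @param x an [abundance_matrix()].
#' @param path output path for the wide table.
#' @rdname abundance_io
#' @export
write_abundance <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  wide <- data.frame(sample_id = x$sample_info$sample_id,
                     compartment = x$sample_info$compartment,
                     pair_id = x$sample_info$pair_id,
                     x$values, check.names = FALSE)
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- x$var_info
  side$mode <- x$mode
  utils::write.table(side, paste0(path, ".vars.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
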