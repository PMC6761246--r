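# Monoisotopic atomic masses (Da), CODATA/IUPAC values.
.MONO <- c(C = 12, H = 1.00782503207, O = 15.99491461956,
           N = 14.0030740048, P = 30.97376163)
.PROTON <- 1.007276466
.NH4 <- .MONO[["N"]] + 4 * .MONO[["H"]] - (.MONO[["H"]] - .PROTON) # NH4+ as adduct mass
.H2O <- 2 * .MONO[["H"]] + .MONO[["O"]]

.mono_mass <- function(C = 0, H = 0, O = 0, N = 0, P = 0) {
  C * .MONO[["C"]] + H * .MONO[["H"]] + O * .MONO[["O"]] +
    N * .MONO[["N"]] + P * .MONO[["P"]]
}

# Neutral monoisotopic mass of a species from its sum-composition shorthand.
# c = total fatty-acyl (or backbone+acyl) carbons, d = total double bonds.
.neutral_mass <- function(class, c, d) {
  switch(class,
    TG   = .mono_mass(C = c + 3, H = 2 * c - 2 * d + 2, O = 6),
    DG   = .mono_mass(C = c + 3, H = 2 * c - 2 * d + 4, O = 5),
    MG   = .mono_mass(C = c + 3, H = 2 * c - 2 * d + 6, O = 4),
    PC   = .mono_mass(C = c + 8, H = 2 * c - 2 * d + 16, O = 8, N = 1, P = 1),
    `PC-O` = .mono_mass(C = c + 8, H = 2 * c - 2 * d + 18, O = 7, N = 1, P = 1),
    PE   = .mono_mass(C = c + 5, H = 2 * c - 2 * d + 10, O = 8, N = 1, P = 1),
    PS   = .mono_mass(C = c + 6, H = 2 * c - 2 * d + 10, O = 10, N = 1, P = 1),
    PI   = .mono_mass(C = c + 9, H = 2 * c - 2 * d + 15, O = 13, P = 1),
    PG   = .mono_mass(C = c + 6, H = 2 * c - 2 * d + 11, O = 10, P = 1),
    SM   = .mono_mass(C = c + 5, H = 2 * c - 2 * d + 13, O = 6, N = 2, P = 1),
    CE   = .mono_mass(C = c + 27, H = 2 * c - 2 * d + 44, O = 2),
    Cer  = .mono_mass(C = c, H = 2 * c - 2 * d + 1, O = 3, N = 1),
    FA   = .mono_mass(C = c, H = 2 * c - 2 * d, O = 2),
    Chol = .mono_mass(C = 27, H = 46, O = 1),
    stop("unknown lipid class: ", class)
  )
}

# Expected ion m/z for the adduct conventionally observed in DIMS for each
# class: [M+H]+ for phospholipids/SM/Cer, [M+NH4]+ for glycerides and CE,
# [M+H-H2O]+ for cholesterol and the DG water-loss fragment, [M-H]- for
# anionic lipids and free fatty acids.
.ion_mz <- function(class, c, d, mode, water_loss = FALSE) {
  m <- .neutral_mass(class, c, d)
  if (mode == "negative") return(m - .PROTON)
  if (water_loss || class == "Chol") return(m + .PROTON - .H2O)
  if (class %in% c("TG", "DG", "MG", "CE")) return(m + .NH4)
  m + .PROTON
}

.VALID_CLASSES <- c("TG", "DG", "MG", "PC", "PC-O", "PE", "PS", "PI", "PG",
                    "SM", "CE", "Chol", "Cer", "FA")

#' Construct a lipid species library
#'
#' A lipid library is a data frame of species, one row per expected ion, with
#' columns `name`, `lipid_class`, `total_carbons`, `double_bonds`,
#' `theoretical_mz`, `mode` and `odd_chain`. Entries keep their supplied order
#' as `rank` (used to pick the reporting label of a composite isobar
#' variable) and are sorted by `mode` then `theoretical_mz` so that
#' mass-window queries are logarithmic.
#'
#' @param entries data frame with columns `name`, `lipid_class`
#'   (alias `class`), `total_carbons` (alias `carbons`), `double_bonds`,
#'   `theoretical_mz` (alias `mz`) and `mode` (`"positive"`/`"negative"`).
#' @return object of class `lipid_library` (a data frame).
#' @export
lipid_library <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  alias <- c(class = "lipid_class", carbons = "total_carbons", mz = "theoretical_mz")
  for (a in names(alias)) {
    if (a %in% names(entries) && !(alias[[a]] %in% names(entries)))
      names(entries)[names(entries) == a] <- alias[[a]]
  }
  need <- c("name", "lipid_class", "total_carbons", "double_bonds",
            "theoretical_mz", "mode")
  miss <- setdiff(need, names(entries))
  if (length(miss)) stop("library is missing columns: ", paste(miss, collapse = ", "))
  if (any(!entries$lipid_class %in% .VALID_CLASSES))
    stop("unknown lipid class: ",
         paste(unique(setdiff(entries$lipid_class, .VALID_CLASSES)), collapse = ", "))
  if (any(entries$theoretical_mz <= 0)) stop("theoretical_mz must be positive")
  if (any(entries$total_carbons < 0) || any(entries$double_bonds < 0))
    stop("carbon and double-bond counts must be non-negative")
  if (any(!entries$mode %in% c("positive", "negative")))
    stop("mode must be 'positive' or 'negative'")
  dup <- duplicated(entries[, c("name", "mode")])
  if (any(dup))
    stop("duplicate species names within a mode: ",
         paste(unique(entries$name[dup]), collapse = ", "))
  entries$odd_chain <- entries$total_carbons %% 2L == 1L
  entries$rank <- seq_len(nrow(entries))
  entries <- entries[order(entries$mode, entries$theoretical_mz), , drop = FALSE]
  rownames(entries) <- NULL
  class(entries) <- c("lipid_library", "data.frame")
  entries
}

#' @export
print.lipid_library <- function(x, ...) {
  cat(sprintf("lipid_library: %d species (%d positive, %d negative), %d classes\n",
              nrow(x), sum(x$mode == "positive"), sum(x$mode == "negative"),
              length(unique(x$lipid_class))))
  invisible(x)
}

#' Relative mass difference in parts per million
#'
#' The ppm difference is computed relative to the theoretical monoisotopic
#' mass, the standard mass-accuracy convention:
#' `1e6 * |observed - theoretical| / theoretical`.
#'
#' @param observed_mz,theoretical_mz masses in Da, both strictly positive.
#'   Vectorised (recycled).
#' @return non-negative ppm difference(s).
#' @examples
#' ppm_difference(760.5912, 760.5851) # ~8 ppm
#' @export
ppm_difference <- function(observed_mz, theoretical_mz) {
  if (any(!is.finite(observed_mz)) || any(!is.finite(theoretical_mz)) ||
      any(observed_mz <= 0) || any(theoretical_mz <= 0))
    stop("masses must be finite and strictly positive")
  1e6 * abs(observed_mz - theoretical_mz) / theoretical_mz
}

#' Annotate peaks against a lipid library
#'
#' Each peak is matched to every library species (of the same ionisation
#' mode) whose theoretical m/z lies within `ppm_tol` parts per million.
#' Peaks with no match are flagged `removed`; peaks matching several species
#' (isobars) keep all candidates for downstream composite aggregation.
#'
#' @param peaks data frame with at least `mz` and `intensity`; an optional
#'   `mode` column must agree with the library subset used.
#' @param library a [lipid_library()].
#' @param mode ionisation mode of the peaks (`"positive"`/`"negative"`).
#' @param ppm_tol mass tolerance in ppm (default 8); matches with
#'   `ppm <= ppm_tol` are kept.
#' @return `peaks` with list-column `matches` (integer indices into
#'   `library` rows) and logical column `removed`.
#' @export
annotate_peaks <- function(peaks, library, mode = NULL, ppm_tol = 8) {
  stopifnot(inherits(library, "lipid_library"))
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  if (is.null(mode)) {
    if (!"mode" %in% names(peaks))
      stop("supply `mode` or include a mode column in `peaks`")
    mode <- unique(peaks$mode)
    if (length(mode) > 1) stop("peaks mix ionisation modes; annotate per mode")
  }
  if ("mode" %in% names(peaks) && nrow(peaks) && any(peaks$mode != mode))
    stop("peak mode column disagrees with requested mode: configuration error")
  if (!mode %in% c("positive", "negative")) stop("invalid mode: ", mode)
  lib <- library[library$mode == mode, , drop = FALSE]
  if (!nrow(lib)) stop("library has no entries for mode ", mode)
  if (nrow(peaks) && (any(peaks$mz <= 0) || any(peaks$intensity < 0)))
    stop("peaks require mz > 0 and intensity >= 0")
  libmz <- lib$theoretical_mz # sorted within mode by construction
  lo <- findInterval(peaks$mz / (1 + ppm_tol * 1e-6), libmz, left.open = TRUE) + 1L
  hi <- findInterval(peaks$mz / (1 - ppm_tol * 1e-6), libmz)
  matches <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    idx <- if (lo[i] > hi[i]) integer(0) else lo[i]:hi[i]
    # the window above is conservative; confirm with the exact ppm rule
    if (length(idx))
      idx <- idx[ppm_difference(peaks$mz[i], libmz[idx]) <= ppm_tol]
    matches[[i]] <- lib$rank[idx] # rank indexes the library's original order
  }
  peaks$matches <- matches
  peaks$removed <- lengths(matches) == 0L
  attr(peaks, "mode") <- mode
  attr(peaks, "library") <- library
  peaks
}

#' Read / write a lipid library as TSV
#'
#' The TSV dialect has header `name class carbons double_bonds mz mode`.
#' @param path file path.
#' @rdname library_io
#' @export
read_library <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lipid_library(tab)
}

#' @param library a [lipid_library()].
#' @rdname library_io
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "lipid_library"))
  out <- library[order(library$rank),
                 c("name", "lipid_class", "total_carbons", "double_bonds",
                   "theoretical_mz", "mode")]
  names(out) <- c("name", "class", "carbons", "double_bonds", "mz", "mode")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
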