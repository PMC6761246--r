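# The bundled species library is generated from sum compositions rather than
# shipped as data: every m/z is the exact monoisotopic ion mass for the
# class's conventional DIMS adduct.

.species_row <- function(class, c, d, mode, water_loss = FALSE, name = NULL) {
  if (is.null(name)) {
    name <- if (class == "Chol") "Chol" else sprintf("%s(%d:%d)", class, c, d)
    if (water_loss) name <- paste0(name, "-H2O")
  }
  data.frame(name = name, lipid_class = class, total_carbons = c,
             double_bonds = d,
             theoretical_mz = .ion_mz(class, c, d, mode, water_loss),
             mode = mode, stringsAsFactors = FALSE)
}

.species_grid <- function(class, carbons, dbs, mode, water_loss = FALSE) {
  g <- expand.grid(c = carbons, d = dbs)
  do.call(rbind, lapply(seq_len(nrow(g)), function(i)
    .species_row(class, g$c[i], g$d[i], mode, water_loss)))
}

#' Bundled default lipid species library
#'
#' A curated species universe spanning the lipid classes seen in plasma and
#' milk DIMS surveys: glycerides (even- and odd-chain TGs with their
#' diglyceride water-loss fragment ions), phosphatidylcholines (including the
#' five candidate growth biomarkers PC(34:1), PC-O(34:1), PC(38:4),
#' PC-O(36:4) and SM(34:2)), sphingomyelins (including odd-chain species),
#' eleven cholesteryl esters, cholesterol, ceramides and PEs in positive
#' mode, and PS/PI/PG/free fatty acids in negative mode. PE(37:1) is
#' deliberately retained although it is an exact isobar of PC(34:1), so the
#' composite-variable machinery is exercised by default.
#'
#' @return a [lipid_library()].
#' @export
default_lipid_library <- function() {
  pos <- list(
    # candidate biomarkers first so they win composite labels
    .species_row("PC", 34, 1, "positive"),
    .species_row("PC-O", 34, 1, "positive"),
    .species_row("PC", 38, 4, "positive"),
    .species_row("PC-O", 36, 4, "positive"),
    .species_row("SM", 34, 2, "positive"),
    .species_grid("PC", c(32, 34, 36, 38), 0:4, "positive"),
    .species_grid("PC-O", c(34, 36), c(2, 3), "positive"),
    .species_grid("SM", c(32, 34, 36, 42), c(0, 1), "positive"),
    .species_grid("SM", seq(31, 47, by = 2), 0:2, "positive"), # odd chain
    # cholesteryl esters: the 11 commonplace plasma species
    do.call(rbind, Map(function(c, d) .species_row("CE", c, d, "positive"),
                       c(16, 16, 18, 18, 18, 18, 20, 20, 20, 22, 22),
                       c(0, 1, 0, 1, 2, 3, 3, 4, 5, 5, 6))),
    .species_row("Chol", 27, 1, "positive"),
    .species_grid("TG", seq(44, 56, by = 2), 1:3, "positive"),
    .species_grid("TG", seq(43, 57, by = 2), 1:5, "positive"), # odd chain
    .species_grid("DG", c(32, 34, 36), c(1, 2), "positive"),
    # water-loss fragment targets for every bundled TG (loss of a 16:0 acyl)
    .species_grid("DG", seq(44, 56, by = 2) - 16, 1:3, "positive", water_loss = TRUE),
    .species_grid("DG", seq(43, 57, by = 2) - 16, 1:5, "positive", water_loss = TRUE),
    .species_grid("MG", c(16, 18), c(0, 1), "positive"),
    .species_grid("PE", c(34, 36, 38), c(1, 2), "positive"),
    .species_row("PE", 37, 1, "positive"), # exact isobar of PC(34:1)
    .species_grid("Cer", c(34, 40, 42), c(1, 2), "positive")
  )
  neg <- list(
    .species_grid("PS", c(36, 38, 40), c(1, 4), "negative"),
    .species_grid("PI", c(36, 38), c(1, 2, 4), "negative"),
    .species_grid("PG", c(34, 36), c(1, 2), "negative"),
    do.call(rbind, Map(function(c, d) .species_row("FA", c, d, "negative"),
                       c(14, 16, 16, 18, 18, 18, 20, 22),
                       c(0, 0, 1, 0, 1, 2, 4, 6)))
  )
  entries <- do.call(rbind, c(pos, neg))
  entries <- entries[!duplicated(entries[, c("name", "mode")]), , drop = FALSE]
  lipid_library(entries)
}

#' Map a triglyceride to its diglyceride water-loss fragment species
#'
#' In-source collisional loss of one fatty acyl (taken as 16:0, the most
#' common residue) from TG(c:d) yields an ion at the m/z of
#' `DG(c-16:d)-H2O`. Used by the synthetic generator to plant the artefact
#' peaks that inflate the apparent DG fraction of milk.
#'
#' @param tg_names character vector of TG shorthand names, e.g. `"TG(52:2)"`.
#' @return character vector of fragment species names.
#' @export
tg_fragment_name <- function(tg_names) {
  m <- regmatches(tg_names, regexec("^TG\\((\\d+):(\\d+)\\)$", tg_names))
  vapply(m, function(x) {
    if (length(x) != 3) return(NA_character_)
    sprintf("DG(%d:%d)-H2O", as.integer(x[2]) - 16L, as.integer(x[3]))
  }, character(1))
}
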