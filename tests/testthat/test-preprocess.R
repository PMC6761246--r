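test_that("blank subtraction uses the mean blank and clips at zero", {
  samples <- matrix(c(1000, 50, 200, 10), 2, 2,
                    dimnames = list(c("s1", "s2"), c("v1", "v2")))
  blanks <- matrix(c(90, 110, 100, 100), 2, 2, byrow = FALSE,
                   dimnames = list(c("b1", "b2"), c("v1", "v2")))
  out <- subtract_blank(samples, blanks)
  expect_equal(out["s1", "v1"], 900)   # 1000 - mean(90, 110)
  expect_equal(out["s2", "v1"], 0)     # 50 - 100, clipped
  expect_warning(pass <- subtract_blank(samples, NULL), "no blank")
  expect_identical(pass, samples)
  expect_error(subtract_blank(samples, blanks[, 1, drop = FALSE]), "share")
})

test_that("presence filter is strictly greater-than", {
  m <- matrix(0, 30, 3, dimnames = list(NULL, c("rare1", "rare2", "never")))
  m[1, "rare1"] <- 5              # 1/30 = 3.3% -> dropped
  m[1:2, "rare2"] <- 5            # 2/30 = 6.7% -> kept
  out <- presence_filter(m, 0.05)
  expect_identical(colnames(out), "rare2")
  # boundary: exactly 5% does not pass
  m2 <- matrix(0, 20, 1, dimnames = list(NULL, "v"))
  m2[1, 1] <- 1                   # exactly 5%
  expect_equal(ncol(presence_filter(m2, 0.05)), 0)
  expect_error(presence_filter(m, 1), "min_fraction")
})

test_that("isobar aggregation merges overlapping candidate sets", {
  lib <- default_lipid_library()
  # one peak hitting the PC(34:1)/PE(37:1) isobar pair, one clean TG peak
  peaks <- data.frame(
    sample_id = c("s1", "s1", "s2"),
    compartment = "maternal_plasma",
    mz = c(760.5851, 876.8015, 760.5851),
    intensity = c(10, 20, 30))
  ann <- annotate_peaks(peaks, lib, mode = "positive")
  agg <- aggregate_isobars(ann)
  expect_equal(ncol(agg$values), 2)
  expect_true("PC(34:1)" %in% agg$var_info$label)  # earlier library rank wins
  iso <- agg$var_info[agg$var_info$label == "PC(34:1)", ]
  expect_match(iso$alternates, "PE\\(37:1\\)")
  expect_equal(agg$values["s1", "PC(34:1)"], 10)
  expect_equal(agg$values["s2", "PC(34:1)"], 30)
  expect_equal(agg$values["s2", "TG(52:2)"], 0)
})

test_that("two same-sample peaks on one species sum into its variable", {
  lib <- toy_library()
  peaks <- data.frame(sample_id = "s1", compartment = "milk",
                      mz = c(760.5851 * (1 + 3e-6), 760.5851 * (1 - 3e-6)),
                      intensity = c(5, 7))
  ann <- annotate_peaks(peaks, lib, mode = "positive")
  agg <- aggregate_isobars(ann)
  expect_equal(unname(agg$values[1, "PC(34:1)"]), 12)
})

test_that("empty peak lists give an empty matrix", {
  lib <- toy_library()
  ann <- annotate_peaks(data.frame(mz = numeric(0), intensity = numeric(0)),
                        lib, mode = "positive")
  agg <- aggregate_isobars(ann)
  expect_equal(ncol(agg$values), 0)
})

test_that("normalization yields rows summing to 100 and is scale-invariant", {
  vals <- matrix(c(25, 75, 40, 60), 2, 2, byrow = TRUE)
  si <- data.frame(sample_id = c("s1", "s2"), compartment = "milk")
  vi <- data.frame(label = c("a", "b"), lipid_class = "TG",
                   members = c("a", "b"), alternates = "")
  am <- normalize_relative(vals, si, vi, "positive")
  expect_equal(unname(am$values[1, ]), c(25, 75))
  expect_equal(rowSums(am$values), c(s1 = 100, s2 = 100))
  am2 <- normalize_relative(vals * c(17, 0.3), si, vi, "positive")
  expect_equal(am2$values, am$values, tolerance = 1e-12)
  # single-variable sample is 100%
  am3 <- normalize_relative(matrix(3, 1, 1), si[1, , drop = FALSE],
                            vi[1, , drop = FALSE], "positive")
  expect_equal(unname(am3$values[1, 1]), 100)
  vals0 <- vals; vals0[2, ] <- 0
  expect_error(normalize_relative(vals0, si, vi, "positive"), "s2")
})

test_that("class summaries conserve the per-sample total", {
  si <- data.frame(sample_id = c("s1", "s2"), compartment = "milk")
  vi <- data.frame(label = c("PC(32:0)", "PC(34:1)", "TG(52:2)"),
                   lipid_class = c("PC", "PC", "TG"),
                   members = "", alternates = "")
  am <- normalize_relative(matrix(c(3, 2, 95, 1, 4, 95), 2, 3, byrow = TRUE),
                           si, vi, "positive")
  cls <- summarize_classes(am)
  expect_equal(unname(cls$per_sample[1, "PC"]), 5)
  expect_equal(unname(rowSums(cls$per_sample)), c(100, 100))
  bad <- am; bad$var_info$lipid_class[1] <- NA
  expect_error(summarize_classes(bad), "unknown")
})

test_that("full preprocessing keeps non-negativity and 100% row sums", {
  spec <- slim_chain_spec(n_pairs = 12)
  g <- generate_cohort(spec, seed = 3)
  ams <- preprocess_peaks(g$peaks, spec$library)
  for (am in ams) {
    expect_true(all(am$values >= 0))
    expect_equal(rowSums(am$values), rep(100, nrow(am$values)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("presence filtering commutes with positive scaling (normalization)", {
  set.seed(5)
  m <- matrix(rpois(200, 0.5), 20, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  m <- m * runif(200, 0.5, 2)
  keep_raw <- colnames(presence_filter(m, 0.2))
  norm <- 100 * m / pmax(rowSums(m), 1e-12)
  keep_norm <- colnames(presence_filter(norm, 0.2))
  expect_identical(keep_raw, keep_norm)
})

test_that("peak-list TSV round-trips through the documented dialect", {
  spec <- slim_chain_spec(n_pairs = 3)
  g <- generate_cohort(spec, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peaklists(g$peaks, path)
  back <- read_peaklists(path)
  expect_identical(names(back),
                   c("sample_id", "compartment", "mode", "mz", "intensity"))
  expect_equal(nrow(back), nrow(g$peaks))
  expect_equal(back$mz, g$peaks$mz, tolerance = 1e-12)
})
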