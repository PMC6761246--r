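test_that("generation is fully determined by the seed", {
  spec <- slim_chain_spec(n_pairs = 6)
  g1 <- generate_cohort(spec, seed = 5)
  g2 <- generate_cohort(spec, seed = 5)
  expect_identical(g1$peaks, g2$peaks)
  expect_identical(g1$ground_truth$factors, g2$ground_truth$factors)
  g3 <- generate_cohort(spec, seed = 6)
  expect_false(identical(g1$peaks$intensity, g3$peaks$intensity))
})

test_that("spec validation names the offending fields", {
  expect_error(cohort_spec(noise_sigma = -1), "noise_sigma")
  expect_error(cohort_spec(dg_fragment_fraction = 1), "dg_fragment_fraction")
  bad_prof <- default_class_profiles()
  bad_prof$milk$positive[["TG"]] <- 50
  expect_error(cohort_spec(class_profiles = bad_prof), "sums to")
  bad_chain <- default_chain_spec()
  bad_chain[[1]]$r <- 1.2
  expect_error(cohort_spec(chain_spec = bad_chain), "\\|r\\|")
})

test_that("noiseless cohorts recover configured class means exactly", {
  # blanks off: the blank profile follows the cross-compartment mean, so a
  # nonzero blank level shifts per-compartment class means by design
  spec <- slim_chain_spec(n_pairs = 8, r = NULL, noise_sigma = 0,
                          blank_level = 0, n_blanks = 0)
  g <- generate_cohort(spec, seed = 4)
  am <- suppressWarnings(preprocess_peaks(g$peaks, spec$library))$positive
  cls <- summarize_classes(am)
  for (cp in names(spec$class_profiles)) {
    prof <- spec$class_profiles[[cp]]$positive
    got <- cls$summary[cls$summary$compartment == cp, ]
    for (cl in names(prof)) {
      expect_equal(got$mean[got$lipid_class == cl], unname(prof[[cl]]),
                   tolerance = 1e-6)
      expect_equal(got$sd[got$lipid_class == cl], 0, tolerance = 1e-6)
    }
  }
})

test_that("pinned species targets are honoured in expectation", {
  spec <- cohort_spec(n_pairs = 150, n_qc = 0, n_blanks = 2,
                      dg_fragment_fraction = 0, cluster_spec = list(),
                      chain_spec = list())
  g <- generate_cohort(spec, seed = 12)
  am <- preprocess_peaks(g$peaks)$positive
  M <- compartment_matrix(am, "maternal_plasma")
  I <- compartment_matrix(am, "infant_plasma")
  # PC(34:1) is measured jointly with its PE(37:1) isobar, whose generated
  # mean must be added to the configured target
  mu <- g$ground_truth$species_means
  expect_equal(mean(M[, "PC(34:1)"]),
               5.66 + unname(mu$maternal_plasma$positive[["PE(37:1)"]]),
               tolerance = 0.05)
  expect_equal(mean(I[, "PC(34:1)"]),
               3.61 + unname(mu$infant_plasma$positive[["PE(37:1)"]]),
               tolerance = 0.05)
  expect_equal(mean(M[, "CE(18:2)"]), 8.05, tolerance = 0.05)
  expect_equal(mean(I[, "CE(18:2)"]), 5.18, tolerance = 0.05)
  expect_equal(mean(M[, "TG(52:2)"]), 2.74, tolerance = 0.05)
  expect_equal(mean(I[, "TG(52:2)"]), 4.23, tolerance = 0.05)
})

test_that("fragment peaks are linear in the source TG and vanish at zero", {
  lib <- default_lipid_library()
  tg <- data.frame(name = c("TG(52:2)", "TG(48:1)"), intensity = c(100, 40))
  fr <- fragment_tgs(tg, lib, 0.2)
  expect_equal(fr$name, c("DG(36:2)-H2O", "DG(32:1)-H2O"))
  expect_equal(fr$intensity, c(20, 8))
  fr2 <- fragment_tgs(transform(tg, intensity = 2 * intensity), lib, 0.2)
  expect_equal(fr2$intensity, 2 * fr$intensity)
  expect_equal(nrow(fragment_tgs(tg, lib, 0)), 0)
  expect_warning(fragment_tgs(data.frame(name = "TG(20:0)", intensity = 1),
                              lib, 0.2), "no fragment")
})

test_that("the DG water-loss artefact is ~12% of the milk total at defaults", {
  spec <- cohort_spec(n_qc = 0, n_blanks = 2)
  g <- generate_cohort(spec, seed = 20)
  am <- preprocess_peaks(g$peaks)$positive
  K <- compartment_matrix(am, "milk")
  frag_vars <- grep("-H2O$", colnames(K), value = TRUE)
  frac <- mean(rowSums(K[, frag_vars, drop = FALSE]))
  expect_equal(frac, 12.2, tolerance = 0.15)
})

test_that("planted chain correlation is achieved within sampling error", {
  spec <- slim_chain_spec(n_pairs = 400, r = 0.7)
  g <- generate_cohort(spec, seed = 33)
  am <- preprocess_peaks(g$peaks, spec$library)$positive
  I <- compartment_matrix(am, "infant_plasma")
  K <- compartment_matrix(am, "milk")
  r <- cor(I[, "PC(34:1)"], K[, "TG(49:4)"])
  expect_equal(r, 0.7, tolerance = 0.06)
})

test_that("planted feature blocks drive simulate_feature_blocks structure", {
  sim <- simulate_feature_blocks(n_clusters = 3, features_per_cluster = 5,
                                 n_columns = 25, seed = 9)
  expect_equal(dim(sim$matrix), c(15, 25))
  expect_equal(unname(table(sim$truth)), rep(5, 3), ignore_attr = TRUE)
  cc <- cor(t(sim$matrix))
  same <- outer(sim$truth, sim$truth, "==") & upper.tri(cc)
  diff <- !outer(sim$truth, sim$truth, "==") & upper.tri(cc)
  expect_gt(mean(cc[same]), mean(cc[diff]) + 0.4)
})
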