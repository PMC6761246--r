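# End-to-end orchestration: generate/read -> preprocess -> mother-infant
# stats -> correlation chain -> latent structure model -> enrichment.

#' Pipeline run configuration
#'
#' Every analysis parameter surfaces as a named, defaulted field so the
#' canonical run (8 ppm window, 5% presence, alpha 0.05 with sqrt
#' correction, |r| >= 0.5 chain, r_k >= 0.5 tree cut) is the default run.
#'
#' @param peaks_path optional TSV of peak lists; when `NULL` a synthetic
#'   cohort is generated from `spec`.
#' @param spec a [cohort_spec()] used when no input file is given.
#' @param library annotation library; defaults to the spec's library.
#' @param ppm_tol annotation tolerance in ppm.
#' @param min_fraction presence-filter threshold.
#' @param alpha nominal significance level.
#' @param paired paired or Welch mother-infant comparison.
#' @param chain_threshold selection threshold on |r|.
#' @param bhc_alpha,bhc_beta,n_bins latent-structure-model hyperparameters.
#' @param tree_cut posterior merge probability below which tree edges are
#'   severed.
#' @param lsm_max_features cap on the number of features entering the LSM,
#'   chosen by decreasing variance across pairs (the analysed feature set
#'   is a configurable subset of all detected variables).
#' @param outdir output directory (created); `NULL` disables file output.
#' @param seed integer seed for generation.
#' @return object of class `run_config` (a list).
#' @export
pipeline_config <- function(peaks_path = NULL, spec = cohort_spec(),
                            library = NULL, ppm_tol = 8, min_fraction = 0.05,
                            alpha = 0.05, paired = TRUE,
                            chain_threshold = 0.5, bhc_alpha = 1,
                            bhc_beta = 1, n_bins = 3, tree_cut = 0.5,
                            lsm_max_features = 120, outdir = NULL, seed = 1L) {
  if (is.null(library)) library <- spec$library
  cfg <- structure(as.list(environment()), class = "run_config")
  viol <- validate_config(cfg)
  if (length(viol)) stop("invalid config:\n  ", paste(viol, collapse = "\n  "))
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()] or plain list.
#' @return character vector of violations, one per offending field; empty
#'   when valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(config$ppm_tol > 0, "ppm_tol: must be > 0")
  chk(config$min_fraction >= 0 && config$min_fraction < 1,
      "min_fraction: must lie in [0, 1)")
  chk(config$alpha > 0 && config$alpha < 1, "alpha: must lie in (0, 1)")
  chk(config$chain_threshold >= 0 && config$chain_threshold <= 1,
      "chain_threshold: must lie in [0, 1]")
  chk(config$bhc_alpha > 0, "bhc_alpha: must be > 0")
  chk(config$bhc_beta > 0, "bhc_beta: must be > 0")
  chk(config$n_bins >= 2, "n_bins: must be >= 2")
  chk(config$tree_cut >= 0 && config$tree_cut <= 1,
      "tree_cut: must lie in [0, 1]")
  chk(config$lsm_max_features >= 2, "lsm_max_features: must be >= 2")
  if (!is.null(config$peaks_path))
    chk(file.exists(config$peaks_path),
        paste0("peaks_path: file not found: ", config$peaks_path))
  if (is.null(config$peaks_path))
    v <- c(v, validate_cohort_spec(config$spec))
  v
}

#' Run the full triad analysis pipeline
#'
#' Stages: (1) load or generate peak lists; (2) DIMS preprocessing per mode;
#' (3) paired mother-vs-infant comparison with the sqrt-corrected threshold,
#' plus PCA over all three compartments; (4) infant-milk-maternal
#' correlation chain; (5) latent structure model (BHC bi-clustering) of the
#' concatenated feature matrix; (6) marker enrichment (candidate
#' biomarkers, cholesteryl esters, odd-chain TG/SM) over the feature
#' clusters. Writes stage TSVs, Newick trees and a JSON run report when
#' `config$outdir` is set.
#'
#' @param config a [pipeline_config()].
#' @return list with all stage results and the `report` (named counts and
#'   thresholds), invisibly written to `outdir` when requested.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config:\n  ", paste(viol, collapse = "\n  "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  peaks <- stage("input", {
    if (!is.null(config$peaks_path)) read_peaklists(config$peaks_path)
    else {
      g <- generate_cohort(config$spec, seed = config$seed)
      truth <- g$ground_truth
      g$peaks
    }
  })

  ams <- stage("preprocess",
               preprocess_peaks(peaks, config$library,
                                ppm_tol = config$ppm_tol,
                                min_fraction = config$min_fraction))
  pre_log <- attr(ams, "log")

  # per-compartment matrices with variables from both modes side by side
  comp_mats <- stage("assemble", {
    lapply(stats::setNames(.COMPARTMENTS, .COMPARTMENTS), function(cp) {
      mats <- lapply(ams, function(a) compartment_matrix(a, cp))
      pairs <- Reduce(intersect, lapply(mats, rownames))
      do.call(cbind, lapply(mats, function(m) m[pairs, , drop = FALSE]))
    })
  })

  n_variables <- sum(vapply(ams, ncol, numeric(1)))
  stats_res <- stage("stats",
    compare_pairs(comp_mats$maternal_plasma, comp_mats$infant_plasma,
                  paired = config$paired, alpha = config$alpha,
                  n_variables = n_variables))
  pca_res <- stage("pca", {
    lapply(ams, function(a) {
      study <- .study_rows(a)
      p <- pca_scores(a$values[study, , drop = FALSE])
      p$compartment <- a$sample_info$compartment[study]
      p
    })
  })

  chain_res <- stage("chain",
    build_chain(comp_mats$infant_plasma, comp_mats$milk,
                comp_mats$maternal_plasma,
                threshold = config$chain_threshold))

  lsm <- stage("lsm", {
    fm <- triad_feature_matrix(comp_mats$maternal_plasma, comp_mats$milk,
                               comp_mats$infant_plasma)
    if (nrow(fm) > config$lsm_max_features) {
      vv <- apply(fm, 1, stats::var)
      fm <- fm[order(-vv)[seq_len(config$lsm_max_features)], , drop = FALSE]
    }
    bc <- bicluster(fm, alpha = config$bhc_alpha, beta = config$bhc_beta,
                    n_bins = config$n_bins)
    bc$feature_clusters <- cut_tree(bc$feature_tree, cut = config$tree_cut)
    bc$individual_clusters <- cut_tree(bc$individual_tree,
                                       cut = config$tree_cut)
    bc$feature_matrix <- fm
    bc
  })

  enrich <- stage("enrich", {
    lib <- config$library
    odd <- lib$name[lib$odd_chain & lib$lipid_class %in% c("TG", "SM")]
    sets <- list(
      growth_cbm = paste0("infant_plasma:", unlist(cbm_default())),
      maternal_CE = paste0("maternal_plasma:",
                           lib$name[lib$lipid_class == "CE"]),
      odd_chain_tg_sm = as.vector(outer(paste0(.COMPARTMENTS, ":"), odd,
                                        paste0)))
    enrichment_report(lsm$feature_clusters, sets)
  })

  report <- list(
    seed = config$seed,
    library_size = nrow(config$library),
    preprocess = pre_log,
    n_variables = n_variables,
    significance_threshold = attr(stats_res, "threshold"),
    n_significant = sum(stats_res$significant, na.rm = TRUE),
    chain_threshold = config$chain_threshold,
    n_milk_selected = length(chain_res$selected_milk),
    lsm_features = nrow(lsm$feature_matrix),
    n_feature_clusters = length(unique(lsm$feature_clusters)),
    n_individual_clusters = length(unique(lsm$individual_clusters))
  )

  result <- list(peaks = peaks, abundance = ams, compartments = comp_mats,
                 stats = stats_res, pca = pca_res, chain = chain_res,
                 lsm = lsm, enrichment = enrich, report = report,
                 ground_truth = truth, config = config)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(config$outdir, ...)
    for (md in names(ams)) write_abundance(ams[[md]], out(paste0("abundance_", md, ".tsv")))
    write_comparison(stats_res, out("mother_vs_infant.tsv"))
    write_chain(chain_res, out("chain"))
    bhc_newick(lsm$feature_tree, out("feature_tree.nwk"))
    bhc_newick(lsm$individual_tree, out("individual_tree.nwk"))
    write_clusters(lsm$feature_clusters, out("feature_clusters.tsv"))
    write_clusters(lsm$individual_clusters, out("individual_clusters.tsv"))
    write_enrichment(enrich, out("enrichment.tsv"))
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(result)
}
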