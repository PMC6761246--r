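# Seeded synthetic mother-milk-infant cohort generator. Emits the same
# long-format peak-list table the preprocessing stage reads, plus ground
# truth, so that every pipeline stage is testable without raw instrument
# data.

.COMPARTMENTS <- c("maternal_plasma", "milk", "infant_plasma")

#' Default per-compartment lipid-class profiles
#'
#' Mean class fractions (percent of per-mode total signal) for each
#' compartment, chosen to match the printed cohort summaries: milk
#' dominated by TGs (80%) with SM ~4% and PC ~0.25%; infant plasma with
#' roughly twice the maternal TG fraction (30.5% vs 16.9%), CE/cholesterol
#' at about 65% of maternal levels and PCs ~20% lower; and in negative
#' mode PG about twice as abundant in infants (16.4% vs 9.0%). Fractions
#' within each compartment and mode sum to 100.
#'
#' @return nested list `compartment$mode` of named numeric vectors.
#' @export
default_class_profiles <- function() {
  list(
    maternal_plasma = list(
      positive = c(TG = 16.9, PC = 37, `PC-O` = 2, SM = 10, CE = 20,
                   Chol = 10, DG = 1.5, PE = 1.5, Cer = 0.6, MG = 0.5),
      negative = c(PS = 40, PI = 13, PG = 9, FA = 38)),
    milk = list(
      positive = c(TG = 80, DG = 3.05, SM = 4, PC = 0.25, `PC-O` = 0.25,
                   PE = 0.75, Cer = 0.7, Chol = 6, MG = 4, CE = 1),
      negative = c(PS = 50, PI = 17, PG = 23, FA = 10)),
    infant_plasma = list(
      positive = c(TG = 30.5, PC = 30, `PC-O` = 1.8, SM = 10.6, CE = 13,
                   Chol = 6.5, DG = 3.5, PE = 1.5, Cer = 0.6, MG = 2),
      negative = c(PS = 36, PI = 11.7, PG = 16.37, FA = 35.93))
  )
}

#' Default single-species abundance targets
#'
#' Species whose cohort means are pinned rather than drawn from the
#' within-class weight prior: PC(34:1) 5.66% in mothers vs 3.61% in
#' infants, CE(18:2) 8.05% vs 5.18%, TG(52:2) 2.74% vs 4.23%.
#'
#' @return list per compartment of named numeric vectors (percent of mode
#'   total).
#' @export
default_species_targets <- function() {
  list(maternal_plasma = c("PC(34:1)" = 5.66, "CE(18:2)" = 8.05,
                           "TG(52:2)" = 2.74),
       infant_plasma = c("PC(34:1)" = 3.61, "CE(18:2)" = 5.18,
                         "TG(52:2)" = 4.23))
}

#' Default planted correlation chain
#'
#' Three infant candidate biomarkers tied to odd-chain milk TG/SM species
#' and onward to maternal cholesteryl esters, each link with target
#' Pearson r = 0.7.
#' @return list of chain entries (`cbm`, `milk`, `maternal`, `r`).
#' @export
default_chain_spec <- function() {
  list(list(cbm = "PC(34:1)", milk = "TG(49:4)", maternal = "CE(18:2)", r = 0.7),
       list(cbm = "PC-O(34:1)", milk = "SM(45:0)", maternal = "CE(18:1)", r = 0.7),
       list(cbm = "PC(38:4)", milk = "TG(55:3)", maternal = "CE(20:4)", r = 0.7))
}

#' Default planted feature-cluster blocks
#'
#' One co-regulated block: the eleven maternal-plasma cholesteryl esters
#' sharing a latent factor with Gaussian-scale loading 0.8.
#' @return list of blocks (`name`, `compartment`, `features`, `loading`).
#' @export
default_cluster_spec <- function() {
  lib <- default_lipid_library()
  ce <- lib$name[lib$lipid_class == "CE"]
  list(list(name = "maternal_CE", compartment = "maternal_plasma",
            features = ce, loading = 0.8))
}

#' Cohort generator specification
#'
#' Bundles every knob of the synthetic triad generator. The defaults are the
#' cohort conditions the analysis assumes: 30 pairs, log-normal
#' multiplicative noise with sigma 0.25 on the log scale, blanks at 1% of
#' mean signal, TG water-loss fragments at 17.4% of each TG's intensity
#' (which puts the artefact DG signal at ~12.2% of the milk total), m/z
#' jitter uniform within +/-4 ppm so every true peak survives the 8 ppm
#' annotation window while exercising it.
#'
#' @param n_pairs number of mother-infant pairs (default 30).
#' @param library a [lipid_library()].
#' @param class_profiles see [default_class_profiles()].
#' @param species_targets see [default_species_targets()].
#' @param noise_sigma log-scale SD of multiplicative noise (>= 0).
#' @param chain_spec planted chain entries; `list()` for none.
#' @param cluster_spec planted feature blocks; `list()` for none.
#' @param blank_level blank intensity as a fraction of mean signal.
#' @param dg_fragment_fraction fraction of each TG intensity duplicated as
#'   its DG-H2O artefact peak, in `[0, 1)`.
#' @param ppm_jitter half-width of the uniform m/z jitter in ppm.
#' @param n_blanks,n_qc numbers of blank and QC samples.
#' @param seed integer seed; `generate_cohort()` uses it when no explicit
#'   seed is passed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 30,
                        library = default_lipid_library(),
                        class_profiles = default_class_profiles(),
                        species_targets = default_species_targets(),
                        noise_sigma = 0.25,
                        chain_spec = default_chain_spec(),
                        cluster_spec = default_cluster_spec(),
                        blank_level = 0.01,
                        dg_fragment_fraction = 0.174,
                        ppm_jitter = 4,
                        n_blanks = 4,
                        n_qc = 2,
                        seed = 1L) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  viol <- validate_cohort_spec(spec)
  if (length(viol)) stop("invalid cohort spec:\n  ", paste(viol, collapse = "\n  "))
  spec
}

#' Validate a cohort spec
#'
#' @param spec a [cohort_spec()] (or plain list with the same fields).
#' @return character vector of violations; empty when valid.
#' @export
validate_cohort_spec <- function(spec) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(spec$n_pairs) && spec$n_pairs >= 1, "n_pairs: must be >= 1")
  chk(inherits(spec$library, "lipid_library"), "library: not a lipid_library")
  chk(spec$noise_sigma >= 0, "noise_sigma: must be >= 0")
  chk(spec$blank_level >= 0, "blank_level: must be >= 0")
  chk(spec$dg_fragment_fraction >= 0 && spec$dg_fragment_fraction < 1,
      "dg_fragment_fraction: must lie in [0, 1)")
  chk(spec$ppm_jitter >= 0, "ppm_jitter: must be >= 0")
  for (cp in names(spec$class_profiles)) {
    chk(cp %in% .COMPARTMENTS, paste0("class_profiles: unknown compartment ", cp))
    for (md in names(spec$class_profiles[[cp]])) {
      s <- sum(spec$class_profiles[[cp]][[md]])
      chk(abs(s - 100) < 1e-6,
          sprintf("class_profiles[%s][%s]: sums to %.4f, not 100", cp, md, s))
    }
  }
  for (ch in spec$chain_spec)
    chk(abs(ch$r) < 1, sprintf("chain_spec: |r| must be < 1 (%s)", ch$milk))
  for (bl in spec$cluster_spec)
    chk(bl$loading >= 0 && bl$loading <= 1,
        sprintf("cluster_spec: loading must lie in [0, 1] (%s)", bl$name))
  v
}

# Gaussian-scale correlation needed so two log-normal variables with common
# log-sd sigma achieve Pearson r on the natural scale.
.gauss_rho <- function(r, sigma) {
  if (sigma == 0) return(r)
  log1p(r * expm1(sigma^2)) / sigma^2
}

# Per-compartment per-mode species means (percent, summing to 100) with
# Dirichlet within-class weights and pinned species targets. Artefact-only
# (-H2O) species get no native abundance. Species carrying a planted chain
# or cluster loading are guaranteed at least an equal share of their class
# (a planted biomarker must be measurable above the blank level).
.draw_species_means <- function(spec) {
  lib <- spec$library
  anchored <- unique(c(
    unlist(lapply(spec$chain_spec, function(ch) c(ch$cbm, ch$milk, ch$maternal))),
    unlist(lapply(spec$cluster_spec, `[[`, "features"))))
  mu <- list()
  for (cp in .COMPARTMENTS) {
    mu[[cp]] <- list()
    for (md in names(spec$class_profiles[[cp]])) {
      prof <- spec$class_profiles[[cp]][[md]]
      sub <- lib[lib$mode == md & lib$lipid_class %in% names(prof), , drop = FALSE]
      native <- !grepl("-H2O$", sub$name)
      m <- stats::setNames(numeric(nrow(sub)), sub$name)
      targets <- spec$species_targets[[cp]]
      for (cl in names(prof)) {
        members <- which(sub$lipid_class == cl & native)
        if (!length(members)) next
        nm <- sub$name[members]
        w <- stats::rgamma(length(members), shape = 1)   # Dirichlet(1)
        w <- w / sum(w)
        names(w) <- nm
        floor_nm <- setdiff(intersect(anchored, nm), names(targets))
        w[floor_nm] <- pmax(w[floor_nm], 1 / length(nm))
        w <- w / sum(w)
        tgt <- targets[names(targets) %in% nm]
        share <- stats::setNames(rep(0, length(nm)), nm)
        if (length(tgt)) {
          share[names(tgt)] <- tgt / prof[[cl]]
          rest <- setdiff(nm, names(tgt))
          if (length(rest)) {
            wr <- w[rest]
            share[rest] <- (1 - sum(share)) * wr / sum(wr)
          }
        } else share[] <- w
        m[nm] <- prof[[cl]] * share
      }
      mu[[cp]][[md]] <- m
    }
  }
  mu
}

# factor loadings per compartment/mode: species x factors matrices
.build_loadings <- function(spec, mu) {
  factors <- character(0)
  for (i in seq_along(spec$chain_spec)) factors <- c(factors, paste0("chain", i))
  for (bl in spec$cluster_spec) factors <- c(factors, bl$name)
  lam <- list()
  for (cp in .COMPARTMENTS) {
    lam[[cp]] <- list()
    for (md in names(mu[[cp]])) {
      L <- matrix(0, length(mu[[cp]][[md]]), length(factors),
                  dimnames = list(names(mu[[cp]][[md]]), factors))
      lam[[cp]][[md]] <- L
    }
  }
  put <- function(cp, species, fac, value) {
    for (md in names(lam[[cp]])) {
      hit <- intersect(species, rownames(lam[[cp]][[md]]))
      if (length(hit)) lam[[cp]][[md]][hit, fac] <<- value
    }
  }
  # closure correction: dividing a species by its sample total attenuates
  # its correlation with outside variables by a = (1-w)/sqrt((1-w)^2 + s),
  # w the species' mean share and s the summed squared shares of the other
  # species; the factor is per-variable, so each loading absorbs 1/a
  closure_gain <- function(cp, species) {
    for (md in names(mu[[cp]])) {
      w_all <- mu[[cp]][[md]] / 100
      if (species %in% names(w_all)) {
        w <- w_all[[species]]
        s <- sum(w_all^2) - w^2
        return(sqrt((1 - w)^2 + s) / (1 - w))
      }
    }
    1
  }
  for (i in seq_along(spec$chain_spec)) {
    ch <- spec$chain_spec[[i]]
    l <- sqrt(.gauss_rho(abs(ch$r), spec$noise_sigma))
    fac <- paste0("chain", i)
    put("infant_plasma", ch$cbm, fac,
        min(0.999, l * closure_gain("infant_plasma", ch$cbm)))
    put("milk", ch$milk, fac,
        sign(ch$r) * min(0.999, l * closure_gain("milk", ch$milk)))
    put("maternal_plasma", ch$maternal, fac,
        min(0.999, l * closure_gain("maternal_plasma", ch$maternal)))
  }
  for (bl in spec$cluster_spec)
    put(bl$compartment, bl$features, bl$name, bl$loading)
  # keep the per-species loading budget below 1, chain loadings taking
  # priority over block loadings
  for (cp in .COMPARTMENTS) for (md in names(lam[[cp]])) {
    L <- lam[[cp]][[md]]
    tot <- rowSums(L^2)
    over <- which(tot > 0.999)
    for (s in over) {
      chain_cols <- grep("^chain", colnames(L))
      chain_part <- sum(L[s, chain_cols]^2)
      block_cols <- setdiff(seq_len(ncol(L)), chain_cols)
      block_part <- sum(L[s, block_cols]^2)
      if (block_part > 0) {
        scale <- sqrt(max(0, 0.999 - chain_part) / block_part)
        L[s, block_cols] <- L[s, block_cols] * scale
      }
    }
    lam[[cp]][[md]] <- L
  }
  lam
}

#' Generate a synthetic mother-milk-infant cohort
#'
#' For each pair and compartment, species abundances are
#' `class mean x within-class weight x exp(sigma z - sigma^2/2)` where `z`
#' combines shared standard-normal latent factors (planting the requested
#' chain correlations and cluster blocks) with independent noise; samples
#' are renormalized, converted to intensities at the species' library m/z
#' with uniform ppm jitter, TGs spawn DG-H2O fragment peaks, and blank/QC
#' samples are appended. Fully determined by the seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer; defaults to `spec$seed`.
#' @return list with `peaks` (long-format data frame
#'   `sample_id compartment mode mz intensity`) and `ground_truth` (species
#'   means, latent factors, loadings, chain and cluster specs).
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  viol <- validate_cohort_spec(spec)
  if (length(viol)) stop("invalid cohort spec:\n  ", paste(viol, collapse = "\n  "))
  set.seed(if (is.null(seed)) spec$seed else seed)
  lib <- spec$library
  n <- spec$n_pairs
  pair_ids <- sprintf("P%02d", seq_len(n))
  sample_of <- c(maternal_plasma = "M", milk = "K", infant_plasma = "I")

  mu <- .draw_species_means(spec)
  lam <- .build_loadings(spec, mu)
  n_factors <- ncol(lam[[1]][[1]])
  U <- matrix(stats::rnorm(n * n_factors), n, n_factors,
              dimnames = list(pair_ids, colnames(lam[[1]][[1]])))

  frag_of <- stats::setNames(tg_fragment_name(lib$name), lib$name)
  warned_missing <- FALSE
  peaks <- list()
  study_intensity <- list() # per mode: named running sums for blanks/QCs

  for (cp in .COMPARTMENTS) {
    for (md in names(mu[[cp]])) {
      m <- mu[[cp]][[md]]
      keep <- m > 0
      m <- m[keep]
      L <- lam[[cp]][[md]][keep, , drop = FALSE]
      resid <- sqrt(pmax(0, 1 - rowSums(L^2)))
      eps <- matrix(stats::rnorm(n * length(m)), n, length(m))
      z <- U %*% t(L) + sweep(eps, 2, resid, "*")
      s <- spec$noise_sigma
      vals <- sweep(exp(s * z - s^2 / 2), 2, m, "*")
      vals <- 100 * vals / rowSums(vals)          # renormalized percent
      totals <- 1e6 * exp(0.2 * stats::rnorm(n))  # arbitrary per-sample scale
      inten <- vals * totals / 100                # pairs x species
      colnames(inten) <- names(m)

      # TG water-loss artefact peaks, added on top of the normalized signal
      if (md == "positive" && spec$dg_fragment_fraction > 0) {
        tg <- colnames(inten)[grepl("^TG\\(", colnames(inten))]
        frag <- frag_of[tg]
        known <- !is.na(frag) & frag %in% lib$name[lib$mode == "positive"]
        if (any(!known) && !warned_missing) {
          warning("fragment species missing from library for: ",
                  paste(tg[!known], collapse = ", "))
          warned_missing <- TRUE
        }
        if (any(known)) {
          fi <- spec$dg_fragment_fraction * inten[, tg[known], drop = FALSE]
          colnames(fi) <- unname(frag[known])
          # several TGs can share one fragment species; sum them
          fi <- t(rowsum(t(fi), group = colnames(fi)))
          inten <- cbind(inten, fi)
        }
      }

      mzs <- lib$theoretical_mz[match(colnames(inten), lib$name)]
      jit <- matrix(stats::runif(length(inten), -spec$ppm_jitter,
                                 spec$ppm_jitter) * 1e-6,
                    nrow(inten), ncol(inten))
      obs_mz <- sweep(jit, 2, mzs, function(j, t) t * (1 + j))
      idx <- which(inten > 0, arr.ind = TRUE)
      peaks[[paste(cp, md)]] <- data.frame(
        sample_id = paste0(sample_of[[cp]], sub("^P", "", pair_ids[idx[, 1]])),
        compartment = cp, mode = md,
        mz = obs_mz[idx], intensity = inten[idx],
        stringsAsFactors = FALSE)
      cm <- colMeans(inten)
      prev <- study_intensity[[md]]
      study_intensity[[md]] <- if (is.null(prev)) list(cm) else c(prev, list(cm))
    }
  }

  # blanks and QCs: species intensity proportional to the study mean
  aux <- list()
  for (md in names(study_intensity)) {
    sums <- Reduce(function(a, b) {
      all_nm <- union(names(a), names(b))
      av <- stats::setNames(numeric(length(all_nm)), all_nm)
      av[names(a)] <- a
      av[names(b)] <- av[names(b)] + b
      av
    }, study_intensity[[md]])
    mean_int <- sums / length(.COMPARTMENTS)
    mzs <- lib$theoretical_mz[match(names(mean_int), lib$name)]
    emit <- function(ids, compartment, level) {
      out <- list()
      for (id in ids) {
        s <- spec$noise_sigma
        noise <- exp(s * stats::rnorm(length(mean_int)) - s^2 / 2)
        inten <- level * mean_int * noise
        jit <- stats::runif(length(inten), -spec$ppm_jitter, spec$ppm_jitter) * 1e-6
        keep <- inten > 0
        out[[id]] <- data.frame(sample_id = id, compartment = compartment,
                                mode = md, mz = (mzs * (1 + jit))[keep],
                                intensity = inten[keep],
                                stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }
    if (spec$n_blanks > 0)
      aux[[paste("blank", md)]] <-
        emit(sprintf("B%d", seq_len(spec$n_blanks)), "blank", spec$blank_level)
    if (spec$n_qc > 0)
      aux[[paste("qc", md)]] <-
        emit(sprintf("Q%d", seq_len(spec$n_qc)), "qc", 1)
  }

  all_peaks <- do.call(rbind, c(peaks, aux))
  rownames(all_peaks) <- NULL
  list(peaks = all_peaks,
       ground_truth = list(species_means = mu, loadings = lam, factors = U,
                           chain_spec = spec$chain_spec,
                           cluster_spec = spec$cluster_spec,
                           class_profiles = spec$class_profiles,
                           species_targets = spec$species_targets))
}

#' Spawn DG-H2O artefact peaks from TG peaks
#'
#' For each TG peak, emits a peak at the library m/z of the corresponding
#' water-loss diglyceride (`DG(c-16:d)-H2O`) with
#' `intensity = fraction x TG intensity`. TGs whose fragment species is
#' absent from the library are skipped with a warning.
#'
#' @param tg_peaks data frame with columns `name` (TG shorthand) and
#'   `intensity`; other columns are carried through.
#' @param library a [lipid_library()].
#' @param fraction fragment intensity fraction in `[0, 1)`.
#' @return data frame of artefact peaks (`name`, `mz`, `intensity` plus
#'   carried columns); zero rows when `fraction = 0`.
#' @export
fragment_tgs <- function(tg_peaks, library, fraction) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  tg_peaks <- as.data.frame(tg_peaks)
  if (fraction == 0 || nrow(tg_peaks) == 0) {
    out <- tg_peaks[integer(0), , drop = FALSE]
    return(out)
  }
  frag <- tg_fragment_name(tg_peaks$name)
  pos <- library[library$mode == "positive", ]
  hit <- !is.na(frag) & frag %in% pos$name
  if (any(!hit))
    warning("no fragment species in library for: ",
            paste(unique(tg_peaks$name[!hit]), collapse = ", "))
  out <- tg_peaks[hit, , drop = FALSE]
  out$name <- frag[hit]
  out$mz <- pos$theoretical_mz[match(out$name, pos$name)]
  out$intensity <- fraction * tg_peaks$intensity[hit]
  rownames(out) <- NULL
  out
}

#' Simulate a feature matrix with planted clusters
#'
#' Continuous features x columns matrix in which features of the same
#' cluster share a cluster-specific column pattern: feature f in cluster k
#' has `x[f, c] = pattern[k, c] + noise`, with patterns drawn N(0, signal_sd)
#' and noise N(0, noise_sd). Used to exercise cluster recovery.
#'
#' @param n_clusters,features_per_cluster,n_columns problem size (defaults
#'   4, 10, 30).
#' @param signal_sd,noise_sd pattern and noise SDs (defaults 1 and 0.5).
#' @param seed optional integer seed.
#' @return list with `matrix` (features x columns) and `truth` (integer
#'   cluster assignment).
#' @export
simulate_feature_blocks <- function(n_clusters = 4, features_per_cluster = 10,
                                    n_columns = 30, signal_sd = 1,
                                    noise_sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- rep(seq_len(n_clusters), each = features_per_cluster)
  pattern <- matrix(stats::rnorm(n_clusters * n_columns, sd = signal_sd),
                    n_clusters, n_columns)
  x <- pattern[truth, , drop = FALSE] +
    matrix(stats::rnorm(length(truth) * n_columns, sd = noise_sd),
           length(truth), n_columns)
  rownames(x) <- sprintf("f%02d_c%d", seq_along(truth), truth)
  colnames(x) <- sprintf("s%02d", seq_len(n_columns))
  list(matrix = x, truth = stats::setNames(truth, rownames(x)))
}
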