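# End-to-end orchestration: simulate -> preprocess -> feature extraction ->
# classification, with reproducible seeds.

#' Canonical feature pools
#'
#' @param config A `maflim_config` (defines the phasor frequency labels).
#' @param n_harmonics Number of phasor harmonics.
#' @return Named list: `intensity` (6), `biexp` (12), `phasor` (36) feature
#'   names.
#' @export
feature_pools <- function(config = acquisition_config(), n_harmonics = 9) {
  list(intensity = intensity_feature_names(),
       biexp = biexp_feature_names(),
       phasor = phasor_feature_names(config, n_harmonics))
}

#' Extract the global feature vector for one lesion image
#'
#' Runs preprocessing and the requested feature extractors on one raw image.
#'
#' @param image A `maflim_image`.
#' @param irf The acquisition `maflim_irf`.
#' @param pools Subset of `c("intensity", "biexp", "phasor")`.
#' @param preprocess_args List of arguments passed to [preprocess_image()].
#' @param n_harmonics Phasor harmonics (default 9).
#' @return Named numeric vector of global features.
#' @export
extract_lesion_features <- function(image, irf,
                                    pools = c("intensity", "biexp", "phasor"),
                                    preprocess_args = list(),
                                    n_harmonics = 9) {
  pools <- match.arg(pools, several.ok = TRUE)
  pre <- do.call(preprocess_image, c(list(image), preprocess_args))
  feats <- numeric(0)
  if (any(pools %in% c("intensity", "biexp"))) {
    td <- extract_td_pools(pre, irf)
    if ("intensity" %in% pools)
      feats <- c(feats, td$features[intensity_feature_names()])
    if ("biexp" %in% pools)
      feats <- c(feats, td$features[biexp_feature_names()])
  }
  if ("phasor" %in% pools)
    feats <- c(feats, extract_phasor_pool(pre, irf, n_harmonics)$features)
  feats
}

#' Extract the feature table for a synthetic cohort
#'
#' @param cohort A `maflim_cohort` from [generate_cohort()].
#' @param pools Feature pools to extract.
#' @param preprocess_args Arguments passed to [preprocess_image()].
#' @param n_harmonics Phasor harmonics.
#' @param verbose Print progress.
#' @return Data frame: `lesion_id`, `patient_id`, `label`, one column per
#'   feature.
#' @export
extract_cohort_features <- function(cohort,
                                    pools = c("intensity", "biexp", "phasor"),
                                    preprocess_args = list(),
                                    n_harmonics = 9, verbose = FALSE) {
  stopifnot(inherits(cohort, "maflim_cohort"))
  rows <- lapply(seq_along(cohort$lesions), function(i) {
    les <- cohort$lesions[[i]]
    if (verbose)
      message(sprintf("  [%d/%d] %s", i, length(cohort$lesions), les$lesion_id))
    f <- extract_lesion_features(les$image, cohort$irf, pools,
                                 preprocess_args, n_harmonics)
    cbind(data.frame(lesion_id = les$lesion_id, patient_id = les$patient_id,
                     label = les$label), as.data.frame(t(f)))
  })
  do.call(rbind, rows)
}

# short deterministic tag of a configuration list, embedded in outputs
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 257)) %% .Machine$integer.max)
}

#' Run a full synthetic maFLIM classification study
#'
#' Generates a patient-grouped synthetic cohort, extracts the requested
#' feature pools, sweeps the SFS feature count per pool inside LOPO-CV,
#' derives each pool's important features by selection frequency, and
#' evaluates weighted-posterior ensembles of the requested pool
#' combinations.  Fully reproducible given the seeds in the specs.
#'
#' @param cohort A `cohort_spec`.
#' @param scene A `scene_spec` template.
#' @param config A `maflim_config`.
#' @param irf Optional `maflim_irf` (generated from `config` if `NULL`).
#' @param pools Feature pools to use.
#' @param ensembles List of character vectors of pool names to combine
#'   (e.g. `list(c("phasor", "biexp"))`); `NULL` for no ensembles.
#' @param n_range SFS sweep range (default 1..min(pool, floor(sqrt(n)))).
#' @param verbose Print progress.
#' @return List: `features` (data frame), `pool_results` (per pool: sweep
#'   table, best `cv_result`, selection frequencies, `fselected`),
#'   `ensemble_results`, `summary` (metrics table shaped like the per-pool /
#'   ensemble performance tables), `seed` and `hash`.
#' @export
run_maflim_study <- function(cohort = cohort_spec(), scene = scene_spec(),
                             config = acquisition_config(), irf = NULL,
                             pools = c("intensity", "biexp", "phasor"),
                             ensembles = list(c("phasor", "biexp")),
                             n_range = NULL, verbose = FALSE) {
  if (is.null(irf)) irf <- generate_irf(config)
  if (verbose) message("generating cohort ...")
  dat <- generate_cohort(cohort, scene, config, irf)
  if (verbose) message("extracting features ...")
  feats <- extract_cohort_features(dat, pools, verbose = verbose)
  pool_defs <- feature_pools(config)[pools]
  pool_results <- list()
  summary_rows <- list()
  for (pn in pools) {
    if (verbose) message("classifying pool ", pn, " ...")
    sw <- sweep_n_sfs(feats, pool_defs[[pn]], n_range = n_range)
    sel <- selection_frequency(sw$cv)
    pool_results[[pn]] <- list(sweep = sw$table, n_selected = sw$n_selected,
                               cv = sw$cv, selection = sel$table,
                               fselected = sel$fselected)
    summary_rows[[pn]] <- data.frame(model = pn, n_features = sw$n_selected,
                                     t(sw$cv$metrics))
  }
  ensemble_results <- list()
  for (comb in ensembles) {
    key <- paste(comb, collapse = "+")
    if (verbose) message("ensemble ", key, " ...")
    fsets <- lapply(pool_results[comb], `[[`, "fselected")
    names(fsets) <- comb
    if (any(vapply(fsets, length, 1L) == 0)) {
      warning("ensemble ", key, " skipped: a pool has no selected features")
      next
    }
    cv <- ensemble_lopo(feats, fsets)
    ensemble_results[[key]] <- cv
    summary_rows[[key]] <- data.frame(model = paste0("ensemble:", key),
                                      n_features = length(unlist(fsets)),
                                      t(cv$metrics))
  }
  list(features = feats, pool_results = pool_results,
       ensemble_results = ensemble_results,
       summary = do.call(rbind, summary_rows),
       seed = cohort$seed,
       hash = config_hash(list(cohort, scene, config)))
}
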