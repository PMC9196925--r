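# Shared fixtures for the test suite.  Expensive objects are memoised so
# several test files can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

small_config <- function(rows = 16, cols = 16) {
  acquisition_config(rows = rows, cols = cols)
}

small_irf <- function(cfg = small_config()) generate_irf(cfg)

# manual region masks: left/right half split of the full (all-valid) grid
half_masks <- function(rows, cols) {
  valid <- matrix(TRUE, rows, cols)
  r1 <- matrix(FALSE, rows, cols)
  r1[, seq_len(floor(cols / 2))] <- TRUE
  structure(list(valid = valid, region1 = r1, region2 = valid & !r1),
            class = "region_masks")
}

# assemble a preprocessed object with externally supplied masks (bypassing
# clustering, e.g. for degenerate identical-region scenes)
preprocess_with_masks <- function(image, masks, n_edge = 5, avg_order = 5) {
  pre <- list(config = image$config, M = max(image$config$n_samples))
  pre$channels <- lapply(image$channels, function(arr) {
    d <- dim(arr)
    sub <- subtract_offset(matrix(aperm(arr, c(3, 1, 2)), d[3], d[1] * d[2]),
                           n_edge)
    avg <- spatial_average(aperm(array(sub, c(d[3], d[1], d[2])), c(2, 3, 1)),
                           avg_order)
    matrix(aperm(avg, c(3, 1, 2)), d[3], d[1] * d[2])
  })
  pre$concat <- pad_and_concatenate(pre$channels)
  pre$masks <- masks
  pre$truth <- image$truth
  structure(pre, class = "maflim_preprocessed")
}

# synthetic lesion record table for classification tests: `n_informative`
# features shifted by `effect` for malignant lesions, the rest pure noise
make_records <- function(n_patients = 10, lesions_per_patient = 2,
                         n_features = 5, n_informative = 1, effect = 3,
                         frac_malignant = 0.4, seed = 1) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    n <- n_patients * lesions_per_patient
    pid <- rep(sprintf("P%02d", seq_len(n_patients)), each = lesions_per_patient)
    lab <- rep(c("malignant", "benign"),
               c(round(frac_malignant * n_patients), n_patients -
                   round(frac_malignant * n_patients)))
    lab <- rep(lab, each = lesions_per_patient)
    X <- matrix(rnorm(n * n_features), n, n_features)
    for (j in seq_len(n_informative))
      X[lab == "malignant", j] <- X[lab == "malignant", j] + effect
    colnames(X) <- sprintf("f%d", seq_len(n_features))
    cbind(data.frame(lesion_id = sprintf("L%03d", seq_len(n)),
                     patient_id = pid, label = lab),
          as.data.frame(X))
  })
}

# recovery-arm cohort features (shared by acceptance + invariant tests)
recovery_features <- function() {
  cached("recovery_features", {
    cfg <- acquisition_config(rows = 32, cols = 32)
    irf <- generate_irf(cfg)
    strong <- list(d_alpha_fast = c(0.10, 0.25, 0.10),
                   d_tau_fast = c(0.00, -0.35, 0.00),
                   d_tau_slow = c(0.80, 0.50, 0.30))
    co <- cohort_spec(effect = strong,
                      inter_patient_sd = list(alpha = 0.01, tau = 0.05,
                                              intensity_frac = 0.03),
                      seed = 101)
    sc <- scene_spec(noise = list(type = "gaussian", snr_db = 35))
    dat <- generate_cohort(co, sc, cfg, irf)
    extract_cohort_features(dat, pools = "biexp")
  })
}
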