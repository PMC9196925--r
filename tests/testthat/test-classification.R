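test_that("QDA posteriors match a brute-force evaluation of the Gaussian class densities", {
  rec <- make_records(n_patients = 12, n_features = 3, effect = 2, seed = 2)
  feats <- c("f1", "f2", "f3")
  m <- train_qda(rec, feats)
  X <- as.matrix(rec[, feats])
  dens <- function(x, p) {
    k <- length(p$mean)
    exp(-0.5 * t(x - p$mean) %*% solve(p$cov) %*% (x - p$mean)) /
      sqrt((2 * pi)^k * det(p$cov))
  }
  brute <- apply(X, 1, function(x) {
    db <- dens(x, m$par$benign) * m$priors["benign"]
    dm <- dens(x, m$par$malignant) * m$priors["malignant"]
    dm / (db + dm)
  })
  expect_equal(posterior_malignant(m, rec), unname(brute), tolerance = 1e-10)
  expect_true(all(posterior_malignant(m, rec) >= 0 &
                    posterior_malignant(m, rec) <= 1))
})

test_that("QDA agrees with the reference discriminant implementation on a well-conditioned fixture", {
  skip_if_not_installed("MASS")
  rec <- make_records(n_patients = 30, n_features = 2, effect = 1.5, seed = 5)
  m <- train_qda(rec, c("f1", "f2"))
  ref <- MASS::qda(rec[, c("f1", "f2")], grouping = factor(rec$label))
  post_ref <- predict(ref, rec[, c("f1", "f2")])$posterior[, "malignant"]
  expect_equal(posterior_malignant(m, rec), unname(post_ref),
               tolerance = 1e-4)
})

test_that("well-separated classes are perfectly classified and symmetric points sit at 0.5", {
  rec <- make_records(n_patients = 20, n_features = 2, effect = 10, seed = 3)
  m <- train_qda(rec, c("f1", "f2"))
  post <- posterior_malignant(m, rec)
  expect_true(all((post >= 0.5) == (rec$label == "malignant")))
  expect_gt(posterior_malignant(
    m, data.frame(f1 = m$par$malignant$mean[1],
                  f2 = m$par$malignant$mean[2])), 0.99)
  # symmetric construction: equal priors, equal covariances, equidistant x
  sym <- data.frame(
    lesion_id = sprintf("L%d", 1:8), patient_id = sprintf("P%d", 1:8),
    label = rep(c("benign", "malignant"), each = 4),
    f1 = c(-1.2, -0.8, -1.1, -0.9, 1.2, 0.8, 1.1, 0.9),
    f2 = c(0.1, -0.1, 0.05, -0.05, 0.1, -0.1, 0.05, -0.05))
  ms <- train_qda(sym, c("f1", "f2"))
  expect_equal(posterior_malignant(ms, data.frame(f1 = 0, f2 = 0)), 0.5,
               tolerance = 1e-9)
})

test_that("ROC AUC equals the brute-force pairwise comparison count, with tie handling", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(c(10, 11, 1, 2, 3), c(FALSE, FALSE, TRUE, TRUE, TRUE)), 0)
  s <- c(0.2, 0.5, 0.5, 0.7, 0.3, 0.5)
  lab <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  brute <- 0
  for (i in which(lab)) for (j in which(!lab))
    brute <- brute + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  expect_equal(roc_auc(s, lab), brute / (sum(lab) * sum(!lab)))
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  skip_if_not_installed("pROC")
  set.seed(7)
  s2 <- rnorm(40)
  lab2 <- rep(c(TRUE, FALSE), 20)
  ref <- suppressMessages(as.numeric(pROC::auc(lab2, s2)))
  expect_equal(roc_auc(s2, lab2), ref, tolerance = 1e-12)
})

test_that("greedy forward selection matches exhaustive stepwise search", {
  rec <- make_records(n_patients = 14, n_features = 5, n_informative = 2,
                      effect = 2.5, seed = 9)
  pool <- sprintf("f%d", 1:5)
  # first selected feature = argmax of all single-feature AUCs
  aucs <- vapply(pool, function(f) {
    m <- train_qda(rec, f)
    roc_auc(posterior_malignant(m, rec), rec$label)
  }, 1)
  sel1 <- sfs_select(rec, pool, 1)
  expect_equal(sel1, names(which.max(aucs)))
  # every later step = exhaustive one-feature-addition search
  sel3 <- sfs_select(rec, pool, 3)
  for (k in 2:3) {
    prev <- sel3[seq_len(k - 1)]
    aucs_k <- vapply(setdiff(pool, prev), function(f) {
      m <- train_qda(rec, c(prev, f))
      roc_auc(posterior_malignant(m, rec), rec$label)
    }, 1)
    expect_equal(sel3[k], names(which.max(aucs_k)))
  }
  # full pool request returns the whole pool
  expect_setequal(sfs_select(rec, pool, 5), pool)
  # a perfectly separating feature is found immediately with AUC 1
  rec$gold <- ifelse(rec$label == "malignant", 1, 0) + rnorm(nrow(rec), 0, 0.01)
  expect_equal(sfs_select(rec, c(pool, "gold"), 1), "gold")
})

test_that("LOPO-CV partitions patients without leakage and errors on single-class folds", {
  rec <- make_records(n_patients = 10, lesions_per_patient = 3,
                      n_features = 4, effect = 2, seed = 4)
  cv <- lopo_cv(rec, sprintf("f%d", 1:4), n_sfs = 2)
  expect_length(cv$folds, 10)
  expect_equal(sum(cv$confusion), nrow(rec))
  for (fold in cv$folds) {
    test_pat <- unique(rec$patient_id[rec$lesion_id %in% fold$lesion_id])
    expect_equal(test_pat, fold$patient)
  }
  expect_setequal(unlist(lapply(cv$folds, `[[`, "lesion_id")), rec$lesion_id)
  # two patients, one entirely malignant: leaving the benign one out fails
  bad <- make_records(n_patients = 2, lesions_per_patient = 2, seed = 1,
                      frac_malignant = 0.5)
  expect_error(lopo_cv(bad, sprintf("f%d", 1:5), n_sfs = 1), "single-class")
})

test_that("the feature-count chooser applies the F-score / sensitivity / parsimony tie rules", {
  tab <- data.frame(n = 1:3, f_score = c(70, 80, 80),
                    sensitivity = c(60, 75, 70))
  expect_equal(choose_best_n(tab), 2)     # F tie -> higher sensitivity
  tab2 <- data.frame(n = 2:4, f_score = c(80, 80, 79),
                     sensitivity = c(70, 70, 90))
  expect_equal(choose_best_n(tab2), 2)    # full tie -> smaller n
  # sweep caps the feature count at floor(sqrt(n_lesions)) and the pool size
  rec <- make_records(n_patients = 30, lesions_per_patient = 2,
                      n_features = 12, effect = 2.5, seed = 6)
  sw <- sweep_n_sfs(rec, sprintf("f%d", 1:12))
  expect_equal(max(sw$table$n), 7)        # floor(sqrt(60)) = 7
  sw6 <- sweep_n_sfs(rec, sprintf("f%d", 1:6))
  expect_equal(max(sw6$table$n), 6)       # capped by the pool size
})

test_that("selection frequency is the per-fold fraction with the boundary included", {
  fake_cv <- function(selections) {
    folds <- lapply(selections, function(fs)
      list(patient = "x", features = fs, lesion_id = "y",
           posterior = 0.1, truth = "benign"))
    structure(list(folds = folds), class = "cv_result")
  }
  cv <- fake_cv(c(replicate(29, c("a", "b"), simplify = FALSE),
                  list(c("a", "c"))))
  sf <- selection_frequency(cv)
  expect_equal(sf$table$frequency_pct[sf$table$feature == "a"], 100)
  expect_equal(sf$table$frequency_pct[sf$table$feature == "b"],
               96.7, tolerance = 0.05)
  cv2 <- fake_cv(c(replicate(15, "a", simplify = FALSE),
                   replicate(15, "b", simplify = FALSE)))
  sf2 <- selection_frequency(cv2)
  expect_setequal(sf2$fselected, c("a", "b"))  # exactly 50% is included
})

test_that("metrics reproduce the published worked examples from their confusion matrices", {
  m1 <- compute_metrics(tn = 33, fp = 8, fn = 6, tp = 13)
  expect_equal(round(unname(m1), 2), c(76.67, 68.42, 80.49, 65.00))
  m2 <- compute_metrics(tn = 29, fp = 12, fn = 3, tp = 16)
  expect_equal(round(unname(m2), 2), c(75.00, 84.21, 70.73, 68.09))
  m3 <- compute_metrics(tn = 37, fp = 4, fn = 3, tp = 16)
  expect_equal(round(unname(m3), 2), c(88.33, 84.21, 90.24, 82.05))
  perfect <- compute_metrics(tn = 41, fp = 0, fn = 0, tp = 19)
  expect_equal(unname(perfect), c(100, 100, 100, 100))
  expect_true(is.na(compute_metrics(tn = 3, fp = 0, fn = 0, tp = 0)[["sensitivity"]]))
})

test_that("weighted-posterior ensembles average correctly and validate their weights", {
  expect_equal(ensemble_predict(c(0.6, 0.8), c(0.5, 0.5))$posterior, 0.7)
  expect_equal(ensemble_predict(c(0.3, 0.6, 0.9), rep(1, 3) / 3)$posterior, 0.6)
  expect_equal(ensemble_predict(c(0.9, 0.2), c(1, 0))$posterior, 0.9)
  expect_equal(ensemble_predict(c(0.49, 0.51), c(0, 1))$label, "malignant")
  expect_error(ensemble_predict(c(0.5, 0.5), c(0.6, 0.6)), "sum to one")
  g2 <- weight_grid(2)
  g3 <- weight_grid(3)
  expect_equal(nrow(g2), 11)
  expect_equal(nrow(g3), 66)
  expect_equal(rowSums(g3), rep(1, 66))
  expect_equal(g2[1, ], c(0, 1))  # lexicographic enumeration
  expect_equal(g2[11, ], c(1, 0))
})

test_that("weight optimisation finds the perfect pool and resolves ties lexicographically", {
  rec <- make_records(n_patients = 12, lesions_per_patient = 2,
                      n_features = 2, n_informative = 0, seed = 10)
  rec$good <- ifelse(rec$label == "malignant", 1, 0) + rnorm(nrow(rec), 0, 0.05)
  pools <- list(good = "good", noise = "f1")
  w <- optimize_weights(rec, pools)
  # the chosen weights achieve a perfect inner ROC point
  inner <- matrix(NA_real_, nrow(rec), 2)
  for (p in unique(rec$patient_id)) {
    te <- rec$patient_id == p
    tr <- rec[!te, ]
    for (j in 1:2)
      inner[te, j] <- posterior_malignant(train_qda(tr, pools[[j]]), rec[te, ])
  }
  pred <- as.numeric(inner %*% w) >= 0.5
  expect_true(all(pred == (rec$label == "malignant")))
  # lexicographic tie rule: no grid vector with smaller weight on the good
  # pool also reaches the ideal ROC point
  for (w1 in seq(0, w[1] - 0.1, by = 0.1)) {
    p <- as.numeric(inner %*% c(w1, 1 - w1)) >= 0.5
    expect_false(all(p == (rec$label == "malignant")))
  }
  # identical pools: every grid point ties; lexicographically smallest wins
  w_tie <- optimize_weights(rec, list(a = "good", b = "good"))
  expect_equal(w_tie, c(0, 1))
})

test_that("a single-pool ensemble degenerates to fixed-feature LOPO-CV and weights satisfy the simplex constraint", {
  rec <- make_records(n_patients = 10, lesions_per_patient = 2,
                      n_features = 4, effect = 2, seed = 12)
  ens <- ensemble_lopo(rec, list(main = c("f1", "f2")))
  ref <- lopo_cv(rec, c("f1", "f2"), features_fixed = c("f1", "f2"))
  expect_equal(ens$confusion, ref$confusion)
  expect_equal(unlist(lapply(ens$folds, `[[`, "posterior")),
               unlist(lapply(ref$folds, `[[`, "posterior")))
  expect_equal(rowSums(ens$weights), rep(1, 10), tolerance = 1e-12)
})

test_that("complementary pools combine into an ensemble at least as good as each alone", {
  set.seed(21)
  n_pat <- 16
  rec <- make_records(n_patients = n_pat, lesions_per_patient = 2,
                      n_features = 1, n_informative = 0, seed = 21)
  z <- ifelse(rec$label == "malignant", 1, 0)
  u <- rnorm(nrow(rec), 0, 0.55)
  rec$fa <- z + u
  rec$fb <- z - u
  pools <- list(A = "fa", B = "fb")
  cvA <- lopo_cv(rec, "fa", features_fixed = "fa")
  cvB <- lopo_cv(rec, "fb", features_fixed = "fb")
  ens <- ensemble_lopo(rec, pools)
  expect_gte(ens$metrics[["f_score"]],
             max(cvA$metrics[["f_score"]], cvB$metrics[["f_score"]]))
})

test_that("record validation rejects missing or non-finite features", {
  rec <- make_records(seed = 1)
  expect_error(train_qda(rec, c("f1", "nope")), "missing feature")
  rec$f2[3] <- NA
  expect_error(train_qda(rec, c("f1", "f2")), "non-finite")
})
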