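# Benign/malignant lesion classification: quadratic discriminant analysis,
# ROC AUC, sequential forward feature selection inside leave-one-patient-out
# cross-validation, selection-frequency feature ranking, performance metrics,
# and weighted-posterior ensembles with inner-loop weight optimisation.

CLASSES <- c("benign", "malignant")

check_records <- function(records, features = NULL) {
  stopifnot(is.data.frame(records),
            all(c("patient_id", "label") %in% names(records)))
  if (!all(records$label %in% CLASSES))
    stop("labels must be 'benign' or 'malignant'")
  if (!is.null(features)) {
    missing <- setdiff(features, names(records))
    if (length(missing))
      stop("missing feature columns: ", paste(missing, collapse = ", "))
    if (any(!is.finite(as.matrix(records[, features, drop = FALSE]))))
      stop("non-finite feature values among the features in use")
  }
  invisible(records)
}

#' Train a quadratic discriminant analysis model
#'
#' Class-conditional multivariate Gaussians estimated by maximum likelihood
#' (per-class mean and unbiased sample covariance) with empirical class
#' priors.  A small ridge (`ridge * mean(diag(cov))` on the diagonal)
#' stabilises near-singular covariances, which arise when the number of
#' features approaches the per-class sample count.
#'
#' @param records Data frame with `label` (`"benign"`/`"malignant"`) and the
#'   feature columns.
#' @param features Character vector of feature names to use.
#' @param ridge Relative ridge regularisation (default 1e-6).
#' @param priors `"empirical"` (training class frequencies) or `"equal"`.
#' @return An object of class `qda_model`.
#' @export
train_qda <- function(records, features, ridge = 1e-6,
                      priors = c("empirical", "equal")) {
  priors <- match.arg(priors)
  check_records(records, features)
  X <- as.matrix(records[, features, drop = FALSE])
  lab <- records$label
  if (any(table(factor(lab, CLASSES)) < 2))
    stop("need at least 2 records per class")
  par <- lapply(CLASSES, function(cl) {
    Xi <- X[lab == cl, , drop = FALSE]
    mu <- colMeans(Xi)
    S <- stats::cov(Xi)
    S <- S + diag(ridge * mean(diag(S)) + 1e-300, ncol(X))
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      S <- S + diag(1e-3 * mean(diag(S)), ncol(X))
      ch <- tryCatch(chol(S), error = function(e)
        stop("singular class covariance after regularization"))
    }
    list(mean = mu, cov = S, chol = ch,
         logdet = 2 * sum(log(diag(ch))))
  })
  names(par) <- CLASSES
  pr <- if (priors == "equal") c(0.5, 0.5)
        else as.numeric(table(factor(lab, CLASSES)) / length(lab))
  names(pr) <- CLASSES
  structure(list(features = features, classes = CLASSES, par = par,
                 priors = pr),
            class = "qda_model")
}

#' Posterior probability of malignancy under a QDA model
#'
#' Bayes posterior of the malignant class under the class-conditional
#' Gaussian densities and class priors.
#'
#' @param model A `qda_model`.
#' @param newdata Data frame containing the model's feature columns.
#' @return Numeric vector in `[0, 1]`, one posterior per row.
#' @export
posterior_malignant <- function(model, newdata) {
  missing <- setdiff(model$features, names(newdata))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  X <- as.matrix(newdata[, model$features, drop = FALSE])
  logp <- vapply(model$classes, function(cl) {
    p <- model$par[[cl]]
    z <- backsolve(p$chol, t(sweep(X, 2, p$mean)), transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * p$logdet + log(model$priors[[cl]])
  }, numeric(nrow(X)))
  logp <- matrix(logp, ncol = 2)
  mx <- pmax(logp[, 1], logp[, 2])
  w <- exp(logp - mx)
  w[, 2] / rowSums(w)
}

#' Area under the ROC curve
#'
#' Computed as the normalised Mann-Whitney U statistic (tied scores count
#' one half), with malignant as the positive class.
#'
#' @param scores Numeric classifier scores, larger = more malignant.
#' @param labels Class labels (`"benign"`/`"malignant"`) or logical
#'   (TRUE = malignant).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "malignant"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for ROC analysis")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

qda_auc <- function(train, test, feats) {
  m <- train_qda(train, feats)
  roc_auc(posterior_malignant(m, test), test$label)
}

#' Sequential forward feature selection
#'
#' Greedy forward search: starting from the empty set, each step adds the
#' pool feature that maximises the ROC AUC of a QDA model trained on the
#' training records.  By default the AUC is evaluated by resubstitution on
#' the same training records; `eval = "lopo"` evaluates each candidate set by
#' an inner leave-one-patient-out pass instead.  AUC ties are broken by the
#' candidate's position in the canonical pool order; candidates whose QDA
#' training fails are skipped with a warning.
#'
#' @param records Training records (data frame).
#' @param pool Character vector of candidate features (canonical order).
#' @param n_sfs Number of features to select (`<= length(pool)`).
#' @param eval `"resub"` (default) or `"lopo"`.
#' @return Character vector of selected features in greedy order.
#' @export
sfs_select <- function(records, pool, n_sfs, eval = c("resub", "lopo")) {
  eval <- match.arg(eval)
  check_records(records, pool)
  stopifnot(n_sfs >= 1, n_sfs <= length(pool))
  eval_auc <- function(feats) {
    if (eval == "resub") return(qda_auc(records, records, feats))
    post <- rep(NA_real_, nrow(records))
    for (p in unique(records$patient_id)) {
      tr <- records[records$patient_id != p, , drop = FALSE]
      te <- records$patient_id == p
      post[te] <- posterior_malignant(train_qda(tr, feats),
                                      records[te, , drop = FALSE])
    }
    roc_auc(post, records$label)
  }
  selected <- character(0)
  for (step in seq_len(n_sfs)) {
    candidates <- setdiff(pool, selected)
    best_auc <- -Inf
    best <- NULL
    for (f in candidates) {
      auc <- tryCatch(eval_auc(c(selected, f)), error = function(e) {
        warning("SFS: skipping candidate '", f, "': ", conditionMessage(e))
        NA_real_
      })
      if (!is.na(auc) && auc > best_auc) {
        best_auc <- auc
        best <- f
      }
    }
    if (is.null(best)) stop("SFS: no candidate could be evaluated")
    selected <- c(selected, best)
  }
  selected
}

#' Classification performance metrics from a confusion matrix
#'
#' Malignant is the positive class: sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), accuracy = (TP+TN)/total, and the F-score is the harmonic mean
#' of precision and sensitivity.  All reported as percentages; metrics with a
#' zero denominator are `NA`.
#'
#' @param tn,fp,fn,tp Confusion-matrix counts (true benign predicted benign,
#'   true benign predicted malignant, true malignant predicted benign, true
#'   malignant predicted malignant).
#' @return Named numeric: `accuracy`, `sensitivity`, `specificity`, `f_score`
#'   in percent.
#' @export
compute_metrics <- function(tn, fp, fn, tp) {
  tn <- unname(tn); fp <- unname(fp); fn <- unname(fn); tp <- unname(tp)
  stopifnot(tn >= 0, fp >= 0, fn >= 0, tp >= 0, tn + fp + fn + tp > 0)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sn <- div(tp, tp + fn)
  sp <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f <- if (is.na(prec) || is.na(sn) || prec + sn == 0) NA_real_
       else 2 * prec * sn / (prec + sn)
  100 * c(accuracy = (tp + tn) / (tn + fp + fn + tp),
          sensitivity = sn, specificity = sp, f_score = f)
}

confusion_counts <- function(pred_malignant, truth) {
  pos <- truth == "malignant"
  c(tn = sum(!pred_malignant & !pos), fp = sum(pred_malignant & !pos),
    fn = sum(!pred_malignant & pos), tp = sum(pred_malignant & pos))
}

make_cv_result <- function(folds) {
  post <- unlist(lapply(folds, `[[`, "posterior"))
  truth <- unlist(lapply(folds, `[[`, "truth"))
  pred <- post >= 0.5
  conf <- confusion_counts(pred, truth)
  structure(list(folds = folds, confusion = conf,
                 metrics = compute_metrics(conf["tn"], conf["fp"],
                                           conf["fn"], conf["tp"])),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LOPO-CV over %d folds, %d lesions\n", length(x$folds),
              sum(x$confusion)))
  cat(sprintf("  confusion (tn fp fn tp): %s\n",
              paste(x$confusion, collapse = " ")))
  cat(sprintf("  accuracy %.2f%%, Sn %.2f%%, Sp %.2f%%, F %.2f%%\n",
              x$metrics["accuracy"], x$metrics["sensitivity"],
              x$metrics["specificity"], x$metrics["f_score"]))
  invisible(x)
}

#' Leave-one-patient-out cross-validation with per-fold feature selection
#'
#' One fold per patient: all of a patient's lesions are held out together so
#' no patient contributes to both training and testing of any fold.  Per
#' fold, SFS selects `n_sfs` features on the training patients, a QDA model
#' is retrained on the selected features, and the left-out lesions are
#' classified by thresholding the malignant posterior at 0.5.  Passing
#' `features_fixed` skips SFS and uses a fixed feature set in every fold.
#'
#' @param records Data frame of lesion records (`lesion_id`, `patient_id`,
#'   `label`, feature columns).
#' @param pool Candidate feature pool (canonical order).
#' @param n_sfs Number of features selected per fold (ignored when
#'   `features_fixed` is given).
#' @param features_fixed Optional fixed feature set.
#' @param sfs_eval Passed to [sfs_select()].
#' @return A `cv_result`: per-fold details (left-out patient, selected
#'   features, per-lesion posteriors), aggregate confusion matrix and
#'   metrics.
#' @export
lopo_cv <- function(records, pool, n_sfs = NULL, features_fixed = NULL,
                    sfs_eval = "resub") {
  check_records(records, pool)
  patients <- unique(records$patient_id)
  if (length(patients) < 2) stop("need at least 2 patients for LOPO-CV")
  folds <- lapply(patients, function(p) {
    te <- records$patient_id == p
    train <- records[!te, , drop = FALSE]
    test <- records[te, , drop = FALSE]
    if (length(unique(train$label)) < 2)
      stop("fold with single-class training data (patient ", p, ")")
    feats <- if (!is.null(features_fixed)) features_fixed
             else sfs_select(train, pool, n_sfs, eval = sfs_eval)
    model <- train_qda(train, feats)
    post <- posterior_malignant(model, test)
    list(patient = p, features = feats, lesion_id = test$lesion_id,
         posterior = post, truth = test$label)
  })
  make_cv_result(folds)
}

#' Per-feature selection frequency over cross-validation folds
#'
#' The fraction of LOPO-CV folds in which each feature was part of the
#' per-fold SFS selection.  Features selected in at least half the folds form
#' the pool's important feature set `fselected`.
#'
#' @param cv A `cv_result` from [lopo_cv()].
#' @param threshold Selection-frequency cut in percent (default 50; the
#'   boundary value is included).
#' @return List with `table` (data frame `feature`, `frequency_pct`, sorted
#'   decreasing) and `fselected` (character vector).
#' @export
selection_frequency <- function(cv, threshold = 50) {
  feats <- unlist(lapply(cv$folds, `[[`, "features"))
  tab <- sort(table(feats), decreasing = TRUE)
  pct <- 100 * as.numeric(tab) / length(cv$folds)
  out <- data.frame(feature = names(tab), frequency_pct = pct)
  list(table = out, fselected = out$feature[out$frequency_pct >= threshold])
}

#' Choose the best feature count from a per-n metric table
#'
#' Selects the row with the highest F-score; ties go to the higher
#' sensitivity, remaining ties to the smaller feature count.
#'
#' @param tab Data frame with columns `n`, `f_score`, `sensitivity`.
#' @return The chosen `n`.
#' @export
choose_best_n <- function(tab) {
  ord <- order(-tab$f_score, -tab$sensitivity, tab$n)
  tab$n[ord[1]]
}

#' Sweep the number of SFS features and pick the best
#'
#' Runs [lopo_cv()] for every feature count in `n_range` (by default 1 up to
#' the smaller of the pool size and `floor(sqrt(n_lesions))`, the
#' rule-of-thumb cap on feature-set size for correlated features) and selects
#' the count with the best F-score (ties: higher sensitivity, then fewer
#' features).
#'
#' @param records Lesion records.
#' @param pool Candidate feature pool.
#' @param n_range Feature counts to try.
#' @param sfs_eval Passed to [sfs_select()].
#' @return List with `n_selected`, `cv` (the winning `cv_result`), `table`
#'   (metrics per n) and `all` (every `cv_result`).
#' @export
sweep_n_sfs <- function(records, pool, n_range = NULL, sfs_eval = "resub") {
  if (is.null(n_range))
    n_range <- seq_len(min(length(pool), floor(sqrt(nrow(records)))))
  stopifnot(all(n_range >= 1), all(n_range <= length(pool)))
  cvs <- lapply(n_range, function(n) lopo_cv(records, pool, n_sfs = n,
                                             sfs_eval = sfs_eval))
  tab <- data.frame(n = n_range,
                    t(vapply(cvs, function(cv) cv$metrics, numeric(4))))
  names(tab)[2:5] <- c("accuracy", "sensitivity", "specificity", "f_score")
  n_best <- choose_best_n(tab)
  list(n_selected = n_best, cv = cvs[[match(n_best, n_range)]],
       table = tab, all = cvs)
}

#' Simplex grid of ensemble weight vectors
#'
#' All length-k weight vectors with entries on a `step` grid summing to one,
#' in lexicographic order (11 vectors for k = 2, 66 for k = 3 at step 0.1).
#'
#' @param k Number of pools.
#' @param step Grid step (default 0.1; `1/step` must be an integer).
#' @return Matrix with k columns, one grid vector per row.
#' @export
weight_grid <- function(k, step = 0.1) {
  m <- round(1 / step)
  if (abs(m * step - 1) > 1e-9) stop("1/step must be an integer")
  grid_int <- function(k, total) {
    if (k == 1) return(matrix(total, 1, 1))
    do.call(rbind, lapply(0:total, function(i)
      cbind(i, grid_int(k - 1, total - i))))
  }
  unname(grid_int(k, m) * step)
}

#' Weighted-posterior ensemble prediction
#'
#' @param posteriors Numeric vector (one lesion) or matrix (lesions x pools)
#'   of per-pool malignant posteriors.
#' @param weights Weight vector, entries in `[0, 1]` summing to one.
#' @return List with `posterior` (weighted average) and `label`
#'   (malignant iff posterior >= 0.5).
#' @export
ensemble_predict <- function(posteriors, weights) {
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0) || any(weights > 1))
    stop("ensemble weights must lie in [0, 1] and sum to one")
  pm <- if (is.null(dim(posteriors))) matrix(posteriors, nrow = 1)
        else posteriors
  stopifnot(ncol(pm) == length(weights))
  p <- as.numeric(pm %*% weights)
  list(posterior = p, label = ifelse(p >= 0.5, "malignant", "benign"))
}

# Held-out per-pool posteriors via an inner LOPO pass over `records`
inner_pool_posteriors <- function(records, pools) {
  post <- matrix(NA_real_, nrow(records), length(pools))
  for (p in unique(records$patient_id)) {
    te <- records$patient_id == p
    train <- records[!te, , drop = FALSE]
    if (length(unique(train$label)) < 2)
      stop("degenerate inner fold: single-class training data")
    for (j in seq_along(pools)) {
      m <- train_qda(train, pools[[j]])
      post[te, j] <- posterior_malignant(m, records[te, , drop = FALSE])
    }
  }
  post
}

#' Optimise ensemble weights on training patients
#'
#' An inner leave-one-patient-out loop over the training patients produces
#' held-out per-pool posteriors; every weight vector on the simplex grid is
#' scored by thresholding its weighted posterior at 0.5 and measuring the
#' ROC-plane distance of `(1 - Sp, Sn)` to the ideal point `(0, 1)`.  The
#' closest vector wins; ties go to the lexicographically smallest vector.
#'
#' @param records Training records (>= 2 patients).
#' @param pools Named list of feature sets, one per ensemble member.
#' @param grid_step Weight grid step (default 0.1).
#' @return Numeric weight vector of length `length(pools)`.
#' @export
optimize_weights <- function(records, pools, grid_step = 0.1) {
  if (length(unique(records$patient_id)) < 2)
    stop("need at least 2 training patients for weight optimization")
  post <- inner_pool_posteriors(records, pools)
  truth <- records$label
  grid <- weight_grid(length(pools), grid_step)
  best_d <- Inf
  best_w <- grid[1, ]
  for (i in seq_len(nrow(grid))) {
    conf <- confusion_counts(as.numeric(post %*% grid[i, ]) >= 0.5, truth)
    sn <- if (conf["tp"] + conf["fn"] > 0) conf["tp"] / (conf["tp"] + conf["fn"]) else 0
    sp <- if (conf["tn"] + conf["fp"] > 0) conf["tn"] / (conf["tn"] + conf["fp"]) else 0
    d <- sqrt((1 - sp)^2 + (1 - sn)^2)
    if (d < best_d - 1e-12) {  # strict improvement; earlier (lexicographically
      best_d <- d              # smaller) grid vectors win ties
      best_w <- grid[i, ]
    }
  }
  unname(best_w)
}

#' Ensemble classification with leave-one-patient-out cross-validation
#'
#' Per outer fold: ensemble weights are optimised on the training patients
#' ([optimize_weights()]), one QDA model per pool is trained on the training
#' lesions using that pool's pre-determined important features, and the
#' left-out lesions are classified by the weighted posterior at threshold
#' 0.5.  The per-pool feature sets must be fixed in advance (from
#' [selection_frequency()]); no feature selection happens inside the
#' ensemble loop.
#'
#' @param records Lesion records.
#' @param pools Named list of per-pool feature sets (`fselected`).
#' @param grid_step Weight grid step (default 0.1).
#' @return A `cv_result` with an additional `weights` matrix
#'   (folds x pools).
#' @export
ensemble_lopo <- function(records, pools, grid_step = 0.1) {
  check_records(records, unique(unlist(pools)))
  patients <- unique(records$patient_id)
  if (length(patients) < 2) stop("need at least 2 patients for LOPO-CV")
  folds <- lapply(patients, function(p) {
    te <- records$patient_id == p
    train <- records[!te, , drop = FALSE]
    test <- records[te, , drop = FALSE]
    if (length(unique(train$label)) < 2)
      stop("fold with single-class training data (patient ", p, ")")
    w <- optimize_weights(train, pools, grid_step)
    post <- vapply(pools, function(feats)
      posterior_malignant(train_qda(train, feats), test),
      numeric(nrow(test)))
    post <- matrix(post, nrow = nrow(test))
    list(patient = p, features = unlist(pools), lesion_id = test$lesion_id,
         posterior = ensemble_predict(post, w)$posterior,
         truth = test$label, weights = w)
  })
  res <- make_cv_result(folds)
  res$weights <- do.call(rbind, lapply(folds, `[[`, "weights"))
  colnames(res$weights) <- names(pools)
  res
}
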