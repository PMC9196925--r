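#!/usr/bin/env Rscript
# Ensemble classification: QDA models trained per pool on that pool's
# important features (from 03), combined by a weighted average of posterior
# probabilities. Weights are optimised per outer LOPO fold in an inner
# leave-one-patient-out loop on a 0.1-step simplex grid, picking the ROC
# point closest to the ideal (0, 1).

library(maflim)

feats <- read.csv("results/features.csv", check.names = FALSE)
sel <- read.csv("results/selection_frequency.csv", check.names = FALSE)
fselected <- split(sel$feature[sel$important], sel$pool[sel$important])

combos <- list(c("biexp", "intensity"), c("phasor", "biexp"),
               c("phasor", "intensity"), c("phasor", "biexp", "intensity"))

perf <- list()
for (comb in combos) {
  key <- paste(comb, collapse = "+")
  if (!all(comb %in% names(fselected))) {
    message("Skipping ", key, ": a pool has no important features.")
    next
  }
  message("Ensemble ", key, " ...")
  ens <- ensemble_lopo(feats, fselected[comb])
  print(ens)
  perf[[key]] <- data.frame(ensemble = key, t(ens$metrics),
                            tn = ens$confusion["tn"], fp = ens$confusion["fp"],
                            fn = ens$confusion["fn"], tp = ens$confusion["tp"])
  w <- as.data.frame(ens$weights)
  w$fold <- seq_len(nrow(w))
  write.csv(w, sprintf("results/ensemble_weights_%s.csv",
                       gsub("\\+", "_", key)), row.names = FALSE)
}

write.csv(do.call(rbind, perf), "results/ensemble_performance.csv",
          row.names = FALSE)
message("Wrote results/ensemble_performance.csv and per-fold weight tables.")
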