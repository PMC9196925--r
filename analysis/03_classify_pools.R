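#!/usr/bin/env Rscript
# Per-pool classification: for each feature pool, sweep the number of SFS
# features (1..min(pool size, floor(sqrt(60)) = 7)) inside leave-one-patient-
# out cross-validation, pick the count with the best F-score (ties: higher
# sensitivity, then fewer features), and rank features by their selection
# frequency across folds (>= 50% defines each pool's important set).

library(maflim)

feats <- read.csv("results/features.csv", check.names = FALSE)
cfg <- acquisition_config()
pools <- feature_pools(cfg)

perf <- list()
sel <- list()
for (pn in names(pools)) {
  message("Pool ", pn, " (", length(pools[[pn]]), " features) ...")
  sw <- sweep_n_sfs(feats, pools[[pn]])
  print(sw$cv)
  sf <- selection_frequency(sw$cv)
  perf[[pn]] <- data.frame(pool = pn, n_selected = sw$n_selected,
                           t(sw$cv$metrics),
                           tn = sw$cv$confusion["tn"], fp = sw$cv$confusion["fp"],
                           fn = sw$cv$confusion["fn"], tp = sw$cv$confusion["tp"])
  sel[[pn]] <- cbind(pool = pn, sf$table,
                     important = sf$table$frequency_pct >= 50)
  message("  important features (>=50% of folds): ",
          paste(sf$fselected, collapse = ", "))
}

write.csv(do.call(rbind, perf), "results/pool_performance.csv",
          row.names = FALSE)
write.csv(do.call(rbind, sel), "results/selection_frequency.csv",
          row.names = FALSE)
message("Wrote results/pool_performance.csv and ",
        "results/selection_frequency.csv")
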