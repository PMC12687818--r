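#!/usr/bin/env Rscript
# Evaluate on the held-out test set: sweep the classification threshold
# over 100 even steps on [0.40, 0.70] to maximize macro-F1, report the
# confusion matrix and per-class metrics at the tuned threshold, and the
# Brier score of the predicted probabilities.

library(hybridsurv)

outdir <- "results/run"
fs <- readRDS(file.path(outdir, "features.rds"))
mdl <- readRDS(file.path(outdir, "model.rds"))

X_test <- fs$fm$values[fs$split$test, ]
y_test <- fs$y[fs$split$test]
probs <- predict_prob(mdl$forest, X_test)

curve <- threshold_sweep(probs, y_test)
tau <- curve$optimal
cm <- confusion(y_test, as.integer(probs >= tau))
m <- class_metrics(cm)
m$brier <- brier(probs, y_test)
m$threshold <- tau

write.csv(data.frame(threshold = curve$grid, macro_f1 = curve$macro_f1),
          file.path(outdir, "threshold_curve.csv"), row.names = FALSE)
yaml::write_yaml(lapply(m, as.numeric), file.path(outdir, "metrics.yml"))
saveRDS(list(probs = probs, tau = tau), file.path(outdir, "eval.rds"))

cat("optimal threshold:", round(tau, 3), "\n")
cat("confusion (tn fp fn tp):", cm$tn, cm$fp, cm$fn, cm$tp, "\n")
cat("accuracy:", round(100 * m$accuracy), "%\n")
cat("non-survivors: precision", round(m$precision_0, 2),
    "recall", round(m$recall_0, 2), "F1", round(m$f1_0, 2), "\n")
cat("survivors:     precision", round(m$precision_1, 2),
    "recall", round(m$recall_1, 2), "F1", round(m$f1_1, 2), "\n")
cat("macro-F1:", round(m$macro_f1, 3), "| Brier:", round(m$brier, 3), "\n")
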