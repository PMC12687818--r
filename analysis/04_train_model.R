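#!/usr/bin/env Rscript
# Train the classifier: SMOTE-balance the training split, run a randomized
# hyperparameter search (50 candidates, 5-fold stratified CV on macro-F1,
# SMOTE applied inside each training fold), and fit the balanced random
# forest with the winning configuration.

library(hybridsurv)

outdir <- "results/run"
seed <- 42L
fs <- readRDS(file.path(outdir, "features.rds"))

X_train <- fs$fm$values[fs$split$train, ]
y_train <- fs$y[fs$split$train]

tuned <- tune_hyperparameters(X_train, y_train, n_candidates = 50,
                              seed = stage_seed(seed, "train"))
bal <- smote(X_train, y_train)
forest <- train_forest(bal$rows, bal$labels, tuned$config)

saveRDS(list(forest = forest, tuned = tuned),
        file.path(outdir, "model.rds"))
write.csv(tuned$cv_table, file.path(outdir, "cv_table.csv"),
          row.names = FALSE)

cat("SMOTE: ", nrow(X_train), " rows -> ", nrow(bal$rows),
    " (", sum(bal$synthetic), " synthetic survivors)\n", sep = "")
best <- tuned$cv_table[which.max(tuned$cv_table$cv_macro_f1), ]
cat("best of", nrow(tuned$cv_table), "candidates: ntree", best$n_estimators,
    "| depth", ifelse(is.na(best$max_depth), "unbounded", best$max_depth),
    "| mtry", best$max_features, "| min split", best$min_samples_split,
    "| min leaf", best$min_samples_leaf, "\n")
cat("CV macro-F1:", round(best$cv_macro_f1, 3), "\n")
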