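#!/usr/bin/env Rscript
# Stage 4: the machine-learning analysis. Simulates the mixed
# concentration panel (37.5-100 uM) at the scale of the original
# dataset, builds the 126-feature matrix, trains the 100-tree random
# forest on a seeded 80:20 split, and reports held-out accuracy,
# grouped feature importances, the barrier-only model, and the
# concentration classifier. This reproduces what
# scripts/acceptance.R measures for targets t3-t5.

suppressMessages({library(trenchshield); library(data.table)})
say <- function(...) message(sprintf(...))
seed <- 1L

panel <- c(37.5, 50, 62.5, 75, 100)
fms <- lapply(seq_along(panel), function(i) {
  cfg <- sim_config(n_trenches = 800, seed = seed * 100L + i)
  tt <- simulate_trenches(cfg, treatment_schedule(
    0, 135, panel[i], t_min = -135, t_max = 135))
  suppressMessages(build_feature_matrix(tt))
})
fm <- do.call(rbind, fms)
attr(fm, "manifest") <- feature_manifest()
class(fm) <- c("feature_matrix", "data.frame")
say("dataset: %d mothers x %d features across %s uM",
    nrow(fm), length(feature_columns(fm)),
    paste(panel, collapse = "/"))
fwrite(fm, "results/feature_matrix.csv")

rep <- fit_peak_regressor(fm, seed = seed)
print(rep)
bo <- barrier_only_model(fm, seed = seed)
say("barrier-only model (56 features): A = %.3f (full model %.3f)",
    bo$accuracy, rep$accuracy)

cl <- train_classifier(fm, seed = seed)
say("concentration classifier: %.0f%% correct (chance %.0f%%)",
    100 * cl$accuracy, 100 / length(panel))
print(round(cl$confusion, 2))

imp <- sort(rep$importances$per_feature, decreasing = TRUE)
say("top features: %s",
    paste(sprintf("%s (%.3f)", names(imp)[1:5], imp[1:5]),
          collapse = ", "))

jsonlite::write_json(list(
  n_mothers = nrow(fm),
  accuracy = rep$accuracy,
  barrier_only_accuracy = bo$accuracy,
  barrier_share = rep$importances$barrier_share,
  mother_share = rep$importances$mother_share,
  top2_share = rep$importances$top_k_share,
  top_features = rep$importances$top_features,
  classifier_accuracy = cl$accuracy,
  confusion = as.data.frame.matrix(cl$confusion)
), "results/model_report.json", auto_unbox = TRUE, digits = NA)
say("written results/model_report.json")
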