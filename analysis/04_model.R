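#!/usr/bin/env Rscript
# Stage 4: train the gradient-boosted stability regressor on a larger
# count-level simulation, predict random sequences, select candidate
# motifs with unexpected stability, and attribute one candidate.
#
# Output: results/model/

suppressMessages(library(psifive))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 20260926L
outdir <- "results/model"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
set.seed(seed)

effects <- effect_model_preset()
sorter <- sort_model()
lib <- sample_motif_library(20000, effects, "WT")
lib <- lib[!duplicated(lib$motif), ]
db <- build_database(simulate_motif_counts(lib, sorter, 200), genotype = "WT")
message("training database: ", nrow(db), " motifs")

cfg <- model_config(split_seed = seed, train_seed = seed)
sp <- prepare_training(db, cfg)
fit <- train_stability_model(sp$train, sp$validation, cfg)
print(fit)
rep <- fit$report
writeLines(sprintf("%s\t%s", names(rep), unlist(rep)),
           file.path(outdir, "train_report.tsv"))

# predicted PSI for 100,000 random five-residue sequences
motifs <- unique(vapply(seq_len(110000), function(i)
  paste(sample(AA_ALPHABET, 5, replace = TRUE), collapse = ""), ""))[1:100000]
ppsi <- predict(fit, motifs)
write.table(data.frame(motif = motifs, ppsi = ppsi),
            file.path(outdir, "random_predictions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
dest <- substr(motifs, 1, 1) %in% AA_GROUPS$CanonicalDestabilizing
message(sprintf("mean pPSI: destabilizing P1 %.2f vs other P1 %.2f",
                mean(ppsi[dest]), mean(ppsi[!dest])))

# unexpectedly stable P1-Leu candidates and unstable non-FLWYRK candidates
stable <- select_candidates(fit, fixed = list("1" = "L"),
                            direction = "stable", threshold = 3.0, k = 5)
unstable <- select_candidates(
  fit, excluded = list("1" = AA_GROUPS$CanonicalDestabilizing),
  direction = "unstable", threshold = 2.8, k = 5)
write.table(rbind(cbind(stable, class = "stable_P1L"),
                  cbind(unstable, class = "unstable_nonFLWYRK")),
            file.path(outdir, "candidates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("candidates:")
print(stable)
print(unstable)

# additive attribution of the top unstable candidate
if (nrow(unstable)) {
  att <- attribute_prediction(fit, unstable$motif[1])
  top <- sort(abs(att$contributions), decreasing = TRUE)[1:10]
  out <- data.frame(feature = c("baseline", names(att$contributions)),
                    contribution = c(att$baseline, att$contributions))
  write.table(out, file.path(outdir,
                             paste0("attribution_", unstable$motif[1], ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message("attribution for ", unstable$motif[1], " (prediction ",
          round(att$prediction, 2), "); top features: ",
          paste(names(top)[1:5], collapse = ", "))
}
message("model outputs written to ", outdir)
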