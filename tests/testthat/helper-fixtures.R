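# Shared fixtures: all synthetic inputs are built in code at test time.

# Random 5-residue motifs over the standard alphabet.
random_motifs <- function(n) {
  vapply(seq_len(n),
         function(i) paste(sample(AA_ALPHABET, 5, replace = TRUE),
                           collapse = ""),
         character(1))
}

# Brute-force Cliff's delta: the all-ordered-pairs definition. Independent
# oracle for the rank-based implementation.
cliffs_delta_bruteforce <- function(x, y) {
  cmp <- outer(x, y, function(a, b) sign(a - b))
  mean(cmp)
}

# Effect model with a single ClpS-dependent destabilizing effect at (F, P1).
single_effect_model <- function(value = -1.0) {
  effect_model(baseline = 3.5,
               residue_effects = data.frame(residue = "F", position = 1L,
                                            value = value,
                                            dependency = "clps"))
}

# Purely additive effect model with every |effect| >= 0.3 (no pairs).
additive_effect_model <- function() {
  re <- rbind(
    data.frame(residue = c("F", "L", "W", "Y", "R", "K"), position = 1L,
               value = c(-1.0, -0.8, -0.6, -0.5, -0.9, -0.45),
               dependency = "none"),
    data.frame(residue = c("P", "G", "Q"), position = 2L,
               value = c(0.5, 0.35, -0.4), dependency = "none"),
    data.frame(residue = c("D", "E", "W"), position = 3L,
               value = c(0.3, 0.3, -0.3), dependency = "none"),
    data.frame(residue = "S", position = 4L, value = 0.3,
               dependency = "none"))
  effect_model(baseline = 3.3, residue_effects = re)
}

# Simulated motif database from an effect model: distinct library motifs,
# per-motif multinomial bin counts, raw-mode PSI.
simulated_database <- function(n_motifs, model, genotype = "WT",
                               reads_per_motif = 200, sort = sort_model()) {
  lib <- sample_motif_library(n_motifs, model, genotype)
  lib <- lib[!duplicated(lib$motif), , drop = FALSE]
  cnt <- simulate_motif_counts(lib, sort, reads_per_motif)
  build_database(cnt, genotype = genotype)
}

# Minimal motif_db straight from a counts data frame.
db_from_counts <- function(motif, counts, ...) {
  m <- matrix(counts, ncol = 4, byrow = TRUE)
  build_database(data.frame(motif = motif, count_b1 = m[, 1],
                            count_b2 = m[, 2], count_b3 = m[, 3],
                            count_b4 = m[, 4]), ...)
}

# A small, fast training configuration for unit tests (the full-size
# configuration is exercised in the acceptance suite).
small_model_config <- function(...) {
  model_config(min_reads = 1L, n_estimators = 120L, max_depth = 6L,
               learning_rate = 0.2, subsample = 1, colsample_bytree = 1, ...)
}
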