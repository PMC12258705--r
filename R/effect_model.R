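#' Ground-truth stability effect model
#'
#' An additive (plus pairwise-interaction) model of true stability on the
#' PSI scale, used by the simulator as injectable ground truth for
#' parameter-recovery tests. Each effect carries a dependency tag saying
#' which degradation component it requires: effects tagged `"clps"` are
#' suppressed in the ClpS-knockout genotype, `"lftr"` in the LFTR knockout,
#' and `"clps+lftr"` in either knockout (LFTR-created neo-degrons still
#' need ClpS for turnover).
#'
#' @param baseline Baseline stability on the PSI scale (dimensionless).
#' @param residue_effects Data frame with columns `residue`, `position`
#'   (1..5), `value`, `dependency` (one of "none", "clps", "lftr",
#'   "clps+lftr"). May be empty/NULL.
#' @param pair_effects Data frame with columns `residue1`, `position1`,
#'   `residue2`, `position2`, `value`, `dependency`. May be empty/NULL.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(baseline = 3.5, residue_effects = NULL,
                         pair_effects = NULL) {
  stopifnot(is.numeric(baseline), length(baseline) == 1)
  empty_res <- data.frame(residue = character(), position = integer(),
                          value = numeric(), dependency = character(),
                          stringsAsFactors = FALSE)
  empty_pair <- data.frame(residue1 = character(), position1 = integer(),
                           residue2 = character(), position2 = integer(),
                           value = numeric(), dependency = character(),
                           stringsAsFactors = FALSE)
  residue_effects <- if (is.null(residue_effects)) empty_res else
    as.data.frame(residue_effects, stringsAsFactors = FALSE)
  pair_effects <- if (is.null(pair_effects)) empty_pair else
    as.data.frame(pair_effects, stringsAsFactors = FALSE)

  if (nrow(residue_effects)) {
    if (!"dependency" %in% names(residue_effects)) residue_effects$dependency <- "none"
    stopifnot(all(residue_effects$residue %in% AA_ALPHABET),
              all(residue_effects$position %in% 1:5))
  }
  if (nrow(pair_effects)) {
    if (!"dependency" %in% names(pair_effects)) pair_effects$dependency <- "none"
    stopifnot(all(c(pair_effects$residue1, pair_effects$residue2) %in% AA_ALPHABET),
              all(c(pair_effects$position1, pair_effects$position2) %in% 1:5))
  }
  deps <- c(residue_effects$dependency, pair_effects$dependency)
  stopifnot(all(deps %in% c("none", "clps", "lftr", "clps+lftr")))

  structure(list(baseline = baseline,
                 residue_effects = residue_effects,
                 pair_effects = pair_effects),
            class = "effect_model")
}

# Which effects are active for a genotype: a knockout suppresses every
# effect whose dependency names the inactivated component.
effect_active <- function(dependency, genotype) {
  genotype <- match.arg(genotype, GENOTYPES)
  switch(genotype,
         WT      = rep(TRUE, length(dependency)),
         CLPS_KO = !grepl("clps", dependency, fixed = TRUE),
         LFTR_KO = !grepl("lftr", dependency, fixed = TRUE))
}

#' True stability of motifs under an effect model
#'
#' Baseline plus the sum of active single-residue and pairwise effects,
#' with the genotype mask applied, clamped to the attainable PSI range
#' \[1, 4\].
#'
#' @param motifs Character vector of 5-residue motifs.
#' @param model An [effect_model()].
#' @param genotype One of `"WT"`, `"CLPS_KO"`, `"LFTR_KO"`.
#' @return Numeric vector of true stabilities in \[1, 4\].
#' @export
true_stability <- function(motifs, model, genotype = "WT") {
  stopifnot(inherits(model, "effect_model"))
  check_motifs(motifs)
  genotype <- match.arg(genotype, GENOTYPES)
  score <- rep(model$baseline, length(motifs))

  re <- model$residue_effects
  if (nrow(re)) {
    re <- re[effect_active(re$dependency, genotype), , drop = FALSE]
    for (i in seq_len(nrow(re))) {
      hit <- substr(motifs, re$position[i], re$position[i]) == re$residue[i]
      score[hit] <- score[hit] + re$value[i]
    }
  }
  pe <- model$pair_effects
  if (nrow(pe)) {
    pe <- pe[effect_active(pe$dependency, genotype), , drop = FALSE]
    for (i in seq_len(nrow(pe))) {
      hit <- substr(motifs, pe$position1[i], pe$position1[i]) == pe$residue1[i] &
             substr(motifs, pe$position2[i], pe$position2[i]) == pe$residue2[i]
      score[hit] <- score[hit] + pe$value[i]
    }
  }
  pmin(4, pmax(1, score))
}

#' Preset effect model encoding known N-degron determinants
#'
#' A test-fixture ground truth that qualitatively encodes the pathway's
#' known behaviour: strong destabilization by bulky (F, L, W, Y) and, via
#' LFTR, positively charged (R, K) P1 residues; P2 Pro/Gly stabilization
#' and P2 Gln destabilization; destabilizing bulky residues and stabilizing
#' acidic and Gly/Ser residues through P2-P5; and an Nt-Cys interaction
#' with downstream acidic/bulky residues. Magnitudes are plausible-scale
#' fixtures for parameter recovery, not measured values.
#'
#' @param baseline Baseline stability (default 3.7: most motifs stable).
#' @return An [effect_model()].
#' @export
effect_model_preset <- function(baseline = 3.7) {
  p1 <- data.frame(
    residue = c("F", "L", "W", "Y", "R", "K"),
    position = 1L,
    value = c(-1.50, -1.00, -0.90, -0.90, -1.45, -0.95),
    dependency = c(rep("clps", 4), rep("clps+lftr", 2)))
  p2 <- data.frame(
    residue = c("P", "G", "Q", "A"),
    position = 2L,
    value = c(1.05, 0.63, -0.51, 0.20),
    dependency = "clps")
  bulky <- expand.grid(residue = c("F", "L", "W", "Y"), position = 2:5,
                       stringsAsFactors = FALSE)
  bulky$value <- c(-0.35, -0.30, -0.15, -0.10)[bulky$position - 1L]
  bulky$dependency <- "clps"
  acidic <- expand.grid(residue = c("D", "E"), position = 2:5,
                        stringsAsFactors = FALSE)
  acidic$value <- 0.25
  acidic$dependency <- "clps"
  flex <- expand.grid(residue = c("G", "S"), position = 3:5,
                      stringsAsFactors = FALSE)
  flex$value <- 0.12
  flex$dependency <- "clps"
  pairs <- data.frame(
    residue1 = c("C", "C"), position1 = 1L,
    residue2 = c("E", "F"), position2 = c(3L, 2L),
    value = c(-0.60, -0.50), dependency = "clps")
  effect_model(baseline = baseline,
               residue_effects = rbind(p1, p2, bulky, acidic, flex),
               pair_effects = pairs)
}
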