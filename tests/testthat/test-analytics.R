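test_that("mean_psi_matrix places a single motif's PSI in exactly its cells", {
  db <- db_from_counts("FAAAA", c(0, 100, 0, 0))
  m <- mean_psi_matrix(db)
  expect_equal(dim(m), c(20, 5))
  expect_equal(m["F", "P1"], 2)
  expect_equal(unname(unclass(m)["A", 2:5]), rep(2, 4))
  expect_equal(sum(!is.na(m)), 5)
  expect_equal(attr(m, "n")["F", "P1"], 1L)
  expect_equal(sum(attr(m, "n")), 5L)
})

test_that("mean_psi_matrix is invariant to motif order", {
  set.seed(14)
  motifs <- unique(random_motifs(200))
  counts <- t(rmultinom(length(motifs), 50, c(0.1, 0.2, 0.3, 0.4)))
  df <- data.frame(motif = motifs, count_b1 = counts[, 1],
                   count_b2 = counts[, 2], count_b3 = counts[, 3],
                   count_b4 = counts[, 4])
  a <- mean_psi_matrix(build_database(df))
  b <- mean_psi_matrix(build_database(df[sample(nrow(df)), ]))
  expect_equal(a, b)
})

test_that("delta_matrix is antisymmetric and NA-propagating", {
  db1 <- db_from_counts(c("FAAAA", "CAAAA"), c(0, 100, 0, 0, 0, 0, 0, 100))
  db2 <- db_from_counts(c("FAAAA", "WAAAA"), c(0, 0, 0, 100, 0, 100, 0, 0))
  m1 <- mean_psi_matrix(db1)
  m2 <- mean_psi_matrix(db2)
  d12 <- delta_matrix(m1, m2)
  d21 <- delta_matrix(m2, m1)
  expect_equal(d12["F", "P1"], -2)
  expect_equal(unclass(d12), -unclass(d21))
  expect_true(is.na(d12["C", "P1"]))  # present only in db1
  expect_true(is.na(d12["W", "P1"]))  # present only in db2
  dd <- delta_matrix(m1, m1)
  expect_equal(max(abs(unclass(dd)), na.rm = TRUE), 0)
})

test_that("genotype delta matrix recovers a masked injected effect", {
  em <- single_effect_model(-1.0)
  sm <- sort_model()
  set.seed(300)
  lib <- sample_motif_library(6000, em, "WT")
  lib <- lib[!duplicated(lib$motif), ]
  wt <- simulate_motif_counts(lib, sm, 200)
  lib_ko <- lib
  lib_ko$true_stability <- true_stability(lib$motif, em, "CLPS_KO")
  ko <- simulate_motif_counts(lib_ko, sm, 200)
  d <- delta_matrix(mean_psi_matrix(build_database(wt)),
                    mean_psi_matrix(build_database(ko)))
  expect_equal(d["F", "P1"], -1, tolerance = 0.05)
  off_target <- unclass(d)
  off_target["F", "P1"] <- NA
  expect_lt(max(abs(off_target), na.rm = TRUE), 0.1)
})

test_that("conditional matrices partition the database over P1", {
  set.seed(15)
  motifs <- unique(random_motifs(500))
  db <- db_from_counts(motifs,
                       as.vector(rmultinom(length(motifs), 40, rep(0.25, 4))))
  total_n <- 0L
  for (res in AA_ALPHABET) {
    cm <- conditional_matrix(db, 1, res)
    expect_equal(colnames(cm), paste0("P", 2:5))
    n_here <- attr(cm, "n")[, 1]
    total_n <- total_n + sum(n_here)
  }
  expect_equal(total_n, nrow(db))  # P1 conditions partition the motifs
  expect_true(all(is.na(conditional_matrix(
    db_from_counts("AAAAA", c(1, 1, 1, 1)), 1, "W"))))
})

test_that("conditional matrix exposes an injected pair interaction", {
  em <- effect_model(baseline = 3.5,
                     pair_effects = data.frame(residue1 = "C", position1 = 1L,
                                               residue2 = "E", position2 = 3L,
                                               value = -0.8,
                                               dependency = "none"))
  sm <- sort_model()
  set.seed(301)
  lib <- sample_motif_library(8000, em, "WT")
  lib <- lib[!duplicated(lib$motif), ]
  db <- build_database(simulate_motif_counts(lib, sm, 200))
  cm <- conditional_matrix(db, 1, "C")
  background <- unclass(cm)[setdiff(AA_ALPHABET, "E"), "P3"]
  expect_lt(cm["E", "P3"], min(background, na.rm = TRUE) - 0.5)
})

test_that("net charge counts R/K as +1, D/E as -1 and H as neutral", {
  expect_equal(net_charge("FDEDE"), -4)
  expect_equal(net_charge("FRKAA"), 2)
  expect_equal(net_charge("AAAAA"), 0)
  expect_equal(net_charge("HHHHH"), 0)
  expect_equal(net_charge("RKDE"), 0)
  # position mask: P2-P5 only
  expect_equal(net_charge("RAAAD", positions = 2:5), -1)
  expect_equal(net_charge(c("FDEDE", "FRKAA")), c(-4, 2))
})

test_that("group_count tallies residue-set membership at masked positions", {
  expect_equal(group_count("FFAAA", "Bulky", positions = 1:2), 2)
  expect_equal(group_count("LGSGS", c("G", "S"), positions = 2:5), 4)
  expect_equal(group_count("FFAAA", AA_ALPHABET), 5)
  expect_equal(group_count(c("FFAAA", "DDDDD"), "Negative"), c(0, 5))
  expect_equal(group_count("FWYHA", "Aromatic", positions = 1:5), 4)
})

test_that("canonical residue groups match their definitions", {
  expect_setequal(AA_GROUPS$Negative, c("D", "E"))
  expect_setequal(AA_GROUPS$Positive, c("R", "K"))
  expect_setequal(AA_GROUPS$Hydrophobic, strsplit("AVILMFWY", "")[[1]])
  expect_setequal(AA_GROUPS$Flexible, c("G", "S", "D", "N"))
  expect_setequal(AA_GROUPS$CanonicalDestabilizing,
                  strsplit("FLWYRK", "")[[1]])
  expect_true(all(unlist(AA_GROUPS) %in% AA_ALPHABET))
})

test_that("enrichment logo is 1 for subset == background and normalizes", {
  set.seed(16)
  motifs <- unique(random_motifs(400))
  db <- db_from_counts(motifs, rep(c(0, 0, 1, 3), length(motifs)))
  logo <- enrichment_logo(db, db)
  expect_equal(unname(unclass(logo)[!is.na(logo)]),
               rep(1, sum(!is.na(logo))))

  # all-"FAAAA" subset over a balanced background: (F,1) fold = 20
  balanced <- db_from_counts(
    paste0(AA_ALPHABET, "AAAA"), rep(c(1, 1, 1, 1), 20))
  subset <- db_from_counts("FAAAA", c(1, 1, 1, 1))
  fold <- enrichment_logo(subset, balanced)
  expect_equal(fold["F", "P1"], 20)

  # background-frequency-weighted mean of folds is 1 at every position
  freq_bg <- sapply(1:5, function(p)
    as.numeric(table(factor(substr(db$motif, p, p), levels = AA_ALPHABET))) /
      nrow(db))
  sub2 <- db[db$psi > 3, , drop = FALSE]
  class(sub2) <- class(db)
  logo2 <- unclass(enrichment_logo(sub2, db))
  logo2[is.na(logo2)] <- 0
  expect_equal(unname(colSums(logo2 * freq_bg)), rep(1, 5), tolerance = 1e-12)
})

test_that("P1/P2 enrichment spans 400 pairs and is 0 for balanced pairs", {
  pairs <- c(outer(AA_ALPHABET, AA_ALPHABET, paste0))
  # one stable (psi 4) and one unstable (psi 1) motif per P1/P2 pair,
  # distinguished at P3 so motifs stay unique
  motifs <- c(paste0(pairs, "AAA"), paste0(pairs, "CAA"))
  counts <- c(rep(c(0, 0, 0, 10), length(pairs)),
              rep(c(10, 0, 0, 0), length(pairs)))
  both <- db_from_counts(motifs, counts)
  e <- p1p2_enrichment(both)
  expect_equal(dim(e), c(20, 20))
  expect_equal(length(e), 400)
  expect_equal(unname(e[!is.na(e)]), rep(0, 400))

  dest <- AA_GROUPS$CanonicalDestabilizing
  expect_equal(sum(outer(rownames(e) %in% dest, colnames(e) %in% dest)), 36)

  # a stratum-empty database is rejected
  flat <- db_from_counts(paste0(pairs[1:10], "AAA"),
                         rep(c(0, 5, 5, 0), 10))
  expect_error(p1p2_enrichment(flat), "stratum")
})

test_that("MetAP comparison flags windows whose exposure destabilizes", {
  # null model: position-shift changes nothing
  null_db <- db_from_counts(c("MFAAA", "FAAAA", "MAAAA", "AAAAA"),
                            rep(c(0, 0, 5, 5), 4))
  res <- metap_comparison(null_db)
  expect_lte(nrow(res), 20)
  expect_equal(res$diff[res$residue == "F"], 0)

  # (F,1) destabilizes: F-led windows lose stability once exposed at P1.
  # A dense sub-alphabet library guarantees every MXYYY window also occurs
  # as an XYYYZ prefix.
  em <- single_effect_model(-1.0)
  sm <- sort_model()
  sub_aa <- c("A", "F", "M", "V")
  grid <- expand.grid(rep(list(sub_aa), 5), stringsAsFactors = FALSE)
  motifs <- do.call(paste0, grid)
  truth <- data.frame(motif = motifs,
                      true_stability = true_stability(motifs, em, "WT"))
  set.seed(302)
  db <- build_database(simulate_motif_counts(truth, sm, 200))
  cmp <- metap_comparison(db)
  f <- cmp[cmp$residue == "F", ]
  expect_gt(f$diff, 0.8)            # MFYYY stabler than FYYYZ
  a <- cmp[cmp$residue == "A", ]
  expect_lt(abs(a$diff), 0.1)       # neutral windows unchanged
})

test_that("bulky-by-acidic crosstab is referenced to the (0,0) cell", {
  # -0.5 per P2-P5 bulky residue from a 3.5 baseline keeps true scores on
  # fixed points of the sorting map, so cell means recover the additive sum
  em <- effect_model(baseline = 3.5, residue_effects =
    transform(expand.grid(residue = c("F", "L", "W", "Y"), position = 2:5,
                          stringsAsFactors = FALSE),
              value = -0.5, dependency = "none"))
  sm <- sort_model()
  set.seed(303)
  lib <- sample_motif_library(10000, em, "WT")
  lib <- lib[!duplicated(lib$motif), ]
  db <- build_database(simulate_motif_counts(lib, sm, 200))
  ct <- crosstab_bulky_negative(db)
  expect_equal(ct["0", "0"], 0)
  expect_equal(ct["1", "0"], -0.5, tolerance = 0.05)
  expect_equal(ct["2", "0"], -1.0, tolerance = 0.08)
  expect_equal(sum(attr(ct, "n")),
               sum(!substr(db$motif, 1, 1) %in%
                     AA_GROUPS$CanonicalDestabilizing))
})

test_that("matrix TSV export preserves labels and values", {
  db <- db_from_counts(c("FAAAA", "CAAAA"), c(0, 100, 0, 0, 0, 0, 0, 100))
  m <- mean_psi_matrix(db)
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  back <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                     check.names = FALSE)
  expect_equal(back$key, AA_ALPHABET)
  expect_equal(back$P1[back$key == "F"], 2)
})
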