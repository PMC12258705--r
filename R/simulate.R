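#' Simulation configuration for the sorted-library generator
#'
#' @param n_motifs Number of distinct NNK library members to draw (DNA
#'   level; stop-containing draws are discarded from the cloned library).
#' @param abundance_dispersion Log-normal sdlog of member abundance
#'   (NNK cloning yields uneven representation). Default 0.5.
#' @param substitution_error_rate Per-base substitution error rate in
#'   \[0, 0.1\]. Default 0.001. Indels are not modelled: downstream
#'   filtering is exact-match, so indel reads would simply be discarded.
#' @param seed Integer seed; identical seeds give byte-identical FASTQ.
#' @param barcodes Named 3-nt barcode per bin (all distinct).
#' @param template An [amplicon_template()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_motifs = 2000,
                       abundance_dispersion = 0.5,
                       substitution_error_rate = 0.001,
                       seed = 1L,
                       barcodes = default_barcodes(),
                       template = default_template()) {
  stopifnot(substitution_error_rate >= 0, substitution_error_rate <= 0.1,
            length(barcodes) == 4, all(nchar(barcodes) == 3),
            !anyDuplicated(barcodes),
            inherits(template, "amplicon_template"))
  structure(list(n_motifs = n_motifs,
                 abundance_dispersion = abundance_dispersion,
                 substitution_error_rate = substitution_error_rate,
                 seed = as.integer(seed),
                 barcodes = barcodes,
                 template = template),
            class = "sim_config")
}

#' Sample an NNK motif library with abundances and true stabilities
#'
#' Draws distinct 15-nt NNK sequences (stop-containing draws discarded, as
#' those members produce no fluorescent reporter), assigns each a
#' log-normal abundance, and computes the amino-acid motif and its true
#' stability under the effect model. Several DNA members may encode the
#' same motif, as in a real NNK library.
#'
#' @param n_motifs Number of distinct DNA members to retain.
#' @param model An [effect_model()].
#' @param genotype Host genotype.
#' @param abundance_dispersion Log-normal sdlog for member abundance.
#' @return Data frame with columns `dna`, `motif`, `abundance`,
#'   `true_stability`.
#' @export
sample_motif_library <- function(n_motifs, model, genotype = "WT",
                                 abundance_dispersion = 0.5) {
  stopifnot(n_motifs >= 1)
  dna <- character(0)
  while (length(dna) < n_motifs) {
    batch <- vapply(seq_len(ceiling(1.2 * (n_motifs - length(dna))) + 8),
                    function(i) sample_nnk_codons(5L), character(1))
    aa <- translate_regions(batch)
    dna <- unique(c(dna, batch[!is.na(aa)]))
  }
  dna <- dna[seq_len(n_motifs)]
  motif <- translate_regions(dna)
  abundance <- stats::rlnorm(n_motifs, meanlog = 0, sdlog = abundance_dispersion)
  data.frame(dna = dna, motif = motif, abundance = abundance,
             true_stability = true_stability(motif, model, genotype),
             stringsAsFactors = FALSE)
}

#' Per-motif bin counts by direct multinomial sampling
#'
#' Count-level fast path past FASTQ generation: each motif receives
#' `reads_per_motif` reads distributed over the four bins by a multinomial
#' draw with its [bin_probabilities()]. The raw-mode PSI of these counts is
#' a consistent estimator of the motif's expected PSI.
#'
#' @param truth Data frame with columns `motif` and `true_stability`
#'   (e.g. from [simulation_truth()] or [sample_motif_library()]).
#' @param sort A [sort_model()].
#' @param reads_per_motif Reads allocated to every motif.
#' @return `truth` with added columns `count_b1`..`count_b4`.
#' @export
simulate_motif_counts <- function(truth, sort, reads_per_motif = 200) {
  stopifnot(inherits(sort, "sort_model"), reads_per_motif >= 1)
  p <- bin_probabilities(truth$true_stability, sort)
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)
  n <- nrow(p)
  # vectorized multinomial via sequential binomial thinning
  c1 <- stats::rbinom(n, reads_per_motif, p[, 1])
  r2 <- reads_per_motif - c1
  q2 <- ifelse(p[, 1] < 1, p[, 2] / (1 - p[, 1]), 0)
  c2 <- stats::rbinom(n, r2, pmin(1, q2))
  r3 <- r2 - c2
  q3 <- ifelse(p[, 1] + p[, 2] < 1, p[, 3] / (1 - p[, 1] - p[, 2]), 0)
  c3 <- stats::rbinom(n, r3, pmin(1, pmax(0, q3)))
  c4 <- r3 - c3
  out <- truth
  out$count_b1 <- c1; out$count_b2 <- c2; out$count_b3 <- c3; out$count_b4 <- c4
  out
}

#' Aggregate a DNA-level library into motif-level ground truth
#'
#' @param library Data frame from [sample_motif_library()].
#' @param sort A [sort_model()] used to compute each motif's expected PSI.
#' @return Data frame with columns `motif`, `true_stability`,
#'   `expected_psi`, `abundance` (summed over DNA members), sorted by motif.
#' @export
simulation_truth <- function(library, sort) {
  agg <- stats::aggregate(library["abundance"], by = library[c("motif")], FUN = sum)
  ts <- library$true_stability[!duplicated(library$motif)]
  names(ts) <- library$motif[!duplicated(library$motif)]
  agg$true_stability <- unname(ts[agg$motif])
  agg$expected_psi <- expected_psi(bin_probabilities(agg$true_stability, sort))
  agg <- agg[order(agg$motif), c("motif", "true_stability", "expected_psi",
                                 "abundance")]
  rownames(agg) <- NULL
  agg
}

# Apply i.i.d. substitution errors to a character vector of reads.
apply_substitution_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  len <- nchar(reads[1])
  hits <- which(stats::runif(length(reads) * len) < rate)
  if (!length(hits)) return(reads)
  bases <- c("A", "C", "G", "T")
  ridx <- (hits - 1L) %/% len + 1L
  pos <- (hits - 1L) %% len + 1L
  for (i in seq_along(hits)) {
    old <- substr(reads[ridx[i]], pos[i], pos[i])
    new <- sample(setdiff(bases, old), 1L)
    substr(reads[ridx[i]], pos[i], pos[i]) <- new
  }
  reads
}

# Write a plain-text FASTQ file with constant Phred+33 quality 'I'.
write_fastq <- function(reads, ids, path) {
  if (length(reads)) {
    qual <- strrep("I", nchar(reads))
    lines <- as.vector(rbind(paste0("@", ids), reads, "+", qual))
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate per-bin amplicon FASTQ reads for a sorted library
#'
#' End-to-end generator: draws an NNK library, sorts it, and writes one
#' FASTQ per bin plus a ground-truth table. Reads are allocated by a
#' single multinomial draw over all (member, bin) pairs with weights
#' `abundance * P(bin | true stability)` and total budget
#' `sum(sort$depths)`: realized per-bin read counts therefore track the
#' population's bin occupancy, as in a screen where each sorted pool is
#' sequenced in proportion to its cell count — the regime in which the
#' raw read-fraction PSI is a consistent estimator. Bins into which no
#' cells sort receive no reads. Each read is the assembled amplicon with
#' i.i.d. substitution errors.
#'
#' @param config A [sim_config()].
#' @param effects An [effect_model()].
#' @param sort A [sort_model()]; `sum(sort$depths)` sets the total read
#'   budget.
#' @param genotype Host genotype.
#' @param outdir Output directory (created if missing). Files are named
#'   `<genotype>_B1.fastq` .. `_B4.fastq` and `<genotype>_truth.tsv`.
#' @return Invisibly, a list with `truth` (data frame), `files` (named
#'   FASTQ paths), `truth_file`, and `allocation` (member x bin read counts).
#' @export
simulate_sorted_reads <- function(config, effects, sort, genotype = "WT",
                                  outdir = tempfile("simreads")) {
  stopifnot(inherits(config, "sim_config"), inherits(effects, "effect_model"),
            inherits(sort, "sort_model"))
  genotype <- match.arg(genotype, GENOTYPES)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  lib <- sample_motif_library(config$n_motifs, effects, genotype,
                              config$abundance_dispersion)
  if (sum(sort$depths) < nrow(lib)) {
    warning("total bin depth (", sum(sort$depths),
            ") is smaller than the library size (", nrow(lib),
            "); many members will be unobserved")
  }
  p <- bin_probabilities(lib$true_stability, sort)
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)

  w <- lib$abundance * p  # (member, bin) sorting weights
  total <- sum(sort$depths)
  alloc <- matrix(as.integer(stats::rmultinom(1, total, prob = as.vector(w))),
                  nrow(lib), 4, dimnames = list(NULL, paste0("B", 1:4)))
  files <- character(4)
  names(files) <- paste0("B", 1:4)
  for (b in 1:4) {
    member <- rep(seq_len(nrow(lib)), alloc[, b])
    reads <- assemble_reads(lib$dna[member], config$barcodes[b], config$template)
    reads <- apply_substitution_errors(reads, config$substitution_error_rate)
    ids <- sprintf("sim_%s_B%d_%07d", genotype, b, seq_along(reads))
    files[b] <- file.path(outdir, sprintf("%s_B%d.fastq", genotype, b))
    write_fastq(reads, ids, files[b])
  }

  truth <- simulation_truth(lib, sort)
  truth_file <- file.path(outdir, sprintf("%s_truth.tsv", genotype))
  utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(truth = truth, files = files, truth_file = truth_file,
                 allocation = alloc, library = lib))
}
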