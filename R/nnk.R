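#' Enumerate the 32 NNK codons
#'
#' NNK degenerate codons have N = A/C/G/T at the first two positions and
#' K = G/T at the third, giving 4 x 4 x 2 = 32 codons that together encode
#' all 20 standard amino acids plus the single stop TAG.
#'
#' @return Character vector of the 32 NNK codons.
#' @export
nnk_codons <- function() {
  n <- c("A", "C", "G", "T")
  k <- c("G", "T")
  grid <- expand.grid(p3 = k, p2 = n, p1 = n, stringsAsFactors = FALSE)
  sort(paste0(grid$p1, grid$p2, grid$p3))
}

#' Amino acids encodable by a single NNK codon
#'
#' Translates all 32 NNK codons with the standard genetic code and returns
#' the distinct non-stop residues (all 20 standard amino acids).
#'
#' @return Character vector of distinct amino acids (length 20).
#' @export
nnk_amino_acids <- function() {
  aa <- translate_codons(nnk_codons())
  sort(unique(aa[aa != "*"]))
}

#' Size of the NNK-accessible five-residue motif space
#'
#' Counts, without materializing, the number of distinct 5-mers over the
#' amino acids encodable by an NNK codon (stop excluded): 20^5 = 3,200,000.
#'
#' @return Integer-valued numeric scalar.
#' @export
nnk_space_size <- function() {
  length(nnk_amino_acids())^5
}

#' Sample NNK codons
#'
#' Draws `n_codons` codons position-wise: positions 1-2 uniform over
#' A/C/G/T, position 3 uniform over G/T, mirroring hand-mixed NNK primer
#' synthesis. Stop-containing codons (TAG) are *not* rejected; they occur
#' at their natural 1/32 frequency. Uses the current R random number state.
#'
#' @param n_codons Number of codons to draw (>= 1).
#' @return A single DNA string of length `3 * n_codons`.
#' @export
sample_nnk_codons <- function(n_codons) {
  stopifnot(is.numeric(n_codons), length(n_codons) == 1, n_codons >= 1)
  n_codons <- as.integer(n_codons)
  p12 <- sample(c("A", "C", "G", "T"), 2L * n_codons, replace = TRUE)
  p3 <- sample(c("G", "T"), n_codons, replace = TRUE)
  codons <- paste0(p12[seq(1, 2L * n_codons, by = 2)],
                   p12[seq(2, 2L * n_codons, by = 2)],
                   p3)
  paste(codons, collapse = "")
}

# Translate a vector of codons with the standard genetic code ("*" = stop,
# NA for codons containing non-ACGT characters).
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

#' Enumerate all five-residue motifs
#'
#' Materializes the full 20^5 = 3.2M motif space. This allocates several
#' hundred MB of strings; `full_space = TRUE` must be passed explicitly as
#' a guard-rail.
#'
#' @param full_space Must be `TRUE` to confirm the 3.2M-row enumeration.
#' @return Character vector of all 3,200,000 motifs, lexicographic order.
#' @export
enumerate_motifs <- function(full_space = FALSE) {
  if (!isTRUE(full_space)) {
    stop("enumerate_motifs() materializes all ", format(nnk_space_size(),
         big.mark = ","), " motifs; call with full_space = TRUE to confirm")
  }
  aa <- AA_ALPHABET
  grid <- expand.grid(p5 = aa, p4 = aa, p3 = aa, p2 = aa, p1 = aa,
                      stringsAsFactors = FALSE)
  paste0(grid$p1, grid$p2, grid$p3, grid$p4, grid$p5)
}
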