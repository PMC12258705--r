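#' Demultiplex reads by their 3-nt bin barcode
#'
#' Exact match at the barcode slot assigns the read to a bin; any mismatch
#' (including ambiguous bases or reads too short to cover the slot) is a
#' `barcode-mismatch` rejection.
#'
#' @param reads Character vector of read sequences.
#' @param template An [amplicon_template()].
#' @param barcode_map Named character vector bin -> 3-nt barcode
#'   (e.g. [default_barcodes()]).
#' @return Character vector of bin ids, `NA` for rejected reads.
#' @export
demultiplex <- function(reads, template, barcode_map = default_barcodes()) {
  stopifnot(inherits(template, "amplicon_template"),
            length(barcode_map) == 4, all(nchar(barcode_map) == 3),
            !anyDuplicated(barcode_map))
  off <- template$barcode_offset
  slot <- substr(reads, off + 1L, off + 3L)
  slot[nchar(reads) < off + 3L] <- NA_character_
  bins <- names(barcode_map)[match(slot, barcode_map)]
  bins
}

#' Validate the consensus sequence of reads
#'
#' A read passes iff every base outside the 3-nt barcode slot and the
#' 15-nt mutagenized region equals the template exactly (zero-mismatch
#' policy; the screen excluded any read varying from the consensus).
#' A length mismatch fails. Ambiguous bases (N) anywhere in the checked
#' consensus fail.
#'
#' @inheritParams demultiplex
#' @param max_mismatch Mismatch budget for the checked consensus;
#'   default 0 (the policy actually applied).
#' @return Logical vector, `TRUE` for reads that pass.
#' @export
validate_consensus <- function(reads, template, max_mismatch = 0L) {
  stopifnot(inherits(template, "amplicon_template"))
  up <- template$upstream_consensus
  off <- template$barcode_offset
  u <- nchar(up)
  expected_len <- template_read_length(template)

  prefix <- substr(up, 1L, off)
  suffix <- substr(up, off + 4L, u)
  tail_consensus <- paste0(template$anchor, template$downstream_consensus)

  parts <- rbind(
    mismatch_count(substr(reads, 1L, off), prefix),
    mismatch_count(substr(reads, off + 4L, u), suffix),
    mismatch_count(substr(reads, u + 16L, expected_len), tail_consensus)
  )
  ok <- nchar(reads) == expected_len & colSums(parts) <= max_mismatch
  ok
}

# Count character mismatches between equal-length strings (vectorized over
# `x`); differing lengths count as Inf.
mismatch_count <- function(x, ref) {
  n <- nchar(ref)
  out <- rep(Inf, length(x))
  same_len <- nchar(x) == n
  if (n == 0L) {
    out[same_len] <- 0
    return(out)
  }
  if (any(same_len)) {
    xm <- matrix(unlist(strsplit(x[same_len], "", fixed = TRUE)),
                 ncol = n, byrow = TRUE)
    rm_ <- strsplit(ref, "", fixed = TRUE)[[1]]
    out[same_len] <- rowSums(xm != rep(rm_, each = sum(same_len)))
  }
  out
}

#' Extract the mutagenized region from reads
#'
#' Locates the first exact occurrence of the 15-nt anchor and returns the
#' 15 nt immediately 5' of it. Reads lacking the anchor, or with fewer
#' than 15 nt preceding it, are rejected (`no-anchor`).
#'
#' @inheritParams demultiplex
#' @return Character vector of 15-nt regions, `NA` for rejected reads.
#' @export
extract_region <- function(reads, template) {
  stopifnot(inherits(template, "amplicon_template"))
  pos <- regexpr(template$anchor, reads, fixed = TRUE)
  region <- ifelse(pos >= 16L, substr(reads, pos - 15L, pos - 1L),
                   NA_character_)
  region
}

#' Translate mutagenized regions into five-residue motifs
#'
#' Translates five codons with the standard genetic code. Regions
#' containing a stop codon (TAG, TAA, TGA) or an ambiguous base (N) in any
#' codon are rejected, as are regions of the wrong length.
#'
#' @param regions Character vector of 15-nt DNA strings (bases A/C/G/T/N).
#' @return Character vector of 5-residue motifs, `NA` for rejected regions.
#' @export
translate_regions <- function(regions) {
  out <- rep(NA_character_, length(regions))
  ok <- !is.na(regions) & nchar(regions) == 15L
  if (!any(ok)) return(out)
  cod <- vapply(1:5, function(i) substr(regions[ok], 3L * i - 2L, 3L * i),
                character(sum(ok)))
  cod <- matrix(cod, ncol = 5)
  aa <- matrix(translate_codons(cod), ncol = 5)
  keep <- rowSums(is.na(aa) | aa == "*") == 0
  out[ok][keep] <- apply(aa[keep, , drop = FALSE], 1, paste, collapse = "")
  out
}

# Rejection reason for regions translate_regions() refused: scans codons
# left to right; the first failing codon's rule wins ("stop-codon" for
# TAG/TAA/TGA, "ambiguous-base" for codons containing N or other non-ACGT).
translation_reject_reason <- function(regions) {
  stops <- c("TAG", "TAA", "TGA")
  vapply(regions, function(r) {
    if (is.na(r) || nchar(r) != 15L) return("ambiguous-base")
    for (i in 1:5) {
      codon <- substr(r, 3L * i - 2L, 3L * i)
      if (codon %in% stops) return("stop-codon")
      if (grepl("[^ACGT]", codon)) return("ambiguous-base")
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# Read sequences from FASTQ (plain or gzip) as a character vector.
read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Count five-residue motifs per sorted bin
#'
#' Applies the full read-filtering cascade in fixed order — demultiplex,
#' consensus validation, region extraction, translation — and tallies kept
#' motifs per bin. Each read is discarded by exactly one rule (first
#' failure wins), so the discard ledger plus kept reads partition the
#' input.
#'
#' @param reads Character vector of read sequences, or a character vector
#'   of FASTQ file paths (plain or gzip) whose reads are pooled.
#' @param template An [amplicon_template()].
#' @param barcode_map Named character vector bin -> barcode.
#' @param genotype Label stored with the table.
#' @return An object of class `bin_count_table`: list with `genotype`,
#'   `counts` (data frame `motif`, `count_b1`..`count_b4`, lexicographic),
#'   `bin_totals`, `ledger` (named rejection counts plus `kept`), `n_raw`.
#' @export
count_motifs <- function(reads, template = default_template(),
                         barcode_map = default_barcodes(),
                         genotype = "WT") {
  if (length(reads) && all(file.exists(reads)) && !any(grepl("^[ACGTN]+$", reads))) {
    reads <- unlist(lapply(reads, read_fastq_seqs), use.names = FALSE)
  }
  n_raw <- length(reads)
  ledger <- c(`barcode-mismatch` = 0L, `consensus-mismatch` = 0L,
              `no-anchor` = 0L, `stop-codon` = 0L, `ambiguous-base` = 0L,
              kept = 0L)

  bins <- demultiplex(reads, template, barcode_map)
  ledger["barcode-mismatch"] <- sum(is.na(bins))
  keep <- !is.na(bins)
  reads <- reads[keep]; bins <- bins[keep]

  ok <- validate_consensus(reads, template)
  ledger["consensus-mismatch"] <- sum(!ok)
  reads <- reads[ok]; bins <- bins[ok]

  region <- extract_region(reads, template)
  ledger["no-anchor"] <- sum(is.na(region))
  keep <- !is.na(region)
  region <- region[keep]; bins <- bins[keep]

  motif <- translate_regions(region)
  bad <- is.na(motif)
  if (any(bad)) {
    reason <- translation_reject_reason(region[bad])
    ledger["stop-codon"] <- sum(reason == "stop-codon")
    ledger["ambiguous-base"] <- sum(reason == "ambiguous-base")
  }
  motif <- motif[!bad]; bins <- bins[!bad]
  ledger["kept"] <- length(motif)

  bin_levels <- names(barcode_map)
  if (length(motif)) {
    tab <- table(motif = motif, bin = factor(bins, levels = bin_levels))
    counts <- data.frame(motif = rownames(tab),
                         count_b1 = as.integer(tab[, 1]),
                         count_b2 = as.integer(tab[, 2]),
                         count_b3 = as.integer(tab[, 3]),
                         count_b4 = as.integer(tab[, 4]),
                         stringsAsFactors = FALSE)
    counts <- counts[order(counts$motif), , drop = FALSE]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(motif = character(), count_b1 = integer(),
                         count_b2 = integer(), count_b3 = integer(),
                         count_b4 = integer(), stringsAsFactors = FALSE)
  }
  bin_totals <- colSums(counts[, paste0("count_b", 1:4), drop = FALSE])
  names(bin_totals) <- bin_levels
  structure(list(genotype = genotype, counts = counts,
                 bin_totals = bin_totals, ledger = ledger, n_raw = n_raw),
            class = "bin_count_table")
}

#' @export
print.bin_count_table <- function(x, ...) {
  cat("bin_count_table:", x$genotype, "-", nrow(x$counts), "motifs from",
      x$n_raw, "reads\n")
  cat("  bin totals:", paste(names(x$bin_totals), x$bin_totals,
                             collapse = ", "), "\n")
  cat("  ledger:", paste(names(x$ledger), x$ledger, collapse = ", "), "\n")
  invisible(x)
}

#' Write a bin-count table and its discard ledger to TSV
#'
#' @param x A `bin_count_table`.
#' @param path Output path for the counts TSV; the ledger is written next
#'   to it with suffix `.ledger.tsv`.
#' @return Invisibly, the counts path.
#' @export
write_bin_counts <- function(x, path) {
  stopifnot(inherits(x, "bin_count_table"))
  utils::write.table(x$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ledger <- data.frame(rule = names(x$ledger), reads = as.integer(x$ledger))
  utils::write.table(ledger, paste0(sub("\\.tsv$", "", path), ".ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
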