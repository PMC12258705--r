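#' Amplicon read architecture
#'
#' Describes the fixed layout of a sequencing read from the sorted-library
#' amplicon: a 5' consensus that carries a 3-nt bin barcode at a declared
#' offset, the 15-nt mutagenized region (five NNK codons, P1-P5), a 15-nt
#' anchor immediately 3' of the region used to locate it, and a 3'
#' consensus. All offsets are 0-based.
#'
#' @param upstream_consensus DNA string 5' of the mutagenized region; the
#'   3-nt barcode slot within it is given by `barcode_offset` (the slot
#'   bases in this string are placeholders, conventionally `NNN`).
#' @param barcode_offset 0-based offset of the barcode slot within
#'   `upstream_consensus`.
#' @param anchor 15-nt DNA string immediately 3' of the mutagenized region.
#'   Must not occur within `upstream_consensus` so that first-match
#'   extraction is unambiguous.
#' @param downstream_consensus DNA string 3' of the anchor.
#' @param region_length Length of the mutagenized region; fixed at 15.
#' @return An object of class `amplicon_template`.
#' @export
amplicon_template <- function(upstream_consensus, barcode_offset, anchor,
                              downstream_consensus, region_length = 15L) {
  stopifnot(is.character(upstream_consensus), length(upstream_consensus) == 1,
            is.character(anchor), nchar(anchor) == 15L,
            region_length == 15L,
            barcode_offset >= 0,
            barcode_offset + 3L <= nchar(upstream_consensus))
  if (grepl(anchor, upstream_consensus, fixed = TRUE)) {
    stop("anchor occurs in upstream_consensus; first-match region ",
         "extraction would be ambiguous")
  }
  structure(list(upstream_consensus = upstream_consensus,
                 barcode_offset = as.integer(barcode_offset),
                 region_length = 15L,
                 anchor = anchor,
                 downstream_consensus = downstream_consensus),
            class = "amplicon_template")
}

#' Default amplicon template
#'
#' A compact read architecture modelled on the screen's reporter fusion:
#' a sequencing-adapter-like prefix, the 3-nt bin barcode, the end of the
#' ubiquitin leader, the 15-nt mutagenized region, a 15-nt anchor encoding
#' the ISDFI template residues downstream of P5, and the start of the sfGFP
#' coding sequence. Total read length 78 nt.
#'
#' @return An [amplicon_template()].
#' @export
default_template <- function() {
  amplicon_template(
    upstream_consensus = paste0("ACACGACGCTCTTCC", "NNN", "ACCCTGCGTGGTGGT"),
    barcode_offset = 15L,
    anchor = "ATTAGCGATTTTATC",
    downstream_consensus = "AGCAAAGGAGAAGAA"
  )
}

#' Default per-bin barcodes
#'
#' Four distinct 3-nt demultiplexing barcodes, one per sorted bin.
#'
#' @return Named character vector `c(B1 = ..., ..., B4 = ...)`.
#' @export
default_barcodes <- function() {
  c(B1 = "ACT", B2 = "CAG", B3 = "GTC", B4 = "TGA")
}

# Total read length implied by a template.
template_read_length <- function(template) {
  nchar(template$upstream_consensus) + template$region_length +
    nchar(template$anchor) + nchar(template$downstream_consensus)
}

# Assemble error-free reads: upstream (barcode substituted) + region +
# anchor + downstream. `regions` is a vector of 15-nt DNA strings.
assemble_reads <- function(regions, barcode, template) {
  if (!length(regions)) return(character(0))
  up <- template$upstream_consensus
  substr(up, template$barcode_offset + 1L, template$barcode_offset + 3L) <- barcode
  paste0(up, regions, template$anchor, template$downstream_consensus)
}
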