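template <- default_template()
barcodes <- default_barcodes()

# One error-free read per bin for a given 15-nt region.
make_read <- function(region, bin = "B1") {
  psifive:::assemble_reads(region, barcodes[[bin]], template)
}

test_that("demultiplex is an exact barcode lookup", {
  region <- "TTTCTGTTTGTGCAG"
  reads <- vapply(names(barcodes), function(b) make_read(region, b), "")
  expect_equal(unname(demultiplex(reads, template, barcodes)),
               names(barcodes))

  bad <- reads[1]
  substr(bad, template$barcode_offset + 2L, template$barcode_offset + 2L) <- "N"
  expect_true(is.na(demultiplex(bad, template, barcodes)))
  # read truncated before the slot end
  expect_true(is.na(demultiplex(substr(reads[1], 1, 10), template, barcodes)))
})

test_that("consensus validation enforces the zero-mismatch policy", {
  region <- "TTTCTGTTTGTGCAG"
  read <- make_read(region, "B2")
  expect_true(validate_consensus(read, template))

  flank_mut <- read
  substr(flank_mut, nchar(read), nchar(read)) <- "A"
  if (substr(read, nchar(read), nchar(read)) == "A") {
    substr(flank_mut, nchar(read), nchar(read)) <- "C"
  }
  expect_false(validate_consensus(flank_mut, template))

  # substitutions inside the mutagenized region are allowed
  region_mut <- read
  u <- nchar(template$upstream_consensus)
  substr(region_mut, u + 1L, u + 1L) <- "G"
  expect_true(validate_consensus(region_mut, template))
  # ... and inside the barcode slot
  bc_mut <- read
  substr(bc_mut, template$barcode_offset + 1L, template$barcode_offset + 3L) <- "AAA"
  expect_true(validate_consensus(bc_mut, template))

  # length mismatch fails
  expect_false(validate_consensus(paste0(read, "A"), template))
  # an N in the checked consensus fails
  n_mut <- read
  substr(n_mut, 1L, 1L) <- "N"
  expect_false(validate_consensus(n_mut, template))
  # a mismatch budget can be opened explicitly
  expect_true(validate_consensus(flank_mut, template, max_mismatch = 1))
})

test_that("region extraction finds the first exact anchor occurrence", {
  region <- "ATGATGATGATGATG"
  read <- make_read(region)
  expect_equal(extract_region(read, template), region)

  no_anchor <- read
  pos <- regexpr(template$anchor, read, fixed = TRUE)
  substr(no_anchor, pos, pos) <- if (substr(read, pos, pos) == "A") "C" else "A"
  expect_true(is.na(extract_region(no_anchor, template)))

  # anchor too close to the read start: fewer than 15 preceding nt
  short <- paste0("ACGTACGTACGT", template$anchor)
  expect_true(is.na(extract_region(short, template)))
  expect_equal(extract_region(paste0(strrep("A", 12), "TTT", template$anchor),
                              template),
               paste0(strrep("A", 12), "TTT"))
})

test_that("templates with ambiguous anchor placement are rejected", {
  expect_error(
    amplicon_template(upstream_consensus = paste0("ATTAGCGATTTTATC", "NNN"),
                      barcode_offset = 15, anchor = "ATTAGCGATTTTATC",
                      downstream_consensus = "AAA"),
    "ambiguous")
})

test_that("translation follows the standard code and rejects stops and Ns", {
  expect_equal(translate_regions("TTTCTGTTTGTGCAG"), "FLFVQ")
  expect_equal(translate_regions("ATGATGATGATGATG"), "MMMMM")
  # stop codons TAG, TAA, TGA anywhere in the region reject the read
  expect_true(is.na(translate_regions("TTTCTGTAGGTGCAG")))
  expect_true(is.na(translate_regions("TAATTGTTGGTGCAG")))
  expect_true(is.na(translate_regions("TTTCTGTTTGTGTGA")))
  expect_true(is.na(translate_regions("TTNCTGTTTGTGCAG")))
  expect_true(is.na(translate_regions("TTTCTG")))
  expect_equal(psifive:::translation_reject_reason("TTTCTGTAGGTGCAG"),
               "stop-codon")
  expect_equal(psifive:::translation_reject_reason("TTNCTGTAGGTGCAG"),
               "ambiguous-base")  # first failing codon wins
})

test_that("count_motifs is lossless on error-free simulator output", {
  cfg <- sim_config(n_motifs = 60, seed = 21, substitution_error_rate = 0)
  em <- effect_model_preset()
  sm <- sort_model(total_reads = 6000)
  sim <- simulate_sorted_reads(cfg, em, sm, "WT", outdir = tempfile())
  bct <- count_motifs(sim$files, template, barcodes, genotype = "WT")

  expect_equal(bct$ledger[["kept"]], bct$n_raw)
  expect_equal(sum(bct$ledger) - bct$ledger[["kept"]], 0)

  # counts equal the simulator's own multinomial allocations, motif-wise
  alloc <- rowsum(sim$allocation, sim$library$motif)
  alloc <- alloc[order(rownames(alloc)), , drop = FALSE]
  observed <- as.matrix(bct$counts[, paste0("count_b", 1:4)])
  expect_identical(bct$counts$motif, rownames(alloc))
  expect_equal(unname(observed), unname(alloc))
})

test_that("the discard ledger partitions every input read", {
  region <- "TTTCTGTTTGTGCAG"
  good <- make_read(region, "B3")
  bad_barcode <- good
  substr(bad_barcode, 16, 18) <- "GGG"
  bad_flank <- good
  substr(bad_flank, 2, 2) <- "T"
  stop_read <- make_read("TAGTAGTAGTAGTAG", "B1")
  n_read <- make_read("TTNCTGTTTGTGCAG", "B2")
  reads <- c(good, bad_barcode, bad_flank, stop_read, n_read, good)

  bct <- count_motifs(reads, template, barcodes)
  expect_equal(bct$n_raw, 6)
  expect_equal(bct$ledger[["barcode-mismatch"]], 1)
  expect_equal(bct$ledger[["consensus-mismatch"]], 1)
  expect_equal(bct$ledger[["stop-codon"]], 1)
  expect_equal(bct$ledger[["ambiguous-base"]], 1)
  expect_equal(bct$ledger[["kept"]], 2)
  expect_equal(sum(bct$ledger), bct$n_raw)
  expect_equal(bct$counts$motif, "FLFVQ")
  expect_equal(bct$counts$count_b3, 2)
})

test_that("all-stop input yields an empty table with a full ledger", {
  reads <- make_read("TAGTAGTAGTAGTAG", "B1")[rep(1, 5)]
  bct <- count_motifs(reads, template, barcodes)
  expect_equal(nrow(bct$counts), 0)
  expect_equal(bct$ledger[["stop-codon"]], 5)
  expect_equal(bct$bin_totals, c(B1 = 0, B2 = 0, B3 = 0, B4 = 0))
})

test_that("counting is invariant to read order", {
  set.seed(4)
  regions <- vapply(1:50, function(i) sample_nnk_codons(5), "")
  bins <- sample(names(barcodes), 50, replace = TRUE)
  reads <- mapply(make_read, regions, bins)
  a <- count_motifs(reads, template, barcodes)
  b <- count_motifs(sample(reads), template, barcodes)
  expect_equal(a$counts, b$counts)
  expect_equal(a$ledger, b$ledger)
})

test_that("count_motifs reads gzip FASTQ the same as plain text", {
  region <- "TTTCTGTTTGTGCAG"
  reads <- make_read(region, "B4")[rep(1, 3)]
  plain <- tempfile(fileext = ".fastq")
  psifive:::write_fastq(reads, paste0("r", 1:3), plain)
  gz <- tempfile(fileext = ".fastq.gz")
  con <- gzfile(gz, "w")
  writeLines(readLines(plain), con)
  close(con)
  a <- count_motifs(plain, template, barcodes)
  b <- count_motifs(gz, template, barcodes)
  expect_equal(a$counts, b$counts)
})
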