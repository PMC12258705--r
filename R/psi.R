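#' Protein Stability Index from per-bin read counts
#'
#' PSI = sum over bins i = 1..4 of `R_i * i`, where `R_i` is the fraction
#' of a motif's reads in bin i (bin B4 = most stable), so PSI ranges from
#' 1 (all reads in B1) to 4 (all reads in B4).
#'
#' Two interpretations of `R_i` are provided. `"raw"` (the default) takes
#' the literal fraction of the motif's reads per bin. `"depth"` first
#' divides each bin's count by that bin's total sequencing depth and then
#' renormalizes, correcting for highly unequal per-bin depths; this is the
#' consistent estimator of the motif's expected PSI when reads are
#' allocated bin-wise (a fixed number of sorted cells per bin).
#'
#' @param counts Length-4 non-negative integer vector (B1..B4), or an
#'   `n x 4` matrix of such rows.
#' @param mode `"raw"` or `"depth"`.
#' @param bin_totals Length-4 positive totals per bin; required for
#'   `mode = "depth"`.
#' @return A list with `R` (fractions, same shape as `counts`) and `psi`
#'   (numeric scalar or vector). All-zero count rows give `NA` psi; such
#'   records are excluded from databases rather than propagated.
#' @export
compute_psi <- function(counts, mode = c("raw", "depth"), bin_totals = NULL) {
  mode <- match.arg(mode)
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1)
  stopifnot(ncol(m) == 4, all(m >= 0, na.rm = TRUE))
  w <- m
  if (mode == "depth") {
    stopifnot(!is.null(bin_totals), length(bin_totals) == 4,
              all(bin_totals > 0))
    w <- sweep(m, 2, as.numeric(bin_totals), "/")
  }
  tot <- rowSums(w)
  R <- w / ifelse(tot > 0, tot, NA_real_)
  psi <- as.numeric(R %*% (1:4))
  if (!is.matrix(counts)) {
    list(R = as.numeric(R[1, ]), psi = psi[1])
  } else {
    list(R = R, psi = psi)
  }
}

#' Build a per-genotype motif -> PSI database
#'
#' One record per motif with total reads >= `min_reads`, in deterministic
#' lexicographic motif order. The database stores each motif's per-bin
#' counts, total, and PSI.
#'
#' @param table A `bin_count_table` from [count_motifs()], or a data frame
#'   with columns `motif`, `count_b1`..`count_b4`.
#' @param mode PSI normalization mode, see [compute_psi()].
#' @param min_reads Minimum total read count to retain a motif (default 1;
#'   model training conventionally uses 20).
#' @param genotype Genotype label; defaults to the table's if available.
#' @return An object of class `motif_db`: a data frame with columns
#'   `motif`, `count_b1`..`count_b4`, `total`, `psi`, with attributes
#'   `genotype`, `mode`, `min_reads`, `bin_totals`.
#' @export
build_database <- function(table, mode = c("raw", "depth"), min_reads = 1L,
                           genotype = NULL) {
  mode <- match.arg(mode)
  if (inherits(table, "bin_count_table")) {
    if (is.null(genotype)) genotype <- table$genotype
    counts <- table$counts
  } else {
    counts <- as.data.frame(table)
    if (is.null(genotype)) genotype <- "unknown"
  }
  cols <- paste0("count_b", 1:4)
  stopifnot(all(c("motif", cols) %in% names(counts)))
  m <- as.matrix(counts[, cols])
  bin_totals <- colSums(m)
  total <- rowSums(m)
  keep <- total >= min_reads & total > 0
  counts <- counts[keep, c("motif", cols), drop = FALSE]
  m <- m[keep, , drop = FALSE]
  counts$total <- as.integer(total[keep])
  counts$psi <- if (nrow(counts)) {
    compute_psi(m, mode = mode,
                bin_totals = if (mode == "depth") pmax(bin_totals, 1) else NULL)$psi
  } else numeric(0)
  counts <- counts[order(counts$motif), , drop = FALSE]
  rownames(counts) <- NULL
  structure(counts, class = c("motif_db", "data.frame"),
            genotype = genotype, mode = mode, min_reads = as.integer(min_reads),
            bin_totals = bin_totals)
}

#' Write a motif database to TSV
#'
#' Columns `motif`, `count_b1`..`count_b4`, `total`, `psi`; a `#`-prefixed
#' header records genotype, normalization mode, and read threshold.
#'
#' @param db A `motif_db`.
#' @param path Output path (gzip if it ends in `.gz`).
#' @return Invisibly, `path`.
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "motif_db"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# genotype=%s mode=%s min_reads=%d",
                     attr(db, "genotype"), attr(db, "mode"),
                     attr(db, "min_reads")), con)
  utils::write.table(db, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif database written by [write_database()]
#'
#' @param path TSV path (plain or gzip).
#' @return A `motif_db` data frame.
#' @export
read_database <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  header <- readLines(con, n = 1)
  close(con)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  meta <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  structure(df, class = c("motif_db", "data.frame"),
            genotype = unname(vals["genotype"]), mode = unname(vals["mode"]),
            min_reads = as.integer(vals["min_reads"]),
            bin_totals = colSums(df[, paste0("count_b", 1:4)]))
}
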