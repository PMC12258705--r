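#' Residue-by-position summary matrices
#'
#' A 20 x k matrix keyed by residue (canonical alphabet order) and
#' position, carrying a summary statistic (mean PSI, delta PSI, log2 or
#' fold enrichment) plus an `n` attribute with the number of contributing
#' motifs per cell. Cells with no contributing motifs are `NA` with n = 0.
#'
#' @name rp_matrix
NULL

new_rp_matrix <- function(values, n, statistic) {
  structure(values, n = n, statistic = statistic,
            class = c("rp_matrix", class(values)))
}

#' @export
print.rp_matrix <- function(x, ...) {
  cat("rp_matrix (", attr(x, "statistic"), ")\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Mean PSI per residue-position combination
#'
#' Cell (a, p) is the mean PSI over motifs carrying residue `a` at
#' position `p`. Computed over the requested positions (all five by
#' default).
#'
#' @param db A `motif_db`.
#' @param positions Positions to include (subset of 1..5).
#' @return An [rp_matrix] (20 x length(positions)) of mean PSI.
#' @export
mean_psi_matrix <- function(db, positions = 1:5) {
  stopifnot(inherits(db, "motif_db"), nrow(db) > 0,
            all(positions %in% 1:5))
  vals <- matrix(NA_real_, 20, length(positions),
                 dimnames = list(AA_ALPHABET, paste0("P", positions)))
  nmat <- matrix(0L, 20, length(positions),
                 dimnames = dimnames(vals))
  for (j in seq_along(positions)) {
    res <- factor(substr(db$motif, positions[j], positions[j]),
                  levels = AA_ALPHABET)
    vals[, j] <- as.numeric(tapply(db$psi, res, mean))
    cnt <- table(res)
    nmat[, j] <- as.integer(cnt)
  }
  new_rp_matrix(vals, nmat, "mean PSI")
}

#' Cellwise difference of two residue-position matrices
#'
#' `a - b` with `n` the cellwise minimum of the operands' n; cells empty
#' in either operand are empty in the result. Antisymmetric under operand
#' swap.
#'
#' @param a,b [rp_matrix] objects with identical keying.
#' @return An [rp_matrix] of delta PSI.
#' @export
delta_matrix <- function(a, b) {
  stopifnot(inherits(a, "rp_matrix"), inherits(b, "rp_matrix"),
            identical(dimnames(a), dimnames(b)))
  vals <- unclass(a) - unclass(b)
  new_rp_matrix(vals, pmin(attr(a, "n"), attr(b, "n")), "delta PSI")
}

#' Conditional residue-position matrix
#'
#' Mean-PSI matrix over the four remaining positions, restricted to motifs
#' with a fixed residue at one position (e.g. the P2-P5 preference profile
#' of each P1 residue).
#'
#' @param db A `motif_db`.
#' @param position Conditioned position (1..5).
#' @param residue Residue required at `position`.
#' @return An [rp_matrix] (20 x 4) over the remaining positions; a matrix
#'   of all-`NA` cells if no motif satisfies the condition.
#' @export
conditional_matrix <- function(db, position, residue) {
  stopifnot(inherits(db, "motif_db"), position %in% 1:5,
            residue %in% AA_ALPHABET)
  keep <- substr(db$motif, position, position) == residue
  rest <- setdiff(1:5, position)
  if (!any(keep)) {
    vals <- matrix(NA_real_, 20, 4,
                   dimnames = list(AA_ALPHABET, paste0("P", rest)))
    return(new_rp_matrix(vals, matrix(0L, 20, 4, dimnames = dimnames(vals)),
                         "mean PSI"))
  }
  sub <- db[keep, , drop = FALSE]
  attr(sub, "genotype") <- attr(db, "genotype")
  class(sub) <- class(db)
  mean_psi_matrix(sub, positions = rest)
}

#' Net side-chain charge of a motif
#'
#' Arg and Lys contribute +1, Asp and Glu -1; all other residues,
#' including His, contribute 0. Termini contribute no charge. An optional
#' position mask restricts the sum (e.g. P2-P5 only).
#'
#' @param motifs Character vector of motifs (length 1-5 residues).
#' @param positions Positions included in the sum; default all.
#' @return Integer vector of net charges.
#' @export
net_charge <- function(motifs, positions = NULL) {
  stopifnot(is.character(motifs), all(nchar(motifs) >= 1),
            all(nchar(motifs) <= 5))
  len <- nchar(motifs[1])
  if (is.null(positions)) positions <- seq_len(len)
  charge <- c(R = 1L, K = 1L, D = -1L, E = -1L)
  out <- integer(length(motifs))
  for (p in positions) {
    res <- substr(motifs, p, p)
    ch <- charge[res]
    ch[is.na(ch)] <- 0L
    out <- out + ch
  }
  unname(out)
}

#' Count group residues at selected positions
#'
#' Number of residues at `positions` belonging to the residue set `group`
#' (a name from [AA_GROUPS] or a character vector of residues).
#'
#' @param motifs Character vector of 5-residue motifs.
#' @param group Residue set or `AA_GROUPS` name.
#' @param positions Positions counted (subset of 1..5).
#' @return Integer vector of counts.
#' @export
group_count <- function(motifs, group, positions = 1:5) {
  if (is.character(group) && length(group) == 1 && group %in% names(AA_GROUPS)) {
    group <- AA_GROUPS[[group]]
  }
  stopifnot(all(group %in% AA_ALPHABET), all(positions %in% 1:5))
  out <- integer(length(motifs))
  for (p in positions) {
    out <- out + (substr(motifs, p, p) %in% group)
  }
  out
}

#' Positionwise fold-enrichment logo matrix
#'
#' Cell (a, p) is the frequency of residue `a` at position `p` in the
#' subset divided by its frequency in the background — the statistic
#' behind fold-enrichment sequence logos (e.g. the composition of low-PSI
#' motifs versus the whole library). Cells with zero background frequency
#' are flagged undefined (`NA`).
#'
#' @param subset_db,background_db `motif_db` objects (non-empty).
#' @return An [rp_matrix] (20 x 5) of fold enrichment; `n` holds subset
#'   residue counts.
#' @export
enrichment_logo <- function(subset_db, background_db) {
  stopifnot(inherits(subset_db, "motif_db"), nrow(subset_db) > 0,
            inherits(background_db, "motif_db"), nrow(background_db) > 0)
  freq <- function(db) {
    sapply(1:5, function(p) {
      tab <- table(factor(substr(db$motif, p, p), levels = AA_ALPHABET))
      as.numeric(tab) / nrow(db)
    })
  }
  fs <- freq(subset_db)
  fb <- freq(background_db)
  vals <- ifelse(fb > 0, fs / fb, NA_real_)
  dimnames(vals) <- list(AA_ALPHABET, paste0("P", 1:5))
  nmat <- sapply(1:5, function(p) {
    as.integer(table(factor(substr(subset_db$motif, p, p),
                            levels = AA_ALPHABET)))
  })
  dimnames(nmat) <- dimnames(vals)
  new_rp_matrix(vals, nmat, "fold enrichment")
}

#' P1/P2 dipeptide log2 stable/unstable enrichment
#'
#' For each of the 400 ordered P1-P2 residue pairs, the log2 ratio of the
#' pair's frequency among stable motifs (PSI > `stable_thr`) to its
#' frequency among unstable motifs (PSI < `unstable_thr`), with each
#' stratum normalized to its own size before the ratio. Pairs absent from
#' either stratum are undefined (`NA`).
#'
#' @param db A `motif_db`.
#' @param stable_thr PSI threshold above which motifs count as stable
#'   (default 3).
#' @param unstable_thr PSI threshold below which motifs count as unstable
#'   (default 2).
#' @return 20 x 20 matrix (rows P1, cols P2) of log2 enrichment ratios,
#'   with attributes `n_stable`, `n_unstable` (stratum sizes).
#' @export
p1p2_enrichment <- function(db, stable_thr = 3, unstable_thr = 2) {
  stopifnot(inherits(db, "motif_db"))
  stable <- db$psi > stable_thr
  unstable <- db$psi < unstable_thr
  if (!any(stable) || !any(unstable)) {
    stop("both the stable and the unstable stratum must be non-empty")
  }
  pair_counts <- function(sel) {
    table(factor(substr(db$motif[sel], 1, 1), levels = AA_ALPHABET),
          factor(substr(db$motif[sel], 2, 2), levels = AA_ALPHABET))
  }
  cs <- pair_counts(stable)
  cu <- pair_counts(unstable)
  fs <- cs / sum(stable)
  fu <- cu / sum(unstable)
  vals <- matrix(NA_real_, 20, 20,
                 dimnames = list(P1 = AA_ALPHABET, P2 = AA_ALPHABET))
  ok <- cs > 0 & cu > 0
  vals[ok] <- log2(as.numeric(fs[ok]) / as.numeric(fu[ok]))
  attr(vals, "n_stable") <- sum(stable)
  attr(vals, "n_unstable") <- sum(unstable)
  vals
}

#' Methionine-aminopeptidase position-shift comparison
#'
#' Compares Nt-Met motifs `M X Y3 Y4 Y5` with the same window shifted to
#' the N-terminus, `X Y3 Y4 Y5 *`: for each residue X, the mean PSI of
#' motifs with Met at P1 and X at P2 versus the mean PSI over motifs whose
#' first four residues match the `X Y3 Y4 Y5` windows observed behind
#' Nt-Met. A positive difference means the window is stabler while still
#' shielded by Met — i.e. MetAP excision of Met would expose a more
#' degradation-prone N-terminus.
#'
#' @param db A `motif_db` containing P1-Met motifs.
#' @return Data frame with one row per residue X observed at P2 behind
#'   Met: `residue`, `mean_psi_met` (MXYYY), `mean_psi_shifted` (XYYYZ),
#'   `diff`, `n_met`, `n_shifted`. Residues without shifted matches have
#'   `NA` in the shifted columns.
#' @export
metap_comparison <- function(db) {
  stopifnot(inherits(db, "motif_db"))
  is_met <- substr(db$motif, 1, 1) == "M"
  if (!any(is_met)) stop("database contains no P1-Met motifs")
  met <- db[is_met, , drop = FALSE]
  window <- substr(met$motif, 2, 5)      # X Y3 Y4 Y5 behind Met
  x <- substr(window, 1, 1)
  prefix4 <- substr(db$motif, 1, 4)

  out <- lapply(sort(unique(x)), function(res) {
    sel <- x == res
    wins <- unique(window[sel])
    shifted <- db$psi[prefix4 %in% wins]
    data.frame(residue = res,
               mean_psi_met = mean(met$psi[sel]),
               mean_psi_shifted = if (length(shifted)) mean(shifted) else NA_real_,
               n_met = sum(sel),
               n_shifted = length(shifted),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$diff <- out$mean_psi_met - out$mean_psi_shifted
  out[, c("residue", "mean_psi_met", "mean_psi_shifted", "diff",
          "n_met", "n_shifted")]
}

#' Bulky-by-acidic P2-P5 crosstab of PSI drops
#'
#' Motifs (restricted to allowed P1 residues, by default the canonically
#' stable set: P1 not in FLWYRK) are cross-tabulated by their count of
#' bulky (FLWY) and negatively charged (DE) residues at P2-P5; each cell
#' holds the mean PSI minus the mean PSI of the (0 bulky, 0 acidic)
#' reference cell, optionally with a [subset_contrast()]-style test of the
#' cell against the reference.
#'
#' @param db A `motif_db`.
#' @param p1_allowed Residues allowed at P1 (default: the 14 canonically
#'   stable residues).
#' @param stats If `TRUE`, attach a matrix of star annotations (cell vs
#'   reference) as attribute `annotation`.
#' @return 5 x 5 matrix (bulky count 0..4 by acidic count 0..4) of mean
#'   delta PSI relative to cell (0, 0), with attributes `n` (cell counts)
#'   and `reference_mean`.
#' @export
crosstab_bulky_negative <- function(db,
                                    p1_allowed = setdiff(AA_ALPHABET,
                                                         AA_GROUPS$CanonicalDestabilizing),
                                    stats = FALSE) {
  stopifnot(inherits(db, "motif_db"))
  keep <- substr(db$motif, 1, 1) %in% p1_allowed
  sub <- db[keep, , drop = FALSE]
  nb <- group_count(sub$motif, "Bulky", positions = 2:5)
  nd <- group_count(sub$motif, "Negative", positions = 2:5)
  ref <- sub$psi[nb == 0 & nd == 0]
  if (!length(ref)) stop("reference cell (0 bulky, 0 acidic) is empty")
  dims <- list(bulky = 0:4, acidic = 0:4)
  vals <- matrix(NA_real_, 5, 5, dimnames = dims)
  nmat <- matrix(0L, 5, 5, dimnames = dims)
  ann <- matrix(NA_character_, 5, 5, dimnames = dims)
  for (i in 0:4) for (j in 0:4) {
    cell <- sub$psi[nb == i & nd == j]
    nmat[i + 1, j + 1] <- length(cell)
    if (length(cell)) {
      vals[i + 1, j + 1] <- mean(cell) - mean(ref)
      if (stats && !(i == 0 && j == 0)) {
        mw <- mann_whitney_u(cell, ref)
        ann[i + 1, j + 1] <- star_annotation(mw$p, abs(cliffs_delta(cell, ref)))
      }
    }
  }
  attr(vals, "n") <- nmat
  attr(vals, "reference_mean") <- mean(ref)
  if (stats) attr(vals, "annotation") <- ann
  vals
}

#' Write a labelled matrix to TSV
#'
#' Row and column labels are written explicitly; a `#`-prefixed provenance
#' header records the statistic and any extra metadata.
#'
#' @param m Matrix (e.g. an [rp_matrix]).
#' @param path Output path.
#' @param what Statistic label for the header.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path, what = attr(m, "statistic")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(what)) writeLines(paste0("# statistic=", what), con)
  df <- data.frame(key = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
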