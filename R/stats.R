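#' Cliff's delta effect size
#'
#' The probability that a random value from `x` exceeds a random value
#' from `y`, minus the reverse probability; bounded in \[-1, 1\]. Makes no
#' distributional assumptions and is valid for skewed, bounded, heavily
#' tied data such as PSI. Computed in O((n1+n2) log(n1+n2)) from midranks,
#' which is exactly equivalent to the all-pairs definition.
#'
#' @param x,y Numeric vectors (non-empty).
#' @return Signed delta in \[-1, 1\]; positive when `x` tends to exceed `y`.
#' @export
cliffs_delta <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(x, y))
  # U1 = #{x > y} + 0.5 #{x == y}
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  2 * u1 / (n1 * n2) - 1
}

#' Two-sided Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()]: exact enumeration when both samples have
#' at most `exact_max` observations and the data are tie-free, otherwise
#' the normal approximation with midranks and tie-corrected variance
#' (PSI values tie heavily at low read counts).
#'
#' @param x,y Numeric vectors.
#' @param exact_max Largest `min(n1, n2)` for which the exact branch is
#'   used (default 8).
#' @return List with `U` (statistic for `x`) and `p` (two-sided p-value).
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Star annotation for a contrast
#'
#' The screen's annotation scheme: significance requires p < 0.05, and the
#' number of stars encodes the effect-size magnitude |delta|:
#' `*` 0-0.25, `**` 0.25-0.50, `***` 0.50-0.75, `****` 0.75-1.0.
#' Non-significant contrasts are annotated `"ns"`.
#'
#' @param p Two-sided p-value.
#' @param es Effect-size magnitude in \[0, 1\].
#' @return Character annotation.
#' @export
star_annotation <- function(p, es) {
  if (is.na(p) || p >= 0.05) return("ns")
  as.character(cut(es, breaks = c(0, 0.25, 0.5, 0.75, 1),
                   labels = c("*", "**", "***", "****"),
                   right = FALSE, include.lowest = TRUE))
}

#' Contrast the PSI distributions of two motif subsets
#'
#' Mann-Whitney U test (two-sided) plus Cliff's delta and mean difference
#' between the PSI values of two subsets of a motif database, with the
#' star annotation of [star_annotation()]. Effect size `es` is reported as
#' |delta| (magnitude); the signed delta is retained.
#'
#' @param db A `motif_db`.
#' @param subset_a,subset_b Either logical vectors over `db` rows or
#'   predicate functions taking the motif character vector and returning a
#'   logical vector.
#' @return An object of class `stat_result`: list with `n1`, `n2`, `U`,
#'   `p`, `delta`, `es`, `mean_diff` (mean A - mean B), `annotation`.
#' @export
subset_contrast <- function(db, subset_a, subset_b) {
  stopifnot(inherits(db, "motif_db"))
  sel <- function(s) {
    if (is.function(s)) s <- s(db$motif)
    stopifnot(is.logical(s), length(s) == nrow(db))
    s
  }
  a <- db$psi[sel(subset_a)]
  b <- db$psi[sel(subset_b)]
  if (!length(a) || !length(b)) stop("both subsets must be non-empty")
  mw <- mann_whitney_u(a, b)
  delta <- cliffs_delta(a, b)
  structure(list(n1 = length(a), n2 = length(b), U = mw$U, p = mw$p,
                 delta = delta, es = abs(delta),
                 mean_diff = mean(a) - mean(b),
                 annotation = star_annotation(mw$p, abs(delta))),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf(
    "stat_result: n1=%d n2=%d U=%.4g p=%.3g delta=%+.3f ES=%.3f mean_diff=%+.3f %s\n",
    x$n1, x$n2, x$U, x$p, x$delta, x$es, x$mean_diff, x$annotation))
  invisible(x)
}

#' Predicate builder for residue-at-position subsets
#'
#' Convenience constructor of predicates over motif vectors, for use with
#' [subset_contrast()] and friends: selects motifs whose residue at
#' `position` is in `residues` (or not in, with `negate = TRUE`).
#'
#' @param position Position 1..5.
#' @param residues Character vector of residues.
#' @param negate If `TRUE`, select motifs whose residue is *not* in the set.
#' @return A function motifs -> logical.
#' @export
residue_at <- function(position, residues, negate = FALSE) {
  stopifnot(position %in% 1:5, all(residues %in% AA_ALPHABET))
  force(negate)
  function(motifs) {
    hit <- substr(motifs, position, position) %in% residues
    if (negate) !hit else hit
  }
}
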