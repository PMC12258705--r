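#' Sorted-cell counts from the four-bin FACS screen
#'
#' Per-genotype sorted cell counts for bins B1 (least fluorescent) to B4
#' (most fluorescent, most stable), as collected in the screen that this
#' pipeline models. Used to default simulated bin depths to realistic
#' relative sizes.
#'
#' @return Named list of integer vectors (B1..B4) per genotype.
#' @export
facs_sorted_counts <- function() {
  list(
    WT      = c(B1 = 955183,  B2 = 1130665, B3 = 1940219, B4 = 5998196),
    LFTR_KO = c(B1 = 913809,  B2 = 998851,  B3 = 1161141, B4 = 6953470),
    CLPS_KO = c(B1 = 853250,  B2 = 483574,  B3 = 1651034, B4 = 7048173)
  )
}

#' Latent-Gaussian four-bin sorting model
#'
#' Maps a true stability score (PSI scale, \[1, 4\]) to four bin
#' probabilities: a cell's latent log-fluorescence is Gaussian with mean
#' equal to the score and spread `noise_sd`, partitioned by three ascending
#' thresholds into bins B1..B4 with B4 the most stable. The constructor
#' enforces that a motif at the scale extremes sorts >= 99% of its mass
#' into the corresponding extreme bin.
#'
#' @param noise_sd Latent spread (PSI units). Default 0.2, the largest
#'   round value compatible with the extreme-bin requirement at the default
#'   thresholds.
#' @param thresholds Three strictly ascending cut points on the latent axis.
#' @param depths Four positive integers: nominal per-bin read budget.
#'   Their sum sets the simulator's total sequencing depth; realized bin
#'   read counts follow the sorted population's bin occupancy. Default:
#'   the screen's WT sorted-cell proportions scaled to `total_reads`.
#' @param total_reads Total depth used to scale the default `depths`.
#' @return An object of class `sort_model`.
#' @export
sort_model <- function(noise_sd = 0.2,
                       thresholds = c(1.5, 2.5, 3.5),
                       depths = NULL,
                       total_reads = 400000) {
  stopifnot(length(thresholds) == 3, all(diff(thresholds) > 0),
            noise_sd >= 0)
  if (is.null(depths)) {
    prop <- facs_sorted_counts()$WT
    depths <- round(total_reads * prop / sum(prop))
  }
  stopifnot(length(depths) == 4, all(depths > 0))
  m <- structure(list(noise_sd = noise_sd, thresholds = thresholds,
                      depths = as.integer(depths), orientation = "B4_stable"),
                 class = "sort_model")
  if (bin_probabilities(4, m)[4] < 0.99 || bin_probabilities(1, m)[1] < 0.99) {
    stop("noise_sd too large: stability extremes must place >= 99% of ",
         "probability mass in the extreme bins")
  }
  m
}

#' Bin membership probabilities for a stability score
#'
#' Gaussian mass between consecutive thresholds, with latent mean equal to
#' the score. Probabilities sum to 1 and the B4 probability is
#' non-decreasing in the score. At `noise_sd = 0` the score's own bin gets
#' all the mass.
#'
#' @param score Numeric vector of stability scores in \[1, 4\].
#' @param sort A [sort_model()].
#' @return For scalar `score`, a length-4 probability vector; otherwise an
#'   `n x 4` matrix with one row per score.
#' @export
bin_probabilities <- function(score, sort) {
  stopifnot(inherits(sort, "sort_model"),
            all(score >= 1 - 1e-9 & score <= 4 + 1e-9))
  thr <- sort$thresholds
  if (sort$noise_sd == 0) {
    bin <- findInterval(score, thr) + 1L
    p <- matrix(0, length(score), 4)
    p[cbind(seq_along(score), bin)] <- 1
  } else {
    cuts <- vapply(thr, function(t) stats::pnorm(t, mean = score,
                                                 sd = sort$noise_sd),
                   numeric(length(score)))
    cuts <- matrix(cuts, nrow = length(score))
    p <- cbind(cuts[, 1],
               cuts[, 2] - cuts[, 1],
               cuts[, 3] - cuts[, 2],
               1 - cuts[, 3])
  }
  colnames(p) <- paste0("B", 1:4)
  if (length(score) == 1) p[1, ] else p
}

#' Expected PSI of a bin-probability vector
#'
#' The estimand of the PSI statistic: `sum(p_i * i)` over bins 1..4.
#'
#' @param p Length-4 probability vector or `n x 4` matrix.
#' @return Numeric scalar or vector in \[1, 4\].
#' @export
expected_psi <- function(p) {
  if (is.matrix(p)) as.numeric(p %*% (1:4)) else sum(p * (1:4))
}
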