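#' One-hot encode motifs for stability regression
#'
#' Encodes each 5-residue motif into 100 binary features: position-major,
#' residue-alphabetical within each position (columns `P1_A` .. `P1_Y`,
#' `P2_A` .. `P5_Y`). Every row sums to exactly 5. The column order is
#' frozen and stored with trained models to prevent silent mismatches.
#'
#' @param motifs Character vector of 5-residue motifs.
#' @param labels Optional numeric PSI labels (same length).
#' @return An object of class `encoded_dataset`: list with `features`
#'   (n x 100 integer matrix), `labels` (numeric or NULL), `motifs`.
#' @export
encode_motifs <- function(motifs, labels = NULL) {
  check_motifs(motifs)
  if (!is.null(labels)) stopifnot(length(labels) == length(motifs))
  n <- length(motifs)
  X <- matrix(0L, n, 100,
              dimnames = list(NULL, feature_columns()))
  for (p in 1:5) {
    res <- match(substr(motifs, p, p), AA_ALPHABET)
    X[cbind(seq_len(n), (p - 1L) * 20L + res)] <- 1L
  }
  structure(list(features = X, labels = labels, motifs = motifs),
            class = "encoded_dataset")
}

# Frozen feature column order: position-major, residue-alphabetical.
feature_columns <- function() {
  as.vector(t(outer(paste0("P", 1:5), AA_ALPHABET, paste, sep = "_")))
}

#' Decode one-hot rows back to motifs
#'
#' Inverse of [encode_motifs()]; used to verify the encoding is injective.
#'
#' @param X n x 100 binary matrix in the frozen column order.
#' @return Character vector of motifs.
#' @export
decode_features <- function(X) {
  stopifnot(ncol(X) == 100, all(rowSums(X) == 5))
  apply(X, 1, function(row) {
    paste(vapply(1:5, function(p) {
      AA_ALPHABET[which(row[(p - 1) * 20 + 1:20] == 1)]
    }, character(1)), collapse = "")
  })
}

#' Combined feature + label matrix
#'
#' The 101-column training matrix: 100 binary residue-position features
#' followed by the PSI label column.
#'
#' @param dataset An `encoded_dataset` with labels.
#' @return n x 101 numeric matrix.
#' @export
encoded_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "encoded_dataset"), !is.null(dataset$labels))
  cbind(dataset$features, psi = dataset$labels)
}

#' Training configuration for the stability model
#'
#' Defaults are the tuned hyperparameters of the screen's model: 986
#' boosting rounds of depth-11 trees at learning rate 0.085 with row
#' subsample 0.904 and per-tree column subsample 0.810, squared-error
#' objective, trained on motifs with at least 20 reads under an 80/20
#' random split.
#'
#' @param min_reads Minimum total read count for training motifs.
#' @param split_fraction Training fraction of the filtered database.
#' @param split_seed Seed for the random split.
#' @param n_estimators,max_depth,learning_rate,subsample,colsample_bytree
#'   Gradient-boosting hyperparameters.
#' @param train_seed Seed passed to the booster.
#' @param nthreads Training threads (default 1 for reproducibility).
#' @return An object of class `model_config`.
#' @export
model_config <- function(min_reads = 20L,
                         split_fraction = 0.8,
                         split_seed = 1L,
                         n_estimators = 986L,
                         max_depth = 11L,
                         learning_rate = 0.085,
                         subsample = 0.904,
                         colsample_bytree = 0.810,
                         train_seed = 1L,
                         nthreads = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1, n_estimators >= 1)
  structure(list(min_reads = as.integer(min_reads),
                 split_fraction = split_fraction,
                 split_seed = as.integer(split_seed),
                 n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 subsample = subsample,
                 colsample_bytree = colsample_bytree,
                 objective = "reg:squarederror",
                 train_seed = as.integer(train_seed),
                 nthreads = as.integer(nthreads)),
            class = "model_config")
}

#' Filter and split a motif database into train/validation sets
#'
#' Applies the minimum read-count filter, then a seeded random shuffle and
#' an 80/20 (by default) split. The partition is disjoint and exhaustive
#' over the filtered database.
#'
#' @param db A `motif_db`.
#' @param config A [model_config()].
#' @return List with `train` and `validation` `encoded_dataset`s.
#' @export
prepare_training <- function(db, config = model_config()) {
  stopifnot(inherits(db, "motif_db"), inherits(config, "model_config"))
  keep <- db$total >= config$min_reads
  if (!any(keep)) stop("no motifs pass the min_reads filter")
  motifs <- db$motif[keep]
  psi <- db$psi[keep]
  n <- length(motifs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$split_seed)
  idx <- sample.int(n)
  n_train <- floor(config$split_fraction * n)
  tr <- idx[seq_len(n_train)]
  va <- idx[-seq_len(n_train)]
  list(train = encode_motifs(motifs[tr], psi[tr]),
       validation = encode_motifs(motifs[va], psi[va]))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Train the gradient-boosted stability regressor
#'
#' Fits gradient-boosted regression trees on one-hot residue-position
#' features with the configuration's hyperparameters and reports
#' validation RMSE and R-squared.
#'
#' @param train,validation `encoded_dataset`s from [prepare_training()].
#' @param config A [model_config()].
#' @return An object of class `stability_model`: list with `booster`,
#'   `config`, `columns` (frozen feature order), and `report`
#'   (`n_train`, `n_val`, `rmse_val`, `r2_val`).
#' @export
train_stability_model <- function(train, validation, config = model_config()) {
  stopifnot(inherits(train, "encoded_dataset"),
            inherits(validation, "encoded_dataset"),
            inherits(config, "model_config"),
            !is.null(train$labels), !is.null(validation$labels))
  booster <- xgboost::xgboost(
    train$features, as.numeric(train$labels),
    nrounds = config$n_estimators,
    max_depth = config$max_depth,
    learning_rate = config$learning_rate,
    subsample = config$subsample,
    colsample_bytree = config$colsample_bytree,
    objective = config$objective,
    nthreads = config$nthreads,
    seed = config$train_seed,
    verbosity = 0)
  pred <- stats::predict(booster, validation$features)
  resid <- validation$labels - pred
  rmse <- sqrt(mean(resid^2))
  ss_tot <- sum((validation$labels - mean(validation$labels))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  if (is.na(r2)) warning("constant validation labels: R-squared undefined")
  structure(list(booster = booster,
                 config = config,
                 columns = feature_columns(),
                 report = list(n_train = length(train$labels),
                               n_val = length(validation$labels),
                               rmse_val = rmse, r2_val = r2)),
            class = "stability_model")
}

#' @export
print.stability_model <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "stability_model: %d trees (depth %d), n_train=%d n_val=%d rmse_val=%.4f r2_val=%.4f\n",
    x$config$n_estimators, x$config$max_depth, r$n_train, r$n_val,
    r$rmse_val, r$r2_val))
  invisible(x)
}

#' Predict PSI for motifs
#'
#' Deterministic given the model artifact; predictions are clamped to the
#' attainable PSI range \[1, 4\] (the regression target is bounded).
#'
#' @param object A `stability_model`.
#' @param motifs Character vector of 5-residue motifs.
#' @param clamp Clamp predictions to \[1, 4\] (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of predicted PSI (pPSI).
#' @export
predict.stability_model <- function(object, motifs, clamp = TRUE, ...) {
  X <- encode_motifs(motifs)$features
  stopifnot(identical(colnames(X), object$columns))
  p <- stats::predict(object$booster, X)
  if (clamp) p <- pmin(4, pmax(1, p)) else p
  as.numeric(p)
}

#' Constrained candidate selection by predicted stability
#'
#' Samples (or enumerates, if the constrained space is small) motifs
#' satisfying a residue-position constraint, ranks them by predicted PSI
#' in the requested direction, and returns the top `k` passing the
#' threshold. Ties break lexicographically by motif.
#'
#' @param model A `stability_model`.
#' @param fixed Named list position -> allowed residue(s),
#'   e.g. `list("1" = "L")` for a P1 Leu constraint.
#' @param excluded Named list position -> disallowed residues,
#'   e.g. `list("1" = AA_GROUPS$CanonicalDestabilizing)`.
#' @param direction `"stable"` (rank by decreasing pPSI, keep
#'   pPSI > threshold) or `"unstable"` (increasing, keep pPSI < threshold).
#' @param threshold pPSI threshold (default 3.5 for stable, 2.5 for
#'   unstable).
#' @param k Number of candidates to return.
#' @param n_sample Number of constrained motifs to draw when the
#'   constrained space is larger than `n_sample` (drawn uniformly over the
#'   allowed residues per position, deduplicated).
#' @return Data frame `motif`, `ppsi`, sorted in the requested direction;
#'   fewer than `k` rows (with a warning) when the threshold admits fewer.
#' @export
select_candidates <- function(model, fixed = list(), excluded = list(),
                              direction = c("stable", "unstable"),
                              threshold = NULL, k = 5L, n_sample = 100000L) {
  direction <- match.arg(direction)
  if (is.null(threshold)) threshold <- if (direction == "stable") 3.5 else 2.5
  allowed <- rep(list(AA_ALPHABET), 5)
  for (p in names(fixed)) allowed[[as.integer(p)]] <- intersect(AA_ALPHABET, fixed[[p]])
  for (p in names(excluded)) {
    allowed[[as.integer(p)]] <- setdiff(allowed[[as.integer(p)]], excluded[[p]])
  }
  if (any(lengths(allowed) == 0)) stop("constraint admits no motifs")
  space <- prod(lengths(allowed))
  if (space <= n_sample) {
    grid <- do.call(expand.grid, c(rev(allowed), stringsAsFactors = FALSE))
    motifs <- do.call(paste0, rev(grid))
  } else {
    motifs <- unique(do.call(paste0, lapply(allowed, function(a) {
      sample(a, n_sample, replace = TRUE)
    })))
  }
  ppsi <- predict(model, motifs)
  pass <- if (direction == "stable") ppsi > threshold else ppsi < threshold
  motifs <- motifs[pass]; ppsi <- ppsi[pass]
  ord <- if (direction == "stable") order(-ppsi, motifs) else order(ppsi, motifs)
  motifs <- motifs[ord]; ppsi <- ppsi[ord]
  if (length(motifs) < k) {
    warning("only ", length(motifs), " motifs pass the threshold (k = ", k, ")")
    k <- length(motifs)
  }
  data.frame(motif = utils::head(motifs, k), ppsi = utils::head(ppsi, k),
             stringsAsFactors = FALSE)
}

#' Additive per-feature attribution for one motif
#'
#' Exact tree-path additive attributions (tree SHAP) for a single
#' prediction: a baseline plus one contribution per one-hot feature, whose
#' sum equals the model's raw (unclamped) prediction up to the booster's
#' single-precision arithmetic.
#'
#' @param model A `stability_model`.
#' @param motif A single 5-residue motif.
#' @return List with `baseline`, `contributions` (named numeric, length
#'   100), and `prediction` (raw model output).
#' @export
attribute_prediction <- function(model, motif) {
  stopifnot(length(motif) == 1)
  X <- encode_motifs(motif)$features
  contrib <- stats::predict(model$booster, X, type = "contrib")
  contrib <- as.numeric(contrib[1, ])
  baseline <- contrib[101]
  contributions <- contrib[1:100]
  names(contributions) <- model$columns
  list(baseline = baseline,
       contributions = contributions,
       prediction = as.numeric(stats::predict(model$booster, X)))
}
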