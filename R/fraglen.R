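#' cDNA fragment length of a paired-end genome alignment
#'
#' The fragment length is the contiguous genomic span from the 5'-most to
#' the 3'-most locus of the pair. Pairs are discarded (returned as `NA`)
#' when the span exceeds `max_len`, when the mates sit on different
#' chromosomes, or when either mate fails the unique-alignment filter
#' (primary, non-secondary, MAPQ >= `min_mapq`).
#'
#' @param pairs data.frame with one row per pair and columns
#'   `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2` (0-based
#'   half-open) and optionally `mapq1`, `mapq2`, `secondary1`, `secondary2`.
#' @param max_len Maximum retained span (default 1000).
#' @param min_mapq MAPQ threshold defining "uniquely aligned" (default 30).
#' @return Integer vector of fragment lengths, `NA` where discarded.
#' @export
fragment_length <- function(pairs, max_len = 1000L, min_mapq = 30L) {
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (!all(req %in% names(pairs))) {
    stop("pairs must have columns: ", paste(req, collapse = ", "))
  }
  if (any(pairs$end1 <= pairs$start1) || any(pairs$end2 <= pairs$start2)) {
    stop("malformed alignment record: empty interval")
  }
  len <- pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2)
  len[pairs$chrom1 != pairs$chrom2] <- NA_integer_
  if (!is.null(pairs$mapq1)) len[pairs$mapq1 < min_mapq | pairs$mapq2 < min_mapq] <- NA_integer_
  if (!is.null(pairs$secondary1)) len[pairs$secondary1 | pairs$secondary2] <- NA_integer_
  len[!is.na(len) & len > max_len] <- NA_integer_
  as.integer(len)
}

#' Empirical fragment-length histogram on 1..max_len
#'
#' Counts the frequency of every fragment length from 1 to `max_len` and
#' normalizes to a discrete probability distribution. Lengths outside the
#' support (and `NA`s) are dropped before normalization.
#'
#' @param lengths Integer vector of fragment lengths.
#' @param max_len Upper end of the support (default 1000).
#' @return Object of class `fraglen_histogram`: list with `probs` (numeric
#'   vector of length `max_len`, sums to 1) and `n_fragments`.
#' @export
build_histogram <- function(lengths, max_len = 1000L) {
  lengths <- lengths[!is.na(lengths) & lengths >= 1L & lengths <= max_len]
  if (!length(lengths)) stop("no fragment lengths within support after exclusions")
  probs <- tabulate(as.integer(lengths), nbins = max_len) / length(lengths)
  structure(list(probs = probs, n_fragments = length(lengths)),
            class = "fraglen_histogram")
}

new_fraglen_model <- function(probs, smoothing = NA_real_, fit = NULL) {
  probs <- pmax(probs, 0)
  s <- sum(probs)
  if (s <= 0) stop("fragment-length model has no mass on its support")
  structure(list(probs = probs / s, smoothing = smoothing,
                 support = c(1L, length(probs)), fit = fit),
            class = "fraglen_model")
}

#' Construct a fragment-length model directly from probabilities
#'
#' Wraps a known discrete distribution on 1..`length(probs)` as a
#' `fraglen_model` (clamped at 0, renormalized). Used to score or simulate
#' with an exactly known distribution rather than a fitted spline.
#'
#' @param probs Numeric vector of (unnormalized) probabilities for lengths
#'   `1..length(probs)`.
#' @return A `fraglen_model`.
#' @export
fraglen_model <- function(probs) new_fraglen_model(probs)

#' Fit the cubic smoothing spline to a fragment-length histogram
#'
#' Fits a cubic smoothing spline through the (length, frequency) pairs of
#' the empirical histogram, then clamps negative excursions to zero and
#' renormalizes over the support so the evaluator is a valid probability
#' distribution.
#'
#' @param h A `fraglen_histogram`.
#' @param smoothing Non-negative smoothing penalty (the spline's lambda).
#'   The default was chosen so the training RMSE on the package's synthetic
#'   default generator is about 1e-4; smaller values interpolate, larger
#'   values smooth harder.
#' @return A `fraglen_model`.
#' @export
fit_fraglen_spline <- function(h, smoothing = 1e-6) {
  stopifnot(inherits(h, "fraglen_histogram"))
  if (!is.numeric(smoothing) || length(smoothing) != 1L || smoothing < 0) {
    stop("smoothing must be a single non-negative number")
  }
  n <- length(h$probs)
  if (smoothing == 0) {
    # interpolation limit: the spline passes through every (length, freq)
    # pair, so on the integer support the evaluator is the histogram itself
    return(new_fraglen_model(h$probs, smoothing = 0))
  }
  fit <- stats::smooth.spline(seq_len(n), h$probs, lambda = smoothing,
                              all.knots = TRUE, keep.data = FALSE)
  probs <- stats::predict(fit, seq_len(n))$y
  new_fraglen_model(probs, smoothing = smoothing, fit = fit)
}

#' Evaluate the fragment-length probability p_f
#'
#' @param model A `fraglen_model`.
#' @param len Numeric vector of lengths; non-integer or out-of-support
#'   values score 0.
#' @return Numeric vector of probabilities.
#' @export
pf_eval <- function(model, len) {
  stopifnot(inherits(model, "fraglen_model"))
  out <- numeric(length(len))
  ok <- !is.na(len) & len == round(len) &
    len >= model$support[1L] & len <= model$support[2L]
  out[ok] <- model$probs[as.integer(len[ok])]
  out
}

#' Root-mean-square error of a fitted model against a histogram
#'
#' @param model A `fraglen_model`.
#' @param h A `fraglen_histogram` on the same support.
#' @return RMSE over every length of the support.
#' @export
fraglen_rmse <- function(model, h) {
  stopifnot(inherits(model, "fraglen_model"), inherits(h, "fraglen_histogram"))
  if (length(h$probs) != model$support[2L]) stop("support mismatch")
  sqrt(mean((model$probs - h$probs)^2))
}

#' K-fold cross-validation of the fragment-length spline
#'
#' Randomly partitions the fragment lengths into `k` folds (seeded), fits
#' one spline per fold on the complement of that fold, and reports the
#' per-length standard deviation of the fitted probabilities across folds —
#' a direct measure of how stable the fitted distribution is under
#' resampling.
#'
#' @param lengths Integer vector of fragment lengths.
#' @param k Number of folds (default 5).
#' @param smoothing Spline smoothing penalty, as in [fit_fraglen_spline()].
#' @param max_len Support upper end.
#' @param seed Integer seed controlling the partition.
#' @return List with `models` (one `fraglen_model` per fold), `sd`
#'   (per-length standard deviation across folds) and `folds` (fold
#'   assignment of each retained length).
#' @export
fraglen_cross_validate <- function(lengths, k = 5L, smoothing = 1e-6,
                                   max_len = 1000L, seed = 1L) {
  lengths <- lengths[!is.na(lengths) & lengths >= 1L & lengths <= max_len]
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > length(lengths)) stop("k exceeds the number of fragments")
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), length(lengths)))
  models <- lapply(seq_len(k), function(i) {
    fit_fraglen_spline(build_histogram(lengths[fold != i], max_len), smoothing)
  })
  pmat <- vapply(models, function(m) m$probs, numeric(max_len))
  list(models = models, sd = apply(pmat, 1L, stats::sd), folds = fold)
}

#' Draw fragment lengths from a fragment-length model
#'
#' @param model A `fraglen_model`.
#' @param n Number of draws.
#' @return Integer vector of lengths in the model support.
#' @export
sample_fraglen <- function(model, n) {
  stopifnot(inherits(model, "fraglen_model"))
  sample.int(model$support[2L], n, replace = TRUE, prob = model$probs)
}

#' Discretized truncated-normal fragment-length distribution
#'
#' The package's reference synthetic fragment-length law: a normal
#' distribution truncated to the support `1..max_len` and discretized per
#' integer length. The defaults (mean 300, sd 60) emulate the insert-size
#' preference of 3' tagged-end libraries.
#'
#' @param mean,sd Normal parameters in bp.
#' @param max_len Support upper end.
#' @return A `fraglen_model` with the exact discretized probabilities.
#' @export
truncnorm_fraglen <- function(mean = 300, sd = 60, max_len = 1000L) {
  x <- seq_len(max_len)
  p <- stats::pnorm(x + 0.5, mean, sd) - stats::pnorm(x - 0.5, mean, sd)
  new_fraglen_model(p)
}
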