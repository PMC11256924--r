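#' ROC curve and AUC for spliced-probability predictions
#'
#' Sweeps the classification threshold over all distinct scores to build
#' the ROC curve (spliced is the positive class) and computes the area
#' under it. The AUC is computed by the rank (Mann-Whitney) formula, which
#' equals the trapezoidal area under the threshold-sweep curve; tied
#' positive-negative score pairs contribute half credit.
#'
#' @param truth Character vector of `"spliced"` / `"unspliced"` truths.
#' @param score Numeric vector of predicted spliced probabilities; `NA`
#'   (ambiguous) entries are excluded and counted.
#' @return List with `auc`, `points` (data.frame of `threshold`, `fpr`,
#'   `tpr`, descending thresholds), `n_used`, `n_ambiguous`.
#' @export
roc_auc <- function(truth, score) {
  stopifnot(length(truth) == length(score))
  keep <- !is.na(score)
  n_amb <- sum(!keep)
  truth <- truth[keep]; score <- score[keep]
  pos <- truth == "spliced"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC needs at least one spliced and one unspliced truth")
  }
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(score), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(score[pos] >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(score[!pos] >= t), numeric(1))
  points <- data.frame(threshold = c(Inf, thr),
                       fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  list(auc = auc, points = points, n_used = length(score), n_ambiguous = n_amb)
}

#' Trivial baseline score sets
#'
#' The three baselines implied by current practice: assign every read a
#' spliced probability of 1 ("all spliced"), 0 ("all unspliced"), or a
#' class-conditional random probability — uniform in `[0, 0.5]` for truly
#' unspliced reads and `[0.5, 1]` for truly spliced reads — whose order is
#' then randomly shuffled across reads ("shuffled random"). Deterministic
#' per seed.
#'
#' @param truth Character vector of `"spliced"` / `"unspliced"` truths.
#' @param seed Integer seed.
#' @return Named list of three numeric score vectors: `all_spliced`,
#'   `all_unspliced`, `shuffled_random`.
#' @export
baseline_scores <- function(truth, seed = 1L) {
  n <- length(truth)
  set.seed(as.integer(seed))
  rnd <- numeric(n)
  uns <- truth == "unspliced"
  rnd[uns] <- stats::runif(sum(uns), 0, 0.5)
  rnd[!uns] <- stats::runif(sum(!uns), 0.5, 1)
  list(all_spliced = rep(1, n), all_unspliced = rep(0, n),
       shuffled_random = sample(rnd))
}

#' Multi-gene read assignment report
#'
#' Among reads mapping to more than one gene: the fraction for which a
#' single best gene could be assigned (exact score ties yield no
#' prediction) and, among those, the fraction whose assigned gene is the
#' true gene of origin.
#'
#' @param predictions Prediction table from [predict_reads()] (needs
#'   `read_id`, `assigned_gene`, `tie`, `n_genes`).
#' @param truth_genes Named character vector (or data.frame with `read_id`,
#'   `gene_id`) of true genes of origin.
#' @return List with `n_multigene`, `single_best_fraction` and `accuracy`
#'   (`NA` when no single-best assignment exists).
#' @export
multigene_report <- function(predictions, truth_genes) {
  if (is.data.frame(truth_genes)) {
    truth_genes <- stats::setNames(truth_genes$gene_id, truth_genes$read_id)
  }
  mg <- predictions[predictions$n_genes > 1L, , drop = FALSE]
  if (!nrow(mg)) {
    return(list(n_multigene = 0L, single_best_fraction = NA_real_,
                accuracy = NA_real_))
  }
  single <- !mg$tie
  acc <- if (any(single)) {
    mean(mg$assigned_gene[single] == truth_genes[mg$read_id[single]])
  } else NA_real_
  list(n_multigene = nrow(mg), single_best_fraction = mean(single),
       accuracy = acc)
}
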