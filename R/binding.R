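#' One-hot encode a priming-window sequence
#'
#' @param seq Character scalar over `ACGTN` (case-insensitive).
#' @return Integer matrix with `nchar(seq)` rows and 4 columns in channel
#'   order A, C, G, T; an `N` yields an all-zero row.
#' @export
encode_window <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  idx <- match(v, c("A", "C", "G", "T"))
  if (any(is.na(idx) & v != "N")) stop("non-ACGTN character in window")
  m <- matrix(0L, nrow = length(v), ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1L
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' @param m Matrix as produced by [encode_window()].
#' @return Character scalar; all-zero rows decode to `N`.
#' @export
decode_window <- function(m) {
  base <- c("A", "C", "G", "T")[max.col(m, ties.method = "first")]
  base[rowSums(m) == 0L] <- "N"
  paste(base, collapse = "")
}

# n x (4W) design matrix for a character vector of equal-width windows
encode_batch <- function(seqs, W) {
  if (any(nchar(seqs) != W)) stop("all windows must have width ", W)
  v <- unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE)
  idx <- match(v, c("A", "C", "G", "T"))
  if (any(is.na(idx) & v != "N")) stop("non-ACGTN character in window")
  n <- length(seqs)
  X <- matrix(0, nrow = n, ncol = 4L * W)
  pos <- rep(seq_len(W), times = n)     # position within window
  row <- rep(seq_len(n), each = W)
  ok <- !is.na(idx)
  X[cbind(row[ok], (pos[ok] - 1L) * 4L + idx[ok])] <- 1
  X
}

#' Extract empirical priming windows downstream of read-1 alignments
#'
#' For each biological read-1 alignment, takes the `W` genome bases starting
#' at the read's 5'-most mapped locus and extending downstream in mRNA
#' orientation — the region the oligo(dT) primer annealed to. Minus-strand
#' windows are reverse-complemented so every window is mRNA-sense.
#' Alignments whose window would overrun a chromosome end are skipped; the
#' skip count is attached as an attribute.
#'
#' @param alignments data.frame with columns `chrom`, `pos` (0-based genomic
#'   coordinate of the read-1 5' base in sequencing orientation) and
#'   `strand` (mRNA sense, `+`/`-`).
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param W Window width (default 32).
#' @return data.frame of `PrimingWindowExample`s: `seq`, `label`
#'   (`"positive"`), `origin`; attribute `n_skipped`.
#' @export
extract_windows <- function(alignments, genome, W = 32L) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  W <- as.integer(W)
  stopifnot(all(c("chrom", "pos", "strand") %in% names(alignments)))
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(!alignments$chrom %in% names(genome))) {
    stop("alignment chromosome absent from genome")
  }
  lens <- clen[alignments$chrom]
  plus <- alignments$strand == "+"
  lo <- ifelse(plus, alignments$pos, alignments$pos - W + 1L)
  hi <- lo + W
  keep <- lo >= 0L & hi <= lens
  n_skipped <- sum(!keep)
  al <- alignments[keep, , drop = FALSE]
  lo <- lo[keep]
  seqs <- character(nrow(al))
  for (cn in unique(al$chrom)) {
    i <- al$chrom == cn
    chr <- as.character(genome[[cn]])
    seqs[i] <- substring(chr, lo[i] + 1L, lo[i] + W)
  }
  minus <- al$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp_vec(seqs[minus])
  out <- data.frame(seq = seqs, label = "positive",
                    origin = paste0(al$chrom, ":", al$pos, al$strand),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

revcomp_vec <- function(s) {
  if (!length(s)) return(s)
  as.character(reverseComplement(DNAStringSet(s)))
}

#' Sample background priming windows from a genome
#'
#' Draws `n` windows uniformly over valid genome positions and strands.
#' Windows that would pass the positive A-SNR pre-filter (a >=6 A-run with
#' at most one mismatch) are excluded and redrawn, so the background class
#' carries no plausibly-primable sequence.
#'
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param n Number of windows.
#' @param W Window width (default 32).
#' @param seed Integer seed.
#' @return data.frame of background `PrimingWindowExample`s.
#' @export
sample_background <- function(genome, n, W = 32L, seed = 1L) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  W <- as.integer(W)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  clen <- Biostrings::width(genome)
  usable <- clen >= W
  if (!any(usable)) stop("no chromosome is at least ", W, " bases long")
  chrs <- names(genome)[usable]
  weight <- (clen[usable] - W + 1)
  chr_str <- lapply(stats::setNames(chrs, chrs),
                    function(cn) as.character(genome[[cn]]))
  set.seed(as.integer(seed))
  out_seq <- character(0); out_origin <- character(0)
  guard <- 0L
  while (length(out_seq) < n) {
    m <- max(64L, 2L * (n - length(out_seq)))
    cn <- sample(chrs, m, replace = TRUE, prob = weight)
    pos <- vapply(cn, function(x) {
      sample.int(clen[names(genome) == x] - W + 1L, 1L) - 1L
    }, integer(1))
    strand <- sample(c("+", "-"), m, replace = TRUE)
    w <- mapply(function(x, p) substring(chr_str[[x]], p + 1L, p + W), cn, pos)
    minus <- strand == "-"
    w[minus] <- revcomp_vec(w[minus])
    pass <- vapply(w, function(s) length(find_asnr(s, 6L, 1L)) > 0L, logical(1))
    out_seq <- c(out_seq, w[!pass])
    out_origin <- c(out_origin, paste0(cn, ":", pos, strand)[!pass])
    guard <- guard + 1L
    if (guard > 10000L) stop("could not sample filter-failing backgrounds")
  }
  data.frame(seq = unname(out_seq[seq_len(n)]), label = "background",
             origin = unname(out_origin[seq_len(n)]),
             stringsAsFactors = FALSE)
}

#' A-SNR pre-filter for priming-window training examples
#'
#' Keeps exactly the windows containing an A-SNR of length at least
#' `min_len` with at most `max_mismatch` mismatches, dropping extracted
#' windows that could not plausibly have been primed (a mislabelling
#' source in empirical training data). Idempotent.
#'
#' @param examples data.frame with a `seq` column.
#' @param min_len,max_mismatch Filter parameters (defaults 6 and 1).
#' @return The filtered data.frame.
#' @export
filter_positives <- function(examples, min_len = 6L, max_mismatch = 1L) {
  keep <- vapply(examples$seq,
                 function(s) length(find_asnr(s, min_len, max_mismatch)) > 0L,
                 logical(1))
  examples[keep, , drop = FALSE]
}

#' Train the oligo(dT) binding-affinity classifier
#'
#' Trains a multilayer perceptron (one-hot input, two rectifier hidden
#' layers, sigmoid output, cross-entropy loss, mini-batch Adam) to separate
#' empirical priming windows from background sequence. A fixed number of
#' examples per class is held out before training and the held-out accuracy
#' at threshold 0.5 is recorded in the model metadata. Training is fully
#' determined by `seed`.
#'
#' @param positives,backgrounds data.frames with a `seq` column of
#'   equal-width windows (run [filter_positives()] on empirical positives
#'   first).
#' @param hidden Hidden layer sizes (default `c(64, 32)`).
#' @param epochs,batch_size,lr Optimizer settings.
#' @param holdout Held-out examples per class (default 1000, capped at a
#'   tenth of the smaller class).
#' @param seed Integer seed.
#' @return Object of class `binding_model`: layers, window width `W`, and
#'   `metadata` (seed, epochs, held-out accuracy, class sizes).
#' @export
train_binding <- function(positives, backgrounds, hidden = c(64L, 32L),
                          epochs = 12L, batch_size = 256L, lr = 1e-3,
                          holdout = 1000L, seed = 1L) {
  if (!nrow(positives) || !nrow(backgrounds)) {
    stop("both a positive and a background class are required")
  }
  W <- unique(nchar(c(positives$seq, backgrounds$seq)))
  if (length(W) != 1L) stop("all windows must share one width")
  holdout <- min(as.integer(holdout),
                 nrow(positives) %/% 10L, nrow(backgrounds) %/% 10L)
  holdout <- max(holdout, 1L)
  set.seed(as.integer(seed))
  hp <- sample.int(nrow(positives), holdout)
  hb <- sample.int(nrow(backgrounds), holdout)
  tr_seq <- c(positives$seq[-hp], backgrounds$seq[-hb])
  tr_y <- c(rep(1, nrow(positives) - holdout),
            rep(0, nrow(backgrounds) - holdout))
  ho_seq <- c(positives$seq[hp], backgrounds$seq[hb])
  ho_y <- c(rep(1, holdout), rep(0, holdout))

  X <- encode_batch(tr_seq, W)
  layers <- mlp_train(X, tr_y, hidden = hidden, epochs = epochs,
                      batch_size = batch_size, lr = lr, seed = seed)
  model <- structure(
    list(layers = layers, W = W,
         metadata = list(seed = as.integer(seed), epochs = as.integer(epochs),
                         hidden = as.integer(hidden),
                         n_positive = nrow(positives),
                         n_background = nrow(backgrounds),
                         holdout_per_class = holdout)),
    class = "binding_model"
  )
  ho_pred <- predict_binding(model, ho_seq)
  model$metadata$holdout_accuracy <- mean((ho_pred > 0.5) == (ho_y == 1))
  model
}

#' Predict binding probability for priming windows
#'
#' Returns the classifier probability in `[0, 1]` for each window. The
#' polyA-tail window (all `A`s) is by convention assigned probability
#' exactly 1: tail priming is taken as certain and only internal sites are
#' scored by the learned model.
#'
#' @param model A `binding_model`.
#' @param windows Character vector of windows of width `model$W`.
#' @return Numeric vector of probabilities.
#' @export
predict_binding <- function(model, windows) {
  stopifnot(inherits(model, "binding_model"))
  if (!length(windows)) return(numeric(0))
  if (any(nchar(windows) != model$W)) {
    stop("windows must have width ", model$W)
  }
  p <- mlp_predict(model$layers, encode_batch(windows, model$W))
  p <- pmin(pmax(p, 0), 1)
  p[toupper(windows) == strrep("A", model$W)] <- 1
  p
}

#' @export
print.binding_model <- function(x, ...) {
  cat("binding-affinity MLP: window width", x$W,
      "| hidden", paste(x$metadata$hidden, collapse = "x"),
      "| held-out accuracy",
      format(x$metadata$holdout_accuracy, digits = 3), "\n")
  invisible(x)
}

#' Synthetic planted-motif priming-window task
#'
#' Generates the package's reference binding-model training task: positive
#' windows are random sequence with one planted A-run of random length
#' (6-12 by default) at a random offset; background windows are random
#' sequence rejected until they fail the A-SNR pre-filter. This emulates
#' the contrast between primable and non-primable genomic sequence while
#' being exactly labelled.
#'
#' @param n_pos,n_bg Examples per class.
#' @param W Window width (default 32).
#' @param run_range Planted A-run length range (default 6..12).
#' @param seed Integer seed.
#' @return List of data.frames `positives` and `backgrounds`.
#' @export
simulate_priming_windows <- function(n_pos, n_bg, W = 32L,
                                     run_range = c(6L, 12L), seed = 1L) {
  set.seed(as.integer(seed))
  W <- as.integer(W)
  rand_windows <- function(m) {
    chars <- sample(c("A", "C", "G", "T"), m * W, replace = TRUE)
    do.call(paste0, split(chars, rep(seq_len(W), times = m)))
  }
  pos <- rand_windows(n_pos)
  run_len <- sample(run_range[1L]:run_range[2L], n_pos, replace = TRUE)
  off <- vapply(run_len, function(l) sample.int(W - l + 1L, 1L), integer(1))
  pos <- vapply(seq_len(n_pos), function(i) {
    paste0(substring(pos[i], 1L, off[i] - 1L), strrep("A", run_len[i]),
           substring(pos[i], off[i] + run_len[i], W))
  }, character(1))
  bg <- character(0)
  while (length(bg) < n_bg) {
    cand <- rand_windows(2L * (n_bg - length(bg)) + 16L)
    pass <- vapply(cand, function(s) length(find_asnr(s, 6L, 1L)) > 0L,
                   logical(1))
    bg <- c(bg, cand[!pass])
  }
  list(
    positives = data.frame(seq = pos, label = "positive",
                           origin = paste0("sim:", seed),
                           stringsAsFactors = FALSE),
    backgrounds = data.frame(seq = unname(bg[seq_len(n_bg)]),
                             label = "background",
                             origin = paste0("sim:", seed),
                             stringsAsFactors = FALSE)
  )
}
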