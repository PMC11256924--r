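#' Locate adenine single-nucleotide repeats (A-SNRs) in a DNA sequence
#'
#' Scans a sequence for runs of adenines that oligo(dT) primers can bind.
#' With `max_mismatch = 0` a site is a maximal run of at least `min_len`
#' consecutive `A`s. With `max_mismatch = 1` every window of `min_len` bases
#' containing at most one non-`A` base qualifies; overlapping qualifying
#' windows are merged into maximal regions and the start of each region is
#' reported. `N` never counts as an adenine.
#'
#' @param seq Character scalar over the alphabet `ACGTN` (case-insensitive).
#' @param min_len Minimum run length (default 6).
#' @param max_mismatch Number of tolerated non-`A` bases per window, 0 or 1.
#' @return Integer vector of 0-based start positions, ascending. Empty when
#'   no site qualifies.
#' @examples
#' find_asnr("CCAAAAAACC")            # 2
#' find_asnr("AAATAAA", max_mismatch = 1)
#' @export
find_asnr <- function(seq, min_len = 6L, max_mismatch = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  min_len <- as.integer(min_len)
  max_mismatch <- as.integer(max_mismatch)
  if (min_len < 1L) stop("min_len must be >= 1")
  if (!max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1")
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (length(v) && any(!v %in% c("A", "C", "G", "T", "N"))) {
    bad <- unique(v[!v %in% c("A", "C", "G", "T", "N")])
    stop("non-ACGTN character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  n <- length(v)
  if (n < min_len) return(integer(0))
  # windowed mismatch count via cumulative sum of non-A indicators
  mism <- cumsum(v != "A")
  starts <- seq_len(n - min_len + 1L)
  wmism <- mism[starts + min_len - 1L] - c(0L, mism)[starts]
  q <- starts[wmism <= max_mismatch]
  if (!length(q)) return(integer(0))
  # merge overlapping/adjacent qualifying windows into maximal regions
  new_region <- c(TRUE, diff(q) > min_len)
  sort(q[new_region]) - 1L
}
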