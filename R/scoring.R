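#' Precompute binding probabilities for every enumerated priming site
#'
#' Scores each priming-site window of the reference once with the binding
#' model so that per-read scoring only looks probabilities up. Tail sites
#' receive probability `tail_weight` x 1 (tail priming taken as certain);
#' internal sites are scored by the classifier.
#'
#' @param spliceu A `spliceu` object with sites enumerated
#'   (see [enumerate_priming_sites()]).
#' @param binding A `binding_model` with matching window width.
#' @param tail_weight Multiplier on the tail-site score expressing the
#'   relative preference for tail versus internal priming (default 1:
#'   the two priming classes are treated equally).
#' @return The `spliceu` object with a `pb` column added to `sites`.
#' @export
score_sites <- function(spliceu, binding, tail_weight = 1) {
  stopifnot(inherits(spliceu, "spliceu"), inherits(binding, "binding_model"))
  if (is.null(spliceu$sites)) stop("run enumerate_priming_sites() first")
  if (attr(spliceu$sites, "window_width") != binding$W) {
    stop("site window width ", attr(spliceu$sites, "window_width"),
         " does not match binding model width ", binding$W)
  }
  pb <- predict_binding(binding, spliceu$sites$window)
  tail <- spliceu$sites$kind == "polyA_tail"
  pb[tail] <- tail_weight * 1
  spliceu$sites$pb <- pb
  spliceu
}

#' Candidate priming sites downstream of a read-2 alignment
#'
#' For a read 2 whose 5' end maps at transcript position `x`, returns every
#' priming site lying downstream of the read body together with the implied
#' fragment length `d`: the fragment runs from `x` to the site — internal
#' sites end the fragment at the A-run start, the tail site at the
#' transcript 3' end. Sites implying `d` beyond the fragment-length support
#' (`max_d`) or a fragment shorter than the read (`site start < x +
#' read2_len`) are excluded.
#'
#' @param spliceu A `spliceu` object with enumerated sites.
#' @param key Record key.
#' @param x Transcript coordinate of the read-2 5' end (0-based).
#' @param read2_len Read-2 length in nt (default 91).
#' @param max_d Fragment-length support upper end (default 1000).
#' @return data.frame of candidate sites (`start`, `kind`, `window`, `d`,
#'   plus `pb` if sites have been scored).
#' @export
pbs_candidates <- function(spliceu, key, x, read2_len = 91L, max_d = 1000L) {
  tr <- spliceu$transcripts[spliceu$transcripts$key == key, ]
  if (!nrow(tr)) stop("unknown spliceu key: ", key)
  if (x < 0L || x >= tr$length) {
    stop("position ", x, " out of range for ", key, " (length ", tr$length, ")")
  }
  s <- spliceu$sites[spliceu$sites$key == key, , drop = FALSE]
  d <- s$start - x
  keep <- s$start >= x + read2_len & d <= max_d
  out <- s[keep, setdiff(names(s), "key"), drop = FALSE]
  out$d <- d[keep]
  rownames(out) <- NULL
  out
}

#' Fragment score of a read against one spliceu record
#'
#' The probability that the read arises from this record, defined as the
#' score of the most likely fragment: the maximum over candidate sites of
#' `p_f(d) * p_b(w)`. Zero when no candidate site exists.
#'
#' @inheritParams pbs_candidates
#' @param fraglen A `fraglen_model`.
#' @return List with `score` and, when positive, the best candidate row
#'   (`site_kind`, `site_start`, `d`).
#' @export
score_transcript <- function(spliceu, key, x, fraglen, read2_len = 91L) {
  cand <- pbs_candidates(spliceu, key, x, read2_len = read2_len,
                         max_d = fraglen$support[2L])
  if (!nrow(cand)) return(list(score = 0, site_kind = NA_character_,
                               site_start = NA_integer_, d = NA_integer_))
  if (is.null(cand$pb)) stop("sites are unscored; run score_sites() first")
  sc <- pf_eval(fraglen, cand$d) * cand$pb
  i <- which.max(sc)
  list(score = sc[i], site_kind = cand$kind[i],
       site_start = cand$start[i], d = cand$d[i])
}

#' Per-status score of a read against one gene
#'
#' The maximum fragment score over the gene's transcripts of the requested
#' splicing status that are compatible with the read; zero when none is.
#'
#' @param spliceu A `spliceu` object with scored sites.
#' @param hits data.frame of the read's mappings (`key`, `x`).
#' @param gene Gene identifier.
#' @param status `"spliced"` or `"unspliced"`.
#' @param fraglen A `fraglen_model`.
#' @param read2_len Read-2 length.
#' @return List with `score` and best-fragment fields (`key`, `site_kind`,
#'   `site_start`, `d`).
#' @export
score_status <- function(spliceu, hits, gene, status, fraglen,
                         read2_len = 91L) {
  tt <- spliceu$transcripts
  keys <- tt$key[tt$gene_id == gene & tt$status == status]
  hh <- hits[hits$key %in% keys, , drop = FALSE]
  best <- list(score = 0, key = NA_character_, site_kind = NA_character_,
               site_start = NA_integer_, d = NA_integer_)
  for (j in seq_len(nrow(hh))) {
    sc <- score_transcript(spliceu, hh$key[j], hh$x[j], fraglen, read2_len)
    if (sc$score > best$score) {
      best <- c(list(score = sc$score, key = hh$key[j]),
                sc[c("site_kind", "site_start", "d")])
    }
  }
  best
}

#' Probability that a read is spliced with respect to a gene
#'
#' `Pr(spliced | read, gene) = Pr(s) / (Pr(s) + Pr(u))` where each term is
#' the per-status fragment score. Undefined (`NA`) when both scores are 0.
#'
#' @inheritParams score_status
#' @return List with `pr_spliced` (`NA` when undefined), `score_spliced`,
#'   `score_unspliced`.
#' @export
splice_prob <- function(spliceu, hits, gene, fraglen, read2_len = 91L) {
  s <- score_status(spliceu, hits, gene, "spliced", fraglen, read2_len)
  u <- score_status(spliceu, hits, gene, "unspliced", fraglen, read2_len)
  denom <- s$score + u$score
  list(pr_spliced = if (denom > 0) s$score / denom else NA_real_,
       score_spliced = s$score, score_unspliced = u$score,
       best_spliced = s, best_unspliced = u)
}

#' Predict splicing status and gene of origin for a set of reads
#'
#' The full scorer: for each read, every (gene, status) pair reachable from
#' its mappings is scored by the best fragment, the gene with the overall
#' maximum score is assigned (exact ties are reported as ties, with no
#' single-gene prediction), and the per-gene spliced probability yields the
#' status call. Reads whose spliced and unspliced evidence is equal (within
#' `ambig_eps` of 0.5) or absent are called ambiguous; reads with no valid
#' candidate fragment at all are additionally flagged `no_candidate`.
#'
#' @param mappings data.frame with one row per (read, transcript) mapping:
#'   `read_id`, `key` (spliceu record key), `x` (transcript coordinate of
#'   the read-2 5' end).
#' @param spliceu A `spliceu` object with scored sites (see
#'   [score_sites()]).
#' @param fraglen A `fraglen_model`.
#' @param read2_len Read-2 length in nt (default 91).
#' @param ambig_eps Half-width of the ambiguity band around 0.5
#'   (default 1e-9).
#' @return data.frame with one row per read: `read_id`, `assigned_gene`
#'   (`NA` on a tie), `tie`, `n_genes`, `pr_spliced`, `status_call`
#'   (`spliced`/`unspliced`/`ambiguous`), `no_candidate`, and best-fragment
#'   fields (`best_key`, `best_site_kind`, `best_d`, `best_score`).
#' @export
predict_reads <- function(mappings, spliceu, fraglen, read2_len = 91L,
                          ambig_eps = 1e-9) {
  stopifnot(all(c("read_id", "key", "x") %in% names(mappings)))
  unknown <- setdiff(unique(mappings$key), spliceu$transcripts$key)
  if (length(unknown)) {
    stop("unknown transcript key(s) in mappings: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  if (is.null(spliceu$sites$pb)) stop("run score_sites() first")
  key2gene <- stats::setNames(spliceu$transcripts$gene_id,
                              spliceu$transcripts$key)
  by_read <- split(mappings[, c("key", "x")], mappings$read_id)
  out <- vector("list", length(by_read))
  for (i in seq_along(by_read)) {
    hits <- by_read[[i]]
    hits <- unique(hits)
    genes <- sort(unique(key2gene[hits$key]))
    per_gene <- lapply(genes, function(g) {
      splice_prob(spliceu, hits, g, fraglen, read2_len)
    })
    gene_best <- vapply(per_gene, function(p) {
      max(p$score_spliced, p$score_unspliced)
    }, numeric(1))
    top <- max(gene_best)
    winners <- which(gene_best == top)
    tie <- length(winners) > 1L || top == 0
    gi <- winners[1L]
    p <- per_gene[[gi]]
    pr <- p$pr_spliced
    no_cand <- top == 0
    status <- if (is.na(pr) || abs(pr - 0.5) <= ambig_eps) {
      "ambiguous"
    } else if (pr > 0.5) "spliced" else "unspliced"
    bf <- if (p$score_spliced >= p$score_unspliced) p$best_spliced else p$best_unspliced
    out[[i]] <- data.frame(
      read_id = names(by_read)[i],
      assigned_gene = if (tie) NA_character_ else genes[gi],
      tie = tie, n_genes = length(genes),
      pr_spliced = pr, status_call = status, no_candidate = no_cand,
      best_key = bf$key, best_site_kind = bf$site_kind,
      best_d = bf$d, best_score = top,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
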