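# Ground-truth labelling of paired-end reads with an exonic read 2, by
# transcript-compatibility set intersections against the spliceu reference.
# An alignment here is a set of genomic blocks on one chromosome; a
# fragment is a (read 1, read 2) pair of alignments.

# labeler exon set of a record in transcript coordinates: real exons for
# spliced records, the whole span (one exon) for unspliced records
labeler_exons_tx <- function(spliceu, key) {
  tr <- spliceu$transcripts[spliceu$transcripts$key == key, ]
  if (tr$status == "spliced") {
    spliceu$blocks[[key]][, c("tx_start", "tx_end")]
  } else {
    data.frame(tx_start = 0L, tx_end = tr$length)
  }
}

#' Exon containment of an alignment against every spliceu record
#'
#' For each record, reports whether every alignment block lies inside an
#' exon of that record (for unspliced records the single "exon" is the
#' genomic span). This is the block-level containment mark used to build
#' the exonic compatibility sets.
#'
#' @param spliceu A `spliceu` object.
#' @param gblocks data.frame of genomic blocks (`g_start`, `g_end`),
#'   0-based half-open, sorted or not.
#' @param chrom Chromosome of the alignment.
#' @return Named logical vector over record keys on that chromosome.
#' @export
exon_containment <- function(spliceu, gblocks, chrom) {
  keys <- spliceu$transcripts$key[spliceu$transcripts$chrom == chrom]
  vapply(stats::setNames(keys, keys), function(k) {
    ex <- spliceu$blocks[[k]]  # genomic exon intervals (span for unspliced)
    all(vapply(seq_len(nrow(gblocks)), function(j) {
      any(ex$g_start <= gblocks$g_start[j] & ex$g_end >= gblocks$g_end[j])
    }, logical(1)))
  }, logical(1))
}

# compatibility + single-exon containment of one read against one record.
# Returns NULL if not compatible, else list(start, end, exon = index of the
# single labeler-exon containing the read or NA if it spans several).
read_vs_record <- function(spliceu, key, gblocks, chrom) {
  tx <- genome_to_tx(spliceu, key, gblocks, chrom)
  if (is.null(tx)) return(NULL)
  ex <- labeler_exons_tx(spliceu, key)
  tx$exon <- exon_index_of(ex, tx$start, tx$end)
  tx
}

#' Classify one paired-end read against the spliceu reference
#'
#' Implements the ground-truth labelling rules for reads whose read 2 is
#' exonic. Compatibility sets are computed over all records: `T_pe`
#' (records explaining the pair, with read 2 upstream of read 1 and an
#' implied fragment length of at most `max_insert`), `T_er1` and `T_er2`
#' (records where the respective read lies inside one exon). The rules,
#' applied in order:
#' \describe{
#'   \item{spliced_e_and_e}{`T_pe & T_er1 & T_er2` non-empty, all spliced,
#'     read 1 and read 2 in different exons in every such record, and the
#'     genomic gap between those exons exceeds `min_exon_gap` nt (guards
#'     against short introns that a fragment could span entirely).}
#'   \item{spliced_e_dot_e}{the triple intersection is empty but
#'     `T_pe & T_er2` is non-empty and all spliced: read 1 spans an
#'     exon-exon junction.}
#'   \item{unspliced_i_or_ie}{`T_pe & T_er1` non-empty and all unspliced:
#'     read 1 is intronic or spans an intron-exon junction.}
#' }
#' Reads matching no rule, with a non-exonic read 2, or whose pair maps to
#' more than one gene are skipped with a reason.
#'
#' @param spliceu A `spliceu` object.
#' @param r1_blocks,r2_blocks data.frames of genomic blocks (`g_start`,
#'   `g_end`) for biological read 1 and read 2.
#' @param chrom Chromosome.
#' @param max_insert Maximum implied fragment length for pair compatibility
#'   (default 1000, the fragment-length support).
#' @param min_exon_gap Genomic distance guard for `spliced_e_and_e`
#'   (default 1000).
#' @return List with `label` (`spliced_e_and_e`, `spliced_e_dot_e`,
#'   `unspliced_i_or_ie` or `skipped`), `status` (`spliced`, `unspliced` or
#'   `NA`), `reason`, and the compatibility sets.
#' @export
classify_pair <- function(spliceu, r1_blocks, r2_blocks, chrom,
                          max_insert = 1000L, min_exon_gap = 1000L) {
  tt <- spliceu$transcripts
  keys <- tt$key[tt$chrom == chrom]
  c1 <- lapply(stats::setNames(keys, keys), function(k)
    read_vs_record(spliceu, k, r1_blocks, chrom))
  c2 <- lapply(stats::setNames(keys, keys), function(k)
    read_vs_record(spliceu, k, r2_blocks, chrom))

  t_er1 <- keys[vapply(keys, function(k)
    !is.null(c1[[k]]) && !is.na(c1[[k]]$exon), logical(1))]
  t_er2 <- keys[vapply(keys, function(k)
    !is.null(c2[[k]]) && !is.na(c2[[k]]$exon), logical(1))]
  t_pe <- keys[vapply(keys, function(k) {
    if (is.null(c1[[k]]) || is.null(c2[[k]])) return(FALSE)
    c2[[k]]$start <= c1[[k]]$start &&
      (c1[[k]]$end - c2[[k]]$start) <= max_insert
  }, logical(1))]

  sets <- list(t_pe = t_pe, t_er1 = t_er1, t_er2 = t_er2)
  skip <- function(reason) c(list(label = "skipped", status = NA_character_,
                                  reason = reason), sets)
  status_of <- function(k) tt$status[match(k, tt$key)]
  # gate: read 2 must sit inside an *annotated* exon (containment in the
  # unspliced span alone means read 2 is intronic, hence determinative by
  # itself and outside this procedure)
  if (!any(status_of(t_er2) == "spliced")) return(skip("read2_not_exonic"))
  if (length(unique(tt$gene_id[match(t_pe, tt$key)])) > 1L) {
    return(skip("multi_gene"))
  }

  that <- intersect(intersect(t_pe, t_er1), t_er2)
  if (length(that) && all(status_of(that) == "spliced")) {
    diff_exon <- vapply(that, function(k)
      c1[[k]]$exon != c2[[k]]$exon, logical(1))
    far_apart <- vapply(that, function(k) {
      e1 <- c1[[k]]$exon; e2 <- c2[[k]]$exon
      if (e1 == e2) return(FALSE)
      bl <- spliceu$blocks[[k]]
      # gap-wise genomic distance between the two exons
      g <- sort(c(bl$g_start[c(e1, e2)], bl$g_end[c(e1, e2)]))
      (g[3L] - g[2L]) > min_exon_gap
    }, logical(1))
    if (all(diff_exon & far_apart)) {
      return(c(list(label = "spliced_e_and_e", status = "spliced",
                    reason = "e_and_e"), sets))
    }
    return(skip(if (all(diff_exon)) "exon_gap_too_small" else "same_exon"))
  }
  if (!length(that)) {
    pe2 <- intersect(t_pe, t_er2)
    if (length(pe2) && all(status_of(pe2) == "spliced")) {
      return(c(list(label = "spliced_e_dot_e", status = "spliced",
                    reason = "e_dot_e"), sets))
    }
  }
  pe1 <- intersect(t_pe, t_er1)
  if (length(pe1) && all(status_of(pe1) == "unspliced")) {
    return(c(list(label = "unspliced_i_or_ie", status = "unspliced",
                  reason = "i_or_ie"), sets))
  }
  skip("no_rule")
}

# project a transcript-space read of a simulated fragment to genomic blocks
frag_read_blocks <- function(spliceu, key, start, end) {
  g <- project_to_genome(spliceu, key, start, end)
  g[order(g$g_start), , drop = FALSE]
}

#' Map a read-2 alignment to every compatible spliceu record
#'
#' Emulates a transcriptome alignment of read 2 treated as single-end: the
#' read's genomic blocks are tested for compatibility against every record
#' on the chromosome, and the transcript coordinate of the read's 5' end is
#' returned for each compatible record.
#'
#' @param spliceu A `spliceu` object.
#' @param gblocks Genomic blocks of the read-2 alignment.
#' @param chrom Chromosome.
#' @return data.frame with `key` and `x` (one row per compatible record).
#' @export
map_read2 <- function(spliceu, gblocks, chrom) {
  tt <- spliceu$transcripts
  keys <- tt$key[tt$chrom == chrom]
  res <- lapply(keys, function(k) {
    tx <- genome_to_tx(spliceu, k, gblocks, chrom)
    if (is.null(tx)) return(NULL)
    data.frame(key = k, x = tx$start, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(key = character(0), x = integer(0)) else out
}

#' Label simulated fragments and emit read-2 mappings for evaluation
#'
#' Runs every simulated fragment through the paired-end ground-truth
#' labeller and, for each labelled read, maps its read 2 (single-end) to
#' all compatible spliceu records — the evaluation set on which the scorer
#' is assessed against the labels.
#'
#' @param fragments Fragment table from [simulate_reads()].
#' @param spliceu A `spliceu` object with sites enumerated.
#' @param max_insert,min_exon_gap As in [classify_pair()].
#' @return List with `labels` (read_id, label, status, reason — every input
#'   read, skipped ones included), `mappings` (read_id, key, x for labelled
#'   reads) and `skip_counts` (table of skip reasons).
#' @export
build_eval_set <- function(fragments, spliceu, max_insert = 1000L,
                           min_exon_gap = 1000L) {
  if (is.null(fragments) || !nrow(fragments)) {
    return(list(labels = data.frame(read_id = character(0),
                                    label = character(0),
                                    status = character(0),
                                    reason = character(0)),
                mappings = data.frame(read_id = character(0),
                                      key = character(0), x = integer(0)),
                skip_counts = table(character(0))))
  }
  tt <- spliceu$transcripts
  labels <- vector("list", nrow(fragments))
  maps <- vector("list", nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    key <- fragments$key[i]
    chrom <- tt$chrom[match(key, tt$key)]
    b1 <- frag_read_blocks(spliceu, key, fragments$read1_start[i],
                           fragments$read1_end[i])
    b2 <- frag_read_blocks(spliceu, key, fragments$read2_start[i],
                           fragments$read2_end[i])
    cl <- classify_pair(spliceu, b1, b2, chrom, max_insert, min_exon_gap)
    labels[[i]] <- data.frame(read_id = fragments$read_id[i],
                              label = cl$label, status = cl$status,
                              reason = cl$reason, stringsAsFactors = FALSE)
    if (cl$label != "skipped") {
      mp <- map_read2(spliceu, b2, chrom)
      if (nrow(mp)) {
        mp$read_id <- fragments$read_id[i]
        maps[[i]] <- mp[, c("read_id", "key", "x")]
      }
    }
  }
  labels <- do.call(rbind, labels)
  mappings <- do.call(rbind, maps)
  if (is.null(mappings)) {
    mappings <- data.frame(read_id = character(0), key = character(0),
                           x = integer(0))
  }
  rownames(labels) <- rownames(mappings) <- NULL
  list(labels = labels, mappings = mappings,
       skip_counts = table(labels$reason[labels$label == "skipped"]))
}
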