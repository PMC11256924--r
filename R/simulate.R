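#' Generate a synthetic toy genome and annotation with planted A-SNRs
#'
#' Builds a small multi-gene reference for training and testing without any
#' external download: multi-exon genes on both strands, random intergenic
#' and intronic sequence with background A-runs of length >= 6 scrubbed, and
#' a known set of planted A-runs in exons and introns whose positions are
#' returned as a truth table. Deterministic for a given seed.
#'
#' @param n_genes Number of genes (default 20).
#' @param n_chroms Number of chromosomes genes are distributed over.
#' @param n_exon_range,exon_range,intron_range Ranges (inclusive) for the
#'   per-gene exon count and per-element lengths in bp.
#' @param arun_rate_exon,arun_rate_intron Expected planted A-runs per kb of
#'   exon / intron (defaults 1 and 1.5; introns are modestly enriched for
#'   primable A-SNRs relative to exons, as in real genomes).
#' @param run_len_range Planted run length range (default 6..12).
#' @param intergenic Intergenic spacer length in bp.
#' @param seed Integer seed.
#' @return List with `genome` (named `DNAStringSet`), `exons` (annotation
#'   table as in [read_gtf_exons()]; one transcript per gene), and
#'   `arun_truth` (data.frame of planted runs: `gene_id`, `chrom`,
#'   `element`, `element_index`, `g_start`, `run_len`).
#' @export
generate_toy_reference <- function(n_genes = 20L, n_chroms = 2L,
                                   n_exon_range = c(3L, 5L),
                                   exon_range = c(150L, 400L),
                                   intron_range = c(600L, 2500L),
                                   arun_rate_exon = 1.0,
                                   arun_rate_intron = 1.5,
                                   run_len_range = c(6L, 12L),
                                   intergenic = 500L, seed = 1L) {
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) {
    v <- sample(bases, n, replace = TRUE)
    # scrub background A- and T-runs of length >= 6 (a genomic T-run is an
    # A-SNR on the minus strand) so every detectable site is planted
    repeat {
      s <- paste(v, collapse = "")
      runs <- c(find_asnr(s, 6L, 0L), find_asnr(chartr("AT", "TA", s), 6L, 0L))
      if (!length(runs)) return(v)
      v[runs + 3L] <- sample(c("C", "G"), length(runs), replace = TRUE)
    }
  }

  chrom_of <- rep_len(paste0("chr", seq_len(n_chroms)), n_genes)
  cursor <- stats::setNames(rep(0L, n_chroms), paste0("chr", seq_len(n_chroms)))
  chrom_seq <- stats::setNames(vector("list", n_chroms),
                               paste0("chr", seq_len(n_chroms)))
  for (cn in names(chrom_seq)) chrom_seq[[cn]] <- character(0)

  exons <- list(); truth <- list()
  for (gi in seq_len(n_genes)) {
    gene_id <- sprintf("gene%02d", gi)
    cn <- chrom_of[gi]
    strand <- sample(c("+", "-"), 1L)
    n_exon <- sample(n_exon_range[1L]:n_exon_range[2L], 1L)
    ex_len <- sample(exon_range[1L]:exon_range[2L], n_exon, replace = TRUE)
    in_len <- if (n_exon > 1L) {
      sample(intron_range[1L]:intron_range[2L], n_exon - 1L, replace = TRUE)
    } else integer(0)

    gene_start <- cursor[[cn]] + intergenic
    spacer <- rand_seq(intergenic)
    elements <- list()      # per element: type, index, len, chars
    for (e in seq_len(n_exon)) {
      elements[[length(elements) + 1L]] <-
        list(type = "exon", index = e, chars = rand_seq(ex_len[e]))
      if (e < n_exon) {
        elements[[length(elements) + 1L]] <-
          list(type = "intron", index = e, chars = rand_seq(in_len[e]))
      }
    }

    # plant A-runs in transcript sense (genomic T-runs for minus-strand
    # genes), flanked by non-run bases so run bounds are exact
    run_base <- if (strand == "+") "A" else "T"
    flank_pool <- c("C", "G")
    off <- gene_start
    for (el in elements) {
      len <- length(el$chars)
      rate <- if (el$type == "exon") arun_rate_exon else arun_rate_intron
      k <- stats::rpois(1L, rate * len / 1000)
      placed <- integer(0)
      for (j in seq_len(k)) {
        rl <- sample(run_len_range[1L]:run_len_range[2L], 1L)
        if (len < rl + 4L) next
        for (try in seq_len(20L)) {
          p <- sample.int(len - rl - 2L, 1L) + 1L  # 1-based, margin 1 each side
          if (!any(abs(p - placed) < rl + 8L)) { placed <- c(placed, p); break }
          p <- NA_integer_
        }
        if (is.na(p)) next
        el$chars[p:(p + rl - 1L)] <- run_base
        el$chars[p - 1L] <- sample(flank_pool, 1L)
        el$chars[p + rl] <- sample(flank_pool, 1L)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gene_id, chrom = cn, element = el$type,
          element_index = el$index, g_start = off + p - 1L, run_len = rl,
          strand = strand, stringsAsFactors = FALSE
        )
      }
      # record exon coordinates
      if (el$type == "exon") {
        exons[[length(exons) + 1L]] <- data.frame(
          gene_id = gene_id,
          transcript_id = paste0(gene_id, ".t1"),
          chrom = cn, strand = strand,
          start = off, end = off + len,
          stringsAsFactors = FALSE
        )
      }
      chrom_seq[[cn]] <- c(chrom_seq[[cn]], spacer, el$chars)
      spacer <- character(0)
      off <- off + len
    }
    cursor[[cn]] <- off
  }
  for (cn in names(chrom_seq)) {
    chrom_seq[[cn]] <- c(chrom_seq[[cn]], rand_seq(intergenic))
  }

  genome <- DNAStringSet(vapply(chrom_seq, paste, character(1), collapse = ""))
  names(genome) <- names(chrom_seq)
  list(
    genome = genome,
    exons = do.call(rbind, exons),
    arun_truth = if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(0), chrom = character(0),
                 element = character(0), element_index = integer(0),
                 g_start = integer(0), run_len = integer(0),
                 strand = character(0))
  )
}

#' Write a toy reference to FASTA and GTF
#'
#' @param ref List as returned by [generate_toy_reference()].
#' @param dir Output directory.
#' @return Invisibly, the paths written (`fasta`, `gtf`, `arun_truth`).
#' @export
write_toy_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  tru <- file.path(dir, "arun_truth.tsv")
  writeXStringSet(ref$genome, fa)
  gr <- GRanges(
    seqnames = ref$exons$chrom,
    ranges = IRanges(start = ref$exons$start + 1L, end = ref$exons$end),
    strand = ref$exons$strand
  )
  mcols(gr)$source <- "spliceprime"
  mcols(gr)$type <- "exon"
  mcols(gr)$gene_id <- ref$exons$gene_id
  mcols(gr)$transcript_id <- ref$exons$transcript_id
  rtracklayer::export(gr, gtf, format = "gtf")
  utils::write.table(ref$arun_truth, tru, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fa, gtf = gtf, arun_truth = tru))
}

# exon index containing tx interval [a, b), or NA when it straddles or
# falls outside every annotated exon of the record
exon_index_of <- function(exons_tx, a, b) {
  i <- which(exons_tx$tx_start <= a & exons_tx$tx_end >= b)
  if (length(i) == 1L) i else NA_integer_
}

#' Simulate splice-aware paired-end reads from a spliceu reference
#'
#' For each (gene, status) pair the requested number of fragments is drawn
#' by rejection sampling: pick a transcript of that status uniformly, a
#' priming site uniformly from the record's ordered candidate list (tail
#' included), and a fragment length from the supplied distribution; the
#' fragment of that length ends at the site. Fragments that would start
#' before the transcript 5' end, are shorter than read 2, or whose read 2
#' is not entirely inside one annotated exon are rejected and resampled, up
#' to `max_attempts` attempts per (gene, status) pair; any shortfall is
#' reported. In `"no_fundamental"` mode, tail-primed fragments and
#' fragments whose read 1 falls inside the same exon as read 2 are also
#' rejected, so no emitted fragment is fundamentally ambiguous.
#'
#' @param counts data.frame with `gene_id`, `n_spliced`, `n_unspliced`.
#' @param spliceu A `spliceu` object with sites enumerated.
#' @param fraglen A `fraglen_model` to draw fragment lengths from.
#' @param mode `"ambiguous_only"` (default; read 2 exonic) or
#'   `"no_fundamental"`.
#' @param read2_len,read1_len Read lengths (defaults 91 and 31, the cycle
#'   lengths of the reference chemistry).
#' @param max_attempts Attempt cap per (gene, status) pair.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `fragments` (one row per emitted read pair: ids,
#'   truth fields, site, `d`, transcript spans and sequences of both reads,
#'   `fundamental_ambiguity`) and `shortfall` (per (gene, status):
#'   requested, emitted, attempts).
#' @export
simulate_reads <- function(counts, spliceu, fraglen,
                           mode = c("ambiguous_only", "no_fundamental"),
                           read2_len = 91L, read1_len = 31L,
                           max_attempts = 100000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(spliceu, "spliceu"), inherits(fraglen, "fraglen_model"))
  if (is.null(spliceu$sites)) stop("run enumerate_priming_sites() first")
  req <- c("gene_id", "n_spliced", "n_unspliced")
  if (!all(req %in% names(counts))) {
    stop("counts must have columns: ", paste(req, collapse = ", "))
  }
  unknown <- setdiff(counts$gene_id, spliceu$transcripts$gene_id)
  if (length(unknown)) {
    stop("unknown gene(s) in counts: ", paste(unknown, collapse = ", "))
  }
  set.seed(as.integer(seed))
  tt <- spliceu$transcripts
  sites_by_key <- split(spliceu$sites, spliceu$sites$key)
  out <- list(); short <- list()
  for (ci in seq_len(nrow(counts))) {
    gene <- counts$gene_id[ci]
    for (status in c("spliced", "unspliced")) {
      want <- if (status == "spliced") counts$n_spliced[ci] else counts$n_unspliced[ci]
      want <- as.integer(want)
      if (want <= 0L) next
      keys <- tt$key[tt$gene_id == gene & tt$status == status]
      if (!length(keys)) stop("gene ", gene, " has no ", status, " transcript")
      got <- list(); n_got <- 0L; attempts <- 0L
      while (n_got < want && attempts < max_attempts) {
        m <- min(8192L, max(64L, 4L * (want - n_got)))
        m <- min(m, max_attempts - attempts)
        attempts <- attempts + m
        key <- sample(keys, m, replace = TRUE)
        d <- sample_fraglen(fraglen, m)
        acc <- draw_fragments(key, d, spliceu, sites_by_key, mode,
                              read2_len, read1_len)
        if (nrow(acc)) {
          got[[length(got) + 1L]] <- acc
          n_got <- n_got + nrow(acc)
        }
      }
      frag <- if (length(got)) utils::head(do.call(rbind, got), want) else NULL
      emitted <- if (is.null(frag)) 0L else nrow(frag)
      short[[length(short) + 1L]] <- data.frame(
        gene_id = gene, status = status, requested = want,
        emitted = emitted, shortfall = want - emitted, attempts = attempts,
        stringsAsFactors = FALSE
      )
      if (emitted) {
        frag$gene_id <- gene
        frag$truth_status <- status
        frag$read_id <- sprintf("sim_%s_%s_%04d", gene,
                                substr(status, 1L, 1L), seq_len(emitted))
        out[[length(out) + 1L]] <- frag
      }
    }
  }
  fragments <- if (length(out)) do.call(rbind, out) else NULL
  if (!is.null(fragments)) {
    rownames(fragments) <- NULL
    fragments <- fragments[, c("read_id", "gene_id", "key", "truth_status",
                               "site_kind", "site_start", "d",
                               "read2_start", "read2_end", "read2_seq",
                               "read1_start", "read1_end", "read1_seq",
                               "fundamental_ambiguity")]
  }
  list(fragments = fragments, shortfall = do.call(rbind, short))
}

# vectorized accept/reject for one batch of (key, d) draws
draw_fragments <- function(key, d, spliceu, sites_by_key, mode,
                           read2_len, read1_len) {
  m <- length(key)
  site_idx <- integer(m); site_start <- integer(m); site_kind <- character(m)
  for (k in unique(key)) {
    s <- sites_by_key[[k]]
    i <- which(key == k)
    pick <- sample.int(nrow(s), length(i), replace = TRUE)
    site_start[i] <- s$start[pick]
    site_kind[i] <- s$kind[pick]
  }
  frag_end <- site_start
  frag_start <- frag_end - d
  ok <- frag_start >= 0L & d >= read2_len
  if (!any(ok)) return(empty_fragments())
  key <- key[ok]; d <- d[ok]
  frag_start <- frag_start[ok]; frag_end <- frag_end[ok]
  site_start <- site_start[ok]; site_kind <- site_kind[ok]

  r2s <- frag_start; r2e <- frag_start + read2_len
  r1e <- frag_end; r1s <- frag_end - read1_len
  r2_exon <- integer(length(key)); r1_exon <- integer(length(key))
  whole_exon <- integer(length(key))
  for (k in unique(key)) {
    ex <- spliceu$exons_tx[[k]]
    i <- which(key == k)
    r2_exon[i] <- vapply(i, function(j) exon_index_of(ex, r2s[j], r2e[j]),
                         integer(1))
    r1_exon[i] <- vapply(i, function(j) exon_index_of(ex, r1s[j], r1e[j]),
                         integer(1))
    whole_exon[i] <- vapply(i, function(j)
      exon_index_of(ex, frag_start[j], frag_end[j]), integer(1))
  }
  keep <- !is.na(r2_exon)
  if (mode == "no_fundamental") {
    keep <- keep & site_kind != "polyA_tail" &
      !(!is.na(r1_exon) & r1_exon == r2_exon)
  }
  if (!any(keep)) return(empty_fragments())
  key <- key[keep]; d <- d[keep]
  frag_start <- frag_start[keep]; frag_end <- frag_end[keep]
  site_start <- site_start[keep]; site_kind <- site_kind[keep]
  r2s <- r2s[keep]; r2e <- r2e[keep]; r1s <- r1s[keep]; r1e <- r1e[keep]
  r2_exon <- r2_exon[keep]; whole_exon <- whole_exon[keep]

  n_exons <- vapply(key, function(k) nrow(spliceu$exons_tx[[k]]), integer(1))
  term_start <- vapply(key, function(k) {
    ex <- spliceu$exons_tx[[k]]
    ex$tx_start[nrow(ex)]
  }, integer(1))
  fund <- (site_kind == "polyA_tail" & frag_start >= term_start) |
    (site_kind != "polyA_tail" & !is.na(whole_exon))

  seqs <- spliceu$sequences[key]
  data.frame(
    key = key,
    site_kind = site_kind, site_start = site_start, d = d,
    read2_start = r2s, read2_end = r2e,
    read2_seq = substring(seqs, r2s + 1L, r2e),
    read1_start = r1s, read1_end = r1e,
    read1_seq = substring(seqs, r1s + 1L, r1e),
    fundamental_ambiguity = fund,
    stringsAsFactors = FALSE
  )
}

empty_fragments <- function() {
  data.frame(key = character(0), site_kind = character(0),
             site_start = integer(0), d = integer(0),
             read2_start = integer(0), read2_end = integer(0),
             read2_seq = character(0), read1_start = integer(0),
             read1_end = integer(0), read1_seq = character(0),
             fundamental_ambiguity = logical(0), stringsAsFactors = FALSE)
}

#' Draw one fragment for a gene and status
#'
#' Single-fragment interface over the batch sampler: one attempt — a
#' transcript, site and length draw plus the geometric validity check — is
#' made and either a one-row fragment table or `NULL` (rejection) is
#' returned. Exon-containment filtering belongs to [simulate_reads()];
#' here only the geometry (fragment fits the transcript and is at least as
#' long as read 2) is enforced.
#'
#' @inheritParams simulate_reads
#' @param gene Gene identifier.
#' @param status `"spliced"` or `"unspliced"`.
#' @return A one-row data.frame or `NULL` on rejection.
#' @export
sample_fragment <- function(gene, status, spliceu, fraglen,
                            read2_len = 91L, read1_len = 31L) {
  tt <- spliceu$transcripts
  keys <- tt$key[tt$gene_id == gene & tt$status == status]
  if (!length(keys)) stop("gene ", gene, " has no ", status, " transcript")
  sites_by_key <- split(spliceu$sites, spliceu$sites$key)
  key <- sample(keys, 1L)
  d <- sample_fraglen(fraglen, 1L)
  s <- sites_by_key[[key]]
  pick <- sample.int(nrow(s), 1L)
  frag_end <- s$start[pick]
  frag_start <- frag_end - d
  if (frag_start < 0L || d < read2_len) return(NULL)
  seqs <- spliceu$sequences[[key]]
  ex <- spliceu$exons_tx[[key]]
  data.frame(
    key = key, site_kind = s$kind[pick], site_start = s$start[pick], d = d,
    read2_start = frag_start, read2_end = frag_start + read2_len,
    read2_seq = substring(seqs, frag_start + 1L, frag_start + read2_len),
    read1_start = frag_end - read1_len, read1_end = frag_end,
    read1_seq = substring(seqs, frag_end - read1_len + 1L, frag_end),
    stringsAsFactors = FALSE
  )
}

#' Apply a uniform substitution error model to simulated reads
#'
#' Each base of each read is substituted, independently with probability
#' `sub_rate`, by a uniformly chosen different base. Truth coordinates are
#' unchanged. Seeded and deterministic.
#'
#' @param fragments Fragment table from [simulate_reads()].
#' @param sub_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The fragment table with mutated `read1_seq` / `read2_seq`.
#' @export
add_read_errors <- function(fragments, sub_rate, seed = 1L) {
  if (sub_rate < 0 || sub_rate > 1) stop("sub_rate must be in [0, 1]")
  if (sub_rate == 0 || is.null(fragments) || !nrow(fragments)) return(fragments)
  set.seed(as.integer(seed))
  mutate <- function(seqs) {
    v <- strsplit(seqs, "", fixed = TRUE)
    lens <- lengths(v)
    flat <- unlist(v, use.names = FALSE)
    hit <- stats::runif(length(flat)) < sub_rate
    if (any(hit)) {
      # uniformly random *different* base: shift by 1..3 in base order
      bases <- c("A", "C", "G", "T")
      cur <- match(flat[hit], bases)
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      flat[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }
    vapply(split(flat, rep(seq_along(lens), lens)), paste, character(1),
           collapse = "")
  }
  fragments$read2_seq <- unname(mutate(fragments$read2_seq))
  fragments$read1_seq <- unname(mutate(fragments$read1_seq))
  fragments
}

#' Write simulated reads as paired FASTQ plus a truth table
#'
#' @param fragments Fragment table from [simulate_reads()].
#' @param dir Output directory.
#' @param prefix File name prefix (default `"sim"`).
#' @return Invisibly, the paths written (`r1`, `r2`, `truth`).
#' @export
write_sim_fastq <- function(fragments, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
  r2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
  tru <- file.path(dir, paste0(prefix, "_truth.tsv"))
  fq <- function(path, ids, seqs) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), con, sep = "\n")
  }
  fq(r1, fragments$read_id, fragments$read1_seq)
  fq(r2, fragments$read_id, fragments$read2_seq)
  utils::write.table(fragments, tru, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(r1 = r1, r2 = r2, truth = tru))
}

#' Draw per-gene spliced/unspliced read counts
#'
#' Negative-binomial counts standing in for an empirical per-gene count
#' table, for end-to-end runs where no real quantification is available.
#'
#' @param gene_ids Character vector of genes.
#' @param mu_spliced,mu_unspliced Mean counts per gene.
#' @param size Negative-binomial dispersion parameter.
#' @param seed Integer seed.
#' @return data.frame with `gene_id`, `n_spliced`, `n_unspliced`.
#' @export
sim_gene_counts <- function(gene_ids, mu_spliced = 20, mu_unspliced = 20,
                            size = 2, seed = 1L) {
  set.seed(as.integer(seed))
  data.frame(
    gene_id = gene_ids,
    n_spliced = stats::rnbinom(length(gene_ids), size = size, mu = mu_spliced),
    n_unspliced = stats::rnbinom(length(gene_ids), size = size, mu = mu_unspliced),
    stringsAsFactors = FALSE
  )
}
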