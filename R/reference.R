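#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Read exon records from a GTF annotation
#'
#' Imports a GTF file and returns the exon table used to build the spliceu
#' reference. GTF coordinates (1-based, closed) are converted to the internal
#' 0-based half-open convention at this boundary; everything downstream of
#' the parser speaks 0-based half-open.
#'
#' @param path Path to a GTF file with `exon` features carrying `gene_id`
#'   and `transcript_id` attributes.
#' @return A data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), one row per exon.
#' @export
read_gtf_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id)) {
    stop("exon features must carry gene_id and transcript_id attributes")
  }
  data.frame(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

norm_exons <- function(exons) {
  req <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  if (!all(req %in% names(exons))) {
    stop("exon table must have columns: ", paste(req, collapse = ", "))
  }
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end <= exons$start)) stop("empty or negative-width exon interval")
  if (!all(exons$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  exons[order(exons$transcript_id, exons$start), , drop = FALSE]
}

#' Build the spliced+unspliced ("spliceu") transcript set
#'
#' For every annotated transcript two records are produced: the spliced form
#' (concatenation of its exons) and the unspliced form (the contiguous
#' genomic span from the first exon start to the last exon end). Sequences
#' are stored mRNA-sense: minus-strand transcripts are reverse-complemented.
#' Unspliced records are keyed `<transcript_id>-U`.
#'
#' @param genome A named `DNAStringSet` or path to a FASTA file.
#' @param exons Exon table as returned by [read_gtf_exons()] (0-based
#'   half-open), or a path to a GTF file.
#' @return An object of class `spliceu`: a list with
#'   \describe{
#'     \item{transcripts}{data.frame keyed by `key` with `transcript_id`,
#'       `gene_id`, `status`, `chrom`, `strand`, `length`.}
#'     \item{sequences}{named character vector of mRNA-sense sequences.}
#'     \item{blocks}{per-key data.frame mapping transcript intervals
#'       (`tx_start`, `tx_end`) to genomic intervals (`g_start`, `g_end`),
#'       rows in 5'->3' transcript order.}
#'     \item{exons_tx}{per-key data.frame of annotated-exon intervals in
#'       transcript coordinates (used for exon-containment logic; for
#'       unspliced records these are the gene's exons mapped into the span).}
#'   }
#' @export
build_spliceu <- function(genome, exons) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(exons) && length(exons) == 1L) exons <- read_gtf_exons(exons)
  exons <- norm_exons(exons)

  missing_chrom <- setdiff(unique(exons$chrom), names(genome))
  if (length(missing_chrom)) {
    stop("chromosome(s) absent from genome: ", paste(missing_chrom, collapse = ", "))
  }
  clen <- Biostrings::width(genome)[match(exons$chrom, names(genome))]
  if (any(exons$start < 0L | exons$end > clen)) {
    stop("exon interval outside chromosome bounds")
  }

  ex_by_tx <- split(exons, exons$transcript_id)
  keys <- character(0); tx_id <- character(0); g_id <- character(0)
  status <- character(0); chrom <- character(0); strnd <- character(0)
  seqs <- character(0)
  blocks <- list(); exons_tx <- list()

  chr_cache <- new.env(parent = emptyenv())  # character chromosomes, lazy
  get_chr <- function(cn) {
    if (is.null(chr_cache[[cn]])) chr_cache[[cn]] <- as.character(genome[[cn]])
    chr_cache[[cn]]
  }

  for (tid in names(ex_by_tx)) {
    ex <- ex_by_tx[[tid]]
    if (length(unique(ex$chrom)) != 1L || length(unique(ex$strand)) != 1L ||
        length(unique(ex$gene_id)) != 1L) {
      stop("transcript ", tid, " mixes chromosomes, strands or genes")
    }
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in transcript ", tid)
    }
    cn <- ex$chrom[1L]; st <- ex$strand[1L]; gid <- ex$gene_id[1L]
    chr <- get_chr(cn)
    span <- c(min(ex$start), max(ex$end))

    # genomic-order exon sequences, then orient mRNA-sense
    ex_seq <- substring(chr, ex$start + 1L, ex$end)
    spliced_seq <- paste(ex_seq, collapse = "")
    unspliced_seq <- substring(chr, span[1L] + 1L, span[2L])
    if (st == "-") {
      spliced_seq <- revcomp(spliced_seq)
      unspliced_seq <- revcomp(unspliced_seq)
    }

    # block tables in transcript (5'->3') order
    ord <- if (st == "+") order(ex$start) else order(-ex$start)
    w <- ex$end[ord] - ex$start[ord]
    tx_end <- cumsum(w)
    spl_blocks <- data.frame(
      tx_start = tx_end - w, tx_end = tx_end,
      g_start = ex$start[ord], g_end = ex$end[ord]
    )
    uns_blocks <- data.frame(
      tx_start = 0L, tx_end = span[2L] - span[1L],
      g_start = span[1L], g_end = span[2L]
    )

    uk <- paste0(tid, "-U")
    keys <- c(keys, tid, uk)
    tx_id <- c(tx_id, tid, tid)
    g_id <- c(g_id, gid, gid)
    status <- c(status, "spliced", "unspliced")
    chrom <- c(chrom, cn, cn)
    strnd <- c(strnd, st, st)
    seqs <- c(seqs, spliced_seq, unspliced_seq)
    blocks[[tid]] <- spl_blocks
    blocks[[uk]] <- uns_blocks
    exons_tx[[tid]] <- spl_blocks[, c("tx_start", "tx_end")]
    # annotated exons mapped into unspliced (span) coordinates
    if (st == "+") {
      ue <- data.frame(tx_start = ex$start[ord] - span[1L],
                       tx_end = ex$end[ord] - span[1L])
    } else {
      ue <- data.frame(tx_start = span[2L] - ex$end[ord],
                       tx_end = span[2L] - ex$start[ord])
    }
    exons_tx[[uk]] <- ue
  }

  transcripts <- data.frame(
    key = keys, transcript_id = tx_id, gene_id = g_id, status = status,
    chrom = chrom, strand = strnd, length = nchar(seqs),
    stringsAsFactors = FALSE
  )
  names(seqs) <- keys
  structure(
    list(transcripts = transcripts, sequences = seqs,
         blocks = blocks, exons_tx = exons_tx),
    class = "spliceu"
  )
}

#' @export
print.spliceu <- function(x, ...) {
  tt <- x$transcripts
  cat("spliceu reference:", sum(tt$status == "spliced"), "transcripts (",
      length(unique(tt$gene_id)), "genes ),",
      nrow(tt), "spliced+unspliced records\n")
  if (!is.null(x$sites)) {
    cat("  priming sites enumerated:", nrow(x$sites),
        "( window width", attr(x$sites, "window_width"), ")\n")
  }
  invisible(x)
}

revcomp <- function(s) {
  as.character(reverseComplement(DNAStringSet(s)))
}

#' Enumerate candidate oligo(dT) priming sites on every spliceu record
#'
#' Internal sites are A-SNRs of at least `min_arun` consecutive adenines
#' (no mismatch); each site carries the priming window of width
#' `window_width` starting at the first base of the A-run, right-padded with
#' `A` where it overruns the 3' end (the transcript continues into polyA).
#' Exactly one polyA-tail site is appended per record, anchored at the 3'
#' end with an all-`A` window. Together these form the ordered candidate
#' list scanned by the fragment scorer.
#'
#' @param spliceu A `spliceu` object.
#' @param window_width Priming-window width in nt; defaults to 32, the
#'   oligo(dT)/polyT length of the library chemistry.
#' @param min_arun Minimum A-run length for an internal site (default 6).
#' @return The `spliceu` object with a `sites` data.frame added (`key`,
#'   `start`, `kind`, `window`), ordered 5'->3' within each record, tail
#'   site last.
#' @export
enumerate_priming_sites <- function(spliceu, window_width = 32L, min_arun = 6L) {
  stopifnot(inherits(spliceu, "spliceu"))
  W <- as.integer(window_width)
  res <- vector("list", nrow(spliceu$transcripts))
  for (i in seq_len(nrow(spliceu$transcripts))) {
    key <- spliceu$transcripts$key[i]
    s <- spliceu$sequences[[key]]
    n <- nchar(s)
    if (n == 0L) stop("empty sequence for ", key)
    starts <- find_asnr(s, min_len = min_arun, max_mismatch = 0L)
    if (length(starts)) {
      win <- substring(s, starts + 1L, pmin(starts + W, n))
      win <- paste0(win, strrep("A", W - nchar(win)))
    } else {
      win <- character(0)
    }
    res[[i]] <- data.frame(
      key = key,
      start = c(starts, n),
      kind = c(rep("internal_asnr", length(starts)), "polyA_tail"),
      window = c(win, strrep("A", W)),
      stringsAsFactors = FALSE
    )
  }
  sites <- do.call(rbind, res)
  attr(sites, "window_width") <- W
  spliceu$sites <- sites
  spliceu
}

#' Project a transcript interval onto the genome
#'
#' Maps a 0-based half-open interval in transcript coordinates of a spliceu
#' record to the ordered list of genomic blocks it covers. For unspliced
#' records the result is always a single block; for spliced records the
#' block lengths sum to the interval length.
#'
#' @param spliceu A `spliceu` object.
#' @param key Record key (`transcript_id` or `<transcript_id>-U`).
#' @param start,end Transcript interval, 0-based half-open.
#' @return data.frame of genomic blocks (`g_start`, `g_end`) in 5'->3'
#'   transcript order, with `chrom` and `strand` attributes.
#' @export
project_to_genome <- function(spliceu, key, start, end) {
  bl <- spliceu$blocks[[key]]
  if (is.null(bl)) stop("unknown spliceu key: ", key)
  tr <- spliceu$transcripts[spliceu$transcripts$key == key, ]
  n <- tr$length
  if (start < 0L || end > n || start >= end) {
    stop("interval [", start, ",", end, ") out of range for ", key,
         " (length ", n, ")")
  }
  st <- tr$strand
  hit <- which(bl$tx_end > start & bl$tx_start < end)
  out <- lapply(hit, function(i) {
    a <- max(start, bl$tx_start[i]); b <- min(end, bl$tx_end[i])
    if (st == "+") {
      c(bl$g_start[i] + (a - bl$tx_start[i]), bl$g_start[i] + (b - bl$tx_start[i]))
    } else {
      c(bl$g_end[i] - (b - bl$tx_start[i]), bl$g_end[i] - (a - bl$tx_start[i]))
    }
  })
  res <- data.frame(
    g_start = vapply(out, `[`, numeric(1), 1L),
    g_end = vapply(out, `[`, numeric(1), 2L)
  )
  res$g_start <- as.integer(res$g_start); res$g_end <- as.integer(res$g_end)
  attr(res, "chrom") <- tr$chrom
  attr(res, "strand") <- st
  res
}

#' Map genomic alignment blocks into transcript coordinates
#'
#' The inverse of [project_to_genome()], and the transcript-compatibility
#' test used throughout: an alignment (a set of genomic blocks on the
#' transcript's chromosome) is compatible with a spliceu record iff every
#' block falls inside the record's exon structure and the mapped pieces
#' concatenate to one contiguous transcript interval — i.e. any alignment
#' gaps coincide exactly with the record's introns.
#'
#' @param spliceu A `spliceu` object.
#' @param key Record key.
#' @param gblocks data.frame with `g_start`, `g_end` (0-based half-open
#'   genomic blocks), any order.
#' @param chrom Chromosome of the alignment; compatibility requires it to
#'   match the record's chromosome.
#' @return `NULL` if incompatible, else a list with `start`, `end` (the
#'   contiguous transcript interval, 0-based half-open).
#' @export
genome_to_tx <- function(spliceu, key, gblocks, chrom = NULL) {
  bl <- spliceu$blocks[[key]]
  if (is.null(bl)) stop("unknown spliceu key: ", key)
  tr <- spliceu$transcripts[spliceu$transcripts$key == key, ]
  if (!is.null(chrom) && chrom != tr$chrom) return(NULL)
  st <- tr$strand
  iv <- matrix(NA_integer_, nrow = nrow(gblocks), ncol = 2L)
  for (j in seq_len(nrow(gblocks))) {
    u <- gblocks$g_start[j]; v <- gblocks$g_end[j]
    i <- which(bl$g_start <= u & bl$g_end >= v)
    if (length(i) != 1L) return(NULL)  # block not within one exon block
    if (st == "+") {
      iv[j, ] <- c(bl$tx_start[i] + (u - bl$g_start[i]),
                   bl$tx_start[i] + (v - bl$g_start[i]))
    } else {
      iv[j, ] <- c(bl$tx_start[i] + (bl$g_end[i] - v),
                   bl$tx_start[i] + (bl$g_end[i] - u))
    }
  }
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1L] != iv[-nrow(iv), 2L])) return(NULL)
  list(start = iv[1L, 1L], end = iv[nrow(iv), 2L])
}

#' Write a spliceu reference to FASTA plus a transcript-to-gene table
#'
#' The FASTA uses the `<transcript_id>-U` header dialect for unspliced
#' records; the 3-column t2g TSV lists transcript key, gene and status.
#'
#' @param spliceu A `spliceu` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`fasta`, `t2g`).
#' @export
write_spliceu <- function(spliceu, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "spliceu.fa")
  t2g <- file.path(dir, "t2g.tsv")
  writeXStringSet(DNAStringSet(spliceu$sequences), fa)
  utils::write.table(
    spliceu$transcripts[, c("key", "gene_id", "status")],
    t2g, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(list(fasta = fa, t2g = t2g))
}
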