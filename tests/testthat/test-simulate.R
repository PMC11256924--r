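test_that("toy reference generation is deterministic and honors rates", {
  r1 <- generate_toy_reference(n_genes = 5, seed = 13)
  r2 <- generate_toy_reference(n_genes = 5, seed = 13)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$exons, r2$exons)
  expect_identical(r1$arun_truth, r2$arun_truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_toy_reference(r1, d1); p2 <- write_toy_reference(r2, d2)
  expect_identical(readLines(p1$fasta), readLines(p2$fasta))
  expect_identical(readLines(p1$gtf), readLines(p2$gtf))

  # zero planting rate: only tail sites exist
  r0 <- generate_toy_reference(n_genes = 4, arun_rate_exon = 0,
                               arun_rate_intron = 0, seed = 14)
  sp0 <- enumerate_priming_sites(build_spliceu(r0$genome, r0$exons))
  expect_true(all(sp0$sites$kind == "polyA_tail"))
  expect_identical(nrow(r0$arun_truth), 0L)
})

test_that("every planted A-run surfaces as an enumerated site", {
  ref <- generate_toy_reference(n_genes = 6, seed = 15)
  sp <- enumerate_priming_sites(build_spliceu(ref$genome, ref$exons))
  tt <- sp$transcripts
  for (i in seq_len(nrow(ref$arun_truth))) {
    tr <- ref$arun_truth[i, ]
    key <- paste0(tr$gene_id, ".t1-U")   # unspliced form sees all elements
    # map the genomic run start to transcript coordinates
    blocks <- data.frame(g_start = tr$g_start, g_end = tr$g_start + tr$run_len)
    tx <- genome_to_tx(sp, key, blocks, chrom = tr$chrom)
    expect_false(is.null(tx))
    expect_true(tx$start %in% sp$sites$start[sp$sites$key == key],
                label = sprintf("planted run %d found on %s", i, key))
  }
})

test_that("fragment geometry follows the site/length definitions", {
  # single-exon 1000 bp transcript with one planted run at 800
  chars <- strsplit(strrep("ACGT", 250), "")[[1]]
  chars[801:807] <- "A"   # genomic/tx 800..806
  genome <- Biostrings::DNAStringSet(c(c1 = paste(chars, collapse = "")))
  exons <- data.frame(gene_id = "g", transcript_id = "t", chrom = "c1",
                      strand = "+", start = 0L, end = 1000L)
  sp <- enumerate_priming_sites(build_spliceu(genome, exons))
  sp_one <- sp
  sp_one$sites <- sp$sites[sp$sites$kind == "internal_asnr", ]   # site at 800

  set.seed(1)
  fr <- sample_fragment("g", "spliced", sp_one, make_pf(300L, 1))
  expect_identical(fr$read2_start, 500L)
  expect_identical(fr$read2_end, 591L)
  expect_identical(fr$read1_start, 769L)
  expect_identical(fr$read1_end, 800L)
  expect_identical(fr$d, 300L)
  expect_identical(nchar(fr$read2_seq), 91L)
  expect_identical(nchar(fr$read1_seq), 31L)

  # d = 900 with the fragment end at 800 would start before the transcript
  expect_null(sample_fragment("g", "spliced", sp_one, make_pf(900L, 1)))
})

test_that("accepted fragment lengths reproduce the supplied distribution", {
  # single internal site far from both ends: no acceptance bias beyond the
  # d >= read2 truncation
  chars <- strsplit(strrep("GCTA", 1250), "")[[1]]
  chars[3001:3008] <- "A"
  genome <- Biostrings::DNAStringSet(c(c1 = paste(chars, collapse = "")))
  exons <- data.frame(gene_id = "g", transcript_id = "t", chrom = "c1",
                      strand = "+", start = 0L, end = 5000L)
  sp <- enumerate_priming_sites(build_spliceu(genome, exons))
  sp$sites <- sp$sites[sp$sites$kind == "internal_asnr" & sp$sites$key == "t", ]
  pf <- truncnorm_fraglen(300, 60)
  cnt <- data.frame(gene_id = "g", n_spliced = 50000, n_unspliced = 0)
  sim <- simulate_reads(cnt, sp, pf, mode = "ambiguous_only", seed = 6)
  d <- sim$fragments$d
  expect_gte(length(d), 49000)
  emp <- tabulate(d, nbins = 1000) / length(d)
  ks <- max(abs(cumsum(emp) - cumsum(pf$probs)))
  expect_lt(ks, 0.02)
})

test_that("mode filters hold for every emitted fragment", {
  ref <- generate_toy_reference(n_genes = 6, seed = 16)
  sp <- enumerate_priming_sites(build_spliceu(ref$genome, ref$exons))
  pf <- truncnorm_fraglen(300, 60)
  cnt <- data.frame(gene_id = unique(sp$transcripts$gene_id),
                    n_spliced = 20, n_unspliced = 20)
  for (mode in c("ambiguous_only", "no_fundamental")) {
    sim <- simulate_reads(cnt, sp, pf, mode = mode, seed = 17)
    fr <- sim$fragments
    # read 2 always within a single annotated exon
    for (i in seq_len(nrow(fr))) {
      ex <- sp$exons_tx[[fr$key[i]]]
      in_one <- any(ex$tx_start <= fr$read2_start[i] &
                    ex$tx_end >= fr$read2_end[i])
      expect_true(in_one)
    }
    if (mode == "no_fundamental") {
      expect_true(all(fr$site_kind != "polyA_tail"))
      expect_false(any(fr$fundamental_ambiguity))
      for (i in seq_len(nrow(fr))) {
        ex <- sp$exons_tx[[fr$key[i]]]
        e2 <- which(ex$tx_start <= fr$read2_start[i] &
                    ex$tx_end >= fr$read2_end[i])
        same <- any(ex$tx_start[e2] <= fr$read1_start[i] &
                    ex$tx_end[e2] >= fr$read1_end[i])
        expect_false(same)
      }
    }
    # count fidelity: emitted = requested - shortfall
    expect_identical(sim$shortfall$emitted,
                     sim$shortfall$requested - sim$shortfall$shortfall)
    agg <- table(paste(fr$gene_id, fr$truth_status))
    for (j in seq_len(nrow(sim$shortfall))) {
      nm <- paste(sim$shortfall$gene_id[j], sim$shortfall$status[j])
      got <- if (nm %in% names(agg)) as.integer(agg[[nm]]) else 0L
      expect_identical(got, sim$shortfall$emitted[j])
    }
  }
})

test_that("a single-exon gene cannot produce no-fundamental fragments", {
  genome <- Biostrings::DNAStringSet(c(c1 = paste0(
    strrep("GCTA", 200), strrep("A", 8), strrep("GCTA", 50))))
  exons <- data.frame(gene_id = "g", transcript_id = "t", chrom = "c1",
                      strand = "+", start = 0L, end = 1008L)
  sp <- enumerate_priming_sites(build_spliceu(genome, exons))
  cnt <- data.frame(gene_id = "g", n_spliced = 10, n_unspliced = 10)
  sim <- simulate_reads(cnt, sp, truncnorm_fraglen(300, 60),
                        mode = "no_fundamental", max_attempts = 5000,
                        seed = 18)
  expect_identical(sum(sim$shortfall$shortfall), 20L)
  expect_null(sim$fragments)
})

test_that("rescoring an emitted fragment recovers its generating site", {
  ref <- generate_toy_reference(n_genes = 5, seed = 19)
  sp <- enumerate_priming_sites(build_spliceu(ref$genome, ref$exons))
  pf <- truncnorm_fraglen(300, 60)
  cnt <- data.frame(gene_id = unique(sp$transcripts$gene_id),
                    n_spliced = 10, n_unspliced = 10)
  sim <- simulate_reads(cnt, sp, pf, mode = "ambiguous_only", seed = 20)
  fr <- sim$fragments
  for (i in seq_len(nrow(fr))) {
    cand <- pbs_candidates(sp, fr$key[i], fr$read2_start[i])
    expect_true(fr$site_start[i] %in% cand$start,
                label = paste("generating site among candidates, read", i))
  }
})

test_that("simulation and FASTQ output are byte-identical under one seed", {
  ref <- generate_toy_reference(n_genes = 4, seed = 21)
  sp <- enumerate_priming_sites(build_spliceu(ref$genome, ref$exons))
  pf <- truncnorm_fraglen(300, 60)
  cnt <- data.frame(gene_id = unique(sp$transcripts$gene_id),
                    n_spliced = 15, n_unspliced = 15)
  s1 <- simulate_reads(cnt, sp, pf, seed = 22)
  s2 <- simulate_reads(cnt, sp, pf, seed = 22)
  expect_identical(s1$fragments, s2$fragments)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  e1 <- add_read_errors(s1$fragments, 0.005, seed = 23)
  e2 <- add_read_errors(s2$fragments, 0.005, seed = 23)
  p1 <- write_sim_fastq(e1, d1); p2 <- write_sim_fastq(e2, d2)
  for (f in c("r1", "r2", "truth")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
})

test_that("the substitution error model hits its rate and its limits", {
  ref <- generate_toy_reference(n_genes = 3, seed = 24)
  sp <- enumerate_priming_sites(build_spliceu(ref$genome, ref$exons))
  cnt <- data.frame(gene_id = unique(sp$transcripts$gene_id),
                    n_spliced = 40, n_unspliced = 40)
  sim <- simulate_reads(cnt, sp, truncnorm_fraglen(300, 60), seed = 25)
  fr <- sim$fragments

  expect_identical(add_read_errors(fr, 0, seed = 1), fr)
  mut1 <- add_read_errors(fr, 1, seed = 2)
  orig <- strsplit(paste(c(fr$read1_seq, fr$read2_seq), collapse = ""), "")[[1]]
  mutated <- strsplit(paste(c(mut1$read1_seq, mut1$read2_seq),
                            collapse = ""), "")[[1]]
  expect_true(all(orig != mutated))

  rate <- 0.01
  mutr <- add_read_errors(fr, rate, seed = 3)
  flat <- strsplit(paste(c(mutr$read1_seq, mutr$read2_seq),
                         collapse = ""), "")[[1]]
  n <- length(flat)
  frac <- mean(flat != orig)
  expect_lt(abs(frac - rate), 3 * sqrt(rate * (1 - rate) / n))
})

test_that("negative-binomial count generation is seeded and well-formed", {
  cnt <- sim_gene_counts(paste0("g", 1:50), seed = 26)
  cnt2 <- sim_gene_counts(paste0("g", 1:50), seed = 26)
  expect_identical(cnt, cnt2)
  expect_true(all(cnt$n_spliced >= 0 & cnt$n_unspliced >= 0))
  expect_true(all(cnt$n_spliced == round(cnt$n_spliced)))
})
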