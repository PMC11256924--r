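# spliceprime

Probabilistic splicing-status inference for 3' tagged-end scRNA-seq reads.

## The problem

In droplet scRNA-seq, oligo(dT) primers capture polyadenylated RNA — but they
also mis-prime on internal adenine single-nucleotide repeats (A-SNRs),
predominantly on unspliced transcripts. A short read 2 that falls entirely
inside an exon is therefore compatible with both the spliced and the
unspliced form of its gene, and the standard heuristics either force all such
reads to "spliced" or discard roughly half of all UMIs as "ambiguous". This
matters directly for RNA-velocity-style analyses, which depend on separate
spliced and unspliced counts.

`spliceprime` resolves exonic reads mechanistically. Every read 2 alignment
is paired with each candidate downstream priming site — internal A-SNRs and
the polyA tail — to form putative cDNA fragments, and each fragment is scored
by how plausible its geometry and its priming sequence are:

- **p_f(d)** — the probability of a cDNA fragment of length *d*, an empirical
  distribution on 1..1000 bp fitted with a cubic smoothing spline from
  paired-end ("biological read 1") alignments;
- **p_b(w)** — the binding affinity of the 32-nt priming window *w*, from a
  small multilayer perceptron trained to separate empirical priming windows
  from background sequence (polyA-tail windows score 1 by convention).

For a read *r* mapping at transcript position *x* of transcript *t*, the
transcript score is the best fragment,

    Pr(t | x) = max over downstream sites (w_i, d_i) of p_f(d_i) * p_b(w_i),

per-status scores take the max over compatible transcripts of a gene,

    Pr(v, r, g) = max over t in tx(v, r, g) of Pr(t | x^t),   v in {s, u},

the spliced probability is the normalized ratio

    Pr(s | r, g) = Pr(s, r, g) / (Pr(s, r, g) + Pr(u, r, g)),

and the gene of origin of a multi-gene read is argmax_g max_v Pr(v, r, g),
with exact ties reported as ties. Reads with equal (or no) evidence in both
statuses are called *ambiguous* — including the fundamentally ambiguous
geometries (tail-primed fragments inside the terminal exon, fragments wholly
inside one exon) that no sequence-based model can resolve.

The package also ships the full synthetic loop that makes the method
trainable and testable without any external data: a toy-reference generator
with planted A-SNRs, a splice-aware paired-end read simulator (91 nt read 2,
31 nt biological read 1, exonic-read-2 rejection sampling, a
no-fundamental-ambiguity mode, a substitution error model), a paired-end
ground-truth labeller (e∧e′ / e·e′ / i / i·e rules), and ROC/AUC evaluation
with the three trivial baselines.

## Worked example

```r
library(spliceprime)

# 1. synthetic reference: 10 genes with planted A-SNRs
ref <- generate_toy_reference(n_genes = 10, seed = 1)
sp  <- enumerate_priming_sites(build_spliceu(ref$genome, ref$exons))
sp
#> spliceu reference: 10 transcripts ( 10 genes ), 20 spliced+unspliced records
#>   priming sites enumerated: 127 ( window width 32 )

# 2. fragment-length model: fit the spline on one sample, check on another
pf_true <- truncnorm_fraglen(mean = 300, sd = 60)
set.seed(2)
fl <- fit_fraglen_spline(build_histogram(sample_fraglen(pf_true, 100000)))
fraglen_rmse(fl, build_histogram(sample_fraglen(pf_true, 100000)))
#> [1] 0.0001057427

# 3. binding model: planted-motif windows vs A-run-free background
win <- simulate_priming_windows(5000, 5000, seed = 3)
bm  <- train_binding(win$positives, win$backgrounds, seed = 4)
bm
#> binding-affinity MLP: window width 32 | hidden 64x32 | held-out accuracy 0.968
sp <- score_sites(sp, bm)

# 4. simulate reads without fundamental ambiguity and score them
cnt <- data.frame(gene_id = unique(sp$transcripts$gene_id),
                  n_spliced = 100, n_unspliced = 100)
sim <- simulate_reads(cnt, sp, pf_true, mode = "no_fundamental", seed = 5)
ev  <- build_eval_set(sim$fragments, sp)     # labels + read-2 mappings
preds <- predict_reads(ev$mappings, sp, fl)
head(preds[, c("read_id", "assigned_gene", "pr_spliced", "status_call")], 3)
#>             read_id assigned_gene pr_spliced status_call
#> 1 sim_gene01_s_0001        gene01  1.0000000     spliced
#> 2 sim_gene01_s_0002        gene01  1.0000000     spliced
#> 3 sim_gene01_s_0003        gene01  0.7811947     spliced

truth <- setNames(sim$fragments$truth_status, sim$fragments$read_id)
roc_auc(truth[preds$read_id], preds$pr_spliced)$auc
#> [1] 0.9673689
```

Here the spline's hold-out RMSE (~1e-4) says the fitted fragment-length
distribution transfers to an independent sample; the MLP's held-out accuracy
is its ability to tell primable windows from background; `pr_spliced` is
Pr(s | r, g) for each read; and the final AUC measures how well that
probability ranks truly spliced above truly unspliced reads.

A thin command-line wrapper over the same functions is installed at
`inst/cli/spliceprime.R` (`toy-ref`, `build-ref`, `fit-fraglen`,
`train-binding`, `simulate`, `label`, `predict`, `evaluate`).

## Methods

See `vignettes/splicing-status-inference.Rmd` for the model, its
assumptions, the synthetic-data design, and known limitations.
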