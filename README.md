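# shapetf — DNA-shape-based prediction of transcription factor binding affinity

Sequence motifs over-predict transcription factor (TF) binding: a genome
carries far more motif occurrences than bound sites, and TFs of one family
share motifs yet bind different loci. `shapetf` is for regulatory
genomicists who want to close that gap with *DNA shape*: it turns each
motif occurrence (plus flanking bases) into 13 per-position structural
descriptors — minor groove width, the intra-base-pair parameters (shear,
stretch, stagger, buckle, propeller twist, opening) and the inter-base-pair
step parameters (shift, slide, rise, tilt, roll, helix twist) — through a
pentamer query table, and trains a random forest regressor of binding
affinity on them.

At its core, for a TF with core motif of length *m* and flank width *b*,
each site is the vector

    x = ( s_f(p) : p in {-b..-1, 1..m, +1..+b}, f in the 13 features )

where `s_f(p)` is the query-table value of feature *f* for the pentamer
centered at position *p* (minus-strand sites reverse complemented first).
The regressor `f(x)` is fit to ampDAP-seq peak height min–max scaled to
[0, 1000] with cross-validated randomized hyperparameter search
(n_trees 10–200, max_features all/sqrt/log2, max_depth 4–12, weighted MSE
loss), and judged by the area under the precision–recall curve (AUPRC) for
ranking bound vs. unbound occurrences against the motif log-odds baseline.
Exact interventional Shapley values attribute predictions to single
`feature@position` descriptors, and a designer proposes novel
motif-containing sequences with extreme predicted affinity.

The full pre-processing chain is implemented: FIMO-style genome scanning
with exact DP p-values at the 5e-4 threshold (palindromes counted once per
locus), FRiP filtering (>5%), cross-dataset artifact-peak removal (>1/3
recurrence), 80-bp summit labeling, homodimer classification, organelle
exclusion, 1:5 / 120,000 / 1:3 class balancing, ratio sample weights and a
stratified 80/20 split. A synthetic-data module generates complete
desk-scale studies (genome, planted motifs, shape-driven affinities,
narrowPeak pseudo-datasets, manifest, symmetry-exact shape-table fixture)
so everything is testable offline.

## Worked example

A complete run on a simulated study (1-Mb genome, 1,000 planted motif
instances whose affinity depends on two flanking shape features):

```r
library(shapetf)

study <- simulate_study(sim_config(), dir = tempdir(), seed = 11)
hits  <- scan_genome(study$genome, study$pwm, pthresh = 5e-4)
ds    <- build_training_dataset(hits, study$manifest, study$genome,
                                study$shape_table, seed = 11)
model <- train(ds, hyper_space(iterations = 6, folds = 3), b = 4, seed = 11)
ev    <- evaluate_model(model, ds)
c(model = ev$pr$auprc, baseline = ev$baseline$auprc)
#>     model  baseline
#> 0.5687348 0.1948718

pipeline_importance(model, ds, n_samples = 60, n_background = 50, seed = 11)
#> Top shape features by mean |Shapley value|:
#>     feature mean_abs_shap
#>     roll@+3     78.166357
#>      MGW@-3     72.868227
#>  stretch@+4      2.613257
#>      MGW@+2      2.110830
#>  stagger@-4      1.924880
```

The shape model nearly triples the motif-only AUPRC on the held-out 20%
(0.57 vs. 0.19), and the two causal shape features planted by the
simulator head the Shapley importance ranking by a wide margin. `width_sweep(ds, c(0, 2, 4, 8), ...)` traces
how much flanking shape adds beyond the core motif, and

```r
cand <- generate_candidates(study$genome, core = pwm_consensus(study$pwm),
                            n = 100000, length = 18, seed = 11)
select_extremes(model, cand, study$shape_table,
                core = pwm_consensus(study$pwm))
```

returns three sequences predicted above 150 and three below 15 affinity
units, none of which occur in the genome — the in-silico design step
ahead of an EMSA competition assay.

A thin command-line front end for real data (FASTA genome, MEME motif,
narrowPeak manifest, query table) is in `inst/cli/shapetf.R`.

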