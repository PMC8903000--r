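# myoregnet

Integrative regulatory genomics of the human myometrium across the
transition to labour.

Transcriptome studies of labouring and non-labouring uterine muscle
find that genes do not change one by one: they move as co-expressed
modules, the modules' genes concentrate inside topologically
associated domains (TADs), their promoters and enhancers share
transcription-factor binding sites, and differentially expressed
miRNAs anti-correlate with module genes and lncRNAs, forming an
integrated regulatory network whose hubs (high-degree lncRNAs, TFs and
miRNAs) are candidate drivers of labour onset. `myoregnet` implements
that whole analysis chain as a tested R package, together with a
synthetic-data generator that emulates the study design (16 samples in
groups of 5 no-labour / 5 early-labour / 6 late-labour; planted
modules of 81/46/36 genes) so that every stage has a recoverable
ground truth.

## What is computed

* **Differential expression** — per-gene moderated Welch t-test on
  log-CPM with BH FDR; calls require |FC| ≥ 1.5 *and* FDR ≤ 0.05.
  For non-coding biotypes the two labouring groups are pooled against
  no-labour.
* **Co-expression modules** — average-linkage clustering on
  `1 − |Pearson r|`, tree cut at r = 0.6, modules below 30 genes
  unassigned; per-class activity as a GSEA net enrichment score
  (weighted Kolmogorov–Smirnov running sum, permutation-normalised).
* **TAD localisation** — strand-aware TSS anchoring into BED
  half-open domain intervals, signed boundary distances, within-domain
  fractions, and a two-sample KS test of module genes against
  size-matched random gene sets.
* **Motif enrichment** — JASPAR PWM scanning of promoters
  (10 kb up / 5 kb down of the TSS) and enhancers with exact
  DP-computed score thresholds; background-subtracted enrichment
  `z = (observed − expected)/sd` against resampled background regions,
  reported at the z ≥ 10, adjusted p ≤ 0.05 convention.
* **Integrated network** — negative significant miRNA:mRNA and
  miRNA:lncRNA correlation edges, TF-binding edges, curated pairs;
  degree and betweenness; hubs at degree ≥ 50 (lncRNA/TF) and > 10
  (miRNA); hypergeometric master-regulator ranking.
* **Sample ranking** — mean z-score over a gene panel ("cigar plot"
  ordering) with low/middle/high candidate selection.

## Worked example

```r
library(myoregnet)

cfg <- sim_config(seed = 1)      # the default synthetic study design
sim <- simulate_all(cfg)         # counts + genome layout + ground truth

mods <- detect_modules(log_cpm(sim$coding))
mods
#> module_set: 3 modules ( M1=80, M2=45, M3=36 ), 502 unassigned

ann <- sim$annotation[sim$annotation$biotype == "coding", ]
loc <- localize_genes(ann, sim$tads)
within_fraction(loc, module_genes(mods, "M2"))
#> [1] 0.7555556

t1 <- localization_test(loc, module_genes(mods, "M1"), seed = 1)
c(D = round(t1$D, 3), p = signif(t1$p, 2))
#>     D     p
#> 0.161 0.033

ed <- correlate_classes(sim$mirna, sim$coding,
                        adj_p_max = 0.05, sign_filter = "negative")
nrow(ed)
#> [1] 101
```

The detected modules recover the planted 81/46/36 blocks almost
exactly (adjusted Rand index 0.88 on this seed); about three quarters
of the M2 genes fall inside a contact domain, matching the planted
0.76 fraction; the localisation KS test flags M1 as non-randomly
placed; and the correlation screen returns the planted miRNA→target
repression pairs among its negative significant edges.

`run_pipeline(pipeline_config(sim = cfg))` chains every stage and
writes TSV/JSON result tables plus a parameter/seed log to an output
directory; `inst/scripts/pipeline.R` wraps it for the shell.

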