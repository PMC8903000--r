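---
title: "Methods: from co-expression modules to an integrated regulatory network"
author: "myoregnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from co-expression modules to an integrated regulatory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoregnet)
```

# Scope

`myoregnet` implements, as a reusable and fully tested pipeline, an
integrative analysis of human myometrial transcriptomes across the
transition to labour: co-expression module detection with per-class net
enrichment scoring, localisation of module genes relative to
topologically associated domains (TADs), transcription-factor
binding-site enrichment in promoters and enhancers, a
miRNA/lncRNA/mRNA/TF correlation network with hub identification, and
the z-score panel ranking used to order samples along the labour
trajectory. Because the original tissue dataset and the external
resources it was analysed against (curated contact domains, motif
databases, enhancer atlases, interaction databases) cannot be bundled,
the package ships a first-class synthetic-data generator that emulates
the study's structure with planted, recoverable ground truth; every
statistical claim the test suite makes is a claim about recovery of
that planted structure or about agreement with exact enumeration.

# The synthetic study design

`sim_config()` defaults encode the study conditions: 16 samples in
three groups (5 no-labour NL, 5 early-labour EL, 6 late-labour LL),
three planted coding-gene modules of 81, 46 and 36 genes over a
background of 500 unstructured coding genes, 27 miRNAs (20 of them
coupled to a module-gene target), 30 lncRNAs, and one 20-Mb synthetic
chromosome carrying 40 contact domains.

**Counts.** Gene counts are negative binomial with gene-specific means
(log2 means drawn from N(7, 1.5), clipped to [3, 12]) and dispersion
`nb_dispersion = 0.05`. Library-size factors are uniform on a two-fold
band. Module genes share a latent per-sample factor plus a planted
between-group shift: module 1 rises monotonically NL → EL → LL, module
2 falls, module 3 steps up at labour onset, mirroring the reported
association of one module with the quiescent and two with the
labouring state. The factor loading is derived analytically from the
dispersion so that the factor component alone gives a within-module,
within-group Pearson correlation of about 0.6 on the log scale; the
group shift (default `module_log2fc = 1`) adds shared variance, so the
marginal within-module correlation across all 16 samples is higher
(about 0.8–0.9), which is what real co-expression modules look like.
We deliberately keep the shift at 1 log2 unit: a much larger shift
makes the three modules' group profiles dominate every gene's variance,
and since module detection clusters on |r|, strongly profiled modules
then merge into a single cluster regardless of their independent
factors.

**Planted repression.** Each planted miRNA tracks the *realised*
log-expression deviation of its target (computed against the realised
coding library sizes, so it is exactly the target's log-CPM up to a
constant), with a coupling coefficient solved from
`corr = repression_r` (default −0.9) using a pilot-simulated estimate
of the miRNA's own log-scale NB noise. Two details matter and were
found the hard way: (i) the delta-method noise approximation
underestimates log-NB noise at this dispersion, so the noise SD is
calibrated by simulation; and (ii) CPM normalisation divides by the
miRNA library size, which itself moves with the planted rows — the
generator therefore draws the non-planted rows first and
pre-compensates each planted mean by the predicted library size. The
large-sample invariant (mean planted correlation within 0.1 of
`repression_r` at n ≈ 200) is enforced in the test suite.

**Genome layout.** The chromosome is segmented into alternating gaps
and domains (gamma-distributed lengths, rescaled). Genes occupy a slot
grid wide enough that promoter windows (10 kb upstream / 5 kb
downstream of the TSS) never overlap; slots within 3 kb of a domain
boundary are unused so the ±1 kb TSS jitter can never flip a gene's
planted side. Per module, `round(frac_in_tad * size)` genes are placed
on inside-domain slots (defaults 0.66 / 0.76 / 0.66, the published
within-domain fractions of the three modules); background genes are
placed uniformly. Promoters receive Poisson(`promoter_motif_rate`,
default 1) planted exact-consensus occurrences of their module's motif
over an i.i.d. background sequence; insertion respects strand, so the
extracted promoter always contains the consensus at the recorded
offset.

**What the generator does not emulate:** GC composition and repeat
structure of real genomes, realistic motif degeneracy in the planted
occurrences, isoform structure, batch effects, and the pervasive
correlation of real transcriptomes. Consequently, passing recovery
tests demonstrates correctness of the statistical machinery under the
declared model, not performance on tissue data.

# Expression statistics

Normalisation is classic log-CPM with a pseudocount (default 0.5):
`log2((count + c) / (libsize + 2c) * 1e6)`.

The original analysis used edgeR-voom. Reimplementing voom's
mean-variance loess weighting faithfully is out of scope here; instead
`differential_expression()` uses a per-gene Welch t-test on log-CPM
with empirical-Bayes shrinkage of each group variance towards the
global median per-gene variance (weight 0.1 by default). The choice is
deliberately transparent and desk-verifiable, and its calibration is a
tested property: across 200 null simulations (2000 genes, 16 samples,
5 vs 11 contrast) the empirical type-I error at α = 0.05 must lie in
[0.03, 0.07]. Calls use the study's filters: |fold change| ≥ 1.5
(applied as |log2FC| ≥ log2 1.5 on group means of log-CPM) *and* BH
FDR ≤ 0.05; genes failing either filter are reported as `unchanged`
rather than dropped, and zero-variance genes are flagged with p = 1.
For the non-coding biotypes the pipeline pools EL+LL against NL, as in
the study. BH (not BY) is used everywhere; overrepresentation uses the
upper-tail hypergeometric probability.

# Co-expression modules and net enrichment

`detect_modules()` replaces the original CEMiTool machinery (whose
parameters the study does not report) with a fixed, fully specified
procedure: average-linkage hierarchical clustering on `1 − |r|`, tree
cut at `1 − correlation_threshold` (default 0.6), clusters below 30
genes folded into `unassigned`, labels M1, M2, … by decreasing size.
The exact module gene lists of the original dataset are therefore not
claimed to be reproducible; what is claimed — and tested — is planted-
block recovery (adjusted Rand index ≥ 0.8 on the default design at the
suite's fixed simulation seed). Across random seeds the recovery on
the default design is itself stochastic: median ARI ≈ 0.82 over ten
seeds, with occasional merging of the two labour-associated modules
when their latent factor realisations happen to correlate at n = 16.
We report this openly rather than widening the generator's separation.

Module activity per class is a GSEA-style running sum: genes are
ranked by the class mean of their gene-standardised log-CPM (the
ranking statistic is declared, since the original tool's internal
choice is unstated); hits add their normalised |statistic|, misses
subtract 1/(N − |S|); ES is the signed extremum, NES divides ES by the
mean |ES| of size-matched random sets (1000 by default, seeded), and
the permutation p uses +1 smoothing so it is never zero. ES is exactly
conserved (the sum returns to zero) and negates under ranking
reversal; both are tested, as is agreement with a hand-enumerated
6-gene example.

# TAD localisation

Genes are anchored at the strand-aware TSS by default (midpoint by
flag); the published analysis says only "mapped genes", so the choice
is exposed rather than asserted. Membership follows the BED half-open
convention `[start, end)`: an anchor at `start` is inside at distance
0; an anchor at `end` belongs to the following gap at distance −1 (the
sign encodes side: positive inside, negative outside). Inside distance
is `min(anchor − start, end − anchor)`.

The non-randomness test compares module boundary distances with pooled
distances of 1000 size-matched random gene sets drawn from the
annotated universe excluding the module (the original null
construction is unspecified; this one is calibration-testable, and the
suite checks that p is uniform when the "module" is itself random).
The KS statistic and p come from `stats::ks.test`, with the exact
small-sample distribution when `n_a · n_b ≤ 1e4` and the pooled sample
is tie-free; an enumeration oracle over all C(m+n, n) labelings
verifies both D and the exact p for all small sample sizes.

# Motif scanning and enrichment

PWMs (JASPAR 2016 text format) are pseudocounted (0.01 per cell) and
scored as log2-odds against the background (uniform by default,
overridable). The hit threshold for a window p-value (default 1e-4) is
computed *exactly* by dynamic programming over the discretised score
distribution: each cell contribution is rounded to 0.01-bit bins and
the per-position distributions are convolved; the 0.01-bit rounding is
the method's exactness limit, and within it the DP tails equal
exhaustive 4^L word enumeration (tested to L = 8). Scanning covers
both strands, skips windows containing N, and counts overlapping hits
without masking (the simplest declared convention).

Enrichment subtracts chance occurrence empirically: observed hits in a
module's regions versus size-matched sets resampled from background
regions (non-module promoters, or unassigned enhancers), z =
(obs − mean)/sd of the null. Null sets are drawn **with replacement**:
a without-replacement null from a finite pool deflates the null
variance by the finite-population factor (1 − (n−1)/(N−1)) and
systematically inflates |z|; the with-replacement choice is what makes
the null z pass its N(0, 1) calibration test. Depleted motifs carry
negative z; reporting follows the published convention of ranking by z
with a cutoff of 10 plus adjusted p ≤ 0.05. The promoter window
defaults to 10000/5000 bp around the TSS (the methods value; the
narrower 1000/5000 caption variant is available through the same
arguments). A binomial analytic null and a GC-matched background are
deliberate non-goals here; the empirical resampling null is
assumption-light and is the one whose calibration we can demonstrate.

# The integrated network

Cross-class Pearson correlations on log-CPM (miRNA:mRNA and
miRNA:lncRNA screened separately, each BH-adjusted within its own
pair class) yield negative significant edges; TF→module-gene edges
come from motifs passing enrichment; curated interaction pairs are a
user-supplied table (the generator emits the planted pairs plus
decoys). The union graph is undirected for centrality — the published
degree/betweenness ranking does not state directionality — with edge
provenance retained. Degree and betweenness (unweighted, unnormalised
by default) come from igraph; an exhaustive geodesic-counting oracle
verifies betweenness on all random graphs up to 8 nodes. Hub calling
uses the published class-specific thresholds: degree ≥ 50 for lncRNA
and TF nodes, degree strictly > 10 for miRNAs; boundary cases (50 in,
10 out) are pinned by tests. Master-regulator ranking scores each TF's
target set by hypergeometric overrepresentation among network members
over the annotated universe, BH-adjusted, ties broken lexically.

# Sample ranking

The panel ranking standardises each panel gene across samples on
log-CPM (the original z-scores were computed on qPCR quantities; the
statistic is scale-free after standardisation, so log expression is
the declared substrate), averages z over the panel per sample, and
ranks ascending with lexical tie-breaks. The "middle band" used to
pick early-labour candidates is operationalised as the samples closest
to the median rank — the published figure is visual, so this is a
declared choice. Defaults select 6 low / 6 high / 5 middle samples, as
in the study's sequencing selection from 60 mothers.

# Numerical and reproducibility choices

* All randomness flows from one root seed per entry point; sub-stages
  derive offsets deterministically, and seeded helpers save and
  restore the caller's RNG state.
* Permutation counts default to 1000 (500 inside the orchestrated
  pipeline, where three modules × three classes are scored); both are
  configuration knobs.
* Problem sizes used by the automated checks were chosen to keep the
  whole suite at a few minutes on a single core: 200 null datasets of
  2000 genes for DE calibration, 200 random motifs over 240 regions
  for z calibration, 100 replicates for localization-p uniformity,
  enumeration oracles at n ≤ 6 (KS), L ≤ 8 (PWM words) and ≤ 8 nodes
  (betweenness).
* Degenerate inputs are contracts, not crashes: all-zero samples,
  zero-variance genes, missing panel genes, PWMs longer than their
  sequence, modules equal to the whole ranked list, sd = 0 enrichment
  nulls and infeasible genome packings all have tested error or
  flagging behaviour.

# Known limitations

The DE test is a moderated Welch test, not voom; exact agreement with
the original gene lists is not expected. Module composition (81/46/36)
is planted, not re-derived. The within-domain percentages and the
degree thresholds reproduce published magnitudes only through the
planted design. Enhancer analysis uses supplied enhancer-gene
assignments; no enhancer calling is performed. The localisation test's
asymptotic KS p is approximate at module sizes of a few dozen when
ties are present (integer distances); the exact path engages
automatically for small tie-free samples.
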