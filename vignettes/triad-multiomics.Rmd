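---
title: "Multi-omics classification in allotriploid Brassica hybrids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics classification in allotriploid Brassica hybrids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models behind
each stage, the thresholds and where they come from, what the synthetic
generator does and does not emulate, and the design decisions taken where
the problem left the design open.

# The biological setting

An allotetraploid *Brassica napus* maternal line (AACC) crossed with a
diploid *B. rapa* paternal line (AA) produces an allotriploid F1 (AAC). The
three genotypes therefore differ in subgenome dosage: the A subgenome is
present at relative copy fractions (1/2, 2/3, 1) in (maternal, hybrid,
paternal), the C subgenome at (1/2, 1/3, 0). Two structural facts propagate
through every assay and drive much of the package's design:

* the paternal line has **no C subgenome at all** — C-subgenome genes,
  peaks and cytosines are structural zeros in every paternal sample, not
  sampled zeros;
* parent-versus-parent comparisons (SPA, SPE, ELD against the paternal
  line) are only biologically defined on the **A subgenome**, and the
  corresponding functions refuse or exclude C-subgenome input rather than
  emitting meaningless labels.

# Accessible chromatin regions

Per-replicate ATAC peaks (post-alignment, post-peak-calling) are the input.
A consensus ACR forms when peaks from at least `min_replicates` (default 2)
distinct replicates are connected by pairwise overlaps **strictly longer
than 50 bp**; the consensus interval is the union of the supporting peaks.
The strict reading of "over 50 bp" makes a 50-bp overlap insufficient, and
the union convention makes merging idempotent.

Classification rules, all exposed in `pipeline_params()`:

* positional: genic (any gene-body overlap) > proximal (within 2 kb of a
  gene body, strand-agnostic) > distal, an exclusive precedence so the
  three classes always partition any ACR set. Whether "within 2 kb"
  should be measured from gene bodies or from the TSS/TTS points alone is
  a genuine ambiguity; gene-body flanks are the more inclusive reading and
  are what this package uses.
* novel / silent: `reads >= 5` in every replicate on the defining side with
  **exact zeros** in every replicate on the other side, evaluated on raw
  counts. A normalized zero is only ever a true zero, which is why the zero
  test precedes any scaling. The read floor could plausibly apply per
  replicate or to pooled replicates; per-replicate is the stricter choice
  and is what the generator plants.
* SPA-M / SPA-P: presence (all replicates at or above the floor) in one
  parent plus the hybrid, absence (all zeros) in the other parent;
  A subgenome only.
* TE-driven: strictly more than half the ACR length covered by the
  **union** of TE features (adjacent or overlapping TEs never
  double-count).
* differential accessibility: the package's NB Wald test per ACR,
  BH-adjusted, with |log2FC| >= 1 by default — there is no canonical fold
  bound for accessibility, so the bound is configurable and deliberately
  looser than the expression DEG rule.

# The count test

The classical tool for replicated count testing is DESeq2; exact parity
with it is a non-goal. The package's `nb_two_group_test()` is a documented
simplified relative with the same skeleton:

1. median-of-ratios size factors (`size_factors()`, geometric-mean
   reference, total-count fallback when no gene is nonzero everywhere);
2. per-feature method-of-moments dispersion from within-group variances,
   with the Poisson component removed;
3. a mean–dispersion trend `a0 + a1/mu` fitted to binned medians of the
   moment estimates (medians, so features with real effects cannot drag
   the trend);
4. shrinkage of each feature's dispersion toward the trend with 10
   pseudo-observations, and a Wald statistic — log2 fold change of group
   means with pseudocount 0.5 over its delta-method standard error —
   referred to `t(df_res + 10)`.

The shrinkage weight and the augmented degrees of freedom were calibrated
once against the design target the package states for itself: on 2,000
simulated null NB genes (mean 100, dispersion 0.1, 3 vs 3 replicates) the
raw p < 0.05 fraction must sit in 0.05 ± 0.02 with at most a couple of
BH-significant features, while 8-fold planted effects must be recovered
essentially always. A plain normal reference is anticonservative at three
replicates; a t on the raw residual df (4) is so heavy-tailed that even
8-fold effects cannot clear BH at realistic feature counts. The moderated
compromise passes both ends (observed null fraction ~0.04–0.05, power
~0.99+). All-zero features return the no-signal contract p = 1, log2FC = 0.

# Expression genetics

**In-silico mid-parent hybrid.** Replicate *i* of the in-silico hybrid is
`round(0.5 * (maternal_i/sf + paternal_i/sf))` per gene. The 1:1 mix is
the mid-parent convention even though the maternal line contributes two of
the hybrid's three genomes; a `weight` argument supports sensitivity
analysis around that choice. Mixing is linear and conserves total
normalized signal by construction.

**Additivity.** Hybrid vs in-silico with the NB test; non-additive requires
FDR < 0.05 *and* |log2FC| >= 1.5. **Pattern.** Hybrid–maternal,
hybrid–paternal and maternal–paternal contrasts at the DEG rule
(|log2FC| >= 2): transgressive-up/down means significantly above/below
*both* parents; ELD-M means indistinguishable from the maternal parent,
different from the paternal one, with the parents themselves differing;
additive (by the additivity call) takes precedence over everything, then
transgressive, then ELD. A consequence worth knowing: a gene sitting
exactly on one parent while the parents differ k-fold is at most
`log2(2k/(k+1)) < 1` from the mid-parent value, so clean dominance rarely
clears the 1.5 additivity bound — most ELD calls come from dominance toward
the *lower* parent, which is the arithmetically detectable direction. The
package uses the DEG rule for all parent contrasts and the 1.5 rule only
against the mid-parent.

**SPE.** Expressed means FPKM > 1 in every replicate (strict, so FPKM
exactly 1 is not expressed); silent means FPKM < 0.1 in every replicate.
The silence bound is a package choice (no canonical value exists) and is
configurable. SPE is A-subgenome-only.

**Dosage dependence.** Expression is Pearson-correlated with the subgenome
dosage vector; dependent requires r² > 0.64 (strict) and BH FDR < 0.05.
Negative correlations with r² > 0.64 count as dependent (the criterion is
on r² alone); the sign is reported. Two deliberate design choices:

* *Replicate-level correlation by default.* With per-genotype means there
  are three points and one t degree of freedom, and a genome-wide BH at
  FDR < 0.05 is then essentially unattainable — which would contradict the
  rule itself. Using all replicates (n = 9, 7 df) makes the stated FDR
  criterion operable; the genotype-mean mode remains available as a
  configuration switch.
* *Normalized counts, not FPKM, inside the pipeline.* FPKM divides by the
  whole-library size, and the paternal library has no C subgenome, so its
  A-subgenome FPKM values are inflated by the missing ~40% of the
  transcriptome; flat genes would then correlate with A dosage purely
  through normalization. Median-of-ratios factors are computed over genes
  nonzero in all samples (necessarily A-subgenome genes) and do not have
  this artifact. Within a gene the two scales differ only by a constant, so
  nothing else changes.

The worked desk check: `pearson_cor(c(1/2, 2/3, 1), c(1.72, 1.96, 2.54))`
gives r = 0.9990, r² = 0.9980 (0.99 when truncated to two decimals),
which exceeds 0.64 and classifies the gene dependent.

# Methylation and small RNA

Methylation levels are always **weighted**: pooled methylated reads over
pooled total reads for sites of one context passing coverage >= 5. Site
averaging is never used (two sites 1/10 and 9/10 pool to 0.5 only because
their coverages match; 1/10 and 9/26 pool to 10/36).

The in-silico methylome mixes the parents 1:1 at shared A-subgenome
positions after scaling each parent to the position's mean coverage, so a
deeply-covered parent cannot dominate the mix; C-subgenome positions carry
maternal counts through unchanged. DMRs are called in fixed 200-bp bins
tiling each chromosome: bins need at least 3 qualifying cytosines in both
samples (a package choice), are tested by two-sided Fisher exact on pooled
counts with BH adjustment (standard WGBS practice), and must exceed the
context level
difference 0.3 (CG), 0.2 (CHG) or 0.1 (CHH), strictly. "Coverage of five
or more" is read as per-cytosine read coverage >= 5, the standard validity
filter; the alternative reading (>= 5 cytosines per region) is covered by
the per-bin site minimum anyway. Direction is hyper when sample 1 exceeds
sample 2, and swapping the samples provably flips every direction.

ACR methylation status calls an ACR unmethylated only when every context
with data lies strictly below (0.1, 0.1, 0.05) for (CG, CHG, CHH) — these
bounds are package inventions, exposed in `pipeline_params()` and flagged
as such.

sRNA reads are length-filtered to 18–30 nt, merged into clusters at a
75-bp gap with a 5-read floor (simplified stand-ins for a dedicated sRNA
clusterer; exact parity with such tools is a non-goal), and normalized to
reads per million of total clean reads. Accumulation shifts inside hyper-
and hypo-DMRs are tested by Wilcoxon rank-sum on per-DMR summed RPM,
hybrid versus in-silico, with directions holding fewer than 3 DMRs flagged
underpowered rather than tested.

# The synthetic study

`simulate_all()` emulates the study design — one maternal AACC sample, one
paternal AA sample, one AAC hybrid, three replicates each — on a toy
genome of two A and two C chromosomes of 1 Mb. Genes (800) occupy the
first 60% of each chromosome, leaving a gene-poor arm so the distal class
is populated; 75% of A genes get a C homolog; 240 TEs land genome-wide.
Scale was chosen to keep a full pipeline run in the low minutes on one
CPU; the vignette's numbers and the acceptance run use exactly these
defaults.

Expression classes are planted on the parent-comparable A subgenome:
additive genes sit at the mid-parent value, ELD genes copy one parent with
the parents 8-fold apart, transgressive genes sit 8-fold beyond the more
extreme parent, SPE silence is structural zeros. The 8-fold effect size is
a design point, not a tuning: the DEG rule is |log2FC| >= 2, so a 4-fold
effect sits exactly on the decision boundary where recovery is 50% by
construction; 8-fold (one doubling beyond the boundary) is the kind of
effect the classification is meant to find. Dispersion is 0.1 — a typical
biological replicate value. Dosage classes are the exception: they are
planted as abundant, low-dispersion transcripts (lognormal scale around
800, dispersion 0.01), because the A-subgenome dosage range spans only
2-fold and is unresolvable against 30%+ counting noise at n = 9; the
planted dosage-independent C genes are modeled as compensation overshoot
(hybrid at twice the maternal level despite a third of the dosage), which
is the only C-gene behavior the r² criterion itself scores as independent
given the structural paternal zero. Non-dosage C genes place the hybrid at
half the maternal level — exactly the mid-parent value of (maternal, 0).

ACR loci are planted on a 1.5-kb grid with per-replicate peaks jittered
±30 bp per edge, so the >50-bp merge rule is genuinely exercised;
presence/absence is structural (absent samples have no peak at all), which
is what makes novel/silent/SPA recovery exact rather than statistical.
TE-driven loci are placed inside TEs; 60% of novel loci are placed inside
transgressive-up gene bodies, emulating hybridization-born accessibility
driving transgressive expression, and the integration table recovers that
planted majority. The methylome plants 200 CG DMR bins (8 extra cytosines
each, level shift 0.4, coverage ~30) plus TE hypermethylation and
proximal hypomethylation; sRNA loci at hyper-DMRs get 2-fold more reads in
the in-silico sample and the reverse at hypo-DMRs.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequence content (coordinates only), mapping and
conversion biases, peak-caller artifacts, overdispersed methylation
(binomial only), linkage between accessibility *magnitude* and expression
(only the categorical novel→transgressive coupling is planted), partial
TE overlaps of C-subgenome reads, and biological replicate correlation
structure. Recovery rates here certify the pipeline's logic, not its field
performance.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere (BED convention); GFF3 is
  converted on read and write.
* Ties in nearest-gene assignment break to the smaller start coordinate,
  then the lexicographically smaller gene id — deterministic output for
  deterministic input, which the byte-identity test relies on.
* Fuzzy c-means (k = 9 for accessibility profiles, m = 2, tol 1e-5,
  max 300 iterations, seeded) z-scores profiles row-wise, drops
  constant rows with a warning, and records the objective each iteration;
  the objective is non-increasing and runs are bit-reproducible for a
  fixed seed. k = 9 matches the analysis design; the other settings are
  conventional defaults.
* Wilcoxon uses the exact distribution up to 25 observations per group
  without ties, the tie-corrected normal approximation beyond.
* Fisher's odds ratio applies the Haldane 0.5 correction when a zero cell
  exists; empty margins return p = 1 rather than an error.
* Zero-variance inputs: correlation returns an undefined flag (never a
  fabricated r); dosage classification maps it to independent; all-zero
  count features return the no-signal contract.

# Known limitations

* The NB test is a moderated approximation, not DESeq2; on real data the
  two will disagree at the margin. All package-internal conclusions rest
  on its calibrated operating characteristics, not on parity.
* DML calling over a whole genome is a per-site Fisher loop — fine at the
  package's scales, slow for a 1-Gb genome.
* ELD sub-rules follow the standard dominance framework, but as noted
  above the additive-first precedence makes high-parent dominance mostly
  unreachable; counts of ELD classes are therefore conservative.
* The dosage criterion is an r²-only rule; on the C
  subgenome the structural paternal zero makes many expression patterns
  correlate with dosage, and "dependent" there should be read as
  "consistent with dosage scaling", not as a causal claim.
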