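---
title: "Models and methods behind mirrormeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirrormeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrormeth)
```

## Why simulate this experiment

Monocytes are post-mitotic: when they differentiate into dendritic cells
(DC) or macrophages (MAC) there is no DNA replication, so any loss of CpG
methylation observed along the way must come from an active, enzymatic
demethylation process rather than passive dilution. The experimental
design that detects such losses genome-wide couples three assays:

1. **MCIp fractionation.** Sonicated genomic DNA (mean fragment size
   ~375 bp) is bound to an MBD-Fc fusion protein and eluted with steps of
   increasing NaCl (250, 300, 350, 400, 450, 500, 1,000 mM). Binding
   strength grows with the number of methylated CpGs a fragment carries,
   so low-salt fractions (250–350 mM) contain unmethylated DNA (the
   *CpG pool*) and high-salt fractions (400–1,000 mM) methylated DNA
   (the *mCpG pool*).
2. **Mirror-image promoter arrays.** The CpG pools of DC and MAC are
   co-hybridized on one two-channel promoter tiling array, the mCpG
   pools on a second. A genuine methylation difference appears with
   opposite sign in the two hybridizations — enrichment in one pool is
   mirrored by depletion in the other — while shared artefacts (copy
   number, probe affinity) move both ratios together. The per-probe
   statistic is the difference of the two log10 ratios,
   \(s = \log_{10}(DC/MAC)_{CpG} - \log_{10}(DC/MAC)_{mCpG}\);
   positive \(s\) marks hypomethylation in DC.
3. **EpiTYPER validation.** Called regions are re-measured by bisulfite
   PCR, in-vitro transcription of the reverse strand (T7-tagged reverse
   primer), base-specific T-cleavage of the transcript, and MALDI-TOF
   mass spectrometry. Each methylated CpG replaces an A by a G in the
   transcript and shifts the covering cleavage fragment's mass by
   ~16 Da, so relative peak intensities of the k-methylated species
   quantify the methylation ratio of each *CpG unit* (the CpGs sharing
   one fragment).

`mirrormeth` implements all three stages over a seeded synthetic genome
and methylome with planted differentially methylated regions (DMRs), so
that every downstream claim — sensitivity, false-discovery proportion,
direction correctness, cross-assay concordance, kinetics classes — can
be checked against a known ground truth.

## The synthetic genome and methylome

`generate_genome()` builds random chromosomes with a controlled
background CpG dinucleotide density (default 0.01/bp), places genes
whose strand-aware promoter windows (−4,000..+1,000 bp around the TSS)
do not overlap, and re-plants CpGs inside each promoter at the density
of its class: *low* (0.02/bp) or *intermediate* (0.05/bp). There is no
CpG-island-like high class because the regions this assay targets are of
low to intermediate CpG content. The generator additionally scatters
dispersed 600-bp CpG clusters (density 0.02/bp, 15 per chromosome)
outside promoters: non-promoter DMRs have to live somewhere, and a
region without clustered CpGs has no methylation signal for either
assay.

`plant_methylome()` assigns every CpG a population methylation fraction
per cell state. Methylation is regionally coherent in real genomes, so
flat baselines are drawn per 2-kb domain from a bimodal-with-shoulder
mixture (45% unmethylated, 45% methylated, 10% intermediate) and
jittered per CpG (sd 0.05). Planted DMRs (default 10; positional mix
40% promoter-proximal, 30% intragenic, 30% intergenic) start methylated
in monocytes (MO fraction drawn in (0.87, 0.95)) and are demethylated
along the DC lineage only. MAC and DC baselines differ from MO by a
truncated-Gaussian offset (sd 0.02) that is clamped at the MO value:
post-mitotic cells cannot gain methylation, so the model contains no de
novo methylation by construction, and DC trajectories are deterministic,
monotone non-increasing curves.

### The demethylation curve

The decay of a DMR CpG is a logistic in time with a locus-specific
onset (midpoint) and steepness, rescaled so that the value at t = 0
equals the initial fraction exactly:

\[
f(t) = f_\infty + (f_0 - f_\infty)\,
\frac{1 + e^{-s\,t_{1/2}}}{1 + e^{s\,(t - t_{1/2})}}
\]

The plain logistic never quite attains \(f_0\) at t = 0; anchoring the
curve there keeps the boundary exact while moving the true midpoint by
less than 0.002 at the default steepness (0.3/h) for onsets of 18 h or
later — negligible against every other noise source, and tested at that
tolerance. Onsets come in two classes matching the observed kinetics:
*early* in [18, 42] h and *late* beyond 51 h. The late range is capped
at 120 h (not the day-7 endpoint, 168 h) because a midpoint at the
endpoint would leave the CpG half-methylated on day 7, contradicting
the requirement that planted DMRs reach a fraction of at most 0.2 by
then.

## The MCIp model

`fragment_genome()` draws uniform fragment starts with truncated-
Gaussian lengths (375 ± 50 bp) at a configurable mean coverage (default
30×) and samples each fragment's methylated-CpG count by independent
Bernoulli draws per overlapped CpG with that site's population
fraction. `elute_fragment()` maps the methylated-CpG count m to an
expected step index through a logistic with midpoint 3.5 mCpGs and
slope 1.2 per mCpG; the realised index is a stochastic rounding of the
expectation (so the mean step is strictly increasing in m even between
counts whose expectations round alike) plus a one-step shift with
probability 0.1. Under these defaults an unmethylated fragment lands in
the CpG pool essentially always and a fragment with ≥ 10 methylated
CpGs elutes at 1,000 mM in ~95% of draws. `pool_fractions()` applies
the 250–350 / 400–1,000 mM pooling rule, and `control_recovery()`
reports per-region pool fractions for the fractionation controls (a
CpG-free "Empty" region, an imprinted-like region at 50% methylation,
and a dense fully methylated region).

## Array simulation and DMR calling

`design_probes()` tiles every promoter window at 200-bp spacing with
50-mers (both window endpoints included), plus optional extra intervals
— the simulated counterpart of a custom array's additional tiled
regions. In `run_pipeline()` these extra tiles cover the planted
non-promoter DMR neighbourhoods ± 2 kb; without them no probe could
interrogate intergenic or intragenic DMRs at any threshold.

Probe intensity is gain × (pool fragment count over the probe +
background 2) × lognormal noise (sdlog 0.1) × a dye bias (1.3) on the
DC channel. `normalize_channels()` removes the dye bias by scaling each
channel to the geometric mean of the two channel medians (linear
normalization); `filter_probes()` flags probes with any channel outside
the (0.001, 0.999) quantiles of that channel — "extremely high or low"
made operational; `mirror_score()` computes \(s\) with a positive
intensity floor before the logs.

`call_dmrs()` requires at least `min_probes` (default 2) consecutive
unflagged probes of the same tile with |s| ≥ `threshold` and a
consistent sign **in both biological replicates** (intersection of the
qualifying probe sets, not score averaging). The shipped threshold is
0.6. This value is a calibration on the generator's default conditions,
not a literature value: adjacent probes (200-bp spacing) share
overlapping ~375-bp fragments, so their sampling noise is correlated and
occasional two-probe runs reach |s| ≈ 0.5 in both replicates at
intermediate-methylation domains; 0.6 removes them while every planted
DMR still scores |s| ≈ 1.5–2. At these settings the recovery properties
(sensitivity ≥ 0.9, false-discovery proportion ≤ 0.1, exact direction)
hold across the seeds exercised in the test suite.

`annotate_dmr()` reports the signed, strand-aware distance from the
central probe midpoint to the nearest TSS, the positional class
(proximal promoter if |distance| ≤ 1,000 bp — a definition this package
fixes, since "proximal" has no universal cutoff — else intragenic
inside a gene body, else intergenic), and CpG count and GC fraction in
the 500-bp window centred on the central probe.

## EpiTYPER simulation

Only the informative reverse-strand T-cleavage reaction is modelled.
After complete bisulfite conversion (C→T outside CpG context; CpG
cytosines retained when methylated), the transcript is the RNA copy of
the amplicon's reverse strand. Its uracils derive from forward-strand
adenines, so the cleavage pattern (cut 3′ of every U) is independent of
methylation; only fragment masses shift, by the G−A residue difference
of 16.00 Da per methylated CpG. Residue masses are fixed average
ribonucleotide-monophosphate masses with an 18.02-Da terminal constant;
correctness is defined by the residue-sum oracle in the test suite, and
the quantification depends only on the 16-Da increment. Peak
intensities of the k-methylated species are proportional to the
Poisson-binomial probability of k methylated CpGs in the unit times
lognormal noise (sd 0.1), and the unit ratio is
\(\sum_k k I_k / (n \sum_k I_k)\). A unit is unmeasurable — flagged,
never silently quantified — if any of its peaks leaves the 1,500–7,000
Da detection window or lies within 0.5 Da of a peak from a different
fragment. Amplicon lengths are bounded to 200–600 bp.

`assess_concordance()` declares an array-called region concordant when
the sign of (MAC mean ratio − DC mean ratio) matches the array
direction, and an array-negative control concordant when the two assays
agree there is no difference (|difference| < 0.1). These operational
definitions are this package's own; the regions entering the
denominator are those with at least one measurable unit in both states
— regions whose amplicons yield nothing are "not detected by MS", just
as some amplicons fail in practice.

## Downstream reports

`fit_demethylation_kinetics()` least-squares-fits the anchored logistic
(steepness fixed at the generator default) and classifies the estimated
onset: *early* up to 46.5 h, *late* beyond — 46.5 h is the midpoint of
the (42, 51] h interval that the two observed classes leave unassigned
— and *none* when the fitted change is below 0.2 or the profile rises
by more than 0.15 (demethylation is monotone; a gaining profile is
flagged rather than fitted). With the default sampling grid (0, 6, 18,
30, 42, 51, 66, 168 h) onsets are recovered to well within ±6 h
wherever the grid covers them; onsets beyond 66 h are not identifiable
from these time points — only their class is — because the curve is
indistinguishable for any midpoint between the last two samples.

`expression_association()` splits DMR-associated genes into
up-regulated (maximum DC fold change over the monocyte baseline ≥ 2 at
any time — a definition this package fixes, as "up-regulated" needs an
operational cutoff) and unchanged, and compares the CpG counts and GC
fractions of the two groups' DMR windows with a two-sided Mann-Whitney
U test: exact enumeration of all group assignments for group sizes up
to 8 (ties handled exactly), mid-rank formula with tie-corrected normal
approximation above that. Expression matrices are normalized to a
common 75th percentile per sample and baseline-transformed to the
monocyte median per gene.

`chip_enrichment()` implements percent-input ChIP-qPCR normalization,
\(100 \times 2^{(Ct_{input} - \log_2(1/f)) - Ct_{IP}}\) with input
fraction f = 0.05, and relative enrichment against the 0-h (monocyte)
sample, which is exactly 1 by construction.

## Problem sizes and determinism

The default study is two 100-kb chromosomes, 20 genes, 10 planted DMRs,
coverage 30×, two biological replicates — a deliberate desk-scale
reduction of a 244K-probe / 17,000-promoter array that keeps every
stage's statistical structure while a full run completes in seconds.
Every stochastic stage draws its own child seed from the master seed;
identical configuration and seed reproduce all outputs bit-for-bit
(sequence files) or to within numerical round-off (tables).

## What the simulation does and does not show

The generator reproduces the *statistical* structure the analysis
relies on: methylation-load-dependent fractionation, reciprocal
two-channel signals, replicate structure, near-binary methylation with
locus-specific decay kinetics, mass-spectral unit structure with
unmeasurable units. It does not model PCR or labelling chemistry biases,
bead capacity, incomplete bisulfite conversion, co-methylation of
neighbouring CpGs on the same molecule (a correlation parameter is
deliberately left at zero), repeat structure or SNPs, or spectral
peak-picking. Passing tests therefore demonstrate the correctness and
internal consistency of the analysis pipeline under its stated model,
not the wet-lab performance of the assays on real chromatin.
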