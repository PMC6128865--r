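---
title: "Models and methods behind spliceoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spliceoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spliceoscope)
```

# Scope

spliceoscope analyzes mis-splicing in myeloid neoplasms carrying
spliceosome-gene mutations (SF3B1, SRSF2, U2AF1) from splice-junction
read counts. It covers the full analytic chain: cataloging alternative
splicing events against gene models, percent-spliced-in (PSI)
quantification, differential splicing between mutation-defined groups,
transcript-consequence classification, PSI-adjusted canonical-transcript
expression testing, nonsense-mediated decay (NMD) assessment from paired
cycloheximide (CHX) experiments, positional splicing-enhancer motif
analysis, 3' splice-site context, and a multi-criteria cascade that
nominates functional targets. A seeded synthetic-study generator with a
complete ground-truth ledger backs every stage with recovery and
calibration experiments; patient-level data never enter the package.

# Data model and conventions

All coordinates are 1-based and inclusive, in the GTF dialect. A
junction is identified by its first and last intronic bases plus strand
(`chr:start-end:+`). Sequence-level operations always work on the sense
strand; minus-strand loci are reverse-complemented on extraction. The
CDS is carried in transcript coordinates and includes the stop codon.

PSI is the percentage of informative reads supporting the isoform the
event measures:

* alternative 5'/3' splice sites — usage of the alternative site
  (inclusion evidence is the novel junction);
* intron retention — the retained fraction, with the mean of the two
  exon–intron boundary counts as inclusion evidence and the spliced
  junction as exclusion;
* cassette exons — exon inclusion, the field's usual orientation, so a
  skipping-promoting mutation shows a negative PSI shift.

Each side's evidence is the mean count over its junction/boundary set
(identical to a sum for single-junction sides, which covers all
alternative-site events). Averaging rather than summing keeps the two
inclusion junctions of a cassette event from being double-counted
against its single skip junction. PSI is undefined below an informative
read total of 5, the threshold the junction-based pipelines in this
field use by default.

# Event enumeration

Intron-retention events are created for every annotated intron — the
annotation plays the role of the curated reference transcript set.
Cassette, mutually exclusive and alternative first/last exon events are
read off annotation-declared alternative transcript structure, requiring
observed junction support on both sides. Novel observed junctions are
assigned to at most one event by precedence: a junction sharing one
annotated anchor site with a novel partner site within 500 nt is an
alternative 5'/3' splice site (signed offset; negative means the mRNA
gains sequence); a junction with both sites annotated in one transcript
and exactly one exon in between is an exon skip. Junctions skipping
several exons at once are deliberately not assigned — coordinate skips
are excluded from the taxonomy — and are reported in a skip counter, as
are junctions on chromosomes the models do not know.

# Differential splicing

Per event and cell fraction, mutated and splicing-factor-unmutated
samples are compared with the two-sided unequal-variance (Welch) t-test;
no PSI-difference floor is applied at the testing stage. Events enter a
comparison when PSI is defined in at least three samples per group;
events whose two groups are both constant are excluded rather than
assigned p = 0, which keeps the null calibration honest.
Benjamini–Hochberg correction runs within each (comparison × fraction)
family, mirroring a per-fraction testing design, and the cross-fraction
"associated" set is the union of per-fraction discoveries at q < 0.01.
PSI fold changes carry a 1-percentage-point pseudocount on both means.

# Transcript consequences

Each event is applied to its anchor transcript (for multi-isoform genes
the longest-CDS transcript) as a single contiguous edit: inserted
intronic segment for upstream alternative 3' sites and intron retention,
removed exon for skips, truncated or extended exons for the other site
shifts. The annotated start codon is kept. Classification:

* edit outside the CDS → `non_coding` (this includes 5'-UTR alternative
  3' sites);
* edit removing the start or stop codon → `alt_first_coding_exon` /
  `alt_last_coding_exon`;
* net length change not divisible by three → `truncating` by
  `frameshift`, regardless of where the new stop lands (a shifted frame
  almost always finds a stop in the 3' UTR);
* in-frame edit with a stop strictly 5' of the annotated stop →
  `truncating` by `PTC_in_frame`; otherwise `non_truncating`.

The 50-nt exon-junction rule is emitted as an auxiliary annotation only:
NMD sensitivity is determined empirically from CHX data, not predicted
from PTC position. The test suite checks the classifier against an
independent oracle that rebuilds each isoform from genomic segments,
aligns it to the canonical mRNA by common prefix/suffix, and translates
codon by codon.

# Canonical-transcript expression

For genes with truncating events, the event with the highest PSI fold
change versus controls scales the gene's counts by `(100 - PSI)/100`
per sample (rounded; undefined PSI leaves the sample unadjusted). The
fold-change criterion (rather than significance rank) selects the
event; both orderings coincide for the strong, specific events this
step is aimed at. Counts are TMM-normalized — the in-package
implementation follows the published weighted-trimmed-mean-of-M-values
recipe (30%/5% two-tailed trims on M and A, precision weights,
geometric-mean-1 factors) and is cross-checked against the reference
implementation in the test suite. Genes above 1 CPM in at least six
samples are tested with a log-link negative-binomial GLM with
`offset(log(lib * factor))` and a likelihood-ratio test against the
intercept-only model.

Dispersions are method-of-moments estimates from within-group variances,
shrunk 75% (on the log scale) toward a lowess mean–dispersion trend.
Gene-wise moment estimates are noisy at cohort scale and the heavier
trend weight keeps the LRT's null type-I rate at the nominal 5% in the
package's calibration experiments while preserving gene-specific
signal; this is the same trade the trended-dispersion practice in
count-model packages makes. Dispersion estimation is deliberately
simpler than full empirical-Bayes machinery — exact numerical
replication of any particular implementation is a non-goal, calibration
is the contract.

# NMD assessment

Paired CHX-treated/untreated samples are compared per event. The default
test is Cochran–Mantel–Haenszel over the per-pair 2×2
inclusion/exclusion × treated/untreated read-count tables — it uses the
read-level evidence directly and handles few pairs gracefully; the
statistic is the classic one-degree chi-square with hypergeometric
variance and no continuity correction (calibration verified by
simulation; for a single stratum it equals `(T-1)/T` times the Pearson
chi-square, which the tests assert exactly). A paired t-test on PSI is
available alongside, since both appear in practice for this contrast.
`nmd_sensitive` requires q < 0.01 and an increase after treatment
(two-sided test plus a sign requirement). An event is "detected" in a
sample when its inclusion evidence is positive and the informative
total meets the read threshold; events detected in treated but in no
untreated or primary samples are CHX-specific — completely degraded
isoforms whose d = 0 makes them invisible without NMD inhibition.

# Motif and splice-site analysis

Exons are split into four near-equal segments 5'→3'; when the length is
not divisible by four the spare nucleotides go to the 3'-most segments
(the region of interest; the convention is stated because no standard
exists). IUPAC matches (S = C/G, N = any) are counted overlapping, with
a match assigned to the segment holding its first base. Enrichment is
the target-to-baseline density ratio with a 95% CI from the normal
approximation of the log rate ratio — counts behave as Poisson at these
scales. The acceptor context reports the −3 base as the last intronic
base before the invariant AG (the standard yAG convention) and the +1
base as the first exonic base; non-AG acceptors are flagged rather than
silently reported. Intron features (length, GC) are compared by
two-sided Mann–Whitney U.

# The synthetic-study generator

The generator is first-class, tested code; its defaults are the study
conditions every calibration experiment runs under.

* **Reference.** One gene per chromosome, 5–7 exons, exon lengths
  90–240 nt; intron lengths lognormal in two regimes — short/GC-rich
  (median 410 nt, GC 54%) and long/GC-poor (median 1.8 kb, GC 43%) —
  with `sdlog` matched to the interquartile ranges those regimes are
  characterized by (0.16–1.1 and 0.58–5.8 kb) and a 50 kb cap on the
  lognormal tail. CDS content is controlled: codons are drawn stop-free,
  planted inserts are built to contain (or provably lack) in-frame stop
  codons at the correct phase, and splice sites keep GT..AG with a
  configurable −3 base. This is what makes the generator's consequence
  labels true by construction.
* **Cohorts.** 30 mutated vs 40 control samples per cell fraction by
  default — large enough to exercise the Welch test, small enough for
  desk scale. Per event and sample, inclusion reads are beta-binomial
  (`rho = 0.02`) around the group's true PSI on a negative-binomial
  informative-read total; biological replicates are overdispersed, and
  binomial sampling alone would make the t-test look better than it is.
  At the default depth used in the power experiment (180 informative
  reads) the within-group PSI standard deviation lands near 8%, the
  design point at which a 10% absolute PSI difference is detectable at
  two-sided alpha 0.001 with 90% power.
* **Planted effects.** The default effect table mirrors the mutation
  signatures under study: near-zero-baseline alternative 3' splice-site
  spikes specific to the SF3B1 group with mixed consequences and NMD on
  the PTC-bearing ones, a small broad intron-retention decrease, and
  cassette-exon inclusion shifts for the SRSF2 group.
* **NMD.** Degradation is multiplicative read thinning of the
  PTC-isoform by a survival factor d in untreated samples; CHX sets
  d = 1. The closed-form untreated PSI, `d·p/(d·p + (1-p))`, is the
  oracle the tests check against; d = 0 produces CHX-specific events
  exactly.
* **Expression.** Gene counts are negative binomial (dispersion 0.1)
  with the mean of truncating-event genes scaled by
  `(1 - truncating PSI/100)`, coupling expression to splicing truth.
* **Motifs.** Chance CCNG/GGNG matches are scrubbed from exon
  backgrounds before occurrences are planted at per-quarter Poisson
  rates, so the realized density ratio equals the planted multiplier —
  included exons get 2× CCNG (and 0.5× GGNG) in their 3'-most quarter by
  default.

What the generator does not emulate: alignment artifacts, batch and
library-preparation effects, correlated events within a gene, fractional
tumor purity in the junction counts, and isoform-level read assignment
ambiguity. Passing recovery tests on this generator therefore
demonstrates the statistical machinery and the classification logic, not
robustness to upstream processing noise in real cohorts.

# Numerical and design choices

* Zero-variance events are excluded from testing rather than given
  p = 0; undefined PSI never enters a mean.
* Degenerate CMH strata (zero margins) are dropped and counted.
* The target cascade's 2-fold rule compares plain means (a pseudocount
  there would contradict the rule's own worked arithmetic); the 10-fold
  specificity rule keeps a 1-pp pseudocount since its controls sit at
  zero.
* Fisher's exact test is two-sided by the point-probability method; odds
  ratios use the Haldane correction when a zero cell exists; a zero
  margin returns p = 1, flagged.
* Recapitulation in isogenic clones uses group-mean direction
  consistency (3 vs 3 clones by default) — per-clone unanimity is not
  required.
* U2AF1 variants are matched by genotype prefix, so S34F/S34Y pool into
  "U2AF1:S34" while S34 and Q157 stay separate.
* Experiment sizes in the acceptance suite (5,000 null events × 20
  seeds; 200 power replicates; ~1,000 classifier events; 2,050
  expression genes; 200 motif seeds) are chosen to make the binomial
  noise of each estimated rate small relative to its acceptance band at
  desk scale.

# Known limitations

Cryptic exons are handled when annotated on an alternative transcript,
not discovered de novo from junction pairs. Intron-retention inclusion
uses boundary counts, not length-normalized intron body coverage, so IR
PSI values are comparable within this package but not numerically
identical to coverage-based pipelines. The expression model tests a
two-level contrast per fraction; covariate-adjusted designs are out of
scope. The cohort-scale discovery counts published for patient data are
not reproducible here by design — the controlled-access cohort is
replaced by the generator, and the package's claims are calibration and
recovery, not replication of patient-level tallies.
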