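---
title: "Variant enhancer loci from paired H3K27ac cohorts: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant enhancer loci from paired H3K27ac cohorts: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velcall)
```

## The problem

Active enhancers carry acetylated H3K27 (H3K27ac). In a cohort of patients
with matched tumor and adjacent normal ("native") tissue, enhancers whose
H3K27ac signal differs strongly within a pair mark regulatory rewiring of
the tumor. A single pair is noisy — tissue composition, ChIP efficiency and
sequencing depth all vary — so the unit of inference is the *recurrently*
variant locus: a genomic region that gains (or loses) acetylation in many
patients independently. `velcall` implements that analysis end to end:

1. classify peaks into promoters and enhancers by TSS distance,
2. quantify per-region signal as reads per million mapped reads (RPM),
3. call per-patient variant enhancer loci (VELs) by fold change,
4. merge calls across patients, count recurrence, and score each merged
   locus with a paired t-test corrected by Benjamini–Hochberg (BH),
5. select the recurrence threshold at which a target share of loci is
   significant,
6. repeat the same machinery at super-enhancer scale (VSELs), and
7. summarise super-enhancer-associated transcription factors as a core
   regulatory circuitry (CRC) network.

All coordinates are 0-based half-open (BED convention). Every user-facing
function takes and returns plain tibbles, so the pipeline composes with
dplyr; fitted results support `tidy()`, `glance()` and `autoplot()`.

## Signal model

**RPM.** Each aligned fragment is reduced to a 200 bp footprint running
3'-ward from its 5' start (minus-strand reads extend leftward, clipped at
zero). Region signal is the mean per-bp footprint coverage over the region,
scaled by $10^6/\text{library size}$. The per-bp *mean* — not the region
sum — is used wherever signals are compared across loci, so values are
comparable between regions of different lengths. The one deliberate
exception is super-enhancer ranking, where signal is the region-*summed*
RPM (mean × length): a long cluster of moderately strong peaks should
outrank a short sharp peak, which is the established convention for
hockey-stick ranking. Whether downstream signal should be per-bp or summed
is genuinely underdetermined by the field's practice; we chose per-bp for
comparability and documented the divergence at the super-enhancer step.

**Promoters and enhancers.** A peak is TSS-proximal iff it overlaps
$[\text{TSS} - 2500, \text{TSS} + 2500)$ for any TSS (any-overlap, not
midpoint containment — "away from the flank" reads naturally as no
overlap). H3K4me3 proximal peaks are promoters; H3K27ac peaks with no
overlap are enhancers. Cohort-level "significant" elements are merged
loci supported by peaks from at least two samples of the same tissue;
singletons are treated as irreproducible.

## The VEL pipeline

Per patient, the tumor and native enhancer peaks are unioned (gap 0) into
that patient's enhancer loci, and

$$\mathrm{fc} = \frac{\mathrm{RPM}_\text{tumor} + c}{\mathrm{RPM}_\text{native} + c}$$

with pseudocount $c = 0.5$ RPM (configurable) guarding against zero native
signal. A locus is a gain VEL when $\mathrm{fc} > 2$ strictly, a lost VEL
when $\mathrm{fc} < 1/2$; a ratio of exactly 2 is not a call.

**Patient QC.** Patients are excluded when either H3K27ac sample has fewer
than 2,500 peaks or when their total VEL count is below 500 (strict
less-than; a patient at exactly the threshold is retained). These defaults
are genome-scale counts: low values indicate a sampled tissue piece with
too few tumor cells rather than biology. On the bundled toy genome
(~2,000 enhancers) the same *rules* apply with scaled values — we use 500
peaks and 50 VELs in the validation runs, chosen from the generator's
expected per-patient call counts (roughly 2,000 peaks and 150–350 VELs per
patient at default noise).

**Recurrence and significance.** Gain and lost calls are merged separately
(gap 0); the recurrence of a merged locus is the number of distinct
patients with an overlapping same-direction call. At every merged locus a
two-sided paired t-test is computed on the region-mean RPM of *all*
retained pairs — carriers and non-carriers alike — because recurrence and
the test are deliberately separate summaries: recurrence measures breadth,
the t-test measures a consistent cohort-level shift. p-values are
BH-adjusted within each direction (the two directions are reported with
separate thresholds, so a joint correction would couple them). Degenerate
loci follow fixed conventions: all differences zero gives $p = 1$;
identical nonzero differences give $p = 0$; a single retained pair gives
$p = 1$ (no evidence).

**Threshold selection.** For each candidate recurrence $r$ from 1 to the
maximum observed, the *cumulative* significant fraction is the share of
records with recurrence $\ge r$ whose adjusted p is below $\alpha$; the
selected threshold $r^\*$ is the smallest $r$ at which that fraction
reaches the target (0.95 for VELs, 0.9 for VSELs and subgroup analyses).
A record is significant iff $p_\text{adj} < \alpha$ *and* its recurrence
reaches $r^\*$. If no $r$ reaches the target the threshold is reported as
"not reached" and nothing in that direction is significant. The default
$\alpha$ is 0.05; 0.1 is equally defensible and is a plain argument.

## Super-enhancers and VSELs

TSS-distal H3K27ac peaks within 12.5 kb are stitched into candidate
regions. Regions are ranked ascending by region-summed RPM; rank and
signal are rescaled to $[0,1]$ and the cutoff is the signal at the first
rank where the discrete slope (first differences) of the rescaled curve
exceeds 1 — the point where a slope-1 tangent touches the hockey stick.
Regions with signal strictly above the cutoff are super-enhancers.
Numerics: the strict comparison carries a $10^{-9}$ tolerance so an
exactly linear curve (slope identically 1, no tangent point) yields zero
super-enhancers rather than floating-point artifacts; ties at the cutoff
value resolve toward fewer super-enhancers; an all-equal signal vector
warns and flags nothing. The cutoff index is invariant to positive affine
rescaling of the signals. By default only stitched regions of two or more
constituent peaks are super-enhancer candidates ("sets of two or more
peaks"); singletons stay in the ranking for diagnostics but are never
flagged. The discrete tangent is deliberately simple and can be sensitive
to large gaps in the upper tail of the background signal distribution —
occasionally a sample's cutoff lands low and many background regions are
flagged; the planted clusters remain above the cutoff regardless.

VSELs run the identical pipeline over per-patient super-enhancer loci
(union of the pair's flagged regions), with patient exclusion below 10
VSELs (strict less-than) and a target fraction of 0.9. Exclusions are
recomputed at each stage rather than inherited, matching how the two QC
rules are stated independently. Super-enhancer-to-gene assignment uses the
nearest TSS within 50 kb of the region midpoint; the data model carries
TSS points rather than gene bodies, so "overlapping gene" assignment
reduces to the same rule. Per gene, SE recurrence is counted per tissue
and the variant recurrence is tumor minus native.

## Subgroup-specific gains

Given per-sample subgroup labels (e.g. consensus molecular subtypes,
consumed as input), a gain VEL is specific to subgroup $S$ iff the mean
tumor RPM of $S$ strictly exceeds 1.5× the mean of *every* other subgroup.
At most one subgroup can win; all-equal means yield none.

## CRC network

Transcription factors associated with super-enhancers form a directed
network: TF$_j$ → TF$_i$ when TF$_j$ has a motif hit inside TF$_i$'s
proximal super-enhancer or promoter. IN degree of TF$_i$ counts distinct
TFs hitting its regions (self-loops count, the usual convention of CRC
software); OUT degree counts TF-associated *super-enhancer* regions
(promoter rows are excluded from OUT) containing a hit of TF$_i$; total =
IN + OUT. Motif hits are consumed from a table (HOMER/FIMO-style); a small
log2-odds PWM scanner over both strands (`scan_pwm`, uniform background,
`N` scores 0, 0-based offsets) is included so tests and examples need no
external scanner. Degrees are computed once per tissue group on the
group's consensus SE set — a per-sample-then-average variant would also be
defensible, but a single network per group is what the delta ranking
(tumor minus native total degree) consumes.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, not raw sequencing:

* a toy genome (default 4 × 30 Mb) with TSS and enhancer loci placed on a
  shuffled 20 kb grid, so ordinary loci can never merge or stitch with one
  another and all loci respect the ±2.5 kb TSS exclusion;
* 30% of ordinary enhancers are placed as 2-peak clusters under 12.5 kb
  apart, so stitched multi-peak regions exist outside the planted
  super-enhancers (real enhancers cluster; an all-singleton background
  would make the hockey stick degenerate);
* negative-binomial fragment counts per locus and sample (variance
  $\mu + \phi\mu^2$, default dispersion $\phi = 0.05$) emulating
  inter-patient biological variability; fragments are 5' positions placed
  uniformly within the locus ± 100 bp;
* planted gain/lost VELs (default 200/50) with tumor:native ratio 3 in
  carriers; carriers are drawn *exactly* — the first
  $\lceil 0.75 n \rceil$ patients of a per-locus shuffle — so planted
  recurrence is a constant, not binomial;
* 10 planted super-enhancer clusters (3 peaks in a 10 kb span at 10× base
  rate), 6 of which gain 3× in carrier tumors;
* a detection floor (count ≥ 5) decides which loci enter a sample's peak
  file, standing in for peak-caller sensitivity;
* every sample is topped up with uniform genome-wide background fragments
  to a fixed depth (200,000 reads), like sequencing libraries to equal
  depth. This matters: if library size were left at the emitted count,
  planted gains would inflate tumor libraries and RPM normalisation would
  push every background locus toward "lost" — a composition bias the
  generator should not build in;
* everything is reproducible from the config seed alone, and the caller's
  RNG state is untouched.

What the generator does **not** emulate: GC and mappability bias,
copy-number confounding, fragment-length distributions, read sequences,
peak-boundary jitter (emitted peaks are the true loci), or
between-patient correlation structure beyond the planted effects. Passing
tests on this cohort therefore demonstrates the pipeline's statistical
behaviour under its own assumptions, not robustness to alignment-level
artifacts.

## Validation design and problem sizes

The test suite validates each kernel against an independent oracle
(brute-force interval union, hand step-up BH, closed-form t, exhaustive
double-loop degree counts, analytic tangent of a quadratic) and the whole
pipeline against planted truth: 40 pairs × 2,000 enhancers with 250
planted VELs for recovery/false-discovery checks, five balanced cohorts of
the same size for null calibration, and a 10-cluster cohort for the
super-enhancer stage. One subtlety: under the null, the p-values of
pipeline *records* are slightly non-uniform by construction, because a
record exists only where at least one pair crossed the fold-change
threshold — a selection effect inherent to the published design, present
in any reimplementation. Calibration is therefore asserted where the
statistic's null distribution is actually pinned down: the paired t over
*all* enhancer loci of a balanced cohort is uniform (KS), and the full
pipeline on the same cohorts reports zero significant loci.

## Known limitations

* The discrete tangent cutoff has no smoothing; heavy-tailed background
  signal occasionally yields permissive per-sample cutoffs.
* Recurrence counts overlap of merged loci, not reciprocal peak matching;
  very broad merged loci can chain distinct events (mitigated here by the
  paired t-test over all pairs).
* Gene assignment is TSS-distance-based; no enhancer–promoter contact
  information is used.
* The VSEL stage consumes per-sample super-enhancer calls as-is; no
  cross-sample consensus stitching is attempted before pairing.
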