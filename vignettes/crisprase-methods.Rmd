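---
title: "Models and methods behind crisprase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crisprase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprase)
library(dplyr)
```

# The experiment this package models

crisprase analyses double-CRISPR enhancer-deletion experiments performed in
an F1 hybrid embryonic stem cell line derived from a CAST x 129 cross. Two
guide RNAs flank a large distal super-enhancer downstream of a focal gene
(the Sox2 situation: a ~13 kb enhancer ~100 kb downstream); non-homologous
end joining fuses the two cut sites and removes the intervening sequence
from one or both chromosomes. Because every transcript carries strain SNPs,
expression can be read out separately per parental allele, which separates
*cis* effects (confined to the deleted chromosome) from *trans* effects
(shared by both alleles, mediated by the depleted protein).

The package implements the full analysis chain — variant QC, allele-specific
read counting, expression signatures, clone genotyping and
restriction-fragment loop profiling — together with a synthetic-data
generator with known ground truth, so that every stage is testable without
any external download.

# The synthetic experiment generator

## Genome, variants and clones

`build_reference()` creates a two-chromosome diploid genome. The scale is
deliberately desk-sized: a 200 kb focal chromosome with a 1.3 kb enhancer
20 kb downstream of a 2 kb focal gene (topologically faithful to the real
locus, ~150x smaller), and a 170 kb control chromosome carrying the
copy-number control interval and most of the gene panel. All distances are
configurable. Variants are planted as a thinned Poisson process at
`snp_density` (default 5/kb, reflecting the high SNP density that makes the
hybrid line attractive); 10% of intergenic variants are indels. Two
diagnostic SNPs are always planted in the downstream junction-amplicon
flank, mirroring the screen design in which two 3' SNPs on the PCR product
identify the targeted allele.

Indels are planted only outside gene bodies. This is a deliberate
simplification: reads then never straddle an indel, so a read's reference
placement is a simple offset while indels still exercise the dummy-read,
VCF and junction machinery. Real data would require gapped placement of
reads across indels, which the assignment module handles by exact window
matching but the generator does not produce by default.

`simulate_clones()` applies the deletion to the rostered alleles. NHEJ
scars are drawn as geometric(0.3) lengths, deletion-biased 2:1 over
insertion and capped at 50 bp — the small heterogeneous junction
variation characteristic of double-cut NHEJ repair. An *inverted* allele
models an occasional repair outcome of double-cut screens — a short
inversion between the cut sites giving a larger but still amplifiable
junction product — as the
enhancer excised with a short (250 bp) enhancer-edge segment reinserted in
reverse complement. The enhancer interior is therefore absent from an
inverted allele and its copy-number assay reads one copy, which is how such
clones are tallied in the screen.

## The expression model

For gene $g$ and allele $h$ the expected count is

$$\mu(g,h) = d \cdot \beta_g \cdot f(g,h), \qquad
f(g,h)=\begin{cases}
\varepsilon & g \text{ focal, } h \text{ deleted}\\
\tau_\downarrow^{\,\delta}\ \text{or}\ \tau_\uparrow^{\,\delta} & g \text{ signature gene}\\
1 & \text{otherwise,}
\end{cases}$$

where $d$ scales the wild-type library to `n_reads_per_clone`,
$\varepsilon$ is the cis residual (default 0.07: a deleted allele keeps ~7%
of the intact allele's output, the effect size this class of super-enhancer
knockout exhibits), and the trans factors
$\tau_\downarrow = 0.15$, $\tau_\uparrow = 6$ apply to both alleles of
signature genes with dosage $\delta$ = 1 in biallelic clones and
$\delta = 1/2$ (the geometric mean of full effect and none) in monoallelic
clones — a functional form chosen to encode "changed, but to a lesser
extent than in the full knockout" without further assumptions.

Counts are gamma-Poisson. The gamma factor (variance `nb_dispersion`,
default 0.005) is drawn per gene and clone and **shared by the two
alleles**, on top of a global lognormal clone factor (`clone_factor_sd` =
0.1) that cancels under library normalisation. Marginally each count is
negative binomial, but the allelic ratio within a clone remains
Poisson-limited — which is precisely the robustness that makes
allele-specific designs powerful, and the reason the knockout:intact ratio
can be estimated tightly from single clones. The residual dispersion value
is what one observes for well-expressed genes between isogenic clonal
cultures; substantially larger values would make single-clone fold-change
calling (no replicates, as in the screen) unreliable.

Gene panel defaults (one focal gene, 46 neutral, 10 down-signature, 10
up-signature, one control gene) put the focal gene at ~2% of the library
and the signature genes at shares small enough that library-composition
shifts stay within a few percent; the up-signature genes are lowly
expressed in the wild type (differentiation genes in an ESC), the
down-signature genes moderately expressed (pluripotency genes).

Reads are `read_length` (default 100 bp, as sequenced in the study design)
substrings of the correct haplotype's transcript, reported on the
transcript strand per the dUTP protocol; antisense reads are not generated.
No sequencing-error model is applied by default (`seq_error` adds uniform
substitutions when wanted).

## qPCR, junction amplicons, contacts

`simulate_qpcr()` emits triplicate wells with
$Ct = Ct_0 - \log_2(\text{copies}) + N(0, \sigma)$; $\sigma$ defaults to
0.15 cycles, a typical well-to-well SYBR spread. Zero template (biallelic
deletion) is a no-amplification sentinel (`NA`), not an arbitrary high Ct.
`simulate_junctions()` assembles the deletion-spanning PCR product from
200 + 220 bp of flank around the cut sites — ~420 bp for a clean fusion —
while intact alleles yield no product (the un-deleted span is beyond the
screen PCR's reach). `simulate_hic()` digests the focal chromosome at
HindIII sites and draws anchor-fragment counts as Poisson with mean
$\propto d^{-1}$ (decay exponent configurable), multiplied by
`loop_enrichment` (default 5) at fragments overlapping the enhancer.
Fragment visibility is uniform: neither fragment length nor GC content
modulates the mean, and the expected model makes the same assumption (see
below).

# Analysis methods

## Variant QC

Three variant-level filters blacklist unreliable variants before any
allele counting; all three operate at the variant level only (no per-read
realignment filtering).

* **Mapping bias.** For each variant, every read-length window overlapping
  the variant is enumerated from both haplotypes ("dummy reads") and mapped
  against the combined diploid index. The default mapper is exact-match
  lookup (deterministic, dependency-free); any aligner honouring the
  placement-count contract can be plugged in. A read counts as mapped iff
  its placement is unique — a unique placement is necessarily the true
  locus, since the read was lifted from the genome. Bias is defined as
  $|m_A - m_B| / \max(m_A, m_B)$ (1 when nothing maps uniquely), a
  symmetric score in $[0,1]$ matching the percent phrasing of the
  blacklisting rule: SNPs strictly above 5% and indels strictly above 10%
  are dropped.
* **Copy-number balance.** Genomic-DNA allele counts are tested against a
  50/50 binomial (two-sided exact test), Benjamini–Hochberg corrected, 5%
  FDR.
* **Heterozygosity.** A poor heterozygous call is detected by a one-sided
  exact binomial test that the minor-allele fraction is at least `min_minor_frac` (default 0.15, configurable), BH
  corrected at 5% FDR. Zero-depth variants are unverifiable and flagged.

## Allele assignment and the specificity statistic

A read votes at every usable SNP it overlaps (base equal to REF → CAST,
equal to ALT → 129, anything else ignored as a sequencing error); reads
overlapping usable indels are compared as whole windows against both
haplotype sequences. The final call is a majority vote, with ties and
uninformative reads unassigned; majority-with-tie-break-to-unassigned is
the conservative choice among reasonable voting rules. Counting
is per gene over the annotated interval, strand-aware; gene bodies stand in
for exonic unions in the synthetic genome (the genes are unspliced).

Per-gene allele specificity is $\log_2((c_{CAST}+10)/(c_{129}+10))$, the
pseudo-count-10 statistic used for the chromosome-wide cis scan; the
pseudo-count is never applied to stored counts. The knockout:intact ratio
averages, over monoallelic clones, the deleted-allele count divided by the
intact-allele count of the focal gene.

## Expression signatures

FPKM is $c \cdot 10^9 / (L \cdot N)$. Signature calls add a pseudo-count of
4 to FPKM and apply a 3-fold cutoff; the boundary (ratio exactly 3) counts
as a call, a recorded package decision. Comparisons are
single clone vs single clone, mirroring the screen (no replicates, no
dispersion modelling); which wild-type clone anchors the comparison is a
parameter. The binomial promoter-binding test compares the bound fraction
of the down list against the pooled bound fraction of both lists — the
natural two-list null for an exact binomial comparison. Signature overlaps are tested per directional quadrant with
an upper binomial tail against the chance expectation $|A||B|/U$.

## Genotyping

The deletion-spanning PCR screen calls a clone product-positive when any
junction amplicon is at most 3 kb. Copy number follows the ddCt method,
normalised to the control assay and to the wild-type reference clone
(which therefore reads exactly 2 by construction); triplicates are
aggregated by mean (configurable). All-missing target wells encode copy
number 0. Class boundaries 0.5 and 1.5 are the midpoints between the ideal
copy numbers {0, 1, 2}, the maximum-margin bands for a noiseless assay.
Junction-SNP calls anchor at the amplicon 3' end, so
the diagnostic offsets are invariant to the NHEJ scar at the fusion point;
the allele is a majority vote over diagnostic positions with ties
ambiguous. The deletion frequency is
$(\#\text{mono} + 2\#\text{bi}) / (2\#\text{clones})$, evaluated in integer
arithmetic. The inversion clone is monoallelic-equivalent throughout, as it
is tallied in the screen.

## Loop calling

The anchor is the restriction fragment containing the focal TSS. The
expected profile is fitted by binning fragments into `n_bins` (default 20)
equal-occupancy log-distance bins, taking each fragment's leave-one-out bin
mean (so a genuine loop spike cannot inflate its own expectation),
enforcing monotone decay with a weighted pool-adjacent-violators fit, and
interpolating log-linearly between bin centres. The interpolation step is a
refinement over a stepwise bin mean: with a steep decay, a step function
misfits high-count near-anchor fragments by more than their Poisson noise
and destroys calibration, while the interpolated fit keeps the empirical
false-positive rate below the nominal FDR (verified over seeds in the test
suite). Significance is an upper Poisson tail per fragment with BH
correction — Poisson, not negative binomial, because fragment-level counts
in the generative model are Poisson, making the calibration check exact by
construction. Production Hi-C expected models additionally regress on fragment length
and GC content; only distance decay is modelled here, a stated limitation.

# Numerical and design choices

* Coordinates are 1-based closed internally (the R/Bioconductor
  convention), 1-based in VCF, 0-based half-open in BED exports.
* All randomness derives from one root seed via fixed per-stage offsets, so
  any subset of stages reproduces exactly; per-clone streams make a clone's
  reads independent of which other clones are simulated.
* Degenerate inputs error loudly: zero library sizes, missing control
  wells, an anchor absent from the fragment table, an all-zero contact
  profile, colliding variant densities, genes shorter than the read length.
* Boundary conventions are explicit: strict bias thresholds, inclusive
  3-fold cutoff, copy-number bands closed on the left.

# Problem sizes used by the checks

The acceptance script regenerates everything at the default scale: the
16-clone screen for genotyping; sixteen monoallelic clones at 200,000 reads
each for the knockout:intact ratio (through the full variant-QC and
read-assignment path); a 104-clone counts-only panel (48 WT, 48
monoallelic, 8 biallelic) for the FPKM reduction estimates, sized so the
Monte-Carlo error of the mean reduction is well under the reporting
precision. The test suite mostly runs a 60 kb + 60 kb genome with ~20,000
reads per clone, which keeps the whole suite in a few minutes while leaving
every statistical check comfortably powered.

# What passing tests do and do not show

The generator emulates the statistical structure the analysis assumes:
phased haplotypes differing only at known variants, error-free reads from
unspliced transcripts, Poisson contacts with pure distance decay, and
well-behaved qPCR noise. Passing tests therefore demonstrate that the
implementations are correct against that model — parameter recovery,
conservation, calibration. They do not demonstrate robustness to the
complications of real data: alignment artefacts beyond exact-match
multimapping, splicing, allele-specific mappability of indels, PCR
duplicates, chromatin-visibility covariates in Hi-C, or qPCR efficiency
drift. Those belong to the upstream tools this package deliberately does
not replace.

# Worked example

```{r example}
cfg <- sim_config(seed = 1, chrom_length = 60000, control_chrom_length = 60000,
                  enhancer_offset = 4000, n_reads_per_clone = 20000,
                  n_neutral_genes = 10, n_down_genes = 3, n_up_genes = 3,
                  hic_total_reads = 5000)
ex <- run_experiment(cfg, quiet = TRUE)
ex
glance(ex)
tidy(ex) |> head()
```

```{r plots, fig.width = 7, fig.height = 4}
autoplot(ex$loops)
autoplot(ex$genotypes)
```
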