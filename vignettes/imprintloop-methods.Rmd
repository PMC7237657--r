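---
title: "Models and methods behind imprintloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind imprintloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintloop)
```

imprintloop analyses the 3D chromatin organisation of imprinted loci — the
motivating system is human 11p15.5, with its two imprinting control regions
(ICR1 governing *IGF2*/*H19*, ICR2 governing *CDKN1C*/*KCNQ1OT1*) — from
three complementary assays: chromosome conformation capture (3C), SNP-based
allele phasing of ligation products, and two-colour 3D DNA FISH. This
vignette explains the models, the tunable parameters and their defaults, the
numerical decisions, and what the synthetic-data generator does and does not
emulate.

## 1. The 3C quantification model

3C converts spatial proximity into ligation products. The pipeline starts
downstream of the wet lab: an in-silico digestion of the region sequence
(BglII, motif `AGATCT`, cutting one base into the motif on the top strand;
BamHI available for re-digestion maps) produces the restriction-fragment
axis, and primers are assigned to the unique fragment that contains them. A
primer straddling a cut site cannot interrogate a unique ligation junction
and is rejected. Coordinates are 0-based half-open (BED convention)
throughout; both enzyme motifs are palindromic, so scanning the top strand
finds every site.

The association frequency between an anchor fragment and a test fragment is

$$ f = \frac{I_{3C}}{I_{ctrl}} $$

the ratio of the PCR band intensity from the 3C library to the intensity of
the same primer pair on a control template — an equimolar digestion-ligation
of clones tiling the region, which carries every possible junction in equal
amounts. The ratio cancels primer-pair efficiency, which is why frequencies
are comparable along the axis. Consequences the package enforces and tests:
frequencies are invariant to any common rescaling of a replicate's
intensities (gel exposure is arbitrary), an undetectable control band makes
the ratio meaningless (the record is flagged and excluded, never imputed),
and fragments without measurements stay explicit gaps because 3C primer
coverage of a region is deliberately partial. Replicates (two independent
assays per line) are summarised as mean ± sample SD (n − 1 denominator,
consistent with reporting mean ± SD of two replicates). A "controls mean"
pools the individual assays of the control lines — four assays from two
lines — rather than averaging line means, so its SD reflects assay-level
dispersion. Frequencies are reported raw; an optional per-profile
max-normalisation exists for cross-panel display and is off by default.

## 2. Differential interactome calling

Control and patient lines are compared per anchor with a fixed-effects
two-way ANOVA (group × fragment, interaction included) on individual assay
values, followed by per-fragment group contrasts using the pooled residual
error — the classical "two-way ANOVA with Bonferroni post-tests" procedure.
The Bonferroni family is the number of fragments on the anchor's axis, i.e.
one pairwise control-versus-line panel. The ANOVA itself is delegated to
`stats::aov()`; the test suite checks the resulting F statistics against an
explicit sums-of-squares computation, and the contrasts against the closed
form

$$ t_j = \frac{\bar y_{case,j} - \bar y_{ctrl,j}}
             {\sqrt{MSE\,(1/n_{ctrl,j} + 1/n_{case,j})}},\qquad
   p_j^{adj} = \min(1,\; k\, p_j). $$

Each fragment is then categorised. With adjusted p > 0.05 the contact is
*unchanged*. Otherwise the call depends on a presence floor
ε = 5% of the anchor profile's maximum mean (configurable via
`stat_config()`): a contact absent in controls but present in the patient
line is *novel*, the mirror case is *lost*, and otherwise the sign of the
difference gives *increased* / *decreased*. The floor mimics band
detectability on a gel — the original calls of "novel" and "lost" are
qualitative observations of bands appearing or disappearing, and a relative
floor is the closest quantitative analogue. A mean exactly at the floor
counts as present, so boundary contacts degrade gracefully to
increased/decreased rather than flipping to novel/lost. Two properties pin
the semantics: lowering ε can only move calls from novel/lost toward
increased/decreased, and swapping the groups mirrors the categories while
leaving every p-value unchanged.

Degenerate designs with zero residual variance everywhere cannot support a
t-statistic; the package flags them (`zero_variance`) and reports p = 1
where the group means coincide and p = 0 where they differ, rather than
NaN. With only two assays per group this occurs in practice only on
constructed data.

The error unit for the control group is the individual assay (four assays
from two lines), not the line; treating lines as units would leave one
degree of freedom per group and no usable pooled error at this design size.
Assays are exchangeable under the null of identical line behaviour, which
the controls' profiles support.

## 3. Allele phasing and methylation status

A 3C ligation product sequenced at heterozygous SNPs reveals whether a
contact involves one or both parental alleles. The qualitative (Sanger)
caller reports *monoallelic* with the haplotype string (alleles concatenated
in genomic coordinate order) when every SNP shows a single allele, and
*biallelic* when any SNP shows both; "shows both" means the minor peak
reaches 20% of the major one, mirroring the quantitative threshold below.
Homozygous samples are *uninformative*. The quantitative (mass-array style)
caller computes the allele-A fraction and calls monoallelic when the major
fraction reaches θ = 0.8 (configurable). No published numeric boundary
separates "predominantly monoallelic" from biallelic in such data; 80/20 is
a standard heuristic, and the threshold is exposed rather than hidden.
Parental origin is never computed — it can only be inferred indirectly — so
maternal/paternal labels are accepted as optional annotations only.

ICR methylation levels (pyrosequencing percentages) are classified against
inclusive normal ranges, ICR1 40–52% and ICR2 39–50%: below is
hypomethylated, above hypermethylated. The pair of statuses maps to the
molecular subtype labels used for 11p15.5 imprinting disorders
(gain at ICR1 → BWS-ICR1-like; isolated ICR2 loss → BWS-ICR2-like; ICR1
gain with ICR2 loss → the paternal-UPD signature; isolated ICR1 loss →
SRS-ICR1-like). The partition of [0, 100] is total and deterministic, which
the suite checks by sweeping the whole range.

## 4. 3D FISH colocalization

Each allele appears as a green–red probe doublet. Nuclei enter the analysis
only with exactly two spots per channel (one doublet per allele); anything
else is excluded with a logged reason rather than salvaged, because partial
spot sets cannot be phased into alleles reliably. With two spots per
channel there are exactly two perfect green–red matchings; the pipeline
takes the one minimising the summed green–red distance, with ties broken by
pairing lowest-index green with lowest-index red. The choice is invariant
under rigid motion of the nucleus, and the test suite compares it against
exhaustive enumeration.

An allele is *cis-colocalized* when its intra-doublet 3D centroid distance
is ≤ 0.35 µm, and a nucleus is *trans-associated* when the distance between
the two doublets is ≤ 1 µm; both cutoffs are boundary-inclusive. The
reference point of a doublet for the trans distance is not uniquely defined
by the assay description; the package uses the doublet midpoint by default
and exposes `green_spot` / `red_spot` alternatives in `fish_config()`.
Coordinates must arrive in micrometres — no pixel or voxel scaling happens
inside the pipeline, because the acquisition geometry is unknown to it.

Nuclei are classified +/+, +/− or −/− by how many alleles colocalize, and a
cohort summary reports category counts, percentages, the allele
colocalization rate (2N₊₊ + N₊₋)/(2n), and the trans rate. Two pooling
conventions coexist and both are implemented explicitly: summing integer
counts before recomputing percentages (used for category percentages of a
pooled control cohort) and unweighted averaging of per-line rates (used for
a mean-of-controls allele rate); the output records which was used. Group
comparisons use Fisher's exact test on the 2×2 in-category × group tables
(with p = 1 and a warning on zero-margin tables) and an unpaired two-sided
t-test on allele-level cis distances when distances are available. The
package ships `fish_reference_counts()`, the per-line integer category
counts of the three lymphoblastoid cohorts it was calibrated against
(302, 290 and 308 nuclei); these counts are uniquely determined by the
published per-line percentages and cohort sizes, and the acceptance script
recomputes all pooled statistics from them at run time.

## 5. The synthetic-data generator

The generator exists so that every stage runs and is testable without
microscopes or gels. For FISH, each nucleus draws one allele midpoint
uniformly in a 3 µm-radius sphere (a plausible lymphoblastoid nucleus
scale); the second midpoint sits within the 1 µm trans cutoff with
probability `p_trans`, otherwise it is redrawn until the separation exceeds
the cutoff. Each allele is colocalized with probability `p_cis`: its
intra-doublet separation is |N(0, 0.1 µm)| capped at the 0.35 µm cutoff,
while non-colocalized alleles draw separations uniformly from 0.5–2 µm.
Because colocalized separations never exceed the cutoff and non-colocalized
ones never fall below it, `p_cis` equals the expected measured
colocalization rate exactly — the parameter is identifiable, and recovery
tests have an exact target. 3C bands multiply a truth profile by a
log-normal control intensity and mean-one log-normal noise with configurable
CV, so zero CV recovers the truth identically. SNP signals mix a true major
fraction of 0.95 (monoallelic) or 0.5 (biallelic) with 10% multiplicative
noise.

A single root seed feeds per-nucleus / per-fragment substreams derived by
counter, so subsets are reproducible independently of iteration order, and
identical seeds give byte-identical tables. Two presets encode the cohorts
the package targets: `CTRL-like` (p_cis 0.44, p_trans 0.05, 300 nuclei) and
`BWS-ICR2-like` (p_cis 0.29, p_trans 0.03, 300 nuclei), calibrated to the
observed allele colocalization rates of 44.06% and 28.73%.

What the generator does **not** emulate: optical artefacts (chromatic
shift, axial anisotropy, spot-detection failures beyond wholesale nucleus
exclusion), chromatin polymer physics, inter-fragment correlation of 3C
noise, or PCR saturation. Passing tests therefore demonstrate that the
*analysis* is correct and well-calibrated under the stated statistical
structure, not that real microscopes or gels behave this way.

## 6. Problem sizes and numerical choices

The test suite verifies digestion against a naive character-scan oracle on
1,000 random kilobase sequences, doublet pairing against brute-force
enumeration on 1,000 random nuclei, ANOVA F statistics against explicit
sums of squares on randomized small balanced designs, p_cis recovery over
50 seeds at 300 nuclei, and preset separability (Fisher p < 0.01) over 100
seed pairs; these sizes give stable statistics while keeping the whole
suite under a minute on one core. Distances and coordinates are plain
doubles; ECDF grids are rounded to 10 decimals to make grid points exact;
overlapping restriction-motif occurrences are resolved left-to-right
(self-overlap is impossible for the shipped palindromic motifs, so this is
a determinism guarantee, not a biological claim).

## 7. Orchestration

`run_pipeline()` executes the stages in dependency order (digest → quant →
diff; fish; phase; methqc) from one YAML/list configuration, writes TSV
outputs plus a manifest with md5 checksums, and logs version, seed and a
config hash; re-running an unchanged configuration is bit-reproducible.
`write_report()` renders whatever stage outputs exist into one markdown
report with percentages at two decimals. The package's interface is its
functions; the orchestration layer is itself an exported, tested function
rather than a separate shell tool.

## 8. Known limitations

* The 3C stage consumes band intensities; densitometry, primer design and
  PCR-efficiency correction are out of scope.
* Whether control-template intensities are shared per primer pair or vary
  per replicate is left to the input table; both layouts are accepted.
* The distance-level t-test and the category-level Fisher tests answer
  related but different questions; the package reports both and does not
  attempt a t-test on percentages.
* Novel/lost calls depend on the presence floor ε; profiles whose maxima
  are themselves noisy make ε noisy. The floor is configurable and the
  monotone behaviour under ε changes is tested.
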