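---
title: "mtclade: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mtclade: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtclade)
```

This vignette is the package's own account of the statistical methods
it implements, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where the design was open.

## The setting

A clonally transmissible cancer spreads between animals as a living
cell lineage. Its mitochondrial genomes, unlike its nuclear genome, are
periodically replaced by capture from transient hosts; tumours
descending from one capture event form a *clade* sharing the donor's
germline haplotype, on top of which each tumour accumulates private
somatic mutations. Sequencing a tumour biopsy yields a mixture of
tumour and host mtDNA, so every variant allele fraction (VAF) is
diluted by host contamination. The analysis chain is: filter raw
variant calls; separate germline from somatic variation and estimate
the tumour mtDNA fraction; characterise the somatic mutational
spectrum; test for negative selection; date the capture events; and
name the haplotypes.

## Reference model

Coordinates are 1-based inclusive throughout. The reference strand is
the *light* strand; heavy-strand context is its reverse complement.
The genome is circular: trinucleotide contexts at positions 1 and L
wrap around the origin. Consequence annotation uses the vertebrate
mitochondrial genetic code (NCBI table 2: TGA = Trp, AGA/AGG = stop,
configurable via the `genetic_code` argument). Whether the original
study's triplet census wrapped the origin is not stated anywhere we
could verify; wrapping is the defensible choice for a circular molecule
and is documented here as this package's convention, not asserted as
the study's.

Excluded positions come in two kinds with deliberately different
scope: *regions* (by default the simple-repeat interval
MT:16129–16430) exclude positions outright, while *excluded sites* are
(position, base-change)-specific for variant filtering but
position-only for triplet counting, since a census has no notion of a
base change.

## Filters

Substitution rules, applied in a fixed order so discard reasons are
stable (the source material lists the filters without an order):

1. at least one third of mutant reads with base quality > 25 — ties at
   exactly one third are kept (`count >= n/3`, a rational comparison);
2. mean mapping quality ≥ 21;
3. calls supported only by the first/last 15 bp of reads are dropped;
4. calls within 10 bp (+REP when REP > 0) of an indel *that itself
   survived indel filtering* in the same sample are dropped
   ("unfiltered indel" is read as "a surviving call");
5. repeat-region exclusion;
6. if the reference allele has a read on both strands, the mutant
   allele must too;
7. configured excluded site changes;
8. the rescue list re-admits a call only when its sole discard reason
   was rule 4.

Region/site exclusions are terminal in the order so that a rescued
variant can never sneak past them. Indels require ≥3 supporting reads
on one strand or ≥2 on both; calls with ≥4 pindel-mapped reads
additionally need a BWA-mapped read or, failing that (only when
REP = 0), pindel reads on both strands. Samples above 300X mtDNA
coverage are excluded from indel calling wholesale.

## Somatic classification and VAF normalisation

With a matched host: shared variants with tumour VAF < 0.9 are host
contamination (discarded); shared with VAF ≥ 0.9 are germline;
tumour-only variants are somatic. Low-coverage hosts (< 20X) cannot
rule out sharing, so any host read supporting the variant discards it
and all tumour VAFs < 0.5 are discarded. Without a matched host, a
per-tumour VAF cutoff (default 0.5, typically raised to 0.6 for more
contaminated tumours) separates tumour from host variants; above ~40%
contamination no cutoff works, and membership in phylogenetically
related tumours and a normal-dog germline panel arbitrate instead.
"Phylogenetically related" is operationalised as sharing the deepest
assignable haplogroup prefix, since this package takes clades as
inputs rather than inferring trees.

The tumour mtDNA fraction is `f = mean(VAF)` over tumour-unique
substitutions (indels excluded, matching the source procedure), and
normalised VAF is `min(raw/f, 1)`. The cap at 1 is this package's
choice — the quantity is a fraction and sampling noise should not push
it above one; the source plots normalised VAF without stating a cap.
Normalised VAF < 1 flags heteroplasmy candidates.

Variant classes per clade: *clade-defining germline* (shared by every
tumour of the clade and present in the dog panel — the donor
haplotype), *potential somatic* (shared by all but absent from the
panel; early-somatic or rare-germline status undecidable),
*somatic* (variable within the clade), and the *conservative somatic*
subset that removes anything with a germline escape route:
recombination-implicated variants, clades with too few somatic
mutations to exclude multiple captures, ancestral-trunk-defining
variants, and hostless putative somatic calls. Class disjointness and
the conservative ⊆ somatic relation are asserted on every build.

## Mutation spectrum

Pyrimidine changes on the reference (light) strand keep their
reference flanks; purine changes are complemented into pyrimidine
context, with flanks read on the heavy strand. Expected counts use
`expected = N * count_s(t) / (3 L)` with L the **full genome length**,
even though excluded positions are removed from the census — this
follows the published worked example (117/16727) exactly, and the
resulting small deflation of `sum(expected)` relative to N when
exclusions are active is documented rather than silently repaired:
with no exclusions `sum(expected) = N` holds exactly.

Rounding happens only at the presentation layer. In presentation mode
the triplet frequency is rounded to 3 decimals before use and the
expected count to 2 before the ratio, reproducing printed values
(0.007, 1.95, 22/1.95 = 11.28); strict mode keeps full precision and
reports 11.30 for the same inputs. Classes observed with zero
expectation are flagged infinite, never dropped.

## Selection inference

**VAF tests.** Two-sample, two-sided Kolmogorov–Smirnov tests compare
normalised VAFs of nonsense vs missense+synonymous substitutions (from
the conservative somatic list) and frameshift vs in-frame somatic
indels. The p-value is exact for `n_a * n_b <= 1e4` without ties,
asymptotic otherwise. An empty group yields a reported skip, not an
error.

**dN/dS.** Observed counts are modelled as
`n[j,i] ~ Poisson(r_j * L[j,i] * w_i)` over j = 192
substitution-in-context types (12 substitutions × 4 five-prime × 4
three-prime bases) and impact i, with `w_syn ≡ 1`. Contexts are
defined on the coding (heavy) strand, and the light-strand-transcribed
gene is excluded entirely, so the heavily strand-biased mutation
spectrum cannot masquerade as selection. Opportunities `L` enumerate
all three substitutions at every included coding site. Estimation is
plain maximum likelihood — the source says only "adapted from" its
citation, so no regularisation or rate pooling is applied; the
log-likelihood separates so that coordinate ascent with closed-form
conditional updates (`r_j` given `w`, `w_i` given `r`) converges
quickly, and with a single context the estimates collapse to the
closed-form rate ratio exactly (a test asserts this). Neutrality
(`w = 1`) is tested per coefficient with a 1-df LRT; 95% CIs come from
the profile likelihood (drop of qchisq(0.95, 1)/2), matching the
error-bar convention of the original figure. Contexts with zero total
opportunity are dropped as uninformative.

## Clade timing

Time since capture is `burden / rate`, linear in burden, so clade age
*ordering* never depends on the calibration. Three rates are
implemented: (i) the youngest clade's burden divided by its
nuclear-DNA age bound (9.437/460 = 0.0205/yr in the source data);
(ii) one homoplasmic mutation per ~1000 cell generations at 4–20-day
generation times (0.0913 and 0.0183/yr; the year is taken as 365.25
days — unstated in the source, and the printed 4-decimal values are
reproduced under either 365 or 365.25); (iii) a human-tumour rate of
0.025/yr. Burdens are reported with and without potential-somatic
variants, since their pre- or post-capture status is undecidable. A
per-clade burden override hook exists because one haplogroup's burden
was adjusted for recombination in the source analysis by an unstated
amount.

## Copy number and qPCR

Copies per cell = `(mtCOV / nuclCOV) × ploidy` (ploidy 2), with
samples above 300X flagged and excluded from averages. Tumour copy
numbers are *not* purity-corrected by default, matching the source
presentation; a correction hook exists. The qPCR module inverts
`Ct = m log10(iA) + b` and normalises to a reference target.

## Haplotype nomenclature

Tumour names are `CTVT_` + clade digit + up to five hierarchical
levels alternating numbers and letters (first letter upper-case,
second lower-case, e.g. `1A1a1`); serial suffixes (`_1`, `_2`, …)
are legal only once all five levels are occupied — `1A_1` is
rejected by the constructor. Host names are haplogroup + `_serial`,
or `unassigned`. Serial numbers are assigned by first appearance
after a canonical sort by sample id, making names independent of
input order (the source does not state its assignment order).
Haplogroup definitions ship as an editable illustrative set; the
published diagnostic tables for dog haplogroups are an external
resource and are not bundled, so name-for-name reproduction of the
study's assignments is out of reach by design. The donor haplotype of
a clade is the union of its clade-defining germline and
potential-somatic variants.

## Synthetic data: what it emulates, what it does not

The generator states a world matching the analysis assumptions:

* five clades (defaults) founded from distinct donor haplotypes, with
  the published clade age point estimates (1097, 460, 244, 1690, 585
  years) and the published somatic rate μ = 0.0205/yr — so expected
  burdens match the published per-clade averages;
* somatic substitutions drawn class-first from a 192-category
  strand-biased spectrum (C>T heavy and T>C light dominate 30:1 over
  the base categories, their mirror classes at 5:1), then placed
  uniformly among matching triplet sites, so the realised class
  distribution converges to the configured weights;
* selection as consequence-specific thinning with the published
  coefficients (w_MIS = 0.748, w_NON = 0.187; frameshift indels thinned
  at 0.187) — the generative counterpart of the Poisson dN/dS model.
  μ is the *realised* (post-selection) rate: selection shapes
  composition, not the total count;
* heteroplasmy: with probability 0.15 a somatic variant is
  heteroplasmic with cell fraction ~ Beta(8, 2) (mean 0.8). The source
  gives no generative model for heteroplasmy; this is an artifact
  choice, made once, that produces both the reduced-VAF and
  reduced-count selection signals at desk scale;
* host contamination per tumour ~ Uniform(0, 0.3), diluting tumour
  VAFs by f = 1 − contamination and injecting host-haplotype alleles
  at VAF ≈ contamination;
* read support: depth ~ Poisson(70), mutant reads binomial, strand
  split binomial(0.5); a variant with zero sampled mutant reads is
  simply not called;
* somatic indels at 1e-4/yr — the rate implied by the published
  counts (27 indels across 449 tumours against ~1005 substitutions),
  not an independent constant;
* cohort sizes are desk-scaled (25 tumours vs 449 in the study);
  tests and the acceptance suite size their cohorts explicitly.

Not emulated: read-level artefacts (the quality fields are drawn
benign, so filter rules are exercised by constructed fixtures, not by
the cohort generator), NuMT contamination, recombination,
back-mutation, within-clade phylogenetic structure (each tumour's
somatic mutations are private draws — a star phylogeny), and
tumour-in-host contamination (off by default). A green cohort test
therefore establishes the statistical pipeline logic, not robustness
to alignment artefacts.

Determinism: one master seed; each stage reseeds from a named
substream, so identical configs give byte-identical outputs.

## Numerical choices and degenerate inputs

* dN/dS boundary cases: zero observed counts in an impact class give
  `w = 0`; an all-zero count matrix is an error; LRT statistics are
  clamped at ≥ 0 against round-off.
* Coordinate-ascent convergence: max parameter change < 1e-12, cap
  5000 iterations.
* Profile CI roots are bracketed by doubling and solved with uniroot
  (tol 1e-8); an unbounded upper limit is reported as `Inf`.
* VAF consistency: a stored VAF disagreeing with mutant/total beyond
  1e-6 is an error, never silently recomputed.
* `estimate_tumour_fraction` with no tumour-unique variant returns an
  explicit undefined flag; the pipeline then skips normalisation
  (f = 1) for that tumour.
* Empty KS groups, empty clades and header-only variant tables all
  have defined, tested behaviour.

## Known limitations

* Clade membership is an input (from config or simulation truth);
  tree inference, recombination detection and NuMT simulation are out
  of scope.
* The dN/dS printed point estimates of the original cohort are only
  reproducible with that cohort's variant list and reference genome,
  which are not desk-scale resources; the package's claim is
  parameter *recovery* on simulated data, verified in the acceptance
  suite.
* The 96-class spectrum is computed and exported; signature
  decomposition against catalogued signatures is not attempted.
* Host haplogroup assignment reproduces the naming *rules*; real-data
  assignments depend on external diagnostic tables.
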