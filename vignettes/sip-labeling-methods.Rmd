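---
title: "Detecting isotope-labeled taxa from SIP gradient fractions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting isotope-labeled taxa from SIP gradient fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipcall)
```

## The problem

DNA stable-isotope probing (DNA-SIP) asks which members of a microbial
community assimilated a substrate. A community is incubated with a
¹³C-labeled substrate (and, in parallel control bottles, the same
substrate with ¹²C); organisms that incorporate the label build
denser DNA. Isopycnic CsCl ultracentrifugation then spreads each genome
along a buoyant-density gradient, 11–12 fractions are collected, and the
fractions are classed *light* (density < 1.715 g/mL) or *heavy*
(≥ 1.72 g/mL). Amplicon sequencing of pooled light and heavy DNA yields a
taxon-by-sample count table; a taxon that shifted toward the heavy
fractions of the labeled bottle — but not of the control — was labeled.

`sipcall` implements the complete inference path from count tables to
labeling calls, together with the descriptive companions such studies use
(relative-abundance profiles, correlation-distance Ward dendrograms with
bootstrap support) and a synthetic gradient generator with known ground
truth, so that the whole pipeline is testable without any sequencing data.

## The labeling statistic

For one taxon in one bottle, with $H_{arc}$ its reads in the heavy
pool, $H_{narc}$ the remaining heavy reads, and $L_{arc}$,
$L_{narc}$ the same for the light pool, the enrichment statistic is
the odds ratio

$$\mathrm{OR} = \frac{H_{arc}/H_{narc}}{L_{arc}/L_{narc}},$$

and the labeling criterion is the ratio of odds ratios between a
¹³C bottle and its paired ¹²C control,

$$\mathrm{RoOR} = \mathrm{OR}_{13C} / \mathrm{OR}_{12C} > 1,$$

evaluated separately for each ¹³C replicate. Dividing by the
control's OR removes heavy-pool enrichment that a taxon shows for reasons
other than label uptake — GC-rich genomes band densely in any gradient —
which is the entire point of running ¹²C controls.

Assumptions worth stating explicitly:

* The contrast is *compositional*: OR compares a taxon against the rest of
  the community within each pool, so a strongly labeled taxon depresses
  the apparent enrichment of everything else in that bottle. This coupling
  is what keeps the false-positive rate low in practice (unlabeled taxa
  are pushed to RoOR < 1 when a labeled taxon soaks up the heavy pool),
  but it also means calls are not independent across taxa.
* `RoOR > 1` is a strict inequality with no significance machinery and no
  multiple-testing adjustment. On unlabeled data it is a coin flip: the
  package's permutation utility `roor_permutation_rate()` measures the
  chance rate at ≈ 0.5, and the acceptance suite verifies this. The
  strength of a call comes from replication (`labeled_all`) and effect
  size, not from the bare inequality.
* Both consensus columns are reported: `labeled_any` (RoOR > 1 in at least
  one replicate, the reading under which single-duplicate signals are
  "suggestive") and `labeled_all` (every replicate with a defined RoOR).
  Neither is privileged; the tests and the acceptance report use
  `labeled_all`, the stricter one.

## The read-count eligibility filter: two readings, and why the default is the bottle-level one

The filter "≥ 5 reads in both the heavy and light fractions" admits two
readings:

1. **taxon-level** — the taxon itself needs ≥ 5 reads in each pool. This
   guarantees all four OR cells are positive, so no division by zero can
   occur.
2. **bottle-level** (`fraction_total`) — each pool of the bottle needs ≥ 5
   total reads; the filter screens out failed libraries, not taxa.

Reading 1 looks safer but has a degenerate consequence that reading 2 does
not: a *fully labeled* taxon moves essentially all of its DNA out of the
light zone (a full ¹³C shift of ~0.036 g/mL is about 7 band standard
deviations), so its light-pool count in the labeled bottle is 0, it fails
the taxon-level filter, and the strongest possible labeling signal is
discarded as "ineligible". We verified this quantitatively on the
synthetic world: under reading 1 the recovery sensitivity for fully
labeled taxa is exactly 0 at any sequencing depth.

`sipcall` therefore defaults to the bottle-level reading, paired with the
standard Haldane–Anscombe continuity correction: when (and only when) a
2×2 table contains a zero cell, 0.5 is added to all four cells. Tables
without zeros — every "ordinary" taxon — keep their exact odds-ratio
values. The taxon-level reading remains available
(`labeling_analysis(..., scope = "taxon")`), and under it low-count
replicates are reported as ineligible (`RoOR = NA`), never silently as
"not labeled numbers".

## Density cut-offs and pooling policy

* `light_max = 1.715`, `heavy_min = 1.72` g/mL; 1.72 itself is heavy
  (boundary inclusive), densities in `[1.715, 1.72)` are *intermediate*.
* Intermediate fractions are **excluded** by default. The original studies
  picked representative fractions using DGGE screening whose per-sample
  choices are unrecoverable; excluding the ambiguous zone is the
  deterministic, data-independent stand-in. `intermediate = "light"` or
  `"heavy"` overrides this.
* All fractions of a class are pooled (again: deterministic, rather than
  an unrecoverable per-sample choice). Pooling conserves counts exactly;
  the invariant `light + heavy + excluded = total` is tested as an integer
  identity.

## The synthetic gradient generator

Each taxon's DNA is modeled as a Gaussian band along the density axis —
the standard isopycnic-band approximation — with:

| parameter | default | why |
|---|---|---|
| unlabeled band center | drawn U(1.69, 1.71) g/mL | typical bacterial/archaeal buoyant densities; keeps unlabeled DNA in the light zone |
| band sd (`density_sd`) | 0.005 g/mL | a narrow post-fractionation band; full labeling then separates the band almost completely |
| full-label shift (`label_shift`) | 0.036 g/mL | literature-typical CsCl shift of fully ¹³C-labeled DNA |
| `atom_excess` | free per taxon, in [0, 1] | achieved labeling is never reported for environmental incubations; partial labeling scales the shift linearly |
| gradient | 12 fractions, edges 1.68–1.76 g/mL | matches the 11–12 fractions collected from real gradients; each fraction's reported density is its bin midpoint |
| `depth` | 10 000 reads per fraction | a realistic per-library amplicon depth; every fraction is sequenced to the same depth, as amplicon libraries are |
| replicates | 2 ¹³C bottles + 1 ¹²C control | the duplicate-plus-control design of the incubations being emulated |
| base abundances | uniform | isolates the density model from abundance effects in the calibration worlds; any abundance vector can be supplied |

Within a fraction, a taxon's expected read proportion is its base
abundance times its band mass in the bin, renormalized over taxa — i.e.
sequencing sees composition, not absolute DNA amounts. The unnormalized
per-bin mass is attached as a DNA-concentration analogue for plotting.
Reads are one multinomial draw per fraction. Per-bottle RNG streams are
sub-seeded deterministically (`seed + 1000·replicate` for ¹³C bottles,
`seed + 500` for the control), so adding a replicate never perturbs the
other bottles, and the caller's RNG state is always restored.

What the generator deliberately does **not** emulate: PCR/primer bias,
chimeras, within-taxon labeling heterogeneity (each taxon has a single
`atom_excess`, not a mixture of labeled and unlabeled subpopulations),
GC-content differences beyond the per-taxon band center, and
DNA-amount-dependent library depth. A green recovery test therefore
establishes that the statistic and its plumbing work on cleanly separated
bands — not that any particular real incubation was analyzed correctly.

One empirical margin is worth knowing: in the default recovery world
(2 fully labeled taxa of 20, 50 seeds), sensitivity is 1.0 but the
fraction of seeds with *zero* false positives is ≈ 0.86–0.94 depending on
the seed stream — with 18 unlabeled taxa, two replicates and no multiplicity
control, occasional double `RoOR > 1` flukes are expected. This is a
property of the published decision rule, not of the implementation.

## Clustering

Community dendrograms use the correlation distance `d = 1 − r` between
samples' taxon vectors and Ward minimum-variance agglomeration in its
squared-distance ("ward.D2") form: Lance–Williams updates on squared
distances, heights reported on the distance scale. The historical "ward"
option of the era's R tooling was ambiguous between two variants; the
squared-distance variant is implemented, and an exhaustive
recompute-from-original-distances oracle in the test suite pins these
exact semantics. Equal merge costs are broken toward the lowest-index
pair in cluster-creation order, making trees deterministic.

Node support is the plain bootstrap probability: taxa (rows) are resampled
with replacement, the tree is rebuilt, and a node's BP is the percentage
of resampled trees containing the same leaf set as a cluster.
Approximately-unbiased multiscale-bootstrap p-values are intentionally out
of scope (they belong to a different method); BP values are what the
`bp` field and the Newick node labels carry. A degenerate resample that
leaves a sample with zero variance counts as supporting no nodes, which
can only deflate support.

## Numerical choices

* Fraction bins with total band mass < 1e-12 are flagged empty and yield
  zero reads rather than a renormalization of numerical noise.
* RoOR ties at the threshold are *not labeled* (strict `>`, as printed).
* Undefined statistics are `NA` end to end, never silently dropped rows;
  bottles that cannot support the analysis at all (no heavy or no light
  fraction) abort with a distinct condition class, which the CLI maps to
  exit code 3 (validation errors are exit 2).
* Pipeline outputs contain a config-hash + seed stamp and no timestamps,
  so reruns under the same config are byte-identical (tested).

## Limitations

* Cross-feeding is indistinguishable from primary label uptake — a
  secondary consumer of ¹³C metabolites is genuinely labeled. Long
  incubations widen this ambiguity; no statistic on a single endpoint can
  remove it.
* The two-pool OR contrast cannot quantify *how much* label was
  incorporated; estimating atom-fraction excess from density shifts
  (quantitative SIP) is a different method and out of scope.
* With deep sequencing the bottle-level filter is nearly always passed, so
  `min_reads` does little work under the default scope; it matters for
  sparsely sequenced samples, which is exactly the situation it was
  written for.
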