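---
title: "Methods: plasma circulating-miRNA profiling across staged cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma circulating-miRNA profiling across staged cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmir)
```

## The problem

Circulating microRNAs in blood plasma are candidate non-invasive biomarkers
for ovarian cancer, which is usually diagnosed late. `plasmir` implements an
analysis pipeline for plasma miRNA profiles measured on a hybridization
counting panel (NanoString nCounter style: per-probe molecule counts, no
amplification) across four cohorts — healthy controls and patients at FIGO
stages I, III and IV — followed by qPCR validation and downstream
target-gene, enrichment and protein–protein interaction (PPI) analyses.

Because raw data of this design are rarely deposited, the package ships a
first-class synthetic-data generator that emulates every input with the
statistical structure the analysis assumes, so the full pipeline is testable
end to end with known ground truth.

## Count normalization

Raw probe counts are normalized in a fixed three-stage order:

1. **Background subtraction.** Per sample, the threshold is the mean plus two
   sample standard deviations of the negative-control probe counts; every
   other count is reduced by that threshold and floored at 0. We read
   "mean ± 2 sd" as the one-sided upper bound: subtracting the lower bound
   would under-correct, and a two-sided subtraction is not defined. Flooring
   at 0 (not 1) lets downstream detection treat 0 as "not detected".
2. **Positive-control (lane) correction.** Each lane is summarized by the
   geometric mean of its spiked positive-control ladder counts; the lane
   factor is the across-lane arithmetic mean of these summaries divided by
   the lane's own summary (the platform convention). A "geometric median of
   the positive code-set" is ambiguous for per-lane scalars, so the geometric
   mean is the default and a geometric across-lane center is selectable via
   `center = "geometric"` (which makes the factors' geometric mean exactly 1).
3. **Housekeeping scaling.** The same arithmetic on the geometric mean of the
   ten housekeeping miRNA counts. Housekeeping rows are rescaled along with
   the endogenous rows and retained (flagged by probe class), which makes the
   stage idempotent: re-running it on its own output yields unit factors.

Zeros are replaced by 1 before any log-averaging; counts are integers, so
this is deterministic and avoids minus infinity without biasing positive
counts. Since every stage acts multiplicatively per lane after background
subtraction, doubling an entire lane changes the normalized matrix by a
single global constant — the invariance the test suite asserts to 1e-9.

## Differential expression and stratification

Counts are compared across the four cohorts with the tie-corrected
Kruskal–Wallis test (chi-square approximation, df = k − 1), delegated to
`stats::kruskal.test()`. Dunn's post hoc pairwise z statistics on the pooled
mid-ranks are computed in-package (no installed package provides them):

$$z_{ij} = \frac{\bar R_i - \bar R_j}
{\sqrt{\left[\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right]
\left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}$$

with two-sided normal p-values multiplied by the number of pairs (the
classical Dunn adjustment; Holm selectable). Fold change is the relative
difference `(stage mean − control mean) / control mean`, so 0 is no change
and −0.5 a halved mean; a zero control mean yields a flagged `NA`, never an
infinity.

"Expressed only in …" statements need an operational detection call, which
the source analysis never defines. The default `detection_rule()` calls a
probe detected in a cohort when its background-corrected count exceeds 0 in
at least half of that cohort's samples; both knobs are configurable.
Stratification is then:

* **group 1** — detected in Control and ≥1 patient cohort, KW p < α;
* **group 2** — not detected in Control, detected in FIGO I only;
* **group 3** — not detected in Control, detected in all three stages;
* **none** — anything else (e.g. detected in FIGO III only).

These rules are mutually exclusive by construction. The published listing
this design mirrors prints one miRNA (hsa-miR-584-5p) in both the group-1 and
group-2 columns; this implementation enforces disjoint groups and documents
that discrepancy instead of reproducing it.

Hierarchical clustering of the differential set z-scores rows of
log2(count + 1), uses Euclidean distance with average linkage, sorts rows
lexicographically first so leaf order is deterministic, flags constant rows
(zero vector assigned), and exports a Newick dendrogram via `ape`.

### Calibration of the Kruskal–Wallis gate

Two facts matter when interpreting the gate's type-I behavior, and both are
properties of the statistics, not of this implementation:

* The chi-square approximation is mildly conservative at 6 samples/cohort
  (empirical rejection rate ≈ 0.038–0.041 at nominal 0.05 on continuous
  nulls). At 12/cohort it is accurate (≈ 0.047). The calibration suite
  therefore measures the null rejection rate at 12 samples/cohort; at the
  study's 6/cohort an exact permutation p (`kruskal_wallis_permutation()`)
  is available, and in the far tail it differs substantially from the
  chi-square value — on the canonical perfectly-separated 4×3 example the
  exact tail is 24/369600 ≈ 6.5e-5 while the approximation gives 0.0156.
* Lane-scale effects are shared by all probes in a lane, which correlates
  probes; a binomial Monte-Carlo band around the nominal level is only valid
  for independent probes, so the calibration run switches lane effects off
  (`lane_scale_sd = 0`). With them on, per-run rejection rates legitimately
  swing (we observed 0.018–0.074 across seeds at sd 0.3).

## qPCR validation

Triplicate Ct plates are ingested with the determinable-range rule: readings
above 45 cycles, or `Undetermined` tokens, are assigned exactly Ct = 45 with
a provenance flag. Relative expression is 2^−ΔCt with ΔCt the difference of
replicate means (target minus reference assay); for balanced triplicates this
equals the mean of per-replicate ΔCt. Ceiling-valued targets keep the
arithmetic and carry a censored flag into the concordance table; an
all-ceiling reference is an error, since the method is undefined without a
detectable reference. Concordance against the panel re-tests each shared
assay's 2^−ΔCt across cohorts with the same KW + Dunn machinery and compares
significance and direction (`both-significant-same-direction`, `discordant`,
`underpowered`).

## Networks, enrichment, PPI

The miRNA–target network is bipartite; centrality ranking uses degree and
classical unnormalized betweenness (endpoints excluded) with deterministic
tie-breaking (degree, then betweenness, then id). The multiply-targeted core
keeps genes with ≥2 miRNA partners, labeled `high` (>2) or `mid` (=2).
Published absolute degree values depend on external database versions and are
context, not reproduction targets; what the suite verifies instead is
agreement with a brute-force all-shortest-paths enumeration on graphs of up
to 12 nodes.

Target-set intersection returns the exact exclusive Venn regions; their sizes
always sum to the size of the union (a conservation property the suite
asserts on random inputs). Over-representation is the one-sided upper-tail
hypergeometric test via `phyper`, with the universe defaulting to all genes
in the collection, user-supplied backgrounds overriding, and query genes
outside the universe dropped (counted, never silently added). Raw p with the
0.05 threshold is the primary criterion; BH q-values are reported alongside
because no multiple-testing correction is stated for the enrichment step in
the source design. The EASE-style (k − 1) variant was considered and left
out: the default raw hypergeometric is the documented choice.

The PPI stage expands seed genes to their first-order interactors (induced
subgraph), optionally restricting the interactome first to tissue-expressed
genes — the filter applies to the interactome, not the seeds, because seeds
are measured targets regardless of annotation. The "minimum network" is
first-order expansion followed by iterative deletion of non-seed nodes of
degree ≤ 1 to a fixed point. This pruning rule is confluent, hence
deletion-order independent and idempotent (both property-tested); a true
Steiner-tree minimum network is out of scope.

## The synthetic-data generator

The generator's defaults are the study conditions:

| parameter | default | why |
|---|---|---|
| cohorts | Control, FIGO I/III/IV, 6 samples each | the profiled cohort design |
| panel | 798 endogenous, 6 negative, 6 positive, 10 housekeeping | panel content; control-probe counts follow platform convention |
| counts | negative binomial, `dispersion = 10` | counting data are over-dispersed; Poisson is the `dispersion → Inf` limit |
| `baseline_mean` | 50 | most plasma miRNA counts are low |
| `background_mean` | 2 | nonspecific binding of a few counts |
| `lane_scale_sd` | 0.3 | log-normal per-lane scale shared by all probes, making positive-control correction identifiable |
| positive ladder | geometric, ×200 → ≈25…25600 counts | the magnitude span real spike-in ladders cover, so the lane scale is well estimated |
| planted groups | 17 / 19 / 9 probes at log2 effect 2 (one group-1 probe at −2) | mirrors the published group sizes, including the single down-regulated miRNA |

"Absent" miRNAs (group 2/3 patterns outside their expressed cohorts) are
simulated as background-only rather than structurally zero, so detection
calls are genuinely exercised. All generators are pure functions of
(config, seed): they restore the caller's RNG state and identical seeds give
byte-identical outputs.

What the generator does **not** emulate: probe-specific hybridization
efficiencies, correlated miRNA modules, sample-quality covariates,
amplification-efficiency differences in qPCR, or the composition of real
target/interactome/gene-set databases (those are randomized with planted
structure). Passing tests therefore demonstrate the pipeline's correctness
and calibration under the assumed model, not biological validity on real
cohorts.

## Problem sizes in the test and acceptance suites

The suites run the full panel (798 probes × 24 samples) for recovery
(20 seeds), 2000 independent probes for null calibration, 150-probe panels
for normalization recovery, and ≤12-node graphs for exhaustive oracles —
sizes chosen so each property is measured with meaningful Monte-Carlo error
on a desktop machine.

## Known limitations

* The chi-square KW p is the default at the study's n = 6/cohort despite its
  mild conservatism there; the permutation variant is provided but not the
  default, matching common practice.
* Group-1 calls admit chance KW rejections among null probes at rate α by
  design; the pipeline reports group counts, and specificity is bounded by
  the α gate, not by detection.
* No alias resolution for gene symbols (symbols are upper-cased only).
* `run_pipeline()` validates in-memory stage state rather than re-reading
  files between stages; files are written for external consumption.
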