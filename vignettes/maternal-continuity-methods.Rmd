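---
title: "Methods: testing maternal genetic continuity from mtDNA control-region data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing maternal genetic continuity from mtDNA control-region data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtcontinuity)
```

## The problem

Did the people buried at an ancient site leave maternal descendants in the
populations living in the same area today? `mtcontinuity` implements the
full analytical chain used to ask that question from mitochondrial DNA
control-region data: haplotype handling under partial ancient-DNA coverage,
haplogroup classification, standard within- and between-population
statistics, and a simulation-based (ABC) test of two demographic
hypotheses — *genealogical continuity* (the modern local population descends
from the ancient deme) versus *genealogical independence* (the ancient
lineage contributed no ancestry to either modern population).

The package is organised around a concrete study design: one ancient
population sampled roughly 96 generations ago (a 5th-century-BC horizon at
25 years per generation) with partial hypervariable-segment coverage, and
two modern populations (a village and its surrounding province, sample
sizes near 25/51/56) typed for the complete control region 16024–576.

## Haplotypes with partial circular coverage

Haplotypes are sets of rCRS-relative variants (`16069T`, `309.1C`,
`249del`) together with the *edition ranges* actually sequenced, modelled
as closed circular intervals on the 16,569-bp mitochondrial genome
(16024–576 wraps the origin and spans 1122 sites). All comparisons are
restricted to the common coverage of the haplotypes involved; this is what
makes ancient partial data comparable at all, and also what inflates
apparent haplotype sharing — `shared_haplotype_groups()` therefore flags
groups whose joint common range is a strict subset of the reference range
as *partial evidence*.

Comparison conventions, chosen to match standard forensic/population
practice for the control region:

* insertions anchored at the poly-C length-heteroplasmy sites 16193, 309
  and 573 are stored but excluded from distances and diversity (length
  heteroplasmy itself is resolved to the majority molecule upstream of this
  package);
* IUPAC ambiguity codes (e.g. `16291Y`, a point heteroplasmy) count as *no
  difference* against any compatible state, including the reference when
  the reference base is unknown — conservative for kinship matching;
* deletions are a distinct state.

The rCRS sequence itself is not bundled (only positions and observed bases
are needed); `RcrsVariant` records therefore carry an optional reference
base, and FASTA realization requires the caller to provide a reference.
Simulated datasets are expressed relative to their own root sequence and
are labelled synthetic throughout.

## Haplogroup classification

The classifier walks an embedded, hand-curated reduced phylogeny
(`inst/extdata/haplogroup_tree.tsv`) restricted to the lineages relevant to
this kind of north-Iberian dataset (R0/H/HV0, JT/J/J1/J1c/J2/T, U/U5/U6/K,
W, X2, L1b). Each node carries incremental control-region motif
requirements and, for the R0/H and U subtrees, coding-region diagnostics
from the minisequencing panel (3010, 11377, 4769, 6776, 3992, 456, 3915,
4793, 13101, 13020, 14470, 8448, 3936, 4745, 6253, plus 7028 and 11467 as
H/U discriminators). A few deep subclade diagnostics (J1c1, K2a5,
U5b1c1a) are control-region stand-ins chosen to be mutually exclusive
within the fixture, because the published diagnostics for those nodes are
coding positions outside the modelled panel; the fixture is
user-replaceable.

The descent rule: a node is entered only when none of its requirements is
contradicted by an observed state *and* at least one is positively
observed. Requirements at positions outside coverage (or coding positions
without a call) are *unobserved*: they neither support nor block. Descent
stops at the deepest enterable node; the label gains a `*` suffix whenever
an unobserved defining position — on the path or in a child that could have
refined the call — left the assignment uncertain. This reproduces the
field's reporting style (`J1*`, `U5b*`) for partially covered ancient
samples. Consequences worth knowing:

* an rCRS-identical haplotype with no coding calls reports `R0*`, not `H`:
  the control region alone cannot separate H from the rest of R0;
* removing coverage of one of several defining positions of a node changes
  only the flag, not the lineage; a node whose *only* diagnostic becomes
  unobserved falls back to its parent with the flag — the honest reading of
  the evidence;
* sibling ties (possible with back-mutations) resolve toward the sibling
  with more positively observed positions; ties supported by mutually
  exclusive minisequencing calls raise an error naming the conflict.

`collapse_to_basal()` pools labels into a configurable basal tier
(H, J, K, U5, W, …) for frequency comparisons across datasets of unequal
resolution, and `haplogroup_frequencies()` optionally counts explicit kin
groups (e.g. two infants from one burial sharing a haplotype) once.

## Population statistics

* **Gene diversity** \(\hat H = \frac{n}{n-1}\bigl(1-\sum_i p_i^2\bigr)\)
  over distinct-haplotype frequencies, sd from Nei's variance estimator.
  Distinct haplotypes are connected components of the zero-distance
  relation (ambiguity codes make plain equality too strict).
* **Mean pairwise differences**
  \(\pi = \binom{n}{2}^{-1}\sum_{i<j} d_{ij}\). Two standard deviations are
  reported side by side because summary tables in this literature do not
  always state which estimator was used: Tajima's total variance under no
  recombination, \((3n(n+1)\pi + 2(n^2+n+3)\pi^2)/(11(n^2-7n+6))\)
  (the headline `pi_sd`), and the sampling+stochastic form
  \((n+1)\pi/(3(n-1)) + 2(n^2+n+3)\pi^2/(9n(n-1))\) (`pi_sd_alt`).
* **Nucleotide diversity** \(\pi_n = \pi/L\) with
  \(V(\pi_n) = \frac{n+1}{3L(n-1)}\pi_n + \frac{2(n^2+n+3)}{9n(n-1)}\pi_n^2\);
  \(L\) counts the sites of the comparison range minus the ignored poly-C
  anchors (1119 for the full control region). This variance form
  reproduces, at published \(\pi\) values for samples of 51 and 56
  control-region sequences, the published standard deviations to their
  printed precision — the check is in the test suite.
* **Pairwise FST**: two-population AMOVA variance partition
  (Excoffier–Smouse–Quattro). The default `frequency` mode uses haplotype
  identity (0/1 distances; FST proper, matching haplotype-based
  differentiation analyses); `distance` mode weights by pairwise
  difference counts (a PhiST analogue). Significance comes from permuting
  individuals across populations (default 1023 permutations) with the
  +1/+1 p-value estimator, so p is never exactly zero; negative estimates
  are reported as computed. The Bonferroni flag uses a caller-supplied
  divisor — ten pairwise comparisons give the conventional adjusted level
  0.005. Note the estimator's small negative offset (about \(-1/(n-1)\))
  for identical compositions; it vanishes with sample size.
* **Chi-square tests** on 2×2 archaeological count tables use the Pearson
  statistic *without* continuity correction (df = 1). On tables as small as
  8-vs-33 burials, Yates' correction roughly doubles the p-value; the
  uncorrected convention is what this literature reports.
* **PCA** on population × basal-haplogroup frequency matrices is
  column-centred covariance PCA on raw frequencies — no scaling and no
  log-ratio transform, mirroring common practice with PAST-style analyses
  of haplogroup tables. Zero-variance columns are dropped with a message.

## The coalescent/ABC engine

### Serial-sampling coalescent

`simulate_genealogy()` runs a heterochronous coalescent over a set of
demes: mtDNA is haploid and maternally inherited, so a deme of effective
female size \(N_e\) coalesces each lineage pair at rate \(1/N_e\) per
generation (no factor 2). Lineages enter at their sampling age (96
generations for the ancient sample), and merge events move whole demes into
their ancestors backward in time. Validity is checked against closed
forms in the tests: \(E[T_2] = N_e\) within 5% over 2000 replicates, the
serial-sampling bound TMRCA ≥ sampling age, no cross-deme coalescence
before the merge, and \(E[\pi] = 2 N_e \mu L\) within 7%.

### Scenarios and priors

`default_scenarios()` encodes the two hypotheses. *Continuity*: the
ancient sample is drawn from the direct ancestor deme of the first modern
population at \(t_s = 96\) generations; the second modern population
splits from that lineage at `t_split`. *Independence*: the ancient deme
splits from the common ancestor of both modern populations at `t_anc`,
constrained (by rejection at draw time) to predate their own split.
Numeric priors are not printed in the source literature for this design,
so the defaults are stated assumptions, all config-overridable:
\(N_e \sim U(100,\,50000)\) per branch, event times
\(\sim U(t_s+1,\,4000)\) generations, and the per-site per-generation
mutation rate \(\mu \sim U(10^{-8},\,10^{-6})\). With different priors the
posterior probabilities of a given dataset will differ; that is inherent
to the method, and the package's acceptance surface is therefore the
property level (calibration, recovery, error rates), not any particular
published posterior.

### HKY sequence evolution

Mutations are placed as a Poisson process at rate \(\mu L\) per generation
along each branch; each mutation hits a uniform site and replaces its base
by a draw from the HKY85 rate-matrix row of the current base (diagonal
excluded), so transitions are favoured by the \(\kappa\) factor and the
stationary composition by the base frequencies. Defaults: \(\kappa = 20\)
and base frequencies (A 0.31, C 0.31, G 0.13, T 0.25) typical of the human
mtDNA control region; \(L = 1122\). With equal base frequencies the
realized transition:transversion ratio converges to \(\kappa/2\), which is
tested. Multiple hits at a site are naturally allowed.

### ABC model choice

Summary statistics are the three pairwise haplotype-identity FST values —
the deliberately minimal, literal choice for this design; the summary
function is pluggable if more are wanted. `build_reference_table()` draws
scenarios with equal prior probability and is bit-reproducible under a
fixed seed (single-threaded). `model_choice()` scales statistics by their
median absolute deviation, retains the `retain_frac` (default 1%) closest
simulations by Euclidean distance, and reports both the direct scenario
proportion among retained simulations and a local logistic regression of
the scenario indicator on the centred statistics with Epanechnikov weights,
evaluated at the observed point. If the retained set is single-scenario the
regression is skipped with a notice. `pca_preevaluation()` projects the
observed vector into the PC space of the simulated statistics and flags it
when it falls outside the convex hull on PC1–PC2 — the standard sanity
check that *some* scenario can produce data like the observed.
`confusion_errors()` estimates type I error (pods from the best-supported
scenario where it is not selected) and type II error (pods from the
alternative where it is wrongly selected) from pseudo-observed datasets
drawn from the priors.

Observed datasets with heterogeneous ancient edition ranges may have an
empty joint coverage intersection; the observed-data path accepts an
explicit comparison window (e.g. an HVS-I core) and the analysis scripts
match the simulated sequence length \(L\) to that window so observed and
simulated statistics are commensurate.

## The synthetic-data generator

`generate_backbone_dataset()` emulates the *statistical structure* the
analysis assumes: haplogroup founder motifs drawn from backbone
frequencies (default: an H1/H3/J1c/U5-dominated spectrum typical of
north-Iberian datasets), Poisson-distributed private substitutions placed
away from any fixture-defining position and the poly-C anchors (so
classification stays unambiguous), explicit kin clusters sharing exact
haplotypes, full minisequencing call sets for R0/U-derived samples, and
coverage degradation that retains HVS-I/II/III with set probabilities and
truncates segment ends (defaults: 0.9/0.95/0.25 and up to 60 sites,
mimicking variable ancient edition ranges). Generation is deterministic
under the template seed.

What it does **not** emulate: sequencing error, contamination, cytosine
deamination damage, genuine phylogenetic correlation between haplogroup
frequencies and private-variant spectra, or length-heteroplasmy itself.
Tests passing on synthetic data therefore certify the statistical
machinery and its conventions, not robustness to ancient-DNA artefacts —
those are assumed to be handled upstream (authentication, replication,
majority-molecule calling).

## Numerical choices and problem sizes

* Permutation p-values use the +1/+1 estimator; permutations default to
  1023.
* FST returns 0 with p = 1 on globally monomorphic input (the degenerate
  denominator), and is otherwise unclamped.
* MAD scales equal to zero are replaced by 1 (a constant statistic carries
  no distance information).
* Logistic regression uses a quasibinomial fit to admit continuous
  Epanechnikov weights; boundary-weight observations get a floor of
  1e-12.
* Tree tie-breaks and the classification descent rule are described above;
  all RNG flows through R's global stream so a single seed reproduces any
  run end to end.
* Problem sizes: the unit suite uses reference tables of a few hundred
  simulations; the full-scale experiments use \(2\times10^4\) simulations,
  retaining 200, with 100 pseudo-observed datasets — the scale at which the
  calibration (posterior 0.50 ± 0.05 under identical scenarios) and
  recovery (≥ 80/100 pods under well-separated scenarios, both error rates
  < 0.2) properties are asserted. Production analyses would use
  \(10^6\)–\(10^7\) simulations; nothing in the design changes, only wall
  time.

## Known limitations

* The haplogroup tree is a reduced fixture: haplotypes from lineages
  outside it classify to the nearest modelled ancestor (often `R0*` or a
  flagged intermediate). Swap in a fuller tree via
  `load_haplogroup_tree(path)` if needed.
* Haplotype-identity FST loses power when nearly every individual is
  unique (common for complete control regions in large samples) and when
  diversity is very low; the `distance` mode and pluggable summaries are
  the escape hatches.
* The two-scenario topology is fixed to the triad design (one ancient, two
  modern populations). More populations or admixture events would need new
  `abc_scenario` definitions — the simulator itself is general over demes
  and merge events.
* Posterior probabilities from ABC model choice are prior-sensitive;
  report them together with the priors and the error rates, never alone.
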