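---
title: "Dating, biogeography and the anatomy of a vicariance test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating, biogeography and the anatomy of a vicariance test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Punta del Morro (PdM), a lava flow of the Transmexican Volcanic Belt reaching
the Gulf of Mexico coast, is the classic break between Nearctic and
Neotropical freshwater fish faunas and has been widely used as a vicariant
calibration: lineages split when the flow formed, roughly 5–7.5 Ma. Whether
a given split was actually *caused* by the barrier is testable: if
calibrations independent of the barrier (fossils, island separations, basin
separations) date the split well before the barrier existed, the vicariance
explanation fails, and the observed range disjunction needs another
mechanism — in the motivating system, dispersal across the region before the
barrier, followed by local extinction in the intervening area during periods
of high sea level.

`pdmvic` implements that whole chain of reasoning as reusable, testable
components: calibrated Bayesian node dating on a fixed topology under
alternative calibration schemes; single-locus species delimitation (GMYC and
a PTP-style model) to establish how many independent lineages are involved;
event-based dispersal–vicariance ancestral-area reconstruction (DIVA/S-DIVA);
the adjacency rule that converts reconstructed range disjunctions into dated,
area-specific extinction hypotheses; and sea-level/elevation tools that ask
whether those extinction windows coincide with high sea stands. A
synthetic-data generator with known ground truth makes every stage testable
end to end without any external downloads.

## Synthetic data: what it emulates, and what it does not

The generator (`sim_config()`, `simulate_dated_tree()`,
`simulate_biogeography()`, `simulate_alignment()`,
`simulate_haplotype_tree()`) emulates a single-genus mitochondrial
phylogeography dataset: a complete protein-coding mtDNA marker (default
1,137 sites — the length of cytochrome *b*), about ten species, tree depths
on a 0–30 Ma scale, and a handful of endemic areas on an adjacency graph.
Species trees are birth–death draws (`ape::rphylo`; defaults 0.3/0.1
events/Ma) conditioned by rejection on a root-age bound. Ranges evolve by
Poisson dispersal to graph-adjacent areas and Poisson extinction (never
emptying a range); at each speciation a multi-area range splits into a
uniformly random disjoint bipartition (a single-area range duplicates) — the
zero-cost events of DIVA, so the reconstruction stage faces data generated
under its own event model. Sequences evolve under HKY (kappa 4, cytb-like
base frequencies) with a strict clock at 0.01 substitutions/site/Ma
(≈2%/Ma pairwise divergence, the conventional fish mtDNA figure) or an
uncorrelated lognormal relaxed clock; the root sequence is drawn from the
stationary frequencies with in-frame stop codons (vertebrate mitochondrial
code) resampled.

What the generator deliberately does **not** emulate: within-species
gene-tree/species-tree discordance (haplotype subtrees are grafted
coalescents with depth drawn below a configurable ceiling, not a full
multispecies coalescent), selection, indels, saturation heterogeneity across
codon positions, and rate variation across sites (see below). Passing tests
therefore demonstrate internal correctness and recoverability under the
model's own assumptions, not robustness to every feature of real mtDNA.

## The dating model

`estimate_node_ages()` samples node ages on a fixed rooted topology by
Metropolis-within-Gibbs. The likelihood is the Felsenstein pruning
likelihood under HKY (compiled kernel; closed-form transition probabilities
verified against an eigendecomposition oracle to machine precision), with
branch lengths `rate × duration`. The prior multiplies

* a tree prior on node ages — pure-birth (Yule) with configurable rate, the
  zero-extinction special case of a birth–death prior, or uniform; at desk
  scale with explicit node calibrations the tree prior contributes little,
  which is why the simple form is the default;
* one truncated-normal calibration density per constraint (mean/SD in Ma,
  truncated at 0) attached to the MRCA of a stated tip set;
* diffuse hyperpriors: log-uniform on the clock rate and kappa; under the
  relaxed clock, iid lognormal branch rates with real-scale mean equal to
  the mean rate and an exponential prior (mean 0.5) on the log-scale SD.

Proposals are uniform slides within each node's (oldest child, parent) age
bracket, a multiplier on the root age, a joint scale-ages/counter-scale-rate
move that decorrelates depth from rate, multipliers on rate and kappa, and
normal log-rate slides per branch under the relaxed clock. Effective sample
sizes are estimated from the autocorrelation and reported; low ESS flags the
sample rather than failing. `hpd_interval()` returns the shortest interval
at the stated mass.

Site-rate heterogeneity: a discrete-gamma HKY likelihood is implemented
(`mcmc_settings(gamma_alpha = ...)`, 4 categories) but the default is
homogeneous rates, matching the generator; gamma quadruples the likelihood
cost and adds nothing on data simulated without it.

The five calibration schemes of the motivating analysis are built by
`build_calibration_scheme()`: (I) fossil 44.25 ± 2.7 Ma plus
Cuba–Hispaniola 22.5 ± 1.5 and Orinoco–Magdalena 10.95 ± 0.6; (II) the two
geological constraints only; (III) the fossil only; (IV) a secondary
calibration 23 ± 2; (V) the PdM constraint itself, mean 7.5 Ma. The source
gives no SD for scheme V; 0.5 Ma is the package default and is explicitly
overridable, so the barrier hypothesis is encoded as a reasonably tight
prior rather than a point mass.

Model choice between strict and relaxed clocks
(`compare_clock_models()`) uses stepping-stone marginal-likelihood
estimation with Beta(0.3, 1)-spaced power posteriors. Stepping stone was
chosen over nested sampling deliberately: the decision target (which clock
wins on marginal likelihood) is the same, the estimator is simpler to
verify, and a self-comparison check (same model twice) must agree within
Monte-Carlo error, which the tests assert.

The barrier test itself (`run_pdm_test()`) makes the verdict rule explicit,
since prose like "rejects the vicariance" needs an operational form: the
split *predates the barrier* when the youngest 95% HPD lower bound across
all barrier-free calibration schemes exceeds the older bound of the barrier
window (default 5–7.5 Ma). The barrier-derived scheme is run for contrast
but never contributes to the verdict. A deliberate property of
mis-calibration is also exposed and tested: calibrating a node at half its
true age compresses the entire timescale by roughly that factor, which is
exactly the behaviour that makes a barrier-derived calibration circular.

## Species delimitation

`gmyc_single_threshold()` fits the generalized mixed Yule-coalescent on an
ultrametric tree. Inter-event intervals contribute `b exp(-b x)`; above the
threshold the hazard is `lambda_Y * k^p_Y` (k = lineages), below it
`lambda_Y * k^p_Y + lambda_C * sum_j (n_j (n_j - 1))^p_C` over clusters; the
final interval contributes its survival probability only. The exponents are
fixed at 1 by default (an option estimates them on a small grid) — profile
fits at desk scale are markedly more stable that way. Thresholds are
profiled over all node heights, tips (0) and root included; the root-height
candidate is the single-cluster structure and nests the single-process null,
so the LR statistic is never negative. The LR is referred to chi-squared
with df = 2 by default (one extra rate plus the threshold); the raw LR is
reported so users can apply a different reference. Exact likelihood ties
resolve to the smaller threshold, i.e. the finer partition: with no
coalescent signal the method should not merge tips.

A known limitation, surfaced by the tests rather than hidden: on trees with
no within-species structure at all, the two-parameter mixed model can
slightly out-fit the pure branching model at an arbitrary interior
threshold. The LR test is the guard — on such trees it is non-significant,
and the per-threshold profile is part of the returned object so the
flatness is visible. Delimitation conclusions should rest on the test, not
on the raw ML threshold.

`ptp_delimit()` models branch lengths on a substitution-scaled tree as two
exponential classes (between- vs within-species), searching over species
partitions (each species a connected subtree) by greedy merge/split hill
climbing from 50 seeded random restarts. Two design choices matter. First,
identifiability: a fit in which the between-species class has a *smaller*
mean than the within-species class is biologically inverted, so such
assignments collapse to the single-class score. Second, exact likelihood
ties resolve toward more species. The two-class likelihood cannot
distinguish "all tips one species" from "every tip its own species" (both
put every edge in a single class), so a tie rule is unavoidable; merging on
no evidence was judged the worse error for a single-locus screen, and the
exhaustive 4-tip oracle in the tests scores with exactly the same rule.

On the familiar question of how well these single-locus delimiters can work
at all: with iid exponential branch-length classes separated only 10-fold in
mean, the globally maximum-likelihood partition differs from the generating
one in roughly a third of replicates whatever the tree size — short
between-species branches are simply absorbed by the within class. Species
counts are recovered reliably (≥70% in the validation suite) on trees whose
between/within separation comes from actual deep divergence versus shallow
coalescence on the substitution scale, which is the structure real
delimitation datasets are expected to show.

`concordance()` compares any set of partitions (including externally
supplied ones, e.g. from a multispecies-coalescent analysis, which this
package deliberately does not implement) against a reference species table,
classifying each species per method as exact / merged / split / mixed and
counting the species recovered exactly by every method.

## Ancestral areas, extinction, and sea level

`diva_optimize()` is an exact subset dynamic program over all nonempty area
sets up to `maxareas` (bitmask representation, up to 16 areas; exhaustive
enumeration is exact, not sampled). Costs follow the dispersal–vicariance
convention: one unit per area gained (dispersal) or lost (extinction) along
a branch; vicariance (disjoint bipartition), duplication, and — unless
`strict = TRUE` — a sympatric-subset inheritance are free at cladogenesis.
All equally optimal ancestral sets per node are recovered via an
inside–outside pass and reported with uniform frequencies; ties are never
broken silently. Adjacency is *not* consulted inside the optimization
(classic DIVA is adjacency-blind); geography enters only through the
extinction rule below, keeping the published algorithm and the study's own
inference rule cleanly separated.

DIVA has a well-known appetite for wide ancestral ranges: a single dispersal
can be absorbed, cost-free, into a larger ancestral set split by vicariance.
The `maxareas` bound exists to control exactly this, and
`maxareas_sensitivity()` reports, per node, whether the optimal sets agree
across settings (disagreements are listed per setting, never averaged). The
recovery experiments in the test suite bound `maxareas` at the true root
range size for this reason; unconstrained runs recover the true root range
markedly less often — that is a property of DIVA, reproduced faithfully, not
a defect of the implementation.

The extinction rule (`classify_node()`): a node whose daughter ranges
overlap or contain graph-adjacent areas is a plain vicariance; otherwise the
split is classified dispersal-with-extinction, and the intervening areas are
the union of the interiors of *all* shortest adjacency paths between the two
ranges (a `single_path` option supports minimal-extinction counting).
"Directly neighbouring" is operationalized as overlap-or-adjacency because
splits that still share an area clearly need no extinction. When equally
optimal reconstructions disagree, the verdict is `ambiguous` with the
per-reconstruction verdicts attached. `date_extinctions()` assigns each
postulated extinction the stem-branch window `[age(parent), age(node)]` —
the loss must postdate the last node at which the full range demonstrably
existed and predate the observation of the disjunction; at the root, where
no stem exists, the window degenerates to the root age (a documented blind
spot: disjunctions already present at the root cannot be dated).

Sea-level tools: `extract_highstands()` interpolates a (age, level) curve
linearly and solves threshold crossings exactly on segments;
`classify_dem()` cuts an elevation grid at `< 60` m (land flooded by the
high stands under study) and `<= 1000` m (the altitudinal ceiling of the
fish fauna), boundaries handled literally; `habitat_connectivity()` counts
4-connected components of habitable cells (8-connectivity by option).
`interval_concordance()` formalizes the otherwise visual claim that dated
extinction windows coincide with high stands: the overlap fraction is
reported together with a one-tailed permutation p-value obtained by
repositioning each target interval uniformly (length-preserving) within
`[0, root bound]`. The permutation test is the package's own construction
and is reported alongside, never instead of, the raw overlap.

## Numerical choices and degenerate inputs

Tolerances: ultrametricity is checked to 1e-6 Ma on input trees and 1e-9 in
the generator's own output; likelihood oracle agreement is asserted to 1e-8
log units; frequency sums to 1e-9. Rate parameters are optimized or sampled
on the log scale with wide bounds (1e-10 to 1e6 for GMYC rates, 1e-8 to 100
for the clock rate). Exponential-class MLEs guard against all-zero branch
classes with a 1e-12 floor; fully zero-length trees are rejected. MCMC age
moves respect the (child, parent) bracket by construction, so every
posterior draw satisfies parent > child; the root uses a multiplier with an
upper truncation (`root_max`). Empty alignments, ragged alignments,
disconnected adjacency graphs, empty tip ranges, `maxareas` below the
largest tip range, all-no-data grids, non-increasing curve ages, and
permutation counts below 100 are all rejected with explicit errors.

## Problem sizes used by the validation suite

The package-level validation runs at sizes chosen to exercise every stage
meaningfully: dating recovery on 20 datasets of 10 tips × 800 sites
(3,000 sweeps, 1,000 burn-in); the barrier test on 20 replicates of 7 tips
with truth at 14 Ma; delimitation recovery on 20 replicates each of
5 species × 4 haplotypes; DIVA against exhaustive enumeration on 1,000
random 4-tip/3-area instances; the extinction rule against brute force on
200 random graphs plus 100 extinction-free histories; and 100 random
multi-peak terrain grids for connectivity monotonicity. The terrain grids
(Manhattan cones with all summits above the tested flood levels) are the
honest domain for that monotonicity: on arbitrary elevation fields a falling
sea can expose disconnected new land — an emerging island is a new
component — so the "falling sea only merges" property holds exactly when no
summit first surfaces inside the tested range. The acceptance script
(`scripts/acceptance.R`) re-runs the same experiments from scratch under a
caller-supplied seed and writes the resulting rates and bounds as JSON.

## Known limitations

Topology is fixed, never inferred (the dating question is about ages given
well-supported topologies). The multispecies-coalescent delimitation used
alongside GMYC/PTP in empirical work enters only through `concordance()` as
an externally supplied partition. The sea-level machinery does no geodesy:
grids are plain matrices with a cell size, which is adequate for
connectivity and class-count questions but not for areas in km². GMYC
threshold instability on structureless trees is discussed above. And the
extinction rule can only postulate extinctions visible as range
disjunctions: an area lost while still occupied by relatives elsewhere
leaves no signal, so inferred extinction counts are lower bounds by
construction.
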