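# pdmvic

Tools for testing putative vicariant barriers in freshwater biogeography,
built around the Punta del Morro (PdM) problem in Middle American cichlids.

## The problem

Punta del Morro — a Transmexican Volcanic Belt lava flow reaching the Gulf
coast — is the classic Nearctic/Neotropical freshwater-fish break and is
routinely used as a vicariant calibration at 5–7.5 Ma. But a barrier only
explains a split if the split is as young as the barrier. `pdmvic`
implements the full inference chain needed to test that:

1. **Calibrated node dating.** Bayesian node-age estimation on a fixed
   rooted topology (Metropolis-within-Gibbs; HKY pruning likelihood in
   compiled code; strict or uncorrelated-lognormal relaxed clock) under
   alternative calibration schemes — fossil *Plesioheros chauliodus*
   (N(44.25, 2.7) Ma), Cuba–Hispaniola separation (N(22.5, 1.5)),
   Orinoco–Magdalena separation (N(10.95, 0.6)), a secondary *Caquetaia*
   calibration (N(23, 2)), and the PdM constraint itself (7.5 Ma) for
   contrast. The split *predates the barrier* when the youngest 95% HPD
   lower bound across barrier-free schemes exceeds the barrier window's
   older bound.
2. **Clock-model choice** by stepping-stone marginal likelihood.
3. **Single-locus species delimitation**: single-threshold GMYC on
   ultrametric trees and a two-rate PTP-style exponential branch-length
   model on substitution trees, plus a cross-method concordance summary.
4. **Ancestral areas**: exact dispersal–vicariance (DIVA) optimization over
   area subsets with the `maxareas` constraint, S-DIVA frequencies over
   tree samples, and a `maxareas` sensitivity report.
5. **Extinction inference**: the adjacency rule — daughter ranges that
   neither overlap nor touch imply a dispersal followed by local extinction
   in the intervening area(s) (all-shortest-path interiors), dated on the
   stem branch `[age(parent), age(node)]`.
6. **Sea-level concordance**: high-stand extraction from a sea-level curve
   (exact segment crossings), three-class elevation-grid habitat
   classification (<60 m flooded / ≤1,000 m habitable / >1,000 m upland),
   habitat connectivity, and a permutation test for overlap between dated
   extinction windows and high stands.
7. **Synthetic data with known truth** (clock-evolved coding alignments,
   dated trees, biogeographic event histories) so the whole chain is
   testable end to end, plus haplotype collapsing and a reading-frame QC
   check for real alignments.

## A worked example

Simulate a clade whose true focal split is at 14 Ma, date it under a
barrier-free calibration and under the barrier-derived calibration, and ask
whether the split predates a 5–7.5 Ma barrier:

```r
library(pdmvic)

cfg  <- sim_config(seed = 9, n_species = 8)
tree <- simulate_dated_tree(cfg, min_internal_age = 0.5)
tree$edge.length <- tree$edge.length * 14 / max(ape::node.depth.edgelength(tree))
ages <- max(ape::node.depth.edgelength(tree)) - ape::node.depth.edgelength(tree)

cal_tips <- ape::extract.clade(tree, 10)$tip.label   # a well-dated inner clade
schA <- calibration_scheme(
  calibration("internal", ages[10], 0.1 * ages[10], tips = cal_tips), id = "A")
schV <- calibration_scheme(
  calibration("punta_del_morro", 7.5, 0.5, tips = tree$tip.label), id = "V")

aln <- simulate_alignment(tree, cfg)
rep <- run_pdm_test(aln, tree, list(schA, schV), focal_tips = tree$tip.label,
                    mcmc = mcmc_settings(iterations = 2500, burnin = 800),
                    seed = 4)
rep
#> Barrier test (window 5-7.5 Ma): verdict = predates barrier
#>  scheme    median hpd_lower hpd_upper used_in_verdict
#>       A 11.831090  9.012906 15.247353            TRUE
#>       V  7.419756  6.368341  8.286833           FALSE
```

Read: under the barrier-free calibration the focal split (truth: 14 Ma) is
dated 11.8 Ma with the 95% HPD bottoming out at 9.0 Ma — still older than
7.5 Ma, so the barrier cannot have caused it. The barrier-derived scheme V,
by construction, squeezes the same split into its own prior window
(median 7.4 Ma): exactly the circularity the test is designed to expose.

Downstream, the biogeography chain turns a reconstructed range disjunction
into a dated extinction hypothesis and checks it against sea level:

```r
tr  <- ape::read.tree(text = "((t1:10,t2:10):4,t3:14);")
cur <- sealevel_curve(c(0, 9, 11, 15, 20), c(0, 20, 80, 80, 0))
chain <- run_biogeo_chain(tr, list(t1 = "a1", t2 = "a3", t3 = "a1"),
                          chain_areas(3), curve = cur, seed = 1)
chain
#> Biogeography chain: DIVA cost 0 | 1 node(s) with postulated extinction | 1 dated extinction event(s)
#> Interval concordance: overlap fraction 0.917 (null mean 0.170, one-tailed p = 0, 1000 permutations)
```

The sister pair `t1` (area a1) / `t2` (area a3) occupies non-adjacent areas
on the chain a1–a2–a3, so an extinction in a2 is postulated on the pair's
stem branch (14–10 Ma) — and almost all of that window falls inside the high
stand the curve puts at roughly 16–10 Ma, far more overlap than random
placement of the window would give (null mean 0.17).

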