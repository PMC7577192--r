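---
title: "Modeling metabolic homeostasis as an age-stratified physiological network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling metabolic homeostasis as an age-stratified physiological network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabonet)
```

## The model

Metabolic homeostasis is maintained by feedback among many physiological
subsystems; no single biomarker captures its state. `metabonet` models a
cohort of adults as a pair of *inference networks* whose links are
estimated from co-variation in the population rather than observed
directly, and asks how the structure of those networks changes across age
groups.

**Physiological-variables network (undirected).** Nodes are 15 continuous
biomarkers: fasting glucose, HbA1c, basal insulin, HDL, LDL,
triglycerides, uric acid, urea, creatinine, waist, weight, height,
axillary temperature, systolic and diastolic pressure. For each pair we
compute the Spearman rank correlation \(\rho_s\) on pairwise-complete
observations (biomarker distributions are rarely normal and often carry
genuine extreme values, so only monotone association is assumed). An edge
is present when the correlation's two-sided p-value, from the
t approximation \(t = \rho_s\sqrt{(n-2)/(1-\rho_s^2)}\), falls below
\(\alpha = 0.001\); its weight is \(\rho_s^2\), which makes weights
positive while the signed \(\rho_s\) is retained as an edge attribute.

**Pathological-states network (directed).** Each participant is also
classified against 12 risk-oriented thresholds (hyperglycemia, high
HbA1c, insulin resistance via HOMA-IR, low HDL, high LDL,
hypertriglyceridemia, hyperuricemia, azotemia, low eGFR via CKD-EPI,
overweight, high temperature, high blood pressure). For an ordered pair
of states \((X, C)\) with \(N_x\) participants in state \(X\) and
marginal prevalence \(P(c)\), the co-occurrence statistic is the binomial
z-score
\[
  \varepsilon(C\mid X) \;=\;
  \frac{N_x\,\bigl(P(c\mid x) - P(c)\bigr)}
       {\sqrt{N_x\,P(c)\,(1 - P(c))}},
\]
the number of standard deviations by which the observed count of
participants in both states exceeds its expectation under independence.
An arc \(X \to C\) is drawn when \(\varepsilon > 1.96\), the two-sided
95% normal quantile. The statistic is directional — \(\varepsilon(C\mid X)\)
and \(\varepsilon(X\mid C)\) share a sign but not a magnitude — so the
network is directed and reciprocity is informative.

Both networks are built for the pooled sample and for six age strata
(`<25`, `25–34`, `35–44`, `45–54`, `55–64`, `65+`, with the
`[lower, upper)` convention), giving seven networks of each kind.

## What is computed on the networks

* **Influence (radial centrality).** Eigencentrality for undirected
  networks (principal eigenvector of the weighted adjacency, computed by
  a shifted power iteration from the uniform vector to a 1e-10 tolerance,
  rescaled to max 1; the diagonal shift makes the Perron eigenvalue
  strictly dominant, so the iteration also converges on bipartite
  graphs). Hub and authority scores for directed networks (principal
  eigenvectors of \(AA^\top\) and \(A^\top A\), the HITS fixed point);
  states without outgoing arcs have hub score 0.
* **Gatekeeping (medial centrality).** Flow betweenness: weights act as
  capacities and a node's score is the total pairwise maximum flow lost
  when the node is removed. Directed networks use directed capacities and
  ordered pairs; undirected networks unordered pairs.
* **Modules.** All largest cliques (maximum fully connected subsets;
  direction ignored), with a per-node membership frequency across the
  seven networks (0–7); Louvain communities on the physiological network
  and spinglass (Reichardt–Bornholdt, simulated annealing, 25 spins,
  seeded) communities on the symmetrized pathological network. Reported
  modularity Q is always recomputed from the returned assignment with the
  package's own weighted-modularity function, never taken from the
  optimizer.
* **Topology.** Density; reciprocity (directed only); characteristic
  path length as the mean hop-count shortest path over connected pairs
  (a weighted variant was considered and rejected as the default: the
  conventional definition is unweighted and hop counts keep strata with
  different weight scales comparable); global transitivity on the
  binarized graph; weighted clustering — Barrat's coefficient for
  undirected networks and the Clemente–Grassi total coefficient (built on
  \((W + W^\top)/2\) and total degrees) for directed ones, normalized so
  that unit weights reduce exactly to the binary coefficients; and the
  small-world index
  \(\mathrm{SWI} = (CC/CC_{rand})/(L/L_{rand})\) with the closed-form
  baselines \(CC_{rand} = 2m/(n(n-1))\) and
  \(L_{rand} = \ln n / \ln \bar k\). The closed forms were chosen over a
  rewired-graph Monte-Carlo baseline because they are deterministic and
  directly testable; both conventions for the "clustering coefficient"
  (binary mean and weighted mean) are emitted, labeled, since common
  usage is ambiguous.
* **Null models.** Conditional uniform graph (CUG) tests: a statistic's
  observed value is compared against graphs random conditional on size
  (each tie fair-coin), on the exact edge count, or on the dyad census
  (directed only). The binarized structure is randomized and the observed
  weights are reassigned uniformly at random to the drawn ties, so
  weighted statistics are tested against structure with the weight
  distribution held fixed. Two one-sided p-values are reported; they
  overlap at ties.

## Threshold choices and their knobs

| Parameter | Default | Notes |
|---|---|---|
| `alpha` | 0.001 | edge gate on the Spearman p-value |
| `epsilon_threshold` | 1.96 | arc gate; 95% two-sided normal quantile |
| `insulin_conversion` | 6.945 pmol/L per uU/mL | laboratory conventions span 6.0–6.945; configurable |
| eGFR equation | CKD-EPI 2009, no race coefficient | the 1.159 coefficient can be supplied |
| `waist_height_ratio` | [0.25, 1.10] | plausibility band for the waist/height consistency rule |
| `boundaries` | 18, 25, 35, 45, 55, 65 | stratum lower bounds; top stratum open |
| `cug_R` | 500 (pipeline), 1000 (standalone) | CUG null draws |

Threshold comparisons for the 12 states are strict (a value exactly at a
cut-off is not abnormal). The harmonized metabolic syndrome flag — at
least 3 of elevated waist, triglycerides \(\ge\) 1.7 mmol/L, reduced HDL,
blood pressure \(\ge\) 130/85, fasting glucose \(\ge\) 5.55 mmol/L — uses
non-strict comparisons per the harmonized consensus, so two blood-pressure
cut-offs deliberately coexist (120/80 for the risk state, 130/85 for the
syndrome criterion). Cleaning masks individual cells, never whole
participants: range violations (reason `implausible`) and waist/height
inconsistencies (reason `inconsistent`, the waist cell is masked as the
likelier recording error). Age trends use per-participant OLS on
continuous age for the variables, and the Cochran–Armitage trend test
with stratum-midpoint-age scores for state prevalences; the open 65+
stratum is scored at 70 (its lower bound plus half the preceding decade),
consistent with the observed mean age of that group.

## The synthetic cohort generator

The generator stands in for real cohort data so that every downstream
stage is testable. It draws each stratum from a Gaussian copula: a latent
multivariate normal with correlation \(2\sin(\pi\rho_s/6)\) — the exact
map from a target Spearman correlation for continuous marginals — pushed
through per-stratum marginal quantile functions. The default
specification (`default_study_spec()`) encodes the reference cohort: six
strata of sizes 680, 528, 445, 468, 352 and 99 (2572 adults, 65% female),
per-stratum biomarker means and SDs of the reference sample (low-precision
values such as "5 ± 2" are taken at face value), normal marginals except
moment-matched lognormals for basal insulin and triglycerides, whose
printed SDs are comparable to their means. The copula was chosen because
the analysis consumes exactly what it controls: rank correlations and
threshold exceedances. A latent matrix that the sine transform pushes
marginally outside the PSD cone is repaired by eigenvalue clipping at
1e-8 (matrices with eigenvalues below −0.01 are rejected as genuinely
invalid).

The default dependence matrix is a documented fixture, not an empirical
claim: moderate positive blocks within adiposity, glycemic, lipid, renal
and pressure variables, weaker positive cross-links through waist, weight,
insulin and uric acid, HDL negatively tied to triglycerides, and
temperature independent. The block strengths make threshold states
co-occur above chance at the default sample sizes, so the pathological
network is non-trivial.

What the generator does *not* emulate: age-dependent dependence structure
(the same copula is shared by all strata, so the real data's
rise-and-fall of transitivity across decades is not reproduced — only the
machinery that would detect it), skewness beyond the two lognormal
marginals, measurement error and digit preference, and any
medication-driven decoupling of biomarkers. Passing tests therefore
demonstrate correctness of the estimators and pipeline on cohorts with
known structure, not epidemiological claims about real populations.

## Numerical and design notes

* Pairwise-complete observations are used for both networks (each state
  pair's \(\varepsilon\) uses its own \(N\)); per-pair sample sizes are
  reported in the association matrix.
* No multiple-testing correction is applied beyond the fixed
  \(\alpha\)/\(\varepsilon\) gates; both gates are configurable.
* Ties in ranks are handled by average ranks; a constant variable has
  undefined correlations and simply contributes no edges.
* Eigenvector sign and scale are fixed by nonnegativity and max = 1.
* Degenerate prevalences (0 or 1) make \(\varepsilon\) undefined; such
  states contribute no arcs and are logged.
* Strata smaller than `low_n` (default 30) are analyzed anyway and
  flagged in the manifest — the 65+ group is small by design and merging
  it away would hide exactly the ages where topology changes fastest.
* With the default spinglass annealing and 25 spins, 2-node components
  are still clustered per component; singleton components become
  singleton communities.
* Reruns with identical configuration and seeds are byte-identical; the
  manifest records a hash of the analytic settings.

## Problem sizes used in the test suite

The suite exercises the estimators at sizes chosen to make the
statistical assertions sharp but cheap: oracle equivalence on graphs of
4–8 nodes (200 random instances for flow betweenness, 100 for clique
enumeration), copula recovery at n = 10,000, type-I calibration of the
edge gate on 500 independent cohorts of n = 2572, CUG calibration with
500 replicates of 12-node graphs at 199 null draws each, and planted
two-block recovery on 50 cohorts of n = 5000. The full pipeline example
in the README runs the complete study-scale analysis (2572 participants,
14 networks, 500 CUG draws per test) in about a minute.

## Known limitations

* The \(\varepsilon\) normal approximation degrades for very rare states
  (small \(N_x P(c)\)); no exact-binomial fallback is provided.
* Flow betweenness recomputes max flow for every (pair, removed-node)
  combination; cost grows as \(n^3\) max-flow calls and the
  implementation is intended for biomarker-scale networks (tens of
  nodes), not large graphs.
* CUG conditioning on the degree sequence (configuration model) is out
  of scope; only size, edge-count and dyad-census nulls are offered.
* The three-stage reading of health (rising, diverging, falling
  clustering) is an interpretation of the topology curves, not a fitted
  model, and the package deliberately does not fit one.
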