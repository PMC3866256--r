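---
title: "Methods: expression-constrained flux intervals and reaction-network ranking"
author: "fluxmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-constrained flux intervals and reaction-network ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmark)
```

# Overview

fluxmark nominates reaction, gene and metabolite biomarkers for a disease
by confronting a genome-scale metabolic model with condition-specific gene
expression.  Two complementary routes are implemented.

**Flux profile comparison (FPC).**  A metabolic model defines the
steady-state polytope $\{v : S v = 0,\; l \le v \le u\}$, where $S$ is the
stoichiometric matrix (metabolites in rows, reactions in columns) and
$l, u$ are flux capacities.  For each condition, gene expression is mapped
onto reactions through gene–protein–reaction (GPR) rules, converted into a
probability of the reaction being active, and used to tighten the
capacities.  Flux variability analysis then yields, per reaction, the
interval $[v_{\min}, v_{\max}]$ of fluxes attainable near optimal
operation.  Reactions whose normal and disease intervals diverge — low
Jaccard overlap or a large midpoint shift — are significant; the genes in
their GPR rules and their participant metabolites are the biomarker
candidates.

**Reaction–reaction network (RRN).**  Reactions become nodes of an
undirected graph with an edge wherever two reactions share a
(compartment-qualified) metabolite.  Because such graphs are dense, the
analysis concentrates on the largest k-means cluster of the reactions'
metabolite-incidence profiles.  Within that subnetwork each reaction is
ranked by the recursion

$$P_i = (1 - d) + d \sum_{j \in M(i)} \frac{P_j}{L(j)},$$

with residual probability $d = 0.85$, $M(i)$ the neighbours linking to
node $i$ and $L(j)$ the out-degree of $j$.  Note the teleport term is
$(1-d)$, not $(1-d)/N$: ranks sum to roughly the node count rather than 1.
We implement this unnormalized fixed point literally (it is the variant
whose scalar form is given above) and expose the conventional normalized
one behind `normalized = TRUE`.  The final significance score of reaction
$k$ combines centrality and activity,

$$z_k = p_k \times |v_k|,$$

where $v$ is an expression-constrained flux balance solution.  The
top-scoring reactions are reported with their genes and metabolites.

# Stage-by-stage choices

## Expression onto reactions

GPR rules are boolean trees over genes; `AND` encodes an enzyme complex,
`OR` isozymes.  We evaluate `AND` as the minimum and `OR` as the maximum
of the member expression levels — the standard convention; a missing gene
is skipped inside `OR` and renders an `AND` branch unobserved.  A reaction
with no rule, or no measurable gene, is *unobserved* and is never
tightened: absence of evidence leaves the structural capacity in place.

## Activity probability

Reaction scores from different platforms live on arbitrary scales, so the
probability of activity is rank-based:
$p = (\mathrm{rank} - 1) / (n - 1)$ over the observed reactions (average
ranks for ties; 0.5 for degenerate distributions).  The min–max form is
deliberate: the least-expressed reaction attains exactly $p = 0$ and the
most-expressed exactly $p = 1$, so the capacity interpolation below can
reach both of its endpoints.  Reactions strictly below the `q_low`
(default 0.25) empirical quantile of scores are classed `low`, strictly
above `q_high` (default 0.75) `high` — the classes are descriptive
labels; the LP uses the continuous probability, so reactions are never
forced on or off.

## Capacity tightening

Each reaction's bounds are scaled by
$f = \texttt{tighten} + (1 - \texttt{tighten})\,p$, linear in $p$ with
floor `tighten` (default 0.1).  A probably-inactive reaction keeps 10% of
its capacity rather than being shut: the evidence is probabilistic and a
hard knockout would propagate infeasibility.  Bounds are only ever shrunk
toward zero, never widened, so the tightened polytope is nested in the
structural one and every monotonicity property of the LP is preserved.

## Flux intervals

`flux_interval()` computes FVA minima/maxima per reaction.  With
`fix_objective` (default 0.9) the FBA optimum $z^\*$ is computed first and
$c^\top v \ge 0.9\, z^\*$ appended, the standard near-optimal FVA
convention; intervals then describe how much freedom each reaction has
while the system performs.  The default objective is the model's declared
one, else a biomass reaction (id matching "biomass"), else total
export-exchange flux — a sensible default for models without a declared
biomass, and the one the synthetic generator declares explicitly.

## Interval divergence

For intervals $[a_1, b_1]$ (normal) and $[a_2, b_2]$ (disease):
overlap is the Jaccard index of the two segments (two identical points
overlap 1, distinct points 0); shift is the midpoint distance divided by
the mean of the two widths (0/0 taken as 0, positive/0 as infinite).
A reaction is significant when overlap $< \theta_{\mathrm{overlap}}$
(default 0.2) *or* shift $> \theta_{\mathrm{shift}}$ (default 1.0).  The
defaults are anchored at the two unambiguous cases: identical intervals
are never significant, disjoint intervals always are.  With several
normal/disease expression pairs, the reported set is the strict
intersection of the per-pair significant sets — a conservative consensus
that suppresses replicate noise.

## Clustering and ranking

k-means (k = 50 by default; 10 restarts, best inertia, deterministic
given the seed) runs on binary metabolite-incidence feature vectors — one
row per reaction marking which metabolites participate.  Incidence makes
"reactions with similar behaviour cluster together" concrete and
reproducible; signed stoichiometric columns are available via
`signed = TRUE`.  The largest cluster (ties to the lowest index, flagged)
is the working subnetwork.  PageRank runs with tolerance $10^{-10}$ on
the infinity norm from the all-ones start; convergence is guaranteed
because the iteration matrix has spectral radius at most $d < 1$.
Isolated nodes have zero columns (dangling) and settle at $1 - d$, the
literal reading of the scalar recursion; uniform redistribution of
dangling mass is only applied in the normalized variant.  In $z_k = p_k
\times |v_k|$ the flux enters as a magnitude because reversible reactions
carry signed flux while significance is direction-free.  Ties in the final
ranking break lexicographically by reaction id and are flagged.

## Currency metabolites

Cofactors (ATP, H2O, NAD(H), Pi, ...) connect most of a network and are
conventionally excluded from reaction graphs.  Exclusion is OFF by
default here because several of them are legitimate biomarker candidates
in metabolic disease; `exclude_currency = TRUE` enables the standard
filter.

# The synthetic study conditions

`generate_model()` builds parallel branches of 1:1 conversions between a
source metabolite (fed by an import exchange) and a sink (drained by an
export), with extra exchanges draining random intermediates.  Internal
capacities are 10 flux units, exchanges 1000, and roughly 30% of internal
reactions are reversible; each internal reaction carries its own 1–3-gene
AND/OR rule.  Construction guarantees stoichiometric consistency and
returns a nonzero certificate flux, so every generated model is feasible
by construction.

`generate_expression_pair()` draws one log-normal baseline per gene
(meanlog 3, sdlog 0.5) shared by all four replicates, plus independent
replicate noise (sdlog 0.1) — expression differences between conditions
are therefore pure noise except at planted genes, which are shifted down
by `effect` baseline standard deviations (default 4) in the disease
replicates.  The planted reaction is the bottleneck (lowest-expression)
reaction of the branch whose *minimum* baseline expression is highest:
a knockdown is planted where there is activity to lose, because
perturbing an already-silent reaction changes no flux and is invisible to
any flux-based method — a scope statement, not a convenience.

Default problem sizes (20 metabolites, 26 internal + 3 exchange
reactions, 1 planted reaction) keep a full two-pair FPC run around a
second, so calibration properties can be estimated over a 100-seed panel.
What the generator does *not* emulate: correlated transcriptional
programs, platform/batch effects, heavy-tailed expression, many-to-many
gene sharing across reactions, and realistic (non-chain) stoichiometry
such as cofactor coupling.  Passing the planted-recovery and
null-calibration checks therefore demonstrates that the pipeline wiring
is sound and calibrated under honest noise — not that the thresholds
transfer untouched to microarray or RNA-seq data on a human
reconstruction.

# Numerical notes

* LPs are solved by the simplex method (`boot::simplex`) on
  bound-shifted variables; variables pinned by equal bounds are
  eliminated before the tableau is formed.  Tests cross-check optima
  against an independently formulated LP solved by a second
  implementation, and FVA against exhaustive vertex enumeration on small
  models.
* Flux vectors at degenerate optima are solver-dependent; only interval
  endpoints and objective values are contractual.
* Mass balance of every returned solution is verified to
  $\|S v\|_\infty < 10^{-8}$ in the test suite.
* Stoichiometric coefficients are stored as doubles; small-integer cases
  are exact, and equality comparisons use a $10^{-9}$ tolerance.
* All randomness (model generation, expression noise, k-means restarts)
  funnels through explicit seeds; pipeline runs embed their full
  configuration in every report and re-running a manifest reproduces
  byte-identical text outputs.

# Known limitations

* The expression-to-bound coupling (linear in $p$, floor `tighten`) is a
  declared modelling choice; other couplings (e.g. GIMME- or
  iMAT-style discrete switching) are out of scope.
* No statistical test or multiple-testing correction backs the
  significance call; the thresholds are descriptive criteria.
* The unnormalized PageRank variant is not guaranteed monotone under
  edge addition; the test suite records rather than asserts that
  behaviour.
* SBML support covers Level 3 core plus the fbc bounds/gene-association
  subset that genome-scale models in practice use; kinetic laws, units
  and SBML writing are out of scope.
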