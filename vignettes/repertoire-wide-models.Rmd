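---
title: "Repertoire-wide phylogenetic models of B-cell receptor evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repertoire-wide phylogenetic models of B-cell receptor evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

B-cell receptor (BCR) repertoires sequenced from blood contain thousands of
clonal lineages, each descended from one naive ancestor whose unmutated
(germline) sequence can be predicted from V(D)J annotation. Affinity
maturation diversifies each lineage by somatic hypermutation (SHM) and
selection, which makes lineages natural phylogenies — but most of them are
tiny (typically ~92% of lineages contain a single unique sequence), far too
small for per-lineage estimation of substitution-model parameters. At the
same time, SHM violates two staples of standard phylogenetic models: it
targets sequence motifs (context-dependent rates), and it starts far from
compositional equilibrium (nonstationarity), with the germline providing a
known root state (nonreversibility).

`bcrphylo` addresses both problems at once. It implements codon substitution
models tailored to SHM (the HLP19 model, plus the HLP17 and GY94 baselines)
and estimates their parameters *repertoire-wide*: the likelihood that is
maximized is the product over all lineage trees of germline-rooted
phylogenetic likelihoods, with the substitution parameters constrained to be
identical across lineages. Small lineages then contribute what little signal
they have instead of being discarded or producing unusable per-lineage
estimates.

## The substitution model

States are the 61 sense codons (stops excluded), ordered lexicographically
with A < C < G < T. For codons $a \neq b$ differing at exactly one
nucleotide position $p$, the HLP19 instantaneous rate is

$$ q_{ab} \;=\; \kappa^{\,[\mathrm{transition}]}\;
   \omega_r^{\,[\mathrm{nonsynonymous}]}\;
   \Big(1 + \textstyle\sum_m h_m\, e_m(a, p)\Big), $$

and $q_{ab} = 0$ when more than one nucleotide differs. The parameters:

* $\kappa$ — transition/transversion rate ratio (dimensionless, start value
  2, bounds $[0.01, 20]$);
* $\omega_{\mathrm{FWR}}, \omega_{\mathrm{CDR}}$ — nonsynonymous/synonymous
  rate ratios for framework and CDR codon sites (start 0.4, bounds
  $[0.001, 20]$); values below 1 indicate negative selection;
* $h_m$ — additive rate modifiers for the six SHM motifs WRC, GYW, WA, TW,
  SYC, GRS (multiplier $1 + h$, so $h > -1$; $h < 0$ is a cold spot; start
  0, bounds $(-0.999, 20]$). The motifs form reverse-complement pairs with
  mirrored target offsets: WRC targets its C, GYW its G, WA its A, TW its
  T, SYC its C, GRS its G — the canonical AID and polymerase-eta hot spots
  and their cold-spot counterparts;
* $\pi$ — a 61-vector of codon frequencies. HLP19 uses $\pi$ only through
  the context expectation, the normalization and the optional pi-at-root
  mode; HLP17 additionally multiplies each permitted entry by $\pi_b$
  (reducing to GY94 when all $h = 0$).

### Mean-field motif context

$e_m(a, p)$ is the probability that position $p$ of codon $a$ is the
targeted base of an occurrence of motif $m$. Within-codon pattern positions
are read off codon $a$ itself (the pre-mutation state — the process is
Markov in the current codon); pattern positions falling in neighbouring
codons are marginalized assuming independent sites: the flank base at
absolute offset $x$ from the codon start uses the $\pi$-marginal of codon
position $(x \bmod 3) + 1$. Occurrences lying fully within the codon give
exact 0/1 entries. This *mean-field* treatment is what keeps the codon
process site-independent (hence prunable) while still carrying SHM context;
its cost is that cross-boundary hot-spot rates are averages rather than the
true 0/1 mixture, which mildly attenuates strong hot-spot estimates at high
divergence (measured on synthetic data below).

### Nonstationarity: midpoint frequencies

BCR composition starts at the germline and drifts. HLP19 therefore
normalizes its generator with codon frequencies *predicted at the midpoint*
of the phylogeny: starting from the germline codon frequencies, the
generator built under the current iterate propagates them forward by half
the mean root-to-tip divergence, and this fixed point is iterated to
convergence (tolerance $10^{-8}$, cap 100 iterations, renormalizing after
each step). The same midpoint vector feeds the mean-field context. During
fitting it is refreshed every coordinate-ascent round.

### Normalization across regions

FWR and CDR sites share branch lengths within a lineage, so the two region
generators must share one scale: both are divided by the mask-weighted mean
rate $f_{\mathrm{FWR}}\, r_{\mathrm{FWR}} + f_{\mathrm{CDR}}\,
r_{\mathrm{CDR}}$ (weights = fractions of scored sites). Branch lengths are
then expected substitutions per codon averaged over sites, and the
total-rate contrast induced by $\omega_{\mathrm{CDR}} \neq
\omega_{\mathrm{FWR}}$ is preserved rather than silently renormalized away.
The exported `build_q_*()` constructors return individually normalized
matrices (mean rate one under their own frequencies); the joint rescale
happens inside the likelihood engine.

## Likelihood and rooting

Each lineage is scored by Felsenstein pruning on its tree with the germline
as the *known state of the root* — the model is nonreversible and
nonstationary, so the root is identifiable and the germline genuinely
informs it. Codons containing gaps, ambiguity characters or stops are
missing data (all-ones partials); `IGNORED` mask sites (the excised CDR3,
whose germline junction cannot be predicted reliably) are dropped entirely.
Multifurcations are equivalent to zero-length resolutions and are handled
natively. Per-site rescaling keeps partial likelihoods finite for trees of
hundreds of tips.

The alternative `root_mode = "pi"` attaches the germline to the root as a
zero-length tip and sums root partials against the model's codon
frequencies — the reversible-model convention. It exists only to put GY94,
HLP17 and HLP19 log-likelihoods on a comparable footing for AIC
(`compare_models_aic()`); parameter estimation uses the germline-root mode.

The repertoire log-likelihood is the sum over lineages under shared
parameters (lineages mutate independently). Constraining parameters this
way always costs likelihood relative to per-lineage fits — that is the
point: it trades a little bias for a large variance reduction, which the
replicate study in the test suite quantifies.

## Estimation

Topologies come first (mirroring the two-stage protocol): heuristic maximum
parsimony per lineage (`parsimony_topology()`: neighbour-joining start, NNI
rearrangements, germline included as a taxon and made the root; duplicate
sequences collapsed during the search and re-attached as zero-length tips;
ACCTRAN change counts / codon sites as starting lengths), optionally
polished by ML branch lengths under GY94 with shared $\kappa/\omega$
(`gy94_branch_refine()`, with optional NNI acceptance above a $10^{-4}$
log-likelihood gain). Topologies are then held fixed.

`fit_repertoire()` maximizes the repertoire likelihood by coordinate
ascent: (a) bounded L-BFGS-B over the shared parameters on a transformed
scale ($\log \kappa$, $\log \omega$, $\log(1+h)$ — making the $h > -1$
constraint implicit), then (b) per-branch Brent optimization (branch bounds
$[0, 10]$) with all other edges' transition matrices cached, refreshing the
HLP19 midpoint frequencies between rounds, until the log-likelihood
improves by less than `tol` ($10^{-3}$ by default, cap 50 rounds). Because
the inner optimizers are iteration-capped, the best visited state is
retained and the branch lengths are given a final polish under the reported
parameters, so they sit on their conditional optimum (verified against a
dense grid in the tests). Transition matrices come from a complex
eigendecomposition of each 61x61 generator (one decomposition per
generator, two complex products per branch), with a Pade
scaling-and-squaring fallback when the eigenvector matrix is
ill-conditioned; fits are deterministic given the data.

Uncertainty is by profile likelihood (`profile_ci()`): a parameter is fixed
at probe values, everything else (including branch lengths) is re-optimized
warm-started from the MLE, and binary search locates the value where the
profiled log-likelihood has dropped $\chi^2_{0.95,1}/2 = 1.92$ units;
endpoints that run into a parameter bound are reported at the bound and
flagged.

## The synthetic-data generator

`generate_repertoire_fixture()` builds the validation datasets: germlines
drawn as random stop-free codon sequences; a V-region-like mask with two
contiguous CDR blocks covering a quarter of the sites (CDR3 exclusion is
expressed as `IGNORED` labels); clone sizes from a discrete power law with
exponent 4 (about 92% singletons and >99% of clones below five unique
sequences, matching observed blood repertoires) or fixed sizes for designed
experiments; Kingman coalescent topologies with an exponential
germline-to-MRCA trunk (mean 0.5 coalescent units), scaled so the expected
tree length equals `branch_scale` (default 0.3 expected substitutions per
codon — the upper range of tree lengths seen in blood-derived repertoires).

Sequences evolve by exact Gillespie simulation under the *fully
context-dependent* HLP19 process: motif membership is evaluated on the
actual flanking bases and refreshed after every substitution, and
stop-creating changes have rate zero. This is deliberately richer than the
mean-field model that is fitted back — the simulator/estimator mismatch is
part of the validation design, probing whether the approximation biases
estimates. Branch lengths are interpreted in the h = 0 base normalization,
so strong hot spots raise the realized substitution load above the nominal
tree length (about 2.1-fold under the reference parameter set); pass
`tree_length_units = "realized"` to target the realized load instead. Two
consequences worth knowing: fitted tree lengths exceed nominal generator
lengths under `"h0"` (tree-length recovery is therefore tested at h = 0,
where the conventions coincide), and strong hot-spot modifiers are
attenuated by roughly 10–20% at these divergences — visible in the
recovery study, and the reason the recovery tolerance for h is wider than
for the rate ratios.

An alternative generator draws per-base rates from a 5-mer mutability table
(`evolve_s5f()`), with substitution identities from the table's profile and
a documented fallback (averages over matching entries) for 5-mers extending
past the sequence ends. The bundled `synthetic_mutability_table()` is built
from the package's own motif definitions — it reproduces the qualitative
hot/cold ranking of empirical 5-mer SHM models and exists so the
table-driven path needs no external data; it is synthetic, not an
empirically derived table, and `read_mutability_table()` accepts a real one.

What the generator does *not* emulate: V(D)J recombination and junctional
diversity, indels, clonal birth–death dynamics, lineage-to-lineage
parameter heterogeneity, isotype structure, and sequencing error. Passing
recovery tests on these fixtures therefore demonstrates correctness of the
estimation machinery under the model family (plus context-dependence), not
robustness to every artefact of real repertoire data.

## Problem sizes used by the test suite

The full recovery experiment fits 50 lineages x 6 tips x 100 codons (seed
1), the same design the acceptance script reruns. The
repertoire-wide-versus-mean-individual replicate study runs 5 replicates of
12 lineages x 5 tips x 60 codons — a reduced version of the same design,
chosen so the whole suite stays fast; the variance/MSE ordering it checks
is insensitive to this scale. Model-comparison fits reuse the seed-1
repertoire with a looser convergence tolerance (0.05), which is far below
the hundreds of AIC units separating the models.

## Known limitations

* The mean-field context is an approximation; with very strong hot spots
  and long branches, hot-spot $h$ estimates attenuate (see above). Fits to
  repertoires with mean tree lengths far beyond ~0.5 substitutions per
  codon should be interpreted with this in mind.
* HLP17 here uses empirical codon frequencies rather than ML-estimated
  ones (ML estimation would more than double the parameter count); its
  free-parameter count in AIC comparisons reflects that choice.
* Repertoire-wide estimates mask lineage-to-lineage variation by
  construction and should not be read as statements about individual
  lineages; per-lineage fits are available (`fit_individual_lineages()`)
  but overfit small clones (the pathological all-nonsynonymous case is
  exercised in the tests).
* Full ML topology search is out of scope; topologies come from parsimony
  (plus optional GY94 NNI refinement) and are then fixed.
* One profile-CI probe re-optimizes every other parameter; intervals for
  several parameters on large repertoires are correspondingly expensive.
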