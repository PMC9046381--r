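---
title: "Quantifying community assembly processes with comassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying community assembly processes with comassembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comassembly)
options(comassembly.verbose = FALSE)
```

## The question the package answers

Host-associated microbial communities are assembled by a mixture of
deterministic processes (environmental and host filtering — *selection*)
and stochastic ones (*dispersal* and ecological *drift*). `comassembly`
takes the three observational objects of an amplicon survey — an OTU count
table (samples × taxa), a rooted phylogeny over the taxa, and per-sample
metadata (host taxonomy, coordinates, climate) — and quantifies how much
each process contributes to the observed turnover, using two complementary
model families:

1. the **Sloan neutral community model**, which asks how well occurrence
   frequencies are explained by metacommunity abundance alone under drift
   plus immigration; and
2. **pairwise null models** (βNTI and Raup–Crick), which classify every
   pair of communities into one of five processes: heterogeneous
   selection, homogeneous selection, dispersal limitation, homogenizing
   dispersal, and drift.

Around this core sit the descriptive layers such a survey needs: alpha
diversity, Bray–Curtis/PCoA/perMANOVA, thresholded Spearman co-occurrence
networks with full topology metrics, distance-decay regression, Mantel
tests, and two-block variance partitioning.

## The neutral model

For an OTU with metacommunity relative abundance $p$, a local community of
$N$ individuals renewed by death–replacement with immigration probability
$m$ has a stationary abundance distribution approximated by
$\mathrm{Beta}(Nmp,\; Nm(1-p))$. The probability of detecting the OTU
above a detection limit $d$ — its predicted occurrence frequency — is

$$\hat f(p) = 1 - I_d\!\left(Nmp,\ Nm(1-p)\right),$$

where $I_d$ is the regularized incomplete Beta function
(`predict_occurrence()`). `fit_sloan_model()` estimates $m$ by bounded
Levenberg–Marquardt least squares of observed against predicted
frequencies, reports $R^2$ about the mean observed frequency (negative
values allowed: the model can be worse than the mean), and classifies each
OTU against a Wilson score envelope at the chosen confidence level.

Defaults and their rationale:

* **Detection limit** `d = 1/N` (one read): the smallest relative
  abundance observable at the average library size.
* **`N` = mean library size**, rounded. If depths vary strongly, rarefy
  first (`rarefy_counts()`).
* **Wilson intervals** rather than Clopper–Pearson: matches the binomial
  confidence machinery conventionally used with this fit, and is
  closed-form (`wilson_interval()`).

One bias is worth knowing about. The fit uses Sloan's diffusion
approximation, whose immigration parameter is $Nm$; the exact stationary
parameter of the death–replacement (Moran-with-migration) process is
$m(N-1)/(1-m)$. The estimator therefore recovers approximately
$m/(1-m)$ rather than $m$: negligible at small $m$, a factor of two at
$m = 0.5$. The parameter-recovery tests bound the error at a factor of
two across $m \in \{0.05, 0.2, 0.5\}$, which is the resolution at which
such migration rates are ecologically interpreted.

## Phylogenetic and taxonomic null models

**βMNTD** (`beta_mntd()`) is, for each community pair, the
abundance-weighted mean patristic distance from each taxon to its nearest
relative in the other community, averaged over both directions. We use the
abundance-weighted variant by default: relative abundances are central to
every other stage of the pipeline, and the weighted form is standard in
the βNTI process framework. **βNTI** (`beta_nti()`) standardizes the
observed βMNTD against a null distribution obtained by shuffling taxon
labels across all tree tips:

$$\beta\mathrm{NTI}(k,l) = \frac{\beta\mathrm{MNTD}_{obs}(k,l) -
\overline{\beta\mathrm{MNTD}}_{null}(k,l)}{\mathrm{sd}\,
\beta\mathrm{MNTD}_{null}(k,l)}.$$

One shuffle per replicate is shared across all pairs. This preserves the
cross-pair correlation structure, and makes the matrix exactly symmetric.
Pairs with zero null standard deviation (possible on a star phylogeny, or
when two samples contain exactly the same taxon set so every shuffle
yields zero) are reported `NaN` and excluded from downstream fractions —
never coerced to zero.

**Raup–Crick** (`raup_crick_bray()`) standardizes Bray–Curtis
dissimilarity against a null that preserves each sample's richness and
read total: member taxa are drawn weighted by occurrence frequency, each
member receives one read, and the remainder is allocated multinomially by
overall relative abundance. With `RC_{raw}` the fraction of null values
below the observed (ties at half weight), `RC = 2(RC_{raw} - 0.5) \in
[-1, 1]`. One null community per sample per replicate is shared across
pairs, mirroring the shared-shuffle design of βNTI; the marginal null
distribution per pair is identical to independent per-pair draws.

**Process partition** (`partition_processes()`), per pair, with strict
inequalities throughout:

| condition | process |
|---|---|
| βNTI > 2 | heterogeneous selection |
| βNTI < −2 | homogeneous selection |
| \|βNTI\| ≤ 2 and RC > 0.95 | dispersal limitation |
| \|βNTI\| ≤ 2 and RC < −0.95 | homogenizing dispersal |
| \|βNTI\| ≤ 2 and \|RC\| ≤ 0.95 | drift |

Boundary semantics are frozen by tests: βNTI exactly ±2 is stochastic; RC
exactly ±0.95 falls to drift.

## The synthetic-data generator

Real surveys of this kind rest on tens of millions of reads; the
generator (`simulate_*`) provides tables whose generating process is
*known*, so every inference stage can be validated end to end.

* `simulate_neutral_communities()` runs the Hubbell death–replacement
  scheme (in compiled code): each death is replaced from the
  metacommunity with probability `m`, otherwise by a local copy. This is
  the generative model the Sloan fit assumes, making parameter recovery a
  fair test rather than a tautology. The default of 10 community
  turnovers erases the initial condition at desk scale; recovery tests
  near small `m` use 60, since relaxation to stationarity takes on the
  order of $1/m$ turnovers and the initial condition (a multinomial draw
  from the metacommunity) is the $m=1$ stationary state.
* `simulate_selected_communities()` evolves a Brownian trait on the same
  tree used for βMNTD and filters sampling weights through a Gaussian
  kernel around each sample's environment. Evolving the trait on that
  tree is essential: βNTI only responds to selection on phylogenetically
  conserved traits.
* `simulate_metadata()` produces clustered coordinates with
  latitude-linked climate, so environmental distance correlates with
  geographic distance, as the Mantel and distance-decay stages assume.

What the generator does **not** emulate: sequencing error, chimeras,
compositional zeros from library-size variation beyond multinomial
sampling, spatially explicit stepping-stone dispersal, or within-host
dynamics. Passing calibration on these simulations shows the statistics
are computed and standardized correctly — not that any particular real
dataset satisfies the models' assumptions.

### Calibration regimes, and a subtlety about Raup–Crick

Under a *drift-dominated* neutral regime (moderate `m`, enough turnovers
for communities to drift apart, richness well below the taxon pool), both
null models calibrate as designed: ≥90% of pairs fall in |βNTI| < 2 and
|RC| < 0.95. Under the *mass-effects* extreme (`m = 1`, every death
replaced from the metacommunity) communities are far **more** similar
than the occurrence-randomized null expects, and RC correctly pins at −1:
the framework classifies the regime as homogenizing dispersal, which is
exactly what `m = 1` is. The acceptance suite asserts both behaviours.
The flip side — strong drift at very small `m` — pushes pairs toward
RC = +1 (dispersal limitation), again as the framework intends.

## Numerical and design choices

* **Shannon index** in natural logs; richness as count of non-zero taxa.
* **Three normalizations for three purposes**, mirroring standard
  practice: rarefaction for alpha diversity, within-sample relative
  abundance for Bray–Curtis and the neutral fit, TMM for distance-decay
  community matrices.
* **PCoA**: classical scaling; negative eigenvalues are excluded from
  `proportion_explained` and no Lingoes/Cailliez correction is applied —
  the simplest defensible convention, visible in the output.
* **perMANOVA** permutes labels freely (no strata).
* **Network rule**: |ρ| > 0.6 *in magnitude* and BH-FDR < 0.05. The
  magnitude reading is forced by the presence of negative edges in the
  reference topology panel (`stonefly_network_table()`). Clustering is
  global transitivity; path length and diameter are computed over
  reachable pairs within components, so fragmented graphs report finite
  values; centralizations are Freeman's, normalized by their theoretical
  maxima. Vertex counts retain isolated post-filter taxa by default.
* **Spearman p-values**: t-approximation for n ≥ 8; exact enumeration of
  all rank permutations below.
* **Distance-decay** reports a Mantel-style permutation p-value (pairs
  sharing a sample are not independent) alongside the naive OLS one.
* **Haversine** uses the mean Earth radius 6371.0 km.
* **Variance partitioning** uses db-RDA with Ezekiel-adjusted $R^2$;
  negative fractions are reported as-is with an optional clamp.
* **Determinism**: every stochastic stage takes an explicit seed and
  restores the caller's RNG state; refitting with the same inputs is
  bit-identical.

## Problem sizes used in validation

The packaged tests run at deliberately modest scales chosen to make the
statistical assertions sharp: parameter recovery at 300 samples × 1000
reads × 300 taxa; null-model calibration at 12–24 samples over pools of
120–500 taxa with 199 null replicates; type-I-error calibration of
perMANOVA and Mantel over 200 seeded replicates at n = 15–20. These sizes
were picked so that Monte-Carlo error is small relative to the tested
margins.

## Known limitations

* Only the product $Nm$ is identified by the occurrence-frequency fit;
  $m$ is reported by dividing out the mean library size, and inherits the
  $m/(1-m)$ diffusion bias described above.
* βNTI requires phylogenetic signal in the selective environment; with
  phylogenetically random traits it has no power, and the partition will
  attribute real selection to drift.
* The Raup–Crick null conditions on observed richness and occupancy; it
  cannot distinguish processes that leave those margins unchanged.
* The process partition is pairwise and does not quantify
  diversification, nor attribute processes to individual taxa.
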