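---
title: "Methods: weighted co-expression networks, trait association, and single-marker causal orienting"
author: "coexnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted co-expression networks, trait association, and single-marker causal orienting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexnet)
```

# The analysis this package implements

`coexnet` implements a liver-style systems-genetics workflow for an F2
intercross: build a weighted gene co-expression network from probe-level
log2 expression, detect modules of co-expressed genes, ask which module is
associated with a quantitative disease trait (e.g. atherosclerotic lesion
size), test modules for gene-set/signature enrichment, and finally use a
genetic marker as a causal anchor to orient the edge between a candidate
gene and the trait with structural equation models. Every stage can be
exercised end to end on simulated crosses with known ground truth, which is
how the package validates itself.

# Synthetic F2 crosses

`simulate_f2_genotypes()` draws marker codes 0/1/2 with the Mendelian F2
frequencies 1/4, 1/2, 1/4 per animal and marker.
`simulate_network_expression()` builds the expression study around latent
module factors rather than an explicit genes-by-genes covariance matrix:
each module has one standard-normal factor $F_m$ per sample and member
genes

$$x = \sqrt{w}\,F_m + \sigma\sqrt{1-w}\,\varepsilon,$$

so with the default noise scale $\sigma = 1$ the expected pairwise
correlation inside a module is exactly $w$ (`within_module_cor`) and memory
stays linear in the gene count. The factor itself is the population-level
eigengene, giving a clean ground truth for the PCA summary below.

The causal chain is planted in the first module: its first gene is

$$G = \sqrt{w}\,F_1 + a_1 M + \sqrt{1-w-a_1^2}\,\varepsilon,$$

with $M$ the standardized additive marker code, and the trait is
$T = a_2\,\mathrm{std}(G) + \sqrt{1-a_2^2}\,\varepsilon$. This keeps the
chain gene's correlation with its module peers at $w$ (so it clusters with
its module), makes $\mathrm{cor}(M,T) \approx a_1 a_2$, and makes the
marker-trait partial correlation given $G$ vanish — the signature the SEM
stage is designed to detect. The construction requires $a_1^2 + w < 1$,
which the configuration validates. Reactive genes are drawn downstream of
the trait, $b\,\mathrm{std}(T) + \sqrt{1-b^2}\,\varepsilon$, and background
genes are independent noise. Each gene receives a baseline intensity near 8
to mimic log2 microarray data; correlations are unaffected.

Defaults describe the study design the package targets: 90 animals, five
modules of 500/300/200/150/100 genes (real module sizes in such data span
roughly 100-900 genes), within-module correlation 0.7, 750 background and
20 reactive genes, and standardized chain paths $a_1 = a_2 = 0.5$ —
moderate effects consistent with the chain strengths used throughout the
package's recovery simulations. The generator does not model microarray
noise structure, batch effects, linkage maps with recombination, or sex:
passing tests demonstrate recovery of the planted statistical structure,
not robustness to those real-data features.

# Network construction

Pairwise gene correlations use Pearson $r$ with pairwise-complete
observations; rows with zero variance are excluded with a warning, and
pairs sharing fewer than 3 finite observations get $r = 0$ (robustness
without imputation — how missing array values were handled upstream is a
choice this package makes explicitly). The adjacency is the classical
unsigned soft threshold

$$a_{ij} = |r_{ij}|^\beta, \qquad \beta = 8 \text{ by default},$$

so anti-correlated genes connect as strongly as correlated ones, and
raising $\beta$ suppresses weak edges relative to strong ones.
Connectivity is $k_i = \sum_{j \ne i} a_{ij}$.

`pick_soft_threshold()` implements the scale-free topology criterion: for
each candidate power, $\log_{10} k$ is split into 10 equal-occupancy bins,
the empirical density of $k$ per bin (count divided by bin width on the $k$
scale) is regressed on $\log_{10}(\bar k)$ in log-log space, and the fit is
summarised as the signed index $-\mathrm{sign}(\text{slope})\,R^2$, which
is positive when frequency falls with connectivity as a power law demands.
The chosen power is the smallest with signed $R^2 \ge 0.85$, falling back
to the maximiser. The pipeline fixes $\beta = 8$ by default but always
records the scan; the binning scheme is exposed via `n_bins`. The density
must be measured per unit of $k$, not per log-bin — measuring per log-bin
tilts the regression by one power of $k$ and can even flip the slope's
sign on modular data.

The topological overlap matrix is

$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
 {\min(k_i, k_j) + 1 - a_{ij}},
 \qquad \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$

with unit diagonal; $1 - \mathrm{TOM}$ is the clustering dissimilarity.
The implementation is a matrix-product form (zeroed diagonal makes
$A^2$ equal the $\ell$ sums exactly); tests verify it against a literal
triple-loop oracle to $10^{-12}$ on hundreds of random networks. Note that
unsigned $\beta = 8$ TOM values are numerically small — two genes
correlated at 0.7 inside a large module overlap at roughly 0.06 — which is
why the graph-export weight cutoff defaults to 0.02.

# Module detection

Genes are clustered by average-linkage hierarchical clustering of the TOM
dissimilarity (the de facto standard linkage for this measure). Branch
cutting is a two-stage procedure controlled by `cut_height` (default 0.97)
and `min_module_size` (default 50):

1. the tree is cut statically at `cut_height`; branches with at least
   `min_module_size` leaves become modules, everything else is
   provisionally grey (unassigned);
2. each grey gene is assigned to the module minimising its mean
   dissimilarity to module members, but only if that mean is below both
   its mean dissimilarity to all non-member genes and `cut_height`.

This is a deliberate simplification of the full Dynamic Hybrid branch-cut
algorithm (no core-scattering statistics, no cluster-merging criteria):
the workflow it reimplements specifies only the algorithm family, the cut
height and the minimum size, and on factor-model data the two-stage cut
recovers planted modules with adjusted Rand index at or near 1. Stage 2
can be disabled (`hybrid_assign = FALSE`) to study the stage-1-only
labelling. Modules are named by size rank with the conventional colour
sequence (turquoise, blue, brown, ...); grey is reserved for unassigned
genes.

The module eigengene is the first principal component of the module's
standardized member expression, scaled to unit variance, with its sign
fixed so it correlates positively with the module's mean expression
profile (PCA signs are otherwise arbitrary). `variance_explained` is the
first singular value's share of total variance; constant genes are dropped
from the decomposition with a warning. kME — module membership — is the
correlation of each gene with each eigengene, and hub genes are the
highest-kME members of their own module.

# Trait association and the permutation threshold

Gene significance (GS) is the absolute Pearson correlation between a
gene's expression and the trait; module significance (MS) is the plain
mean GS over member genes. The significance threshold for MS is built by
permutation: draw `set_size` GS values (default 400) without replacement
from the observed GS vector, record the mean, repeat `n_sets` times
(default 10000), and take the 0.95 one-sided quantile. Sampling without
replacement matches a gene-label permutation reading of the construction;
`set_size` is configurable because real module sizes vary widely.

One property of this procedure deserves emphasis: its null assumes module
GS values are exchangeable with the pool. For truly uncorrelated genes the
call is exactly calibrated (the package measures type-I error
$\approx 0.05$ on such nulls), but genes inside a correlated module have
correlated GS values, which inflates the variance of their mean by a
factor of roughly $1 + (n_\text{module}-1)\bar\rho_{GS}$ relative to the
permutation null. Even weak within-module correlation therefore makes the
call anti-conservative for null modules — a limitation of the procedure
itself, visible in demonstrations as an occasional false module call, and
the reason the package's calibration checks use independent-gene nulls.

# Gene-set enrichment

Module-versus-signature overlap is tested with the one-sided upper-tail
hypergeometric (Fisher) test; fold enrichment is $(k/m)/(K/N)$ with $k$
the overlap, $m$ the set size in background, $K$ the module size, $N$ the
background size. Identifiers are upper-cased before matching and set
members outside the background are ignored. The background defaults to
everything that entered the network (assigned plus grey), collapsed to one
probe per gene symbol — keeping the probe with the highest connectivity —
so contingency tables never double-count a gene. FDR is Benjamini-Hochberg
across all (module, set) tests. For clusters of annotation terms the
package also provides the cluster enrichment score,
$-\log_{10}$ of the geometric mean of the terms' unadjusted p-values.
Depletion testing and term-database hosting are out of scope.

# Single-marker causal orienting

For a candidate gene $G$, marker $M$ and trait $T$ (all standardized, the
marker from its additive 0/1/2 codes), three structural equation models
are compared:

* causal: $M \to G \to T$, implying $\rho(M,T \mid G) = 0$;
* reactive: $M \to T \to G$, implying $\rho(M,G \mid T) = 0$;
* independent: $G \leftarrow M \to T$, implying $\rho(G,T \mid M) = 0$.

Each is a recursive path model imposing exactly one vanishing partial
correlation, so its Gaussian ML solution reproduces the sample correlation
matrix except for the non-adjacent entry, which becomes the product of the
two adjacent correlations. The fit statistic is
$\chi^2 = (n-1) F_{ML}$ with
$F_{ML} = \log\det\hat\Sigma - \log\det S +
\mathrm{tr}(S\hat\Sigma^{-1}) - 3$ and one degree of freedom;
algebraically this equals the likelihood-ratio form
$-(n-1)\log(1-\hat\rho_\text{partial}^2)$, which the test suite uses as an
independent oracle. Model "probabilities" are the $\chi^2_1$
goodness-of-fit p-values (the network-edge-orienting convention — larger
means the constraint is consistent with the data), not posterior
probabilities. The orienting score is

$$\mathrm{LEO} = \log_{10} p_\text{causal} -
  \log_{10} \max(p_\text{reactive}, p_\text{independent}),$$

so $\mathrm{LEO} > 0.3$ means the causal model fits about twice as well as
the best alternative ($10^{0.3} \approx 2$). Fit quality is additionally
gated by $\mathrm{RMSEA} = \sqrt{\max((\chi^2 - 1)/(n-1),\,0)} \le 0.05$.
Exact ties between the causal and the best alternative p-value give
LEO = 0 and an "ambiguous" best model. Dominance genotype codings and
multi-marker or multi-gene model variants are out of scope.

`screen_candidates()` applies the fit to every gene of a module against a
common marker and outcome — the clinical trait, or a designated gene's
expression when asking which genes sit downstream of a candidate (the
outcome gene is excluded from its own screen). Genes whose fit fails (for
example a singular covariance) stay in the table with `NA` statistics.

A statistical caveat worth knowing when reading single runs: under the
*true* causal model the $\chi^2$ statistic is still a $\chi^2_1$ draw, so
the RMSEA gate $\chi^2 \le 1 + 0.05^2 (n-1)$ passes with probability only
about 0.81 at $n = 300$, rising to about 0.99 at $n = 2000$. Rate
statements (e.g. "the causal gene exceeds LEO 0.3 in at least 80% of
replicates") are therefore the meaningful guarantees at intercross sample
sizes; this is also why the packaged end-to-end demonstration simulates a
large cross (n = 2000), so a single fixed-seed run reflects the method
rather than one $\chi^2$ draw.

# Cross-dataset validation

`map_by_entrez()` transfers module labels to an external dataset by Entrez
id; ids mapping to more than one module are dropped as conflicts and
unmatched probes counted. `module_group_difference()` computes per-probe
differences of group mean log2 values (group 2 minus group 1) and
summarises each module by the mean difference; significance is a
two-sided two-sample t-test of module probes' differences against
background (grey) probes' differences — the external data's own grouping
names no test, so this choice is the package's and is not claimed to match
any particular published figure. `paired_gene_difference()` handles paired
designs (one diseased and one intact sample per subject) with per-gene
paired t-tests; zero-variance differences are flagged degenerate rather
than tested. External matrices are expected pre-normalized on the log2
scale; normalization is upstream of this package.

# Numerical and design choices

* Unsigned network: with an even power, raising Pearson $r$ to the
  $\beta$-th power equals $|r|^\beta$; unsigned is the classical default
  and is documented as such.
* Equal-occupancy connectivity binning with per-$k$ densities for the
  scale-free index; degenerate scans (zero connectivity variance) are
  marked invalid rather than scored.
* Eigengene sign convention: positive correlation with the module mean
  profile; negating all member genes flips the eigengene exactly.
* Permutation, simulation and pipeline runs are seeded through explicit
  `seed` arguments; rerunning a pipeline with the same configuration
  produces byte-identical result tables (numeric columns are formatted
  with a fixed `%.10g`).
* Module labels are invariant to gene input order up to colour renaming;
  ties in module size are broken by branch id.
* The demo fixture and the validation suite run at deliberately modest
  problem sizes — about 1000-2000 genes, crosses of 90 animals for
  network/module/trait checks, chains of 300 for orientation-rate checks,
  and the large n = 2000 cross for the single-seed end-to-end
  demonstration — chosen so planted structure is comfortably above the
  detection limits the checks assert.

# Known limitations

* The branch cut is the two-stage simplification described above, not the
  full Dynamic Hybrid algorithm; on weakly separated or nested modules the
  two can differ.
* The MS permutation call is anti-conservative for correlated null
  modules (see above).
* Signed and signed-hybrid networks, robust correlations (bicor,
  Spearman), block-wise construction for very large probe sets, eigengene
  merging, and multi-marker edge orienting are not implemented.
* The generator's independence assumptions (no batch structure, no
  linkage) make recovery easier than on real arrays; results on real data
  depend on preprocessing quality in ways the tests cannot certify.

# A worked run

```{r, eval = FALSE}
dir <- tempfile()
demo <- prepare_demo_study(file.path(dir, "inputs"))
run <- run_pipeline(demo$config, file.path(dir, "out"))
print(run)
hub_genes(run$modules$kme, run$modules$labels,
          run$trait_association$significant_modules[1])
```

The demo study plants four modules, ties the first to the trait through a
marker-anchored causal gene, and hides a signature inside it; the run
detects the modules, calls exactly the planted module trait-significant,
ranks the planted signature first by FDR, and flags exactly the planted
causal mediator in the SEM screen.
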