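---
title: "Joint analysis of GWAS summary statistics with a hidden Markov random field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint analysis of GWAS summary statistics with a hidden Markov random field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiograph)
```

## The model

Genome-wide association studies of related phenotypes share genetic signal:
a variant that raises risk for one autoimmune disease often shifts the
association statistics of another. pleiograph integrates such studies at the
summary-statistic level. The input is a $T \times n$ matrix of association
p-values $p_{it}$ (SNP $t$, phenotype $i$), probit-transformed to scores
$y_{it} = \Phi^{-1}(1 - p_{it})$, so that null p-values (uniform under the
theoretical null) become standard-normal scores.

Each entry carries a latent binary indicator $e_{it}$ of true association.
Given the indicator, scores are emitted from a two-group mixture

$$ y_{it} \mid e_{it} \sim e_{it}\,\mathrm{LN}(\mu_i, \sigma_i^2) +
(1 - e_{it})\,N(0, 1), $$

where $\mathrm{LN}$ is the log-normal density with mean
$e^{\mu_i + \sigma_i^2/2}$ on the score scale. The log-normal support
(positive reals) encodes the assumption that associated SNPs essentially
never have p-values above one half; any score $y \le 0$ receives zero
association probability, exactly, rather than a numerical floor.

Across phenotypes, the indicator vector $\mathbf e_t = (e_{1t}, \dots,
e_{nt})$ of each SNP follows an auto-logistic Markov random field on an
unknown graph $G$:

$$ p(\mathbf e_t \mid \alpha, \beta, G) \propto
\exp\Big( \sum_i \alpha_i e_{it} + \sum_{i \sim j} \beta_{ij}\, e_{it} e_{jt}
\Big), $$

with baseline propensities $\alpha_i$ (negative: association is rare) and
nonnegative couplings $\beta_{ij}$ on the edges of $G$. An edge means the
two phenotypes are conditionally dependent given the others — the graph is
a parsimonious map of pleiotropy. The normalizing constant is computed by
exact enumeration of the $2^n$ joint states; at $n = 12$ that is 4,096
configurations, and the implementation caps $n$ at 20.

Priors are conjugate where possible: $\mu_i \sim N(\theta_\mu, \tau_\mu^2)$,
$\sigma_i^2 \sim \mathrm{IG}(a_\sigma, b_\sigma)$, $\alpha_i \sim
N(\theta_\alpha, \tau_\alpha^2)$, and a spike-and-slab on couplings —
$\beta_{ij} \sim \Gamma(a_\beta, b_\beta)$ when the edge is present, a point
mass at zero otherwise (represented structurally by the adjacency, not by a
numeric sentinel). The graph prior $p(G) \propto 1/\max(|E|, 1)$ favors
sparse graphs; the $\max$ regularizes the empty graph, which the plain
$1/|E|$ form leaves undefined, so that the empty graph stays reachable.
Defaults ($\theta_\mu = \theta_\alpha = 0$, $\tau^2 = 10^4$, $a_\sigma =
b_\sigma = 0.5$, $a_\beta = 4$, $b_\beta = 2$) are weakly informative; the
coupling prior has mean 2 and variance 1, keeping couplings on present
edges away from zero.

## Posterior computation

`fit_hmrf()` runs a Metropolis-Hastings-within-Gibbs sampler. One sweep:

1. **Field refresh.** Every indicator $e_{it}$ is redrawn from its Bernoulli
   full conditional, logistic in $\alpha_i + \sum_{j \sim i} \beta_{ij}
   e_{jt} + \log \mathrm{LR}(y_{it})$, in a systematic scan; SNPs are
   conditionally independent and the hot loop is compiled code. In
   addition, a rotating third of the SNPs (default `block_stride = 3`) is
   refreshed *blockwise*: the whole $n$-vector $\mathbf e_t$ is redrawn from
   its exact conditional over all $2^n$ states.
2. **Signal parameters.** Conjugate draws of $\mu_i$ (precision-weighted
   normal) and $\sigma_i^2$ (inverse-gamma) from $\{\log y_{it} : e_{it} =
   1\}$; pure prior draws when the set is empty.
3. **Baselines and couplings.** Random-walk Metropolis for each $\alpha_i$
   (scale 0.1) and, on the log scale, for each present coupling
   (scale 0.2); each acceptance ratio uses the exact normalizer.
4. **Graph moves.** Reversible-jump birth/death proposals on uniformly
   chosen phenotype pairs, by default $n(n-1)/2$ proposals per sweep. A
   birth draws the new coupling from its $\Gamma(a_\beta, b_\beta)$ prior,
   so the proposal and prior densities cancel and the acceptance ratio
   reduces to the likelihood term plus the graph-prior ratio.

Two composition choices deserve comment, because naive schedules mix
poorly. First, the blockwise field refresh: with strong couplings the
componentwise scan crosses configurations like $(0,0) \to (1,1)$ through
low-probability intermediates, and — more importantly — the sampled field
"remembers" a currently present edge (its co-association counts reflect the
coupling), which makes edge deaths look locally unattractive and lets
spurious edges linger for thousands of sweeps. Blockwise refreshment breaks
that memory at a fixed extra cost of one $2^n$-state draw per SNP every
`block_stride` sweeps. Second, proposing every pair once per sweep (rather
than a single pair) keeps graph-move frequency from being the mixing
bottleneck. Both kernels leave the posterior invariant individually, so any
schedule of them is valid; both are configurable.

Initialization is data-driven: the field starts at $e_{it} = 1\{p_{it} <
0.01,\ y_{it} > 0\}$, signal parameters at moments of $\log y$ over the
seeded set, baselines at the (clamped) logit of the seeded fraction, and
the graph empty. The liberal 0.01 seed matters for weak-signal data: a
genome-wide-significance cut would seed an empty component whose
prior-drawn parameters ($\tau^2 = 10^4$) make early likelihood ratios
useless, and burn-in lengthens substantially.

All randomness flows from one integer seed through R's global RNG; a fit is
reproducible bitwise from (data, configuration, seed). The full $T \times n$
field draws are not stored by default — only running means of $e_{it}$ and
of the pairwise products $e_{it} e_{jt}$, which are exactly what inference
consumes; `store_field = TRUE` keeps the draws on small problems.

## Inference outputs

* **Graph.** `summarize_edges()` reports, per pair, the posterior inclusion
  probability $p(E(i,j) \mid Y)$ and coupling summaries computed two ways:
  marginal over all draws (absent-edge draws contribute zeros — the spike)
  and conditional on presence. Because couplings are positive exactly when
  the edge is present, the exceedance probability $p(\beta_{ij} > 0 \mid Y)$
  numerically equals the inclusion probability; both are reported so the
  two published decision rules can be compared. `declare_edges()` selects
  edges with inclusion $> 0.5$ and exceedance $> 0.95$ (default), or, by
  flag, inclusion $> 0.5$ with the marginal 95% interval excluding zero.
  Which variant the original analyses used on the marginal-versus-
  conditional question is not documented; we expose both rather than guess.
* **Association mapping.** `local_fdr()` returns $f_{it} = 1 - p(e_{it} = 1
  \mid Y)$ per phenotype, or $f_{ijt} = 1 - p(e_{it} = 1, e_{jt} = 1 \mid
  Y)$ per pair. `control_fdr()` applies the direct posterior probability
  rule: sort fdr values ascending (ties broken by input order, so outputs
  are deterministic), call the largest prefix whose running mean stays at
  or below the nominal level $\tau$. The realized global FDR estimate over
  the called set is then $\le \tau$ by construction, and call sets are
  nested in $\tau$.
* **Diagnostics.** Acceptance rates per move type, a Geweke-style z-score
  on the log-posterior trace (first 10% vs last 50%, spectral variances
  from an AR fit), and edge-inclusion frequencies.

The independence baseline (`independent = TRUE`) fixes the empty graph and
skips coupling and graph moves — the same two-group model fit separately
per phenotype, useful as the comparison point for what pleiotropy buys.

## The synthetic-data generator

`benchmark_scenario()` encodes a 7-phenotype study: a tightly linked group
P1–P2–P3 ($\beta_{12} = 4.0$, $\beta_{13} = 1.8$, $\beta_{23} = 2.3$), a
weakly linked chain P3–P4–P5 ($\beta_{34} = 2.5$, $\beta_{45} = 5.0$),
two isolated negative controls P6, P7, baselines $\alpha = (-4.7, -3.0,
-5.5, -4.8, -3.6, -2.5, -3.5)$, and 20,000 SNPs. `simulate_dataset()` draws
each SNP's indicator vector by 1,000 Gibbs sweeps of the MRF (validated
against exact enumeration of the stationary law), then emits scores — and
this is deliberate — from a *normal* $N(\mu_i, \sigma_i^2)$ signal
distribution with $\mu = (1.1, 1.0, 1.2, 1.2, 1.3, 1.1, 1.3)$ and $\sigma =
(0.4, 0.3, 0.35, 0.3, 0.45, 0.4, 0.3)$, not from the log-normal family the
model fits. The signal strengths are weak on purpose, mimicking the
p-value distributions of real GWAS.

What the generator does *not* emulate: linkage disequilibrium (variants are
independent; users of real data should LD-prune first), overlapping study
subjects (which can induce non-genetic correlation between phenotypes), and
minor-allele-frequency structure. Passing tests on these data therefore
demonstrate correctness of the model and sampler under idealized
independence, not robustness to those real-data features.

`lognormal_signal = TRUE` switches the generator to the fitted family (the
log-normal with matching score-scale mean and SD) for exact model-match
experiments.

## What the benchmark does and does not recover

The emission mismatch has consequences that users of the benchmark should
know about. Because the small fraction of signal mass the normal generator
places at nonpositive scores is unassociable under the log-normal emission,
and because weakly separated signals are partially absorbed into the null
component, the fitted mixture need not center on the generating values:
baselines attenuate, strong couplings shrink, and within a strongly coupled
triangle the likelihood can nearly re-express one edge's weight through
another, so the graph posterior spreads over neighboring topologies rather
than concentrating on the generating one. The model is behaving correctly
given the data it sees; this is a property of fitting a log-normal signal
family to normal-generated scores at weak signal strength. The generator's
`lognormal_signal = TRUE` switch exists precisely to separate the two
effects: under the matched generator the same sampler recovers the
generating configuration. Relatedly, signal parameters are compared on the
score scale — `signal_mean()` ($e^{\mu + \sigma^2/2}$) and `signal_sd()` —
the only scale on which normal-generated and log-normal-fitted parameters
are comparable. FDR control is the most robust output under the mismatch:
calling is conservative (often empty at $\tau = 0.1$ for the weakest
phenotypes), and the realized false discovery proportion stays at or below
the nominal level whenever calls are made.

## Numerical choices

* P-values of exactly 0 or 1 are clamped to $[10^{-12}, 1 - 10^{-12}]$
  (configurable): the probit transform diverges at the endpoints, and
  $10^{-12}$ preserves the ordering of genome-wide-significant hits without
  overflow. Rows with missing cells are dropped, not imputed — the model
  has no missing-data mechanism.
* The exact normalizer uses a single log-sum-exp over cached state
  enumerations; normalizer values are carried across Metropolis updates so
  each proposal costs one evaluation.
* Problem sizes in the test suite: the simulation-study checks run the
  full 20,000-SNP benchmark with 2,000 burn-in + 8,000 main iterations —
  about one-fifth of the iteration budget used for the headline analyses —
  which keeps each fit around three minutes while leaving Monte-Carlo
  error well inside the tolerances asserted.
* Degenerate inputs: a SNP with all scores nonpositive has association
  probability zero for every phenotype (local fdr exactly 1); an empty
  association set draws signal parameters from their priors; `T = 0`
  reduces every kernel to prior sampling (tested).

## Limitations

Beyond the generator's idealizations listed above: the coupling prior
restricts $\beta > 0$, so antagonistic pleiotropy is representable only as
edge absence; the exact-enumeration normalizer caps the analysis at 20
phenotypes; and the block field refresh, while a large improvement, does
not make the graph posterior mix instantly — very strongly coupled triangles
still show mode-switching between nearly likelihood-equivalent topologies,
which is visible (honestly) as intermediate edge probabilities rather than
hidden by early stopping.
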