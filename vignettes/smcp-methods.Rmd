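---
title: "SMCP: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SMCP: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcpgwas)
```

## The problem and the model

Single-SNP association scans treat each marker independently and are noisy
exactly where help is available: adjacent SNPs in linkage disequilibrium
(LD) carry correlated information about the same underlying signal. SMCP
(smoothed minimax concave penalization) is a multi-SNP selection method
that exploits this. For standardized genotype scores $x_{ij}$
($\sum_i x_{ij} = 0$, $\sum_i x_{ij}^2 = n_j$ over the $n_j$ subjects
nonmissing at SNP $j$) and a centered working response $y$, it minimizes

$$
\sum_{j=1}^p \frac{1}{2 n_j} \sum_i (y_i - x_{ij}\beta_j)^2
+ \sum_{j=1}^p \rho(\beta_j;\lambda_1,\gamma)
+ \frac{\lambda_2}{2}\sum_{j=1}^{p-1} \varsigma_j
  \left(|\beta_j| - |\beta_{j+1}|\right)^2 .
$$

Three modelling choices matter:

* **Marginal loss.** The loss is a sum of per-SNP univariate squared
  errors, not a joint multiple-regression residual. Coordinates therefore
  decouple except through the smoothing term, each coordinate problem has
  unit curvature under our standardization, and missing genotypes are
  handled exactly — sums simply run over the subjects nonmissing at that
  SNP, with no imputation. The price is that $\beta_j$ estimates marginal,
  not partial, effects: members of a causal LD block each carry close to
  the full block signal (this matters for model selection; see below).
* **MCP sparsity.** $\rho(t;\lambda_1,\gamma) = \lambda_1|t| -
  t^2/(2\gamma)$ for $|t| \le \gamma\lambda_1$, constant
  $\gamma\lambda_1^2/2$ beyond. Unlike the LASSO ($\gamma = \infty$), MCP
  applies no shrinkage to effects past the plateau, reducing estimator
  bias and improving selection consistency. $\gamma = 1$ is the
  hard-threshold boundary; we expose it as a documented mode rather than
  rejecting it.
* **LD-weighted smoothing of absolute effects.** The quadratic penalty on
  $|\beta_j| - |\beta_{j+1}|$, weighted by the absolute lag-one Pearson
  correlation $\varsigma_j$ of the genotype scores, encourages similar
  effect *magnitudes* at adjacent SNPs in strong LD. Acting on $|\beta|$
  rather than $\beta$ makes the objective invariant to the arbitrary
  reference-allele choice at each SNP (flipping labels negates a column
  and its coefficient); a fused-LASSO penalty on raw differences would
  break this invariance, which is why it is not usable on genotype data.
  Weights are set to 0 across chromosome boundaries (lag-one LD is a
  within-chromosome notion) and when fewer than 3 shared nonmissing
  subjects exist. Only lag-one weights are used: pairwise smoothing over
  all SNP pairs is quadratic in $p$ and computationally out of reach at
  genome scale.

Covariates (sex, age, smoking, population-group dummies) are removed
beforehand by ordinary least squares: the penalized fit uses the
residuals as $y$. This two-stage scheme also serves as a simple
population-stratification adjustment. The response is centered once
globally; it is not rescaled per SNP.

## Tuning parameters

| symbol | meaning | default | rationale |
|---|---|---|---|
| $\gamma$ | MCP concavity | 3 | standard MCP practice; small enough to be near-unbiased, large enough to keep coordinate problems well behaved |
| $\eta$ | smoothing fraction | 0.1 | fraction of the total penalty budget devoted to smoothing |
| $\tau$ | overall penalty level | EBIC-selected | the single free tuning dimension |
| $\varsigma_j$ | adjacency weights | $|r|$ of adjacent genotype columns | measured LD, not assumed |
| tol | max coefficient change per sweep | 1e-6 | coefficient scale is $O(|z_j|) \lesssim 1$ |
| max_sweeps | sweep cap | 1000 | non-convergence is reported, not hidden |

The two penalty levels are tied by the reparameterization
$\lambda_1 = (1-\eta)\tau$, $\lambda_2 = \eta\tau$. This is a declared
convention: $\eta$ is the fraction of the total penalty devoted to
smoothing, $\eta = 0$ recovers pure MCP, and any alternative map that
differs only by rescaling relabels $\tau$ without changing the model
family. Similarly, the factor $\tfrac12$ in front of the smoothing sum is
a convention absorbed into the scale of $\lambda_2$.

## The coordinate-descent algorithm

Holding neighbors fixed, the objective restricted to $\beta_j$ is, up to a
constant and with $u = |b|$ on the sign branch of $z_j = \sum_i x_{ij}
y_i / n_j$,

$$
f(u) = \tfrac12 (1 + w)\,u^2 - (|z_j| + m)\,u + \rho(u;\lambda_1,\gamma),
\qquad
w = \lambda_2(\varsigma_{j-1}+\varsigma_j),\quad
m = \lambda_2(\varsigma_{j-1}|\beta_{j-1}| + \varsigma_j|\beta_{j+1}|).
$$

The opposite sign branch is pointwise no better (its linear term is
weakly larger), so only this branch is searched. On it, $f$ is piecewise
quadratic with two regimes ($u \le \gamma\lambda_1$ and beyond), so the
global minimizer is one of at most four candidates: the origin, the
stationary point of each regime (when it lies inside its regime), and the
regime boundary $\gamma\lambda_1$. The update evaluates $f$ at each and
takes the argmin — exact, including the degenerate case
$\gamma(1 + w) \le 1$ where the inner regime is concave and its minimum
must sit at a boundary; no numeric fallback is needed. When $z_j = 0$ and
the neighbor pull $m$ is positive the two branches tie; the nonnegative
branch is returned deterministically.

Sweeps are cyclic in ascending SNP order (deterministic and
reproducible), and each update is an exact 1-D minimization, so the
objective trace is non-increasing by construction — this is asserted in
the test suite over randomized problems. The objective is nonconvex:
coordinate descent reaches a stationary point, not a certified global
minimum. Warm starts along the $\tau$ path are the standard mitigation.
Monomorphic SNPs are flagged inactive (coefficient fixed at 0, reported
with estimate 0) and their adjacency weights set to 0. The inner loop is
implemented in C++ (Rcpp); because the marginal loss reduces every
per-coordinate problem to the scalars $(z_j, C_j)$, the solver never
touches the genotype matrix and a full 100-point path on a
$697 \times 2000$ panel takes well under a second.

## Tuning path and EBIC

The default grid is 100 log-spaced $\tau$ values from $\tau_{\max} =
\max_j |z_j| / (1-\eta)$ — the smallest level at which every update from
zero stays at zero, so the path provably starts at the null model — down
to $0.01\,\tau_{\max}$, each fit warm-started from its predecessor.
$\tau$ is chosen by the extended Bayesian information criterion

$$
\mathrm{EBIC}(\tau) = n\log(\mathrm{RSS}_\tau/n) + k_\tau \log n +
2\gamma_{\mathrm{EBIC}} \log\binom{p}{k_\tau},
$$

with $k_\tau$ the support size, RSS the *joint* residual sum of squares
of the penalized estimates (a plug-in; no refit), and
$\gamma_{\mathrm{EBIC}} = 1 - \log n/(2\log p)$ clipped to $[0,1]$. Ties
break toward larger $\tau$ (the sparser model); $k \ge n$ yields
$+\infty$. The binomial coefficient is computed on the log scale.

Two interactions of this criterion with the marginal loss are worth
knowing. First, because each member of a causal LD block carries nearly
its full marginal effect, the joint plug-in prediction over a selected
block overshoots, and the overshoot is larger for MCP's unbiased
estimates than for the LASSO's shrunken ones. EBIC consequently tends to
stop SMCP at a sparser point of its path than the LASSO comparator. In
simulations with one strong causal block and a couple of borderline
isolated causal SNPs, this shows up as SMCP recovering the block
essentially always with near-zero false positives, while the LASSO —
pushed to a lower $\tau$ by its falling joint RSS — picks up borderline
true *and* false positives more often, and can post a slightly higher
mean true-positive count. On panels with many weak causal variants the
balance shifts the other way. The package reports both methods side by
side so the trade-off is visible rather than hidden. Second, the
plug-in (refit-free) RSS makes the criterion conservative; a refit-based
EBIC would select larger models for both methods but is not what this
implementation uses.

The LASSO comparator is the same machinery at $\gamma = \infty$,
$\eta = 0$; each coordinate update is then exactly
$\mathrm{sign}(z_j)(|z_j| - \lambda_1)_+$, which the tests verify against
the general path at $\gamma = 10^{12}$.

## Leave-one-out p-values

For each selected SNP $j$ the model is refitted at the *same* penalty
configuration with $\beta_j$ constrained to 0 (warm-started from the full
solution), and
$D_j = n \log(\mathrm{RSS}_{-j}/\mathrm{RSS})$, clipped at 0, is referred
to $\chi^2_1$. Two approximations are explicit: the tuning level is held
fixed, so the p-value conditions on the selected $\tau$ and is not
adjusted for selection; and the statistic uses the penalized (not
refitted-unpenalized) coefficients. Calibration is therefore checked
empirically, not assumed: for a null SNP forced into the support by a
weak penalty, the LOO p-value distribution over 200 replicates is close
to uniform (Kolmogorov–Smirnov distance about 0.08 in the shipped
acceptance run).

The univariate baseline is the per-SNP simple regression over nonmissing
subjects with a Wald t-test ($n_j - 2$ df), reported on the per-allele
scale, with Benjamini–Hochberg step-up control of the false discovery
rate across the panel (via `stats::p.adjust`).

## The simulator: what it emulates, and what it does not

`simulate_study()` generates, per subject, two latent Gaussian haplotype
processes with AR(1) correlation `rho` along the SNP axis (restarting at
chromosome boundaries), thresholds each at the per-SNP MAF quantile, and
sums the two allele indicators into 0/1/2 codes. This was chosen over
haplotype-copying models for transparency and exact seeding; the cost is
that genotype-scale LD is attenuated relative to `rho` (strongly so for
rare variants), which is why the *realized* lag-one $|r|$ is always
returned rather than assumed. The trait is a linear model on the
complete (pre-missingness) codes plus covariate effects and Gaussian
noise.

`gaw17_like_preset()` fixes the study conditions used throughout the
evaluation: 697 subjects; 2000 SNPs on two chromosomes (a desk-scale
panel; the full-scale panel is a config change, not a code change);
log-uniform MAFs on $[0.005, 0.5]$, a rare-variant-heavy spectrum;
latent `rho = 0.7`, giving realized adjacent-LD around 0.3–0.5 for
common pairs; one block of 3 adjacent causal SNPs (per-allele effects
1.0/1.2/0.9 at MAFs 0.04/0.05/0.04 — detectable but rare, emulating a
cluster of causal variants within one gene) plus two isolated weaker
causal SNPs (0.6 at MAF 0.10, 0.5 at MAF 0.08, deliberately near the
detection boundary at $n = 697$); sex/age/smoking covariates and seven
population groups coded as dummies; residual SD 1. Features of real
exome panels the generator does **not** reproduce: population-specific
allele-frequency spectra, recombination-map-driven LD decay, genotyping
batch artifacts, and relatedness. Passing tests on this generator
therefore demonstrate algorithmic correctness and the selection behavior
described above, not field performance on any particular cohort.

## Problem sizes used in the shipped checks

Module tests run on panels up to a few hundred subjects and a few dozen
SNPs. The deeper property checks use: 100 random separable problems
($n = 200$, $p = 50$) against the analytic MCP threshold (tolerance
1e-8); 200 random one-coordinate problems against a 1e-4-step grid
search (tolerance 2e-4); 100 random smoothed fits for objective
monotonicity (relative tolerance 1e-9); 50 preset replicates
($697 \times 2000$) for selection quality; 50 null panels
($200 \times 500$) for empty-model selection; and 200 replicates for LOO
calibration. The full set runs in about two minutes on one CPU.

## Known limitations

* Marginal-loss coefficients are marginal effects; they should not be
  read as adjusted effect sizes in a joint model.
* LOO p-values condition on the selected tuning; no selective-inference
  correction is applied.
* Only lag-one LD enters the smoothing penalty; signals spread over
  non-adjacent markers in LD gain nothing from it.
* Coordinate descent on a nonconvex objective can, in principle, return
  different stationary points from different starts; the shipped paths
  always start at the null model with warm starts, which is
  deterministic.
* Quantitative traits only; no logistic or survival loss.
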