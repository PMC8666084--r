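---
title: "Kernel association testing for CNV profiles: model, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel association testing for CNV profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mckat)
```

## The model

A copy number variant (CNV) is described by four coordinates: its interval
$[X^{(1)}, X^{(2)}]$ on a chromosome, its type $X^{(3)}$ (1 = deletion,
3 = amplification) and its dosage $X^{(4)}$, the total copy number of the
segment (2 is the diploid reference). The similarity of two CNVs on the
same chromosome is the product of three sub-kernels:

$$K_s(X_1, X_2) =
  \underbrace{\frac{|I_1 \cap I_2|}{|I_1 \cup I_2|}}_{\text{position}}
  \times
  \underbrace{\frac{(X_1^{(3)} {=} X_2^{(3)}) + 1}{2}}_{\text{type}}
  \times
  \underbrace{2^{-\left|DR(X_1^{(4)}) - DR(X_2^{(4)})\right|}}_{\text{dosage}},
  \qquad DR(d) = |d - 2|.$$

Intervals are 1-based inclusive (length $=$ end $-$ start $+ 1$), so a
single-base CNV has length 1 and the Jaccard denominator is never zero.
$K_s \in [0, 1]$, with 1 exactly when interval, type and dosage distance
all agree, and 0 when the intervals are disjoint.

Profile similarity between subjects $i$ and $j$ within a region is the
unnormalized double sum over all cross pairs,
$K_w(R_i, R_j) = \sum_{a=1}^{p_i}\sum_{b=1}^{q_j} K_s(X_a^i, X_b^j)$,
defined as 0 when either profile is empty. The $n \times n$ matrix
$K_{ij} = K_w(R_i, R_j)$ is positive semi-definite: each sub-kernel is PSD
(Jaccard; a shifted agreement indicator; the exponential of a metric), and
products and sums of PSD kernels are PSD.

Association with a binary trait $y$ is tested under the logistic mixed
model $\operatorname{logit} P(y_i = 1) = \beta_0 + Z_i\beta + f_i$ with
$f \sim N(0, \tau K)$, testing $H_0\!: \tau = 0$ with the
variance-component score statistic $Q = (y - \hat y)' K (y - \hat y)$,
where $\hat y$ is the fitted value of the covariate-only logistic null
model. Under $H_0$, $Q$ is asymptotically $\sum_i \lambda_i \chi^2_{1,i}$,
with $\lambda_i$ the eigenvalues of $P_0^{1/2} K P_0^{1/2}$,
$P_0 = V - V\tilde Z (\tilde Z' V \tilde Z)^{-1} \tilde Z' V$,
$V = \mathrm{diag}(\hat y_i (1 - \hat y_i))$, $\tilde Z = [1\,|\,Z]$.
(Note $P_0$ is not idempotent, so this is *not* the same as the
eigenvalues of $P_0 K P_0$; the square-root form is the one whose trace
matches $E[Q] = \operatorname{tr}(P_0 K)$, which the test suite checks
against label permutation.) With no covariates, $P_0 = v(I - J/n)$ and
$P_0^{1/2} K P_0^{1/2}$ reduces to $v$ times the doubly centered kernel;
the implementation uses this closed form and keeps the generic projection
for covariate-adjusted nulls.

## Tail probabilities of the mixture

The p-value $P(\sum_i \lambda_i \chi^2_{1,i} \ge Q)$ is computed by
numerical inversion of the characteristic function (the Davies approach,
in Imhof's integral form):

$$P(Q' \ge q) = \frac12 + \frac1\pi \int_0^\infty
  \frac{\sin\theta(u)}{u\,\rho(u)}\,du, \quad
  \theta(u) = \tfrac12\sum_r \arctan(\lambda_r u) - \tfrac{qu}2, \quad
  \rho(u) = \prod_r (1 + \lambda_r^2 u^2)^{1/4}.$$

$\theta$ is concave on $u \ge 0$ (its derivative is strictly decreasing),
so the integrand's sign changes are fully characterized: $\theta$ rises to
a single maximum and then decreases to $-\infty$ with asymptotic slope
$-q/2$. The integral is evaluated lobe-by-lobe between consecutive zeros
of $\sin\theta$ (each lobe by adaptive quadrature at relative tolerance
$10^{-12}$), and the alternating tail of the lobe series is summed by
repeated averaging (an Euler transformation). That acceleration matters:
for a single weight the integrand decays only like $u^{-3/2}$, yet the
averaged series reaches machine precision within a few dozen lobes. The
suite verifies agreement with the exact $\chi^2_k$ survival function to
better than $10^{-9}$ absolute for $k = 1\ldots200$ and tail
probabilities down to $10^{-12}$, and with $10^6$-draw Monte Carlo
mixtures within Monte-Carlo error.

Defaults: absolute accuracy $10^{-9}$ (reported p-values must resolve
below $10^{-8}$), at most 300 lobes. If the inversion faults or returns a
value outside $[0, 1]$, the implementation falls back to a
moment-matching (Liu-type) approximation — a scaled non-central chi-square
matched to the first moments of the mixture — and labels the result
`moment_fallback`. Eigenvalues below $10^{-10} \lambda_{\max}$ are treated
as numerical zeros; if none remain, the test is degenerate and $p = 1$.
Reported p-values are floored at $10^{-300}$ and flagged rather than
printed as 0.

## Scans and multiplicity

`scan_genome()` tests each chromosome present in the data and applies a
Bonferroni threshold $\alpha/m$; $m$ defaults to the number of
chromosomes tested, with `m_tests` available to reproduce a fixed divisor
such as $0.05/23 \approx 2.2\times10^{-3}$ for the 23 human chromosome
pairs. `scan_bands()` tests every cytogenetic band containing at least one
cohort CNV. Band membership is *any base-pair overlap*, the CNV
contributes whole (no clipping), and a boundary-spanning CNV counts in
every band it touches; this is the weakest assumption and keeps
single-pair kernel values identical across scales. By default the band
scan reuses the per-chromosome threshold (the convention of reporting
band-level hot spots within chromosome-level error control);
`band_threshold = "band"` switches to an honest band-level Bonferroni.
Because the profile kernel is an unnormalized double sum, kernels over
disjoint regions add exactly; `combined_band_profile()` exploits this to
test a selected set of bands jointly as one region.

## What the simulator emulates

The generator reproduces the structure of real CNV call sets as the
cohort-level summaries describe them:

* **Recurrent loci.** CNVs recur at polymorphic loci. A pool of candidate
  loci is drawn first (default 20 per chromosome, allocated proportional
  to chromosome length for genome-wide cohorts), and each subject's CNVs
  sample loci without replacement with $\pm 10\%$ breakpoint jitter per
  carrier. Without recurrence, independently placed intervals essentially
  never overlap between subjects, the kernel matrix is nearly diagonal,
  and the score statistic carries no between-subject information — a
  degenerate regime no real call set exhibits.
* **Scenario structure.** The rare scenario confines the cohort to one
  randomly chosen chromosome with 1–5 CNVs per subject (uniform); the
  common scenario draws Poisson(3) CNVs per subject genome-wide (source
  call sets average about 2.8–3.2 CNVs/subject).
* **Types and dosages.** Deletions with probability 0.35 (the observed
  deletion:amplification ratio of roughly 0.35:0.65); deletion dosages 0/1
  with probability 0.5 each, amplification dosages 3–7 with probability
  0.2 each.
* **Lengths.** Log-uniform between 10 kb and 1 Mb, spanning the range
  from large copy number polymorphisms to the megabase-scale rare
  variants.
* **Labels.** Case-control labels are drawn from a logistic model whose
  per-CNV terms cover length, type, dosage distance $|d-2|$, and
  length × type × dosage interactions. The intercept defaults to
  $\operatorname{logit}(877/1214)$, the affected:control composition of
  the neurological-deficit cohorts (877 dyslexia/intellectual-disability
  individuals vs 337 controls) whose structure the generator emulates.
  All other coefficients default to zero (the null scenario).

For power studies a nonzero per-CNV effect shifts the cohort-average
linear predictor by about $\beta \cdot E[m] \cdot E[DR]$ and would drive
the prevalence toward 0 or 1; `power_effects()` therefore centers the
intercept so the marginal prevalence stays at its baseline. The published
grid $\beta^{Dsg} \in \{0.20, 0.25, 0.30\}$ was chosen once so that
empirical power at $n = 300$ spans roughly 0.2–0.9.

## Problem sizes and calibration

The calibration and power studies in the test suite and acceptance script
use $n = 300$ subjects with 2000 null replicates and 500 replicates per
power point — a deliberate desk-scale reduction of the original design
(about 1200 subjects, $10^5$ replicates).

One consequence is worth stating plainly. For a *binary* trait the
squared residuals $(y_i - \hat y)^2$ are nearly deterministic (exactly
deterministic at prevalence 0.5), while the Gaussian mixture
approximation attributes full chi-square variance to the kernel's
diagonal — each subject's self-similarity, which the unnormalized double
sum makes substantial ($K_{ii} \approx$ the subject's CNV count). The
mixture therefore *overestimates* the null variance of $Q$ by a factor
that scales like (loci per chromosome)/(cohort size), and the test is
mildly conservative at desk-scale $n$: null rejection at $\alpha = 0.05$
runs around 0.03–0.04 at $n = 300$ and approaches the nominal level only
near the original cohort size. This is the known conservatism of
variance-component score tests for binary traits in small samples, not an
implementation artifact: the suite separately verifies that the
permutation mean of $Q$ matches $\sum_i\lambda_i$ and that the
covariate-adjusted mixture is exact for Gaussian residuals. The same
mechanism means an exact-permutation p-value and the analytic p-value
differ noticeably at $n = 40$, so small-sample analyses should prefer
permutation. Errors are in the conservative (type-I-protecting)
direction.

What passing the simulation tests does *not* show about real data: the
generator draws types independently per CNV (real loci are
type-consistent), carrier dosages independently (real carriers at a locus
share dosage more often), and loci uniformly (real hot spots cluster);
none of these affect the null distribution machinery, but power against
real signals will differ from power against simulated ones.

## Numerical and degenerate-input conventions

* Chromosome labels are matched after stripping an optional `chr` prefix
  and re-attached on output; "8" and "chr8" are the same chromosome.
* UCSC cytoband input (0-based half-open) is converted on read to the
  1-based inclusive convention used throughout.
* A region with no CNVs yields an all-zero kernel and is reported as
  $Q = 0$, $p = 1$, `degenerate` — never an error — so genome scans are
  total.
* Subjects with empty profiles are retained and carry all-zero kernel
  rows.
* Missing dosage columns are imputed as 1 (deletions) and 3
  (amplifications), matching call sets that lack copy-number estimates.
* The type sub-kernel's mismatch value defaults to 0.5, the value the
  product formula yields; a documented switch sets it to 0 for the
  stricter convention under which mismatched types annihilate the pair.
  The discrepancy between the two conventions is surfaced in the
  configuration rather than silently resolved.
* Strict input validation rejects type/dosage inconsistencies (deletion
  with dosage > 1, amplification with dosage ≤ 2); a lenient flag
  downgrades them to warnings because real call sets frequently violate
  the rule.
* Degenerate label draws in simulation replicates (all cases or all
  controls) are redrawn and counted, never silently dropped.

## Limitations

* The pairwise kernel block is materialized densely; regions with more
  than a few tens of thousands of CNVs need chunking that the package
  does not implement.
* Only binary traits are supported; no continuous-trait version, no
  small-sample moment corrections, and no resampling-based FWER control.
* Band scans export plot-ready tables (Manhattan/QQ data); rendering of
  ideograms is out of scope.
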