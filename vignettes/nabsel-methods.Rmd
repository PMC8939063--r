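---
title: "Models and methods behind nabsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nabsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nabsel)
```

`nabsel` studies a two-line divergent mass-selection program for
KLH-binding natural-antibody titers in which a near-fully dominant major
locus segregates on top of a polygenic background. This vignette is the
package's own account of the models it implements, the assumptions the
synthetic-data generator makes, and the numerical decisions taken where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` do not themselves compute.

## 1. The animal model

The workhorse is the mixed linear animal model

$$y = \mu + \mathrm{Plate} + \mathrm{Sex}\;(+\,\mathrm{Line} +
\mathrm{Genotype}) + a + d + e,$$

with $a \sim N(0, \mathbf{A}\sigma^2_A)$ structured by the pedigree
numerator relationship matrix, an iid maternal environmental dam effect
$d \sim N(0, \mathbf{I}\sigma^2_m)$, and residual
$e \sim N(0, \mathbf{I}\sigma^2_e)$. Heritability and the maternal ratio
are $h^2 = \sigma^2_A/(\sigma^2_A+\sigma^2_m+\sigma^2_e)$ and
$m^2 = \sigma^2_m/(\sigma^2_A+\sigma^2_m+\sigma^2_e)$; plate is a fixed
effect and does not enter the denominator. ELISA plate and generation are
confounded by design (each generation is assayed on its own plates), so
generation is never fitted alongside plate; the fitter raises a singularity
error naming the aliased columns if a user tries.

The maternal *genetic* extension adds a second pedigree-structured effect
for the dam with covariance
$\mathrm{Cov}(a, m_g) = \mathbf{A}\sigma_{a,m_g}$; the implied
direct–maternal correlation is reported with a flag when the estimate sits
at the boundary of the parameter space (see §5).

**Restricted likelihood.** Variance components maximize the restricted
log-likelihood, computed through the mixed-model-equation identity
$\log|\mathbf{V}| + \log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}| =
\log|\mathbf{R}| + \log|\mathbf{G}| + \log|\mathbf{C}|$ with sparse
Cholesky factorization of the coefficient matrix $\mathbf{C}$. We report
the parameterization-invariant form that subtracts
$\log|\mathbf{X}'\mathbf{X}|$, so the value is unchanged by the choice of
fixed-effect contrasts (a constant offset relative to the textbook
expression; all likelihood-ratio statistics are unaffected). A dense-matrix
evaluation of the same definition serves as an oracle in the tests, which
agree to better than $10^{-6}$.

**Optimization.** Components are optimized on the log scale (covariances
through a tanh-scaled correlation), with Nelder–Mead (Brent in one
dimension), relative tolerance $10^{-10}$, and the mixed-model equations
refactorized per evaluation through a fixed-sparsity-pattern assembly (only
the numeric slot of $\mathbf{C}$ changes between evaluations, so the
symbolic analysis is done once). Components named in `fixed_variances` are
held constant; with all components fixed the fit is a single GLS/BLUP
solve, which the tests verify against a dense GLS oracle to $10^{-8}$.
Standard errors come from a central-difference Hessian of the restricted
likelihood at the optimum; ratios and correlations use the delta method.

**Bivariate models** stack the records of two traits (or of one trait split
by sex) with additive covariance $\mathbf{S}_a \otimes \mathbf{A}$,
maternal covariance $\mathbf{S}_m \otimes \mathbf{I}$, and per-animal
2×2 residual blocks. In sex-split mode no animal contributes to both
traits, so the residual covariance is structurally inestimable; it is fixed
at 0 and reported as `NA` — a documented modelling decision, not an
estimate. Holding the genetic correlation at 0.999 supports the boundary
likelihood-ratio test of $r_a = 1$.

## 2. Pedigree machinery

$\mathbf{A}$ is built by the tabular recursion
$a_{ij} = \tfrac12(a_{i,s(j)} + a_{i,d(j)})$,
$a_{jj} = 1 + \tfrac12 a_{s(j),d(j)}$; dense $\mathbf{A}$ is only
materialized for moderate pedigrees (default cap 2,000 animals) and exists
for oracle and reporting use. Model fitting always goes through the sparse
$\mathbf{A}^{-1}$ assembled by Henderson's rules with Mendelian-sampling
variances $D_i = \tfrac12 - \tfrac14(F_s + F_d)$ corrected for parental
inbreeding; inbreeding coefficients come from the Meuwissen–Luo ancestor
traversal, which matches $\mathrm{diag}(\mathbf{A})-1$ exactly. Unknown
parents are unrelated, non-inbred founders. The rate of inbreeding uses
$\Delta F_t = (F_t - F_{t-1})/(1 - F_{t-1})$.

The tests cross-check $\mathbf{A}$ against a gene-dropping Monte-Carlo
oracle (identity-by-descent probabilities from simulated allele
transmission) and verify $\mathbf{A}\mathbf{A}^{-1} = \mathbf{I}$ on random
inbred pedigrees.

## 3. The synthetic-data generator

The generator emulates the study design: a base population (default 4,855
birds, 64% female, genotypes in Hardy–Weinberg proportions at $p_0 = 0.45$),
then seven generations in two lines. Per line and generation, the 25
top-ranked males and 50 top-ranked females on the criterion trait (IgTotal
by default; the Low line ranks ascending) are selected on own phenotype,
each sire is allocated two dams by exact bipartite matching that excludes
full- and half-sib pairs (falling back, with a warning, to the
least-related available pairing only when no sib-free assignment exists),
and offspring counts are distributed evenly over matings to hit the
generation totals 946, 820, 526, 915, 1135, 707, 974 — the study's printed
sizes, split equally between lines.

Phenotypes follow the fitted model used generatively: trait value = mean +
plate effect + sex effect + genotype value + polygenic value + maternal
effect + residual. Defaults are the study's architecture: IgM
$\sigma^2_A = 0.345$, $\sigma^2_m = 0.0345$, $\sigma^2_e = 0.7705$
($\sigma^2_P = 1.15$, $h^2 = 0.30$, $m^2 = 0.03$); IgTotal and IgG analogous
with $\sigma^2_P$ 1.85 and 1.95 and $h^2$ 0.12; a −0.13 titer-point male
effect on IgM; major-locus genotype values (GG/CG/CC) of 0/1.01/1.12 (IgM),
0/0.49/0.44 (IgTotal), 0/0.22/0.07 (IgG). Plate variances are
back-computed from the reported shares of phenotypic variance explained
when plate is random (18/22/14% for IgM/IgTotal/IgG), plates hold 20 birds
and mix lines and sexes within a generation (a flag reproduces the
confounded single-sex base-population layout). In multivariate mode the
additive, maternal and residual draws use the reported correlation
structure ($r_a$ 0.91/0.94/0.77 for IgM–IgTotal/IgG–IgTotal/IgM–IgG); the
two unreported residual correlations are set so the implied phenotypic
correlations match the reported ones (0.461 IgM–IgTotal, 0.826
IgG–IgTotal), and the construction reproduces the reported 0.30 IgM–IgG
phenotypic correlation as a consistency check.

Transmission is Mendelian at the locus and infinitesimal for the polygenes:
offspring polygenic value = midparent + a deviation with variance
$\tfrac12\sigma^2_A(1 - (F_s+F_d)/2)$, keeping the polygenic covariance
consistent with $\mathbf{A}$. Inbreeding is tracked exactly by carrying the
relationship matrix of each cohort forward one tabular step per generation.
Maternal effects are drawn once per dam and shared by full sibs; founders,
whose dams are unknown, each receive a singleton maternal draw, and the
fitter gives unknown-dam animals singleton dam levels so the generating and
fitted models coincide (no phantom dam families are invented). All
randomness flows from a single root seed through named child streams, so
identical configurations and seeds give byte-identical output files.

**What the generator does not emulate:** the base population's two
overlapping recruitment batches (the overlap affects none of the
implemented estimators), overlapping generations, linked markers, drifting
assay standards, or survival outcomes. Passing tests therefore demonstrate
correctness of the machinery under the stated architecture, not robustness
to those real-data features.

The ELISA endpoint rule is implemented as a standalone operation: the titer
is $\log_2$ of the dilution (series 1:40 … 1:2560) whose extinction is
nearest 50% of the standard's maximum, with an endpoint flag at the series
boundary and the lower dilution chosen on an exact tie. Interpolating
between dilutions would be a natural extension; the nearest-point reading
is what the assay protocol states.

## 4. Selection theory

Selection intensity is $i = \varphi(z)/p$ for truncation proportion $p$.
Because sires and dams are selected at different proportions, per-generation
intensities are sex-averaged, $i = (i_m + i_f)/2$ — the standard half-sum
of the parental pathways. Default proportions divide 25 sires and 50 dams
by the per-sex, per-line candidate counts implied by the printed generation
sizes (one quarter of the previous generation's total); the first selection
round draws on the whole base population with its printed sex counts
(1,756 males, 3,099 females).

One generation of mass selection moves the C-allele frequency by
$\Delta p = i\,p\,q\,\alpha/\sigma_P$ with average effect
$\alpha = a + d(q-p)$; the trajectory iterates this, re-imposing
Hardy–Weinberg proportions each generation and recomputing $\alpha$.
$\sigma_P$ is held at its base value — the approximation supplies no update
rule for eroding variance, and this choice is documented rather than
hidden. The locus contributes additive variance $2pq\alpha^2$ and dominance
variance $(2pqd)^2$; under full dominance the additive-variance curve peaks
below $p = 0.5$, which is why the Low line first gains and then loses locus
variance on its way down. The change in the Hardy–Weinberg mean genotypic
value $M(p) = 2pq\,v_{CG} + p^2 v_{CC}$ (GG baseline) decomposes any total
genetic trend into a locus part and a polygenic remainder that reconstruct
the total exactly.

With these defaults the seven-generation High-line prediction lands at
0.757. The exact intensities behind the study's corresponding figure are
not printed; the reconstruction above is the package's documented default,
and the acceptance band for that endpoint reflects this (±0.05).

## 5. Numerical choices and edge cases

* **Boundary estimates.** Variances are log-parameterized and correlations
  tanh-parameterized, so estimates cannot leave the parameter space;
  instead, estimates at the boundary (a vanishing variance, or
  $|\hat r| \ge 0.99$) are flagged. Unconstrained REML implementations can
  report correlations far outside $[-1, 1]$ in the same situation; the flag
  is this package's equivalent signal.
* **Ties** in truncation selection are broken by stable ordering on animal
  id, making selection deterministic.
* **Degenerate groups** in descriptive tables: a singleton group omits its
  SD with a flag; when both groups of a comparison have zero variance the
  standard error is floored at machine epsilon so the Welch statistic stays
  finite.
* **Convergence** is declared at a relative change of the restricted
  log-likelihood below the optimizer tolerance; the evaluation count and a
  convergence flag are returned with every fit.
* **Problem sizes.** The test suite and acceptance script run reduced
  versions of the study design — bases of 400–1,500 birds, generations of
  300–1,135, 4–10 replicates — chosen so each stochastic check retains a
  2-standard-error resolution well below the effect being recovered while
  the whole suite completes in a few minutes on one CPU. The forward
  simulation for the allele-frequency endpoint keeps the full design sizes,
  because the selection intensities (and hence the endpoint) depend on
  them.

## 6. A note on estimating a major-gene effect inside a selected pedigree

Recovering the genotype-class effects by fixing the variance components at
the whole-data animal-model estimates — the study's procedure — is subtly
sensitive to how the data arose. Generations of selection build
gametic-phase disequilibrium between the major locus and the polygenic
background, and the whole-data $\hat\sigma^2_A$ absorbs the locus's own
additive variance; the resulting BLUP shrinks family differences with a
variance that over-states the polygenic share, which attenuates the fixed
genotype contrast. In experiments simulated with direct selection on the
trait carrying the locus this attenuation reaches ~18%; under the study's
actual design — selection on IgTotal, with IgM responding as a correlated
trait — it is within sampling error of zero, and the acceptance experiment
recovers the generating CG effect accordingly. Users applying
`fit_animal_model()` with `fixed_variances` to their own selected
populations should be aware of this mechanism.

## 7. Known limitations

* The REML engine targets the study's model family (one or two traits,
  additive + maternal structures); it is not a general-purpose mixed-model
  fitter.
* Trivariate correlation tables are obtained pairwise, as in the study.
* Allele-frequency predictions ignore drift (the stochastic simulator is
  the tool for that) and second-order effects of selection on variance.
* The simulator's plate effects are independent across traits and
  generations; slow assay drift is not modelled.
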