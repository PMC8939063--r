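# nabsel

Quantitative-genetic machinery for divergent mass selection on natural-antibody
(NAb) titers in laying hens when a single near-fully dominant major locus
segregates alongside a polygenic background.

Natural antibodies — here, titers binding keyhole limpet hemocyanin (KLH),
measured as log2 ELISA endpoint dilutions — are a heritable indicator trait for
general disease resistance in poultry. A divergent breeding program selects,
in each of two lines, the ~25 males and ~50 females with the most extreme
total-NAb (IgTotal) titers, mates each sire to two dams while avoiding full-
and half-sib matings, and repeats this for seven generations. A biallelic
toll-like-receptor-family locus with a near-fully dominant C allele (base
frequency ≈ 0.45) has a large effect on IgM titers, so mass selection moves
its frequency far and fast — and asymmetrically, because dominance hides the
G allele in heterozygotes on the way up but exposes it on the way down.

`nabsel` provides the four pieces needed to study such a program end to end:

* **pedigree** — validated, topologically sorted pedigrees; the numerator
  relationship matrix **A** by the tabular recursion; Meuwissen–Luo
  inbreeding coefficients; Henderson's sparse **A**⁻¹ with inbreeding
  correction; inbreeding trends by line and generation.
* **simulate** — a forward-in-time generator of the whole design: Hardy–
  Weinberg founders, truncation selection within sex, sib-avoiding mate
  allocation (exact bipartite matching), Mendelian transmission with
  inbreeding-adjusted Mendelian-sampling variance, maternal environmental
  effects shared by full sibs, ELISA plate effects, multi-trait genetic and
  residual correlations, and the endpoint-titer rule.
* **varcomp** — REML/BLUP animal models on sparse mixed-model equations:

  `y = mean + Plate + Sex (+ Line + Genotype) + a + d + e`,
  `a ~ N(0, A σ²_A)`, `d ~ N(0, I σ²_m)`, `e ~ N(0, I σ²_e)`,

  with optional pedigree-structured maternal genetic effects (including the
  direct–maternal covariance), fixed variance components (GLS mode),
  likelihood-ratio tests, additive/dominance genotype contrasts
  (`Additive = (CC − GG)/2`, `Dominance = CG − (CC + GG)/2`), interaction
  Wald tests, bivariate fits (trait pairs, or one trait split by sex) with
  genetic/maternal/residual correlations, and EBV-based genetic trends.
  Heritability is `h² = σ²_A / (σ²_A + σ²_m + σ²_e)` and the maternal ratio
  `m² = σ²_m / (σ²_A + σ²_m + σ²_e)`.
* **seltheory** — deterministic predictions: selection intensity
  `i = φ(z)/p`, the breeder's equation, the single-locus mass-selection
  approximation `Δp = i p q α / σ_P` with average effect `α = a + d(q − p)`,
  locus variances `2pqα²` and `(2pq d)²`, allele-frequency trajectories, and
  the decomposition of a genetic trend into its major-locus part
  `M(p_t) − M(p_0)` and a polygenic remainder.

A thin pipeline layer (`run_pipeline()`) chains simulate → fit → trend →
theory from one configuration and writes every table as CSV.

## Worked example

Simulate a reduced three-generation divergent experiment on IgM (polygenic
h² = 0.30, m² = 0.03, dominant locus with genotype effects 0/1.01/1.12) and
fit the maternal-environment animal model by REML:

```r
library(nabsel)

cfg <- sim_config(
  n_base = 800, generations = 3, generation_sizes = rep(700, 3),
  traits = list(IgM = trait_spec("IgM", mean = 7.10, sigma2_A = 0.345,
                                 sigma2_m = 0.0345, sigma2_e = 0.7705,
                                 sigma2_plate = 0.25, sex_effect = -0.13)),
  locus = locus_spec(p0 = 0.45, values = list(IgM = c(0, 1.01, 1.12))),
  selection_criterion = "IgM")

sim <- run_experiment(cfg, seed = 42)
fit <- fit_animal_model(sim$phenotypes, sim$pedigree, model_spec("IgM"))
fit
#> Animal-model REML fit: IgM
#>   records: 2900  fixed df: 146
#>   logL: -4183.8759  converged: TRUE  evaluations: 134
#>          estimate      se
#> sigma2_A  0.51185 0.03736
#> sigma2_m  0.06492 0.02533
#> sigma2_e  0.78369 0.03500
```

The estimated σ²_A (0.51) exceeds the generating polygenic 0.345 because the
segregating major locus contributes its own additive variance (≈ 0.18 at
p = 0.45), exactly as a whole-genome heritability estimate would absorb it.
Selection separates the lines at the locus within three generations:

```r
sim$summary[, c("line", "generation", "n", "p_C")]
#>   line generation   n       p_C
#> 1 base          0 800 0.4562500
#> 2 high          1 350 0.6428571
#> 3  low          1 350 0.2885714
#> ...
#> 6 high          3 350 0.8371429
#> 7  low          3 350 0.1242857
```

Deterministic theory for the full seven-generation design — intensities from
the design's selected fractions, IgTotal locus effects, σ_P = √1.85 —
predicts the High-line C frequency to reach ≈ 0.76 by generation 7:

```r
di <- design_intensities()
allele_trajectory(locus_model(0.45, c(0, 0.49, 0.44)),
                  di$intensity, sqrt(1.85), 7, "up")$p[8]
#> [1] 0.7566339
```

and the decomposition of a −1.60 titer-point Low-line IgM trend, with the C
frequency moving 0.45 → 0.04, attributes −0.65 points to the locus and −0.95
to the polygenic background:

```r
igm <- locus_model(0.45, c(0, 1.01, 1.12))
locus_response_split(0.45, 0.04, igm, total_trend = -1.60)
#>     locus polygenic
#>  -0.64739  -0.95261
```

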