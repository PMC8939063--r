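#' Major-locus model
#'
#' A biallelic locus with increasing allele C at frequency `p` and genotype
#' values (GG, CG, CC) on the trait scale. The additive effect is
#' a = (v_CC − v_GG)/2 and the dominance deviation d = v_CG − (v_CC + v_GG)/2;
#' full dominance corresponds to d = a.
#'
#' @param p frequency of the C allele, in \[0, 1\].
#' @param values numeric length-3 vector of genotype values `c(GG, CG, CC)`.
#' @return list of class `locus_model` with `p`, `values`, `a`, `d`.
#' @examples
#' locus_model(0.45, c(0, 1.01, 1.12))  # near-full dominance
#' @export
locus_model <- function(p, values) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1,
            is.numeric(values), length(values) == 3L)
  values <- unname(values)
  structure(list(p = p, values = values,
                 a = (values[3L] - values[1L]) / 2,
                 d = values[2L] - (values[3L] + values[1L]) / 2),
            class = "locus_model")
}

#' Selection intensity for truncation selection
#'
#' The standardized mean deviation of the selected fraction of a normal
#' distribution: i = phi(z)/p with z the upper-tail quantile at proportion p.
#'
#' @param proportion fraction selected, in (0, 1].
#' @return selection intensity (0 when everything is selected).
#' @examples
#' selection_intensity(0.5)   # ~0.798
#' selection_intensity(0.1)   # ~1.755
#' @export
selection_intensity <- function(proportion) {
  if (any(!is.finite(proportion)) || any(proportion <= 0) || any(proportion > 1))
    stop("proportion must be in (0, 1]")
  ifelse(proportion == 1, 0,
         dnorm(qnorm(proportion, lower.tail = FALSE)) / proportion)
}

#' Additive and dominance variance of the major locus
#'
#' Under Hardy–Weinberg proportions the locus contributes additive variance
#' 2pq alpha^2 with average effect alpha = a + d(q − p), and dominance
#' variance (2pq d)^2.
#'
#' @param locus a [locus_model()].
#' @param p optional frequency overriding `locus$p` (vectorized).
#' @return data frame with `p`, `alpha`, `var_additive`, `var_dominance`.
#' @export
locus_variances <- function(locus, p = locus$p) {
  stopifnot(inherits(locus, "locus_model"), all(p >= 0), all(p <= 1))
  q <- 1 - p
  alpha <- locus$a + locus$d * (q - p)
  data.frame(p = p, alpha = alpha,
             var_additive = 2 * p * q * alpha^2,
             var_dominance = (2 * p * q * locus$d)^2)
}

#' Population mean contribution of the major locus
#'
#' M(p) = q^2 v_GG + 2pq v_CG + p^2 v_CC under Hardy–Weinberg proportions.
#'
#' @inheritParams locus_variances
#' @return numeric mean genotypic value (vectorized over `p`).
#' @export
mean_genotypic_value <- function(locus, p = locus$p) {
  stopifnot(inherits(locus, "locus_model"), all(p >= 0), all(p <= 1))
  q <- 1 - p
  v <- locus$values
  q^2 * v[1L] + 2 * p * q * v[2L] + p^2 * v[3L]
}

#' One-generation allele-frequency change under mass selection
#'
#' The classical single-locus approximation for truncation selection on the
#' phenotype: delta p = i p q alpha / sigma_P, with average effect
#' alpha = a + d(q − p). A negative intensity encodes downward selection.
#' The result is clipped so that p + delta p stays in \[0, 1\].
#'
#' @param locus a [locus_model()].
#' @param intensity selection intensity i (sign gives the direction).
#' @param sigma_p phenotypic standard deviation of the selected trait.
#' @param p optional frequency overriding `locus$p`.
#' @return delta p.
#' @export
delta_p <- function(locus, intensity, sigma_p, p = locus$p) {
  stopifnot(inherits(locus, "locus_model"))
  if (!is.finite(sigma_p) || sigma_p <= 0) stop("sigma_p must be > 0")
  stopifnot(all(p >= 0), all(p <= 1))
  q <- 1 - p
  alpha <- locus$a + locus$d * (q - p)
  dp <- intensity * p * q * alpha / sigma_p
  pmin(pmax(p + dp, 0), 1) - p
}

#' Deterministic allele-frequency trajectory under recurrent mass selection
#'
#' Iterates [delta_p()] over generations, recomputing the average effect each
#' step and re-imposing Hardy–Weinberg proportions (random mating within
#' line). Records the locus variances and mean genotypic value along the
#' path. By default the phenotypic SD is held at its base value; the
#' approximation supplies no update rule for eroding variance.
#'
#' @param locus a [locus_model()] giving the base frequency and effects.
#' @param intensities per-generation selection intensity, recycled to
#'   `generations` (already sex-averaged; see [design_intensities()]).
#' @param sigma_p base phenotypic standard deviation.
#' @param generations number of selection steps.
#' @param direction `"up"` (favouring C) or `"down"`.
#' @return data frame of class `locus_trajectory`: `generation` (0 =
#'   base), `p`, `alpha`, `var_additive`, `var_dominance`, `locus_mean`,
#'   `locus_response` (cumulative change in locus mean).
#' @examples
#' loc <- locus_model(0.45, c(0, 0.49, 0.44))
#' allele_trajectory(loc, 1.5, sqrt(1.85), 7, "up")
#' @export
allele_trajectory <- function(locus, intensities, sigma_p, generations,
                              direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(generations >= 1)
  intensities <- rep_len(abs(intensities), generations)
  sgn <- if (direction == "up") 1 else -1
  p <- numeric(generations + 1L)
  p[1L] <- locus$p
  for (t in seq_len(generations))
    p[t + 1L] <- p[t] + delta_p(locus, sgn * intensities[t], sigma_p, p = p[t])
  lv <- locus_variances(locus, p = p)
  m <- mean_genotypic_value(locus, p = p)
  out <- data.frame(generation = 0:generations, p = p, alpha = lv$alpha,
                    var_additive = lv$var_additive,
                    var_dominance = lv$var_dominance,
                    locus_mean = m, locus_response = m - m[1L])
  class(out) <- c("locus_trajectory", "data.frame")
  out
}

#' Sex-averaged selection intensities from a breeding design
#'
#' Converts per-generation candidate counts and the numbers of selected sires
#' and dams per line into sex-averaged selection intensities
#' i = (i_male + i_female)/2, the half-sum of the parental selection
#' pathways. For the first selection round both lines draw on the common
#' base population (`base_candidates`, per sex); afterwards candidates are
#' the previous generation of the line, split equally between the sexes.
#'
#' @param generation_sizes total born per generation across both lines
#'   (length = number of selection rounds); defaults to the study design.
#' @param n_sires,n_dams parents selected per line per generation.
#' @param base_candidates named counts `c(male = , female = )` available in
#'   the base population.
#' @return data frame with `generation`, per-sex proportions and intensities,
#'   and the sex-averaged `intensity`.
#' @export
design_intensities <- function(generation_sizes = default_generation_sizes(),
                               n_sires = 25, n_dams = 50,
                               base_candidates = c(male = 1756, female = 3099)) {
  g <- length(generation_sizes)
  cand_m <- c(base_candidates[["male"]], generation_sizes[-g] / 4)
  cand_f <- c(base_candidates[["female"]], generation_sizes[-g] / 4)
  pm <- pmin(n_sires / cand_m, 1)
  pf <- pmin(n_dams / cand_f, 1)
  data.frame(generation = seq_len(g),
             prop_male = pm, prop_female = pf,
             i_male = selection_intensity(pm),
             i_female = selection_intensity(pf),
             intensity = (selection_intensity(pm) + selection_intensity(pf)) / 2)
}

#' Per-generation population totals of the reference breeding design
#'
#' Total number of birds born per selection generation, both lines combined.
#'
#' @return integer vector of length 7.
#' @export
default_generation_sizes <- function() {
  c(946L, 820L, 526L, 915L, 1135L, 707L, 974L)
}

#' Expected cumulative polygenic response to mass selection
#'
#' The breeder's-equation prediction per generation,
#' `delta G_t = h2 * s_t * sigma_P`, where s_t is the sex-averaged
#' standardized selection differential (or intensity), accumulated over
#' generations.
#'
#' @param differentials per-generation standardized differentials (already
#'   sex-averaged), recycled if scalar.
#' @param h2 heritability.
#' @param sigma2_p phenotypic variance.
#' @param generations number of generations (defaults to
#'   `length(differentials)`).
#' @return data frame with `generation`, `delta_g`, `cumulative`.
#' @export
expected_response <- function(differentials, h2, sigma2_p,
                              generations = length(differentials)) {
  stopifnot(h2 >= 0, h2 <= 1, sigma2_p > 0, generations >= 1)
  s <- rep_len(differentials, generations)
  dg <- h2 * s * sqrt(sigma2_p)
  data.frame(generation = seq_len(generations), delta_g = dg,
             cumulative = cumsum(dg))
}

#' Decompose a total genetic trend into major-locus and polygenic parts
#'
#' The locus part is the change in Hardy–Weinberg mean genotypic value,
#' M(p_t) − M(p_0); the polygenic part is the remainder of the total trend.
#' The two parts reconstruct the total exactly by construction.
#'
#' @param p0,p_t allele frequencies at the start and end of the period.
#' @param locus a [locus_model()] (its own `p` is ignored).
#' @param total_trend total genetic change in trait units over the period.
#' @return named numeric vector `c(locus = , polygenic = )`.
#' @examples
#' igm <- locus_model(0.45, c(0, 1.01, 1.12))
#' locus_response_split(0.45, 0.04, igm, total_trend = -1.60)
#' @export
locus_response_split <- function(p0, p_t, locus, total_trend) {
  stopifnot(p0 >= 0, p0 <= 1, p_t >= 0, p_t <= 1)
  lp <- mean_genotypic_value(locus, p = p_t) - mean_genotypic_value(locus, p = p0)
  c(locus = lp, polygenic = total_trend - lp)
}

#' Linear-scale fold change of a log2 titer difference
#'
#' Titers are log2 dilutions, so a difference of `delta` titer points is a
#' `2^delta`-fold difference on the linear scale.
#'
#' @param delta_log2_titer difference in titer points.
#' @return fold change.
#' @examples
#' fold_change(2.39)  # ~5.2
#' @export
fold_change <- function(delta_log2_titer) 2^delta_log2_titer
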