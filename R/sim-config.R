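#' Trait architecture specification
#'
#' Variance components and fixed shifts of one log2-titer trait as used
#' generatively by the simulator. Defaults follow the reference design for
#' the three KLH-binding antibody isotypes: the phenotypic variance excluding
#' plate and major-locus contributions is `sigma2_A + sigma2_m + sigma2_e`
#' (IgM: 0.345 + 0.0345 + 0.7705 = 1.15, i.e. h2 = 0.30, m2 = 0.03).
#'
#' @param name trait name.
#' @param mean intercept on the titer scale.
#' @param sigma2_A polygenic additive variance.
#' @param sigma2_m maternal environmental variance.
#' @param sigma2_e residual variance.
#' @param sigma2_plate between-ELISA-plate variance.
#' @param sex_effect additive shift for males, in titer points.
#' @return list of class `trait_spec`.
#' @export
trait_spec <- function(name, mean = 0, sigma2_A, sigma2_m, sigma2_e,
                       sigma2_plate = 0, sex_effect = 0) {
  stopifnot(sigma2_A >= 0, sigma2_m >= 0, sigma2_e >= 0, sigma2_plate >= 0)
  structure(list(name = name, mean = mean, sigma2_A = sigma2_A,
                 sigma2_m = sigma2_m, sigma2_e = sigma2_e,
                 sigma2_plate = sigma2_plate, sex_effect = sex_effect),
            class = "trait_spec")
}

default_traits <- function() {
  # plate variance back-computed from the share of total variance explained
  # when plate is fitted random: 18/22/14 % for IgM/IgTotal/IgG
  list(
    IgM = trait_spec("IgM", mean = 7.10, sigma2_A = 0.345,
                     sigma2_m = 0.0345, sigma2_e = 0.7705,
                     sigma2_plate = 0.18 / 0.82 * 1.15, sex_effect = -0.13),
    IgG = trait_spec("IgG", mean = 6.16, sigma2_A = 0.234,
                     sigma2_m = 0.039, sigma2_e = 1.677,
                     sigma2_plate = 0.14 / 0.86 * 1.95, sex_effect = 0),
    IgTotal = trait_spec("IgTotal", mean = 6.89, sigma2_A = 0.222,
                         sigma2_m = 0.0555, sigma2_e = 1.5725,
                         sigma2_plate = 0.22 / 0.78 * 1.85, sex_effect = 0)
  )
}

#' Major-locus specification for the simulator
#'
#' @param p0 base-population frequency of the C allele.
#' @param values named list of per-trait genotype values `c(GG, CG, CC)`.
#'   Defaults are the estimated effects of the major toll-like-receptor
#'   polymorphism on the three isotypes.
#' @return list of class `locus_spec`.
#' @export
locus_spec <- function(p0 = 0.45,
                       values = list(IgM = c(0, 1.01, 1.12),
                                     IgG = c(0, 0.22, 0.07),
                                     IgTotal = c(0, 0.49, 0.44))) {
  stopifnot(p0 >= 0, p0 <= 1, is.list(values),
            all(vapply(values, length, 1L) == 3L))
  structure(list(p0 = p0, values = values), class = "locus_spec")
}

#' Cross-trait correlation structure for multivariate simulation
#'
#' Correlation matrices for the additive, maternal environmental and
#' residual effects across the traits (order: IgM, IgG, IgTotal for the
#' defaults). Each must be symmetric positive semi-definite with unit
#' diagonal. Default residual correlations are chosen so that, with the
#' default variances, the implied phenotypic correlations match the
#' reference estimates (0.30 IgM–IgG, 0.54 IgM–IgTotal, 0.84 IgG–IgTotal);
#' the IgM–IgG residual correlation itself is the reported 0.21.
#'
#' @param additive,maternal,residual correlation matrices with dimnames
#'   matching the trait names.
#' @return list of class `genetic_correlations`.
#' @export
genetic_correlations <- function(additive = NULL, maternal = NULL,
                                 residual = NULL) {
  tn <- c("IgM", "IgG", "IgTotal")
  mk <- function(x) matrix(x, 3, 3, dimnames = list(tn, tn))
  if (is.null(additive))
    additive <- mk(c(1, 0.77, 0.91, 0.77, 1, 0.94, 0.91, 0.94, 1))
  if (is.null(maternal))
    maternal <- mk(c(1, 0.41, 0.65, 0.41, 1, 0.87, 0.65, 0.87, 1))
  if (is.null(residual))
    residual <- mk(c(1, 0.21, 0.461, 0.21, 1, 0.826, 0.461, 0.826, 1))
  for (m in list(additive, maternal, residual)) {
    stopifnot(isSymmetric(unname(m)), all(abs(diag(m) - 1) < 1e-12))
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  }
  structure(list(additive = additive, maternal = maternal,
                 residual = residual), class = "genetic_correlations")
}

#' Simulation configuration for the divergent breeding design
#'
#' Full parametrization of the two-line divergent mass-selection experiment:
#' a base population, then `generations` rounds of within-line truncation
#' selection of `n_sires` males and `n_dams` females on the criterion trait
#' (High line: highest titers; Low line: lowest), each sire mated to
#' `mating_ratio` dams while avoiding full- and half-sib matings.
#'
#' @param n_base base-population size.
#' @param generations number of selection generations.
#' @param n_sires,n_dams parents selected per line per generation.
#' @param mating_ratio dams per sire.
#' @param generation_sizes target total born per generation (both lines
#'   combined); recycled to `generations`.
#' @param base_female_prop proportion of females in the base population
#'   (the reference base had 3099 of 4855 female); later generations are
#'   50/50 in expectation.
#' @param plate_size samples per ELISA plate.
#' @param traits list of [trait_spec()] objects (named by trait).
#' @param locus a [locus_spec()].
#' @param correlations optional [genetic_correlations()]; when supplied,
#'   additive, maternal and residual effects are drawn jointly across traits.
#' @param selection_criterion trait selected on.
#' @param base_plate_confounded if `TRUE`, base-population plates are
#'   single-sex (the confounded historical layout); default mixes sexes and,
#'   from generation 1 on, lines within plate.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_base = 4855L,
                       generations = 7L,
                       n_sires = 25L,
                       n_dams = 50L,
                       mating_ratio = 2L,
                       generation_sizes = default_generation_sizes(),
                       base_female_prop = 3099 / 4855,
                       plate_size = 20L,
                       traits = default_traits(),
                       locus = locus_spec(),
                       correlations = NULL,
                       selection_criterion = "IgTotal",
                       base_plate_confounded = FALSE) {
  stopifnot(n_base > 0, generations >= 1, n_sires > 0, n_dams > 0,
            mating_ratio >= 1, plate_size > 0,
            n_dams <= n_sires * mating_ratio)
  generation_sizes <- rep_len(generation_sizes, generations)
  if (is.null(names(traits)))
    names(traits) <- vapply(traits, `[[`, "", "name")
  if (!selection_criterion %in% names(traits))
    stop("selection_criterion '", selection_criterion, "' is not a trait")
  if (!is.null(correlations)) {
    stopifnot(inherits(correlations, "genetic_correlations"))
    if (!all(names(traits) %in% rownames(correlations$additive)))
      stop("correlation matrices must cover all traits")
  }
  missing_vals <- setdiff(names(traits), names(locus$values))
  if (length(missing_vals))
    for (tn in missing_vals) locus$values[[tn]] <- c(0, 0, 0)
  structure(list(n_base = as.integer(n_base),
                 generations = as.integer(generations),
                 n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
                 mating_ratio = as.integer(mating_ratio),
                 generation_sizes = as.integer(round(generation_sizes)),
                 base_female_prop = base_female_prop,
                 plate_size = as.integer(plate_size),
                 traits = traits, locus = locus,
                 correlations = correlations,
                 selection_criterion = selection_criterion,
                 base_plate_confounded = base_plate_confounded),
            class = "sim_config")
}

#' Read a simulation / pipeline configuration from JSON
#'
#' Recognizes top-level blocks `sim` (fields of [sim_config()], with
#' `traits` as a named list of [trait_spec()] fields and `locus` as
#' [locus_spec()] fields), `theory`, `models`, `replicates` and `seed`.
#'
#' @param file path to a JSON file.
#' @return list with a validated `sim` element plus the remaining blocks.
#' @export
read_config <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  sim_args <- cfg$sim
  if (!is.null(sim_args)) {
    if (!is.null(sim_args$traits))
      sim_args$traits <- lapply(names(sim_args$traits), function(tn)
        do.call(trait_spec, c(list(name = tn),
                              sim_args$traits[[tn]][setdiff(names(sim_args$traits[[tn]]), "name")])))
    if (!is.null(sim_args$locus))
      sim_args$locus <- do.call(locus_spec, sim_args$locus)
    cfg$sim <- do.call(sim_config, sim_args)
  } else {
    cfg$sim <- sim_config()
  }
  cfg
}
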