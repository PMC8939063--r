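# Shared fixtures: small configurations and simulation oracles.

# IgM-only configuration; locus effects optional (zeroed by default so that
# variance-component recovery is against the pure polygenic architecture)
igm_config <- function(n_base = 400, generations = 2,
                       generation_sizes = rep(300, generations),
                       n_sires = 15, n_dams = 30,
                       locus_values = c(0, 0, 0), p0 = 0.45,
                       sigma2_plate = 0.25, criterion = "IgM") {
  sim_config(
    n_base = n_base, generations = generations,
    generation_sizes = generation_sizes,
    n_sires = n_sires, n_dams = n_dams,
    traits = list(IgM = trait_spec("IgM", mean = 7, sigma2_A = 0.345,
                                   sigma2_m = 0.0345, sigma2_e = 0.7705,
                                   sigma2_plate = sigma2_plate,
                                   sex_effect = -0.13)),
    locus = locus_spec(p0 = p0, values = list(IgM = locus_values)),
    selection_criterion = criterion)
}

# two-trait configuration with the default cross-trait correlations
pair_config <- function(traits = c("IgM", "IgTotal"), n_base = 500,
                        generations = 2, generation_sizes = rep(550, generations),
                        n_sires = 20, n_dams = 40, with_locus = FALSE) {
  all_tr <- default_traits()[traits]
  gc <- genetic_correlations()
  sub <- function(m) m[traits, traits]
  gc$additive <- sub(gc$additive)
  gc$maternal <- sub(gc$maternal)
  gc$residual <- sub(gc$residual)
  vals <- if (with_locus) locus_spec()$values[traits] else
    setNames(rep(list(c(0, 0, 0)), length(traits)), traits)
  sim_config(n_base = n_base, generations = generations,
             generation_sizes = generation_sizes,
             n_sires = n_sires, n_dams = n_dams,
             traits = all_tr,
             locus = locus_spec(values = vals),
             correlations = gc,
             selection_criterion = traits[2L])
}

assign_plates_for_test <- function(n, plate_size) {
  sprintf("P%03d", ceiling(seq_len(n) / plate_size))
}

# random pedigree: founders plus g generations of random matings
random_pedigree <- function(n_founders = 10, g = 3, per_gen = 10, seed = 1) {
  set.seed(seed)
  animal <- sprintf("F%02d", seq_len(n_founders))
  sire <- dam <- rep(NA_character_, n_founders)
  sex <- rep(c("male", "female"), length.out = n_founders)
  gen <- rep(0L, n_founders)
  for (t in seq_len(g)) {
    males <- animal[sex == "male" & gen == t - 1L]
    females <- animal[sex == "female" & gen == t - 1L]
    if (t == 1L) {
      males <- animal[sex == "male"]
      females <- animal[sex == "female"]
    }
    for (i in seq_len(per_gen)) {
      id <- sprintf("G%d_%02d", t, i)
      animal <- c(animal, id)
      sire <- c(sire, sample(males, 1))
      dam <- c(dam, sample(females, 1))
      sex <- c(sex, sample(c("male", "female"), 1))
      gen <- c(gen, t)
    }
  }
  build_pedigree(data.frame(animal = animal, sire = sire, dam = dam,
                            sex = sex, generation = gen, line = "base"))
}

# gene-dropping Monte-Carlo estimate of additive relationships: drop two
# distinct alleles per founder, transmit one random parental allele per
# locus replicate; a_ij = 2 * P(random allele of i IBD to random allele of j)
gene_drop_A <- function(ped, n_rep = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  al1 <- matrix(0L, n_rep, n)
  al2 <- matrix(0L, n_rep, n)
  next_id <- 1L
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]
    d <- ped$dam_idx[i]
    if (s == 0L) {
      al_s <- matrix(rep(c(next_id, next_id + 1L), each = n_rep), n_rep, 2)
      next_id <- next_id + 2L
    } else {
      pick <- runif(n_rep) < 0.5
      al_s <- cbind(ifelse(pick, al1[, s], al2[, s]), 0L)
    }
    if (d == 0L) {
      al_d <- matrix(rep(c(next_id, next_id + 1L), each = n_rep), n_rep, 2)
      next_id <- next_id + 2L
    } else {
      pick <- runif(n_rep) < 0.5
      al_d <- cbind(ifelse(pick, al1[, d], al2[, d]), 0L)
    }
    al1[, i] <- al_s[, 1L]
    al2[, i] <- al_d[, 1L]
  }
  list(al1 = al1, al2 = al2)
}

# pairwise relationship estimate and its Monte-Carlo SE from a gene drop
gene_drop_pair <- function(gd, i, j) {
  # kinship: P(random allele from i == random allele from j)
  p <- (  (gd$al1[, i] == gd$al1[, j]) + (gd$al1[, i] == gd$al2[, j])
        + (gd$al2[, i] == gd$al1[, j]) + (gd$al2[, i] == gd$al2[, j])) / 4
  m <- mean(p)
  list(a = 2 * m, se = 2 * sd(p) / sqrt(length(p)))
}

# balanced paternal half-sib layout for the ANOVA-oracle checks
balanced_halfsib <- function(ns = 60, k = 15, s2A = 0.4, s2e = 0.6,
                             seed = 1) {
  set.seed(seed)
  sires <- sprintf("S%03d", seq_len(ns))
  prog <- data.frame(animal = sprintf("P%04d", seq_len(ns * k)),
                     sire = rep(sires, each = k), dam = 0)
  ped <- build_pedigree(rbind(data.frame(animal = sires, sire = 0, dam = 0),
                              prog))
  u <- rnorm(ns, 0, sqrt(s2A))
  y <- 5 + 0.5 * rep(u, each = k) + rnorm(ns * k, 0, sqrt(s2e + 0.75 * s2A))
  list(ped = ped,
       data = data.frame(animal = prog$animal, dam = NA, sex = "male",
                         y = y),
       sire = prog$sire)
}

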