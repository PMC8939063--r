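# Oracles: closed-form ANOVA on balanced half-sib families, a dense-matrix
# evaluation of the restricted log-likelihood, and GLS at fixed components.

dense_reml_logL <- function(data, ped, fixed, th, response = "IgM") {
  y <- data[[response]]
  X <- as.matrix(nabsel:::build_fixed(data, fixed))
  A <- relationship_matrix(ped)$a_matrix
  Za <- matrix(0, nrow(data), nrow(ped))
  Za[cbind(seq_len(nrow(data)), match(data$animal, ped$animal))] <- 1
  dl <- nabsel:::dam_levels(data)
  Zm <- matrix(0, nrow(data), nlevels(dl))
  Zm[cbind(seq_len(nrow(data)), as.integer(dl))] <- 1
  V <- th[["additive"]] * Za %*% A %*% t(Za) +
    th[["maternal_env"]] * tcrossprod(Zm) +
    th[["residual"]] * diag(nrow(data))
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  n <- nrow(data); p <- ncol(X)
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                     determinant(V, TRUE)$modulus +
                     determinant(XVX, TRUE)$modulus +
                     t(y) %*% P %*% y -
                     determinant(crossprod(X), TRUE)$modulus))
}

test_that("REML equals the ANOVA estimator on balanced half-sib data", {
  hs <- balanced_halfsib(ns = 100, k = 20, seed = 4)
  av <- anova(lm(hs$data$y ~ factor(hs$sire)))
  s2s_anova <- (av$"Mean Sq"[1] - av$"Mean Sq"[2]) / 20
  fit <- fit_animal_model(hs$data, hs$ped,
                          model_spec("y", fixed = character(0),
                                     random = "additive"), se = FALSE)
  expect_equal(fit$components[["sigma2_A"]] / 4, s2s_anova, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("the restricted log-likelihood matches a dense-matrix oracle", {
  cfg <- igm_config(n_base = 120, generations = 2,
                    generation_sizes = c(120, 120), n_sires = 8, n_dams = 16)
  sim <- run_experiment(cfg, seed = 11)
  for (th in list(c(additive = 0.3, maternal_env = 0.05, residual = 0.8),
                  c(additive = 0.6, maternal_env = 0.01, residual = 0.5))) {
    f <- fit_animal_model(sim$phenotypes, sim$pedigree,
                          model_spec("IgM", fixed_variances = th), se = FALSE)
    expect_equal(f$logL,
                 dense_reml_logL(sim$phenotypes, sim$pedigree,
                                 c("plate", "sex"), th),
                 tolerance = 1e-6)
  }
})

test_that("logL is invariant to the fixed-effect parameterization", {
  cfg <- igm_config(n_base = 120, generations = 1, generation_sizes = 120,
                    n_sires = 8, n_dams = 16)
  sim <- run_experiment(cfg, seed = 12)
  th <- c(additive = 0.35, maternal_env = 0.03, residual = 0.77)
  f1 <- fit_animal_model(sim$phenotypes, sim$pedigree,
                         model_spec("IgM", fixed_variances = th), se = FALSE)
  # relabel plate levels: reverses the dummy coding (different baseline)
  dat2 <- sim$phenotypes
  dat2$plate <- factor(dat2$plate,
                       levels = rev(sort(unique(as.character(dat2$plate)))))
  f2 <- fit_animal_model(dat2, sim$pedigree,
                         model_spec("IgM", fixed_variances = th), se = FALSE)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-6)
})

test_that("aliased fixed effects raise a singularity error naming columns", {
  cfg <- igm_config(n_base = 80, generations = 1, generation_sizes = 80,
                    n_sires = 6, n_dams = 12)
  sim <- run_experiment(cfg, seed = 13)
  expect_error(fit_animal_model(sim$phenotypes, sim$pedigree,
                                model_spec("IgM", fixed = c("plate", "generation"))),
               "aliased with 'plate'")
  # a duplicated column is also caught by the rank check
  dat <- sim$phenotypes
  dat$genotype <- "CG"   # constant carrier indicator aliases the intercept
  expect_error(fit_animal_model(dat, sim$pedigree,
                                model_spec("IgM", fixed = c("sex", "genotype2"))),
               "aliased")
})

test_that("h2 and m2 are recovered from data simulated under the model", {
  cfg <- igm_config(n_base = 500, generations = 3,
                    generation_sizes = rep(450, 3), n_sires = 20, n_dams = 40)
  res <- sapply(1:4, function(r) {
    sim <- run_experiment(cfg, seed = 400 + r)
    fit <- fit_animal_model(sim$phenotypes, sim$pedigree, model_spec("IgM"),
                            se = FALSE)
    vc_ratios(fit)$estimate
  })
  se_h2 <- sd(res[1, ]) / 2
  expect_lt(abs(mean(res[1, ]) - 0.30), 2 * se_h2 + 0.02)
  expect_lt(abs(mean(res[2, ]) - 0.03), 2 * sd(res[2, ]) / 2 + 0.01)
})

test_that("ratios follow the definition with delta-method edge cases", {
  r <- vc_ratios(c(additive = 0.345, maternal_env = 0.0345,
                   residual = 0.7705))
  expect_equal(r$estimate[r$ratio == "h2"], 0.30)
  expect_equal(r$estimate[r$ratio == "m2"], 0.03)
  expect_equal(vc_ratios(c(additive = 0, maternal_env = 0.2,
                           residual = 0.8))$estimate[1], 0)
  expect_equal(vc_ratios(c(additive = 0.7, maternal_env = 0,
                           residual = 0))$estimate[1], 1)
  expect_error(vc_ratios(c(additive = 0, maternal_env = 0, residual = 0)),
               "zero total")
})

test_that("component SEs come from the curvature of the likelihood", {
  cfg <- igm_config(n_base = 300, generations = 2,
                    generation_sizes = c(250, 250), n_sires = 12, n_dams = 24)
  sim <- run_experiment(cfg, seed = 15)
  fit <- fit_animal_model(sim$phenotypes, sim$pedigree, model_spec("IgM"),
                          se = TRUE)
  expect_true(all(is.finite(fit$vc_se[fit$free])))
  r <- vc_ratios(fit)
  expect_true(all(is.finite(r$se)))
  expect_true(all(r$se > 0 & r$se < 0.5))
})

test_that("likelihood-ratio tests follow the chi-square tail", {
  expect_equal(lrt(10, 10, 1)$lr, 0)
  expect_equal(lrt(10, 10, 1)$p_value, 1)
  expect_lt(lrt(13.15, 0, 1)$p_value, 0.001)           # LR = 26.3
  expect_equal(lrt(3.25, 0, 2)$p_value, exp(-6.5 / 2), # LR = 6.5, 2 df
               tolerance = 1e-12)
  expect_equal(round(lrt(3.25, 0, 2)$p_value, 2), 0.04)
  expect_equal(lrt(5, 8, 1)$lr, 0)                     # clipped at zero
  expect_error(lrt(1, 0, 0), "df")
})

test_that("the LRT statistic is invariant to data scaling", {
  cfg <- igm_config(n_base = 150, generations = 1, generation_sizes = 150,
                    n_sires = 8, n_dams = 16)
  sim <- run_experiment(cfg, seed = 16)
  spec1 <- model_spec("IgM")
  spec2 <- model_spec("IgM", random = "additive")
  f1 <- fit_animal_model(sim$phenotypes, sim$pedigree, spec1, se = FALSE)
  f2 <- fit_animal_model(sim$phenotypes, sim$pedigree, spec2, se = FALSE)
  dat3 <- sim$phenotypes
  dat3$IgM <- dat3$IgM * 3.7
  g1 <- fit_animal_model(dat3, sim$pedigree, spec1, se = FALSE)
  g2 <- fit_animal_model(dat3, sim$pedigree, spec2, se = FALSE)
  expect_equal(lrt(f1, f2, 1)$lr, lrt(g1, g2, 1)$lr, tolerance = 1e-3)
})

test_that("fixed components give exact GLS fixed effects and BLUP", {
  cfg <- igm_config(n_base = 100, generations = 1, generation_sizes = 100,
                    n_sires = 6, n_dams = 12)
  sim <- run_experiment(cfg, seed = 17)
  th <- c(additive = 0.345, maternal_env = 0.0345, residual = 0.7705)
  fit <- fit_animal_model(sim$phenotypes, sim$pedigree,
                          model_spec("IgM", fixed_variances = th), se = FALSE)
  # dense GLS oracle
  dat <- sim$phenotypes
  X <- as.matrix(nabsel:::build_fixed(dat, c("plate", "sex")))
  A <- relationship_matrix(sim$pedigree)$a_matrix
  Za <- matrix(0, nrow(dat), nrow(sim$pedigree))
  Za[cbind(seq_len(nrow(dat)), match(dat$animal, sim$pedigree$animal))] <- 1
  dl <- nabsel:::dam_levels(dat)
  Zm <- matrix(0, nrow(dat), nlevels(dl))
  Zm[cbind(seq_len(nrow(dat)), as.integer(dl))] <- 1
  V <- th[1] * Za %*% A %*% t(Za) + th[2] * tcrossprod(Zm) +
    th[3] * diag(nrow(dat))
  Vi <- solve(V)
  beta_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% dat$IgM)
  expect_equal(fit$fixed_effects$estimate, as.numeric(beta_gls),
               tolerance = 1e-8)
  # BLUP of breeding values at the same components
  u_blup <- th[1] * A %*% t(Za) %*% Vi %*%
    (dat$IgM - X %*% beta_gls)
  expect_equal(unname(fit$ebv), as.numeric(u_blup), tolerance = 1e-8)
})

test_that("EBVs center near zero in the base generation of a fresh fit", {
  cfg <- igm_config(n_base = 400, generations = 2,
                    generation_sizes = c(350, 350), n_sires = 15, n_dams = 30)
  sim <- run_experiment(cfg, seed = 18)
  fit <- fit_animal_model(sim$phenotypes, sim$pedigree, model_spec("IgM"),
                          se = FALSE)
  tr <- genetic_trend(fit)
  sA <- sqrt(fit$components[["sigma2_A"]])
  expect_lt(abs(tr$mean_ebv[tr$line == "base"]), 0.25 * sA)
  # constant EBVs give a flat trend
  fit2 <- fit
  fit2$ebv[] <- 1.3
  tr2 <- genetic_trend(fit2)
  expect_true(all(tr2$mean_ebv == 1.3))
})

test_that("divergent selection shows opposite EBV trends", {
  cfg <- igm_config(n_base = 500, generations = 3,
                    generation_sizes = rep(400, 3), n_sires = 20, n_dams = 40,
                    locus_values = c(0, 1.01, 1.12))
  ok <- sapply(1:3, function(r) {
    sim <- run_experiment(cfg, seed = 700 + r)
    fit <- fit_animal_model(sim$phenotypes, sim$pedigree, model_spec("IgM"),
                            se = FALSE)
    tr <- genetic_trend(fit)
    hi <- tr$mean_ebv[tr$line == "high"][-1]
    lo <- tr$mean_ebv[tr$line == "low"][-1]
    tail(hi, 1) > 0 && tail(lo, 1) < 0 && all(diff(hi) > -0.05) &&
      all(diff(lo) < 0.05)
  })
  expect_true(all(ok))
})

test_that("genotype contrasts reparametrize the class effects", {
  cfg <- igm_config(n_base = 400, generations = 3,
                    generation_sizes = rep(400, 3), n_sires = 18, n_dams = 36,
                    locus_values = c(0, 1.01, 1.12))
  sim <- run_experiment(cfg, seed = 19)
  sub <- sim$phenotypes[sim$phenotypes$generation >= 2, ]
  th <- c(additive = 0.345, maternal_env = 0.0345)
  fit <- fit_animal_model(sub, sim$pedigree,
                          model_spec("IgM",
                                     fixed = c("plate", "sex", "line",
                                               "genotype3"),
                                     fixed_variances = th), se = FALSE)
  gc_ <- genotype_contrasts(fit)
  fe <- fit$fixed_effects
  cg <- fe$estimate[fe$term == "genotypeCG"]
  cc <- fe$estimate[fe$term == "genotypeCC"]
  expect_equal(gc_$estimate[gc_$effect == "additive"], cc / 2)
  expect_equal(gc_$estimate[gc_$effect == "dominance"], cg - cc / 2)
  # recovered within sampling error of the generating values
  expect_lt(abs(cg - 1.01), 3 * fe$se[fe$term == "genotypeCG"] + 0.05)
  # arithmetic on the generating values themselves
  expect_equal(locus_model(0.45, c(0, 1.01, 1.12))$a, 0.56)
  expect_equal(locus_model(0.45, c(0, 1.01, 1.12))$d, 0.45)

  # 2-class fit refuses contrasts with a pointer to the dominant coding
  fit2 <- fit_animal_model(sub, sim$pedigree,
                           model_spec("IgM",
                                      fixed = c("plate", "sex", "genotype2"),
                                      fixed_variances = th), se = FALSE)
  expect_error(genotype_contrasts(fit2), "dominant")
})

test_that("interaction fits test the block and report simple effects", {
  cfg <- igm_config(n_base = 400, generations = 2,
                    generation_sizes = c(400, 400), n_sires = 18, n_dams = 36,
                    locus_values = c(0, 1.0, 1.0))
  sim <- run_experiment(cfg, seed = 20)
  dat <- sim$phenotypes[sim$phenotypes$generation >= 1, ]
  th <- c(additive = 0.345, maternal_env = 0.0345)
  base_spec <- model_spec("IgM", fixed = c("plate", "sex", "line"),
                          fixed_variances = th)
  # no interaction generated: non-significant at alpha = 0.05 (fixed seed)
  ia <- interaction_fit(dat, sim$pedigree, base_spec, "sex", se = FALSE)
  expect_gt(ia$wald$p_value, 0.05)
  expect_equal(nrow(ia$simple_effects), 2L)

  # sex-specific locus effect is recovered within 2 SE
  dat2 <- dat
  carrier <- dat2$genotype %in% c("CG", "CC")
  dat2$IgM <- dat2$IgM + carrier * ifelse(dat2$sex == "male", 0.15, -0.08)
  ia2 <- interaction_fit(dat2, sim$pedigree, base_spec, "sex", se = FALSE)
  sm <- ia2$simple_effects
  em <- sm$estimate[sm$level == "sexmale"]
  ef <- sm$estimate[sm$level == "female"]
  expect_lt(abs(em - 1.15), 2 * sm$se[sm$level == "sexmale"])
  expect_lt(abs(ef - 0.92), 2 * sm$se[sm$level == "female"])
  # the joint Wald block is the squared z of the single interaction column
  fe2 <- ia2$fit$fixed_effects
  b_int <- fe2$estimate[fe2$term == "carrier:sexmale"]
  expect_equal(em - ef, b_int, tolerance = 1e-10)
  expect_equal(ia2$wald$df, 1L)

  # duplicating the main effect is caught as aliasing
  expect_error(fit_animal_model(dat, sim$pedigree,
                                model_spec("IgM",
                                           fixed = c("plate", "sex",
                                                     "genotype2",
                                                     "genotype2:sex",
                                                     "genotype2:sex"),
                                           fixed_variances = th)),
               "aliased")
})

test_that("maternal genetic effects are detected when present and not invented", {
  cfg <- igm_config(n_base = 400, generations = 3,
                    generation_sizes = rep(350, 3), n_sires = 15, n_dams = 30)
  spec1 <- model_spec("IgM")
  specg <- model_spec("IgM", random = c("additive", "maternal_env",
                                        "maternal_gen"))
  # null data: LRT should rarely reject
  null_rej <- sapply(1:3, function(r) {
    sim <- run_experiment(cfg, seed = 800 + r)
    f1 <- fit_animal_model(sim$phenotypes, sim$pedigree, spec1, se = FALSE)
    fg <- fit_maternal_genetic(sim$phenotypes, sim$pedigree, specg,
                               se = FALSE)
    expect_true(is.finite(fg$r_a_mg) || fg$r_a_mg_flag)
    lrt(fg, f1, 2)$p_value < 0.05
  })
  expect_lte(sum(null_rej), 1)

  # data with substantial maternal genetic variance: inject a dam-BV effect
  power_rej <- sapply(1:3, function(r) {
    sim <- run_experiment(cfg, seed = 900 + r)
    ph <- sim$phenotypes
    tbv_dam <- sim$truth$tbv_IgM[match(ph$dam, sim$truth$animal)]
    extra <- ifelse(is.na(tbv_dam), 0, 0.8 * tbv_dam)
    ph$IgM <- ph$IgM + extra
    f1 <- fit_animal_model(ph, sim$pedigree, spec1, se = FALSE)
    fg <- fit_maternal_genetic(ph, sim$pedigree, specg, se = FALSE)
    lrt(fg, f1, 2)$p_value < 0.05
  })
  expect_gte(sum(power_rej), 2)
})
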