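test_that("base population follows Hardy-Weinberg at the configured frequency", {
  cfg <- igm_config(p0 = 0)
  base <- simulate_base(cfg, seed = 1)
  expect_true(all(base$geno == 0L))

  cfg2 <- igm_config()
  freqs <- sapply(1:20, function(s) {
    b <- simulate_base(sim_config(n_base = 10000, traits = cfg2$traits,
                                  locus = cfg2$locus,
                                  selection_criterion = "IgM"), seed = s)
    c(p = mean(b$geno) / 2, het = mean(b$geno == 1L))
  })
  se_p <- sqrt(0.45 * 0.55 / (2 * 10000)) / sqrt(20)
  expect_lt(abs(mean(freqs["p", ]) - 0.45), 3 * se_p)
  het_exp <- 2 * 0.45 * 0.55
  se_h <- sqrt(het_exp * (1 - het_exp) / 10000) / sqrt(20)
  expect_lt(abs(mean(freqs["het", ]) - het_exp), 3 * se_h)

  cfg3 <- igm_config()
  cfg3$traits$IgM$sigma2_A <- 0
  b0 <- simulate_base(cfg3, seed = 3)
  expect_true(all(b0$bv == 0))
})

test_that("phenotypes decompose into the generative effects", {
  cfg <- igm_config()
  cfg$traits$IgM <- trait_spec("IgM", mean = 7, sigma2_A = 0, sigma2_m = 0,
                               sigma2_e = 0, sigma2_plate = 0,
                               sex_effect = -0.13)
  cfg$locus$values$IgM <- c(0, 0, 0)
  base <- simulate_base(cfg, seed = 5)
  ph <- sim_phenotype(base, cfg, rep("P1", cfg$n_base), seed = 6)
  expect_equal(ph$IgM, 7 - 0.13 * (ph$sex == "male"))

  # full sibs share the identical dam-effect draw
  cfg2 <- igm_config(n_base = 200, generations = 1, generation_sizes = 200,
                     n_sires = 10, n_dams = 20)
  sim <- run_experiment(cfg2, seed = 8)
  off <- sim$phenotypes[sim$phenotypes$generation == 1, ]
  mat <- sim$truth$mat_IgM[match(off$animal, sim$truth$animal)]
  per_dam_sd <- tapply(mat, off$dam, sd)
  expect_true(all(per_dam_sd[!is.na(per_dam_sd)] == 0))

  # an animal set without dam labels errors when sigma2_m > 0
  base_nodam <- base
  base_nodam$mat <- NULL
  cfgm <- igm_config()
  expect_error(sim_phenotype(base_nodam, cfgm, rep("P1", cfg$n_base), 1),
               "maternal")
})

test_that("base phenotypic variance adds up across components", {
  # sigma2_P = sigma2_A + sigma2_m + sigma2_e (= 1.15) + plate + locus
  cfg <- igm_config(locus_values = c(0, 1.01, 1.12), sigma2_plate = 0.25)
  lv <- locus_variances(locus_model(0.45, c(0, 1.01, 1.12)))
  target <- 1.15 + 0.25 + lv$var_additive + lv$var_dominance
  vars <- sapply(1:8, function(s) {
    b <- simulate_base(sim_config(n_base = 5000, traits = cfg$traits,
                                  locus = cfg$locus,
                                  selection_criterion = "IgM"), seed = s)
    ph <- sim_phenotype(b, cfg, assign_plates_for_test(5000, 20), seed = s + 100)
    var(ph$IgM)
  })
  se <- sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - target), 3 * se + 0.02 * target)
})

test_that("truncation selection picks the right tails with stable ties", {
  ph <- data.frame(animal = c("a1", "a2", "a3", "b1", "b2", "b3"),
                   sex = rep(c("male", "female"), each = 3),
                   y = c(5, 3, 1, 2, 4, 6))
  sel <- select_parents(ph, "y", 2, 2, "high")
  expect_setequal(sel$sires, c("a1", "a2"))
  expect_setequal(sel$dams, c("b3", "b2"))
  sel_lo <- select_parents(ph, "y", 2, 2, "low")
  expect_setequal(sel_lo$sires, c("a3", "a2"))

  # tie at the cutoff: stable order on animal id
  tie <- data.frame(animal = c("m2", "m1", "m3"), sex = "male",
                    y = c(1, 1, 0))
  expect_identical(select_parents(tie, "y", 1, 0, "high")$sires, "m1")

  expect_error(select_parents(ph, "y", 4, 1, "high"), "fewer")

  # standardized differential converges to phi(z)/p for 50 % selected
  set.seed(11)
  big <- data.frame(animal = sprintf("x%05d", 1:40000),
                    sex = rep(c("male", "female"), 20000),
                    y = rnorm(40000))
  s <- select_parents(big, "y", 10000, 10000, "high")
  expect_equal(mean(s$differentials$differential), 0.798, tolerance = 0.02)
  # low-direction differentials are sign-flipped to positive
  s2 <- select_parents(big, "y", 10000, 10000, "low")
  expect_gt(min(s2$differentials$differential), 0)
})

test_that("matings avoid full and half sibs whenever feasible", {
  parents <- data.frame(animal = c("s1", "s2", "d1", "d2", "d3", "d4"),
                        sire = NA, dam = NA)
  m <- make_matings(c("s1", "s2"), c("d1", "d2", "d3", "d4"), parents,
                    ratio = 2, seed = 1)
  expect_equal(sort(table(m$sire)), sort(c(s1 = 2L, s2 = 2L)),
               ignore_attr = TRUE)
  expect_setequal(m$dam, c("d1", "d2", "d3", "d4"))

  # a dam full sib to every sire forces the fallback with a warning
  parents2 <- data.frame(animal = c("s1", "d1"),
                         sire = c("F", "F"), dam = c("M", "M"))
  expect_warning(m2 <- make_matings("s1", "d1", parents2, ratio = 1, seed = 2),
                 "least-related")
  expect_equal(nrow(m2), 1L)

  # randomized instances with known feasible sib-free assignments
  for (s in 1:20) {
    set.seed(s)
    fams <- sprintf("fam%d", 1:6)
    sire_fam <- sample(fams, 5, replace = TRUE)
    dam_fam <- sample(fams, 10, replace = TRUE)
    # feasibility guard: each dam family must leave enough non-sib slots
    slots_ok <- all(vapply(unique(dam_fam), function(f)
      sum(dam_fam == f) <= 2 * sum(sire_fam != f), TRUE))
    if (!slots_ok) next
    parents3 <- data.frame(
      animal = c(sprintf("s%d", 1:5), sprintf("d%d", 1:10)),
      sire = paste0("S_", c(sire_fam, dam_fam)),
      dam = paste0("D_", c(sire_fam, dam_fam)))
    m3 <- make_matings(sprintf("s%d", 1:5), sprintf("d%d", 1:10),
                       parents3, ratio = 2, seed = s)
    sf <- sire_fam[match(m3$sire, sprintf("s%d", 1:5))]
    df <- dam_fam[match(m3$dam, sprintf("d%d", 1:10))]
    expect_equal(sum(sf == df), 0)
  }
})

test_that("breeding transmits alleles and polygenes correctly", {
  cfg <- igm_config()
  parents <- list(
    info = data.frame(animal = c("S", "D"), sire = NA, dam = NA,
                      sex = c("male", "female"), generation = 0L,
                      line = "base"),
    geno = c(2L, 0L),
    bv = matrix(c(1, 3), 2, 1, dimnames = list(NULL, "IgM")),
    f = c(0, 0), A = NULL)
  mat <- data.frame(sire = "S", dam = "D")
  off <- breed(mat, parents, cfg, 50, 1, "high", seed = 3)
  expect_true(all(off$geno == 1L))           # CC x GG -> all CG

  # sigma2_A = 0: offspring polygenic value exactly midparent
  cfg0 <- igm_config()
  cfg0$traits$IgM$sigma2_A <- 0
  off0 <- breed(mat, parents, cfg0, 10, 1, "high", seed = 4)
  expect_equal(off0$bv[, 1], rep(2, 10), ignore_attr = TRUE)

  # CG x CG: 1:2:1 within Monte-Carlo error
  parents2 <- parents
  parents2$geno <- c(1L, 1L)
  off2 <- breed(mat, parents2, cfg, 1e5, 1, "high", seed = 7, track_a = FALSE)
  tab <- tabulate(off2$geno + 1L, 3) / 1e5
  se <- sqrt(0.25 * 0.75 / 1e5)
  expect_lt(abs(tab[1] - 0.25), 3 * se)
  expect_lt(abs(tab[2] - 0.50), 3 * sqrt(0.5 * 0.5 / 1e5))
  expect_lt(abs(tab[3] - 0.25), 3 * se)

  # Mendelian-sampling variance shrinks with parental inbreeding
  parents3 <- parents
  parents3$f <- c(0.5, 0.5)
  off3 <- breed(mat, parents3, cfg, 2e4, 1, "high", seed = 6, track_a = FALSE)
  expect_equal(var(off3$bv[, 1]), 0.5 * 0.345 * 0.5, tolerance = 0.02)
})

test_that("the divergent experiment separates lines and respects design sizes", {
  cfg <- igm_config(n_base = 600, generations = 3,
                    generation_sizes = c(420, 380, 400),
                    n_sires = 20, n_dams = 40,
                    locus_values = c(0, 1.01, 1.12))
  sim <- run_experiment(cfg, seed = 17)
  s <- sim$summary
  expect_equal(s$n[s$line == "base"], 600)
  for (g in 1:3)
    expect_equal(sum(s$n[s$generation == g]), cfg$generation_sizes[g])
  # every phenotyped animal is in the pedigree
  expect_true(all(sim$phenotypes$animal %in% sim$pedigree$animal))
  # selection separates the lines at the locus
  expect_lt(s$p_C[s$line == "low" & s$generation == 3],
            s$p_C[s$line == "high" & s$generation == 3])

  # direction holds across replicates
  res <- sapply(1:10, function(r) {
    sm <- run_experiment(cfg, seed = 100 + r)$summary
    c(lo = sm$p_C[sm$line == "low" & sm$generation == 3],
      hi = sm$p_C[sm$line == "high" & sm$generation == 3])
  })
  expect_true(all(res["lo", ] < res["hi", ]))
})

test_that("without selection allele frequencies only drift", {
  cfg <- igm_config(n_base = 400, generations = 3,
                    generation_sizes = rep(300, 3), n_sires = 15, n_dams = 30,
                    locus_values = c(0, 1.01, 1.12))
  dp <- sapply(1:12, function(r) {
    sm <- run_experiment(cfg, seed = 500 + r, random_mating = TRUE)$summary
    mean(sm$p_C[sm$generation == 3]) - sm$p_C[sm$line == "base"]
  })
  se <- sd(dp) / sqrt(length(dp))
  expect_lt(abs(mean(dp)), 3 * se)
})

test_that("identical seeds give byte-identical simulation output", {
  cfg <- igm_config(n_base = 150, generations = 2,
                    generation_sizes = c(140, 140), n_sires = 8, n_dams = 16)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sim(run_experiment(cfg, seed = 33), d1)
  write_sim(run_experiment(cfg, seed = 33), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  d3 <- run_experiment(cfg, seed = 34)
  expect_false(identical(run_experiment(cfg, seed = 33)$phenotypes$IgM,
                         d3$phenotypes$IgM))
})

test_that("ELISA titers pick the dilution nearest half-maximal extinction", {
  r <- elisa_titer(c(1.9, 1.5, 0.8, 0.2), e_max = 1.8)
  expect_equal(r$titer, log2(640), tolerance = 1e-12)
  expect_false(r$endpoint)

  # all extinctions above target: endpoint at the highest dilution
  r2 <- elisa_titer(c(1.9, 1.8, 1.7, 1.6), e_max = 1.8)
  expect_equal(r2$titer, log2(2560))
  expect_true(r2$endpoint)

  # exact tie: lower dilution wins
  r3 <- elisa_titer(c(1.0, 0.8, 0.1, 0.05), e_max = 1.8)
  expect_equal(r3$titer, log2(40))

  expect_error(elisa_titer(numeric(0), 1), "empty")
  expect_error(elisa_titer(c(1, 1, 1, 1), -2), "e_max")
})
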