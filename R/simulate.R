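# Forward-in-time simulator of the divergent mass-selection design.
#
# Internally a cohort is a list with:
#   info : data.frame(animal, sire, dam, sex, generation, line)
#   geno : integer C-allele counts 0/1/2
#   bv   : n x T matrix of true polygenic breeding values
#   mat  : n x T matrix of maternal effects received (shared by full sibs)
#   f    : inbreeding coefficients
#   A    : dense additive relationship matrix among cohort members, or NULL
#          meaning identity (unrelated founders)

trait_sd <- function(traits, field) sqrt(vapply(traits, `[[`, 0, field))

# covariance matrix for one effect type across traits
effect_cov <- function(traits, field, correlations, cor_name) {
  s <- trait_sd(traits, field)
  if (is.null(correlations)) return(diag(s^2, nrow = length(s)))
  R <- correlations[[cor_name]][names(traits), names(traits)]
  diag(s, length(s)) %*% R %*% diag(s, length(s))
}

draw_mvn <- function(n, Sigma) {
  k <- ncol(Sigma)
  if (all(Sigma == 0)) return(matrix(0, n, k))
  ev <- eigen(Sigma, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)
  matrix(rnorm(n * k), n, k) %*% rt
}

#' Simulate the base population
#'
#' Founders with Hardy–Weinberg genotypes at the base C-allele frequency,
#' polygenic breeding values drawn from the additive covariance across
#' traits, per-founder maternal-effect draws (each founder is its own
#' singleton dam family, since its dam is unknown), and sexes at the
#' configured base ratio.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a cohort list (see package internals); `info` holds the pedigree
#'   rows.
#' @export
simulate_base <- function(config, seed = 1L) {
  set.seed(seed)
  n <- config$n_base
  traits <- config$traits
  Sa <- effect_cov(traits, "sigma2_A", config$correlations, "additive")
  Sm <- effect_cov(traits, "sigma2_m", config$correlations, "maternal")
  info <- data.frame(
    animal = sprintf("B%05d", seq_len(n)),
    sire = NA_character_, dam = NA_character_,
    sex = ifelse(runif(n) < config$base_female_prop, "female", "male"),
    generation = 0L, line = "base", stringsAsFactors = FALSE)
  geno <- rbinom(n, 2L, config$locus$p0)
  bv <- draw_mvn(n, Sa)
  mat <- draw_mvn(n, Sm)
  colnames(bv) <- colnames(mat) <- names(traits)
  list(info = info, geno = geno, bv = bv, mat = mat,
       f = numeric(n), A = NULL)
}

#' Generate phenotypes for a set of animals
#'
#' Applies the generative model
#' `y = mean + plate + sex + genotype value + polygenic value + maternal
#' effect + residual` per trait. Plate effects are drawn once per plate and
#' trait (independent across traits: each isotype is assayed in its own
#' ELISA run); residuals are drawn per animal from the residual covariance.
#'
#' @param cohort a cohort list (e.g. from [simulate_base()]).
#' @param config a [sim_config()].
#' @param plate character/factor plate assignment, one entry per animal.
#' @param seed integer seed.
#' @return data frame with columns `animal, sire, dam, sex, line,
#'   generation, plate, genotype` and one column per trait.
#' @export
sim_phenotype <- function(cohort, config, plate, seed = 1L) {
  set.seed(seed)
  traits <- config$traits
  n <- nrow(cohort$info)
  stopifnot(length(plate) == n)
  if (any(vapply(traits, `[[`, 0, "sigma2_m") > 0) && is.null(cohort$mat))
    stop("animals carry no maternal-effect (dam) labels but sigma2_m > 0")
  Se <- effect_cov(traits, "sigma2_e", config$correlations, "residual")
  resid <- draw_mvn(n, Se)
  plate <- as.character(plate)
  plates <- unique(plate)
  out <- cbind(cohort$info[, c("animal", "sire", "dam", "sex")],
               line = cohort$info$line, generation = cohort$info$generation,
               plate = plate,
               genotype = c("GG", "CG", "CC")[cohort$geno + 1L],
               stringsAsFactors = FALSE)
  for (k in seq_along(traits)) {
    tr <- traits[[k]]
    pe <- rnorm(length(plates), 0, sqrt(tr$sigma2_plate))
    names(pe) <- plates
    gv <- config$locus$values[[tr$name]][cohort$geno + 1L]
    out[[tr$name]] <- tr$mean + pe[plate] +
      tr$sex_effect * (cohort$info$sex == "male") + gv +
      cohort$bv[, k] + cohort$mat[, k] + resid[, k]
  }
  rownames(out) <- NULL
  out
}

assign_plates <- function(info, plate_size, generation, seed,
                          by_sex = FALSE) {
  set.seed(seed)
  n <- nrow(info)
  ord <- sample.int(n)
  if (by_sex) ord <- ord[order(info$sex[ord])]  # single-sex plates
  plate <- character(n)
  plate[ord] <- sprintf("G%d_P%03d", generation,
                        ceiling(seq_len(n) / plate_size))
  plate
}

#' Truncation selection of parents on own phenotype
#'
#' Selects the top (direction `"high"`) or bottom (`"low"`) `n_males` males
#' and `n_females` females on the criterion trait, within the candidate set.
#' Ties at the cutoff are resolved by stable ordering on animal id. Realized
#' standardized differentials, `(mean selected − mean candidates)/SD
#' candidates`, are reported per sex with the sign flipped for the Low
#' direction, so that a positive value always means effective selection
#' toward the line's objective.
#'
#' @param phenos data frame with columns `animal`, `sex` and the criterion.
#' @param criterion trait column selected on.
#' @param n_males,n_females numbers to select.
#' @param direction `"high"` or `"low"`.
#' @return list with `sires`, `dams` (animal ids) and `differentials`
#'   (data frame per sex).
#' @export
select_parents <- function(phenos, criterion, n_males, n_females,
                           direction = c("high", "low")) {
  direction <- match.arg(direction)
  y <- phenos[[criterion]]
  if (is.null(y)) stop("criterion '", criterion, "' not found")
  pick <- function(sex, k) {
    w <- which(phenos$sex == sex & !is.na(y))
    if (length(w) < k)
      stop("fewer ", sex, " candidates (", length(w), ") than requested (",
           k, ")")
    ord <- w[order(if (direction == "high") -y[w] else y[w],
                   phenos$animal[w])]
    sel <- ord[seq_len(k)]
    s <- (mean(y[sel]) - mean(y[w])) / sd(y[w])
    if (direction == "low") s <- -s
    list(ids = phenos$animal[sel],
         diff = data.frame(sex = sex, n_candidates = length(w),
                           n_selected = k, differential = s))
  }
  m <- pick("male", n_males)
  f <- pick("female", n_females)
  list(sires = m$ids, dams = f$ids,
       differentials = rbind(m$diff, f$diff))
}

#' Pair selected sires and dams avoiding full- and half-sib matings
#'
#' Each sire receives at most `ratio` dams and each dam is used once. Pairs
#' sharing a known parent (full or half sibs) are avoided via exact bipartite
#' matching (augmenting paths over sire slots), randomized subject to the
#' constraints; if no complete sib-free assignment exists, the remaining
#' dams are paired with the least-related available sire (fewest shared
#' parents) and a warning is issued.
#'
#' @param sires,dams animal ids of selected parents.
#' @param parents data frame with columns `animal`, `sire`, `dam` covering
#'   the selected animals (unknown parents `NA`).
#' @param ratio maximum dams per sire.
#' @param seed integer seed for the randomization.
#' @return data frame with columns `sire`, `dam`.
#' @export
make_matings <- function(sires, dams, parents, ratio = 2L, seed = 1L) {
  set.seed(seed)
  stopifnot(length(dams) <= length(sires) * ratio)
  look <- parents[match(c(sires, dams), parents$animal), c("sire", "dam")]
  ps <- look$sire
  pd <- look$dam
  ns <- length(sires)
  nd <- length(dams)
  is_sib <- function(di, si) {
    a <- ns + di
    (!is.na(ps[a]) && !is.na(ps[si]) && ps[a] == ps[si]) ||
      (!is.na(pd[a]) && !is.na(pd[si]) && pd[a] == pd[si])
  }
  compat <- matrix(TRUE, nd, ns)
  for (di in seq_len(nd)) for (si in seq_len(ns))
    compat[di, si] <- !is_sib(di, si)

  # Kuhn's augmenting-path matching over sire slots (capacity = ratio)
  slot_sire <- rep(seq_len(ns), each = ratio)
  n_slot <- length(slot_sire)
  slot_of <- integer(n_slot)           # dam matched to each slot, 0 = free
  dam_slot <- integer(nd)
  slot_order <- lapply(seq_len(nd), function(i) sample.int(n_slot))
  vis <- logical(n_slot)
  try_dam <- function(di) {
    for (sl in slot_order[[di]]) {
      if (vis[sl] || !compat[di, slot_sire[sl]]) next
      vis[sl] <<- TRUE
      if (slot_of[sl] == 0L || try_dam(slot_of[sl])) {
        slot_of[sl] <<- di
        dam_slot[di] <<- sl
        return(TRUE)
      }
    }
    FALSE
  }
  unmatched <- integer(0)
  for (di in sample.int(nd)) {
    vis <- logical(n_slot)
    if (!try_dam(di)) unmatched <- c(unmatched, di)
  }
  if (length(unmatched)) {
    warning("no sib-free pairing for ", length(unmatched),
            " dam(s); using least-related available sire")
    for (di in unmatched) {
      cap <- tabulate(slot_sire[slot_of > 0L], ns)
      open <- which(cap < ratio)
      score <- vapply(open, function(si) {
        a <- ns + di
        sum(c(!is.na(ps[a]) && !is.na(ps[si]) && ps[a] == ps[si],
              !is.na(pd[a]) && !is.na(pd[si]) && pd[a] == pd[si]))
      }, 0)
      si <- open[which.min(score)]
      sl <- which(slot_sire == si & slot_of == 0L)[1L]
      slot_of[sl] <- di
      dam_slot[di] <- sl
    }
  }
  data.frame(sire = sires[slot_sire[dam_slot]], dam = dams,
             stringsAsFactors = FALSE)
}

#' Produce an offspring cohort from a set of matings
#'
#' Locus genotypes follow independent Mendelian sampling of one allele per
#' parent; polygenic values are midparent plus a Mendelian-sampling deviation
#' with variance `0.5 * sigma2_A * (1 − (F_sire + F_dam)/2)` (per trait, with
#' the cross-trait additive covariance); maternal effects are drawn once per
#' dam and shared by full sibs; sexes are Bernoulli(1/2).
#'
#' @param matings data frame from [make_matings()].
#' @param parent_cohort cohort list containing all mated parents.
#' @param config a [sim_config()].
#' @param n_offspring total offspring to produce, distributed as evenly as
#'   possible over matings.
#' @param generation,line labels for the new cohort.
#' @param seed integer seed.
#' @param track_a keep the dense relationship matrix among the offspring
#'   (needed when the cohort will itself be bred from; disable for very
#'   large one-off cohorts).
#' @return a cohort list, including the relationship matrix among the
#'   offspring (for inbreeding bookkeeping in later rounds).
#' @export
breed <- function(matings, parent_cohort, config, n_offspring,
                  generation, line, seed = 1L, track_a = TRUE) {
  set.seed(seed)
  traits <- config$traits
  nm <- nrow(matings)
  base_n <- n_offspring %/% nm
  extra <- sample.int(nm, n_offspring %% nm)
  counts <- rep(base_n, nm)
  counts[extra] <- counts[extra] + 1L
  midx <- rep(seq_len(nm), counts)

  pid <- parent_cohort$info$animal
  sp <- match(matings$sire, pid)[midx]   # parent-cohort index per offspring
  dp <- match(matings$dam, pid)[midx]
  if (anyNA(sp) || anyNA(dp)) stop("mated parent missing from parent cohort")

  n <- length(midx)
  geno <- rbinom(n, 1L, parent_cohort$geno[sp] / 2) +
          rbinom(n, 1L, parent_cohort$geno[dp] / 2)

  Ap <- parent_cohort$A
  np <- length(pid)
  if (is.null(Ap)) Ap <- diag(np)
  f_off <- 0.5 * Ap[cbind(sp, dp)]
  Sa <- effect_cov(traits, "sigma2_A", config$correlations, "additive")
  scale <- sqrt(0.5 * (1 - (parent_cohort$f[sp] + parent_cohort$f[dp]) / 2))
  bv <- 0.5 * (parent_cohort$bv[sp, , drop = FALSE] +
               parent_cohort$bv[dp, , drop = FALSE]) +
        draw_mvn(n, Sa) * scale
  Sm <- effect_cov(traits, "sigma2_m", config$correlations, "maternal")
  mat_by_dam <- draw_mvn(nm, Sm)
  mat <- mat_by_dam[midx, , drop = FALSE]
  colnames(bv) <- colnames(mat) <- names(traits)

  prefix <- paste0(toupper(substr(line, 1L, 1L)), generation)
  info <- data.frame(
    animal = sprintf("%s_%05d", prefix, seq_len(n)),
    sire = matings$sire[midx], dam = matings$dam[midx],
    sex = ifelse(rbinom(n, 1L, 0.5) == 1L, "female", "male"),
    generation = generation, line = line, stringsAsFactors = FALSE)

  # relationship among offspring via the tabular step from the parent matrix
  A <- NULL
  if (track_a) {
    P <- 0.5 * (Ap[sp, , drop = FALSE] + Ap[dp, , drop = FALSE])
    A <- 0.5 * (P[, sp, drop = FALSE] + P[, dp, drop = FALSE])
    diag(A) <- 1 + f_off
  }

  list(info = info, geno = geno, bv = bv, mat = mat, f = f_off, A = A)
}

#' Run the full divergent selection experiment
#'
#' Simulates the base population and, per generation and line, the cycle
#' phenotype -> select -> mate -> breed. Both lines draw their first parents
#' from the common base population (High takes the top, Low the bottom of
#' the criterion distribution); afterwards selection is within line. ELISA
#' plates mix lines and sexes within each generation.
#'
#' @param config a [sim_config()].
#' @param seed root seed; every stage draws from a derived child stream.
#' @param random_mating if `TRUE`, parents are drawn at random instead of by
#'   truncation (drift-only control).
#' @return object of class `nab_sim`: list with `pedigree` (a
#'   [build_pedigree()] result), `phenotypes`, `truth`, `summary` (per
#'   line x generation: size, C-allele frequency, means/SDs),
#'   `differentials`, `config`, `seed`.
#' @export
run_experiment <- function(config = sim_config(), seed = 1L,
                           random_mating = FALSE) {
  tn <- names(config$traits)
  base <- simulate_base(config, child_seed(seed, "base"))
  bp <- assign_plates(base$info, config$plate_size, 0L,
                      child_seed(seed, "plates", 0L),
                      by_sex = config$base_plate_confounded)
  pheno <- sim_phenotype(base, config, bp, child_seed(seed, "pheno", 0L))
  cohorts <- list(base)
  phenos <- list(pheno)
  diffs <- list()
  cand <- list(high = list(cohort = base, pheno = pheno),
               low = list(cohort = base, pheno = pheno))

  for (t in seq_len(config$generations)) {
    new <- list()
    for (ln in c("high", "low")) {
      cc <- cand[[ln]]
      if (random_mating) {
        set.seed(child_seed(seed, paste0("rand_", ln), t))
        males <- cc$pheno$animal[cc$pheno$sex == "male"]
        females <- cc$pheno$animal[cc$pheno$sex == "female"]
        if (length(males) < config$n_sires || length(females) < config$n_dams)
          stop("fewer candidates than requested parents")
        sel <- list(sires = sample(males, config$n_sires),
                    dams = sample(females, config$n_dams),
                    differentials = data.frame(sex = c("male", "female"),
                                               n_candidates = c(length(males), length(females)),
                                               n_selected = c(config$n_sires, config$n_dams),
                                               differential = NA_real_))
      } else {
        sel <- select_parents(cc$pheno, config$selection_criterion,
                              config$n_sires, config$n_dams,
                              direction = ln)
      }
      diffs[[length(diffs) + 1L]] <-
        cbind(line = ln, generation = t, sel$differentials)

      keep <- match(c(sel$sires, sel$dams), cc$cohort$info$animal)
      par_cohort <- list(info = cc$cohort$info[keep, , drop = FALSE],
                         geno = cc$cohort$geno[keep],
                         bv = cc$cohort$bv[keep, , drop = FALSE],
                         f = cc$cohort$f[keep],
                         A = if (is.null(cc$cohort$A)) NULL
                             else cc$cohort$A[keep, keep, drop = FALSE])
      matings <- make_matings(sel$sires, sel$dams, par_cohort$info,
                              ratio = config$mating_ratio,
                              seed = child_seed(seed, paste0("mate_", ln), t))
      half <- config$generation_sizes[t] %/% 2L
      target <- if (ln == "high") config$generation_sizes[t] - half else half
      new[[ln]] <- breed(matings, par_cohort, config, target, t, ln,
                         seed = child_seed(seed, paste0("breed_", ln), t))
    }
    both_info <- rbind(new$high$info, new$low$info)
    plate <- assign_plates(both_info, config$plate_size, t,
                           child_seed(seed, "plates", t))
    nh <- nrow(new$high$info)
    merged <- list(info = both_info,
                   geno = c(new$high$geno, new$low$geno),
                   bv = rbind(new$high$bv, new$low$bv),
                   mat = rbind(new$high$mat, new$low$mat),
                   f = c(new$high$f, new$low$f))
    ph <- sim_phenotype(merged, config, plate, child_seed(seed, "pheno", t))
    for (ln in c("high", "low")) {
      idx <- if (ln == "high") seq_len(nh) else nh + seq_len(nrow(new$low$info))
      cohort <- new[[ln]]
      cohort$mat <- merged$mat[idx, , drop = FALSE]
      cand[[ln]] <- list(cohort = cohort, pheno = ph[idx, , drop = FALSE])
      cohorts[[length(cohorts) + 1L]] <- cohort
    }
    phenos[[length(phenos) + 1L]] <- ph
  }

  phenotypes <- do.call(rbind, phenos)
  rownames(phenotypes) <- NULL
  ped_raw <- phenotypes[, c("animal", "sire", "dam", "sex", "generation", "line")]
  pedigree <- build_pedigree(ped_raw)

  truth <- do.call(rbind, lapply(cohorts, function(co) {
    df <- data.frame(animal = co$info$animal, genotype = co$geno,
                     f = co$f, stringsAsFactors = FALSE)
    for (k in seq_along(tn)) df[[paste0("tbv_", tn[k])]] <- co$bv[, k]
    for (k in seq_along(tn)) df[[paste0("mat_", tn[k])]] <- co$mat[, k]
    df
  }))
  rownames(truth) <- NULL

  summ <- do.call(rbind, lapply(split(seq_len(nrow(phenotypes)),
                                      list(phenotypes$line, phenotypes$generation),
                                      drop = TRUE), function(w) {
    g <- phenotypes[w, , drop = FALSE]
    row <- data.frame(line = g$line[1L], generation = g$generation[1L],
                      n = nrow(g),
                      p_C = mean(truth$genotype[match(g$animal, truth$animal)]) / 2)
    for (nm in tn) {
      row[[paste0("mean_", nm)]] <- mean(g[[nm]])
      row[[paste0("sd_", nm)]] <- sd(g[[nm]])
    }
    row
  }))
  summ <- summ[order(summ$generation, summ$line), , drop = FALSE]
  rownames(summ) <- NULL
  differentials <- do.call(rbind, diffs)
  rownames(differentials) <- NULL

  structure(list(config = config, seed = seed, pedigree = pedigree,
                 phenotypes = phenotypes, truth = truth, summary = summ,
                 differentials = differentials),
            class = "nab_sim")
}

#' Write simulation outputs to CSV
#'
#' Writes `pedigree.csv`, `phenotypes.csv`, `truth.csv`, `summary.csv` and
#' `differentials.csv` into `dir`, floats with 10 significant digits.
#'
#' @param sim a [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "nab_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_df <- function(df) {
    for (k in names(df)) if (is.double(df[[k]])) df[[k]] <- fmt10(df[[k]])
    df
  }
  ped <- as.data.frame(sim$pedigree)[, c("animal", "sire", "dam", "sex",
                                         "generation", "line")]
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  paths <- c(pedigree = file.path(dir, "pedigree.csv"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             truth = file.path(dir, "truth.csv"),
             summary = file.path(dir, "summary.csv"),
             differentials = file.path(dir, "differentials.csv"))
  write.csv(ped, paths["pedigree"], row.names = FALSE, quote = FALSE)
  write.csv(fmt_df(sim$phenotypes), paths["phenotypes"], row.names = FALSE,
            quote = FALSE)
  write.csv(fmt_df(sim$truth), paths["truth"], row.names = FALSE, quote = FALSE)
  write.csv(fmt_df(sim$summary), paths["summary"], row.names = FALSE,
            quote = FALSE)
  write.csv(fmt_df(sim$differentials), paths["differentials"],
            row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Endpoint titer from an ELISA dilution series
#'
#' The titer is the log2 of the dilution factor whose extinction is closest
#' to 50% of the standard's maximum extinction. On an exact tie the lower
#' dilution is chosen. A flag marks titers read at an endpoint of the
#' series, where the true titer may lie outside the tested range.
#'
#' @param extinctions extinction values, one per dilution, in the order of
#'   `dilutions`.
#' @param e_max maximum extinction of the standard positive.
#' @param dilutions dilution factors of the series (default 1:40 ... 1:2560).
#' @return list with `titer` (log2 dilution) and `endpoint` (logical flag).
#' @examples
#' elisa_titer(c(1.9, 1.5, 0.8, 0.2), e_max = 1.8)  # log2(640)
#' @export
elisa_titer <- function(extinctions, e_max,
                        dilutions = c(40, 160, 640, 2560)) {
  if (!length(extinctions)) stop("empty extinction list")
  if (!is.finite(e_max) || e_max <= 0) stop("e_max must be > 0")
  stopifnot(length(extinctions) == length(dilutions))
  ord <- order(dilutions)
  dilutions <- dilutions[ord]
  extinctions <- extinctions[ord]
  idx <- which.min(abs(extinctions - 0.5 * e_max))  # ties: lower dilution
  list(titer = log2(dilutions[idx]),
       endpoint = idx %in% c(1L, length(dilutions)))
}
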