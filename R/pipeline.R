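# Orchestration: simulate -> fit -> trend -> theory from one configuration.

#' Descriptive statistics per line and generation
#'
#' Means and SDs per line x generation and trait, with the High − Low
#' difference and a Welch two-sided t-test per generation. When a group has
#' fewer than two records its SD is omitted and flagged; when both groups
#' are degenerate (zero variance) the standard error is floored at machine
#' epsilon so the t statistic stays finite, and the p-value is reported
#' accordingly.
#'
#' @param phenos phenotype table with `line`, `generation` and trait columns.
#' @param traits trait columns to summarise (default: the numeric columns
#'   among `IgM`, `IgG`, `IgTotal` that are present).
#' @return list with `groups` (per line x generation summaries) and
#'   `differences` (per generation High − Low tests).
#' @export
descriptives <- function(phenos, traits = intersect(c("IgM", "IgG", "IgTotal"),
                                                    names(phenos))) {
  stopifnot(length(traits) >= 1L)
  groups <- list()
  for (tr in traits) {
    sp <- split(phenos[[tr]], list(phenos$line, phenos$generation),
                drop = TRUE)
    key <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
    g <- data.frame(trait = tr, line = key[, 1L],
                    generation = as.integer(key[, 2L]),
                    n = vapply(sp, length, 0L),
                    mean = vapply(sp, mean, 0, na.rm = TRUE),
                    sd = vapply(sp, function(x)
                      if (sum(!is.na(x)) < 2L) NA_real_ else sd(x, na.rm = TRUE), 0),
                    row.names = NULL)
    g$sd_flag <- is.na(g$sd)
    groups[[tr]] <- g
  }
  groups <- do.call(rbind, groups)
  rownames(groups) <- NULL

  diffs <- list()
  for (tr in traits) {
    for (gen in sort(unique(phenos$generation))) {
      hi <- phenos[[tr]][phenos$line == "high" & phenos$generation == gen]
      lo <- phenos[[tr]][phenos$line == "low" & phenos$generation == gen]
      hi <- hi[!is.na(hi)]; lo <- lo[!is.na(lo)]
      if (!length(hi) || !length(lo)) next
      d <- mean(hi) - mean(lo)
      se2 <- (if (length(hi) > 1L) var(hi) / length(hi) else 0) +
             (if (length(lo) > 1L) var(lo) / length(lo) else 0)
      se_d <- max(sqrt(se2), sqrt(.Machine$double.eps))
      tstat <- d / se_d
      dfree <- if (se2 > 0 && length(hi) > 1L && length(lo) > 1L) {
        (var(hi) / length(hi) + var(lo) / length(lo))^2 /
          ((var(hi) / length(hi))^2 / (length(hi) - 1) +
           (var(lo) / length(lo))^2 / (length(lo) - 1))
      } else max(length(hi) + length(lo) - 2, 1)
      diffs[[length(diffs) + 1L]] <-
        data.frame(trait = tr, generation = gen, difference = d,
                   t = tstat, df = dfree,
                   p_value = 2 * pt(-abs(tstat), dfree))
    }
  }
  diffs <- if (length(diffs)) do.call(rbind, diffs) else NULL
  if (!is.null(diffs)) rownames(diffs) <- NULL
  list(groups = groups, differences = diffs)
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes simulate -> animal-model fit -> genetic trend -> major-locus
#' analysis -> deterministic theory comparison, from a single configuration
#' and root seed, and assembles the result tables. With `replicates > 1`
#' the key scalar outcomes are aggregated across replicate runs (mean and
#' empirical SE); a failing replicate is logged, skipped and counted.
#'
#' @param config a [sim_config()].
#' @param seed root seed; replicate r uses a derived child seed.
#' @param replicates number of replicate simulations.
#' @param fit_traits traits to fit with the REML animal model (default: the
#'   selection criterion).
#' @param genotype_model also fit the major-locus fixed-effect model on the
#'   last three generations, with variance components held at the
#'   animal-model estimates (default `TRUE`).
#' @param out_dir optional directory: per-replicate artifact CSVs and the
#'   report tables are written there.
#' @param verbose print per-stage progress.
#' @return object of class `nab_report`; see Details. Sections:
#'   `descriptives`, `components`, `ratios`, `genotype_effects`, `trend`,
#'   `allele_freq`, `theory`, `replicate_summary`, `meta`.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L, replicates = 1L,
                         fit_traits = config$selection_criterion,
                         genotype_model = TRUE, out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(replicates >= 1L)
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  rep_rows <- list()
  failures <- 0L
  first <- NULL

  for (r in seq_len(replicates)) {
    rseed <- child_seed(seed, "replicate", r)
    res <- tryCatch(
      pipeline_once(config, rseed, fit_traits, genotype_model, say),
      error = function(e) {
        warning("replicate ", r, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) { failures <- failures + 1L; next }
    if (is.null(first)) first <- res
    row <- data.frame(replicate = r, seed = rseed)
    for (tr in fit_traits) {
      rt <- res$ratios[[tr]]
      row[[paste0("h2_", tr)]] <- rt$estimate[rt$ratio == "h2"]
      row[[paste0("m2_", tr)]] <- rt$estimate[rt$ratio == "m2"]
    }
    endp <- res$allele_freq[res$allele_freq$generation == config$generations, ]
    row$p_low <- endp$p_C[endp$line == "low"]
    row$p_high <- endp$p_C[endp$line == "high"]
    if (!is.null(res$genotype_effects))
      row$cg_effect <- res$genotype_effects$estimate[
        res$genotype_effects$term == "genotypeCG"]
    rep_rows[[length(rep_rows) + 1L]] <- row
    if (!is.null(out_dir) && r == 1L)
      write_sim(res$sim, file.path(out_dir, "replicate1"))
  }
  if (is.null(first)) stop("all replicates failed")
  reps <- do.call(rbind, rep_rows)
  agg <- NULL
  if (nrow(reps) > 1L) {
    num <- reps[, setdiff(names(reps), c("replicate", "seed")), drop = FALSE]
    agg <- data.frame(quantity = names(num),
                      mean = vapply(num, mean, 0, na.rm = TRUE),
                      emp_se = vapply(num, function(x)
                        sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))), 0),
                      row.names = NULL)
  }

  report <- structure(list(
    meta = list(seed = seed, replicates = replicates, failures = failures,
                elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                criterion = config$selection_criterion),
    descriptives = first$descriptives,
    components = first$components,
    ratios = first$ratios,
    genotype_effects = first$genotype_effects,
    trend = first$trend,
    allele_freq = first$allele_freq,
    theory = first$theory,
    replicates = reps,
    replicate_summary = agg), class = "nab_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

pipeline_once <- function(config, rseed, fit_traits, genotype_model, say) {
  say("simulating (seed %d)", rseed)
  sim <- run_experiment(config, seed = rseed)
  desc <- descriptives(sim$phenotypes, traits = names(config$traits))

  comps <- list(); rats <- list(); trends <- list()
  fit1 <- NULL
  for (tr in fit_traits) {
    say("fitting animal model: %s", tr)
    fit <- fit_animal_model(sim$phenotypes, sim$pedigree,
                            model_spec(tr, fixed = c("plate", "sex")),
                            se = FALSE)
    if (is.null(fit1)) fit1 <- fit
    comps[[tr]] <- fit$components
    rats[[tr]] <- vc_ratios(fit)
    trends[[tr]] <- cbind(trait = tr, genetic_trend(fit))
  }
  trend <- do.call(rbind, trends)
  rownames(trend) <- NULL

  gmod <- NULL
  if (genotype_model) {
    say("fitting major-locus model (last 3 generations)")
    gens <- seq(max(1L, config$generations - 2L), config$generations)
    sub <- sim$phenotypes[sim$phenotypes$generation %in% gens, , drop = FALSE]
    crit <- fit_traits[1L]
    f1 <- comps[[crit]]
    spec5 <- model_spec(crit, fixed = c("plate", "sex", "line", "genotype3"),
                        fixed_variances = c(
                          additive = unname(f1[["sigma2_A"]]),
                          maternal_env = unname(f1[["sigma2_m"]]),
                          residual = unname(f1[["sigma2_e"]])))
    fit5 <- fit_animal_model(sub, sim$pedigree, spec5, se = FALSE)
    gmod <- fit5$fixed_effects[grepl("^genotype", fit5$fixed_effects$term), ]
    gmod <- rbind(gmod,
                  cbind(genotype_contrasts(fit5)[, c("estimate", "se")],
                        term = c("additive", "dominance"))[, c("term", "estimate", "se")])
  }

  af <- sim$summary[sim$summary$line != "base",
                    c("line", "generation", "n", "p_C")]
  base_p <- sim$summary$p_C[sim$summary$line == "base"]
  af <- rbind(data.frame(line = c("high", "low"), generation = 0L,
                         n = sim$summary$n[sim$summary$line == "base"],
                         p_C = base_p), af)
  af <- af[order(af$line, af$generation), ]
  rownames(af) <- NULL

  say("deterministic theory comparison")
  crit <- config$selection_criterion
  tr_spec <- config$traits[[crit]]
  sigma_p <- sqrt(tr_spec$sigma2_A + tr_spec$sigma2_m + tr_spec$sigma2_e)
  loc <- locus_model(config$locus$p0, config$locus$values[[crit]])
  di <- design_intensities(config$generation_sizes, config$n_sires,
                           config$n_dams,
                           base_candidates = c(
                             male = round(config$n_base * (1 - config$base_female_prop)),
                             female = round(config$n_base * config$base_female_prop)))
  theory <- do.call(rbind, lapply(c("high", "low"), function(ln) {
    tj <- allele_trajectory(loc, di$intensity, sigma_p, config$generations,
                            direction = if (ln == "high") "up" else "down")
    obs <- af$p_C[af$line == ln][match(tj$generation,
                                       af$generation[af$line == ln])]
    cbind(line = ln, tj, p_observed = obs)
  }))
  rownames(theory) <- NULL

  list(sim = sim, descriptives = desc, components = comps, ratios = rats,
       genotype_effects = gmod, trend = trend, allele_freq = af,
       theory = theory)
}

#' Write report tables to CSV and a plain-text summary
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "nab_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (is.null(df)) return()
    for (k in names(df)) if (is.double(df[[k]])) df[[k]] <- fmt10(df[[k]])
    write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE,
              quote = FALSE)
  }
  wr(report$descriptives$groups, "descriptives_groups")
  wr(report$descriptives$differences, "descriptives_differences")
  comp <- do.call(rbind, lapply(names(report$components), function(tr)
    data.frame(trait = tr, component = names(report$components[[tr]]),
               estimate = as.numeric(report$components[[tr]]))))
  wr(comp, "variance_components")
  rat <- do.call(rbind, lapply(names(report$ratios), function(tr)
    cbind(trait = tr, report$ratios[[tr]])))
  wr(rat, "ratios")
  wr(report$genotype_effects, "genotype_effects")
  wr(report$trend, "genetic_trend")
  wr(report$allele_freq, "allele_frequencies")
  wr(report$theory, "theory_comparison")
  wr(report$replicates, "replicates")
  wr(report$replicate_summary, "replicate_summary")
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(c(
    "nabsel pipeline report",
    sprintf("seed: %d  replicates: %d  failures: %d  elapsed: %.1fs",
            report$meta$seed, report$meta$replicates, report$meta$failures,
            report$meta$elapsed_s),
    sprintf("selection criterion: %s", report$meta$criterion),
    "",
    "tables written: descriptives_groups, descriptives_differences,",
    "variance_components, ratios, genotype_effects, genetic_trend,",
    "allele_frequencies, theory_comparison, replicates, replicate_summary"),
    con)
  invisible(dir)
}

#' @export
print.nab_report <- function(x, ...) {
  cat("nabsel pipeline report —", x$meta$replicates, "replicate(s),",
      x$meta$failures, "failure(s)\n")
  cat("criterion:", x$meta$criterion, "\n")
  if (!is.null(x$replicate_summary)) {
    cat("replicate summary:\n")
    print(x$replicate_summary)
  } else {
    af <- x$allele_freq
    g <- max(af$generation)
    cat(sprintf("final C frequency: high %.3f, low %.3f\n",
                af$p_C[af$line == "high" & af$generation == g],
                af$p_C[af$line == "low" & af$generation == g]))
  }
  invisible(x)
}
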