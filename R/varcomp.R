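# Animal-model REML/BLUP via sparse mixed-model equations.
#
# The restricted log-likelihood is computed through the standard identity
#   log|V| + log|X'V^-1 X| = log|R| + log|G| + log|C|,
# with C the mixed-model-equation coefficient matrix, and is reported in the
# parameterization-invariant form (a  −log|X'X|  adjustment makes it
# independent of the fixed-effect contrast coding).

#' Specify an animal model
#'
#' @param response trait (column of the phenotype table) to analyse.
#' @param fixed character vector of fixed terms, in order, from:
#'   `"plate"`, `"sex"`, `"line"`, `"generation"`, `"genotype3"` (3-class
#'   major-locus genotype, GG baseline), `"genotype2"` (dominant coding:
#'   GG vs C-carrier), `"genotype2:sex"`, `"genotype2:line"`,
#'   `"genotype2:generation"`. An intercept is always included. Note that
#'   generation is confounded with ELISA plate in the reference design;
#'   requesting both raises a singularity error.
#' @param random subset of `"additive"` (pedigree-structured),
#'   `"maternal_env"` (iid dam effect) and `"maternal_gen"`
#'   (pedigree-structured dam effect with a direct–maternal covariance;
#'   requires `"additive"`).
#' @param fixed_variances optional named numeric vector of components to
#'   hold constant during fitting; names among `"additive"`,
#'   `"maternal_env"`, `"maternal_gen"`, `"cov_a_mg"`, `"residual"`. When
#'   all components of the model are fixed the fit reduces to GLS/BLUP at
#'   those values.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(response, fixed = c("plate", "sex"),
                       random = c("additive", "maternal_env"),
                       fixed_variances = NULL) {
  allowed_fixed <- c("plate", "sex", "line", "generation", "genotype3",
                     "genotype2", "genotype2:sex", "genotype2:line",
                     "genotype2:generation")
  if (!all(fixed %in% allowed_fixed))
    stop("unknown fixed term(s): ",
         paste(setdiff(fixed, allowed_fixed), collapse = ", "))
  allowed_rand <- c("additive", "maternal_env", "maternal_gen")
  if (!all(random %in% allowed_rand))
    stop("unknown random term(s): ",
         paste(setdiff(random, allowed_rand), collapse = ", "))
  if ("maternal_gen" %in% random && !"additive" %in% random)
    stop("maternal_gen requires additive")
  if (!is.null(fixed_variances)) {
    ok <- c("additive", "maternal_env", "maternal_gen", "cov_a_mg", "residual")
    if (is.null(names(fixed_variances)) || !all(names(fixed_variances) %in% ok))
      stop("fixed_variances must be named among: ", paste(ok, collapse = ", "))
  }
  structure(list(response = response, fixed = fixed, random = random,
                 fixed_variances = fixed_variances), class = "model_spec")
}

# drop-first-level sparse dummies
dummy_cols <- function(f, prefix) {
  f <- droplevels(factor(f))
  if (nlevels(f) < 2L)
    return(Matrix::Matrix(0, length(f), 0, sparse = TRUE))
  X <- Matrix::sparse.model.matrix(~ 0 + f)
  X <- X[, -1L, drop = FALSE]
  colnames(X) <- paste0(prefix, levels(f)[-1L])
  X
}

one_col <- function(x, name) {
  Matrix::Matrix(as.numeric(x), ncol = 1, sparse = TRUE,
                 dimnames = list(NULL, name))
}

build_fixed <- function(data, fixed) {
  if (all(c("plate", "generation") %in% fixed))
    stop("singular fixed design: 'generation' is aliased with 'plate' ",
         "(plates are nested within generations)")
  n <- nrow(data)
  carrier <- function() {
    if (is.null(data$genotype)) stop("no 'genotype' column in data")
    as.numeric(data$genotype %in% c("CG", "CC"))
  }
  mats <- list(one_col(rep(1, n), "(Intercept)"))
  for (term in fixed) {
    X <- switch(term,
      plate = dummy_cols(data$plate, "plate"),
      sex = one_col(data$sex == "male", "sexmale"),
      line = dummy_cols(data$line, "line"),
      generation = dummy_cols(data$generation, "generation"),
      genotype3 = dummy_cols(factor(data$genotype,
                                    levels = c("GG", "CG", "CC")),
                             "genotype"),
      genotype2 = one_col(carrier(), "carrier"),
      "genotype2:sex" = one_col(carrier() * (data$sex == "male"),
                                "carrier:sexmale"),
      "genotype2:line" = {
        D <- dummy_cols(data$line, "carrier:line")
        D * carrier()
      },
      "genotype2:generation" = {
        D <- dummy_cols(data$generation, "carrier:generation")
        D * carrier()
      })
    mats[[length(mats) + 1L]] <- X
  }
  X <- do.call(cbind, mats)
  XtX <- as.matrix(Matrix::crossprod(X))
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular fixed design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  X
}

# dam-effect levels: the dam id where known, otherwise a singleton level
# per animal (unknown-dam animals carry their own maternal draw)
dam_levels <- function(data) {
  d <- as.character(data$dam)
  d[is.na(d) | d == "" | d == "0"] <-
    paste0("self:", data$animal[is.na(d) | d == "" | d == "0"])
  factor(d)
}

incidence <- function(j, ncol, dimn = NULL) {
  Matrix::sparseMatrix(i = seq_along(j), j = j, x = 1,
                       dims = c(length(j), ncol),
                       dimnames = list(NULL, dimn))
}

chol_logdet <- function(ch) {
  # log-determinant of the factored matrix from a CHMfactor
  2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
}

#' Fit a univariate animal model by REML
#'
#' Restricted maximum likelihood for mixed models of the form
#' `y = Xb + Z_a a + Z_m m + e` with `a ~ N(0, A sigma2_A)` structured by the
#' pedigree relationship matrix, an optional iid maternal environmental dam
#' effect, and (via `random = "maternal_gen"`) an optional pedigree-structured
#' maternal genetic effect with direct–maternal covariance. Variance
#' components are optimized on the log scale (correlations on the tanh
#' scale) by direct restricted-likelihood maximization over the sparse
#' mixed-model equations; BLUP breeding values and GLS fixed effects are
#' returned at the converged (or fixed) components.
#'
#' @param data phenotype table (one record per animal) with columns
#'   `animal`, `dam`, the response, and any fixed-effect columns used.
#' @param ped a [build_pedigree()] result covering all phenotyped animals.
#' @param spec a [model_spec()].
#' @param start optional named starting values (natural scale).
#' @param se compute approximate standard errors of the components via a
#'   numerical Hessian (default `TRUE`).
#' @return object of class `nab_fit` with elements `components`
#'   (named vector), `vc_se`, `vc_cov`, `fixed_effects` (data frame),
#'   `beta_cov`, `ebv` (named, all pedigree animals), `logL`, `converged`,
#'   `n_evaluations`, `boundary`, and for maternal-genetic fits `r_a_mg`
#'   with an out-of-range/boundary flag.
#' @export
fit_animal_model <- function(data, ped, spec, start = NULL, se = TRUE) {
  stopifnot(inherits(spec, "model_spec"), inherits(ped, "nab_pedigree"))
  y <- data[[spec$response]]
  if (is.null(y)) stop("response '", spec$response, "' not found")
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)

  aidx <- match(data$animal, ped$animal)
  if (anyNA(aidx)) stop("phenotyped animals missing from pedigree: ",
                        paste(utils::head(data$animal[is.na(aidx)]),
                              collapse = ", "))
  X <- build_fixed(data, spec$fixed)
  p <- ncol(X)
  q <- nrow(ped)

  Ainv <- a_inverse(ped)
  ldetA <- -chol_logdet(Matrix::Cholesky(Ainv, LDL = FALSE))

  has_m <- "maternal_env" %in% spec$random
  has_g <- "maternal_gen" %in% spec$random
  if (!"additive" %in% spec$random) stop("model must include the additive effect")

  Za <- incidence(aidx, q, ped$animal)
  blocks <- list(X, Za)
  if (has_g) {
    didx <- ped$dam_idx[aidx]                  # dam's pedigree position
    gj <- ifelse(didx > 0L, didx, NA_integer_)
    Zg <- Matrix::sparseMatrix(i = which(!is.na(gj)), j = gj[!is.na(gj)],
                               x = 1, dims = c(n, q))
    blocks[[length(blocks) + 1L]] <- Zg
  }
  if (has_m) {
    dl <- dam_levels(data)
    Zm <- incidence(as.integer(dl), nlevels(dl), levels(dl))
    blocks[[length(blocks) + 1L]] <- Zm
  }
  W <- do.call(cbind, blocks)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  Wty <- as.numeric(Matrix::crossprod(W, y))
  yty <- sum(y * y)
  ldetXtX <- as.numeric(determinant(as.matrix(Matrix::crossprod(X)),
                                    logarithm = TRUE)$modulus)
  qm <- if (has_m) ncol(Zm) else 0L

  # parameter bookkeeping ----------------------------------------------
  comp_names <- c("additive",
                  if (has_g) c("maternal_gen", "cov_a_mg"),
                  if (has_m) "maternal_env",
                  "residual")
  vy <- var(y)
  default_start <- c(additive = 0.3 * vy, maternal_gen = 0.05 * vy,
                     cov_a_mg = 0, maternal_env = 0.05 * vy,
                     residual = 0.6 * vy)
  th0 <- default_start[comp_names]
  names(th0) <- comp_names
  if (!is.null(start)) th0[names(start)] <- start
  fixedv <- spec$fixed_variances
  th0[names(fixedv)] <- fixedv
  free <- setdiff(comp_names, names(fixedv))

  # fixed-pattern assembly of C(theta): components and their coefficients
  m_dim <- nrow(WtW)
  off_a <- p
  off_g <- p + q
  off_m <- p + q + if (has_g) q else 0L
  comp_mats <- c(list(WtW, pad_sym(Ainv, m_dim, off_a)),
                 if (has_g) list(pad_sym(Ainv, m_dim, off_g),
                                 pad_cross(Ainv, m_dim, off_a, off_g)),
                 if (has_m) list(pad_sym(Matrix::Diagonal(qm), m_dim, off_m)))
  lc <- sparse_lincomb(comp_mats)

  coef_ldet <- function(th) {
    sa <- th[["additive"]]
    se2 <- th[["residual"]]
    if (has_g) {
      S <- matrix(c(sa, th[["cov_a_mg"]], th[["cov_a_mg"]],
                    th[["maternal_gen"]]), 2, 2)
      Si <- solve(S)
      cf <- c(1 / se2, Si[1, 1], Si[2, 2], Si[1, 2])
      ldet <- q * as.numeric(determinant(S, logarithm = TRUE)$modulus) +
        2 * ldetA
    } else {
      cf <- c(1 / se2, 1 / sa)
      ldet <- q * log(sa) + ldetA
    }
    if (has_m) {
      cf <- c(cf, 1 / th[["maternal_env"]])
      ldet <- ldet + qm * log(th[["maternal_env"]])
    }
    list(coefs = cf, ldetG = ldet)
  }

  chol_cache <- NULL
  objective <- function(th) {
    se2 <- th[["residual"]]
    cl <- coef_ldet(th)
    C <- lc$eval(cl$coefs)
    if (is.null(chol_cache)) {
      chol_cache <<- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    } else {
      chol_cache <<- update(chol_cache, C)
    }
    rhs <- Wty / se2
    sol <- as.numeric(Matrix::solve(chol_cache, rhs, system = "A"))
    ypy <- yty / se2 - sum(sol * rhs)
    ll <- -0.5 * ((n - p) * log(2 * pi) + n * log(se2) + cl$ldetG +
                  chol_logdet(chol_cache) + ypy - ldetXtX)
    attr(ll, "sol") <- sol
    ll
  }

  to_nat <- function(z) {
    th <- th0
    for (k in seq_along(free)) {
      nm <- free[k]
      if (nm == "cov_a_mg") next
      th[[nm]] <- exp(z[[k]])
    }
    if ("cov_a_mg" %in% free) {
      r <- tanh(z[[match("cov_a_mg", free)]])
      th[["cov_a_mg"]] <- r * sqrt(th[["additive"]] * th[["maternal_gen"]])
    }
    th
  }
  z0 <- vapply(free, function(nm) {
    if (nm == "cov_a_mg") {
      r <- th0[["cov_a_mg"]] /
        sqrt(th0[["additive"]] * th0[["maternal_gen"]])
      atanh(max(min(r, 0.95), -0.95))
    } else log(th0[[nm]])
  }, 0)

  n_eval <- 0L
  neg <- function(z) {
    n_eval <<- n_eval + 1L
    -as.numeric(objective(to_nat(z)))
  }

  if (length(free) == 0L) {
    opt <- list(par = numeric(0), convergence = 0L)
  } else if (length(free) == 1L) {
    opt <- optim(z0, neg, method = "Brent",
                 lower = z0 - 14, upper = z0 + 6,
                 control = list(reltol = 1e-12))
  } else {
    opt <- optim(z0, neg, method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 4000))
  }
  converged <- opt$convergence == 0L
  th_hat <- to_nat(opt$par)
  ll <- objective(th_hat)
  sol <- attr(ll, "sol")

  beta <- sol[seq_len(p)]
  names(beta) <- colnames(X)
  ebv <- sol[p + seq_len(q)]
  names(ebv) <- ped$animal

  # fixed-effect covariance: the X-block of C^-1
  Ip <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                             dims = c(nrow(WtW), p))
  beta_cov <- as.matrix(Matrix::solve(chol_cache, Ip, system = "A"))[seq_len(p), , drop = FALSE]
  dimnames(beta_cov) <- list(colnames(X), colnames(X))

  vc_cov <- NULL
  vc_se <- setNames(rep(NA_real_, length(comp_names)), comp_names)
  if (se && length(free)) {
    H <- num_hessian(function(v) {
      th <- th_hat
      th[free] <- v
      if (any(th[setdiff(free, "cov_a_mg")] <= 0)) return(NA_real_)
      as.numeric(objective(th))
    }, th_hat[free])
    vc_cov <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(vc_cov)) {
      dimnames(vc_cov) <- list(free, free)
      dg <- diag(vc_cov)
      vc_se[free] <- ifelse(dg > 0, sqrt(dg), NA_real_)
    }
  }

  boundary <- any(th_hat[setdiff(comp_names, c("cov_a_mg", "residual"))] <
                  1e-6 * vy)
  r_a_mg <- NULL
  r_flag <- FALSE
  if (has_g) {
    r_a_mg <- th_hat[["cov_a_mg"]] /
      sqrt(th_hat[["additive"]] * th_hat[["maternal_gen"]])
    r_flag <- !is.finite(r_a_mg) || abs(r_a_mg) >= 0.99
  }

  comp_out <- c(sigma2_A = th_hat[["additive"]],
                if (has_g) c(sigma2_mg = th_hat[["maternal_gen"]],
                             cov_a_mg = th_hat[["cov_a_mg"]]),
                if (has_m) c(sigma2_m = th_hat[["maternal_env"]]),
                sigma2_e = th_hat[["residual"]])

  structure(list(
    spec = spec, components = comp_out,
    theta = th_hat, free = free,
    vc_se = vc_se, vc_cov = vc_cov,
    fixed_effects = data.frame(term = colnames(X), estimate = beta,
                               se = sqrt(pmax(diag(beta_cov), 0)),
                               row.names = NULL),
    beta_cov = beta_cov, ebv = ebv,
    logL = as.numeric(ll), converged = converged,
    n_evaluations = n_eval, boundary = boundary,
    r_a_mg = r_a_mg, r_a_mg_flag = r_flag,
    n = n, p = p,
    records = data.frame(animal = data$animal,
                         line = if (is.null(data$line)) NA else data$line,
                         generation = if (is.null(data$generation)) NA
                                      else data$generation,
                         stringsAsFactors = FALSE)),
    class = "nab_fit")
}

#' @export
print.nab_fit <- function(x, ...) {
  cat("Animal-model REML fit:", x$spec$response, "\n")
  cat("  records:", x$n, " fixed df:", x$p, "\n")
  cat("  logL:", format(x$logL, digits = 8),
      " converged:", x$converged,
      " evaluations:", x$n_evaluations, "\n")
  comp <- data.frame(estimate = x$components,
                     se = x$vc_se[c("additive",
                                    if ("sigma2_mg" %in% names(x$components))
                                      c("maternal_gen", "cov_a_mg"),
                                    if ("sigma2_m" %in% names(x$components))
                                      "maternal_env",
                                    "residual")])
  print(round(comp, 5))
  invisible(x)
}

#' Fit the maternal-genetic animal model
#'
#' Convenience wrapper adding a pedigree-structured maternal genetic effect
#' (with direct–maternal genetic covariance) to the maternal-environment
#' animal model, and reporting the implied direct–maternal correlation with
#' a flag when the estimate sits at the boundary of the parameter space.
#'
#' @inheritParams fit_animal_model
#' @return a `nab_fit`; see [fit_animal_model()].
#' @export
fit_maternal_genetic <- function(data, ped, spec = NULL, start = NULL,
                                 se = TRUE) {
  if (is.null(spec)) stop("a model_spec is required")
  if (!"maternal_gen" %in% spec$random)
    spec$random <- union(spec$random, "maternal_gen")
  fit_animal_model(data, ped, spec, start = start, se = se)
}

num_hessian <- function(f, x, rel = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x), 1e-3) * rel
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) for (j in i:k) {
    if (i == j) {
      xp <- x; xp[i] <- x[i] + h[i]
      xm <- x; xm[i] <- x[i] - h[i]
      H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
    } else {
      xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
      xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Likelihood-ratio test for nested variance-component models
#'
#' `LR = 2 (logL_full − logL_reduced)`, clipped at zero, against the plain
#' chi-square upper tail with the stated degrees of freedom (no boundary
#' mixture).
#'
#' @param full,reduced fitted models (`nab_fit`) or log-likelihood values.
#' @param df degrees of freedom (number of restricted parameters).
#' @return list with `lr`, `df`, `p_value`.
#' @examples
#' lrt(10, 5, df = 1)
#' @export
lrt <- function(full, reduced, df = 1L) {
  if (df <= 0) stop("df must be positive")
  get_ll <- function(x)
    if (inherits(x, c("nab_fit", "nab_bifit"))) x$logL else x
  lf <- get_ll(full)
  lr <- get_ll(reduced)
  stat <- max(0, 2 * (lf - lr))
  list(lr = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Heritability and maternal-effect ratios
#'
#' `h2 = sigma2_A / (sigma2_A + sigma2_m + sigma2_e)` and
#' `m2 = sigma2_m / (sigma2_A + sigma2_m + sigma2_e)` (plate is a fixed
#' effect and does not enter the denominator), with delta-method standard
#' errors when the component covariance is available.
#'
#' @param fit a `nab_fit`, or a numeric vector
#'   `c(additive = , maternal_env = , residual = )`.
#' @return data frame with `ratio`, `estimate`, `se`.
#' @examples
#' vc_ratios(c(additive = 0.345, maternal_env = 0.0345, residual = 0.7705))
#' @export
vc_ratios <- function(fit) {
  if (inherits(fit, "nab_fit")) {
    th <- fit$theta
    vcov <- fit$vc_cov
  } else {
    th <- fit
    if (!"maternal_env" %in% names(th)) th <- c(th, maternal_env = 0)
    vcov <- NULL
  }
  sa <- th[["additive"]]
  sm <- if ("maternal_env" %in% names(th)) th[["maternal_env"]] else 0
  se2 <- th[["residual"]]
  tot <- sa + sm + se2
  if (tot <= 0) stop("zero total variance")
  h2 <- sa / tot
  m2 <- sm / tot
  se_h2 <- se_m2 <- NA_real_
  if (!is.null(vcov)) {
    nm <- colnames(vcov)
    g <- function(grad_full) {
      gr <- grad_full[nm]
      gr[is.na(gr)] <- 0
      sqrt(max(0, t(gr) %*% vcov %*% gr))
    }
    se_h2 <- g(c(additive = (tot - sa) / tot^2, maternal_env = -sa / tot^2,
                 residual = -sa / tot^2, maternal_gen = 0, cov_a_mg = 0))
    se_m2 <- g(c(additive = -sm / tot^2, maternal_env = (tot - sm) / tot^2,
                 residual = -sm / tot^2, maternal_gen = 0, cov_a_mg = 0))
  }
  data.frame(ratio = c("h2", "m2"), estimate = c(h2, m2),
             se = c(se_h2, se_m2))
}

#' Additive and dominance contrasts of the 3-class genotype effect
#'
#' Reparametrizes the fitted genotype-class effects into
#' `additive = (CC − GG)/2` and `dominance = CG − (CC + GG)/2` as general
#' linear contrasts of the fixed effects, with Wald standard errors and
#' two-sided p-values.
#'
#' @param fit a `nab_fit` whose spec includes `"genotype3"`.
#' @return data frame with one row per contrast.
#' @export
genotype_contrasts <- function(fit) {
  stopifnot(inherits(fit, "nab_fit"))
  if (!"genotype3" %in% fit$spec$fixed) {
    if ("genotype2" %in% fit$spec$fixed)
      stop("genotype fitted with dominant 2-class coding; refit with ",
           "'genotype3' for additive/dominance contrasts")
    stop("no 3-class genotype term in the model")
  }
  terms <- fit$fixed_effects$term
  iCG <- match("genotypeCG", terms)
  iCC <- match("genotypeCC", terms)
  if (is.na(iCG) || is.na(iCC)) stop("genotype coefficients not found")
  p <- length(terms)
  L <- matrix(0, p, 2, dimnames = list(terms, c("additive", "dominance")))
  L[iCC, "additive"] <- 0.5                      # (CC - GG)/2, GG baseline
  L[iCG, "dominance"] <- 1
  L[iCC, "dominance"] <- -0.5
  est <- drop(t(L) %*% fit$fixed_effects$estimate)
  se <- sqrt(diag(t(L) %*% fit$beta_cov %*% L))
  z <- est / se
  data.frame(effect = c("additive", "dominance"), estimate = est, se = se,
             z = z, p_value = 2 * pnorm(-abs(z)), row.names = NULL)
}

#' Fit a genotype-by-factor interaction and test it
#'
#' Adds a `genotype2:term` interaction (dominant 2-class genotype coding, as
#' appropriate for a near-fully dominant allele) to the supplied model,
#' tests the interaction block with a joint Wald chi-square, and reports the
#' genotype effect within each level of the interacting factor.
#'
#' @inheritParams fit_animal_model
#' @param interaction one of `"sex"`, `"line"`, `"generation"`.
#' @return list with `fit` (`nab_fit`), `wald` (`statistic`, `df`,
#'   `p_value`) and `simple_effects` (carrier effect per level).
#' @export
interaction_fit <- function(data, ped, spec, interaction = c("sex", "line",
                                                             "generation"),
                            start = NULL, se = TRUE) {
  interaction <- match.arg(interaction)
  if ("genotype3" %in% spec$fixed)
    spec$fixed <- setdiff(spec$fixed, "genotype3")
  if (!"genotype2" %in% spec$fixed)
    spec$fixed <- c(spec$fixed, "genotype2")
  iterm <- paste0("genotype2:", interaction)
  if (iterm %in% spec$fixed) stop("interaction term duplicates the model")
  # the main effect of the interacting factor (generation excepted: it is
  # aliased with plate and deliberately never fitted)
  if (interaction != "generation" && !interaction %in% spec$fixed)
    spec$fixed <- c(spec$fixed, interaction)
  spec$fixed <- c(spec$fixed, iterm)
  fit <- fit_animal_model(data, ped, spec, start = start, se = se)

  terms <- fit$fixed_effects$term
  int_idx <- grep("^carrier:", terms)
  b <- fit$fixed_effects$estimate[int_idx]
  Vb <- fit$beta_cov[int_idx, int_idx, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(Vb) %*% b)
  dfw <- length(int_idx)

  carrier_idx <- match("carrier", terms)
  lv_names <- sub("^carrier:", "", terms[int_idx])
  base_lv <- switch(interaction,
                    sex = "female",
                    line = paste0("line", sort(unique(as.character(data$line)))[1L]),
                    generation = paste0("generation",
                                        sort(unique(data$generation))[1L]))
  p <- length(terms)
  mkL <- function(extra_idx) {
    l <- rep(0, p)
    l[carrier_idx] <- 1
    if (!is.na(extra_idx)) l[extra_idx] <- 1
    l
  }
  Ls <- cbind(mkL(NA_integer_),
              vapply(int_idx, function(i) mkL(i), numeric(p)))
  est <- drop(t(Ls) %*% fit$fixed_effects$estimate)
  ses <- sqrt(diag(t(Ls) %*% fit$beta_cov %*% Ls))
  simple <- data.frame(level = c(base_lv, lv_names), estimate = est,
                       se = ses, row.names = NULL)
  list(fit = fit,
       wald = list(statistic = stat, df = dfw,
                   p_value = pchisq(stat, dfw, lower.tail = FALSE)),
       simple_effects = simple)
}

#' Genetic trend from estimated breeding values
#'
#' Averages the fitted EBVs of all phenotyped individuals per
#' line-by-generation combination, both in titer points and in additive
#' genetic standard deviations (`sigma_A = sqrt(sigma2_A)` from the same
#' fit).
#'
#' @param fit a `nab_fit`.
#' @return data frame with `line`, `generation`, `n`, `mean_ebv`,
#'   `mean_ebv_sd_units`.
#' @export
genetic_trend <- function(fit) {
  stopifnot(inherits(fit, "nab_fit"))
  rec <- fit$records
  if (all(is.na(rec$line)) || all(is.na(rec$generation)))
    stop("records carry no line/generation labels")
  ebv <- fit$ebv[rec$animal]
  sA <- sqrt(fit$components[["sigma2_A"]])
  out <- aggregate(list(mean_ebv = ebv),
                   by = list(line = rec$line, generation = rec$generation),
                   FUN = mean)
  nn <- aggregate(list(n = ebv),
                  by = list(line = rec$line, generation = rec$generation),
                  FUN = length)
  out <- merge(out, nn, by = c("line", "generation"))
  out$mean_ebv_sd_units <- out$mean_ebv / sA
  out <- out[order(out$line, out$generation),
             c("line", "generation", "n", "mean_ebv", "mean_ebv_sd_units")]
  rownames(out) <- NULL
  out
}
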