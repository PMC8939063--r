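# Two-trait REML: additive effects structured by kron(Sa, A), maternal
# environmental effects by kron(Sm, I_dams), residuals by per-animal 2x2
# blocks (records of the same animal in both traits are correlated).

#' Fit a bivariate animal model by REML
#'
#' Estimates the additive, maternal-environmental and residual covariance
#' matrices of two traits under the pedigree-structured animal model, and
#' reports the genetic (`r_a`), maternal (`r_m`), residual (`r_e`) and
#' implied phenotypic (`r_p`) correlations. Two modes:
#'
#' * trait-pair mode (`sex_as_traits = FALSE`): the two responses are two
#'   trait columns, each animal can contribute one record per trait, and the
#'   residual covariance between an animal's two records is estimated;
#' * sex-split mode (`sex_as_traits = TRUE`): one trait column is treated as
#'   two traits, male and female expression. Each animal contributes to
#'   exactly one of them, so the residual covariance is inestimable and is
#'   fixed at 0, and sex is dropped from the fixed effects.
#'
#' `fix_ra` supports the likelihood-ratio test of a genetic correlation of 1
#' by holding `r_a` at a boundary value such as 0.999.
#'
#' @param data phenotype table.
#' @param ped a [build_pedigree()] result covering all phenotyped animals.
#' @param traits character of length 2 (trait-pair mode) or length 1
#'   (sex-split mode).
#' @param sex_as_traits treat male and female expression as two traits.
#' @param fixed fixed-effect terms per trait (see [model_spec()]); sex is
#'   removed automatically in sex-split mode.
#' @param fix_ra optional value at which the additive correlation is held.
#' @param start optional named list with elements among `additive`,
#'   `maternal`, `residual`, each `c(v1 = , v2 = , r = )`.
#' @param prefit when no `start` is given, run quick univariate fits per
#'   trait to obtain variance starting values (cuts the number of
#'   bivariate-likelihood evaluations substantially).
#' @param se compute numerical-Hessian standard errors.
#' @return object of class `nab_bifit`: per-trait components, correlations
#'   with SEs, `logL`, `converged`, `ebv` (matrix, one column per trait).
#' @export
fit_bivariate <- function(data, ped, traits, sex_as_traits = FALSE,
                          fixed = c("plate", "sex"), fix_ra = NULL,
                          start = NULL, prefit = TRUE, se = TRUE) {
  stopifnot(inherits(ped, "nab_pedigree"))
  if (sex_as_traits) {
    stopifnot(length(traits) == 1L)
    fixed <- setdiff(fixed, "sex")
    tr_names <- paste0(traits, c("_male", "_female"))
    data[[tr_names[1L]]] <- ifelse(data$sex == "male", data[[traits]], NA)
    data[[tr_names[2L]]] <- ifelse(data$sex == "female", data[[traits]], NA)
    traits <- tr_names
  }
  stopifnot(length(traits) == 2L)
  y1 <- data[[traits[1L]]]
  y2 <- data[[traits[2L]]]
  if (is.null(y1) || is.null(y2)) stop("trait column(s) not found")
  keep <- !(is.na(y1) & is.na(y2))
  data <- data[keep, , drop = FALSE]
  y1 <- y1[keep]; y2 <- y2[keep]
  if (!any(!is.na(y1)) || !any(!is.na(y2)))
    stop("fewer than 2 traits observed")

  q <- nrow(ped)
  aidx <- match(data$animal, ped$animal)
  if (anyNA(aidx)) stop("phenotyped animals missing from pedigree")
  dl <- dam_levels(data)
  qd <- nlevels(dl)

  # long layout: records of trait 1, then trait 2
  o1 <- which(!is.na(y1)); o2 <- which(!is.na(y2))
  y <- c(y1[o1], y2[o2])
  n <- length(y)
  mk_side <- function(rows, tr) {
    X <- build_fixed(data[rows, , drop = FALSE], fixed)
    colnames(X) <- paste0(tr, ":", colnames(X))
    X
  }
  X1 <- mk_side(o1, traits[1L])
  X2 <- mk_side(o2, traits[2L])
  X <- Matrix::bdiag(X1, X2)
  colnames(X) <- c(colnames(X1), colnames(X2))
  p <- ncol(X)
  Za <- rbind(cbind(incidence(aidx[o1], q), Matrix::Matrix(0, length(o1), q, sparse = TRUE)),
              cbind(Matrix::Matrix(0, length(o2), q, sparse = TRUE), incidence(aidx[o2], q)))
  Zm <- rbind(cbind(incidence(as.integer(dl)[o1], qd), Matrix::Matrix(0, length(o1), qd, sparse = TRUE)),
              cbind(Matrix::Matrix(0, length(o2), qd, sparse = TRUE), incidence(as.integer(dl)[o2], qd)))
  W <- cbind(X, Za, Zm)

  # residual structure bookkeeping: animals observed in both traits form
  # correlated 2x2 blocks
  both <- intersect(o1, o2)
  p1 <- match(both, o1)                    # rows (trait1 side) of pairs
  p2 <- length(o1) + match(both, o2)
  s1 <- setdiff(seq_along(o1), p1)
  s2 <- setdiff(length(o1) + seq_along(o2), p2)
  Wp1 <- W[p1, , drop = FALSE]; Wp2 <- W[p2, , drop = FALSE]
  Ws1 <- W[s1, , drop = FALSE]; Ws2 <- W[s2, , drop = FALSE]
  yp1 <- y[p1]; yp2 <- y[p2]; ys1 <- y[s1]; ys2 <- y[s2]
  M11 <- Matrix::crossprod(Wp1); M22 <- Matrix::crossprod(Wp2)
  M12 <- Matrix::crossprod(Wp1, Wp2)
  N1 <- Matrix::crossprod(Ws1); N2 <- Matrix::crossprod(Ws2)
  v_p1 <- as.numeric(Matrix::crossprod(Wp1, yp1))
  v_p2 <- as.numeric(Matrix::crossprod(Wp2, yp2))
  v_p12 <- as.numeric(Matrix::crossprod(Wp1, yp2))
  v_p21 <- as.numeric(Matrix::crossprod(Wp2, yp1))
  v_s1 <- as.numeric(Matrix::crossprod(Ws1, ys1))
  v_s2 <- as.numeric(Matrix::crossprod(Ws2, ys2))

  Ainv <- a_inverse(ped)
  ldetA <- -chol_logdet(Matrix::Cholesky(Ainv, LDL = FALSE))
  ldetXtX <- as.numeric(determinant(as.matrix(Matrix::crossprod(X)),
                                    logarithm = TRUE)$modulus)
  Iqd <- Matrix::Diagonal(qd)

  # fixed-pattern assembly of C over its 11 structural components
  m_dim <- ncol(W)
  lc <- sparse_lincomb(list(
    M11, M22, M12 + Matrix::t(M12), N1, N2,
    pad_sym(Ainv, m_dim, p), pad_sym(Ainv, m_dim, p + q),
    pad_cross(Ainv, m_dim, p, p + q),
    pad_sym(Iqd, m_dim, p + 2L * q),
    pad_sym(Iqd, m_dim, p + 2L * q + qd),
    pad_cross(Iqd, m_dim, p + 2L * q, p + 2L * q + qd)))

  free_re <- !sex_as_traits && length(both) > 0L
  cov2 <- function(v1, v2, r) {
    matrix(c(v1, r * sqrt(v1 * v2), r * sqrt(v1 * v2), v2), 2, 2)
  }

  # parameters: log-variances and atanh-correlations
  pn <- c("la1", "la2", "za", "lm1", "lm2", "zm", "le1", "le2",
          if (free_re) "ze")
  if (!is.null(fix_ra)) pn <- setdiff(pn, "za")

  v1 <- var(y1, na.rm = TRUE); v2 <- var(y2, na.rm = TRUE)
  r0 <- if (length(both) > 10L) {
    max(min(stats::cor(y1[both], y2[both]), 0.9), -0.9)
  } else 0.5
  st <- list(additive = c(0.3 * v1, 0.3 * v2, r0),
             maternal = c(0.05 * v1, 0.05 * v2, r0 / 2),
             residual = c(0.6 * v1, 0.6 * v2, r0))
  if (is.null(start) && prefit) {
    uni <- lapply(traits, function(tr)
      fit_animal_model(data, ped, model_spec(tr, fixed = fixed), se = FALSE))
    g <- function(i, nm) uni[[i]]$theta[[nm]]
    st$additive[1:2] <- c(g(1, "additive"), g(2, "additive"))
    st$maternal[1:2] <- pmax(c(g(1, "maternal_env"), g(2, "maternal_env")),
                             1e-4 * c(v1, v2))
    st$residual[1:2] <- c(g(1, "residual"), g(2, "residual"))
  }
  if (!is.null(start)) st[names(start)] <- start
  z_full <- c(la1 = log(st$additive[1L]), la2 = log(st$additive[2L]),
              za = atanh(max(min(st$additive[3L], 0.95), -0.95)),
              lm1 = log(st$maternal[1L]), lm2 = log(st$maternal[2L]),
              zm = atanh(max(min(st$maternal[3L], 0.95), -0.95)),
              le1 = log(st$residual[1L]), le2 = log(st$residual[2L]),
              ze = atanh(max(min(st$residual[3L], 0.95), -0.95)))
  z0 <- z_full[pn]

  unpack <- function(z) {
    zf <- z_full
    zf[pn] <- z
    ra <- if (is.null(fix_ra)) tanh(zf[["za"]]) else fix_ra
    re <- if (free_re) tanh(zf[["ze"]]) else 0
    list(Sa = cov2(exp(zf[["la1"]]), exp(zf[["la2"]]), ra),
         Sm = cov2(exp(zf[["lm1"]]), exp(zf[["lm2"]]), tanh(zf[["zm"]])),
         Se = cov2(exp(zf[["le1"]]), exp(zf[["le2"]]), re))
  }

  chol_cache <- NULL
  objective <- function(par) {
    Sa <- par$Sa; Sm <- par$Sm; Se <- par$Se
    Ei <- solve(Se)
    Sai <- solve(Sa)
    Smi <- solve(Sm)
    C <- lc$eval(c(Ei[1, 1], Ei[2, 2], Ei[1, 2],
                   1 / Se[1, 1], 1 / Se[2, 2],
                   Sai[1, 1], Sai[2, 2], Sai[1, 2],
                   Smi[1, 1], Smi[2, 2], Smi[1, 2]))
    WRy <- Ei[1, 1] * v_p1 + Ei[2, 2] * v_p2 + Ei[1, 2] * (v_p12 + v_p21) +
      v_s1 / Se[1, 1] + v_s2 / Se[2, 2]
    yRy <- Ei[1, 1] * sum(yp1^2) + Ei[2, 2] * sum(yp2^2) +
      2 * Ei[1, 2] * sum(yp1 * yp2) +
      sum(ys1^2) / Se[1, 1] + sum(ys2^2) / Se[2, 2]
    if (is.null(chol_cache)) {
      chol_cache <<- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    } else {
      chol_cache <<- update(chol_cache, C)
    }
    sol <- as.numeric(Matrix::solve(chol_cache, WRy, system = "A"))
    ypy <- yRy - sum(sol * WRy)
    ldetR <- length(p1) * as.numeric(determinant(Se, TRUE)$modulus) +
      length(s1) * log(Se[1, 1]) + length(s2) * log(Se[2, 2])
    ldetG <- q * as.numeric(determinant(Sa, TRUE)$modulus) + 2 * ldetA +
      qd * as.numeric(determinant(Sm, TRUE)$modulus)
    ll <- -0.5 * ((n - p) * log(2 * pi) + ldetR + ldetG +
                  chol_logdet(chol_cache) + ypy - ldetXtX)
    attr(ll, "sol") <- sol
    ll
  }

  n_eval <- 0L
  neg <- function(z) {
    n_eval <<- n_eval + 1L
    -as.numeric(objective(unpack(z)))
  }
  opt <- optim(z0, neg, method = "Nelder-Mead",
               control = list(reltol = 1e-8, maxit = 5000))
  converged <- opt$convergence == 0L
  par_hat <- unpack(opt$par)
  ll <- objective(par_hat)
  sol <- attr(ll, "sol")

  ebv <- matrix(sol[p + seq_len(2 * q)], q, 2,
                dimnames = list(ped$animal, traits))
  beta <- sol[seq_len(p)]

  corr_of <- function(S) S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  Sa <- par_hat$Sa; Sm <- par_hat$Sm; Se <- par_hat$Se
  Sp <- Sa + Sm + Se
  res <- list(
    traits = traits,
    components = list(additive = Sa, maternal = Sm, residual = Se),
    r_a = corr_of(Sa), r_m = corr_of(Sm),
    r_e = if (free_re) corr_of(Se) else NA_real_,
    r_p = corr_of(Sp),
    h2 = diag(Sa) / diag(Sp), m2 = diag(Sm) / diag(Sp),
    sigma2_p = diag(Sp),
    fix_ra = fix_ra,
    fixed_effects = data.frame(term = colnames(X), estimate = beta,
                               row.names = NULL),
    ebv = ebv, logL = as.numeric(ll), converged = converged,
    n_evaluations = n_eval, n = n, p = p,
    boundary = abs(corr_of(Sa)) >= 0.99)

  if (se) {
    # Hessian on the natural scale (v1, v2, r) per matrix
    nat <- c(a1 = Sa[1, 1], a2 = Sa[2, 2], ra = corr_of(Sa),
             m1 = Sm[1, 1], m2 = Sm[2, 2], rm = corr_of(Sm),
             e1 = Se[1, 1], e2 = Se[2, 2],
             if (free_re) c(re = corr_of(Se)))
    fr <- names(nat)
    if (!is.null(fix_ra)) fr <- setdiff(fr, "ra")
    f <- function(v) {
      nt <- nat
      nt[fr] <- v
      if (any(nt[c("a1", "a2", "m1", "m2", "e1", "e2")] <= 0)) return(NA_real_)
      rr <- c(nt["ra"], nt["rm"], if (free_re) nt["re"] else 0)
      if (any(abs(rr) >= 1)) return(NA_real_)
      as.numeric(objective(list(
        Sa = cov2(nt[["a1"]], nt[["a2"]],
                  if (is.null(fix_ra)) nt[["ra"]] else fix_ra),
        Sm = cov2(nt[["m1"]], nt[["m2"]], nt[["rm"]]),
        Se = cov2(nt[["e1"]], nt[["e2"]],
                  if (free_re) nt[["re"]] else 0))))
    }
    H <- num_hessian(f, nat[fr])
    vc_cov <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(vc_cov)) {
      dimnames(vc_cov) <- list(fr, fr)
      res$vc_cov <- vc_cov
      res$se <- setNames(sqrt(pmax(diag(vc_cov), 0)), fr)
    }
  }
  structure(res, class = "nab_bifit")
}

#' @export
print.nab_bifit <- function(x, ...) {
  cat("Bivariate animal-model REML fit:", paste(x$traits, collapse = " / "), "\n")
  cat("  logL:", format(x$logL, digits = 8), " converged:", x$converged, "\n")
  cat(sprintf("  r_a = %.3f  r_m = %.3f  r_e = %s  r_p = %.3f\n",
              x$r_a, x$r_m,
              if (is.na(x$r_e)) "fixed 0" else sprintf("%.3f", x$r_e),
              x$r_p))
  cat("  h2:", paste(sprintf("%.3f", x$h2), collapse = ", "),
      " m2:", paste(sprintf("%.3f", x$m2), collapse = ", "), "\n")
  invisible(x)
}
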