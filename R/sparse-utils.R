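# Fast repeated assembly of mixed-model-equation coefficient matrices.
#
# REML optimization refactorizes C(theta) = sum_k coef_k(theta) * M_k many
# times with a fixed sparsity pattern. sparse_lincomb() precomputes, for a
# list of symmetric sparse components, their entry positions inside the
# union pattern, so each evaluation is a handful of scatter-adds into the
# @x slot of one prebuilt dsCMatrix — no coercions, no pattern analysis.

as_dsC <- function(m) {
  m <- methods::as(m, "CsparseMatrix")
  m <- Matrix::forceSymmetric(m, uplo = "U")
  methods::as(m, "CsparseMatrix")
}

# symmetric sparse matrix M embedded at diagonal offset (off, off), or the
# symmetrized cross block M placed at (roff, coff) plus its transpose
pad_sym <- function(M, dim_out, off) {
  T <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  as_dsC(Matrix::sparseMatrix(i = T@i + 1L + off, j = T@j + 1L + off,
                              x = T@x, dims = c(dim_out, dim_out)))
}

pad_cross <- function(M, dim_out, roff, coff) {
  T <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  P <- Matrix::sparseMatrix(i = T@i + 1L + roff, j = T@j + 1L + coff,
                            x = T@x, dims = c(dim_out, dim_out))
  as_dsC(P + Matrix::t(P))
}

sparse_lincomb <- function(mats) {
  ms <- lapply(mats, as_dsC)
  d <- ncol(ms[[1L]])
  tmpl <- Reduce(`+`, lapply(ms, function(m) {
    m@x[] <- 1
    m
  }))
  tmpl <- as_dsC(tmpl)
  keys <- function(m) {
    j <- rep.int(seq_len(d), diff(m@p))
    as.double(m@i) * d + j
  }
  tk <- keys(tmpl)
  parts <- lapply(ms, function(m) {
    list(pos = match(keys(m), tk), val = m@x)
  })
  nnz <- length(tmpl@x)
  list(
    eval = function(coefs) {
      x <- numeric(nnz)
      for (k in seq_along(parts))
        if (coefs[k] != 0) {
          pk <- parts[[k]]
          x[pk$pos] <- x[pk$pos] + coefs[k] * pk$val
        }
      tmpl@x <- x
      tmpl
    },
    template = tmpl)
}
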