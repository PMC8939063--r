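#' Build and validate a pedigree
#'
#' Validates raw parentage rows and returns a topologically sorted pedigree in
#' which every parent precedes its offspring. Unknown parents (encoded as
#' `0`, `""` or `NA`) are treated as unrelated, non-inbred founders.
#'
#' @param records data frame with columns `animal`, `sire`, `dam` and
#'   optionally `sex` (`"male"`/`"female"`), `generation` (integer) and
#'   `line` (`"base"`, `"high"`, `"low"`).
#' @param missing_parent what to do when a parent id never appears as an
#'   animal: `"founder"` adds it as a founder row, `"error"` aborts.
#' @return A data frame of class `nab_pedigree`, topologically sorted, with
#'   integer columns `sire_idx`/`dam_idx` (0 = unknown) pointing at row
#'   positions.
#' @examples
#' ped <- build_pedigree(data.frame(animal = c("A", "B", "C"),
#'                                  sire = c(0, 0, "A"),
#'                                  dam  = c(0, 0, "B")))
#' ped$animal
#' @export
build_pedigree <- function(records, missing_parent = c("founder", "error")) {
  missing_parent <- match.arg(missing_parent)
  stopifnot(is.data.frame(records))
  for (col in c("animal", "sire", "dam"))
    if (is.null(records[[col]])) stop("records must have a '", col, "' column")

  norm_id <- function(x) {
    x <- trimws(as.character(x))
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  animal <- norm_id(records$animal)
  if (anyNA(animal)) stop("missing animal identifiers")
  if (anyDuplicated(animal)) {
    stop("duplicated animal identifiers: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  sire <- norm_id(records$sire)
  dam <- norm_id(records$dam)

  sex <- if (is.null(records$sex)) rep(NA_character_, length(animal)) else {
    s <- tolower(trimws(as.character(records$sex)))
    s[s %in% c("m", "1")] <- "male"
    s[s %in% c("f", "2")] <- "female"
    if (!all(is.na(s) | s %in% c("male", "female")))
      stop("sex must be 'male' or 'female'")
    s
  }
  generation <- if (is.null(records$generation)) rep(NA_integer_, length(animal))
                else as.integer(records$generation)
  line <- if (is.null(records$line)) rep(NA_character_, length(animal))
          else as.character(records$line)

  # animals used both as sire and as dam carry contradictory sexes
  both <- intersect(unique(sire[!is.na(sire)]), unique(dam[!is.na(dam)]))
  if (length(both))
    stop("sex conflict: used as both sire and dam: ",
         paste(both, collapse = ", "))

  undefined <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), animal)
  if (length(undefined)) {
    if (missing_parent == "error")
      stop("parent referenced but never defined: ",
           paste(undefined, collapse = ", "))
    add_sex <- ifelse(undefined %in% sire, "male", "female")
    animal <- c(undefined, animal)
    sire <- c(rep(NA_character_, length(undefined)), sire)
    dam <- c(rep(NA_character_, length(undefined)), dam)
    sex <- c(add_sex, sex)
    generation <- c(rep(NA_integer_, length(undefined)), generation)
    line <- c(rep(NA_character_, length(undefined)), line)
  }

  # sex consistency against parental roles
  as_sire <- animal %in% sire
  as_dam <- animal %in% dam
  bad <- (as_sire & !is.na(sex) & sex == "female") |
         (as_dam & !is.na(sex) & sex == "male")
  if (any(bad))
    stop("sex conflict: parental role contradicts recorded sex for: ",
         paste(animal[bad], collapse = ", "))

  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  if (any(si == idx) || any(di == idx))
    stop("cycle detected: animal is its own parent: ",
         paste(animal[si == idx | di == idx], collapse = ", "))

  # Kahn's algorithm: parents before offspring
  n_par <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in idx) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  order_out <- integer(0)
  queue <- which(n_par == 0L)
  remaining <- n_par
  while (length(queue)) {
    queue <- queue[order(queue)]
    v <- queue[1L]
    queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (ch in children[[v]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) < n)
    stop("cycle detected among: ",
         paste(animal[setdiff(idx, order_out)], collapse = ", "))

  pos <- integer(n)
  pos[order_out] <- seq_len(n)
  ped <- data.frame(animal = animal[order_out],
                    sire = sire[order_out],
                    dam = dam[order_out],
                    sex = sex[order_out],
                    generation = generation[order_out],
                    line = line[order_out],
                    stringsAsFactors = FALSE)
  remap <- function(v) {
    out <- integer(length(v))
    out[v > 0L] <- pos[v[v > 0L]]
    out
  }
  ped$sire_idx <- remap(si[order_out])
  ped$dam_idx <- remap(di[order_out])
  class(ped) <- c("nab_pedigree", "data.frame")
  ped
}

#' Read a pedigree CSV
#'
#' Expects a header-bearing CSV with columns
#' `animal,sire,dam,sex,generation,line`; unknown parents encoded as `0` or
#' empty.
#'
#' @param file path to the CSV file.
#' @inheritParams build_pedigree
#' @return a [build_pedigree()] result.
#' @export
read_pedigree <- function(file, missing_parent = "founder") {
  build_pedigree(read.csv(file, stringsAsFactors = FALSE),
                 missing_parent = missing_parent)
}

#' Per-animal inbreeding coefficients
#'
#' Computes F by the Meuwissen–Luo algorithm (ancestor traversal of the
#' L-matrix rows with Mendelian-sampling variances), without materializing
#' the full relationship matrix.
#'
#' @param ped a [build_pedigree()] result.
#' @return named numeric vector of inbreeding coefficients, pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "nab_pedigree"))
  s <- ped$sire_idx
  d <- ped$dam_idx
  n <- length(s)
  Fv <- numeric(n)
  Dv <- numeric(n)
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0L) Fv[s[i]] else 0
    fd <- if (d[i] > 0L) Fv[d[i]] else 0
    np <- (s[i] > 0L) + (d[i] > 0L)
    Dv[i] <- switch(np + 1L, 1, 0.75 - 0.25 * (fs + fd),
                    0.5 - 0.25 * (fs + fd))
    if (s[i] == 0L || d[i] == 0L) next          # founders/one unknown: F = 0
    L <- numeric(i)
    L[i] <- 1
    for (j in i:1) {
      lj <- L[j]
      if (lj != 0) {
        if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
        if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
      }
    }
    Fv[i] <- sum(L * L * Dv[seq_len(i)]) - 1
  }
  names(Fv) <- ped$animal
  Fv
}

#' Numerator relationship matrix and inbreeding summary
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' recursion a_ij = 0.5 (a_i,sire(j) + a_i,dam(j)), with diagonal
#' 1 + 0.5 a_sire,dam. Dense A is only materialized for moderate pedigrees;
#' use [a_inverse()] for model fitting.
#'
#' @param ped a [build_pedigree()] result.
#' @param max_n refuse to materialize dense A above this many animals.
#' @return list of class `relationship_summary` with elements `a_matrix`
#'   (dense, dimnames = animal ids), `inbreeding` (named vector F = diag − 1)
#'   and `group_means` (mean F by line x generation, when labels exist).
#' @export
relationship_matrix <- function(ped, max_n = 2000L) {
  stopifnot(inherits(ped, "nab_pedigree"))
  n <- nrow(ped)
  if (n > max_n)
    stop("refusing dense A for ", n, " animals (max_n = ", max_n, ")")
  s <- ped$sire_idx
  d <- ped$dam_idx
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (s[i] > 0L) A[s[i], j] else 0) +
                    (if (d[i] > 0L) A[d[i], j] else 0))
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + (if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0)
  }
  Fv <- diag(A) - 1
  gm <- NULL
  if (!all(is.na(ped$generation)) || !all(is.na(ped$line))) {
    keep <- !is.na(ped$generation) & !is.na(ped$line)
    if (any(keep)) {
      gm <- aggregate(list(mean_F = Fv[keep]),
                      by = list(line = ped$line[keep],
                                generation = ped$generation[keep]),
                      FUN = mean)
      gm <- gm[order(gm$line, gm$generation), , drop = FALSE]
      rownames(gm) <- NULL
    }
  }
  structure(list(a_matrix = A, inbreeding = Fv, group_means = gm),
            class = "relationship_summary")
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A^-1 directly from the pedigree by Henderson's rules with the
#' inbreeding correction: each animal contributes 1/D_i to the system, where
#' D_i is its Mendelian-sampling variance given parental inbreeding.
#'
#' @param ped a [build_pedigree()] result.
#' @param f optional precomputed inbreeding coefficients (pedigree order);
#'   computed by [inbreeding()] when `NULL`.
#' @return sparse symmetric matrix (`dsCMatrix`) with animal-id dimnames.
#' @export
a_inverse <- function(ped, f = NULL) {
  stopifnot(inherits(ped, "nab_pedigree"))
  n <- nrow(ped)
  if (is.null(f)) f <- inbreeding(ped)
  s <- ped$sire_idx
  d <- ped$dam_idx
  fs <- ifelse(s > 0L, f[pmax(s, 1L)], 0)
  fd <- ifelse(d > 0L, f[pmax(d, 1L)], 0)
  np <- (s > 0L) + (d > 0L)
  Dv <- ifelse(np == 2L, 0.5 - 0.25 * (fs + fd),
        ifelse(np == 1L, 0.75 - 0.25 * (fs + fd), 1))
  al <- 1 / Dv
  i_idx <- seq_len(n)

  ii <- c(i_idx, s[s > 0L], i_idx[s > 0L], d[d > 0L], i_idx[d > 0L],
          s[s > 0L & d > 0L], d[s > 0L & d > 0L],
          s[s > 0L], d[d > 0L])
  jj <- c(i_idx, i_idx[s > 0L], s[s > 0L], i_idx[d > 0L], d[d > 0L],
          d[s > 0L & d > 0L], s[s > 0L & d > 0L],
          s[s > 0L], d[d > 0L])
  xx <- c(al,
          rep(-al[s > 0L] / 2, 2),
          rep(-al[d > 0L] / 2, 2),
          rep(al[s > 0L & d > 0L] / 4, 2),
          al[s > 0L] / 4, al[d > 0L] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  methods::as(Matrix::forceSymmetric(Ainv), "CsparseMatrix")
}

#' Inbreeding trend by line and generation
#'
#' Mean inbreeding per line x generation with the per-generation rate
#' `delta_F_t = (Fbar_t − Fbar_{t−1}) / (1 − Fbar_{t−1})`, the standard
#' rate-of-inbreeding definition.
#'
#' @param ped a [build_pedigree()] result with `line` and `generation`.
#' @param f optional precomputed inbreeding coefficients (pedigree order).
#' @return data frame with `line`, `generation`, `n`, `mean_F`, `delta_F`.
#' @export
inbreeding_trend <- function(ped, f = NULL) {
  stopifnot(inherits(ped, "nab_pedigree"))
  if (is.null(f)) f <- inbreeding(ped)
  keep <- !is.na(ped$line) & !is.na(ped$generation)
  if (!all(keep)) warning(sum(!keep), " animals without line/generation excluded")
  dat <- data.frame(line = ped$line[keep], generation = ped$generation[keep],
                    f = f[keep])
  out <- aggregate(f ~ line + generation, data = dat,
                   FUN = function(x) c(n = length(x), mean = mean(x)))
  res <- data.frame(line = out$line, generation = out$generation,
                    n = out$f[, "n"], mean_F = out$f[, "mean"])
  res <- res[order(res$line, res$generation), , drop = FALSE]
  res$delta_F <- NA_real_
  for (ln in unique(res$line)) {
    w <- which(res$line == ln)
    if (length(w) > 1L) {
      fm <- res$mean_F[w]
      res$delta_F[w[-1L]] <- (fm[-1L] - fm[-length(fm)]) /
        (1 - fm[-length(fm)])
    }
  }
  rownames(res) <- NULL
  res
}

#' Write per-animal inbreeding and group means to CSV
#'
#' @param ped a [build_pedigree()] result.
#' @param dir output directory (created if needed).
#' @param f optional precomputed inbreeding coefficients.
#' @return invisibly, the two file paths written.
#' @export
write_inbreeding <- function(ped, dir, f = NULL) {
  if (is.null(f)) f <- inbreeding(ped)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "inbreeding.csv")
  write.csv(data.frame(animal = ped$animal, f = fmt10(f)),
            p1, row.names = FALSE, quote = FALSE)
  tr <- inbreeding_trend(ped, f = f)
  tr$mean_F <- fmt10(tr$mean_F)
  tr$delta_F <- fmt10(tr$delta_F)
  p2 <- file.path(dir, "inbreeding_trend.csv")
  write.csv(tr, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

# 10 significant digits for all floats written to disk
fmt10 <- function(x) ifelse(is.na(x), NA, formatC(x, digits = 10, format = "g"))
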