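#' Inbreeding coefficients and Mendelian sampling variances
#'
#' Computes the exact inbreeding coefficient F for every animal by the
#' Meuwissen & Luo (1992) recursion, together with the Mendelian sampling
#' variance scaling d used by Henderson's rules for the inverse numerator
#' relationship matrix:
#' \deqn{d_i = 0.5 - 0.25 (F_s + F_d),}
#' where an unknown parent contributes F = -1, so d = 1 for founders and
#' 0.75 for animals with one known parent.
#'
#' @param ped a [pedigree()] object.
#' @return A list of class `"relationship_factors"` with numeric vectors
#'   `f` (inbreeding, 0 for founders) and `d` (in (0, 1]), both in pedigree
#'   order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  s <- ifelse(is.na(ped$sire), -1L, ped$sire - 1L)
  d <- ifelse(is.na(ped$dam), -1L, ped$dam - 1L)
  out <- ml_inbreeding(s, d)
  structure(out, class = "relationship_factors")
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse by Henderson's rules with inbreeding: for animal i with
#' Mendelian variance scaling d_i, add 1/d_i at (i,i), -0.5/d_i between i and
#' each known parent, and 0.25/d_i between (pairs of) known parents.
#'
#' @param ped a [pedigree()] object.
#' @param factors optionally, precomputed [inbreeding()] output.
#' @return A sparse symmetric matrix (`dsCMatrix`) of order `ped$n` with
#'   dimnames equal to the animal tokens.
#' @export
a_inverse <- function(ped, factors = inbreeding(ped)) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$n
  a <- seq_len(n)
  s <- ped$sire
  m <- ped$dam
  w <- 1 / factors$d

  ii <- list(a); jj <- list(a); xx <- list(w)
  ks <- !is.na(s)
  km <- !is.na(m)
  ii <- c(ii, list(a[ks], s[ks], a[km], m[km], s[ks & km], m[ks & km],
                   s[ks], m[km]))
  jj <- c(jj, list(s[ks], a[ks], m[km], a[km], m[ks & km], s[ks & km],
                   s[ks], m[km]))
  xx <- c(xx, list(-0.5 * w[ks], -0.5 * w[ks], -0.5 * w[km], -0.5 * w[km],
                   0.25 * w[ks & km], 0.25 * w[ks & km],
                   0.25 * w[ks], 0.25 * w[km]))
  A_inv <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n, n), dimnames = list(ped$id, ped$id)
  )
  methods::as(Matrix::forceSymmetric(A_inv), "CsparseMatrix")
}

#' Triangular factor of A-inverse
#'
#' Returns the sparse lower-triangular matrix U with A-inverse = U'U, built
#' from the decomposition A^-1 = (I - P)' D^-1 (I - P), where P carries 0.5
#' at (animal, known parent) and D = diag(d). Also returns log det(A) =
#' sum(log d), used in restricted likelihood evaluation.
#'
#' @param ped a [pedigree()] object.
#' @param factors optionally, precomputed [inbreeding()] output.
#' @return list with sparse matrix `u` (lower triangular, n x n) and scalar
#'   `logdet_a`.
#' @keywords internal
ainv_factor <- function(ped, factors = inbreeding(ped)) {
  n <- ped$n
  a <- seq_len(n)
  s <- ped$sire
  m <- ped$dam
  rd <- 1 / sqrt(factors$d)
  ks <- !is.na(s)
  km <- !is.na(m)
  u <- Matrix::sparseMatrix(
    i = c(a, a[ks], a[km]),
    j = c(a, s[ks], m[km]),
    x = c(rd, -0.5 * rd[ks], -0.5 * rd[km]),
    dims = c(n, n)
  )
  list(u = u, logdet_a = sum(log(factors$d)))
}

#' Dense relationship submatrix by the tabular method
#'
#' Computes the numerator relationship matrix A restricted to the requested
#' animals, by running the tabular method over the ancestral closure of those
#' animals. Diagonals equal 1 + F. Intended for moderate id sets; the
#' closure is materialised densely.
#'
#' @param ped a [pedigree()] object.
#' @param ids animal tokens (default: all animals).
#' @return dense numeric matrix with dimnames = requested ids.
#' @export
relationship_matrix <- function(ped, ids = ped$id) {
  idx <- ped_index(ped, ids)
  # ancestral closure
  need <- logical(ped$n)
  need[idx] <- TRUE
  for (i in rev(seq_len(ped$n))) {
    if (need[i]) {
      if (!is.na(ped$sire[i])) need[ped$sire[i]] <- TRUE
      if (!is.na(ped$dam[i])) need[ped$dam[i]] <- TRUE
    }
  }
  cl <- which(need)  # increasing => topologically valid
  pos <- integer(ped$n)
  pos[cl] <- seq_along(cl)
  m <- length(cl)
  A <- matrix(0, m, m)
  for (k in seq_len(m)) {
    i <- cl[k]
    s <- ped$sire[i]; d <- ped$dam[i]
    sp <- if (!is.na(s)) pos[s] else 0L
    dp <- if (!is.na(d)) pos[d] else 0L
    A[k, k] <- 1 + if (sp > 0L && dp > 0L) 0.5 * A[sp, dp] else 0
    if (k > 1L) {
      prev <- seq_len(k - 1L)
      v <- numeric(k - 1L)
      if (sp > 0L) v <- v + 0.5 * A[prev, sp]
      if (dp > 0L) v <- v + 0.5 * A[prev, dp]
      A[k, prev] <- v
      A[prev, k] <- v
    }
  }
  out <- A[pos[idx], pos[idx], drop = FALSE]
  dimnames(out) <- list(ped$id[idx], ped$id[idx])
  out
}
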