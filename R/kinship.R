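#' Numerator relationship matrix from a pedigree
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' (recursive) method, including inbreeding: for animal \eqn{i} with
#' parents \eqn{s, d},
#' \eqn{a_{ij} = \tfrac12 (a_{js} + a_{jd})} for earlier animals \eqn{j}
#' and \eqn{a_{ii} = 1 + F_i} with \eqn{F_i = \tfrac12 a_{sd}}.
#' Unknown parents contribute 0 and are treated as unrelated, non-inbred
#' founders.
#'
#' @param ped a pedigree data frame (\code{animal}, \code{sire},
#'   \code{dam}; \code{NA} = unknown), topologically ordered.
#' @return a dense symmetric matrix with animal ids as dimnames.
#' @export
#' @examples
#' ped <- data.frame(animal = c("s", "d", "o"),
#'                   sire = c(NA, NA, "s"), dam = c(NA, NA, "d"))
#' build_a_matrix(ped)["s", "o"]  # parent-offspring relationship 0.5
build_a_matrix <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (s) A[j, s] else 0) + (if (d) A[j, d] else 0))
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s && d) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' @param ped a topologically ordered pedigree.
#' @return named vector of inbreeding coefficients \eqn{F_i}.
#' @export
inbreeding <- function(ped) {
  diag(build_a_matrix(ped)) - 1
}

#' Inverse of the numerator relationship matrix by Henderson's rules
#'
#' Assembles \eqn{A^{-1}} directly in sparse triplet form without forming
#' A: each animal contributes \eqn{\alpha_i = 1/d_i} with Mendelian
#' sampling variance \eqn{d_i = \tfrac12 - \tfrac14 (F_s + F_d)} when both
#' parents are known, \eqn{d_i = \tfrac34 - \tfrac14 F_{known}} with one
#' known parent, and \eqn{d_i = 1} for founders; coefficients 1, -1/2, 1/4
#' go to the animal/parent index pairs.  Inbreeding coefficients come from
#' the tabular A computation.
#'
#' @param ped a topologically ordered pedigree.
#' @param f optional precomputed inbreeding coefficients in pedigree order
#'   (skips the tabular pass).
#' @return a sparse symmetric \code{\link[Matrix]{Matrix}} with animal ids
#'   as dimnames.
#' @export
build_a_inverse <- function(ped, f = NULL) {
  validate_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  if (is.null(f)) f <- inbreeding(ped) else stopifnot(length(f) == n)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dmend <- if (s && d) 0.5 - 0.25 * (f[s] + f[d])
    else if (s || d) 0.75 - 0.25 * f[max(s, d)]
    else 1
    a <- 1 / dmend
    add(i, i, a)
    for (p in c(s, d)) {
      if (p) {
        add(i, p, -a / 2); add(p, i, -a / 2)
        add(p, p, a / 4)
      }
    }
    if (s && d) { add(s, d, a / 4); add(d, s, a / 4) }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}
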