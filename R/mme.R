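#' Variance specification for the SNP mixed model
#'
#' Variance components are inputs to the analysis (predetermined, as is
#' usual for deregressed-proof evaluations), not estimated.  The SNP prior
#' variance is \eqn{\sigma^2_a / N_{SNP}}, the residual polygenic variance
#' \eqn{\rho\,\sigma^2_a} with \eqn{\rho} the polygenic ratio (0.4 by
#' convention), and bull \eqn{i}'s residual variance
#' \eqn{\sigma^2_e / EDC_i}.
#'
#' @param sigma2_a additive genetic variance of the trait (trait units^2).
#' @param sigma2_e residual variance of one daughter-equivalent record.
#' @param polygenic_ratio fraction of \code{sigma2_a} assigned to the
#'   residual polygenic effect; default 0.4.
#' @return a list of class \code{"variance_spec"}.
#' @export
variance_spec <- function(sigma2_a, sigma2_e, polygenic_ratio = 0.4) {
  if (sigma2_a <= 0 || sigma2_e <= 0)
    stop("variance_spec: sigma2_a and sigma2_e must be > 0")
  if (polygenic_ratio <= 0 || polygenic_ratio > 1)
    stop("variance_spec: polygenic_ratio must lie in (0, 1]")
  structure(list(sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 polygenic_ratio = polygenic_ratio),
            class = "variance_spec")
}

#' Derive variance components from heritability
#'
#' Convenience helper mirroring how per-trait components are set from a
#' published heritability table: \eqn{\sigma^2_a = h^2\,\mathrm{var}(y)}
#' and \eqn{\sigma^2_e = (1 - h^2)\,\mathrm{var}(y)} with \eqn{y} the DRPs.
#' For high-EDC bulls the realised DRP residual variance is much smaller
#' than \eqn{\sigma^2_e} because it is divided by the EDC.
#'
#' @param drp numeric vector of deregressed proofs.
#' @param h2 heritability in (0, 1).
#' @param polygenic_ratio passed through to \code{\link{variance_spec}}.
#' @return a \code{\link{variance_spec}}.
#' @export
variances_from_h2 <- function(drp, h2, polygenic_ratio = 0.4) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
  vy <- stats::var(drp)
  variance_spec(h2 * vy, (1 - h2) * vy, polygenic_ratio)
}

#' Assemble and factorize Henderson's mixed-model equations
#'
#' Builds the 3x3-block coefficient matrix of the SNP-BLUP model with a
#' residual polygenic effect,
#' \deqn{y = Xb + Z_1 g + Z_2 a + e,}
#' with \eqn{X} a column of ones, \eqn{Z_1} the (imputed) genotype matrix
#' coded -1/0/1, \eqn{Z_2} the incidence of phenotyped bulls into the
#' pedigree, \eqn{R^{-1} = \mathrm{diag}(EDC_i)/\sigma^2_e},
#' \eqn{G_1^{-1} = I\,N_{SNP}/\sigma^2_a} and
#' \eqn{G_2^{-1} = A^{-1}/(\rho\,\sigma^2_a)}; factorizes it by Cholesky
#' and extracts the prediction-error variances of \eqn{g} from the inverse
#' coefficient matrix.  The factorization is kept so that many traits
#' sharing the same design (genotypes and EDCs) can be solved cheaply with
#' \code{\link{solve_mme}}.
#'
#' @param geno a complete (imputed) \code{\link{genotype_matrix}} whose rows
#'   cover the phenotyped animals.
#' @param edc named vector of effective daughter contributions, names =
#'   animal ids (the phenotyped bulls).
#' @param a_inv sparse inverse relationship matrix from
#'   \code{\link{build_a_inverse}}; may contain extra ancestors.
#' @param vs a \code{\link{variance_spec}}.
#' @return a list of class \code{"mme_system"} holding the Cholesky factor,
#'   prediction-error variances of g, index maps and dimensions.
#' @export
mme_system <- function(geno, edc, a_inv, vs) {
  stopifnot(inherits(vs, "variance_spec"))
  animals <- names(edc)
  if (is.null(animals)) stop("`edc` must be named by animal id")
  if (anyDuplicated(animals))
    stop("one EDC per bull expected; duplicated: ",
         animals[duplicated(animals)][1])
  if (any(edc <= 0)) stop("EDC must be strictly positive")
  G <- geno$genotypes
  missing_geno <- setdiff(animals, rownames(G))
  if (length(missing_geno))
    stop("phenotyped bulls without genotypes: ",
         paste(utils::head(missing_geno, 5), collapse = ", "))
  ped_ids <- rownames(a_inv)
  missing_ped <- setdiff(animals, ped_ids)
  if (length(missing_ped))
    stop("phenotyped bulls absent from the pedigree: ",
         paste(utils::head(missing_ped, 5), collapse = ", "))
  Z1 <- G[animals, , drop = FALSE]
  if (anyNA(Z1)) stop("genotypes contain missing calls; run impute_mean()")
  storage.mode(Z1) <- "double"
  n <- length(animals)
  m <- ncol(Z1)
  q <- length(ped_ids)
  pos <- match(animals, ped_ids)

  rinv <- edc / vs$sigma2_e
  g1_inv <- m / vs$sigma2_a
  g2_scale <- 1 / (vs$polygenic_ratio * vs$sigma2_a)

  p <- 1L + m + q
  C <- matrix(0, p, p)
  ib <- 1L
  ig <- 1L + seq_len(m)
  ia <- 1L + m + seq_len(q)

  Z1w <- Z1 * rinv                       # R^{-1} Z1
  C[ib, ib] <- sum(rinv)
  xz1 <- colSums(Z1w)
  C[ib, ig] <- xz1; C[ig, ib] <- xz1
  xz2 <- numeric(q); xz2[pos] <- rinv    # one record per bull
  C[ib, ia] <- xz2; C[ia, ib] <- xz2
  C[ig, ig] <- crossprod(Z1 * sqrt(rinv))
  diag(C)[ig] <- diag(C)[ig] + g1_inv
  C[ig, ia[pos]] <- t(Z1w)
  C[ia[pos], ig] <- Z1w
  z2rz2 <- numeric(q); z2rz2[pos] <- rinv
  A22 <- as.matrix(a_inv) * g2_scale
  C[ia, ia] <- A22
  diag(C)[ia] <- diag(C)[ia] + z2rz2

  R <- tryCatch(chol(C), error = function(e)
    stop("MME coefficient matrix is not positive definite (singular ",
         "system, e.g. duplicate SNP columns): ", conditionMessage(e)))
  Cinv_diag <- diag(chol2inv(R))
  structure(list(chol = R, pev_g = Cinv_diag[ig] ,
                 pev_a = Cinv_diag[ia],
                 animals = animals, ped_ids = ped_ids, pos = pos,
                 rinv = rinv, Z1 = Z1, map = geno$map,
                 n = n, m = m, q = q, ib = ib, ig = ig, ia = ia,
                 vs = vs),
            class = "mme_system")
}

#' Solve the mixed-model equations for one or more traits
#'
#' @param sys an \code{\link{mme_system}}.
#' @param y numeric vector of DRPs in the order of \code{sys$animals}, or a
#'   matrix with one column per replicate trait sharing the design.
#' @return for a vector \code{y}, a list of class \code{"mme_fit"} with
#'   \code{b_hat}, \code{g_hat} (named), \code{a_hat}, \code{pev_g} and
#'   \code{map}; for a matrix, a list with matrices \code{b_hat},
#'   \code{g_hat}, \code{a_hat} (columns = traits) and \code{pev_g}.
#' @export
solve_mme <- function(sys, y) {
  yv <- as.matrix(y)
  if (nrow(yv) != sys$n) stop("y must have one entry per phenotyped bull")
  k <- ncol(yv)
  ry <- yv * sys$rinv
  rhs <- matrix(0, 1L + sys$m + sys$q, k)
  rhs[sys$ib, ] <- colSums(ry)
  rhs[sys$ig, ] <- crossprod(sys$Z1, ry)
  rhs[sys$ia[sys$pos], ] <- ry
  sol <- backsolve(sys$chol, backsolve(sys$chol, rhs, transpose = TRUE))
  g_hat <- sol[sys$ig, , drop = FALSE]
  rownames(g_hat) <- colnames(sys$Z1)
  if (ncol(yv) == 1L) {
    structure(list(b_hat = sol[sys$ib, 1], g_hat = g_hat[, 1],
                   a_hat = stats::setNames(sol[sys$ia, 1], sys$ped_ids),
                   pev_g = stats::setNames(sys$pev_g, colnames(sys$Z1)),
                   map = sys$map, n = sys$n, m = sys$m, q = sys$q),
              class = "mme_fit")
  } else {
    list(b_hat = sol[sys$ib, ], g_hat = g_hat,
         a_hat = sol[sys$ia, , drop = FALSE],
         pev_g = stats::setNames(sys$pev_g, colnames(sys$Z1)),
         map = sys$map, n = sys$n, m = sys$m, q = sys$q)
  }
}

#' Assemble and solve the SNP-BLUP mixed-model equations
#'
#' One-call wrapper around \code{\link{mme_system}} and
#' \code{\link{solve_mme}} for a single trait.
#'
#' @param geno a complete (imputed) \code{\link{genotype_matrix}}.
#' @param trait data frame with columns \code{animal}, \code{drp},
#'   \code{edc}, one record per bull.
#' @param a_inv sparse \eqn{A^{-1}} from \code{\link{build_a_inverse}}.
#' @param vs a \code{\link{variance_spec}}.
#' @return an \code{"mme_fit"}; see \code{\link{solve_mme}}.
#' @export
assemble_and_solve_mme <- function(geno, trait, a_inv, vs) {
  stopifnot(all(c("animal", "drp", "edc") %in% names(trait)))
  if (anyDuplicated(trait$animal))
    stop("one DRP record per bull expected; duplicated: ",
         trait$animal[duplicated(trait$animal)][1])
  sys <- mme_system(geno, stats::setNames(trait$edc, trait$animal), a_inv, vs)
  solve_mme(sys, trait$drp)
}
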