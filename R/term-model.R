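#' Variance specification for the term-level model
#'
#' @param sigma2_p term-effect variance (trait units^2).
#' @param sigma2_e_star residual variance of the absolute SNP effects.
#' @param estimated logical flag: were these values estimated from the data
#'   (\code{\link{estimate_term_variances}}) or supplied?
#' @return a list of class \code{"term_variance_spec"}.
#' @export
term_variance_spec <- function(sigma2_p, sigma2_e_star, estimated = FALSE) {
  if (sigma2_p <= 0 || sigma2_e_star <= 0)
    stop("term_variance_spec: variances must be > 0")
  structure(list(sigma2_p = sigma2_p, sigma2_e_star = sigma2_e_star,
                 estimated = estimated),
            class = "term_variance_spec")
}

#' Fit the term-level mixed model
#'
#' Fits \deqn{y^* = u + Z^* p + e^*} where \eqn{y^*} holds the absolute
#' SNP effects, \eqn{u} is a fixed overall mean, \eqn{p \sim N(0,
#' P\sigma^2_p)} the random term effects with the overlap covariance
#' \eqn{P}, and \eqn{e^* \sim N(0, L\sigma^2_{e^*})} with \eqn{L} the
#' diagonal weight matrix (1 for SNPs assigned to a term, 10 otherwise).
#' The two-block mixed-model equations are solved densely; standard errors
#' are the square roots of the p-block diagonal of the inverse coefficient
#' matrix, Wald statistics are referred to the standard normal two-sided,
#' and Bonferroni correction uses the number of terms tested.
#'
#' @param inputs a \code{"term_model_inputs"} from
#'   \code{\link{build_term_inputs}}.
#' @param vs a \code{\link{term_variance_spec}}.
#' @param alpha family-wise significance level (default 0.05).
#' @param include_mean keep the fixed overall mean \eqn{u} (default TRUE;
#'   FALSE reduces the single-term model to a weighted ridge regression).
#' @return a data frame (term effect table) with columns \code{term_id},
#'   \code{effect}, \code{se}, \code{wald}, \code{p}, \code{p_bonf},
#'   \code{significant}, \code{n_snps}, \code{n_genes}; the fitted mean is
#'   attached as attribute \code{"u_hat"}.
#' @export
fit_term_model <- function(inputs, vs, alpha = 0.05, include_mean = TRUE) {
  stopifnot(inherits(inputs, "term_model_inputs"),
            inherits(vs, "term_variance_spec"))
  y <- inputs$y_star
  Z <- inputs$z_star
  P <- inputs$p_cov
  l <- inputs$l_weights
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("term covariance P is not positive definite; ",
         "rebuild it with term_overlap_covariance() (eigenvalue repair)")
  k <- ncol(Z)
  linv <- 1 / l
  Pinv <- chol2inv(chol(P))
  Cpp <- crossprod(Z * sqrt(linv)) / vs$sigma2_e_star + Pinv / vs$sigma2_p
  rp <- crossprod(Z, linv * y) / vs$sigma2_e_star
  if (include_mean) {
    C <- rbind(cbind(sum(linv) / vs$sigma2_e_star,
                     t(colSums(Z * linv)) / vs$sigma2_e_star),
               cbind(colSums(Z * linv) / vs$sigma2_e_star, Cpp))
    rhs <- c(sum(linv * y) / vs$sigma2_e_star, rp)
    Cinv <- chol2inv(chol(C))
    sol <- Cinv %*% rhs
    u_hat <- sol[1]
    p_hat <- sol[-1]
    se <- sqrt(diag(Cinv)[-1])
  } else {
    Cinv <- chol2inv(chol(Cpp))
    p_hat <- drop(Cinv %*% rp)
    u_hat <- 0
    se <- sqrt(diag(Cinv))
  }
  w <- p_hat / se
  p_nom <- 2 * pnorm(-abs(w))
  p_bonf <- pmin(1, k * p_nom)
  out <- data.frame(term_id = inputs$term_ids, effect = p_hat, se = se,
                    wald = w, p = p_nom, p_bonf = p_bonf,
                    significant = p_bonf <= alpha,
                    n_snps = as.integer(colSums(Z > 0)),
                    n_genes = as.integer(
                      inputs$genes_per_term[inputs$term_ids]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "u_hat") <- u_hat
  attr(out, "vs") <- vs
  out
}

#' Estimate the term-model variance components by profiled REML
#'
#' Profiles the restricted likelihood of the two-variance model over a grid
#' of ratios \eqn{\gamma = \sigma^2_{e^*}/\sigma^2_p}.  For each ratio the
#' scale \eqn{\sigma^2_p} has a closed-form REML estimate, so only the
#' one-dimensional grid is searched.  Computations use the Woodbury
#' identity on \eqn{K = Z^* P Z^{*T} + \gamma L}, so the cost is linear in
#' the number of SNPs.
#'
#' @param inputs a \code{"term_model_inputs"}.
#' @param grid positive ratio values to profile over (>= 2 distinct values
#'   unless a single value is deliberately repeated); default a log-spaced
#'   grid from 0.01 to 100.
#' @param include_mean profile the REML of the model with the fixed mean
#'   (default TRUE).
#' @return a \code{\link{term_variance_spec}} with \code{estimated = TRUE};
#'   attribute \code{"profile"} holds the grid and log-likelihoods.
#' @export
estimate_term_variances <- function(inputs,
                                    grid = 10^seq(-2, 2, length.out = 41),
                                    include_mean = TRUE) {
  stopifnot(inherits(inputs, "term_model_inputs"))
  if (length(grid) < 2) {
    if (length(grid) != 1) stop("empty ratio grid")
    grid <- rep(grid, 2)
  }
  if (any(grid <= 0)) stop("ratio grid must be positive")
  y <- inputs$y_star
  if (stats::sd(y) == 0)
    stop("degenerate response: constant absolute SNP effects")
  Z <- inputs$z_star
  P <- inputs$p_cov
  l <- inputs$l_weights
  n <- length(y)
  r <- if (include_mean) 1L else 0L
  Pinv <- chol2inv(chol(P))
  ldP <- as.numeric(determinant(P, logarithm = TRUE)$modulus)
  X <- matrix(1, n, 1)

  prof <- vapply(grid, function(g) {
    dinv <- 1 / (g * l)
    M <- Pinv + crossprod(Z * sqrt(dinv))
    cM <- chol(M)
    ldK <- sum(log(g * l)) + ldP +
      2 * sum(log(diag(cM)))
    Kinv_mult <- function(v) {
      dv <- dinv * v
      dv - dinv * (Z %*% backsolve(cM, backsolve(cM, crossprod(Z, dv),
                                                 transpose = TRUE)))
    }
    Ky <- Kinv_mult(y)
    if (include_mean) {
      KX <- Kinv_mult(X)
      xkx <- crossprod(X, KX)[1, 1]
      Py <- Ky - KX %*% (crossprod(X, Ky) / xkx)
      quad <- sum(y * Py)
      s2p <- quad / (n - r)
      -0.5 * ((n - r) * log(s2p) + ldK + log(xkx) + (n - r))
    } else {
      quad <- sum(y * Ky)
      s2p <- quad / n
      -0.5 * (n * log(s2p) + ldK + n)
    }
  }, numeric(1))

  best <- which.max(prof)
  g <- grid[best]
  dinv <- 1 / (g * l)
  M <- Pinv + crossprod(Z * sqrt(dinv))
  cM <- chol(M)
  Kinv_mult <- function(v) {
    dv <- dinv * v
    dv - dinv * (Z %*% backsolve(cM, backsolve(cM, crossprod(Z, dv),
                                               transpose = TRUE)))
  }
  Ky <- Kinv_mult(y)
  if (include_mean) {
    KX <- Kinv_mult(X)
    xkx <- crossprod(X, KX)[1, 1]
    Py <- Ky - KX %*% (crossprod(X, Ky) / xkx)
    s2p <- sum(y * Py) / (n - r)
  } else {
    s2p <- sum(y * Ky) / n
  }
  out <- term_variance_spec(s2p, g * s2p, estimated = TRUE)
  attr(out, "profile") <- data.frame(ratio = grid, reml_loglik = prof)
  out
}
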