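#' Per-SNP Wald tests with Bonferroni correction
#'
#' For every SNP, \eqn{W_j = \hat g_j / \sqrt{PEV_j}} where the
#' prediction-error variance comes from the inverse mixed-model coefficient
#' matrix; under the null hypothesis \eqn{g_j = 0} the statistic is
#' referred to the standard normal, two-sided.  Bonferroni-adjusted
#' p-values are \eqn{\min(1, m\,p)} with \eqn{m} the number of SNPs tested.
#'
#' @param sol an \code{"mme_fit"} from \code{\link{assemble_and_solve_mme}}.
#' @param alpha family-wise significance level for the \code{significant}
#'   flag (default 0.05).
#' @return a data frame (the SNP effect table) with columns \code{snp_id},
#'   \code{chrom}, \code{pos_bp}, \code{effect}, \code{se}, \code{wald},
#'   \code{p}, \code{p_bonf}, \code{significant}.
#' @export
wald_tests <- function(sol, alpha = 0.05) {
  g <- sol$g_hat
  pev <- sol$pev_g
  bad <- !(pev > 0)
  if (any(bad))
    stop("non-positive prediction-error variance for SNP ",
         names(pev)[bad][1])
  se <- sqrt(pev)
  w <- g / se
  p <- 2 * pnorm(-abs(w))
  m <- length(g)
  p_bonf <- pmin(1, m * p)
  map <- sol$map
  stopifnot(identical(map$snp_id, names(g)))
  data.frame(snp_id = map$snp_id, chrom = map$chrom, pos_bp = map$pos_bp,
             effect = unname(g), se = unname(se), wald = unname(w),
             p = unname(p), p_bonf = unname(p_bonf),
             significant = unname(p_bonf <= alpha),
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected critical value of the Wald statistic
#'
#' Upper standard-normal quantile at \eqn{1 - \alpha/(2m)}: the |W| value a
#' SNP must exceed for two-sided family-wise significance at level
#' \code{alpha} over \code{m} tests.  With \code{m = 1} this is the nominal
#' critical value (1.96 at 5\%); at medium-density chip scale
#' (\code{m = 46216}) it is 4.88.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of tests (>= 1).
#' @return the critical |W| value.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  qnorm(1 - alpha / (2 * m))
}

#' Genomic inflation factor
#'
#' Genomic-control lambda: the median of the squared Wald statistics
#' divided by the median of the chi-square distribution with one degree of
#' freedom (0.4549...).  Values near 1 indicate calibrated tests; values
#' above 1, inflation.
#'
#' @param table a SNP effect table from \code{\link{wald_tests}}, or a
#'   numeric vector of Wald statistics.
#' @return lambda (dimensionless).
#' @export
inflation_lambda <- function(table) {
  w <- if (is.numeric(table)) table else table$wald
  if (!length(w)) stop("inflation_lambda: no Wald statistics")
  median(w^2) / qchisq(0.5, df = 1)
}

#' Phenotypic variance explained by the significant SNPs
#'
#' Empirical convention: the variance over bulls of the genetic values
#' built from the significant SNPs only,
#' \eqn{\mathrm{var}(Z_{1,sig}\,\hat g_{sig})} with centred genotype
#' columns, divided by the phenotypic variance of the DRPs, as a
#' percentage.
#'
#' @param table a SNP effect table from \code{\link{wald_tests}}.
#' @param geno the (imputed) \code{\link{genotype_matrix}} used in the fit.
#' @param trait the trait data frame (\code{animal}, \code{drp},
#'   \code{edc}).
#' @return percentage of phenotypic variance explained (0 if no SNP is
#'   significant).
#' @export
variance_explained <- function(table, geno, trait) {
  sig <- table$snp_id[table$significant]
  if (!length(sig)) return(0)
  Z <- geno$genotypes[trait$animal, sig, drop = FALSE]
  if (anyNA(Z)) stop("genotypes contain missing calls; run impute_mean()")
  storage.mode(Z) <- "double"
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  gv <- drop(Zc %*% table$effect[table$significant])
  if (nrow(Zc) < 2) return(0)
  100 * stats::var(gv) / stats::var(trait$drp)
}
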