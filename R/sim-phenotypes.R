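#' Simulate deregressed proofs with known ground truth
#'
#' Builds phenotypes under the additive model
#' \deqn{y = \mu + Z_1 g + a + e}
#' where \eqn{g} holds the true SNP effects, \eqn{a} the residual polygenic
#' values generated through the pedigree recursion, and
#' \eqn{e_i \sim N(0, \sigma^2_e / EDC_i)} the DRP residual whose variance
#' shrinks with a bull's effective daughter contribution.
#'
#' SNP effects are i.i.d. \eqn{N(0, \sigma^2_a / N_{SNP})} unless
#' \code{cfg$n_causal} concentrates \code{cfg$causal_var_fraction} of
#' \eqn{\sigma^2_a} on a random causal subset.  Polygenic values follow the
#' standard recursion: founders \eqn{N(0, \rho\sigma^2_a)} with
#' \eqn{\rho} the polygenic ratio, offspring = parent average + a Mendelian
#' sampling deviation with variance
#' \eqn{\tfrac12 \rho\sigma^2_a (1 - (F_s + F_d)/2)} (half-unknown
#' parentage uses the matching three-quarter variance), so that the
#' generated vector has covariance \eqn{A\,\rho\sigma^2_a}.
#'
#' @param geno a \code{\link{genotype_matrix}} covering the phenotyped
#'   animals; its \code{complete} genotypes (or the observed ones when no
#'   call is missing) enter the genetic values.
#' @param ped the pedigree the genotypes were dropped through.
#' @param cfg a \code{\link{sim_config}}.
#' @param seed seed for this trait's draws; defaults to the config seed.
#'   Pass different seeds to create replicate traits on the same genotypes.
#'   EDCs are a design-level quantity and always derive from the config
#'   seed, so replicate traits share them (and the factorized MME).
#' @param g_true optional vector of true SNP effects overriding the random
#'   draw (e.g. all zero for a null trait).
#' @param causal_ids optional SNP ids forced to be the causal subset when
#'   \code{cfg$n_causal} is set (used for shared-causal multi-trait runs).
#' @return a list with \code{trait} (data frame \code{animal}, \code{drp},
#'   \code{edc}) and \code{truth} (list \code{g_true}, \code{a_true},
#'   \code{causal_snp_ids}, \code{mu}).
#' @export
simulate_phenotypes <- function(geno, ped, cfg, seed = cfg$seed,
                                g_true = NULL, causal_ids = NULL) {
  validate_pedigree(ped)
  validate_sim_config(cfg)
  if (cfg$sigma2_e < 0 || cfg$sigma2_a < 0) stop("variances must be >= 0")
  Z1 <- geno$complete
  if (is.null(Z1)) Z1 <- geno$genotypes
  if (anyNA(Z1))
    stop("phenotype construction needs complete genotypes; impute first")
  if (!all(rownames(Z1) %in% ped$animal))
    stop("genotyped animals missing from the pedigree")
  m <- ncol(Z1)

  set.seed(derive_seed(seed, "phenotypes"))
  if (is.null(g_true)) {
    if (is.null(cfg$n_causal)) {
      g_true <- rnorm(m, 0, sqrt(cfg$sigma2_a / m))
    } else {
      k <- cfg$n_causal
      if (is.null(causal_ids)) causal_ids <- sample(colnames(Z1), k)
      stopifnot(all(causal_ids %in% colnames(Z1)), length(causal_ids) == k)
      g_true <- numeric(m)
      names(g_true) <- colnames(Z1)
      g_true[causal_ids] <-
        rnorm(k, 0, sqrt(cfg$causal_var_fraction * cfg$sigma2_a / k))
      rest <- setdiff(colnames(Z1), causal_ids)
      if (length(rest))
        g_true[rest] <- rnorm(length(rest), 0,
                              sqrt((1 - cfg$causal_var_fraction) *
                                     cfg$sigma2_a / length(rest)))
    }
  } else {
    stopifnot(length(g_true) == m)
  }
  names(g_true) <- colnames(Z1)

  s2p <- cfg$polygenic_ratio * cfg$sigma2_a
  Fi <- inbreeding(ped)
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal
  a_true <- numeric(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s) && is.na(d)) {
      a_true[i] <- rnorm(1, 0, sqrt(s2p))
    } else if (is.na(s) || is.na(d)) {
      pk <- idx[[if (is.na(s)) d else s]]
      a_true[i] <- 0.5 * a_true[pk] +
        rnorm(1, 0, sqrt((0.75 - 0.25 * Fi[pk]) * s2p))
    } else {
      si <- idx[[s]]; di <- idx[[d]]
      dvar <- 0.5 * (1 - (Fi[si] + Fi[di]) / 2) * s2p
      a_true[i] <- 0.5 * (a_true[si] + a_true[di]) + rnorm(1, 0, sqrt(dvar))
    }
  }
  names(a_true) <- ped$animal

  animals <- rownames(Z1)
  # EDC is a design-level quantity (daughter counts), shared by every
  # trait simulated on this config: keyed to the config seed, not `seed`.
  set.seed(derive_seed(cfg$seed, "edc"))
  edc <- runif(length(animals), cfg$edc_low, cfg$edc_high)
  set.seed(derive_seed(seed, "edc"))
  e <- rnorm(length(animals), 0, sqrt(cfg$sigma2_e / edc))
  y <- cfg$mu + drop(Z1 %*% g_true) + a_true[animals] + e
  trait <- data.frame(animal = animals, drp = unname(y), edc = edc,
                      stringsAsFactors = FALSE)
  truth <- list(g_true = g_true, a_true = a_true,
                causal_snp_ids = causal_ids, mu = cfg$mu)
  list(trait = trait, truth = truth)
}
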