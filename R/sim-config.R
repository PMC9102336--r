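#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator.  Defaults
#' emulate a progeny-tested dairy bull population: a closed multi-generation
#' pedigree, a medium-density chip with unlinked biallelic SNPs (minor
#' allele frequency at least 0.01), deregressed proofs (DRPs) whose residual
#' variance is scaled by the reciprocal of a bull's effective daughter
#' contribution (EDC), a residual polygenic effect carrying 40% of the
#' additive SNP variance, and overlapping GO/KEGG-like gene sets.
#'
#' @param n_founders number of unrelated, non-inbred founder animals.
#' @param n_generations number of discrete offspring generations appended
#'   to the founders (0 = founders only).
#' @param offspring_per_mating offspring produced by each mating pair.
#' @param n_snp number of biallelic SNPs on the simulated chip.
#' @param n_chromosomes number of autosome-like chromosomes.
#' @param chromosome_length_bp length of each chromosome in base pairs.
#' @param maf_low,maf_high founder allele-frequency bounds (drawn uniform);
#'   both in (0, 0.5].
#' @param missing_rate fraction of genotype calls masked as missing.
#' @param sigma2_a additive genetic variance captured by the SNPs
#'   (trait units squared).
#' @param sigma2_e residual variance of a single daughter-equivalent record;
#'   a bull's DRP residual variance is \code{sigma2_e / EDC}.
#' @param polygenic_ratio ratio of the residual polygenic variance to
#'   \code{sigma2_a}; the field convention modelled here is 0.4.
#' @param edc_low,edc_high bounds of the uniform EDC distribution.  The
#'   defaults (1000–5000) describe heavily progeny-tested bulls whose DRPs
#'   are almost noise-free, which is the information regime in which the
#'   per-SNP Wald test is well calibrated (inflation factor near 1).
#' @param n_genes number of annotated genes.
#' @param mean_gene_length_bp mean gene length (lengths are exponential).
#' @param n_terms number of functional terms (GO/KEGG-like gene sets).
#' @param genes_per_term_low,genes_per_term_high bounds on term sizes;
#'   terms sample genes with replacement across terms, so they overlap.
#' @param n_causal optional number of large-effect causal SNPs.  When
#'   \code{NULL} every SNP effect is drawn i.i.d.
#'   \eqn{N(0, \sigma^2_a / N_{SNP})}; when set, the causal SNPs share
#'   \code{causal_var_fraction} of \code{sigma2_a} and the remaining SNPs
#'   share the rest.
#' @param causal_var_fraction fraction of \code{sigma2_a} carried by the
#'   causal SNPs when \code{n_causal} is set.
#' @param mu overall trait mean (trait units).
#' @param seed integer seed fixing every downstream draw.
#'
#' @return a list of class \code{"sim_config"}.
#' @export
#' @examples
#' cfg <- sim_config(n_founders = 10, n_generations = 2, n_snp = 50)
sim_config <- function(n_founders = 100,
                       n_generations = 3,
                       offspring_per_mating = 2,
                       n_snp = 1000,
                       n_chromosomes = 5,
                       chromosome_length_bp = 1e7,
                       maf_low = 0.01,
                       maf_high = 0.5,
                       missing_rate = 0,
                       sigma2_a = 0.1,
                       sigma2_e = 0.9,
                       polygenic_ratio = 0.4,
                       edc_low = 1000,
                       edc_high = 5000,
                       n_genes = 250,
                       mean_gene_length_bp = 40000,
                       n_terms = 20,
                       genes_per_term_low = 5,
                       genes_per_term_high = 20,
                       n_causal = NULL,
                       causal_var_fraction = 0.8,
                       mu = 0,
                       seed = 1L) {
  cfg <- list(n_founders = n_founders, n_generations = n_generations,
              offspring_per_mating = offspring_per_mating, n_snp = n_snp,
              n_chromosomes = n_chromosomes,
              chromosome_length_bp = chromosome_length_bp,
              maf_low = maf_low, maf_high = maf_high,
              missing_rate = missing_rate,
              sigma2_a = sigma2_a, sigma2_e = sigma2_e,
              polygenic_ratio = polygenic_ratio,
              edc_low = edc_low, edc_high = edc_high,
              n_genes = n_genes, mean_gene_length_bp = mean_gene_length_bp,
              n_terms = n_terms,
              genes_per_term_low = genes_per_term_low,
              genes_per_term_high = genes_per_term_high,
              n_causal = n_causal,
              causal_var_fraction = causal_var_fraction,
              mu = mu, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_founders", "n_generations", "offspring_per_mating", "n_snp",
              "n_chromosomes", "chromosome_length_bp", "n_genes",
              "mean_gene_length_bp", "n_terms", "genes_per_term_low",
              "genes_per_term_high")
  for (nm in counts) {
    v <- cfg[[nm]]
    lo <- if (nm == "n_generations") 0 else 1
    if (!is.numeric(v) || length(v) != 1 || v < lo)
      stop("sim_config: `", nm, "` must be a count >= ", lo)
  }
  if (cfg$n_founders < 2) stop("sim_config: need n_founders >= 2 for mating")
  if (cfg$maf_low <= 0 || cfg$maf_high > 0.5 || cfg$maf_low > cfg$maf_high)
    stop("sim_config: need 0 < maf_low <= maf_high <= 0.5")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("sim_config: missing_rate must lie in [0, 1)")
  if (cfg$sigma2_a < 0 || cfg$sigma2_e < 0)
    stop("sim_config: variances must be non-negative")
  if (cfg$polygenic_ratio <= 0 || cfg$polygenic_ratio > 1)
    stop("sim_config: polygenic_ratio must lie in (0, 1]")
  if (cfg$edc_low <= 0 || cfg$edc_low > cfg$edc_high)
    stop("sim_config: need 0 < edc_low <= edc_high")
  if (cfg$genes_per_term_low > cfg$genes_per_term_high)
    stop("sim_config: genes_per_term_low > genes_per_term_high")
  if (!is.null(cfg$n_causal) &&
      (cfg$n_causal < 1 || cfg$n_causal > cfg$n_snp))
    stop("sim_config: n_causal must lie in [1, n_snp]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  pedigree : %d founders, %d generations, %d offspring/mating\n",
              x$n_founders, x$n_generations, x$offspring_per_mating))
  cat(sprintf("  genome   : %d SNPs on %d chromosomes of %g bp\n",
              x$n_snp, x$n_chromosomes, x$chromosome_length_bp))
  cat(sprintf("  variance : sigma2_a = %g, sigma2_e = %g, polygenic ratio = %g\n",
              x$sigma2_a, x$sigma2_e, x$polygenic_ratio))
  cat(sprintf("  EDC      : uniform [%g, %g]\n", x$edc_low, x$edc_high))
  cat(sprintf("  annotation: %d genes, %d terms (%d-%d genes/term)\n",
              x$n_genes, x$n_terms, x$genes_per_term_low,
              x$genes_per_term_high))
  cat(sprintf("  seed     : %d\n", x$seed))
  invisible(x)
}
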