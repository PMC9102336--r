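#' Genotype quality control
#'
#' Removes SNPs failing the chip-editing criteria: minor allele frequency
#' below \code{min_maf} (computed from called genotypes; allele frequency
#' \eqn{p = (2\,n_{1} + n_{0}) / (2\,n_{called})}, MAF = \eqn{\min(p, 1-p)})
#' or call rate below \code{min_call_rate}.  SNP order is preserved.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @param min_call_rate minimum fraction of called genotypes (default 0.99).
#' @return the filtered \code{geno_matrix}; attribute \code{"qc_report"}
#'   holds the counts removed per criterion.
#' @export
qc_filter <- function(geno, min_maf = 0.01, min_call_rate = 0.99) {
  G <- geno$genotypes
  n_called <- colSums(!is.na(G))
  call_rate <- n_called / nrow(G)
  p <- (2 * colSums(G == 1L, na.rm = TRUE) +
          colSums(G == 0L, na.rm = TRUE)) / (2 * pmax(n_called, 1L))
  maf <- pmin(p, 1 - p)
  fail_cr <- call_rate < min_call_rate
  fail_maf <- maf < min_maf
  keep <- !(fail_cr | fail_maf)
  if (!any(keep))
    stop("qc_filter: no SNP survives MAF >= ", min_maf,
         " and call rate >= ", min_call_rate)
  report <- list(n_input = ncol(G), n_removed_call_rate = sum(fail_cr),
                 n_removed_maf = sum(fail_maf & !fail_cr),
                 n_retained = sum(keep),
                 min_maf = min_maf, min_call_rate = min_call_rate)
  out <- genotype_matrix(G[, keep, drop = FALSE],
                         geno$map[keep, , drop = FALSE],
                         complete = if (!is.null(geno$complete))
                           geno$complete[, keep, drop = FALSE])
  attr(out, "qc_report") <- report
  out
}

#' Mean imputation of missing genotype calls
#'
#' Replaces every missing call by the per-SNP mean of the called genotypes
#' (a real number in \eqn{[-1, 1]}); called entries are untouched.  This is
#' the simple stand-in the pipeline uses between QC and the mixed model.
#'
#' @param geno a \code{\link{genotype_matrix}} that passed QC (so every SNP
#'   has at least one called genotype).
#' @return a \code{geno_matrix} whose \code{genotypes} element is a numeric
#'   matrix with no missing entries.
#' @export
impute_mean <- function(geno) {
  G <- geno$genotypes
  storage.mode(G) <- "double"
  nas <- is.na(G)
  if (any(nas)) {
    mu <- colMeans(G, na.rm = TRUE)
    fill <- matrix(mu, nrow(G), ncol(G), byrow = TRUE)
    G[nas] <- fill[nas]
  }
  out <- geno
  out$genotypes <- G
  out
}
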