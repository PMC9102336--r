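#' Construct a genotype matrix object
#'
#' Container for bulls-by-SNPs genotypes coded -1 (homozygous reference),
#' 0 (heterozygous) or 1 (alternative homozygous), with the chip map.
#' Missing calls are \code{NA}.
#'
#' @param values integer matrix, animals in rows, SNPs in columns; entries
#'   in \{-1, 0, 1, NA\}; dimnames give animal and SNP ids.
#' @param map data frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos_bp} (1-based), one row per column of \code{values}, sorted by
#'   position within chromosome.
#' @param complete optional fully-called copy of \code{values} (used by the
#'   simulator so phenotypes can be built before missingness is applied).
#' @return a list of class \code{"geno_matrix"} with elements
#'   \code{genotypes}, \code{map} and optionally \code{complete}.
#' @export
genotype_matrix <- function(values, map, complete = NULL) {
  stopifnot(is.matrix(values), ncol(values) == nrow(map),
            all(c("snp_id", "chrom", "pos_bp") %in% names(map)))
  obs <- values[!is.na(values)]
  if (length(obs) && !all(obs %in% c(-1L, 0L, 1L)))
    stop("genotypes must be coded -1/0/1 (NA = missing)")
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (is.unsorted(p))
      stop("SNP positions must be sorted within chromosome ", ch)
  }
  colnames(values) <- map$snp_id
  if (!is.null(complete)) dimnames(complete) <- dimnames(values)
  structure(list(genotypes = values, map = map, complete = complete),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d animals x %d SNPs on %d chromosome(s)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$map$chrom))))
  nm <- sum(is.na(x$genotypes))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nm,
              100 * nm / length(x$genotypes)))
  invisible(x)
}

#' Simulate chip genotypes through a pedigree
#'
#' Founder allele frequencies are drawn uniform in
#' \code{[maf_low, maf_high]} and founder genotypes in Hardy–Weinberg
#' proportions.  SNPs are unlinked: each non-founder receives, per SNP, one
#' allele drawn at random from each parent's pair (an independent
#' gene-drop).  Genotypes are coded -1/0/1; missing calls are inserted
#' completely at random at \code{missing_rate} and marked \code{NA}.  SNP
#' positions are uniform over chromosomes and sorted within chromosome.
#'
#' @param ped a pedigree from \code{\link{simulate_pedigree}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return a \code{\link{genotype_matrix}}; its \code{complete} element
#'   holds the genotypes before missingness, and attribute
#'   \code{"founder_freq"} stores the drawn allele frequencies.
#' @export
simulate_genotypes <- function(ped, cfg) {
  validate_pedigree(ped)
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, "genotypes"))
  n <- nrow(ped)
  m <- cfg$n_snp
  freq <- runif(m, cfg$maf_low, cfg$maf_high)

  # one haplotype matrix per gamete, entries 0/1 = reference/alternative
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    if (is.na(s)) h1[i, ] <- rbinom(m, 1L, freq)
    else {
      si <- idx[[s]]
      pick <- rbinom(m, 1L, 0.5) == 1L
      h1[i, ] <- ifelse(pick, h1[si, ], h2[si, ])
    }
    if (is.na(d)) h2[i, ] <- rbinom(m, 1L, freq)
    else {
      di <- idx[[d]]
      pick <- rbinom(m, 1L, 0.5) == 1L
      h2[i, ] <- ifelse(pick, h1[di, ], h2[di, ])
    }
  }
  geno <- h1 + h2 - 1L
  rownames(geno) <- ped$animal

  chrom <- sort(sample.int(cfg$n_chromosomes, m, replace = TRUE))
  pos <- integer(m)
  for (ch in seq_len(cfg$n_chromosomes)) {
    k <- sum(chrom == ch)
    if (k) pos[chrom == ch] <-
        sort(sample.int(cfg$chromosome_length_bp, k, replace = FALSE))
  }
  map <- data.frame(snp_id = sprintf("SNP%06d", seq_len(m)),
                    chrom = paste0("chr", chrom), pos_bp = pos,
                    stringsAsFactors = FALSE)

  complete <- geno
  observed <- geno
  if (cfg$missing_rate > 0) {
    mask <- matrix(runif(n * m) < cfg$missing_rate, n, m)
    observed[mask] <- NA_integer_
  }
  out <- genotype_matrix(observed, map, complete = complete)
  attr(out, "founder_freq") <- freq
  out
}
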