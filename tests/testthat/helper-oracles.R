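# Independent oracles and random-instance builders shared by the tests.
# These never call the MME / Henderson code paths they are used to check.

# Dense GLS/BLUP oracle for the SNP mixed model, built from the marginal
# covariance V = Z1 G1 Z1' + Z2 G2 Z2' + R and explicit inversion.
gls_blup_oracle <- function(Z1, y, edc, A, ped_ids, animals, vs) {
  n <- length(y)
  m <- ncol(Z1)
  X <- matrix(1, n, 1)
  Z2 <- matrix(0, n, length(ped_ids))
  Z2[cbind(seq_len(n), match(animals, ped_ids))] <- 1
  G1 <- diag(vs$sigma2_a / m, m)
  G2 <- vs$polygenic_ratio * vs$sigma2_a * A
  R <- diag(vs$sigma2_e / edc, n)
  V <- Z1 %*% G1 %*% t(Z1) + Z2 %*% G2 %*% t(Z2) + R
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  b <- solve(XVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  g <- G1 %*% t(Z1) %*% Vi %*% r
  a <- G2 %*% t(Z2) %*% Vi %*% r
  Pm <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  pev <- diag(G1 - G1 %*% t(Z1) %*% Pm %*% Z1 %*% G1)
  list(b = drop(b), g = drop(g), a = drop(a), pev_g = pev)
}

# Dense GLS/BLUP oracle for the term-level model, from
# V* = Z P Z' s2p + diag(l) s2e.
term_gls_oracle <- function(y, Z, P, l, s2p, s2e, include_mean = TRUE) {
  n <- length(y)
  V <- Z %*% P %*% t(Z) * s2p + diag(l) * s2e
  Vi <- solve(V)
  G <- s2p * P
  if (include_mean) {
    X <- matrix(1, n, 1)
    XVX <- t(X) %*% Vi %*% X
    u <- solve(XVX, t(X) %*% Vi %*% y)
    r <- y - X %*% u
    Pm <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  } else {
    u <- 0
    r <- y
    Pm <- Vi
  }
  p <- G %*% t(Z) %*% Vi %*% r
  pev <- diag(G - G %*% t(Z) %*% Pm %*% Z %*% G)
  list(u = drop(u), p = drop(p), pev_p = pev)
}

# Random topologically ordered pedigree with unknown, half-known and
# full parentage mixed in.
random_test_pedigree <- function(n, seed) {
  set.seed(seed)
  animal <- sprintf("A%03d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i <= 3) next
    u <- runif(1)
    if (u < 0.15) next                       # founder
    cand <- animal[seq_len(i - 1)]
    if (u < 0.30) {                          # one known parent
      if (runif(1) < 0.5) sire[i] <- sample(cand, 1)
      else dam[i] <- sample(cand, 1)
    } else {
      pr <- sample(cand, 2)
      sire[i] <- pr[1]
      dam[i] <- pr[2]
    }
  }
  ped <- data.frame(animal = animal, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Random small SNP-model instance: pedigree with extra ancestors, a subset
# of phenotyped genotyped bulls, genotypes in {-1,0,1}.
random_mme_instance <- function(seed, n_max = 20, m_max = 30, ped_max = 25) {
  set.seed(seed)
  q <- sample(10:ped_max, 1)
  ped <- random_test_pedigree(q, seed + 1000)
  n <- sample(5:min(n_max, q), 1)
  m <- sample(3:m_max, 1)
  animals <- sample(ped$animal, n)
  Z1 <- matrix(sample(c(-1L, 0L, 1L), n * m, replace = TRUE), n, m,
               dimnames = list(animals, sprintf("S%03d", seq_len(m))))
  map <- data.frame(snp_id = colnames(Z1), chrom = "chr1",
                    pos_bp = sort(sample.int(1e6, m)),
                    stringsAsFactors = FALSE)
  geno <- funcblup::genotype_matrix(Z1, map)
  edc <- stats::setNames(runif(n, 5, 50), animals)
  y <- rnorm(n)
  vs <- funcblup::variance_spec(sigma2_a = runif(1, 0.2, 2),
                                sigma2_e = runif(1, 0.2, 2),
                                polygenic_ratio = 0.4)
  list(ped = ped, geno = geno, Z1 = Z1, animals = animals, edc = edc,
       y = y, vs = vs)
}

# All-pairs brute-force SNP-gene assignment scan.
brute_force_assign <- function(map, genes, max_dist) {
  rows <- list()
  k <- 1L
  for (i in seq_len(nrow(map))) {
    for (j in seq_len(nrow(genes))) {
      if (map$chrom[i] != genes$chrom[j]) next
      pos <- map$pos_bp[i]
      d <- if (pos >= genes$start_bp[j] && pos <= genes$end_bp[j]) 0L
           else min(abs(pos - genes$start_bp[j]), abs(pos - genes$end_bp[j]))
      if (d <= max_dist) {
        rows[[k]] <- data.frame(snp_id = map$snp_id[i],
                                gene_id = genes$gene_id[j],
                                distance_bp = as.integer(d),
                                stringsAsFactors = FALSE)
        k <- k + 1L
      }
    }
  }
  if (!length(rows))
    return(data.frame(snp_id = character(), gene_id = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(match(out$snp_id, map$snp_id), out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Relative max deviation, guarded for near-zero references.
rel_err <- function(x, ref) {
  max(abs(x - ref)) / max(abs(ref), 1e-8)
}
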