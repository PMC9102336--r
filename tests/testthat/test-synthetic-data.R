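tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_founders = 10, n_generations = 2, n_snp = 20,
                   n_genes = 30, n_terms = 5, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}

test_that("pedigree generator respects structure and ordering", {
  # founders only
  ped <- simulate_pedigree(tiny_cfg(n_founders = 2, n_generations = 0))
  expect_identical(nrow(ped), 2L)
  expect_true(all(is.na(ped$sire)) && all(is.na(ped$dam)))

  # every generation-2 animal has generation-1 parents
  ped <- simulate_pedigree(tiny_cfg(n_founders = 4, n_generations = 2,
                                    offspring_per_mating = 2))
  g2 <- ped[ped$generation == 2, ]
  g1_ids <- ped$animal[ped$generation == 1]
  expect_true(all(g2$sire %in% g1_ids) && all(g2$dam %in% g1_ids))
  expect_true(all(g2$sire != g2$dam))
  expect_silent(validate_pedigree(ped))

  expect_error(sim_config(n_founders = 1), "n_founders")
})

test_that("seed fixes every simulated artefact, including written files", {
  cfg <- tiny_cfg(n_founders = 10, n_generations = 3, seed = 1,
                  missing_rate = 0.05)
  p1 <- simulate_pedigree(cfg)
  p2 <- simulate_pedigree(cfg)
  expect_identical(p1, p2)
  g1 <- simulate_genotypes(p1, cfg)
  g2 <- simulate_genotypes(p2, cfg)
  expect_identical(g1, g2)
  a1 <- simulate_annotation(cfg)
  expect_identical(a1, simulate_annotation(cfg))
  ph1 <- simulate_phenotypes(g1, p1, cfg)
  expect_identical(ph1, simulate_phenotypes(g2, p2, cfg))

  f1 <- tempfile(); f2 <- tempfile()
  write_pedigree_tsv(p1, f1); write_pedigree_tsv(p2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  write_gmt(a1$terms, f1); write_gmt(simulate_annotation(cfg)$terms, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("founder genotypes are in Hardy-Weinberg proportions", {
  cfg <- tiny_cfg(n_founders = 3000, n_generations = 0, n_snp = 5,
                  maf_low = 0.2, maf_high = 0.5, seed = 5)
  geno <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  freq <- attr(geno, "founder_freq")
  for (j in seq_len(5)) {
    het <- mean(geno$genotypes[, j] == 0L)
    p_alt <- mean(geno$genotypes[, j] + 1L) / 2
    expect_lt(abs(het - 2 * freq[j] * (1 - freq[j])), 0.04)
    expect_lt(abs(p_alt - freq[j]), 0.03)
  }
})

test_that("gene-drop transmission is Mendelian-consistent", {
  cfg <- tiny_cfg(n_founders = 20, n_generations = 2, n_snp = 50, seed = 8)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  G <- geno$complete + 1L  # alternative-allele dosage 0/1/2
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  off <- which(!is.na(ped$sire))
  for (i in off) {
    s <- G[idx[ped$sire[i]], ]
    d <- G[idx[ped$dam[i]], ]
    ch <- G[i, ]
    expect_true(all(ch >= (s == 2) + (d == 2)))
    expect_true(all(ch <= 2 - ((s == 0) + (d == 0))))
  }
})

test_that("missingness control works and zero rate means full call rate", {
  cfg0 <- tiny_cfg(missing_rate = 0, n_snp = 40)
  g0 <- simulate_genotypes(simulate_pedigree(cfg0), cfg0)
  expect_false(anyNA(g0$genotypes))
  cfg1 <- tiny_cfg(n_founders = 100, n_generations = 1, n_snp = 100,
                   missing_rate = 0.1)
  g1 <- simulate_genotypes(simulate_pedigree(cfg1), cfg1)
  expect_lt(abs(mean(is.na(g1$genotypes)) - 0.1), 0.01)
  expect_identical(sum(is.na(g1$complete)), 0L)
})

test_that("gene intervals do not overlap and term sizes obey the bounds", {
  cfg <- tiny_cfg(n_genes = 80, n_terms = 12, genes_per_term_low = 5,
                  genes_per_term_high = 5)
  ann <- simulate_annotation(cfg)
  for (ch in unique(ann$genes$chrom)) {
    g <- ann$genes[ann$genes$chrom == ch, ]
    g <- g[order(g$start_bp), ]
    expect_true(all(g$start_bp <= g$end_bp))
    if (nrow(g) > 1)
      expect_true(all(g$end_bp[-nrow(g)] < g$start_bp[-1]))
  }
  expect_true(all(lengths(ann$terms) == 5))
  expect_true(all(unlist(ann$terms) %in% ann$genes$gene_id))
})

test_that("founder polygenic variance matches the 0.4 ratio", {
  cfg <- tiny_cfg(n_founders = 2000, n_generations = 0, n_snp = 2,
                  sigma2_a = 1, sigma2_e = 1, seed = 31)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(geno, ped, cfg)
  expect_lt(abs(var(ph$truth$a_true) - 0.4), 0.04)
})

test_that("replicated polygenic draws reproduce 0.4*sigma2_a*A", {
  cfg <- tiny_cfg(n_founders = 4, n_generations = 2, n_snp = 2,
                  offspring_per_mating = 2, sigma2_a = 1, seed = 12)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  draws <- vapply(seq_len(4000), function(r)
    simulate_phenotypes(geno, ped, cfg, seed = r)$truth$a_true,
    numeric(nrow(ped)))
  emp <- stats::cov(t(draws))
  expect_lt(max(abs(emp - 0.4 * build_a_matrix(ped))), 0.06)
})

test_that("phenotypes reduce to the mean without variance and track Z1 g", {
  cfg <- tiny_cfg(n_founders = 40, n_generations = 2, n_snp = 30,
                  sigma2_a = 1e-12, sigma2_e = 1e-12, mu = 3.5)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(geno, ped, cfg)
  expect_lt(max(abs(ph$trait$drp - 3.5)), 1e-4)

  # with tiny residual noise, OLS of y on Z1 g_true has slope ~ 1
  cfg <- tiny_cfg(n_founders = 300, n_generations = 1, n_snp = 80,
                  sigma2_a = 1, sigma2_e = 1e-6, seed = 13)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(geno, ped, cfg)
  gv <- drop(geno$complete %*% ph$truth$g_true)
  slope <- coef(lm(ph$trait$drp ~ gv))[2]
  expect_lt(abs(slope - 1), 0.15)
})

test_that("causal-subset configuration concentrates the SNP variance", {
  cfg <- tiny_cfg(n_snp = 200, n_causal = 10, causal_var_fraction = 0.8,
                  sigma2_a = 1, seed = 77)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(geno, ped, cfg)
  expect_length(ph$truth$causal_snp_ids, 10)
  forced <- simulate_phenotypes(geno, ped, cfg,
                                causal_ids = colnames(geno$complete)[1:10])
  expect_identical(forced$truth$causal_snp_ids,
                   colnames(geno$complete)[1:10])
  # null override
  ph0 <- simulate_phenotypes(geno, ped, cfg, g_true = rep(0, 200))
  expect_true(all(ph0$truth$g_true == 0))
})
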