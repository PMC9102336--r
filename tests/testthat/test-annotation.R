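test_that("SNP-gene assignment applies the distance window exactly", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chrom = c("chr1", "chr1", "chr1"),
                      start_bp = c(100L, 6800L, 20000L),
                      end_bp = c(200L, 6900L, 21000L),
                      stringsAsFactors = FALSE)
  map <- data.frame(
    snp_id = c("in", "edge_in", "edge_out", "between", "far"),
    chrom = "chr1",
    pos_bp = c(150L, 5200L, 5201L, 3500L, 500000L),
    stringsAsFactors = FALSE)
  asg <- map_snps_to_genes(map, genes, max_dist = 5000)
  # inside the gene: distance 0
  expect_identical(asg$distance_bp[asg$snp_id == "in" &
                                     asg$gene_id == "g1"], 0L)
  # 5000 bp past the end of g1 (200): assigned at exactly the window
  expect_true(any(asg$snp_id == "edge_in" & asg$gene_id == "g1"))
  expect_identical(asg$distance_bp[asg$snp_id == "edge_in" &
                                     asg$gene_id == "g1"], 5000L)
  # 5001 bp away: excluded
  expect_false(any(asg$snp_id == "edge_out" & asg$gene_id == "g1"))
  # equidistant (3,300 bp) between two genes: assigned to both
  between <- asg[asg$snp_id == "between", ]
  expect_setequal(between$gene_id, c("g1", "g2"))
  expect_identical(unique(between$distance_bp), 3300L)
  # far from everything: absent
  expect_false("far" %in% asg$snp_id)

  bad <- map
  bad$chrom <- "chrX"
  expect_error(map_snps_to_genes(bad, genes), "chromosome")
})

test_that("window assignment agrees with the brute-force all-pairs scan", {
  for (seed in 1:3) {
    set.seed(seed)
    n_g <- 40
    genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_g)),
                        chrom = sample(c("chr1", "chr2"), n_g, TRUE),
                        start_bp = sample.int(2e5, n_g),
                        stringsAsFactors = FALSE)
    genes$end_bp <- genes$start_bp + sample.int(5000, n_g)
    pos <- c(sample.int(250000, 300),
             genes$end_bp[1:20] + 5000L,       # exact boundary hits
             genes$start_bp[1:20] - 5001L)     # exact boundary misses
    pos <- pmax(pos, 1L)
    map <- data.frame(snp_id = sprintf("s%04d", seq_along(pos)),
                      chrom = sample(c("chr1", "chr2"), length(pos), TRUE),
                      pos_bp = pos, stringsAsFactors = FALSE)
    asg <- map_snps_to_genes(map, genes, 5000)
    bf <- brute_force_assign(map, genes, 5000)
    rownames(asg) <- NULL
    expect_equal(asg, bf)
  }
})

test_that("term overlap covariance honours the denominator conventions", {
  terms <- list(t1 = c("a", "b"), t2 = c("b", "c"), t3 = c("x", "y", "z"),
                t4 = c("a", "b"))
  P <- term_overlap_covariance(terms)
  expect_equal(P["t1", "t2"], 1 / 3)       # |{b}| / |{a,b,c}|
  expect_equal(P["t1", "t4"], 1)           # identical sets
  expect_equal(P["t1", "t3"], 0)           # disjoint
  expect_true(isSymmetric(P))
  expect_equal(unname(diag(P)), rep(1, 4))

  Pm <- term_overlap_covariance(terms, convention = "min-size")
  expect_equal(Pm["t1", "t2"], 1 / 2)
  Pg <- term_overlap_covariance(terms, convention = "geometric-mean")
  expect_equal(Pg["t1", "t2"], 1 / 2)
  expect_equal(Pg["t2", "t3"], 0)

  # restriction to a gene universe
  Pr <- term_overlap_covariance(list(t1 = c("a", "b"), t2 = c("b", "z")),
                                restrict_to = c("a", "b"))
  expect_equal(Pr["t1", "t2"], 1 / 2)
  expect_warning(
    term_overlap_covariance(list(t1 = c("a"), t2 = c("z")),
                            restrict_to = "a"), "dropping")
})

test_that("eigenvalue repair restores positive definiteness", {
  # three identical terms: P is all ones, rank 1
  terms <- list(t1 = c("a", "b"), t2 = c("a", "b"), t3 = c("a", "b"))
  P <- term_overlap_covariance(terms)
  expect_true(attr(P, "repaired"))
  expect_true(isSymmetric(P))
  expect_equal(unname(diag(P)), rep(1, 3))
  expect_gte(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), 0)

  # a clean matrix is left untouched
  P2 <- term_overlap_covariance(list(t1 = c("a", "b"), t2 = c("b", "c")))
  expect_false(attr(P2, "repaired"))
})

test_that("term-model inputs partition SNPs into assigned and unassigned", {
  assignments <- data.frame(
    snp_id = c("s1", "s1", "s2"),
    gene_id = c("gA", "gB", "gC"),
    distance_bp = c(0L, 100L, 0L), stringsAsFactors = FALSE)
  terms <- list(T1 = c("gA", "gZ"), T2 = c("gB", "gC"), T3 = c("gC"))
  effects <- data.frame(snp_id = c("s1", "s2", "s3"),
                        effect = c(-0.3, 0.2, 0.05),
                        stringsAsFactors = FALSE)
  inp <- build_term_inputs(assignments, terms, effects)
  expect_equal(unname(inp$y_star), c(0.3, 0.2, 0.05))
  # s1 -> gA in T1, gB in T2: two 1s, weight 1
  expect_equal(unname(inp$z_star["s1", ]), c(1, 1, 0))
  expect_equal(inp$l_weights[["s1"]], 1)
  # s3 intergenic: all-zero row, weight 10
  expect_equal(sum(inp$z_star["s3", ]), 0)
  expect_equal(inp$l_weights[["s3"]], 10)
  # partition property: weight 1 iff the row is non-empty, classes sum to N
  assigned <- rowSums(inp$z_star) > 0
  expect_identical(unname(inp$l_weights == 1), unname(assigned))
  expect_identical(sum(assigned) + sum(!assigned), nrow(inp$z_star))
  expect_equal(inp$genes_per_term[["T2"]], 2L)

  # unknown-gene term dropped with a warning; unmatched effects error
  expect_warning(
    build_term_inputs(assignments, c(terms, list(T4 = "gNOPE")), effects),
    "T4")
  expect_error(
    build_term_inputs(rbind(assignments,
                            data.frame(snp_id = "ghost", gene_id = "gA",
                                       distance_bp = 0L)),
                      terms, effects),
    "ghost")
  expect_error(
    suppressWarnings(
      build_term_inputs(assignments, list(T9 = "gNOPE"), effects)),
    "no SNP maps")
})
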