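# Minimal constructor for term-model inputs used by the solver tests.
mk_inputs <- function(y, Z, P = NULL, l = NULL) {
  n <- length(y)
  k <- ncol(Z)
  t_ids <- sprintf("T%02d", seq_len(k))
  s_ids <- sprintf("s%04d", seq_len(n))
  dimnames(Z) <- list(s_ids, t_ids)
  if (is.null(P)) P <- diag(k)
  dimnames(P) <- list(t_ids, t_ids)
  if (is.null(l)) l <- ifelse(rowSums(Z) > 0, 1, 10)
  structure(list(y_star = stats::setNames(y, s_ids), z_star = Z,
                 p_cov = P, l_weights = stats::setNames(l, s_ids),
                 snp_ids = s_ids, term_ids = t_ids,
                 genes_per_term = stats::setNames(rep(1L, k), t_ids)),
            class = "term_model_inputs")
}

test_that("single-term model without a mean matches the ridge closed form", {
  set.seed(10)
  n <- 40
  y <- abs(rnorm(n))
  Z <- matrix(1, n, 1)
  s2p <- 0.7
  s2e <- 1.3
  tab <- fit_term_model(mk_inputs(y, Z), term_variance_spec(s2p, s2e),
                        include_mean = FALSE)
  expect_equal(tab$effect, sum(y) / (n + s2e / s2p), tolerance = 1e-10)
})

test_that("with a fixed mean and a single all-ones term the effect is zero", {
  # the mean absorbs the signal: both MME and GLS give p_hat = 0
  set.seed(11)
  y <- abs(rnorm(30))
  Z <- matrix(1, 30, 1)
  tab <- fit_term_model(mk_inputs(y, Z), term_variance_spec(1, 1))
  expect_lt(abs(tab$effect), 1e-10)
})

test_that("term-model MME matches the dense V* GLS/BLUP oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(20:50, 1)
    k <- sample(2:6, 1)
    Z <- matrix(rbinom(n * k, 1, 0.35), n, k)
    gsets <- lapply(seq_len(k), function(i)
      sample(letters, sample(3:8, 1)))
    names(gsets) <- sprintf("T%02d", seq_len(k))
    P <- term_overlap_covariance(gsets)
    y <- abs(rnorm(n, 0.2, 0.5))
    l <- ifelse(rowSums(Z) > 0, 1, 10)
    s2p <- runif(1, 0.2, 2)
    s2e <- runif(1, 0.2, 2)
    inp <- mk_inputs(y, Z, P, l)
    for (with_mean in c(TRUE, FALSE)) {
      tab <- fit_term_model(inp, term_variance_spec(s2p, s2e),
                            include_mean = with_mean)
      orc <- term_gls_oracle(y, Z, P, l, s2p, s2e,
                             include_mean = with_mean)
      expect_lt(rel_err(tab$effect, orc$p), 1e-6)
      expect_lt(rel_err(tab$se^2, orc$pev_p), 1e-6)
      if (with_mean)
        expect_lt(rel_err(attr(tab, "u_hat"), orc$u), 1e-6)
    }
  }
})

test_that("an all-zero response gives zero effects and no significance", {
  set.seed(12)
  Z <- matrix(rbinom(60, 1, 0.4), 20, 3)
  tab <- fit_term_model(mk_inputs(rep(0, 20), Z),
                        term_variance_spec(1, 1))
  expect_equal(tab$effect, rep(0, 3))
  expect_false(any(tab$significant))
})

test_that("term effects shrink monotonically as the variance ratio grows", {
  set.seed(13)
  n <- 50
  Z <- matrix(rbinom(n * 4, 1, 0.3), n, 4)
  y <- abs(rnorm(n)) + Z[, 2] * 0.5
  inp <- mk_inputs(y, Z)
  mags <- sapply(c(0.1, 1, 10, 100), function(r)
    abs(fit_term_model(inp, term_variance_spec(1, r))$effect))
  for (j in seq_len(nrow(mags)))
    expect_true(all(diff(mags[j, ]) <= 1e-10))
})

test_that("a non-positive-definite P is rejected with repair advice", {
  Z <- matrix(rbinom(40, 1, 0.5), 20, 2)
  inp <- mk_inputs(abs(rnorm(20)), Z,
                   P = matrix(c(1, 1, 1, 1), 2))
  expect_error(fit_term_model(inp, term_variance_spec(1, 1)),
               "term_overlap_covariance")
})

test_that("profiled REML recovers the simulated variance ratio", {
  # the ratio is identified through the term-effect spread, so its
  # sampling error scales with sqrt(2/k); 30 terms give a usable check
  set.seed(14)
  n <- 2000
  k <- 30
  Z <- matrix(rbinom(n * k, 1, 0.2), n, k)
  gsets <- lapply(seq_len(k), function(i)
    sample(c(letters, LETTERS), 6))
  names(gsets) <- sprintf("T%02d", seq_len(k))
  P <- term_overlap_covariance(gsets)
  cP <- chol(P)
  ratio_true <- 5
  s2p_true <- 0.09
  est <- sapply(1:3, function(s) {
    set.seed(100 + s)
    p <- drop(crossprod(cP, rnorm(k))) * sqrt(s2p_true)
    l <- ifelse(rowSums(Z) > 0, 1, 10)
    y <- 0.3 + drop(Z %*% p) + rnorm(n, 0, sqrt(ratio_true * s2p_true * l))
    tv <- estimate_term_variances(mk_inputs(y, Z, P, l))
    tv$sigma2_e_star / tv$sigma2_p
  })
  expect_true(all(est > ratio_true / 4 & est < ratio_true * 4))
  geo <- exp(mean(log(est)))
  expect_gt(geo, ratio_true / 2)
  expect_lt(geo, ratio_true * 2)
})

test_that("REML grid handling: repeated value and scale equivariance", {
  set.seed(15)
  n <- 120
  Z <- matrix(rbinom(n * 3, 1, 0.4), n, 3)
  y <- abs(rnorm(n)) + Z[, 1] * 0.4
  inp <- mk_inputs(y, Z)
  tv_fixed <- estimate_term_variances(inp, grid = 2.5)
  expect_equal(tv_fixed$sigma2_e_star / tv_fixed$sigma2_p, 2.5)
  expect_true(tv_fixed$estimated)

  grid <- 10^seq(-1, 1, length.out = 11)
  tv1 <- estimate_term_variances(inp, grid = grid)
  inp2 <- inp
  inp2$y_star <- inp$y_star * 2
  tv2 <- estimate_term_variances(inp2, grid = grid)
  expect_equal(tv2$sigma2_p, 4 * tv1$sigma2_p, tolerance = 1e-8)
  expect_equal(tv2$sigma2_e_star / tv2$sigma2_p,
               tv1$sigma2_e_star / tv1$sigma2_p)

  expect_error(estimate_term_variances(mk_inputs(rep(1, 20),
                                                 matrix(1, 20, 1))),
               "degenerate")
})
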