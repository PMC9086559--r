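test_that("FPKM and SRPBM match hand-computed values", {
  cm <- make_counts(matrix(c(100, 0, 50,
                             10, 50, 0,
                             20, 40, 80,
                             7, 3, 1), nrow = 3, ncol = 4),
                    lib_sizes = c(1e6, 2e6, 5e5, 1e7),
                    lengths = c(1, 0.5, 2))
  f <- fpkm(cm)$values
  expect_equal(f[1, 1], 100)                  # 100 / (1e6/1e6 * 1 kb)
  expect_equal(f[2, 1], 0)                    # zero fragments
  expect_equal(f[2, 2], 50 / (2 * 0.5))       # 50 frags, 2M reads, 0.5 kb
  expect_equal(unname(f), unname(cm$values / outer(c(1, 0.5, 2),
                                                   c(1, 2, 0.5, 10))))
  s <- srpbm(cm)$values
  expect_equal(s[1, 1], 100 / (1e6 / 1e9))
  expect_equal(unname(s),
               unname(sweep(cm$values, 2, c(1e6, 2e6, 5e5, 1e7) / 1e9, "/")))
  expect_error(fpkm(make_counts(matrix(1:4, 2), lib_sizes = c(1, 1))),
               "feature_lengths")
  expect_error(expr_matrix(matrix(1:4, 2,
                                  dimnames = list(c("a", "b"), c("x", "y"))),
                           "count", lib_sizes = c(0, 1)), "positive")
})

test_that("quantification is linear in counts and inverse-linear in depth", {
  set.seed(42)
  for (r in 1:5) {
    v <- matrix(rpois(60, 30), 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    L <- runif(10, 0.2, 5); N <- runif(6, 1e6, 1e8)
    a <- fpkm(expr_matrix(v, "count", N, L))$values
    b <- fpkm(expr_matrix(3 * v, "count", N, L))$values
    expect_equal(b, 3 * a)
    d <- fpkm(expr_matrix(v, "count", 2 * N, L))$values
    expect_equal(d, a / 2)
    expect_equal(srpbm(expr_matrix(2 * v, "count", N))$values,
                 2 * srpbm(expr_matrix(v, "count", N))$values)
  }
})

test_that("TMM factors are 1 for identical and depth-scaled libraries", {
  set.seed(7)
  base <- rpois(300, 100)
  v <- matrix(rep(base, 4), ncol = 4,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:4)))
  expect_equal(unname(tmm_factors(make_counts(v))), rep(1, 4))
  # column j = 2 x column k elementwise: pure depth, absorbed by lib size
  v2 <- cbind(s1 = base, s2 = 2 * base, s3 = base, s4 = 4 * base)
  rownames(v2) <- paste0("g", 1:300)
  expect_equal(unname(tmm_factors(make_counts(v2))), rep(1, 4),
               tolerance = 1e-8)
  expect_error(tmm_factors(make_counts(cbind(a = c(1, 2), b = c(0, 0)))),
               "all-zero")
})

test_that("TMM trimming shrugs off a small fraction of extreme features", {
  set.seed(11)
  n <- 1000
  base <- rpois(n, 200)
  clean <- cbind(s1 = rpois(n, base), s2 = rpois(n, base))
  rownames(clean) <- paste0("g", 1:n)
  # hold the assumed depths fixed so only the composition outliers vary
  N <- c(2e5, 2e5)
  f0 <- tmm_factors(make_counts(clean, lib_sizes = N))
  dirty <- clean
  hot <- sample(n, 50)                         # 5% wildly up in sample 2
  dirty[hot, 2] <- dirty[hot, 2] * 50
  f1 <- tmm_factors(make_counts(dirty, lib_sizes = N))
  expect_lt(abs(f1[2] / f0[2] - 1), 0.05)
})

test_that("TMM agrees with the edgeR reference on random counts", {
  skip_if_not_installed("edgeR")
  set.seed(99)
  v <- matrix(rnbinom(4000, mu = 80, size = 5), 1000, 4,
              dimnames = list(paste0("g", 1:1000), paste0("s", 1:4)))
  ours <- tmm_factors(make_counts(v))
  ref <- edgeR::calcNormFactors(v, method = "TMM")
  expect_equal(unname(ours), unname(ref), tolerance = 0.02)
})

test_that("exact conditional test matches binomial tails and symmetry", {
  # identical groups: p = 1, logFC = 0
  v <- matrix(c(5, 7, 5, 7), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  d <- de_test(expr_matrix(v, "count", rep(1e6, 4)),
               c("a", "a", "b", "b"), normalize = FALSE)
  expect_equal(d$p, 1)
  expect_equal(d$logFC, 0)
  # group sums 0 vs 20 at equal effective depth: p = 2 * (1/2)^20
  v2 <- rbind(g1 = c(0, 0, 12, 8), g2 = c(50, 50, 50, 50))
  colnames(v2) <- paste0("s", 1:4)
  d2 <- de_test(expr_matrix(v2, "count", rep(1e6, 4)),
                c("a", "a", "b", "b"), normalize = FALSE)
  expect_equal(d2$p[1], 2 * 0.5^20, tolerance = 1e-12)
  expect_gt(d2$logFC[1], 0)
})

test_that("BH adjustment follows the step-up formula and is monotone", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  set.seed(5)
  v <- matrix(rpois(400 * 6, 40), 400, 6,
              dimnames = list(paste0("g", 1:400), paste0("s", 1:6)))
  d <- de_test(make_counts(v), rep(c("a", "b"), each = 3))
  expect_true(all(d$adj_p >= d$p - 1e-12))
  o <- order(d$p)
  expect_true(all(diff(d$adj_p[o]) >= -1e-12))
})

test_that("call_de applies strict thresholds and sets direction", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    logFC = c(2.5, 2.0, -3, 1),
                    p = c(0.001, 0.001, 0.01, 0.2),
                    adj_p = c(0.01, 0.01, 0.04, 0.4),
                    direction = "ns")
  out <- call_de(res, 2, 0.05, use_adjusted = TRUE)
  expect_setequal(out$feature_id, c("a", "c"))
  expect_equal(out$direction[out$feature_id == "a"], "up")
  expect_equal(out$direction[out$feature_id == "c"], "down")
  # logFC exactly at the threshold is excluded
  expect_false("b" %in% out$feature_id)
  expect_error(call_de(res, 0, 0.05), "positive")
})

test_that("paired mode conditions within pairs", {
  set.seed(3)
  mu <- rpois(30, 50) + 1
  v <- cbind(matrix(rpois(60, mu), 30, 2), matrix(rpois(60, mu), 30, 2))
  rownames(v) <- paste0("g", 1:30); colnames(v) <- paste0("s", 1:4)
  d <- de_test(make_counts(v, lib_sizes = rep(1e6, 4)),
               c("a", "a", "b", "b"), paired = TRUE, normalize = FALSE)
  expect_true(all(d$p > 0 & d$p <= 1))
  # a feature identical within each pair is null at equal pair depths
  v[1, ] <- c(10, 20, 10, 20)
  d2 <- de_test(make_counts(v, lib_sizes = rep(1e6, 4)),
                c("a", "a", "b", "b"), paired = TRUE, normalize = FALSE)
  expect_equal(d2$p[1], 1)
})
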