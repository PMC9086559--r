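test_that("Kaplan-Meier matches the product-limit arithmetic", {
  rec <- data.frame(time = c(1, 2, 3, 4), event = 1)
  km <- km_curve(rec)
  expect_equal(km$surv, c(1, 0.75, 0.5, 0.25, 0))
  # all censored: survival stays at 1
  expect_true(all(km_curve(data.frame(time = 1:5, event = 0))$surv == 1))
  # single subject: drops to 0 at its event time
  km1 <- km_curve(data.frame(time = 2.5, event = 1))
  expect_equal(km1$surv, c(1, 0))
  expect_equal(km1$time, c(0, 2.5))
  expect_error(km_curve(data.frame(time = c(1, -1), event = 1)), "positive")
})

test_that("KM without censoring equals one minus the empirical CDF", {
  set.seed(8)
  tt <- rexp(200, 0.2)
  km <- km_curve(data.frame(time = tt, event = 1))
  ec <- stats::ecdf(tt)
  expect_equal(km$surv, 1 - ec(km$time))
})

test_that("log-rank matches hand arithmetic and is null under relabeling", {
  a <- data.frame(time = c(1, 3, 5), event = c(1, 1, 0))
  b <- data.frame(time = c(2, 4, 6), event = c(1, 0, 1))
  lr <- logrank(a, b)
  want <- oracle_logrank(c(a$time, b$time), c(a$event, b$event),
                         rep(c("A", "B"), each = 3))
  expect_equal(lr$chisq, want, tolerance = 1e-10)
  same <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  lr0 <- logrank(same, same)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  expect_warning(lr1 <- logrank(data.frame(time = 1:3, event = 0),
                                data.frame(time = 1:3, event = 0)),
                 "no events")
  expect_equal(lr1$p, 1)
})

test_that("log-rank detects a planted hazard ratio", {
  hits <- 0; n_seed <- 50
  for (s in seq_len(n_seed)) {
    v <- gen_survival(400, c(g1 = log(3)), censor_rate = 0.2,
                      seed = 7000 + s)$survival
    hi <- v$g1 > median(v$g1)
    if (logrank(v[hi, ], v[!hi, ])$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_seed, 0.95)
})

test_that("Cox estimates are replication-invariant and consistent", {
  v <- gen_survival(300, c(g1 = 0.8), censor_rate = 0.2, seed = 31)$survival
  f1 <- cox_univariate(v, "g1")
  f2 <- cox_univariate(rbind(v, v), "g1")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  v2 <- gen_survival(2000, c(g1 = 1), censor_rate = 0.2, seed = 32)$survival
  expect_lt(abs(cox_univariate(v2, "g1")$beta - 1), 0.15)
  expect_error(cox_univariate(v, "missing_gene"), "not in records")
})

test_that("unpenalised LASSO equals the Newton-Raphson Cox fit", {
  v <- gen_survival(500, c(g1 = 0.7, g2 = -0.5), censor_rate = 0.2,
                    seed = 41)$survival
  x <- as.matrix(v[, c("g1", "g2")])
  y <- survival::Surv(v$time, v$event)
  gfit <- glmnet::glmnet(x, y, family = "cox",
                         lambda = c(0.5, 0.1, 0.01, 0), thresh = 1e-14)
  bg <- as.numeric(stats::coef(gfit, s = 0))
  bc <- stats::coef(survival::coxph(y ~ g1 + g2, data = v, ties = "breslow"))
  expect_equal(bg, unname(bc), tolerance = 1e-3)
})

test_that("LASSO drops everything at huge lambda and keeps order structure", {
  v <- gen_survival(200, c(g1 = 1, g2 = 0.6), n_null_genes = 3,
                    censor_rate = 0.2, seed = 51)$survival
  genes <- c("g1", "g2", paste0("null", sprintf("%03d", 1:3)))
  m <- lasso_cox(v, genes, lambda_grid = c(100, 50), n_folds = 3, seed = 1)
  expect_equal(length(m$genes), 0)
  expect_error(lasso_cox(v, genes, lambda_grid = numeric(0)), "empty")
  # non-zero count is non-increasing along the regularisation path
  x <- as.matrix(v[, genes]); y <- survival::Surv(v$time, v$event)
  fit <- glmnet::glmnet(x, y, family = "cox")
  nz <- fit$df
  expect_true(all(diff(nz[order(-fit$lambda)]) >= -1))  # monotone modulo step
  m2 <- lasso_cox(v, genes, n_folds = 5, seed = 3)
  expect_true(all(c("g1", "g2") %in% m2$genes))
})

test_that("risk scores follow the linear predictor and median split", {
  model <- structure(list(genes = c("a", "b", "c"),
                          betas = c(a = 0.5, b = -0.3, c = 0.2),
                          cutoff = 0, lambda = 0.1, auc = numeric(0)),
                     class = "RiskModel")
  rs <- suppressWarnings(risk_scores(model, data.frame(a = 1, b = 1, c = 1)))
  expect_equal(rs$score, 0.4)
  expect_equal(rs$group, "high")
  # rank invariance: a monotone transform of a one-gene model's inputs
  m1 <- structure(list(genes = "a", betas = c(a = 1), cutoff = 0.5,
                       lambda = 0, auc = numeric(0)), class = "RiskModel")
  x <- data.frame(a = c(0.1, 0.4, 0.9, 2))
  g1 <- risk_scores(m1, x)$group
  m2 <- m1; m2$cutoff <- exp(0.5)
  g2 <- risk_scores(m2, data.frame(a = exp(x$a)))$group
  expect_identical(g1, g2)
  m0 <- structure(list(genes = character(), betas = numeric(0), cutoff = 0,
                       lambda = 1, auc = numeric(0)), class = "RiskModel")
  expect_warning(rs0 <- risk_scores(m0, x), "constant|degenerate")
  expect_true(all(rs0$score == 0))
  expect_error(risk_scores(m1, data.frame(b = 1)), "missing")
})

test_that("time-dependent AUC hits its closed-form extremes", {
  set.seed(61)
  tt <- sort(rexp(100, 0.2))
  rec <- data.frame(time = tt, event = 1)
  perfect <- -tt                                  # earlier event, higher score
  auc <- td_auc(rec, perfect, c(2, 5, 8))
  expect_equal(unname(auc), c(1, 1, 1))
  expect_warning(a2 <- td_auc(rec, perfect, max(tt) + 1), "no cases|no controls")
  expect_true(is.na(a2))
  const <- td_auc(rec, rep(1, 100), c(2, 5))
  expect_equal(unname(const), c(0.5, 0.5))
})

test_that("median split groups deterministically and flags constants", {
  v <- gen_survival(4, c(g1 = 0), censor_rate = 0, seed = 71)$survival
  ms <- median_split_survival(v, "g1")
  expect_equal(ms$n_high + ms$n_low, 4)
  expect_equal(ms$n_low, 2)
  v$g1 <- 1
  expect_error(median_split_survival(v, "g1"), "constant")
  expect_error(median_split_survival(v[1:3, ], "g1"), "at least 4")
})

test_that("median split separates a planted prognostic gene", {
  hits <- 0
  for (s in 1:30) {
    v <- gen_survival(500, c(g1 = 1), censor_rate = 0.2,
                      seed = 8100 + s)$survival
    if (median_split_survival(v, "g1")$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.9)
})
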