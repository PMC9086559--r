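check_surv <- function(records) {
  if (!all(c("time", "event") %in% names(records)))
    stop("survival records need 'time' and 'event' columns")
  if (any(records$time <= 0)) stop("times must be positive")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(records)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator; right-continuous, with S(0) = 1.
#'
#' @param records data.frame with `time` (years) and `event` (1 = event,
#'   0 = censored).
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv`, starting
#'   at time 0 with survival 1.
#' @export
km_curve <- function(records) {
  check_surv(records)
  if (nrow(records) < 1) stop("need at least one record")
  f <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = c(0, f$time),
             n_risk = c(nrow(records), f$n.risk),
             n_event = c(0, f$n.event),
             surv = c(1, f$surv))
}

#' Two-group log-rank test
#'
#' @param groupA,groupB survival record data.frames.
#' @return list with `chisq` (1 df) and `p`.
#' @export
logrank <- function(groupA, groupB) {
  check_surv(groupA); check_surv(groupB)
  if (nrow(groupA) == 0 || nrow(groupB) == 0)
    stop("both groups must be non-empty")
  d <- rbind(data.frame(time = groupA$time, event = groupA$event, g = "A"),
             data.frame(time = groupB$time, event = groupB$event, g = "B"))
  if (sum(d$event) == 0) {
    warning("no events in either group; log-rank undefined, returning p = 1")
    return(list(chisq = 0, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation with Breslow tie handling; Wald
#' confidence interval and p value.
#'
#' @param records survival records including a column for `gene`.
#' @param gene covariate column name.
#' @return list with `beta`, `hr`, `ci_lower`, `ci_upper`, `p`,
#'   `converged`.
#' @export
cox_univariate <- function(records, gene) {
  check_surv(records)
  if (!gene %in% names(records)) stop("gene not in records: ", gene)
  if (sum(records$event) < 2) stop("need at least 2 events")
  d <- data.frame(time = records$time, event = records$event,
                  x = records[[gene]])
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "breslow")
  s <- summary(fit)
  beta <- unname(stats::coef(fit))
  se <- s$coefficients[1, "se(coef)"]
  if (!is.finite(se) || abs(beta) > 15)
    warning("possible monotone likelihood (separation); estimate unstable")
  list(beta = beta, hr = exp(beta),
       ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
       p = s$coefficients[1, "Pr(>|z|)"],
       converged = is.finite(se) && abs(beta) <= 15)
}

#' LASSO-penalised Cox signature selection
#'
#' L1-penalised Cox partial-likelihood fit over a lambda grid, with the
#' penalty chosen by k-fold cross-validated partial-likelihood deviance
#' (minimum rule by default, 1-SE available). Genes with zero coefficients
#' at the chosen penalty are dropped. The risk-score cutoff stored in the
#' model is the median training risk score.
#'
#' @param records survival records with one column per candidate gene.
#' @param genes candidate gene columns.
#' @param lambda_grid optional decreasing lambda sequence (glmnet default
#'   path when NULL).
#' @param n_folds cross-validation folds (default 5).
#' @param rule `"min"` (minimum mean CV deviance) or `"1se"`.
#' @param seed integer seed controlling fold assignment.
#' @return a `RiskModel` list: `genes`, `betas`, `cutoff`, `lambda`,
#'   `auc` (empty; filled by [td_auc()] downstream).
#' @export
lasso_cox <- function(records, genes, lambda_grid = NULL, n_folds = 5,
                      rule = c("min", "1se"), seed = 1) {
  rule <- match.arg(rule)
  check_surv(records)
  if (!is.null(lambda_grid) && length(lambda_grid) == 0)
    stop("empty lambda grid")
  if (sum(records$event) < n_folds)
    stop("need at least n_folds events")
  miss <- setdiff(genes, names(records))
  if (length(miss) > 0) stop("genes not in records: ",
                             paste(miss, collapse = ", "))
  x <- as.matrix(records[, genes, drop = FALSE])
  y <- survival::Surv(records$time, records$event)
  set.seed(seed)
  cv <- glmnet::cv.glmnet(x, y, family = "cox", nfolds = n_folds,
                          lambda = lambda_grid)
  lam <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  b <- as.numeric(stats::coef(cv, s = lam))
  keep <- which(b != 0)
  betas <- stats::setNames(b[keep], genes[keep])
  scores <- if (length(keep) > 0) drop(x[, keep, drop = FALSE] %*% b[keep])
            else rep(0, nrow(x))
  structure(list(genes = genes[keep], betas = betas,
                 cutoff = stats::median(scores), lambda = lam,
                 auc = numeric(0)),
            class = "RiskModel")
}

#' @method print RiskModel
#' @export
print.RiskModel <- function(x, ...) {
  cat(sprintf("RiskModel: %d gene(s), lambda = %.4g, cutoff = %.4g\n",
              length(x$genes), x$lambda, x$cutoff))
  if (length(x$genes))
    print(round(x$betas, 4))
  invisible(x)
}

#' Per-patient risk scores and high/low stratification
#'
#' Risk score = sum of model coefficients times expression; a patient is
#' high-risk when the score strictly exceeds the training-median cutoff.
#'
#' @param model a `RiskModel`.
#' @param expr data.frame/matrix of expression (samples in rows, genes in
#'   columns) or survival records containing the model genes.
#' @return data.frame with `score` and `group` (`high`/`low`).
#' @export
risk_scores <- function(model, expr) {
  expr <- as.data.frame(expr)
  miss <- setdiff(model$genes, names(expr))
  if (length(miss) > 0) stop("missing gene(s): ", paste(miss, collapse = ", "))
  score <- if (length(model$genes) > 0)
    drop(as.matrix(expr[, model$genes, drop = FALSE]) %*% model$betas)
  else rep(0, nrow(expr))
  if (length(unique(score)) == 1)
    warning("constant risk scores; high/low split is degenerate")
  data.frame(score = score,
             group = ifelse(score > model$cutoff, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Time-dependent ROC AUC (cumulative cases / dynamic controls, IPCW)
#'
#' At horizon t, cases are subjects with an event by t and controls are
#' subjects still event-free beyond t; concordance between their scores
#' is weighted by inverse probability of censoring (Kaplan-Meier of the
#' censoring distribution). Tied scores count 1/2. With constant scores
#' the AUC is 0.5 by this tie convention.
#'
#' @param records survival records.
#' @param scores numeric risk scores, one per record (higher = worse).
#' @param horizons numeric vector of horizons (years).
#' @return named numeric vector of AUCs; `NA` (with a warning) at a
#'   horizon lacking cases or controls.
#' @export
td_auc <- function(records, scores, horizons) {
  check_surv(records)
  if (length(scores) != nrow(records))
    stop("one score per record required")
  # censoring survivor function G
  cens <- survival::survfit(survival::Surv(time, 1 - event) ~ 1,
                            data = records)
  G <- function(t) {
    if (length(cens$time) == 0) return(1)
    s <- c(1, cens$surv)[findInterval(t, cens$time) + 1]
    pmax(s, 1e-10)
  }
  out <- stats::setNames(numeric(length(horizons)), as.character(horizons))
  for (h in seq_along(horizons)) {
    t0 <- horizons[h]
    case <- which(records$time <= t0 & records$event == 1)
    ctrl <- which(records$time > t0)
    if (length(case) == 0 || length(ctrl) == 0) {
      warning("no cases or no controls at horizon ", t0)
      out[h] <- NA_real_
      next
    }
    wi <- 1 / G(pmax(records$time[case] - 1e-12, 0))
    num <- 0; den <- 0
    for (k in seq_along(case)) {
      conc <- sum(scores[case[k]] > scores[ctrl]) +
        0.5 * sum(scores[case[k]] == scores[ctrl])
      num <- num + wi[k] * conc
      den <- den + wi[k] * length(ctrl)
    }
    out[h] <- num / den
  }
  out
}

#' Median-split survival comparison for one gene
#'
#' Patients at or below the median expression form the low group (ties go
#' low); the rest form the high group. Returns both Kaplan-Meier curves
#' and the log-rank test.
#'
#' @param records survival records containing `gene`.
#' @param gene covariate column name.
#' @return list with `km_high`, `km_low`, `chisq`, `p`, `n_high`, `n_low`.
#' @export
median_split_survival <- function(records, gene) {
  check_surv(records)
  if (nrow(records) < 4) stop("need at least 4 samples")
  x <- records[[gene]]
  if (is.null(x)) stop("gene not in records: ", gene)
  if (length(unique(x)) == 1)
    stop("constant expression; median split undefined for ", gene)
  hi <- x > stats::median(x)
  a <- records[hi, , drop = FALSE]; b <- records[!hi, , drop = FALSE]
  lr <- logrank(a, b)
  list(km_high = km_curve(a), km_low = km_curve(b),
       chisq = lr$chisq, p = lr$p, n_high = sum(hi), n_low = sum(!hi))
}
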