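test_that("Cox coefficients match brute-force partial-likelihood maximization on a 4-patient toy", {
  x <- c(0.5, 1.2, -0.3, 2.0)
  time <- c(3, 5, 8, 11)
  event <- c(1, 1, 1, 1)
  fit <- cox_fit(data.frame(x = x), time, event)
  brute <- optimize(function(b) -cox_pll_1d(b, x, time, event),
                    interval = c(-10, 10), tol = 1e-9)
  expect_lt(abs(coef(fit)[["x"]] - brute$minimum), 1e-4)
})

test_that("a true hazard ratio of 2 is recovered at n = 2000", {
  set.seed(31)
  g <- rep(0:1, each = 1000)
  time <- rexp(2000, 0.05 * 2^g)
  cens <- rexp(2000, 0.02)
  fit <- cox_fit(data.frame(g = g), pmin(time, cens),
                 as.numeric(time <= cens))
  expect_gt(fit$table$hr, 1.8)
  expect_lt(fit$table$hr, 2.2)
})

test_that("Wald p-values are uniform under the null", {
  ps <- vapply(1:100, function(r) {
    set.seed(600 + r)
    x <- rnorm(60)
    time <- rexp(60, 0.05)
    cox_fit(data.frame(x = x), time, rep(1, 60))$table$wald_p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("perfect separation is reported with the covariate name", {
  time <- c(1, 2, 3, 4, 10, 11, 12, 13)
  sep <- as.numeric(time < 5)
  expect_error(cox_fit(data.frame(sep = sep), time, rep(1, 8)),
               "sep")
})

test_that("stepwise selection keeps a strong covariate and admits noise at the entry rate", {
  kept_strong <- 0L
  no_noise <- 0L
  m_noise <- 4
  for (r in 1:50) {
    set.seed(700 + r)
    n <- 150
    x <- data.frame(strong = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n), n4 = rnorm(n))
    time <- rexp(n, 0.05 * exp(1 * x$strong))
    cens <- rexp(n, 0.02)
    sw <- suppressWarnings(
      stepwise_cox(x, pmin(time, cens), as.numeric(time <= cens)))
    if ("strong" %in% sw$selected) kept_strong <- kept_strong + 1L
    if (identical(sw$selected, "strong")) no_noise <- no_noise + 1L
  }
  expect_gte(kept_strong, 48L)
  # with m independent noise candidates tested at 0.05 each, the no-noise
  # fraction should sit near 0.95^m
  expect_gt(no_noise / 50, 0.95^m_noise - 0.15)
  expect_lt(no_noise / 50, 0.95^m_noise + 0.15)
})

test_that("all-null candidates yield an empty model at roughly (1-0.05)^m", {
  m <- 5
  empty <- 0L
  for (r in 1:60) {
    set.seed(800 + r)
    n <- 100
    x <- as.data.frame(matrix(rnorm(n * m), n))
    time <- rexp(n, 0.05)
    sw <- suppressWarnings(stepwise_cox(x, time, rep(1, n)))
    if (length(sw$selected) == 0L) empty <- empty + 1L
  }
  expect_gt(empty / 60, 0.95^m - 0.18)
  expect_lt(empty / 60, 0.95^m + 0.18)
})

test_that("duplicated covariates enter only once", {
  set.seed(41)
  n <- 120
  z <- rnorm(n)
  x <- data.frame(a = z, b = z)
  time <- rexp(n, 0.05 * exp(z))
  sw <- stepwise_cox(x, time, rep(1, n))
  expect_length(sw$selected, 1L)
})

test_that("stepwise fixed point: kept covariates stay, excluded stay out", {
  set.seed(43)
  n <- 200
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  time <- rexp(n, 0.05 * exp(0.8 * x$a + 0.5 * x$b))
  sw <- suppressWarnings(stepwise_cox(x, time, rep(1, n)))
  ll <- function(cols) {
    if (length(cols) == 0)
      survival::coxph(survival::Surv(time, rep(1, n)) ~ 1)$loglik[1]
    else survival::coxph(survival::Surv(time, rep(1, n)) ~ .,
                         data = x[, cols, drop = FALSE])$loglik[2]
  }
  for (v in sw$selected) {
    p_rm <- pchisq(2 * (ll(sw$selected) - ll(setdiff(sw$selected, v))),
                   1, lower.tail = FALSE)
    expect_lte(p_rm, 0.10)
  }
  for (v in setdiff(names(x), sw$selected)) {
    p_in <- pchisq(2 * (ll(c(sw$selected, v)) - ll(sw$selected)),
                   1, lower.tail = FALSE)
    expect_gte(p_in, 0.05)
  }
})

test_that("log-rank matches the hand-worked 6-patient example to 1e-10", {
  group <- c("a", "a", "a", "b", "b", "b")
  time <- c(4, 7, 9, 2, 5, 12)
  event <- c(1, 0, 1, 1, 1, 0)
  res <- km_logrank(group, time, event)
  expect_lt(abs(res$chisq - logrank_by_hand(group, time, event)), 1e-10)
  expect_equal(res$p, pchisq(res$chisq, 1, lower.tail = FALSE))
})

test_that("identical groups give a zero log-rank statistic", {
  time <- c(2, 4, 6, 8)
  res <- km_logrank(rep(c("a", "b"), each = 4), rep(time, 2),
                    rep(1, 8))
  expect_lt(res$chisq, 1e-12)
  expect_equal(res$p, 1)
})

test_that("without censoring the KM curve equals the empirical survival function", {
  set.seed(51)
  time <- sort(rexp(40, 0.1))
  res <- km_logrank(rep(c("a", "b"), 20), time, rep(1, 40))
  for (t0 in c(5, 10, 20)) {
    expect_equal(sitesig:::km_at(time, rep(1, 40), t0), mean(time > t0))
  }
})

test_that("time-dependent AUC is 1 for a perfect marker and 0.5 for a constant", {
  set.seed(61)
  time <- c(rexp(50, 0.2), 60 + rexp(50, 0.01))
  score <- -time  # earlier failure = higher score
  r <- td_roc(score, time, rep(1, 100), horizon = 30, method = "KM")
  expect_equal(r$auc, 1)
  rc <- td_roc(rep(1, 100), time, rep(1, 100), horizon = 30, method = "KM")
  expect_equal(rc$auc, 0.5)
})

test_that("an uninformative score has AUC near one half", {
  aucs <- vapply(1:50, function(r) {
    set.seed(900 + r)
    n <- 300
    time <- rexp(n, 0.03)
    cens <- pmin(rexp(n, 0.015), 120)
    td_roc(rnorm(n), pmin(time, cens), as.numeric(time <= cens), 30)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("on uncensored data the KM estimator reduces to the empirical AUC to 1e-10", {
  set.seed(62)
  n <- 200
  score <- rnorm(n)
  time <- rexp(n, 0.05 * exp(0.6 * score))
  h <- median(time)
  r <- td_roc(score, time, rep(1, n), h, method = "KM")
  expect_lt(abs(r$auc - sitesig:::auc_rank(score, time <= h)), 1e-10)
})

test_that("the NNE AUC is invariant under strictly monotone score transforms", {
  set.seed(63)
  n <- 150
  score <- rnorm(n)
  time <- rexp(n, 0.05 * exp(0.5 * score))
  cens <- rexp(n, 0.02)
  tm <- pmin(time, cens); ev <- as.numeric(time <= cens)
  r1 <- td_roc(score, tm, ev, quantile(tm, 0.5))
  r2 <- td_roc(exp(3 * score), tm, ev, quantile(tm, 0.5))
  expect_lt(abs(r1$auc - r2$auc), 1e-6)
  expect_true(all(r1$TP >= -1e-9 & r1$TP <= 1 + 1e-9))
  expect_true(all(r1$FP >= -1e-9 & r1$FP <= 1 + 1e-9))
})

test_that("degenerate horizons are rejected", {
  time <- c(5, 10, 15)
  expect_error(td_roc(1:3, time, c(1, 1, 1), 100), "time range")
  expect_error(td_roc(1:3, time, c(0, 0, 1), 1), "no cases")
})

test_that("concordance matches exhaustive pair enumeration, including ties and censoring", {
  set.seed(71)
  for (r in 1:10) {
    n <- sample(8:30, 1)
    score <- sample(1:5, n, replace = TRUE)  # forces score ties
    time <- sample(1:10, n, replace = TRUE)  # forces time ties
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) next
    expect_equal(c_index(score, time, event),
                 cindex_enumerate(score, time, event))
  }
})

test_that("concordance hits its boundary cases and the reversal identity", {
  t5 <- toy_surv()
  expect_equal(c_index(-t5$time, t5$time, t5$event), 1)
  expect_equal(c_index(rep(2, 5), t5$time, t5$event), 0.5)
  set.seed(72)
  s <- rnorm(30); tm <- rexp(30, 0.1); ev <- rbinom(30, 1, 0.6)
  expect_equal(c_index(s, tm, ev), 1 - c_index(-s, tm, ev))
  # cross-check against the survival package on tie-free data
  cc <- survival::concordance(survival::Surv(tm, ev) ~ s, reverse = TRUE)
  expect_equal(c_index(s, tm, ev), unname(cc$concordance))
})

test_that("bootstrap optimism correction shrinks an overfitted model's concordance", {
  set.seed(81)
  n <- 80
  dat <- data.frame(matrix(rnorm(n * 6), n))
  dat$time <- rexp(n, 0.05)
  dat$event <- rep(1, n)
  res <- bootstrap_cindex(
    dat,
    fit_fun = function(d) cox_fit(d[1:6], d$time, d$event),
    score_fun = function(m, d) predict(m, d),
    B = 60, seed = 4)
  expect_gt(res$optimism, 0)
  expect_lt(res$adjusted, res$apparent)
  expect_true(res$ci[1] <= res$apparent && res$apparent <= res$ci[2])
})

test_that("a model compared with itself gives a large rank-sum p for several seeds", {
  set.seed(82)
  n <- 150
  s <- rnorm(n)
  time <- rexp(n, 0.04 * exp(0.5 * s))
  cens <- pmin(rexp(n, 0.02), 100)
  tm <- pmin(time, cens); ev <- as.numeric(time <= cens)
  for (sd in 1:4) {
    res <- compare_roc(s, s, tm, ev, horizon = 30, B = 100, seed = sd)
    expect_gt(res$p, 0.5)
  }
})

test_that("ROC comparison is symmetric and detects a planted strong model", {
  set.seed(83)
  n <- 300
  s <- rnorm(n)
  time <- rexp(n, 0.03 * exp(1.2 * s))
  cens <- pmin(rexp(n, 0.015), 120)
  tm <- pmin(time, cens); ev <- as.numeric(time <= cens)
  noise <- rnorm(n)
  r_ab <- compare_roc(s, noise, tm, ev, horizon = 30, B = 200, seed = 9)
  r_ba <- compare_roc(noise, s, tm, ev, horizon = 30, B = 200, seed = 9)
  expect_lt(r_ab$p, 0.01)
  expect_equal(r_ab$p, r_ba$p)
})
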