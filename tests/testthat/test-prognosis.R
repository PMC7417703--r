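fit_small_models <- function(seed = 21, n = 200, B = 100) {
  pr <- make_prognostic(n = n, p = 20, n_planted = 3, seed = seed)
  rm <- fit_risk_model(pr$x, pr$planted, pr$time, pr$event)
  clin <- pr$samples[, c("neoplasm_status", "residual_tumour", "radiation",
                         "stage")]
  list(pr = pr, rm = rm,
       bm = build_models(clin, rm, B = B, seed = seed))
}

test_that("median split halves the cohort with ties going low", {
  pr <- make_prognostic(n = 80, p = 5, n_planted = 2, seed = 31)
  rm <- fit_risk_model(pr$x, pr$planted, pr$time, pr$event)
  rm$scores <- setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  rm$median <- median(rm$scores)
  rm$time <- c(5, 6, 7, 8); rm$event <- c(1, 1, 1, 0)
  sp <- median_split(rm)
  expect_identical(as.vector(table(sp$group)), c(2L, 2L))
  expect_identical(unname(sp$group[1:2]), factor(c("low", "low"),
                                                 levels = c("low", "high")))
  # odd n with the middle value exactly at the median -> it goes low
  rm$scores <- setNames(c(1, 2, 3, 4, 5), paste0("s", 1:5))
  rm$median <- 3
  rm$time <- 1:5; rm$event <- rep(1, 5)
  sp2 <- median_split(rm)
  expect_identical(as.vector(table(sp2$group)), c(3L, 2L))
  rm$scores[] <- 1
  expect_error(median_split(rm), "identical")
})

test_that("a planted prognostic signature separates survival at p < 0.001", {
  pr <- make_prognostic(n = 300, p = 20, n_planted = 5, seed = 32)
  rm <- fit_risk_model(pr$x, pr$planted, pr$time, pr$event)
  sp <- median_split(rm)
  expect_lt(sp$km$p, 0.001)
})

test_that("combined models nest their components on training data", {
  fm <- fit_small_models(seed = 33)
  tab <- fm$bm$auc_table
  expect_gte(tab$apparent_auc[tab$model == "combined"],
             tab$apparent_auc[tab$model == "traditional"] - 1e-9)
  score_only <- td_roc(fm$rm$scores, fm$rm$time, fm$rm$event, 60)$auc
  expect_gte(tab$apparent_auc[tab$model == "combined"] + 0.02, score_only)
})

test_that("an uninformative clinical set reduces the combined model to the score", {
  pr <- make_prognostic(n = 150, p = 10, n_planted = 3, seed = 34)
  rm <- fit_risk_model(pr$x, pr$planted, pr$time, pr$event)
  set.seed(1)
  clin <- data.frame(j1 = rnorm(150), j2 = rnorm(150))
  bm <- build_models(clin, rm, B = 60, seed = 3)
  if (length(bm$clinical_selected) == 0L) {
    expect_null(bm$traditional)
    expect_identical(names(coef(bm$combined)), "risk_score")
  } else {
    succeed("noise covariate entered by chance; nothing further to assert")
  }
})

test_that("a zero-signal risk score adds nothing to the traditional model", {
  # null expression signal, ordinary clinical effects
  cfg <- sim_config(n_tumour = 200, n_normal = 8, n_features = 10,
                    n_de = 0, n_prog = 0, beta_prog = numeric(0), seed = 35)
  ds <- simulate_site_data(cfg)
  ss <- ds$samples[ds$samples$tissue == "tumour", ]
  x <- t(log2p1(ds$expression$values[, ss$sample_id]))
  pr <- list(x = x, time = ss$time, event = ss$event, samples = ss)
  set.seed(2)
  rm <- fit_risk_model(pr$x, colnames(pr$x)[1:2], pr$time, pr$event)
  clin <- pr$samples[, c("neoplasm_status", "residual_tumour", "radiation",
                         "stage")]
  bm <- build_models(clin, rm, B = 100, seed = 5)
  tab <- bm$auc_table
  expect_lt(abs(tab$apparent_auc[2] - tab$apparent_auc[1]), 0.1)
  expect_gt(bm$compare_p, 0.001)
})

test_that("nomogram points are linear 0-100 for a single covariate", {
  set.seed(36)
  x <- data.frame(marker = runif(100, 2, 10))
  time <- rexp(100, 0.03 * exp(0.5 * x$marker - 3))
  fit <- cox_fit(x, time, rep(1, 100))
  nm <- build_nomogram(fit, x, horizon = 24)
  g <- seq(min(x$marker), max(x$marker), length.out = 5)
  pts <- nomogram_points(nm, data.frame(marker = g))
  expect_equal(unname(pts[1, 1]), 0)
  expect_equal(unname(pts[5, 1]), 100)
  d <- diff(pts[, 1])
  expect_true(all(abs(d - d[1]) < 1e-9))
})

test_that("the nomogram round trip reproduces the direct Cox prediction to 1e-10", {
  fm <- fit_small_models(seed = 37)
  nm <- build_nomogram(fm$bm$combined, fm$bm$combined_data, horizon = 60)
  pred <- predict(nm, fm$bm$combined_data)
  direct <- survival_at(fm$bm$combined, fm$bm$combined_data, 60)
  expect_lt(max(abs(pred$survival - direct)), 1e-10)
  # and against the survival package's own survfit(newdata) curve
  cfit <- fm$bm$combined$fit
  sf <- survival::survfit(cfit, newdata = fm$bm$combined_data[1:5, ],
                          se.fit = FALSE)
  at60 <- summary(sf, times = 60)$surv
  expect_equal(unname(pred$survival[1:5]), as.vector(at60),
               tolerance = 1e-8)
})

test_that("scaling every coefficient leaves points unchanged but moves survival", {
  fm <- fit_small_models(seed = 38)
  nm <- build_nomogram(fm$bm$combined, fm$bm$combined_data)
  fit2 <- fm$bm$combined
  fit2$table$beta <- fit2$table$beta * 2
  nm2 <- build_nomogram(fit2, fm$bm$combined_data)
  pts1 <- nomogram_points(nm, fm$bm$combined_data)
  pts2 <- nomogram_points(nm2, fm$bm$combined_data)
  expect_equal(pts1, pts2, tolerance = 1e-10)
  s1 <- predict(nm, fm$bm$combined_data)$survival
  s2 <- predict(nm2, fm$bm$combined_data)$survival
  expect_gt(max(abs(s1 - s2)), 1e-4)
})

test_that("zero-range covariates are excluded from the nomogram with a warning", {
  set.seed(39)
  x <- data.frame(a = rnorm(80), b = rnorm(80))
  time <- rexp(80, 0.05 * exp(0.6 * x$a))
  fit <- cox_fit(x, time, rep(1, 80))
  x_flat <- x
  x_flat$b <- 1
  expect_warning(nm <- build_nomogram(fit, x_flat), "zero-range")
  expect_identical(nm$covariates, "a")
})

test_that("calibration recovers a self-simulated model within its intervals", {
  fm <- fit_small_models(seed = 40, n = 250)
  pred <- survival_at(fm$bm$combined, fm$bm$combined_data, 36)
  pred <- pmin(pmax(pred, 1e-6), 1 - 1e-6)
  cal <- calibrate(pred, fm$rm$time, fm$rm$event, horizon = 36,
                   groups = 3, B = 150, seed = 6)
  expect_equal(nrow(cal), 3)
  expect_true(all(cal$observed >= cal$lower - 1e-9 &
                    cal$observed <= cal$upper + 1e-9))
  within <- cal$predicted >= cal$lower & cal$predicted <= cal$upper
  expect_gte(sum(within), 2)
})

test_that("inverted predictions produce a monotone mismatch", {
  fm <- fit_small_models(seed = 41, n = 250)
  pred <- survival_at(fm$bm$combined, fm$bm$combined_data, 36)
  pred <- pmin(pmax(pred, 1e-6), 1 - 1e-6)
  cal_bad <- calibrate(1 - pred, fm$rm$time, fm$rm$event, horizon = 36,
                       groups = 3, B = 60, seed = 7)
  # groups ordered by (inverted) prediction: observed survival now falls
  # while predicted rises
  expect_lt(cor(cal_bad$predicted, cal_bad$observed), 0)
})

test_that("single-group calibration compares overall means", {
  fm <- fit_small_models(seed = 42)
  pred <- pmin(pmax(survival_at(fm$bm$combined, fm$bm$combined_data, 36),
                    1e-6), 1 - 1e-6)
  cal <- calibrate(pred, fm$rm$time, fm$rm$event, horizon = 36, groups = 1,
                   B = 50, seed = 8)
  expect_equal(nrow(cal), 1)
  expect_equal(cal$predicted, mean(pred))
  expect_equal(cal$observed,
               sitesig:::km_at(fm$rm$time, fm$rm$event, 36))
})

test_that("decision-curve net benefit matches the contingency table without censoring", {
  set.seed(43)
  n <- 200
  risk <- runif(n)
  event_by_h <- rbinom(n, 1, risk)
  time <- ifelse(event_by_h == 1, 10, 50)
  dc <- decision_curve(risk, time, rep(1, n), horizon = 36,
                       thresholds = c(0.2, 0.5, 0.8))
  for (i in seq_len(nrow(dc))) {
    pt <- dc$threshold[i]
    tp <- sum(risk > pt & event_by_h == 1) / n
    fp <- sum(risk > pt & event_by_h == 0) / n
    expect_equal(dc$net_benefit[i], tp - fp * pt / (1 - pt))
  }
  expect_true(all(dc$treat_none == 0))
})

test_that("an uninformative model cannot beat treat-all at low thresholds", {
  set.seed(44)
  n <- 300
  event_by_h <- rbinom(n, 1, 0.4)
  time <- ifelse(event_by_h == 1, 10, 50)
  risk <- runif(n)  # independent of outcome
  dc <- decision_curve(risk, time, rep(1, n), horizon = 36,
                       thresholds = seq(0.05, 0.3, 0.05))
  expect_true(all(dc$net_benefit <= dc$treat_all + 0.02))
})
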