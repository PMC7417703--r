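test_that("folds partition samples, are stratified and reproducible", {
  y <- factor(rep(c("a", "b"), c(60, 30)))
  f1 <- make_folds(y, 3, seed = 5)
  f2 <- make_folds(y, 3, seed = 5)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:3)
  for (k in 1:3) {
    expect_equal(sum(f1 == k & y == "a"), 20)
    expect_equal(sum(f1 == k & y == "b"), 10)
  }
  expect_false(identical(f1, make_folds(y, 3, seed = 6)))
})

test_that("a perfectly separating feature reaches SVM fitness 1", {
  set.seed(101)
  n <- 90
  y <- factor(rep(c("a", "b"), each = n / 2))
  x <- matrix(rnorm(n * 5), n)
  x[y == "a", 1] <- x[y == "a", 1] + 20
  fit <- svm_fitness(x, y, make_folds(y, 3, 1))
  expect_equal(fit(c(TRUE, rep(FALSE, 4))), 1)
})

test_that("randomly permuted labels give SVM fitness near one half", {
  set.seed(102)
  n <- 90
  x <- matrix(rnorm(n * 6), n)
  y0 <- factor(rep(c("a", "b"), each = n / 2))
  vals <- vapply(1:50, function(r) {
    set.seed(2000 + r)
    y <- sample(y0)
    fit <- svm_fitness(x, y, make_folds(y, 3, r))
    fit(rep(TRUE, 6))
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.5), 0.05)
})

test_that("a planted discriminative feature beats pure noise", {
  tc <- make_twoclass(n_per_class = 60, p = 20, n_planted = 1, seed = 7)
  folds <- make_folds(tc$labels, 3, 2)
  fit <- svm_fitness(tc$x, tc$labels, folds)
  planted_mask <- colnames(tc$x) %in% tc$planted
  noise_mask <- !planted_mask & seq_len(20) <= 6
  expect_gt(fit(planted_mask), fit(noise_mask))
})

test_that("Cox fitness rewards a planted prognostic feature", {
  pr <- make_prognostic(n = 300, p = 10, n_planted = 1, seed = 8)
  folds <- make_folds(pr$event, 3, 3)
  fit <- cox_fitness(pr$x, pr$time, pr$event, folds)
  planted_mask <- colnames(pr$x) %in% pr$planted
  expect_gt(fit(planted_mask), 0.7)
  noise_mask <- !planted_mask & seq_len(10) <= 4
  expect_gt(fit(planted_mask), fit(noise_mask))
})

test_that("negating the expression matrix leaves the Cox fitness unchanged", {
  pr <- make_prognostic(n = 150, p = 6, n_planted = 2, seed = 9)
  folds <- make_folds(pr$event, 3, 4)
  f_pos <- cox_fitness(pr$x, pr$time, pr$event, folds)
  f_neg <- cox_fitness(-pr$x, pr$time, pr$event, folds)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(f_pos(mask), f_neg(mask), tolerance = 1e-10)
})

test_that("the fitness horizon must be observable", {
  pr <- make_prognostic(n = 50, p = 4, n_planted = 1, seed = 10)
  folds <- make_folds(pr$event, 3, 5)
  expect_error(cox_fitness(pr$x, pr$time, pr$event, folds,
                           horizon = max(pr$time) + 1),
               "beyond")
})

test_that("forward selection follows the first-maximum rule", {
  curve <- c(0.6, 0.9, 0.9, 0.7)
  fit <- function(mask) curve[sum(mask)]
  sel <- forward_select(paste0("f", 1:4), paste0("f", 1:4), fit)
  expect_equal(sel$chosen_k, 2)
  expect_identical(sel$chosen, c("f1", "f2"))
  # strictly increasing curve -> chooses the full prefix
  fit2 <- function(mask) sum(mask) / 4
  sel2 <- forward_select(paste0("f", 1:4), paste0("f", 1:4), fit2)
  expect_equal(sel2$chosen_k, 4)
})

test_that("risk scores are the plain sum of beta times log2 expression", {
  pr <- make_prognostic(n = 80, p = 5, n_planted = 2, seed = 11)
  rm <- fit_risk_model(pr$x, colnames(pr$x)[1:3], pr$time, pr$event)
  manual <- drop(pr$x[, 1:3] %*% rm$beta)
  expect_equal(unname(rm$scores), unname(manual))
  # single feature with beta 0.7 at X = 2 scores 1.4
  rm1 <- rm
  rm1$features <- colnames(pr$x)[1]
  rm1$beta <- c(0.7)
  names(rm1$beta) <- rm1$features
  nd <- matrix(2, 1, 1, dimnames = list("s", rm1$features))
  expect_equal(unname(predict(rm1, nd)), 1.4)
  # all-zero coefficients give all-zero scores
  rm0 <- rm1
  rm0$beta[] <- 0
  expect_equal(unname(predict(rm0, nd)), 0)
})

test_that("risk-model coefficients match brute-force partial likelihood on a 4-patient toy", {
  x <- matrix(c(0.2, 1.5, -0.4, 0.9), 4, 1,
              dimnames = list(paste0("p", 1:4), "f1"))
  time <- c(2, 6, 9, 14)
  rm <- fit_risk_model(x, "f1", time, rep(1, 4))
  brute <- optimize(function(b) -cox_pll_1d(b, x[, 1], time, rep(1, 4)),
                    interval = c(-10, 10), tol = 1e-9)
  expect_lt(abs(rm$beta[["f1"]] - brute$minimum), 1e-6)
})

test_that("a duplicated signature feature triggers the ridge-stabilized refit", {
  pr <- make_prognostic(n = 80, p = 4, n_planted = 1, seed = 12)
  x <- cbind(pr$x, dup = pr$x[, pr$planted])
  expect_warning(rm <- fit_risk_model(x, c(pr$planted, "dup"), pr$time,
                                      pr$event),
                 "ridge")
  expect_true(rm$ridged)
  expect_true(all(is.finite(rm$beta)))
})

test_that("end-to-end GA selection is deterministic in (data seed, GA seed)", {
  pr <- make_prognostic(n = 120, p = 12, n_planted = 2, seed = 13)
  run_once <- function() {
    ga_select(pr$x, colnames(pr$x), type = "cox", time = pr$time,
              event = pr$event,
              params = ga_params(generations = 8, pop_size = 12),
              top_k = 10, max_k = 6, seed = 77)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$selection$chosen, b$selection$chosen)
  expect_identical(a$run$fitness, b$run$fitness)
  expect_equal(a$selection$chosen_auc, b$selection$chosen_auc)
})
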