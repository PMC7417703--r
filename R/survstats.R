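# Survival-statistics layer: Cox fitting, p-value stepwise selection,
# Kaplan-Meier / log-rank, time-dependent ROC, concordance, ROC comparison.

validate_survival <- function(time, event, n = NULL) {
  if (!is.null(n) && (length(time) != n || length(event) != n)) {
    stop("survival vectors must match the number of samples")
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("survival times must be finite and non-negative")
  }
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  if (sum(event) < 1) stop("no events observed: survival analysis undefined")
  invisible(TRUE)
}

# Thin wrapper over survival::coxph.fit for hot loops (GA fitness, stepwise).
# Returns NULL on failure / non-convergence instead of erroring.
fast_cox <- function(x, time, event, init = NULL) {
  x <- as.matrix(x)
  fit <- tryCatch(
    suppressWarnings(survival::coxph.fit(
      x = x, y = survival::Surv(time, event), strata = NULL, offset = NULL,
      init = init, control = survival::coxph.control(iter.max = 25),
      weights = NULL, method = "efron", rownames = NULL
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || any(!is.finite(fit$coefficients)) ||
      any(abs(fit$coefficients) > 20)) {
    return(NULL)
  }
  fit
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with the Efron approximation for tied
#' event times and returns the coefficient table (hazard ratios with 95 per
#' cent confidence intervals, Wald and likelihood-ratio p-values) together
#' with the baseline cumulative hazard evaluated at the covariate means.
#'
#' @param x data frame or matrix of numeric covariates (one column each).
#' @param time follow-up time in months.
#' @param event 1 = event observed, 0 = censored.
#' @return object of class \code{cox_fit}.
#' @export
cox_fit <- function(x, time, event) {
  x <- as.data.frame(x)
  if (ncol(x) == 0L) stop("cox_fit needs at least one covariate")
  validate_survival(time, event, nrow(x))
  if (sum(event) < 2) stop("cox_fit needs at least 2 events")
  if (any(!is.finite(as.matrix(x)))) stop("covariates must be finite")
  dat <- cbind(x, .time = time, .event = event)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(x)), collapse = " + ")
  ))
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron", x = TRUE),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  bad <- !is.finite(coef(fit)) | abs(coef(fit)) > 20
  if (any(bad) || any(grepl("infinite", warns))) {
    culprit <- names(coef(fit))[bad]
    if (length(culprit) == 0L) culprit <- names(coef(fit))
    stop(sprintf(
      "monotone partial likelihood (perfect separation) for covariate(s): %s",
      paste(culprit, collapse = ", ")
    ))
  }
  s <- summary(fit)
  tab <- data.frame(
    covariate = names(coef(fit)),
    beta = unname(coef(fit)),
    se = unname(s$coefficients[, "se(coef)"]),
    hr = unname(exp(coef(fit))),
    hr_lower = unname(s$conf.int[, "lower .95"]),
    hr_upper = unname(s$conf.int[, "upper .95"]),
    wald_p = unname(s$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  base <- survival::survfit(fit)
  structure(list(
    fit = fit, table = tab, loglik = fit$loglik,
    lr_p = unname(pchisq(2 * diff(fit$loglik), df = length(coef(fit)),
                         lower.tail = FALSE)),
    baseline = list(time = base$time, cumhaz = base$cumhaz, surv = base$surv),
    means = fit$means, n = fit$n, nevent = fit$nevent
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit: n=%d, events=%d\n", x$n, x$nevent))
  tab <- x$table
  tab$hr_ci <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$hr_lower, tab$hr_upper)
  print(tab[, c("covariate", "beta", "hr_ci", "wald_p")], row.names = FALSE)
  cat(sprintf("Likelihood-ratio p = %.3g\n", x$lr_p))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  setNames(object$table$beta, object$table$covariate)
}

#' Linear predictor (risk score) for new data
#' @param object a \code{cox_fit}.
#' @param newdata data frame with the model's covariates.
#' @param ... unused.
#' @export
predict.cox_fit <- function(object, newdata, ...) {
  b <- coef(object)
  xm <- as.matrix(newdata[, names(b), drop = FALSE])
  drop(xm %*% b)
}

#' Predicted survival probability at a time point
#'
#' Uses S(t | x) = exp(-H0(t) * exp(lp - mean lp)), with the baseline
#' cumulative hazard H0 from the fit (evaluated at covariate means).
#' @param object a \code{cox_fit}.
#' @param newdata covariate data frame.
#' @param horizon time point (months).
#' @export
survival_at <- function(object, newdata, horizon) {
  stopifnot(inherits(object, "cox_fit"))
  lp <- predict(object, newdata)
  lp_bar <- sum(coef(object) * object$means)
  h0 <- baseline_cumhaz_at(object, horizon)
  exp(-h0 * exp(lp - lp_bar))
}

baseline_cumhaz_at <- function(object, horizon) {
  bt <- object$baseline$time
  bh <- object$baseline$cumhaz
  idx <- findInterval(horizon, bt)
  if (idx == 0L) 0 else bh[idx]
}

#' Forward-backward stepwise Cox regression driven by p-values
#'
#' Adds, at each step, the candidate with the smallest likelihood-ratio
#' p-value if it is below \code{p_enter}; after each addition, removes any
#' included covariate whose likelihood-ratio p-value (against the model
#' without it) exceeds \code{p_remove}; iterates to a fixed point.
#'
#' @param x data frame of candidate covariates.
#' @param time,event survival outcome.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @return a \code{stepwise_cox} object: the final \code{cox_fit} (or NULL if
#'   no candidate entered), selected covariate names, and the inclusion trace.
#' @export
stepwise_cox <- function(x, time, event, p_enter = 0.05, p_remove = 0.10) {
  x <- as.data.frame(x)
  if (ncol(x) == 0L) stop("stepwise_cox needs at least one candidate")
  validate_survival(time, event, nrow(x))
  xm <- as.matrix(x)
  null_ll <- survival::coxph(survival::Surv(time, event) ~ 1)$loglik[1]
  loglik_of <- function(cols) {
    if (length(cols) == 0L) return(null_ll)
    f <- fast_cox(xm[, cols, drop = FALSE], time, event)
    if (is.null(f)) NA_real_ else f$loglik[2]
  }
  included <- character(0)
  trace <- list()
  ll_cur <- null_ll
  repeat {
    changed <- FALSE
    candidates <- setdiff(colnames(xm), included)
    if (length(candidates) > 0L) {
      ps <- vapply(candidates, function(cn) {
        ll1 <- loglik_of(c(included, cn))
        if (is.na(ll1)) return(NA_real_)
        pchisq(2 * (ll1 - ll_cur), df = 1, lower.tail = FALSE)
      }, numeric(1))
      ps <- ps[!is.na(ps)]
      if (length(ps) > 0L && min(ps) < p_enter) {
        best <- names(ps)[which.min(ps)]
        included <- c(included, best)
        ll_cur <- loglik_of(included)
        trace[[length(trace) + 1L]] <- list(action = "add", covariate = best,
                                            p = unname(min(ps)))
        changed <- TRUE
      }
    }
    # backward pass
    repeat {
      if (length(included) == 0L) break
      ps_rm <- vapply(included, function(cn) {
        ll0 <- loglik_of(setdiff(included, cn))
        if (is.na(ll0)) return(0)
        pchisq(2 * (ll_cur - ll0), df = 1, lower.tail = FALSE)
      }, numeric(1))
      if (max(ps_rm) > p_remove) {
        worst <- names(ps_rm)[which.max(ps_rm)]
        included <- setdiff(included, worst)
        ll_cur <- loglik_of(included)
        trace[[length(trace) + 1L]] <- list(action = "remove",
                                            covariate = worst,
                                            p = unname(max(ps_rm)))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- NULL
  if (length(included) > 0L) {
    fit <- cox_fit(x[, included, drop = FALSE], time, event)
  } else {
    warning("no candidate covariate entered the stepwise Cox model")
  }
  structure(list(fit = fit, selected = included, trace = trace,
                 p_enter = p_enter, p_remove = p_remove),
            class = "stepwise_cox")
}

#' @export
print.stepwise_cox <- function(x, ...) {
  if (length(x$selected) == 0L) {
    cat("Stepwise Cox: empty model (no covariate entered)\n")
  } else {
    cat("Stepwise Cox, selected:", paste(x$selected, collapse = ", "), "\n")
    print(x$fit)
  }
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' @param group factor-like group labels, one per subject.
#' @param time,event survival outcome.
#' @return a \code{km_logrank} object with per-group product-limit curves, the
#'   log-rank chi-square statistic, degrees of freedom and two-sided p-value.
#' @export
km_logrank <- function(group, time, event) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("km_logrank needs at least 2 groups")
  if (any(table(group) == 0L)) stop("every group must contain subjects")
  validate_survival(time, event, length(group))
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  structure(list(
    survfit = sf, chisq = sd$chisq, df = df,
    p = pchisq(sd$chisq, df = df, lower.tail = FALSE),
    groups = levels(group), n = as.vector(table(group))
  ), class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test over %d groups (%s): chisq=%.3f, df=%d, p=%.3g\n",
              length(x$groups), paste(x$n, collapse = "/"),
              x$chisq, x$df, x$p))
  invisible(x)
}

#' @export
plot.km_logrank <- function(x, col = seq_along(x$groups), xlab = "Months",
                            ylab = "Survival probability", ...) {
  plot(x$survfit, col = col, xlab = xlab, ylab = ylab, ...)
  graphics::legend("topright", legend = x$groups, col = col, lty = 1,
                   bty = "n")
  graphics::mtext(sprintf("log-rank p = %.3g", x$p), side = 3, adj = 1,
                  cex = 0.8)
  invisible(x)
}

# Product-limit survival at t0, optionally with case weights (used by the
# nearest-neighbour bivariate estimator). Vectorized: risk sets via sorted
# cumulative weights, event counts via rowsum.
km_at <- function(time, event, t0, weights = NULL) {
  if (!is.null(weights)) {
    keep <- weights > 0
    time <- time[keep]; event <- event[keep]; weights <- weights[keep]
  }
  if (length(time) == 0L) return(NA_real_)
  sel <- event == 1 & time <= t0
  if (!any(sel)) return(1)
  ut <- sort(unique(time[sel]))
  ord <- order(time)
  w <- if (is.null(weights)) rep(1, length(time)) else weights
  cw <- cumsum(w[ord])
  tot <- cw[length(cw)]
  n_lt <- findInterval(ut, time[ord], left.open = TRUE)  # strictly before u
  r <- tot - c(0, cw)[n_lt + 1L]
  d <- as.vector(rowsum(w[sel], match(time[sel], ut)))
  prod(1 - d / r)
}

#' Time-dependent ROC curve for censored survival (cumulative/dynamic)
#'
#' Estimates the ROC curve at a fixed horizon with cumulative cases (event by
#' the horizon) and dynamic controls (event-free past it). The default
#' estimator is the nearest-neighbour bivariate survival estimator with span
#' 0.25 * n^(-0.20); the simpler Kaplan-Meier variant (conditional KM within
#' marker subgroups) is available via \code{method = "KM"} and reduces to the
#' plain empirical ROC when there is no censoring.
#'
#' @param score numeric marker, higher = higher risk.
#' @param time,event survival outcome (months, 0/1).
#' @param horizon evaluation time (months).
#' @param method "NNE" (default) or "KM".
#' @param span percentile half-width of the nearest-neighbour window;
#'   default 0.25 * n^(-0.20).
#' @return a \code{td_roc} object: cutoffs, TP (sensitivity), FP
#'   (1 - specificity) and trapezoidal AUC.
#' @export
td_roc <- function(score, time, event, horizon,
                   method = c("NNE", "KM"), span = NULL) {
  method <- match.arg(method)
  validate_survival(time, event, length(score))
  if (any(!is.finite(score))) stop("scores must be finite")
  if (horizon <= 0 || horizon > max(time)) {
    stop("horizon must lie within the observed time range")
  }
  n <- length(score)
  n_case <- sum(time <= horizon & event == 1)
  n_ctrl <- sum(time > horizon)
  if (n_case == 0L) stop("no cases by the horizon: AUC undefined")
  if (n_ctrl == 0L) stop("no controls past the horizon: AUC undefined")
  cutoffs <- sort(unique(score))

  if (method == "KM") {
    # conditional KM within every nested subgroup {score > c} in one pass:
    # order samples by score (descending), cumulate event/at-risk counts over
    # prefixes, and read off the product-limit estimate per prefix.
    ord_s <- order(score, decreasing = TRUE)
    ts <- time[ord_s]; es <- event[ord_s]
    ut <- sort(unique(ts[es == 1 & ts <= horizon]))
    m <- length(ut)
    tmat <- matrix(ts, m, n, byrow = TRUE)
    D <- (tmat == matrix(ut, m, n)) &
      matrix(es == 1, m, n, byrow = TRUE)
    R <- tmat >= matrix(ut, m, n)
    Dc <- if (m > 0L) t(apply(D, 1, cumsum)) else matrix(0, 0, n)
    Rc <- if (m > 0L) t(apply(R, 1, cumsum)) else matrix(0, 0, n)
    ratio <- Dc / Rc
    ratio[!is.finite(ratio)] <- 0
    s_prefix <- if (m > 0L) {
      exp(colSums(log1p(-ratio)))
    } else rep(1, n)
    s_all <- s_prefix[n]
    n_gt <- n - findInterval(cutoffs, sort(score))  # strictly above cutoff
    tp <- fp <- numeric(length(cutoffs) + 1L)
    tp[1] <- 1; fp[1] <- 1  # cutoff below the minimum
    for (k in seq_along(cutoffs)) {
      j <- n_gt[k]
      if (j == 0L) {
        tp[k + 1L] <- 0; fp[k + 1L] <- 0
      } else {
        s_c <- s_prefix[j]
        p_c <- j / n
        tp[k + 1L] <- (1 - s_c) * p_c / (1 - s_all)
        fp[k + 1L] <- s_c * p_c / s_all
      }
    }
    cut_out <- c(-Inf, cutoffs)
  } else {
    if (is.null(span)) span <- 0.25 * n^(-0.20)
    pct <- rank(score, ties.method = "average") / n
    s_i <- vapply(seq_len(n), function(i) {
      w <- as.numeric(abs(pct - pct[i]) <= span)
      km_at(time, event, horizon, weights = w)
    }, numeric(1))
    denom_case <- sum(1 - s_i)
    denom_ctrl <- sum(s_i)
    if (denom_case <= 0 || denom_ctrl <= 0) {
      stop("degenerate nearest-neighbour estimate: no cases or no controls")
    }
    tp <- fp <- numeric(length(cutoffs) + 1L)
    tp[1] <- 1; fp[1] <- 1
    for (k in seq_along(cutoffs)) {
      idx <- score > cutoffs[k]
      tp[k + 1L] <- sum((1 - s_i)[idx]) / denom_case
      fp[k + 1L] <- sum(s_i[idx]) / denom_ctrl
    }
    cut_out <- c(-Inf, cutoffs)
  }
  # integrate along the cutoff-parametrized curve (FP runs 1 -> 0)
  auc <- sum(-diff(fp) * (head(tp, -1) + tp[-1]) / 2)
  structure(list(cutoffs = cut_out, TP = tp, FP = fp, auc = auc,
                 horizon = horizon, method = method,
                 n_case = n_case, n_ctrl = n_ctrl),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf(
    "Time-dependent ROC (%s) at t=%g: AUC=%.3f (%d cases, %d controls)\n",
    x$method, x$horizon, x$auc, x$n_case, x$n_ctrl))
  invisible(x)
}

#' @export
plot.td_roc <- function(x, xlab = "1 - specificity", ylab = "Sensitivity",
                        ...) {
  plot(x$FP, x$TP, type = "l", xlab = xlab, ylab = ylab, ...)
  graphics::abline(0, 1, lty = 3)
  graphics::mtext(sprintf("AUC = %.3f at t = %g", x$auc, x$horizon),
                  side = 3, adj = 1, cex = 0.8)
  invisible(x)
}

#' Harrell's concordance index
#'
#' Over comparable pairs (the subject with shorter follow-up experienced the
#' event; tied times are comparable only when exactly one had the event),
#' counts 1 for a concordant pair (higher score fails first), 0.5 for a tied
#' score.
#'
#' @param score risk score, higher = worse prognosis.
#' @param time,event survival outcome.
#' @export
c_index <- function(score, time, event) {
  validate_survival(time, event, length(score))
  n <- length(score)
  conc <- comp <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    # who is the case (fails first)?
    i_case <- (time[i] < time[j] & event[i] == 1) |
      (time[i] == time[j] & event[i] == 1 & event[j] == 0)
    j_case <- (time[j] < time[i] & event[j] == 1) |
      (time[i] == time[j] & event[j] == 1 & event[i] == 0)
    comp <- comp + sum(i_case) + sum(j_case)
    conc <- conc + sum(i_case * ((score[i] > score[j]) +
                                   0.5 * (score[i] == score[j]))) +
      sum(j_case * ((score[j] > score[i]) + 0.5 * (score[i] == score[j])))
  }
  if (comp == 0) stop("no comparable pairs: concordance undefined")
  conc / comp
}

#' Optimism-corrected concordance by bootstrap
#'
#' Refits the model on each bootstrap resample, computes the optimism
#' (resample concordance minus the resample-fitted model's concordance on the
#' original data) and subtracts its mean from the apparent concordance.
#'
#' @param data data frame holding covariates plus \code{time} and
#'   \code{event} columns.
#' @param fit_fun function(data) -> fitted model.
#' @param score_fun function(model, data) -> numeric risk scores.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return list with apparent, adjusted, optimism, and a 95 per cent
#'   percentile CI for the apparent concordance.
#' @export
bootstrap_cindex <- function(data, fit_fun, score_fun, B = 1000, seed = 1) {
  stopifnot(all(c("time", "event") %in% names(data)))
  model0 <- fit_fun(data)
  apparent <- c_index(score_fun(model0, data), data$time, data$event)
  n <- nrow(data)
  with_seed(seed, {
    optimism <- numeric(0)
    c_boot <- numeric(0)
    b <- 0L
    tries <- 0L
    while (b < B && tries < 10L * B) {
      tries <- tries + 1L
      idx <- sample.int(n, n, replace = TRUE)
      dat_b <- data[idx, , drop = FALSE]
      res <- tryCatch({
        m_b <- fit_fun(dat_b)
        c_b <- c_index(score_fun(m_b, dat_b), dat_b$time, dat_b$event)
        c_orig <- c_index(score_fun(m_b, data), data$time, data$event)
        c(c_b, c_b - c_orig)
      }, error = function(e) NULL)
      if (is.null(res)) next
      b <- b + 1L
      c_boot[b] <- res[1]
      optimism[b] <- res[2]
    }
    if (b < B) warning(sprintf("only %d of %d bootstrap resamples usable",
                               b, B))
    list(apparent = apparent,
         adjusted = apparent - mean(optimism),
         optimism = mean(optimism),
         ci = unname(quantile(c_boot, c(0.025, 0.975))),
         B = b)
  })
}

#' Compare two risk models' time-dependent ROC curves by bootstrap
#'
#' Draws B bootstrap resamples of the cohort, computes each model's
#' time-dependent AUC at the horizon on every resample, and compares the two
#' AUC samples with a two-sided Wilcoxon rank-sum test.
#'
#' @param score_a,score_b risk scores of the two models on the same samples.
#' @param time,event survival outcome.
#' @param horizon evaluation time (months, default 60).
#' @param B bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param method ROC estimator passed to \code{\link{td_roc}}; "KM" default
#'   here for stability on resamples.
#' @return list with the rank-sum p-value and the two AUC samples.
#' @export
compare_roc <- function(score_a, score_b, time, event, horizon = 60,
                        B = 1000, seed = 1, method = "KM") {
  stopifnot(length(score_a) == length(score_b))
  validate_survival(time, event, length(score_a))
  n <- length(score_a)
  with_seed(seed, {
    auc_a <- auc_b <- numeric(0)
    b <- 0L; tries <- 0L; redrawn <- 0L
    while (b < B && tries < 10L * B) {
      tries <- tries + 1L
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch(c(
        td_roc(score_a[idx], time[idx], event[idx], horizon,
               method = method)$auc,
        td_roc(score_b[idx], time[idx], event[idx], horizon,
               method = method)$auc
      ), error = function(e) NULL)
      if (is.null(res)) { redrawn <- redrawn + 1L; next }
      b <- b + 1L
      auc_a[b] <- res[1]; auc_b[b] <- res[2]
    }
    if (b < 2L) stop("too few usable bootstrap resamples for ROC comparison")
    p <- suppressWarnings(
      wilcox.test(auc_a, auc_b, exact = FALSE)$p.value
    )
    if (is.nan(p)) p <- 1  # all ties: distributions identical
    list(p = p, auc_a = auc_a, auc_b = auc_b,
         mean_auc_a = mean(auc_a), mean_auc_b = mean(auc_b),
         B = b, redrawn = redrawn)
  })
}
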