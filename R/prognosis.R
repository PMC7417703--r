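# Traditional vs combined prognostic models, nomogram, calibration and
# decision curves.

#' Build traditional and combined site-specific prognostic models
#'
#' The traditional model is a p-value stepwise Cox fit on the clinical
#' covariates alone; the combined model adds the transcriptomic risk score
#' as one continuous covariate. Both are scored with the time-dependent AUC
#' at the horizon, apparent and 3-fold cross-validated, and the two ROC
#' curves are compared by bootstrap rank-sum.
#'
#' @param clinical data frame of numeric clinical covariates (one row per
#'   patient, same order as the risk model's cohort).
#' @param risk_model a \code{\link{fit_risk_model}} result.
#' @param horizon months (default 60).
#' @param B bootstrap resamples for the ROC comparison (default 1000).
#' @param seed RNG seed for folds and bootstrap.
#' @param stepwise run stepwise selection on the clinical covariates
#'   (default TRUE); if FALSE all are kept.
#' @return a \code{site_models} object: traditional/combined fits, the AUC
#'   table and the comparison p-value.
#' @export
build_models <- function(clinical, risk_model, horizon = 60, B = 1000,
                         seed = 1, stepwise = TRUE) {
  stopifnot(inherits(risk_model, "risk_model"))
  clinical <- as.data.frame(clinical)
  time <- risk_model$time
  event <- risk_model$event
  stopifnot(nrow(clinical) == length(time))

  if (stepwise && ncol(clinical) > 0L) {
    sw <- withCallingHandlers(
      stepwise_cox(clinical, time, event),
      warning = function(w) invokeRestart("muffleWarning"))
    clin_sel <- sw$selected
  } else {
    sw <- NULL
    clin_sel <- colnames(clinical)
  }

  traditional <- if (length(clin_sel) > 0L) {
    cox_fit(clinical[, clin_sel, drop = FALSE], time, event)
  } else NULL

  comb_df <- cbind(clinical[, clin_sel, drop = FALSE],
                   risk_score = unname(risk_model$scores))
  combined <- cox_fit(comb_df, time, event)

  score_trad <- if (is.null(traditional)) rep(0, length(time)) else
    predict(traditional, clinical)
  score_comb <- predict(combined, comb_df)

  app_trad <- if (is.null(traditional)) 0.5 else
    td_roc(score_trad, time, event, horizon)$auc
  app_comb <- td_roc(score_comb, time, event, horizon)$auc

  folds <- make_folds(event, 3, seed = child_seed(seed, 11))
  cv_trad <- if (is.null(traditional)) 0.5 else
    cv_cox_auc(clinical[, clin_sel, drop = FALSE], time, event, folds,
               horizon)
  cv_comb <- cv_cox_auc(comb_df, time, event, folds, horizon)

  cmp <- if (is.null(traditional)) NULL else
    compare_roc(score_trad, score_comb, time, event, horizon = horizon,
                B = B, seed = child_seed(seed, 12))

  auc_table <- data.frame(
    model = c("traditional", "combined"),
    apparent_auc = c(app_trad, app_comb),
    cv_auc = c(cv_trad, cv_comb)
  )
  structure(list(
    stepwise = sw, clinical_selected = clin_sel,
    traditional = traditional, combined = combined,
    combined_data = comb_df,
    score_traditional = score_trad, score_combined = score_comb,
    auc_table = auc_table, compare_p = if (is.null(cmp)) NA_real_ else cmp$p,
    horizon = horizon, time = time, event = event
  ), class = "site_models")
}

# 3-fold cross-validated td-AUC of a Cox model on a covariate frame
cv_cox_auc <- function(x, time, event, folds, horizon) {
  xm <- as.matrix(x)
  aucs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- fast_cox(xm[tr, , drop = FALSE], time[tr], event[tr])
    if (is.null(fit)) return(NA_real_)
    sc <- drop(xm[!tr, , drop = FALSE] %*% fit$coefficients)
    tryCatch(td_roc(sc, time[!tr], event[!tr], horizon, method = "KM")$auc,
             error = function(e) NA_real_)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' @export
print.site_models <- function(x, ...) {
  cat("Site-specific prognostic models\n")
  cat("  clinical covariates kept:",
      if (length(x$clinical_selected)) paste(x$clinical_selected,
                                             collapse = ", ") else "(none)",
      "\n")
  print(x$auc_table, row.names = FALSE)
  cat(sprintf("  ROC comparison (combined vs traditional): p = %.3g\n",
              x$compare_p))
  invisible(x)
}

#' Build a nomogram from a fitted Cox model
#'
#' Maps each covariate value to points on a 0-100 scale — the most
#' influential covariate (largest |beta| times observed range) spans the
#' full 100 — with the reference point at the range endpoint of minimum
#' risk. Total points map affinely back to the linear predictor, and
#' survival at the horizon is S0(t)^exp(lp - mean lp), so the chain
#' covariates -> points -> total points -> survival reproduces the model's
#' direct prediction exactly.
#'
#' @param fit a \code{\link{cox_fit}} (typically the combined model).
#' @param data covariate data frame the model was fitted on (defines the
#'   observed ranges).
#' @param horizon months for the headline survival axis (default 60).
#' @return a \code{site_nomogram}.
#' @export
build_nomogram <- function(fit, data, horizon = 60) {
  stopifnot(inherits(fit, "cox_fit"))
  b <- coef(fit)
  data <- as.data.frame(data)[, names(b), drop = FALSE]
  rng <- lapply(data, range)
  span <- vapply(names(b), function(j) abs(b[j]) * diff(rng[[j]]),
                 numeric(1))
  zero <- span == 0
  if (any(zero)) {
    warning("zero-range covariate(s) excluded from the nomogram: ",
            paste(names(b)[zero], collapse = ", "))
  }
  keep <- names(b)[!zero]
  if (length(keep) == 0L) stop("no covariate with nonzero range")
  D <- max(span[keep])
  ref <- vapply(keep, function(j) {
    if (b[j] > 0) rng[[j]][1] else rng[[j]][2]  # minimum-risk endpoint
  }, numeric(1))
  # lp over excluded (zero-range) covariates is constant; fold into offset
  lp_const <- sum(vapply(names(b)[zero], function(j) b[j] * rng[[j]][1],
                         numeric(1)))
  lp_at_ref <- sum(b[keep] * ref) + lp_const
  lp_bar <- sum(b * fit$means[names(b)])
  structure(list(
    fit = fit, covariates = keep, beta = b[keep], ref = ref,
    ranges = rng[keep], scale = 100 / D,
    lp_at_ref = lp_at_ref, lp_bar = lp_bar, lp_const = lp_const,
    horizon = horizon
  ), class = "site_nomogram")
}

#' Per-covariate nomogram points
#' @param nomogram a \code{site_nomogram}.
#' @param newdata covariate data frame.
#' @return matrix of points, one column per covariate.
#' @export
nomogram_points <- function(nomogram, newdata) {
  newdata <- as.data.frame(newdata)
  # beta < 0: moving x below ref raises risk; points = |beta|(ref - x)*scale
  pts <- vapply(nomogram$covariates, function(j) {
    x <- newdata[[j]]
    if (nomogram$beta[j] > 0) {
      nomogram$scale * nomogram$beta[j] * (x - nomogram$ref[j])
    } else {
      nomogram$scale * (-nomogram$beta[j]) * (nomogram$ref[j] - x)
    }
  }, numeric(nrow(newdata)))
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1,
                                       dimnames = list(NULL,
                                                       nomogram$covariates))
  pts
}

#' Total points -> survival probability at a horizon
#' @param nomogram a \code{site_nomogram}.
#' @param total_points numeric vector.
#' @param horizon months (default: the nomogram's horizon).
#' @export
nomogram_survival <- function(nomogram, total_points,
                              horizon = nomogram$horizon) {
  lp <- nomogram$lp_at_ref + total_points / nomogram$scale
  h0 <- baseline_cumhaz_at(nomogram$fit, horizon)
  exp(-h0 * exp(lp - nomogram$lp_bar))
}

#' Predict survival through the nomogram point chain
#' @param object a \code{site_nomogram}.
#' @param newdata covariate data frame.
#' @param horizon months.
#' @param ... unused.
#' @return list: per-covariate points, total points, survival probability.
#' @export
predict.site_nomogram <- function(object, newdata,
                                  horizon = object$horizon, ...) {
  pts <- nomogram_points(object, newdata)
  total <- rowSums(pts)
  list(points = pts, total_points = total,
       survival = nomogram_survival(object, total, horizon))
}

#' @export
print.site_nomogram <- function(x, ...) {
  cat(sprintf("Nomogram over %d covariates (horizon %g months)\n",
              length(x$covariates), x$horizon))
  for (j in x$covariates) {
    cat(sprintf("  %-18s beta=%+.3f  range [%.3g, %.3g]  max points %.1f\n",
                j, x$beta[j], x$ranges[[j]][1], x$ranges[[j]][2],
                x$scale * abs(x$beta[j]) * diff(x$ranges[[j]])))
  }
  invisible(x)
}

#' @export
plot.site_nomogram <- function(x, n_grid = 50, ...) {
  p <- length(x$covariates)
  graphics::par(mfrow = c(p + 1, 1), mar = c(2, 8, 1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  for (j in x$covariates) {
    g <- seq(x$ranges[[j]][1], x$ranges[[j]][2], length.out = n_grid)
    nd <- setNames(data.frame(g), j)
    for (o in setdiff(x$covariates, j)) nd[[o]] <- x$ref[o]
    pts <- nomogram_points(x, nd)[, j]
    plot(g, pts, type = "l", ylim = c(0, 100), ylab = j, xlab = "", ...)
  }
  tp <- seq(0, 100 * length(x$covariates), length.out = n_grid)
  plot(tp, nomogram_survival(x, tp), type = "l", ylab = "Survival",
       xlab = "Total points", ylim = c(0, 1))
  invisible(x)
}

#' Calibration of predicted survival against Kaplan-Meier observation
#'
#' Bins patients into equal-size groups by predicted survival at the
#' horizon; per group, compares the mean prediction with the KM estimate
#' and attaches a bootstrap percentile CI to the latter.
#'
#' @param predicted predicted survival probabilities in (0, 1).
#' @param time,event observed outcome.
#' @param horizon months (default 36: 3-year calibration is used when few
#'   patients have follow-up past 5 years).
#' @param groups number of bins (default 3).
#' @param B bootstrap resamples for the CI (default 1000).
#' @param seed RNG seed.
#' @return a \code{calibration_table} data frame.
#' @export
calibrate <- function(predicted, time, event, horizon = 36, groups = 3,
                      B = 1000, seed = 1) {
  validate_survival(time, event, length(predicted))
  if (any(predicted <= 0 | predicted >= 1)) {
    stop("predictions must lie strictly in (0, 1)")
  }
  grp <- if (groups == 1L) rep(1L, length(predicted)) else {
    as.integer(cut(rank(predicted, ties.method = "first"),
                   breaks = groups, labels = FALSE))
  }
  rows <- lapply(sort(unique(grp)), function(g) {
    idx <- grp == g
    if (!any(time[idx] >= horizon) && sum(event[idx]) == 0) {
      message(sprintf("calibration group %d dropped: no information at horizon", g))
      return(NULL)
    }
    obs <- km_at(time[idx], event[idx], horizon)
    ci <- with_seed(child_seed(seed, g), {
      bs <- replicate(B, {
        jj <- sample(which(idx), sum(idx), replace = TRUE)
        km_at(time[jj], event[jj], horizon)
      })
      quantile(bs, c(0.025, 0.975), na.rm = TRUE)
    })
    data.frame(group = g, n = sum(idx),
               predicted = mean(predicted[idx]), observed = obs,
               lower = unname(ci[1]), upper = unname(ci[2]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_table", "data.frame")
  attr(out, "horizon") <- horizon
  out
}

#' @export
plot.calibration_table <- function(x, ...) {
  plot(x$predicted, x$observed, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Predicted survival", ylab = "Observed (KM) survival", ...)
  graphics::arrows(x$predicted, x$lower, x$predicted, x$upper,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Decision-curve analysis (net benefit) under censoring
#'
#' Net benefit at threshold p_t is TP/n - (FP/n) * p_t / (1 - p_t), where a
#' patient is "treated" if the predicted event risk at the horizon exceeds
#' p_t, and the event probability among the treated is estimated by
#' Kaplan-Meier to respect censoring. Includes treat-all and treat-none
#' reference curves.
#'
#' @param risk predicted event probability at the horizon (1 - survival).
#' @param time,event observed outcome.
#' @param horizon months (default 36).
#' @param thresholds probability thresholds in (0, 1); values at 0 or 1 are
#'   dropped.
#' @return a \code{decision_curve} data frame: threshold, net benefit of the
#'   model, of treat-all, and treat-none (0).
#' @export
decision_curve <- function(risk, time, event, horizon = 36,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  validate_survival(time, event, length(risk))
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  if (length(thresholds) == 0L) stop("no usable thresholds in (0, 1)")
  n <- length(risk)
  ev_all <- 1 - km_at(time, event, horizon)
  rows <- lapply(thresholds, function(pt) {
    treated <- risk > pt
    if (!any(treated)) {
      nb <- 0
    } else {
      ev_tr <- 1 - km_at(time[treated], event[treated], horizon)
      tp <- ev_tr * mean(treated)
      fp <- (1 - ev_tr) * mean(treated)
      nb <- tp - fp * pt / (1 - pt)
    }
    nb_all <- ev_all - (1 - ev_all) * pt / (1 - pt)
    data.frame(threshold = pt, net_benefit = nb, treat_all = nb_all,
               treat_none = 0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("decision_curve", "data.frame")
  attr(out, "horizon") <- horizon
  out
}

#' @export
plot.decision_curve <- function(x, ...) {
  plot(x$threshold, x$net_benefit, type = "l", lwd = 2,
       xlab = "Threshold probability", ylab = "Net benefit",
       ylim = range(c(x$net_benefit, x$treat_all, 0)), ...)
  graphics::lines(x$threshold, x$treat_all, lty = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("model", "treat all", "treat none"),
                   lty = c(1, 2, 3), lwd = c(2, 1, 1), bty = "n")
  invisible(x)
}
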