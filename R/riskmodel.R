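# Risk-score model: one multivariable Cox fit over the selected signature,
# per-patient score sum(beta_i * X_i) on the log2 scale, median split.

#' Fit a prognostic risk-score model over a feature signature
#'
#' Fits one multivariable Cox model on the full cohort over the selected
#' features (log2(x+1) expression) and defines each patient's risk score as
#' the linear predictor sum(beta_i * X_i). Collinear signatures trigger a
#' ridge-stabilized refit (penalty 1e-4) with a warning.
#'
#' @param x samples-by-features matrix of log2 expression (or a raw-scale
#'   \code{\link{expression_matrix}}, transformed internally).
#' @param features signature feature ids (columns/rows of \code{x}).
#' @param time,event survival outcome per sample.
#' @return a \code{risk_model}: coefficient table, per-patient scores,
#'   median threshold and the underlying \code{cox_fit}.
#' @export
fit_risk_model <- function(x, features, time, event) {
  if (inherits(x, "expression_matrix")) {
    x <- t(log2_values(x))
  }
  if (length(features) == 0L) stop("signature is empty")
  missing <- setdiff(features, colnames(x))
  if (length(missing)) {
    stop("features absent from the matrix: ", paste(missing, collapse = ", "))
  }
  xm <- as.data.frame(x[, features, drop = FALSE])
  validate_survival(time, event, nrow(xm))
  fit <- tryCatch(cox_fit(xm, time, event), error = function(e) e)
  ridged <- FALSE
  if (inherits(fit, "error") || any(is.na(coef(fit)))) {
    warning("collinear or degenerate signature; ridge-stabilized refit (penalty 1e-4)")
    ridged <- TRUE
    fit <- ridge_cox_fit(xm, time, event, theta = 1e-4)
  }
  beta <- coef(fit)
  scores <- drop(as.matrix(xm) %*% beta)
  names(scores) <- rownames(x)
  structure(list(
    features = features, beta = beta, fit = fit,
    scores = scores, median = median(scores),
    time = time, event = event, ridged = ridged
  ), class = "risk_model")
}

ridge_cox_fit <- function(x, time, event, theta = 1e-4) {
  dat <- cbind(x, .time = time, .event = event)
  vars <- paste(sprintf("`%s`", names(x)), collapse = ", ")
  fml <- stats::as.formula(sprintf(
    "survival::Surv(.time, .event) ~ ridge(%s, theta = %g, scale = FALSE)",
    vars, theta))
  fit <- suppressWarnings(survival::coxph(fml, data = dat, ties = "efron"))
  b <- coef(fit)
  names(b) <- names(x)
  base <- survival::survfit(fit)
  tab <- data.frame(covariate = names(x), beta = unname(b),
                    se = sqrt(diag(fit$var)), hr = unname(exp(b)),
                    hr_lower = NA_real_, hr_upper = NA_real_,
                    wald_p = NA_real_, stringsAsFactors = FALSE)
  structure(list(fit = fit, table = tab, loglik = fit$loglik,
                 lr_p = NA_real_,
                 baseline = list(time = base$time, cumhaz = base$cumhaz,
                                 surv = base$surv),
                 means = fit$means, n = fit$n, nevent = fit$nevent),
            class = "cox_fit")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Risk-score model: %d features, %d patients (%d events)\n",
              length(x$features), length(x$scores), sum(x$event)))
  print(x$fit)
  cat(sprintf("Median risk score: %.3f\n", x$median))
  invisible(x)
}

#' @export
summary.risk_model <- function(object, ...) {
  tab <- object$fit$table
  cat("Signature coefficients (hazard ratios on log2 expression):\n")
  print(tab, row.names = FALSE)
  sp <- median_split(object)
  print(sp$km)
  invisible(tab)
}

#' @export
coef.risk_model <- function(object, ...) object$beta

#' Risk scores for new samples
#' @param object a \code{risk_model}.
#' @param newdata samples-by-features log2 matrix (or raw
#'   \code{expression_matrix}).
#' @param ... unused.
#' @export
predict.risk_model <- function(object, newdata, ...) {
  if (inherits(newdata, "expression_matrix")) {
    newdata <- t(log2_values(newdata))
  }
  drop(as.matrix(newdata[, object$features, drop = FALSE]) %*% object$beta)
}

#' Split patients at the median risk score and test survival separation
#'
#' Patients with score strictly above the median are high-risk (ties at the
#' median go to the low-risk group, so group sizes differ by at most one for
#' a unique median); returns the Kaplan-Meier / log-rank comparison.
#'
#' @param model a \code{\link{fit_risk_model}} result.
#' @return list: \code{group} factor, and \code{km} (a
#'   \code{\link{km_logrank}}).
#' @export
median_split <- function(model) {
  stopifnot(inherits(model, "risk_model"))
  scores <- model$scores
  if (length(scores) < 4L) stop("median split needs at least 4 patients")
  if (max(scores) == min(scores)) {
    stop("all risk scores identical: median split undefined")
  }
  grp <- factor(ifelse(scores > model$median, "high", "low"),
                levels = c("low", "high"))
  list(group = grp,
       km = km_logrank(grp, model$time, model$event))
}

#' @export
plot.risk_model <- function(x, ...) {
  sp <- median_split(x)
  plot(sp$km, col = c("steelblue", "firebrick"),
       main = "Median-split survival by risk score", ...)
  invisible(x)
}
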