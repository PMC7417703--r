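# Fitness functions for the GA (SVM classification AUC; Cox time-dependent
# AUC) and the forward-addition final selection over the frequency ranking.

#' Stratified cross-validation folds
#'
#' Fold assignment depends only on the sample order, the stratification key
#' and the seed — never on the feature subset under evaluation — so fitness
#' values of different masks are comparable.
#'
#' @param strata class label (SVM) or event indicator (Cox), one per sample.
#' @param n_folds number of folds (default 3).
#' @param seed fold seed.
#' @return integer fold id per sample.
#' @export
make_folds <- function(strata, n_folds = 3, seed = 1) {
  strata <- as.factor(strata)
  n <- length(strata)
  if (n < n_folds) stop("fewer samples than folds")
  folds <- integer(n)
  with_seed(seed, {
    for (lv in levels(strata)) {
      idx <- which(strata == lv)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

scale_train_test <- function(xtr, xte) {
  n <- nrow(xtr)
  mu <- colMeans(xtr)
  sg <- sqrt(pmax(colSums(xtr * xtr) - n * mu * mu, 0) / (n - 1))
  sg[sg == 0 | !is.finite(sg)] <- 1
  list(train = t((t(xtr) - mu) / sg), test = t((t(xte) - mu) / sg))
}

#' SVM fitness: 3-fold cross-validated classification AUC
#'
#' Builds a closure suitable as a GA fitness function. For a mask, a linear
#' support vector machine (C = 1, balanced class weights) is trained per
#' fold on training-fold-standardized log2 expression; fitness is the mean
#' held-out AUC of the decision values.
#'
#' @param x samples-by-candidates numeric matrix (log2 scale).
#' @param labels two-level factor of class labels.
#' @param folds fold ids from \code{\link{make_folds}} (stratified by
#'   label); if a fold misses a class, folds are redrawn once.
#' @param cost SVM cost parameter.
#' @return function(mask) -> AUC in \[0, 1\].
#' @export
svm_fitness <- function(x, labels, folds, cost = 1) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  folds <- check_folds(folds, labels)
  cw <- length(labels) / (2 * table(labels))
  names(cw) <- levels(labels)
  function(mask) {
    if (!any(mask)) stop("empty mask")
    xm <- x[, mask, drop = FALSE]
    aucs <- vapply(sort(unique(folds)), function(f) {
      tr <- folds != f
      sc <- scale_train_test(xm[tr, , drop = FALSE], xm[!tr, , drop = FALSE])
      m <- e1071::svm(sc$train, labels[tr], kernel = "linear", cost = cost,
                      class.weights = cw, scale = FALSE, fitted = FALSE,
                      tolerance = 0.01)
      # decision value of a linear SVM, computed directly from the support
      # vectors; positive margin corresponds to the first internal label
      dv <- drop(sc$test %*% drop(crossprod(m$coefs, m$SV))) - m$rho
      pos <- m$levels[m$labels[1]]
      auc_rank(dv, labels[!tr] == pos)
    }, numeric(1))
    mean(aucs)
  }
}

check_folds <- function(folds, strata) {
  for (f in unique(folds)) {
    held <- strata[folds == f]
    if (length(unique(held)) < length(unique(strata))) {
      stop("a fold is missing a stratum; regenerate folds with another seed")
    }
  }
  folds
}

#' Cox fitness: 3-fold cross-validated time-dependent AUC at a horizon
#'
#' For a mask, a multivariable Cox model is fitted on each training fold
#' over the masked log2 expression; the held-out risk scores (sum of beta_i
#' X_i) are evaluated with the time-dependent ROC AUC at the horizon, and
#' the fold mean is returned. Non-convergent fits score 0. The KM variant
#' of the ROC estimator is the default here: held-out folds are small and
#' the nearest-neighbour span is unstable at that size.
#'
#' @param x samples-by-candidates numeric matrix (log2 scale).
#' @param time,event survival outcome of the same samples.
#' @param folds fold ids (stratify by event indicator).
#' @param horizon evaluation time in months (default 60 = 5 years).
#' @param roc_method passed to \code{\link{td_roc}}.
#' @return function(mask) -> AUC in \[0, 1\].
#' @export
cox_fitness <- function(x, time, event, folds, horizon = 60,
                        roc_method = "KM") {
  validate_survival(time, event, nrow(x))
  if (horizon > max(time)) {
    stop("horizon lies beyond the last observed time")
  }
  folds <- check_folds(folds, event)
  function(mask) {
    if (!any(mask)) stop("empty mask")
    xm <- x[, mask, drop = FALSE]
    aucs <- vapply(sort(unique(folds)), function(f) {
      tr <- folds != f
      fit <- fast_cox(xm[tr, , drop = FALSE], time[tr], event[tr])
      if (is.null(fit)) return(NA_real_)
      sc <- drop(xm[!tr, , drop = FALSE] %*% fit$coefficients)
      tryCatch(
        td_roc(sc, time[!tr], event[!tr], horizon,
               method = roc_method)$auc,
        error = function(e) NA_real_
      )
    }, numeric(1))
    if (all(is.na(aucs))) return(0)
    mean(aucs, na.rm = TRUE)
  }
}

#' Forward-addition selection along a frequency ranking
#'
#' Evaluates prefixes of the ranked feature list with a subset-level fitness
#' function; the chosen subset is the prefix with maximum cross-validated
#' AUC (first occurrence wins ties).
#'
#' @param ranked character vector of features, best-ranked first.
#' @param candidates full candidate vector the fitness masks refer to.
#' @param fitness_fn function(mask) -> AUC (typically a fresh-fold
#'   \code{\link{svm_fitness}} or \code{\link{cox_fitness}} closure).
#' @param max_k longest prefix to evaluate (default: the whole ranking).
#' @return a \code{selection_result}: the ranking, the AUC-vs-k curve, the
#'   chosen subset and its AUC.
#' @export
forward_select <- function(ranked, candidates, fitness_fn, max_k = NULL) {
  if (length(ranked) == 0L) stop("ranked feature list is empty")
  if (!all(ranked %in% candidates)) {
    stop("ranked features must be among the candidates")
  }
  K <- if (is.null(max_k)) length(ranked) else min(max_k, length(ranked))
  auc <- numeric(K)
  for (k in seq_len(K)) {
    mask <- candidates %in% ranked[seq_len(k)]
    auc[k] <- fitness_fn(mask)
  }
  chosen_k <- which.max(auc)
  structure(list(
    ranked = ranked,
    auc_curve = data.frame(k = seq_len(K), auc = auc),
    chosen_k = chosen_k,
    chosen = ranked[seq_len(chosen_k)],
    chosen_auc = auc[chosen_k]
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "Forward selection over %d ranked features: chose k=%d (AUC %.3f)\n",
    length(x$ranked), x$chosen_k, x$chosen_auc))
  cat("  chosen:", paste(x$chosen, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.selection_result <- function(x, xlab = "Subset size k",
                                  ylab = "Cross-validated AUC", ...) {
  plot(x$auc_curve$k, x$auc_curve$auc, type = "b", xlab = xlab, ylab = ylab,
       ...)
  graphics::abline(v = x$chosen_k, lty = 3)
  invisible(x)
}

#' GA wrapper feature selection (GA-SVM or GA-Cox), end to end
#'
#' Runs the full chain: evolve masks under the requested fitness, extract
#' the top subsets, rank features by frequency across them, then
#' forward-select along the ranking with a fresh set of folds. All
#' randomness derives from \code{seed}.
#'
#' @param x samples-by-candidates matrix of log2 expression.
#' @param candidates candidate feature ids (columns of \code{x}).
#' @param type "svm" (binary labels) or "cox" (survival).
#' @param labels two-level factor, required for type "svm".
#' @param time,event survival outcome, required for type "cox".
#' @param horizon months, Cox fitness horizon (default 60).
#' @param params \code{\link{ga_params}}.
#' @param top_k number of top subsets for the frequency consensus
#'   (default 50).
#' @param max_k longest forward-selection prefix (default: all ranked).
#' @param seed master seed; folds, GA and selection folds are derived from
#'   it.
#' @param n_folds folds for the cross-validated fitness (default 3).
#' @return a \code{ga_selection}: the \code{ga_run}, frequency ranking and
#'   \code{selection_result}.
#' @export
ga_select <- function(x, candidates = colnames(x),
                      type = c("svm", "cox"), labels = NULL,
                      time = NULL, event = NULL, horizon = 60,
                      params = ga_params(), top_k = 50, max_k = NULL,
                      seed = 1, n_folds = 3) {
  type <- match.arg(type)
  stopifnot(ncol(x) == length(candidates))
  colnames(x) <- candidates
  strat <- if (type == "svm") labels else event
  folds_ga <- make_folds(strat, n_folds, seed = child_seed(seed, 1))
  folds_fs <- make_folds(strat, n_folds, seed = child_seed(seed, 3))
  if (type == "svm") {
    if (is.null(labels)) stop("type 'svm' needs labels")
    fit_ga <- svm_fitness(x, labels, folds_ga)
    fit_fs <- svm_fitness(x, labels, folds_fs)
  } else {
    if (is.null(time) || is.null(event)) stop("type 'cox' needs survival")
    fit_ga <- cox_fitness(x, time, event, folds_ga, horizon = horizon)
    fit_fs <- cox_fitness(x, time, event, folds_fs, horizon = horizon)
  }
  run <- ga_evolve(candidates, fit_ga, params = params,
                   seed = child_seed(seed, 2))
  top <- ga_top_sets(run, k = top_k)
  ranking <- ga_frequency_rank(top)
  sel <- forward_select(ranking$feature, candidates, fit_fs, max_k = max_k)
  structure(list(run = run, ranking = ranking, selection = sel,
                 type = type, seed = seed),
            class = "ga_selection")
}

#' @export
print.ga_selection <- function(x, ...) {
  cat(sprintf("GA-%s selection (seed %s)\n", toupper(x$type), x$seed))
  print(x$run)
  print(x$selection)
  invisible(x)
}
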