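# Expression container, log transform and the four-criterion site filter.

#' Construct an expression matrix container
#'
#' A features-by-samples matrix of non-negative values with an explicit
#' scale flag, so the log2(x+1) transform is applied exactly once, and a
#' modality label (gene / miRNA / lncRNA).
#'
#' @param values numeric matrix, rows = features, columns = samples, with
#'   dimnames set.
#' @param scale "raw" or "log2".
#' @param modality one of "gene", "miRNA", "lncRNA".
#' @export
expression_matrix <- function(values, scale = c("raw", "log2"),
                              modality = c("gene", "miRNA", "lncRNA")) {
  scale <- match.arg(scale)
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs feature and sample ids as dimnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(values < 0)) stop("expression values must be non-negative")
  structure(list(values = values, scale = scale, modality = modality),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix (%s, %s scale): %d features x %d samples\n",
              x$modality, x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Apply the log2(x + 1) transform once
#'
#' @param matrix an \code{\link{expression_matrix}} on the raw scale.
#' @return the matrix on the log2 scale; refuses to transform twice.
#' @export
log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale == "log2") {
    stop("matrix is already log2(x+1)-transformed; refusing to transform twice")
  }
  matrix$values <- log2p1(matrix$values)
  matrix$scale <- "log2"
  matrix
}

# log2 view regardless of stored scale (raw kept for call rate / FC)
log2_values <- function(matrix) {
  if (matrix$scale == "log2") matrix$values else log2p1(matrix$values)
}

#' Four-criterion site-specific biomarker filter
#'
#' For every feature, computed within one anatomic site: (a) call rate —
#' fraction of that site's samples (tumour and normal jointly) with raw
#' value > 0 — must exceed \code{call_rate}; (b) |log2 fold change| of raw
#' tumour mean over raw normal mean must exceed \code{log2fc}; (c) two-sided
#' t test on log2(x+1) values, tumour vs normal, p below \code{p_t}; (d)
#' univariate Cox p of the log2(x+1) value among the site's tumour samples
#' below \code{p_cox}. All inequalities strict. A feature passes overall iff
#' it passes all four.
#'
#' @param matrix raw-scale \code{\link{expression_matrix}}.
#' @param samples sample table with sample_id, tissue, site, time, event.
#' @param site site to filter within.
#' @param call_rate,log2fc,p_t,p_cox thresholds (defaults 0.70, 1, 0.05,
#'   0.05).
#' @param welch use the unequal-variance t test (default TRUE; groups are
#'   typically very unbalanced).
#' @param fc_on_log compute fold change on log2 means instead of raw means
#'   (default FALSE: raw means, matching FPKM-scale reporting).
#' @return a \code{filter_report} data frame: per-feature call rate, fold
#'   change, log2 FC, t and Cox p-values, per-criterion flags and overall
#'   pass.
#' @export
filter_features <- function(matrix, samples, site,
                            call_rate = 0.70, log2fc = 1,
                            p_t = 0.05, p_cox = 0.05,
                            welch = TRUE, fc_on_log = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (matrix$scale != "raw") {
    stop("filter_features needs the raw-scale matrix (call rate and fold change are raw-scale quantities)")
  }
  keep <- samples$site == site & samples$sample_id %in% colnames(matrix$values)
  ss <- samples[keep, , drop = FALSE]
  if (!any(ss$tissue == "tumour") || !any(ss$tissue == "normal")) {
    stop(sprintf("site '%s' needs both tumour and normal samples", site))
  }
  tum <- ss$sample_id[ss$tissue == "tumour"]
  nor <- ss$sample_id[ss$tissue == "normal"]
  surv <- ss[ss$tissue == "tumour", c("sample_id", "time", "event")]
  if (any(is.na(surv$time)) || any(is.na(surv$event))) {
    stop("tumour samples must carry survival records")
  }
  if (sum(surv$event) < 1) {
    stop(sprintf("site '%s' has no events: univariate Cox criterion undefined",
                 site))
  }
  raw <- matrix$values[, c(tum, nor), drop = FALSE]
  lg <- log2p1(raw)
  n_feat <- nrow(raw)
  tum_i <- seq_along(tum)
  nor_i <- length(tum) + seq_along(nor)

  cr <- rowMeans(raw > 0)
  mean_t <- rowMeans(raw[, tum_i, drop = FALSE])
  mean_n <- rowMeans(raw[, nor_i, drop = FALSE])
  if (fc_on_log) {
    fc <- 2^(rowMeans(lg[, tum_i, drop = FALSE]) -
               rowMeans(lg[, nor_i, drop = FALSE]))
  } else {
    fc <- mean_t / mean_n
  }
  l2fc <- log2(fc)

  t_p <- vapply(seq_len(n_feat), function(i) {
    xt <- lg[i, tum_i]; xn <- lg[i, nor_i]
    if (sd(xt) == 0 && sd(xn) == 0) return(1)
    tryCatch(t.test(xt, xn, var.equal = !welch)$p.value,
             error = function(e) 1)
  }, numeric(1))

  xs <- lg[, surv$sample_id, drop = FALSE]
  cox_p <- vapply(seq_len(n_feat), function(i) {
    f <- fast_cox(cbind(xs[i, ]), surv$time, surv$event)
    if (is.null(f)) return(1)
    se <- sqrt(diag(f$var))
    2 * pnorm(-abs(f$coefficients / se))
  }, numeric(1))

  pass_cr <- cr > call_rate
  pass_fc <- !is.na(l2fc) & abs(l2fc) > log2fc  # Inf FC passes, flagged below
  pass_t <- t_p < p_t
  pass_cox <- cox_p < p_cox
  rep <- data.frame(
    feature = rownames(raw), call_rate = cr,
    mean_tumour = mean_t, mean_normal = mean_n,
    fc = fc, log2fc = l2fc, t_p = t_p, cox_p = cox_p,
    pass_call_rate = pass_cr, pass_fc = pass_fc, pass_t = pass_t,
    pass_cox = pass_cox,
    pass = pass_cr & pass_fc & pass_t & pass_cox,
    fc_infinite = is.infinite(fc),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(rep, "site") <- site
  attr(rep, "thresholds") <- c(call_rate = call_rate, log2fc = log2fc,
                               p_t = p_t, p_cox = p_cox)
  class(rep) <- c("filter_report", "data.frame")
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "Filter report, site '%s': %d/%d features pass all four criteria\n",
    attr(x, "site"), sum(x$pass), nrow(x)))
  cat(sprintf("  call rate > %.2f: %d | |log2FC| > %g: %d | t p < %g: %d | Cox p < %g: %d\n",
              th["call_rate"], sum(x$pass_call_rate), th["log2fc"],
              sum(x$pass_fc), th["p_t"], sum(x$pass_t), th["p_cox"],
              sum(x$pass_cox)))
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a \code{filter_report}.
#' @param path output file.
#' @export
write_filter_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
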