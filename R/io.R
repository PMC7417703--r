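# TSV readers/writers and the end-to-end site pipeline.

#' Read an expression TSV (rows = features, columns = samples)
#'
#' First column holds feature ids, header row holds sample ids. Values must
#' parse as non-negative numbers (scientific notation accepted); duplicate
#' ids or negative values are errors.
#'
#' @param path TSV file.
#' @param scale scale of the stored values ("raw" default).
#' @param modality modality label.
#' @export
read_expression <- function(path, scale = "raw", modality = "gene") {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a feature column and at least one sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature id: ", ids[duplicated(ids)][1])
  }
  sids <- colnames(df)[-1]
  if (anyDuplicated(sids)) {
    stop("duplicate sample column: ", sids[duplicated(sids)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 1,
                                              as.numeric)))[1])
    stop("malformed numeric value near data line ", bad)
  }
  if (anyNA(m)) {
    stop("malformed/missing value at data line ",
         which(rowSums(is.na(m)) > 0)[1])
  }
  rownames(m) <- ids
  expression_matrix(m, scale = scale, modality = modality)
}

#' Write an expression matrix to TSV
#' @param matrix an \code{\link{expression_matrix}}.
#' @param path output file.
#' @export
write_expression <- function(matrix, path) {
  v <- matrix$values
  # 17 significant digits: doubles survive the text round trip bit-exactly
  fm <- matrix(formatC(v, digits = 17, format = "g"), nrow = nrow(v),
               dimnames = dimnames(v))
  df <- data.frame(feature_id = rownames(v), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation TSV
#'
#' Expects columns sample_id, tissue (tumour/normal), site, time, event plus
#' any clinical covariates. Tumour rows must carry positive survival times
#' and a 0/1 event flag.
#'
#' @param path TSV file.
#' @export
read_samples <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "site", "time", "event")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("sample TSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id: ", df$sample_id[duplicated(df$sample_id)][1])
  }
  if (!all(df$tissue %in% c("tumour", "normal"))) {
    stop("tissue must be 'tumour' or 'normal'")
  }
  tum <- df$tissue == "tumour"
  if (any(is.na(df$time[tum])) || any(df$time[tum] <= 0) ||
      !all(df$event[tum] %in% c(0, 1))) {
    stop("tumour samples need time > 0 and event in {0,1}")
  }
  df
}

#' Pipeline configuration
#'
#' @param site site to analyse.
#' @param call_rate,log2fc,p_t,p_cox filter thresholds.
#' @param ga \code{\link{ga_params}} for both GA stages.
#' @param top_k top subsets for the frequency consensus.
#' @param max_k forward-selection cap.
#' @param horizon risk-model evaluation horizon (months).
#' @param calib_horizon calibration / decision-curve horizon (months).
#' @param clinical_covariates columns of the sample table used as clinical
#'   covariates.
#' @param max_candidates cap on filter survivors fed to the GA (best by
#'   univariate Cox p); keeps the search space commensurate with the
#'   evidence.
#' @param B bootstrap resamples (ROC comparison, C-index).
#' @param seed master seed; all stage seeds derive from it.
#' @export
pipeline_config <- function(site = "cardia", call_rate = 0.70, log2fc = 1,
                            p_t = 0.05, p_cox = 0.05,
                            ga = ga_params(generations = 200,
                                           pop_size = 100),
                            top_k = 50, max_k = 30, horizon = 60,
                            calib_horizon = 36,
                            clinical_covariates = c("neoplasm_status",
                                                    "residual_tumour",
                                                    "radiation", "stage"),
                            max_candidates = 200, B = 1000, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the site-specific discovery pipeline end to end
#'
#' Filter -> GA-Cox prognostic selection over the filter survivors -> risk
#' model with median-split survival -> stepwise clinical model -> combined
#' model with ROC comparison -> nomogram with optimism-corrected C-index,
#' calibration and decision curve. Only the given site's samples are ever
#' touched. One seed drives every stochastic stage.
#'
#' @param expression raw-scale \code{\link{expression_matrix}} (or a list of
#'   them, one per modality, pooled after filtering).
#' @param samples sample table (see \code{\link{read_samples}}).
#' @param config a \code{\link{pipeline_config}}.
#' @return a \code{site_result} bundle.
#' @export
run_pipeline <- function(expression, samples, config = pipeline_config()) {
  if (inherits(expression, "expression_matrix")) {
    expression <- list(expression)
  }
  site <- config$site
  stage <- "filter"
  result <- list(site = site, config = config)
  out <- tryCatch({
    reports <- lapply(expression, function(em) {
      filter_features(em, samples, site, call_rate = config$call_rate,
                      log2fc = config$log2fc, p_t = config$p_t,
                      p_cox = config$p_cox)
    })
    result$filter <- reports
    candidates <- unlist(lapply(reports, function(r) r$feature[r$pass]))
    if (length(candidates) == 0L) {
      stop("no feature passed the four filter criteria; pipeline stopped after filtering")
    }
    # pooled log2 matrix over the site's tumour samples
    ss <- samples[samples$site == site & samples$tissue == "tumour", ]
    lg <- do.call(rbind, lapply(expression, function(em) {
      log2_values(em)[intersect(rownames(em$values), candidates),
                      ss$sample_id, drop = FALSE]
    }))
    if (length(candidates) > config$max_candidates) {
      rep_all <- do.call(rbind, lapply(reports, as.data.frame))
      rep_all <- rep_all[rep_all$feature %in% candidates, ]
      keep <- rep_all$feature[order(rep_all$cox_p)][
        seq_len(config$max_candidates)]
      candidates <- candidates[candidates %in% keep]
      lg <- lg[candidates, , drop = FALSE]
    }
    x <- t(lg)

    stage <- "ga_cox"
    gasel <- ga_select(x, candidates, type = "cox",
                       time = ss$time, event = ss$event,
                       horizon = config$horizon, params = config$ga,
                       top_k = config$top_k, max_k = config$max_k,
                       seed = child_seed(config$seed, 21))
    result$ga_cox <- gasel

    stage <- "risk_model"
    rm <- fit_risk_model(x, gasel$selection$chosen, ss$time, ss$event)
    result$risk_model <- rm
    result$median_split <- median_split(rm)

    stage <- "models"
    clin <- ss[, intersect(config$clinical_covariates, colnames(ss)),
               drop = FALSE]
    models <- build_models(clin, rm, horizon = config$horizon, B = config$B,
                           seed = child_seed(config$seed, 22))
    result$models <- models

    stage <- "nomogram"
    nomo <- build_nomogram(models$combined, models$combined_data,
                           horizon = config$horizon)
    result$nomogram <- nomo
    pred <- predict(nomo, models$combined_data)
    result$nomogram_roundtrip_max_error <- max(abs(
      pred$survival - survival_at(models$combined, models$combined_data,
                                  config$horizon)))

    stage <- "evaluation"
    dat_c <- cbind(models$combined_data, time = ss$time, event = ss$event)
    result$cindex <- bootstrap_cindex(
      dat_c,
      fit_fun = function(d) cox_fit(d[setdiff(names(d), c("time", "event"))],
                                    d$time, d$event),
      score_fun = function(m, d) predict(m, d),
      B = config$B, seed = child_seed(config$seed, 23))
    surv_pred <- survival_at(models$combined, models$combined_data,
                             config$calib_horizon)
    surv_pred <- pmin(pmax(surv_pred, 1e-12), 1 - 1e-12)
    result$calibration <- calibrate(surv_pred, ss$time, ss$event,
                                    horizon = config$calib_horizon,
                                    B = config$B,
                                    seed = child_seed(config$seed, 24))
    result$decision <- decision_curve(1 - surv_pred, ss$time, ss$event,
                                      horizon = config$calib_horizon)
    result$manifest <- list(
      package_version = as.character(utils::packageVersion("sitesig")),
      seed = config$seed, site = site,
      n_tumour = nrow(ss), n_candidates = length(candidates),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    )
    structure(result, class = "site_result")
  }, error = function(e) {
    e$message <- sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e))
    stop(e)
  })
  out
}

#' @export
print.site_result <- function(x, ...) {
  cat(sprintf("Site '%s' pipeline result\n", x$site))
  for (r in x$filter) print(r)
  cat(sprintf("GA-Cox signature (%d features): %s\n",
              length(x$risk_model$features),
              paste(x$risk_model$features, collapse = ", ")))
  print(x$median_split$km)
  print(x$models)
  cat(sprintf("C-index: apparent %.3f, adjusted %.3f (95%% CI %.3f-%.3f)\n",
              x$cindex$apparent, x$cindex$adjusted, x$cindex$ci[1],
              x$cindex$ci[2]))
  invisible(x)
}

#' Write the main pipeline artifacts to a directory
#' @param result a \code{site_result}.
#' @param dir output directory.
#' @export
write_site_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(result$filter)) {
    write_filter_report(result$filter[[i]],
                        file.path(dir, sprintf("filter_%d.tsv", i)))
  }
  write_ga_run(result$ga_cox$run, file.path(dir, "ga_cox_run.json"))
  jsonlite::write_json(list(
    signature = result$risk_model$features,
    beta = as.list(result$risk_model$beta),
    median_score = result$risk_model$median,
    logrank_p = result$median_split$km$p,
    auc = result$models$auc_table,
    compare_p = result$models$compare_p,
    cindex = result$cindex[c("apparent", "adjusted")],
    manifest = result$manifest
  ), file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  write.table(as.data.frame(result$calibration),
              file.path(dir, "calibration.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(result$decision),
              file.path(dir, "decision_curve.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
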