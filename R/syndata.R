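# Seeded synthetic transcriptomic + survival data with planted effects.
#
# Expression mimics FPKM: skewed log-normal values with a point mass at zero.
# A subset of features is differentially expressed between tumour and normal
# tissue; a subset of those also carries a planted log-hazard on survival.

#' Simulation configuration
#'
#' Defines one site's cohort. Defaults mirror a TCGA-like stomach cohort:
#' many more tumours than normals, FPKM-scale skew with a zero mass, a
#' handful of planted differential and prognostic features, months as the
#' time unit and "5-year survival" meaning 60 months.
#'
#' @param n_tumour,n_normal sample counts.
#' @param n_features number of features in the modality.
#' @param n_de number of planted differential features.
#' @param de_start index of the first planted feature (default 1), so two
#'   simulated sites can carry distinct differential sets.
#' @param n_prog number of planted prognostic features (a subset of the
#'   differential ones).
#' @param log2fc_de planted mean log2 fold change (tumour vs normal).
#' @param beta_prog Cox log-hazard coefficients of the planted prognostic
#'   features (length \code{n_prog}); applied to centred, unit-scaled
#'   log2(x+1) expression.
#' @param zero_inflation probability that any value is zeroed.
#' @param baseline_hazard events per month for a patient at average risk.
#' @param censor_rate rate of the independent exponential censoring time.
#' @param admin_censor_time administrative censoring cap (months).
#' @param beta_clinical named log-hazards for the clinical covariates
#'   (neoplasm_status, residual_tumour, radiation, stage per-level trend).
#' @param site label attached to the generated samples.
#' @param modality expression modality label.
#' @param seed RNG seed.
#' @export
sim_config <- function(n_tumour = 150, n_normal = 32, n_features = 1000,
                       n_de = 20, de_start = 1, n_prog = 5, log2fc_de = 2,
                       beta_prog = rep(0.8, n_prog), zero_inflation = 0.1,
                       baseline_hazard = 0.005, censor_rate = 0.015,
                       admin_censor_time = 120,
                       beta_clinical = c(neoplasm_status = 1.0,
                                         residual_tumour = 1.2,
                                         radiation = -0.8, stage = 0.45),
                       site = "cardia", modality = "gene", seed = 1) {
  cfg <- list(n_tumour = n_tumour, n_normal = n_normal,
              n_features = n_features, n_de = n_de, de_start = de_start,
              n_prog = n_prog,
              log2fc_de = log2fc_de, beta_prog = beta_prog,
              zero_inflation = zero_inflation,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              admin_censor_time = admin_censor_time,
              beta_clinical = beta_clinical, site = site,
              modality = modality, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(n_tumour = cfg$n_tumour, n_normal = cfg$n_normal,
              n_features = cfg$n_features)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop_config("sample and feature counts must be positive integers")
  }
  if (cfg$n_de < 0 || cfg$n_prog < 0 || cfg$n_prog > cfg$n_de ||
      cfg$n_de > cfg$n_features) {
    stop_config("need 0 <= n_prog <= n_de <= n_features")
  }
  if (is.null(cfg$de_start) || cfg$de_start < 1 ||
      cfg$de_start + max(cfg$n_de - 1, 0) > cfg$n_features) {
    stop_config("planted features must fit inside the feature range")
  }
  if (cfg$zero_inflation < 0 || cfg$zero_inflation > 1) {
    stop_config("zero_inflation must be a probability")
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1) {
    stop_config("censor_rate must be in [0,1]")
  }
  if (cfg$baseline_hazard <= 0) stop_config("baseline_hazard must be > 0")
  if (length(cfg$beta_prog) != cfg$n_prog) {
    stop_config("beta_prog must have length n_prog")
  }
  invisible(TRUE)
}

#' Generate one site's synthetic dataset
#'
#' Non-differential features are drawn i.i.d. log-normal(meanlog=1, sdlog=1)
#' on the raw scale for tumour and normal alike; planted differential
#' features have the tumour meanlog shifted by \code{log2fc_de * log(2)}, so
#' their population log2 fold change equals \code{log2fc_de}. Each value is
#' then independently zeroed with probability \code{zero_inflation}. Tumour
#' samples receive event times from an exponential law with hazard
#' \code{baseline_hazard * exp(sum(beta_j * z_j) + clinical terms)}, z being
#' centred unit-scaled log2(x+1) expression of the planted prognostic
#' features; censoring is the minimum of an independent exponential time and
#' the administrative cap.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{synthetic_dataset}: raw-scale \code{expression_matrix},
#'   sample table (tumour rows carry time/event and clinical covariates),
#'   and the planted truth.
#' @export
simulate_site_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, {
    p <- config$n_features
    nt <- config$n_tumour
    nn <- config$n_normal
    feat_ids <- sprintf("%s_%04d", toupper(config$modality), seq_len(p))
    samp_ids <- c(sprintf("%s_T%03d", config$site, seq_len(nt)),
                  sprintf("%s_N%03d", config$site, seq_len(nn)))
    tissue <- rep(c("tumour", "normal"), c(nt, nn))

    de_idx <- if (config$n_de > 0) {
      seq(config$de_start, length.out = config$n_de)
    } else integer(0)
    prog_idx <- de_idx[seq_len(config$n_prog)]

    meanlog <- matrix(1, nrow = p, ncol = nt + nn)
    if (length(de_idx)) {
      meanlog[de_idx, tissue == "tumour"] <- 1 + config$log2fc_de * log(2)
    }
    vals <- matrix(rlnorm(p * (nt + nn), meanlog = as.vector(meanlog),
                          sdlog = 1), nrow = p)
    if (config$zero_inflation > 0) {
      drop_mask <- matrix(runif(p * (nt + nn)) < config$zero_inflation,
                          nrow = p)
      vals[drop_mask] <- 0
    }
    dimnames(vals) <- list(feat_ids, samp_ids)
    expr <- expression_matrix(vals, scale = "raw",
                              modality = config$modality)

    samples <- data.frame(
      sample_id = samp_ids, tissue = tissue,
      site = config$site, stringsAsFactors = FALSE
    )
    # clinical covariates for tumour samples
    is_t <- samples$tissue == "tumour"
    samples$neoplasm_status <- NA_real_
    samples$residual_tumour <- NA_real_
    samples$radiation <- NA_real_
    samples$stage <- NA_real_
    samples$neoplasm_status[is_t] <- rbinom(nt, 1, 0.3)
    samples$residual_tumour[is_t] <- rbinom(nt, 1, 0.15)
    samples$radiation[is_t] <- rbinom(nt, 1, 0.35)
    samples$stage[is_t] <- sample(1:4, nt, replace = TRUE,
                                  prob = c(0.15, 0.3, 0.4, 0.15))
    samples$time <- NA_real_
    samples$event <- NA_real_

    truth <- list(de_features = feat_ids[de_idx],
                  prog_features = feat_ids[prog_idx],
                  log2fc_de = config$log2fc_de,
                  beta_prog = setNames(config$beta_prog,
                                       feat_ids[prog_idx]))

    ds <- structure(list(expression = expr, samples = samples,
                         truth = truth, config = config),
                    class = "synthetic_dataset")
    ds$samples <- simulate_survival(ds, config)
    ds
  })
}

#' Draw survival outcomes for the tumour samples of a dataset
#'
#' Exponential event times under a proportional-hazards model on the planted
#' prognostic features (and clinical covariates), censored by an independent
#' exponential time capped administratively. Exposed separately so survival
#' can be re-drawn on a fixed expression matrix.
#'
#' @param dataset a \code{synthetic_dataset} (expression + samples present).
#' @param config its \code{\link{sim_config}}.
#' @return the sample table with \code{time}/\code{event} filled in for
#'   tumour rows.
#' @export
simulate_survival <- function(dataset, config) {
  samples <- dataset$samples
  is_t <- samples$tissue == "tumour"
  nt <- sum(is_t)
  if (nt == 0L) stop("no tumour samples to assign survival to")
  prog <- dataset$truth$prog_features
  if (length(prog) > 0 &&
      !all(prog %in% rownames(dataset$expression$values))) {
    stop("planted prognostic feature missing from the expression matrix")
  }
  lp <- rep(0, nt)
  if (length(prog) > 0) {
    xs <- log2p1(dataset$expression$values[prog,
                                           samples$sample_id[is_t],
                                           drop = FALSE])
    z <- t(scale(t(xs)))  # centre and unit-scale each feature across patients
    z[!is.finite(z)] <- 0
    lp <- lp + drop(crossprod(z, dataset$truth$beta_prog[prog]))
  }
  bc <- config$beta_clinical
  clin <- cbind(neoplasm_status = samples$neoplasm_status[is_t],
                residual_tumour = samples$residual_tumour[is_t],
                radiation = samples$radiation[is_t],
                stage = samples$stage[is_t] - 1)
  lp <- lp + drop(clin %*% bc[colnames(clin)])

  hazard <- config$baseline_hazard * exp(lp)
  t_event <- rexp(nt, rate = hazard)
  t_cens <- if (config$censor_rate > 0) {
    rexp(nt, rate = config$censor_rate)
  } else rep(Inf, nt)
  t_cens <- pmin(t_cens, config$admin_censor_time)
  samples$time[is_t] <- pmin(t_event, t_cens)
  samples$event[is_t] <- as.numeric(t_event <= t_cens)
  samples
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic %s dataset (%s): %d features x %d samples (%d tumour/%d normal)\n",
    x$config$modality, x$config$site, nrow(x$expression$values),
    ncol(x$expression$values), x$config$n_tumour, x$config$n_normal))
  cat(sprintf("  planted: %d differential (log2FC %.1f), %d prognostic\n",
              x$config$n_de, x$config$log2fc_de, x$config$n_prog))
  tt <- x$samples[x$samples$tissue == "tumour", ]
  cat(sprintf("  tumour survival: %d events / %d patients, median follow-up %.0f months\n",
              sum(tt$event), nrow(tt), median(tt$time)))
  invisible(x)
}

#' Generate a two-site study (independent truth per site)
#'
#' @param config_cardia,config_noncardia per-site configurations; sites are
#'   forced to "cardia" and "noncardia".
#' @return list of two \code{synthetic_dataset}s, one per site.
#' @export
simulate_study <- function(config_cardia = sim_config(site = "cardia"),
                           config_noncardia = sim_config(site = "noncardia",
                                                         seed = 2)) {
  config_cardia$site <- "cardia"
  config_noncardia$site <- "noncardia"
  list(cardia = simulate_site_data(config_cardia),
       noncardia = simulate_site_data(config_noncardia))
}

#' Write a synthetic dataset to TSV (+ truth JSON)
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return invisibly, the written paths.
#' @export
write_dataset <- function(dataset, dir, prefix = "synthetic") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, paste0(prefix, "_expression.tsv")),
    samples = file.path(dir, paste0(prefix, "_samples.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_expression(dataset$expression, paths["expression"])
  write.table(dataset$samples, paths["samples"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
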