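# Shared fixtures and independent oracles, all built in code.

# Small uncensored survival fixture with distinct times.
toy_surv <- function() {
  list(time = c(2, 5, 7, 11, 13), event = c(1, 1, 1, 1, 1),
       score = c(5, 4, 3, 2, 1))
}

# Exhaustive-pair Harrell C (double loop; independent of the package's
# vectorized implementation).
cindex_enumerate <- function(score, time, event) {
  n <- length(score)
  conc <- comp <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    case <- if (time[i] < time[j] && event[i] == 1) TRUE
    else if (time[i] == time[j] && event[i] == 1 && event[j] == 0) TRUE
    else FALSE
    if (!case) next
    comp <- comp + 1
    if (score[i] > score[j]) conc <- conc + 1
    else if (score[i] == score[j]) conc <- conc + 0.5
  }
  conc / comp
}

# Cox partial log-likelihood for a single covariate, no ties (hand-coded).
cox_pll_1d <- function(beta, x, time, event) {
  ord <- order(time)
  x <- x[ord]; event <- event[ord]
  ll <- 0
  for (i in seq_along(x)) {
    if (event[i] == 1) {
      risk <- i:length(x)
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# Hand-computed two-group log-rank chi-square: sum over event times of
# (O1 - E1), variance by the hypergeometric formula.
logrank_by_hand <- function(group, time, event) {
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (u in ut) {
    at_risk <- time >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == levels(factor(group))[1])
    d <- sum(time == u & event == 1)
    d1 <- sum(time == u & event == 1 & group == levels(factor(group))[1])
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Two-class expression data for GA-SVM: two cohorts whose tumours differ in
# the first n_planted features by the planted log2 fold change.
make_twoclass <- function(n_per_class = 150, p = 100, n_planted = 5,
                          seed = 1) {
  ca <- sim_config(n_tumour = n_per_class, n_normal = 8, n_features = p,
                   n_de = n_planted, n_prog = 0, beta_prog = numeric(0),
                   site = "cardia", seed = seed)
  cb <- sim_config(n_tumour = n_per_class, n_normal = 8, n_features = p,
                   n_de = 0, n_prog = 0, beta_prog = numeric(0),
                   site = "noncardia", seed = seed + 5000)
  da <- simulate_site_data(ca)
  db <- simulate_site_data(cb)
  ta <- da$samples$sample_id[da$samples$tissue == "tumour"]
  tb <- db$samples$sample_id[db$samples$tissue == "tumour"]
  x <- rbind(t(log2p1(da$expression$values[, ta])),
             t(log2p1(db$expression$values[, tb])))
  list(x = x,
       labels = factor(rep(c("cardia", "noncardia"),
                           c(length(ta), length(tb)))),
       planted = da$truth$de_features)
}

# Tumour-only prognostic dataset for GA-Cox.
make_prognostic <- function(n = 300, p = 100, n_planted = 5, seed = 1,
                            null = FALSE) {
  cfg <- sim_config(
    n_tumour = n, n_normal = 8, n_features = p,
    n_de = if (null) 0 else n_planted,
    n_prog = if (null) 0 else n_planted,
    beta_prog = if (null) numeric(0) else rep(0.8, n_planted),
    # "null" means no planted effects at all, clinical included
    beta_clinical = if (null) c(neoplasm_status = 0, residual_tumour = 0,
                                radiation = 0, stage = 0) else
      eval(formals(sim_config)$beta_clinical),
    seed = seed)
  ds <- simulate_site_data(cfg)
  ss <- ds$samples[ds$samples$tissue == "tumour", ]
  list(x = t(log2p1(ds$expression$values[, ss$sample_id])),
       time = ss$time, event = ss$event,
       planted = ds$truth$prog_features, samples = ss, dataset = ds)
}

# Construct a 70-sample (40 tumour, 30 normal) toy of 10 features where
# exactly features 1-3 satisfy all four criteria; verify each criterion
# against an independent oracle computed directly from the matrix.
build_filter_toy <- function() {
  set.seed(421)
  nt <- 40; nn <- 30
  base <- function() rlnorm(nt + nn, 1, 0.4)
  v <- matrix(NA_real_, 10, nt + nn)
  tum <- 1:nt; nor <- nt + 1:nn
  for (i in 1:3) {            # pass all four
    v[i, ] <- base()
    v[i, tum] <- v[i, tum] * 4
  }
  v[4, ] <- base()            # null: fails FC and t
  v[5, ] <- base(); v[5, tum] <- v[5, tum] * 4
  v[5, sample(nt + nn, 30)] <- 0   # call rate ~57% -> fails (a)
  v[6, ] <- base() * c(rep(1.9, nt), rep(1, nn))  # FC < 2 -> fails (b)
  v[7, ] <- base(); v[7, tum] <- v[7, tum] * 4    # will break Cox link
  v[8, ] <- base()
  v[9, ] <- base() * c(rep(1.9, nt), rep(1, nn))
  v[10, ] <- base()
  dimnames(v) <- list(sprintf("f%02d", 1:10),
                      sprintf("s%02d", seq_len(nt + nn)))
  # survival driven by features 1-3; f7 is differential but not prognostic
  lp <- scale(colSums(log2p1(v[1:3, tum])))
  set.seed(500)
  time <- rexp(nt, 0.03 * exp(3 * lp))
  samples <- data.frame(
    sample_id = colnames(v),
    tissue = rep(c("tumour", "normal"), c(nt, nn)),
    site = "cardia", time = c(time, rep(NA, nn)),
    event = c(rep(1, nt), rep(NA, nn)))
  list(matrix = expression_matrix(v), samples = samples,
       tum = tum, nor = nor)
}
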