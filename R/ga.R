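# Genetic algorithm over binary feature-inclusion masks with an archive of
# every evaluated subset. Fitness is pluggable (SVM AUC, Cox time-dependent
# AUC, or anything mapping a mask to [0, 1]).

#' GA parameters
#'
#' @param generations number of generations (200 is the headline setting;
#'   smaller values are adequate for small candidate pools).
#' @param pop_size population size.
#' @param crossover_rate probability a mating pair undergoes uniform
#'   crossover.
#' @param mutation_rate per-bit flip probability; default max(1/p, 0.01).
#' @param n_elite elite individuals copied unchanged each generation.
#' @param init_p probability a bit starts set; default min(0.5, 10/p) so
#'   initial subsets are small, matching the small signatures the method
#'   targets.
#' @param tournament_size selection tournament size.
#' @export
ga_params <- function(generations = 200, pop_size = 100,
                      crossover_rate = 0.8, mutation_rate = NULL,
                      n_elite = 1, init_p = NULL, tournament_size = 2) {
  stopifnot(generations >= 1, pop_size >= 2, n_elite >= 0,
            n_elite < pop_size, crossover_rate >= 0, crossover_rate <= 1)
  structure(list(generations = generations, pop_size = pop_size,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, n_elite = n_elite,
                 init_p = init_p, tournament_size = tournament_size),
            class = "ga_params")
}

mask_key <- function(mask) paste(which(mask), collapse = ",")

#' Evolve feature subsets by genetic algorithm
#'
#' Tournament selection, uniform crossover, per-bit mutation, elitism. Every
#' unique mask ever evaluated is archived with its fitness, so the best
#' subsets of the whole run (not just the final generation) can be
#' extracted. A chromosome mutated to all-zero has one uniformly random bit
#' restored; a fitness of NaN/NA is recorded as 0.
#'
#' @param candidates character vector of candidate feature ids (length p >= 2).
#' @param fitness_fn function(mask) -> fitness in \[0, 1\]; mask is a logical
#'   vector over \code{candidates}.
#' @param params a \code{\link{ga_params}}.
#' @param seed RNG seed; the run is fully reproducible given it.
#' @return a \code{ga_run}: archive (list of mask index vectors), fitness
#'   vector, per-generation best-fitness trace, final population.
#' @export
ga_evolve <- function(candidates, fitness_fn, params = ga_params(),
                      seed = 1) {
  p <- length(candidates)
  if (p < 2L) stop("need at least 2 candidate features")
  mut <- if (is.null(params$mutation_rate)) max(1 / p, 0.01) else
    params$mutation_rate
  init_p <- if (is.null(params$init_p)) min(0.5, 10 / p) else params$init_p

  arch_fit <- new.env(parent = emptyenv(), hash = TRUE)
  arch_masks <- list()
  n_nan <- 0L

  evaluate <- function(mask) {
    key <- mask_key(mask)
    hit <- get0(key, envir = arch_fit, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    f <- tryCatch(fitness_fn(mask), error = function(e) NaN)
    if (!is.finite(f)) { f <- 0; n_nan <<- n_nan + 1L }
    assign(key, f, envir = arch_fit)
    arch_masks[[length(arch_masks) + 1L]] <<- which(mask)
    f
  }

  with_seed(seed, {
    pop <- matrix(runif(params$pop_size * p) < init_p,
                  nrow = params$pop_size)
    # repair empty chromosomes
    for (i in which(rowSums(pop) == 0L)) pop[i, sample.int(p, 1)] <- TRUE
    fit <- apply(pop, 1, evaluate)
    best_so_far <- max(fit)
    trace <- numeric(params$generations)
    for (g in seq_len(params$generations)) {
      ord <- order(fit, decreasing = TRUE)
      newpop <- matrix(FALSE, params$pop_size, p)
      k <- 0L
      if (params$n_elite > 0L) {
        elite <- ord[seq_len(params$n_elite)]
        newpop[seq_len(params$n_elite), ] <- pop[elite, , drop = FALSE]
        k <- params$n_elite
      }
      while (k < params$pop_size) {
        pa <- tournament(fit, params$tournament_size)
        pb <- tournament(fit, params$tournament_size)
        c1 <- pop[pa, ]; c2 <- pop[pb, ]
        if (runif(1) < params$crossover_rate) {
          swap <- runif(p) < 0.5
          tmp <- c1[swap]; c1[swap] <- c2[swap]; c2[swap] <- tmp
        }
        for (child in list(c1, c2)) {
          if (k >= params$pop_size) break
          flip <- runif(p) < mut
          child <- xor(child, flip)
          if (!any(child)) child[sample.int(p, 1)] <- TRUE
          k <- k + 1L
          newpop[k, ] <- child
        }
      }
      pop <- newpop
      fit <- apply(pop, 1, evaluate)
      best_so_far <- max(best_so_far, max(fit))
      trace[g] <- best_so_far
    }
    keys <- vapply(arch_masks, function(ix) paste(ix, collapse = ","),
                   character(1))
    structure(list(
      candidates = candidates,
      archive = arch_masks,
      fitness = vapply(keys, function(k) get(k, envir = arch_fit),
                       numeric(1), USE.NAMES = FALSE),
      trace = trace,
      final_population = pop,
      final_fitness = fit,
      params = params, seed = seed, n_nan = n_nan
    ), class = "ga_run")
  })
}

tournament <- function(fit, size) {
  idx <- sample.int(length(fit), size, replace = TRUE)
  idx[which.max(fit[idx])]
}

#' @export
print.ga_run <- function(x, ...) {
  cat(sprintf(
    "GA run: %d candidates, %d generations, population %d\n  archive: %d unique subsets, best fitness %.4f\n",
    length(x$candidates), x$params$generations, x$params$pop_size,
    length(x$archive), max(x$fitness)))
  invisible(x)
}

#' @export
plot.ga_run <- function(x, xlab = "Generation", ylab = "Best fitness", ...) {
  plot(seq_along(x$trace), x$trace, type = "s", xlab = xlab, ylab = ylab,
       ...)
  invisible(x)
}

#' Extract the k best archived subsets
#'
#' @param run a \code{\link{ga_evolve}} result.
#' @param k number of subsets (the consensus step uses 50).
#' @param pool "archive" (default: best unique subsets over the whole run)
#'   or "final" (final generation only).
#' @return list with \code{masks} (list of candidate-index vectors) and
#'   \code{fitness}, sorted by fitness descending. Warns and returns all if
#'   fewer than k are available.
#' @export
ga_top_sets <- function(run, k = 50, pool = c("archive", "final")) {
  pool <- match.arg(pool)
  stopifnot(inherits(run, "ga_run"))
  if (k <= 0) stop("k must be positive")
  if (pool == "archive") {
    masks <- run$archive
    fit <- run$fitness
  } else {
    masks <- lapply(seq_len(nrow(run$final_population)),
                    function(i) which(run$final_population[i, ]))
    keys <- vapply(masks, function(ix) paste(ix, collapse = ","),
                   character(1))
    keep <- !duplicated(keys)
    masks <- masks[keep]
    fit <- run$final_fitness[keep]
  }
  if (length(masks) == 0L) stop("archive is empty")
  if (length(masks) < k) {
    warning(sprintf("only %d unique subsets available (k = %d)",
                    length(masks), k))
    k <- length(masks)
  }
  ord <- order(fit, decreasing = TRUE)[seq_len(k)]
  list(masks = masks[ord], fitness = fit[ord],
       candidates = run$candidates)
}

#' Frequency ranking of features across the top subsets
#'
#' Each feature's frequency is the number of top subsets containing it;
#' features absent from all subsets are dropped. Ties broken by the mean
#' fitness of the containing subsets (descending), then candidate index.
#'
#' @param top result of \code{\link{ga_top_sets}}.
#' @return data frame: feature, candidate index, frequency, mean fitness of
#'   containing subsets, ordered by rank.
#' @export
ga_frequency_rank <- function(top) {
  if (length(top$masks) == 0L) stop("no subsets to rank over")
  p <- length(top$candidates)
  freq <- integer(p)
  fitsum <- numeric(p)
  for (s in seq_along(top$masks)) {
    ix <- top$masks[[s]]
    freq[ix] <- freq[ix] + 1L
    fitsum[ix] <- fitsum[ix] + top$fitness[s]
  }
  keep <- which(freq > 0L)
  mean_fit <- fitsum[keep] / freq[keep]
  ord <- order(-freq[keep], -mean_fit, keep)
  data.frame(
    feature = top$candidates[keep][ord],
    index = keep[ord],
    frequency = freq[keep][ord],
    mean_fitness = mean_fit[ord],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Serialize a GA run to JSON
#' @param run a \code{ga_run}.
#' @param path output file.
#' @export
write_ga_run <- function(run, path) {
  jsonlite::write_json(list(
    candidates = run$candidates,
    subsets = lapply(run$archive, function(ix) run$candidates[ix]),
    fitness = run$fitness,
    trace = run$trace,
    seed = run$seed,
    params = unclass(run$params)
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
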