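#' Risk-map coverage of a station subset
#'
#' Sums the risk scores of every lattice cell whose centre lies within
#' `radius` of at least one selected station; overlapping discs count each
#' cell once.
#'
#' @param selected station ids (rows of `stations`); an empty selection
#'   scores 0 with a warning.
#' @param risk a `risk_map` from [combine_risk()] (any [raster_grid()]
#'   works).
#' @param stations data.frame with columns `id`, `x`, `y`.
#' @param radius coverage radius in metres (default 3000, the siting
#'   assumption for one drone station).
#' @return the covered risk mass (numeric scalar).
#' @export
coverage_score <- function(selected, risk, stations, radius = 3000) {
  if (length(selected) == 0) {
    warning("empty station selection covers nothing")
    return(0)
  }
  sel <- stations[match(selected, stations$id), , drop = FALSE]
  covered <- covered_cells(sel, risk, radius)
  sum(risk$values[covered])
}

# Logical matrix of cells with centre within radius of any station in `sel`.
covered_cells <- function(sel, risk, radius) {
  cc <- cell_centers(risk)
  d <- dim(risk$values)
  covered <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(nrow(sel))) {
    d2 <- outer((cc$y - sel$y[i])^2, (cc$x - sel$x[i])^2, `+`)
    covered <- covered | (d2 <= radius^2)
  }
  covered
}

# Per-candidate coverage masks flattened to cells, for fast GA fitness.
coverage_masks <- function(stations, risk, radius) {
  cc <- cell_centers(risk)
  d <- dim(risk$values)
  gx <- rep(cc$x, each = d[1])
  gy <- rep(cc$y, times = d[2])
  t(vapply(seq_len(nrow(stations)), function(i) {
    (gx - stations$x[i])^2 + (gy - stations$y[i])^2 <= radius^2
  }, logical(length(gx))))
}

#' Genetic-algorithm hyper-parameters
#'
#' @param pop_size population size.
#' @param generations maximum generations.
#' @param tournament tournament size for parent selection.
#' @param mutation_rate per-gene swap-mutation probability.
#' @param stagnation stop after this many generations without improvement.
#' @return a `ga_params` list.
#' @export
ga_params <- function(pop_size = 50, generations = 200, tournament = 3,
                      mutation_rate = 0.1, stagnation = 40) {
  stopifnot(pop_size >= 2, generations >= 1, tournament >= 1,
            mutation_rate >= 0, mutation_rate <= 1, stagnation >= 1)
  structure(list(pop_size = pop_size, generations = generations,
                 tournament = tournament, mutation_rate = mutation_rate,
                 stagnation = stagnation), class = "ga_params")
}

#' Select k drone stations by genetic algorithm
#'
#' Maximizes [coverage_score()] over k-subsets of the candidate stations.
#' Chromosomes are k-subsets; parents are chosen by tournament, combined by
#' uniform crossover with repair back to cardinality k, perturbed by
#' per-gene swap mutation, and the best individual always survives
#' (elitism), so fitness never decreases across generations. Fully
#' reproducible given `seed`.
#'
#' @param stations candidate data.frame (`id`, `x`, `y`).
#' @param k number of stations to select (`1 <= k <= nrow(stations)`).
#' @param risk a `risk_map`.
#' @param radius coverage radius (m).
#' @param seed integer RNG seed for the GA stream.
#' @param params a [ga_params()].
#' @param seed_individuals optional list of id vectors injected into the
#'   initial population (padded/truncated to size k); used by [sweep_k()]
#'   to warm-start from the previous solution.
#' @return an `allocation_result`: list with `k`, `selected` (ids),
#'   `coverage_score`, `ga_seed`, `generations_run`.
#' @export
ga_select <- function(stations, k, risk, radius = 3000, seed = 1L,
                      params = ga_params(), seed_individuals = NULL) {
  n <- nrow(stations)
  if (k > n) stop("k exceeds the number of candidate stations")
  if (k < 1) stop("k must be >= 1")
  masks <- coverage_masks(stations, risk, radius)
  v <- as.vector(risk$values)
  fit <- function(sel) {
    cov <- if (length(sel) == 1) masks[sel, ] else
      colSums(masks[sel, , drop = FALSE]) > 0
    sum(v[cov])
  }
  result <- function(sel, gens) {
    structure(list(k = k, selected = sort(stations$id[sel]),
                   coverage_score = fit(sel), ga_seed = as.integer(seed),
                   generations_run = gens),
              class = "allocation_result")
  }
  if (k == n) return(result(seq_len(n), 0L))

  # sample() on a length-1 integer vector would sample 1:v; index instead
  sample_vec <- function(v, m) v[sample.int(length(v), m)]
  set.seed(as.integer(seed))
  p <- params
  pop <- lapply(seq_len(p$pop_size), function(i) sort(sample.int(n, k)))
  for (j in seq_along(seed_individuals)) {
    idx <- match(seed_individuals[[j]], stations$id)
    idx <- unique(idx[!is.na(idx)])
    if (length(idx) > k) idx <- idx[seq_len(k)]
    if (length(idx) < k) {
      idx <- c(idx, sample_vec(setdiff(seq_len(n), idx), k - length(idx)))
    }
    pop[[min(j, p$pop_size)]] <- sort(idx)
  }
  fitness <- vapply(pop, fit, 0)
  best_i <- which.max(fitness)
  best <- pop[[best_i]]
  best_fit <- fitness[best_i]
  stagnant <- 0L
  gens <- 0L

  tour <- function() {
    cand <- sample.int(p$pop_size, p$tournament, replace = TRUE)
    pop[[cand[which.max(fitness[cand])]]]
  }
  for (g in seq_len(p$generations)) {
    gens <- g
    newpop <- vector("list", p$pop_size)
    newpop[[1]] <- best                       # elitism
    for (i in 2:p$pop_size) {
      p1 <- tour(); p2 <- tour()
      core <- intersect(p1, p2)
      pool <- setdiff(union(p1, p2), core)
      child <- c(core, if (length(pool))
        sample_vec(pool, min(k - length(core), length(pool))))
      if (length(child) < k) {
        child <- c(child, sample_vec(setdiff(seq_len(n), child),
                                     k - length(child)))
      }
      mut <- which(stats::runif(k) < p$mutation_rate)
      for (m in mut) {
        repl <- setdiff(seq_len(n), child)
        if (length(repl)) child[m] <- sample_vec(repl, 1)
      }
      newpop[[i]] <- sort(child)
    }
    pop <- newpop
    fitness <- vapply(pop, fit, 0)
    gen_best <- which.max(fitness)
    if (fitness[gen_best] > best_fit) {
      best_fit <- fitness[gen_best]
      best <- pop[[gen_best]]
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= p$stagnation) break
    }
  }
  result(best, gens)
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf("allocation_result: k = %d, coverage = %.3f (%d generations)\n",
              x$k, x$coverage_score, x$generations_run))
  cat("  stations:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Sweep the number of stations
#'
#' Runs [ga_select()] for an ascending series of station counts, injecting
#' each solution into the next run's initial population; together with
#' elitism this guarantees coverage non-decreasing in k.
#'
#' @inheritParams ga_select
#' @param k_values ascending station counts (default 5, 10, ..., capped at
#'   the candidate count).
#' @return list of `allocation_result`, one per k.
#' @export
sweep_k <- function(stations, risk,
                    k_values = seq(5, nrow(stations), by = 5),
                    radius = 3000, seed = 1L, params = ga_params()) {
  if (is.unsorted(k_values)) stop("k_values must be ascending")
  res <- vector("list", length(k_values))
  prev <- NULL
  for (i in seq_along(k_values)) {
    res[[i]] <- ga_select(stations, k_values[i], risk, radius = radius,
                          seed = as.integer(seed) + i,
                          params = params,
                          seed_individuals = if (!is.null(prev))
                            list(prev$selected))
    prev <- res[[i]]
  }
  res
}
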