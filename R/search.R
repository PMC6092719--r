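#' Stop condition for the search engines
#'
#' At least one criterion must be set. Time-based conditions make runs
#' adapt to collection size; evaluation-count conditions make them
#' machine-independent and reproducible.
#'
#' @param max_time maximum wall time in seconds.
#' @param max_stall_time maximum time in seconds without improvement of
#'   the best solution. The engine default, when nothing is specified,
#'   is 10 seconds without improvement.
#' @param max_stall_evals maximum number of objective evaluations
#'   without improvement.
#' @param max_evals maximum total number of objective evaluations.
#' @return an object of class `cs_stop`.
#' @export
stop_condition <- function(max_time = NULL, max_stall_time = NULL,
                           max_stall_evals = NULL, max_evals = NULL) {
  given <- !c(is.null(max_time), is.null(max_stall_time),
              is.null(max_stall_evals), is.null(max_evals))
  if (!any(given)) stop("at least one stop criterion must be set")
  num <- function(x) if (is.null(x)) Inf else as.numeric(x)
  structure(list(max_time = num(max_time),
                 max_stall_time = num(max_stall_time),
                 max_stall_evals = num(max_stall_evals),
                 max_evals = num(max_evals)),
            class = "cs_stop")
}

default_stop <- function() stop_condition(max_stall_time = 10)

as_stop_list <- function(stop) {
  stopifnot(inherits(stop, "cs_stop"))
  unclass(stop)
}

#' Metropolis acceptance probability of a candidate swap
#'
#' \deqn{p(\Delta, t) = 1 \textrm{ if } \Delta > 0; \; e^{\Delta/t}
#'   \textrm{ otherwise}}
#' where `delta` is the objective change `F(C') - F(C)` and `t` the
#' replica temperature. Improvements are always accepted; inferior
#' moves with probability decaying in the deficit and the inverse
#' temperature. Ties (`delta = 0`) are accepted since `e^0 = 1`.
#'
#' @param delta objective function change of the move.
#' @param t temperature, `> 0`.
#' @return probability in `(0, 1]`.
#' @export
acceptance_probability <- function(delta, t) {
  if (any(t <= 0)) stop("temperature must be positive")
  ifelse(delta > 0, 1, exp(delta / t))
}

#' Replica-exchange (swap) probability in parallel tempering
#'
#' \deqn{q(\Delta_r, t_r, t_{r+1}) = 1 \textrm{ if } \Delta_r > 0; \;
#'   e^{(1/t_r - 1/t_{r+1})\Delta_r} \textrm{ otherwise}}
#' with `delta_r = F(C_{r+1}) - F(C_r)`: a better solution in the
#' hotter replica always moves down the ladder, the reverse exchange
#' happens with exponentially decaying probability.
#'
#' @param delta_r objective difference between replica r+1 and r.
#' @param t_r,t_r1 the two temperatures, `0 < t_r < t_r1`.
#' @return probability in `(0, 1]`.
#' @export
swap_probability <- function(delta_r, t_r, t_r1) {
  if (any(t_r <= 0) || any(t_r1 <= t_r)) {
    stop("temperatures must satisfy 0 < t_r < t_r1")
  }
  ifelse(delta_r > 0, 1, exp((1 / t_r - 1 / t_r1) * delta_r))
}

#' Temperature ladder for parallel tempering
#'
#' Temperatures are equally spaced over `[t_min, t_max]`.
#'
#' @param replicas number of replicas `p >= 2`.
#' @param t_min,t_max temperature range.
#' @return numeric vector of length `replicas`.
#' @export
replica_temperatures <- function(replicas = 10, t_min = 1e-8,
                                 t_max = 1e-4) {
  if (replicas < 2) stop("at least 2 replicas are required")
  if (t_min <= 0 || t_max <= t_min) stop("invalid temperature range")
  t_min + (t_max - t_min) * (seq_len(replicas) - 1) / (replicas - 1)
}

#' All single-swap moves from a core
#'
#' The single-swap neighbourhood replaces one selected accession with
#' one currently unselected accession; it has exactly `k * (n - k)`
#' distinct moves.
#'
#' @param core a [core_subset()].
#' @return data.frame with columns `remove` and `add`.
#' @export
swap_neighbourhood <- function(core) {
  unsel <- setdiff(seq_len(core$n), core$selected)
  expand.grid(remove = core$selected, add = unsel,
              KEEP.OUT.ATTRS = FALSE)
}

# ---------------------------------------------------------------------------
# data preparation shared by the engines

MEASURE_CODE <- c("E-NE" = 0L, "A-NE" = 1L, "HE" = 2L, "avg-EE" = 3L)

prepare_search_data <- function(dataset, objectives, ranges = NULL) {
  if (is.null(ranges)) ranges <- objectives$normalization
  objs <- objectives$objectives
  dist_cache <- new.env()
  dist_list <- list()
  dist_key <- character(0)
  dist_idx <- integer(length(objs))
  for (i in seq_along(objs)) {
    o <- objs[[i]]
    if (o$measure == "HE") {
      dist_idx[i] <- -1L
      if (is.null(dataset$genotypes)) stop("HE requires genotype data")
      next
    }
    d <- resolve_distances(dataset, o$data, dist_cache)
    key <- paste0(o$data, ":", format(sum(d$d)))
    at <- match(key, dist_key)
    if (is.na(at)) {
      dist_list[[length(dist_list) + 1L]] <- d$d
      dist_key <- c(dist_key, key)
      at <- length(dist_list)
    }
    dist_idx[i] <- at - 1L
  }
  norm <- !is.null(ranges)
  if (norm && nrow(ranges$table) != length(objs)) {
    stop("normalization ranges do not cover the configured objectives")
  }
  spec <- data.frame(
    measure = MEASURE_CODE[vapply(objs, `[[`, "", "measure")],
    dist_idx = dist_idx,
    sign = vapply(objs, sign_of, 1),
    weight = vapply(objs, `[[`, 1, "weight"),
    normalize = if (norm) 1L else 0L,
    degenerate = if (norm) ranges$table$degenerate * 1L else 0L,
    lower = if (norm) ranges$table$lower else 0,
    upper = if (norm) ranges$table$upper else 1
  )
  geno <- NULL
  locus_of <- NULL
  if (any(spec$measure == MEASURE_CODE["HE"])) {
    geno <- dataset$genotypes$freq
    locus_of <- dataset$genotypes$locus_of
  }
  list(dist_list = dist_list, spec = spec, geno = geno,
       locus_of = locus_of, n = length(dataset$ids))
}

make_result <- function(raw, dataset, objectives, method, seed) {
  core <- core_subset(raw$selected, length(dataset$ids))
  structure(list(core = core, value = raw$value, evals = raw$evals,
                 trace = raw$trace, method = method, seed = seed),
            class = "cs_search_result")
}

#' @export
print.cs_search_result <- function(x, ...) {
  cat(sprintf("%s search: best value %.6f after %.0f evaluations (k = %d, seed %s)\n",
              x$method, x$value, x$evals, x$core$k, format(x$seed)))
  invisible(x)
}

check_k <- function(k, n) {
  k <- as.integer(k)
  if (k < 2L || k > n - 1L) {
    stop("core size must satisfy 2 <= k <= n - 1")
  }
  k
}

# ---------------------------------------------------------------------------
# engines

#' Random descent (stochastic hill climber)
#'
#' Starts from a uniformly random core of size k and repeatedly draws a
#' uniformly random single-swap move, accepting it if and only if it
#' strictly improves the objective value.
#'
#' @param dataset a [core_dataset()].
#' @param objectives a [cs_objective_config()].
#' @param k core size.
#' @param stop a [stop_condition()]; defaults to 10 s without
#'   improvement.
#' @param seed integer seed; identical seeds give identical results.
#' @param init optional [core_subset()] to start from instead of a
#'   random core.
#' @return a `cs_search_result` with elements `core`, `value` (the
#'   sign-adjusted, possibly normalized objective value), `evals`,
#'   `trace` (best-so-far value at each improvement) and `seed`.
#' @export
random_descent <- function(dataset, objectives, k, stop = default_stop(),
                           seed = 42, init = NULL) {
  pd <- prepare_search_data(dataset, objectives)
  k <- check_k(k, pd$n)
  init_sel <- if (is.null(init)) integer(0) else init$selected
  raw <- cpp_random_descent(pd$dist_list, pd$spec, pd$geno, pd$locus_of,
                            pd$n, k, as.integer(init_sel),
                            as.double(seed), as_stop_list(stop))
  make_result(raw, dataset, objectives, "random descent", seed)
}

#' Parallel tempering (replica exchange) search
#'
#' Runs `replicas` Metropolis searches at fixed temperatures equally
#' spaced in `[t_min, t_max]`, each over the single-swap neighbourhood
#' with acceptance probability [acceptance_probability()]. After every
#' `q` steps per replica, adjacent replica pairs attempt to exchange
#' their current selections with probability [swap_probability()],
#' pushing promising solutions towards the coldest replica while hot
#' replicas escape local optima. The globally best solution across all
#' replicas is tracked and returned.
#'
#' @inheritParams random_descent
#' @param replicas number of replicas (default 10).
#' @param t_min,t_max temperature range (defaults `1e-8`, `1e-4`).
#' @param q Metropolis steps per replica between exchange passes
#'   (default 500).
#' @return a `cs_search_result`.
#' @export
parallel_tempering <- function(dataset, objectives, k,
                               stop = default_stop(), seed = 42,
                               replicas = 10, t_min = 1e-8,
                               t_max = 1e-4, q = 500) {
  replica_temperatures(replicas, t_min, t_max)  # validates
  pd <- prepare_search_data(dataset, objectives)
  k <- check_k(k, pd$n)
  raw <- cpp_parallel_tempering(pd$dist_list, pd$spec, pd$geno,
                                pd$locus_of, pd$n, k, as.double(seed),
                                as_stop_list(stop),
                                as.integer(replicas), t_min, t_max,
                                as.integer(q))
  make_result(raw, dataset, objectives, "parallel tempering", seed)
}

# uniform k-subset of the union of two parents' selections; with
# identical parents the child equals them
ga_crossover <- function(parent1, parent2, k) {
  pool <- union(parent1, parent2)
  if (length(pool) == k) return(sort(pool))
  sort(sample(pool, k))
}

#' Genetic algorithm for core selection
#'
#' Maintains a population of cores. Each generation produces `children`
#' new cores: parents are chosen by tournament selection (the best of
#' `tournament` random candidates), combined by a crossover that keeps
#' accessions selected in either parent until size k is reached, and
#' mutated by random descent until `mutation_stall` consecutive
#' proposals yield no improvement. Survival then discards `children`
#' cores by roulette with weight `1/F(C)`, inversely proportional to
#' fitness, keeping the population size fixed. When non-positive
#' fitness values occur, all weights are shifted by `|min F| + 1e-9`
#' before inverting.
#'
#' @inheritParams random_descent
#' @param population population size (default 25).
#' @param children children per generation (default 5).
#' @param tournament tournament size for parent selection (default 5).
#' @param mutation_stall unimproving proposals that end a child's
#'   random-descent mutation (default 5000).
#' @return a `cs_search_result`.
#' @export
genetic_algorithm <- function(dataset, objectives, k,
                              stop = default_stop(), seed = 42,
                              population = 25, children = 5,
                              tournament = 5, mutation_stall = 5000) {
  if (population <= tournament) {
    stop("population must exceed the tournament size")
  }
  pd <- prepare_search_data(dataset, objectives)
  n <- pd$n
  k <- check_k(k, n)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed %% .Machine$integer.max)

  t0 <- Sys.time()
  elapsed <- function() as.numeric(difftime(Sys.time(), t0, units = "secs"))
  evals <- 0
  stall <- 0
  best_val <- -Inf
  best_sel <- NULL
  last_improve_t <- 0
  trace <- list(evals = numeric(0), time = numeric(0),
                value = numeric(0))
  note_best <- function(val, sel) {
    if (val > best_val) {
      best_val <<- val
      best_sel <<- sel
      stall <<- 0
      last_improve_t <<- elapsed()
      trace$evals <<- c(trace$evals, evals)
      trace$time <<- c(trace$time, last_improve_t)
      trace$value <<- c(trace$value, val)
    }
  }
  done <- function() {
    evals >= stop$max_evals || stall >= stop$max_stall_evals ||
      elapsed() >= stop$max_time ||
      (elapsed() - last_improve_t) >= stop$max_stall_time
  }
  eval_sel <- function(sel) {
    evals <<- evals + 1
    stall <<- stall + 1
    cpp_evaluate_selection(pd$dist_list, pd$spec, pd$geno, pd$locus_of,
                           n, k, as.integer(sel))$value
  }

  pop <- replicate(population, sort(sample.int(n, k)), simplify = FALSE)
  fit <- vapply(pop, eval_sel, 1)
  for (i in seq_along(pop)) note_best(fit[i], pop[[i]])

  while (!done()) {
    for (ch in seq_len(children)) {
      if (done()) break
      pick_parent <- function() {
        cand <- sample.int(length(pop), tournament)
        cand[which.max(fit[cand])]
      }
      child <- ga_crossover(pop[[pick_parent()]], pop[[pick_parent()]], k)
      budget_left <- stop$max_evals - evals
      if (budget_left < 1) break
      mstop <- list(max_evals = budget_left,
                    max_stall_evals = min(mutation_stall,
                                          stop$max_stall_evals),
                    max_time = if (is.finite(stop$max_time)) {
                      max(stop$max_time - elapsed(), 0.001)
                    } else Inf,
                    max_stall_time = stop$max_stall_time)
      mut <- cpp_random_descent(pd$dist_list, pd$spec, pd$geno,
                                pd$locus_of, n, k, as.integer(child),
                                as.double(sample.int(.Machine$integer.max, 1)),
                                mstop)
      evals <- evals + mut$evals
      stall <- stall + mut$evals
      pop[[length(pop) + 1L]] <- sort(mut$selected)
      fit <- c(fit, mut$value)
      note_best(mut$value, sort(mut$selected))
    }
    # roulette survival: discard down to the fixed population size
    n_discard <- length(pop) - population
    if (n_discard > 0) {
      f <- fit
      if (min(f) <= 0) f <- f - min(f) + 1e-9
      drop <- sample.int(length(pop), n_discard, prob = 1 / f)
      pop <- pop[-drop]
      fit <- fit[-drop]
    }
  }
  raw <- list(selected = best_sel, value = best_val, evals = evals,
              trace = data.frame(evals = trace$evals, time = trace$time,
                                 value = trace$value))
  make_result(raw, dataset, objectives, "genetic algorithm", seed)
}

#' Exhaustive search over all k-subsets
#'
#' Enumerates every core of size k and returns the one maximizing the
#' configured objective (sign-adjusted; A-NE is minimized). Ties are
#' broken towards the lexicographically smallest index set. Intended as
#' a test oracle for small instances; refuses instances with more than
#' `choose(n, k) = 1e6` subsets.
#'
#' @inheritParams random_descent
#' @return list with `core` (a [core_subset()]) and `value`.
#' @export
brute_force_optimum <- function(dataset, objectives, k) {
  pd <- prepare_search_data(dataset, objectives)
  n <- pd$n
  k <- check_k(k, n)
  if (choose(n, k) > 1e6) stop("instance too large for enumeration")
  sels <- utils::combn(n, k)
  vals <- cpp_evaluate_many(pd$dist_list, pd$spec, pd$geno, pd$locus_of,
                            n, k, sels)
  best <- which.max(vals)  # combn is lexicographic; which.max takes first
  list(core = core_subset(sels[, best], n), value = vals[best])
}
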