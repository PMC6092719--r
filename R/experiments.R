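#' Resolve a core size given as absolute k or fraction of n
#'
#' Fractions are rounded half up and clamped to the feasible range
#' `[2, n - 1]`; typical practice samples cores of 20% of the
#' collection, or 10% for very large collections.
#'
#' @param n collection size.
#' @param k absolute core size (exclusive with `fraction`).
#' @param fraction core size as a fraction of n, in `(0, 1)`.
#' @return integer core size.
#' @export
resolve_core_size <- function(n, k = NULL, fraction = NULL) {
  if (is.null(k) == is.null(fraction)) {
    stop("specify exactly one of `k` and `fraction`")
  }
  if (!is.null(fraction)) {
    if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
    k <- floor(fraction * n + 0.5)  # round half up
  }
  k <- max(2L, min(as.integer(k), n - 1L))
  check_k(k, n)
}

# dispatch a method name to the matching selector; baselines are scored
# with the same objective configuration afterwards
run_method <- function(method, dataset, objectives, k, stop, seed) {
  switch(method,
    rd = random_descent(dataset, objectives, k, stop, seed),
    pt = parallel_tempering(dataset, objectives, k, stop, seed),
    ga = genetic_algorithm(dataset, objectives, k, stop, seed),
    gdopt = ,
    `simeli-ara` = ,
    `simeli-he` = {
      core <- switch(method,
        gdopt = gdopt_select(dataset, k, seed),
        `simeli-ara` = simeli_select(dataset, k, "A-RA", seed),
        `simeli-he` = simeli_select(dataset, k, "HE", seed))
      ev <- evaluate_core(dataset, core, objectives)
      structure(list(core = core, value = ev$index, evals = NA_real_,
                     trace = data.frame(evals = numeric(0),
                                        time = numeric(0),
                                        value = numeric(0)),
                     method = method, seed = seed),
                class = "cs_search_result")
    },
    stop("unknown method: ", method)
  )
}

#' Run configuration for [run_sampling()]
#'
#' @param genotypes,phenotypes,distances optional input CSV paths (at
#'   least one required). `genotype_dialect` selects the genotype CSV
#'   dialect; `phenotype_kinds` maps trait columns to their kind (when
#'   omitted, numeric-looking columns are treated as quantitative).
#' @param genotype_dialect `"dosage"` or `"frequency"`.
#' @param phenotype_kinds named character vector of trait kinds.
#' @param size absolute core size (exclusive with `fraction`).
#' @param fraction core size as fraction of the collection.
#' @param objectives list of `list(measure=, weight=, data=)` entries
#'   (weight defaults to an equal split; data to `"auto"`).
#' @param method `"rd"`, `"pt"`, `"ga"`, `"gdopt"`, `"simeli-ara"` or
#'   `"simeli-he"`.
#' @param seed integer seed.
#' @param max_time,max_stall_time,max_stall_evals,max_evals stop
#'   criteria (see [stop_condition()]); all unset means 10 s without
#'   improvement.
#' @param out path for the written core file (optional).
#' @return an object of class `cs_run_config`.
#' @export
run_config <- function(genotypes = NULL, phenotypes = NULL,
                       distances = NULL, genotype_dialect = "dosage",
                       phenotype_kinds = NULL, size = NULL,
                       fraction = NULL, objectives = list(
                         list(measure = "E-NE")),
                       method = "pt", seed = 42, max_time = NULL,
                       max_stall_time = NULL, max_stall_evals = NULL,
                       max_evals = NULL, out = NULL) {
  if (is.null(genotypes) && is.null(phenotypes) && is.null(distances)) {
    stop("at least one data path is required")
  }
  if (is.null(size) == is.null(fraction)) {
    stop("specify exactly one of `size` and `fraction`")
  }
  structure(as.list(environment()), class = "cs_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Accepts the same keys as [run_config()].
#'
#' @param path YAML file path.
#' @return a `cs_run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$phenotype_kinds)) {
    vals$phenotype_kinds <- unlist(vals$phenotype_kinds)
  }
  do.call(run_config, vals)
}

load_config_dataset <- function(config) {
  geno <- pheno <- dmat <- NULL
  if (!is.null(config$genotypes)) {
    geno <- read_genotypes(config$genotypes, config$genotype_dialect)
  }
  if (!is.null(config$phenotypes)) {
    kinds <- config$phenotype_kinds
    if (is.null(kinds)) {
      tab <- utils::read.csv(config$phenotypes, check.names = FALSE,
                             stringsAsFactors = FALSE, nrows = 50)
      cols <- names(tab)[-1]
      numeric_like <- vapply(tab[-1], function(v) {
        suppressWarnings(!anyNA(as.numeric(v[!is.na(v) & v != ""])))
      }, TRUE)
      kinds <- ifelse(numeric_like, "quantitative", "qualitative")
      names(kinds) <- cols
    }
    pheno <- read_phenotypes(config$phenotypes, kinds)
  }
  if (!is.null(config$distances)) {
    dmat <- read_distance_matrix(config$distances)
  }
  core_dataset(genotypes = geno, phenotypes = pheno, distances = dmat)
}

config_objectives <- function(config) {
  objs <- lapply(config$objectives, function(o) {
    objective(measure = o$measure,
              weight = if (is.null(o$weight)) {
                1 / length(config$objectives)
              } else o$weight,
              data = if (is.null(o$data)) "auto" else o$data)
  })
  objective_config(objs)
}

config_stop <- function(config) {
  if (is.null(config$max_time) && is.null(config$max_stall_time) &&
      is.null(config$max_stall_evals) && is.null(config$max_evals)) {
    default_stop()
  } else {
    stop_condition(max_time = config$max_time,
                   max_stall_time = config$max_stall_time,
                   max_stall_evals = config$max_stall_evals,
                   max_evals = config$max_evals)
  }
}

#' Execute a configured sampling run
#'
#' Loads the configured data, resolves the core size, runs the chosen
#' method and, if `config$out` is set, writes the core file with an
#' evaluation report that always includes DMIN when distances are
#' available. Multi-objective configurations are normalized first via
#' [compute_normalization_ranges()] under the same stop budget.
#'
#' @param config a [run_config()] (or path handled by
#'   [read_run_config()]).
#' @return list with `result` (a `cs_search_result`), `core`, `report`
#'   (named numeric) and `out` (the written path or `NULL`).
#' @export
run_sampling <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "cs_run_config"))
  dataset <- load_config_dataset(config)
  n <- length(dataset$ids)
  k <- resolve_core_size(n, k = config$size, fraction = config$fraction)
  objectives <- config_objectives(config)
  stop_cond <- config_stop(config)
  if (length(objectives$objectives) > 1L &&
      config$method %in% c("rd", "pt", "ga")) {
    objectives$normalization <- compute_normalization_ranges(
      dataset, objectives, k, stop = stop_cond, seed = config$seed)
  }
  result <- run_method(config$method, dataset, objectives, k,
                       stop_cond, config$seed)
  ev <- evaluate_core(dataset, result$core, objectives)
  out <- NULL
  if (!is.null(config$out)) {
    out <- write_core(result$core, dataset, config$out,
                      report = ev$report)
  }
  list(result = result, core = result$core, report = ev$report,
       out = out)
}

#' Pareto weight sweep over two objectives
#'
#' Samples cores for weights `alpha1 = 0, step, ..., 1` assigned to
#' objective A (`alpha2 = 1 - alpha1` to objective B) and evaluates
#' both raw measures on every core, approximating the Pareto front of
#' the two criteria. Interior weights optimize the normalized weighted
#' index (normalization bounds are computed once per sweep and shared);
#' the endpoint weights degenerate to unnormalized single-objective
#' runs. Sub-seeds are `seed + run_index` per weight setting.
#'
#' @param dataset a [core_dataset()].
#' @param objective_a,objective_b the two [objective()]s (weights
#'   ignored).
#' @param k core size.
#' @param step weight step (must divide 1; default 0.05, giving 21
#'   settings).
#' @param runs independently seeded runs per weight setting.
#' @param stop [stop_condition()] per run.
#' @param seed base seed.
#' @param method `"rd"`, `"pt"` or `"ga"`.
#' @param norm_stop optional separate budget for the normalization
#'   bound searches (defaults to `stop`).
#' @return object of class `cs_pareto_sweep`: `table` (per-weight mean
#'   and sd of both raw measures), `cores` (list of per-weight lists),
#'   `values` (per-core raw and normalized values) and `ranges`.
#' @export
pareto_sweep <- function(dataset, objective_a, objective_b, k,
                         step = 0.05, runs = 10,
                         stop = default_stop(), seed = 42,
                         method = "pt", norm_stop = NULL) {
  stopifnot(inherits(objective_a, "cs_objective"),
            inherits(objective_b, "cs_objective"))
  n_steps <- 1 / step
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("step must divide 1")
  }
  alphas <- seq(0, 1, by = step)
  if (is.null(norm_stop)) norm_stop <- stop
  both <- objective_config(list(
    objective(objective_a$measure, 0.5, objective_a$data),
    objective(objective_b$measure, 0.5, objective_b$data)))
  ranges <- compute_normalization_ranges(dataset, both, k,
                                         stop = norm_stop, seed = seed)
  rows <- list()
  cores <- list()
  values <- list()
  for (ai in seq_along(alphas)) {
    a1 <- alphas[ai]
    cfg <- if (a1 == 0) {
      objective_config(list(objective(objective_b$measure, 1,
                                      objective_b$data)))
    } else if (a1 == 1) {
      objective_config(list(objective(objective_a$measure, 1,
                                      objective_a$data)))
    } else {
      objective_config(list(
        objective(objective_a$measure, a1, objective_a$data),
        objective(objective_b$measure, 1 - a1, objective_b$data)),
        normalization = ranges)
    }
    va <- vb <- na_ <- nb_ <- numeric(runs)
    run_cores <- vector("list", runs)
    for (r in seq_len(runs)) {
      res <- run_method(method, dataset, cfg, k, stop, seed + r)
      run_cores[[r]] <- res$core
      va[r] <- raw_measure(dataset, res$core, objective_a)
      vb[r] <- raw_measure(dataset, res$core, objective_b)
      na_[r] <- normalized_value(va[r], objective_a, ranges, 1)
      nb_[r] <- normalized_value(vb[r], objective_b, ranges, 2)
    }
    rows[[ai]] <- data.frame(alpha1 = a1, mean_a = mean(va),
                             sd_a = stats::sd(va), mean_b = mean(vb),
                             sd_b = stats::sd(vb))
    cores[[ai]] <- run_cores
    values[[ai]] <- data.frame(alpha1 = a1, run = seq_len(runs),
                               raw_a = va, raw_b = vb, norm_a = na_,
                               norm_b = nb_)
  }
  structure(list(table = do.call(rbind, rows),
                 cores = cores, values = do.call(rbind, values),
                 ranges = ranges,
                 measures = c(objective_a$measure,
                              objective_b$measure)),
            class = "cs_pareto_sweep")
}

normalized_value <- function(raw, obj, ranges, row) {
  if (ranges$table$degenerate[row]) return(1)
  v <- sign_of(obj) * raw
  z <- (v - ranges$table$lower[row]) /
    (ranges$table$upper[row] - ranges$table$lower[row])
  min(max(z, 0), 1)
}

#' @export
print.cs_pareto_sweep <- function(x, ...) {
  cat(sprintf("Pareto sweep over (%s, %s): %d weight settings\n",
              x$measures[1], x$measures[2], nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Compare selection methods over repeated seeded runs
#'
#' Runs every method `runs` times with sub-seeds `base_seed +
#' run_index` (the same seeds across methods) and summarizes the
#' achieved objective values; search traces are collected for
#' convergence plots of best-so-far value against time and evaluation
#' count.
#'
#' @param dataset a [core_dataset()].
#' @param objectives a [cs_objective_config()].
#' @param k core size.
#' @param methods character vector of method names (see
#'   [run_method()] values: `"rd"`, `"pt"`, `"ga"`, `"gdopt"`,
#'   `"simeli-ara"`, `"simeli-he"`).
#' @param runs runs per method.
#' @param stop [stop_condition()] per run.
#' @param base_seed base seed.
#' @return object of class `cs_comparison`: `summary` (method, mean,
#'   sd, best), `runs` (one row per run with the value and core) and
#'   `traces` (long data.frame: method, run, evals, time, value).
#' @export
compare_algorithms <- function(dataset, objectives, k,
                               methods = c("rd", "pt", "ga"),
                               runs = 10, stop = default_stop(),
                               base_seed = 42) {
  stopifnot(length(methods) >= 1)
  run_rows <- list()
  traces <- list()
  cores <- list()
  for (m in methods) {
    for (r in seq_len(runs)) {
      res <- run_method(m, dataset, objectives, k, stop,
                        base_seed + r)
      run_rows[[length(run_rows) + 1L]] <-
        data.frame(method = m, run = r, seed = base_seed + r,
                   value = res$value, evals = res$evals)
      if (nrow(res$trace)) {
        traces[[length(traces) + 1L]] <-
          cbind(method = m, run = r, res$trace)
      }
      cores[[paste(m, r)]] <- res$core
    }
  }
  runs_df <- do.call(rbind, run_rows)
  summary <- do.call(rbind, lapply(methods, function(m) {
    v <- runs_df$value[runs_df$method == m]
    data.frame(method = m, mean = mean(v), sd = stats::sd(v),
               best = max(v))
  }))
  structure(list(summary = summary, runs = runs_df,
                 traces = if (length(traces)) do.call(rbind, traces)
                          else NULL,
                 cores = cores),
            class = "cs_comparison")
}

#' @export
print.cs_comparison <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
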