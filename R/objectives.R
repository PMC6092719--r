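#' Entry-to-nearest-entry distance (E-NE) of a core
#'
#' Average distance between each selected accession and the closest
#' other core entry. Maximized to obtain diverse cores in which every
#' entry differs from all others; unlike average entry-to-entry
#' distance it does not overrepresent extremes, and unlike the raw
#' minimum distance it gives local search a smooth gradient.
#'
#' @param d a [distance_matrix()].
#' @param core a [core_subset()] (k >= 2).
#' @return non-negative mean nearest-entry distance.
#' @export
entry_to_nearest_entry <- function(d, core) {
  sel <- core$selected
  dd <- d$d[sel, sel, drop = FALSE]
  diag(dd) <- Inf
  mean(apply(dd, 1, min))
}

#' Accession-to-nearest-entry distance (A-NE) of a core
#'
#' Mean distance between each accession of the entire collection and
#' the most similar core entry (itself, at distance 0, if selected).
#' Minimized to obtain cores that represent all individual accessions.
#'
#' @inheritParams entry_to_nearest_entry
#' @return non-negative mean nearest-entry distance over all accessions.
#' @export
accession_to_nearest_entry <- function(d, core) {
  dd <- d$d[, core$selected, drop = FALSE]
  mean(apply(dd, 1, min))
}

#' Expected heterozygosity (HE) of a core
#'
#' Average expected heterozygosity per locus,
#' \deqn{HE = (1/L) \sum_l (1 - \sum_a \hat p_{la}^2)}
#' where \eqn{\hat p_{la}} is the frequency of allele a at locus l in
#' the selected core, computed as the unweighted mean of the entry
#' allele-frequency vectors over core entries with observed data at
#' that locus. Loci unobserved in the whole core are dropped from the
#' average; it is an error if no observed locus remains.
#'
#' @param geno a [genotype_matrix()].
#' @param core a [core_subset()] (k >= 2).
#' @return HE in `[0, 1]`; 0 iff the core is monomorphic at every locus.
#' @export
expected_heterozygosity <- function(geno, core) {
  f <- geno$freq[core$selected, , drop = FALSE]
  p <- colMeans(f, na.rm = TRUE)          # mean over observed entries
  het <- 1 - rowsum(ifelse(is.nan(p), NA, p)^2, group = geno$locus_of)
  het <- het[!is.na(het)]
  if (!length(het)) stop("no locus observed in any core entry")
  mean(het)
}

#' Minimum pairwise distance (DMIN) among core entries
#'
#' Reported for evaluation only: DMIN is deliberately not exposed as an
#' optimizable objective because local searches handle it poorly (many
#' swaps leave it unchanged); maximizing E-NE indirectly keeps it high.
#'
#' @inheritParams entry_to_nearest_entry
#' @return minimum over all selected pairs.
#' @export
min_distance <- function(d, core) {
  sel <- core$selected
  dd <- d$d[sel, sel, drop = FALSE]
  min(dd[upper.tri(dd)])
}

#' Average entry-to-entry distance of a core
#'
#' Mean over all `k(k-1)/2` selected pairs; the classical diversity
#' criterion, kept as a comparator measure.
#'
#' @inheritParams entry_to_nearest_entry
#' @return mean pairwise distance among entries.
#' @export
average_entry_to_entry <- function(d, core) {
  sel <- core$selected
  dd <- d$d[sel, sel, drop = FALSE]
  mean(dd[upper.tri(dd)])
}

# ---------------------------------------------------------------------------
# objective configuration

OBJ_MEASURES <- c("E-NE", "A-NE", "HE", "avg-EE")

#' Declare one optimization objective
#'
#' @param measure `"E-NE"`, `"A-NE"`, `"HE"` or `"avg-EE"`. The
#'   direction is implied: A-NE is minimized, all others maximized.
#'   DMIN is evaluation-only and cannot be declared as an objective.
#' @param weight weight in `(0, 1]`; weights of an [objective_config()]
#'   must sum to 1.
#' @param data which dataset component supplies the distances:
#'   `"auto"` (precomputed if present, else genotypes via Modified
#'   Rogers, else phenotypes via Gower), `"genotypes"`, `"phenotypes"`
#'   or `"precomputed"`. Ignored for HE, which always reads genotypes.
#' @return an object of class `cs_objective`.
#' @export
objective <- function(measure = OBJ_MEASURES, weight = 1,
                      data = c("auto", "genotypes", "phenotypes",
                               "precomputed")) {
  measure <- match.arg(measure)
  data <- match.arg(data)
  if (!is.numeric(weight) || weight <= 0 || weight > 1) {
    stop("weight must lie in (0, 1]")
  }
  structure(
    list(measure = measure,
         direction = if (measure == "A-NE") "minimize" else "maximize",
         weight = as.numeric(weight), data = data),
    class = "cs_objective"
  )
}

#' Bundle objectives into a configuration
#'
#' @param ... [objective()] objects (or a single list of them).
#' @param normalization optional [compute_normalization_ranges()] result
#'   attached to the configuration.
#' @return an object of class `cs_objective_config`.
#' @export
objective_config <- function(..., normalization = NULL) {
  objs <- list(...)
  if (length(objs) == 1L && !inherits(objs[[1]], "cs_objective")) {
    objs <- objs[[1]]
  }
  if (!length(objs)) stop("at least one objective is required")
  stopifnot(all(vapply(objs, inherits, TRUE, "cs_objective")))
  w <- vapply(objs, `[[`, 1, "weight")
  if (abs(sum(w) - 1) > 1e-9) {
    stop("objective weights must sum to 1 (got ", sum(w), ")")
  }
  structure(list(objectives = objs, normalization = normalization),
            class = "cs_objective_config")
}

#' @export
print.cs_objective_config <- function(x, ...) {
  for (o in x$objectives) {
    cat(sprintf("  %s (%s, weight %.2f, data %s)\n", o$measure,
                o$direction, o$weight, o$data))
  }
  if (!is.null(x$normalization)) cat("  [normalized]\n")
  invisible(x)
}

# sign-adjusted raw value: maximized measures as-is, minimized negated
sign_of <- function(obj) if (obj$direction == "minimize") -1 else 1

raw_measure <- function(dataset, core, obj, dist_cache = NULL) {
  if (obj$measure == "HE") {
    if (is.null(dataset$genotypes)) {
      stop("HE requires genotype data")
    }
    return(expected_heterozygosity(dataset$genotypes, core))
  }
  d <- resolve_distances(dataset, obj$data, dist_cache)
  switch(obj$measure,
    "E-NE" = entry_to_nearest_entry(d, core),
    "A-NE" = accession_to_nearest_entry(d, core),
    "avg-EE" = average_entry_to_entry(d, core)
  )
}

# pick / compute (and memoise in an environment) the distance matrix an
# objective reads
resolve_distances <- function(dataset, data = "auto", cache = NULL) {
  if (data == "auto") {
    data <- if (!is.null(dataset$distances)) "precomputed"
            else if (!is.null(dataset$genotypes)) "genotypes"
            else "phenotypes"
  }
  if (data == "precomputed") {
    if (is.null(dataset$distances)) stop("no precomputed distance matrix")
    return(dataset$distances)
  }
  key <- data
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  d <- switch(data,
    genotypes = pairwise_matrix(dataset, "modified_rogers"),
    phenotypes = pairwise_matrix(dataset, "gower")
  )
  if (!is.null(cache)) cache[[key]] <- d
  d
}

#' Normalization ranges for a multi-objective configuration
#'
#' Implements the Pareto-minimum upper/lower-bound normalization. For
#' each sign-adjusted objective i, the upper bound `U_i` is the best
#' value found by a dedicated single-objective random-descent search;
#' the lower bound `L_i` is the worst (minimum) value objective i takes
#' across the optima returned for the other objectives — the Pareto
#' minimum. Each objective's normalized value `(v - L_i)/(U_i - L_i)`
#' then spans `[0, 1]` over the interesting region regardless of its
#' original scale. An objective with `U_i <= L_i` (all single-objective
#' optima coincide for it) is degenerate: it is dropped from
#' normalization with a warning and treated as the constant 1.
#'
#' @param dataset a [core_dataset()].
#' @param objectives a [cs_objective_config()] with >= 2 objectives.
#' @param k core size.
#' @param stop a [stop_condition()] budget for each bound search.
#' @param seed integer seed; sub-seeds per objective are derived from it
#'   so the ranges are reproducible.
#' @return object of class `cs_norm_ranges`: data.frame with columns
#'   `measure`, `lower`, `upper`, `degenerate` (bounds on the
#'   sign-adjusted scale) plus the single-objective optima.
#' @export
compute_normalization_ranges <- function(dataset, objectives, k,
                                         stop = stop_condition(max_stall_evals = 20000),
                                         seed = 42) {
  objs <- objectives$objectives
  if (length(objs) < 2L) stop("normalization needs at least 2 objectives")
  m <- length(objs)
  sols <- vector("list", m)
  upper <- numeric(m)
  for (i in seq_len(m)) {
    single <- objective_config(list(objective(objs[[i]]$measure, 1,
                                              objs[[i]]$data)))
    res <- random_descent(dataset, single, k, stop = stop,
                          seed = seed + i)
    sols[[i]] <- res$core
    upper[i] <- res$value  # sign-adjusted by construction
  }
  dist_cache <- new.env()
  lower <- numeric(m)
  for (i in seq_len(m)) {
    at <- vapply(seq_len(m), function(j) {
      sign_of(objs[[i]]) * raw_measure(dataset, sols[[j]], objs[[i]],
                                       dist_cache)
    }, 1)
    upper[i] <- max(upper[i], at[i])
    lower[i] <- min(at)
  }
  degen <- upper <= lower + 1e-12
  if (any(degen)) {
    warning("degenerate normalization range for ",
            paste(vapply(objs[degen], `[[`, "", "measure"),
                  collapse = ", "),
            "; objective treated as constant")
  }
  structure(
    list(table = data.frame(
           measure = vapply(objs, `[[`, "", "measure"),
           lower = lower, upper = upper, degenerate = degen,
           stringsAsFactors = FALSE),
         optima = sols, seed = seed),
    class = "cs_norm_ranges"
  )
}

#' Weighted multi-objective index
#'
#' Each raw measure value is sign-adjusted (minimized measures negated),
#' normalized to `(v - L_i) / (U_i - L_i)` with the bounds from
#' [compute_normalization_ranges()], clamped to `[0, 1]`, and combined
#' as the weighted sum `F(C) = sum_i alpha_i F_i(C)`.
#'
#' @param raw_values numeric vector of raw measure values, one per
#'   objective (unadjusted scale, i.e. A-NE as a distance).
#' @param objectives a [cs_objective_config()].
#' @param ranges a `cs_norm_ranges` object covering all objectives.
#' @return index in `[0, 1]`.
#' @export
weighted_index <- function(raw_values, objectives, ranges) {
  objs <- objectives$objectives
  if (length(raw_values) != length(objs)) {
    stop("one raw value per objective is required")
  }
  w <- vapply(objs, `[[`, 1, "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  total <- 0
  if (nrow(ranges$table) != length(objs)) {
    stop("normalization ranges do not cover the objectives")
  }
  for (i in seq_along(objs)) {
    row <- i
    if (!identical(ranges$table$measure[i], objs[[i]]$measure)) {
      stop("normalization ranges were computed for different objectives")
    }
    v <- sign_of(objs[[i]]) * raw_values[i]
    x <- if (ranges$table$degenerate[row]) 1 else {
      z <- (v - ranges$table$lower[row]) /
        (ranges$table$upper[row] - ranges$table$lower[row])
      min(max(z, 0), 1)
    }
    total <- total + w[i] * x
  }
  total
}

#' Evaluate a core against a dataset
#'
#' Computes the raw value of every configured measure, always adds DMIN
#' (and E-NE/A-NE context) when a distance matrix exists, and — when the
#' configuration carries normalization ranges or has a single objective
#' — the scalar objective value the search engines optimize.
#'
#' @param dataset a [core_dataset()].
#' @param core a [core_subset()].
#' @param objectives a [cs_objective_config()].
#' @param ranges optional `cs_norm_ranges`; defaults to the ones stored
#'   in the configuration, if any.
#' @return list with `measures` (named numeric of raw values),
#'   `report` (measures plus DMIN) and `index` (scalar objective value;
#'   for a single unnormalized objective the sign-adjusted raw value).
#' @export
evaluate_core <- function(dataset, core, objectives, ranges = NULL) {
  if (is.null(ranges)) ranges <- objectives$normalization
  objs <- objectives$objectives
  dist_cache <- new.env()
  raw <- vapply(objs, function(o) raw_measure(dataset, core, o,
                                              dist_cache), 1)
  names(raw) <- vapply(objs, `[[`, "", "measure")
  report <- raw
  has_dist <- !is.null(dataset$distances) || !is.null(dataset$genotypes) ||
    !is.null(dataset$phenotypes)
  if (has_dist) {
    d <- resolve_distances(dataset, "auto", dist_cache)
    report <- c(report, DMIN = min_distance(d, core))
  }
  index <- if (length(objs) == 1L && is.null(ranges)) {
    sign_of(objs[[1]]) * raw[1]
  } else if (!is.null(ranges)) {
    weighted_index(raw, objectives, ranges)
  } else {
    NA_real_
  }
  list(measures = raw, report = report, index = unname(index))
}
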