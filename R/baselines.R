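#' PAM k-medoids clustering (BUILD + SWAP)
#'
#' Partitioning around medoids in the classical two-phase form: BUILD
#' greedily adds the medoid that most reduces the total
#' point-to-nearest-medoid distance; SWAP repeatedly applies the best
#' medoid/non-medoid exchange until no exchange reduces the total cost.
#' The result is locally optimal under single exchanges. Deterministic:
#' ties are broken towards the lowest index.
#'
#' @param d a [distance_matrix()] (or plain symmetric matrix).
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed unused (the algorithm is deterministic); accepted for
#'   interface uniformity.
#' @return list with `medoids` (sorted indices), `assignment` (nearest
#'   medoid index per accession) and `cost`
#'   (`sum_a min_m d(a, m)`).
#' @export
pam_kmedoids <- function(d, k, seed = NULL) {
  D <- if (inherits(d, "distance_matrix")) d$d else as.matrix(d)
  n <- nrow(D)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must lie in 1..n")

  # BUILD
  meds <- unname(which.min(colSums(D)))
  d1 <- D[, meds]
  while (length(meds) < k) {
    cand <- setdiff(seq_len(n), meds)
    gain <- colSums(pmax(d1 - D[, cand, drop = FALSE], 0))
    add <- cand[which.max(gain)]
    meds <- c(meds, add)
    d1 <- pmin(d1, D[, add])
  }

  nearest2 <- function(meds) {
    Dm <- D[, meds, drop = FALSE]
    o1 <- apply(Dm, 1, which.min)
    d1 <- Dm[cbind(seq_len(n), o1)]
    Dm[cbind(seq_len(n), o1)] <- Inf
    o2 <- apply(Dm, 1, which.min)
    d2 <- Dm[cbind(seq_len(n), o2)]
    list(idx1 = o1, d1 = d1, d2 = d2)
  }

  # SWAP
  if (k < n && k >= 1L) {
    repeat {
      nn <- nearest2(meds)
      cand <- setdiff(seq_len(n), meds)
      Cand <- D[, cand, drop = FALSE]
      M0 <- pmin(Cand - nn$d1, 0)
      base <- colSums(M0)
      best_delta <- 0
      best_m <- best_h <- NA_integer_
      for (mi in seq_along(meds)) {
        jm <- which(nn$idx1 == mi)
        corr <- if (length(jm)) {
          colSums(pmin(nn$d2[jm], Cand[jm, , drop = FALSE]) -
                    nn$d1[jm] - M0[jm, , drop = FALSE])
        } else 0
        delta <- base + corr
        h <- which.min(delta)
        if (delta[h] < best_delta - 1e-12) {
          best_delta <- delta[h]
          best_m <- mi
          best_h <- cand[h]
        }
      }
      if (is.na(best_m)) break
      meds[best_m] <- best_h
    }
  }
  meds <- sort(meds)
  Dm <- D[, meds, drop = FALSE]
  a1 <- apply(Dm, 1, which.min)
  list(medoids = meds, assignment = meds[a1],
       cost = sum(Dm[cbind(seq_len(n), a1)]))
}

#' GDOpt core selection (k-medoids representatives)
#'
#' Clusters the collection into k groups with [pam_kmedoids()] and
#' selects the medoids as the core, so that each accession is
#' represented by a similar core entry. By construction the selected
#' core's A-NE equals the PAM cost divided by n.
#'
#' @param dataset a [core_dataset()].
#' @param k core size (`>= 2`; a single medoid is not a valid core).
#' @param seed unused; interface uniformity.
#' @return a [core_subset()] with the PAM result attached as attribute
#'   `"pam"`.
#' @export
gdopt_select <- function(dataset, k, seed = NULL) {
  d <- resolve_distances(dataset, "auto")
  fit <- pam_kmedoids(d, k, seed)
  core <- core_subset(fit$medoids, length(dataset$ids))
  attr(core, "pam") <- fit
  core
}

he_of_rows <- function(geno, rows) {
  f <- geno$freq[rows, , drop = FALSE]
  p <- colMeans(f, na.rm = TRUE)
  het <- 1 - rowsum(ifelse(is.nan(p), NA, p)^2, group = geno$locus_of)
  het <- het[!is.na(het)]
  if (!length(het)) stop("no locus observed")
  mean(het)
}

#' SimEli core selection (iterative elimination)
#'
#' Repeatedly locates the two most similar remaining accessions and
#' eliminates one of them until k accessions remain. With the `"A-RA"`
#' criterion each member of the closest pair is scored by its mean
#' distance to the other remaining accessions (the pair partner
#' excluded) and the one with the smaller score is eliminated, keeping
#' the accession that is on average farther from the rest. With `"HE"`
#' the member whose removal leaves the reduced collection with the
#' higher expected heterozygosity is eliminated. Ties (closest pair and
#' criterion) are broken towards the lower index.
#'
#' @param dataset a [core_dataset()].
#' @param k core size.
#' @param criterion `"A-RA"` or `"HE"` (the latter requires genotypes).
#' @param seed unused; interface uniformity.
#' @return a [core_subset()] with attribute `"trace"`: a data.frame of
#'   the closest pair and eliminated accession at every step.
#' @export
simeli_select <- function(dataset, k, criterion = c("A-RA", "HE"),
                          seed = NULL) {
  criterion <- match.arg(criterion)
  n <- length(dataset$ids)
  k <- check_k(k, n)
  if (criterion == "HE" && is.null(dataset$genotypes)) {
    stop("the HE elimination criterion requires genotype data")
  }
  D <- resolve_distances(dataset, "auto")$d
  remaining <- seq_len(n)
  trace <- data.frame(step = integer(0), pair_i = integer(0),
                      pair_j = integer(0), eliminated = integer(0))
  step <- 0L
  while (length(remaining) > k) {
    step <- step + 1L
    Dr <- D[remaining, remaining, drop = FALSE]
    Dr[lower.tri(Dr, diag = TRUE)] <- Inf
    hits <- which(Dr == min(Dr), arr.ind = TRUE)
    hit <- hits[order(hits[, 1], hits[, 2])[1], ]
    i <- remaining[hit[1]]
    j <- remaining[hit[2]]
    if (criterion == "A-RA") {
      others <- setdiff(remaining, c(i, j))
      score_i <- mean(D[i, others])
      score_j <- mean(D[j, others])
      # keep the member farther from the rest; ties drop the lower index
      drop <- if (score_i < score_j) i else if (score_j < score_i) j
              else min(i, j)
    } else {
      he_wo_i <- he_of_rows(dataset$genotypes, setdiff(remaining, i))
      he_wo_j <- he_of_rows(dataset$genotypes, setdiff(remaining, j))
      drop <- if (he_wo_i > he_wo_j) i else if (he_wo_j > he_wo_i) j
              else min(i, j)
    }
    remaining <- setdiff(remaining, drop)
    trace <- rbind(trace, data.frame(step = step, pair_i = i,
                                     pair_j = j, eliminated = drop))
  }
  core <- core_subset(remaining, n)
  attr(core, "trace") <- trace
  core
}
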