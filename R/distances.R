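#' Modified Rogers distance between two accessions
#'
#' Euclidean-type distance between allele-frequency profiles, scaled so
#' that two homozygotes for different alleles at every locus are at
#' distance 1:
#' \deqn{MR(i, j) = \sqrt{ \sum_l \sum_a (p_{ila} - p_{jla})^2 / (2 L) }}
#' Loci missing in either accession are dropped pairwise and `L` is the
#' number of mutually observed loci.
#'
#' @param geno a [genotype_matrix()].
#' @param i,j accession indices (1-based), `i != j` allowed equal only
#'   for the trivial zero case.
#' @return distance in `[0, 1]`.
#' @export
modified_rogers <- function(geno, i, j) {
  fi <- geno$freq[i, ]
  fj <- geno$freq[j, ]
  obs <- !(is.na(fi) | is.na(fj))
  loci_obs <- unique(geno$locus_of[obs])
  if (!length(loci_obs)) {
    stop("accessions ", geno$ids[i], " and ", geno$ids[j],
         " share no observed locus")
  }
  sq <- sum((fi[obs] - fj[obs])^2)
  sqrt(sq / (2 * length(loci_obs)))
}

#' Gower distance between two accessions
#'
#' Mean over mutually observed traits of a per-trait dissimilarity:
#' `|x - y| / range` for quantitative traits (0 when the observed range
#' is 0), and 0/1 matching for qualitative traits. All traits carry
#' equal weight. Ranges are the observed ranges stored in the table.
#'
#' @param pheno a [phenotype_table()].
#' @param i,j accession indices (1-based).
#' @return distance in `[0, 1]`.
#' @export
gower_distance <- function(pheno, i, j) {
  contrib <- gower_trait_contrib(pheno, i, j)
  if (!length(contrib)) {
    stop("accessions ", pheno$ids[i], " and ", pheno$ids[j],
         " share no observed trait")
  }
  mean(contrib)
}

gower_trait_contrib <- function(pheno, i, j) {
  out <- numeric(0)
  for (t in seq_len(nrow(pheno$traits))) {
    x <- pheno$values[i, t]
    y <- pheno$values[j, t]
    if (is.na(x) || is.na(y)) next
    if (pheno$traits$kind[t] == "quantitative") {
      rng <- pheno$traits$max[t] - pheno$traits$min[t]
      out <- c(out, if (rng == 0) 0 else abs(x - y) / rng)
    } else {
      out <- c(out, as.numeric(x != y))
    }
  }
  out
}

#' Full pairwise distance matrix for a dataset
#'
#' @param dataset a [core_dataset()].
#' @param kind `"modified_rogers"` (requires genotypes), `"gower"`
#'   (requires phenotypes) or `"precomputed"` (passes the stored
#'   [distance_matrix()] through unchanged).
#' @return a [distance_matrix()].
#' @export
pairwise_matrix <- function(dataset,
                            kind = c("modified_rogers", "gower",
                                     "precomputed")) {
  kind <- match.arg(kind)
  switch(kind,
    precomputed = {
      if (is.null(dataset$distances)) {
        stop("dataset has no precomputed distance matrix")
      }
      dataset$distances
    },
    modified_rogers = {
      if (is.null(dataset$genotypes)) {
        stop("Modified Rogers distance requires genotype data")
      }
      mr_matrix(dataset$genotypes)
    },
    gower = {
      if (is.null(dataset$phenotypes)) {
        stop("Gower distance requires phenotype data")
      }
      gower_matrix(dataset$phenotypes)
    }
  )
}

# Vectorized Modified Rogers over all pairs. With missing loci the
# squared difference sum and the mutually-observed locus count are both
# assembled from cross products, so the result matches the element-wise
# definition with pairwise deletion.
mr_matrix <- function(geno) {
  G <- geno$freq
  n <- nrow(G)
  L <- length(geno$locus_names)
  obsL <- matrix(TRUE, n, L)
  for (l in seq_len(L)) {
    obsL[, l] <- !is.na(G[, which(geno$locus_of == l)[1]])
  }
  G0 <- G
  G0[is.na(G0)] <- 0
  # per-locus sum of squared frequencies, n x L
  S2 <- t(rowsum(t(G0^2), group = geno$locus_of))
  O <- obsL * 1
  Lobs <- tcrossprod(O)
  if (any(Lobs[upper.tri(Lobs)] == 0)) {
    stop("some accession pair shares no observed locus")
  }
  # S2 is zero at loci missing in the row accession, so S2 %*% t(O)
  # already restricts to mutually observed loci; same for the cross term
  sq <- S2 %*% t(O) + O %*% t(S2) - 2 * tcrossprod(G0)
  d <- sqrt(pmax(sq, 0) / (2 * Lobs))
  diag(d) <- 0
  distance_matrix(pmin(d, 1), accessions = geno$ids)
}

gower_matrix <- function(pheno) {
  n <- length(pheno$ids)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (t in seq_len(nrow(pheno$traits))) {
    v <- pheno$values[[t]]
    obs <- !is.na(v)
    w <- tcrossprod(obs * 1)
    if (pheno$traits$kind[t] == "quantitative") {
      rng <- pheno$traits$max[t] - pheno$traits$min[t]
      v0 <- ifelse(obs, v, 0)
      diff <- abs(outer(v0, v0, "-"))
      contrib <- if (rng == 0) 0 * diff else diff / rng
    } else {
      v0 <- ifelse(obs, v, "\r")
      contrib <- outer(v0, v0, "!=") * 1
    }
    num <- num + contrib * w
    den <- den + w
  }
  if (any(den[upper.tri(den)] == 0)) {
    stop("some accession pair shares no observed trait")
  }
  d <- num / den
  diag(d) <- 0
  distance_matrix(pmin(pmax(d, 0), 1), accessions = pheno$ids)
}
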