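# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Specification for the synthetic data generators
#'
#' The defaults emulate the structural features of typical germplasm
#' panels: a SNP panel of a few hundred markers over ~100 accessions
#' (maize-like), an SSR panel with 2--10 alleles per locus
#' (coconut-like) when `marker_model = "multiallelic-SSR"`, and a mixed
#' trait table of 28 qualitative plus 11 quantitative traits
#' (rice-like).
#'
#' @param n number of accessions (`>= 3`).
#' @param marker_model `"biallelic-SNP"` or `"multiallelic-SSR"`.
#' @param loci number of marker loci.
#' @param alleles_range integer range of alleles per SSR locus.
#' @param spread allele-frequency prior spread in `[0, 1]`: 1 draws
#'   population allele frequencies uniformly, 0 collapses every locus
#'   to monomorphism.
#' @param duplicate_groups number of planted duplicate groups.
#' @param duplicate_copies accessions per duplicate group (identical
#'   copies, zero mutual distance).
#' @param missing_rate probability that a locus (or trait) observation
#'   is missing, in `[0, 1]`.
#' @param n_qualitative,n_quantitative trait counts for
#'   [generate_phenotypes()].
#' @param categories_range integer range of category counts for
#'   qualitative traits.
#' @param seed integer seed; all generators are bit-identical for equal
#'   seeds.
#' @return an object of class `cs_synthetic_spec`.
#' @export
synthetic_spec <- function(n = 100, marker_model = c("biallelic-SNP",
                                                     "multiallelic-SSR"),
                           loci = 200, alleles_range = c(2, 10),
                           spread = 1, duplicate_groups = 0,
                           duplicate_copies = 2, missing_rate = 0,
                           n_qualitative = 28, n_quantitative = 11,
                           categories_range = c(2, 6), seed = 1) {
  marker_model <- match.arg(marker_model)
  if (n < 3) stop("n must be at least 3")
  if (missing_rate < 0 || missing_rate > 1 || spread < 0 || spread > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (duplicate_groups * duplicate_copies > n) {
    stop("duplicate groups exceed the collection size")
  }
  structure(as.list(environment()), class = "cs_synthetic_spec")
}

#' Generate a synthetic genotype matrix
#'
#' Population allele frequencies are drawn per locus from a symmetric
#' prior whose spread is controlled by `spec$spread`; accession-level
#' frequency vectors are then sampled as diploid genotypes (binomial
#' dosages for SNPs, two allele draws for SSRs). Planted duplicate
#' groups, if requested, are injected afterwards via
#' [inject_duplicates()] and reported in attribute `"duplicate_groups"`.
#'
#' @param spec a [synthetic_spec()].
#' @return a valid [genotype_matrix()].
#' @export
generate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "cs_synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    L <- spec$loci
    ids <- sprintf("acc%03d", seq_len(n))
    if (spec$marker_model == "biallelic-SNP") {
      b <- stats::rbinom(L, 1, 0.5)
      pop <- (1 - spec$spread) * b + spec$spread * stats::runif(L)
      freq <- matrix(NA_real_, n, 2L * L)
      for (l in seq_len(L)) {
        g <- stats::rbinom(n, 2, pop[l]) / 2
        freq[, 2L * l - 1L] <- g
        freq[, 2L * l] <- 1 - g
      }
      loci_names <- sprintf("snp%04d", seq_len(L))
      colnames(freq) <- as.vector(rbind(paste0(loci_names, ".A"),
                                        paste0(loci_names, ".B")))
    } else {
      n_alleles <- sample(seq(spec$alleles_range[1],
                              spec$alleles_range[2]), L, replace = TRUE)
      blocks <- list()
      for (l in seq_len(L)) {
        na_l <- n_alleles[l]
        w <- stats::rgamma(na_l, 1)
        w <- w / sum(w)
        major <- sample.int(na_l, 1)
        e <- as.numeric(seq_len(na_l) == major)
        w <- (1 - spec$spread) * e + spec$spread * w
        block <- matrix(0, n, na_l)
        for (i in seq_len(n)) {
          al <- sample.int(na_l, 2, replace = TRUE, prob = w)
          block[i, ] <- tabulate(al, na_l) / 2
        }
        colnames(block) <- sprintf("ssr%03d.a%02d", l, seq_len(na_l))
        blocks[[l]] <- block
      }
      freq <- do.call(cbind, blocks)
    }
    if (spec$missing_rate > 0) {
      locus_of <- sub("\\.[^.]*$", "", colnames(freq))
      for (l in unique(locus_of)) {
        miss <- stats::runif(n) < spec$missing_rate
        freq[miss, locus_of == l] <- NA_real_
      }
    }
    geno <- genotype_matrix(freq, accessions = ids)
    if (spec$duplicate_groups > 0) {
      inj <- inject_duplicates(geno, spec$duplicate_groups,
                               spec$duplicate_copies,
                               seed = spec$seed + 1)
      geno <- inj$data
      attr(geno, "duplicate_groups") <- inj$group_map
    }
    geno
  })
}

#' Generate a synthetic phenotype table
#'
#' Qualitative traits are sampled uniformly over per-trait category
#' sets; quantitative traits uniformly over per-trait ranges of varying
#' width (zero-width ranges are allowed by passing degenerate
#' `categories_range`/custom specs and contribute 0 to Gower).
#'
#' @param spec a [synthetic_spec()].
#' @return a valid [phenotype_table()].
#' @export
generate_phenotypes <- function(spec) {
  stopifnot(inherits(spec, "cs_synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    ids <- sprintf("acc%03d", seq_len(n))
    vals <- list()
    kinds <- character(0)
    for (t in seq_len(spec$n_qualitative)) {
      ncat <- sample(seq(spec$categories_range[1],
                         spec$categories_range[2]), 1)
      v <- sample(paste0("cat", seq_len(ncat)), n, replace = TRUE)
      if (spec$missing_rate > 0) {
        v[stats::runif(n) < spec$missing_rate] <- NA
      }
      vals[[sprintf("qual%02d", t)]] <- v
      kinds <- c(kinds, "qualitative")
    }
    for (t in seq_len(spec$n_quantitative)) {
      lo <- stats::runif(1, 0, 10)
      width <- stats::runif(1, 0.5, 10)
      v <- stats::runif(n, lo, lo + width)
      if (spec$missing_rate > 0) {
        v[stats::runif(n) < spec$missing_rate] <- NA
      }
      vals[[sprintf("quant%02d", t)]] <- v
      kinds <- c(kinds, "quantitative")
    }
    pheno <- phenotype_table(as.data.frame(vals,
                                           stringsAsFactors = FALSE),
                             kinds = kinds, accessions = ids)
    if (spec$duplicate_groups > 0) {
      inj <- inject_duplicates(pheno, spec$duplicate_groups,
                               spec$duplicate_copies,
                               seed = spec$seed + 1)
      pheno <- inj$data
      attr(pheno, "duplicate_groups") <- inj$group_map
    }
    pheno
  })
}

#' Plant groups of exact duplicate accessions
#'
#' Overwrites randomly chosen accessions with exact copies of a group
#' template so that all within-group pairs are at distance 0 under both
#' the Modified Rogers and Gower measures. Used to probe duplicate
#' avoidance: any core containing two members of one group gains
#' nothing in E-NE from the second member.
#'
#' @param data a [genotype_matrix()] or [phenotype_table()].
#' @param groups number of duplicate groups.
#' @param copies accessions per group (including the template).
#' @param seed integer seed for choosing the affected accessions.
#' @return list with `data` (modified copy) and `group_map`
#'   (data.frame: `accession` index, `group`).
#' @export
inject_duplicates <- function(data, groups, copies, seed = 1) {
  n <- length(accession_ids(data))
  total <- groups * copies
  if (total > n) stop("groups x copies exceeds the collection size")
  with_seed(seed, {
    chosen <- sample.int(n, total)
    group <- rep(seq_len(groups), each = copies)
    for (g in seq_len(groups)) {
      members <- chosen[group == g]
      template <- members[1]
      for (m in members[-1]) {
        if (inherits(data, "genotype_matrix")) {
          data$freq[m, ] <- data$freq[template, ]
        } else {
          data$values[m, ] <- data$values[template, ]
        }
      }
    }
    list(data = data,
         group_map = data.frame(accession = chosen, group = group))
  })
}

#' Generate a synthetic distance matrix directly
#'
#' `"uniform"` draws off-diagonal entries independently from U(0, 1)
#' (the triangle inequality is deliberately not enforced: none of the
#' nearest-entry measures require metricity). `"clustered"` places
#' accessions in latent groups with small within-group distances
#' (U(0.02, 0.15)) and large between-group distances (U(0.4, 0.95)),
#' so the minimum between-group distance always exceeds the maximum
#' within-group distance.
#'
#' @param n number of accessions (`>= 3`).
#' @param seed integer seed.
#' @param structure `"uniform"` or `"clustered"`.
#' @param groups number of latent groups for the clustered structure.
#' @return a [distance_matrix()]; for the clustered structure the group
#'   labels are attached as attribute `"groups"`.
#' @export
generate_distance_matrix <- function(n, seed = 1,
                                     structure = c("uniform",
                                                   "clustered"),
                                     groups = 4) {
  structure_kind <- match.arg(structure)
  if (n < 3) stop("n must be at least 3")
  with_seed(seed, {
    d <- matrix(0, n, n)
    if (structure_kind == "uniform") {
      d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2)
    } else {
      grp <- sample(rep_len(seq_len(groups), n))
      same <- outer(grp, grp, "==")[upper.tri(d)]
      m <- sum(upper.tri(d))
      vals <- numeric(m)
      vals[same] <- stats::runif(sum(same), 0.02, 0.15)
      vals[!same] <- stats::runif(sum(!same), 0.4, 0.95)
      d[upper.tri(d)] <- vals
    }
    d <- d + t(d)
    out <- distance_matrix(d, accessions = sprintf("acc%03d",
                                                   seq_len(n)))
    if (structure_kind == "clustered") attr(out, "groups") <- grp
    out
  })
}
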