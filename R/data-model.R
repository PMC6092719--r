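#' Construct a genotype matrix of per-accession allele frequencies
#'
#' A `genotype_matrix` stores, for every accession and marker locus, a
#' vector of within-accession allele frequencies. For a biallelic SNP
#' scored as a dosage g in \{0, 1, 2\} the two frequencies are g/2 and
#' 1 - g/2; for multiallelic markers (e.g. SSRs) the vector has one entry
#' per observed allele. Every non-missing frequency vector must sum to 1.
#' A locus that was not scored for an accession is recorded as `NA` across
#' the whole locus block and is handled by pairwise deletion downstream.
#'
#' @param frequencies numeric matrix, accessions x allele columns. Column
#'   names must be `"locus.allele"`; row names are the accession ids
#'   unless `accessions` is given.
#' @param loci character/factor of length `ncol(frequencies)` giving the
#'   locus each column belongs to. Defaults to the part of the column
#'   name before the last `"."`.
#' @param accessions character vector of unique accession ids.
#' @return an object of class `genotype_matrix` with elements `ids`,
#'   `freq` (numeric matrix), `locus_of` (integer column -> locus map),
#'   `locus_names`, and `alleles` (list of allele names per locus).
#' @export
genotype_matrix <- function(frequencies, loci = NULL,
                            accessions = rownames(frequencies)) {
  frequencies <- as.matrix(frequencies)
  storage.mode(frequencies) <- "double"
  if (is.null(accessions)) {
    stop("accession ids are required (row names or `accessions`)")
  }
  if (is.null(loci)) {
    cn <- colnames(frequencies)
    if (is.null(cn)) stop("column names 'locus.allele' or `loci` required")
    loci <- sub("\\.[^.]*$", "", cn)
  }
  loci <- as.character(loci)
  locus_names <- unique(loci)
  locus_of <- match(loci, locus_names)
  allele_names <- if (!is.null(colnames(frequencies))) {
    sub("^.*\\.", "", colnames(frequencies))
  } else {
    as.character(stats::ave(seq_along(loci), loci, FUN = seq_along))
  }
  obj <- structure(
    list(
      ids = as.character(accessions),
      freq = frequencies,
      locus_of = locus_of,
      locus_names = locus_names,
      alleles = split(allele_names, factor(loci, levels = locus_names))
    ),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(obj)
  obj
}

validate_genotype_matrix <- function(x) {
  n <- length(x$ids)
  if (n < 3L) stop("a genotype matrix needs at least 3 accessions")
  if (anyDuplicated(x$ids)) stop("duplicate accession ids")
  if (nrow(x$freq) != n) stop("frequency rows do not match accession ids")
  L <- length(x$locus_names)
  if (L < 1L) stop("at least one locus is required")
  if (any(vapply(x$alleles, length, 1L) < 2L)) {
    stop("every locus needs at least 2 alleles")
  }
  f <- x$freq
  if (any(f < -1e-9 | f > 1 + 1e-9, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  for (l in seq_len(L)) {
    cols <- which(x$locus_of == l)
    block <- f[, cols, drop = FALSE]
    miss <- rowSums(is.na(block))
    partial <- miss > 0L & miss < length(cols)
    if (any(partial)) {
      stop("locus ", x$locus_names[l],
           ": frequencies must be missing for all alleles or none")
    }
    s <- rowSums(block)
    bad <- which(!is.na(s) & abs(s - 1) > 1e-6)
    if (length(bad)) {
      stop("locus ", x$locus_names[l], ": frequencies of accession ",
           x$ids[bad[1]], " sum to ", format(s[bad[1]]), ", not 1")
    }
  }
  invisible(x)
}

#' Number of accessions in a collection object
#' @param x a `genotype_matrix`, `phenotype_table`, `distance_matrix` or
#'   `core_dataset`.
#' @return integer count of accessions.
#' @export
n_accessions <- function(x) length(accession_ids(x))

#' Accession identifiers of a collection object
#' @inheritParams n_accessions
#' @return character vector of ids, in collection order.
#' @export
accession_ids <- function(x) UseMethod("accession_ids")

#' @export
accession_ids.genotype_matrix <- function(x) x$ids
#' @export
accession_ids.phenotype_table <- function(x) x$ids
#' @export
accession_ids.distance_matrix <- function(x) x$ids
#' @export
accession_ids.core_dataset <- function(x) x$ids

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d loci (%d allele columns)\n",
              length(x$ids), length(x$locus_names), ncol(x$freq)))
  invisible(x)
}

#' Construct a phenotype table of mixed qualitative/quantitative traits
#'
#' @param values data.frame of trait values (one row per accession).
#'   Quantitative traits must be numeric; qualitative traits are coerced
#'   to character. `NA` marks a missing observation.
#' @param kinds character vector (`"qualitative"` / `"quantitative"`),
#'   one per trait column.
#' @param accessions character vector of unique accession ids.
#' @return an object of class `phenotype_table` with elements `ids`,
#'   `traits` (data.frame: name, kind, min, max with the observed range
#'   of each quantitative trait) and `values`.
#' @export
phenotype_table <- function(values, kinds, accessions = rownames(values)) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (is.null(accessions)) stop("accession ids are required")
  accessions <- as.character(accessions)
  if (anyDuplicated(accessions)) stop("duplicate accession ids")
  if (length(kinds) != ncol(values)) {
    stop("`kinds` must name one kind per trait column")
  }
  kinds <- match.arg(kinds, c("qualitative", "quantitative"),
                     several.ok = TRUE)
  rng_min <- rng_max <- rep(NA_real_, ncol(values))
  for (j in seq_along(values)) {
    v <- values[[j]]
    if (all(is.na(v))) {
      stop("trait ", names(values)[j], " has no observed values")
    }
    if (kinds[j] == "quantitative") {
      if (!is.numeric(v)) {
        suppressWarnings(vn <- as.numeric(v))
        if (anyNA(vn) != anyNA(v) || any(is.na(vn) & !is.na(v))) {
          stop("non-numeric value in quantitative trait ", names(values)[j])
        }
        v <- vn
      }
      rng_min[j] <- min(v, na.rm = TRUE)
      rng_max[j] <- max(v, na.rm = TRUE)
      values[[j]] <- v
    } else {
      values[[j]] <- as.character(v)
    }
  }
  rownames(values) <- accessions
  structure(
    list(
      ids = accessions,
      traits = data.frame(name = names(values), kind = kinds,
                          min = rng_min, max = rng_max,
                          stringsAsFactors = FALSE),
      values = values
    ),
    class = "phenotype_table"
  )
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d accessions x %d traits (%d qualitative, %d quantitative)\n",
              length(x$ids), nrow(x$traits),
              sum(x$traits$kind == "qualitative"),
              sum(x$traits$kind == "quantitative")))
  invisible(x)
}

#' Construct a symmetric accession-by-accession distance matrix
#'
#' @param d numeric n x n matrix, symmetric (tolerance 1e-9), zero
#'   diagonal, non-negative entries.
#' @param accessions character vector of unique ids (defaults to the
#'   row names of `d`).
#' @return an object of class `distance_matrix` with elements `ids` and
#'   `d` (the matrix, with ids as dimnames).
#' @export
distance_matrix <- function(d, accessions = rownames(d)) {
  d <- as.matrix(d)
  storage.mode(d) <- "double"
  if (is.null(accessions)) accessions <- paste0("acc", seq_len(nrow(d)))
  accessions <- as.character(accessions)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (anyDuplicated(accessions)) stop("duplicate accession ids")
  if (length(accessions) != nrow(d)) stop("ids do not match matrix size")
  if (any(is.na(d))) stop("distances may not be missing")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be exactly 0")
  if (any(d < 0)) stop("distances must be non-negative")
  d <- (d + t(d)) / 2  # remove sub-tolerance asymmetry
  dimnames(d) <- list(accessions, accessions)
  structure(list(ids = accessions, d = d), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d accessions, entries in [%.4g, %.4g]\n",
              length(x$ids), min(x$d), max(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Construct a core subset (a set of selected accession indices)
#'
#' @param selected integer vector of selected accession indices
#'   (1-based, distinct).
#' @param n total number of accessions in the collection.
#' @return an object of class `core_subset` with elements `selected`
#'   (sorted indices), `k` and `n`. Requires `2 <= k <= n - 1`: a core
#'   of size 1 has no "closest other entry" so entry-to-nearest-entry
#'   would be undefined.
#' @export
core_subset <- function(selected, n) {
  selected <- sort(as.integer(selected))
  k <- length(selected)
  if (anyDuplicated(selected)) stop("selected indices must be distinct")
  if (k < 2L || k > n - 1L) {
    stop("core size must satisfy 2 <= k <= n - 1 (got k = ", k,
         ", n = ", n, ")")
  }
  if (selected[1] < 1L || selected[k] > n) stop("index out of range")
  structure(list(selected = selected, k = k, n = as.integer(n)),
            class = "core_subset")
}

#' @export
print.core_subset <- function(x, ...) {
  cat(sprintf("core_subset: %d of %d accessions selected\n", x$k, x$n))
  invisible(x)
}

#' Bundle genotype, phenotype and/or distance data for one collection
#'
#' All supplied components must list identical accession ids in
#' identical order; objectives later declare which component they read.
#'
#' @param genotypes optional [genotype_matrix()].
#' @param phenotypes optional [phenotype_table()].
#' @param distances optional [distance_matrix()] (precomputed).
#' @return an object of class `core_dataset`.
#' @export
core_dataset <- function(genotypes = NULL, phenotypes = NULL,
                         distances = NULL) {
  parts <- list(genotypes = genotypes, phenotypes = phenotypes,
                distances = distances)
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) stop("at least one data component is required")
  ids <- accession_ids(parts[[1]])
  for (p in parts) {
    if (!identical(accession_ids(p), ids)) {
      stop("all dataset components must share accession ids and order")
    }
  }
  structure(list(ids = ids, genotypes = genotypes,
                 phenotypes = phenotypes, distances = distances),
            class = "core_dataset")
}

#' @export
print.core_dataset <- function(x, ...) {
  comp <- c(if (!is.null(x$genotypes)) "genotypes",
            if (!is.null(x$phenotypes)) "phenotypes",
            if (!is.null(x$distances)) "distances")
  cat(sprintf("core_dataset: %d accessions [%s]\n", length(x$ids),
              paste(comp, collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# readers / writers

#' Read genotype data from CSV
#'
#' Two dialects are supported. `"dosage"`: a header of marker names and
#' one row per accession (`id,2,0,1,...`) with integer allele dosages 0,
#' 1, 2 or empty/NA; dosage g becomes the biallelic frequency pair
#' (g/2, 1 - g/2). `"frequency"`: columns named `locus.allele` holding
#' explicit allele frequencies; the frequencies of each locus must sum to
#' 1 (tolerance 1e-6; violations are an error, never renormalized, so
#' that downstream evaluation is deterministic).
#'
#' @param path CSV file path.
#' @param dialect `"dosage"` or `"frequency"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("dosage", "frequency")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(tab) < 2L) stop("expected an id column plus data columns")
  ids <- tab[[1]]
  if (anyDuplicated(ids)) stop("duplicate accession ids in ", path)
  raw <- as.matrix(tab[, -1, drop = FALSE])
  raw[raw %in% c("", "NA")] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                 dimnames = dimnames(raw)))
  if (any(is.na(num) & !is.na(raw))) {
    stop("non-numeric genotype value in ", path)
  }
  if (dialect == "dosage") {
    ok <- is.na(num) | num %in% c(0, 1, 2)
    if (!all(ok)) {
      stop("dosage values must be 0, 1 or 2 (or missing) in ", path)
    }
    markers <- colnames(num)
    freq <- matrix(NA_real_, nrow(num), 2L * ncol(num))
    freq[, seq(1, ncol(freq), by = 2)] <- num / 2
    freq[, seq(2, ncol(freq), by = 2)] <- 1 - num / 2
    colnames(freq) <- as.vector(rbind(paste0(markers, ".A"),
                                      paste0(markers, ".B")))
    genotype_matrix(freq, accessions = ids)
  } else {
    genotype_matrix(num, accessions = ids)
  }
}

#' Write genotype data to CSV (frequency dialect)
#'
#' @param geno a [genotype_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  out <- data.frame(id = geno$ids, geno$freq, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read phenotype data from CSV
#'
#' @param path CSV with a header of trait names and one row per
#'   accession, first column the accession id.
#' @param trait_spec named character vector mapping every trait column to
#'   `"qualitative"` or `"quantitative"`.
#' @return a [phenotype_table()]; quantitative ranges are the observed
#'   min/max.
#' @export
read_phenotypes <- function(path, trait_spec) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  ids <- tab[[1]]
  vals <- tab[, -1, drop = FALSE]
  vals[vals == ""] <- NA
  unknown <- setdiff(names(trait_spec), names(vals))
  if (length(unknown)) {
    stop("trait_spec names unknown trait(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!all(names(vals) %in% names(trait_spec))) {
    stop("trait_spec must cover every trait column")
  }
  phenotype_table(vals, kinds = unname(trait_spec[names(vals)]),
                  accessions = ids)
}

#' Write phenotype data to CSV
#' @param pheno a [phenotype_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  out <- data.frame(id = pheno$ids, pheno$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a precomputed symmetric distance matrix from CSV
#'
#' @param path square CSV with accession ids in the first row and first
#'   column. Asymmetry beyond 1e-9, a nonzero diagonal, or a non-square
#'   table are errors.
#' @return a [distance_matrix()].
#' @export
read_distance_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("distance matrix in ", path, " is not square")
  if (!identical(ids, colnames(m))) {
    stop("row and column ids differ in ", path)
  }
  distance_matrix(m, accessions = ids)
}

#' Write a distance matrix to CSV
#' @param dmat a [distance_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dmat, path) {
  out <- data.frame(id = dmat$ids, dmat$d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("id", dmat$ids)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a selected core to a plain-text file
#'
#' The file holds an optional header block of evaluated measures
#' (`# measure value`, 6 decimal digits) followed by the selected
#' accession ids, one per line.
#'
#' @param core a [core_subset()].
#' @param dataset the [core_dataset()] the core was selected from
#'   (supplies the accession ids).
#' @param path output file path.
#' @param report optional named numeric vector of evaluated measures to
#'   record in the header.
#' @return `path`, invisibly.
#' @export
write_core <- function(core, dataset, path, report = NULL) {
  ids <- accession_ids(dataset)[core$selected]
  lines <- character(0)
  if (length(report)) {
    lines <- sprintf("# %s %.6f", names(report), as.numeric(report))
  }
  writeLines(c(lines, ids), path)
  invisible(path)
}

#' Read a core file written by [write_core()]
#'
#' @param path core file path.
#' @param dataset the [core_dataset()] the core refers to.
#' @return a list with `core` (a [core_subset()]), `ids` and `report`
#'   (named numeric vector, possibly empty).
#' @export
read_core <- function(path, dataset) {
  lines <- readLines(path)
  hdr <- grepl("^# ", lines)
  report <- numeric(0)
  if (any(hdr)) {
    parts <- strsplit(sub("^# ", "", lines[hdr]), " ")
    report <- vapply(parts, function(p) as.numeric(p[2]), 1)
    names(report) <- vapply(parts, `[`, "", 1)
  }
  ids <- lines[!hdr & nzchar(lines)]
  all_ids <- accession_ids(dataset)
  idx <- match(ids, all_ids)
  if (anyNA(idx)) stop("core file lists unknown accession id(s)")
  list(core = core_subset(idx, length(all_ids)), ids = ids,
       report = report)
}
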