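test_that("dosage CSV rows convert to biallelic frequency pairs", {
  path <- write_tmp_csv(c("id,m1,m2", "acc1,2,0", "acc2,1,1",
                          "acc3,0,2"))
  geno <- read_genotypes(path, dialect = "dosage")
  expect_equal(unname(geno$freq[1, ]), c(1, 0, 0, 1))
  expect_equal(unname(geno$freq[2, ]), c(0.5, 0.5, 0.5, 0.5))
  expect_equal(length(geno$locus_names), 2L)
  # conversion preserves 2 alleles per locus and frequency sum 1
  for (l in 1:2) {
    block <- geno$freq[, geno$locus_of == l]
    expect_equal(ncol(block), 2L)
    expect_equal(unname(rowSums(block)), rep(1, 3))
  }
})

test_that("invalid genotype input is rejected", {
  bad_dosage <- write_tmp_csv(c("id,m1", "a,3", "b,1", "c,0"))
  expect_error(read_genotypes(bad_dosage, "dosage"), "dosage")
  bad_freq <- write_tmp_csv(c("id,l1.A,l1.B", "a,0.5,0.4", "b,1,0",
                              "c,0,1"))
  expect_error(read_genotypes(bad_freq, "frequency"), "sum")
  dup <- write_tmp_csv(c("id,m1", "a,1", "a,2", "c,0"))
  expect_error(read_genotypes(dup, "dosage"), "duplicate")
})

test_that("phenotype reader computes observed quantitative ranges", {
  path <- write_tmp_csv(c("id,height,color", "a,2,red", "b,7,blue",
                          "c,4,red"))
  spec <- c(height = "quantitative", color = "qualitative")
  ph <- read_phenotypes(path, spec)
  expect_equal(ph$traits$min[1], 2)
  expect_equal(ph$traits$max[1], 7)
  expect_equal(length(unique(stats::na.omit(ph$values$color))), 2L)
  # all-missing column
  path2 <- write_tmp_csv(c("id,x", "a,", "b,", "c,"))
  expect_error(read_phenotypes(path2, c(x = "quantitative")), "observed")
  # non-numeric quantitative value
  path3 <- write_tmp_csv(c("id,x", "a,1", "b,tall", "c,2"))
  expect_error(read_phenotypes(path3, c(x = "quantitative")),
               "non-numeric")
  # unknown trait in spec
  expect_error(read_phenotypes(path, c(height = "quantitative",
                                       color = "qualitative",
                                       ghost = "qualitative")),
               "unknown")
})

test_that("distance matrix reader enforces symmetry and zero diagonal", {
  ok <- write_tmp_csv(c("id,a,b,c", "a,0,0.3,0.5", "b,0.3,0,0.2",
                        "c,0.5,0.2,0"))
  dm <- read_distance_matrix(ok)
  expect_s3_class(dm, "distance_matrix")
  asym <- write_tmp_csv(c("id,a,b,c", "a,0,0.3,0.5", "b,0.4,0,0.2",
                          "c,0.5,0.2,0"))
  expect_error(read_distance_matrix(asym), "symmetric")
  diag_bad <- write_tmp_csv(c("id,a,b,c", "a,0.1,0.3,0.5",
                              "b,0.3,0,0.2", "c,0.5,0.2,0"))
  expect_error(read_distance_matrix(diag_bad), "diagonal")
  nonsq <- write_tmp_csv(c("id,a,b", "a,0,0.3", "b,0.3,0", "c,0.5,0.2"))
  expect_error(read_distance_matrix(nonsq), "square")
})

test_that("core files round-trip ids, selection and report", {
  ds <- toy_dataset()
  core <- core_subset(c(2, 4), 4)
  path <- tempfile()
  write_core(core, ds, path, report = c(`E-NE` = 0.7, DMIN = 0.7))
  back <- read_core(path, ds)
  expect_equal(back$core$selected, core$selected)
  expect_equal(back$ids, c("acc2", "acc4"))
  expect_equal(unname(back$report), c(0.7, 0.7))
  # formatting contract: 6 decimal digits in header lines
  expect_match(readLines(path)[1], "^# E-NE 0\\.700000$")
  # empty report: ids only
  write_core(core, ds, path)
  expect_equal(readLines(path), c("acc2", "acc4"))
})

test_that("genotype, phenotype and distance CSVs round-trip", {
  spec <- synthetic_spec(n = 8, loci = 5, seed = 3, missing_rate = 0.1)
  geno <- generate_genotypes(spec)
  gpath <- tempfile(fileext = ".csv")
  write_genotypes(geno, gpath)
  geno2 <- read_genotypes(gpath, dialect = "frequency")
  expect_equal(geno2$ids, geno$ids)
  expect_equal(geno2$freq, geno$freq, tolerance = 1e-12)

  pheno <- generate_phenotypes(synthetic_spec(n = 6, n_qualitative = 2,
                                              n_quantitative = 2,
                                              seed = 4))
  ppath <- tempfile(fileext = ".csv")
  write_phenotypes(pheno, ppath)
  kinds <- stats::setNames(pheno$traits$kind, pheno$traits$name)
  pheno2 <- read_phenotypes(ppath, kinds)
  expect_equal(pheno2$ids, pheno$ids)
  expect_equal(pheno2$values$qual01, pheno$values$qual01)
  expect_equal(pheno2$values$quant01, pheno$values$quant01,
               tolerance = 1e-6)

  dmat <- generate_distance_matrix(7, seed = 5)
  dpath <- tempfile(fileext = ".csv")
  write_distance_matrix(dmat, dpath)
  dmat2 <- read_distance_matrix(dpath)
  expect_equal(dmat2$ids, dmat$ids)
  expect_equal(dmat2$d, dmat$d, tolerance = 1e-12)
})

test_that("core subset and dataset invariants are enforced", {
  expect_error(core_subset(1, 4), "2 <= k")
  expect_error(core_subset(1:4, 4), "2 <= k")
  expect_error(core_subset(c(2, 2, 3), 5), "distinct")
  expect_silent(core_subset(c(3, 1), 4))
  d <- toy_dmat()
  g <- generate_genotypes(synthetic_spec(n = 5, loci = 3, seed = 1))
  expect_error(core_dataset(genotypes = g, distances = d), "share")
  expect_error(core_dataset(), "at least one")
})
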