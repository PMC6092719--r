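test_that("nearest-entry measures match hand-enumerated values", {
  d <- toy_dmat()
  core134 <- core_subset(c(1, 3, 4), 4)
  core24 <- core_subset(c(2, 4), 4)
  # E-NE {1,3,4}: nearest entries 3(0.5), 4(0.2), 3(0.2)
  expect_equal(entry_to_nearest_entry(d, core134), 0.3,
               tolerance = 1e-9)
  # k=2: E-NE equals the pairwise distance
  expect_equal(entry_to_nearest_entry(d, core24), 0.7)
  # A-NE {2,4}: (min(0.1,0.6) + 0 + min(0.4,0.2) + 0)/4
  expect_equal(accession_to_nearest_entry(d, core24), 0.075,
               tolerance = 1e-9)
  # DMIN {1,3,4}: min(0.5, 0.6, 0.2)
  expect_equal(min_distance(d, core134), 0.2)
  # avg-EE {1,3,4}: (0.5+0.6+0.2)/3
  expect_equal(average_entry_to_entry(d, core134), 1.3 / 3,
               tolerance = 1e-9)
  expect_equal(average_entry_to_entry(d, core24), 0.7)
})

test_that("duplicate entries contribute zero to E-NE and A-NE", {
  m <- matrix(0.5, 4, 4)
  diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 0  # accessions 1 and 2 identical
  d <- distance_matrix(m, paste0("a", 1:4))
  core <- core_subset(c(1, 2, 3), 4)
  # entries 1 and 2 contribute 0 each; entry 3 contributes 0.5
  expect_equal(entry_to_nearest_entry(d, core), 0.5 / 3)
  # every accession with a zero-distance selected duplicate -> A-NE 0
  # (3 duplicates 1, 4 duplicates 2; only 1 and 2 selected)
  m2 <- matrix(0, 4, 4)
  m2[1, 2] <- m2[2, 1] <- 0.5
  m2[1, 4] <- m2[4, 1] <- 0.5
  m2[2, 3] <- m2[3, 2] <- 0.5
  m2[3, 4] <- m2[4, 3] <- 0.5
  d2 <- distance_matrix(m2, paste0("a", 1:4))
  expect_equal(accession_to_nearest_entry(d2, core_subset(1:2, 4)), 0)
})

test_that("expected heterozygosity matches its worked examples", {
  # 1 locus, entries (1,0) and (0,1): p-hat = (0.5, 0.5), HE = 0.5
  g <- make_geno(list(c(1, 0), c(0, 1), c(1, 0)), 2)
  expect_equal(expected_heterozygosity(g, core_subset(1:2, 3)), 0.5)
  # second, monomorphic locus halves the average: (0.5 + 0)/2
  g2 <- make_geno(list(c(1, 0, 1, 0), c(0, 1, 1, 0), c(1, 0, 1, 0)),
                  c(2, 2))
  expect_equal(expected_heterozygosity(g2, core_subset(1:2, 3)), 0.25)
  # fully monomorphic core -> 0
  expect_equal(expected_heterozygosity(g, core_subset(c(1, 3), 3)), 0)
  # HE stays in [0,1] on random SSR data
  geno <- generate_genotypes(synthetic_spec(
    n = 15, loci = 8, marker_model = "multiallelic-SSR", seed = 12))
  for (s in 1:10) {
    core <- core_subset(sample.int(15, 5), 15)
    he <- expected_heterozygosity(geno, core)
    expect_true(he >= 0 && he <= 1)
  }
})

test_that("E-NE dominates DMIN on random matrices and cores", {
  for (s in 1:20) {
    d <- generate_distance_matrix(10, seed = 100 + s)
    k <- sample(2:8, 1)
    core <- core_subset(sample.int(10, k), 10)
    expect_gte(entry_to_nearest_entry(d, core), min_distance(d, core))
  }
})

test_that("for k = 2 the E-NE optimum is the most distant pair", {
  d <- generate_distance_matrix(9, seed = 42)
  bf <- brute_force_optimum(core_dataset(distances = d), ene_config(), 2)
  expect_equal(bf$value, max(d$d))
  pair <- which(d$d == max(d$d), arr.ind = TRUE)[1, ]
  expect_setequal(bf$core$selected, as.integer(pair))
})

test_that("weighted index normalizes, clamps and weight-sums", {
  ranges <- structure(list(table = data.frame(
    measure = c("E-NE", "A-NE"), lower = c(0, -1), upper = c(1, 0),
    degenerate = c(FALSE, FALSE))), class = "cs_norm_ranges")
  cfg <- objective_config(list(objective("E-NE", 0.5),
                               objective("A-NE", 0.5)))
  # normalized values 0.4 and 0.6 -> 0.5
  expect_equal(weighted_index(c(0.4, 0.4), cfg, ranges), 0.5)
  # minimized objective at its best (sign-adjusted upper) bound
  # contributes its full weight
  expect_equal(weighted_index(c(1, 0), cfg, ranges), 1)
  # values outside the bounds clamp to [0,1]
  expect_equal(weighted_index(c(2, 2), cfg, ranges), 0.5)
  # single objective, weight 1, no ranges: index is the raw value
  one <- objective_config(list(objective("E-NE")))
  d <- toy_dmat()
  ev <- evaluate_core(core_dataset(distances = d),
                      core_subset(c(1, 3, 4), 4), one)
  expect_equal(ev$index, 0.3, tolerance = 1e-9)
  expect_true("DMIN" %in% names(ev$report))
})

test_that("normalization bounds match an exhaustive Pareto oracle", {
  # instance with distinct, search-reachable single-objective optima,
  # so the exhaustive Pareto bounds are well defined and non-degenerate
  d <- generate_distance_matrix(6, seed = 2)
  ds <- core_dataset(distances = d)
  cfg <- objective_config(list(objective("E-NE", 0.5),
                               objective("A-NE", 0.5)))
  k <- 3
  ranges <- suppressWarnings(compute_normalization_ranges(
    ds, cfg, k, stop = stop_condition(max_stall_evals = 2000),
    seed = 5))
  # brute-force single-objective optima over all C(6,3)=20 subsets
  sub <- utils::combn(6, k)
  ene <- apply(sub, 2, function(s)
    entry_to_nearest_entry(d, core_subset(s, 6)))
  ane <- apply(sub, 2, function(s)
    -accession_to_nearest_entry(d, core_subset(s, 6)))
  best_ene <- which.max(ene)
  best_ane <- which.max(ane)
  expect_equal(ranges$table$upper[1], max(ene), tolerance = 1e-12)
  expect_equal(ranges$table$upper[2], max(ane), tolerance = 1e-12)
  expect_equal(ranges$table$lower[1],
               min(ene[best_ene], ene[best_ane]), tolerance = 1e-12)
  expect_equal(ranges$table$lower[2],
               min(ane[best_ene], ane[best_ane]), tolerance = 1e-12)
  expect_true(all(ranges$table$upper > ranges$table$lower))
})

test_that("degenerate normalization ranges are flagged", {
  # one subset simultaneously optimizes both objectives: duplicate
  # groups make E-NE and avg-EE optima coincide on a 2-cluster toy
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 1e-6
  m[3, 4] <- m[4, 3] <- 1e-6
  m[1, 3] <- m[3, 1] <- m[1, 4] <- m[4, 1] <- 1
  m[2, 3] <- m[3, 2] <- m[2, 4] <- m[4, 2] <- 1
  d <- distance_matrix(m, paste0("a", 1:4))
  cfg <- objective_config(list(objective("E-NE", 0.5),
                               objective("avg-EE", 0.5)))
  expect_warning(
    ranges <- compute_normalization_ranges(
      core_dataset(distances = d), cfg, 2,
      stop = stop_condition(max_stall_evals = 2000), seed = 1),
    "degenerate")
  expect_true(any(ranges$table$degenerate))
})

test_that("measure/data mismatches raise errors", {
  ds <- toy_dataset()
  he_cfg <- objective_config(list(objective("HE")))
  expect_error(evaluate_core(ds, core_subset(1:2, 4), he_cfg),
               "genotype")
  expect_error(objective("E-NE", weight = 0), "weight")
  expect_error(objective_config(list(objective("E-NE", 0.5),
                                     objective("HE", 0.2))),
               "sum to 1")
})
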