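test_that("acceptance and swap probabilities follow their formulas", {
  expect_equal(acceptance_probability(0.05, 1e-6), 1)
  expect_equal(acceptance_probability(-1e-4, 1e-4), exp(-1),
               tolerance = 1e-12)
  expect_equal(acceptance_probability(0, 1e-5), 1)
  expect_error(acceptance_probability(0.1, 0), "positive")

  expect_equal(swap_probability(0.01, 1e-8, 1e-4), 1)
  expect_equal(swap_probability(0, 1e-8, 1e-4), 1)
  expect_equal(swap_probability(-1.0001e-8, 1e-8, 1e-4), exp(-1),
               tolerance = 1e-4)
  expect_error(swap_probability(0.1, 1e-4, 1e-8), "temperatures")
})

test_that("the replica temperature ladder is equally spaced", {
  t <- replica_temperatures(10, 1e-8, 1e-4)
  expect_equal(t[1], 1e-8)
  expect_equal(t[10], 1e-4)
  expect_equal(diff(t), rep((1e-4 - 1e-8) / 9, 9))
})

test_that("the single-swap neighbourhood has k*(n-k) distinct moves", {
  core <- core_subset(c(2, 5, 7), 9)
  moves <- swap_neighbourhood(core)
  expect_equal(nrow(unique(moves)), 3 * 6)
  expect_true(all(moves$remove %in% core$selected))
  expect_false(any(moves$add %in% core$selected))
})

test_that("brute force enumerates the toy optima", {
  ds <- toy_dataset()
  bf2 <- brute_force_optimum(ds, ene_config(), 2)
  expect_equal(bf2$core$selected, c(2L, 4L))
  expect_equal(bf2$value, 0.7)
  bf3 <- brute_force_optimum(ds, ene_config(), 3)
  expect_equal(bf3$core$selected, c(1L, 3L, 4L))
  expect_equal(bf3$value, 0.3, tolerance = 1e-12)
})

test_that("random descent reaches the toy optimum and is deterministic", {
  ds <- toy_dataset()
  res <- random_descent(ds, ene_config(), 3,
                        stop_condition(max_evals = 500), seed = 11)
  expect_equal(res$core$selected, c(1L, 3L, 4L))
  expect_equal(res$value, 0.3, tolerance = 1e-12)
  res2 <- random_descent(ds, ene_config(), 3,
                         stop_condition(max_evals = 500), seed = 11)
  expect_identical(res$core$selected, res2$core$selected)
  # wall-clock column aside, traces are bit-identical
  expect_identical(res$trace$evals, res2$trace$evals)
  expect_identical(res$trace$value, res2$trace$value)
  # zero-budget run returns the evaluated initial core
  res0 <- random_descent(ds, ene_config(), 3,
                         stop_condition(max_evals = 0), seed = 11)
  expect_equal(res0$core$k, 3)
  expect_equal(nrow(res0$trace), 1L)
  # traces never decrease
  expect_false(is.unsorted(res$trace$value))
  expect_equal(res$value, res$trace$value[nrow(res$trace)])
})

test_that("all engines are seed-deterministic with monotone traces", {
  d <- generate_distance_matrix(15, seed = 21, structure = "clustered")
  ds <- core_dataset(distances = d)
  st <- stop_condition(max_evals = 3000)
  for (engine in list(random_descent, parallel_tempering,
                      genetic_algorithm)) {
    a <- engine(ds, ene_config(), 5, st, seed = 31)
    b <- engine(ds, ene_config(), 5, st, seed = 31)
    expect_identical(a$core$selected, b$core$selected)
    expect_equal(a$value, b$value)
    expect_false(is.unsorted(a$trace$value))
    expect_equal(a$value, a$trace$value[nrow(a$trace)])
    expect_equal(a$core$k, 5)
  }
})

test_that("parallel tempering escapes local optima on small instances", {
  cfg <- ene_config()
  st <- stop_condition(max_evals = 20000)
  hits <- 0
  for (i in 1:5) {
    d <- generate_distance_matrix(12, seed = 500 + i,
                                  structure = "clustered")
    ds <- core_dataset(distances = d)
    bf <- brute_force_optimum(ds, cfg, 4)
    pt <- parallel_tempering(ds, cfg, 4, st, seed = 600 + i)
    hits <- hits + (abs(pt$value - bf$value) < 1e-12)
  }
  expect_gte(hits, 4)
})

test_that("GA crossover produces valid children of the parent union", {
  withr::with_seed(1, {
    for (i in 1:20) {
      p1 <- sort(sample.int(20, 6))
      p2 <- sort(sample.int(20, 6))
      child <- coresampler:::ga_crossover(p1, p2, 6)
      expect_equal(length(child), 6L)
      expect_true(all(child %in% union(p1, p2)))
    }
    # identical parents reproduce themselves
    p <- sort(sample.int(20, 6))
    expect_equal(coresampler:::ga_crossover(p, p, 6), p)
  })
})

test_that("delta-evaluated swaps agree with full re-evaluation", {
  geno <- generate_genotypes(synthetic_spec(n = 40, loci = 25,
                                            seed = 13,
                                            missing_rate = 0.1))
  ds <- core_dataset(genotypes = geno)
  cfg <- objective_config(list(objective("E-NE", 0.3),
                               objective("A-NE", 0.3),
                               objective("HE", 0.2),
                               objective("avg-EE", 0.2)))
  pd <- coresampler:::prepare_search_data(ds, cfg)
  chk <- coresampler:::cpp_delta_check(pd$dist_list, pd$spec, pd$geno,
                                       pd$locus_of, pd$n, 8L, 1000L, 17)
  expect_lt(max(abs(chk$incremental - chk$full)), 1e-12)
})

test_that("stop conditions validate and bound the evaluation count", {
  expect_error(stop_condition(), "at least one")
  d <- generate_distance_matrix(20, seed = 3)
  ds <- core_dataset(distances = d)
  res <- random_descent(ds, ene_config(), 5,
                        stop_condition(max_evals = 123), seed = 2)
  expect_equal(res$evals, 123)
  res2 <- parallel_tempering(ds, ene_config(), 5,
                             stop_condition(max_evals = 2000), seed = 2)
  expect_lte(res2$evals, 2000)
})
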