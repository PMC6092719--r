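test_that("core sizes resolve from fractions with round-half-up", {
  expect_equal(resolve_core_size(1000, fraction = 0.2), 200L)
  expect_equal(resolve_core_size(4428, fraction = 0.1), 443L)
  expect_equal(resolve_core_size(10, k = 3), 3L)
  # clamped to the feasible range
  expect_equal(resolve_core_size(10, fraction = 0.01), 2L)
  expect_error(resolve_core_size(10, k = 3, fraction = 0.5), "exactly one")
  expect_error(resolve_core_size(10, fraction = 1.2), "fraction")
})

test_that("run_sampling is reproducible and writes the core report", {
  dmat <- generate_distance_matrix(25, seed = 31,
                                   structure = "clustered")
  dpath <- tempfile(fileext = ".csv")
  write_distance_matrix(dmat, dpath)
  out1 <- tempfile()
  out2 <- tempfile()
  cfg <- run_config(distances = dpath, fraction = 0.2, method = "pt",
                    seed = 5, max_evals = 3000, out = out1)
  res1 <- run_sampling(cfg)
  cfg$out <- out2
  res2 <- run_sampling(cfg)
  expect_equal(res1$core$k, 5L)  # 0.2 * 25
  expect_identical(readLines(out1), readLines(out2))
  expect_true("DMIN" %in% names(res1$report))
  expect_match(readLines(out1)[1], "^# E-NE ")
})

test_that("YAML run configs load and validate", {
  dmat <- generate_distance_matrix(20, seed = 32)
  dpath <- tempfile(fileext = ".csv")
  write_distance_matrix(dmat, dpath)
  ypath <- tempfile(fileext = ".yaml")
  writeLines(c(
    paste0("distances: ", dpath),
    "size: 4",
    "method: rd",
    "seed: 9",
    "max_evals: 2000",
    "objectives:",
    "  - measure: E-NE"), ypath)
  res <- run_sampling(ypath)
  expect_equal(res$core$k, 4L)
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("nonsense: 1"), bad)
  expect_error(read_run_config(bad), "unknown config key")
})

test_that("pareto sweeps cover the weight grid with valid cores", {
  d <- generate_distance_matrix(20, seed = 33, structure = "clustered")
  ds <- core_dataset(distances = d)
  sw <- pareto_sweep(ds, objective("E-NE"), objective("A-NE"), 4,
                     step = 0.25, runs = 2,
                     stop = stop_condition(max_evals = 2000),
                     seed = 77, method = "rd")
  expect_equal(nrow(sw$table), 5L)
  expect_equal(sw$table$alpha1, seq(0, 1, 0.25))
  for (wcores in sw$cores) {
    for (core in wcores) expect_equal(core$k, 4L)
  }
  # means over the two runs match the recorded per-run values
  expect_equal(sw$table$mean_a[1],
               mean(sw$values$raw_a[sw$values$alpha1 == 0]))
  # 21 rows for the default step of 0.05
  expect_equal(length(seq(0, 1, 0.05)), 21L)
  expect_error(pareto_sweep(ds, objective("E-NE"), objective("A-NE"),
                            4, step = 0.3), "divide")
})

test_that("endpoint sweep runs match plain single-objective runs", {
  d <- generate_distance_matrix(18, seed = 34, structure = "clustered")
  ds <- core_dataset(distances = d)
  st <- stop_condition(max_evals = 2000)
  sw <- pareto_sweep(ds, objective("E-NE"), objective("A-NE"), 4,
                     step = 0.5, runs = 1, stop = st, seed = 40,
                     method = "rd")
  # alpha1 = 1: objective A alone, unnormalized, same sub-seed
  direct <- random_descent(ds, ene_config(), 4, st, seed = 41)
  expect_equal(sw$cores[[3]][[1]]$selected, direct$core$selected)
  # alpha1 = 0: objective B alone
  direct_b <- random_descent(ds, objective_config(list(
    objective("A-NE"))), 4, st, seed = 41)
  expect_equal(sw$cores[[1]][[1]]$selected, direct_b$core$selected)
})

test_that("compare_algorithms summarizes seeded runs per method", {
  d <- generate_distance_matrix(15, seed = 35, structure = "clustered")
  ds <- core_dataset(distances = d)
  cmp <- compare_algorithms(ds, ene_config(), 4,
                            methods = c("rd", "pt", "gdopt"),
                            runs = 3,
                            stop = stop_condition(max_evals = 2000),
                            base_seed = 50)
  expect_equal(nrow(cmp$summary), 3L)
  expect_equal(cmp$summary$method, c("rd", "pt", "gdopt"))
  expect_equal(nrow(cmp$runs), 9L)
  # deterministic baseline: zero spread across seeds
  expect_equal(cmp$summary$sd[cmp$summary$method == "gdopt"], 0)
  # traces exported for the stochastic engines
  expect_true(all(c("rd", "pt") %in% cmp$traces$method))
})

test_that("the CLI samples, simulates and reports", {
  tmp <- tempfile()
  dir.create(tmp)
  owd <- setwd(tmp)
  on.exit(setwd(owd))
  expect_equal(cli_main(c("simulate", "--n", "12", "--loci", "20",
                          "--seed", "3", "--out", "syn")), 0L)
  expect_true(file.exists("syn-genotypes.csv"))
  expect_true(file.exists("syn-distances.csv"))
  status <- cli_main(c("sample", "--distances", "syn-distances.csv",
                       "--size", "4", "--method", "rd",
                       "--objective", "E-NE:1", "--seed", "2",
                       "--max-evals", "2000", "--out", "core.txt"))
  expect_equal(status, 0L)
  core_lines <- readLines("core.txt")
  expect_equal(sum(!grepl("^#", core_lines)), 4L)
  expect_equal(cli_main(c("bogus")), 1L)
})
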