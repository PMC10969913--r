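test_that("simulation is deterministic in the seed and seeds differ", {
  cfg <- simulation_config(n_background = 200, n_planted_f = 5,
                           n_planted_m = 5, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$call_sets, b$call_sets)
  c <- simulate_cohort(simulation_config(n_background = 200, n_planted_f = 5,
                                         n_planted_m = 5, seed = 12))
  expect_false(identical(a$truth, c$truth))
})

test_that("planted variants follow the truth-table presence contract", {
  sim <- simulate_cohort(simulation_config(
    n_background = 300, carrier_prob = 0.5,
    n_planted_f = 20, n_planted_m = 15, seed = 3
  ))
  pm <- build_presence_matrix(sim$call_sets, sim$patients)
  ids <- rownames(pm$cells)
  is_f <- sim$patients$sex == "F"
  for (status in c("planted_f", "planted_m")) {
    planted_ids <- variant_id(sim$truth[sim$truth$status == status, ])
    block <- pm$cells[ids %in% planted_ids, , drop = FALSE]
    own <- if (status == "planted_f") is_f else !is_f
    expect_true(all(block[, own] == "P"))
    expect_true(all(block[, !own] == "A"))
  }
  # background variants: none absent everywhere (resampling contract)
  expect_true(all(rowSums(pm$cells == "P") >= 1))
  # every simulated background variant made it into the matrix
  expect_equal(nrow(pm$variants), nrow(sim$truth))
})

test_that("a carrier probability of 1 makes every background variant shared", {
  sim <- simulate_cohort(simulation_config(
    n_background = 100, carrier_prob = 1,
    n_planted_f = 0, n_planted_m = 0, seed = 5
  ))
  pm <- build_presence_matrix(sim$call_sets, sim$patients)
  res <- filter_sex_specific(pm)
  expect_true(all(res$pattern == "shared"))
  expect_true(all(res$p_two_sided == 1))
  expect_false(any(res$significant))
})

test_that("the filter recovers exactly the planted set when background cannot split", {
  for (seed in c(2, 9)) {
    sim <- simulate_cohort(simulation_config(
      n_background = 150, carrier_prob = 1,
      n_planted_f = 10, n_planted_m = 10, seed = seed
    ))
    pm <- build_presence_matrix(sim$call_sets, sim$patients)
    res <- filter_sex_specific(pm)
    rec <- evaluate_recovery(sim, res)
    expect_equal(rec$recall, 1)
    expect_equal(rec$precision_planted, 1)
    expect_equal(rec$n_false_splits, 0L)
    expect_equal(sum(res$significant), 20L)
  }
})

test_that("background false perfect splits match their permutation-null rate", {
  # 4v4 at carrier_prob 0.5: P(split) = 2 * 0.5^8 conditioned on presence
  sim <- simulate_cohort(simulation_config(
    n_background = 5000, carrier_prob = 0.5,
    n_planted_f = 0, n_planted_m = 0, seed = 17
  ))
  pm <- build_presence_matrix(sim$call_sets, sim$patients)
  res <- filter_sex_specific(pm)
  p_split <- 2 * 0.5^8 / (1 - 0.5^8)
  expected <- 5000 * p_split
  sigma <- sqrt(5000 * p_split * (1 - p_split))
  expect_true(abs(sum(res$significant) - expected) <= 3 * sigma)
})

test_that("simulated region classes follow the configured distribution", {
  cfg <- simulation_config(n_background = 1e5, carrier_prob = 1,
                           n_planted_f = 0, n_planted_m = 0, seed = 23)
  sim <- simulate_cohort(cfg)
  observed <- table(factor(sim$truth$region_class,
                           levels = names(cfg$region_dist)))
  gof <- suppressWarnings(
    stats::chisq.test(observed, p = cfg$region_dist)
  )
  expect_gt(gof$p.value, 0.01)
  # indel fraction within binomial noise of its configured value
  n_indel <- sum(sim$truth$variant_type == "InDel")
  expect_equal(n_indel / 1e5, cfg$indel_frac, tolerance = 0.01)
})

test_that("written cohorts are byte-stable and round-trip through the readers", {
  cfg <- simulation_config(n_background = 120, carrier_prob = 0.6,
                           n_planted_f = 8, n_planted_m = 6, seed = 31)
  sim <- simulate_cohort(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(sim, d1)
  write_cohort(sim, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("byte-stable", f))
  }

  sheet <- read_sample_sheet(file.path(d1, "sample_sheet.csv"))
  call_sets <- lapply(file.path(d1, sheet$vcf_path), read_patient_calls)
  names(call_sets) <- sheet$patient_id
  pm_file <- build_presence_matrix(call_sets, sheet)
  pm_mem <- build_presence_matrix(sim$call_sets, sim$patients)
  expect_identical(pm_file$cells, pm_mem$cells)
  expect_equal(pm_file$variants, pm_mem$variants)

  ann <- read_annotation_table(file.path(d1, "annotation.tsv"))
  expect_equal(nrow(ann), nrow(sim$truth))
})

test_that("infeasible simulation configs are rejected", {
  expect_error(simulation_config(carrier_prob = 1.5))
  expect_error(simulation_config(n_f = 0))
  cfg <- simulation_config(n_background = 100, seed = 1)
  cfg$n_background <- 1e10  # beyond the per-chromosome address space
  expect_error(simulate_cohort(cfg), "infeasible")
})
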