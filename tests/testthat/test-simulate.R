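test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 400, seed = 5)
  a <- simulate_hybrid(cfg)
  b <- simulate_hybrid(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_hybrid(cfg, seed = 6)
  expect_false(identical(a$counts, c2$counts))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(mode_proportions = c(ADD = 0.5, ODO = 0.4)), "mode_proportions")
  p <- c(ADD = 0.5, HPD = 0.2, LPD = 0.1, ODO = 0.1, UDO = 0.05,
         PPD = 0.05, NPD = 0.1) # sums to 1.1
  expect_error(sim_config(mode_proportions = p), "sum to 1")
  expect_error(sim_config(effect_fold = 0.5))
})

test_that("counts are non-negative integers and TE flags follow te_fraction", {
  sim <- simulate_hybrid(sim_config(n_genes = 500, te_fraction = 0, seed = 3))
  for (col in c("count_P1", "count_P2", "count_F1")) {
    v <- sim$counts[[col]]
    expect_true(all(v >= 0 & v == round(v)))
  }
  expect_false(any(sim$annotation$is_te))
  expect_true(all(sim$counts$length_bp >= 200))
  sim2 <- simulate_hybrid(sim_config(n_genes = 500, te_fraction = 0.5, seed = 3))
  expect_gt(sum(sim2$annotation$is_te), 100)
})

test_that("true rates respect each mode's geometry", {
  sim <- simulate_hybrid(sim_config(n_genes = 2000, seed = 12))
  tr <- sim$truth
  hi <- pmax(tr$lambda_P1, tr$lambda_P2)
  lo <- pmin(tr$lambda_P1, tr$lambda_P2)
  mid <- (hi + lo) / 2
  eps <- 1e-8
  expect_true(all(abs(tr$lambda_F1 - mid)[tr$true_mode == "ADD"] < eps))
  expect_true(all((tr$lambda_F1 > hi * (1 + 1e-9))[tr$true_mode == "ODO"]))
  expect_true(all((tr$lambda_F1 < lo * (1 - 1e-9))[tr$true_mode == "UDO"]))
  expect_true(all(abs(tr$lambda_F1 - hi)[tr$true_mode == "HPD"] < eps))
  expect_true(all(abs(tr$lambda_F1 - lo)[tr$true_mode == "LPD"] < eps))
  ppd <- tr$true_mode == "PPD"
  expect_true(all(tr$lambda_F1[ppd] > mid[ppd] & tr$lambda_F1[ppd] < hi[ppd]))
  npd <- tr$true_mode == "NPD"
  expect_true(all(tr$lambda_F1[npd] < mid[npd] & tr$lambda_F1[npd] > lo[npd]))
})

test_that("an all-additive Poisson run hits midparent scaling on average", {
  p <- c(ADD = 1, HPD = 0, LPD = 0, ODO = 0, UDO = 0, PPD = 0, NPD = 0)
  sim <- simulate_hybrid(sim_config(n_genes = 5000, mode_proportions = p,
                                    dispersion = 0, seed = 4))
  mid_expected <- (sim$truth$lambda_P1 + sim$truth$lambda_P2) / 2 # equal lib sizes
  ratio <- sum(sim$counts$count_F1) / sum(mid_expected)
  expect_lt(abs(ratio - 1), 0.01) # law of large numbers at n = 5000
  # expected RPKM matches the configured abundance within sampling error
  expr <- call_expressed(sim$counts)
  lam_rpkm <- 1e9 * sim$truth$lambda_F1 /
    (lib_sizes(sim$counts)[["F1"]] * sim$counts$length_bp)
  expect_lt(abs(sum(expr$rpkm_F1) / sum(lam_rpkm) - 1), 0.02)
})

test_that("injected enrichment concentrates the mode on the chromosome", {
  cfg <- sim_config(n_genes = 4000, seed = 17,
                    injected_enrichment = list(chromosome = "C07",
                                               mode = "LPD", fold = 5))
  sim <- simulate_hybrid(cfg)
  tr <- sim$truth
  rate_lpd <- mean(tr$chromosome[tr$true_mode == "LPD"] == "C07")
  rate_bg <- mean(tr$chromosome[tr$true_mode != "LPD"] == "C07")
  expect_gt(rate_lpd, 3 * rate_bg)
})

test_that("a simulated experiment round-trips through a directory", {
  sim <- simulate_hybrid(sim_config(n_genes = 50, seed = 2))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  counts <- read_count_table(file.path(dir, "counts.tsv"),
                             file.path(dir, "sizes.yaml"))
  expect_equal(counts$count_F1, sim$counts$count_F1)
  expect_equal(lib_sizes(counts), lib_sizes(sim$counts))
  ann <- read_results(file.path(dir, "annot.tsv"))
  expect_equal(ann$chromosome, sim$annotation$chromosome)
  expect_equal(ann$go_terms, sim$annotation$go_terms)
})

test_that("recovery reports validate ids and handle degenerate calls", {
  sim <- simulate_hybrid(sim_config(n_genes = 100, seed = 6))
  perfect <- tibble::tibble(gene_id = sim$truth$gene_id,
                            mode = sim$truth$true_mode)
  rec <- recovery_report(perfect, sim$truth)
  expect_equal(rec$accuracy, 1)
  expect_true(all(rec$per_mode$recovery == 1))

  all_other <- dplyr::mutate(perfect, mode = "OTHER")
  rec2 <- recovery_report(all_other, sim$truth)
  expect_equal(rec2$accuracy, mean(sim$truth$true_mode == "OTHER"))

  alien <- tibble::tibble(gene_id = "nope", mode = "ADD")
  expect_error(recovery_report(alien, sim$truth), "absent")
})
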